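---
title: "Time-averaged NMR restraints on a coarse-grained bead chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-averaged NMR restraints on a coarse-grained bead chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tardyn)
```

## The problem

NMR observables are time and ensemble averages.  The NOE-derived distance
between two protons reflects a millisecond-scale average of $d^{-6}$ (in
practice $d^{-3}$ for time averaging along a trajectory), so for a flexible
or multistate protein no single conformation needs to satisfy all distance
restraints simultaneously.  Restrained molecular dynamics that forces every
restraint onto every frame therefore collapses a genuinely heterogeneous
ensemble onto an artificial compromise structure.  The remedy is to restrain
*time averages* of the measured quantities over a trailing memory window of
the trajectory.

`tardyn` implements a numerically stable variant of this idea on a
deliberately small model — a single-bead-per-residue C$^\alpha$ chain with a
declared toy potential — so that every claim about the *algorithm* (energy
conservation, thermostat behaviour, restraint-force scaling, ensemble
recovery) can be tested end to end in seconds to minutes.  The algorithm
itself is exactly the production scheme used with full coarse-grained
protein force fields; only the underlying force field is a stand-in.

## Restraint potentials

All restraints are flat-bottom wells with Gaussian walls.  For a distance
$d$ with bounds $[d_l, d_u]$, depth $A$, wall width $\sigma$ and
large-distance slope $\kappa$:

$$
V_\mathrm{dist}(d) =
\begin{cases}
 -A\,e^{-(d_l-d)^2/2\sigma^2} & d < d_l\\
 -A & d_l \le d \le d_u\\
 -A\,e^{-(d-d_u)^2/2\sigma^2} + \kappa\,(d-d_u) & d > d_u .
\end{cases}
$$

The small slope $\kappa = 0.01$ kcal mol$^{-1}$Å$^{-1}$ keeps a gentle
restoring gradient at large distances without forcing the fulfilment of
mutually contradictory restraints; $\sigma$ defaults to 1 Å (the larger
attractor region appropriate for time-averaged runs; 0.5 Å, used for
non-averaged restraints in earlier practice, remains configurable).  The
value of the potential meets the tail with a slope discontinuity of
magnitude $\kappa$ at $d_u$; this kink is accepted and bounded by
$\kappa = 0.01$.  Virtual-bond-angle restraints ($\theta$, default depth
1 kcal/mol) and virtual-bond-dihedral restraints ($\gamma$, default depth
5 kcal/mol) use the same construction without a linear tail; the dihedral
well is periodic, using the wrapped angular distance to the nearer
boundary, so $V(\gamma) = V(\gamma + 360^\circ)$.  Angular wall widths are
not fixed by convention; the default of $10^\circ$ gives the angular wells
a reduced-unit geometry comparable to the distance term and is
configurable.  Equivalent-site groups (e.g. methyl protons) are supported
as index groups whose cross distances are $r^{-6}$-combined with equal
weights inside each conformation.

## Exponential-memory time averaging

The restrained quantity $y_j$ enters the penalty not with its momentary
value but with

$$
\bar y_j(t) = \left[\frac{1}{\tau(1-e^{-1})}
  \int_{t-\tau}^{t} e^{-(t-s)/\tau}\, y_j(s)^{-m}\, ds\right]^{-1/m},
$$

with $m = 3$ for distances and $m = -1$ (direct averaging) for angles;
dihedrals average their sines and cosines and recover the angle through
`atan2`.  The memory is truncated at one window length $\tau$, which makes
the printed normalization $\tau(1-e^{-1})$ exact up to quadrature error.

Discretely, the integral is committed in blocks of `n_ave` steps: each
committed block stores the simple average of $y^{-m}$ over the block,
the block $k$ positions back carries weight $e^{-k\,n_\mathrm{ave}\Delta
t/\tau}$, and blocks older than $\tau$ are evicted from the ring buffer.
*Between* commits the momentary value stands in for the current block with
weight one.  Two properties follow and are tested:

* within a block the extended energy depends only on the current
  coordinates and frozen history, so a microcanonical run conserves the
  total energy inside every block (it jumps at commits);
* once the window is full, the total weight approaches
  $\tau(1-e^{-1})/(n_\mathrm{ave}\Delta t)$ block units, so the momentary
  term — and with it the restraint gradient — is attenuated by
  $n_\mathrm{ave}\Delta t/[\tau(1-e^{-1})]$.

That attenuation would turn restrained dynamics into effectively
unrestrained dynamics.  The forces (never the energies) are therefore
scaled by a factor $f_i$ that grows from 1 to
$f_\mathrm{max} = (1-e^{-1})\tau/(n_\mathrm{ave}\Delta t)$ over
$N_\tau$ steps ($\lfloor\tau/\Delta t\rfloor$ by default).  The growth is
linear in the step index; only the endpoints and duration are fixed by the
method, and a linear ramp is the simplest monotone choice.  At a frozen
geometry with a filled window the scaling cancels the attenuation exactly,
which the test suite verifies to within quadrature error (well below the
2% budget).  Replica-exchange acceptance always uses the *unscaled*
restraint energies — scaled energies differ so much between replicas that
no exchange would ever be accepted.

The weighted window sums are recomputed exactly from the ring buffer at
every commit rather than updated by a decay-and-subtract recursion; this
costs $O(K_\mathrm{max})$ per commit and makes a run resumed from a
checkpoint bit-identical to an uninterrupted one.

Numerical behaviour worth knowing: with scaled forces the lag between
$y$ and $\bar y$ makes the restraint forces non-conservative across
commits, and a microcanonical run heats steadily — the canonical-mode
analogue is an elevated kinetic temperature that shrinks as $\tau$ and
`n_ave` grow (the test suite asserts this monotonicity between
$\tau = 4.89$ ps, `n_ave = 1` and $\tau = 489$ ps, `n_ave = 1000`).
Production settings of $\tau = 48.9$ ps with `n_ave = 500` (or 489 ps
with 1000) keep the elevation to a few tens of kelvin on the toy systems
here, mirroring the behaviour reported for full coarse-grained force
fields.  Well depths much beyond 5 kcal/mol destabilize time-averaged
runs; 5 kcal/mol is the default compromise.

## The toy chain and force field

The model is a chain of C$^\alpha$ beads (mass 110 amu, virtual bond
$b_0 = 3.8$ Å).  The declared stand-in potential has harmonic bonds
($k_b = 20$ kcal mol$^{-1}$Å$^{-2}$), harmonic virtual-bond angles
($\theta_0 = 105^\circ$, $k_\theta = 0.005$ kcal mol$^{-1}$deg$^{-2}$), a
small cosine dihedral series ($c_1 = 0.2$, $c_3 = 0.3$ kcal/mol) and a
purely repulsive WCA excluded-volume term ($\epsilon = 0.5$ kcal/mol,
$\sigma_\mathrm{ev} = 4$ Å, zero with zero slope at $2^{1/6}\sigma$).
The constants were chosen so that the stiffest virtual-bond normal mode
(period $\approx 360$ fs) is resolved about 70-fold by the production time
step of 4.89 fs and 700-fold by the diagnostic step of 0.489 fs.  The
model is intentionally minimal: it has no side chains, no chirality, no
temperature-dependent terms and no correlation potentials, so passing
tests demonstrate properties of the restraint algorithm, not the realism
of the force field.

Starting structures are generated residue by residue from the N terminus:
each dihedral is drawn uniformly on $(-180^\circ, 180^\circ]$, each angle
from the Boltzmann weight of the harmonic angle term at 300 K, overlaps
closer than 3.7 Å (where the excluded-volume energy reaches a few $kT$)
are rejected with up to 100 retrials per residue before backtracking one
residue.

## Dynamics

Velocity Verlet integrates the equations of motion; the Langevin
thermostat uses the BAOAB splitting (exactly velocity Verlet at zero
friction, fluctuation–dissipation at the bath temperature otherwise), and
the Berendsen thermostat rescales velocities with
$\lambda = \sqrt{1 + (\Delta t/\tau_B)(T_\mathrm{bath}/T_\mathrm{kin}-1)}$.
The base friction is 0.01 fs$^{-1}$, so a friction scale of 0.05 — the
conventional "scaled-down water friction" — gives a velocity correlation
time of 2 ps on the bead scale.  Kinetic temperature uses
$N_\mathrm{dof} = 3n$ (no centre-of-mass correction; Langevin dynamics
does not conserve momentum), with $3n-3$ available for NVE diagnostics.
Runs abort with their step index when a coordinate passes $10^4$ Å or an
energy turns non-finite, in preference to silent NaN propagation.
Temperature replica exchange swaps bath temperatures (not coordinates)
between neighbours with Metropolis probability
$\min\{1, e^{(\beta_a-\beta_b)(E_a-E_b)}\}$ on the extended potential
energy with unscaled restraint terms; each replica owns an independent
seeded RNG stream.

## Ensemble analysis

Ensemble-averaged distances are
$\bar d = (\sum_l w_l d_l^{-6})^{-1/6}$ with normalized conformation
weights.  Violations against the upper bounds are summarized by
$\rho_u^+ = [\tfrac1{N_d}\sum_i \max(\bar d_i - d^u_i, 0)^2]^{1/2}$,
the count of violated restraints and the count of excesses of at least
2 Å.  Structure comparison uses Kabsch superposition (proper rotations
only, via SVD) and GDT_TS as the mean percentage of beads within 1, 2, 4
and 8 Å — computed after a single whole-chain superposition, a documented
lower-bound variant of the multi-superposition GDT search, chosen for
reproducibility without external software.  Ensembles are reduced by Ward
(minimum-variance, Lance–Williams) clustering on the pairwise RMSD matrix;
families are ranked by cumulative weight and represented by the member
with the lowest per-conformation $\rho_u^+$ against the restraint set —
the simplest consistent per-structure violation score, since ensemble
averaging does not apply to a single frame.  Ties break to the lowest
index, making the clustering deterministic given the ensemble order.

## Synthetic restraints and what the experiments show

`synthesize_restraints()` turns one or more reference conformations into a
distance-restraint table: every bead pair at sequence separation of at
least two whose (weight-normalized) $r^{-6}$-average distance lies within
a cutoff (8 Å by default, an NOE-like contact range) becomes a restraint
with bounds $\bar d \mp 0.5$ Å.  The package's scaled-down experiments,
wired into the test suite and `scripts/acceptance.R`, are:

* **Microcanonical stability** — a 25-bead chain restrained to its own
  start structure, $\Delta t = 0.489$ fs, $10^5$ steps: with
  instantaneous restraints the total energy stays constant to well below
  0.001 kcal/mol; with time-averaged restraints and the energy-scaling
  diagnostic it is constant inside each `n_ave` block and jumps at
  commits.  The conservation measurement uses constant scaling
  ($N_\tau = 0$, as in the microcanonical diagnostics the scheme was
  designed against) and the early, still-thermally-clean segment of the
  run, because the commit-lag heating described above accumulates in NVE.
* **Canonical temperature control** — Berendsen-thermostatted runs
  (4 seeds, $5\times10^5$ steps at 4.89 fs) hold a 300 K bath to within a
  few hundredths of a kelvin in the second-half average.
* **Two-reference recovery** — restraints $r^{-6}$-averaged (weights
  0.5/0.5) over two 15-bead reference chains more than 6 Å apart.  The
  references are themselves random chains, screened so that each one alone
  is recoverable to below about 2 Å by non-averaged restrained MD — the
  single-reference control without which "recovering" a reference would be
  meaningless.  Four seeded Langevin trajectories per mode
  ($\tau = 48.9$ ps, `n_ave = 500`, $10^6$ steps at 4.89 fs): the
  time-averaged mode visits within 2.5 Å of *both* references, while the
  instantaneous mode collapses toward one and never reaches the other.

Problem sizes throughout (15–25 beads, $10^5$–$10^6$ steps, 4 trajectories
per condition) are the package's chosen desk-scale study conditions: large
enough for the phenomena — block-wise conservation, thermostat control,
between-structure alternation — to be unambiguous, small enough that the
whole suite re-runs routinely.

## Known limitations

* The toy force field is achiral and has no side chains; mirror images of
  a reference satisfy its distance restraints exactly.  The recovery
  experiments measure proper-rotation RMSD to the stated reference, so
  mirror visits simply do not count as recovery.
* Replica-averaged (as opposed to time-averaged) restraints, WHAM
  reweighting, ambiguous NOE assignment beyond equivalent-site groups,
  variable time steps and $\phi/\psi\to\theta/\gamma$ bound conversion are
  out of scope; ensemble weights are user inputs.
* The run configuration format is YAML (one structured-text dialect was
  needed; YAML has first-class R support).  Unknown keys are rejected and
  every run echoes its fully resolved configuration and seed.
* Checkpoints serialize the full averaging state and the RNG stream as an
  RDS file; resumed runs are bit-identical, which the suite asserts.

## A minimal session

```{r example, eval = FALSE}
ff <- toy_forcefield()
ref <- generate_random_chain(20, seed = 1)
set <- synthesize_restraints(ref, cutoff = 8, pad = 0.5)
cfg <- md_config(n_steps = 200000, dt = 4.89, restraint_mode = "time_averaged",
                 tau = 48900, n_ave = 500,
                 thermostat = thermostat_spec("langevin", T_bath = 300),
                 seed = 2)
rec <- run_trajectory(generate_random_chain(20, seed = 3), ff, set, cfg)
D <- t(vapply(rec$conformations, function(cf) measure(cf, set)$dist,
              numeric(length(set$distance))))
violation_report(r6_ensemble_average(D),
                 vapply(set$distance, `[[`, numeric(1), "d_u"))
```
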