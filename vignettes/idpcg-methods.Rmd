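---
title: "Coarse-grained heteropolymer simulation of disordered proteins: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained heteropolymer simulation of disordered proteins: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpcg)
```

## The model

`idpcg` represents an intrinsically disordered protein (IDP) as a chain of
$N$ beads, each assigned one of four types: neutral (`P`), cohesive (`H`),
positively charged (`+`) or negatively charged (`-`). The reduction is
motivated by the observation that disorder and compaction of IDPs are
largely controlled by the balance of order-promoting (hydrophobic),
disorder-promoting (polar) and charged residues — prominently so for FG
nucleoporins, whose cohesive FG/FxFG/GLFG patches are interspersed with
polar spacers.

Bonded neighbours interact through a FENE spring; all pairs repel through
a soft 8–6 Lennard-Jones core; cohesive pairs additionally attract through
an 8–6 tail of depth controlled by the cohesiveness $\epsilon$ (in units
of $k_BT$, the model's main control parameter); charged pairs interact via
a screened Coulomb (Debye–Hückel) potential with dimensionless prefactor
$Q$ and Debye length $L_D$:

$$U_{rep}(r) = \epsilon_{LJ}\left[\left(\tfrac{b}{r}\right)^{8}
  - \tfrac43 \left(\tfrac{b}{r}\right)^{6}\right]
  + \tfrac13(\epsilon_{LJ}-\epsilon_{pair}), \quad r < b,$$

$$U_{coh}(r) = \epsilon\left[\left(\tfrac{b}{r}\right)^{8}
  - \tfrac43\left(\tfrac{b}{r}\right)^{6}\right], \quad b < r < 4b, \qquad
U_Q(r) = Q\, z_i z_j \frac{e^{-r/L_D}}{r}.$$

The contact distance is $b = (B_i+B_j)/2$ with $B = B_0 = 3/2$ for neutral
and cohesive beads and $B_+ = 2.44$, $B_- = 2.29$ for the charged beads
(relative volumes of lysine and glutamate); bonded pairs use $b = B_0$.
The constant shift of the repulsive branch makes the potential continuous
at contact, where the combined cohesive pair potential has its minimum,
$-\epsilon/3$. The cohesive tail is truncated (not shifted) at $4b$, where
it has decayed to about 0.1% of its depth; the resulting force
discontinuity of order $10^{-4}\epsilon$ is accepted. The model has no
bond-angle or dihedral terms and spherically symmetric beads; these are
the main idealisations relative to atomistic chains.

### Units

Lengths are measured in $x_c = \sqrt{2k_BT/k} = \tfrac23 b_0$, time in
$t_c = \xi_0/k$ ($\xi_0 = 6\pi\eta a_0$ is the Stokes drag of the
reference bead of radius $a_0 = B_0/2$) and forces in $f_c = 2k_BT/x_c$.
In these units the FENE force is exactly $R/(1-(R/L_{max})^2)$ with
$L_{max} = 2B_0 = 3$, and pair forces are $-\tfrac12\,dU_{kT}/dr$. One
length unit corresponds to roughly 0.28 nm (the nominal bond length of
1.35 units ~ 0.38 nm between adjacent C$\alpha$ atoms); the default
$L_D = 4$ then corresponds to ~1.1 nm, i.e. about 75 mM monovalent salt.
The nominal bond length 1.35 is the minimum of the FENE-plus-repulsion
bond potential; because the potential is soft, the thermal mean bond
length is slightly larger (about 1.50).

### Dynamics

Configurations evolve by the overdamped Ermak–McCammon step
$$\Delta X = M F \,\Delta T + H\, \Delta W, \qquad H H^\top = M,$$
with $\Delta W$ i.i.d. Gaussian of variance $\Delta T$ per component and
$\Delta T = 0.001$ by default. With hydrodynamics on, $M$ is the
Rotne–Prager–Yamakawa (RPY) tensor in units of $1/\xi_0$, including the
overlapping-sphere correction for $r < 2a$ so the matrix is positive
definite for every configuration, and $H$ is its lower Cholesky factor.
Unequal-radius pairs (only the charged beads differ, by a few percent)
use the mean radius $a = (A_i + A_j)/2$ inside the equal-radius RPY form.
The spurious-drift term $\nabla\cdot D$ of the general Ermak–McCammon
scheme vanishes identically for RPY and is omitted. With hydrodynamics
off ("free draining") all cross blocks are zero and the step reduces to
per-bead Langevin updates; equilibrium statics are unaffected by this
choice, which the test suite verifies.

Numerical safeguards: a proposed step that would stretch any bond to
$L_{max}$ or beyond is rejected and retried with fresh noise (a bounded
number of times). At $\Delta T = 0.001$ rejections are vanishingly rare,
so the perturbation of the stationary distribution is negligible; this
was preferred over clamping, which would bias bond statistics. Nonbonded
forces use a Verlet neighbour list with per-pair-type cutoffs and a skin
of 1.2 units, rebuilt when the two largest accumulated displacements sum
past the skin — a strictly conservative trigger. Electrostatics are
truncated at $5 L_D$ (the interaction there is below 1% of its contact
scale); the cutoff is configurable. With RPY, the mobility matrix and its
Cholesky factor can be recomputed every `cholesky_stride` steps as a
documented speed approximation; the default is every step.

The integrator is held to exact references in the test suite: a
two-bead chain reproduces the quadrature Boltzmann bond density
(Kolmogorov–Smirnov distance < 0.01 at $10^6$ samples), a three-bead
chain matches exact quadrature moments of $R_e^2$ and $R_g^2$ to about a
percent, a free bead has per-component displacement variance exactly
$\Delta T$, and equilibrium dimensions agree with hydrodynamics on and
off.

### Initial conditions and replicas

Runs start from self-avoiding random walks: fixed bond length 1.35,
uniform random directions, nonbonded pairs kept at least $B_0$ apart by
per-bead retries with whole-chain restarts. Because placements are grown
bead by bead with local retries, this ensemble is noticeably more
compact than the equilibrium coil, so a leading segment of every run is
discarded. The end-to-end vector is the slowest mode: free draining its
relaxation time is of order $10^6$ steps at $N = 100$ (the Rouse
estimate $2N^2b^2/3\pi^2$ time units), which dictates both the discard
length and the error analysis. For long chains the package
therefore also offers `init = "pivot"`: a pivot Metropolis Monte Carlo
pre-equilibrator (random tail rotations accepted on the full potential
energy) that decorrelates global shape orders of magnitude faster than
local dynamics. Its one caveat — pivots never change bond lengths — is
immaterial because bonds rethermalise within a few time units of
Brownian dynamics; the swollen-statics acceptance checks run from pivot
initial states. Replica
sub-seeds are drawn once from the master seed, making every ensemble
reproducible from a single integer while keeping replicas independent.

## Observables

Per frame: end-to-end distance $R_e = |\vec R_1 - \vec R_N|$, gyration
tensor and its eigenvalues $\lambda_x \ge \lambda_y \ge \lambda_z$
($R_g^2 = \sum\lambda$), and asphericity
$\delta = 1 - 3(\lambda_x\lambda_y + \lambda_y\lambda_z +
\lambda_z\lambda_x)/R_g^4 \in [0, 1]$ (0 for a sphere, 1 for a rod).
Degenerate all-coincident frames would make $\delta$ a 0/0; they are
flagged and excluded rather than defined to zero. The Kirkwood
hydrodynamic radius averages reciprocal distances over frames *first* and
inverts afterwards,
$R_k = [N^{-2}\sum_{i\ne j}\langle 1/r_{ij}\rangle]^{-1}$; the order
matters and is fixed by the estimator's definition. The true hydrodynamic
radius is estimated separately from the centre-of-mass mean-squared
displacement via Stokes–Einstein ($R_h = a_0/(2D_e)$ in simulation
units); the MSD fit window is configurable and defaults to the upper
decade of available lags, which the single-bead and dimer tests justify.

Conditional end-to-end distributions $p(R_e\,|\,R_g)$ bin both quantities
at width 0.5 simulation units; bins with fewer than 100 frames are
flagged low-confidence. The reference model treats the two chain ends as
independent uniform points in a ball of radius $R^* = \sqrt5\,R_g$ — the
radius is fixed by requiring the model's second moment to equal
$6R_g^2$, and the closed-form density
$p(d) = 3d^2/R^{*3} - 9d^3/(4R^{*4}) + 3d^5/(16R^{*6})$ integrates to 1
with mean $36R^*/35$. Analytic anchors used in the tests: uniform-ball
ensembles give $R_e^2/R_g^2 = 2$, $R_g/R_h = \sqrt{3/5} \approx 0.774$
and $R_g/R_k = \tfrac65\sqrt{3/5} \approx 0.93$; freely jointed chains
give $R_e^2/R_g^2 = 6N/(N+1)$. The classical theta-solvent ratio
$R_g/R_k \approx 1.5$ is an *asymptotic* statement: the Kirkwood double
sum carries an $O(1/\sqrt N)$ discreteness deficit (about
$1.4/\sqrt N$, i.e. the exact freely-jointed value is $\approx 1.30$
at $N = 100$ and $\approx 1.46$ at $N = 1600$), so the package computes
the reference value by finite-size extrapolation of the ratio against
$1/\sqrt N$ over a ladder of chain lengths.

## Dynamic observables

The end-to-end *rotation* correlation is the dot-product autocorrelation
of the end-to-end vector, normalised by $\langle R_e^2\rangle$ with no
mean subtraction; the *reconfiguration* correlation is the
mean-subtracted, variance-normalised autocorrelation of the scalar
distance $|R_e|$. Both are computed by an FFT estimator (zero-padded,
lag-wise normalised) that the tests hold to within $10^{-10}$ of the
direct $O(n^2)$ sum; a `method = "direct"` path exposes the brute-force
estimator. Correlation times integrate the normalised correlation by the
trapezoidal rule up to $3\tau_e$, where $\tau_e$ (located by linear
interpolation between bracketing lags) is the first crossing of $e^{-1}$;
a correlation that never crosses $e^{-1}$ is an error, not a number. For
a pure exponential this truncation returns $0.9502\,\tau_0$, the figure
the synthetic Ornstein–Uhlenbeck recovery test checks. Replica
correlation functions are averaged first and integrated once.

Multimodality of $p(R_e)$ is diagnosed on the 0.5-unit histogram after
Gaussian kernel smoothing with a bandwidth of one bin; raw histogram
maxima are too noisy at desk scale. Peaks below 5% of the modal mass are
ignored, so tail noise does not count as a second state.

## Sequence patterning metrics

The sequence charge decoration is
$\mathrm{SCD} = N^{-1}\sum_{i>j} q_i q_j \sqrt{i-j}$, with the
square-root distance weighting of the original definition — the variant
that reproduces the reference scores for the cohesive/neutral
patch family ($q_P = +1$, $q_H = -1$): $-0.410$, $-0.537$, $-0.778$,
$-1.002$, $-1.319$ for patch sizes 1–5 at 30H/30P. For polyampholytes
$q = \pm1$ on charged residues. SCD is returned signed as computed
(magnitude conventions differ across the literature — the blocky 50-mer
polyampholyte is usually quoted as its magnitude 2.070); `abs()` gives
the magnitude. The blob-based $\kappa$ uses window sizes $\{5, 6\}$, the
local charge asymmetry $\sigma = (f_+-f_-)^2/(f_++f_-)$ (windows with no
charges contribute $\sigma = 0$), and normalises by $\delta_{max}$ of the
maximally segregated arrangement of the same composition (all negative,
then neutral, then positive) rather than a global search — the standard
construction; the exact appendix-level variant used elsewhere is not
reproducible from the main-text definition, so this choice is documented
rather than inferred.

## Effective-homopolymer calibration

Homopolymer reference curves (observable vs $\epsilon$) are isotonized
before piecewise-linear inverse interpolation, so sampling noise cannot
make the inverse multivalued. The mapping from sequence cohesiveness to
equivalent-homopolymer cohesiveness is fitted by least squares to
$\epsilon_h = (e^{a\epsilon}-1)/b$ for points before the coil-to-globule
inflection; the inflection cutoff is user-specified because no robust
automatic rule exists at desk-scale noise. In the small-$a$ limit the
form degenerates to a line of slope $a/b$, which the fit handles
gracefully. Patterning-score regressions (e.g. $R_g/R_k$ vs SCD) use
isotonic regression (pool-adjacent-violators) followed by a 3-point
moving average; both the fitted step function and the smoothed curve are
returned.

## Scaled-down study protocol

Paper-scale runs of this kind of model use $10^8$ steps per replica. The
package's tests and the acceptance script use a documented desk-scale
protocol chosen to fit a single CPU: chains of $N \le 100$; for swollen
statics at $N = 100$, at least 4 replicas of $\ge 5\times10^6$ steps with
a discard of a slow-mode relaxation time or more; for the fast
$\theta$-point smoke test, $N = 50$ with the crossing of
$R_e^2/R_g^2 = 6$ only located within $[0.6, 0.9]\,k_BT$ (the crossing
is weakly $N$-dependent); qualitative sequence-patterning comparisons at
$\ge 10^7$ steps per condition; hydrodynamic (RPY) runs at $N \le 60$
where the dense Cholesky factorisation stays affordable. At these scales
slow-mode statistics, not per-step cost, dominate the error budget: the
end-to-end ratio at $N=100$ carries a few percent standard error, the
mean asphericity a standard error of several hundredths, and integrated
correlation times tens of percent. Statistical acceptance checks in the
test suite therefore compare point estimates to their reference bands
with an explicit allowance of about two estimator standard errors
(between-replica or jackknife), and heavy campaigns start from
pivot-pre-equilibrated states so the discarded segment stays short.

What the synthetic fixtures do and do not show: freely jointed chains and
uniform-ball point pairs validate the observable estimators against
closed forms — they say nothing about the force field; the bead-spring
ensembles validate the sampling machinery; none of them capture
bond-angle stiffness, side-chain geometry, or sequence-specific
atomistic effects, so quantitative transfer to real IDPs is at the level
of trends and ratios, not absolute dimensions.

## Known limitations

- Isotropic pair potentials cannot limit the valence of cohesive
  contacts (no $\pi$-stacking anisotropy), which favours compact ordered
  globules for blocky sequences slightly more than atomistic models do.
- Dense RPY hydrodynamics costs $O(N^2)$ memory and $O(N^3)$ per
  Cholesky refresh, limiting hydrodynamic runs to a few hundred beads.
- Single chains only; no periodic boundaries or multi-chain assemblies.
- The Euler–Maruyama discretisation carries an $O(\Delta T)$ stationary
  bias; at the default $\Delta T$ it is below the statistical resolution
  of every test in the suite (verified by halving and quartering
  $\Delta T$).

## A worked example

```{r example, eval = FALSE}
library(idpcg)
library(dplyr)

# patterning metrics of the 60-mer patch family
metrics <- sequence_metrics(tibble::tibble(
  spec = c("(HP)30", "(PHHP)15", "(PHHHPP)10", "PP(HHHHPPPP)7HH",
           "(PPHHHHHPPP)6")))
metrics

# a short simulation of the alternating 60-mer near its theta point
cfg <- simulation_config(n_steps = 2e6, n_equil = 4e5, n_runs = 2, seed = 1,
                         forcefield = forcefield(eps = 2.8))
traj <- run_simulation("(HP)30", cfg)
ensemble_summary(traj) |> tidy()
```
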