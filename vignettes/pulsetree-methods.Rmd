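---
title: "Methods: one-dimensional haemodynamics with structured-tree outflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-dimensional haemodynamics with structured-tree outflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pulsetree simulates pulse-wave propagation in patient-specific arterial
networks and calibrates wall-stiffness and outflow parameters against flow
and cuff-pressure measurements. This vignette is the package's account of
the underlying model, the numerical choices, and what the synthetic-data
experiments do and do not demonstrate.

## The large-vessel model

Each artery is a one-dimensional compliant tube. With cross-sectional area
$A(x,t)$ (cm²) and volumetric flow $q(x,t)$ (ml/s), mass and momentum
balance read

$$A_t + q_x = 0, \qquad
q_t + \left(\frac{q^2}{A}\right)_x + \frac{A}{\rho}p_x
  = -\frac{2\pi\nu R}{\delta}\,\frac{q}{A},$$

where the friction term comes from a Stokes boundary layer of thickness
$\delta = \sqrt{\nu T / 2\pi}$ (flat core profile, linear shear layer at the
wall). The tube law closing the system is

$$p - p_0 = \frac{4}{3}\,\frac{Eh}{r_0}\left(1 - \sqrt{A_0/A}\right),
\qquad \frac{Eh}{r_0} = k_1 e^{k_2 r_0} + k_3,$$

with $k_2 < 0$: smaller vessels are stiffer. Junctions impose flow
conservation and pressure continuity, $q_p = q_{d1} + q_{d2}$,
$p_p = p_{d1} = p_{d2}$. The linearised pulse-wave speed at the unstressed
state is $c_0 = \sqrt{2Eh/(3\rho r_0)}$.

Vessels are grouped (four large-vessel groups, four small-vessel groups) so
that stiffness constants are shared within a group; the canonical
17-vessel aortic-arch network (`canonical_network()`) carries these labels,
cohort-mean dimensions for the native-aorta (DORV) and reconstructed-aorta
(HLHS) single-ventricle groups, and termination radii for its nine terminal
vessels. Geometry outside an imaged region is obtained by allometric
scaling, $L_2 = L_1 (W_1/W_2)^{0.35}$.

## Structured-tree outflow

Each terminal vessel is loaded with a self-similar asymmetric binary tree
of small vessels: daughters scale the radius by $\alpha = 0.9$ and
$\beta = 0.6$, lengths are $\ell = \mathrm{lrr}\cdot r$ with
$\mathrm{lrr} = 50$, and branches terminate once the radius falls below
$r_\mathrm{min}$ (0.001 cm, arteriolar; 0.01 cm for the descending aorta,
which is truncated at a larger calibre). In the small vessels inertia is
negligible and the linearised equations admit the frequency-domain
solution; one vessel maps its distal impedance $Z(L,\omega)$ to

$$Z(0,\omega) =
\frac{i g^{-1} \sin(\omega L/c) + Z(L,\omega)\cos(\omega L/c)}
     {\cos(\omega L/c) + i g\, Z(L,\omega) \sin(\omega L/c)},$$

with $g = \sqrt{C A_0 (1 - F_J)/\rho}$, $c = \sqrt{A_0(1-F_J)/(\rho C)}$,
compliance $C = 3A_0 r_0/(2Eh)$, and the Womersley factor
$F_J = 2J_1(w_0)/(w_0 J_0(w_0))$, $w_0^2 = i^3 r_0^2\omega/\nu$. At
$\omega = 0$ the analytic Poiseuille limit
$Z(0,0) = 8\mu L/(\pi r_0^4) + Z(L,0)$ replaces the (singular) formula.
Terminal branches see zero impedance; daughters combine in parallel.
The Bessel-function ratio is evaluated by a continued fraction for
$|w_0| \le 15$ and by its large-argument asymptotic series above (relative
error about $10^{-6}$ at the crossover, falling as $|w_0|^{-4}$).

Two numerical choices matter here:

* **Smooth termination (pinch ramp).** With a hard cutoff the tree
  topology, and with it the root impedance, jumps every time a branch
  crosses $r_\mathrm{min}$ as $\alpha$, $\beta$ or lrr vary. That makes the
  calibration objective discontinuous and traps gradient-based optimisers.
  pulsetree therefore ramps the termination: a daughter with radius in
  $[0.9\,r_\mathrm{min}, r_\mathrm{min})$ is kept as a terminal stub whose
  length shrinks smoothly to zero, and below $0.9\,r_\mathrm{min}$ it is a
  zero-impedance short, i.e. the terminal boundary condition applied at the
  junction. The root impedance is then a C¹ function of the tree
  parameters. For radii away from the narrow ramp zone the hard-cutoff
  description is recovered exactly.
* **Time-domain coupling.** The spectrum at harmonics $2\pi k/T$ is
  extended by conjugate symmetry and inverse-transformed into a real
  periodic kernel $z_m$ with $p(L,t_m) = p_0 + \sum_j z_j q(L, t_{m-j})$;
  the kernel sums to the DC resistance. Harmonics above
  `kernel_harmonics` (default 512; 64 in the desk-scale configuration)
  are extended flat at the last computed value, which is accurate because
  the root impedance plateaus at high frequency.

## The solver

The nonlinear system is advanced by the explicit two-step
(Richtmyer) Lax–Wendroff scheme in conservation form. The pressure
gradient is written in a well-balanced form that vanishes identically at
the unstressed state, so a tapered vessel at rest is an exact discrete
equilibrium — without this, coarse grids leak several percent of the mean
flow in strongly tapered segments. Boundary nodes are conservative
half-cells: their area update uses the interior half-step mass flux and
the boundary flow, so in the periodic regime the cycle-averaged flow
telescopes exactly from the inlet through every junction to the terminals
(global mass balance is then limited only by residual non-periodicity).
The remaining boundary unknowns are closed by the physical conditions
(prescribed inflow; junction continuity, solved by Newton iteration;
terminal impedance convolution). The unstressed radius between the
measured end radii follows an exponential taper
$r_0(x) = r_\mathrm{in}(r_\mathrm{out}/r_\mathrm{in})^{x/L}$ (a linear
taper is available).

Runs start from $A = A_0$, $q = 0$ and repeat cardiac cycles until the
mid-vessel pressure is cycle-periodic to `periodicity_tol` (default
$10^{-3}$ relative L2) or for a fixed cycle count. The time step satisfies
`dt <= cfl * dx / max(|u| + c)`; when not supplied, the number of steps per
cycle is chosen automatically from the unstressed wave speeds with a
safety margin, rounded up to a multiple of 64. Inside calibration loops
the step count must not change between parameter evaluations (the
objective would jump), so `choose_nt()` pins one CFL-safe value for the
whole sweep, with the stiffness inflated by a margin covering the bounds,
and a fixed cycle count (four in the desk-scale configuration) keeps the
objective smooth and deterministic. An optional conservative
second-difference dissipation (`visc`) is available for extreme
geometries and is off by default.

Default problem sizes: two grid points per cm (at least five per vessel),
CFL 0.5. The canonical 17-vessel run then uses about 360 grid nodes and
8192 steps per cycle and reaches periodicity in about seven cycles. The
desk-scale three-vessel configuration uses one point per cm (at least
four), CFL 0.8, four cycles, and about 1280 steps per cycle.

## Post-processing

Wave-intensity analysis splits pressure/velocity increments into forward
and backward components, $dp_\pm = (dp \pm \rho c\, d\bar u)/2$,
$d\bar u_\pm = (d\bar u \pm dp/(\rho c))/2$, cumulates them from the first
sample, and forms time-normalised intensities
$WI_\pm = (dp_\pm/dt)(d\bar u_\pm/dt)$. The wave speed used is the local
linearised $c_0$ (a PU-loop estimate could be substituted). The reflection
coefficient is the ratio of the largest compressive excursions (total rise
over a maximal run of positive $dp_\pm$) of the backward and forward
components; with no incident compressive wave it is flagged missing. Wall
shear stress uses the boundary-layer formula $\tau_w = \mu \bar u/\delta$
with dynamic viscosity (a stress requires dynamic, not kinematic,
viscosity). Pulse metrics (systolic/diastolic/pulse pressure, pulse flow,
relative area deformation) are max/min summaries of the final cycle.

## Sensitivity, identifiability, inference

Sensitivities of the flow-residual vector are taken with respect to
log-scaled parameters (positivity plus common scale); the decaying
exponents $k_2, k_{s2}$ are carried as positive magnitudes and applied
with the negative sign. Local analysis uses centred differences with step
$\psi = 0.01$ and ranks by column 2-norm. Morris screening perturbs one
parameter at a time on an $M = 60$-level grid with step
$\Delta = M/(2(M-1)) \approx 0.508$ in unit-hypercube coordinates
(stiffness ±10%, tree constants ±5% about nominal), draws $K = 100$
elementary effects per parameter, summarises each by the residual 2-norm,
and ranks by $\mu^{*2} + \sigma^2$ (ties by $\mu^*$). The covariance
analysis forms $V = s^2 (\tilde S^\top \tilde S)^{-1}$ and flags pairs
with $|v_{nj}| > 0.9$; a singular information matrix is handled by a
pseudo-inverse and reported as structural non-identifiability. Subset
selection drops parameters below a relative influence cutoff and, within
each flagged pair, fixes the lower-ranked member (average of local and
Morris ranks), with an audit log.

The calibration objective is the residual sum of squares of four
flow-waveform blocks, each normalised by the site's peak measured flow,
plus two relative cuff-pressure residuals at the brachial (or cuff-site)
midpoint. It is minimised by box-bounded Levenberg–Marquardt on the
log-parameters with finite-difference Jacobians (tolerance $10^{-8}$).
Two robustness choices were needed and are deliberate design decisions:

* **Logit bounds.** Hard projection onto the box interacts badly with the
  trust-region step and falsely pins parameters at bounds; bounds are
  instead enforced by a smooth logit reparameterisation.
* **Stiff-first staging.** Parameter influences span orders of magnitude
  (the tree asymmetry ratio dominates); a plain start lets the first
  Gauss–Newton steps overshoot the weakly identified directions into
  spurious basins. Each start therefore first optimises the top-ranked
  parameters alone (ranking by local sensitivity), then all parameters.

Multistart inference draws 12 starts uniformly within ±30% of nominal,
computes the coefficient of variation of each parameter across converged
starts, and while any CV exceeds 0.10 remediates and repeats: per-group
copies of a constant are first collapsed to one global value, and a
parameter without a family to collapse is removed (fixed at nominal). The
reported estimate is the minimum-RSS start; fit quality is the per-site
$R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ against the site-mean
waveforms.

## Synthetic patients

`generate_patient()` builds complete, seed-reproducible test subjects: a
geometry-jittered network (log-normal, σ = 0.05, preserving the
HLHS arch-wider-than-ascending-aorta signature), a half-sine ejection
inflow with cardiac output and cycle length drawn from the observed cohort
ranges (CO 2.8–5.4 l/min, T 0.598–0.942 s) sampled at 19–28 points per
cycle, a ground-truth forward solve, and emulated measurements: five
replicates per site with 5% multiplicative Gaussian noise, per-vessel
bias factors of 5–15% that deliberately violate mass conservation (as
velocity-encoded imaging does) and are removed by the minimum-norm
rescaling, and a cuff pair offset by 2 mmHg measurement noise. Truth
parameters are the cohort nominals, so the DORV and HLHS twins differ in
stiffness the way the cohorts do.

The generator uses a reference pressure $p_0 = 45$ mmHg. The structured
trees truncated at the stated radii with zero terminal impedance supply a
total DC resistance of only ~0.5 mmHg s/ml for the canonical network —
the resistance of the vascular bed distal to the truncation is not part
of the model — and $p_0$ represents that distal pressure head so that
emulated cuff pressures fall in the observed clinical range. It is a
constant common to data generation and calibration and does not influence
the inference.

The desk-scale twin used in tests and in `scripts/acceptance.R` is the
rooted three-vessel subnetwork (aortic arch II, left subclavian,
descending aorta) with four calibration sites (mid/outlet of each
daughter vessel), the cuff at the subclavian midpoint, and the subset
{tree asymmetry, k3 per group, global ks2, ks3 per group} — six
parameters for the two groups present.

What these experiments show: the full pipeline — rescaling, sensitivity
ranking, multistart with pruning — is internally consistent, recovers
known truth from its own forward model at the injected noise level, and
reproduces the identifiability structure (the weakly informative
subclavian wall stiffness is the parameter the CV criterion removes).
What they do not show: robustness to model misfit. The twins are
generated by the same discretisation that fits them, so discretisation
and model-structure error, registration artefacts, and the divergence
structure of real velocimetry noise are all outside the evidence the
tests provide.

## Known limitations

* Junction energy losses are not modelled. The cohort-mean HLHS
  geometry — a narrow, expanding subclavian beside a wide reconstructed
  arch — develops near-sonic velocities at mean cardiac output, and the
  explicit scheme then fails (flow collapse) regardless of resolution.
  Full-network synthetic twins therefore default to the DORV cohort;
  reduced twins work for both cohorts and carry the HLHS stiffness
  nominals.
* The interior scheme is second order, but the boundary treatment is
  lower order; mean quantities are protected by the conservative
  half-cell closure, not pointwise accuracy at the junctions.
* The structured trees use constant viscosity (no radius-dependent
  rheology) and zero terminal impedance; mean pressure levels are set by
  the truncated-tree resistance plus the reference pressure, not by a
  physiological total peripheral resistance.
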