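---
title: "Methods: free-energy profiles, landscapes and kinetics in fepland"
author: "fepland authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy profiles, landscapes and kinetics in fepland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepland)
```

# Scope

`fepland` implements the analysis layer of a QM/MM mechanistic study of
enzyme catalysis, exercised here on the workflow typical of serine-hydrolase
(Ser-Ser-Lys urethanase) systems: free-energy profiles along intrinsic
reaction coordinate (IRC) paths by free energy perturbation (FEP), harmonic
vibrational corrections at stationary points, assembly of multi-step
free-energy landscapes with an effective (rate-determining) barrier,
Eyring transition-state-theory (TST) kinetics, titration-curve analysis of
constant-pH simulation output, and descriptive trajectory statistics. The
quantum-chemistry and molecular-dynamics engines that *produce* the inputs
(QM/MM energies, IRC paths, constant-pH sampling, long MD) are out of
scope; paths, energies and samples are inputs here. A synthetic-data module
generates every input with known ground truth, so the whole pipeline is
testable end to end without external engines or downloads.

All energies are kcal/mol, lengths Angstrom, masses amu, wavenumbers
cm^-1, temperatures K. Constants are CODATA-2018, exposed as
`phys_constants` (R = 1.987204e-3 kcal/(mol K)).

# Mass-weighted path coordinate

An IRC path is an ordered sequence of QM-subsystem structures in a common
frame. The path coordinate accumulates the mass-weighted Cartesian
displacement between consecutive structures,

$$ s_i = s_{i-1} + \Big[\sum_{j \in \mathrm{QM}} m_j\,
   \big(\Delta x_{j}^2 + \Delta y_{j}^2 + \Delta z_{j}^2\big)\Big]^{1/2}, $$

with $s_1 = 0$ and units amu$^{1/2}$ Å. The mass is per atom ($m_j$) inside
the sum — the standard mass-weighted metric of IRC theory. No superposition
is applied between consecutive frames: an IRC is traced in a fixed frame,
and aligning frames would silently change increments. Only the *relative*
spacing of windows matters downstream, so no conversion to mass-weighted
atomic units is offered; the amu$^{1/2}$ Å choice is documented rather than
configurable.

# FEP free-energy profile

The free-energy change from the reference window $R$ to window $j$ is the
gas-phase QM energy difference plus accumulated interaction-term
increments,

$$ \Delta G(s_j) = \big[E^0_{QM}(s_j) - E^0_{QM}(s_R)\big]
   + \sum_{i=R}^{j-1} g_i , \qquad
   g_i = -k_BT \ln \big\langle e^{-\Delta E_i / k_BT} \big\rangle_i , $$

where $\Delta E_i$ is the difference of QM/MM interaction energies between
windows $i{+}1$ and $i$ evaluated over window $i$'s MM ensemble. This is the
Zwanzig exponential-average estimator, evaluated with an overflow-safe
log-sum-exp (finite for $|\Delta E|$ up to at least $10^4$ kcal/mol). A
second convention, `as_printed`, with the sign inside the exponential
flipped, is selectable for literal reproduction of sources that print the
inverted form; the default is validated by the Gaussian closed form
$g \to \mu - \sigma^2 / (2 k_B T)$ for $\Delta E \sim N(\mu, \sigma^2)$.

**The surrogate $\Delta E$.** Re-evaluating neighbour-window geometries on
the same MM configurations requires the original QM/MM engine. When only
each window's own interaction samples exist, the package uses window $i$'s
centred fluctuations shifted by the difference of window means,
$\Delta E_{i,k} = (x_{i,k} - \bar x_i) + (\bar x_{i+1} - \bar x_i)$. When
paired per-transition samples are available they can be passed directly
(`paired_delta_e`) and are used verbatim.

**Errors.** The standard error of one window term uses the delta method on
the variance of the exponential, with the effective sample size taken from
block averaging (default 10 blocks; serial correlation inflates the
block-mean variance and hence the error; below 20 samples the naive i.i.d.
estimate is used with a warning). On the surrogate route the mean-shift
term carries additional sampling variance from *both* window means, which
the delta method on centred samples cannot see; the window error therefore
adds the block-averaged standard errors of the two means in quadrature.
Profile errors accumulate across windows in quadrature, i.e. windows are
treated as independent — inter-window correlation of the MM ensembles is
assumed negligible and not modelled. Vibrational corrections are applied
only at labelled stationary points, as differences of the harmonic
vibrational free energy relative to the reference point.

Temperature defaults to 303 K, the production temperature of the window MD
this package is designed to post-process.

# Harmonic thermochemistry

`normal_modes()` mass-weights a Cartesian Hessian (kcal/mol/Å$^2$),
optionally applies an Eckart projection of rigid translations and rotations
(off by default — toy reduced Hessians have no meaningful rigid modes; on
for molecular fixtures, where it yields six near-zero modes), and converts
eigenvalues to wavenumbers, with negative wavenumbers encoding imaginary
modes. Classification follows the imaginary-mode count: 0 a minimum, 1 a
transition state, $\geq 2$ higher order. Modes with $|\tilde\nu| < 5$
cm^-1 are treated as numerical zeros and excluded from thermochemistry.

$$ \mathrm{ZPE} = \sum_{\tilde\nu > 0} \tfrac12 h c \tilde\nu N_A, \qquad
   G_{vib}(T) = \sum_{\tilde\nu > 0} \Big[\tfrac12 h c \tilde\nu
   + k_BT \ln\big(1 - e^{-h c \tilde\nu / k_BT}\big)\Big] N_A . $$

Real modes below a 20 cm^-1 floor contribute ZPE but not the thermal term,
whose logarithm diverges as $\tilde\nu \to 0$; the floor is configurable.
No rotational or translational partition functions are included: the
correction targets the vibrations of the QM subsystem only.

# Landscape assembly and effective barrier

A multi-step mechanism is supplied as ordered steps, each with an
activation free energy and a reaction free energy. Stitching is cumulative
— each step's reactant minimum is the previous step's product — except for
steps flagged `global_reference`, whose TS *and* product are placed
relative to the designated global reference minimum. That convention
expresses barriers quoted "from the most stable reactant state" rather than
from the local minimum, as is done for the acylation step of the urethanase
demo landscape. The hydrolysis barrier of that demo (18.2 kcal/mol) is
anchored at the acyl-enzyme minimum, its step reactant; anchoring at an
internal intermediate instead is expressible through the same enum.

The effective barrier scans every transition state against the lowest
minimum preceding it and returns the largest gap (ties: earliest TS). This
matches the "preceding minima only" usage of the demo study; no periodic
energetic-span turnover formalism is applied (a deliberate non-goal, as is
microkinetic ODE modelling). For the built-in four-step landscape
(conformational 4.5/+2.6; acylation 21.2/−16.7 global; hydrolysis
18.2/−11.1; decarboxylation 12.1/+9.1) the minima sit at 0, 2.6, −16.7,
−27.8, −18.7 and the effective barrier is 21.2 kcal/mol at the acylation
TS:

```{r landscape}
ls <- assemble_landscape(list(
  mechanism_step("conformational", 4.5, 2.6,
                 ts_label = "TSconf", product_label = "ES_active"),
  mechanism_step("acylation", 21.2, -16.7, reference = "global_reference",
                 ts_label = "TS1(A)", product_label = "EA"),
  mechanism_step("hydrolysis", 18.2, -11.1,
                 ts_label = "TS(H)", product_label = "PC(H)"),
  mechanism_step("decarboxylation", 12.1, 9.1,
                 ts_label = "TS(D)", product_label = "PC(D)")),
  start_label = "ES", global_reference_label = "ES")
print(ls)
```

# TST kinetics and progress curves

Eyring interconversion uses $k = (k_BT/h)\,e^{-\Delta G^\ddagger / RT}$
with transmission coefficient fixed at 1 (the barriers handled here are
phenomenological). 25 °C is 298.15 K. The round trip
rate → barrier → rate is exact to $10^{-10}$ relative across at least 12
decades of $k$.

Progress-curve analysis computes the turnover frequency as the
least-squares initial slope per enzyme (window default: through the third
time point, matching sampling schemes with points at 0, 1.5 and 3 h), the
total turnover number as final product per enzyme, and the inactivation
plateau by fitting $P(t) = P_\infty(1 - e^{-\kappa t})$
(first-order enzyme inactivation; Levenberg–Marquardt via `minpack.lm`,
falling back — flagged — to the maximum observed concentration if the fit
fails). Enzyme amount may be given as a molar concentration or as mass plus
molar mass; the molar mass has **no default**, so per-enzyme quantities are
only reported when the user supplies one — which is also why a printed
total turnover number cannot be reproduced from concentration data alone.
Michaelis–Menten fitting is out of scope. Beer–Lambert rates are
`slope / (epsilon * pathlength)`.

# Titration analysis

Constant-pH output is reduced to protonated fraction versus pH and fitted
with the Hill form of the Henderson–Hasselbalch curve,
$f(\mathrm{pH}) = 1/\big(1 + 10^{\,n(\mathrm{pH} - \mathrm{p}K_a)}\big)$
(base form, appropriate for lysine; an acid-form flag flips the sign). The
Hill coefficient is free by default, with a constrained $n = 1$ mode.
Raw 0/1 records are aggregated with per-pH counts used as weights. Starting
values are $\mathrm{p}K_a$ at the fraction nearest 0.5 and $n = 1$;
standard errors come from the local curvature. Classification at a working
pH uses thresholds 0.1/0.9 on the protonated fraction — pragmatic cutoffs,
configurable, with "mixed" in between. Only single-site fits are provided;
coupled multi-site titration is out of scope.

# Trajectory analysis

Distances, signed dihedrals (degrees in $(-180, 180]$, `NA` on collinear
degeneracies), population histograms (default 0.1 Å bins; counts always sum
to the frame count), Kabsch-superposed RMSD (SVD with reflection guard;
never exceeds raw RMSD), per-residue RMSD after a *single* global fit,
water-site occupancy (oxygens of water residues within a cutoff of a site
centroid; an exchange event is an identity change at constant count), and
persistent-threshold unbinding detection (defaults 10 Å / 50 frames —
pragmatic choices for a ligand-release event). Readers cover multi-frame
XYZ and a minimal multi-model PDB dialect (fixed columns, first alternate
location, no insertion codes); no binary trajectory formats, no clustering,
no free-energy estimates from populations.

# Synthetic data: what it emulates, and what it does not

Every generator draws from one explicit integer seed, restores the caller's
RNG state, and returns a machine-readable truth record alongside the data.

**FEP windows.** Windows sit at evenly spaced path coordinates on $[0,1]$
with a chosen truth profile (default: double well, 10 kcal/mol barrier,
−3 kcal/mol reaction free energy — a landscape of the magnitude typical of
enzymatic chemical steps). A fraction `qm_fraction` (default 0.5) of the
truth is carried by the gas-phase energies, the rest by the interaction
ensembles, which are Gaussian with per-window spread `noise_sigma` (default
0.5 kcal/mol, in line with ~1 kcal/mol overall error budgets) and 2000
samples per window (a free choice: per-window subsampling of ps-scale MD is
never reported in enough detail to copy). Consecutive window means are
offset by $+\sigma^2/(2 k_B T)$ beyond the truth increment, so that the
*exponential average* — the quantity the estimator computes, and for a
Gaussian ensemble the free energy — reproduces the truth; at zero noise the
mean differences equal the truth increments exactly. An optional AR(1)
coefficient adds the serial correlation real window MD has (default 0).
The generator makes no attempt to mimic force-field energetics, anharmonic
tails, or fat-tailed $\Delta E$ distributions; recovery tests therefore
demonstrate estimator correctness and calibration of the error model under
Gaussian sampling, not robustness to poorly overlapping windows.

**Titration.** Bernoulli draws per pH from the Hill curve at a chosen
$\mathrm{p}K_a$ — the exact model class of the fitter, so recovery tests
probe identifiability and precision, not model misspecification.

**Progress curves.** $P(t) = (v_0/k_{inact})(1 - e^{-k_{inact} t})$ plus
Gaussian noise, degenerating to $v_0 t$ at $k_{inact} = 0$. Defaults
($v_0 = 3.33$ uM/h, $k_{inact} = 0.12$ /h, points at 0, 1.5, 3, 19, 48,
120 h, noise 0.5 uM) emulate a low-turnover hydrolase assay that plateaus
within the first day through enzyme inactivation.

**Trajectories.** A tagged atom pair realizes a piecewise-constant distance
program (optional Gaussian jitter), with the pair distance driven past
15 Å from a programmed unbinding frame; remaining atoms are a static
scaffold. Nothing about water structure or protein flexibility is
emulated; the generator exists to give the detectors a known event.

# Numerical choices and degenerate inputs

* Log-sum-exp for all exponential averages; no overflow for
  $|\Delta E| \le 10^4$ kcal/mol.
* Zero-variance samples give exactly zero window error; single-window
  profiles are $[0]$; single-structure paths are $[s] = [0]$.
* Block averaging: 10 blocks by default; under 20 samples, naive SE plus a
  warning.
* Hessians are symmetrized after a $10^{-6}$ relative symmetry check;
  near-zero modes ($|\tilde\nu| < 5$ cm^-1) never enter thermochemistry.
* Landscape ties at the effective barrier resolve to the earliest TS.
* Degenerate dihedrals yield `NA`, never an arbitrary angle.
* Titration fits refuse all-0/all-1 fractions (non-identifiable) and fewer
  than 4 pH points.

# Problem sizes used in the shipped studies

The recovery studies run at sizes chosen to make sampling error, not
runtime, the limiting factor: 200 replicates of 21 windows × 2000 samples
for FEP recovery (with a 2000-vs-8000 sample pair for the error-scaling
check and $10^5$ samples for the Gaussian closed form), 100 replicates of
15 pH points × 5000 Bernoulli draws for titration recovery, and
1000-frame trajectories for event detection. The full suite runs in well
under a minute on one core.

# Known limitations

* The FEP estimator is one-directional exponential averaging, as in the
  workflow it reimplements; BAR/MBAR and umbrella/WHAM estimators are
  deliberately absent.
* Window independence is assumed in error propagation; correlated windows
  would make the propagated profile errors optimistic.
* The surrogate $\Delta E$ is exact for the mean-shift-plus-fluctuation
  structure the generator produces, and an approximation for real data
  whose neighbour-window re-evaluations are unavailable.
* The harmonic treatment ignores anharmonicity and mode coupling; the
  vibrational correction is only as good as the stationary-point Hessians.
* Titration fits are single-site; strongly coupled sites need a joint
  model.
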