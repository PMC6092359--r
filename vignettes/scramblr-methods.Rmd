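---
title: "Quantifying lipid scrambling and groove dynamics with scramblr"
author: "scramblr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid scrambling and groove dynamics with scramblr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblr)
```

# Scope

`scramblr` has two arms. The **assay arm** turns dithionite-bleaching
fluorescence recordings and end-point chloride flux measurements from
reconstituted TMEM16-family scramblase liposomes into rate constants,
activity fractions and mutant impact classes. The **trajectory arm**
computes the structural observables that describe how the membrane-exposed
hydrophilic groove of such a scramblase opens for lipid passage: groove and
compartment occupancy, residue-lipid contacts, the extracellular gate
(E313/E318/R432) state, lipid flip events, the TM3-TM6 opening, and a
tICA/microstate decomposition of the gating-and-translocation dynamics.
Both arms come with synthetic generators that produce inputs with exact
ground truth, so every operation is testable end to end without any
experimental recording or MD trajectory.

# The three-state bleaching model

A liposome preparation is a mixture: a fraction $f_0$ of vesicles carries
no active scramblase. Dithionite added outside bleaches the
NBD-labeled reporter lipids of the outer leaflet at rate
$\gamma = \gamma'[D]$. In protein-free vesicles the inner-leaflet reporters
are protected, so

$$F_{PF}(t) = L_i^{PF} + (1 - L_i^{PF})\,e^{-\gamma t},$$

a decay to a plateau of $L_i^{PF}$ (about 50% under symmetric labeling). In
scramblase-containing vesicles lipids exchange between leaflets with
forward/backward rate constants $\alpha$ and $\beta$, giving the three-state
scheme $L_i \rightleftharpoons L_o \rightarrow L^{*}$. Its solution from
the scramblase-generated equilibrium ($L_i(0)=\beta/(\alpha+\beta)$) is the
closed form implemented in `fScr()`, with eigenvalues

$$\lambda_{1,2} = -\tfrac{1}{2}\left[(\alpha+\beta+\gamma) \mp
\sqrt{(\alpha+\beta+\gamma)^2 - 4\alpha\gamma}\right].$$

`eigenstructure()` evaluates $\lambda_1$ through the algebraically
equivalent form $-2\alpha\gamma/\big((\alpha+\beta+\gamma)+\sqrt{\cdot}\big)$,
which avoids catastrophic cancellation when $\alpha\gamma$ is small — the
Vieta identities $\lambda_1\lambda_2=\alpha\gamma$ and
$\lambda_1+\lambda_2=-(\alpha+\beta+\gamma)$ then hold to machine
precision, and the package's tests assert them. Near-coincident eigenvalues
(relative discriminant below $10^{-12}$, reachable only when $\beta \to 0$
and $\alpha \approx \gamma$) switch to the exact degenerate-matrix
expansion $e^{\lambda t}(I + t(A-\lambda I))x_0$. The total signal is the
mixture $F_{tot} = f_0 F_{PF} + (1-f_0)F_{Scr}$; `fScr()` is verified
against adaptive ODE integration to $10^{-8}$ relative over a
100-point parameter grid.

## The leak model

Protein-free vesicles show a very slow residual decay
($L \approx 5.4\times10^{-5}\,s^{-1}$; dithionite leakage or spontaneous
flipping). We generalize it into the generative model by multiplying the
*protected* (inner-leaflet) fluorescence by $e^{-Lt}$ in both populations:
$F_{PF} = L_i^{PF}e^{-Lt} + (1-L_i^{PF})e^{-\gamma t}$ and, in scramblase
vesicles, the $L_i(t)$ component of the closed-form solution. For
$Lt \ll 1$ this reduces to the additive linear term used in the slow-regime
protocol below, while keeping one self-consistent model for simulation and
fitting.

## Fitting protocol and its constraints

The calibration chain mirrors experimental practice and is enforced by
`runAssayPipeline()`:

1. **Protein-free traces** (`fitProteinFree()`): $\gamma$ and $L_i^{PF}$ by
   bounded nonlinear least squares on the exponential phase
   ($t \le 7/\gamma$, iterated once), then $L$ from a linear fit of the
   tail ($t > 5/\gamma$), corrected for the residual exponential curvature
   by a fixed-point iteration. $\gamma'$ is never assumed; it is always
   this per-batch calibration divided by the dithionite concentration.
2. **WT(+Ca²⁺) traces** (`fitFull()` with `f0 = NULL`): $\alpha$, $\beta$
   and $f_0$ free; the batch $f_0$ is the mean over replicates.
3. **Everything else**: $L_i^{PF}$, $\gamma$, $L$, $f_0$ fixed; only
   $\alpha$ and $\beta$ free (optionally constrained $\alpha=\beta$ with
   `symmetric = TRUE`, matching the empirical near-symmetry).

Rates are optimized in $\log_{10}$ space within
$\alpha,\beta \in [10^{-7}, 50]$, $\gamma \in [0.01, 20]$ s⁻¹, from three
log-spaced starts — the multi-start guards against the $\alpha/\gamma$
exchange minimum where the fit swaps the roles of scrambling and chemistry.
Standard errors come from the Levenberg–Marquardt Hessian by the delta
method.

**Rate-limited detection.** When scrambling outruns the chemistry the
decay carries no information about $\alpha$ beyond "fast". Simulation
shows identifiability degrades above $\alpha/\gamma \approx 0.1$, so
`resolveRateLimited()` marks fits with
$\hat\alpha \ge \kappa\gamma$ ($\kappa = 0.1$) as lower bounds and reports
$\max(\hat\alpha,\ 0.2\,\gamma/2)$ — the canonical $>0.2$ s⁻¹ bound at
$\gamma = 2$ s⁻¹, rescaled to the calibrated $\gamma$.

**The linear slow regime.** For $\alpha=\beta\ll\gamma$ the
post-exponential trace is effectively linear,
$F \approx F_0 - C(\alpha+L)t$. The constant $C$ has no canonical operational definition, so we derived
it from the generative model: the tail is
$f_0 L_i^{PF} e^{-Lt} + (1-f_0)\,w\,e^{-(\lambda_1+L)t}$ with
$w=\beta/(\alpha+\beta)$, so `fitLinear()` uses $C = (1-f_0)w$, subtracts
the protein-free leak contribution $f_0 L_i^{PF} L$ from the measured
slope, corrects the curvature at the tail's time centroid by fixed-point
iteration, and converts the slow eigenvalue back to $\alpha$ through
$\lambda_1 = \alpha\gamma/(2\alpha+\gamma)$. `fitScrambling()` selects the
linear protocol automatically when $\hat\alpha\,t_{max} < 0.3$ — less than
~30% of the slow decay inside the recording, the regime (rates around
$10^{-5}$–$10^{-4}$ s⁻¹ on hour-long traces) where the full fit is poorly
conditioned and the linear approximation is accurate.

**Impact classes.** `classifyImpact()` uses the fold reduction
$\alpha_{WT}/\alpha_{mut}$ with thresholds 10 and 100 (low / medium /
high). A fold of 0.5 or below is labeled *enhanced* — the three standard
classes cover only reductions, but rate-increasing substitutions exist
and deserve a label. Rate-limited mutants are classified low, since
only a bound is known. The conversion to lipids transported per second per
protein uses $n_{lip} = 10^5$ lipids per scramblase-containing vesicle
(`transportRate()`), the unique factor consistent with both canonical
conversions ($0.2 \to 2\times10^4$ and $0.001 \to \sim100$ lipid s⁻¹).

## What the trace generator emulates — and what it does not

`simulateTrace()` produces a 30 s pre-addition unity segment followed by
$F_{tot}$ on a regular grid with i.i.d. Gaussian noise. Defaults are the
study conditions: $\gamma = 2$ s⁻¹ (protein-free decay on the seconds
scale), noise SD 0.003 of full scale, 1 Hz sampling, $f_0 = 0.55$,
$L_i^{PF} = 0.5$, leak $5.4\times10^{-5}$ s⁻¹; slow constructs are
recorded for at least 4000 s as in the slow-mutant protocol. Not modeled:
photobleaching, instrument drift beyond the linear leak, vesicle size or
protein-copy heterogeneity (per-vesicle Poisson statistics are absorbed
into the free $f_0$), and correlated noise. Passing recovery tests on this
generator therefore demonstrates correctness of the estimator under the
stated noise model, not robustness to instrument pathologies.

Monte-Carlo recovery (tested): $\alpha$ in the zero-Ca WT regime
($10^{-3}$ s⁻¹) within ±20% in >90% of seeds; the leak within ±30%;
median absolute error <25% across a log-grid
$\alpha \in [10^{-5}, 0.05]$ s⁻¹ with automatic mode selection. Problem
sizes (30–40 seeds per suite, 4000-sample traces) keep the whole test run
under a minute for the assay arm while leaving the recovery distributions
well resolved.

# Flux quantification

`activityFraction()` implements $A = 100(1 - \Delta Cl/\Delta Cl_{PF})$,
the fraction of vesicles holding at least one active channel. $A$ is
scale-invariant; negative values (sample releasing more chloride than the
protein-free reference) are retained with a warning rather than clamped,
because they diagnose a reference mismatch. The assay is an end point
without kinetic resolution, so no rate is derived from it.

# Trajectory observables

All observables are parameterized by a `GrooveDefinition`: the 34
groove-lining residues (4WIS numbering), cutoffs (3 Å water, 5 Å lipid
phosphorus, 7 Å residue-lipid contact, 3 Å gate bond, 5 Å near-pair), the
T381/Q436 compartment boundary, and the TM3 (315–318) / TM6 (432–435)
C$_\alpha$ spans. Every cutoff is closed (boundary included) — a
deterministic tie-break. Distances use the minimum-image convention for
orthorhombic boxes; triclinic cells are out of scope. "Sidechain" means
heavy atoms excluding backbone N/CA/C/O; glycine degenerates to C$_\alpha$
and is flagged. The membrane mid-point is defined per frame as the mean z
of all lipid phosphorus atoms and is centered to z = 0 on ingestion; the
compartment planes are likewise recomputed per frame so they track protein
motion.

Operational choices that protocol descriptions in this field commonly
leave open, decided here:

* The T381–Q436 slab is reported as the **central** compartment of the
  groove (it is also describable as the base of the extracellular
  vestibule); the boundary residues are configurable.
* **Near E313/R432** means within 5 Å of the union of the two residues'
  atoms, so `fLip()` counts frames with ≥2 phosphorus atoms there.
* **Lipid tilt** (which has no standard operational definition) is the angle
  between the P→tail-carbon-centroid vector and +z; 0° points
  extracellular.
* **Flip completion**: a groove lipid's P crossing z = 0 opens an event;
  completion requires reaching 10 Å beyond the mid-point on the
  destination side with the tilt consistent with tails pointing back to
  the origin leaflet (>90° for IC→EC). A lipid dipping across and
  returning yields an uncompleted event.
* **Tracked lipid** for the eight tICA features: the groove lipid with the
  largest z-range while groove-assigned, an operational stand-in for "the
  translocated lipid".
* The rare **tail-first blockade** mode is annotated (`tailBlockade()`):
  ≥3 tail carbons of a non-groove-assigned lipid inside the EC compartment
  slab within the lipid cutoff of the groove sidechains.

# tICA and microstates

`fitTICA()` solves $C(\tau)v = \lambda C(0)v$ with the lagged covariance
symmetrized and lag pairs pooled within (never across) series. $C(0)$
receives a relative ridge of $10^{-8}$; a near-singular $C(0)$ (duplicated
or constant features) additionally warns. The default lag is 10 frames, and the sensitivity over lags 5/10/20 on
the AR(1) toy is simply $\rho^\tau$, as the tests verify; the choice
rescales eigenvalues monotonically without reordering components.
"Fraction of total dynamics" is defined as the eigenvalue mass of the top
components over all positive eigenvalues (`explainedFraction()`); negative
eigenvalues estimate no slow autocorrelation and are excluded.

`kmeansMicrostates()` discretizes the 2-D score plane into k = 50 states
by default. Initialization is k-means++ with 10 restarts under a fixed
seed: uniform random initial centers essentially never cover dozens of
well-separated basins (a coupon-collector failure that plateaus near
ARI 0.9 on the 50-blob benchmark), whereas D²-weighted seeding recovers
the partition exactly. `microstateProfiles()` attaches per-state
histograms of frame-aligned structural metrics (z-distance to the R432
C$_\alpha$, tilt, T333–Y439 distance, TM3–TM6 opening).

# The toy trajectory generator

`trajScript()`/`renderToyTrajectory()` realize a declarative script —
per-frame gate states, central-constriction states, lipid paths and groove
water counts per protomer — as a two-protomer pseudo-protein with every
residue the groove definition references, plus lipids (P + two tail
carbons) and waters, in a 160×64×70 Å box. The geometry is engineered
around the cutoffs: groove sidechain atoms ring the axis at 4 Å radius
(axis lipids sit ~4.1 Å from the nearest sidechain, margin ~0.9 Å to the
5 Å cutoff), bonded gate pairs at 2.4 Å and unbonded ones at ≥5.9 Å
(margins ≥0.6 Å to the 3 Å cutoff), far molecules at ≥18 Å. Every scripted
lipid has a mirror twin at $-z$ so the membrane mid-point stays exactly at
z = 0. Jitter is truncated Gaussian (2 SD, capped at 0.25 Å) so scripted
classifications survive it; boundary-exact fixtures are generated only at
zero jitter. Ground truth comes from the schedule where the schedule *is*
the truth (gate booleans, f_int, water counts, flip events) and from a
generator-internal plain-loop distance computation on the jitter-free
coordinates for the geometric counts — scripted lipids inevitably sweep
through the near-gate zone, so those counts cannot be declared a priori.
The test suite checks the package's vectorized minimum-image machinery
against both this manifest and its own independent brute-force oracle.

The generator writes topology and coordinates as (multi-model) PDB;
readers additionally accept DCD. None of this pretends physical realism:
there is no force field, no membrane self-assembly, and the pseudo-residues
only mimic the atom names the observables need. What passing tests show is
that the *measurement* machinery is exact, not that it has been validated
against real MD force-field output.

# Numerical and reproducibility notes

* All fits are deterministic given the data; all generators take explicit
  seeds and are bit-reproducible.
* `fScr()` with zero leak evaluates the closed form verbatim; with leak it
  evaluates the leaflet components from the analytic eigen-decomposition.
  The two paths agree identically at L = 0.
* Degenerate inputs: $\alpha+\beta=0$ is protein-free kinetics (an error
  in `fScr()`, a fallback in `fTot()`); $\gamma=0$ conserves total
  fluorescence exactly; empty grooves, empty flip lists and single-frame
  trajectories produce valid degenerate reports.
* Known limitations: the linear-regime estimator assumes the symmetric
  weight $w=1/2$ unless told otherwise; contact frequencies are
  protomer-averaged by default; tICA assumes frame-equidistant sampling;
  the flux arm performs no electrode calibration.
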