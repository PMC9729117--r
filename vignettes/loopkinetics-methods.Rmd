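---
title: "LoopKinetics: models and methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LoopKinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LoopKinetics)
```

LoopKinetics connects two views of transcription-factor (TF) function
in the nucleus: the *structural* view, in which chromatin loops and
topologically associating domains (TADs) place enhancers near
promoters, and the *kinetic* view, in which a TF's output is set by how
often and how long it binds chromatin. The package provides a
self-contained analysis chain for both views — contact-map processing,
domain and loop calling, loop–expression association, and
single-molecule kinetics — together with a synthetic-data module that
generates every input with known ground truth, so that each estimator
in the package can be validated end to end.

This vignette documents the models, the algorithms, and the reasoning
behind the default parameters. The worked example in the README shows
the code path; here the emphasis is on *why* each method is built the
way it is.

# Contact-map core

## Pair orientation and binning

Chromosome-conformation reads come as position pairs with strand
information. `parsePairOrientation()` maps strand combinations to the
ligation-orientation vocabulary (IN-IN for `+/-`, OUT-OUT for `-/+`,
and the two uni-directional classes, optionally merged as UNI), and
`orientPairs()` enforces `pos1 <= pos2` (swapping strands along with
positions) and flags pairs closer than `minSep` (default 100 bp), which
are dominated by un-ligated or self-ligated fragments.

`binPairs()` uses the half-open convention: position $p$ falls in bin
$\lfloor p / \text{binSize} \rfloor$, so a position exactly at a bin
edge opens the next bin. Counts are accumulated into a symmetric
matrix; the total pair count is conserved.

## Iterative correction (ICE)

`balanceICE()` removes multiplicative per-bin biases by finding weights
$w_i$ such that the balanced matrix $w_i C_{ij} w_j$ has uniform row
sums. The fixed point is reached by repeatedly dividing each weight by
its current row sum and renormalizing; convergence is declared when the
relative variance of row sums falls below `tol`. Bins whose marginal
coverage is below a fraction of the median are masked first — balancing
cannot distinguish a poorly covered bin from a genuinely
non-interacting one, and unmasked near-empty rows destabilize the
iteration. The implementation iterates to machine precision if asked;
the unit tests verify agreement with an independent fixed-point
implementation to ~1e-14 relative error.

## Observed over expected and contact decay

`observedOverExpected()` divides each cell by the mean balanced value
of its diagonal (computed over unmasked cells only), so every diagonal
of the output has mean 1. The computation is vectorized over diagonals
with `rowsum()` on the $|i-j|$ index, which keeps it $O(n^2)$ and
fast enough for chromosome-arm-sized matrices.

`contactDecay()` estimates the contact-probability curve $P(s)$ as a
*probability density* per base pair: pairs are binned into log-spaced
separation bins and each bin's count is divided by the number of valid
pairs and by the bin width in bp. Under this convention a sample whose
separations are distributed $\propto 1/s$ gives a log–log slope of
$-1$, matching the standard P(s) literature, and an orientation-subset
curve integrates to that subset's share of valid pairs — which is how
the tests check the orientation split.

# Domains and compartments

`insulationScore()` slides a $w \times w$ diamond window along the
diagonal, averages the balanced contacts crossing each bin, and reports
$\log_2$ of the ratio to the genome-wide mean; windows clipped by the
matrix edge are `NA`. `callBoundaries()` finds local minima of the
insulation track and keeps those whose *prominence* — the height the
track rises on both sides before descending again — exceeds
`minProminence`. Prominence separates true boundaries from noise far
better than depth alone: on the simulated maps used in the test suite,
planted boundaries have prominences around 2 while noise minima sit
around 0.1, so any threshold in between (the tests use 0.5) recovers
all and only the planted boundaries. Plateau minima break ties to the
leftmost bin, deterministically.

`compartmentEigenvector()` takes the leading eigenvector of the
correlation matrix of the O/E map, with its sign anchored by
correlation with a user-supplied activity signal (positive = A
compartment). `saddlePlot()` sorts bins by eigenvector rank, aggregates
O/E into quantile blocks, and reports compartment strength as the
ratio of corner means (AA·BB)/(AB·BA) — exactly 4 on a clean 2-versus-0.5
checkerboard, which the tests assert to numerical precision.

`aggregateDomains()` rescales each domain (with flanks) onto a common
grid using an area-weighted, mass-conserving rescale operator and
averages; the interior/flank ratio quantifies domain strength.

# Loops

`scoreLoops()` computes, for each loop, the ratio of the center mean to
the mean of the lower-left corner of a $(2w+1)^2$ O/E window — the
corner that reflects the background at the same separation. Windows
clipped by the matrix edge or reaching the diagonal are `NA` rather
than silently biased. `apa()` (aggregate peak analysis) averages the
windows themselves and reports the center-to-corner ratio of the
pileup; planted dots give ratios well above 2 while random
equidistant pairs give 1.

`classifyLoops()` labels each anchor from a `ChromatinStateTrack`
(12-state chromatin vocabulary plus optional CTCF and cohesin peak
tracks) and combines anchor labels into loop classes with precedence
promoter > enhancer > polycomb > CTCF/cohesin; a "cohesin" call
additionally requires both peak tracks at both anchors, since a
CTCF-state segment without factor occupancy is weak evidence for an
extrusion anchor.

`differentialLoops()` compares per-loop scores between conditions
after median-centering the log fold-changes. Median-centering absorbs
global depth and balancing differences but is only identifiable when
*most* loops are unchanged; if half the loops change, the median
itself moves. This is an inherent limitation of unmatched-depth
designs, documented here rather than hidden: the test suite plants a
40%-depleted composition and recovers the depleted class with 100%
class-conditional accuracy.

`annotateBoundaryCrossing()` classifies loops as intra- or inter-domain
relative to a boundary list, with an anchor exclusion zone (default
1 kb): a boundary essentially *at* an anchor is a shared CTCF site, not
a crossing. `crossingRetention()` compares crossing and non-crossing
loops matched on genomic distance, and `boundaryCrossedProfile()`
contrasts the insulation profile of crossed versus uncrossed
boundaries.

# Loop–expression association

`assignExpression()` attaches gene expression to loops by overlap of
the transcription start site with anchor flanks.
`strengthExpressionCurve()` fits a LOESS curve of loop strength against
expression rank and returns pointwise standard errors; the tests check
that a planted monotone link is recovered and that a null curve is flat
relative to both its own standard errors and the linked curve.
`metageneProfile()` rescales gene bodies onto a fixed number of bins
(strand-aware) with fixed-width flanks. `degAnchorEnrichment()`
permutes gene labels to test whether differentially expressed genes
(DEGs) concentrate at loop anchors, and `degLoopCdf()` compares the
cumulative distributions of differential loop scores for DEG-anchored
versus background loops (Kolmogorov–Smirnov test plus a median shift).

# Single-molecule kinetics

## Diffusion-state mixture

`fitDiffusionMixture()` models lag-1 squared jump lengths $r^2$ as a
mixture of 2D diffusion states. For state $k$ with coefficient $D_k$,
$r^2$ is exponential with mean
$\mu_k = 4 D_k \Delta t + 4 \sigma_{loc}^2$, where $\sigma_{loc}$ is
the localization error — which is why even a chromatin-bound molecule
shows apparent motion.

Two likelihoods are available. The default, `method = "trajectory"`,
treats each trajectory as one molecule in one state: all of a
trajectory's jumps share a latent state, and the per-trajectory
likelihood depends on the data only through two sufficient statistics
(the summed $r^2$ and the jump count), so EM over thousands of
trajectories is fast and the state assignment is per molecule. This
matches how short single-particle-tracking (SPT) trajectories are
actually generated — a molecule rarely switches state within a few
frames — and in validation it recovers planted occupancies several
times more tightly than the marginal alternative.
`method = "jump"` fits the marginal mixture over pooled jumps
(optionally weighting each molecule equally), which is the textbook
formulation and the one the package's likelihood-oracle tests exercise.

Fractions are reported three ways: raw mixture weights, weights after
defocalization correction, and weights aggregated into bound / slow /
fast classes using conventional $D$ thresholds (bound $< 0.1$, slow
$0.1$–$2$, fast $> 2\ \mu m^2/s$).

**Defocalization correction.** Fast molecules leave the microscope's
detection slab (half-depth `halfDepth`, default 0.7 µm) sooner than
bound ones, so raw mixture weights over-represent slow states. The
package applies a closed-form, single-frame correction: the
probability that a molecule with coefficient $D$ remains in the slab
over one frame, averaged over a uniform axial starting position, is
computed by integrating the one-dimensional survival function, and
fractions are reweighted by its reciprocal. This is a first-order
per-molecule correction; a full time-dependent axial model is out of
scope and the residual bias is visible in the package's own validation
(fractions recovered within ±0.5 percentage points at $n = 20{,}000$
trajectories, not exactly).

Default simulation parameters (`kineticParams()`) are chosen as
representative of fast live-cell TF imaging: 7.5-ms frames, 1-ms
stroboscopic exposure, $\sigma_{loc} = 35$ nm, diffusion coefficients
0.005 / 0.5 / 5 µm²/s for the bound / slow / fast states, and a
per-frame bleach rate scaled by the exposure duty cycle. These are
calibration choices of the simulator, not measurements.

## Residence times: survival curves and FRAP

`fitSurvival()` estimates the dissociation rate from binding-duration
data recorded at long exposures (slow SPT). Durations are observed in
frames with a minimum-length filter, so the likelihood is geometric:
if the apparent rate is $k_{app}$, the number of frames beyond the
minimum is geometric with
$q = e^{-k_{app} \cdot \text{frameInterval}}$, and the maximum
likelihood estimate is closed-form. The apparent rate contains
photobleaching: $k_{app} = k_{off} + k_b \cdot
(\text{exposure}/\text{frameInterval})$, with $k_b$ the per-exposure
bleach rate. Two corrections are supported: subtracting a known $k_b$,
or fitting at several exposures and extrapolating $k_{app}$ linearly to
zero exposure. A two-exponential mixture (`model = "2-exp"`) separates
a short-lived and a long-lived bound population.

`fitFrap()` fits fluorescence-recovery-after-photobleaching curves in
the reaction-dominant regime, where recovery is limited by exchange at
binding sites: $I(t) = 1 - \sum_k A_k e^{-k_k t}$. The prebleach
baseline is checked for linear drift (warning and detrending beyond 5%
across the prebleach window) and curves without a detectable bleach
depth are rejected. A practical identifiability caveat: a residence
time comparable to or longer than the acquisition window cannot be
recovered from a noisy curve regardless of fitter quality; resolving a
~60 s component at 1% noise requires acquisitions of ~2.5 times the
residence time, which is why the package's two-state validation uses a
150 s window.

## Search kinetics

`inferSearchKinetics()` converts a bound fraction and a residence time
into the steady-state two-state quantities: pseudo-on rate
$k^*_{on} = k_{off} F / (1 - F)$ and mean search time
$\tau_{search} = 1/k^*_{on} = \tau_{res}(1-F)/F$.
`compareConditions()` and `searchTimeFoldChange()` express
between-condition changes; because $\tau_{search} \propto 1/k^*_{on}$,
a fractional decrease $d$ in the on-rate implies a $1/(1-d)$-fold
increase in search time, exactly. `bootstrapSearchKinetics()`
propagates trajectory-level resampling uncertainty through the whole
chain.

# The synthetic-data module

Every estimator above is validated against `simulateContactMap()`,
`simulateTrajectories()`, `simulateFrap()`,
`simulateBindingDurations()` and `simulateExpression()`, which share
their parameter conventions with the fitters (the same
$k_{app}$ contract, the same state vocabulary, the same orientation
rules). Contact maps are Poisson samples of an expected matrix built
from a power-law decay, TAD blocks with tunable boundary insulation,
and Gaussian loop dots with per-class amplitudes; the returned truth
object carries the planted loops, boundaries and amplitudes. Problem
sizes in the test suite (megabase maps at 2–20-kb bins, sequencing
depths from 4×10⁶ to 10⁸ pairs, 2×10⁴ trajectories) are chosen so the
full validation runs in minutes on one CPU while leaving each
estimator's signal-to-noise regime realistic.

# Limitations

* Single-chromosome containers: there is no trans-contact or
  genome-wide matrix support.
* The defocalization correction is single-frame and per-molecule, not
  a full axial diffusion model.
* Median-centered differential loop calls assume an unchanged
  majority.
* The FRAP model is purely reaction-dominant; diffusion-coupled
  recovery is not modeled.
* Simulated ground truth is idealized (Poisson counts, exponential
  dwell times, no state switching within trajectories unless
  requested); estimator performance on real data will be worse than
  the validation numbers.
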