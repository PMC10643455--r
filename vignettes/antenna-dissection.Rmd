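---
title: "Dissecting a cryptophyte soluble antenna: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a cryptophyte soluble antenna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoantenna)
```

This vignette is the package's own account of the science behind each
pipeline stage: the models it fits, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
synthetic-data suite does and does not demonstrate about real data.

## The system

Cryptophyte algae carry a soluble light-harvesting antenna of
phycobiliproteins (PBPs) packed into the thylakoid lumen. Each PBP is a
dimer of two αβ protomers; the β subunit is nearly invariant while a
diverse α-subunit family controls the quaternary structure. Three forms
matter here: *closed*; *open*, produced by a single-residue (Asp)
insertion in the α subunit immediately before the chromophore-binding
cysteine; and *open-braced*, an open form with an additional
seven-residue loop (L1) between β-strand S2 and helix H1 that partially
re-closes and stabilizes the dimer. The chromophores are linear
tetrapyrroles (bilins): phycoerythrobilin (PEB), phycocyanobilin (PCB)
and dihydrobiliverdin (DBV), distinguishable from atomic coordinates by
ring-A planarity and the coplanarity of the C–D ring linkage.

## Sequence catalogue

**Motif filter.** Candidate α transcripts are kept iff they contain
`AP-x(9–10)-C`. The filter is a plain regular expression and is
idempotent.

**Maturation.** Signal peptides end at an `A-x-A` site; cleavage falls
after the second alanine. When a precursor has several such sites, we
pick the one whose mature N-terminus carries the fewest extension
residues relative to the reference frame start (the conserved `AP`).
The selection rule among multiple sites is not uniquely determined by
the biology; minimal N-terminal extension is the choice that reproduces
the observed mature starts and is applied uniformly. A precursor with no
site is kept whole and flagged `no_AxA_site`; non-canonical cut sites
found by external predictors can be imposed explicitly.

**Deduplication.** Reads from different strains are grouped when their
mature regions are identical up to `X` misreads and truncation
(wildcard-tolerant containment, transitively closed). Each group keeps
its most complete read: cleanly cleaved before long, then longest,
fewest `X`, smallest id. Reads carrying two copies of the motif are
concatenation artefacts (tandem reads); they are flagged and excluded
from grouping. Note that wildcard matching makes deduplication slightly
aggressive when misread rates are high: two genuinely distinct subunits
differing only at misread positions can merge. The noiseless guarantees
below therefore hold at `ambiguity_rate = 0`.

**Form classification.** Each mature subunit is aligned globally
(affine gaps, BLOSUM62) to a packaged single-sequence reference frame — a
synthetic closed-form consensus starting at the `AP` motif with the
chromophore Cys at column 12 and the S2–H1 span annotated at columns
23–30. A pairwise alignment suffices because only insertion positions
relative to reference columns are needed, not a full multiple alignment.
Decision rule: an insertion anchored immediately before the Cys column →
*open*; additionally an insertion of 5–8 residues (default window;
the canonical L1 loop is 7) anchored in the S2–H1 span → *open-braced*;
smaller insertions in that span leave the form *open* (such forms are
known); neither → *closed*. Alignments scoring below 30% of the
reference self-score, or with no alignable Cys, are *unclassified*. The
5-residue lower edge of the bracing window is a configurable judgement
call: the known "smaller insertions" that do not brace are 1–4 residues
in our reading.

**Masses.** Average (not monoisotopic) residue masses plus one water,
plus 586.7 Da per PEB bilin and 16 Da per methionine oxidation — average
masses because the bilin increment is an average mass. `X` is a wildcard
for deduplication but a hard error for mass computation, carrying the
offending positions.

## Chromatogram deconvolution

Peaks are fitted with

$$f(x) = \frac{A}{\pi}\,\frac{\Gamma/2}{|x-a|^{2+\varepsilon} +
(\Gamma/2)^2},$$

with $A$ a height scaling (area-like; for $\varepsilon = 0$ the model is
the unit-area Lorentzian scaled by $A$), $\Gamma$ the width in mL, $a$
the elution position in mL and $\varepsilon$ a non-Lorentzian exponent
offset. For $\varepsilon \neq 0$ the two denominator terms carry
different implied units; the formula is nevertheless evaluated literally
on numeric mL values, as is conventional for this empirical lineshape.
A constant baseline is co-fitted per window (the data often sit on a
small pedestal from neighbouring tails). Fitting is bounded
Levenberg–Marquardt ($\Gamma > 0$, $A > 0$,
$\varepsilon \in (-1, 3)$), initialized at the window argmax, an FWHM
estimate, and $\varepsilon = 0$. Areas are adaptive quadrature over the
stated window only — matching the windowed-integration convention of the
abundance protocol — so a fitted Lorentzian's area is the closed form
$(2A/\pi)\arctan(2W/\Gamma)$, about 99.4% of $A$ for a $\pm 50\Gamma$
window.

**Saturation rescue.** Detector saturation pins 560 nm samples at a
rail. Saturated samples are detected as near-maximum runs (≥ 3 samples
within 0.5% of the channel maximum) of constant value — the constancy
requirement distinguishes a rail from a smooth noisy peak top. The
unsaturated 280 nm channel is scaled onto 560 nm by least squares over a
linear region (replacing by-eye matching; the scale's standard error is
recorded as the scaling uncertainty) and substituted over the flagged
samples only.

**Abundances.** Total signal = ∫pink560 + (7/8)·∫purple560 of the raw
traces; the 7/8 reflects the altered chromophore complement of the
purple-fraction protein (one bilin in eight absorbs elsewhere). Each
named peak's fitted area (purple peaks also scaled by 7/8) over the
total gives its fraction; fractions plus an explicit residual sum to 1
by construction. We integrate the *raw* total signal, so minor unfitted
peaks land in the residual rather than inflating named fractions.

**Default scenarios.** `antenna_scenario()` emulates the pink/purple
separation of the *H. andersenii* antenna: five peaks (555A, 555B, 560A
pink; 645A, 645B purple) whose amplitudes are solved so the windowed
procedure's ground-truth abundances equal the published headline values
(63% / 14% / 8%), with the two minor peaks in the published 8:7
proportion absorbing the ~1% window-tail residual; exponents
$\varepsilon \approx 1$ keep tails light, as observed for these sharp
ion-exchange peaks. `recovery_scenario()` is the parameter-recovery
study: three well-separated peaks of comparable height on a 0.05 mL
grid, per-peak signal-to-noise 100, the tallest peak clipped at 90% of
its height so the 280 nm rescue is always exercised. With a shared noise
floor, "SNR 100" cannot hold for peaks whose heights differ eightfold —
the smallest peak would sit at SNR ~13 and its exponent would be poorly
determined — so the study fixes SNR per peak.

## Spectra and energetics

Replicate absorption spectra are interpolated to a common grid, averaged
pointwise, and normalized to unit area (trapezoid rule) or unit maximum.
EEMs are collapsed by summing over excitation *first*; Rayleigh scatter
is then removed from the collapsed spectrum — that order follows the
stated processing of the source maps. The scatter model is
$c\,\lambda^n$ in emission wavelength, fitted by nonlinear least squares
with the amplitude parameterized in log space (the direct $(c, n)$
parameterization is catastrophically ill-conditioned for steep
exponents); the exponent's sign is unconstrained. Samples inside
fluorescence bands are excluded from the fit — by default ±3σ around
detected bands with σ from the half-width at half-maximum. Corrected
spectra keep signed residuals unless clipping is requested.

Peak finding reports local maxima above a topographic-prominence
threshold, with positions refined by a three-point parabola; the
reported uncertainty is never below the grid spacing, matching the
±1–2 nm convention for printed band positions.

The overlap integral $J = \int \bar F_D(\lambda)\,
\varepsilon_A(\lambda)\,\lambda^4\,d\lambda$ uses a donor re-normalized
internally to unit area (so $J$ ignores donor scaling) and trapezoid
quadrature on the common support. The Förster radius follows
$R_0 = 0.02108\,(\kappa^2 n^{-4} Q_D J)^{1/6}$ nm with $J$ in
M⁻¹cm⁻¹nm⁴; $\kappa^2 = 2/3$ (isotropic) and $n = 1.4$ are defaults,
both overridable, since the exact experimental choices behind the
published 50%-efficiency statement are not printed — accordingly the
package verifies $E(R_0) = 1/2$ and the distance dependence
$E = R_0^6/(R_0^6 + r^6)$, not a particular $R_0$ in nm. The lumen
packing estimate reports (floor, round) of width/diameter, which
reproduces the published "3–4 proteins" for a 12.7 nm lumen and 3.5 nm
proteins and "up to 10–13" for very-low-light widths.

## Chromophore geometry

Ring planes are total-least-squares fits (smallest principal component);
a 5-point plane fit absorbs three of the five out-of-plane degrees of
freedom, so its residual rms under coordinate noise σ is ~σ√(2/5), which
the tests assert. Dihedral pairs (θ_inner, θ_outer) walk outward from
the central rings: central-ring plane vs the three-atom methine-bridge
plane (flanking ring carbon, methine, flanking ring carbon), then bridge
plane vs outer-ring plane, acute convention. The B–C inter-plane angle
is reported as a diagnostic; it is near zero for unstrained bilins.

**Identity calls.** DBV has a planar sp2 ring A: atoms bonded to the two
tested ring-A carbons lie in the ring plane (deviation ≈ 0), whereas sp3
hybridization (PEB, PCB) pushes them ~0.72 Å out of plane (tetrahedral
geometry). The verdict thresholds a summary of those deviations at
t_lo = 0.35 / t_hi = 0.45 Å with an indeterminate band between. These
thresholds are a design choice: the ideal separation is 0 vs 0.72 Å, and
at a realistic coordinate noise of 0.1 Å per coordinate the deviation
statistic has σ ≈ 0.10–0.14 Å (direct noise plus plane tilt), so
boundaries at 0.35/0.45 leave ≳2.5σ margins on both sides; boundaries
much lower (for example 0.15 Å) would misread a noisy sp2 ring as
non-planar in a quarter of cases. For the same reason the default
verdict statistic is the *mean* of the per-substituent |deviations|
rather than their maximum — identical on ideal geometry, √2 less noisy —
with the maximum available as a conservative option.

PEB vs PCB is decided at the C–D linkage: sp2 (PCB) holds the bridge
methine in the ring D plane, sp3 (PEB) kinks it out. The call measures
the methine's elevation over the five-atom ring D plane, expressed as an
angle about the linking bond, against a 20° threshold; on ideal geometry
this equals the bridge-plane/ring-plane dihedral, but the five-atom
plane is much better conditioned under noise than the three-atom bridge
plane (≈5° vs ≈8° angle noise at 0.1 Å), which is what makes ≥95%
identity recovery at that noise level attainable.

**Surface areas and superpositions.** SASA is Shrake–Rupley sampling:
960 deterministic golden-spiral points per atom at van der Waals radius
plus a 1.4 Å probe; buried area between protomers uses the
half-difference convention (SASA_a + SASA_b − SASA_ab)/2, with the full
difference attached. Exactly coincident spheres share one surface (an
index tie-break), so duplicated atoms do not double-count. Superposition
is the SVD-based optimal rotation without reflection, pairing atoms by
chain/residue/atom-name; it is cross-checked in the tests against an
independent reference implementation.

## EM striations

The detector is Canny-style: Gaussian smoothing (σ = 2 px), Sobel
gradients, non-maximum suppression in four quantized directions, and
hysteresis at 0.1/0.2 of the maximum gradient magnitude — stand-ins for
an unnamed built-in detector, all exposed as arguments. Spacings are
measured per row (adjacent edge pixels merged into one edge at their
mean column), pooled over rows, and converted to nm; rows with odd edge
counts simply contribute their valid consecutive pairs. Whether the
original measurement pooled per-row distances or used a collapsed
profile is not determinable; per-row pooling is this package's
documented choice, and the generated square-wave images use equal dark
and light band widths so every consecutive-edge distance estimates the
same spacing.

## The synthetic-data suite — what it shows and what it does not

Every generator is seeded and bit-reproducible, writes a truth record
sufficient to score the downstream operation, and emits the same tabular
layouts the readers consume, so generators double as format round-trip
tests. Noise is additive Gaussian (Poisson optional for EEM counts).

Emulated: peak shapes, detector clipping, a 280 nm channel tracking the
clean signal; Gaussian absorption/emission bands with power-law scatter
collapsing exactly to $c\,\lambda^n$; idealized planar pyrrole rings with
exact bend/torsion constructions (the outer-ring kink is a *bend* at the
ring-linking carbon — a pure torsion about that bond cannot represent
sp3 pyramidalization, since it leaves the methine coplanar with the
ring at any angle); square-wave striations; reference-derived α-subunit
families with controlled insertions, duplicates, truncations, misreads
and tandem reads.

Not emulated — so passing tests do not certify them on real data:
correlated detector drift and baseline wander in chromatograms; real
bilin bond-length/angle heterogeneity and crystallographic anisotropy;
instrument response and inner-filter effects in EEMs; real sequence
divergence between cryptophyte genera (the generator mutates a single
reference frame); and photographic EM artefacts (charging, stain
gradients, curvature of membranes). Problem sizes used throughout
(100-replicate recovery studies, 300-case identity studies, 128×256 px
micrographs, 1101-point chromatograms) were chosen to make sampling
error a small fraction of each tolerance.

## Known limitations

- The reference frame is a single synthetic consensus; classifying α
  subunits from distant genera may need a genus-specific frame
  (`read_reference_frame()` accepts one).
- Wildcard deduplication can merge distinct subunits at high misread
  rates (see above).
- The abundance residual depends on window choices; published
  percentage tables that sum to exactly 100 are only reproducible up to
  that residual convention.
- Buried-surface-area values for deposited crystal structures require
  those coordinate files as input; the package validates its sampler
  against closed-form sphere oracles and leaves structure-specific
  values to the user's data.
- FRET distances in nm are deliberately not asserted: they depend on
  $Q_D$, $\kappa^2$ and $n$ assumptions that are exposed as parameters.
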