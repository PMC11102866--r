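---
title: "Methods: quantifying pioneer factor engagement with nucleosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pioneer factor engagement with nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucseen)
```

# Scope

Pioneer transcription factors bind their sequence motif on nucleosomal DNA
and can locally open chromatin. Characterizing such an interaction
quantitatively involves four largely independent readouts, all implemented
here: where on the nucleosome the factor binds (SeEN-seq), where nucleosomes
sit on a DNA molecule (in vitro MNase dyad mapping), how binding changes DNA
wrapping over time (smFRET two-state kinetics), and what the bound geometry
implies sterically (rigid-body structural analysis). A seeded synthetic-data
module emulates every input with ground-truth sidecars, so each estimator is
validated by parameter recovery rather than by fixtures of unknown
provenance.

# Coordinate conventions

Sequence and fragment coordinates are 0-based half-open internally (fragment
length is always `end - start`); anything user-facing — motif positions,
dyad calls, CLI output — is 1-based, the convention in which motif positions
on the Widom 601 sequence are quoted. The dyad of a 147-bp core is its
central base pair, bp 74.

Superhelical locations (SHL) count helical turns from the dyad (SHL 0),
positive toward the 3' end of the top strand, quantized to half turns. Three
conventions are configurable but have defaults chosen so that one coherent
rule reproduces all four half-integer labels quoted for the constructs this
package was validated against (+5.5 for a motif starting at bp 128 of a
147-bp core; +4, +2.5 and +0.5 for dyad registers 73, 87 and 108 of the same
native sequence):

* the SHL reference point of a motif is its **central base** (start + 4 for
  a 9-bp motif), while quoted base-pair distances refer to the start
  coordinate (position 128 is 54 bp from the dyad; its center is 58 bp out,
  58/10.4 = 5.58 turns, label +5.5);
* helical periodicity **10.4 bp/turn**, the standard twist of nucleosomal
  DNA;
* rounding to the nearest half-integer with **ties away from zero**, so
  labels are symmetric under reflection through the dyad.

When a nucleosome changes register on fixed DNA (dyad moves from `a` to
`b`), a motif's distance from the dyad changes by `-(b - a)` and the label
is re-quantized (`relocate_shl()`). Quantization means a round trip can move
a label by up to half a turn; the property suite asserts that bound.

# SeEN-seq enrichment

The library tiles a 9-bp motif at 1-bp steps across the 147-bp backbone by
substitution, giving 139 constructs (`pos1` ... `pos139`, named by 1-based
motif start). Bound and unbound fractions are sequenced together with a
spike-in of unmodified backbone. For construct $c$ in one
(replicate, fraction) library, the normalized abundance is

$$\tilde n_c = \frac{n_c / N}{n_{\mathrm{spike}} / N} = n_c / n_{\mathrm{spike}},$$

and the enrichment score is $\log_2(\tilde n_c^{\mathrm{bound}} /
\tilde n_c^{\mathrm{unbound}})$. The library size $N$ cancels algebraically;
both steps are retained for transparency, and the invariance is asserted
exactly in the tests. The spike-in scores 0 identically.

Zero counts produce `status = "missing"` with no pseudocount — tiled
libraries genuinely lose positions (the validation dataset lost motif
positions 6 and 136), and reporting gaps matches how such profiles are
published. Replicate profiles report the mean and **sample** s.d. (n − 1
denominator; with n = 3 replicates the population formula would understate
spread). Whether lost positions should be dropped before or after
normalization is ambiguous; here a zero count simply propagates to a missing
score after normalization, which is equivalent for the spike-in-ratio
estimator.

Read-to-construct assignment belongs to the upstream aligner;
`classify_reads()` is an exact-match convenience for error-free synthetic
reads only. The deposited physical library carries adapter flanks (153 bp
total); tiling operates on the 147-bp core, since flank content is chemistry
rather than analysis.

The generator draws unbound counts from a multinomial that is uniform over
constructs plus a spike-in fraction (default 0.2 of reads — large enough
that spike-in noise does not dominate the shared normalization term), and
bound counts with probabilities proportional to $2^{e_c}$. At $10^5$ reads
per fraction each construct receives ~575 reads and the per-position
standard error of the score is ~0.13 log2 units, so the 3-sigma recovery
criterion is meaningful rather than vacuous.

# MNase dyad mapping

Nucleosome-protected fragments of 145-147 bp (inclusive bounds) are kept;
the midpoint of each half-open interval, `floor((start + end - 1)/2)`, is
the inferred dyad. For even lengths this takes the lower central base — a
deterministic choice whose effect is at most half a base pair given the
3-bp length window. Dyad density is the percentage of kept dyads per
position (sums to 100); the factor-induced change is the per-bp log2 ratio
between conditions, with zero-density positions flagged undefined rather
than infinite.

Position calling is deliberately simple (the validated registers were
published as positions, not as a procedure): greedy peak picking on a
boxcar-smoothed profile (window ±3 bp), weight = fraction of kept dyads
within the window, suppression of ±10 bp around each call, stop below a
weight of 0.05. A delta peak is flat under a boxcar across the whole window,
so ties in the smoothed maximum are resolved by the raw density (then by the
lower coordinate); without that rule a call can land `window` bp early.

The generator draws dyads from a weighted mixture and centers fragments on
them (`start = dyad0 - floor((L-1)/2)`), which makes midpoint recovery exact
for every length in the default 145-147 set. At the ends of a construct a
full symmetric footprint may not fit — on the validated 180-bp construct the
registers at bp 73 and 108 cannot carry a centered 147-bp fragment — so the
length draw is conditioned per register on the footprint fitting the
reference, mimicking the stronger trimming of edge nucleosomes while keeping
recovery exact. Duplicate-fragment removal and the in vivo genome-wide
branch are upstream and out of scope.

# smFRET two-state kinetics

Input is per-molecule background-subtracted donor/acceptor intensity traces
(image-level processing is upstream). The pipeline is: per-molecule QC,
corrected FRET efficiency, threshold segmentation, exponential dwell
kinetics.

**QC.** Photobleach steps are located by the largest change point (the split
minimizing two-segment squared error; a step is accepted when it exceeds
twice the robust noise s.d. estimated from the MAD of first differences — no
numeric criterion is standard, so the threshold is noise-scaled). Accepted
molecules must show acceptor signal at the start, exactly one bleach step
per fluorophore, at least 5 frames of FRET before the first bleach, and
donor recovery after the acceptor bleach. Two implementation details
matter:

* Extra bleach steps are detected on the **leakage-corrected total**
  intensity $I_D + I_A - \alpha I_D$, which is constant through FRET
  switching and through a clean acceptor bleach; a partial (multi-step)
  bleach appears there as a dip, caught by a robust outlier-frame rule
  rather than a second change-point split (a dip's means dilute a split).
* The SSE-optimal acceptor change point can land early, at a FRET switch
  preceding the bleach, because the low-FRET acceptor level has less
  contrast against background. The bleach frame is therefore refined to the
  last frame significantly above the re-estimated post-bleach background.
  Without this refinement the recovered dwell means are biased by 5-10%.

**Efficiency.** $E = (I_A - \alpha I_D) / (\gamma I_D + I_A - \alpha I_D)$,
with leakage $\alpha$ and detection/quantum-yield ratio $\gamma$. Both are
instrument properties and are required inputs with no defaults. Frames with
a non-positive denominator are flagged invalid; values are never clipped for
fitting.

**Segmentation.** Frames with $E \geq 0.48$ (the threshold separating
wrapped from unwrapped/bound populations) are high-FRET; runs become dwells
of run length x frame interval, with first and last runs flagged censored.

**Kinetics and the discrete-sampling correction.** `fit_exponential()` is
the closed-form exponential MLE (mean of uncensored dwells; right-censored
MLE optionally). But frame-quantized dwells are *not* exponential samples:
at the validated regime (mean dwells of 9-20 s at 6-10 s frames) a naive
mean of observed run durations overestimates the low-FRET mean by >60%,
because (i) conditioning on a dwell being observed inflates run lengths
geometrically and (ii) dwells of the opposite state shorter than a frame are
missed, merging adjacent runs. An additive half-frame adjustment (in either
direction) cannot repair this — simulation at the wild-type parameters shows
residual bias of 30-90% — so the package's discrete-time correction inverts
the sampled two-state process instead. For a two-state continuous-time
Markov chain sampled instantaneously every $\Delta t$, the observed state is
itself a Markov chain with persistence

$$p_{\mathrm{stay}} = \pi + (1 - \pi)\,e^{-(k_{\mathrm{low}} +
k_{\mathrm{high}})\Delta t},$$

and the two persistences invert in closed form to both rates
(`dwell_kinetics(correction = "markov")`). Persistence is estimated by
transition counting over **all** runs, censored ones included — the
Markov-chain MLE — because using only uncensored run lengths length-biases
against long runs in short pre-bleach windows (a further ~9% bias at the
validated window lengths). Instantaneous sampling is the physically right
model here: excitation pulses (~200 ms) are short relative to the 6-10 s
frame interval. With it, the estimator recovers the generator's dwell means
to within ~2% on average (s.d. ~4% at 300 molecules); both states are
asserted within 15% in the acceptance suite. A `"half_frame"` correction is
retained for comparison, documented as subtracting half a frame (adequate
only when frames are much shorter than dwells).

Half-life is $\tau \ln 2$ and the reported rate is $1/t_{1/2}$ — the
half-life-inversion convention of the validated study — with $1/\tau$
available by using `tau` directly. Replicates are fitted separately
(pooling molecules within a replicate) and compared by a classical
pooled-variance unpaired t-test.

**Generator.** Dwells are sampled in continuous time and then quantized at
frame midpoints (not per-frame Bernoulli switching), so the correction is
testable against exact exponential truth. Defaults: efficiencies 0.75/0.25
straddling the 0.48 threshold symmetrically; total intensity 1000 a.u. with
noise s.d. 30 (flips across the threshold ~4 sigma away, i.e. negligible);
exponential photobleach times with means 600 s (acceptor) and 1500 s
(donor) against 30-min videos, giving realistic QC yields of ~25-30%;
15% donor-only and 5% multi-step molecules as QC bait. The `WT` preset uses
dwell means 16.4 s (low-FRET) / 20.27 s (high-FRET) at 10-s frames and the
`D159A` preset 9.19 s / 16.44 s at 6-s frames — the reported per-variant
averages and acquisition intervals. The generator does not model blinking,
diffusive background or baseline drift, so a green recovery test validates
the estimator under the stated noise model, not robustness to photophysics
beyond it.

# Structural geometry

Superposition is the standard SVD (Kabsch) least-squares rigid fit with
reflection correction, cross-checked in the tests against an independent
closed-form quaternion solution. Per-residue C-alpha RMSD is measured after
superposing on a stated anchor (all shared chains by default, or one chain
to follow the matchmaker-on-chain-A convention). Steric clashes use Bondi
van der Waals radii with a 0.4 Angstrom tolerance (a common softness
allowance), hydrogens ignored; both are configurable. Minor-groove anchor
occupancy measures side-chain nitrogen distances to the canonical groove
floor atoms (purine N3, pyrimidine O2) with a 4.0 Angstrom cutoff; sugar
C1'/C4' flank distances are reported but excluded from the occupancy call,
since "occupies the minor groove" has no standard numeric definition.

Docking a DNA-bound domain onto nucleosomal DNA aligns the domain's duplex
backbone (P and C1' atoms, motif ±2 bp recommended) onto the nucleosomal
motif segment — DNA-frame alignment being the standard way to transplant a
DNA-bound domain for clash analysis. The DNA unwrap angle is measured, after
core superposition, between least-squares lines through the base-pair
centers (C1' midpoints) of the terminal segment in each model; the exact
vector definition behind published "reorientation by ~N degrees" figures is
rarely stated, so the segment is a required, recorded parameter (20 terminal
bp on the factor-bound side is the recommended default) and the convention
is validated on synthetically rotated arcs to ±0.5 degrees. Both structure
parsers (PDB fixed-column and a minimal mmCIF `atom_site` reader) keep model
1 only and resolve altlocs to the highest-occupancy conformer; deposited
nucleosome models are single-model files. No R PDB parser is available in
the supported dependency set, which is why this small parser exists at all;
it is not a general mmCIF implementation.

The checks against the *deposited* coordinate models (a 2.97 Angstrom
histone hydrogen bond; the ~50 degree unwrap between bound and free DNA
paths) require downloading those models and are therefore not part of the
offline test suite; the operations they exercise are covered by synthetic
fixtures labelled as such.

# Numerical choices and degenerate inputs

* Change-point detection needs ≥ 4 frames; a constant series returns "no
  change point" (`<=` on the effect threshold makes the noiseless constant
  case unambiguous).
* `segment_states()` carries the previous classification through invalid
  (`NA`) efficiency frames; a leading invalid frame defaults to high-FRET
  (wrapped is the resting state).
* Exponential fits require 10 uncensored dwells by default; the Markov
  inversion falls back to uncorrected means with a warning if the sampled
  persistences are inconsistent with a two-state process
  (`p_a + p_b <= 1`).
* Superposition requires ≥ 3 non-collinear pairs; collinear input is an
  error, not a silent least-squares answer.
* Unwrap segments require ≥ 4 base pairs (a 3-point line fit is unstable).
* Ties: SHL rounding away from zero; altloc occupancy ties keep the first
  conformer listed; equal smoothed peaks resolve by raw density then lower
  coordinate.

# Known limitations

SeEN-seq ingestion starts at count tables (no aligner integration); MNase
analysis has no sequence-bias correction and no genome-scale branch; the
smFRET model is strictly two-state (no hidden-Markov multi-state fitting, no
blinking correction); structural analysis is rigid-body only (no energy
minimization, flexible docking or map-space analysis). The generator-backed
green tests establish estimator correctness under the stated models, not
under every failure mode of real instruments.
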