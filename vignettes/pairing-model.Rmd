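---
title: "The pairing model: fragment-length priors and mismap posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pairing model: fragment-length priors and mismap posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairprob)
```

## The problem

A paired-end sequencing run reads both ends of each DNA fragment. When a
local aligner maps the two reads of a pair independently, each read ends up
with a set of candidate alignments — often several, because genomes are
repetitive and reads are short and error-prone. The pairing information
(the two ends come from one fragment, whose length follows a fairly tight
distribution) can resolve much of this ambiguity, but only if it is used
probabilistically: a pair may also genuinely come from disjoint locations
(structural variation, translocations, contamination, a diverged or
incomplete reference), and forcing every pair to be concordant would hide
exactly the reads many studies care about.

`pairprob` takes the candidate alignments as given — produced by any
aligner whose integer scores are scaled log-likelihood ratios — and
computes, for every candidate alignment of every read, the **marginal
posterior probability** that this alignment is the read's true genomic
source. The complement, the *mismap probability*, is reported raw and as a
phred-scaled MAPQ. The marginal formulation is deliberate: the quantity of
interest is per alignment of one read, summed over everything the mate
might be doing, not a joint score for an alignment pair.

## The model

Let $\alpha, \beta$ be the reads of one pair, $A$ and $B$ their candidate
alignment sets, $s_a$ the integer score of candidate $a$, and $T$ the
scale factor such that $s/T$ is a natural-log likelihood ratio. Let $2g$
be the number of bases in both strands of the haploid reference, $\pi(f)$
the fitted fragment-length density, and $d$ the prior probability that the
pair is disjoint. With $I = 1$ for a conjoint and $I = 0$ for a disjoint
pair, the prior over source configurations is taken uniform over genome
positions:

$$
P(a, b, I) \;=\;
\begin{cases}
 (1-d)\,\pi(f_{ab})/(2g) & I = 1,\ a,b \text{ compatible} \\
 d/(2g)^2 & I = 0,
\end{cases}
$$

where $f_{ab}$ is the fragment length implied by the two placements.
The conjoint case spends one uniform $1/(2g)$ factor on the first read's
location and $\pi(f)$ on the mate's displacement; the disjoint case spends
$1/(2g)$ on each end. The aligner's scores supply the likelihood through
$P(\alpha,\beta \mid a,b) \propto e^{s_a/T}\, e^{s_b/T}$, so the marginal
posterior of a candidate $a \in A$ is

$$
P(a \mid \alpha, \beta) \;=\;
\frac{e^{s_a/T}\left[(1-d)\,2g \sum_{b \sim a} e^{s_b/T}\pi(f_{ab})
      \;+\; d \sum_{b \in B} e^{s_b/T}\right]}
     {\sum_{a' \in A} (\text{numerator for } a') \;+\; w},
$$

(the whole expression scaled by $(2g)^2$), with $b \sim a$ ranging over
mate candidates on the opposite strand of the same chromosome. Computed
this way — per candidate $a$: one conjoint sum $c(a)$ and the shared
totals $Y = \sum_b e^{s_b/T}$ — the cost is one pass over the compatible
$(a,b)$ grid instead of a triple sum over $(a, b, I)$ per candidate. The
package carries both routes: `pair_posteriors()` is the factorized
computation, `brute_force_posteriors()` the explicit enumeration, and the
test suite holds them to $10^{-12}$ relative agreement on a thousand
random instances.

Because the marginal posteriors over one read's candidates sum to at most
1, at most one candidate per read can have mismap below 0.5 — which is
what makes the mismap threshold sweep in the evaluator well defined.

### Fragment lengths

For two alignments on opposite strands of one chromosome, the implied
fragment runs from the forward-strand member's start to the reverse-strand
member's end (forward reference coordinates, half-open). The value is
**signed and unbounded**: wrong-order or absurdly distant pairs are not
excluded by rule, they are simply priced by the tail of $\pi$. Two
same-strand placements, or placements on different chromosomes, have no
conjoint interpretation at all. On a circular chromosome of length $L$ the
fragment may straddle the origin of the linear representation, so the
member of $\{f, f-L, f+L\}$ with the highest density is used — a pair that
straddles the origin is then indistinguishable from any other conjoint
pair, which is the point (`conjoint_fragment_length()`).

$\pi$ is fitted, not user-supplied. The estimator walks read pairs, and
for each pair whose opposite-strand same-chromosome alignment combinations
imply **exactly one distinct** fragment length, records that value
(`collect_fragment_lengths()`). Ambiguous pairs contribute nothing, and no
bound is imposed on the recorded values. The fit is then deliberately
crude and robust: mean = sample median, standard deviation =
interquartile range / 1.34898, the IQR of a unit normal, with quartiles by
linear interpolation (`stats::quantile` type 7). Medians and quartiles
ignore a minority of arbitrarily wild values, so chimeric pairs and
cross-chromosome artifacts cannot drag the fit. They are bounded, not
unbiased: under 5% one-sided gross contamination the median sits at the
clean sample's 52.5th percentile ($+0.063\sigma$, about $+3$ bases at
$\sigma = 50$) and the IQR-based scale a similar amount high. The test
suite asserts exactly these analytic displacements rather than pretending
the estimator is unaffected.

Two practical notes. For circular chromosomes the collector uses the raw
(unwrapped) length, since no fitted model exists yet to choose a wrap; the
handful of origin-straddling pairs land in the tails the robust fit
ignores. On large inputs the model can be estimated from a reservoir
sample of read pairs (`estimate_from_sample()`), which is deterministic
under a seed; a sample at least as large as the input reproduces the
full-data estimate exactly.

### RNA mode

For RNA-seq reads mapped to a genome, the two ends of a conjoint pair may
straddle introns, so the genomic span distribution is heavy-tailed —
empirically close to a mixture of log-normals with a dominant short-intron
component. The package follows the simpler single log-normal: the same
median/IQR fit applied to log-lengths (`robust_lognormal_fit()`), with
$\pi$ the log-normal density (maximum at $e^{\mu - \sigma^2}$). To
compensate for the unmodelled long-intron mass, RNA mode raises the
default disjoint prior from 0.01 to 0.02. Those two changes — distribution
family and $d$ default — are the whole of RNA mode.

### The score cutoff correction

The alignment phase reports only candidates with score at least $e$. A
read whose true alignment scored $e-1$ (the best possible score below an
integer cutoff) may still have a random alignment at $e$ or above — and
with the true competitor invisible, the naive posterior would confidently
back the impostor. The correction assumes exactly this unlucky case: a
hypothetical alignment of the read with score $e-1$, placed at the optimal
fragment distance from the mate's best alignment. Its would-be mass

$$
w \;=\; e^{(e-1)/T}\left[(1-d)\,2g\,\pi_{\max}\,e^{s^B_{\max}/T}
        + d \sum_{b} e^{s_b/T}\right]
$$

is added to the denominator when scoring this read's side (symmetrically
for the mate). Reported posteriors then sum to $1 - w/Z < 1$ per read: the
missing mass is the model's allowance for the invisible competitor. As
$e \to -\infty$ the correction vanishes and the corrected posteriors
converge to the uncorrected ones. The functional form — in particular the
inclusion of the disjoint component $d\,Y$ and the per-side application —
is this package's own reconstruction of a correction described only in
prose in the literature on this model family; it is chosen so that the
hypothetical behaves exactly like one more real candidate would
(`cutoff_correction()`).

### Empty candidate sets

When one read of a pair has no candidates at all, its mate is scored as if
the missing read had a single alignment on a different chromosome from
every candidate — a pure disjoint scenario. The virtual alignment's score
cancels from the ratio (every term in numerator and denominator carries
the same $e^{s_b/T}$ factor), so no score parameter is exposed; the test
suite verifies the cancellation by planting real far-chromosome mates of
arbitrary score and recovering identical posteriors. With the cutoff
correction on, the closed form keeps a lone weak candidate from looking
certain:

$$
P(a) = \frac{e^{s_a/T}\,d}
  {\sum_{a'} e^{s_{a'}/T}\,d + e^{(e-1)/T}\left[(1-d)\,2g\,\pi_{\max} + d\right]}.
$$

Pairs where **both** candidate sets are empty produce explicit unmapped
records — visible in SAM output with the unmapped flag — never silent
drops.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `d` | prior probability of a disjoint pair | 0.01 (DNA), 0.02 (RNA) | can be estimated from uniquely mapping pairs (`estimate_disjoint_prior()`); `d = 1` degenerates to single-end softmax, `d = 0` forbids disjoint pairs |
| `T` | score units per nat of log-likelihood ratio | none | a property of the scoring scheme; read from the `# T=` header, never guessed |
| `e` | integer score cutoff of the alignment phase | none | read from the `# e=` header; drives the correction term |
| `two_g` | bases in both strands of the haploid genome | derived | `2 * sum(chromosome lengths)` |
| `apply_cutoff_correction` | add the unlucky-case mass | `TRUE` | turn off to get exactly normalized posteriors |
| `mapq_cap` | ceiling for phred-scaled MAPQ | 60 | raw mismap is always reported alongside |
| disjoint tail threshold | density below which a unique pair counts as disjoint when estimating `d` | $\pi_{\max} \cdot 10^{-6}$ | our cut; $\pm 5.26\sigma$ for a normal model |

## Numerical choices

Only ratios of $e^{s/T}$ matter, so all exponentials are shifted —
**per side**: each read's terms by that read's maximum score. A single
instance-wide shift is not enough, because the two mates' scores can
differ by more than $T \ln(\text{double precision})$ and the smaller
side's exponentials would underflow to an all-zero denominator. With
per-side shifts every numerator and correction term of one side shares
one common scale factor and the computation is exact for arbitrary score
gaps; a regression test drives an 8000-unit gap through both routes.

$\pi(f)$ is the continuous density evaluated at integer $f$, used as a
per-base mass approximation — smooth in $f$, no binning artifacts, and
$\pi_{\max}$ has a closed form for both families. A pair whose model
probability is exactly zero (possible only with $d = 0$ and no compatible
geometry) yields posterior 0 / mismap 1 for every candidate rather than
0/0. Mismap is computed as $(Z - N_a)/Z$ — the complementary mass directly
— so values near 0 keep full relative precision, and both posterior and
mismap are clamped to $[0,1]$ against half-ulp summation spill. A zero
IQR floors the fitted scale at 1 base with a warning rather than emitting
a degenerate point-mass model.

## The synthetic benchmark

The generator exists so the whole method is testable without downloads,
and its defaults are the package's study conditions: two 500 kb
chromosomes at GC 0.41, a diploid individual with per-site polymorphism
rate $10^{-3}$, $10^4$ read pairs of 100 bp, fragment lengths
Normal(400, 50), per-base errors from a quality profile whose mean phred
decays from 38 to 25 along the read, decoy rate 1, score cutoff 120 at
scale $T = 4$.

`make_read_pairs()` draws fragments at uniform positions and strands,
reads the two opposite-strand ends 5′→3′, draws each base's quality from
the per-position profile and flips the base with probability
$10^{-Q/10}$. The translocation benchmark then permutes a fraction
(0.4 in the standard setting) of the second-mate reads among themselves,
re-assigning those pairs to disjoint sources; truth rows record the
re-assignment.

`make_candidate_sets()` bypasses the alignment phase: each read gets its
true-location alignment plus Poisson-distributed decoys at uniform
positions. Scores are where the design earns its keep. Decoy scores
follow a geometric law on $[e, \infty)$ with decay rate $1/T + 1/\omega$;
true-alignment scores follow the **same law exponentially tilted by**
$e^{s/T}$, i.e. a geometric with rate $1/\omega$. If the true score is
drawn from the decoy law tilted by $e^{s/T}$, then scores *are* calibrated
likelihood ratios by construction — the posterior computed by the model is
exactly the probability that the candidate is the read's source — so the
calibration test checks the implementation, not a hopeful approximation.
The spread $\omega$ defaults to the standard deviation of a full-read
alignment score under the base-level scoring model
(`make_scoring_model()`; about 23 score units for 100 bp at the default
$T = 4$ scoring, whose integer scores are $S_{xy} = \mathrm{round}(T
\ln(M_{xy}/A_x B_y))$). That choice makes true scores vary the way real
alignment scores do, while decoys cluster a few units above the cutoff —
so a realistic minority of reads is genuinely ambiguous for a single-end
scorer, which is the regime where pairing information earns its large
accuracy margin. A configurable suppression probability (default 0.02 in
the standard benchmark) withholds a read's true alignment entirely,
exercising the cutoff-correction and empty-mate paths.

What the simulation does **not** emulate: repeats (decoys are uniform and
their scores independent, whereas real decoys cluster in repeat families
with correlated, near-true scores), indel errors and adapter
contamination, quality-score miscalibration, and real polymorphism
spectra. Passing tests therefore demonstrate that the estimator is
correct and calibrated *for data obeying its own assumptions* and that
its qualitative advantages (pairing benefit, shuffle tolerance) hold
under honest ambiguity — not that MAPQs on any particular real library
are perfectly calibrated, where score correlations in repeats are the
dominant unmodelled effect.

The evaluator (`evaluate_mappings()`) restricts predictions to mismap
≤ 0.5 (at most one candidate per read survives), calls a prediction
correct iff it names the true chromosome and strand and overlaps the true
interval by at least one base (configurable), and sweeps the mismap
threshold to a curve of (fraction of all reads correctly mapped, fraction
wrongly mapped). `accuracy_at_error()` reads the curve at a matched
wrongly-mapped fraction, which is how the paired and single-end
(`d = 1`) runs are compared.

## Problem sizes and determinism

Every stochastic step takes a seed and is reproducible bit-for-bit; the
pipeline is deterministic end to end under one seed. The test suite and
the acceptance script use: 1000 random instances (candidate sets up to
20×20) for the oracle and normalization checks; $10^5$ draws for the
fragment-fit recovery; 25 000 pairs (≈ $10^5$ candidates) for the
calibration battery, with the binomial 99% bounds Bonferroni-split across
the 12 mismap bins so the battery as a whole is one 99% test; $10^4$
pairs for the pairing-benefit and shuffle-tolerance comparisons. These
sizes put every Monte-Carlo tolerance at a few estimator standard errors
and run in a couple of minutes on one core.

## Known limitations

- Gapless candidate records: the tabular writer emits one block per
  alignment; imported gapped MAF blocks keep their spans but CIGARs for
  unequal spans are written with a single trailing indel operation.
- The cutoff correction is a principled but conservative reconstruction;
  corrected posteriors are deliberately *not* calibrated (they hedge
  against an invisible competitor), so the calibration battery runs with
  the correction off.
- In-stream model estimation materializes the pair list before the second
  pass; the group-by-group streaming path (`iterate_pairs()`) is
  single-pass and suits pipes, but then the fragment model must be
  supplied or travel in the header.
- `estimate_disjoint_prior()` needs uniquely mapping pairs; on inputs
  where every read is multi-mapped it falls back to the default with a
  warning.
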