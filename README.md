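# pairprob

Probabilistic pairing of paired-end read alignments: given candidate local
alignments of each read of a pair — produced independently by any aligner
whose integer scores are scaled log-likelihood ratios — `pairprob`
estimates the fragment-length distribution from the candidates themselves
and computes, for **every candidate alignment**, the marginal posterior
probability that it is the read's true genomic source. The complement (the
*mismap probability*) is reported raw and as a phred-scaled MAPQ.

It is aimed at people building or studying read-mapping pipelines: the
pairing stage is isolated from the alignment stage, fully probabilistic
(no concordant/discordant cutoffs, no hard insert-size bounds), and ships
with a seeded synthetic benchmark so every statistical claim in the
package is testable offline.

## The model

For a read pair α, β with candidate sets *A*, *B*, scores *s* on scale *T*
(score = *T*·ln likelihood-ratio), genome size 2*g* (bases, both strands),
fragment-length density π(*f*) and prior disjoint probability *d*, the
marginal posterior of candidate *a* ∈ *A* is

    P(a | α, β) ∝ exp(s_a/T) · [ (1−d) · 2g · Σ_{b~a} exp(s_b/T) π(f_ab)  +  d · Σ_b exp(s_b/T) ]

normalized over *A* (plus, optionally, a correction mass for a
hypothetical alignment with score *e*−1 just below the aligner's cutoff
*e*, placed at the optimal distance from the mate's best alignment — the
"unlucky case" that otherwise produces confident false mappings). Here
*b*~*a* ranges over mate candidates on the opposite strand of the same
chromosome and *f_ab* is the signed, unbounded implied fragment length,
with wraparound on circular chromosomes. π is fitted robustly (mean =
median, sd = IQR/1.34898) from pairs that imply exactly one distinct
fragment length; RNA mode swaps in a log-normal and raises the default
*d* from 0.01 to 0.02. A read whose mate has no candidates is scored
against a virtual mate on a different chromosome (the score of which
provably cancels). See the methods vignette
(`vignettes/pairing-model.Rmd`) for the full model, the numerical
safeguards, and what the synthetic benchmark does and does not emulate.

## Worked example

Simulate the standard benchmark (10⁴ read pairs of 100 bp from a toy
diploid genome, fragment lengths Normal(400, 50), one decoy alignment per
read on average, 2% of true alignments withheld), then pair and evaluate:

```r
library(pairprob)
sim <- run_simulate("demo", n_pairs = 10000, seed = 1)
res <- run_pair("demo/candidates.tab", output = "demo/annotated.tab", seed = 1)
ev  <- run_evaluate("demo/annotated.tab", "demo/truth.tsv", output = "demo/curve.tsv")
```

which logs

```
pairprob pair: estimated fragment model from a sample of 9999 pair(s)
pairprob pair: # fraglen: kind=normal location=399 scale=51.149757594627047 n_samples=4974
pairprob pair: d=0.01 T=4 e=120 2g=2e+06 cutoff_correction=TRUE filter=none
pairprob pair: 9999 pair(s): 9864 with both mates aligned, 135 with an empty mate, 0 unmapped
```

The estimated fragment model (location 399, scale 51.1) recovers the
simulation truth (400, 50) from the 4974 pairs with an unambiguous
fragment length; 135 pairs lost one mate to the score cutoff and one pair
vanished entirely. Per-candidate output (here read `rd0000002`):

```
 mate chrom strand ref_start score posterior    mismap mapq
    1  chr1      -    228566   134     0.661 3.390e-01    5
    2  chr1      +    228140   176     1.000 1.412e-05   49
```

Mate 1 scored only 14 units above the cutoff, so even with mate support
the model hedges: posterior 0.661, MAPQ 5. Mate 2 is strong and
conjoint-supported. The threshold sweep against the simulation truth ends

```
 threshold frac_correct frac_wrong
 4.99e-01      0.89335           0
 5.00e-01      0.89370           0
```

i.e. 89.4% of all reads confidently and correctly mapped with zero
wrongly mapped at mismap ≤ 0.5 — on this repeat-free benchmark the
mismaps the model cannot avoid are all flagged above 0.5. Re-running with
`d = 1` (a single-end surrogate that ignores the mate) drops accuracy at
a matched 0.1% error budget from 89.4% to 46.8%: the pairing prior is
doing most of the disambiguation work.

The same four stages are available from the shell via the thin script
`inst/scripts/pairprob` (`pairprob simulate | estimate | pair |
evaluate`), reading stdin and writing stdout so stages compose in pipes;
`pair` can also emit MAF or SAM (`--out-format sam`).

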