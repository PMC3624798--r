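test_that("score_to_odds exponentiates on the T scale and rejects bad T", {
  expect_equal(score_to_odds(0, 4), 1.0)
  expect_equal(score_to_odds(7 * log(2), 7), 2.0)
  expect_equal(score_to_odds(10, 4, shift = 10), 1.0)
  expect_error(score_to_odds(5, 0), "positive")
  expect_error(score_to_odds(5, -1), "positive")
})

test_that("fragment length follows the forward-start to reverse-end rule", {
  g <- genome_info(c(chr1 = 1e6, chr2 = 1e6))
  a <- list(chrom = "chr1", strand = "+", ref_start = 1000, ref_end = 1100)
  b <- list(chrom = "chr1", strand = "-", ref_start = 1300, ref_end = 1400)
  expect_equal(conjoint_fragment_length(a, b, g), 400)
  # symmetric in the mate roles
  expect_equal(conjoint_fragment_length(b, a, g), 400)
  # wrong-order pair: negative, not clamped
  b2 <- list(chrom = "chr1", strand = "-", ref_start = 100, ref_end = 200)
  expect_equal(conjoint_fragment_length(a, b2, g), -800)
  # different chromosome or same strand are incompatible
  expect_true(is.na(conjoint_fragment_length(
    a, list(chrom = "chr2", strand = "-", ref_start = 10, ref_end = 20), g)))
  expect_true(is.na(conjoint_fragment_length(
    a, list(chrom = "chr1", strand = "+", ref_start = 1300, ref_end = 1400),
    g)))
  expect_error(conjoint_fragment_length(
    a, list(chrom = "chrZ", strand = "-", ref_start = 10, ref_end = 20), g),
    "absent")
})

test_that("circular chromosomes pick the wrap with the highest density", {
  g <- genome_info(c(chrM = 1000), circular = "chrM")
  m <- fragment_model("normal", 200, 50)
  a <- list(chrom = "chrM", strand = "+", ref_start = 900, ref_end = 950)
  b <- list(chrom = "chrM", strand = "-", ref_start = 50, ref_end = 100)
  # raw f = -800; wrapping by +L gives 200, at the model mode
  expect_equal(conjoint_fragment_length(a, b, g, m), 200)
})

test_that("pair_prior has the stated disjoint and conjoint forms", {
  m <- fragment_model("normal", 400, 50)
  p <- default_params(d = 0.01, two_g = 2e6)
  expect_equal(pair_prior(400, 0, p, m), 0.01 / (2e6)^2)
  expect_equal(pair_prior(400, 1, p, m),
               0.99 * (1 / (50 * sqrt(2 * pi))) / 2e6)
  expect_equal(pair_prior("incompatible", 1, p, m), 0)
  p0 <- default_params(d = 0, two_g = 2e6)
  expect_equal(pair_prior(123, 0, p0, m), 0)
})

test_that("posteriors match a longhand enumeration on the worked example", {
  genome <- genome_info(c(chr1 = 1e6, chr7 = 1e6))
  model <- fragment_model("normal", 400, 50)
  params <- pair_params(d = 0.01, T = 4, e = 20, two_g = 2e6,
                        apply_cutoff_correction = FALSE)
  A <- candidates("r", 1, c("chr1", "chr7"), c("+", "+"),
                  c(1000, 5000), c(1100, 5100), c(30, 25))
  B <- candidates("r", 2, "chr1", "-", 1300, 1400, 30)
  r <- pair_posteriors(A, B, params, model, genome)
  # frozen from the explicit double sum over (a, b, I)
  expect_rel_equal(r$first$posterior,
                   c(0.999999818646353, 1.81353646414107e-07), 1e-12)
  expect_equal(r$second$posterior, 1.0)
  bf <- brute_force_posteriors(A, B, params, model, genome)
  expect_rel_equal(r$first$posterior, bf$first$posterior, 1e-12)
})

test_that("degenerate priors give the expected limits", {
  g <- default_genome(); m <- default_model()
  # d = 0, one conjoint pair: the only admissible outcome
  A <- candidates("r", 1, "chr1", "+", 1000, 1100, 40)
  B <- candidates("r", 2, "chr1", "-", 1300, 1400, 35)
  r <- pair_posteriors(A, B, default_params(d = 0), m, g)
  expect_equal(r$first$posterior, 1.0)
  expect_equal(r$second$posterior, 1.0)
  # d = 1: mate-independent softmax; equal scores split evenly
  A2 <- candidates("r", 1, c("chr1", "chr2"), c("+", "+"),
                   c(1000, 8000), c(1100, 8100), c(10, 10))
  r2 <- pair_posteriors(A2, B, default_params(d = 1), m, g)
  expect_equal(r2$first$posterior, c(0.5, 0.5))
  set.seed(41)
  for (i in 1:20) {
    inst <- make_example_instance(d = 1)
    r <- pair_posteriors(inst$A, inst$B, inst$params, inst$model,
                         inst$genome)
    soft <- exp(inst$A$score / 4) / sum(exp(inst$A$score / 4))
    expect_rel_equal(r$first$posterior, soft, 1e-9)
  }
})

test_that("factorized and brute-force posteriors agree on random instances", {
  set.seed(7)
  for (i in 1:200) {
    inst <- make_example_instance(
      n_a = sample.int(20L, 1L), n_b = sample.int(20L, 1L),
      d = sample(c(0, 0.01, 0.2, 1), 1L),
      apply_cutoff_correction = (i %% 2 == 0L))
    a <- pair_posteriors(inst$A, inst$B, inst$params, inst$model,
                         inst$genome)
    b <- brute_force_posteriors(inst$A, inst$B, inst$params, inst$model,
                                inst$genome)
    expect_rel_equal(a$first$posterior, b$first$posterior, 1e-12)
    expect_rel_equal(a$second$posterior, b$second$posterior, 1e-12)
  }
  big <- make_example_instance(n_a = 110L, n_b = 100L)
  expect_error(brute_force_posteriors(big$A, big$B, big$params, big$model,
                                      big$genome), "too large")
})

test_that("posteriors are invariant to the overflow shift and to huge scores", {
  set.seed(11)
  inst <- make_example_instance(n_a = 5L, n_b = 4L)
  base <- pair_posteriors(inst$A, inst$B, inst$params, inst$model,
                          inst$genome)
  # adding a constant to every score only changes the shift
  for (off in c(400, 4000, 40000)) {
    A2 <- inst$A; A2$score <- A2$score + off
    B2 <- inst$B; B2$score <- B2$score + off
    p2 <- inst$params; p2$e <- p2$e + off
    r <- pair_posteriors(A2, B2, p2, inst$model, inst$genome)
    expect_rel_equal(r$first$posterior, base$first$posterior, 1e-12)
  }
  # wildly asymmetric scores between the two mates must not underflow
  A3 <- inst$A; A3$score <- A3$score + 8000
  r3 <- pair_posteriors(A3, inst$B, inst$params, inst$model, inst$genome)
  expect_true(all(is.finite(r3$first$posterior)))
  expect_true(all(is.finite(r3$second$posterior)))
  expect_rel_equal(sum(r3$second$posterior), 1, 1e-9)
})

test_that("posteriors normalize, with correction mass accounted for", {
  set.seed(13)
  for (i in 1:50) {
    inst <- make_example_instance(apply_cutoff_correction = FALSE)
    r <- pair_posteriors(inst$A, inst$B, inst$params, inst$model,
                         inst$genome)
    expect_lt(abs(sum(r$first$posterior) - 1), 1e-9)
    expect_lt(abs(sum(r$second$posterior) - 1), 1e-9)
    inst$params$apply_cutoff_correction <- TRUE
    r2 <- pair_posteriors(inst$A, inst$B, inst$params, inst$model,
                          inst$genome)
    im <- r2$intermediates
    d <- inst$params$d; g2 <- inst$params$two_g
    ZA <- sum(im$eA * ((1 - d) * g2 * im$c_first + d * im$Y)) + im$w_first
    expect_lt(abs(sum(r2$first$posterior) + im$w_first / ZA - 1), 1e-9)
    # at most one candidate per read can exceed posterior 0.5
    expect_lte(sum(r2$first$posterior > 0.5), 1L)
    expect_lte(sum(r2$second$posterior > 0.5), 1L)
  }
})

test_that("raising a score raises its posterior; a conjoint mate helps", {
  set.seed(17)
  for (i in 1:20) {
    inst <- make_example_instance(n_a = 4L, n_b = 3L)
    r0 <- pair_posteriors(inst$A, inst$B, inst$params, inst$model,
                          inst$genome)$first$posterior
    A2 <- inst$A; A2$score[2] <- A2$score[2] + 1
    r1 <- pair_posteriors(A2, inst$B, inst$params, inst$model,
                          inst$genome)$first$posterior
    expect_gt(r1[2], r0[2])
  }
  # planting a mate candidate at the fragment mode boosts the conjoint a
  g <- default_genome(); m <- default_model()
  A <- candidates("r", 1, c("chr1", "chr2"), c("+", "+"),
                  c(1000, 5000), c(1100, 5100), c(30, 30))
  B0 <- candidates("r", 2, "chr2", "+", 9000, 9100, 28)  # incompatible
  B1 <- rbind(B0, candidates("r", 2, "chr1", "-", 1300, 1400, 28))
  p <- default_params(d = 0.5)
  r0 <- pair_posteriors(A, B0, p, m, g)$first$posterior
  r1 <- pair_posteriors(A, B1, p, m, g)$first$posterior
  expect_gt(r1[1], r0[1])
})

test_that("cutoff correction penalizes a lone weak survivor", {
  g <- default_genome(); m <- default_model()
  e <- 30L
  # the unlucky case: read 1's true alignment scored e-1 and was dropped;
  # a random alignment squeaked past at e; read 2 is unique and strong
  A <- candidates("r", 1, "chr2", "+", 700000, 700100, e)
  B <- candidates("r", 2, "chr1", "-", 1300, 1400, 80)
  off <- pair_posteriors(A, B, default_params(e = e, correction = FALSE),
                         m, g)$first$posterior
  on <- pair_posteriors(A, B, default_params(e = e, correction = TRUE),
                        m, g)$first$posterior
  expect_equal(off, 1.0)        # uncorrected: confident and wrong
  expect_lt(on, 0.01)           # corrected: the hypothetical dominates
  # as e -> -Inf the correction mass vanishes
  low <- pair_posteriors(A, B, default_params(e = -4000L, correction = TRUE),
                         m, g)$first$posterior
  expect_rel_equal(low, off, 1e-9)
})

test_that("empty mate reduces to the virtual-alignment closed form", {
  g <- default_genome(); m <- default_model()
  A <- candidates("r", 1, c("chr1", "chr2"), c("+", "-"),
                  c(1000, 5000), c(1100, 5100), c(20, 20))
  r <- empty_mate_posteriors(A, default_params(correction = FALSE), m)
  expect_equal(r$posterior, c(0.5, 0.5))
  r1 <- empty_mate_posteriors(A[1, ], default_params(correction = FALSE), m)
  expect_equal(r1$posterior, 1.0)
  # correction on, single candidate at the cutoff: closed form
  p <- default_params(d = 0.01, T = 4, e = 30L, two_g = 2e6,
                      correction = TRUE)
  Ae <- candidates("r", 1, "chr1", "+", 1000, 1100, 30)
  got <- empty_mate_posteriors(Ae, p, m)$posterior
  pimax <- 1 / (50 * sqrt(2 * pi))
  want <- 0.01 / (0.01 + exp(-1 / 4) * (0.99 * 2e6 * pimax + 0.01))
  expect_rel_equal(got, want, 1e-12)
  # the virtual mate's score cancels: a real far-chromosome mate candidate
  # of any score gives identical posteriors for A
  for (sb in c(31, 60, 500)) {
    B <- candidates("r", 2, "chr2", "+", 900000, 900100, sb)
    full <- pair_posteriors(Ae, B, p, m, g <- genome_info(
      c(chr1 = 1e6, chr2 = 1e6)))$first$posterior
    expect_rel_equal(full, want, 1e-12)
  }
})

test_that("conjoint pairs keep their posterior across a circular origin", {
  m <- fragment_model("normal", 400, 50)
  g <- genome_info(c(chrM = 16000, chr1 = 1e6), circular = "chrM")
  p <- default_params(two_g = g$two_g, correction = TRUE)
  base_a <- 2000; base_b <- base_a + 400 - 100
  ref <- NULL
  for (delta in c(0, 8000, 13750, 15900)) {
    a1 <- (base_a + delta) %% 16000
    b1 <- (base_b + delta) %% 16000
    A <- candidates("r", 1, c("chrM", "chr1"), c("+", "+"),
                    c(a1, 5000), c(a1 + 100, 5100), c(40, 38))
    B <- candidates("r", 2, "chrM", "-", b1, b1 + 100, 39)
    r <- pair_posteriors(A, B, p, m, g)$first$posterior
    if (is.null(ref)) ref <- r else expect_rel_equal(r, ref, 1e-9)
  }
})

test_that("mismap converts to phred-scaled MAPQ with cap and clamping", {
  expect_identical(mismap_to_mapq(0.1), 10L)
  expect_identical(mismap_to_mapq(1.0), 0L)
  expect_identical(mismap_to_mapq(1e-7, cap = 60L), 60L)
  expect_identical(mismap_to_mapq(0), 60L)
  expect_identical(mismap_to_mapq(0.5, cap = 37L), 3L)
  expect_error(mismap_to_mapq(-0.1), "\\[0, 1\\]")
  expect_error(mismap_to_mapq(1.5), "\\[0, 1\\]")
})

test_that("candidate tables enforce their invariants", {
  expect_error(candidates("r", 1, "chr1", "+", 100, 100, 10), "ref_start")
  expect_error(candidates("r", 1, "chr1", "*", 100, 200, 10), "strand")
  expect_error(candidates("r", 1, "chr1", "+", 100, 200, 10.5), "integer")
  expect_error(pair_params(d = 2, T = 4, e = 1, two_g = 10), "probability")
  expect_error(pair_params(d = 0.1, e = 1, two_g = 10), "scale factor")
})
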