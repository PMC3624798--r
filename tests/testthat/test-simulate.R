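test_that("genome generation is seeded, GC-controlled and length-true", {
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  g1 <- make_genome(c(chr1 = 10000), gc = 0.41, seed = 1L, fasta = fa1)
  g2 <- make_genome(c(chr1 = 10000), gc = 0.41, seed = 1L, fasta = fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_equal(g1$info$two_g, 2 * 10000)
  gc_only <- make_genome(c(chr1 = 5000), gc = 1.0, seed = 2L)
  expect_true(grepl("^[GC]+$", as.character(gc_only$seq[[1]])))
  at_only <- make_genome(c(chr1 = 5000), gc = 0, seed = 2L)
  expect_true(grepl("^[AT]+$", as.character(at_only$seq[[1]])))
})

test_that("diploid polymorphism rate and variant table are consistent", {
  gen <- make_genome(c(chr1 = 50000), seed = 5L)
  dip0 <- make_diploid(gen$seq, snp_rate = 0, seed = 6L)
  expect_identical(as.character(dip0$haplotypes[[1]]),
                   as.character(gen$seq))
  expect_equal(nrow(dip0$variants), 0L)
  dip <- make_diploid(gen$seq, snp_rate = 0.01, seed = 7L)
  # each haplotype mutates independently: 2 * L Bernoulli(rate) sites
  n_var <- nrow(dip$variants)
  expect_gt(n_var, qbinom(0.005, 2 * 50000, 0.01))
  expect_lt(n_var, qbinom(0.995, 2 * 50000, 0.01))
  expect_true(all(dip$variants$ref != dip$variants$alt))
  # applying the variant table to the reference reproduces each haplotype
  for (h in 1:2) {
    chars <- strsplit(as.character(gen$seq[["chr1"]]), "")[[1]]
    v <- dip$variants[dip$variants$hap == h, ]
    expect_identical(chars[v$pos], v$ref)
    chars[v$pos] <- v$alt
    expect_identical(paste(chars, collapse = ""),
                     as.character(dip$haplotypes[[h]][["chr1"]]))
  }
})

test_that("quality profiles are proper distributions", {
  pr <- make_quality_profile(100L)
  expect_equal(dim(pr), c(100L, 40L))
  expect_equal(rowSums(pr), rep(1, 100))
  flat <- flat_quality_profile(50L, 40L)
  expect_equal(rowSums(flat), rep(1, 50))
})

test_that("fragment lengths of unshuffled pairs follow the model", {
  b <- get_benchmark(0)
  fr <- b$sim$truth$fragment_length[b$sim$truth$mate == 1L]
  expect_true(all(b$sim$truth$conjoint))
  # KS against the generating distribution (integer rounding is far below
  # the detectable scale at sigma = 50)
  ks <- suppressWarnings(stats::ks.test(fr, "pnorm", 400, 50))
  expect_gt(ks$p.value, 0.01)
})

test_that("the truth geometry matches the fragment convention", {
  b <- get_benchmark(0, n_pairs = 500L, seed = 901L)
  tr <- b$sim$truth
  m1 <- tr[tr$mate == 1L, ]; m2 <- tr[tr$mate == 2L, ]
  expect_true(all(m1$chrom == m2$chrom))
  expect_true(all(m1$strand != m2$strand))
  fwd_start <- ifelse(m1$strand == "+", m1$start, m2$start)
  rev_end <- ifelse(m1$strand == "+", m2$end, m1$end)
  expect_equal(rev_end - fwd_start, m1$fragment_length)
  # reads stay within their chromosome
  lens <- b$gen$info$chrom_lengths[tr$chrom]
  expect_true(all(tr$start >= 0 & tr$end <= lens))
})

test_that("shuffling re-assigns close to the requested fraction", {
  b <- get_benchmark(0.4)
  tr <- b$sim$truth
  frac <- mean(!tr$conjoint[tr$mate == 1L])
  expect_lt(abs(frac - 0.4), 0.015)
  expect_true(all(is.na(tr$fragment_length[!tr$conjoint])))
  # mate-1 reads are untouched by the shuffle
  b0 <- get_benchmark(0)
  t1 <- tr[tr$mate == 1L, c("chrom", "strand", "start", "end")]
  t0 <- b0$sim$truth[b0$sim$truth$mate == 1L,
                     c("chrom", "strand", "start", "end")]
  expect_identical(t1, t0)
})

test_that("sequencing errors match the phred probabilities", {
  # snp_rate 0 so reads differ from the reference only by simulated errors
  gen <- make_genome(c(chr1 = 2e5), seed = 21L)
  sim <- make_read_pairs(gen$seq, gen$info, 5000L, read_len = 100L,
                         profile = flat_quality_profile(100L, 40L),
                         seed = 22L)
  chars <- strsplit(as.character(gen$seq[["chr1"]]), "")[[1]]
  count_mm <- function(reads, truth_rows) {
    mm <- 0L
    seqs <- reads$seq
    for (i in seq_along(seqs)) {
      tr <- truth_rows[i, ]
      ref <- paste(chars[(tr$start + 1):tr$end], collapse = "")
      if (tr$strand == "-")
        ref <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(ref)))
      mm <- mm + sum(strsplit(seqs[i], "")[[1]] != strsplit(ref, "")[[1]])
    }
    mm
  }
  t1 <- sim$truth[sim$truth$mate == 1L, ]
  mm <- count_mm(sim$reads1, t1)
  # 5e5 bases at error rate 1e-4: binomial 99.9% band
  expect_gt(mm, qbinom(5e-4, 5e5, 1e-4))
  expect_lt(mm, qbinom(1 - 5e-4, 5e5, 1e-4))
})

test_that("FASTQ output is well-formed and parses back", {
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  gen <- make_genome(c(chr1 = 50000), seed = 31L)
  sim <- make_read_pairs(gen$seq, gen$info, 50L, seed = 32L,
                         fastq1 = fq1, fastq2 = fq2)
  x <- Biostrings::readDNAStringSet(fq1, format = "fastq",
                                    with.qualities = TRUE)
  expect_length(x, 50L)
  expect_true(all(Biostrings::width(x) == 100L))
  expect_identical(names(x), paste0(sim$truth$read_id[
    sim$truth$mate == 1L], "/1"))
  expect_identical(as.character(x), sim$reads1$seq, ignore_attr = TRUE)
})

test_that("scoring model scores are rounded log-likelihood ratios", {
  sc <- make_scoring_model(match_prob = 0.99, T = 4)
  expect_equal(sum(sc$M), 1)
  expect_identical(sc$S, round(sc$T * log(sc$M / outer(sc$A, sc$B))))
  expect_equal(unname(diag(sc$S)), rep(6, 4))
  expect_gt(sc$expected_pair_score, 0)
  expect_gt(sc$sd_pair_score, 0)
})

test_that("candidate sets contain the truth, respect the cutoff and seed", {
  b <- get_benchmark(0, n_pairs = 400L, seed = 801L)
  tr <- b$sim$truth
  # decoy_rate 0, suppression 0: every set is a singleton at the truth
  cs0 <- make_candidate_sets(tr, b$gen$info, decoy_rate = 0,
                             suppress_prob = 0, seed = 9L)
  expect_equal(nrow(cs0$candidates), nrow(tr))
  expect_equal(cs0$candidates$ref_start, tr$start)
  expect_equal(cs0$candidates$chrom, tr$chrom)
  expect_true(all(cs0$candidates$score >= cs0$e))
  # full suppression of mate 2 empties every B set
  tr2 <- tr
  cs1 <- make_candidate_sets(tr2[tr2$mate == 1L, ], b$gen$info,
                             decoy_rate = 0, suppress_prob = 0, seed = 9L)
  expect_true(all(cs1$candidates$mate == 1L))
  # determinism
  csa <- make_candidate_sets(tr, b$gen$info, seed = 10L)
  csb <- make_candidate_sets(tr, b$gen$info, seed = 10L)
  expect_identical(csa$candidates, csb$candidates)
  expect_true(all(csa$candidates$score >= csa$e))
})

test_that("true and decoy scores follow the tilted-geometric laws", {
  b <- get_benchmark(0, n_pairs = 5000L, seed = 1001L, suppress_prob = 0,
                     decoy_rate = 1)
  cand <- b$cs$candidates
  tr <- b$sim$truth
  key_t <- paste(tr$read_id, tr$mate, tr$chrom, tr$strand, tr$start)
  is_true <- paste(cand$read_id, cand$mate, cand$chrom, cand$strand,
                   cand$ref_start) %in% key_t
  spread <- b$cs$score_spread
  geom_mean <- function(lam) exp(-lam) / (1 - exp(-lam))
  mean_true <- mean(cand$score[is_true])
  mean_dec <- mean(cand$score[!is_true])
  expect_lt(abs(mean_true - (b$cs$e + geom_mean(1 / spread))), 1.5)
  expect_lt(abs(mean_dec - (b$cs$e + geom_mean(1 / b$cs$T + 1 / spread))),
            0.25)
  # decoys are (statistically) weaker than true alignments
  expect_gt(mean_true, mean_dec + 10)
})
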