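# Shared fixtures, built once per test session.

.bench_cache <- new.env(parent = emptyenv())

default_model <- function() fragment_model("normal", 400, 50)
default_genome <- function() genome_info(c(chr1 = 1e6, chr2 = 1e6))

default_params <- function(d = 0.01, T = 4, e = 30L, two_g = 4e6,
                           correction = FALSE) {
  pair_params(d = d, T = T, e = e, two_g = two_g,
              apply_cutoff_correction = correction)
}

# the standard synthetic benchmark: 1e4 pairs, decoy rate 1, 2% suppressed
# true alignments, fixed seeds; shuffle_fraction is the only varying knob
get_benchmark <- function(shuffle = 0, n_pairs = 10000L, seed = 101L,
                          suppress_prob = 0.02, decoy_rate = 1) {
  key <- paste(shuffle, n_pairs, seed, suppress_prob, decoy_rate, sep = "_")
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  gen <- make_genome(seed = seed)
  dip <- make_diploid(gen$seq, snp_rate = 0.001, seed = seed + 1L)
  fm <- fragment_model("normal", 400, 50)
  sim <- make_read_pairs(dip$haplotypes, gen$info, n_pairs, frag_model = fm,
                         shuffle_fraction = shuffle, seed = seed + 2L)
  cs <- make_candidate_sets(sim$truth, gen$info, decoy_rate = decoy_rate,
                            suppress_prob = suppress_prob, seed = seed + 3L)
  out <- list(gen = gen, dip = dip, sim = sim, cs = cs, fm = fm)
  .bench_cache[[key]] <- out
  out
}

pair_benchmark <- function(b, d = 0.01, correction = TRUE) {
  params <- pair_params(d = d, T = b$cs$T, e = b$cs$e,
                        two_g = b$gen$info$two_g,
                        apply_cutoff_correction = correction)
  pair_all(group_pairs(b$cs$candidates), params, b$fm, b$gen$info)$records
}

# accuracy (correct-call fraction at mismap <= 0.5) over a subset of reads
accuracy_on <- function(eval_res, truth, subset = rep(TRUE, nrow(truth))) {
  keys <- paste(truth$read_id, truth$mate)[subset]
  hits <- eval_res$calls$correct &
    paste(eval_res$calls$read_id, eval_res$calls$mate) %in% keys
  sum(hits) / length(keys)
}

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
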