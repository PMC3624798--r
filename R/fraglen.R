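#' Collect unambiguous fragment lengths from candidate alignments
#'
#' Walks read pairs and, for each, enumerates every alignment pair on
#' opposite strands of the same chromosome and the fragment length each
#' implies. If a pair's set of distinct fragment lengths has size exactly
#' one, that value is recorded; pairs implying zero or several distinct
#' lengths contribute nothing. No bound is imposed on the recorded lengths:
#' outliers are left in and handled by the robust fit.
#'
#' Distinctness compares exact integers. For circular chromosomes the raw
#' (unwrapped) length is used here, since no fitted model exists yet to
#' choose a wrap; the robust estimator absorbs the few straddling pairs as
#' outliers.
#'
#' @param pairs A list of read pairs, each a list with candidate tables `A`
#'   and `B` (either may have zero rows); see [read_candidates()].
#' @param genome A [genome_info()].
#' @return Numeric vector of recorded signed fragment lengths (possibly
#'   empty).
#' @export
collect_fragment_lengths <- function(pairs, genome) {
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    A <- pairs[[i]]$A; B <- pairs[[i]]$B
    if (is.null(A) || is.null(B) || !nrow(A) || !nrow(B)) next
    f <- frag_len_matrix(A, B, genome, model = NULL)
    f <- unique(f[!is.na(f)])
    if (length(f) == 1L) out[[i]] <- f
  }
  as.numeric(unlist(out))
}

#' Robust normal fit of fragment lengths (median / IQR)
#'
#' Fits a normal fragment-length distribution with mean = sample median and
#' standard deviation = interquartile range / 1.34898, the IQR of a unit
#' normal. Both statistics ignore a minority of arbitrarily wild values, so
#' chimeric pairs and cross-chromosome artifacts cannot drag the fit.
#' Quartiles use linear interpolation (`stats::quantile` type 7).
#'
#' @param lengths Numeric vector of at least 2 fragment lengths. Signed
#'   values are allowed: the normal model is defined on the whole line.
#' @return A [fragment_model()] with `kind = "normal"`. A zero IQR is
#'   floored at scale 1.0 with a warning.
#' @examples
#' robust_normal_fit(1:5)  # location 3, scale 2/1.34898
#' @export
robust_normal_fit <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) < 2L)
    stop("need at least 2 fragment lengths to estimate the distribution; ",
         "supply the fragment model manually instead")
  q <- stats::quantile(lengths, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  scale <- (q[3] - q[1]) / 1.34898
  if (scale == 0) {
    warning("interquartile range is 0; flooring scale at 1.0")
    scale <- 1.0
  }
  fragment_model("normal", location = q[2], scale = scale,
                 n_samples = length(lengths))
}

#' Robust log-normal fit of fragment lengths (RNA mode)
#'
#' RNA-seq read pairs can straddle introns, so the genomic span distribution
#' is heavy-tailed and is modelled as a single log-normal: the median/IQR
#' fit of [robust_normal_fit()] applied to natural logs of the lengths.
#' Non-positive lengths have no logarithm and are discarded with a message.
#'
#' @inheritParams robust_normal_fit
#' @return A [fragment_model()] with `kind = "lognormal"`.
#' @export
robust_lognormal_fit <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  bad <- lengths <= 0
  if (any(bad)) {
    message(sum(bad), " non-positive fragment length(s) discarded for the ",
            "log-normal fit")
    lengths <- lengths[!bad]
  }
  if (length(lengths) < 2L)
    stop("need at least 2 positive fragment lengths for the log-normal fit")
  m <- robust_normal_fit(log(lengths))
  fragment_model("lognormal", location = m$location, scale = m$scale,
                 n_samples = m$n_samples)
}

#' Estimate the fragment model from a sample of read pairs
#'
#' On large inputs the fragment-length distribution is estimated from a
#' reservoir sample of read pairs instead of the complete set; a
#' large-enough sample gives the same answer at a fraction of the cost.
#' Classic reservoir sampling keeps each pair with equal probability in one
#' pass and is deterministic under a fixed seed.
#'
#' @inheritParams collect_fragment_lengths
#' @param sample_size Number of read pairs to retain (>= 2). A sample at
#'   least as large as the input reproduces the full-data estimate exactly.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param kind `"normal"` or `"lognormal"`.
#' @return A [fragment_model()].
#' @export
estimate_from_sample <- function(pairs, genome, sample_size = 1e4L,
                                 seed = NULL, kind = c("normal", "lognormal")) {
  kind <- match.arg(kind)
  if (sample_size < 2L) stop("'sample_size' must be at least 2")
  keep <- with_seed_or_not(seed, reservoir_indices(length(pairs), sample_size))
  lens <- collect_fragment_lengths(pairs[keep], genome)
  if (length(lens) < 2L)
    stop("fewer than 2 unambiguous fragment lengths in the sample; ",
         "increase the sample size or supply the model manually")
  if (kind == "normal") robust_normal_fit(lens) else robust_lognormal_fit(lens)
}

# internal: indices retained by streaming reservoir sampling, in stream order
reservoir_indices <- function(n, k) {
  if (n <= k) return(seq_len(n))
  res <- seq_len(k)
  for (i in (k + 1L):n) {
    j <- sample.int(i, 1L)
    if (j <= k) res[j] <- i
  }
  sort(res)
}

#' Estimate the disjoint prior d from uniquely mapping pairs
#'
#' Among read pairs where both ends have exactly one candidate alignment,
#' returns the fraction whose unique alignment pair is incompatible
#' (different chromosome or same strand) or has fragment-length density in
#' the far tail of the fitted model (below `pi_max * tail_frac`). These
#' pairs are the ones the conjoint model cannot explain, so their frequency
#' estimates the prior probability of a disjoint pair. The estimate is
#' floored at `d_min` so a perfectly conjoint sample never yields a
#' degenerate zero prior.
#'
#' @inheritParams collect_fragment_lengths
#' @param model A fitted [fragment_model()].
#' @param tail_frac Density threshold as a fraction of the density maximum
#'   (default `1e-6`).
#' @param d_min Floor for the estimate (default `1e-4`).
#' @param d_default Returned, with a warning, when no uniquely mapping pairs
#'   exist (default 0.01, the standard DNA prior).
#' @return An estimate of `d` in `[d_min, 1]` (or `d_default`).
#' @export
estimate_disjoint_prior <- function(pairs, model, genome, tail_frac = 1e-6,
                                    d_min = 1e-4, d_default = 0.01) {
  stopifnot(inherits(model, "fragment_model"))
  cut <- frag_density_max(model) * tail_frac
  n_unique <- 0L; n_disjoint <- 0L
  for (p in pairs) {
    A <- p$A; B <- p$B
    if (is.null(A) || is.null(B) || nrow(A) != 1L || nrow(B) != 1L) next
    n_unique <- n_unique + 1L
    f <- conjoint_fragment_length(A, B, genome, model)
    if (is.na(f) || frag_density(model, f) < cut)
      n_disjoint <- n_disjoint + 1L
  }
  if (n_unique == 0L) {
    warning("no uniquely mapping pairs; returning the default d = ",
            d_default)
    return(d_default)
  }
  max(d_min, n_disjoint / n_unique)
}
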