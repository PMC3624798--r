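#' Build a candidate-alignment table
#'
#' Candidate alignments are plain data frames with one row per scored local
#' alignment of one read end. Coordinates are 0-based, half-open, always on
#' the forward strand of the reference; `strand` is the strand of the read
#' relative to the reference. `qstart`/`qend` are the aligned span on the
#' read (0-based half-open, forward read coordinates).
#'
#' @param read_id Read (pair) identifier, without any `/1` `/2` mate suffix.
#' @param mate Integer 1 or 2: which end of the pair.
#' @param chrom,strand,ref_start,ref_end Reference placement; `strand` is
#'   `"+"` or `"-"`, `ref_start < ref_end`.
#' @param score Integer alignment score (scaled log-likelihood ratio).
#' @param qstart,qend,read_len Aligned span on the read and full read length.
#' @return A data frame of class `candidate_df`.
#' @export
candidates <- function(read_id, mate, chrom, strand, ref_start, ref_end,
                       score, qstart = 0L, qend = ref_end - ref_start,
                       read_len = qend) {
  df <- data.frame(read_id = as.character(read_id), mate = as.integer(mate),
                   chrom = as.character(chrom), strand = as.character(strand),
                   ref_start = as.numeric(ref_start),
                   ref_end = as.numeric(ref_end),
                   score = as.numeric(score),
                   qstart = as.numeric(qstart), qend = as.numeric(qend),
                   read_len = as.numeric(read_len),
                   stringsAsFactors = FALSE)
  if (any(df$ref_start >= df$ref_end))
    stop("candidate alignments need ref_start < ref_end")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$score != round(df$score)))
    stop("alignment scores must be integers")
  if (any(df$qstart >= df$qend | df$qend > df$read_len))
    stop("read span must satisfy qstart < qend <= read_len")
  class(df) <- c("candidate_df", "data.frame")
  df
}

#' Convert an alignment score to a likelihood-ratio odds factor
#'
#' Scores are `T`-scaled natural-log likelihood ratios, so the odds of a
#' candidate alignment against the null is `exp(score / T)`. A caller-supplied
#' `shift` guards against overflow: only ratios of these factors ever enter a
#' posterior, so `exp((score - shift) / T)` with `shift = max(score)` is used
#' throughout the package.
#'
#' @param score Numeric score vector (integer score units).
#' @param T Positive score scale.
#' @param shift Score subtracted before exponentiation (default 0).
#' @return `exp((score - shift) / T)`.
#' @examples
#' score_to_odds(0, 4)         # 1
#' score_to_odds(4 * log(2), 4) # 2
#' @export
score_to_odds <- function(score, T, shift = 0) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0)
    stop("'T' must be a positive scale factor")
  exp((score - shift) / T)
}

#' Fragment length implied by a pair of candidate alignments
#'
#' For two alignments of opposite mates on opposite strands of the same
#' chromosome, the implied fragment runs from the forward-strand member's
#' start to the reverse-strand member's end (forward reference coordinates,
#' exclusive). The result is signed and unbounded: a wrong-order pair yields
#' a negative or tiny length and is penalized through the tail of pi(f),
#' not by a hard rule. Same-chromosome same-strand pairs and
#' different-chromosome pairs are incompatible (`NA`).
#'
#' On a circular chromosome of length `L`, a fragment may straddle the
#' origin of the linear representation; the member of `{f, f - L, f + L}`
#' with the highest density under `model` is returned, so such pairs are not
#' mistaken for disjoint ones.
#'
#' @param a,b One-row data frames (or lists) with `chrom`, `strand`,
#'   `ref_start`, `ref_end` for candidates of the two opposite mates.
#' @param genome A [genome_info()].
#' @param model A [fragment_model()]; needed only for the circular wrap
#'   choice (may be `NULL` for linear chromosomes).
#' @return A signed integer fragment length, or `NA` if incompatible.
#' @export
conjoint_fragment_length <- function(a, b, genome, model = NULL) {
  chrom_length(genome, c(a$chrom, b$chrom))  # errors on unknown chromosomes
  if (a$chrom != b$chrom || a$strand == b$strand) return(NA_real_)
  if (a$strand == "+") {
    f <- b$ref_end - a$ref_start
  } else {
    f <- a$ref_end - b$ref_start
  }
  if (genome$circular[[a$chrom]]) {
    L <- genome$chrom_lengths[[a$chrom]]
    cand <- c(f, f - L, f + L)
    if (is.null(model)) return(f)
    f <- cand[which.max(frag_density(model, cand))]
  }
  f
}

# internal: nA x nB matrix of fragment lengths (NA where incompatible),
# with the circular wrap applied when model is non-NULL
frag_len_matrix <- function(A, B, genome, model = NULL) {
  chrom_length(genome, unique(c(A$chrom, B$chrom)))
  nA <- nrow(A); nB <- nrow(B)
  compat <- outer(A$chrom, B$chrom, "==") & outer(A$strand, B$strand, "!=")
  a_fwd <- matrix(A$strand == "+", nA, nB)
  pf <- ifelse(a_fwd, matrix(A$ref_start, nA, nB),
               matrix(B$ref_start, nA, nB, byrow = TRUE))
  pr <- ifelse(a_fwd, matrix(B$ref_end, nA, nB, byrow = TRUE),
               matrix(A$ref_end, nA, nB))
  f <- pr - pf
  f[!compat] <- NA_real_
  if (any(genome$circular) && !is.null(model)) {
    circ <- matrix(genome$circular[A$chrom], nA, nB) & compat
    idx <- which(circ)
    if (length(idx)) {
      L <- matrix(genome$chrom_lengths[A$chrom], nA, nB)[idx]
      f0 <- f[idx]
      cand <- cbind(f0, f0 - L, f0 + L)
      dens <- matrix(frag_density(model, cand), ncol = 3L)
      f[idx] <- cand[cbind(seq_along(idx), max.col(dens, ties.method = "first"))]
    }
  }
  f
}

#' Prior probability of a candidate alignment pair
#'
#' The generative prior over a read pair's source: with probability `d` the
#' two ends come from disjoint locations, each uniform over the `2g` bases of
#' both strands of the reference, giving `d / (2g)^2` per location pair; with
#' probability `1 - d` they are conjoint, spending one uniform `1 / (2g)`
#' factor on the first end's location and the fragment-length density
#' `pi(f)` on the mate's displacement, giving `(1 - d) * pi(f) / (2g)`.
#' An incompatible geometry has conjoint prior 0.
#'
#' @param f Signed fragment length, or `NA`/`"incompatible"` for an
#'   incompatible pair.
#' @param I 0 (disjoint) or 1 (conjoint).
#' @param params A [pair_params()].
#' @param model A [fragment_model()].
#' @return A nonnegative prior density value.
#' @export
pair_prior <- function(f, I, params, model) {
  stopifnot(inherits(params, "pair_params"))
  if (!I %in% c(0, 1)) stop("'I' must be 0 (disjoint) or 1 (conjoint)")
  if (is.character(f)) f <- if (identical(f, "incompatible")) NA_real_
                            else as.numeric(f)
  if (I == 0) return(params$d / params$two_g^2)
  if (is.na(f)) return(0)
  (1 - params$d) * frag_density(model, f) / params$two_g
}

#' Intermediate values of the factorized posterior computation
#'
#' The marginal posterior for each candidate in `A` needs, per candidate, the
#' score-weighted mass of the whole mate set (`Y`) and the conjoint part
#' `c(a) = sum_b exp(s_b/T) * pi(f_ab)`; symmetric values serve `B`. These
#' and the per-side cutoff-correction masses are computed once here and
#' shared. Each side's exponentials are shifted by that side's maximum
#' score, so arbitrary score gaps between the mates cannot underflow.
#'
#' @param A,B Candidate tables (see [candidates()]) for the two mates; both
#'   nonempty.
#' @inheritParams pair_prior
#' @param genome A [genome_info()].
#' @return A list of class `pair_intermediates`: `eA`, `eB` (shifted odds),
#'   `X`, `Y`, `c_first`, `c_second`, `s_max_A`, `s_max_B`, `w_first`,
#'   `w_second`, `shift_A`, `shift_B`.
#' @export
pair_intermediates <- function(A, B, params, model, genome) {
  stopifnot(inherits(params, "pair_params"), inherits(model, "fragment_model"))
  if (!nrow(A) || !nrow(B))
    stop("both candidate sets must be nonempty; route empty mates to ",
         "empty_mate_posteriors()")
  # each side is shifted by its own maximum score: posteriors are ratios
  # within a side, and every numerator and correction term of one side
  # carries the same exp(-(shift_A + shift_B)/T) scale, so neither huge
  # score gaps between mates nor large absolute scores can underflow
  shift_A <- max(A$score); shift_B <- max(B$score)
  Ts <- params$T
  eA <- exp((A$score - shift_A) / Ts)
  eB <- exp((B$score - shift_B) / Ts)
  f <- frag_len_matrix(A, B, genome, model)
  pim <- frag_density(model, f)
  pim[is.na(pim)] <- 0
  dim(pim) <- dim(f)
  im <- list(
    eA = eA, eB = eB, X = sum(eA), Y = sum(eB),
    c_first = as.numeric(pim %*% eB),
    c_second = as.numeric(crossprod(pim, eA)),
    s_max_A = max(A$score), s_max_B = max(B$score),
    shift_A = shift_A, shift_B = shift_B
  )
  im$w_first <- if (params$apply_cutoff_correction)
    cutoff_correction("first", im, params, model) else 0
  im$w_second <- if (params$apply_cutoff_correction)
    cutoff_correction("second", im, params, model) else 0
  class(im) <- "pair_intermediates"
  im
}

#' Cutoff-correction mass for one side of a read pair
#'
#' The alignment phase only reports candidates scoring at least `e`, so a
#' read's true alignment may be missing while a random one survives,
#' producing a confident wrong mapping. The correction assumes the unlucky
#' case: a hypothetical alignment of this read with score `e - 1` (the
#' highest integer score below the cutoff), placed at the optimal fragment
#' distance from the mate's best alignment. Its would-be posterior mass,
#'
#' `w = exp((e-1)/T) * ((1-d) * 2g * pi_max * exp(s_mate_max/T) + d * Y_mate)`,
#'
#' is added to the denominator when scoring this side, deflating every
#' reported posterior accordingly.
#'
#' @param side `"first"` (scoring A, hypothetical competes using B) or
#'   `"second"`.
#' @param intermediates A [pair_intermediates()] list.
#' @inheritParams pair_prior
#' @return The nonnegative correction mass (on the same shifted scale as the
#'   numerators in `intermediates`).
#' @export
cutoff_correction <- function(side = c("first", "second"), intermediates,
                              params, model) {
  side <- match.arg(side)
  im <- intermediates
  pimax <- frag_density_max(model)
  own_shift <- if (side == "first") im$shift_A else im$shift_B
  mate_shift <- if (side == "first") im$shift_B else im$shift_A
  mate_max <- if (side == "first") im$s_max_B else im$s_max_A
  mate_Y <- if (side == "first") im$Y else im$X
  exp((params$e - 1 - own_shift) / params$T) *
    ((1 - params$d) * params$two_g * pimax *
       exp((mate_max - mate_shift) / params$T) +
     params$d * mate_Y)
}

# internal: attach posterior/mismap/mapq columns; mismap computed as the
# complementary mass over Z to keep precision when posterior ~ 1
posterior_records <- function(df, numer, Z, mapq_cap = 60L) {
  if (Z <= 0) {
    # the model assigns this instance probability zero (e.g. d = 0 with no
    # conjoint-compatible geometry): nothing is credible
    numer <- numer * 0
    Z <- 1
  }
  mismap <- pmin(1, pmax(0, (Z - numer) / Z))
  cols <- unclass(df)
  cols$posterior <- pmin(1, pmax(0, numer / Z))
  cols$mismap <- mismap
  cols$mapq <- mismap_to_mapq(mismap, cap = mapq_cap)
  structure(cols, row.names = c(NA_integer_, -length(numer)),
            class = "data.frame")
}

#' Marginal posterior probabilities for the candidates of a read pair
#'
#' For each candidate `a` of the first read, the posterior that `a` is the
#' read's true genomic source marginalizes over every candidate `b` of the
#' mate and over the conjoint/disjoint indicator:
#'
#' `N(a) = exp(s_a/T) * ((1-d) * 2g * c(a) + d * Y)`,
#' `posterior(a) = N(a) / (sum_a' N(a') + w)`,
#'
#' where `c(a)` sums `exp(s_b/T) * pi(f_ab)` over mate candidates conjoint
#' with `a`, `Y` sums `exp(s_b/T)` over all of them, and `w` is the
#' [cutoff_correction()] mass (0 when the correction is off). The same
#' computation with roles swapped serves the mate. This factorization equals
#' the explicit double sum over all `(a, b, I)` outcomes (see
#' [brute_force_posteriors()]) at a fraction of the cost.
#'
#' @inheritParams pair_intermediates
#' @param mapq_cap Cap for the phred-scaled MAPQ (default 60).
#' @return A list with elements `first` and `second`: the input candidate
#'   tables with `posterior`, `mismap` and `mapq` columns appended, plus
#'   `intermediates`.
#' @export
pair_posteriors <- function(A, B, params, model, genome, mapq_cap = 60L) {
  im <- pair_intermediates(A, B, params, model, genome)
  d <- params$d; g2 <- params$two_g
  nA <- im$eA * ((1 - d) * g2 * im$c_first + d * im$Y)
  nB <- im$eB * ((1 - d) * g2 * im$c_second + d * im$X)
  list(first = posterior_records(A, nA, sum(nA) + im$w_first, mapq_cap),
       second = posterior_records(B, nB, sum(nB) + im$w_second, mapq_cap),
       intermediates = im)
}

#' Posteriors when the mate has no candidate alignments
#'
#' When one read of a pair has an empty candidate set, its mate is scored as
#' if the missing read had a single alignment on a different chromosome from
#' every candidate — i.e. the pair can only be disjoint. The virtual
#' alignment's score cancels algebraically from the ratio, so none is
#' needed. With the cutoff correction off this reduces to a softmax of the
#' scores; with it on, the hypothetical sub-threshold mass keeps a lone weak
#' candidate from looking certain:
#'
#' `posterior(a) = exp(s_a/T) * d / (sum_a' exp(s_a'/T) * d +
#'    exp((e-1)/T) * ((1-d) * 2g * pi_max + d))`
#'
#' @param A Nonempty candidate table for the read that did align.
#' @inheritParams pair_posteriors
#' @return The candidate table with `posterior`, `mismap`, `mapq` appended.
#' @export
empty_mate_posteriors <- function(A, params, model, mapq_cap = 60L) {
  stopifnot(inherits(params, "pair_params"))
  if (!nrow(A)) return(A)
  shift <- max(A$score)
  numer <- exp((A$score - shift) / params$T) * params$d
  Z <- sum(numer)
  if (params$apply_cutoff_correction) {
    Z <- Z + exp((params$e - 1 - shift) / params$T) *
      ((1 - params$d) * params$two_g * frag_density_max(model) + params$d)
  } else {
    # without the correction the disjoint-only model is a plain softmax
    numer <- exp((A$score - shift) / params$T)
    Z <- sum(numer)
  }
  posterior_records(A, numer, Z, mapq_cap)
}

#' Reference implementation of the pair posterior by explicit enumeration
#'
#' Computes the same marginal posteriors as [pair_posteriors()] by the
#' explicit double sum over every `(a, b)` candidate pair and both values of
#' the conjoint indicator, plus (when the correction is on) the hypothetical
#' sub-threshold alignment as one extra outcome per side: conjoint with the
#' mate's best candidate at the density maximum, disjoint with every mate
#' candidate. Quadratic and intended only as a test oracle; refuses
#' instances with more than `10^4` candidate pairs.
#'
#' @inheritParams pair_posteriors
#' @return As [pair_posteriors()] (without `intermediates`).
#' @export
brute_force_posteriors <- function(A, B, params, model, genome,
                                   mapq_cap = 60L) {
  stopifnot(inherits(params, "pair_params"))
  if (nrow(A) * nrow(B) > 1e4)
    stop("instance too large for the brute-force oracle")
  if (!nrow(A) || !nrow(B)) stop("both candidate sets must be nonempty")
  shift_A <- max(A$score); shift_B <- max(B$score)
  Ts <- params$T; d <- params$d; g2 <- params$two_g
  eA <- exp((A$score - shift_A) / Ts)
  eB <- exp((B$score - shift_B) / Ts)
  f <- frag_len_matrix(A, B, genome, model)
  pim <- frag_density(model, f)
  pim[is.na(pim)] <- 0
  dim(pim) <- dim(f)
  like <- outer(eA, eB)                      # exp((s_a + s_b)/T), shifted
  conj <- like * (1 - d) * g2 * pim          # (2g)^2-scaled conjoint terms
  disj <- like * d
  termA <- rowSums(conj + disj)
  termB <- colSums(conj + disj)
  wA <- wB <- 0
  if (params$apply_cutoff_correction) {
    e1A <- exp((params$e - 1 - shift_A) / Ts)
    e1B <- exp((params$e - 1 - shift_B) / Ts)
    pimax <- frag_density_max(model)
    wA <- e1A * max(eB) * (1 - d) * g2 * pimax + e1A * d * sum(eB)
    wB <- e1B * max(eA) * (1 - d) * g2 * pimax + e1B * d * sum(eA)
  }
  list(first = posterior_records(A, termA, sum(termA) + wA, mapq_cap),
       second = posterior_records(B, termB, sum(termB) + wB, mapq_cap))
}

#' Convert a mismap probability to a phred-scaled mapping quality
#'
#' `round(-10 * log10(p))`, clamped to `[0, cap]`; `p = 0` maps to `cap`.
#'
#' @param p Mismap probabilities in `[0, 1]`.
#' @param cap Integer cap (default 60).
#' @return Integer MAPQ values.
#' @examples
#' mismap_to_mapq(0.1)  # 10
#' @export
mismap_to_mapq <- function(p, cap = 60L) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("mismap probabilities must lie in [0, 1]")
  q <- -10 * log10(p)
  q[p == 0] <- Inf
  as.integer(pmax(0, pmin(cap, round(q))))
}
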