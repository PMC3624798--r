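#' Generate a toy reference genome
#'
#' I.i.d. random sequence at a given GC content: a deliberately
#' repeat-free stand-in for a real reference, small enough to simulate
#' against in memory. Deterministic under a seed.
#'
#' @param lengths Numeric vector of chromosome lengths (names optional;
#'   defaults `chr1`, `chr2`, ...). Default: two 500 kb chromosomes.
#' @param gc GC content in `[0, 1]` (default 0.41, the human genome-wide
#'   value).
#' @param circular Character vector of circular chromosome names, or `NULL`.
#' @param seed Integer seed or `NULL`.
#' @param fasta Optional path; when given, the sequences are written there.
#' @return A list with `seq` (a [Biostrings::DNAStringSet]) and `info`
#'   (a [genome_info()]; its `two_g` is twice the summed lengths).
#' @export
make_genome <- function(lengths = c(5e5, 5e5), gc = 0.41, circular = NULL,
                        seed = NULL, fasta = NULL) {
  stopifnot(all(lengths >= 1), gc >= 0, gc <= 1)
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed_or_not(seed, {
    Biostrings::DNAStringSet(vapply(lengths, function(L) {
      paste(sample(names(prob), L, replace = TRUE, prob = prob),
            collapse = "")
    }, ""))
  })
  names(seqs) <- names(lengths)
  if (!is.null(fasta)) Biostrings::writeXStringSet(seqs, fasta)
  list(seq = seqs, info = genome_info(lengths, circular = circular))
}

#' Simulate a diploid individual from a reference
#'
#' Incorporates polymorphisms: every site of each of the two haplotypes is
#' substituted independently with probability `snp_rate` (uniformly to one
#' of the three other bases). The variant table records site, reference and
#' alternate allele per haplotype and is sufficient to reconstruct the
#' haplotypes from the reference.
#'
#' @param genome_seq A [Biostrings::DNAStringSet] reference.
#' @param snp_rate Per-site substitution probability in `[0, 0.1]`.
#' @param seed Integer seed or `NULL`.
#' @return A list with `haplotypes` (list of two `DNAStringSet`s) and
#'   `variants` (data frame: `hap`, `chrom`, `pos` 1-based, `ref`, `alt`).
#' @export
make_diploid <- function(genome_seq, snp_rate = 0.001, seed = NULL) {
  stopifnot(snp_rate >= 0, snp_rate <= 0.1)
  bases <- c("A", "C", "G", "T")
  with_seed_or_not(seed, {
    ref_chars <- lapply(as.character(genome_seq), function(s)
      strsplit(s, "")[[1L]])
    haps <- vector("list", 2L)
    vars <- list()
    for (h in 1:2) {
      hap_chars <- ref_chars
      for (chrom in names(genome_seq)) {
        L <- length(ref_chars[[chrom]])
        at <- which(stats::runif(L) < snp_rate)
        if (!length(at)) next
        ref <- ref_chars[[chrom]][at]
        alt <- bases[(match(ref, bases) - 1L +
                        sample.int(3L, length(at), replace = TRUE)) %% 4L + 1L]
        hap_chars[[chrom]][at] <- alt
        vars[[length(vars) + 1L]] <- data.frame(
          hap = h, chrom = chrom, pos = at, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
      }
      haps[[h]] <- Biostrings::DNAStringSet(
        vapply(hap_chars, paste, "", collapse = ""))
    }
    variants <- if (length(vars)) do.call(rbind, vars)
      else data.frame(hap = integer(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    list(haplotypes = haps, variants = variants)
  })
}

#' Per-position base-quality profile
#'
#' A `read_len x n_phred` matrix: row `i` is the distribution of
#' phred-scaled quality scores at read position `i` (5' to 3'). Each row
#' sums to 1. The default emulates the familiar pattern of real profiles:
#' high, tight quality near the 5' end, decaying mean and widening spread
#' toward the 3' end.
#'
#' @param read_len Read length in bases.
#' @param q5,q3 Mean phred quality at the 5' and 3' ends.
#' @param spread Standard deviation of the per-position quality
#'   distribution.
#' @param qmin,qmax Phred support bounds (columns of the matrix).
#' @return A matrix of class `quality_profile`; columns named by phred
#'   value.
#' @export
make_quality_profile <- function(read_len = 100L, q5 = 38, q3 = 25,
                                 spread = 4, qmin = 2L, qmax = 41L) {
  qs <- qmin:qmax
  pr <- t(vapply(seq_len(read_len), function(i) {
    mu <- q5 + (q3 - q5) * ((i - 1) / max(1, read_len - 1))^1.5
    w <- stats::dnorm(qs, mean = mu, sd = spread)
    w / sum(w)
  }, numeric(length(qs))))
  colnames(pr) <- qs
  structure(pr, class = c("quality_profile", "matrix"))
}

#' Constant-quality profile (all bases at one phred value)
#'
#' @param read_len Read length.
#' @param q The single phred value.
#' @return A `quality_profile` matrix with all mass on `q`.
#' @export
flat_quality_profile <- function(read_len = 100L, q = 40L) {
  pr <- matrix(1, nrow = read_len, ncol = 1L, dimnames = list(NULL, q))
  structure(pr, class = c("quality_profile", "matrix"))
}

# internal: vector of phred draws per position for n reads -> n x len matrix
sample_qualities <- function(profile, n) {
  qs <- as.integer(colnames(profile))
  len <- nrow(profile)
  qmat <- matrix(0L, n, len)
  for (j in seq_len(len)) {
    qmat[, j] <- if (length(qs) == 1L) rep.int(qs, n)
                 else sample(qs, n, replace = TRUE, prob = profile[j, ])
  }
  qmat
}

#' Simulate paired-end reads with quality-profile errors
#'
#' Draws `n_pairs` fragments from the fragment-length model at uniform
#' genomic positions and strands on a random haplotype, takes the two
#' opposite-strand ends of each fragment as the read pair (each read 5' to
#' 3'), then applies sequencing errors: each base's phred score is drawn
#' from the per-position profile and the base is substituted with
#' probability `10^(-Q/10)` (uniformly to another base). Fragment draws
#' shorter than the read length (or longer than their chromosome) are
#' redrawn, with a message. Finally, a `shuffle_fraction` of the
#' second-mate reads are randomly permuted among themselves, re-assigning
#' those pairs to disjoint sources, which mimics the effect of
#' translocations between sample and reference; affected truth rows are
#' flagged non-conjoint.
#'
#' @param haplotypes List of two [Biostrings::DNAStringSet] haplotypes
#'   (from [make_diploid()]); a single `DNAStringSet` is accepted for a
#'   haploid simulation.
#' @param genome The [genome_info()] of the reference.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length in bases (default 100).
#' @param frag_model A [fragment_model()] to draw fragment lengths from.
#' @param profile A quality profile ([make_quality_profile()]).
#' @param shuffle_fraction Fraction of second mates to shuffle, in `[0, 1]`.
#' @param seed Integer seed or `NULL`.
#' @param fastq1,fastq2 Optional paths; when given, FASTQ (phred+33) is
#'   written.
#' @return A list with `truth` (data frame: `read_id`, `mate`, `chrom`,
#'   `strand`, `start`, `end` 0-based half-open, `conjoint`,
#'   `fragment_length`), `reads1`, `reads2` (data frames: `read_id`, `seq`,
#'   `qual`).
#' @export
make_read_pairs <- function(haplotypes, genome, n_pairs, read_len = 100L,
                            frag_model = fragment_model("normal", 400, 50),
                            profile = make_quality_profile(read_len),
                            shuffle_fraction = 0, seed = NULL,
                            fastq1 = NULL, fastq2 = NULL) {
  stopifnot(shuffle_fraction >= 0, shuffle_fraction <= 1)
  if (methods::is(haplotypes, "DNAStringSet"))
    haplotypes <- list(haplotypes, haplotypes)
  if (nrow(profile) != read_len)
    stop("quality profile has ", nrow(profile), " positions for read_len ",
         read_len)
  mode_f <- if (frag_model$kind == "normal") frag_model$location
            else exp(frag_model$location - frag_model$scale^2)
  if (mode_f < read_len)
    warning("fragment model mode (", round(mode_f),
            ") is below the read length; most draws will be redrawn")
  chroms <- names(genome$chrom_lengths)
  lens <- as.numeric(genome$chrom_lengths)
  draw_f <- function(n) {
    if (frag_model$kind == "normal")
      round(stats::rnorm(n, frag_model$location, frag_model$scale))
    else round(stats::rlnorm(n, frag_model$location, frag_model$scale))
  }
  with_seed_or_not(seed, {
    chrom_i <- sample.int(length(chroms), n_pairs, replace = TRUE,
                          prob = lens)
    f <- draw_f(n_pairs)
    redrawn <- 0L
    repeat {
      bad <- which(f < read_len | f > lens[chrom_i])
      if (!length(bad)) break
      redrawn <- redrawn + length(bad)
      f[bad] <- draw_f(length(bad))
    }
    if (redrawn > 0)
      message(redrawn, " fragment draw(s) redrawn (shorter than the read ",
              "or longer than the chromosome)")
    hap_i <- sample.int(2L, n_pairs, replace = TRUE)
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    start <- floor(stats::runif(n_pairs) * (lens[chrom_i] - f + 1))
    # read placement on the reference (0-based half-open, forward coords)
    plus <- strand == "+"
    r1_start <- ifelse(plus, start, start + f - read_len)
    r2_start <- ifelse(plus, start + f - read_len, start)
    r1_strand <- strand
    r2_strand <- ifelse(plus, "-", "+")
    ids <- sprintf("rd%07d", seq_len(n_pairs))
    hap_chr <- lapply(haplotypes, as.character)
    fetch <- function(rstart, rstrand) {
      s <- character(n_pairs)
      for (h in 1:2) {
        sel <- hap_i == h
        s[sel] <- substring(hap_chr[[h]][chroms[chrom_i[sel]]],
                            rstart[sel] + 1, rstart[sel] + read_len)
      }
      neg <- rstrand == "-"
      if (any(neg))
        s[neg] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(s[neg])))
      s
    }
    seq1 <- fetch(r1_start, r1_strand)
    seq2 <- fetch(r2_start, r2_strand)
    err <- function(seqs) {
      q <- sample_qualities(profile, length(seqs))
      m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
      flip <- which(matrix(stats::runif(length(m)), nrow(m)) < 10^(-q / 10))
      if (length(flip)) {
        bases <- c("A", "C", "G", "T")
        orig <- match(m[flip], bases)
        orig[is.na(orig)] <- sample.int(4L, sum(is.na(orig)), replace = TRUE)
        m[flip] <- bases[(orig - 1L +
                           sample.int(3L, length(flip), replace = TRUE)) %% 4L + 1L]
      }
      qc <- matrix(rawToChar(as.raw(q + 33L), multiple = TRUE), nrow(q))
      list(seq = do.call(paste0, as.data.frame(m)),
           qual = do.call(paste0, as.data.frame(qc)))
    }
    e1 <- err(seq1); e2 <- err(seq2)
    conjoint <- rep(TRUE, n_pairs)
    frag_out <- f
    k <- round(shuffle_fraction * n_pairs)
    if (k > 0) {
      sel <- sample.int(n_pairs, k)
      donor <- sel[sample.int(k)]
      e2$seq[sel] <- e2$seq[donor]
      e2$qual[sel] <- e2$qual[donor]
      r2_start[sel] <- r2_start[donor]
      r2_strand[sel] <- r2_strand[donor]
      chrom2 <- chroms[chrom_i]; chrom2[sel] <- chrom2[donor]
      moved <- sel[donor != sel]
      conjoint[moved] <- FALSE
      frag_out[moved] <- NA
    } else chrom2 <- chroms[chrom_i]
    truth <- rbind(
      data.frame(read_id = ids, mate = 1L, chrom = chroms[chrom_i],
                 strand = r1_strand, start = r1_start,
                 end = r1_start + read_len, conjoint = conjoint,
                 fragment_length = frag_out, stringsAsFactors = FALSE),
      data.frame(read_id = ids, mate = 2L, chrom = chrom2,
                 strand = r2_strand, start = r2_start,
                 end = r2_start + read_len, conjoint = conjoint,
                 fragment_length = frag_out, stringsAsFactors = FALSE))
    truth <- truth[order(match(truth$read_id, ids), truth$mate), ]
    rownames(truth) <- NULL
    reads1 <- data.frame(read_id = ids, seq = e1$seq, qual = e1$qual,
                         stringsAsFactors = FALSE)
    reads2 <- data.frame(read_id = ids, seq = e2$seq, qual = e2$qual,
                         stringsAsFactors = FALSE)
    if (!is.null(fastq1)) write_fastq(reads1, 1L, fastq1)
    if (!is.null(fastq2)) write_fastq(reads2, 2L, fastq2)
    list(truth = truth, reads1 = reads1, reads2 = reads2)
  })
}

# internal: FASTQ writer (Sanger phred+33) via Biostrings
write_fastq <- function(reads, mate, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- paste0(reads$read_id, "/", mate)
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Base-level scoring model with integer log-likelihood-ratio scores
#'
#' The substitution score for aligning reference base `x` to read base `y`
#' is `S_xy = round(T * ln(M_xy / (A_x * B_y)))`: a `T`-scaled integer
#' log-likelihood ratio of the aligned-pair probability `M_xy` against the
#' background abundances. The expected per-base score of a true alignment,
#' `sum(M_xy * S_xy)`, anchors the score level the candidate generator aims
#' at.
#'
#' @param match_prob Probability that a truly aligned base pair is identical
#'   (absorbs both polymorphism and sequencing error; default 0.99).
#' @param T Score scale factor (default 4).
#' @param abundances Named base probabilities (default uniform).
#' @return An object of class `scoring_model` with fields `S` (4x4 integer
#'   matrix), `A`, `B`, `M`, `T` and `expected_pair_score`.
#' @export
make_scoring_model <- function(match_prob = 0.99, T = 4,
                               abundances = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  stopifnot(match_prob > 0, match_prob < 1, T > 0,
            abs(sum(abundances) - 1) < 1e-9)
  A <- B <- abundances
  M <- outer(A, rep(1, 4)) *
    (diag(4) * match_prob + (1 - diag(4)) * (1 - match_prob) / 3)
  dimnames(M) <- list(names(A), names(A))
  S <- round(T * log(M / outer(A, B)))
  mu <- sum(M * S)
  structure(list(S = S, A = A, B = B, M = M, T = T,
                 expected_pair_score = mu,
                 sd_pair_score = sqrt(sum(M * S^2) - mu^2)),
            class = "scoring_model")
}

#' Generate candidate alignment sets from a truth table
#'
#' Bypasses the alignment phase: for each read it emits the true-location
#' alignment plus `Poisson(decoy_rate)` decoys at uniform positions and
#' strands. Scores are integer log-likelihood ratios on the model's scale:
#' decoy scores follow a geometric law on `[e, Inf)` with decay rate
#' `1/T + 1/spread`, and true-alignment scores follow the same law
#' exponentially tilted by `exp(score / T)` (a geometric with decay rate
#' `1/spread`, mean `e + spread`). This tilt is exactly the relation scores
#' must satisfy to be likelihood ratios, so posteriors computed from these
#' candidates are exactly calibrated. `score_spread` defaults to the
#' standard deviation of a full-length true alignment's score under the
#' [make_scoring_model()] (about 23 for 100 bp reads at the default
#' scoring), so true scores vary the way real alignment scores do while
#' decoys cluster just above the cutoff.
#'
#' With probability `suppress_prob` a read's true alignment is withheld
#' (as if it scored below the cutoff), exercising the cutoff-correction and
#' empty-mate paths. Every emitted score is `>= e` by construction.
#'
#' @param truth Truth table from [make_read_pairs()].
#' @param genome A [genome_info()].
#' @param scoring A [make_scoring_model()].
#' @param decoy_rate Mean number of decoy alignments per read.
#' @param score_spread Mean of true scores above the cutoff; `NULL` derives
#'   it from `scoring` and the read length.
#' @param e Integer score cutoff.
#' @param suppress_prob Probability of withholding a read's true alignment.
#' @param seed Integer seed or `NULL`.
#' @param path Optional output path for the tab-format candidate file (with
#'   `# T=... e=...` header).
#' @return A list with `candidates` (a [candidates()] table), `T`, `e`,
#'   `score_spread`, and `path` (or `NULL`).
#' @export
make_candidate_sets <- function(truth, genome, scoring = make_scoring_model(),
                                decoy_rate = 1, score_spread = NULL,
                                e = 120L, suppress_prob = 0, seed = NULL,
                                path = NULL) {
  stopifnot(inherits(scoring, "scoring_model"), decoy_rate >= 0,
            suppress_prob >= 0, suppress_prob <= 1)
  n <- nrow(truth)
  read_len <- truth$end - truth$start
  if (is.null(score_spread))
    score_spread <- max(1, round(sqrt(mean(read_len)) * scoring$sd_pair_score))
  Ts <- scoring$T
  lam_q <- 1 / Ts + 1 / score_spread   # decoy decay; tilts to 1/score_spread
  chroms <- names(genome$chrom_lengths)
  lens <- as.numeric(genome$chrom_lengths)
  with_seed_or_not(seed, {
    keep <- stats::runif(n) >= suppress_prob
    true_scores <- e + stats::rgeom(n, prob = 1 - exp(-1 / score_spread))
    true_df <- data.frame(
      read_id = truth$read_id, mate = truth$mate, chrom = truth$chrom,
      strand = truth$strand, ref_start = truth$start, ref_end = truth$end,
      score = true_scores, row = seq_len(n), stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
    n_dec <- stats::rpois(n, decoy_rate)
    m <- sum(n_dec)
    if (m > 0) {
      row <- rep.int(seq_len(n), n_dec)
      rl <- read_len[row]
      ci <- sample.int(length(chroms), m, replace = TRUE, prob = lens)
      dstart <- floor(stats::runif(m) * (lens[ci] - rl + 1))
      dec_df <- data.frame(
        read_id = truth$read_id[row], mate = truth$mate[row],
        chrom = chroms[ci],
        strand = sample(c("+", "-"), m, replace = TRUE),
        ref_start = dstart, ref_end = dstart + rl,
        score = e + stats::rgeom(m, prob = 1 - exp(-lam_q)),
        row = row, stringsAsFactors = FALSE)
      df <- rbind(true_df, dec_df)
    } else df <- true_df
    df <- df[order(df$row, df$mate), ]
    rl_all <- df$ref_end - df$ref_start
    out <- candidates(df$read_id, df$mate, df$chrom, df$strand,
                      df$ref_start, df$ref_end, df$score,
                      qstart = 0L, qend = rl_all, read_len = rl_all)
    # keep both mates of a pair adjacent in file order
    out <- out[order(match(out$read_id, unique(truth$read_id)), out$mate), ]
    rownames(out) <- NULL
    if (!is.null(path)) {
      params <- pair_params(T = Ts, e = e, two_g = 2 * sum(lens))
      write_candidates(out, path, params, genome = genome)
    }
    list(candidates = out, T = Ts, e = as.numeric(e),
         score_spread = score_spread, path = path)
  })
}

#' Group a flat candidate table into per-pair candidate sets
#'
#' @param df A [candidates()] table covering many reads.
#' @return A list of `list(read_id, A, B)` in order of first appearance;
#'   `A`/`B` may have zero rows.
#' @export
group_pairs <- function(df) {
  ids <- unique(df$read_id)
  idx <- split(seq_len(nrow(df)), factor(df$read_id, levels = ids))
  cols <- as.list(df)
  cls <- class(df)
  lapply(ids, function(id) {
    i <- idx[[id]]
    m <- cols$mate[i]
    list(read_id = id,
         A = slice_df(cols, i[m == 1L], cls),
         B = slice_df(cols, i[m == 2L], cls))
  })
}

#' Generate a small random candidate-set instance
#'
#' Utility for exercising and cross-checking the posterior computation on
#' arbitrary inputs (in the spirit of the example-data constructors common
#' to analysis packages). Draws a read pair's two candidate sets with
#' random placements and geometric scores above the cutoff; a fraction of
#' mate candidates is planted at a model-typical fragment distance from a
#' first-mate candidate so the conjoint term is routinely exercised.
#'
#' @param n_a,n_b Candidate-set sizes (default: uniform on 1..6).
#' @param model A [fragment_model()].
#' @param genome A [genome_info()] (default: two 1 Mb chromosomes).
#' @param T,e,d Model constants (see [pair_params()]).
#' @param conjoint_prob Probability that a mate candidate is planted
#'   conjoint with a random first-mate candidate.
#' @param apply_cutoff_correction Passed to [pair_params()].
#' @param read_len Alignment span in bases.
#' @return A list with `A`, `B`, `params`, `model`, `genome`.
#' @export
make_example_instance <- function(n_a = sample.int(6L, 1L),
                                  n_b = sample.int(6L, 1L),
                                  model = fragment_model("normal", 400, 50),
                                  genome = genome_info(c(chr1 = 1e6,
                                                         chr2 = 1e6)),
                                  T = 4, e = 30L, d = 0.01,
                                  conjoint_prob = 0.5,
                                  apply_cutoff_correction = FALSE,
                                  read_len = 100L) {
  chroms <- names(genome$chrom_lengths)
  lens <- as.numeric(genome$chrom_lengths)
  rand_side <- function(n, id, mate) {
    ci <- sample.int(length(chroms), n, replace = TRUE, prob = lens)
    start <- floor(stats::runif(n) * (lens[ci] - read_len))
    candidates(id, mate, chroms[ci],
               sample(c("+", "-"), n, replace = TRUE),
               start, start + read_len,
               e + stats::rgeom(n, prob = 0.1),
               qstart = 0L, qend = read_len, read_len = read_len)
  }
  A <- rand_side(n_a, "pair1", 1L)
  B <- rand_side(n_b, "pair1", 2L)
  plant <- which(stats::runif(n_b) < conjoint_prob)
  for (j in plant) {
    i <- sample.int(n_a, 1L)
    f <- round(if (model$kind == "normal")
      stats::rnorm(1, model$location, model$scale)
      else stats::rlnorm(1, model$location, model$scale))
    B$chrom[j] <- A$chrom[i]
    B$strand[j] <- if (A$strand[i] == "+") "-" else "+"
    if (A$strand[i] == "+") {
      B$ref_end[j] <- A$ref_start[i] + f
      B$ref_start[j] <- B$ref_end[j] - read_len
    } else {
      B$ref_start[j] <- A$ref_end[i] - f
      B$ref_end[j] <- B$ref_start[j] + read_len
    }
    L <- genome$chrom_lengths[[B$chrom[j]]]
    if (B$ref_start[j] < 0 || B$ref_end[j] > L) {
      B$ref_start[j] <- max(0, min(L - read_len, B$ref_start[j]))
      B$ref_end[j] <- B$ref_start[j] + read_len
    }
  }
  params <- pair_params(d = d, T = T, e = e, two_g = genome$two_g,
                        apply_cutoff_correction = apply_cutoff_correction)
  list(A = A, B = B, params = params, model = model, genome = genome)
}
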