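# internal: fast rbind for many same-shaped record data frames
rbind_records <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  lst <- lst[vapply(lst, nrow, 0L) > 0L]
  if (!length(lst)) return(NULL)
  cols <- names(lst[[1L]])
  out <- lapply(cols, function(cn)
    unlist(lapply(lst, `[[`, cn), use.names = FALSE))
  names(out) <- cols
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  df
}

# internal: placeholder record for a read with no candidates at all
unmapped_record <- function(read_id, mate) {
  data.frame(read_id = read_id, mate = mate, chrom = NA_character_,
             strand = NA_character_, ref_start = NA_real_,
             ref_end = NA_real_, score = NA_real_, qstart = NA_real_,
             qend = NA_real_, read_len = NA_real_, ref_len = NA_real_,
             posterior = NA_real_, mismap = NA_real_, mapq = NA_integer_,
             stringsAsFactors = FALSE)
}

RECORD_SCHEMA <- c("read_id", "mate", "chrom", "strand", "ref_start",
                   "ref_end", "score", "qstart", "qend", "read_len",
                   "ref_len", "posterior", "mismap", "mapq")

# internal: align record columns to a common schema and append the mate's
# best candidate (for SAM FLAG/RNEXT fields); plain list ops for speed
conform_records <- function(df, mate_rec) {
  cols <- unclass(df)
  n <- length(cols[[1L]])
  cols <- c(cols[intersect(RECORD_SCHEMA, names(cols))],
            lapply(stats::setNames(nm = setdiff(RECORD_SCHEMA, names(cols))),
                   function(cn) rep(NA, n)))[RECORD_SCHEMA]
  if (is.null(mate_rec) || !nrow(mate_rec) || all(is.na(mate_rec$mismap))) {
    cols$mate_chrom <- rep(NA_character_, n)
    cols$mate_pos <- rep(NA_real_, n)
    cols$mate_strand <- rep(NA_character_, n)
    cols$mate_unmapped <- rep(TRUE, n)
  } else {
    b <- which.min(mate_rec$mismap)
    cols$mate_chrom <- rep(mate_rec$chrom[b], n)
    cols$mate_pos <- rep(mate_rec$ref_start[b], n)
    cols$mate_strand <- rep(mate_rec$strand[b], n)
    cols$mate_unmapped <- rep(FALSE, n)
  }
  structure(cols, row.names = c(NA_integer_, -n), class = "data.frame")
}

#' Compute posteriors for every read pair in a candidate collection
#'
#' Routes each pair to the appropriate computation: both candidate sets
#' nonempty to [pair_posteriors()]; exactly one empty to
#' [empty_mate_posteriors()] (the disjoint-only closed form); both empty to
#' an explicit unmapped record, never a silent drop. Each record is also
#' annotated with its mate's best candidate (`mate_chrom`, `mate_pos`,
#' `mate_strand`, `mate_unmapped`) for SAM output.
#'
#' @param pairs List of `list(read_id, A, B)` (from [read_candidates()] or
#'   [group_pairs()]).
#' @inheritParams pair_posteriors
#' @return A list with `records` (one annotated data frame over all
#'   candidates) and `counts` (named integer vector: `pairs`, `both_mapped`,
#'   `empty_mate`, `unmapped`).
#' @export
pair_all <- function(pairs, params, model, genome, mapq_cap = 60L) {
  n <- length(pairs)
  acc <- vector("list", 2L * n)
  n_both <- n_empty <- n_unmapped <- 0L
  for (i in seq_len(n)) {
    p <- pairs[[i]]
    nA <- nrow(p$A); nB <- nrow(p$B)
    if (nA > 0L && nB > 0L) {
      n_both <- n_both + 1L
      r <- pair_posteriors(p$A, p$B, params, model, genome, mapq_cap)
      recA <- r$first; recB <- r$second
    } else if (nA == 0L && nB == 0L) {
      n_unmapped <- n_unmapped + 1L
      recA <- unmapped_record(p$read_id, 1L)
      recB <- unmapped_record(p$read_id, 2L)
    } else {
      n_empty <- n_empty + 1L
      recA <- if (nA > 0L)
        empty_mate_posteriors(p$A, params, model, mapq_cap)
      else unmapped_record(p$read_id, 1L)
      recB <- if (nB > 0L)
        empty_mate_posteriors(p$B, params, model, mapq_cap)
      else unmapped_record(p$read_id, 2L)
    }
    acc[[2L * i - 1L]] <- conform_records(recA, if (nB > 0L) recB else NULL)
    acc[[2L * i]] <- conform_records(recB, if (nA > 0L) recA else NULL)
  }
  list(records = rbind_records(acc),
       counts = c(pairs = n, both_mapped = n_both, empty_mate = n_empty,
                  unmapped = n_unmapped))
}

# internal: genome_info reconstructed from the reference lengths carried by
# candidate records (every dialect records refSeqSize per alignment)
genome_from_pairs <- function(pairs, circular = NULL) {
  chroms <- character(); lens <- numeric()
  for (p in pairs) {
    for (side in c("A", "B")) {
      df <- p[[side]]
      if (!is.null(df) && nrow(df) && "ref_len" %in% names(df)) {
        new <- !duplicated(df$chrom) & !(df$chrom %in% chroms)
        chroms <- c(chroms, df$chrom[new])
        lens <- c(lens, df$ref_len[new])
      }
    }
  }
  if (!length(chroms))
    stop("cannot derive chromosome lengths from the candidate records; ",
         "supply a genome (FASTA or length table)")
  genome_info(stats::setNames(lens, chroms), circular = circular)
}
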