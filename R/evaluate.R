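#' Threshold-curve evaluation of annotated mappings against truth
#'
#' Mirrors the standard accuracy/error sweep for mapping-quality-aware
#' aligners: predictions are first restricted to mismap probability at most
#' 0.5 (above that a read can carry several candidates and "the" predicted
#' location is ill-defined; at or below it, at most one candidate per read
#' survives). A prediction is correct iff it names the read's true
#' chromosome and strand and its reference interval overlaps the truth
#' interval by at least `min_overlap` bases. For every distinct mismap
#' threshold the fraction of all reads mapped correctly and the fraction
#' mapped wrongly are reported; both are non-decreasing as the threshold
#' loosens.
#'
#' @param predictions Posterior record table (`read_id`, `mate`, `chrom`,
#'   `strand`, `ref_start`, `ref_end`, `mismap`).
#' @param truth Truth table from [make_read_pairs()].
#' @param min_overlap Minimum overlap in bases to call a prediction correct
#'   (default 1).
#' @param max_mismap Upper mismap bound for the sweep (default 0.5).
#' @return A list with `curve` (data frame: `threshold`, `frac_correct`,
#'   `frac_wrong`), `n_reads` (denominator: all reads in `truth`), and
#'   `calls` (the per-read best predictions with a `correct` flag).
#' @export
evaluate_mappings <- function(predictions, truth, min_overlap = 1,
                              max_mismap = 0.5) {
  key_t <- paste(truth$read_id, truth$mate)
  pred <- predictions[!is.na(predictions$chrom) &
                        !is.na(predictions$mismap) &
                        predictions$mismap <= max_mismap, , drop = FALSE]
  key_p <- paste(pred$read_id, pred$mate)
  miss <- !(key_p %in% key_t)
  if (any(miss))
    stop("prediction(s) for read(s) absent from truth: ",
         paste(utils::head(unique(key_p[miss]), 3L), collapse = ", "))
  # defensively keep the single best candidate per read
  pred <- pred[order(pred$mismap), , drop = FALSE]
  pred <- pred[!duplicated(paste(pred$read_id, pred$mate)), , drop = FALSE]
  ti <- match(paste(pred$read_id, pred$mate), key_t)
  ov <- pmin(pred$ref_end, truth$end[ti]) -
    pmax(pred$ref_start, truth$start[ti])
  pred$correct <- pred$chrom == truth$chrom[ti] &
    pred$strand == truth$strand[ti] & ov >= min_overlap
  n_reads <- nrow(truth)
  o <- order(pred$mismap)
  mm <- pred$mismap[o]; corr <- pred$correct[o]
  last <- !duplicated(mm, fromLast = TRUE)
  curve <- data.frame(
    threshold = mm[last],
    frac_correct = cumsum(corr)[last] / n_reads,
    frac_wrong = cumsum(!corr)[last] / n_reads)
  rownames(curve) <- NULL
  list(curve = curve, n_reads = n_reads, calls = pred)
}

#' Correct-mapping fraction at a matched error level
#'
#' Reads a threshold curve at a given wrongly-mapped fraction: the largest
#' correctly-mapped fraction achievable while keeping the wrongly-mapped
#' fraction at or below `wrong`. Used to compare two runs at matched error.
#'
#' @param curve A curve data frame from [evaluate_mappings()].
#' @param wrong Wrongly-mapped fraction(s) to match.
#' @return Numeric vector of correct fractions (0 where no threshold
#'   qualifies).
#' @export
accuracy_at_error <- function(curve, wrong) {
  vapply(wrong, function(w) {
    ok <- curve$frac_wrong <= w
    if (!any(ok)) 0 else max(curve$frac_correct[ok])
  }, numeric(1))
}
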