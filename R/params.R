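#' Pairing model parameters
#'
#' Bundle of the constants of the pairing model: the prior probability `d`
#' that a read pair derives from disjoint genomic locations, the score scale
#' `T` (score units per natural log of likelihood ratio; a property of the
#' scoring scheme used by the aligner, so it has no default), the integer
#' score cutoff `e` below which the aligner reports nothing, and `two_g`,
#' the number of bases in both strands of the haploid reference.
#'
#' @param d Prior disjoint probability, in `[0, 1]`. The DNA default used
#'   throughout is 0.01; RNA mode uses 0.02.
#' @param T Positive score scale factor. Alignment scores divided by `T`
#'   are natural-log likelihood ratios.
#' @param e Integer score cutoff of the candidate-generation phase.
#' @param two_g Number of bases in both strands of the haploid genome
#'   (i.e. twice the total reference length).
#' @param apply_cutoff_correction Logical; add the unlucky-case correction
#'   mass for a hypothetical alignment with score `e - 1` (see
#'   [pair_posteriors()]).
#' @return An object of class `pair_params`.
#' @seealso [genome_info()], [pair_posteriors()]
#' @export
pair_params <- function(d = 0.01, T, e, two_g, apply_cutoff_correction = TRUE) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1)
    stop("'d' must be a probability in [0, 1]")
  if (missing(T) || !is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0)
    stop("'T' must be a positive scale factor (it has no default: it is a ",
         "property of the scoring scheme and must come from the input header ",
         "or configuration)")
  if (missing(e) || !is.numeric(e) || length(e) != 1L || is.na(e))
    stop("'e' must be the integer score cutoff of the alignment phase")
  if (!is.numeric(two_g) || length(two_g) != 1L || is.na(two_g) || two_g < 1)
    stop("'two_g' must be a positive count of bases (both strands)")
  structure(
    list(d = as.numeric(d), T = as.numeric(T), e = as.numeric(e),
         two_g = as.numeric(two_g),
         apply_cutoff_correction = isTRUE(apply_cutoff_correction)),
    class = "pair_params"
  )
}

#' @export
print.pair_params <- function(x, ...) {
  cat(sprintf(
    "pair_params: d=%g T=%g e=%g two_g=%g cutoff_correction=%s\n",
    x$d, x$T, x$e, x$two_g, x$apply_cutoff_correction))
  invisible(x)
}

#' Reference genome summary
#'
#' Chromosome lengths plus optional circularity flags. The model only needs
#' lengths (for the uniform location prior and circular wraparound), never
#' the sequence itself.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#' @param circular Either a named logical vector (names matching
#'   `chrom_lengths`), or a character vector of circular chromosome names.
#'   Defaults to all-linear.
#' @return An object of class `genome_info` with fields `chrom_lengths` and
#'   `circular` (parallel named logical vector), and `two_g = 2 * sum(lengths)`.
#' @export
genome_info <- function(chrom_lengths, circular = NULL) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)))
    stop("'chrom_lengths' must be a named vector")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  circ <- stats::setNames(rep(FALSE, length(chrom_lengths)), names(chrom_lengths))
  if (!is.null(circular)) {
    if (is.character(circular)) {
      unknown <- setdiff(circular, names(chrom_lengths))
      if (length(unknown))
        stop("circular chromosome(s) not in the genome: ",
             paste(unknown, collapse = ", "))
      circ[circular] <- TRUE
    } else if (is.logical(circular)) {
      if (is.null(names(circular)))
        stop("logical 'circular' must be named")
      circ[names(circular)] <- circular
    } else stop("'circular' must be a character or named logical vector")
  }
  structure(
    list(chrom_lengths = chrom_lengths, circular = circ,
         two_g = 2 * sum(as.numeric(chrom_lengths))),
    class = "genome_info"
  )
}

#' @export
print.genome_info <- function(x, ...) {
  cat(sprintf("genome_info: %d chromosome(s), 2g = %g%s\n",
              length(x$chrom_lengths), x$two_g,
              if (any(x$circular))
                paste0(" (circular: ",
                       paste(names(x$circular)[x$circular], collapse = ","), ")")
              else ""))
  invisible(x)
}

# internal: chromosome length lookup with a clear error
chrom_length <- function(genome, chrom) {
  len <- genome$chrom_lengths[chrom]
  if (anyNA(len))
    stop("chromosome(s) absent from genome_info: ",
         paste(unique(chrom[is.na(len)]), collapse = ", "))
  unname(len)
}

# internal: run an expression under a fixed seed without disturbing the
# caller's RNG state; seed = NULL leaves the current stream untouched.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
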