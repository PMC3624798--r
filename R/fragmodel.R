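#' Fragment-length distribution model
#'
#' The fitted fragment-length distribution pi(f) used as the conjoint prior.
#' Two families are supported: `normal` for genomic DNA fragments (location =
#' mean in bases, scale = standard deviation in bases) and `lognormal` for
#' RNA-seq genomic spans, where intron inclusion skews the distribution
#' (location = mean of log-lengths, scale = sd of log-lengths).
#'
#' The density is evaluated directly at integer fragment lengths as a
#' per-base probability-mass approximation, so pi(f) is smooth in f and the
#' density maximum `pi_max` has a closed form (see [frag_density_max()]).
#'
#' @param kind `"normal"` or `"lognormal"`.
#' @param location Real location parameter (bases, or log-bases for
#'   `lognormal`).
#' @param scale Nonnegative scale parameter (same units as `location`).
#' @param n_samples Number of fragment lengths the fit was based on
#'   (0 for a hand-specified model).
#' @return An object of class `fragment_model`.
#' @examples
#' m <- fragment_model("normal", 400, 50)
#' frag_density(m, 400) == frag_density_max(m)
#' @export
fragment_model <- function(kind = c("normal", "lognormal"), location, scale,
                           n_samples = 0L) {
  kind <- match.arg(kind)
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location))
    stop("'location' must be a finite number")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale < 0)
    stop("'scale' must be a nonnegative number")
  structure(
    list(kind = kind, location = as.numeric(location),
         scale = as.numeric(scale), n_samples = as.integer(n_samples)),
    class = "fragment_model"
  )
}

#' Fragment-length density pi(f)
#'
#' @param model A [fragment_model()].
#' @param f Numeric vector of (signed) fragment lengths in bases. For the
#'   log-normal family, non-positive `f` has density 0.
#' @return Numeric vector of densities.
#' @export
frag_density <- function(model, f) {
  stopifnot(inherits(model, "fragment_model"))
  if (model$kind == "normal") {
    stats::dnorm(f, mean = model$location, sd = model$scale)
  } else {
    out <- numeric(length(f))
    pos <- !is.na(f) & f > 0
    out[pos] <- stats::dlnorm(f[pos], meanlog = model$location,
                              sdlog = model$scale)
    out[is.na(f)] <- NA_real_
    out
  }
}

#' Maximum of the fragment-length density (the model's pi_max)
#'
#' Closed form: `1 / (scale * sqrt(2*pi))` for the normal family; the
#' log-normal density peaks at its mode `exp(location - scale^2)`.
#'
#' @inheritParams frag_density
#' @return The maximum density value, a single number.
#' @export
frag_density_max <- function(model) {
  stopifnot(inherits(model, "fragment_model"))
  if (model$scale == 0) stop("degenerate model: scale is 0")
  if (model$kind == "normal") {
    1 / (model$scale * sqrt(2 * pi))
  } else {
    stats::dlnorm(exp(model$location - model$scale^2),
                  meanlog = model$location, sdlog = model$scale)
  }
}

#' @export
print.fragment_model <- function(x, ...) {
  cat(model_header(x), sep = "\n")
  invisible(x)
}

#' Serialize / parse the fragment model header block
#'
#' The fitted model travels with output files as a small key=value comment
#' block so downstream runs can reuse it verbatim:
#' ```
#' # fraglen: kind=normal location=400.0 scale=50.0 n_samples=9500
#' ```
#'
#' @param model A [fragment_model()].
#' @return `model_header()`: a character vector of header lines.
#' @export
model_header <- function(model) {
  stopifnot(inherits(model, "fragment_model"))
  sprintf("# fraglen: kind=%s location=%.17g scale=%.17g n_samples=%d",
          model$kind, model$location, model$scale, model$n_samples)
}

#' @param lines Character vector of file lines (comment lines included).
#' @return `parse_model_header()`: the [fragment_model()] found in `lines`,
#'   or `NULL` if none present.
#' @rdname model_header
#' @export
parse_model_header <- function(lines) {
  hit <- grep("^#\\s*fraglen:", lines, value = TRUE)
  if (!length(hit)) return(NULL)
  kv <- parse_key_values(sub("^#\\s*fraglen:\\s*", "", hit[[1L]]))
  need <- c("kind", "location", "scale")
  if (!all(need %in% names(kv)))
    stop("malformed fraglen header: ", hit[[1L]])
  fragment_model(kind = kv[["kind"]],
                 location = as.numeric(kv[["location"]]),
                 scale = as.numeric(kv[["scale"]]),
                 n_samples = if ("n_samples" %in% names(kv))
                   as.integer(kv[["n_samples"]]) else 0L)
}

# internal: "a=1 b=x" -> named character vector
parse_key_values <- function(s) {
  parts <- strsplit(trimws(s), "\\s+")[[1L]]
  parts <- parts[nzchar(parts)]
  has_eq <- grepl("=", parts, fixed = TRUE)
  parts <- parts[has_eq]
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  stats::setNames(vals, keys)
}
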