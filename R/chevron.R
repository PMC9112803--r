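#' Chevron dataset for one variant
#'
#' Observed relaxation rate constants of one protein variant as a function of
#' denaturant concentration. Replicate urea values are allowed; points are
#' kept in input order.
#'
#' @param variant_id Character label; wild type is `"wt"` (case-insensitive)
#'   by convention.
#' @param urea Denaturant concentrations, M (>= 0).
#' @param kobs Observed rate constants, s^-1 (> 0).
#' @param sigma Optional per-point standard errors on `kobs` (s^-1, > 0).
#' @return Object of class `chevron_dataset` with a `points` data.frame.
#' @export
chevron_dataset <- function(variant_id, urea, kobs, sigma = NULL) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L)
  check_urea(urea)
  if (length(kobs) != length(urea))
    stop("urea and kobs must have the same length", call. = FALSE)
  if (any(!is.finite(kobs)) || any(kobs <= 0))
    stop("kobs values must be finite and strictly positive", call. = FALSE)
  if (!is.null(sigma)) {
    if (length(sigma) != length(kobs) || any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must match kobs in length and be strictly positive",
           call. = FALSE)
  }
  pts <- data.frame(urea = as.numeric(urea), kobs = as.numeric(kobs))
  pts$sigma <- if (is.null(sigma)) NA_real_ else as.numeric(sigma)
  structure(list(variant_id = variant_id, points = pts),
            class = "chevron_dataset")
}

#' @export
print.chevron_dataset <- function(x, ...) {
  cat(sprintf("Chevron dataset '%s': %d points, urea %.2f-%.2f M, kobs %.3g-%.3g s^-1\n",
              x$variant_id, nrow(x$points), min(x$points$urea),
              max(x$points$urea), min(x$points$kobs), max(x$points$kobs)))
  invisible(x)
}

is_wildtype_id <- function(id, wt_id = "wt") tolower(id) == tolower(wt_id)
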