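#' Mutational free-energy changes between wild type and a variant
#'
#' Differences in activation and equilibrium free energies caused by a point
#' mutation, from the microscopic rate constants (destabilising mutation =
#' positive `ddG_eq`):
#'
#' * `ddG_D_TS1  = RT * ln(kf_wt / kf_mut)` — change of the barrier from the
#'   denatured state to the early transition state;
#' * `ddG_TS1_N  = RT * ln(ku_mut / ku_wt)` — change of the unfolding barrier
#'   over TS1;
#' * `ddG_TS2_N  = RT * ln((ku/Kpart)_mut / (ku/Kpart)_wt)` — change of the
#'   unfolding barrier over the late transition state (requires `Kpart > 0`
#'   in both variants);
#' * `ddG_eq     = RT * ln((kf/ku)_wt / (kf/ku)_mut)` — change in overall
#'   stability, identically `ddG_D_TS1 + ddG_TS1_N`.
#'
#' Standard errors, when rate-constant errors are supplied, are propagated to
#' first order: the error on `RT*ln(a/b)` is
#' `RT * sqrt((se_a/a)^2 + (se_b/b)^2)`.
#'
#' @param wt,mut [kinetic_params] for wild type and mutant (must share `RT`).
#' @param wt_se,mut_se Optional named vectors of standard errors with
#'   elements among `kf0`, `ku0`, `Kpart`.
#' @return A list with the four `ddG` terms (kcal mol^-1) and, when errors
#'   were given, matching `*_se` elements.
#' @export
ddg_terms <- function(wt, mut, wt_se = NULL, mut_se = NULL) {
  stopifnot(inherits(wt, "kinetic_params"), inherits(mut, "kinetic_params"))
  if (!isTRUE(all.equal(wt$RT, mut$RT)))
    stop("wt and mutant parameters use different RT", call. = FALSE)
  RT <- wt$RT
  out <- list(
    ddG_D_TS1 = RT * log(wt$kf0 / mut$kf0),
    ddG_TS1_N = RT * log(mut$ku0 / wt$ku0),
    ddG_TS2_N = if (wt$Kpart > 0 && mut$Kpart > 0)
      RT * log((mut$ku0 / mut$Kpart) / (wt$ku0 / wt$Kpart))
    else NA_real_,
    ddG_eq = RT * log((wt$kf0 / wt$ku0) / (mut$kf0 / mut$ku0)))
  if (wt$Kpart <= 0 || mut$Kpart <= 0)
    warning("Kpart = 0 in wt or mutant: ddG_TS2_N undefined", call. = FALSE)

  if (!is.null(wt_se) || !is.null(mut_se)) {
    rel <- function(se, val) if (is.null(se) || is.na(se[1])) 0 else se / val
    rkf <- c(rel(wt_se["kf0"], wt$kf0), rel(mut_se["kf0"], mut$kf0))
    rku <- c(rel(wt_se["ku0"], wt$ku0), rel(mut_se["ku0"], mut$ku0))
    rKp <- c(rel(wt_se["Kpart"], wt$Kpart), rel(mut_se["Kpart"], mut$Kpart))
    out$ddG_D_TS1_se <- RT * sqrt(sum(rkf^2))
    out$ddG_TS1_N_se <- RT * sqrt(sum(rku^2))
    out$ddG_TS2_N_se <- RT * sqrt(sum(rku^2) + sum(rKp^2))
    out$ddG_eq_se <- RT * sqrt(sum(rkf^2) + sum(rku^2))
  }
  out
}

#' Phi-values for the early and late transition states
#'
#' \deqn{\Phi_{TS1} = \Delta\Delta G_{D-TS1} / \Delta\Delta G_{eq}}
#' \deqn{\Phi_{TS2} = 1 - \Delta\Delta G_{TS2-N} / \Delta\Delta G_{eq}}
#' Variants whose overall destabilisation is too small to normalise reliably
#' — `|ddG_eq|` below `exclusion_threshold` — are excluded (the absolute
#' value is compared, so slightly *stabilising* substitutions are excluded on
#' the same footing). Stabilising mutants beyond the threshold are computed
#' and reported, including the resulting negative Phi-values.
#'
#' First-order error propagation through each ratio is applied when the term
#' errors are present in `terms`.
#'
#' @param terms Output of [ddg_terms()]. The `ddG_eq` used for normalisation
#'   can be overridden via `ddG_eq` (e.g. to use an equilibrium-measured
#'   value), with optional `ddG_eq_se`.
#' @param exclusion_threshold kcal mol^-1, default 0.4.
#' @param ddG_eq,ddG_eq_se Optional overrides of the normalising stability
#'   change and its error.
#' @return A list with `phi_ts1`, `phi_ts2`, `excluded` (logical) and, when
#'   propagation was possible, `phi_ts1_se`, `phi_ts2_se`. Excluded variants
#'   carry `NA` Phi-values.
#' @export
phi_values <- function(terms, exclusion_threshold = 0.4, ddG_eq = NULL,
                       ddG_eq_se = NULL) {
  e <- if (is.null(ddG_eq)) terms$ddG_eq else ddG_eq
  e_se <- if (is.null(ddG_eq)) terms$ddG_eq_se else ddG_eq_se
  if (abs(e) < exclusion_threshold)
    return(list(phi_ts1 = NA_real_, phi_ts2 = NA_real_, excluded = TRUE))
  if (e == 0)
    stop("division error: ddG_eq is exactly zero and the exclusion ",
         "threshold is zero", call. = FALSE)
  a <- terms$ddG_D_TS1
  b <- terms$ddG_TS2_N
  out <- list(phi_ts1 = a / e, phi_ts2 = 1 - b / e, excluded = FALSE)
  if (!is.null(terms$ddG_D_TS1_se) && !is.null(e_se)) {
    out$phi_ts1_se <- sqrt((terms$ddG_D_TS1_se / e)^2 + (a * e_se / e^2)^2)
    out$phi_ts2_se <- sqrt((terms$ddG_TS2_N_se / e)^2 + (b * e_se / e^2)^2)
  }
  out
}

#' Classify a Phi-value into the standard four categories
#'
#' `[0, 0.3)` low, `[0.3, 0.7)` intermediate, `[0.7, 1]` high, and outside
#' `[0, 1]` non-canonical (values below 0 or above 1 suggest non-native
#' interactions in the probed transition state). Vectorised; `NA` maps to
#' `"excluded"`.
#'
#' @param phi Numeric Phi-value(s).
#' @return Character vector of category labels.
#' @export
classify_phi <- function(phi) {
  out <- rep("excluded", length(phi))
  ok <- is.finite(phi)
  out[ok & (phi < 0 | phi > 1)] <- "non_canonical"
  out[ok & phi >= 0 & phi < 0.3] <- "low"
  out[ok & phi >= 0.3 & phi < 0.7] <- "intermediate"
  out[ok & phi >= 0.7 & phi <= 1] <- "high"
  out
}

#' Per-variant Phi-value table from a global fit
#'
#' Computes [ddg_terms()] and [phi_values()] for every non-wild-type variant
#' of a [global_fit()] result, with first-order error propagation from the
#' fit's standard errors, and attaches category labels. Row order follows
#' the result's variant order.
#'
#' @param result A `global_fit_result` containing the wild type.
#' @param exclusion_threshold kcal mol^-1, default 0.4.
#' @return A data.frame with one row per mutant: rate constants, `ddG` terms,
#'   Phi-values, their standard errors, and `category_ts1`/`category_ts2`.
#' @export
phi_table <- function(result, exclusion_threshold = 0.4) {
  stopifnot(inherits(result, "global_fit_result"))
  ids <- names(result$per_variant)
  wt_pos <- which(is_wildtype_id(ids, result$wt_id))
  if (length(wt_pos) != 1L)
    stop("state error: wild type ('", result$wt_id,
         "') missing from global fit result", call. = FALSE)
  wt <- result$per_variant[[wt_pos]]
  se_row <- function(i) {
    r <- result$standard_errors[i, ]
    c(kf0 = r$kf0, ku0 = r$ku0, Kpart = r$Kpart)
  }
  rows <- lapply(setdiff(seq_along(ids), wt_pos), function(i) {
    mut <- result$per_variant[[i]]
    tm <- ddg_terms(wt, mut, wt_se = se_row(wt_pos), mut_se = se_row(i))
    ph <- phi_values(tm, exclusion_threshold)
    data.frame(
      variant = ids[i],
      kf0 = mut$kf0, ku0 = mut$ku0, Kpart = mut$Kpart,
      ddG_D_TS1 = tm$ddG_D_TS1, ddG_TS1_N = tm$ddG_TS1_N,
      ddG_TS2_N = tm$ddG_TS2_N, ddG_eq = tm$ddG_eq,
      ddG_D_TS1_se = tm$ddG_D_TS1_se, ddG_TS1_N_se = tm$ddG_TS1_N_se,
      ddG_TS2_N_se = tm$ddG_TS2_N_se, ddG_eq_se = tm$ddG_eq_se,
      phi_ts1 = ph$phi_ts1, phi_ts2 = ph$phi_ts2,
      phi_ts1_se = if (is.null(ph$phi_ts1_se)) NA_real_ else ph$phi_ts1_se,
      phi_ts2_se = if (is.null(ph$phi_ts2_se)) NA_real_ else ph$phi_ts2_se,
      excluded = ph$excluded,
      category_ts1 = classify_phi(ph$phi_ts1),
      category_ts2 = classify_phi(ph$phi_ts2))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(), kf0 = numeric(), ku0 = numeric(),
               Kpart = numeric(), ddG_D_TS1 = numeric(), ddG_TS1_N = numeric(),
               ddG_TS2_N = numeric(), ddG_eq = numeric(),
               ddG_D_TS1_se = numeric(), ddG_TS1_N_se = numeric(),
               ddG_TS2_N_se = numeric(), ddG_eq_se = numeric(),
               phi_ts1 = numeric(), phi_ts2 = numeric(),
               phi_ts1_se = numeric(), phi_ts2_se = numeric(),
               excluded = logical(), category_ts1 = character(),
               category_ts2 = character())
  rownames(out) <- NULL
  out
}
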