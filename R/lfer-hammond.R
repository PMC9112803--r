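#' Linear free-energy relationship (alpha value) across variants
#'
#' Regresses the mutational free-energy change of a transition state on the
#' change in overall stability, across site-directed variants. The slope
#' (the alpha value, nominally between 0 and 1) measures the average degree
#' of native-like structure in that transition state:
#'
#' * TS1: `y = ddG_D_TS1`, the destabilisation of the early barrier;
#' * TS2: `y = ddG_eq - ddG_TS2_N` (= `ddG_D_TS2`), the destabilisation of
#'   the late barrier measured from the denatured state.
#'
#' `x = ddG_eq` in both cases. Ordinary least squares with a free intercept.
#' Variants marked excluded (insufficient `|ddG_eq|`) are dropped, as are
#' any ids in `drop_ids` (e.g. variants rejected upstream for unreliable
#' fits); the ids actually used are recorded for reproducibility.
#'
#' @param thermo A data.frame as returned by [phi_table()] (columns
#'   `variant`, `ddG_D_TS1`, `ddG_TS2_N`, `ddG_eq`, `excluded`).
#' @param which_ts `"ts1"` or `"ts2"`.
#' @param drop_ids Optional character vector of variant ids to exclude.
#' @return List of class `lfer_result`: `which_ts`, `alpha`, `intercept`,
#'   `se_alpha`, `se_intercept`, `n_variants`, `included_ids`.
#' @export
lfer_fit <- function(thermo, which_ts = c("ts1", "ts2"), drop_ids = NULL) {
  which_ts <- match.arg(which_ts)
  stopifnot(is.data.frame(thermo))
  keep <- !thermo$excluded & !(thermo$variant %in% drop_ids)
  d <- thermo[keep, ]
  if (nrow(d) < 3L)
    stop("input error: LFER needs at least 3 non-excluded variants",
         call. = FALSE)
  x <- d$ddG_eq
  y <- if (which_ts == "ts1") d$ddG_D_TS1 else d$ddG_eq - d$ddG_TS2_N
  fit <- stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit)$coefficients)  # exact fits give SE ~ 0
  structure(list(which_ts = which_ts, alpha = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 se_alpha = unname(co["x", "Std. Error"]),
                 se_intercept = unname(co["(Intercept)", "Std. Error"]),
                 n_variants = nrow(d), included_ids = d$variant),
            class = "lfer_result")
}

#' @export
print.lfer_result <- function(x, ...) {
  cat(sprintf("LFER %s: alpha = %.3f +/- %.3f (intercept %.3f, n = %d)\n",
              toupper(x$which_ts), x$alpha, x$se_alpha, x$intercept,
              x$n_variants))
  invisible(x)
}

#' Hammond-effect regression of beta-Tanford against stability
#'
#' Linear fit of a transition state's Tanford beta value against the
#' variants' folding free energy `dG_DN`. A negative slope — the transition
#' state drifting toward the native state as the native state is
#' destabilised — is the Hammond-consistent outcome; the sign is reported,
#' never enforced.
#'
#' @param betas Named list of `tanford_betas` (e.g. from
#'   [betas_per_variant()]).
#' @param stabilities Named numeric vector of `dG_DN` values (kcal mol^-1);
#'   names must match `betas`.
#' @param which_ts `"ts1"` or `"ts2"`.
#' @return List of class `hammond_result`: `which_ts`, `slope` (beta per
#'   kcal mol^-1), `intercept`, `se_slope`, `n_variants`.
#' @export
hammond_fit <- function(betas, stabilities, which_ts = c("ts1", "ts2")) {
  which_ts <- match.arg(which_ts)
  ids <- intersect(names(betas), names(stabilities))
  if (length(ids) < 3L)
    stop("input error: Hammond fit needs at least 3 variants with both a ",
         "beta and a stability", call. = FALSE)
  field <- paste0("beta_", which_ts)
  y <- vapply(betas[ids], function(b) b[[field]], numeric(1))
  x <- as.numeric(stabilities[ids])
  fit <- stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit)$coefficients)  # exact fits give SE ~ 0
  se_slope <- if (nrow(co) >= 2L && "Std. Error" %in% colnames(co))
    unname(co["x", "Std. Error"]) else NA_real_
  structure(list(which_ts = which_ts, slope = unname(stats::coef(fit)[["x"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 se_slope = se_slope, n_variants = length(ids)),
            class = "hammond_result")
}

#' @export
print.hammond_result <- function(x, ...) {
  cat(sprintf("Hammond %s: d(beta)/d(dG) = %.4f +/- %.4f per kcal/mol (n = %d)%s\n",
              toupper(x$which_ts), x$slope, x$se_slope, x$n_variants,
              if (is.finite(x$slope) && x$slope < 0)
                "  [Hammond-consistent]" else ""))
  invisible(x)
}

#' Phi-vs-Phi comparison between two homologous domains
#'
#' Pairs Phi-values of structurally equivalent residues of two homologous
#' domains (the residue correspondence comes from an externally supplied
#' alignment mapping) and summarises how similar the probed folding stages
#' are: mean offset (B minus A), root-mean-square deviation from the
#' identity line, and Pearson correlation. Positions missing or excluded on
#' either side are dropped, with the dropped count reported.
#'
#' @param mapping Data.frame with columns `pos_a`, `pos_b` (1-based residue
#'   numbers in each domain).
#' @param phis_a,phis_b Named numeric vectors of Phi-values, names being the
#'   residue numbers as characters (or numbers); `NA` marks excluded
#'   positions.
#' @param stage Label for the folding stage compared (`"early"` or
#'   `"late"`).
#' @return List of class `phi_vs_phi_result`: `pairs` (data.frame `pos_a`,
#'   `pos_b`, `phi_a`, `phi_b`, `stage`), `n`, `n_dropped`, `mean_offset`,
#'   `rmsd_identity`, `pearson_r`.
#' @export
phi_vs_phi <- function(mapping, phis_a, phis_b, stage = c("early", "late")) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(mapping), all(c("pos_a", "pos_b") %in% names(mapping)))
  pa <- phis_a[as.character(mapping$pos_a)]
  pb <- phis_b[as.character(mapping$pos_b)]
  ok <- is.finite(pa) & is.finite(pb)
  n_dropped <- sum(!ok)
  if (!any(ok))
    stop("input error: no residue pair has a usable Phi-value on both sides",
         call. = FALSE)
  if (n_dropped > 0)
    message(n_dropped, " mapped position(s) dropped (missing or excluded Phi)")
  pairs <- data.frame(pos_a = mapping$pos_a[ok], pos_b = mapping$pos_b[ok],
                      phi_a = as.numeric(pa[ok]), phi_b = as.numeric(pb[ok]),
                      stage = stage)
  r <- if (nrow(pairs) >= 3L && stats::sd(pairs$phi_a) > 0 &&
           stats::sd(pairs$phi_b) > 0)
    stats::cor(pairs$phi_a, pairs$phi_b) else NA_real_
  structure(list(pairs = pairs, n = nrow(pairs), n_dropped = n_dropped,
                 mean_offset = mean(pairs$phi_b - pairs$phi_a),
                 rmsd_identity = sqrt(mean((pairs$phi_b - pairs$phi_a)^2)),
                 pearson_r = r),
            class = "phi_vs_phi_result")
}

#' @export
print.phi_vs_phi_result <- function(x, ...) {
  cat(sprintf("Phi-vs-Phi (%s): n = %d pairs (%d dropped); mean offset = %+.3f, RMSD from identity = %.3f, r = %.3f\n",
              x$pairs$stage[1], x$n, x$n_dropped, x$mean_offset,
              x$rmsd_identity, x$pearson_r))
  invisible(x)
}
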