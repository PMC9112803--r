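#' Fitting control settings
#'
#' Numerical settings shared by [fit_single_chevron()] and [global_fit()].
#' Chevrons are fitted in log10(kobs) space; positivity of the rate constants
#' and of the partitioning constant is enforced by optimising their
#' logarithms, while m-values are bounded below at zero.
#'
#' @param n_starts Number of multistart attempts: one deterministic start from
#'   a grid-scan initialisation plus `n_starts - 1` randomised perturbations
#'   of it (default 10).
#' @param seed Seed making the multistart perturbations reproducible
#'   (default 1).
#' @param ftol Relative tolerance on the sum of squared residuals (default
#'   1e-10).
#' @param maxfev Maximum number of residual evaluations per start (default
#'   5000).
#' @param wt_id Identifier of the wild-type dataset (matched
#'   case-insensitively; default `"wt"`).
#' @return A list of class `chevron_control`.
#' @export
chevron_control <- function(n_starts = 10L, seed = 1L, ftol = 1e-10,
                            maxfev = 5000L, wt_id = "wt") {
  stopifnot(n_starts >= 1L, ftol > 0, maxfev > 0)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 ftol = ftol, maxfev = as.integer(maxfev), wt_id = wt_id),
            class = "chevron_control")
}

# evaluate code with a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# log-linear limb regression giving crude two-state parameters
init_two_state <- function(pts, RT) {
  lk <- log(pts$kobs)
  i_min <- which.min(lk)
  fold <- pts$urea < pts$urea[i_min] | seq_len(nrow(pts)) == i_min
  unf <- pts$urea > pts$urea[i_min] | seq_len(nrow(pts)) == i_min
  limb <- function(sel, sgn) {
    if (sum(sel) >= 2L && length(unique(pts$urea[sel])) >= 2L) {
      co <- stats::coef(stats::lm(lk[sel] ~ pts$urea[sel]))
      c(k = exp(co[[1L]]), m = max(sgn * co[[2L]] * RT, 0.05))
    } else c(k = exp(lk[i_min]), m = 0.5)
  }
  f <- limb(fold, -1); u <- limb(unf, +1)
  list(kf0 = max(f[["k"]], 1e-8), mf = f[["m"]],
       ku0 = max(u[["k"]], 1e-10), mu = u[["m"]])
}

# grid scan over (Kpart, mpart) around the two-state skeleton; the apparent
# unfolding slope of a kinked chevron is (mu - mpart), so mu is offset by
# each candidate mpart
init_three_state <- function(pts, RT) {
  ts <- init_two_state(pts, RT)
  best <- NULL
  for (Kp in c(0.005, 0.02, 0.1, 0.4))
    for (mp in c(0.1, 0.3, 0.45, 0.7)) {
      cand <- list(kf0 = ts$kf0 * (1 + Kp), mf = ts$mf, ku0 = ts$ku0 * (1 + Kp),
                   mu = ts$mu + mp, Kpart = Kp, mpart = mp)
      k <- (cand$kf0 * exp(-cand$mf * pts$urea / RT) +
              cand$ku0 * exp(cand$mu * pts$urea / RT)) /
        (1 + Kp * exp(mp * pts$urea / RT))
      ssr <- sum((log10(k) - log10(pts$kobs))^2)
      if (is.null(best) || ssr < best$ssr) best <- c(cand, list(ssr = ssr))
    }
  best[setdiff(names(best), "ssr")]
}

run_lm_multistart <- function(p0, lower, resid_fun, control) {
  perturb <- with_seed(control$seed, {
    lapply(seq_len(max(control$n_starts - 1L, 0L)), function(i) {
      dp <- stats::rnorm(length(p0), sd = 0.4)
      p <- p0
      is_m <- lower == 0           # m-values live on the raw scale
      p[is_m] <- pmax(p[is_m] * exp(dp[is_m] * 0.5), 0)
      p[!is_m] <- p[!is_m] + dp[!is_m]
      p
    })
  })
  best <- NULL
  for (st in c(list(p0), perturb)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(st, lower = lower, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = control$ftol, ptol = 1e-12,
                           maxfev = control$maxfev, maxiter = 1024)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("fit-failure: no multistart attempt converged", call. = FALSE)
  best
}

# covariance-derived standard errors; warns (not errors) on singularity
se_from_fit <- function(fit, context = "fit") {
  dof <- max(length(fit$fvec) - length(fit$par), 1L)
  resvar <- fit$deviance / dof
  qrh <- qr(fit$hessian)
  if (qrh$rank < ncol(fit$hessian)) {
    bad <- colnames(fit$hessian)[qrh$pivot[(qrh$rank + 1L):ncol(fit$hessian)]]
    warning("degeneracy in ", context,
            ": singular Jacobian; unreliable parameters: ",
            paste(bad, collapse = ", "), call. = FALSE)
    se <- rep(NA_real_, length(fit$par))
    ok <- qrh$pivot[seq_len(qrh$rank)]
    cov_ok <- tryCatch(solve(fit$hessian[ok, ok, drop = FALSE]) * resvar,
                       error = function(e) NULL)
    if (!is.null(cov_ok)) se[ok] <- sqrt(pmax(diag(cov_ok), 0))
    names(se) <- names(fit$par)
    return(se)
  }
  se <- sqrt(pmax(diag(solve(fit$hessian)) * resvar, 0))
  names(se) <- names(fit$par)
  se
}

log10_weights <- function(pts, weighted) {
  if (weighted && all(is.finite(pts$sigma)))
    1 / (pts$sigma / (pts$kobs * log(10)))   # sigma on kobs -> sigma on log10
  else rep(1, nrow(pts))
}

#' Fit one chevron plot
#'
#' Least-squares fit of a single variant's `(urea, kobs)` data to the
#' two-state or three-state rate law. Residuals are computed on
#' `log10(kobs)`, the space in which chevrons are analysed and displayed;
#' they are unweighted unless `weighted = TRUE` and per-point sigmas are
#' available. Rates (and `Kpart`) are fitted as logarithms, m-values bounded
#' at zero.
#'
#' @param data A [chevron_dataset] with >= 5 points (two-state) or >= 7
#'   points (three-state).
#' @param model `"three_state"` (default) or `"two_state"`.
#' @param init Optional [kinetic_params] used as the central start; otherwise
#'   a limb-regression / grid-scan initialisation is used.
#' @param weighted Use per-point sigmas as weights (default FALSE).
#' @param RT Thermal energy, kcal mol^-1.
#' @param control A [chevron_control].
#' @return List with `params` ([kinetic_params]), `se` (named standard
#'   errors on the natural scale), `objective` (SSR in log10 kobs),
#'   `converged`, `n_points`.
#' @export
fit_single_chevron <- function(data, model = c("three_state", "two_state"),
                               init = NULL, weighted = FALSE, RT = RT_25C,
                               control = chevron_control()) {
  stopifnot(inherits(data, "chevron_dataset"))
  model <- match.arg(model)
  pts <- data$points
  need <- if (model == "three_state") 7L else 5L
  if (nrow(pts) < need)
    stop(sprintf("input error: variant '%s' has %d points; %s fit needs >= %d",
                 data$variant_id, nrow(pts), model, need), call. = FALSE)

  w <- log10_weights(pts, weighted)
  y <- log10(pts$kobs)
  u <- pts$urea

  if (is.null(init)) {
    ini <- if (model == "three_state") init_three_state(pts, RT)
           else init_two_state(pts, RT)
  } else {
    stopifnot(inherits(init, "kinetic_params"))
    ini <- init
  }

  if (model == "three_state") {
    p0 <- c(lkf0 = log(ini$kf0), mf = ini$mf, lku0 = log(ini$ku0),
            mu = ini$mu, lKpart = log(max(ini$Kpart, 1e-6)),
            mpart = ini$mpart)
    lower <- c(-Inf, 0, -Inf, 0, -Inf, 0)
    fn <- function(p) {
      k <- (exp(p[["lkf0"]]) * exp(-p[["mf"]] * u / RT) +
              exp(p[["lku0"]]) * exp(p[["mu"]] * u / RT)) /
        (1 + exp(p[["lKpart"]]) * exp(p[["mpart"]] * u / RT))
      w * (log10(k) - y)
    }
  } else {
    p0 <- c(lkf0 = log(ini$kf0), mf = ini$mf, lku0 = log(ini$ku0), mu = ini$mu)
    lower <- c(-Inf, 0, -Inf, 0)
    fn <- function(p) {
      k <- exp(p[["lkf0"]]) * exp(-p[["mf"]] * u / RT) +
        exp(p[["lku0"]]) * exp(p[["mu"]] * u / RT)
      w * (log10(k) - y)
    }
  }

  fit <- run_lm_multistart(p0, lower, fn, control)
  se_int <- se_from_fit(fit, context = paste0("chevron '", data$variant_id, "'"))
  p <- fit$par

  params <- if (model == "three_state")
    kinetic_params(exp(p[["lkf0"]]), p[["mf"]], exp(p[["lku0"]]), p[["mu"]],
                   exp(p[["lKpart"]]), p[["mpart"]], RT = RT)
  else
    kinetic_params(exp(p[["lkf0"]]), p[["mf"]], exp(p[["lku0"]]), p[["mu"]],
                   RT = RT)

  se <- c(kf0 = params$kf0 * se_int[["lkf0"]], mf = se_int[["mf"]],
          ku0 = params$ku0 * se_int[["lku0"]], mu = se_int[["mu"]])
  if (model == "three_state")
    se <- c(se, Kpart = params$Kpart * se_int[["lKpart"]],
            mpart = se_int[["mpart"]])

  list(params = params, se = se, objective = fit$deviance,
       converged = fit$info %in% 1:4, n_points = nrow(pts))
}

scheme_shared <- function(scheme) {
  switch(scheme,
         shared_all_m = c("mf", "mu", "mpart"),
         free_mf_mu = "mpart",
         free_mf = c("mu", "mpart"),
         stop("unknown constraint scheme: ", scheme, call. = FALSE))
}

#' Global fit of many chevrons with shared m-values
#'
#' Fits all variants' chevron plots as a single joint least-squares problem
#' under the three-state rate law. Per-variant `kf0`, `ku0` and `Kpart` are
#' always free; the kinetic m-values are constrained according to `scheme`:
#'
#' * `"shared_all_m"` — `mf`, `mu`, `mpart` common to all variants (the main
#'   analysis scheme; mutations are assumed to change barrier heights, not
#'   solvent exposure).
#' * `"free_mf_mu"` — per-variant `mf` and `mu`, shared `mpart` (used to probe
#'   Hammond-type transition-state movement).
#' * `"free_mf"` — per-variant `mf`, shared `mu` and `mpart` (robustness
#'   check on the early transition state).
#'
#' The fully unconstrained fit (all m-values free per variant) is nearly
#' always degenerate for realistic data; it is not offered as a scheme, and
#' rank deficiency encountered in any scheme raises a degeneracy warning
#' naming the affected parameters.
#'
#' Datasets are internally ordered by variant id, so the result is invariant
#' to the input ordering; the `per_variant` output follows the input order.
#'
#' @param datasets List of [chevron_dataset]s (>= 2), one of which must be
#'   the wild type (id `"wt"`, case-insensitive, see [chevron_control()]).
#' @param scheme Constraint scheme, see above.
#' @param init Optional named list of [kinetic_params] (by variant id) used
#'   as central starts.
#' @param weighted Use per-point sigmas as weights (default FALSE).
#' @param RT Thermal energy, kcal mol^-1.
#' @param control A [chevron_control].
#' @return Object of class `global_fit_result`: `scheme`, `per_variant`
#'   (named list of [kinetic_params]), `standard_errors` (data.frame),
#'   `shared` (named vector of shared m-values), `objective`, `converged`,
#'   `n_points`.
#' @export
global_fit <- function(datasets,
                       scheme = c("shared_all_m", "free_mf_mu", "free_mf"),
                       init = NULL, weighted = FALSE, RT = RT_25C,
                       control = chevron_control()) {
  scheme <- match.arg(scheme)
  stopifnot(is.list(datasets),
            all(vapply(datasets, inherits, logical(1), "chevron_dataset")))
  if (length(datasets) < 2L)
    stop("input error: global fit needs at least 2 datasets", call. = FALSE)
  ids_in <- vapply(datasets, function(d) d$variant_id, character(1))
  if (anyDuplicated(ids_in))
    stop("input error: duplicated variant ids", call. = FALSE)
  if (!any(is_wildtype_id(ids_in, control$wt_id)))
    stop("input error: no wild-type dataset (id '", control$wt_id,
         "') present", call. = FALSE)
  small <- ids_in[vapply(datasets, function(d) nrow(d$points), integer(1)) < 7L]
  if (length(small))
    stop("input error: fewer than 7 points for variant(s): ",
         paste(small, collapse = ", "), call. = FALSE)

  ord <- order(ids_in)
  ds <- datasets[ord]
  ids <- ids_in[ord]
  V <- length(ds)
  shared <- scheme_shared(scheme)
  free_m <- setdiff(c("mf", "mu", "mpart"), shared)

  u_all <- unlist(lapply(ds, function(d) d$points$urea))
  y_all <- unlist(lapply(ds, function(d) log10(d$points$kobs)))
  w_all <- unlist(lapply(ds, function(d) log10_weights(d$points, weighted)))
  vidx <- rep(seq_len(V), vapply(ds, function(d) nrow(d$points), integer(1)))

  # per-variant grid-scan initialisation; shared m starts at the median
  inis <- lapply(seq_len(V), function(i) {
    if (!is.null(init) && !is.null(init[[ids[i]]])) init[[ids[i]]]
    else init_three_state(ds[[i]]$points, RT)
  })
  med <- function(field) stats::median(vapply(inis, function(x) x[[field]],
                                              numeric(1)))

  p0 <- numeric(0); lower <- numeric(0)
  for (m in shared) { p0[m] <- med(m); lower[m] <- 0 }
  for (i in seq_len(V)) {
    p0[paste0("lkf0_", i)] <- log(inis[[i]]$kf0); lower[paste0("lkf0_", i)] <- -Inf
    p0[paste0("lku0_", i)] <- log(inis[[i]]$ku0); lower[paste0("lku0_", i)] <- -Inf
    p0[paste0("lKpart_", i)] <- log(max(inis[[i]]$Kpart, 1e-6))
    lower[paste0("lKpart_", i)] <- -Inf
    for (m in free_m) { p0[paste0(m, "_", i)] <- inis[[i]][[m]]
                        lower[paste0(m, "_", i)] <- 0 }
  }

  decode <- function(p) {
    g <- list(kf0 = exp(p[paste0("lkf0_", seq_len(V))]),
              ku0 = exp(p[paste0("lku0_", seq_len(V))]),
              Kpart = exp(p[paste0("lKpart_", seq_len(V))]))
    for (m in c("mf", "mu", "mpart"))
      g[[m]] <- if (m %in% shared) rep(p[[m]], V)
                else p[paste0(m, "_", seq_len(V))]
    g
  }
  fn <- function(p) {
    g <- decode(p)
    k <- (g$kf0[vidx] * exp(-g$mf[vidx] * u_all / RT) +
            g$ku0[vidx] * exp(g$mu[vidx] * u_all / RT)) /
      (1 + g$Kpart[vidx] * exp(g$mpart[vidx] * u_all / RT))
    w_all * (log10(k) - y_all)
  }

  fit <- run_lm_multistart(p0, lower, fn, control)
  if (!fit$info %in% 1:4)
    stop("fit-failure: global fit did not converge; affected variants: ",
         paste(ids, collapse = ", "), call. = FALSE)
  se_int <- se_from_fit(fit, context = paste0("global fit (", scheme, ")"))
  g <- decode(fit$par)

  per_variant <- vector("list", V); names(per_variant) <- ids
  se_rows <- vector("list", V)
  for (i in seq_len(V)) {
    per_variant[[i]] <- kinetic_params(g$kf0[[i]], g$mf[[i]], g$ku0[[i]],
                                       g$mu[[i]], g$Kpart[[i]], g$mpart[[i]],
                                       RT = RT)
    pick <- function(m) if (m %in% shared) se_int[[m]]
                        else se_int[[paste0(m, "_", i)]]
    se_rows[[i]] <- data.frame(
      variant = ids[i],
      kf0 = g$kf0[[i]] * se_int[[paste0("lkf0_", i)]],
      mf = pick("mf"),
      ku0 = g$ku0[[i]] * se_int[[paste0("lku0_", i)]],
      mu = pick("mu"),
      Kpart = g$Kpart[[i]] * se_int[[paste0("lKpart_", i)]],
      mpart = pick("mpart"))
  }
  ses <- do.call(rbind, se_rows)

  # restore input ordering
  back <- match(ids_in, ids)
  per_variant <- per_variant[back]
  ses <- ses[back, , drop = FALSE]
  rownames(ses) <- NULL

  shared_vals <- vapply(shared, function(m) fit$par[[m]], numeric(1))
  structure(list(scheme = scheme, per_variant = per_variant,
                 standard_errors = ses, shared = shared_vals,
                 objective = fit$deviance, converged = fit$info %in% 1:4,
                 n_points = length(u_all), wt_id = control$wt_id),
            class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("Global chevron fit (%s): %d variants, %d points, SSR(log10 kobs) = %.4g\n",
              x$scheme, length(x$per_variant), x$n_points, x$objective))
  if (length(x$shared))
    cat("  shared m-values:",
        paste(sprintf("%s = %.3f", names(x$shared), x$shared), collapse = ", "),
        "\n")
  invisible(x)
}

#' Tanford beta values for each variant of a global fit
#'
#' Applies [beta_tanford()] to every variant's fitted parameters. Under the
#' `shared_all_m` scheme all variants share one set of m-values and the betas
#' are necessarily identical across variants; this is permitted but flagged
#' with a warning, since a Hammond analysis needs a scheme with per-variant
#' m-values.
#'
#' @param result A `global_fit_result`.
#' @return Named list of `tanford_betas`, in the result's variant order.
#' @export
betas_per_variant <- function(result) {
  stopifnot(inherits(result, "global_fit_result"))
  if (result$scheme == "shared_all_m")
    warning("scheme 'shared_all_m' has common m-values: all betas identical",
            call. = FALSE)
  lapply(result$per_variant, beta_tanford)
}
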