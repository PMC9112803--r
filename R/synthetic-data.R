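#' Default wild-type parameters of the packaged reference protein
#'
#' Three-state parameters used as the default truth for synthetic data:
#' rate constants and partitioning constant from the packaged reference
#' table's wild-type row (`kf0 = 300`, `ku0 = 0.06`, `Kpart = 0.017`), with
#' `mu = 0.52` and `mpart = 0.45` kcal mol^-1 M^-1 from the relaxed global
#' fits of the same study and `mf = 0.81` back-derived from the reported
#' early-transition-state position `beta_TS1 = 0.61`
#' (`mf = beta_TS1/(1 - beta_TS1) * mu`).
#'
#' @param RT Thermal energy, kcal mol^-1.
#' @return A [kinetic_params] object.
#' @export
reference_wt_params <- function(RT = RT_25C) {
  kinetic_params(kf0 = 300, mf = 0.81, ku0 = 0.06, mu = 0.52,
                 Kpart = 0.017, mpart = 0.45, RT = RT)
}

#' Construct a mutant with prescribed destabilisation and Phi-values
#'
#' Inverts the Phi-value formulas: given the wild type, a target overall
#' destabilisation and target Phi-values for the two transition states,
#' returns the mutant rate constants that reproduce them exactly:
#' `kf = kf_wt * exp(-phi_ts1 * ddG_eq / RT)`,
#' `ku = ku_wt * exp((1 - phi_ts1) * ddG_eq / RT)` (so that the activation
#' terms sum to `ddG_eq`), and
#' `Kpart = Kpart_wt * exp((phi_ts2 - phi_ts1) * ddG_eq / RT)` (so that
#' `ddG_TS2_N = (1 - phi_ts2) * ddG_eq`). m-values are held at the wild-type
#' values unless overridden — the world assumed by the shared-m fitting
#' scheme; per-variant overrides let stability-correlated m-shifts
#' (Hammond-behaving ensembles) be manufactured.
#'
#' @param wt Wild-type [kinetic_params].
#' @param ddG_eq Target stability change, kcal mol^-1 (positive =
#'   destabilising).
#' @param phi_ts1,phi_ts2 Target Phi-values.
#' @param mf,mu,mpart Optional m-value overrides.
#' @return A [kinetic_params] object.
#' @export
make_mutant <- function(wt, ddG_eq, phi_ts1, phi_ts2,
                        mf = wt$mf, mu = wt$mu, mpart = wt$mpart) {
  stopifnot(inherits(wt, "kinetic_params"))
  stopifnot(is.finite(ddG_eq), is.finite(phi_ts1), is.finite(phi_ts2))
  kinetic_params(
    kf0 = wt$kf0 * exp(-phi_ts1 * ddG_eq / wt$RT),
    mf = mf,
    ku0 = wt$ku0 * exp((1 - phi_ts1) * ddG_eq / wt$RT),
    mu = mu,
    Kpart = wt$Kpart * exp((phi_ts2 - phi_ts1) * ddG_eq / wt$RT),
    mpart = mpart,
    RT = wt$RT)
}

#' Default synthetic urea grid
#'
#' 0 to 9 M in 0.25 M steps — wide enough to sample both chevron limbs and
#' the kink in the unfolding arm where the rate-limiting step switches.
#'
#' @return Numeric vector of urea concentrations, M.
#' @export
default_urea_grid <- function() seq(0, 9, by = 0.25)

#' Simulate a chevron dataset from known parameters
#'
#' Evaluates the three-state rate law on a urea grid and applies
#' multiplicative lognormal noise, `kobs = model * 10^eps` with
#' `eps ~ Normal(0, noise_sd_log)` — additive Gaussian noise in log10 space,
#' matching the space in which chevrons are fitted.
#'
#' @param params True [kinetic_params].
#' @param urea_grid Urea concentrations, M.
#' @param noise_sd_log Standard deviation of the log10 noise (default 0.02,
#'   i.e. about 5% multiplicative scatter).
#' @param seed Integer seed; required whenever `noise_sd_log > 0`.
#' @param variant_id Label for the dataset (default `"wt"`).
#' @return A [chevron_dataset].
#' @export
simulate_chevron <- function(params, urea_grid = default_urea_grid(),
                             noise_sd_log = 0.02, seed = NULL,
                             variant_id = "wt") {
  stopifnot(inherits(params, "kinetic_params"))
  k <- three_state_rate(params, urea_grid)
  if (noise_sd_log > 0) {
    if (is.null(seed))
      stop("a seed is required for noisy simulation", call. = FALSE)
    eps <- with_seed(seed, stats::rnorm(length(k), sd = noise_sd_log))
    k <- k * 10^eps
  }
  chevron_dataset(variant_id, urea_grid, k)
}

#' Simulate a stopped-flow fluorescence trace
#'
#' Single-exponential time course with rate `three_state_rate(params, urea)`,
#' sampled over a window of `10 / kobs` (ten relaxation times), plus optional
#' additive Gaussian noise. Refolding traces rise (negative amplitude),
#' unfolding traces decay (positive amplitude).
#'
#' @param params True [kinetic_params].
#' @param urea Final urea concentration, M.
#' @param direction `"folding"` or `"unfolding"`.
#' @param n_points Number of samples (default 1000).
#' @param trace_noise_sd Additive noise, a.u. (default 0).
#' @param seed Integer seed; required when `trace_noise_sd > 0`.
#' @param amplitude,offset Signal amplitude magnitude and baseline, a.u.
#' @param variant_id Label for the trace (default `"wt"`).
#' @return An unfitted [trace_record].
#' @export
simulate_trace <- function(params, urea, direction = c("folding", "unfolding"),
                           n_points = 1000L, trace_noise_sd = 0, seed = NULL,
                           amplitude = 1, offset = 1, variant_id = "wt") {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "kinetic_params"))
  k <- three_state_rate(params, urea)
  tt <- seq(0, 10 / k, length.out = n_points)
  a <- if (direction == "folding") -abs(amplitude) else abs(amplitude)
  ff <- offset + a * exp(-k * tt)
  if (trace_noise_sd > 0) {
    if (is.null(seed))
      stop("a seed is required for noisy simulation", call. = FALSE)
    ff <- ff + with_seed(seed, stats::rnorm(n_points, sd = trace_noise_sd))
  }
  trace_record(variant_id, urea, tt, ff)
}

#' Specification of a synthetic mutant ensemble
#'
#' Describes the statistical design of a simulated mutagenesis study:
#' how many variants, the true wild type, the ranges the true `ddG_eq` and
#' Phi-values are drawn from (uniformly), the urea grid, and the noise
#' levels. Defaults mirror a realistic single-domain study: 29 variants,
#' stability changes between -1.3 and +3.3 kcal mol^-1, Phi-values anywhere
#' in \[0, 1\], 2% multiplicative noise on `kobs`.
#'
#' `hammond_dbeta_ddG` optionally tilts the per-variant m-values so that
#' `beta_TS1` (and with it `beta_TS2`) varies linearly with the variant's
#' stability with the given slope (beta per kcal mol^-1 of `dG_DN`), holding
#' `mf + mu` and `mpart` fixed — an ensemble with a built-in Hammond effect.
#'
#' @param n_variants Number of mutants (default 29).
#' @param wt_params True wild type (default [reference_wt_params()]).
#' @param ddG_eq_range,phi_ts1_range,phi_ts2_range Sampling intervals.
#' @param urea_grid Urea concentrations, M.
#' @param noise_sd_log sd of log10 noise on kobs (default 0.02).
#' @param trace_noise_sd Additive trace noise, a.u. (default 0.01).
#' @param hammond_dbeta_ddG Slope of beta_TS1 versus dG_DN (default 0, no
#'   m-value perturbation).
#' @param seed Integer seed (mandatory).
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_variants = 29L, wt_params = reference_wt_params(),
                          ddG_eq_range = c(-1.3, 3.3),
                          phi_ts1_range = c(0, 1), phi_ts2_range = c(0, 1),
                          urea_grid = default_urea_grid(),
                          noise_sd_log = 0.02, trace_noise_sd = 0.01,
                          hammond_dbeta_ddG = 0, seed) {
  stopifnot(inherits(wt_params, "kinetic_params"), n_variants >= 0)
  chk <- function(r) stopifnot(length(r) == 2L, r[1] <= r[2])
  chk(ddG_eq_range); chk(phi_ts1_range); chk(phi_ts2_range)
  if (missing(seed) || !is.finite(seed))
    stop("ensemble_spec requires an explicit integer seed", call. = FALSE)
  structure(list(n_variants = as.integer(n_variants), wt_params = wt_params,
                 ddG_eq_range = ddG_eq_range, phi_ts1_range = phi_ts1_range,
                 phi_ts2_range = phi_ts2_range, urea_grid = urea_grid,
                 noise_sd_log = noise_sd_log, trace_noise_sd = trace_noise_sd,
                 hammond_dbeta_ddG = hammond_dbeta_ddG,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Simulate a full mutant ensemble
#'
#' Draws true `(ddG_eq, phi_ts1, phi_ts2)` for each mutant from the spec's
#' ranges, constructs the mutants with [make_mutant()], simulates one noisy
#' chevron per variant (wild type included), and returns the datasets
#' together with the truth table used for recovery scoring.
#'
#' @param spec An [ensemble_spec].
#' @return List with `datasets` (list of [chevron_dataset], wild type first)
#'   and `truth` (data.frame: `variant`, true `kf0`, `ku0`, `Kpart`, `mf`,
#'   `mu`, `mpart`, `ddG_eq`, `phi_ts1`, `phi_ts2`, `dG_DN`).
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  wt <- spec$wt_params
  n <- spec$n_variants
  draws <- with_seed(spec$seed, list(
    ddG = stats::runif(n, spec$ddG_eq_range[1], spec$ddG_eq_range[2]),
    p1 = stats::runif(n, spec$phi_ts1_range[1], spec$phi_ts1_range[2]),
    p2 = stats::runif(n, spec$phi_ts2_range[1], spec$phi_ts2_range[2]),
    sub = sample.int(.Machine$integer.max %/% 2L, n + 1L)))

  wt_stab <- stability(wt)
  muts <- vector("list", n)
  for (i in seq_len(n)) {
    m <- list(mf = wt$mf, mu = wt$mu)
    if (spec$hammond_dbeta_ddG != 0) {
      # beta_TS1 tilted linearly in the variant's stability, m_DN held fixed
      m_DN <- wt$mf + wt$mu
      b1 <- wt$mf / m_DN +
        spec$hammond_dbeta_ddG * ((wt_stab$dG_DN - draws$ddG[i]) - wt_stab$dG_DN)
      b1 <- min(max(b1, 0.05), 0.95)
      m <- list(mf = b1 * m_DN, mu = (1 - b1) * m_DN)
    }
    muts[[i]] <- make_mutant(wt, draws$ddG[i], draws$p1[i], draws$p2[i],
                             mf = m$mf, mu = m$mu)
  }

  ids <- c("wt", sprintf("mut%02d", seq_len(n)))
  all_params <- c(list(wt), muts)
  datasets <- lapply(seq_along(all_params), function(i)
    simulate_chevron(all_params[[i]], spec$urea_grid, spec$noise_sd_log,
                     seed = draws$sub[i], variant_id = ids[i]))

  truth <- do.call(rbind, lapply(seq_along(all_params), function(i) {
    p <- all_params[[i]]
    data.frame(variant = ids[i], kf0 = p$kf0, ku0 = p$ku0, Kpart = p$Kpart,
               mf = p$mf, mu = p$mu, mpart = p$mpart,
               ddG_eq = if (i == 1L) 0 else draws$ddG[i - 1L],
               phi_ts1 = if (i == 1L) NA_real_ else draws$p1[i - 1L],
               phi_ts2 = if (i == 1L) NA_real_ else draws$p2[i - 1L],
               dG_DN = stability(p)$dG_DN)
  }))
  rownames(truth) <- NULL
  list(datasets = datasets, truth = truth)
}
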