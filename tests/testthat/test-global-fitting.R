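test_that("a noiseless chevron returns the generating parameters", {
  wt <- wt_params()
  d <- simulate_chevron(wt, seq(0, 9, length.out = 25), noise_sd_log = 0)
  f <- fit_single_chevron(d, control = fast_ctrl())
  for (nm in c("kf0", "mf", "ku0", "mu", "Kpart", "mpart"))
    expect_equal(f$params[[nm]], wt[[nm]], tolerance = 1e-4)
  expect_true(f$converged)
  expect_lt(f$objective, 1e-12)
  expect_true(all(f$se >= 0 | is.na(f$se)))
})

test_that("too few points raise an input error", {
  few <- chevron_dataset("x", 0:3, c(100, 20, 5, 10))
  expect_error(fit_single_chevron(few), "input error")
  six <- chevron_dataset("x", 0:5, c(300, 90, 30, 10, 6, 9))
  expect_error(fit_single_chevron(six, "three_state"), "input error")
})

test_that("kf0 is recovered within 10% median error under 5% noise", {
  wt <- wt_params()
  u <- seq(0, 9, length.out = 25)
  errs <- vapply(1:20, function(s) {
    d <- simulate_chevron(wt, u, noise_sd_log = 0.05 / log(10), seed = 1000 + s)
    f <- fit_single_chevron(d, control = fast_ctrl())
    abs(f$params$kf0 - wt$kf0) / wt$kf0
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("global fit recovers shared and per-variant truth without noise", {
  ens <- noiseless_ensemble(n = 5)
  fit <- global_fit(ens$datasets, "shared_all_m", control = fast_ctrl())
  expect_true(fit$converged)
  wt <- wt_params()
  expect_equal(unname(fit$shared["mf"]), wt$mf, tolerance = 1e-5)
  expect_equal(unname(fit$shared["mu"]), wt$mu, tolerance = 1e-5)
  expect_equal(unname(fit$shared["mpart"]), wt$mpart, tolerance = 1e-4)
  for (i in seq_len(nrow(ens$truth))) {
    v <- ens$truth$variant[i]
    expect_equal(fit$per_variant[[v]]$kf0, ens$truth$kf0[i], tolerance = 1e-4)
    expect_equal(fit$per_variant[[v]]$ku0, ens$truth$ku0[i], tolerance = 1e-4)
    expect_equal(fit$per_variant[[v]]$Kpart, ens$truth$Kpart[i],
                 tolerance = 1e-3)
  }
})

test_that("global fit validates its inputs", {
  ens <- noiseless_ensemble(n = 3)
  no_wt <- ens$datasets[-1]
  expect_error(global_fit(no_wt, "shared_all_m"), "wild-type")
  expect_error(global_fit(ens$datasets[1], "shared_all_m"), "at least 2")
  short <- c(ens$datasets[1],
             list(chevron_dataset("mut99", 0:5, c(300, 90, 30, 10, 6, 9))))
  expect_error(global_fit(short, "shared_all_m"), "fewer than 7")
})

test_that("relaxing m-value constraints never increases the joint SSR", {
  spec <- ensemble_spec(n_variants = 6, noise_sd_log = 0.02, seed = 3)
  ens <- simulate_ensemble(spec)
  ssr <- vapply(c("shared_all_m", "free_mf", "free_mf_mu"), function(sch)
    suppressWarnings(global_fit(ens$datasets, sch,
                                control = fast_ctrl())$objective),
    numeric(1))
  expect_lte(ssr[["free_mf_mu"]], ssr[["free_mf"]] + 1e-10)
  expect_lte(ssr[["free_mf"]], ssr[["shared_all_m"]] + 1e-10)
})

test_that("result does not depend on dataset ordering", {
  spec <- ensemble_spec(n_variants = 4, noise_sd_log = 0.02, seed = 9)
  ens <- simulate_ensemble(spec)
  f1 <- global_fit(ens$datasets, "shared_all_m", control = fast_ctrl())
  f2 <- global_fit(rev(ens$datasets), "shared_all_m", control = fast_ctrl())
  expect_equal(f1$shared, f2$shared, tolerance = 1e-10)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-10)
  for (v in names(f1$per_variant))
    expect_equal(f1$per_variant[[v]]$kf0, f2$per_variant[[v]]$kf0,
                 tolerance = 1e-8)
  expect_equal(names(f2$per_variant), rev(names(f1$per_variant)))
})

test_that("betas are identical under shared m-values, varying when freed", {
  ens <- noiseless_ensemble(n = 4)
  fit <- global_fit(ens$datasets, "shared_all_m", control = fast_ctrl())
  expect_warning(b <- betas_per_variant(fit), "identical")
  b1 <- vapply(b, function(x) x$beta_ts1, numeric(1))
  expect_equal(max(b1) - min(b1), 0, tolerance = 1e-12)

  spec <- ensemble_spec(n_variants = 6, hammond_dbeta_ddG = -0.04,
                        noise_sd_log = 0.01, seed = 13)
  ens2 <- simulate_ensemble(spec)
  fit2 <- suppressWarnings(global_fit(ens2$datasets, "free_mf_mu",
                                      control = fast_ctrl()))
  b2 <- suppressWarnings(betas_per_variant(fit2))
  b2v <- vapply(b2, function(x) x$beta_ts1, numeric(1))
  expect_gt(max(b2v) - min(b2v), 0.02)
})

test_that("90% standard-error intervals cover the truth at a sane rate", {
  wt <- wt_params()
  u <- seq(0, 9, length.out = 25)
  z <- qnorm(0.95)
  hits <- vapply(1:25, function(s) {
    d <- simulate_chevron(wt, u, noise_sd_log = 0.02, seed = 400 + s)
    f <- fit_single_chevron(d, control = fast_ctrl())
    abs(f$params$kf0 - wt$kf0) <= z * f$se[["kf0"]]
  }, logical(1))
  expect_gte(mean(hits), 0.90 - 0.15)
  expect_lte(mean(hits), 1.00)
})
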