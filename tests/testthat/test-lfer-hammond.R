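fake_thermo <- function(x, y_ts1 = NULL, y_ts2 = NULL) {
  n <- length(x)
  data.frame(variant = sprintf("m%02d", seq_len(n)),
             ddG_eq = x,
             ddG_D_TS1 = if (is.null(y_ts1)) 0.5 * x else y_ts1,
             ddG_TS2_N = if (is.null(y_ts2)) 0.5 * x else x - y_ts2,
             excluded = FALSE)
}

test_that("LFER slope recovers exact linear constructions", {
  th <- fake_thermo(x = c(0.5, 1, 1.5, 2, 3))
  f <- lfer_fit(th, "ts1")
  expect_equal(f$alpha, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$n_variants, 5)
  expect_setequal(f$included_ids, th$variant)

  ident <- fake_thermo(x = 1:5, y_ts1 = 1:5, y_ts2 = 1:5)
  expect_equal(lfer_fit(ident, "ts1")$alpha, 1, tolerance = 1e-12)
  expect_equal(lfer_fit(ident, "ts2")$alpha, 1, tolerance = 1e-12)
})

test_that("LFER drops excluded variants and enforces the minimum count", {
  th <- fake_thermo(x = c(0.5, 1, 1.5, 2))
  th$excluded[1:2] <- TRUE
  expect_error(lfer_fit(th, "ts1"), "at least 3")
  th2 <- fake_thermo(x = 1:5)
  f <- lfer_fit(th2, "ts1", drop_ids = "m01")
  expect_equal(f$n_variants, 4)
  expect_false("m01" %in% f$included_ids)
})

test_that("LFER slope lands within 2 SE of the construction in >= 90% of replicates", {
  hits <- vapply(1:200, function(s) {
    d <- withr::with_seed(s, list(x = runif(15, 0.4, 3),
                                  e = rnorm(15, sd = 0.15)))
    th <- fake_thermo(d$x, y_ts1 = 0.6 * d$x + d$e)
    f <- lfer_fit(th, "ts1")
    abs(f$alpha - 0.6) <= 2 * f$se_alpha
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("Hammond regression reports slope and sign faithfully", {
  mk_beta <- function(b1) structure(list(beta_ts1 = b1, beta_ts2 = b1 + 0.3,
                                         out_of_range = FALSE),
                                    class = "tanford_betas")
  ids <- sprintf("m%d", 1:6)
  stab <- setNames(seq(3, 5.5, 0.5), ids)

  const <- setNames(lapply(rep(0.6, 6), mk_beta), ids)
  expect_equal(hammond_fit(const, stab, "ts1")$slope, 0, tolerance = 1e-12)

  tilted <- setNames(lapply(0.8 - 0.05 * (stab - 3), mk_beta), ids)
  h <- hammond_fit(tilted, stab, "ts1")
  expect_equal(h$slope, -0.05, tolerance = 1e-12)
  expect_lt(h$slope, 0)
  h2 <- hammond_fit(tilted, stab, "ts2")
  expect_equal(h2$slope, -0.05, tolerance = 1e-12)

  expect_error(hammond_fit(tilted[1:2], stab[1:2], "ts1"), "at least 3")
})

test_that("Hammond-built synthetic ensembles return the construction slope", {
  spec <- ensemble_spec(n_variants = 10, hammond_dbeta_ddG = -0.03,
                        noise_sd_log = 0.01, seed = 7)
  ens <- simulate_ensemble(spec)
  truth_b1 <- ens$truth$mf / (ens$truth$mf + ens$truth$mu)
  betas <- setNames(lapply(seq_len(nrow(ens$truth)), function(i)
    suppressWarnings(
      beta_tanford(kinetic_params(ens$truth$kf0[i], ens$truth$mf[i],
                                  ens$truth$ku0[i], ens$truth$mu[i],
                                  ens$truth$Kpart[i], ens$truth$mpart[i])))),
    ens$truth$variant)
  stab <- setNames(ens$truth$dG_DN, ens$truth$variant)
  h <- hammond_fit(betas, stab, "ts1")
  expect_equal(h$slope, -0.03, tolerance = 1e-6)
  expect_equal(truth_b1, vapply(betas, function(b) b$beta_ts1, numeric(1)),
               ignore_attr = TRUE)
})

test_that("Phi-vs-Phi summarises identity, offset, and noise correctly", {
  mapping <- data.frame(pos_a = 1:10, pos_b = 101:110)
  phi <- setNames(seq(0.05, 0.95, 0.1), 1:10)
  phi_b <- setNames(unname(phi), 101:110)

  same <- phi_vs_phi(mapping, phi, phi_b, "early")
  expect_equal(same$rmsd_identity, 0)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$n, 10)

  off <- phi_vs_phi(mapping, phi, phi_b + 0.2, "early")
  expect_equal(off$mean_offset, 0.2, tolerance = 1e-12)
  expect_equal(off$rmsd_identity, 0.2, tolerance = 1e-12)
  expect_equal(off$pearson_r, 1)

  d <- withr::with_seed(31, list(a = runif(20), b = runif(20)))
  m20 <- data.frame(pos_a = 1:20, pos_b = 1:20)
  rnd <- phi_vs_phi(m20, setNames(d$a, 1:20), setNames(d$b, 1:20), "late")
  expect_equal(rnd$pearson_r, cor(d$a, d$b), tolerance = 1e-12)
  expect_lt(abs(rnd$pearson_r), 0.5)
})

test_that("Phi-vs-Phi drops unusable pairs and is symmetric up to offset sign", {
  mapping <- data.frame(pos_a = 1:5, pos_b = 1:5)
  a <- setNames(c(0.1, 0.5, NA, 0.8, 0.3), 1:5)
  b <- setNames(c(0.2, 0.4, 0.6, NA, 0.5), 1:5)
  expect_message(res <- phi_vs_phi(mapping, a, b, "early"), "dropped")
  expect_equal(res$n, 3)
  expect_equal(res$n_dropped, 2)

  swapped <- suppressMessages(phi_vs_phi(mapping, b, a, "early"))
  expect_equal(swapped$mean_offset, -res$mean_offset, tolerance = 1e-12)
  expect_equal(swapped$rmsd_identity, res$rmsd_identity, tolerance = 1e-12)
  expect_equal(swapped$pearson_r, res$pearson_r, tolerance = 1e-12)

  none <- setNames(rep(NA_real_, 5), 1:5)
  expect_error(phi_vs_phi(mapping, none, b, "early"), "input error")
})
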