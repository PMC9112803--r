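RT <- 0.5925

test_that("mutational ddG terms reproduce the published L117A row", {
  wt <- kinetic_params(300, 0.81, 0.06, 0.52, 0.017, 0.45, RT = RT)
  mut <- kinetic_params(90, 0.81, 0.96, 0.52, 0.037, 0.45, RT = RT)
  tm <- ddg_terms(wt, mut)
  # published: ddG_TS1 = 1.65 +/- 0.15, ddG_TS2 = 1.20 +/- 0.20
  expect_equal(tm$ddG_TS1_N, RT * log(0.96 / 0.06), tolerance = 1e-12)
  expect_lt(abs(tm$ddG_TS1_N - 1.65), 0.15)
  expect_lt(abs(tm$ddG_TS2_N - 1.20), 0.20)
  expect_equal(tm$ddG_D_TS1 + tm$ddG_TS1_N, tm$ddG_eq, tolerance = 1e-12)
})

test_that("identical variants give zero ddG everywhere", {
  wt <- wt_params()
  tm <- ddg_terms(wt, wt)
  expect_equal(unlist(tm), c(ddG_D_TS1 = 0, ddG_TS1_N = 0, ddG_TS2_N = 0,
                             ddG_eq = 0))
})

test_that("swapping wild type and mutant negates every term", {
  wt <- wt_params()
  mut <- make_mutant(wt, 1.7, 0.4, 0.8)
  a <- ddg_terms(wt, mut)
  b <- ddg_terms(mut, wt)
  for (nm in c("ddG_D_TS1", "ddG_TS1_N", "ddG_TS2_N", "ddG_eq"))
    expect_equal(a[[nm]], -b[[nm]], tolerance = 1e-12)
})

test_that("Kpart = 0 leaves the late-barrier term undefined", {
  wt <- wt_params()
  mut2 <- kinetic_params(90, 0.81, 0.96, 0.52, Kpart = 0, RT = wt$RT)
  expect_warning(tm <- ddg_terms(wt, mut2), "undefined")
  expect_true(is.na(tm$ddG_TS2_N))
})

test_that("Phi-values reproduce published spot rows within printed errors", {
  tab <- load_table1()
  wt <- table1_params(tab, "wt", RT = RT)
  row_phi <- function(v) {
    tm <- ddg_terms(wt, table1_params(tab, v, RT = RT))
    phi_values(tm, ddG_eq = tab$ddG_eq[tab$variant == v])
  }
  p <- row_phi("L117A")
  expect_lt(abs(p$phi_ts1 - 0.31), 0.13)
  expect_lt(abs(p$phi_ts2 - 0.50), 0.12)
  expect_lt(abs(row_phi("V148A")$phi_ts2 - 1.21), 0.04)
  expect_lt(abs(row_phi("L136A")$phi_ts2 - 0.60), 0.08)
  expect_lt(abs(row_phi("L149A")$phi_ts1 - 1.00), 0.10)
  expect_lt(abs(row_phi("V194A")$phi_ts2 - 0.77), 0.04)
  expect_true(row_phi("T127S")$excluded)
})

test_that("small stability changes are excluded symmetrically", {
  tm <- list(ddG_D_TS1 = 0.1, ddG_TS2_N = 0.05, ddG_eq = 0.39)
  expect_true(phi_values(tm)$excluded)
  tm$ddG_eq <- -0.39
  expect_true(phi_values(tm)$excluded)
  tm$ddG_eq <- -0.41
  p <- phi_values(tm)
  expect_false(p$excluded)
  expect_lt(p$phi_ts1, 0)      # stabilising mutants keep their negative Phi
  tm$ddG_eq <- 0
  expect_error(phi_values(tm, exclusion_threshold = 0), "division")
})

test_that("the two Phi_TS1 routes agree when terms share one parameter set", {
  wt <- wt_params()
  for (seed in 1:20) {
    d <- withr::with_seed(seed, runif(3))
    mut <- make_mutant(wt, -1.3 + 4.6 * d[1], d[2], d[3])
    tm <- ddg_terms(wt, mut)
    if (abs(tm$ddG_eq) < 0.4) next
    p <- phi_values(tm)
    expect_equal(p$phi_ts1, 1 - tm$ddG_TS1_N / tm$ddG_eq, tolerance = 1e-12)
  }
})

test_that("Phi categories use the standard boundaries", {
  expect_equal(classify_phi(c(0, 0.29, 0.3, 0.5, 0.69, 0.7, 1)),
               c("low", "low", "intermediate", "intermediate", "intermediate",
                 "high", "high"))
  expect_equal(classify_phi(c(-0.01, 1.21)),
               c("non_canonical", "non_canonical"))
  expect_equal(classify_phi(NA_real_), "excluded")
})

test_that("phi_table summarises a global fit against its wild type", {
  ens <- noiseless_ensemble(n = 5)
  fit <- global_fit(ens$datasets, "shared_all_m", control = fast_ctrl())
  pt <- phi_table(fit)
  expect_equal(nrow(pt), 5)
  truth <- ens$truth[ens$truth$variant != "wt", ]
  idx <- match(pt$variant, truth$variant)
  expect_equal(pt$ddG_eq, truth$ddG_eq[idx], tolerance = 1e-3)
  keep <- !pt$excluded
  expect_equal(pt$phi_ts1[keep], truth$phi_ts1[idx][keep], tolerance = 1e-3)
  expect_true(all(is.na(pt$phi_ts1[!keep])))
  expect_true(all(pt$category_ts1[!keep] == "excluded"))

  only_wt <- global_fit(ens$datasets[c(1, 2)], "shared_all_m",
                        control = fast_ctrl())
  only_wt$per_variant <- only_wt$per_variant[1]
  only_wt$standard_errors <- only_wt$standard_errors[1, ]
  expect_equal(nrow(phi_table(only_wt)), 0)

  bad <- fit
  names(bad$per_variant)[1] <- "not_wt"
  expect_error(phi_table(bad), "state error")
})
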