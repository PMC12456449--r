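cfg_fast <- function(seed, m = 400L, s = 0.002)
  grid_config(s = s, m = m, seed = seed)

test_that("grid configuration validates its invariants", {
  expect_error(grid_config(s = 0.7), "s < 0.5")
  expect_error(grid_config(alpha = 1.2), "alpha < 1")
  expect_error(grid_config(m = 0), "m >= 1")
  cfg <- grid_config(seed = 5L)
  expect_identical(cfg$seed, 5L)
})

test_that("Monte-Carlo p-values are lattice-valued, deterministic, and one at the point estimate", {
  d <- make_balanced_meta(10, 8, 0.45, 0.02, seed = 12)
  est <- mom_estimates(d)
  cfg <- cfg_fast(101)
  # T(point) = 0 is never exceeded in absolute terms by a non-negative draw
  pv <- mc_pvalue(est$mu_hat, 0.01, d, cfg)
  expect_equal(pv$t_obs, 0)
  expect_equal(pv$p, 1)
  expect_equal(profile_pvalue(est$mu_hat, d, cfg)$p, 1)

  pv1 <- profile_pvalue(0.5, d, cfg)
  pv2 <- profile_pvalue(0.5, d, cfg)
  expect_identical(pv1$p, pv2$p)  # fixed seed, identical substream
  expect_lt(abs(pv1$p * pv1$m - round(pv1$p * pv1$m)), 1e-9)  # 1/m lattice
  expect_gte(pv1$p, 0)
  expect_lte(pv1$p, 1)

  expect_error(mc_pvalue(0.5, 0.2, d, cfg), "constraint violation")
})

test_that("upper-tail probability grows with the nuisance variance", {
  # empirical stochastic dominance: at fixed mu, the p-value evaluated at
  # a larger v is at least the p-value at a smaller v, within MC error
  d <- make_balanced_meta(12, 10, 0.42, 0.02, seed = 40)
  cfg <- grid_config(s = 0.002, m = 3000, seed = 17)
  mu <- 0.5
  vs <- v_sup(mu) * c(0.1, 0.5, 1)
  ps <- vapply(vs, function(v) mc_pvalue(mu, v, d, cfg)$p, numeric(1))
  expect_gte(ps[2], ps[1] - 0.05)
  expect_gte(ps[3], ps[2] - 0.05)
})

test_that("exact CI on symmetric data is centred and respects its invariants", {
  d <- meta_data(tibble::tibble(y1 = c(2L, 3L, 1L, 4L, 2L),
                                n1 = 150L,
                                y2 = c(2L, 3L, 1L, 4L, 2L),
                                n2 = 150L))
  ci <- exact_ci(d, cfg_fast(7))
  expect_equal(ci$point, 0.5)  # arm-exchange symmetry of the estimator
  expect_lte(ci$lower, 0.5)
  expect_gte(ci$upper, 0.5)
  expect_gte(ci$p_at_null, ci$alpha)
  # endpoints sit on the s-grid
  expect_equal(ci$lower / ci$settings$s, round(ci$lower / ci$settings$s))
  expect_equal(ci$upper / ci$settings$s, round(ci$upper / ci$settings$s))
  expect_true(ci$lower <= ci$point && ci$point <= ci$upper)
})

test_that("confidence intervals nest across levels and reproduce bit-for-bit", {
  d <- make_balanced_meta(10, 12, 0.4, 0.02, seed = 33)
  cfg95 <- cfg_fast(55)
  ci95 <- exact_ci(d, cfg95)
  ci95b <- exact_ci(d, cfg95)
  expect_identical(tidy(ci95), tidy(ci95b))  # seed reproducibility

  cfg90 <- grid_config(s = 0.002, m = 400, alpha = 0.10, seed = 55)
  ci90 <- exact_ci(d, cfg90)
  expect_gte(ci90$lower, ci95$lower)
  expect_lte(ci90$upper, ci95$upper)
})

test_that("the interval is invariant to the order studies are listed", {
  set.seed(61)
  d <- meta_data(tibble::tibble(y1 = c(2, 0, 5, 1, 3, 1), n1 = c(80, 100, 220, 45, 160, 75),
                                y2 = c(1, 2, 3, 0, 4, 2), n2 = c(50, 90, 200, 45, 80, 75)))
  perm <- d[c(4, 1, 6, 2, 5, 3), ]
  ci1 <- exact_ci(d, cfg_fast(21))
  ci2 <- exact_ci(meta_data(perm), cfg_fast(21))
  expect_identical(tidy(ci1), tidy(ci2))
})

test_that("swapping treated and control arms mirrors the analysis around 0.5", {
  d <- make_balanced_meta(10, 9, 0.38, 0.02, seed = 83)
  swapped <- meta_data(tibble::tibble(y1 = d$y2, n1 = d$n2,
                                      y2 = d$y1, n2 = d$n1))
  a <- mom_estimates(d)
  b <- mom_estimates(swapped)
  expect_equal(b$mu_hat, 1 - a$mu_hat, tolerance = 1e-12)
  expect_equal(b$v_hat, a$v_hat, tolerance = 1e-12)
  expect_equal(b$var_mu_hat, a$var_mu_hat, tolerance = 1e-12)
  # the exact test statistic mirrors too, so p-values agree in
  # distribution; with finite m they agree within Monte-Carlo error
  cfg <- grid_config(m = 2000, seed = 19)
  p1 <- profile_pvalue(0.45, d, cfg)$p
  p2 <- profile_pvalue(0.55, swapped, cfg)$p
  expect_lt(abs(p1 - p2), 0.1)
})

test_that("a clear effect excludes the null consistently with its p-value", {
  fm <- read_meta_csv(rex_example("facemask_synthetic"))
  ci <- exact_ci(fm, cfg_fast(3, m = 500))
  expect_lt(ci$p_at_null, 0.05)
  expect_lt(ci$upper, 0.5)  # CI and test agree
  expect_lt(ci$point, 0.5)
  gl <- glance(ci)
  expect_gt(gl$n_grid, 0)
  td <- tidy(ci)
  expect_named(td, c("estimate", "conf.low", "conf.high", "p.value",
                     "null.value", "conf.level"))
})

test_that("CI results serialize to reproducible JSON and plot cleanly", {
  d <- make_balanced_meta(8, 10, 0.45, 0.02, seed = 10)
  ci <- exact_ci(d, cfg_fast(42))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_ci_json(ci, f1)
  write_ci_json(exact_ci(d, cfg_fast(42)), f2)
  expect_identical(readLines(f1), readLines(f2))
  rec <- jsonlite::fromJSON(f1)
  expect_equal(rec$lower, ci$lower)
  expect_equal(rec$seed, 42)
  p <- autoplot(ci)
  expect_s3_class(p, "ggplot")
})
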