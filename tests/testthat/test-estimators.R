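test_that("resampling support matches the worked unbalanced example", {
  sp <- resample_support(2, 80, 1, 50)
  expect_equal(sp$y1_star, 0:2)
  expect_equal(sp$ydot_star, 1:3)
  # hypergeometric weights, cross-checked against the binomial-coefficient
  # ratio oracle and against their published rounding
  expect_equal(sp$weight, hyper_weight_oracle(0:2, 2, 80, 50),
               tolerance = 1e-10)
  expect_equal(round(sp$weight, 4), c(0.1377, 0.4747, 0.3877))
  expect_equal(sum(sp$weight), 1, tolerance = 1e-12)
})

test_that("double-zero correction drops the outcome that empties the study", {
  # zero control events: l = 0 would be double-zero, so support is {1}
  sp <- resample_support(1, 100, 0, 90)
  expect_equal(sp$y1_star, 1)
  expect_equal(sp$weight, 1)
  # mirrored case: control arm larger and treated arm empty
  sp2 <- resample_support(0, 90, 1, 100)
  expect_equal(sp2$y1_star, 0)
  expect_equal(sp2$ydot_star, 1)
  expect_equal(sp2$weight, 1)
  # balanced study: singleton at the observed count
  sp3 <- resample_support(3, 50, 1, 50)
  expect_equal(sp3$y1_star, 3)
  expect_equal(sp3$ydot_star, 4)
  expect_equal(sp3$weight, 1)
})

test_that("weights are a probability law on the admissible support", {
  set.seed(31)
  for (rep in 1:60) {
    st <- random_study()
    sp <- resample_support(st$y1, st$n1, st$y2, st$n2)
    expect_true(all(sp$weight >= 0))
    expect_equal(sum(sp$weight), 1, tolerance = 1e-12)
    expect_true(all(sp$ydot_star >= 1))  # never a double-zero outcome
    y_lg <- if (st$n1 >= st$n2) st$y1 else st$y2
    n_lg <- max(st$n1, st$n2)
    n_sm <- min(st$n1, st$n2)
    l <- if (st$n1 >= st$n2) sp$y1_star else sp$ydot_star - st$y1
    expect_true(all(l >= max(0, n_sm - n_lg + y_lg) & l <= y_lg))
  }
})

test_that("balanced moment estimates follow the closed forms", {
  # six studies of (0, 20): protective toy data
  toy <- meta_data(tibble::tibble(y1 = 0L, n1 = 100L, y2 = 20L, n2 = 100L)[rep(1, 6), ])
  # mu_hat = 0 with v_hat = 0 is the advertised boundary degeneracy
  expect_warning(est <- mom_balanced(toy), "degenerate point estimate")
  expect_equal(est$mu_hat, 0)
  # corrected moments go negative, so the truncation floors v at 0
  mu_int <- 0.5 / 21
  num <- 6 * (mu_int^2 - mu_int / 21)
  expect_lt(num / (6 * (1 - 1 / 21)) - mu_int^2, 0)
  expect_equal(est$v_hat, 0)
  expect_gt(est$var_mu_hat, 0)

  # constant ratios: mu_hat reproduces the common ratio
  cons <- meta_data(tibble::tibble(y1 = 3L, n1 = 60L, y2 = 9L, n2 = 60L)[rep(1, 5), ])
  expect_equal(mom_balanced(cons)$mu_hat, 0.25)

  # design guard
  unb <- meta_data(tibble::tibble(y1 = c(1, 2), n1 = c(50, 80),
                                  y2 = c(1, 1), n2 = c(50, 40)))
  expect_error(mom_balanced(unb), "design error")
  expect_error(mom_balanced(toy[1, ]), "at least two")
})

test_that("balanced and weighted estimators agree exactly on balanced data", {
  for (seed in 1:5) {
    d <- make_balanced_meta(10, sample(3:30, 1), 0.45, 0.02, seed = seed)
    a <- mom_balanced(d)
    b <- mom_weighted(d)
    expect_equal(a$mu_hat, b$mu_hat, tolerance = 1e-12)
    expect_equal(a$v_hat, b$v_hat, tolerance = 1e-12)
    expect_equal(a$var_mu_hat, b$var_mu_hat, tolerance = 1e-12)
    expect_identical(mom_estimates(d)$design, "balanced")
  }
})

test_that("weighted estimator reproduces the hand-expanded two-study value", {
  d <- meta_data(tibble::tibble(y1 = c(2, 1), n1 = c(80, 100),
                                y2 = c(1, 0), n2 = c(50, 90)))
  est <- mom_weighted(d)
  w <- hyper_weight_oracle(0:2, 2, 80, 50)
  # study 1 contributes sum_l l/(l+1) * p_l; study 2 is {1} after the DZ
  # correction and contributes 1/1
  expect_equal(est$mu_hat, 0.5 * (sum((0:2) / (1:3) * w) + 1),
               tolerance = 1e-12)
  expect_identical(est$design, "weighted")
})

test_that("moment estimators are consistent on simulated balanced data", {
  d <- make_balanced_meta(5000, 20, 0.5, 0.02, seed = 77)
  est <- mom_balanced(d)
  se <- sqrt(est$var_mu_hat)
  expect_lt(abs(est$mu_hat - 0.5), 4 * se)
  expect_equal(est$v_hat, 0.02, tolerance = 0.15)
  # v_hat truncation: never negative over sparse datasets
  set.seed(13)
  for (rep in 1:20) {
    d2 <- make_balanced_meta(6, 1, 0.5, 0.01)
    if (nrow(d2) < 2) next
    expect_gte(mom_balanced(d2)$v_hat, 0)
  }
})

test_that("Wald statistic is a symmetric quadratic in the null value", {
  d <- make_balanced_meta(10, 10, 0.4, 0.02, seed = 3)
  est <- mom_estimates(d)
  expect_equal(wald_statistic(est$mu_hat, est), 0)
  expect_equal(wald_statistic(est$mu_hat + 0.07, est),
               wald_statistic(est$mu_hat - 0.07, est))
  fake <- structure(list(mu_hat = 0.6, v_hat = 0, var_mu_hat = 0.01,
                         design = "balanced", k = 10), class = "rex_mom")
  expect_equal(wald_statistic(0.5, fake), 1)
  fake$var_mu_hat <- 0
  expect_error(wald_statistic(0.5, fake), "degenerate variance")
})

test_that("tidy and glance expose the estimates as tibbles", {
  d <- make_balanced_meta(8, 12, 0.4, 0.02, seed = 9)
  est <- mom_estimates(d)
  td <- tidy(est)
  expect_equal(td$term, c("mu", "v"))
  expect_equal(td$estimate[1], est$mu_hat)
  gl <- glance(est)
  expect_equal(gl$k, 8L)
})
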