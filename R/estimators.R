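#' Hypergeometric resampling support for one study
#'
#' An unbalanced study is reduced to a weighted mixture of balanced ones by
#' "resampling" the larger arm down to the smaller arm's size without
#' replacement. The possible numbers of events retained from the larger arm
#' follow a hypergeometric law:
#' \deqn{p_l = \binom{Y_{lg}}{l}\binom{N_{lg}-Y_{lg}}{N_{sm}-l} \Big/
#'   \binom{N_{lg}}{N_{sm}},}
#' for `l` from `max(0, N_sm - N_lg + Y_lg)` to `Y_lg`. If the arm that is
#' *not* resampled has zero events, the outcome `l = 0` would create a
#' double-zero study; since the method removes those, that outcome is
#' dropped and the weights renormalized. A balanced study has the singleton
#' support `{y1}` with weight 1.
#'
#' The contrast ratio attached to each outcome is always (treated events) /
#' (total events) of the resampled study: when the treated arm is larger
#' the support enumerates treated events retained; when the control arm is
#' larger it enumerates control events retained while the treated count
#' stays fixed.
#'
#' @param y1,n1 Treated-arm events and size.
#' @param y2,n2 Control-arm events and size.
#' @return A tibble with columns `y1_star` (treated events), `ydot_star`
#'   (total events) and `weight` (summing to 1).
#' @examples
#' resample_support(2, 80, 1, 50)
#' resample_support(1, 100, 0, 90)  # DZ correction: singleton {1}
#' @export
resample_support <- function(y1, n1, y2, n2) {
  stopifnot(y1 >= 0, y2 >= 0, n1 >= 1, n2 >= 1, y1 <= n1, y2 <= n2)
  if (y1 + y2 < 1L) abort("double-zero study has no resampling support.")
  as_tibble(resample_support_counts(y1, n1, y2, n2))
}

# list(y1_star, ydot_star, weight) without tibble overhead (hot path)
resample_support_counts <- function(y1, n1, y2, n2) {
  if (n1 == n2) {
    return(list(y1_star = y1, ydot_star = y1 + y2, weight = 1))
  }
  if (n1 > n2) {
    l <- max(0L, n2 - n1 + y1):y1
    w <- dhyper(l, y1, n1 - y1, n2)
    if (y2 == 0L) {
      keep <- l >= 1L
      l <- l[keep]
      w <- w[keep]
    }
    y1s <- l
    yds <- l + y2
  } else {
    l <- max(0L, n1 - n2 + y2):y2
    w <- dhyper(l, y2, n2 - y2, n1)
    if (y1 == 0L) {
      keep <- l >= 1L
      l <- l[keep]
      w <- w[keep]
    }
    y1s <- rep(y1, length(l))
    yds <- y1 + l
  }
  list(y1_star = y1s, ydot_star = yds, weight = w / sum(w))
}

# Weighted per-study moment contributions. With continuity-corrected
# counts Ỹ1 = y1* + 0.5 and Ỹ. = ydot* + 1:
#   A  = sum w * y1*/ydot*          (raw first-moment term)
#   B  = sum w * Ỹ1/Ỹ.              (corrected first-moment term)
#   S1 = sum w * (Ỹ1/Ỹ.)^2
#   S2 = sum w / Ỹ.
#   S3 = sum w * (1 - 1/Ỹ.)
# Every estimator below is linear in these five numbers.
support_terms <- function(y1, n1, y2, n2) {
  sp <- resample_support_counts(y1, n1, y2, n2)
  yt <- sp$ydot_star + 1
  b <- (sp$y1_star + 0.5) / yt
  w <- sp$weight
  c(A = sum(w * sp$y1_star / sp$ydot_star),
    B = sum(w * b),
    S1 = sum(w * b * b),
    S2 = sum(w / yt),
    S3 = sum(w * (1 - 1 / yt)))
}

# Term table over all possible treated counts y1 = 0..ydot for fixed margins;
# row r corresponds to y1 = r - 1. Lets the Monte-Carlo step score thousands
# of simulated datasets by indexing instead of re-enumerating supports.
study_term_table <- function(n1, n2, ydot) {
  out <- matrix(0, nrow = ydot + 1L, ncol = 5L,
                dimnames = list(NULL, c("A", "B", "S1", "S2", "S3")))
  for (y1 in 0:ydot) {
    out[y1 + 1L, ] <- support_terms(y1, n1, n2 = n2, y2 = ydot - y1)
  }
  out
}

# Point estimate, truncated variance component, and variance of the point
# estimate from summed per-study terms. Vectorized over replicates.
mom_from_termsums <- function(sA, sB, sS1, sS2, sS3, k) {
  mu <- sA / k
  mu_int <- sB / k
  v <- pmax(0, (sS1 - mu_int * sS2) / sS3 - mu_int^2)
  # mu(1-mu) floored at machine epsilon so a degenerate point estimate at
  # 0 or 1 with v = 0 still yields a usable statistic; the same floor is
  # applied to observed and simulated data, so exactness is unaffected
  var <- (pmax(mu * (1 - mu), .Machine$double.eps) * sS2 + sS3 * v) / k^2
  list(mu_hat = mu, v_hat = v, var_mu_hat = var)
}

new_rex_mom <- function(fit, design, k) {
  structure(
    list(mu_hat = fit$mu_hat, v_hat = fit$v_hat,
         var_mu_hat = fit$var_mu_hat, design = design, k = k),
    class = "rex_mom")
}

#' Method-of-moments estimates of the contrast mean and variance
#'
#' `mom_estimates()` dispatches on the design: the closed-form estimator
#' when every study is balanced (`n1 == n2`), and the hypergeometric
#' resampling-weighted estimator otherwise. The two agree exactly on
#' balanced data, where the resampling support is a singleton.
#'
#' For balanced data the point estimate is the raw mean ratio
#' \eqn{\hat\mu = K^{-1}\sum_i Y_{i1}/Y_{i\cdot}} (no continuity
#' correction), while the between-study variance uses corrected counts
#' \eqn{\tilde Y_{i1} = Y_{i1} + 0.5}, \eqn{\tilde Y_{i\cdot} = Y_{i\cdot} +
#' 1} so that every study contributes even when \eqn{Y_{i\cdot} = 1} and the
#' within-study variance term never degenerates:
#' \deqn{\hat v = \max\Big(0, \frac{\sum_i\{(\tilde Y_{i1}/\tilde
#'   Y_{i\cdot})^2 - \hat\mu_{int}/\tilde Y_{i\cdot}\}}{\sum_i (1 - 1/\tilde
#'   Y_{i\cdot})} - \hat\mu_{int}^2\Big).}
#' The variance of the point estimate is
#' \eqn{K^{-2}\sum_i\{\hat\mu(1-\hat\mu)/\tilde Y_{i\cdot} + (1 - 1/\tilde
#' Y_{i\cdot})\hat v\}}; corrected totals are used throughout the variance
#' so it stays positive for sparse data. The correction constants are the
#' conventional 0.5/1 and are not configurable; they affect efficiency
#' only, not validity, because the test calibrates the statistic's exact
#' distribution.
#'
#' Weighted versions replace each study's term by its expectation over the
#' resampling support ([resample_support()]). The double-zero correction
#' inside the weights biases the point estimator away from 0.5 in sparse
#' unbalanced data; this again affects CI length, not coverage.
#'
#' @param data A `rex_meta` dataset (or coercible data frame) with at least
#'   two retained studies.
#' @return An object of class `rex_mom`: a list with `mu_hat`, `v_hat`,
#'   `var_mu_hat`, `design` ("balanced" or "weighted") and `k`. Has
#'   [tidy()] and [glance()] methods.
#' @export
mom_estimates <- function(data) {
  data <- as_rex_meta(data)
  if (all(data$n1 == data$n2)) mom_balanced(data) else mom_weighted(data)
}

#' @rdname mom_estimates
#' @export
mom_balanced <- function(data) {
  data <- as_rex_meta(data)
  if (nrow(data) < 2L) abort("at least two retained studies are required.")
  if (any(data$n1 != data$n2)) {
    abort("design error: unbalanced study present; use mom_weighted().")
  }
  k <- nrow(data)
  ydot <- data$y1 + data$y2
  yt <- ydot + 1
  b <- (data$y1 + 0.5) / yt
  fit <- mom_from_termsums(sum(data$y1 / ydot), sum(b), sum(b * b),
                           sum(1 / yt), sum(1 - 1 / yt), k)
  warn_if_degenerate(fit)
  new_rex_mom(fit, "balanced", k)
}

#' @rdname mom_estimates
#' @export
mom_weighted <- function(data) {
  data <- as_rex_meta(data)
  if (nrow(data) < 2L) abort("at least two retained studies are required.")
  terms <- mapply(support_terms, data$y1, data$n1, data$y2, data$n2)
  fit <- mom_from_termsums(sum(terms["A", ]), sum(terms["B", ]),
                           sum(terms["S1", ]), sum(terms["S2", ]),
                           sum(terms["S3", ]), nrow(data))
  warn_if_degenerate(fit)
  new_rex_mom(fit, "weighted", nrow(data))
}

warn_if_degenerate <- function(fit) {
  if (fit$v_hat == 0 && (fit$mu_hat <= 0 || fit$mu_hat >= 1)) {
    warn(paste("degenerate point estimate at the boundary with zero",
               "between-study variance; variance floored at machine",
               "epsilon."))
  }
  invisible(fit)
}

#' Wald statistic for a hypothesized contrast mean
#'
#' \eqn{T(\mu) = (\hat\mu - \mu)^2 / \widehat{Var}(\hat\mu)}. The statistic
#' is cheap to recompute, which is what makes Monte-Carlo calibration of
#' its exact distribution practical; its validity does not depend on the
#' asymptotic chi-square approximation.
#'
#' @param mu_null Hypothesized mean contrast.
#' @param est A `rex_mom` object.
#' @return Non-negative scalar; 0 iff `mu_null` equals the point estimate.
#' @export
wald_statistic <- function(mu_null, est) {
  stopifnot(inherits(est, "rex_mom"))
  if (!is.finite(est$var_mu_hat) || est$var_mu_hat <= 0) {
    abort("degenerate variance: the Wald statistic is undefined.")
  }
  (est$mu_hat - mu_null)^2 / est$var_mu_hat
}

#' @export
print.rex_mom <- function(x, ...) {
  cat(sprintf(
    "<rex_mom> %s design, k = %d\n  mu_hat = %.4f  v_hat = %.5f  se(mu_hat) = %.4f\n",
    x$design, x$k, x$mu_hat, x$v_hat, sqrt(x$var_mu_hat)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rex_mom <- function(x, ...) {
  tibble(term = c("mu", "v"),
         estimate = c(x$mu_hat, x$v_hat),
         std.error = c(sqrt(x$var_mu_hat), NA_real_))
}

#' @exportS3Method generics::glance
glance.rex_mom <- function(x, ...) {
  tibble(mu_hat = x$mu_hat, v_hat = x$v_hat, var_mu_hat = x$var_mu_hat,
         design = x$design, k = x$k)
}
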