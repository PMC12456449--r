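#' Unimodality bound on the contrast variance
#'
#' The study-specific treatment contrast \eqn{\pi = \lambda_1 / (\lambda_1 +
#' \lambda_2)} is modelled as Beta with both shape parameters at least 1, so
#' the random-effects law is unimodal and its mean is an interpretable,
#' identifiable centre. In mean/variance coordinates the constraint is
#' \deqn{v \le v_{sup}(\mu) = \mu(1-\mu)\,\min\{\mu/(1+\mu),\,
#'   (1-\mu)/(2-\mu)\},}
#' which is symmetric about \eqn{\mu = 0.5} where it equals 1/12.
#'
#' @param mu Mean contrast, strictly inside (0, 1).
#' @return The largest admissible variance at `mu`.
#' @examples
#' v_sup(0.5)  # 1/12
#' @export
v_sup <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    abort("`mu` must lie strictly inside (0, 1).")
  }
  mu * (1 - mu) * pmin(mu / (1 + mu), (1 - mu) / (2 - mu))
}

#' Beta shape parameters from mean and variance
#'
#' Maps the contrast-scale parameters \eqn{(\mu, v)} to Beta shapes
#' \deqn{\alpha = \mu\{\mu(1-\mu) - v\}/v, \qquad
#'       \beta = (1-\mu)\{\mu(1-\mu) - v\}/v.}
#' Inside the unimodal region both shapes exceed 1; exactly on the boundary
#' `v = v_sup(mu)` the smaller shape equals 1 (the profile search evaluates
#' there, so the boundary is closed and shapes are clipped at 1 against
#' roundoff).
#'
#' @param mu Mean contrast in (0, 1).
#' @param v Variance, with `0 < v <= v_sup(mu)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @seealso [moments_from_shape()], [v_sup()]
#' @export
shape_from_moments <- function(mu, v) {
  if (!is.finite(mu) || mu <= 0 || mu >= 1) {
    abort("`mu` must lie strictly inside (0, 1).")
  }
  if (!is.finite(v) || v <= 0) abort("`v` must be strictly positive.")
  if (v >= mu * (1 - mu)) {
    abort("infeasible variance: `v` must be below mu * (1 - mu).")
  }
  vs <- v_sup(mu)
  if (v > vs * (1 + 1e-8)) {
    abort(sprintf(
      "constraint violation: v = %.6g exceeds v_sup(%.4g) = %.6g (unimodality).",
      v, mu, vs))
  }
  s <- (mu * (1 - mu) - v) / v
  out <- c(alpha = mu * s, beta = (1 - mu) * s)
  # clip roundoff just below the boundary value of 1
  out[out < 1 & out > 1 - 1e-9] <- 1
  out
}

#' Mean and variance of a Beta contrast law
#'
#' @param alpha,beta Positive Beta shape parameters.
#' @return Named numeric vector `c(mu, v)` with `mu = alpha/(alpha+beta)`
#'   and `v = mu(1-mu)/(alpha+beta+1)`.
#' @export
moments_from_shape <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    abort("Beta shape parameters must be strictly positive.")
  }
  mu <- alpha / (alpha + beta)
  c(mu = mu, v = mu * (1 - mu) / (alpha + beta + 1))
}

#' Limiting point mass at zero of an unconstrained Beta law
#'
#' When both shape parameters shrink towards zero the Beta(\eqn{\alpha},
#' \eqn{\beta}) law degenerates to a two-point mixture with mass
#' \eqn{\beta/(\alpha+\beta)} at 0 and \eqn{\alpha/(\alpha+\beta)} at 1.
#' This is the bimodal pathology that the unimodality constraint
#' (`v <= v_sup(mu)`) rules out: a nominal mean far from 0 can coexist with
#' most studies' contrasts sitting essentially at 0. Exposed for
#' illustrating that failure mode; not used by the inference path.
#'
#' @inheritParams moments_from_shape
#' @return The limiting probability mass at \eqn{\pi = 0}.
#' @export
beta_limit_mass0 <- function(alpha, beta) {
  if (alpha <= 0 || beta <= 0) abort("shape parameters must be positive.")
  beta / (alpha + beta)
}

#' Conditional success probability of the treated arm
#'
#' Under independent Poisson event counts with rates \eqn{n_1 \lambda e^\xi}
#' (treated) and \eqn{n_2 \lambda} (control), the treated count given the
#' study total is Binomial with success probability
#' \deqn{expit\{logit(\pi) + S\}, \quad S = \log(n_1/n_2),}
#' where \eqn{\pi = expit(\xi)} is the treatment contrast. Conditioning
#' eliminates the baseline rate \eqn{\lambda}; with a balanced design
#' (`s = 0`) the probability is the contrast itself.
#'
#' @param pi Treatment contrast in (0, 1).
#' @param s Design offset `log(n1/n2)`; must be finite.
#' @return Success probability in (0, 1).
#' @export
conditional_success_prob <- function(pi, s) {
  if (any(!is.finite(s))) abort("offset `s` must be finite.")
  if (any(pi <= 0) || any(pi >= 1)) {
    abort("`pi` must lie strictly inside (0, 1).")
  }
  plogis(qlogis(pi) + s)
}

# Draw k x m treated-arm counts under the conditional model, holding each
# study's total and offset fixed. Workhorse shared by the public sampler and
# the Monte-Carlo p-value. Assumes the RNG state is already set.
draw_y1_matrix <- function(mu, v, ydot, offset, m) {
  k <- length(ydot)
  if (v < 1e-10) {
    # point-mass limit of the Beta law; the Beta sampler is unstable with
    # enormous shapes
    p <- matrix(plogis(qlogis(mu) + offset), nrow = k, ncol = m)
  } else {
    shp <- shape_from_moments(mu, v)
    pi <- matrix(rbeta(k * m, shp[["alpha"]], shp[["beta"]]), nrow = k)
    p <- plogis(qlogis(pi) + offset)
  }
  matrix(rbinom(k * m, size = ydot, prob = p), nrow = k)
}

#' Simulate a dataset from the conditional model
#'
#' Generates one replicate of the observed data holding every study's total
#' event count, arm sizes, and offsets fixed at the template's values: for
#' study *i*, \eqn{\pi_i \sim} Beta(`mu`, `v`) (moment parameterization),
#' then \eqn{Y_{i1} \sim} Binomial\eqn{(y_{i\cdot},
#' expit\{logit(\pi_i) + S_i\})} and \eqn{Y_{i2} = y_{i\cdot} - Y_{i1}}.
#' Because the margins are copied, no double-zero study can arise. This is
#' the sampler the exact test uses to calibrate its Monte-Carlo p-values.
#'
#' @param mu,v Contrast mean and variance; `v` may be 0-like, in which case
#'   all contrasts equal `mu`.
#' @param template A `rex_meta` dataset supplying margins and offsets.
#' @param seed Optional integer seed.
#' @return A `rex_meta` dataset with the same margins as `template`.
#' @export
sample_conditional_dataset <- function(mu, v, template, seed = NULL) {
  template <- as_rex_meta(template)
  if (nrow(template) < 1L) abort("template must contain at least one study.")
  if (!is.null(seed)) set.seed(seed)
  ydot <- template$y1 + template$y2
  y1 <- drop(draw_y1_matrix(mu, v, ydot, template$offset, 1L))
  out <- template
  out$y1 <- as.integer(y1)
  out$y2 <- as.integer(ydot - y1)
  out
}
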