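# Fixture builders and independent oracles shared across test files.

# Balanced beta-binomial meta-dataset: k studies, common total ydot,
# contrasts drawn from Beta(mu, v) in moment coordinates.
make_balanced_meta <- function(k, ydot, mu, v, n = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shp <- shape_from_moments(mu, v)
  pi <- rbeta(k, shp[["alpha"]], shp[["beta"]])
  y1 <- rbinom(k, ydot, pi)
  # avoid an all-zero row becoming double-zero only when ydot == 0
  df <- tibble::tibble(y1 = y1, n1 = n, y2 = ydot - y1, n2 = n)
  meta_data(df[df$y1 + df$y2 > 0, ])
}

# Random single study, possibly unbalanced in either direction, non-DZ.
random_study <- function() {
  n1 <- sample(5:120, 1)
  n2 <- sample(5:120, 1)
  y1 <- sample(0:min(8, n1), 1)
  y2 <- sample(0:min(8, n2), 1)
  if (y1 + y2 == 0) y1 <- 1
  list(y1 = y1, n1 = n1, y2 = y2, n2 = n2)
}

# Hypergeometric pmf by the ratio-of-binomial-coefficients formula,
# independent of dhyper: probability of retaining l of y_lg events when
# drawing n_sm of n_lg subjects.
hyper_weight_oracle <- function(l, y_lg, n_lg, n_sm) {
  choose(y_lg, l) * choose(n_lg - y_lg, n_sm - l) / choose(n_lg, n_sm)
}

# Conditional law of the treated count given the study total, by direct
# enumeration of the joint law of two independent Poissons with rates
# n1 * lam * exp(xi) (treated) and n2 * lam (control).
cond_pmf_oracle <- function(total, xi, s, lam = 0.7, n2 = 1) {
  n1 <- n2 * exp(s)
  r1 <- n1 * lam * exp(xi)
  r2 <- n2 * lam
  y <- 0:total
  num <- dpois(y, r1) * dpois(total - y, r2)
  num / sum(num)
}
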