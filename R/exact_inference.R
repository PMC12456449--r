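#' Settings for the exact test and its inversion
#'
#' @param s Grid step on the contrast scale; the CI endpoints land on this
#'   grid. 0.001 resolves the magnitude of most effect sizes.
#' @param m Monte-Carlo replicates per evaluated \eqn{(\mu, v)} point. At
#'   least 2000 is recommended for production use: the standard error of an
#'   estimated p-value near 0.05 is about 0.005 at that size. Smaller
#'   values are fine for exploration and simulation studies.
#' @param alpha Test level / one minus the confidence level.
#' @param correction_span Number of extra grid points examined beyond each
#'   provisional CI limit, in units of `s`; guards against failures of the
#'   stochastic-dominance shortcut used for profiling.
#' @param seed Integer seed governing every Monte-Carlo draw. Each grid
#'   point derives its own substream deterministically from `(seed,
#'   mu-index, v-index)`, so p-value surfaces are reproducible and
#'   identical across repeated or reordered searches.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(s = 0.001, m = 2000L, alpha = 0.05,
                        correction_span = 10L, seed = NULL) {
  stopifnot(s > 0, s < 0.5, m >= 1, alpha > 0, alpha < 1,
            correction_span >= 0)
  structure(list(s = s, m = as.integer(m), alpha = alpha,
                 correction_span = as.integer(correction_span),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "grid_config")
}

# Deterministic substream seed for a (mu, v) grid point. Arguments stay far
# below 2^53 so the modular arithmetic is exact in doubles.
point_seed <- function(seed, mu, v, s) {
  imu <- round(mu / s)
  iv <- round(v * 1e7)
  as.integer((seed + 1000003 * imu + 7919 * iv) %% 2147483629 + 1)
}

#' Monte-Carlo p-value of the exact test at a parameter point
#'
#' Computes the observed Wald statistic \eqn{T(\mu)} from `data`, simulates
#' `cfg$m` datasets from the conditional model at \eqn{(\mu, v)} holding
#' the observed margins and offsets fixed, recomputes the *same* estimator
#' pipeline and statistic on each, and returns the tail proportion
#' \deqn{p = m^{-1} \sum_m I(T_m \ge T_{obs}),}
#' with ties counted as extreme. The p-value therefore lives on the `1/m`
#' lattice and the test that rejects when `p < alpha` is exact (conservative
#' up to Monte-Carlo error) at the generating parameter.
#'
#' @param mu,v Parameter point inside the constrained space
#'   (`v <= v_sup(mu)`).
#' @param data A `rex_meta` dataset.
#' @param cfg A [grid_config()]; if `cfg$seed` is `NULL` a seed is drawn and
#'   recorded.
#' @return A list of class `rex_pvalue` with `mu`, `v`, `t_obs`, `p`, `m`.
#' @export
mc_pvalue <- function(mu, v, data, cfg = grid_config()) {
  data <- canonical_sort(as_rex_meta(data))
  if (is.null(cfg$seed)) cfg$seed <- sample.int(2147483000L, 1L)
  tables <- lapply(seq_len(nrow(data)), function(i) {
    study_term_table(data$n1[i], data$n2[i], data$y1[i] + data$y2[i])
  })
  mc_pvalue_impl(mu, v, data, cfg, mom_estimates(data), tables)
}

mc_pvalue_impl <- function(mu, v, data, cfg, est, tables) {
  vs <- v_sup(mu)
  if (v > vs * (1 + 1e-8)) {
    abort("constraint violation: v exceeds v_sup(mu).")
  }
  t_obs <- wald_statistic(mu, est)
  k <- nrow(data)
  m <- cfg$m
  ydot <- data$y1 + data$y2
  set.seed(point_seed(cfg$seed, mu, v, cfg$s))
  y1 <- draw_y1_matrix(mu, min(v, vs), ydot, data$offset, m)
  sA <- sB <- sS1 <- sS2 <- sS3 <- numeric(m)
  for (i in seq_len(k)) {
    tab <- tables[[i]]
    idx <- y1[i, ] + 1L
    sA <- sA + tab[idx, 1L]
    sB <- sB + tab[idx, 2L]
    sS1 <- sS1 + tab[idx, 3L]
    sS2 <- sS2 + tab[idx, 4L]
    sS3 <- sS3 + tab[idx, 5L]
  }
  fit <- mom_from_termsums(sA, sB, sS1, sS2, sS3, k)
  t_sim <- (fit$mu_hat - mu)^2 / fit$var_mu_hat
  structure(list(mu = mu, v = v, t_obs = t_obs,
                 p = mean(t_sim >= t_obs), m = m),
            class = "rex_pvalue")
}

#' Profile p-value over the nuisance variance
#'
#' The exact test of \eqn{H_0: \mu_0 = \mu} must account for the unknown
#' between-study variance; the profile p-value is the supremum of
#' [mc_pvalue()] over admissible `v`. Empirically the statistic's upper
#' tail grows with `v` (first-order stochastic dominance), so the supremum
#' sits at the boundary and is approximated by a single evaluation at
#' `v = v_sup(mu)`. The CI search's correction step re-examines points past
#' the provisional limits precisely because this shortcut is an
#' approximation.
#'
#' @inheritParams mc_pvalue
#' @return A `rex_pvalue` evaluated at `(mu, v_sup(mu))`.
#' @export
profile_pvalue <- function(mu, data, cfg = grid_config()) {
  mc_pvalue(mu, v_sup(mu), data, cfg)
}

#' @export
print.rex_pvalue <- function(x, ...) {
  cat(sprintf("<rex_pvalue> p = %.4f at (mu = %.4g, v = %.4g), m = %d, t_obs = %.3f\n",
              x$p, x$mu, x$v, x$m, x$t_obs))
  invisible(x)
}

#' Exact confidence interval for the mean treatment contrast
#'
#' Inverts the family of Monte-Carlo profile tests: the \eqn{(1-\alpha)}
#' CI is the set of grid values \eqn{\mu} whose profile p-value is at least
#' \eqn{\alpha}. The search has three stages:
#'
#' 1. **Initialize.** Asymptotic Wald bounds `point +/- z * se`, widened by
#'    50% of their half-width as a safety margin, snapped to the `s`-grid
#'    and clipped to `[s, 1-s]`. If the variance is degenerate the search
#'    starts at the point estimate's grid cell.
#' 2. **Iterate.** From each initial bound, walk outward in steps of `s`
#'    while the profile p-value stays at or above `alpha` (or inward until
#'    it first reaches `alpha` if the initial bound is already rejected).
#'    The provisional limits are the outermost accepted grid points.
#' 3. **Correct.** Examine `correction_span` further grid points beyond
#'    each provisional limit and extend to the outermost accepted point,
#'    since boundary profiling is only an approximation to the supremum
#'    over `v`.
#'
#' Coverage is guaranteed at or above the nominal level (up to Monte-Carlo
#' error) for any number of studies, sample sizes, or event rates, because
#' the test is calibrated against the exact conditional distribution of the
#' statistic rather than an asymptotic approximation.
#'
#' @param data A `rex_meta` dataset (or coercible data frame) with at least
#'   two retained studies.
#' @param cfg A [grid_config()].
#' @param null_value Reference contrast reported alongside the CI as
#'   `p_at_null`; 0.5 is "no effect".
#' @return An object of class `rex_ci`: list with `lower`, `upper`, `point`
#'   (the method-of-moments estimate), `p_at_null`, `alpha`, `k`, `k_tot`,
#'   `settings`, `flags`, `runtime` (seconds), and `diagnostics`, a tibble
#'   of every grid point evaluated (`mu`, `v`, `p`, `t_obs`, `stage`). Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' dat <- read_meta_csv(rex_example("facemask_synthetic"))
#' ci <- exact_ci(dat, grid_config(s = 0.005, m = 200, seed = 7))
#' tidy(ci)
#' @export
exact_ci <- function(data, cfg = grid_config(), null_value = 0.5) {
  t0 <- proc.time()[["elapsed"]]
  data <- canonical_sort(as_rex_meta(data))
  if (nrow(data) < 2L) abort("at least two retained studies are required.")
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(2147483000L, 1L)
    message("no seed supplied; using generated seed ", cfg$seed)
  }
  est <- mom_estimates(data)
  tables <- lapply(seq_len(nrow(data)), function(i) {
    study_term_table(data$n1[i], data$n2[i], data$y1[i] + data$y2[i])
  })
  s <- cfg$s
  alpha <- cfg$alpha
  imax <- round((1 - s) / s)  # grid indices 1..imax <-> mu = s..1-s
  flags <- character(0)

  cache <- new.env(parent = emptyenv())
  eval_p <- function(i, stage) {
    key <- as.character(i)
    if (!is.null(cache[[key]])) return(cache[[key]]$p)
    mu <- i * s
    res <- mc_pvalue_impl(mu, v_sup(mu), data, cfg, est, tables)
    cache[[key]] <- list(p = res$p, t_obs = res$t_obs, v = res$v,
                         stage = stage, mu = mu)
    res$p
  }
  snap <- function(mu) max(1L, min(imax, as.integer(round(mu / s))))

  se <- sqrt(est$var_mu_hat)
  ipoint <- snap(est$mu_hat)
  degenerate <- !is.finite(se) || se <= 0
  if (degenerate) {
    flags <- c(flags, "degenerate_variance")
    ilo <- ihi <- ipoint
  } else {
    half <- 1.5 * qnorm(1 - alpha / 2) * se
    ilo <- snap(est$mu_hat - half)
    ihi <- snap(est$mu_hat + half)
  }

  # iterate: outermost accepted grid point in each direction
  walk <- function(i, dir, stage) {
    # dir = -1 lower bound, +1 upper bound
    if (eval_p(i, stage) >= alpha) {
      while (i + dir >= 1L && i + dir <= imax &&
             eval_p(i + dir, stage) >= alpha) {
        i <- i + dir
      }
      if (i == 1L || i == imax) flags <<- c(flags, "clipped_at_grid_edge")
      i
    } else {
      repeat {
        i <- i - dir  # move inward
        if (i < 1L || i > imax) return(NA_integer_)
        if (eval_p(i, stage) >= alpha) return(i)
      }
    }
  }
  ilow <- walk(ilo, -1L, "iterate_lower")
  ihigh <- walk(ihi, +1L, "iterate_upper")
  if (is.na(ilow) || is.na(ihigh) || ilow > ihigh) {
    flags <- c(flags, "no_grid_point_accepted")
    ilow <- ihigh <- ipoint
    eval_p(ipoint, "fallback_point")
  }

  # correction: extend to the outermost accepted point within the span
  span <- cfg$correction_span
  if (span > 0L) {
    lo_cand <- (ilow - span):(ilow - 1L)
    lo_cand <- lo_cand[lo_cand >= 1L]
    acc <- lo_cand[vapply(lo_cand, eval_p, numeric(1),
                          stage = "correct_lower") >= alpha]
    if (length(acc)) ilow <- min(acc)
    hi_cand <- (ihigh + 1L):(ihigh + span)
    hi_cand <- hi_cand[hi_cand <= imax]
    acc <- hi_cand[vapply(hi_cand, eval_p, numeric(1),
                          stage = "correct_upper") >= alpha]
    if (length(acc)) ihigh <- max(acc)
  }

  p_null <- eval_p(snap(null_value), "null")

  keys <- as.integer(ls(cache))
  diag <- purrr::map_dfr(sort(keys), function(i) {
    e <- cache[[as.character(i)]]
    tibble(mu = e$mu, v = e$v, p = e$p, t_obs = e$t_obs, stage = e$stage)
  })

  structure(list(
    lower = ilow * s, upper = ihigh * s,
    point = est$mu_hat, estimates = est,
    p_at_null = p_null, null_value = null_value,
    alpha = alpha, k = nrow(data), k_tot = attr(data, "k_tot"),
    settings = cfg, flags = unique(flags),
    diagnostics = diag,
    runtime = proc.time()[["elapsed"]] - t0),
    class = "rex_ci")
}

#' @export
print.rex_ci <- function(x, ...) {
  cat(sprintf("<rex_ci> %d%% exact CI for the mean treatment contrast\n",
              round(100 * (1 - x$alpha))))
  cat(sprintf("  point = %.3f  CI = [%.3f, %.3f]  (relative risk %.2f [%.2f, %.2f])\n",
              x$point, x$lower, x$upper,
              x$point / (1 - x$point), x$lower / (1 - x$lower),
              x$upper / (1 - x$upper)))
  cat(sprintf("  p-value at contrast %.2f: %.4g   (k = %d of %d studies, m = %d, s = %g, seed = %d)\n",
              x$null_value, x$p_at_null, x$k, x$k_tot,
              x$settings$m, x$settings$s, x$settings$seed))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rex_ci <- function(x, ...) {
  tibble(estimate = x$point, conf.low = x$lower, conf.high = x$upper,
         p.value = x$p_at_null, null.value = x$null_value,
         conf.level = 1 - x$alpha)
}

#' @exportS3Method generics::glance
glance.rex_ci <- function(x, ...) {
  tibble(estimate = x$point, conf.low = x$lower, conf.high = x$upper,
         p.value = x$p_at_null, alpha = x$alpha, k = x$k, k_tot = x$k_tot,
         s = x$settings$s, m = x$settings$m, seed = x$settings$seed,
         n_grid = nrow(x$diagnostics), runtime = x$runtime)
}

#' Serialize an exact CI result to JSON
#'
#' Writes a flat, reproducible record of the interval and its settings.
#' Runtime is intentionally excluded so identical configurations and seeds
#' yield byte-identical files; it is available via [glance()].
#'
#' @param x A `rex_ci` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ci_json <- function(x, path) {
  stopifnot(inherits(x, "rex_ci"))
  rec <- list(scale = "treatment contrast (0.5 = no effect)",
              point = x$point, lower = x$lower, upper = x$upper,
              relative_risk = x$point / (1 - x$point),
              p_at_null = x$p_at_null, null_value = x$null_value,
              alpha = x$alpha, s = x$settings$s, m = x$settings$m,
              seed = x$settings$seed, k = x$k, k_tot = x$k_tot,
              flags = x$flags)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot the profile p-value surface of an exact CI
#'
#' Shows every grid point the search evaluated, the rejection threshold
#' `alpha`, the interval, and the point estimate. Useful for checking that
#' the correction step did not uncover accepted points far beyond the
#' provisional limits.
#'
#' @param object A `rex_ci` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rex_ci <- function(object, ...) {
  d <- object$diagnostics
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mu, y = .data$p)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2,
                        colour = "grey40") +
    ggplot2::annotate("rect", xmin = object$lower, xmax = object$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.12,
                      fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 1.4) +
    ggplot2::geom_vline(xintercept = object$point, linetype = 3) +
    ggplot2::labs(
      x = "mean treatment contrast μ",
      y = "Monte-Carlo profile p-value",
      colour = "search stage",
      title = sprintf("Exact %d%% CI: [%.3f, %.3f]",
                      round(100 * (1 - object$alpha)),
                      object$lower, object$upper)) +
    ggplot2::theme_minimal()
}
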