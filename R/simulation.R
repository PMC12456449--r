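#' Define a Poisson-Gamma simulation setting
#'
#' The generating mechanism draws, for study *i*, arm rates
#' \deqn{\lambda_{i1} \sim Gamma(\alpha_0,\ \alpha_0/r_0), \qquad
#'       \lambda_{i2} \sim Gamma(\beta_0,\ \alpha_0/r_0)}
#' (shape, rate), so the treated arm's mean event rate is `r0`, the control
#' arm's is `r0 * beta0 / alpha0`, and -- because the two Gamma laws share a
#' rate -- the contrast \eqn{\pi_i = \lambda_{i1}/(\lambda_{i1} +
#' \lambda_{i2})} is exactly Beta(\eqn{\alpha_0, \beta_0}). Event counts
#' are then Poisson with mean (arm size) x (arm rate).
#'
#' Canonical heterogeneity levels used throughout the package's numerical
#' studies: shapes (1.45, 1.45) for high, (5.5, 5.5) for moderate and
#' (145, 145) for low between-study heterogeneity under the null, with
#' protective counterparts (1.10, 1.65), (4.20, 6.30) and (110, 165) giving
#' a mean contrast of 0.4 (relative risk 2/3).
#'
#' @param alpha0,beta0 Beta shape parameters of the contrast law; both must
#'   be at least 1 (unimodality), which is equivalent to the implied
#'   variance respecting `v_sup`.
#' @param r0 Mean event rate in the treated arm.
#' @param k_tot Number of studies generated per dataset (before double-zero
#'   removal).
#' @param size_source Data frame with columns `n1`, `n2` from which study
#'   size pairs are sampled with replacement, or `NULL` to draw synthetic
#'   pairs (control sizes log-uniform on [60, 700]; treated size a ratio of
#'   1, 1.6 or 2 times larger, echoing the unequal randomisation common in
#'   drug-safety trials).
#' @param label Free-text description.
#' @return A list of class `sim_setting` carrying the implied `(mu0, v0)`.
#' @export
sim_setting <- function(alpha0, beta0, r0 = 0.01, k_tot = 12L,
                        size_source = NULL, label = "") {
  stopifnot(r0 > 0, r0 < 1, k_tot >= 1)
  if (alpha0 < 1 || beta0 < 1) {
    abort(paste("shape parameters below 1 violate the unimodality",
                "constraint (implied v0 > v_sup(mu0))."))
  }
  if (!is.null(size_source)) {
    stopifnot(is.data.frame(size_source),
              all(c("n1", "n2") %in% names(size_source)),
              nrow(size_source) >= 1)
  }
  mom <- moments_from_shape(alpha0, beta0)
  structure(list(alpha0 = alpha0, beta0 = beta0, r0 = r0,
                 k_tot = as.integer(k_tot), size_source = size_source,
                 mu0 = mom[["mu"]], v0 = mom[["v"]], label = label),
            class = "sim_setting")
}

#' Synthetic study-size pairs
#'
#' Control-arm sizes are log-uniform on [60, 700]; the treated arm is
#' larger by a ratio drawn from {1, 1.6, 2}. Used when no empirical size
#' table is supplied, so the simulation harness is self-contained.
#'
#' @param n Number of pairs.
#' @return A tibble with columns `n1`, `n2`.
#' @export
synthetic_size_pairs <- function(n) {
  n2 <- round(exp(stats::runif(n, log(60), log(700))))
  ratio <- sample(c(1, 1.6, 2), n, replace = TRUE)
  tibble(n1 = as.integer(round(n2 * ratio)), n2 = as.integer(n2))
}

#' Generate one meta-analysis dataset from a simulation setting
#'
#' Draws arm rates, sizes and Poisson counts as described in
#' [sim_setting()]. Counts are truncated at the arm size (the event is
#' observed at most once per subject); at the rare event rates of interest
#' truncation essentially never fires, and the number of truncated counts
#' is reported so that can be checked.
#'
#' @param setting A [sim_setting()].
#' @param seed Optional integer seed.
#' @return A list with `full` (all `k_tot` studies as a tibble), `data`
#'   (the double-zero-filtered `rex_meta` dataset, or `NULL` if fewer than
#'   one study remains), `n_removed`, and `n_truncated`.
#' @export
generate_meta_dataset <- function(setting, seed = NULL) {
  stopifnot(inherits(setting, "sim_setting"))
  if (!is.null(seed)) set.seed(seed)
  k <- setting$k_tot
  sizes <- if (is.null(setting$size_source)) {
    synthetic_size_pairs(k)
  } else {
    setting$size_source[sample.int(nrow(setting$size_source), k,
                                   replace = TRUE), c("n1", "n2")]
  }
  rate <- setting$alpha0 / setting$r0
  lam1 <- rgamma(k, shape = setting$alpha0, rate = rate)
  lam2 <- rgamma(k, shape = setting$beta0, rate = rate)
  y1_raw <- rpois(k, sizes$n1 * lam1)
  y2_raw <- rpois(k, sizes$n2 * lam2)
  n_trunc <- sum(y1_raw > sizes$n1) + sum(y2_raw > sizes$n2)
  full <- tibble(label = paste0("sim_", seq_len(k)),
                 y1 = as.integer(pmin(y1_raw, sizes$n1)),
                 n1 = as.integer(sizes$n1),
                 y2 = as.integer(pmin(y2_raw, sizes$n2)),
                 n2 = as.integer(sizes$n2))
  flt <- filter_double_zero(full)
  data <- if (nrow(flt$retained) >= 1L) meta_data(full) else NULL
  list(full = full, data = data, n_removed = flt$n_removed,
       n_truncated = n_trunc)
}

#' Operating characteristics of the exact procedure by simulation
#'
#' Repeatedly generates datasets from `setting` and either tests
#' `H0: mu0 = mu_null` with the Monte-Carlo profile p-value
#' (`mode = "test_only"`, cheap) or computes the full exact CI
#' (`mode = "full_ci"`), then summarizes rejection rate (type-I error when
#' `mu_null` equals the generating mean, power otherwise), coverage of the
#' generating mean, mean CI length, and the double-zero fraction, each with
#' binomial Monte-Carlo standard errors.
#'
#' Replicates whose filtered dataset retains fewer than two studies are
#' counted (`n_redrawn`) and redrawn, since the estimators need at least
#' two. Every replicate derives its generation seed and its test seed
#' deterministically from `cfg$seed`, so whole runs are reproducible.
#'
#' @param setting A [sim_setting()].
#' @param mu_null Contrast value under test; 0.5 is "no effect".
#' @param n_reps Number of simulated meta-analyses.
#' @param cfg A [grid_config()]; `m` of a few hundred is typical here.
#' @param mode `"test_only"` or `"full_ci"`.
#' @return An object of class `rex_oc`: list with a one-row `summary`
#'   tibble, the per-replicate `replicates` tibble, the setting and
#'   configuration. Has [tidy()] and [glance()] methods.
#' @export
run_operating_characteristics <- function(setting, mu_null = 0.5,
                                          n_reps = 300L,
                                          cfg = grid_config(m = 500L),
                                          mode = c("test_only", "full_ci")) {
  stopifnot(inherits(setting, "sim_setting"), n_reps >= 1)
  mode <- match.arg(mode)
  if (is.null(cfg$seed)) cfg$seed <- sample.int(1000000L, 1L)
  base <- cfg$seed %% 1000000L
  n_redrawn <- 0L
  recs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    attempt <- 0L
    repeat {
      gseed <- (base + 7919 * i + 104729 * attempt) %% 2147483629 + 1
      gen <- generate_meta_dataset(setting, seed = gseed)
      if (!is.null(gen$data) && nrow(gen$data) >= 2L) break
      n_redrawn <- n_redrawn + 1L
      attempt <- attempt + 1L
      if (attempt > 1000L) abort("could not generate a usable dataset.")
    }
    cfg_i <- cfg
    cfg_i$seed <- as.integer((base + 7919 * i + 13) %% 2147483629 + 1)
    rec <- tibble(rep = i, k = nrow(gen$data),
                  dz_fraction = gen$n_removed / setting$k_tot)
    if (mode == "test_only") {
      pv <- profile_pvalue(mu_null, gen$data, cfg_i)
      rec$p <- pv$p
      rec$reject <- pv$p < cfg$alpha
      rec$cover <- NA
      rec$ci_length <- NA_real_
    } else {
      ci <- exact_ci(gen$data, cfg_i, null_value = mu_null)
      rec$p <- ci$p_at_null
      rec$reject <- ci$p_at_null < cfg$alpha
      rec$cover <- ci$lower <= setting$mu0 && setting$mu0 <= ci$upper
      rec$ci_length <- ci$upper - ci$lower
    }
    recs[[i]] <- rec
  }
  reps <- dplyr::bind_rows(recs)
  rate <- mean(reps$reject)
  cover <- if (mode == "full_ci") mean(reps$cover) else 1 - rate
  binse <- function(p) sqrt(p * (1 - p) / n_reps)
  summary <- tibble(
    label = setting$label, mode = mode, mu_null = mu_null,
    mu0 = setting$mu0, v0 = setting$v0, r0 = setting$r0,
    k_tot = setting$k_tot, n_reps = n_reps, m = cfg$m,
    rejection_rate = rate, rejection_se = binse(rate),
    coverage = cover, coverage_se = binse(cover),
    mean_ci_length = if (mode == "full_ci") mean(reps$ci_length) else
      NA_real_,
    dz_fraction = mean(reps$dz_fraction),
    n_redrawn = n_redrawn, seed = cfg$seed)
  structure(list(summary = summary, replicates = reps, setting = setting,
                 settings = cfg),
            class = "rex_oc")
}

#' @export
print.rex_oc <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rex_oc> %s: %d reps, mode %s\n  rejection %.3f (SE %.3f)  coverage %.3f  DZ fraction %.3f\n",
    ifelse(nzchar(s$label), s$label, "simulation"), s$n_reps, s$mode,
    s$rejection_rate, s$rejection_se, s$coverage, s$dz_fraction))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rex_oc <- function(x, ...) x$replicates

#' @exportS3Method generics::glance
glance.rex_oc <- function(x, ...) x$summary
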