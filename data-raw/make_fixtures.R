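# Builds the two bundled SYNTHETIC example tables under inst/extdata/.
#
# Both are stand-ins generated from the package's own Poisson-Gamma
# mechanism, shaped to the published summary characteristics of two
# well-known meta-analyses (study counts, approximate size profiles,
# double-zero prevalence, direction and rough magnitude of effect). They
# are NOT the real per-study tables; filenames and documentation say so.
#
# Construction is deterministic (fixed seed) and was frozen before any
# downstream measurement. Run from the package root:
#   Rscript data-raw/make_fixtures.R

devtools::load_all(".", quiet = TRUE)
set.seed(20260920)

# --- rosiglitazone-style drug-safety table: 48 studies, two rare endpoints.
# Size profile: two large trials; 40 smaller trials with log-normal treated
# arms (median ~230), 60% using 2:1 randomisation; 6 additional small
# double-zero studies.
small_n1 <- pmin(pmax(round(rlnorm(40, log(232), 0.75)), 40), 1200)
small_ratio2 <- runif(40) < 0.6
small_n2 <- ifelse(small_ratio2, round(small_n1 / 2), small_n1)
extra_n1 <- round(runif(6, 80, 400))
extra_ratio2 <- runif(6) < 0.6
extra_n2 <- ifelse(extra_ratio2, round(extra_n1 / 2), extra_n1)
n1 <- c(2635L, 1456L, small_n1, extra_n1)
n2 <- c(2634L, 2895L, small_n2, extra_n2)
k <- length(n1)  # 48

gen_counts <- function(n1, n2, alpha, beta, r0) {
  rate <- alpha / r0
  lam1 <- rgamma(length(n1), alpha, rate = rate)
  lam2 <- rgamma(length(n2), beta, rate = rate)
  list(y1 = pmin(rpois(length(n1), n1 * lam1), n1),
       y2 = pmin(rpois(length(n2), n2 * lam2), n2))
}

# Deterministically adjust a pair of event vectors so that exactly
# `target_dz` studies are double-zero: zero out the smallest non-DZ
# studies, or seed one treated event in the largest DZ studies.
force_dz <- function(y1, y2, n1, n2, target_dz, protect = integer(0)) {
  repeat {
    dz <- which(y1 + y2 == 0)
    if (length(dz) == target_dz) return(list(y1 = y1, y2 = y2))
    if (length(dz) < target_dz) {
      cand <- setdiff(order(n1 + n2), c(dz, protect))
      i <- cand[cand %in% which(y1 + y2 > 0)][1]
      y1[i] <- 0; y2[i] <- 0
    } else {
      i <- dz[order(-(n1 + n2)[dz])][1]
      y1[i] <- 1
    }
  }
}

mi <- gen_counts(n1, n2, alpha = 6.7, beta = 3.3, r0 = 0.006)
cvd <- gen_counts(n1, n2, alpha = 7.9, beta = 2.1, r0 = 0.0035)
extras <- 43:48
mi$y1[extras] <- 0; mi$y2[extras] <- 0
cvd$y1[extras] <- 0; cvd$y2[extras] <- 0
# published scale: 10 of 48 studies with no MIs, 25 of 48 with no CVD;
# the two large trials are never zeroed
mi <- force_dz(mi$y1, mi$y2, n1, n2, target_dz = 10, protect = 1:2)
cvd <- force_dz(cvd$y1, cvd$y2, n1, n2, target_dz = 25, protect = 1:2)

rosi <- tibble::tibble(
  label = paste0("trial_", sprintf("%02d", seq_len(k))),
  n1 = n1, n2 = n2,
  mi1 = as.integer(mi$y1), mi2 = as.integer(mi$y2),
  cvd1 = as.integer(cvd$y1), cvd2 = as.integer(cvd$y2))
readr::write_csv(rosi, "inst/extdata/rosiglitazone_synthetic.csv")

# --- face-mask-style table: 29 studies, higher event rate, strongly
# protective contrast (mean ~0.19), heterogeneous study sizes.
fm_n1 <- pmin(pmax(round(rlnorm(29, log(120), 0.9)), 10), 1500)
fm_n2 <- round(fm_n1 * sample(c(0.7, 1, 1.5), 29, replace = TRUE))
fm <- gen_counts(fm_n1, fm_n2, alpha = 1.9, beta = 8.1, r0 = 0.035)
facemask <- tibble::tibble(
  label = paste0("study_", sprintf("%02d", 1:29)),
  y1 = as.integer(fm$y1), n1 = as.integer(fm_n1),
  y2 = as.integer(fm$y2), n2 = as.integer(fm_n2))
readr::write_csv(facemask, "inst/extdata/facemask_synthetic.csv")

cat("rosiglitazone_synthetic: ", nrow(rosi), "studies; MI DZ =",
    sum(rosi$mi1 + rosi$mi2 == 0), "; CVD DZ =",
    sum(rosi$cvd1 + rosi$cvd2 == 0), "\n")
cat("facemask_synthetic:", nrow(facemask), "studies; DZ =",
    sum(facemask$y1 + facemask$y2 == 0), "\n")
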