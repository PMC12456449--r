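#' Study-level two-arm count data
#'
#' A meta-analysis dataset is a tibble with one row per study and integer
#' columns `y1`, `n1` (events and sample size in the treated arm) and `y2`,
#' `n2` (control arm), plus an optional `label`. `meta_data()` validates the
#' counts, removes double-zero (DZ) studies -- studies with no events in
#' either arm, which carry no information about the relative risk once each
#' study is conditioned on its total event count -- and attaches the
#' per-study design offset `offset = log(n1/n2)`.
#'
#' The returned object is a tibble of class `rex_meta` carrying the number
#' of studies before filtering (`k_tot`) and the number removed
#' (`n_removed`) as attributes; `k`, the number of retained studies, is
#' simply `nrow()`.
#'
#' @param x A data frame with columns `y1`, `n1`, `y2`, `n2` (remappable via
#'   `column_map`) and optionally `label`.
#' @param column_map Optional named character vector mapping the canonical
#'   names to the columns of `x`, e.g.
#'   `c(y1 = "mi1", n1 = "nt", y2 = "mi2", n2 = "nc")`. Extra columns in `x`
#'   are ignored.
#' @return A `rex_meta` tibble with columns `label`, `y1`, `n1`, `y2`, `n2`,
#'   `offset`.
#' @examples
#' meta_data(tibble::tibble(y1 = c(2, 1), n1 = c(80, 100),
#'                          y2 = c(1, 0), n2 = c(50, 90)))
#' @export
meta_data <- function(x, column_map = NULL) {
  stopifnot(is.data.frame(x))
  canon <- c("y1", "n1", "y2", "n2")
  map <- setNames(canon, canon)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || !all(names(column_map) %in% canon)) {
      abort("`column_map` must be named with a subset of y1, n1, y2, n2.")
    }
    map[names(column_map)] <- unname(column_map)
  }
  missing_cols <- setdiff(unname(map), names(x))
  if (length(missing_cols)) {
    abort(paste0("Input is missing count column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  label <- if ("label" %in% names(x)) as.character(x[["label"]]) else
    paste0("study_", seq_len(nrow(x)))
  out <- tibble(
    label = label,
    y1 = parse_count(x[[map[["y1"]]]], map[["y1"]]),
    n1 = parse_count(x[[map[["n1"]]]], map[["n1"]]),
    y2 = parse_count(x[[map[["y2"]]]], map[["y2"]]),
    n2 = parse_count(x[[map[["n2"]]]], map[["n2"]])
  )
  bad_n <- which(out$n1 < 1L | out$n2 < 1L)
  if (length(bad_n)) {
    abort(paste0("Sample sizes must be >= 1; offending row(s): ",
                 paste(bad_n, collapse = ", ")))
  }
  bad_y <- which(out$y1 > out$n1 | out$y2 > out$n2)
  if (length(bad_y)) {
    abort(paste0("Event count exceeds arm size in row(s): ",
                 paste(bad_y, collapse = ", ")))
  }
  flt <- filter_double_zero(out)
  if (nrow(flt$retained) == 0L) {
    abort("all studies double-zero: no informative studies remain.")
  }
  ret <- flt$retained
  ret$offset <- log(ret$n1 / ret$n2)
  new_rex_meta(ret, k_tot = nrow(out), n_removed = flt$n_removed)
}

parse_count <- function(v, name) {
  iv <- suppressWarnings(as.numeric(v))
  bad <- which(!is.finite(iv) | iv < 0 | iv != round(iv))
  if (length(bad)) {
    abort(paste0("Column `", name, "` must hold non-negative integers; ",
                 "malformed row(s): ", paste(bad, collapse = ", ")))
  }
  as.integer(round(iv))
}

new_rex_meta <- function(df, k_tot, n_removed) {
  out <- as_tibble(df)
  attr(out, "k_tot") <- as.integer(k_tot)
  attr(out, "n_removed") <- as.integer(n_removed)
  class(out) <- c("rex_meta", class(out))
  out
}

#' Coerce to a validated meta-analysis dataset
#'
#' @param x A `rex_meta` object or plain data frame acceptable to
#'   [meta_data()].
#' @return A `rex_meta` tibble.
#' @export
as_rex_meta <- function(x) {
  if (inherits(x, "rex_meta") && !is.null(attr(x, "k_tot"))) return(x)
  meta_data(x)
}

# Reorder studies by a canonical key so Monte-Carlo draws (which consume
# randomness in row order) and hence p-values and CIs are invariant to the
# order studies were entered. Estimator sums are order-free already.
canonical_sort <- function(data) {
  ord <- order(data$n1, data$n2, data$y1 + data$y2, data$y1)
  new_rex_meta(data[ord, ], k_tot = attr(data, "k_tot"),
               n_removed = attr(data, "n_removed"))
}

#' Remove double-zero studies
#'
#' Drops studies with `y1 + y2 == 0`, preserving the original order of the
#' remainder. Idempotent; an empty input is legal here (downstream
#' estimators reject datasets with fewer than two studies).
#'
#' @param studies A data frame with columns `y1` and `y2`.
#' @return A list with elements `retained` (the filtered rows) and
#'   `n_removed`.
#' @export
filter_double_zero <- function(studies) {
  stopifnot(is.data.frame(studies))
  if (nrow(studies) == 0L) {
    return(list(retained = as_tibble(studies), n_removed = 0L))
  }
  keep <- (studies$y1 + studies$y2) >= 1L
  list(retained = as_tibble(studies[keep, , drop = FALSE]),
       n_removed = sum(!keep))
}

#' Read a study-level count table from CSV
#'
#' Expects a header row and one study per row. Default column names are
#' `y1,n1,y2,n2` (treated events/size, control events/size); use
#' `column_map` to point at differently named columns, e.g. the bundled
#' rosiglitazone-style table which stores two endpoints side by side.
#' Double-zero studies are removed (and counted in the `n_removed`
#' attribute); row order is preserved.
#'
#' @param path Path to a CSV file.
#' @inheritParams meta_data
#' @return A `rex_meta` tibble.
#' @export
read_meta_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Input file does not exist: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta_data(raw, column_map = column_map)
}

#' Write a study-level count table to CSV
#'
#' Inverse of [read_meta_csv()] up to double-zero removal: writing then
#' reading reproduces the retained counts exactly.
#'
#' @param data A `rex_meta` object or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_csv <- function(data, path) {
  data <- as_rex_meta(data)
  readr::write_csv(data[c("label", "y1", "n1", "y2", "n2")], path,
                   progress = FALSE)
  invisible(path)
}

#' @export
print.rex_meta <- function(x, ...) {
  cat(sprintf("<rex_meta> %d studies retained (%d double-zero removed)\n",
              nrow(x), attr(x, "n_removed")))
  NextMethod()
}

#' Path to a bundled example dataset
#'
#' The package ships two *synthetic* study-level tables generated from the
#' package's own Poisson-Gamma mechanism: `"rosiglitazone_synthetic"`
#' (48 studies, columns `mi1`/`mi2` and `cvd1`/`cvd2` for two rare
#' endpoints, emulating the scale and size profile of a large drug-safety
#' meta-analysis) and `"facemask_synthetic"` (29 studies, single endpoint,
#' higher event rate, strongly protective contrast). They are stand-ins for
#' real supplementary tables and are labelled synthetic for that reason;
#' use them for examples, tests, and as a size source for the simulation
#' harness.
#'
#' @param name One of `"rosiglitazone_synthetic"`, `"facemask_synthetic"`.
#' @return A file path.
#' @export
rex_example <- function(name = c("rosiglitazone_synthetic",
                                 "facemask_synthetic")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".csv"), package = "rexmeta",
              mustWork = TRUE)
}
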