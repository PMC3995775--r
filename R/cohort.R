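#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences `a - b`. Zero
#' differences are dropped before ranking (Wilcoxon's original treatment).
#' With 25 or fewer non-zero, untied differences the exact null
#' distribution is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric vectors of equal length, paired by position.
#' @return One-row tibble: `statistic` (V, sum of positive ranks),
#'   `p_value`, `n_pairs`, `n_nonzero`, `exact` (logical).
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) {
    abort("paired samples must have equal length", class = "gv_validation_error")
  }
  if (length(a) < 5) {
    abort("need at least 5 pairs", class = "gv_validation_error")
  }
  d <- a - b
  dnz <- d[d != 0]
  if (!length(dnz)) {
    abort("all paired differences are zero: test is degenerate",
      class = "gv_degenerate_test"
    )
  }
  n <- length(dnz)
  use_exact <- n <= 25 && !any(duplicated(abs(dnz)))
  ht <- suppressWarnings(
    stats::wilcox.test(dnz, mu = 0, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_pairs = length(a),
    n_nonzero = n,
    exact = use_exact
  )
}

#' Two-sided variance-ratio F test
#'
#' Compares the spread of two independent samples. The statistic is the
#' larger sample variance over the smaller, with the two-sided p value
#' from the F distribution on (n1 - 1, n2 - 1) degrees of freedom; the
#' result is symmetric in the arguments.
#'
#' @param a,b Numeric vectors, each with at least 2 values and non-zero
#'   variance.
#' @return One-row tibble: `statistic` (F >= 1), `df1`, `df2`, `p_value`,
#'   `sd_a`, `sd_b`.
#' @export
variance_f_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least 2 values", class = "gv_validation_error")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va < .Machine$double.eps || vb < .Machine$double.eps) {
    abort("zero variance in a sample: F test is degenerate",
      class = "gv_degenerate_test"
    )
  }
  if (va >= vb) {
    f <- va / vb
    df <- c(length(a) - 1, length(b) - 1)
  } else {
    f <- vb / va
    df <- c(length(b) - 1, length(a) - 1)
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  tibble::tibble(
    statistic = f, df1 = df[1], df2 = df[2], p_value = p,
    sd_a = sqrt(va), sd_b = sqrt(vb)
  )
}

#' Summary statistics for a version table
#'
#' @param results Version table with a `version_deg` column.
#' @param ... Grouping columns (tidy-select style), e.g. `method`, `side`.
#' @return Tibble of n, mean, sd, min, max of `version_deg` per group
#'   (degrees).
#' @export
cohort_summary <- function(results, ...) {
  results |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(c(...))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_deg = mean(.data$version_deg),
      sd_deg = stats::sd(.data$version_deg),
      min_deg = min(.data$version_deg),
      max_deg = max(.data$version_deg),
      .groups = "drop"
    )
}

#' Average repeated ratings to one version value per shoulder and method
#'
#' Collapses a long rating table (multiple raters and sessions per
#' shoulder) to its per-shoulder mean, the aggregation applied before any
#' cohort-level comparison.
#'
#' @param ratings Long table with `shoulder_id`, `method`, `version_deg`
#'   and any of `subject_id`, `side`, `dominance` to carry through.
#' @return Tibble with one row per shoulder and method.
#' @export
aggregate_ratings <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  keys <- intersect(
    c("shoulder_id", "subject_id", "side", "dominance", "method", "variant"),
    names(ratings)
  )
  dplyr::summarise(ratings,
    version_deg = mean(.data$version_deg),
    .by = dplyr::all_of(keys)
  )
}

#' Compare the vault and conventional methods on one cohort
#'
#' Pairs the two methods per shoulder, then reports per-method summary
#' statistics, the paired Wilcoxon signed-rank test of vault versus
#' conventional version, the two-sided variance-ratio F test of their
#' distributions, and the mean signed difference.
#'
#' @param results Version table from [measure_version()] with both methods
#'   present for every shoulder.
#' @return Object of class `gv_method_comparison` with elements `summary`
#'   (per-method tibble), `wilcoxon`, `f_test`, `mean_difference_deg`,
#'   `n_shoulders`. Supports [tidy()] and [glance()].
#' @export
compare_methods <- function(results) {
  diffs <- method_difference(results)
  comp <- structure(
    list(
      summary = cohort_summary(results, dplyr::all_of("method")),
      wilcoxon = paired_wilcoxon(diffs$vault_deg, diffs$conventional_deg),
      f_test = variance_f_test(diffs$conventional_deg, diffs$vault_deg),
      mean_difference_deg = mean(diffs$difference_deg),
      n_shoulders = nrow(diffs)
    ),
    class = "gv_method_comparison"
  )
  comp
}

#' @export
print.gv_method_comparison <- function(x, ...) {
  cat("Glenoid version: vault vs conventional method,",
      x$n_shoulders, "shoulders\n\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-12s %5.1f deg +/- %.1f (range %.1f to %.1f)\n",
      s$method[i], s$mean_deg[i], s$sd_deg[i], s$min_deg[i], s$max_deg[i]
    ))
  }
  cat(sprintf(
    "\n  mean difference (vault - conventional): %.1f deg\n",
    x$mean_difference_deg
  ))
  cat(sprintf(
    "  paired Wilcoxon: V = %.0f, p = %.3f\n",
    x$wilcoxon$statistic, x$wilcoxon$p_value
  ))
  cat(sprintf(
    "  variance F test: F = %.2f, p = %.3f\n",
    x$f_test$statistic, x$f_test$p_value
  ))
  invisible(x)
}

#' @rdname compare_methods
#' @param x A `gv_method_comparison` object.
#' @param ... Unused.
#' @export
tidy.gv_method_comparison <- function(x, ...) {
  x$summary
}

#' @rdname compare_methods
#' @export
glance.gv_method_comparison <- function(x, ...) {
  tibble::tibble(
    n_shoulders = x$n_shoulders,
    mean_difference_deg = x$mean_difference_deg,
    wilcoxon_v = x$wilcoxon$statistic,
    wilcoxon_p = x$wilcoxon$p_value,
    f_statistic = x$f_test$statistic,
    f_p = x$f_test$p_value
  )
}

#' Compare dominant and nondominant sides in a paired cohort
#'
#' Pairs shoulders by `subject_id`, and for each method runs the paired
#' Wilcoxon signed-rank test of dominant versus nondominant version along
#' with per-side summaries.
#'
#' @param results Version table with columns `subject_id`, `dominance`
#'   (`"dominant"`/`"nondominant"`), `method`, `version_deg`; every subject
#'   must contribute both sides for every method.
#' @return Object of class `gv_side_comparison`: `summary` (per method and
#'   dominance), `tests` (per-method Wilcoxon with mean shift), `n_pairs`.
#'   Supports [tidy()] and [glance()].
#' @export
compare_sides <- function(results) {
  results <- tibble::as_tibble(results)
  needed <- c("subject_id", "dominance", "method", "version_deg")
  lack <- setdiff(needed, names(results))
  if (length(lack)) {
    abort(paste0("results lack column(s): ", paste(lack, collapse = ", ")),
      class = "gv_validation_error"
    )
  }
  wide <- results |>
    dplyr::select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(names_from = "dominance", values_from = "version_deg")
  lack_side <- !c("dominant", "nondominant") %in% names(wide)
  if (any(lack_side)) {
    abort("results lack a dominant/nondominant side",
      class = "gv_validation_error"
    )
  }
  bad <- wide$subject_id[is.na(wide$dominant) | is.na(wide$nondominant)]
  if (length(bad)) {
    abort(
      paste0(
        "subject(s) without both sides: ",
        paste(unique(bad), collapse = ", ")
      ),
      class = "gv_validation_error"
    )
  }
  tests <- wide |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(rows, key) {
      wt <- paired_wilcoxon(rows$dominant, rows$nondominant)
      dplyr::mutate(wt,
        mean_shift_deg = mean(rows$dominant - rows$nondominant),
        .before = 1
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(
      summary = cohort_summary(
        results,
        dplyr::all_of(c("method", "dominance"))
      ),
      tests = tests,
      n_pairs = nrow(wide) / length(unique(wide$method))
    ),
    class = "gv_side_comparison"
  )
}

#' @export
print.gv_side_comparison <- function(x, ...) {
  cat("Side-to-side glenoid version comparison,", x$n_pairs, "pairs\n\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-12s %-11s %5.1f deg +/- %.1f\n",
      s$method[i], s$dominance[i], s$mean_deg[i], s$sd_deg[i]
    ))
  }
  cat("\n")
  t <- x$tests
  for (i in seq_len(nrow(t))) {
    cat(sprintf(
      "  %-12s dominant - nondominant = %+.1f deg, Wilcoxon p = %.3f\n",
      t$method[i], t$mean_shift_deg[i], t$p_value[i]
    ))
  }
  invisible(x)
}

#' @rdname compare_sides
#' @param x A `gv_side_comparison` object.
#' @param ... Unused.
#' @export
tidy.gv_side_comparison <- function(x, ...) {
  x$summary
}

#' @rdname compare_sides
#' @export
glance.gv_side_comparison <- function(x, ...) {
  dplyr::mutate(x$tests, n_pairs = x$n_pairs)
}
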