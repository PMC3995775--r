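#' Intraclass correlation coefficient for a subjects-by-measurements table
#'
#' Single-measure ICC estimators with F-distribution 95% confidence
#' intervals, in the two random-effects forms used for rater-agreement
#' studies:
#'
#' * `model = "oneway"` — ICC(1,1), one-way random effects. Columns are
#'   exchangeable repeated measurements (e.g. two sessions of the same
#'   rater): \eqn{ICC = (BMS - WMS) / (BMS + (k-1) WMS)}.
#' * `model = "twoway"` — ICC(2,1), two-way random effects, absolute
#'   agreement. Columns are distinct raters drawn from a population of
#'   raters: \eqn{ICC = (BMS - EMS) / (BMS + (k-1) EMS + k (JMS - EMS)/n)}.
#'
#' `BMS`, `WMS`, `JMS`, `EMS` are the between-subject, within-subject,
#' between-rater and residual mean squares of the one- or two-way ANOVA
#' decomposition. Negative estimates are reported as computed, with a
#' warning, rather than truncated at zero.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, repeated
#'   measurements/raters in columns; complete (no missing cells).
#' @param model `"oneway"` (ICC(1,1)) or `"twoway"` (ICC(2,1)).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `gv_icc` with fields `model`, `estimate`,
#'   `ci_low`, `ci_high`, `n_subjects`, `n_raters`, `conf_level` and the
#'   mean squares. Supports [tidy()] and [glance()].
#' @references Shrout, P. E. and Fleiss, J. L. (1979). Intraclass
#'   correlations: uses in assessing rater reliability. Psychological
#'   Bulletin 86, 420-428.
#' @export
icc <- function(ratings, model = c("oneway", "twoway"), conf_level = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    abort("ratings table has missing cells; a complete design is required",
      class = "gv_validation_error"
    )
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    abort("need at least 2 subjects and 2 measurements per subject",
      class = "gv_validation_error"
    )
  }
  if (stats::var(as.vector(m)) < .Machine$double.eps) {
    abort("all ratings identical: reliability is undefined",
      class = "gv_degenerate_test"
    )
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  bss <- k * sum((row_m - grand)^2) # between subjects
  jss <- n * sum((col_m - grand)^2) # between raters/sessions
  tss <- sum((m - grand)^2)
  bms <- bss / (n - 1)
  alpha <- 1 - conf_level
  if (model == "oneway") {
    wss <- tss - bss
    wms <- wss / (n * (k - 1))
    est <- (bms - wms) / (bms + (k - 1) * wms)
    fobs <- bms / wms
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    ms <- list(bms = bms, wms = wms)
  } else {
    ess <- tss - bss - jss
    ems <- ess / ((n - 1) * (k - 1))
    jms <- jss / (k - 1)
    est <- (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
    # Satterthwaite degrees of freedom for the absolute-agreement interval
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * jms + b * ems)^2 /
      ((a * jms)^2 / (k - 1) + (b * ems)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    low <- n * (bms - fl * ems) /
      (fl * (k * jms + (k * n - k - n) * ems) + n * bms)
    up <- n * (fu * bms - ems) /
      (k * jms + (k * n - k - n) * ems + n * fu * bms)
    ci <- c(low, up)
    ms <- list(bms = bms, jms = jms, ems = ems)
  }
  # perfect agreement (zero error mean square) collapses the F bounds
  if (!is.finite(ci[1])) ci[1] <- est
  if (!is.finite(ci[2])) ci[2] <- est
  if (is.finite(est) && est < 0) {
    warn("negative ICC estimate; reported as computed, not truncated at 0")
  }
  structure(
    c(
      list(
        model = if (model == "oneway") "ICC(1,1)" else "ICC(2,1)",
        estimate = est,
        ci_low = min(ci[1], est),
        ci_high = max(ci[2], est),
        n_subjects = n,
        n_raters = k,
        conf_level = conf_level
      ),
      ms
    ),
    class = "gv_icc"
  )
}

#' @export
print.gv_icc <- function(x, ...) {
  cat(sprintf(
    "%s = %.3f (%d%% CI %.3f-%.3f), %d subjects x %d measurements\n",
    x$model, x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$n_subjects, x$n_raters
  ))
  invisible(x)
}

#' @rdname icc
#' @param x A `gv_icc` object.
#' @param ... Unused.
#' @export
tidy.gv_icc <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    estimate = x$estimate,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    conf_level = x$conf_level
  )
}

#' @rdname icc
#' @export
glance.gv_icc <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    estimate = x$estimate,
    n_subjects = x$n_subjects,
    n_raters = x$n_raters
  )
}

#' Full reliability report for a rating study
#'
#' Reproduces the reliability design of a multi-rater, two-session
#' measurement study: intrarater reliability per rater as ICC(1,1) across
#' that rater's sessions, and interrater reliability as ICC(2,1) across
#' raters. By default each rater enters the interrater analysis with the
#' mean of their sessions; `interrater = "first_session"` restricts to
#' session 1.
#'
#' @param ratings Long rating table with columns `shoulder_id`, `rater`,
#'   `session`, `version_deg` and optionally `method` (the report is
#'   stratified by method when present).
#' @param interrater `"session_means"` (default) or `"first_session"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per coefficient: `method`, `analysis`
#'   (`"intrarater"`/`"interrater"`), `rater` (NA for interrater), `model`,
#'   `estimate`, `ci_low`, `ci_high`, `n_subjects`, `n_raters`.
#' @export
reliability_report <- function(ratings,
                               interrater = c("session_means", "first_session"),
                               conf_level = 0.95) {
  interrater <- match.arg(interrater)
  ratings <- tibble::as_tibble(ratings)
  needed <- c("shoulder_id", "rater", "session", "version_deg")
  lack <- setdiff(needed, names(ratings))
  if (length(lack)) {
    abort(paste0("ratings lack column(s): ", paste(lack, collapse = ", ")),
      class = "gv_validation_error"
    )
  }
  if (!"method" %in% names(ratings)) ratings$method <- "all"
  one_icc_row <- function(fit, analysis, rater) {
    tibble::tibble(
      analysis = analysis,
      rater = rater,
      model = fit$model,
      estimate = fit$estimate,
      ci_low = fit$ci_low,
      ci_high = fit$ci_high,
      n_subjects = fit$n_subjects,
      n_raters = fit$n_raters
    )
  }
  ratings |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(rows, key) {
      complete <- rows |>
        dplyr::count(.data$shoulder_id, .data$rater) |>
        dplyr::pull(.data$n)
      if (length(unique(complete)) != 1) {
        abort("incomplete rating design: unequal sessions per shoulder/rater",
          class = "gv_validation_error"
        )
      }
      intra <- rows |>
        dplyr::group_split(.data$rater) |>
        purrr::map(function(rr) {
          wide <- tidyr::pivot_wider(
            rr[, c("shoulder_id", "session", "version_deg")],
            names_from = "session", values_from = "version_deg"
          )
          fit <- icc(wide[, -1], model = "oneway", conf_level = conf_level)
          one_icc_row(fit, "intrarater", as.character(rr$rater[1]))
        }) |>
        purrr::list_rbind()
      inter_in <- if (interrater == "session_means") {
        rows |>
          dplyr::summarise(
            version_deg = mean(.data$version_deg),
            .by = c("shoulder_id", "rater")
          )
      } else {
        first <- sort(unique(rows$session))[1]
        dplyr::filter(rows, .data$session == first)
      }
      wide <- tidyr::pivot_wider(
        inter_in[, c("shoulder_id", "rater", "version_deg")],
        names_from = "rater", values_from = "version_deg"
      )
      inter <- one_icc_row(
        icc(wide[, -1], model = "twoway", conf_level = conf_level),
        "interrater", NA_character_
      )
      dplyr::bind_rows(intra, inter)
    }) |>
    dplyr::ungroup()
}
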