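#' Intraclass correlation ICC(2,1), Shrout-Fleiss single score
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC computed
#' from the ANOVA mean squares of a targets x raters matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with
#' `MSR` the between-target, `MSC` the between-column and `MSE` the residual
#' mean square, `n` targets and `k` columns. Rows containing missing values
#' are dropped listwise with a message; a matrix with zero total variance
#' raises an error rather than returning a sentinel.
#'
#' @param table numeric matrix, targets in rows, raters/occasions in columns.
#' @return An `icc_result` with `icc`, `MSR`, `MSC`, `MSE`, `n`, `k`.
#' @export
icc_2_1 <- function(table) {
  x <- as.matrix(table)
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    message(sum(!complete), " targets dropped (missing values)")
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 columns")
  if (!all(is.finite(x))) stop("non-finite ratings")
  g <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  MSR <- k * sum((rm_ - g)^2) / (n - 1)
  MSC <- n * sum((cm - g)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (sum((x - g)^2) < 1e-24 * max(1, g^2))
    stop("zero total variance: ICC is undefined for a constant table")
  structure(list(icc = (MSR - MSE) / denom, MSR = MSR, MSC = MSC, MSE = MSE,
                 n = n, k = k), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  (n = %d targets, k = %d columns)\n",
              x$icc, x$n, x$k))
  cat(sprintf("  MSR %.4g  MSC %.4g  MSE %.4g\n", x$MSR, x$MSC, x$MSE))
  invisible(x)
}

#' Bland-Altman agreement summary
#'
#' Per-pair difference `a - b` against per-pair mean `(a + b) / 2`, with the
#' mean difference and limits of agreement at exactly +/- 2 standard
#' deviations. Pairs in which either member is zero (no contact stress) are
#' omitted and counted.
#'
#' @param a,b paired measurements (equal length), or `a` an n x 2 matrix.
#' @return A `bland_altman` list: `mean_difference`, `sd_difference`,
#'   `upper_limit`, `lower_limit`, `points` (data frame mean/difference),
#'   `n_omitted_zeros`.
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) {
    a <- as.matrix(a)
    b <- a[, 2]
    a <- a[, 1]
  }
  if (length(a) != length(b)) stop("paired measurements of unequal length")
  zero <- a == 0 | b == 0
  n_omitted <- sum(zero)
  a <- a[!zero]
  b <- b[!zero]
  if (length(a) < 2)
    stop("fewer than 2 pairs survive zero-omission")
  diffs <- a - b
  means <- (a + b) / 2
  m <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(mean_difference = m, sd_difference = s,
                 upper_limit = m + 2 * s, lower_limit = m - 2 * s,
                 points = data.frame(mean = means, difference = diffs),
                 n_omitted_zeros = n_omitted),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman: mean difference %.4g, SD %.4g, ",
                     "limits [%.4g, %.4g], %d zero pairs omitted\n"),
              x$mean_difference, x$sd_difference, x$lower_limit,
              x$upper_limit, x$n_omitted_zeros))
  invisible(x)
}

#' Day-to-day and interrater reliability report
#'
#' Takes a long ratings table (columns `knee_id`, `rater_id`, `day`,
#' `metric`, `compartment`, `value_mpa`) covering peak and mean contact
#' stress in both compartments and emits ICC(2,1) tables shaped like the
#' study design: rows {day-to-day, interrater} x {medial, lateral}, columns
#' {peak, mean}.
#'
#' Aggregation convention (configurable by subsetting the input): day-to-day
#' uses the days as columns with knee x rater combinations stacked as
#' targets; interrater uses the raters as columns with day-1 values.
#'
#' @param ratings long-format data frame as above.
#' @return List with `table` (4 x 2 data frame of ICCs) and `details`
#'   (the underlying `icc_result` objects). Missing design arms yield `NA`
#'   cells rather than an error.
#' @export
reliability_report <- function(ratings) {
  need <- c("knee_id", "rater_id", "day", "metric", "compartment", "value_mpa")
  if (!all(need %in% names(ratings)))
    stop("ratings must have columns ", paste(need, collapse = ", "))
  metrics <- c("peak", "mean")
  comps <- c("medial", "lateral")
  rows <- expand.grid(reliability = c("day-to-day", "interrater"),
                      compartment = comps, stringsAsFactors = FALSE)
  rows <- rows[order(rows$reliability), ]
  out <- data.frame(rows, peak = NA_real_, mean = NA_real_)
  details <- list()
  for (m in metrics) {
    for (cp in comps) {
      sub <- ratings[ratings$metric == m & ratings$compartment == cp, ]
      if (nrow(sub) == 0) next
      # day-to-day: columns = days, targets = knee x rater
      d2d <- tryCatch({
        wide <- stats::reshape(
          sub[, c("knee_id", "rater_id", "day", "value_mpa")],
          idvar = c("knee_id", "rater_id"), timevar = "day",
          direction = "wide")
        icc_2_1(as.matrix(wide[, -(1:2), drop = FALSE]))
      }, error = function(e) NULL)
      # interrater: columns = raters, day-1 values
      d1 <- sub[sub$day == sort(unique(sub$day))[1], ]
      irr <- tryCatch({
        wide <- stats::reshape(
          d1[, c("knee_id", "rater_id", "value_mpa")],
          idvar = "knee_id", timevar = "rater_id", direction = "wide")
        icc_2_1(as.matrix(wide[, -1, drop = FALSE]))
      }, error = function(e) NULL)
      if (!is.null(d2d))
        out[out$reliability == "day-to-day" & out$compartment == cp, m] <-
          d2d$icc
      if (!is.null(irr))
        out[out$reliability == "interrater" & out$compartment == cp, m] <-
          irr$icc
      details[[paste(m, cp, sep = "_")]] <- list(day_to_day = d2d,
                                                 interrater = irr)
    }
  }
  list(table = out, details = details)
}

#' Write a reliability report as CSV + JSON
#' @param report a [reliability_report()] result.
#' @param path_prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @export
write_reliability_report <- function(report, path_prefix) {
  write.csv(report$table, paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(report$table, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}
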