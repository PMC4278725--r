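#' Coefficient of variation of a measurement pair
#'
#' The within-subject CV for two measurements of the same quantity, using
#' the sample-standard-deviation convention standard in test-retest imaging:
#' sd(x, y) = |x - y| / sqrt(2), divided by the pair mean, in percent.
#' Vectorised over pairs.
#'
#' @param x,y the two measurements (method A/B or visit 1/2).
#' @return CV in percent; `NA` where the pair mean is not positive.
#' @examples
#' cv_pair(8, 12)   # 100 * (4/sqrt(2)) / 10 = 28.28
#' @export
cv_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  m <- (x + y) / 2
  out <- 100 * (abs(x - y) / sqrt(2)) / m
  out[!is.finite(m) | m <= 0] <- NA_real_
  out
}

#' Paired measurements of one parameter under two methods or visits
#'
#' @param subject_ids identifier vector.
#' @param x,y values under method/visit A and B.
#' @param label parameter name carried through to reports.
#' @return An object of class `"paired_measurements"`.
#' @export
paired_measurements <- function(subject_ids, x, y, label = "") {
  if (length(x) != length(y) || length(x) != length(subject_ids))
    stop("'subject_ids', 'x' and 'y' must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in 'x'/'y'")
  structure(list(subject_ids = subject_ids, x = as.numeric(x),
                 y = as.numeric(y), label = label),
            class = "paired_measurements")
}

#' Bland-Altman agreement with per-subject CVs
#'
#' Per-subject percent differences d_i = 100 (x_i - y_i) / pair mean; the
#' bias is mean(d) and the 95% limits of agreement are
#' bias +/- 1.96 sd(d) (sample SD, n - 1). Pairs with non-positive mean are
#' excluded and counted. The report also carries the mean and range of the
#' per-subject [cv_pair()] values.
#'
#' @param pairs a [paired_measurements()].
#' @param mode `"percent"` (differences in percent of the pair mean,
#'   matching how agreement limits are reported for perfusion parameters) or
#'   `"absolute"` (raw differences x - y).
#' @return An object of class `"agreement_report"`: `label`, `mean_cv_pct`,
#'   `cv_range_pct` (min, max), `bias_pct`, `loa_low_pct`, `loa_high_pct`,
#'   `n_used`, `n_excluded`, `mode`.
#' @examples
#' p <- paired_measurements(1:3, c(10, 10, 10), c(10, 12, 14), "Fa")
#' bland_altman(p)
#' @export
bland_altman <- function(pairs, mode = c("percent", "absolute")) {
  stopifnot(inherits(pairs, "paired_measurements"))
  mode <- match.arg(mode)
  if (length(pairs$x) < 2L)
    stop("Bland-Altman needs at least 2 pairs")
  m <- (pairs$x + pairs$y) / 2
  keep <- m > 0
  n_excluded <- sum(!keep)
  x <- pairs$x[keep]; y <- pairs$y[keep]; m <- m[keep]
  if (length(x) < 2L)
    stop("fewer than 2 pairs with positive mean")
  d <- if (mode == "percent") 100 * (x - y) / m else x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  cvs <- cv_pair(x, y)
  structure(list(label = pairs$label,
                 mean_cv_pct = mean(cvs),
                 cv_range_pct = c(min = min(cvs), max = max(cvs)),
                 bias_pct = bias,
                 loa_low_pct = bias - 1.96 * sdd,
                 loa_high_pct = bias + 1.96 * sdd,
                 n_used = length(x), n_excluded = n_excluded,
                 mode = mode),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf(
    paste0("<agreement_report>%s n = %d (%d excluded)\n",
           "  mean CV %.2f%% (range %.2f-%.2f%%)\n",
           "  bias %.2f%s, 95%% limits of agreement [%.2f, %.2f]%s\n"),
    if (nzchar(x$label)) paste0(" ", x$label) else "", x$n_used,
    x$n_excluded, x$mean_cv_pct, x$cv_range_pct[["min"]],
    x$cv_range_pct[["max"]], x$bias_pct, unit,
    x$loa_low_pct, x$loa_high_pct, unit))
  invisible(x)
}

#' Test-retest CV summary across visits
#'
#' For each parameter column shared by the two visit tables, computes the
#' per-subject [cv_pair()] across visits and summarises it as mean and
#' (min, max) range — the layout used for test-retest reproducibility
#' tables.
#'
#' @param visit1,visit2 data frames with a `subject_id` column plus one
#'   numeric column per parameter; subjects must match across visits.
#' @return A data frame with columns `parameter`, `mean_cv`, `min_cv`,
#'   `max_cv` (all percent).
#' @export
test_retest_cv <- function(visit1, visit2) {
  stopifnot(is.data.frame(visit1), is.data.frame(visit2),
            "subject_id" %in% names(visit1),
            "subject_id" %in% names(visit2))
  unmatched <- c(setdiff(visit1$subject_id, visit2$subject_id),
                 setdiff(visit2$subject_id, visit1$subject_id))
  if (length(unmatched) > 0L)
    stop("unmatched subject(s) across visits: ",
         paste(unique(unmatched), collapse = ", "))
  visit2 <- visit2[match(visit1$subject_id, visit2$subject_id), , drop = FALSE]
  params <- setdiff(intersect(names(visit1), names(visit2)), "subject_id")
  if (length(params) == 0L) stop("no shared parameter columns")
  rows <- lapply(params, function(p) {
    cvs <- cv_pair(visit1[[p]], visit2[[p]])
    data.frame(parameter = p,
               mean_cv = mean(cvs, na.rm = TRUE),
               min_cv = min(cvs, na.rm = TRUE),
               max_cv = max(cvs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
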