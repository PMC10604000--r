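# Agreement and error statistics for validating measurement engines against
# human raters: ICC(2,1) with F-based confidence interval and the customary
# classification, Bland-Altman limits of agreement, and absolute-error
# summaries (MAE, SD of AE, Pearson r, R^2).

#' Create a rater table
#'
#' Cases x raters matrix of one parameter measured by several raters. Cases
#' with any missing value are dropped listwise (the dropped count is kept as
#' an attribute).
#'
#' @param values Numeric matrix or data frame, one row per case, one column
#'   per rater.
#' @param case_ids Optional case identifiers (default: row numbers).
#' @param rater_ids Optional rater identifiers (default: column names or
#'   `rater1..k`).
#' @return An object of class `rater_table`.
#' @export
rater_table <- function(values, case_ids = NULL, rater_ids = NULL) {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  if (is.null(rater_ids)) {
    rater_ids <- if (!is.null(colnames(x))) colnames(x) else paste0("rater", seq_len(ncol(x)))
  }
  if (is.null(case_ids)) {
    case_ids <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x)))
  }
  complete <- stats::complete.cases(x)
  dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  case_ids <- case_ids[complete]
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("a rater table needs at least 2 complete cases and 2 raters")
  }
  dimnames(x) <- list(case_ids, rater_ids)
  if (dropped > 0) {
    message(sprintf("rater_table: dropped %d case(s) with missing values", dropped))
  }
  structure(list(values = x, case_ids = case_ids, rater_ids = rater_ids,
                 dropped_cases = dropped),
            class = "rater_table")
}

#' Read a rater table from CSV
#'
#' Wide format: a `case_id` column (first column) followed by one numeric
#' column per rater.
#'
#' @param path CSV path.
#' @return A `rater_table`.
#' @export
read_rater_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rater_table(tab[, -1, drop = FALSE], case_ids = as.character(tab[[1]]))
}

#' @export
print.rater_table <- function(x, ...) {
  cat(sprintf("<rater_table> %d cases x %d raters (%s)\n", nrow(x$values),
              ncol(x$values), paste(x$rater_ids, collapse = ", ")))
  invisible(x)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' The intraclass correlation for interchangeable raters, computed from the
#' two-way ANOVA mean squares as
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the 95%
#' confidence interval by the Shrout-Fleiss F-distribution method and the
#' p value from the F test of between-case variance (`MSR/MSE` on
#' `n-1, (n-1)(k-1)` df). Because the form penalizes systematic rater bias,
#' it is bounded above by the Pearson correlation of biased raters.
#'
#' @param table A `rater_table` (or a bare n x k matrix).
#' @param conf_level Confidence level, default 0.95.
#' @return List with `icc`, `ci95` (length-2), `p_value`, `classification`,
#'   and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  x <- if (inherits(table, "rater_table")) table$values else as.matrix(table)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("ICC needs at least 2 cases and 2 raters")
  gm <- mean(x)
  if (sum((x - gm)^2) < 1e-24) {
    .stop_cls("ICC undefined: zero total variance", "spinalign_undefined_icc")
  }
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((x - gm)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  fv <- msr / mse
  p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fu <- stats::qf(1 - alpha / 2, n - 1, v)
  fl <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fu * mse) / (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fl * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fl * msr)
  list(icc = icc, ci95 = c(lower, upper), p_value = p,
       classification = classify_icc(icc), msr = msr, msc = msc, mse = mse)
}

#' Classify an ICC value
#'
#' The customary cut-points: poor (< 0.40), fair (0.40-0.60), good
#' (0.60-0.75), excellent (0.75-1.00). A value equal to a cut-point takes the
#' higher label.
#'
#' @param icc ICC value (<= 1).
#' @return One of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
classify_icc <- function(icc) {
  stopifnot(is.numeric(icc), icc <= 1 + 1e-12)
  cuts <- c(0.40, 0.60, 0.75)
  labels <- c("poor", "fair", "good", "excellent")
  labels[findInterval(icc, cuts) + 1]
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference summary: bias = mean difference, limits of agreement =
#' bias +/- 1.96 sample SD of the differences.
#'
#' @param a,b Paired measurement vectors of equal length (>= 2); differences
#'   are `a - b`.
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    .stop_cls("Bland-Altman needs paired vectors of equal length", "spinalign_paired_data")
  }
  if (length(a) < 2) .stop_cls("Bland-Altman needs at least 2 pairs", "spinalign_paired_data")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Absolute-error and correlation summaries
#'
#' MAE = mean absolute difference, STD of AE = sample SD of the absolute
#' differences, Pearson correlation, and its square.
#'
#' @param a,b Paired measurement vectors of equal length (>= 3).
#' @return List with `mae`, `std_ae`, `pearson_r`, `r_squared`.
#' @export
error_stats <- function(a, b) {
  if (length(a) != length(b)) {
    .stop_cls("error_stats needs paired vectors of equal length", "spinalign_paired_data")
  }
  if (length(a) < 3) .stop_cls("error_stats needs at least 3 pairs", "spinalign_paired_data")
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    .stop_cls("correlation undefined for a zero-variance vector", "spinalign_undefined_correlation")
  }
  ae <- abs(a - b)
  r <- stats::cor(a, b)
  list(mae = mean(ae), std_ae = stats::sd(ae), pearson_r = r, r_squared = r^2)
}

#' Agreement report against a reference rater
#'
#' For each non-reference rater: the pairwise ICC(2,1) with CI, p value and
#' classification, Bland-Altman bias and limits of agreement (reference minus
#' rater), and the absolute-error summaries; plus the pooled ICC over all
#' raters.
#'
#' @param table A `rater_table`.
#' @param reference_rater Id (or index) of the reference rater.
#' @return An object of class `agreement_report`: data frame with one row per
#'   compared rater; the pooled ICC is in `attr(, "pooled_icc")`, the number
#'   of listwise-dropped cases in `attr(, "dropped_cases")`.
#' @export
agreement_report <- function(table, reference_rater = 1) {
  stopifnot(inherits(table, "rater_table"))
  x <- table$values
  ids <- table$rater_ids
  ref <- if (is.character(reference_rater)) match(reference_rater, ids) else as.integer(reference_rater)
  if (is.na(ref) || ref < 1 || ref > ncol(x)) stop("reference rater not found in the table")
  others <- setdiff(seq_len(ncol(x)), ref)
  rows <- lapply(others, function(j) {
    ic <- icc_2_1(x[, c(ref, j)])
    ba <- bland_altman(x[, ref], x[, j])
    es <- error_stats(x[, ref], x[, j])
    data.frame(rater = ids[j], reference = ids[ref],
               icc = ic$icc, ci_low = ic$ci95[1], ci_high = ic$ci95[2],
               p_value = ic$p_value, classification = ic$classification,
               mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               mae = es$mae, std_ae = es$std_ae,
               pearson_r = es$pearson_r, r_squared = es$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- icc_2_1(x)
  attr(out, "pooled_icc") <- pooled
  attr(out, "n_cases") <- nrow(x)
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  pooled <- attr(x, "pooled_icc")
  cat(sprintf("Agreement vs reference '%s' over %d cases (pooled ICC %.3f, %s):\n",
              x$reference[1], attr(x, "n_cases"), pooled$icc, pooled$classification))
  df <- data.frame(rater = x$rater,
                   icc = round(x$icc, digits),
                   ci = sprintf("[%.2f, %.2f]", x$ci_low, x$ci_high),
                   class = x$classification,
                   bias = round(x$mean_diff, digits),
                   mae = round(x$mae, digits),
                   r = round(x$pearson_r, digits),
                   r2 = round(x$r_squared, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
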