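# Diagnostic-accuracy statistics: 2x2 metrics with exact fractions, ROC/AUC,
# DeLong variance and paired test, Cohen's kappa, Pearson chi-square.

#' Round a fraction to a one-decimal percentage (half up)
#'
#' Display convention for report tables: `round_percent(72, 104)` is `69.2`.
#' Rounding is *half up* on the exact rational (computed in integer
#' arithmetic, so `round_percent(1, 16)` is `6.3`, never subject to binary
#' floating-point ties).
#'
#' @param numerator,denominator Integer vectors; `denominator > 0`.
#' @return Numeric vector of percentages with one decimal.
#' @export
round_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  num <- as.numeric(numerator) * 1000
  q <- num %/% denominator
  r <- num %% denominator
  (q + (2 * r >= denominator)) / 10
}

#' Build a 2x2 confusion table
#'
#' Malignant is the positive class throughout the package.
#'
#' @param predicted_positive Logical vector: test positive.
#' @param truth_malignant Logical vector of the same length: lesion malignant.
#' @return A `confusion_table`: list with integer cells `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
build_confusion <- function(predicted_positive, truth_malignant) {
  p <- as.logical(predicted_positive)
  t <- as.logical(truth_malignant)
  if (length(p) != length(t)) stop("length mismatch", call. = FALSE)
  if (length(p) < 1L) stop("empty input", call. = FALSE)
  if (anyNA(p) || anyNA(t)) stop("NA in predictions or truth", call. = FALSE)
  confusion_table(sum(p & t), sum(p & !t), sum(!p & t), sum(!p & !t))
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn Non-negative integer cell counts (used to reconstruct
#'   published tables directly).
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(cells) || any(cells < 0)) stop("cells must be non-negative", call. = FALSE)
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              truth = c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Diagnostic metrics from a confusion table
#'
#' Sensitivity, specificity, accuracy, PPV and NPV, each kept as an exact
#' fraction (numerator, denominator) alongside the one-decimal percent
#' display value of [round_percent()]. A metric whose denominator is zero is
#' reported as undefined (`NA`), never as 0.
#'
#' @param x A `confusion_table`.
#' @return A `metric_set`: data frame with columns `metric`, `numerator`,
#'   `denominator`, `value` (exact fraction as numeric) and `percent`.
#' @examples
#' confusion_metrics(confusion_table(tp = 72, fp = 28, fn = 32, tn = 91))
#' @export
confusion_metrics <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  n <- x$tp + x$fp + x$fn + x$tn
  num <- c(sensitivity = x$tp, specificity = x$tn, accuracy = x$tp + x$tn,
           ppv = x$tp, npv = x$tn)
  den <- c(sensitivity = x$tp + x$fn, specificity = x$tn + x$fp, accuracy = n,
           ppv = x$tp + x$fp, npv = x$tn + x$fn)
  defined <- den > 0L
  out <- data.frame(
    metric = names(num), numerator = unname(num), denominator = unname(den),
    value = ifelse(defined, unname(num) / unname(den), NA_real_),
    percent = NA_real_, stringsAsFactors = FALSE, row.names = NULL
  )
  out$percent[defined] <- round_percent(out$numerator[defined],
                                        out$denominator[defined])
  class(out) <- c("metric_set", "data.frame")
  out
}

# --- ROC / AUC ---------------------------------------------------------------

#' @keywords internal
.split_classes <- function(scores, truth) {
  t <- as.logical(truth)
  if (length(scores) != length(t)) stop("length mismatch", call. = FALSE)
  if (anyNA(scores) || anyNA(t)) stop("NA in scores or truth", call. = FALSE)
  if (!any(t) || all(t)) {
    stop("both classes must be present to form a ROC curve", call. = FALSE)
  }
  list(pos = scores[t], neg = scores[!t])
}

#' ROC operating points for an ordinal score
#'
#' Operating points use the convention "positive iff score > c", malignant
#' being the positive class, with one point per distinct observed score plus
#' the (0,0) and (1,1) endpoints. Points are monotone non-decreasing in both
#' coordinates.
#'
#' @param scores Numeric/integer vector.
#' @param truth Logical vector (`TRUE` = malignant) or anything coercible.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth) {
  cl <- .split_classes(scores, truth)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(c) mean(cl$neg > c), numeric(1)),
    tpr = vapply(thr, function(c) mean(cl$pos > c), numeric(1))
  )
}

#' Nonparametric (Mann-Whitney) AUC with midrank tie handling
#'
#' Equals the pairwise statistic \eqn{\frac{1}{mn}\sum_i\sum_j
#' \psi(x_i, y_j)} over malignant scores \eqn{x} and benign scores \eqn{y},
#' with \eqn{\psi = 1} when \eqn{x > y}, \eqn{0.5} on ties and 0 otherwise,
#' and also equals the trapezoidal area under [roc_points()]. Ties are
#' frequent on an 11-level ordinal score, hence the midrank convention.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, truth) {
  cl <- .split_classes(scores, truth)
  m <- length(cl$pos); n <- length(cl$neg)
  r <- rank(c(cl$pos, cl$neg))            # midranks
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc Data frame from [roc_points()].
#' @return Numeric area; equals [auc_mann_whitney()] on the same data.
#' @export
auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' DeLong structural components of the AUC
#'
#' For malignant scores \eqn{x_1..x_m} and benign scores \eqn{y_1..y_n},
#' the structural components are \eqn{V10_i = \frac1n\sum_j \psi(x_i,y_j)}
#' and \eqn{V01_j = \frac1m\sum_i \psi(x_i,y_j)}; the AUC variance estimate
#' is \eqn{S_{10}/m + S_{01}/n} with \eqn{S} the sample variances.
#'
#' @inheritParams roc_points
#' @return List with `auc`, `var`, and the component vectors `v10`, `v01`.
#' @export
delong_components <- function(scores, truth) {
  cl <- .split_classes(scores, truth)
  m <- length(cl$pos); n <- length(cl$neg)
  if (m < 2L || n < 2L) {
    stop("need at least 2 observations in each class", call. = FALSE)
  }
  sy <- sort(cl$neg)
  v10 <- vapply(cl$pos, function(x) {
    (sum(sy < x) + 0.5 * sum(sy == x)) / n
  }, numeric(1))
  sx <- sort(cl$pos)
  v01 <- vapply(cl$neg, function(y) {
    (sum(sx > y) + 0.5 * sum(sx == y)) / m
  }, numeric(1))
  auc <- mean(v10)
  list(auc = auc, var = stats::var(v10) / m + stats::var(v01) / n,
       v10 = v10, v01 = v01)
}

#' AUC with DeLong standard error and normal confidence interval
#'
#' @inheritParams roc_points
#' @param conf_level Confidence level for the interval.
#' @return An `auc_estimate`: list with `auc`, `se`, `ci` (truncated to
#'   \[0, 1\]) and `n_pos`, `n_neg`.
#' @export
auc_estimate <- function(scores, truth, conf_level = 0.95) {
  d <- delong_components(scores, truth)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(d$var)
  structure(
    list(auc = d$auc, se = se,
         ci = c(max(0, d$auc - z * se), min(1, d$auc + z * se)),
         n_pos = length(d$v10), n_neg = length(d$v01)),
    class = "auc_estimate"
  )
}

#' @export
print.auc_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("AUC %.*f (95%% CI %.*f-%.*f), DeLong SE %.*f\n",
              digits, x$auc, digits, x$ci[1], digits, x$ci[2], digits, x$se))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same lesions. The
#' covariance of the two AUC estimates is obtained from the paired structural
#' components; the test statistic \eqn{z = (AUC_1 - AUC_2)/\sqrt{v_1 + v_2 -
#' 2c}} is referred to the standard normal (two-sided). Swapping the two
#' score vectors negates `z` and leaves `p` unchanged. When the variance of
#' the difference is zero and the AUCs are equal (e.g. identical scores) the
#' result is `z = 0`, `p = 1`; a zero variance with unequal AUCs is an error.
#'
#' @param scores1,scores2 Score vectors on the same lesions.
#' @param truth Logical truth vector (`TRUE` = malignant).
#' @return A `paired_auc_test`: list with `auc1`, `auc2`, `var1`, `var2`,
#'   `covariance`, `z`, `p`.
#' @export
delong_paired_test <- function(scores1, scores2, truth) {
  if (length(scores1) != length(scores2)) stop("length mismatch", call. = FALSE)
  d1 <- delong_components(scores1, truth)
  d2 <- delong_components(scores2, truth)
  m <- length(d1$v10); n <- length(d1$v01)
  cv <- stats::cov(d1$v10, d2$v10) / m + stats::cov(d1$v01, d2$v01) / n
  vd <- d1$var + d2$var - 2 * cv
  delta <- d1$auc - d2$auc
  if (vd <= .Machine$double.eps^0.5) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      stop("degenerate comparison: zero variance with unequal AUCs",
           call. = FALSE)
    }
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc1 = d1$auc, auc2 = d2$auc, var1 = d1$var, var2 = d2$var,
         covariance = cv, z = z, p = p),
    class = "paired_auc_test"
  )
}

#' @export
print.paired_auc_test <- function(x, digits = 3, ...) {
  cat(sprintf("DeLong paired AUC test: %.*f vs %.*f, z = %.*f, p = %.4g\n",
              digits, x$auc1, digits, x$auc2, digits, x$z, x$p))
  invisible(x)
}

# --- Agreement ---------------------------------------------------------------

#' Cohen's kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between
#' two readings of the same items. The standard error is the large-sample
#' estimate of Fleiss, Cohen and Everitt for the point estimate (not the null
#' SE), giving the interval \eqn{\kappa \pm 1.96\,SE}. Agreement bands follow
#' the convention used for reader studies: below 0.4 bad, 0.4 to 0.7 good,
#' above 0.7 excellent. Two raters that are constant and identical (chance
#' agreement 1) are assigned \eqn{\kappa = 1}.
#'
#' @param ratings1,ratings2 Vectors of categorical ratings (equal length,
#'   at least 2 items). Symmetric in its two arguments.
#' @return A `kappa_estimate`: list with `kappa`, `se`, `ci` and `band`.
#' @export
cohen_kappa <- function(ratings1, ratings2) {
  r1 <- as.character(ratings1); r2 <- as.character(ratings2)
  if (length(r1) != length(r2)) stop("length mismatch", call. = FALSE)
  n <- length(r1)
  if (n < 2L) stop("need at least 2 rated items", call. = FALSE)
  lev <- sort(unique(c(r1, r2)))
  tab <- table(factor(r1, lev), factor(r2, lev)) / n
  po <- sum(diag(tab))
  pr <- rowSums(tab); pc <- colSums(tab)
  pe <- sum(pr * pc)
  if (1 - pe < .Machine$double.eps^0.5) {
    kap <- 1; se <- 0
  } else {
    kap <- (po - pe) / (1 - pe)
    # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
    k <- length(lev)
    a <- 0
    for (i in seq_len(k)) {
      a <- a + tab[i, i] * ((1 - pe) - (pr[i] + pc[i]) * (1 - po))^2
    }
    b <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) b <- b + tab[i, j] * (pc[i] + pr[j])^2
    }
    b <- (1 - po)^2 * b
    cc <- (po * pe - 2 * pe + po)^2
    se <- sqrt(max(0, a + b - cc) / (n * (1 - pe)^4))
  }
  band <- if (kap < 0.4) "bad" else if (kap <= 0.7) "good" else "excellent"
  structure(
    list(kappa = as.numeric(kap), se = as.numeric(se),
         ci = c(kap - 1.96 * se, kap + 1.96 * se), band = band),
    class = "kappa_estimate"
  )
}

#' @export
print.kappa_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Cohen's kappa %.*f (95%% CI %.*f-%.*f), agreement: %s\n",
              digits, x$kappa, digits, x$ci[1], digits, x$ci[2], x$band))
  invisible(x)
}

# --- Proportions -------------------------------------------------------------

#' Pearson chi-square comparison of two proportions (2x2)
#'
#' Wraps `stats::chisq.test` with the continuity correction OFF by default:
#' published two-sided p-values for reader-study subgroup comparisons are
#' reproduced by the uncorrected Pearson statistic. A table with a zero row
#' or column marginal leaves the test undefined and raises an error.
#'
#' @param table A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` filled row-wise.
#' @param correct Apply the Yates continuity correction.
#' @return A `proportion_comparison`: list with `chi2`, `df = 1`, `p`.
#' @examples
#' chi2_2x2(c(65, 14, 26, 14))  # p ~= 0.036
#' @export
chi2_2x2 <- function(table, correct = FALSE) {
  if (!is.matrix(table)) {
    stopifnot(length(table) == 4L)
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (anyNA(table) || any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(table) < 1) stop("empty table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("undefined test: zero row or column marginal", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  structure(
    list(chi2 = unname(ht$statistic), df = 1L, p = unname(ht$p.value)),
    class = "proportion_comparison"
  )
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4g, df = 1, p = %.4g\n", x$chi2, x$p))
  invisible(x)
}
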