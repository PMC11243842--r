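#' Multi-class confusion matrix
#'
#' Cross-tabulates true against predicted stress classes; rows are the true
#' labels, columns the predicted ones.
#'
#' @param truth,predicted Vectors (character or factor) of equal positive
#'   length over the same label set.
#' @param labels Ordered label set; defaults to Calm/Normal/Stressed.
#' @return A `labels x labels` integer matrix of class `"confusion_matrix"`.
#' @examples
#' confusion(c("Calm", "Calm", "Normal"), c("Calm", "Stressed", "Normal"))
#' @export
confusion <- function(truth, predicted, labels = stress_labels()) {
  if (length(truth) != length(predicted) || length(truth) == 0)
    stop("truth and predicted must have equal positive length")
  truth <- as.character(truth); predicted <- as.character(predicted)
  bad <- unique(c(setdiff(truth, labels), setdiff(predicted, labels)))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = labels),
             factor(predicted, levels = labels))
  out <- matrix(as.integer(m), nrow = length(labels),
                dimnames = list(true = labels, predicted = labels))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class one-vs-rest performance metrics
#'
#' Treats each class in turn as positive and the rest as negative, giving
#' per-class TP/TN/FP/FN, then sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, accuracy `(TP+TN)/N`, and F1, the
#' harmonic mean of precision and sensitivity. A metric whose denominator is
#' zero is reported as `NA`, never as 0.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with one row per class and columns `class`, `tp`,
#'   `tn`, `fp`, `fn`, `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `f1`.
#' @examples
#' cm <- confusion(rep(c("Calm", "Normal"), c(5, 5)),
#'                 rep(c("Calm", "Normal"), c(6, 4)))
#' per_class_metrics(cm)
#' @export
per_class_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    if (!is.matrix(cm) || nrow(cm) != ncol(cm))
      stop("cm must be a square confusion matrix")
  }
  cm <- unclass(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  labels <- rownames(cm)
  rows <- lapply(seq_along(labels), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    p <- safe_div(tp, tp + fp)
    s <- safe_div(tp, tp + fn)
    data.frame(class = labels[i], tp = tp, tn = tn, fp = fp, fn = fn,
               sensitivity = s,
               specificity = safe_div(tn, tn + fp),
               precision = p,
               accuracy = (tp + tn) / n,
               f1 = f1_score(p, s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

safe_div <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 * P * S / (P + S)`; `NA` if either input is `NA` or
#' both are zero.
#'
#' @param precision,sensitivity Values in `[0, 1]`; vectorised.
#' @return F1 in `[0, 1]` or `NA`.
#' @examples
#' f1_score(0.88, 0.82)  # 0.85 to 2 d.p.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(is.na(precision) | is.na(sensitivity) |
           (precision + sensitivity) == 0,
         NA_real_,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Pearson and Spearman correlation of two series
#'
#' Convenience wrapper reporting both coefficients and the sample size.
#' A constant series makes Pearson undefined; it is reported as `NA` with
#' `constant = TRUE`. Spearman uses midranks for ties.
#'
#' @param a,b Numeric vectors of equal length >= 3, finite.
#' @return List with `pearson`, `spearman`, `n`, `constant`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)  # pearson 1
#' @export
correlate <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("need two equal-length series of at least 3 values")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("invalid input: non-finite values")
  constant <- stats::sd(a) == 0 || stats::sd(b) == 0
  pearson <- if (constant) NA_real_ else stats::cor(a, b)
  spearman <- if (constant) NA_real_ else
    stats::cor(a, b, method = "spearman")
  list(pearson = pearson, spearman = spearman, n = length(a),
       constant = constant)
}

#' Correlation report for the stress / glucose / blood-pressure triple
#'
#' Computes [correlate()] for the three pairs examined in the protocol
#' analyses: stress-glucose, glucose-BP (systolic and diastolic) and
#' stress-BP.
#'
#' @param records A protocol data frame (see [generate_protocol_data()])
#'   containing `glucose`, `sbp`, `dbp` and a stress column.
#' @param stress_col Column holding the stress level: the numeric `score`
#'   from [predict.stress_fis()] or the latent class (coerced 1-3).
#' @return Data frame with one row per pair and columns `pair`, `pearson`,
#'   `spearman`, `n`.
#' @export
correlation_report <- function(records, stress_col = "score") {
  s <- records[[stress_col]]
  if (is.null(s)) stop("no column '", stress_col, "' in records")
  if (is.factor(s) || is.character(s))
    s <- as.integer(factor(as.character(s), levels = stress_labels()))
  pairs <- list(stress_glucose = list(s, records$glucose),
                glucose_sbp = list(records$glucose, records$sbp),
                glucose_dbp = list(records$glucose, records$dbp),
                stress_sbp = list(s, records$sbp),
                stress_dbp = list(s, records$dbp))
  rows <- lapply(names(pairs), function(nm) {
    r <- correlate(pairs[[nm]][[1]], pairs[[nm]][[2]])
    data.frame(pair = nm, pearson = r$pearson, spearman = r$spearman,
               n = r$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
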