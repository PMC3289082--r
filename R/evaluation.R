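#' ROC curve and AUC for charge-state scores
#'
#' Sweeps a threshold over the unique score values with the +3 charge state
#' as the positive class. Tied scores are grouped at a single threshold, so
#' the trapezoidal area equals the two-sample rank (Mann-Whitney) statistic
#' scaled to `[0, 1]`: concordant pairs plus half the ties over all
#' positive-negative pairs.
#'
#' @param scores Numeric vector, larger meaning more +3-like (e.g. the
#'   posterior probability of +3).
#' @param labels Integer vector of true charges (2 or 3), same length.
#' @return An object of class `roc_result`: `points` (data frame of `fpr`,
#'   `tpr`, starting at (0,0) and ending at (1,1)), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(3, 3, 2, 2))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(2L, 3L)))
  pos <- labels == 3L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both charge classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  # group ties: cut after the last member of each tied run
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_run]
  fp <- cumsum(!p)[last_of_run]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positive, %d negative, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Single-feature discriminant power
#'
#' AUC of each feature column used alone as the score, orientation-corrected
#' (`max(auc, 1 - auc)`) so a discriminant feature scores above 0.5
#' whichever charge class it favours; the orientation is reported alongside.
#'
#' @param matrix A `feature_matrix` (see [build_feature_matrix()]) or a
#'   plain numeric matrix with column names.
#' @param labels True charges (2 or 3), one per row.
#' @return Data frame with columns `feature`, `auc`, `orientation`
#'   (`"+3-high"` when larger values indicate +3).
#' @export
per_feature_auc <- function(matrix, labels) {
  m <- if (inherits(matrix, "feature_matrix")) matrix$scaled else as.matrix(matrix)
  stopifnot(nrow(m) == length(labels), !is.null(colnames(m)))
  rows <- lapply(colnames(m), function(f) {
    a <- roc_auc(m[, f], labels)$auc
    data.frame(feature = f,
               auc = max(a, 1 - a),
               orientation = if (a >= 0.5) "+3-high" else "+3-low",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-class feature means and expected-direction check
#'
#' Mean of each (scaled) feature within the +2 and +3 classes, with a
#' pass/fail check of the expected inequality for that feature: the
#' complementary-pair features should be larger for +2, the doubly charged
#' regional intensity and basic-site pseudo-count larger for +3.
#'
#' @inheritParams per_feature_auc
#' @return Data frame with columns `feature`, `mean_plus2`, `mean_plus3`,
#'   `expected`, `pass`.
#' @export
class_mean_report <- function(matrix, labels) {
  m <- if (inherits(matrix, "feature_matrix")) matrix$scaled else as.matrix(matrix)
  stopifnot(nrow(m) == length(labels), all(labels %in% c(2L, 3L)),
            !is.null(colnames(m)))
  if (length(unique(labels)) < 2) stop("both charge classes must be present")
  m2 <- colMeans(m[labels == 2L, , drop = FALSE])
  m3 <- colMeans(m[labels == 3L, , drop = FALSE])
  dirs <- .feature_directions[colnames(m)]
  expected <- ifelse(is.na(dirs), NA_character_,
                     ifelse(dirs > 0, "+2 > +3", "+2 < +3"))
  pass <- ifelse(is.na(dirs), NA, ifelse(dirs > 0, m2 > m3, m2 < m3))
  data.frame(
    feature = colnames(m), mean_plus2 = unname(m2), mean_plus3 = unname(m3),
    expected = unname(expected), pass = unname(pass),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
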