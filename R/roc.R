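#' Pooled ROC curve with AUC and equal error rate
#'
#' Builds the receiver operating characteristic from pooled scores, with
#' higher scores predicting the positive class. Thresholds are placed at
#' every distinct score; tied scores form diagonal ROC segments. The AUC is
#' computed by midrank pair counting (the probability a random positive
#' outscores a random negative, ties counting one half), which equals the
#' trapezoidal area under the curve exactly. The EER is the error rate at
#' the operating point where the false-positive rate equals the
#' false-negative rate, linearly interpolated between adjacent ROC vertices.
#'
#' @param scored A data frame with numeric `score` and logical `truth`
#'   columns (e.g. from [run_iterated()]), or a numeric vector of scores if
#'   `truth` is supplied separately.
#' @param truth Optional logical vector when `scored` is a numeric vector.
#' @return A `conc_roc` object: `points` (tibble of `fpr`, `tpr`,
#'   `threshold`), `auc`, `eer`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- pooled_roc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc  # 1: perfect separation
pooled_roc <- function(scored, truth = NULL) {
  if (is.data.frame(scored)) {
    score <- scored$score
    truth <- scored$truth
  } else {
    score <- scored
  }
  if (is.null(truth) || length(truth) != length(score)) {
    abort("`truth` must accompany every score.")
  }
  if (!any(truth) || all(truth)) {
    abort("ROC needs at least one positive and one negative score.")
  }
  if (any(!is.finite(score))) abort("Scores must be finite.")
  n_pos <- sum(truth)
  n_neg <- sum(!truth)

  # midrank pair counting: P(score+ > score-) + 0.5 P(tie)
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # curve: sweep thresholds over distinct scores, descending
  ord <- order(score, decreasing = TRUE)
  s_sorted <- score[ord]
  t_sorted <- truth[ord]
  grp <- cumsum(!duplicated(s_sorted))
  tp <- cumsum(t_sorted)
  fp <- cumsum(!t_sorted)
  last <- which(!duplicated(grp, fromLast = TRUE))
  points <- tibble::tibble(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos),
    threshold = c(Inf, s_sorted[last])
  )

  structure(
    list(points = points, auc = auc, eer = roc_eer(points),
         n_pos = n_pos, n_neg = n_neg),
    class = "conc_roc"
  )
}

# EER: crossing of fpr = 1 - tpr along the piecewise-linear curve
roc_eer <- function(points) {
  g <- points$fpr - (1 - points$tpr)     # increases monotonically -1 -> +1
  i <- which(g >= 0)[1]
  if (i == 1) return(points$fpr[1])
  lambda <- -g[i - 1] / (g[i] - g[i - 1])
  points$fpr[i - 1] + lambda * (points$fpr[i] - points$fpr[i - 1])
}

#' @export
print.conc_roc <- function(x, ...) {
  cat(sprintf("<roc> AUC %.3f  EER %.3f  (%d positives, %d negatives)\n",
              x$auc, x$eer, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.conc_roc <- function(x, ...) x$points

#' @export
glance.conc_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, eer = x$eer, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.conc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::annotate("point", x = object$eer, y = 1 - object$eer,
                      shape = 21, fill = "white", colour = "#d95f02") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("AUC %.3f, EER %.3f", object$auc, object$eer)
    ) +
    ggplot2::theme_minimal()
}
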