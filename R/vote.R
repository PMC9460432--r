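# Three-channel majority-vote label correction.
#
# Each 1.8 s sample is predicted independently on FP1, FP2 and FZ; the
# sample-level label is the one at least two channels agree on. A
# three-way disagreement gets the explicit code 0 and always scores as
# wrong.

#' Majority vote over the three channel predictions of one sample
#'
#' @param labels integer vector of exactly 3 labels, each in 1..3
#'   (ordered FP1, FP2, FZ; the vote is permutation-invariant).
#' @return the label occurring at least twice, or 0 when all three
#'   disagree.
#' @examples
#' majority_vote(c(1, 2, 1))  # 1
#' majority_vote(c(3, 1, 2))  # 0
#' @export
majority_vote <- function(labels) {
  if (length(labels) != 3L) stop("majority_vote expects exactly 3 labels")
  if (any(!labels %in% 1:3)) stop("labels must lie in {1, 2, 3}")
  tab <- tabulate(labels, nbins = 3L)
  if (max(tab) >= 2L) which.max(tab) else 0L
}

#' Build the per-sample voted prediction table
#'
#' @param sample_id,channel,pred_label,real_label parallel vectors, one
#'   entry per channel row (three rows per sample).
#' @return data frame `sample_id, channel, pred_label, vote_label,
#'   real_label` mirroring the published results layout.
#' @export
vote_predictions <- function(sample_id, channel, pred_label, real_label) {
  df <- data.frame(sample_id = sample_id, channel = channel,
                   pred_label = as.integer(pred_label),
                   real_label = as.integer(real_label),
                   stringsAsFactors = FALSE)
  votes <- tapply(df$pred_label, df$sample_id, function(v) majority_vote(v))
  df$vote_label <- as.integer(votes[as.character(df$sample_id)])
  df[, c("sample_id", "channel", "pred_label", "vote_label", "real_label")]
}

#' Voted per-sample classification accuracy
#'
#' Percentage of samples whose voted label equals the true label; votes of
#' 0 (three-way disagreement) always count as wrong.
#'
#' @param predictions table from [vote_predictions()].
#' @return accuracy in percent.
#' @export
corrected_accuracy <- function(predictions) {
  if (!nrow(predictions)) stop("empty predictions table")
  per_sample <- !duplicated(predictions$sample_id)
  ps <- predictions[per_sample, ]
  100 * mean(ps$vote_label == ps$real_label)
}

#' Per-class confusion matrix with true-positive rates
#'
#' @param true,pred integer label vectors.
#' @param n_classes number of classes.
#' @return list with `matrix` (rows = true, cols = predicted; an extra
#'   column 0 appears if any prediction is the disagreement code) and
#'   `tpr` (per-class true-positive rate, percent).
#' @export
confusion_matrix <- function(true, pred, n_classes = 3) {
  lev <- sort(unique(c(seq_len(n_classes), pred)))
  m <- table(factor(true, levels = seq_len(n_classes)),
             factor(pred, levels = lev))
  tpr <- 100 * diag(m[, as.character(seq_len(n_classes)), drop = FALSE]) /
    pmax(rowSums(m), 1)
  list(matrix = m, tpr = tpr)
}
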