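# Applicability domain for the QSAR ensemble: a reliability-density score in
# fingerprint-similarity space. Each query accumulates kernel-weighted
# evidence from training compounds that were predicted correctly under
# cross-validation; dense, well-predicted neighborhoods give high
# reliability, sparse or poorly-predicted ones give low reliability. The
# score is an unnormalized kernel sum, so adding a nearby correctly-predicted
# neighbor can never lower it.

#' Reliability-density applicability-domain score
#'
#' For query `q`, `reliability(q) = sum_i K(1 - sim(q, i)) * correct_i`
#' over training compounds `i`, where `sim` is Tanimoto similarity on the
#' Morgan-fingerprint block, `K` a Gaussian kernel with bandwidth
#' `bandwidth`, and `correct_i` the out-of-fold CV correctness from
#' [cv_correctness()]. Training compounds sharing no on-bit with the query
#' contribute nothing; a query with zero kernel support scores 0.
#'
#' @param train_fp binary fingerprint matrix of the training set.
#' @param correct logical CV-correctness per training row.
#' @param query_fp binary fingerprint matrix of the queries.
#' @param bandwidth Gaussian kernel bandwidth on Tanimoto distance
#'   (default 0.25).
#' @return numeric reliability per query row (>= 0).
#' @export
rdn_reliability <- function(train_fp, correct, query_fp, bandwidth = 0.25) {
  if (is.null(dim(train_fp)) || nrow(train_fp) == 0) stop("empty training set")
  stopifnot(length(correct) == nrow(train_fp),
            ncol(train_fp) == ncol(query_fp), bandwidth > 0)
  inter <- query_fp %*% t(train_fp)
  union <- outer(rowSums(query_fp), rowSums(train_fp), "+") - inter
  sim <- ifelse(union > 0, inter / union, 0)
  w <- exp(-(1 - sim)^2 / (2 * bandwidth^2))
  w[sim <= 0] <- 0
  as.vector(w %*% as.numeric(correct))
}

#' Precision/coverage trade-off across applicability-domain cutoffs
#'
#' At each cutoff, keeps predictions with reliability at or above the
#' cutoff and reports the precision for actives among accepted predicted
#' actives and the accepted fraction (coverage).
#'
#' @param predictions data.frame from [predict_majority()] with an added
#'   `reliability` column.
#' @param labels true labels aligned to `predictions`.
#' @param cutoffs non-empty numeric cutoff grid.
#' @return data.frame: `cutoff`, `coverage`, `n_accepted`,
#'   `precision_active` (`NA` when no accepted predicted actives).
#' @export
ad_curve <- function(predictions, labels, cutoffs) {
  if (length(cutoffs) == 0) stop("empty cutoff grid")
  stopifnot("reliability" %in% names(predictions),
            nrow(predictions) == length(labels))
  rows <- lapply(cutoffs, function(cut) {
    acc <- predictions$reliability >= cut
    pa <- acc & predictions$predicted_label == "active"
    data.frame(cutoff = cut, coverage = mean(acc), n_accepted = sum(acc),
               precision_active = if (any(pa)) mean(labels[pa] == "active")
               else NA_real_)
  })
  do.call(rbind, rows)
}
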