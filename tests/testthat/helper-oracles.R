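# Independent brute-force oracles. These deliberately re-derive each
# quantity by explicit enumeration/counting, sharing no code with the
# package implementations they check.

# count contacts per residue over the top-n poses by explicit loops
oracle_robust_plif <- function(table, top_n, min_poses, vocab) {
  sc <- table$scores
  ord <- order(-sc$score, sc$pose_index)
  top <- sc$pose_index[ord][1:top_n]
  bits <- integer(length(vocab))
  for (v in seq_along(vocab)) {
    n <- 0L
    for (p in top) {
      rows <- table$contacts$pose_index == p &
        table$contacts$residue_id == vocab[v]
      if (any(rows)) n <- n + 1L
    }
    bits[v] <- as.integer(n >= min_poses)
  }
  names(bits) <- vocab
  bits
}

oracle_tanimoto <- function(on_a, on_b) {
  u <- union(on_a, on_b)
  if (length(u) == 0) return(0)
  length(intersect(on_a, on_b)) / length(u)
}

oracle_score_signature <- function(subset, fps, labels) {
  match_all <- function(i) all(fps[i, subset] == 1)
  act <- which(labels == "active"); inact <- which(labels == "inactive")
  fa <- sum(vapply(act, match_all, logical(1))) / length(act)
  fi <- sum(vapply(inact, match_all, logical(1))) / length(inact)
  list(freq_active = fa, freq_inactive = fi,
       ratio = if (fi > 0) fa / fi else Inf)
}

# selection-and-count enrichment oracle; threshold from an independently
# written linear-interpolation percentile (type-7 convention)
oracle_enrichment <- function(scores, labels, p) {
  h <- (length(scores) - 1) * p / 100
  lo <- floor(h)
  s <- sort(scores)
  thr <- s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
  sel <- which(scores > thr)
  list(n = length(sel),
       precision = if (length(sel)) mean(labels[sel] == "active") else NA_real_)
}

oracle_confusion <- function(pred, truth) {
  ta <- 0L; ti <- 0L; pa <- 0L; pin <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == "active") pa <- pa + 1L else pin <- pin + 1L
    if (pred[i] == "active" && truth[i] == "active") ta <- ta + 1L
    if (pred[i] == "inactive" && truth[i] == "inactive") ti <- ti + 1L
  }
  list(precision_active = if (pa) ta / pa else NA_real_,
       accuracy = (ta + ti) / length(pred))
}

# random pose-contact fixture
random_pose_table <- function(id, n_poses, vocab, seed) {
  set.seed(seed)
  scores <- data.frame(pose_index = 1:n_poses,
                       score = round(rnorm(n_poses, 50, 5), 3))
  rows <- expand.grid(pose_index = 1:n_poses, residue_id = vocab,
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.4, , drop = FALSE]
  rows$interaction_type <- "hydrophobic"
  pose_contact_table(id, scores, rows)
}

random_plif_matrix <- function(n, vocab, p, seed) {
  set.seed(seed)
  matrix(rbinom(n * length(vocab), 1, p), n, length(vocab),
         dimnames = list(NULL, vocab))
}
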