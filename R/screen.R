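# Consensus hit selection. Docking contributes two rules (the four-residue
# contact signature and PLIF similarity to the reference ligand above a
# cutoff); the QSAR ensemble contributes reliability-accepted active
# predictions. Tier-1 hits satisfy both models; remaining slots are
# backfilled from docking-only candidates ranked by their anchorage to known
# chemical space (largest MCS to the reference compound set).

#' Apply the docking-derived screening rules
#'
#' Flags the four-residue signature and the PLIF-similarity rule
#' independently; a docking candidate passes both. Missing similarities are
#' flagged (`similarity_missing`) and fail the similarity rule rather than
#' passing silently.
#'
#' @param fps binary interaction-fingerprint matrix (rows = compounds).
#' @param rule a `signature_rule` or character vector of residues.
#' @param similarities PLIF similarity to the reference, aligned to rows.
#' @param sim_cutoff similarity cutoff, strict `>` (default 0.83).
#' @return data.frame: `compound_id`, `passes_signature`, `plif_similarity`,
#'   `similarity_missing`, `passes_similarity`, `docking_candidate`.
#' @export
docking_rules_filter <- function(fps, rule, similarities,
                                 sim_cutoff = 0.83) {
  stopifnot(nrow(fps) == length(similarities))
  sig <- apply_signature_filter(fps, rule)
  missing <- is.na(similarities)
  sim_ok <- !missing & similarities > sim_cutoff
  data.frame(compound_id = rownames(fps) %||% as.character(seq_len(nrow(fps))),
             passes_signature = sig,
             plif_similarity = similarities,
             similarity_missing = missing,
             passes_similarity = sim_ok,
             docking_candidate = sig & sim_ok,
             stringsAsFactors = FALSE)
}

#' Consensus hit selection
#'
#' Tier 1 is the intersection of docking candidates with accepted QSAR
#' actives; if fewer than `k`, the list is backfilled from remaining docking
#' candidates ranked by descending MCS anchor size (ties: larger PLIF
#' similarity, then input order). Selection is deterministic.
#'
#' @param results data.frame from [docking_rules_filter()] augmented with
#'   `qsar_accepted_active` (logical) and `mcs_anchor_size` (integer).
#' @param k number of hits to return (default 50).
#' @return the selected rows, ranked, with a `consensus_tier` column
#'   (`"qsar_docking"` or `"docking_only"`).
#' @export
consensus_select <- function(results, k = 50) {
  stopifnot(all(c("docking_candidate", "qsar_accepted_active",
                  "mcs_anchor_size") %in% names(results)))
  if (k == 0) return(results[0, , drop = FALSE])
  cand <- results[results$docking_candidate, , drop = FALSE]
  cand$.order <- seq_len(nrow(cand))
  tier1 <- cand[cand$qsar_accepted_active, , drop = FALSE]
  tier1$consensus_tier <- rep("qsar_docking", nrow(tier1))
  rest <- cand[!cand$qsar_accepted_active, , drop = FALSE]
  rest$consensus_tier <- rep("docking_only", nrow(rest))
  rest <- rest[order(-rest$mcs_anchor_size, -rest$plif_similarity,
                     rest$.order), , drop = FALSE]
  out <- rbind(tier1, rest)
  if (k > nrow(out)) {
    warning(sprintf("requested %d hits but only %d candidates", k, nrow(out)))
    k <- nrow(out)
  }
  out <- out[seq_len(k), , drop = FALSE]
  out$.order <- NULL
  rownames(out) <- NULL
  out
}

#' Chemical-novelty report for selected hits
#'
#' For each hit, finds the training compound with the largest maximum
#' common substructure and reports the shared heavy-atom fraction on both
#' sides (`|MCS| / heavy atoms`). Pairs whose MCS is smaller than
#' `min_mcs_atoms` report fractions of 0.
#'
#' @param hits an `SDFset` of hit compounds.
#' @param training an `SDFset` of training compounds.
#' @param min_mcs_atoms smallest MCS considered a shared scaffold
#'   (default 3).
#' @param params an [mcs_params()].
#' @return data.frame: `hit_id`, `nearest_train_id`, `mcs_heavy_atoms`,
#'   `shared_fraction_hit`, `shared_fraction_train`.
#' @export
novelty_report <- function(hits, training, min_mcs_atoms = 3,
                           params = mcs_params()) {
  train_graphs <- lapply(seq_along(training), function(i) mol_graph(training[[i]]))
  train_heavy <- vapply(train_graphs, function(g) length(g$elements), integer(1))
  train_ids <- ChemmineR::cid(training)
  rows <- lapply(seq_along(hits), function(i) {
    gh <- mol_graph(hits[[i]])
    best <- 0L; best_j <- NA_integer_
    for (j in seq_along(train_graphs)) {
      s <- as.integer(mcs_size(gh, train_graphs[[j]], params))
      if (s > best) { best <- s; best_j <- j }
      if (best >= length(gh$elements)) break
    }
    ok <- best >= min_mcs_atoms
    data.frame(hit_id = ChemmineR::cid(hits)[i],
               nearest_train_id = if (ok) train_ids[best_j] else NA_character_,
               mcs_heavy_atoms = if (ok) best else 0L,
               shared_fraction_hit = if (ok) best / length(gh$elements) else 0,
               shared_fraction_train = if (ok) best / train_heavy[best_j] else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
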