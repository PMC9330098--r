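# Residue-signature mining: enumerate residue subsets, score how much more
# frequently actives engage all residues of a subset simultaneously than
# inactives do, and select the predictive rule. Six key residues and subset
# sizes 2-6 give the canonical 57 candidate signatures.

#' Enumerate residue subsets
#'
#' Every subset of each size exactly once, ordered by size then
#' lexicographically.
#'
#' @param residues residue-id vector.
#' @param min_size,max_size subset size bounds.
#' @return list of character vectors.
#' @export
enumerate_signatures <- function(residues, min_size = 2, max_size = 6) {
  if (min_size < 1 || min_size > max_size || max_size > length(residues))
    stop("need 1 <= min_size <= max_size <= length(residues)")
  residues <- sort(unique(residues))
  out <- list()
  for (k in min_size:max_size)
    out <- c(out, combn(residues, k, simplify = FALSE))
  out
}

#' Score one residue signature
#'
#' `freq_active` is the fraction of actives whose fingerprint has *all*
#' subset bits on (this is also the rule's coverage); likewise
#' `freq_inactive`. The enrichment ratio is `freq_active / freq_inactive`,
#' with `Inf` as the sentinel when no inactive matches.
#'
#' @param subset residue-id vector (non-empty).
#' @param fps binary fingerprint matrix, columns named by residue.
#' @param labels `"active"`/`"inactive"` vector aligned to rows of `fps`.
#' @return list of class `signature_rule`: `residues`, `freq_active`,
#'   `freq_inactive`, `ratio`, `coverage`.
#' @export
score_signature <- function(subset, fps, labels) {
  if (length(subset) == 0) stop("empty residue subset")
  if (!all(subset %in% colnames(fps))) stop("subset outside vocabulary")
  act <- labels == "active"; inact <- labels == "inactive"
  if (!any(act) || !any(inact)) stop("need both actives and inactives")
  hit <- rowSums(fps[, subset, drop = FALSE]) == length(subset)
  fa <- mean(hit[act]); fi <- mean(hit[inact])
  structure(list(residues = sort(subset), freq_active = fa,
                 freq_inactive = fi,
                 ratio = if (fi > 0) fa / fi else Inf,
                 coverage = fa),
            class = "signature_rule")
}

#' @export
print.signature_rule <- function(x, ...) {
  cat(sprintf("<signature_rule> {%s}: actives %.1f%%, inactives %.1f%%, ratio %s\n",
              paste(x$residues, collapse = ", "), 100 * x$freq_active,
              100 * x$freq_inactive,
              if (is.finite(x$ratio)) sprintf("%.2f", x$ratio) else "Inf"))
  invisible(x)
}

#' Score many signatures into a rules table
#'
#' @param subsets list of residue subsets (see [enumerate_signatures()]).
#' @inheritParams score_signature
#' @return data.frame: `residues` (";"-joined), `size`, `freq_active`,
#'   `freq_inactive`, `ratio`, `coverage`.
#' @export
score_signatures <- function(subsets, fps, labels) {
  rows <- lapply(subsets, function(s) {
    r <- score_signature(s, fps, labels)
    data.frame(residues = paste(r$residues, collapse = ";"),
               size = length(r$residues), freq_active = r$freq_active,
               freq_inactive = r$freq_inactive, ratio = r$ratio,
               coverage = r$coverage, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the best signature rule
#'
#' Among rules with coverage at least `min_coverage`, picks the maximum
#' enrichment ratio; ties broken by higher coverage, then larger subset,
#' then lexicographic residue order.
#'
#' @param rules data.frame from [score_signatures()].
#' @param min_coverage minimum fraction of actives covered (default 0.5).
#' @return one-row `signature_rule` as a list.
#' @export
select_best_signature <- function(rules, min_coverage = 0.5) {
  if (is.null(rules) || nrow(rules) == 0) stop("empty rules table")
  cand <- rules[rules$coverage >= min_coverage, , drop = FALSE]
  if (nrow(cand) == 0)
    stop(sprintf("no signature reaches coverage >= %.2f", min_coverage))
  ord <- order(-cand$ratio, -cand$coverage, -cand$size, cand$residues)
  best <- cand[ord[1], , drop = FALSE]
  structure(list(residues = strsplit(best$residues, ";")[[1]],
                 freq_active = best$freq_active,
                 freq_inactive = best$freq_inactive,
                 ratio = best$ratio, coverage = best$coverage),
            class = "signature_rule")
}

#' Apply a signature rule to fingerprints
#'
#' @param fps binary fingerprint matrix, columns named by residue.
#' @param rule a `signature_rule` (or character vector of residues).
#' @return logical vector: `TRUE` when all rule residues are contacted.
#' @export
apply_signature_filter <- function(fps, rule) {
  residues <- if (inherits(rule, "signature_rule")) rule$residues else rule
  if (!all(residues %in% colnames(fps)))
    stop("rule residues absent from fingerprint vocabulary")
  rowSums(fps[, residues, drop = FALSE]) == length(residues)
}

#' Ligand efficiency
#'
#' Docking score normalized by molecular size (heavy-atom count).
#'
#' @param score docking score (higher = better).
#' @param heavy_atoms positive integer heavy-atom count.
#' @return numeric ligand efficiency.
#' @export
ligand_efficiency <- function(score, heavy_atoms) {
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be >= 1")
  score / heavy_atoms
}

#' Enrichment curve for a ranking score
#'
#' For each percentile cutoff, selects compounds scoring strictly above that
#' percentile of the score distribution and reports the precision for
#' actives among the selection ("% enrichment" when multiplied by 100).
#' Cutoffs with an empty selection report `NA` precision, never 0.
#'
#' @param scores numeric scores, higher = better.
#' @param labels `"active"`/`"inactive"` aligned to `scores`.
#' @param percentiles percentile grid (default `seq(0, 95, by = 5)`).
#' @return data.frame: `percentile`, `threshold`, `n_selected`, `precision`.
#' @export
enrichment_curve <- function(scores, labels, percentiles = seq(0, 95, by = 5)) {
  stopifnot(length(scores) == length(labels), length(scores) > 0)
  rows <- lapply(percentiles, function(p) {
    thr <- unname(quantile(scores, p / 100, type = 7))
    sel <- scores > thr
    data.frame(percentile = p, threshold = thr, n_selected = sum(sel),
               precision = if (any(sel)) mean(labels[sel] == "active") else NA_real_)
  })
  do.call(rbind, rows)
}
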