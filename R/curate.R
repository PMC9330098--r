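# Bioactivity curation: quality filtering, activity binarization at 2 uM,
# structure standardization + InChIKey deduplication, and class balancing.

#' Curation settings
#'
#' Defaults reproduce strict binding-assay curation: confidence strictly
#' above 7, binding ("B") assays, human target, IC50/Ki/Kd measurements, and
#' censored relations admissible only on the side of the activity threshold
#' they can still classify (">" at or above the threshold, "<" at or below).
#' Every filter can be switched off individually.
#'
#' @param confidence_min records must have confidence strictly greater.
#' @param assay_type required assay type token, or `NULL` to skip.
#' @param organism required organism token, or `NULL` to skip.
#' @param measures admissible measurement types, or `NULL` to skip.
#' @param activity_threshold threshold in uM used both for censored-relation
#'   admissibility and downstream binarization.
#' @param check_confidence,check_assay_type,check_organism,check_measure,check_relation
#'   logical switches for the individual filters.
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(confidence_min = 7,
                            assay_type = "B",
                            organism = "Homo sapiens",
                            measures = c("IC50", "Ki", "Kd"),
                            activity_threshold = 2,
                            check_confidence = TRUE,
                            check_assay_type = TRUE,
                            check_organism = TRUE,
                            check_measure = TRUE,
                            check_relation = TRUE) {
  stopifnot(activity_threshold > 0)
  structure(list(confidence_min = confidence_min, assay_type = assay_type,
                 organism = organism, measures = measures,
                 activity_threshold = activity_threshold,
                 check_confidence = check_confidence,
                 check_assay_type = check_assay_type,
                 check_organism = check_organism,
                 check_measure = check_measure,
                 check_relation = check_relation),
            class = "curation_config")
}

#' Curate bioactivity records
#'
#' Applies the quality filters of a [curation_config()] to a bioactivity
#' table. Each rejected record carries exactly one reason (the first failing
#' filter, in a fixed order); rejects are attached as the `"rejects"`
#' attribute, never silently dropped.
#'
#' @param records data.frame with columns `compound_id, smiles, value_um,
#'   relation, measure, assay_type, confidence, organism, source`.
#' @param config a [curation_config()].
#' @return the retained subset of `records`, with attribute `rejects`
#'   (data.frame: `compound_id`, `reason`).
#' @export
curate_bioactivity <- function(records, config = curation_config()) {
  stopifnot(is.data.frame(records))
  reason <- rep(NA_character_, nrow(records))
  has_value <- !is.na(records$value_um)
  thr <- config$activity_threshold

  bad_rel <- !is.na(records$relation) & !records$relation %in% c("=", ">", "<")
  reason[bad_rel] <- "malformed_relation"

  fail <- function(cond, why) {
    idx <- is.na(reason) & cond
    reason[idx] <<- why
  }
  if (config$check_confidence)
    fail(is.na(records$confidence) | records$confidence <= config$confidence_min,
         "low_confidence")
  if (config$check_assay_type && !is.null(config$assay_type))
    fail(is.na(records$assay_type) | records$assay_type != config$assay_type,
         "assay_type")
  if (config$check_organism && !is.null(config$organism))
    fail(is.na(records$organism) | records$organism != config$organism,
         "organism")
  if (config$check_measure && !is.null(config$measures))
    fail(is.na(records$measure) | !records$measure %in% config$measures,
         "measure")
  if (config$check_relation) {
    fail(has_value & records$relation == ">" & records$value_um < thr,
         "censored_above_below_threshold")
    fail(has_value & records$relation == "<" & records$value_um > thr,
         "censored_below_above_threshold")
  }

  kept <- records[is.na(reason), , drop = FALSE]
  rejects <- data.frame(compound_id = records$compound_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  attr(kept, "rejects") <- rejects
  kept
}

#' Binarize activity values
#'
#' A compound is active when its effective activity is strictly below the
#' threshold. `"<"`-censored values use the bound as effective value, so a
#' bound at or below the threshold classifies as active; `">"`-censored
#' values are inactive; missing values are unlabeled.
#'
#' @param value numeric activity in uM.
#' @param relation `"="`, `">"` or `"<"` (recycled).
#' @param threshold activity threshold in uM (default 2).
#' @return character vector: `"active"`, `"inactive"` or `"unlabeled"`.
#' @export
binarize_activity <- function(value, relation = "=", threshold = 2) {
  stopifnot(threshold > 0)
  n <- max(length(value), length(relation))
  value <- rep_len(value, n); relation <- rep_len(relation, n)
  out <- rep("unlabeled", n)
  has <- !is.na(value)
  if (any(has & value <= 0)) stop("activity values must be positive")
  out[has & relation == "="] <-
    ifelse(value[has & relation == "="] < threshold, "active", "inactive")
  out[has & relation == "<"] <-
    ifelse(value[has & relation == "<"] <= threshold, "active", "inactive")
  out[has & relation == ">"] <- "inactive"
  out
}

#' Standardize structures and merge duplicates
#'
#' Strips salts, canonicalizes, computes the InChIKey structure key, and
#' merges records sharing a key, keeping the minimum activity value among
#' duplicates. Output rows are sorted by structure key, which makes the
#' operation idempotent and input-order invariant. Unparseable structures go
#' to the `rejects` attribute.
#'
#' @param records data.frame with at least `compound_id` and `smiles`;
#'   `value_um` is used for duplicate resolution when present.
#' @return data.frame of unique compounds (`structure_key`, standardized
#'   `smiles`, plus the originating record's other columns), with attribute
#'   `rejects`.
#' @export
standardize_and_dedupe <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  std <- standardize_smiles(records$smiles)
  bad <- is.na(std)
  rejects <- data.frame(compound_id = records$compound_id[bad],
                        smiles = records$smiles[bad],
                        reason = rep("unparseable_smiles", sum(bad)),
                        stringsAsFactors = FALSE)
  keep <- records[!bad, , drop = FALSE]
  keep$smiles <- std[!bad]
  keep$structure_key <- structure_key(keep$smiles)

  value <- if ("value_um" %in% names(keep)) keep$value_um else rep(NA_real_, nrow(keep))
  ord <- order(keep$structure_key, !is.finite(value), value)
  keep <- keep[ord, , drop = FALSE]
  dedup <- keep[!duplicated(keep$structure_key), , drop = FALSE]
  dedup <- dedup[, c("structure_key", setdiff(names(dedup), "structure_key")),
                 drop = FALSE]
  rownames(dedup) <- NULL
  attr(dedup, "rejects") <- rejects
  dedup
}

#' Balance classes by sampling inactives from a pool
#'
#' Samples, without replacement and reproducibly under `seed`, enough
#' compounds from `inactive_pool` to equalize active and inactive counts.
#'
#' @param records data.frame of labeled compounds (column `label`).
#' @param inactive_pool data.frame of inactive compounds to draw from.
#' @param seed integer seed.
#' @return row-bound balanced data.frame.
#' @export
balance_classes <- function(records, inactive_pool, seed) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  n_act <- sum(records$label == "active")
  n_inact <- sum(records$label == "inactive")
  need <- n_act - n_inact
  if (need < 0) stop("more inactives than actives; pool sampling only adds inactives")
  if (need > nrow(inactive_pool))
    stop(sprintf("inactive pool too small: need %d, have %d (short by %d)",
                 need, nrow(inactive_pool), need - nrow(inactive_pool)))
  picked <- with_seed(seed, sample.int(nrow(inactive_pool), need))
  extra <- inactive_pool[sort(picked), , drop = FALSE]
  extra$label <- "inactive"
  common <- intersect(names(records), names(extra))
  out <- rbind(records[, common, drop = FALSE], extra[, common, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Compute molecular feature blocks
#'
#' @param compounds data.frame with standardized `smiles` and `compound_id`.
#' @return list with elements `physchem` (descriptor matrix), `morgan`
#'   (1024-bit fingerprint matrix) and `heavy_atoms` (integer vector), all
#'   row-aligned with `compounds`.
#' @export
compute_features <- function(compounds) {
  stopifnot(is.data.frame(compounds), nrow(compounds) >= 1)
  if (anyNA(compounds$smiles)) stop("invalid structures present; standardize first")
  sdf <- parse_smiles(compounds$smiles, compounds$compound_id)
  list(physchem = physchem_panel(sdf),
       morgan = morgan_fp(sdf),
       heavy_atoms = stats::setNames(heavy_atom_counts(sdf),
                                     compounds$compound_id))
}

#' Drug-likeness prefilter for screening libraries
#'
#' Keeps compounds with QED strictly above `qed_min` and, optionally, no
#' PAINS substructure match. Removal counts per filter are reported via
#' `message()` and attached as the `removed` attribute.
#'
#' @param compounds data.frame with standardized `smiles` and `compound_id`.
#' @param qed_min QED cutoff (strict `>`), default 0.85.
#' @param pains apply the PAINS filter (default `TRUE`).
#' @param pains_smarts named SMARTS vector, default [pains_patterns()].
#' @return filtered data.frame with attribute `removed`
#'   (`c(qed = ..., pains = ...)`).
#' @export
prefilter_library <- function(compounds, qed_min = 0.85, pains = TRUE,
                              pains_smarts = pains_patterns()) {
  sdf <- parse_smiles(compounds$smiles, compounds$compound_id)
  qed <- qed_score(sdf)
  drop_qed <- !(qed > qed_min)
  drop_pains <- if (pains) pains_flags(sdf, pains_smarts) else rep(FALSE, length(sdf))
  keep <- compounds[!drop_qed & !drop_pains, , drop = FALSE]
  removed <- c(qed = sum(drop_qed), pains = sum(drop_pains & !drop_qed))
  message(sprintf("prefilter: removed %d by QED<=%.2f, %d by PAINS; %d kept",
                  removed[["qed"]], qed_min, removed[["pains"]], nrow(keep)))
  attr(keep, "removed") <- removed
  keep
}
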