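# Protein-ligand interaction fingerprints. A PLIF is a binary per-residue
# contact vector over a fixed residue vocabulary; the "robust" fingerprint
# marks a residue only when it is contacted in at least `min_poses` of the
# `top_n` best-scoring docking poses, which suppresses pose-to-pose noise and
# removes the bias toward the single top pose.

#' Six key binding-site residues of the RIPK1 allosteric back pocket
#'
#' LEU70, VAL75 and LEU78 from the binding loop, LEU129 from the alpha-E
#' helix, and ASP156/LEU157 from the DLG motif of the activation loop.
#'
#' @return character vector of residue ids.
#' @export
key_residues <- function() {
  c("LEU70", "VAL75", "LEU78", "LEU129", "ASP156", "LEU157")
}

#' Four-residue activity signature
#'
#' The residue subset whose simultaneous engagement separates RIPK1 actives
#' from inactives: compounds must bridge both sides of the narrow allosteric
#' back pocket.
#'
#' @return character vector of residue ids.
#' @export
signature_residues <- function() c("LEU70", "VAL75", "ASP156", "LEU157")

#' Construct an interaction fingerprint
#'
#' @param bits logical/integer vector aligned to `vocabulary`, or a character
#'   vector of on-residues.
#' @param vocabulary ordered residue-id vector.
#' @return object of class `plif` with fields `vocabulary` and `bits`.
#' @export
interaction_fingerprint <- function(bits, vocabulary) {
  stopifnot(!anyDuplicated(vocabulary))
  if (is.character(bits)) {
    if (!all(bits %in% vocabulary)) stop("on-bits outside vocabulary")
    bits <- as.integer(vocabulary %in% bits)
  }
  stopifnot(length(bits) == length(vocabulary))
  structure(list(vocabulary = as.character(vocabulary),
                 bits = stats::setNames(as.integer(bits != 0), vocabulary)),
            class = "plif")
}

#' @export
print.plif <- function(x, ...) {
  on <- x$vocabulary[x$bits == 1]
  cat(sprintf("<plif> %d/%d residues on: %s\n", length(on),
              length(x$vocabulary), paste(on, collapse = ", ")))
  invisible(x)
}

#' Construct a per-compound pose contact table
#'
#' @param compound_id identifier token.
#' @param scores data.frame with `pose_index` and `score` (one row per pose;
#'   higher score = better pose).
#' @param contacts data.frame with `pose_index`, `residue_id`,
#'   `interaction_type`.
#' @return object of class `pose_contact_table`.
#' @export
pose_contact_table <- function(compound_id, scores, contacts) {
  stopifnot(all(c("pose_index", "score") %in% names(scores)),
            all(c("pose_index", "residue_id", "interaction_type") %in% names(contacts)),
            !anyDuplicated(scores$pose_index))
  if (nrow(contacts) > 0 && !all(contacts$pose_index %in% scores$pose_index))
    stop("contacts reference unknown pose_index")
  structure(list(compound_id = compound_id,
                 scores = scores[order(-scores$score, scores$pose_index), ,
                                 drop = FALSE],
                 contacts = contacts),
            class = "pose_contact_table")
}

#' Read pose contact tables from CSV
#'
#' Schema: `compound_id, pose_index, score, residue_id, interaction_type`.
#' Rows with empty `residue_id` declare a pose with no contacts.
#'
#' @param path CSV file path.
#' @return named list of [pose_contact_table()] objects.
#' @export
read_contact_tables <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$compound_id), function(d) {
    scores <- unique(d[, c("pose_index", "score")])
    contacts <- d[!is.na(d$residue_id) & nzchar(d$residue_id),
                  c("pose_index", "residue_id", "interaction_type")]
    pose_contact_table(d$compound_id[1], scores, contacts)
  })
}

#' Write pose contact tables to CSV
#'
#' @param tables list of [pose_contact_table()] objects.
#' @param path output CSV path.
#' @export
write_contact_tables <- function(tables, path) {
  rows <- lapply(tables, function(t) {
    sc <- t$scores
    ct <- merge(t$contacts, sc, by = "pose_index")
    empty <- sc[!sc$pose_index %in% t$contacts$pose_index, , drop = FALSE]
    if (nrow(empty)) {
      empty$residue_id <- ""; empty$interaction_type <- ""
      ct <- rbind(ct, empty[, names(ct)])
    }
    cbind(compound_id = t$compound_id, ct)
  })
  out <- do.call(rbind, rows)
  write.csv(out[order(out$compound_id, out$pose_index), ], path,
            row.names = FALSE)
  invisible(path)
}

#' Robust interaction fingerprint from docking poses
#'
#' A residue bit is on iff the residue shows any interaction type in at
#' least `min_poses` of the `top_n` highest-scoring poses (score ties broken
#' by pose index). Tables with fewer than `top_n` poses are an error: the
#' robust fingerprint is undefined.
#'
#' @param table a [pose_contact_table()].
#' @param top_n number of best poses considered (default 5).
#' @param min_poses minimum poses showing the contact (default 4).
#' @param vocabulary ordered residue vocabulary (default [key_residues()]).
#' @return a `plif` object.
#' @export
robust_plif <- function(table, top_n = 5, min_poses = 4,
                        vocabulary = key_residues()) {
  stopifnot(inherits(table, "pose_contact_table"), min_poses <= top_n)
  if (nrow(table$scores) < top_n)
    stop(sprintf("compound %s has %d poses; robust fingerprint needs >= %d",
                 table$compound_id, nrow(table$scores), top_n))
  top <- table$scores$pose_index[seq_len(top_n)]
  ct <- table$contacts[table$contacts$pose_index %in% top &
                         table$contacts$residue_id %in% vocabulary, ,
                       drop = FALSE]
  n_pose <- vapply(vocabulary, function(r)
    length(unique(ct$pose_index[ct$residue_id == r])), integer(1))
  interaction_fingerprint(as.integer(n_pose >= min_poses), vocabulary)
}

#' Robust fingerprints for many compounds as a matrix
#'
#' @param tables list of [pose_contact_table()] objects.
#' @inheritParams robust_plif
#' @return binary integer matrix, rows = compounds, columns = vocabulary.
#' @export
robust_plif_matrix <- function(tables, top_n = 5, min_poses = 4,
                               vocabulary = key_residues()) {
  m <- t(vapply(tables, function(t)
    robust_plif(t, top_n, min_poses, vocabulary)$bits,
    integer(length(vocabulary))))
  rownames(m) <- vapply(tables, `[[`, character(1), "compound_id")
  colnames(m) <- vocabulary
  m
}

#' Tanimoto similarity between interaction fingerprints
#'
#' `|A n B| / |A u B|` over on-bits, optionally restricted to a residue
#' subset. An empty restricted union (no shared contact evidence at all)
#' yields 0.
#'
#' @param a,b `plif` objects over identical vocabularies.
#' @param subset residue ids to restrict to, or `NULL` for all.
#' @return similarity in `[0, 1]`.
#' @export
plif_tanimoto <- function(a, b, subset = NULL) {
  stopifnot(inherits(a, "plif"), inherits(b, "plif"))
  if (!identical(a$vocabulary, b$vocabulary))
    stop("fingerprint vocabularies differ")
  idx <- if (is.null(subset)) seq_along(a$vocabulary) else {
    if (!all(subset %in% a$vocabulary)) stop("subset outside vocabulary")
    match(subset, a$vocabulary)
  }
  x <- a$bits[idx]; y <- b$bits[idx]
  u <- sum(x | y)
  if (u == 0) return(0)
  sum(x & y) / u
}

#' PLIF similarity of many compounds to a reference
#'
#' @param fps binary matrix (rows = compounds, columns = residue vocabulary).
#' @param reference a `plif` object over the same vocabulary.
#' @param subset optional residue restriction (e.g. [key_residues()]).
#' @return numeric similarity vector, named by row.
#' @export
plif_similarity <- function(fps, reference, subset = NULL) {
  stopifnot(inherits(reference, "plif"),
            identical(colnames(fps), reference$vocabulary))
  cols <- if (is.null(subset)) colnames(fps) else {
    if (!all(subset %in% colnames(fps))) stop("subset outside vocabulary")
    subset
  }
  x <- fps[, cols, drop = FALSE]
  r <- reference$bits[cols]
  inter <- as.vector(x %*% r)
  union <- rowSums(x) + sum(r) - inter
  ifelse(union == 0, 0, inter / union)
}

#' Percentile cutoff over a similarity distribution
#'
#' Linear-interpolation percentile (type-7 quantile). Compounds strictly
#' above the returned value pass the similarity rule.
#'
#' @param similarities numeric vector.
#' @param percentile percentile in `[0, 100]` (default 80).
#' @return the cutoff value.
#' @export
similarity_percentile_cutoff <- function(similarities, percentile = 80) {
  similarities <- similarities[!is.na(similarities)]
  if (length(similarities) == 0) stop("no similarities supplied")
  unname(quantile(similarities, percentile / 100, type = 7))
}

## ---- simplified geometric contact detector -------------------------------

#' Parameters for the built-in contact detector
#'
#' @param hydrophobic_dist apolar-carbon pair distance cutoff in Angstrom.
#' @param hbond_dist donor-acceptor heavy-atom distance cutoff in Angstrom.
#' @param hbond_angle minimum donor angle in degrees.
#' @return list of class `contact_params`.
#' @export
contact_params <- function(hydrophobic_dist = 4.0, hbond_dist = 3.5,
                           hbond_angle = 120) {
  structure(list(hydrophobic_dist = hydrophobic_dist,
                 hbond_dist = hbond_dist, hbond_angle = hbond_angle),
            class = "contact_params")
}

#' Detect residue contacts for one ligand pose (simplified)
#'
#' A deliberately small geometric backend: apolar carbon pairs within
#' `hydrophobic_dist` give hydrophobic contacts; ligand N/O versus protein
#' N/O pairs within `hbond_dist` give hydrogen bonds, with the donor angle
#' (neighbor-donor-acceptor) checked when the ligand table carries neighbor
#' coordinates (`nbr_x/nbr_y/nbr_z`). Full interaction typing (water
#' bridges, metals, halogen geometry) is out of scope; externally computed
#' contact tables are accepted everywhere instead.
#'
#' @param ligand data.frame: `x, y, z, element`, optional `has_h` (donor
#'   capability) and `nbr_x, nbr_y, nbr_z`.
#' @param protein data.frame: `x, y, z, element, residue_id`.
#' @param params a [contact_params()].
#' @return data.frame `residue_id, interaction_type`, unique rows.
#' @export
detect_contacts <- function(ligand, protein, params = contact_params()) {
  need_l <- c("x", "y", "z", "element")
  if (!all(need_l %in% names(ligand)) ||
      !all(c(need_l, "residue_id") %in% names(protein)))
    stop("missing atom typing: ligand needs x/y/z/element, protein also residue_id")
  d2 <- function(i, j) (ligand$x[i] - protein$x[j])^2 +
    (ligand$y[i] - protein$y[j])^2 + (ligand$z[i] - protein$z[j])^2
  out <- list()
  lc <- which(ligand$element == "C")
  pc <- which(protein$element == "C")
  for (i in lc) for (j in pc)
    if (d2(i, j) <= params$hydrophobic_dist^2)
      out[[length(out) + 1L]] <- c(protein$residue_id[j], "hydrophobic")
  lp <- which(ligand$element %in% c("N", "O"))
  pp <- which(protein$element %in% c("N", "O"))
  has_nbr <- all(c("nbr_x", "nbr_y", "nbr_z") %in% names(ligand))
  for (i in lp) for (j in pp) {
    if (d2(i, j) > params$hbond_dist^2) next
    if (has_nbr && !is.na(ligand$nbr_x[i])) {
      v1 <- c(ligand$nbr_x[i] - ligand$x[i], ligand$nbr_y[i] - ligand$y[i],
              ligand$nbr_z[i] - ligand$z[i])
      v2 <- c(protein$x[j] - ligand$x[i], protein$y[j] - ligand$y[i],
              protein$z[j] - ligand$z[i])
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang < params$hbond_angle) next
    }
    donor <- if ("has_h" %in% names(ligand) && !is.na(ligand$has_h[i]))
      isTRUE(as.logical(ligand$has_h[i])) else ligand$element[i] == "N"
    out[[length(out) + 1L]] <-
      c(protein$residue_id[j], if (donor) "hbond_donor" else "hbond_acceptor")
  }
  if (!length(out))
    return(data.frame(residue_id = character(0),
                      interaction_type = character(0)))
  m <- unique(do.call(rbind, out))
  data.frame(residue_id = m[, 1], interaction_type = m[, 2],
             stringsAsFactors = FALSE)
}

#' Read ligand pose atoms from an SDF file
#'
#' @param path SDF file with one or more poses.
#' @return list of data.frames (`x, y, z, element`), one per pose, with the
#'   `score` attribute taken from the `score` SDF data field when present.
#' @export
read_ligand_sdf <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    d <- data.frame(x = ab[, 1], y = ab[, 2], z = ab[, 3],
                    element = sub("_.*$", "", rownames(ab)),
                    stringsAsFactors = FALSE)
    db <- ChemmineR::datablock(sdf[[i]])
    if ("score" %in% names(db)) attr(d, "score") <- as.numeric(db[["score"]])
    d
  })
}

#' Read protein atoms from a PDB file
#'
#' @param path PDB file.
#' @return data.frame `x, y, z, element, residue_id` (residue_id =
#'   `RESNAME + RESNUM`, e.g. `LEU70`).
#' @export
read_protein_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- if ("elesy" %in% names(at) && any(nzchar(at$elesy)))
    toupper(at$elesy) else toupper(substr(trimws(at$elety), 1, 1))
  data.frame(x = at$x, y = at$y, z = at$z, element = elem,
             residue_id = paste0(toupper(at$resid), at$resno),
             stringsAsFactors = FALSE)
}

#' Read a reference interaction fingerprint from CSV
#'
#' Schema: columns `residue_id`, `bit`. The package ships a synthetic
#' stand-in for a co-crystal ligand fingerprint at
#' `system.file("extdata", "ref_plif_synthetic.csv", package = "ripscreen")`;
#' replace it with a measured reference for real screening.
#'
#' @param path CSV path.
#' @param vocabulary residue vocabulary; defaults to the file's residues.
#' @return a `plif` object.
#' @export
read_plif_csv <- function(path, vocabulary = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(vocabulary)) vocabulary <- tab$residue_id
  bits <- stats::setNames(rep(0L, length(vocabulary)), vocabulary)
  on <- tab$residue_id[tab$bit != 0]
  if (!all(on %in% vocabulary)) stop("reference residues outside vocabulary")
  bits[on] <- 1L
  interaction_fingerprint(bits, vocabulary)
}

#' Default (synthetic) reference fingerprint
#'
#' @param vocabulary residue vocabulary (default [key_residues()]).
#' @return a `plif` object with the six key residues on.
#' @export
default_reference_plif <- function(vocabulary = key_residues()) {
  read_plif_csv(system.file("extdata", "ref_plif_synthetic.csv",
                            package = "ripscreen"), vocabulary)
}
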