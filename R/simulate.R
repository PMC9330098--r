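# Seeded synthetic fixtures. Compounds come from a small fragment-decoration
# grammar (scaffold x two substituents), so every structure is valid and the
# chemistry backend can be exercised end to end. Residue contacts are planted
# at the level the downstream method consumes: a compound *carries* the
# signature (all signature residues contacted in its underlying profile)
# with a class-dependent probability, every other residue is background.
# Docking-pose tables add independent per-pose contact flip noise and
# class-conditional scores.

# scaffold templates with two substitution slots (R1, R2)
grammar_templates <- function() c(
  "c1ccc(R1)c(R2)c1",      # ortho-disubstituted benzene
  "c1cc(R1)cc(R2)c1",      # meta
  "c1ccc(R1)cc1R2",        # para
  "c1ccnc(R1)c1R2",        # pyridine
  "c1cnc(R1)nc1R2",        # pyrimidine
  "c1cc(R1)sc1R2",         # thiophene
  "c1cc(R1)oc1R2",         # furan
  "C1CCC(R1)(R2)CC1",      # gem-disubstituted cyclohexane
  "C1CN(R1)CCN1R2",        # N,N'-disubstituted piperazine
  "c1ccc2cc(R1)ccc2c1R2")  # naphthalene

grammar_substituents <- function() c(
  "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "F", "Cl", "Br", "C(=O)C", "C(=O)N", "C(=O)O", "C#N", "CO", "CN", "S")

# batch canonical SMILES for grammar output (valid by construction; falls
# back to per-molecule conversion if OpenBabel disagrees)
canonical_batch <- function(smiles) {
  out <- tryCatch(suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n"))),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("\t.*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(smiles)) return(canonical_smiles(smiles))
  lines
}

structure_key_batch <- function(smiles) {
  out <- tryCatch(suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "INCHIKEY", paste0(paste(smiles, collapse = "\n"), "\n"))),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("[\t ].*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(smiles)) return(structure_key(smiles))
  lines
}

#' Synthetic binding-pocket residue vocabulary
#'
#' The six key residues plus 18 invented pocket residue ids. This vocabulary
#' is synthetic plumbing for the generator; it is not a crystallographic
#' pocket annotation.
#'
#' @return character vector of 24 residue ids.
#' @export
synthetic_pocket_vocabulary <- function() {
  c("GLU63", "MET66", "GLY67", "LEU70", "VAL75", "LEU78",
    "ASP89", "LEU90", "MET92", "THR93", "TYR128", "LEU129",
    "GLY133", "VAL134", "HIS136", "ARG137", "ALA155", "ASP156",
    "LEU157", "SER161", "PHE162", "ASN159", "LYS165", "ILE168")
}

#' Configuration of the synthetic-data generator
#'
#' `p_contact_active` / `p_contact_inactive` are the probabilities that an
#' active / inactive compound *carries* the planted signature (all signature
#' residues present in its underlying contact profile); defaults reproduce
#' the observed 61% / 25% co-contact contrast. Residues not fixed by a
#' carried signature are contacted independently with `background_p`.
#'
#' @param n_active,n_inactive labeled set sizes.
#' @param residue_vocabulary ordered residue ids.
#' @param planted_signature residue subset planted as the activity signature.
#' @param p_contact_active,p_contact_inactive signature carrier
#'   probabilities per class.
#' @param background_p background per-residue contact probability.
#' @param n_poses docking poses per compound (>= 5).
#' @param pose_flip_noise per-pose, per-residue contact flip probability.
#' @param score_model list with `active`/`inactive` elements, each
#'   `c(mean=, sd=)`, for pose docking scores.
#' @param library_size,hit_fraction screening-library size and planted hit
#'   fraction.
#' @param seed integer seed; the generator is a pure function of
#'   config + seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_active = 300, n_inactive = 300,
                             residue_vocabulary = synthetic_pocket_vocabulary(),
                             planted_signature = signature_residues(),
                             p_contact_active = 0.61,
                             p_contact_inactive = 0.25,
                             background_p = 0.45,
                             n_poses = 10,
                             pose_flip_noise = 0.05,
                             score_model = list(active = c(mean = 50, sd = 5),
                                                inactive = c(mean = 52, sd = 5)),
                             library_size = 1000, hit_fraction = 0.05,
                             seed = 1) {
  probs <- c(p_contact_active, p_contact_inactive, background_p,
             pose_flip_noise, hit_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_poses < 5) stop("n_poses must be >= 5 for robust fingerprints")
  if (!all(planted_signature %in% residue_vocabulary))
    stop("planted signature outside residue vocabulary")
  if (n_active < 1 || n_inactive < 1 || library_size < 1)
    stop("set sizes must be positive")
  structure(list(n_active = n_active, n_inactive = n_inactive,
                 residue_vocabulary = residue_vocabulary,
                 planted_signature = planted_signature,
                 p_contact_active = p_contact_active,
                 p_contact_inactive = p_contact_inactive,
                 background_p = background_p, n_poses = n_poses,
                 pose_flip_noise = pose_flip_noise,
                 score_model = score_model, library_size = library_size,
                 hit_fraction = hit_fraction, seed = seed),
            class = "generator_config")
}

#' Generate unique synthetic compound structures
#'
#' Deterministic under `seed`; structures are unique by InChIKey, so they
#' survive [standardize_and_dedupe()] unchanged in count.
#'
#' @param n number of compounds.
#' @param seed integer seed.
#' @param templates scaffold templates (with `R1`/`R2` slots).
#' @return data.frame: `compound_id`, `smiles` (canonical), `scaffold`
#'   (template index).
#' @export
simulate_compounds <- function(n, seed = 1, templates = grammar_templates()) {
  subs <- grammar_substituents()
  grid <- expand.grid(t = seq_along(templates), a = seq_along(subs),
                      b = seq_along(subs))
  if (n > nrow(grid)) stop(sprintf("grammar yields at most %d raw structures",
                                   nrow(grid)))
  ord <- with_seed(seed, sample.int(nrow(grid)))
  picked <- data.frame(smiles = character(0), scaffold = integer(0))
  seen <- character(0)
  pos <- 1L
  while (nrow(picked) < n && pos <= nrow(grid)) {
    take <- ord[pos:min(nrow(grid), pos + max(2L * n, 200L) - 1L)]
    pos <- pos + length(take)
    raw <- vapply(take, function(g) {
      s <- sub("R1", subs[grid$a[g]], templates[grid$t[g]], fixed = TRUE)
      sub("R2", subs[grid$b[g]], s, fixed = TRUE)
    }, character(1))
    can <- canonical_batch(raw)
    key <- structure_key_batch(can)
    ok <- !is.na(can) & !is.na(key) & !duplicated(key) & !key %in% seen
    seen <- c(seen, key[ok])
    picked <- rbind(picked, data.frame(smiles = can[ok],
                                       scaffold = grid$t[take][ok]))
  }
  if (nrow(picked) < n)
    stop(sprintf("grammar exhausted at %d unique structures (need %d)",
                 nrow(picked), n))
  picked <- picked[seq_len(n), , drop = FALSE]
  data.frame(compound_id = sprintf("SYN%05d", seq_len(n)),
             smiles = picked$smiles, scaffold = picked$scaffold,
             stringsAsFactors = FALSE)
}

# underlying contact profiles: carrier model per class
simulate_contact_profiles <- function(labels, config, seed) {
  vocab <- config$residue_vocabulary
  n <- length(labels)
  with_seed(seed, {
    p_car <- ifelse(labels == "active", config$p_contact_active,
                    config$p_contact_inactive)
    carrier <- rbinom(n, 1, p_car) == 1
    prof <- matrix(rbinom(n * length(vocab), 1, config$background_p),
                   n, length(vocab), dimnames = list(NULL, vocab))
    prof[carrier, config$planted_signature] <- 1L
    attr(prof, "carrier") <- carrier
    prof
  })
}

# pose tables: per-pose contact = profile xor flip noise; scores by class
simulate_pose_tables <- function(profiles, ids, classes, config, seed) {
  vocab <- colnames(profiles)
  hydroph <- grepl("^(LEU|VAL|ILE|ALA|MET|PHE|GLY|TYR)", vocab)
  itype <- ifelse(hydroph, "hydrophobic", "hbond_acceptor")
  seeds <- derive_seeds(seed, nrow(profiles))
  lapply(seq_len(nrow(profiles)), function(i) {
    with_seed(seeds[i], {
      sm <- config$score_model[[classes[i]]]
      scores <- data.frame(pose_index = seq_len(config$n_poses),
                           score = rnorm(config$n_poses, sm["mean"], sm["sd"]))
      flip <- matrix(rbinom(config$n_poses * length(vocab), 1,
                            config$pose_flip_noise),
                     config$n_poses, length(vocab))
      prof <- matrix(profiles[i, ] == 1, config$n_poses, length(vocab),
                     byrow = TRUE)
      on <- (flip == 1) != prof
      idx <- which(on, arr.ind = TRUE)
      contacts <- data.frame(pose_index = idx[, 1],
                             residue_id = vocab[idx[, 2]],
                             interaction_type = itype[idx[, 2]],
                             stringsAsFactors = FALSE)
      pose_contact_table(ids[i], scores, contacts)
    })
  })
}

#' Fast sampler of robust fingerprints
#'
#' Draws the robust PLIF of each profile directly: over the `top_n` poses a
#' profile-on bit is detected with probability `P(Binom(top_n, 1 - flip) >=
#' min_poses)` and a profile-off bit with the symmetric false-positive rate.
#' Because pose contacts are independent of pose scores, this is
#' distributionally identical to generating full pose tables and running
#' [robust_plif()] (an equivalence the test suite checks).
#'
#' @param profiles binary profile matrix.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param top_n,min_poses robust-fingerprint parameters.
#' @return binary fingerprint matrix.
#' @export
simulate_plif_matrix <- function(profiles, config, seed, top_n = 5,
                                 min_poses = 4) {
  det_on <- stats::pbinom(min_poses - 1, top_n, 1 - config$pose_flip_noise,
                          lower.tail = FALSE)
  det_off <- stats::pbinom(min_poses - 1, top_n, config$pose_flip_noise,
                           lower.tail = FALSE)
  p <- ifelse(profiles == 1, det_on, det_off)
  with_seed(seed, matrix(rbinom(length(p), 1, as.vector(p)), nrow(profiles),
                         ncol(profiles), dimnames = dimnames(profiles)))
}

#' Simulate a labeled compound set with planted contact structure
#'
#' @param config a [generator_config()].
#' @param structures generate chemical structures (default `TRUE`).
#' @param pose_tables generate full docking-pose contact tables
#'   (default `TRUE`).
#' @return list of class `synthetic_set`: `compounds`, `labels`,
#'   `profiles` (with `carrier` attribute), `pose_tables`, `config`.
#' @export
simulate_labeled_set <- function(config = generator_config(),
                                 structures = TRUE, pose_tables = TRUE) {
  n <- config$n_active + config$n_inactive
  labels <- rep(c("active", "inactive"), c(config$n_active, config$n_inactive))
  seeds <- derive_seeds(config$seed, 3)
  compounds <- if (structures) simulate_compounds(n, seeds[1]) else
    data.frame(compound_id = sprintf("SYN%05d", seq_len(n)),
               smiles = NA_character_, scaffold = NA_integer_,
               stringsAsFactors = FALSE)
  profiles <- simulate_contact_profiles(labels, config, seeds[2])
  tables <- if (pose_tables)
    simulate_pose_tables(profiles, compounds$compound_id, labels, config,
                         seeds[3]) else NULL
  structure(list(compounds = compounds, labels = labels,
                 profiles = profiles, pose_tables = tables, config = config),
            class = "synthetic_set")
}

#' Simulate an unlabeled screening library with planted hits
#'
#' Exactly `round(library_size * hit_fraction)` compounds carry the planted
#' signature (all signature residues on in the underlying profile); the
#' rest are pure background. The hidden truth is returned for evaluation
#' only.
#'
#' @param config a [generator_config()].
#' @inheritParams simulate_labeled_set
#' @return list of class `synthetic_library`: `compounds`, `profiles`,
#'   `pose_tables`, `truth` (data.frame `compound_id`, `planted`), `config`.
#' @export
simulate_library <- function(config = generator_config(), structures = TRUE,
                             pose_tables = TRUE) {
  n <- config$library_size
  n_hits <- round(n * config$hit_fraction)
  seeds <- derive_seeds(config$seed + 17L, 4)
  planted <- rep(FALSE, n)
  planted[with_seed(seeds[1], sample.int(n, n_hits))] <- TRUE
  compounds <- if (structures) simulate_compounds(n, seeds[2]) else
    data.frame(compound_id = sprintf("LIB%05d", seq_len(n)),
               smiles = NA_character_, scaffold = NA_integer_,
               stringsAsFactors = FALSE)
  compounds$compound_id <- sprintf("LIB%05d", seq_len(n))
  vocab <- config$residue_vocabulary
  profiles <- with_seed(seeds[3], {
    prof <- matrix(rbinom(n * length(vocab), 1, config$background_p),
                   n, length(vocab), dimnames = list(NULL, vocab))
    prof[planted, config$planted_signature] <- 1L
    prof
  })
  classes <- ifelse(planted, "active", "inactive")
  tables <- if (pose_tables)
    simulate_pose_tables(profiles, compounds$compound_id, classes, config,
                         seeds[4]) else NULL
  structure(list(compounds = compounds, profiles = profiles,
                 pose_tables = tables,
                 truth = data.frame(compound_id = compounds$compound_id,
                                    planted = planted,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "synthetic_library")
}

#' Simulate a structure-labeled set with a mislabeled low-density region
#'
#' Labels are determined by scaffold (alternate scaffolds are active), so a
#' fingerprint-based QSAR model can learn them; compounds of one additional
#' rare scaffold get random labels unrelated to structure, creating a
#' sparse region of irreducible label noise for applicability-domain
#' evaluation.
#'
#' @param n_per_scaffold compounds per main scaffold (default 30).
#' @param n_scaffolds number of main scaffolds (default 6, max 6). The main
#'   scaffolds are drawn from structurally distinct templates (one benzene
#'   isomer, pyridine, pyrimidine, thiophene, cyclohexane, piperazine) so
#'   the scaffold-label rule is learnable from fingerprints; the rare
#'   scaffold (furan) is reserved for the corrupted region.
#' @param n_rare compounds of the rare mislabeled scaffold (default 12).
#' @param seed integer seed.
#' @return list: `compounds`, `labels` (observed, with flips),
#'   `true_labels`, `mislabeled` (logical), `scaffold_set` (template
#'   indices, rare last).
#' @export
simulate_ad_set <- function(n_per_scaffold = 30, n_scaffolds = 6,
                            n_rare = 12, seed = 1) {
  mains <- c(1L, 4L, 5L, 6L, 8L, 9L)
  rare <- 7L
  stopifnot(n_scaffolds >= 1, n_scaffolds <= length(mains))
  mains <- mains[seq_len(n_scaffolds)]
  pool <- simulate_compounds(
    min(2400L, 8L * (n_scaffolds + 1L) * max(n_per_scaffold, n_rare)), seed)
  rows <- integer(0)
  for (s in mains) {
    avail <- which(pool$scaffold == s)
    if (length(avail) < n_per_scaffold)
      stop("grammar pool too small for requested scaffold counts")
    rows <- c(rows, avail[seq_len(n_per_scaffold)])
  }
  rare_avail <- which(pool$scaffold == rare)
  if (length(rare_avail) < n_rare) stop("not enough rare-scaffold compounds")
  rows <- c(rows, rare_avail[seq_len(n_rare)])
  compounds <- pool[rows, , drop = FALSE]
  rownames(compounds) <- NULL
  compounds$compound_id <- sprintf("AD%05d", seq_len(nrow(compounds)))
  scaffold_set <- c(mains, rare)
  pos <- match(compounds$scaffold, scaffold_set)
  true_labels <- ifelse(pos %% 2 == 1, "active", "inactive")
  mislabeled <- compounds$scaffold == rare
  labels <- true_labels
  labels[mislabeled] <- with_seed(seed + 1L,
    sample(c("active", "inactive"), sum(mislabeled), replace = TRUE))
  list(compounds = compounds, labels = labels, true_labels = true_labels,
       mislabeled = mislabeled, scaffold_set = scaffold_set)
}

#' Curation bookkeeping fixture
#'
#' A synthetic four-source bioactivity fixture sized like a realistic
#' kinase-inhibitor assembly: a primary public subset that curates and
#' deduplicates to 248 unique compounds, two literature/patent subsets of 72
#' and 118, and a 277-compound inactive pool from which class balancing
#' draws 186, for a balanced total of 624 (312 actives / 312 inactives).
#' The primary subset includes records that each quality filter must
#' reject, plus salted duplicates that deduplication must merge.
#'
#' @param seed integer seed.
#' @return list of raw record data.frames: `chembl`, `harris`, `roche`,
#'   `pubchem_pool`.
#' @export
make_curation_fixture <- function(seed = 1) {
  pool <- simulate_compounds(248 + 72 + 118 + 277, seed)
  mk <- function(ids, smiles, value, relation, measure, assay, conf, org, src)
    data.frame(compound_id = ids, smiles = smiles, value_um = value,
               relation = relation, measure = measure, assay_type = assay,
               confidence = conf, organism = org, source = src,
               stringsAsFactors = FALSE)
  take <- function(n) {
    out <- pool[seq_len(n), , drop = FALSE]
    pool <<- pool[-seq_len(n), , drop = FALSE]
    out
  }
  hs <- "Homo sapiens"
  with_seed(seed + 1L, {
    ch <- take(248)
    ch_val <- c(runif(177, 0.05, 1.9), runif(71, 2.5, 80))
    chembl <- mk(sprintf("CHEMBL%04d", 1:248), ch$smiles, ch_val, "=",
                 sample(c("IC50", "Ki", "Kd"), 248, replace = TRUE), "B", 8,
                 hs, "chembl")
    # records every filter must reject, built on already-used structures
    bad <- rbind(
      mk("REJ_CONF", ch$smiles[1], 1.0, "=", "IC50", "B", 6, hs, "chembl"),
      mk("REJ_ASSAY", ch$smiles[2], 1.0, "=", "IC50", "F", 8, hs, "chembl"),
      mk("REJ_ORG", ch$smiles[3], 1.0, "=", "IC50", "B", 8, "Mus musculus", "chembl"),
      mk("REJ_MEAS", ch$smiles[4], 1.0, "=", "EC50", "B", 8, hs, "chembl"),
      mk("REJ_RELGT", ch$smiles[5], 0.5, ">", "IC50", "B", 8, hs, "chembl"),
      mk("REJ_RELLT", ch$smiles[6], 10, "<", "IC50", "B", 8, hs, "chembl"),
      mk("REJ_MALF", ch$smiles[7], 1.0, "~", "IC50", "B", 8, hs, "chembl"))
    # salted duplicates of curated structures with larger values: curation
    # keeps them, deduplication must merge them back onto the minimum
    dup <- mk(sprintf("DUP%02d", 1:5), paste0(ch$smiles[1:5], ".Cl"),
              ch_val[1:5] + 5, "=", "IC50", "B", 9, hs, "chembl")
    chembl <- rbind(chembl, bad, dup)

    ha <- take(72)
    harris <- mk(sprintf("HARRIS%03d", 1:72), ha$smiles,
                 c(runif(60, 0.01, 1.5), runif(12, 3, 40)), "=", "Ki", "B",
                 9, hs, "harris")
    ro <- take(118)
    roche <- mk(sprintf("ROCHE%03d", 1:118), ro$smiles,
                c(runif(75, 0.01, 1.8), runif(43, 2.2, 60)), "=", "IC50",
                "B", 9, hs, "roche")
    pc <- take(277)
    pubchem <- mk(sprintf("PUBCHEM%03d", 1:277), pc$smiles,
                  runif(277, 20, 200), "=", "IC50", "B", 8, hs, "pubchem")
  })
  list(chembl = chembl, harris = harris, roche = roche,
       pubchem_pool = pubchem)
}
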