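# Pipeline orchestration: one structured config drives the whole funnel
# (curate/simulate -> fingerprint -> mine -> train -> screen -> consensus ->
# novelty), with per-stage counts recorded in a reproducibility manifest.

#' Default pipeline configuration
#'
#' All tunable parameters with their defaults: activity threshold 2 uM,
#' PLIF similarity cutoff 0.83, robust fingerprints from >= 4 of the top 5
#' poses, signature sizes 2-6 at minimum coverage 0.5, a 100-member
#' random-forest ensemble (700 trees, 90% bags), and the synthetic
#' generator's study conditions.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    curation = list(activity_threshold = 2, confidence_min = 7),
    prefilter = list(enabled = FALSE, qed_min = 0.85, pains = TRUE),
    plif = list(top_n = 5L, min_poses = 4L, sim_cutoff = 0.83,
                percentile = 80),
    mining = list(min_size = 2L, max_size = 6L, min_coverage = 0.5),
    qsar = list(optimize = FALSE, n_trees = 700L,
                blocks = c("physchem", "residue_contacts"),
                trees_grid = seq(100L, 1000L, by = 100L), cv_folds = 10L,
                n_members = 100L, bag_fraction = 0.9, test_fraction = 0.3,
                ad_bandwidth = 0.25, ad_coverage = 0.3),
    screen = list(k = 50L, min_mcs_atoms = 3L, mcs_timeout = 5,
                  reference_size = 40L),
    generator = list(n_active = 300L, n_inactive = 300L,
                     p_contact_active = 0.61, p_contact_inactive = 0.25,
                     background_p = 0.45, n_poses = 10L,
                     pose_flip_noise = 0.05, library_size = 1000L,
                     hit_fraction = 0.05),
    inputs = list(labeled_compounds = NULL, labeled_contacts = NULL,
                  library_compounds = NULL, library_contacts = NULL,
                  reference_plif = NULL)
  )
}

merge_config <- function(base, override, path = character(0)) {
  bad <- character(0)
  for (nm in names(override)) {
    key <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) { bad <- c(bad, key); next }
    if (is.null(override[[nm]])) next    # YAML null: keep the default
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      res <- merge_config(base[[nm]], override[[nm]], c(path, nm))
      base[[nm]] <- res$config
      bad <- c(bad, res$bad)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  list(config = base, bad = bad)
}

validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(config$curation$activity_threshold > 0,
      "curation.activity_threshold must be > 0")
  chk(config$plif$sim_cutoff >= 0 && config$plif$sim_cutoff <= 1,
      "plif.sim_cutoff must lie in [0, 1]")
  chk(config$plif$min_poses <= config$plif$top_n,
      "plif.min_poses must be <= plif.top_n")
  chk(config$mining$min_size >= 1 &&
        config$mining$min_size <= config$mining$max_size,
      "mining sizes must satisfy 1 <= min_size <= max_size")
  chk(config$qsar$bag_fraction > 0 && config$qsar$bag_fraction <= 1,
      "qsar.bag_fraction must lie in (0, 1]")
  chk(config$qsar$ad_coverage > 0 && config$qsar$ad_coverage <= 1,
      "qsar.ad_coverage must lie in (0, 1]")
  chk(config$screen$k >= 0, "screen.k must be >= 0")
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  invisible(config)
}

#' Load a pipeline configuration from YAML
#'
#' Fills unspecified values with [default_config()] defaults, rejects
#' unknown keys (every offending key is listed), validates values, and
#' echoes the effective configuration to the message stream.
#'
#' @param path YAML file path.
#' @param quiet suppress the config echo.
#' @return validated config list.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  res <- merge_config(default_config(), user %||% list())
  if (length(res$bad))
    stop("unknown config keys: ", paste(res$bad, collapse = ", "))
  config <- validate_config(res$config)
  if (!quiet)
    message("config: ", jsonlite::toJSON(config, auto_unbox = TRUE,
                                         null = "null"))
  config
}

#' Save a pipeline configuration to YAML
#'
#' @param config config list.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

generator_from_config <- function(config) {
  g <- config$generator
  generator_config(n_active = g$n_active, n_inactive = g$n_inactive,
                   p_contact_active = g$p_contact_active,
                   p_contact_inactive = g$p_contact_inactive,
                   background_p = g$background_p, n_poses = g$n_poses,
                   pose_flip_noise = g$pose_flip_noise,
                   library_size = g$library_size,
                   hit_fraction = g$hit_fraction, seed = config$seed)
}

load_labeled_inputs <- function(config) {
  inp <- config$inputs
  compounds <- read.csv(inp$labeled_compounds, stringsAsFactors = FALSE)
  tables <- read_contact_tables(inp$labeled_contacts)
  tables <- tables[compounds$compound_id]
  labels <- binarize_activity(compounds$value_um, compounds$relation,
                              config$curation$activity_threshold)
  list(compounds = compounds, labels = labels, pose_tables = tables)
}

#' Run the full screening funnel
#'
#' Executes every stage in order on either synthetic data (default) or
#' file inputs named in `config$inputs`: labeled-set fingerprinting,
#' signature mining, QSAR ensemble training with reliability-density
#' applicability domain, docking-rules screening of the library, consensus
#' selection and novelty reporting. Per-stage counts (the funnel) and a
#' config hash go into the manifest; re-running with an identical config
#' reproduces all outputs.
#'
#' @param config config list from [load_config()] / [default_config()].
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @return list of class `screening_run`: `rule`, `sim_cutoff_mined`,
#'   `model`, `test_metrics`, `results`, `hits`, `novelty`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  validate_config(config)
  counts <- list()
  stage <- function(nm) message("stage: ", nm)
  gen <- generator_from_config(config)
  vocab <- gen$residue_vocabulary

  stage("labeled set")
  labeled <- if (!is.null(config$inputs$labeled_compounds))
    load_labeled_inputs(config) else simulate_labeled_set(gen)
  counts$labeled <- length(labeled$labels)

  stage("fingerprints")
  fps <- robust_plif_matrix(labeled$pose_tables, config$plif$top_n,
                            config$plif$min_poses, vocab)
  reference <- if (!is.null(config$inputs$reference_plif))
    read_plif_csv(config$inputs$reference_plif, vocab)
  else interaction_fingerprint(intersect(key_residues(), vocab), vocab)
  sims <- plif_similarity(fps, reference, intersect(key_residues(), vocab))

  stage("signature mining")
  subsets <- enumerate_signatures(intersect(key_residues(), vocab),
                                  config$mining$min_size,
                                  min(config$mining$max_size,
                                      length(intersect(key_residues(), vocab))))
  rules <- score_signatures(subsets, fps, labeled$labels)
  rule <- select_best_signature(rules, config$mining$min_coverage)
  sim_cutoff_mined <- similarity_percentile_cutoff(sims,
                                                   config$plif$percentile)
  counts$signatures_scored <- nrow(rules)

  stage("qsar features")
  features <- compute_features(labeled$compounds)
  x <- assemble_feature_matrix(features, fps)
  split <- split_train_test(labeled$labels, config$qsar$test_fraction,
                            config$seed)
  y <- labeled$labels
  counts$train <- length(split$train); counts$test <- length(split$test)

  stage("qsar training")
  qcfg <- config$qsar
  if (qcfg$optimize) {
    opt <- optimize_hyperparameters(x[split$train, , drop = FALSE],
                                    y[split$train], qcfg$trees_grid,
                                    cv_folds = qcfg$cv_folds,
                                    seed = config$seed)
    n_trees <- opt$n_trees; blocks <- opt$blocks
  } else {
    opt <- NULL; n_trees <- qcfg$n_trees; blocks <- qcfg$blocks
  }
  tags <- attr(x, "block")
  cols <- tags %in% blocks
  xb <- x[, cols, drop = FALSE]; attr(xb, "block") <- tags[cols]
  model <- train_ensemble(xb[split$train, , drop = FALSE], y[split$train],
                          n_trees, qcfg$n_members, qcfg$bag_fraction,
                          config$seed)
  test_pred <- predict_majority(model, xb[split$test, , drop = FALSE])
  test_metrics <- evaluate_predictions(test_pred$predicted_label,
                                       y[split$test])
  correct <- cv_correctness(xb[split$train, , drop = FALSE], y[split$train],
                            qcfg$cv_folds, n_trees, config$seed)

  stage("library")
  library_set <- if (!is.null(config$inputs$library_compounds)) {
    inp <- list(compounds = read.csv(config$inputs$library_compounds,
                                     stringsAsFactors = FALSE),
                pose_tables = read_contact_tables(config$inputs$library_contacts))
    inp$pose_tables <- inp$pose_tables[inp$compounds$compound_id]
    inp$truth <- NULL
    inp
  } else simulate_library(gen)
  lib_compounds <- library_set$compounds
  counts$library <- nrow(lib_compounds)

  if (config$prefilter$enabled) {
    stage("prefilter")
    keep <- prefilter_library(lib_compounds, config$prefilter$qed_min,
                              config$prefilter$pains)
    sel <- lib_compounds$compound_id %in% keep$compound_id
    lib_compounds <- lib_compounds[sel, , drop = FALSE]
    library_set$pose_tables <- library_set$pose_tables[sel]
    counts$prefiltered <- nrow(lib_compounds)
  }

  stage("docking rules")
  lib_fps <- robust_plif_matrix(library_set$pose_tables, config$plif$top_n,
                                config$plif$min_poses, vocab)
  lib_sims <- plif_similarity(lib_fps, reference,
                              intersect(key_residues(), vocab))
  results <- docking_rules_filter(lib_fps, rule, lib_sims,
                                  config$plif$sim_cutoff)
  counts$pass_signature <- sum(results$passes_signature)
  counts$pass_similarity <- sum(results$passes_similarity)
  counts$docking_candidates <- sum(results$docking_candidate)

  stage("qsar screening")
  lib_features <- compute_features(lib_compounds)
  lib_x <- assemble_feature_matrix(lib_features, lib_fps)[, cols, drop = FALSE]
  lib_pred <- predict_majority(model, lib_x)
  lib_rel <- rdn_reliability(features$morgan[split$train, , drop = FALSE],
                             correct, lib_features$morgan,
                             qcfg$ad_bandwidth)
  ad_cutoff <- unname(quantile(lib_rel, 1 - qcfg$ad_coverage, type = 7))
  results$qsar_vote_fraction <- lib_pred$vote_fraction_active
  results$qsar_reliability <- lib_rel
  results$qsar_accepted_active <- lib_pred$predicted_label == "active" &
    lib_rel >= ad_cutoff
  counts$qsar_accepted_actives <- sum(results$qsar_accepted_active)
  counts$tier1 <- sum(results$qsar_accepted_active & results$docking_candidate)

  stage("mcs anchors")
  ref_rows <- which(labeled$labels == "active")[
    seq_len(min(config$screen$reference_size,
                sum(labeled$labels == "active")))]
  anchors <- rep(NA_integer_, nrow(results))
  cand <- which(results$docking_candidate)
  if (length(cand) && !anyNA(lib_compounds$smiles)) {
    ref_sdf <- parse_smiles(labeled$compounds$smiles[ref_rows],
                            labeled$compounds$compound_id[ref_rows])
    cand_sdf <- parse_smiles(lib_compounds$smiles[cand],
                             lib_compounds$compound_id[cand])
    anchors[cand] <- mcs_anchor_sizes(cand_sdf, ref_sdf,
                                      mcs_params(timeout = config$screen$mcs_timeout))
  }
  results$mcs_anchor_size <- anchors

  stage("consensus")
  hits <- consensus_select(results, config$screen$k)
  counts$hits <- nrow(hits)

  stage("novelty")
  novelty <- NULL
  if (nrow(hits) && !anyNA(lib_compounds$smiles)) {
    hit_sdf <- parse_smiles(
      lib_compounds$smiles[match(hits$compound_id, lib_compounds$compound_id)],
      hits$compound_id)
    train_sdf <- parse_smiles(labeled$compounds$smiles[ref_rows],
                              labeled$compounds$compound_id[ref_rows])
    novelty <- novelty_report(hit_sdf, train_sdf,
                              config$screen$min_mcs_atoms,
                              mcs_params(timeout = config$screen$mcs_timeout))
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   counts = counts,
                   rule = paste(rule$residues, collapse = ";"),
                   sim_cutoff_mined = sim_cutoff_mined,
                   ad_cutoff = ad_cutoff,
                   cv_optimized = !is.null(opt))
  run <- structure(list(rule = rule, rules = rules,
                        sim_cutoff_mined = sim_cutoff_mined, model = model,
                        optimization = opt, test_metrics = test_metrics,
                        results = results, hits = hits, novelty = novelty,
                        manifest = manifest, config = config),
                   class = "screening_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.screening_run <- function(x, ...) {
  cat("<screening_run>\n  rule:", paste(x$rule$residues, collapse = ", "),
      sprintf("(ratio %.2f, coverage %.2f)\n", x$rule$ratio, x$rule$coverage))
  cat(sprintf("  test accuracy %.3f | funnel: %s\n", x$test_metrics$accuracy,
              paste(sprintf("%s=%d", names(x$manifest$counts),
                            unlist(x$manifest$counts)), collapse = " ")))
  invisible(x)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$rules, file.path(outdir, "signature_rules.csv"),
            row.names = FALSE)
  write.csv(run$results, file.path(outdir, "screening_results.csv"),
            row.names = FALSE)
  write.csv(run$hits, file.path(outdir, "hits.csv"), row.names = FALSE)
  if (!is.null(run$novelty))
    write.csv(run$novelty, file.path(outdir, "novelty.csv"),
              row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
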