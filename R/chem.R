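# Structure backend. All chemistry I/O goes through OpenBabel via ChemmineOB /
# ChemmineR; the rest of the package only sees SMILES vectors, SDFset objects
# and plain matrices. OpenBabel aborts a batch conversion at the first invalid
# SMILES, so validation is always per molecule.

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to its OpenBabel canonical form. Invalid structures
#' yield `NA` rather than an error so callers can assemble rejects reports.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- sub("[\t\n].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Hashed canonical structure key (InChIKey)
#'
#' @param smiles character vector of *valid* SMILES (see
#'   [canonical_smiles()] for validation).
#' @return character vector of InChIKeys.
#' @export
structure_key <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHIKEY", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- sub("[\t\n].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Strip salts and solvents
#'
#' Keeps the largest covalent component of each (dot-disconnected) SMILES.
#'
#' @param smiles character vector.
#' @return character vector with only the largest component retained.
#' @export
strip_salts <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(s)
    sizes <- vapply(frags, function(f) {
      f2 <- gsub("\\[[^]]*\\]", "Q", f)
      m <- gregexpr("Cl|Br|Si|Se|[BCNOPSFIQ]|[bcnops]", f2)[[1]]
      if (m[1] == -1) 0L else length(m)
    }, integer(1))
    frags[which.max(sizes)]
  }, character(1), USE.NAMES = FALSE)
}

#' Standardize SMILES
#'
#' Salt stripping followed by canonicalization. This is the open-source
#' standardization step used throughout the package; tautomer/protomer
#' normalization beyond OpenBabel's canonical form is not attempted.
#'
#' @inheritParams canonical_smiles
#' @return canonical SMILES of the largest component, `NA` if unparseable.
#' @export
standardize_smiles <- function(smiles) {
  canonical_smiles(strip_salts(smiles))
}

#' Parse SMILES into an SDFset
#'
#' @param smiles character vector of valid SMILES.
#' @param ids compound identifiers, used as compound ids of the set.
#' @return a [ChemmineR::SDFset-class] object.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  stopifnot(length(smiles) >= 1L, !anyNA(smiles))
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  if (length(sdf) != length(smiles))
    stop("some SMILES failed to parse; standardize first and remove rejects")
  ChemmineR::cid(sdf) <- as.character(ids)
  sdf
}

#' Heavy-atom counts
#'
#' @param sdf an SDFset.
#' @return integer vector of non-hydrogen atom counts.
#' @export
heavy_atom_counts <- function(sdf) {
  vapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    sum(!grepl("^H_", rownames(ab)))
  }, integer(1))
}

#' Radius-2 circular (Morgan) fingerprints, 1024 bits
#'
#' ECFP4 fingerprints from OpenBabel (4096 bits) folded by OR to the
#' requested width.
#'
#' @param sdf an SDFset.
#' @param n_bits fingerprint width after folding (default 1024).
#' @return binary integer matrix, one row per compound.
#' @export
morgan_fp <- function(sdf, n_bits = 1024L) {
  raw <- methods::slot(suppressWarnings(ChemmineR::fingerprintOB(sdf, "ECFP4")),
                       "fpma")
  stopifnot(ncol(raw) %% n_bits == 0)
  folds <- ncol(raw) / n_bits
  out <- matrix(0L, nrow(raw), n_bits)
  for (f in seq_len(folds))
    out <- out | raw[, ((f - 1L) * n_bits + 1L):(f * n_bits), drop = FALSE]
  out <- matrix(as.integer(out), nrow(raw), n_bits)
  rownames(out) <- ChemmineR::cid(sdf)
  colnames(out) <- paste0("fp", seq_len(n_bits))
  out
}

# named SMARTS count panel; patterns kept OpenBabel-friendly
smarts_panel <- function() c(
  n_rotatable      = "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]",
  n_amide          = "C(=O)N",
  n_ester          = "[CX3](=O)[OX2][#6]",
  n_carboxylic_acid = "C(=O)[OX2H1]",
  n_ketone         = "[#6][CX3](=O)[#6]",
  n_aldehyde       = "[CX3H1]=O",
  n_hydroxyl       = "[OX2H]",
  n_phenol         = "[OX2H]c",
  n_ether          = "[OD2]([#6])[#6]",
  n_amine_primary  = "[NX3;H2;!$(NC=O)]",
  n_amine_secondary = "[NX3;H1;!$(NC=O)]",
  n_amine_tertiary = "[NX3;H0;!$(NC=O);!$(N=*)]",
  n_aromatic_n     = "n",
  n_aromatic_o     = "o",
  n_aromatic_s     = "s",
  n_nitrile        = "C#N",
  n_nitro          = "[N+](=O)[O-]",
  n_sulfonyl       = "S(=O)(=O)",
  n_halogen        = "[F,Cl,Br,I]",
  n_thioether      = "[SD2]([#6])[#6]"
)

count_smarts <- function(sdf, patterns) {
  out <- vapply(patterns, function(p)
    as.integer(suppressWarnings(ChemmineR::smartsSearchOB(sdf, p))),
    integer(length(sdf)))
  if (length(sdf) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(patterns)))
  rownames(out) <- ChemmineR::cid(sdf)
  out
}

# ring counts (size-capped so fused-ring envelopes are not counted)
ring_counts <- function(sdf) {
  rc <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 8, type = "count", arom = TRUE)),
    error = function(e) NULL)
  if (is.null(rc)) {
    m <- matrix(0L, length(sdf), 2, dimnames = list(NULL, c("RINGS", "AROMATIC")))
    return(m)
  }
  if (is.null(dim(rc))) rc <- matrix(rc, nrow = 1L,
                                     dimnames = list(NULL, names(rc)))
  rc
}

#' Names of the physicochemical descriptor panel
#'
#' The panel order is frozen: feature matrices are column-stable across runs.
#' @return character vector of descriptor names.
#' @export
physchem_names <- function() {
  c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
    "n_heavy", "n_bonds", "n_single", "n_double", "n_triple",
    "n_rings", "n_aromatic_rings",
    "n_C", "n_N", "n_O", "n_S", "n_hetero", "frac_hetero",
    names(smarts_panel()))
}

#' Physicochemical descriptor panel
#'
#' Fixed-order named descriptor matrix combining OpenBabel whole-molecule
#' properties (MW, logP, TPSA, molar refractivity, H-bond counts), molecular
#' graph counts, and SMARTS-defined functional-group counts.
#'
#' @param sdf an SDFset.
#' @return numeric matrix, rows = compounds, columns = [physchem_names()].
#' @export
physchem_panel <- function(sdf) {
  props <- suppressWarnings(ChemmineR::propOB(sdf))
  graph <- t(vapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    el <- sub("_.*$", "", rownames(ab))
    heavy <- el != "H"
    ords <- if (nrow(bb) > 0) bb[, 3] else integer(0)
    c(n_heavy = sum(heavy),
      n_bonds = nrow(bb),
      n_single = sum(ords == 1), n_double = sum(ords == 2),
      n_triple = sum(ords == 3),
      n_C = sum(el == "C"), n_N = sum(el == "N"),
      n_O = sum(el == "O"), n_S = sum(el == "S"),
      n_hetero = sum(heavy & el != "C"))
  }, numeric(10)))
  rc <- ring_counts(sdf)
  sm <- count_smarts(sdf, smarts_panel())
  out <- cbind(
    MW = props$MW, logP = props$logP, TPSA = props$TPSA, MR = props$MR,
    HBA1 = props$HBA1, HBA2 = props$HBA2, HBD = props$HBD, nF = props$nF,
    graph[, c("n_heavy", "n_bonds", "n_single", "n_double", "n_triple"),
          drop = FALSE],
    n_rings = rc[, "RINGS"], n_aromatic_rings = rc[, "AROMATIC"],
    graph[, c("n_C", "n_N", "n_O", "n_S", "n_hetero"), drop = FALSE],
    frac_hetero = graph[, "n_hetero"] / pmax(graph[, "n_heavy"], 1),
    sm)
  rownames(out) <- ChemmineR::cid(sdf)
  out[, physchem_names(), drop = FALSE]
}

## ---- drug-likeness -------------------------------------------------------

# Asymmetric double sigmoid desirability parameters for the QED score
# (Bickerton et al. parameterization; columns a..f, dmax).
qed_ads_params <- function() {
  m <- rbind(
    MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
    ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
    HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
    HBD    = c(1.618662227, 1010.051101, 0.985094388, 1e-09, 0.713820843, 0.920922555, 258.1632616),
    PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
    ROTB   = c(0.01, 272.4121427, 2.55837997, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
    AROM   = c(3.21778897, 957.7374108, 2.274627939, 1e-09, 1.317690384, 0.375760881, 312.337261),
    ALERTS = c(0.01, 1199.094025, -0.09002883, 1e-09, 0.185904477, 0.875193782, 417.725314))
  colnames(m) <- c("a", "b", "c", "d", "e", "f", "dmax")
  m
}

qed_weights <- function() c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                            PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  (p["a"] +
     p["b"] / (1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])) *
     (1 - 1 / (1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])))) / p["dmax"]
}

# small built-in set of structural alerts feeding the QED ALERTS term
alert_patterns <- function() c(
  nitro       = "[N+](=O)[O-]",
  azide       = "N=[N+]=[N-]",
  azo         = "N=N",
  acyl_halide = "C(=O)[F,Cl,Br,I]",
  aldehyde    = "[CX3H1]=O",
  thiol       = "[SX2H]",
  peroxide    = "[OX2][OX2]",
  isocyanate  = "N=C=O",
  epoxide     = "C1OC1",
  hydrazine   = "[NX3][NX3]",
  michael_acceptor = "C=CC(=O)[#6]",
  polyene     = "[C;!R]=[C;!R][C;!R]=[C;!R]"
)

#' QED component properties
#'
#' @param sdf an SDFset.
#' @return data.frame with columns MW, ALOGP, HBA, HBD, PSA, ROTB, AROM,
#'   ALERTS (count of matched structural-alert patterns).
#' @export
qed_properties <- function(sdf) {
  props <- suppressWarnings(ChemmineR::propOB(sdf))
  rc <- ring_counts(sdf)
  rotb <- as.integer(suppressWarnings(
    ChemmineR::smartsSearchOB(sdf, smarts_panel()[["n_rotatable"]])))
  alerts <- count_smarts(sdf, alert_patterns())
  data.frame(MW = props$MW, ALOGP = props$logP, HBA = props$HBA2,
             HBD = props$HBD, PSA = props$TPSA, ROTB = rotb,
             AROM = rc[, "AROMATIC"],
             ALERTS = rowSums(alerts > 0),
             row.names = ChemmineR::cid(sdf))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted-desirability QED built on the backend's property values. Property
#' values (logP, H-bond acceptor counts) come from OpenBabel, so absolute QED
#' values differ slightly from implementations built on other toolkits; the
#' desirability aggregation itself follows the published parameterization.
#'
#' @param x an SDFset, or a data.frame as returned by [qed_properties()].
#' @return numeric vector of QED scores in `[0, 1]`.
#' @export
qed_score <- function(x) {
  props <- if (is.data.frame(x)) x else qed_properties(x)
  ads <- qed_ads_params()
  w <- qed_weights()
  d <- vapply(rownames(ads), function(nm)
    unname(qed_ads(props[[nm]], ads[nm, ])), numeric(nrow(props)))
  if (nrow(props) == 1L) d <- matrix(d, nrow = 1L, dimnames = list(NULL, rownames(ads)))
  exp(as.vector(d %hlog% w))
}

# weighted geometric-mean helper: exp(sum(w*log(d))/sum(w)) row-wise
`%hlog%` <- function(d, w) {
  (log(pmax(d, 1e-12)) %*% w) / sum(w)
}

#' Built-in PAINS substructure patterns
#'
#' A compact set of pan-assay interference (PAINS) family motifs expressed as
#' OpenBabel-compatible SMARTS. It covers the most frequently matched PAINS
#' families (quinones, catechols, ene-rhodanines and related exocyclic-ene
#' heterocycles, hydroxyphenyl hydrazones, aryl azos, beta-diketones); it is
#' not the full published catalogue. Supply a two-column file
#' (name, smarts) to screen with a custom list.
#'
#' @param file optional path to a whitespace-separated file with columns
#'   `name` and `smarts`.
#' @return named character vector of SMARTS.
#' @export
pains_patterns <- function(file = NULL) {
  if (!is.null(file)) {
    tab <- read.table(file, header = TRUE, stringsAsFactors = FALSE)
    return(stats::setNames(tab$smarts, tab$name))
  }
  c(para_quinone        = "O=C1C=CC(=O)C=C1",
    ortho_quinone       = "O=C1C(=O)C=CC=C1",
    catechol            = "[OX2H]c1ccccc1[OX2H]",
    ene_rhodanine       = "C=C1SC(=S)NC1=O",
    ene_thiazolidinedione = "C=C1SC(=O)NC1=O",
    alkylidene_barbiturate = "C=C1C(=O)NC(=O)NC1=O",
    hydroxyphenyl_hydrazone = "[OX2H]c1ccccc1C=NN",
    aryl_azo            = "cN=Nc",
    beta_diketone       = "C(=O)CC(=O)",
    enamine_nitrile     = "N#CC=CN",
    imine_phenol        = "[OX2H]c1ccccc1C=N",
    isothiazolone       = "O=C1C=CSN1")
}

#' Flag compounds matching PAINS patterns
#'
#' @param sdf an SDFset.
#' @param patterns named SMARTS vector, default [pains_patterns()].
#' @return logical vector, `TRUE` when any pattern matches.
#' @export
pains_flags <- function(sdf, patterns = pains_patterns()) {
  hits <- count_smarts(sdf, patterns)
  rowSums(hits > 0) > 0
}
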