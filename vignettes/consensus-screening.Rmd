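---
title: "Consensus docking + QSAR screening for RIPK1 inhibitors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus docking + QSAR screening for RIPK1 inhibitors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripscreen)
```

## The problem

Necroptosis is a programmed, caspase-independent form of necrotic cell
death driven by RIPK1, RIPK3 and MLKL, and RIPK1 inhibition is a drug
target in inflammatory, neurodegenerative and ischemic disease. RIPK1 has
an unusual, narrow, "L"-shaped allosteric back pocket (the DLG-out
inactive conformation), and docking scores alone rank compounds poorly
against it: enrichment curves for raw docking score or ligand efficiency
degrade at the strictest cutoffs. `ripscreen` implements an alternative
screening strategy that exploits the *geometry* of docking poses rather
than their scores: protein-ligand interaction fingerprints (PLIFs),
residue-signature rules mined from them, and an ensemble random-forest
QSAR model, combined by consensus.

## The screening funnel

1. **Curation and binarization.** Bioactivity records are kept when they
   pass binding-assay quality filters (confidence strictly above 7, assay
   type "B", human target, IC50/Ki/Kd). A compound is *active* when its
   activity is strictly below 2 uM; `"<"`-censored values use the bound as
   the effective value, `">"`-censored values are inactive. Censored
   relations are admissible only on the side of the threshold they can
   still classify. Structures are salt-stripped, canonicalized, keyed by
   InChIKey, and duplicates merged onto the minimum value. Classes are
   balanced by sampling additional inactives from a confirmatory-assay
   pool.

2. **Robust PLIFs.** For each compound, a residue bit is set only when the
   residue is contacted in at least 4 of the top 5 docking poses. This
   deliberately ignores single-pose evidence: the top pose's score does
   not track activity, but contacts that persist across the best poses do.

3. **Signature mining.** Over the six key pocket residues (LEU70, VAL75,
   LEU78 from the binding loop, LEU129 from the alpha-E helix, ASP156 and
   LEU157 from the DLG motif), all `r length(enumerate_signatures(key_residues(), 2, 6))`
   residue subsets of sizes 2-6 are scored by how often actives versus
   inactives contact *all* subset residues simultaneously. The selected
   rule maximizes the active:inactive frequency ratio among rules covering
   at least half of the actives. Ratio rather than absolute difference is
   used as the headline criterion because the contrast of interest is
   multiplicative ("x times more frequent in actives"); the coverage floor
   of 0.5 keeps high-ratio but rarely-matching subsets out.

4. **PLIF similarity.** Tanimoto similarity between a compound's
   fingerprint and a reference-ligand fingerprint, restricted to the six
   key residues. The operational cutoff is the 80th percentile of the
   similarity distribution (strictly above passes); on the original data
   that percentile corresponds to similarity 0.83, which is the shipped
   default cutoff.

5. **QSAR ensemble.** Features come in three blocks: a physicochemical
   descriptor panel, 1024-bit radius-2 circular (Morgan) fingerprints, and
   the six key-residue contacts. Tree count (100-1000, step 100) and the
   seven non-empty block combinations are selected by stratified 10-fold
   cross-validation accuracy. The final classifier is an ensemble of 100
   random forests, each trained on an independent 90% sample of the
   training rows drawn without replacement; a compound is predicted active
   only when strictly more than 50% of members vote active (an exact tie
   is inactive).

6. **Applicability domains.** Two, one per model family.
   *QSAR:* a reliability-density score — each query accumulates
   Gaussian-kernel-weighted (bandwidth 0.25 on Tanimoto distance over the
   Morgan block) evidence from training compounds that were predicted
   correctly under cross-validation. The score is an unnormalized kernel
   sum: sparse neighborhoods and neighborhoods of poorly-predicted
   compounds both score low. Only predictions above a reliability cutoff
   are *accepted*. *Docking:* a query must share a sufficiently large
   connected maximum common substructure (MCS) with the reference compound
   set; candidates are ranked by that anchor size.

7. **Consensus and novelty.** Tier-1 hits pass both docking rules *and*
   are accepted QSAR actives; remaining slots up to `k` are backfilled
   from docking-only candidates in decreasing MCS-anchor order. For each
   hit, the novelty report finds the training compound with the largest
   MCS and reports the shared heavy-atom fraction on both sides.

## What the synthetic generator emulates

No public data ships with the package; every stage is exercised against a
seeded generator (`generator_config()`, `simulate_labeled_set()`,
`simulate_library()`) whose defaults *are* the study conditions used by
the test suite and the acceptance script:

- **Structures** come from a fragment-decoration grammar (10 scaffolds x
  20 x 20 substituents), canonicalized and deduplicated by InChIKey, so
  they are valid, unique, and survive re-standardization byte-identically.
- **Planted signature.** A compound *carries* the four-residue signature
  (all four residues present in its underlying contact profile) with
  probability 0.61 for actives and 0.25 for inactives — the observed
  co-contact contrast, giving the analytic enrichment ratio
  0.61/0.25 = 2.44. Carrying is all-or-none: modeling the published
  *joint* contact frequencies requires the signature to be planted as a
  unit, not as independent per-residue coin flips (independent 0.61 draws
  would give a co-contact rate of only 0.61^4 = 0.14).
- **Background contacts.** Every residue not fixed by a carried signature
  is contacted with probability 0.45. The value reflects that common
  pocket residues are contacted by nearly half of all docked compounds
  regardless of class — which is precisely why single-residue frequencies
  separate the classes poorly and only the joint signature is
  discriminative. It also sets the false-positive rate of the signature
  filter at 0.45^4 = 4.1% per background compound, the closed-form
  expectation the funnel tests check.
- **Poses and noise.** 10 poses per compound (a speed-scaled stand-in for
  a 50-pose docking run; the robust-PLIF rule only consumes the top 5),
  per-pose contact flip noise 5%, and class-conditional Gaussian scores
  with inactives slightly *higher* (mean 52 vs 50, sd 5) — scores are
  deliberately anti-informative, as observed for this pocket.
- **Library.** 1000 compounds with exactly 5% planted hits; the hidden
  truth is emitted separately and used only for evaluation.

The generator does **not** emulate: realistic 3D geometry or energetics,
correlated contact patterns beyond the planted signature,
structure-activity coupling (labels are independent of structures in the
default mode), assay noise on activity values, or realistic chemical
diversity. Passing tests therefore demonstrate that the pipeline's logic
and statistics behave as designed under known truth — not that the method
will enrich actives on a particular real target.

A second labeled mode, `simulate_ad_set()`, couples labels *to*
structures (scaffold determines the label) and confines random label
noise to one rare scaffold. Its main scaffolds are drawn from six
structurally distinct templates so the scaffold-label rule is learnable
from fingerprints; the three benzene substitution isomers of the grammar
are deliberately not mixed as separate classes, since they are nearly
identical in folded Morgan space and would add irreducible error
unrelated to the applicability-domain question the fixture exists to
probe.

## Numerical and design choices

- **Boundary conventions.** Activity exactly 2 uM is inactive ("below"
  read strictly); QED exactly at the cutoff is dropped (strict `>`);
  similarity exactly 0.83 fails (strict `>`); a 50% vote tie is inactive.
- **Percentiles** use the linear-interpolation (type-7) convention
  everywhere; selection is strictly above the threshold.
- **Empty denominators.** Precision with no predicted actives, and
  enrichment at a cutoff selecting nothing, are reported as missing —
  never as zero. An empty Tanimoto union scores 0 (no shared evidence).
  A zero inactive-match frequency gives the ratio an infinite sentinel
  that ranks above all finite ratios.
- **Ties in model selection** prefer fewer trees, then fewer feature
  columns, then lexicographic block names; signature-rule ties prefer
  higher coverage, then larger subsets, then lexicographic residue order.
  Consensus backfill ties prefer larger PLIF similarity, then input
  order. All selections are deterministic under a seed.
- **Robust PLIF of short tables.** A table with fewer than `top_n` poses
  is a hard error (the fingerprint is undefined), not a prorated
  threshold.
- **Bagging** is without replacement at 90% (a switch enables
  replacement). Cross-validation folds are stratified by class.
- **Randomness.** Every stochastic step derives its seed from the
  top-level seed; the forest backend's predict-time tie-breaking is also
  pinned. Re-running any stage with the same config reproduces its output
  byte-for-byte.
- **MCS matching** defaults to connected, element-, ring-membership- and
  bond-order-sensitive matching on the kekulized heavy-atom graph, with a
  5 s per-pair budget; on timeout the best size found is returned and
  flagged as a lower bound.
- **Structure standardization** is salt stripping plus OpenBabel
  canonicalization with InChIKey keys. Tautomer/protomer normalization at
  pH 7.4 (commercial-tool territory) is not attempted; InChIKey's own
  tautomer-insensitive layer absorbs part of the difference.
- **Descriptor panel.** The physicochemical block is the full frozen
  panel of the chosen backend — OpenBabel whole-molecule properties plus
  molecular-graph and SMARTS-defined group counts,
  `r length(physchem_names())` descriptors in fixed order. That is
  smaller than the ~200-descriptor panels of other toolkits; the block's
  role in the model (a dense physicochemical summary next to the sparse
  fingerprint block) is unchanged.
- **QED and PAINS.** QED is computed from the published desirability
  parameterization on the backend's property values; absolute values
  differ slightly from other toolkits because logP and acceptor counts
  do. The PAINS screen ships a compact built-in subset of the most
  frequently matched family motifs and accepts a user-supplied SMARTS
  file for the full catalogue.
- **Reliability-density AD.** The published reliability-density
  neighborhood idea is adapted, not reproduced: the kernel, bandwidth and
  acceptance scale here are this package's own (documented above), so
  reliability values are not numerically comparable to other
  implementations — only the qualitative precision/coverage trade-off is.
  The AD interface is a plain numeric score, so alternative definitions
  can be swapped in.
- **Backfill policy.** When tier-1 consensus hits are fewer than `k`, the
  original workflow topped the list up with further docking hits subject
  to vendor availability; availability is not modelable, so backfill is
  deterministic by MCS-anchor rank instead.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run, per check: signature
recovery on 300 + 300 compounds x 100 replicates (contact level);
oracle-equivalence suites on 100 random small fixtures per operation; the
funnel on a 1000-compound library at zero pose noise; block-combination
search on 300 compounds x 20 replicates at a single mid-grid tree count
(the full 70-configuration grid is exercised separately at small n);
applicability-domain evaluation on ~200 structures x 20 estimator seeds;
and one full default-conditions pipeline run with a 50-member ensemble.
These sizes were chosen so the whole battery completes on a single CPU in
minutes while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

- The contact detector is a simplified geometric backend (distance and
  donor-angle rules for hydrophobic and hydrogen-bond contacts); water
  bridges, metal coordination, halogen-bond geometry and salt-bridge
  typing are out of scope. Externally computed contact tables are the
  intended input for production use.
- No statistical significance testing of signatures; frequencies and
  ratios only.
- No probability calibration of the vote fraction.
- The MCS search is exact branch-and-bound and scales to drug-like
  molecules; for much larger structures the per-pair timeout converts
  results into flagged lower bounds.
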