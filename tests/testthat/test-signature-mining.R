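# signature enumeration, scoring, selection; ligand efficiency; enrichment

test_that("subset enumeration is complete, unique and deterministically ordered", {
  subs <- enumerate_signatures(key_residues(), 2, 6)
  expect_length(subs, 57)
  expect_length(enumerate_signatures(c("A1", "A2"), 2, 2), 1)
  expect_length(enumerate_signatures(paste0("R", 1:4), 2, 3), 10)
  keys <- vapply(subs, paste, character(1), collapse = ";")
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(subs, enumerate_signatures(key_residues(), 2, 6))
  sizes <- lengths(subs)
  expect_true(all(diff(sizes) >= 0))
  expect_error(enumerate_signatures(key_residues(), 0, 3), "min_size")
  expect_error(enumerate_signatures(key_residues(), 2, 9), "max_size")
  # cardinality equals the binomial-coefficient sum for random vocabularies
  for (i in 1:20) {
    set.seed(i)
    n <- sample(3:12, 1)
    a <- sample.int(n, 1)
    b <- (a:n)[sample.int(n - a + 1, 1)]
    got <- length(enumerate_signatures(paste0("R", 1:n), a, b))
    expect_identical(got, as.integer(sum(choose(n, a:b))))
  }
})

test_that("signature scoring counts simultaneous contacts per class", {
  vocab <- c("LEU70", "VAL75", "ASP156")
  fps <- rbind(matrix(rep(c(1, 1, 0), 6), 6, 3, byrow = TRUE),
               matrix(0, 4, 3),
               matrix(rep(c(1, 1, 1), 2), 2, 3, byrow = TRUE),
               matrix(0, 8, 3))
  colnames(fps) <- vocab
  labels <- rep(c("active", "inactive"), each = 10)
  r <- score_signature(c("LEU70", "VAL75"), fps, labels)
  expect_equal(r$freq_active, 0.6)
  expect_equal(r$freq_inactive, 0.2)
  expect_equal(r$ratio, 3.0)
  expect_equal(r$coverage, 0.6)
  zi <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(NULL, "LEU70"))
  none <- score_signature("LEU70", zi,
                          c("active", "active", "inactive", "inactive"))
  expect_identical(none$ratio, Inf)
  expect_error(score_signature(character(0), fps, labels), "empty")
  expect_error(score_signature("LEU70", fps, rep("active", 20)), "both")
})

test_that("signature scoring matches the counting oracle and is monotone", {
  vocab <- paste0("R", 1:10)
  for (i in 1:100) {
    fps <- random_plif_matrix(sample(20:60, 1), vocab, 0.5, seed = i)
    labels <- rep(c("active", "inactive"),
                  c(nrow(fps) %/% 2, nrow(fps) - nrow(fps) %/% 2))
    set.seed(i + 1000)
    sub <- sample(vocab, sample(1:4, 1))
    got <- score_signature(sub, fps, labels)
    want <- oracle_score_signature(sub, fps, labels)
    expect_equal(got$freq_active, want$freq_active)
    expect_equal(got$freq_inactive, want$freq_inactive)
    expect_equal(got$ratio, want$ratio)
    # adding a residue can only shrink both frequencies
    extra <- sample(setdiff(vocab, sub), 1)
    grown <- score_signature(c(sub, extra), fps, labels)
    expect_lte(grown$freq_active, got$freq_active)
    expect_lte(grown$freq_inactive, got$freq_inactive)
  }
})

test_that("rule selection honors the coverage floor and tie-breaks", {
  rules <- data.frame(residues = c("A;B", "C;D", "E;F"), size = 2,
                      freq_active = c(0.6, 0.1, 0.6),
                      freq_inactive = c(0.2, 0.02, 0.3),
                      ratio = c(3, 5, 2), coverage = c(0.6, 0.1, 0.6),
                      stringsAsFactors = FALSE)
  best <- select_best_signature(rules, 0.5)
  expect_identical(best$residues, c("A", "B"))
  # tie on ratio prefers higher coverage
  tie <- rules; tie$ratio <- 3; tie$coverage <- c(0.6, 0.1, 0.7)
  tie$freq_active <- tie$coverage
  expect_identical(select_best_signature(tie, 0.5)$residues, c("E", "F"))
  expect_error(select_best_signature(rules[0, ]), "empty")
  expect_error(select_best_signature(rules, 0.95), "coverage")
})

test_that("signature filter demands all rule residues simultaneously", {
  vocab <- key_residues()
  fps <- rbind(all4 = as.integer(vocab %in% signature_residues()),
               miss1 = as.integer(vocab %in% signature_residues()[-1]),
               zero = rep(0L, 6))
  colnames(fps) <- vocab
  got <- apply_signature_filter(fps, signature_residues())
  expect_identical(unname(got), c(TRUE, FALSE, FALSE))
  expect_error(apply_signature_filter(fps, c("LEU70", "XXX9")), "absent")
})

test_that("ligand efficiency divides score by heavy atoms", {
  expect_equal(ligand_efficiency(50, 25), 2)
  expect_equal(ligand_efficiency(0, 12), 0)
  expect_error(ligand_efficiency(10, 0), "heavy_atoms")
})

test_that("enrichment curve equals the selection-and-count oracle", {
  # perfectly separating score: full precision at cutoffs inside prevalence
  scores <- c(10:6, 5:1)
  labels <- rep(c("active", "inactive"), each = 5)
  ec <- enrichment_curve(scores, labels, c(50, 60, 70, 80, 90))
  expect_true(all(ec$precision == 1))
  expect_true(all(diff(ec$n_selected) <= 0))
  all_act <- enrichment_curve(1:20, rep("active", 20))
  expect_true(all(all_act$precision == 1, na.rm = TRUE))
  for (i in 1:100) {
    set.seed(i)
    n <- sample(15:60, 1)
    sc <- rnorm(n); lb <- sample(c("active", "inactive"), n, replace = TRUE)
    p <- sample(seq(0, 95, 5), 1)
    got <- enrichment_curve(sc, lb, p)
    want <- oracle_enrichment(sc, lb, p)
    expect_identical(got$n_selected, want$n)
    expect_equal(got$precision, want$precision)
  }
  # empty selection reports NA, never zero
  top <- enrichment_curve(rep(1, 5), rep("inactive", 5), 50)
  expect_identical(top$n_selected, 0L)
  expect_true(is.na(top$precision))
})
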