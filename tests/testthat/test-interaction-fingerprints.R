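# robust PLIFs, Tanimoto similarity, percentile cutoffs, contact detection

vocab6 <- key_residues()

simple_table <- function(contact_poses, residue = "LEU70", n_poses = 6) {
  scores <- data.frame(pose_index = 1:n_poses, score = n_poses:1)
  contacts <- data.frame(pose_index = contact_poses,
                         residue_id = rep(residue, length(contact_poses)),
                         interaction_type = "hydrophobic",
                         stringsAsFactors = FALSE)
  pose_contact_table("cpd", scores, contacts)
}

test_that("robust fingerprint requires >= min_poses of the top-n poses", {
  expect_identical(unname(robust_plif(simple_table(1:4))$bits["LEU70"]), 1L)
  expect_identical(unname(robust_plif(simple_table(1:3))$bits["LEU70"]), 0L)
  expect_identical(unname(robust_plif(simple_table(6))$bits["LEU70"]), 0L)
  short <- pose_contact_table("s", data.frame(pose_index = 1:4, score = 4:1),
                              data.frame(pose_index = 1, residue_id = "LEU70",
                                         interaction_type = "hydrophobic"))
  expect_error(robust_plif(short), "poses")
})

test_that("robust fingerprint matches the brute-force pose-count oracle", {
  vocab <- paste0("RES", 1:20)
  for (i in 1:100) {
    tab <- random_pose_table("x", n_poses = sample(5:10, 1), vocab, seed = i)
    got <- robust_plif(tab, vocabulary = vocab)$bits
    expect_identical(got, oracle_robust_plif(tab, 5, 4, vocab))
  }
})

test_that("poses outside the top-n never change the fingerprint", {
  for (i in 1:20) {
    tab <- random_pose_table("x", 7, paste0("R", 1:8), seed = i)
    base <- robust_plif(tab, vocabulary = paste0("R", 1:8))
    worse <- min(tab$scores$score) - 10
    extra <- pose_contact_table("x",
      rbind(tab$scores, data.frame(pose_index = 99, score = worse)),
      rbind(tab$contacts,
            data.frame(pose_index = 99, residue_id = "R1",
                       interaction_type = "hydrophobic")))
    expect_identical(robust_plif(extra, vocabulary = paste0("R", 1:8))$bits,
                     base$bits)
  }
})

test_that("tanimoto similarity follows set arithmetic and is symmetric", {
  a <- interaction_fingerprint(c("LEU70", "VAL75", "ASP156"), vocab6)
  b <- interaction_fingerprint(c("LEU70", "ASP156", "LEU157"), vocab6)
  expect_equal(plif_tanimoto(a, b), 0.5)
  expect_equal(plif_tanimoto(a, a), 1)
  disj <- interaction_fingerprint("LEU129", vocab6)
  expect_equal(plif_tanimoto(a, disj), 0)
  empty <- interaction_fingerprint(character(0), vocab6)
  expect_equal(plif_tanimoto(empty, empty), 0)
  other <- interaction_fingerprint("X1", c("X1", "X2"))
  expect_error(plif_tanimoto(a, other), "vocabular")
  # random set-enumeration oracle, with and without subset restriction
  for (i in 1:100) {
    set.seed(i)
    on_a <- sample(vocab6, sample(0:6, 1))
    on_b <- sample(vocab6, sample(0:6, 1))
    fa <- interaction_fingerprint(on_a, vocab6)
    fb <- interaction_fingerprint(on_b, vocab6)
    expect_equal(plif_tanimoto(fa, fb), oracle_tanimoto(on_a, on_b))
    expect_equal(plif_tanimoto(fa, fb), plif_tanimoto(fb, fa))
    sub <- sample(vocab6, 3)
    expect_equal(plif_tanimoto(fa, fb, sub),
                 oracle_tanimoto(intersect(on_a, sub), intersect(on_b, sub)))
  }
})

test_that("matrix similarity to a reference agrees with pairwise tanimoto", {
  ref <- interaction_fingerprint(signature_residues(), vocab6)
  m <- random_plif_matrix(40, vocab6, 0.4, seed = 3)
  sims <- plif_similarity(m, ref, vocab6)
  for (i in seq_len(10)) {
    fi <- interaction_fingerprint(m[i, ], vocab6)
    expect_equal(unname(sims[i]), plif_tanimoto(fi, ref))
  }
})

test_that("percentile cutoff uses the linear-interpolation convention", {
  expect_equal(similarity_percentile_cutoff(rep(0.4, 9), 80), 0.4)
  x <- seq(0.1, 1.0, by = 0.1)
  h <- (10 - 1) * 0.8
  expected <- sort(x)[floor(h) + 1] +
    (h - floor(h)) * (sort(x)[floor(h) + 2] - sort(x)[floor(h) + 1])
  expect_equal(similarity_percentile_cutoff(x, 80), expected)
  expect_equal(similarity_percentile_cutoff(x, 0), min(x))
  expect_error(similarity_percentile_cutoff(numeric(0)), "no similarities")
})

test_that("geometric contact detector applies distance and angle rules", {
  protein <- data.frame(x = c(0, 10), y = 0, z = 0, element = c("C", "O"),
                        residue_id = c("LEU70", "ASP156"),
                        stringsAsFactors = FALSE)
  lig_close <- data.frame(x = 3.5, y = 0, z = 0, element = "C")
  got <- detect_contacts(lig_close, protein)
  expect_identical(got$residue_id, "LEU70")
  expect_identical(got$interaction_type, "hydrophobic")
  lig_far <- data.frame(x = 4.5, y = 0, z = 0, element = "C")
  expect_identical(nrow(detect_contacts(lig_far, protein)), 0L)
  # donor N at 2.9 A from acceptor O, neighbor placed for a 150 degree angle
  ang <- 150 * pi / 180
  lig_hb <- data.frame(x = 10 - 2.9, y = 0, z = 0, element = "N",
                       nbr_x = 10 - 2.9 + cos(ang) * 1.4,
                       nbr_y = sin(ang) * 1.4, nbr_z = 0)
  got_hb <- detect_contacts(lig_hb, protein)
  expect_identical(got_hb$residue_id, "ASP156")
  expect_identical(got_hb$interaction_type, "hbond_donor")
  # same geometry bent to 90 degrees fails the angle rule
  ang2 <- 90 * pi / 180
  lig_bad <- transform(lig_hb, nbr_x = 10 - 2.9 + cos(ang2) * 1.4,
                       nbr_y = sin(ang2) * 1.4)
  expect_identical(nrow(detect_contacts(lig_bad, protein)), 0L)
  expect_error(detect_contacts(data.frame(x = 1, y = 1, z = 1), protein),
               "atom typing")
})

test_that("contact tables survive a CSV round trip", {
  tabs <- lapply(1:3, function(i)
    random_pose_table(paste0("c", i), 6, paste0("R", 1:5), seed = i))
  names(tabs) <- paste0("c", 1:3)
  f <- tempfile(fileext = ".csv")
  write_contact_tables(tabs, f)
  back <- read_contact_tables(f)
  vocab <- paste0("R", 1:5)
  expect_identical(robust_plif_matrix(back, vocabulary = vocab),
                   robust_plif_matrix(tabs, vocabulary = vocab))
})
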