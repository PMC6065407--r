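test_that("clone trees satisfy their structural invariants across seeds", {
  for (s in 1:10) {
    tree <- simulate_clone_tree(n_clones = 1 + s %% 5, n_samples = 2 + s %% 3,
                                selection_shift = 0.4, seed = s)
    expect_silent(validate_clone_tree(tree))
    m <- tree_ccf_matrix(tree)
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
    expect_equal(unname(m[1, ]), rep(1, ncol(m)))
  }
})

test_that("a single-clone tree is just the trunk at CCF 1", {
  tree <- simulate_clone_tree(1, 3, 0.5, seed = 7)
  expect_equal(unique(tree$clone_id), 1L)
  expect_equal(tree$ccf, rep(1, 3))
})

test_that("zero selection shift freezes CCFs across samples", {
  m <- tree_ccf_matrix(simulate_clone_tree(4, 2, 0, seed = 1))
  expect_equal(m[, 1], m[, 2], tolerance = 1e-12)
})

test_that("clonal drift is largest at derivation and decays along passages", {
  m <- tree_ccf_matrix(simulate_clone_tree(4, 5, 0.6, seed = 1))
  d_first <- mean(abs(m[, 2] - m[, 1]))
  d_last <- mean(abs(m[, 5] - m[, 4]))
  expect_gt(d_first, d_last)
})

test_that("identical seeds reproduce trees exactly; min_separation is honored", {
  t1 <- simulate_clone_tree(4, 3, 0.5, seed = 42)
  t2 <- simulate_clone_tree(4, 3, 0.5, seed = 42)
  expect_identical(t1$ccf, t2$ccf)
  tsep <- simulate_clone_tree(4, 2, 0.5, seed = 11, min_separation = 0.15)
  m <- tree_ccf_matrix(tsep)
  pairs <- utils::combn(nrow(m), 2, simplify = FALSE)
  seps <- vapply(pairs, function(p) max(abs(m[p[1], ] - m[p[2], ])), numeric(1))
  expect_true(all(seps >= 0.15))
})

test_that("tree and mutation inputs are validated", {
  expect_error(simulate_clone_tree(0, 2, seed = 1), class = "concord_input_error")
  expect_error(simulate_clone_tree(3, 1, seed = 1), class = "concord_input_error")
  tree <- simulate_clone_tree(2, 2, seed = 1)
  cat6 <- test_catalog()
  expect_error(simulate_mutations(tree, cat6, rep(0, 6), 10, seed = 1),
               class = "concord_input_error")
  expect_error(simulate_mutations(tree, cat6, c(-1, rep(1, 5)), 10, seed = 1),
               class = "concord_input_error")
})

test_that("mutation channels follow the exposure-weighted signature mixture", {
  cat6 <- test_catalog()
  tree <- simulate_clone_tree(1, 2, seed = 1)
  muts <- simulate_mutations(tree, cat6, c(0, 0, 1, 0, 0, 0), 1000, seed = 1)
  counts <- mutation_spectrum(muts)
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = cat6$matrix[3, ], rescale.p = TRUE)
  )
  expect_gt(gof$p.value, 0.01)
  # all mutations on the only existing clone; positions unique
  expect_true(all(muts$clone_id == 1L))
  expect_equal(anyDuplicated(muts[c("chrom", "pos")]), 0L)
  expect_equal(nrow(simulate_mutations(tree, cat6, c(1, 0, 0, 0, 0, 0), 0,
                                       seed = 1)), 0L)
})

test_that("read counts follow the purity/copy-number VAF law", {
  # trunk mutation, purity 1, cn 2, forced depth 100: expected VAF 0.5
  expect_equal(expected_vaf(1, 1, 2, 1), 0.5)
  expect_equal(expected_vaf(1, 0.5, 2, 1), 0.25)
  tree <- fixed_tree(list(c(1, 1)), parents = NA_integer_)
  truth <- simulate_ground_truth(tree = tree, tumor_purity = 1,
                                 mean_depth = 100, seed = 1)
  cat6 <- test_catalog()
  muts <- simulate_mutations(tree, cat6, rep(1, 6), 10000, seed = 2)
  obs <- simulate_read_counts(muts, tree, truth, "tumor", seed = 3,
                              depth = 100)
  ci <- stats::qbinom(c(0.005, 0.995), 100, 0.5)
  expect_true(all(obs$depth == 100))
  expect_gt(mean(obs$alt_count >= ci[1] & obs$alt_count <= ci[2]), 0.98)
  # mean observed VAF within 3 standard errors of the formula value
  se <- sqrt(0.5 * 0.5 / 100) / sqrt(nrow(obs))
  expect_lt(abs(mean(obs$alt_count / obs$depth) - 0.5), 3 * se)
})

test_that("a clone absent from a passage yields zero alternate reads there", {
  tree <- fixed_tree(list(c(1, 1), c(0.5, 0)), parents = c(NA, 1L))
  truth <- simulate_ground_truth(tree = tree, tumor_purity = 1,
                                 mean_depth = 60, seed = 1)
  muts <- simulate_mutations(tree, test_catalog(), rep(1, 6), 400, seed = 4)
  obs <- simulate_read_counts(muts, tree, truth, "P1", seed = 5)
  dead <- obs$alt_count[muts$clone_id == 2L]
  expect_true(all(dead == 0L))
  expect_error(simulate_read_counts(muts, tree, truth, "P9", seed = 1),
               class = "concord_input_error")
})

test_that("expression simulation is seeded and guards program sizes", {
  s1 <- simulate_expression(n_genes = 400, patients = 2, seed = 3,
                            n_patient_program = 10)
  s2 <- simulate_expression(n_genes = 400, patients = 2, seed = 3,
                            n_patient_program = 10)
  expect_identical(s1$counts, s2$counts)
  expect_error(simulate_expression(n_genes = 100, patients = 4, seed = 1),
               class = "concord_input_error")
})

test_that("plate simulation produces the half-log ladder and sane controls", {
  doses <- half_log_doses(1e-5, 7)
  expect_equal(doses[1] / doses[7], 1000, tolerance = 1e-9)
  expect_equal(doses * 1e6,
               c(10, 3.1623, 1, 0.31623, 0.1, 0.031623, 0.01),
               tolerance = 1e-4)
  # noiseless plate with IC50 far above the range: all wells fully viable
  pl <- simulate_plate(1e-2, noise_sd = 0, seed = 1)
  smp <- pl[pl$role == "sample", ]
  expect_true(all(smp$viability > 0.99))
  # sigmoid midpoint: dose == IC50 gives viability one half
  pl2 <- simulate_plate(1e-6, noise_sd = 0, seed = 1)
  expect_equal(pl2$viability[pl2$role == "sample" &
                               abs(pl2$concentration - 1e-6) < 1e-12], 0.5)
  expect_true(all(pl$viability[pl$role == "neg_ctrl"] == 1))
  expect_true(all(pl$viability[pl$role == "pos_ctrl"] == 0))
  expect_error(simulate_plate(1e-6, noise_sd = -0.1, seed = 1),
               class = "concord_input_error")
  expect_error(simulate_plate(0, seed = 1), class = "concord_input_error")
})
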