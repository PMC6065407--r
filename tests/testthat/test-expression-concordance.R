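test_that("median-of-ratios size factors behave as specified", {
  counts <- tibble::tibble(gene = paste0("g", 1:100),
                           A = rpois(100, 50) + 1L)
  counts$B <- counts$A
  nc <- normalize_counts(counts)
  expect_equal(unname(nc$size_factors), c(1, 1), tolerance = 1e-12)
  # doubling every count doubles the size factor
  counts2 <- dplyr::mutate(counts, B = 2L * A)
  sf <- normalize_counts(counts2)$size_factors
  expect_equal(unname(sf["B"] / sf["A"]), 2, tolerance = 1e-6)
  # an all-zero gene stays zero everywhere on the normalized scale
  counts3 <- counts
  counts3[1, c("A", "B")] <- 0L
  lg <- normalize_counts(counts3)$log2
  expect_equal(unlist(lg[1, c("A", "B")]), c(A = 0, B = 0))
  expect_error(normalize_counts(counts[, 1:2]), class = "concord_input_error")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_expression(n_genes = 500, patients = 3, seed = 2,
                             n_patient_program = 20)
  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$gene
  ours <- normalize_counts(sim$counts)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same estimator up to the gene pool used for the geometric reference
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("expressed-SNV classes match the rule on an exhaustive sweep", {
  oracle <- function(depth, alt) {
    if (depth >= 4 && alt / max(depth, 1) > 0) "alternative_expressed"
    else if (depth >= 4) "reference_expressed"
    else "not_expressed"
  }
  grid <- expand.grid(depth = 0:12, alt = 0:12)
  grid <- grid[grid$alt <= grid$depth, ]
  got <- classify_expressed_snv(grid$depth, grid$alt)
  want <- mapply(oracle, grid$depth, grid$alt)
  expect_identical(got, unname(want))
  # quoted boundary cases
  expect_equal(classify_expressed_snv(3, 1), "not_expressed")
  expect_equal(classify_expressed_snv(10, 0), "reference_expressed")
  expect_equal(classify_expressed_snv(4, 1), "alternative_expressed")
  expect_error(classify_expressed_snv(3, 4), class = "concord_input_error")
})

test_that("the Welch engine finds planted fold changes and is calibrated", {
  n_genes <- 2000
  mu <- rep(200, n_genes)
  mk <- function(mu_vec, n, seed) {
    withr::with_seed(seed, {
      m <- sapply(seq_len(n), function(i) rnbinom(n_genes, mu = mu_vec,
                                                  size = 10))
      colnames(m) <- paste0("s", seed, "_", seq_len(n))
      m
    })
  }
  up <- mu
  up[1] <- mu[1] * 4    # planted 4-fold gene
  counts <- cbind(mk(up, 5, 1), mk(mu, 5, 2))
  colnames(counts) <- c(paste0("a", 1:5), paste0("b", 1:5))
  rownames(counts) <- paste0("g", seq_len(n_genes))
  nc <- normalize_counts(counts)
  de <- differential_expression(nc, paste0("a", 1:5), paste0("b", 1:5))
  expect_equal(de$log2fc[1], 2, tolerance = 0.5)
  expect_lte(de$p_value[1], 0.01)
  # null genes: empirical type-I error at p <= 0.01 stays near nominal
  expect_true(dplyr::between(mean(de$p_value[-1] <= 0.01), 0.002, 0.03))
  # identical groups: no signal
  de0 <- differential_expression(nc, paste0("a", 1:5), paste0("a", 1:5))
  expect_true(all(abs(de0$log2fc) < 1e-12))
  expect_error(differential_expression(nc, "a1", paste0("b", 1:5)),
               class = "concord_input_error")
})

test_that("three-step selection recovers planted patient-specific genes", {
  sim <- simulate_expression(seed = 5)
  nc <- normalize_counts(sim$counts)
  pats <- unique(stats::na.omit(sim$samples$patient))
  sets <- lapply(stats::setNames(pats, pats), function(p) {
    select_signature_genes(nc, sim$samples, p)
  })
  expect_true(all(lengths(sets) > 0))
  pool <- unlist(sim$truth$patient_program)
  own_frac <- vapply(pats, function(p) {
    mean(sets[[p]] %in% sim$truth$patient_program[[p]])
  }, numeric(1))
  for (p in pats) {
    # every selected gene carries patient-level signal, the culture
    # program never survives step 2, and each patient recovers at least
    # one gene of their own planted program
    expect_true(all(sets[[p]] %in% pool))
    expect_false(any(sets[[p]] %in% sim$truth$culture_program))
    expect_true(any(sets[[p]] %in% sim$truth$patient_program[[p]]))
  }
  # sets are strongly enriched for the selecting patient's own program:
  # a patient owns ~1/6 of the candidate pool but over a third of what
  # their one-vs-all contrast selects
  expect_gt(mean(own_frac), 2 / length(pats))
})

test_that("loosening selection thresholds never shrinks a gene set", {
  sim <- simulate_expression(seed = 6)
  nc <- normalize_counts(sim$counts)
  p <- "PAT1"
  strict <- select_signature_genes(nc, sim$samples, p)
  loose <- select_signature_genes(nc, sim$samples, p,
                                  p1 = 0.05, p3 = 0.2, top_n = 100)
  expect_true(all(strict %in% loose))
})

test_that("matched tumor-organoid pairs dominate the correlation matrix", {
  sim <- simulate_expression(seed = 1)
  nc <- normalize_counts(sim$counts)
  pats <- unique(stats::na.omit(sim$samples$patient))
  sets <- lapply(stats::setNames(pats, pats), function(p) {
    select_signature_genes(nc, sim$samples, p)
  })
  cmx <- correlation_matrix(nc, sim$samples, sets)
  expect_gte(cmx$match_rate, 0.8)
  expect_true(all(cmx$matrix >= -1 & cmx$matrix <= 1))
  expect_equal(rownames(cmx$matrix), pats)
  # union order does not matter
  cmx2 <- correlation_matrix(nc, sim$samples, rev(sets))
  expect_equal(cmx$matrix, cmx2$matrix)
})

test_that("correlation is exactly +/-1 for identical and mirrored profiles", {
  genes <- paste0("g", 1:50)
  vals <- withr::with_seed(1, stats::runif(50, 2, 10))
  lg <- tibble::tibble(gene = genes,
                       P1_T = vals, P2_T = rev(vals),
                       P1_O1 = vals,
                       P2_O1 = mean(vals) - (rev(vals) - mean(vals)))
  samples <- tibble::tibble(
    sample = c("P1_T", "P2_T", "P1_O1", "P2_O1"),
    class = c("tumor", "tumor", "organoid", "organoid"),
    patient = c("P1", "P2", "P1", "P2")
  )
  cmx <- correlation_matrix(lg, samples, genes)
  expect_equal(cmx$matrix["P1", "P1"], 1, tolerance = 1e-12)
  expect_equal(cmx$matrix["P2", "P2"], -1, tolerance = 1e-12)
})

test_that("expressed mutant alleles coincide with DNA-shared variants", {
  tree <- fixed_tree()   # all clones well represented in both samples
  truth <- simulate_ground_truth(tree = tree, tumor_purity = 0.55,
                                 mean_depth = 50, seed = 1)
  cat6 <- test_catalog()
  muts <- simulate_mutations(tree, cat6, rep(1, 6), 600, seed = 31)
  obs <- purrr::map(c("tumor", "P1"), function(s) {
    simulate_read_counts(muts, tree, truth, s, seed = 32 + match(s, c("tumor", "P1")))
  }) |> purrr::list_rbind()
  trios <- build_trios(dplyr::filter(obs, sample == "tumor"),
                       dplyr::filter(obs, sample == "P1")) |>
    rescue_status()
  rna <- simulate_read_counts(muts, tree, truth, "P1", seed = 35, depth = 30)
  status <- classify_expressed_snv(rna$depth, rna$alt_count)
  alt_pos <- rna$pos[status == "alternative_expressed"]
  shared_pos <- trios$pos[trios$status == "shared"]
  expect_gte(mean(alt_pos %in% shared_pos), 0.95)
})
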