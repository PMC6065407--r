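test_that("CCF estimation applies the purity/copy-number correction", {
  obs <- tibble::tibble(
    alt_count = c(50, 25, 50),
    depth = c(100, 100, 100),
    purity = c(1, 0.5, 1),
    total_cn = c(2, 2, 4)
  )
  est <- estimate_ccf(obs)
  expect_equal(est$multiplicity, c(1, 1, 2))
  expect_equal(est$ccf, c(1, 1, 1), tolerance = 1e-12)
  expect_false(any(est$ccf_clipped))
  expect_error(estimate_ccf(dplyr::mutate(obs, purity = 0)),
               class = "concord_input_error")
})

truncal_obs <- function(n, depth, samples = c("tumor", "P1"), seed = 1,
                        ccf = NULL) {
  # n mutations per cluster at the given per-sample CCFs (defaults truncal)
  ccf <- ccf %||% rep(1, length(samples))
  withr::with_seed(seed, {
    purrr::imap(stats::setNames(samples, samples), function(s, nm) {
      p <- 0.5 * ccf[match(s, samples)]
      tibble::tibble(mutation_id = seq_len(n), sample = s,
                     alt_count = stats::rbinom(n, depth, p), depth = depth,
                     purity = 1, total_cn = 2)
    }) |> purrr::list_rbind()
  })
}

test_that("a single truncal population is recovered as one cluster near 1", {
  obs <- truncal_obs(200, 100, seed = 2)
  fit <- cluster_ccf(obs, seed = 1)
  expect_equal(length(unique(fit$clusters$cluster_id)), 1L)
  expect_true(all(abs(fit$clusters$ccf - 1) <= 0.05))
})

test_that("a truncal and a drifting subclone are both recovered", {
  top <- truncal_obs(200, 100, seed = 3)
  sub <- truncal_obs(200, 100, seed = 4, ccf = c(0.3, 0.9)) |>
    dplyr::mutate(mutation_id = mutation_id + 200L)
  fit <- cluster_ccf(dplyr::bind_rows(top, sub), seed = 1)
  w <- tidyr::pivot_wider(fit$clusters, id_cols = "cluster_id",
                          names_from = "sample", values_from = "ccf")
  expect_equal(nrow(w), 2L)
  expect_equal(unname(unlist(w[1, c("tumor", "P1")])), c(1, 1),
               tolerance = 0.08)
  expect_equal(unname(unlist(w[2, c("tumor", "P1")])), c(0.3, 0.9),
               tolerance = 0.08)
})

test_that("clustering is deterministic under a fixed seed", {
  obs <- truncal_obs(150, 80, seed = 5)
  f1 <- cluster_ccf(obs, seed = 9)
  f2 <- cluster_ccf(obs, seed = 9)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$clusters, f2$clusters)
  expect_error(cluster_ccf(truncal_obs(10, 80), seed = 1),
               class = "concord_input_error")
})

test_that("pure-organoid clustering pins the trunk near CCF 1", {
  obs <- truncal_obs(300, 100, samples = "P1", seed = 6)
  fit <- cluster_ccf(obs, seed = 2)
  trunk <- dplyr::filter(fit$clusters, cluster_id == 1L)
  expect_true(all(abs(trunk$ccf - 1) <= 0.03))
})

test_that("minor tumor clones that expand in the organoid are detected", {
  top <- truncal_obs(250, 100, seed = 7)
  minor <- truncal_obs(250, 100, seed = 8, ccf = c(0.08, 0.75)) |>
    dplyr::mutate(mutation_id = mutation_id + 250L)
  fit <- cluster_ccf(dplyr::bind_rows(top, minor), seed = 3)
  w <- tidyr::pivot_wider(fit$clusters, id_cols = "cluster_id",
                          names_from = "sample", values_from = "ccf")
  expect_equal(nrow(w), 2L)
  expect_true(any(abs(w$P1 - 0.75) < 0.1 & abs(w$tumor - 0.08) < 0.1))
})


test_that("QC rule 1 rejects clusters under 1% of all mutations", {
  fit <- qc_fixture(c(996, 4))
  qc <- qc_clusters(fit)
  expect_false(qc$retained[qc$cluster_id == 2])
  expect_match(qc$reasons[qc$cluster_id == 2], "too_few_mutations")
  expect_true(qc$retained[qc$cluster_id == 1])
})

test_that("QC rule 2 rejects clusters deviating from the DP CCF by over 0.2", {
  fit <- qc_fixture(c(500, 500), dev = 0.25)
  qc <- qc_clusters(fit)
  expect_false(qc$retained[qc$cluster_id == 2])
  expect_match(qc$reasons[qc$cluster_id == 2], "ccf_deviation")
  # a deviation of exactly 0.2 is tolerated ("more than 0.2")
  qc_edge <- qc_clusters(qc_fixture(c(500, 500), dev = 0.2))
  expect_true(all(qc_edge$retained))
})

test_that("QC rule 3 rejects clusters concentrated on one chromosome", {
  fit <- qc_fixture(c(500, 500), chrom_conc = 0.6)
  qc <- qc_clusters(fit)
  expect_false(qc$retained[qc$cluster_id == 2])
  expect_match(qc$reasons[qc$cluster_id == 2], "chromosome_concentration")
})

wide_clusters <- function(ccf_list, samples = c("A", "B")) {
  purrr::imap(ccf_list, function(cc, i) {
    tibble::tibble(cluster_id = i, sample = samples[seq_along(cc)], ccf = cc)
  }) |> purrr::list_rbind()
}

test_that("the sum rule admits siblings whose CCFs fit under the parent", {
  cl <- wide_clusters(list(c(1, 1), c(0.6, 0.6), c(0.3, 0.3)))
  tree <- build_tree(cl)
  expect_equal(tree$trunk, 1L)
  expect_setequal(tree$edges$parent, 1L)   # both nested as siblings
  expect_false(any(tree$edges$flagged))
})

test_that("the pigeonhole forces nesting when sibling CCFs exceed the parent", {
  cl <- wide_clusters(list(1, 0.7, 0.6), samples = "A")
  tree <- build_tree(cl)
  e <- tree$edges
  expect_equal(e$parent[e$child == 2L], 1L)
  expect_equal(e$parent[e$child == 3L], 2L)  # 0.7 + 0.6 > 1, so 2 contains 3
})

test_that("the crossing rule places flipped clusters on disjoint branches", {
  cl <- wide_clusters(list(c(1, 1), c(0.7, 0.2), c(0.2, 0.7)))
  tree <- build_tree(cl)
  expect_equal(nrow(tree$disjoint_pairs), 1L)
  expect_setequal(unlist(tree$disjoint_pairs[, c("a", "b")]), c(2L, 3L))
  e <- tree$edges
  expect_equal(e$parent[e$child == 2L], 1L)
  expect_equal(e$parent[e$child == 3L], 1L)
})

test_that("constructed trees never violate the sum rule afterwards", {
  for (s in 1:10) {
    sim_cl <- withr::with_seed(s, {
      k <- 3 + s %% 3
      wide_clusters(c(list(c(1, 1)), lapply(seq_len(k - 1), function(i) {
        stats::runif(2, 0.05, 0.9)
      })))
    })
    tree <- build_tree(sim_cl)
    wide <- tree$ccf
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$cluster_id
    kids <- split(tree$edges$child, tree$edges$parent)
    for (p in names(kids)) {
      ok <- colSums(m[as.character(kids[[p]]), , drop = FALSE]) <=
        m[p, ] + tree$tau + 1e-9
      flagged <- tree$edges$flagged[tree$edges$child %in% kids[[p]]]
      expect_true(all(ok) || any(flagged))
    }
  }
})

test_that("a clustering without a clonal cluster is a structure error", {
  cl <- wide_clusters(list(c(0.6, 0.5), c(0.3, 0.2)))
  expect_error(build_tree(cl), class = "concord_structure_error")
})

test_that("clone dynamics are classified from the CCF trajectories", {
  mk <- function(ccfs_by_clone) {
    purrr::imap(ccfs_by_clone, function(cc, i) {
      tibble::tibble(cluster_id = i, sample = paste0("S", seq_along(cc)),
                     ccf = cc)
    }) |> purrr::list_rbind()
  }
  stable <- mk(list(c(1, 1, 1), c(0.5, 0.52, 0.49)))
  expect_equal(track_dynamics(stable)$classification, "stable")
  rapid <- mk(list(c(1, 1, 1), c(0.2, 0.8, 0.82)))
  expect_equal(track_dynamics(rapid)$classification, "rapid_then_static")
  gradual <- mk(list(c(1, 1, 1, 1, 1), c(0.2, 0.35, 0.5, 0.65, 0.8)))
  expect_equal(track_dynamics(gradual)$classification, "gradual")
  expect_error(track_dynamics(mk(list(1))), class = "concord_input_error")
})

test_that("clusters are matched across passages by member-set Jaccard", {
  a <- tibble::tibble(mutation_id = 1:100,
                      cluster_id = rep(1:2, each = 50))
  b <- tibble::tibble(mutation_id = 1:100,
                      cluster_id = c(rep(1L, 45), rep(2L, 55)))
  m <- match_clusters(a, b)
  expect_equal(m$cluster_b[m$cluster_a == 1], 1L)
  expect_equal(m$cluster_b[m$cluster_a == 2], 2L)
  expect_true(all(m$matched))
  noise <- tibble::tibble(mutation_id = 1:100,
                          cluster_id = rep(1:4, 25))
  m2 <- match_clusters(a, noise)
  expect_false(any(m2$matched))
})
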