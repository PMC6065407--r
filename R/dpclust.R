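#' Cluster mutations into subclones by their multi-sample CCFs
#'
#' Fits a Dirichlet-process binomial mixture over the joint CCF space of
#' all samples, using a truncated stick-breaking representation sampled by
#' Gibbs. Each cluster carries one CCF per sample on a discrete grid; a
#' mutation's alternate-read count in sample `s` is binomial with success
#' probability `f * ccf`, where `f` is the purity/copy-number conversion
#' factor of that observation. Because cluster CCFs live on a fixed grid,
#' the per-mutation likelihood of every grid value is precomputed once and
#' each sweep reduces to table lookups, so chains are fast and exactly
#' reproducible under a seed.
#'
#' Label switching is resolved by reordering clusters by descending mean
#' CCF at every recorded sweep. A mutation's posterior CCF per sample is
#' the average over recorded sweeps of its assigned cluster's CCF; the
#' reported cluster CCF is the median of its members' posterior CCFs, and
#' `dp_ccf` is the cluster's own posterior mean CCF (used by QC rule 2).
#'
#' @param observations Long tibble with one row per mutation x sample:
#'   `mutation_id`, `sample`, `alt_count`, `depth`, `purity`, optionally
#'   `total_cn` (default 2) and `chrom` (enables the chromosome QC filter).
#'   Every mutation must appear in every sample.
#' @param seed Integer seed.
#' @param iterations Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before recording.
#' @param max_clusters Truncation level of the stick-breaking DP.
#' @param alpha DP concentration parameter.
#' @param grid_step CCF grid resolution.
#' @param merge_tol Post-hoc merge tolerance: clusters whose centers sit
#'   within this distance in every sample are collapsed into one. The
#'   default is twice the binomial standard error of a CCF near 0.5 at
#'   depth 100 (~0.05): components closer than that cannot be resolved at
#'   realistic depths and arise when the DP spreads one subclone's mass
#'   over two adjacent components.
#' @return An object of class `ccf_clustering`: list with `clusters`
#'   (tibble: `cluster_id`, `sample`, `ccf`, `dp_ccf`, `n_mutations`),
#'   `assignments` (tibble: `mutation_id`, `cluster_id`), `posterior`
#'   (tibble: `mutation_id`, `sample`, `ccf`), `samples`, `n_mutations`,
#'   and `chrom` (per-mutation chromosome, if supplied).
#' @export
cluster_ccf <- function(observations, seed = 1L, iterations = 2000L,
                        burn_in = 500L, max_clusters = 8L, alpha = 1,
                        grid_step = 0.01, merge_tol = 0.1) {
  if (!"total_cn" %in% names(observations)) observations$total_cn <- 2
  samples <- unique(observations$sample)
  muts <- unique(observations$mutation_id)
  N <- length(muts)
  S <- length(samples)
  if (N < 20L) stop_input("need at least 20 mutations to cluster")
  if (nrow(observations) != N * S ||
      nrow(distinct(observations, .data$mutation_id, .data$sample)) != N * S) {
    stop_input("every mutation must be observed exactly once in every sample")
  }
  if (any(observations$depth <= 0)) stop_input("`depth` must be positive")
  if (burn_in >= iterations) stop_input("`burn_in` must be below `iterations`")

  grid <- seq(0, 1, by = grid_step)
  G <- length(grid)
  K <- as.integer(max_clusters)

  # per-sample N x G log-likelihood tables, computed in blocks of constant
  # conversion factor f = purity * m / (purity * cn + (1 - purity) * 2)
  obs <- observations |>
    estimate_ccf() |>
    mutate(.f = .data$purity * .data$multiplicity /
             (.data$purity * .data$total_cn + (1 - .data$purity) * 2))
  L <- vector("list", S)
  for (s in seq_len(S)) {
    os <- obs |> filter(.data$sample == samples[s])
    os <- os[match(muts, os$mutation_id), ]
    Ls <- matrix(0, N, G)
    for (fv in unique(os$.f)) {
      rows <- which(os$.f == fv)
      p <- pmin(pmax(fv * grid, 1e-6), 1 - 1e-6)
      Ls[rows, ] <- outer(os$alt_count[rows], log(p)) +
        outer(os$depth[rows] - os$alt_count[rows], log1p(-p))
    }
    L[[s]] <- Ls
  }

  chrom <- NULL
  if ("chrom" %in% names(observations)) {
    ch <- observations |> distinct(.data$mutation_id, .data$chrom)
    chrom <- ch$chrom[match(muts, ch$mutation_id)]
  }

  # naive per-mutation CCF estimates, used only to initialize the chain
  ccf0 <- obs |>
    mutate(.ccf = pmin(pmax(.data$ccf, 0), 1)) |>
    select("mutation_id", "sample", ".ccf") |>
    tidyr::pivot_wider(names_from = "sample", values_from = ".ccf")
  ccf0 <- as.matrix(ccf0[match(muts, ccf0$mutation_id), -1, drop = FALSE])

  with_seed(seed, {
    # k-means warm start: random chains routinely fail to split clusters
    # that start merged, because an empty DP component must land on the
    # right CCF and capture members within one sweep
    km <- tryCatch(
      suppressWarnings(
        stats::kmeans(ccf0, centers = min(K, max(2L, N %/% 10L)),
                      nstart = 5, iter.max = 50)
      ),
      error = function(e) NULL
    )
    G_idx <- matrix(sample.int(G, K * S, replace = TRUE), K, S)
    if (is.null(km)) {
      z <- sample.int(K, N, replace = TRUE)
    } else {
      z <- km$cluster
      centers_init <- pmin(pmax(km$centers, 0), 1)
      G_idx[seq_len(nrow(centers_init)), ] <-
        matrix(round(centers_init / grid_step) + 1L, nrow(centers_init), S)
    }
    n_kept <- 0L
    assign_counts <- matrix(0L, N, K)
    mut_post_sum <- matrix(0, N, S)
    phi_sum <- matrix(0, K, S)

    for (it in seq_len(iterations)) {
      # cluster CCFs: discrete posterior over the grid, per cluster/sample
      for (s in seq_len(S)) {
        sums <- rowsum(L[[s]], group = z)
        present <- as.integer(rownames(sums))
        for (k in seq_len(K)) {
          lp <- if (k %in% present) sums[match(k, present), ] else rep(0, G)
          lp <- lp - max(lp)
          G_idx[k, s] <- sample.int(G, 1L, prob = exp(lp))
        }
      }
      phi <- matrix(grid[G_idx], K, S)

      # stick-breaking weights
      nk <- tabulate(z, K)
      ngt <- sum(nk) - cumsum(nk)
      v <- rbeta(K, 1 + nk, alpha + ngt)
      v[K] <- 1
      logv <- log(pmax(v, 1e-12))
      log1mv <- log(pmax(1 - v, 1e-12))
      logw <- logv + c(0, cumsum(log1mv))[seq_len(K)]

      # assignments via Gumbel-max over clusters
      lp <- matrix(logw, N, K, byrow = TRUE)
      for (s in seq_len(S)) {
        lp <- lp + L[[s]][, G_idx[, s], drop = FALSE]
      }
      gum <- -log(-log(matrix(runif(N * K), N, K)))
      z <- max.col(lp + gum)

      if (it > burn_in) {
        n_kept <- n_kept + 1L
        ord <- order(-rowMeans(phi))
        rank_of <- integer(K)
        rank_of[ord] <- seq_len(K)
        canon <- rank_of[z]
        idx <- cbind(seq_len(N), canon)
        assign_counts[idx] <- assign_counts[idx] + 1L
        mut_post_sum <- mut_post_sum + phi[z, , drop = FALSE]
        phi_sum <- phi_sum + phi[ord, , drop = FALSE]
      }
    }

    mut_post <- mut_post_sum / n_kept
    dp_ccf_canon <- phi_sum / n_kept
    modal <- max.col(assign_counts)

    # MAP refinement: relabeling across sweeps can leave a shadow label
    # between two real clusters; a few hard reassignment passes against
    # the final cluster CCFs dissolve it (mutations go to whichever real
    # cluster explains their counts best, emptied labels are dropped)
    grid_index <- function(x) pmin(pmax(round(x / grid_step), 0), G - 1L) + 1L
    for (pass in 1:10) {
      labels <- sort(unique(modal))
      if (length(labels) < 2L) break
      cen <- matrix(vapply(labels, function(k) {
        apply(mut_post[modal == k, , drop = FALSE], 2, median)
      }, numeric(S)), ncol = S, byrow = TRUE)
      lp <- matrix(0, N, length(labels))
      for (s in seq_len(S)) {
        lp <- lp + L[[s]][, grid_index(cen[, s]), drop = FALSE]
      }
      new_modal <- labels[max.col(lp)]
      if (all(new_modal == modal)) break
      modal <- new_modal
    }

    # collapse components whose centers are indistinguishable everywhere
    center_of <- function(k) {
      apply(mut_post[modal == k, , drop = FALSE], 2, median)
    }
    repeat {
      labels <- sort(unique(modal))
      if (length(labels) < 2L) break
      cen <- matrix(vapply(labels, center_of, numeric(S)),
                    ncol = S, byrow = TRUE)
      d <- as.matrix(dist(cen, method = "maximum"))
      diag(d) <- Inf
      if (min(d) >= merge_tol) break
      pair <- which(d == min(d), arr.ind = TRUE)[1L, ]
      keep <- labels[min(pair)]
      drop <- labels[max(pair)]
      modal[modal == drop] <- keep
      # pool the DP posterior CCF, weighted by component size
      nk <- colSums(assign_counts)[c(keep, drop)]
      dp_ccf_canon[keep, ] <- (nk[1] * dp_ccf_canon[keep, ] +
                                 nk[2] * dp_ccf_canon[drop, ]) / sum(nk)
      assign_counts[, keep] <- assign_counts[, keep] + assign_counts[, drop]
      assign_counts[, drop] <- 0L
    }

    labels <- sort(unique(modal))
    centers <- matrix(vapply(labels, center_of, numeric(S)),
                      ncol = S, byrow = TRUE)
    # final ids ordered by descending mean CCF
    final_order <- order(-rowMeans(centers))
    id_of <- integer(length(labels))
    id_of[final_order] <- seq_along(labels)

    clusters <- list_rbind(lapply(seq_along(labels), function(i) {
      tibble(cluster_id = id_of[i], sample = samples,
             ccf = centers[i, ],
             dp_ccf = dp_ccf_canon[labels[i], ],
             n_mutations = sum(modal == labels[i]))
    })) |> arrange(.data$cluster_id, match(.data$sample, samples))

    assignments <- tibble(mutation_id = muts,
                          cluster_id = id_of[match(modal, labels)])
    posterior <- tibble(
      mutation_id = rep(muts, S),
      sample = rep(samples, each = N),
      ccf = as.vector(mut_post)
    )

    structure(
      list(clusters = clusters, assignments = assignments,
           posterior = posterior, samples = samples, n_mutations = N,
           chrom = chrom,
           settings = list(seed = seed, iterations = iterations,
                           burn_in = burn_in, max_clusters = K,
                           alpha = alpha, grid_step = grid_step)),
      class = "ccf_clustering"
    )
  })
}

#' @export
print.ccf_clustering <- function(x, ...) {
  k <- length(unique(x$clusters$cluster_id))
  cat("<ccf_clustering> ", x$n_mutations, " mutations, ",
      length(x$samples), " samples, ", k, " clusters\n", sep = "")
  print(tidyr::pivot_wider(x$clusters,
                           id_cols = c("cluster_id", "n_mutations"),
                           names_from = "sample", values_from = "ccf"))
  invisible(x)
}

#' Quality-control subclone clusters
#'
#' Applies the three artifact filters for CCF clusters: (1) clusters
#' holding fewer than `min_frac` (default 1%) of all clustered mutations;
#' (2) clusters whose members' median CCF deviates from the
#' Dirichlet-process cluster CCF by more than `max_ccf_dev` (default 0.2)
#' in one or more samples; (3) clusters with more than `max_chrom_frac`
#' (default 50%) of member mutations on a single chromosome. A cluster is
#' rejected if any rule fires; all reasons are reported.
#'
#' @param fit A `ccf_clustering` from [cluster_ccf()].
#' @param min_frac Rule-1 minimum fraction of all mutations.
#' @param max_ccf_dev Rule-2 maximum |median member CCF - DP CCF|.
#' @param max_chrom_frac Rule-3 maximum fraction of members on one
#'   chromosome.
#' @param chrom Optional per-mutation chromosome vector overriding the one
#'   captured at clustering time; rule 3 is skipped when unavailable.
#' @return Tibble: `cluster_id`, `n_mutations`, `retained`, `reasons`
#'   (comma-separated, `NA` when retained).
#' @export
qc_clusters <- function(fit, min_frac = 0.01, max_ccf_dev = 0.2,
                        max_chrom_frac = 0.5, chrom = NULL) {
  stopifnot(inherits(fit, "ccf_clustering"))
  chrom <- chrom %||% fit$chrom
  total <- fit$n_mutations
  per_cluster <- fit$clusters |>
    group_by(.data$cluster_id) |>
    summarise(n_mutations = .data$n_mutations[1],
              max_dev = max(abs(.data$ccf - .data$dp_ccf)),
              .groups = "drop")
  chrom_frac <- rep(0, nrow(per_cluster))
  if (!is.null(chrom)) {
    cl <- fit$assignments$cluster_id
    chrom_frac <- vapply(per_cluster$cluster_id, function(k) {
      tab <- table(chrom[cl == k])
      if (length(tab) == 0) 0 else max(tab) / sum(tab)
    }, numeric(1))
  }
  per_cluster |>
    mutate(
      rule1 = .data$n_mutations < min_frac * total,
      rule2 = .data$max_dev > max_ccf_dev + 1e-9,
      rule3 = chrom_frac > max_chrom_frac,
      retained = !(.data$rule1 | .data$rule2 | .data$rule3),
      reasons = purrr::pmap_chr(
        list(.data$rule1, .data$rule2, .data$rule3),
        function(r1, r2, r3) {
          r <- c("too_few_mutations", "ccf_deviation",
                 "chromosome_concentration")[c(r1, r2, r3)]
          if (length(r)) paste(r, collapse = ",") else NA_character_
        })
    ) |>
    select("cluster_id", "n_mutations", "retained", "reasons")
}
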