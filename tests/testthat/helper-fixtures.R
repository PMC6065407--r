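# Shared fixtures and independent oracles used across test files.

library(dplyr)

test_catalog <- function(seed = 1) random_signature_catalog(seed = seed)

# Hand-built two-sample clone tree with all clones well represented in the
# tumor (used where a property presumes clones observable in both samples).
fixed_tree <- function(ccfs = list(c(1, 1), c(0.6, 0.75), c(0.25, 0.45)),
                       parents = c(NA, 1L, 2L),
                       samples = c("tumor", "P1")) {
  out <- purrr::imap(ccfs, function(cc, i) {
    tibble::tibble(clone_id = i, parent_id = parents[i],
                   sample = samples, ccf = cc)
  }) |> purrr::list_rbind()
  attr(out, "samples") <- samples
  class(out) <- c("clone_tree", class(out))
  out
}

# Independent oracle for the exposure QP: grid search over the simplex
# spanned by `active` signatures (step 0.005), with the optimal
# non-negative scale solved in closed form per grid point.
grid_search_exposures <- function(counts, catalog, active, step = 0.005) {
  P <- catalog$matrix[active, , drop = FALSE]
  k <- length(active)
  stopifnot(k <= 3)
  mesh <- seq(0, 1, by = step)
  props <- if (k == 1) {
    matrix(1, 1, 1)
  } else if (k == 2) {
    cbind(mesh, 1 - mesh)
  } else {
    g <- expand.grid(a = mesh, b = mesh)
    g <- g[g$a + g$b <= 1, ]
    cbind(g$a, g$b, 1 - g$a - g$b)
  }
  spectra <- props %*% P                     # n_grid x 96
  num <- as.vector(spectra %*% counts)
  den <- rowSums(spectra^2)
  scale <- pmax(num / pmax(den, 1e-300), 0)
  resid <- sum(counts^2) - 2 * scale * num + scale^2 * den
  best <- which.min(resid)
  full <- numeric(length(catalog$names))
  full[match(active, seq_along(catalog$names))] <- props[best, ]
  list(proportions = full, objective = resid[best])
}

# Direct transcription of the quoted copy-number cut-offs, used as the
# brute-force oracle for classify_segment.
classify_segment_oracle <- function(cn, ps) {
  if (cn == 0) return("deletion")
  if (cn >= 2 * ps) return("amplification")
  if (cn > 1.25 * ps) return("gain")
  if (cn < 0.75 * ps) return("loss")
  "neutral"
}

# Minimal ccf_clustering stand-in for unit-testing the QC rules in
# isolation from the Gibbs sampler.
fake_clustering <- function(clusters, assignments, chrom = NULL,
                            n_mutations = sum(assignments$n %||% 0)) {
  structure(
    list(clusters = clusters, assignments = assignments,
         posterior = NULL, samples = unique(clusters$sample),
         n_mutations = n_mutations, chrom = chrom,
         settings = list()),
    class = "ccf_clustering"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

objective_sse <- function(e, counts, catalog) {
  sum((as.vector(e %*% catalog$matrix) - counts)^2)
}

qc_fixture <- function(n_per_cluster, dev = 0, chrom_conc = NULL,
                       total = sum(n_per_cluster)) {
  k <- length(n_per_cluster)
  ccfs <- seq(1, by = -0.3, length.out = k)
  clusters <- purrr::imap(n_per_cluster, function(n, i) {
    tibble::tibble(cluster_id = i, sample = "tumor",
                   ccf = ccfs[i], dp_ccf = ccfs[i] + ifelse(i == k, dev, 0),
                   n_mutations = n)
  }) |> purrr::list_rbind()
  assignments <- tibble::tibble(
    mutation_id = seq_len(total),
    cluster_id = rep(seq_len(k), times = n_per_cluster)
  )
  chrom <- rep(1:22, length.out = total)
  if (!is.null(chrom_conc)) {
    # concentrate the last cluster's members on chromosome 1
    last <- assignments$cluster_id == k
    n_last <- sum(last)
    chrom[last] <- c(rep(1L, ceiling(chrom_conc * n_last)),
                     rep(2:22, length.out = n_last - ceiling(chrom_conc * n_last)))
  }
  fake_clustering(clusters, assignments, chrom = chrom, n_mutations = total)
}

replicate_panel <- function(rep, ic50s, noise_sd = 0.05) {
  purrr::map(seq_along(ic50s), function(i) {
    pl <- simulate_plate(ic50s[i], noise_sd = noise_sd,
                         seed = 1000 * rep + i,
                         organoid = paste0("o", (i - 1) %% 6 + 1),
                         compound = paste0("c", i))
    fit_plate(pl)
  }) |> purrr::list_rbind()
}
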