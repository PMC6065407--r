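#' concord: tumor-organoid concordance and clonal dynamics
#'
#' See the package vignette for the scientific background and a worked
#' end-to-end analysis on a simulated paired cohort.
#'
#' @keywords internal
"_PACKAGE"

#' Derivation efficiency of an organoid biobank
#'
#' The fraction of attempted tissue samples that yielded an established
#' culture, as a percentage.
#'
#' @param n_success Number of successfully established cultures.
#' @param n_attempted Number of samples put into derivation.
#' @return One-row tibble: `n_success`, `n_attempted`, `efficiency_pct`.
#' @export
#' @examples
#' derivation_efficiency(10, 32)
derivation_efficiency <- function(n_success, n_attempted) {
  n_success <- check_positive_int(n_success, "n_success")
  n_attempted <- check_positive_int(n_attempted, "n_attempted")
  if (n_success > n_attempted) {
    stop_input("`n_success` cannot exceed `n_attempted`")
  }
  tibble(n_success = n_success, n_attempted = n_attempted,
         efficiency_pct = 100 * n_success / n_attempted)
}

#' Simulate a complete paired tumor/organoid variant call set
#'
#' Convenience wrapper running the full DNA-side generator for one
#' patient: clone tree, signature-mixed mutations, and per-sample allele
#' counts with caller flags for the tumor and every passage.
#'
#' @param truth A `ground_truth` from [simulate_ground_truth()] (or `NULL`
#'   to build one from `...`).
#' @param catalog A [signature_catalog()]; default a seeded random one.
#' @param exposures Per-signature mutation budgets; default an uneven
#'   six-signature mixture.
#' @param n_mutations Total mutations to plant.
#' @param seed Integer seed for mutation placement and read counts.
#' @param depth Optional fixed depth passed to [simulate_read_counts()].
#' @param ... Passed to [simulate_ground_truth()] when `truth` is `NULL`.
#' @return List of class `cohort_sim`: `truth`, `catalog`, `exposures`,
#'   `mutations`, and `observations` (long tibble over all samples with
#'   `purity` and `total_cn` columns ready for [cluster_ccf()]).
#' @export
#' @examples
#' sim <- simulate_patient(n_clones = 2, n_samples = 2, seed = 3,
#'                         n_mutations = 100)
#' dplyr::count(sim$observations, sample, called)
simulate_patient <- function(truth = NULL, catalog = NULL, exposures = NULL,
                             n_mutations = 600, seed = 1L, depth = NULL,
                             ...) {
  truth <- truth %||% simulate_ground_truth(seed = seed, ...)
  catalog <- catalog %||% random_signature_catalog(seed = child_seed(seed, 1))
  exposures <- exposures %||% c(0.30, 0.10, 0.15, 0.25, 0.12, 0.08) * n_mutations
  tree <- truth$tree
  samples <- attr(tree, "samples") %||% unique(tree$sample)
  muts <- simulate_mutations(tree, catalog, exposures, n_mutations,
                             seed = child_seed(seed, 2))
  obs <- purrr::imap(setNames(samples, samples), function(s, nm) {
    simulate_read_counts(muts, tree, truth, s,
                         seed = child_seed(seed, 10 + match(s, samples)),
                         depth = depth) |>
      mutate(purity = truth$purity[[s]], total_cn = 2)
  }) |> list_rbind()
  structure(
    list(truth = truth, catalog = catalog, exposures = exposures,
         mutations = muts, observations = obs),
    class = "cohort_sim"
  )
}
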