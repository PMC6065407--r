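#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a CCF clustering
#'
#' @param x A `ccf_clustering`.
#' @param ... Unused.
#' @return Tibble: one row per cluster x sample with CCFs and sizes.
#' @method tidy ccf_clustering
#' @export
tidy.ccf_clustering <- function(x, ...) {
  x$clusters
}

#' @rdname tidy.ccf_clustering
#' @return For `glance()`: one row with `n_mutations`, `n_clusters`,
#'   `n_samples`, `iterations`.
#' @method glance ccf_clustering
#' @export
glance.ccf_clustering <- function(x, ...) {
  tibble(n_mutations = x$n_mutations,
         n_clusters = length(unique(x$clusters$cluster_id)),
         n_samples = length(x$samples),
         iterations = x$settings$iterations)
}

#' Tidy a dose-response fit table
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return The per-curve parameters without the embedded data points.
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  out <- x |> select(-dplyr::any_of(c("conc", "viability")))
  class(out) <- setdiff(class(out), "dose_response_fit")
  out
}

#' @rdname tidy.dose_response_fit
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(n_curves = nrow(x),
         n_converged = sum(x$converged),
         n_censored = sum(x$ic50_censored != "none"),
         median_auc = median(x$auc))
}

#' Tidy an expression concordance matrix
#'
#' @param x An `expression_concordance`.
#' @param ... Unused.
#' @return Long tibble: `tumor`, `organoid`, `correlation`, `matched_pair`.
#' @method tidy expression_concordance
#' @export
tidy.expression_concordance <- function(x, ...) {
  as_tibble(x$matrix, rownames = "tumor") |>
    tidyr::pivot_longer(-"tumor", names_to = "organoid",
                        values_to = "correlation") |>
    mutate(matched_pair = .data$tumor == .data$organoid)
}

#' @rdname tidy.expression_concordance
#' @method glance expression_concordance
#' @export
glance.expression_concordance <- function(x, ...) {
  x$summary |> mutate(match_rate = x$match_rate, n_genes = length(x$genes))
}

#' Tidy an inferred clone tree
#'
#' @param x A `clone_tree_inferred`.
#' @param ... Unused.
#' @return The edge list (`parent`, `child`, `flagged`, `note`).
#' @method tidy clone_tree_inferred
#' @export
tidy.clone_tree_inferred <- function(x, ...) {
  x$edges
}

#' Tidy an exposure trajectory
#'
#' @param x An `exposure_trajectory`.
#' @param ... Unused.
#' @return Tibble of per-passage exposures and proportions.
#' @method tidy exposure_trajectory
#' @export
tidy.exposure_trajectory <- function(x, ...) {
  x$exposures
}

#' @rdname tidy.exposure_trajectory
#' @method glance exposure_trajectory
#' @export
glance.exposure_trajectory <- function(x, ...) {
  tibble(n_passages = length(unique(x$exposures$passage)),
         drift = x$drift)
}

#' Serialize an inferred clone tree to JSON
#'
#' @param tree A `clone_tree_inferred`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  payload <- list(trunk = tree$trunk,
                  edges = tree$edges,
                  ccf = tree$ccf,
                  disjoint_pairs = tree$disjoint_pairs,
                  tau = tree$tau)
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
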