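#' Build a clone tree from subclone clusters via the sum and crossing rules
#'
#' Decides nesting versus branching from multi-sample CCFs. The *crossing
#' rule* makes two clusters disjoint when their CCF ordering flips between
#' samples (A above B in one sample, below it in another, beyond tolerance
#' `tau`). Every other cluster starts out nested under the trunk-most
#' cluster that encloses it (CCF at least the child's, minus `tau`, in
#' every sample, without crossing). The *sum rule* then repairs sibling
#' sets: whenever siblings' CCFs sum above their parent's CCF plus `tau`
#' in some sample they cannot all be disjoint children (pigeonhole), so
#' the smallest is re-nested under the largest sibling and flagged;
#' sibling sets that violate the sum rule but cannot nest (they cross)
#' are flagged unresolved.
#'
#' @param clusters Tibble with `cluster_id`, `sample`, `ccf` (e.g.
#'   `fit$clusters` from [cluster_ccf()], ideally after [qc_clusters()]
#'   filtering), or a `ccf_clustering` object.
#' @param tau CCF tolerance for both rules.
#' @param trunk_tol How far below 1 the trunk's CCF may sit in any sample.
#' @return Object of class `clone_tree_inferred`: list with `edges`
#'   (tibble: `parent`, `child`, `flagged`, `note`), `disjoint_pairs`,
#'   `ccf` (wide cluster x sample tibble), `trunk`, `tau`.
#' @export
build_tree <- function(clusters, tau = 0.05, trunk_tol = 0.1) {
  if (inherits(clusters, "ccf_clustering")) clusters <- clusters$clusters
  wide <- clusters |>
    tidyr::pivot_wider(id_cols = "cluster_id", names_from = "sample",
                       values_from = "ccf")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cluster_id
  ord <- order(-rowMeans(m))
  m <- m[ord, , drop = FALSE]
  ids <- wide$cluster_id[ord]
  K <- length(ids)

  if (any(m[1, ] < 1 - trunk_tol)) {
    abort("no trunk-compatible cluster (CCF ~ 1 in all samples)",
          class = "concord_structure_error")
  }

  crossing <- function(i, j) {
    any(m[i, ] > m[j, ] + tau) && any(m[i, ] < m[j, ] - tau)
  }
  encloses <- function(anc, desc) {
    !crossing(anc, desc) && all(m[anc, ] >= m[desc, ] - tau)
  }

  disjoint <- list()
  parent <- rep(NA_integer_, K)   # indices into ids
  if (K > 1) {
    for (i in 2:K) {
      cand <- Filter(function(j) encloses(j, i), seq_len(i - 1L))
      for (j in seq_len(i - 1L)) {
        if (crossing(i, j)) {
          disjoint[[length(disjoint) + 1L]] <-
            tibble(a = ids[j], b = ids[i], reason = "crossing")
        }
      }
      if (length(cand) == 0) {
        abort(sprintf("cluster %s fits under no ancestor", ids[i]),
              class = "concord_structure_error")
      }
      parent[i] <- cand[which.max(rowMeans(m)[cand])]
    }
  }

  flagged <- rep(FALSE, K)
  note <- rep(NA_character_, K)
  # sum-rule repair: re-nest the smallest violating sibling under the largest
  repeat {
    changed <- FALSE
    for (p in seq_len(K)) {
      kids <- which(parent == p)
      if (length(kids) < 2) next
      viol <- any(colSums(m[kids, , drop = FALSE]) > m[p, ] + tau)
      if (!viol) next
      kids <- kids[order(-rowMeans(m)[kids])]
      big <- kids[1L]
      small <- rev(kids)[1L]
      if (encloses(big, small)) {
        parent[small] <- big
        flagged[small] <- TRUE
        note[small] <- "sum_rule_nested"
        changed <- TRUE
      } else {
        flagged[kids] <- TRUE
        note[kids] <- "sum_rule_unresolved"
      }
    }
    if (!changed) break
  }

  edges <- tibble(parent = ids[parent[-1L]], child = ids[-1L],
                  flagged = flagged[-1L], note = note[-1L])
  if (K == 1) {
    edges <- tibble(parent = integer(), child = integer(),
                    flagged = logical(), note = character())
  }
  structure(
    list(edges = edges,
         disjoint_pairs = if (length(disjoint)) list_rbind(disjoint) else
           tibble(a = integer(), b = integer(), reason = character()),
         ccf = wide, trunk = ids[1L], tau = tau),
    class = "clone_tree_inferred"
  )
}

#' @export
print.clone_tree_inferred <- function(x, ...) {
  cat("<clone_tree_inferred> trunk = cluster ", x$trunk, "\n", sep = "")
  if (nrow(x$edges)) print(x$edges) else cat("  (single cluster)\n")
  invisible(x)
}

#' Match clusters between two clusterings by member overlap
#'
#' @param assignments_a,assignments_b Tibbles with `mutation_id`,
#'   `cluster_id` (e.g. from separate per-passage clusterings).
#' @param min_jaccard Minimum Jaccard index of member sets to accept a
#'   match.
#' @return Tibble: `cluster_a`, `cluster_b`, `jaccard`, `matched`; every
#'   cluster of `a` appears once, unmatched ones with `matched = FALSE`.
#' @export
match_clusters <- function(assignments_a, assignments_b, min_jaccard = 0.5) {
  split_a <- split(assignments_a$mutation_id, assignments_a$cluster_id)
  split_b <- split(assignments_b$mutation_id, assignments_b$cluster_id)
  list_rbind(purrr::imap(split_a, function(mem_a, ka) {
    jac <- vapply(split_b, function(mem_b) {
      length(intersect(mem_a, mem_b)) / length(union(mem_a, mem_b))
    }, numeric(1))
    best <- which.max(jac)
    tibble(cluster_a = as.integer(ka),
           cluster_b = as.integer(names(split_b)[best]),
           jaccard = jac[best],
           matched = jac[best] >= min_jaccard)
  }))
}

#' Clone-fraction trajectories across passages
#'
#' Tabulates each clone's CCF over an ordered sample series (tumor followed
#' by passages) and classifies the overall dynamic: `stable` when no clone
#' moves by more than `stable_max` across any transition; otherwise
#' `rapid_then_static` when at least `rapid_share` of the total CCF change
#' falls on the first transition (the derivation bottleneck); `gradual`
#' otherwise.
#'
#' @param clusters Tibble with `cluster_id`, `sample`, `ccf`, or a
#'   `ccf_clustering`.
#' @param sample_order Ordered sample labels; defaults to their first
#'   appearance.
#' @param rapid_share Fraction of total change on the first transition that
#'   defines rapid-then-static.
#' @param stable_max Maximum per-clone per-transition change for `stable`.
#' @return Object of class `clone_dynamics`: list with `trajectory`
#'   (tibble: `cluster_id`, `sample`, `ccf`, `delta`), `classification`,
#'   `first_transition_share`, `max_change`.
#' @export
track_dynamics <- function(clusters, sample_order = NULL, rapid_share = 0.7,
                           stable_max = 0.1) {
  if (inherits(clusters, "ccf_clustering")) clusters <- clusters$clusters
  sample_order <- sample_order %||% unique(clusters$sample)
  if (length(sample_order) < 2) stop_input("need at least 2 samples")
  traj <- clusters |>
    mutate(sample = factor(.data$sample, levels = sample_order)) |>
    arrange(.data$cluster_id, .data$sample) |>
    group_by(.data$cluster_id) |>
    mutate(delta = .data$ccf - dplyr::lag(.data$ccf)) |>
    ungroup()
  per_transition <- traj |>
    filter(!is.na(.data$delta)) |>
    group_by(.data$sample) |>
    summarise(change = sum(abs(.data$delta)), .groups = "drop")
  total <- sum(per_transition$change)
  first_share <- if (total > 0) per_transition$change[1] / total else 0
  max_change <- max(abs(traj$delta), na.rm = TRUE)
  classification <- if (max_change < stable_max) {
    "stable"
  } else if (first_share >= rapid_share) {
    "rapid_then_static"
  } else {
    "gradual"
  }
  structure(
    list(trajectory = traj, classification = classification,
         first_transition_share = first_share, max_change = max_change),
    class = "clone_dynamics"
  )
}
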