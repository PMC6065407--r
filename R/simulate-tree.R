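#' Simulate a clone tree with per-sample cancer cell fractions
#'
#' Generates a rooted clone tree and, for an ordered series of samples
#' (tumor followed by organoid passages), a cancer cell fraction (CCF) for
#' every clone in every sample. The trunk is fully clonal (CCF 1) everywhere.
#' Non-trunk clones occupy random fractions of their parent's CCF, and those
#' fractions drift between consecutive samples. The drift magnitude is
#' largest at the first transition — tumor to first passage, where organoid
#' derivation exerts its selection bottleneck — and decays geometrically at
#' later passages.
#'
#' @param n_clones Number of clones including the trunk (>= 1).
#' @param n_samples Number of samples (>= 2): one tumor plus passages.
#' @param selection_shift Drift magnitude in `[0, 1]`; 0 freezes the clonal
#'   composition across all samples.
#' @param seed Integer seed; identical seeds give identical trees.
#' @param decay Geometric decay of the drift magnitude per later transition.
#' @param sample_names Optional sample labels; default `tumor, P1, P2, ...`.
#' @param min_separation Minimum pairwise clone separation (largest
#'   per-sample CCF difference between any two clones). The default 0
#'   places no constraint; recovery benchmarks should set it well above
#'   the read-count noise floor (e.g. 0.15 at depth 100), because two
#'   clones with coinciding CCFs in every sample are a single statistical
#'   population that no CCF-based method can split. Enforced by rejection
#'   sampling; an error is raised if no admissible tree is found.
#' @return A tibble of class `clone_tree` with columns `clone_id`,
#'   `parent_id` (`NA` for the trunk), `sample`, `ccf`, carrying the ordered
#'   sample labels in `attr(, "samples")`.
#' @export
#' @examples
#' tree <- simulate_clone_tree(4, 3, selection_shift = 0.5, seed = 1)
#' tree_ccf_matrix(tree)
simulate_clone_tree <- function(n_clones, n_samples, selection_shift = 0.5,
                                seed = 1L, decay = 0.3,
                                sample_names = NULL, min_separation = 0) {
  n_clones <- check_positive_int(n_clones, "n_clones")
  n_samples <- check_positive_int(n_samples, "n_samples")
  if (n_samples < 2L) {
    stop_input("`n_samples` must be >= 2 (tumor plus at least one passage)")
  }
  if (selection_shift < 0 || selection_shift > 1) {
    stop_input("`selection_shift` must lie in [0, 1]")
  }
  samples <- sample_names %||% c("tumor", paste0("P", seq_len(n_samples - 1L)))
  if (length(samples) != n_samples) {
    stop_input("`sample_names` must have length `n_samples`")
  }

  with_seed(seed, {
    for (attempt in seq_len(500L)) {
      parent <- rep(NA_integer_, n_clones)
      if (n_clones > 1L) {
        for (j in 2:n_clones) {
          parent[j] <- sample.int(j - 1L, 1L)
        }
      }
      children <- lapply(seq_len(n_clones), function(p) which(parent == p))

      # Per-parent stick-breaking state: raw child weights and the fraction
      # of the parent's CCF its children jointly occupy. Drift perturbs
      # these between samples.
      w <- rgamma(n_clones, shape = 2, rate = 1)     # per-clone raw weight
      occ <- rbeta(n_clones, 5, 2)                   # per-parent occupancy

      ccf_from_state <- function(w, occ) {
        ccf <- numeric(n_clones)
        ccf[1L] <- 1
        for (p in seq_len(n_clones)) {
          kids <- children[[p]]
          if (length(kids)) {
            frac <- occ[p] * w[kids] / sum(w[kids])
            ccf[kids] <- ccf[p] * frac
          }
        }
        ccf
      }

      ccfs <- matrix(0, n_clones, n_samples,
                     dimnames = list(NULL, samples))
      ccfs[, 1L] <- ccf_from_state(w, occ)
      if (n_samples > 1L) {
        for (t in 2:n_samples) {
          shift <- selection_shift * decay^(t - 2L)
          w <- w * exp(shift * 4 * rnorm(n_clones))
          occ <- stats::plogis(stats::qlogis(pmin(pmax(occ, 1e-6), 1 - 1e-6)) +
                                 shift * 2 * rnorm(n_clones))
          ccfs[, t] <- ccf_from_state(w, occ)
        }
      }

      if (min_separation <= 0 || n_clones == 1L) break
      sep <- min(vapply(utils::combn(n_clones, 2, simplify = FALSE),
                        function(p) max(abs(ccfs[p[1], ] - ccfs[p[2], ])),
                        numeric(1)))
      if (sep >= min_separation) break
      if (attempt == 500L) {
        stop_input("no clone tree satisfying `min_separation` found")
      }
    }

    out <- tidyr::expand_grid(clone_id = seq_len(n_clones), sample = samples) |>
      mutate(parent_id = parent[.data$clone_id],
             ccf = ccfs[cbind(.data$clone_id, match(.data$sample, samples))]) |>
      select("clone_id", "parent_id", "sample", "ccf")
    attr(out, "samples") <- samples
    class(out) <- c("clone_tree", class(out))
    out
  })
}

#' CCF matrix view of a clone tree
#'
#' @param tree A `clone_tree` tibble (or any tibble with `clone_id`,
#'   `sample`, `ccf`).
#' @return Numeric matrix, clones by samples, in the tree's sample order.
#' @export
tree_ccf_matrix <- function(tree) {
  samples <- attr(tree, "samples") %||% unique(tree$sample)
  clones <- sort(unique(tree$clone_id))
  m <- matrix(NA_real_, length(clones), length(samples),
              dimnames = list(clones, samples))
  m[cbind(match(tree$clone_id, clones), match(tree$sample, samples))] <- tree$ccf
  m
}

#' Validate clone-tree invariants
#'
#' Checks that there is exactly one root, that it is fully clonal (CCF 1) in
#' every sample, that all CCFs lie in `[0, 1]`, and that in every sample the
#' CCFs of a clone's children never sum to more than its own (within `tol`).
#'
#' @param tree A `clone_tree` tibble.
#' @param tol Numerical slack for the pigeonhole constraint.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_clone_tree <- function(tree, tol = 1e-9) {
  roots <- unique(tree$clone_id[is.na(tree$parent_id)])
  if (length(roots) != 1L) {
    stop_input("clone tree must have exactly one root")
  }
  if (any(tree$ccf < -tol | tree$ccf > 1 + tol)) {
    stop_input("all CCFs must lie in [0, 1]")
  }
  if (any(abs(tree$ccf[tree$clone_id == roots] - 1) > tol)) {
    stop_input("the trunk must have CCF 1 in every sample")
  }
  parent_of <- tree |> distinct(.data$clone_id, .data$parent_id)
  kid_sums <- tree |>
    filter(!is.na(.data$parent_id)) |>
    group_by(.data$parent_id, .data$sample) |>
    summarise(kid_ccf = sum(.data$ccf), .groups = "drop") |>
    left_join(tree, by = c(parent_id = "clone_id", sample = "sample"))
  if (any(kid_sums$kid_ccf > kid_sums$ccf + tol)) {
    stop_input("children's CCFs exceed their parent's CCF in some sample")
  }
  invisible(TRUE)
}

#' Simulate a clone tree whose clones are resolvable at given study conditions
#'
#' Recovery benchmarks need planted clones that are statistically
#' distinguishable: two clones whose CCFs differ by less than the
#' read-count noise floor in every sample are one population to any
#' CCF-based method. A CCF difference `d` in a sample with purity `rho`
#' translates (diploid heterozygous case) to a VAF difference `d * rho/2`,
#' against a binomial standard deviation of roughly
#' `sqrt(p * (1 - p) / depth)` per mutation — so low-purity samples shrink
#' the effective separation substantially. This wrapper redraws trees from
#' [simulate_clone_tree()] until every clone pair sits at least `min_z`
#' joint per-mutation standard deviations apart, the conventional
#' resolvability floor.
#'
#' @inheritParams simulate_clone_tree
#' @param purity Per-sample purity (first sample the tumor, rest organoid
#'   passages); recycled if length 1.
#' @param depth Sequencing depth used to express the noise floor.
#' @param min_z Minimum joint per-mutation z-separation between any two
#'   clones (default 3).
#' @param max_attempts Redraws before giving up.
#' @return A `clone_tree` (see [simulate_clone_tree()]).
#' @export
resolvable_clone_tree <- function(n_clones, n_samples, selection_shift = 0.5,
                                  seed = 1L, purity = c(0.55, 1),
                                  depth = 100, min_z = 3,
                                  max_attempts = 200L, ...) {
  purity <- rep_len(purity, n_samples)
  f <- purity / 2                      # VAF per unit CCF, diploid het
  for (attempt in seq_len(max_attempts)) {
    tree <- simulate_clone_tree(n_clones, n_samples, selection_shift,
                                seed = child_seed(seed, attempt), ...)
    m <- tree_ccf_matrix(tree)
    if (n_clones == 1L) return(tree)
    ok <- TRUE
    for (pair in utils::combn(n_clones, 2, simplify = FALSE)) {
      zs <- vapply(seq_len(n_samples), function(s) {
        p_mid <- f[s] * (m[pair[1], s] + m[pair[2], s]) / 2
        sdv <- sqrt(max(p_mid * (1 - p_mid), 1e-6) / depth)
        f[s] * abs(m[pair[1], s] - m[pair[2], s]) / sdv
      }, numeric(1))
      if (sqrt(sum(zs^2)) < min_z) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(tree)
  }
  stop_input("no resolvable clone tree found; lower `min_z` or n_clones")
}

#' Assemble the ground truth for one simulated patient
#'
#' Bundles a clone tree with the remaining per-sample truth a paired
#' tumor/organoid simulation needs: purities (organoid passages are pure,
#' primary tumors are not), average ploidy, and mean sequencing depth.
#'
#' @param tree A `clone_tree`, or `NULL` to simulate one from the `...`
#'   arguments passed to [simulate_clone_tree()].
#' @param tumor_purity Purity of the first (tumor) sample, in `(0, 1]`.
#'   Primary tumors in resection cohorts typically fall between roughly
#'   0.3 and 0.8; the default sits mid-range.
#' @param mean_depth Mean sequencing depth, recycled across samples.
#' @param ploidy Average ploidy per sample, recycled.
#' @param seed Integer seed (stored; used when `tree` is simulated here).
#' @param ... Passed to [simulate_clone_tree()] when `tree` is `NULL`.
#' @return A list of class `ground_truth` with elements `tree`, `purity`
#'   (named per sample), `ploidy`, `mean_depth`, `seed`.
#' @export
#' @examples
#' truth <- simulate_ground_truth(n_clones = 3, n_samples = 2, seed = 7)
#' truth$purity
simulate_ground_truth <- function(tree = NULL, tumor_purity = 0.55,
                                  mean_depth = 50, ploidy = 2, seed = 1L,
                                  ...) {
  if (is.null(tree)) {
    tree <- simulate_clone_tree(..., seed = seed)
  }
  if (tumor_purity <= 0 || tumor_purity > 1) {
    stop_input("`tumor_purity` must lie in (0, 1]")
  }
  if (any(mean_depth <= 0)) {
    stop_input("`mean_depth` must be positive")
  }
  samples <- attr(tree, "samples") %||% unique(tree$sample)
  purity <- setNames(c(tumor_purity, rep(1, length(samples) - 1L)), samples)
  structure(
    list(tree = tree,
         purity = purity,
         ploidy = setNames(rep_len(ploidy, length(samples)), samples),
         mean_depth = setNames(rep_len(mean_depth, length(samples)), samples),
         seed = seed),
    class = "ground_truth"
  )
}
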