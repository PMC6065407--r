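#' Simulate somatic mutations on a clone tree
#'
#' Assigns mutations to clones and draws each mutation's trinucleotide
#' channel from the exposure-weighted mixture of catalog signatures, so the
#' cohort's mutation spectrum reflects a known signature composition.
#' Positions are drawn without replacement over a toy genome of 22
#' chromosomes of 10 Mb each, which keeps chromosome-based QC testable.
#'
#' @param tree A `clone_tree` from [simulate_clone_tree()].
#' @param catalog A [signature_catalog()].
#' @param exposures Non-negative numeric vector, one entry per catalog
#'   signature: expected mutation counts (or any proportional weights)
#'   attributed to each signature. Must not be all zero.
#' @param n_mutations Number of mutations to draw (0 gives an empty table).
#' @param seed Integer seed.
#' @param clone_weights Relative mutation budget per clone; defaults to
#'   equal budgets across clones.
#' @return Tibble with columns `mutation_id`, `clone_id`, `channel`
#'   (1..96, COSMIC order), `chrom`, `pos`, `ref`, `alt`.
#' @export
#' @examples
#' tree <- simulate_clone_tree(2, 2, seed = 1)
#' cat6 <- random_signature_catalog(seed = 1)
#' muts <- simulate_mutations(tree, cat6, exposures = c(1, 0, 0, 0, 0, 0),
#'                            n_mutations = 100, seed = 2)
simulate_mutations <- function(tree, catalog, exposures, n_mutations,
                               seed = 1L, clone_weights = NULL) {
  stopifnot(inherits(catalog, "signature_catalog"))
  if (length(exposures) != nrow(catalog$matrix)) {
    stop_input("`exposures` must have one entry per catalog signature")
  }
  if (any(exposures < 0)) {
    stop_input("`exposures` must be non-negative")
  }
  if (sum(exposures) == 0) {
    stop_input("`exposures` must not be all zero")
  }
  if (n_mutations < 0) stop_input("`n_mutations` must be >= 0")
  clones <- sort(unique(tree$clone_id))
  clone_weights <- clone_weights %||% rep(1, length(clones))
  if (length(clone_weights) != length(clones) || any(clone_weights < 0)) {
    stop_input("`clone_weights` must be non-negative, one per clone")
  }
  empty <- tibble(mutation_id = integer(), clone_id = integer(),
                  channel = integer(), chrom = integer(), pos = integer(),
                  ref = character(), alt = character())
  if (n_mutations == 0) return(empty)

  channel_probs <- as.vector(exposures %*% catalog$matrix) / sum(exposures)
  with_seed(seed, {
    clone <- clones[sample.int(length(clones), n_mutations, replace = TRUE,
                               prob = clone_weights)]
    channel <- sample.int(96L, n_mutations, replace = TRUE,
                          prob = channel_probs)
    # unique loci over a 22 x 10 Mb toy genome
    idx <- sample(2.2e8, n_mutations, replace = FALSE)
    labels <- sbs96_channels()[channel]
    tibble(
      mutation_id = seq_len(n_mutations),
      clone_id = clone,
      channel = channel,
      chrom = as.integer((idx - 1) %/% 1e7 + 1),
      pos = as.integer((idx - 1) %% 1e7 + 1),
      ref = substr(labels, 3, 3),
      alt = substr(labels, 5, 5)
    )
  })
}

#' Simulate per-sample allele counts for simulated mutations
#'
#' Emulates the allele counts a somatic caller would tabulate from a BAM
#' file. For a mutation with cancer cell fraction `ccf`, mutation copy
#' number (multiplicity) `m` and locus total copy number `cn` in a sample
#' of purity `rho`, the expected variant allele fraction is
#' `rho * m * ccf / (rho * cn + (1 - rho) * 2)`. Depth is Poisson around
#' the sample's mean depth (or forced constant via `depth`), and the
#' alternate-read count is binomial at the expected VAF. Variants drawing
#' zero alternate reads are still emitted (caller-missed sites matter for
#' concordance and rescue).
#'
#' @param mutations Tibble from [simulate_mutations()].
#' @param tree The `clone_tree` the mutations were placed on.
#' @param truth A `ground_truth` from [simulate_ground_truth()].
#' @param sample Sample label; must be one of the tree's samples.
#' @param seed Integer seed.
#' @param depth Optional fixed depth overriding the Poisson draw.
#' @param total_cn Locus total copy number (scalar or per-mutation).
#' @param multiplicity Mutation copy number (scalar or per-mutation);
#'   1 corresponds to a heterozygous diploid event.
#' @param min_alt,min_vaf Detection rule applied to set the `called` flag
#'   (see [call_variants()]).
#' @return Tibble with columns `mutation_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `alt_count`, `depth`, `called`.
#' @export
simulate_read_counts <- function(mutations, tree, truth, sample, seed = 1L,
                                 depth = NULL, total_cn = 2,
                                 multiplicity = 1,
                                 min_alt = 3L, min_vaf = 0.05) {
  samples <- attr(tree, "samples") %||% unique(tree$sample)
  if (!sample %in% samples) {
    stop_input(sprintf("unknown sample label '%s'", sample))
  }
  n <- nrow(mutations)
  tree_s <- tree |> filter(.data$sample == !!sample)
  ccf <- tree_s$ccf[match(mutations$clone_id, tree_s$clone_id)]
  rho <- truth$purity[[sample]]
  cn <- rep_len(total_cn, n)
  m <- rep_len(multiplicity, n)
  evaf <- expected_vaf(ccf, rho, cn, m)
  with_seed(seed, {
    dp <- if (is.null(depth)) rpois(n, truth$mean_depth[[sample]]) else rep_len(depth, n)
    alt <- rbinom(n, dp, evaf)
    out <- mutations |>
      select("mutation_id", "chrom", "pos", "ref", "alt") |>
      rename(alt_allele = "alt") |>
      mutate(sample = !!sample, alt_count = alt, depth = dp) |>
      rename(alt = "alt_allele")
    call_variants(out, min_alt = min_alt, min_vaf = min_vaf)
  })
}

#' Expected variant allele fraction under purity and copy number
#'
#' @param ccf Cancer cell fraction of the mutation's clone.
#' @param purity Sample purity in `(0, 1]`.
#' @param total_cn Tumor total copy number at the locus.
#' @param multiplicity Copies of the mutant allele per tumor cell.
#' @return Expected VAF in `[0, 1]`.
#' @export
#' @examples
#' expected_vaf(1, 0.5, 2, 1)  # 0.25
expected_vaf <- function(ccf, purity, total_cn = 2, multiplicity = 1) {
  if (any(purity <= 0 | purity > 1)) stop_input("`purity` must be in (0, 1]")
  purity * multiplicity * ccf / (purity * total_cn + (1 - purity) * 2)
}

#' Apply the detection rule that emulates a somatic caller
#'
#' A variant counts as called in a sample when it has at least `min_alt`
#' alternate reads and an observed VAF of at least `min_vaf`. This stands in
#' for the caller-plus-filters stack whose per-call behavior the upstream
#' tools do not expose numerically.
#'
#' @param observations Tibble with `alt_count` and `depth` columns.
#' @param min_alt Minimum alternate reads (default 3).
#' @param min_vaf Minimum observed VAF (default 0.05).
#' @return The input with a logical `called` column (re)computed.
#' @export
call_variants <- function(observations, min_alt = 3L, min_vaf = 0.05) {
  observations |>
    mutate(called = .data$alt_count >= min_alt &
             .data$depth > 0 &
             .data$alt_count / pmax(.data$depth, 1L) >= min_vaf)
}
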