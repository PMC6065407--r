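#' Variant allele fraction
#'
#' @param alt_count Alternate-allele read count(s).
#' @param depth Total read depth(s); zero depth yields `NA` (undefined VAF).
#' @return Numeric VAF(s) in `[0, 1]`.
#' @export
#' @examples
#' compute_vaf(8, 33)
#' compute_vaf(23, 23)
compute_vaf <- function(alt_count, depth) {
  if (any(depth < 0)) stop_input("`depth` must be non-negative")
  if (any(alt_count > depth)) stop_input("`alt_count` cannot exceed `depth`")
  if (any(alt_count < 0)) stop_input("`alt_count` must be non-negative")
  ifelse(depth == 0, NA_real_, alt_count / depth)
}

#' Pair tumor and organoid observations into variant trios
#'
#' Joins per-sample variant observations on (chrom, pos, ref, alt) and
#' models the pooled call: pooling tumor and organoid reads increases depth
#' at sites where a subclonal variant hovers below the caller's threshold
#' in one sample, so the pooled-call flag is the detection rule applied to
#' the summed alternate counts and summed depths.
#'
#' @param tumor,organoid Tibbles of per-sample observations with columns
#'   `chrom`, `pos`, `ref`, `alt`, `alt_count`, `depth`, `called`.
#' @param min_alt,min_vaf Detection rule used for the pooled call.
#' @return Tibble with one row per variant: key columns plus
#'   `tumor_alt`, `tumor_depth`, `tumor_called`, `organoid_alt`,
#'   `organoid_depth`, `organoid_called`, `pooled_called`.
#' @export
build_trios <- function(tumor, organoid, min_alt = 3L, min_vaf = 0.05) {
  key <- c("chrom", "pos", "ref", "alt")
  t <- tumor |> select(dplyr::all_of(key), tumor_alt = "alt_count",
                       tumor_depth = "depth", tumor_called = "called")
  o <- organoid |> select(dplyr::all_of(key), organoid_alt = "alt_count",
                          organoid_depth = "depth", organoid_called = "called")
  dplyr::full_join(t, o, by = key) |>
    mutate(across(c("tumor_alt", "tumor_depth", "organoid_alt",
                    "organoid_depth"), ~ tidyr::replace_na(.x, 0L)),
           across(c("tumor_called", "organoid_called"),
                  ~ tidyr::replace_na(.x, FALSE)),
           pooled_alt = .data$tumor_alt + .data$organoid_alt,
           pooled_depth = .data$tumor_depth + .data$organoid_depth,
           pooled_called = .data$pooled_alt >= min_alt &
             .data$pooled_depth > 0 &
             .data$pooled_alt / pmax(.data$pooled_depth, 1L) >= min_vaf)
}

#' Classify each variant trio with the pooled-rescue rule
#'
#' A variant called in both samples is shared. A variant called in only one
#' sample is rescued into the shared class when the pooled call succeeds
#' and the variant allele is represented (at least `min_rescue_alt` reads)
#' in the other sample's alignment; otherwise it stays unique to the sample
#' it was called in. Variants called nowhere are `absent`.
#'
#' @param trios Tibble from [build_trios()] (columns `tumor_called`,
#'   `organoid_called`, `tumor_alt`, `organoid_alt`, `pooled_called`).
#' @param rescue Apply the pooled rescue (default `TRUE`); with `FALSE` the
#'   classification uses per-sample calls only.
#' @param min_rescue_alt Minimum alternate reads for "the variant allele is
#'   represented" in the uncalled sample; literal reading is 1 read.
#' @return The input with `status` (`shared`, `tumor_only`, `organoid_only`,
#'   `absent`) and logical `rescued` columns.
#' @export
rescue_status <- function(trios, rescue = TRUE, min_rescue_alt = 1L) {
  trios |>
    mutate(
      rescued = rescue & .data$pooled_called & (
        (.data$tumor_called & !.data$organoid_called &
           .data$organoid_alt >= min_rescue_alt) |
          (.data$organoid_called & !.data$tumor_called &
             .data$tumor_alt >= min_rescue_alt)),
      status = case_when(
        .data$tumor_called & .data$organoid_called ~ "shared",
        .data$rescued ~ "shared",
        .data$tumor_called ~ "tumor_only",
        .data$organoid_called ~ "organoid_only",
        .default = "absent"
      )
    )
}

#' Summarize tumor-organoid variant concordance
#'
#' Applies [rescue_status()] and reports counts and proportions of shared,
#' tumor-only and organoid-only variants over the union of present variants
#' (absent variants are excluded from all denominators).
#'
#' @param trios Tibble from [build_trios()].
#' @inheritParams rescue_status
#' @return One-row tibble of class `concordance_summary`: `n_shared`,
#'   `n_tumor_only`, `n_organoid_only`, `n_rescued`, `prop_shared`,
#'   `prop_tumor_only`, `prop_organoid_only`.
#' @export
summarize_concordance <- function(trios, rescue = TRUE, min_rescue_alt = 1L) {
  if (nrow(trios) == 0) stop_input("no variant trios supplied")
  st <- rescue_status(trios, rescue = rescue, min_rescue_alt = min_rescue_alt)
  present <- st |> filter(.data$status != "absent")
  n <- nrow(present)
  if (n == 0) stop_input("no variant is present in either sample")
  out <- tibble(
    n_shared = sum(present$status == "shared"),
    n_tumor_only = sum(present$status == "tumor_only"),
    n_organoid_only = sum(present$status == "organoid_only"),
    n_rescued = sum(present$rescued)
  ) |>
    mutate(prop_shared = .data$n_shared / n,
           prop_tumor_only = .data$n_tumor_only / n,
           prop_organoid_only = .data$n_organoid_only / n)
  class(out) <- c("concordance_summary", class(out))
  out
}

#' Overlay variants on cancer driver gene intervals
#'
#' Assigns variants to genes by interval overlap (1-based positions,
#' half-open `[start, end)` intervals) and reports presence and VAF per
#' gene and sample, the per-gene view used to compare driver events
#' between a tumor and its organoid.
#'
#' @param trios Tibble from [build_trios()], ideally after
#'   [rescue_status()].
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end`
#'   (half-open).
#' @return Tibble with one row per (gene, sample): `gene`, `sample`,
#'   `n_variants`, `mean_vaf`, `status` (concordance status of the gene's
#'   variants).
#' @export
driver_overlay <- function(trios, genes) {
  if (any(genes$end <= genes$start)) {
    stop_input("gene intervals must satisfy end > start (half-open)")
  }
  if (!"status" %in% names(trios)) trios <- rescue_status(trios)
  hits <- dplyr::inner_join(trios, genes, by = "chrom",
                            relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos < .data$end)
  hits |>
    mutate(tumor_vaf = compute_vaf(.data$tumor_alt, .data$tumor_depth),
           organoid_vaf = compute_vaf(.data$organoid_alt,
                                      .data$organoid_depth)) |>
    tidyr::pivot_longer(c("tumor_vaf", "organoid_vaf"),
                        names_to = "sample", values_to = "vaf") |>
    mutate(sample = sub("_vaf$", "", .data$sample)) |>
    group_by(.data$gene, .data$sample) |>
    summarise(n_variants = n(),
              mean_vaf = mean(.data$vaf, na.rm = TRUE),
              status = paste(sort(unique(.data$status)), collapse = ","),
              .groups = "drop")
}
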