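#' Classify a copy-number segment relative to sample ploidy
#'
#' Cut-offs are defined on the segmental total copy number `cn` relative to
#' the sample's average ploidy `p_s`: deletion when `cn = 0`; amplification
#' when `cn >= 2 * p_s`; gain when `1.25 * p_s < cn < 2 * p_s`; loss when
#' `0 < cn < 0.75 * p_s`; neutral otherwise. The gain/amplification
#' boundary makes the five classes a partition. Vectorized over `total_cn`.
#'
#' @param total_cn Segment total copy number(s), >= 0.
#' @param ploidy Sample average ploidy `p_s` (> 0).
#' @return Character vector of classes in
#'   `{deletion, loss, neutral, gain, amplification}`.
#' @export
#' @examples
#' classify_segment(c(0, 1, 2, 2.6, 4), ploidy = 2)
classify_segment <- function(total_cn, ploidy) {
  if (any(ploidy <= 0)) stop_input("`ploidy` must be positive")
  if (any(total_cn < 0)) stop_input("`total_cn` must be non-negative")
  case_when(
    total_cn == 0 ~ "deletion",
    total_cn >= 2 * ploidy ~ "amplification",
    total_cn > 1.25 * ploidy ~ "gain",
    total_cn < 0.75 * ploidy ~ "loss",
    .default = "neutral"
  )
}

#' Average copy number over a gene family
#'
#' Pathway-level copy-number status (e.g. the RAS family summarizing HRAS,
#' KRAS and NRAS) is the arithmetic mean of the member genes' total copy
#' numbers, classified with the same ploidy-relative cut-offs.
#'
#' @param gene_cns Numeric vector of per-gene total copy numbers (>= 1 gene),
#'   or a tibble with a `total_cn` column.
#' @param ploidy Sample average ploidy.
#' @return One-row tibble: `mean_cn`, `class`.
#' @export
#' @examples
#' family_average(c(2, 6, 2), ploidy = 2)
family_average <- function(gene_cns, ploidy) {
  if (is.data.frame(gene_cns)) gene_cns <- gene_cns$total_cn
  if (length(gene_cns) == 0) stop_input("gene family must contain >= 1 gene")
  m <- mean(gene_cns)
  tibble(mean_cn = m, class = classify_segment(m, ploidy))
}

#' Flag loss of heterozygosity
#'
#' LOH means the minor allele is lost while some copy of the locus remains:
#' minor copy number 0 with total copy number above 0. A homozygous
#' deletion (total 0) is a deletion, not LOH.
#'
#' @param total_cn,minor_cn Numeric vectors (or a tibble with those columns
#'   as the first argument).
#' @return Logical vector.
#' @export
loh_flag <- function(total_cn, minor_cn = NULL) {
  if (is.data.frame(total_cn)) {
    minor_cn <- total_cn$minor_cn
    total_cn <- total_cn$total_cn
  }
  minor_cn == 0 & total_cn > 0
}

#' Genome fraction amplified, deleted, and under LOH
#'
#' Length-weighted fractions of the profiled genome whose segments classify
#' as amplification or deletion relative to ploidy, or carry LOH. Tracked
#' across passages, these fractions summarize large-scale genomic
#' stability of a culture.
#'
#' @param segments Tibble with `chrom`, `start`, `end` (half-open),
#'   `total_cn`, `minor_cn`.
#' @param ploidy Sample average ploidy.
#' @return One-row tibble: `amplified`, `deleted`, `loh`, `total_bp`.
#' @export
genome_fraction_altered <- function(segments, ploidy) {
  if (nrow(segments) == 0) stop_input("profile has no segments")
  len <- segments$end - segments$start
  if (any(len <= 0)) stop_input("segments must satisfy end > start")
  total <- sum(len)
  if (total <= 0) stop_input("profile has zero total segment length")
  cls <- classify_segment(segments$total_cn, ploidy)
  tibble(
    amplified = sum(len[cls == "amplification"]) / total,
    deleted = sum(len[cls == "deletion"]) / total,
    loh = sum(len[loh_flag(segments$total_cn, segments$minor_cn)]) / total,
    total_bp = total
  )
}

#' Filter structural variant calls
#'
#' Applies the artifact filters used for short-read SV call sets: calls
#' with a breakpoint in blacklisted regions (assembly gaps, satellites,
#' long simple repeats, extreme-depth regions) are removed; deletions
#' under 1000 bp without at least one supporting read are removed; and
#' inversions under 10 kb are removed as likely artefacts. Every call is
#' returned with its fate and reason, so the filter is auditable.
#'
#' @param svs Tibble with columns `sv_type` (`deletion`, `duplication`,
#'   `inversion`, `translocation`), `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `size` (bp, intra-chromosomal types), `supporting_reads`.
#' @param blacklist Tibble of half-open intervals: `chrom`, `start`, `end`.
#' @return The input with `retained` (logical) and `reject_reason`
#'   (`NA` when retained).
#' @export
#' @examples
#' svs <- tibble::tibble(sv_type = "inversion", chrom1 = 1, pos1 = 100,
#'                       chrom2 = 1, pos2 = 5100, size = 5000,
#'                       supporting_reads = 20)
#' filter_svs(svs, blacklist = tibble::tibble(chrom = integer(),
#'                                            start = integer(),
#'                                            end = integer()))
filter_svs <- function(svs, blacklist) {
  intra <- svs$sv_type %in% c("deletion", "duplication", "inversion")
  if (any(intra & (is.na(svs$size) | svs$size <= 0))) {
    stop_input("intra-chromosomal SVs must have size > 0")
  }
  in_blacklist <- function(chrom, pos) {
    if (nrow(blacklist) == 0) return(rep(FALSE, length(pos)))
    vapply(seq_along(pos), function(i) {
      any(blacklist$chrom == chrom[i] &
            pos[i] >= blacklist$start & pos[i] < blacklist$end)
    }, logical(1))
  }
  bl <- in_blacklist(svs$chrom1, svs$pos1) | in_blacklist(svs$chrom2, svs$pos2)
  small_del <- svs$sv_type == "deletion" & svs$size < 1000 &
    svs$supporting_reads < 1
  small_inv <- svs$sv_type == "inversion" & svs$size < 10000
  svs |>
    mutate(
      reject_reason = case_when(
        bl ~ "blacklist_overlap",
        small_del ~ "small_unsupported_deletion",
        small_inv ~ "small_inversion",
        .default = NA_character_
      ),
      retained = is.na(.data$reject_reason)
    )
}
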