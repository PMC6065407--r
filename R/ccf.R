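#' Estimate cancer cell fractions from allele counts
#'
#' Converts observed VAFs to cancer cell fractions with the standard
#' purity/copy-number correction. For an observation with VAF `v`, purity
#' `rho` and locus total copy number `cn`, the read-weighted denominator is
#' `d = rho * cn + (1 - rho) * 2`. The mutation multiplicity is estimated
#' as `m = clamp(round(v * d / rho), 1, max(cn, 1))` and the CCF is
#' `v * d / (rho * m)`, clipped to `[0, 1.5]`; clipping is recorded.
#'
#' @param observations Tibble with columns `alt_count`, `depth`, `purity`
#'   and optionally `total_cn` (default 2).
#' @return The input with `vaf`, `multiplicity`, `ccf`, `ccf_clipped`
#'   columns added.
#' @export
#' @examples
#' estimate_ccf(tibble::tibble(alt_count = 25, depth = 100,
#'                             purity = 0.5, total_cn = 2))
estimate_ccf <- function(observations) {
  if (!"total_cn" %in% names(observations)) observations$total_cn <- 2
  if (any(observations$purity <= 0 | observations$purity > 1)) {
    stop_input("`purity` must lie in (0, 1]")
  }
  if (any(observations$depth <= 0)) {
    stop_input("`depth` must be positive for CCF estimation")
  }
  observations |>
    mutate(
      vaf = .data$alt_count / .data$depth,
      .denom = .data$purity * .data$total_cn + (1 - .data$purity) * 2,
      multiplicity = pmin(pmax(round(.data$vaf * .denom / .data$purity), 1),
                          pmax(.data$total_cn, 1)),
      .raw_ccf = .data$vaf * .denom / (.data$purity * .data$multiplicity),
      ccf = pmin(pmax(.raw_ccf, 0), 1.5),
      ccf_clipped = .raw_ccf != .data$ccf
    ) |>
    select(-".denom", -".raw_ccf")
}
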