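#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_tile
#'   facet_wrap labs scale_fill_gradient2 scale_x_log10 theme_minimal
#'   autoplot
NULL

#' @export
ggplot2::autoplot

#' Stacked concordance proportions
#'
#' @param object A `concordance_summary` (rows may carry a `sample` or
#'   `patient` column for faceting/stacking several cases).
#' @param ... Unused.
#' @return A ggplot: stacked shared / tumor-only / organoid-only
#'   proportions.
#' @method autoplot concordance_summary
#' @export
autoplot.concordance_summary <- function(object, ...) {
  df <- as_tibble(object)
  if (!"case" %in% names(df)) df$case <- paste0("case", seq_len(nrow(df)))
  long <- df |>
    tidyr::pivot_longer(dplyr::all_of(c("prop_shared", "prop_tumor_only",
                                        "prop_organoid_only")),
                        names_to = "status", values_to = "proportion") |>
    mutate(status = sub("^prop_", "", .data$status))
  ggplot(long, aes(x = .data$case, y = .data$proportion,
                   fill = .data$status)) +
    geom_col() +
    labs(x = NULL, y = "proportion of union",
         title = "Tumor-organoid variant concordance") +
    theme_minimal()
}

#' Dose-response curves
#'
#' @param object A `dose_response_fit` tibble.
#' @param ... Unused.
#' @return A ggplot of viability against concentration with the fitted
#'   logistic overlaid, one facet per (organoid, compound).
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  pts <- object |>
    mutate(curve = paste(.data$organoid, .data$compound)) |>
    select("curve", "log10_ic50", "slope", "conc", "viability") |>
    tidyr::unnest(c("conc", "viability"))
  curves <- pts |>
    group_by(.data$curve, .data$log10_ic50, .data$slope) |>
    summarise(lo = min(log10(.data$conc)), hi = max(log10(.data$conc)),
              .groups = "drop") |>
    filter(is.finite(.data$log10_ic50)) |>
    purrr::pmap(function(curve, log10_ic50, slope, lo, hi) {
      x <- seq(lo, hi, length.out = 80)
      tibble(curve = curve, x = x,
             v = logistic_viability(x, log10_ic50, slope))
    }) |>
    list_rbind()
  ggplot(pts, aes(x = .data$conc, y = .data$viability)) +
    geom_point() +
    geom_line(data = curves,
              aes(x = 10^.data$x, y = .data$v)) +
    scale_x_log10() +
    facet_wrap(~curve) +
    labs(x = "concentration (M)", y = "relative viability") +
    theme_minimal()
}

#' Signature proportion trajectory across passages
#'
#' @param trajectory An `exposure_trajectory`.
#' @return A ggplot of per-signature proportions over passages.
#' @export
plot_exposure_trajectory <- function(trajectory) {
  df <- trajectory$exposures |>
    mutate(passage = factor(.data$passage,
                            levels = unique(.data$passage)))
  ggplot(df, aes(x = .data$passage, y = .data$proportion,
                 group = .data$signature, colour = .data$signature)) +
    geom_line() +
    geom_point() +
    labs(x = "passage", y = "signature proportion") +
    theme_minimal()
}

#' Tumor x organoid correlation heatmap
#'
#' @param object An `expression_concordance`.
#' @param ... Unused.
#' @return A ggplot heatmap ordered by the complete-linkage dendrograms.
#' @method autoplot expression_concordance
#' @export
autoplot.expression_concordance <- function(object, ...) {
  df <- tidy(object) |>
    mutate(tumor = factor(.data$tumor, levels = object$row_order),
           organoid = factor(.data$organoid, levels = object$col_order))
  ggplot(df, aes(x = .data$organoid, y = .data$tumor,
                 fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = "organoid", y = "tumor", fill = "Pearson r") +
    theme_minimal()
}

#' Clone CCF trajectories across passages
#'
#' @param object A `clone_dynamics`.
#' @param ... Unused.
#' @return A ggplot of per-clone CCFs over the sample series.
#' @method autoplot clone_dynamics
#' @export
autoplot.clone_dynamics <- function(object, ...) {
  ggplot(object$trajectory,
         aes(x = .data$sample, y = .data$ccf,
             group = factor(.data$cluster_id),
             colour = factor(.data$cluster_id))) +
    geom_line() +
    geom_point() +
    labs(x = "sample", y = "cancer cell fraction", colour = "clone",
         subtitle = paste("dynamics:", object$classification)) +
    theme_minimal()
}
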