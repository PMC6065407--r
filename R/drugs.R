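#' Fit a dose-response curve and derive IC50 and AUC
#'
#' Least-squares fit of a two-parameter logistic with asymptotes fixed at
#' 1 and 0 on range-normalized viability:
#' `v(x) = 1 / (1 + exp((x - x0) / s))`, `x = log10(concentration)`.
#' The IC50 is `10^x0`, reported as censored at the range edge when the
#' fitted midpoint falls outside the tested concentrations. AUC is the
#' mean fitted viability over the tested doses, so an all-viable curve has
#' AUC 1 and `1 - AUC` is a sensitivity score in `[0, 1]`. Initialization
#' is taken from the data (dose nearest half-maximal viability), making
#' the fit deterministic; on non-convergence the AUC falls back to the
#' trapezoid of the raw points and the fit is flagged.
#'
#' @param concentrations Molar concentrations (>= 5 points).
#' @param viabilities Non-negative viabilities (same length).
#' @param organoid,compound Labels carried into the result.
#' @return One-row tibble of class `dose_response_fit`: `organoid`,
#'   `compound`, `ic50`, `ic50_censored` (`"none"`, `"above"`, `"below"`),
#'   `log10_ic50`, `slope`, `auc`, `sensitivity`, `converged`, `rss`,
#'   plus list-columns `conc` and `viability` with the input data.
#' @export
#' @examples
#' d <- half_log_doses(1e-5)
#' fit_curve(d, 1 / (1 + exp((log10(d) - log10(1e-6)) / 0.3)))
fit_curve <- function(concentrations, viabilities,
                      organoid = NA_character_, compound = NA_character_) {
  keep <- is.finite(concentrations) & is.finite(viabilities)
  x <- log10(concentrations[keep])
  v <- viabilities[keep]
  if (length(x) < 5) stop_input("need at least 5 valid dose points")
  if (any(v < 0)) stop_input("viabilities must be non-negative")

  # initialize midpoint at the dose nearest half-maximal viability
  x0_init <- x[which.min(abs(v - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ 1 / (1 + exp((x - x0) / s)),
      start = list(x0 = x0_init, s = 0.5),
      lower = c(min(x) - 6, 0.01), upper = c(max(x) + 6, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    # degenerate or non-convergent data: AUC from the trapezoid of the raw
    # points; the midpoint lies beyond whichever edge the response favors
    ord <- order(x)
    auc <- sum(diff(x[ord]) * (head(v[ord], -1) + tail(v[ord], -1)) / 2) /
      diff(range(x))
    auc <- min(max(auc, 0), 1)
    censored <- if (auc > 0.5) "above" else "below"
    out <- tibble(organoid = organoid, compound = compound,
                  ic50 = 10^(if (auc > 0.5) max(x) else min(x)),
                  ic50_censored = censored,
                  log10_ic50 = NA_real_, slope = NA_real_,
                  auc = auc, sensitivity = 1 - auc,
                  converged = FALSE, rss = NA_real_)
  } else {
    cf <- stats::coef(fit)
    x0 <- unname(cf["x0"]); s <- unname(cf["s"])
    fitted_v <- logistic_viability(x, x0, s)
    auc <- min(max(mean(fitted_v), 0), 1)
    censored <- if (x0 > max(x)) "above" else if (x0 < min(x)) "below" else "none"
    ic50 <- 10^switch(censored, above = max(x), below = min(x), none = x0)
    out <- tibble(organoid = organoid, compound = compound,
                  ic50 = ic50, ic50_censored = censored,
                  log10_ic50 = x0, slope = s, auc = auc,
                  sensitivity = 1 - auc, converged = TRUE,
                  rss = sum((v - fitted_v)^2))
  }
  out$conc <- list(10^x)
  out$viability <- list(v)
  class(out) <- c("dose_response_fit", class(out))
  out
}

#' Fit dose-response curves for a long-format plate table
#'
#' Viability is the well signal divided by the median negative-control
#' signal of the same (organoid, compound) block; values above 1 are kept.
#'
#' @param plate Long tibble with columns `organoid`, `compound`, `role`,
#'   `concentration`, and `viability` (or `signal`).
#' @return A `dose_response_fit` tibble, one row per (organoid, compound).
#' @export
fit_plate <- function(plate) {
  if (!"viability" %in% names(plate) && "signal" %in% names(plate)) {
    plate <- rename(plate, viability = "signal")
  }
  plate |>
    group_by(.data$organoid, .data$compound) |>
    dplyr::group_map(function(df, key) {
      neg <- median(df$viability[df$role == "neg_ctrl"])
      scale <- if (is.finite(neg) && neg > 0) neg else 1
      smp <- df |> filter(.data$role == "sample")
      fit_curve(smp$concentration, smp$viability / scale,
                organoid = key$organoid, compound = key$compound)
    }) |>
    list_rbind() |>
    (\(x) { class(x) <- c("dose_response_fit", class(x)); x })()
}

#' Plate quality control by Z-factor
#'
#' `Z = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Z is at most 1;
#' positive values indicate controls separated well beyond their spread.
#'
#' @param negative_controls,positive_controls Numeric vectors (>= 2 wells
#'   each); negative controls are untreated (full viability), positive
#'   controls fully inhibited.
#' @return One-row tibble of class `plate_qc`: `z_factor`, `n_neg`,
#'   `n_pos`, `mean_neg`, `sd_neg`, `mean_pos`, `sd_pos`, `separated`.
#' @export
#' @examples
#' z_factor(rnorm(16, 1, 0.05), rnorm(16, 0, 0.05))
z_factor <- function(negative_controls, positive_controls) {
  if (length(negative_controls) < 2 || length(positive_controls) < 2) {
    stop_input("need at least 2 wells per control group")
  }
  mn <- mean(negative_controls); mp <- mean(positive_controls)
  if (mn == mp) {
    abort("control means are equal; Z-factor undefined",
          class = "concord_undefined_zfactor")
  }
  z <- 1 - 3 * (sd(positive_controls) + sd(negative_controls)) / abs(mp - mn)
  out <- tibble(z_factor = z,
                n_neg = length(negative_controls),
                n_pos = length(positive_controls),
                mean_neg = mn, sd_neg = sd(negative_controls),
                mean_pos = mp, sd_pos = sd(positive_controls),
                separated = z > 0)
  class(out) <- c("plate_qc", class(out))
  out
}

#' Replicate concordance of drug-response metrics
#'
#' Spearman rank correlation of AUC (or IC50) across replicate screens,
#' over the (organoid, compound) pairs present in both. Censored IC50s
#' already sit at the range edge, so ranks are well defined.
#'
#' @param fits_rep1,fits_rep2 `dose_response_fit` tibbles.
#' @param metric `"auc"` or `"ic50"`.
#' @return One-row tibble: `metric`, `n_pairs`, `spearman`.
#' @export
replicate_correlation <- function(fits_rep1, fits_rep2,
                                  metric = c("auc", "ic50")) {
  metric <- match.arg(metric)
  key <- c("organoid", "compound")
  j <- dplyr::inner_join(
    fits_rep1 |> select(dplyr::all_of(key), v1 = dplyr::all_of(metric)),
    fits_rep2 |> select(dplyr::all_of(key), v2 = dplyr::all_of(metric)),
    by = key
  )
  if (nrow(j) < 5) stop_input("need at least 5 shared (organoid, compound) pairs")
  tibble(metric = metric, n_pairs = nrow(j),
         spearman = cor(j$v1, j$v2, method = "spearman"))
}

#' Sensitivity matrix and potency counts across a drug panel
#'
#' Builds the organoids x compounds matrix of `1 - AUC` sensitivity
#' scores, counts per organoid how many compounds elicit an uncensored
#' IC50 below 1 uM and below 0.1 uM, and clusters both axes
#' (complete-linkage, Euclidean).
#'
#' @param fits A `dose_response_fit` tibble covering the panel.
#' @return Object of class `sensitivity_matrix`: list with `matrix`
#'   (1 - AUC), `counts` (tibble: `organoid`, `n_ic50_below_1uM`,
#'   `n_ic50_below_0.1uM`), `row_order`, `col_order`.
#' @export
sensitivity_matrix <- function(fits) {
  wide <- fits |>
    select("organoid", "compound", "sensitivity") |>
    tidyr::pivot_wider(names_from = "compound", values_from = "sensitivity")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$organoid
  counts <- fits |>
    group_by(.data$organoid) |>
    summarise(
      n_ic50_below_1uM = sum(.data$ic50_censored == "none" &
                               .data$ic50 < 1e-6, na.rm = TRUE),
      n_ic50_below_0.1uM = sum(.data$ic50_censored == "none" &
                                 .data$ic50 < 1e-7, na.rm = TRUE),
      .groups = "drop"
    )
  row_order <- rownames(m)
  col_order <- colnames(m)
  if (nrow(m) > 1 && !anyNA(m)) {
    row_order <- rownames(m)[hclust(dist(m), "complete")$order]
  }
  if (ncol(m) > 1 && !anyNA(m)) {
    col_order <- colnames(m)[hclust(dist(t(m)), "complete")$order]
  }
  structure(
    list(matrix = m, counts = counts,
         row_order = row_order, col_order = col_order),
    class = "sensitivity_matrix"
  )
}

#' Anchored chemotherapy combination plate design
#'
#' The standard triplet layout: two anchor drugs held at fixed
#' concentrations in every well while the third is titrated along the
#' 7-point half-log ladder. Defaults follow the cisplatin (4 uM) +
#' 5-fluorouracil (10 uM) anchors with epirubicin titrated from 10 uM.
#'
#' @param anchor_a,anchor_b Named lists `list(compound =, concentration =)`
#'   (molar, > 0).
#' @param titrated List `list(compound =, max_conc =)`.
#' @param n_points Ladder length (default 7).
#' @return Tibble: `well`, one column per anchor compound, `titrated_compound`,
#'   `titrated_concentration`.
#' @export
#' @examples
#' anchored_combination_layout()
anchored_combination_layout <- function(
    anchor_a = list(compound = "cisplatin", concentration = 4e-6),
    anchor_b = list(compound = "5-fluorouracil", concentration = 1e-5),
    titrated = list(compound = "epirubicin", max_conc = 1e-5),
    n_points = 7) {
  if (anchor_a$concentration <= 0 || anchor_b$concentration <= 0 ||
      titrated$max_conc <= 0) {
    stop_input("anchor and titrated concentrations must be positive")
  }
  doses <- half_log_doses(titrated$max_conc, n_points)
  out <- tibble(well = paste0("W", seq_len(n_points)))
  out[[anchor_a$compound]] <- anchor_a$concentration
  out[[anchor_b$compound]] <- anchor_b$concentration
  out$titrated_compound <- titrated$compound
  out$titrated_concentration <- doses
  out
}
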