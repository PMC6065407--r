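#' Simulate a paired tumor/normal/organoid expression cohort
#'
#' Generates negative-binomial gene counts for a cohort in which every
#' patient contributes one primary tumor sample and several organoid
#' passages, alongside a panel of normal squamous samples. Three gene
#' programs are planted on top of a lognormal baseline:
#'
#' * a **tumor program**, up-regulated in all tumors and organoids relative
#'   to normals (malignant identity shared by tumor and model);
#' * a **culture program**, shifted in all organoids regardless of patient
#'   (the in vitro environment effect that patient-specific gene selection
#'   must discard);
#' * a **patient program** per patient: genes carrying the tumor-program
#'   shift plus an additional signed modulation shared only by that
#'   patient's tumor and organoid passages. Layering the patient effect on
#'   tumor-program genes is deliberate — a gene expressed only in one
#'   patient could never pass a cohort-level normal-vs-tumor filter, so
#'   patient identity in this simulation lives in genes that are already
#'   tumor-associated, as it does in real cohorts.
#'
#' @param n_genes Total genes; must exceed the summed program sizes.
#' @param patients Number of patients (>= 2) or a character vector of labels.
#' @param seed Integer seed.
#' @param n_passages Organoid passages sequenced per patient.
#' @param n_normals Number of normal squamous samples.
#' @param n_tumor_program,n_culture_program,n_patient_program Program sizes
#'   (patient program is per patient; programs are disjoint).
#' @param lfc_tumor,lfc_culture Log2 effect sizes of the shared programs.
#' @param patient_lfc_range Magnitude range of the per-gene patient
#'   modulation (sign random per gene).
#' @param dispersion Negative-binomial dispersion. Either a single value
#'   (constant 1/size for every gene) or, as in the default, a length-2
#'   vector `c(a0, a1)` giving the standard mean-dependent trend
#'   `a0 + a1 / mu`: weakly expressed genes are strongly overdispersed
#'   while highly expressed genes approach the asymptotic dispersion
#'   `a0`, the shape parametric fits recover from bulk RNA-seq.
#' @return A list of class `expression_sim`: `counts` (tibble, `gene` column
#'   plus one column per sample), `samples` (tibble: `sample`, `class`,
#'   `patient`), and `truth` (planted program gene ids and effects).
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 300, patients = 2, seed = 1,
#'                            n_patient_program = 10)
#' dim(sim$counts)
simulate_expression <- function(n_genes = 2000, patients = 6, seed = 1L,
                                n_passages = 3, n_normals = 6,
                                n_tumor_program = 150,
                                n_culture_program = 100,
                                n_patient_program = 50,
                                lfc_tumor = 2, lfc_culture = 1.5,
                                patient_lfc_range = c(0.6, 1),
                                dispersion = c(0.02, 4)) {
  pat <- if (is.character(patients)) patients else paste0("PAT", seq_len(patients))
  if (length(pat) < 2) stop_input("need at least 2 patients")
  need <- n_tumor_program + n_culture_program + n_patient_program * length(pat)
  if (n_genes < need) {
    stop_input(sprintf("`n_genes` (%d) smaller than total program sizes (%d)",
                       n_genes, need))
  }

  samples <- bind_rows(
    tibble(sample = paste0(pat, "_T"), class = "tumor", patient = pat),
    tidyr::expand_grid(patient = pat, passage = seq_len(n_passages)) |>
      mutate(sample = paste0(.data$patient, "_O", .data$passage),
             class = "organoid") |>
      select("sample", "class", "patient"),
    tibble(sample = paste0("N", seq_len(n_normals)), class = "normal",
           patient = NA_character_)
  )

  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    # program gene blocks are disjoint; high baseline means for the patient
    # programs so they rank at the top of base-mean expression
    idx <- seq_len(need)
    tumor_idx <- idx[seq_len(n_tumor_program)]
    culture_idx <- idx[n_tumor_program + seq_len(n_culture_program)]
    patient_idx <- split(
      idx[n_tumor_program + n_culture_program +
            seq_len(n_patient_program * length(pat))],
      rep(pat, each = n_patient_program)
    )

    mu <- exp(rnorm(n_genes, log(20), 1))
    mu[tumor_idx] <- exp(rnorm(n_tumor_program, log(80), 0.6))
    mu[culture_idx] <- exp(rnorm(n_culture_program, log(80), 0.6))
    for (p in pat) {
      mu[patient_idx[[p]]] <- exp(rnorm(n_patient_program, log(600), 0.35))
    }

    mag <- patient_lfc_range
    patient_effect <- lapply(setNames(pat, pat), function(p) {
      sign <- sample(c(-1, 1), n_patient_program, replace = TRUE)
      sign * runif(n_patient_program, mag[1], mag[2])
    })

    log2fc_for_sample <- function(class, patient) {
      lfc <- numeric(n_genes)
      if (class != "normal") {
        lfc[tumor_idx] <- lfc[tumor_idx] + lfc_tumor
        for (p in pat) lfc[patient_idx[[p]]] <- lfc[patient_idx[[p]]] + lfc_tumor
      }
      if (class == "organoid") {
        lfc[culture_idx] <- lfc[culture_idx] + lfc_culture
      }
      if (!is.na(patient) && class != "normal") {
        lfc[patient_idx[[patient]]] <-
          lfc[patient_idx[[patient]]] + patient_effect[[patient]]
      }
      lfc
    }

    disp_of <- function(mu) {
      if (length(dispersion) == 1L) rep_len(dispersion, length(mu))
      else dispersion[1] + dispersion[2] / mu
    }
    counts <- tibble(gene = genes)
    for (i in seq_len(nrow(samples))) {
      lfc <- log2fc_for_sample(samples$class[i], samples$patient[i])
      mui <- mu * 2^lfc
      counts[[samples$sample[i]]] <-
        rnbinom(n_genes, mu = mui, size = 1 / disp_of(mui))
    }

    structure(
      list(counts = counts,
           samples = samples,
           truth = list(tumor_program = genes[tumor_idx],
                        culture_program = genes[culture_idx],
                        patient_program = lapply(patient_idx, function(i) genes[i]),
                        patient_effect = patient_effect,
                        base_mean = setNames(mu, genes))),
      class = "expression_sim"
    )
  })
}

#' Simulate a 7-point half-log dose-response plate
#'
#' Emulates a viability screen well block for one (organoid, compound)
#' pair: a half-log dilution ladder from `max_conc` spanning a 1000-fold
#' concentration range, a two-parameter logistic viability response with
#' Gaussian noise (clipped at zero), and positive/negative control wells.
#'
#' @param true_ic50 True IC50 in molar (> 0).
#' @param slope Sigmoid slope parameter on the log10-concentration axis.
#' @param max_conc Top concentration in molar (default 10 uM).
#' @param n_points Number of doses (default 7).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param organoid,compound Labels carried into the output table.
#' @param n_controls Wells per control group.
#' @return Long-format tibble with columns `organoid`, `compound`, `well`,
#'   `role` (`sample`, `neg_ctrl`, `pos_ctrl`), `concentration` (molar; `NA`
#'   for controls), `viability`.
#' @export
#' @examples
#' simulate_plate(1e-6, seed = 1)$viability
simulate_plate <- function(true_ic50, slope = 0.3, max_conc = 1e-5,
                           n_points = 7, noise_sd = 0.05, seed = 1L,
                           organoid = "ORG1", compound = "drug",
                           n_controls = 16) {
  if (true_ic50 <= 0) stop_input("`true_ic50` must be positive")
  if (noise_sd < 0) stop_input("`noise_sd` must be non-negative")
  doses <- half_log_doses(max_conc, n_points)
  truev <- logistic_viability(log10(doses), log10(true_ic50), slope)
  with_seed(seed, {
    v <- pmax(truev + rnorm(n_points, 0, noise_sd), 0)
    neg <- pmax(rnorm(n_controls, 1, noise_sd), 0)
    pos <- pmax(rnorm(n_controls, 0, noise_sd), 0)
    bind_rows(
      tibble(role = "sample", concentration = doses, viability = v),
      tibble(role = "neg_ctrl", concentration = NA_real_, viability = neg),
      tibble(role = "pos_ctrl", concentration = NA_real_, viability = pos)
    ) |>
      mutate(organoid = organoid, compound = compound,
             well = paste0("W", row_number())) |>
      select("organoid", "compound", "well", "role", "concentration",
             "viability")
  })
}

#' Half-log dilution ladder
#'
#' @param max_conc Top concentration (molar).
#' @param n_points Number of doses.
#' @return Strictly decreasing concentrations, each `10^0.5` below the last
#'   (7 points span a 1000-fold range).
#' @export
#' @examples
#' half_log_doses(1e-5)  # 10 uM down to 10 nM
half_log_doses <- function(max_conc, n_points = 7) {
  if (max_conc <= 0) stop_input("`max_conc` must be positive")
  max_conc * 10^(-0.5 * (seq_len(n_points) - 1))
}

# Two-parameter logistic on log10 concentration, asymptotes fixed at 1 / 0.
logistic_viability <- function(x, x0, s) {
  1 / (1 + exp((x - x0) / s))
}
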