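test_that("flat curves censor the IC50 at the range edges", {
  d <- half_log_doses(1e-5)
  hi <- fit_curve(d, rep(1, 7))
  expect_equal(hi$auc, 1, tolerance = 1e-6)
  expect_equal(hi$sensitivity, 0, tolerance = 1e-6)
  expect_equal(hi$ic50_censored, "above")
  expect_equal(hi$ic50, 1e-5, tolerance = 1e-9)
  lo <- fit_curve(d, rep(0, 7))
  expect_equal(lo$auc, 0, tolerance = 1e-6)
  expect_equal(lo$ic50_censored, "below")
  expect_error(fit_curve(d[1:4], rep(1, 4)), class = "concord_input_error")
  expect_error(fit_curve(d, rep(-1, 7)), class = "concord_input_error")
})

test_that("a noiseless sigmoid is recovered within 5% across the range", {
  d <- half_log_doses(1e-5)
  for (x0 in seq(-7.6, -5.4, by = 0.2)) {
    v <- 1 / (1 + exp((log10(d) - x0) / 0.3))
    fit <- fit_curve(d, v)
    expect_equal(fit$ic50_censored, "none")
    expect_lt(abs(fit$ic50 - 10^x0) / 10^x0, 0.05)
  }
})

test_that("IC50 censoring matches the viability at the top dose", {
  d <- half_log_doses(1e-5)
  for (seed in 1:12) {
    pl <- withr::with_seed(seed, {
      x0 <- stats::runif(1, -9, -4)
      simulate_plate(10^x0, noise_sd = 0.05, seed = seed)
    })
    fit <- fit_plate(pl)
    if (!fit$converged) next
    v_top <- concord:::logistic_viability(log10(max(d)), fit$log10_ic50, fit$slope)
    expect_equal(fit$ic50_censored == "above", v_top > 0.5)
  }
})

test_that("pointwise-lower viabilities never raise the AUC", {
  d <- half_log_doses(1e-5)
  v <- 1 / (1 + exp((log10(d) + 6.2) / 0.4))
  base <- fit_curve(d, v)$auc
  lower <- fit_curve(d, pmax(v - 0.15, 0))$auc
  expect_lte(lower, base + 1e-9)
})

test_that("the Z-factor matches its arithmetic definition", {
  qc <- z_factor(c(0.95, 1.05, 1, 0.95, 1.05), c(0, 0.1, -0.1 + 0.2, 0, 0))
  oracle <- function(neg, pos) 1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg))
  for (s in 1:5) {
    neg <- withr::with_seed(s, rnorm(16, 1, 0.05))
    pos <- withr::with_seed(100 + s, rnorm(16, 0, 0.05))
    expect_equal(z_factor(neg, pos)$z_factor, oracle(neg, pos),
                 tolerance = 1e-12)
  }
  # mu_n 1 sd 0.05, mu_p 0 sd 0.05: Z = 1 - 3 * 0.1 / 1 = 0.7
  expect_equal(z_factor(c(0.95, 1, 1.05), c(-0.05, 0, 0.05))$z_factor, 0.7,
               tolerance = 1e-9)
  expect_equal(z_factor(c(1, 1), c(0, 0))$z_factor, 1)
  expect_lt(z_factor(c(0.6, 1.4), c(-0.4, 0.4))$z_factor, 0)
  expect_error(z_factor(c(1, 1), c(1, 1)),
               class = "concord_undefined_zfactor")
  expect_error(z_factor(1, c(0, 0)), class = "concord_input_error")
})


test_that("replicate screens rank compounds concordantly", {
  ic50s <- withr::with_seed(5, 10^stats::runif(30, -7.5, -5.2))
  f1 <- replicate_panel(1, ic50s)
  f2 <- replicate_panel(2, ic50s)
  expect_equal(replicate_correlation(f1, f1, "auc")$spearman, 1)
  expect_gt(replicate_correlation(f1, f2, "auc")$spearman, 0.8)
  expect_gt(replicate_correlation(f1, f2, "ic50")$spearman, 0.8)
  # independently shuffled pairs lose the association
  shuf <- f2
  shuf$auc <- withr::with_seed(9, sample(shuf$auc))
  expect_lt(abs(replicate_correlation(f1, shuf, "auc")$spearman), 0.4)
  expect_error(replicate_correlation(f1[1:3, ], f2[1:3, ]),
               class = "concord_input_error")
})

test_that("sensitivity matrix counts potent compounds per organoid", {
  ic50s <- c(5e-8, 5e-7, 5e-6)
  fits <- purrr::map(seq_along(ic50s), function(i) {
    pl <- simulate_plate(ic50s[i], noise_sd = 0, seed = i,
                         organoid = "O1", compound = paste0("c", i))
    fit_plate(pl)
  }) |> purrr::list_rbind()
  flat <- fit_curve(half_log_doses(1e-5), rep(1, 7),
                    organoid = "O2", compound = "c1")
  sm <- sensitivity_matrix(dplyr::bind_rows(fits, flat))
  counts <- sm$counts
  expect_equal(counts$n_ic50_below_1uM[counts$organoid == "O1"], 2L)
  expect_equal(counts$n_ic50_below_0.1uM[counts$organoid == "O1"], 1L)
  expect_equal(counts$n_ic50_below_1uM[counts$organoid == "O2"], 0L)
  expect_true(all(sm$matrix >= 0 - 1e-9 & sm$matrix <= 1 + 1e-9, na.rm = TRUE))
})

test_that("identical organoids merge first in the sensitivity dendrogram", {
  mk <- function(org) {
    purrr::map(1:4, function(i) {
      pl <- simulate_plate(10^(-7 + 0.5 * i), noise_sd = 0, seed = i,
                           organoid = org, compound = paste0("c", i))
      fit_plate(pl)
    }) |> purrr::list_rbind()
  }
  twin1 <- mk("T1"); twin2 <- mk("T2")
  other <- purrr::map(1:4, function(i) {
    pl <- simulate_plate(1e-8, noise_sd = 0, seed = i,
                         organoid = "Z", compound = paste0("c", i))
    fit_plate(pl)
  }) |> purrr::list_rbind()
  sm <- sensitivity_matrix(dplyr::bind_rows(twin1, twin2, other))
  ord <- sm$row_order
  expect_equal(abs(match("T1", ord) - match("T2", ord)), 1L)
})

test_that("the anchored combination layout fixes anchors and titrates", {
  lay <- anchored_combination_layout()
  expect_equal(nrow(lay), 7L)
  expect_true(all(lay$cisplatin == 4e-6))
  expect_true(all(lay$`5-fluorouracil` == 1e-5))
  expect_equal(lay$titrated_concentration * 1e6,
               c(10, 3.1623, 1, 0.31623, 0.1, 0.031623, 0.01),
               tolerance = 1e-4)
  expect_error(anchored_combination_layout(
    anchor_a = list(compound = "cisplatin", concentration = 0)),
    class = "concord_input_error")
  # serialization round trip
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(lay, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(lay), tolerance = 1e-12)
})
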