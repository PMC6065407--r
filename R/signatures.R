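#' Fit mutational-signature exposures by non-negative least squares
#'
#' Models a genome's 96-channel mutation spectrum as a non-negative mixture
#' of catalog signatures: minimize `|| t(P) e - c ||^2` subject to
#' `e >= 0`, where `P` is the signatures x 96 probability matrix and `c`
#' the observed channel counts. This is the quadratic-programming exposure
#' fit in its standard non-negative least-squares form, solved exactly with
#' an active-set (Lawson-Hanson) iteration; the result is deterministic.
#'
#' @param counts Numeric vector of 96 non-negative channel counts in COSMIC
#'   order, or a tibble with columns `channel` and `count`.
#' @param catalog A [signature_catalog()].
#' @return A tibble of class `exposure_fit` with one row per signature:
#'   `signature`, `exposure` (mutations attributed), `proportion` (share of
#'   the total; `NA` when the spectrum is empty, with attribute
#'   `empty_spectrum = TRUE`).
#' @export
#' @examples
#' cat6 <- random_signature_catalog(seed = 1)
#' fit_exposures(500 * cat6$matrix[3, ], cat6)
fit_exposures <- function(counts, catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  counts <- spectrum_vector(counts)
  if (any(counts < 0)) stop_input("channel counts must be non-negative")
  A <- t(catalog$matrix)                     # 96 x n_signatures
  e <- nnls_fit(A, counts)
  total <- sum(e)
  out <- tibble(
    signature = catalog$names,
    exposure = e,
    proportion = if (total > 0) e / total else rep(NA_real_, length(e))
  )
  attr(out, "empty_spectrum") <- total == 0
  attr(out, "catalog_names") <- catalog$names
  class(out) <- c("exposure_fit", class(out))
  out
}

spectrum_vector <- function(counts) {
  if (is.data.frame(counts)) {
    if (!all(c("channel", "count") %in% names(counts))) {
      stop_input("spectrum tibble needs `channel` and `count` columns")
    }
    v <- numeric(96)
    ch <- counts$channel
    if (is.character(ch)) ch <- match(ch, sbs96_channels())
    v[ch] <- counts$count
    counts <- v
  }
  if (length(counts) != 96L) {
    stop_input("a mutation spectrum has 96 channels")
  }
  as.numeric(counts)
}

#' Tabulate a 96-channel spectrum from simulated mutations
#'
#' @param mutations Tibble with a `channel` column (1..96).
#' @return Integer vector of 96 channel counts.
#' @export
mutation_spectrum <- function(mutations) {
  tabulate(mutations$channel, nbins = 96L)
}

# Lawson-Hanson active-set non-negative least squares: argmin ||A x - b||^2
# s.t. x >= 0. A has few columns here (signatures), so the normal-equation
# solves are tiny; iteration count is bounded in practice.
nnls_fit <- function(A, b, tol = NULL) {
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)[, 1]
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(Atb), 1) * n)
  passive <- rep(FALSE, n)
  x <- numeric(n)
  w <- Atb - AtA %*% x
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      p <- which(passive)
      s[p] <- solve(AtA[p, p, drop = FALSE], Atb[p])
      if (all(s[p] > 0)) break
      # step back to the boundary, drop newly-zeroed variables
      neg <- p[s[p] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[p][x[p] <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- Atb - AtA %*% x
  }
  pmax(as.numeric(x), 0)
}

#' Assign the mutational-signature subtype of a genome
#'
#' The subtype is the one mapped from the most prevalent signature in the
#' fitted exposures, except that the two S17-like signatures are summed and
#' their combined contribution counts toward the "mutagenic" subtype. Exact
#' ties are broken by catalog order, with a warning.
#'
#' @param fit An `exposure_fit` from [fit_exposures()], or a named numeric
#'   vector of exposures/proportions.
#' @param catalog The [signature_catalog()] supplying the subtype map.
#' @return A one-row tibble: `subtype`, `top_contributor` (signature label
#'   or `"S17A+S17B"`), `top_proportion`.
#' @export
#' @examples
#' cat6 <- random_signature_catalog(seed = 1)
#' fit <- fit_exposures(1000 * cat6$matrix[4, ], cat6)
#' assign_subtype(fit, cat6)
assign_subtype <- function(fit, catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  e <- if (is.data.frame(fit)) setNames(fit$exposure, fit$signature) else fit
  e <- e[catalog$names]
  total <- sum(e)
  if (!isTRUE(total > 0)) {
    abort("cannot assign a subtype to an empty mutation spectrum",
          class = "concord_undefined_subtype")
  }
  prop <- e / total
  s17 <- grepl("^S17", catalog$names)
  groups <- ifelse(s17, "S17A+S17B", catalog$names)
  grouped <- vapply(unique(groups), function(g) sum(prop[groups == g]),
                    numeric(1))
  # ties resolved by first appearance in catalog order
  best <- which(grouped == max(grouped))
  if (length(best) > 1L) {
    warn("exposure tie between signature groups; using catalog order")
  }
  winner <- names(grouped)[best[1L]]
  subtype <- if (winner == "S17A+S17B") "mutagenic" else
    unname(catalog$subtype_map[winner])
  tibble(subtype = subtype, top_contributor = winner,
         top_proportion = unname(grouped[best[1L]]))
}

#' Exposure trajectory across serial passages
#'
#' Fits exposures independently at each passage and reports, per signature,
#' how much its proportion moves over the series; the headline `drift` is
#' the largest such movement. Stable mutational processes across passages
#' show near-zero drift.
#'
#' @param series A list of 96-channel spectra (vectors or `channel`/`count`
#'   tibbles), one per passage, optionally named.
#' @param catalog A [signature_catalog()].
#' @return A list of class `exposure_trajectory`: `exposures` (tibble:
#'   `passage`, `signature`, `exposure`, `proportion`), `drift_by_signature`,
#'   and `drift` (max over signatures of max - min proportion).
#' @export
exposure_trajectory <- function(series, catalog) {
  if (length(series) < 2L) {
    stop_input("need spectra from at least 2 passages")
  }
  labels <- names(series) %||% paste0("P", seq_along(series))
  fits <- purrr::imap(setNames(series, labels), function(cts, lab) {
    fit_exposures(cts, catalog) |> mutate(passage = lab, .before = 1)
  }) |> list_rbind()
  drift_by_sig <- fits |>
    group_by(.data$signature) |>
    summarise(drift = max(.data$proportion) - min(.data$proportion),
              .groups = "drop")
  structure(
    list(exposures = fits,
         drift_by_signature = drift_by_sig,
         drift = max(drift_by_sig$drift)),
    class = "exposure_trajectory"
  )
}
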