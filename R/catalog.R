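#' The 96 trinucleotide substitution channels in COSMIC order
#'
#' Single-base substitutions are reported on the pyrimidine strand
#' (C>A, C>G, C>T, T>A, T>C, T>G), each in its 16 trinucleotide contexts,
#' ordered by substitution, then 5' base, then 3' base — the column order
#' used by the COSMIC signature matrices.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p, q) {
      paste0(p, "[", s, "]", q)
    })))
  }))
}

#' Construct a mutational signature catalog
#'
#' A catalog bundles a set of signatures (rows of a signatures x 96
#' probability matrix), their names, and a map from each signature to a
#' molecular subtype label. Subtype assignment sums the two S17-like
#' signatures toward the "mutagenic" subtype, so both must map to it.
#'
#' @param matrix Numeric matrix, one row per signature, 96 columns, each row
#'   a probability vector (sums to 1).
#' @param names Character vector of signature labels (defaults to rownames).
#' @param subtype_map Named character vector mapping every signature name to
#'   one of `"mutagenic"`, `"DDR impaired"`, `"C>A/T dominant"`.
#' @return An object of class `signature_catalog`.
#' @export
signature_catalog <- function(matrix,
                              names = rownames(matrix),
                              subtype_map = default_subtype_map(names)) {
  if (is.null(names)) {
    names <- paste0("S", seq_len(nrow(matrix)))
  }
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 96L) {
    stop_input("signature matrix must have 96 columns (trinucleotide channels)")
  }
  if (any(matrix < 0)) {
    stop_input("signature matrix entries must be non-negative")
  }
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-8)) {
    stop_input("each signature row must sum to 1 (tolerance 1e-8)")
  }
  if (length(names) != nrow(matrix)) {
    stop_input("`names` length must match the number of signature rows")
  }
  if (!all(names %in% base::names(subtype_map))) {
    stop_input("`subtype_map` must cover every signature name")
  }
  valid <- c("mutagenic", "DDR impaired", "C>A/T dominant")
  if (!all(subtype_map %in% valid)) {
    stop_input(paste0("subtypes must be one of: ", paste(valid, collapse = ", ")))
  }
  s17 <- grepl("^S17", names)
  if (any(s17) && !all(subtype_map[names[s17]] == "mutagenic")) {
    stop_input("S17A/S17B must map to the 'mutagenic' subtype")
  }
  rownames(matrix) <- names
  colnames(matrix) <- sbs96_channels()
  structure(
    list(names = names, matrix = matrix, subtype_map = subtype_map[names]),
    class = "signature_catalog"
  )
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("<signature_catalog> ", length(x$names), " signatures x 96 channels\n",
      sep = "")
  cat("  ", paste0(x$names, " [", x$subtype_map, "]", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Default six-signature naming convention used throughout: two S17-like
# (mutagenic) signatures, a DDR-impaired signature, and three others
# dominated by C>A/T transversions or ageing-like C>T.
default_subtype_map <- function(names) {
  map <- setNames(rep("C>A/T dominant", length(names)), names)
  map[grepl("^S17", names)] <- "mutagenic"
  map[grepl("^S3$|BRCA|DDR", names)] <- "DDR impaired"
  map
}

#' Generate a random sparse signature catalog
#'
#' Six synthetic signatures, each concentrated on a handful of channels, for
#' testing and simulation. The published catalogs are inputs
#' ([read_signature_catalog()]); this generator just provides well-separated
#' probability vectors with known structure.
#'
#' @param n_signatures Number of signatures (default 6).
#' @param seed Integer seed; identical seeds give identical catalogs.
#' @param sparsity Number of dominant channels per signature.
#' @return A [signature_catalog()].
#' @export
#' @examples
#' cat6 <- random_signature_catalog(seed = 1)
#' rowSums(cat6$matrix)
random_signature_catalog <- function(n_signatures = 6L, seed = 1L,
                                     sparsity = 8L) {
  n_signatures <- check_positive_int(n_signatures, "n_signatures")
  with_seed(seed, {
    m <- matrix(0, n_signatures, 96)
    for (i in seq_len(n_signatures)) {
      # disjoint-leaning support keeps signatures identifiable
      heavy <- sample.int(96, sparsity)
      w <- rep(0.02 / 96, 96)
      w[heavy] <- w[heavy] + rgamma(sparsity, shape = 2)
      m[i, ] <- w / sum(w)
    }
    nms <- if (n_signatures == 6L) {
      c("S1", "S2", "S3", "S17A", "S17B", "S6")
    } else {
      paste0("S", seq_len(n_signatures))
    }
    signature_catalog(m, names = nms)
  })
}

#' Read a COSMIC-style signature matrix
#'
#' Expects a TSV with channels as rows (first column the channel label in
#' `A[C>A]A` notation) and signatures as columns. Channels are reordered to
#' the canonical COSMIC order and validated.
#'
#' @param path Path to the TSV file.
#' @param subtype_map Optional named character vector; defaults to
#'   [default_subtype_map()] over the column names.
#' @return A [signature_catalog()].
#' @export
read_signature_catalog <- function(path, subtype_map = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  channels <- df[[1]]
  if (!setequal(channels, sbs96_channels())) {
    stop_input("first column must contain the 96 COSMIC channel labels")
  }
  m <- t(as.matrix(df[match(sbs96_channels(), channels), -1, drop = FALSE]))
  signature_catalog(m, names = rownames(m),
                    subtype_map = subtype_map %||% default_subtype_map(rownames(m)))
}

#' Write a signature catalog as a COSMIC-style TSV
#'
#' @param catalog A [signature_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- tibble(channel = sbs96_channels())
  for (nm in catalog$names) {
    df[[nm]] <- catalog$matrix[nm, ]
  }
  readr::write_tsv(df, path)
  invisible(path)
}
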