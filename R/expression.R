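#' Normalize counts by median-of-ratios size factors
#'
#' Computes one size factor per sample as the median ratio of its counts to
#' the per-gene geometric mean, taken over genes expressed in every sample,
#' then returns log2-stabilized values `log2(count / size_factor + 1)`. The
#' log transform flattens the count-variance relationship enough for the
#' Welch-based differential tests and Pearson correlations downstream.
#'
#' @param counts Tibble with a `gene` column and one numeric column per
#'   sample, or a numeric matrix with gene rownames.
#' @return Object of class `normalized_counts`: list with `log2`
#'   (genes x samples tibble), `size_factors` (named vector), `base_mean`
#'   (mean normalized count per gene, on the count scale).
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 300, patients = 2, seed = 1,
#'                            n_patient_program = 10)
#' nc <- normalize_counts(sim$counts)
#' nc$size_factors
normalize_counts <- function(counts) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2) stop_input("need at least 2 samples")
  everywhere <- rowSums(m > 0) == ncol(m)
  if (!any(everywhere)) {
    stop_input("no gene is expressed in every sample; size factors undefined")
  }
  loggeo <- rowMeans(log(m[everywhere, , drop = FALSE]))
  sf <- apply(m[everywhere, , drop = FALSE], 2, function(cnts) {
    exp(median(log(cnts) - loggeo))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop_input("non-positive size factor; check input counts")
  }
  norm <- sweep(m, 2, sf, "/")
  lg <- log2(norm + 1)
  structure(
    list(log2 = tibble(gene = rownames(m)) |> bind_cols(as_tibble(lg)),
         size_factors = sf,
         base_mean = rowMeans(norm)),
    class = "normalized_counts"
  )
}

counts_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    genes <- counts$gene %||% counts[[1]]
    m <- as.matrix(counts[setdiff(names(counts), "gene")])
    rownames(m) <- genes
    m
  } else {
    as.matrix(counts)
  }
}

log2_matrix <- function(normalized) {
  if (inherits(normalized, "normalized_counts")) normalized <- normalized$log2
  counts_matrix(normalized)
}

#' Classify an expressed somatic variant from RNA read counts
#'
#' A site counts as expressed when its RNA read depth is at least 4; with
#' any alternate read (VAF above 0) the mutant allele is expressed,
#' otherwise only the reference allele is.
#'
#' @param rna_depth,rna_alt_count Non-negative integer vectors.
#' @return Character vector in
#'   `{not_expressed, reference_expressed, alternative_expressed}`.
#' @export
#' @examples
#' classify_expressed_snv(c(3, 10, 4), c(1, 0, 1))
classify_expressed_snv <- function(rna_depth, rna_alt_count) {
  if (any(rna_depth < 0 | rna_alt_count < 0)) {
    stop_input("read counts must be non-negative")
  }
  if (any(rna_alt_count > rna_depth)) {
    stop_input("`rna_alt_count` cannot exceed `rna_depth`")
  }
  case_when(
    rna_depth < 4 ~ "not_expressed",
    rna_alt_count == 0 ~ "reference_expressed",
    .default = "alternative_expressed"
  )
}

#' Per-gene differential expression between two sample groups
#'
#' Welch two-sample t-test on normalized log2 values, with the log2 fold
#' change taken as the difference of group means (group A minus group B)
#' and the base mean as the mean normalized count over all tested samples.
#' The engine is deliberately simple and deterministic; the gene-selection
#' procedure built on top of it is what matters here.
#'
#' @param normalized A `normalized_counts` object (or its `log2` tibble).
#' @param group_a,group_b Character vectors of sample names (>= 2 each).
#' @return Tibble: `gene`, `log2fc`, `p_value`, `base_mean`.
#' @export
differential_expression <- function(normalized, group_a, group_b) {
  m <- log2_matrix(normalized)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_input("each group needs at least 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) {
    stop_input(paste("unknown samples:", paste(missing, collapse = ", ")))
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  # zero-variance genes: identical values give no evidence either way
  p[!is.finite(tstat)] <- 1
  base_mean <- if (inherits(normalized, "normalized_counts")) {
    normalized$base_mean[rownames(m)]
  } else {
    rowMeans(2^m[, c(group_a, group_b), drop = FALSE] - 1)
  }
  tibble(gene = rownames(m), log2fc = unname(ma - mb),
         p_value = unname(p), base_mean = unname(base_mean))
}

#' Select a patient-specific expression signature gene set
#'
#' Three-step selection that isolates genes informative about which tumor
#' an organoid came from, while stripping normal-tissue and
#' culture-environment effects:
#'
#' 1. keep genes differentially expressed between normal and tumor samples
#'    and lower in normals (`p <= 0.01`, normal-vs-tumor log2FC <= -1);
#' 2. discard genes generally differentially expressed between tumors and
#'    organoids (`p <= 0.01`, |log2FC| >= 1) — the culture-environment
#'    effect;
#' 3. keep genes specifically up- or down-regulated in this patient's
#'    organoid(s) versus all other organoids (`p <= 0.05`, |log2FC| <= 1,
#'    or >= 1 with `strict_lfc = TRUE`) that rank among the top
#'    `top_n` genes by base mean expression within the step-1/2 survivors.
#'
#' @param normalized A `normalized_counts` object.
#' @param samples Tibble with `sample`, `class`
#'   (`tumor`/`normal`/`organoid`), `patient`.
#' @param patient Patient label whose signature to select.
#' @param p1,lfc1 Step-1 thresholds. @param p2,lfc2 Step-2 thresholds.
#' @param p3,lfc3 Step-3 thresholds. @param top_n Base-mean cut (top 50).
#' @param strict_lfc Step-3 fold-change read as `|log2FC| >= lfc3` instead
#'   of `<= lfc3`.
#' @return Character vector of selected gene ids (possibly empty).
#' @export
select_signature_genes <- function(normalized, samples, patient,
                                   p1 = 0.01, lfc1 = -1,
                                   p2 = 0.01, lfc2 = 1,
                                   p3 = 0.05, lfc3 = 1, top_n = 50,
                                   strict_lfc = FALSE) {
  need <- c("tumor", "normal", "organoid")
  if (!all(need %in% samples$class)) {
    stop_input("`samples` must contain tumor, normal and organoid classes")
  }
  sm <- function(cls) samples$sample[samples$class == cls]
  de1 <- differential_expression(normalized, sm("normal"), sm("tumor"))
  step1 <- de1$gene[de1$p_value <= p1 & de1$log2fc <= lfc1]
  de2 <- differential_expression(normalized, sm("tumor"), sm("organoid"))
  step2_drop <- de2$gene[de2$p_value <= p2 & abs(de2$log2fc) >= lfc2]
  survivors <- setdiff(step1, step2_drop)

  own <- samples$sample[samples$class == "organoid" &
                          !is.na(samples$patient) &
                          samples$patient == patient]
  others <- setdiff(sm("organoid"), own)
  if (length(own) == 0) stop_input(sprintf("no organoid for patient %s", patient))
  de3 <- differential_expression(normalized, own, others)
  lfc_ok <- if (strict_lfc) abs(de3$log2fc) >= lfc3 else abs(de3$log2fc) <= lfc3
  step3 <- de3$gene[de3$p_value <= p3 & lfc_ok]

  bm <- de1$base_mean[match(survivors, de1$gene)]
  top <- survivors[order(-bm)][seq_len(min(top_n, length(survivors)))]
  intersect(intersect(top, step3), survivors)
}

#' Tumor x organoid correlation matrix over signature genes
#'
#' Pearson correlations of normalized log2 values between every tumor and
#' every organoid culture, over the union of the per-patient signature
#' gene sets. Organoid passages of one culture are averaged into a single
#' profile. Rows and columns are ordered by complete-linkage hierarchical
#' clustering of Euclidean distances, and each tumor is flagged by whether
#' its best-correlated organoid is its own patient's culture.
#'
#' @param normalized A `normalized_counts` object.
#' @param samples Sample sheet (`sample`, `class`, `patient`).
#' @param gene_sets Named list (per patient) or character vector of genes.
#' @return Object of class `expression_concordance`: list with `matrix`
#'   (tumors x organoids), `matched` (per-tumor logical), `match_rate`,
#'   `row_order`, `col_order`, `genes`, and `summary` (mean/median/range).
#' @export
correlation_matrix <- function(normalized, samples, gene_sets) {
  genes <- unique(unlist(gene_sets, use.names = FALSE))
  if (length(genes) == 0) stop_input("union of gene sets is empty")
  m <- log2_matrix(normalized)
  genes <- intersect(genes, rownames(m))
  tum <- samples |> filter(.data$class == "tumor")
  org <- samples |> filter(.data$class == "organoid", !is.na(.data$patient))
  if (nrow(tum) < 2 || nrow(org) < 2) {
    stop_input("need at least 2 tumors and 2 organoids")
  }
  org_profiles <- vapply(split(org$sample, org$patient), function(ss) {
    rowMeans(m[genes, ss, drop = FALSE])
  }, numeric(length(genes)))
  tum_profiles <- m[genes, tum$sample, drop = FALSE]
  colnames(tum_profiles) <- tum$patient
  sds <- c(apply(tum_profiles, 2, sd), apply(org_profiles, 2, sd))
  if (any(sds == 0)) {
    warn("zero-variance expression profile; correlations undefined there")
  }
  cm <- suppressWarnings(cor(tum_profiles, org_profiles))
  matched <- vapply(rownames(cm), function(p) {
    colnames(cm)[which.max(cm[p, ])] == p
  }, logical(1))
  row_hc <- hclust(dist(cm), method = "complete")
  col_hc <- hclust(dist(t(cm)), method = "complete")
  structure(
    list(matrix = cm, matched = matched,
         match_rate = mean(matched),
         row_order = rownames(cm)[row_hc$order],
         col_order = colnames(cm)[col_hc$order],
         row_hclust = row_hc, col_hclust = col_hc,
         genes = genes,
         summary = tibble(mean = mean(cm), median = median(cm),
                          min = min(cm), max = max(cm))),
    class = "expression_concordance"
  )
}

#' @export
print.expression_concordance <- function(x, ...) {
  cat("<expression_concordance> ", nrow(x$matrix), " tumors x ",
      ncol(x$matrix), " organoids over ", length(x$genes), " genes\n",
      "  matched-pair rate: ", sprintf("%.2f", x$match_rate), "\n", sep = "")
  invisible(x)
}
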