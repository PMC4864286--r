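## Per-term codon-usage matrix, PCA, PC1-vs-GC correlation, and the
## enriched-vs-non-enriched translational-efficiency comparison.

#' Aggregate codon-usage matrix over catalog terms
#'
#' One row per term, one column per sense codon; entries are the sum of the
#' member genes' canonical-CDS codon counts (`mode = "count"`) or the
#' row-normalized frequencies (`mode = "frequency"`). Genes without a
#' canonical CDS are skipped with a warning; terms left with no usable gene
#' are dropped with a warning. Terms below the catalog's size floor are kept
#' (they are flagged by [catalog_terms()], not silently removed).
#'
#' @param catalog A `cf_catalog`.
#' @param genome Canonical-CDS table.
#' @param mode `"count"` or `"frequency"`. Term sizes vary by orders of
#'   magnitude, so frequencies are the right input for PCA; counts are the
#'   raw aggregation.
#' @return A numeric matrix (terms x 61) with term ids as row names.
#' @export
go_codon_matrix <- function(catalog, genome, mode = c("count", "frequency")) {
  mode <- match.arg(mode)
  genome <- eligible_genes(genome)
  cmat <- gene_codon_matrix(genome)
  members <- as_tibble(catalog)
  missing <- setdiff(unique(members$gene_id), rownames(cmat))
  if (length(missing) > 0L) {
    warn(sprintf(
      "%d catalog gene(s) without canonical CDS skipped", length(missing)
    ))
    members <- members |> dplyr::filter(.data$gene_id %in% rownames(cmat))
  }
  empty <- setdiff(unique(as_tibble(catalog)$term_id), unique(members$term_id))
  if (length(empty) > 0L) {
    warn(sprintf("%d term(s) with no usable genes dropped", length(empty)))
  }
  if (nrow(members) == 0L) abort("no term has usable genes")
  terms <- split(members$gene_id, members$term_id)
  mat <- t(vapply(
    terms,
    function(g) colSums(cmat[g, , drop = FALSE]),
    numeric(61L)
  ))
  colnames(mat) <- SENSE_CODONS
  if (mode == "frequency") mat <- mat / rowSums(mat)
  mat
}

#' PCA of per-term codon usage
#'
#' Principal components analysis of the term-by-codon matrix. The default
#' input is row-normalized frequencies, mean-centered and unscaled (the 61
#' columns are commensurate frequencies). The sign of a principal axis is
#' arbitrary; when per-term GC fractions are supplied, PC1 is oriented so
#' that its correlation with GC is positive, making scores deterministic.
#'
#' @param mat Term-by-codon matrix from [go_codon_matrix()] (frequency mode
#'   recommended); at least 3 terms.
#' @param gc Optional named per-term GC fractions used to orient PC1.
#' @return An object of class `cf_pca` with elements `scores` (tibble:
#'   `term_id`, `PC1`, `PC2`), `loadings`, `var_explained` and `flipped`
#'   (whether PC1 was sign-flipped for orientation).
#' @export
pca_codon_usage <- function(mat, gc = NULL) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3L) abort("PCA needs at least 3 terms")
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  scores <- fit$x
  loadings <- fit$rotation
  var_expl <- fit$sdev^2 / sum(fit$sdev^2)
  if (ncol(scores) < 2L || fit$sdev[2] == 0) {
    ## rank-deficient input: report PC2 as zero-variance
    scores <- cbind(scores[, 1, drop = FALSE], PC2 = 0)
    loadings <- cbind(loadings[, 1, drop = FALSE], PC2 = 0)
  }
  flipped <- FALSE
  if (!is.null(gc)) {
    gc <- gc[rownames(mat)]
    rho <- suppressWarnings(spearman_rho(scores[, 1], gc))
    if (!is.na(rho) && rho < 0) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
      flipped <- TRUE
    }
  }
  structure(
    list(
      scores = tibble(
        term_id = rownames(mat),
        PC1 = scores[, 1], PC2 = scores[, 2]
      ),
      loadings = loadings[, 1:2, drop = FALSE],
      var_explained = var_expl,
      flipped = flipped
    ),
    class = "cf_pca"
  )
}

#' @export
print.cf_pca <- function(x, ...) {
  cat(sprintf(
    "<cf_pca> %d terms; PC1 %.1f%%, PC2 %.1f%% of variance%s\n",
    nrow(x$scores), 100 * x$var_explained[1],
    100 * (if (length(x$var_explained) > 1) x$var_explained[2] else 0),
    if (x$flipped) " (PC1 sign-flipped to align with GC)" else ""
  ))
  invisible(x)
}

#' @rdname pca_codon_usage
#' @param x,object A `cf_pca`.
#' @param ... Unused.
#' @export
tidy.cf_pca <- function(x, ...) x$scores

#' @rdname pca_codon_usage
#' @export
glance.cf_pca <- function(x, ...) {
  tibble(
    n_terms = nrow(x$scores),
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else 0,
    flipped = x$flipped
  )
}

#' Per-term GC content
#'
#' GC fraction of the concatenated canonical coding sequences of each term's
#' member genes.
#'
#' @param catalog A `cf_catalog`.
#' @param genome Canonical-CDS table.
#' @return A named numeric vector of per-term GC fractions.
#' @export
term_gc_content <- function(catalog, genome) {
  genome <- eligible_genes(genome)
  members <- as_tibble(catalog) |>
    dplyr::filter(.data$gene_id %in% genome$gene_id)
  seqs <- setNames(genome$cds, genome$gene_id)
  vapply(
    split(members$gene_id, members$term_id),
    function(g) gc_content(seqs[g]),
    numeric(1)
  )
}

#' Correlation between PC1 scores and per-term GC content
#'
#' @param pca A `cf_pca` from [pca_codon_usage()].
#' @param gc Named per-term GC fractions ([term_gc_content()]), covering the
#'   PCA's terms.
#' @return Spearman's rho between PC1 and GC.
#' @export
pc1_gc_correlation <- function(pca, gc) {
  stopifnot(inherits(pca, "cf_pca"))
  if (!is.null(names(gc))) {
    if (!all(pca$scores$term_id %in% names(gc))) {
      abort("`gc` does not cover every term in the PCA")
    }
    gc <- gc[pca$scores$term_id]
  } else if (length(gc) != nrow(pca$scores)) {
    abort("`gc` length does not match the number of terms")
  }
  if (length(unique(gc)) == 1L) {
    abort("GC is identical for all terms; ranks (and rho) are undefined")
  }
  spearman_rho(pca$scores$PC1, gc)
}

#' Enriched vs non-enriched translational efficiency
#'
#' One-tailed Mann-Whitney-Wilcoxon test of whether terms labelled enriched
#' in a condition have higher mean translational efficiency than the
#' remaining terms (alternative: enriched > non-enriched), Bonferroni
#' corrected over `family_size` conditions.
#'
#' @param te_by_term Data frame with columns `term_id` and `te` (each term's
#'   mean matching-condition TE for one condition).
#' @param enriched Character vector of enriched term ids; both classes must
#'   be non-empty.
#' @param family_size Bonferroni family size (default 1).
#' @return A one-row tibble: `n_enriched`, `n_other`, `statistic`, `p_value`,
#'   `bonferroni_p`, `signif_code`.
#' @export
enriched_te_test <- function(te_by_term, enriched, family_size = 1) {
  stopifnot(all(c("term_id", "te") %in% names(te_by_term)))
  grp <- te_by_term$term_id %in% enriched
  if (!any(grp) || all(grp)) {
    abort("both enriched and non-enriched terms are required")
  }
  e <- te_by_term$te[grp]
  o <- te_by_term$te[!grp]
  has_ties <- anyDuplicated(c(e, o)) > 0L
  use_exact <- min(length(e), length(o)) <= 8L && !has_ties
  ht <- suppressWarnings(wilcox.test(
    e, o,
    alternative = "greater", exact = use_exact, correct = TRUE
  ))
  p_adj <- min(1, ht$p.value * family_size)
  tibble(
    n_enriched = length(e), n_other = length(o),
    statistic = unname(ht$statistic), p_value = ht$p.value,
    family_size = family_size, bonferroni_p = p_adj,
    signif_code = signif_code(p_adj)
  )
}
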