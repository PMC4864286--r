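## Resampling null for gene-set codon-usage divergence: size-matched random
## gene sets, correlation with the exonic background, empirical p-values and
## FDR calls.

#' Aggregate codon usage of the exonic background
#'
#' The element-wise sum of sense-codon counts over the canonical coding
#' sequences of all eligible genes. Mitochondrial genes are excluded (they
#' use a different genetic code and tRNA set).
#'
#' @param genome A canonical-CDS table from [canonical_cds()] (or
#'   [generate_genome()]), with columns `gene_id`, `cds` and optionally
#'   `is_mt`.
#' @return A tibble with columns `codon` (the 61 sense codons) and `count`.
#' @export
background_codon_usage <- function(genome) {
  genome <- eligible_genes(genome)
  if (nrow(genome) == 0L) abort("no eligible (non-mitochondrial) genes")
  counts <- colSums(gene_codon_matrix(genome))
  tibble(codon = SENSE_CODONS, count = as.numeric(counts))
}

eligible_genes <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("gene_id", "cds") %in% names(genome)))
  if ("is_mt" %in% names(genome)) {
    genome <- genome[!genome$is_mt, , drop = FALSE]
  }
  genome
}

#' Sample the codon-usage null distribution for given set sizes
#'
#' For each requested set size, draws `n_samples` gene sets uniformly without
#' replacement from the eligible (non-mitochondrial) genes, computes each
#' set's aggregate codon usage, and Spearman-correlates it with the exonic
#' background. The spread of these correlations is the stochastic variation
#' expected from sampling alone; small sets vary substantially more than
#' large ones. Sampling uses one substream per size derived from `seed`, so
#' adding a size leaves the draws for other sizes unchanged.
#'
#' @param genome Canonical-CDS table ([canonical_cds()]).
#' @param sizes Integer vector of set sizes (each between 1 and the number of
#'   eligible genes).
#' @param n_samples Random sets per size (default 10000).
#' @param seed Master seed.
#' @return An object of class `cf_null`: a list with `draws` (tibble of
#'   `size`, `rho`), `background` (codon-usage tibble), `sizes`,
#'   `n_samples` and `seed`.
#' @export
sample_null <- function(genome, sizes, n_samples = 10000, seed = 1L) {
  genome <- eligible_genes(genome)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L)) abort("set sizes must be >= 1")
  if (any(sizes > nrow(genome))) {
    abort(sprintf(
      "set size %d exceeds the number of eligible genes (%d)",
      max(sizes), nrow(genome)
    ))
  }
  cmat <- gene_codon_matrix(genome)
  bg <- colSums(cmat)
  draws <- purrr::map_dfr(sizes, function(s) {
    set.seed(derive_seed(seed, s))
    idx <- replicate(n_samples, sample.int(nrow(cmat), s), simplify = FALSE)
    agg <- sparse_set_sums(idx, cmat)
    tibble(size = s, rho = row_spearman(agg, bg))
  })
  structure(
    list(
      draws = draws,
      background = tibble(codon = SENSE_CODONS, count = as.numeric(bg)),
      sizes = sizes, n_samples = n_samples, seed = seed
    ),
    class = "cf_null"
  )
}

## aggregate codon counts of many gene index sets via one sparse product
sparse_set_sums <- function(idx_list, cmat) {
  sizes <- lengths(idx_list)
  ind <- Matrix::sparseMatrix(
    i = rep(seq_along(idx_list), sizes),
    j = unlist(idx_list),
    x = 1,
    dims = c(length(idx_list), nrow(cmat))
  )
  as.matrix(ind %*% cmat)
}

#' @export
print.cf_null <- function(x, ...) {
  cat(sprintf(
    "<cf_null> %d draws per size over sizes {%s}, seed %d\n",
    x$n_samples, paste(x$sizes, collapse = ", "), x$seed
  ))
  invisible(x)
}

#' @export
#' @rdname sample_null
#' @param x,object A `cf_null`.
#' @param ... Unused.
tidy.cf_null <- function(x, ...) {
  x$draws |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      median = median(.data$rho),
      q25 = quantile(.data$rho, 0.25, names = FALSE),
      q75 = quantile(.data$rho, 0.75, names = FALSE),
      p02 = quantile(.data$rho, 0.02, names = FALSE),
      p98 = quantile(.data$rho, 0.98, names = FALSE),
      iqr = .data$q75 - .data$q25,
      .groups = "drop"
    )
}

#' @export
#' @rdname sample_null
glance.cf_null <- function(x, ...) {
  tibble(
    n_sizes = length(x$sizes), n_samples = x$n_samples, seed = x$seed
  )
}

#' Empirical codon-usage divergence of catalog terms
#'
#' For every term in the catalog, correlates the term's aggregate codon usage
#' with the exonic background and asks how that correlation compares with
#' size-matched random gene sets. The empirical p-value is the fraction of
#' random sets whose correlation is strictly smaller than the term's: terms
#' whose codon usage diverges more than expected by chance sit below the
#' null and get small p. P-values are FDR-adjusted by Benjamini-Hochberg;
#' terms with `q < alpha` are called significantly divergent.
#'
#' @param catalog A `cf_catalog` of term-gene pairs.
#' @param null A `cf_null` from [sample_null()].
#' @param genome Canonical-CDS table (the same genome the null was built on).
#' @param add_one Use the (r+1)/(n+1) estimator instead of the plain
#'   fraction, so p is never exactly zero (recommended when feeding the
#'   p-values into FDR adjustment). Default `FALSE` (plain fraction).
#' @param nearest_size If a term's size was not sampled in `null`, map it to
#'   the nearest sampled size instead of erroring. Default `FALSE`.
#' @param alpha FDR level for the `significant` call (default 0.05).
#' @return A tibble with `term_id`, `size`, `rho`, `empirical_p`, `q`,
#'   `significant`.
#' @export
empirical_divergence <- function(catalog, null, genome,
                                 add_one = FALSE, nearest_size = FALSE,
                                 alpha = 0.05) {
  stopifnot(inherits(null, "cf_null"))
  genome <- eligible_genes(genome)
  cmat <- gene_codon_matrix(genome)
  bg <- cu_vec(null$background)
  members <- catalog |>
    as_tibble() |>
    dplyr::filter(.data$gene_id %in% rownames(cmat))
  terms <- split(members$gene_id, members$term_id)
  if (length(terms) == 0L) abort("no catalog term has genes in the genome")
  sizes_avail <- null$sizes
  res <- purrr::imap_dfr(terms, function(genes, term) {
    s <- length(genes)
    s_null <- if (s %in% sizes_avail) {
      s
    } else if (nearest_size) {
      sizes_avail[which.min(abs(sizes_avail - s))]
    } else {
      abort(sprintf(
        "term '%s' has size %d, not sampled in the null (sizes: %s); %s",
        term, s, paste(sizes_avail, collapse = ", "),
        "use nearest_size = TRUE or extend the null"
      ))
    }
    usage <- colSums(cmat[genes, , drop = FALSE])
    rho <- spearman_rho(usage, bg)
    nd <- null$draws$rho[null$draws$size == s_null]
    r <- sum(nd < rho)
    p <- if (add_one) (r + 1) / (length(nd) + 1) else r / length(nd)
    tibble(
      term_id = term, size = s, null_size = s_null,
      rho = rho, empirical_p = p
    )
  })
  res$q <- p.adjust(res$empirical_p, method = "BH")
  res$significant <- res$q < alpha
  res |> dplyr::arrange(.data$term_id)
}
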