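## End-to-end orchestration: ingest (or simulate) inputs, run the resampling
## null, the match/mismatch TE contrasts and the PCA/GC decomposition, and
## write tabular outputs with a threshold log.

#' Run the full codon-usage / translational-efficiency analysis
#'
#' Drives every stage over one dataset: expression filters and size factors,
#' the size-matched resampling null for catalog-term codon-usage divergence,
#' translational-efficiency values for every gene-set menu entry and sample
#' pairing with the match/mismatch rank test, and the per-term PCA with its
#' GC decomposition and enriched-vs-non-enriched test. Inputs are either
#' file paths (`input = list(fasta =, mrna_counts =, mrna_samples =,
#' trna_counts =, trna_samples =, catalog =, de_tables =, gene_lists =)`) or
#' an in-memory synthetic dataset (`input = synthetic_config()`), in which
#' case the data are generated under `seed`.
#'
#' @param input A named list of paths, or a [synthetic_config()].
#' @param dissimilar List of dissimilar condition pairs (default: taken from
#'   the synthetic config, or required for path input).
#' @param out_dir Output directory for TSVs and the run log; `NULL` to skip
#'   writing.
#' @param seed Seed controlling the null resampling (and data generation for
#'   synthetic input).
#' @param null_samples Random sets per size in the null (default 10000).
#' @param n_top Genes per upregulated set (default 200).
#' @param variants TE variants to compute (default `"strict"`).
#' @param ramp_n Optional first-N-codons restriction for the rank variants.
#' @param fdr_level FDR level for divergence calls (default 0.05).
#' @param menu_entries Which gene-set menu entries to evaluate.
#' @param enriched_terms Named list (per contrast) of enriched term ids;
#'   defaults to the synthetic ground truth when input is synthetic.
#' @param add_one Use the never-zero empirical p estimator in the null stage.
#' @return A list of class `cf_run` with `divergence`, `te`, `contrasts`,
#'   `pca` (scores + GC + per-term TE), `enrichment_tests`, `null`,
#'   `thresholds`, and `paths` of written files.
#' @export
run_analysis <- function(input,
                         dissimilar = NULL,
                         out_dir = NULL,
                         seed = 1L,
                         null_samples = 10000,
                         n_top = 200,
                         variants = "strict",
                         ramp_n = NULL,
                         fdr_level = 0.05,
                         menu_entries = c("all", "DE", "GO", "HK", "RP", "PP"),
                         enriched_terms = NULL,
                         add_one = FALSE) {
  thresholds <- list(
    null_samples = null_samples, n_top = n_top,
    variants = paste(variants, collapse = ","),
    ramp_n = ramp_n %||% NA, fdr_level = fdr_level, seed = seed
  )

  if (inherits(input, "cf_config")) {
    input$seed <- seed
    genome_obj <- generate_genome(input)
    expr <- generate_expression(input, genome_obj)
    genome <- genome_obj$genome
    catalog <- genome_obj$catalog
    dissimilar <- dissimilar %||% input$dissimilar
    enriched_terms <- enriched_terms %||% expr$enriched_terms
    mrna <- expr$mrna
    trna <- expr$trna
    de_tables <- expr$de_tables
    gene_lists <- expr$gene_lists
  } else {
    need <- c(
      "fasta", "mrna_counts", "mrna_samples", "trna_counts", "trna_samples",
      "catalog"
    )
    missing <- setdiff(need, names(input))
    if (length(missing) > 0L) {
      abort(sprintf("input paths missing: %s", paste(missing, collapse = ", ")))
    }
    if (is.null(dissimilar)) {
      abort("`dissimilar` condition pairs are required for path input")
    }
    genome <- canonical_cds(read_cds_fasta(input$fasta))
    tr <- read_trna_counts(input$trna_counts)
    mrna <- list(
      counts = read_counts(input$mrna_counts),
      samples = read_sample_sheet(input$mrna_samples)
    )
    trna <- list(
      counts = tr$counts, annotation = tr$annotation,
      samples = read_sample_sheet(input$trna_samples)
    )
    catalog <- read_gene_set_catalog(input$catalog, genome_ids = genome$gene_id)
    de_tables <- purrr::map(input$de_tables %||% list(), read_de_table)
    gene_lists <- purrr::map(
      input$gene_lists %||% list(),
      read_gene_list,
      genome_ids = genome$gene_id
    )
  }

  shared <- intersect(genome$gene_id, mrna$counts$gene_id)
  if (length(shared) == 0L) {
    abort(paste0(
      "gene universes of the CDS annotation and the mRNA counts are ",
      "disjoint; check identifiers"
    ))
  }
  annotation <- genome[, c("gene_id", "chromosome")]

  ## --- filters and normalization ------------------------------------
  mrna_factors <- estimate_size_factors(mrna$counts)
  trna_factors <- estimate_size_factors(trna$counts)
  expressed <- filter_expressed_mrna(mrna$counts, annotation)
  expressed <- intersect(expressed, genome$gene_id)
  trna_genes <- filter_expressed_trna(
    trna$counts, trna$samples, trna_factors, trna$annotation
  )

  ## --- resampling null over catalog term sizes ----------------------
  term_info <- catalog_terms(catalog)
  usable_terms <- term_info |> dplyr::filter(!.data$below_floor)
  cat_use <- catalog |>
    dplyr::filter(
      .data$term_id %in% usable_terms$term_id,
      .data$gene_id %in% genome$gene_id
    )
  sizes <- cat_use |>
    dplyr::count(.data$term_id) |>
    dplyr::pull("n") |>
    unique()
  null <- sample_null(genome, sizes, n_samples = null_samples, seed = seed)
  divergence <- empirical_divergence(
    cat_use, null, genome,
    add_one = add_one, alpha = fdr_level
  )

  ## --- match/mismatch TE contrasts ----------------------------------
  design <- study_design(mrna$samples, trna$samples, dissimilar)
  menu_entries <- intersect(
    menu_entries,
    c(
      "all",
      if (length(de_tables) > 0) "DE",
      if (!is.null(enriched_terms)) "GO",
      intersect(names(gene_lists), c("HK", "RP", "PP"))
    )
  )
  menu <- build_gene_set_menu(
    expressed,
    de_tables = de_tables, catalog = catalog,
    enriched_terms = enriched_terms, gene_lists = gene_lists,
    entries = menu_entries, n_top = n_top
  )
  te <- compute_te(
    genome, menu, design,
    mrna_counts = mrna$counts, trna_counts = trna$counts,
    trna_annotation = trna$annotation,
    mrna_factors = mrna_factors, trna_factors = trna_factors,
    trna_genes = trna_genes, variants = variants, ramp_n = ramp_n
  )
  ## one contrast family per menu entry x variant
  contrasts <- compare_match_mismatch(te)

  ## --- per-term PCA, GC, and enriched-vs-rest TE --------------------
  freq <- go_codon_matrix(cat_use, genome, mode = "frequency")
  gc <- term_gc_content(cat_use, genome)
  pca <- pca_codon_usage(freq, gc = gc)
  pc1_gc_rho <- pc1_gc_correlation(pca, gc)
  term_te <- per_term_matching_te(
    genome, cat_use, design, mrna, trna,
    mrna_factors, trna_factors, trna_genes
  )
  enrichment_tests <- NULL
  if (!is.null(enriched_terms)) {
    by_cond <- split(
      unlist(enriched_terms, use.names = FALSE),
      rep(
        sub("_vs_.*", "", names(enriched_terms)),
        lengths(enriched_terms)
      )
    )
    by_cond <- purrr::map(by_cond, unique)
    by_cond <- by_cond[purrr::map_int(by_cond, length) > 0]
    enrichment_tests <- purrr::imap_dfr(by_cond, function(terms, cond) {
      tt <- term_te |> dplyr::filter(.data$condition == cond)
      if (nrow(tt) == 0L || all(tt$term_id %in% terms) ||
        !any(tt$term_id %in% terms)) {
        return(tibble())
      }
      enriched_te_test(tt, terms, family_size = length(by_cond)) |>
        dplyr::mutate(condition = cond, .before = 1)
    })
  }

  result <- structure(
    list(
      divergence = divergence,
      te = te,
      contrasts = contrasts,
      pca = list(
        fit = pca,
        scores = dplyr::left_join(
          tidy.cf_pca(pca),
          tibble(term_id = names(gc), gc = unname(gc)),
          by = "term_id"
        ),
        pc1_gc_rho = pc1_gc_rho,
        term_te = term_te
      ),
      enrichment_tests = enrichment_tests,
      null = null,
      expressed = expressed,
      trna_genes = trna_genes,
      thresholds = thresholds,
      paths = NULL
    ),
    class = "cf_run"
  )
  if (!is.null(out_dir)) {
    result$paths <- write_run_outputs(result, out_dir)
  }
  result
}

## mean matching-condition TE of every catalog term, per condition
per_term_matching_te <- function(genome, catalog, design, mrna, trna,
                                 mrna_factors, trna_factors, trna_genes) {
  pairings <- enumerate_pairings(design) |>
    dplyr::filter(.data$match == "match")
  mmat <- as_count_matrix(mrna$counts)
  usable <- intersect(rownames(mmat), genome$gene_id)
  members <- as_tibble(catalog) |>
    dplyr::filter(.data$gene_id %in% usable)
  terms <- split(members$gene_id, members$term_id)
  pools <- purrr::map(
    setNames(nm = unique(pairings$trna_sample)),
    function(s) {
      anticodon_pool(trna$counts, trna$annotation, s,
        factors = trna_factors, genes = trna_genes
      )
    }
  )
  purrr::map_dfr(unique(pairings$mrna_sample), function(ms) {
    x <- setNames(mmat[usable, ms] / mrna_factors[[ms]], usable)
    rows <- pairings |> dplyr::filter(.data$mrna_sample == ms)
    cus <- purrr::map(terms, function(g) weighted_codon_usage(genome, x[g]))
    purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      pool <- pools[[rows$trna_sample[i]]]
      tibble(
        term_id = names(terms),
        condition = rows$mrna_condition[i],
        mrna_sample = ms,
        trna_sample = rows$trna_sample[i],
        value = purrr::map_dbl(
          cus,
          function(cu) translational_efficiency(cu, pool, "strict")$value
        )
      )
    })
  }) |>
    dplyr::group_by(.data$term_id, .data$condition) |>
    dplyr::summarise(te = mean(.data$value), .groups = "drop")
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wtsv <- function(x, name) {
    fp <- file.path(out_dir, name)
    readr::write_tsv(x, fp)
    fp
  }
  paths["divergence"] <- wtsv(result$divergence, "term_divergence.tsv")
  paths["null"] <- wtsv(result$null$draws, "null_draws.tsv")
  paths["te"] <- wtsv(result$te, "te_values.tsv")
  paths["contrasts"] <- wtsv(result$contrasts, "contrasts.tsv")
  paths["pca"] <- wtsv(
    dplyr::left_join(
      result$pca$scores,
      result$pca$term_te |>
        tidyr::pivot_wider(
          names_from = "condition", values_from = "te",
          names_prefix = "te_"
        ),
      by = "term_id"
    ),
    "term_pca.tsv"
  )
  if (!is.null(result$enrichment_tests) &&
    nrow(result$enrichment_tests) > 0) {
    paths["enrichment"] <- wtsv(
      result$enrichment_tests, "enrichment_tests.tsv"
    )
  }
  summary <- list(
    thresholds = result$thresholds,
    n_terms_tested = nrow(result$divergence),
    n_terms_divergent = sum(result$divergence$significant),
    pc1_gc_rho = result$pca$pc1_gc_rho,
    contrast_p = setNames(
      as.list(result$contrasts$bonferroni_p),
      paste(result$contrasts$gene_set, result$contrasts$variant, sep = "|")
    )
  )
  fp <- file.path(out_dir, "summary.yaml")
  yaml::write_yaml(summary, fp)
  paths["summary"] <- fp
  paths
}

#' @export
print.cf_run <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cf_run>\n  %d terms tested, %d significantly divergent\n",
      "  %d TE values over %d contrast(s)\n  PC1-GC rho = %.3f\n"
    ),
    nrow(x$divergence), sum(x$divergence$significant),
    nrow(x$te), nrow(x$contrasts), x$pca$pc1_gc_rho
  ))
  invisible(x)
}
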