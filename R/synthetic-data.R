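## Seeded synthetic-data generator: coding sequences with a controllable GC
## gradient, gene-set catalogs, overdispersed mRNA/tRNA counts with
## condition effects, and anticodon pools whose rank agreement with codon
## usage is a tunable parameter (the adaptation knob alpha).

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the structure of a two-assay (RNA-seq + Pol III
#' ChIP-seq) liver study: a quiescent healthy condition and two proliferating
#' cancer lines, dissimilar only to the healthy tissue, with four biological
#' replicates per assay; 40% of genes differentially expressed between
#' dissimilar conditions; gene-set GC gradient spanning 0.35-0.65; and a
#' tRNA anticodon repertoire of 45 (every anticodon except the genomically
#' A-starting ones, which are the classic inosine-edited absences).
#'
#' @param n_genes Number of protein-coding genes.
#' @param length_meanlog,length_sdlog,length_min Lognormal gene length
#'   distribution in sense codons (minimum 30).
#' @param gene_gc_range Range of per-gene target GC.
#' @param n_terms,term_size_range Catalog size and per-term gene-count range
#'   (log-uniform; floor 40).
#' @param gc_gradient Term-level GC gradient endpoints, or `NULL` for terms
#'   drawn uniformly at random (no GC structure).
#' @param conditions Condition names; the first is the quiescent reference.
#' @param dissimilar List of dissimilar condition pairs.
#' @param n_rep_mrna,n_rep_trna Replicates per condition per assay.
#' @param mu_meanlog,mu_sdlog Lognormal distribution of mRNA base means.
#' @param dispersion,trna_dispersion Negative-binomial dispersions for the
#'   mRNA and tRNA counts (tRNA ChIP replicates are tightly correlated, so
#'   the default is smaller).
#' @param de_fraction Fraction of genes differentially expressed per
#'   non-reference condition.
#' @param lfc_mean,lfc_sd Magnitude distribution of log2 fold changes.
#' @param de_gc_bias Named (or scalar, recycled) per-condition coefficient
#'   coupling expression to gene GC content: each condition's log2 fold
#'   change gains `de_gc_bias * standardized(gc)`. Zero (the default) makes
#'   condition effects GC-neutral; opposite signs between conditions create
#'   condition-specific, GC-polarized codon usage, the regime in which a
#'   tRNA pool adapted to one condition is genuinely unsuited to another.
#' @param n_enriched_terms Terms per non-reference condition whose member
#'   genes get a coordinated expression boost (ground-truth enrichment).
#' @param enrich_lfc Extra log2 fold change added to member genes of
#'   enriched terms.
#' @param n_trna_genes Number of tRNA genes spread over the repertoire.
#' @param trna_mu Mean tRNA gene count scale.
#' @param trna_abundance_span Fold range of the anticodon abundance profile
#'   (most- to least-abundant), on the scale of Pol III occupancy spreads.
#' @param adaptation_alpha Named (or scalar, recycled) per-condition alpha in
#'   `[0, 1]`: 1 builds each condition's pool rank-identical to its own
#'   expression-weighted codon usage, 0 uses a random permutation.
#' @param seed Master seed; every stage derives its own substream.
#' @return A list of class `cf_config`.
#' @export
synthetic_config <- function(n_genes = 5000,
                             length_meanlog = log(350), length_sdlog = 0.35,
                             length_min = 30,
                             gene_gc_range = c(0.30, 0.70),
                             n_terms = 100,
                             term_size_range = c(40, 200),
                             gc_gradient = c(0.35, 0.65),
                             conditions = c("healthy", "cancer1", "cancer2"),
                             dissimilar = list(
                               c("healthy", "cancer1"),
                               c("healthy", "cancer2")
                             ),
                             n_rep_mrna = 4, n_rep_trna = 4,
                             mu_meanlog = 4, mu_sdlog = 1.5,
                             dispersion = 0.05,
                             de_fraction = 0.4,
                             lfc_mean = 1, lfc_sd = 0.5,
                             de_gc_bias = 0,
                             n_enriched_terms = 10,
                             enrich_lfc = 1,
                             n_trna_genes = 120,
                             trna_mu = 500,
                             trna_dispersion = 0.1,
                             trna_abundance_span = 150,
                             adaptation_alpha = 0,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_genes >= 1, length_min >= 30,
    all(gene_gc_range >= 0.25 & gene_gc_range <= 0.75),
    n_terms >= 1, term_size_range[1] >= 1,
    term_size_range[2] <= n_genes,
    n_rep_mrna >= 1, n_rep_trna >= 1,
    de_fraction >= 0 && de_fraction <= 1,
    all(adaptation_alpha >= 0 & adaptation_alpha <= 1)
  )
  for (field in c("adaptation_alpha", "de_gc_bias")) {
    if (is.null(names(cfg[[field]]))) {
      cfg[[field]] <- setNames(
        rep(cfg[[field]], length.out = length(conditions)), conditions
      )
    }
    if (!all(conditions %in% names(cfg[[field]]))) {
      abort(sprintf("%s must name every condition", field))
    }
  }
  structure(cfg, class = "cf_config")
}

## number of G/C bases per sense codon (fixed lookup)
SENSE_GC_COUNTS <- vapply(
  strsplit(SENSE_CODONS, ""),
  function(ch) sum(ch %in% c("G", "C")), numeric(1)
)

## sense-codon distribution with nucleotide GC weight p
sense_codon_probs <- function(p) {
  w <- (p / 2)^SENSE_GC_COUNTS * ((1 - p) / 2)^(3 - SENSE_GC_COUNTS)
  w / sum(w)
}

## map a target realized GC to the nucleotide parameter that achieves it
## under the stop-codon-free codon distribution (monotone, interpolated)
gc_param_for_target <- local({
  grid <- NULL
  function(target) {
    if (is.null(grid)) {
      ps <- seq(0.02, 0.98, by = 0.005)
      realized <- vapply(ps, function(p) {
        pr <- sense_codon_probs(p)
        sum(pr * SENSE_GC_COUNTS) / 3
      }, numeric(1))
      grid <<- list(p = ps, gc = realized)
    }
    stats::approx(grid$gc, grid$p, xout = target, rule = 2)$y
  }
})

#' Generate a synthetic genome and gene-set catalog
#'
#' Emits a canonical-CDS table in which every sequence is a valid CDS
#' (`ATG` start, sampled stop, no in-frame stops), with per-gene codon
#' composition drawn from a GC-parameterized sense-codon distribution whose
#' parameter is calibrated so realized gene GC tracks its target. Terms are
#' assembled by sampling genes near each term's target GC (when a gradient
#' is configured) or uniformly. A small fraction of genes is placed on a sex
#' chromosome or the mitochondrial genome to exercise the autosome filters.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genome` (canonical-CDS tibble with `gene_id`,
#'   `chromosome`, `cds`, `n_codons`, `gc`, `is_mt`, `target_gc`), `catalog`
#'   (a `cf_catalog`) and `truth` (per-gene and per-term targets).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "cf_config"))
  set.seed(derive_seed(config$seed, 101))
  n <- config$n_genes
  lens <- pmax(
    config$length_min,
    round(rlnorm(n, config$length_meanlog, config$length_sdlog))
  )
  target_gc <- stats::runif(n, config$gene_gc_range[1], config$gene_gc_range[2])
  params <- gc_param_for_target(target_gc)
  stops <- sample(STOP_CODONS, n, replace = TRUE)
  cds <- vapply(seq_len(n), function(i) {
    body <- sample(SENSE_CODONS, lens[i] - 1L,
      replace = TRUE,
      prob = sense_codon_probs(params[i])
    )
    paste0("ATG", paste(body, collapse = ""), stops[i])
  }, character(1))
  chrom <- sample(as.character(1:19), n, replace = TRUE)
  n_x <- max(0L, round(0.01 * n))
  n_mt <- max(0L, round(0.005 * n))
  special <- sample.int(n, n_x + n_mt)
  chrom[special[seq_len(n_x)]] <- "X"
  if (n_mt > 0) chrom[special[n_x + seq_len(n_mt)]] <- "MT"
  genome <- tibble(
    gene_id = sprintf("gene%05d", seq_len(n)),
    chromosome = chrom,
    cds = cds
  ) |>
    canonical_cds() |>
    dplyr::mutate(target_gc = target_gc)

  ## catalog over eligible autosomal genes so set sizes are exact
  eligible <- genome |> dplyr::filter(is_autosome(.data$chromosome))
  set.seed(derive_seed(config$seed, 102))
  sizes <- round(exp(stats::runif(
    config$n_terms,
    log(config$term_size_range[1]), log(config$term_size_range[2])
  )))
  sizes <- pmin(sizes, nrow(eligible))
  term_ids <- sprintf("TERM%04d", seq_len(config$n_terms))
  if (is.null(config$gc_gradient)) {
    term_target <- rep(NA_real_, config$n_terms)
    members <- purrr::map2(sizes, term_ids, function(s, id) {
      sample(eligible$gene_id, s)
    })
  } else {
    term_target <- seq(config$gc_gradient[1], config$gc_gradient[2],
      length.out = config$n_terms
    )
    members <- purrr::map2(sizes, term_target, function(s, t) {
      w <- stats::dnorm(eligible$target_gc, t, 0.03) + 1e-12
      sample(eligible$gene_id, s, prob = w)
    })
  }
  catalog <- gene_set_catalog(
    tibble(
      term_id = rep(term_ids, sizes),
      gene_id = unlist(members)
    ),
    genome_ids = genome$gene_id
  )
  list(
    genome = genome,
    catalog = catalog,
    truth = list(
      term_target_gc = setNames(term_target, term_ids),
      term_sizes = setNames(sizes, term_ids)
    )
  )
}

## anticodon repertoire: every anticodon except the A-starting ones (the
## inosine-edited absences); 45 anticodons, matching mammalian pools
default_anticodon_repertoire <- function() {
  ac <- unique(revcomp(SENSE_CODONS))
  sort(ac[substr(ac, 1L, 1L) != "A"])
}

#' Generate synthetic expression data, DE tables and tRNA pools
#'
#' Produces overdispersed (negative-binomial) mRNA counts with per-condition
#' fold changes on ground-truth DE genes; tRNA counts whose per-condition
#' anticodon pool interpolates, via the adaptation knob alpha, between a
#' random permutation (alpha = 0) and rank-identity with that condition's
#' expression-weighted codon usage (alpha = 1); per-contrast DE tables from
#' a simple two-sample rank test on replicate counts (a documented stand-in
#' sufficient for top-gene selection -- not a re-analysis); enrichment
#' labels; and housekeeping/ribosomal/proliferation-style gene lists.
#'
#' @param config A [synthetic_config()].
#' @param genome_obj Output of [generate_genome()].
#' @return A list with components `mrna` (`counts`, `samples`), `trna`
#'   (`counts`, `annotation`, `samples`), `de_tables` (one per ordered
#'   dissimilar contrast `A_vs_B`), `enriched_terms` (per contrast),
#'   `gene_lists` (`HK`, `RP`, `PP`) and `truth`.
#' @export
generate_expression <- function(config, genome_obj) {
  stopifnot(inherits(config, "cf_config"))
  genome <- genome_obj$genome
  catalog <- genome_obj$catalog
  conds <- config$conditions
  ref <- conds[1]
  n <- nrow(genome)

  set.seed(derive_seed(config$seed, 201))
  base_mu <- rlnorm(n, config$mu_meanlog, config$mu_sdlog)
  lfc <- matrix(0, n, length(conds), dimnames = list(genome$gene_id, conds))
  for (cond in setdiff(conds, ref)) {
    idx <- sample.int(n, round(config$de_fraction * n))
    lfc[idx, cond] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      abs(stats::rnorm(length(idx), config$lfc_mean, config$lfc_sd))
  }
  ## GC-coupled expression tilt (condition-specific codon usage)
  gcz <- as.numeric(scale(genome$gc))
  for (cond in conds) {
    bias <- config$de_gc_bias[[cond]]
    if (bias != 0) lfc[, cond] <- lfc[, cond] + bias * gcz
  }

  ## ground-truth enriched terms: coordinated boost of member genes
  terms_all <- unique(as_tibble(catalog)$term_id)
  enriched <- list()
  for (cond in setdiff(conds, ref)) {
    picked <- sample(terms_all, min(config$n_enriched_terms, length(terms_all)))
    enriched[[cond]] <- picked
    member <- unique(catalog$gene_id[catalog$term_id %in% picked])
    lfc[rownames(lfc) %in% member, cond] <-
      lfc[rownames(lfc) %in% member, cond] + config$enrich_lfc
  }

  mu_cond <- base_mu * 2^lfc # genes x conditions

  mrna_samples <- tidyr::expand_grid(
    condition = conds, replicate = seq_len(config$n_rep_mrna)
  ) |>
    dplyr::mutate(sample_id = paste0("mrna_", .data$condition, "_r", .data$replicate)) |>
    dplyr::select("sample_id", "condition", "replicate")
  set.seed(derive_seed(config$seed, 202))
  depth_m <- exp(stats::runif(nrow(mrna_samples), log(0.7), log(1.4)))
  mrna_mat <- sapply(seq_len(nrow(mrna_samples)), function(j) {
    rnbinom(n,
      mu = depth_m[j] * mu_cond[, mrna_samples$condition[j]],
      size = 1 / config$dispersion
    )
  })
  colnames(mrna_mat) <- mrna_samples$sample_id
  rownames(mrna_mat) <- genome$gene_id

  ## ordered dissimilar contrasts and their stand-in DE tables
  contrasts <- purrr::map_dfr(config$dissimilar, function(p) {
    tibble(a = c(p[1], p[2]), b = c(p[2], p[1]))
  })
  de_tables <- purrr::pmap(contrasts, function(a, b) {
    welch_de_table(mrna_mat, mrna_samples, a, b)
  })
  names(de_tables) <- paste0(contrasts$a, "_vs_", contrasts$b)

  true_de_up <- purrr::pmap(contrasts, function(a, b) {
    genome$gene_id[lfc[, a] - lfc[, b] > 0]
  })
  names(true_de_up) <- names(de_tables)

  enriched_by_contrast <- purrr::pmap(contrasts, function(a, b) {
    if (a == ref) {
      ## reference is "enriched" where the other condition is depleted;
      ## our construction only boosts non-reference conditions
      character(0)
    } else {
      enriched[[a]]
    }
  })
  names(enriched_by_contrast) <- names(de_tables)

  ## --- tRNA side -----------------------------------------------------
  repertoire <- default_anticodon_repertoire()
  n_ac <- length(repertoire)
  set.seed(derive_seed(config$seed, 203))
  ## assign isoacceptor gene copies: every anticodon gets >= 1 gene
  extra <- config$n_trna_genes - n_ac
  if (extra < 0) abort("n_trna_genes must be >= the repertoire size (45)")
  copies <- 1L + tabulate(sample.int(n_ac, extra, replace = TRUE), nbins = n_ac)
  trna_annotation <- tibble(
    gene_id = sprintf("trna%03d", seq_len(sum(copies) + 2L)),
    anticodon = c(
      rep(repertoire, copies),
      sample(repertoire, 2L) # non-autosomal decoys, filtered downstream
    ),
    chromosome = c(
      sample(as.character(1:19), sum(copies), replace = TRUE),
      c("X", "MT")
    )
  )
  ## fixed within-anticodon gene shares; the non-autosomal decoys carry a
  ## negligible share so that filtering them barely perturbs the pool
  shares <- stats::runif(nrow(trna_annotation), 0.5, 1.5)
  shares[nrow(trna_annotation) - c(1L, 0L)] <- 0.02

  ## expected expression-weighted codon usage per condition (truth-based)
  cmat <- gene_codon_matrix(genome)
  eligible <- is_autosome(genome$chromosome)
  cu_cond <- sapply(conds, function(cond) {
    w <- mu_cond[eligible, cond] / genome$n_codons[eligible]
    as.numeric(t(cmat[eligible, , drop = FALSE]) %*% w)
  })
  rownames(cu_cond) <- SENSE_CODONS

  ## abundance profile: geometric series over the configured span
  profile <- config$trna_mu *
    config$trna_abundance_span^(seq(0, 1, length.out = n_ac) - 0.5)

  wc_codon <- revcomp(repertoire)
  ## one codon-usage-unrelated pool shape shared by every condition: tRNA
  ## pools are stable across cell states, so the alpha = 0 limit is a common
  ## random ordering, not an independent permutation per condition
  set.seed(derive_seed(config$seed, 300))
  perm_rank <- sample(seq_len(n_ac))
  pool_mean <- sapply(conds, function(cond) {
    alpha <- config$adaptation_alpha[[cond]]
    adapted_rank <- rank(cu_cond[wc_codon, cond])
    blend <- alpha * adapted_rank + (1 - alpha) * perm_rank
    ## most abundant anticodon <-> highest blended rank
    profile[rank(blend, ties.method = "first")]
  })
  rownames(pool_mean) <- repertoire

  trna_samples <- tidyr::expand_grid(
    condition = conds, replicate = seq_len(config$n_rep_trna)
  ) |>
    dplyr::mutate(sample_id = paste0("trna_", .data$condition, "_r", .data$replicate)) |>
    dplyr::select("sample_id", "condition", "replicate")
  set.seed(derive_seed(config$seed, 204))
  depth_t <- exp(stats::runif(nrow(trna_samples), log(0.7), log(1.4)))
  gene_mean <- sapply(conds, function(cond) {
    per_ac <- pool_mean[, cond]
    share_sum <- tapply(shares, trna_annotation$anticodon, sum)
    per_ac[trna_annotation$anticodon] * shares /
      share_sum[trna_annotation$anticodon]
  })
  trna_mat <- sapply(seq_len(nrow(trna_samples)), function(j) {
    mu <- depth_t[j] * gene_mean[, trna_samples$condition[j]]
    rnbinom(length(mu), mu = mu, size = 1 / config$trna_dispersion)
  })
  colnames(trna_mat) <- trna_samples$sample_id
  rownames(trna_mat) <- trna_annotation$gene_id

  ## synthetic stand-ins for the fixed gene lists: housekeeping = stably
  ## expressed non-DE genes; ribosomal = a small high-expression subset;
  ## proliferation = genes truly upregulated in every cancer condition
  set.seed(derive_seed(config$seed, 205))
  non_de <- genome$gene_id[rowSums(lfc != 0) == 0 & eligible]
  hk <- sample(non_de, min(200L, length(non_de)))
  high_expr <- non_de[order(-base_mu[match(non_de, genome$gene_id)])]
  rp <- head(high_expr, 80L)
  up_everywhere <- genome$gene_id[
    eligible & rowSums(lfc[, setdiff(conds, ref), drop = FALSE] > 0) ==
      length(conds) - 1L
  ]
  pp <- sample(up_everywhere, min(150L, length(up_everywhere)))

  list(
    mrna = list(
      counts = dplyr::bind_cols(
        tibble(gene_id = genome$gene_id), as_tibble(mrna_mat)
      ),
      samples = mrna_samples
    ),
    trna = list(
      counts = dplyr::bind_cols(
        tibble(gene_id = trna_annotation$gene_id), as_tibble(trna_mat)
      ),
      annotation = trna_annotation,
      samples = trna_samples
    ),
    de_tables = de_tables,
    enriched_terms = enriched_by_contrast,
    gene_lists = list(HK = hk, RP = rp, PP = pp),
    truth = list(
      base_mu = setNames(base_mu, genome$gene_id),
      lfc = lfc,
      de_genes_up = true_de_up,
      enriched_terms = enriched,
      pool_mean = pool_mean,
      adaptation_alpha = config$adaptation_alpha,
      mrna_depth = setNames(depth_m, mrna_samples$sample_id),
      trna_depth = setNames(depth_t, trna_samples$sample_id)
    )
  )
}

## Stand-in DE table: per-gene Welch t-test on log2 depth-normalized counts
## (condition `a` vs `b`), two-sided, with log2 fold change (a over b) and
## BH adjustment. A documented simplification sufficient to rank genes for
## top-gene selection -- with a handful of replicates a rank test's p-values
## are too granular to order thousands of genes -- not an emulation of a
## count-model DE analysis.
welch_de_table <- function(mat, samples, a, b) {
  ja <- samples$sample_id[samples$condition == a]
  jb <- samples$sample_id[samples$condition == b]
  sf <- estimate_size_factors(mat[, c(ja, jb), drop = FALSE])
  norm <- sweep(mat[, c(ja, jb), drop = FALSE], 2, sf, "/")
  lg <- log2(norm + 0.5)
  na <- length(ja)
  nb <- length(jb)
  xa <- lg[, seq_len(na), drop = FALSE]
  xb <- lg[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1) / na
  vb <- rowSums((xb - mb)^2) / (nb - 1) / nb
  se <- sqrt(va + vb)
  tstat <- (ma - mb) / se
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  pvalue <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  pvalue[!is.finite(pvalue)] <- 1
  mean_a <- rowMeans(norm[, seq_len(na), drop = FALSE])
  mean_b <- rowMeans(norm[, na + seq_len(nb), drop = FALSE])
  tibble(
    gene_id = rownames(mat),
    baseMean = rowMeans(norm),
    log2FoldChange = log2((mean_a + 0.5) / (mean_b + 0.5)),
    pvalue = pvalue,
    padj = p.adjust(pvalue, method = "BH")
  )
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits exactly the plain-text formats the readers consume: a CDS FASTA
#' (`>gene_id|transcript_id|chromosome`), mRNA and tRNA count TSVs, sample
#' sheets, a two-column catalog TSV, per-contrast DE TSVs, gene-list files
#' and a ground-truth YAML.
#'
#' @param genome_obj Output of [generate_genome()].
#' @param expr_obj Output of [generate_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_data <- function(genome_obj, expr_obj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  p <- file.path(dir, "cds.fasta")
  genome <- genome_obj$genome
  writeLines(
    paste0(
      ">", genome$gene_id, "|", genome$gene_id, ".t1|", genome$chromosome,
      "\n", genome$cds
    ),
    p
  )
  paths["fasta"] <- p

  wtsv <- function(x, name) {
    fp <- file.path(dir, name)
    readr::write_tsv(x, fp)
    fp
  }
  paths["mrna_counts"] <- wtsv(expr_obj$mrna$counts, "mrna_counts.tsv")
  paths["mrna_samples"] <- wtsv(expr_obj$mrna$samples, "mrna_samples.tsv")
  trna_out <- dplyr::left_join(
    expr_obj$trna$counts, expr_obj$trna$annotation,
    by = "gene_id"
  )
  paths["trna_counts"] <- wtsv(trna_out, "trna_counts.tsv")
  paths["trna_samples"] <- wtsv(expr_obj$trna$samples, "trna_samples.tsv")
  ## association-style two-column file, no header
  fp <- file.path(dir, "catalog.tsv")
  readr::write_tsv(
    as_tibble(genome_obj$catalog)[, c("term_id", "gene_id")],
    fp,
    col_names = FALSE
  )
  paths["catalog"] <- fp
  for (nm in names(expr_obj$de_tables)) {
    paths[paste0("de_", nm)] <- wtsv(
      expr_obj$de_tables[[nm]], paste0("de_", nm, ".tsv")
    )
  }
  for (nm in names(expr_obj$gene_lists)) {
    fp <- file.path(dir, paste0("genes_", nm, ".txt"))
    writeLines(expr_obj$gene_lists[[nm]], fp)
    paths[paste0("list_", nm)] <- fp
  }
  fp <- file.path(dir, "ground_truth.yaml")
  yaml::write_yaml(
    list(
      adaptation_alpha = as.list(expr_obj$truth$adaptation_alpha),
      de_genes_up = expr_obj$truth$de_genes_up,
      enriched_terms = expr_obj$truth$enriched_terms
    ),
    fp
  )
  paths["truth"] <- fp
  invisible(paths)
}
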