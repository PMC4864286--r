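## Match/mismatch pairing enumeration, gene-set menus, and one-tailed
## Mann-Whitney-Wilcoxon contrasts with Bonferroni correction.

#' Describe a match/mismatch study design
#'
#' Records which mRNA and tRNA samples belong to which condition and which
#' condition pairs are "dissimilar" (e.g. healthy liver vs either cancer
#' cell line, but not the cancer lines between each other). The dissimilar
#' relation is explicit and symmetric; it is never inferred.
#'
#' @param mrna_samples,trna_samples Sample sheets (`sample_id`, `condition`,
#'   `replicate`) for the two assays.
#' @param dissimilar A two-column data frame (or list of length-2 character
#'   vectors) of unordered condition pairs.
#' @return An object of class `cf_design`.
#' @export
study_design <- function(mrna_samples, trna_samples, dissimilar) {
  if (!is.data.frame(dissimilar)) {
    dissimilar <- do.call(rbind, lapply(dissimilar, function(p) {
      tibble(a = p[1], b = p[2])
    }))
  }
  names(dissimilar)[1:2] <- c("a", "b")
  if (any(dissimilar$a == dissimilar$b)) {
    abort("the dissimilar relation may not pair a condition with itself")
  }
  conds <- union(mrna_samples$condition, trna_samples$condition)
  unknown <- setdiff(c(dissimilar$a, dissimilar$b), conds)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "dissimilar pair names unknown condition(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  for (cond in conds) {
    if (!cond %in% mrna_samples$condition ||
      !cond %in% trna_samples$condition) {
      abort(sprintf(
        "condition '%s' needs at least one replicate in both assays", cond
      ))
    }
  }
  structure(
    list(
      mrna_samples = as_tibble(mrna_samples),
      trna_samples = as_tibble(trna_samples),
      dissimilar = as_tibble(dissimilar)
    ),
    class = "cf_design"
  )
}

#' @export
print.cf_design <- function(x, ...) {
  cat(sprintf(
    "<cf_design> %d mRNA / %d tRNA samples over conditions {%s}; %d dissimilar pair(s)\n",
    nrow(x$mrna_samples), nrow(x$trna_samples),
    paste(unique(x$mrna_samples$condition), collapse = ", "),
    nrow(x$dissimilar)
  ))
  invisible(x)
}

#' Enumerate match and mismatch sample pairings
#'
#' "Match" pairings are all pairwise combinations of mRNA and tRNA replicates
#' of the same condition; "mismatch" pairings combine the mRNA replicates of
#' one condition with the tRNA replicates of every dissimilar condition
#' (both directions of each dissimilar pair).
#'
#' @param design A `cf_design` from [study_design()].
#' @return A tibble with one row per pairing: `mrna_sample`,
#'   `mrna_condition`, `trna_sample`, `trna_condition`, `match`
#'   (`"match"`/`"mismatch"`).
#' @export
enumerate_pairings <- function(design) {
  stopifnot(inherits(design, "cf_design"))
  mr <- design$mrna_samples
  tr <- design$trna_samples
  cross <- function(cond_m, cond_t, label) {
    tidyr::expand_grid(
      mrna_sample = mr$sample_id[mr$condition == cond_m],
      trna_sample = tr$sample_id[tr$condition == cond_t]
    ) |>
      dplyr::mutate(
        mrna_condition = cond_m, trna_condition = cond_t, match = label
      )
  }
  match_part <- purrr::map_dfr(
    unique(mr$condition),
    function(cond) cross(cond, cond, "match")
  )
  sym <- dplyr::bind_rows(
    design$dissimilar,
    tibble(a = design$dissimilar$b, b = design$dissimilar$a)
  ) |> dplyr::distinct()
  mismatch_part <- purrr::pmap_dfr(
    sym,
    function(a, b) cross(a, b, "mismatch")
  )
  out <- dplyr::bind_rows(match_part, mismatch_part)
  if (nrow(out) == 0L) abort("design yields no pairings")
  out |>
    dplyr::select(
      "mrna_sample", "mrna_condition", "trna_sample", "trna_condition",
      "match"
    )
}

#' Assemble the six-entry gene-set menu
#'
#' Builds the named gene sets whose translational efficiencies are contrasted
#' between matching and mismatching tRNA pools: the whole transcriptome
#' (`all`), the top upregulated genes of each contrast (`DE`), the union of
#' significantly enriched catalog terms per contrast (`GO`; enrichment labels
#' are supplied externally), and fixed housekeeping / ribosomal-protein /
#' proliferation gene lists (`HK`, `RP`, `PP`).
#'
#' @param expressed Character vector of expressed gene ids (the `all` set and
#'   the universe against which list sets are checked).
#' @param de_tables Named list of DE tables, one per contrast, for the `DE`
#'   entry.
#' @param catalog A `cf_catalog`, for the `GO` entry.
#' @param enriched_terms Named list (per contrast) of significantly enriched
#'   term ids, as produced upstream by a gene-set enrichment analysis.
#' @param gene_lists Named list of character vectors for `HK`, `RP`, `PP`.
#' @param entries Which menu entries to build.
#' @param n_top Genes per DE set (default 200).
#' @return A tibble with columns `menu`, `set_id`, `gene_id`.
#' @export
build_gene_set_menu <- function(expressed,
                                de_tables = NULL,
                                catalog = NULL,
                                enriched_terms = NULL,
                                gene_lists = NULL,
                                entries = c("all", "DE", "GO", "HK", "RP", "PP"),
                                n_top = 200) {
  sets <- list()
  if ("all" %in% entries) {
    sets[[length(sets) + 1L]] <-
      tibble(menu = "all", set_id = "all", gene_id = expressed)
  }
  if ("DE" %in% entries) {
    if (is.null(de_tables)) abort("menu entry 'DE' requested but no DE tables")
    sets[[length(sets) + 1L]] <- purrr::imap_dfr(
      de_tables,
      function(de, contrast) {
        tibble(
          menu = "DE", set_id = paste0("DE:", contrast),
          gene_id = select_top_upregulated(de, n = n_top)
        )
      }
    )
  }
  if ("GO" %in% entries) {
    if (is.null(catalog) || is.null(enriched_terms)) {
      abort("menu entry 'GO' requested but catalog or enrichment labels missing")
    }
    sets[[length(sets) + 1L]] <- purrr::imap_dfr(
      enriched_terms,
      function(terms, contrast) {
        genes <- catalog$gene_id[catalog$term_id %in% terms]
        tibble(
          menu = "GO", set_id = paste0("GO:", contrast),
          gene_id = unique(genes)
        )
      }
    )
  }
  for (lst in intersect(c("HK", "RP", "PP"), entries)) {
    if (is.null(gene_lists[[lst]])) {
      abort(sprintf("menu entry '%s' requested but no gene list supplied", lst))
    }
    genes <- unique(gene_lists[[lst]])
    absent <- setdiff(genes, expressed)
    if (length(absent) > 0L) {
      warn(sprintf(
        "%s list: %d gene(s) not in the expressed universe dropped",
        lst, length(absent)
      ))
      genes <- intersect(genes, expressed)
    }
    sets[[length(sets) + 1L]] <- tibble(
      menu = lst, set_id = lst, gene_id = genes
    )
  }
  dplyr::bind_rows(sets)
}

#' Translational efficiency across all pairings and gene sets
#'
#' Computes one TE value per (gene set, sample pairing, variant): the
#' expression-weighted codon usage of the gene set in the mRNA sample
#' correlated against (or, for `tai`, scored on) the anticodon pool of the
#' tRNA sample. Every row carries full provenance.
#'
#' @param genome Canonical-CDS table.
#' @param gene_sets Menu tibble from [build_gene_set_menu()] (columns `menu`,
#'   `set_id`, `gene_id`), or a named list of gene-id vectors.
#' @param design A `cf_design`.
#' @param mrna_counts,trna_counts Count tables (`gene_id` + sample columns).
#' @param trna_annotation Data frame with `gene_id`, `anticodon`.
#' @param mrna_factors,trna_factors Named size factors (default: estimated
#'   from the supplied counts).
#' @param trna_genes Optional expressed tRNA gene subset
#'   ([filter_expressed_trna()]).
#' @param variants Subset of `c("strict", "wobble", "tai")`.
#' @param ramp_n If non-`NULL`, use only the first `ramp_n` codons of each
#'   CDS ([ramp_codon_usage()]) for the rank-based variants.
#' @param s_values,rules tAI penalties and wobble rules.
#' @return A tibble with columns `menu`, `gene_set`, `variant`,
#'   `mrna_sample`, `mrna_condition`, `trna_sample`, `trna_condition`,
#'   `match`, `value`, `n_pairs`.
#' @export
compute_te <- function(genome, gene_sets, design,
                       mrna_counts, trna_counts, trna_annotation,
                       mrna_factors = NULL, trna_factors = NULL,
                       trna_genes = NULL,
                       variants = "strict", ramp_n = NULL,
                       s_values = tai_s_values(), rules = wobble_rules()) {
  variants <- match.arg(variants, c("strict", "wobble", "tai"),
    several.ok = TRUE
  )
  if (!is.data.frame(gene_sets)) {
    gene_sets <- purrr::imap_dfr(
      gene_sets,
      function(g, id) tibble(menu = id, set_id = id, gene_id = g)
    )
  }
  mrna_factors <- mrna_factors %||% estimate_size_factors(mrna_counts)
  trna_factors <- trna_factors %||% estimate_size_factors(trna_counts)
  pairings <- enumerate_pairings(design)
  mmat <- as_count_matrix(mrna_counts)

  ## anticodon pool per tRNA sample
  pools <- purrr::map(
    setNames(nm = unique(pairings$trna_sample)),
    function(s) {
      anticodon_pool(trna_counts, trna_annotation, s,
        factors = trna_factors, genes = trna_genes
      )
    }
  )

  set_ids <- unique(gene_sets$set_id)
  set_genes <- split(gene_sets$gene_id, gene_sets$set_id)[set_ids]
  set_menu <- gene_sets |> dplyr::distinct(.data$set_id, .data$menu)

  ## expression vector per mRNA sample, restricted to genes with a CDS
  usable <- intersect(rownames(mmat), genome$gene_id)
  xs <- purrr::map(
    setNames(nm = unique(pairings$mrna_sample)),
    function(s) {
      setNames(mmat[usable, s] / mrna_factors[[s]], usable)
    }
  )

  ## abundance vector and cached tAI weights per pool
  abs_by_pool <- purrr::map(
    pools,
    function(p) setNames(p$abundance, p$anticodon)
  )
  tai_by_pool <- if ("tai" %in% variants) {
    purrr::map(abs_by_pool, tai_weights, s_values = s_values, rules = rules)
  }

  out <- purrr::map(set_ids, function(sid) {
    genes <- intersect(set_genes[[sid]], usable)
    if (length(genes) == 0L) {
      abort(sprintf("gene set '%s' has no usable genes", sid))
    }
    cus <- NULL
    if (any(variants %in% c("strict", "wobble"))) {
      cus <- purrr::map(xs, function(x) {
        cu <- if (is.null(ramp_n)) {
          weighted_codon_usage(genome, x[genes])
        } else {
          ramp_codon_usage(genome, x[genes], n_codons = ramp_n)
        }
        cu_vec(cu, "weight")
      })
    }
    cmat_set <- rs_set <- NULL
    if ("tai" %in% variants) {
      cmat_set <- gene_codon_matrix(
        genome[match(genes, genome$gene_id), , drop = FALSE]
      )
      rs_set <- rowSums(cmat_set)
    }
    grid <- tidyr::expand_grid(pairing = seq_len(nrow(pairings)), variant = variants)
    vals <- purrr::map2(grid$pairing, grid$variant, function(i, v) {
      ms <- pairings$mrna_sample[i]
      ts <- pairings$trna_sample[i]
      if (v == "tai") {
        tw <- tai_by_pool[[ts]]
        x <- xs[[ms]][genes]
        tai_g <- exp(as.vector(cmat_set %*% log(tw$w)) / rs_set)
        list(value = sum(tai_g * x) / sum(x), n_pairs = sum(tw$nonzero))
      } else {
        te_pair_values(cus[[ms]], abs_by_pool[[ts]], v, rules)
      }
    })
    dplyr::bind_cols(
      tibble(
        menu = set_menu$menu[set_menu$set_id == sid],
        gene_set = sid,
        variant = grid$variant
      ),
      pairings[grid$pairing, ],
      tibble(
        value = purrr::map_dbl(vals, "value"),
        n_pairs = purrr::map_int(vals, function(z) as.integer(z$n_pairs))
      )
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::select(
      "menu", "gene_set", "variant", "mrna_sample", "mrna_condition",
      "trna_sample", "trna_condition", "match", "value", "n_pairs"
    )
}

#' One-tailed match vs mismatch Mann-Whitney-Wilcoxon test
#'
#' Tests, per gene set and variant, whether TE values obtained with matching
#' tRNA pools are stochastically larger than those obtained with mismatching
#' pools (alternative: match > mismatch). The exact U distribution is used
#' for small samples without ties (smaller group of at most 8); otherwise the
#' tie-corrected normal approximation with continuity correction. P-values
#' are Bonferroni-corrected over `family_size` contrasts; significance codes
#' follow 0-0.001 `***`, 0.001-0.01 `**`, 0.01-0.05 `*`.
#'
#' @param te TE tibble ([compute_te()]) with at least `match` and `value`;
#'   grouped per `gene_set` x `variant` when those columns are present.
#' @param family_size Number of contrasts in the Bonferroni family (default:
#'   the number of gene_set x variant combinations in `te`).
#' @return A tibble with one row per contrast: `gene_set`, `variant`,
#'   `n_match`, `n_mismatch`, `statistic` (U), `p_value`, `family_size`,
#'   `bonferroni_p`, `significant`, `signif_code`.
#' @examples
#' te <- tibble::tibble(
#'   match = rep(c("match", "mismatch"), each = 3),
#'   value = c(3, 4, 5, 0, 1, 2)
#' )
#' compare_match_mismatch(te)
#' @export
compare_match_mismatch <- function(te, family_size = NULL) {
  stopifnot(all(c("match", "value") %in% names(te)))
  if (!"gene_set" %in% names(te)) te$gene_set <- "all"
  if (!"variant" %in% names(te)) te$variant <- "strict"
  groups <- te |> dplyr::group_by(.data$gene_set, .data$variant)
  family_size <- family_size %||% dplyr::n_groups(groups)
  out <- groups |>
    dplyr::group_modify(function(d, key) {
      m <- d$value[d$match == "match"]
      mm <- d$value[d$match == "mismatch"]
      if (length(m) == 0L || length(mm) == 0L) {
        abort("both match and mismatch values are required for the test")
      }
      has_ties <- anyDuplicated(c(m, mm)) > 0L
      use_exact <- min(length(m), length(mm)) <= 8L && !has_ties
      ht <- suppressWarnings(wilcox.test(
        m, mm,
        alternative = "greater", exact = use_exact, correct = TRUE
      ))
      tibble(
        n_match = length(m), n_mismatch = length(mm),
        statistic = unname(ht$statistic), p_value = ht$p.value,
        exact = use_exact
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      family_size = family_size,
      bonferroni_p = pmin(1, .data$p_value * family_size),
      significant = .data$bonferroni_p < 0.05,
      signif_code = signif_code(.data$bonferroni_p)
    )
  out
}

signif_code <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}
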