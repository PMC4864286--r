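## Count-matrix ingestion, median-of-ratios size factors, expression filters,
## DE-table ingestion and gene-set catalog reading.

#' Read a TSV count matrix
#'
#' First column `gene_id`, remaining columns one per sample. tRNA tables may
#' carry extra annotation columns `anticodon` and `chromosome`, which are
#' split off into the `annotation` attribute-free companion: use
#' [read_trna_counts()] for those.
#'
#' @param path Path to a tab-separated count file.
#' @return A tibble with `gene_id` and one numeric column per sample.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  names(out)[1] <- "gene_id"
  out
}

#' @rdname read_counts
#' @return `read_trna_counts()` returns a list with `counts` (gene_id +
#'   sample columns) and `annotation` (`gene_id`, `anticodon`, `chromosome`).
#' @export
read_trna_counts <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  names(raw)[1] <- "gene_id"
  ann_cols <- intersect(c("anticodon", "chromosome"), names(raw))
  if (length(ann_cols) < 2L) {
    abort("tRNA count table must carry `anticodon` and `chromosome` columns")
  }
  list(
    counts = raw |> dplyr::select(-dplyr::all_of(ann_cols)),
    annotation = raw |> dplyr::select("gene_id", dplyr::all_of(ann_cols))
  )
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `condition`, `replicate`.
#' @return A tibble with those columns.
#' @export
read_sample_sheet <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(out))) {
    abort(sprintf(
      "sample sheet must have columns %s", paste(need, collapse = ", ")
    ))
  }
  if (anyDuplicated(out$sample_id)) abort("duplicate sample_id in sample sheet")
  out
}

#' Median-of-ratios library size factors
#'
#' The Anders-Huber estimator: for each sample, the median over genes (with a
#' positive geometric mean across samples) of the ratio between the gene's
#' count and its geometric mean. Genes with a zero count in any sample drop
#' out of the median. mRNA and tRNA libraries are distinct experiments and
#' should be normalized separately.
#'
#' @param counts A data frame with `gene_id` plus one numeric column per
#'   sample, or a numeric matrix (genes x samples).
#' @return A named numeric vector of positive per-sample factors.
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b"), s1 = c(2, 8), s2 = c(4, 16))
#' estimate_size_factors(m)
#' @export
estimate_size_factors <- function(counts) {
  mat <- as_count_matrix(counts)
  if (any(mat < 0)) abort("counts must be non-negative")
  loggeo <- rowMeans(log(mat)) # -Inf for genes with any zero
  use <- is.finite(loggeo)
  if (!any(use)) {
    abort(paste0(
      "no gene has positive counts in every sample; ",
      "size factors are undefined"
    ))
  }
  factors <- apply(mat[use, , drop = FALSE], 2, function(cnt) {
    exp(median(log(cnt) - loggeo[use]))
  })
  setNames(factors, colnames(mat))
}

as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    return(counts)
  }
  stopifnot(is.data.frame(counts))
  mat <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  if (!is.numeric(mat)) abort("count columns must be numeric")
  rownames(mat) <- counts$gene_id
  mat
}

#' Expressed-gene filter for mRNA counts
#'
#' A protein-coding gene is called expressed when at least one library
#' replicate has a nonzero raw count. The analysis is restricted to
#' protein-coding genes on the nuclear autosomes, so genes on sex chromosomes
#' or the mitochondrial genome are excluded regardless of counts when an
#' annotation is supplied.
#'
#' @param counts Data frame: `gene_id` plus raw count columns.
#' @param annotation Optional data frame with `gene_id` and `chromosome`;
#'   genes whose chromosome is `X`, `Y` or mitochondrial (or `chr`-prefixed
#'   variants) are excluded.
#' @return Character vector of expressed gene ids, in input order.
#' @export
filter_expressed_mrna <- function(counts, annotation = NULL) {
  mat <- as_count_matrix(counts)
  keep <- rowSums(mat > 0) >= 1L
  ids <- rownames(mat)[keep]
  if (!is.null(annotation)) {
    excl <- annotation$gene_id[!is_autosome(annotation$chromosome)]
    ids <- setdiff(ids, excl)
  }
  ids
}

#' Is a chromosome a nuclear autosome?
#'
#' @param chromosome Character vector of chromosome names; `X`, `Y` and the
#'   mitochondrial genome (`M`/`MT`, optionally `chr`-prefixed) are not
#'   autosomes.
#' @return Logical vector.
#' @export
is_autosome <- function(chromosome) {
  !(sub("^chr", "", chromosome) %in% c("X", "Y", "M", "MT", "mt"))
}

#' Expressed-gene filter for tRNA counts
#'
#' tRNA quantification (Pol III ChIP) is noisier than mRNA-seq, so a stricter
#' filter is used: a tRNA gene is kept iff there is at least one assayed
#' condition in which every replicate has a normalized count (raw count /
#' size factor) of at least `threshold` (inclusive). Only tRNA genes on
#' nuclear autosomes are retained.
#'
#' @param counts Data frame: `gene_id` plus raw count columns.
#' @param samples Sample sheet (`sample_id`, `condition`, `replicate`)
#'   covering the count columns.
#' @param factors Per-sample size factors from [estimate_size_factors()].
#' @param annotation Optional data frame with `gene_id`, `chromosome`.
#' @param threshold Minimum normalized count (default 10).
#' @return Character vector of retained tRNA gene ids.
#' @export
filter_expressed_trna <- function(counts, samples, factors,
                                  annotation = NULL, threshold = 10) {
  mat <- as_count_matrix(counts)
  if (!all(samples$sample_id %in% colnames(mat))) {
    abort("every sample_id in `samples` must be a column of `counts`")
  }
  mat <- mat[, samples$sample_id, drop = FALSE]
  norm <- sweep(mat, 2, factors[samples$sample_id], "/")
  by_cond <- split(seq_len(nrow(samples)), samples$condition)
  ok <- Reduce(`|`, lapply(by_cond, function(idx) {
    rowSums(norm[, idx, drop = FALSE] >= threshold) == length(idx)
  }))
  ids <- rownames(mat)[ok]
  if (!is.null(annotation)) {
    excl <- annotation$gene_id[!is_autosome(annotation$chromosome)]
    ids <- setdiff(ids, excl)
  }
  ids
}

#' Read a differential-expression result table
#'
#' @param path TSV with columns `gene_id`, `baseMean`, `log2FoldChange`,
#'   `pvalue`, `padj`.
#' @return A tibble with those columns.
#' @export
read_de_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "baseMean", "log2FoldChange", "pvalue", "padj")
  if (!all(need %in% names(out))) {
    abort(sprintf(
      "DE table must have columns %s", paste(need, collapse = ", ")
    ))
  }
  out
}

#' Top upregulated genes of a contrast
#'
#' Reproduces the selection of the most upregulated genes for a condition:
#' genes in the lower three quartiles of base mean expression are discarded
#' (linear-interpolation percentile; a gene exactly at the 75th percentile is
#' kept), genes must be upregulated (`log2FoldChange > 0`, condition of
#' interest as numerator), and the `n` genes with the smallest p-values are
#' returned (all survivors if fewer). P-value ties are broken by descending
#' `baseMean`, then `gene_id`, for determinism.
#'
#' @param de A DE table ([read_de_table()]).
#' @param n Number of genes to select (default 200).
#' @param p_column Which p-value column ranks genes; the selection is on raw
#'   `"pvalue"` by default, `"padj"` is accepted.
#' @return Character vector of at most `n` gene ids.
#' @export
select_top_upregulated <- function(de, n = 200, p_column = c("pvalue", "padj")) {
  p_column <- match.arg(p_column)
  stopifnot(is.data.frame(de), nrow(de) >= 4L)
  cut <- quantile(de$baseMean, 0.75, type = 7, names = FALSE)
  surv <- de |>
    dplyr::filter(.data$baseMean >= cut, .data$log2FoldChange > 0)
  if (nrow(surv) == 0L) {
    abort(paste0(
      "no gene survives the selection (baseMean >= 75th percentile ",
      sprintf("= %.4g and log2FoldChange > 0)", cut)
    ))
  }
  surv |>
    dplyr::arrange(
      .data[[p_column]], dplyr::desc(.data$baseMean), .data$gene_id
    ) |>
    dplyr::slice_head(n = n) |>
    dplyr::pull("gene_id")
}

#' Read a gene-set catalog
#'
#' Two-column `(term_id, gene_id)` tab- or whitespace-separated text in the
#' style of a GO association export; lines starting with `#` or `!` are
#' comments. Duplicate `(term, gene)` pairs are collapsed.
#'
#' @param path Path to the catalog file.
#' @param genome_ids Optional character vector of known gene ids; member
#'   genes absent from it are flagged in the `in_genome` column.
#' @param min_size Terms with fewer genes than this are flagged (not
#'   dropped) via the `below_floor` column of [catalog_terms()]. Default 40.
#' @return A tibble of class `cf_catalog` with columns `term_id`, `gene_id`,
#'   `in_genome`, and attribute `min_size`.
#' @export
read_gene_set_catalog <- function(path, genome_ids = NULL, min_size = 40) {
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^[#!]", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warn(sprintf("'%s' contains no gene-set entries; empty catalog", path))
    return(new_catalog(
      tibble(term_id = character(), gene_id = character()),
      genome_ids, min_size
    ))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    first_bad <- which(keep)[which(nf != 2L)[1]]
    abort(sprintf(
      "malformed catalog line %d: expected two fields (term_id, gene_id)",
      first_bad
    ))
  }
  m <- do.call(rbind, fields)
  new_catalog(
    tibble(term_id = m[, 1], gene_id = m[, 2]),
    genome_ids, min_size
  )
}

new_catalog <- function(pairs, genome_ids = NULL, min_size = 40) {
  pairs <- dplyr::distinct(pairs, .data$term_id, .data$gene_id)
  pairs$in_genome <- if (is.null(genome_ids)) {
    NA
  } else {
    pairs$gene_id %in% genome_ids
  }
  structure(pairs, class = c("cf_catalog", class(pairs)), min_size = min_size)
}

#' Build a catalog from a data frame of (term_id, gene_id) pairs
#'
#' @param pairs Data frame with columns `term_id`, `gene_id`.
#' @inheritParams read_gene_set_catalog
#' @return A `cf_catalog` tibble; see [read_gene_set_catalog()].
#' @export
gene_set_catalog <- function(pairs, genome_ids = NULL, min_size = 40) {
  stopifnot(all(c("term_id", "gene_id") %in% names(pairs)))
  new_catalog(as_tibble(pairs), genome_ids, min_size)
}

#' Per-term summary of a catalog
#'
#' @param catalog A `cf_catalog` ([read_gene_set_catalog()]).
#' @return A tibble with `term_id`, `size` and `below_floor` (terms smaller
#'   than the catalog's size floor are flagged, not dropped).
#' @export
catalog_terms <- function(catalog) {
  floor <- attr(catalog, "min_size") %||% 40
  catalog |>
    as_tibble() |>
    dplyr::count(.data$term_id, name = "size") |>
    dplyr::mutate(below_floor = .data$size < floor)
}

#' Read a plain gene-list file
#'
#' One gene id per line; `#` comments and blank lines ignored.
#'
#' @param path Path to the list file.
#' @param genome_ids Optional known gene universe; absent genes are dropped
#'   with a warning.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path, genome_ids = NULL) {
  ids <- readr::read_lines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  ids <- unique(ids)
  if (!is.null(genome_ids)) {
    missing <- setdiff(ids, genome_ids)
    if (length(missing) > 0L) {
      warn(sprintf(
        "%d gene(s) in '%s' absent from the genome and dropped: %s",
        length(missing), path,
        paste(head(missing, 5), collapse = ", ")
      ))
      ids <- intersect(ids, genome_ids)
    }
  }
  ids
}

`%||%` <- function(a, b) if (is.null(a)) b else a
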