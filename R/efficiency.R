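## Expression-weighted codon usage, anticodon pools, and the three
## translational-efficiency statistics (strict, wobble-aware, tAI), plus the
## first-N-codons ramp variant.

#' Expression-weighted codon usage of a gene set
#'
#' For a gene set GS and one mRNA sample, the aggregate codon usage of codon
#' c is \deqn{CU_c = \sum_{g \in GS} CU_{cg} \cdot x_g / l_g,} i.e. each
#' gene's codon counts weighted by its expression `x_g` and normalized by
#' its coding-sequence length `l_g` (measured in sense codons, consistent
#' with the counts). Doubling all `x_g` doubles `CU` element-wise and leaves
#' every rank-based statistic unchanged.
#'
#' @param genome Canonical-CDS table ([canonical_cds()]).
#' @param expression A data frame with columns `gene_id` and `x` (the
#'   size-factor-normalized expression of one sample), or a named numeric
#'   vector.
#' @param genes Gene ids forming the set; default all genes in `expression`.
#' @return A tibble with columns `codon` and `weight` (length 61).
#' @examples
#' g <- tibble::tibble(gene_id = "g1", cds = "ATGAAAAAATGA")
#' g <- canonical_cds(g)
#' weighted_codon_usage(g, tibble::tibble(gene_id = "g1", x = 10))
#' @export
weighted_codon_usage <- function(genome, expression, genes = NULL) {
  x <- as_expression_vector(expression)
  genes <- genes %||% names(x)
  missing_cds <- setdiff(genes, genome$gene_id)
  if (length(missing_cds) > 0L) {
    abort(sprintf(
      "%d gene(s) in the set have no canonical CDS: %s",
      length(missing_cds), paste(head(missing_cds, 5), collapse = ", ")
    ))
  }
  missing_x <- setdiff(genes, names(x))
  if (length(missing_x) > 0L) {
    abort(sprintf(
      "%d gene(s) in the set have no expression value: %s",
      length(missing_x), paste(head(missing_x, 5), collapse = ", ")
    ))
  }
  sub <- genome[match(genes, genome$gene_id), , drop = FALSE]
  cmat <- gene_codon_matrix(sub)
  w <- x[genes] / sub$n_codons
  tibble(codon = SENSE_CODONS, weight = as.numeric(t(cmat) %*% w))
}

as_expression_vector <- function(expression) {
  if (is.data.frame(expression)) {
    stopifnot(all(c("gene_id", "x") %in% names(expression)))
    x <- setNames(expression$x, expression$gene_id)
  } else {
    x <- expression
    if (is.null(names(x))) abort("expression vector must be named by gene_id")
  }
  if (any(x < 0)) abort("expression values must be non-negative")
  x
}

#' Codon usage of the translational ramp (first N codons)
#'
#' As [weighted_codon_usage()], but counting only the first `n_codons` sense
#' codons of each canonical CDS (the slowly translated ramp at the start of
#' the transcript), with `l_g = n_codons` for every gene. `n_codons` may not
#' exceed the length of the shortest transcript in the set.
#'
#' @inheritParams weighted_codon_usage
#' @param n_codons Number of leading sense codons to use (default 10).
#' @return A tibble with columns `codon` and `weight`.
#' @export
ramp_codon_usage <- function(genome, expression, genes = NULL, n_codons = 10) {
  x <- as_expression_vector(expression)
  genes <- genes %||% names(x)
  missing_cds <- setdiff(genes, genome$gene_id)
  if (length(missing_cds) > 0L) {
    abort(sprintf(
      "%d gene(s) in the set have no canonical CDS: %s",
      length(missing_cds), paste(head(missing_cds, 5), collapse = ", ")
    ))
  }
  sub <- genome[match(genes, genome$gene_id), , drop = FALSE]
  shortest <- min(sub$n_codons)
  if (n_codons > shortest) {
    abort(sprintf(
      "n_codons = %d exceeds the shortest transcript in the set (%d codons)",
      n_codons, shortest
    ))
  }
  cmat <- t(vapply(sub$cds, function(s) {
    starts <- seq.int(1L, by = 3L, length.out = n_codons)
    codons <- substring(s, starts, starts + 2L)
    tabulate(factor(codons, levels = SENSE_CODONS), nbins = 61L)
  }, integer(61L), USE.NAMES = FALSE))
  w <- x[genes] / n_codons
  tibble(codon = SENSE_CODONS, weight = as.numeric(t(cmat) %*% w))
}

#' Anticodon abundance pool of one tRNA sample
#'
#' Sums the (size-factor-normalized) expression of isoacceptor tRNA genes --
#' genes sharing an anticodon -- into one abundance per anticodon.
#' Anticodons with no expressed tRNA gene are absent from the pool; the
#' strict translational-efficiency variant excludes their codons from the
#' correlation.
#'
#' @param counts Data frame: `gene_id` plus raw count columns (pre-filtered
#'   with [filter_expressed_trna()] if desired).
#' @param annotation Data frame with `gene_id` and `anticodon`.
#' @param sample_id Which count column to use.
#' @param factors Optional named size factors; when supplied, counts are
#'   divided by `factors[sample_id]`.
#' @param genes Optional subset of tRNA gene ids (e.g. the expressed set).
#' @return A tibble with columns `anticodon` and `abundance`.
#' @export
anticodon_pool <- function(counts, annotation, sample_id, factors = NULL,
                           genes = NULL) {
  mat <- as_count_matrix(counts)
  if (!sample_id %in% colnames(mat)) {
    abort(sprintf("sample '%s' not found in counts", sample_id))
  }
  v <- mat[, sample_id]
  if (!is.null(genes)) v <- v[intersect(names(v), genes)]
  if (!is.null(factors)) v <- v / factors[[sample_id]]
  ann <- setNames(annotation$anticodon, annotation$gene_id)
  no_ann <- setdiff(names(v), names(ann))
  if (length(no_ann) > 0L) {
    abort(sprintf(
      "tRNA gene(s) without anticodon annotation: %s",
      paste(head(no_ann, 5), collapse = ", ")
    ))
  }
  tibble(gene_id = names(v), abundance = as.numeric(v)) |>
    dplyr::mutate(anticodon = unname(ann[.data$gene_id])) |>
    dplyr::group_by(.data$anticodon) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::arrange(.data$anticodon)
}

#' Wobble pairing rules
#'
#' The unique wobble-paired anticodon used for codons whose Watson-Crick
#' anticodon is absent from the pool, keyed by the codon's third base. The
#' default table (G:T, T:G and inosine pairings) ships as an editable YAML
#' file in `inst/extdata/wobble_rules.yaml`.
#'
#' @param path Optional YAML file overriding the default rules.
#' @return A named character vector: codon third base -> anticodon wobble
#'   base.
#' @export
wobble_rules <- function(path = NULL) {
  path <- path %||% system.file(
    "extdata", "wobble_rules.yaml",
    package = "codonflux", mustWork = TRUE
  )
  rules <- unlist(yaml::read_yaml(path))
  if (!all(c("A", "C", "G", "T") %in% names(rules))) {
    abort("wobble rules must map every codon third base (A, C, G, T)")
  }
  rules[c("A", "C", "G", "T")]
}

#' tAI wobble penalties (s-values)
#'
#' The per-interaction-class selective constraints used by [modified_tai()].
#' Defaults are the initial (non-optimised) s-values of dos Reis et al.
#' (2004), shipped as `inst/extdata/tai_s_values.yaml`; they are
#' configuration, not constants, and can be overridden.
#'
#' @param path Optional YAML file with components `watson_crick` and
#'   `wobble`, each a mapping from codon third base to a penalty in `[0, 1]`.
#' @return A list with named numeric vectors `watson_crick` and `wobble`.
#' @export
tai_s_values <- function(path = NULL) {
  path <- path %||% system.file(
    "extdata", "tai_s_values.yaml",
    package = "codonflux", mustWork = TRUE
  )
  s <- yaml::read_yaml(path)
  for (cls in c("watson_crick", "wobble")) {
    v <- unlist(s[[cls]])
    if (!all(c("A", "C", "G", "T") %in% names(v))) {
      abort(sprintf("s-values '%s' must cover third bases A, C, G, T", cls))
    }
    if (any(v < 0 | v > 1)) abort("s-values must lie in [0, 1]")
    s[[cls]] <- v[c("A", "C", "G", "T")]
  }
  s[c("watson_crick", "wobble")]
}

## anticodons decoding each sense codon: watson_crick and the unique wobble
## partner per the rule table (memoised per rule table)
decoding_anticodons <- local({
  cache <- list()
  function(rules = wobble_rules()) {
    key <- paste(names(rules), rules, sep = ":", collapse = ",")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    third <- substr(SENSE_CODONS, 3L, 3L)
    stem <- revcomp(substr(SENSE_CODONS, 1L, 2L))
    wc_base <- c(A = "T", C = "G", G = "C", T = "A")
    out <- tibble(
      codon = SENSE_CODONS,
      watson_crick = paste0(wc_base[third], stem),
      wobble = paste0(rules[third], stem),
      third_base = third
    )
    cache[[key]] <<- out
    out
  }
})

## per-codon tAI decoding weights for one pool: W_i from the two interaction
## classes, normalised by the maximum, zeros replaced by the geometric mean
## of the nonzero weights
tai_weights <- function(ab, s_values, rules) {
  dec <- decoding_anticodons(rules)
  a_wc <- ifelse(dec$watson_crick %in% names(ab), ab[dec$watson_crick], 0)
  a_wob <- ifelse(dec$wobble %in% names(ab), ab[dec$wobble], 0)
  W <- (1 - s_values$watson_crick[dec$third_base]) * a_wc +
    (1 - s_values$wobble[dec$third_base]) * a_wob
  if (all(W == 0)) abort("all decoding weights are zero for this pool")
  w <- W / max(W)
  nz <- w > 0
  w[!nz] <- exp(mean(log(w[nz])))
  names(w) <- SENSE_CODONS
  list(w = w, nonzero = nz)
}

## core of the rank-based TE statistic, shared by the user-facing wrapper
## and the vectorised pipeline path
te_pair_values <- function(cuv, ab, variant, rules) {
  dec <- decoding_anticodons(rules)
  anticodon <- dec$watson_crick
  if (variant == "wobble") {
    unpaired <- !(anticodon %in% names(ab))
    anticodon[unpaired] <- dec$wobble[unpaired]
  }
  keep <- anticodon %in% names(ab)
  if (sum(keep) < 3L) {
    abort(sprintf(
      "only %d codon-anticodon pairs available; need at least 3", sum(keep)
    ))
  }
  list(
    value = spearman_rho(cuv[keep], ab[anticodon[keep]]),
    n_pairs = sum(keep)
  )
}

#' Spearman translational efficiency of a codon pool against a tRNA pool
#'
#' Correlates expression-weighted codon usage with anticodon abundances after
#' pairing each codon with its anticodon. Under the `strict` variant each
#' codon is paired only with its Watson-Crick anticodon (the reverse
#' complement); codons whose anticodon is absent from the pool are excluded
#' from the correlation. Under the `wobble` variant such unpaired codons are
#' instead paired with their unique wobble anticodon ([wobble_rules()]);
#' codons whose wobble anticodon is also absent remain excluded. The
#' statistic is Spearman's rho (average ranks), so any rescaling of either
#' pool leaves it unchanged.
#'
#' @param cu Codon-usage tibble (`codon`, `weight`) from
#'   [weighted_codon_usage()] or [ramp_codon_usage()].
#' @param pool Anticodon pool tibble ([anticodon_pool()]).
#' @param variant `"strict"` or `"wobble"`.
#' @param rules Wobble rule table (used by the `wobble` variant).
#' @return A one-row tibble with `variant`, `value` (rho) and `n_pairs` (the
#'   number of codon-anticodon pairs entering the correlation).
#' @export
translational_efficiency <- function(cu, pool,
                                     variant = c("strict", "wobble"),
                                     rules = wobble_rules()) {
  variant <- match.arg(variant)
  cuv <- cu_vec(cu, "weight")
  if (nrow(pool) == 0L) abort("anticodon pool is empty")
  ab <- setNames(pool$abundance, pool$anticodon)
  res <- te_pair_values(cuv, ab, variant, rules)
  tibble(variant = variant, value = res$value, n_pairs = res$n_pairs)
}

#' Expression-based tRNA adaptation index of a gene set
#'
#' A tRNA adaptation index in which the tRNA gene copy number of the classic
#' formulation is replaced by tRNA abundance estimated from tRNA gene
#' expression. For each codon i the decoding weight is
#' \deqn{W_i = (1 - s_{wc}) A_{wc(i)} + (1 - s_{wob}) A_{wob(i)},}
#' where `A` is the pool abundance of the codon's Watson-Crick and unique
#' wobble anticodon and the s-values penalise each interaction class
#' ([tai_s_values()]). Weights are normalized by their maximum
#' (`w_i = W_i / max W`); codons with `w_i = 0` are assigned the geometric
#' mean of the nonzero weights. A gene's tAI is the geometric mean of `w`
#' over its codons, and the set-level value is the expression-weighted
#' average \deqn{\sum_g tAI_g x_g / \sum_g x_g.}
#'
#' @inheritParams weighted_codon_usage
#' @param pool Anticodon pool tibble ([anticodon_pool()]).
#' @param s_values Penalty list from [tai_s_values()].
#' @param rules Wobble rule table ([wobble_rules()]).
#' @param exclude_start Drop one ATG count per gene (the initiator) before
#'   taking the geometric mean. Default `FALSE`.
#' @return A one-row tibble with `variant = "tai"`, `value` in `[0, 1]` and
#'   `n_pairs` (codons with nonzero decoding weight).
#' @export
modified_tai <- function(genome, expression, genes = NULL,
                         pool, s_values = tai_s_values(),
                         rules = wobble_rules(), exclude_start = FALSE) {
  x <- as_expression_vector(expression)
  genes <- genes %||% names(x)
  missing_cds <- setdiff(genes, genome$gene_id)
  if (length(missing_cds) > 0L) {
    abort(sprintf(
      "%d gene(s) in the set have no canonical CDS: %s",
      length(missing_cds), paste(head(missing_cds, 5), collapse = ", ")
    ))
  }
  if (nrow(pool) == 0L) abort("anticodon pool is empty")
  ab <- setNames(pool$abundance, pool$anticodon)
  tw <- tai_weights(ab, s_values, rules)
  w <- tw$w
  nz <- tw$nonzero
  sub <- genome[match(genes, genome$gene_id), , drop = FALSE]
  cmat <- gene_codon_matrix(sub)
  if (exclude_start) cmat[, "ATG"] <- pmax(cmat[, "ATG"] - 1L, 0L)
  tai_g <- exp(as.vector(cmat %*% log(w)) / rowSums(cmat))
  xg <- x[genes]
  if (sum(xg) == 0) abort("all expression weights are zero")
  tibble(
    variant = "tai",
    value = sum(tai_g * xg) / sum(xg),
    n_pairs = sum(nz)
  )
}
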