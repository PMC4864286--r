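## CDS validation, canonical-CDS selection, codon counting and GC content.

## Uppercase and map RNA U -> DNA T; error on any other character.
normalize_seq <- function(seq, arg = "seq") {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(
      sprintf(
        "%s contains non-ACGT characters (after uppercasing and U->T): e.g. %s",
        arg, sub(".*?([^ACGT]).*", "'\\1'", seq[bad][1])
      ),
      class = "codonflux_invalid_alphabet"
    )
  }
  seq
}

#' Validate a coding sequence
#'
#' A CDS is valid when it starts with the start codon `ATG`, ends with a stop
#' codon (`TAA`, `TAG` or `TGA`) and its length is divisible by 3. Sequences
#' are uppercased and `U` is read as `T`; any other character raises an
#' invalid-alphabet error (a condition of class `codonflux_invalid_alphabet`),
#' which is distinct from returning `FALSE`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Logical vector, one element per sequence.
#' @examples
#' is_valid_cds(c("ATGTAA", "ATGAAA", "GTGAAATAA"))
#' @export
is_valid_cds <- function(seq) {
  stopifnot(is.character(seq))
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  ok <- n >= 6 & n %% 3L == 0L
  start_ok <- substr(seq, 1L, 3L) == "ATG"
  stop_ok <- substr(seq, n - 2L, n) %in% STOP_CODONS
  ok & start_ok & stop_ok
}

#' Select the canonical CDS among a gene's annotated transcripts
#'
#' The canonical coding sequence of a gene is its longest annotated valid
#' coding sequence ([is_valid_cds()]). Ties in length are broken by keeping
#' the first candidate in annotation (input) order. Genes with no valid
#' candidate are dropped.
#'
#' @param transcripts A data frame with one row per annotated transcript,
#'   containing at least `gene_id` and `cds` (the coding sequence); other
#'   columns (e.g. `chromosome`, `transcript_id`) are carried through from
#'   the selected row.
#' @return A tibble with one row per gene that has a canonical CDS, the
#'   selected `cds`, its length in sense codons (`n_codons`), its
#'   [gc_content()] (`gc`) and, when a `chromosome` column is present, the
#'   mitochondrial flag `is_mt` (chromosome named `MT`, `chrM` or `chrMT`).
#' @examples
#' tx <- tibble::tibble(
#'   gene_id = c("g1", "g1", "g2"),
#'   cds = c("ATGTAA", "ATGAAATAA", "ATGCC")
#' )
#' canonical_cds(tx)
#' @export
canonical_cds <- function(transcripts) {
  stopifnot(is.data.frame(transcripts))
  if (!all(c("gene_id", "cds") %in% names(transcripts))) {
    abort("`transcripts` needs columns `gene_id` and `cds`")
  }
  out <- transcripts |>
    as_tibble() |>
    dplyr::mutate(
      cds = toupper(chartr("u", "t", chartr("U", "T", .data$cds))),
      .alpha_ok = !grepl("[^ACGT]", .data$cds)
    ) |>
    dplyr::filter(.data$.alpha_ok) |>
    dplyr::filter(is_valid_cds(.data$cds)) |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$gene_id) |>
    ## longest wins; equal length -> first in annotation order
    dplyr::arrange(dplyr::desc(nchar(.data$cds)), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord", -".alpha_ok")
  out <- out |>
    dplyr::mutate(
      n_codons = nchar(.data$cds) %/% 3L - 1L,
      gc = nchar(gsub("[AT]", "", .data$cds)) / nchar(.data$cds)
    )
  if ("chromosome" %in% names(out)) {
    out$is_mt <- out$chromosome %in% c("MT", "chrM", "chrMT", "mt")
  }
  attr(out, "codon_matrix") <- {
    mat <- t(vapply(out$cds, count_codons, integer(61L), USE.NAMES = FALSE))
    rownames(mat) <- out$gene_id
    colnames(mat) <- SENSE_CODONS
    mat
  }
  out
}

#' Count sense codons in a valid CDS
#'
#' Counts in-frame triplets of a valid coding sequence over the 61 sense
#' codons. The terminal stop codon is excluded; the initial `ATG` is counted
#' as an ordinary `ATG`. The total always equals `nchar(seq)/3 - 1`.
#'
#' @param seq A single valid CDS (see [is_valid_cds()]).
#' @return A named integer vector of length 61 (lexicographic
#'   [sense_codons()] order) with attribute sum equal to the codon total.
#' @examples
#' counts <- count_codons("ATGGCGGCGTGA")
#' counts[counts > 0]
#' @export
count_codons <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- normalize_seq(seq)
  if (!is_valid_cds(seq)) {
    abort("`seq` is not a valid CDS (ATG start, stop end, length %% 3 == 0)")
  }
  starts <- seq.int(1L, nchar(seq) - 5L, by = 3L) # drop terminal stop
  codons <- substring(seq, starts, starts + 2L)
  tab <- tabulate(factor(codons, levels = SENSE_CODONS), nbins = 61L)
  setNames(as.integer(tab), SENSE_CODONS)
}

## genes x 61 sense-codon count matrix for a canonical-CDS table; a cached
## matrix (attribute "codon_matrix", set by canonical_cds) is reused when it
## covers the requested genes
gene_codon_matrix <- function(genome) {
  stopifnot(all(c("gene_id", "cds") %in% names(genome)))
  cache <- attr(genome, "codon_matrix")
  if (!is.null(cache) && all(genome$gene_id %in% rownames(cache))) {
    return(cache[genome$gene_id, , drop = FALSE])
  }
  mat <- t(vapply(genome$cds, count_codons, integer(61L), USE.NAMES = FALSE))
  rownames(mat) <- genome$gene_id
  colnames(mat) <- SENSE_CODONS
  mat
}

#' GC content of a set of sequences
#'
#' The G+C to A+C+G+T frequency ratio over the concatenation of the input
#' sequences (equivalently, the length-weighted mean of per-sequence GC).
#'
#' @param seqs Character vector of DNA sequences; at least one must be
#'   non-empty.
#' @return A fraction in `[0, 1]`.
#' @examples
#' gc_content(c("ATGC", "GG"))
#' @export
gc_content <- function(seqs) {
  stopifnot(is.character(seqs))
  seqs <- normalize_seq(seqs, arg = "seqs")
  total <- sum(nchar(seqs))
  if (length(seqs) == 0L || total == 0L) {
    abort("`seqs` must contain at least one non-empty sequence")
  }
  gc <- sum(nchar(gsub("[AT]", "", seqs)))
  gc / total
}

#' Read per-transcript CDS records from a FASTA file
#'
#' Expects one record per annotated transcript with headers of the form
#' `>gene_id|transcript_id|chromosome` (separator configurable). Sequences
#' are uppercased and `U` is read as `T`.
#'
#' @param path Path to a FASTA file.
#' @param sep Field separator inside the header (default `"|"`).
#' @return A tibble with columns `gene_id`, `transcript_id`, `chromosome`
#'   and `cds`, suitable for [canonical_cds()].
#' @export
read_cds_fasta <- function(path, sep = "|") {
  ## BStringSet rather than DNAStringSet so RNA (U) and ambiguity codes
  ## survive reading; validation happens downstream
  recs <- Biostrings::readBStringSet(path)
  headers <- names(recs)
  fields <- stringr::str_split_fixed(headers, stringr::fixed(sep), 3L)
  tibble(
    gene_id = fields[, 1],
    transcript_id = fields[, 2],
    chromosome = fields[, 3],
    cds = toupper(chartr("Uu", "Tt", as.character(unname(recs))))
  )
}
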