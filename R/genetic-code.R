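## Standard (nuclear) genetic code, DNA alphabet. Sense codons are kept in
## lexicographic order so that codon-indexed vectors align across the package.

CODON_TABLE <- local({
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(
    as.vector(outer(bases, bases, paste0)), bases, paste0
  ))
  codons <- sort(codons)
  aa <- c(
    AAA = "K", AAC = "N", AAG = "K", AAT = "N",
    ACA = "T", ACC = "T", ACG = "T", ACT = "T",
    AGA = "R", AGC = "S", AGG = "R", AGT = "S",
    ATA = "I", ATC = "I", ATG = "M", ATT = "I",
    CAA = "Q", CAC = "H", CAG = "Q", CAT = "H",
    CCA = "P", CCC = "P", CCG = "P", CCT = "P",
    CGA = "R", CGC = "R", CGG = "R", CGT = "R",
    CTA = "L", CTC = "L", CTG = "L", CTT = "L",
    GAA = "E", GAC = "D", GAG = "E", GAT = "D",
    GCA = "A", GCC = "A", GCG = "A", GCT = "A",
    GGA = "G", GGC = "G", GGG = "G", GGT = "G",
    GTA = "V", GTC = "V", GTG = "V", GTT = "V",
    TAA = "*", TAC = "Y", TAG = "*", TAT = "Y",
    TCA = "S", TCC = "S", TCG = "S", TCT = "S",
    TGA = "*", TGC = "C", TGG = "W", TGT = "C",
    TTA = "L", TTC = "F", TTG = "L", TTT = "F"
  )
  stopifnot(identical(sort(names(aa)), codons))
  aa[codons]
})

STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE == "*"]
SENSE_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]

#' The standard genetic code
#'
#' Returns the 64-codon standard genetic code as a tibble. Codons are DNA
#' triplets in lexicographic order; stop codons are marked with amino acid
#' `"*"`. All codon-indexed vectors in the package follow this ordering.
#'
#' @return A tibble with columns `codon`, `amino_acid` and logical `is_stop`.
#' @examples
#' genetic_code()
#' @export
genetic_code <- function() {
  tibble(
    codon = names(CODON_TABLE),
    amino_acid = unname(CODON_TABLE),
    is_stop = CODON_TABLE == "*"
  )
}

#' Sense and stop codons
#'
#' @return `sense_codons()` returns the 61 amino-acid-encoding codons in
#'   lexicographic order; `stop_codons()` returns the three stop codons
#'   (`TAA`, `TAG`, `TGA`).
#' @examples
#' length(sense_codons())
#' stop_codons()
#' @export
sense_codons <- function() SENSE_CODONS

#' @rdname sense_codons
#' @export
stop_codons <- function() STOP_CODONS

## reverse complement of DNA strings (vectorised, uppercase ACGT only)
revcomp <- function(x) {
  rc <- chartr("ACGT", "TGCA", x)
  vapply(
    strsplit(rc, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

#' Pair a codon with its Watson-Crick anticodon
#'
#' Anticodons throughout the package are written 5'->3' in the DNA alphabet,
#' i.e. the reverse complement of the codon (`AAA` pairs `TTT`). The first
#' letter of the anticodon is its wobble (position 34) base.
#'
#' @param codon Character vector of DNA triplets.
#' @return Character vector of anticodon triplets.
#' @examples
#' pair_codon_anticodon(c("AAA", "ATG", "GCT"))
#' @export
pair_codon_anticodon <- function(codon) {
  stopifnot(is.character(codon))
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    abort(paste0(
      "`codon` must be DNA triplets over {A,C,G,T}; offending values: ",
      paste(unique(codon[bad]), collapse = ", ")
    ), class = "codonflux_invalid_alphabet")
  }
  revcomp(codon)
}
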