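## Small numeric helpers shared across modules.

#' Spearman rank correlation
#'
#' Thin wrapper over [stats::cor()] with `method = "spearman"` (average ranks
#' for ties), kept as a named entry point so every module correlates ranks
#' the same way.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  cor(x, y, method = "spearman")
}

## Row-wise Spearman correlation of each row of `mat` against `ref`.
## Vectorised: rank rows once, then a single matrix product.
row_spearman <- function(mat, ref) {
  stopifnot(ncol(mat) == length(ref))
  rr <- t(apply(mat, 1, rank))
  rb <- rank(ref)
  rrc <- rr - rowMeans(rr)
  rbc <- rb - mean(rb)
  den <- sqrt(rowSums(rrc^2) * sum(rbc^2))
  num <- as.vector(rrc %*% rbc)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

## coerce a codon-usage tibble (codon, <value>) or named vector to a numeric
## vector aligned with sense_codons()
cu_vec <- function(x, value_col = NULL) {
  if (is.data.frame(x)) {
    value_col <- value_col %||%
      intersect(c("weight", "count", "value"), names(x))[1]
    if (is.na(value_col) || !"codon" %in% names(x)) {
      abort("codon-usage table needs a `codon` column and a value column")
    }
    v <- setNames(x[[value_col]], x$codon)
  } else {
    v <- x
  }
  if (is.null(names(v))) {
    stopifnot(length(v) == 61L)
    names(v) <- SENSE_CODONS
  }
  out <- setNames(rep(0, 61L), SENSE_CODONS)
  keep <- intersect(names(v), SENSE_CODONS)
  out[keep] <- v[keep]
  out
}

## deterministic substream seed from a master seed and a small key
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(key) * 7919) %% 2147483587L) + 1L
}
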