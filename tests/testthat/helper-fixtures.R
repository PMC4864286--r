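# Shared fixtures. Expensive objects are built once per test session and
# cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a tiny hand-written genome: 4 nuclear genes + 1 mitochondrial
toy_genome <- function() {
  canonical_cds(tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "gmt"),
    chromosome = c("1", "1", "2", "3", "MT"),
    cds = c(
      "ATGAAAAAATGA", # 3 sense codons: ATG AAA AAA
      "ATGGCGGCGTAA", # ATG GCG GCG
      "ATGCCCGGGTAG", # ATG CCC GGG
      "ATGTTTAAAGCGTGA", # ATG TTT AAA GCG
      "ATGAAATAA"
    )
  ))
}

# random valid CDS of n_codons sense codons (uniform codon usage)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(
    "ATG",
    paste(sample(sense_codons(), n_codons - 1L, replace = TRUE), collapse = ""),
    sample(stop_codons(), 1L)
  )
}

# small default-condition synthetic dataset shared across test files
small_synthetic <- function() {
  cached("small_synthetic", {
    cfg <- synthetic_config(
      n_genes = 500, n_terms = 12, term_size_range = c(40, 60), seed = 42
    )
    g <- generate_genome(cfg)
    list(cfg = cfg, genome = g$genome, catalog = g$catalog, truth = g$truth,
         expr = generate_expression(cfg, g))
  })
}

# run the TE match/mismatch stage once for a given alpha / GC-tilt setting
run_te_study <- function(seed, alpha, gc_bias = 0, n_genes = 500) {
  cfg <- synthetic_config(
    n_genes = n_genes, n_terms = 1, term_size_range = c(40, 40),
    adaptation_alpha = alpha, de_gc_bias = gc_bias, seed = seed
  )
  g <- generate_genome(cfg)
  e <- generate_expression(cfg, g)
  mf <- estimate_size_factors(e$mrna$counts)
  tf <- estimate_size_factors(e$trna$counts)
  expressed <- filter_expressed_mrna(
    e$mrna$counts, g$genome[, c("gene_id", "chromosome")]
  )
  tg <- filter_expressed_trna(
    e$trna$counts, e$trna$samples, tf, e$trna$annotation
  )
  design <- study_design(e$mrna$samples, e$trna$samples, cfg$dissimilar)
  te <- compute_te(
    g$genome, list(all = expressed), design,
    mrna_counts = e$mrna$counts, trna_counts = e$trna$counts,
    trna_annotation = e$trna$annotation,
    mrna_factors = mf, trna_factors = tf, trna_genes = tg,
    variants = "strict"
  )
  list(
    te = te,
    p = compare_match_mismatch(te, family_size = 1)$p_value,
    match_mean = mean(te$value[te$match == "match"])
  )
}

# independent one-sided Mann-Whitney oracle: full enumeration over all
# group assignments (alternative: x > y)
mww_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  u_stat <- function(xi) {
    sum(rank(pooled)[xi]) - k * (k + 1) / 2
  }
  obs <- u_stat(seq_len(k))
  combos <- utils::combn(n, k)
  us <- apply(combos, 2, u_stat)
  mean(us >= obs)
}

# independent Benjamini-Hochberg oracle, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
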