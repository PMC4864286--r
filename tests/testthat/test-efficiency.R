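test_that("expression-weighted codon usage follows CU_c = sum(count * x / l)", {
  g <- canonical_cds(tibble::tibble(
    gene_id = "g1", cds = "ATGAAAAAATGA" # codons ATG AAA AAA, l = 3
  ))
  cu <- weighted_codon_usage(g, tibble::tibble(gene_id = "g1", x = 10))
  v <- setNames(cu$weight, cu$codon)
  expect_equal(unname(v["AAA"]), 2 * 10 / 3)
  expect_equal(unname(v["ATG"]), 10 / 3)
  expect_equal(sum(v > 0), 2L)
  # a gene with x = 0 contributes nothing
  g2 <- canonical_cds(tibble::tibble(
    gene_id = c("g1", "g2"), cds = c("ATGAAAAAATGA", "ATGCCCTAG")
  ))
  cu2 <- weighted_codon_usage(g2, c(g1 = 10, g2 = 0))
  expect_equal(cu2$weight, cu$weight)
  # doubling expression doubles CU element-wise
  cu3 <- weighted_codon_usage(g2, c(g1 = 20, g2 = 0))
  expect_equal(cu3$weight, 2 * cu2$weight)
  expect_error(
    weighted_codon_usage(g, c(g1 = 1, missing = 2)),
    "no canonical CDS"
  )
})

test_that("ramp usage counts only the first N codons with l = N", {
  g <- canonical_cds(tibble::tibble(
    gene_id = c("a", "b"),
    cds = c("ATGAAACCCGGGTGA", "ATGTTTTAA") # 4 and 2 sense codons
  ))
  x <- c(a = 6, b = 3)
  # n_codons = 1: pure ATG for every gene
  r1 <- ramp_codon_usage(g, x, n_codons = 1)
  v1 <- setNames(r1$weight, r1$codon)
  expect_equal(unname(v1["ATG"]), 6 / 1 + 3 / 1)
  expect_equal(sum(v1 > 0), 1L)
  # a transcript of exactly n codons matches its full-length usage
  full_b <- weighted_codon_usage(g, x["b"])
  ramp_b <- ramp_codon_usage(g, x["b"], n_codons = 2)
  expect_equal(ramp_b$weight, full_b$weight)
  expect_error(ramp_codon_usage(g, x, n_codons = 3), "shortest")
})

test_that("anticodon pools sum isoacceptor gene expression", {
  counts <- tibble::tibble(
    gene_id = c("t1", "t2", "t3"),
    s1 = c(5, 7, 2)
  )
  ann <- tibble::tibble(
    gene_id = c("t1", "t2", "t3"),
    anticodon = c("AGC", "AGC", "TTT")
  )
  pool <- anticodon_pool(counts, ann, "s1")
  expect_equal(pool$abundance[pool$anticodon == "AGC"], 12)
  expect_equal(pool$abundance[pool$anticodon == "TTT"], 2)
  expect_equal(nrow(pool), 2L) # distinct anticodons never merge
  # size factors divide through
  pool2 <- anticodon_pool(counts, ann, "s1", factors = c(s1 = 2))
  expect_equal(pool2$abundance, pool$abundance / 2)
  expect_error(
    anticodon_pool(counts, ann[1:2, ], "s1"),
    "without anticodon annotation"
  )
})

test_that("strict TE excludes codons without a pooled anticodon", {
  # pool over 4 anticodons; cu ranks equal to pool ranks over paired codons
  pool <- tibble::tibble(
    anticodon = c("TTT", "GGC", "CAT", "AGC"),
    abundance = c(1, 2, 3, 4)
  )
  cu <- rep(0, 61)
  names(cu) <- sense_codons()
  cu[c("AAA", "GCC", "ATG", "GCT")] <- c(10, 20, 30, 40)
  cu_tbl <- tibble::tibble(codon = names(cu), weight = unname(cu))
  te <- translational_efficiency(cu_tbl, pool, "strict")
  expect_equal(te$n_pairs, 4L)
  expect_equal(te$value, 1)
  # reversed ranks give -1
  cu[c("AAA", "GCC", "ATG", "GCT")] <- c(40, 30, 20, 10)
  te_rev <- translational_efficiency(
    tibble::tibble(codon = names(cu), weight = unname(cu)), pool, "strict"
  )
  expect_equal(te_rev$value, -1)
  # positive rescaling of the pool leaves rho unchanged
  pool10 <- dplyr::mutate(pool, abundance = abundance * 10)
  expect_equal(
    translational_efficiency(cu_tbl, pool10, "strict")$value, te$value
  )
  expect_error(
    translational_efficiency(cu_tbl, pool[1:2, ], "strict"),
    "at least 3"
  )
})

test_that("the wobble variant pairs orphan codons via the rule table", {
  # pool anticodons pair codons AAC, AAA, ATG, GCT by Watson-Crick; the
  # orphan AAT (whose cognate ATT is absent) wobble-pairs to GTT
  pool <- tibble::tibble(
    anticodon = c("GTT", "TTT", "CAT", "AGC"),
    abundance = c(8, 1, 2, 4)
  )
  cu <- setNames(rep(0, 61), sense_codons())
  cu[c("AAC", "AAT", "AAA", "ATG", "GCT")] <- c(80, 80, 10, 20, 40)
  cu_tbl <- tibble::tibble(codon = names(cu), weight = unname(cu))
  strict <- translational_efficiency(cu_tbl, pool, "strict")
  wobble <- translational_efficiency(cu_tbl, pool, "wobble")
  expect_equal(strict$n_pairs, 4L) # AAT and other orphans excluded
  expect_equal(strict$value, 1)
  # hand-built wobble pairing oracle: Watson-Crick plus, for orphans, the
  # rule-table anticodon where present (AAT/AAG via TT stem, GCC/GCA via GC)
  pairing <- c(
    AAC = "GTT", AAA = "TTT", ATG = "CAT", GCT = "AGC",
    AAT = "GTT", AAG = "TTT", GCC = "AGC", GCA = "AGC"
  )
  ab <- setNames(pool$abundance, pool$anticodon)
  expect_equal(wobble$n_pairs, length(pairing))
  expect_equal(
    wobble$value,
    cor(rank(cu[names(pairing)]), rank(ab[pairing]))
  )
  expect_false(isTRUE(all.equal(wobble$value, strict$value)))
  # monotone transforms of CU leave the statistic unchanged
  cu_tbl2 <- dplyr::mutate(cu_tbl, weight = log1p(weight) * 3)
  expect_equal(
    translational_efficiency(cu_tbl2, pool, "wobble")$value, wobble$value
  )
})

test_that("tAI closed forms hold: uniform pool gives 1, w = {1/4, 1} gives 1/2", {
  s0 <- list(
    watson_crick = c(A = 0, C = 0, G = 0, T = 0),
    wobble = c(A = 0, C = 0, G = 0, T = 0)
  )
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(
    as.vector(outer(bases, bases, paste0)), bases, paste0
  ))
  uniform <- tibble::tibble(anticodon = all64, abundance = 1)
  g <- canonical_cds(tibble::tibble(
    gene_id = "g1", cds = random_cds(30, seed = 4)
  ))
  tai <- modified_tai(g, c(g1 = 5), pool = uniform, s_values = s0)
  expect_equal(tai$value, 1)
  # two-codon gene with decoding weights 0.25 and 1 -> geometric mean 0.5
  g2 <- canonical_cds(tibble::tibble(gene_id = "g2", cds = "ATGAAAGAATAA"))
  pool2 <- tibble::tibble(anticodon = c("TTT", "TTC"), abundance = c(1, 4))
  tai2 <- modified_tai(
    g2, c(g2 = 3),
    pool = pool2, s_values = s0, exclude_start = TRUE
  )
  expect_equal(tai2$value, 0.5)
  # a single-gene set equals that gene's tAI for any positive weight
  tai2b <- modified_tai(
    g2, c(g2 = 700),
    pool = pool2, s_values = s0, exclude_start = TRUE
  )
  expect_equal(tai2b$value, tai2$value)
  # rescaling the pool cancels in the weight normalization
  pool2x <- dplyr::mutate(pool2, abundance = abundance * 37)
  expect_equal(
    modified_tai(
      g2, c(g2 = 3),
      pool = pool2x, s_values = s0, exclude_start = TRUE
    )$value,
    tai2$value
  )
})

test_that("shipped s-values and wobble rules load and validate", {
  s <- tai_s_values()
  expect_named(s, c("watson_crick", "wobble"))
  expect_equal(unname(s$watson_crick), rep(0, 4))
  expect_equal(s$wobble[["T"]], 0.41)
  expect_equal(s$wobble[["C"]], 0.28)
  expect_equal(s$wobble[["A"]], 0.9999)
  expect_equal(s$wobble[["G"]], 0.68)
  rules <- wobble_rules()
  expect_equal(unname(rules[c("T", "G", "C", "A")]), c("G", "T", "A", "A"))
})

test_that("rank-based TE is invariant to monotone transforms of either input", {
  set.seed(31)
  pool <- tibble::tibble(
    anticodon = pair_codon_anticodon(sample(sense_codons(), 20)),
    abundance = rlnorm(20, 3, 1)
  )
  cu <- tibble::tibble(codon = sense_codons(), weight = rlnorm(61, 1, 1))
  base <- translational_efficiency(cu, pool, "strict")$value
  expect_equal(
    translational_efficiency(
      dplyr::mutate(cu, weight = weight^3), pool, "strict"
    )$value,
    base
  )
  expect_equal(
    translational_efficiency(
      cu, dplyr::mutate(pool, abundance = exp(abundance)), "strict"
    )$value,
    base
  )
})

test_that("ramp TE is defined across the whole 5..min-length sweep", {
  syn <- small_synthetic()
  e <- syn$expr
  mf <- estimate_size_factors(e$mrna$counts)
  tf <- estimate_size_factors(e$trna$counts)
  expressed <- filter_expressed_mrna(
    e$mrna$counts, syn$genome[, c("gene_id", "chromosome")]
  )
  design <- study_design(e$mrna$samples, e$trna$samples, syn$cfg$dissimilar)
  genes <- intersect(expressed, syn$genome$gene_id)[1:40]
  min_len <- min(syn$genome$n_codons[syn$genome$gene_id %in% genes])
  for (n in unique(c(5, 10, min_len))) {
    te <- compute_te(
      syn$genome, list(ramp = genes), design,
      mrna_counts = e$mrna$counts, trna_counts = e$trna$counts,
      trna_annotation = e$trna$annotation,
      mrna_factors = mf, trna_factors = tf,
      variants = "strict", ramp_n = n
    )
    expect_true(all(is.finite(te$value)))
    expect_true(all(abs(te$value) <= 1))
  }
  expect_error(
    compute_te(
      syn$genome, list(ramp = genes), design,
      mrna_counts = e$mrna$counts, trna_counts = e$trna$counts,
      trna_annotation = e$trna$annotation,
      mrna_factors = mf, trna_factors = tf,
      variants = "strict", ramp_n = min_len + 1
    ),
    "shortest"
  )
})
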