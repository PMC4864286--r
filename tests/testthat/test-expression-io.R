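test_that("median-of-ratios size factors match hand-derived values", {
  m <- tibble::tibble(gene_id = c("a", "b"), s1 = c(5, 5), s2 = c(5, 5))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))
  # second column twice the first: factors (1/sqrt(2), sqrt(2))
  m2 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(2, 8), s2 = c(4, 16))
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # a gene with a zero anywhere is excluded from the median
  m3 <- tibble::tibble(
    gene_id = c("a", "b", "z"),
    s1 = c(2, 8, 0), s2 = c(4, 16, 1e6)
  )
  expect_equal(unname(estimate_size_factors(m3)), c(1 / sqrt(2), sqrt(2)))
  expect_error(
    estimate_size_factors(
      tibble::tibble(gene_id = c("a", "b"), s1 = c(0, 3), s2 = c(3, 0))
    ),
    "no gene has positive counts"
  )
})

test_that("size factors are scale-equivariant and agree with DESeq2", {
  set.seed(11)
  mat <- matrix(rpois(200, 50) + 1, ncol = 4,
    dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4))
  )
  base <- estimate_size_factors(mat)
  scaled <- mat
  scaled[, 2] <- scaled[, 2] * 3
  ## factors are defined up to the gene-wise geometric-mean reference, so
  ## column scaling moves factor *ratios*, not single factors
  sc <- estimate_size_factors(scaled)
  expect_equal(
    unname(sc / sc[1]),
    unname(base * c(1, 3, 1, 1) / base[1])
  )
  # two-sample all-positive matrix: scaling one column by c multiplies the
  # factor ratio by c
  two <- mat[, 1:2]
  f2 <- estimate_size_factors(two)
  two_scaled <- two
  two_scaled[, 2] <- two_scaled[, 2] * 5
  f2s <- estimate_size_factors(two_scaled)
  expect_equal(f2s[[2]] / f2s[[1]], 5 * f2[[2]] / f2[[1]])
  expect_equal(
    unname(base),
    unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
    tolerance = 1e-8
  )
})

test_that("mRNA expression filter keeps nonzero autosomal genes", {
  counts <- tibble::tibble(
    gene_id = c("zero", "one", "chrx", "mt"),
    r1 = c(0, 0, 10, 10), r2 = c(0, 1, 10, 10)
  )
  ann <- tibble::tibble(
    gene_id = c("zero", "one", "chrx", "mt"),
    chromosome = c("1", "2", "X", "MT")
  )
  expect_setequal(filter_expressed_mrna(counts, ann), "one")
  # without annotation only the count rule applies
  expect_setequal(filter_expressed_mrna(counts), c("one", "chrx", "mt"))
})

test_that("tRNA filter needs >= 10 normalized in every replicate of a condition", {
  counts <- tibble::tibble(
    gene_id = c("at10", "at9.9", "onecond", "mito"),
    a1 = c(20, 19.8, 2, 40), a2 = c(20, 19.8, 4, 40),
    b1 = c(2, 2, 20, 40), b2 = c(2, 2, 20, 40)
  )
  samples <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    condition = c("A", "A", "B", "B"),
    replicate = c(1, 2, 1, 2)
  )
  factors <- c(a1 = 2, a2 = 2, b1 = 2, b2 = 2)
  ann <- tibble::tibble(
    gene_id = c("at10", "at9.9", "onecond", "mito"),
    chromosome = c("1", "1", "2", "MT")
  )
  kept <- filter_expressed_trna(counts, samples, factors, ann)
  expect_setequal(kept, c("at10", "onecond")) # boundary inclusive; chrM dropped
  # invariant to replicate relabelling within a condition
  samples2 <- samples[c(2, 1, 4, 3), ]
  expect_setequal(
    filter_expressed_trna(counts, samples2, factors, ann), kept
  )
})

test_that("top-upregulated selection applies quartile cut, direction and ties", {
  de <- tibble::tibble(
    gene_id = paste0("g", 1:8),
    baseMean = 1:8,
    log2FoldChange = c(1, 1, 1, 1, 1, 1, 1, -1),
    pvalue = c(.01, .01, .01, .01, .01, .005, .2, .001),
    padj = pvalue
  )
  # 75th percentile of 1..8 is 6.25: only baseMeans 7, 8 survive; g8 is
  # downregulated, so g7 (p = 0.2) is all that is left
  expect_equal(select_top_upregulated(de, n = 1), "g7")
  # all p equal: ties broken by descending baseMean then gene_id
  de2 <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    baseMean = c(10, 10, 40, 40),
    log2FoldChange = 1, pvalue = 0.5, padj = 0.5
  )
  expect_equal(select_top_upregulated(de2, n = 2), c("c", "d"))
  # boundary gene exactly at the 75th percentile is kept
  de3 <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    baseMean = c(1, 2, 3, 4, 4),
    log2FoldChange = 1, pvalue = 0.1, padj = 0.1
  )
  expect_true("d" %in% select_top_upregulated(de3, n = 5))
  expect_error(
    select_top_upregulated(
      tibble::tibble(
        gene_id = letters[1:4], baseMean = 1:4,
        log2FoldChange = -1, pvalue = 0.5, padj = 0.5
      )
    ),
    "no gene survives"
  )
})

test_that("selection size and membership rules hold on random DE tables", {
  set.seed(21)
  for (i in 1:10) {
    n_genes <- sample(20:200, 1)
    de <- tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      baseMean = rlnorm(n_genes, 3, 1),
      log2FoldChange = rnorm(n_genes),
      pvalue = runif(n_genes)
    )
    de$padj <- p.adjust(de$pvalue, "BH")
    n <- sample(c(5, 25, 300), 1)
    sel <- tryCatch(select_top_upregulated(de, n = n), error = function(e) NULL)
    if (is.null(sel)) next
    expect_lte(length(sel), n)
    cut <- quantile(de$baseMean, 0.75, names = FALSE)
    picked <- de[match(sel, de$gene_id), ]
    expect_true(all(picked$baseMean >= cut))
    expect_true(all(picked$log2FoldChange > 0))
  }
})

test_that("gene-set catalogs read, deduplicate and flag correctly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment", "GO:1\tg1", "GO:1\tg2", "GO:2\tg1", "GO:1\tg2"
  ), path)
  cat1 <- read_gene_set_catalog(path, genome_ids = c("g1", "g3"))
  expect_equal(dplyr::n_distinct(cat1$term_id), 2L)
  expect_equal(nrow(cat1), 3L) # duplicate pair collapsed
  expect_equal(cat1$in_genome, c(TRUE, FALSE, TRUE))
  terms <- catalog_terms(cat1)
  expect_true(all(terms$below_floor)) # both terms below the 40-gene floor
  # malformed line reported with its line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GO:1\tg1", "justonefield"), bad)
  expect_error(read_gene_set_catalog(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing here", empty)
  expect_warning(out <- read_gene_set_catalog(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("plain gene lists drop genes missing from the genome with a warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("g1", "g2", "g2", "nope", "# note"), path)
  expect_warning(
    ids <- read_gene_list(path, genome_ids = c("g1", "g2", "g3")),
    "absent"
  )
  expect_setequal(ids, c("g1", "g2"))
})
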