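test_that("background codon usage sums canonical CDSs, excluding chrM", {
  g <- toy_genome()
  bg <- background_codon_usage(g)
  one <- background_codon_usage(g[g$gene_id == "g1", ])
  expect_equal(
    cu_bg <- setNames(one$count, one$codon)[c("ATG", "AAA")],
    c(ATG = 1, AAA = 2)
  )
  # two identical genes double the counts
  twice <- background_codon_usage(g[c(1, 1), ])
  expect_equal(twice$count, 2 * one$count)
  # adding a mitochondrial gene changes nothing
  without_mt <- background_codon_usage(g[g$gene_id != "gmt", ])
  expect_equal(bg$count, without_mt$count)
})

test_that("null sampling is seeded, size-complete and degenerate at full size", {
  set.seed(3)
  g <- canonical_cds(tibble::tibble(
    gene_id = sprintf("g%02d", 1:12),
    chromosome = "1",
    cds = vapply(1:12, function(i) random_cds(30), character(1))
  ))
  n1 <- sample_null(g, sizes = c(3, 12), n_samples = 50, seed = 7)
  n2 <- sample_null(g, sizes = c(3, 12), n_samples = 50, seed = 7)
  expect_equal(n1$draws, n2$draws) # reproducible
  # a set of every gene is the background itself
  expect_true(all(n1$draws$rho[n1$draws$size == 12] == 1))
  # adding a size leaves existing substreams untouched
  n3 <- sample_null(g, sizes = c(3, 5, 12), n_samples = 50, seed = 7)
  expect_equal(
    n3$draws$rho[n3$draws$size == 3],
    n1$draws$rho[n1$draws$size == 3]
  )
  expect_error(sample_null(g, sizes = 13, n_samples = 5, seed = 1), "exceeds")
})

test_that("size-1 null draws enumerate the per-gene correlations evenly", {
  g2 <- canonical_cds(tibble::tibble(
    gene_id = c("a", "b"),
    chromosome = "1",
    cds = c(random_cds(40, seed = 1), random_cds(40, seed = 2))
  ))
  bg <- setNames(
    background_codon_usage(g2)$count, background_codon_usage(g2)$codon
  )
  per_gene <- vapply(
    g2$cds,
    function(s) cor(rank(count_codons(s)), rank(bg)), # rank-then-Pearson
    numeric(1)
  )
  nl <- sample_null(g2, sizes = 1, n_samples = 2000, seed = 5)
  expect_setequal(round(unique(nl$draws$rho), 10), round(unname(per_gene), 10))
  prop <- mean(abs(nl$draws$rho - per_gene[1]) < 1e-12)
  expect_gt(prop, 0.4) # ~1:1 proportion
  expect_lt(prop, 0.6)
})

test_that("null spread shrinks and centre rises with set size", {
  syn <- small_synthetic()
  nl <- sample_null(syn$genome, sizes = c(10, 40, 160), n_samples = 400, seed = 2)
  qs <- tidy(nl)
  expect_true(all(diff(qs$median) > 0))
  expect_true(all(diff(qs$iqr) < 0))
})

test_that("empirical divergence matches a brute-force enumeration oracle", {
  set.seed(8)
  genome <- canonical_cds(tibble::tibble(
    gene_id = sprintf("g%d", 1:8),
    chromosome = "1",
    cds = vapply(1:8, function(i) random_cds(25), character(1))
  ))
  cmat <- t(vapply(genome$cds, count_codons, integer(61)))
  bg <- colSums(cmat)
  k <- 3
  subsets <- utils::combn(8, k)
  all_rho <- apply(subsets, 2, function(idx) {
    cor(rank(colSums(cmat[idx, , drop = FALSE])), rank(bg))
  })
  exhaustive_null <- structure(
    list(
      draws = tibble::tibble(size = k, rho = all_rho),
      background = tibble::tibble(codon = sense_codons(), count = as.numeric(bg)),
      sizes = k, n_samples = length(all_rho), seed = 0L
    ),
    class = "cf_null"
  )
  catalog <- gene_set_catalog(tibble::tibble(
    term_id = rep(c("t1", "t2"), each = k),
    gene_id = c("g1", "g2", "g3", "g4", "g6", "g8")
  ))
  res <- empirical_divergence(catalog, exhaustive_null, genome)
  # oracle: plain fraction of enumerated subsets strictly below the observed
  for (term in c("t1", "t2")) {
    genes <- catalog$gene_id[catalog$term_id == term]
    obs <- cor(
      rank(colSums(cmat[genome$gene_id %in% genes, ])), rank(bg)
    )
    expect_equal(
      res$empirical_p[res$term_id == term],
      mean(all_rho < obs)
    )
  }
  expect_equal(res$q, bh_oracle(res$empirical_p))
})

test_that("empirical p-values hit the 0 and 1 boundaries and BH matches hand values", {
  fake_null <- structure(
    list(
      draws = tibble::tibble(size = 2, rho = seq(0.2, 0.8, length.out = 50)),
      background = tibble::tibble(
        codon = sense_codons(),
        count = as.numeric(count_codons(random_cds(50, seed = 3))) + 1
      ),
      sizes = 2, n_samples = 50, seed = 0L
    ),
    class = "cf_null"
  )
  # BH on (0.01, 0.02, 0.03, 0.04) gives q = 0.04 everywhere
  expect_equal(
    p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
    rep(0.04, 4)
  )
  expect_equal(
    bh_oracle(c(0.01, 0.02, 0.03, 0.04)),
    rep(0.04, 4)
  )
  # add-one estimator never returns exactly zero
  syn <- small_synthetic()
  nl <- sample_null(syn$genome, sizes = c(40, 60), n_samples = 50, seed = 1)
  sizes_ok <- dplyr::count(tibble::as_tibble(syn$catalog), term_id)
  div <- empirical_divergence(
    syn$catalog, nl, syn$genome,
    add_one = TRUE, nearest_size = TRUE
  )
  expect_true(all(div$empirical_p >= 1 / 51))
  # unknown term size errors unless nearest-size mapping is enabled
  expect_error(
    empirical_divergence(syn$catalog, nl, syn$genome),
    "not sampled"
  )
})

test_that("Spearman wrapper equals the rank-then-Pearson oracle under ties", {
  set.seed(13)
  for (i in 1:25) {
    x <- sample(1:8, 30, replace = TRUE) # heavy ties
    y <- rnorm(30)
    expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)))
  }
})
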