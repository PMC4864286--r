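make_samples <- function(prefix, conds, reps) {
  tidyr::expand_grid(condition = conds, replicate = seq_len(reps)) |>
    dplyr::mutate(
      sample_id = paste0(prefix, condition, "_r", replicate)
    ) |>
    dplyr::select(sample_id, condition, replicate)
}

test_that("pairing enumeration yields the expected match/mismatch counts", {
  d <- study_design(
    make_samples("m_", c("A", "B"), 2),
    make_samples("t_", c("A", "B"), 2),
    list(c("A", "B"))
  )
  pr <- enumerate_pairings(d)
  expect_equal(sum(pr$match == "match"), 8L) # 2 conditions x 2 x 2
  expect_equal(sum(pr$match == "mismatch"), 8L) # both directions of A-B
  # match rows pair identical conditions; mismatch rows never do
  expect_true(all(
    (pr$mrna_condition == pr$trna_condition) == (pr$match == "match")
  ))
})

test_that("non-dissimilar condition pairs are never mismatched", {
  d <- study_design(
    make_samples("m_", c("L", "B", "C"), 2),
    make_samples("t_", c("L", "B", "C"), 2),
    list(c("L", "B"), c("L", "C")) # B and C are both cell lines
  )
  pr <- enumerate_pairings(d)
  bc <- pr[pr$mrna_condition == "B" & pr$trna_condition == "C", ]
  cb <- pr[pr$mrna_condition == "C" & pr$trna_condition == "B", ]
  expect_equal(nrow(bc) + nrow(cb), 0L)
  # |match| and |mismatch| follow the replicate-product formulas
  set.seed(17)
  for (i in 1:5) {
    rm <- sample(1:4, 3, replace = TRUE)
    rt <- sample(1:4, 3, replace = TRUE)
    ms <- dplyr::bind_rows(lapply(1:3, function(k) {
      make_samples(paste0("m", k, "_"), LETTERS[k], rm[k])
    }))
    ts <- dplyr::bind_rows(lapply(1:3, function(k) {
      make_samples(paste0("t", k, "_"), LETTERS[k], rt[k])
    }))
    dd <- study_design(ms, ts, list(c("A", "B"), c("A", "C")))
    pp <- enumerate_pairings(dd)
    expect_equal(sum(pp$match == "match"), sum(rm * rt))
    expect_equal(
      sum(pp$match == "mismatch"),
      rm[1] * rt[2] + rm[2] * rt[1] + rm[1] * rt[3] + rm[3] * rt[1]
    )
  }
  expect_error(
    study_design(
      make_samples("m_", "A", 2), make_samples("t_", "A", 2),
      list(c("A", "A"))
    ),
    "may not pair a condition with itself"
  )
})

test_that("one-tailed match/mismatch test matches exact and hand values", {
  te <- tibble::tibble(
    match = rep(c("match", "mismatch"), each = 3),
    value = c(3, 4, 5, 0, 1, 2)
  )
  res <- compare_match_mismatch(te, family_size = 1)
  expect_equal(res$p_value, 1 / 20) # only 1 of C(6,3) splits as extreme
  expect_true(res$exact)
  # identical multisets carry no one-sided evidence
  te2 <- tibble::tibble(
    match = rep(c("match", "mismatch"), each = 3),
    value = c(5, 6, 7, 5, 6, 7)
  )
  expect_gte(compare_match_mismatch(te2, family_size = 1)$p_value, 0.5)
  # Bonferroni multiplies (0.05 x 3 = 0.15, not significant) and caps at 1
  res3 <- compare_match_mismatch(te, family_size = 3)
  expect_equal(res3$bonferroni_p, 0.15)
  expect_false(res3$significant)
  res40 <- compare_match_mismatch(te, family_size = 40)
  expect_equal(res40$bonferroni_p, 1)
  expect_error(
    compare_match_mismatch(
      tibble::tibble(match = "match", value = 1),
      family_size = 1
    ),
    "both match and mismatch"
  )
})

test_that("exact MWW p agrees with full permutation enumeration", {
  set.seed(23)
  for (i in 1:12) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- round(rnorm(n1), 4)
    y <- round(rnorm(n2, -0.5), 4)
    if (anyDuplicated(c(x, y)) > 0) next
    te <- tibble::tibble(
      match = rep(c("match", "mismatch"), c(n1, n2)),
      value = c(x, y)
    )
    expect_equal(
      compare_match_mismatch(te, family_size = 1)$p_value,
      mww_exact_oracle(x, y)
    )
  }
})

test_that("significance codes follow the 0.001/0.01/0.05 ladder", {
  codes <- codonflux:::signif_code(c(0.0005, 0.005, 0.03, 0.2))
  expect_equal(codes, c("***", "**", "*", ""))
})

test_that("the gene-set menu assembles all six entry types", {
  syn <- small_synthetic()
  expressed <- filter_expressed_mrna(
    syn$expr$mrna$counts, syn$genome[, c("gene_id", "chromosome")]
  )
  menu <- build_gene_set_menu(
    expressed,
    de_tables = syn$expr$de_tables,
    catalog = syn$catalog,
    enriched_terms = syn$expr$enriched_terms,
    gene_lists = syn$expr$gene_lists,
    n_top = 30
  )
  expect_setequal(
    unique(menu$menu), c("all", "DE", "GO", "HK", "RP", "PP")
  )
  # the "all" entry is exactly the expressed universe
  expect_setequal(menu$gene_id[menu$set_id == "all"], expressed)
  # one DE set per contrast, each with at most n_top genes
  de_sets <- menu[menu$menu == "DE", ]
  expect_equal(
    dplyr::n_distinct(de_sets$set_id), length(syn$expr$de_tables)
  )
  expect_true(all(table(de_sets$set_id) <= 30))
  # a gene list with members outside the universe shrinks with a warning
  expect_warning(
    m2 <- build_gene_set_menu(
      expressed[1:50],
      gene_lists = list(HK = c(expressed[1:4], "ghost")),
      entries = "HK"
    ),
    "not in the expressed universe"
  )
  expect_equal(nrow(m2), 4L)
})
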