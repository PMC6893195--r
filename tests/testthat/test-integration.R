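module_fpr_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    term = vapply(rows, `[[`, "", 1),
    module_index = as.integer(vapply(rows, `[[`, "", 2)),
    gene_id = vapply(rows, `[[`, "", 3),
    fpr = as.numeric(vapply(rows, `[[`, "", 4))
  )
}

toy_candidates <- function(ids) {
  tibble::tibble(
    gene_id = ids, chrom = "chr1",
    start = seq_along(ids) * 1e6, end = seq_along(ids) * 1e6 + 1e5
  )
}

test_that("the functional score is the max of -log10 FPR over modules", {
  tbl <- module_fpr_tbl(
    c("t1", "1", "g1", "0.1"), c("t2", "1", "g1", "0.01"),
    c("t1", "1", "g2", "0.5")
  )
  fs <- functional_score(tbl)
  expect_equal(fs$functional_score[fs$gene_id == "g1"], 2)
  expect_equal(fs$best_term[fs$gene_id == "g1"], "t2")
  expect_equal(fs$functional_score[fs$gene_id == "g2"], -log10(0.5))
  # one strong module outranks uniform moderate ties
  peaked <- functional_score(module_fpr_tbl(
    c("t1", "1", "gp", "0.01"), c("t2", "1", "gp", "0.9"),
    c("t1", "1", "gu", "0.2"), c("t2", "1", "gu", "0.2")
  ))
  expect_gt(peaked$functional_score[peaked$gene_id == "gp"],
            peaked$functional_score[peaked$gene_id == "gu"])
  expect_error(functional_score(module_fpr_tbl(c("t", "1", "g", "0"))),
               "FPR <= 0")
})

test_that("combined scores normalize each axis by its candidate maximum", {
  cand <- toy_candidates(c("g1", "g2", "g3"))
  func <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         functional_score = c(2, 1, 0))
  pos <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        max_neglog10p = c(0.5, 1.0, 0))
  tab <- combined_score(cand, func, pos)
  expect_equal(tab$s_cg[match(c("g1", "g2", "g3"), tab$gene_id)],
               c(1.5, 1.5, 0))
  # ties on s_cg break lexicographically
  expect_equal(tab$gene_id[1:2], c("g1", "g2"))
  expect_equal(max(tab$norm_positional), 1)
  expect_equal(max(tab$norm_functional), 1)
  expect_true(all(tab$s_cg >= 0 & tab$s_cg <= 2))

  # a gene attaining both maxima scores exactly 2
  tab2 <- combined_score(
    toy_candidates(c("a", "b")),
    tibble::tibble(gene_id = c("a", "b"), functional_score = c(3, 1)),
    tibble::tibble(gene_id = c("a", "b"), max_neglog10p = c(4, 2))
  )
  expect_equal(tab2$s_cg[tab2$gene_id == "a"], 2)

  # zero positional maximum collapses that term with a warning
  expect_warning(
    tab3 <- combined_score(
      toy_candidates(c("a", "b")),
      tibble::tibble(gene_id = c("a", "b"), functional_score = c(3, 1)),
      tibble::tibble(gene_id = c("a", "b"), max_neglog10p = c(0, 0))
    ),
    "positional"
  )
  expect_equal(tab3$norm_positional, c(0, 0))
  expect_equal(tab3$s_cg[tab3$gene_id == "a"], 1)
})

test_that("candidates missing from network or scan are kept and flagged", {
  cand <- toy_candidates(c("g1", "g2"))
  tab <- combined_score(
    cand,
    tibble::tibble(gene_id = "g1", functional_score = 2),
    tibble::tibble(gene_id = "g1", max_neglog10p = 3),
    network_genes = "g1"
  )
  g2 <- tab[tab$gene_id == "g2", ]
  expect_true(g2$not_in_network)
  expect_equal(g2$s_cg, 0)
  expect_equal(nrow(tab), 2)
})

test_that("ranking is invariant to uniform rescaling of raw p-values", {
  cand <- toy_candidates(paste0("g", 1:6))
  set.seed(4)
  p <- runif(6, 1e-8, 0.5)
  func <- tibble::tibble(gene_id = cand$gene_id,
                         functional_score = runif(6, 0, 3))
  t1 <- combined_score(cand, func, tibble::tibble(
    gene_id = cand$gene_id, max_neglog10p = -log10(p)
  ))
  t2 <- combined_score(cand, func, tibble::tibble(
    gene_id = cand$gene_id, max_neglog10p = -log10(p) + 2  # p scaled by 1e-2
  ))
  # multiplying all p by a constant shifts -log10 uniformly; the
  # normalized ordering of the positional axis is preserved
  expect_equal(order(t1$norm_positional), order(t2$norm_positional))
})

test_that("the Pareto front matches dominance enumeration", {
  # hand case
  tab <- tibble::tibble(
    norm_positional = c(1, 0, 0.5, 0.4),
    norm_functional = c(0, 1, 0.5, 0.4)
  )
  expect_equal(pareto_front(tab), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(pareto_front(tibble::tibble(norm_positional = 0.2,
                                          norm_functional = 0.1)))
  # random instances vs the O(n^2) oracle, including ties and duplicates
  set.seed(14)
  for (i in 1:20) {
    n <- 100
    x <- sample(round(runif(n), sample(1:3, 1)))
    y <- sample(round(runif(n), sample(1:3, 1)))
    expect_identical(pareto_front(tibble::tibble(norm_positional = x,
                                                 norm_functional = y)),
                     brute_pareto(x, y))
  }
})

test_that("the top-ranked gene is always on the Pareto front", {
  set.seed(15)
  for (i in 1:10) {
    cand <- toy_candidates(paste0("g", 1:20))
    tab <- combined_score(
      cand,
      tibble::tibble(gene_id = cand$gene_id,
                     functional_score = runif(20, 0, 3)),
      tibble::tibble(gene_id = cand$gene_id,
                     max_neglog10p = runif(20, 0, 8))
    )
    expect_true(tab$pareto[1])
  }
})

test_that("ranked outputs round-trip and flag confident module hits", {
  cand <- toy_candidates(c("g1", "g2"))
  tab <- combined_score(
    cand,
    tibble::tibble(gene_id = c("g1", "g2"), functional_score = c(2, 1)),
    tibble::tibble(gene_id = c("g1", "g2"), max_neglog10p = c(3, 1))
  )
  ms <- module_fpr_tbl(
    c("t1", "1", "g1", "0.15"), c("t1", "1", "g2", "0.25")
  )
  dir <- withr::local_tempdir()
  paths <- write_ranked_outputs(tab, dir, module_scores = ms)
  back <- readr::read_tsv(paths[["ranked"]], show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tibble::as_tibble(tab)))
  mm <- readr::read_tsv(paths[["module_matrix"]], show_col_types = FALSE)
  expect_true(mm$high_confidence[mm$gene_id == "g1"])   # FPR 0.15 <= 0.2
  expect_false(mm$high_confidence[mm$gene_id == "g2"])  # FPR 0.25 > 0.2
  # empty module set still writes a (row-less) matrix with a warning
  expect_warning(write_ranked_outputs(tab, dir), "No module scores")
})
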