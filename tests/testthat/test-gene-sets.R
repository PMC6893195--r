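local_geneset_dir <- function(sets, envir = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = envir)
  for (nm in names(sets)) writeLines(sets[[nm]], file.path(dir, paste0(nm, ".txt")))
  dir
}

test_that("gene-set directories load with de-duplication and skipping", {
  dir <- local_geneset_dir(list(
    anaphylaxis = paste0("g", 1:120),
    cardiac = c("g1", "g2", "g1"),
    empty = character()
  ))
  file.create(file.path(dir, "empty.txt"))
  sets <- suppressMessages(suppressWarnings(read_gene_sets(dir)))
  suppressMessages(expect_warning(
    expect_warning(read_gene_sets(dir), "duplicate"),
    "no valid lines"
  ))
  expect_setequal(unique(sets$term), c("anaphylaxis", "cardiac"))
  expect_equal(sum(sets$term == "anaphylaxis"), 120)
  expect_equal(sum(sets$term == "cardiac"), 2)
  expect_error(suppressMessages(read_gene_sets(withr::local_tempdir())),
               "No gene-set files")
})

test_that("candidate exclusion removes genes and refuses to empty a term", {
  sets <- tibble::tibble(term = "t", gene_id = c("a", "b", "c"))
  expect_equal(
    suppressMessages(exclude_genes(sets, "b"))$gene_id, c("a", "c")
  )
  # disjoint exclusion is the identity
  expect_equal(suppressMessages(exclude_genes(sets, "zz")), sets)
  expect_error(
    suppressMessages(exclude_genes(sets, c("a", "b", "c"))),
    "untrainable"
  )
})

test_that("fast-greedy splits two bridged cliques at maximum modularity", {
  net <- two_clique_network()
  part <- fast_greedy_partition(net, net$nodes)
  expect_equal(dplyr::n_distinct(part$community), 2)
  # community labels align exactly with the cliques
  split_groups <- split(part$gene_id, part$community)
  expect_setequal(
    vapply(split_groups, function(g) paste(sort(substr(g, 1, 1)), collapse = ""),
           ""),
    c("aaaaa", "bbbbb")
  )
  # oracle: no 2-part split of the 10 nodes beats the returned modularity
  g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- -Inf
  for (mask in 0:(2^9 - 1)) {
    memb <- c(1, as.integer(intToBits(mask))[1:9]) + 1
    m <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    best <- max(best, m)
  }
  expect_gte(attr(part, "modularity") + 1e-12, best)
})

test_that("single cliques and edgeless subgraphs give one community", {
  net <- two_clique_network()
  part <- fast_greedy_partition(net, paste0("a", 1:5))
  expect_equal(dplyr::n_distinct(part$community), 1)

  iso <- functional_network(toy_edges(c("x", "y", "0.5")),
                            nodes = c("p", "q", "r"))
  expect_warning(part2 <- fast_greedy_partition(iso, c("p", "q", "r")),
                 "no edges")
  expect_equal(unique(part2$community), 1L)
  expect_error(fast_greedy_partition(iso, "p"), "at least 2")
})

test_that("planted three-block networks are recovered up to relabeling", {
  sim <- small_planted(n_genes = 180, n_modules = 3, module_size = 60, seed = 1)
  part <- fast_greedy_partition(sim$network, sim$network$nodes)
  truth <- sim$truth$module[match(part$gene_id, sim$truth$gene_id)]
  tab <- table(truth, part$community)
  # each planted block maps to exactly one found community
  expect_equal(dplyr::n_distinct(part$community), 3)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0) == 1)))
})

test_that("partition modularity beats the all-singleton baseline", {
  for (seed in 1:3) {
    sim <- small_planted(n_genes = 60, module_size = 15, seed = seed)
    net <- sim$network
    part <- fast_greedy_partition(net, net$nodes)
    g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    singleton <- igraph::modularity(g, seq_along(net$nodes),
                                    weights = igraph::E(g)$weight)
    expect_gte(attr(part, "modularity"), singleton)
  }
})

test_that("iterative clustering respects max_size and partitions exactly", {
  # a set already within max_size is returned whole, unclustered
  sim <- small_planted(n_genes = 400, module_size = 50)
  genes350 <- sim$network$nodes[1:350]
  mod <- cluster_gene_set(sim$network, genes350, max_size = 400)
  expect_equal(unique(mod$module_index), 1L)
  expect_setequal(mod$gene_id, genes350)

  # 900-gene union of 3 planted blocks splits into 3 modules, each < 400
  sim3 <- small_planted(n_genes = 900, n_modules = 3, module_size = 300,
                        seed = 2)
  mods <- suppressMessages(
    cluster_gene_set(sim3$network, sim3$network$nodes[1:900], max_size = 400)
  )
  sizes <- table(mods$module_index)
  expect_equal(length(sizes), 3)
  expect_true(all(sizes < 400))
  # modules are disjoint and their union is the mapped set
  expect_equal(sort(mods$gene_id), sim3$network$nodes[1:900])
})

test_that("unsplittable oversize communities terminate with a warning", {
  tri <- functional_network(toy_edges(
    c("a", "b", "1"), c("b", "c", "1"), c("a", "c", "1")
  ))
  expect_warning(
    mods <- cluster_gene_set(tri, c("a", "b", "c"), max_size = 2),
    "could not be split|kept as one"
  )
  expect_setequal(mods$gene_id, c("a", "b", "c"))
})

test_that("clustering is deterministic across repeated runs", {
  sim <- small_planted(n_genes = 500, n_modules = 2, module_size = 220,
                       seed = 5)
  sets <- tibble::tibble(term = "t", gene_id = sim$network$nodes[1:440])
  m1 <- suppressMessages(suppressWarnings(cluster_gene_sets(sim$network, sets)))
  m2 <- suppressMessages(suppressWarnings(cluster_gene_sets(sim$network, sets)))
  expect_identical(m1, m2)
})
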