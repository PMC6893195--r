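#' Configuration for a synthetic study fixture
#'
#' The fixture emulates the statistical structure the prioritization method
#' assumes: a thresholded weighted functional network with planted gene
#' modules, trait gene sets built from planted modules plus noise, a locus
#' tiled with positional candidate genes, and an inbred strain panel whose
#' binary phenotype is driven by one causal SNP near a planted-module gene.
#'
#' @param n_genes Total genes in the network.
#' @param n_modules Number of planted modules.
#' @param module_size Genes per planted module.
#' @param within_weight_mean Mean edge weight inside a planted module
#'   (edges Beta-distributed).
#' @param between_weight_mean Mean weight of background edges.
#' @param background_degree Mean background degree per gene (the network is
#'   sparse, mimicking a "top edges" file).
#' @param n_terms Number of trait gene sets; term t is built from planted
#'   module t.
#' @param geneset_noise_frac Fraction of each set drawn as random non-module
#'   genes.
#' @param n_strains Strains in the panel.
#' @param n_haplotype_groups Number of strain haplotype groups (kinship
#'   blocks).
#' @param n_locus_snps SNPs inside the locus.
#' @param n_background_snps Genome-background SNPs used for kinship.
#' @param locus Locus definition `list(chrom, start, end)`.
#' @param n_candidate_genes Positional candidates tiling the locus.
#' @param causal_gene_index Which candidate slot (1-based) holds the causal
#'   gene; the causal gene is a member of planted module 1.
#' @param penetrance P(phenotype = 1) for strains carrying the causal
#'   alternate allele.
#' @param background_rate P(phenotype = 1) otherwise; must be below
#'   `penetrance`.
#' @param seed Master seed; every simulated object is a deterministic
#'   function of the config.
#' @return A validated `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 800,
                           n_modules = 4,
                           module_size = 60,
                           within_weight_mean = 0.8,
                           between_weight_mean = 0.05,
                           background_degree = 30,
                           n_terms = 2,
                           geneset_noise_frac = 0.15,
                           n_strains = 23,
                           n_haplotype_groups = 4,
                           n_locus_snps = 400,
                           n_background_snps = 600,
                           locus = list(chrom = "chr1", start = 4e7, end = 8e7),
                           n_candidate_genes = 25,
                           causal_gene_index = 13,
                           penetrance = 0.9,
                           background_rate = 0.05,
                           seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_modules = n_modules, module_size = module_size,
    within_weight_mean = within_weight_mean,
    between_weight_mean = between_weight_mean,
    background_degree = background_degree,
    n_terms = n_terms, geneset_noise_frac = geneset_noise_frac,
    n_strains = n_strains, n_haplotype_groups = n_haplotype_groups,
    n_locus_snps = n_locus_snps, n_background_snps = n_background_snps,
    locus = as_region(locus), n_candidate_genes = n_candidate_genes,
    causal_gene_index = causal_gene_index,
    penetrance = penetrance, background_rate = background_rate,
    seed = as.integer(seed)
  )
  if (cfg$module_size * cfg$n_modules > cfg$n_genes) {
    abort("module_size * n_modules must not exceed n_genes.")
  }
  if (cfg$penetrance <= cfg$background_rate) {
    abort("penetrance must exceed background_rate.")
  }
  if (cfg$n_terms > cfg$n_modules) abort("n_terms must not exceed n_modules.")
  if (cfg$causal_gene_index < 1 ||
      cfg$causal_gene_index > cfg$n_candidate_genes) {
    abort("causal_gene_index must index a candidate slot.")
  }
  if (cfg$within_weight_mean <= 0 || cfg$within_weight_mean >= 1 ||
      cfg$between_weight_mean <= 0 || cfg$between_weight_mean >= 1) {
    abort("Edge-weight means must lie in (0, 1).")
  }
  structure(cfg, class = "fixture_config")
}

gene_ids <- function(n) sprintf("gene%04d", seq_len(n))

# Beta(shape1, shape2) with the requested mean and a fixed total
# concentration, so within-module weights are tight and background weights
# are right-skewed like a thresholded network's tail.
rbeta_mean <- function(n, mean, concentration = 10) {
  rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Simulate a planted-partition weighted functional network
#'
#' Planted modules are complete subgraphs with Beta-distributed weights of
#' mean `within_weight_mean`; background edges are sparse random pairs with
#' mean weight `between_weight_mean`. Deterministic given the config seed.
#'
#' @param cfg A [fixture_config()].
#' @return List with `network` (a [functional_network]) and `truth`
#'   (tibble `gene_id`, `module` with NA for background genes).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(derive_seed(cfg$seed, 101), {
    ids <- gene_ids(cfg$n_genes)
    module_of <- rep(NA_integer_, cfg$n_genes)
    for (m in seq_len(cfg$n_modules)) {
      module_of[((m - 1) * cfg$module_size + 1):(m * cfg$module_size)] <- m
    }
    within <- purrr::map_dfr(seq_len(cfg$n_modules), function(m) {
      members <- ids[which(module_of == m)]
      pairs <- utils::combn(members, 2)
      tibble(
        from = pairs[1, ], to = pairs[2, ],
        weight = rbeta_mean(ncol(pairs), cfg$within_weight_mean)
      )
    })
    n_bg <- round(cfg$n_genes * cfg$background_degree / 2)
    i <- sample.int(cfg$n_genes, n_bg, replace = TRUE)
    j <- sample.int(cfg$n_genes, n_bg, replace = TRUE)
    keep <- i != j
    bg <- tibble(
      from = pmin(ids[i[keep]], ids[j[keep]]),
      to = pmax(ids[i[keep]], ids[j[keep]]),
      weight = rbeta_mean(sum(keep), cfg$between_weight_mean)
    )
    # background pairs duplicating a within-module edge are dropped
    wkey <- paste(pmin(within$from, within$to), pmax(within$from, within$to))
    bg <- bg[!duplicated(paste(bg$from, bg$to)) &
               !(paste(bg$from, bg$to) %in% wkey), ]
    net <- functional_network(dplyr::bind_rows(within, bg), nodes = ids)
    truth <- tibble(gene_id = ids, module = module_of)
    list(network = net, truth = truth)
  })
}

#' Simulate trait gene sets from planted modules
#'
#' Term t is the union of planted module t and a fraction
#' `geneset_noise_frac` of random non-module genes, mirroring curated trait
#' lists that mix a coherent process with unrelated genes. The causal
#' gene's module is always module 1, so term 1 covers it.
#'
#' @param cfg A [fixture_config()].
#' @param truth The `truth` tibble from [simulate_network()].
#' @return Tibble (`term`, `gene_id`).
#' @export
simulate_gene_sets <- function(cfg, truth) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(derive_seed(cfg$seed, 202), {
    non_module <- truth$gene_id[is.na(truth$module)]
    purrr::map_dfr(seq_len(cfg$n_terms), function(t) {
      core <- truth$gene_id[!is.na(truth$module) & truth$module == t]
      n_noise <- round(cfg$geneset_noise_frac * length(core))
      noise <- if (n_noise > 0) sample(non_module, n_noise) else character()
      tibble(term = sprintf("term%02d", t),
             gene_id = sort(unique(c(core, noise))))
    })
  })
}

#' Simulate an inbred strain cohort with one causal SNP
#'
#' Strains fall into haplotype groups; each SNP's strain pattern derives
#' from group-level alleles with a small strain-level flip rate, and
#' consecutive locus SNPs copy the previous pattern with high probability
#' (haplotype blocks). Background SNPs on a second chromosome induce
#' block-structured kinship. The causal SNP sits inside the causal gene's
#' body and its alternate allele raises the Bernoulli phenotype probability
#' from `background_rate` to `penetrance`. Candidate gene bodies tile the
#' locus so every gene has nearby SNPs.
#'
#' @param cfg A [fixture_config()].
#' @param truth The `truth` tibble from [simulate_network()].
#' @return List with `genotypes` (tibble, [read_genotypes()] layout),
#'   `phenotype` (tibble `strain`, `value`), `annotations` (tibble
#'   `gene_id`, `chrom`, `start`, `end`), `candidates` (character),
#'   `causal_gene`, `causal_snp`.
#' @export
simulate_cohort <- function(cfg, truth) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(derive_seed(cfg$seed, 303), {
    strains <- sprintf("strain%02d", seq_len(cfg$n_strains))
    group <- rep(seq_len(cfg$n_haplotype_groups), length.out = cfg$n_strains)
    group <- sort(group)
    flip_rate <- 0.1

    # --- candidate genes tiling the locus -------------------------------
    locus <- cfg$locus
    nc <- cfg$n_candidate_genes
    body <- floor((locus$end - locus$start) / (nc * 2))
    spacing <- floor((locus$end - locus$start - body) / max(nc - 1, 1))
    starts <- locus$start + (seq_len(nc) - 1) * spacing
    module1 <- truth$gene_id[!is.na(truth$module) & truth$module == 1]
    background <- truth$gene_id[is.na(truth$module)]
    causal_gene <- module1[1 + (cfg$causal_gene_index %% length(module1))]
    others <- sample(background, nc - 1)
    cand_ids <- character(nc)
    cand_ids[cfg$causal_gene_index] <- causal_gene
    cand_ids[-cfg$causal_gene_index] <- others
    annotations <- tibble(
      gene_id = cand_ids, chrom = locus$chrom,
      start = starts, end = starts + body
    )

    # --- genotypes -------------------------------------------------------
    draw_pattern <- function() {
      ga <- rbinom(cfg$n_haplotype_groups, 1, 0.5)
      g <- ga[group]
      flip <- rbinom(cfg$n_strains, 1, flip_rate) == 1
      g[flip] <- 1 - g[flip]
      g
    }
    sim_block <- function(n, copy_prob) {
      out <- matrix(0L, n, cfg$n_strains)
      prev <- draw_pattern()
      for (s in seq_len(n)) {
        if (s > 1 && runif(1) < copy_prob) {
          g <- prev
          flip <- rbinom(cfg$n_strains, 1, 0.02) == 1
          g[flip] <- 1 - g[flip]
        } else {
          g <- draw_pattern()
        }
        out[s, ] <- g
        prev <- g
      }
      out
    }
    locus_pos <- sort(locus$start - 1 +
                        sample.int(locus$end - locus$start + 1,
                                   cfg$n_locus_snps))
    locus_calls <- sim_block(cfg$n_locus_snps, copy_prob = 0.7)
    bg_pos <- sort(1e6 - 1 + sample.int(1.49e8, cfg$n_background_snps))
    bg_calls <- sim_block(cfg$n_background_snps, copy_prob = 0.3)

    # causal SNP: a polymorphic pattern placed inside the causal gene body
    causal_row <- which(annotations$gene_id == causal_gene)
    causal_pos <- floor((annotations$start[causal_row] +
                           annotations$end[causal_row]) / 2)
    lo <- max(2, floor(cfg$n_strains / 4))
    repeat {
      causal_calls <- draw_pattern()
      if (sum(causal_calls) >= lo && sum(causal_calls) <= cfg$n_strains - lo) break
    }
    ins <- findInterval(causal_pos, locus_pos)
    locus_pos <- append(locus_pos, causal_pos, after = ins)
    locus_calls <- rbind(
      locus_calls[seq_len(ins), , drop = FALSE],
      causal_calls,
      locus_calls[setdiff(seq_len(cfg$n_locus_snps), seq_len(ins)), ,
                  drop = FALSE]
    )
    causal_snp <- sprintf("snp_locus%05d", ins + 1)

    genotypes <- dplyr::bind_rows(
      tibble(
        snp_id = sprintf("snp_locus%05d", seq_along(locus_pos)),
        chrom = locus$chrom, pos = as.numeric(locus_pos)
      ) |> dplyr::bind_cols(as_tibble(`colnames<-`(locus_calls, strains))),
      tibble(
        snp_id = sprintf("snp_bg%05d", seq_along(bg_pos)),
        chrom = "chr2", pos = as.numeric(bg_pos)
      ) |> dplyr::bind_cols(as_tibble(`colnames<-`(bg_calls, strains)))
    )

    # --- phenotype -------------------------------------------------------
    prob <- ifelse(causal_calls == 1, cfg$penetrance, cfg$background_rate)
    phenotype <- tibble(strain = strains, value = rbinom(cfg$n_strains, 1, prob))

    list(
      genotypes = genotypes, phenotype = phenotype,
      annotations = annotations,
      candidates = cand_ids, causal_gene = causal_gene,
      causal_snp = causal_snp
    )
  })
}

#' Simulate a complete study fixture
#'
#' @param cfg A [fixture_config()].
#' @return List with `network`, `truth` (module membership + causal
#'   gene/SNP), `gene_sets`, `genotypes`, `phenotype`, `annotations`,
#'   `config`.
#' @export
simulate_fixture <- function(cfg = fixture_config()) {
  net <- simulate_network(cfg)
  sets <- simulate_gene_sets(cfg, net$truth)
  cohort <- simulate_cohort(cfg, net$truth)
  list(
    network = net$network,
    truth = list(
      module_membership = net$truth,
      causal_gene = cohort$causal_gene,
      causal_snp = cohort$causal_snp
    ),
    gene_sets = sets,
    genotypes = cohort$genotypes,
    phenotype = cohort$phenotype,
    annotations = cohort$annotations,
    config = cfg
  )
}

#' Write a fixture to disk in the formats the loaders consume
#'
#' Writes `network.tsv` (edge list), `genesets/<term>.txt`,
#' `annotations.tsv`, `genotypes.tsv`, `phenotype.tsv`, `truth.tsv`, and a
#' ready-to-run `config.yaml` for [run_pipeline()].
#'
#' @param fix A fixture from [simulate_fixture()].
#' @param dir Output directory.
#' @param ensemble Named list of ensemble settings recorded in the written
#'   pipeline config (defaults: `n_runs` 10, `folds` 10, `max_size` 400).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir,
                          ensemble = list(n_runs = 10, folds = 10,
                                          max_size = 400)) {
  dir.create(file.path(dir, "genesets"), recursive = TRUE,
             showWarnings = FALSE)
  write_edge_list(fix$network, file.path(dir, "network.tsv"))
  for (tm in unique(fix$gene_sets$term)) {
    writeLines(
      fix$gene_sets$gene_id[fix$gene_sets$term == tm],
      file.path(dir, "genesets", paste0(tm, ".txt"))
    )
  }
  readr::write_tsv(fix$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(fix$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(fix$phenotype, file.path(dir, "phenotype.tsv"))
  readr::write_tsv(
    dplyr::mutate(
      fix$truth$module_membership,
      causal_gene = .data$gene_id == fix$truth$causal_gene
    ),
    file.path(dir, "truth.tsv")
  )
  cfg <- list(
    network = file.path(dir, "network.tsv"),
    gene_sets_dir = file.path(dir, "genesets"),
    annotations = file.path(dir, "annotations.tsv"),
    annotations_format = "tsv",
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    locus = fix$config$locus,
    ensemble = ensemble,
    alpha = 0.05,
    seed = fix$config$seed,
    out_dir = file.path(dir, "results")
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
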