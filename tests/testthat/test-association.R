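make_geno <- function(calls, chrom = "chr1", pos = NULL,
                      strains = paste0("s", seq_len(ncol(calls)))) {
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 1000
  dplyr::bind_cols(
    tibble::tibble(
      snp_id = sprintf("snp%04d", seq_len(nrow(calls))),
      chrom = chrom, pos = as.numeric(pos)
    ),
    tibble::as_tibble(`colnames<-`(calls, strains))
  )
}

test_that("IBS kinship hits its extremes and ignores excluded regions", {
  calls <- cbind(a = c(0, 1, 0, 1), b = c(0, 1, 0, 1), c = c(1, 0, 1, 0))
  geno <- make_geno(calls, strains = c("a", "b", "c"))
  K <- suppressMessages(compute_kinship(geno))
  expect_equal(K["a", "b"], 1)
  expect_equal(K["a", "c"], 0)
  expect_equal(diag(unclass(K)), c(a = 1, b = 1, c = 1))
  expect_equal(unclass(K), t(unclass(K)))

  # editing genotypes inside the excluded region leaves K unchanged
  region <- list(chrom = "chr1", start = 1, end = 2500)
  K1 <- suppressMessages(compute_kinship(geno, region))
  geno2 <- geno
  geno2$a[1:2] <- c(1, 0)
  K2 <- suppressMessages(compute_kinship(geno2, region))
  expect_identical(K1, K2)
  expect_error(
    suppressMessages(compute_kinship(geno, list(chrom = "chr1", start = 0,
                                                end = 1e9))),
    "No SNPs remain"
  )
})

test_that("kinship is invariant to SNP order and handles missing calls", {
  set.seed(6)
  calls <- matrix(rbinom(200, 1, 0.5), 50, 4)
  calls[sample(200, 15)] <- NA
  geno <- make_geno(calls)
  K1 <- suppressMessages(compute_kinship(geno))
  K2 <- suppressMessages(compute_kinship(geno[sample(50), ]))
  expect_equal(unclass(K1), unclass(K2))
  calls_bad <- calls
  calls_bad[, 2] <- NA
  expect_error(suppressMessages(compute_kinship(make_geno(calls_bad))),
               "all-missing")
})

test_that("with identity kinship the ML fit equals the OLS likelihood", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(15:40, 1)
    y <- rnorm(n)
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    K <- diag(n)
    fit <- lmm_ml_fit(y, X, K)
    r <- residuals(stats::lm.fit(X, y))
    ols_ll <- -n / 2 * (log(2 * pi) + log(sum(r^2) / n) + 1)
    expect_lt(abs(fit$loglik - ols_ll), 1e-6)
  }
  expect_error(lmm_ml_fit(rnorm(10), cbind(1, rep(2, 10)), diag(10)),
               "singular")
  expect_error(lmm_ml_fit(c(rnorm(9), NA), cbind(rep(1, 10)), diag(10)),
               "non-finite")
})

test_that("degenerate constant phenotypes still return a finite loglik", {
  fit <- lmm_ml_fit(rep(1, 12), matrix(1, 12, 1), diag(12))
  expect_true(is.finite(fit$loglik))
})

test_that("the variance ratio is recovered in simulation", {
  set.seed(8)
  n <- 200
  grp <- rep(1:10, each = 20)
  K <- 0.6 * outer(grp, grp, "==") + 0.4 * diag(n)
  diag(K) <- 1
  L <- chol(K)
  X <- matrix(1, n, 1)
  deltas <- replicate(100, {
    y <- drop(t(L) %*% rnorm(n)) + rnorm(n)  # sigma_g2 = sigma_e2 = 1
    lmm_ml_fit(y, X, K)$delta
  })
  expect_gte(stats::median(deltas), 0.5)
  expect_lte(stats::median(deltas), 2)
})

test_that("scan p-values match the OLS chi-square oracle when K = I", {
  set.seed(17)
  n <- 20
  strains <- paste0("s", 1:n)
  K <- diag(n); dimnames(K) <- list(strains, strains)
  ols_lrt_p <- function(y, g) {
    ll <- function(X) {
      r <- residuals(stats::lm.fit(X, y))
      -n / 2 * (log(2 * pi) + log(sum(r^2) / n) + 1)
    }
    lrt <- 2 * (ll(cbind(1, g)) - ll(matrix(1, n, 1)))
    pchisq(max(lrt, 0), 1, lower.tail = FALSE)
  }
  for (i in 1:8) {
    calls <- matrix(rbinom(5 * n, 1, 0.5), 5, n)
    y <- rnorm(n)
    sc <- suppressMessages(snp_scan(
      make_geno(calls, strains = strains),
      tibble::tibble(strain = strains, value = y), K
    ))
    oracle <- apply(calls, 1, function(g) ols_lrt_p(y, g))
    polym <- apply(calls, 1, function(g) min(sum(g), n - sum(g)) > 0)
    expect_equal(sc$p_value[polym], unname(oracle[polym]), tolerance = 1e-6)
  }

  # a SNP perfectly tracking a strong effect is highly significant
  g <- rep(c(0, 1), each = n / 2)
  y <- 2 * g + rnorm(n, sd = 0.5)
  sc <- suppressMessages(snp_scan(
    make_geno(matrix(g, 1), strains = strains),
    tibble::tibble(strain = strains, value = y), K
  ))
  expect_lt(sc$p_value[1], 0.001)
})

test_that("monomorphic and NA-bearing SNPs are flagged or dropped", {
  n <- 10
  strains <- paste0("s", 1:n)
  K <- diag(n); dimnames(K) <- list(strains, strains)
  calls <- rbind(rep(1, n), rbinom(n, 1, 0.5), c(NA, rbinom(n - 1, 1, 0.5)))
  calls[2, 1:5] <- 1; calls[2, 6:10] <- 0
  sc <- suppressMessages(snp_scan(
    make_geno(calls, strains = strains),
    tibble::tibble(strain = strains, value = rnorm(n)), K
  ))
  expect_equal(nrow(sc), 2)  # NA SNP dropped
  expect_equal(attr(sc, "n_dropped_na"), 1)
  expect_equal(sc$flag[1], "monomorphic")
  expect_equal(sc$p_value[1], 1)
})

test_that("Bonferroni thresholds reproduce the published arithmetic", {
  expect_equal(signif(bonferroni_threshold(0.05, 13598), 3), 3.68e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 15302), 3), 3.27e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("SNPs are assigned to the nearest gene within 1 Mb", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(1e6, 2e6), end = c(1.2e6, 2.3e6)
  )
  scan <- tibble::tibble(
    snp_id = paste0("s", 1:5), chrom = c(rep("chr1", 4), "chr9"),
    pos = c(1.1e6,   # inside gA
            1.6e6,   # 0.4 Mb from both bodies: tie broken to smaller start
            4.0e6,   # 1.7 Mb from gB: unassigned
            2.4e6,   # 0.1 Mb past gB
            1.1e6),  # wrong chromosome
    p_value = c(1e-4, 1e-6, 1e-10, 1e-2, 1e-8)
  )
  res <- suppressMessages(assign_snps_to_genes(scan, genes))
  asn <- attr(res, "assignments")
  expect_equal(asn$gene_id, c("gA", "gA", NA, "gB", NA))
  expect_equal(res$max_neglog10p[res$gene_id == "gA"], 6)
  expect_equal(res$max_neglog10p[res$gene_id == "gB"], 2)
  expect_equal(res$n_snps, c(2, 1))

  # gene with no assigned SNP scores 0
  res2 <- suppressMessages(assign_snps_to_genes(
    scan[3, ], genes
  ))
  expect_equal(res2$max_neglog10p, c(0, 0))
})

test_that("precomputed p-value tables round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    snp_id = "s1", chrom = "chr1", pos = 100, p = 0.01
  ), path)
  sc <- read_snp_pvalues(path)
  expect_s3_class(sc, "assoc_scan")
  expect_equal(sc$p_value, 0.01)
  readr::write_tsv(tibble::tibble(
    snp_id = "s1", chrom = "chr1", pos = 100, p = 0
  ), path)
  expect_error(read_snp_pvalues(path), "\\(0, 1\\]")
})
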