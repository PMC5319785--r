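test_that("hwe_exact_p: canonical configurations and symmetry", {
  # (25,50,25) is the most probable configuration given its allele counts
  expect_gt(hwe_exact_p(25, 50, 25), 0.99)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-20)
  # allele-label symmetry
  for (cnt in list(c(10, 5, 3), c(0, 7, 2), c(40, 12, 1))) {
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 hwe_exact_p(cnt[3], cnt[2], cnt[1]))
  }
  expect_error(hwe_exact_p(-1, 0, 1), ">= 0")
  expect_error(hwe_exact_p(0, 0, 0), "not all")
})

test_that("hwe_exact_p equals the recurrence oracle on assorted counts", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(1:150, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_p(nAA, nAa, naa), oracle_hwe_p(nAA, nAa, naa),
                 tolerance = 1e-9)
  }
})

test_that("qc_filter applies the published thresholds", {
  set.seed(41)
  n <- 200; m <- 100
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  d[, 2] <- 0L; d[2:17, 2] <- 1L          # MAF 0.04: fails >5%
  d[2:3, 3] <- NA                         # call rate 197/199: fails >99%
  d[, 4] <- rep(c(0L, 2L), each = n / 2)  # no hets: fails HWE
  d[1, ] <- NA                            # sample call rate 0: removed
  gm <- genotype_matrix(sprintf("s%03d", 1:n),
                        data.frame(id = paste0("v", 1:m), chrom = 1L,
                                   pos = 1:m * 100L, ref = "A", alt = "C"), d)
  res <- qc_filter(gm, controls = rep(TRUE, n))
  expect_equal(res$report$samples_removed, "s001")
  expect_equal(res$report$snps_removed_maf, "v2")
  expect_equal(res$report$snps_removed_callrate, "v3")
  expect_equal(res$report$snps_removed_hwe, "v4")
  expect_equal(ncol(res$genotypes$dosage), m - 3L)
  expect_equal(length(res$genotypes$sample_ids), n - 1L)
  expect_error(qc_filter(gm, maf_min = 0.999, controls = rep(TRUE, n)),
               "no SNPs")
})

test_that("ensure_minor_coded flips major-coded SNPs and flags them", {
  d <- cbind(rbinom(100, 2, 0.9), rbinom(100, 2, 0.2))
  gm <- genotype_matrix(sprintf("s%03d", 1:100),
                        data.frame(id = c("hi", "lo"), chrom = 1L,
                                   pos = c(1L, 2L), ref = "A", alt = "C"), d)
  out <- ensure_minor_coded(gm)
  expect_equal(out$snps$flipped, c(TRUE, FALSE))
  expect_equal(unname(out$dosage[, 1]), unname(2L - d[, 1]))
  expect_equal(out$snps$ref[1], "C")
  expect_lte(mean(out$dosage[, 1]) / 2, 0.5)
})

test_that("ancestry_pca: orthonormal scores, sign convention, degenerate input", {
  set.seed(19)
  d <- matrix(rbinom(50 * 80, 2, 0.3), 50, 80)
  pcs <- ancestry_pca(d, 3)
  expect_equal(crossprod(pcs), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # monomorphic SNPs are skipped with a warning
  d2 <- cbind(d, 0L)
  expect_warning(ancestry_pca(d2, 2), "monomorphic")
  # identical samples carry no variation
  d3 <- matrix(rep(rbinom(30, 2, 0.4), 10), nrow = 10, byrow = TRUE)
  expect_error(suppressWarnings(ancestry_pca(d3, 1)), "no variation|no polymorphic")
  # missing dosages are mean-imputed, not dropped
  d4 <- d; d4[sample(length(d4), 100)] <- NA
  expect_silent(pcs4 <- ancestry_pca(d4, 2))
  expect_equal(dim(pcs4), c(50, 2))
})

test_that("strata_guard removes exactly the one-sided strata", {
  status <- c(rep("case", 12), rep("control", 8))
  strata <- data.frame(site = c(rep("A", 10), rep("B", 10)),
                       platform = "p1")
  # site A: 10 cases, 0 controls -> removed; site B: 2 cases, 8 controls
  sg <- strata_guard(status, strata)
  expect_equal(sum(sg$removed), 10L)
  expect_true(all(sg$removed[1:10]))
  tab <- sg$table
  expect_equal(tab$removed, c(TRUE, FALSE))
  # all-mixed strata: nothing removed
  sg2 <- strata_guard(c("case", "control", "case", "control"),
                      data.frame(site = c("A", "A", "B", "B")))
  expect_equal(sum(sg2$removed), 0L)
  # postcondition: every remaining stratum has both labels
  keep <- !sg$removed
  k <- table(strata$site[keep], status[keep])
  expect_true(all(k > 0))
})

test_that("logistic_assoc reproduces the closed-form 2x2 odds ratio", {
  # cases 30 exposed / 70 not; controls 10 exposed / 90 not
  dosage <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  status <- rep(c("case", "control"), each = 100)
  res <- logistic_assoc(dosage, status)
  oracle <- oracle_2x2(30, 70, 10, 90)
  expect_true(res$converged)
  expect_equal(res$or, oracle$or, tolerance = 1e-6)
  expect_equal(res$or, 3.857143, tolerance = 1e-6)
  expect_equal(res$ci_low, oracle$ci[1], tolerance = 1e-6)
  expect_equal(res$ci_high, oracle$ci[2], tolerance = 1e-6)
  # tail probabilities amplify the Wald z's numerical error ~z-fold
  expect_equal(res$p, oracle$p, tolerance = 1e-4)
})

test_that("logistic_assoc flags separation, constant dosage, empty groups", {
  status <- rep(c("case", "control"), each = 50)
  sep <- c(rep(2, 50), rep(0, 50))           # perfect separation
  res <- logistic_assoc(sep, status)
  expect_false(res$converged)
  expect_true(is.na(res$or))
  const <- rep(1, 100)                        # degenerate design
  expect_false(logistic_assoc(const, status)$converged)
  res0 <- logistic_assoc(rep(c(0, 1), 50), rep("control", 100))
  expect_false(res0$converged)                # no cases at all
  # missing dosage drops samples for this SNP only
  d <- rep(c(0, 1), 50); d[1:10] <- NA
  expect_equal(logistic_assoc(d, status)$n_used, 90)
})

test_that("logistic_assoc null p-values are approximately uniform", {
  set.seed(23)
  status <- rep(c("case", "control"), each = 150)
  p <- replicate(400, logistic_assoc(rbinom(300, 2, 0.3), status)$p)
  # occasional duplicate genotype tables tie p-values; ties only trigger a
  # ks.test warning, they do not bias the statistic
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  expect_true(mean(p < 0.05) > 0.02 && mean(p < 0.05) < 0.09)
})

test_that("lambda_gc: uniform grid, monotonicity, bounds check", {
  p <- (1:9999) / 10000
  expect_equal(lambda_gc(p), 1, tolerance = 1e-3)
  expect_gt(lambda_gc(p / 2), lambda_gc(p))
  expect_error(lambda_gc(c(0.5, 0)), "> 0")
  expect_error(lambda_gc(numeric(0)))
})

test_that("plot_data tables have the documented shape", {
  res <- data.frame(snp = c("a", "b", "c"), chrom = c(1L, 1L, 2L),
                    pos = c(100L, 200L, 50L), p = c(0.5, 0.01, 0.2),
                    beta = 0, or = 1, ci_low = 1, ci_high = 1,
                    n_used = 10, converged = TRUE)
  pd <- plot_data(res)
  expect_equal(nrow(pd$manhattan), 3L)
  expect_equal(nrow(pd$qq), 3L)
  expect_equal(pd$qq$expected, -log10((1:3 - 0.5) / 3))
  expect_equal(pd$qq$observed, sort(-log10(res$p), decreasing = TRUE))
  # chromosome 2 positions are offset beyond chromosome 1
  expect_true(pd$manhattan$genome_pos[3] > max(pd$manhattan$genome_pos[1:2]))
  one <- plot_data(res[1, ])
  expect_equal(nrow(one$manhattan), 1L)
})

test_that("lookup_known reports availability, significance, concordance", {
  res <- data.frame(snp = c("rs1", "rs2", "rs3"), chrom = 1L, pos = 1:3,
                    beta = c(0.7, -0.4, 0.01), or = exp(c(0.7, -0.4, 0.01)),
                    ci_low = 1, ci_high = 1, p = c(1e-5, 2e-4, 0.8),
                    n_used = 100, converged = TRUE)
  catalog <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs_absent"),
                        direction = c("+", "+", "-", "+"))
  lk <- lookup_known(res, catalog, alpha = 0.001)
  expect_equal(lk$available, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(lk$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(lk$concordant, c(TRUE, FALSE, FALSE, FALSE))
  # alpha = 1: every available SNP is significant
  expect_equal(lookup_known(res, catalog, alpha = 1)$significant,
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("run_gwas results are invariant to sample permutation", {
  spec <- geno_sim_spec(n_snps = 40, maf_range = c(0.2, 0.4),
                        fst_like_divergence = 0.05, missing_rate = 0.005,
                        causal = data.frame(snp = 1, or = 1.8), seed = 33)
  labels <- rep(c("case", "control"), 150)
  g <- simulate_genotypes(spec, labels)
  set.seed(34)
  cov <- data.frame(sex = sample(c("male", "female"), 300, replace = TRUE),
                    site = rep(c("A", "B"), each = 150),
                    platform = "p1")
  r1 <- run_gwas(g$genotypes, labels, cov, k_pcs = 2)
  perm <- sample(300)
  gp <- genotype_matrix(g$genotypes$sample_ids[perm], g$genotypes$snps,
                        g$genotypes$dosage[perm, ])
  r2 <- run_gwas(gp, labels[perm], cov[perm, ], k_pcs = 2)
  expect_equal(r1$results, r2$results, tolerance = 1e-8)
  expect_equal(r1$lambda_gc, r2$lambda_gc, tolerance = 1e-8)
})

test_that("adding PCs under planted structure deflates lambda", {
  spec <- geno_sim_spec(n_snps = 250, maf_range = c(0.1, 0.4),
                        fst_like_divergence = 0.1, missing_rate = 0, seed = 27)
  n <- 500
  set.seed(27)
  subpop <- rep(1:2, each = n / 2)
  # confounding: case probability differs by subpopulation
  labels <- ifelse(runif(n) < ifelse(subpop == 1, 0.65, 0.35),
                   "case", "control")
  g <- simulate_genotypes(spec, labels, subpop = subpop)
  r0 <- run_gwas(g$genotypes, labels, k_pcs = 0)
  r2 <- run_gwas(g$genotypes, labels, k_pcs = 2)
  expect_gt(r0$lambda_gc, r2$lambda_gc)
})
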