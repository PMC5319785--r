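as_case01 <- function(status) {
  if (is.numeric(status)) {
    if (!all(status %in% 0:1)) stop2("numeric phenotype must be 0/1")
    return(as.integer(status))
  }
  s <- as.character(status)
  s[s %in% c("CASE_CONTROLLED", "CASE_UNCONTROLLED")] <- "case"
  s[s == "CONTROL"] <- "control"
  if (!all(s %in% c("case", "control")))
    stop2("phenotype must be 'case'/'control' (or CASE_*/CONTROL statuses)")
  as.integer(s == "case")
}

#' Force the counted (alt) allele to be the minor allele
#'
#' SNPs whose alt-allele frequency exceeds 0.5 have their dosages flipped to
#' `2 - dosage` and ref/alt swapped; a `flipped` flag is recorded in the SNP
#' table.
#'
#' @param gm a [genotype_matrix()].
#' @return A [genotype_matrix()] with an added `snps$flipped` column.
#' @export
ensure_minor_coded <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- colMeans(gm$dosage, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    gm$dosage[, flip] <- 2L - gm$dosage[, flip]
    tmp <- gm$snps$ref[flip]
    gm$snps$ref[flip] <- gm$snps$alt[flip]
    gm$snps$alt[flip] <- tmp
  }
  gm$snps$flipped <- unname(flip)
  gm
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the allele counts, the p-value is the total
#' probability of heterozygote counts no more probable than the observed one
#' under the HWE sampling distribution.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#' @return Two-sided exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop2("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop2("genotype counts must not all be zero")
  nA <- 2L * n_AA + n_Aa
  d <- hwe_het_log_probs(nA, n)
  obs <- match(n_Aa, d$het)
  # tolerance guards ties against floating-point jitter
  sum(exp(d$logp[d$logp <= d$logp[obs] + 1e-10]))
}

# log P(het = h | allele count nA, n genotypes) over all attainable h
hwe_het_log_probs <- function(nA, n) {
  na <- 2L * n - nA
  het <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  list(het = het, logp = logp)
}

#' Genotype quality control
#'
#' Sample call-rate filtering is applied first; SNP filters (call rate,
#' minor allele frequency, HWE exact test in controls) are then computed on
#' the remaining samples. All thresholds are strict: a sample is kept when
#' its call rate exceeds `sample_cr_min`, a SNP when its call rate exceeds
#' `snp_cr_min` and its MAF exceeds `maf_min`, and removed when its
#' HWE p-value falls below `hwe_p_min`.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_cr_min,snp_cr_min,maf_min,hwe_p_min thresholds in [0, 1].
#' @param controls optional logical vector (aligned with `gm$sample_ids`)
#'   marking controls; the HWE test is computed in controls only, the
#'   conventional practice since true associations distort HWE in cases.
#'   When omitted, all samples are used and a message is emitted.
#' @return List with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (class `qc_report`).
#' @export
qc_filter <- function(gm, sample_cr_min = 0.98, snp_cr_min = 0.99,
                      maf_min = 0.05, hwe_p_min = 1e-6, controls = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"),
            sample_cr_min >= 0, sample_cr_min <= 1,
            snp_cr_min >= 0, snp_cr_min <= 1, maf_min >= 0, maf_min <= 1)
  d <- gm$dosage
  cr_sample <- rowMeans(!is.na(d))
  drop_sample <- cr_sample <= sample_cr_min
  if (all(drop_sample)) stop2("no samples pass the call-rate filter")
  if (!is.null(controls)) {
    stopifnot(length(controls) == length(gm$sample_ids))
    controls <- controls[!drop_sample]
  } else {
    message("qc_filter: no control labels supplied; HWE computed in all samples")
    controls <- rep(TRUE, sum(!drop_sample))
  }
  d <- d[!drop_sample, , drop = FALSE]

  cr_snp <- colMeans(!is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  dc <- d[controls, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(dc)), function(j) {
    x <- dc[, j]
    cnt <- c(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
             sum(x == 2L, na.rm = TRUE))
    if (sum(cnt) == 0L) return(1)
    hwe_exact_p(cnt[1L], cnt[2L], cnt[3L])
  }, numeric(1))

  fail_cr <- cr_snp <= snp_cr_min
  fail_maf <- !fail_cr & (is.na(maf) | maf <= maf_min)
  fail_hwe <- !fail_cr & !fail_maf & hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) stop2("no SNPs pass QC")

  report <- structure(list(
    n_samples_in = length(gm$sample_ids), n_snps_in = ncol(gm$dosage),
    samples_removed = gm$sample_ids[drop_sample],
    snps_removed_callrate = gm$snps$id[fail_cr],
    snps_removed_maf = gm$snps$id[fail_maf],
    snps_removed_hwe = gm$snps$id[fail_hwe],
    thresholds = c(sample_cr_min = sample_cr_min, snp_cr_min = snp_cr_min,
                   maf_min = maf_min, hwe_p_min = hwe_p_min)),
    class = "qc_report")
  gm2 <- genotype_matrix(gm$sample_ids[!drop_sample],
                         gm$snps[keep, , drop = FALSE],
                         d[, keep, drop = FALSE])
  list(genotypes = gm2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples, %d SNPs in\n", x$n_samples_in, x$n_snps_in))
  cat(sprintf("  samples removed (call rate): %d\n", length(x$samples_removed)))
  cat(sprintf("  SNPs removed: call rate %d, MAF %d, HWE %d\n",
              length(x$snps_removed_callrate), length(x$snps_removed_maf),
              length(x$snps_removed_hwe)))
  invisible(x)
}

#' Ancestry principal components from genotypes
#'
#' EIGENSTRAT-style PCA: each SNP column is centered by twice its allele
#' frequency and scaled by the binomial standard deviation
#' `sqrt(2 p (1-p))`; missing dosages are replaced by the column mean before
#' scaling; monomorphic SNPs are skipped with a warning. Sample scores are
#' the top-k left singular vectors (orthonormal columns), with each
#' component's sign fixed so its largest-magnitude SNP loading is positive.
#'
#' @param gm a [genotype_matrix()] (or a bare dosage matrix).
#' @param k number of components (1 to min(dim) - 1).
#' @return Matrix of sample scores, samples x k.
#' @export
ancestry_pca <- function(gm, k) {
  d <- if (inherits(gm, "genotype_matrix")) gm$dosage else as.matrix(gm)
  stopifnot(k >= 1, k <= min(dim(d)) - 1)
  p <- colMeans(d, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) {
    warning(sprintf("ancestry_pca: skipping %d monomorphic SNP(s)", sum(mono)))
    d <- d[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(d) == 0L) stop2("no polymorphic SNPs for PCA")
  x <- sweep(d, 2L, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2L, sqrt(2 * p * (1 - p)), "/")
  s <- svd(x, nu = k, nv = k)
  if (s$d[1L] < sqrt(.Machine$double.eps))
    stop2("ancestry_pca: genotype matrix has no variation")
  scores <- s$u
  for (j in seq_len(k)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(d)
  scores
}

#' Remove samples in case-only or control-only strata
#'
#' Cross-classifies samples by the given stratum columns (by default study
#' site and genotyping platform) and removes every sample belonging to a
#' stratum that contains only cases or only controls — the strata that
#' prevent an adjusted logistic model from converging.
#'
#' @param status case/control labels (see [logistic_assoc()]).
#' @param strata data.frame of stratum columns, rows aligned with `status`.
#' @return List with `removed` (logical vector) and `table` (per-stratum
#'   case/control counts and removal flags).
#' @export
strata_guard <- function(status, strata) {
  y <- as_case01(status)
  stopifnot(is.data.frame(strata), nrow(strata) == length(y))
  key <- do.call(paste, c(strata, sep = "/"))
  tab <- data.frame(stratum = sort(unique(key)), stringsAsFactors = FALSE)
  tab$n_case <- vapply(tab$stratum, function(s) sum(y == 1L & key == s), integer(1))
  tab$n_control <- vapply(tab$stratum, function(s) sum(y == 0L & key == s), integer(1))
  tab$removed <- tab$n_case == 0L | tab$n_control == 0L
  removed <- key %in% tab$stratum[tab$removed]
  rownames(tab) <- NULL
  list(removed = removed, table = tab)
}

# IRLS logistic fit with Wald inference for the dosage term.
# Returns NA statistics with converged = FALSE on separation, collinearity,
# or failure to converge within 25 iterations.
fit_logistic_dosage <- function(dosage, y, covar = NULL) {
  x <- cbind(`(Intercept)` = 1, dosage = dosage, covar)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 25)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- ncol(x)
  if (fit$rank < p || !fit$converged)
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cov))
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
  se_all <- rep(NA_real_, p)
  se_all[piv] <- sqrt(diag(cov))
  beta <- unname(fit$coefficients["dosage"])
  se <- se_all[2L]
  # absurd per-allele log-odds or standard error signals (quasi-)separation
  converged <- !sep && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15 && se < 20
  if (!converged) return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
  list(beta = beta, se = se, converged = TRUE)
}

#' Additive-model logistic association for one SNP
#'
#' Maximum-likelihood logistic regression of case status on allele dosage
#' (0/1/2) plus covariates; per-allele log-odds with Wald standard error,
#' 95% CI and two-sided p-value. Samples with missing dosage (or missing
#' covariates) are dropped for this SNP. Separation, collinearity (including
#' constant dosage) and non-convergence yield a flagged result with absent
#' statistics, never an exception.
#'
#' @param dosage numeric vector of dosages (NA = missing).
#' @param status case/control labels: `"case"`/`"control"`, the phenotyper's
#'   statuses, or a 0/1 numeric vector (1 = case).
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return One-row data.frame: `beta`, `or`, `ci_low`, `ci_high`, `p`,
#'   `n_used`, `converged`.
#' @export
logistic_assoc <- function(dosage, status, covariates = NULL) {
  y <- as_case01(status)
  stopifnot(length(dosage) == length(y))
  covar <- if (!is.null(covariates)) as.matrix(covariates)
  keep <- !is.na(dosage) & !is.na(y)
  if (!is.null(covar)) keep <- keep & stats::complete.cases(covar)
  res <- data.frame(beta = NA_real_, or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_,
                    n_used = sum(keep), converged = FALSE)
  if (sum(y[keep] == 1L) == 0L || sum(y[keep] == 0L) == 0L) return(res)
  fit <- fit_logistic_dosage(dosage[keep], y[keep],
                             if (!is.null(covar)) covar[keep, , drop = FALSE])
  if (!fit$converged) return(res)
  z <- stats::qnorm(0.975)
  res$beta <- fit$beta
  res$or <- exp(fit$beta)
  res$ci_low <- exp(fit$beta - z * fit$se)
  res$ci_high <- exp(fit$beta + z * fit$se)
  res$p <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
  res$converged <- TRUE
  res
}

build_design <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0L) return(NULL)
  df <- as.data.frame(covariates)
  cols <- list()
  for (nm in names(df)) {
    x <- df[[nm]]
    if (nm == "sex") {
      cols[[nm]] <- as.integer(as.character(x) == "female")
    } else if (is.numeric(x)) {
      cols[[nm]] <- x
    } else {
      x <- factor(x)
      if (nlevels(x) < 2L) next  # constant factor carries no information
      mm <- stats::model.matrix(~ x)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(x)[-1L])
      for (cc in colnames(mm)) cols[[cc]] <- mm[, cc]
    }
  }
  if (length(cols) == 0L) return(NULL)
  do.call(cbind, cols)
}

#' Run the full association scan
#'
#' Pipeline: force minor-allele coding, genotype QC ([qc_filter()]), removal
#' of case-only/control-only strata ([strata_guard()]), ancestry PCA
#' ([ancestry_pca()]), then per-SNP additive logistic regression adjusted
#' for the supplied covariates (sex, decade of birth, median BMI, platform)
#' plus `k_pcs` principal components. Results are ordered by
#' (chrom, pos, id).
#'
#' @param gm a [genotype_matrix()].
#' @param status per-sample case/control labels (see [logistic_assoc()]).
#' @param covariates optional data.frame aligned with samples; columns named
#'   in `strata_cols` are used for the stratum guard (not regression),
#'   `sex` is coded female = 1, character columns become factor dummies.
#' @param k_pcs number of ancestry PCs to include (0 = none).
#' @param strata_cols columns of `covariates` defining convergence-guard
#'   strata; silently reduced to those present.
#' @param sample_cr_min,snp_cr_min,maf_min,hwe_p_min QC thresholds, see
#'   [qc_filter()].
#' @return List of class `gwas_result`: `results` (per-SNP data.frame with
#'   `snp`, `chrom`, `pos`, `n_used`, `beta`, `or`, `ci_low`, `ci_high`,
#'   `p`, `converged`), `qc` (the [qc_filter()] report), `strata` (the
#'   [strata_guard()] table), `pcs` (score matrix), and `lambda_gc`.
#' @export
run_gwas <- function(gm, status, covariates = NULL, k_pcs = 10,
                     strata_cols = c("site", "platform"),
                     sample_cr_min = 0.98, snp_cr_min = 0.99,
                     maf_min = 0.05, hwe_p_min = 1e-6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  status <- as_case01(status)
  stopifnot(length(status) == length(gm$sample_ids))
  if (!is.null(covariates)) stopifnot(nrow(covariates) == length(status))

  gm <- ensure_minor_coded(gm)
  qc <- qc_filter(gm, sample_cr_min, snp_cr_min, maf_min, hwe_p_min,
                  controls = status == 0L)
  keep <- gm$sample_ids %in% qc$genotypes$sample_ids
  status <- status[keep]
  covariates <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
  gm <- qc$genotypes

  strata_cols <- intersect(strata_cols, colnames(covariates))
  strata_tab <- NULL
  if (length(strata_cols)) {
    sg <- strata_guard(status, covariates[strata_cols])
    strata_tab <- sg$table
    if (any(sg$removed)) {
      gm <- genotype_matrix(gm$sample_ids[!sg$removed], gm$snps,
                            gm$dosage[!sg$removed, , drop = FALSE])
      status <- status[!sg$removed]
      covariates <- covariates[!sg$removed, , drop = FALSE]
    }
  }

  pcs <- NULL
  if (k_pcs > 0) pcs <- ancestry_pca(gm, k_pcs)
  design_cov <- if (!is.null(covariates))
    covariates[setdiff(colnames(covariates), strata_cols)]
  design <- cbind(build_design(design_cov), pcs)

  rows <- lapply(seq_len(ncol(gm$dosage)), function(j)
    logistic_assoc(gm$dosage[, j], status, design))
  results <- cbind(data.frame(snp = gm$snps$id, chrom = gm$snps$chrom,
                              pos = gm$snps$pos, stringsAsFactors = FALSE),
                   do.call(rbind, rows))
  results <- results[order(results$chrom, results$pos, results$snp), ,
                     drop = FALSE]
  rownames(results) <- NULL
  lam <- lambda_gc(results$p[results$converged & !is.na(results$p)])
  structure(list(results = results, qc = qc$report, strata = strata_tab,
                 pcs = pcs, lambda_gc = lam, n_samples = length(status)),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("<gwas_result> %d SNPs x %d samples, lambda_GC = %.3f\n",
              nrow(x$results), x$n_samples, x$lambda_gc))
  top <- x$results[order(x$results$p), ][1L, ]
  cat(sprintf("  top hit: %s (chr%s:%d) OR %.3f, p = %.3g\n", top$snp,
              top$chrom, top$pos, top$or, top$p))
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' Median of the 1-df chi-square statistics implied by the p-values, divided
#' by the null median 0.4549.
#'
#' @param pvals p-values in (0, 1].
#' @return Lambda (about 1 under a well-calibrated null).
#' @export
lambda_gc <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  stopifnot(length(pvals) > 0, all(pvals > 0 & pvals <= 1))
  stats::median(stats::qchisq(pvals, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Manhattan and QQ plot tables
#'
#' @param results the `results` data.frame of a [run_gwas()] object.
#' @return List with `manhattan` (snp, chrom, pos, cumulative `genome_pos`,
#'   `neglog10p`) and `qq` (sorted observed vs expected -log10 p, expected
#'   quantile `(i - 0.5) / n`).
#' @export
plot_data <- function(results) {
  if (inherits(results, "gwas_result")) results <- results$results
  stopifnot(nrow(results) > 0)
  res <- results[!is.na(results$p), , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  offsets <- c(0, cumsum(tapply(res$pos, factor(res$chrom), max)))
  names(offsets) <- NULL
  chrom_idx <- as.integer(factor(res$chrom))
  manhattan <- data.frame(snp = res$snp, chrom = res$chrom, pos = res$pos,
                          genome_pos = res$pos + offsets[chrom_idx],
                          neglog10p = -log10(res$p), stringsAsFactors = FALSE)
  obs <- sort(-log10(res$p), decreasing = TRUE)
  n <- length(obs)
  qq <- data.frame(expected = -log10((seq_len(n) - 0.5) / n), observed = obs)
  list(manhattan = manhattan, qq = qq)
}

#' Look up previously reported variants in the association results
#'
#' For each catalog SNP, reports whether it is available in the results and,
#' if so, its odds ratio, p-value, a significance flag at `alpha`, and
#' whether the estimated direction of effect agrees with the reported one.
#'
#' @param results a [run_gwas()] object or its `results` data.frame.
#' @param catalog data.frame with columns `snp_id` and `direction`
#'   (`"+"`/`"-"`, or any positive/negative number for risk/protective).
#' @param alpha look-up significance threshold.
#' @return data.frame: `snp_id`, `available`, `or`, `p`, `significant`,
#'   `concordant`.
#' @export
lookup_known <- function(results, catalog, alpha = 0.001) {
  if (inherits(results, "gwas_result")) results <- results$results
  stopifnot(all(c("snp_id", "direction") %in% names(catalog)),
            alpha > 0, alpha <= 1)
  dir_sign <- function(d) {
    if (is.numeric(d)) sign(d)
    else ifelse(d %in% c("+", "risk"), 1, ifelse(d %in% c("-", "protective"), -1, NA))
  }
  i <- match(catalog$snp_id, results$snp)
  available <- !is.na(i)
  beta <- results$beta[i]
  p <- results$p[i]
  out <- data.frame(snp_id = catalog$snp_id, available = available,
                    or = results$or[i], p = p,
                    significant = available & !is.na(p) & p < alpha,
                    concordant = available & !is.na(beta) &
                      sign(beta) == dir_sign(catalog$direction),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
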