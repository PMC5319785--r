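#' Construct a genotype matrix
#'
#' The container used throughout the association engine: biallelic SNPs with
#' minor-allele dosages 0/1/2 (`NA` = missing), one row per sample.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param dosage integer matrix, samples x SNPs, values in {0,1,2,NA},
#'   counting copies of the alt allele.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, snps, dosage) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop2("duplicate sample ids")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snps)))
    stop2("snps must have columns: ", paste(need, collapse = ", "))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != nrow(snps))
    stop2("dosage dimensions do not match sample_ids / snps")
  if (any(snps$pos < 1)) stop2("pos must be >= 1")
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop2("dosage values must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_ids, snps$id)
  rownames(snps) <- NULL
  structure(list(sample_ids = sample_ids, snps = snps, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
              length(x$sample_ids), nrow(x$snps),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Specification for genotype simulation
#'
#' Two subpopulations diverge around a shared ancestral allele frequency in
#' Balding-Nichols fashion: each subpopulation's frequency is a Beta draw
#' with mean equal to the ancestral frequency and variance controlled by
#' `fst_like_divergence`. Genotypes are in Hardy-Weinberg proportions within
#' subpopulation. Causal SNPs are sampled retrospectively: genotype
#' frequencies conditional on case/control status are derived from an
#' additive logistic (per-allele odds ratio) penetrance model calibrated to
#' the population `prevalence`.
#'
#' @param n_snps number of SNPs.
#' @param maf_range ancestral minor-allele frequency range, drawn uniformly.
#' @param fst_like_divergence divergence parameter in [0, 1); 0 = a single
#'   panmictic population.
#' @param causal data.frame with columns `snp` (1-based SNP index) and `or`
#'   (per-allele odds ratio, > 0); all other SNPs are null (OR 1).
#' @param missing_rate uniform genotype missingness in [0, 1).
#' @param prevalence disease prevalence used to calibrate penetrances.
#' @param seed integer RNG seed.
#' @return An object of class `geno_sim_spec`.
#' @export
geno_sim_spec <- function(n_snps, maf_range = c(0.05, 0.45),
                          fst_like_divergence = 0.1,
                          causal = NULL, missing_rate = 0.02,
                          prevalence = 0.10, seed = 1L) {
  stopifnot(n_snps >= 1, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            fst_like_divergence >= 0, fst_like_divergence < 1,
            missing_rate >= 0, missing_rate < 1,
            prevalence > 0, prevalence < 1)
  if (is.null(causal))
    causal <- data.frame(snp = integer(), or = numeric())
  stopifnot(all(c("snp", "or") %in% names(causal)))
  if (any(causal$or <= 0)) stop2("causal ORs must be > 0")
  if (any(causal$snp < 1 | causal$snp > n_snps)) stop2("causal snp index out of range")
  structure(list(n_snps = as.integer(n_snps), maf_range = maf_range,
                 fst_like_divergence = fst_like_divergence, causal = causal,
                 missing_rate = missing_rate, prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "geno_sim_spec")
}

#' Simulate genotypes conditional on case/control status
#'
#' @param spec a [geno_sim_spec()].
#' @param labels character vector per sample: `"case"`/`"control"` (the
#'   phenotyper's `CASE_*`/`CONTROL` statuses are also accepted).
#' @param subpop optional integer vector (1 or 2) assigning samples to
#'   subpopulations; assigned equiprobably when omitted.
#' @param sample_ids optional sample identifiers.
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (data.frame: `snp_id`, `or`, `maf_ancestral`, plus per-sample `subpop`
#'   as an attribute-free second data.frame `samples`).
#' @export
simulate_genotypes <- function(spec, labels, subpop = NULL, sample_ids = NULL) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  labels <- as.character(labels)
  labels[labels %in% c("CASE_CONTROLLED", "CASE_UNCONTROLLED")] <- "case"
  labels[labels == "CONTROL"] <- "control"
  if (!all(labels %in% c("case", "control")))
    stop2("labels must be 'case'/'control' (or CASE_*/CONTROL statuses)")
  n <- length(labels)
  set.seed(spec$seed)
  if (is.null(subpop)) subpop <- sample(1:2, n, replace = TRUE)
  stopifnot(length(subpop) == n, all(subpop %in% 1:2))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n))

  ors <- rep(1, spec$n_snps)
  ors[spec$causal$snp] <- spec$causal$or
  fst <- spec$fst_like_divergence

  dosage <- matrix(NA_integer_, n, spec$n_snps)
  maf_anc <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  grp <- interaction(subpop, labels, drop = FALSE)
  grp_idx <- split(seq_len(n), grp)

  for (j in seq_len(spec$n_snps)) {
    p_anc <- maf_anc[j]
    p_sub <- if (fst > 0) {
      a <- p_anc * (1 - fst) / fst
      b <- (1 - p_anc) * (1 - fst) / fst
      pmin(pmax(stats::rbeta(2L, a, b), 1e-3), 1 - 1e-3)
    } else rep(p_anc, 2L)
    if (ors[j] == 1) {
      dosage[, j] <- stats::rbinom(n, 2L, p_sub[subpop])
    } else {
      for (s in 1:2) {
        cc <- case_control_freqs(p_sub[s], ors[j], spec$prevalence,
                                 effect_scale = "odds")
        for (lab in c("case", "control")) {
          idx <- grp_idx[[paste(s, lab, sep = ".")]]
          if (length(idx))
            dosage[idx, j] <- sample(0:2, length(idx), replace = TRUE,
                                     prob = if (lab == "case") cc$case else cc$control)
        }
      }
    }
  }
  if (spec$missing_rate > 0)
    dosage[stats::runif(length(dosage)) < spec$missing_rate] <- NA_integer_

  chrom <- ((seq_len(spec$n_snps) - 1L) %% 22L) + 1L
  pos <- 10000L + 1000L * (((seq_len(spec$n_snps) - 1L) %/% 22L) + 1L)
  snps <- data.frame(id = sprintf("snp%05d", seq_len(spec$n_snps)),
                     chrom = chrom, pos = pos, ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(sample_ids, snps, dosage)
  truth <- data.frame(snp_id = snps$id, or = ors, maf_ancestral = maf_anc,
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_ids, label = labels,
                        subpop = as.integer(subpop), stringsAsFactors = FALSE)
  list(genotypes = gm, truth = truth, samples = samples)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a standards-compliant VCFv4.2 with a single `GT` FORMAT field;
#' dosages 0/1/2 become `0/0`, `0/1`, `1/1` and missing becomes `./.`.
#' `read_vcf(write_vcf(x, f))` reproduces the dosages exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param extra_header optional character vector of extra `##` header lines
#'   (each must already start with `##`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, extra_header = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt <- matrix(c("0/0", "0/1", "1/1")[gm$dosage + 1L],
               nrow = nrow(gm$dosage))
  gt[is.na(gm$dosage)] <- "./."
  body <- cbind(gm$snps$chrom, gm$snps$pos, gm$snps$id, gm$snps$ref,
                gm$snps$alt, ".", "PASS", ".", "GT", t(gt))
  lines <- c("##fileformat=VCFv4.2",
             "##source=rhtn",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             extra_header,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

GT_DOSAGE <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
               "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
               "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)

#' Read genotypes from a VCF file
#'
#' Minimal reader for biallelic GT-format VCFs (the subset produced by
#' [write_vcf()], and by common tools when restricted to hard genotype
#' calls). Dosage counts the ALT allele; phased and unphased separators are
#' accepted.
#'
#' @param path VCF file path.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop2("VCF not found: ", path)
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) stop2(path, ": missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop2(path, ": no sample columns")
  samples <- cols[-(1:9)]
  data <- lines[-seq_len(hdr)]
  data <- data[nzchar(data)]
  if (length(data) == 0L) stop2(path, ": no variant records")
  mat <- do.call(rbind, strsplit(data, "\t", fixed = TRUE))
  if (ncol(mat) != length(cols)) stop2(path, ": ragged variant records")
  fmt1 <- vapply(strsplit(mat[, 9L], ":", fixed = TRUE), `[[`, character(1), 1L)
  if (!all(fmt1 == "GT")) stop2(path, ": GT must be the first FORMAT field")
  gt <- sub(":.*$", "", mat[, -(1:9), drop = FALSE])
  dos <- GT_DOSAGE[gt]
  unknown <- is.na(dos) & !gt %in% names(GT_DOSAGE)
  if (any(unknown))
    stop2(path, ": unsupported genotype ", dQuote(gt[unknown][1L]))
  dosage <- t(matrix(dos, nrow = nrow(mat)))
  snps <- data.frame(id = mat[, 3L], chrom = as.integer(mat[, 1L]),
                     pos = as.integer(mat[, 2L]), ref = mat[, 4L],
                     alt = mat[, 5L], stringsAsFactors = FALSE)
  genotype_matrix(samples, snps, dosage)
}
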