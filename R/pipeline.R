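#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the simulate -> phenotype -> associate -> power
#' workflow with its documented default. The effective configuration is
#' serialized (with its MD5 hash) alongside every run, and the hash is
#' stamped as a `#` comment into each delimited output, so any output file
#' can be traced to the exact configuration that produced it.
#'
#' @param out_dir run directory (created by [run_all()]).
#' @param seed master RNG seed; the cohort and genotype generators derive
#'   their seeds from it deterministically.
#' @param n_per_archetype cohort composition, see [cohort_sim_spec()].
#' @param bp_noise_sd blood-pressure noise SD (mm Hg).
#' @param n_snps,maf_range,fst_like_divergence,missing_rate,prevalence
#'   genotype generation, see [geno_sim_spec()].
#' @param causal planted effects, see [geno_sim_spec()].
#' @param k_pcs ancestry principal components in the association model.
#' @param mention_window_days,collapse_diuretics,uncontrolled_bp_lag_days
#'   phenotyping options, see [phenotype_options()].
#' @param lookup_alpha significance threshold for the known-variant look-up.
#' @param power_alpha,power_target power-report settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       n_per_archetype = stats::setNames(rep(40L, 7L), ARCHETYPES),
                       bp_noise_sd = 4,
                       n_snps = 200L,
                       maf_range = c(0.1, 0.4),
                       fst_like_divergence = 0.05,
                       missing_rate = 0.01,
                       prevalence = 0.10,
                       causal = data.frame(snp = 1:2, or = c(2.0, 0.5)),
                       k_pcs = 2L,
                       mention_window_days = 90,
                       collapse_diuretics = FALSE,
                       uncontrolled_bp_lag_days = 30,
                       lookup_alpha = 0.001,
                       power_alpha = 5e-8,
                       power_target = 0.80) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_per_archetype = n_per_archetype, bp_noise_sd = bp_noise_sd,
              n_snps = as.integer(n_snps), maf_range = maf_range,
              fst_like_divergence = fst_like_divergence,
              missing_rate = missing_rate, prevalence = prevalence,
              causal = causal, k_pcs = as.integer(k_pcs),
              mention_window_days = mention_window_days,
              collapse_diuretics = collapse_diuretics,
              uncontrolled_bp_lag_days = uncontrolled_bp_lag_days,
              lookup_alpha = lookup_alpha, power_alpha = power_alpha,
              power_target = power_target)
  hashed <- cfg[setdiff(names(cfg), "out_dir")]
  cfg$config_hash <- md5_of_object(hashed)
  structure(cfg, class = "run_config")
}

write_run_table <- function(df, path, hash, sep = "\t") {
  con <- file(path, "w")
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  close(con)
}

read_run_table <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2(sprintf("stage %s failed: %s", name, conditionMessage(e))))
}

#' Run the full pipeline end to end
#'
#' Stages, in the order of the study workflow: simulate a labelled cohort;
#' write and phenotype it; simulate genotypes for the phenotyped
#' cases/controls (with planted effects); write a VCF; run QC + PCA +
#' per-SNP logistic association; look up the planted (known) variants;
#' compute the analytic power report; and write a machine-readable manifest.
#' Rerunning with the same configuration reproduces every output
#' byte-for-byte.
#'
#' @param config a [run_config()].
#' @return The run directory, invisibly. Outputs: `config.json`, `cohort/`,
#'   `truth.csv`, `calls.csv`, `summary.csv`, `genotypes.vcf`, `assoc.tsv`,
#'   `qc_report.tsv`, `strata.tsv`, `manhattan.tsv`, `qq.tsv`,
#'   `lookup.tsv`, `power.tsv`, `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop2("cannot create run directory ", out)
  hash <- config$config_hash
  # out_dir is implied by the file's location; omitting it keeps the
  # serialized config identical across reruns in different directories
  jsonlite::write_json(unclass(config)[setdiff(names(config), "out_dir")],
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dict <- default_med_dictionary()
  cfg_excl <- default_exclusion_config()
  opts <- phenotype_options(config$mention_window_days,
                            config$collapse_diuretics,
                            config$uncontrolled_bp_lag_days)

  sim <- pipeline_stage("simulate_cohort", {
    spec <- cohort_sim_spec(config$n_per_archetype, seed = config$seed,
                            bp_noise_sd = config$bp_noise_sd)
    simulate_cohort(spec, dict)
  })
  write_cohort(sim$cohort, file.path(out, "cohort"),
               comment = paste0("config_hash=", hash))
  write_run_table(sim$truth, file.path(out, "truth.csv"), hash, sep = ",")

  ph <- pipeline_stage("phenotype", phenotype_cohort(sim$cohort, dict, cfg_excl, opts))
  write_run_table(ph$calls, file.path(out, "calls.csv"), hash, sep = ",")
  sum_df <- data.frame(status = names(ph$summary$by_status),
                       n = as.integer(ph$summary$by_status))
  write_run_table(sum_df, file.path(out, "summary.csv"), hash, sep = ",")

  cc <- ph$calls[ph$calls$status %in% c("CASE_CONTROLLED", "CASE_UNCONTROLLED",
                                        "CONTROL"), , drop = FALSE]
  if (nrow(cc) < 4L) stop2("stage simulate_genotypes failed: fewer than 4 cases+controls")
  gen <- pipeline_stage("simulate_genotypes", {
    gspec <- geno_sim_spec(config$n_snps, config$maf_range,
                           config$fst_like_divergence, config$causal,
                           config$missing_rate, config$prevalence,
                           seed = config$seed + 1L)
    subpop <- sim$truth$subpop[match(cc$patient_id, sim$truth$patient_id)]
    simulate_genotypes(gspec, cc$status, subpop = subpop,
                       sample_ids = cc$patient_id)
  })
  write_vcf(gen$genotypes, file.path(out, "genotypes.vcf"),
            extra_header = paste0("##config_hash=", hash))
  write_run_table(gen$truth, file.path(out, "snp_truth.csv"), hash, sep = ",")

  gw <- pipeline_stage("gwas", {
    demo <- sim$cohort$demographics
    i <- match(cc$patient_id, demo$patient_id)
    covars <- data.frame(sex = demo$sex[i],
                         birth_decade = demo$birth_decade[i],
                         median_bmi = vapply(cc$patient_id, function(id)
                           median_bmi(patient_record(sim$cohort, id)),
                           numeric(1)),
                         platform = demo$platform[i], site = demo$site[i],
                         stringsAsFactors = FALSE)
    run_gwas(gen$genotypes, cc$status, covars, k_pcs = config$k_pcs)
  })
  write_run_table(gw$results, file.path(out, "assoc.tsv"), hash)
  qc_df <- data.frame(
    filter = c("sample_callrate", "snp_callrate", "snp_maf", "snp_hwe"),
    n_removed = c(length(gw$qc$samples_removed),
                  length(gw$qc$snps_removed_callrate),
                  length(gw$qc$snps_removed_maf),
                  length(gw$qc$snps_removed_hwe)))
  write_run_table(qc_df, file.path(out, "qc_report.tsv"), hash)
  if (!is.null(gw$strata))
    write_run_table(gw$strata, file.path(out, "strata.tsv"), hash)
  pd <- plot_data(gw$results)
  write_run_table(pd$manhattan, file.path(out, "manhattan.tsv"), hash)
  write_run_table(pd$qq, file.path(out, "qq.tsv"), hash)

  lk <- pipeline_stage("lookup", {
    causal <- gen$truth[gen$truth$or != 1, , drop = FALSE]
    catalog <- data.frame(snp_id = causal$snp_id,
                          direction = ifelse(causal$or > 1, "+", "-"),
                          stringsAsFactors = FALSE)
    lookup_known(gw$results, catalog, alpha = config$lookup_alpha)
  })
  write_run_table(lk, file.path(out, "lookup.tsv"), hash)

  pow <- pipeline_stage("power", {
    n_case <- sum(cc$status != "CONTROL")
    n_ctrl <- sum(cc$status == "CONTROL")
    grid <- expand.grid(maf = c(0.05, 0.20), or = c(1.2, 1.41, 1.5, 2.0))
    grid$power <- vapply(seq_len(nrow(grid)), function(i)
      power_additive(n_case, n_ctrl, grid$maf[i], grid$or[i],
                     config$prevalence, config$power_alpha)$power, numeric(1))
    # small demo cohorts can make the target unreachable; report NA then
    min_or <- vapply(c(0.05, 0.20), function(m)
      tryCatch(min_detectable_or(n_case, n_ctrl, m, config$prevalence,
                                 config$power_alpha, config$power_target),
               error = function(e) NA_real_), numeric(1))
    list(grid = grid,
         min_or = data.frame(maf = c(0.05, 0.20), min_detectable_or = min_or))
  })
  write_run_table(pow$grid, file.path(out, "power.tsv"), hash)
  write_run_table(pow$min_or, file.path(out, "power_min_or.tsv"), hash)

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("rhtn")),
    config_hash = hash, seed = config$seed,
    n_patients = nrow(sim$cohort$demographics),
    phenotype_counts = as.list(ph$summary$by_status),
    n_gwas_samples = gw$n_samples, n_gwas_snps = nrow(gw$results),
    lambda_gc = gw$lambda_gc,
    files = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Summarize a completed run directory
#'
#' Regenerates a deterministic human-readable report from the run's output
#' files (identical across regenerations of the same run).
#'
#' @param run_dir directory produced by [run_all()].
#' @param write if `TRUE`, also writes `report.txt` into the directory.
#' @return Character vector of report lines, invisibly when `write = TRUE`.
#' @export
run_report <- function(run_dir, write = TRUE) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) stop2("incomplete run directory: no manifest.json")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  calls <- read_run_table(file.path(run_dir, "calls.csv"), sep = ",")
  truth <- read_run_table(file.path(run_dir, "truth.csv"), sep = ",")
  assoc <- read_run_table(file.path(run_dir, "assoc.tsv"))
  lk <- read_run_table(file.path(run_dir, "lookup.tsv"))
  pow <- read_run_table(file.path(run_dir, "power_min_or.tsv"))
  top <- assoc[which.min(assoc$p), ]
  arch_counts <- table(truth$archetype)
  lines <- c(
    sprintf("run %s (config %s, seed %d)", run_dir, man$config_hash, man$seed),
    sprintf("patients: %d", man$n_patients),
    "archetypes:",
    sprintf("  %-26s %d", names(arch_counts), as.integer(arch_counts)),
    "phenotype calls:",
    sprintf("  %-17s %d", names(man$phenotype_counts),
            unlist(man$phenotype_counts)),
    sprintf("gwas: %d samples x %d SNPs, lambda_GC = %.3f",
            man$n_gwas_samples, man$n_gwas_snps, man$lambda_gc),
    sprintf("top association: %s OR %.3f p %.3g", top$snp, top$or, top$p),
    sprintf("lookup: %d/%d catalog SNPs significant and concordant at alpha",
            sum(lk$significant & lk$concordant), nrow(lk)),
    "power (80% target):",
    sprintf("  maf %.2f -> min detectable OR %.3f", pow$maf,
            pow$min_detectable_or))
  if (write) {
    writeLines(lines, file.path(run_dir, "report.txt"))
    return(invisible(lines))
  }
  lines
}
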