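#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run — simulation,
#' quantification, DMR calling, GWAS, variance components, population
#' genetics — with the analysis constants surfaced as named defaults
#' (200/100 bp analysis windows, 100 bp DMR tiles, FDR 0.05, minimum
#' difference 0.3, 50 kb / 100 kb cis windows, 10 restarts, permutation
#' counts). All parameters are validated before any stage runs.
#'
#' @param sim A [sim_config()].
#' @param window_size,window_step Sliding-window size/step (bp).
#' @param dmr_window DMR tile width (bp).
#' @param fdr DMR FDR threshold.
#' @param min_diff Minimum absolute methylation difference for a DMR call.
#' @param top_windows Number of most-variable windows retained.
#' @param n_dmr_accessions Number of accessions used for per-accession
#'   temperature-DMR calling (the per-accession tests are independent, so
#'   a subset bounds the stage's cost without changing its statistics).
#' @param n_gwas_windows Number of window phenotypes scanned by GWAS.
#' @param n_varcomp_windows Number of window phenotypes decomposed.
#' @param cis_window_gwas,cis_window_varcomp Cis distances (bp).
#' @param restarts Variance-component restarts.
#' @param n_perm Permutation count for enrichment tests.
#' @param min_coverage Site-level coverage cutoff.
#' @param stages Character vector of stages to run, in dependency order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            window_size = 200, window_step = 100,
                            dmr_window = 100, fdr = 0.05, min_diff = 0.3,
                            top_windows = 500, n_dmr_accessions = 12,
                            n_gwas_windows = 40,
                            n_varcomp_windows = 20,
                            cis_window_gwas = 1e5, cis_window_varcomp = 5e4,
                            restarts = 10, n_perm = 1000, min_coverage = 1,
                            stages = c("simulate", "quant", "dmr", "gwas",
                                       "varcomp", "popgen")) {
  stopf(inherits(sim, "sim_config"), "sim must be a sim_config")
  stopf(is_fraction(fdr) && fdr > 0, "fdr must be in (0,1]")
  stopf(is.numeric(min_diff) && min_diff >= 0 && min_diff <= 1,
        "min_diff must be in [0,1]")
  stopf(window_size %% window_step == 0, "window_size must be a multiple of step")
  stopf(is_count(top_windows) && is_count(n_gwas_windows) &&
          is_count(n_varcomp_windows) && is_count(restarts) &&
          is_count(n_dmr_accessions) &&
          is_count(n_perm) && is_count(min_coverage),
        "counts must be positive integers")
  stopf(all(stages %in% c("simulate", "quant", "dmr", "gwas", "varcomp",
                          "popgen")), "unknown stage name")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate, quant, dmr, gwas,
#' varcomp, popgen) on simulated data, writing each stage's result tables
#' as TSV into `out_dir` together with a provenance manifest (package
#' version, seed, parameter hash, file checksums). A failed stage halts
#' the downstream stages; completed outputs are retained and the failure
#' recorded in the manifest. Re-running with the same config and seed
#' reproduces every table bit-identically.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @param seed Master seed (overrides `cfg$sim$seed` when given).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  stopf(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(paste0("[methclime] ", ...))
  res <- list()
  status <- list()
  t0 <- Sys.time()

  write_out <- function(tb, name) {
    readr::write_tsv(tb, file.path(out_dir, paste0(name, ".tsv")))
  }

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    say("stage: ", name)
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     warn(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
                     FALSE
                   })
    status[[name]] <<- ok
    if (!ok) cfg$stages <<- cfg$stages[seq_len(match(name, cfg$stages))]
    invisible(ok)
  }

  run_stage("simulate", function() {
    res$genotypes <<- simulate_genotypes(cfg$sim)
    res$annot <<- simulate_annotations(cfg$sim)
    sim <- simulate_methylomes(res$genotypes, res$annot, cfg$sim)
    res$counts <<- sim$counts
    res$truth <<- sim$truth
    res$expression <<- simulate_expression(res$genotypes, res$annot,
                                           sim$truth, cfg$sim)
    write_out(res$genotypes$accessions, "accessions")
    write_out(res$annot$features, "features")
  })

  run_stage("quant", function() {
    res$efficiency <<- conversion_efficiency(res$counts)
    res$ctx_avg <<- context_averages(res$counts, min_coverage = cfg$min_coverage)
    res$te_chh <<- feature_average(res$counts, res$annot$features,
                                   context = "CHH", type = "TE",
                                   min_length = 2000)
    wm <- sliding_windows(res$counts, size = cfg$window_size,
                          step = cfg$window_step, context = "CHH",
                          chrom_lengths = res$annot$chrom_lengths)
    res$windows <<- wm
    wm10 <- dplyr::filter(wm, .data$env == levels(factor(wm$env))[1])
    res$variable_windows <<- suppressWarnings(
      select_variable_windows(wm10, top_n = cfg$top_windows,
                              accessions = rownames(res$genotypes$calls)))
    gene_cg <- purrr::map_dfr(c("CG", "CHG", "CHH"), function(ctx)
      dplyr::mutate(
        dplyr::rename(feature_average(res$counts, res$annot$features,
                                      context = ctx, type = "gene"),
                      gene_id = "feature_id"),
        context = ctx))
    res$gene_levels <<- gene_cg
    res$gbm <<- classify_gbm_genes(
      dplyr::filter(gene_cg, .data$env == levels(factor(gene_cg$env))[1]))
    write_out(res$efficiency, "conversion_efficiency")
    write_out(res$ctx_avg, "context_averages")
    write_out(res$variable_windows, "variable_windows")
    write_out(res$gbm, "gbm_classification")
  })

  run_stage("dmr", function() {
    dmr_acc <- head(rownames(res$genotypes$calls), cfg$n_dmr_accessions)
    res$temp_dmrs <<- temperature_dmrs(
      dplyr::filter(res$counts, .data$accession %in% dmr_acc),
      window = cfg$dmr_window, fdr = cfg$fdr, min_diff = cfg$min_diff,
      context = "CHH")
    tes <- dplyr::filter(res$annot$features, .data$type == "TE")
    if (nrow(res$temp_dmrs$consensus) > 0) {
      res$dmr_overlap <<- annotate_overlap(res$temp_dmrs$consensus, tes)
      hit <- overlap_join(
        dplyr::mutate(res$temp_dmrs$consensus,
                      pos = (.data$start + .data$end) %/% 2L), tes)
      observed_variable <- unique(hit$feature_id)
      if (length(observed_variable) > 0)
        res$te_enrichment <<- te_family_enrichment(
          observed_variable, tes, n_perm = cfg$n_perm, seed = cfg$sim$seed)
    }
    write_out(res$temp_dmrs$per_accession, "temperature_dmr_counts")
    write_out(res$temp_dmrs$consensus, "temperature_dmr_consensus")
    if (!is.null(res$te_enrichment)) write_out(res$te_enrichment, "te_enrichment")
  })

  run_stage("gwas", function() {
    K <- kinship_ibs(res$genotypes)
    env1 <- sort(unique(res$te_chh$env))[1]
    te_pheno <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(res$te_chh, .data$env == env1),
                      .data$accession),
      value = mean(.data$level), .groups = "drop")
    res$major_scan <<- lmm_scan(te_pheno, res$genotypes, K)
    res$stepwise <<- stepwise_scan(te_pheno, res$genotypes, K,
                                   max_cofactors = 3)
    wins <- head(res$variable_windows, cfg$n_gwas_windows)
    wm1 <- dplyr::filter(res$windows, .data$env == env1)
    assoc <- purrr::map_dfr(seq_len(nrow(wins)), function(i) {
      wy <- wm1[wm1$window_id == wins$window_id[i], c("accession", "level")]
      if (nrow(wy) < nrow(res$genotypes$calls)) return(NULL)
      sc <- lmm_scan(setNames(wy$level, wy$accession), res$genotypes, K)
      dplyr::mutate(tibble::as_tibble(sc), phenotype = wins$window_id[i],
                    .before = 1)
    })
    res$window_assoc <<- assoc
    anchors <- dplyr::select(wins, phenotype = "window_id", "chrom",
                             "start", "end")
    res$cis_trans <<- classify_cis_trans(assoc, anchors,
                                         cis_window = cfg$cis_window_gwas)
    write_out(tibble::as_tibble(res$major_scan), "major_locus_scan")
    write_out(res$cis_trans$associations, "window_associations")
    write_out(res$cis_trans$summary, "cis_trans_summary")
  })

  run_stage("varcomp", function() {
    env_levels <- sort(unique(res$windows$env))
    wins <- head(res$variable_windows, cfg$n_varcomp_windows)
    fits <- purrr::map(seq_len(nrow(wins)), function(i) {
      wy <- res$windows[res$windows$window_id == wins$window_id[i], ]
      Y <- tidyr::pivot_wider(wy[, c("accession", "env", "level")],
                              names_from = "env", values_from = "level")
      Y <- Y[match(rownames(res$genotypes$calls), Y$accession), ]
      Ym <- as.matrix(Y[, env_levels])
      parts <- snp_partition(res$genotypes,
                             list(chrom = wins$chrom[i], start = wins$start[i],
                                  end = wins$end[i]),
                             cis_window = cfg$cis_window_varcomp)
      R_cis <- if (length(parts$cis) >= 1)
        tryCatch(relatedness_from_snps(res$genotypes, parts$cis),
                 error = function(e) NULL) else NULL
      fit <- fit_varcomp(Ym,
                         R_cmt2 = relatedness_from_snps(res$genotypes, parts$major),
                         R_cis = R_cis,
                         R_trans = relatedness_from_snps(res$genotypes, parts$trans),
                         restarts = cfg$restarts, seed = cfg$sim$seed + i)
      dplyr::mutate(fit$fractions, phenotype = wins$window_id[i],
                    converged = fit$converged, loglik = fit$loglik,
                    .before = 1)
    })
    frac <- dplyr::bind_rows(fits)
    res$varcomp <<- dplyr::filter(frac, .data$converged)
    res$varcomp_bins <<- bin_by_total_variance(res$varcomp)
    write_out(frac, "varcomp_fractions")
    write_out(res$varcomp_bins, "varcomp_bins")
  })

  run_stage("popgen", function() {
    res$fst <<- hudson_fst(res$genotypes)
    gbm_genes <- res$gbm$gene_id[res$gbm$label == "GBM"]
    env1 <- sort(unique(res$gene_levels$env))[1]
    gbm_pheno <- dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(res$gene_levels, .data$context == "CG",
                      .data$env == env1, .data$gene_id %in% gbm_genes),
        .data$accession),
      value = mean(.data$level), .groups = "drop")
    res$qst <<- qst(gbm_pheno, res$genotypes)
    pheno <- dplyr::rename(res$ctx_avg, level = "level")
    res$env_cor <<- env_correlations(
      pheno, res$genotypes$accessions[, c("accession", "latitude")])
    res$expr_cmp <<- expression_comparisons(
      res$expression, dplyr::rename(res$gbm, label = "label"),
      tibble::tibble(accession = res$genotypes$accessions$accession,
                     group = res$genotypes$accessions$region))
    write_out(glance(res$fst), "fst")
    write_out(tibble::as_tibble(res$qst), "qst")
    write_out(res$env_cor, "env_correlations")
    write_out(res$expr_cmp$class_contrast, "expression_contrasts")
  })

  # provenance manifest
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "stages")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tsvs <- sort(list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE))
  manifest <- list(
    package = "methclime",
    version = as.character(utils::packageVersion("methclime")),
    seed = cfg$sim$seed,
    param_hash = param_hash(as.character(cfg_json)),
    stages_run = names(status),
    stages_ok = unlist(status),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
    files = lapply(tsvs, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  # the manifest must be bit-reproducible, so no timestamps beyond elapsed
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[setdiff(names(manifest), "elapsed_sec")],
                       manifest_path, auto_unbox = TRUE, pretty = TRUE)
  say("done (", manifest$elapsed_sec, "s); manifest at ", manifest_path)
  invisible(c(res, list(manifest = manifest)))
}

param_hash <- function(s) {
  f <- tempfile()
  writeLines(s, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
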