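#' Simulation configuration
#'
#' Builds the configuration object consumed by every `simulate_*()`
#' generator. The defaults describe a scaled-down two-subpopulation
#' (north/south Sweden) panel of naturally inbred accessions grown at two
#' temperatures (10 and 16 degrees C), with the genetic architecture the
#' downstream analyses assume: a major trans-acting locus on one chromosome
#' controlling CHH methylation of transposons (a CMT2-like chromomethylase),
#' local cis variants acting on individual transposons, a polygenic,
#' latitude-correlated trans architecture for CG gene-body methylation, a
#' genome-wide temperature response of CHH methylation, and bisulfite
#' conversion error.
#'
#' @param n_accessions Number of inbred accessions in the panel.
#' @param n_snps Number of biallelic SNPs to simulate.
#' @param genome_length Total nuclear genome length in bp, split evenly
#'   across `n_chromosomes`.
#' @param n_chromosomes Number of nuclear chromosomes.
#' @param pop_split Fraction of accessions belonging to the northern
#'   subpopulation.
#' @param fst_target Target Hudson Fst between the two subpopulations
#'   (Balding--Nichols divergence parameter). The study panel's SNP Fst
#'   estimate is 0.187, the default here.
#' @param n_genes,n_tes Number of genes and transposable elements.
#' @param architecture Named list of effect sizes, all on the logit
#'   (log-odds) scale of per-site methylation probability. See Details.
#' @param conversion_error Probability that an unmethylated cytosine is read
#'   as methylated (and vice versa) after bisulfite treatment. Default
#'   0.0041, i.e. a 99.59% conversion efficiency.
#' @param depth_mean Mean sequencing depth per cytosine (Poisson).
#' @param site_spacing Average spacing (bp) between simulated cytosines
#'   inside annotated features; intergenic spacing is 10x sparser.
#' @param variable_te_fraction Fraction of TEs flagged as temperature
#'   "variable" (hosts of planted temperature DMRs); default 2.7%.
#' @param gbm_gene_fraction Fraction of genes carrying gene-body
#'   methylation (GBM).
#' @param seed Integer seed; every generator is deterministic given the
#'   config.
#'
#' @details The `architecture` list understands:
#' \describe{
#'   \item{major_effect_a, major_effect_b}{logit shifts of CHH methylation
#'     at major-locus-dependent TE sites for carriers of the two
#'     repulsion-phase non-reference alleles (default +0.9 / -0.9).}
#'   \item{cis_effect}{logit shift per planted cis allele (default 1.2).}
#'   \item{cis_fraction}{fraction of TEs given a cis-acting SNP.}
#'   \item{chh_ratio_16_10}{target ratio of genome-wide mean CHH
#'     methylation at 16C over 10C (default 1.14, the study's observed
#'     14% increase). The corresponding genome-wide logit shift is
#'     calibrated numerically against the simulated site ensemble.}
#'   \item{env_effect}{optional explicit logit shift of CHH methylation at
#'     16C; when NULL (default) it is derived from `chh_ratio_16_10`.}
#'   \item{temp_dmr_effect}{extra 16C logit shift inside variable TEs
#'     (gain-type hosts; loss-type hosts get the negative).}
#'   \item{n_trans_gbm}{number of diverged trans SNPs feeding the GBM
#'     liability (default 15).}
#'   \item{gbm_lat_effect, gbm_acc_noise}{scale of the accession-level GBM
#'     liability score and of accession noise around it; the defaults give
#'     a latitude--CG correlation of roughly 0.7.}
#' }
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 60,
                       n_snps = 3000,
                       genome_length = 2e6,
                       n_chromosomes = 5,
                       pop_split = 0.4,
                       fst_target = 0.187,
                       n_genes = 250,
                       n_tes = 400,
                       architecture = list(),
                       conversion_error = 0.0041,
                       depth_mean = 20,
                       site_spacing = 15,
                       variable_te_fraction = 0.027,
                       gbm_gene_fraction = 0.3,
                       seed = 1L) {
  arch_default <- list(
    major_effect_a = 0.9,
    major_effect_b = -0.9,
    major_dependent_fraction = 0.6,
    cis_effect = 1.2,
    cis_fraction = 0.5,
    chh_ratio_16_10 = 1.14,
    env_effect = NULL,
    temp_dmr_effect = 1.5,
    temp_dmr_loss_fraction = 1 / 3,
    n_trans_gbm = 15,
    gbm_trans_effect = 0.4,
    gbm_lat_effect = 0.5,
    gbm_acc_noise = 0.51,
    gbm_gene_sd = 0.6
  )
  unknown <- setdiff(names(architecture), names(arch_default))
  stopf(length(unknown) == 0, "unknown architecture fields: %s",
        paste(unknown, collapse = ", "))
  arch <- utils::modifyList(arch_default, architecture)
  stopf(is.null(arch$env_effect) || is.numeric(arch$env_effect),
        "env_effect must be numeric or NULL (calibrated)")

  stopf(is_count(n_accessions) && is_count(n_snps) && is_count(n_chromosomes) &&
          is_count(n_genes + 1) && is_count(n_tes + 1),
        "counts must be positive integers")
  stopf(is.numeric(genome_length) && genome_length > 0, "genome_length must be > 0")
  stopf(is_fraction(pop_split), "pop_split must be in [0,1]")
  stopf(is.numeric(fst_target) && fst_target >= 0 && fst_target < 1,
        "fst_target must be in [0,1)")
  stopf(is_fraction(conversion_error), "conversion_error must be in [0,1]")
  stopf(is.numeric(depth_mean) && depth_mean >= 1, "depth_mean must be >= 1")
  stopf(is_fraction(variable_te_fraction) && is_fraction(gbm_gene_fraction),
        "fractions must be in [0,1]")

  structure(list(
    n_accessions = as.integer(n_accessions),
    n_snps = as.integer(n_snps),
    genome_length = genome_length,
    n_chromosomes = as.integer(n_chromosomes),
    pop_split = pop_split,
    fst_target = fst_target,
    n_genes = as.integer(n_genes),
    n_tes = as.integer(n_tes),
    architecture = arch,
    conversion_error = conversion_error,
    depth_mean = depth_mean,
    site_spacing = site_spacing,
    variable_te_fraction = variable_te_fraction,
    gbm_gene_fraction = gbm_gene_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_accessions, " accessions, ", x$n_snps, " SNPs, ",
      x$n_chromosomes, " chromosomes (", format(x$genome_length, big.mark = ","),
      " bp), Fst target ", x$fst_target, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

chrom_lengths <- function(cfg) {
  len <- rep(floor(cfg$genome_length / cfg$n_chromosomes), cfg$n_chromosomes)
  names(len) <- paste0("Chr", seq_len(cfg$n_chromosomes))
  len
}

#' @rdname sim_config
#' @format NULL
#' @details The chloroplast control contig is always named `"ChrC"`; it is
#'   simulated fully unmethylated, so apparent methylation there measures
#'   conversion error.
#' @export
chloroplast_contig <- function() "ChrC"
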