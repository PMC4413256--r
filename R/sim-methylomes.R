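#' Simulate bisulfite methylomes with known truth
#'
#' Generates per-cytosine methylation count tables for every accession at
#' both growth temperatures (10C and 16C). Cytosine sites are placed along
#' each chromosome (densely inside annotated features, sparsely between
#' them) and each site's latent methylation probability is a logistic
#' function of additive logit-scale contributions:
#' a context-by-feature baseline; a major trans locus acting on CHH sites of
#' a configurable subset of TEs (the CMT2-like pathway); per-TE cis SNP
#' effects; a polygenic, latitudinally structured trans architecture on CG
#' gene-body methylation; a genome-wide CHH temperature response; and a
#' stronger temperature response inside "variable" TEs (the planted
#' temperature DMRs, gain- or loss-oriented). Observed methylated read
#' counts are Binomial with success probability `p(1-e) + (1-p)e`, where
#' `e` is the bisulfite conversion error, and Poisson read depth. The
#' chloroplast control contig is simulated with latent `p = 0`, so its
#' apparent methylation equals the conversion error.
#'
#' @param genotypes A `geno_table` from [simulate_genotypes()].
#' @param annot An `annot_set` from [simulate_annotations()].
#' @param cfg The shared [sim_config()].
#' @param cmt2_null,dcl3_null Character vectors of accession ids simulated
#'   as pathway knockouts: the corresponding pathway's contribution is
#'   removed and its dependent CHH sites fall to a near-zero floor,
#'   emulating T-DNA mutant methylomes.
#' @param environments Character vector of environment labels; the second
#'   is treated as the warm (16C) environment.
#' @return A list with `counts` — a tibble in cytosine-report layout
#'   (`accession`, `env`, `chrom`, `pos`, `strand`, `context`, `meth`,
#'   `total`; sites with zero depth are retained with `total = 0`) — and
#'   `truth`, a `truth_record` carrying the planted architecture (causal
#'   cis SNPs, pathway-dependent TE sets, temperature-DMR hosts, GBM
#'   liability scores, effect sizes).
#' @export
simulate_methylomes <- function(genotypes, annot, cfg,
                                cmt2_null = character(),
                                dcl3_null = character(),
                                environments = c("10C", "16C")) {
  stopf(inherits(genotypes, "geno_table"), "genotypes must be a geno_table")
  stopf(inherits(annot, "annot_set"), "annot must be an annot_set")
  stopf(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  stopf(length(environments) == 2, "exactly two environments are supported")
  arch <- cfg$architecture
  acc <- rownames(genotypes$calls)
  n <- length(acc)
  seeds <- derive_seeds(cfg$seed + 2L, 6)

  sites <- build_sites(annot, cfg, seeds[1])
  S <- nrow(sites)

  feats <- annot$features
  te_ids <- feats$feature_id[feats$type == "TE"]

  # pathway-dependent TE sets
  truth_sets <- with_seed(seeds[2], {
    n_dep <- round(arch$major_dependent_fraction * length(te_ids))
    cmt2_tes <- if (n_dep > 0) sample(te_ids, n_dep) else character()
    var_tes <- feats$feature_id[feats$variable %in% TRUE]
    extra <- setdiff(te_ids, var_tes)
    rddm_tes <- union(var_tes,
                      if (length(extra)) sample(extra, round(0.15 * length(extra)))
                      else character())
    list(cmt2 = cmt2_tes, rddm = rddm_tes)
  })

  # cis architecture: a nearby SNP (within 50 kb) per selected TE
  causal_cis <- with_seed(seeds[3], {
    n_cis <- round(arch$cis_fraction * length(te_ids))
    pick <- if (n_cis > 0) sample(te_ids, n_cis) else character()
    rows <- feats[match(pick, feats$feature_id), ]
    out <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      on_chrom <- genotypes$snps$chrom == rows$chrom[i]
      d <- abs(genotypes$snps$pos - (rows$start[i] + rows$end[i]) / 2)
      ok <- which(on_chrom & d <= 5e4 &
                    !(genotypes$snps$snp_id %in% genotypes$major_locus))
      if (!length(ok)) next
      snp <- ok[which.min(d[ok])]
      out[[i]] <- tibble::tibble(
        feature_id = rows$feature_id[i],
        snp_id = genotypes$snps$snp_id[snp],
        effect = arch$cis_effect * sample(c(-1, 1), 1))
    }
    dplyr::bind_rows(out)
  })

  # GBM trans architecture: diverged SNPs, north-common allele increases GBM
  gbm <- with_seed(seeds[4], {
    north <- genotypes$accessions$region == "north"
    p_n <- colMeans(genotypes$calls[north, , drop = FALSE])
    p_s <- colMeans(genotypes$calls[!north, , drop = FALSE])
    div <- abs(p_n - p_s)
    div[match(genotypes$major_locus, colnames(genotypes$calls))] <- -1
    k <- min(arch$n_trans_gbm, sum(div > 0))
    trans_snps <- colnames(genotypes$calls)[order(div, decreasing = TRUE)[seq_len(k)]]
    polarity <- sign(p_n - p_s)[trans_snps]     # +1 if non-ref commoner north
    eff <- arch$gbm_trans_effect * ifelse(polarity >= 0, 1, -1)
    score <- as.numeric(genotypes$calls[, trans_snps, drop = FALSE] %*% eff)
    z <- if (sd(score) > 0) (score - mean(score)) / sd(score) else score * 0
    acc_liab <- arch$gbm_lat_effect * z + rnorm(n, 0, arch$gbm_acc_noise)
    gbm_genes <- feats$feature_id[feats$gbm_gene %in% TRUE]
    gene_base <- rnorm(length(gbm_genes), 0, arch$gbm_gene_sd)
    liab <- outer(gene_base, rep(1, n)) +
      matrix(acc_liab, length(gbm_genes), n, byrow = TRUE) +
      matrix(rnorm(length(gbm_genes) * n, 0, 0.2), length(gbm_genes), n)
    dimnames(liab) <- list(gbm_genes, acc)
    list(trans_snps = tibble::tibble(snp_id = trans_snps, effect = eff),
         score = tibble::tibble(accession = acc, score = z, liability = acc_liab),
         liability = liab)
  })

  # accession-level major-locus effect
  ga <- genotypes$calls[, genotypes$major_locus["a"]]
  gb <- genotypes$calls[, genotypes$major_locus["b"]]
  major_acc <- arch$major_effect_a * ga + arch$major_effect_b * gb
  is_cmt2_null <- acc %in% cmt2_null
  is_dcl3_null <- acc %in% dcl3_null

  # site-level index vectors
  site_te <- sites$feature_id
  chh <- sites$context == "CHH"
  cmt2_sites <- chh & site_te %in% truth_sets$cmt2
  rddm_sites <- chh & site_te %in% truth_sets$rddm
  var_gain <- chh & site_te %in%
    feats$feature_id[feats$variable %in% TRUE & feats$variable_direction == "gain"]
  var_loss <- chh & site_te %in%
    feats$feature_id[feats$variable %in% TRUE & feats$variable_direction == "loss"]
  cp <- sites$chrom == annot$chloroplast

  base <- sites$base_logit
  eps <- cfg$conversion_error

  # assemble the latent logit matrix (sites x accessions), shared across envs
  L0 <- matrix(base, S, n)
  if (any(cmt2_sites))
    L0[cmt2_sites, ] <- L0[cmt2_sites, ] +
      matrix(major_acc, sum(cmt2_sites), n, byrow = TRUE)
  if (nrow(causal_cis)) {
    for (i in seq_len(nrow(causal_cis))) {
      rows <- which(chh & site_te == causal_cis$feature_id[i])
      if (!length(rows)) next
      gsnp <- genotypes$calls[, causal_cis$snp_id[i]]
      L0[rows, ] <- L0[rows, ] +
        matrix(causal_cis$effect[i] * gsnp, length(rows), n, byrow = TRUE)
    }
  }
  # loss-direction temperature-DMR hosts are highly methylated in the cool
  # environment (a loss is only observable from an elevated baseline)
  if (any(var_loss)) L0[var_loss, ] <- L0[var_loss, ] + 1.6

  gbm_rows <- which(sites$context == "CG" & site_te %in% rownames(gbm$liability))
  if (length(gbm_rows)) {
    L0[gbm_rows, ] <- L0[gbm_rows, ] +
      gbm$liability[site_te[gbm_rows], , drop = FALSE]
  }
  # pathway knockouts: dependent CHH sites collapse to a near-zero floor
  if (any(is_cmt2_null) && any(cmt2_sites))
    L0[cmt2_sites, is_cmt2_null] <- -5
  if (any(is_dcl3_null) && any(rddm_sites))
    L0[rddm_sites, is_dcl3_null] <- -5

  # environment effect: either the explicit logit shift, or the shift that
  # makes the genome-wide (nuclear) mean CHH level higher at 16C by the
  # target ratio, solved on the simulated site ensemble
  env_effect <- arch$env_effect
  if (is.null(env_effect)) {
    nuc_chh <- chh & !cp
    p10 <- plogis(L0[nuc_chh, , drop = FALSE])
    m10 <- mean(p10 * (1 - eps) + (1 - p10) * eps)
    target <- arch$chh_ratio_16_10 * m10
    # the warm-environment ensemble includes the planted temperature-DMR
    # gains/losses, so the ratio is calibrated genome-wide, not just at
    # unaffected sites
    dmr_shift <- (arch$temp_dmr_effect * var_gain -
                    (arch$temp_dmr_effect + 0.5) * var_loss)[nuc_chh]
    env_effect <- stats::uniroot(function(d) {
      p16 <- plogis(L0[nuc_chh, , drop = FALSE] + d + dmr_shift)
      mean(p16 * (1 - eps) + (1 - p16) * eps) - target
    }, c(-1, 3), tol = 1e-6)$root
  }

  pieces <- vector("list", 2)
  for (e in 1:2) {
    L <- L0
    if (e == 2) {
      L[chh, ] <- L[chh, ] + env_effect
      if (any(var_gain))
        L[var_gain, ] <- L[var_gain, ] + arch$temp_dmr_effect
      if (any(var_loss))
        L[var_loss, ] <- L[var_loss, ] - (arch$temp_dmr_effect + 0.5)
    }
    p <- plogis(L)
    p[cp, ] <- 0
    pobs <- p * (1 - eps) + (1 - p) * eps
    cnt <- with_seed(seeds[4 + e], {
      depth <- matrix(rpois(S * n, cfg$depth_mean), S, n)
      meth <- matrix(rbinom(S * n, depth, pobs), S, n)
      list(depth = depth, meth = meth)
    })
    pieces[[e]] <- tibble::tibble(
      accession = rep(acc, each = S),
      env = environments[e],
      chrom = rep(sites$chrom, n),
      pos = rep(sites$pos, n),
      strand = rep(sites$strand, n),
      context = rep(sites$context, n),
      meth = as.integer(cnt$meth),
      total = as.integer(cnt$depth))
  }

  truth <- structure(list(
    causal_cis = causal_cis,
    major_locus = genotypes$major_locus,
    major_effects = c(a = arch$major_effect_a, b = arch$major_effect_b),
    cmt2_dependent_tes = truth_sets$cmt2,
    rddm_dependent_tes = truth_sets$rddm,
    temp_dmr_hosts = feats[feats$variable %in% TRUE,
                           c("feature_id", "chrom", "start", "end",
                             "variable_direction")],
    gbm_trans_snps = gbm$trans_snps,
    gbm_scores = gbm$score,
    gbm_liability = gbm$liability,
    env_effect = env_effect,
    conversion_error = eps,
    knockouts = list(cmt2 = cmt2_null, dcl3 = dcl3_null)
  ), class = "truth_record")

  list(counts = dplyr::bind_rows(pieces), truth = truth)
}

# Place cytosine sites: dense inside features, 10x sparser outside, plus a
# fully unmethylated chloroplast contig. Baseline logits depend on feature
# type and context.
build_sites <- function(annot, cfg, seed) {
  feats <- annot$features
  lens <- annot$chrom_lengths
  with_seed(seed, {
    out <- vector("list", length(lens))
    for (ci in seq_along(lens)) {
      chromosome <- names(lens)[ci]
      is_cp <- chromosome == annot$chloroplast
      spacing <- if (is_cp) 50 else cfg$site_spacing
      pos <- seq(1L, lens[ci], by = spacing)
      pos <- pos + sample.int(max(spacing - 1, 1), length(pos), replace = TRUE) - 1L
      pos <- unique(pmin(pos, lens[ci]))
      ftype <- rep("intergenic", length(pos))
      fid <- rep(NA_character_, length(pos))
      if (!is_cp) {
        f <- feats[feats$chrom == chromosome, ]
        if (nrow(f)) {
          idx <- findInterval(pos, f$start)
          hit <- idx > 0 & pos <= f$end[pmax(idx, 1)]
          ftype[hit] <- f$type[idx[hit]]
          fid[hit] <- f$feature_id[idx[hit]]
        }
        keep <- ftype != "intergenic" | (seq_along(pos) %% 10 == 0)
        pos <- pos[keep]; ftype <- ftype[keep]; fid <- fid[keep]
      } else {
        ftype <- rep("chloroplast", length(pos))
      }
      ctx <- sample(c("CG", "CHG", "CHH"), length(pos), replace = TRUE,
                    prob = c(0.25, 0.2, 0.55))
      out[[ci]] <- tibble::tibble(
        chrom = chromosome, pos = as.integer(pos),
        strand = sample(c("+", "-"), length(pos), replace = TRUE),
        context = ctx, feature_type = ftype, feature_id = fid)
    }
    sites <- dplyr::bind_rows(out)
    gbm_genes <- feats$feature_id[feats$gbm_gene %in% TRUE]
    base <- dplyr::case_when(
      sites$feature_type == "TE" & sites$context == "CG" ~ 1.7,
      sites$feature_type == "TE" & sites$context == "CHG" ~ -0.6,
      sites$feature_type == "TE" & sites$context == "CHH" ~ -1.6,
      sites$feature_type == "gene" & sites$context == "CG" &
        sites$feature_id %in% gbm_genes ~ -1.5,
      sites$feature_type == "gene" ~ -3.9,
      TRUE ~ -3.5)
    sites$base_logit <- base
    sites
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> ", nrow(x$causal_cis), " cis SNPs; ",
      length(x$cmt2_dependent_tes), " CMT2-dependent TEs; ",
      length(x$rddm_dependent_tes), " RdDM-dependent TEs; ",
      nrow(x$temp_dmr_hosts), " temperature-DMR hosts\n", sep = "")
  invisible(x)
}
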