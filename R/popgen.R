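#' Hudson Fst between two populations
#'
#' Per-site Hudson estimator: with sample allele frequencies `p1, p2` and
#' haploid sample sizes `n1, n2`, the numerator is
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`. The genome-wide value combines sites as a ratio
#' of averages (sum of numerators over sum of denominators); the
#' average-of-ratios value is also reported for comparison. Sites
#' monomorphic in both populations (zero denominator) are excluded.
#'
#' @param g A `geno_table` (inbred accessions: one haploid-equivalent
#'   allele each), or 0/1 matrix.
#' @param labels Optional tibble with `accession`, `group` (two groups);
#'   defaults to the `region` column of the genotype table.
#' @return List of class `fst_result`: `per_site` tibble (`snp_id`,
#'   `p1`, `p2`, `numerator`, `denominator`, `fst`), `fst` (ratio of
#'   averages), `fst_mean_of_ratios`, `n_sites_used`.
#' @export
hudson_fst <- function(g, labels = NULL) {
  calls <- if (inherits(g, "geno_table")) g$calls else as.matrix(g)
  if (is.null(labels)) {
    stopf(inherits(g, "geno_table"), "labels required for a bare matrix")
    labels <- tibble::tibble(accession = g$accessions$accession,
                             group = g$accessions$region)
  }
  grp <- labels$group[match(rownames(calls), labels$accession)]
  stopf(!anyNA(grp), "every accession must be labelled")
  gl <- sort(unique(grp))
  stopf(length(gl) == 2, "exactly two populations required")
  g1 <- calls[grp == gl[1], , drop = FALSE]
  g2 <- calls[grp == gl[2], , drop = FALSE]
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  stopf(all(n1 >= 2) && all(n2 >= 2),
        "need >= 2 sampled alleles per population per site")
  p1 <- colMeans(g1, na.rm = TRUE); p2 <- colMeans(g2, na.rm = TRUE)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  per_site <- tibble::tibble(
    snp_id = colnames(calls) %||% as.character(seq_along(p1)),
    p1 = p1, p2 = p2, numerator = num, denominator = den,
    fst = ifelse(keep, num / den, NA_real_))
  structure(list(per_site = per_site,
                 fst = sum(num[keep]) / sum(den[keep]),
                 fst_mean_of_ratios = mean(num[keep] / den[keep]),
                 n_sites_used = sum(keep),
                 populations = gl),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> Hudson Fst (ratio of averages) = ", round(x$fst, 4),
      " over ", x$n_sites_used, " sites (", paste(x$populations, collapse = " vs "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_site

#' @export
glance.fst_result <- function(x, ...)
  tibble::tibble(fst = x$fst, fst_mean_of_ratios = x$fst_mean_of_ratios,
                 n_sites_used = x$n_sites_used)

#' Haseman--Elston additive genetic variance
#'
#' Regresses the pairwise phenotype cross-products `y_i y_j` (i < j, with
#' the phenotype centered within the analysis group) on the corresponding
#' kinship entries `K[i, j]`, with an intercept. The slope estimates the
#' additive genetic variance and is floored at zero.
#'
#' Since the phenotype is mean-centered, the kinship is Gower
#' double-centered for the regression (the covariance of centered
#' phenotypes is the double-centered kinship scaled by the additive
#' variance); without this the slope is attenuated whenever relatedness
#' has row structure, as in a two-population panel. The centered kinship
#' is then rescaled to mean diagonal 1, so the slope is the additive
#' variance on the observable per-individual scale (the usual GRM
#' normalization).
#'
#' @param y Phenotype vector aligned to the rows of `K`.
#' @param K Kinship / IBS matrix.
#' @param center Center `y` (and correspondingly double-center `K`)
#'   before forming cross-products (default TRUE).
#' @return Scalar `sigma2_A` with attribute `slope` (unfloored) and
#'   `intercept`.
#' @export
he_additive_variance <- function(y, K, center = TRUE) {
  stopf(length(y) == nrow(K), "y and K dimensions differ")
  Kr <- K
  if (center) {
    y <- y - mean(y)
    rm_ <- rowMeans(K)
    Kr <- K - outer(rm_, rep(1, ncol(K))) -
      outer(rep(1, nrow(K)), colMeans(K)) + mean(K)
    Kr <- Kr / mean(diag(Kr))
  }
  ut <- upper.tri(Kr)
  kij <- Kr[ut]
  stopf(sd(kij) > 0, "constant kinship off-diagonals: slope undefined")
  cp <- tcrossprod(y)[ut]
  fit <- lm.fit(cbind(1, kij), cp)
  slope <- coef(fit)[2]
  structure(max(0, slope), slope = unname(slope),
            intercept = unname(coef(fit)[1]))
}

#' Qst for a quantitative trait across two populations
#'
#' Estimates the overall, northern and southern additive variances by
#' Haseman--Elston regression on SNP-based IBS matrices (each population's
#' matrix computed on its own subsample so the IBS normalization stays
#' internal), forms the weighted within-population variance (weights
#' `n_k - 1`), the between-population variance as the excess of the
#' overall additive variance over the within component (floored at zero),
#' and `Qst = sigma2_B / (sigma2_B + 2 sigma2_w)`.
#'
#' @param y Named phenotype vector or tibble (`accession`, `value`).
#' @param g A `geno_table`.
#' @param labels Optional tibble `accession`, `group`; defaults to the
#'   genotype table's regions.
#' @return One-row tibble of class `qst_result`: the three additive
#'   variances, `sigma2_w`, `sigma2_B`, `qst`, `degenerate` flag.
#' @export
qst <- function(y, g, labels = NULL) {
  stopf(inherits(g, "geno_table"), "g must be a geno_table")
  if (is.null(labels))
    labels <- tibble::tibble(accession = g$accessions$accession,
                             group = g$accessions$region)
  y <- align_phenotype(y, rownames(g$calls))
  names(y) <- rownames(g$calls)
  grp <- labels$group[match(names(y), labels$accession)]
  gl <- sort(unique(grp))
  stopf(length(gl) == 2, "exactly two populations required")
  ns <- table(grp)[gl]
  stopf(all(ns >= 4), "both populations need >= 4 accessions")

  sig_overall <- he_additive_variance(y, kinship_ibs(g))
  sig_g <- vapply(gl, function(lv) {
    acc <- names(y)[grp == lv]
    sub <- subset_accessions(g, acc)
    he_additive_variance(y[acc], kinship_ibs(sub))
  }, numeric(1))
  out <- qst_from_variances(as.numeric(sig_overall), sig_g[1], sig_g[2],
                            as.numeric(ns[1]), as.numeric(ns[2]))
  names(out)[2:3] <- paste0("sigma2_", gl)
  class(out) <- c("qst_result", class(out))
  out
}

#' @rdname qst
#' @param sigma2_overall,sigma2_1,sigma2_2 Overall and per-population
#'   additive variances.
#' @param n_1,n_2 Population sample sizes (the within-population weights
#'   are `n_k - 1`).
#' @return `qst_from_variances()` returns the same one-row tibble from
#'   already-estimated variances; exposed so the combination rule can be
#'   checked in closed form.
#' @export
qst_from_variances <- function(sigma2_overall, sigma2_1, sigma2_2, n_1, n_2) {
  w <- c(n_1, n_2) - 1
  sigma2_w <- sum(w * c(sigma2_1, sigma2_2)) / sum(w)
  sigma2_B <- max(0, sigma2_overall - sigma2_w)
  denom <- sigma2_B + 2 * sigma2_w
  tibble::tibble(
    sigma2_overall = sigma2_overall,
    sigma2_1 = sigma2_1, sigma2_2 = sigma2_2,
    sigma2_w = sigma2_w, sigma2_B = sigma2_B,
    qst = if (denom > 0) sigma2_B / denom else NA_real_,
    degenerate = denom <= 0)
}

#' Correlations with environment-of-origin variables
#'
#' Pairwise-complete Pearson and Spearman correlations of per-accession
#' methylation averages (by context and growth temperature) with
#' environment-of-origin variables, with the two-sided Spearman p-value —
#' the layout of climate-correlation tables.
#'
#' @param pheno Tibble with `accession`, `context`, `env`, `level`.
#' @param env_table Tibble with `accession` plus one column per
#'   environment variable (e.g. latitude).
#' @return Tibble: `context`, `env`, `variable`, `pearson_r`,
#'   `spearman_rho`, `p` (`NA` for zero-variance variables).
#' @export
env_correlations <- function(pheno, env_table) {
  vars <- setdiff(names(env_table), "accession")
  combos <- dplyr::distinct(pheno[, c("context", "env")])
  purrr::pmap_dfr(combos, function(context, env) {
    d <- dplyr::inner_join(
      pheno[pheno$context == context & pheno$env == env, ],
      env_table, by = "accession")
    purrr::map_dfr(vars, function(v) {
      ok <- complete.cases(d$level, d[[v]])
      if (sum(ok) < 3 || sd(d[[v]][ok]) == 0 || sd(d$level[ok]) == 0)
        return(tibble::tibble(context = context, env = env, variable = v,
                              pearson_r = NA_real_, spearman_rho = NA_real_,
                              p = NA_real_))
      ct <- suppressWarnings(
        cor.test(d$level[ok], d[[v]][ok], method = "spearman", exact = FALSE))
      tibble::tibble(context = context, env = env, variable = v,
                     pearson_r = cor(d$level[ok], d[[v]][ok]),
                     spearman_rho = unname(ct$estimate),
                     p = ct$p.value)
    })
  })
}

#' Allele frequencies by region and latitude correlation for a SNP set
#'
#' Per-SNP non-reference allele frequency in each region, point-biserial
#' correlation between the allele and accession latitude, and a
#' Kolmogorov--Smirnov comparison of the set's overall frequency spectrum
#' against randomly drawn background SNPs.
#'
#' @param g A `geno_table`.
#' @param snp_set Character vector of SNP ids.
#' @param n_background Number of random background SNPs (default
#'   `10 * length(snp_set)`, capped at the panel size).
#' @param seed Seed for the background draw.
#' @return List of class `allele_geography`: `per_snp` tibble (`snp_id`,
#'   `freq_<region>`, `freq_all`, `latitude_cor`), `background`
#'   (frequencies of the random SNPs), `ks` (statistic and p-value).
#' @export
allele_geography <- function(g, snp_set, n_background = NULL, seed = 1) {
  stopf(inherits(g, "geno_table"), "g must be a geno_table")
  stopf(length(snp_set) > 0, "empty SNP set")
  stopf(all(snp_set %in% colnames(g$calls)), "unknown SNP ids in set")
  calls <- g$calls
  lat <- g$accessions$latitude
  regions <- sort(unique(g$accessions$region))
  per_snp <- tibble::tibble(snp_id = snp_set)
  for (r in regions) {
    sel <- g$accessions$region == r
    per_snp[[paste0("freq_", r)]] <-
      colMeans(calls[sel, snp_set, drop = FALSE], na.rm = TRUE)
  }
  per_snp$freq_all <- colMeans(calls[, snp_set, drop = FALSE], na.rm = TRUE)
  per_snp$latitude_cor <- apply(calls[, snp_set, drop = FALSE], 2, function(s) {
    if (sd(s, na.rm = TRUE) == 0) return(NA_real_)
    cor(s, lat, use = "pairwise.complete.obs")
  })
  pool <- setdiff(colnames(calls), snp_set)
  nb <- min(n_background %||% (10 * length(snp_set)), length(pool))
  bg_ids <- with_seed(seed, sample(pool, nb))
  bg <- colMeans(calls[, bg_ids, drop = FALSE], na.rm = TRUE)
  ks <- suppressWarnings(ks.test(per_snp$freq_all, bg))
  structure(list(per_snp = per_snp,
                 background = tibble::tibble(snp_id = bg_ids, freq_all = bg),
                 ks = tibble::tibble(statistic = unname(ks$statistic),
                                     p = ks$p.value)),
            class = "allele_geography")
}

#' Permutation enrichment of a SNP set in genomic regions
#'
#' Counts how many SNPs of a focal set fall inside target regions (or
#' within `flank` bp of anchor SNPs), then draws `n_perm`
#' frequency-matched random SNP sets of the same size (allele-frequency
#' bins of width `maf_bin`; uniform draws as a logged fallback when a bin
#' cannot be matched) to obtain the fold enrichment
#' `observed / mean(null)` and the add-one empirical p-value.
#'
#' @param g A `geno_table`.
#' @param snp_set Character vector of focal SNP ids.
#' @param regions Tibble `chrom`, `start`, `end`; or NULL when using
#'   `anchors`.
#' @param anchors Character vector of anchor SNP ids (used with `flank`).
#' @param flank Distance around anchors in bp (e.g. 2000).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param freq_match Frequency-match the null draws (default TRUE).
#' @param maf_bin Width of the matching frequency bins.
#' @return One-row tibble: `observed`, `expected` (null mean), `fold`,
#'   `p`, `n_perm`.
#' @export
snp_overlap_permutation <- function(g, snp_set, regions = NULL,
                                    anchors = NULL, flank = 2000,
                                    n_perm = 1000, seed = 1,
                                    freq_match = TRUE, maf_bin = 0.02) {
  stopf(inherits(g, "geno_table"), "g must be a geno_table")
  stopf(xor(is.null(regions), is.null(anchors)),
        "supply exactly one of regions or anchors")
  snps <- g$snps
  if (is.null(regions)) {
    an <- snps[match(anchors, snps$snp_id), ]
    regions <- tibble::tibble(chrom = an$chrom,
                              start = pmax(1, an$pos - flank),
                              end = an$pos + flank)
  }
  gr_snp <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, width = 1))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start, regions$end))
  inside <- GenomicRanges::countOverlaps(gr_snp, gr_reg) > 0
  names(inside) <- snps$snp_id
  observed <- sum(inside[snp_set])

  freq <- colMeans(g$calls, na.rm = TRUE)
  bins <- cut(pmin(freq, 1 - freq), seq(0, 0.5 + maf_bin, by = maf_bin),
              include.lowest = TRUE)
  names(bins) <- colnames(g$calls)
  all_ids <- colnames(g$calls)
  null <- with_seed(seed, {
    if (freq_match) {
      by_bin <- split(all_ids, bins)
      set_bins <- as.character(bins[snp_set])
      can_match <- all(vapply(set_bins,
                              function(b) length(by_bin[[b]]) >= 1, logical(1)))
      if (!can_match) {
        inform("cannot frequency-match; falling back to uniform draws")
        freq_match <- FALSE
      }
    }
    vapply(seq_len(n_perm), function(i) {
      draw <- if (freq_match)
        vapply(set_bins, function(b) {
          ids <- by_bin[[b]]
          ids[sample.int(length(ids), 1)]
        }, character(1))
      else all_ids[sample.int(length(all_ids), length(snp_set))]
      sum(inside[draw])
    }, numeric(1))
  })
  expected <- mean(null)
  tibble::tibble(observed = observed, expected = expected,
                 fold = if (expected > 0) observed / expected else NA_real_,
                 p = (sum(null >= observed) + 1) / (n_perm + 1),
                 n_perm = n_perm)
}

#' North/south expression contrasts for GBM and non-GBM genes
#'
#' Normalizes expression by each sample's effective library size (the
#' median over genes), then per gene class (GBM vs non-GBM) and
#' environment compares per-accession class-mean expression between the
#' two regions (Wilcoxon rank-sum); additionally compares the per-gene
#' between-temperature variation (|warm - cool| of the gene's regional
#' mean) between regions, and reports each accession's GBM-class mean
#' expression normalized by its non-GBM mean.
#'
#' @param expression Tibble `gene_id`, `accession`, `env`, `expression`.
#' @param gene_labels Tibble `gene_id`, `label` with labels `"GBM"` and
#'   anything else treated as non-GBM.
#' @param labels Tibble `accession`, `group` (two regions).
#' @param normalize Apply median library-size normalization.
#' @return List of class `expression_comparison`: `class_contrast`
#'   (label, env, group medians, Wilcoxon p), `temp_variation` (label,
#'   per-region mean |delta|, Wilcoxon p), `gbm_ratio` (accession,
#'   group, GBM/non-GBM expression ratio).
#' @export
expression_comparisons <- function(expression, gene_labels, labels,
                                   normalize = TRUE) {
  lab <- dplyr::mutate(gene_labels,
                       class = ifelse(.data$label == "GBM", "GBM", "non-GBM"))
  x <- dplyr::inner_join(expression, lab[, c("gene_id", "class")], by = "gene_id")
  x <- dplyr::inner_join(x, labels, by = "accession")
  cls_sizes <- table(unique(x[, c("gene_id", "class")])$class)
  keep_cls <- names(cls_sizes)[cls_sizes >= 2]
  x <- dplyr::filter(x, .data$class %in% keep_cls)
  if (normalize) {
    libsize <- dplyr::summarise(
      dplyr::group_by(expression, .data$accession, .data$env),
      lib = median(.data$expression), .groups = "drop")
    x <- dplyr::mutate(dplyr::inner_join(x, libsize, by = c("accession", "env")),
                       expression = .data$expression / .data$lib)
  }
  acc_mean <- dplyr::summarise(
    dplyr::group_by(x, .data$accession, .data$group, .data$env, .data$class),
    mean_expr = mean(log2(.data$expression + 1e-9)), .groups = "drop")
  gl <- sort(unique(labels$group))
  class_contrast <- dplyr::summarise(
    dplyr::group_by(acc_mean, .data$class, .data$env),
    median_1 = median(.data$mean_expr[.data$group == gl[1]]),
    median_2 = median(.data$mean_expr[.data$group == gl[2]]),
    p = wilcox.test(.data$mean_expr[.data$group == gl[1]],
                    .data$mean_expr[.data$group == gl[2]])$p.value,
    .groups = "drop")
  names(class_contrast)[3:4] <- paste0("median_", gl)

  gene_env <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id, .data$class, .data$group, .data$env),
    m = mean(log2(.data$expression + 1e-9)), .groups = "drop")
  deltas <- dplyr::summarise(
    dplyr::group_by(gene_env, .data$gene_id, .data$class, .data$group),
    delta = abs(diff(.data$m[order(.data$env)])), .groups = "drop")
  temp_variation <- dplyr::summarise(
    dplyr::group_by(deltas, .data$class),
    mean_delta_1 = mean(.data$delta[.data$group == gl[1]]),
    mean_delta_2 = mean(.data$delta[.data$group == gl[2]]),
    p = wilcox.test(.data$delta[.data$group == gl[1]],
                    .data$delta[.data$group == gl[2]])$p.value,
    .groups = "drop")
  names(temp_variation)[2:3] <- paste0("mean_delta_", gl)

  wide <- tidyr::pivot_wider(acc_mean, names_from = "class",
                             values_from = "mean_expr")
  gbm_ratio <- if (all(c("GBM", "non-GBM") %in% names(wide)))
    dplyr::transmute(wide, accession = .data$accession, group = .data$group,
                     env = .data$env,
                     gbm_ratio = .data$GBM - .data$`non-GBM`)
  else NULL
  structure(list(class_contrast = class_contrast,
                 temp_variation = temp_variation,
                 gbm_ratio = gbm_ratio),
            class = "expression_comparison")
}

#' @export
print.expression_comparison <- function(x, ...) {
  print(x$class_contrast)
  invisible(x)
}
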