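test_that("Hudson Fst matches the per-site brute-force oracle exactly", {
  set.seed(1)
  n1 <- 9; n2 <- 11
  G <- matrix(rbinom((n1 + n2) * 60, 1, runif(60)[rep(1:60, each = n1 + n2)]),
              n1 + n2)
  rownames(G) <- paste0("a", seq_len(n1 + n2))
  labels <- tibble::tibble(accession = rownames(G),
                           group = rep(c("north", "south"), c(n1, n2)))
  f <- hudson_fst(G, labels)
  for (j in seq_len(60)) {
    o <- hudson_site_oracle(G[1:n1, j], G[n1 + 1:n2, j])
    expect_equal(f$per_site$numerator[j], unname(o["num"]), tolerance = 1e-12)
    expect_equal(f$per_site$denominator[j], unname(o["den"]), tolerance = 1e-12)
  }
  # genome value is the ratio of averages, and differs from mean of ratios
  keep <- f$per_site$denominator > 0
  expect_equal(f$fst, sum(f$per_site$numerator[keep]) /
                 sum(f$per_site$denominator[keep]), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f$fst, f$fst_mean_of_ratios)))
})

test_that("Hudson Fst handles fixation and the balanced plug-in case", {
  G <- rbind(matrix(1, 10, 1), matrix(0, 10, 1))
  rownames(G) <- paste0("a", 1:20)
  labels <- tibble::tibble(accession = rownames(G),
                           group = rep(c("n", "s"), each = 10))
  expect_equal(hudson_fst(G, labels)$per_site$fst, 1)
  # p1 = p2 = 0.5 with n = 10 each: numerator -0.0556, denominator 0.5
  G2 <- rbind(matrix(rep(c(1, 0), 5), 10, 1), matrix(rep(c(1, 0), 5), 10, 1))
  rownames(G2) <- paste0("a", 1:20)
  f2 <- hudson_fst(G2, labels)
  expect_equal(f2$per_site$numerator, -2 * 0.25 / 9, tolerance = 1e-12)
  expect_equal(f2$per_site$denominator, 0.5)
  expect_equal(f2$per_site$fst, -1 / 9, tolerance = 1e-9)
  # monomorphic-in-both sites are excluded
  G3 <- cbind(G, 0)
  f3 <- hudson_fst(G3, labels)
  expect_identical(f3$n_sites_used, 1L)
})

test_that("Haseman-Elston variance is scale-equivariant and null-calibrated", {
  K <- random_grm(100, 300, seed = 2)
  set.seed(3)
  y <- rmvn_scaled(K, 0.5) + rnorm(100, 0, sqrt(0.5))
  v1 <- he_additive_variance(y, K)
  v2 <- he_additive_variance(2 * y, K)
  expect_equal(attr(v2, "slope"), 4 * attr(v1, "slope"), tolerance = 1e-10)
  # independent phenotype: small additive variance on average
  set.seed(4)
  nulls <- replicate(60, attr(he_additive_variance(rnorm(100), K), "slope"))
  expect_lt(abs(mean(nulls)), 0.05)
  expect_error(he_additive_variance(rnorm(4), matrix(0.5, 4, 4) + diag(0.5, 4)),
               "constant kinship")
})

test_that("h2 = 0.5 is recovered from simulated kinship at n = 150", {
  h <- vapply(1:20, function(s) {
    cfg <- sim_config(n_accessions = 150, n_snps = 300, genome_length = 1e6,
                      n_genes = 10, n_tes = 10, fst_target = 0, seed = s)
    g <- simulate_genotypes(cfg)
    K <- kinship_ibs(g)
    C <- diag(150) - 1 / 150
    Kc <- C %*% K %*% C; Kc <- Kc / mean(diag(Kc))
    y <- with_test_seed(s + 500, rmvn_scaled(Kc, 0.5) + rnorm(150, 0, sqrt(0.5)))
    as.numeric(he_additive_variance(y, K)) / var(y)
  }, numeric(1))
  expect_gt(median(h), 0.3)
  expect_lt(median(h), 0.7)
})

test_that("Qst combination rule is exact in closed form", {
  # sigma2_B = 0 when the overall variance equals the within component
  q0 <- qst_from_variances(0.5, 0.5, 0.5, 20, 20)
  expect_equal(q0$qst, 0)
  # sigma2_B = sigma2_w gives exactly 1/3
  q13 <- qst_from_variances(1.0, 0.5, 0.5, 20, 20)
  expect_identical(q13$qst, 1 / 3)
  # weights are n_k - 1
  qw <- qst_from_variances(1.0, 0.3, 0.9, 11, 31)
  expect_equal(qw$sigma2_w, (10 * 0.3 + 30 * 0.9) / 40)
  # flooring keeps Qst in [0, 1]
  qf <- qst_from_variances(0.1, 0.5, 0.5, 20, 20)
  expect_equal(qf$qst, 0)
  qd <- qst_from_variances(0, 0, 0, 20, 20)
  expect_true(qd$degenerate)
  expect_true(is.na(qd$qst))
})

test_that("a diverged polygenic trait shows Qst above Fst", {
  wins <- vapply(1:10, function(s) {
    cfg <- sim_config(n_accessions = 100, n_snps = 2000, genome_length = 1e6,
                      n_genes = 10, n_tes = 10, fst_target = 0.187, seed = s)
    g <- simulate_genotypes(cfg)
    north <- g$accessions$region == "north"
    p_n <- colMeans(g$calls[north, ]); p_s <- colMeans(g$calls[!north, ])
    top <- order(abs(p_n - p_s), decreasing = TRUE)[1:15]
    eff <- 0.4 * sign(p_n - p_s)[top]   # north-polarized, like a GBM trait
    y <- with_test_seed(s + 900,
                        drop(g$calls[, top] %*% eff) + rnorm(100, 0, 0.3))
    q <- qst(setNames(y, rownames(g$calls)), g)
    q$qst > hudson_fst(g)$fst
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("environment correlations recover a planted latitude coupling", {
  set.seed(6)
  n <- 150
  lat <- c(runif(n * 0.4, 63, 68), runif(n * 0.6, 55, 59))
  z <- scale(lat)[, 1]
  level <- 0.2 + 0.05 * (0.7 * z + sqrt(1 - 0.49) * rnorm(n))
  pheno <- tibble::tibble(accession = paste0("a", 1:n), context = "CG",
                          env = "10C", level = level)
  env_table <- tibble::tibble(accession = paste0("a", 1:n), latitude = lat)
  ec <- env_correlations(pheno, env_table)
  expect_equal(ec$pearson_r, 0.7, tolerance = 0.1)
  expect_lt(ec$p, 1e-6)
  # the phenotype correlates perfectly with itself
  self_tab <- tibble::tibble(accession = paste0("a", 1:n), self = level)
  ec2 <- env_correlations(pheno, self_tab)
  expect_equal(ec2$pearson_r, 1)
  expect_equal(ec2$spearman_rho, 1)
  # zero-variance variable is reported missing
  const_tab <- tibble::tibble(accession = paste0("a", 1:n), flat = 1)
  expect_true(is.na(env_correlations(pheno, const_tab)$pearson_r))
})

test_that("allele geography separates regional frequency patterns", {
  cfg <- sim_config(n_accessions = 80, n_snps = 1500, genome_length = 1e6,
                    n_genes = 10, n_tes = 10, fst_target = 0.187, seed = 3)
  g <- simulate_genotypes(cfg)
  north <- g$accessions$region == "north"
  p_n <- colMeans(g$calls[north, ]); p_s <- colMeans(g$calls[!north, ])
  # north-restricted SNPs: present in north, absent in south
  restricted <- colnames(g$calls)[p_n > 0.15 & p_s == 0]
  if (length(restricted) >= 3) {
    ag <- allele_geography(g, restricted, seed = 1)
    expect_true(all(ag$per_snp$freq_north > 0))
    expect_true(all(ag$per_snp$freq_south == 0))
    expect_true(all(ag$per_snp$latitude_cor > 0, na.rm = TRUE))
  }
  # a random SNP set has latitude correlations centered at zero
  rnd <- with_test_seed(2, sample(colnames(g$calls), 100))
  ag2 <- allele_geography(g, rnd, seed = 2)
  expect_lt(abs(mean(ag2$per_snp$latitude_cor, na.rm = TRUE)), 0.1)
  expect_error(allele_geography(g, character()), "empty")
})

test_that("SNP-set region enrichment is calibrated and floors its p", {
  cfg <- sim_config(n_accessions = 60, n_snps = 2000, genome_length = 1e6,
                    n_genes = 10, n_tes = 10, seed = 4)
  g <- simulate_genotypes(cfg)
  # regions covering the whole genome: fold 1, p near 1
  whole <- tibble::tibble(chrom = names(g$chrom_lengths),
                          start = 1, end = unname(g$chrom_lengths))
  res <- snp_overlap_permutation(g, with_test_seed(1, sample(colnames(g$calls), 40)),
                                 regions = whole, n_perm = 99, seed = 1)
  expect_equal(res$fold, 1)
  expect_gt(res$p, 0.9)
  # set drawn entirely from regions holding ~10% of SNPs: fold near 10
  on1 <- g$snps[g$snps$chrom == "Chr1", ]
  tenth <- tibble::tibble(chrom = "Chr1", start = 1,
                          end = stats::quantile(on1$pos, 0.5))
  inside <- on1$snp_id[on1$pos <= tenth$end]
  # fraction of all SNPs inside:
  frac <- length(inside) / ncol(g$calls)
  res2 <- snp_overlap_permutation(g, with_test_seed(2, sample(inside, 15)),
                                  regions = tenth, n_perm = 199, seed = 2,
                                  freq_match = FALSE)
  expect_equal(res2$fold, 1 / frac, tolerance = 0.25)
  expect_equal(res2$p, 1 / 200)
  # reproducibility under seed
  res3 <- snp_overlap_permutation(g, with_test_seed(2, sample(inside, 15)),
                                  regions = tenth, n_perm = 199, seed = 2,
                                  freq_match = FALSE)
  expect_identical(res2, res3)
})

test_that("expression contrasts find planted GBM coupling and normalize", {
  pan <- small_panel(13)
  expr <- simulate_expression(pan$g, pan$an, pan$truth, pan$cfg, coupling = 1.2)
  gbm_label <- tibble::tibble(
    gene_id = pan$an$features$feature_id[pan$an$features$type == "gene"])
  gbm_label$label <- ifelse(gbm_label$gene_id %in%
                              rownames(pan$truth$gbm_liability), "GBM", "other")
  labels <- tibble::tibble(accession = pan$g$accessions$accession,
                           group = pan$g$accessions$region)
  res <- expression_comparisons(expr, gbm_label, labels)
  expect_true(all(c("class", "env", "p") %in% names(res$class_contrast)))
  expect_identical(nrow(res$class_contrast), 4L)    # 2 classes x 2 envs
  # identical groups: build expression with no regional signal
  expr0 <- simulate_expression(pan$g, pan$an, pan$truth, pan$cfg, coupling = 0)
  res0 <- expression_comparisons(expr0, gbm_label, labels)
  expect_true(all(res0$class_contrast$p > 0.001))
  # a planted 2x library confounder is removed by median normalization
  libf <- setNames(ifelse(pan$g$accessions$region == "north", 2, 1),
                   pan$g$accessions$accession)
  expr_conf <- simulate_expression(pan$g, pan$an, pan$truth, pan$cfg,
                                   coupling = 0, library_factor = libf)
  res_conf <- expression_comparisons(expr_conf, gbm_label, labels)
  res_raw <- expression_comparisons(expr_conf, gbm_label, labels,
                                    normalize = FALSE)
  expect_true(min(res_raw$class_contrast$p) < 1e-3)   # confounder visible raw
  expect_true(all(res_conf$class_contrast$p > 0.001)) # gone after normalization
})
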