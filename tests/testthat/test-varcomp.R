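test_that("relatedness matrices are normalized, PSD and partition SNPs", {
  pan <- small_panel(2)
  g <- pan$g
  # single SNP: rank 1
  poly <- colnames(g$calls)[apply(g$calls, 2, sd) > 0]
  R1 <- relatedness_from_snps(g, poly[1])
  expect_lte(sum(eigen(R1, symmetric = TRUE, only.values = TRUE)$values > 1e-8), 1)
  # all SNPs: agrees with IBS kinship up to normalization
  Rall <- relatedness_from_snps(g, colnames(g$calls))
  K <- kinship_ibs(g)
  expect_gt(cor(Rall[upper.tri(Rall)], K[upper.tri(K)]), 0.9)
  expect_equal(mean(diag(Rall)), 1)
  expect_gte(min(eigen(Rall, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # cis/trans/major partition covers the SNP set exactly once
  anchor <- list(chrom = "Chr1", start = 10000, end = 10200)
  parts <- snp_partition(g, anchor)
  expect_setequal(c(parts$cis, parts$trans, parts$major), g$snps$snp_id)
  expect_identical(length(intersect(parts$cis, parts$trans)), 0L)
  expect_true(all(g$major_locus %in% parts$major))
})

test_that("the Kronecker likelihood equals a dense MVN oracle at N <= 8", {
  set.seed(42)
  N <- 8
  R1 <- random_grm(N, 40, seed = 1)
  R2 <- random_grm(N, 60, seed = 2)
  Y <- matrix(rnorm(N * 2), N, 2)
  params <- c(cmt2.a = 0.5, cmt2.b1 = 0.3, cmt2.b2 = 0.2,
              trans.a = 0.4, trans.b1 = 0.1, trans.b2 = 0.2,
              noise.a = 0.3, noise.b1 = 0.4, noise.b2 = 0.5)
  mu <- c(0.2, -0.1)
  dense_ll <- function(Ymat, mu) {
    V <- matrix(0, 2 * N, 2 * N)
    Rl <- list(cmt2 = R1, trans = R2, noise = diag(N))
    for (k in names(Rl)) {
      a2 <- params[paste0(k, ".a")]^2
      C <- matrix(c(a2 + params[paste0(k, ".b1")]^2, a2, a2,
                    a2 + params[paste0(k, ".b2")]^2), 2)
      for (e in 1:2) for (f in 1:2)
        V[(e - 1) * N + 1:N, (f - 1) * N + 1:N] <-
          V[(e - 1) * N + 1:N, (f - 1) * N + 1:N] + C[e, f] * Rl[[k]]
    }
    obs <- which(!is.na(c(Ymat)))
    mvtnorm::dmvnorm(c(Ymat)[obs], rep(mu, each = N)[obs],
                     V[obs, obs, drop = FALSE], log = TRUE)
  }
  ll <- varcomp_loglik(Y, params, R_cmt2 = R1, R_trans = R2, mu = mu)
  expect_equal(ll, dense_ll(Y, mu), tolerance = 1e-8)
  # with missing cells
  Ym <- Y; Ym[2, 1] <- NA; Ym[5, 2] <- NA
  expect_equal(varcomp_loglik(Ym, params, R_cmt2 = R1, R_trans = R2, mu = mu),
               dense_ll(Ym, mu), tolerance = 1e-8)
})

test_that("the reported optimum is a stationary point of the likelihood", {
  set.seed(3)
  N <- 30
  R1 <- random_grm(N, 50, seed = 4)
  Y <- matrix(rnorm(N * 2), N, 2) + rep(c(0.3, 0.6), each = N)
  fit <- fit_varcomp(Y, R_cmt2 = R1, restarts = 4, seed = 2)
  expect_true(fit$converged)
  ll_hat <- varcomp_loglik(Y, fit$params, R_cmt2 = R1)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  # no small perturbation of the parameters improves the likelihood
  set.seed(10)
  for (i in 1:10) {
    pert <- fit$params + rnorm(length(fit$params), 0, 0.05)
    expect_lte(varcomp_loglik(Y, pert, R_cmt2 = R1), ll_hat + 1e-6)
  }
})

test_that("white-noise phenotypes are assigned to the noise component", {
  N <- 150
  Rc <- random_grm(N, 60, seed = 5)
  Rt <- random_grm(N, 400, seed = 6)
  fracs <- vapply(1:10, function(s) {
    Y <- with_test_seed(s + 40, matrix(rnorm(N * 2), N, 2))
    fit <- fit_varcomp(Y, R_cmt2 = Rc, R_trans = Rt, restarts = 5, seed = s)
    sum(fit$fractions$fraction[fit$fractions$component %in%
                                 c("noise")])
  }, numeric(1))
  expect_gt(median(fracs), 0.9)
})

test_that("planted shared-trans architecture is recovered", {
  N <- 200
  Rt <- random_grm(N, 600, seed = 7)
  errs <- vapply(1:4, function(s) {
    Y <- with_test_seed(s, {
      u <- rmvn_scaled(Rt, 0.4)
      cbind(u + rnorm(N, 0, sqrt(0.2)), u + rnorm(N, 0, sqrt(0.2)))
    })
    fit <- fit_varcomp(Y, R_trans = Rt, restarts = 8, seed = s)
    fr <- setNames(fit$fractions$fraction, fit$fractions$component)
    fr["trans"] - 0.4 / 0.6
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.1)
})

test_that("degenerate designs behave: equal means, duplicate environments", {
  N <- 60
  Rt <- random_grm(N, 200, seed = 8)
  Y <- with_test_seed(9, {
    u <- rmvn_scaled(Rt, 0.5)
    cbind(u + rnorm(N, 0, 0.3), u + rnorm(N, 0, 0.3))
  })
  fit <- fit_varcomp(Y - mean(Y), R_trans = Rt, restarts = 5, seed = 1)
  fr <- setNames(fit$fractions$fraction, fit$fractions$component)
  expect_lt(fr["E"], 0.05)                     # no environment-mean shift
  # duplicated environments: environment-specific parts vanish (shared
  # parts, including environment-shared noise, legitimately remain)
  Ydup <- cbind(Y[, 1], Y[, 1])
  fit2 <- fit_varcomp(Ydup, R_trans = Rt, restarts = 5, seed = 2)
  fr2 <- setNames(fit2$fractions$fraction, fit2$fractions$component)
  expect_lt(fr2[["transxE"]], 0.05)
  specific_noise <- mean(fit2$params[c("noise.b1", "noise.b2")]^2)
  expect_lt(specific_noise, 0.05 * sum(fit2$fractions$variance))
  # error paths
  expect_error(fit_varcomp(Y[, 1, drop = FALSE], R_trans = Rt), "two environments")
  Yempty <- Y; Yempty[, 2] <- NA
  expect_error(fit_varcomp(Yempty, R_trans = Rt), "no observations")
  bad <- Rt; bad[1, 2] <- bad[1, 2] + 5        # asymmetric/non-PSD input
  expect_error(fit_varcomp(Y, R_trans = (bad + t(bad)) / 2 - diag(2, N)),
               "positive semidefinite")
})

test_that("fractions are scale-invariant and refuse non-converged fits", {
  N <- 60
  Rt <- random_grm(N, 200, seed = 10)
  Y <- with_test_seed(11, {
    u <- rmvn_scaled(Rt, 0.3)
    cbind(0.2 + u + rnorm(N, 0, 0.4), 0.6 + u + rnorm(N, 0, 0.4))
  })
  f1 <- fit_varcomp(Y, R_trans = Rt, restarts = 5, seed = 1)
  f2 <- fit_varcomp(5 * Y, R_trans = Rt, restarts = 5, seed = 1)
  expect_equal(f1$fractions$fraction, f2$fractions$fraction, tolerance = 0.02)
  expect_true(f1$converged)
  fake <- f1; fake$converged <- FALSE
  expect_error(partition_variance(fake), "did not converge")
  # loglik is the max over restarts: more restarts never reports worse
  l1 <- fit_varcomp(Y, R_trans = Rt, restarts = 1, seed = 3)$loglik
  l5 <- fit_varcomp(Y, R_trans = Rt, restarts = 5, seed = 3)$loglik
  expect_gte(l5, l1 - 1e-6)
})

test_that("tidiers and binning summarize fits", {
  N <- 50
  Rt <- random_grm(N, 150, seed = 12)
  mk_fit <- function(s, v) {
    Y <- with_test_seed(s, {
      u <- rmvn_scaled(Rt, v)
      cbind(u + rnorm(N, 0, 0.3), u + rnorm(N, 0, 0.3))
    })
    fit_varcomp(Y, R_trans = Rt, restarts = 4, seed = s)
  }
  fits <- list(mk_fit(1, 1.5), mk_fit(2, 0.02))
  td <- tidy(fits[[1]])
  expect_setequal(td$component, c("E", "trans", "transxE", "noise"))
  expect_equal(sum(td$fraction), 1, tolerance = 1e-6)
  gl <- glance(fits[[1]])
  expect_true(gl$converged)
  frac <- dplyr::bind_rows(
    dplyr::mutate(tidy(fits[[1]]), phenotype = "hi"),
    dplyr::mutate(tidy(fits[[2]]), phenotype = "lo"))
  bins <- bin_by_total_variance(frac, n_bins = 5)
  expect_gte(dplyr::n_distinct(bins$bin), 2L)                # separated bins
  # permuting input rows leaves the binning unchanged
  bins2 <- bin_by_total_variance(frac[sample.int(nrow(frac)), ], n_bins = 5)
  expect_equal(dplyr::arrange(bins, bin, component),
               dplyr::arrange(bins2, bin, component))
})

test_that("GBM-like and CHH-like architectures produce the expected contrast", {
  N <- 120
  Rc <- random_grm(N, 20, seed = 13)
  Rt <- random_grm(N, 400, seed = 14)
  # GBM-like: big shared trans, no environment effect
  Y_gbm <- with_test_seed(15, {
    u <- rmvn_scaled(Rt, 0.6)
    cbind(u + rnorm(N, 0, 0.45), u + rnorm(N, 0, 0.45))
  })
  # CHH-like: major-locus + environment mean shift + GxE
  Y_chh <- with_test_seed(16, {
    u <- rmvn_scaled(Rc, 0.35)
    e1 <- rmvn_scaled(Rc, 0.15); e2 <- rmvn_scaled(Rc, 0.15)
    cbind(u + e1 + rnorm(N, 0, 0.45), 0.5 + u + e2 + rnorm(N, 0, 0.45))
  })
  f_gbm <- fit_varcomp(Y_gbm, R_cmt2 = Rc, R_trans = Rt, restarts = 6, seed = 1)
  f_chh <- fit_varcomp(Y_chh, R_cmt2 = Rc, R_trans = Rt, restarts = 6, seed = 2)
  fr_g <- setNames(f_gbm$fractions$fraction, f_gbm$fractions$component)
  fr_c <- setNames(f_chh$fractions$fraction, f_chh$fractions$component)
  # ordering, not magnitudes: trans dominates the GBM-like trait,
  # environment and major-locus terms dominate the CHH-like one
  expect_gt(fr_g[["trans"]], fr_c[["trans"]])
  expect_gt(fr_c[["E"]] + fr_c[["cmt2"]] + fr_c[["cmt2xE"]],
            fr_g[["E"]] + fr_g[["cmt2"]] + fr_g[["cmt2xE"]])
  expect_lt(fr_g[["E"]], 0.05)
})
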