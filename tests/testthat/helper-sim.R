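# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

tiny_cfg <- function(seed = 1, ...) {
  sim_config(n_accessions = 16, n_snps = 400, genome_length = 4.8e5,
             n_chromosomes = 4, n_genes = 30, n_tes = 60, seed = seed, ...)
}

small_panel <- function(seed = 1, ...) {
  cfg <- tiny_cfg(seed, ...)
  g <- simulate_genotypes(cfg)
  an <- simulate_annotations(cfg)
  sim <- simulate_methylomes(g, an, cfg)
  list(cfg = cfg, g = g, an = an, counts = sim$counts, truth = sim$truth)
}

# unstructured normalized GRM from random biallelic draws (no fixed columns)
random_grm <- function(n, m, seed = 1, maf = 0.5) {
  with_test_seed(seed, {
    Z <- matrix(rbinom(n * m, 1, maf), n)
    Z <- Z[, apply(Z, 2, stats::sd) > 0, drop = FALSE]
    R <- tcrossprod(scale(Z)) / ncol(Z)
    R / mean(diag(R))
  })
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# draw from N(0, v * R)
rmvn_scaled <- function(R, v) {
  drop(crossprod(chol(v * R + diag(1e-9, nrow(R))), rnorm(nrow(R))))
}

# cytosine-report tibble for a single sample from per-window latent levels
counts_from_window_p <- function(p_by_win, sites_per = 5, depth = 30,
                                 window = 100, chrom = "Chr1") {
  n_win <- length(p_by_win)
  offs <- round(seq(10, window - 10, length.out = sites_per))
  pos <- as.integer(outer(offs, (seq_len(n_win) - 1) * window, "+"))
  o <- order(pos)
  p <- rep(p_by_win, each = sites_per)[o]
  tot <- rpois(length(pos), depth)
  tibble::tibble(chrom = chrom, pos = pos[o], strand = "+", context = "CHH",
                 meth = rbinom(length(pos), tot, p), total = tot)
}

# two-sided Fisher p by direct hypergeometric-tail summation (oracle)
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  k <- a + b          # row margin
  K <- a + c          # column margin
  xs <- max(0, K + k - n):min(K, k)
  probs <- stats::dhyper(xs, K, n - K, k)
  obs <- stats::dhyper(a, K, n - K, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force per-site Hudson Fst (oracle, scalar arithmetic)
hudson_site_oracle <- function(x1, x2) {
  p1 <- mean(x1); p2 <- mean(x2)
  n1 <- length(x1); n2 <- length(x2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}

# GBM-like diverged trait with a within-population polygenic component
# scaled (from the realized true genetic values, not from any estimate) so
# the planted Qst equals `qst_target`; returns the named phenotype vector.
diverged_trait <- function(g, qst_target = 0.77, noise_sd = 0.3, seed = 1) {
  north <- g$accessions$region == "north"
  p_n <- colMeans(g$calls[north, , drop = FALSE])
  p_s <- colMeans(g$calls[!north, , drop = FALSE])
  top <- order(abs(p_n - p_s), decreasing = TRUE)[1:15]
  eff <- 0.4 * sign(p_n - p_s)[top]
  a_div <- drop(g$calls[, top, drop = FALSE] %*% eff)
  with_test_seed(seed, {
    pool <- setdiff(seq_len(ncol(g$calls)), top)
    rnd <- sample(pool, min(200, length(pool)))
    u <- drop(g$calls[, rnd, drop = FALSE] %*% rnorm(length(rnd), 0, 0.05))
    true_qst <- function(lambda) {
      a <- a_div + lambda * u
      grp <- g$accessions$region
      ns <- table(grp)
      sw <- sum((ns - 1) * tapply(a, grp, var)) / sum(ns - 1)
      sb <- max(0, var(a) - sw)
      sb / (sb + 2 * sw)
    }
    lam <- tryCatch(
      stats::uniroot(function(l) true_qst(l) - qst_target, c(0, 50))$root,
      error = function(e) 0)
    setNames(a_div + lam * u + rnorm(nrow(g$calls), 0, noise_sd),
             rownames(g$calls))
  })
}
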