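#' Identity-by-state kinship matrix
#'
#' Pairwise accession similarity as the fraction of SNPs with identical
#' alleles (pairwise-complete over missing genotypes). The diagonal is 1
#' by definition of IBS on homozygous accessions.
#'
#' @param g A `geno_table` or a 0/1 accession-by-SNP matrix (NA allowed).
#' @return Symmetric accession-by-accession matrix with attribute
#'   `method = "IBS"`.
#' @export
kinship_ibs <- function(g) {
  calls <- if (inherits(g, "geno_table")) g$calls else as.matrix(g)
  stopf(nrow(calls) >= 2, "need at least 2 accessions")
  stopf(!any(colSums(!is.na(calls)) == 0), "SNPs with all genotypes missing")
  obs <- !is.na(calls)
  stopf(all(rowSums(obs) > 0), "accession with all genotypes missing")
  x <- calls; x[!obs] <- 0
  same <- tcrossprod(x) + tcrossprod((1 - x) * obs)
  denom <- tcrossprod(obs * 1)
  K <- same / denom
  diag(K) <- 1
  attr(K, "method") <- "IBS"
  K
}

# Null-model fit of y = X b + u + e, u ~ N(0, sg^2 K): ML profile over the
# variance ratio delta = se^2/sg^2 on the eigenbasis of K (EMMA-style).
# Returns the rotation and GLS machinery reused by every per-SNP test.
lmm_null <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  negll <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    xtwx <- crossprod(Xs, Xs * w)
    beta <- solve(xtwx, crossprod(Xs, ys * w))
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    0.5 * (n * log(rss / n) + sum(log(d + delta)))
  }
  opt <- optimize(negll, c(-10, 10))
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  xtwx <- crossprod(Xs, Xs * w)
  beta <- solve(xtwx, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  sg2 <- sum(w * r^2) / n
  list(U = U, d = d, delta = delta, w = w, ys = ys, Xs = Xs,
       beta = drop(beta), sigma_g2 = sg2, sigma_e2 = sg2 * delta,
       h2 = 1 / (1 + delta), loglik = -opt$objective - n / 2 * (1 + log(2 * pi)))
}

#' Kinship-corrected single-marker association scan
#'
#' Tests each SNP against a phenotype under the linear mixed model
#' `y = SNP b + cofactors + u + e` with `u ~ N(0, sg^2 K)`. The variance
#' ratio is estimated once on the null model (the usual
#' population-parameters-previously-determined approximation) and each SNP
#' is then tested by generalized least squares with a Wald t-test;
#' `exact = TRUE` re-estimates the variance ratio per SNP. SNPs collinear
#' with the cofactors (including the cofactors themselves) are skipped
#' with `p = NA`. The genome-wide significance flag is Bonferroni at
#' `alpha / n_snps_tested`.
#'
#' @param y Named phenotype vector (names = accessions) or tibble with
#'   `accession` and `value` columns.
#' @param g A `geno_table`.
#' @param K Kinship matrix (default [kinship_ibs()] of `g`).
#' @param cofactors Character vector of SNP ids included as fixed
#'   covariates.
#' @param maf_min Minor-allele-frequency filter (default 0.05); filtered
#'   SNPs are absent from the result.
#' @param alpha Genome-wide significance level before Bonferroni division.
#' @param exact Re-estimate variance components per SNP (slow).
#' @return Tibble of class `assoc_scan`: `snp_id`, `chrom`, `pos`,
#'   `maf`, `beta`, `se`, `p`, `significant`. Attributes carry the null
#'   fit (`h2`, variance ratio) and the Bonferroni threshold.
#' @export
lmm_scan <- function(y, g, K = NULL, cofactors = character(),
                     maf_min = 0.05, alpha = 0.05, exact = FALSE) {
  stopf(inherits(g, "geno_table"), "g must be a geno_table")
  y <- align_phenotype(y, rownames(g$calls))
  if (is.null(K)) K <- kinship_ibs(g)
  calls <- g$calls
  n <- nrow(calls)

  # mean-impute missing genotypes per SNP
  if (anyNA(calls)) {
    mu <- colMeans(calls, na.rm = TRUE)
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- mu[idx[, 2]]
  }
  maf <- pmin(colMeans(calls), 1 - colMeans(calls))
  test_ids <- colnames(calls)[maf >= maf_min]
  test_ids <- setdiff(test_ids, cofactors)

  X <- matrix(1, n, 1)
  if (length(cofactors)) {
    stopf(all(cofactors %in% colnames(calls)), "unknown cofactor SNP ids")
    X <- cbind(X, calls[, cofactors, drop = FALSE])
  }
  null <- lmm_null(y, K, X)

  S <- crossprod(null$U, calls[, test_ids, drop = FALSE])
  w <- null$w
  # residualize SNPs and phenotype against X under the GLS weights
  Xs <- null$Xs
  xtwx <- crossprod(Xs, Xs * w)
  px <- function(M) M - Xs %*% solve(xtwx, crossprod(Xs, M * w))
  Sr <- px(S)
  yr <- px(null$ys)
  stw <- colSums(w * Sr^2)
  sty <- colSums(w * Sr * drop(yr))
  yty <- sum(w * yr^2)
  p_fixed <- ncol(Xs)
  dfree <- n - p_fixed - 1
  ok <- stw > 1e-10
  beta <- se <- pval <- rep(NA_real_, length(test_ids))
  beta[ok] <- sty[ok] / stw[ok]
  rss <- yty - sty^2 / stw
  sigma2 <- rss / dfree
  se[ok] <- sqrt(sigma2[ok] / stw[ok])
  tstat <- beta / se
  pval[ok] <- 2 * pt(abs(tstat[ok]), dfree, lower.tail = FALSE)

  if (exact) {
    for (j in which(ok)) {
      fit <- lmm_null(y, K, cbind(X, calls[, test_ids[j]]))
      # Wald on the SNP coefficient under the per-SNP variance estimate
      k <- ncol(X) + 1
      Xj <- crossprod(null$U, cbind(X, calls[, test_ids[j]]))
      wj <- 1 / (null$d + fit$delta)
      xtwxj <- crossprod(Xj, Xj * wj)
      covb <- solve(xtwxj) * fit$sigma_g2 * n / (n - k)
      beta[j] <- fit$beta[k]
      se[j] <- sqrt(covb[k, k])
      pval[j] <- 2 * pt(abs(beta[j] / se[j]), n - k, lower.tail = FALSE)
    }
  }

  thresh <- alpha / sum(ok)
  snps <- g$snps[match(test_ids, g$snps$snp_id), ]
  out <- tibble::tibble(snp_id = test_ids,
                        chrom = snps$chrom, pos = snps$pos,
                        maf = maf[test_ids],
                        beta = beta, se = se, p = pval,
                        significant = !is.na(pval) & pval <= thresh)
  structure(out, class = c("assoc_scan", class(out)),
            null_fit = null[c("delta", "sigma_g2", "sigma_e2", "h2", "loglik")],
            bonferroni = thresh, cofactors = cofactors)
}

align_phenotype <- function(y, accessions) {
  if (is.data.frame(y)) {
    stopf(all(c("accession", "value") %in% names(y)),
          "phenotype tibble needs accession and value columns")
    y <- setNames(y$value, y$accession)
  }
  if (!is.null(names(y))) {
    stopf(all(accessions %in% names(y)), "phenotype missing some accessions")
    y <- y[accessions]
  } else {
    stopf(length(y) == length(accessions),
          "unnamed phenotype must match the accession count")
  }
  stopf(!anyNA(y), "phenotype contains NA")
  as.numeric(y)
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat("<assoc_scan> ", nrow(x), " SNPs tested; ", sum(x$significant),
      " significant (Bonferroni p <= ", signif(attr(x, "bonferroni"), 3),
      "); null h2 = ", round(attr(x, "null_fit")$h2, 3), "\n", sep = "")
  NextMethod()
}

#' Stepwise multi-locus scan
#'
#' Iteratively adds the most significant SNP as a fixed-effect cofactor
#' and rescans, stopping when no SNP passes the Bonferroni threshold or
#' `max_cofactors` is reached. With a repulsion-phase linked pair (like
#' the two major-locus SNPs), the second scan conditioned on the first
#' SNP recovers the partner.
#'
#' @inheritParams lmm_scan
#' @param max_cofactors Maximum number of cofactors to add.
#' @return List of class `stepwise_scan`: `cofactors` (tibble in order of
#'   inclusion with each SNP's p at inclusion) and `scans` (list of
#'   per-step `assoc_scan` results; element i is the scan that selected
#'   cofactor i).
#' @export
stepwise_scan <- function(y, g, K = NULL, max_cofactors = 5, maf_min = 0.05,
                          alpha = 0.05) {
  stopf(is_count(max_cofactors), "max_cofactors must be >= 1")
  if (is.null(K)) K <- kinship_ibs(g)
  cof <- character()
  cof_p <- numeric()
  scans <- list()
  for (step in seq_len(max_cofactors + 1)) {
    sc <- lmm_scan(y, g, K, cofactors = cof, maf_min = maf_min, alpha = alpha)
    scans[[step]] <- sc
    hit <- dplyr::filter(sc, .data$significant)
    if (nrow(hit) == 0 || length(cof) >= max_cofactors) break
    best <- hit$snp_id[which.min(hit$p)]
    cof <- c(cof, best)
    cof_p <- c(cof_p, min(hit$p))
  }
  structure(list(
    cofactors = tibble::tibble(snp_id = cof, p_at_inclusion = cof_p),
    scans = scans), class = "stepwise_scan")
}

#' @export
print.stepwise_scan <- function(x, ...) {
  cat("<stepwise_scan> ", nrow(x$cofactors), " cofactors: ",
      paste(x$cofactors$snp_id, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Label associations as cis or trans
#'
#' Given association results for anchored phenotypes (windows or genes),
#' labels each association cis when the SNP lies on the anchor's
#' chromosome within `cis_window` bp of the anchor interval, and
#' summarizes the fraction of phenotypes with at least one significant
#' cis association and the fraction of significant associations in trans.
#'
#' @param assoc Tibble of associations with `phenotype`, `snp_id`,
#'   `chrom`, `pos`, `p`, `significant` columns.
#' @param anchors Tibble with `phenotype`, `chrom`, `start`, `end`
#'   (the phenotype's genomic anchor).
#' @param cis_window Distance threshold in bp (default 100 kb).
#' @return List of class `cis_trans`: `associations` (labelled tibble)
#'   and `summary` (one-row tibble with `n_phenotypes`, `frac_cis_phenotypes`,
#'   `frac_trans_associations`).
#' @export
classify_cis_trans <- function(assoc, anchors, cis_window = 1e5) {
  x <- dplyr::inner_join(assoc, dplyr::rename(anchors, anchor_chrom = "chrom",
                                              anchor_start = "start",
                                              anchor_end = "end"),
                         by = "phenotype")
  dropped <- setdiff(unique(assoc$phenotype), unique(anchors$phenotype))
  if (length(dropped))
    warn(sprintf("%d phenotypes without anchors excluded", length(dropped)))
  x <- dplyr::mutate(x,
    dist = pmax(0, pmax(.data$anchor_start - .data$pos,
                        .data$pos - .data$anchor_end)),
    label = ifelse(.data$chrom == .data$anchor_chrom &
                     .data$dist <= cis_window, "cis", "trans"))
  sig <- dplyr::filter(x, .data$significant)
  phen <- dplyr::summarise(dplyr::group_by(x, .data$phenotype),
                           has_cis = any(.data$significant & .data$label == "cis"),
                           .groups = "drop")
  structure(list(
    associations = dplyr::select(x, -dplyr::any_of(c("anchor_chrom",
                                                     "anchor_start",
                                                     "anchor_end"))),
    summary = tibble::tibble(
      n_phenotypes = nrow(phen),
      frac_cis_phenotypes = mean(phen$has_cis),
      n_significant = nrow(sig),
      frac_trans_associations = if (nrow(sig)) mean(sig$label == "trans")
      else NA_real_)),
    class = "cis_trans")
}

#' @export
print.cis_trans <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Direction of non-reference-allele effects by cis/trans class
#'
#' Tallies, separately for cis and trans associations, how often the
#' non-reference allele is associated with decreased vs increased
#' phenotype (the sign of the effect under 0/1 non-reference coding),
#' reports both orientation ratios, and tests the split against 50/50
#' with a two-sided exact binomial test.
#'
#' @param assoc Labelled association tibble (from [classify_cis_trans()]
#'   `$associations`), significant rows are used.
#' @return Tibble per `label`: `n_down`, `n_up`, `ratio_down_up`,
#'   `ratio_up_down`, `p` (ratios are `NA` when a class is empty).
#' @export
effect_direction_summary <- function(assoc) {
  sig <- dplyr::filter(assoc, .data$significant, !is.na(.data$beta))
  purrr::map_dfr(split(sig, sig$label), function(d) {
    n_down <- sum(d$beta < 0); n_up <- sum(d$beta > 0)
    tibble::tibble(
      label = d$label[1], n_down = n_down, n_up = n_up,
      ratio_down_up = if (n_up > 0) n_down / n_up else NA_real_,
      ratio_up_down = if (n_down > 0) n_up / n_down else NA_real_,
      p = if (n_down + n_up > 0)
        binom.test(n_down, n_down + n_up, 0.5)$p.value else NA_real_)
  })
}

#' Structure-corrected phenotype via BLUP subtraction
#'
#' Fits the null mixed model `y = mu + u + e`, `u ~ N(0, sg^2 K)`, and
#' returns `y` minus the best linear unbiased predictor of `u`, removing
#' the phenotypic signal attributable to genome-wide relatedness (as used
#' for genotype-class plots after correcting for population structure).
#'
#' @param y Phenotype vector or tibble (see [lmm_scan()]).
#' @param K Kinship matrix; if not positive semidefinite it is shrunk by
#'   `K + delta I` with the smallest sufficient `delta` (logged).
#' @return Numeric vector named by accession, with attributes `h2` and
#'   `shrinkage`.
#' @export
blup_correct <- function(y, K) {
  acc <- rownames(K)
  y <- align_phenotype(y, acc %||% names(y) %||% seq_along(diag(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  shrink <- 0
  if (min(ev) < -1e-8) {
    shrink <- -min(ev) + 1e-8
    inform(sprintf("kinship not PSD; shrinking with delta = %.3g", shrink))
    K <- K + diag(shrink, nrow(K))
  }
  fit <- lmm_null(y, K)
  if (fit$sigma_g2 * max(fit$d) < 1e-12 * fit$sigma_e2) {
    out <- y
  } else {
    # BLUP of u on the eigenbasis: u_hat = U diag(d/(d+delta)) U' (y - mu)
    r <- fit$ys - fit$Xs %*% fit$beta
    u_hat <- fit$U %*% (r * fit$d / (fit$d + fit$delta))
    out <- drop(y - u_hat)
  }
  names(out) <- acc
  attr(out, "h2") <- fit$h2
  attr(out, "shrinkage") <- shrink
  out
}
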