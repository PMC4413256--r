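#' Genetic relatedness matrix from a SNP subset
#'
#' Standardized-genotype cross-product relatedness `Z Z' / m` over a
#' declared SNP subset (cis: within a window of the phenotype anchor;
#' trans: all others; major locus: its region), rescaled so the mean
#' diagonal is 1. Positive semidefinite by construction.
#'
#' @param g A `geno_table`.
#' @param snp_ids Character vector of SNP ids to use.
#' @return Accession-by-accession matrix with attribute `n_snps`.
#' @export
relatedness_from_snps <- function(g, snp_ids) {
  stopf(inherits(g, "geno_table"), "g must be a geno_table")
  stopf(length(snp_ids) >= 1, "at least one SNP required")
  stopf(all(snp_ids %in% colnames(g$calls)), "unknown SNP ids")
  Z <- g$calls[, snp_ids, drop = FALSE]
  sds <- apply(Z, 2, sd)
  Z <- Z[, sds > 0, drop = FALSE]
  stopf(ncol(Z) >= 1, "all selected SNPs are monomorphic")
  Z <- scale(Z)
  R <- tcrossprod(Z) / ncol(Z)
  R <- R / mean(diag(R))
  attr(R, "n_snps") <- ncol(Z)
  R
}

#' Select cis / trans / major-locus SNP sets around an anchor
#'
#' Partitions the SNPs of a genotype table into the cis set (within
#' `cis_window` of the anchor interval on its chromosome), the major-locus
#' set (within `locus_window` of the designated major-locus SNPs) and the
#' trans set (everything else).
#'
#' @param g A `geno_table`.
#' @param anchor One-row tibble or list with `chrom`, `start`, `end`.
#' @param cis_window Cis distance in bp (default 50 kb, the
#'   variance-component convention; GWAS labelling uses 100 kb).
#' @param locus_window Window around the major-locus SNPs.
#' @return List of character vectors `cis`, `trans`, `major`.
#' @export
snp_partition <- function(g, anchor, cis_window = 5e4, locus_window = 5e4) {
  snps <- g$snps
  d_anchor <- ifelse(snps$chrom == anchor$chrom,
                     pmax(0, pmax(anchor$start - snps$pos,
                                  snps$pos - anchor$end)), Inf)
  ml <- snps[match(g$major_locus, snps$snp_id), ]
  d_major <- rep(Inf, nrow(snps))
  for (i in seq_len(nrow(ml)))
    d_major <- pmin(d_major, ifelse(snps$chrom == ml$chrom[i],
                                    abs(snps$pos - ml$pos[i]), Inf))
  major <- snps$snp_id[d_major <= locus_window]
  cis <- setdiff(snps$snp_id[d_anchor <= cis_window], major)
  trans <- setdiff(snps$snp_id, c(cis, major))
  list(cis = cis, trans = trans, major = major)
}

# Negative profiled log-likelihood of the observed cells with analytic
# gradient: V(theta) = sum_j theta_j^2 B_j; environment means by GLS
# (mu fixed instead when supplied).
varcomp_objective <- function(yo, X, B) {
  n_par <- length(B)
  n_obs <- length(yo)
  function(theta, mu = NULL) {
    V <- matrix(0, n_obs, n_obs)
    for (j in seq_len(n_par)) V <- V + theta[j]^2 * B[[j]]
    ch <- tryCatch(chol(V + diag(1e-10, n_obs)), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = rep(0, n_par)))
    Vinv <- chol2inv(ch)
    if (is.null(mu)) {
      XtVi <- crossprod(X, Vinv)
      mu <- drop(solve(XtVi %*% X, XtVi %*% yo))
    }
    r <- yo - X %*% mu
    w <- Vinv %*% r
    logdet <- 2 * sum(log(diag(ch)))
    nll <- 0.5 * (n_obs * log(2 * pi) + logdet + sum(r * w))
    grad <- vapply(seq_len(n_par), function(j) {
      -theta[j] * (sum(w * (B[[j]] %*% w)) - sum(Vinv * B[[j]]))
    }, numeric(1))
    list(value = nll, grad = grad, mu = mu)
  }
}

#' Log-likelihood of the two-environment model at fixed parameters
#'
#' Evaluates the observed-cell Gaussian log-likelihood at a given
#' parameter vector (and optionally fixed environment means), through the
#' same covariance construction the fitter optimizes. Intended for
#' numerical verification and model comparison.
#'
#' @inheritParams fit_varcomp
#' @param params Named parameter vector in the fitter's layout
#'   (`<component>.a`, `<component>.b1`, `<component>.b2` for each
#'   included component and `noise.*`); entries enter the covariance as
#'   squares.
#' @param mu Optional length-2 vector of environment means; profiled by
#'   GLS when NULL.
#' @return Scalar log-likelihood.
#' @export
varcomp_loglik <- function(Y, params, R_cmt2 = NULL, R_cis = NULL,
                           R_trans = NULL, mu = NULL) {
  Y <- as_pheno_matrix(Y)
  N <- nrow(Y)
  R_list <- list(cmt2 = R_cmt2, cis = R_cis, trans = R_trans)
  R_list <- R_list[!vapply(R_list, is.null, logical(1))]
  R_list$noise <- diag(N)
  yv <- c(Y)
  obs <- which(!is.na(yv))
  env_of <- rep(1:2, each = N)[obs]
  X <- cbind(as.numeric(env_of == 1), as.numeric(env_of == 2))
  B <- varcomp_bases(R_list, obs, N)
  stopf(all(names(B) %in% names(params)),
        "params must cover: %s", paste(names(B), collapse = ", "))
  obj <- varcomp_objective(yv[obs], X, B)
  -obj(params[names(B)], mu = mu)$value
}

# Precompute the design of the two-environment matrix-normal model on the
# observed cells of vec(Y) (environment slow, accession fast): for each
# random effect, the three basis matrices corresponding to the shared
# (a^2 J) and environment-specific (b_e^2 E_ee) parts of its 2x2 trait
# covariance.
varcomp_bases <- function(R_list, obs, N) {
  J <- matrix(1, 2, 2)
  E1 <- diag(c(1, 0)); E2 <- diag(c(0, 1))
  out <- list()
  for (k in names(R_list)) {
    R <- R_list[[k]]
    out[[paste0(k, ".a")]] <- kronecker(J, R)[obs, obs]
    out[[paste0(k, ".b1")]] <- kronecker(E1, R)[obs, obs]
    out[[paste0(k, ".b2")]] <- kronecker(E2, R)[obs, obs]
  }
  out
}

#' Fit the two-environment variance-component model
#'
#' Maximum-likelihood fit of the matrix-normal mixed model
#' `Y = 1 mu' + U_cmt2 + U_cis + U_trans + psi` for an N x 2 phenotype
#' (accessions by environments, missing cells allowed): each random
#' effect `U_k ~ MVN(0, C_k, R_k)` has a 2x2 trait covariance over
#' environments and a fixed accession relatedness `R_k`; the noise has
#' `C = Sigma`, `R = I`. Each 2x2 covariance is parameterized as
#' `a^2 J + diag(b1^2, b2^2)` — an environment-shared component plus
#' environment-specific ones — which makes the G, GxE split direct. The
#' covariance of the observed cells is `sum_k C_k (x) R_k + Sigma (x) I`
#' (Kronecker ordering: environment slow, accession fast); environment
#' means are profiled out by GLS, and the 12 variance parameters are
#' optimized by L-BFGS with analytic gradients, with up to `restarts`
#' random restarts, stopping at the first convergence.
#'
#' @param Y N x 2 numeric matrix (rownames = accessions) or a tibble with
#'   `accession`, `env`, `value`.
#' @param R_cmt2,R_cis,R_trans Relatedness matrices
#'   (see [relatedness_from_snps()]); any may be NULL to drop that
#'   component.
#' @param restarts Maximum number of optimizer restarts (default 10).
#' @param seed Seed for restart initialization.
#' @param max_iter Iteration cap per restart.
#' @return Object of class `varcomp_fit`: environment means `mu`, the
#'   2x2 covariance components `C` per effect, parameter estimates,
#'   `loglik`, `converged`, `n_restarts_used`, per-environment sample
#'   sizes, and the variance `fractions` from [partition_variance()].
#' @export
fit_varcomp <- function(Y, R_cmt2 = NULL, R_cis = NULL, R_trans = NULL,
                        restarts = 10, seed = 1, max_iter = 500) {
  Y <- as_pheno_matrix(Y)
  N <- nrow(Y)
  R_list <- list(cmt2 = R_cmt2, cis = R_cis, trans = R_trans)
  R_list <- R_list[!vapply(R_list, is.null, logical(1))]
  for (k in names(R_list)) {
    stopf(nrow(R_list[[k]]) == N, "R_%s dimension mismatch", k)
    ev <- min(eigen(R_list[[k]], symmetric = TRUE, only.values = TRUE)$values)
    stopf(ev > -1e-6, "R_%s is not positive semidefinite", k)
  }
  R_list$noise <- diag(N)

  yv <- c(Y)                                       # env slow, accession fast
  obs <- which(!is.na(yv))
  env_of <- rep(1:2, each = N)[obs]
  stopf(all(tabulate(env_of, 2) >= 2),
        "need at least 2 observed accessions per environment")
  yo <- yv[obs]
  # standardize internally so the optimizer sees a unit-scale problem and
  # the fractions are exactly invariant to rescaling Y
  y_scale <- stats::sd(yo)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  yo <- yo / y_scale
  X <- cbind(as.numeric(env_of == 1), as.numeric(env_of == 2))
  B <- varcomp_bases(R_list, obs, N)
  n_par <- length(B)
  objective <- varcomp_objective(yo, X, B)

  v0 <- stats::var(yo)
  init_list <- c(list(rep(sqrt(v0 / (2 * n_par)), n_par)),
                 lapply(derive_seeds(seed, max(restarts - 1, 0)),
                        function(s) with_seed(s, {
                          sqrt(v0 * exp(runif(n_par, log(1e-3), log(1))))
                        })))
  # optim calls fn and gr separately at the same point; cache one evaluation
  cache <- new.env(parent = emptyenv())
  obj_cached <- function(p) {
    key <- paste(p, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- objective(p)
      cache$key <- key
    }
    cache$val
  }
  best <- NULL
  n_used <- 0
  for (init in init_list[seq_len(max(1, min(restarts, length(init_list))))]) {
    n_used <- n_used + 1
    opt <- optim(init,
                 fn = function(p) obj_cached(p)$value,
                 gr = function(p) obj_cached(p)$grad,
                 method = "L-BFGS-B",
                 control = list(maxit = max_iter, factr = 1e7, pgtol = 1e-5))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) break
  }
  converged <- best$convergence == 0
  theta <- best$par
  final <- objective(theta)

  # undo the internal standardization
  theta <- theta * y_scale
  final$mu <- final$mu * y_scale
  final$value <- final$value + length(yo) * log(y_scale)

  names(theta) <- names(B)
  comps <- sub("\\..*", "", names(B))
  C <- lapply(unique(comps), function(k) {
    a2 <- theta[paste0(k, ".a")]^2
    b1 <- theta[paste0(k, ".b1")]^2
    b2 <- theta[paste0(k, ".b2")]^2
    matrix(c(a2 + b1, a2, a2, a2 + b2), 2, 2,
           dimnames = list(colnames(Y), colnames(Y)))
  })
  names(C) <- unique(comps)

  fit <- structure(list(
    mu = setNames(final$mu, colnames(Y)),
    C = C,
    params = theta,
    loglik = -final$value,
    converged = converged,
    n_restarts_used = n_used,
    n_per_env = tabulate(env_of, 2),
    components = setdiff(unique(comps), "noise"),
    N = N, environments = colnames(Y)
  ), class = "varcomp_fit")
  fit$fractions <- partition_variance(fit, check_converged = FALSE)
  fit
}

as_pheno_matrix <- function(Y) {
  if (is.data.frame(Y)) {
    stopf(all(c("accession", "env", "value") %in% names(Y)),
          "phenotype tibble needs accession, env, value")
    wide <- tidyr::pivot_wider(Y[, c("accession", "env", "value")],
                               names_from = "env", values_from = "value")
    Y <- as.matrix(wide[, -1])
    rownames(Y) <- wide$accession
  }
  Y <- as.matrix(Y)
  stopf(ncol(Y) == 2, "exactly two environments are supported")
  if (is.null(colnames(Y))) colnames(Y) <- c("env1", "env2")
  stopf(!all(is.na(Y[, 1])) && !all(is.na(Y[, 2])),
        "an environment with no observations cannot be fitted")
  Y
}

#' Partition phenotypic variance into component fractions
#'
#' Decomposes the fitted model into fractions of total phenotypic
#' variance: the environment fraction is the pooled variance of the
#' fitted environment means around their sample-size-weighted grand mean;
#' each random effect contributes a shared fraction (proportional to its
#' `a^2`) and an environment-interaction fraction (the mean of its
#' environment-specific `b^2`); noise is the analogous total for the
#' residual. Fractions are normalized to sum to one.
#'
#' @param fit A `varcomp_fit`.
#' @param check_converged Refuse non-converged fits (default TRUE).
#' @return Tibble with `component` (`E`, `<effect>`, `<effect>xE`,
#'   `noise`), `variance` and `fraction`.
#' @export
partition_variance <- function(fit, check_converged = TRUE) {
  stopf(inherits(fit, "varcomp_fit"), "fit must be a varcomp_fit")
  if (check_converged)
    stopf(fit$converged, "fit did not converge; refusing to partition")
  n_e <- fit$n_per_env
  mu_bar <- sum(n_e * fit$mu) / sum(n_e)
  var_E <- sum(n_e * (fit$mu - mu_bar)^2) / sum(n_e)
  th <- fit$params
  rows <- list(tibble::tibble(component = "E", variance = var_E))
  for (k in fit$components) {
    v <- c(th[paste0(k, ".a")]^2,
           (th[paste0(k, ".b1")]^2 + th[paste0(k, ".b2")]^2) / 2)
    rows <- c(rows, list(tibble::tibble(
      component = c(k, paste0(k, "xE")), variance = v)))
  }
  noise_v <- th["noise.a"]^2 + (th["noise.b1"]^2 + th["noise.b2"]^2) / 2
  rows <- c(rows, list(tibble::tibble(component = "noise",
                                      variance = unname(noise_v))))
  out <- dplyr::bind_rows(rows)
  out$fraction <- out$variance / sum(out$variance)
  out
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("<varcomp_fit> loglik ", round(x$loglik, 2),
      if (x$converged) " (converged, " else " (NOT converged, ",
      x$n_restarts_used, " restart(s))\n", sep = "")
  cat("  mu:", paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = ", "), "\n")
  f <- x$fractions
  cat("  fractions:", paste(sprintf("%s=%.2f", f$component, f$fraction),
                            collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_varcomp
#' @param x A `varcomp_fit`.
#' @param ... Unused.
#' @export
tidy.varcomp_fit <- function(x, ...) x$fractions

#' @rdname fit_varcomp
#' @export
glance.varcomp_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged,
                 n_restarts_used = x$n_restarts_used,
                 n_obs = sum(x$n_per_env),
                 explained = 1 - x$fractions$fraction[
                   x$fractions$component == "noise"])
}

#' Bin fitted phenotypes by total variance explained
#'
#' For a table of per-phenotype variance fractions, computes the total
#' variance explained by the model (1 minus the noise fraction), bins
#' phenotypes into equal-width bins on [0, 1], and returns per-bin mean
#' fractions plus the phenotype density per bin — the summary behind
#' stacked variance-decomposition displays.
#'
#' @param fractions Tibble with `phenotype`, `component`, `fraction`
#'   (long; e.g. row-bound [tidy.varcomp_fit()] outputs).
#' @param n_bins Number of equal-width bins.
#' @return Tibble: `bin`, `bin_mid`, `n`, `density`, one row per
#'   component per occupied bin with `mean_fraction`.
#' @export
bin_by_total_variance <- function(fractions, n_bins = 10) {
  stopf(nrow(fractions) > 0, "no fitted phenotypes")
  tot <- dplyr::summarise(
    dplyr::group_by(fractions, .data$phenotype),
    explained = 1 - sum(.data$fraction[.data$component == "noise"]),
    .groups = "drop")
  brk <- seq(0, 1, length.out = n_bins + 1)
  tot$bin <- cut(pmin(pmax(tot$explained, 0), 1), brk, include.lowest = TRUE)
  x <- dplyr::inner_join(fractions, tot, by = "phenotype")
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$bin, .data$component),
    n = dplyr::n_distinct(.data$phenotype),
    mean_fraction = mean(.data$fraction), .groups = "drop")
  out$bin_mid <- (brk[as.integer(out$bin)] + brk[as.integer(out$bin) + 1]) / 2
  out$density <- out$n / dplyr::n_distinct(tot$phenotype)
  out
}
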