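haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# F2 genotype transition matrix over {0 = AA, 1 = AB, 2 = BB} for one
# interval with recombination fraction r (two independent gametes).
f2_transition <- function(r) {
  s <- 1 - r
  matrix(c(s^2, 2 * r * s, r^2,
           r * s, s^2 + r^2, r * s,
           r^2, 2 * r * s, s^2), 3, 3, byrow = TRUE)
}

#' Simulate an F2 intercross
#'
#' Generates F2 genotypes at evenly spaced markers by simulating two
#' independent gametes per individual along each chromosome with Haldane
#' (no-interference) recombination, plus a phenotype controlled by
#' optional additive/dominance QTL and Gaussian noise.
#'
#' @param n Number of F2 individuals.
#' @param chr_lengths_cM Numeric vector of chromosome lengths in cM.
#' @param marker_spacing_cM Distance between adjacent markers.
#' @param qtl Optional tibble with `chrom` (index), `pos_cM`, `add`,
#'   `dom` giving QTL positions and effects (additive effect per allele,
#'   dominance deviation).
#' @param noise_sd Residual phenotype sd.
#' @param seed RNG seed.
#' @return List of class `f2_cross`: `geno` (individuals x markers matrix
#'   coded 0/1/2), `map` (tibble `marker`, `chrom`, `pos_cM`),
#'   `phenotype` (numeric), `qtl`.
#' @export
simulate_f2 <- function(n = 113, chr_lengths_cM = rep(100, 5),
                        marker_spacing_cM = 10, qtl = NULL,
                        noise_sd = 1, seed = 1) {
  map <- purrr::map_dfr(seq_along(chr_lengths_cM), function(c) {
    pos <- seq(0, chr_lengths_cM[c], by = marker_spacing_cM)
    tibble::tibble(chrom = c, pos_cM = pos)
  })
  map$marker <- sprintf("m%03d", seq_len(nrow(map)))
  # simulate at marker positions plus QTL positions, then drop the QTL cols
  sim_pts <- map[, c("chrom", "pos_cM")]
  if (!is.null(qtl))
    sim_pts <- dplyr::distinct(dplyr::bind_rows(
      sim_pts, qtl[, c("chrom", "pos_cM")]))
  sim_pts <- dplyr::arrange(sim_pts, .data$chrom, .data$pos_cM)
  with_seed(seed, {
    gam <- function() {
      out <- matrix(NA_integer_, n, nrow(sim_pts))
      for (c in unique(sim_pts$chrom)) {
        idx <- which(sim_pts$chrom == c)
        a <- rbinom(n, 1, 0.5)
        out[, idx[1]] <- a
        for (j in seq_along(idx)[-1]) {
          r <- haldane_r(sim_pts$pos_cM[idx[j]] - sim_pts$pos_cM[idx[j - 1]])
          flip <- rbinom(n, 1, r)
          a <- ifelse(flip == 1, 1 - a, a)
          out[, idx[j]] <- a
        }
      }
      out
    }
    geno_all <- gam() + gam()
    pheno <- rnorm(n, 0, noise_sd)
    if (!is.null(qtl)) {
      for (i in seq_len(nrow(qtl))) {
        j <- which(sim_pts$chrom == qtl$chrom[i] &
                     sim_pts$pos_cM == qtl$pos_cM[i])
        gq <- geno_all[, j]
        pheno <- pheno + qtl$add[i] * (gq - 1) + qtl$dom[i] * (gq == 1)
      }
    }
    keep <- match(paste(map$chrom, map$pos_cM),
                  paste(sim_pts$chrom, sim_pts$pos_cM))
    geno <- geno_all[, keep, drop = FALSE]
    colnames(geno) <- map$marker
    structure(list(geno = geno, map = map, phenotype = pheno, qtl = qtl),
              class = "f2_cross")
  })
}

# Genotype probabilities at a grid point between (or at) flanking markers,
# conditioning on both observed flanking genotypes through the F2 Markov
# chain: P(g | gL, gR) propto T(rL)[gL, g] * T(rR)[g, gR].
grid_genoprob <- function(gL, gR, rL, rR) {
  TL <- f2_transition(rL)
  TR <- f2_transition(rR)
  pr <- TL[gL + 1L, ] * t(TR[, gR + 1L])
  pr / rowSums(pr)
}

#' Haley--Knott QTL scan for an F2 population
#'
#' Scans the genome on a cM grid: at each position, expected additive and
#' dominance dosages are computed from flanking-marker genotype
#' probabilities under the Haldane map function, the phenotype is
#' regressed on them, and `LOD = (n/2) log10(RSS0/RSS1)`. The genome-wide
#' 5% significance threshold is the 95th percentile of the maximum LOD
#' over phenotype permutations, and a 1.5-LOD support interval is
#' reported around the peak.
#'
#' @param cross An `f2_cross` (markers must be ordered within
#'   chromosomes).
#' @param step_cM Scan grid step (default 4 cM).
#' @param n_perm Number of phenotype permutations for the threshold.
#' @param seed RNG seed for the permutations.
#' @param alpha Genome-wide significance level.
#' @return List of class `hk_scan`: `lod` (tibble `chrom`, `pos_cM`,
#'   `lod`), `threshold`, `peak` (one-row tibble), `support` (1.5-LOD
#'   interval on the peak chromosome), `n_perm`, `alpha`.
#' @export
hk_scan <- function(cross, step_cM = 4, n_perm = 1000, seed = 1,
                    alpha = 0.05) {
  stopf(inherits(cross, "f2_cross"), "cross must be an f2_cross")
  map <- cross$map
  stopf(!is.unsorted(order(map$chrom, map$pos_cM)), "markers must be ordered")
  for (c in unique(map$chrom))
    stopf(!is.unsorted(map$pos_cM[map$chrom == c]),
          "markers unordered on chromosome %s", c)
  y <- cross$phenotype
  n <- length(y)

  grid <- purrr::map_dfr(unique(map$chrom), function(c) {
    pos <- map$pos_cM[map$chrom == c]
    tibble::tibble(chrom = c,
                   pos_cM = unique(sort(c(seq(min(pos), max(pos), by = step_cM),
                                          max(pos)))))
  })

  # design (x = additive dosage, z = dominance indicator prob) per grid point
  designs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    c <- grid$chrom[i]; pos <- grid$pos_cM[i]
    mk <- which(map$chrom == c)
    at <- mk[map$pos_cM[mk] == pos]
    if (length(at) == 1) {
      g <- cross$geno[, at]
      pr <- matrix(0, n, 3)
      pr[cbind(seq_len(n), g + 1L)] <- 1
    } else {
      left <- max(mk[map$pos_cM[mk] < pos])
      right <- min(mk[map$pos_cM[mk] > pos])
      rL <- haldane_r(pos - map$pos_cM[left])
      rR <- haldane_r(map$pos_cM[right] - pos)
      pr <- grid_genoprob(cross$geno[, left], cross$geno[, right], rL, rR)
    }
    designs[[i]] <- cbind(1, pr[, 3] - pr[, 1], pr[, 2])
  }

  lod_for <- function(Y) {   # Y: n x m phenotype matrix -> m-max over grid
    Yc <- sweep(Y, 2, colMeans(Y))
    rss0 <- colSums(Yc^2)
    lods <- matrix(0, nrow(grid), ncol(Y))
    for (i in seq_len(nrow(grid))) {
      qrX <- qr(designs[[i]])
      res <- qr.resid(qrX, Y)
      rss1 <- colSums(res^2)
      lods[i, ] <- (n / 2) * log10(rss0 / rss1)
    }
    lods
  }

  lods <- lod_for(matrix(y, n, 1))[, 1]
  perm_max <- with_seed(seed, {
    P <- vapply(seq_len(n_perm), function(i) y[sample.int(n)],
                numeric(n))
    apply(lod_for(P), 2, max)
  })
  threshold <- as.numeric(quantile(perm_max, 1 - alpha, type = 7))

  peak_i <- which.max(lods)
  peak <- tibble::tibble(chrom = grid$chrom[peak_i],
                         pos_cM = grid$pos_cM[peak_i],
                         lod = lods[peak_i])
  on_chr <- grid$chrom == peak$chrom
  keep <- on_chr & lods >= peak$lod - 1.5
  support <- tibble::tibble(chrom = peak$chrom,
                            lo_cM = min(grid$pos_cM[keep]),
                            hi_cM = max(grid$pos_cM[keep]))
  structure(list(lod = dplyr::mutate(grid, lod = lods),
                 threshold = threshold, peak = peak, support = support,
                 n_perm = n_perm, alpha = alpha, perm_max = perm_max),
            class = "hk_scan")
}

#' @export
print.hk_scan <- function(x, ...) {
  cat("<hk_scan> peak LOD ", round(x$peak$lod, 2), " at chr", x$peak$chrom,
      ":", x$peak$pos_cM, " cM; genome-wide ", 100 * (1 - x$alpha),
      "% threshold ", round(x$threshold, 2), " (", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}
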