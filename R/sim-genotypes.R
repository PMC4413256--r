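#' Simulate structured inbred genotypes
#'
#' Generates a biallelic 0/1 genotype matrix for naturally inbred
#' accessions drawn from two subpopulations (north/south) whose
#' allele-frequency divergence follows the Balding--Nichols model: each
#' SNP's ancestral frequency is drawn uniformly, and each subpopulation
#' frequency is Beta-distributed around it with divergence parameter
#' `cfg$fst_target`, so the realized Hudson Fst matches the target closely.
#' Two adjacent SNPs on one chromosome form a designated major-locus pair in
#' complete repulsion-phase linkage disequilibrium: the non-reference
#' alleles of the two SNPs never co-occur in the same accession, mirroring
#' the CMT2a/CMT2b haplotype structure. Accession latitudes are drawn north
#' or south of a 60 degree split.
#'
#' @param cfg A [sim_config()] object.
#' @return An object of class `geno_table`: a list with
#'   \describe{
#'     \item{calls}{integer matrix, accessions x SNPs, 0 = reference
#'       allele, 1 = non-reference (accessions are homozygous).}
#'     \item{snps}{tibble with `snp_id`, `chrom`, `pos`.}
#'     \item{accessions}{tibble with `accession`, `region`
#'       (north/south), `latitude`.}
#'     \item{major_locus}{named character vector, the `a` and `b` SNP ids
#'       of the repulsion pair.}
#'   }
#' @export
simulate_genotypes <- function(cfg) {
  stopf(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  n <- cfg$n_accessions
  n_north <- round(cfg$pop_split * n)
  n_south <- n - n_north
  stopf(n_north >= 4 && n_south >= 4,
        "need at least 4 accessions per subpopulation (have %d north, %d south)",
        n_north, n_south)

  seeds <- derive_seeds(cfg$seed, 3)
  m <- cfg$n_snps
  Fst <- cfg$fst_target

  with_seed(seeds[1], {
    lens <- chrom_lengths(cfg)
    chrom <- sort(sample.int(cfg$n_chromosomes, m, replace = TRUE))
    pos <- integer(m)
    for (c in seq_along(lens)) {
      idx <- which(chrom == c)
      pos[idx] <- sort(sample.int(lens[c], length(idx)))
    }
    p_anc <- runif(m, 0.1, 0.9)
    if (Fst > 0) {
      shape <- (1 - Fst) / Fst
      p_n <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
      p_s <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
    } else {
      p_n <- p_s <- p_anc
    }
    calls <- matrix(0L, n, m)
    calls[seq_len(n_north), ] <- matrix(
      rbinom(n_north * m, 1L, rep(p_n, each = n_north)), n_north, m)
    calls[n_north + seq_len(n_south), ] <- matrix(
      rbinom(n_south * m, 1L, rep(p_s, each = n_south)), n_south, m)
  })

  # Major-locus pair: two adjacent SNPs on the last chromosome (or Chr4 when
  # five chromosomes are simulated), overwritten with repulsion-phase
  # haplotype classes at region-specific frequencies (south commoner).
  major_chrom <- min(4L, cfg$n_chromosomes)
  cand <- which(chrom == major_chrom)
  stopf(length(cand) >= 2, "need at least 2 SNPs on the major-locus chromosome")
  mid <- cand[ceiling(length(cand) / 2)]
  major_idx <- c(a = mid, b = if (mid + 1L %in% cand) mid + 1L else mid - 1L)
  with_seed(seeds[2], {
    qa <- ifelse(seq_len(n) <= n_north, 0.095, 0.226)
    qb <- ifelse(seq_len(n) <= n_north, 0.079, 0.306)
    u <- runif(n)
    class <- ifelse(u < qa, "a", ifelse(u < qa + qb, "b", "ref"))
    calls[, major_idx["a"]] <- as.integer(class == "a")
    calls[, major_idx["b"]] <- as.integer(class == "b")
  })

  with_seed(seeds[3], {
    latitude <- c(runif(n_north, 62.9, 68.4), runif(n_south, 55.4, 59.4))
  })

  snp_id <- sprintf("snp%05d", seq_len(m))
  acc <- sprintf("acc%03d", seq_len(n))
  dimnames(calls) <- list(acc, snp_id)

  structure(list(
    calls = calls,
    snps = tibble::tibble(snp_id = snp_id,
                          chrom = names(lens)[chrom],
                          pos = pos),
    accessions = tibble::tibble(
      accession = acc,
      region = rep(c("north", "south"), c(n_north, n_south)),
      latitude = latitude),
    major_locus = setNames(snp_id[major_idx], c("a", "b")),
    chrom_lengths = lens,
    fst_target = Fst
  ), class = "geno_table")
}

#' @export
print.geno_table <- function(x, ...) {
  cat("<geno_table> ", nrow(x$calls), " accessions x ", ncol(x$calls),
      " SNPs; regions: ", paste(table(x$accessions$region), collapse = "/"),
      " (north/south); major locus ", paste(x$major_locus, collapse = "+"),
      "\n", sep = "")
  invisible(x)
}

#' Subset a genotype table to a set of accessions
#'
#' @param g A `geno_table`.
#' @param accessions Character vector of accession ids to keep.
#' @return A `geno_table` restricted to those accessions.
#' @export
subset_accessions <- function(g, accessions) {
  stopf(inherits(g, "geno_table"), "g must be a geno_table")
  keep <- match(accessions, rownames(g$calls))
  stopf(!anyNA(keep), "unknown accession ids")
  g$calls <- g$calls[keep, , drop = FALSE]
  g$accessions <- g$accessions[match(accessions, g$accessions$accession), ]
  g
}
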