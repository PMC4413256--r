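default_te_families <- function() {
  tibble::tibble(
    family = c("ATREP3", "ATREP15", "VANDAL17", "ATHAT6", "COPIA78",
               "META1", "ATLINE1_4", "SIMPLEHAT2", "ATSINE1", "ATMU5"),
    superfamily = c("Helitron", "Helitron", "MuDR", "HAT", "LTR/Copia",
                    "LTR/Gypsy", "LINE/L1", "HAT", "SINE", "MuDR"),
    weight = c(0.20, 0.12, 0.10, 0.08, 0.06, 0.05, 0.12, 0.07, 0.08, 0.12)
  )
}

#' Simulate gene and transposon annotations
#'
#' Places non-overlapping gene and TE intervals on each nuclear chromosome,
#' assigns TEs to families/superfamilies from a frequency table, flags a
#' subset of TEs as "variable" (the hosts of planted temperature DMRs;
#' default 2.7% of TEs, the fraction reported for the study's variable-TE
#' set), flags a subset of genes as gene-body-methylated (GBM), and adds an
#' unmethylated chloroplast-like control contig.
#'
#' @param cfg A [sim_config()] object.
#' @param te_families Tibble with `family`, `superfamily`, `weight`
#'   columns; defaults to a 10-family table loosely modeled on the
#'   Arabidopsis TE complement.
#' @param variable_family_bias Multiplier applied to the sampling weight of
#'   TEs from the first two families when drawing the variable set, so
#'   family enrichment among variable TEs is non-trivial by construction.
#' @return An object of class `annot_set`: list with `features` (tibble:
#'   `feature_id`, `chrom`, `start`, `end`, `strand`, `type`, `family`,
#'   `superfamily`, `variable`, `variable_direction`, `gbm_gene`),
#'   `chrom_lengths` (named vector including the chloroplast contig) and
#'   `chloroplast` (its name).
#' @export
simulate_annotations <- function(cfg, te_families = default_te_families(),
                                 variable_family_bias = 4) {
  stopf(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  lens <- chrom_lengths(cfg)
  seeds <- derive_seeds(cfg$seed + 1L, 2)

  feats <- with_seed(seeds[1], {
    n_feat <- cfg$n_genes + cfg$n_tes
    if (n_feat == 0) {
      tibble::tibble(feature_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     type = character(), family = character(),
                     superfamily = character())
    } else {
      type <- sample(rep(c("gene", "TE"), c(cfg$n_genes, cfg$n_tes)))
      len <- ifelse(type == "gene",
                    pmin(pmax(round(stats::rlnorm(n_feat, log(1800), 0.5)), 400), 8000),
                    pmin(pmax(round(stats::rlnorm(n_feat, log(700), 1.0)), 100), 12000))
      chrom <- sample(names(lens), n_feat, replace = TRUE,
                      prob = lens / sum(lens))
      out <- vector("list", length(lens))
      for (ci in seq_along(lens)) {
        idx <- which(chrom == names(lens)[ci])
        if (!length(idx)) next
        l <- len[idx]
        slack <- lens[ci] - sum(l)
        stopf(slack > 0,
              "feature footprint exceeds chromosome %s; shrink n_genes/n_tes",
              names(lens)[ci])
        gaps <- c(stats::rmultinom(1, slack, rep(1, length(l) + 1)))
        start <- cumsum(gaps[-length(gaps)] + c(0, l[-length(l)])) + 1
        out[[ci]] <- tibble::tibble(chrom = names(lens)[ci],
                                    start = as.integer(start),
                                    end = as.integer(start + l - 1),
                                    type = type[idx])
      }
      dplyr::bind_rows(out)
    }
  })

  feats <- with_seed(seeds[2], {
    n_te <- sum(feats$type == "TE")
    fam <- rep(NA_character_, nrow(feats))
    sup <- rep(NA_character_, nrow(feats))
    if (n_te > 0) {
      pick <- sample.int(nrow(te_families), n_te, replace = TRUE,
                         prob = te_families$weight)
      fam[feats$type == "TE"] <- te_families$family[pick]
      sup[feats$type == "TE"] <- te_families$superfamily[pick]
    }
    feats$strand <- sample(c("+", "-"), nrow(feats), replace = TRUE)
    feats$family <- fam
    feats$superfamily <- sup

    # variable TEs: the planted temperature-DMR hosts, drawn with a family
    # bias so that downstream family enrichment has signal to detect
    feats$variable <- FALSE
    feats$variable_direction <- NA_character_
    if (n_te > 0 && cfg$variable_te_fraction > 0) {
      te_rows <- which(feats$type == "TE")
      n_var <- max(1L, round(cfg$variable_te_fraction * n_te))
      w <- ifelse(feats$family[te_rows] %in% te_families$family[1:2],
                  variable_family_bias, 1)
      var_rows <- te_rows[sample.int(length(te_rows), min(n_var, length(te_rows)),
                                     prob = w)]
      feats$variable[var_rows] <- TRUE
      n_loss <- round(cfg$architecture$temp_dmr_loss_fraction * length(var_rows))
      dir <- rep("gain", length(var_rows))
      if (n_loss > 0) dir[sample.int(length(var_rows), n_loss)] <- "loss"
      feats$variable_direction[var_rows] <- dir
    }

    feats$gbm_gene <- FALSE
    gene_rows <- which(feats$type == "gene")
    n_gbm <- round(cfg$gbm_gene_fraction * length(gene_rows))
    if (n_gbm > 0)
      feats$gbm_gene[sample(gene_rows, n_gbm)] <- TRUE
    feats
  })

  feats <- dplyr::arrange(feats, .data$chrom, .data$start)
  feats$feature_id <- sprintf("%s%04d",
                              ifelse(feats$type == "gene", "g", "te"),
                              seq_len(nrow(feats)))
  feats <- dplyr::relocate(feats, "feature_id")

  ov <- overlapping_fraction(feats)
  if (ov > 0.5)
    warn(sprintf("%.0f%% of features overlap another feature; unrealistic annotation",
                 100 * ov))

  all_lens <- c(lens, setNames(100000, chloroplast_contig()))
  structure(list(features = feats,
                 chrom_lengths = all_lens,
                 chloroplast = chloroplast_contig()),
            class = "annot_set")
}

overlapping_fraction <- function(feats) {
  if (nrow(feats) < 2) return(0)
  f <- dplyr::arrange(feats, .data$chrom, .data$start)
  same_chrom <- f$chrom[-1] == f$chrom[-nrow(f)]
  ov <- same_chrom & (f$start[-1] <= f$end[-nrow(f)])
  mean(c(FALSE, ov))
}

#' @export
print.annot_set <- function(x, ...) {
  tab <- table(x$features$type)
  cat("<annot_set> ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "; variable TEs: ", sum(x$features$variable),
      "; GBM genes: ", sum(x$features$gbm_gene),
      "; contigs: ", paste(names(x$chrom_lengths), collapse = ","),
      "\n", sep = "")
  invisible(x)
}
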