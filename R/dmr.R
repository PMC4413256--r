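#' Pairwise differential methylation test
#'
#' Calls differentially methylated windows between two samples of the same
#' genome from summed counts in non-overlapping tiles (default 100 bp). In
#' each window with coverage on both sides, a two-sided Fisher's exact
#' test compares the (methylated, unmethylated) read totals; p-values are
#' Benjamini--Hochberg adjusted across tested windows, and a window is
#' reported when `q <= fdr` and the absolute level difference reaches
#' `min_diff` (0.3 by default; `semantics = "ratio"` switches the filter
#' to a fold-change interpretation). Direction is the sign of B minus A.
#'
#' @param counts_a,counts_b Cytosine-report tibbles for the two samples.
#' @param window Tile width in bp (non-overlapping).
#' @param fdr FDR threshold on BH-adjusted p-values.
#' @param min_diff Minimum absolute difference `|level_b - level_a|`
#'   (or minimum `|log2(level_b/level_a)|` under ratio semantics).
#' @param semantics `"difference"` (default) or `"ratio"`.
#' @param context Optional context restriction.
#' @param all Return all tested windows (with a `call` flag) instead of
#'   calls only.
#' @return Tibble of DMR calls: window coordinates, `level_a`, `level_b`,
#'   `difference`, `p`, `q`, `direction` (`gain` when B exceeds A). The
#'   number of tested windows is in attribute `n_tested`.
#' @export
pairwise_dmr_test <- function(counts_a, counts_b, window = 100, fdr = 0.05,
                              min_diff = 0.3,
                              semantics = c("difference", "ratio"),
                              context = NULL, all = FALSE) {
  semantics <- match.arg(semantics)
  stopf(is.numeric(window) && window > 0, "window must be > 0")
  stopf(is_fraction(fdr), "fdr must be in [0,1]")
  agg <- function(x, side) {
    if (!is.null(context)) x <- dplyr::filter(x, .data$context %in% !!context)
    x <- dplyr::filter(x, .data$total > 0)
    x$win <- (x$pos - 1L) %/% as.integer(window)
    out <- dplyr::summarise(dplyr::group_by(x, .data$chrom, .data$win),
                            meth = sum(.data$meth), total = sum(.data$total),
                            .groups = "drop")
    names(out)[3:4] <- paste0(c("meth_", "total_"), side)
    out
  }
  tab <- dplyr::inner_join(agg(counts_a, "a"), agg(counts_b, "b"),
                           by = c("chrom", "win"))
  if (nrow(tab) == 0) {
    return(structure(tibble::tibble(), n_tested = 0L))
  }
  p <- vapply(seq_len(nrow(tab)), function(i) {
    m <- matrix(c(tab$meth_a[i], tab$total_a[i] - tab$meth_a[i],
                  tab$meth_b[i], tab$total_b[i] - tab$meth_b[i]), 2)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  tab <- dplyr::mutate(tab,
                       start = .data$win * as.integer(window) + 1L,
                       end = (.data$win + 1L) * as.integer(window),
                       window_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
                       level_a = .data$meth_a / .data$total_a,
                       level_b = .data$meth_b / .data$total_b,
                       difference = .data$level_b - .data$level_a,
                       p = p,
                       q = p.adjust(p, "BH"),
                       direction = ifelse(.data$difference >= 0, "gain", "loss"))
  eff <- if (semantics == "difference") abs(tab$difference) else
    abs(log2((tab$level_b + 1e-9) / (tab$level_a + 1e-9)))
  tab$call <- tab$q <= fdr & eff >= min_diff
  out <- dplyr::select(tab, "window_id", "chrom", "start", "end",
                       "level_a", "level_b", "difference", "p", "q",
                       "direction", "call")
  if (!all) out <- dplyr::filter(out, .data$call)
  structure(out, n_tested = nrow(tab))
}

#' Temperature DMRs across accessions
#'
#' Runs the pairwise DMR test between the two growth temperatures within
#' each accession, oriented warm minus cool (16C - 10C), then summarizes
#' per-accession gained/lost window counts and builds a consensus set of
#' windows called in at least `k` accessions.
#'
#' @param counts Cytosine-report tibble with `accession` and `env`
#'   columns covering both environments.
#' @param env_cool,env_warm Environment labels (test orientation is
#'   warm minus cool).
#' @param k Minimum number of accessions calling a window for it to enter
#'   the consensus set.
#' @param ... Passed to [pairwise_dmr_test()] (window, fdr, min_diff,
#'   context, ...).
#' @return List of class `temperature_dmrs`: `per_accession` (accession,
#'   `n_gain`, `n_loss`), `consensus` (window coordinates, `n_accessions`,
#'   modal `direction`), and `calls` (all per-accession calls).
#' @export
temperature_dmrs <- function(counts, env_cool = "10C", env_warm = "16C",
                             k = 1, ...) {
  accs <- unique(counts$accession)
  both <- vapply(accs, function(a) {
    e <- unique(counts$env[counts$accession == a])
    all(c(env_cool, env_warm) %in% e)
  }, logical(1))
  stopf(any(both), "no accession observed in both environments")
  calls <- purrr::map_dfr(accs[both], function(a) {
    ca <- dplyr::filter(counts, .data$accession == a, .data$env == env_cool)
    cb <- dplyr::filter(counts, .data$accession == a, .data$env == env_warm)
    res <- pairwise_dmr_test(ca, cb, ...)
    if (nrow(res) == 0) return(NULL)
    dplyr::mutate(res, accession = a, .before = 1)
  })
  if (nrow(calls) == 0)
    calls <- tibble::tibble(accession = character(), window_id = character(),
                            chrom = character(), start = integer(),
                            end = integer(), direction = character())
  counts_by <- dplyr::count(calls, .data$accession, .data$direction)
  per_acc <- tidyr::pivot_wider(counts_by, names_from = "direction",
                                values_from = "n", values_fill = 0L)
  for (col in c("gain", "loss"))
    if (!col %in% names(per_acc)) per_acc[[col]] <- 0L
  per_acc <- dplyr::right_join(
    dplyr::rename(per_acc, n_gain = "gain", n_loss = "loss"),
    tibble::tibble(accession = accs[both]), by = "accession")
  per_acc[is.na(per_acc)] <- 0L
  consensus <- dplyr::filter(
    dplyr::summarise(
      dplyr::group_by(calls, .data$window_id, .data$chrom, .data$start, .data$end),
      n_accessions = dplyr::n(),
      direction = names(sort(table(.data$direction), decreasing = TRUE))[1],
      .groups = "drop"),
    .data$n_accessions >= k)
  structure(list(per_accession = per_acc, consensus = consensus, calls = calls),
            class = "temperature_dmrs")
}

#' @export
print.temperature_dmrs <- function(x, ...) {
  cat("<temperature_dmrs> ", nrow(x$per_accession), " accessions; mean gains ",
      round(mean(x$per_accession$n_gain), 1), ", mean losses ",
      round(mean(x$per_accession$n_loss), 1), "; consensus windows ",
      nrow(x$consensus), "\n", sep = "")
  invisible(x)
}

#' Overlap of DMRs with annotated features
#'
#' Fraction of query DMRs directly overlapping a feature, and fraction
#' lying within `flank` bp of the nearest feature edge (intervals are
#' 1-based closed; touching intervals are at distance 0, so a DMR ending
#' exactly `flank` bp before a feature counts as within the flank).
#'
#' @param dmrs Tibble with `chrom`, `start`, `end`.
#' @param features Tibble with `chrom`, `start`, `end`.
#' @param flank Distance threshold in bp.
#' @return One-row tibble: `n_dmrs`, `n_direct`, `n_within_flank`,
#'   `frac_direct`, `frac_within_flank`.
#' @export
annotate_overlap <- function(dmrs, features, flank = 500) {
  stopf(nrow(dmrs) > 0, "empty DMR set: overlap fractions undefined")
  stopf(nrow(features) >= 0, "features must be a data frame")
  q <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(dmrs$start, dmrs$end))
  if (nrow(features) == 0) {
    return(tibble::tibble(n_dmrs = nrow(dmrs), n_direct = 0L,
                          n_within_flank = 0L, frac_direct = 0,
                          frac_within_flank = 0))
  }
  s <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start, features$end))
  direct <- GenomicRanges::countOverlaps(q, s) > 0
  d <- GenomicRanges::distanceToNearest(q, s)
  dist <- rep(Inf, length(q))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  near <- dist <= flank
  tibble::tibble(n_dmrs = nrow(dmrs),
                 n_direct = sum(direct),
                 n_within_flank = sum(near),
                 frac_direct = mean(direct),
                 frac_within_flank = mean(near))
}

#' Pathway-dependent DMRs from mutant vs wild type
#'
#' Calls pairwise DMRs between a methylation-pathway mutant and its
#' wild-type control and keeps, by default, the windows that lose
#' methylation in the mutant — the pathway-dependent set (e.g.
#' CMT2-dependent, DCL3-dependent), labelled by the mutated gene.
#'
#' @param mutant_counts,wildtype_counts Cytosine-report tibbles.
#' @param label Name of the mutated gene (labels the returned set).
#' @param direction `"loss"` (default) restricts to windows with lower
#'   methylation in the mutant; `"both"` disables the filter.
#' @param ... Passed to [pairwise_dmr_test()].
#' @return Tibble of calls with a `dependent_on` column.
#' @export
dependent_dmrs <- function(mutant_counts, wildtype_counts, label = "mutant",
                           direction = c("loss", "both"), ...) {
  direction <- match.arg(direction)
  # orientation: A = wild type, B = mutant, so loss-in-mutant == "loss"
  calls <- pairwise_dmr_test(wildtype_counts, mutant_counts, ...)
  if (direction == "loss")
    calls <- dplyr::filter(calls, .data$direction == "loss")
  dplyr::mutate(calls, dependent_on = label)
}

#' Fisher overlap enrichment between two window sets
#'
#' Given two window sets and the set each overlaps (e.g. pathway-dependent
#' DMRs vs the consensus temperature DMRs), builds the 2x2 contingency
#' table of overlap counts, reports per-set overlap percentages (rounded
#' to the nearest integer), the odds ratio, and Fisher's exact p-value.
#'
#' `overlap_enrichment()` works from id vectors;
#' `overlap_enrichment_counts()` from the four printed counts directly.
#'
#' @param set_a,set_b Character vectors of window ids.
#' @param reference Character vector: the windows both sets are tested for
#'   overlap with.
#' @param universe Character vector containing all candidate windows
#'   (supersets of both sets).
#' @return One-row tibble: counts, `pct_a`, `pct_b`, `odds_ratio`, `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, reference, universe) {
  stopf(length(universe) > 0, "empty universe")
  stopf(all(set_a %in% universe) && all(set_b %in% universe),
        "sets must be subsets of the universe")
  overlap_enrichment_counts(sum(set_a %in% reference), length(set_a),
                            sum(set_b %in% reference), length(set_b))
}

#' @rdname overlap_enrichment
#' @param n_a_overlap,n_a Overlapping and total counts for set A.
#' @param n_b_overlap,n_b Overlapping and total counts for set B.
#' @export
overlap_enrichment_counts <- function(n_a_overlap, n_a, n_b_overlap, n_b) {
  stopf(n_a > 0 && n_b > 0, "both sets must be non-empty")
  stopf(n_a_overlap <= n_a && n_b_overlap <= n_b,
        "overlap counts cannot exceed set sizes")
  tab <- matrix(c(n_a_overlap, n_a - n_a_overlap,
                  n_b_overlap, n_b - n_b_overlap), 2,
                dimnames = list(c("overlap", "no_overlap"), c("A", "B")))
  ft <- stats::fisher.test(tab)
  or <- unname(ft$estimate)
  # degenerate tables (e.g. identical fully-overlapping sets) have an
  # undefined conditional-MLE odds ratio; report the infinity cap
  if (is.na(or) || !is.finite(or) ||
      (n_a_overlap == n_a && n_b_overlap == n_b)) or <- Inf
  tibble::tibble(n_a = n_a, n_a_overlap = n_a_overlap,
                 n_b = n_b, n_b_overlap = n_b_overlap,
                 pct_a = round(100 * n_a_overlap / n_a),
                 pct_b = round(100 * n_b_overlap / n_b),
                 odds_ratio = or,
                 p = max(ft$p.value, .Machine$double.xmin))
}

#' Transposon-family enrichment among variable TEs
#'
#' For each TE family (or superfamily), compares the observed number of
#' "variable" TEs in the family with the expectation under random
#' labelling, and calibrates significance by permuting the variable label
#' over all TEs: a family is over-represented when its observed count
#' exceeds the 95th percentile of the permutation null. The empirical
#' p-value uses the add-one rule `(r + 1) / (n_perm + 1)`.
#'
#' @param variable_ids Character vector of variable TE ids (subset of
#'   `tes$feature_id`).
#' @param tes Tibble of all TEs with `feature_id` and the grouping column.
#' @param group Grouping column name, `"family"` or `"superfamily"`.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Tibble per family: `n_family`, `observed`, `expected`,
#'   `enrichment`, `q95` (95th null percentile), `p`,
#'   `over_represented`.
#' @export
te_family_enrichment <- function(variable_ids, tes, group = "family",
                                 n_perm = 1000, seed = 1) {
  stopf(all(variable_ids %in% tes$feature_id),
        "variable_ids must be a subset of tes$feature_id")
  fam <- factor(tes[[group]])
  keep <- !is.na(fam)
  fam <- droplevels(fam[keep])
  ids <- tes$feature_id[keep]
  n_all <- length(ids)
  n_var <- sum(ids %in% variable_ids)
  fam_sizes <- table(fam)
  observed <- table(fam[ids %in% variable_ids])
  expected <- n_var * as.numeric(fam_sizes) / n_all
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      lab <- sample.int(n_all, n_var)
      as.numeric(table(fam[lab]))
    }, numeric(nlevels(fam))))
  })
  q95 <- apply(null, 2, quantile, probs = 0.95, type = 1)
  r <- vapply(seq_len(nlevels(fam)),
              function(j) sum(null[, j] >= as.numeric(observed)[j]), numeric(1))
  tibble::tibble(
    !!group := levels(fam),
    n_family = as.integer(fam_sizes),
    observed = as.integer(observed),
    expected = expected,
    enrichment = ifelse(expected > 0, as.numeric(observed) / expected, NA_real_),
    q95 = q95,
    p = (r + 1) / (n_perm + 1),
    over_represented = as.numeric(observed) > q95 & as.numeric(observed) > expected)
}
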