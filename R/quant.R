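#' Per-site methylation levels
#'
#' Computes the methylation level of every cytosine individually as
#' `meth / total`, leaving sites below the coverage cutoff (or with zero
#' coverage) missing. Records with `meth > total` are rejected.
#'
#' @param counts Cytosine-report tibble with at least `meth` and `total`
#'   columns (any grouping columns such as `accession`, `env`, `chrom`,
#'   `pos`, `context` are carried through).
#' @param min_coverage Minimum read depth for a site level to be defined.
#' @return The input tibble with a `level` column (`NA` where
#'   undercovered).
#' @export
site_levels <- function(counts, min_coverage = 1) {
  stopf(is_count(min_coverage), "min_coverage must be a positive integer")
  stopf(all(c("meth", "total") %in% names(counts)),
        "counts must have meth and total columns")
  bad <- which(counts$meth > counts$total)
  stopf(length(bad) == 0, "%d records have meth > total (first at row %d)",
        length(bad), if (length(bad)) bad[1] else 0L)
  dplyr::mutate(tibble::as_tibble(counts),
                level = ifelse(.data$total >= min_coverage,
                               .data$meth / .data$total, NA_real_))
}

#' Bisulfite conversion efficiency from the chloroplast
#'
#' The chloroplast genome is unmethylated, so any apparent methylation
#' there reflects failed conversion. Efficiency is estimated per sample as
#' `1 - sum(meth) / sum(total)` over chloroplast cytosines.
#'
#' @param counts Cytosine-report tibble with a `chrom` column.
#' @param chloroplast Name of the chloroplast contig.
#' @param by Grouping columns (default per accession and environment; use
#'   `character()` for a single pooled estimate).
#' @return Tibble with the grouping columns, `efficiency`, and the read
#'   totals it is based on.
#' @export
conversion_efficiency <- function(counts, chloroplast = chloroplast_contig(),
                                  by = intersect(c("accession", "env"),
                                                 names(counts))) {
  cp <- dplyr::filter(counts, .data$chrom == chloroplast, .data$total > 0)
  stopf(nrow(cp) > 0, "no covered chloroplast cytosines (contig '%s')",
        chloroplast)
  dplyr::summarise(dplyr::group_by(cp, dplyr::across(dplyr::all_of(by))),
                   meth_reads = sum(.data$meth),
                   total_reads = sum(.data$total),
                   efficiency = 1 - .data$meth_reads / .data$total_reads,
                   .groups = "drop")
}

#' Genome-wide context averages
#'
#' Mean methylation level per sequence context for each accession and
#' environment, excluding the chloroplast control contig. By default this
#' is the unweighted mean of per-site levels over covered sites; with
#' `weighted = TRUE` it is the read-count-weighted level
#' `sum(meth)/sum(total)`.
#'
#' @param counts Cytosine-report tibble.
#' @param contexts Contexts to include.
#' @param min_coverage Minimum depth for a site to contribute.
#' @param weighted Use count-weighted averaging instead of the unweighted
#'   mean of site levels.
#' @param chloroplast Contig excluded from the averages.
#' @return Tibble with `accession`, `env`, `context`, `level`, `n_sites`.
#' @export
context_averages <- function(counts, contexts = c("CG", "CHG", "CHH"),
                             min_coverage = 1, weighted = FALSE,
                             chloroplast = chloroplast_contig()) {
  missing_ctx <- setdiff(contexts, unique(counts$context))
  if (length(missing_ctx))
    warn(paste("contexts absent from data:", paste(missing_ctx, collapse = ", ")))
  sl <- site_levels(dplyr::filter(counts, .data$context %in% contexts,
                                  .data$chrom != chloroplast),
                    min_coverage = min_coverage)
  sl <- dplyr::filter(sl, !is.na(.data$level))
  by <- intersect(c("accession", "env", "context"), names(sl))
  out <- dplyr::summarise(
    dplyr::group_by(sl, dplyr::across(dplyr::all_of(by))),
    level = if (weighted) sum(.data$meth) / sum(.data$total) else mean(.data$level),
    n_sites = dplyr::n(), .groups = "drop")
  dplyr::mutate(out, context = factor(.data$context, levels = contexts))
}

#' Average methylation over genomic features
#'
#' Coverage-weighted mean methylation (`sum(meth)/sum(total)` over all
#' cytosines within the feature span) per feature and sample, in the style
#' of feature-averaging over genes or large transposons. Features can be
#' filtered by type, minimum length, or an arbitrary predicate before
#' averaging.
#'
#' @param counts Cytosine-report tibble.
#' @param features Feature tibble (`feature_id`, `chrom`, `start`, `end`,
#'   plus optional `type`).
#' @param context Optional single context to restrict to.
#' @param type Optional feature type filter (e.g. `"TE"`).
#' @param min_length Keep only features at least this long (bp), e.g.
#'   2000 for large transposons.
#' @param genome_lengths Optional named vector of contig lengths; features
#'   extending beyond their contig are rejected.
#' @return Tibble with `feature_id`, grouping columns, `level`,
#'   `coverage` (total reads). Features with no covered site are absent.
#' @export
feature_average <- function(counts, features, context = NULL, type = NULL,
                            min_length = 0, genome_lengths = NULL) {
  stopf(nrow(features) > 0, "features must be non-empty")
  f <- features
  if (!is.null(type)) f <- dplyr::filter(f, .data$type %in% !!type)
  if (min_length > 0)
    f <- dplyr::filter(f, .data$end - .data$start + 1 >= min_length)
  if (!is.null(genome_lengths)) {
    bad <- f$start < 1 | f$end > genome_lengths[f$chrom]
    stopf(!anyNA(bad), "features on contigs absent from genome_lengths")
    if (any(bad)) {
      warn(sprintf("rejecting %d features outside genome bounds", sum(bad)))
      f <- f[!bad, ]
    }
  }
  x <- counts
  if (!is.null(context)) x <- dplyr::filter(x, .data$context %in% !!context)
  hit <- overlap_join(x, f)
  by <- intersect(c("feature_id", "accession", "env"), names(hit))
  dplyr::summarise(dplyr::group_by(hit, dplyr::across(dplyr::all_of(by))),
                   level = sum(.data$meth) / sum(.data$total),
                   coverage = sum(.data$total), .groups = "drop")
}

# Join point records (chrom, pos) to intervals (chrom, start, end);
# returns records annotated with the matching feature columns.
overlap_join <- function(points, intervals) {
  pts <- GenomicRanges::GRanges(points$chrom,
                                IRanges::IRanges(points$pos, width = 1))
  iv <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start, intervals$end))
  ov <- GenomicRanges::findOverlaps(pts, iv)
  cbind(points[S4Vectors::queryHits(ov), ],
        intervals[S4Vectors::subjectHits(ov),
                  setdiff(names(intervals), names(points))])
}

#' Sliding-window methylation matrix
#'
#' Aggregates site counts into overlapping sliding windows (default 200 bp
#' windows centered every 100 bp) per accession and environment, using
#' count-weighted levels. Windows tile each chromosome from position 1;
#' only full-size windows are kept, and a window with no covered site in a
#' sample is missing for that sample.
#'
#' @param counts Cytosine-report tibble.
#' @param size Window size in bp; must be a multiple of `step`.
#' @param step Window step in bp.
#' @param context Optional context restriction (e.g. `"CHH"`).
#' @param chrom_lengths Named vector of chromosome lengths; inferred from
#'   the data maximum when absent.
#' @param chloroplast Contig to exclude.
#' @return Tibble with `window_id`, `chrom`, `start`, `end`, `accession`,
#'   `env`, `level`, `coverage`.
#' @export
sliding_windows <- function(counts, size = 200, step = 100, context = NULL,
                            chrom_lengths = NULL,
                            chloroplast = chloroplast_contig()) {
  stopf(is.numeric(size) && size > 0, "size must be > 0")
  stopf(size %% step == 0, "size must be a multiple of step")
  m <- size %/% step
  x <- dplyr::filter(counts, .data$chrom != chloroplast, .data$total > 0)
  if (!is.null(context)) x <- dplyr::filter(x, .data$context %in% !!context)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(x$pos, x$chrom, max)
  }
  # window k (1-based) covers [1 + (k-1)*step, (k-1)*step + size]
  n_win <- pmax(0, (as.integer(chrom_lengths) - size) %/% step + 1)
  names(n_win) <- names(chrom_lengths)
  reps <- vector("list", m)
  for (j in seq_len(m)) {
    k <- (x$pos - 1L) %/% step + 1L - (j - 1L)      # j-th window holding pos
    ok <- k >= 1 & k <= n_win[x$chrom] & x$pos <= (k - 1) * step + size
    reps[[j]] <- dplyr::mutate(x[ok, ], win = k[ok])
  }
  xr <- dplyr::bind_rows(reps)
  by <- intersect(c("chrom", "win", "accession", "env"), names(xr))
  out <- dplyr::summarise(dplyr::group_by(xr, dplyr::across(dplyr::all_of(by))),
                          level = sum(.data$meth) / sum(.data$total),
                          coverage = sum(.data$total), .groups = "drop")
  out <- dplyr::mutate(out,
                       start = (.data$win - 1L) * as.integer(step) + 1L,
                       end = (.data$win - 1L) * as.integer(step) + as.integer(size),
                       window_id = paste0(.data$chrom, ":", .data$start, "-", .data$end))
  dplyr::select(out, "window_id", "chrom", "start", "end",
                dplyr::any_of(c("accession", "env")), "level", "coverage")
}

#' Select the most variable windows
#'
#' Reproduces the variable-window (DMR) selection used upstream of GWAS:
#' windows with missing data in more than `max_missing` of the accessions
#' are dropped (default: any missing accession drops the window), the
#' remainder are ranked by across-accession variance of the window level,
#' and the `top_n` most variable are returned. Ties are broken by genomic
#' order (earlier coordinate first).
#'
#' @param wm Window tibble from [sliding_windows()], typically filtered to
#'   one environment.
#' @param top_n Number of windows to keep.
#' @param max_missing Maximum tolerated fraction of accessions with
#'   missing level per window (default 0: complete data required).
#' @param accessions Optional character vector giving the full accession
#'   panel (defaults to those observed in `wm`).
#' @return Tibble of selected windows (`window_id`, `chrom`, `start`,
#'   `end`, `variance`, `rank`), in rank order.
#' @export
select_variable_windows <- function(wm, top_n, max_missing = 0,
                                    accessions = unique(wm$accession)) {
  n_acc <- length(accessions)
  stats <- dplyr::summarise(
    dplyr::group_by(wm, .data$window_id, .data$chrom, .data$start, .data$end),
    n_obs = dplyr::n_distinct(.data$accession),
    variance = stats::var(.data$level), .groups = "drop")
  stats <- dplyr::filter(stats, (n_acc - .data$n_obs) / n_acc <= max_missing,
                         !is.na(.data$variance))
  if (nrow(stats) < top_n) {
    warn(sprintf("only %d windows pass the missingness filter (requested %d)",
                 nrow(stats), top_n))
    top_n <- nrow(stats)
  }
  stats <- dplyr::arrange(stats, dplyr::desc(.data$variance),
                          .data$chrom, .data$start)
  dplyr::mutate(dplyr::slice_head(stats, n = top_n),
                rank = dplyr::row_number())
}

#' Classify genes as gene-body methylated
#'
#' A gene is gene-body methylated (GBM) when its across-accession mean CG
#' methylation is at least `cg_min` while CHG (and by default CHH) stays
#' below `chg_max`; genes below the CG cutoff with low non-CG methylation
#' are "unmethylated", and genes with substantial non-CG methylation are
#' "TE-like" and excluded from GBM analyses. Genes missing a required
#' context are excluded with a reason.
#'
#' @param gene_levels Tibble with `gene_id`, `accession`, `context`,
#'   `level` (long layout; one row per gene x accession x context).
#' @param cg_min Minimum mean CG level for GBM (default 0.05).
#' @param chg_max Maximum mean CHG (and CHH) level (default 0.05).
#' @param use_chh Also require CHH below `chg_max`.
#' @return Tibble with `gene_id`, mean `cg`, `chg`, `chh` and `label` in
#'   `{GBM, unmethylated, TE-like, excluded}`.
#' @export
classify_gbm_genes <- function(gene_levels, cg_min = 0.05, chg_max = 0.05,
                               use_chh = TRUE) {
  means <- dplyr::summarise(
    dplyr::group_by(gene_levels, .data$gene_id, .data$context),
    level = mean(.data$level, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "context",
                             values_from = "level")
  for (ctx in c("CG", "CHG", "CHH"))
    if (!ctx %in% names(wide)) wide[[ctx]] <- NA_real_
  need_chh <- use_chh
  dplyr::transmute(
    wide,
    gene_id = .data$gene_id,
    cg = .data$CG, chg = .data$CHG, chh = .data$CHH,
    label = dplyr::case_when(
      is.na(cg) | is.na(chg) | (need_chh & is.na(chh)) ~ "excluded",
      cg >= cg_min & chg < chg_max & (!need_chh | chh < chg_max) ~ "GBM",
      cg < cg_min & chg < chg_max & (!need_chh | chh < chg_max) ~ "unmethylated",
      TRUE ~ "TE-like"))
}

#' Compare per-site methylation between two accession groups
#'
#' For each site, computes the mean level within each group of accessions
#' (e.g. northern vs southern), the first-minus-second difference, and,
#' per group, the count of sites where methylation is detectable (group
#' mean at or above `detect_cutoff`).
#'
#' @param levels Site-level tibble (from [site_levels()]) with an
#'   `accession` column.
#' @param groups Tibble with `accession` and `group` columns; every
#'   group needs at least 2 accessions.
#' @param detect_cutoff Detection threshold on the group mean level.
#' @return List of class `site_group_comparison` with `per_site` (site
#'   coordinates, the two group means, `diff`) and `detected` (per-group
#'   detected-site counts).
#' @export
site_group_comparison <- function(levels, groups, detect_cutoff = 0.01) {
  gtab <- table(groups$group)
  stopf(length(gtab) == 2, "exactly two groups required")
  stopf(all(gtab >= 2), "each group needs at least 2 accessions")
  gl <- levels(factor(groups$group))
  x <- dplyr::inner_join(levels, groups, by = "accession")
  key <- intersect(c("chrom", "pos", "strand", "context"), names(x))
  per_site <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(x, dplyr::across(dplyr::all_of(c(key, "group")))),
      mean_level = mean(.data$level, na.rm = TRUE), .groups = "drop"),
    names_from = "group", values_from = "mean_level")
  per_site$diff <- per_site[[gl[1]]] - per_site[[gl[2]]]
  detected <- tibble::tibble(
    group = gl,
    n_detected = vapply(gl, function(g)
      sum(per_site[[g]] >= detect_cutoff, na.rm = TRUE), integer(1)),
    n_sites = vapply(gl, function(g)
      sum(!is.na(per_site[[g]])), integer(1)))
  structure(list(per_site = per_site, detected = detected),
            class = "site_group_comparison")
}

#' @export
print.site_group_comparison <- function(x, ...) {
  cat("<site_group_comparison> ", nrow(x$per_site), " sites; median diff ",
      signif(median(x$per_site$diff, na.rm = TRUE), 3), "\n", sep = "")
  print(x$detected)
  invisible(x)
}
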