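test_that("site levels follow the coverage rule and reject bad records", {
  counts <- tibble::tibble(chrom = "Chr1", pos = c(10L, 20L, 30L),
                           strand = "+", context = "CG",
                           meth = c(3L, 0L, 2L), total = c(10L, 0L, 4L))
  lv <- site_levels(counts)
  expect_equal(lv$level, c(0.3, NA, 0.5))
  lv5 <- site_levels(counts, min_coverage = 5)
  expect_equal(lv5$level, c(0.3, NA, NA))
  bad <- counts; bad$meth[1] <- 11L
  expect_error(site_levels(bad), "meth > total")
})

test_that("conversion efficiency reproduces the chloroplast arithmetic", {
  cp <- tibble::tibble(chrom = chloroplast_contig(), pos = 1:100, strand = "+",
                       context = "CHH", meth = 0L, total = 50L)
  expect_equal(conversion_efficiency(cp, by = character())$efficiency, 1)
  cp2 <- cp; cp2$meth <- c(41L, rep(0L, 99)); cp2$total <- rep(100L, 100)
  expect_equal(conversion_efficiency(cp2, by = character())$efficiency,
               1 - 41 / 10000)
  expect_equal(conversion_efficiency(cp2, by = character())$efficiency, 0.9959)
  cp3 <- cp; cp3$meth <- cp3$total
  expect_equal(conversion_efficiency(cp3, by = character())$efficiency, 0)
  expect_error(conversion_efficiency(dplyr::mutate(cp, chrom = "Chr1")),
               "chloroplast")
})

test_that("context averages are unweighted site means with a weighted option", {
  counts <- tibble::tibble(
    accession = "a1", env = "10C", chrom = "Chr1", pos = c(1L, 2L),
    strand = "+", context = "CG", meth = c(1L, 9L), total = c(10L, 10L))
  ca <- context_averages(counts, contexts = "CG")
  expect_equal(ca$level, 0.5)                       # (0.1 + 0.9) / 2
  caw <- context_averages(counts, contexts = "CG", weighted = TRUE)
  expect_equal(caw$level, 0.5)                      # 10/20 here too
  counts2 <- counts; counts2$total <- c(10L, 90L); counts2$meth <- c(1L, 45L)
  expect_equal(context_averages(counts2, contexts = "CG")$level, 0.3)
  expect_equal(context_averages(counts2, contexts = "CG", weighted = TRUE)$level,
               46 / 100)
  # duplicated accession gives identical values
  dup <- dplyr::mutate(counts, accession = "a2")
  ca2 <- context_averages(dplyr::bind_rows(counts, dup), contexts = "CG")
  expect_equal(ca2$level[1], ca2$level[2])
  expect_warning(context_averages(counts, contexts = c("CG", "CHH")),
                 "absent")
})

test_that("feature averages are count-weighted and honor filters", {
  counts <- tibble::tibble(
    accession = "a1", env = "10C", chrom = "Chr1",
    pos = c(100L, 150L, 500L), strand = "+", context = "CHH",
    meth = c(1L, 9L, 5L), total = c(10L, 10L, 10L))
  feats <- tibble::tibble(feature_id = c("te1", "te2"), chrom = "Chr1",
                          start = c(50L, 450L), end = c(200L, 520L),
                          type = "TE")
  fa <- feature_average(counts, feats)
  expect_equal(fa$level[fa$feature_id == "te1"], 10 / 20)   # not mean(0.1, 0.9)
  expect_equal(fa$level[fa$feature_id == "te2"], 0.5)
  # length filter keeps only features of the requested size
  fa2 <- feature_average(counts, feats, min_length = 100)
  expect_identical(unique(fa2$feature_id), "te1")
  # out-of-bounds features are rejected
  expect_warning(
    fa3 <- feature_average(counts, feats, genome_lengths = c(Chr1 = 300)),
    "outside genome bounds")
  expect_identical(unique(fa3$feature_id), "te1")
  expect_error(feature_average(counts, feats[0, ]), "non-empty")
})

test_that("sliding windows tile half-overlapping and propagate coverage", {
  # chromosome of length 1000 with 200/100 windows: 9 full windows
  counts <- tibble::tibble(
    accession = "a1", env = "10C", chrom = "Chr1",
    pos = seq(5L, 995L, by = 10L), strand = "+", context = "CHH",
    meth = 2L, total = 4L)
  wm <- sliding_windows(counts, size = 200, step = 100,
                        chrom_lengths = c(Chr1 = 1000))
  expect_identical(dplyr::n_distinct(wm$window_id), 9L)
  expect_true(all(wm$level == 0.5))

  # one covered interior site lands in exactly two windows
  one <- counts[counts$pos == 255L, ]
  w1 <- sliding_windows(one, size = 200, step = 100,
                        chrom_lengths = c(Chr1 = 1000))
  expect_identical(nrow(w1), 2L)
  expect_setequal(w1$start, c(101L, 201L))
  expect_true(all(w1$level == 0.5))

  # sites with no reads produce no windows
  zero <- dplyr::mutate(counts, meth = 0L, total = 0L)
  expect_identical(nrow(sliding_windows(zero, size = 200, step = 100,
                                        chrom_lengths = c(Chr1 = 1000))), 0L)
  expect_error(sliding_windows(counts, size = -1, step = 1), "size")
  expect_error(sliding_windows(counts, size = 150, step = 100), "multiple")
})

test_that("variable-window selection ranks by variance with genomic ties", {
  mk <- function(acc, lv) tibble::tibble(
    window_id = paste0("Chr1:", c(1, 101, 201), "-", c(200, 300, 400)),
    chrom = "Chr1", start = c(1L, 101L, 201L), end = c(200L, 300L, 400L),
    accession = acc, env = "10C", level = lv, coverage = 10L)
  wm <- dplyr::bind_rows(mk("a1", c(0.1, 0.5, 0.3)), mk("a2", c(0.1, 0.9, 0.7)))
  sel <- select_variable_windows(wm, top_n = 1)
  expect_identical(sel$start, 101L)                  # most variable window
  all3 <- select_variable_windows(wm, top_n = 3)
  expect_identical(nrow(all3), 3L)
  # equal variance: earlier coordinate wins
  tie <- dplyr::bind_rows(mk("a1", c(0.2, 0.2, 0.1)), mk("a2", c(0.8, 0.8, 0.1)))
  sel_tie <- select_variable_windows(tie, top_n = 1)
  expect_identical(sel_tie$start, 1L)
  # missingness filter: window absent for one accession is dropped
  holey <- dplyr::bind_rows(mk("a1", c(0.1, 0.5, 0.3)),
                            mk("a2", c(0.1, 0.9, 0.7))[-2, ])
  sel_h <- suppressWarnings(select_variable_windows(holey, top_n = 3,
                                                    accessions = c("a1", "a2")))
  expect_identical(nrow(sel_h), 2L)
  expect_false("Chr1:101-300" %in% sel_h$window_id)
  expect_warning(select_variable_windows(wm, top_n = 5), "only")
})

test_that("GBM classification applies the CG/CHG cutoffs and is stable", {
  gl <- tidyr::expand_grid(gene_id = c("g1", "g2", "g3", "g4"),
                           accession = c("a1", "a2"),
                           context = c("CG", "CHG", "CHH"))
  lvl <- c(g1 = NA, g2 = NA, g3 = NA, g4 = NA)
  gl$level <- dplyr::case_when(
    gl$gene_id == "g1" & gl$context == "CG" ~ 0.30,
    gl$gene_id == "g2" & gl$context == "CG" ~ 0.04,
    gl$gene_id == "g3" & gl$context == "CG" ~ 0.80,
    gl$gene_id == "g3" & gl$context == "CHG" ~ 0.40,
    gl$gene_id == "g4" & gl$context == "CG" ~ 0.10,
    TRUE ~ 0.01)
  cls <- classify_gbm_genes(gl)
  lab <- setNames(cls$label, cls$gene_id)
  expect_identical(unname(lab[c("g1", "g2", "g3", "g4")]),
                   c("GBM", "unmethylated", "TE-like", "GBM"))
  # permutation invariance over accessions
  cls2 <- classify_gbm_genes(gl[sample.int(nrow(gl)), ])
  expect_identical(dplyr::arrange(cls, gene_id), dplyr::arrange(cls2, gene_id))
  # idempotence of the boundary: exactly 5% CG is GBM, just under is not
  gb <- tibble::tibble(gene_id = c("e1", "e2"), accession = "a1",
                       context = "CG", level = c(0.05, 0.049999))
  gb <- dplyr::bind_rows(gb, dplyr::mutate(gb, context = "CHG", level = 0.01),
                         dplyr::mutate(gb, context = "CHH", level = 0.01))
  clb <- classify_gbm_genes(gb)
  expect_identical(setNames(clb$label, clb$gene_id)[c("e1", "e2")],
                   c(e1 = "GBM", e2 = "unmethylated"))
  # missing context -> excluded
  miss <- tibble::tibble(gene_id = "gm", accession = "a1", context = "CG",
                         level = 0.3)
  expect_identical(classify_gbm_genes(miss)$label, "excluded")
})

test_that("site group comparison recovers planted shifts and detection counts", {
  set.seed(1)
  n_sites <- 300
  base <- runif(n_sites, 0.1, 0.4)
  delta <- 0.1
  mk <- function(acc, shift) tibble::tibble(
    accession = acc, chrom = "Chr1", pos = seq_len(n_sites), strand = "+",
    context = "CG", level = pmin(pmax(base + shift + rnorm(n_sites, 0, 0.02), 0), 1))
  lv <- dplyr::bind_rows(mk("n1", delta), mk("n2", delta),
                         mk("s1", 0), mk("s2", 0))
  groups <- tibble::tibble(accession = c("n1", "n2", "s1", "s2"),
                           group = c("north", "north", "south", "south"))
  cmpres <- site_group_comparison(lv, groups)
  expect_equal(median(cmpres$per_site$diff), delta, tolerance = 0.02)
  # identical groups: all differences zero
  lv0 <- dplyr::bind_rows(mk("n1", 0), mk("n2", 0), mk("s1", 0), mk("s2", 0))
  lv0$level <- rep(base, 4)
  cmp0 <- site_group_comparison(lv0, groups)
  expect_true(all(cmp0$per_site$diff == 0))
  # zero cutoff counts every covered site as detected
  cmp_all <- site_group_comparison(lv, groups, detect_cutoff = 0)
  expect_true(all(cmp_all$detected$n_detected == cmp_all$detected$n_sites))
  expect_error(site_group_comparison(lv, groups[1:2, ]), "two groups")
})
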