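test_that("pairwise DMR test matches Fisher, filters and orients correctly", {
  mk <- function(meth, total) tibble::tibble(
    chrom = "Chr1", pos = 50L, strand = "+", context = "CHH",
    meth = meth, total = total)
  # equal proportions: p = 1, no call
  res <- pairwise_dmr_test(mk(50L, 100L), mk(50L, 100L), all = TRUE)
  expect_equal(res$p, 1)
  expect_false(res$call)
  # extreme difference: tiny p, difference 1, gain in B
  res2 <- pairwise_dmr_test(mk(0L, 60L), mk(60L, 60L))
  expect_identical(nrow(res2), 1L)
  expect_lt(res2$p, 1e-15)
  expect_equal(res2$difference, 1)
  expect_identical(res2$direction, "gain")
  # min_diff filters small differences regardless of p
  a <- mk(100L, 1000L); b <- mk(300L, 1000L)       # diff 0.2, p astronomically small
  res3 <- pairwise_dmr_test(a, b, all = TRUE)
  expect_lt(res3$p, 1e-10)
  expect_false(res3$call)
  expect_identical(nrow(pairwise_dmr_test(a, b)), 0L)
})

test_that("Fisher p equals hypergeometric-tail summation on small tables", {
  set.seed(42)
  for (i in 1:25) {
    tot_a <- sample(5:100, 1); tot_b <- sample(5:100, 1)
    ma <- rbinom(1, tot_a, runif(1)); mb <- rbinom(1, tot_b, runif(1))
    ca <- tibble::tibble(chrom = "Chr1", pos = 10L, strand = "+",
                         context = "CHH", meth = ma, total = tot_a)
    cb <- dplyr::mutate(ca, meth = mb, total = tot_b)
    res <- pairwise_dmr_test(ca, cb, all = TRUE)
    expect_equal(res$p, fisher_oracle(ma, tot_a - ma, mb, tot_b - mb),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and call count non-increasing in fdr", {
  set.seed(7)
  A <- counts_from_window_p(rep(0.1, 300))
  pB <- rep(0.1, 300); pB[1:30] <- 0.6
  B <- counts_from_window_p(pB)
  res <- pairwise_dmr_test(A, B, all = TRUE)
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
  n_strict <- nrow(pairwise_dmr_test(A, B, fdr = 0.01))
  n_loose <- nrow(pairwise_dmr_test(A, B, fdr = 0.10))
  expect_lte(n_strict, n_loose)
})

test_that("temperature DMRs count gains/losses antisymmetrically", {
  set.seed(11)
  mk_counts <- function(acc, env, p) dplyr::mutate(
    counts_from_window_p(p), accession = acc, env = env, .before = 1)
  p10 <- rep(0.1, 200); p16 <- p10; p16[1:20] <- 0.7; p16[21:30] <- NA
  p16[21:30] <- 0.1; p10b <- p10; p10b[21:30] <- 0.7   # loss windows
  counts <- dplyr::bind_rows(mk_counts("a1", "10C", p10b),
                             mk_counts("a1", "16C", p16))
  td <- temperature_dmrs(counts)
  expect_gt(td$per_accession$n_gain, 10)
  expect_gt(td$per_accession$n_loss, 5)
  # swapped environment labels exchange gains and losses exactly
  swapped <- dplyr::mutate(counts, env = ifelse(env == "10C", "16C", "10C"))
  td_sw <- temperature_dmrs(swapped)
  expect_identical(td$per_accession$n_gain, td_sw$per_accession$n_loss)
  expect_identical(td$per_accession$n_loss, td_sw$per_accession$n_gain)
  # null pair: background consistent with the FDR level
  set.seed(12)
  null_counts <- dplyr::bind_rows(mk_counts("a1", "10C", rep(0.2, 300)),
                                  mk_counts("a1", "16C", rep(0.2, 300)))
  td0 <- temperature_dmrs(null_counts)
  expect_lte(td0$per_accession$n_gain + td0$per_accession$n_loss, 15)
  expect_error(temperature_dmrs(mk_counts("a1", "10C", p10)), "both environments")
})

test_that("overlap annotation uses closed intervals and the flank boundary", {
  tes <- tibble::tibble(chrom = "Chr1", start = 2000L, end = 3000L)
  dmr_in <- tibble::tibble(chrom = "Chr1", start = 2400L, end = 2500L)
  ov <- annotate_overlap(dmr_in, tes)
  expect_equal(ov$frac_direct, 1)
  # ends exactly 500 bp before the TE: within flank; 501 bp: outside
  dmr_edge <- tibble::tibble(chrom = "Chr1", start = 1400L, end = 1500L)
  expect_equal(annotate_overlap(dmr_edge, tes, flank = 500)$frac_within_flank, 1)
  dmr_far <- tibble::tibble(chrom = "Chr1", start = 1398L, end = 1498L)
  expect_equal(annotate_overlap(dmr_far, tes, flank = 500)$frac_within_flank, 0)
  # empty inputs
  expect_error(annotate_overlap(dmr_in[0, ], tes), "empty DMR set")
  ov0 <- annotate_overlap(dmr_in, tes[0, ])
  expect_equal(ov0$frac_direct, 0)
})

test_that("pathway-dependent DMRs recover planted knockout windows", {
  set.seed(5)
  n_win <- 400
  planted <- sample(n_win, 60)
  p_wt <- rep(0.55, n_win)
  p_mut <- p_wt; p_mut[planted] <- 0.02
  wt <- counts_from_window_p(p_wt, depth = 30)
  mut <- counts_from_window_p(p_mut, depth = 30)
  dd <- dependent_dmrs(mut, wt, label = "CMT2")
  called <- unique(dd$start %/% 100 + 1)
  expect_gte(mean(planted %in% called), 0.9)
  expect_identical(unique(dd$dependent_on), "CMT2")
  expect_true(all(dd$direction == "loss"))
  # wild type against itself: at most an FDR-consistent trickle
  set.seed(6)
  wt2 <- counts_from_window_p(p_wt, depth = 30)
  expect_lte(nrow(dependent_dmrs(wt2, wt)), 0.05 * n_win)
  # direction filter off also returns gains
  p_mut2 <- p_wt; p_mut2[1:10] <- 0.02; p_mut2[11:20] <- 1.0
  dd2 <- dependent_dmrs(counts_from_window_p(p_mut2, depth = 50), wt,
                        direction = "both")
  expect_true(all(c("loss", "gain") %in% dd2$direction))
})

test_that("overlap enrichment reproduces printed-count arithmetic", {
  oe <- overlap_enrichment_counts(4703, 10138, 2299, 33422)
  expect_identical(oe$pct_a, 46)
  expect_identical(oe$pct_b, 7)
  expect_lt(oe$p, 2.2e-16)
  expect_gt(oe$odds_ratio, 1)
  # id-vector interface agrees with the count interface
  universe <- paste0("w", 1:500)
  setA <- universe[1:100]; setB <- universe[101:300]
  ref <- universe[c(1:46, 101:115)]
  oe2 <- overlap_enrichment(setA, setB, ref, universe)
  expect_identical(oe2$pct_a, 46)
  expect_identical(oe2$n_b_overlap, 15L)
  # identical sets: capped odds ratio, representable p
  oe3 <- overlap_enrichment(setA, setA, setA, universe)
  expect_true(is.infinite(oe3$odds_ratio) || oe3$odds_ratio > 1e6)
  expect_gt(oe3$p, 0)
  expect_error(overlap_enrichment(setA, setB, ref, character()), "universe")
})

test_that("TE family enrichment is calibrated and exact in closed form", {
  tes <- tibble::tibble(feature_id = paste0("te", 1:200),
                        family = rep(c("A", "B", "C", "D"), c(80, 60, 40, 20)))
  # all variable TEs planted into one family: enrichment = |all| / |family|
  var_in_d <- tes$feature_id[tes$family == "D"][1:10]
  en <- te_family_enrichment(var_in_d, tes, n_perm = 200, seed = 1)
  expect_equal(en$enrichment[en$family == "D"], 200 / 20)
  expect_true(en$over_represented[en$family == "D"])
  expect_lt(en$p[en$family == "D"], 0.05)
  # observed < expected is never flagged
  expect_true(all(!en$over_represented[en$family != "D"]))
  # uniform null: mean enrichment per family near 1 across seeds
  means <- sapply(1:30, function(s) {
    v <- with_test_seed(s, sample(tes$feature_id, 40))
    te_family_enrichment(v, tes, n_perm = 50, seed = s)$enrichment
  })
  expect_true(all(abs(rowMeans(means) - 1) < 0.1))
  # reproducible under seed
  e1 <- te_family_enrichment(var_in_d, tes, n_perm = 100, seed = 9)
  e2 <- te_family_enrichment(var_in_d, tes, n_perm = 100, seed = 9)
  expect_identical(e1, e2)
})
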