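# Enrichment factors, exact tests, rank/hotspot profiles, conservation,
# positional composition, transcriptome scan.

test_that("enrichment factor arithmetic and degenerate cases", {
  e <- enrichment_factor(30, 100, 10, 100)
  expect_equal(e$r, 3)
  expect_false(e$r_undefined)
  # identical tables: r = 1, p = 1
  e2 <- enrichment_factor(25, 50, 25, 50)
  expect_equal(e2$r, 1)
  expect_equal(e2$p, 1)
  # zero non-hit count: infinite r, flagged
  e3 <- enrichment_factor(5, 50, 0, 50)
  expect_true(is.infinite(e3$r) && e3$r_undefined)
  expect_error(enrichment_factor(-1, 10, 0, 10), "negative")
  expect_error(enrichment_factor(11, 10, 0, 10), "exceeds")
})

test_that("two-sided Fisher p matches enumeration and the reference test", {
  # worked reference table: [[1,9],[11,3]]
  p_oracle <- oracle_fisher(1, 10, 11, 14)
  expect_equal(p_oracle, 0.00276, tolerance = 2e-3)
  expect_equal(fisher_p(1, 10, 11, 14), p_oracle, tolerance = 1e-12)
  expect_equal(fisher_p(1, 10, 11, 14),
               stats::fisher.test(rbind(c(1, 9), c(11, 3)))$p.value,
               tolerance = 1e-10)
  set.seed(33)
  for (k in 1:200) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_p(k1, n1, k2, n2), oracle_fisher(k1, n1, k2, n2),
                 tolerance = 1e-12)
    expect_equal(fisher_p(k1, n1, k2, n2),
                 stats::fisher.test(rbind(c(k1, n1 - k1),
                                          c(k2, n2 - k2)))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("r is invariant under scaling both cohorts", {
  for (m in c(2, 5, 10)) {
    expect_equal(enrichment_factor(6 * m, 20 * m, 3 * m, 30 * m)$r,
                 enrichment_factor(6, 20, 3, 30)$r)
  }
})

test_that("BH adjustment is monotone and dominated by the raw p", {
  set.seed(5)
  res <- do.call(rbind, lapply(1:30, function(i) {
    enrichment_factor(sample(0:20, 1), 20, sample(0:20, 1), 20,
                      motif_name = paste0("m", i))
  }))
  adj <- adjust_enrichment(res, "BH")
  expect_true(all(adj$p_adj >= adj$p - 1e-15))
  ord <- order(adj$p)
  expect_true(all(diff(adj$p_adj[ord]) >= -1e-15))
  bonf <- adjust_enrichment(res, "bonferroni")
  expect_true(all(bonf$p_adj >= adj$p_adj - 1e-15))
})

test_that("motif enrichment counts per siRNA, honours exclusion, is monotone in conjunction", {
  ft <- data.frame(
    sirna_id = c("h1", "h2", "h3", "n1", "n2", "n3", "n4"),
    any_site = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    n_sites = c(2, 1, 0, 1, 0, 0, 0),
    t1A = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  hits <- c("h1", "h2", "h3"); nons <- c("n1", "n2", "n3", "n4")
  e <- motif_enrichment(ft, hits, nons, "any_site")
  expect_equal(e$k_hits, 2); expect_equal(e$k_non, 1)
  expect_equal(e$r, (2 / 3) / (1 / 4))
  # exclusion applied to both cohorts first
  e2 <- motif_enrichment(ft, hits, nons, "t1A",
                         exclude = function(d) d$n_sites >= 2)
  expect_equal(e2$n_hits, 2)              # h1 excluded
  expect_equal(e2$k_hits, 0)
  # no-op exclusion equals no exclusion
  e3 <- motif_enrichment(ft, hits, nons, "any_site",
                         exclude = function(d) rep(FALSE, nrow(d)))
  expect_equal(e3[, -1], e[, -1])
  # conjunction never has larger counts than its terms
  conj <- motif_enrichment(ft, hits, nons,
                           function(d) d$any_site & d$t1A)
  expect_lte(conj$k_hits, e$k_hits)
  expect_error(motif_enrichment(ft, hits, nons, "any_site",
                                exclude = function(d) rep(TRUE, nrow(d))),
               "empty cohort")
  expect_error(motif_enrichment(ft, hits, c(nons, "h1"), "any_site"),
               "disjoint")
})

test_that("rank moving average matches a direct windowed mean", {
  expect_equal(rank_moving_average(rep(TRUE, 100), 10)$value, rep(1, 100))
  alt <- rep(c(0, 1), 50)
  rv <- rank_moving_average(alt, 2)$value
  expect_true(all(rv[1:99] == 0.5))
  step <- c(rep(1, 500), rep(0, 700))
  expect_equal(rank_moving_average(step, 500)$value,
               oracle_moving_mean(step, 500))
  expect_true(all(diff(rank_moving_average(step, 500)$value) <= 1e-12))
  set.seed(2)
  x <- runif(300) < 0.3
  for (w in c(1, 2, 7, 50, 301)) {
    expect_equal(rank_moving_average(x, w)$value, oracle_moving_mean(x, w))
  }
})

test_that("UTR hotspot profile peaks where hit sites cluster", {
  # identical site sets with equal cohort sizes: ratio exactly 1
  st <- c(5L, 40L, 41L, 90L)
  pr <- utr_hotspot_profile(st, st, 120, window = 20, n_hits = 10,
                            n_nonhits = 10)
  expect_equal(pr$ratio, rep(1, 120))
  # hits clustered in one block, non-hits uniform
  hit <- rep(100:140, 3)
  non <- seq(0, 390, by = 10)
  pr2 <- utr_hotspot_profile(hit, non, 400, window = 50)
  expect_true(which.max(pr2$ratio) >= 100 && which.max(pr2$ratio) <= 145)
  # direct windowed-density oracle
  ch <- tabulate(hit + 1L, 400); cn <- tabulate(non + 1L, 400)
  want <- (oracle_moving_mean(ch, 50) + 0.5) / (oracle_moving_mean(cn, 50) + 0.5)
  expect_equal(pr2$ratio, want)
  # no non-hit sites anywhere: pseudocount keeps the ratio finite
  pr3 <- utr_hotspot_profile(hit, integer(0), 400, window = 50)
  expect_true(all(is.finite(pr3$ratio)))
  # UTR shorter than the window behaves as a single truncated window
  expect_equal(nrow(utr_hotspot_profile(c(1L), integer(0), 10, window = 50)),
               10)
  expect_error(utr_hotspot_profile(500L, integer(0), 100), "outside")
})

test_that("conserved-region enrichment follows the site rule and the filter fraction", {
  hit_sites <- data.frame(sirna_id = c("h1", "h2", "h3"),
                          start = c(10L, 50L, 80L), length = 7L)
  non_sites <- data.frame(sirna_id = c("n1", "n2"),
                          start = c(10L, 80L), length = 7L)
  ones <- rep(1, 120); zeros <- rep(0, 120)
  all_in <- conserved_region_enrichment(hit_sites, non_sites, ones,
                                        n_hits = 3, n_non = 10)
  expect_equal(all_in$fraction_hits_predicted, 1)
  expect_equal(all_in$k_non, 2)
  none <- conserved_region_enrichment(hit_sites, non_sites, zeros,
                                      n_hits = 3, n_non = 10)
  expect_equal(none$k_hits, 0)
  expect_equal(none$fraction_hits_predicted, 0)
  # conserved only around the h1/n1 site: hand-computed ratio
  track <- zeros; track[11:17] <- 1
  sel <- conserved_region_enrichment(hit_sites, non_sites, track,
                                     n_hits = 3, n_non = 10)
  expect_equal(sel$k_hits, 1)
  expect_equal(sel$r_conserved, (1 / 3) / (1 / 10))
  expect_equal(sel$fraction_hits_predicted, 1 / 3)
  # mean rule vs all-bases rule at a half-covered site
  track2 <- zeros; track2[11:14] <- 1     # 4 of 7 bases, mean 4/7 >= 0.5
  m <- conserved_region_enrichment(hit_sites[1, ], non_sites[0, ], track2,
                                   n_hits = 1, n_non = 10)
  expect_equal(m$k_hits, 1)
  a <- conserved_region_enrichment(hit_sites[1, ], non_sites[0, ], track2,
                                   n_hits = 1, n_non = 10, rule = "all")
  expect_equal(a$k_hits, 0)
  expect_error(conserved_region_enrichment(hit_sites, non_sites, NULL,
                                           3, 10), "missing")
})

test_that("positional nucleotide ratios collapse duplicate seeds and compute exact ratios", {
  # a library whose position-2 bases are exactly uniform
  lib <- c("AAAAAAAAA", "ACAAAAAAA", "AGAAAAAAA", "AUAAAAAAA")
  lib <- vapply(seq_along(lib), function(i)
    paste0(substr(lib[i], 1, 9), strrep("A", 10)), character(1))
  hits <- lib[4]                           # all hits have U at position 2
  m <- position_nucleotide_ratio(hits, lib, positions = 2)
  expect_equal(unname(m["U", 1]), 4)
  expect_true(is.nan(m["C", 1]) || m["C", 1] == 0)  # freq 0 in hits
  # hits == library: every defined ratio is exactly 1
  m2 <- position_nucleotide_ratio(lib, lib, positions = 2:8)
  expect_true(all(m2[!is.nan(m2)] %in% c(1)))
  # duplicate seeds collapse
  m3 <- position_nucleotide_ratio(c(hits, hits, hits), lib, positions = 2)
  expect_equal(m3, position_nucleotide_ratio(hits, lib, positions = 2))
})

test_that("transcriptome scan ranks a planted off-target gene first", {
  lib <- generate_library(30, rng_seed = 41)
  txs <- generate_transcripts(8, utr3_length_range = c(250, 300),
                              rng_seed = 41)
  top <- lib$sirna_id[1:6]
  non <- lib$sirna_id[7:30]
  plan <- data.frame(sirna_id = top, transcript_id = names(txs)[3])
  pl <- plant_sites(txs, lib, plan, rng_seed = 41)
  scan <- transcriptome_offtarget_scan(lib, top, non, pl$transcripts,
                                       strands = "guide")
  expect_equal(scan$transcript_id[1], names(txs)[3])
  expect_equal(scan$k_top[1], 6)
  expect_equal(scan$k_non[1], 0)
  expect_lt(scan$p_adj[1], 0.01)
  # null: no sites anywhere -> all p = 1
  null_scan <- transcriptome_offtarget_scan(lib, top, non, pl$transcripts[-3],
                                            strands = "guide")
  expect_true(all(null_scan$p == 1))
  # both-strand union counts at least as many matches as either strand
  s_g <- transcriptome_offtarget_scan(lib, top, non, pl$transcripts, "guide")
  s_b <- transcriptome_offtarget_scan(lib, top, non, pl$transcripts, "both")
  m <- match(s_g$transcript_id, s_b$transcript_id)
  expect_true(all(s_b$k_top[m] >= s_g$k_top))
  expect_error(transcriptome_offtarget_scan(lib, top, non, list()), "empty")
})
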