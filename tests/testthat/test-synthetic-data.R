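# Generators: design rules, planted-site closure, screen simulation,
# determinism.

test_that("generated guides satisfy the design rules and are unique", {
  lib <- generate_library(150, rng_seed = 1)
  expect_equal(nrow(lib), 150)
  expect_false(anyDuplicated(lib$guide) > 0)
  expect_true(all(check_design_rules(lib$guide)))
  for (g in lib$guide[1:25]) {
    ch <- strsplit(g, "")[[1]]
    expect_true((ch[1] %in% c("A", "U") && ch[9] %in% c("A", "U")) ||
                  ch[19] %in% c("G", "C"))
    expect_gte(sum(ch[1:7] %in% c("A", "U")), 3)
  }
  expect_equal(lib$passenger, reverse_complement(lib$guide))
})

test_that("library generation is deterministic per seed and differs across seeds", {
  expect_identical(generate_library(40, rng_seed = 9),
                   generate_library(40, rng_seed = 9))
  expect_false(identical(generate_library(40, rng_seed = 9)$guide,
                         generate_library(40, rng_seed = 10)$guide))
})

test_that("planted sites are re-detected with their planned features (closure)", {
  lib <- generate_library(10, rng_seed = 23)
  txs <- generate_transcripts(3, utr3_length_range = c(260, 300),
                              rng_seed = 23)
  # find a guide that admits a wobble from the default preset
  wa <- wobble_preset("site")
  wob_i <- 0L; wob_p <- 0L
  for (i in seq_len(nrow(lib))) {
    g <- strsplit(lib$guide[i], "")[[1]]
    for (q in seq_len(nrow(wa))) {
      if (g[wa$position[q]] == wa$base[q]) { wob_i <- i; wob_p <- wa$position[q]; break }
    }
    if (wob_i > 0) break
  }
  expect_gt(wob_i, 0)
  others <- setdiff(seq_len(nrow(lib)), wob_i)
  plan <- data.frame(
    sirna_id = lib$sirna_id[c(others[1:3], wob_i)],
    transcript_id = names(txs)[1],
    n_sites = c(1L, 3L, 1L, 1L),
    wobble_position = c(0L, 0L, 0L, wob_p),
    t1A = c(TRUE, FALSE, FALSE, FALSE),
    pair3p = c(TRUE, FALSE, FALSE, FALSE),
    pos16 = c(TRUE, FALSE, TRUE, FALSE))
  pl <- plant_sites(txs, lib, plan, rng_seed = 23)
  tx <- pl$transcripts[[1]]
  # siRNA 1: one site carrying t1A, 3' pairing and the position-16 match
  s1 <- find_seed_sites(lib$guide[others[1]], tx, "utr3")
  expect_equal(nrow(s1), 1)
  f1 <- annotate_site(s1[1, ], lib$guide[others[1]],
                      region_sequence(tx, "utr3"))
  expect_true(f1$t1A && f1$pair3p_34_offset2 && f1$pair3p_45_1019 &&
                f1$pos16_match && f1$pos16_isolated)
  # siRNA 2: exactly three sites
  expect_equal(nrow(find_seed_sites(lib$guide[others[2]], tx, "utr3")), 3)
  # siRNA 3: t1A was planted FALSE -> anchor forced away from A
  s3 <- find_seed_sites(lib$guide[others[3]], tx, "utr3")
  f3 <- annotate_site(s3[1, ], lib$guide[others[3]],
                      region_sequence(tx, "utr3"))
  expect_false(f3$t1A)
  expect_true(f3$pos16_match)
  # wobbled siRNA: invisible to the exact scan, found with one wobble
  expect_equal(nrow(find_seed_sites(lib$guide[wob_i], tx, "utr3")), 0)
  sw <- find_seed_sites(lib$guide[wob_i], tx, "utr3", max_wobbles = 1,
                        wobble_allowed = wa)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$wobble_positions, as.character(wob_p))
  # infeasible wobble plans are refused
  bad <- data.frame(sirna_id = lib$sirna_id[1], transcript_id = names(txs)[1],
                    wobble_position = 9L)
  expect_error(plant_sites(txs, lib, bad, rng_seed = 1), "infeasible")
})

test_that("rejection-sampled backgrounds carry no unplanned guide sites", {
  lib <- generate_library(25, rng_seed = 31)
  txs <- generate_transcripts(4, utr3_length_range = c(220, 260),
                              rng_seed = 31)
  plan <- data.frame(sirna_id = lib$sirna_id[1:3],
                     transcript_id = names(txs)[2])
  pl <- plant_sites(txs, lib, plan, rng_seed = 31)
  truth <- pl$truth
  for (tx in pl$transcripts) {
    for (i in seq_len(nrow(lib))) {
      for (region in c("utr5", "orf", "utr3")) {
        found <- find_seed_sites(lib$guide[i], tx, region)
        planned <- truth[truth$sirna_id == lib$sirna_id[i] &
                           truth$transcript_id == tx$transcript_id &
                           truth$region == region &
                           truth$wobble_position == 0, ]
        expect_equal(sort(found$start), sort(planned$start),
                     info = paste(tx$transcript_id, lib$sirna_id[i], region))
      }
    }
  }
})

test_that("noiseless null screens normalize to exactly zero", {
  lib <- generate_library(116, rng_seed = 2)
  cfg <- screen_sim_config(n_plates = 1, dims = c(10, 12), noise_sd = 0,
                           rng_seed = 2)
  sim <- simulate_screen(lib, NULL, cfg)
  norm <- normalize_screen(sim$wells)
  expect_lt(max(abs(norm$scores$z), na.rm = TRUE), 1e-9)
})

test_that("planted effects of -4 SD or more are recovered by hit calling", {
  lib <- generate_library(368, rng_seed = 14)
  eff <- data.frame(sirna_id = lib$sirna_id[1:8], z_shift = -4)
  sim <- simulate_screen(lib, eff, screen_sim_config(
    n_plates = 2, dims = c(12, 16), rng_seed = 14))
  h <- call_hits(normalize_screen(sim$wells), 2.5)
  expect_true(all(h$group[h$sirna_id %in% eff$sirna_id] == "decrease"))
  expect_equal(sim$true_scores$true_z[match(eff$sirna_id,
                                            sim$true_scores$sirna_id)],
               rep(-4, 8))
})

test_that("doubling the bias slope doubles the fitted count dependence", {
  lib <- generate_library(116, rng_seed = 3)
  base <- screen_sim_config(n_plates = 1, dims = c(10, 12), noise_sd = 0,
                            bias_A = -4e-4, rng_seed = 3)
  dbl <- screen_sim_config(n_plates = 1, dims = c(10, 12), noise_sd = 0,
                           bias_A = -8e-4, rng_seed = 3)
  s1 <- simulate_screen(lib, NULL, base)$wells
  s2 <- simulate_screen(lib, NULL, dbl)$wells
  b1 <- coef(lm(nc_ratio ~ cell_count, s1))[2]
  b2 <- coef(lm(nc_ratio ~ cell_count, s2))[2]
  expect_equal(unname(b2 / b1), 2, tolerance = 1e-6)
})

test_that("the benchmark is byte-deterministic and internally consistent", {
  b1 <- synthetic_benchmark(5, "tiny")
  b2 <- synthetic_benchmark(5, "tiny")
  expect_identical(b1, b2)
  expect_false(identical(b1$wells$nc_ratio,
                         synthetic_benchmark(6, "tiny")$wells$nc_ratio))
  # every planted siRNA has at least one (possibly wobbled) site in the target
  tx <- b1$transcripts[[b1$target_id]]
  for (id in b1$hit_ids) {
    g <- b1$library$guide[b1$library$sirna_id == id]
    n <- nrow(find_seed_sites(g, tx, "utr3", max_wobbles = 1))
    expect_gte(n, 1)
  }
  # conservation track covers planted sites
  cons <- region_conservation(tx, "utr3")
  tr <- b1$truth[b1$truth$transcript_id == b1$target_id, ]
  for (k in seq_len(nrow(tr))) {
    expect_true(all(cons[(tr$start[k] + 1):(tr$start[k] + 7)] >= 0.5))
  }
})
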