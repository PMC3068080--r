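# Seed extraction, site scanning (exact + wobble), annotation features.

test_that("seed_of extracts positions 2..(L+1) and nests hexamer in heptamer", {
  expect_equal(seed_of("UAAAGUGCUUAUAGUGCAGGUAG", 7), "AAAGUGC")
  expect_equal(seed_of("GAAGUGCUUCGAUUUUGGGGUGU", 7), "AAGUGCU")
  set.seed(11)
  for (k in 1:10) {
    s <- random_rna(19)
    expect_true(startsWith(seed_of(s, 7), seed_of(s, 6)))
  }
  expect_error(seed_of("ACGUACGU", 7), "at least 9")
})

test_that("exact sites are found at planted positions, with multiplicity", {
  guide <- "UAAAGUGCUUAUAGUGCAG"        # seed AAAGUGC, site GCACUUU
  target <- paste0("AA", "GCACUUU", "AA")
  sites <- scan_seed_sites(guide, target)
  expect_equal(sites$start, 2)
  expect_equal(sites$wobble_positions, "")
  # two concatenated planted sites
  t2 <- paste0("GCACUUU", "GCACUUU")
  expect_equal(scan_seed_sites(guide, t2)$start, c(0, 7))
  # no site
  expect_equal(nrow(scan_seed_sites(guide, "AAAAAAAAAAAA")), 0L)
  # hexamer site of the same guide: reverse complement of positions 2-7
  expect_equal(scan_seed_sites(guide, paste0("CC", "CACUUU", "CC"),
                               seed_len = 6)$start, 2)
})

test_that("single G:U wobbles are admitted only at allowed (position, base) pairs", {
  guide <- "UAAAGUGCUUAUAGUGCAG"        # position 5 = G, position 7 = G
  # strand G at position 5 opposite target U: site GCAUUUU (column 4 U)
  wa <- data.frame(position = 5L, base = "G")
  s <- scan_seed_sites(guide, "AAGCAUUUUAA", max_wobbles = 1,
                       wobble_allowed = wa)
  expect_equal(s$start, 2)
  expect_equal(s$wobble_positions, "5")
  # the same target yields nothing when position 5 is not allowed
  expect_equal(nrow(scan_seed_sites(guide, "AAGCAUUUUAA", max_wobbles = 1,
                                    wobble_allowed = wobble_preset("site"))),
               0L)
  # max_wobbles = 0 never reports wobbled sites
  expect_equal(nrow(scan_seed_sites(guide, "AAGCAUUUUAA", max_wobbles = 0,
                                    wobble_allowed = wa)), 0L)
  # N never matches, including opposite N
  expect_equal(nrow(scan_seed_sites(guide, "AAGCACUNUAA")), 0L)
})

test_that("scanner agrees with the brute-force oracle on random inputs", {
  set.seed(101)
  presets <- list(NULL, wobble_preset("site"), wobble_preset("composition"))
  for (k in 1:300) {
    rna <- random_rna(19)
    target <- random_rna(sample(10:120, 1))
    seed_len <- sample(c(6, 7), 1)
    mw <- sample(0:1, 1)
    wa <- presets[[sample(3, 1)]]
    got <- scan_seed_sites(rna, target, seed_len, mw,
                           if (is.null(wa)) wobble_preset("site") else wa)
    want <- oracle_scan(rna, target, seed_len,
                        if (is.null(wa)) 0 else mw, wa)
    expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"),
                 info = sprintf("k=%d rna=%s", k, rna))
    got_wob <- lapply(strsplit(got$wobble_positions, ","),
                      function(x) sort(as.integer(x[nzchar(x)])))
    want_wob <- lapply(want, `[[`, "wobbles")
    expect_equal(unname(got_wob), lapply(want_wob, as.integer))
    if (mw == 0) expect_true(all(got$wobble_positions == ""))
  }
})

test_that("every heptamer site implies a hexamer site at the same anchor", {
  set.seed(7)
  for (k in 1:40) {
    rna <- random_rna(19)
    target <- random_rna(200)
    hept <- scan_seed_sites(rna, target, 7)$start
    hex <- scan_seed_sites(rna, target, 6)$start
    # heptamer [i, i+7) pairs 8..2; its hexamer part (7..2) starts at i+1
    expect_true(all((hept + 1) %in% hex))
  }
})

test_that("true-hexamer-only logic follows the subsumption rule", {
  guide <- "UAAAGUGCUUAUAGUGCAG"        # hexamer site CACUUU, heptamer GCACUUU
  tx <- function(utr3) transcript_record("t", paste0(random_rna(30), utr3),
                                         utr3 = c(31, 30 + nchar(utr3)))
  set.seed(2)
  # hexamer followed by a base != U at the heptamer-extending position:
  # GCACUUU requires G immediately 5' of CACUUU on the mRNA
  expect_true(has_true_hexamer_only(guide, tx("AAACACUUUAAA")))
  expect_false(has_true_hexamer_only(guide, tx("AAGCACUUUAAA")))  # subsumed
  expect_false(has_true_hexamer_only(guide, tx("AAAAAAAAAAAA")))  # no match
})

test_that("site annotation computes register-arithmetic features correctly", {
  # construct guide and target explicitly by antiparallel alignment:
  # guide 5'-> 3' pos:   1  2  3  4  5  6  7  8  9 ... 16 17 18 19
  guide <- "CAAAGUGCGUUACGAGCAU"
  # heptamer site pairs positions 8..2 -> site = rc(AAAGUGC) = GCACUUU
  # build a target where the site starts at region index i = 12
  # pos16 = G -> paired target base C at i-8 = 4; flanks i-9, i-10 chosen
  # non-complementary to positions 17 (A->U) and 18 (C->G)
  left <- paste0("AA", "A", "C", "C", "AAAAAAA")  # indices 0..11; idx4="C"
  # idx3 = "C" (pairs pos17: complement would be U -> no match)
  # idx2 = "A" (pairs pos18: complement would be G -> no match)
  target <- paste0(left, "GCACUUU", "A", "CC")    # t1 = A at idx 19
  tchars <- strsplit(target, "")[[1]]
  expect_equal(paste(tchars[13:19], collapse = ""), "GCACUUU")
  site <- data.frame(start = 12, length = 7)
  f <- annotate_site(site, guide, target)
  expect_true(f$t1A)
  # position 9 pairs idx 11 ("A"); guide pos 9 is G -> no WC match, but t9 in {A,U}
  expect_true(f$t9_AU)
  expect_false(f$pos9_match)
  expect_true(f$pos16_match)
  expect_true(f$pos16_isolated)
  # t1A false when the anchor base is not A
  target2 <- paste0(left, "GCACUUU", "G", "CC")
  expect_false(annotate_site(site, guide, target2)$t1A)
  # site at region start: upstream features are out of region, hence FALSE
  f0 <- annotate_site(data.frame(start = 0, length = 7), guide, "GCACUUUA")
  expect_false(f0$pos9_match)
  expect_false(f0$pos16_match)
  expect_true(f0$t1A)
})

test_that("3' pairing features respect their windows and offsets", {
  guide <- "CAAAGUGCGUUACGAGCAU"
  # in-register block for guide positions 12-15 ("ACGA"):
  # target indices i-7..i-4 get rc(positions 12..15) read 3'->5'
  rc4 <- reverse_complement(substr(guide, 12, 15))
  base <- strsplit(paste0(strrep("A", 12), "GCACUUU", "AA"), "")[[1]]
  base[(12 - 7 + 1):(12 - 4 + 1)] <- strsplit(rc4, "")[[1]]
  target <- paste(base, collapse = "")
  f <- annotate_site(data.frame(start = 12, length = 7), guide, target)
  expect_true(f$pair3p_34_offset2)
  expect_true(f$pair3p_45_1019)          # 4-mer at 12-15 is within 10-19
  # shift the same block by 2 nt: still allowed for the 12-19 feature,
  # no longer in register for the 10-19 feature
  base2 <- strsplit(paste0(strrep("A", 12), "GCACUUU", "AA"), "")[[1]]
  base2[(12 - 7 + 1):(12 - 4 + 1) - 2] <- strsplit(rc4, "")[[1]]
  f2 <- annotate_site(data.frame(start = 12, length = 7), guide,
                      paste(base2, collapse = ""))
  expect_true(f2$pair3p_34_offset2)
  expect_false(f2$pair3p_45_1019)
})

test_that("feature vectors summarize per strand and region, with strand union", {
  lib <- generate_library(4, rng_seed = 13)
  tx <- generate_transcripts(1, utr3_length_range = c(200, 200),
                             rng_seed = 13)[[1]]
  # plant the guide seed of siRNA 1 twice in the 3'UTR
  plan <- data.frame(sirna_id = lib$sirna_id[1], transcript_id = tx$transcript_id,
                     n_sites = 2L)
  pl <- plant_sites(stats::setNames(list(tx), tx$transcript_id), lib[1, ],
                    plan, rng_seed = 13)
  tx2 <- pl$transcripts[[1]]
  fv <- feature_vector(lib[1, ], tx2, strands = c("guide", "passenger"),
                       regions = c("utr3", "orf", "utr5"))
  u3g <- fv[fv$strand == "guide" & fv$region == "utr3", ]
  expect_true(u3g$any_site)
  expect_equal(u3g$n_sites, 2L)
  expect_false(any(fv$any_site[fv$region != "utr3" & fv$strand == "guide"]))
  # union semantics
  fb <- feature_vector(lib[1, ], tx2, strands = "both", regions = "utr3")
  expect_equal(fb$n_sites, u3g$n_sites +
                 fv$n_sites[fv$strand == "passenger" & fv$region == "utr3"])
  expect_equal(fb$any_site, TRUE)
})

test_that("site counts are invariant under non-matching flanks", {
  set.seed(19)
  guide <- generate_library(1, rng_seed = 19)$guide
  core <- paste0(random_rna(40), reverse_complement(seed_of(guide, 7)),
                 random_rna(40))
  n0 <- nrow(scan_seed_sites(guide, core))
  # append flanks that cannot pair (poly-A flanks; site needs GCACUUU-like rc)
  flank <- strrep(substr(seed_of(guide, 7), 2, 2), 30)  # repeats of a seed base
  n1 <- nrow(scan_seed_sites(guide, paste0(flank, core)))
  n2 <- nrow(scan_seed_sites(guide, paste0(core, flank)))
  # flanks may only add sites if they accidentally contain the site string;
  # verify with the oracle instead of assuming
  expect_equal(n1, length(oracle_starts(guide, paste0(flank, core))))
  expect_equal(n2, length(oracle_starts(guide, paste0(core, flank))))
  expect_gte(n1, n0)
  expect_gte(n2, n0)
})
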