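# miRNA-like seed matching of small-RNA strands against transcript regions.
#
# Conventions (fixed here and used everywhere, including the annotation
# features):
#   * small-RNA positions are 1-based 5'->3'; the seed is positions 2..8
#     (heptamer) or 2..7 (hexamer)
#   * a seed site of length L occupies L consecutive mRNA bases pairing the
#     strand antiparallel; with the site 5'-most base at 0-based region index
#     i, strand position p pairs target index  i + (L+1) - p
#     (heptamer: t1 anchor = i+7, position 9 = i-1, position 16 = i-8)
#   * an exact site is therefore the reverse complement of the seed
#   * G:U wobbles (strand G opposite target U, strand U opposite target G)
#     are permitted only at configured (position, strand-base) pairs, at most
#     max_wobbles per site
#   * N never matches anything, including N

#' Seed substring of a small RNA
#'
#' @param small_rna RNA string (>= 9 nt).
#' @param length seed length, 7 (positions 2-8) or 6 (positions 2-7).
#' @return the seed as an RNA string.
#' @examples
#' seed_of("UAAAGUGCUUAUAGUGCAGGUAG", 7)  # "AAAGUGC"
#' @export
seed_of <- function(small_rna, length = 7) {
  stopifnot(length %in% c(6L, 7L))
  small_rna <- normalize_rna(small_rna)
  if (any(nchar(small_rna) < 9L)) stop("small RNA must be at least 9 nt")
  substr(small_rna, 2L, length + 1L)
}

#' G:U wobble position presets
#'
#' Two empirically motivated presets for which (seed position, strand base)
#' pairs may form a G:U wobble with the target:
#' \describe{
#'   \item{site}{the positions enriched in wobble-containing matched sites of
#'     hit siRNAs: U at positions 2 and 4, G at positions 3 and 8 (default).}
#'   \item{composition}{the positions suggested by hit-strand base
#'     composition: U at positions 2, 4, 5 and 7, G at positions 3 and 6.}
#' }
#'
#' @param name "site" or "composition".
#' @return data.frame with columns position, base.
#' @export
wobble_preset <- function(name = c("site", "composition")) {
  name <- match.arg(name)
  switch(name,
    site = data.frame(position = c(2L, 4L, 3L, 8L),
                      base = c("U", "U", "G", "G")),
    composition = data.frame(position = c(2L, 4L, 5L, 7L, 3L, 6L),
                             base = c("U", "U", "U", "U", "G", "G")))
}

# Core scanner over a plain region string. Returns a data.frame with 0-based
# site starts and the wobbled strand positions of each site.
#' Scan a target sequence for seed sites of a small RNA
#'
#' Low-level scanner over a plain RNA string; see \code{\link{find_seed_sites}}
#' for the transcript-aware interface. All (possibly overlapping) sites are
#' reported, left to right.
#'
#' @param small_rna small-RNA strand, 5'->3'.
#' @param target target region sequence, 5'->3'.
#' @param seed_len 7 or 6.
#' @param max_wobbles 0 or 1 G:U wobbles per site.
#' @param wobble_allowed data.frame (position, base) of permitted wobbles,
#'   e.g. \code{\link{wobble_preset}("site")}.
#' @return data.frame with columns start (0-based), length, wobble_positions
#'   (comma-separated strand positions, "" for exact sites).
#' @export
scan_seed_sites <- function(small_rna, target, seed_len = 7, max_wobbles = 0,
                            wobble_allowed = wobble_preset("site")) {
  stopifnot(seed_len %in% c(6L, 7L), max_wobbles %in% c(0L, 1L))
  small_rna <- normalize_rna(small_rna)
  target <- normalize_rna(target)
  empty <- data.frame(start = integer(), length = integer(),
                      wobble_positions = character(),
                      stringsAsFactors = FALSE)
  L <- as.integer(seed_len)
  n_off <- nchar(target) - L + 1L
  if (n_off < 1L) return(empty)
  rna_ch <- strsplit(small_rna, "", fixed = TRUE)[[1L]]
  # column j (1..L) of a site pairs strand position p_j
  p_col <- (L + 1L):2L
  strand_base <- rna_ch[p_col]
  required <- complement_bases(strand_base)           # == rev-comp of the seed
  wob_target <- rep(NA_character_, L)
  if (max_wobbles > 0L && nrow(wobble_allowed)) {
    for (j in seq_len(L)) {
      ok <- wobble_allowed$position == p_col[j] &
        wobble_allowed$base == strand_base[j]
      if (any(ok) && strand_base[j] %in% c("G", "U")) {
        wob_target[j] <- if (strand_base[j] == "G") "U" else "G"
      }
    }
  }
  tch <- strsplit(target, "", fixed = TRUE)[[1L]]
  idx <- outer(seq_len(n_off) - 1L, seq_len(L), `+`)   # 1-based target index
  M <- matrix(tch[idx], nrow = n_off)
  exact <- sweep(M, 2L, required, `==`) & M != "N" &
    matrix(required != "N", n_off, L, byrow = TRUE)
  ok <- exact
  wob <- matrix(FALSE, n_off, L)
  if (max_wobbles > 0L) {
    for (j in which(!is.na(wob_target))) {
      wob[, j] <- !exact[, j] & M[, j] == wob_target[j]
    }
    ok <- exact | wob
  }
  n_mis <- L - rowSums(exact)
  hit <- rowSums(ok) == L & n_mis <= max_wobbles
  if (!any(hit)) return(empty)
  starts <- which(hit) - 1L
  wp <- vapply(which(hit), function(r) {
    paste(p_col[wob[r, ]], collapse = ",")
  }, character(1L))
  data.frame(start = starts, length = L, wobble_positions = wp,
             stringsAsFactors = FALSE)
}

#' Find seed sites of a small RNA in a transcript region
#'
#' @param small_rna small-RNA strand, 5'->3'.
#' @param transcript a \code{\link{transcript_record}} (or a plain RNA string,
#'   in which case \code{region} is ignored).
#' @param region "utr3" (default), "orf", "utr5" or "full".
#' @inheritParams scan_seed_sites
#' @return data.frame of sites as in \code{\link{scan_seed_sites}}, with
#'   additional columns transcript_id and region; starts are 0-based within
#'   the region.
#' @export
find_seed_sites <- function(small_rna, transcript, region = "utr3",
                            seed_len = 7, max_wobbles = 0,
                            wobble_allowed = wobble_preset("site")) {
  if (inherits(transcript, "transcript_record")) {
    target <- region_sequence(transcript, region)
    id <- transcript$transcript_id
  } else {
    target <- transcript
    id <- NA_character_
    region <- "full"
  }
  sites <- scan_seed_sites(small_rna, target, seed_len = seed_len,
                           max_wobbles = max_wobbles,
                           wobble_allowed = wobble_allowed)
  if (nrow(sites)) {
    sites <- cbind(transcript_id = id, region = region, sites,
                   stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(transcript_id = character(), region = character(),
                        start = integer(), length = integer(),
                        wobble_positions = character(),
                        stringsAsFactors = FALSE)
  }
  sites
}

#' Does a small RNA have only "true" hexamer matches in a region?
#'
#' TRUE iff the region contains at least one exact hexamer (positions 2-7)
#' site and no exact heptamer (positions 2-8) site. (Any heptamer site
#' contains a hexamer site at the same anchor, so the presence of a heptamer
#' anywhere means the hexamer signal is not "true" hexamer signal.)
#'
#' @inheritParams find_seed_sites
#' @return logical scalar.
#' @export
has_true_hexamer_only <- function(small_rna, transcript, region = "utr3") {
  hex <- find_seed_sites(small_rna, transcript, region, seed_len = 6,
                         max_wobbles = 0)
  if (!nrow(hex)) return(FALSE)
  hept <- find_seed_sites(small_rna, transcript, region, seed_len = 7,
                          max_wobbles = 0)
  nrow(hept) == 0L
}

# index paired by strand position p for a site of length L at 0-based start i
.pair_index <- function(i, L, p) i + (L + 1L) - p

#' Annotate one seed site with auxiliary pairing features
#'
#' Computes the target-side and 3'-pairing features of a seed site: the t1A
#' anchor (A in the mRNA opposite strand position 1, i.e. immediately 3' of
#' the site), A/U or a match opposite position 9, a match at position 16 of
#' the strand (and whether it is isolated, i.e. unaccompanied by matches at
#' positions 17/18), and two supplementary 3'-pairing definitions: a 3/4-mer
#' of positions 12-19 pairing with a register offset of at most 2 nt, and a
#' 4/5-mer of positions 10-19 pairing in register. Features that would need
#' target bases outside the region are FALSE.
#'
#' @param site one row of a site data.frame (needs \code{start},
#'   \code{length}).
#' @param small_rna the strand the site belongs to.
#' @param target the region sequence the site was found in (or a
#'   \code{transcript_record} plus \code{region}).
#' @param region region name when \code{target} is a transcript record.
#' @return one-row data.frame: t1A, t9_AU, pos9_match, pair3p_34_offset2,
#'   pair3p_45_1019, pos16_match, pos16_isolated.
#' @export
annotate_site <- function(site, small_rna, target, region = "utr3") {
  if (inherits(target, "transcript_record")) {
    target <- region_sequence(target, region)
  }
  small_rna <- normalize_rna(small_rna)
  target <- normalize_rna(target)
  tch <- strsplit(target, "", fixed = TRUE)[[1L]]
  rch <- strsplit(small_rna, "", fixed = TRUE)[[1L]]
  n <- length(tch)
  i <- as.integer(site$start)
  L <- as.integer(site$length)
  tbase <- function(idx0) {           # 0-based target index -> base or NA
    if (idx0 < 0L || idx0 >= n) NA_character_ else tch[idx0 + 1L]
  }
  wc <- function(p, delta = 0L) {     # WC pairing of strand position p
    if (p > length(rch)) return(FALSE)
    b <- tbase(.pair_index(i, L, p) + delta)
    !is.na(b) && b != "N" && rch[p] != "N" && b == complement_bases(rch[p])
  }
  t1 <- tbase(i + L)
  t9 <- tbase(.pair_index(i, L, 9L))
  t1A <- !is.na(t1) && t1 == "A"
  t9_AU <- !is.na(t9) && t9 %in% c("A", "U")
  pos9_match <- wc(9L)
  pos16_match <- wc(16L)
  pos16_isolated <- pos16_match && !wc(17L) && !wc(18L)
  run_pairs <- function(p0, m, delta) all(vapply(p0:(p0 + m - 1L), wc,
                                                 logical(1L), delta = delta))
  pair3p_34 <- FALSE
  for (m in c(3L, 4L)) for (p0 in 12L:(19L - m + 1L)) for (d in -2L:2L) {
    if (run_pairs(p0, m, d)) { pair3p_34 <- TRUE; break }
  }
  pair3p_45 <- FALSE
  for (m in c(4L, 5L)) for (p0 in 10L:(19L - m + 1L)) {
    if (run_pairs(p0, m, 0L)) { pair3p_45 <- TRUE; break }
  }
  data.frame(t1A = t1A, t9_AU = t9_AU, pos9_match = pos9_match,
             pair3p_34_offset2 = pair3p_34, pair3p_45_1019 = pair3p_45,
             pos16_match = pos16_match, pos16_isolated = pos16_isolated)
}

.FEATURE_COLS <- c("t1A", "t9_AU", "pos9_match", "pair3p_34_offset2",
                   "pair3p_45_1019", "pos16_match", "pos16_isolated")

.empty_features <- function() {
  as.data.frame(as.list(stats::setNames(rep(FALSE, length(.FEATURE_COLS)),
                                        .FEATURE_COLS)))
}

#' Per-strand, per-region site summary for one siRNA duplex
#'
#' Scans the requested strands of a duplex against the requested regions of a
#' transcript and summarizes: total site count, whether any site exists, and
#' the features of the best-annotated site (the site with the most TRUE
#' features; ties broken by the 5'-most site). With \code{strands = "both"}
#' rows for the union of guide and passenger are appended (site counts sum,
#' feature booleans are OR-ed).
#'
#' @param duplex one-row data.frame with sirna_id, guide, passenger.
#' @param transcript a \code{\link{transcript_record}}.
#' @param strands subset of c("guide", "passenger", "both").
#' @param regions subset of c("utr3", "orf", "utr5").
#' @inheritParams scan_seed_sites
#' @return data.frame, one row per strand x region: sirna_id, transcript_id,
#'   strand, region, n_sites, any_site, n_wobble_sites, best_start (1-based,
#'   NA if no site) and the feature columns.
#' @export
feature_vector <- function(duplex, transcript,
                           strands = c("guide", "passenger"),
                           regions = "utr3", seed_len = 7, max_wobbles = 0,
                           wobble_allowed = wobble_preset("site")) {
  want_both <- "both" %in% strands
  base_strands <- unique(c(setdiff(strands, "both"),
                           if (want_both) c("guide", "passenger")))
  rows <- list()
  for (strand in base_strands) {
    rna <- duplex[[strand]]
    for (region in regions) {
      target <- region_sequence(transcript, region)
      sites <- scan_seed_sites(rna, target, seed_len = seed_len,
                               max_wobbles = max_wobbles,
                               wobble_allowed = wobble_allowed)
      if (nrow(sites)) {
        feats <- do.call(rbind, lapply(seq_len(nrow(sites)), function(k) {
          annotate_site(sites[k, ], rna, target)
        }))
        score <- rowSums(feats)
        best <- which(score == max(score))[1L]
        row <- cbind(data.frame(sirna_id = duplex$sirna_id,
                                transcript_id = transcript$transcript_id,
                                strand = strand, region = region,
                                n_sites = nrow(sites), any_site = TRUE,
                                n_wobble_sites = sum(sites$wobble_positions != ""),
                                best_start = sites$start[best] + 1L),
                     feats[best, , drop = FALSE])
      } else {
        row <- cbind(data.frame(sirna_id = duplex$sirna_id,
                                transcript_id = transcript$transcript_id,
                                strand = strand, region = region,
                                n_sites = 0L, any_site = FALSE,
                                n_wobble_sites = 0L, best_start = NA_integer_),
                     .empty_features())
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (want_both) {
    for (region in regions) {
      g <- out[out$strand == "guide" & out$region == region, , drop = FALSE]
      p <- out[out$strand == "passenger" & out$region == region, , drop = FALSE]
      b <- g
      b$strand <- "both"
      b$n_sites <- g$n_sites + p$n_sites
      b$any_site <- g$any_site | p$any_site
      b$n_wobble_sites <- g$n_wobble_sites + p$n_wobble_sites
      b$best_start <- if (is.na(g$best_start)) p$best_start else g$best_start
      b[.FEATURE_COLS] <- g[.FEATURE_COLS] | p[.FEATURE_COLS]
      out <- rbind(out, b)
    }
  }
  out <- out[out$strand %in% strands, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Seed-site feature table for a whole library
#'
#' Applies \code{\link{feature_vector}} to every duplex in a library against
#' every transcript in a collection; the workhorse behind the enrichment
#' statistics and the transcriptome-wide off-target scan.
#'
#' @param library an \code{sirna_library} data.frame.
#' @param transcripts list of \code{\link{transcript_record}}s.
#' @inheritParams feature_vector
#' @return data.frame with one row per siRNA x transcript x strand x region.
#' @export
scan_library <- function(library, transcripts,
                         strands = c("guide", "passenger"),
                         regions = "utr3", seed_len = 7, max_wobbles = 0,
                         wobble_allowed = wobble_preset("site")) {
  if (inherits(transcripts, "transcript_record")) transcripts <- list(transcripts)
  rows <- vector("list", nrow(library) * length(transcripts))
  k <- 0L
  for (tx in transcripts) {
    for (i in seq_len(nrow(library))) {
      k <- k + 1L
      rows[[k]] <- feature_vector(library[i, , drop = FALSE], tx,
                                  strands = strands, regions = regions,
                                  seed_len = seed_len,
                                  max_wobbles = max_wobbles,
                                  wobble_allowed = wobble_allowed)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fully annotated site list for a library (one row per site)
#'
#' @inheritParams scan_library
#' @return data.frame: sirna_id, transcript_id, region, strand, start
#'   (1-based), length, wobble_positions and all annotation features.
#' @export
site_table <- function(library, transcripts,
                       strands = c("guide", "passenger"), regions = "utr3",
                       seed_len = 7, max_wobbles = 0,
                       wobble_allowed = wobble_preset("site")) {
  if (inherits(transcripts, "transcript_record")) transcripts <- list(transcripts)
  rows <- list()
  for (tx in transcripts) {
    for (region in regions) {
      target <- region_sequence(tx, region)
      for (i in seq_len(nrow(library))) {
        for (strand in strands) {
          rna <- library[[strand]][i]
          sites <- scan_seed_sites(rna, target, seed_len = seed_len,
                                   max_wobbles = max_wobbles,
                                   wobble_allowed = wobble_allowed)
          if (!nrow(sites)) next
          feats <- do.call(rbind, lapply(seq_len(nrow(sites)), function(k) {
            annotate_site(sites[k, ], rna, target)
          }))
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(sirna_id = library$sirna_id[i],
                       transcript_id = tx$transcript_id, region = region,
                       strand = strand, start = sites$start + 1L,
                       length = sites$length,
                       wobble_positions = sites$wobble_positions),
            feats)
        }
      }
    }
  }
  if (!length(rows)) {
    return(cbind(data.frame(sirna_id = character(), transcript_id = character(),
                            region = character(), strand = character(),
                            start = integer(), length = integer(),
                            wobble_positions = character()),
                 .empty_features()[0, ]))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
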