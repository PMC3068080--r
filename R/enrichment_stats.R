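# Enrichment and profiling statistics for off-target sequence analysis.
#
# All cohort enrichment is counted per siRNA (an siRNA either carries a motif
# or it does not), matching the "percentage of siRNAs" convention; site-level
# densities are used only for the positional hotspot profile. The enrichment
# factor r is the motif frequency among hit siRNAs divided by its frequency
# among non-hit siRNAs; p-values are two-sided Fisher exact probabilities
# (minimum-likelihood convention), multiplicity-adjusted by Benjamini-
# Hochberg (default) or Bonferroni.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Own implementation by the minimum-likelihood rule: the p-value is the sum
#' of hypergeometric point probabilities not exceeding that of the observed
#' table (with the customary 1+1e-7 relative tolerance).
#'
#' @param k_hits,n_hits motif-positive count and size of the hit cohort.
#' @param k_non,n_non same for the non-hit cohort; the table tested is
#'   rbind(c(k_hits, n_hits-k_hits), c(k_non, n_non-k_non)).
#' @return p-value in (0, 1].
#' @export
fisher_p <- function(k_hits, n_hits, k_non, n_non) {
  if (any(c(k_hits, n_hits, k_non, n_non) < 0)) stop("negative counts")
  if (k_hits > n_hits || k_non > n_non) stop("k exceeds n")
  K <- k_hits + k_non                 # marginal motif-positive total
  support <- max(0L, K - n_non):min(K, n_hits)
  d <- stats::dhyper(support, n_hits, n_non, K)
  p_obs <- stats::dhyper(k_hits, n_hits, n_non, K)
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

#' Motif enrichment factor with exact test
#'
#' @inheritParams fisher_p
#' @param motif_name optional label carried into the result.
#' @return one-row data.frame: motif_name, k_hits, n_hits, k_non, n_non,
#'   freq_hits, freq_non, r (Inf with \code{r_undefined = TRUE} when the
#'   non-hit frequency is zero), p, p_adj (NA until adjusted).
#' @examples
#' enrichment_factor(30, 100, 10, 100)$r  # 3
#' @export
enrichment_factor <- function(k_hits, n_hits, k_non, n_non, motif_name = NA) {
  if (n_hits <= 0 || n_non <= 0) stop("cohort sizes must be positive")
  p <- fisher_p(k_hits, n_hits, k_non, n_non)
  fh <- k_hits / n_hits
  fn <- k_non / n_non
  r <- if (k_non == 0) Inf else fh / fn
  data.frame(motif_name = motif_name, k_hits = k_hits, n_hits = n_hits,
             k_non = k_non, n_non = n_non, freq_hits = fh, freq_non = fn,
             r = r, r_undefined = k_non == 0, p = p, p_adj = NA_real_,
             stringsAsFactors = FALSE)
}

#' Adjust the p-values of an enrichment table
#'
#' @param results data.frame with a \code{p} column (e.g. rbind-ed rows from
#'   \code{\link{enrichment_factor}}).
#' @param method "BH" (default) or "bonferroni".
#' @return the table with \code{p_adj} filled in and the method recorded in
#'   attribute \code{adjust_method}.
#' @export
adjust_enrichment <- function(results, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  results$p_adj <- stats::p.adjust(results$p, method = method)
  attr(results, "adjust_method") <- method
  results
}

# Evaluate a motif predicate per siRNA over a feature table: `motif` is a
# column name or a function(df) -> logical; multiple rows per siRNA are
# OR-ed.
.per_sirna_flag <- function(feature_table, ids, motif) {
  flag_rows <- if (is.function(motif)) motif(feature_table) else
    feature_table[[motif]]
  if (is.null(flag_rows)) stop("unknown motif column")
  vapply(ids, function(id) {
    rows <- feature_table$sirna_id == id
    any(flag_rows[rows], na.rm = TRUE)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Cohort motif enrichment from a feature table
#'
#' Counts, per siRNA, whether the motif predicate holds anywhere in its
#' feature rows, then compares hit and non-hit cohorts. An optional exclusion
#' predicate removes siRNAs from both cohorts first (e.g. dropping siRNAs
#' with a 3'UTR seed match before testing ORF enrichment).
#'
#' @param feature_table output of \code{\link{scan_library}} (or any
#'   data.frame with an \code{sirna_id} column and the columns the predicates
#'   use).
#' @param hits,nonhits disjoint character vectors of siRNA ids.
#' @param motif column name or function(data.frame) -> logical, evaluated per
#'   row and OR-ed per siRNA.
#' @param exclude optional predicate in the same form; siRNAs for which it
#'   holds are removed from both cohorts before testing.
#' @param motif_name label for the result row.
#' @return one-row data.frame as \code{\link{enrichment_factor}}.
#' @export
motif_enrichment <- function(feature_table, hits, nonhits, motif,
                             exclude = NULL, motif_name = NA) {
  if (length(intersect(hits, nonhits))) stop("cohorts must be disjoint")
  if (!is.null(exclude)) {
    drop_h <- .per_sirna_flag(feature_table, hits, exclude)
    drop_n <- .per_sirna_flag(feature_table, nonhits, exclude)
    hits <- hits[!drop_h]
    nonhits <- nonhits[!drop_n]
  }
  if (!length(hits) || !length(nonhits)) stop("empty cohort after exclusion")
  k_h <- sum(.per_sirna_flag(feature_table, hits, motif))
  k_n <- sum(.per_sirna_flag(feature_table, nonhits, motif))
  enrichment_factor(k_h, length(hits), k_n, length(nonhits),
                    motif_name = motif_name)
}

# centered moving mean with windows truncated at both ends
.moving_mean <- function(x, window) {
  n <- length(x)
  stopifnot(window >= 1L)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - (window - 1L) %/% 2L)
  hi <- pmin(n, i + window %/% 2L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving average of a match flag along the screen ranking
#'
#' @param match_flags logical/0-1 vector ordered by screen rank (rank 1
#'   first).
#' @param window window size (default 500); centered, truncated at the ends.
#' @return object of class \code{rank_curve}: data.frame (rank, value).
#' @export
rank_moving_average <- function(match_flags, window = 500) {
  v <- .moving_mean(as.numeric(match_flags), window)
  structure(data.frame(rank = seq_along(v), value = v),
            window = window, class = c("rank_curve", "data.frame"))
}

#' Positional hotspot profile along a 3'UTR
#'
#' Smoothed per-position density of hit-cohort seed-site starts divided by
#' the smoothed non-hit density. Densities are windowed site-start counts,
#' normalized per cohort siRNA when cohort sizes are given; a pseudocount is
#' added to both smoothed counts so the ratio stays finite.
#'
#' @param hit_starts,nonhit_starts 0-based site start positions within the
#'   UTR.
#' @param utr_length UTR length in nt.
#' @param window smoothing window (default 50).
#' @param n_hits,n_nonhits cohort sizes used to express densities as
#'   per-siRNA fractions (optional).
#' @param pseudocount added to both smoothed counts (default 0.5).
#' @return object of class \code{hotspot_profile}: data.frame (position
#'   1-based, hit_density, nonhit_density, ratio).
#' @export
utr_hotspot_profile <- function(hit_starts, nonhit_starts, utr_length,
                                window = 50, n_hits = NULL, n_nonhits = NULL,
                                pseudocount = 0.5) {
  stopifnot(utr_length >= 1L)
  if (length(hit_starts) && (min(hit_starts) < 0 || max(hit_starts) >= utr_length))
    stop("hit site starts outside [0, utr_length)")
  if (length(nonhit_starts) &&
      (min(nonhit_starts) < 0 || max(nonhit_starts) >= utr_length))
    stop("non-hit site starts outside [0, utr_length)")
  window <- min(window, utr_length)
  ch <- tabulate(hit_starts + 1L, nbins = utr_length)
  cn <- tabulate(nonhit_starts + 1L, nbins = utr_length)
  sh <- .moving_mean(ch, window) + pseudocount
  sn <- .moving_mean(cn, window) + pseudocount
  if (!is.null(n_hits)) sh <- sh / n_hits
  if (!is.null(n_nonhits)) sn <- sn / n_nonhits
  structure(data.frame(position = seq_len(utr_length),
                       hit_density = sh, nonhit_density = sn,
                       ratio = sh / sn),
            window = window, pseudocount = pseudocount,
            class = c("hotspot_profile", "data.frame"))
}

#' Enrichment of seed matches in conserved regions
#'
#' A site is conserved when the mean conservation score over its bases
#' reaches the threshold (rule "mean", default) or when every base does
#' (rule "all"). Counting is per siRNA: an siRNA has a conserved match when
#' any of its sites is conserved. Returns the hit-vs-non-hit enrichment
#' factor of conserved matches and the fraction of hit siRNAs that a
#' conservation filter would retain.
#'
#' @param hit_sites,nonhit_sites site data.frames (columns sirna_id, start
#'   0-based, length) for the two cohorts, from \code{\link{scan_seed_sites}}
#'   or \code{\link{site_table}} (subtract 1 from 1-based starts).
#' @param conservation numeric per-base score vector for the region.
#' @param n_hits,n_non cohort sizes.
#' @param threshold conservation threshold (default 0.5).
#' @param rule "mean" or "all".
#' @return list of class \code{conservation_summary}: r_conserved, p,
#'   fraction_hits_predicted, k_hits, k_non, threshold, rule.
#' @export
conserved_region_enrichment <- function(hit_sites, nonhit_sites, conservation,
                                        n_hits, n_non, threshold = 0.5,
                                        rule = c("mean", "all")) {
  rule <- match.arg(rule)
  if (is.null(conservation) || !length(conservation))
    stop("conservation track is missing")
  conserved_site <- function(start0, len) {
    sc <- conservation[(start0 + 1L):(start0 + len)]
    if (anyNA(sc)) return(FALSE)
    if (rule == "mean") mean(sc) >= threshold else all(sc >= threshold)
  }
  per_sirna <- function(sites) {
    if (!nrow(sites)) return(character(0L))
    keep <- vapply(seq_len(nrow(sites)), function(k)
      conserved_site(sites$start[k], sites$length[k]), logical(1L))
    unique(sites$sirna_id[keep])
  }
  k_h <- length(per_sirna(hit_sites))
  k_n <- length(per_sirna(nonhit_sites))
  ef <- enrichment_factor(k_h, n_hits, k_n, n_non,
                          motif_name = "conserved_heptamer")
  structure(list(r_conserved = ef$r, p = ef$p,
                 fraction_hits_predicted = k_h / n_hits,
                 k_hits = k_h, k_non = k_n, n_hits = n_hits, n_non = n_non,
                 threshold = threshold, rule = rule),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf(
    "<conservation_summary> r = %.3g (p = %.3g); filter retains %.1f%% of hits (%d/%d)\n",
    x$r_conserved, x$p, 100 * x$fraction_hits_predicted, x$k_hits, x$n_hits))
  invisible(x)
}

#' Per-position nucleotide frequency ratios, hits vs library
#'
#' Ratio of per-position base frequencies in hit strands with unique seeds to
#' the frequencies in the entire library. Duplicate hit seeds are collapsed
#' before counting (repeating a seed does not change the matrix).
#'
#' @param hit_strands hit strand sequences (5'->3').
#' @param library_strands all library strand sequences.
#' @param positions strand positions to tabulate (default 2:8, the seed).
#' @param unique_seeds collapse hits sharing a seed (positions 2-8) before
#'   counting (default TRUE).
#' @return numeric matrix bases x positions; entries where the library
#'   frequency is zero are NaN and flagged in attribute \code{undefined}.
#' @export
position_nucleotide_ratio <- function(hit_strands, library_strands,
                                      positions = 2:8, unique_seeds = TRUE) {
  hit_strands <- normalize_rna(hit_strands)
  library_strands <- normalize_rna(library_strands)
  if (!length(hit_strands)) stop("need at least one hit strand")
  if (unique_seeds) {
    hit_strands <- hit_strands[!duplicated(substr(hit_strands, 2L, 8L))]
  }
  freq <- function(strands) {
    m <- vapply(positions, function(p) {
      b <- substr(strands, p, p)
      counts <- table(factor(b, levels = RNA_BASES))
      as.numeric(counts) / length(strands)
    }, numeric(4L))
    dimnames(m) <- list(RNA_BASES, paste0("pos", positions))
    m
  }
  fh <- freq(hit_strands)
  fl <- freq(library_strands)
  ratio <- fh / fl
  ratio[fl == 0] <- NaN
  attr(ratio, "undefined") <- which(fl == 0, arr.ind = TRUE)
  attr(ratio, "n_unique_hit_seeds") <- length(hit_strands)
  ratio
}

#' Transcriptome-wide scan for the most off-targeted gene
#'
#' For every transcript in a collection, counts how many siRNAs of the top
#' cohort versus the non-hit cohort carry at least one heptamer seed match in
#' its 3'UTR, computes a two-sided Fisher exact p per transcript, adjusts for
#' multiplicity, and ranks transcripts by adjusted p (ties by raw p, then by
#' descending enrichment).
#'
#' @param library an \code{sirna_library} data.frame.
#' @param top_ids,nonhit_ids disjoint vectors of siRNA ids (e.g. the top 200
#'   screen ranks versus ranks 12,001-17,000).
#' @param transcripts list of \code{\link{transcript_record}}s.
#' @param strands "guide", "passenger" or "both" ("both" counts an siRNA when
#'   either strand matches).
#' @param region scanned region (default "utr3").
#' @param seed_len seed length (default 7).
#' @param adjust "BH" or "bonferroni".
#' @return data.frame ranked by significance: transcript_id, k_top, n_top,
#'   k_non, n_non, r, p, p_adj, rank.
#' @export
transcriptome_offtarget_scan <- function(library, top_ids, nonhit_ids,
                                         transcripts,
                                         strands = c("guide", "passenger", "both"),
                                         region = "utr3", seed_len = 7,
                                         adjust = c("BH", "bonferroni")) {
  strands <- match.arg(strands)
  adjust <- match.arg(adjust)
  if (!length(transcripts)) stop("empty transcript collection")
  if (length(intersect(top_ids, nonhit_ids))) stop("cohorts must be disjoint")
  use_strands <- if (strands == "both") c("guide", "passenger") else strands
  ids <- c(top_ids, nonhit_ids)
  lib <- library[match(ids, library$sirna_id), , drop = FALSE]
  if (anyNA(lib$sirna_id)) stop("cohort ids missing from the library")
  # exact sites are fixed strings: the reverse complement of each seed
  pats <- lapply(use_strands, function(s)
    reverse_complement(seed_of(lib[[s]], seed_len)))
  is_top <- ids %in% top_ids
  rows <- lapply(transcripts, function(tx) {
    target <- region_sequence(tx, region)
    hit <- rep(FALSE, length(ids))
    for (p in pats) {
      hit <- hit | vapply(p, function(pat)
        grepl(pat, target, fixed = TRUE), logical(1L), USE.NAMES = FALSE)
    }
    data.frame(transcript_id = tx$transcript_id,
               k_top = sum(hit[is_top]), n_top = sum(is_top),
               k_non = sum(hit[!is_top]), n_non = sum(!is_top),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$r <- ifelse(out$k_non > 0,
                  (out$k_top / out$n_top) / (out$k_non / out$n_non),
                  ifelse(out$k_top > 0, Inf, NA_real_))
  out$p <- vapply(seq_len(nrow(out)), function(i)
    fisher_p(out$k_top[i], out$n_top[i], out$k_non[i], out$n_non[i]),
    numeric(1L))
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  ord <- order(out$p_adj, out$p, -pmin(out$r, .Machine$double.xmax),
               out$transcript_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  row.names(out) <- NULL
  attr(out, "adjust_method") <- adjust
  attr(out, "strands") <- strands
  out
}
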