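# One-config orchestration: simulate -> normalize -> scan -> enrich -> report.

.fnv1a <- function(x) {
  # tiny config fingerprint (FNV-1a, 32 bit) for output provenance headers
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Default pipeline configuration
#'
#' Every tunable of the pipeline stages with its default. Unknown keys in a
#' user configuration are rejected by \code{\link{run_pipeline}}.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    rng_seed = 1L,
    simulate = list(enabled = TRUE, preset = "small"),
    inputs = list(wells = NULL, library = NULL, transcripts_fasta = NULL,
                  regions = NULL, conservation = NULL,
                  receptor_knockdown = NULL),
    normalize = list(min_cells = 400, k_neighbors = 24, robust_iters = 2,
                     kernel = "tricube"),
    hits = list(sigma_threshold = 2.5),
    scan = list(region = "utr3", seed_len = 7, max_wobbles = 0,
                wobble_preset = "site"),
    enrich = list(top_n = 200, nonhit_ranks = c(12001, 17000),
                  scan_strands = "guide", adjust = "BH",
                  rank_window = 500, hotspot_window = 50,
                  conservation_threshold = 0.5)
  )
}

.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under ", path) else "",
                 paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

.stage <- function(name, expr, quiet = FALSE) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or input loading), normalization, hit calling, the
#' transcriptome off-target scan, per-motif enrichment against the
#' top-scanned gene, rank/hotspot profiles and (when a conservation track is
#' available) conserved-site enrichment; writes per-stage TSVs plus JSON and
#' Markdown reports into \code{out_dir}. Every output file starts with a
#' provenance header (package version, config hash, rng seed). Re-running
#' with the same configuration reproduces identical outputs.
#'
#' @param config nested list overriding \code{\link{default_run_config}}, or
#'   the path of a JSON file with such a list. Unknown keys are rejected.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage timing messages.
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- .merge_config(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE,
                               null = "null")
  writeLines(cfg_json, file.path(out_dir, "config.json"))
  hdr <- sprintf("# rnaiscreen %s | config=%s | rng_seed=%d",
                 as.character(utils::packageVersion("rnaiscreen")),
                 .fnv1a(as.character(cfg_json)), as.integer(cfg$rng_seed))

  # --- inputs / simulation -------------------------------------------------
  bench <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    bench <- .stage("simulate", synthetic_benchmark(
      rng_seed = as.integer(cfg$rng_seed), preset = cfg$simulate$preset),
      quiet)
    library <- bench$library
    transcripts <- bench$transcripts
    wells <- bench$wells
    write_library_table(library, file.path(out_dir, "library.tsv"))
    write_transcript_fasta(transcripts, file.path(out_dir, "transcripts.fasta"),
                           file.path(out_dir, "regions.tsv"))
    write_conservation_track(transcripts,
                             file.path(out_dir, "conservation.bedgraph"))
    write_tsv(wells, file.path(out_dir, "wells.tsv"), hdr)
    write_tsv(bench$truth, file.path(out_dir, "truth.tsv"), hdr)
  } else {
    ins <- cfg$inputs
    if (is.null(ins$wells) || is.null(ins$library) ||
        is.null(ins$transcripts_fasta) || is.null(ins$regions)) {
      stop("stage 'inputs' failed: need wells, library, transcripts_fasta and regions when simulate is disabled")
    }
    library <- .stage("inputs", read_library_table(ins$library), quiet)
    transcripts <- read_transcript_fasta(ins$transcripts_fasta, ins$regions)
    if (!is.null(ins$conservation)) {
      transcripts <- read_conservation_track(ins$conservation, transcripts)
    }
    wells <- read_well_table(ins$wells)
  }

  # --- normalization and hit calling ---------------------------------------
  norm <- .stage("normalize", normalize_screen(
    wells, min_cells = cfg$normalize$min_cells,
    k_neighbors = cfg$normalize$k_neighbors,
    robust_iters = cfg$normalize$robust_iters,
    kernel = cfg$normalize$kernel), quiet)
  hits <- call_hits(norm, sigma_threshold = cfg$hits$sigma_threshold)
  counts <- attr(hits, "counts")
  scores_out <- merge(norm$scores, hits[, c("sirna_id", "group")],
                      by = "sirna_id", all.x = TRUE, sort = FALSE)
  scores_out$group[is.na(scores_out$group)] <- "none"
  scores_out <- scores_out[order(scores_out$rank, scores_out$sirna_id), ]
  write_tsv(scores_out, file.path(out_dir, "scores.tsv"), hdr)
  write_tsv(norm$bias, file.path(out_dir, "bias.tsv"), hdr)
  jsonlite::write_json(norm$qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")

  # --- receptor classification (optional knockdown table) ------------------
  receptor <- NULL
  if (!is.null(cfg$inputs$receptor_knockdown)) {
    kd <- utils::read.delim(cfg$inputs$receptor_knockdown, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    receptor <- .stage("classify", classify_receptor_effects(kd), quiet)
    write_tsv(receptor$table, file.path(out_dir, "receptor_classes.tsv"), hdr)
  }

  # --- cohorts -------------------------------------------------------------
  ranked <- hits[order(hits$rank), ]
  n_ranked <- nrow(ranked)
  # top cohort never swallows more than half the screen
  n_top <- min(cfg$enrich$top_n, max(1L, n_ranked %/% 2L))
  top_ids <- ranked$sirna_id[seq_len(n_top)]
  nr <- cfg$enrich$nonhit_ranks
  nonhit_ids <- ranked$sirna_id[ranked$rank >= nr[1L] & ranked$rank <= nr[2L]]
  if (!length(nonhit_ids)) {
    # screen smaller than the requested rank band: use the back part,
    # excluding the top cohort
    lo <- min(max(n_top + 1L, ceiling(n_ranked * 0.4)), n_ranked)
    nonhit_ids <- ranked$sirna_id[lo:n_ranked]
  }
  nonhit_ids <- setdiff(nonhit_ids, top_ids)
  if (!length(nonhit_ids)) {
    stop("stage 'cohorts' failed: no non-hit siRNAs left after excluding the top cohort")
  }

  # --- transcriptome scan --------------------------------------------------
  gene_scan <- .stage("scan", transcriptome_offtarget_scan(
    library, top_ids, nonhit_ids, transcripts,
    strands = cfg$enrich$scan_strands, region = cfg$scan$region,
    seed_len = cfg$scan$seed_len, adjust = cfg$enrich$adjust), quiet)
  write_tsv(gene_scan, file.path(out_dir, "gene_scan.tsv"), hdr)
  top_gene <- if (nrow(gene_scan)) gene_scan$transcript_id[1L] else NA_character_

  # --- motif enrichment on the top gene ------------------------------------
  enrichment <- NULL
  curves <- NULL
  if (!is.na(top_gene)) {
    tx <- transcripts[[top_gene]]
    cohort_ids <- c(top_ids, nonhit_ids)
    cohort_lib <- library[library$sirna_id %in% cohort_ids, , drop = FALSE]
    strand <- if (cfg$enrich$scan_strands == "both") "both" else
      cfg$enrich$scan_strands
    ft <- .stage("enrich", scan_library(
      cohort_lib, tx, strands = strand, regions = c("utr3", "orf"),
      seed_len = cfg$scan$seed_len, max_wobbles = 0), quiet)
    ft_wob <- scan_library(cohort_lib, tx, strands = strand,
                           regions = cfg$scan$region,
                           seed_len = cfg$scan$seed_len, max_wobbles = 1,
                           wobble_allowed = wobble_preset(cfg$scan$wobble_preset))
    u3 <- ft[ft$region == "utr3", , drop = FALSE]
    motifs <- list(
      heptamer = function(d) d$any_site,
      multiple_heptamers = function(d) d$n_sites >= 2,
      t1A = function(d) d$any_site & d$t1A,
      t9_AU_or_match = function(d) d$any_site & (d$t9_AU | d$pos9_match),
      pair3p_12_19 = function(d) d$any_site & d$pair3p_34_offset2,
      pair3p_10_19 = function(d) d$any_site & d$pair3p_45_1019,
      pos16 = function(d) d$any_site & d$pos16_match,
      seed_t1A_pair3p = function(d) d$any_site & d$t1A & d$pair3p_34_offset2)
    enr <- lapply(names(motifs), function(nm) {
      motif_enrichment(u3, top_ids, nonhit_ids, motifs[[nm]], motif_name = nm)
    })
    enr[[length(enr) + 1L]] <- motif_enrichment(
      ft_wob, top_ids, nonhit_ids,
      function(d) d$any_site & d$n_wobble_sites > 0,
      motif_name = "wobble_seed")
    enr[[length(enr) + 1L]] <- motif_enrichment(
      ft[ft$region == "orf", , drop = FALSE], top_ids, nonhit_ids,
      function(d) d$any_site, motif_name = "orf_heptamer")
    # ORF enrichment after excluding every siRNA with a 3'UTR match
    utr_ids <- u3$sirna_id[u3$any_site]
    enr[[length(enr) + 1L]] <- motif_enrichment(
      ft[ft$region == "orf", , drop = FALSE], top_ids, nonhit_ids,
      function(d) d$any_site,
      exclude = function(d) d$sirna_id %in% utr_ids,
      motif_name = "orf_heptamer_no_utr_match")
    enrichment <- adjust_enrichment(
      do.call(rbind, c(enr, list(make.row.names = FALSE))),
      method = cfg$enrich$adjust)
    write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"), hdr)

    # rank curve of top-gene seed matches over the whole screen ranking
    all_ranked <- hits[order(hits$rank), ]
    pats <- reverse_complement(seed_of(
      library$guide[match(all_ranked$sirna_id, library$sirna_id)],
      cfg$scan$seed_len))
    target <- region_sequence(tx, cfg$scan$region)
    flags <- vapply(pats, grepl, logical(1L), x = target, fixed = TRUE,
                    USE.NAMES = FALSE)
    curve <- rank_moving_average(flags,
                                 window = min(cfg$enrich$rank_window, n_ranked))
    write_tsv(as.data.frame(curve), file.path(out_dir, "rank_curve.tsv"), hdr)

    hit_sites <- site_table(library[library$sirna_id %in% top_ids, ], tx,
                            strands = "guide", regions = "utr3",
                            seed_len = cfg$scan$seed_len)
    non_sites <- site_table(library[library$sirna_id %in% nonhit_ids, ], tx,
                            strands = "guide", regions = "utr3",
                            seed_len = cfg$scan$seed_len)
    utr_len <- nchar(region_sequence(tx, "utr3"))
    prof <- utr_hotspot_profile(hit_sites$start - 1L, non_sites$start - 1L,
                                utr_len, window = cfg$enrich$hotspot_window,
                                n_hits = length(top_ids),
                                n_nonhits = length(nonhit_ids))
    write_tsv(as.data.frame(prof), file.path(out_dir, "utr_hotspot.tsv"), hdr)
    curves <- list(rank_curve = curve, hotspot = prof)

    conservation <- NULL
    if (!is.null(tx$conservation)) {
      cons <- region_conservation(tx, "utr3")
      hs <- hit_sites; hs$start <- hs$start - 1L
      ns <- non_sites; ns$start <- ns$start - 1L
      conservation <- conserved_region_enrichment(
        hs, ns, cons, n_hits = length(top_ids), n_non = length(nonhit_ids),
        threshold = cfg$enrich$conservation_threshold)
    }
  } else {
    conservation <- NULL
  }

  # --- report --------------------------------------------------------------
  report <- list(
    config_hash = .fnv1a(as.character(cfg_json)),
    rng_seed = cfg$rng_seed,
    n_sirnas = nrow(library),
    hit_counts = as.list(counts),
    sigma_threshold = cfg$hits$sigma_threshold,
    receptor_classification = if (!is.null(receptor)) as.list(receptor$counts),
    strict_list_sizes = if (!is.null(receptor))
      list(r1 = length(receptor$strict_r1), r2 = length(receptor$strict_r2)),
    top_gene = top_gene,
    gene_scan_top = utils::head(gene_scan, 10L),
    enrichment = enrichment,
    conservation = if (!is.null(conservation)) unclass(conservation),
    planted_target = if (!is.null(bench)) bench$target_id
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  md <- c(sprintf("# rnaiscreen report (%s)", report$config_hash),
          "",
          sprintf("- siRNAs analysed: %d", report$n_sirnas),
          sprintf("- hits at %.1f SD: %d decrease / %d increase",
                  report$sigma_threshold, counts[["decrease"]],
                  counts[["increase"]]),
          sprintf("- most off-targeted transcript: %s", top_gene),
          "",
          "## Motif enrichment (top transcript, 3'UTR)",
          if (!is.null(enrichment)) {
            c("", "| motif | r | p | p_adj |", "|---|---|---|---|",
              sprintf("| %s | %.3g | %.3g | %.3g |", enrichment$motif_name,
                      enrichment$r, enrichment$p, enrichment$p_adj))
          } else "(no enrichment computed)")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(report)
}
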