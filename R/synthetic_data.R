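# Synthetic ground-truth data: siRNA libraries following the screen's design
# rules, transcript collections with planted miRNA-like target sites, block
# conservation tracks, and simulated screen plates with a planted
# cell-density bias. Everything is deterministic given rng_seed.

.rand_bases <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Check a guide strand against the library design rules
#'
#' Rule 1: A/U at positions 1 and 9, and/or G/C at position 19. Rule 2: at
#' least three A/U among positions 1-7.
#'
#' @param guide 19-nt guide strand(s).
#' @return logical vector.
#' @export
check_design_rules <- function(guide) {
  guide <- normalize_rna(guide)
  vapply(guide, function(g) {
    ch <- strsplit(g, "", fixed = TRUE)[[1L]]
    if (length(ch) != 19L) return(FALSE)
    rule1 <- (ch[1L] %in% c("A", "U") && ch[9L] %in% c("A", "U")) ||
      ch[19L] %in% c("G", "C")
    rule2 <- sum(ch[1:7] %in% c("A", "U")) >= 3L
    rule1 && rule2
  }, logical(1L), USE.NAMES = FALSE)
}

#' Generate a synthetic siRNA duplex library
#'
#' Guides are sampled uniformly over 19-mers and rejection-filtered through
#' the design rules (see \code{\link{check_design_rules}}); all guides are
#' unique; the passenger strand is the exact reverse complement of the guide
#' (the duplex core; the fixed dTdT overhang is never represented).
#'
#' @param n number of duplexes.
#' @param rng_seed integer seed.
#' @param gc guide GC content (default 0.5).
#' @param max_attempts sampling budget before giving up on uniqueness.
#' @return an \code{sirna_library} data.frame.
#' @export
generate_library <- function(n, rng_seed = 1, gc = 0.5,
                             max_attempts = 1000 * n) {
  stopifnot(n >= 1)
  set.seed(rng_seed)
  guides <- character(0L)
  attempts <- 0L
  while (length(guides) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("could not generate %d unique rule-passing guides", n))
    }
    g <- paste(.rand_bases(19L, gc), collapse = "")
    if (check_design_rules(g) && !(g %in% guides)) guides <- c(guides, g)
  }
  validate_library(data.frame(
    sirna_id = sprintf("si%05d", seq_len(n)),
    intended_gene = sprintf("GENE%04d", seq_len(n)),
    guide = guides,
    passenger = reverse_complement(guides),
    stringsAsFactors = FALSE))
}

#' Generate random transcripts with UTR/ORF annotation
#'
#' Background sequence is i.i.d. with configurable GC content; each
#' transcript gets a 5'UTR, an ORF and a 3'UTR of the requested sizes.
#'
#' @param n_genes number of transcripts.
#' @param utr3_length_range c(min, max) 3'UTR length.
#' @param utr5_length,orf_length fixed lengths of the other regions.
#' @param gc GC content (default 0.5).
#' @param rng_seed integer seed.
#' @param id_prefix transcript id prefix.
#' @return named list of \code{\link{transcript_record}}s.
#' @export
generate_transcripts <- function(n_genes, utr3_length_range = c(300, 500),
                                 utr5_length = 100, orf_length = 300,
                                 gc = 0.5, rng_seed = 1, id_prefix = "TX") {
  set.seed(rng_seed)
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    lens <- seq.int(utr3_length_range[1L], utr3_length_range[2L])
    u3 <- if (length(lens) == 1L) lens else sample(lens, 1L)
    n <- utr5_length + orf_length + u3
    seq <- paste(.rand_bases(n, gc), collapse = "")
    out[[i]] <- transcript_record(
      sprintf("%s%03d", id_prefix, i), seq,
      utr5 = c(1L, utr5_length),
      orf = c(utr5_length + 1L, utr5_length + orf_length),
      utr3 = c(utr5_length + orf_length + 1L, n))
  }
  names(out) <- vapply(out, `[[`, character(1L), "transcript_id")
  out
}

.pick_base_not <- function(forbidden) {
  setdiff(RNA_BASES, forbidden)[1L]
}

#' Plant miRNA-like target sites into transcript regions
#'
#' Writes exact (or single-wobble) seed-match sites for chosen siRNAs into
#' chosen transcripts, together with their planned auxiliary features (t1A
#' anchor, 3' pairing block over guide positions 12-15, position-16 match
#' with non-pairing flanks), and then rejection-samples the background so
#' that no unplanned sites remain: exact guide-strand sites are eliminated on
#' every transcript, wobble-tolerant sites on every transcript that carries a
#' planted site.
#'
#' @param transcripts named list of \code{\link{transcript_record}}s.
#' @param library an \code{sirna_library} data.frame.
#' @param plan data.frame with columns sirna_id, transcript_id and optionally
#'   region ("utr3"), n_sites (1), wobble_position (0 = exact), t1A (FALSE),
#'   pair3p (FALSE), pos16 (FALSE). Auxiliary features apply to the first
#'   planted site of the row.
#' @param rng_seed seed for the background resampling.
#' @param scan_strands strands checked during rejection (default "guide").
#' @param reject_max_wobbles wobble setting used when purging unplanned sites
#'   from transcripts that carry planted sites (default 1).
#' @param wobble_allowed permitted wobbles, as in
#'   \code{\link{scan_seed_sites}}.
#' @param site_spacing distance between consecutive planted site starts in
#'   one transcript (default 30 nt).
#' @param max_iter rejection-sampling iteration budget.
#' @return list with elements \code{transcripts} (sites planted) and
#'   \code{truth} (data.frame: sirna_id, transcript_id, region, start 0-based,
#'   length, wobble_position, t1A, pair3p, pos16).
#' @export
plant_sites <- function(transcripts, library, plan, rng_seed = 1,
                        scan_strands = "guide", reject_max_wobbles = 1,
                        wobble_allowed = wobble_preset("site"),
                        site_spacing = 30, max_iter = 200) {
  set.seed(rng_seed)
  defaults <- list(region = "utr3", n_sites = 1L, wobble_position = 0L,
                   t1A = FALSE, pair3p = FALSE, pos16 = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(plan)) plan[[nm]] <- defaults[[nm]]
  }
  chars <- lapply(transcripts, function(tx)
    strsplit(tx$sequence, "", fixed = TRUE)[[1L]])
  protected <- lapply(transcripts, function(tx)
    logical(nchar(tx$sequence)))
  slot <- new.env(parent = emptyenv())   # per (transcript, region) counter
  truth <- list()
  margin <- 12L
  for (k in seq_len(nrow(plan))) {
    row <- plan[k, ]
    tx_id <- as.character(row$transcript_id)
    tx <- transcripts[[tx_id]]
    if (is.null(tx)) stop(sprintf("unknown transcript '%s'", tx_id))
    lib_i <- match(as.character(row$sirna_id), library$sirna_id)
    if (is.na(lib_i)) stop(sprintf("unknown siRNA '%s'", row$sirna_id))
    rna <- strsplit(library$guide[lib_i], "", fixed = TRUE)[[1L]]
    reg <- tx[[row$region]]
    if (is.null(reg)) stop(sprintf("transcript '%s' has no %s", tx_id, row$region))
    off <- reg["start"]                      # absolute 0-based region offset
    reg_len <- reg["end"] - reg["start"]
    slot_key <- paste(tx_id, row$region)
    for (s in seq_len(row$n_sites)) {
      used <- if (is.null(slot[[slot_key]])) 0L else slot[[slot_key]]
      i <- margin + used * site_spacing          # 0-based start within region
      slot[[slot_key]] <- used + 1L
      if (i + 9L > reg_len) {
        stop(sprintf("plan infeasible: no room for site %d of '%s' in %s/%s",
                     s, row$sirna_id, tx_id, row$region))
      }
      site <- complement_bases(rev(rna[2:8]))   # reverse complement of seed
      wp <- if (s == 1L) as.integer(row$wobble_position) else 0L
      if (wp > 0L) {
        b <- rna[wp]
        ok <- any(wobble_allowed$position == wp & wobble_allowed$base == b)
        if (!ok) {
          stop(sprintf("plan infeasible: wobble at position %d needs G or U in '%s'",
                       wp, row$sirna_id))
        }
        site[9L - wp] <- if (b == "G") "U" else "G"
      }
      abs0 <- off + i                           # absolute 0-based site start
      put <- function(idx0, base) {             # absolute 0-based write
        chars[[tx_id]][idx0 + 1L] <<- base
        protected[[tx_id]][idx0 + 1L] <<- TRUE
      }
      for (j in seq_len(7L)) put(abs0 + j - 1L, site[j])
      first <- s == 1L
      # t1 anchor base: forced to A or forced away from A, always recorded
      if (i + 7L < reg_len) {
        put(abs0 + 7L, if (first && isTRUE(row$t1A)) "A" else
          .pick_base_not("A"))
      }
      if (first && isTRUE(row$pair3p)) {        # guide 12-15 in register
        for (p in 12:15) put(abs0 + 8L - p, complement_bases(rna[p]))
      }
      if (first && isTRUE(row$pos16)) {
        if (i < 10L) stop("plan infeasible: pos16 needs site start >= 10")
        put(abs0 - 8L, complement_bases(rna[16L]))
        put(abs0 - 9L, .pick_base_not(complement_bases(rna[17L])))
        put(abs0 - 10L, .pick_base_not(complement_bases(rna[18L])))
      }
      truth[[length(truth) + 1L]] <- data.frame(
        sirna_id = as.character(row$sirna_id), transcript_id = tx_id,
        region = row$region, start = as.integer(i), length = 7L,
        wobble_position = wp,
        t1A = first && isTRUE(row$t1A),
        pair3p = first && isTRUE(row$pair3p),
        pos16 = first && isTRUE(row$pos16),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  # --- rejection sampling of the background --------------------------------
  # exact sites are fixed 7-mer strings; search them with an overlapping
  # regex over the full transcript (also killing sites spanning region
  # boundaries). Wobble-tolerant purging is only needed where sites were
  # planted.
  planted_tx <- unique(truth$transcript_id)
  pats <- lapply(scan_strands, function(s)
    reverse_complement(seed_of(library[[s]], 7)))
  names(pats) <- scan_strands
  for (tx_id in names(transcripts)) {
    tx <- transcripts[[tx_id]]
    planned_here <- truth[truth$transcript_id == tx_id, , drop = FALSE]
    # absolute 0-based starts of planned exact sites per siRNA
    planned_abs <- function(li, strand) {
      if (strand != "guide" || !nrow(planned_here)) return(integer(0L))
      rows <- planned_here$sirna_id == library$sirna_id[li] &
        planned_here$wobble_position == 0L
      if (!any(rows)) return(integer(0L))
      vapply(which(rows), function(k)
        tx[[planned_here$region[k]]]["start"] + planned_here$start[k],
        numeric(1L))
    }
    wob_here <- if (tx_id %in% planted_tx) reject_max_wobbles else 0L
    for (iter in seq_len(max_iter)) {
      seq_now <- paste(chars[[tx_id]], collapse = "")
      dirty <- integer(0L)                     # absolute 0-based indices
      for (strand in scan_strands) {
        for (li in seq_len(nrow(library))) {
          m <- gregexpr(paste0("(?=", pats[[strand]][li], ")"), seq_now,
                        perl = TRUE)[[1L]]
          starts <- if (m[1L] == -1L) integer(0L) else as.integer(m) - 1L
          starts <- setdiff(starts, planned_abs(li, strand))
          for (st in starts) dirty <- c(dirty, st + 0:6)
        }
      }
      if (wob_here > 0L) {
        for (strand in scan_strands) {
          for (li in seq_len(nrow(library))) {
            for (region in c("utr5", "orf", "utr3")) {
              reg <- tx[[region]]
              if (is.null(reg)) next
              target <- substr(seq_now, reg["start"] + 1L, reg["end"])
              sites <- scan_seed_sites(library[[strand]][li], target,
                                       seed_len = 7, max_wobbles = wob_here,
                                       wobble_allowed = wobble_allowed)
              for (st in sites$start) {
                planned <- any(planned_here$sirna_id == library$sirna_id[li] &
                               planned_here$region == region &
                               planned_here$start == st)
                if (!planned) dirty <- c(dirty, reg["start"] + st + 0:6)
              }
            }
          }
        }
      }
      dirty <- unique(dirty)
      dirty <- dirty[!protected[[tx_id]][dirty + 1L]]
      if (!length(dirty)) break
      if (iter == max_iter) {
        stop(sprintf("could not purge unplanned sites from '%s'", tx_id))
      }
      chars[[tx_id]][dirty + 1L] <- .rand_bases(length(dirty))
    }
    transcripts[[tx_id]]$sequence <- paste(chars[[tx_id]], collapse = "")
  }
  list(transcripts = transcripts, truth = truth)
}

#' Generate a block-constant conservation track
#'
#' Planted sites (from a truth table) can be made to fall inside conserved
#' blocks; additional conserved background blocks are placed at random.
#'
#' @param transcripts named list of transcript records.
#' @param truth optional truth table from \code{\link{plant_sites}}; every
#'   planted site is covered by a conserved block when
#'   \code{conserve_planted}.
#' @param conserve_planted cover planted sites with conserved blocks
#'   (default TRUE).
#' @param conserved_score,background_score block scores (defaults 0.9, 0.05).
#' @param block_len conserved block length (default 40).
#' @param n_background_blocks random conserved blocks per transcript
#'   (default 1).
#' @param rng_seed integer seed.
#' @return the transcripts with conservation attached.
#' @export
generate_conservation <- function(transcripts, truth = NULL,
                                  conserve_planted = TRUE,
                                  conserved_score = 0.9,
                                  background_score = 0.05,
                                  block_len = 40, n_background_blocks = 1,
                                  rng_seed = 1) {
  set.seed(rng_seed)
  for (tx_id in names(transcripts)) {
    tx <- transcripts[[tx_id]]
    n <- nchar(tx$sequence)
    sc <- rep(background_score, n)
    for (b in seq_len(n_background_blocks)) {
      s <- sample.int(max(1L, n - block_len), 1L)
      sc[s:(s + block_len - 1L)] <- conserved_score
    }
    if (conserve_planted && !is.null(truth)) {
      here <- truth[truth$transcript_id == tx_id, , drop = FALSE]
      for (k in seq_len(nrow(here))) {
        reg <- tx[[here$region[k]]]
        a <- reg["start"] + here$start[k] + 1L   # 1-based absolute
        lo <- max(1L, a - 5L)
        hi <- min(n, a + here$length[k] + 4L)
        sc[lo:hi] <- conserved_score
      }
    }
    transcripts[[tx_id]] <- set_conservation(tx, sc)
  }
  transcripts
}

#' Configuration for the plate simulator
#'
#' @param n_plates number of plates.
#' @param dims c(rows, cols) plate dimensions (default 16 x 24, 384-well).
#' @param base_nc baseline N:C ratio (default 1.6).
#' @param bias_A per-plate slope(s) of the cell-count bias (recycled;
#'   negative = ratios fall with imaged cell number, the observed direction).
#' @param bias_B per-plate offset(s) (recycled).
#' @param noise_sd Gaussian well noise SD (default 0.02).
#' @param effect_scale N:C units per unit of planted z-shift (default 0.05).
#' @param base_count central imaged cell count (default 700).
#' @param edge_drop fractional count reduction at the plate border (default
#'   0.5); negative values invert the gradient direction.
#' @param edge_width border band width in wells (default 2).
#' @param count_sd Gaussian cell-count noise SD (default 25).
#' @param n_controls_per_plate control wells placed at plate centre
#'   (default 4).
#' @param rng_seed integer seed.
#' @return list of class \code{screen_sim_config}.
#' @export
screen_sim_config <- function(n_plates = 2, dims = c(16, 24), base_nc = 1.6,
                              bias_A = -4e-4, bias_B = 0, noise_sd = 0.02,
                              effect_scale = 0.05, base_count = 700,
                              edge_drop = 0.5, edge_width = 2, count_sd = 25,
                              n_controls_per_plate = 4, rng_seed = 1) {
  structure(list(n_plates = n_plates, dims = dims, base_nc = base_nc,
                 bias_A = rep_len(bias_A, n_plates),
                 bias_B = rep_len(bias_B, n_plates),
                 noise_sd = noise_sd, effect_scale = effect_scale,
                 base_count = base_count, edge_drop = edge_drop,
                 edge_width = edge_width, count_sd = count_sd,
                 n_controls_per_plate = n_controls_per_plate,
                 rng_seed = rng_seed),
            class = "screen_sim_config")
}

#' Simulate raw screen plates with planted bias and effects
#'
#' Cell counts follow a spatial field with reduced counts in a border band
#' (mimicking uneven cell settling; direction configurable through the sign
#' of \code{edge_drop}); the raw N:C ratio of a well is
#' \code{base_nc + A_p * N + B_p + effect_scale * z_shift + noise}. siRNAs
#' with a planted effect are assigned to the most interior wells (spread over
#' plates) so that the low-count edge filter cannot remove them. Control
#' wells sit at the plate centre.
#'
#' @param library an \code{sirna_library} data.frame; must fit into
#'   \code{n_plates * (wells - controls)} wells (it may be smaller; leftover
#'   wells stay empty and are omitted).
#' @param effects data.frame (sirna_id, z_shift); siRNAs not listed have
#'   shift 0.
#' @param cfg a \code{\link{screen_sim_config}}.
#' @return list: \code{wells} (raw well table), \code{true_scores}
#'   (sirna_id, true_z), \code{config}.
#' @export
simulate_screen <- function(library, effects = NULL, cfg = screen_sim_config()) {
  set.seed(cfg$rng_seed)
  R <- cfg$dims[1L]; C <- cfg$dims[2L]
  shift <- stats::setNames(rep(0, nrow(library)), library$sirna_id)
  if (!is.null(effects) && nrow(effects)) {
    shift[as.character(effects$sirna_id)] <- effects$z_shift
  }
  # control well positions: a centre block
  cr <- floor(R / 2); cc <- floor(C / 2)
  ctrl_pos <- utils::head(expand.grid(row = c(cr, cr + 1L),
                                      col = c(cc, cc + 1L)),
                          cfg$n_controls_per_plate)
  grid <- expand.grid(row = seq_len(R), col = seq_len(C))
  is_ctrl_cell <- paste(grid$row, grid$col) %in% paste(ctrl_pos$row, ctrl_pos$col)
  lib_cells <- grid[!is_ctrl_cell, , drop = FALSE]
  capacity <- cfg$n_plates * nrow(lib_cells)
  if (nrow(library) > capacity) {
    stop(sprintf("library (%d) exceeds capacity (%d wells)", nrow(library),
                 capacity))
  }
  # effect siRNAs go to interior wells (safe from the edge-count filter) and
  # are spread out so that no local-regression neighbourhood is dominated by
  # planted effects; nulls fill the remaining wells.
  d_edge <- pmin(lib_cells$row - 1L, R - lib_cells$row,
                 lib_cells$col - 1L, C - lib_cells$col)
  lib_cells <- lib_cells[order(-d_edge, lib_cells$row, lib_cells$col), ]
  n_interior <- sum(d_edge >= cfg$edge_width)
  eff_idx <- which(shift != 0)
  null_idx <- which(shift == 0)
  cap <- nrow(lib_cells)
  plate_of_eff <- rep(seq_len(cfg$n_plates), length.out = length(eff_idx))
  rows <- list()
  next_null <- 1L
  for (p in seq_len(cfg$n_plates)) {
    eff_p <- eff_idx[plate_of_eff == p]
    n_null_p <- min(cap - length(eff_p),
                    length(null_idx) - next_null + 1L)
    null_p <- if (n_null_p > 0L)
      null_idx[next_null:(next_null + n_null_p - 1L)] else integer(0L)
    next_null <- next_null + n_null_p
    slots <- integer(0L)                       # cell index per effect siRNA
    if (length(eff_p)) {
      interior <- seq_len(max(n_interior, length(eff_p)))
      # greedy maximin scatter over interior wells so that no local-fit
      # neighbourhood sees several planted effects at once
      slots <- interior[1L]
      while (length(slots) < length(eff_p)) {
        cand <- setdiff(interior, slots)
        dmin <- vapply(cand, function(i) min(
          (lib_cells$row[i] - lib_cells$row[slots])^2 +
            (lib_cells$col[i] - lib_cells$col[slots])^2), numeric(1L))
        slots <- c(slots, cand[which.max(dmin)])
      }
    }
    free <- setdiff(seq_len(cap), slots)[seq_along(null_p)]
    assign_idx <- c(eff_p, null_p)
    cell_idx <- c(slots, free)
    for (k in seq_along(assign_idx)) {
      li <- assign_idx[k]
      cell <- lib_cells[cell_idx[k], ]
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = sprintf("P%02d", p), row = cell$row, col = cell$col,
        sirna_id = library$sirna_id[li], is_control = FALSE,
        z_shift = unname(shift[library$sirna_id[li]]),
        stringsAsFactors = FALSE)
    }
  }
  for (p in seq_len(cfg$n_plates)) {
    for (q in seq_len(nrow(ctrl_pos))) {
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = sprintf("P%02d", p),
        row = ctrl_pos$row[q], col = ctrl_pos$col[q],
        sirna_id = sprintf("CTRL%02d_P%02d", q, p), is_control = TRUE,
        z_shift = 0, stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p_idx <- as.integer(sub("^P", "", wells$plate_id))
  d <- pmin(wells$row - 1L, R - wells$row, wells$col - 1L, C - wells$col)
  edge_factor <- pmax(0, 1 - d / cfg$edge_width)
  N <- cfg$base_count * (1 - cfg$edge_drop * edge_factor)
  if (cfg$count_sd > 0) N <- N + stats::rnorm(length(N), 0, cfg$count_sd)
  wells$cell_count <- pmax(1L, as.integer(round(N)))
  nc <- cfg$base_nc + cfg$bias_A[p_idx] * wells$cell_count +
    cfg$bias_B[p_idx] + cfg$effect_scale * wells$z_shift
  if (cfg$noise_sd > 0) nc <- nc + stats::rnorm(length(nc), 0, cfg$noise_sd)
  wells$nc_ratio <- pmax(nc, 1e-3)
  true_scores <- data.frame(sirna_id = library$sirna_id,
                            true_z = unname(shift[library$sirna_id]),
                            stringsAsFactors = FALSE)
  wells$z_shift <- NULL
  list(wells = wells[, c("plate_id", "row", "col", "sirna_id", "cell_count",
                         "nc_ratio", "is_control")],
       true_scores = true_scores, config = cfg)
}

#' Build the default synthetic benchmark
#'
#' A complete, seeded miniature of the screen: a rule-conforming library, a
#' transcript collection with one designated off-target gene into which seed
#' sites of the "hit" siRNAs are planted (with a mix of multiplicities,
#' wobbles, t1A anchors, 3' pairing and position-16 matches), a conservation
#' track covering the planted sites, and simulated plates in which the hit
#' siRNAs carry a strong negative z-shift.
#'
#' @param rng_seed integer seed driving every stage.
#' @param preset "small" (default; 184 siRNAs on two 8x12 plates, 40 genes)
#'   or "tiny" (56 siRNAs on one plate, 12 genes; for quick tests).
#' @return list: library, transcripts, truth, wells, true_scores, target_id,
#'   hit_ids, config, plan.
#' @export
synthetic_benchmark <- function(rng_seed = 1, preset = c("small", "tiny")) {
  preset <- match.arg(preset)
  ps <- switch(preset,
    small = list(n_plates = 2L, dims = c(12L, 16L), n_genes = 40L, n_hits = 16L),
    tiny = list(n_plates = 1L, dims = c(8L, 12L), n_genes = 12L, n_hits = 6L))
  n_ctrl <- 4L
  n_lib <- ps$n_plates * (prod(ps$dims) - n_ctrl)
  library <- generate_library(n_lib, rng_seed = rng_seed)
  utr3_range <- if (preset == "small") c(650, 750) else c(350, 450)
  transcripts <- generate_transcripts(ps$n_genes,
                                      utr3_length_range = utr3_range,
                                      rng_seed = rng_seed + 1L)
  target_id <- names(transcripts)[1L]
  hit_ids <- library$sirna_id[seq_len(ps$n_hits)]
  # feature plan: multiplicities and auxiliary features cycle over the hits;
  # a couple of hits get a single-wobble site instead of an exact one
  plan <- data.frame(sirna_id = hit_ids, transcript_id = target_id,
                     region = "utr3",
                     n_sites = rep_len(c(1L, 2L, 1L, 1L), ps$n_hits),
                     wobble_position = 0L,
                     t1A = rep_len(c(TRUE, TRUE, FALSE, TRUE), ps$n_hits),
                     pair3p = rep_len(c(TRUE, FALSE, TRUE, FALSE), ps$n_hits),
                     pos16 = rep_len(c(FALSE, TRUE, TRUE, FALSE), ps$n_hits),
                     stringsAsFactors = FALSE)
  # give the last two hits a wobble site where the guide seed admits one
  wa <- wobble_preset("site")
  n_wob <- 0L
  for (i in rev(seq_len(ps$n_hits))) {
    if (n_wob >= 2L) break
    g <- strsplit(library$guide[i], "", fixed = TRUE)[[1L]]
    for (q in seq_len(nrow(wa))) {
      if (g[wa$position[q]] == wa$base[q]) {
        plan$wobble_position[i] <- wa$position[q]
        plan$n_sites[i] <- 1L
        n_wob <- n_wob + 1L
        break
      }
    }
  }
  planted <- plant_sites(transcripts, library, plan,
                         rng_seed = rng_seed + 2L, scan_strands = "guide")
  transcripts <- generate_conservation(planted$transcripts, planted$truth,
                                       rng_seed = rng_seed + 3L)
  effects <- data.frame(sirna_id = hit_ids,
                        z_shift = -5 - (seq_len(ps$n_hits) %% 3))
  cfg <- screen_sim_config(n_plates = ps$n_plates, dims = ps$dims,
                           rng_seed = rng_seed + 4L)
  sim <- simulate_screen(library, effects, cfg)
  list(library = library, transcripts = transcripts, truth = planted$truth,
       wells = sim$wells, true_scores = sim$true_scores,
       target_id = target_id, hit_ids = hit_ids, config = cfg, plan = plan)
}
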