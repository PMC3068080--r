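# Normalization of image-derived screen scores.
#
# The raw readout is a per-well nuclear:cytosolic (N:C) fluorescence ratio
# that carries a cell-density artefact: wells with fewer imaged cells show
# elevated ratios, and cell counts fall off towards plate edges. The
# correction pipeline is
#
#   1. plate_standardize   - each plate to mean 0 / SD 1
#   2. filter_low_count    - drop wells imaged with < 400 cells
#   3. fit_local_bias      - per-well local linear model  nc ~ A*N + B
#                            (nearest-neighbour kernel regression, robust)
#   4. correct_bias        - subtract the fitted bias term
#   5. global_standardize  - final cross-plate standardization to SD 1
#
# normalize_screen() runs all five and returns a `screen_scores` object.
# Sample (n-1) SD is used throughout.

#' Flag wells imaged with too few cells
#'
#' The removal rule is strict: a well with \code{cell_count < min_cells} is
#' dropped; a well exactly at the threshold is kept.
#'
#' @param wells well data.frame (see \code{\link{read_well_table}}).
#' @param min_cells minimum imaged cell count (default 400).
#' @return wells with a logical \code{retained} column (existing
#'   \code{retained} flags are AND-ed in, so a well dropped earlier stays
#'   dropped).
#' @export
filter_low_count <- function(wells, min_cells = 400) {
  keep <- wells$cell_count >= min_cells
  if ("retained" %in% names(wells)) keep <- keep & wells$retained
  wells$retained <- keep
  wells
}

.retained <- function(wells) {
  if ("retained" %in% names(wells)) wells$retained else rep(TRUE, nrow(wells))
}

#' Standardize each plate to mean 0 and SD 1
#'
#' Statistics are computed over retained library (non-control) wells of the
#' plate and the affine transform is applied to every well on it. Plates with
#' fewer than two usable wells, or zero spread, are dropped with a warning.
#'
#' @param wells well data.frame; \code{nc_ratio} (or a previously transformed
#'   \code{nc}) is standardized into column \code{nc}.
#' @return wells with columns \code{nc} (standardized value) and
#'   \code{retained} updated.
#' @export
plate_standardize <- function(wells) {
  if (!"nc" %in% names(wells)) wells$nc <- wells$nc_ratio
  wells$retained <- .retained(wells)
  for (p in unique(wells$plate_id)) {
    on_plate <- wells$plate_id == p
    use <- on_plate & wells$retained & !wells$is_control
    n <- sum(use)
    s <- if (n >= 2L) stats::sd(wells$nc[use]) else NA_real_
    if (n < 2L || !is.finite(s) || s == 0) {
      warning(sprintf("plate '%s' dropped (%d usable wells, sd=%s)",
                      p, n, format(s)))
      wells$retained[on_plate] <- FALSE
      next
    }
    m <- mean(wells$nc[use])
    wells$nc[on_plate] <- (wells$nc[on_plate] - m) / s
  }
  wells
}

#' Fit a per-well local linear cell-count bias model
#'
#' For every retained well, the coefficients (A, B) of \code{nc ~ A*N + B}
#' are estimated by weighted least squares over the \code{k_neighbors}
#' nearest retained library wells on the same plate, excluding the well
#' itself (leave-one-out, so an outlying well cannot absorb its own signal
#' into its bias estimate; with the default k = 24 this is the 5x5
#' neighbourhood minus self away from plate borders). Distances are
#' Euclidean in (row, col); neighbourhoods are truncated at plate borders,
#' no wrap-around. Weights come from a tricube kernel on distance, refined
#' by Tukey-bisquare robust re-weighting of residuals. Control wells never contribute observations to
#' the fit but do receive coefficients so that they can be corrected and
#' reported.
#'
#' @param wells plate-standardized, filtered well data.frame (column
#'   \code{nc}).
#' @param k_neighbors neighbourhood size excluding the well itself (default
#'   24, i.e. a full 5x5 block away from edges).
#' @param robust_iters rounds of bisquare re-weighting (default 2).
#' @param kernel "tricube" (default) or "uniform".
#' @param bisquare_c bisquare tuning constant (default 4.685).
#' @return data.frame (plate_id, row, col, A, B, degenerate) with one row per
#'   retained well.
#' @export
fit_local_bias <- function(wells, k_neighbors = 24, robust_iters = 2,
                           kernel = c("tricube", "uniform"),
                           bisquare_c = 4.685) {
  kernel <- match.arg(kernel)
  wells$retained <- .retained(wells)
  out <- list()
  for (p in unique(wells$plate_id)) {
    plate <- wells[wells$plate_id == p & wells$retained, , drop = FALSE]
    if (!nrow(plate)) next
    pool <- which(!plate$is_control)   # observation pool: library wells
    A <- B <- rep(NA_real_, nrow(plate))
    degen <- logical(nrow(plate))
    for (i in seq_len(nrow(plate))) {
      d2 <- (plate$row[pool] - plate$row[i])^2 + (plate$col[pool] - plate$col[i])^2
      ord <- order(d2, plate$row[pool], plate$col[pool])  # deterministic ties
      nb_sorted <- pool[ord]
      # leave-one-out: the well's own observation never enters its own fit,
      # so an outlying well cannot drag its own bias estimate towards itself
      others <- nb_sorted[nb_sorted != i]
      nb <- utils::head(others, k_neighbors)
      if (!length(nb)) { A[i] <- 0; B[i] <- 0; degen[i] <- TRUE; next }
      d <- sqrt((plate$row[nb] - plate$row[i])^2 + (plate$col[nb] - plate$col[i])^2)
      w <- if (kernel == "uniform" || max(d) == 0) {
        rep(1, length(nb))
      } else {
        (1 - (d / (max(d) * 1.0001))^3)^3
      }
      x <- plate$cell_count[nb]
      y <- plate$nc[nb]
      fit <- .wls_line(x, y, w)
      for (r in seq_len(robust_iters)) {
        res <- y - (fit["A"] * x + fit["B"])
        s <- stats::median(abs(res)) / 0.6745
        if (!is.finite(s) || s < 1e-12) break
        u <- res / (bisquare_c * s)
        wr <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
        if (sum(w * wr) < 1e-12) break
        fit <- .wls_line(x, y, w * wr)
      }
      A[i] <- fit["A"]; B[i] <- fit["B"]; degen[i] <- fit["degenerate"] == 1
    }
    out[[p]] <- data.frame(plate_id = p, row = plate$row, col = plate$col,
                           A = A, B = B, degenerate = degen,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Weighted least squares for y ~ A*x + B. A degenerate design (all x equal)
# yields A = 0, B = weighted mean, flagged.
.wls_line <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx < 1e-10 * max(1, mx^2)) {
    return(c(A = 0, B = my, degenerate = 1))
  }
  a <- sum(w * (x - mx) * (y - my)) / sxx
  c(A = a, B = my - a * mx, degenerate = 0)
}

#' Subtract the fitted cell-count bias from each well
#'
#' @param wells well data.frame with column \code{nc}.
#' @param bias bias table from \code{\link{fit_local_bias}}.
#' @return wells with \code{nc} replaced by \code{nc - (A*N + B)} for every
#'   well that has coefficients (others are left as-is but deflagged).
#' @export
correct_bias <- function(wells, bias) {
  wells$retained <- .retained(wells)
  key_w <- paste(wells$plate_id, wells$row, wells$col, sep = "\r")
  key_b <- paste(bias$plate_id, bias$row, bias$col, sep = "\r")
  idx <- match(key_w, key_b)
  have <- !is.na(idx)
  wells$nc[have] <- wells$nc[have] -
    (bias$A[idx[have]] * wells$cell_count[have] + bias$B[idx[have]])
  wells$retained <- wells$retained & have
  wells
}

#' Final cross-plate standardization
#'
#' Re-centres the corrected values to mean 0 (see the package vignette: only
#' the SD = 1 step is dictated by the procedure; the centring is a package
#' choice) and scales to sample SD 1 over all retained library wells.
#'
#' @param wells corrected well data.frame with column \code{nc}.
#' @return data.frame of normalized scores: sirna_id, plate_id, row, col, z,
#'   rank (1 = strongest decrease), retained, is_control. Rank is computed
#'   over retained library wells only.
#' @export
global_standardize <- function(wells) {
  wells$retained <- .retained(wells)
  use <- wells$retained & !wells$is_control
  if (sum(use) < 2L) stop("fewer than two retained library wells")
  m <- mean(wells$nc[use])
  s <- stats::sd(wells$nc[use])
  if (!is.finite(s) || s < 1e-12) s <- 1   # degenerate all-equal input
  z <- (wells$nc - m) / s
  scores <- data.frame(sirna_id = wells$sirna_id,
                       plate_id = wells$plate_id,
                       row = wells$row, col = wells$col,
                       z = ifelse(wells$retained, z, NA_real_),
                       rank = NA_integer_,
                       retained = wells$retained,
                       is_control = wells$is_control,
                       stringsAsFactors = FALSE)
  scores$rank[use] <- rank(scores$z[use], ties.method = "first")
  scores
}

#' Run the full screen-normalization pipeline
#'
#' @param wells raw well data.frame or TSV path
#'   (see \code{\link{read_well_table}}).
#' @param min_cells low-count filter threshold (default 400).
#' @inheritParams fit_local_bias
#' @return an object of class \code{screen_scores}: list with elements
#'   \code{scores} (see \code{\link{global_standardize}}), \code{bias},
#'   \code{wells} (augmented input), and \code{qc} (per-plate means/SDs and
#'   dropped-well counts).
#' @export
normalize_screen <- function(wells, min_cells = 400, k_neighbors = 24,
                             robust_iters = 2,
                             kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  if (is.character(wells)) wells <- read_well_table(wells)
  wells <- validate_wells(wells)
  raw_qc <- do.call(rbind, lapply(split(wells, wells$plate_id), function(p) {
    lib <- p[!p$is_control, ]
    data.frame(plate_id = p$plate_id[1L], n_wells = nrow(p),
               raw_mean = mean(lib$nc_ratio), raw_sd = stats::sd(lib$nc_ratio))
  }))
  wells <- plate_standardize(wells)
  wells <- filter_low_count(wells, min_cells = min_cells)
  bias <- fit_local_bias(wells, k_neighbors = k_neighbors,
                         robust_iters = robust_iters, kernel = kernel)
  wells <- correct_bias(wells, bias)
  scores <- global_standardize(wells)
  qc <- list(
    plates = raw_qc,
    n_dropped_low_count = sum(!wells$retained),
    n_retained = sum(wells$retained),
    min_cells = min_cells, k_neighbors = k_neighbors,
    robust_iters = robust_iters, kernel = kernel)
  structure(list(scores = scores, bias = bias, wells = wells, qc = qc),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("<screen_scores> %d wells on %d plates; %d retained library wells\n",
              nrow(x$wells), length(unique(x$wells$plate_id)),
              sum(x$scores$retained & !x$scores$is_control)))
  cat(sprintf("  settings: min_cells=%d, k_neighbors=%d, robust_iters=%d, kernel=%s\n",
              x$qc$min_cells, x$qc$k_neighbors, x$qc$robust_iters, x$qc$kernel))
  invisible(x)
}

#' Summarize normalized screen scores
#' @param object a \code{screen_scores} object.
#' @param sigma_threshold SD cutoff used for the hit-count summary.
#' @param ... unused.
#' @method summary screen_scores
#' @export
summary.screen_scores <- function(object, sigma_threshold = 2.5, ...) {
  h <- call_hits(object, sigma_threshold = sigma_threshold)
  counts <- attr(h, "counts")
  cat(sprintf("retained library wells: %d\n",
              sum(object$scores$retained & !object$scores$is_control)))
  cat(sprintf("hits at %.1f SD: %d decrease, %d increase\n",
              sigma_threshold, counts[["decrease"]], counts[["increase"]]))
  invisible(counts)
}

#' Call screen hits at a standard-deviation cutoff
#'
#' A retained library siRNA is a "decrease" hit when z <= -threshold and an
#' "increase" hit when z >= +threshold; all others are "none".
#'
#' @param scores a \code{screen_scores} object or a scores data.frame with
#'   columns sirna_id, z (and optionally retained / is_control).
#' @param sigma_threshold SD cutoff (default 2.5).
#' @return data.frame (sirna_id, z, rank, group) for retained library wells,
#'   with an attribute \code{counts} = c(decrease=, increase=, none=).
#' @export
call_hits <- function(scores, sigma_threshold = 2.5) {
  if (inherits(scores, "screen_scores")) scores <- scores$scores
  keep <- rep(TRUE, nrow(scores))
  if ("retained" %in% names(scores)) keep <- keep & scores$retained
  if ("is_control" %in% names(scores)) keep <- keep & !scores$is_control
  df <- scores[keep, , drop = FALSE]
  group <- ifelse(df$z <= -sigma_threshold, "decrease",
                  ifelse(df$z >= sigma_threshold, "increase", "none"))
  out <- data.frame(sirna_id = df$sirna_id, z = df$z,
                    rank = if ("rank" %in% names(df)) df$rank else
                      rank(df$z, ties.method = "first"),
                    group = group, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(decrease = sum(group == "decrease"),
                           increase = sum(group == "increase"),
                           none = sum(group == "none"))
  attr(out, "sigma_threshold") <- sigma_threshold
  out
}

#' Classify validated hits by their measured receptor knockdown
#'
#' Applies the loose (> 25 percent on either receptor) off-target rule to a
#' per-siRNA knockdown table and additionally emits the strict (>= 40
#' percent) per-receptor hit lists used by the downstream sequence analyses.
#' An siRNA exceeding the strict threshold on both receptors appears in both
#' strict lists.
#'
#' @param knockdown data.frame with columns sirna_id, knockdown_r1,
#'   knockdown_r2 (fractions in [0,1]).
#' @param loose loose off-target threshold (default 0.25, strict >).
#' @param strict strict list threshold (default 0.40, inclusive >=).
#' @return list of class \code{receptor_classification}: \code{table}
#'   (data.frame sirna_id, knockdown_r1, knockdown_r2, class), \code{counts}
#'   (named vector over R1_only/R2_only/both/none), \code{strict_r1} and
#'   \code{strict_r2} (character id vectors).
#' @export
classify_receptor_effects <- function(knockdown, loose = 0.25, strict = 0.40) {
  stopifnot(all(c("sirna_id", "knockdown_r1", "knockdown_r2") %in% names(knockdown)))
  k1 <- knockdown$knockdown_r1
  k2 <- knockdown$knockdown_r2
  if (any(k1 < 0 | k1 > 1 | k2 < 0 | k2 > 1, na.rm = TRUE)) {
    stop("knockdown fractions must lie in [0,1]")
  }
  e1 <- k1 > loose
  e2 <- k2 > loose
  cls <- ifelse(e1 & e2, "both",
                ifelse(e1, "R1_only", ifelse(e2, "R2_only", "none")))
  tab <- data.frame(sirna_id = as.character(knockdown$sirna_id),
                    knockdown_r1 = k1, knockdown_r2 = k2, class = cls,
                    stringsAsFactors = FALSE)
  counts <- c(R1_only = sum(cls == "R1_only"), R2_only = sum(cls == "R2_only"),
              both = sum(cls == "both"), none = sum(cls == "none"))
  structure(list(table = tab, counts = counts,
                 strict_r1 = tab$sirna_id[k1 >= strict],
                 strict_r2 = tab$sirna_id[k2 >= strict],
                 loose = loose, strict = strict),
            class = "receptor_classification")
}

#' @export
print.receptor_classification <- function(x, ...) {
  cat(sprintf("<receptor_classification> %d siRNAs (loose > %.0f%%, strict >= %.0f%%)\n",
              nrow(x$table), 100 * x$loose, 100 * x$strict))
  print(x$counts)
  cat(sprintf("strict lists: %d (receptor 1), %d (receptor 2)\n",
              length(x$strict_r1), length(x$strict_r2)))
  invisible(x)
}
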