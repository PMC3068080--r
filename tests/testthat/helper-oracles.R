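# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately share no code with the package: the
# scanner tests every offset base by base, the Fisher oracle enumerates
# hypergeometric point masses from binomial coefficients.

ORACLE_COMP <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# brute-force seed-site scanner: returns list of (start, wobbles) per site
oracle_scan <- function(small_rna, target, seed_len = 7, max_wobbles = 0,
                        wobble_allowed = NULL) {
  r <- strsplit(small_rna, "")[[1L]]
  t <- strsplit(target, "")[[1L]]
  out <- list()
  n_off <- length(t) - seed_len + 1L
  if (n_off < 1L) return(out)
  for (i in 0:(n_off - 1L)) {                 # 0-based site start
    wob <- integer(0L)
    ok <- TRUE
    for (p in 2:(seed_len + 1L)) {            # strand seed positions
      tb <- t[i + (seed_len + 1L) - p + 1L]   # target base paired by p
      sb <- r[p]
      if (tb == "N" || sb == "N") { ok <- FALSE; break }
      if (tb == ORACLE_COMP[sb]) next
      wob_ok <- !is.null(wobble_allowed) &&
        any(wobble_allowed$position == p & wobble_allowed$base == sb) &&
        ((sb == "G" && tb == "U") || (sb == "U" && tb == "G"))
      if (wob_ok) wob <- c(wob, p) else { ok <- FALSE; break }
    }
    if (ok && length(wob) <= max_wobbles) {
      out[[length(out) + 1L]] <- list(start = i, wobbles = sort(wob))
    }
  }
  out
}

oracle_starts <- function(...) {
  vapply(oracle_scan(...), `[[`, numeric(1L), "start")
}

# two-sided Fisher p by direct enumeration with binomial coefficients
oracle_fisher <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  N <- n1 + n2
  denom <- choose(N, K)
  support <- max(0L, K - n2):min(K, n1)
  probs <- choose(n1, support) * choose(n2, K - support) / denom
  p_obs <- choose(n1, k1) * choose(n2, K - k1) / denom
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# direct centered truncated windowed mean
oracle_moving_mean <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - (w - 1L) %/% 2L)
    hi <- min(n, i + w %/% 2L)
    mean(x[lo:hi])
  }, numeric(1L))
}

# small fully-controlled plate for normalization tests: a single plate whose
# N:C values follow a planted linear cell-count law plus optional extras
make_linear_plate <- function(R = 8, C = 10, A = 0.004, B = 0.2,
                              counts = NULL, plate_id = "P01") {
  grid <- expand.grid(row = seq_len(R), col = seq_len(C))
  if (is.null(counts)) {
    counts <- 400 + ((grid$row * 13 + grid$col * 7) %% 37) * 10
  }
  data.frame(plate_id = plate_id, row = grid$row, col = grid$col,
             sirna_id = sprintf("s%03d", seq_len(nrow(grid))),
             cell_count = counts, nc_ratio = A * counts + B,
             is_control = FALSE, stringsAsFactors = FALSE)
}
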