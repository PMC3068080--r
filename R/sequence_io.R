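# Sequence and table I/O shared by all pipeline stages.
#
# Conventions used throughout the package:
#   * internal alphabet is RNA {A,C,G,U}; DNA input (T) is converted on read
#   * internal coordinates are 0-based half-open; user-facing coordinates
#     (region specs, output tables) are 1-based inclusive
#   * the ambiguity code N never pairs with anything, including N

RNA_BASES <- c("A", "C", "G", "U")

.COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and converts T to U. Any residual character outside
#' \{A,C,G,U,N\} is an error naming the first offending position.
#'
#' @param seq character vector of nucleotide strings (DNA or RNA).
#' @return character vector over \{A,C,G,U,N\}.
#' @export
normalize_rna <- function(seq) {
  out <- chartr("tT", "uU", seq)
  out <- toupper(out)
  bad <- regexpr("[^ACGUN]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid nucleotide '%s' at position %d of sequence %d",
                 substr(out[i], bad[i], bad[i]), bad[i], i))
  }
  out
}

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement read 3'->5', returned 5'->3'. N maps to N.
#'
#' @param seq character vector of RNA strings over \{A,C,G,U,N\}
#'   (T accepted and treated as U).
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AAAGUGC")  # "GCACUUU"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_rna(seq)
  vapply(seq, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
    paste(.COMPLEMENT[ch], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Complement a vector of single RNA bases (no reversal)
#' @param bases character vector of single bases over \{A,C,G,U,N\}.
#' @return complementary bases; N stays N.
#' @keywords internal
complement_bases <- function(bases) {
  unname(.COMPLEMENT[bases])
}

# ---------------------------------------------------------------------------
# Transcript records

#' Construct a transcript record with region annotation
#'
#' @param transcript_id transcript identifier.
#' @param sequence nucleotide string (DNA or RNA; stored as RNA).
#' @param utr5,orf,utr3 1-based inclusive c(start, end) ranges, or NULL for an
#'   absent region. Stored internally as 0-based half-open intervals.
#' @param conservation optional numeric vector in [0,1], one score per base.
#' @return an object of class \code{transcript_record}.
#' @export
transcript_record <- function(transcript_id, sequence,
                              utr5 = NULL, orf = NULL, utr3 = NULL,
                              conservation = NULL) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  conv <- function(rng, name) {
    if (is.null(rng) || (length(rng) == 1L && is.na(rng))) return(NULL)
    if (length(rng) != 2L || any(is.na(rng))) {
      stop(sprintf("region '%s' must be c(start, end), 1-based inclusive", name))
    }
    if (rng[1L] < 1L || rng[2L] > n || rng[1L] > rng[2L]) {
      stop(sprintf("region '%s' [%d,%d] outside sequence of length %d (%s)",
                   name, rng[1L], rng[2L], n, transcript_id))
    }
    c(start = rng[1L] - 1L, end = rng[2L])   # 0-based half-open
  }
  rec <- structure(list(
    transcript_id = as.character(transcript_id),
    sequence = sequence,
    utr5 = conv(utr5, "utr5"),
    orf = conv(orf, "orf"),
    utr3 = conv(utr3, "utr3"),
    conservation = NULL
  ), class = "transcript_record")
  # ordering: utr5 <= orf <= utr3 where present
  ends <- list(rec$utr5, rec$orf, rec$utr3)
  present <- !vapply(ends, is.null, logical(1L))
  if (sum(present) > 1L) {
    pp <- ends[present]
    for (i in seq_len(length(pp) - 1L)) {
      if (pp[[i]]["end"] > pp[[i + 1L]]["start"] &&
          !(pp[[i]]["start"] <= pp[[i + 1L]]["start"])) {
        stop(sprintf("regions of '%s' are out of order", transcript_id))
      }
    }
    starts <- vapply(pp, `[`, numeric(1L), "start")
    if (is.unsorted(starts)) {
      stop(sprintf("regions of '%s' are out of order", transcript_id))
    }
  }
  if (!is.null(conservation)) rec <- set_conservation(rec, conservation)
  rec
}

#' @export
print.transcript_record <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "-" else sprintf("%d-%d", r["start"] + 1L, r["end"])
  cat(sprintf("<transcript_record> %s (%d nt)\n", x$transcript_id, nchar(x$sequence)))
  cat(sprintf("  5'UTR %s | ORF %s | 3'UTR %s | conservation: %s\n",
              fmt(x$utr5), fmt(x$orf), fmt(x$utr3),
              if (is.null(x$conservation)) "none" else "attached"))
  invisible(x)
}

#' Attach a per-base conservation track to a transcript record
#' @param tx a \code{transcript_record}.
#' @param scores numeric vector in [0,1] of length \code{nchar(tx$sequence)}.
#' @return the updated record.
#' @export
set_conservation <- function(tx, scores) {
  stopifnot(inherits(tx, "transcript_record"))
  if (length(scores) != nchar(tx$sequence)) {
    stop(sprintf("conservation length %d != sequence length %d (%s)",
                 length(scores), nchar(tx$sequence), tx$transcript_id))
  }
  if (any(!is.na(scores) & (scores < 0 | scores > 1))) {
    stop("conservation scores must lie in [0,1]")
  }
  tx$conservation <- as.numeric(scores)
  tx
}

#' Extract a region's sequence from a transcript record
#' @param tx a \code{transcript_record}.
#' @param region one of "utr5", "orf", "utr3", or "full".
#' @return RNA string (empty string if the region is absent).
#' @export
region_sequence <- function(tx, region = c("utr3", "orf", "utr5", "full")) {
  region <- match.arg(region)
  if (region == "full") return(tx$sequence)
  r <- tx[[region]]
  if (is.null(r)) return("")
  substr(tx$sequence, r["start"] + 1L, r["end"])
}

#' Extract a region's conservation scores
#' @inheritParams region_sequence
#' @return numeric vector (length 0 if region absent or no track attached).
#' @export
region_conservation <- function(tx, region = c("utr3", "orf", "utr5", "full")) {
  region <- match.arg(region)
  if (is.null(tx$conservation)) return(numeric(0L))
  if (region == "full") return(tx$conservation)
  r <- tx[[region]]
  if (is.null(r)) return(numeric(0L))
  tx$conservation[(r["start"] + 1L):r["end"]]
}

#' Read transcripts from FASTA plus a region specification
#'
#' The region spec uses the 1-based inclusive coordinate style of sequence
#' databases (e.g. an ORF "383-2161" and a 3'UTR "2108-4680" on a 4680-nt
#' record). Missing values are written ".".
#'
#' @param fasta_path path to a (possibly mixed-case, DNA or RNA) FASTA file.
#' @param region_spec a data.frame with columns transcript_id, utr5_start,
#'   utr5_end, orf_start, orf_end, utr3_start, utr3_end (1-based inclusive,
#'   NA/"." for absent regions) or the path of a TSV with those columns.
#' @return named list of \code{transcript_record}s.
#' @export
read_transcript_fasta <- function(fasta_path, region_spec) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.character(region_spec) && length(region_spec) == 1L) {
    region_spec <- read_tsv_checked(region_spec,
      c("transcript_id", "utr5_start", "utr5_end", "orf_start", "orf_end",
        "utr3_start", "utr3_end"))
  }
  stopifnot(is.data.frame(region_spec))
  rng <- function(row, what) {
    s <- suppressWarnings(as.integer(row[[paste0(what, "_start")]]))
    e <- suppressWarnings(as.integer(row[[paste0(what, "_end")]]))
    if (is.na(s) && is.na(e)) return(NULL)
    if (is.na(s) || is.na(e)) stop(sprintf("half-specified %s range", what))
    c(s, e)
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    j <- which(region_spec$transcript_id == ids[i])
    if (length(j) == 0L) {
      stop(sprintf("transcript '%s' missing from the region specification", ids[i]))
    }
    row <- region_spec[j[1L], , drop = FALSE]
    out[[i]] <- transcript_record(
      ids[i], as.character(seqs[[i]]),
      utr5 = rng(row, "utr5"), orf = rng(row, "orf"), utr3 = rng(row, "utr3"))
  }
  names(out) <- ids
  out
}

#' Write transcripts to FASTA and a matching region-spec TSV
#' @param transcripts list of \code{transcript_record}s.
#' @param fasta_path,regions_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcript_fasta <- function(transcripts, fasta_path, regions_path) {
  seqs <- Biostrings::BStringSet(vapply(transcripts, `[[`, character(1L), "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, character(1L), "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  one <- function(tx, what) {
    r <- tx[[what]]
    if (is.null(r)) c(NA_integer_, NA_integer_) else c(r["start"] + 1L, r["end"])
  }
  spec <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(transcript_id = tx$transcript_id,
               utr5_start = one(tx, "utr5")[1L], utr5_end = one(tx, "utr5")[2L],
               orf_start = one(tx, "orf")[1L], orf_end = one(tx, "orf")[2L],
               utr3_start = one(tx, "utr3")[1L], utr3_end = one(tx, "utr3")[2L])
  }))
  write_tsv(spec, regions_path)
  invisible(c(fasta_path, regions_path))
}

# ---------------------------------------------------------------------------
# Tabular I/O

#' @keywords internal
read_tsv_checked <- function(path, required_cols) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = ".", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(df), required_cols)
  if (length(unknown)) {
    stop(sprintf("%s: unknown column(s): %s", path, paste(unknown, collapse = ", ")))
  }
  df
}

#' Write a data.frame as a TSV ("." for missing)
#' @param df data.frame.
#' @param path output path.
#' @param header_lines optional character vector of '#'-prefixed comment lines.
#' @return invisibly, \code{path}.
#' @export
write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read an siRNA duplex library table
#'
#' Expects a TSV with columns sirna_id, intended_gene, guide, passenger;
#' strands are 19-mers written 5'->3' (the fixed dTdT overhang is not part of
#' the table). T is normalized to U. Duplicate siRNA ids are an error.
#'
#' @param path TSV path.
#' @return data.frame with class \code{c("sirna_library","data.frame")}.
#' @export
read_library_table <- function(path) {
  df <- read_tsv_checked(path, c("sirna_id", "intended_gene", "guide", "passenger"))
  validate_library(df)
}

#' Validate (and alphabet-normalize) an siRNA library data.frame
#' @param df data.frame with sirna_id, intended_gene, guide, passenger.
#' @return the validated data.frame, classed \code{sirna_library}.
#' @export
validate_library <- function(df) {
  df$sirna_id <- as.character(df$sirna_id)
  dup <- df$sirna_id[duplicated(df$sirna_id)]
  if (length(dup)) {
    stop(sprintf("duplicate sirna_id: %s", paste(unique(dup), collapse = ", ")))
  }
  df$guide <- normalize_rna(df$guide)
  df$passenger <- normalize_rna(df$passenger)
  badlen <- nchar(df$guide) != 19L | nchar(df$passenger) != 19L
  if (any(badlen)) {
    stop(sprintf("strands must be 19 nt; offending sirna_id: %s",
                 paste(df$sirna_id[badlen], collapse = ", ")))
  }
  class(df) <- c("sirna_library", "data.frame")
  df
}

#' Write an siRNA library table
#' @param df an \code{sirna_library} data.frame.
#' @param path output TSV path.
#' @export
write_library_table <- function(df, path) {
  write_tsv(df[, c("sirna_id", "intended_gene", "guide", "passenger")], path)
}

#' Read a raw screen well table
#'
#' Expects a TSV with columns plate_id, row, col, sirna_id, cell_count,
#' nc_ratio and optionally is_control (0/1). (plate, row, col) must be unique
#' and nc_ratio positive.
#'
#' @param path TSV path.
#' @return data.frame of wells.
#' @export
read_well_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plate_id", "row", "col", "sirna_id", "cell_count", "nc_ratio")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  extra <- setdiff(names(df), c(need, "is_control"))
  if (length(extra)) {
    stop(sprintf("%s: unknown column(s): %s", path, paste(extra, collapse = ", ")))
  }
  validate_wells(df)
}

#' Validate a well data.frame
#' @param df wells data.frame (plate_id,row,col,sirna_id,cell_count,nc_ratio
#'   and optional is_control).
#' @return validated data.frame.
#' @export
validate_wells <- function(df) {
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  df$is_control <- as.logical(df$is_control)
  key <- paste(df$plate_id, df$row, df$col, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (plate_id, row, col) well positions")
  if (any(df$nc_ratio <= 0, na.rm = TRUE)) stop("nc_ratio must be positive")
  if (any(df$cell_count < 0, na.rm = TRUE)) stop("cell_count must be >= 0")
  df
}

#' Read a bedGraph-like conservation track
#'
#' Four columns, no header: transcript_id, start (0-based), end (half-open),
#' score in [0,1]. Returns one numeric vector per transcript; bases not
#' covered by any interval get NA.
#'
#' @param path track path.
#' @param transcripts named list of \code{transcript_record}s the track
#'   applies to; used for lengths and to attach the scores.
#' @return the list of transcripts with conservation attached.
#' @export
read_conservation_track <- function(path, transcripts) {
  bg <- utils::read.delim(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(bg) < 4L) stop("conservation track needs 4 columns")
  names(bg)[1:4] <- c("transcript_id", "start", "end", "score")
  for (id in names(transcripts)) {
    n <- nchar(transcripts[[id]]$sequence)
    sc <- rep(NA_real_, n)
    rows <- bg[bg$transcript_id == id, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      s <- rows$start[i]; e <- rows$end[i]
      if (s < 0L || e > n || s >= e) {
        stop(sprintf("conservation interval [%d,%d) outside '%s'", s, e, id))
      }
      sc[(s + 1L):e] <- rows$score[i]
    }
    if (nrow(rows)) transcripts[[id]] <- set_conservation(transcripts[[id]], sc)
  }
  transcripts
}

#' Write a block-constant conservation track in bedGraph-like form
#' @param transcripts named list of transcript records with conservation.
#' @param path output path.
#' @export
write_conservation_track <- function(transcripts, path) {
  rows <- list()
  for (tx in transcripts) {
    sc <- tx$conservation
    if (is.null(sc)) next
    r <- rle(ifelse(is.na(sc), -1, sc))
    e <- cumsum(r$lengths)
    s <- c(0L, e[-length(e)])
    keep <- r$values >= 0
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id, start = s[keep], end = e[keep],
        score = r$values[keep])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), score = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Packaged microRNA mimic sequences
#'
#' Returns the small set of synthetic miRNA mimic duplex strands bundled with
#' the package (miR-20a/-20a*, miR-34b/-34b*, miR-373/-373*), as used for
#' probing seed-mediated repression of the type II TGF-beta receptor. These
#' can be scanned with the same seed machinery as siRNA strands.
#'
#' @return data.frame with columns name, sequence.
#' @export
mirna_mimics <- function() {
  path <- system.file("extdata", "mirna_mimics.fasta", package = "rnaiscreen",
                      mustWork = TRUE)
  seqs <- Biostrings::readBStringSet(path)
  data.frame(name = sub("\\s.*$", "", names(seqs)),
             sequence = normalize_rna(as.character(seqs)),
             stringsAsFactors = FALSE)
}
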