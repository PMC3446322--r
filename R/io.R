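#' Read scaffolds from a FASTA file
#'
#' Sequences are passed through [normalize_sequence()], so the result is a
#' named character vector over A/C/G/T/N.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of normalized scaffold sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("empty sequence for record '%s' in %s",
                 ids[which(nchar(seqs) == 0L)[1L]], path))
  }
  names(seqs) <- NULL
  out <- normalize_sequence(seqs, id = ids)
  names(out) <- ids
  out
}

#' Write sequences to FASTA, wrapped at 60 columns
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Strip mate decorations: trailing /1 or /2, or a Casava-style " 1:..."/" 2:..."
# suffix (anything after the first whitespace is dropped first).
strip_mate_id <- function(id) {
  sub("/[12]$", "", sub("\\s.*$", "", id))
}

#' Read a pair of read files (FASTQ or FASTA)
#'
#' The two files must contain the mates of each pair in the same order.
#' Format is auto-detected from the first character of each file (`>` FASTA,
#' `@` FASTQ). Qualities, when present, are read but not used by the
#' algorithm; base-quality information plays no role in extension.
#'
#' @param file1,file2 Paths to the two mate files.
#' @return A data frame with columns `id` (mate-stripped), `seq1`, `seq2`.
#' @export
read_pairs <- function(file1, file2) {
  r1 <- .read_reads(file1)
  r2 <- .read_reads(file2)
  if (length(r1$seq) != length(r2$seq)) {
    stop(sprintf(
      "mate files disagree in record count: %s has %d, %s has %d",
      file1, length(r1$seq), file2, length(r2$seq)))
  }
  id1 <- strip_mate_id(r1$id)
  id2 <- strip_mate_id(r2$id)
  bad <- which(id1 != id2)
  if (length(bad) > 0L) {
    stop(sprintf("mate ids disagree at record %d: '%s' vs '%s'",
                 bad[1L], id1[bad[1L]], id2[bad[1L]]))
  }
  data.frame(id = id1, seq1 = r1$seq, seq2 = r2$seq)
}

.read_reads <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  set <- Biostrings::readBStringSet(path, format = fmt)
  if (length(set) == 0L) stop(sprintf("no reads in %s", path))
  seqs <- as.character(set)
  names(seqs) <- NULL
  list(id = names(set), seq = normalize_sequence(seqs, id = names(set)))
}

#' Parse a library description file
#'
#' One whitespace-separated line per library:
#' `name fileA fileB insert_size deviation orientation`.
#' `#` starts a comment. `orientation` is `FR` (paired-end, mates facing
#' inward) or `RF` (mate pair, facing outward; normalized to FR on input by
#' reverse-complementing both mates). Precomputed placements can be supplied
#' by writing `sam:<path>` in the fileA column and `-` as fileB.
#'
#' @param path Path to the library file.
#' @return A list of library records, each a list with fields `name`,
#'   `file1`, `file2`, `sam`, `insert_size`, `deviation`, `orientation`.
#' @export
parse_library_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  libs <- list()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(line))) next
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(f) != 6L) {
      stop(sprintf("%s line %d: expected 6 columns, got %d", path, ln,
                   length(f)))
    }
    ins <- suppressWarnings(as.numeric(f[4L]))
    dev <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(ins) || ins <= 0) {
      stop(sprintf("%s line %d: insert size '%s' is not a positive number",
                   path, ln, f[4L]))
    }
    if (is.na(dev) || dev < 0 || dev >= 1) {
      stop(sprintf("%s line %d: deviation '%s' must be a number in [0, 1)",
                   path, ln, f[5L]))
    }
    if (!f[6L] %in% c("FR", "RF")) {
      stop(sprintf("%s line %d: orientation must be FR or RF, got '%s'",
                   path, ln, f[6L]))
    }
    sam <- if (startsWith(f[2L], "sam:")) sub("^sam:", "", f[2L]) else NULL
    libs[[length(libs) + 1L]] <- list(
      name = f[1L],
      file1 = if (is.null(sam)) f[2L] else NA_character_,
      file2 = if (is.null(sam)) f[3L] else NA_character_,
      sam = sam,
      insert_size = ins, deviation = dev, orientation = f[6L])
  }
  libs
}

# Minimal plain-text SAM parser (header + the 11 mandatory fields). Only the
# fields the pipeline needs are kept; BAM/CRAM are out of scope.
.parse_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_ids <- vapply(strsplit(sq, "\t"), function(f) {
    sn <- f[startsWith(f, "SN:")]
    if (length(sn) == 0L) NA_character_ else sub("^SN:", "", sn[1L])
  }, character(1))
  if (length(body) == 0L) {
    return(list(sq = sq_ids[!is.na(sq_ids)],
                rec = data.frame(qname = character(), flag = integer(),
                                 rname = character(), pos = integer(),
                                 seq = character())))
  }
  f <- strsplit(body, "\t")
  bad <- which(lengths(f) < 11L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: SAM record %d has fewer than 11 fields", path, bad[1L]))
  }
  list(sq = sq_ids[!is.na(sq_ids)],
       rec = data.frame(
         qname = vapply(f, `[`, "", 1L),
         flag = as.integer(vapply(f, `[`, "", 2L)),
         rname = vapply(f, `[`, "", 3L),
         pos = as.integer(vapply(f, `[`, "", 4L)),
         seq = vapply(f, `[`, "", 10L)))
}

#' Read precomputed read placements from a SAM file
#'
#' Compatibility mode for users who prefer an external aligner over the
#' built-in anchorer. Mapped, non-secondary, non-supplementary records are
#' converted to placements; unmapped records are skipped. A sequence stored
#' reverse-complemented (FLAG 0x10) is restored to original read orientation
#' in the `seq` column.
#'
#' @param path Path to a plain-text SAM file with `@SQ` headers.
#' @param scaffolds Named character vector of scaffolds the alignments refer
#'   to; an `@SQ` id absent from this set is a hard error.
#' @return A data frame with columns `read_id` (mate-stripped), `mate`
#'   (1, 2, or NA when FLAG carries no mate bit), `scaffold_id`, `start`
#'   (1-based leftmost base), `strand` (`+`/`-`), `seq`.
#' @export
read_sam_placements <- function(path, scaffolds) {
  rec <- .read_sam_records(path, scaffolds)
  rec[!is.na(rec$scaffold_id), , drop = FALSE]
}

# All primary SAM records, mapped or not; unmapped rows keep their sequence
# (needed to recruit the gap-side mate) with scaffold_id/start/strand NA.
.read_sam_records <- function(path, scaffolds) {
  sam <- .parse_sam(path)
  missing_sq <- setdiff(sam$sq, names(scaffolds))
  if (length(missing_sq) > 0L) {
    stop(sprintf("SAM @SQ id '%s' is not among the scaffolds", missing_sq[1L]))
  }
  r <- sam$rec
  keep <- bitwAnd(r$flag, 0x100) == 0L & bitwAnd(r$flag, 0x800) == 0L
  r <- r[keep, , drop = FALSE]
  unmapped <- bitwAnd(r$flag, 0x4) != 0L
  rev <- bitwAnd(r$flag, 0x10) != 0L
  seq <- normalize_sequence(r$seq)
  seq[rev] <- revcomp(seq[rev])
  mate <- ifelse(bitwAnd(r$flag, 0x40) != 0L, 1L,
                 ifelse(bitwAnd(r$flag, 0x80) != 0L, 2L, NA_integer_))
  out <- data.frame(read_id = strip_mate_id(r$qname), mate = mate,
                    scaffold_id = r$rname, start = r$pos,
                    strand = ifelse(rev, "-", "+"), seq = seq)
  out$scaffold_id[unmapped] <- NA_character_
  out$start[unmapped] <- NA_integer_
  out$strand[unmapped] <- NA_character_
  rownames(out) <- NULL
  out
}

#' N50 of a set of lengths
#'
#' The length L such that pieces of length >= L together contain at least
#' half of the summed length.
#'
#' @param lengths Integer vector of sequence lengths.
#' @return The N50, or 0 for an empty set.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Summary statistics of an assembly
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @return List with `scaffolds`, `gap_count`, `gap_length` (total Ns in
#'   internal and terminal N-runs), `n50`.
#' @export
assembly_summary <- function(scaffolds) {
  gaps <- lapply(unname(scaffolds), find_gaps)
  list(scaffolds = length(scaffolds),
       gap_count = sum(vapply(gaps, nrow, 0L)),
       gap_length = sum(vapply(gaps, function(g) sum(g$length), 0L)),
       n50 = n50(nchar(scaffolds)))
}

#' Write the per-gap TSV report
#'
#' One row per original gap with its coordinates, expected insertion length,
#' closure status and diagnostics, followed by `#`-prefixed summary lines
#' (scaffold count, gap count and total gap length before/after, N50
#' before/after).
#'
#' @param gaps Data frame of per-gap results (as produced by
#'   [fill_scaffold_gaps()], element `gaps`).
#' @param path Output path.
#' @param before,after Summaries from [assembly_summary()] for the input and
#'   final assemblies.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(gaps, path, before, after) {
  cols <- c("scaffold_id", "orig_start", "orig_end", "expected_len",
            "status", "filled_len", "remaining_n", "overlap_len", "reason")
  tab <- gaps[, cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(tab) > 0L) {
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  writeLines(c(
    sprintf("# scaffolds\t%d", before$scaffolds),
    sprintf("# gap_count_before\t%d", before$gap_count),
    sprintf("# gap_count_after\t%d", after$gap_count),
    sprintf("# gap_length_before\t%d", before$gap_length),
    sprintf("# gap_length_after\t%d", after$gap_length),
    sprintf("# n50_before\t%d", round(before$n50)),
    sprintf("# n50_after\t%d", round(after$n50))), con)
  invisible(path)
}
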