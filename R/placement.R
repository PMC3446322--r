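#' Build a seed index over scaffold sequences
#'
#' Hashes every N-free window of length `seed_len` on the forward strand of
#' every scaffold. The index backs the built-in read anchorer, which looks
#' up a read's first `seed_len` bases (and those of its reverse complement)
#' and then verifies candidates over the full read length.
#'
#' @param scaffolds Named character vector of normalized scaffolds.
#' @param seed_len Seed window length in nucleotides.
#' @return An object of class `"scaffold_index"`.
#' @export
build_index <- function(scaffolds, seed_len) {
  stopifnot(length(scaffolds) > 0L, !is.null(names(scaffolds)))
  seed_len <- as.integer(seed_len)
  if (all(nchar(scaffolds) < seed_len)) {
    stop(sprintf("seed_len (%d) exceeds the length of every scaffold",
                 seed_len))
  }
  all_scaf <- integer(0)
  all_pos <- integer(0)
  all_win <- character(0)
  for (si in seq_along(scaffolds)) {
    L <- nchar(scaffolds[[si]])
    if (L < seed_len) next
    starts <- seq_len(L - seed_len + 1L)
    win <- substring(scaffolds[[si]], starts, starts + seed_len - 1L)
    ok <- !grepl("N", win, fixed = TRUE)
    all_scaf <- c(all_scaf, rep.int(si, sum(ok)))
    all_pos <- c(all_pos, starts[ok])
    all_win <- c(all_win, win[ok])
  }
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(1L, length(all_win)))
  if (length(all_win) > 0L) {
    grp <- split(seq_along(all_win), all_win)
    list2env(grp, envir = env)
  }
  structure(list(env = env, scaf = all_scaf, pos = all_pos,
                 seed_len = seed_len,
                 ids = names(scaffolds),
                 seq_int = lapply(unname(scaffolds), utf8ToInt),
                 lens = unname(nchar(scaffolds))),
            class = "scaffold_index")
}

#' @export
print.scaffold_index <- function(x, ...) {
  cat(sprintf("scaffold index: %d scaffolds, %d seed windows (seed_len=%d)\n",
              length(x$ids), length(x$pos), x$seed_len))
  invisible(x)
}

# Core anchoring routine. Looks up candidate loci through the seed index on
# both strands, verifies each candidate by full-length ungapped comparison
# within the mismatch budget, and demands a unique best-scoring locus.
# Returns list(scaf, start, strand, mismatches) or NULL.
.place <- function(read, rc, index, max_mismatch_frac) {
  len <- nchar(read)
  if (len < index$seed_len) return(NULL)
  budget <- floor(max_mismatch_frac * len)
  fwd_hits <- get0(substr(read, 1L, index$seed_len), envir = index$env,
                   ifnotfound = NULL)
  rc_hits <- get0(substr(rc, 1L, index$seed_len), envir = index$env,
                  ifnotfound = NULL)
  if (is.null(fwd_hits) && is.null(rc_hits)) return(NULL)
  best <- NULL
  best_mm <- budget + 1L
  tie <- FALSE
  read_int <- NULL
  rc_int <- NULL
  for (strand in c("+", "-")) {
    hits <- if (strand == "+") fwd_hits else rc_hits
    if (is.null(hits)) next
    qi <- if (strand == "+") {
      if (is.null(read_int)) read_int <- utf8ToInt(read)
      read_int
    } else {
      if (is.null(rc_int)) rc_int <- utf8ToInt(rc)
      rc_int
    }
    for (h in hits) {
      si <- index$scaf[h]
      p <- index$pos[h]
      if (p + len - 1L > index$lens[si]) next
      mm <- sum(index$seq_int[[si]][p:(p + len - 1L)] != qi)
      if (mm > budget) next
      if (mm < best_mm) {
        best <- list(scaf = si, start = p, strand = strand, mismatches = mm)
        best_mm <- mm
        tie <- FALSE
      } else if (mm == best_mm &&
                 !(identical(best$scaf, si) && best$start == p &&
                   best$strand == strand)) {
        tie <- TRUE
      }
    }
  }
  if (is.null(best) || tie) return(NULL)
  best
}

#' Anchor a single read on the scaffolds
#'
#' Candidate loci are found by exact lookup of the read's first `seed_len`
#' bases (forward and reverse complement) in the index and verified by
#' full-length ungapped comparison allowing at most
#' `floor(max_mismatch_frac * read_length)` mismatches. The placement must
#' be unique: a best score shared by two distinct loci yields no placement.
#'
#' @param read Read sequence (A/C/G/T/N).
#' @param index A [build_index()] result.
#' @param params A [gap_params()] object (uses `max_mismatch_frac`; the
#'   index carries its own `seed_len`).
#' @return A one-row data frame (`scaffold_id`, `start`, `strand`,
#'   `mismatches`) or `NULL` when the read cannot be placed uniquely.
#' @export
place_read <- function(read, index, params = gap_params()) {
  hit <- .place(read, revcomp(read), index, params$max_mismatch_frac)
  if (is.null(hit)) return(NULL)
  data.frame(scaffold_id = index$ids[hit$scaf], start = hit$start,
             strand = hit$strand, mismatches = hit$mismatches)
}

#' Predicted scaffold window for the unanchored mate
#'
#' Given one anchored mate of an FR pair, the insert size `I` (5'-to-5'
#' outer distance) and its allowed fractional deviation `v` bound the
#' scaffold positions the other mate can cover:
#' an anchor on `+` at leftmost base `s` predicts the mate within
#' `[s + (1-v)I - mate_len + 1, s + (1+v)I - 1]` (1-based, inclusive), and
#' an anchor on `-` the mirrored window left of its 5' end. The window is
#' clipped to the scaffold; an empty clipped window discards the pair.
#'
#' @param start 1-based leftmost scaffold base of the anchored mate.
#' @param strand `"+"` or `"-"`.
#' @param anchor_len,mate_len Read lengths in nucleotides.
#' @param insert_size,deviation Library insert mean and fractional
#'   deviation.
#' @param scaffold_len Length of the anchored scaffold.
#' @return `c(lo, hi)` in 1-based inclusive coordinates, or `NULL` when the
#'   clipped window is empty.
#' @export
mate_window <- function(start, strand, anchor_len, mate_len,
                        insert_size, deviation, scaffold_len) {
  I <- insert_size
  v <- deviation
  if (strand == "+") {
    lo <- start + (1 - v) * I - mate_len
    hi <- start - 1 + (1 + v) * I
  } else {
    e <- start + anchor_len  # one past the anchor's 5' (rightmost) base
    lo <- e - (1 + v) * I
    hi <- e - 1 - (1 - v) * I + mate_len
  }
  lo <- max(1, floor(lo))
  hi <- min(scaffold_len, ceiling(hi))
  if (lo > hi) return(NULL)
  c(lo, hi)
}

#' Recruit gap-spanning mates from paired reads
#'
#' For each pair, mate 1 is anchored first; if it cannot be placed uniquely,
#' mate 2 is tried and the roles swap. The unanchored mate is recruited to
#' every gap on the anchored scaffold whose interval overlaps the pair's
#' [mate_window()] by at least one base. Pairs whose anchor is ambiguous, or
#' whose window misses every gap, contribute nothing. Mate-pair (RF)
#' libraries must already be normalized to FR (both mates
#' reverse-complemented), as [fill_scaffold_gaps()] does on input.
#'
#' @param pairs Data frame from [read_pairs()].
#' @param index A [build_index()] result over the (trimmed) scaffolds.
#' @param gaps Data frame of fillable gaps: columns `gap_id`, `scaffold_id`,
#'   `start`, `end` (1-based inclusive, post-trim intervals).
#' @param lib Library record (uses `insert_size` and `deviation`).
#' @param params A [gap_params()] object.
#' @return Named list mapping `gap_id` to a character vector of recruited
#'   mate sequences (named by read id, sorted by read id for determinism).
#' @export
recruit_pairs <- function(pairs, index, gaps, lib, params = gap_params()) {
  out <- .empty_gapreadset(gaps$gap_id)
  if (nrow(pairs) == 0L || nrow(gaps) == 0L) return(out)
  rc1 <- revcomp(pairs$seq1)
  rc2 <- revcomp(pairs$seq2)
  gap_by_scaf <- split(seq_len(nrow(gaps)), gaps$scaffold_id)
  acc_gap <- vector("list", nrow(pairs))
  acc_seq <- vector("list", nrow(pairs))
  for (pi in seq_len(nrow(pairs))) {
    hit <- .place(pairs$seq1[pi], rc1[pi], index, params$max_mismatch_frac)
    if (!is.null(hit)) {
      anchor_seq <- pairs$seq1[pi]
      recruit <- pairs$seq2[pi]
    } else {
      hit <- .place(pairs$seq2[pi], rc2[pi], index, params$max_mismatch_frac)
      if (is.null(hit)) next
      anchor_seq <- pairs$seq2[pi]
      recruit <- pairs$seq1[pi]
    }
    gidx <- .window_gaps(hit, nchar(anchor_seq), nchar(recruit),
                         index$ids[hit$scaf], lib, index$lens[hit$scaf],
                         gap_by_scaf, gaps)
    if (length(gidx) > 0L) {
      acc_gap[[pi]] <- gidx
      acc_seq[[pi]] <- recruit
    }
  }
  .collect_gapreadset(out, acc_gap, acc_seq, pairs$id)
}

.empty_gapreadset <- function(gap_ids) {
  out <- rep(list(character(0)), length(gap_ids))
  names(out) <- gap_ids
  out
}

.window_gaps <- function(hit, anchor_len, mate_len, scaffold_id, lib,
                         scaffold_len, gap_by_scaf, gaps) {
  w <- mate_window(hit$start, hit$strand, anchor_len, mate_len,
                   lib$insert_size, lib$deviation, scaffold_len)
  if (is.null(w)) return(integer(0))
  cand <- gap_by_scaf[[scaffold_id]]
  if (is.null(cand)) return(integer(0))
  cand[gaps$start[cand] <= w[2L] & gaps$end[cand] >= w[1L]]
}

.collect_gapreadset <- function(out, acc_gap, acc_seq, ids) {
  used <- which(!vapply(acc_gap, is.null, TRUE))
  if (length(used) == 0L) return(out)
  gidx <- unlist(acc_gap[used], use.names = FALSE)
  seqs <- rep(unlist(acc_seq[used], use.names = FALSE),
              lengths(acc_gap[used]))
  rid <- rep(ids[used], lengths(acc_gap[used]))
  names(seqs) <- rid
  for (g in unique(gidx)) {
    sel <- gidx == g
    v <- seqs[sel]
    out[[names(out)[g]]] <- v[order(names(v))]
  }
  out
}

#' Recruit gap-spanning mates from precomputed SAM placements
#'
#' External-aligner mode: SAM placements stand in for the built-in anchorer.
#' For each read id, the mapped mate (mate 1 preferred when both are mapped)
#' acts as anchor and the other mate's sequence is recruited through the same
#' window logic as [recruit_pairs()]. Pass the full primary-record table
#' (mapped and unmapped rows) so that the gap-side mate's sequence is
#' available even when the aligner left it unmapped.
#'
#' @param placements Data frame with columns `read_id`, `mate`,
#'   `scaffold_id` (NA when unmapped), `start`, `strand`, `seq` — the shape
#'   produced by the SAM reader behind [read_sam_placements()].
#' @param scaffolds Named character vector of scaffolds.
#' @param gaps Data frame of fillable gaps (see [recruit_pairs()]).
#' @param lib Library record.
#' @param params A [gap_params()] object.
#' @return Named list mapping `gap_id` to recruited sequences.
#' @export
recruit_sam <- function(placements, scaffolds, gaps, lib,
                        params = gap_params()) {
  out <- .empty_gapreadset(gaps$gap_id)
  if (nrow(placements) == 0L || nrow(gaps) == 0L) return(out)
  gap_by_scaf <- split(seq_len(nrow(gaps)), gaps$scaffold_id)
  scaf_len <- nchar(scaffolds)
  byid <- split(seq_len(nrow(placements)), placements$read_id)
  acc_gap <- vector("list", length(byid))
  acc_seq <- vector("list", length(byid))
  pid <- names(byid)
  for (bi in seq_along(byid)) {
    rows <- byid[[bi]]
    mates <- placements$mate[rows]
    r1 <- rows[which(mates == 1L)]
    r2 <- rows[which(mates == 2L)]
    if (length(r1) != 1L || length(r2) != 1L) next
    mapped1 <- !is.na(placements$scaffold_id[r1])
    anchor <- if (mapped1) r1 else r2
    other <- if (mapped1) r2 else r1
    if (is.na(placements$scaffold_id[anchor])) next
    hit <- list(scaf = NA_integer_, start = placements$start[anchor],
                strand = placements$strand[anchor])
    sid <- placements$scaffold_id[anchor]
    gidx <- .window_gaps(hit, nchar(placements$seq[anchor]),
                         nchar(placements$seq[other]), sid, lib,
                         scaf_len[[sid]], gap_by_scaf, gaps)
    if (length(gidx) > 0L) {
      acc_gap[[bi]] <- gidx
      acc_seq[[bi]] <- placements$seq[other]
    }
  }
  .collect_gapreadset(out, acc_gap, acc_seq, pid)
}
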