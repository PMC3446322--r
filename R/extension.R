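#' Trim gap edges before filling
#'
#' Contig ends flanking a gap often carry assembly errors, so up to `t`
#' bases on each side of every internal gap are masked to N before filling.
#' The actual trims are limited by flank availability: a flank shared with a
#' neighbouring gap yields at most half its length to each side, and a flank
#' bounded by a scaffold end can be consumed entirely. The expected
#' insertion length of a gap is its original N-count plus the bases actually
#' trimmed, so a size-exact closure conserves scaffold length.
#'
#' @param seq A single normalized scaffold sequence.
#' @param gaps Data frame from [find_gaps()] for `seq`.
#' @param t Maximum trim per side, nucleotides.
#' @return List with `seq` (trimmed scaffold, same length) and `gaps` (one
#'   row per gap: `orig_start`, `orig_end`, `start`, `end` of the enlarged
#'   interval, `tl`, `tr`, `expected_len`, `terminal`).
#' @export
trim_gap_edges <- function(seq, gaps, t) {
  t <- as.integer(t)
  ng <- nrow(gaps)
  rec <- data.frame(orig_start = gaps$start, orig_end = gaps$end,
                    start = gaps$start, end = gaps$end,
                    tl = integer(ng), tr = integer(ng),
                    expected_len = gaps$length, terminal = gaps$terminal)
  if (ng == 0L || t == 0L) return(list(seq = seq, gaps = rec))
  L <- nchar(seq)
  chars <- NULL
  for (g in seq_len(ng)) {
    if (gaps$terminal[g]) next
    # left flank runs from the previous gap (or scaffold start) to this gap
    prev_end <- if (g > 1L) gaps$end[g - 1L] else 0L
    fl <- gaps$start[g] - prev_end - 1L
    # a flank shared with a neighbouring gap is split between the two and
    # never fully consumed, so distinct gaps stay distinct N-runs
    tl <- if (g > 1L) min(t, (fl - 1L) %/% 2L) else min(t, fl)
    next_start <- if (g < ng) gaps$start[g + 1L] else L + 1L
    fr <- next_start - gaps$end[g] - 1L
    tr <- if (g < ng) min(t, (fr - 1L) %/% 2L) else min(t, fr)
    rec$tl[g] <- tl
    rec$tr[g] <- tr
    rec$start[g] <- gaps$start[g] - tl
    rec$end[g] <- gaps$end[g] + tr
    rec$expected_len[g] <- gaps$length[g] + tl + tr
    if (tl + tr > 0L) {
      if (is.null(chars)) chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      chars[rec$start[g]:rec$end[g]] <- "N"
    }
  }
  list(seq = if (is.null(chars)) seq else paste(chars, collapse = ""),
       gaps = rec)
}

.BASES <- c("A", "C", "G", "T")

.kmerize <- function(reads, k) {
  both <- c(reads, revcomp(reads))
  both <- both[nchar(both) >= k]
  if (length(both) == 0L) return(character(0))
  km <- unlist(lapply(both, function(s) {
    starts <- seq_len(nchar(s) - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  km[!grepl("N", km, fixed = TRUE)]
}

#' Build a k-mer multiset from recruited reads
#'
#' Every length-`k` window of every read and of its reverse complement is
#' counted; windows containing N and reads shorter than `k` contribute
#' nothing. Including both strands makes the store strand-symmetric, so it
#' does not matter which strand a recruited mate was sequenced from.
#'
#' @param reads Character vector of read sequences.
#' @param k K-mer size.
#' @return An object of class `"kmer_store"` (a mutable counted multiset).
#' @export
kmer_store <- function(reads, k) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  env <- new.env(hash = TRUE, parent = emptyenv())
  km <- .kmerize(reads, k)
  if (length(km) > 0L) {
    tb <- table(km)
    list2env(stats::setNames(as.list(as.integer(tb)), names(tb)), envir = env)
  }
  structure(list(env = env, k = k), class = "kmer_store")
}

#' Count of one k-mer in a store
#' @param store A [kmer_store()].
#' @param kmer K-mer string.
#' @return Integer count (0 when absent).
#' @export
store_count <- function(store, kmer) {
  get0(kmer, envir = store$env, ifnotfound = 0L)
}

#' Total k-mer count in a store
#' @param store A [kmer_store()].
#' @return Sum of all multiplicities.
#' @export
store_total <- function(store) {
  sum(unlist(as.list(store$env), use.names = FALSE))
}

#' @export
print.kmer_store <- function(x, ...) {
  cat(sprintf("k-mer store: k=%d, %d distinct k-mers, total count %d\n",
              x$k, length(ls(x$env)), store_total(x)))
  invisible(x)
}

#' One overhang-voting extension step
#'
#' Counts the k-mers `edge_mer + B` for each base B. The winning base is
#' incorporated only when its support is at least `o`, it holds at least a
#' fraction `r` of the total overhang support, and the maximum is unique.
#' On success all copies of the used k-mer are removed from the store
#' (consuming evidence prevents a small set of reads from being reused
#' indefinitely).
#'
#' @param edge_mer The current edge: the last `k - 1` bases of the growing
#'   flank, N-free.
#' @param store A [kmer_store()]; modified in place on success.
#' @param o Minimum overhang coverage.
#' @param r Majority voting ratio.
#' @return List with `base` (single character, or `NULL`) and `reason`
#'   (`"OK"`, `"NO_COVERAGE"` — winning support below `o` —, or
#'   `"AMBIGUOUS"` — tied maximum or voting ratio not reached).
#' @export
extend_step <- function(edge_mer, store, o, r) {
  counts <- unlist(mget(paste0(edge_mer, .BASES), envir = store$env,
                        ifnotfound = 0L), use.names = FALSE)
  total <- sum(counts)
  cbest <- max(counts)
  if (cbest < o) return(list(base = NULL, reason = "NO_COVERAGE"))
  if (sum(counts == cbest) > 1L || cbest / total < r) {
    return(list(base = NULL, reason = "AMBIGUOUS"))
  }
  b <- .BASES[which.max(counts)]
  rm(list = paste0(edge_mer, b), envir = store$env)
  list(base = b, reason = "OK")
}

#' Grow one gap edge by repeated overhang voting
#'
#' Appends one base at a time to `flank_suffix` via [extend_step()] on the
#' last `m` bases, until voting fails or the extension reaches `cap`. A
#' right-hand gap edge is handled by calling this on the reverse complement
#' of the right flank's prefix and reverse-complementing the result back.
#'
#' @param flank_suffix At least `m` N-free bases ending at the gap edge;
#'   otherwise the edge cannot seed extension and `""` with reason
#'   `"NO_COVERAGE"` is returned.
#' @param store A [kmer_store()]; consumed k-mers are removed in place.
#' @param params A [gap_params()].
#' @param cap Maximum extension length (the caller uses
#'   `expected_len + d`: anything longer necessarily fails the size test,
#'   and the cap bounds runtime on repetitive k-mer sets).
#' @return List with `ext` (extension string) and `reason` for stopping
#'   (`"NO_COVERAGE"`, `"AMBIGUOUS"`, or `"CAP"`).
#' @export
extend_edge <- function(flank_suffix, store, params = gap_params(), cap) {
  m <- params$m
  if (nchar(flank_suffix) < m ||
      grepl("N", substr(flank_suffix, nchar(flank_suffix) - m + 1L,
                        nchar(flank_suffix)), fixed = TRUE)) {
    return(list(ext = "", reason = "NO_COVERAGE"))
  }
  cur <- flank_suffix
  ext <- ""
  while (nchar(ext) < cap) {
    edge <- substr(cur, nchar(cur) - m + 1L, nchar(cur))
    st <- extend_step(edge, store, params$o, params$r)
    if (is.null(st$base)) return(list(ext = ext, reason = st$reason))
    ext <- paste0(ext, st$base)
    cur <- paste0(cur, st$base)
  }
  list(ext = ext, reason = "CAP")
}

#' Merge the two gap-edge extensions under the size constraint
#'
#' Searches all overlaps of length `x >= n` where a suffix of the left
#' extension equals a prefix of the right extension. Each overlap defines a
#' candidate insertion `L + R[(x+1):]` of length `|L| + |R| - x`; among the
#' candidates whose length differs from the expected gap length by at most
#' `d`, the one minimizing that difference wins (ties to the larger
#' overlap).
#'
#' @param left_full Left extension, scaffold orientation.
#' @param right_full Right extension, scaffold orientation (the sequence
#'   immediately left of the right flank).
#' @param expected_len Expected insertion length.
#' @param n Minimum merge overlap.
#' @param d Maximum allowed size difference.
#' @return List with `status` (`"CLOSED"` or `"OPEN"`), `inserted_seq`,
#'   `overlap_len`, and `reason` (`"OK"`, `"NO_OVERLAP"`, or
#'   `"SIZE_MISMATCH"` when overlaps exist but none satisfies the size
#'   test).
#' @export
try_close <- function(left_full, right_full, expected_len, n, d) {
  nl <- nchar(left_full)
  nr <- nchar(right_full)
  mx <- min(nl, nr)
  if (mx < n) {
    return(list(status = "OPEN", inserted_seq = NULL, overlap_len = NA_integer_,
                reason = "NO_OVERLAP"))
  }
  xs <- n:mx
  hit <- xs[substring(left_full, nl - xs + 1L, nl) ==
              substring(right_full, 1L, xs)]
  if (length(hit) == 0L) {
    return(list(status = "OPEN", inserted_seq = NULL, overlap_len = NA_integer_,
                reason = "NO_OVERLAP"))
  }
  lens <- nl + nr - hit
  diff <- abs(lens - expected_len)
  ok <- diff <= d
  if (!any(ok)) {
    return(list(status = "OPEN", inserted_seq = NULL, overlap_len = NA_integer_,
                reason = "SIZE_MISMATCH"))
  }
  cand <- hit[ok]
  cd <- diff[ok]
  best <- cand[cd == min(cd)]
  x <- max(best)
  list(status = "CLOSED",
       inserted_seq = paste0(left_full, substr(right_full, x + 1L, nr)),
       overlap_len = x, reason = "OK")
}

.comp1 <- function(b) chartr("ACGTN", "TGCAN", b)

#' Fill one gap from its recruited reads
#'
#' Builds the k-mer store, then alternates single [extend_step()] calls on
#' the left and right edges (right edge in reverse-complement space),
#' checking after every incorporated base whether the two extensions can be
#' merged by [try_close()]. When both edges are stuck the store is rebuilt
#' once from all reads — restoring consumed k-mers so that repeated context
#' can be traversed a second time — and extension resumes; when both edges
#' are stuck again the gap is left `PARTIAL` (some extension) or `OPEN`.
#'
#' @param left_flank The `m` (or fewer) bases immediately left of the
#'   enlarged gap interval.
#' @param right_flank The `m` (or fewer) bases immediately right of it.
#' @param expected_len Expected insertion length (N-count plus trimmed
#'   bases).
#' @param reads Character vector of recruited mate sequences.
#' @param params A [gap_params()].
#' @return A closure result: list with `status` (`"CLOSED"`, `"PARTIAL"`,
#'   `"OPEN"`), `inserted_seq` and `overlap_len` (CLOSED only), `left_ext`
#'   and `right_ext` (scaffold orientation), and `reason` (`"OK"`,
#'   `"NO_READS"`, `"NO_COVERAGE"`, `"AMBIGUOUS"`, `"NO_OVERLAP"`,
#'   `"SIZE_MISMATCH"`).
#' @export
fill_gap <- function(left_flank, right_flank, expected_len, reads,
                     params = gap_params()) {
  res <- list(status = "OPEN", inserted_seq = NULL, overlap_len = NA_integer_,
              left_ext = "", right_ext = "", reason = "NO_READS")
  if (length(reads) == 0L) return(res)
  m <- params$m
  cap <- expected_len + params$d
  seed_ok <- function(fl) nchar(fl) >= m && !grepl("N", fl, fixed = TRUE)
  l_ok <- seed_ok(left_flank)
  r_ok <- seed_ok(right_flank)
  if (!l_ok && !r_ok) {
    res$reason <- "NO_COVERAGE"
    return(res)
  }
  store <- kmer_store(reads, params$k)
  l_cur <- left_flank               # forward space, grows rightward
  r_cur <- revcomp(right_flank)     # rc space, grows rightward
  l_ext <- ""
  r_ext <- ""                       # scaffold orientation, grows leftward
  alive_l <- l_ok
  alive_r <- r_ok
  rebuilt <- FALSE
  last_reason <- "NO_COVERAGE"
  saw_size_mismatch <- FALSE
  turn <- "L"
  repeat {
    if (!alive_l && !alive_r) {
      if (!rebuilt) {
        store <- kmer_store(reads, params$k)
        rebuilt <- TRUE
        alive_l <- l_ok && nchar(l_ext) < cap
        alive_r <- r_ok && nchar(r_ext) < cap
        turn <- "L"
        if (!alive_l && !alive_r) break
      } else {
        break
      }
    }
    side <- turn
    turn <- if (turn == "L") "R" else "L"
    if (side == "L" && !alive_l) next
    if (side == "R" && !alive_r) next
    cur <- if (side == "L") l_cur else r_cur
    st <- extend_step(substr(cur, nchar(cur) - m + 1L, nchar(cur)),
                      store, params$o, params$r)
    if (is.null(st$base)) {
      last_reason <- st$reason
      if (side == "L") alive_l <- FALSE else alive_r <- FALSE
      next
    }
    if (side == "L") {
      l_cur <- paste0(l_cur, st$base)
      l_ext <- paste0(l_ext, st$base)
      if (nchar(l_ext) >= cap) alive_l <- FALSE
    } else {
      r_cur <- paste0(r_cur, st$base)
      r_ext <- paste0(.comp1(st$base), r_ext)
      if (nchar(r_ext) >= cap) alive_r <- FALSE
    }
    if (nchar(l_ext) >= params$n && nchar(r_ext) >= params$n) {
      cl <- try_close(l_ext, r_ext, expected_len, params$n, params$d)
      if (cl$status == "CLOSED") {
        return(list(status = "CLOSED", inserted_seq = cl$inserted_seq,
                    overlap_len = cl$overlap_len, left_ext = l_ext,
                    right_ext = r_ext, reason = "OK"))
      }
      # the merge window is transient: once both extensions overshoot each
      # other's origin no suffix/prefix overlap remains, so a size-rejected
      # overlap seen here is the gap's true failure mode
      if (cl$reason == "SIZE_MISMATCH") saw_size_mismatch <- TRUE
    }
  }
  final <- try_close(l_ext, r_ext, expected_len, params$n, params$d)
  if (final$status == "CLOSED") {
    return(list(status = "CLOSED", inserted_seq = final$inserted_seq,
                overlap_len = final$overlap_len, left_ext = l_ext,
                right_ext = r_ext, reason = "OK"))
  }
  reason <- if (final$reason == "SIZE_MISMATCH" || saw_size_mismatch)
              "SIZE_MISMATCH"
            else if (last_reason %in% c("NO_COVERAGE", "AMBIGUOUS")) last_reason
            else "NO_OVERLAP"
  list(status = if (nchar(l_ext) + nchar(r_ext) > 0L) "PARTIAL" else "OPEN",
       inserted_seq = NULL, overlap_len = NA_integer_,
       left_ext = l_ext, right_ext = r_ext, reason = reason)
}

#' Rewrite a scaffold with one gap's closure result
#'
#' A `CLOSED` gap's enlarged interval is replaced by the inserted sequence;
#' a `PARTIAL` gap keeps its extensions with the remaining expected length
#' as Ns in between (at least one N, so the gap stays detectable); an
#' `OPEN` gap is left untouched.
#'
#' @param seq Scaffold sequence.
#' @param start,end 1-based inclusive bounds of the (enlarged) gap interval.
#' @param expected_len Expected insertion length.
#' @param result A [fill_gap()] result.
#' @return List with `seq` (rewritten scaffold) and `new_len` (length of the
#'   replacement interval).
#' @export
apply_closure <- function(seq, start, end, expected_len, result) {
  rep_str <- switch(result$status,
    CLOSED = result$inserted_seq,
    PARTIAL = paste0(result$left_ext,
                     strrep("N", max(1L, expected_len -
                                       nchar(result$left_ext) -
                                       nchar(result$right_ext))),
                     result$right_ext),
    OPEN = substr(seq, start, end))
  list(seq = paste0(substr(seq, 1L, start - 1L), rep_str,
                    substr(seq, end + 1L, nchar(seq))),
       new_len = nchar(rep_str))
}
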