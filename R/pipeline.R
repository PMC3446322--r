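# Load a library's read data once: pairs (RF normalized to FR) and, for
# SAM-mode libraries, the primary records for iteration-1 placements.
.load_library <- function(lib, scaffolds) {
  if (!is.null(lib$sam)) {
    rec <- .read_sam_records(lib$sam, scaffolds)
    byid <- split(seq_len(nrow(rec)), rec$read_id)
    keep <- vapply(byid, function(rows) {
      sum(rec$mate[rows] == 1L, na.rm = TRUE) == 1L &&
        sum(rec$mate[rows] == 2L, na.rm = TRUE) == 1L
    }, TRUE)
    ids <- names(byid)[keep]
    s1 <- vapply(byid[keep], function(rows) {
      rec$seq[rows[which(rec$mate[rows] == 1L)]]
    }, "")
    s2 <- vapply(byid[keep], function(rows) {
      rec$seq[rows[which(rec$mate[rows] == 2L)]]
    }, "")
    pairs <- data.frame(id = ids, seq1 = unname(s1), seq2 = unname(s2))
  } else {
    pairs <- read_pairs(lib$file1, lib$file2)
    rec <- NULL
  }
  if (identical(lib$orientation, "RF") && nrow(pairs) > 0L) {
    pairs$seq1 <- revcomp(pairs$seq1)
    pairs$seq2 <- revcomp(pairs$seq2)
  }
  list(lib = lib, pairs = pairs, sam_records = rec)
}

# Initial gap table: one row per original gap, with the trimmed (enlarged)
# interval as the current working interval.
.init_gap_table <- function(assembly, t) {
  rows <- list()
  seqs <- assembly
  for (sid in names(assembly)) {
    g <- find_gaps(assembly[[sid]])
    tr <- trim_gap_edges(assembly[[sid]], g, t)
    seqs[[sid]] <- tr$seq
    if (nrow(tr$gaps) == 0L) next
    df <- tr$gaps
    df$scaffold_id <- sid
    rows[[length(rows) + 1L]] <- df
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(orig_start = integer(), orig_end = integer(),
               start = integer(), end = integer(), tl = integer(),
               tr = integer(), expected_len = integer(),
               terminal = logical(), scaffold_id = character())
  n <- nrow(tab)
  tab$gap_id <- if (n > 0L)
    sprintf("%s:%d-%d", tab$scaffold_id, tab$orig_start, tab$orig_end)
    else character(0)
  tab$cur_start <- tab$start
  tab$cur_end <- tab$end
  tab$status <- rep("OPEN", n)
  tab$reason <- ifelse(tab$terminal, "NO_READS", NA_character_)
  tab$overlap_len <- rep(NA_integer_, n)
  tab$filled_len <- rep(0L, n)
  tab$remaining_n <- tab$expected_len
  list(assembly = seqs, gaps = tab)
}

# The N-run currently inside a gap's working interval (iterations > 1 work
# on what is left after earlier rewrites).
.current_run <- function(seq, lo, hi) {
  sub <- substr(seq, lo, hi)
  mt <- regexpr("N+", sub)
  if (mt == -1L) return(NULL)
  s <- lo + as.integer(mt) - 1L
  c(s, s + attr(mt, "match.length") - 1L)
}

#' Run one global iteration: recruit, fill, rewrite
#'
#' @param assembly Named character vector of scaffolds (already edge-trimmed
#'   by [fill_scaffold_gaps()] on the first iteration).
#' @param libdata List of loaded libraries (internal shape; see
#'   [fill_scaffold_gaps()]).
#' @param gap_table Per-gap tracking table.
#' @param params A [gap_params()].
#' @param iteration Iteration number (SAM placements are only valid on the
#'   first, when coordinates still match the input scaffolds).
#' @return List with `assembly`, `gaps` (updated table), and `stats`
#'   (`closed`, `inserted_nt`, `remaining`, `gap_length`).
#' @keywords internal
#' @export
run_iteration <- function(assembly, libdata, gap_table, params,
                          iteration = 1L) {
  tab <- gap_table
  work <- which(!tab$terminal & tab$status != "CLOSED")
  runs <- vector("list", nrow(tab))
  for (w in work) {
    runs[[w]] <- .current_run(assembly[[tab$scaffold_id[w]]],
                              tab$cur_start[w], tab$cur_end[w])
    if (is.null(runs[[w]])) work <- setdiff(work, w)
  }
  stats <- list(closed = 0L, inserted_nt = 0L, remaining = 0L, gap_length = 0L)
  if (length(work) > 0L) {
    fillable <- data.frame(
      gap_id = tab$gap_id[work],
      scaffold_id = tab$scaffold_id[work],
      start = vapply(runs[work], `[`, 0L, 1L),
      end = vapply(runs[work], `[`, 0L, 2L))
    need_index <- any(vapply(libdata, function(ld) {
      is.null(ld$sam_records) || iteration > 1L
    }, TRUE))
    index <- if (need_index) build_index(assembly, params$seed_len) else NULL
    recruits <- .empty_gapreadset(fillable$gap_id)
    for (ld in libdata) {
      rs <- if (!is.null(ld$sam_records) && iteration == 1L) {
        recruit_sam(ld$sam_records, assembly, fillable, ld$lib, params)
      } else {
        recruit_pairs(ld$pairs, index, fillable, ld$lib, params)
      }
      for (g in names(recruits)) {
        if (length(rs[[g]]) > 0L) {
          v <- c(recruits[[g]], rs[[g]])
          recruits[[g]] <- v[order(names(v))]
        }
      }
    }
    results <- vector("list", nrow(fillable))
    for (fi in seq_len(nrow(fillable))) {
      sid <- fillable$scaffold_id[fi]
      seq <- assembly[[sid]]
      lo <- fillable$start[fi]
      hi <- fillable$end[fi]
      lf <- substr(seq, max(1L, lo - params$m), lo - 1L)
      rf <- substr(seq, hi + 1L, min(nchar(seq), hi + params$m))
      results[[fi]] <- fill_gap(lf, rf, hi - lo + 1L,
                                recruits[[fillable$gap_id[fi]]], params)
    }
    # rewrite scaffolds left to right, shifting all downstream gap rows
    for (sid in unique(fillable$scaffold_id)) {
      rows <- which(tab$scaffold_id == sid)
      rows <- rows[order(tab$cur_start[rows])]
      delta <- 0L
      for (ri in rows) {
        tab$cur_start[ri] <- tab$cur_start[ri] + delta
        tab$cur_end[ri] <- tab$cur_end[ri] + delta
        fi <- match(tab$gap_id[ri], fillable$gap_id)
        if (is.na(fi) || fillable$scaffold_id[fi] != sid) next
        res <- results[[fi]]
        lo <- fillable$start[fi] + delta
        hi <- fillable$end[fi] + delta
        expected <- hi - lo + 1L
        ap <- apply_closure(assembly[[sid]], lo, hi, expected, res)
        assembly[[sid]] <- ap$seq
        shift <- ap$new_len - expected
        # working interval now spans the full replacement
        tab$cur_start[ri] <- min(tab$cur_start[ri], lo)
        tab$cur_end[ri] <- max(tab$cur_end[ri] + shift, lo + ap$new_len - 1L)
        delta <- delta + shift
        stats$inserted_nt <- stats$inserted_nt +
          nchar(res$left_ext) + nchar(res$right_ext)
        if (res$status == "CLOSED") {
          stats$closed <- stats$closed + 1L
          tab$status[ri] <- "CLOSED"
          tab$reason[ri] <- "OK"
          tab$overlap_len[ri] <- res$overlap_len
          tab$remaining_n[ri] <- 0L
          tab$filled_len[ri] <- tab$cur_end[ri] - tab$cur_start[ri] + 1L
        } else {
          if (res$status == "PARTIAL") tab$status[ri] <- "PARTIAL"
          # a re-fill that incorporated nothing learned nothing new, and a
          # size mismatch is conclusive (no amount of further extension can
          # make the insertion match the scaffolder's estimate): keep those
          progressed <- nchar(res$left_ext) + nchar(res$right_ext) > 0L
          sticky <- identical(tab$reason[ri], "SIZE_MISMATCH")
          if ((progressed || is.na(tab$reason[ri])) && !sticky) {
            tab$reason[ri] <- res$reason
          }
          rep_sub <- substr(assembly[[sid]], tab$cur_start[ri],
                            tab$cur_end[ri])
          nn <- nchar(gsub("[^N]", "", rep_sub))
          tab$remaining_n[ri] <- nn
          tab$filled_len[ri] <- nchar(rep_sub) - nn
        }
      }
    }
  }
  open_rows <- tab$status != "CLOSED"
  stats$remaining <- sum(open_rows)
  stats$gap_length <- sum(vapply(unname(assembly), function(s) {
    nchar(gsub("[^N]", "", s))
  }, 0L))
  list(assembly = assembly, gaps = tab, stats = stats)
}

#' Close the gaps of an assembly with one or more paired-read libraries
#'
#' The full pipeline: gap edges are trimmed once, then up to `params$i`
#' global iterations of anchoring, recruitment, per-gap k-mer extension and
#' scaffold rewriting are run, stopping early as soon as an iteration
#' incorporates no nucleotide. Mate-pair (RF) libraries are normalized to FR
#' on input; SAM-mode libraries use their precomputed placements on the
#' first iteration and the built-in anchorer afterwards.
#'
#' @param scaffolds Named character vector of scaffolds, or a FASTA path.
#' @param libraries List of library records, or a library-file path for
#'   [parse_library_file()].
#' @param params A [gap_params()].
#' @param basename Optional output basename; when given,
#'   `<basename>.gapfilled.fasta`, `<basename>.gaps.tsv` and
#'   `<basename>.summary.txt` are written.
#' @param verbose Log per-iteration statistics to stderr.
#' @return An object of class `"gapfill_result"`: list with `assembly`
#'   (final scaffolds), `gaps` (per-gap table: original and current
#'   coordinates, trims, expected length, status, reason, overlap and
#'   filled/remaining lengths), `iterations` (per-iteration stats),
#'   `summary_before`, `summary_after`, `params`.
#' @examples
#' ref <- simulate_genome(6000, rng_seed = 7)
#' sim <- make_gapped_scaffolds(ref, gap_specs = list(c(2000, 60)))
#' fq <- simulate_read_pairs(ref, coverage = 40, read_len = 70,
#'                           insert_mean = 300, insert_sd = 30,
#'                           error_rate = 0, rng_seed = 8,
#'                           dir = tempfile("rds"))
#' lib <- list(name = "pe", file1 = fq$file1, file2 = fq$file2, sam = NULL,
#'             insert_size = 300, deviation = 0.25, orientation = "FR")
#' res <- fill_scaffold_gaps(sim$scaffolds, list(lib))
#' res$gaps$status
#' @export
fill_scaffold_gaps <- function(scaffolds, libraries, params = gap_params(),
                               basename = NULL, verbose = FALSE) {
  if (is.character(scaffolds) && length(scaffolds) == 1L &&
      is.null(names(scaffolds)) && file.exists(scaffolds)) {
    scaffolds <- read_fasta(scaffolds)
  }
  if (is.character(libraries)) libraries <- parse_library_file(libraries)
  if (length(libraries) == 0L) stop("at least one read library is required")
  before <- assembly_summary(scaffolds)
  libdata <- lapply(libraries, .load_library, scaffolds = scaffolds)
  init <- .init_gap_table(scaffolds, params$t)
  assembly <- init$assembly
  tab <- init$gaps
  iters <- list()
  for (it in seq_len(params$i)) {
    step <- run_iteration(assembly, libdata, tab, params, iteration = it)
    assembly <- step$assembly
    tab <- step$gaps
    iters[[it]] <- data.frame(iteration = it, closed = step$stats$closed,
                              inserted_nt = step$stats$inserted_nt,
                              remaining = step$stats$remaining,
                              gap_length = step$stats$gap_length)
    if (verbose) {
      message(sprintf(
        "iteration %d: closed %d gap(s), inserted %d nt, %d gap(s) remain (%d N)",
        it, step$stats$closed, step$stats$inserted_nt,
        step$stats$remaining, step$stats$gap_length))
    }
    if (step$stats$inserted_nt == 0L) break
  }
  tab$reason[is.na(tab$reason)] <- "NO_READS"
  after <- assembly_summary(assembly)
  res <- structure(list(assembly = assembly, gaps = tab,
                        iterations = do.call(rbind, iters),
                        summary_before = before, summary_after = after,
                        params = params),
                   class = "gapfill_result")
  if (!is.null(basename)) {
    write_fasta(assembly, paste0(basename, ".gapfilled.fasta"))
    write_gap_report(tab, paste0(basename, ".gaps.tsv"), before, after)
    writeLines(format_summary(res), paste0(basename, ".summary.txt"))
  }
  res
}

#' Plain-text summary of a gap-filling run
#' @param res A `gapfill_result`.
#' @return Character vector of report lines.
#' @export
format_summary <- function(res) {
  b <- res$summary_before
  a <- res$summary_after
  c(sprintf("scaffolds\t%d", b$scaffolds),
    sprintf("gaps before\t%d", b$gap_count),
    sprintf("gaps after\t%d", a$gap_count),
    sprintf("gap length before\t%d", b$gap_length),
    sprintf("gap length after\t%d", a$gap_length),
    sprintf("N50 before\t%d", round(b$n50)),
    sprintf("N50 after\t%d", round(a$n50)),
    sprintf("gaps closed\t%d", sum(res$gaps$status == "CLOSED")),
    sprintf("iterations run\t%d", nrow(res$iterations)))
}

#' @export
print.gapfill_result <- function(x, ...) {
  writeLines(format_summary(x))
  invisible(x)
}
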