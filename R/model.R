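#' Algorithm parameters
#'
#' Bundles every tunable of the gap-closing algorithm with its default and
#' validates the mutual constraints. The extension k-mer size is always
#' `m + 1`: a k-mer must overlap the current edge over `m` bases and
#' contribute exactly one overhang nucleotide.
#'
#' @param t Gap-edge trim length in nucleotides. Before filling, up to `t`
#'   bases on each side of every gap are masked to N, because contig ends
#'   flanking a gap frequently carry assembly errors.
#' @param m Extension overlap length in nucleotides; the k-mer size used for
#'   edge extension is `m + 1`.
#' @param o Minimum overhang coverage: the winning overhang base must be
#'   supported by at least this many k-mers.
#' @param r Majority voting ratio in [0.5, 1]: fraction of the overhang
#'   support that the winning base must hold (0.5 is the permissive
#'   low-coverage setting; ties are always rejected regardless of `r`).
#' @param n Minimum merge overlap in nucleotides between the left and right
#'   extensions for a closure to be accepted.
#' @param d Maximum allowed difference, in nucleotides, between the inserted
#'   sequence length and the expected gap length.
#' @param i Maximum number of global iterations (align, recruit, fill,
#'   rewrite) over the whole assembly.
#' @param seed_len Seed length, in nucleotides, used by the built-in read
#'   anchorer.
#' @param max_mismatch_frac Mismatch budget for full-read verification of an
#'   anchoring candidate, as a fraction of read length.
#' @param rng_seed Optional integer seed for stochastic components
#'   (simulation only; the gap-closing algorithm itself is deterministic).
#' @return A list of class `"gap_params"`.
#' @examples
#' p <- gap_params()
#' p$k  # 30
#' @export
gap_params <- function(t = 10L, m = 29L, o = 2L, r = 0.7, n = 10L, d = 50L,
                       i = 10L, seed_len = 30L, max_mismatch_frac = 0.04,
                       rng_seed = NULL) {
  t <- as.integer(t); m <- as.integer(m); o <- as.integer(o)
  n <- as.integer(n); d <- as.integer(d); i <- as.integer(i)
  seed_len <- as.integer(seed_len)
  k <- m + 1L
  if (k < 2L) stop("k = m + 1 must be >= 2 (m >= 1)")
  if (o < 1L) stop("minimum overhang coverage o must be >= 1")
  if (!(r >= 0.5 && r <= 1)) stop("voting ratio r must lie in [0.5, 1]")
  if (n < 1L) stop("minimum merge overlap n must be >= 1")
  if (d < 0L) stop("size tolerance d must be >= 0")
  if (i < 1L) stop("iteration cap i must be >= 1")
  if (t < 0L) stop("trim length t must be >= 0")
  if (seed_len < 1L) stop("seed_len must be >= 1")
  if (max_mismatch_frac < 0 || max_mismatch_frac >= 1)
    stop("max_mismatch_frac must lie in [0, 1)")
  structure(list(t = t, m = m, k = k, o = o, r = r, n = n, d = d, i = i,
                 seed_len = seed_len, max_mismatch_frac = max_mismatch_frac,
                 rng_seed = rng_seed),
            class = "gap_params")
}

#' @export
print.gap_params <- function(x, ...) {
  cat("gap-closing parameters:\n")
  cat(sprintf("  trim t=%d  overlap m=%d (k=%d)  coverage o=%d  ratio r=%g\n",
              x$t, x$m, x$k, x$o, x$r))
  cat(sprintf("  merge overlap n=%d  size tolerance d=%d  iterations i=%d\n",
              x$n, x$d, x$i))
  cat(sprintf("  anchoring: seed_len=%d  max_mismatch_frac=%g\n",
              x$seed_len, x$max_mismatch_frac))
  invisible(x)
}

# IUPAC one-letter codes; everything ambiguous collapses to N because only
# unambiguous bases can seed or extend k-mers.
.IUPAC <- "ACGTUNRYSWKMBDHVacgtunryswkmbdhv.-"

#' Normalize a nucleotide sequence to the {A,C,G,T,N} alphabet
#'
#' Uppercases, maps U to T, maps every IUPAC ambiguity code and the gap
#' characters `-` and `.` to N. Any character outside the IUPAC nucleotide
#' alphabet is a hard error.
#'
#' @param raw Character vector of raw sequences (e.g. straight from FASTA).
#' @param id Optional identifier(s) used in error messages.
#' @return Character vector over A/C/G/T/N, same length as `raw`.
#' @examples
#' normalize_sequence("acgtn")  # "ACGTN"
#' normalize_sequence("ACRGT")  # "ACNGT"
#' @export
normalize_sequence <- function(raw, id = NULL) {
  bad <- grepl(sprintf("[^%s]", .IUPAC), raw)
  if (any(bad)) {
    w <- which(bad)[1L]
    ch <- regmatches(raw[w], regexpr(sprintf("[^%s]", .IUPAC), raw[w]))
    lab <- if (is.null(id)) sprintf("sequence %d", w) else id[min(w, length(id))]
    stop(sprintf("invalid character '%s' in record '%s'", ch, lab))
  }
  up <- gsub("[.-]", "N", toupper(raw))
  chartr("URYSWKMBDHV", "TNNNNNNNNNN", up)
}

#' Locate gaps (maximal N-runs) in a scaffold sequence
#'
#' @param seq A single normalized scaffold sequence.
#' @return A data frame with one row per maximal N-run: `start`, `end`
#'   (1-based, inclusive), `length`, and `terminal` (`TRUE` when the run
#'   touches a scaffold end and therefore lacks a second flank, so it can
#'   never be filled).
#' @examples
#' find_gaps("AANNNAA")  # one gap at 3..5
#' @export
find_gaps <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) > 0L)
  mt <- gregexpr("N+", seq, fixed = FALSE)[[1L]]
  if (mt[1L] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), terminal = logical()))
  }
  start <- as.integer(mt)
  len <- attr(mt, "match.length")
  end <- start + len - 1L
  data.frame(start = start, end = end, length = len,
             terminal = start == 1L | end == nchar(seq))
}

#' Reverse complement
#'
#' Vectorized over sequences; N maps to N.
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
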