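# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Simulate a random reference genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2`. A repeat can be
#' injected by copying a stated substring to another locus, which is how the
#' repeat-failure behaviour of gap closing is exercised on otherwise
#' non-repetitive sequence.
#'
#' @param length Genome length in bp.
#' @param gc GC content as a fraction in [0, 1].
#' @param rng_seed Integer seed; a fixed seed gives a reproducible genome.
#' @param repeat_from Optional `c(start, len)`: substring to copy.
#' @param repeat_at Optional 1-based position the copy overwrites.
#' @return A single character string over A/C/G/T.
#' @export
simulate_genome <- function(length, gc = 0.5, rng_seed = NULL,
                            repeat_from = NULL, repeat_at = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("genome length must be >= 1")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  g <- .with_seed(rng_seed, function() {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  })
  if (!is.null(repeat_from)) {
    stopifnot(!is.null(repeat_at))
    piece <- substr(g, repeat_from[1L], repeat_from[1L] + repeat_from[2L] - 1L)
    stopifnot(repeat_at + nchar(piece) - 1L <= nchar(g))
    g <- paste0(substr(g, 1L, repeat_at - 1L), piece,
                substr(g, repeat_at + nchar(piece), nchar(g)))
  }
  g
}

#' Mask reference intervals with N to create gapped scaffolds
#'
#' Each gap spec masks a reference interval with a run of N whose length can
#' deviate from the true length by `size_offsets`, emulating a scaffolder's
#' imperfect gap-size estimates (this is what the size tolerance `d` has to
#' absorb, or reject). The truth registry records, per gap, the reference
#' interval, the true sequence, and the N-run's scaffold coordinates.
#'
#' @param genome Reference sequence (single string, optionally named; the
#'   scaffold inherits the name, default `"scaffold_1"`).
#' @param gap_specs List of `c(start, length)` pairs, 1-based, in ascending
#'   order.
#' @param size_offsets Integer offset(s) added to each N-run length
#'   (recycled); the true sequence is unchanged.
#' @param min_separation Minimum distance in bp between consecutive gaps
#'   (and from the scaffold ends); closer or overlapping specs are an
#'   error, because adjacent gaps share flanks and cannot be filled
#'   independently.
#' @return List with `scaffolds` (named character vector) and `registry`
#'   (list: `reference`, `gaps` data frame with `scaffold_id`, `ref_start`,
#'   `ref_end`, `scaf_start`, `scaf_end`, `true_seq`, `n_len`).
#' @export
make_gapped_scaffolds <- function(genome, gap_specs, size_offsets = 0L,
                                  min_separation = 30L) {
  stopifnot(length(genome) == 1L)
  sid <- if (!is.null(names(genome))) names(genome)[1L] else "scaffold_1"
  g <- unname(genome)
  G <- nchar(g)
  if (length(gap_specs) == 0L) {
    scaf <- stats::setNames(g, sid)
    return(list(scaffolds = scaf,
                registry = list(reference = g,
                                gaps = data.frame(
                                  scaffold_id = character(),
                                  ref_start = integer(), ref_end = integer(),
                                  scaf_start = integer(), scaf_end = integer(),
                                  true_seq = character(), n_len = integer()))))
  }
  st <- vapply(gap_specs, `[`, 0, 1L)
  ln <- vapply(gap_specs, `[`, 0, 2L)
  en <- st + ln - 1L
  if (any(st < 1L | en > G)) stop("gap spec outside the reference")
  if (is.unsorted(st, strictly = TRUE)) stop("gap specs must be ascending")
  sep <- c(st[1L] - 1L, st[-1L] - en[-length(en)] - 1L, G - en[length(en)])
  if (any(sep < min_separation)) {
    stop(sprintf("gaps closer than %d bp to each other or a scaffold end",
                 min_separation))
  }
  off <- rep_len(as.integer(size_offsets), length(st))
  n_len <- pmax(1L, ln + off)
  pieces <- character(2L * length(st) + 1L)
  prev <- 1L
  scaf_start <- integer(length(st))
  pos <- 0L
  for (i in seq_along(st)) {
    flank <- substr(g, prev, st[i] - 1L)
    pieces[2L * i - 1L] <- flank
    pieces[2L * i] <- strrep("N", n_len[i])
    scaf_start[i] <- pos + nchar(flank) + 1L
    pos <- pos + nchar(flank) + n_len[i]
    prev <- en[i] + 1L
  }
  pieces[2L * length(st) + 1L] <- substr(g, prev, G)
  scaf <- stats::setNames(paste(pieces, collapse = ""), sid)
  reg <- data.frame(scaffold_id = sid, ref_start = st, ref_end = en,
                    scaf_start = scaf_start,
                    scaf_end = scaf_start + n_len - 1L,
                    true_seq = substring(g, st, en), n_len = n_len)
  list(scaffolds = scaf, registry = list(reference = g, gaps = reg))
}

#' Simulate paired-end reads (wgsim-style) from a genome
#'
#' Fragment starts are uniform, fragment lengths are drawn from a rounded
#' normal truncated below at `2 * read_len` and above at the remaining
#' genome, read 1 is the fragment prefix and read 2 the reverse complement
#' of the fragment suffix (FR). Substitution errors are applied i.i.d. per
#' base; read indels are not simulated. RF mode emits the same pairs with
#' both mates reverse-complemented. Output is FASTQ with constant quality.
#'
#' @param genome Reference sequence (single string).
#' @param coverage Target sequence coverage; the number of pairs is
#'   `round(coverage * G / (2 * read_len))`.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Fragment-length (5'-to-5') mean and SD, bp.
#' @param error_rate Per-base substitution probability.
#' @param orientation `"FR"` or `"RF"`.
#' @param rng_seed Integer seed; fixed seed gives byte-identical output.
#' @param dir Output directory (created); files are `reads_1.fq`,
#'   `reads_2.fq`.
#' @return List with `file1`, `file2`, `n_pairs`.
#' @export
simulate_read_pairs <- function(genome, coverage, read_len, insert_mean,
                                insert_sd, error_rate = 0,
                                orientation = "FR", rng_seed = NULL,
                                dir = tempfile("simreads")) {
  stopifnot(length(genome) == 1L, orientation %in% c("FR", "RF"))
  g <- unname(genome)
  G <- nchar(g)
  if (G < insert_mean) stop("genome shorter than the mean insert size")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0, 1)")
  n <- round(coverage * G / (2 * read_len))
  if (n < 1L) stop("coverage too low: zero pairs")
  sim <- .with_seed(rng_seed, function() {
    start <- sample.int(G - 2L * read_len + 1L, n, replace = TRUE)
    len <- round(stats::rnorm(n, insert_mean, insert_sd))
    len <- pmax(2L * read_len, pmin(len, G - start + 1L))
    r1 <- substring(g, start, start + read_len - 1L)
    r2 <- revcomp(substring(g, start + len - read_len, start + len - 1L))
    if (error_rate > 0) {
      reads <- c(r1, r2)
      hit <- which(matrix(stats::runif(2L * n * read_len) < error_rate,
                          nrow = 2L * n), arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        shift <- sample.int(3L, nrow(hit), replace = TRUE)
        for (j in seq_len(nrow(hit))) {
          ri <- hit[j, 1L]
          pos <- hit[j, 2L]
          b <- substr(reads[ri], pos, pos)
          alt <- setdiff(c("A", "C", "G", "T"), b)[shift[j] %% 3L + 1L]
          substr(reads[ri], pos, pos) <- alt
        }
      }
      r1 <- reads[seq_len(n)]
      r2 <- reads[n + seq_len(n)]
    }
    list(r1 = r1, r2 = r2)
  })
  r1 <- sim$r1
  r2 <- sim$r2
  if (orientation == "RF") {
    r1 <- revcomp(r1)
    r2 <- revcomp(r2)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("frag_%06d", seq_len(n))
  qual <- strrep("I", read_len)
  f1 <- file.path(dir, "reads_1.fq")
  f2 <- file.path(dir, "reads_2.fq")
  writeLines(as.vector(rbind(paste0("@", ids, "/1"), r1, "+", qual)), f1)
  writeLines(as.vector(rbind(paste0("@", ids, "/2"), r2, "+", qual)), f2)
  list(file1 = f1, file2 = f2, n_pairs = n)
}
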