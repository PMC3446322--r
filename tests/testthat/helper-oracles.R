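# Independent brute-force oracles and small fixture builders.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All-offsets anchoring oracle: scan every offset on both strands of every
# scaffold, count mismatches by direct base comparison, demand a unique
# best within the budget. Mirrors only the contract, not the index.
bf_place <- function(read, scaffolds, max_mismatch_frac) {
  L <- nchar(read)
  budget <- floor(max_mismatch_frac * L)
  q_fwd <- utf8ToInt(read)
  q_rev <- utf8ToInt(revcomp(read))
  hits <- list()
  for (sid in names(scaffolds)) {
    s <- utf8ToInt(scaffolds[[sid]])
    if (length(s) < L) next
    offs <- seq_len(length(s) - L + 1L)
    idx <- outer(offs - 1L, seq_len(L), `+`)
    win <- matrix(s[idx], nrow = length(offs))
    for (strand in c("+", "-")) {
      q <- if (strand == "+") q_fwd else q_rev
      mm <- rowSums(win != matrix(q, nrow = length(offs), ncol = L,
                                  byrow = TRUE))
      for (o in which(mm <= budget)) {
        hits[[length(hits) + 1L]] <- list(scaffold_id = sid, start = offs[o],
                                          strand = strand, mismatches = mm[o])
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  mms <- vapply(hits, `[[`, 0, "mismatches")
  best <- which(mms == min(mms))
  if (length(best) > 1L) return(NULL)
  hits[[best]]
}

# Enumeration oracle for one voting step, from an explicit k-mer count list.
bf_extend_decision <- function(edge, counts, o, r) {
  c_b <- vapply(c("A", "C", "G", "T"), function(b) {
    cnt <- counts[[paste0(edge, b)]]
    if (is.null(cnt)) 0L else cnt
  }, 0L)
  total <- sum(c_b)
  cbest <- max(c_b)
  if (cbest < o) return(list(base = NULL, reason = "NO_COVERAGE"))
  if (sum(c_b == cbest) > 1L) return(list(base = NULL, reason = "AMBIGUOUS"))
  if (cbest / total < r) return(list(base = NULL, reason = "AMBIGUOUS"))
  list(base = c("A", "C", "G", "T")[which.max(c_b)], reason = "OK")
}

# Brute-force overlap merge: enumerate every candidate by character-level
# comparison, then apply the size filter and tie rules directly.
bf_try_close <- function(L, R, expected_len, n, d) {
  lc <- strsplit(L, "")[[1L]]
  rc <- strsplit(R, "")[[1L]]
  cands <- list()
  for (x in seq_len(min(length(lc), length(rc)))) {
    if (x < n) next
    if (all(lc[(length(lc) - x + 1L):length(lc)] == rc[seq_len(x)])) {
      len <- length(lc) + length(rc) - x
      cands[[length(cands) + 1L]] <- list(x = x, len = len,
                                          diff = abs(len - expected_len))
    }
  }
  if (length(cands) == 0L) return(list(status = "OPEN", reason = "NO_OVERLAP"))
  ok <- Filter(function(c) c$diff <= d, cands)
  if (length(ok) == 0L) return(list(status = "OPEN", reason = "SIZE_MISMATCH"))
  diffs <- vapply(ok, `[[`, 0, "diff")
  xs <- vapply(ok, `[[`, 0, "x")
  pick <- ok[[which(diffs == min(diffs) &
                      xs == max(xs[diffs == min(diffs)]))[1L]]]
  list(status = "CLOSED",
       inserted_seq = paste0(L, substr(R, pick$x + 1L, nchar(R))),
       overlap_len = pick$x, reason = "OK")
}

# Quadratic unit-cost edit-distance DP.
bf_edit_dist <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  prev <- 0:length(bv)
  for (i in seq_along(av)) {
    cur <- numeric(length(bv) + 1L)
    cur[1L] <- i
    for (j in seq_along(bv)) {
      cur[j + 1L] <- min(prev[j] + (av[i] != bv[j]),
                         prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[length(bv) + 1L]
}

# Small simulated study: genome, gapped scaffold, one FR library on disk.
make_sim <- function(genome_len, gap_specs, coverage = 30, read_len = 70,
                     insert_mean = 300, insert_sd = 30, error_rate = 0,
                     genome_seed = 101, read_seed = 202, size_offsets = 0L,
                     genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(genome_len, rng_seed = genome_seed)
  sim <- make_gapped_scaffolds(genome, gap_specs, size_offsets = size_offsets)
  fq <- simulate_read_pairs(genome, coverage = coverage, read_len = read_len,
                            insert_mean = insert_mean, insert_sd = insert_sd,
                            error_rate = error_rate, rng_seed = read_seed,
                            dir = tempfile("simlib"))
  lib <- list(name = "pe", file1 = fq$file1, file2 = fq$file2, sam = NULL,
              insert_size = insert_mean, deviation = 0.25,
              orientation = "FR")
  list(genome = genome, scaffolds = sim$scaffolds, registry = sim$registry,
       fq = fq, lib = lib)
}
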