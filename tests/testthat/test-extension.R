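test_that("gap edges are trimmed within flank availability", {
  seq25 <- paste0(strrep("A", 10), strrep("N", 5), strrep("C", 10))
  tr <- trim_gap_edges(seq25, find_gaps(seq25), t = 2L)
  expect_equal(tr$gaps$start, 9L)
  expect_equal(tr$gaps$end, 17L)
  expect_equal(tr$gaps$expected_len, 9L)
  expect_equal(substr(tr$seq, 9, 17), strrep("N", 9))
  expect_equal(nchar(tr$seq), 25L)
  # t = 0 is the identity
  tr0 <- trim_gap_edges(seq25, find_gaps(seq25), t = 0L)
  expect_identical(tr0$seq, seq25)
  expect_equal(tr0$gaps$expected_len, 5L)
  # short flanks clip the trim: whole scaffold becomes N
  tr2 <- trim_gap_edges("ANNNA", find_gaps("ANNNA"), t = 2L)
  expect_equal(tr2$gaps[, c("tl", "tr")], data.frame(tl = 1L, tr = 1L))
  expect_equal(tr2$gaps$start, 1L)
  expect_equal(tr2$gaps$end, 5L)
  expect_equal(tr2$gaps$expected_len, 5L)
  # a flank shared by two gaps is split, never consumed
  shared <- paste0(strrep("A", 40), strrep("N", 5), strrep("C", 8),
                   strrep("N", 5), strrep("G", 40))
  trs <- trim_gap_edges(shared, find_gaps(shared), t = 10L)
  expect_equal(trs$gaps$tr[1L], 3L)
  expect_equal(trs$gaps$tl[2L], 3L)
  expect_false(grepl("N", substr(trs$seq, 49, 50)))
  # terminal gaps are never trimmed
  trt <- trim_gap_edges("NNNNACGTACGT", find_gaps("NNNNACGTACGT"), t = 2L)
  expect_equal(trt$gaps$tl, 0L)
  expect_true(trt$gaps$terminal)
})

test_that("k-mer stores count both strands and skip N windows", {
  st <- kmer_store("ACGTA", k = 4L)
  expect_equal(store_count(st, "ACGT"), 2L)  # own reverse complement
  expect_equal(store_count(st, "CGTA"), 1L)
  expect_equal(store_count(st, "TACG"), 1L)
  expect_equal(store_total(st), 4L)
  expect_equal(store_total(kmer_store("ACG", 4L)), 0L)
  expect_equal(store_total(kmer_store("ACNTA", 4L)), 0L)
})

test_that("extend_step applies coverage, ratio, uniqueness, and removal", {
  inject <- function(...) {
    st <- kmer_store(character(0), 4L)
    counts <- c(...)
    for (km in names(counts)) assign(km, counts[[km]], envir = st$env)
    st
  }
  st <- inject(ACGT = 3L, ACGA = 1L)
  r <- extend_step("ACG", st, o = 2L, r = 0.7)
  expect_equal(r$base, "T")  # 3 >= 2 and 3/4 = 0.75 >= 0.7
  expect_equal(store_count(st, "ACGT"), 0L)   # all copies removed
  expect_equal(store_count(st, "ACGA"), 1L)
  expect_equal(extend_step("ACG", inject(ACGT = 1L), 2L, 0.7)$reason,
               "NO_COVERAGE")
  expect_equal(extend_step("ACG", inject(ACGT = 2L, ACGA = 2L),
                           2L, 0.7)$reason, "AMBIGUOUS")
  # ratio failure without a tie is also ambiguous
  expect_equal(extend_step("ACG", inject(ACGT = 4L, ACGA = 2L),
                           2L, 0.7)$reason, "AMBIGUOUS")
})

test_that("a successful step conserves the store total minus the used k-mer", {
  set.seed(41)
  for (rep in 1:25) {
    reads <- replicate(6, rand_seq(12))
    st <- kmer_store(reads, 5L)
    edge <- substr(reads[1L], 1L, 4L)
    before <- store_total(st)
    counts <- vapply(c("A", "C", "G", "T"),
                     function(b) store_count(st, paste0(edge, b)), 0L)
    r <- extend_step(edge, st, o = 1L, r = 0.5)
    if (!is.null(r$base)) {
      expect_gte(unname(counts[r$base]), 1L)
      expect_equal(store_total(st), before - unname(counts[r$base]))
    } else {
      expect_equal(store_total(st), before)
    }
  }
})

test_that("extend_step matches the enumeration oracle on random stores", {
  set.seed(42)
  for (rep in 1:200) {
    edge <- rand_seq(3)
    counts <- list()
    for (b in c("A", "C", "G", "T")) {
      cnt <- sample(0:4, 1L)
      if (cnt > 0L) counts[[paste0(edge, b)]] <- cnt
    }
    o <- sample(1:3, 1L)
    r <- sample(c(0.5, 0.7, 0.9), 1L)
    st <- kmer_store(character(0), 4L)
    for (km in names(counts)) assign(km, counts[[km]], envir = st$env)
    mine <- extend_step(edge, st, o, r)
    oracle <- bf_extend_decision(edge, counts, o, r)
    expect_identical(mine$base, oracle$base)
    expect_identical(mine$reason, oracle$reason)
  }
})

test_that("extend_edge recovers a uniquely covered continuation", {
  set.seed(43)
  region <- rand_seq(120)
  p <- gap_params(m = 14)  # k = 15
  starts <- seq(1L, 120L - 29L, by = 2L)
  reads <- substring(region, starts, starts + 29L)
  st <- kmer_store(rep(reads, 3L), p$k)
  flank <- substr(region, 1L, 20L)
  got <- extend_edge(flank, st, p, cap = 200L)
  expect_equal(got$ext,
               substr(region, 21L, 20L + nchar(got$ext)))
  expect_gt(nchar(got$ext), 60L)
})

test_that("extend_edge terminates on cyclic k-mer sets and honours the cap", {
  # periodic store: removal-on-use drains the cycle, so it halts
  p <- gap_params(m = 3)
  st <- kmer_store(strrep("ACG", 20L), p$k)
  got <- extend_edge("TACG", st, p, cap = 1000L)
  expect_lt(nchar(got$ext), 1000L)
  # a long unique path is clipped at the cap
  set.seed(44)
  path <- rand_seq(300)
  p2 <- gap_params(m = 14)
  starts <- seq(1L, 300L - 29L, by = 1L)
  st2 <- kmer_store(rep(substring(path, starts, starts + 29L), 2L), p2$k)
  got2 <- extend_edge(substr(path, 1L, 20L), st2, p2, cap = 10L)
  expect_equal(nchar(got2$ext), 10L)
  expect_equal(got2$reason, "CAP")
  # an edge containing N cannot seed extension
  expect_equal(extend_edge("ACGNACGTACGTACGT", st2, p2, cap = 10L)$reason,
               "NO_COVERAGE")
})

test_that("try_close merges extensions under the overlap and size rules", {
  r <- try_close("ACGTGATTAAGG", "TTAAGGCCAGTA", expected_len = 18L,
                 n = 3L, d = 5L)
  expect_equal(r$status, "CLOSED")
  expect_equal(r$overlap_len, 6L)
  expect_equal(r$inserted_seq, "ACGTGATTAAGGCCAGTA")
  expect_equal(try_close("ACGTGATTAAGG", "TTAAGGCCAGTA", 18L, 10L, 5L)$reason,
               "NO_OVERLAP")
  expect_equal(try_close("ACGTGATTAAGG", "TTAAGGCCAGTA", 100L, 3L, 50L)$reason,
               "SIZE_MISMATCH")
})

test_that("try_close agrees with brute-force enumeration on random strings", {
  set.seed(45)
  for (rep in 1:300) {
    # half the cases share a planted overlap so CLOSED paths are exercised
    if (rep %% 2L == 0L) {
      ov <- rand_seq(sample(3:12, 1L))
      L <- paste0(rand_seq(sample(0:20, 1L)), ov)
      R <- paste0(ov, rand_seq(sample(0:20, 1L)))
    } else {
      L <- rand_seq(sample(5:40, 1L))
      R <- rand_seq(sample(5:40, 1L))
    }
    expected <- sample(5:60, 1L)
    n <- sample(2:8, 1L)
    d <- sample(c(0L, 5L, 20L), 1L)
    mine <- try_close(L, R, expected, n, d)
    oracle <- bf_try_close(L, R, expected, n, d)
    expect_equal(mine$status, oracle$status)
    expect_equal(mine$reason, oracle$reason)
    if (oracle$status == "CLOSED") {
      expect_equal(mine$inserted_seq, oracle$inserted_seq)
      expect_equal(mine$overlap_len, oracle$overlap_len)
    }
  }
})

test_that("fill_gap closes a well-covered gap with the true sequence", {
  set.seed(46)
  U <- rand_seq(500)
  # gap region: positions 201..300; flanks of m bases each side
  p <- gap_params()
  lf <- substr(U, 201L - p$m, 200L)
  rf <- substr(U, 301L, 300L + p$m)
  starts <- seq(100L, 330L, by = 3L)
  reads <- substring(U, starts, starts + 69L)
  res <- fill_gap(lf, rf, expected_len = 100L, reads = reads, params = p)
  expect_equal(res$status, "CLOSED")
  expect_equal(res$inserted_seq, substr(U, 201L, 300L))
  expect_gte(res$overlap_len, p$n)
  # no reads at all
  empty <- fill_gap(lf, rf, 100L, character(0), p)
  expect_equal(empty$status, "OPEN")
  expect_equal(empty$reason, "NO_READS")
  # one-sided coverage leaves a partial gap with a left extension only
  left_reads <- substring(U, seq(150L, 210L, by = 3L),
                          seq(150L, 210L, by = 3L) + 69L)
  part <- fill_gap(lf, rf, 200L, left_reads, p)
  expect_equal(part$status, "PARTIAL")
  expect_gt(nchar(part$left_ext), 0L)
  expect_lt(nchar(part$right_ext), nchar(part$left_ext))
})

test_that("closure results are invariant to reverse-complementing all reads", {
  set.seed(47)
  U <- rand_seq(400)
  p <- gap_params()
  lf <- substr(U, 151L - p$m, 150L)
  rf <- substr(U, 231L, 230L + p$m)
  starts <- seq(60L, 280L, by = 4L)
  reads <- substring(U, starts, starts + 69L)
  a <- fill_gap(lf, rf, 80L, reads, p)
  b <- fill_gap(lf, rf, 80L, revcomp(reads), p)
  expect_identical(a, b)
  expect_equal(a$status, "CLOSED")
})

test_that("apply_closure rewrites the interval per status", {
  seq <- paste0(strrep("A", 10), strrep("N", 9), strrep("C", 10))
  closed <- list(status = "CLOSED", inserted_seq = "GGGGGGGGG",
                 left_ext = "", right_ext = "")
  out <- apply_closure(seq, 11L, 19L, 9L, closed)
  expect_equal(nchar(out$seq), nchar(seq))
  expect_equal(substr(out$seq, 11, 19), "GGGGGGGGG")
  partial <- list(status = "PARTIAL", left_ext = "GGGGG", right_ext = "TTT")
  out2 <- apply_closure(seq, 11L, 19L, 20L, partial)
  expect_equal(substr(out2$seq, 11, 30), paste0("GGGGG", strrep("N", 12), "TTT"))
  # extensions meeting or exceeding the expectation keep one sentinel N
  part_big <- list(status = "PARTIAL", left_ext = strrep("G", 12),
                   right_ext = strrep("T", 10))
  out3 <- apply_closure(seq, 11L, 19L, 20L, part_big)
  expect_equal(nchar(gsub("[^N]", "", out3$seq)), 1L)
  open <- list(status = "OPEN", left_ext = "", right_ext = "")
  expect_identical(apply_closure(seq, 11L, 19L, 9L, open)$seq, seq)
})
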