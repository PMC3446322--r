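test_that("simulate_genome validates input and is seed-deterministic", {
  expect_error(simulate_genome(0), "length")
  expect_error(simulate_genome(100, gc = 1.2), "gc")
  a <- simulate_genome(500, rng_seed = 5)
  b <- simulate_genome(500, rng_seed = 5)
  expect_identical(a, b)
  expect_equal(nchar(a), 500L)
  gconly <- simulate_genome(300, gc = 1, rng_seed = 6)
  expect_false(grepl("[^GC]", gconly))
  # repeat injection copies a substring verbatim
  g <- simulate_genome(1000, rng_seed = 7, repeat_from = c(101, 50),
                       repeat_at = 701)
  expect_identical(substr(g, 701, 750), substr(g, 101, 150))
})

test_that("gapped scaffolds mask the stated intervals and record the truth", {
  g <- simulate_genome(10000, rng_seed = 8)
  sim <- make_gapped_scaffolds(g, list(c(1000, 50), c(5000, 200)))
  gaps <- find_gaps(sim$scaffolds[[1L]])
  expect_equal(gaps$length, c(50L, 200L))
  expect_equal(gaps$start, sim$registry$gaps$scaf_start)
  # reconstruction: splicing the true sequences back yields the reference
  s <- sim$scaffolds[[1L]]
  for (i in rev(seq_len(nrow(sim$registry$gaps)))) {
    r <- sim$registry$gaps[i, ]
    s <- paste0(substr(s, 1, r$scaf_start - 1), r$true_seq,
                substr(s, r$scaf_end + 1, nchar(s)))
  }
  expect_identical(s, g)
  # perturbed N-run lengths shift downstream coordinates
  simoff <- make_gapped_scaffolds(g, list(c(1000, 50), c(5000, 200)),
                                  size_offsets = 60L)
  expect_equal(find_gaps(simoff$scaffolds[[1L]])$length, c(110L, 260L))
  expect_identical(simoff$registry$gaps$true_seq, sim$registry$gaps$true_seq)
  # empty specs are the identity
  none <- make_gapped_scaffolds(g, list())
  expect_identical(unname(none$scaffolds), g)
  expect_equal(nrow(none$registry$gaps), 0L)
  expect_error(make_gapped_scaffolds(g, list(c(1000, 50), c(1040, 30))),
               "closer")
  expect_error(make_gapped_scaffolds(g, list(c(9990, 50))), "outside")
})

test_that("read simulation honours pair count, determinism and orientation", {
  g <- simulate_genome(10000, rng_seed = 9)
  fq <- simulate_read_pairs(g, coverage = 30, read_len = 70,
                            insert_mean = 300, insert_sd = 30,
                            rng_seed = 10, dir = tempfile())
  expect_equal(fq$n_pairs, 2143L)  # round(30 * 10000 / 140)
  expect_equal(length(readLines(fq$file1)), 4L * 2143L)
  fq2 <- simulate_read_pairs(g, coverage = 30, read_len = 70,
                             insert_mean = 300, insert_sd = 30,
                             rng_seed = 10, dir = tempfile())
  expect_identical(readLines(fq$file1), readLines(fq2$file1))
  expect_identical(readLines(fq$file2), readLines(fq2$file2))
  # error-free reads are exact substrings of the genome or its complement
  reads <- read_pairs(fq$file1, fq$file2)
  both <- paste0(g, "#", revcomp(g))
  for (s in c(head(reads$seq1, 25L), head(reads$seq2, 25L))) {
    expect_true(grepl(s, both, fixed = TRUE))
  }
  # RF mode emits the same fragments with both mates flipped
  rf <- simulate_read_pairs(g, coverage = 30, read_len = 70,
                            insert_mean = 300, insert_sd = 30,
                            orientation = "RF", rng_seed = 10,
                            dir = tempfile())
  rf_reads <- read_pairs(rf$file1, rf$file2)
  expect_identical(rf_reads$seq1, revcomp(reads$seq1))
  expect_identical(rf_reads$seq2, revcomp(reads$seq2))
  expect_error(simulate_read_pairs(substr(g, 1, 200), 30, 70, 300, 30),
               "shorter")
})

test_that("the untouched gapped assembly evaluates to all-OPEN, zero errors", {
  sim <- make_sim(8000, list(c(2000, 60), c(5000, 120)), coverage = 5,
                  genome_seed = 11, read_seed = 12)
  res <- fill_scaffold_gaps(sim$scaffolds, list(sim$lib),
                            gap_params(i = 1L, o = 1000L))
  # absurd coverage threshold: nothing can be filled
  ev <- evaluate_closure(res, sim$registry)
  expect_true(all(ev$gaps$status == "OPEN"))
  expect_equal(ev$totals$closed, 0L)
  expect_equal(ev$totals$snps + ev$totals$indels_le5 + ev$totals$indels_gt5, 0L)
})

test_that("evaluation classifies SNPs and indel events against the truth", {
  set.seed(48)
  sim <- make_sim(9000, list(c(3000, 60), c(6000, 60)), coverage = 35,
                  genome_seed = 13, read_seed = 14)
  res <- fill_scaffold_gaps(sim$scaffolds, list(sim$lib))
  expect_true(all(res$gaps$status == "CLOSED"))
  ev0 <- evaluate_closure(res, sim$registry)
  expect_equal(ev0$totals$perfect, 2L)
  # plant one substitution inside the first closed gap
  mut <- res
  s <- mut$assembly[[1L]]
  pos <- mut$gaps$cur_start[1L] + 20L
  orig <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), orig)[1L]
  mut$assembly[[1L]] <- s
  ev1 <- evaluate_closure(mut, sim$registry)
  expect_equal(ev1$gaps$snps[1L], 1L)
  expect_equal(ev1$gaps$status[1L], "CLOSED_WITH_ERRORS")
  expect_equal(sum(ev1$gaps$indels_le5, ev1$gaps$indels_gt5), 0L)
  # plant a 3 bp deletion in the second gap (shifts downstream coordinates,
  # so patch the tracking table the way the pipeline would)
  del <- res
  s <- del$assembly[[1L]]
  dpos <- del$gaps$cur_start[2L] + 10L
  del$assembly[[1L]] <- paste0(substr(s, 1, dpos - 1),
                               substr(s, dpos + 3, nchar(s)))
  del$gaps$cur_end[2L] <- del$gaps$cur_end[2L] - 3L
  ev2 <- evaluate_closure(del, sim$registry)
  expect_equal(ev2$gaps$indels_le5[2L], 1L)
  expect_equal(ev2$gaps$indels_gt5[2L], 0L)
  expect_equal(ev2$gaps$snps[2L], 0L)
  # a 7 bp deletion is a long indel event
  del7 <- res
  s <- del7$assembly[[1L]]
  del7$assembly[[1L]] <- paste0(substr(s, 1, dpos - 1),
                                substr(s, dpos + 7, nchar(s)))
  del7$gaps$cur_end[2L] <- del7$gaps$cur_end[2L] - 7L
  ev3 <- evaluate_closure(del7, sim$registry)
  expect_equal(ev3$gaps$indels_gt5[2L], 1L)
  expect_equal(ev3$gaps$indels_le5[2L], 0L)
})

test_that("edit alignment totals agree with the quadratic DP oracle", {
  set.seed(49)
  for (rep in 1:30) {
    len <- if (rep <= 2L) 200L else sample(10:60, 1L)
    a <- rand_seq(len)
    b <- a
    # random small edits
    for (e in seq_len(sample(0:4, 1L))) {
      p <- sample(nchar(b), 1L)
      b <- switch(sample(3L, 1L),
                  paste0(substr(b, 1, p - 1), rand_seq(1),
                         substr(b, p + 1, nchar(b))),
                  paste0(substr(b, 1, p - 1), substr(b, p + 1, nchar(b))),
                  paste0(substr(b, 1, p), rand_seq(1),
                         substr(b, p, nchar(b))))
    }
    cls <- gapmender:::.edit_stats(a, b)
    expect_equal(cls$edit_dist, bf_edit_dist(a, b))
    # the affine-gap event classification never undercounts the distance
    expect_gte(cls$snps + cls$indels_le5 + cls$indels_gt5,
               as.integer(cls$edit_dist > 0L))
  }
})

test_that("evaluation reports round-trip through JSON", {
  sim <- make_sim(6000, list(c(2500, 40)), coverage = 30, genome_seed = 15,
                  read_seed = 16)
  res <- fill_scaffold_gaps(sim$scaffolds, list(sim$lib))
  ev <- evaluate_closure(res, sim$registry)
  f <- tempfile(fileext = ".json")
  write_eval_json(ev, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$totals$gaps, ev$totals$gaps)
  expect_equal(back$totals$perfect, ev$totals$perfect)
})
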