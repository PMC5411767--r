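# shared correction fixture: noisy reads, sketch overlaps, filters
correction_fixture <- function() {
  fixture("correction", {
    rs <- noisy_reads_20k()
    cfg <- assembly_config(genome_size = 20000, seed = 60)
    ov <- overlap_reads(rs$reads, k = cfg$k, s = cfg$s,
                        min_overlap = cfg$min_overlap, seed = cfg$seed)
    sym <- symmetrize_overlaps(ov)
    list(reads = rs$reads, genome = rs$genome, cfg = cfg, sym = sym)
  })
}

test_that("the global filter keeps the C best overlaps per donor", {
  fx <- correction_fixture()
  C <- 10L
  don <- global_filter(fx$sym, C)
  counts <- table(don$a)
  expect_true(all(counts <= C))
  # brute-force scoring oracle for a handful of donors
  for (rid in head(unique(fx$sym$a), 5)) {
    ov <- fx$sym[fx$sym$a == rid, ]
    score <- pmax(ov$a_end - ov$a_start, ov$b_end - ov$b_start) * (1 - ov$error)
    want <- ov$b[order(-score, ov$b)][seq_len(min(C, nrow(ov)))]
    got <- don$b[don$a == rid]
    expect_setequal(got, want)
  }
  # donors with <= C overlaps keep everything
  few <- names(table(fx$sym$a))[table(fx$sym$a) <= C]
  if (length(few) > 0) {
    rid <- as.integer(few[1])
    expect_equal(sum(don$a == rid), sum(fx$sym$a == rid))
  }
})

test_that("direct score ranking keeps the two highest products", {
  ov <- tibble::tibble(
    a = 1L, b = 2:4,
    a_start = 0L, a_end = c(4000L, 3000L, 5000L),
    b_start = 0L, b_end = c(4000L, 3000L, 5000L),
    orient = "+", error = c(0.02, 0.01, 0.10),
    kind = "dovetail", evidence = "sketch"
  )
  don <- global_filter(ov, 2L)
  # products: 3920, 2970, 4500 -> keep partners 4 and 2
  expect_setequal(don$b, c(4L, 2L))
})

test_that("the local filter keeps at most 2C accepted donations per target", {
  fx <- correction_fixture()
  C <- 4L
  acc <- local_filter(global_filter(fx$sym, 20L), C)
  expect_true(all(table(acc$b) <= 2 * C))
  # 5C donations to one target -> exactly the 2C top-scoring survive
  don <- tibble::tibble(
    a = 1:20, b = 99L,
    a_start = 0L, a_end = seq(1000L, 20000L, by = 1000L),
    b_start = 0L, b_end = seq(1000L, 20000L, by = 1000L),
    orient = "+", error = 0.01, kind = "dovetail", evidence = "sketch"
  )
  don$score <- sketchasm:::overlap_score(don)
  kept <- local_filter(don, C)
  expect_equal(nrow(kept), 8)
  expect_setequal(kept$a, 13:20)
})

test_that("corrected length estimates follow evidence coverage", {
  reads <- tibble::tibble(id = 1L, seq = strrep("A", 4000), length = 4000L)
  full <- tibble::tibble(a = 2:4, b = 1L, b_start = 0L, b_end = 4000L,
                         a_start = 0L, a_end = 4000L, score = 1)
  est <- estimate_corrected_lengths(reads, full)
  expect_equal(est$corrected_length, 4000L)
  half <- full %>% dplyr::mutate(b_end = c(2000L, 2050L, 1990L))
  est2 <- estimate_corrected_lengths(reads, half)
  expect_lt(abs(est2$corrected_length - 2000L), 100)
  none <- full[0, ]
  est3 <- estimate_corrected_lengths(reads, none)
  expect_equal(est3$corrected_length, 0L)
})

test_that("read selection is greedy by estimated length with id tie-break", {
  est <- tibble::tibble(id = 1:6, length = 0L,
                        corrected_length = c(5000L, 3000L, 3000L, 8000L, 0L, 2000L))
  sel <- select_longest(est, target_coverage = 1, genome_size = 16000)
  # descending: 4 (8k), 1 (5k), 2 (3k, lower id first) -> cumulative 16k
  expect_equal(sel$id, c(4L, 1L, 2L))
  # insufficient data: everything with evidence is returned
  all_sel <- select_longest(est, 10, 16000)
  expect_setequal(all_sel$id, c(1L, 2L, 3L, 4L, 6L))
})

test_that("DAG correction reproduces the template from error-free evidence", {
  tpl <- random_seq(2000, seed = 61)
  read <- tibble::tibble(id = 1L, seq = tpl, length = 2000L)
  reads <- tibble::tibble(id = 1:11, seq = c(tpl, rep(tpl, 10)),
                          length = 2000L)
  ev <- tibble::tibble(
    a = 2:11, b = 1L, a_start = 0L, a_end = 2000L,
    b_start = 0L, b_end = 2000L, orient = "+", error = 0.01
  )
  out <- dag_correct(read, reads, ev)
  expect_equal(nrow(out), 1)
  expect_identical(out$seq, tpl)
})

test_that("evidence covering two disjoint halves splits the read", {
  tpl <- random_seq(4000, seed = 62)
  halves <- c(rep(substr(tpl, 1, 1500), 5), rep(substr(tpl, 2501, 4000), 5))
  reads <- tibble::tibble(id = 1:11, seq = c(tpl, halves),
                          length = nchar(c(tpl, halves)))
  ev <- tibble::tibble(
    a = 2:11, b = 1L,
    a_start = 0L, a_end = 1500L,
    b_start = c(rep(0L, 5), rep(2500L, 5)),
    b_end = c(rep(1500L, 5), rep(4000L, 5)),
    orient = "+", error = 0.02
  )
  out <- dag_correct(tibble::tibble(id = 1L, seq = tpl, length = 4000L),
                     reads, ev, min_piece_length = 400L)
  expect_equal(nrow(out), 2)
  expect_lt(out$tpl_end[1], 2000)
  expect_gt(out$tpl_start[2], 2000)
})

test_that("noisy reads are corrected to at least 99% identity", {
  fx <- correction_fixture()
  cor <- correct_reads(fx$reads, fx$cfg, overlaps = fx$sym %>%
                         dplyr::filter(.data$a < .data$b))
  expect_gt(nrow(cor), 0.8 * nrow(fx$reads))
  ids <- vapply(head(seq_len(nrow(cor)), 25), function(i) {
    r <- cor[i, ]
    truth <- substr(fx$genome$seq, r$start + 1, r$end)
    if (r$strand == "-") truth <- revcomp(truth)
    sequence_identity(r$seq, truth)$identity
  }, numeric(1))
  expect_gt(mean(ids), 0.99)
})

test_that("repeat reads donate mostly to same-copy partners at 5% divergence", {
  g <- simulate_genome(genome_spec(
    24000, repeat_spec(5000, 0.05, c(4000, 15000)), seed = 63))
  reads <- simulate_reads(g, coverage = 30, error_rate = 0.10, seed = 64)
  ov <- overlap_reads(reads, s = 256, min_overlap = 500, seed = 65)
  don <- global_filter(symmetrize_overlaps(ov),
                       C = round(sum(reads$length) / 24000))
  rt <- g$repeat_truth
  copy_of <- function(s, e) {
    m <- (s + e) / 2
    ifelse(m > rt$start[1] & m < rt$end[1], 1L,
           ifelse(m > rt$start[2] & m < rt$end[2], 2L, 0L))
  }
  ca <- copy_of(reads$start, reads$end)[match(don$a, reads$id)]
  cb <- copy_of(reads$start, reads$end)[match(don$b, reads$id)]
  rep_d <- !is.na(cb) & cb != 0 & !is.na(ca) & ca != 0
  same <- mean(ca[rep_d] == cb[rep_d])
  # clustering is directional: clearly enriched for same-copy evidence
  expect_gt(same, 0.6)
})

test_that("iterated correction does not reduce read identity", {
  g <- simulate_genome(genome_spec(15000, seed = 66))
  reads <- simulate_reads(g, coverage = 25, error_rate = 0.15, seed = 67)
  cfg <- assembly_config(genome_size = 15000, seed = 68)
  mean_id <- function(rd) {
    mean(vapply(head(seq_len(nrow(rd)), 15), function(i) {
      r <- rd[i, ]
      truth <- substr(g$seq, r$start + 1, r$end)
      if (r$strand == "-") truth <- revcomp(truth)
      sequence_identity(r$seq, truth)$identity
    }, numeric(1)))
  }
  r1 <- iterate_correction(reads, rounds = 1, cfg, passthrough = TRUE)
  r2 <- iterate_correction(reads, rounds = 2, cfg, passthrough = TRUE)
  expect_gte(mean_id(r2) + 0.002, mean_id(r1))
  expect_gt(mean_id(r1), mean_id(reads))
  # empty input passes through
  expect_equal(nrow(iterate_correction(reads[0, ], rounds = 2, cfg)), 0)
})
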