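# build a same-locus read stack with controlled errors for voting tests
stack_reads <- function(n, len = 3000, err = 0.02, seed = 90, src = NULL) {
  src <- src %||% random_seq(len, seed = seed)
  tibble::tibble(
    id = seq_len(n),
    seq = vapply(seq_len(n), function(i) mutate_seq(src, err, seed = seed + i), "")
  )
}

stack_overlaps <- function(reads) {
  dp_overlap(reads, min_overlap = 300)
}

test_that("unanimous disagreement proposes an edit, split columns do not", {
  src <- random_seq(2000, seed = 91)
  # read 1 carries one isolated substitution; partners are clean
  other <- setdiff(c("A", "C", "G", "T"), substr(src, 1000, 1000))[1]
  bad <- paste0(substr(src, 1, 999), other, substr(src, 1001, 2000))
  reads <- tibble::tibble(id = 1:11, seq = c(bad, rep(src, 10)))
  sym <- symmetrize_overlaps(stack_overlaps(reads))
  edits <- vote_errors(reads, sym)
  e1 <- edits[edits$id == 1, ]
  expect_equal(nrow(e1), 1)
  expect_equal(e1$pos, 999)
  expect_equal(e1$type, "sub")
  # partners all agree with each other: no edits elsewhere
  expect_equal(nrow(edits[edits$id != 1, ]), 0)
})

test_that("a balanced variant column is preserved", {
  src <- random_seq(2000, seed = 92)
  alt <- paste0(substr(src, 1, 999),
                setdiff(c("A", "C", "G", "T"), substr(src, 1000, 1000))[1],
                substr(src, 1001, 2000))
  # 5 reads of each haplotype: 5 vs 5 split at the variant column
  reads <- tibble::tibble(id = 1:10, seq = c(rep(src, 5), rep(alt, 5)))
  sym <- symmetrize_overlaps(stack_overlaps(reads))
  edits <- vote_errors(reads, sym)
  expect_equal(nrow(edits[edits$pos == 999, ]), 0)
})

test_that("adjusted error rates drop for same-locus noisy reads", {
  reads <- stack_reads(12, err = 0.02, seed = 93)
  ov <- stack_overlaps(reads)
  adj <- adjust_overlaps(reads, symmetrize_overlaps(ov))
  half <- adj$overlaps %>% dplyr::filter(.data$a < .data$b)
  expect_lt(mean(half$error), mean(half$error_raw))
  expect_lt(median(half$error), 0.01)
  # no edits: store unchanged
  noedit <- recompute_error_rates(reads, ov, vote_errors(reads, ov[0, ]))
  expect_equal(noedit$error, noedit$error_raw)
})

test_that("diverged-copy overlap errors stay near the true divergence", {
  src <- random_seq(3000, seed = 94)
  copy2 <- mutate_seq(src, 0.03, seed = 95, mix = c(1, 0, 0))
  reads <- dplyr::bind_rows(
    stack_reads(8, err = 0.02, seed = 96, src = src),
    stack_reads(8, err = 0.02, seed = 120, src = copy2) %>%
      dplyr::mutate(id = .data$id + 8L)
  )
  sym <- symmetrize_overlaps(stack_overlaps(reads))
  adj <- adjust_overlaps(reads, sym)
  half <- adj$overlaps %>% dplyr::filter(.data$a < .data$b) %>%
    dplyr::mutate(cross = (.data$a <= 8) != (.data$b <= 8))
  same <- half$error[!half$cross]
  cross <- half$error[half$cross]
  # bimodal separation: same-copy near 0, cross-copy near the divergence
  expect_lt(median(same), 0.01)
  expect_gt(median(cross), 0.015)
  expect_lt(abs(median(cross) - 0.03), 0.015)
  # a single threshold classifies better after adjustment
  err_of <- function(e_same, e_cross) {
    thr <- sort(unique(c(e_same, e_cross)))
    min(vapply(thr, function(t)
      (sum(e_same > t) + sum(e_cross <= t)) /
        (length(e_same) + length(e_cross)), numeric(1)))
  }
  raw_same <- half$error_raw[!half$cross]
  raw_cross <- half$error_raw[half$cross]
  expect_lte(err_of(same, cross), err_of(raw_same, raw_cross))
})

test_that("the edit log serializes cleanly", {
  reads <- stack_reads(8, err = 0.03, seed = 97)
  sym <- symmetrize_overlaps(stack_overlaps(reads))
  edits <- vote_errors(reads, sym)
  expect_gt(nrow(edits), 0)
  f <- withr::local_tempfile()
  write_edits_tsv(edits, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(edits))
  expect_named(back, c("id", "pos", "from", "to"))
})
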