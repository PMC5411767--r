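test_that("mash distance matches the closed form and its boundary cases", {
  expect_equal(mash_distance(1, 16), 0)
  expect_equal(mash_distance(0, 16), 1)   # clamp at j = 0
  expect_equal(mash_distance(0.5, 16), -log(2 * 0.5 / 1.5) / 16)
  j <- c(0.05, 0.2, 0.8)
  expect_equal(mash_distance(j, 21), pmin(pmax(-log(2 * j / (1 + j)) / 21, 0), 1))
})

test_that("disjoint random reads produce essentially no candidates", {
  # expected false candidates well below 1 per 100-read set at s = 512
  withr::local_seed(40)
  total <- 0
  for (rep in 1:3) {
    reads <- tibble::tibble(
      id = 1:100,
      seq = vapply(1:100, function(i)
        paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""), "")
    )
    sp <- count_kmers(reads)
    sk <- build_sketch(reads, sp, s = 512, seed = rep)
    total <- total + nrow(find_candidates(sk, min_slot_matches = 2))
  }
  expect_lte(total, 3)
})

test_that("a read and its own prefix are candidates", {
  r <- random_seq(4000, seed = 41)
  reads <- tibble::tibble(id = 1:2, seq = c(r, substr(r, 1, 2000)))
  sp <- count_kmers(reads)
  sk <- build_sketch(reads, sp, s = 256, seed = 1)
  cand <- find_candidates(sk)
  expect_true(any(cand$a == 1 & cand$b == 2))
})

test_that("candidates cover all truth pairs at clean 30x coverage", {
  rs <- clean_reads_20k()
  reads <- rs$reads
  sp <- count_kmers(reads)
  sk <- build_sketch(reads, sp, s = 512, seed = 2)
  cand <- find_candidates(sk)
  key <- paste(pmin(cand$a, cand$b), pmax(cand$a, cand$b))
  ids <- reads$id
  missed <- 0; truth_pairs <- 0
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      if (true_overlap(reads, ids[i], ids[j]) >= 2000) {
        truth_pairs <- truth_pairs + 1
        if (!(paste(min(ids[i], ids[j]), max(ids[i], ids[j])) %in% key)) {
          missed <- missed + 1
        }
      }
    }
  }
  expect_gt(truth_pairs, 100)
  expect_equal(missed, 0)
})

test_that("estimated overlaps recover extent, orientation and error", {
  rs <- noisy_reads_20k()
  reads <- rs$reads
  sp <- count_kmers(reads)
  sk <- build_sketch(reads, sp, s = 256, seed = 3)
  bt <- build_bottom_sketch(reads)
  ov <- estimate_overlap(bt, find_candidates(sk))

  # identical reads: jaccard 1, error 0, containment
  two <- tibble::tibble(id = 1:2, seq = rep(reads$seq[1], 2))
  bt2 <- build_bottom_sketch(two)
  est <- estimate_overlap(bt2, tibble::tibble(a = 1L, b = 2L))
  expect_equal(est$jaccard, 1)
  expect_equal(est$error, 0)
  expect_equal(est$kind, "containment")

  # estimated intervals overlap the truth intervals (interval Jaccard >= 0.8)
  checked <- 0
  for (i in seq_len(nrow(ov))) {
    if (checked >= 40) break
    a <- ov$a[i]; b <- ov$b[i]
    tov <- true_overlap(reads, a, b)
    if (tov < 3000) next
    ra <- reads[match(a, reads$id), ]
    lo <- max(ra$start, reads$start[match(b, reads$id)])
    hi <- min(ra$end, reads$end[match(b, reads$id)])
    # truth interval on read a (approximate, error-free coordinates)
    if (ra$strand == "+") {
      ts <- lo - ra$start; te <- hi - ra$start
    } else {
      ts <- ra$end - hi; te <- ra$end - lo
    }
    isec <- max(0, min(te, ov$a_end[i]) - max(ts, ov$a_start[i]))
    uni <- max(te, ov$a_end[i]) - min(ts, ov$a_start[i])
    expect_gt(isec / uni, 0.8)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("mash error estimates track DP alignment error within 2 points", {
  # simulated pairs at three true divergences, 20 pairs each
  for (d in c(0.02, 0.05, 0.10)) {
    est <- dp <- numeric(0)
    for (p in 1:20) {
      src <- random_seq(4000, seed = 5000 + p)
      a <- mutate_seq(src, d / 2, seed = 2 * p)
      b <- mutate_seq(src, d / 2, seed = 2 * p + 1)
      rt <- tibble::tibble(id = 1:2, seq = c(a, b))
      bt <- build_bottom_sketch(rt)
      e <- estimate_overlap(bt, tibble::tibble(a = 1L, b = 2L))
      o <- dp_overlap(rt, e)
      if (nrow(e) == 1 && nrow(o) == 1) {
        est <- c(est, e$error)
        dp <- c(dp, o$error)
      }
    }
    expect_gt(length(est), 15)
    expect_lt(abs(mean(est) - mean(dp)), 0.02)
  }
})

test_that("dp overlap confirms extents on noisy dovetails", {
  g <- random_seq(12000, seed = 42)
  a <- mutate_seq(substr(g, 1, 8000), 0.1, seed = 43)
  b <- mutate_seq(substr(g, 4001, 12000), 0.1, seed = 44)
  rt <- tibble::tibble(id = 1:2, seq = c(a, b))
  dp <- dp_overlap(rt)
  expect_equal(nrow(dp), 1)
  expect_equal(dp$kind, "dovetail")
  expect_lt(abs(dp$error - 0.19), 0.04)
  # extents near truth (4000 bp overlap at the ends)
  expect_lt(abs(dp$a_end[1] - dp$a_start[1] - 4000), 450)
  # identical reads: containment at error 0
  same <- dp_overlap(tibble::tibble(id = 1:2, seq = c(a, a)))
  expect_equal(same$kind, "containment")
  expect_equal(same$error, 0)
  # unrelated reads: nothing
  un <- dp_overlap(tibble::tibble(id = 1:2, seq = c(
    random_seq(3000, seed = 45), random_seq(3000, seed = 46))))
  expect_equal(nrow(un), 0)
})

test_that("overlaps are symmetric under role swap", {
  rs <- noisy_reads_20k()
  ov <- overlap_reads(head(rs$reads, 40), s = 256, dp = TRUE, seed = 4)
  sym <- symmetrize_overlaps(ov)
  expect_equal(nrow(sym), 2 * nrow(ov))
  for (i in head(seq_len(nrow(ov)), 20)) {
    rec <- ov[i, ]
    swp <- sym[sym$a == rec$b & sym$b == rec$a &
                 sym$a_start == rec$b_start, ]
    expect_equal(nrow(swp), 1)
    expect_equal(swp$b_end, rec$a_end)
    expect_equal(swp$error, rec$error)
    expect_equal(swp$orient, rec$orient)
  }
})

test_that("PAF serialization round-trips", {
  rs <- noisy_reads_20k()
  reads <- head(rs$reads, 30)
  ov <- overlap_reads(reads, s = 256, dp = TRUE, seed = 5)
  f <- withr::local_tempfile(fileext = ".paf")
  write_paf(ov, reads, f)
  back <- read_paf(f)
  expect_equal(back$a, ov$a)
  expect_equal(back$b, ov$b)
  expect_equal(back$a_start, ov$a_start)
  expect_equal(back$b_end, ov$b_end)
  expect_equal(back$orient, ov$orient)
  expect_equal(back$kind, ov$kind)
  expect_equal(back$error, ov$error, tolerance = 1e-4)
})
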