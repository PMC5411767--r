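test_that("genome specs validate placements and divergence", {
  expect_error(repeat_spec(5000, 0.7, c(0, 10000)), "divergence")
  expect_error(genome_spec(10000, repeat_spec(5000, 0.1, c(0, 4000))),
               "overlap")
  expect_error(genome_spec(10000, repeat_spec(12000, 0.1, 0)), "smaller")
  expect_silent(genome_spec(20000, repeat_spec(5000, 0.1, c(1000, 8000))))
})

test_that("a repeat-free genome is i.i.d. sequence with empty annotation", {
  g <- simulate_genome(genome_spec(10000, seed = 1))
  expect_equal(nchar(g$seq), 10000)
  expect_equal(nrow(g$repeat_truth), 0)
  counts <- table(strsplit(g$seq, "")[[1]])
  expect_true(all(sort(names(counts)) == c("A", "C", "G", "T")))
  # uniform base composition at binomial tolerance
  expect_true(all(abs(counts / 10000 - 0.25) < 4 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("zero-divergence repeat copies are exact string copies", {
  g <- simulate_genome(genome_spec(
    20000, repeat_spec(4000, 0, c(2000, 12000)), seed = 2))
  c1 <- substr(g$seq, 2001, 6000)
  c2 <- substr(g$seq, 12001, 16000)
  expect_identical(c1, c2)
})

test_that("pairwise repeat divergence matches binomial expectation", {
  # 2 copies, 5 kb unit, 3% divergence: Hamming distance ~ 150 +- sampling
  g <- simulate_genome(genome_spec(
    20000, repeat_spec(5000, 0.03, c(2000, 12000)), seed = 3))
  c1 <- strsplit(substr(g$seq, 2001, 7000), "")[[1]]
  c2 <- strsplit(substr(g$seq, 12001, 17000), "")[[1]]
  mism <- sum(c1 != c2)
  expect_gt(mism, 150 - 4 * sqrt(150))
  expect_lt(mism, 150 + 4 * sqrt(150))
  # truth annotation records exact coordinates
  expect_equal(g$repeat_truth$start, c(2000, 12000))
  expect_equal(g$repeat_truth$end, c(7000, 17000))
  # observed per-copy divergence from consensus within 3 sd of binomial
  for (cp in 1:2) {
    n <- sum(g$mutations$copy == cp)
    expect_lt(abs(n - 5000 * 0.015), 3 * sqrt(5000 * 0.015 * 0.985) + 1)
  }
})

test_that("noiseless reads are exact substrings on the recorded strand", {
  g <- simulate_genome(genome_spec(8000, seed = 4))
  reads <- simulate_reads(g, coverage = 5, error_rate = 0, seed = 5,
                          min_length = 600)
  for (i in seq_len(nrow(reads))) {
    src <- substr(g$seq, reads$start[i] + 1, reads$end[i])
    if (reads$strand[i] == "-") src <- revcomp(src)
    expect_identical(reads$seq[i], src)
  }
  expect_setequal(unique(reads$strand), c("+", "-"))
})

test_that("identical seeds give byte-identical read sets", {
  g <- simulate_genome(genome_spec(10000, seed = 6))
  r1 <- simulate_reads(g, coverage = 10, error_rate = 0.1, seed = 7)
  r2 <- simulate_reads(g, coverage = 10, error_rate = 0.1, seed = 7)
  expect_identical(r1, r2)
  r3 <- simulate_reads(g, coverage = 10, error_rate = 0.1, seed = 8)
  expect_false(identical(r1$seq, r3$seq))
})

test_that("coverage is conserved and lengths follow the log-normal", {
  g <- simulate_genome(genome_spec(100000, seed = 9))
  reads <- simulate_reads(g, coverage = 30, error_rate = 0, seed = 10,
                          length_meanlog = 8.1, length_sdlog = 0.45)
  total <- sum(reads$end - reads$start)
  expect_lt(abs(total - 30 * 100000) / (30 * 100000), 0.05)
  # KS test against the truncated log-normal at alpha = 0.01
  lens <- reads$end - reads$start
  plo <- plnorm(500, 8.1, 0.45)
  phi <- plnorm(15000, 8.1, 0.45)
  cdf <- function(x) (plnorm(x, 8.1, 0.45) - plo) / (phi - plo)
  ks <- suppressWarnings(ks.test(lens, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated error rates are recovered by alignment to the source", {
  g <- simulate_genome(genome_spec(30000, seed = 11))
  for (e in c(0.05, 0.15)) {
    reads <- simulate_reads(g, coverage = 2, error_rate = e, seed = 12)
    obs <- vapply(seq_len(min(15, nrow(reads))), function(i) {
      src <- substr(g$seq, reads$start[i] + 1, reads$end[i])
      if (reads$strand[i] == "-") src <- revcomp(src)
      len <- reads$end[i] - reads$start[i]
      sequence_identity(reads$seq[i], src)$dist / len
    }, numeric(1))
    # edit distance slightly undercounts clustered errors; binomial tolerance
    expect_lt(abs(mean(obs) - e), max(0.012, 4 * sqrt(e * (1 - e) / 2000)))
  }
})

test_that("exclude_spanning_reads removes exactly the spanning reads", {
  g <- simulate_genome(genome_spec(30000, seed = 13))
  reads <- simulate_reads(g, coverage = 20, error_rate = 0, seed = 14)
  iv <- c(12000, 15000)
  kept <- exclude_spanning_reads(reads, iv)
  # brute-force containment check over the truth layout
  spans <- reads$start <= iv[1] & reads$end >= iv[2]
  expect_equal(nrow(kept), nrow(reads) - sum(spans))
  expect_false(any(kept$start <= iv[1] & kept$end >= iv[2]))
  # interval beyond every read: unchanged
  expect_equal(nrow(exclude_spanning_reads(reads, c(0, 30000))),
               nrow(reads) - sum(reads$start == 0 & reads$end == 30000))
})

test_that("chimera and hairpin injectors record truth", {
  rs <- clean_reads_20k()
  ch <- inject_chimeras(rs$reads, frac = 0.1, min_distance = 8000, seed = 15)
  expect_gt(sum(ch$is_chimera), 0)
  expect_true(all(!is.na(ch$chimera_junction[ch$is_chimera])))
  hp <- inject_hairpins(ch, n = 3, seed = 16)
  expect_equal(sum(hp$is_hairpin), 3)
  i <- which(hp$is_hairpin)[1]
  s <- hp$seq[i]
  piv <- hp$hairpin_pivot[i]
  # the prefix before the adapter reverse-complements the suffix
  pre <- substr(s, 1, piv - 30)
  suf <- substr(s, nchar(s) - nchar(pre) + 1, nchar(s))
  expect_identical(revcomp(pre), suf)
})

test_that("fastq/fasta round trips preserve sequences", {
  skip_if_not_installed("Biostrings")
  rs <- clean_reads_20k()
  reads <- head(rs$reads, 5)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads(reads, fq)
  back <- read_reads(fq)
  expect_equal(back$seq, reads$seq)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_reads(reads, fa)
  expect_equal(read_reads(fa)$seq, reads$seq)
})
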