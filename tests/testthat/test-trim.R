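test_that("clear ranges follow qualifying coverage", {
  reads <- tibble::tibble(id = 1L, seq = strrep("A", 4000), length = 4000L)
  mk <- function(a_start, a_end, error = 0.01) {
    tibble::tibble(a = 1L, b = seq_along(a_start) + 1L,
                   a_start = a_start, a_end = a_end,
                   b_start = 0L, b_end = a_end - a_start,
                   orient = "+", error = error, kind = "dovetail",
                   evidence = "dp")
  }
  # uniform depth >= 2 over the whole read: full-length clear range
  full <- mk(c(0L, 0L, 100L), c(4000L, 3900L, 4000L))
  cr <- compute_clear_ranges(reads, full)
  expect_equal(cr$status, "trimmed")
  expect_lte(cr$begin, 100L)
  expect_gte(cr$end, 3900L)

  # coverage dip to depth 1 in the middle: clear range = the longer flank
  dip <- mk(c(0L, 0L, 2200L, 2300L, 0L), c(1800L, 1900L, 4000L, 4000L, 4000L))
  # per-base coverage oracle: depth >= 2 on [0,1900) and [2300,4000);
  # the left flank is shorter, so the right flank wins? lengths 1900 vs 1700
  cr2 <- compute_clear_ranges(reads, dip)
  expect_equal(cr2$begin, 0L)
  expect_equal(cr2$end, 1900L)

  # zero overlaps: discarded
  cr3 <- compute_clear_ranges(reads, full[0, ])
  expect_equal(cr3$status, "discarded")

  # overlaps above the error bound never support a clear range
  bad <- mk(c(0L, 0L), c(4000L, 4000L), error = 0.2)
  expect_equal(compute_clear_ranges(reads, bad)$status, "discarded")
})

trim_fixture <- function() {
  fixture("trimfx", {
    g <- simulate_genome(genome_spec(50000, seed = 70))
    reads <- simulate_reads(g, coverage = 30, error_rate = 0.01, seed = 71)
    list(genome = g, reads = reads)
  })
}

test_that("hairpin constructs are detected and genomic inverted repeats are not", {
  fx <- trim_fixture()
  reads <- inject_hairpins(fx$reads, n = 6, seed = 72)
  cfg <- assembly_config(genome_size = 50000, seed = 73)
  tr <- trim_reads(reads, cfg)
  hp <- tr$hairpins
  truth <- reads[reads$is_hairpin, ]
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    j <- match(truth$id[i], hp$id)
    if (!is.na(j) && abs(hp$pivot[j] - truth$hairpin_pivot[i]) <= 150) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 5)
  # false hairpin flags on clean reads stay rare
  fp <- sum(!(hp$id %in% truth$id))
  expect_lte(fp, ceiling(0.02 * nrow(reads)))
  # flagged reads are trimmed to the larger side, never enlarged
  cl <- tr$clear_ranges
  for (i in seq_len(nrow(truth))) {
    j <- match(truth$id[i], cl$id)
    if (cl$status[j] == "split") {
      expect_lte(cl$end[j] - cl$begin[j], truth$length[i] * 0.75)
    }
  }
})

test_that("a genuine inverted repeat with spanning reads is not flagged", {
  # genome containing S ... revcomp(S): reads spanning the junction exist
  withr::local_seed(74)
  s <- random_seq(1200, seed = 75)
  g <- paste0(random_seq(8000, seed = 76), s, random_seq(3000, seed = 77),
              revcomp(s), random_seq(8000, seed = 78))
  gen <- structure(list(seq = g, length = nchar(g), circular = FALSE,
                        repeat_truth = tibble::tibble(), mutations = tibble::tibble()),
                   class = "sx_genome")
  reads <- simulate_reads(gen, coverage = 30, error_rate = 0.01, seed = 79)
  cfg <- assembly_config(genome_size = nchar(g), seed = 80)
  tr <- trim_reads(reads, cfg)
  expect_lte(nrow(tr$hairpins), ceiling(0.02 * nrow(reads)))
})

test_that("chimeric junctions are found and reads trimmed to the larger side", {
  fx <- trim_fixture()
  reads <- inject_chimeras(fx$reads, frac = 0.05, min_distance = 15000,
                           seed = 81)
  cfg <- assembly_config(genome_size = 50000, seed = 82)
  tr <- trim_reads(reads, cfg)
  truth <- reads[reads$is_chimera, ]
  expect_gt(nrow(truth), 5)
  det <- tr$chimeras
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    j <- which(det$id == truth$id[i])
    if (length(j) > 0 &&
        min(abs(det$junction[j] - truth$chimera_junction[i])) <= 400) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / nrow(truth), 0.75)
  # larger-side rule: split reads keep their longest supported piece
  cl <- tr$clear_ranges
  split_ids <- intersect(cl$id[cl$status == "split"], truth$id)
  for (rid in split_ids) {
    i <- match(rid, truth$id)
    j <- match(rid, cl$id)
    junc <- truth$chimera_junction[i]
    len <- truth$length[i]
    kept <- c(cl$begin[j], cl$end[j])
    larger <- if (junc >= len / 2) c(0, junc) else c(junc, len)
    # the kept side is on the larger side of the junction
    expect_gt(min(kept[2], larger[2]) - max(kept[1], larger[1]), 0)
  }
  # false-positive splits among clean reads are rare
  clean <- setdiff(reads$id, truth$id)
  fp <- sum(cl$status[match(clean, cl$id)] == "split", na.rm = TRUE)
  expect_lte(fp / length(clean), 0.02)
})

test_that("trimming never enlarges the clear range", {
  fx <- trim_fixture()
  cfg <- assembly_config(genome_size = 50000, seed = 83)
  tr <- trim_reads(head(fx$reads, 120), cfg)
  cl <- tr$clear_ranges
  lens <- fx$reads$length[match(cl$id, fx$reads$id)]
  expect_true(all(cl$begin >= 0))
  expect_true(all(cl$end <= lens))
  expect_true(all(cl$end - cl$begin <= lens))
})
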