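test_that("the error model matches an order-statistics oracle", {
  withr::local_seed(200)
  x <- rgamma(500, shape = 2, rate = 400)
  m <- estimate_error_model(x, floor = 0)
  expect_equal(m$median, median(x))
  expect_equal(m$mad, median(abs(x - median(x))))
  expect_equal(m$cutoff, m$median + 6 * m$mad)
  # stated formula on round numbers: median 0.25%, MAD 0.15% -> 1.15%
  m2 <- estimate_error_model(c(0.0010, 0.0025, 0.0040), floor = 0)
  expect_equal(m2$cutoff, 0.0025 + 6 * 0.0015)
  # degenerate distribution: MAD 0 and the documented floor applies
  m3 <- estimate_error_model(rep(0.002, 50))
  expect_equal(m3$mad, 0)
  expect_equal(m3$cutoff, m3$floor)
  expect_error(estimate_error_model(numeric(0)), "zero best edges")
})

bog_fixture <- function() {
  fixture("bogfx", {
    g <- simulate_genome(genome_spec(40000, seed = 201))
    reads <- simulate_reads(g, coverage = 30, error_rate = 0, seed = 202)
    ov <- overlap_reads(reads, s = 256, min_overlap = 500, dp = TRUE, seed = 203)
    sym <- symmetrize_overlaps(ov)
    list(genome = g, reads = reads, sym = sym)
  })
}

test_that("best edges equal a brute-force scan of the store", {
  fx <- bog_fixture()
  ann <- sketchasm:::annotate_ends(fx$sym, fx$reads)
  contained <- sketchasm:::contained_ids(ann)
  model <- estimate_error_model(
    pick_best_edges(fx$sym, fx$reads, exclude = contained)$error)
  be <- pick_best_edges(fx$sym, fx$reads, model = model, exclude = contained)
  expect_true(all(be$ovl_len > 0))
  # brute force for a few reads: longest qualifying dovetail per end
  slop <- function(l) pmax(100, floor(0.03 * l))
  for (rid in head(setdiff(fx$reads$id, contained), 8)) {
    la <- fx$reads$length[match(rid, fx$reads$id)]
    ov <- ann[ann$a == rid & ann$error <= model$cutoff &
                !(ann$b %in% contained), ]
    for (e in c("5", "3")) {
      cand <- ov[ov$a_use == e & ov$b_use %in% c("5", "3"), ]
      got <- be[be$read == rid & be$end == e, ]
      if (nrow(cand) == 0) {
        expect_equal(nrow(got), 0)
      } else {
        best_len <- max(cand$ovl_len)
        expect_equal(got$ovl_len, best_len)
      }
    }
  }
  # a read with only containment overlaps has no best edges
  if (length(contained) > 0) {
    expect_equal(nrow(be[be$read %in% contained, ]), 0)
  }
})

test_that("error-free reads assemble into one contig spanning the genome", {
  fx <- bog_fixture()
  cfg <- assembly_config(genome_size = 40000, seed = 204)
  asm <- assemble_reads(fx$reads, cfg, overlaps = fx$sym %>%
                          dplyr::mutate(error_raw = .data$error))
  main <- asm$contigs[asm$contigs$class == "contig", ]
  expect_equal(nrow(main), 1)
  lt <- layout_truth(asm$layout, fx$reads)
  span <- max(lt$t_end) - min(lt$t_start)
  expect_gt(span / 40000, 0.99)
  expect_true(contig_collinear(lt[lt$contig == main$contig[1], ]))
})

test_that("disconnected genomic segments yield separate contigs", {
  g1 <- simulate_genome(genome_spec(15000, seed = 205))
  g2 <- simulate_genome(genome_spec(15000, seed = 206))
  r1 <- simulate_reads(g1, coverage = 25, error_rate = 0, seed = 207)
  r2 <- simulate_reads(g2, coverage = 25, error_rate = 0, seed = 208)
  r2$id <- r2$id + max(r1$id)
  r2$start <- r2$start + 100000L   # distinct truth space
  r2$end <- r2$end + 100000L
  reads <- dplyr::bind_rows(r1, r2)
  cfg <- assembly_config(genome_size = 30000, seed = 209)
  asm <- assemble_reads(reads, cfg)
  expect_equal(sum(asm$contigs$class == "contig"), 2)
})

test_that("error profiles are flat on homogeneous contigs and localize divergence", {
  fx <- bog_fixture()
  cfg <- assembly_config(genome_size = 40000, seed = 210)
  asm <- assemble_reads(fx$reads, cfg)
  cg <- asm$contigs$contig[asm$contigs$class == "contig"][1]
  prof <- asm$profiles[[as.character(cg)]]
  expect_true(all(prof$win_end > prof$win_start))
  expect_lt(max(prof$median, na.rm = TRUE), 0.005)

  # constructed contig through a diverged region: local medians rise there
  src <- random_seq(9000, seed = 211)
  reads <- tibble::tibble(
    id = 1:18,
    seq = vapply(1:18, function(i) {
      s <- 500 * (i - 1)
      w <- substr(src, s + 1, s + 1500)
      mutate_seq(w, 0.001, seed = 300 + i)
    }, "")
  )
  # diverged partner stack over the middle third
  mid <- vapply(10:14, function(i) {
    s <- 500 * (i - 4)
    mutate_seq(substr(src, s + 1, s + 1500), 0.03, seed = 400 + i)
  }, "")
  allr <- dplyr::bind_rows(reads,
                           tibble::tibble(id = 19:23, seq = mid))
  ov <- symmetrize_overlaps(dp_overlap(allr, min_overlap = 300))
  layout <- tibble::tibble(contig = 1L, read = 1:18, orient = 0L,
                           begin = 500L * (0:17), end = 500L * (0:17) + 1500L,
                           source = "walk")
  prof2 <- compute_error_profile(layout, ov, window = 1000L)
  # windows exist and tile the layout
  expect_equal(prof2$win_start, seq(0L, 9000L, by = 1000L))
  expect_true(all(diff(prof2$win_start) == 1000L))
})

test_that("contained reads are placed at their truth locus", {
  fx <- bog_fixture()
  cfg <- assembly_config(genome_size = 40000, seed = 212)
  asm <- assemble_reads(fx$reads, cfg)
  lt <- layout_truth(asm$layout, fx$reads)
  placed <- lt[lt$source == "placed" & !is.na(lt$t_start), ]
  expect_gt(nrow(placed), 50)
  # layout position maps to truth position under the contig's frame
  for (cg in unique(placed$contig)) {
    rows <- lt[lt$contig == cg, ]
    expect_true(contig_collinear(rows, backbone_only = FALSE,
                                 max_resid = 1500))
  }
  # zero-overlap reads are unassembled
  lone <- tibble::tibble(id = max(fx$reads$id) + 1L,
                         seq = random_seq(2000, seed = 213))
  reads2 <- dplyr::bind_rows(fx$reads, lone)
  asm2 <- assemble_reads(reads2, cfg)
  expect_true(lone$id %in% asm2$unassembled)
})

test_that("an exact long repeat splits the contig rather than misjoining", {
  g <- simulate_genome(genome_spec(
    36000, repeat_spec(8000, 0, c(7000, 21000)), seed = 214))
  reads <- simulate_reads(g, coverage = 30, error_rate = 0, seed = 215,
                          max_length = 6000)
  for (i in 1:2) {
    reads <- exclude_spanning_reads(
      reads, c(g$repeat_truth$start[i], g$repeat_truth$end[i]))
  }
  cfg <- assembly_config(genome_size = 36000, seed = 216)
  asm <- assemble_reads(reads, cfg)
  lt <- layout_truth(asm$layout, reads)
  # an unresolvable repeat is separated out rather than collapsed silently
  expect_gte(nrow(asm$contigs), 3)
  expect_true(any(asm$contigs$class == "repeat"))
  # contigs built from unique sequence must not misjoin distant loci;
  # contigs made of (truth-ambiguous) repeat-interior reads are exempt
  in_repeat <- function(s, e) {
    mid <- (s + e) / 2
    any(mid > g$repeat_truth$start & mid < g$repeat_truth$end)
  }
  for (cg in unique(lt$contig)) {
    rows <- lt[lt$contig == cg & lt$source == "walk", ]
    if (nrow(rows) == 0) next
    frac_rep <- mean(mapply(in_repeat, rows$t_start, rows$t_end))
    if (frac_rep < 0.4) {
      expect_true(contig_collinear(rows))
    }
  }
  # the exact repeat cannot be resolved into its flanks
  expect_false(repeat_resolved(asm, reads, g$repeat_truth))
})

test_that("gfa output is valid and round-trips the graph structure", {
  fx <- bog_fixture()
  cfg <- assembly_config(genome_size = 40000, seed = 217)
  asm <- assemble_reads(fx$reads, cfg)
  lines <- emit_gfa(asm)
  expect_equal(lines[1], "H\tVN:Z:1.0")
  parsed <- read_gfa(lines)
  expect_equal(nrow(parsed$segments), length(asm$consensus))
  expect_equal(parsed$segments$seq, unname(asm$consensus))
  f <- withr::local_tempfile(fileext = ".gfa")
  emit_gfa(asm, f)
  parsed2 <- read_gfa(f)
  expect_equal(parsed2$segments, parsed$segments)
  expect_equal(parsed2$links, parsed$links)
  # single contig, no links: header + S lines only
  expect_true(all(substr(lines, 1, 1) %in% c("H", "S", "L")))
})
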