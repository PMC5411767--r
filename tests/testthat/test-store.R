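ov_fixture <- function(n = 30, n_reads = 10, seed = 50) {
  withr::with_seed(seed, {
    a <- sample.int(n_reads, n, TRUE)
    b <- ((a + sample.int(n_reads - 1, n, TRUE) - 1) %% n_reads) + 1
    tibble::tibble(
      a = a, b = b,
      a_start = sample.int(2000, n), a_end = 0L, b_start = sample.int(2000, n),
      b_end = 0L, orient = sample(c("+", "-"), n, TRUE),
      error = runif(n, 0, 0.05),
      kind = sample(c("dovetail", "containment"), n, TRUE),
      evidence = "dp"
    ) %>% dplyr::mutate(a_end = .data$a_start + 1000L,
                        b_end = .data$b_start + 1000L)
  })
}

test_that("an empty input builds a valid empty store", {
  st <- build_store(sketchasm:::empty_overlaps())
  expect_s3_class(st, "overlap_store")
  expect_equal(st$n_records, 0)
  expect_equal(nrow(store_dump(st)), 0)
  expect_equal(nrow(get_overlaps(st, 1L)), 0)
})

test_that("every overlap is stored twice and reconstructs the input", {
  ov <- tibble::tibble(
    a = c(1L, 1L, 2L), b = c(2L, 3L, 3L),
    a_start = c(0L, 100L, 50L), a_end = c(900L, 1000L, 950L),
    b_start = c(10L, 0L, 0L), b_end = c(910L, 900L, 900L),
    orient = c("+", "-", "+"), error = c(0.01, 0.02, 0.03),
    kind = c("dovetail", "dovetail", "containment"), evidence = "dp"
  )
  st <- build_store(ov)
  expect_equal(st$n_records, 6)
  all3 <- dplyr::bind_rows(get_overlaps(st, 1L), get_overlaps(st, 2L),
                           get_overlaps(st, 3L))
  expect_equal(nrow(all3), 6)
  # the A->B half reconstructs the input set
  half <- all3 %>% dplyr::filter(.data$a < .data$b) %>%
    dplyr::arrange(.data$a, .data$b)
  expect_equal(half, ov %>% dplyr::arrange(.data$a, .data$b))
})

test_that("bucket-sorted stores equal the in-memory sort oracle byte for byte", {
  ov <- ov_fixture(n = 400, n_reads = 25)
  # in-memory oracle: symmetrize and globally sort
  oracle <- symmetrize_overlaps(ov) %>%
    dplyr::arrange(.data$a, .data$b, .data$a_start)
  paths <- character(0)
  for (buckets in c(1, 4, 16)) {
    cap <- max(1, ceiling(2 * nrow(ov) / buckets))
    p <- withr::local_tempfile()
    st <- build_store(ov, path = p, max_bucket_size = cap)
    expect_equal(store_dump(st) %>% as.data.frame(),
                 oracle %>% as.data.frame())
    paths <- c(paths, p)
  }
  raw1 <- readBin(paths[1], "raw", file.size(paths[1]))
  for (p in paths[-1]) {
    expect_identical(readBin(p, "raw", file.size(p)), raw1)
  }
})

test_that("get_overlaps matches a brute-force filter and survives reopen", {
  ov <- ov_fixture(n = 120, n_reads = 12, seed = 51)
  p <- withr::local_tempfile()
  st <- build_store(ov, path = p, max_bucket_size = 40)
  sym <- symmetrize_overlaps(ov)
  for (rid in 1:12) {
    want <- sym %>% dplyr::filter(.data$a == rid) %>%
      dplyr::arrange(.data$a, .data$b, .data$a_start)
    got <- get_overlaps(st, rid)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
  # idempotent across reopen
  st2 <- open_store(p)
  expect_equal(store_dump(st2), store_dump(st))
  # unknown read id: empty
  expect_equal(nrow(get_overlaps(st, 999L)), 0)
})

test_that("records referencing unknown reads are rejected with a diagnostic", {
  ov <- ov_fixture(n = 10, n_reads = 5)
  expect_error(build_store(ov, known_ids = 1:3), "unknown read id")
})

test_that("accepted overlap inputs may arrive as multiple files", {
  ov <- ov_fixture(n = 60, n_reads = 10, seed = 52)
  st1 <- build_store(ov)
  st2 <- build_store(list(ov[1:30, ], ov[31:60, ]))
  expect_equal(store_dump(st1), store_dump(st2))
})
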