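test_that("k-mer counting is exact and strand-canonical", {
  sp <- count_kmers("AAAA", k = 2, filter_cutoff = 1)
  expect_equal(sp$f_max, 3)          # "AA" occurs 3 times
  expect_equal(nrow(sp$recorded), 1)
  expect_equal(sp$recorded$count, 3)

  r <- random_seq(500, seed = 20)
  s1 <- count_kmers(r, k = 7, filter_cutoff = 1)
  s2 <- count_kmers(revcomp(r), k = 7, filter_cutoff = 1)
  expect_identical(s1$recorded, s2$recorded)
})

test_that("the recorded set equals the top-cutoff fraction of an exhaustive count", {
  withr::local_seed(21)
  reads <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), "")
  k <- 6L
  # exhaustive canonical counter oracle in R
  canon <- function(km) {
    rc <- revcomp(km)
    ifelse(km <= rc, km, rc)
  }
  all_kmers <- unlist(lapply(reads, function(s) {
    n <- nchar(s)
    canon(substring(s, 1:(n - k + 1), k:n))
  }))
  tab <- table(all_kmers)
  frac <- 0.01
  n_rec <- ceiling(frac * length(tab))
  thr <- sort(as.integer(tab), decreasing = TRUE)[n_rec]
  oracle <- names(tab)[as.integer(tab) >= thr]

  sp <- count_kmers(reads, k = k, filter_cutoff = frac)
  expect_equal(sp$f_max, max(as.integer(tab)))
  expect_setequal(sp$recorded$hash, kmer_hash(oracle))
  expect_equal(sort(sp$recorded$count),
               sort(as.integer(tab[as.integer(tab) >= thr])))
})

test_that("idf weights follow the rescaled log formula", {
  withr::local_seed(22)
  reads <- c(strrep("ACGT", 500),          # makes some k-mers frequent
             vapply(1:30, function(i)
               paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""), ""))
  sp <- count_kmers(reads, k = 8, filter_cutoff = 0.05)
  pars <- tfidf_params(a = 0.9, idf_max = 3)
  rec <- sp$recorded
  # endpoint: the most frequent k-mer gets the minimum weight 1
  top <- rec$hash[which.max(rec$count)]
  expect_equal(idf(top, sp, pars), 1L)
  # absent k-mers get idf_max
  absent <- kmer_hash("AAAAAAAG")
  if (!absent %in% rec$hash) {
    expect_equal(idf(absent, sp, pars), 3L)
  }
  # scalar formula oracle for recorded k-mers
  lo <- log(1 - pars$a)
  hi <- log(sp$f_max / sp$f_cut - pars$a)
  oracle <- function(fq) {
    x <- log(sp$f_max / fq - pars$a)
    x <- min(max(x, lo), hi)
    w <- floor(1 + (pars$idf_max - 1) * (x - lo) / (hi - lo) + 0.5)
    as.integer(min(max(w, 1), pars$idf_max))
  }
  got <- idf(rec$hash, sp, pars)
  expect_equal(got, vapply(rec$count, oracle, integer(1)))
  # monotone non-increasing in frequency
  ord <- order(rec$count)
  expect_true(all(diff(got[ord]) <= 0 | diff(rec$count[ord]) == 0))
})

test_that("tf-idf weights equal the brute-force tf x idf table", {
  read <- paste0(strrep("ACGTACGTTG", 3), random_seq(60, seed = 23))
  sp <- count_kmers(read, k = 5, filter_cutoff = 1)
  pars <- tfidf_params(tf_cap = 4)
  n <- nchar(read)
  kmers <- substring(read, 1:(n - 4), 5:n)
  h <- kmer_hash(kmers)
  tf <- table(h)
  for (q in names(head(tf, 10))) {
    w <- tf_idf(as.numeric(q), read, sp, pars)
    expect_equal(w, min(as.integer(tf[[q]]), 4) * idf(as.numeric(q), sp, pars))
  }
})

test_that("uniform weights reduce the weighted sketch to plain MinHash", {
  rs <- clean_reads_20k()
  reads <- head(rs$reads, 6)
  sp <- count_kmers(reads, filter_cutoff = 0)
  # idf_max = 1, tf_cap = 1 forces weight 1 everywhere (tf-idf path);
  # the threshold mode with no exclusions is an independent weight-1 path
  s1 <- build_sketch(reads, sp, s = 64,
                     params = tfidf_params(idf_max = 1, tf_cap = 1), seed = 9)
  s2 <- build_sketch(reads, sp, s = 64, seed = 9,
                     filter_mode = "threshold", max_count = Inf)
  expect_identical(s1$mat, s2$mat)
  # identical reads sketch identically
  two <- reads[c(1, 1), ]
  two$id <- 1:2
  sk <- build_sketch(two, sp, s = 64, seed = 9)
  expect_equal(sketch_similarity(sk, 1, 2), 1)
})

test_that("sketch similarity estimates the exact weighted Jaccard", {
  # constructed k-mer multisets via two overlapping synthetic reads
  a <- paste0(random_seq(400, seed = 24), random_seq(400, seed = 25))
  b <- paste0(random_seq(400, seed = 25), random_seq(400, seed = 26))
  rt <- tibble::tibble(id = 1:2, seq = c(a, b))
  sp <- count_kmers(rt, k = 12, filter_cutoff = 0.02)
  pars <- tfidf_params()

  # exact weighted Jaccard oracle: sum(min w) / sum(max w); numeric hash
  # keys must never pass through character conversion (53-bit values)
  weights_of <- function(s) {
    kh <- sketchasm:::read_kmer_hashes_cpp(s, 12L)$hash
    u <- sort(unique(kh))
    tf <- tabulate(match(kh, u), nbins = length(u))
    list(h = u, w = pmin(tf, pars$tf_cap) * idf(u, sp, pars))
  }
  wa <- weights_of(a)
  wb <- weights_of(b)
  keys <- union(wa$h, wb$h)
  va <- vb <- numeric(length(keys))
  va[match(wa$h, keys)] <- wa$w
  vb[match(wb$h, keys)] <- wb$w
  exact <- sum(pmin(va, vb)) / sum(pmax(va, vb))

  s <- 256
  est <- vapply(1:50, function(seed) {
    sk <- build_sketch(rt, sp, s = s, params = pars, seed = seed)
    sketch_similarity(sk, 1, 2)
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - exact), 3 * se + 1e-8)
})

test_that("bottom sketches are substring-consistent and merge to exact Jaccard", {
  r <- random_seq(4000, seed = 27)
  bs <- build_bottom_sketch(r, k = 16, size = 1500)
  # read with fewer distinct k-mers than the sketch size keeps them all
  small <- build_bottom_sketch(substr(r, 1, 300), k = 16, size = 1500)
  expect_equal(length(small$sketches[[1]]$val), 300 - 16 + 1)
  # substring sketch values are a subset of the full-read sketch values
  sub <- build_bottom_sketch(substr(r, 1001, 3000), k = 16, size = 1500)
  expect_true(all(sub$sketches[[1]]$val %in%
                    build_bottom_sketch(r, k = 16, size = 4000)$sketches[[1]]$val))

  # merged bottom sketches estimate the exact Jaccard of full k-mer sets
  r2 <- paste0(substr(r, 2001, 4000), random_seq(2000, seed = 28))
  ka <- unique(sketchasm:::read_kmer_hashes_cpp(r, 16L)$hash)
  kb <- unique(sketchasm:::read_kmer_hashes_cpp(r2, 16L)$hash)
  exact <- length(intersect(ka, kb)) / length(union(ka, kb))
  both <- build_bottom_sketch(c(r, r2), k = 16, size = 1000)
  va <- both$sketches[[1]]$val
  vb <- both$sketches[[2]]$val
  merged <- sort(union(va, vb))[1:1000]
  j <- sum(merged %in% va & merged %in% vb) / 1000
  expect_lt(abs(j - exact), 3 * sqrt(exact * (1 - exact) / 1000) + 0.01)
})

test_that("tf-idf weighting flattens a 100x overrepresented k-mer family", {
  withr::local_seed(29)
  unit <- random_seq(300, seed = 30)
  # plasmid-like overrepresented family plus unique background
  reads <- c(replicate(60, mutate_seq(unit, 0.02, seed = sample.int(1e6, 1))),
             vapply(1:40, function(i)
               paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), ""))
  rt <- tibble::tibble(id = seq_along(reads), seq = reads)
  sp <- count_kmers(rt, k = 12, filter_cutoff = 0.02)

  gini <- function(x) {
    x <- sort(x)
    n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  # per-k-mer inclusion counts across all sketches: uniform means every
  # distinct k-mer is equally likely to be indexed
  inclusion_counts <- function(sk) {
    v <- as.vector(sk$mat)
    v <- v[!is.na(v)]
    u <- sort(unique(v))
    tabulate(match(v, u), nbins = length(u))
  }
  sk_w <- build_sketch(rt, sp, s = 32, seed = 31)
  sk_u <- build_sketch(rt, sp, s = 32, seed = 31,
                       params = tfidf_params(idf_max = 1, tf_cap = 1))
  expect_lt(gini(inclusion_counts(sk_w)), gini(inclusion_counts(sk_u)))
})

test_that("spectrum files round-trip", {
  rs <- clean_reads_20k()
  sp <- count_kmers(head(rs$reads, 10), k = 16, filter_cutoff = 0.01)
  f <- withr::local_tempfile()
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$recorded, sp$recorded)
  expect_equal(back$k, sp$k)
  expect_equal(back$f_max, sp$f_max)
  expect_error(read_spectrum(withr::local_tempfile(lines = "not a spectrum")),
               "magic")
})
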