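#' tf-idf weighting parameters
#'
#' @param a Preference exponent in [0, 1]; controls how strongly less common
#'   k-mers are preferred (default 0.9).
#' @param idf_max Maximum integer idf weight (default 3).
#' @param tf_cap Cap on the term-frequency factor, so the total hash
#'   evaluations per k-mer and slot never exceed `tf_cap * idf_max`.
#' @param cutoff_as How the upper endpoint of the idf rescaling is obtained:
#'   `"count"` plugs in the observed count at the filter cutoff rank,
#'   `"fraction"` plugs in `filter_cutoff * total k-mer instances`.
#' @return A `tfidf_params` list.
#' @export
tfidf_params <- function(a = 0.9, idf_max = 3L, tf_cap = 4L,
                         cutoff_as = c("count", "fraction")) {
  if (a < 0 || a > 1) abort("a must be in [0, 1]")
  idf_max <- as.integer(idf_max)
  if (idf_max < 1) abort("idf_max must be a positive integer")
  structure(
    list(a = a, idf_max = idf_max, tf_cap = as.integer(tf_cap),
         cutoff_as = match.arg(cutoff_as)),
    class = "tfidf_params"
  )
}

#' Count canonical k-mers and record the most abundant fraction
#'
#' Counts strand-canonical k-mers (a k-mer and its reverse complement share
#' one count) across all reads and records counts only for the
#' `filter_cutoff` most abundant fraction of distinct k-mers; all other
#' k-mers are implicitly assigned the minimum observed frequency and receive
#' the maximum idf weight.
#'
#' @param reads Read tibble or character vector of sequences.
#' @param k K-mer size (<= 31).
#' @param filter_cutoff Fraction of distinct k-mers to record (default
#'   5e-6). Ties at the cutoff count are all recorded.
#' @return A `kmer_spectrum` object.
#' @export
count_kmers <- function(reads, k = 16L, filter_cutoff = 5e-6) {
  reads <- as_read_tbl(reads)
  k <- as.integer(k)
  if (k < 1L || k > 31L) abort("k must be in [1, 31]")
  if (all(reads$length < k)) abort("k is longer than every read")
  sp <- count_kmers_cpp(reads$seq, k, filter_cutoff)
  structure(
    list(k = k, filter_cutoff = filter_cutoff,
         recorded = tibble(hash = sp$hash, count = sp$count),
         f_max = sp$f_max, f_min = sp$f_min, f_cut = sp$f_cut,
         n_distinct = sp$n_distinct, total = sp$total),
    class = "kmer_spectrum"
  )
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("<kmer_spectrum> k=", x$k, ", ", format(x$n_distinct, big.mark = ","),
      " distinct k-mers, ", nrow(x$recorded), " recorded (cutoff ",
      format(x$filter_cutoff), "), f_max=", x$f_max, "\n", sep = "")
  invisible(x)
}

#' Canonical k-mer hash
#'
#' The fixed 53-bit base hash used to index k-mers everywhere in the
#' package; a k-mer and its reverse complement hash identically.
#'
#' @param kmers Character vector of k-mer strings.
#' @return Numeric vector of hashes.
#' @export
kmer_hash <- function(kmers) kmer_hash_cpp(as.character(kmers))

as_query_hash <- function(q) {
  if (is.character(q)) kmer_hash(q) else as.numeric(q)
}

#' Inverse document frequency weight of k-mers
#'
#' Implements `idf_q = T(log(f_max / f_q - a))` with `T` the linear
#' rescaling onto `[1, idf_max]` followed by round-half-up to an integer.
#' K-mers absent from the recorded spectrum receive `idf_max`.
#'
#' @param q K-mer strings or hashes.
#' @param spectrum A [count_kmers()] spectrum.
#' @param params [tfidf_params()].
#' @return Integer weights in `[1, idf_max]`.
#' @export
idf <- function(q, spectrum, params = tfidf_params()) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  qh <- as_query_hash(q)
  rec <- spectrum$recorded
  hit <- match(qh, rec$hash)
  fq <- rec$count[hit]
  if (any(!is.na(fq) & fq > spectrum$f_max))
    abort("recorded k-mer frequency exceeds f_max (corrupt spectrum)")
  idf_weights_cpp(qh, rec$hash, rec$count, spectrum$f_max, spectrum$f_cut,
                  spectrum$total, params$a, params$idf_max,
                  if (params$cutoff_as == "count") 0L else 1L,
                  spectrum$filter_cutoff)
}

#' tf-idf weight of k-mers within a read
#'
#' `w_q = min(tf_q, tf_cap) * idf_q`, where `tf_q` is the number of
#' occurrences of the (canonical) k-mer in the read.
#'
#' @inheritParams idf
#' @param read A single read sequence.
#' @return Integer weights.
#' @export
tf_idf <- function(q, read, spectrum, params = tfidf_params()) {
  qh <- as_query_hash(q)
  kh <- read_kmer_hashes_cpp(as.character(read), spectrum$k)$hash
  tf <- vapply(qh, function(h) sum(kh == h), numeric(1))
  pmin(tf, params$tf_cap) * idf(qh, spectrum, params)
}

#' Build weighted MinHash sketches
#'
#' For sketch slot `i`, a k-mer with discrete weight `w` is hashed `w` times
#' using a seeded xorshift stream keyed on the slot constant and the k-mer's
#' fixed base hash, and the slot stores the base hash of the k-mer attaining
#' the minimum draw.  Higher-weighted k-mers are therefore more likely to be
#' selected, while identical k-mers still match across reads regardless of
#' weight.
#'
#' @param reads Read tibble or character vector.
#' @param spectrum [count_kmers()] spectrum (defines `k`).
#' @param s Sketch size (number of slots).
#' @param params [tfidf_params()].
#' @param seed Sketch seed (integer).
#' @param filter_mode `"tfidf"` for adaptive weighting (default) or
#'   `"threshold"` for the classical all-or-nothing filter that excludes
#'   k-mers whose recorded count exceeds `max_count`.
#' @param max_count Count threshold for `filter_mode = "threshold"`.
#' @return An `sx_sketches` object.
#' @export
build_sketch <- function(reads, spectrum, s = 512L, params = tfidf_params(),
                         seed = 1L, filter_mode = c("tfidf", "threshold"),
                         max_count = Inf) {
  reads <- as_read_tbl(reads)
  filter_mode <- match.arg(filter_mode)
  s <- as.integer(s)
  if (s < 1L) abort("sketch size s must be >= 1")
  rec <- spectrum$recorded
  mat <- build_sketches_cpp(
    reads$seq, spectrum$k, s, rec$hash, rec$count,
    as.numeric(spectrum$f_max), as.numeric(spectrum$f_cut), spectrum$total,
    params$a, params$idf_max, params$tf_cap,
    if (params$cutoff_as == "count") 0L else 1L, spectrum$filter_cutoff,
    as.integer(seed), if (filter_mode == "tfidf") 0L else 1L,
    as.numeric(max_count)
  )
  structure(
    list(mat = mat, id = reads$id, k = spectrum$k, s = s, seed = as.integer(seed),
         filter_mode = filter_mode),
    class = "sx_sketches"
  )
}

#' Estimated similarity between two sketched reads
#'
#' The fraction of matching sketch slots, an unbiased estimate of the
#' weighted Jaccard similarity of the two reads' weighted k-mer sets.
#'
#' @param sketches [build_sketch()] result.
#' @param a,b Read ids.
#' @return Numeric scalar in [0, 1].
#' @export
sketch_similarity <- function(sketches, a, b) {
  ia <- match(a, sketches$id)
  ib <- match(b, sketches$id)
  va <- sketches$mat[, ia]
  vb <- sketches$mat[, ib]
  mean(!is.na(va) & !is.na(vb) & va == vb)
}

#' Build bottom sketches
#'
#' A bottom sketch keeps the `size` smallest distinct canonical k-mer hashes
#' of a read under a single hash function, together with the k-mer's first
#' position in the read.  Any substring's bottom sketch is obtained by
#' eliminating min-mers that do not occur in the substring.
#'
#' @param reads Read tibble or character vector.
#' @param k K-mer size.
#' @param size Sketch size (default 1500).
#' @return An `sx_bottom` object.
#' @export
build_bottom_sketch <- function(reads, k = 16L, size = 1500L) {
  reads <- as_read_tbl(reads)
  sk <- bottom_sketches_cpp(reads$seq, as.integer(k), as.integer(size))
  structure(
    list(sketches = sk, id = reads$id, length = reads$length,
         k = as.integer(k), size = as.integer(size)),
    class = "sx_bottom"
  )
}

# ---------------------------------------------------------------------------
# spectrum persistence: small binary format
# (magic, version, k, cutoff, f_max, f_min, f_cut, n_distinct, total,
#  n_recorded, then sorted hash/count pairs)
# ---------------------------------------------------------------------------

#' Write a k-mer spectrum to a small binary file
#' @param spectrum A `kmer_spectrum`.
#' @param path Output path.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("KSPC", con, nchars = 4, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(spectrum$k, con, size = 4, endian = "little")
  writeBin(as.numeric(c(spectrum$filter_cutoff, spectrum$f_max, spectrum$f_min,
                        spectrum$f_cut, spectrum$n_distinct, spectrum$total)),
           con, size = 8, endian = "little")
  writeBin(nrow(spectrum$recorded), con, size = 4, endian = "little")
  writeBin(spectrum$recorded$hash, con, size = 8, endian = "little")
  writeBin(as.integer(spectrum$recorded$count), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a k-mer spectrum written by [write_spectrum()]
#' @param path Input path.
#' @return A `kmer_spectrum`.
#' @export
read_spectrum <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "KSPC")) abort("not a spectrum file (bad magic)")
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ver != 1L) abort("unsupported spectrum version")
  k <- readBin(con, "integer", 1, size = 4, endian = "little")
  num <- readBin(con, "numeric", 6, size = 8, endian = "little")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  hash <- readBin(con, "numeric", n, size = 8, endian = "little")
  count <- readBin(con, "integer", n, size = 4, endian = "little")
  structure(
    list(k = k, filter_cutoff = num[1],
         recorded = tibble(hash = hash, count = count),
         f_max = num[2], f_min = num[3], f_cut = num[4],
         n_distinct = num[5], total = num[6]),
    class = "kmer_spectrum"
  )
}
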