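#' Mash distance from a Jaccard estimate
#'
#' `d = -(1/k) * ln(2j / (1 + j))`, clamped to `[0, 1]`; `j = 0` maps to 1.
#'
#' @param j Jaccard similarity in [0, 1].
#' @param k K-mer size.
#' @return Estimated per-base error rate (divergence).
#' @export
mash_distance <- function(j, k) {
  vapply(j, function(x) mash_distance_cpp(x, as.integer(k)), numeric(1))
}

#' First-stage overlap candidates from weighted sketches
#'
#' Reports a read pair as a candidate when at least `min_slot_matches` of
#' their sketch slots hold the same min-mer.  Symmetric; self-pairs are
#' excluded.
#'
#' @param sketches [build_sketch()] result (all reads sketched with the same
#'   k, s and seed).
#' @param min_slot_matches Minimum matching slots (default 2, chosen so the
#'   binomial null gives well under 1e-3 expected false candidates per pair
#'   at s = 512).
#' @param max_bucket Slot-value buckets larger than this are skipped
#'   (guards against degenerate low-complexity values).
#' @return Tibble with `a`, `b` (read ids, a < b in sketch order) and
#'   `matches`.
#' @export
find_candidates <- function(sketches, min_slot_matches = 2L, max_bucket = 4096L) {
  stopifnot(inherits(sketches, "sx_sketches"))
  res <- find_candidates_cpp(sketches$mat, as.integer(min_slot_matches),
                             as.integer(max_bucket))
  tibble(a = sketches$id[res$a], b = sketches$id[res$b], matches = res$m)
}

#' Second-stage overlap estimation from bottom sketches
#'
#' For each candidate pair, shared min-mers give the relative orientation
#' (position consistency under the same vs flipped transform), the overlap
#' extent (median offset of consistent shared min-mers), and the error rate
#' (Mash distance of the Jaccard computed on the overlap substrings'
#' sketches).
#'
#' @param bottoms [build_bottom_sketch()] result.
#' @param pairs Tibble with `a`, `b` read id columns (e.g. from
#'   [find_candidates()]).
#' @param min_shared Minimum consistent shared min-mers (default 2).
#' @param min_overlap Minimum estimated overlap length to report.
#' @return Overlap tibble: `a`, `b`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open, forward-strand coordinates on each read),
#'   `orient` ("+" same / "-" flipped), `error`, `jaccard`, `shared`,
#'   `kind` ("dovetail"/"containment"), `evidence = "sketch"`.
#' @export
estimate_overlap <- function(bottoms, pairs, min_shared = 2L, min_overlap = 500L) {
  stopifnot(inherits(bottoms, "sx_bottom"))
  if (nrow(pairs) == 0) return(empty_overlaps())
  ia <- match(pairs$a, bottoms$id)
  ib <- match(pairs$b, bottoms$id)
  est <- estimate_overlaps_cpp(bottoms$sketches, ia, ib, bottoms$length,
                               bottoms$k, bottoms$size, as.integer(min_shared))
  out <- tibble(
    a = pairs$a, b = pairs$b,
    a_start = est$a_start, a_end = est$a_end,
    b_start = est$b_start, b_end = est$b_end,
    orient = ifelse(est$orient == 1L, "-", "+"),
    error = est$error, jaccard = est$jaccard, shared = est$shared,
    kind = kind_label(est$kind), evidence = "sketch",
    ok = est$ok == 1L
  )
  out <- filter(out, .data$ok,
                pmax(.data$a_end - .data$a_start,
                     .data$b_end - .data$b_start) >= min_overlap)
  select(out, -"ok")
}

#' Confirm overlaps with a banded gapped alignment
#'
#' Runs a banded overlap alignment (free end gaps, band centred on the
#' estimated diagonal and sized from the estimated error rate) for each
#' overlap record and replaces extents and error rates with exact,
#' edit-distance-based values (`error = edits / alignment columns`).
#' Overlaps whose alignment fails or falls below `min_overlap` are dropped.
#'
#' @param reads Read tibble.
#' @param overlaps Overlap tibble with sketch-estimated extents (hints).
#' @param min_band,max_band Band half-width bounds.
#' @param min_overlap Minimum confirmed overlap length.
#' @return Overlap tibble with `evidence = "dp"`, `nmatch`, `nedit`, `cols`
#'   columns and `kind` including `"partial"` for alignments that stop short
#'   of the read ends (e.g. at a repeat boundary).
#' @export
dp_overlap <- function(reads, overlaps = NULL, min_band = 50L, max_band = 800L,
                       min_overlap = 500L) {
  reads <- as_read_tbl(reads)
  if (is.null(overlaps)) {
    bottoms <- build_bottom_sketch(reads)
    pairs <- tidyr::expand_grid(a = reads$id, b = reads$id) %>%
      filter(.data$a < .data$b)
    overlaps <- estimate_overlap(bottoms, pairs, min_overlap = min_overlap)
  }
  if (nrow(overlaps) == 0) return(empty_overlaps(dp = TRUE))
  ia <- read_index(reads, overlaps$a)
  ib <- read_index(reads, overlaps$b)
  res <- dp_overlap_batch_cpp(
    reads$seq, ia, ib, as.integer(overlaps$orient == "-"),
    as.integer(overlaps$a_start), as.integer(overlaps$a_end),
    as.integer(overlaps$b_start), as.integer(overlaps$b_end),
    as.numeric(overlaps$error), as.integer(min_band), as.integer(max_band),
    as.integer(min_overlap)
  )
  out <- tibble(
    a = overlaps$a, b = overlaps$b,
    a_start = res$a_start, a_end = res$a_end,
    b_start = res$b_start, b_end = res$b_end,
    orient = overlaps$orient,
    error = res$error, nmatch = res$nmatch, nedit = res$nedit,
    cols = res$cols, kind = kind_label(res$kind), evidence = "dp",
    ok = res$ok == 1L
  )
  out <- filter(out, .data$ok,
                pmax(.data$a_end - .data$a_start,
                     .data$b_end - .data$b_start) >= min_overlap)
  select(out, -"ok")
}

empty_overlaps <- function(dp = FALSE) {
  base <- tibble(
    a = integer(), b = integer(), a_start = integer(), a_end = integer(),
    b_start = integer(), b_end = integer(), orient = character(),
    error = numeric()
  )
  if (dp) {
    base$nmatch <- integer(); base$nedit <- integer(); base$cols <- integer()
  } else {
    base$jaccard <- numeric(); base$shared <- integer()
  }
  base$kind <- character(); base$evidence <- character()
  base
}

#' One-call overlapper: sketch, filter, estimate, optionally confirm
#'
#' @param reads Read tibble.
#' @param k K-mer size.
#' @param s Sketch size.
#' @param filter_cutoff Spectrum filter cutoff fraction.
#' @param params [tfidf_params()].
#' @param min_slot_matches First-stage threshold.
#' @param bottom_size Bottom sketch size.
#' @param min_overlap Minimum overlap length.
#' @param dp Confirm with gapped alignment?
#' @param seed Sketch seed.
#' @param filter_mode,max_count Passed to [build_sketch()].
#' @return Overlap tibble (sketch-estimated or DP-confirmed).
#' @export
overlap_reads <- function(reads, k = 16L, s = 512L, filter_cutoff = 5e-6,
                          params = tfidf_params(), min_slot_matches = 2L,
                          bottom_size = 1500L, min_overlap = 500L, dp = FALSE,
                          seed = 1L, filter_mode = "tfidf", max_count = Inf) {
  reads <- as_read_tbl(reads)
  spectrum <- count_kmers(reads, k = k, filter_cutoff = filter_cutoff)
  sk <- build_sketch(reads, spectrum, s = s, params = params, seed = seed,
                     filter_mode = filter_mode, max_count = max_count)
  cand <- find_candidates(sk, min_slot_matches = min_slot_matches)
  bottoms <- build_bottom_sketch(reads, k = k, size = bottom_size)
  ov <- estimate_overlap(bottoms, cand, min_overlap = min_overlap)
  if (dp) ov <- dp_overlap(reads, ov, min_overlap = min_overlap)
  ov
}

#' Duplicate overlaps with read roles swapped
#'
#' Every overlap A-B is also stored as B-A (same alignment, swapped roles),
#' so all overlaps of any read can be listed together.
#'
#' @param overlaps Overlap tibble.
#' @return Overlap tibble with both orientations of each record.
#' @export
symmetrize_overlaps <- function(overlaps) {
  swapped <- overlaps
  swapped$a <- overlaps$b
  swapped$b <- overlaps$a
  swapped$a_start <- overlaps$b_start
  swapped$a_end <- overlaps$b_end
  swapped$b_start <- overlaps$a_start
  swapped$b_end <- overlaps$a_end
  bind_rows(overlaps, swapped) %>%
    arrange(.data$a, .data$b, .data$a_start)
}

# ---------------------------------------------------------------------------
# PAF-compatible serialization
# ---------------------------------------------------------------------------

#' Write overlaps in PAF-compatible form
#'
#' Columns: query, qlen, qstart, qend, strand, target, tlen, tstart, tend,
#' residue matches, block length, mapq, plus `er:f:` (error rate), `tp:A:`
#' (kind code) and `ev:Z:` (evidence stage) tags.
#'
#' @param overlaps Overlap tibble.
#' @param reads Read tibble (for lengths).
#' @param path Output path.
#' @export
write_paf <- function(overlaps, reads, path) {
  reads <- as_read_tbl(reads)
  la <- reads$length[read_index(reads, overlaps$a)]
  lb <- reads$length[read_index(reads, overlaps$b)]
  nmatch <- overlaps$nmatch %||% NA_integer_
  cols <- overlaps$cols %||% NA_integer_
  blk <- ifelse(is.na(cols), pmax(overlaps$a_end - overlaps$a_start,
                                  overlaps$b_end - overlaps$b_start), cols)
  nm <- ifelse(is.na(nmatch), round(blk * (1 - overlaps$error)), nmatch)
  lines <- paste(
    overlaps$a, la, overlaps$a_start, overlaps$a_end, overlaps$orient,
    overlaps$b, lb, overlaps$b_start, overlaps$b_end,
    nm, blk, 255L,
    paste0("er:f:", format(overlaps$error, digits = 6, scientific = FALSE, trim = TRUE)),
    paste0("tp:A:", substr(overlaps$kind, 1, 1)),
    paste0("ev:Z:", overlaps$evidence),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read overlaps written by [write_paf()]
#' @param path Input path.
#' @return Overlap tibble.
#' @export
read_paf <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (nrow(x) == 0) return(empty_overlaps())
  kindmap <- c(d = "dovetail", c = "containment", p = "partial")
  get_tag <- function(row, prefix) {
    v <- as.character(row[13:15])
    hit <- v[startsWith(v, prefix)]
    if (length(hit) == 0) NA_character_ else sub(prefix, "", hit[1], fixed = TRUE)
  }
  er <- apply(x, 1, get_tag, prefix = "er:f:")
  tp <- apply(x, 1, get_tag, prefix = "tp:A:")
  ev <- apply(x, 1, get_tag, prefix = "ev:Z:")
  tibble(
    a = as.integer(x$X1), b = as.integer(x$X6),
    a_start = as.integer(x$X3), a_end = as.integer(x$X4),
    b_start = as.integer(x$X8), b_end = as.integer(x$X9),
    orient = x$X5,
    error = as.numeric(er),
    nmatch = as.integer(x$X10), cols = as.integer(x$X11),
    kind = unname(kindmap[tp]), evidence = ev
  )
}
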