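# Overlap-based trimming of corrected reads, plus hairpin-adapter and
# chimeric-junction detection.

coverage_runs <- function(starts, ends, min_depth) {
  if (length(starts) == 0) return(tibble(begin = integer(), end = integer()))
  ev <- rbind(cbind(starts, 1L), cbind(ends, -1L))
  ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
  depth <- cumsum(ev[, 2])
  pos <- ev[, 1]
  ok <- depth >= min_depth
  runs <- list()
  open <- NA_integer_
  for (i in seq_along(ok)) {
    if (ok[i] && is.na(open)) open <- pos[i]
    if (!ok[i] && !is.na(open)) {
      runs[[length(runs) + 1]] <- c(open, pos[i])
      open <- NA_integer_
    }
  }
  if (!is.na(open)) runs[[length(runs) + 1]] <- c(open, pos[length(pos)])
  if (length(runs) == 0) return(tibble(begin = integer(), end = integer()))
  m <- do.call(rbind, runs)
  tibble(begin = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Compute clear ranges from DP-confirmed overlaps
#'
#' Each read is trimmed to the largest portion covered to at least depth `C`
#' by overlaps of at most `E` error and minimum length `L`.  Reads with no
#' qualifying interval of at least `min_output` bases are discarded.
#'
#' @param reads Read tibble.
#' @param overlaps Symmetric DP-confirmed overlap tibble.
#' @param C Minimum supporting depth (default 2).
#' @param E Maximum overlap error rate (default 0.045 for corrected reads).
#' @param L Minimum overlap length (default 500).
#' @param min_output Minimum clear-range length to keep a read.
#' @return Clear-range tibble: `id`, `begin`, `end`, `status`
#'   ("trimmed"/"discarded"); 0-based half-open read coordinates.
#' @export
compute_clear_ranges <- function(reads, overlaps, C = 2L, E = 0.045, L = 500L,
                                 min_output = 500L) {
  reads <- as_read_tbl(reads)
  qual <- overlaps %>%
    filter(.data$error <= E, .data$a_end - .data$a_start >= L)
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rid <- reads$id[i]
    ov <- qual[qual$a == rid, ]
    runs <- coverage_runs(ov$a_start, ov$a_end, C)
    if (nrow(runs) == 0) {
      out[[i]] <- tibble(id = rid, begin = 0L, end = 0L, status = "discarded")
      next
    }
    best <- runs %>% mutate(len = .data$end - .data$begin) %>%
      arrange(desc(.data$len), .data$begin) %>% slice_head(n = 1)
    status <- if (best$len >= min_output) "trimmed" else "discarded"
    out[[i]] <- tibble(id = rid, begin = best$begin, end = best$end,
                       status = status)
  }
  bind_rows(out)
}

#' Detect hairpin-adapter reads
#'
#' A hairpin read contains a sequence followed by its reverse complement
#' around a short adapter.  Partners covering the duplicated region match
#' the read in both orientations around a common pivot; the pivot is
#' detected when at least `min_votes` partners vote for a consistent
#' position and at most `max_spanning` confirmed overlaps span it (true
#' genomic inverted repeats are spanned and therefore not flagged).
#'
#' @param reads Read tibble.
#' @param bottoms [build_bottom_sketch()] of the reads.
#' @param candidates Candidate pair tibble.
#' @param overlaps Symmetric DP-confirmed overlaps (for spanning counts).
#' @param min_votes Minimum partner votes (default 5).
#' @param max_spanning Maximum spanning overlaps (default 2).
#' @param pivot_window Pivot clustering half-width in bases.
#' @return Tibble `id`, `pivot` (0-based read coordinate) for flagged reads.
#' @export
detect_hairpin <- function(reads, bottoms, candidates, overlaps,
                           min_votes = 5L, max_spanning = 2L,
                           pivot_window = 250L) {
  reads <- as_read_tbl(reads)
  pairs <- bind_rows(
    select(candidates, a = "a", b = "b"),
    select(candidates, a = "b", b = "a")
  )
  ia <- match(pairs$a, bottoms$id)
  ib <- match(pairs$b, bottoms$id)
  keep <- !is.na(ia) & !is.na(ib)
  votes <- hairpin_votes_cpp(bottoms$sketches, ia[keep], ib[keep],
                             bottoms$length, bottoms$k, 3L)
  if (length(votes$a) == 0) return(tibble(id = integer(), pivot = integer()))
  vt <- tibble(id = bottoms$id[votes$a], pivot = votes$pivot)
  flagged <- list()
  for (rid in unique(vt$id)) {
    v <- vt$pivot[vt$id == rid]
    if (length(v) < min_votes) next
    med <- median(v)
    cluster <- v[abs(v - med) <= pivot_window]
    if (length(cluster) < min_votes) next
    pivot <- as.integer(round(median(cluster)))
    span <- overlaps %>%
      filter(.data$a == rid, .data$a_start <= pivot - 100,
             .data$a_end >= pivot + 100)
    if (nrow(span) > max_spanning) next
    flagged[[length(flagged) + 1]] <- tibble(id = rid, pivot = pivot)
  }
  if (length(flagged) == 0) return(tibble(id = integer(), pivot = integer()))
  bind_rows(flagged)
}

#' Detect chimeric junctions
#'
#' A chimeric junction is an interior position of the clear range with at
#' most `max_spanning` overlaps spanning `[pos - 100, pos + 100]`.
#' Positions within `margin` of the clear-range ends are not considered
#' (coverage naturally tapers there).
#'
#' @param reads Read tibble.
#' @param overlaps Symmetric DP-confirmed overlaps.
#' @param clear Clear-range tibble from [compute_clear_ranges()].
#' @param max_spanning Maximum spanning overlaps at a junction (default 1).
#' @param margin Interior margin in bases (default 400).
#' @param step Scan step in bases.
#' @return Tibble `id`, `junction` (0-based read coordinate), one row per
#'   detected junction.
#' @export
detect_chimera <- function(reads, overlaps, clear, max_spanning = 1L,
                           margin = 400L, step = 50L) {
  reads <- as_read_tbl(reads)
  out <- list()
  for (i in seq_len(nrow(clear))) {
    if (clear$status[i] == "discarded") next
    rid <- clear$id[i]
    lo <- clear$begin[i] + margin
    hi <- clear$end[i] - margin
    if (hi - lo < step) next
    ov <- overlaps[overlaps$a == rid, ]
    if (nrow(ov) == 0) next
    grid <- seq(lo, hi, by = step)
    span_count <- vapply(grid, function(p) {
      sum(ov$a_start <= p - 100 & ov$a_end >= p + 100)
    }, numeric(1))
    bad <- span_count <= max_spanning
    if (!any(bad)) next
    # merge adjacent weak positions into junctions
    r <- rle(bad)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values)) {
      jpos <- as.integer(round(mean(grid[idx_start[j]:idx_end[j]])))
      out[[length(out) + 1]] <- tibble(id = rid, junction = jpos)
    }
  }
  if (length(out) == 0) return(tibble(id = integer(), junction = integer()))
  bind_rows(out)
}

#' Run the full trimming stage
#'
#' Recomputes DP-confirmed overlaps for the input reads, computes clear
#' ranges, detects hairpin adapters and chimeric junctions, and trims each
#' read to its largest supported region.
#'
#' @param reads Read tibble (typically corrected reads).
#' @param config [assembly_config()].
#' @param overlaps Optional precomputed DP overlap tibble (each pair once).
#' @return List with `reads` (trimmed read tibble, provenance updated),
#'   `clear_ranges`, `hairpins`, `chimeras`, `overlaps` (symmetric).
#' @export
trim_reads <- function(reads, config = assembly_config(), overlaps = NULL) {
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0) {
    return(list(reads = reads, clear_ranges = tibble(), hairpins = tibble(),
                chimeras = tibble(), overlaps = empty_overlaps(dp = TRUE)))
  }
  spectrum <- count_kmers(reads, k = config$k, filter_cutoff = config$filter_cutoff)
  sk <- build_sketch(reads, spectrum, s = config$s, params = config$tfidf,
                     seed = config$seed)
  cand <- find_candidates(sk, min_slot_matches = config$min_slot_matches)
  bottoms <- build_bottom_sketch(reads, k = config$k, size = config$bottom_size)
  if (is.null(overlaps)) {
    est <- estimate_overlap(bottoms, cand, min_overlap = config$min_overlap)
    overlaps <- dp_overlap(reads, est, min_overlap = config$min_overlap)
  }
  sym <- symmetrize_overlaps(overlaps)
  # spanning evidence must itself qualify (flaw-crossing alignments are
  # low-identity partials and would otherwise mask the flaw)
  sym_q <- sym %>% filter(.data$error <= config$trim_E)
  clear <- compute_clear_ranges(reads, sym, C = config$trim_C,
                                E = config$trim_E, L = config$trim_L,
                                min_output = config$min_read_length)
  hp <- detect_hairpin(reads, bottoms, cand, sym_q,
                       min_votes = config$hairpin_min_votes,
                       max_spanning = config$hairpin_max_spanning)
  # apply hairpin cuts before chimera scanning
  for (i in seq_len(nrow(hp))) {
    j <- match(hp$id[i], clear$id)
    if (is.na(j) || clear$status[j] == "discarded") next
    piv <- hp$pivot[i]
    b <- clear$begin[j]; e <- clear$end[j]
    left <- c(b, min(e, max(b, piv - 20L)))
    right <- c(max(b, min(e, piv + 20L)), e)
    side <- if (diff(left) >= diff(right)) left else right
    clear$begin[j] <- side[1]; clear$end[j] <- side[2]
    clear$status[j] <- if (diff(side) >= config$min_read_length) "split" else "discarded"
  }
  ch <- detect_chimera(reads, sym_q, clear,
                       max_spanning = config$chimera_max_spanning)
  for (rid in unique(ch$id)) {
    j <- match(rid, clear$id)
    if (is.na(j) || clear$status[j] == "discarded") next
    cuts <- sort(ch$junction[ch$id == rid])
    bounds <- c(clear$begin[j], cuts, clear$end[j])
    lens <- diff(bounds)
    best <- which.max(lens)
    clear$begin[j] <- bounds[best]; clear$end[j] <- bounds[best + 1]
    clear$status[j] <- if (lens[best] >= config$min_read_length) "split" else "discarded"
  }

  kept <- clear %>% filter(.data$status != "discarded")
  idx <- match(kept$id, reads$id)
  trimmed <- tibble(
    id = seq_len(nrow(kept)),
    seq = substr(reads$seq[idx], kept$begin + 1L, kept$end),
    orig_id = col_or(reads, "orig_id", reads$id)[idx],
    src_begin = kept$begin, src_end = kept$end,
    stage = "trimmed"
  )
  trimmed$length <- nchar(trimmed$seq)
  # compose truth provenance if present
  if (all(c("start", "end", "strand") %in% names(reads))) {
    plus <- reads$strand[idx] == "+"
    trimmed$start <- ifelse(plus, reads$start[idx] + kept$begin,
                            reads$end[idx] - kept$end)
    trimmed$end <- ifelse(plus, reads$start[idx] + kept$end,
                          reads$end[idx] - kept$begin)
    trimmed$strand <- reads$strand[idx]
  }
  list(reads = trimmed, clear_ranges = clear, hairpins = hp, chimeras = ch,
       overlaps = sym)
}

#' Write clear ranges as a tab-separated file
#' @param clear Clear-range tibble.
#' @param path Output path.
#' @export
write_clear_ranges <- function(clear, path) {
  readr::write_tsv(select(clear, "id", "begin", "end", "status"), path)
  invisible(path)
}
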