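# Hierarchical read correction: global/local evidence filters, corrected
# length estimation, read selection, and DAG consensus correction.

overlap_score <- function(ov) {
  len <- pmax(ov$a_end - ov$a_start, ov$b_end - ov$b_start)
  len * (1 - ov$error)
}

#' Global correction filter: where each read donates evidence
#'
#' Each read scores its overlaps by `overlap_length * identity` and donates
#' correction evidence only to its `C` best partners, clustering repetitive
#' reads with partners likely to come from the same repeat copy.  Ties are
#' broken by longer overlap, then lower partner id.
#'
#' @param overlaps Symmetric overlap tibble (each record lists the donor as
#'   `a`; use [symmetrize_overlaps()] or a store dump).
#' @param C Expected read depth: the maximum number of reads each read may
#'   help correct.
#' @return Donation tibble (overlap rows with a `score` column; `a` is the
#'   donor, `b` the correction target).
#' @export
global_filter <- function(overlaps, C) {
  C <- max(1L, as.integer(C))
  ovl_len <- pmax(overlaps$a_end - overlaps$a_start,
                  overlaps$b_end - overlaps$b_start)
  overlaps %>%
    mutate(score = overlap_score(overlaps), .ovl_len = ovl_len) %>%
    arrange(.data$a, desc(.data$score), desc(.data$.ovl_len), .data$b) %>%
    group_by(.data$a) %>%
    slice_head(n = C) %>%
    ungroup() %>%
    select(-".ovl_len")
}

#' Local correction filter: which evidence each read accepts
#'
#' Each correction target keeps at most `2C` donated overlaps, best by the
#' same score and tie rules as the global filter.
#'
#' @param donations Output of [global_filter()].
#' @param C Expected read depth.
#' @return Accepted-evidence tibble (`b` is the target).
#' @export
local_filter <- function(donations, C) {
  C <- max(1L, as.integer(C))
  ovl_len <- pmax(donations$a_end - donations$a_start,
                  donations$b_end - donations$b_start)
  donations %>%
    mutate(.ovl_len = ovl_len) %>%
    arrange(.data$b, desc(.data$score), desc(.data$.ovl_len), .data$a) %>%
    group_by(.data$b) %>%
    slice_head(n = 2L * C) %>%
    ungroup() %>%
    select(-".ovl_len")
}

covered_bases <- function(starts, ends, min_depth) {
  if (length(starts) == 0) return(0L)
  ev <- rbind(cbind(starts, 1L), cbind(ends, -1L))
  ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
  depth <- cumsum(ev[, 2])
  pos <- ev[, 1]
  # bases between consecutive events where running depth >= min_depth
  if (nrow(ev) < 2) return(0L)
  sum((pos[-1] - pos[-length(pos)])[depth[-length(depth)] >= min_depth])
}

#' Predict each read's expected corrected length
#'
#' The expected corrected length is the number of read bases covered by at
#' least `min_depth` accepted evidence alignments (0 for reads with no
#' evidence), accounting for reads with partial or no overlaps.
#'
#' @param reads Read tibble.
#' @param accepted Accepted-evidence tibble from [local_filter()] (`b` is
#'   the target; `b_start`/`b_end` the covered interval).
#' @param min_depth Minimum evidence depth to count a base as supported.
#' @return Tibble `id`, `length`, `corrected_length`.
#' @export
estimate_corrected_lengths <- function(reads, accepted, min_depth = 2L) {
  reads <- as_read_tbl(reads)
  est <- accepted %>%
    group_by(.data$b) %>%
    summarise(corrected_length = covered_bases(.data$b_start, .data$b_end,
                                               min_depth),
              .groups = "drop") %>%
    rename(id = "b")
  reads %>%
    select("id", "length") %>%
    left_join(est, by = "id") %>%
    mutate(corrected_length = as.integer(dplyr::coalesce(.data$corrected_length, 0L)))
}

#' Select the longest reads up to a target coverage
#'
#' Greedily takes reads by descending estimated corrected length (ties:
#' lower read id first) until the cumulative bases reach
#' `target_coverage * genome_size`; returns all reads if the total is
#' insufficient.
#'
#' @param estimates Output of [estimate_corrected_lengths()].
#' @param target_coverage Fold coverage to retain.
#' @param genome_size Estimated genome size in bases.
#' @return The selected rows of `estimates`.
#' @export
select_longest <- function(estimates, target_coverage, genome_size) {
  if (genome_size <= 0) abort("genome_size must be positive")
  target <- target_coverage * genome_size
  est <- estimates %>%
    arrange(desc(.data$corrected_length), .data$id) %>%
    mutate(cum = cumsum(.data$corrected_length))
  keep <- est$cum - est$corrected_length < target
  est %>% filter(keep, .data$corrected_length > 0) %>% select(-"cum")
}

orient_evidence <- function(reads, evidence) {
  # evidence rows: a = donor, b = target; orient target-forward evidence
  ia <- read_index(reads, evidence$a)
  seqs <- reads$seq[ia]
  lens <- reads$length[ia]
  flip <- evidence$orient == "-"
  seqs[flip] <- revcomp(seqs[flip])
  p_s <- ifelse(flip, lens - evidence$a_end, evidence$a_start)
  p_e <- ifelse(flip, lens - evidence$a_start, evidence$a_end)
  list(seqs = seqs, p_s = as.integer(p_s), p_e = as.integer(p_e))
}

#' Correct one read with a DAG consensus over its evidence alignments
#'
#' Evidence reads are aligned to the template read with the banded
#' overlap aligner; alignment tags form a DAG whose highest-weight path is
#' the corrected sequence.  Template columns whose best advancing edge has
#' weight below `min_edge_weight` split the output into pieces; pieces
#' shorter than `min_piece_length` are dropped.  The template itself
#' contributes weight 1.
#'
#' @param read A single-row read tibble (the template).
#' @param reads Read tibble holding the evidence reads.
#' @param evidence Accepted-evidence tibble rows targeting this read
#'   (`b == read$id`).
#' @param min_edge_weight DAG edge weight below which the read splits
#'   (default 4).
#' @param min_piece_length Minimum output piece length (default 500).
#' @return Tibble of corrected pieces: `orig_id`, `piece`, `seq`, `length`,
#'   `tpl_start`, `tpl_end` (template coordinates).
#' @export
dag_correct <- function(read, reads, evidence, min_edge_weight = 4L,
                        min_piece_length = 500L) {
  stopifnot(nrow(read) == 1)
  ev <- orient_evidence(reads, evidence)
  res <- dag_consensus_cpp(
    read$seq, ev$seqs,
    as.integer(evidence$b_start), as.integer(evidence$b_end),
    ev$p_s, ev$p_e, as.numeric(evidence$error),
    50L, 800L, as.integer(min_edge_weight), as.integer(min_piece_length),
    TRUE
  )
  if (res$n_pieces == 0) {
    return(tibble(orig_id = integer(), piece = integer(), seq = character(),
                  length = integer(), tpl_start = integer(), tpl_end = integer()))
  }
  tibble(
    orig_id = read$id, piece = seq_len(res$n_pieces), seq = res$piece,
    length = nchar(res$piece), tpl_start = res$start, tpl_end = res$end
  )
}

# compose provenance: map template-coordinate pieces back to genome truth
piece_truth <- function(read, pieces) {
  if (!all(c("start", "end", "strand") %in% names(read))) {
    pieces$start <- NA_integer_; pieces$end <- NA_integer_
    pieces$strand <- NA_character_
    return(pieces)
  }
  plus <- identical(read$strand, "+")
  if (plus) {
    pieces$start <- as.integer(read$start + pieces$tpl_start)
    pieces$end <- as.integer(read$start + pieces$tpl_end)
  } else {
    pieces$start <- as.integer(read$end - pieces$tpl_end)
    pieces$end <- as.integer(read$end - pieces$tpl_start)
  }
  pieces$strand <- read$strand
  pieces
}

#' Run the full correction stage
#'
#' Overlaps the input reads with the weighted-sketch overlapper, applies the
#' global and local evidence filters, predicts corrected lengths, selects
#' the longest reads up to `target_coverage`, and corrects each selected
#' read with the DAG consensus.
#'
#' @param reads Read tibble.
#' @param config An [assembly_config()].
#' @param overlaps Optional precomputed sketch overlap tibble (symmetric
#'   records not required; each pair once).
#' @return Corrected read tibble with provenance columns (`orig_id`,
#'   `piece`, `src_start`, `src_end` in original-read coordinates, truth
#'   `start`/`end`/`strand` when available) and `stage = "corrected"`.
#' @export
correct_reads <- function(reads, config = assembly_config(), overlaps = NULL) {
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0) return(corrected_empty())
  if (is.null(overlaps)) {
    overlaps <- overlap_reads(
      reads, k = config$k, s = config$s, filter_cutoff = config$filter_cutoff,
      params = config$tfidf, min_slot_matches = config$min_slot_matches,
      bottom_size = config$bottom_size, min_overlap = config$min_overlap,
      dp = FALSE, seed = config$seed
    )
  }
  store <- build_store(overlaps, known_ids = reads$id,
                       max_bucket_size = config$store_bucket_size)
  sym <- store_dump(store)
  C <- config$C
  if (is.null(C) || is.na(C)) {
    C <- max(1L, round(sum(reads$length) / config$genome_size))
  }
  don <- global_filter(sym, C)
  acc <- local_filter(don, C)
  est <- estimate_corrected_lengths(reads, acc, config$min_evidence_depth)
  sel <- select_longest(est, config$cor_out_coverage, config$genome_size)

  out <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    rid <- sel$id[i]
    read <- reads[reads$id == rid, ]
    ev <- acc[acc$b == rid, ]
    if (nrow(ev) == 0) next
    pieces <- dag_correct(read, reads, ev,
                          min_edge_weight = config$min_dag_edge,
                          min_piece_length = config$min_read_length)
    if (nrow(pieces) == 0) next
    out[[i]] <- piece_truth(read, pieces)
  }
  pieces <- bind_rows(out)
  if (nrow(pieces) == 0) return(corrected_empty())
  tibble(
    id = seq_len(nrow(pieces)),
    seq = pieces$seq, length = pieces$length,
    orig_id = pieces$orig_id, piece = pieces$piece,
    src_start = pieces$tpl_start, src_end = pieces$tpl_end,
    start = pieces$start, end = pieces$end, strand = pieces$strand,
    stage = "corrected"
  )
}

corrected_empty <- function() {
  tibble(id = integer(), seq = character(), length = integer(),
         orig_id = integer(), piece = integer(), src_start = integer(),
         src_end = integer(), start = integer(), end = integer(),
         strand = character(), stage = character())
}

#' Iterate correction rounds
#'
#' Re-runs overlap computation and correction for `rounds` rounds, feeding
#' each round's output into the next — the workflow used for very noisy
#' reads.  With `passthrough = TRUE`, reads that produce no corrected piece
#' are carried through unchanged so later rounds can retry them.
#'
#' @param reads Read tibble.
#' @param rounds Number of correction rounds (>= 1).
#' @param config [assembly_config()].
#' @param passthrough Keep uncorrectable reads unchanged?
#' @return Corrected read tibble after the final round.
#' @export
iterate_correction <- function(reads, rounds = 1L, config = assembly_config(),
                               passthrough = FALSE) {
  if (rounds < 1) abort("rounds must be >= 1")
  cur <- as_read_tbl(reads)
  for (r in seq_len(rounds)) {
    if (nrow(cur) == 0) return(corrected_empty())
    out <- correct_reads(cur, config)
    if (passthrough) {
      missed <- cur %>% filter(!(.data$id %in% out$orig_id))
      if (nrow(missed) > 0) {
        missed_std <- tibble(
          id = missed$id, seq = missed$seq, length = missed$length,
          orig_id = col_or(missed, "orig_id", missed$id), piece = 1L,
          src_start = 0L, src_end = missed$length,
          start = col_or(missed, "start", NA_integer_),
          end = col_or(missed, "end", NA_integer_),
          strand = col_or(missed, "strand", NA_character_),
          stage = "corrected"
        )
        out <- bind_rows(out, missed_std) %>% arrange(.data$orig_id)
        out$id <- seq_len(nrow(out))
      }
    }
    # keep lineage to the ORIGINAL input read across rounds
    if (r > 1L) {
      lineage <- setNames(cur$orig_id, cur$id)
      out$orig_id <- unname(lineage[as.character(out$orig_id)])
    }
    cur <- out
  }
  cur
}
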