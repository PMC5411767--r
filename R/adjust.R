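# Overlap error adjustment: two-pass majority-vote detection of residual
# sequencing errors and recomputation of overlap error rates as if those
# errors were fixed.  Read sequences themselves are never rewritten (that
# would invalidate the computed overlaps).

#' Pass one: propose base edits by majority vote over aligned overlaps
#'
#' For each aligned column of each read, an edit is proposed when the read's
#' base disagrees with a strict majority of covering partners and fewer than
#' `support_frac` of the partners agree with the read (so genuine variants —
#' diverged repeat copies, haplotypes — are preserved).  Indel columns vote
#' with gap symbols.
#'
#' @param reads Read tibble.
#' @param overlaps Symmetric DP-confirmed overlap tibble.
#' @param support_frac Fraction of covering partners that must agree with
#'   the read to protect it from editing (default 0.4: genuine variants sit
#'   near 50% support, while alignment-artifact support for sequencing
#'   errors stays below ~30%).
#' @param min_cover Minimum covering partners to call a vote.
#' @return Edit tibble: `id`, `pos` (0-based), `type`
#'   ("sub"/"del"/"ins"), `from`, `to`, `cover`, `support`.
#' @export
vote_errors <- function(reads, overlaps, support_frac = 0.4, min_cover = 4L) {
  reads <- as_read_tbl(reads)
  empty <- tibble(id = integer(), pos = integer(), type = character(),
                  from = character(), to = character(), cover = integer(),
                  support = integer())
  if (nrow(overlaps) == 0) return(empty)
  ov <- overlaps %>% arrange(.data$a, .data$b, .data$a_start)
  res <- vote_all_cpp(reads$seq, read_index(reads, ov$a),
                      read_index(reads, ov$b),
                      as.integer(ov$orient == "-"),
                      as.integer(ov$a_start), as.integer(ov$a_end),
                      as.integer(ov$b_start), as.integer(ov$b_end),
                      as.numeric(ov$error), 50L, 800L, support_frac,
                      as.integer(min_cover))
  if (length(res$id) == 0) return(empty)
  bases <- c("A", "C", "G", "T")
  code_chr <- function(code) {
    out <- rep("-", length(code))
    hit <- code >= 0
    out[hit] <- bases[code[hit] + 1L]
    out
  }
  tibble(
    id = reads$id[res$id], pos = res$pos,
    type = c("sub", "del", "ins")[res$type + 1L],
    from = code_chr(res$from), to = code_chr(res$to),
    cover = res$cover, support = res$support
  )
}

apply_edit_tbl <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  type <- match(edits$type, c("sub", "del", "ins")) - 1L
  to <- match(edits$to, c("A", "C", "G", "T")) - 1L
  to[is.na(to)] <- 0L
  apply_edits_cpp(seq, as.integer(edits$pos), as.integer(type), as.integer(to))
}

#' Pass two: recompute overlap error rates with edits applied
#'
#' Applies the proposed edits to temporary copies of both reads of every
#' overlap, realigns, and replaces the stored error rate; intervals are
#' unchanged.  Overlaps between reads with no edits keep their error rate.
#'
#' @param reads Read tibble.
#' @param overlaps Overlap tibble (each pair once; symmetric input is
#'   deduplicated on `a < b`).
#' @param edits Edit tibble from [vote_errors()].
#' @return Overlap tibble with adjusted `error` (and an `error_raw` column
#'   keeping the original value).
#' @export
recompute_error_rates <- function(reads, overlaps, edits) {
  reads <- as_read_tbl(reads)
  ov <- overlaps %>% filter(.data$a < .data$b)
  if (nrow(ov) == 0) return(overlaps)
  edited <- reads
  touched <- unique(edits$id)
  for (rid in touched) {
    i <- match(rid, edited$id)
    edited$seq[i] <- apply_edit_tbl(edited$seq[i], edits[edits$id == rid, ])
  }
  edited$length <- nchar(edited$seq)
  redo <- dp_overlap(edited, ov, min_overlap = 1L)
  # realigned records come back in input order minus failures; join by a,b
  ov$error_raw <- ov$error
  m <- match(paste(ov$a, ov$b), paste(redo$a, redo$b))
  hit <- !is.na(m)
  ov$error[hit] <- redo$error[m[hit]]
  ov
}

#' Run both passes of overlap error adjustment
#'
#' @param reads Read tibble.
#' @param overlaps Symmetric DP-confirmed overlap tibble.
#' @param support_frac,min_cover Passed to [vote_errors()].
#' @return List with `overlaps` (symmetric, adjusted error rates, original
#'   rates in `error_raw`) and `edits` (the proposed-edit log).
#' @export
adjust_overlaps <- function(reads, overlaps, support_frac = 0.25,
                            min_cover = 4L) {
  edits <- vote_errors(reads, overlaps, support_frac = support_frac,
                       min_cover = min_cover)
  uniq <- overlaps %>% filter(.data$a < .data$b)
  adj <- recompute_error_rates(reads, uniq, edits)
  list(overlaps = symmetrize_overlaps(adj), edits = edits)
}

#' Write the edit log as a tab-separated file
#' @param edits Edit tibble.
#' @param path Output path.
#' @export
write_edits_tsv <- function(edits, path) {
  readr::write_tsv(select(edits, "id", "pos", "from", "to"), path)
  invisible(path)
}
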