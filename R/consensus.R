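# Contig consensus: template splicing along the best overlap path, then a
# DAG consensus over all contig reads aligned to the template (the same DAG
# implementation used for read correction).

oriented_layout_seq <- function(reads, rows) {
  idx <- read_index(reads, rows$read)
  seqs <- reads$seq[idx]
  flip <- rows$orient == 1L
  seqs[flip] <- revcomp(seqs[flip])
  seqs
}

#' Build a contig template by splicing layout reads
#'
#' Walks the layout in order and appends each read's non-redundant
#' extension beyond the current template end.  The template is accurate
#' within reads but may carry indel error at read junctions; the DAG
#' consensus repairs those.
#'
#' @param reads Read tibble.
#' @param rows Layout rows of one contig (sorted by `begin`).
#' @return List `template` (sequence) and `anchors` (tibble `read`,
#'   `t_start`, `t_end`: template-coordinate hints per read).
#' @export
build_template <- function(reads, rows) {
  # the template follows the best-overlap path: only walked backbone reads
  # splice it (individually placed reads are evidence, not structure)
  if ("source" %in% names(rows) && any(rows$source == "walk")) {
    rows <- rows %>% filter(.data$source == "walk")
  }
  rows <- rows %>% arrange(.data$begin, .data$read)
  seqs <- oriented_layout_seq(reads, rows)
  tpl <- seqs[1]
  anchors <- tibble(read = rows$read[1], t_start = 0L, t_end = nchar(tpl))
  if (nrow(rows) > 1) {
    for (i in 2:nrow(rows)) {
      cur_len <- nchar(tpl)
      ovl <- cur_len - rows$begin[i]   # layout estimate, drifts with indels
      li <- nchar(seqs[i])
      if (ovl < 0) ovl <- 0
      ext_from <- ovl + 1L
      t_start <- max(0L, cur_len - max(ovl, 0L))
      # refine the junction by aligning a probe of the read's head into the
      # template tail, so splices stay exact despite coordinate drift
      plen <- min(600L, max(100L, ovl - 100L), li)
      if (ovl >= 200 && plen >= 100) {
        w0 <- max(0L, cur_len - (ovl + 500L))
        win <- substr(tpl, w0 + 1L, cur_len)
        probe <- substr(seqs[i], 1L, plen)
        al <- bp_ops_cpp(probe, win, (cur_len - ovl) - w0, 300L)
        if (isTRUE(al$ok)) {
          # read position plen corresponds to template w0 + al$b_end; the
          # extension begins where the read passes the template end
          ext_from <- plen + (cur_len - (w0 + al$b_end)) + 1L
          t_start <- w0 + al$b_start
        }
      }
      if (ext_from <= li) {
        tpl <- paste0(tpl, substr(seqs[i], ext_from, li))
      }
      anchors <- bind_rows(anchors, tibble(
        read = rows$read[i],
        t_start = as.integer(t_start),
        t_end = as.integer(min(t_start + li, nchar(tpl)))
      ))
    }
  }
  list(template = tpl, anchors = anchors)
}

#' Consensus of one contig from its template and reads
#'
#' All layout reads are aligned to the template around their anchor
#' positions and merged into an alignment-tag DAG; the consensus is the
#' highest-weight path, with ties broken toward the template base.
#'
#' @param reads Read tibble.
#' @param rows Layout rows of one contig.
#' @param min_band,max_band Alignment band bounds.
#' @return Consensus sequence (character scalar).
#' @export
contig_consensus <- function(reads, rows, min_band = 50L, max_band = 800L) {
  tp <- build_template(reads, rows)
  rows <- rows %>% arrange(.data$begin, .data$read)
  seqs <- oriented_layout_seq(reads, rows)
  lens <- nchar(seqs)
  # layout coordinates approximate template coordinates closely enough to
  # anchor every read (backbone and placed alike)
  tlen <- nchar(tp$template)
  t_s <- pmin(pmax(rows$begin, 0L), tlen)
  t_e <- pmin(rows$end, tlen)
  res <- dag_consensus_cpp(
    tp$template, seqs,
    as.integer(t_s), as.integer(t_e),
    rep(0L, length(seqs)), as.integer(lens),
    rep(0.05, length(seqs)),
    as.integer(min_band), as.integer(max_band), 0L, 1L, TRUE
  )
  if (res$n_pieces == 0) return(tp$template)
  paste(res$piece, collapse = "")
}

contig_consensus_all <- function(reads, layout, config) {
  ids <- unique(layout$contig)
  out <- setNames(character(length(ids)), ids)
  for (cg in ids) {
    rows <- layout[layout$contig == cg, ]
    out[as.character(cg)] <- contig_consensus(reads, rows)
  }
  out
}

#' Write contig consensus sequences to FASTA
#' @param assembly An `sx_assembly`.
#' @param path Output path.
#' @export
write_contigs_fasta <- function(assembly, path) {
  cls <- setNames(assembly$contigs$class, assembly$contigs$contig)
  nm <- names(assembly$consensus)
  hdr <- paste0(">contig", nm, " class=", cls[nm],
                " reads=", assembly$contigs$n_reads[match(as.integer(nm), assembly$contigs$contig)])
  writeLines(as.vector(rbind(hdr, unname(assembly$consensus))), path)
  invisible(path)
}
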