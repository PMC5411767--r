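# GFA 1.0 assembly-graph output: one segment per contig, one link per
# unused qualifying contig-end overlap.

#' Emit the assembly graph in GFA 1.0 format
#'
#' @param assembly An `sx_assembly`.
#' @param path Optional output path; when `NULL` the GFA lines are returned.
#' @return The GFA lines, invisibly when written to a file.
#' @export
emit_gfa <- function(assembly, path = NULL) {
  stopifnot(inherits(assembly, "sx_assembly"))
  segs <- names(assembly$consensus)
  lines <- c(
    "H\tVN:Z:1.0",
    vapply(segs, function(nm) {
      paste0("S\tcontig", nm, "\t", assembly$consensus[[nm]],
             "\tLN:i:", nchar(assembly$consensus[[nm]]))
    }, character(1), USE.NAMES = FALSE)
  )
  if (nrow(assembly$links %||% tibble()) > 0) {
    l <- assembly$links
    lines <- c(lines, paste0(
      "L\tcontig", l$from, "\t", l$from_orient,
      "\tcontig", l$to, "\t", l$to_orient, "\t", l$overlap, "M"
    ))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a GFA 1.0 document
#'
#' @param x Path to a GFA file or a character vector of GFA lines.
#' @return List with `header`, `segments` (tibble `name`, `seq`, `length`)
#'   and `links` (tibble `from`, `from_orient`, `to`, `to_orient`,
#'   `overlap`).
#' @export
read_gfa <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  rt <- substr(lines, 1, 1)
  segs <- strsplit(lines[rt == "S"], "\t", fixed = TRUE)
  links <- strsplit(lines[rt == "L"], "\t", fixed = TRUE)
  bad <- !(rt %in% c("H", "S", "L", "C", "P", "#"))
  if (any(bad)) abort("not a GFA 1.0 document: unknown record type")
  seg_tbl <- tibble(
    name = unname(vapply(segs, `[`, character(1), 2)),
    seq = unname(vapply(segs, `[`, character(1), 3))
  )
  seg_tbl$length <- nchar(seg_tbl$seq)
  link_tbl <- tibble(
    from = vapply(links, `[`, character(1), 2),
    from_orient = vapply(links, `[`, character(1), 3),
    to = vapply(links, `[`, character(1), 4),
    to_orient = vapply(links, `[`, character(1), 5),
    overlap = vapply(links, `[`, character(1), 6)
  )
  if (nrow(link_tbl) > 0) {
    okc <- grepl("^[0-9]+M$|^\\*$", link_tbl$overlap)
    if (!all(okc)) abort("invalid CIGAR in GFA link record")
    bad_or <- !(link_tbl$from_orient %in% c("+", "-")) |
      !(link_tbl$to_orient %in% c("+", "-"))
    if (any(bad_or)) abort("invalid orientation in GFA link record")
  }
  list(header = lines[rt == "H"], segments = seg_tbl, links = link_tbl)
}
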