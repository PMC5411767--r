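#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) revcomp_cpp(as.character(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a read input to the canonical read tibble
#'
#' Accepts a tibble with at least `id` and `seq` columns or a (named)
#' character vector of sequences.
#' @param reads Reads as tibble or character vector.
#' @return A tibble with `id` (integer), `seq`, `length` columns.
#' @keywords internal
as_read_tbl <- function(reads) {
  if (is.character(reads)) {
    reads <- tibble(
      id = seq_along(reads),
      name = names(reads) %||% as.character(seq_along(reads)),
      seq = unname(reads)
    )
  }
  if (!is.data.frame(reads) || !all(c("id", "seq") %in% names(reads))) {
    abort("`reads` must be a tibble with `id` and `seq` columns or a character vector")
  }
  reads <- as_tibble(reads)
  if (anyDuplicated(reads$id)) abort("read ids must be unique")
  reads$length <- nchar(reads$seq)
  reads
}

# map read ids to row indices (1-based) for C++ batch calls
read_index <- function(reads, ids) {
  idx <- match(ids, reads$id)
  if (anyNA(idx)) abort("overlap record references unknown read id")
  idx
}

# deterministic kind labels
kind_label <- function(code) c("dovetail", "containment", "partial")[code + 1L]
kind_code <- function(label) {
  match(label, c("dovetail", "containment", "partial")) - 1L
}

# contig/assembly N50-style statistic
nx_stat <- function(lengths, frac = 0.5, total = sum(lengths)) {
  if (length(lengths) == 0 || total <= 0) return(0L)
  lengths <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(lengths) >= frac * total)[1]
  if (is.na(i)) 0L else lengths[i]
}

#' Identity between two sequences by banded edit distance
#'
#' Computes a banded global edit distance between two sequences (band sized
#' to the length difference plus `extra_band`) and reports identity as
#' `1 - dist / max(nchar(a), nchar(b))`.
#'
#' @param a,b Sequences.
#' @param extra_band Additional band half-width beyond the length difference
#'   (500 covers the residual drift of long consensus-vs-truth comparisons).
#' @return A list with `dist` and `identity`.
#' @export
sequence_identity <- function(a, b, extra_band = 500L) {
  band_edit_cpp(a, b, as.integer(extra_band))
}

# optional column access without tibble's unknown-column warning
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}
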