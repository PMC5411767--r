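# Indexed on-disk overlap store.
#
# Records are fixed-width little-endian doubles in the column order below;
# every overlap is present twice (A->B and B->A) and records are globally
# sorted by (a, b, a_start), so all overlaps of one read are contiguous.
# A JSON sidecar holds the per-read index (offset, count).

STORE_FIELDS <- c("a", "b", "a_start", "a_end", "b_start", "b_end",
                  "orient", "error", "kind", "evidence")
STORE_REC_BYTES <- 8L * length(STORE_FIELDS)

store_encode <- function(overlaps) {
  m <- cbind(
    overlaps$a, overlaps$b, overlaps$a_start, overlaps$a_end,
    overlaps$b_start, overlaps$b_end,
    as.numeric(overlaps$orient == "-"),
    overlaps$error,
    as.numeric(kind_code(overlaps$kind)),
    as.numeric(overlaps$evidence == "dp")
  )
  storage.mode(m) <- "double"
  m
}

store_decode <- function(m) {
  colnames(m) <- STORE_FIELDS
  tibble(
    a = as.integer(m[, "a"]), b = as.integer(m[, "b"]),
    a_start = as.integer(m[, "a_start"]), a_end = as.integer(m[, "a_end"]),
    b_start = as.integer(m[, "b_start"]), b_end = as.integer(m[, "b_end"]),
    orient = ifelse(m[, "orient"] == 1, "-", "+"),
    error = m[, "error"],
    kind = kind_label(as.integer(m[, "kind"])),
    evidence = ifelse(m[, "evidence"] == 1, "dp", "sketch")
  )
}

#' Build an indexed on-disk overlap store with a bucket sort
#'
#' Each input overlap is duplicated with read roles swapped, reads are
#' assigned to buckets balanced by overlap count (no bucket above
#' `max_bucket_size` records unless a single read exceeds it), each bucket
#' is sorted by (read, partner, a_start) and written out, and a sidecar
#' index records each read's offset and count.  The final file is
#' byte-identical for any bucket size.
#'
#' @param overlaps Overlap tibble (each pair once) or list of overlap
#'   tibbles ("files" from parallel overlap jobs).
#' @param path Store path (binary records; `<path>.idx.json` sidecar).
#' @param max_bucket_size Maximum records per sort bucket.
#' @param known_ids Optional vector of valid read ids; records referencing
#'   other ids raise an error.
#' @return An `overlap_store` handle.
#' @export
build_store <- function(overlaps, path = tempfile("ovlstore_"),
                        max_bucket_size = 250000L, known_ids = NULL) {
  if (is.data.frame(overlaps)) overlaps <- list(overlaps)
  all_ov <- bind_rows(overlaps)
  if (!is.null(known_ids) && nrow(all_ov) > 0) {
    bad <- setdiff(unique(c(all_ov$a, all_ov$b)), known_ids)
    if (length(bad) > 0)
      abort(paste0("overlap record references unknown read id(s): ",
                   paste(head(bad, 5), collapse = ", ")))
  }
  dup <- if (nrow(all_ov) > 0) symmetrize_overlaps(all_ov) else all_ov

  # bucket boundaries balanced by per-read record counts
  counts <- if (nrow(dup) > 0) {
    dup %>% dplyr::count(.data$a) %>% arrange(.data$a)
  } else {
    tibble(a = integer(), n = integer())
  }
  bucket_of <- integer(nrow(counts))
  bi <- 1L; acc <- 0L
  for (i in seq_len(nrow(counts))) {
    if (acc > 0L && acc + counts$n[i] > max_bucket_size) { bi <- bi + 1L; acc <- 0L }
    bucket_of[i] <- bi
    acc <- acc + counts$n[i]
  }
  con <- file(path, "wb")
  for (b in unique(bucket_of)) {
    ids <- counts$a[bucket_of == b]
    chunk <- dup %>% filter(.data$a %in% ids) %>%
      arrange(.data$a, .data$b, .data$a_start)
    writeBin(as.vector(t(store_encode(chunk))), con, size = 8, endian = "little")
  }
  close(con)

  idx <- counts %>% mutate(offset = cumsum(dplyr::lag(.data$n, default = 0L)))
  jsonlite::write_json(
    list(fields = STORE_FIELDS, n_records = nrow(dup),
         reads = idx$a, offsets = idx$offset, counts = idx$n),
    paste0(path, ".idx.json"), auto_unbox = TRUE
  )
  open_store(path)
}

#' Open an existing overlap store
#' @param path Store path.
#' @return An `overlap_store` handle.
#' @export
open_store <- function(path) {
  idx <- jsonlite::read_json(paste0(path, ".idx.json"), simplifyVector = TRUE)
  structure(
    list(path = path, n_records = idx$n_records,
         index = tibble(a = as.integer(idx$reads),
                        offset = as.integer(idx$offsets),
                        count = as.integer(idx$counts))),
    class = "overlap_store"
  )
}

#' @export
print.overlap_store <- function(x, ...) {
  cat("<overlap_store> ", x$n_records, " records (",
      nrow(x$index), " reads) at ", x$path, "\n", sep = "")
  invisible(x)
}

read_store_records <- function(store, offset, count) {
  if (count == 0) return(store_decode(matrix(numeric(0), ncol = length(STORE_FIELDS))))
  con <- file(store$path, "rb")
  on.exit(close(con))
  seek(con, offset * STORE_REC_BYTES)
  v <- readBin(con, "numeric", count * length(STORE_FIELDS), size = 8,
               endian = "little")
  store_decode(matrix(v, ncol = length(STORE_FIELDS), byrow = TRUE))
}

#' List all overlaps of a read, in sorted order
#' @param store An `overlap_store`.
#' @param read_id Read id (first-read role).
#' @return Overlap tibble (possibly empty).
#' @export
get_overlaps <- function(store, read_id) {
  stopifnot(inherits(store, "overlap_store"))
  hit <- which(store$index$a == read_id)
  if (length(hit) == 0)
    return(read_store_records(store, 0L, 0L))
  read_store_records(store, store$index$offset[hit], store$index$count[hit])
}

#' Dump the full store as a tibble
#' @param store An `overlap_store`.
#' @return Overlap tibble with all (duplicated) records in global order.
#' @export
store_dump <- function(store) {
  stopifnot(inherits(store, "overlap_store"))
  read_store_records(store, 0L, store$n_records)
}
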