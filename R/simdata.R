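#' Specify a repeat family for a simulated genome
#'
#' A repeat family is a single unit sequence copied at the given placements,
#' with each copy mutated independently at half the pairwise divergence so
#' that the expected pairwise divergence between any two copies equals
#' `divergence`.  Divergence is applied as substitutions only, so "3%
#' divergence" is an unambiguous Hamming fraction.
#'
#' @param unit_length Length of the repeat unit in bases.
#' @param divergence Expected pairwise divergence between copies, in [0, 0.5].
#' @param placements Integer vector of 0-based start positions, one per copy.
#' @return A `repeat_spec` list.
#' @export
repeat_spec <- function(unit_length, divergence, placements) {
  if (divergence < 0 || divergence > 0.5) abort("divergence must be in [0, 0.5]")
  if (unit_length < 1) abort("unit_length must be positive")
  structure(
    list(unit_length = as.integer(unit_length),
         divergence = divergence,
         placements = as.integer(placements),
         copy_count = length(placements)),
    class = "repeat_spec"
  )
}

#' Specify a simulated genome
#'
#' @param length Genome length in bases.
#' @param repeats List of [repeat_spec()] objects.
#' @param circular Is the genome circular?
#' @param seed Integer seed; identical specs yield identical genomes.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length, repeats = list(), circular = FALSE, seed = 1L) {
  length <- as.integer(length)
  if (length < 1) abort("genome length must be positive")
  if (inherits(repeats, "repeat_spec")) repeats <- list(repeats)
  iv <- list()
  for (rp in repeats) {
    if (!inherits(rp, "repeat_spec")) abort("repeats must be repeat_spec objects")
    if (rp$unit_length >= length) abort("repeat unit_length must be smaller than genome length")
    for (p in rp$placements) {
      if (p < 0 || p + rp$unit_length > length)
        abort("repeat placement outside genome")
      iv[[length(iv) + 1]] <- c(p, p + rp$unit_length)
    }
  }
  if (length(iv) > 1) {
    m <- do.call(rbind, iv)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2]))
      abort("repeat placements overlap; choose non-overlapping positions")
  }
  structure(
    list(length = length, repeats = repeats, circular = isTRUE(circular),
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at `pos` (1-based) with a uniformly chosen different base
substitute_bases <- function(seq, pos) {
  if (length(pos) == 0) return(list(seq = seq, from = character(), to = character()))
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  from <- x[pos]
  alt <- lapply(from, function(b) setdiff(c("A", "C", "G", "T"), b))
  to <- vapply(alt, function(a) a[sample.int(3L, 1L)], character(1))
  x[pos] <- to
  list(seq = paste(x, collapse = ""), from = from, to = to)
}

#' Simulate a genome with divergent repeat copies
#'
#' Generates an i.i.d. uniform ACGT background sequence and pastes in repeat
#' copies.  Each copy is mutated from the family unit at rate
#' `divergence / 2` (substitutions only), so two copies differ at an expected
#' `divergence` fraction of positions.  The returned truth annotation records
#' exact copy coordinates and the per-copy mutation lists.
#'
#' @param spec A [genome_spec()].
#' @return An `sx_genome` list with elements `seq`, `length`, `circular`,
#'   `repeat_truth` (tibble: repeat, copy, start, end, divergence; 0-based
#'   half-open coordinates) and `mutations` (tibble: repeat, copy, pos, from,
#'   to; `pos` is the 0-based genome coordinate).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    seq <- random_dna(spec$length)
    truth <- list()
    muts <- list()
    for (ri in seq_along(spec$repeats)) {
      rp <- spec$repeats[[ri]]
      unit <- random_dna(rp$unit_length)
      for (ci in seq_along(rp$placements)) {
        p0 <- rp$placements[ci]
        nmut <- stats::rbinom(1L, rp$unit_length, rp$divergence / 2)
        pos <- sort(sample.int(rp$unit_length, nmut))
        mut <- substitute_bases(unit, pos)
        substr(seq, p0 + 1L, p0 + rp$unit_length) <- mut$seq
        truth[[length(truth) + 1]] <- tibble(
          repeat_id = ri, copy = ci, start = p0, end = p0 + rp$unit_length,
          divergence = rp$divergence
        )
        if (nmut > 0) {
          muts[[length(muts) + 1]] <- tibble(
            repeat_id = ri, copy = ci, pos = p0 + pos - 1L,
            from = mut$from, to = mut$to
          )
        }
      }
    }
    structure(
      list(seq = seq, length = spec$length, circular = spec$circular,
           repeat_truth = bind_rows(truth), mutations = bind_rows(muts),
           spec = spec),
      class = "sx_genome"
    )
  })
}

#' @export
print.sx_genome <- function(x, ...) {
  cat("<sx_genome> ", x$length, " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      nrow(x$repeat_truth %||% tibble()), " repeat copies\n", sep = "")
  invisible(x)
}

apply_read_errors <- function(seq, error_rate, mix) {
  n <- nchar(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(n) < error_rate)
  if (length(hit) == 0) return(list(seq = seq, n_errors = 0L))
  op <- sample.int(3L, length(hit), replace = TRUE, prob = mix)
  repl <- x
  sub_i <- hit[op == 1L]
  if (length(sub_i)) {
    repl[sub_i] <- vapply(x[sub_i], function(b) {
      setdiff(c("A", "C", "G", "T"), b)[sample.int(3L, 1L)]
    }, character(1), USE.NAMES = FALSE)
  }
  ins <- character(n)
  ins_i <- hit[op == 2L]
  if (length(ins_i)) {
    ins[ins_i] <- sample(c("A", "C", "G", "T"), length(ins_i), replace = TRUE)
  }
  keep <- rep(TRUE, n)
  keep[hit[op == 3L]] <- FALSE
  parts <- paste0(ins, ifelse(keep, repl, ""))
  list(seq = paste(parts, collapse = ""), n_errors = length(hit))
}

#' Simulate noisy long reads from a genome
#'
#' Read lengths follow a log-normal distribution truncated to
#' `[min_length, max_length]`; start positions are uniform; both strands are
#' sampled with equal probability; per-base errors are uniform random with
#' the given substitution/insertion/deletion mix.  Reads are drawn until the
#' total read bases reach `coverage` times the genome length.  Circular
#' genomes are sampled by virtual concatenation of the first `max_length`
#' bases, so truth `end` coordinates may exceed the genome length.
#'
#' @param genome An `sx_genome` or a plain sequence string.
#' @param coverage Target fold coverage (> 0).
#' @param error_rate Per-base error probability in [0, 0.5].
#' @param error_mix Proportions of substitution, insertion, deletion errors
#'   (normalised to sum to 1).  Default is an even mix.
#' @param length_meanlog,length_sdlog Log-normal parameters of the read
#'   length distribution (defaults give a median read of ~3.3 kb).
#' @param min_length,max_length Truncation bounds for read lengths.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A tibble of reads with truth layout columns: `id`, `seq`,
#'   `length`, `start`, `end` (0-based half-open source interval on the
#'   forward strand), `strand` ("+"/"-"), `n_errors`, `stage = "raw"`.
#' @export
simulate_reads <- function(genome, coverage = 30, error_rate = 0.10,
                           error_mix = c(1, 1, 1) / 3,
                           length_meanlog = 8.1, length_sdlog = 0.45,
                           min_length = 500L, max_length = 15000L,
                           seed = 1L) {
  seq <- if (inherits(genome, "sx_genome")) genome$seq else as.character(genome)
  circular <- if (inherits(genome, "sx_genome")) genome$circular else FALSE
  G <- nchar(seq)
  if (G < 1) abort("genome must be nonempty")
  if (coverage <= 0) abort("coverage must be positive")
  if (error_rate < 0 || error_rate > 0.5) abort("error_rate must be in [0, 0.5]")
  error_mix <- error_mix / sum(error_mix)
  max_eff <- min(max_length, if (circular) G else G)
  if (min_length > max_eff)
    abort("read length distribution incompatible with genome length")
  ext <- if (circular) paste0(seq, substr(seq, 1L, min(max_eff, G))) else seq

  withr::with_seed(seed, {
    target <- coverage * G
    lens <- integer(0)
    while (sum(lens) < target) {
      batch <- round(rlnorm(256L, length_meanlog, length_sdlog))
      batch <- batch[batch >= min_length & batch <= max_eff]
      need <- which(cumsum(batch) >= target - sum(lens))[1]
      if (!is.na(need)) batch <- batch[seq_len(need)]
      lens <- c(lens, batch)
    }
    n <- length(lens)
    starts <- if (circular) {
      floor(runif(n) * G)
    } else {
      floor(runif(n) * (G - lens + 1))
    }
    strands <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- character(n)
    nerr <- integer(n)
    for (i in seq_len(n)) {
      raw <- substr(ext, starts[i] + 1L, starts[i] + lens[i])
      if (strands[i] == "-") raw <- revcomp(raw)
      er <- apply_read_errors(raw, error_rate, error_mix)
      seqs[i] <- er$seq
      nerr[i] <- er$n_errors
    }
    tibble(
      id = seq_len(n), seq = seqs, length = nchar(seqs),
      start = as.integer(starts), end = as.integer(starts + lens),
      strand = strands, n_errors = nerr, stage = "raw"
    )
  })
}

#' Remove reads whose source interval spans a genomic interval
#'
#' Drops every read whose truth source interval fully contains
#' `[interval[1], interval[2])`; used to construct repeat-resolution
#' experiments in which no read spans a repeat copy.
#'
#' @param reads Read tibble with truth `start`/`end` columns.
#' @param interval Length-2 numeric, 0-based half-open genome interval.
#' @return Filtered read tibble.
#' @export
exclude_spanning_reads <- function(reads, interval) {
  stopifnot(length(interval) == 2, all(c("start", "end") %in% names(reads)))
  filter(reads, !(.data$start <= interval[1] & .data$end >= interval[2]))
}

#' Inject chimeric reads into a simulated read set
#'
#' Replaces a fraction of reads with chimeras formed by joining the first
#' part of the read to the tail of another read originating at least
#' `min_distance` away on the genome, emulating library artifacts that join
#' discontiguous loci.
#'
#' @param reads Read tibble with truth columns.
#' @param frac Fraction of reads to convert.
#' @param min_distance Minimum truth distance between joined loci.
#' @param seed Seed.
#' @return Read tibble with logical `is_chimera` and integer
#'   `chimera_junction` (0-based read coordinate of the junction) columns.
#' @export
inject_chimeras <- function(reads, frac = 0.05, min_distance = 10000L, seed = 1L) {
  withr::with_seed(seed, {
    n <- nrow(reads)
    reads$is_chimera <- FALSE
    reads$chimera_junction <- NA_integer_
    m <- max(1L, round(frac * n))
    cand <- sample.int(n, min(2L * m + 10L, n))
    done <- 0L
    for (i in cand) {
      if (done >= m) break
      far <- which(abs(reads$start - reads$start[i]) >= min_distance &
                     !reads$is_chimera)
      far <- setdiff(far, i)
      if (length(far) == 0) next
      j <- far[sample.int(length(far), 1L)]
      la <- reads$length[i]
      lb <- reads$length[j]
      cut <- floor(la * runif(1, 0.3, 0.7))
      tail_len <- min(lb, la - cut)
      chim <- paste0(substr(reads$seq[i], 1L, cut),
                     substr(reads$seq[j], lb - tail_len + 1L, lb))
      reads$seq[i] <- chim
      reads$length[i] <- nchar(chim)
      reads$is_chimera[i] <- TRUE
      reads$chimera_junction[i] <- cut
      done <- done + 1L
    }
    reads
  })
}

#' Inject hairpin-adapter reads into a simulated read set
#'
#' Converts selected reads into `S + adapter + reverse_complement(S)`
#' constructs, the signature of an unremoved hairpin adapter.
#'
#' @param reads Read tibble.
#' @param n Number of reads to convert.
#' @param adapter_length Length of the random adapter linker.
#' @param seed Seed.
#' @return Read tibble with logical `is_hairpin` and integer `hairpin_pivot`
#'   (0-based read coordinate of the adapter midpoint) columns.
#' @export
inject_hairpins <- function(reads, n = 5L, adapter_length = 40L, seed = 1L) {
  withr::with_seed(seed, {
    reads$is_hairpin <- FALSE
    reads$hairpin_pivot <- NA_integer_
    pool <- which(!col_or(reads, "is_chimera", rep(FALSE, nrow(reads))))
    sel <- sample(pool, min(n, length(pool)))
    adapter <- random_dna(adapter_length)
    for (i in sel) {
      s <- reads$seq[i]
      reads$seq[i] <- paste0(s, adapter, revcomp(s))
      reads$length[i] <- nchar(reads$seq[i])
      reads$is_hairpin[i] <- TRUE
      reads$hairpin_pivot[i] <- nchar(s) + adapter_length %/% 2L
    }
    reads
  })
}

# ---------------------------------------------------------------------------
# text-format input/output
# ---------------------------------------------------------------------------

#' Write a genome to FASTA
#' @param genome `sx_genome` or sequence string.
#' @param path Output path.
#' @param name Sequence name.
#' @export
write_genome_fasta <- function(genome, path, name = "genome") {
  seq <- if (inherits(genome, "sx_genome")) genome$seq else as.character(genome)
  writeLines(c(paste0(">", name), seq), path)
  invisible(path)
}

#' Write reads to FASTQ (dummy qualities) or FASTA
#' @param reads Read tibble.
#' @param path Output path; ".fasta"/".fa" suffix selects FASTA.
#' @export
write_reads <- function(reads, path) {
  fasta <- grepl("\\.fa(sta)?$", path)
  if (fasta) {
    out <- rbind(paste0(">read", reads$id), reads$seq)
  } else {
    out <- rbind(paste0("@read", reads$id), reads$seq, "+",
                 vapply(reads$length, function(n) strrep("I", n), character(1)))
  }
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read FASTA/FASTQ reads into the canonical tibble
#' @param path Input path (FASTA or FASTQ, optionally gzipped).
#' @return Read tibble with `id`, `name`, `seq`, `length`, `stage` columns.
#' @export
read_reads <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA/FASTQ requires the Biostrings package")
  }
  first <- substr(readLines(path, n = 1L), 1, 1)
  ss <- if (first == "@") {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  tibble(
    id = seq_along(ss),
    name = sub("\\s.*$", "", names(ss)),
    seq = unname(as.character(ss)),
    length = Biostrings::width(ss),
    stage = "input"
  )
}

#' Write the truth layout as a tab-separated file
#' @param reads Read tibble with truth columns.
#' @param path Output path.
#' @export
write_truth_tsv <- function(reads, path) {
  readr::write_tsv(select(reads, "id", "start", "end", "strand"), path)
  invisible(path)
}
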