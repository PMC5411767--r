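# Three-stage pipeline orchestration (correction -> trimming -> assembly),
# each stage independently runnable, plus configuration and truth-based
# evaluation utilities for simulated data.

#' Assembly configuration
#'
#' One configuration object mirrors the pipeline's key parameters; all
#' defaults are desk-scale choices documented in the methods vignette.
#'
#' @param genome_size Estimated genome size in bases (required for coverage
#'   computations).
#' @param k K-mer size for sketching.
#' @param s Weighted MinHash sketch size.
#' @param filter_cutoff Fraction of distinct k-mers recorded in the
#'   spectrum (default 5e-6).
#' @param min_slot_matches First-stage candidate threshold.
#' @param bottom_size Bottom sketch size.
#' @param min_overlap Minimum overlap length.
#' @param C Expected read depth for correction filters; `NA` = computed
#'   from the data as total bases / genome size.
#' @param cor_out_coverage Coverage of longest reads selected for
#'   correction (default 40).
#' @param min_evidence_depth Depth for corrected-length support.
#' @param min_dag_edge DAG edge weight below which corrected reads split.
#' @param min_read_length Minimum corrected/trimmed read length.
#' @param trim_C,trim_E,trim_L Trimming depth, max error, min length.
#' @param hairpin_min_votes,hairpin_max_spanning Hairpin detection
#'   thresholds.
#' @param chimera_max_spanning Chimeric junction spanning threshold.
#' @param adjust_support_frac,adjust_min_cover Overlap error adjustment
#'   voting parameters.
#' @param mad_mult Error-model MAD multiplier (default 6).
#' @param error_floor Error-model cutoff floor (default 0.015).
#' @param profile_window Error-profile window in bases.
#' @param place_tol_mads Local placement tolerance in window MADs.
#' @param bubble_min_reads Minimum reads for a non-bubble contig.
#' @param repeat_margin_mads "Significantly better" margin for repeat
#'   confirmation.
#' @param store_bucket_size Overlap-store bucket cap.
#' @param tfidf [tfidf_params()].
#' @param correction_rounds Number of correction rounds.
#' @param seed Sketch seed.
#' @return An `assembly_config` list.
#' @export
assembly_config <- function(genome_size = 100000L, k = 16L, s = 256L,
                            filter_cutoff = 5e-6, min_slot_matches = 2L,
                            bottom_size = 1500L, min_overlap = 500L,
                            C = NA_integer_, cor_out_coverage = 40,
                            min_evidence_depth = 2L, min_dag_edge = 4L,
                            min_read_length = 500L,
                            trim_C = 2L, trim_E = 0.045, trim_L = 500L,
                            hairpin_min_votes = 5L, hairpin_max_spanning = 2L,
                            chimera_max_spanning = 1L,
                            adjust_support_frac = 0.4, adjust_min_cover = 4L,
                            mad_mult = 6, error_floor = 0.015,
                            profile_window = 1000L, place_tol_mads = 5,
                            bubble_min_reads = 3L, repeat_margin_mads = 3,
                            store_bucket_size = 250000L,
                            tfidf = tfidf_params(), correction_rounds = 1L,
                            seed = 1L) {
  structure(as.list(environment()), class = "assembly_config")
}

#' @export
print.assembly_config <- function(x, ...) {
  cat("<assembly_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (inherits(v, "tfidf_params"))
      v <- sprintf("a=%g idf_max=%d tf_cap=%d", v$a, v$idf_max, v$tf_cap)
    cat(sprintf("  %-22s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Read an assembly configuration from a YAML file
#' @param path YAML file whose keys match [assembly_config()] arguments.
#' @return An `assembly_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(assembly_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  do.call(assembly_config, vals)
}

#' Run the correction stage
#'
#' @param reads Read tibble (raw reads).
#' @param config [assembly_config()].
#' @return Corrected read tibble (see [correct_reads()]); rounds > 1 chain
#'   correction as for very noisy reads.
#' @export
run_correction <- function(reads, config = assembly_config()) {
  iterate_correction(reads, rounds = config$correction_rounds, config = config)
}

#' Run the trimming stage
#' @param reads Corrected read tibble.
#' @param config [assembly_config()].
#' @return List from [trim_reads()].
#' @export
run_trimming <- function(reads, config = assembly_config()) {
  trim_reads(reads, config = config)
}

#' Run the assembly stage
#' @param reads Trimmed read tibble.
#' @param config [assembly_config()].
#' @return An `sx_assembly` (see [assemble_reads()]).
#' @export
run_assembly <- function(reads, config = assembly_config()) {
  assemble_reads(reads, config = config)
}

#' Run the pipeline end to end
#'
#' @param reads Raw read tibble.
#' @param config [assembly_config()].
#' @param stages Character vector of stages to run, a prefix of
#'   `c("correct", "trim", "assemble")`.
#' @return List with `corrected`, `trimmed` (trim stage list), `assembly`
#'   (when requested) and `report` (summary text).
#' @export
run_pipeline <- function(reads, config = assembly_config(),
                         stages = c("correct", "trim", "assemble")) {
  stages <- match.arg(stages, c("correct", "trim", "assemble"),
                      several.ok = TRUE)
  out <- list()
  cur <- as_read_tbl(reads)
  if ("correct" %in% stages) {
    cur <- run_correction(cur, config)
    out$corrected <- cur
  }
  if ("trim" %in% stages) {
    tr <- run_trimming(cur, config)
    out$trimmed <- tr
    cur <- tr$reads
  }
  if ("assemble" %in% stages) {
    out$assembly <- run_assembly(cur, config)
  }
  out$report <- pipeline_report(out, config)
  out
}

pipeline_report <- function(out, config) {
  lines <- character(0)
  if (!is.null(out$corrected)) {
    lines <- c(lines, sprintf("corrected reads: %d (%s bases)",
                              nrow(out$corrected),
                              format(sum(out$corrected$length), big.mark = ",")))
  }
  if (!is.null(out$trimmed)) {
    cl <- out$trimmed$clear_ranges
    lines <- c(lines, sprintf(
      "trimmed reads: %d kept, %d discarded, %d split",
      sum(cl$status != "discarded"), sum(cl$status == "discarded"),
      sum(cl$status == "split")))
  }
  if (!is.null(out$assembly)) {
    asm <- out$assembly
    lens <- nchar(asm$consensus)
    lines <- c(lines, sprintf(
      "contigs: %d (N50 %d, NG50 %d), classes: %s",
      length(lens), nx_stat(lens), nx_stat(lens, total = config$genome_size),
      paste(sprintf("%s=%d", names(table(asm$contigs$class)),
                    as.integer(table(asm$contigs$class))), collapse = " ")),
      sprintf("error model: median %.3f%% MAD %.3f%% cutoff %.3f%%",
              100 * asm$model$median, 100 * asm$model$mad,
              100 * asm$model$cutoff))
  }
  lines
}

# ---------------------------------------------------------------------------
# truth-based evaluation of simulated assemblies
# ---------------------------------------------------------------------------

#' Truth coordinates of assembled reads
#'
#' Joins a contig layout with the truth columns carried through the
#' pipeline's provenance, giving each layout read a genome interval.
#'
#' @param layout Layout tibble.
#' @param reads Read tibble with `start`/`end`/`strand` truth columns.
#' @return Layout tibble with `t_start`, `t_end`, `t_strand` columns.
#' @export
layout_truth <- function(layout, reads) {
  idx <- match(layout$read, reads$id)
  out <- layout %>% mutate(
    t_start = reads$start[idx], t_end = reads$end[idx],
    t_strand = reads$strand[idx]
  )
  # account for contig-end clipping: a clip on the layout-left of a read
  # removes genome-left bases iff layout orientation matches truth strand
  if (all(c("clip_l", "clip_r") %in% names(layout))) {
    left_is_gleft <- (out$orient == 0L) == (out$t_strand == "+")
    out <- out %>% mutate(
      t_start = .data$t_start +
        ifelse(left_is_gleft, .data$clip_l, .data$clip_r),
      t_end = .data$t_end -
        ifelse(left_is_gleft, .data$clip_r, .data$clip_l)
    )
  }
  out
}

#' Check that a contig maps collinearly to the truth genome
#'
#' A contig is collinear when its layout coordinates map onto truth
#' coordinates by a single shift (in either orientation): the residuals of
#' `truth_mid ~ +/- layout_mid + c` stay within `max_resid`, and
#' consecutive reads' truth intervals are within `max_gap` of touching.
#' A misjoin that connects distant loci, or that mixes the two copies of a
#' repeat, displaces residuals by far more than the alignment jitter.
#'
#' @param rows Layout rows of one contig with truth columns
#'   (see [layout_truth()]).
#' @param max_resid Maximum absolute residual in bases (default 1000).
#' @param backbone_only Check only walked backbone reads when the layout
#'   records sources; individually placed contained reads do not define the
#'   contig's structure.
#' @param max_gap Maximum truth gap between layout-consecutive reads.
#' @return Logical scalar.
#' @export
contig_collinear <- function(rows, max_resid = 1000, max_gap = 500,
                             backbone_only = TRUE) {
  if (backbone_only && "source" %in% names(rows)) {
    bb <- rows %>% filter(.data$source == "walk")
    if (nrow(bb) > 0) rows <- bb
  }
  rows <- rows %>% arrange(.data$begin, .data$read) %>%
    filter(!is.na(.data$t_start))
  if (nrow(rows) <= 1) return(TRUE)
  mid_l <- (rows$begin + rows$end) / 2
  mid_t <- (rows$t_start + rows$t_end) / 2
  res_f <- mid_t - mid_l
  res_r <- mid_t + mid_l
  dev <- function(r) max(abs(r - median(r)))
  if (dev(res_f) > max_resid && dev(res_r) > max_resid) return(FALSE)
  gap_ok <- vapply(seq_len(nrow(rows) - 1), function(i) {
    lo <- max(rows$t_start[i], rows$t_start[i + 1])
    hi <- min(rows$t_end[i], rows$t_end[i + 1])
    hi - lo >= -max_gap
  }, logical(1))
  all(gap_ok)
}

#' Is a two-copy repeat resolved into its correct flanking contigs?
#'
#' Succeeds when every contig is truth-collinear (no misjoins) and, for
#' each repeat copy, a single collinear contig covers the copy plus at
#' least `flank` bases of unique sequence on both sides — which pins each
#' copy to its correct flanks.
#'
#' @param assembly An `sx_assembly`.
#' @param reads Read tibble with truth columns (the assembly input).
#' @param repeat_truth Tibble with `start`/`end` per repeat copy (e.g.
#'   `genome$repeat_truth`).
#' @param flank Unique flank coverage required on each side (bases).
#' @return Logical scalar.
#' @export
repeat_resolved <- function(assembly, reads, repeat_truth, flank = 2000) {
  lt <- layout_truth(assembly$layout, reads)
  main <- assembly$contigs %>% filter(.data$class %in% c("contig", "repeat"))
  for (cg in unique(lt$contig)) {
    if (!contig_collinear(lt[lt$contig == cg, ])) return(FALSE)
  }
  if ("source" %in% names(lt)) {
    bb <- lt %>% filter(.data$source == "walk")
    if (nrow(bb) > 0) lt <- bb
  }
  for (i in seq_len(nrow(repeat_truth))) {
    rs <- repeat_truth$start[i]
    re <- repeat_truth$end[i]
    okc <- FALSE
    for (cg in main$contig) {
      rows <- lt %>% filter(.data$contig == cg, !is.na(.data$t_start))
      if (nrow(rows) == 0) next
      cov <- covered_bases(rows$t_start, rows$t_end, 1L)
      span_s <- min(rows$t_start)
      span_e <- max(rows$t_end)
      if (span_s <= rs - flank && span_e >= re + flank) {
        # require contiguous coverage across the copy and both flanks
        sub <- rows %>% filter(.data$t_end > rs - flank, .data$t_start < re + flank)
        cov_in <- covered_bases(pmax(sub$t_start, rs - flank),
                                pmin(sub$t_end, re + flank), 1L)
        if (cov_in >= (re - rs) + 2 * flank - 200) { okc <- TRUE; break }
      }
    }
    if (!okc) return(FALSE)
  }
  TRUE
}

#' Identity of the assembly consensus to the truth genome
#'
#' Maps each contig to its truth interval via the layout provenance and
#' computes banded edit-distance identity of consensus vs truth.
#'
#' @param assembly An `sx_assembly`.
#' @param reads Read tibble with truth columns.
#' @param genome `sx_genome` or genome sequence.
#' @return Tibble `contig`, `t_start`, `t_end`, `identity`,
#'   `length_ratio` (consensus length / truth interval length).
#' @export
assembly_identity <- function(assembly, reads, genome) {
  gseq <- if (inherits(genome, "sx_genome")) genome$seq else as.character(genome)
  lt <- layout_truth(assembly$layout, reads)
  out <- list()
  for (nm in names(assembly$consensus)) {
    cg <- as.integer(nm)
    rows <- lt %>% filter(.data$contig == cg, !is.na(.data$t_start))
    if (nrow(rows) == 0) next
    ts <- max(0L, min(rows$t_start))
    te <- min(nchar(gseq), max(rows$t_end))
    truth <- substr(gseq, ts + 1L, te)
    cons <- assembly$consensus[[nm]]
    # a contig may be assembled on either strand: orient by the majority of
    # layout-vs-truth strand agreements
    concord <- mean((rows$orient == 0L) == (rows$t_strand == "+"), na.rm = TRUE)
    if (!is.na(concord) && concord < 0.5) cons <- revcomp(cons)
    id <- sequence_identity(cons, truth)
    out[[length(out) + 1]] <- tibble(
      contig = cg, t_start = ts, t_end = te,
      identity = id$identity,
      length_ratio = nchar(cons) / max(1L, te - ts)
    )
  }
  bind_rows(out)
}

#' Sweep repeat divergence and find the resolution threshold
#'
#' Simulates a genome with a two-copy repeat at each divergence, removes
#' all reads spanning either copy, runs the full pipeline, and reports
#' whether the repeat was resolved into its correct flanking contigs.
#'
#' @param divergences Numeric vector of pairwise divergences (fractions).
#' @param genome_length Total genome length.
#' @param repeat_length Repeat unit length.
#' @param coverage Read coverage.
#' @param error_rate Read error rate.
#' @param seed Base seed.
#' @param config Optional [assembly_config()]; genome size is overridden.
#' @return Tibble `divergence`, `resolved`, `n_contigs`, `cutoff`.
#' @export
divergence_sweep <- function(divergences = seq(0, 0.08, by = 0.01),
                             genome_length = 60000L, repeat_length = 8000L,
                             coverage = 30, error_rate = 0.10, seed = 1L,
                             config = NULL) {
  flank <- round((genome_length - 2 * repeat_length) / 3)
  p1 <- flank
  p2 <- 2 * flank + repeat_length
  out <- list()
  for (d in divergences) {
    gs <- genome_spec(
      genome_length,
      repeats = repeat_spec(repeat_length, d, c(p1, p2)),
      seed = seed + round(1000 * d)
    )
    genome <- simulate_genome(gs)
    reads <- simulate_reads(genome, coverage = coverage,
                            error_rate = error_rate, seed = seed)
    for (i in seq_len(nrow(genome$repeat_truth))) {
      reads <- exclude_spanning_reads(
        reads, c(genome$repeat_truth$start[i], genome$repeat_truth$end[i]))
    }
    cfg <- config %||% assembly_config(genome_size = genome_length, seed = seed)
    cfg$genome_size <- genome_length
    res <- run_pipeline(reads, cfg)
    trimmed <- res$trimmed$reads
    resolved <- repeat_resolved(res$assembly, trimmed, genome$repeat_truth)
    out[[length(out) + 1]] <- tibble(
      divergence = d, resolved = resolved,
      n_contigs = nrow(res$assembly$contigs),
      cutoff = res$assembly$model$cutoff
    )
  }
  bind_rows(out)
}

#' Minimum divergence at which the repeat is stably resolved
#'
#' The resolution threshold is the smallest divergence such that the
#' repeat is resolved at that divergence and at every larger swept value.
#'
#' @param sweep Output of [divergence_sweep()].
#' @return Divergence fraction, or `NA` if never resolved.
#' @export
resolution_threshold <- function(sweep) {
  sweep <- sweep %>% arrange(.data$divergence)
  ok <- rev(cumprod(rev(sweep$resolved))) == 1
  if (!any(ok)) return(NA_real_)
  min(sweep$divergence[ok])
}
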