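# Greedy best-overlap-graph assembly with statistical repeat separation:
# automatic error-threshold estimation, suspicious-read filtering, best-edge
# selection, contig construction, per-window error profiles, contained-read
# placement, bubble handling, and repeat annotation/splitting.

#' Estimate the overlap error model from best edges
#'
#' The residual read error left after correction is summarised by the median
#' and median absolute deviation (MAD, unscaled) of the best-edge error
#' rates; the global overlap error cutoff is `median + mad_mult * MAD`,
#' floored at `floor` (default 1.5%, near the typical auto-selected operating point
#' for corrected long reads) to handle degenerate or over-tight
#' distributions.
#'
#' @param errors Numeric error rates (e.g. of best edges) or a best-edge
#'   tibble with an `error` column.
#' @param mad_mult MAD multiplier (default 6).
#' @param floor Minimum cutoff (default 0.015).
#' @return An `error_model` with `median`, `mad`, `cutoff`.
#' @export
estimate_error_model <- function(errors, mad_mult = 6, floor = 0.015) {
  if (is.data.frame(errors)) errors <- errors$error
  if (length(errors) == 0) abort("cannot estimate an error model from zero best edges")
  med <- median(errors)
  md <- mad(errors, constant = 1)
  structure(
    list(median = med, mad = md, mad_mult = mad_mult, floor = floor,
         cutoff = max(med + mad_mult * md, floor), n = length(errors)),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> median %.4f%%, MAD %.4f%%, cutoff %.4f%% (n = %d)\n",
              100 * x$median, 100 * x$mad, 100 * x$cutoff, x$n))
  invisible(x)
}

# which end of read a does a dovetail overlap use? ("5", "3", "both", "none")
overlap_end <- function(ov, read_len, slop) {
  left <- ov$a_start <= slop
  right <- read_len - ov$a_end <= slop
  dplyr::case_when(left & right ~ "both", left ~ "5", right ~ "3",
                   TRUE ~ "none")
}

end_slop <- function(len) pmax(100, floor(0.03 * len))

annotate_ends <- function(overlaps, reads) {
  la <- reads$length[read_index(reads, overlaps$a)]
  lb <- reads$length[read_index(reads, overlaps$b)]
  overlaps %>% mutate(
    a_len = la, b_len = lb,
    a_use = overlap_end(overlaps, la, end_slop(la)),
    b_use = {
      tmp <- tibble(a_start = overlaps$b_start, a_end = overlaps$b_end)
      overlap_end(tmp, lb, end_slop(lb))
    },
    ovl_len = pmax(.data$a_end - .data$a_start, .data$b_end - .data$b_start)
  )
}

#' Flag contained reads
#' @param overlaps Annotated symmetric overlaps (internal).
#' @return Integer vector of contained read ids.
#' @keywords internal
contained_ids <- function(overlaps) {
  unique(overlaps$a[overlaps$a_use == "both"])
}

#' Pick the best (longest qualifying dovetail) overlap per read end
#'
#' @param overlaps Symmetric overlap tibble.
#' @param reads Read tibble.
#' @param model Optional [estimate_error_model()]; when given, overlaps with
#'   error above the cutoff are excluded.
#' @param exclude Read ids excluded from graph construction (flagged or
#'   contained); neither endpoint may be excluded.
#' @return Best-edge tibble: `read`, `end` ("5"/"3"), `partner`,
#'   `partner_end`, `ovl_len`, `error`, `orient`, plus interval columns.
#' @export
pick_best_edges <- function(overlaps, reads, model = NULL, exclude = integer()) {
  ann <- annotate_ends(overlaps, reads)
  qual <- ann %>%
    filter(.data$a_use %in% c("5", "3"), .data$b_use %in% c("5", "3"),
           !(.data$a %in% exclude), !(.data$b %in% exclude))
  if (!is.null(model)) qual <- filter(qual, .data$error <= model$cutoff)
  qual %>%
    arrange(.data$a, .data$a_use, desc(.data$ovl_len), .data$error, .data$b) %>%
    group_by(.data$a, .data$a_use) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    select(read = "a", end = "a_use", partner = "b", partner_end = "b_use",
           "ovl_len", "error", "orient", "a_start", "a_end", "b_start",
           "b_end", "a_len", "b_len")
}

#' Flag suspicious reads before graph construction
#'
#' Reads not fully covered (up to an end slop) by overlaps below the error
#' cutoff are flagged as potentially chimeric; reads whose best edge is
#' nonmutual with a large overlap-length disagreement are flagged as
#' anomalous.  Flagged reads are excluded from contig seeding and walking
#' but may be placed later.
#'
#' @param reads Read tibble.
#' @param overlaps Symmetric overlap tibble.
#' @param model [estimate_error_model()].
#' @param cov_slop Uncovered end slack in bases.
#' @param len_ratio Nonmutual flag when our overlap is shorter than this
#'   fraction of the partner's mutual-best overlap length.
#' @return List with `chimeric`, `nonmutual` (id vectors).
#' @export
filter_suspicious_reads <- function(reads, overlaps, model, cov_slop = 100L,
                                    len_ratio = 0.5) {
  qual <- overlaps %>% filter(.data$error <= model$cutoff)
  chimeric <- integer(0)
  for (i in seq_len(nrow(reads))) {
    rid <- reads$id[i]
    len <- reads$length[i]
    ov <- qual[qual$a == rid, ]
    cov <- covered_bases(pmax(ov$a_start, cov_slop),
                         pmin(ov$a_end, len - cov_slop), 1L)
    if (cov < len - 2L * cov_slop) chimeric <- c(chimeric, rid)
  }
  contained <- contained_ids(annotate_ends(overlaps, reads))
  best <- pick_best_edges(overlaps, reads, model = model, exclude = contained)
  nonmutual <- integer(0)
  if (nrow(best) > 0) {
    bk <- best %>% mutate(key = paste(.data$read, .data$end))
    for (i in seq_len(nrow(bk))) {
      rec <- bk[bk$read == bk$partner[i] & bk$end == bk$partner_end[i], ]
      if (nrow(rec) == 0) next
      if (rec$partner[1] == bk$read[i]) next  # mutual
      if (bk$ovl_len[i] < len_ratio * rec$ovl_len[1])
        nonmutual <- c(nonmutual, bk$read[i])
    }
  }
  list(chimeric = unique(chimeric), nonmutual = unique(nonmutual))
}

# contig-coordinate placement of a partner read given the current read's
# placement and the overlap record (midpoint matching, reversal-invariant)
place_partner <- function(p0, la, co, ov) {
  flip <- ov$orient == "-"
  po <- xor(co == 1L, flip)
  ma <- (ov$a_start + ov$a_end) / 2
  mb <- (ov$b_start + ov$b_end) / 2
  cma <- if (co == 0L) p0 + ma else p0 + la - ma
  q0 <- if (!po) cma - mb else cma - (ov$b_len - mb)
  list(q0 = q0, orient = as.integer(po))
}

#' Build initial contigs from the best overlap graph
#'
#' Greedy walk: seeds are unused, unflagged, non-contained reads in id
#' order; each seed extends in both the 5' and 3' directions following best
#' edges until encountering no overlap, a flagged or contained read, or a
#' read already incorporated in another contig.
#'
#' @param reads Read tibble.
#' @param best_edges [pick_best_edges()] output (qualifying edges only).
#' @param exclude Flagged/contained read ids (not walkable).
#' @return Layout tibble: `contig`, `read`, `orient` (0 forward / 1
#'   reverse), `begin`, `end` (contig coordinates).
#' @export
build_contigs <- function(reads, best_edges, exclude = integer()) {
  edge_key <- paste(best_edges$read, best_edges$end)
  used <- new.env(parent = emptyenv())
  layouts <- list()
  contig_i <- 0L
  walkable <- setdiff(reads$id, exclude)

  for (seed in sort(walkable)) {
    if (!is.null(used[[as.character(seed)]])) next
    contig_i <- contig_i + 1L
    la <- reads$length[match(seed, reads$id)]
    rows <- tibble(read = seed, orient = 0L, begin = 0, end = la)
    used[[as.character(seed)]] <- TRUE

    for (dir in c("3", "5")) {
      cur <- seed
      cur_or <- 0L
      cur_begin <- 0
      cur_end <- la
      # the read end (in read coordinates) pointing in walk direction
      cur_exit <- dir
      repeat {
        i <- match(paste(cur, cur_exit), edge_key)
        if (is.na(i)) break
        e <- best_edges[i, ]
        nxt <- e$partner
        if (nxt %in% exclude) break
        if (!is.null(used[[as.character(nxt)]])) break
        # only mutual best edges are walkable: the partner's best overlap
        # on the entered end must point back
        j <- match(paste(nxt, e$partner_end), edge_key)
        if (is.na(j) || best_edges$partner[j] != cur) break
        pl <- place_partner(cur_begin, e$a_len, cur_or, e)
        used[[as.character(nxt)]] <- TRUE
        rows <- bind_rows(rows, tibble(read = nxt, orient = pl$orient,
                                       begin = pl$q0, end = pl$q0 + e$b_len))
        cur <- nxt
        cur_or <- pl$orient
        cur_begin <- pl$q0
        cur_end <- pl$q0 + e$b_len
        # we entered through partner_end; exit through the other read end
        cur_exit <- if (e$partner_end == "5") "3" else "5"
      }
    }
    off <- min(rows$begin)
    rows$begin <- as.integer(round(rows$begin - off))
    rows$end <- as.integer(round(rows$end - off))
    rows$contig <- contig_i
    rows$source <- "walk"
    layouts[[contig_i]] <- rows
  }
  if (length(layouts) == 0) {
    return(tibble(contig = integer(), read = integer(), orient = integer(),
                  begin = integer(), end = integer(), source = character()))
  }
  bind_rows(layouts) %>%
    arrange(.data$contig, .data$begin, .data$read) %>%
    select("contig", "read", "orient", "begin", "end", "source")
}

#' Per-window error profile of a contig
#'
#' Windows tile the contig; each window summarises (median, unscaled MAD)
#' the error rates of overlaps between contig reads whose projected
#' interval intersects the window.  Empty windows inherit the previous
#' (then next) window's values.
#'
#' @param layout Layout rows of one contig.
#' @param overlaps Symmetric overlap tibble.
#' @param window Window size in bases (default 1000).
#' @return Tibble `win_start`, `win_end`, `median`, `mad`, `n`.
#' @export
compute_error_profile <- function(layout, overlaps, window = 1000L) {
  len <- max(layout$end)
  starts <- seq(0L, max(0L, len - 1L), by = window)
  ids <- layout$read
  pos <- layout %>% select("read", "begin", "end")
  ov <- overlaps %>%
    filter(.data$a %in% ids, .data$b %in% ids, .data$a < .data$b) %>%
    left_join(pos, by = c(a = "read")) %>%
    rename(pa_b = "begin", pa_e = "end") %>%
    left_join(pos, by = c(b = "read")) %>%
    rename(pb_b = "begin", pb_e = "end") %>%
    mutate(proj_s = pmax(.data$pa_b, .data$pb_b),
           proj_e = pmin(.data$pa_e, .data$pb_e)) %>%
    filter(.data$proj_e > .data$proj_s)
  prof <- tibble(win_start = as.integer(starts),
                 win_end = as.integer(pmin(starts + window, len)),
                 median = NA_real_, mad = NA_real_, n = 0L)
  for (w in seq_len(nrow(prof))) {
    hit <- ov$proj_s < prof$win_end[w] & ov$proj_e > prof$win_start[w]
    if (any(hit)) {
      prof$median[w] <- median(ov$error[hit])
      prof$mad[w] <- mad(ov$error[hit], constant = 1)
      prof$n[w] <- sum(hit)
    }
  }
  # inherit from neighbours
  for (w in seq_len(nrow(prof))) {
    if (is.na(prof$median[w]) && w > 1) {
      prof$median[w] <- prof$median[w - 1]; prof$mad[w] <- prof$mad[w - 1]
    }
  }
  for (w in rev(seq_len(nrow(prof)))) {
    if (is.na(prof$median[w]) && w < nrow(prof)) {
      prof$median[w] <- prof$median[w + 1]; prof$mad[w] <- prof$mad[w + 1]
    }
  }
  prof
}

profile_tolerance <- function(profile, at, mads = 5, floor = 0.005) {
  w <- findInterval(at, profile$win_start)
  w <- pmin(pmax(w, 1L), nrow(profile))
  pmax(profile$median[w] + mads * profile$mad[w], floor)
}

# Vectorised candidate placements for a set of reads onto a fixed layout:
# one row per (read, contig, position cluster), scored by mean overlap
# error, positioned at the cluster's best (lowest-error, longest) overlap.
batch_placements <- function(ids, reads, overlaps, layout,
                             cluster_width = 2000) {
  empty <- tibble(a = integer(), contig = integer(), q0 = numeric(),
                  orient = integer(), la = integer(), error = numeric(),
                  n_ov = integer())
  if (length(ids) == 0 || nrow(layout) == 0) return(empty)
  ov <- overlaps[overlaps$a %in% ids & overlaps$b %in% layout$read, ]
  if (nrow(ov) == 0) return(empty)
  hit <- match(ov$b, layout$read)
  p0 <- layout$begin[hit]
  plen <- layout$end[hit] - p0
  p_or <- layout$orient[hit]
  contig <- layout$contig[hit]
  la <- reads$length[match(ov$a, reads$id)]
  flip <- ov$orient == "-"
  po <- as.integer(xor(p_or == 1L, flip))
  mb <- (ov$a_start + ov$a_end) / 2  # midpoint on the read being placed
  ma <- (ov$b_start + ov$b_end) / 2  # midpoint on the placed partner
  cma <- ifelse(p_or == 0L, p0 + ma, p0 + plen - ma)
  q0 <- ifelse(po == 0L, cma - mb, cma - (la - mb))
  tibble(a = ov$a, contig = contig, q0 = q0, orient = po, la = la,
         error = ov$error, ovl = pmax(ov$a_end - ov$a_start, 1L)) %>%
    mutate(cluster = round(.data$q0 / cluster_width)) %>%
    arrange(.data$error, desc(.data$ovl)) %>%
    group_by(.data$a, .data$contig, .data$cluster) %>%
    summarise(q0 = first(.data$q0), orient = first(.data$orient),
              la = first(.data$la), mean_error = mean(.data$error),
              n_ov = dplyr::n(), .groups = "drop") %>%
    rename(error = "mean_error") %>%
    select("a", "contig", "q0", "orient", "la", "error", "n_ov")
}

# per-row local tolerance lookup across contig profiles
placement_tolerance <- function(plc, profiles, tol_mads) {
  tol <- rep(NA_real_, nrow(plc))
  for (cg in unique(plc$contig)) {
    pr <- profiles[[as.character(cg)]]
    if (is.null(pr)) next
    i <- which(plc$contig == cg)
    tol[i] <- profile_tolerance(pr, pmax(0, plc$q0[i]), tol_mads)
  }
  tol
}

#' Place contained and previously filtered reads into contigs
#'
#' Every unplaced read's overlaps to placed reads define candidate
#' placements scored by mean overlap error; a placement is rejected when its
#' mean error exceeds the contig's local error profile tolerance
#' (window median + `tol_mads` window MADs).  The lowest-error accepted
#' placement wins; reads with no accepted placement are "unassembled".
#'
#' @param reads Read tibble.
#' @param layout Current layout tibble.
#' @param overlaps Symmetric overlap tibble.
#' @param profiles Named list of per-contig error profiles.
#' @param tol_mads Local tolerance multiplier (default 5).
#' @return List `layout` (augmented), `placed`, `unassembled` (id vectors).
#' @export
place_contained_reads <- function(reads, layout, overlaps, profiles,
                                  tol_mads = 5) {
  unplaced <- setdiff(reads$id, layout$read)
  plc <- batch_placements(unplaced, reads, overlaps, layout)
  acc <- plc[0, ]
  if (nrow(plc) > 0) {
    plc$tol <- placement_tolerance(plc, profiles, tol_mads)
    # placements live inside the contig: reads hanging off the walked
    # extent are not contained there
    ext <- layout %>%
      group_by(.data$contig) %>%
      summarise(c_len = max(.data$end), .groups = "drop")
    plc <- plc %>% left_join(ext, by = "contig") %>%
      filter(.data$q0 >= -200, .data$q0 + .data$la <= .data$c_len + 200)
    acc <- plc %>%
      filter(!is.na(.data$tol), .data$error <= .data$tol) %>%
      arrange(.data$a, .data$error, .data$q0) %>%
      group_by(.data$a) %>%
      slice_head(n = 1) %>%
      ungroup()
  }
  if (nrow(acc) > 0) {
    add <- tibble(contig = acc$contig, read = acc$a, orient = acc$orient,
                  begin = as.integer(round(acc$q0)),
                  end = as.integer(round(acc$q0)) + acc$la,
                  source = "placed")
    layout <- bind_rows(layout, add) %>%
      arrange(.data$contig, .data$begin, .data$read)
  }
  list(layout = layout, placed = acc$a,
       unassembled = setdiff(unplaced, acc$a))
}

#' Identify and absorb assembly bubbles
#'
#' Contigs with fewer than `min_reads` reads, or with more than 75% of
#' their reads overlapping reads of other contigs, are potential bubbles:
#' their reads are re-placed into other contigs where the local error
#' profile accepts them.  Fully absorbed contigs are removed; unplaceable
#' bubble contigs are retained and labelled `"bubble"`.
#'
#' @param reads Read tibble.
#' @param layout Layout tibble.
#' @param overlaps Symmetric overlaps.
#' @param profiles Per-contig profiles (list).
#' @param min_reads Bubble read-count threshold (default 3).
#' @param tol_mads Placement tolerance multiplier.
#' @return List `layout`, `bubble_contigs` (ids retained as bubbles).
#' @export
handle_bubbles <- function(reads, layout, overlaps, profiles, min_reads = 3L,
                           tol_mads = 5) {
  sizes <- layout %>% dplyr::count(.data$contig)
  bubbles <- integer(0)
  dropped <- integer(0)
  for (cg in sizes$contig) {
    rows <- layout[layout$contig == cg, ]
    others <- layout[layout$contig != cg, ]
    if (nrow(others) == 0) next
    frac_ext <- mean(rows$read %in%
                       overlaps$a[overlaps$b %in% others$read])
    # a bubble is the smaller, locus-scale alternate reconstruction: never
    # consider a contig holding the majority of the overlapping reads, and
    # leave large multi-locus structures to the repeat-splitting phase
    n_largest_other <- max(sizes$n[sizes$contig != cg])
    if (nrow(rows) >= min_reads &&
        (frac_ext <= 0.75 || nrow(rows) > 0.5 * n_largest_other ||
           nrow(rows) > 50)) next
    # try to place every read of this contig elsewhere
    plc <- batch_placements(rows$read, reads, overlaps, others)
    acc <- plc[0, ]
    if (nrow(plc) > 0) {
      plc$tol <- placement_tolerance(plc, profiles, tol_mads)
      ext <- others %>%
        group_by(.data$contig) %>%
        summarise(c_len = max(.data$end), .groups = "drop")
      plc <- plc %>% left_join(ext, by = "contig") %>%
        filter(.data$q0 >= -200, .data$q0 + .data$la <= .data$c_len + 200)
      acc <- plc %>%
        filter(!is.na(.data$tol), .data$error <= .data$tol) %>%
        arrange(.data$a, .data$error, .data$q0) %>%
        group_by(.data$a) %>%
        slice_head(n = 1) %>%
        ungroup()
    }
    n_reads_cg <- length(unique(rows$read))
    if (nrow(acc) >= ceiling(0.9 * n_reads_cg)) {
      # dissolve: re-place what places; the remainder is unassembled
      add <- tibble(contig = acc$contig, read = acc$a, orient = acc$orient,
                    begin = as.integer(round(acc$q0)),
                    end = as.integer(round(acc$q0)) + acc$la,
                    source = "placed")
      dropped <- c(dropped, setdiff(rows$read, acc$a))
      layout <- bind_rows(others, add) %>%
        arrange(.data$contig, .data$begin, .data$read)
    } else {
      bubbles <- c(bubbles, cg)
    }
  }
  list(layout = layout, bubble_contigs = bubbles, dropped = dropped)
}

#' Annotate conflicting external reads and split unconfirmed repeats
#'
#' External reads whose overlaps are compatible with a contig's local error
#' profile, but which end inside the contig while the read continues,
#' indicate an alternative branch (a repeat boundary).  A merged annotated
#' region is confirmed when a layout read spans it, or when the internal
#' joining overlap is better than the best conflicting overlap by at least
#' `margin_mads` local MADs; otherwise the contig is split into flanks and
#' a middle piece labelled `"repeat"`.
#'
#' @param reads Read tibble.
#' @param layout Layout tibble.
#' @param overlaps Symmetric overlaps.
#' @param profiles Per-contig profiles.
#' @param model Global [estimate_error_model()].
#' @param bubble_contigs Contigs excluded as conflict sources.
#' @param tol_mads Local profile tolerance multiplier.
#' @param margin_mads "Significantly better" margin (default 3).
#' @param min_conflict Minimum conflicting reads to annotate a region.
#' @return List `layout` (with possibly renumbered split contigs) and
#'   `classes` tibble (`contig`, `class`).
#' @export
split_repeats <- function(reads, layout, overlaps, profiles, model,
                          bubble_contigs = integer(), tol_mads = 5,
                          margin_mads = 3, min_conflict = 1L) {
  classes <- tibble(contig = unique(layout$contig), class = "contig")
  classes$class[classes$contig %in% bubble_contigs] <- "bubble"
  out_layout <- list()
  next_id <- max(layout$contig) + 1L
  new_classes <- list()

  for (cg in unique(layout$contig)) {
    rows <- layout[layout$contig == cg, ] %>% arrange(.data$begin)
    cls <- classes$class[classes$contig == cg]
    if (cls == "bubble" || nrow(rows) < 3) {
      out_layout[[length(out_layout) + 1]] <- rows
      new_classes[[length(new_classes) + 1]] <- tibble(contig = cg, class = cls)
      next
    }
    prof <- profiles[[as.character(cg)]]
    clen <- max(rows$end)
    ext_ids <- setdiff(reads$id, rows$read)
    ext_ids <- setdiff(ext_ids, layout$read[layout$contig %in% bubble_contigs])
    # external reads with profile-compatible overlaps to this contig
    ext_ov <- overlaps %>%
      filter(.data$a %in% ext_ids, .data$b %in% rows$read,
             .data$error <= model$cutoff)
    conf <- tibble()
    if (nrow(ext_ov) > 0) {
      plc <- batch_placements(unique(ext_ov$a), reads, ext_ov,
                              rows %>% mutate(contig = cg)) %>%
        arrange(.data$a, .data$error) %>%
        group_by(.data$a) %>%
        slice_head(n = 1) %>%
        ungroup()
      if (nrow(plc) > 0) {
        plc$tol <- profile_tolerance(prof, pmax(0, plc$q0), tol_mads)
        plc <- plc %>% filter(!is.na(.data$tol), .data$error <= .data$tol)
      }
      if (nrow(plc) > 0) {
        # supported interval per read: union of its projected overlaps
        hit <- match(ext_ov$b, rows$read)
        ovp <- tibble(a = ext_ov$a, bb = rows$begin[hit], be = rows$end[hit]) %>%
          semi_join(plc, by = "a") %>%
          left_join(plc %>% select("a", "q0", "la", "error"), by = "a") %>%
          mutate(ps = pmax(.data$bb, .data$q0),
                 pe = pmin(.data$be, .data$q0 + .data$la)) %>%
          group_by(.data$a) %>%
          summarise(sup_s = min(.data$ps), sup_e = max(.data$pe),
                    q0 = first(.data$q0), la = first(.data$la),
                    err = first(.data$error), .groups = "drop") %>%
          mutate(lead_in = .data$sup_s - .data$q0,
                 lead_out = .data$q0 + .data$la - .data$sup_e)
        conf <- ovp %>%
          filter((.data$lead_out > 300 & .data$sup_e < clen - 300) |
                   (.data$lead_in > 300 & .data$sup_s > 300)) %>%
          select(s = "sup_s", e = "sup_e", "err")
      }
    }
    if (nrow(conf) < max(min_conflict, 2L)) {
      out_layout[[length(out_layout) + 1]] <- rows
      new_classes[[length(new_classes) + 1]] <- tibble(contig = cg, class = cls)
      next
    }
    conf <- conf %>% arrange(.data$s)
    # merge overlapping annotated regions
    regions <- list()
    cur <- conf[1, c("s", "e")]
    cur_err <- conf$err[1]
    for (i in seq_len(nrow(conf))[-1]) {
      if (conf$s[i] <= cur$e) {
        cur$e <- max(cur$e, conf$e[i])
        cur_err <- min(cur_err, conf$err[i])
      } else {
        regions[[length(regions) + 1]] <- c(cur$s, cur$e, cur_err)
        cur <- conf[i, c("s", "e")]
        cur_err <- conf$err[i]
      }
    }
    regions[[length(regions) + 1]] <- c(cur$s, cur$e, cur_err)

    split_at <- NULL
    for (rg in regions) {
      rs <- rg[1]; re <- rg[2]; conflict_err <- rg[3]
      spanned <- any(rows$begin <= rs - 100 & rows$end >= re + 100)
      if (spanned) next
      # internal joining overlaps across the region
      internal <- overlaps %>%
        filter(.data$a %in% rows$read, .data$b %in% rows$read,
               .data$a < .data$b)
      pos <- rows %>% select("read", "begin", "end")
      internal <- internal %>%
        left_join(pos, by = c(a = "read")) %>% rename(ab = "begin", ae = "end") %>%
        left_join(pos, by = c(b = "read")) %>% rename(bb = "begin", be = "end") %>%
        filter(pmax(.data$ab, .data$bb) < re, pmin(.data$ae, .data$be) > rs)
      int_err <- if (nrow(internal) > 0) min(internal$error) else NA_real_
      wloc <- min(max(findInterval((rs + re) / 2, prof$win_start), 1L), nrow(prof))
      local_mad <- max(prof$mad[wloc], 5e-4, na.rm = TRUE)
      if (!is.na(int_err) && !is.na(conflict_err) &&
          int_err <= conflict_err - margin_mads * local_mad) next
      split_at <- rbind(split_at, c(rs, re))
    }
    if (is.null(split_at)) {
      out_layout[[length(out_layout) + 1]] <- rows
      new_classes[[length(new_classes) + 1]] <- tibble(contig = cg, class = cls)
      next
    }
    # split the contig at the unconfirmed regions (by read midpoint)
    bounds <- sort(unique(as.vector(split_at)))
    cutpoints <- c(0, bounds, clen + 1)
    mid <- (rows$begin + rows$end) / 2
    piece <- findInterval(mid, cutpoints, rightmost.closed = TRUE)
    repeat_pieces <- unique(findInterval((split_at[, 1] + split_at[, 2]) / 2,
                                         cutpoints, rightmost.closed = TRUE))
    for (pc in sort(unique(piece))) {
      sub <- rows[piece == pc, ]
      if (nrow(sub) == 0) next
      sub$contig <- next_id
      off <- min(sub$begin)
      sub$begin <- sub$begin - off
      sub$end <- sub$end - off
      out_layout[[length(out_layout) + 1]] <- sub
      new_classes[[length(new_classes) + 1]] <- tibble(
        contig = next_id,
        class = if (pc %in% repeat_pieces) "repeat" else "contig"
      )
      next_id <- next_id + 1L
    }
  }
  list(layout = bind_rows(out_layout),
       classes = bind_rows(new_classes))
}

#' Assemble trimmed reads into contigs with the best-overlap-graph strategy
#'
#' Runs the full graph-construction phase: initial best edges from all
#' overlaps, automatic error model (median + 6 MAD), suspicious-read
#' filtering, qualifying best edges, greedy contig construction, per-contig
#' error profiles, contained-read placement, bubble handling, repeat
#' annotation/splitting, and per-contig DAG consensus.
#'
#' @param reads Read tibble (trimmed reads).
#' @param config [assembly_config()].
#' @param overlaps Optional precomputed symmetric overlap tibble with
#'   adjusted error rates.
#' @return An `sx_assembly` object: `contigs` (tibble with class, length,
#'   n_reads, consensus length), `layout`, `consensus` (named character),
#'   `model`, `profiles`, `links`, `unassembled`, `flags`.
#' @export
assemble_reads <- function(reads, config = assembly_config(), overlaps = NULL) {
  reads <- as_read_tbl(reads)
  if (is.null(overlaps)) {
    ov <- overlap_reads(
      reads, k = config$k, s = config$s, filter_cutoff = config$filter_cutoff,
      params = config$tfidf, min_slot_matches = config$min_slot_matches,
      bottom_size = config$bottom_size, min_overlap = config$min_overlap,
      dp = TRUE, seed = config$seed
    )
    adj <- adjust_overlaps(reads, symmetrize_overlaps(ov),
                           support_frac = config$adjust_support_frac,
                           min_cover = config$adjust_min_cover)
    overlaps <- adj$overlaps
  }
  ann <- annotate_ends(overlaps, reads)
  contained <- contained_ids(ann)

  init_best <- pick_best_edges(overlaps, reads, model = NULL,
                               exclude = contained)
  if (nrow(init_best) == 0) abort("no dovetail overlaps: cannot assemble")
  model <- estimate_error_model(init_best$error, mad_mult = config$mad_mult,
                                floor = config$error_floor)
  flags <- filter_suspicious_reads(reads, overlaps, model)
  exclude <- unique(c(contained, flags$chimeric, flags$nonmutual))
  best <- pick_best_edges(overlaps, reads, model = model, exclude = exclude)
  layout <- build_contigs(reads, best, exclude = exclude)

  profiles <- purrr::map(
    setNames(unique(layout$contig), unique(layout$contig)),
    function(cg) compute_error_profile(layout[layout$contig == cg, ],
                                       overlaps, window = config$profile_window)
  )
  pl <- place_contained_reads(reads, layout, overlaps, profiles,
                              tol_mads = config$place_tol_mads)
  layout <- pl$layout
  profiles <- purrr::map(
    setNames(unique(layout$contig), unique(layout$contig)),
    function(cg) compute_error_profile(layout[layout$contig == cg, ],
                                       overlaps, window = config$profile_window)
  )
  bb <- handle_bubbles(reads, layout, overlaps, profiles,
                       min_reads = config$bubble_min_reads,
                       tol_mads = config$place_tol_mads)
  layout <- bb$layout
  pl$unassembled <- union(pl$unassembled, bb$dropped)
  sr <- split_repeats(reads, layout, overlaps, profiles, model,
                      bubble_contigs = bb$bubble_contigs,
                      tol_mads = config$place_tol_mads,
                      margin_mads = config$repeat_margin_mads)
  layout <- sr$layout
  classes <- sr$classes

  # trim contig ends to >= 2-read support: single-read overhangs carry
  # residual error the consensus cannot remove
  cl <- clip_thin_contig_ends(layout)
  layout <- cl$layout
  consensus <- contig_consensus_all(reads, cl$full_layout, config)
  for (nm in names(consensus)) {
    ct <- cl$cuts[cl$cuts$contig == as.integer(nm), ]
    if (nrow(ct) == 1 && (ct$cut_l > 0 || ct$cut_r > 0)) {
      consensus[[nm]] <- substr(consensus[[nm]], ct$cut_l + 1L,
                                nchar(consensus[[nm]]) - ct$cut_r)
    }
  }
  contigs <- layout %>%
    group_by(.data$contig) %>%
    summarise(length = max(.data$end) - min(.data$begin),
              n_reads = dplyr::n(), .groups = "drop") %>%
    left_join(classes, by = "contig") %>%
    mutate(class = dplyr::coalesce(.data$class, "contig"),
           consensus_length = nchar(consensus[as.character(.data$contig)]))

  links <- contig_links(reads, layout, overlaps, model)
  structure(
    list(contigs = contigs, layout = layout, consensus = consensus,
         model = model, profiles = profiles, links = links,
         unassembled = pl$unassembled, flags = flags, config = config),
    class = "sx_assembly"
  )
}

#' @export
print.sx_assembly <- function(x, ...) {
  cat("<sx_assembly> ", nrow(x$contigs), " contigs (",
      sum(x$contigs$class == "repeat"), " repeat, ",
      sum(x$contigs$class == "bubble"), " bubble), total ",
      format(sum(x$contigs$length), big.mark = ","), " bp; error cutoff ",
      sprintf("%.2f%%", 100 * x$model$cutoff), "\n", sep = "")
  invisible(x)
}

# Clip contig layouts to the region supported by at least two reads; the
# clipped amounts per read are recorded so truth provenance can follow.
clip_thin_contig_ends <- function(layout) {
  cuts <- list()
  out <- list()
  for (cg in unique(layout$contig)) {
    rows <- layout[layout$contig == cg, ]
    if (nrow(rows) < 3) {
      rows$clip_l <- 0L; rows$clip_r <- 0L
      out[[length(out) + 1]] <- rows
      cuts[[length(cuts) + 1]] <- tibble(contig = cg, cut_l = 0L, cut_r = 0L)
      next
    }
    s2 <- sort(rows$begin)[2]
    e2 <- sort(rows$end, decreasing = TRUE)[2]
    rows$clip_l <- pmax(0L, s2 - rows$begin)
    rows$clip_r <- pmax(0L, rows$end - e2)
    rows$begin <- pmax(rows$begin, s2) - s2
    rows$end <- pmin(rows$end, e2) - s2
    rows <- rows[rows$end > rows$begin, ]
    out[[length(out) + 1]] <- rows
    cuts[[length(cuts) + 1]] <- tibble(contig = cg, cut_l = s2,
                                       cut_r = max(layout$end[layout$contig == cg]) - e2)
  }
  list(layout = bind_rows(out), cuts = bind_rows(cuts),
       full_layout = layout)
}

# graph links between contig ends from unused qualifying overlaps
contig_links <- function(reads, layout, overlaps, model) {
  if (nrow(layout) == 0) return(tibble())
  term <- layout %>%
    group_by(.data$contig) %>%
    summarise(first = .data$read[which.min(.data$begin)],
              last = .data$read[which.max(.data$end)],
              f_or = .data$orient[which.min(.data$begin)],
              l_or = .data$orient[which.max(.data$end)], .groups = "drop")
  tread <- unique(c(term$first, term$last))
  side_of <- function(rid, use) {
    # contig side reached by a read-end, given the read's layout orientation
    hit <- layout[layout$read == rid, ][1, ]
    or <- hit$orient
    left <- (use == "5" & or == 0L) | (use == "3" & or == 1L)
    list(contig = hit$contig, side = ifelse(left, "L", "R"))
  }
  ann <- annotate_ends(overlaps, reads) %>%
    filter(.data$a %in% tread, .data$b %in% tread, .data$a < .data$b,
           .data$error <= model$cutoff, .data$a_use %in% c("5", "3"),
           .data$b_use %in% c("5", "3"))
  if (nrow(ann) == 0) return(tibble())
  out <- list()
  for (i in seq_len(nrow(ann))) {
    o <- ann[i, ]
    sa <- side_of(o$a, o$a_use)
    sb <- side_of(o$b, o$b_use)
    if (sa$contig == sb$contig) {
      la <- layout[layout$read == o$a, ][1, ]
      lb <- layout[layout$read == o$b, ][1, ]
      # overlapping layout intervals = adjacency already inside the contig
      if (max(la$begin, lb$begin) < min(la$end, lb$end)) next
      # circularizing self link joins opposite contig ends only
      if (sa$side == sb$side) next
    }
    out[[length(out) + 1]] <- tibble(
      from = sa$contig, from_orient = if (sa$side == "R") "+" else "-",
      to = sb$contig, to_orient = if (sb$side == "L") "+" else "-",
      overlap = o$ovl_len
    )
  }
  if (length(out) == 0) return(tibble())
  bind_rows(out) %>% distinct()
}
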