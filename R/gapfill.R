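# Desk-scale long-read gap filling: unique-k-mer read anchoring (chained
# colinearly, unique best scaffold per read with a bestn-1 tie rule),
# consensus splicing of gap-spanning read sequence, scaffold-end connection
# events, and a mapping-efficiency report.

# k-mer index over an assembly: only k-mers that occur exactly once in the
# whole assembly (and contain no N) are kept.
build_kmer_index <- function(assembly, k) {
  per <- lapply(names(assembly$seqs), function(nm) {
    L <- nchar(assembly$seqs[[nm]])
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(assembly$seqs[[nm]], st, st + k - 1L),
                           scaffold = nm, s = st - 1L)
  })
  idx <- data.table::rbindlist(per)
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  idx <- idx[!(duplicated(kmer) | duplicated(kmer, fromLast = TRUE))]
  data.table::setkey(idx, kmer)
  idx
}

#' Anchor long reads to an assembly by unique k-mers
#'
#' Read k-mers (both orientations) matching assembly-unique k-mers are
#' chained colinearly per (scaffold, strand) by longest increasing
#' subsequence; chains with at least `min_anchors` k-mers are retained.
#' Each read is assigned to the single scaffold of its best chain; when the
#' two best chains on different scaffolds tie and cover the same part of
#' the read, the read is left unanchored (unique-best mapping).  The
#' remaining chains of a read over disjoint read intervals (its "path") are
#' kept for connection detection.
#'
#' @param reads An `mw_reads`.
#' @param assembly An `mw_assembly`.
#' @param k k-mer size (>= 15; default 17).
#' @param min_anchors Minimum k-mers per chain (default 3).
#' @param stride Sample every `stride`-th read k-mer (default 3).
#' @return An `mw_anchors` object: `anchors` (best chain per read), `paths`
#'   (all selected chains), `hits` (retained k-mer hits), `report`.
#' @export
anchor_reads <- function(reads, assembly, k = 17L, min_anchors = 3L,
                         stride = 3L) {
  stopifnot(inherits(reads, "mw_reads"), inherits(assembly, "mw_assembly"),
            k >= 15)
  nms <- names(reads$seqs)
  rl <- stats::setNames(nchar(reads$seqs), nms)
  empty_report <- list(n_reads = length(nms), n_mapped = 0L,
                       n_unmapped = length(nms), covered_scaffolds = 0L,
                       n_scaffolds = length(assembly$seqs))
  empty <- structure(list(anchors = NULL, paths = NULL, hits = NULL,
                          report = empty_report, k = k, stride = stride,
                          read_len = rl),
                     class = "mw_anchors")
  if (length(nms) == 0) return(empty)
  idx <- build_kmer_index(assembly, k)
  if (nrow(idx) == 0) return(empty)
  scaffold_len <- scaffold_lengths(assembly)

  rcs <- revcomp(reads$seqs)
  tab_for <- function(ss, orient) {
    per <- lapply(seq_along(ss), function(i) {
      L <- nchar(ss[[i]])
      if (L < k) return(NULL)
      qs <- seq.int(1L, L - k + 1L, by = stride)
      data.table::data.table(read = nms[i], strand = orient, q = qs - 1L,
                             kmer = substring(ss[[i]], qs, qs + k - 1L))
    })
    data.table::rbindlist(per)
  }
  qt <- data.table::rbindlist(list(tab_for(reads$seqs, "+"),
                                   tab_for(rcs, "-")))
  hits <- idx[qt, on = "kmer", nomatch = NULL]
  if (nrow(hits) == 0) return(empty)
  hits[, kmer := NULL]
  hits[, qf := ifelse(strand == "+", q, rl[read] - k - q)]
  data.table::setorder(hits, read, scaffold, strand, q)
  keep <- hits[, .(row = .I[lis_indices(s)]), by = .(read, scaffold, strand)]
  hits <- hits[keep$row]
  ch <- hits[, .(n_kmer = .N, q_lo = min(q), q_hi = max(q),
                 qf_lo = min(qf), qf_hi = max(qf),
                 s_lo = min(s), s_hi = max(s)),
             by = .(read, scaffold, strand)]
  ch <- ch[n_kmer >= min_anchors]
  if (nrow(ch) == 0) return(empty)

  # per-read path selection: greedy non-overlapping read intervals by score
  paths <- list(); anchors <- list()
  for (dtr in split(ch, by = "read")) {
    dtr <- dtr[order(-n_kmer, scaffold, strand)]
    # bestn-1 tie rule: equal-score top chains on different scaffolds over
    # the same read interval leave the read unanchored
    if (nrow(dtr) >= 2 && dtr$n_kmer[1] == dtr$n_kmer[2] &&
        dtr$scaffold[1] != dtr$scaffold[2]) {
      o0 <- max(dtr$qf_lo[1], dtr$qf_lo[2])
      o1 <- min(dtr$qf_hi[1] + k, dtr$qf_hi[2] + k)
      span <- min(dtr$qf_hi[1] + k - dtr$qf_lo[1],
                  dtr$qf_hi[2] + k - dtr$qf_lo[2])
      if (o1 - o0 >= 0.5 * span) next
    }
    sel <- integer(0)
    for (i in seq_len(nrow(dtr))) {
      ok <- TRUE
      for (j in sel) {
        o0 <- max(dtr$qf_lo[i], dtr$qf_lo[j])
        o1 <- min(dtr$qf_hi[i] + k, dtr$qf_hi[j] + k)
        if (o1 - o0 > 0.5 * (dtr$qf_hi[i] + k - dtr$qf_lo[i])) ok <- FALSE
      }
      if (ok) sel <- c(sel, i)
    }
    p <- dtr[sel]
    paths[[length(paths) + 1L]] <- p
    anchors[[length(anchors) + 1L]] <- dtr[1]
  }
  if (length(anchors) == 0) return(empty)
  anchors <- data.table::rbindlist(anchors)
  paths <- data.table::rbindlist(paths)
  hits <- hits[paths[, .(read, scaffold, strand)],
               on = c("read", "scaffold", "strand")]
  report <- list(
    n_reads = length(nms),
    n_mapped = nrow(anchors),
    n_unmapped = length(nms) - nrow(anchors),
    covered_scaffolds = length(unique(anchors$scaffold)),
    n_scaffolds = length(assembly$seqs))
  structure(list(anchors = as.data.frame(anchors),
                 paths = as.data.frame(paths), hits = hits,
                 report = report, k = k, stride = stride, read_len = rl,
                 scaffold_len = scaffold_len),
            class = "mw_anchors")
}

#' @export
print.mw_anchors <- function(x, ...) {
  r <- x$report
  cat(sprintf("mw_anchors: %d/%d reads mapped (%s%%), %d/%d scaffolds covered (%s%%)\n",
              r$n_mapped, r$n_reads, format_pct(r$n_mapped, max(r$n_reads, 1)),
              r$covered_scaffolds, r$n_scaffolds,
              format_pct(r$covered_scaffolds, max(r$n_scaffolds, 1))))
  invisible(x)
}

#' Mapping-efficiency report
#'
#' Counts of mapped and unmapped reads (optionally per read set) and of
#' covered scaffolds (scaffolds with at least one anchored read), with
#' percentages relative to the read-set totals (covered scaffolds relative
#' to the assembly scaffold count), formatted one-decimal half-up.
#'
#' @param anchors An `mw_anchors`.
#' @param groups Optional named factor/character vector (by read name)
#'   splitting reads into sets.
#' @return data.frame `metric`, `set`, `count`, `pct`.
#' @export
mapping_report <- function(anchors, groups = NULL) {
  stopifnot(inherits(anchors, "mw_anchors"))
  r <- anchors$report
  if (r$n_reads == 0)
    return(data.frame(metric = character(0), set = character(0),
                      count = integer(0), pct = character(0),
                      stringsAsFactors = FALSE))
  all_reads <- names(anchors$read_len)
  mapped_reads <- if (is.null(anchors$anchors)) character(0) else
    anchors$anchors$read
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(all_reads)),
                                                 all_reads)
  rows <- list()
  for (g in unique(groups)) {
    ids <- all_reads[groups[all_reads] == g]
    nm <- sum(ids %in% mapped_reads)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "mapped_reads", set = g, count = nm,
      pct = format_pct(nm, length(ids)), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "total_mapped", set = "all", count = r$n_mapped,
    pct = format_pct(r$n_mapped, r$n_reads), stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "unmapped_reads", set = "all", count = r$n_unmapped,
    pct = format_pct(r$n_unmapped, r$n_reads), stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "covered_scaffolds", set = "all", count = r$covered_scaffolds,
    pct = format_pct(r$covered_scaffolds, r$n_scaffolds),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

empty_fill_events <- function() {
  data.frame(scaffold = character(0), kind = character(0), start = integer(0),
             end = integer(0), inserted = character(0), support = integer(0),
             end_a_scaffold = character(0), end_a_side = character(0),
             end_b_scaffold = character(0), end_b_side = character(0),
             stringsAsFactors = FALSE)
}

fill_event_row <- function(scaffold = NA, kind, start = NA, end = NA,
                           inserted = "", support = 0L,
                           ea = NA, eas = NA, eb = NA, ebs = NA) {
  data.frame(scaffold = scaffold, kind = kind, start = start, end = end,
             inserted = inserted, support = support,
             end_a_scaffold = ea, end_a_side = eas,
             end_b_scaffold = eb, end_b_side = ebs,
             stringsAsFactors = FALSE)
}

oriented_read_seq <- function(reads, read, strand) {
  s <- reads$seqs[[read]]
  if (strand == "-") revcomp(s) else s
}

#' Fill assembly gaps (and join scaffold ends) with anchored long reads
#'
#' For each gap of at least `min_gap` Ns with at least `min_support` reads
#' anchored on both flanks, the majority read subsequence spanning the gap
#' is spliced in (closing the gap, possibly to zero inserted bases).  Gaps
#' reached from only one side are partially filled, always leaving at least
#' one N (`gap_reduced`).  Reads whose anchor path leaves the end of one
#' scaffold and enters the end of another with consistent orientation create
#' `connection` events that join the two scaffolds through the read
#' sequence; conflicting evidence for a scaffold end leaves that end
#' unjoined and is logged.
#'
#' @param assembly An `mw_assembly`.
#' @param anchors `mw_anchors` computed on this assembly.
#' @param reads The `mw_reads` used for anchoring.
#' @param min_gap Minimum gap size considered (default 10).
#' @param min_support Minimum spanning reads to close a gap or make a
#'   connection (default 1).
#' @param flank Maximum distance from the gap edge to the nearest anchoring
#'   k-mer (default 2000).
#' @param end_margin Maximum unanchored scaffold-end overhang for a
#'   connection (default 200).
#' @param join_connections Apply connection events (default TRUE).
#' @return List with `assembly`, `events`, `chain` (input -> output
#'   coordinates), `gaps` (updated registry) and `conflicts`.
#' @export
fill_gaps <- function(assembly, anchors, reads, min_gap = 10L,
                      min_support = 1L, flank = 2000L, end_margin = 200L,
                      join_connections = TRUE) {
  stopifnot(inherits(assembly, "mw_assembly"), inherits(anchors, "mw_anchors"))
  gaps <- assembly$gaps
  if (is.null(gaps) || nrow(gaps) == 0) gaps <- assembly_gaps(assembly, 1L)
  hits <- anchors$hits
  events <- list()
  new_seqs <- assembly$seqs
  blocks <- list()
  new_gaps <- list()
  oriented_cache <- new.env(parent = emptyenv())
  get_oriented <- function(read, strand) {
    key <- paste0(read, strand)
    if (!is.null(oriented_cache[[key]])) return(oriented_cache[[key]])
    s <- oriented_read_seq(reads, read, strand)
    oriented_cache[[key]] <- s
    s
  }

  for (sc in names(assembly$seqs)) {
    L <- nchar(assembly$seqs[[sc]])
    g_sc <- gaps[gaps$scaffold == sc, , drop = FALSE]
    g_sc <- g_sc[order(g_sc$start), , drop = FALSE]
    h_sc <- if (!is.null(hits)) hits[hits$scaffold == sc] else NULL
    parts <- character(0)
    blk_start <- 0L
    delta <- 0L
    for (gi in seq_len(nrow(g_sc))) {
      gs <- g_sc$start[gi]; ge <- g_sc$end[gi]; gl <- ge - gs
      if (gl < min_gap || is.null(h_sc) || nrow(h_sc) == 0) {
        new_gaps[[length(new_gaps) + 1L]] <- data.frame(
          scaffold = sc, start = gs + delta, end = ge + delta,
          provenance = g_sc$provenance[gi], nominal_len = g_sc$nominal_len[gi],
          stringsAsFactors = FALSE)
        next
      }
      left <- h_sc[s + anchors$k <= gs & s >= gs - flank]
      right <- h_sc[s >= ge & s <= ge + flank]
      spans <- list(); left_ext <- NULL; right_ext <- NULL
      grp <- unique(rbind(left[, .(read, strand)], right[, .(read, strand)]))
      for (ri in seq_len(nrow(grp))) {
        rd <- grp$read[ri]; st <- grp$strand[ri]
        hl <- left[read == rd & strand == st]
        hr <- right[read == rd & strand == st]
        rlen <- anchors$read_len[[rd]]
        q_gs <- if (nrow(hl) > 0) {
          i <- which.max(hl$s); hl$q[i] + (gs - hl$s[i])
        } else NA
        q_ge <- if (nrow(hr) > 0) {
          i <- which.min(hr$s); hr$q[i] - (hr$s[i] - ge)
        } else NA
        if (!is.na(q_gs) && !is.na(q_ge)) {
          if (q_gs >= 0 && q_ge >= q_gs && q_ge <= rlen) {
            spans[[length(spans) + 1L]] <- substring(get_oriented(rd, st),
                                                     q_gs + 1L, q_ge)
          }
        } else if (!is.na(q_gs) && q_gs >= 0 && q_gs < rlen) {
          avail <- rlen - q_gs
          if (is.null(left_ext) || avail > nchar(left_ext))
            left_ext <- substring(get_oriented(rd, st), q_gs + 1L, rlen)
        } else if (!is.na(q_ge) && q_ge > 0 && q_ge <= rlen) {
          if (is.null(right_ext) || q_ge > nchar(right_ext))
            right_ext <- substring(get_oriented(rd, st), 1L, q_ge)
        }
      }
      if (length(spans) >= min_support) {
        tab <- sort(table(unlist(spans)), decreasing = TRUE)
        fills <- names(tab)[tab == max(tab)]
        fill <- sort(fills)[1]
        parts <- c(parts, substring(new_seqs[[sc]], blk_start + 1L, gs), fill)
        if (gs > blk_start)
          blocks[[length(blocks) + 1L]] <- data.frame(
            src = sc, src_start = blk_start, src_end = gs, tgt = sc,
            tgt_start = blk_start + delta, tgt_end = gs + delta,
            strand = "+", stringsAsFactors = FALSE)
        events[[length(events) + 1L]] <- fill_event_row(
          sc, "gap_closed", gs, ge, fill, length(spans))
        delta <- delta + nchar(fill) - gl
        blk_start <- ge
      } else if (!is.null(left_ext) || !is.null(right_ext)) {
        budget <- gl - 1L
        lL <- min(nchar(left_ext %||% ""), budget)
        lR <- min(nchar(right_ext %||% ""), budget - lL)
        if (lL + lR == 0L) {
          new_gaps[[length(new_gaps) + 1L]] <- data.frame(
            scaffold = sc, start = gs + delta, end = ge + delta,
            provenance = g_sc$provenance[gi],
            nominal_len = g_sc$nominal_len[gi], stringsAsFactors = FALSE)
          next
        }
        le <- if (lL > 0) substring(left_ext, 1L, lL) else ""
        re <- if (lR > 0) substring(right_ext, nchar(right_ext) - lR + 1L,
                                    nchar(right_ext)) else ""
        nN <- max(gl - lL - lR, 1L)
        seg <- paste0(le, strrep("N", nN), re)
        parts <- c(parts, substring(new_seqs[[sc]], blk_start + 1L, gs), seg)
        if (gs > blk_start)
          blocks[[length(blocks) + 1L]] <- data.frame(
            src = sc, src_start = blk_start, src_end = gs, tgt = sc,
            tgt_start = blk_start + delta, tgt_end = gs + delta,
            strand = "+", stringsAsFactors = FALSE)
        events[[length(events) + 1L]] <- fill_event_row(
          sc, "gap_reduced", gs, ge, seg, 1L)
        new_gaps[[length(new_gaps) + 1L]] <- data.frame(
          scaffold = sc, start = gs + delta + lL, end = gs + delta + lL + nN,
          provenance = g_sc$provenance[gi],
          nominal_len = g_sc$nominal_len[gi], stringsAsFactors = FALSE)
        delta <- delta + nchar(seg) - gl
        blk_start <- ge
      } else {
        new_gaps[[length(new_gaps) + 1L]] <- data.frame(
          scaffold = sc, start = gs + delta, end = ge + delta,
          provenance = g_sc$provenance[gi], nominal_len = g_sc$nominal_len[gi],
          stringsAsFactors = FALSE)
      }
    }
    if (blk_start == 0L) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = sc, src_start = 0L, src_end = L, tgt = sc, tgt_start = 0L,
        tgt_end = L, strand = "+", stringsAsFactors = FALSE)
      next  # sequence unchanged
    }
    parts <- c(parts, substring(new_seqs[[sc]], blk_start + 1L, L))
    if (L > blk_start)
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = sc, src_start = blk_start, src_end = L, tgt = sc,
        tgt_start = blk_start + delta, tgt_end = L + delta,
        strand = "+", stringsAsFactors = FALSE)
    new_seqs[[sc]] <- paste(parts, collapse = "")
  }
  fill_chain <- new_lift_chain(do.call(rbind, blocks))
  gap_reg <- if (length(new_gaps) > 0) do.call(rbind, new_gaps) else
    empty_gap_registry()
  filled <- new_assembly(new_seqs, origins = assembly$origins, gaps = gap_reg,
                         components = lift_component_table(assembly$components,
                                                           fill_chain),
                         validate = FALSE)
  events_df <- if (length(events) > 0) do.call(rbind, events) else
    empty_fill_events()
  conflicts <- character(0)

  if (join_connections && !is.null(anchors$paths)) {
    conn <- detect_connections(anchors, reads, end_margin = end_margin)
    conflicts <- conn$conflicts
    edges <- conn$edges[conn$edges$support >= min_support, , drop = FALSE]
    if (nrow(edges) > 0) {
      mg <- merge_connected_scaffolds(filled, edges)
      filled <- mg$assembly
      fill_chain <- compose_chains(fill_chain, mg$chain)
      for (i in seq_len(nrow(edges)))
        events_df <- rbind(events_df, fill_event_row(
          NA, "connection", NA, NA, edges$linker[i], edges$support[i],
          edges$a_scaffold[i], edges$a_side[i],
          edges$b_scaffold[i], edges$b_side[i]))
    }
  }
  list(assembly = filled, events = events_df, chain = fill_chain,
       gaps = filled$gaps, conflicts = conflicts)
}

# Derive scaffold-end connection candidates from read anchor paths.
detect_connections <- function(anchors, reads, end_margin = 200L) {
  k <- anchors$k
  slen <- anchors$scaffold_len
  paths <- anchors$paths
  cand <- list()
  if (!is.null(paths) && nrow(paths) > 0) {
    for (p in split(as.data.frame(paths), paths$read)) {
      if (nrow(p) < 2 || length(unique(p$scaffold)) < 2) next
      p <- p[order(p$qf_lo), , drop = FALSE]
      for (i in seq_len(nrow(p) - 1L)) {
        c1 <- p[i, ]; c2 <- p[i + 1L, ]
        if (c1$scaffold == c2$scaffold) next
        lenA <- slen[[c1$scaffold]]; lenB <- slen[[c2$scaffold]]
        sideA <- if (c1$strand == "+") "R" else "L"
        distA <- if (sideA == "R") lenA - (c1$s_hi + k) else c1$s_lo
        sideB <- if (c2$strand == "+") "L" else "R"
        distB <- if (sideB == "L") c2$s_lo else lenB - (c2$s_hi + k)
        if (distA > end_margin || distB > end_margin) next
        qa <- if (c1$strand == "+") c1$qf_hi + lenA - c1$s_hi else
          c1$qf_hi + k + c1$s_lo
        qb <- if (c2$strand == "+") c2$qf_lo - c2$s_lo else
          c2$qf_lo - (lenB - (c2$s_hi + k))
        linker <- if (qb > qa)
          substring(reads$seqs[[c1$read]], qa + 1L, qb) else ""
        endA <- c(c1$scaffold, sideA); endB <- c(c2$scaffold, sideB)
        if (paste(endB, collapse = "|") < paste(endA, collapse = "|")) {
          tmp <- endA; endA <- endB; endB <- tmp
          linker <- if (nchar(linker) > 0) revcomp(linker) else ""
        }
        cand[[length(cand) + 1L]] <- data.frame(
          a_scaffold = endA[1], a_side = endA[2],
          b_scaffold = endB[1], b_side = endB[2],
          linker = linker, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0)
    return(list(edges = data.frame(a_scaffold = character(0),
                                   a_side = character(0),
                                   b_scaffold = character(0),
                                   b_side = character(0),
                                   linker = character(0),
                                   support = integer(0),
                                   stringsAsFactors = FALSE),
                conflicts = character(0)))
  cand <- do.call(rbind, cand)
  key <- paste(cand$a_scaffold, cand$a_side, cand$b_scaffold, cand$b_side,
               sep = "|")
  edges <- do.call(rbind, lapply(split(cand, key), function(d) {
    tab <- sort(table(d$linker), decreasing = TRUE)
    data.frame(a_scaffold = d$a_scaffold[1], a_side = d$a_side[1],
               b_scaffold = d$b_scaffold[1], b_side = d$b_side[1],
               linker = names(tab)[1], support = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  # conflict rule: a scaffold end with more than one distinct partner stays
  # unjoined
  ends <- c(paste(edges$a_scaffold, edges$a_side),
            paste(edges$b_scaffold, edges$b_side))
  bad_ends <- unique(ends[duplicated(ends)])
  conflicts <- character(0)
  if (length(bad_ends) > 0) {
    hit <- paste(edges$a_scaffold, edges$a_side) %in% bad_ends |
      paste(edges$b_scaffold, edges$b_side) %in% bad_ends
    conflicts <- sprintf("conflicting connection evidence at end(s): %s",
                         paste(bad_ends, collapse = ", "))
    edges <- edges[!hit, , drop = FALSE]
  }
  # drop self-circularisations
  edges <- edges[edges$a_scaffold != edges$b_scaffold, , drop = FALSE]
  list(edges = edges, conflicts = conflicts)
}

# Merge scaffolds along connection edges.  Each edge joins end (a_scaffold,
# a_side) to (b_scaffold, b_side) with `linker` inserted, where the merged
# sequence is orient(a, exit a_side) + linker + orient(b, enter b_side).
merge_connected_scaffolds <- function(assembly, edges) {
  lens <- scaffold_lengths(assembly)
  edge_at <- list()
  for (i in seq_len(nrow(edges))) {
    edge_at[[paste(edges$a_scaffold[i], edges$a_side[i])]] <- i
    edge_at[[paste(edges$b_scaffold[i], edges$b_side[i])]] <- i
  }
  visited <- character(0)
  seqs <- character(0); origins <- list(); blocks <- list()
  for (start_sc in sort(names(assembly$seqs))) {
    if (start_sc %in% visited) next
    # walk left to the start of the path
    cur <- start_sc; cur_or <- "+"
    walk_guard <- character(0)
    repeat {
      back <- if (cur_or == "+") "L" else "R"
      ei <- edge_at[[paste(cur, back)]]
      if (is.null(ei)) break
      e <- edges[ei, ]
      if (e$a_scaffold == cur && e$a_side == back) {
        nxt <- e$b_scaffold
        nxt_or <- if (e$b_side == "R") "+" else "-"   # exits toward us via b_side
      } else {
        nxt <- e$a_scaffold
        nxt_or <- if (e$a_side == "R") "+" else "-"
      }
      if (nxt %in% walk_guard || nxt == start_sc) break  # cycle
      walk_guard <- c(walk_guard, cur)
      cur <- nxt; cur_or <- nxt_or
    }
    # walk right, building the merged scaffold
    path <- list(list(sc = cur, or = cur_or))
    linkers <- character(0)
    repeat {
      fwd <- if (cur_or == "+") "R" else "L"
      ei <- edge_at[[paste(cur, fwd)]]
      if (is.null(ei)) break
      e <- edges[ei, ]
      if (e$a_scaffold == cur && e$a_side == fwd) {
        nxt <- e$b_scaffold
        nxt_or <- if (e$b_side == "L") "+" else "-"
        lk <- e$linker
      } else {
        nxt <- e$a_scaffold
        nxt_or <- if (e$a_side == "L") "+" else "-"
        lk <- if (nchar(e$linker) > 0) revcomp(e$linker) else ""
      }
      if (nxt %in% vapply(path, `[[`, "", "sc")) break  # cycle guard
      path[[length(path) + 1L]] <- list(sc = nxt, or = nxt_or)
      linkers <- c(linkers, lk)
      cur <- nxt; cur_or <- nxt_or
    }
    members <- vapply(path, `[[`, "", "sc")
    visited <- c(visited, members)
    if (length(members) == 1L) {
      seqs[[start_sc]] <- assembly$seqs[[start_sc]]
      origins[[start_sc]] <- assembly$origins[[start_sc]]
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = start_sc, src_start = 0L, src_end = unname(lens[[start_sc]]),
        tgt = start_sc, tgt_start = 0L, tgt_end = unname(lens[[start_sc]]),
        strand = "+", stringsAsFactors = FALSE)
      next
    }
    obj <- paste(members, collapse = "+")
    at <- 0L; parts <- character(0)
    for (i in seq_along(path)) {
      sc <- path[[i]]$sc; or <- path[[i]]$or
      if (i > 1L) {
        parts <- c(parts, linkers[i - 1L])
        at <- at + nchar(linkers[i - 1L])
      }
      s <- assembly$seqs[[sc]]
      if (or == "-") s <- revcomp(s)
      parts <- c(parts, s)
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = sc, src_start = 0L, src_end = unname(lens[[sc]]), tgt = obj,
        tgt_start = at, tgt_end = at + unname(lens[[sc]]), strand = or,
        stringsAsFactors = FALSE)
      at <- at + unname(lens[[sc]])
    }
    seqs[[obj]] <- paste(parts, collapse = "")
    origins[[obj]] <- unlist(assembly$origins[members], use.names = FALSE)
  }
  chain <- new_lift_chain(do.call(rbind, blocks))
  out <- new_assembly(seqs, origins = origins,
                      gaps = lift_gap_registry(assembly$gaps, chain),
                      components = lift_component_table(assembly$components,
                                                        chain),
                      validate = FALSE)
  list(assembly = out, chain = chain)
}
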