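# Reconciliation between the long-read fill of the base assembly and the
# map-integrated assembly.  A connection found on the base assembly can be
# impossible on the integrated assembly when one of its scaffold ends is
# already joined (by the genetic map) to a different neighbour; such
# junctions are split, the split assembly is re-filled so the connection can
# form, junctions not re-joined by reads are reconnected with exactly 100
# Ns, and map-join gaps that were only partially filled are restored to
# exactly 100 Ns.

# Neighbour of an ancestor end inside an integrated assembly, or NULL when
# the end is exposed at a scaffold boundary.
ancestor_neighbor <- function(components, anc, side) {
  row <- components[components$component == anc, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  row <- row[1, ]
  dir_right <- (row$strand == "+" && side == "R") ||
    (row$strand == "-" && side == "L")
  obj <- components[components$object == row$object, , drop = FALSE]
  obj <- obj[order(obj$obj_start), , drop = FALSE]
  pos <- which(obj$component == anc)
  j <- if (dir_right) pos + 1L else pos - 1L
  if (j < 1L || j > nrow(obj)) return(NULL)
  nb <- obj[j, ]
  nb_side <- if (nb$strand == "+") {
    if (dir_right) "L" else "R"
  } else {
    if (dir_right) "R" else "L"
  }
  lo <- min(pos, j); hi <- max(pos, j)
  list(component = nb$component, side = nb_side, object = row$object,
       gap_start = obj$obj_end[lo], gap_end = obj$obj_start[hi])
}

#' Detect base-assembly connections blocked by the map integration
#'
#' A connection between two scaffold ends found on the base assembly is
#' blocked when, in the integrated assembly, at least one of the two ends is
#' interior (already joined to a different neighbour).  A base connection
#' that coincides with an integrated join is not blocked.  Returns both the
#' blocked connections and the unique map-join junctions that must be split
#' so the connections can form.
#'
#' @param base_events Event table from [fill_gaps()] on the base assembly.
#' @param integrated The map-integrated `mw_assembly` (its `components`
#'   table must reference the base scaffolds).
#' @return List with `blocked` (subset of connection events) and `junctions`
#'   (data.frame `object`, `gap_start`, `gap_end`).
#' @export
detect_blocked_connections <- function(base_events, integrated) {
  stopifnot(inherits(integrated, "mw_assembly"))
  conns <- base_events[base_events$kind == "connection", , drop = FALSE]
  comp <- integrated$components
  blocked <- list(); junctions <- list()
  for (i in seq_len(nrow(conns))) {
    A <- conns$end_a_scaffold[i]; sa <- conns$end_a_side[i]
    B <- conns$end_b_scaffold[i]; sb <- conns$end_b_side[i]
    nbA <- ancestor_neighbor(comp, A, sa)
    nbB <- ancestor_neighbor(comp, B, sb)
    joined <- (!is.null(nbA) && nbA$component == B && nbA$side == sb) ||
      (!is.null(nbB) && nbB$component == A && nbB$side == sa)
    if (joined) next
    if (is.null(nbA) && is.null(nbB)) next  # both ends free: not blocked
    blocked[[length(blocked) + 1L]] <- conns[i, , drop = FALSE]
    for (nb in list(nbA, nbB)) {
      if (is.null(nb)) next
      junctions[[length(junctions) + 1L]] <- data.frame(
        object = nb$object, gap_start = nb$gap_start, gap_end = nb$gap_end,
        stringsAsFactors = FALSE)
    }
  }
  jdf <- if (length(junctions) > 0) unique(do.call(rbind, junctions)) else
    data.frame(object = character(0), gap_start = integer(0),
               gap_end = integer(0), stringsAsFactors = FALSE)
  rownames(jdf) <- NULL
  list(blocked = if (length(blocked) > 0) do.call(rbind, blocked) else
    empty_fill_events()[0, ],
    junctions = jdf)
}

#' Split an integrated assembly at map-join junctions
#'
#' Each listed junction gap (typically a 100-N map join) is removed and the
#' flanking parts become separate scaffolds, named by their ancestor
#' content.  Original intra-scaffold gaps are never split.
#'
#' @param integrated The integrated `mw_assembly`.
#' @param junctions data.frame `object`, `gap_start`, `gap_end` (from
#'   [detect_blocked_connections()]).
#' @return List with `assembly`, `chain` (integrated -> split coordinates)
#'   and `registry` (one row per split junction: the piece names and the
#'   piece ends that used to face each other).
#' @export
split_at_junctions <- function(integrated, junctions) {
  stopifnot(inherits(integrated, "mw_assembly"))
  seqs <- character(0); origins <- list(); blocks <- list()
  gaps <- list(); comps <- list(); registry <- list()
  for (obj in names(integrated$seqs)) {
    L <- nchar(integrated$seqs[[obj]])
    jn <- junctions[junctions$object == obj, , drop = FALSE]
    if (nrow(jn) == 0) {
      seqs[[obj]] <- integrated$seqs[[obj]]
      origins[[obj]] <- integrated$origins[[obj]]
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = obj, src_start = 0L, src_end = L, tgt = obj, tgt_start = 0L,
        tgt_end = L, strand = "+", stringsAsFactors = FALSE)
      g <- integrated$gaps[integrated$gaps$scaffold == obj, , drop = FALSE]
      if (nrow(g) > 0) gaps[[length(gaps) + 1L]] <- g
      cc <- integrated$components[integrated$components$object == obj, ,
                                  drop = FALSE]
      if (nrow(cc) > 0) comps[[length(comps) + 1L]] <- cc
      next
    }
    jn <- jn[order(jn$gap_start), , drop = FALSE]
    bounds <- rbind(data.frame(s = c(0L, jn$gap_end), e = c(jn$gap_start, L)))
    comp_obj <- integrated$components[integrated$components$object == obj, ,
                                      drop = FALSE]
    comp_obj <- comp_obj[order(comp_obj$obj_start), , drop = FALSE]
    piece_names <- character(nrow(bounds))
    piece_meta <- list()
    for (pi in seq_len(nrow(bounds))) {
      p0 <- bounds$s[pi]; p1 <- bounds$e[pi]
      cc <- comp_obj[comp_obj$obj_start >= p0 & comp_obj$obj_end <= p1, ,
                     drop = FALSE]
      nm <- if (nrow(cc) > 0) paste(cc$component, collapse = "+") else
        sprintf("%s_part%d", obj, pi)
      piece_names[pi] <- nm
      seqs[[nm]] <- substring(integrated$seqs[[obj]], p0 + 1L, p1)
      origins[[nm]] <- if (nrow(cc) > 0) cc$component else nm
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = obj, src_start = p0, src_end = p1, tgt = nm, tgt_start = 0L,
        tgt_end = p1 - p0, strand = "+", stringsAsFactors = FALSE)
      g <- integrated$gaps[integrated$gaps$scaffold == obj &
                             integrated$gaps$start >= p0 &
                             integrated$gaps$end <= p1, , drop = FALSE]
      if (nrow(g) > 0) {
        g$scaffold <- nm; g$start <- g$start - p0; g$end <- g$end - p0
        gaps[[length(gaps) + 1L]] <- g
      }
      if (nrow(cc) > 0) {
        cc$object <- nm
        cc$obj_start <- cc$obj_start - p0
        cc$obj_end <- cc$obj_end - p0
        cc$part <- seq_len(nrow(cc))
        comps[[length(comps) + 1L]] <- cc
        piece_meta[[pi]] <- cc
      } else piece_meta[[pi]] <- NULL
    }
    for (ji in seq_len(nrow(jn))) {
      lp <- piece_meta[[ji]]; rp <- piece_meta[[ji + 1L]]
      registry[[length(registry) + 1L]] <- data.frame(
        object = obj,
        left_piece = piece_names[ji], right_piece = piece_names[ji + 1L],
        left_anchor = if (!is.null(lp)) lp$component[nrow(lp)] else NA,
        left_anchor_strand = if (!is.null(lp)) lp$strand[nrow(lp)] else NA,
        right_anchor = if (!is.null(rp)) rp$component[1] else NA,
        right_anchor_strand = if (!is.null(rp)) rp$strand[1] else NA,
        stringsAsFactors = FALSE)
    }
  }
  reg <- if (length(registry) > 0) do.call(rbind, registry) else
    data.frame(object = character(0), left_piece = character(0),
               right_piece = character(0), stringsAsFactors = FALSE)
  list(assembly = new_assembly(
    seqs, origins = origins,
    gaps = if (length(gaps) > 0) do.call(rbind, gaps) else empty_gap_registry(),
    components = if (length(comps) > 0) do.call(rbind, comps) else NULL,
    validate = FALSE),
    chain = new_lift_chain(do.call(rbind, blocks)),
    registry = reg)
}

# Restore every map_join gap whose N run shrank below `join_gap` back to
# exactly `join_gap` Ns (partial fills keep their added flanking sequence).
restore_map_join_gaps <- function(assembly, join_gap = 100L) {
  gaps <- assembly$gaps
  target <- which(gaps$provenance == "map_join" &
                    (gaps$end - gaps$start) < join_gap)
  if (length(target) == 0)
    return(list(assembly = assembly, chain = identity_chain(assembly),
                n_restored = 0L))
  seqs <- assembly$seqs
  blocks <- list()
  new_gaps <- gaps
  for (sc in names(seqs)) {
    idx <- target[gaps$scaffold[target] == sc]
    L <- nchar(seqs[[sc]])
    if (length(idx) == 0) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = sc, src_start = 0L, src_end = L, tgt = sc, tgt_start = 0L,
        tgt_end = L, strand = "+", stringsAsFactors = FALSE)
      next
    }
    idx <- idx[order(gaps$start[idx])]
    parts <- character(0); blk <- 0L; delta <- 0L
    for (i in idx) {
      gs <- gaps$start[i]; ge <- gaps$end[i]
      parts <- c(parts, substring(seqs[[sc]], blk + 1L, gs),
                 strrep("N", join_gap))
      if (gs > blk)
        blocks[[length(blocks) + 1L]] <- data.frame(
          src = sc, src_start = blk, src_end = gs, tgt = sc,
          tgt_start = blk + delta, tgt_end = gs + delta, strand = "+",
          stringsAsFactors = FALSE)
      new_gaps$start[new_gaps$scaffold == sc & new_gaps$start > gs] <-
        new_gaps$start[new_gaps$scaffold == sc & new_gaps$start > gs] +
        (join_gap - (ge - gs))
      new_gaps$end[new_gaps$scaffold == sc & new_gaps$end > ge] <-
        new_gaps$end[new_gaps$scaffold == sc & new_gaps$end > ge] +
        (join_gap - (ge - gs))
      new_gaps$start[i] <- gs + delta
      new_gaps$end[i] <- gs + delta + join_gap
      delta <- delta + join_gap - (ge - gs)
      blk <- ge
    }
    parts <- c(parts, substring(seqs[[sc]], blk + 1L, L))
    if (L > blk)
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = sc, src_start = blk, src_end = L, tgt = sc,
        tgt_start = blk + delta, tgt_end = L + delta, strand = "+",
        stringsAsFactors = FALSE)
    seqs[[sc]] <- paste(parts, collapse = "")
  }
  chain <- new_lift_chain(do.call(rbind, blocks))
  out <- new_assembly(seqs, origins = assembly$origins, gaps = new_gaps,
                      components = lift_component_table(assembly$components,
                                                        chain),
                      validate = FALSE)
  list(assembly = out, chain = chain, n_restored = length(target))
}

#' Reconcile base-assembly and map-integrated long-read improvements
#'
#' Runs the full reconciliation: (1) fill the base assembly with the reads
#' and record its connection events; (2) fill the integrated assembly and
#' note which connections are realisable there; (3) split the integrated
#' assembly at the map-join junctions that block base connections; (4)
#' re-fill the split assembly; (5) reconnect, with exactly `join_gap` Ns,
#' every split junction the reads did not re-join; (6) restore partially
#' filled map-join gaps to exactly `join_gap` Ns.  The returned lift chain
#' composes all steps (integrated -> final coordinates).
#'
#' @param base The base `mw_assembly` (pre-integration scaffolds).
#' @param integrated The map-integrated `mw_assembly` built from the same
#'   scaffolds.
#' @param reads An `mw_reads`.
#' @param k,stride,min_anchors Anchoring parameters (see [anchor_reads()]).
#' @param min_gap,min_support,flank,end_margin Filling parameters (see
#'   [fill_gaps()]).
#' @param join_gap Length of reconnection/restored N joins (default 100).
#' @return List with `assembly`, `chain` (integrated -> final), `events`,
#'   and `report` (blocked connections, junctions split, reconnected and
#'   restored counts, realisable connections, conflicts).
#' @export
reconcile <- function(base, integrated, reads, k = 17L, stride = 3L,
                      min_anchors = 3L, min_gap = 10L, min_support = 1L,
                      flank = 2000L, end_margin = 200L, join_gap = 100L) {
  anc_names <- sort(unlist(integrated$origins, use.names = FALSE))
  base_anc <- sort(unlist(base$origins, use.names = FALSE))
  if (!all(anc_names %in% base_anc))
    stopf("integrated assembly has ancestors unknown to the base assembly")
  ab <- anchor_reads(reads, base, k = k, min_anchors = min_anchors,
                     stride = stride)
  fb <- fill_gaps(base, ab, reads, min_gap = min_gap,
                  min_support = min_support, flank = flank,
                  end_margin = end_margin)
  ai <- anchor_reads(reads, integrated, k = k, min_anchors = min_anchors,
                     stride = stride)
  fi <- fill_gaps(integrated, ai, reads, min_gap = min_gap,
                  min_support = min_support, flank = flank,
                  end_margin = end_margin)
  det <- detect_blocked_connections(fb$events, integrated)
  n_reconnected <- 0L
  if (nrow(det$junctions) == 0) {
    asm <- fi$assembly
    chain <- fi$chain
    events <- fi$events
    conflicts <- fi$conflicts
  } else {
    sp <- split_at_junctions(integrated, det$junctions)
    a2 <- anchor_reads(reads, sp$assembly, k = k, min_anchors = min_anchors,
                       stride = stride)
    f2 <- fill_gaps(sp$assembly, a2, reads, min_gap = min_gap,
                    min_support = min_support, flank = flank,
                    end_margin = end_margin)
    asm <- f2$assembly
    chain <- compose_chains(sp$chain, f2$chain)
    events <- f2$events
    conflicts <- f2$conflicts
    # reconnect junctions that the reads did not re-join
    for (ri in seq_len(nrow(sp$registry))) {
      reg <- sp$registry[ri, ]
      comp <- asm$components
      lrow <- comp[comp$component == reg$left_anchor, , drop = FALSE]
      rrow <- comp[comp$component == reg$right_anchor, , drop = FALSE]
      if (nrow(lrow) == 0 || nrow(rrow) == 0) next
      lrow <- lrow[1, ]; rrow <- rrow[1, ]
      if (lrow$object == rrow$object) next  # re-joined through the reads
      lens <- scaffold_lengths(asm)
      l_flip <- lrow$strand != reg$left_anchor_strand
      r_flip <- rrow$strand != reg$right_anchor_strand
      # left piece's right end must be exposed at an end of its object
      l_ok <- if (!l_flip) {
        abs(lrow$obj_end - lens[[lrow$object]]) <= 0
      } else lrow$obj_start <= 0
      r_ok <- if (!r_flip) rrow$obj_start <= 0 else
        abs(rrow$obj_end - lens[[rrow$object]]) <= 0
      if (!l_ok || !r_ok) next  # end became interior elsewhere; leave as is
      sl <- asm$seqs[[lrow$object]]
      if (l_flip) sl <- revcomp(sl)
      sr <- asm$seqs[[rrow$object]]
      if (r_flip) sr <- revcomp(sr)
      obj <- paste(lrow$object, rrow$object, sep = "+")
      Ll <- nchar(sl); Lr <- nchar(sr)
      blocks <- rbind(
        data.frame(src = lrow$object, src_start = 0L, src_end = Ll, tgt = obj,
                   tgt_start = if (l_flip) 0L else 0L,
                   tgt_end = Ll, strand = if (l_flip) "-" else "+",
                   stringsAsFactors = FALSE),
        data.frame(src = rrow$object, src_start = 0L, src_end = Lr, tgt = obj,
                   tgt_start = Ll + join_gap, tgt_end = Ll + join_gap + Lr,
                   strand = if (r_flip) "-" else "+", stringsAsFactors = FALSE))
      for (other in setdiff(names(asm$seqs), c(lrow$object, rrow$object)))
        blocks <- rbind(blocks, data.frame(
          src = other, src_start = 0L, src_end = nchar(asm$seqs[[other]]),
          tgt = other, tgt_start = 0L, tgt_end = nchar(asm$seqs[[other]]),
          strand = "+", stringsAsFactors = FALSE))
      step <- new_lift_chain(blocks)
      seqs <- asm$seqs[setdiff(names(asm$seqs), c(lrow$object, rrow$object))]
      seqs[[obj]] <- paste0(sl, strrep("N", join_gap), sr)
      origins <- asm$origins[setdiff(names(asm$seqs),
                                     c(lrow$object, rrow$object))]
      origins[[obj]] <- c(asm$origins[[lrow$object]],
                          asm$origins[[rrow$object]])
      gapreg <- rbind(lift_gap_registry(asm$gaps, step),
                      data.frame(scaffold = obj, start = Ll,
                                 end = Ll + join_gap, provenance = "map_join",
                                 nominal_len = join_gap,
                                 stringsAsFactors = FALSE))
      asm <- new_assembly(seqs, origins = origins, gaps = gapreg,
                          components = lift_component_table(asm$components,
                                                            step),
                          validate = FALSE)
      chain <- compose_chains(chain, step)
      n_reconnected <- n_reconnected + 1L
    }
  }
  rs <- restore_map_join_gaps(asm, join_gap)
  asm <- rs$assembly
  chain <- compose_chains(chain, rs$chain)
  realizable <- fi$events[fi$events$kind == "connection", , drop = FALSE]
  list(assembly = asm, chain = chain, events = events,
       report = list(blocked = det$blocked, junctions = det$junctions,
                     realizable_connections = realizable,
                     n_reconnected = n_reconnected,
                     n_restored = rs$n_restored,
                     conflicts = conflicts,
                     base_events = fb$events))
}
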