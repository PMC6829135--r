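# Genetic-map anchoring of scaffolds: assign each scaffold to a linkage
# group, order and orient it by its markers, concatenate per-LG into
# pseudomolecules joined by 100-N gaps, and emit a lift chain.

#' Place scaffolds on linkage groups
#'
#' Each scaffold with at least one mapped marker is assigned to the majority
#' linkage group of its markers (ties broken by the larger summed pairwise
#' LOD among the scaffold's markers inside each candidate group, then by the
#' smaller group number).  The anchor position is the median cM of its
#' markers in that group; the orientation is the sign of the Spearman rank
#' correlation between marker bp and cM (`"?"`, treated as `"+"`, when fewer
#' than two markers or the correlation is zero).
#'
#' @param assembly An `mw_assembly`.
#' @param map An `mw_genetic_map` whose `anchors` give marker scaffold/bp.
#' @return data.frame of class `mw_placements`: `scaffold`, `lg`,
#'   `position_cm`, `orientation`, `n_markers`, `rho`.
#' @export
place_scaffolds <- function(assembly, map) {
  stopifnot(inherits(assembly, "mw_assembly"), inherits(map, "mw_genetic_map"))
  anchors <- map$anchors
  unknown <- setdiff(unique(anchors$scaffold), names(assembly$seqs))
  if (length(unknown) > 0)
    stopf("markers anchored to unknown scaffold(s): %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  marker_lg <- list(); marker_cm <- list()
  for (i in seq_along(map$groups)) {
    gr <- map$groups[[i]]
    marker_lg[gr$markers] <- i
    marker_cm[gr$markers] <- gr$cm
  }
  rows <- list()
  for (sc in unique(anchors$scaffold)) {
    a <- anchors[anchors$scaffold == sc, , drop = FALSE]
    lg <- unlist(marker_lg[a$id])
    if (length(lg) == 0) next
    mapped <- a[a$id %in% names(lg), , drop = FALSE]
    tab <- table(lg)
    best <- as.integer(names(tab)[tab == max(tab)])
    if (length(best) > 1) {
      lodsum <- vapply(best, function(b) {
        ids <- mapped$id[lg[mapped$id] == b]
        if (length(ids) < 2) return(0)
        l <- map$linkage$lod[ids, ids]
        sum(l[upper.tri(l)], na.rm = TRUE)
      }, 1)
      best <- best[order(-lodsum, best)][1]
    }
    sel <- mapped[lg[mapped$id] == best, , drop = FALSE]
    cm <- unlist(marker_cm[sel$id])
    rho <- if (nrow(sel) >= 2)
      suppressWarnings(stats::cor(sel$position, cm, method = "spearman")) else NA
    orientation <- if (is.na(rho) || rho == 0) "?" else if (rho > 0) "+" else "-"
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = sc, lg = best, position_cm = stats::median(cm),
      orientation = orientation, n_markers = nrow(sel),
      rho = ifelse(is.na(rho), NA_real_, rho), stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(scaffold = character(0), lg = integer(0),
               position_cm = numeric(0), orientation = character(0),
               n_markers = integer(0), rho = numeric(0),
               stringsAsFactors = FALSE)
  class(out) <- c("mw_placements", class(out))
  out
}

#' Build pseudomolecules from placements
#'
#' Per linkage group, placed scaffolds are concatenated in increasing anchor
#' cM (ties: longer scaffold first, then name), reverse-complemented when
#' oriented `-` (`?` is treated as `+`), and joined by exactly `join_gap` Ns
#' recorded as `map_join` gaps.  Unplaced scaffolds pass through unchanged.
#' The returned lift chain maps every source base to its new coordinate.
#'
#' @param assembly An `mw_assembly`.
#' @param placements An `mw_placements` from [place_scaffolds()].
#' @param join_gap Join gap length in bp (default 100).
#' @return List with `assembly` (pseudomolecules + pass-through scaffolds),
#'   `chain` (`mw_chain` source -> new coordinates) and `placements`.
#' @export
build_pseudomolecules <- function(assembly, placements, join_gap = 100L) {
  stopifnot(inherits(assembly, "mw_assembly"))
  if (anyDuplicated(placements$scaffold))
    stopf("scaffold placed twice: %s",
          placements$scaffold[duplicated(placements$scaffold)][1])
  lens <- scaffold_lengths(assembly)
  blocks <- list(); seqs <- character(0); origins <- list()
  gaps <- list(); comp <- list()
  for (lg in sort(unique(placements$lg))) {
    p <- placements[placements$lg == lg, , drop = FALSE]
    p <- p[order(p$position_cm, -lens[p$scaffold], p$scaffold), , drop = FALSE]
    obj <- sprintf("LGpm_%02d", lg)
    at <- 0L
    parts <- character(0)
    for (i in seq_len(nrow(p))) {
      sc <- p$scaffold[i]
      L <- unname(lens[[sc]])
      flip <- p$orientation[i] == "-"
      if (i > 1) {
        gaps[[length(gaps) + 1L]] <- data.frame(
          scaffold = obj, start = at, end = at + join_gap,
          provenance = "map_join", nominal_len = join_gap,
          stringsAsFactors = FALSE)
        parts <- c(parts, strrep("N", join_gap))
        at <- at + join_gap
      }
      parts <- c(parts, if (flip) revcomp(assembly$seqs[[sc]]) else
        assembly$seqs[[sc]])
      blocks[[length(blocks) + 1L]] <- data.frame(
        src = sc, src_start = 0L, src_end = L, tgt = obj,
        tgt_start = at, tgt_end = at + L, strand = if (flip) "-" else "+",
        stringsAsFactors = FALSE)
      comp[[length(comp) + 1L]] <- data.frame(
        object = obj, part = i, component = sc,
        strand = if (flip) "-" else "+", obj_start = at, obj_end = at + L,
        stringsAsFactors = FALSE)
      at <- at + L
    }
    seqs[[obj]] <- paste(parts, collapse = "")
    origins[[obj]] <- unlist(assembly$origins[p$scaffold], use.names = FALSE)
  }
  placed <- placements$scaffold
  for (sc in setdiff(names(assembly$seqs), placed)) {
    seqs[[sc]] <- assembly$seqs[[sc]]
    origins[[sc]] <- assembly$origins[[sc]]
    L <- unname(lens[[sc]])
    blocks[[length(blocks) + 1L]] <- data.frame(
      src = sc, src_start = 0L, src_end = L, tgt = sc, tgt_start = 0L,
      tgt_end = L, strand = "+", stringsAsFactors = FALSE)
    comp[[length(comp) + 1L]] <- data.frame(
      object = sc, part = 1L, component = sc, strand = "+",
      obj_start = 0L, obj_end = L, stringsAsFactors = FALSE)
  }
  chain <- new_lift_chain(do.call(rbind, blocks))
  gapreg <- rbind(lift_gap_registry(assembly$gaps, chain),
                  if (length(gaps) > 0) do.call(rbind, gaps) else NULL)
  gapreg <- gapreg[order(gapreg$scaffold, gapreg$start), , drop = FALSE]
  rownames(gapreg) <- NULL
  out <- new_assembly(seqs, origins = origins, gaps = gapreg,
                      components = do.call(rbind, comp), validate = FALSE)
  list(assembly = out, chain = chain, placements = placements)
}

#' Per-LG colinearity between physical and genetic order
#'
#' Lifts each mapped marker to its pseudomolecule coordinate and computes,
#' per linkage group, the Spearman correlation between physical order and cM
#' order; the overall score is the marker-count-weighted mean of the
#' per-group absolute values of rho with their sign retained per group.
#'
#' @param map An `mw_genetic_map`.
#' @param chain The `mw_chain` from [build_pseudomolecules()].
#' @return List with `per_lg` (data.frame `lg`, `n_markers`, `rho`) and
#'   `weighted_rho` (weighted mean of per-group rho).
#' @export
colinearity_score <- function(map, chain) {
  rows <- list()
  for (i in seq_along(map$groups)) {
    gr <- map$groups[[i]]
    a <- map$anchors[match(gr$markers, map$anchors$id), ]
    lifted <- lapply(seq_len(nrow(a)), function(k)
      lift_point(chain, a$scaffold[k], a$position[k]))
    ok <- !vapply(lifted, is.null, TRUE)
    if (sum(ok) < 2) next
    tgt <- vapply(lifted[ok], `[[`, "", "scaffold")
    keep <- tgt == names(sort(table(tgt), decreasing = TRUE))[1]
    pos <- vapply(lifted[ok][keep], `[[`, 1, "pos")
    cm <- gr$cm[ok][keep]
    rho <- suppressWarnings(stats::cor(pos, cm, method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(lg = i, n_markers = sum(keep),
                                            rho = rho)
  }
  per_lg <- do.call(rbind, rows)
  list(per_lg = per_lg,
       weighted_rho = sum(per_lg$rho * per_lg$n_markers) / sum(per_lg$n_markers))
}
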