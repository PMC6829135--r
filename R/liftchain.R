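# Lift chains: ordered interval maps between assembly versions.  A chain is a
# set of blocks (source scaffold, source interval, target scaffold, target
# interval, strand); block lengths are equal on both sides, target intervals
# never overlap, and chains compose.  Coordinates are 0-based half-open.

#' Construct a lift chain
#'
#' @param blocks data.frame with columns `src`, `src_start`, `src_end`,
#'   `tgt`, `tgt_start`, `tgt_end`, `strand` (`+` or `-`). For a `-` block,
#'   source position `p` maps to `tgt_end - 1 - (p - src_start)`.
#' @return An object of class `mw_chain`.
#' @export
new_lift_chain <- function(blocks) {
  need <- c("src", "src_start", "src_end", "tgt", "tgt_start", "tgt_end", "strand")
  stopifnot(all(need %in% names(blocks)))
  blocks <- as.data.frame(blocks)[need]
  if (nrow(blocks) > 0) {
    if (any(blocks$src_end - blocks$src_start !=
            blocks$tgt_end - blocks$tgt_start))
      stopf("chain block lengths differ between source and target")
    if (any(blocks$src_end <= blocks$src_start))
      stopf("empty or negative chain block")
  }
  blocks <- blocks[order(blocks$src, blocks$src_start), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks), class = "mw_chain")
}

empty_chain_blocks <- function() {
  data.frame(src = character(0), src_start = integer(0), src_end = integer(0),
             tgt = character(0), tgt_start = integer(0), tgt_end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Identity chain over an assembly
#' @param assembly An `mw_assembly`.
#' @return An `mw_chain` mapping every scaffold to itself.
#' @export
identity_chain <- function(assembly) {
  lens <- scaffold_lengths(assembly)
  new_lift_chain(data.frame(
    src = names(lens), src_start = 0L, src_end = unname(lens),
    tgt = names(lens), tgt_start = 0L, tgt_end = unname(lens),
    strand = "+", stringsAsFactors = FALSE))
}

#' @export
print.mw_chain <- function(x, ...) {
  cat(sprintf("mw_chain: %d blocks, %d source scaffold(s) -> %d target scaffold(s)\n",
              nrow(x$blocks), length(unique(x$blocks$src)),
              length(unique(x$blocks$tgt))))
  invisible(x)
}

#' Lift a single position through a chain
#'
#' @param chain An `mw_chain`.
#' @param scaffold Source scaffold name.
#' @param pos 0-based source position.
#' @return A list with `scaffold`, `pos` and `flipped` (logical), or `NULL`
#'   when the position is not covered by any block.
#' @export
lift_point <- function(chain, scaffold, pos) {
  b <- chain$blocks
  i <- which(b$src == scaffold & b$src_start <= pos & pos < b$src_end)
  if (length(i) == 0) return(NULL)
  i <- i[1]
  if (b$strand[i] == "+") {
    list(scaffold = b$tgt[i], pos = b$tgt_start[i] + (pos - b$src_start[i]),
         flipped = FALSE)
  } else {
    list(scaffold = b$tgt[i], pos = b$tgt_end[i] - 1L - (pos - b$src_start[i]),
         flipped = TRUE)
  }
}

#' Lift an interval through a chain
#'
#' The source interval is intersected with chain blocks; the result is the
#' list of image pieces. `contiguous` is `TRUE` when the whole interval is
#' covered and its image is one unbroken interval on a single target scaffold
#' and strand.
#'
#' @param chain An `mw_chain`.
#' @param scaffold Source scaffold.
#' @param start,end 0-based half-open source interval.
#' @return List with `pieces` (data.frame `tgt`, `tgt_start`, `tgt_end`,
#'   `flipped`, `src_start`, `src_end`) and `contiguous`.
#' @export
lift_interval <- function(chain, scaffold, start, end) {
  b <- chain$blocks
  b <- b[b$src == scaffold & b$src_end > start & b$src_start < end, , drop = FALSE]
  if (nrow(b) == 0)
    return(list(pieces = data.frame(), contiguous = FALSE, covered = 0L))
  b <- b[order(b$src_start), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(b)), function(i) {
    s0 <- max(start, b$src_start[i]); s1 <- min(end, b$src_end[i])
    if (b$strand[i] == "+") {
      t0 <- b$tgt_start[i] + (s0 - b$src_start[i])
      data.frame(tgt = b$tgt[i], tgt_start = t0, tgt_end = t0 + (s1 - s0),
                 flipped = FALSE, src_start = s0, src_end = s1,
                 stringsAsFactors = FALSE)
    } else {
      t1 <- b$tgt_end[i] - (s0 - b$src_start[i])
      data.frame(tgt = b$tgt[i], tgt_start = t1 - (s1 - s0), tgt_end = t1,
                 flipped = TRUE, src_start = s0, src_end = s1,
                 stringsAsFactors = FALSE)
    }
  })
  pieces <- do.call(rbind, pieces)
  covered <- sum(pieces$src_end - pieces$src_start)
  contiguous <- FALSE
  if (covered == end - start && length(unique(pieces$tgt)) == 1 &&
      length(unique(pieces$flipped)) == 1) {
    # source-ordered pieces must abut on the target in orientation order
    if (nrow(pieces) == 1) {
      contiguous <- TRUE
    } else if (!pieces$flipped[1]) {
      contiguous <- all(pieces$tgt_start[-1] == pieces$tgt_end[-nrow(pieces)])
    } else {
      contiguous <- all(pieces$tgt_end[-1] == pieces$tgt_start[-nrow(pieces)])
    }
  }
  list(pieces = pieces, contiguous = contiguous, covered = covered)
}

#' Compose two chains
#'
#' `compose_chains(a, b)` returns the chain that maps `a`'s source
#' coordinates directly to `b`'s target coordinates (apply `a`, then `b`).
#' Blocks of `a` whose images span several blocks of `b` are split.
#'
#' @param a,b `mw_chain` objects, with `a`'s targets being `b`'s sources.
#' @return An `mw_chain`.
#' @export
compose_chains <- function(a, b) {
  out <- list()
  bb <- b$blocks
  for (i in seq_len(nrow(a$blocks))) {
    ab <- a$blocks[i, ]
    ov <- bb[bb$src == ab$tgt & bb$src_end > ab$tgt_start &
               bb$src_start < ab$tgt_end, , drop = FALSE]
    for (j in seq_len(nrow(ov))) {
      o0 <- max(ab$tgt_start, ov$src_start[j])
      o1 <- min(ab$tgt_end, ov$src_end[j])
      len <- o1 - o0
      # source-a interval producing [o0, o1) on the intermediate scaffold
      if (ab$strand == "+") {
        s0 <- ab$src_start + (o0 - ab$tgt_start)
      } else {
        s0 <- ab$src_start + (ab$tgt_end - o1)
      }
      # image of [o0, o1) through the b block
      if (ov$strand[j] == "+") {
        t0 <- ov$tgt_start[j] + (o0 - ov$src_start[j])
      } else {
        t0 <- ov$tgt_end[j] - (o1 - ov$src_start[j])
      }
      strand <- if (ab$strand == ov$strand[j]) "+" else "-"
      out[[length(out) + 1L]] <- data.frame(
        src = ab$src, src_start = s0, src_end = s0 + len,
        tgt = ov$tgt[j], tgt_start = t0, tgt_end = t0 + len,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(new_lift_chain(empty_chain_blocks()))
  new_lift_chain(do.call(rbind, out))
}

# Lift a gap registry through a chain; gaps whose interval does not lift
# contiguously are dropped (they no longer exist as such).
lift_gap_registry <- function(gaps, chain) {
  if (nrow(gaps) == 0) return(gaps)
  rows <- lapply(seq_len(nrow(gaps)), function(i) {
    li <- lift_interval(chain, gaps$scaffold[i], gaps$start[i], gaps$end[i])
    if (!li$contiguous) return(NULL)
    p <- li$pieces
    data.frame(scaffold = p$tgt[1], start = min(p$tgt_start),
               end = max(p$tgt_end), provenance = gaps$provenance[i],
               nominal_len = gaps$nominal_len[i], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_gap_registry())
  out <- do.call(rbind, rows)
  out[order(out$scaffold, out$start), , drop = FALSE]
}

# Lift a component table through a chain (order/strand bookkeeping for
# reconciliation). Components that do not lift contiguously are dropped.
lift_component_table <- function(components, chain) {
  if (nrow(components) == 0) return(components)
  rows <- lapply(seq_len(nrow(components)), function(i) {
    li <- lift_interval(chain, components$object[i],
                        components$obj_start[i], components$obj_end[i])
    if (li$covered == 0) return(NULL)
    p <- li$pieces
    # keep the dominant piece (fills may nibble edges); order/strand is what
    # matters downstream
    p <- p[which.max(p$tgt_end - p$tgt_start), ]
    strand <- components$strand[i]
    if (p$flipped) strand <- if (strand == "+") "-" else "+"
    data.frame(object = p$tgt, part = NA_integer_,
               component = components$component[i], strand = strand,
               obj_start = p$tgt_start, obj_end = p$tgt_end,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(components[0, , drop = FALSE])
  out <- do.call(rbind, rows)
  out <- out[order(out$object, out$obj_start), , drop = FALSE]
  out$part <- stats::ave(seq_len(nrow(out)), out$object, FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Write a chain as tab-separated block text
#'
#' One row per block: `src src_start src_end tgt tgt_start tgt_end strand`
#' (0-based half-open, source strand always `+`).
#'
#' @param chain An `mw_chain`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chain <- function(chain, path) {
  utils::write.table(chain$blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a chain written by [write_chain()]
#' @param path File path.
#' @return An `mw_chain`.
#' @export
read_chain <- function(path) {
  new_lift_chain(utils::read.delim(path, stringsAsFactors = FALSE))
}
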