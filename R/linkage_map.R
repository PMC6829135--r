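# RIL linkage map construction: pairwise recombination fractions with the
# selfing-RIL correction R = 2r/(1+2r), binomial LOD scores, single-linkage
# LOD grouping, seriation + 2-opt marker ordering, Kosambi/Haldane map
# distances and co-segregation pruning.

#' Pairwise linkage statistics for all marker pairs
#'
#' For each pair, lines homozygous at both loci (calls A or B, H and missing
#' excluded) are informative; `R_obs` is the observed RIL recombinant
#' fraction among them.  The meiotic recombination fraction is recovered by
#' inverting the selfing-RIL relation `R = 2r/(1+2r)`, capped at 0.5.  The
#' LOD is the binomial likelihood ratio
#' `k*log10(Rhat) + (n-k)*log10(1-Rhat) - n*log10(0.5)` with
#' `Rhat = max(R_obs, 1/(2n))`, floored at 0.
#'
#' @param g An `mw_geno`.
#' @param min_informative Pairs with fewer doubly-informative lines are
#'   marked untestable (`NA`).
#' @return A list of class `mw_linkage` with matrices `n`, `R`, `r`, `lod`
#'   (markers x markers, marker ids as dimnames).
#' @export
pairwise_linkage <- function(g, min_informative = 10L) {
  stopifnot(inherits(g, "mw_geno"))
  A <- (g$calls == "A") * 1; A[is.na(A)] <- 0
  B <- (g$calls == "B") * 1; B[is.na(B)] <- 0
  O <- A + B
  n <- tcrossprod(O)
  same <- tcrossprod(A) + tcrossprod(B)
  k <- n - same
  R <- ifelse(n > 0, k / n, NA_real_)
  r <- ifelse(R < 1, R / (2 * (1 - R)), Inf)
  r <- pmin(r, 0.5)
  Rhat <- pmin(pmax(R, 1 / (2 * n)), 1 - 1e-12)
  lod <- k * log10(Rhat) + (n - k) * log10(1 - Rhat) - n * log10(0.5)
  lod <- pmax(lod, 0)
  untest <- n < min_informative
  R[untest] <- NA_real_; r[untest] <- NA_real_; lod[untest] <- NA_real_
  ids <- g$markers$id
  dimnames(n) <- dimnames(R) <- dimnames(r) <- dimnames(lod) <- list(ids, ids)
  structure(list(n = n, R = R, r = r, lod = lod,
                 min_informative = min_informative),
            class = "mw_linkage")
}

#' Linkage statistics for one marker pair
#'
#' @param g An `mw_geno`.
#' @param i,j Marker ids or indices.
#' @inheritParams pairwise_linkage
#' @return A one-row data.frame `marker_i`, `marker_j`, `n_informative`,
#'   `R_obs`, `r`, `lod`, `testable`.
#' @export
linkage_pair <- function(g, i, j, min_informative = 10L) {
  stopifnot(inherits(g, "mw_geno"))
  if (is.character(i)) i <- match(i, g$markers$id)
  if (is.character(j)) j <- match(j, g$markers$id)
  a <- g$calls[i, ]; b <- g$calls[j, ]
  inf <- a %in% c("A", "B") & b %in% c("A", "B")
  n <- sum(inf)
  k <- sum(a[inf] != b[inf])
  testable <- n >= min_informative
  R <- if (n > 0) k / n else NA_real_
  r <- if (!is.na(R)) min(if (R < 1) R / (2 * (1 - R)) else Inf, 0.5) else NA_real_
  lod <- if (n > 0) {
    Rhat <- min(max(R, 1 / (2 * n)), 1 - 1e-12)
    max(k * log10(Rhat) + (n - k) * log10(1 - Rhat) - n * log10(0.5), 0)
  } else NA_real_
  data.frame(marker_i = g$markers$id[i], marker_j = g$markers$id[j],
             n_informative = n, R_obs = R, r = r, lod = lod,
             testable = testable, stringsAsFactors = FALSE)
}

#' Group markers by LOD threshold
#'
#' Single-linkage transitive closure over pairs with `lod >= threshold`.
#' Groups are sorted by descending marker count; single-marker groups are
#' reported separately.
#'
#' @param linkage An `mw_linkage`.
#' @param lod_threshold Grouping threshold (default 9.0).
#' @return List with `groups` (list of marker-id vectors) and `singletons`.
#' @export
group_markers <- function(linkage, lod_threshold = 9.0) {
  lod <- linkage$lod
  n <- nrow(lod)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sel <- which(!is.na(lod) & lod >= lod_threshold & upper.tri(lod),
               arr.ind = TRUE)
  for (kk in seq_len(nrow(sel))) {
    a <- find(sel[kk, 1]); b <- find(sel[kk, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, 1L)
  comps <- split(rownames(lod), root)
  sizes <- lengths(comps)
  comps <- comps[order(-sizes, vapply(comps, `[`, "", 1))]
  multi <- comps[lengths(comps) >= 2]
  names(multi) <- NULL
  list(groups = multi,
       singletons = unlist(comps[lengths(comps) == 1], use.names = FALSE))
}

# Sum of adjacent r along a path; untestable r counts as 0.5.
path_cost <- function(ord, r) {
  rr <- r[cbind(ord[-length(ord)], ord[-1])]
  rr[is.na(rr)] <- 0.5
  sum(rr)
}

#' Order the markers of one linkage group
#'
#' Seriation by greedy nearest neighbour on the recombination fraction,
#' refined by 2-opt moves until no swap improves the sum of adjacent `r`.
#' The orientation is canonicalised so that the first marker has the
#' lexicographically smaller id of the two ends.  Deterministic for a fixed
#' input.
#'
#' @param group Character vector of marker ids.
#' @param linkage An `mw_linkage`.
#' @return Ordered character vector of marker ids.
#' @export
order_markers <- function(group, linkage) {
  if (length(group) <= 2) {
    ord <- group
  } else {
    r <- linkage$r[group, group]
    r[is.na(r)] <- 0.5
    diag(r) <- Inf
    # start at the marker farthest from any other (a likely end)
    start <- which.max(apply(ifelse(is.finite(r), r, -Inf), 1, max))
    ord <- integer(length(group))
    used <- logical(length(group))
    ord[1] <- start; used[start] <- TRUE
    for (i in 2:length(group)) {
      cand <- r[ord[i - 1], ]
      cand[used] <- Inf
      ord[i] <- which.min(cand)
      used[ord[i]] <- TRUE
    }
    # 2-opt on the open path
    m <- length(ord)
    rr <- r; diag(rr) <- 0
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in 1:(m - 1)) {
        for (j in (i + 1):m) {
          # reverse ord[i..j]
          left <- if (i > 1) rr[ord[i - 1], ord[i]] else 0
          right <- if (j < m) rr[ord[j], ord[j + 1]] else 0
          new_left <- if (i > 1) rr[ord[i - 1], ord[j]] else 0
          new_right <- if (j < m) rr[ord[i], ord[j + 1]] else 0
          if (new_left + new_right < left + right - 1e-12) {
            ord[i:j] <- rev(ord[i:j])
            improved <- TRUE
          }
        }
      }
    }
    ord <- group[ord]
  }
  if (length(ord) >= 2 && ord[length(ord)] < ord[1]) ord <- rev(ord)
  ord
}

#' Convert adjacent recombination fractions to cM positions
#'
#' Adjacent `r` values are converted with the Kosambi
#' (`d = 0.25*ln((1+2r)/(1-2r))`) or Haldane (`d = -0.5*ln(1-2r)`) mapping
#' function, expressed in cM; positions are cumulative from 0.  An adjacent
#' `r` of 0.5 (or an untestable pair) is capped at 50 cM with a warning.
#'
#' @param order Ordered marker ids.
#' @param linkage An `mw_linkage`.
#' @param fn `"kosambi"` (default) or `"haldane"`.
#' @return Numeric vector of cM positions, first position 0.
#' @export
map_distances <- function(order, linkage, fn = c("kosambi", "haldane")) {
  fn <- match.arg(fn)
  if (length(order) == 1) return(stats::setNames(0, order))
  r <- linkage$r[cbind(order[-length(order)], order[-1])]
  capped <- is.na(r) | r >= 0.5
  if (any(capped))
    warning(sprintf("%d adjacent pair(s) at r = 0.5; distance capped at 50 cM",
                    sum(capped)))
  r <- pmin(ifelse(is.na(r), 0.5, r), 0.5 - 1e-9)
  d <- switch(fn,
              kosambi = 0.25 * log((1 + 2 * r) / (1 - 2 * r)),
              haldane = -0.5 * log(1 - 2 * r)) * 100
  d[capped] <- 50
  stats::setNames(cumsum(c(0, d)), order)
}

#' Prune co-segregating markers by minimum cM spacing
#'
#' Each group is scanned left to right; a marker is kept only when its
#' distance from the last kept marker exceeds `min_spacing` cM.  The first
#' marker is always kept.
#'
#' @param map An `mw_genetic_map`.
#' @param min_spacing Minimum spacing in cM (default 0.1).
#' @return The pruned `mw_genetic_map`.
#' @export
prune_cosegregating <- function(map, min_spacing = 0.1) {
  stopifnot(inherits(map, "mw_genetic_map"))
  map$groups <- lapply(map$groups, function(gr) {
    keep <- logical(length(gr$markers))
    keep[1] <- TRUE
    last <- gr$cm[1]
    for (i in seq_along(gr$markers)[-1]) {
      if (gr$cm[i] - last > min_spacing) {
        keep[i] <- TRUE
        last <- gr$cm[i]
      }
    }
    list(markers = gr$markers[keep], cm = gr$cm[keep] - gr$cm[keep][1])
  })
  map$provenance$min_spacing <- min_spacing
  map
}

#' Build a genetic map from a genotype matrix
#'
#' Runs the full mapping stack: pairwise linkage, LOD grouping, per-group
#' ordering, mapping-function distances and co-segregation pruning.
#'
#' @param g An `mw_geno` (already marker-QC'ed).
#' @param lod_threshold LOD grouping threshold (default 9.0).
#' @param fn Mapping function, `"kosambi"` (default) or `"haldane"`.
#' @param min_spacing Pruning spacing in cM (default 0.1; `NULL` skips
#'   pruning).
#' @param min_informative Minimum doubly-informative lines per pair.
#' @return An `mw_genetic_map`: `groups` (each with `markers` and `cm`),
#'   `anchors` (marker scaffold/bp positions), `singletons`, `fn`,
#'   `provenance`, plus the `linkage` object used.
#' @export
build_genetic_map <- function(g, lod_threshold = 9.0,
                              fn = c("kosambi", "haldane"),
                              min_spacing = 0.1, min_informative = 10L) {
  fn <- match.arg(fn)
  linkage <- pairwise_linkage(g, min_informative = min_informative)
  grp <- group_markers(linkage, lod_threshold = lod_threshold)
  groups <- lapply(grp$groups, function(ids) {
    ord <- order_markers(ids, linkage)
    cm <- suppressWarnings(map_distances(ord, linkage, fn = fn))
    list(markers = ord, cm = unname(cm))
  })
  map <- structure(list(groups = groups, singletons = grp$singletons,
                        anchors = g$markers, fn = fn, linkage = linkage,
                        provenance = list(lod_threshold = lod_threshold,
                                          min_informative = min_informative,
                                          min_spacing = min_spacing)),
                   class = "mw_genetic_map")
  if (!is.null(min_spacing)) map <- prune_cosegregating(map, min_spacing)
  map
}

#' @export
print.mw_genetic_map <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$markers), 1L)
  spans <- vapply(x$groups, function(g) max(g$cm), 1)
  cat(sprintf(
    "mw_genetic_map (%s): %d group(s), %d markers, %d singleton(s)\n",
    x$fn, length(x$groups), sum(sizes), length(x$singletons)))
  if (length(sizes) > 0)
    cat(sprintf("  group sizes: %s\n  spans (cM): %s\n",
                paste(sizes, collapse = ", "),
                paste(sprintf("%.1f", spans), collapse = ", ")))
  invisible(x)
}

#' Flatten a genetic map to a data.frame
#'
#' @param map An `mw_genetic_map`.
#' @return data.frame `lg`, `marker`, `scaffold`, `position`, `cm`.
#' @export
map_to_df <- function(map) {
  stopifnot(inherits(map, "mw_genetic_map"))
  rows <- lapply(seq_along(map$groups), function(i) {
    gr <- map$groups[[i]]
    a <- map$anchors[match(gr$markers, map$anchors$id), ]
    data.frame(lg = i, marker = gr$markers, scaffold = a$scaffold,
               position = a$position, cm = gr$cm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a genetic map as TSV
#' @param map An `mw_genetic_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(map_to_df(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
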