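# Marker-level QC and reduction of a GBS genotype matrix before mapping.
# Calls are in {A, B, H, NA}; the pipeline contract applies the filters in
# the order missing -> window collapse -> similarity collapse.

#' Construct a genotype matrix
#'
#' @param markers data.frame with columns `id`, `scaffold`, `position`
#'   (0-based bp); ids must be unique.
#' @param calls Character matrix markers x lines with values `"A"`, `"B"`,
#'   `"H"` or `NA`; rownames are marker ids, colnames line names.
#' @return An object of class `mw_geno`.
#' @export
new_geno_matrix <- function(markers, calls) {
  stopifnot(is.data.frame(markers),
            all(c("id", "scaffold", "position") %in% names(markers)),
            is.matrix(calls), nrow(calls) == nrow(markers))
  if (anyDuplicated(markers$id)) stopf("duplicate marker ids")
  if (any(markers$position < 0)) stopf("negative marker position")
  bad <- !(calls %in% c("A", "B", "H") | is.na(calls))
  if (any(bad)) stopf("invalid genotype call '%s'", calls[bad][1])
  if (is.null(colnames(calls))) stopf("calls must have line names as colnames")
  rownames(calls) <- markers$id
  rownames(markers) <- NULL
  structure(list(markers = markers, lines = colnames(calls), calls = calls),
            class = "mw_geno")
}

#' @export
print.mw_geno <- function(x, ...) {
  cat(sprintf("mw_geno: %d markers x %d lines (%.1f%% missing)\n",
              nrow(x$markers), length(x$lines),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

subset_markers <- function(g, keep) {
  new_geno_matrix(g$markers[keep, , drop = FALSE],
                  g$calls[keep, , drop = FALSE])
}

#' Drop markers with excessive missing data
#'
#' Removes markers whose missing fraction exceeds `max_missing`; marker
#' order is preserved.
#'
#' @param g An `mw_geno`.
#' @param max_missing Maximum tolerated missing fraction (default 0.30).
#' @return The filtered `mw_geno`.
#' @export
filter_missing <- function(g, max_missing = 0.30) {
  stopifnot(inherits(g, "mw_geno"))
  miss <- rowMeans(is.na(g$calls))
  subset_markers(g, miss <= max_missing)
}

# identical on pairwise non-missing entries
calls_compatible <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  all(a[ok] == b[ok])
}

#' Collapse SNP islands within windows
#'
#' Within each scaffold, consecutive markers within `window_bp` of the
#' current group's first marker whose call vectors are identical on pairwise
#' non-missing entries are merged into one marker.  The representative is
#' the first (leftmost) member; its calls become the group consensus, with
#' missing entries filled from any member.
#'
#' @param g An `mw_geno`, markers sorted by (scaffold, position).
#' @param window_bp Window size in bp (default 10,000).
#' @return List with `genotypes` (collapsed `mw_geno`) and `representatives`
#'   (data.frame `member`, `representative`).
#' @export
collapse_window <- function(g, window_bp = 10000L) {
  stopifnot(inherits(g, "mw_geno"))
  m <- g$markers
  ord <- order(m$scaffold, m$position)
  if (!identical(ord, seq_len(nrow(m))))
    stopf("markers must be sorted by (scaffold, position)")
  rep_of <- character(nrow(m))
  keep_rows <- integer(0)
  cons <- list()
  i <- 1L
  while (i <= nrow(m)) {
    first <- i
    consensus <- g$calls[first, ]
    j <- i + 1L
    while (j <= nrow(m) &&
           m$scaffold[j] == m$scaffold[first] &&
           m$position[j] - m$position[first] <= window_bp &&
           calls_compatible(consensus, g$calls[j, ])) {
      fill <- is.na(consensus)
      consensus[fill] <- g$calls[j, fill]
      j <- j + 1L
    }
    rep_of[first:(j - 1L)] <- m$id[first]
    keep_rows <- c(keep_rows, first)
    cons[[length(cons) + 1L]] <- consensus
    i <- j
  }
  calls <- do.call(rbind, cons)
  colnames(calls) <- g$lines
  list(genotypes = new_geno_matrix(m[keep_rows, , drop = FALSE], calls),
       representatives = data.frame(member = m$id,
                                    representative = rep_of,
                                    stringsAsFactors = FALSE))
}

#' Pairwise marker similarity matrix
#'
#' Similarity = matching calls / pairwise non-missing comparisons (H counts
#' as a third state); a pair with no shared non-missing entries has
#' similarity 0.
#'
#' @param g An `mw_geno`.
#' @return A symmetric numeric matrix.
#' @export
marker_similarity <- function(g) {
  states <- c("A", "B", "H")
  ind <- lapply(states, function(s) {
    x <- (g$calls == s) * 1
    x[is.na(x)] <- 0
    x
  })
  obs <- Reduce(`+`, ind)
  n <- tcrossprod(obs)
  match <- Reduce(`+`, lapply(ind, tcrossprod))
  sim <- ifelse(n > 0, match / n, 0)
  dimnames(sim) <- list(g$markers$id, g$markers$id)
  sim
}

#' Collapse highly similar markers
#'
#' Markers are clustered by complete-linkage hierarchical clustering on
#' `1 - similarity`, cut so that every within-cluster pair has similarity
#' strictly above `threshold`; each cluster is represented by the member
#' with the least missing data (ties broken by input order, leftmost
#' first).  The step is repeated on the representatives until no retained
#' pair exceeds the threshold, so the filter is idempotent.  Complete
#' linkage bounds the cluster diameter, so clusters stay groups of
#' near-duplicate markers instead of chaining along a chromosome.
#'
#' @param g An `mw_geno`.
#' @param threshold Similarity threshold (default 0.90).
#' @return List with `genotypes` and `representatives` as in
#'   [collapse_window()].
#' @export
collapse_similar <- function(g, threshold = 0.90) {
  stopifnot(inherits(g, "mw_geno"))
  rep_of_all <- stats::setNames(g$markers$id, g$markers$id)
  repeat {
    n <- nrow(g$markers)
    if (n <= 1) break
    sim <- marker_similarity(g)
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "complete")
    root <- stats::cutree(hc, h = (1 - threshold) - 1e-9)
    if (max(root) == n) break  # nothing above threshold: fixpoint reached
    miss <- rowSums(is.na(g$calls))
    rep_idx <- vapply(split(seq_len(n), root), function(idx)
      idx[which.min(miss[idx])], 1L)
    rep_of <- stats::setNames(g$markers$id[rep_idx[as.character(root)]],
                              g$markers$id)
    rep_of_all <- stats::setNames(unname(rep_of[rep_of_all]),
                                  names(rep_of_all))
    g <- subset_markers(g, sort(unique(unname(rep_idx))))
  }
  list(genotypes = g,
       representatives = data.frame(member = names(rep_of_all),
                                    representative = unname(rep_of_all),
                                    stringsAsFactors = FALSE))
}

#' Test markers for segregation distortion
#'
#' Chi-square goodness of fit against the 1:1 A:B RIL expectation among
#' homozygous calls (H excluded), 1 degree of freedom.  Markers with fewer
#' than 10 informative calls are untested (`NA` flag).
#'
#' @param g An `mw_geno`.
#' @param alpha Significance level; when `bonferroni = TRUE` it is divided
#'   by the number of tested markers.
#' @param bonferroni Apply Bonferroni correction (default TRUE).
#' @return data.frame `id`, `n_A`, `n_B`, `chi2`, `p`, `distorted`
#'   (logical, `NA` when untested).
#' @export
segregation_distortion <- function(g, alpha = 0.05, bonferroni = TRUE) {
  stopifnot(inherits(g, "mw_geno"))
  nA <- rowSums(g$calls == "A", na.rm = TRUE)
  nB <- rowSums(g$calls == "B", na.rm = TRUE)
  n <- nA + nB
  chi2 <- ifelse(n > 0, (nA - n / 2)^2 / (n / 2) + (nB - n / 2)^2 / (n / 2), NA)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  testable <- n >= 10
  thr <- if (bonferroni) alpha / max(sum(testable), 1L) else alpha
  flag <- ifelse(testable, p < thr, NA)
  chi2[!testable] <- NA
  p[!testable] <- NA
  data.frame(id = g$markers$id, n_A = nA, n_B = nB, chi2 = chi2, p = p,
             distorted = flag, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a genotype matrix as TSV
#'
#' Columns: `marker`, `scaffold`, `position`, then one column per line;
#' missing calls are written as `-`.
#'
#' @param g An `mw_geno`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_geno_tsv <- function(g, path) {
  calls <- g$calls
  calls[is.na(calls)] <- "-"
  df <- cbind(data.frame(marker = g$markers$id, scaffold = g$markers$scaffold,
                         position = g$markers$position,
                         stringsAsFactors = FALSE),
              as.data.frame(calls, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix written by [write_geno_tsv()]
#' @param path File path.
#' @return An `mw_geno`.
#' @export
read_geno_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  calls <- as.matrix(df[, -(1:3), drop = FALSE])
  calls[calls == "-"] <- NA_character_
  new_geno_matrix(data.frame(id = df$marker, scaffold = df$scaffold,
                             position = df$position, stringsAsFactors = FALSE),
                  calls)
}
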