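# Assembly data model: named scaffolds over {A,C,G,T,N} with a gap registry,
# ancestor bookkeeping and (optionally) a component table describing how each
# scaffold is composed of ancestor scaffolds.  All internal coordinates are
# 0-based half-open; 1-based inclusive conversion happens only at the
# AGP/GFF3 boundary.

#' Construct an assembly
#'
#' An assembly is a set of uniquely named scaffolds over the alphabet
#' `{A,C,G,T,N}` together with a registry of gaps (N runs) carrying their
#' provenance, the list of ancestor scaffolds each scaffold was built from,
#' and an optional component table recording where each ancestor lies inside
#' the current scaffold.
#'
#' @param seqs Named character vector of scaffold sequences.
#' @param origins Named list mapping scaffold name to the character vector of
#'   ancestor scaffold names. Defaults to each scaffold being its own
#'   ancestor.
#' @param gaps Gap registry: data.frame with columns `scaffold`, `start`,
#'   `end` (0-based half-open), `provenance` (`original`, `map_join` or
#'   `residual`) and `nominal_len`. `NULL` means "scan the sequences and call
#'   every N run an original gap".
#' @param components Optional data.frame with columns `object`, `part`,
#'   `component`, `strand`, `obj_start`, `obj_end` describing the ancestor
#'   layout of composite scaffolds.
#' @param validate Check alphabet and name uniqueness (skip for trusted
#'   internal construction).
#' @return An object of class `mw_assembly`.
#' @export
new_assembly <- function(seqs, origins = NULL, gaps = NULL, components = NULL,
                         validate = TRUE) {
  if (length(seqs) == 0) stopf("assembly must contain at least one scaffold")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stopf("all scaffolds must be named")
  if (anyDuplicated(names(seqs)))
    stopf("duplicate scaffold names: %s",
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (validate) {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stopf("scaffold %s contains characters outside {A,C,G,T,N}",
            names(seqs)[bad][1])
    if (any(nchar(seqs) == 0)) stopf("empty scaffold sequence")
  }
  if (is.null(origins)) origins <- as.list(stats::setNames(names(seqs), names(seqs)))
  if (is.null(gaps)) {
    gaps <- do.call(rbind, lapply(names(seqs), function(nm)
      find_gaps(seqs[[nm]], min_gap = 1L, scaffold = nm)))
    if (is.null(gaps)) gaps <- empty_gap_registry()
  }
  if (is.null(components)) {
    components <- data.frame(object = names(seqs), part = 1L,
                             component = names(seqs), strand = "+",
                             obj_start = 0L, obj_end = nchar(seqs),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(seqs = seqs, origins = origins, gaps = gaps,
                 components = components),
            class = "mw_assembly")
}

empty_gap_registry <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             provenance = character(0), nominal_len = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.mw_assembly <- function(x, ...) {
  st <- compute_stats(x)
  cat(sprintf("mw_assembly: %d scaffolds, %s bp (N50 %s, L50 %d, %s%% N)\n",
              st$n_scaffolds, format(st$n_bases, big.mark = ","),
              format(st$N50, big.mark = ","), st$L50,
              format_pct(st$n_N, st$n_bases)))
  invisible(x)
}

#' @export
length.mw_assembly <- function(x) length(x$seqs)

scaffold_lengths <- function(assembly) nchar(assembly$seqs)

#' Assembly contiguity and gap statistics
#'
#' N50 is the length of the scaffold at which the cumulative length of
#' scaffolds sorted in descending order first reaches at least half the total
#' assembly length (N bases included); L50 is that scaffold's rank.
#' Percentages are rounded half-up to one decimal.
#'
#' @param assembly An `mw_assembly`.
#' @return A list of class `mw_stats` with `n_bases`, `n_scaffolds`, `n_N`,
#'   `n_scaffolds_with_N`, `N50`, `L50` and `pct_N`.
#' @export
compute_stats <- function(assembly) {
  stopifnot(inherits(assembly, "mw_assembly"))
  lens <- sort(scaffold_lengths(assembly), decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  l50 <- which(cum >= total / 2)[1]
  nN <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(assembly$seqs), "N"))
  withN <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(assembly$seqs), "N") > 0)
  structure(list(
    n_bases = total,
    n_scaffolds = length(lens),
    n_N = as.numeric(nN),
    n_scaffolds_with_N = as.integer(withN),
    N50 = unname(lens[l50]),
    L50 = as.integer(l50),
    pct_N = round_half_up(100 * nN / total, 1)
  ), class = "mw_stats")
}

#' @export
print.mw_stats <- function(x, ...) {
  cat(sprintf(
    "bases %s | scaffolds %d | N %s (%s%%) | scaffolds with N %d | N50 %s | L50 %d\n",
    format(x$n_bases, big.mark = ","), x$n_scaffolds,
    format(x$n_N, big.mark = ","), format_pct(x$n_N, x$n_bases),
    x$n_scaffolds_with_N, format(x$N50, big.mark = ","), x$L50))
  invisible(x)
}

#' Locate gaps (N runs) in a scaffold sequence
#'
#' Maximal runs of `N` of length at least `min_gap`, reported 0-based
#' half-open and sorted by position; shorter N runs are ignored.
#'
#' @param seq A single scaffold sequence (character scalar).
#' @param min_gap Minimum run length to report (default 10, the minimal gap
#'   size used for long-read gap filling).
#' @param scaffold Scaffold name recorded in the output.
#' @param provenance Provenance label for the records.
#' @return A gap-registry data.frame (possibly 0 rows).
#' @export
find_gaps <- function(seq, min_gap = 10L, scaffold = "scaffold",
                      provenance = "original") {
  stopifnot(min_gap >= 1)
  m <- gregexpr(sprintf("N{%d,}", min_gap), seq)[[1]]
  if (m[1] == -1L) return(empty_gap_registry())
  st <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(scaffold = scaffold, start = st, end = st + len,
             provenance = provenance, nominal_len = len,
             stringsAsFactors = FALSE)
}

#' Find gaps across a whole assembly
#' @param assembly An `mw_assembly`.
#' @inheritParams find_gaps
#' @return Gap registry data.frame over all scaffolds.
#' @export
assembly_gaps <- function(assembly, min_gap = 10L) {
  out <- do.call(rbind, lapply(names(assembly$seqs), function(nm)
    find_gaps(assembly$seqs[[nm]], min_gap = min_gap, scaffold = nm)))
  if (is.null(out)) empty_gap_registry() else out
}

#' Contamination screening rule
#'
#' A scaffold is flagged as contaminant when the summed length of its 1-kbp
#' fragments with a bacterial hit at bit score >= `min_bitscore` exceeds
#' `bacterial_fraction` of the scaffold length AND it has no Viridiplantae
#' hit at that score.
#'
#' @param fragment_len Fragment size used for the per-fragment hits (bp).
#' @param min_bitscore Minimum bit score for a hit to count.
#' @param bacterial_fraction Fraction of scaffold length that must be
#'   bacterial.
#' @return A list of class `mw_contamination_rule`.
#' @export
contamination_rule <- function(fragment_len = 1000L, min_bitscore = 50,
                               bacterial_fraction = 0.5) {
  stopifnot(fragment_len > 0, min_bitscore > 0, bacterial_fraction > 0)
  structure(list(fragment_len = as.integer(fragment_len),
                 min_bitscore = min_bitscore,
                 bacterial_fraction = bacterial_fraction),
            class = "mw_contamination_rule")
}

#' Screen an assembly for contaminant scaffolds
#'
#' @param assembly An `mw_assembly`.
#' @param hits Hit table: data.frame with columns `scaffold`, `frag_index`
#'   (1-based), `frag_len`, `taxon` (`bacteria`, `Viridiplantae` or `none`)
#'   and `bitscore`. The trailing sub-fragment of a scaffold is kept and
#'   weighted by its true length.
#' @param rule A [contamination_rule()].
#' @return Character vector of flagged scaffold names.
#' @export
screen_contamination <- function(assembly, hits, rule = contamination_rule()) {
  stopifnot(inherits(assembly, "mw_assembly"))
  unknown <- setdiff(unique(hits$scaffold), names(assembly$seqs))
  if (length(unknown) > 0)
    stopf("hit table references unknown scaffold(s): %s",
          paste(unknown, collapse = ", "))
  lens <- scaffold_lengths(assembly)
  strong <- hits[hits$bitscore >= rule$min_bitscore, , drop = FALSE]
  flagged <- character(0)
  for (nm in names(assembly$seqs)) {
    h <- strong[strong$scaffold == nm, , drop = FALSE]
    if (any(h$taxon == "Viridiplantae")) next
    bact <- sum(h$frag_len[h$taxon == "bacteria"])
    if (bact > rule$bacterial_fraction * lens[[nm]]) flagged <- c(flagged, nm)
  }
  flagged
}

#' Drop scaffolds from an assembly
#' @param assembly An `mw_assembly`.
#' @param names Scaffold names to remove.
#' @return The reduced assembly.
#' @export
drop_scaffolds <- function(assembly, names) {
  keep <- setdiff(base::names(assembly$seqs), names)
  if (length(keep) == 0) stopf("removing all scaffolds leaves an empty assembly")
  new_assembly(assembly$seqs[keep],
               origins = assembly$origins[keep],
               gaps = assembly$gaps[assembly$gaps$scaffold %in% keep, , drop = FALSE],
               components = assembly$components[
                 assembly$components$object %in% keep, , drop = FALSE],
               validate = FALSE)
}

#' Rename scaffolds by the length-ranked LG/CSC/SC convention
#'
#' Scaffolds are sorted by length from long to short (ties broken
#' lexicographically by prior name). Pseudomolecules (scaffolds listed in
#' `lg_scaffolds`) are named `LG-<rank>`, other scaffolds concatenated from
#' two or more ancestors `CSC-<rank>`, and single-ancestor scaffolds
#' `SC-<rank>`, where `<rank>` is the position in the length ordering. The
#' ancestor names, joined by `"."`, follow after a blank.
#'
#' @param assembly An `mw_assembly`.
#' @param lg_scaffolds Character vector of scaffold names that are
#'   linkage-group pseudomolecules.
#' @return List with `assembly` (renamed) and `name_map` (named character
#'   vector old -> new).
#' @export
rename_scaffolds <- function(assembly, lg_scaffolds = character(0)) {
  stopifnot(inherits(assembly, "mw_assembly"))
  lens <- scaffold_lengths(assembly)
  ord <- order(-lens, names(assembly$seqs))
  old <- names(assembly$seqs)[ord]
  type <- ifelse(old %in% lg_scaffolds, "LG",
                 ifelse(vapply(assembly$origins[old], length, 1L) >= 2,
                        "CSC", "SC"))
  newnames <- sprintf("%s-%d %s", type, seq_along(old),
                      vapply(assembly$origins[old], paste, "", collapse = "."))
  if (anyDuplicated(newnames)) stopf("internal error: duplicate scaffold names")
  name_map <- stats::setNames(newnames, old)
  seqs <- assembly$seqs[old]
  names(seqs) <- newnames
  origins <- assembly$origins[old]
  names(origins) <- newnames
  gaps <- assembly$gaps
  gaps$scaffold <- unname(name_map[gaps$scaffold])
  comp <- assembly$components
  comp$object <- unname(name_map[comp$object])
  list(assembly = new_assembly(seqs, origins = origins, gaps = gaps,
                               components = comp, validate = FALSE),
       name_map = name_map)
}

#' Write an assembly layout as AGP v2.1
#'
#' Emits one W row per ancestor component and one U row (gap length 100,
#' `gap_type` "map", linkage "yes") per map-join gap. Coordinates are
#' converted to AGP's 1-based inclusive convention.
#'
#' @param assembly An `mw_assembly` whose `components` describe the layout.
#' @param path Output file path.
#' @return Invisibly, the AGP lines.
#' @export
write_agp <- function(assembly, path) {
  stopifnot(inherits(assembly, "mw_assembly"))
  lines <- c("##agp-version\t2.1")
  for (obj in unique(assembly$components$object)) {
    comp <- assembly$components[assembly$components$object == obj, , drop = FALSE]
    comp <- comp[order(comp$obj_start), , drop = FALSE]
    joins <- assembly$gaps[assembly$gaps$scaffold == obj &
                             assembly$gaps$provenance == "map_join", , drop = FALSE]
    rows <- list()
    part <- 0L
    for (i in seq_len(nrow(comp))) {
      if (i > 1) {
        g <- joins[joins$start >= comp$obj_end[i - 1] &
                     joins$end <= comp$obj_start[i], , drop = FALSE]
        for (j in seq_len(nrow(g))) {
          part <- part + 1L
          rows[[length(rows) + 1L]] <- sprintf(
            "%s\t%d\t%d\t%d\tU\t%d\tmap\tyes\tmap", obj,
            g$start[j] + 1L, g$end[j], part, g$end[j] - g$start[j])
        }
      }
      part <- part + 1L
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s", obj,
        comp$obj_start[i] + 1L, comp$obj_end[i], part, comp$component[i],
        1L, comp$obj_end[i] - comp$obj_start[i], comp$strand[i])
    }
    lines <- c(lines, unlist(rows))
  }
  writeLines(lines, path)
  invisible(lines)
}

#' Read an assembly from FASTA
#'
#' @param path FASTA file.
#' @return An `mw_assembly`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  seqs <- as.character(set)
  new_assembly(seqs)
}

#' Write an assembly to FASTA (wrapped at 80 columns)
#'
#' @param assembly An `mw_assembly`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(assembly, path) {
  stopifnot(inherits(assembly, "mw_assembly"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(assembly$seqs), path,
                              width = 80L)
  invisible(path)
}
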