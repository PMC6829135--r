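# Synthetic-data generators.  These emulate the statistical structure of the
# study system: a multi-chromosome plant genome fragmented into gapped draft
# scaffolds, two parental haplotypes differing by SNPs, an F8 RIL population
# produced by single-seed descent with Haldane-model (no-interference)
# crossovers, GBS-like missingness and genotyping error, and error-bearing
# long reads.  Every generator is byte-deterministic for a fixed seed, and
# ground truth (scaffold placements, removed gap sequence, per-line
# breakpoints) is retained so downstream results can be verified exactly.

#' Simulate a multi-chromosome reference genome
#'
#' Chromosome sequences are i.i.d. over `{A,C,G,T}` at the requested GC
#' fraction.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param lengths Chromosome lengths in bp (recycled to `n_chromosomes`).
#' @param gc GC fraction.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return A `mw_truth` object holding the chromosomes; other truth slots are
#'   filled by the later simulation stages.
#' @export
simulate_reference <- function(n_chromosomes, lengths, gc = 0.38, seed = 1L) {
  stopifnot(n_chromosomes >= 1, gc > 0, gc < 1)
  lengths <- rep_len(as.numeric(lengths), n_chromosomes)
  if (any(lengths <= 0)) stopf("chromosome lengths must be positive")
  chroms <- withr::with_seed(substream_seed(seed, "reference"), {
    stats::setNames(
      vapply(lengths, function(L) rand_dna(L, gc), ""),
      sprintf("chr%02d", seq_len(n_chromosomes)))
  })
  structure(list(chromosomes = chroms, gc = gc,
                 parental_snps = NULL, scaffold_placements = NULL,
                 gap_truth = NULL, ril = NULL, contaminants = character(0),
                 seed = seed),
            class = "mw_truth")
}

#' @export
print.mw_truth <- function(x, ...) {
  cat(sprintf("mw_truth: %d chromosome(s), %s bp", length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  if (!is.null(x$parental_snps))
    cat(sprintf(", %d parental SNPs", nrow(x$parental_snps)))
  if (!is.null(x$scaffold_placements))
    cat(sprintf(", %d placed scaffolds", nrow(x$scaffold_placements)))
  if (!is.null(x$ril)) cat(sprintf(", %d RIL lines", length(x$ril)))
  cat("\n")
  invisible(x)
}

#' Simulate parental SNP divergence
#'
#' SNP positions are drawn without replacement along each chromosome at the
#' given per-bp rate; the alternative allele always differs from the
#' reference allele and neither is N.
#'
#' @param truth A `mw_truth` from [simulate_reference()].
#' @param snp_rate Per-bp SNP probability, in (0, 0.1) (0 gives no SNPs).
#' @param seed Integer seed.
#' @return The `mw_truth` with `parental_snps` filled: data.frame of `chrom`,
#'   `pos` (0-based), `allele_A` (reference parent), `allele_B`.
#' @export
simulate_parents <- function(truth, snp_rate, seed = 1L) {
  stopifnot(inherits(truth, "mw_truth"), snp_rate >= 0, snp_rate < 0.1)
  snps <- withr::with_seed(substream_seed(seed, "parents"), {
    rows <- lapply(names(truth$chromosomes), function(cn) {
      L <- nchar(truth$chromosomes[[cn]])
      n <- stats::rbinom(1L, L, snp_rate)
      if (n == 0L) return(NULL)
      pos <- sort(sample.int(L, n)) - 1L
      ref <- substring(truth$chromosomes[[cn]], pos + 1L, pos + 1L)
      alt <- vapply(ref, function(b) sample(setdiff(dna_alphabet, b), 1L), "")
      data.frame(chrom = cn, pos = pos, allele_A = unname(ref),
                 allele_B = unname(alt), stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0)
      data.frame(chrom = character(0), pos = integer(0),
                 allele_A = character(0), allele_B = character(0),
                 stringsAsFactors = FALSE)
    else do.call(rbind, rows)
  })
  truth$parental_snps <- snps
  truth
}

# --- meiosis machinery -------------------------------------------------------

# A haplotype along one chromosome is a mosaic of parental origins:
# breaks = positions (0-based) where the origin changes, alleles = origin
# (1 = parent A, 2 = parent B) of each segment (length(breaks) + 1 segments).
hap_const <- function(allele) list(breaks = numeric(0), alleles = allele)

hap_allele_at <- function(h, pos) {
  h$alleles[findInterval(pos, h$breaks) + 1L]
}

# One gamete from a diploid (h1, h2): crossovers are a Poisson process with
# mean = map length in Morgans (Haldane model, no interference), placed
# uniformly along the chromosome.
sim_gamete <- function(h1, h2, L, morgans) {
  nco <- stats::rpois(1L, morgans)
  cur <- sample.int(2L, 1L)
  if (nco == 0L) return(if (cur == 1L) h1 else h2)
  co <- sort(stats::runif(nco, 0, L))
  starts <- c(0, sort(unique(c(h1$breaks, h2$breaks, co))))
  nswitch <- findInterval(starts, co)
  src <- ifelse(nswitch %% 2L == 0L, cur, 3L - cur)
  alleles <- vapply(seq_along(starts), function(i) {
    h <- if (src[i] == 1L) h1 else h2
    hap_allele_at(h, starts[i])
  }, 1)
  keep <- c(TRUE, alleles[-1L] != alleles[-length(alleles)])
  list(breaks = starts[keep][-1L], alleles = alleles[keep])
}

#' Simulate an F-generation RIL population and genotype it
#'
#' Each line descends from a heterozygous F1 by `n_selfing_generations`
#' rounds of single-seed descent; meioses place crossovers as a Poisson
#' process with mean equal to the chromosome map length in Morgans (Haldane
#' model, no interference).  Genotype calls at every parental SNP are then
#' degraded: flipped to a random other state with probability `error_rate`
#' and masked to missing with probability `missing_rate`.  Residual
#' heterozygosity per locus is expected to be about `0.5^g` for `g` selfing
#' rounds.
#'
#' Markers are anchored to draft scaffolds when the truth already carries
#' scaffold placements (SNPs falling into gap-masked sequence are dropped);
#' otherwise they are anchored to chromosome coordinates.
#'
#' @param truth A `mw_truth` with parental SNPs.
#' @param n_lines Number of RIL lines (>= 2).
#' @param n_selfing_generations Selfing rounds after F1 (7 gives an F8
#'   population).
#' @param missing_rate,error_rate GBS-like degradation rates in `[0, 1)`.
#' @param morgans_per_chromosome Map length per chromosome in Morgans
#'   (recycled). Default 1.625 (an average linkage group of 162.5 cM).
#' @param seed Integer seed.
#' @return List with `genotypes` (an `mw_geno`) and `truth` (with per-line
#'   breakpoints stored in `$ril`).
#' @export
simulate_ril_population <- function(truth, n_lines, n_selfing_generations = 7L,
                                    missing_rate = 0.05, error_rate = 0.01,
                                    morgans_per_chromosome = 1.625,
                                    seed = 1L) {
  stopifnot(inherits(truth, "mw_truth"), n_lines >= 2,
            missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1)
  if (is.null(truth$parental_snps) || nrow(truth$parental_snps) == 0)
    stopf("truth carries no parental SNPs; run simulate_parents() first")
  chroms <- names(truth$chromosomes)
  lens <- nchar(truth$chromosomes)
  morg <- rep_len(morgans_per_chromosome, length(chroms))
  names(morg) <- chroms
  snps <- truth$parental_snps

  res <- withr::with_seed(substream_seed(seed, "ril"), {
    lines <- vector("list", n_lines)
    calls <- matrix(NA_character_, nrow = nrow(snps), ncol = n_lines)
    for (li in seq_len(n_lines)) {
      haps <- lapply(chroms, function(cn) list(h1 = hap_const(1), h2 = hap_const(2)))
      names(haps) <- chroms
      for (g in seq_len(n_selfing_generations)) {
        haps <- lapply(chroms, function(cn) {
          h <- haps[[cn]]
          list(h1 = sim_gamete(h$h1, h$h2, lens[[cn]], morg[[cn]]),
               h2 = sim_gamete(h$h1, h$h2, lens[[cn]], morg[[cn]]))
        })
        names(haps) <- chroms
      }
      lines[[li]] <- haps
      for (cn in chroms) {
        idx <- which(snps$chrom == cn)
        if (length(idx) == 0) next
        a1 <- hap_allele_at(haps[[cn]]$h1, snps$pos[idx])
        a2 <- hap_allele_at(haps[[cn]]$h2, snps$pos[idx])
        calls[idx, li] <- ifelse(a1 == a2, ifelse(a1 == 1, "A", "B"), "H")
      }
    }
    # genotyping error: flip to a random other state
    if (error_rate > 0) {
      flip <- which(stats::runif(length(calls)) < error_rate)
      states <- c("A", "B", "H")
      if (length(flip) > 0)
        calls[flip] <- vapply(calls[flip], function(s)
          sample(setdiff(states, s), 1L), "")
    }
    # GBS missingness
    if (missing_rate > 0)
      calls[stats::runif(length(calls)) < missing_rate] <- NA_character_
    list(lines = lines, calls = calls)
  })

  line_names <- sprintf("RIL%03d", seq_len(n_lines))
  colnames(res$calls) <- line_names
  truth$ril <- stats::setNames(res$lines, line_names)

  markers <- data.frame(id = sprintf("%s_%07d", snps$chrom, snps$pos),
                        scaffold = snps$chrom, position = snps$pos,
                        stringsAsFactors = FALSE)
  calls <- res$calls
  rownames(calls) <- markers$id

  if (!is.null(truth$scaffold_placements)) {
    anch <- anchor_snps_to_scaffolds(truth)
    keep <- !is.na(anch$scaffold)
    markers <- data.frame(id = markers$id[keep],
                          scaffold = anch$scaffold[keep],
                          position = anch$position[keep],
                          stringsAsFactors = FALSE)
    calls <- calls[keep, , drop = FALSE]
  }
  ord <- order(markers$scaffold, markers$position)
  list(genotypes = new_geno_matrix(markers[ord, , drop = FALSE],
                                   calls[ord, , drop = FALSE]),
       truth = truth)
}

# Map parental SNP chromosome coordinates onto draft scaffold coordinates
# using the recorded placements; SNPs inside gap-masked sequence (N in the
# scaffold) get NA.
anchor_snps_to_scaffolds <- function(truth) {
  snps <- truth$parental_snps
  pl <- truth$scaffold_placements
  out_sc <- rep(NA_character_, nrow(snps))
  out_pos <- rep(NA_integer_, nrow(snps))
  for (cn in unique(snps$chrom)) {
    p <- pl[pl$chrom == cn, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    idx <- which(snps$chrom == cn)
    hit <- findInterval(snps$pos[idx], p$start)
    ok <- hit >= 1 & snps$pos[idx] < p$end[pmax(hit, 1L)]
    for (k in which(ok)) {
      row <- p[hit[k], ]
      off <- snps$pos[idx[k]] - row$start
      sc_len <- row$end - row$start
      pos <- if (row$orientation == "+") off else sc_len - 1L - off
      base <- substring(truth$chromosomes[[cn]], snps$pos[idx[k]] + 1L,
                        snps$pos[idx[k]] + 1L)
      # the scaffold may have Ns where gap sequence was removed
      sc_base <- substring(truth$scaffold_seq_cache[[row$scaffold]],
                           pos + 1L, pos + 1L)
      if (!identical(sc_base, "N")) {
        out_sc[idx[k]] <- row$scaffold
        out_pos[idx[k]] <- pos
      }
    }
  }
  list(scaffold = out_sc, position = out_pos)
}

#' Fragment chromosomes into a gapped, shuffled draft assembly
#'
#' Chromosomes are cut at Poisson-process points (mean segment
#' `mean_scaffold_bp`); each resulting scaffold receives, with probability
#' `gap_rate`, one internal gap whose sequence is replaced by the same number
#' of Ns (length drawn uniformly from `gap_len_range`); the removed sequence
#' is recorded in the truth so gap fills can be verified byte-exactly.
#' Scaffold order is shuffled and orientations randomly flipped; placements
#' are stored in the truth.
#'
#' @param truth A `mw_truth`.
#' @param mean_scaffold_bp Mean scaffold length (>= 1000).
#' @param gap_rate Per-scaffold probability of carrying one internal gap.
#' @param gap_len_range Length range (bp) for the gap.
#' @param min_scaffold_bp Segments shorter than this are merged into their
#'   neighbour.
#' @param gap_margin Minimum distance of a gap from either scaffold end.
#' @param seed Integer seed.
#' @return List with `assembly` (`mw_assembly`) and `truth` (placements and
#'   removed gap sequence filled in).
#' @export
fragment_assembly <- function(truth, mean_scaffold_bp, gap_rate = 0.5,
                              gap_len_range = c(50L, 400L),
                              min_scaffold_bp = 1000L, gap_margin = 500L,
                              seed = 1L) {
  stopifnot(inherits(truth, "mw_truth"), mean_scaffold_bp >= 1000)
  res <- withr::with_seed(substream_seed(seed, "fragment"), {
    placements <- list(); seqs <- list(); gap_truth <- list()
    sc_i <- 0L
    for (cn in names(truth$chromosomes)) {
      L <- nchar(truth$chromosomes[[cn]])
      cuts <- numeric(0); at <- 0
      repeat {
        at <- at + stats::rexp(1L, 1 / mean_scaffold_bp)
        if (at >= L) break
        cuts <- c(cuts, floor(at))
      }
      bounds <- unique(c(0, cuts, L))
      # merge segments below the minimum into the previous one
      keep <- c(TRUE, diff(bounds) >= min_scaffold_bp)
      keep[length(bounds)] <- TRUE
      bounds <- bounds[keep]
      if (bounds[length(bounds)] - bounds[length(bounds) - 1] < min_scaffold_bp &&
          length(bounds) > 2)
        bounds <- bounds[-(length(bounds) - 1)]
      for (i in seq_len(length(bounds) - 1L)) {
        sc_i <- sc_i + 1L
        s0 <- bounds[i]; s1 <- bounds[i + 1L]
        seq <- substring(truth$chromosomes[[cn]], s0 + 1L, s1)
        slen <- s1 - s0
        removed <- NULL
        if (stats::runif(1L) < gap_rate && slen > 2 * gap_margin + gap_len_range[2]) {
          glen <- sample(gap_len_range[1]:gap_len_range[2], 1L)
          gpos <- sample((gap_margin):(slen - gap_margin - glen), 1L)
          removed <- substring(seq, gpos + 1L, gpos + glen)
          seq <- paste0(substring(seq, 1L, gpos),
                        strrep("N", glen),
                        substring(seq, gpos + glen + 1L))
          removed <- data.frame(start = gpos, end = gpos + glen,
                                removed = removed, stringsAsFactors = FALSE)
        }
        orient <- if (stats::runif(1L) < 0.5) "+" else "-"
        if (orient == "-") {
          seq <- revcomp(seq)
          if (!is.null(removed)) {
            removed <- data.frame(start = slen - removed$end,
                                  end = slen - removed$start,
                                  removed = revcomp(removed$removed),
                                  stringsAsFactors = FALSE)
          }
        }
        placements[[sc_i]] <- data.frame(
          idx = sc_i, chrom = cn, start = s0, end = s1,
          orientation = orient, stringsAsFactors = FALSE)
        seqs[[sc_i]] <- seq
        gap_truth[sc_i] <- list(removed)
      }
    }
    shuffle <- sample.int(sc_i)
    list(placements = placements, seqs = seqs, gap_truth = gap_truth,
         shuffle = shuffle)
  })

  n <- length(res$seqs)
  names_out <- sprintf("Scaffold_%04d", seq_len(n))
  # shuffle: scaffold j in output order is original segment res$shuffle[j]
  pl_rows <- list(); gap_rows <- list(); seqs <- character(n)
  for (j in seq_len(n)) {
    oi <- res$shuffle[j]
    seqs[j] <- res$seqs[[oi]]
    p <- res$placements[[oi]]
    pl_rows[[j]] <- data.frame(scaffold = names_out[j], chrom = p$chrom,
                               start = p$start, end = p$end,
                               orientation = p$orientation,
                               stringsAsFactors = FALSE)
    g <- res$gap_truth[[oi]]
    if (!is.null(g))
      gap_rows[[length(gap_rows) + 1L]] <- data.frame(
        scaffold = names_out[j], start = g$start, end = g$end,
        removed = g$removed, stringsAsFactors = FALSE)
  }
  names(seqs) <- names_out
  truth$scaffold_placements <- do.call(rbind, pl_rows)
  truth$gap_truth <- if (length(gap_rows) > 0) do.call(rbind, gap_rows) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               removed = character(0), stringsAsFactors = FALSE)
  truth$scaffold_seq_cache <- as.list(seqs)
  gaps <- if (nrow(truth$gap_truth) > 0) {
    data.frame(scaffold = truth$gap_truth$scaffold,
               start = truth$gap_truth$start, end = truth$gap_truth$end,
               provenance = "original",
               nominal_len = truth$gap_truth$end - truth$gap_truth$start,
               stringsAsFactors = FALSE)
  } else empty_gap_registry()
  list(assembly = new_assembly(seqs, gaps = gaps, validate = FALSE),
       truth = truth)
}

#' Reconstruct chromosomes from a fragmented assembly and its truth
#'
#' Restores the removed gap sequence, reverse-complements flipped scaffolds
#' and concatenates them by placement; used to verify that fragmentation is
#' lossless.
#'
#' @param assembly The fragmented `mw_assembly`.
#' @param truth The matching `mw_truth`.
#' @return Named character vector of chromosome sequences.
#' @export
reassemble_truth <- function(assembly, truth) {
  out <- character(0)
  for (cn in names(truth$chromosomes)) {
    p <- truth$scaffold_placements
    p <- p[p$chrom == cn, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    parts <- vapply(seq_len(nrow(p)), function(i) {
      s <- assembly$seqs[[p$scaffold[i]]]
      g <- truth$gap_truth[truth$gap_truth$scaffold == p$scaffold[i], , drop = FALSE]
      for (k in seq_len(nrow(g)))
        s <- paste0(substring(s, 1L, g$start[k]), g$removed[k],
                    substring(s, g$end[k] + 1L))
      if (p$orientation[i] == "-") s <- revcomp(s)
      s
    }, "")
    out[[cn]] <- paste(parts, collapse = "")
  }
  out
}

#' Simulate error-bearing long reads
#'
#' Reads are sampled uniformly from the chromosomes (both strands) with
#' lengths from a truncated geometric law; substitutions and indels are
#' applied at `error_rate`.  The true origin of each read is retained.
#'
#' @param truth A `mw_truth`.
#' @param n_reads Number of reads.
#' @param length_law `c(mean, min, max)` read length in bp.
#' @param error_rate Total per-base error rate (< 0.3), split 60/20/20
#'   between substitutions, insertions and deletions.
#' @param seed Integer seed.
#' @return An `mw_reads` object: `seqs` (named character vector) and
#'   `origin` (data.frame `read`, `chrom`, `start`, `end`, `strand`).
#' @export
simulate_long_reads <- function(truth, n_reads, length_law = c(4000, 500, 20000),
                                error_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "mw_truth"), error_rate < 0.3, n_reads >= 0)
  if (n_reads == 0)
    return(structure(list(seqs = character(0),
                          origin = data.frame(read = character(0),
                                              chrom = character(0),
                                              start = integer(0), end = integer(0),
                                              strand = character(0),
                                              stringsAsFactors = FALSE)),
                     class = "mw_reads"))
  lens <- nchar(truth$chromosomes)
  res <- withr::with_seed(substream_seed(seed, "long_reads"), {
    chrom <- sample(names(lens), n_reads, replace = TRUE, prob = lens / sum(lens))
    rl <- pmin(length_law[2] + stats::rgeom(n_reads,
                                            1 / max(length_law[1] - length_law[2], 1)),
               length_law[3])
    rl <- pmin(rl, lens[chrom])
    start <- floor(stats::runif(n_reads) * (lens[chrom] - rl + 1))
    strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- substring(truth$chromosomes[[chrom[i]]], start[i] + 1L, start[i] + rl[i])
      if (strand[i] == "-") s <- revcomp(s)
      if (error_rate > 0) s <- corrupt_read(s, error_rate)
      seqs[i] <- s
    }
    list(chrom = chrom, start = start, len = rl, strand = strand, seqs = seqs)
  })
  nm <- sprintf("read_%06d", seq_len(n_reads))
  names(res$seqs) <- nm
  structure(list(
    seqs = res$seqs,
    origin = data.frame(read = nm, chrom = res$chrom, start = res$start,
                        end = res$start + res$len, strand = res$strand,
                        stringsAsFactors = FALSE)),
    class = "mw_reads")
}

corrupt_read <- function(seq, error_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  err <- which(stats::runif(length(ch)) < error_rate)
  if (length(err) == 0) return(seq)
  type <- sample(c("sub", "ins", "del"), length(err), replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  for (k in seq_along(err)) {
    i <- err[k]
    ch[i] <- switch(type[k],
                    sub = sample(setdiff(dna_alphabet, ch[i]), 1L),
                    ins = paste0(ch[i], sample(dna_alphabet, 1L)),
                    del = "")
  }
  paste(ch, collapse = "")
}

#' @export
print.mw_reads <- function(x, ...) {
  cat(sprintf("mw_reads: %d reads, %s bp total\n", length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Write reads as FASTQ (phred+33, constant quality)
#' @param reads An `mw_reads`.
#' @param path Output path.
#' @param quality Constant phred quality character (default "I", Q40).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  set <- Biostrings::DNAStringSet(reads$seqs)
  quals <- Biostrings::BStringSet(vapply(nchar(reads$seqs),
                                         function(n) strrep(quality, n), ""))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into an `mw_reads`
#' @param path FASTQ path.
#' @return An `mw_reads` (origin unknown).
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- as.character(set)
  structure(list(seqs = seqs,
                 origin = data.frame(read = names(seqs), chrom = NA_character_,
                                     start = NA_integer_, end = NA_integer_,
                                     strand = NA_character_,
                                     stringsAsFactors = FALSE)),
            class = "mw_reads")
}

#' Append contaminant scaffolds and build a taxon hit table
#'
#' Adds `n_contaminant` short random scaffolds flagged as contaminant in the
#' truth and emits a per-1-kbp-fragment hit table in which contaminant
#' fragments hit bacteria (bit score >= 50) and genuine fragments hit
#' Viridiplantae.
#'
#' @param assembly An `mw_assembly`.
#' @param n_contaminant Number of contaminant scaffolds to append.
#' @param truth Optional `mw_truth` in which to record the contaminant names.
#' @param seed Integer seed.
#' @return List with `assembly`, `hits` (data.frame `scaffold`, `frag_index`,
#'   `frag_len`, `taxon`, `bitscore`), `contaminants` and (if supplied)
#'   `truth`.
#' @export
simulate_contamination <- function(assembly, n_contaminant, truth = NULL,
                                   seed = 1L) {
  stopifnot(inherits(assembly, "mw_assembly"), n_contaminant >= 0)
  res <- withr::with_seed(substream_seed(seed, "contamination"), {
    cseqs <- character(0)
    if (n_contaminant > 0) {
      cseqs <- stats::setNames(
        vapply(sample(600:2500, n_contaminant, replace = TRUE),
               function(L) rand_dna(L, 0.5), ""),
        sprintf("ContamScaffold_%02d", seq_len(n_contaminant)))
    }
    all_seqs <- c(assembly$seqs, cseqs)
    rows <- list()
    for (nm in names(all_seqs)) {
      L <- nchar(all_seqs[[nm]])
      nfrag <- ceiling(L / 1000)
      flen <- rep(1000L, nfrag)
      if (L %% 1000 != 0) flen[nfrag] <- L %% 1000
      contam <- nm %in% names(cseqs)
      if (contam) {
        taxon <- rep("bacteria", nfrag)
        score <- stats::runif(nfrag, 55, 150)
      } else {
        taxon <- sample(c("Viridiplantae", "none"), nfrag, replace = TRUE,
                        prob = c(0.9, 0.1))
        score <- ifelse(taxon == "none", 0, stats::runif(nfrag, 60, 200))
      }
      rows[[nm]] <- data.frame(scaffold = nm, frag_index = seq_len(nfrag),
                               frag_len = flen, taxon = taxon,
                               bitscore = round(score, 1),
                               stringsAsFactors = FALSE)
    }
    list(cseqs = cseqs, hits = do.call(rbind, rows))
  })
  out_asm <- new_assembly(c(assembly$seqs, res$cseqs),
                          origins = c(assembly$origins,
                                      as.list(stats::setNames(names(res$cseqs),
                                                              names(res$cseqs)))),
                          gaps = assembly$gaps, validate = FALSE)
  rownames(res$hits) <- NULL
  out <- list(assembly = out_asm, hits = res$hits,
              contaminants = names(res$cseqs))
  if (!is.null(truth)) {
    truth$contaminants <- c(truth$contaminants, names(res$cseqs))
    out$truth <- truth
  }
  out
}

#' Simulate gene models on an assembly
#'
#' Random multi-exon gene structures placed on N-free stretches of the
#' scaffolds (gene = mRNA span; CDS = exons).  These are structural
#' fixtures for liftover testing; no attempt is made to give them open
#' reading frames, so classification flags reflect the underlying random
#' sequence.
#'
#' @param assembly An `mw_assembly`.
#' @param n_genes Number of genes to attempt (placements colliding with
#'   gaps or scaffold ends are retried a few times, then skipped).
#' @param n_exons_range Range of exon counts per gene.
#' @param exon_len_range,intron_len_range Length ranges in bp.
#' @param seed Integer seed.
#' @return An `mw_genes` gene set.
#' @export
simulate_gene_models <- function(assembly, n_genes, n_exons_range = c(1L, 4L),
                                 exon_len_range = c(90L, 300L),
                                 intron_len_range = c(60L, 200L), seed = 1L) {
  stopifnot(inherits(assembly, "mw_assembly"), n_genes >= 0)
  lens <- scaffold_lengths(assembly)
  rows <- withr::with_seed(substream_seed(seed, "gene_models"), {
    out <- list()
    gi <- 0L
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in 1:20) {
        sc <- sample(names(lens), 1L, prob = lens / sum(lens))
        ne <- sample(n_exons_range[1]:n_exons_range[2], 1L)
        el <- sample(exon_len_range[1]:exon_len_range[2], ne, replace = TRUE)
        il <- if (ne > 1) sample(intron_len_range[1]:intron_len_range[2],
                                 ne - 1L, replace = TRUE) else integer(0)
        span <- sum(el) + sum(il)
        if (lens[[sc]] < span + 200L) next
        g0 <- sample.int(lens[[sc]] - span - 100L, 1L) + 50L
        gene_seq <- substring(assembly$seqs[[sc]], g0 + 1L, g0 + span)
        if (grepl("N", gene_seq, fixed = TRUE)) next
        strand <- if (stats::runif(1L) < 0.5) "+" else "-"
        gi <- gi + 1L
        gid <- sprintf("gene%04d", gi)
        mid <- sprintf("%s.m1", gid)
        ex_start <- g0 + c(0L, cumsum(el + c(il, 0L))[-ne])
        feats <- list(
          data.frame(seqid = sc, type = "gene", start = g0, end = g0 + span,
                     strand = strand, ID = gid, Parent = NA_character_,
                     gene = gid, stringsAsFactors = FALSE),
          data.frame(seqid = sc, type = "mRNA", start = g0, end = g0 + span,
                     strand = strand, ID = mid, Parent = gid, gene = gid,
                     stringsAsFactors = FALSE))
        for (e in seq_len(ne)) {
          feats[[length(feats) + 1L]] <- data.frame(
            seqid = sc, type = "exon", start = ex_start[e],
            end = ex_start[e] + el[e], strand = strand,
            ID = sprintf("%s.exon%d", mid, e), Parent = mid, gene = gid,
            stringsAsFactors = FALSE)
          feats[[length(feats) + 1L]] <- data.frame(
            seqid = sc, type = "CDS", start = ex_start[e],
            end = ex_start[e] + el[e], strand = strand,
            ID = sprintf("%s.cds%d", mid, e), Parent = mid, gene = gid,
            stringsAsFactors = FALSE)
        }
        out[[length(out) + 1L]] <- do.call(rbind, feats)
        placed <- TRUE
        break
      }
    }
    out
  })
  if (length(rows) == 0)
    return(new_gene_set(data.frame(seqid = character(0), type = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0), ID = character(0),
                                   Parent = character(0), gene = character(0),
                                   stringsAsFactors = FALSE)))
  new_gene_set(do.call(rbind, rows))
}
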