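# Shared fixtures and independent oracles used across the test files.

# Random DNA string (test-local, independent of the package generator).
rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Independent reverse complement (character-level, no Biostrings).
rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Brute-force N50/L50 oracle: walk the descending-sorted lengths.
n50_brute <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (i in seq_along(lens)) {
    acc <- acc + lens[i]
    if (acc >= half) return(list(N50 = lens[i], L50 = i))
  }
}

# rle-based gap oracle.
gaps_brute <- function(seq, min_gap) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(ch == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_gap
  data.frame(start = starts[keep], end = ends[keep])
}

# Binomial-likelihood LOD oracle.
lod_brute <- function(k, n) {
  R <- max(k / n, 1 / (2 * n))
  k * log10(R) + (n - k) * log10(1 - R) - n * log10(0.5)
}

# Genotype matrix from a plain call matrix.
geno_from_matrix <- function(calls, positions = NULL, scaffold = "s1") {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("m%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("L%03d", seq_len(ncol(calls)))
  if (is.null(positions)) positions <- seq_len(nrow(calls)) * 1000L
  new_geno_matrix(
    data.frame(id = rownames(calls), scaffold = scaffold,
               position = positions, stringsAsFactors = FALSE),
    calls)
}

# An mw_reads object built from explicit sequences.
reads_from_seqs <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("r%03d", seq_along(seqs))
  n <- length(seqs)
  structure(list(seqs = seqs,
                 origin = data.frame(read = names(seqs),
                                     chrom = rep(NA_character_, n),
                                     start = rep(NA_integer_, n),
                                     end = rep(NA_integer_, n),
                                     strand = rep(NA_character_, n),
                                     stringsAsFactors = FALSE)),
            class = "mw_reads")
}

# Fig.2-style scenario: truth chromosome split into X/Y/Z; the "map" joined
# X and Z directly with a 100-N gap while Y stayed separate.
xyz_scenario <- function(piece = 8000L, seed = 5L) {
  t <- simulate_reference(1, 3L * piece, gc = 0.45, seed = seed)
  chr <- t$chromosomes[[1]]
  X <- substring(chr, 1, piece)
  Y <- substring(chr, piece + 1L, 2L * piece)
  Z <- substring(chr, 2L * piece + 1L, 3L * piece)
  base <- new_assembly(c(X = X, Y = Y, Z = Z))
  integrated <- new_assembly(
    c(XZ = paste0(X, strrep("N", 100), Z), Y = Y),
    origins = list(XZ = c("X", "Z"), Y = "Y"),
    gaps = data.frame(scaffold = "XZ", start = piece, end = piece + 100L,
                      provenance = "map_join", nominal_len = 100L,
                      stringsAsFactors = FALSE),
    components = data.frame(object = c("XZ", "XZ", "Y"), part = c(1L, 2L, 1L),
                            component = c("X", "Z", "Y"), strand = "+",
                            obj_start = c(0L, piece + 100L, 0L),
                            obj_end = c(piece, 2L * piece + 100L, piece),
                            stringsAsFactors = FALSE))
  list(truth = t, chr = chr, base = base, integrated = integrated)
}

# Gene set with a single mRNA and explicit CDS intervals (0-based half-open).
single_gene <- function(seqid, cds_starts, cds_ends, strand = "+",
                        gid = "g1") {
  n <- length(cds_starts)
  mid <- paste0(gid, ".m1")
  new_gene_set(rbind(
    data.frame(seqid = seqid, type = "gene", start = min(cds_starts),
               end = max(cds_ends), strand = strand, ID = gid,
               Parent = NA_character_, gene = gid, stringsAsFactors = FALSE),
    data.frame(seqid = seqid, type = "mRNA", start = min(cds_starts),
               end = max(cds_ends), strand = strand, ID = mid, Parent = gid,
               gene = gid, stringsAsFactors = FALSE),
    data.frame(seqid = seqid, type = "CDS", start = cds_starts,
               end = cds_ends, strand = strand,
               ID = sprintf("%s.c%d", mid, seq_len(n)), Parent = mid,
               gene = gid, stringsAsFactors = FALSE)))
}

# Independent pseudogene-classification oracle built on Biostrings::translate
# (all feature/frame substrings translated in one batched call).  The
# pre/finish split lets many fixtures share a single translate call.
classify_brute_pre <- function(assembly, cds_df) {
  cds_df <- cds_df[order(cds_df$start), , drop = FALSE]
  strand <- cds_df$strand[1]
  pieces <- vapply(seq_len(nrow(cds_df)), function(i)
    substring(assembly$seqs[[cds_df$seqid[i]]], cds_df$start[i] + 1L,
              cds_df$end[i]), "")
  spliced <- paste(pieces, collapse = "")
  if (strand == "-") spliced <- rc(spliced)
  n <- nchar(spliced)
  no_start <- substring(spliced, 1, 3) != "ATG"
  no_stop <- !(substring(spliced, n - 2, n) %in% c("TAA", "TAG", "TGA"))
  mod3 <- n %% 3 != 0
  # per-CDS-feature frame scan, terminal stop excluded
  term <- if (strand == "+") which.max(cds_df$end) else which.min(cds_df$start)
  frame_seqs <- character(0)
  frame_feat <- integer(0)
  clean_short <- rep(FALSE, nrow(cds_df))  # a frame with no full codon is clean
  for (i in seq_len(nrow(cds_df))) {
    fs <- pieces[i]
    if (strand == "-") fs <- rc(fs)
    if (i == term && !no_stop && nchar(fs) > 3)
      fs <- substring(fs, 1, nchar(fs) - 3)
    for (f in 0:2) {
      m <- (nchar(fs) - f) - (nchar(fs) - f) %% 3
      if (m < 3) {
        clean_short[i] <- TRUE
      } else {
        frame_seqs <- c(frame_seqs, substring(fs, f + 1, f + m))
        frame_feat <- c(frame_feat, i)
      }
    }
  }
  list(no_start = no_start, no_stop = no_stop, cds_len_mod3 = mod3,
       frame_seqs = frame_seqs, frame_feat = frame_feat,
       clean_short = clean_short, n_feat = nrow(cds_df))
}

classify_brute_finish <- function(pre, has_stop) {
  internal <- FALSE
  for (i in seq_len(pre$n_feat)) {
    frames <- has_stop[pre$frame_feat == i]
    if (!pre$clean_short[i] && length(frames) > 0 && all(frames)) {
      internal <- TRUE
      break
    }
  }
  list(no_start = pre$no_start, no_stop = pre$no_stop,
       internal_stop = internal, cds_len_mod3 = pre$cds_len_mod3,
       pseudo = pre$no_start || pre$no_stop || internal || pre$cds_len_mod3)
}

translate_has_stop <- function(seqs) {
  if (length(seqs) == 0) return(logical(0))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                           if.fuzzy.codon = "X"))
  grepl("*", aa, fixed = TRUE)
}

classify_brute <- function(assembly, cds_df) {
  pre <- classify_brute_pre(assembly, cds_df)
  classify_brute_finish(pre, translate_has_stop(pre$frame_seqs))
}

# Batched oracle over a list of `classify_brute_pre` results: one translate
# call for every frame substring of every fixture.
classify_brute_batch <- function(pres) {
  lens <- vapply(pres, function(p) length(p$frame_seqs), 1L)
  hs <- translate_has_stop(unlist(lapply(pres, `[[`, "frame_seqs")))
  idx <- cumsum(lens)
  lapply(seq_along(pres), function(i) {
    take <- if (lens[i] > 0) hs[(idx[i] - lens[i] + 1):idx[i]] else logical(0)
    classify_brute_finish(pres[[i]], take)
  })
}
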