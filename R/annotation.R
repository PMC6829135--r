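# Gene-model liftover through a lift chain, with merge of two candidate
# liftover sets, neighbour-offset rescue of unlifted features, pseudogene
# classification, duplicate removal, renaming and a migration report.
# Gene sets are flat feature tables (gene/mRNA/exon/CDS) with internal
# 0-based half-open coordinates; GFF3 I/O converts to 1-based inclusive.

#' Construct a gene set
#'
#' @param df data.frame with columns `seqid`, `type` (gene, mRNA, exon,
#'   CDS), `start`, `end` (0-based half-open), `strand`, `ID`, `Parent`
#'   (`NA` for genes) and `gene` (owning gene id).
#' @return An object of class `mw_genes` (a data.frame).
#' @export
new_gene_set <- function(df) {
  need <- c("seqid", "type", "start", "end", "strand", "ID", "Parent", "gene")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)
  if (any(df$end <= df$start)) stopf("empty feature interval")
  rownames(df) <- NULL
  class(df) <- unique(c("mw_genes", class(df)))
  df
}

gene_ids <- function(genes) unique(genes$gene)

leaf_types <- c("exon", "CDS")

#' Lift gene models through a chain
#'
#' Each exon/CDS interval is mapped block-wise; a feature maps when its
#' image is contiguous on one target scaffold (strand flipped through `-`
#' blocks).  A gene with every leaf mapped is `lifted_full` (inserted fill
#' sequence inside introns is allowed, since exons lift independently);
#' with some leaves unmapped it is `partial`; with none, `failed`.  Gene
#' and mRNA spans are recomputed as hulls of their mapped children.
#'
#' @param genes An `mw_genes` on the chain's source coordinates.
#' @param chain An `mw_chain`.
#' @return List with `genes` (lifted `mw_genes`), `status` (data.frame
#'   `gene`, `status`, `n_leaves`, `n_mapped`), `unmapped` (original
#'   unmapped leaf rows) and `leaf_map` (per-leaf source/target intervals).
#' @export
lift_features <- function(genes, chain) {
  stopifnot(inherits(genes, "mw_genes"), inherits(chain, "mw_chain"))
  leaves <- genes[genes$type %in% leaf_types, , drop = FALSE]
  mapped <- list(); unmapped <- list(); leaf_map <- list()
  for (i in seq_len(nrow(leaves))) {
    lf <- leaves[i, ]
    li <- lift_interval(chain, lf$seqid, lf$start, lf$end)
    if (!li$contiguous) {
      unmapped[[length(unmapped) + 1L]] <- lf
      next
    }
    p <- li$pieces
    t0 <- min(p$tgt_start); t1 <- max(p$tgt_end)
    flipped <- p$flipped[1]
    new <- lf
    new$seqid <- p$tgt[1]
    new$start <- t0; new$end <- t1
    if (flipped) new$strand <- if (lf$strand == "+") "-" else "+"
    mapped[[length(mapped) + 1L]] <- new
    leaf_map[[length(leaf_map) + 1L]] <- data.frame(
      ID = lf$ID, gene = lf$gene, src_seqid = lf$seqid, src_start = lf$start,
      src_end = lf$end, tgt_seqid = new$seqid, tgt_start = t0, tgt_end = t1,
      flipped = flipped, stringsAsFactors = FALSE)
  }
  mapped_df <- if (length(mapped) > 0) do.call(rbind, mapped) else leaves[0, ]
  unmapped_df <- if (length(unmapped) > 0) do.call(rbind, unmapped) else
    leaves[0, ]
  # demote leaves landing off their gene's majority scaffold/strand
  if (nrow(mapped_df) > 0) {
    bad <- logical(nrow(mapped_df))
    for (g in unique(mapped_df$gene)) {
      idx <- which(mapped_df$gene == g)
      key <- paste(mapped_df$seqid[idx], mapped_df$strand[idx])
      maj <- names(sort(table(key), decreasing = TRUE))[1]
      bad[idx[key != maj]] <- TRUE
    }
    if (any(bad)) {
      orig <- leaves[match(mapped_df$ID[bad], leaves$ID), , drop = FALSE]
      unmapped_df <- rbind(unmapped_df, orig)
      lm_df <- do.call(rbind, leaf_map)
      leaf_map <- list(lm_df[!lm_df$ID %in% mapped_df$ID[bad], , drop = FALSE])
      mapped_df <- mapped_df[!bad, , drop = FALSE]
    }
  }
  status <- do.call(rbind, lapply(gene_ids(genes), function(g) {
    nl <- sum(leaves$gene == g)
    nm <- sum(mapped_df$gene == g)
    st <- if (nm == nl && nl > 0) "lifted_full" else if (nm > 0) "partial"
    else "failed"
    data.frame(gene = g, status = st, n_leaves = nl, n_mapped = nm,
               stringsAsFactors = FALSE)
  }))
  out <- rebuild_hulls(genes, mapped_df)
  list(genes = out, status = status, unmapped = unmapped_df,
       leaf_map = if (length(leaf_map) > 0) do.call(rbind, leaf_map) else
         data.frame())
}

# Recompute mRNA and gene rows as hulls of their mapped leaves.
rebuild_hulls <- function(template, leaves_df) {
  if (nrow(leaves_df) == 0) return(new_gene_set(template[0, , drop = FALSE]))
  rows <- list(leaves_df)
  mrna <- template[template$type == "mRNA", , drop = FALSE]
  for (i in seq_len(nrow(mrna))) {
    kids <- leaves_df[leaves_df$Parent == mrna$ID[i], , drop = FALSE]
    if (nrow(kids) == 0) next
    r <- mrna[i, ]
    r$seqid <- kids$seqid[1]; r$strand <- kids$strand[1]
    r$start <- min(kids$start); r$end <- max(kids$end)
    rows[[length(rows) + 1L]] <- r
  }
  gene <- template[template$type == "gene", , drop = FALSE]
  built <- do.call(rbind, rows)
  for (i in seq_len(nrow(gene))) {
    kids <- built[built$gene == gene$gene[i] & built$type == "mRNA", ,
                  drop = FALSE]
    if (nrow(kids) == 0) next
    r <- gene[i, ]
    r$seqid <- kids$seqid[1]; r$strand <- kids$strand[1]
    r$start <- min(kids$start); r$end <- max(kids$end)
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seqid, out$start,
                   match(out$type, c("gene", "mRNA", "exon", "CDS"))), ,
             drop = FALSE]
  new_gene_set(out)
}

#' Merge two candidate liftover sets
#'
#' Genes present in both sets with identical lifted features count as
#' `both`; genes that differ keep the primary set's version (still counted
#' `both`); genes present in only one set are taken from it.
#'
#' @param primary,secondary Lift results (lists from [lift_features()]).
#' @return List with `genes`, `status` and `provenance` (data.frame `gene`,
#'   `source`), plus `counts`.
#' @export
merge_liftover_sets <- function(primary, secondary) {
  gp <- primary$genes; gs <- secondary$genes
  ids_p <- unique(gp$gene); ids_s <- unique(gs$gene)
  sig <- function(df, g) {
    d <- df[df$gene == g & df$type %in% leaf_types, , drop = FALSE]
    d <- d[order(d$type, d$start), , drop = FALSE]
    paste(d$seqid, d$type, d$start, d$end, d$strand, collapse = ";")
  }
  rows <- list(); prov <- list()
  for (g in union(ids_p, ids_s)) {
    if (g %in% ids_p && g %in% ids_s) {
      src <- "both"
      rows[[length(rows) + 1L]] <- gp[gp$gene == g, , drop = FALSE]
    } else if (g %in% ids_p) {
      src <- "primary_only"
      rows[[length(rows) + 1L]] <- gp[gp$gene == g, , drop = FALSE]
    } else {
      src <- "secondary_only"
      rows[[length(rows) + 1L]] <- gs[gs$gene == g, , drop = FALSE]
    }
    prov[[length(prov) + 1L]] <- data.frame(gene = g, source = src,
                                            stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, prov)
  status <- merge_status(primary$status, secondary$status)
  list(genes = new_gene_set(do.call(rbind, rows)), status = status,
       provenance = prov,
       counts = table(prov$source))
}

merge_status <- function(sp, ss) {
  rank <- c(lifted_full = 3, partial = 2, failed = 1)
  all_g <- union(sp$gene, ss$gene)
  do.call(rbind, lapply(all_g, function(g) {
    a <- sp[sp$gene == g, , drop = FALSE]
    b <- ss[ss$gene == g, , drop = FALSE]
    best <- if (nrow(a) > 0 && (nrow(b) == 0 ||
                                rank[a$status] >= rank[b$status])) a else b
    best
  }))
}

#' Rescue unlifted features from neighbouring lifted features
#'
#' An unlifted exon/CDS of a partially lifted gene receives a candidate
#' target interval inferred from the offset of the nearest lifted feature
#' of the same gene; the candidate is accepted only when its target
#' sequence is byte-identical to the source sequence (reverse-complemented
#' for flipped regions).
#'
#' @param lifted A result list from [lift_features()] (fields `genes`,
#'   `status`, `unmapped`, `leaf_map`).
#' @param source_assembly,target_assembly `mw_assembly` objects.
#' @return The updated result list, with `rescued` (character vector of
#'   gene ids that gained features).
#' @export
rescue_features <- function(lifted, source_assembly, target_assembly) {
  un <- lifted$unmapped
  if (is.null(un) || nrow(un) == 0) {
    lifted$rescued <- character(0)
    return(lifted)
  }
  lm <- lifted$leaf_map
  rescued_genes <- character(0)
  added <- list()
  still <- logical(nrow(un))
  for (i in seq_len(nrow(un))) {
    lf <- un[i, ]
    fl <- lm[lm$gene == lf$gene & lm$src_seqid == lf$seqid, , drop = FALSE]
    still[i] <- TRUE
    if (nrow(fl) == 0) next
    d_left <- lf$start - fl$src_end
    d_right <- fl$src_start - lf$end
    cand <- fl[order(pmin(ifelse(d_left >= 0, d_left, Inf),
                          ifelse(d_right >= 0, d_right, Inf))), , drop = FALSE]
    f <- cand[1, ]
    if (!f$flipped) {
      off <- f$tgt_start - f$src_start
      t0 <- lf$start + off; t1 <- lf$end + off
    } else {
      t1 <- f$tgt_end - (lf$start - f$src_start)
      t0 <- f$tgt_end - (lf$end - f$src_start)
    }
    tseq <- target_assembly$seqs[[f$tgt_seqid]]
    if (is.null(tseq) || t0 < 0 || t1 > nchar(tseq) || t1 <= t0) next
    src_seq <- substring(source_assembly$seqs[[lf$seqid]], lf$start + 1L,
                         lf$end)
    cand_seq <- substring(tseq, t0 + 1L, t1)
    if (f$flipped) cand_seq <- revcomp(cand_seq)
    if (!identical(cand_seq, src_seq)) next
    new <- lf
    new$seqid <- f$tgt_seqid; new$start <- t0; new$end <- t1
    if (f$flipped) new$strand <- if (lf$strand == "+") "-" else "+"
    added[[length(added) + 1L]] <- new
    lifted$leaf_map <- rbind(lifted$leaf_map, data.frame(
      ID = lf$ID, gene = lf$gene, src_seqid = lf$seqid, src_start = lf$start,
      src_end = lf$end, tgt_seqid = new$seqid, tgt_start = t0, tgt_end = t1,
      flipped = f$flipped, stringsAsFactors = FALSE))
    rescued_genes <- c(rescued_genes, lf$gene)
    still[i] <- FALSE
  }
  if (length(added) > 0) {
    leaves <- rbind(lifted$genes[lifted$genes$type %in% leaf_types, ,
                                 drop = FALSE],
                    do.call(rbind, added))
    # rebuild hulls from the original template implied by status table
    template <- rbind(lifted$genes, do.call(rbind, added))
    lifted$genes <- rebuild_hulls(template, leaves)
    lifted$unmapped <- un[still, , drop = FALSE]
    st <- lifted$status
    for (g in unique(rescued_genes)) {
      st$n_mapped[st$gene == g] <- st$n_mapped[st$gene == g] +
        sum(rescued_genes == g)
      if (st$n_mapped[st$gene == g] >= st$n_leaves[st$gene == g])
        st$status[st$gene == g] <- "lifted_full"
      else st$status[st$gene == g] <- "partial"
    }
    lifted$status <- st
  }
  lifted$rescued <- unique(rescued_genes)
  lifted
}

stop_codons <- c("TAA", "TAG", "TGA")

oriented_feature_seq <- function(assembly, seqid, start, end, strand) {
  s <- substring(assembly$seqs[[seqid]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

spliced_cds_seq <- function(assembly, cds) {
  cds <- cds[order(cds$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(cds)), function(i)
    substring(assembly$seqs[[cds$seqid[i]]], cds$start[i] + 1L, cds$end[i]),
    ""), collapse = "")
  if (cds$strand[1] == "-") revcomp(s) else s
}

has_stop_free_frame <- function(seq) {
  n <- nchar(seq)
  for (f in 0:2) {
    starts <- seq.int(f + 1L, by = 3L, length.out = max((n - f) %/% 3L, 0L))
    if (length(starts) == 0) return(TRUE)
    codons <- substring(seq, starts, starts + 2L)
    if (!any(codons %in% stop_codons)) return(TRUE)
  }
  FALSE
}

#' Classify genes for pseudogene defects
#'
#' Per gene (first mRNA's CDS chain): `no_start` when the spliced CDS does
#' not begin with ATG; missing terminal stop is first given a rescue
#' attempt — when extending the terminal CDS by exactly 3 bases yields a
#' stop codon the CDS is corrected (`corrected_cds`) instead of flagged
#' `no_stop`; `internal_stop` when at least one CDS feature has no reading
#' frame free of stop codons (the annotated terminal stop is excluded from
#' the scan); `cds_len_mod3` when the spliced CDS length is not divisible
#' by 3.  `pseudo` is the disjunction of the four defect flags.  A CDS
#' extending beyond its scaffold marks the gene `failed`.
#'
#' @param genes An `mw_genes`.
#' @param assembly The `mw_assembly` the coordinates refer to.
#' @return List with `genes` (CDS corrections applied) and `flags`
#'   (data.frame `gene`, `no_start`, `no_stop`, `internal_stop`,
#'   `cds_len_mod3`, `corrected_cds`, `pseudo`, `failed`).
#' @export
classify_genes <- function(genes, assembly) {
  stopifnot(inherits(genes, "mw_genes"), inherits(assembly, "mw_assembly"))
  out <- genes
  flags <- list()
  for (g in gene_ids(genes)) {
    mrnas <- genes$ID[genes$type == "mRNA" & genes$gene == g]
    cds <- genes[genes$type == "CDS" & genes$gene == g &
                   (length(mrnas) == 0 | genes$Parent == sort(mrnas)[1]), ,
                 drop = FALSE]
    if (nrow(cds) == 0) {
      flags[[length(flags) + 1L]] <- data.frame(
        gene = g, no_start = FALSE, no_stop = FALSE, internal_stop = FALSE,
        cds_len_mod3 = FALSE, corrected_cds = FALSE, pseudo = FALSE,
        failed = FALSE, stringsAsFactors = FALSE)
      next
    }
    sl <- nchar(assembly$seqs[[cds$seqid[1]]])
    if (is.na(sl) || is.null(assembly$seqs[[cds$seqid[1]]]) ||
        any(cds$end > sl) || any(cds$start < 0)) {
      flags[[length(flags) + 1L]] <- data.frame(
        gene = g, no_start = NA, no_stop = NA, internal_stop = NA,
        cds_len_mod3 = NA, corrected_cds = FALSE, pseudo = NA, failed = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    strand <- cds$strand[1]
    spliced <- spliced_cds_seq(assembly, cds)
    n <- nchar(spliced)
    no_start <- substring(spliced, 1L, 3L) != "ATG"
    corrected <- FALSE
    no_stop <- FALSE
    last3 <- if (n >= 3) substring(spliced, n - 2L, n) else ""
    if (!(last3 %in% stop_codons)) {
      # try extending the terminal CDS by exactly 3 bases
      ti <- if (strand == "+") which.max(cds$end) else which.min(cds$start)
      ext_ok <- FALSE
      if (strand == "+" && cds$end[ti] + 3L <= sl) {
        codon <- substring(assembly$seqs[[cds$seqid[ti]]],
                           cds$end[ti] + 1L, cds$end[ti] + 3L)
        if (codon %in% stop_codons) {
          row_id <- which(out$ID == cds$ID[ti] & out$type == "CDS" &
                            out$start == cds$start[ti])
          out$end[row_id] <- out$end[row_id] + 3L
          cds$end[ti] <- cds$end[ti] + 3L
          ext_ok <- TRUE
        }
      } else if (strand == "-" && cds$start[ti] - 3L >= 0) {
        codon <- revcomp(substring(assembly$seqs[[cds$seqid[ti]]],
                                   cds$start[ti] - 2L, cds$start[ti]))
        if (codon %in% stop_codons) {
          row_id <- which(out$ID == cds$ID[ti] & out$type == "CDS" &
                            out$start == cds$start[ti])
          out$start[row_id] <- out$start[row_id] - 3L
          cds$start[ti] <- cds$start[ti] - 3L
          ext_ok <- TRUE
        }
      }
      if (ext_ok) {
        corrected <- TRUE
        spliced <- spliced_cds_seq(assembly, cds)
        n <- nchar(spliced)
      } else no_stop <- TRUE
    }
    # per-feature frame scan; the annotated terminal stop is excluded
    ti <- if (strand == "+") which.max(cds$end) else which.min(cds$start)
    internal <- FALSE
    for (ci in seq_len(nrow(cds))) {
      fs <- oriented_feature_seq(assembly, cds$seqid[ci], cds$start[ci],
                                 cds$end[ci], strand)
      if (ci == ti && !no_stop && nchar(fs) > 3)
        fs <- substring(fs, 1L, nchar(fs) - 3L)
      if (!has_stop_free_frame(fs)) {
        internal <- TRUE
        break
      }
    }
    mod3 <- (n %% 3L) != 0L
    flags[[length(flags) + 1L]] <- data.frame(
      gene = g, no_start = no_start, no_stop = no_stop,
      internal_stop = internal, cds_len_mod3 = mod3,
      corrected_cds = corrected,
      pseudo = no_start || no_stop || internal || mod3, failed = FALSE,
      stringsAsFactors = FALSE)
  }
  list(genes = out, flags = do.call(rbind, flags))
}

#' Remove duplicate and contained genes
#'
#' Genes identical to another gene (same scaffold, strand, start and end)
#' are collapsed to the lexicographically smallest id; genes whose interval
#' lies strictly within another gene's interval on the same scaffold are
#' removed.
#'
#' @param genes An `mw_genes`.
#' @return List with `genes`, `removed_identical`, `removed_contained`
#'   (character vectors of removed gene ids).
#' @export
dedupe_genes <- function(genes) {
  stopifnot(inherits(genes, "mw_genes"))
  gr <- genes[genes$type == "gene", , drop = FALSE]
  key <- paste(gr$seqid, gr$strand, gr$start, gr$end)
  removed_identical <- character(0)
  for (kk in unique(key[duplicated(key)])) {
    ids <- sort(gr$gene[key == kk])
    removed_identical <- c(removed_identical, ids[-1])
  }
  gr2 <- gr[!gr$gene %in% removed_identical, , drop = FALSE]
  removed_contained <- character(0)
  for (sc in unique(gr2$seqid)) {
    d <- gr2[gr2$seqid == sc, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      inside <- d$start <= d$start[i] & d$end >= d$end[i] &
        !(d$start == d$start[i] & d$end == d$end[i])
      if (any(inside)) removed_contained <- c(removed_contained, d$gene[i])
    }
  }
  removed_contained <- unique(removed_contained)
  drop <- c(removed_identical, removed_contained)
  list(genes = new_gene_set(genes[!genes$gene %in% drop, , drop = FALSE]),
       removed_identical = removed_identical,
       removed_contained = removed_contained)
}

# Parse "LG-1 anc1.anc2" / "SC-12 anc" style names to the compact type+number
# token used in gene names ("LG1", "SC12"); other names are sanitised.
scaffold_name_token <- function(nm) {
  m <- regmatches(nm, regexec("^(LG|CSC|SC)-(\\d+)", nm))[[1]]
  if (length(m) == 3) return(paste0(m[2], m[3]))
  gsub("[^A-Za-z0-9]", "", nm)
}

#' Rename genes by the versioned locus convention
#'
#' Per scaffold, genes are numbered from 1 starting at the 5' end of the
#' forward strand; the name is `Aa3` + scaffold type/number token + `G` +
#' number (e.g. `Aa3LG1G2`); transcript isoforms append `.1`, `.2`, ...
#' The previous gene id is kept in the `note` column.
#'
#' @param genes An `mw_genes`.
#' @param lg_of_scaffold Optional named vector mapping scaffold name to LG
#'   number, appended to the note.
#' @return List with `genes` (renamed) and `name_map` (old gene id -> new).
#' @export
rename_genes <- function(genes, lg_of_scaffold = NULL) {
  stopifnot(inherits(genes, "mw_genes"))
  gr <- genes[genes$type == "gene", , drop = FALSE]
  name_map <- character(0)
  notes <- character(0)
  for (sc in unique(gr$seqid)) {
    d <- gr[gr$seqid == sc, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    tok <- scaffold_name_token(sc)
    for (i in seq_len(nrow(d))) {
      newname <- sprintf("Aa3%sG%d", tok, i)
      name_map[[d$gene[i]]] <- newname
      note <- sprintf("prior_id=%s", d$gene[i])
      if (!is.null(lg_of_scaffold) && sc %in% names(lg_of_scaffold))
        note <- paste0(note, sprintf(";lg=%s", lg_of_scaffold[[sc]]))
      notes[[newname]] <- note
    }
  }
  if (anyDuplicated(unlist(name_map))) stopf("internal error: duplicate gene names")
  out <- genes
  out$note <- NA_character_
  new_id <- out$ID
  new_parent <- out$Parent
  for (g in names(name_map)) {
    sel <- out$gene == g
    gname <- name_map[[g]]
    # isoforms numbered within the gene
    mr <- which(sel & out$type == "mRNA")
    mr <- mr[order(out$ID[mr])]
    iso_of <- stats::setNames(sprintf("%s.%d", gname, seq_along(mr)),
                              out$ID[mr])
    for (i in which(sel)) {
      if (out$type[i] == "gene") {
        new_id[i] <- gname
        out$note[i] <- notes[[gname]]
      } else if (out$type[i] == "mRNA") {
        new_id[i] <- iso_of[[out$ID[i]]]
        new_parent[i] <- gname
      } else {
        new_parent[i] <- iso_of[[out$Parent[i]]]
        new_id[i] <- sprintf("%s.%s%d", iso_of[[out$Parent[i]]],
                             tolower(out$type[i]),
                             sum(out$type[seq_len(i)][sel[seq_len(i)]] ==
                                   out$type[i] &
                                   out$Parent[seq_len(i)][sel[seq_len(i)]] ==
                                   out$Parent[i]))
      }
    }
    out$gene[sel] <- gname
  }
  out$ID <- new_id
  out$Parent <- new_parent
  list(genes = new_gene_set(out), name_map = name_map)
}

#' Migration report
#'
#' Aggregates liftover, merge, rescue, classification and deduplication
#' counts and checks that the status categories partition the genes.
#'
#' @param status Status table (after rescue).
#' @param provenance Provenance table from [merge_liftover_sets()].
#' @param flags Flag table from [classify_genes()].
#' @param dedupe Result list from [dedupe_genes()].
#' @param rescued Character vector of rescued gene ids.
#' @return Named list of counts.
#' @export
liftover_report <- function(status, provenance = NULL, flags = NULL,
                            dedupe = NULL, rescued = character(0)) {
  n <- nrow(status)
  n_full <- sum(status$status == "lifted_full")
  n_partial <- sum(status$status == "partial")
  n_failed <- sum(status$status == "failed")
  if (n_full + n_partial + n_failed != n)
    stopf("liftover report inconsistent: %d + %d + %d != %d",
          n_full, n_partial, n_failed, n)
  out <- list(n_genes = n, lifted_full = n_full, partial = n_partial,
              failed = n_failed, rescued = length(unique(rescued)))
  if (!is.null(provenance)) {
    out$lifted_both <- sum(provenance$source == "both")
    out$lifted_primary_only <- sum(provenance$source == "primary_only")
    out$lifted_secondary_only <- sum(provenance$source == "secondary_only")
  }
  if (!is.null(flags)) {
    out$no_start <- sum(flags$no_start, na.rm = TRUE)
    out$no_stop <- sum(flags$no_stop, na.rm = TRUE)
    out$internal_stop <- sum(flags$internal_stop, na.rm = TRUE)
    out$cds_len_mod3 <- sum(flags$cds_len_mod3, na.rm = TRUE)
    out$corrected_cds <- sum(flags$corrected_cds, na.rm = TRUE)
    out$pseudo <- sum(flags$pseudo, na.rm = TRUE)
  }
  if (!is.null(dedupe)) {
    out$removed_identical <- length(dedupe$removed_identical)
    out$removed_contained <- length(dedupe$removed_contained)
  }
  out
}

#' Read gene models from GFF3
#' @param path GFF3 file.
#' @return An `mw_genes` (0-based half-open internal coordinates).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    Parent = vapply(as.list(gr$Parent), function(p)
      if (length(p) == 0) NA_character_ else p[[1]], ""),
    stringsAsFactors = FALSE)
  # propagate gene ownership down the hierarchy
  df$gene <- NA_character_
  df$gene[df$type == "gene"] <- df$ID[df$type == "gene"]
  for (pass in 1:3) {
    need <- which(is.na(df$gene) & !is.na(df$Parent))
    df$gene[need] <- df$gene[match(df$Parent[need], df$ID)]
  }
  if (!is.null(gr$note)) df$note <- as.character(gr$note)
  new_gene_set(df)
}

#' Write gene models as GFF3
#'
#' Coordinates are emitted 1-based inclusive; pseudogene flags (from a
#' classification `flags` table) are written as `pseudo=true`.
#'
#' @param genes An `mw_genes`.
#' @param path Output path.
#' @param flags Optional flag table from [classify_genes()].
#' @param status Optional status table; partial genes get `partial=true`.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path, flags = NULL, status = NULL) {
  stopifnot(inherits(genes, "mw_genes"))
  ord <- order(genes$seqid, genes$start,
               match(genes$type, c("gene", "mRNA", "exon", "CDS")))
  g <- as.data.frame(genes)[ord, , drop = FALSE]
  pseudo_genes <- if (!is.null(flags))
    flags$gene[which(flags$pseudo %in% TRUE)] else character(0)
  partial_genes <- if (!is.null(status))
    status$gene[status$status == "partial"] else character(0)
  rows <- vapply(seq_len(nrow(g)), function(i) {
    a <- sprintf("ID=%s", g$ID[i])
    if (!is.na(g$Parent[i])) a <- paste0(a, ";Parent=", g$Parent[i])
    if (!is.null(g$note) && !is.na(g$note[i]))
      a <- paste0(a, ";note=", g$note[i])
    if (g$type[i] == "gene") {
      if (g$gene[i] %in% pseudo_genes) a <- paste0(a, ";pseudo=true")
      if (g$gene[i] %in% partial_genes) a <- paste0(a, ";partial=true")
    }
    sprintf("%s\tmapweave\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            g$seqid[i], g$type[i], g$start[i] + 1L, g$end[i], g$strand[i],
            if (g$type[i] == "CDS") "0" else ".", a)
  }, "")
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
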