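test_that("lifting through an identity chain is the identity", {
  t <- simulate_reference(1, 3e4, gc = 0.4, seed = 83)
  fr <- fragment_assembly(t, 12000, gap_rate = 0.3, seed = 83)
  genes <- simulate_gene_models(fr$assembly, 12, seed = 83)
  lf <- lift_features(genes, identity_chain(fr$assembly))
  expect_true(all(lf$status$status == "lifted_full"))
  got <- lf$genes[order(lf$genes$ID), ]
  want <- as.data.frame(genes)[order(genes$ID), ]
  expect_identical(got$start, want$start)
  expect_identical(got$end, want$end)
  expect_identical(got$seqid, want$seqid)
  expect_identical(got$strand, want$strand)
})

test_that("offset and flipped blocks lift genes with intact spliced CDS", {
  withr::with_seed(29, s1 <- rand_seq(4000))
  asm <- new_assembly(c(s1 = s1))
  target <- new_assembly(c(pm = paste0(strrep("N", 100), rc(s1))))
  chain <- new_lift_chain(data.frame(
    src = "s1", src_start = 0L, src_end = 4000L,
    tgt = "pm", tgt_start = 100L, tgt_end = 4100L, strand = "-"))
  genes <- single_gene("s1", c(500L, 900L), c(800L, 1200L), strand = "+")
  lf <- lift_features(genes, chain)
  expect_identical(lf$status$status, "lifted_full")
  cds_new <- lf$genes[lf$genes$type == "CDS", ]
  expect_true(all(cds_new$strand == "-"))
  spliced_src <- paste0(substring(s1, 501, 800), substring(s1, 901, 1200))
  cds_new <- cds_new[order(cds_new$start), ]
  spliced_tgt <- rc(paste(vapply(seq_len(nrow(cds_new)), function(i)
    substring(target$seqs[["pm"]], cds_new$start[i] + 1, cds_new$end[i]),
    ""), collapse = ""))
  expect_identical(spliced_tgt, spliced_src)
  # translation is preserved (frame and exon order survived the flip)
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X"))
  expect_identical(tr(spliced_tgt), tr(spliced_src))
})

test_that("features crossing an unmapped region make the gene partial", {
  # block covers only [0, 1000): the second exon is lost
  chain <- new_lift_chain(data.frame(
    src = "s1", src_start = 0L, src_end = 1000L,
    tgt = "t", tgt_start = 0L, tgt_end = 1000L, strand = "+"))
  genes <- single_gene("s1", c(100L, 1500L), c(400L, 1800L))
  lf <- lift_features(genes, chain)
  expect_identical(lf$status$status, "partial")
  expect_equal(nrow(lf$unmapped), 1)
  # no feature lifts at all -> failed
  chain2 <- new_lift_chain(data.frame(
    src = "zz", src_start = 0L, src_end = 10L, tgt = "t", tgt_start = 0L,
    tgt_end = 10L, strand = "+"))
  expect_identical(lift_features(genes, chain2)$status$status, "failed")
})

test_that("merging liftover sets prefers the primary on disagreement", {
  chain_a <- new_lift_chain(data.frame(
    src = "s1", src_start = 0L, src_end = 2000L, tgt = "t", tgt_start = 0L,
    tgt_end = 2000L, strand = "+"))
  chain_b <- new_lift_chain(data.frame(
    src = "s1", src_start = 0L, src_end = 2000L, tgt = "t", tgt_start = 50L,
    tgt_end = 2050L, strand = "+"))
  g1 <- single_gene("s1", 100L, 400L, gid = "gA")
  g2 <- single_gene("s1", 600L, 900L, gid = "gB")
  g3 <- single_gene("s1", 1200L, 1500L, gid = "gC")
  both <- new_gene_set(rbind(g1, g2, g3))
  prim <- lift_features(both, chain_a)
  sec_full <- lift_features(both, chain_b)
  # secondary lacks gA, has a different gB, and is the only source of gC
  sec <- sec_full
  sec$genes <- new_gene_set(sec$genes[sec$genes$gene != "gA", ])
  sec$status <- sec$status[sec$status$gene != "gA", ]
  prim$genes <- new_gene_set(prim$genes[prim$genes$gene != "gC", ])
  prim$status <- prim$status[prim$status$gene != "gC", ]
  mg <- merge_liftover_sets(prim, sec)
  expect_identical(mg$provenance$source[mg$provenance$gene == "gA"],
                   "primary_only")
  expect_identical(mg$provenance$source[mg$provenance$gene == "gB"], "both")
  expect_identical(mg$provenance$source[mg$provenance$gene == "gC"],
                   "secondary_only")
  # gB kept the primary's coordinates
  expect_equal(mg$genes$start[mg$genes$gene == "gB" & mg$genes$type == "CDS"],
               600)
  # gC kept the secondary's coordinates
  expect_equal(mg$genes$start[mg$genes$gene == "gC" & mg$genes$type == "CDS"],
               1250)
})

test_that("rescue accepts uniform shifts and rejects changed bytes", {
  withr::with_seed(31, {
    s1 <- rand_seq(3000); ins <- rand_seq(50)
  })
  # the target inserts 50 bp inside an intron; exon2's block is missing from
  # the chain, but its bytes are present, shifted by the insertion
  tseq <- paste0(substring(s1, 1, 1000), ins, substring(s1, 1001, 3000))
  src <- new_assembly(c(s1 = s1))
  tgt <- new_assembly(c(t1 = tseq))
  # exon1 sits in the +50-shifted block; exon2's block is missing entirely
  chain <- new_lift_chain(data.frame(
    src = "s1", src_start = c(0L, 1000L), src_end = c(1000L, 1400L),
    tgt = "t1", tgt_start = c(0L, 1050L), tgt_end = c(1000L, 1450L),
    strand = "+"))
  genes <- single_gene("s1", c(1100L, 1600L), c(1250L, 1900L))
  lf <- lift_features(genes, chain)
  expect_identical(lf$status$status, "partial")
  rs <- rescue_features(lf, src, tgt)
  expect_identical(rs$rescued, "g1")
  expect_identical(rs$status$status, "lifted_full")
  got <- rs$genes[rs$genes$type == "CDS" & rs$genes$start > 1500, ]
  expect_identical(substring(tseq, got$start + 1, got$end),
                   substring(s1, 1601, 1900))

  # bytes changed at the candidate location -> rescue refused
  tbad <- paste0(substring(tseq, 1, 1700), rand_seq(100),
                 substring(tseq, 1801, nchar(tseq)))
  rs2 <- rescue_features(lf, src, new_assembly(c(t1 = tbad)))
  expect_length(rs2$rescued, 0)
  expect_identical(rs2$status$status, "partial")
})

test_that("classification flags start/stop/frame defects with CDS correction", {
  seq <- paste0(strrep("T", 50), "ATGGCTGCAGGATAA", strrep("T", 50))
  asm <- new_assembly(c(s1 = seq))
  ok <- classify_genes(single_gene("s1", 50L, 65L), asm)$flags
  expect_false(any(unlist(ok[, c("no_start", "no_stop", "internal_stop",
                                 "cds_len_mod3", "pseudo")])))

  # stop lies exactly 3 bases past the annotated CDS end -> corrected
  cor <- classify_genes(single_gene("s1", 50L, 62L), asm)
  expect_true(cor$flags$corrected_cds)
  expect_false(cor$flags$no_stop)
  expect_false(cor$flags$pseudo)
  expect_equal(cor$genes$end[cor$genes$type == "CDS"], 65)

  # no ATG and not a multiple of three
  bad <- classify_genes(single_gene("s1", 51L, 64L), asm)$flags
  expect_true(bad$no_start)
  expect_true(bad$cds_len_mod3)
  expect_true(bad$pseudo)

  # a CDS feature with a stop in every reading frame (TAA/TGA/TAG at
  # offsets 0/1/2 of "TAAATGAATAGA")
  allstop <- paste0(strrep("A", 30), "TAAATGAATAGA", "ATGGCTTAA",
                    strrep("A", 30))
  asm2 <- new_assembly(c(s2 = allstop))
  f2 <- classify_genes(single_gene("s2", c(30L, 42L), c(42L, 51L)),
                       asm2)$flags
  expect_true(f2$internal_stop)
  expect_true(f2$pseudo)

  # CDS beyond the scaffold end -> failed
  f3 <- classify_genes(single_gene("s1", 100L, 1000L), asm)$flags
  expect_true(f3$failed)

  # reverse strand: a clean ORF on the minus strand
  mseq <- paste0(strrep("G", 40), rc("ATGGCTGCAGGATAA"), strrep("G", 40))
  f4 <- classify_genes(single_gene("s3", 40L, 55L, strand = "-"),
                       new_assembly(c(s3 = mseq)))$flags
  expect_false(f4$pseudo)
})

test_that("classification agrees with a translation-based oracle on random fixtures", {
  withr::with_seed(91, {
    n_mismatch <- 0L
    flags <- c("no_start", "no_stop", "internal_stop", "cds_len_mod3",
               "pseudo")
    for (rep in 1:60) {
      L <- 600L
      s <- rand_seq(L)
      asm <- new_assembly(c(sc = s))
      ne <- sample(1:3, 1)
      starts <- sort(sample(seq(10L, L - 120L, by = 3L), ne))
      lens <- sample(c(30L, 45L, 60L, 33L, 47L), ne, replace = TRUE)
      ends <- pmin(starts + lens, L - 5L)
      keep <- c(TRUE, if (ne > 1) starts[-1] > ends[-ne] else NULL)
      starts <- starts[keep]; ends <- ends[keep]
      strand <- sample(c("+", "-"), 1)
      g <- single_gene("sc", starts, ends, strand = strand)
      got <- classify_genes(g, asm)
      cds_after <- got$genes[got$genes$type == "CDS", ]
      want <- classify_brute(asm, cds_after)
      if (!identical(unname(unlist(got$flags[flags])),
                     unname(unlist(want[flags]))))
        n_mismatch <- n_mismatch + 1L
    }
    expect_equal(n_mismatch, 0L)
  })
})

test_that("deduplication removes identical and strictly contained genes", {
  mk <- function(gid, start, end, strand = "+")
    single_gene("s1", start, end, strand = strand, gid = gid)
  genes <- new_gene_set(rbind(
    mk("gB", 100L, 500L), mk("gA", 100L, 500L),      # identical pair
    mk("gC", 150L, 300L),                            # contained in gA/gB
    mk("gD", 400L, 900L),                            # partial overlap: kept
    mk("gE", 1000L, 1200L)))
  dd <- dedupe_genes(genes)
  expect_identical(dd$removed_identical, "gB")       # smallest id kept
  expect_identical(dd$removed_contained, "gC")
  expect_setequal(unique(dd$genes$gene), c("gA", "gD", "gE"))
})

test_that("gene renaming follows the versioned locus convention", {
  g1 <- single_gene("LG-1 Scaffold_0001.Scaffold_0002", 100L, 400L,
                    gid = "old1")
  g2 <- single_gene("LG-1 Scaffold_0001.Scaffold_0002", 600L, 900L,
                    gid = "old2")
  g3 <- single_gene("SC-2601 Scaffold_0009", 50L, 350L, gid = "old3")
  genes <- new_gene_set(rbind(g1, g2, g3))
  # add a second isoform to old2
  iso <- data.frame(seqid = "LG-1 Scaffold_0001.Scaffold_0002", type = "mRNA",
                    start = 600L, end = 900L, strand = "+", ID = "old2.m2",
                    Parent = "old2", gene = "old2", stringsAsFactors = FALSE)
  genes <- new_gene_set(rbind(genes, iso))
  rn <- rename_genes(genes, lg_of_scaffold = c(
    "LG-1 Scaffold_0001.Scaffold_0002" = 1))
  expect_identical(unname(rn$name_map[["old2"]]), "Aa3LG1G2")
  expect_identical(unname(rn$name_map[["old3"]]), "Aa3SC2601G1")
  mr <- rn$genes[rn$genes$gene == "Aa3LG1G2" & rn$genes$type == "mRNA", ]
  expect_setequal(mr$ID, c("Aa3LG1G2.1", "Aa3LG1G2.2"))
  note <- rn$genes$note[rn$genes$ID == "Aa3LG1G2"]
  expect_match(note, "prior_id=old2")
  expect_match(note, "lg=1")
})

test_that("the migration report partitions genes and checks its totals", {
  status <- data.frame(
    gene = sprintf("g%d", 1:10),
    status = c(rep("lifted_full", 7), rep("partial", 2), "failed"),
    n_leaves = 2L, n_mapped = 2L, stringsAsFactors = FALSE)
  rep <- liftover_report(status)
  expect_equal(rep$lifted_full, 7)
  expect_equal(rep$partial, 2)
  expect_equal(rep$failed, 1)
  bad <- status
  bad$status[1] <- "nonsense"
  expect_error(liftover_report(bad), "inconsistent")
})

test_that("GFF3 output round-trips through the Bioconductor importer", {
  t <- simulate_reference(1, 2e4, gc = 0.4, seed = 97)
  fr <- fragment_assembly(t, 15000, gap_rate = 0, seed = 97)
  genes <- simulate_gene_models(fr$assembly, 8, seed = 97)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, path)
  back <- read_gff3(path)
  expect_equal(nrow(back), nrow(genes))
  ga <- as.data.frame(genes)[order(genes$ID, genes$start), ]
  gb <- as.data.frame(back)[order(back$ID, back$start), ]
  expect_identical(gb$start, ga$start)
  expect_identical(gb$end, ga$end)
  expect_identical(gb$gene, ga$gene)
})
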