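test_that("reference simulation is deterministic and respects its GC target", {
  a <- simulate_reference(1, 1000, gc = 0.40, seed = 7)
  b <- simulate_reference(1, 1000, gc = 0.40, seed = 7)
  expect_identical(a$chromosomes, b$chromosomes)
  expect_equal(nchar(a$chromosomes[[1]]), 1000)

  t <- simulate_reference(2, c(1e5, 5e4), gc = 0.50, seed = 3)
  expect_equal(length(t$chromosomes), 2)
  expect_equal(unname(nchar(t$chromosomes)), c(1e5, 5e4))
  n <- 1.5e5
  gc_obs <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(t$chromosomes), "GC"))
  expect_lt(abs(gc_obs - 0.5 * n), 3 * sqrt(n * 0.25))

  expect_error(simulate_reference(1, -5, seed = 1), "positive")
})

test_that("parental SNP simulation matches its binomial law and allele rules", {
  t <- simulate_reference(1, 2e5, gc = 0.4, seed = 11)
  expect_equal(nrow(simulate_parents(t, 0, seed = 1)$parental_snps), 0)

  t2 <- simulate_parents(t, 1e-3, seed = 11)
  s <- t2$parental_snps
  expect_lt(abs(nrow(s) - 200), 3 * sqrt(2e5 * 1e-3 * (1 - 1e-3)))
  expect_true(all(s$allele_A %in% c("A", "C", "G", "T")))
  expect_true(all(s$allele_B %in% c("A", "C", "G", "T")))
  expect_true(all(s$allele_A != s$allele_B))
  expect_false(anyDuplicated(paste(s$chrom, s$pos)) > 0)
  # allele_A is the reference base
  ref <- substring(t$chromosomes[[1]], s$pos + 1, s$pos + 1)
  expect_identical(unname(ref), s$allele_A)
})

test_that("RIL genotypes are consistent with the simulated breakpoints", {
  t <- simulate_reference(2, 5e4, gc = 0.4, seed = 13)
  t <- simulate_parents(t, 1e-3, seed = 13)
  ril <- simulate_ril_population(t, 12, 7, missing_rate = 0, error_rate = 0,
                                 seed = 13)
  g <- ril$genotypes
  tr <- ril$truth
  # brute-force interval lookup against the stored per-line haplotypes
  allele_at <- function(h, pos) h$alleles[findInterval(pos, h$breaks) + 1]
  for (li in seq_along(tr$ril)) {
    for (i in seq_len(nrow(g$markers))) {
      cn <- g$markers$scaffold[i]   # markers anchored to chromosomes here
      pos <- g$markers$position[i]
      h <- tr$ril[[li]][[cn]]
      a1 <- allele_at(h$h1, pos); a2 <- allele_at(h$h2, pos)
      want <- if (a1 == a2) (if (a1 == 1) "A" else "B") else "H"
      expect_identical(unname(g$calls[i, li]), want)
    }
  }
})

test_that("residual heterozygosity at F8 matches single-seed descent", {
  t <- simulate_reference(11, 3e4, gc = 0.4, seed = 17)
  t <- simulate_parents(t, 2e-4, seed = 17)
  ril <- simulate_ril_population(t, 216, 7, missing_rate = 0, error_rate = 0,
                                 seed = 17)
  g <- ril$genotypes
  # one marker per chromosome -> independent loci across lines
  first <- !duplicated(g$markers$scaffold)
  calls <- g$calls[first, , drop = FALSE]
  p <- 0.5^7
  n <- length(calls)
  expect_lt(abs(mean(calls == "H") - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("RIL recombinant fraction follows the Haldane-Waddington relation", {
  # two markers 10 cM apart on a 1-Morgan chromosome
  L <- 1e5
  t <- simulate_reference(1, L, gc = 0.4, seed = 19)
  t$parental_snps <- data.frame(chrom = "chr01", pos = c(1000L, 11000L),
                                allele_A = c("A", "A"),
                                allele_B = c("C", "C"),
                                stringsAsFactors = FALSE)
  ril <- simulate_ril_population(t, 400, 7, missing_rate = 0, error_rate = 0,
                                 morgans_per_chromosome = L / 1e4 * 0.1,
                                 seed = 19)
  calls <- ril$genotypes$calls
  inf <- calls[1, ] %in% c("A", "B") & calls[2, ] %in% c("A", "B")
  R_obs <- mean(calls[1, inf] != calls[2, inf])
  r <- 0.5 * (1 - exp(-2 * 0.1))        # Haldane at 10 cM
  R_exp <- 2 * r / (1 + 2 * r)          # selfing-RIL inflation
  expect_lt(abs(R_obs - R_exp), 3 * sqrt(R_exp * (1 - R_exp) / sum(inf)))
})

test_that("fragmentation is lossless and honours the zero-gap case", {
  t <- simulate_reference(2, c(6e4, 4e4), gc = 0.4, seed = 23)
  t <- simulate_parents(t, 5e-4, seed = 23)
  fr0 <- fragment_assembly(t, 12000, gap_rate = 0, seed = 23)
  expect_false(any(grepl("N", fr0$assembly$seqs, fixed = TRUE)))

  fr <- fragment_assembly(t, 12000, gap_rate = 0.7, seed = 23)
  expect_gt(nrow(fr$assembly$gaps), 0)
  expect_identical(reassemble_truth(fr$assembly, fr$truth),
                   fr$truth$chromosomes)
  # placements tile each chromosome without overlap
  for (cn in names(t$chromosomes)) {
    p <- fr$truth$scaffold_placements
    p <- p[p$chrom == cn, ]
    p <- p[order(p$start), ]
    expect_equal(p$start[1], 0)
    expect_equal(p$end[nrow(p)], nchar(t$chromosomes[[cn]]))
    if (nrow(p) > 1) expect_equal(p$start[-1], p$end[-nrow(p)])
  }
})

test_that("scaffold count is near the Poisson-cut expectation", {
  t <- simulate_reference(1, 4.4e5, gc = 0.4, seed = 29)
  fr <- fragment_assembly(t, 10000, gap_rate = 0, seed = 29)
  expect_lt(abs(length(fr$assembly) - 44), 3 * sqrt(44) + 5)
})

test_that("long reads are exact substrings at zero error and hit the coverage target", {
  t <- simulate_reference(2, 4e4, gc = 0.4, seed = 31)
  expect_length(simulate_long_reads(t, 0, seed = 1)$seqs, 0)

  reads <- simulate_long_reads(t, 200, length_law = c(3000, 500, 8000),
                               error_rate = 0, seed = 31)
  for (i in seq_len(20)) {
    o <- reads$origin[i, ]
    truth_seq <- substring(t$chromosomes[[o$chrom]], o$start + 1, o$end)
    if (o$strand == "-") truth_seq <- rc(truth_seq)
    expect_identical(unname(reads$seqs[[i]]), truth_seq)
  }
  big <- simulate_long_reads(t, 5000, length_law = c(3000, 500, 8000),
                             error_rate = 0, seed = 32)
  mean_len <- mean(nchar(big$seqs))
  expect_lt(abs(mean_len / 3000 - 1), 0.1)
})

test_that("contamination fixtures are flagged by the screen and fragment counts add up", {
  t <- simulate_reference(1, 5e4, gc = 0.4, seed = 37)
  fr <- fragment_assembly(t, 15000, gap_rate = 0, seed = 37)

  c0 <- simulate_contamination(fr$assembly, 0, seed = 37)
  expect_length(screen_contamination(c0$assembly, c0$hits), 0)

  c3 <- simulate_contamination(fr$assembly, 3, seed = 37)
  flagged <- screen_contamination(c3$assembly, c3$hits)
  expect_setequal(flagged, c3$contaminants)
  lens <- nchar(c3$assembly$seqs)
  expect_equal(nrow(c3$hits), sum(ceiling(lens / 1000)))
  expect_equal(sum(c3$hits$frag_len), sum(lens))
})

test_that("population simulation with degradation is byte-deterministic", {
  t <- simulate_reference(1, 4e4, gc = 0.4, seed = 41)
  t <- simulate_parents(t, 1e-3, seed = 41)
  full <- simulate_ril_population(t, 20, 7, missing_rate = 0.2,
                                  error_rate = 0.05, seed = 41)$genotypes
  again <- simulate_ril_population(t, 20, 7, missing_rate = 0.2,
                                   error_rate = 0.05, seed = 41)$genotypes
  expect_identical(full$calls, again$calls)
  expect_gt(mean(is.na(full$calls)), 0.1)
})
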