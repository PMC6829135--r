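test_that("error-free reads anchor uniquely with correct strand; repeats stay unanchored", {
  withr::with_seed(33, {
    s1 <- rand_seq(6000); s2 <- rand_seq(6000)
  })
  asm <- new_assembly(c(s1 = s1, s2 = s2))
  reads <- reads_from_seqs(c(
    fwd = substring(s1, 1001, 3000),
    rev = rc(substring(s2, 2001, 4000)),
    alien = rand_seq(1500)))
  an <- anchor_reads(reads, asm, k = 17, stride = 1)
  a <- an$anchors
  expect_identical(a$scaffold[a$read == "fwd"], "s1")
  expect_identical(a$strand[a$read == "fwd"], "+")
  expect_identical(a$scaffold[a$read == "rev"], "s2")
  expect_identical(a$strand[a$read == "rev"], "-")
  expect_false("alien" %in% a$read)
  expect_equal(an$report$n_mapped, 2)
  expect_equal(an$report$n_unmapped, 1)

  # a read matching two identical scaffolds equally ties -> unanchored
  dup <- new_assembly(c(d1 = s1, d2 = s1))
  rd <- reads_from_seqs(c(amb = substring(s1, 1001, 3000)))
  an2 <- anchor_reads(rd, dup, k = 17, stride = 1)
  expect_equal(an2$report$n_mapped, 0)
})

test_that("spanning reads close gaps byte-exactly; one-sided reads reduce them", {
  withr::with_seed(35, {
    left <- rand_seq(3000); mid <- rand_seq(20); right <- rand_seq(3000)
  })
  sc <- paste0(left, strrep("N", 20), right)
  asm <- new_assembly(c(sc = sc))
  truth_sc <- paste0(left, mid, right)
  spans <- reads_from_seqs(c(
    r1 = substring(truth_sc, 2001, 4500),
    r2 = substring(truth_sc, 1501, 4000),
    r3 = rc(substring(truth_sc, 2501, 5000))))
  an <- anchor_reads(spans, asm, k = 17, stride = 1)
  fg <- fill_gaps(asm, an, spans, min_gap = 10, min_support = 3)
  ev <- fg$events
  expect_identical(ev$kind, "gap_closed")
  expect_identical(ev$inserted, mid)
  expect_equal(ev$support, 3)
  expect_identical(fg$assembly$seqs[["sc"]], truth_sc)
  expect_equal(nrow(fg$gaps), 0)

  # a 100-N gap reached only from the left stays open with >= 1 N
  sc2 <- paste0(left, strrep("N", 100), right)
  asm2 <- new_assembly(c(sc = sc2))
  lread <- reads_from_seqs(c(r1 = substring(paste0(left, mid), 2001, 3005)))
  an2 <- anchor_reads(lread, asm2, k = 17, stride = 1)
  fg2 <- fill_gaps(asm2, an2, lread, min_gap = 10, min_support = 1)
  expect_identical(fg2$events$kind, "gap_reduced")
  g2 <- fg2$gaps
  expect_equal(nrow(g2), 1)
  expect_gte(g2$end - g2$start, 1)
  expect_lt(g2$end - g2$start, 100)
  # the filled-in prefix is the truth bytes
  expect_identical(substring(fg2$assembly$seqs[["sc"]], 3001, 3005),
                   substring(mid, 1, 5))
})

test_that("gap count never increases through filling", {
  t <- simulate_reference(1, 8e4, gc = 0.4, seed = 73)
  fr <- fragment_assembly(t, 15000, gap_rate = 0.8, seed = 73)
  reads <- simulate_long_reads(fr$truth, 300, length_law = c(3000, 800, 8000),
                               error_rate = 0, seed = 73)
  an <- anchor_reads(reads, fr$assembly, k = 17, stride = 3)
  fg <- fill_gaps(fr$assembly, an, reads)
  expect_lte(nrow(fg$gaps), nrow(fr$assembly$gaps))
})

test_that("reads spanning scaffold junctions create connection events", {
  withr::with_seed(37, {
    A <- rand_seq(4000); B <- rand_seq(4000)
  })
  chr <- paste0(A, B)
  asm <- new_assembly(c(A = A, B = B))
  reads <- reads_from_seqs(c(j1 = substring(chr, 3001, 5000),
                             j2 = rc(substring(chr, 2501, 5500)),
                             j3 = substring(chr, 3501, 5800)))
  an <- anchor_reads(reads, asm, k = 17, stride = 1)
  fg <- fill_gaps(asm, an, reads)
  conn <- fg$events[fg$events$kind == "connection", ]
  expect_equal(nrow(conn), 1)
  expect_equal(conn$support, 3)
  expect_length(fg$assembly$seqs, 1)
  expect_identical(unname(fg$assembly$seqs[[1]]), chr)

  # conflicting evidence for one end leaves it unjoined
  withr::with_seed(38, C <- rand_seq(4000))
  asm3 <- new_assembly(c(A = A, B = B, C = C))
  confl <- reads_from_seqs(c(
    ab = substring(paste0(A, B), 3001, 5000),
    ac = substring(paste0(A, C), 3001, 5000)))
  an3 <- anchor_reads(confl, asm3, k = 17, stride = 1)
  fg3 <- fill_gaps(asm3, an3, confl)
  expect_length(fg3$assembly$seqs, 3)
  expect_gt(length(fg3$conflicts), 0)
})

test_that("blocked-connection detection distinguishes interior, free and identical joins", {
  comp <- data.frame(object = c("pm", "pm", "pm"), part = 1:3,
                     component = c("X", "Y2", "Z"), strand = "+",
                     obj_start = c(0L, 1100L, 2200L),
                     obj_end = c(1000L, 2100L, 3200L),
                     stringsAsFactors = FALSE)
  seqs <- c(pm = paste0(strrep("A", 1000), strrep("N", 100),
                        strrep("C", 1000), strrep("N", 100),
                        strrep("G", 1000)),
            W = strrep("T", 500), V = strrep("A", 400))
  integ <- new_assembly(seqs, origins = list(pm = c("X", "Y2", "Z"), W = "W",
                                             V = "V"),
                        gaps = data.frame(scaffold = "pm",
                                          start = c(1000L, 2100L),
                                          end = c(1100L, 2200L),
                                          provenance = "map_join",
                                          nominal_len = 100L),
                        components = rbind(comp, data.frame(
                          object = c("W", "V"), part = 1L,
                          component = c("W", "V"), strand = "+",
                          obj_start = 0L, obj_end = c(500L, 400L))))
  ev <- function(a, sa, b, sb) fill_event_row(NA, "connection", ea = a,
                                              eas = sa, eb = b, ebs = sb)
  # X's right end is interior (joined to Y2): X-W is blocked at junction X|Y2
  det <- detect_blocked_connections(ev("W", "L", "X", "R"), integ)
  expect_equal(nrow(det$blocked), 1)
  expect_equal(det$junctions$gap_start, 1000)
  # two free ends: not blocked
  det2 <- detect_blocked_connections(ev("V", "R", "W", "L"), integ)
  expect_equal(nrow(det2$blocked), 0)
  # the base connection that the map already made: not blocked
  det3 <- detect_blocked_connections(ev("X", "R", "Y2", "L"), integ)
  expect_equal(nrow(det3$blocked), 0)
})

test_that("reconcile reproduces the X-Y-Z truth through split and re-fill", {
  sc <- xyz_scenario(piece = 6000, seed = 5)
  reads <- simulate_long_reads(sc$truth, 80, length_law = c(3500, 1500, 6000),
                               error_rate = 0, seed = 6)
  rec <- reconcile(sc$base, sc$integrated, reads, k = 17, stride = 3)
  expect_length(rec$assembly$seqs, 1)
  expect_identical(unname(rec$assembly$seqs[[1]]), sc$chr)
  expect_gt(nrow(rec$report$blocked), 0)
  expect_equal(nrow(rec$report$junctions), 1)
})

test_that("with nothing blocked, reconcile equals filling the integrated assembly", {
  withr::with_seed(41, {
    A <- rand_seq(5000); B <- rand_seq(5000); mid <- rand_seq(30)
  })
  # one scaffold with an internal gap; map did not touch anything
  sc_seq <- paste0(A, strrep("N", 30), B)
  truth_seq <- paste0(A, mid, B)
  base <- new_assembly(c(s = sc_seq))
  integ <- new_assembly(c(s = sc_seq))
  reads <- reads_from_seqs(c(r1 = substring(truth_seq, 4001, 6500),
                             r2 = substring(truth_seq, 3501, 6200)))
  rec <- reconcile(base, integ, reads, k = 17, stride = 1)
  an <- anchor_reads(reads, integ, k = 17, stride = 1)
  direct <- fill_gaps(integ, an, reads)
  expect_identical(rec$assembly$seqs, direct$assembly$seqs)
  expect_identical(unname(rec$assembly$seqs[["s"]]), truth_seq)
})

test_that("partially filled map-join gaps are restored to exactly 100 N", {
  withr::with_seed(43, {
    X <- rand_seq(5000); gapseq <- rand_seq(4000); Z <- rand_seq(5000)
  })
  # the map joined X and Z although 4 kbp of truth lies between them;
  # 2.5-kbp reads can only nibble at the join from each side
  truth_seq <- paste0(X, gapseq, Z)
  base <- new_assembly(c(X = X, Z = Z))
  integ <- new_assembly(
    c(XZ = paste0(X, strrep("N", 100), Z)),
    origins = list(XZ = c("X", "Z")),
    gaps = data.frame(scaffold = "XZ", start = 5000L, end = 5100L,
                      provenance = "map_join", nominal_len = 100L),
    components = data.frame(object = "XZ", part = 1:2,
                            component = c("X", "Z"), strand = "+",
                            obj_start = c(0L, 5100L), obj_end = c(5000L, 10100L)))
  reads <- reads_from_seqs(c(l = substring(truth_seq, 3501, 6000),
                             r = substring(truth_seq, 8001, 10500)))
  rec <- reconcile(base, integ, reads, k = 17, stride = 1)
  expect_equal(rec$report$n_restored, 1)
  g <- rec$assembly$gaps
  mj <- g[g$provenance == "map_join", ]
  expect_equal(nrow(mj), 1)
  expect_equal(mj$end - mj$start, 100)
  # the N run in the sequence itself is exactly 100
  runs <- find_gaps(rec$assembly$seqs[["XZ"]], min_gap = 1)
  expect_equal(runs$end - runs$start, 100)
  # and the partial fill kept the true flanking bytes (99 = gap length - 1)
  expect_identical(substring(rec$assembly$seqs[["XZ"]], 5001, 5099),
                   substring(gapseq, 1, 99))
})

test_that("every non-N input segment survives filling and reconciliation", {
  t <- simulate_reference(1, 6e4, gc = 0.4, seed = 79)
  fr <- fragment_assembly(t, 12000, gap_rate = 0.6, seed = 79)
  reads <- simulate_long_reads(fr$truth, 250, length_law = c(3000, 800, 8000),
                               error_rate = 0, seed = 79)
  an <- anchor_reads(reads, fr$assembly, k = 17, stride = 3)
  fg <- fill_gaps(fr$assembly, an, reads)
  out <- c(fg$assembly$seqs, vapply(fg$assembly$seqs, rc, ""))
  for (nm in names(fr$assembly$seqs)) {
    pieces <- strsplit(fr$assembly$seqs[[nm]], "N+")[[1]]
    pieces <- pieces[nchar(pieces) > 0]
    for (p in pieces)
      expect_true(any(vapply(out, function(o) grepl(p, o, fixed = TRUE),
                             TRUE)),
                  label = sprintf("segment of %s present in output", nm))
  }
})

test_that("mapping reports use read-set denominators with one-decimal rounding", {
  withr::with_seed(47, s1 <- rand_seq(5000))
  asm <- new_assembly(c(s1 = s1))
  reads <- reads_from_seqs(c(tur_1 = substring(s1, 1, 2000),
                             tur_2 = substring(s1, 2001, 4000),
                             cyp_1 = rand_seq(1500)))
  an <- anchor_reads(reads, asm, k = 17, stride = 1)
  rep <- mapping_report(an, groups = c(tur_1 = "TUR", tur_2 = "TUR",
                                       cyp_1 = "CYP"))
  expect_identical(rep$pct[rep$metric == "mapped_reads" & rep$set == "TUR"],
                   "100.0")
  expect_identical(rep$pct[rep$metric == "mapped_reads" & rep$set == "CYP"],
                   "0.0")
  expect_identical(rep$pct[rep$metric == "total_mapped"], "66.7")
  expect_identical(rep$pct[rep$metric == "covered_scaffolds"], "100.0")
  # the convention reproduces the published mapped-read percentage
  expect_identical(format_pct(198675, 228624), "86.9")
  # empty read set -> empty report
  empty <- anchor_reads(reads_from_seqs(character(0)), asm)
  expect_equal(nrow(mapping_report(empty)), 0)
})
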