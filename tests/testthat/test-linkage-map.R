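# Construct a genotype pair with exactly k recombinant lines among n.
pair_geno <- function(n, k) {
  a <- rep(c("A", "B"), length.out = n)
  b <- a
  if (k > 0) b[seq_len(k)] <- ifelse(a[seq_len(k)] == "A", "B", "A")
  geno_from_matrix(rbind(m1 = a, m2 = b), positions = c(0, 1000))
}

test_that("pairwise linkage recovers R, r and the binomial LOD", {
  g0 <- pair_geno(100, 0)
  p0 <- linkage_pair(g0, "m1", "m2")
  expect_equal(p0$R_obs, 0)
  expect_equal(p0$r, 0)
  expect_equal(p0$lod, lod_brute(0, 100), tolerance = 1e-10)

  p10 <- linkage_pair(pair_geno(100, 10), "m1", "m2")
  expect_equal(p10$R_obs, 0.1)
  expect_equal(p10$r, 0.1 / (2 * 0.9), tolerance = 1e-12)
  expect_equal(p10$r, 0.0556, tolerance = 1e-3)
  expect_equal(p10$lod, lod_brute(10, 100), tolerance = 1e-10)
  expect_equal(p10$lod, 15.985, tolerance = 1e-2)

  p50 <- linkage_pair(pair_geno(100, 50), "m1", "m2")
  expect_equal(p50$R_obs, 0.5)
  expect_equal(p50$r, 0.5)
  expect_equal(p50$lod, 0)

  # H and missing calls are excluded from the informative count
  g <- pair_geno(40, 4)
  g$calls[1, 1:6] <- "H"
  g$calls[2, 7:8] <- NA
  p <- linkage_pair(g, 1, 2)
  expect_equal(p$n_informative, 32)

  # matrix form agrees with the single-pair route and is symmetric
  lk <- pairwise_linkage(pair_geno(100, 10))
  expect_equal(lk$R["m1", "m2"], 0.1)
  expect_equal(lk$lod["m1", "m2"], lk$lod["m2", "m1"])
  expect_equal(unname(lk$lod["m1", "m2"]), 15.985, tolerance = 1e-2)

  # too few informative lines -> untestable
  expect_false(linkage_pair(pair_geno(8, 1), 1, 2)$testable)
})

test_that("LOD grouping is the transitive closure above the threshold", {
  calls <- rbind(a = rep(c("A", "B"), 50), b = rep(c("A", "B"), 50),
                 c = rep(c("A", "B"), 50), d = rep(c("B", "A"), 50))
  g <- geno_from_matrix(calls)
  lk <- pairwise_linkage(g)
  # hand-crafted LOD matrix: chain a-b, b-c strong; a-c weak; d isolated
  lod <- matrix(0, 4, 4, dimnames = list(rownames(calls), rownames(calls)))
  lod["a", "b"] <- lod["b", "a"] <- 20
  lod["b", "c"] <- lod["c", "b"] <- 12
  lod["a", "c"] <- lod["c", "a"] <- 3
  lk$lod <- lod
  grp <- group_markers(lk, 9)
  expect_length(grp$groups, 1)
  expect_setequal(grp$groups[[1]], c("a", "b", "c"))
  expect_identical(grp$singletons, "d")

  lk$lod[] <- 0
  grp0 <- group_markers(lk, 9)
  expect_length(grp0$groups, 0)
  expect_length(grp0$singletons, 4)
})

test_that("marker ordering is exact for three markers and recovers truth for eight", {
  fake_linkage <- function(r) {
    structure(list(r = r, lod = r * 0 + 100, n = r * 0 + 100, R = r,
                   min_informative = 10), class = "mw_linkage")
  }
  r3 <- matrix(c(0, .05, .10,
                 .05, 0, .05,
                 .10, .05, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ord <- order_markers(c("a", "b", "c"), fake_linkage(r3))
  expect_identical(ord, c("a", "b", "c"))  # canonical end: a < c

  expect_identical(order_markers(c("x", "y"), fake_linkage(r3[1:2, 1:2])),
                   c("x", "y"))

  # eight markers with additive distances; exhaustive check that the 2-opt
  # result attains the optimal adjacent-r sum
  pos <- c(0, 3, 7, 12, 20, 26, 31, 40)
  ids <- sprintf("m%d", 1:8)
  r8 <- outer(pos, pos, function(x, y) pmin(abs(x - y) / 100, 0.5))
  dimnames(r8) <- list(ids, ids)
  ord8 <- order_markers(ids, fake_linkage(r8))
  expect_true(identical(ord8, ids) || identical(ord8, rev(ids)))
})

test_that("ordering matches truth order on simulated error-free data", {
  t <- simulate_reference(1, 6e4, gc = 0.4, seed = 61)
  t <- simulate_parents(t, 2e-4, seed = 61)
  g <- simulate_ril_population(t, 216, 7, missing_rate = 0, error_rate = 0,
                               seed = 61)$genotypes
  lk <- pairwise_linkage(g)
  ord <- order_markers(g$markers$id, lk)
  pos <- g$markers$position[match(ord, g$markers$id)]
  tau <- stats::cor(seq_along(pos), pos, method = "kendall")
  expect_equal(abs(tau), 1)
})

test_that("map distances follow the Kosambi and Haldane closed forms", {
  fake_linkage <- function(rv) {
    n <- length(rv) + 1
    ids <- sprintf("m%d", seq_len(n))
    r <- matrix(0.5, n, n, dimnames = list(ids, ids))
    for (i in seq_along(rv)) r[i, i + 1] <- r[i + 1, i] <- rv[i]
    diag(r) <- 0
    structure(list(r = r), class = "mw_linkage")
  }
  d0 <- map_distances(c("m1", "m2"), fake_linkage(0))
  expect_equal(unname(d0), c(0, 0))

  dk <- map_distances(c("m1", "m2"), fake_linkage(0.0556), fn = "kosambi")
  expect_equal(unname(dk[2]),
               0.25 * log((1 + 2 * 0.0556) / (1 - 2 * 0.0556)) * 100,
               tolerance = 1e-9)
  expect_equal(unname(dk[2]), 5.58, tolerance = 1e-2)

  dh <- map_distances(c("m1", "m2"), fake_linkage(0.1), fn = "haldane")
  expect_equal(unname(dh[2]), -0.5 * log(1 - 0.2) * 100, tolerance = 1e-9)
  expect_equal(unname(dh[2]), 11.16, tolerance = 1e-2)

  expect_warning(dcap <- map_distances(c("m1", "m2"), fake_linkage(0.5)),
                 "capped")
  expect_equal(unname(dcap[2]), 50)

  # cumulative positions
  dc <- map_distances(c("m1", "m2", "m3"), fake_linkage(c(0.1, 0.1)),
                      fn = "haldane")
  expect_equal(unname(dc[3]), 2 * unname(dc[2]))
})

test_that("co-segregation pruning keeps the left marker of close pairs", {
  map <- structure(list(
    groups = list(list(markers = c("a", "b", "c"), cm = c(0, 0.05, 0.2)),
                  list(markers = c("x", "y"), cm = c(0, 5))),
    singletons = character(0),
    anchors = data.frame(id = c("a", "b", "c", "x", "y"), scaffold = "s",
                         position = 1:5, stringsAsFactors = FALSE),
    fn = "kosambi", provenance = list()), class = "mw_genetic_map")
  out <- prune_cosegregating(map, 0.1)
  expect_identical(out$groups[[1]]$markers, c("a", "c"))
  expect_identical(out$groups[[2]]$markers, c("x", "y"))

  all0 <- structure(list(
    groups = list(list(markers = c("a", "b", "c"), cm = c(0, 0, 0))),
    singletons = character(0),
    anchors = data.frame(id = c("a", "b", "c"), scaffold = "s",
                         position = 1:3, stringsAsFactors = FALSE),
    fn = "kosambi", provenance = list()), class = "mw_genetic_map")
  expect_identical(prune_cosegregating(all0, 0.1)$groups[[1]]$markers, "a")
})

test_that("map length inflates monotonically with genotyping error", {
  t <- simulate_reference(2, 5e4, gc = 0.4, seed = 67)
  t <- simulate_parents(t, 8e-4, seed = 67)
  total_len <- function(err) {
    g <- simulate_ril_population(t, 100, 7, missing_rate = 0,
                                 error_rate = err, seed = 67)$genotypes
    map <- build_genetic_map(g, lod_threshold = 9, min_spacing = NULL)
    sum(vapply(map$groups, function(gr) max(gr$cm), 1))
  }
  l0 <- total_len(0)
  l3 <- total_len(0.03)
  expect_gt(l3, l0)
})
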