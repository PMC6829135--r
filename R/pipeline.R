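# End-to-end pipeline: simulate -> marker QC -> genetic map (v2.5-analog) ->
# map anchoring (vAM-analog) -> long-read fill + reconciliation
# (v2.6/v3.0-analog) -> renaming -> annotation liftover -> marker re-call and
# second map -> reports.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the study analog with the documented
#' defaults (30% missing, 10 kbp window, 90% similarity, LOD 9.0, 0.1 cM,
#' min gap 10, 100-N joins, 1-kbp/50-bit/50% contamination rule).
#'
#' @param seed Global seed; each stage derives its own substream.
#' @param out_dir Output directory for artifacts (`NULL`: no files written).
#' @param n_chromosomes,chrom_length,gc Reference genome shape.
#' @param snp_rate Parental SNP rate per bp.
#' @param n_lines,n_selfing_generations RIL population design.
#' @param missing_rate,error_rate GBS degradation rates.
#' @param morgans_per_chromosome Map length per chromosome (Morgans).
#' @param mean_scaffold_bp,gap_rate,gap_len_range Draft fragmentation shape.
#' @param n_reads,read_length_law,read_error_rate Long-read simulation.
#' @param n_genes,n_contaminant Annotation / contamination fixtures.
#' @param max_missing,window_bp,similarity_threshold Marker QC thresholds.
#' @param lod_threshold,mapping_fn,min_spacing Linkage mapping parameters.
#' @param k,stride,min_anchors,min_gap,min_support,join_gap Gap-fill and
#'   reconciliation parameters.
#' @return A list of class `mw_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            n_chromosomes = 11L, chrom_length = 120000L,
                            gc = 0.38, snp_rate = 1.4e-3,
                            n_lines = 216L, n_selfing_generations = 7L,
                            missing_rate = 0.05, error_rate = 0.01,
                            morgans_per_chromosome = 1.625,
                            mean_scaffold_bp = 15000L, gap_rate = 0.5,
                            gap_len_range = c(80L, 400L),
                            n_reads = 2200L,
                            read_length_law = c(4000, 800, 15000),
                            read_error_rate = 0.01,
                            n_genes = 150L, n_contaminant = 3L,
                            max_missing = 0.30, window_bp = 10000L,
                            similarity_threshold = 0.90,
                            lod_threshold = 9.0, mapping_fn = "kosambi",
                            min_spacing = 0.1,
                            k = 17L, stride = 3L, min_anchors = 3L,
                            min_gap = 10L, min_support = 1L,
                            join_gap = 100L) {
  cfg <- as.list(environment())
  stopifnot(cfg$max_missing > 0, cfg$max_missing <= 1,
            cfg$similarity_threshold > 0, cfg$similarity_threshold <= 1,
            cfg$lod_threshold > 0, cfg$k >= 15, cfg$join_gap > 0)
  class(cfg) <- "mw_config"
  cfg
}

run_marker_qc <- function(geno, config) {
  qc <- filter_missing(geno, config$max_missing)
  cw <- collapse_window(qc, config$window_bp)
  cs <- collapse_similar(cw$genotypes, config$similarity_threshold)
  cs$genotypes
}

#' Run the full pipeline
#'
#' Executes the study analog end to end on synthetic data and returns every
#' intermediate artifact.  Stages: reference + parental SNPs; draft
#' fragmentation (v2.5-analog); contamination screen; RIL genotyping; marker
#' QC; genetic map (v2.5-analog); map anchoring into pseudomolecules
#' (vAM-analog); long-read simulation; fill + reconciliation (v3.0-analog
#' content); scaffold renaming; annotation liftover; marker re-call against
#' the improved assembly and a second genetic map; map comparison and
#' assembly statistics per version.
#'
#' @param config An `mw_config` from [pipeline_config()].
#' @return A list of class `mw_pipeline` with (among others) `truth`,
#'   `v25`, `vam`, `v30`, `chain_v25_v30`, `map25`, `map30`, `placements`,
#'   `reconcile_report`, `liftover`, `map_comparison`, `stats_table`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "mw_config"))
  seed <- config$seed

  # -- simulation ------------------------------------------------------------
  truth <- simulate_reference(config$n_chromosomes, config$chrom_length,
                              gc = config$gc, seed = seed)
  truth <- simulate_parents(truth, config$snp_rate, seed = seed)
  fr <- fragment_assembly(truth, config$mean_scaffold_bp, config$gap_rate,
                          config$gap_len_range, seed = seed)
  truth <- fr$truth
  cont <- simulate_contamination(fr$assembly, config$n_contaminant,
                                 truth = truth, seed = seed)
  truth <- cont$truth %||% truth
  flagged <- screen_contamination(cont$assembly, cont$hits)
  v25 <- if (length(flagged) > 0) drop_scaffolds(cont$assembly, flagged) else
    cont$assembly
  ril <- simulate_ril_population(
    truth, config$n_lines, config$n_selfing_generations,
    missing_rate = config$missing_rate, error_rate = config$error_rate,
    morgans_per_chromosome = config$morgans_per_chromosome, seed = seed)
  truth <- ril$truth
  geno_raw <- ril$genotypes

  # -- genetic map v2.5-analog ----------------------------------------------
  geno25 <- run_marker_qc(geno_raw, config)
  distortion <- segregation_distortion(geno25)
  map25 <- build_genetic_map(geno25, lod_threshold = config$lod_threshold,
                             fn = config$mapping_fn,
                             min_spacing = config$min_spacing)

  # -- map integration (vAM-analog) -----------------------------------------
  placements <- place_scaffolds(v25, map25)
  pm <- build_pseudomolecules(v25, placements, join_gap = config$join_gap)
  vam <- pm$assembly

  # -- long-read fill + reconciliation --------------------------------------
  reads <- simulate_long_reads(truth, config$n_reads,
                               length_law = config$read_length_law,
                               error_rate = config$read_error_rate,
                               seed = seed)
  rec <- reconcile(v25, vam, reads, k = config$k, stride = config$stride,
                   min_anchors = config$min_anchors, min_gap = config$min_gap,
                   min_support = config$min_support,
                   join_gap = config$join_gap)
  v26 <- rec$assembly

  # -- v3.0-analog naming ----------------------------------------------------
  lg_scaffolds <- character(0)
  lg_of <- integer(0)
  for (lg in sort(unique(placements$lg))) {
    members <- placements$scaffold[placements$lg == lg]
    hosts <- rec$assembly$components$object[
      rec$assembly$components$component %in% members]
    if (length(hosts) == 0) next
    host <- names(sort(table(hosts), decreasing = TRUE))[1]
    lg_scaffolds <- c(lg_scaffolds, host)
    lg_of[host] <- lg
  }
  lg_scaffolds <- unique(lg_scaffolds)
  rn <- rename_scaffolds(v26, lg_scaffolds)
  v30 <- rn$assembly
  rename_chain <- new_lift_chain(data.frame(
    src = names(rn$name_map), src_start = 0L,
    src_end = unname(nchar(v26$seqs[names(rn$name_map)])),
    tgt = unname(rn$name_map), tgt_start = 0L,
    tgt_end = unname(nchar(v26$seqs[names(rn$name_map)])),
    strand = "+", stringsAsFactors = FALSE))
  chain_vam_v30 <- compose_chains(rec$chain, rename_chain)
  chain_v25_v30 <- compose_chains(pm$chain, chain_vam_v30)

  # -- annotation liftover ---------------------------------------------------
  genes25 <- simulate_gene_models(v25, config$n_genes, seed = seed)
  lift_primary <- lift_features(genes25, chain_v25_v30)
  lift_secondary <- rescue_features(lift_features(genes25, chain_v25_v30),
                                    v25, v30)
  merged <- merge_liftover_sets(lift_primary, lift_secondary)
  rescued <- rescue_features(list(genes = merged$genes,
                                  status = merged$status,
                                  unmapped = lift_primary$unmapped,
                                  leaf_map = lift_primary$leaf_map),
                             v25, v30)
  cls <- classify_genes(rescued$genes, v30)
  dd <- dedupe_genes(cls$genes)
  renamed <- rename_genes(dd$genes,
                          lg_of_scaffold = stats::setNames(
                            lg_of[names(lg_of)],
                            unname(rn$name_map[names(lg_of)])))
  lift_report <- liftover_report(rescued$status, merged$provenance,
                                 cls$flags, dd, rescued$rescued)

  # -- marker re-call on the improved assembly -------------------------------
  lifted_anchor <- lapply(seq_len(nrow(geno_raw$markers)), function(i)
    lift_point(chain_v25_v30, geno_raw$markers$scaffold[i],
               geno_raw$markers$position[i]))
  ok <- !vapply(lifted_anchor, is.null, TRUE)
  markers30 <- data.frame(
    id = geno_raw$markers$id[ok],
    scaffold = vapply(lifted_anchor[ok], `[[`, "", "scaffold"),
    position = vapply(lifted_anchor[ok], `[[`, 1, "pos"),
    stringsAsFactors = FALSE)
  ord <- order(markers30$scaffold, markers30$position)
  geno30_raw <- new_geno_matrix(markers30[ord, , drop = FALSE],
                                geno_raw$calls[ok, , drop = FALSE][ord, ,
                                                                   drop = FALSE])
  geno30 <- run_marker_qc(geno30_raw, config)
  map30 <- build_genetic_map(geno30, lod_threshold = config$lod_threshold,
                             fn = config$mapping_fn,
                             min_spacing = config$min_spacing)
  comparison <- compare_maps(map25, map30)

  # -- statistics ------------------------------------------------------------
  stats_table <- do.call(rbind, lapply(
    list(`v2.5` = v25, vAM = vam, `v3.0` = v30), function(a) {
      s <- compute_stats(a)
      data.frame(n_bases = s$n_bases, n_scaffolds = s$n_scaffolds,
                 n_N = s$n_N, n_scaffolds_with_N = s$n_scaffolds_with_N,
                 N50 = s$N50, L50 = s$L50, pct_N = s$pct_N)
    }))
  stats_table <- cbind(version = rownames(stats_table), stats_table)
  rownames(stats_table) <- NULL

  out <- list(config = config, truth = truth, v25 = v25, vam = vam,
              v26 = v26, v30 = v30, reads = reads,
              geno_raw = geno_raw, geno25 = geno25, geno30 = geno30,
              distortion = distortion,
              map25 = map25, map30 = map30, placements = placements,
              chain_v25_vam = pm$chain, chain_vam_v30 = chain_vam_v30,
              chain_v25_v30 = chain_v25_v30,
              contamination = list(hits = cont$hits, flagged = flagged),
              reconcile_report = rec$report, fill_events = rec$events,
              genes25 = genes25,
              liftover = list(genes = renamed$genes,
                              name_map = renamed$name_map,
                              status = rescued$status,
                              provenance = merged$provenance,
                              flags = cls$flags, report = lift_report),
              map_comparison = comparison, stats_table = stats_table,
              scaffold_name_map = rn$name_map)
  class(out) <- "mw_pipeline"
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

#' @export
print.mw_pipeline <- function(x, ...) {
  cat("mw_pipeline run\n")
  print(x$stats_table)
  cat(sprintf("map v2.5-analog: %d groups | map v3.0-analog: %d groups\n",
              length(x$map25$groups), length(x$map30$groups)))
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(res$v25, p("assembly_v2.5.fasta"))
  write_fasta(res$vam, p("assembly_vAM.fasta"))
  write_fasta(res$v30, p("assembly_v3.0.fasta"))
  write_agp(res$v30, p("assembly_v3.0.agp"))
  write_chain(res$chain_v25_v30, p("v2.5_to_v3.0.chain.tsv"))
  write_geno_tsv(res$geno25, p("genotypes_qc_v2.5.tsv"))
  write_map_tsv(res$map25, p("genetic_map_v2.5.tsv"))
  write_map_tsv(res$map30, p("genetic_map_v3.0.tsv"))
  write_fastq(res$reads, p("long_reads.fastq"))
  write_gff3(res$genes25, p("genes_v2.5.gff3"))
  write_gff3(res$liftover$genes, p("genes_v3.0.gff3"),
             flags = res$liftover$flags, status = res$liftover$status)
  utils::write.table(res$stats_table, p("assembly_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$fill_events, p("fill_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- res$config
  class(cfg) <- NULL
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare two genetic maps
#'
#' Groups are matched by shared-marker majority; for each matched pair the
#' rank correlation (Kendall and Spearman) of the shared markers' order is
#' reported, with a negative correlation flagged as an orientation flip.
#'
#' @param map_a,map_b `mw_genetic_map` objects sharing marker ids.
#' @return List with `table` (data.frame `lg_a`, `lg_b`, `n_shared`, `tau`,
#'   `rho`, `flipped`) and `unmatched` (groups of `map_a` without shared
#'   markers).
#' @export
compare_maps <- function(map_a, map_b) {
  lg_b_of <- list()
  pos_b_of <- list()
  for (j in seq_along(map_b$groups)) {
    gr <- map_b$groups[[j]]
    lg_b_of[gr$markers] <- j
    pos_b_of[gr$markers] <- seq_along(gr$markers)
  }
  rows <- list(); unmatched <- integer(0)
  for (i in seq_along(map_a$groups)) {
    gr <- map_a$groups[[i]]
    shared <- gr$markers[gr$markers %in% names(lg_b_of)]
    if (length(shared) == 0) {
      unmatched <- c(unmatched, i)
      next
    }
    bl <- unlist(lg_b_of[shared])
    j <- as.integer(names(sort(table(bl), decreasing = TRUE))[1])
    sh <- shared[bl == j]
    if (length(sh) < 2) {
      rows[[length(rows) + 1L]] <- data.frame(
        lg_a = i, lg_b = j, n_shared = length(sh), tau = NA_real_,
        rho = NA_real_, flipped = NA, stringsAsFactors = FALSE)
      next
    }
    oa <- match(sh, gr$markers)
    ob <- unlist(pos_b_of[sh])
    tau <- suppressWarnings(stats::cor(oa, ob, method = "kendall"))
    rho <- suppressWarnings(stats::cor(oa, ob, method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(
      lg_a = i, lg_b = j, n_shared = length(sh), tau = tau, rho = rho,
      flipped = !is.na(tau) && tau < 0, stringsAsFactors = FALSE)
  }
  list(table = if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(lg_a = integer(0), lg_b = integer(0), n_shared = integer(0),
               tau = numeric(0), rho = numeric(0), flipped = logical(0)),
    unmatched = unmatched)
}
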