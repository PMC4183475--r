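# Pipeline orchestration: a single entry point chaining
# demultiplex -> filters -> alignment screen -> precluster -> chimera
# removal -> frame correction -> OTU picking -> taxonomy -> consensus ->
# molecular taxa -> community statistics, with a funnel table and a
# machine-readable run report.  Identical config + inputs give identical
# artifacts.

#' Pipeline configuration
#'
#' All thresholds carry their field defaults: 200 bp length filter, 60%
#' alignment screen, 99.7% precluster, 0.8% K2P OTU threshold, 1400-read
#' rarefaction depth, 2000 ANOSIM permutations, k = 8 classifier with 100
#' bootstraps.
#'
#' @param min_len Minimum raw read length.
#' @param length_includes_prefix Length filter counts barcode/primer.
#' @param max_barcode_mismatch Demultiplexing mismatch allowance.
#' @param min_similarity Alignment-screen identity cutoff.
#' @param precluster_similarity Precluster identity.
#' @param otu_threshold OTU K2P distance threshold.
#' @param chimera_skew,chimera_min_ident,chimera_min_margin,
#'   chimera_min_parent_bases Chimera-detector settings.
#' @param classifier_k,classifier_bootstraps,classifier_min_conf
#'   Classifier settings.
#' @param nj_bootstraps,nj_min_support NJ assignment settings.
#' @param target_phylum Phylum retained by the off-target filter.
#' @param aliases Optional species -> MT alias table (see
#'   [aggregate_to_mts()]).
#' @param rarefy_depth Rarefaction depth.
#' @param permutations ANOSIM permutations.
#' @param seed Integer seed driving every stochastic step.
#' @return List of class `gp_pipeline_config`.
#' @export
pipeline_config <- function(min_len = 200L, length_includes_prefix = TRUE,
                            max_barcode_mismatch = 1L,
                            min_similarity = 0.60,
                            precluster_similarity = 0.997,
                            otu_threshold = 0.008,
                            chimera_skew = 2.0, chimera_min_ident = 0.99,
                            chimera_min_margin = 0.01,
                            chimera_min_parent_bases = 30L,
                            classifier_k = 8L,
                            classifier_bootstraps = 100L,
                            classifier_min_conf = 0.80,
                            nj_bootstraps = 100L, nj_min_support = 0.70,
                            target_phylum = GP_TARGET_PHYLUM,
                            aliases = NULL,
                            rarefy_depth = 1400L, permutations = 2000L,
                            seed = 1L) {
  structure(as.list(environment()), class = "gp_pipeline_config")
}

#' Specificity percentages
#'
#' The report's primer-specificity arithmetic: with `n_offtarget`
#' off-target reads among `n_total` length-passing reads, specificity is
#' `100 * (1 - n_offtarget/n_total)` and the off-target share its
#' complement, both rounded to two decimals (15 of 23263 prints 99.94 /
#' 0.06).
#'
#' @param n_offtarget Number of off-target reads.
#' @param n_total Reads passing the length filter.
#' @return List with `specificity` and `offtarget` percentages.
#' @export
specificity_percentages <- function(n_offtarget, n_total) {
  if (n_total <= 0) return(list(specificity = NA_real_,
                                offtarget = NA_real_))
  list(specificity = round(100 * (1 - n_offtarget / n_total), 2),
       offtarget = round(100 * n_offtarget / n_total, 2))
}

#' Evaluate a reference set as a barcoding marker
#'
#' Runs the full marker evaluation: pairwise K2P matrix, 50-bp sliding
#' window profile, barcode-gap records and the derived OTU threshold.
#'
#' @param refset A [reference_set()].
#' @param window,step Sliding-window settings.
#' @param excluded_taxa Species excluded from threshold derivation.
#' @param outdir Optional directory for TSV artifacts.
#' @return List: `distances`, `profile`, `gaps`, `threshold`.
#' @export
eval_marker <- function(refset, window = 50L, step = 1L,
                        excluded_taxa = character(), outdir = NULL) {
  d <- pairwise_k2p(refset)
  prof <- sliding_window_profile(refset, window = window, step = step)
  gaps <- barcode_gap(d, species = refset$species)
  thr <- tryCatch(derive_otu_threshold(gaps, excluded_taxa = excluded_taxa),
                  error = function(e) e)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(d, file.path(outdir, "k2p_distances.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(prof, file.path(outdir, "window_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gaps, file.path(outdir, "barcode_gaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(distances = d, profile = prof, gaps = gaps, threshold = thr)
}

.funnel_row <- function(stage, n_in, n_out) {
  data.frame(stage = stage, reads_in = n_in, reads_out = n_out,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes the cascade end to end on raw reads and a reference set, and
#' assembles a run report.  Any stage error aborts with the stage name.
#'
#' @param reads Named character vector of raw barcoded reads.
#' @param sample_map Sample map data.frame.
#' @param refset Reference [reference_set()] with lineages and annotation.
#' @param tree Reference tree (`phylo`) for placement.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for artifacts.
#' @return `gp_run_report`: funnel, parameter snapshot, specificity, OTU
#'   and MT counts, community statistics and (invisible in print) the
#'   intermediate objects under `$state`.
#' @export
run_pipeline <- function(reads, sample_map, refset, tree,
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "gp_pipeline_config"))
  funnel <- list()
  n0 <- length(reads)

  dm <- demultiplex(reads, sample_map,
                    max_mismatch = config$max_barcode_mismatch)
  funnel[[1]] <- .funnel_row("demultiplex", n0, nrow(dm$reads))

  lf <- length_ambiguity_filter(dm$reads, min_len = config$min_len,
                                length_includes_prefix =
                                  config$length_includes_prefix)
  funnel[[2]] <- .funnel_row("length_ambiguity", nrow(dm$reads), nrow(lf))
  n_length_pass <- nrow(lf)

  sc <- alignment_screen(lf, refset, min_similarity = config$min_similarity)
  funnel[[3]] <- .funnel_row("alignment_screen", nrow(lf), nrow(sc$reads))

  # primer specificity: reads whose best-matching reference is from a
  # non-target phylum, over the length-passing reads
  ref_phyla <- if (is.null(refset$lineages)) character(0) else
    vapply(refset$lineages, function(l)
      if (length(l)) unname(l[["phylum"]]) else NA_character_,
      character(1))
  n_offtarget_reads <- if (length(ref_phyla))
    sum(ref_phyla[sc$reads$best_ref] != config$target_phylum,
        na.rm = TRUE) else 0L
  spec <- specificity_percentages(n_offtarget_reads, n_length_pass)

  cent <- precluster(sc, similarity = config$precluster_similarity)
  funnel[[4]] <- .funnel_row("precluster", nrow(sc$reads),
                             sum(cent$abundance))

  chim <- detect_chimeras(cent, skew = config$chimera_skew,
                          min_ident = config$chimera_min_ident,
                          min_margin = config$chimera_min_margin,
                          min_parent_bases =
                            config$chimera_min_parent_bases)
  cent_nc <- .drop_centroids(cent, which(chim$flagged))
  funnel[[5]] <- .funnel_row("chimera_removal", sum(cent$abundance),
                             sum(cent_nc$abundance))

  fc <- frame_correct(cent_nc, refset)
  funnel[[6]] <- .funnel_row("frame_correction", sum(cent_nc$abundance),
                             sum(fc$centroids$abundance))

  otus <- cluster_otus(fc$centroids,
                       distance_threshold = config$otu_threshold)

  # OTU-level chimera re-scan (the final check re-examines OTUs)
  otu_chim <- if (length(otus$otu_id)) {
    detect_chimeras(structure(list(
      seqs = otus$rep_seq, abundance = otus$abundance,
      seed_read = otus$otu_id), class = "gp_centroids"),
      skew = config$chimera_skew, min_ident = config$chimera_min_ident,
      min_margin = config$chimera_min_margin,
      min_parent_bases = config$chimera_min_parent_bases)$flagged
  } else logical(0)

  # taxonomy only for OTUs that can survive the final check
  tax_idx <- which(otus$abundance >= 2L & !otu_chim)
  set.seed(.subseed(config$seed, 11L))
  tax <- if (length(tax_idx)) {
    assign_taxonomy(.drop_otus(otus, setdiff(seq_along(otus$otu_id),
                                             tax_idx)),
                    refset, tree, k = config$classifier_k,
                    bootstraps = config$classifier_bootstraps,
                    min_conf = config$classifier_min_conf,
                    nj_bootstraps = config$nj_bootstraps,
                    min_support = config$nj_min_support)
  } else list(lineages = list(), audit = NULL)

  rs <- remove_singletons_and_offtarget(otus, tax$lineages,
                                        target_phylum =
                                          config$target_phylum,
                                        chimera_flags = otu_chim)
  funnel[[7]] <- .funnel_row("singleton_offtarget", sum(otus$abundance),
                             sum(rs$otus$abundance))

  mts <- aggregate_to_mts(rs$otus, tax$lineages, aliases = config$aliases)

  table <- otu_table_gp(rs$otus$counts, vapply(
    rs$otus$otu_id, function(id) lineage_string(tax$lineages[[id]]),
    character(1)))

  community <- .community_block(table, rs$otus, sample_map, mts, config)

  funnel <- do.call(rbind, funnel)
  report <- structure(list(
    funnel = funnel,
    parameters = unclass(config),
    seed = config$seed,
    n_length_pass = n_length_pass,
    n_analysed = sum(rs$otus$abundance),
    n_offtarget_reads = n_offtarget_reads,
    specificity = spec$specificity,
    offtarget_pct = spec$offtarget,
    otu_count = length(rs$otus$otu_id),
    mt_count = nrow(mts$mts),
    removal_report = rs$report,
    anosim = community$anosim,
    anosim_grouped = community$anosim_grouped,
    state = list(demux = dm, filtered = lf, screened = sc,
                 centroids = cent, chimeras = chim,
                 frame = fc, otus_all = otus, taxonomy = tax,
                 otus = rs$otus, mts = mts, table = table,
                 community = community)),
    class = "gp_run_report")
  if (!is.null(outdir)) .write_artifacts(report, outdir)
  report
}

# rarefaction, UniFrac, PCoA, ANOSIM on the retained OTU table; degenerate
# inputs (too few OTUs or samples) yield NULL components rather than errors
.community_block <- function(table, otus, sample_map, mts, config) {
  out <- list(table_rarefied = NULL, tree = NULL, unifrac_uw = NULL,
              unifrac_w = NULL, pcoa = NULL, anosim = NULL,
              anosim_grouped = NULL, composition = NULL)
  if (nrow(table$counts) < 3L || ncol(table$counts) < 4L) return(out)
  rt <- tryCatch(suppressWarnings(
    rarefy(table, depth = config$rarefy_depth,
           seed = .subseed(config$seed, 21L))),
    error = function(e) NULL)
  if (is.null(rt) || ncol(rt$counts) < 4L) return(out)
  out$table_rarefied <- rt
  reps <- otus$rep_seq[rownames(rt$counts)]
  d <- .fill_undefined(pairwise_k2p(reps))
  otree <- ape::nj(stats::as.dist(d))
  otree$edge.length[otree$edge.length < 0] <- 0
  out$tree <- otree
  out$unifrac_uw <- unifrac(rt, otree, weighted = FALSE)
  out$unifrac_w <- unifrac(rt, otree, weighted = TRUE, normalized = TRUE)
  out$pcoa <- pcoa_ord(out$unifrac_w)
  grp <- sample_map$treatment[match(colnames(rt$counts),
                                    sample_map$sample_id)]
  out$anosim <- tryCatch(
    anosim_test(out$unifrac_w, grp, permutations = config$permutations,
                seed = .subseed(config$seed, 22L)),
    error = function(e) NULL)
  till_grp <- ifelse(grp == "no_tillage", "no_tillage", "disturbed")
  out$anosim_grouped <- tryCatch(
    anosim_test(out$unifrac_w, till_grp,
                permutations = config$permutations,
                seed = .subseed(config$seed, 23L)),
    error = function(e) NULL)
  out$composition <- composition_summary(rt, mts$mapping, sample_map)
  out
}

#' @method print gp_run_report
#' @export
print.gp_run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  print(x$funnel, row.names = FALSE)
  cat(sprintf("reads analysed: %d; OTUs: %d; MTs: %d\n",
              x$n_analysed, x$otu_count, x$mt_count))
  if (!is.na(x$specificity))
    cat(sprintf("specificity: %.2f%% (off-target %.2f%%)\n",
                x$specificity, x$offtarget_pct))
  if (!is.null(x$anosim)) print(x$anosim)
  invisible(x)
}

#' Write a run report to JSON
#'
#' @param report A `gp_run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  payload <- list(
    seed = report$seed,
    funnel = report$funnel,
    parameters = Filter(function(p) !is.null(p) && !is.function(p),
                        report$parameters),
    n_length_pass = report$n_length_pass,
    n_analysed = report$n_analysed,
    n_offtarget_reads = report$n_offtarget_reads,
    specificity = report$specificity,
    offtarget_pct = report$offtarget_pct,
    otu_count = report$otu_count,
    mt_count = report$mt_count,
    anosim = if (!is.null(report$anosim))
      list(R = report$anosim$R, p = report$anosim$p,
           permutations = report$anosim$permutations),
    anosim_grouped = if (!is.null(report$anosim_grouped))
      list(R = report$anosim_grouped$R, p = report$anosim_grouped$p))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.write_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- report$state
  utils::write.table(report$funnel, file.path(outdir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # denoised centroids with abundance annotations
  cent <- st$frame$centroids
  if (length(cent$seqs)) {
    den <- stats::setNames(.ungap(cent$seqs),
                           sprintf("%s;size=%d", cent$seed_read,
                                   cent$abundance))
    write_fasta(den, file.path(outdir, "denoised.fasta"))
  }
  write_otu_table(st$table, file.path(outdir, "otu_table.tsv"))
  if (!is.null(st$taxonomy$audit))
    utils::write.table(st$taxonomy$audit,
                       file.path(outdir, "taxonomy_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(st$mts$mts, file.path(outdir, "mt_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comm <- st$community
  if (!is.null(comm$unifrac_w)) {
    utils::write.table(comm$unifrac_w,
                       file.path(outdir, "unifrac_weighted.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(comm$unifrac_uw,
                       file.path(outdir, "unifrac_unweighted.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(comm$pcoa$coordinates,
                       file.path(outdir, "pcoa_coordinates.tsv"),
                       sep = "\t", quote = FALSE)
  }
  write_run_report(report, file.path(outdir, "run_report.json"))
  invisible(outdir)
}
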