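# Community statistics: rarefaction, UniFrac distances on the OTU tree,
# principal coordinates, ANOSIM and per-treatment composition summaries.

#' Rarefy an OTU table to equal depth
#'
#' Subsamples every sample without replacement to `depth` reads
#' (deterministic given `seed`); samples below the depth are dropped with
#' a warning.  No OTU absent before rarefaction can be present after.
#'
#' @param table A [otu_table_gp()].
#' @param depth Target depth (paper value 1400).
#' @param seed Integer seed.
#' @return Rarefied `gp_otu_table` (possibly with fewer samples).
#' @export
rarefy <- function(table, depth = 1400L, seed = 1L) {
  stopifnot(inherits(table, "gp_otu_table"))
  if (depth <= 0L) stop("rarefaction depth must be positive")
  totals <- colSums(table$counts)
  low <- totals < depth
  if (any(low))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(names(totals)[low], collapse = ", "))
  keep <- table$counts[, !low, drop = FALSE]
  set.seed(seed)
  if (ncol(keep)) {
    # rrarefy's "observed counts" heads-up is spurious for these matrices
    sub <- t(suppressWarnings(vegan::rrarefy(t(keep), depth)))
    storage.mode(sub) <- "integer"
  } else sub <- keep
  otu_table_gp(sub, table$taxonomy)
}

#' Rarefaction curves
#'
#' Mean observed OTU richness per sample over a grid of subsampling
#' depths.  Each replicate draws one random read permutation per sample,
#' so every replicate curve (and hence the mean) is non-decreasing and
#' reaches the observed richness at full depth.
#'
#' @param table A `gp_otu_table`.
#' @param depths Ascending integer grid; defaults to ten steps up to the
#'   smallest sample total.
#' @param reps Random permutations per sample.
#' @param seed Integer seed.
#' @return `data.frame` with `sample`, `depth`, `mean_otus`.
#' @export
rarefaction_curves <- function(table, depths = NULL, reps = 10L,
                               seed = 1L) {
  stopifnot(inherits(table, "gp_otu_table"))
  totals <- colSums(table$counts)
  if (is.null(depths))
    depths <- unique(pmax(1L, round(seq(1L, min(totals), length.out = 10L))))
  if (is.unsorted(depths)) stop("depth grid must be ascending")
  set.seed(seed)
  out <- list()
  for (s in colnames(table$counts)) {
    reads <- rep(seq_len(nrow(table$counts)), table$counts[, s])
    d_use <- depths[depths <= length(reads)]
    acc <- matrix(0, length(d_use), reps)
    for (r in seq_len(reps)) {
      perm <- sample(reads)
      newcum <- cumsum(!duplicated(perm))
      acc[, r] <- newcum[d_use]
    }
    out[[s]] <- data.frame(sample = s, depth = d_use,
                           mean_otus = rowMeans(acc),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# edge x leaf descendant incidence for a phylo tree
.edge_leaf_matrix <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_edge <- nrow(tree$edge)
  M <- matrix(FALSE, n_edge, ntip,
              dimnames = list(NULL, tree$tip.label))
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2L]
    parent <- po$edge[e, 1L]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  for (e in seq_len(n_edge)) M[e, below[[tree$edge[e, 2L]]]] <- TRUE
  M
}

#' UniFrac distances between samples
#'
#' Unweighted UniFrac is the fraction of tree branch length leading only
#' to taxa of one of the two samples, over the branch length leading to
#' taxa of either.  Weighted UniFrac is `sum(b_i * |pA_i - pB_i|)` over
#' branches, with the normalized variant divided by
#' `sum(b_i * (pA_i + pB_i))` so values stay in `[0, 1]`.
#'
#' @param table A `gp_otu_table`; every OTU must be a leaf of `tree`.
#' @param tree `phylo` tree over the OTUs (non-negative branch lengths);
#'   extra leaves are pruned.
#' @param weighted Weighted (abundance) variant instead of presence.
#' @param normalized Normalize the weighted variant (ignored when
#'   unweighted).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  stopifnot(inherits(table, "gp_otu_table"))
  otus <- rownames(table$counts)
  missing <- setdiff(otus, tree$tip.label)
  if (length(missing))
    stop("OTU(s) missing from the tree: ", paste(missing, collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (length(setdiff(tree$tip.label, otus)))
    tree <- ape::keep.tip(tree, otus)
  M <- .edge_leaf_matrix(tree)[, otus, drop = FALSE]
  b <- tree$edge.length
  P <- sweep(table$counts, 2L, pmax(colSums(table$counts), 1L), "/")
  load <- M %*% P  # edge x sample
  samples <- colnames(P)
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      if (weighted) {
        num <- sum(b * abs(load[, i] - load[, j]))
        d[i, j] <- d[j, i] <- if (normalized)
          num / sum(b * (load[, i] + load[, j])) else num
      } else {
        pi_ <- load[, i] > 0
        pj <- load[, j] > 0
        d[i, j] <- d[j, i] <- sum(b[xor(pi_, pj)]) / sum(b[pi_ | pj])
      }
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling of a symmetric zero-diagonal distance matrix;
#' coordinates are scaled by the square root of each non-negative
#' eigenvalue.  Negative eigenvalues (non-Euclidean input) are reported,
#' never dropped.
#'
#' @param d Symmetric distance matrix.
#' @return `gp_pcoa` list: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (relative to
#'   the positive eigenvalue total).
#' @export
pcoa_ord <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("PCoA input must be a symmetric distance matrix")
  if (any(abs(diag(d)) > 1e-12)) stop("PCoA input must have a zero diagonal")
  n <- nrow(d)
  # cmdscale warns that not all n-1 axes have positive eigenvalues; that
  # is expected here, negative eigenvalues are part of the result
  sc <- suppressWarnings(stats::cmdscale(d, k = max(n - 1L, 1L),
                                         eig = TRUE))
  eig <- sc$eig
  pos <- sum(eig[eig > 0])
  structure(list(
    coordinates = sc$points,
    eigenvalues = eig,
    proportion_explained = if (pos > 0) eig / pos else eig * 0),
    class = "gp_pcoa")
}

#' @method print gp_pcoa
#' @export
print.gp_pcoa <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat("PCoA:", nrow(x$coordinates), "points; first axes explain",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a distance matrix:
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`, mid-ranks for ties; the p-value is
#' `(#permuted R >= observed + 1) / (permutations + 1)`.
#'
#' @param d Symmetric distance matrix.
#' @param grouping Factor-like vector, one label per sample (each group
#'   needs >= 2 members).
#' @param permutations Number of permutations (paper value 2000).
#' @param seed Integer seed for the permutations.
#' @return `gp_anosim` list: `R`, `p`, `permutations`, `grouping`.
#' @export
anosim_test <- function(d, grouping, permutations = 2000L, seed = 1L) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2L)
    stop("ANOSIM needs at least two groups")
  if (any(table(droplevels(grouping)) < 2L))
    stop("every ANOSIM group needs at least two members")
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), grouping,
                       permutations = permutations)
  structure(list(R = unname(fit$statistic), p = fit$signif,
                 permutations = permutations,
                 grouping = paste(levels(droplevels(grouping)),
                                  collapse = " vs ")),
            class = "gp_anosim")
}

#' @method print gp_anosim
#' @export
print.gp_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM (%s): R = %.3f, p = %.4g (%d permutations)\n",
              x$grouping, x$R, x$p, x$permutations))
  invisible(x)
}

#' Per-plot and per-treatment composition summary
#'
#' Aggregates OTU counts to molecular taxa and reports relative abundances
#' per plot sample and per treatment (pooled reads), plus per-treatment
#' presence counts (number of plots in which each MT occurs).
#'
#' @param table A `gp_otu_table`.
#' @param mt_mapping Named character vector OTU id -> MT name.
#' @param metadata Sample map with `sample_id` and `treatment`.
#' @return List: `per_plot` (`sample`, `treatment`, `mt`,
#'   `relative_abundance`), `per_treatment` (`treatment`, `mt`,
#'   `relative_abundance`, `n_plots_present`).
#' @export
composition_summary <- function(table, mt_mapping, metadata) {
  stopifnot(inherits(table, "gp_otu_table"))
  otus <- rownames(table$counts)
  if (!all(otus %in% names(mt_mapping)))
    stop("mt_mapping missing OTU(s): ",
         paste(setdiff(otus, names(mt_mapping)), collapse = ", "))
  mt_counts <- rowsum(table$counts, group = mt_mapping[otus])
  rel <- sweep(mt_counts, 2L, pmax(colSums(mt_counts), 1L), "/")
  samples <- colnames(mt_counts)
  tr <- metadata$treatment[match(samples, metadata$sample_id)]
  per_plot <- data.frame(
    sample = rep(samples, each = nrow(rel)),
    treatment = rep(tr, each = nrow(rel)),
    mt = rep(rownames(rel), length(samples)),
    relative_abundance = as.vector(rel), stringsAsFactors = FALSE)
  out <- list()
  for (t in unique(tr)) {
    cols <- which(tr == t)
    pooled <- rowSums(mt_counts[, cols, drop = FALSE])
    out[[t]] <- data.frame(
      treatment = t, mt = rownames(mt_counts),
      relative_abundance = pooled / max(sum(pooled), 1L),
      n_plots_present = rowSums(mt_counts[, cols, drop = FALSE] > 0),
      stringsAsFactors = FALSE)
  }
  list(per_plot = per_plot,
       per_treatment = do.call(rbind, c(out, list(make.row.names = FALSE))))
}
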