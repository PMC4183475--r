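# Marker evaluation: K2P distances, sliding-window variability and
# diagnostic-nucleotide profiles, barcode-gap analysis and derivation of the
# OTU clustering threshold from the gap.
#
# Distances follow Kimura's two-parameter closed form
#   d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]
# with P the transition and Q the transversion proportion over comparable
# sites.  Columns where either sequence carries a gap, an N or lies outside
# read coverage are excluded pairwise (pairwise deletion; the reference sets
# mix fragment lengths, so complete deletion would discard most columns).
# Where the logarithm's argument is non-positive, or no sites are
# comparable, the distance is UNDEFINED and reported as NA -- never as
# infinity; downstream minima/maxima skip it.

# Integer coding: A=1 C=2 G=3 T=4, everything else (N, -, .) 0 = not
# comparable.  Transitions are A<->G and C<->T.
.code_seq <- function(s) {
  x <- utf8ToInt(s)
  out <- integer(length(x))
  out[x == 65L] <- 1L  # A
  out[x == 67L] <- 2L  # C
  out[x == 71L] <- 3L  # G
  out[x == 84L] <- 4L  # T
  out
}

.code_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  m <- matrix(0L, length(seqs), L, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) m[i, ] <- .code_seq(seqs[[i]])
  m
}

# purine = codes 1,3; pyrimidine = 2,4
.is_transition <- function(a, b) {
  (a != b) & ((a == 1L & b == 3L) | (a == 3L & b == 1L) |
              (a == 2L & b == 4L) | (a == 4L & b == 2L))
}

.k2p_from_counts <- function(n_comp, n_ts, n_tv, min_sites = 1L) {
  if (n_comp < min_sites) return(NA_real_)
  P <- n_ts / n_comp
  Q <- n_tv / n_comp
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' @param seq_a,seq_b Equal-length aligned sequence strings.
#' @param min_sites Minimum number of comparable sites for the distance to
#'   be defined.
#' @return Distance in substitutions/site, or `NA` where undefined (log of
#'   a non-positive argument, or fewer than `min_sites` comparable sites).
#' @export
k2p <- function(seq_a, seq_b, min_sites = 1L) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("k2p: sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  a <- .code_seq(seq_a)
  b <- .code_seq(seq_b)
  comp <- a > 0L & b > 0L
  ts <- .is_transition(a, b) & comp
  tv <- comp & (a != b) & !ts
  .k2p_from_counts(sum(comp), sum(ts), sum(tv), min_sites)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing comparable sites under pairwise deletion.
#'
#' @inheritParams k2p
#' @return Proportion in `[0, 1]`, or `NA` with no comparable sites.
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- .code_seq(seq_a)
  b <- .code_seq(seq_b)
  comp <- a > 0L & b > 0L
  if (!any(comp)) return(NA_real_)
  sum(a[comp] != b[comp]) / sum(comp)
}

# ---- reference sets ---------------------------------------------------------

#' Construct a reference set
#'
#' Bundles an aligned, species-labelled set of marker sequences with
#' optional lineages, isolate labels and an exon/intron region annotation.
#'
#' @param seqs Named character vector of aligned sequences (equal length).
#' @param species Named character vector mapping sequence id to species
#'   label; every sequence must be labelled.  Species identity is the label
#'   string; no name parsing is attempted.
#' @param lineages Optional named list of lineages ([parse_lineage()]) per
#'   sequence id.
#' @param isolate Optional named character vector of isolate labels.
#' @param annotation Optional region annotation ([region_annotation()])
#'   covering the alignment.
#' @return An object of class `gp_reference_set`.
#' @export
reference_set <- function(seqs, species, lineages = NULL, isolate = NULL,
                          annotation = NULL) {
  if (length(unique(nchar(seqs))) > 1L)
    stop("reference sequences must be aligned to equal length")
  miss <- setdiff(names(seqs), names(species))
  if (length(miss))
    stop("no species label for sequence ", .msg_id(miss[1L]))
  if (!is.null(annotation)) region_labels(annotation, nchar(seqs[[1L]]))
  structure(list(seqs = seqs, species = species[names(seqs)],
                 lineages = lineages, isolate = isolate,
                 annotation = annotation),
            class = "gp_reference_set")
}

#' @method print gp_reference_set
#' @export
print.gp_reference_set <- function(x, ...) {
  cat("Reference set:", length(x$seqs), "sequences,",
      length(unique(x$species)), "species, alignment length",
      nchar(x$seqs[[1L]]), "\n")
  invisible(x)
}

#' Pairwise K2P distance matrix
#'
#' @param x A `gp_reference_set` or a named character vector of aligned
#'   sequences.
#' @param min_sites Minimum comparable sites per pair.
#' @return Symmetric numeric matrix with zero diagonal; undefined pairs are
#'   `NA` (reported, not dropped).
#' @export
pairwise_k2p <- function(x, min_sites = 1L) {
  seqs <- if (inherits(x, "gp_reference_set")) x$seqs else x
  m <- .code_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    a <- m[i, ]
    for (j in seq.int(i + 1L, n)) {
      b <- m[j, ]
      comp <- a > 0L & b > 0L
      ts <- .is_transition(a, b) & comp
      tv <- comp & (a != b) & !ts
      d[i, j] <- d[j, i] <- .k2p_from_counts(sum(comp), sum(ts), sum(tv),
                                             min_sites)
    }
  }
  d
}

# ---- sliding windows --------------------------------------------------------

#' Sliding-window K2P and diagnostic-nucleotide profile
#'
#' Slides a window along the alignment and reports, per window position, the
#' mean pairwise K2P distance (over pairs with at least `min_pair_sites`
#' comparable columns in the window; other pairs are treated as undefined)
#' and the sum of diagnostic nucleotides.
#'
#' @param refset A `gp_reference_set`.
#' @param window Window size in alignment columns.
#' @param step Step between window starts.
#' @param min_pair_sites A pair with fewer comparable columns than this
#'   within a window is treated as undefined for that window.
#' @return `data.frame` with `start` (0-based window start), `window`,
#'   `mean_k2p` (`NA` if no pair defined) and `diagnostic_sum`.
#' @export
sliding_window_profile <- function(refset, window = 50L, step = 1L,
                                   min_pair_sites = 10L) {
  stopifnot(inherits(refset, "gp_reference_set"))
  if (window < 2L) stop("window must be >= 2 columns")
  m <- .code_matrix(refset$seqs)
  L <- ncol(m)
  if (window > L) stop("window exceeds alignment length ", L)
  n <- nrow(m)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  # cumulative per-pair site-class counts -> O(1) window sums
  ccomp <- cts <- ctv <- matrix(0, np, L + 1L)
  for (p in seq_len(np)) {
    a <- m[pairs[1L, p], ]
    b <- m[pairs[2L, p], ]
    comp <- a > 0L & b > 0L
    ts <- .is_transition(a, b) & comp
    tv <- comp & (a != b) & !ts
    ccomp[p, ] <- c(0, cumsum(comp))
    cts[p, ] <- c(0, cumsum(ts))
    ctv[p, ] <- c(0, cumsum(tv))
  }
  diag_cum <- c(0, cumsum(diagnostic_columns(refset)))
  starts <- seq.int(0L, L - window, by = step)
  mean_k2p <- numeric(length(starts))
  dsum <- integer(length(starts))
  for (w in seq_along(starts)) {
    s <- starts[[w]]
    nc <- ccomp[, s + window + 1L] - ccomp[, s + 1L]
    nt <- cts[, s + window + 1L] - cts[, s + 1L]
    nv <- ctv[, s + window + 1L] - ctv[, s + 1L]
    dvals <- vapply(seq_len(np), function(p)
      .k2p_from_counts(nc[p], nt[p], nv[p], min_sites = min_pair_sites),
      numeric(1))
    mean_k2p[[w]] <- if (all(is.na(dvals))) NA_real_ else
      mean(dvals, na.rm = TRUE)
    dsum[[w]] <- diag_cum[[s + window + 1L]] - diag_cum[[s + 1L]]
  }
  data.frame(start = starts, window = window, mean_k2p = mean_k2p,
             diagnostic_sum = dsum)
}

#' Per-column diagnostic nucleotide counts
#'
#' A column is diagnostic for species S iff every member of S carries the
#' same unambiguous base there and no non-member carries that base.  The
#' column's count is the number of species it is diagnostic for.
#'
#' @param refset A `gp_reference_set`.
#' @return Integer vector, one count per alignment column.
#' @export
diagnostic_columns <- function(refset) {
  stopifnot(inherits(refset, "gp_reference_set"))
  m <- .code_matrix(refset$seqs)
  species <- refset$species
  out <- integer(ncol(m))
  for (sp in unique(species)) {
    idx <- which(species == sp)
    sub <- m[idx, , drop = FALSE]
    base <- sub[1L, ]
    shared <- base > 0L & colSums(sub == rep(base, each = nrow(sub))) ==
      nrow(sub)
    if (length(idx) == nrow(m)) { # single species: nothing to contrast
      next
    }
    other <- m[-idx, , drop = FALSE]
    clash <- colSums(other == rep(base, each = nrow(other))) > 0L
    out <- out + as.integer(shared & !clash)
  }
  out
}

#' Per-window diagnostic-nucleotide sums
#'
#' @inheritParams sliding_window_profile
#' @return `data.frame` with `start` and `diagnostic_sum`.
#' @export
diagnostic_nucleotides <- function(refset, window = 50L, step = 1L) {
  if (length(unique(refset$species)) < 2L)
    return(data.frame(
      start = seq.int(0L, nchar(refset$seqs[[1L]]) - window, by = step),
      diagnostic_sum = 0L))
  per_col <- diagnostic_columns(refset)
  L <- length(per_col)
  cs <- c(0L, cumsum(per_col))
  starts <- seq.int(0L, L - window, by = step)
  data.frame(start = starts,
             diagnostic_sum = cs[starts + window + 1L] - cs[starts + 1L])
}

# ---- barcode gap ------------------------------------------------------------

#' Barcode-gap analysis
#'
#' For every sequence, the maximum K2P distance to conspecifics (0 for
#' species represented by a single sequence) and the minimum distance to
#' heterospecifics; the gap is their difference.  Undefined distances are
#' excluded from the minima/maxima; a sequence whose interspecific
#' distances are all undefined is flagged `excluded` and takes no part in
#' threshold derivation.
#'
#' @param x A `gp_reference_set`, or a precomputed K2P matrix (then
#'   `species` is required).
#' @param species Named character vector of species labels (ignored when
#'   `x` is a reference set).
#' @return `data.frame` with `id`, `species`, `max_intraspecific`,
#'   `min_interspecific`, `gap`, `excluded`.
#' @export
barcode_gap <- function(x, species = NULL) {
  if (inherits(x, "gp_reference_set")) {
    species <- x$species
    d <- pairwise_k2p(x)
  } else {
    d <- x
    if (is.null(species)) stop("species labels required with a matrix input")
    species <- species[rownames(d)]
  }
  if (length(unique(species)) < 2L)
    stop("barcode gap needs at least two species")
  ids <- rownames(d)
  n <- length(ids)
  max_intra <- min_inter <- rep(NA_real_, n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    con <- which(species == species[[i]])
    con <- setdiff(con, i)
    het <- which(species != species[[i]])
    di <- d[i, con]
    max_intra[[i]] <- if (length(di) == 0L || all(is.na(di))) 0 else
      max(di, na.rm = TRUE)
    dh <- d[i, het]
    if (all(is.na(dh))) {
      excluded[[i]] <- TRUE
    } else {
      min_inter[[i]] <- min(dh, na.rm = TRUE)
    }
  }
  data.frame(id = ids, species = unname(species),
             max_intraspecific = max_intra, min_interspecific = min_inter,
             gap = min_inter - max_intra, excluded = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive the OTU clustering threshold from barcode gaps
#'
#' The threshold is one resolution step below the floored minimum gap over
#' non-excluded records: a minimum usable gap of 0.9% yields a 0.8%
#' threshold.  Taxa named in `excluded_taxa` (e.g. a species complex with
#' no usable gap) are ignored in the derivation, as are records flagged
#' `excluded` by [barcode_gap()].
#'
#' @param gap_records Output of [barcode_gap()].
#' @param excluded_taxa Character vector of species labels to ignore.
#' @param resolution Threshold granularity (default 0.001 = 0.1 K2P
#'   percentage points).
#' @return List of class `gp_threshold` with elements `threshold`,
#'   `min_gap`, `max_intraspecific` (over the records used) and `warning`
#'   (`NULL`, or a message when the threshold falls below the maximum
#'   intraspecific distance, in which case clustering at the threshold will
#'   split species into several OTUs).
#' @export
derive_otu_threshold <- function(gap_records, excluded_taxa = character(),
                                 resolution = 0.001) {
  use <- !gap_records$excluded & !(gap_records$species %in% excluded_taxa)
  if (!any(use)) stop("no non-excluded barcode-gap records")
  gaps <- gap_records$gap[use]
  min_gap <- min(gaps)
  if (min_gap <= resolution)
    stop("no usable barcode gap: minimum gap ", signif(min_gap, 3),
         " <= resolution ", resolution)
  k <- floor(min_gap / resolution + 1e-9)
  threshold <- (k - 1) * resolution
  max_intra <- max(gap_records$max_intraspecific[use])
  warn <- NULL
  if (threshold < max_intra)
    warn <- paste0("threshold ", threshold,
                   " is below the maximum intraspecific distance ",
                   signif(max_intra, 3),
                   "; species will be split across OTUs")
  structure(list(threshold = threshold, min_gap = min_gap,
                 max_intraspecific = max_intra, warning = warn),
            class = "gp_threshold")
}

#' @method print gp_threshold
#' @export
print.gp_threshold <- function(x, ...) {
  cat("OTU threshold:", x$threshold, "(min gap", signif(x$min_gap, 3),
      ")\n")
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}
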