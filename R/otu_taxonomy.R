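# OTU picking at the barcode-gap-derived threshold, taxonomy assignment by
# three independent methods (k-mer naive Bayes classifier, parsimony
# placement on the reference tree, bootstrapped neighbour joining on K2P
# distances), the consensus rules combining them, and aggregation of OTUs
# into species-level molecular taxa (MTs).

#' Cluster denoised centroids into OTUs
#'
#' Greedy abundance-sorted centroid clustering: processed in decreasing
#' abundance (ties to the longer sequence, then the smaller id), a sequence
#' joins the first OTU whose representative lies within
#' `distance_threshold` K2P distance.  Read counts are conserved.
#'
#' @param centroids A `gp_centroids` object (after chimera removal and
#'   frame correction).
#' @param distance_threshold Maximum K2P distance to the representative
#'   (default 0.008, the barcode-gap-derived value).
#' @param min_overlap Minimum comparable columns for a distance to count.
#' @return A `gp_otus` list: `otu_id`, `rep_seq` (alignment space),
#'   `rep_read`, `best_ref`, `abundance`, `counts` (OTU x sample),
#'   `members` (read-id vectors).
#' @export
cluster_otus <- function(centroids, distance_threshold = 0.008,
                         min_overlap = 50L) {
  samples <- colnames(centroids$counts)
  if (length(centroids$seqs) == 0L) {
    return(structure(list(
      otu_id = character(0), rep_seq = character(0),
      rep_read = character(0), best_ref = character(0),
      abundance = integer(0),
      counts = matrix(0L, 0L, length(samples),
                      dimnames = list(NULL, samples)),
      members = list()), class = "gp_otus"))
  }
  ncov <- nchar(gsub(".", "", centroids$seqs, fixed = TRUE))
  ord <- .cluster_order(centroids$abundance, ncov, centroids$seed_read)
  assign <- .gp_greedy_cluster(centroids$seqs, ord, distance_threshold,
                               k2p = TRUE, min_overlap = min_overlap)$assign
  reps <- sort(unique(assign))
  grp <- match(assign, reps)
  counts <- matrix(0L, length(reps), length(samples),
                   dimnames = list(NULL, samples))
  for (g in seq_along(reps))
    counts[g, ] <- as.integer(colSums(
      centroids$counts[grp == g, , drop = FALSE]))
  members <- lapply(seq_along(reps), function(g)
    unlist(centroids$members[grp == g], use.names = FALSE))
  abund <- as.integer(rowSums(counts))
  o <- order(-abund, centroids$seed_read[reps])
  ids <- sprintf("OTU_%04d", seq_along(reps))
  structure(list(
    otu_id = ids,
    rep_seq = stats::setNames(unname(centroids$seqs[reps][o]), ids),
    rep_read = centroids$seed_read[reps][o],
    best_ref = centroids$best_ref[reps][o],
    abundance = abund[o],
    counts = {
      m <- counts[o, , drop = FALSE]
      rownames(m) <- ids
      m
    },
    members = stats::setNames(members[o], ids)), class = "gp_otus")
}

#' @method print gp_otus
#' @export
print.gp_otus <- function(x, ...) {
  cat("OTU set:", length(x$otu_id), "OTUs,", sum(x$abundance), "reads,",
      ncol(x$counts), "samples\n")
  invisible(x)
}

.drop_otus <- function(otus, drop) {
  keep <- setdiff(seq_along(otus$otu_id), drop)
  structure(list(
    otu_id = otus$otu_id[keep], rep_seq = otus$rep_seq[keep],
    rep_read = otus$rep_read[keep], best_ref = otus$best_ref[keep],
    abundance = otus$abundance[keep],
    counts = otus$counts[keep, , drop = FALSE],
    members = otus$members[keep]), class = "gp_otus")
}

#' Remove singleton, chimeric and off-target OTUs
#'
#' The final OTU check: drops OTUs with a single read, OTUs flagged as
#' chimeric (e.g. by an OTU-level [detect_chimeras()] re-scan), and OTUs
#' whose consensus phylum differs from the target phylum; every removal is
#' tallied in a report.
#'
#' @param otus A `gp_otus` object.
#' @param assignments Named list of consensus lineages per OTU id.
#' @param target_phylum Phylum retained (default `Glomeromycota`).
#' @param chimera_flags Optional logical vector (one per OTU) of chimera
#'   verdicts.
#' @return List: `otus` (retained), `report` data.frame (`reason`,
#'   `n_otus`, `n_reads`) with reasons `singleton`, `chimera`,
#'   `offtarget`.
#' @export
remove_singletons_and_offtarget <- function(otus, assignments,
                                            target_phylum =
                                              GP_TARGET_PHYLUM,
                                            chimera_flags = NULL) {
  singleton <- otus$abundance <= 1L
  if (is.null(chimera_flags)) chimera_flags <- logical(length(singleton))
  chimera <- chimera_flags & !singleton
  phyla <- vapply(otus$otu_id, function(id) {
    lin <- assignments[[id]]
    if (is.null(lin) || length(lin) == 0L) NA_character_ else
      unname(lin[["phylum"]])
  }, character(1))
  offtarget <- !is.na(phyla) & phyla != target_phylum & !singleton &
    !chimera
  report <- data.frame(
    reason = c("singleton", "chimera", "offtarget"),
    n_otus = c(sum(singleton), sum(chimera), sum(offtarget)),
    n_reads = c(sum(otus$abundance[singleton]),
                sum(otus$abundance[chimera]),
                sum(otus$abundance[offtarget])),
    stringsAsFactors = FALSE)
  list(otus = .drop_otus(otus, which(singleton | chimera | offtarget)),
       report = report)
}

# ---- taxonomy assignment ----------------------------------------------------

.ungap <- function(x) gsub("[-.]", "", x)

.empty_assignment <- function(method) {
  list(method = method, lineage = character(0), confidence = 0)
}

#' Naive-Bayes k-mer classifier with bootstrap confidence
#'
#' Classifies a query sequence against the reference species by naive
#' Bayes over k-mer presence (Wang-style): the species score is the sum of
#' log-probabilities of the query's distinct k-mers, with word priors
#' shared across species.  Confidence per rank is the fraction of
#' `bootstraps` subsamples (each of 1/8 of the query k-mers, drawn with
#' replacement) whose winning species agrees at that rank; the lineage is
#' truncated at the deepest rank still reaching `min_conf`.
#'
#' @param query Query DNA string (gaps are removed).
#' @param refset Reference set with lineages.
#' @param k K-mer size.
#' @param bootstraps Number of bootstrap subsamples.
#' @param min_conf Minimum per-rank bootstrap confidence.
#' @return Assignment list: `method = "classifier"`, `lineage` (named
#'   character vector, possibly empty), `confidence` (at the deepest
#'   retained rank), `rank_confidence` (all ranks).
#' @export
classify_kmer_bayes <- function(query, refset, k = 8L, bootstraps = 100L,
                                min_conf = 0.80) {
  if (is.null(refset$lineages)) stop("reference set carries no lineages")
  q <- .ungap(query)
  if (nchar(q) < k) return(.empty_assignment("classifier"))
  qk <- unique(substring(q, 1:(nchar(q) - k + 1L), k:nchar(q)))
  qk <- qk[!grepl("N", qk, fixed = TRUE)]
  if (length(qk) == 0L) return(.empty_assignment("classifier"))
  min_shared <- 5L  # abstain without usable evidence

  refs <- .ungap(refset$seqs)
  species <- refset$species
  sp <- sort(unique(species))
  ref_kmers <- lapply(refs, function(s)
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))))
  dict <- unique(unlist(ref_kmers))
  N <- length(refs)
  n_w <- integer(length(dict))
  m_ws <- matrix(0L, length(dict), length(sp),
                 dimnames = list(NULL, sp))
  for (i in seq_along(refs)) {
    ix <- match(ref_kmers[[i]], dict)
    n_w[ix] <- n_w[ix] + 1L
    si <- match(species[[i]], sp)
    m_ws[ix, si] <- m_ws[ix, si] + 1L
  }
  M_s <- as.integer(table(factor(species, levels = sp)))
  prior <- (n_w + 0.5) / (N + 1)
  logp <- log(sweep(m_ws + prior, 2L, M_s + 1L, "/"))  # kmer x species
  # unseen words share the minimal prior
  logp_unseen <- log((0.5 / (N + 1)) / (M_s + 1L))
  if (sum(qk %in% dict) < min_shared)
    return(.empty_assignment("classifier"))

  score_kmers <- function(kset) {
    ix <- match(kset, dict)
    seen <- !is.na(ix)
    s <- if (any(seen)) colSums(logp[ix[seen], , drop = FALSE]) else
      numeric(length(sp))
    s + sum(!seen) * logp_unseen
  }
  winner <- function(kset) sp[which.max(score_kmers(kset))]
  top <- winner(qk)
  nb <- max(1L, ceiling(length(qk) / 8))
  boot_win <- vapply(seq_len(bootstraps), function(b)
    winner(qk[sample.int(length(qk), nb, replace = TRUE)]), character(1))
  top_lin <- refset$lineages[[match(top, species)]]
  conf <- vapply(seq_along(top_lin), function(d) {
    mean(vapply(boot_win, function(w) {
      wl <- refset$lineages[[match(w, species)]]
      length(wl) >= d && identical(unname(wl[[d]]), unname(top_lin[[d]]))
    }, logical(1)))
  }, numeric(1))
  depth <- 0L
  for (d in seq_along(conf)) {
    if (conf[[d]] >= min_conf) depth <- d else break
  }
  if (depth == 0L) return(.empty_assignment("classifier"))
  out <- .empty_assignment("classifier")
  out$lineage <- top_lin[seq_len(depth)]
  out$confidence <- conf[[depth]]
  out$rank_confidence <- stats::setNames(conf, names(top_lin))
  out
}

# longest common prefix of a list of lineages (named character vectors)
.shared_lineage <- function(lins) {
  lins <- lins[lengths(lins) > 0L]
  if (length(lins) == 0L) return(character(0))
  d <- 0L
  repeat {
    nd <- d + 1L
    if (any(lengths(lins) < nd)) break
    vals <- vapply(lins, function(l) unname(l[[nd]]), character(1))
    if (length(unique(vals)) > 1L) break
    d <- nd
  }
  lins[[1L]][seq_len(d)]
}

# lineage label of the smallest labelled clade at-or-above `node`
.clade_lineage <- function(tree, node, refset) {
  ntip <- ape::Ntip(tree)
  repeat {
    leaves <- if (node <= ntip) tree$tip.label[node] else
      ape::extract.clade(tree, node)$tip.label
    leaves <- intersect(leaves, names(refset$seqs))
    lin <- .shared_lineage(refset$lineages[leaves])
    if (length(lin)) return(lin)
    parent <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (length(parent) == 0L) return(character(0))
    node <- parent
  }
}

#' Taxonomy by parsimony placement on the reference tree
#'
#' Attaches the query to every edge of the reference tree in turn and
#' scores each insertion by Fitch parsimony over the aligned columns; the
#' edge minimising the added score wins.  The assignment is the lineage of
#' the smallest labelled clade containing the chosen edge (the shared
#' lineage of the clade's references); for a pendant edge this is the
#' leaf's own lineage.  Confidence is `1 - (ties - 1)/edges`.
#'
#' @param query Alignment-space query string (same columns as the
#'   reference alignment).
#' @param tree Reference tree (`phylo`; leaves are reference ids).
#' @param refset Reference set with lineages.
#' @param min_cols Queries aligned to fewer reference columns are returned
#'   unassigned.
#' @return Assignment list: `method = "placement"`, `lineage`,
#'   `confidence`, `edge` (1-based row of `tree$edge`).
#' @export
assign_by_placement <- function(query, tree, refset, min_cols = 50L) {
  qv <- strsplit(query, "", fixed = TRUE)[[1]]
  ok_cols <- qv %in% DNA_BASES
  if (sum(ok_cols) < min_cols) return(.empty_assignment("placement"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  ids <- tree$tip.label
  if (!all(ids %in% names(refset$seqs)))
    stop("reference tree leaves missing from the alignment: ",
         paste(setdiff(ids, names(refset$seqs)), collapse = ", "))
  mat <- do.call(rbind, c(
    lapply(refset$seqs[ids],
           function(s) strsplit(s, "", fixed = TRUE)[[1]]),
    list(query = qv)))
  mat[!mat %in% c("A", "C", "G", "T")] <- "?"
  dat <- phangorn::phyDat(mat, type = "DNA")
  n_edge <- nrow(tree$edge)
  scores <- vapply(seq_len(n_edge), function(e) {
    child <- tree$edge[e, 2L]
    pos <- tree$edge.length[e] / 2
    t2 <- phytools::bind.tip(tree, "query", edge.length = pos,
                             where = child, position = pos)
    phangorn::parsimony(t2, dat)
  }, numeric(1))
  best <- which(scores == min(scores))
  e <- best[[1L]]
  if (length(best) > 1L) {
    # parsimony ties are common around the root, where attachments are
    # unrooted-equivalent; break them towards the clade whose sequences
    # are closest to the query
    ntip <- ape::Ntip(tree)
    prox <- vapply(best, function(ei) {
      node <- tree$edge[ei, 2L]
      leaves <- if (node <= ntip) tree$tip.label[node] else
        ape::extract.clade(tree, node)$tip.label
      dmin <- suppressWarnings(min(vapply(leaves, function(l)
        p_distance(query, refset$seqs[[l]]), numeric(1)), na.rm = TRUE))
      if (is.finite(dmin)) dmin else 1
    }, numeric(1))
    e <- best[[which.min(prox)]]
  }
  out <- .empty_assignment("placement")
  out$lineage <- .clade_lineage(tree, tree$edge[e, 2L], refset)
  out$confidence <- 1 - (length(best) - 1) / n_edge
  out$edge <- e
  out
}

# K2P distance matrix from an integer-coded character matrix restricted to
# `cols` (used by the NJ bootstrap)
.k2p_matrix_codes <- function(codes, cols) {
  m <- codes[, cols, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n - 1L)) {
    a <- m[i, ]
    for (j in seq.int(i + 1L, n)) {
      b <- m[j, ]
      comp <- a > 0L & b > 0L
      ts <- .is_transition(a, b) & comp
      tv <- comp & (a != b) & !ts
      d[i, j] <- d[j, i] <- .k2p_from_counts(sum(comp), sum(ts), sum(tv))
    }
  }
  d
}

# replace undefined distances by 1.2x the largest defined one so NJ can run
.fill_undefined <- function(d) {
  if (!anyNA(d)) return(d)
  mx <- suppressWarnings(max(d, na.rm = TRUE))
  if (!is.finite(mx)) return(d)
  d[is.na(d)] <- 1.2 * mx
  d
}

#' Taxonomy by bootstrapped neighbour joining
#'
#' Builds an NJ tree of the references plus the query from K2P distances,
#' roots it at the reference farthest from the query, and walks up from the
#' query: the first enclosing clade whose bootstrap support (over
#' `bootstraps` column resamples) reaches `min_support` provides the
#' assignment as the shared lineage of its references.
#'
#' @param query Alignment-space query string.
#' @param refset Reference set with lineages (>= 4 references).
#' @param bootstraps Bootstrap replicates.
#' @param min_support Minimum clade support.
#' @return Assignment list: `method = "nj"`, `lineage`, `confidence` (the
#'   supporting clade's bootstrap fraction).
#' @export
assign_by_nj <- function(query, refset, bootstraps = 100L,
                         min_support = 0.70) {
  if (length(refset$seqs) < 4L) stop("NJ assignment needs >= 4 references")
  seqs <- c(refset$seqs, query = query)
  codes <- .code_matrix(seqs)
  full <- .k2p_matrix_codes(codes, seq_len(ncol(codes)))
  qd <- full["query", colnames(full) != "query"]
  if (all(is.na(qd))) return(.empty_assignment("nj"))
  full <- .fill_undefined(full)
  main <- ape::nj(as.dist(full))
  og <- names(refset$seqs)[which.max(qd[names(refset$seqs)])]
  main <- ape::root(main, outgroup = og, resolve.root = TRUE)
  boot <- vector("list", bootstraps)
  L <- ncol(codes)
  for (b in seq_len(bootstraps)) {
    cols <- sample.int(L, L, replace = TRUE)
    db <- .fill_undefined(.k2p_matrix_codes(codes, cols))
    if (anyNA(db)) db[is.na(db)] <- 1
    tb <- ape::nj(as.dist(db))
    boot[[b]] <- ape::root(tb, outgroup = og, resolve.root = TRUE)
  }
  supp <- ape::prop.clades(main, boot, rooted = FALSE)
  supp[is.na(supp)] <- 0L
  ntip <- ape::Ntip(main)
  node <- main$edge[main$edge[, 2L] == which(main$tip.label == "query"), 1L]
  while (length(node)) {
    s <- if (node == ntip + 1L) bootstraps else supp[[node - ntip]]
    leaves <- setdiff(ape::extract.clade(main, node)$tip.label, "query")
    if (s / bootstraps >= min_support && length(leaves)) {
      lin <- .shared_lineage(refset$lineages[leaves])
      if (length(lin)) {
        out <- .empty_assignment("nj")
        out$lineage <- lin
        out$confidence <- s / bootstraps
        return(out)
      }
    }
    node <- main$edge[main$edge[, 2L] == node, 1L]
  }
  .empty_assignment("nj")
}

# ---- consensus --------------------------------------------------------------

.prefix_compatible <- function(a, b) {
  d <- min(length(a), length(b))
  d == 0L || identical(unname(a[seq_len(d)]), unname(b[seq_len(d)]))
}

#' Consensus of the three taxonomy assignments
#'
#' Combines classifier, placement and NJ assignments: when the two
#' tree-based methods agree (one lineage a prefix of the other) the deeper
#' tree lineage is preferred and may refine the classifier; when they
#' disagree, placement outranks NJ; when the classifier contradicts the
#' preferred tree lineage, the result is truncated to the deepest rank on
#' which all non-overruled assignments agree.
#'
#' @param a_classifier,a_placement,a_nj Assignment lists (from the three
#'   `classify_*`/`assign_*` functions); empty assignments are ignored.
#' @return List: `lineage` (possibly empty), `rule` (one of `all_empty`,
#'   `tree`, `classifier_only`, `placement_over_nj`, `lca`).
#' @export
consensus_assignment <- function(a_classifier, a_placement, a_nj) {
  cl <- a_classifier$lineage
  pl <- a_placement$lineage
  nj <- a_nj$lineage
  if (!length(cl) && !length(pl) && !length(nj))
    return(list(lineage = character(0), rule = "all_empty"))
  if (length(pl) && length(nj)) {
    if (.prefix_compatible(pl, nj)) {
      tree_lin <- if (length(pl) >= length(nj)) pl else nj
      tree_rule <- "tree"
    } else {
      tree_lin <- pl
      nj <- character(0)  # overruled
      tree_rule <- "placement_over_nj"
    }
  } else if (length(pl) || length(nj)) {
    tree_lin <- if (length(pl)) pl else nj
    tree_rule <- "tree"
  } else {
    return(list(lineage = cl, rule = "classifier_only"))
  }
  if (!length(cl) || .prefix_compatible(cl, tree_lin)) {
    lineage <- if (length(cl) > length(tree_lin)) cl else tree_lin
    return(list(lineage = lineage, rule = tree_rule))
  }
  list(lineage = .shared_lineage(list(cl, tree_lin, nj)[c(TRUE, TRUE,
                                                          length(nj) > 0L)]),
       rule = "lca")
}

#' Assign taxonomy to every OTU by all three methods plus consensus
#'
#' @param otus A `gp_otus` object.
#' @param refset Reference set with lineages.
#' @param tree Reference tree for placement.
#' @param k,bootstraps,min_conf Classifier settings.
#' @param nj_bootstraps,min_support NJ settings.
#' @return List: `lineages` (named list per OTU), `audit` data.frame with
#'   the three method lineages, confidences, consensus and rule fired.
#' @export
assign_taxonomy <- function(otus, refset, tree, k = 8L, bootstraps = 100L,
                            min_conf = 0.80, nj_bootstraps = 100L,
                            min_support = 0.70) {
  n <- length(otus$otu_id)
  lineages <- stats::setNames(vector("list", n), otus$otu_id)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    q <- otus$rep_seq[[i]]
    a_cl <- classify_kmer_bayes(.ungap(q), refset, k = k,
                                bootstraps = bootstraps,
                                min_conf = min_conf)
    a_pl <- assign_by_placement(q, tree, refset)
    a_nj <- assign_by_nj(q, refset, bootstraps = nj_bootstraps,
                         min_support = min_support)
    cons <- consensus_assignment(a_cl, a_pl, a_nj)
    lineages[[i]] <- cons$lineage
    rows[[i]] <- data.frame(
      otu_id = otus$otu_id[[i]],
      classifier = lineage_string(a_cl$lineage),
      classifier_conf = a_cl$confidence,
      placement = lineage_string(a_pl$lineage),
      placement_conf = a_pl$confidence,
      nj = lineage_string(a_nj$lineage),
      nj_conf = a_nj$confidence,
      consensus = lineage_string(cons$lineage),
      rule = cons$rule, stringsAsFactors = FALSE)
  }
  list(lineages = lineages, audit = do.call(rbind, rows))
}

# ---- molecular taxa ---------------------------------------------------------

#' Aggregate OTUs into species-level molecular taxa
#'
#' OTUs sharing the same deepest-named consensus lineage merge into one MT,
#' named at species level where available and `"<deepest taxon> sp."`
#' otherwise.  An alias table can merge sibling species indistinguishable
#' on short reads into a single MT.
#'
#' @param otus A `gp_otus` object.
#' @param lineages Named list of consensus lineages per OTU id.
#' @param aliases Optional named character vector mapping species names to
#'   a merged MT name (e.g. both members of a sibling pair to
#'   `"A sp1/sp2"`).
#' @return List: `mts` data.frame (`mt_name`, `rank`, `n_otus`,
#'   `n_reads`), `mapping` named character vector OTU id -> MT name.
#' @export
aggregate_to_mts <- function(otus, lineages, aliases = NULL) {
  if (length(otus$otu_id) == 0L)
    return(list(mts = data.frame(mt_name = character(0),
                                 rank = character(0),
                                 n_otus = integer(0),
                                 n_reads = integer(0)),
                mapping = character(0)))
  mt_of <- vapply(otus$otu_id, function(id) {
    lin <- lineages[[id]]
    if (is.null(lin) || length(lin) == 0L) return("Unclassified sp.")
    deepest <- unname(lin[[length(lin)]])
    rank <- names(lin)[[length(lin)]]
    if (rank == "species") {
      if (!is.null(aliases) && deepest %in% names(aliases))
        return(unname(aliases[[deepest]]))
      return(deepest)
    }
    paste(deepest, "sp.")
  }, character(1))
  rank_of <- vapply(otus$otu_id, function(id) {
    lin <- lineages[[id]]
    if (is.null(lin) || length(lin) == 0L) return("unassigned")
    names(lin)[[length(lin)]]
  }, character(1))
  agg <- data.frame(mt_name = mt_of, rank = rank_of,
                    reads = otus$abundance, stringsAsFactors = FALSE)
  sp <- split(agg, agg$mt_name)
  mts <- do.call(rbind, lapply(sp, function(g) data.frame(
    mt_name = g$mt_name[[1L]], rank = g$rank[[1L]], n_otus = nrow(g),
    n_reads = sum(g$reads), stringsAsFactors = FALSE)))
  mts <- mts[order(-mts$n_reads, mts$mt_name), ]
  rownames(mts) <- NULL
  list(mts = mts, mapping = mt_of)
}
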