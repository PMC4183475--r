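# Read-processing cascade: demultiplex -> length/ambiguity filter ->
# reference alignment screen -> precluster -> chimera detection -> frame
# correction.  The cascade order is fixed; every stage reports read counts
# in/out so the pipeline can assemble a funnel table.
#
# After the alignment screen all sequences live in reference-alignment
# space: a string with one character per alignment column ('.' outside the
# read, '-' a deletion relative to the reference) plus a record of inserted
# bases keyed by alignment column.  This common coordinate system is what
# makes preclustering, chimera scanning, frame correction and OTU picking
# cheap column operations.

#' Demultiplex barcoded reads
#'
#' Assigns each read to the sample whose barcode matches the read prefix
#' with at most `max_mismatch` mismatches (the >= 4-mismatch barcode design
#' makes the nearest barcode unique at 1 mismatch), then trims barcode and
#' forward primer.
#'
#' @param reads Named character vector of raw reads.
#' @param sample_map Sample map (see [read_sample_map()]).
#' @param primer Forward primer sequence trimmed after the barcode.
#' @param max_mismatch Maximum barcode mismatches for assignment.
#' @return List: `reads` data.frame (`read_id`, `sample_id`, `seq` trimmed,
#'   `raw_length`), `unassigned` character vector of read ids.
#' @export
demultiplex <- function(reads, sample_map, primer = GP_FWD_PRIMER,
                        max_mismatch = 1L) {
  validate_sample_map(sample_map)
  bl <- nchar(sample_map$barcode[[1L]])
  pl <- nchar(primer)
  raw_len <- nchar(reads)
  long_enough <- raw_len >= bl + pl
  pre <- substr(reads, 1L, bl)
  mm <- matrix(0L, length(reads), nrow(sample_map))
  for (p in seq_len(bl)) {
    rc <- substr(pre, p, p)
    for (b in seq_len(nrow(sample_map))) {
      mm[, b] <- mm[, b] +
        (rc != substr(sample_map$barcode[[b]], p, p))
    }
  }
  best <- max.col(-mm, ties.method = "first")
  best_mm <- mm[cbind(seq_along(reads), best)]
  ok <- long_enough & best_mm <= max_mismatch
  df <- data.frame(
    read_id = names(reads)[ok],
    sample_id = sample_map$sample_id[best[ok]],
    seq = unname(substr(reads[ok], bl + pl + 1L, raw_len[ok])),
    raw_length = unname(raw_len[ok]),
    stringsAsFactors = FALSE)
  list(reads = df, unassigned = names(reads)[!ok])
}

#' Length and ambiguity filter
#'
#' Keeps reads whose raw length (including barcode, primer and adapter,
#' as in the printed sequence accounting) is at least `min_len` and whose
#' trimmed sequence contains no ambiguous base.  Set
#' `length_includes_prefix = FALSE` to apply the cutoff to the trimmed
#' length instead.
#'
#' @param reads Data.frame from [demultiplex()].
#' @param min_len Minimum length in bp.
#' @param length_includes_prefix Apply `min_len` to the raw read
#'   (default) or to the trimmed sequence.
#' @return Filtered data.frame.
#' @export
length_ambiguity_filter <- function(reads, min_len = 200L,
                                    length_includes_prefix = TRUE) {
  len <- if (length_includes_prefix) reads$raw_length else nchar(reads$seq)
  keep <- len >= min_len & !grepl("N", reads$seq, fixed = TRUE)
  reads[keep, , drop = FALSE]
}

# ---- alignment screen -------------------------------------------------------

# k-mer sets of the ungapped reference sequences, as a sparse kmer x ref
# incidence matrix plus the dictionary
.ref_kmer_index <- function(ref_ungapped, k) {
  all_kmers <- lapply(ref_ungapped, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  dict <- unique(unlist(all_kmers))
  i <- match(unlist(all_kmers), dict)
  j <- rep(seq_along(all_kmers), lengths(all_kmers))
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(dict), length(all_kmers)))
  list(dict = dict, M = M)
}

#' Screen reads against the reference alignment
#'
#' Each distinct read sequence is matched to its best reference by shared
#' 8-mers, then globally aligned to that reference (free end gaps on the
#' reference side).  Identity is matches over aligned read columns; reads
#' under `min_similarity` are discarded.  Kept reads are projected into
#' reference-alignment coordinates.
#'
#' @param reads Data.frame from [length_ambiguity_filter()].
#' @param refset Reference [reference_set()] (the alignment to screen
#'   against).
#' @param min_similarity Minimum alignment identity to keep a read.
#' @param k K-mer size of the prescreen.
#' @return List: `reads` (input rows kept, plus `best_ref` and `identity`
#'   columns), `aligned` (named character vector: per kept read id, the
#'   alignment-space sequence), `insertions` (named list of
#'   `data.frame(col, base)` per read id with insertions).
#' @export
alignment_screen <- function(reads, refset, min_similarity = 0.60, k = 8L) {
  stopifnot(inherits(refset, "gp_reference_set"))
  if (nrow(reads) == 0L)
    return(list(reads = cbind(reads, best_ref = character(0),
                              identity = numeric(0)),
                aligned = character(0), insertions = list()))
  ref_aln <- refset$seqs
  L_aln <- nchar(ref_aln[[1L]])
  ref_ungapped <- gsub("-", "", ref_aln, fixed = TRUE)
  # ungapped position -> alignment column, per reference
  colmap <- lapply(ref_aln, function(s)
    which(strsplit(s, "", fixed = TRUE)[[1]] != "-"))

  uniq <- unique(reads$seq)
  ui <- match(reads$seq, uniq)

  idx <- .ref_kmer_index(ref_ungapped, k)
  n <- nchar(uniq)
  starts <- lapply(n, function(m) if (m >= k) 1:(m - k + 1L) else integer(0))
  read_kmers <- substring(rep(uniq, lengths(starts)), unlist(starts),
                          unlist(starts) + k - 1L)
  rk_read <- rep(seq_along(uniq), lengths(starts))
  hit <- match(read_kmers, idx$dict)
  keep <- !is.na(hit)
  R <- Matrix::sparseMatrix(i = rk_read[keep], j = hit[keep], x = 1,
                            dims = c(length(uniq), length(idx$dict)))
  shared <- as.matrix(R %*% idx$M)
  best_ref_i <- max.col(shared, ties.method = "first")

  aligned_u <- character(length(uniq))
  ins_u <- vector("list", length(uniq))
  ident_u <- numeric(length(uniq))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE)
  for (r in sort(unique(best_ref_i))) {
    sel <- which(best_ref_i == r)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(uniq[sel]),
      subject = Biostrings::DNAString(ref_ungapped[[r]]),
      type = "global-local", substitutionMatrix = sub_mat,
      gapOpening = 4, gapExtension = 2)
    # aligned() gives the pattern in subject coordinates (insertions
    # removed, deletion gaps kept, '-' padding outside the aligned range)
    al <- as.character(Biostrings::aligned(aln))
    s0 <- Biostrings::start(Biostrings::subject(aln))
    e0 <- Biostrings::end(Biostrings::subject(aln))
    nm <- Biostrings::nmatch(aln)
    n_ins <- Biostrings::insertion(Biostrings::nindel(aln))[, "WidthSum"]
    cmap <- colmap[[r]]
    for (q in seq_along(sel)) {
      ident_u[[sel[[q]]]] <- nm[[q]] /
        (e0[[q]] - s0[[q]] + 1L + n_ins[[q]])
      v <- strsplit(al[[q]], "", fixed = TRUE)[[1]]
      pos <- seq_along(v)
      v[pos < s0[[q]] | pos > e0[[q]]] <- "."
      full <- rep(".", L_aln)
      full[cmap] <- v
      aligned_u[[sel[[q]]]] <- paste(full, collapse = "")
    }
    # inserted bases (rare): recover their location from the full
    # alignment strings of just those reads
    with_ins <- which(n_ins > 0L)
    if (length(with_ins)) {
      pat <- as.character(Biostrings::alignedPattern(aln[with_ins]))
      sbj <- as.character(Biostrings::alignedSubject(aln[with_ins]))
      for (w in seq_along(with_ins)) {
        q <- with_ins[[w]]
        ps <- strsplit(pat[[w]], "", fixed = TRUE)[[1]]
        ss <- strsplit(sbj[[w]], "", fixed = TRUE)[[1]]
        refadv <- ss != "-"
        refpos <- s0[[q]] - 1L + cumsum(refadv)
        at <- refpos[!refadv]  # subject position after which each sits
        ins_u[[sel[[q]]]] <- data.frame(
          col = ifelse(at >= 1L, cmap[pmax(at, 1L)], 0L),
          base = ps[!refadv], stringsAsFactors = FALSE)
      }
    }
  }
  keep_u <- ident_u >= min_similarity
  keep_r <- keep_u[ui]
  out <- reads[keep_r, , drop = FALSE]
  out$best_ref <- names(ref_aln)[best_ref_i[ui[keep_r]]]
  out$identity <- ident_u[ui[keep_r]]
  aligned <- stats::setNames(aligned_u[ui[keep_r]], out$read_id)
  insertions <- stats::setNames(ins_u[ui[keep_r]], out$read_id)
  insertions <- insertions[!vapply(insertions, is.null, logical(1))]
  list(reads = out, aligned = aligned, insertions = insertions)
}

# ---- preclustering ----------------------------------------------------------

# processing order for greedy clustering: abundance desc, then longer
# (more covered columns), then lexicographic id
.cluster_order <- function(abund, ncov, ids) {
  order(-abund, -ncov, ids)
}

#' Greedy precluster of aligned reads
#'
#' Deduplicates alignment-space sequences, then clusters them greedily in
#' abundance order: a sequence joins the first centroid within
#' `1 - similarity` mismatch distance over their shared columns (ties in
#' abundance break to the longer sequence, then the smaller id).  Per-sample
#' abundances are preserved on the centroids; total abundance is conserved.
#'
#' @param screened Output of [alignment_screen()].
#' @param similarity Minimum identity for a sequence to join a centroid
#'   (paper value 0.997).
#' @param min_overlap Minimum shared columns for a comparison.
#' @return A `gp_centroids` list: `seqs` (alignment-space strings),
#'   `insertions`, `seed_read`, `best_ref`, `abundance`, `counts`
#'   (centroid x sample matrix), `members` (list of read-id vectors).
#' @export
precluster <- function(screened, similarity = 0.997, min_overlap = 100L) {
  reads <- screened$reads
  samples <- sort(unique(reads$sample_id))
  if (nrow(reads) == 0L) {
    return(structure(list(
      seqs = character(0), insertions = list(), seed_read = character(0),
      best_ref = character(0), abundance = integer(0),
      counts = matrix(0L, 0L, length(samples),
                      dimnames = list(NULL, samples)),
      members = list()), class = "gp_centroids"))
  }
  key <- screened$aligned[reads$read_id]
  uniq <- unique(key)
  ui <- match(key, uniq)
  first_read <- reads$read_id[match(seq_along(uniq), ui)]
  abund <- tabulate(ui, length(uniq))
  ncov <- nchar(gsub(".", "", uniq, fixed = TRUE))
  ord <- .cluster_order(abund, ncov, first_read)
  res <- .gp_greedy_cluster(uniq, ord, 1 - similarity, k2p = FALSE,
                            min_overlap = min_overlap, extend = TRUE)
  assign <- res$assign
  cent_idx <- sort(unique(assign))
  # coverage-extended centroid sequences, keyed by founding sequence index
  ext <- stats::setNames(as.character(res$centroid_seq),
                         res$centroid_index)
  cmap <- match(assign, cent_idx)  # unique seq -> centroid number
  read_cent <- cmap[ui]
  counts <- matrix(0L, length(cent_idx), length(samples),
                   dimnames = list(NULL, samples))
  tab <- table(read_cent, factor(reads$sample_id, levels = samples))
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  seed_ids <- first_read[cent_idx]
  structure(list(
    seqs = stats::setNames(unname(ext[as.character(cent_idx)]), seed_ids),
    insertions = stats::setNames(
      lapply(seed_ids, function(id) screened$insertions[[id]]), seed_ids),
    seed_read = seed_ids,
    best_ref = reads$best_ref[match(seed_ids, reads$read_id)],
    abundance = as.integer(rowSums(counts)),
    counts = counts,
    members = split(reads$read_id, read_cent)), class = "gp_centroids")
}

#' @method print gp_centroids
#' @export
print.gp_centroids <- function(x, ...) {
  cat("Centroid set:", length(x$seqs), "centroids,", sum(x$abundance),
      "reads,", ncol(x$counts), "samples\n")
  invisible(x)
}

# drop centroids by index, keeping the structure consistent
.drop_centroids <- function(cent, drop) {
  if (!length(drop)) return(cent)
  keep <- setdiff(seq_along(cent$seqs), drop)
  structure(list(
    seqs = cent$seqs[keep], insertions = cent$insertions[keep],
    seed_read = cent$seed_read[keep], best_ref = cent$best_ref[keep],
    abundance = cent$abundance[keep],
    counts = cent$counts[keep, , drop = FALSE],
    members = cent$members[keep]), class = "gp_centroids")
}

#' De novo two-parent chimera detection
#'
#' Scans centroids in ascending abundance for single-crossover two-parent
#' models built from centroids at least `skew` times more abundant.  A
#' centroid is flagged chimeric when the best model identity reaches
#' `min_ident`, improves on the best single parent by `min_margin`, and
#' both parents contribute at least `min_parent_bases` read positions.
#'
#' @param centroids A `gp_centroids` object.
#' @param skew Minimum parent/query abundance ratio.
#' @param min_ident Minimum two-parent model identity.
#' @param min_margin Required improvement over the best single parent.
#' @param min_parent_bases Minimum per-parent contribution.
#' @return `data.frame` with one row per centroid: `seed_read`, `flagged`,
#'   `parent_a`, `parent_b` (seed read ids), `crossover_col`,
#'   `model_identity`, `single_identity`.
#' @export
detect_chimeras <- function(centroids, skew = 2.0, min_ident = 0.99,
                            min_margin = 0.01, min_parent_bases = 30L) {
  v <- .gp_chimera_scan(centroids$seqs, as.numeric(centroids$abundance),
                        skew = skew, min_ident = min_ident,
                        min_margin = min_margin,
                        min_parent_bases = min_parent_bases)
  data.frame(
    seed_read = centroids$seed_read,
    flagged = v$flagged,
    parent_a = ifelse(is.na(v$parent_a), NA_character_,
                      centroids$seed_read[v$parent_a]),
    parent_b = ifelse(is.na(v$parent_b), NA_character_,
                      centroids$seed_read[v$parent_b]),
    crossover_col = v$crossover_col,
    model_identity = v$model_identity,
    single_identity = v$single_identity,
    stringsAsFactors = FALSE)
}

# ---- frame correction -------------------------------------------------------

# homopolymer runs (length >= min_run) of a reference in alignment space,
# restricted to exon columns; returns list of (cols, base)
.ref_homopolymer_runs <- function(ref_aln_seq, exon_cols, min_run = 3L) {
  v <- strsplit(ref_aln_seq, "", fixed = TRUE)[[1]]
  is_exon <- logical(length(v))
  is_exon[exon_cols] <- TRUE
  runs <- list()
  i <- 1L
  L <- length(v)
  while (i <= L) {
    if (!(v[[i]] %in% DNA_BASES) || !is_exon[[i]]) { i <- i + 1L; next }
    j <- i
    while (j < L && v[[j + 1L]] == v[[i]] && is_exon[[j + 1L]]) j <- j + 1L
    if (j - i + 1L >= min_run)
      runs[[length(runs) + 1L]] <- list(cols = i:j, base = v[[i]])
    i <- j + 1L
  }
  runs
}

#' Homopolymer frame-shift correction
#'
#' Aligns each centroid against its best reference (already available in
#' alignment space), and inside exon regions repairs homopolymer runs
#' (reference run length >= 3) where the read differs by exactly one base:
#' a missing base is re-inserted, a surplus base removed.  Intron columns
#' are never edited.  After correction the exon translation is checked in
#' the annotated frame: centroids with remaining frame shifts or in-frame
#' stop codons are flagged for discard; centroids with no exon overlap
#' pass through flagged `no_exon`.
#'
#' @param centroids A `gp_centroids` object.
#' @param refset Reference set providing the aligned references.
#' @param annotation Region annotation over the reference alignment
#'   (defaults to the one carried by `refset`).
#' @return List: `centroids` (corrected sequences, discarded centroids
#'   removed), `flags` data.frame (`seed_read`, `status` in
#'   `ok`/`frameshift`/`stop_codon`/`no_exon`, `n_inserted`, `n_deleted`),
#'   `discarded` (`gp_centroids` of the removed ones).
#' @export
frame_correct <- function(centroids, refset, annotation = NULL) {
  annotation <- annotation %||% refset$annotation
  if (is.null(annotation)) stop("no region annotation available")
  L <- nchar(refset$seqs[[1L]])
  labels <- region_labels(annotation, L)
  exon_cols <- which(labels == "exon")
  frame <- attr(annotation, "frame")
  # exon index (1-based position within the concatenated exon stretch)
  exon_rank <- integer(L)
  exon_rank[exon_cols] <- seq_along(exon_cols)

  run_cache <- list()
  n <- length(centroids$seqs)
  status <- character(n)
  n_ins <- integer(n)
  n_del <- integer(n)
  new_seqs <- centroids$seqs
  new_ins <- centroids$insertions
  for (ci in seq_len(n)) {
    ref_id <- centroids$best_ref[[ci]]
    if (is.null(run_cache[[ref_id]]))
      run_cache[[ref_id]] <- .ref_homopolymer_runs(refset$seqs[[ref_id]],
                                                   exon_cols)
    runs <- run_cache[[ref_id]]
    v <- strsplit(centroids$seqs[[ci]], "", fixed = TRUE)[[1]]
    ins <- centroids$insertions[[ci]]
    cov <- which(v != ".")
    cov_exon <- intersect(cov, exon_cols)
    if (length(cov_exon) < 3L) {
      status[[ci]] <- "no_exon"
      next
    }
    for (run in runs) {
      rc <- run$cols
      if (any(v[rc] == ".")) next  # run not fully covered
      n_b <- sum(v[rc] == run$base)
      gaps <- which(v[rc] == "-")
      run_ins <- if (is.null(ins)) integer(0) else
        which(ins$base == run$base &
              ins$col >= rc[[1L]] - 1L & ins$col <= rc[[length(rc)]])
      if (length(gaps) == 1L && n_b == length(rc) - 1L &&
          length(run_ins) == 0L) {
        v[rc[gaps]] <- run$base               # re-insert the missing base
        n_ins[[ci]] <- n_ins[[ci]] + 1L
      } else if (length(gaps) == 0L && n_b == length(rc) &&
                 length(run_ins) == 1L) {
        ins <- ins[-run_ins[[1L]], , drop = FALSE]  # drop the surplus base
        n_del[[ci]] <- n_del[[ci]] + 1L
      }
    }
    if (!is.null(ins) && nrow(ins) == 0L) ins <- NULL
    # remaining exon indels -> frame shift?
    del_left <- sum(v[cov_exon] == "-")
    ins_left <- if (is.null(ins)) 0L else
      sum(ins$col %in% exon_cols | (ins$col + 1L) %in% exon_cols)
    new_seqs[[ci]] <- paste(v, collapse = "")
    new_ins[ci] <- list(ins)
    if ((ins_left - del_left) %% 3L != 0L) {
      status[[ci]] <- "frameshift"
      next
    }
    # translate the covered exon stretch in the annotated frame
    chars <- v[cov_exon]
    keep <- chars %in% DNA_BASES
    exseq <- paste(chars[keep], collapse = "")
    e0 <- exon_rank[[cov_exon[[1L]]]]
    off <- (3L - ((e0 - 1L - frame) %% 3L)) %% 3L
    if (.has_stop(exseq, off)) {
      status[[ci]] <- "stop_codon"
      next
    }
    status[[ci]] <- "ok"
  }
  flags <- data.frame(seed_read = centroids$seed_read, status = status,
                      n_inserted = n_ins, n_deleted = n_del,
                      stringsAsFactors = FALSE)
  out <- centroids
  out$seqs <- new_seqs
  out$insertions <- new_ins
  bad <- which(!status %in% c("ok", "no_exon"))
  list(centroids = .drop_centroids(out, bad), flags = flags,
       discarded = .drop_centroids(out, setdiff(seq_len(n), bad)))
}
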