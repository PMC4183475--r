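# Synthetic-data generator: reference sets evolved on a species tree under
# a K2P substitution process with faster-evolving introns, and barcoded
# pyrosequencing-style community reads with per-read ground truth
# (substitution errors, homopolymer-length indels, single-crossover
# chimeras, treatment x plot community design).
#
# Everything is driven by `sim_config()`; identical seed + config gives
# byte-identical output.

# Conserved primer-binding sites (the first/last 20 marker columns).  Both
# are stop-codon-free in the simulated reading frame.
GP_FWD_PRIMER <- "ATGGCTCGTGAAGGTATCCA"
GP_REV_SITE <- "GGTCACGGTCGTCAAGCTAT"

# Multiplexing barcodes: 9 bp, every pair >= 4 mismatches apart, no
# homopolymer run of 3+.
GP_BARCODES <- c(
  "TTCCATGAA", "CTCCTCTTA", "GCAGCACTG", "CAATAATCA", "GGTCTGCGA",
  "TGCACGCTA", "AGGCATCGC", "TTAGGATGC", "GTGACCGTA", "ATCCTCGCC",
  "GGAGTTGTG", "AGTGTGAAT", "TTGCGTAAG", "GATATTAAG", "GTGCGTTGA",
  "GAGGCTGGC", "CGTATTCCA", "TTGCTAACC", "ACATTAGCA", "AGTCGGCTC",
  "AACCAGTCT", "TTATTAATG", "CCACCGACT", "GACTAAGGC")

GP_TARGET_PHYLUM <- "Glomeromycota"

.default_layout <- function() {
  # marker architecture: three exons (507 coding bases, frame 0) split by
  # two introns; primer sites sit at the very ends of exon 1 / exon 3
  region_annotation(start = c(0L, 141L, 231L, 411L, 491L),
                    end = c(141L, 231L, 411L, 491L, 677L),
                    label = c("exon", "intron", "exon", "intron", "exon"),
                    frame = 0L)
}

.default_treatments <- function(n_species) {
  w <- rev(seq_len(n_species)) + n_species / 2
  w <- sort(w / sum(w), decreasing = TRUE)
  if (n_species >= 8)
    w <- c(0.30, 0.20, 0.12, 0.10, 0.08, 0.08, 0.06, 0.06,
           rep(0, n_species - 8))[seq_len(n_species)]
  w <- w / sum(w)
  rot <- function(x, k) x[((seq_along(x) - 1 + k) %% length(x)) + 1]
  list(list(name = "no_tillage", mean = w),
       list(name = "chisel", mean = rot(w, 3L)),
       list(name = "tillage", mean = rot(w, 5L)))
}

#' Simulation configuration
#'
#' Builds the configuration driving [simulate_reference_set()] and
#' [simulate_community_reads()].  The defaults describe the study design the
#' package's validation targets: 8 target species (2 isolates each), a
#' 677-column exon/intron marker with introns evolving 4x faster, mean
#' between-species exon divergence 8% with within-species divergence 1.5%,
#' three treatments x four plots at 1800 reads per plot sample, triangular
#' read lengths (145, 254, 515) bp, 0.1% substitution errors, homopolymer
#' indels at 0.002 x (run length - 1) per run, and 5% single-crossover
#' chimeras.
#'
#' @param n_species Number of target species (>= 2).
#' @param isolates_per_species Isolates simulated per species.
#' @param layout Exon/intron [region_annotation()] for the marker.
#' @param intron_rate_multiplier Intron substitution rate relative to exons
#'   (>= 1).
#' @param kappa Transition/transversion rate ratio.
#' @param target_inter_species_divergence Mean pairwise exon K2P divergence
#'   between species.
#' @param min_species_separation Minimum pairwise species divergence, as a
#'   fraction of the target; coalescent trees with closer species pairs
#'   are redrawn (species in a barcoding reference set are distinguishable
#'   by construction).
#' @param intra_species_divergence Expected divergence between isolates of
#'   one species.
#' @param substitution_error_rate Per-base sequencing substitution rate.
#' @param n_rate Per-base rate of ambiguous (N) base calls.
#' @param homopolymer_indel_base_rate Per-run indel probability is this
#'   rate times (run length - 1), capped at 0.5; indels only occur in runs
#'   of length >= 2 and change the run length by exactly 1.
#' @param chimera_rate Fraction of reads generated as two-parent chimeras.
#' @param read_length `c(min, mode, max)` of the triangular read-length
#'   distribution (marker portion, excluding barcode/primer).
#' @param treatments List of `list(name=, mean=)` per-treatment Dirichlet
#'   mean compositions over species (each summing to 1).
#' @param concentration Common Dirichlet concentration for per-plot
#'   composition draws.
#' @param plots_per_treatment Replicate plots (= samples) per treatment.
#' @param reads_per_sample Reads per plot sample (exact unless
#'   `poisson_depth`).
#' @param poisson_depth Draw per-sample depth as Poisson(reads_per_sample).
#' @param offtarget_rate Fraction of reads drawn from the non-target
#'   outgroup species instead of the target community (default 0.06%, the
#'   non-target share the primers showed in the field).
#' @param seed Integer seed; every randomness source derives from it.
#' @return A list of class `gp_sim_config`.
#' @export
sim_config <- function(n_species = 8L,
                       isolates_per_species = 2L,
                       layout = .default_layout(),
                       intron_rate_multiplier = 4,
                       kappa = 2,
                       target_inter_species_divergence = 0.08,
                       min_species_separation = 0.25,
                       intra_species_divergence = 0.015,
                       substitution_error_rate = 0.001,
                       n_rate = 1e-4,
                       homopolymer_indel_base_rate = 0.002,
                       chimera_rate = 0.05,
                       read_length = c(145L, 254L, 515L),
                       treatments = NULL,
                       concentration = 40,
                       plots_per_treatment = 4L,
                       reads_per_sample = 1800L,
                       poisson_depth = FALSE,
                       offtarget_rate = 6e-4,
                       seed = 42L) {
  if (n_species < 2L) stop("n_species must be >= 2")
  rates <- c(substitution_error_rate, n_rate, homopolymer_indel_base_rate,
             chimera_rate, offtarget_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (intron_rate_multiplier < 1) stop("intron_rate_multiplier must be >= 1")
  if (!(read_length[1] <= read_length[2] && read_length[2] <= read_length[3]))
    stop("read_length must satisfy min <= mode <= max")
  if (is.null(treatments)) treatments <- .default_treatments(n_species)
  for (t in treatments) {
    if (length(t$mean) != n_species || abs(sum(t$mean) - 1) > 1e-8)
      stop("treatment ", t$name, ": composition must have length ",
           n_species, " and sum to 1")
  }
  labels <- region_labels(layout, max(layout$end))
  n_exon <- sum(labels == "exon")
  if ((n_exon - (3L - attr(layout, "frame")) %% 3L) %% 3L != 0L)
    stop("exon total (", n_exon, ") is not frame-consistent")
  structure(list(
    n_species = as.integer(n_species),
    isolates_per_species = as.integer(isolates_per_species),
    layout = layout,
    intron_rate_multiplier = intron_rate_multiplier,
    kappa = kappa,
    target_inter_species_divergence = target_inter_species_divergence,
    min_species_separation = min_species_separation,
    intra_species_divergence = intra_species_divergence,
    substitution_error_rate = substitution_error_rate,
    n_rate = n_rate,
    homopolymer_indel_base_rate = homopolymer_indel_base_rate,
    chimera_rate = chimera_rate,
    read_length = as.integer(read_length),
    treatments = treatments,
    concentration = concentration,
    plots_per_treatment = as.integer(plots_per_treatment),
    reads_per_sample = as.integer(reads_per_sample),
    poisson_depth = poisson_depth,
    offtarget_rate = offtarget_rate,
    seed = as.integer(seed)), class = "gp_sim_config")
}

# ---- sequence evolution -----------------------------------------------------

# per-column substitution rates; primer-site columns are held invariant
.column_rates <- function(config) {
  labels <- region_labels(config$layout, max(config$layout$end))
  r <- ifelse(labels == "intron", config$intron_rate_multiplier, 1)
  L <- length(r)
  r[seq_len(nchar(GP_FWD_PRIMER))] <- 0
  r[seq.int(L - nchar(GP_REV_SITE) + 1L, L)] <- 0
  r
}

# stop-free root: exons built codon-wise from the 61 sense codons, primer
# sites overwritten (both chosen stop-free in frame)
.root_sequence <- function(config) {
  labels <- region_labels(config$layout, max(config$layout$end))
  L <- length(labels)
  seqv <- character(L)
  seqv[labels == "intron"] <- sample(DNA_BASES, sum(labels == "intron"),
                                     replace = TRUE)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste,
                  collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  n_exon <- sum(labels == "exon")
  exon_seq <- paste(sample(sense, ceiling(n_exon / 3), replace = TRUE),
                    collapse = "")
  seqv[labels == "exon"] <- strsplit(substr(exon_seq, 1L, n_exon), "",
                                     fixed = TRUE)[[1]]
  fwd <- strsplit(GP_FWD_PRIMER, "", fixed = TRUE)[[1]]
  rev_ <- strsplit(GP_REV_SITE, "", fixed = TRUE)[[1]]
  seqv[seq_along(fwd)] <- fwd
  seqv[seq.int(L - length(rev_) + 1L, L)] <- rev_
  seqv
}

# K2P substitution along one branch; any exon substitution that would
# create an in-frame stop codon is reverted.
.evolve_branch <- function(seqv, branch_len, rates, config, exon_idx,
                           frame) {
  if (branch_len <= 0) return(seqv)
  kappa <- config$kappa
  n_events <- stats::rpois(length(seqv), branch_len * rates)
  hit <- which(n_events > 0L)
  if (length(hit) == 0L) return(seqv)
  ts_prob <- kappa / (kappa + 2)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  out <- seqv
  for (i in hit) {
    for (k in seq_len(n_events[[i]])) {
      b <- out[[i]]
      if (stats::runif(1) < ts_prob) {
        out[[i]] <- transition[[b]]
      } else {
        out[[i]] <- sample(setdiff(DNA_BASES, c(b, transition[[b]])), 1L)
      }
    }
  }
  # revert codons that became stops
  exon_seq <- out[exon_idx]
  cod <- .codons(paste(exon_seq, collapse = ""), frame)
  bad <- which(cod %in% STOP_CODONS)
  for (cb in bad) {
    pos <- frame + (cb - 1L) * 3L + 1:3  # positions within exon stretch
    out[exon_idx[pos]] <- seqv[exon_idx[pos]]
  }
  out
}

#' Simulate a reference set and its species tree
#'
#' Evolves a stop-codon-free marker along a random coalescent species tree
#' scaled so the mean pairwise path length equals the target divergence;
#' introns evolve `intron_rate_multiplier` times faster than exons, primer
#' sites are invariant.  Each species receives `isolates_per_species`
#' isolates diverged by the intraspecific target.  One deeply divergent
#' outgroup species (a different phylum) is included so that off-target
#' reads can be recognized downstream.
#'
#' @param config A [sim_config()].
#' @return List with `refset` (a [reference_set()]; sequences are the
#'   aligned references, all equal length), `tree` (`phylo`, leaves are the
#'   reference ids) and `species_tree` (`phylo` over species labels).
#' @export
simulate_reference_set <- function(config) {
  stopifnot(inherits(config, "gp_sim_config"))
  set.seed(config$seed)
  n <- config$n_species
  sp <- sprintf("Species%02d", seq_len(n))
  tgt <- config$target_inter_species_divergence
  min_sep <- (config$min_species_separation %||% 0) * tgt
  tre <- ape::rcoal(n, tip.label = sp)
  tre <- .scale_species_tree(tre, tgt, min_sep)

  labels <- region_labels(config$layout, max(config$layout$end))
  exon_idx <- which(labels == "exon")
  frame <- attr(config$layout, "frame")
  rates <- .column_rates(config)

  root <- .root_sequence(config)
  # post-order walk from root to tips
  node_seq <- vector("list", ape::Ntip(tre) + tre$Nnode)
  root_node <- ape::Ntip(tre) + 1L
  node_seq[[root_node]] <- root
  ord <- ape::reorder.phylo(tre, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    node_seq[[child]] <- .evolve_branch(node_seq[[par]],
                                        ord$edge.length[[e]], rates, config,
                                        exon_idx, frame)
  }
  sp_seq <- stats::setNames(lapply(seq_len(n), function(i) node_seq[[i]]),
                            tre$tip.label)

  k <- config$isolates_per_species
  half <- config$intra_species_divergence / 2
  seqs <- character(0)
  species <- character(0)
  isolate <- character(0)
  for (s in sp) {
    for (j in seq_len(k)) {
      id <- sprintf("%s_iso%d", s, j)
      v <- .evolve_branch(sp_seq[[s]], half, rates, config, exon_idx, frame)
      seqs[[id]] <- paste(v, collapse = "")
      species[[id]] <- s
      isolate[[id]] <- sprintf("iso%d", j)
    }
  }
  # outgroup: same layout, far from the root
  og_id <- "Outgroup01_iso1"
  ogv <- .evolve_branch(root, 0.30, rates, config, exon_idx, frame)
  seqs[[og_id]] <- paste(ogv, collapse = "")
  species[[og_id]] <- "Outgroup01"
  isolate[[og_id]] <- "iso1"

  lineages <- .derive_taxonomy(tre, sp)
  lineages[["Outgroup01"]] <- stats::setNames(
    c("Outgroupia", "Outgroupomycetes", "Outgroupales", "Outgroupaceae",
      "Outgroupus", "Outgroup01"), TAX_RANKS)
  ref_lineages <- lapply(species, function(s) lineages[[s]])

  refset <- reference_set(seqs, species, lineages = ref_lineages,
                          isolate = isolate, annotation = config$layout)
  tree <- .isolate_tree(tre, sp, k, half, og_id)
  list(refset = refset, tree = tree, species_tree = tre)
}

# scale an ultrametric species tree so the mean pairwise distance hits the
# target, then lift too-recent splits so no species pair falls below
# `min_sep` (clamping node heights keeps the tree ultrametric; one
# rescale-and-reclamp pass keeps the mean close to the target)
.scale_species_tree <- function(tre, target, min_sep) {
  mean_pair <- function(t) {
    cop <- ape::cophenetic.phylo(t)
    mean(cop[upper.tri(cop)])
  }
  clamp <- function(t, h_min) {
    ntip <- ape::Ntip(t)
    depth <- ape::node.depth.edgelength(t)
    height <- max(depth[seq_len(ntip)]) - depth
    height[seq_len(ntip)] <- 0
    height[-seq_len(ntip)] <- pmax(height[-seq_len(ntip)], h_min)
    t$edge.length <- height[t$edge[, 1L]] - height[t$edge[, 2L]]
    t
  }
  tre$edge.length <- tre$edge.length * target / mean_pair(tre)
  if (min_sep > 0) {
    tre <- clamp(tre, min_sep / 2)
    tre$edge.length <- tre$edge.length * target / mean_pair(tre)
    tre <- clamp(tre, min_sep / 2)
  }
  tre
}

# rank structure derived by cutting the species tree at fixed relative
# heights: shallow clades become genera, deeper ones families
.derive_taxonomy <- function(tre, sp) {
  d <- ape::cophenetic.phylo(tre)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  maxh <- max(hc$height)
  genus <- stats::cutree(hc, h = 0.40 * maxh)
  family <- stats::cutree(hc, h = 0.75 * maxh)
  lin <- list()
  for (s in sp) {
    lin[[s]] <- stats::setNames(
      c(GP_TARGET_PHYLUM, "Glomeromycetes", "Glomerales",
        sprintf("Family%02d", family[[s]]), sprintf("Genus%02d", genus[[s]]),
        s), TAX_RANKS)
  }
  lin
}

# expand species tips into isolate stars and attach the outgroup at the
# root (text-level Newick surgery keeps branch lengths exact)
.isolate_tree <- function(tre, sp, k, half, og_id) {
  txt <- ape::write.tree(tre)
  for (s in sp) {
    iso <- sprintf("%s_iso%d", s, seq_len(k))
    rep_txt <- if (k == 1L) iso else
      paste0("(", paste(sprintf("%s:%g", iso, max(half, 1e-9)),
                        collapse = ","), ")")
    txt <- sub(paste0(s, ":"), paste0(rep_txt, ":"), txt, fixed = TRUE)
  }
  txt <- paste0("(", sub(";$", "", txt), ":0.05,", og_id, ":0.30);")
  ape::read.tree(text = txt)
}

# ---- community reads --------------------------------------------------------

.rtriangular <- function(n, lo, mode, hi) {
  if (hi <= lo) return(rep(as.integer(lo), n))
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  x <- ifelse(u < fc, lo + sqrt(u * (hi - lo) * (mode - lo)),
              hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
  as.integer(round(x))
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# sequencing-style errors on one fragment vector; returns the mutated
# vector plus error counts
.apply_read_errors <- function(v, config) {
  n_sub <- 0L; n_indel <- 0L; n_n <- 0L
  L <- length(v)
  if (config$substitution_error_rate > 0) {
    k <- stats::rbinom(1L, L, config$substitution_error_rate)
    if (k > 0L) {
      pos <- sample.int(L, k)
      for (p in pos) v[[p]] <- sample(setdiff(DNA_BASES, v[[p]]), 1L)
      n_sub <- k
    }
  }
  if (config$homopolymer_indel_base_rate > 0) {
    r <- rle(v)
    runs <- which(r$lengths >= 2L & r$values %in% DNA_BASES)
    if (length(runs)) {
      pr <- pmin(config$homopolymer_indel_base_rate *
                 (r$lengths[runs] - 1L), 0.5)
      hitr <- runs[stats::runif(length(runs)) < pr]
      if (length(hitr)) {
        ends <- cumsum(r$lengths)
        # edit right-to-left so earlier run coordinates stay valid
        for (ri in rev(hitr)) {
          e <- ends[[ri]]
          if (stats::runif(1) < 0.5) {
            v <- append(v, r$values[[ri]], after = e)   # run +1
          } else {
            v <- v[-e]                                   # run -1
          }
          n_indel <- n_indel + 1L
        }
      }
    }
  }
  if (config$n_rate > 0) {
    k <- stats::rbinom(1L, length(v), config$n_rate)
    if (k > 0L) {
      pos <- sample.int(length(v), k)
      v[pos] <- "N"
      n_n <- k
    }
  }
  list(seq = v, n_subs = n_sub, n_indels = n_indel, n_ns = n_n)
}

#' Simulate barcoded community reads with ground truth
#'
#' Draws per-plot community compositions (Dirichlet around the treatment
#' mean), assigns reads to isolates, cuts primer-anchored fragments of
#' triangular length, forms single-crossover chimeras between two earlier
#' reads of the same sample, and applies substitution, ambiguous-base and
#' homopolymer-indel errors.  Every emitted read is
#' `barcode + forward primer + fragment`.
#'
#' @param config A [sim_config()].
#' @param refsim Output of [simulate_reference_set()] run on the same
#'   config.
#' @return List with `reads` (named character vector of raw reads),
#'   `sample_map` (data.frame: sample_id, barcode, treatment, plot),
#'   `ground_truth` (one row per read: read_id, sample_id, species,
#'   isolate, ref_id, is_chimera, parent_a, parent_b, crossover, length,
#'   n_subs, n_indels, n_ns) and `amplicons` (the error-free full-length
#'   marker of each reference, for oracle use).
#' @export
simulate_community_reads <- function(config, refsim) {
  stopifnot(inherits(config, "gp_sim_config"))
  set.seed(.subseed(config$seed, 2L))
  refset <- refsim$refset
  sp <- sprintf("Species%02d", seq_len(config$n_species))
  plen <- nchar(GP_FWD_PRIMER)
  L <- nchar(refset$seqs[[1L]])
  for (id in names(refset$seqs)) {
    if (substr(refset$seqs[[id]], 1L, plen) != GP_FWD_PRIMER)
      stop("forward primer not found in reference of species ",
           .msg_id(refset$species[[id]]))
  }
  # fragment templates: marker beyond the forward primer
  tpl <- lapply(refset$seqs,
                function(s) strsplit(substr(s, plen + 1L, L), "",
                                     fixed = TRUE)[[1]])
  iso_by_sp <- split(names(refset$seqs), refset$species)

  n_t <- length(config$treatments)
  n_p <- config$plots_per_treatment
  smap <- data.frame(
    sample_id = character(0), barcode = character(0),
    treatment = character(0), plot = character(0), stringsAsFactors = FALSE)
  idx <- 0L
  for (t in config$treatments) {
    for (p in seq_len(n_p)) {
      idx <- idx + 1L
      if (idx > length(GP_BARCODES))
        stop("barcode table supports at most ", length(GP_BARCODES),
             " samples")
      smap <- rbind(smap, data.frame(
        sample_id = sprintf("%s_p%d", t$name, p),
        barcode = GP_BARCODES[[idx]], treatment = t$name,
        plot = sprintf("p%d", p), stringsAsFactors = FALSE))
    }
  }
  validate_sample_map(smap)

  reads <- character(0)
  gt <- vector("list", nrow(smap))
  read_no <- 0L
  lo <- config$read_length[[1L]]; mo <- config$read_length[[2L]]
  hi <- min(config$read_length[[3L]], L - plen)
  for (si in seq_len(nrow(smap))) {
    t <- config$treatments[[(si - 1L) %/% n_p + 1L]]
    comp <- .rdirichlet1(config$concentration * t$mean)
    depth <- if (config$poisson_depth)
      stats::rpois(1L, config$reads_per_sample) else config$reads_per_sample
    sp_draw <- sample(sp, depth, replace = TRUE, prob = comp)
    off <- stats::runif(depth) < config$offtarget_rate
    lens <- .rtriangular(depth, lo, mo, hi)
    is_chim <- stats::runif(depth) < config$chimera_rate
    is_chim[1:2] <- FALSE

    frag_list <- vector("list", depth)
    iso_ids <- character(depth)
    for (i in seq_len(depth)) {
      iso_ids[[i]] <- if (off[[i]]) "Outgroup01_iso1" else
        sample(iso_by_sp[[sp_draw[[i]]]], 1L)
      frag_list[[i]] <- tpl[[iso_ids[[i]]]][seq_len(lens[[i]])]
    }

    sample_reads <- character(depth)
    bc <- smap$barcode[[si]]
    rows <- vector("list", depth)
    for (i in seq_len(depth)) {
      read_no <- read_no + 1L
      rid <- sprintf("read%06d", read_no)
      if (is_chim[[i]]) {
        pj <- sample.int(i - 1L, 2L)
        fa <- frag_list[[pj[[1L]]]]; fb <- frag_list[[pj[[2L]]]]
        xmax <- min(length(fa), length(fb)) - 1L
        x <- sample.int(xmax, 1L)
        frag <- c(fa[seq_len(x)], fb[seq.int(x + 1L, length(fb))])
        src_sp <- NA_character_; src_iso <- NA_character_
        pa <- sprintf("read%06d", read_no - i + pj[[1L]])
        pb <- sprintf("read%06d", read_no - i + pj[[2L]])
      } else {
        frag <- frag_list[[i]]
        src_sp <- if (off[[i]]) "Outgroup01" else sp_draw[[i]]
        src_iso <- iso_ids[[i]]
        pa <- NA_character_; pb <- NA_character_; x <- NA_integer_
      }
      err <- .apply_read_errors(frag, config)
      sample_reads[[i]] <- paste0(bc, GP_FWD_PRIMER,
                                  paste(err$seq, collapse = ""))
      rows[[i]] <- data.frame(
        read_id = rid, sample_id = smap$sample_id[[si]], species = src_sp,
        isolate = src_iso,
        ref_id = if (is_chim[[i]]) NA_character_ else iso_ids[[i]],
        is_chimera = is_chim[[i]], parent_a = pa, parent_b = pb,
        crossover = if (is_chim[[i]]) x else NA_integer_,
        length = length(err$seq), n_subs = err$n_subs,
        n_indels = err$n_indels, n_ns = err$n_ns, stringsAsFactors = FALSE)
    }
    names(sample_reads) <- vapply(rows, function(r) r$read_id, character(1))
    reads <- c(reads, sample_reads)
    gt[[si]] <- do.call(rbind, rows)
  }
  gt <- do.call(rbind, gt)
  rownames(gt) <- NULL
  amplicons <- vapply(tpl, paste, character(1), collapse = "")
  list(reads = reads, sample_map = smap, ground_truth = gt,
       amplicons = amplicons)
}

#' Score chimera detection against ground truth
#'
#' Compares [detect_chimeras()] verdicts with the simulator's ground truth.
#' Recall is reported at two levels: distinct sequences (centroids whose
#' seed read is a chimera) and reads (members of flagged centroids); both
#' can be restricted to chimeras whose parents diverge by at least
#' `min_parent_divergence` (p-distance over the parents' shared amplicon
#' prefix), since chimeras of near-identical parents are sequence-identical
#' to ordinary reads.  The false-positive rate is the flagged fraction of
#' non-chimeric centroids / reads.
#'
#' @param centroids The scanned `gp_centroids` object.
#' @param verdicts Output of [detect_chimeras()] on `centroids`.
#' @param sim Output of [simulate_community_reads()] (ground truth and
#'   amplicons).
#' @param min_parent_divergence Minimum parent divergence for a chimera to
#'   enter the recall denominator.
#' @return List: `recall_seq`, `fpr_seq`, `recall_read`, `fpr_read`,
#'   `n_chimeric_seq`, `n_chimeric_read`.
#' @export
chimera_eval <- function(centroids, verdicts, sim,
                         min_parent_divergence = 0) {
  gt <- sim$ground_truth
  gtc <- gt[gt$is_chimera, , drop = FALSE]
  pd <- function(ra, rb) {
    if (is.na(ra) || is.na(rb)) return(NA_real_)
    a <- sim$amplicons[[ra]]
    b <- sim$amplicons[[rb]]
    n <- min(nchar(a), nchar(b))
    p_distance(substr(a, 1L, n), substr(b, 1L, n))
  }
  div <- mapply(pd, gt$ref_id[match(gtc$parent_a, gt$read_id)],
                gt$ref_id[match(gtc$parent_b, gt$read_id)])
  eligible <- gtc$read_id[!is.na(div) & div >= min_parent_divergence]

  seed_chim <- gt$is_chimera[match(centroids$seed_read, gt$read_id)]
  seed_elig <- centroids$seed_read %in% eligible
  flag <- verdicts$flagged
  flagged_reads <- unlist(centroids$members[flag], use.names = FALSE)
  all_reads <- unlist(centroids$members, use.names = FALSE)
  chim_reads <- intersect(all_reads, eligible)
  nonchim_reads <- setdiff(all_reads, gtc$read_id)
  list(
    recall_seq = mean(flag[seed_elig]),
    fpr_seq = mean(flag[!seed_chim]),
    recall_read = mean(chim_reads %in% flagged_reads),
    fpr_read = mean(nonchim_reads %in% flagged_reads),
    n_chimeric_seq = sum(seed_elig),
    n_chimeric_read = length(chim_reads))
}
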