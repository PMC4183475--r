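# read-processing cascade

make_map <- function() {
  data.frame(sample_id = c("sA", "sB"),
             barcode = c("AAAAAAAAA", "TTTTAAAAA"),
             treatment = c("t1", "t2"), plot = c("p1", "p1"),
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns within one mismatch and trims", {
  map <- make_map()
  primer <- "ACGTACGTAC"
  payload <- strrep("GATC", 60)
  reads <- c(
    exact = paste0("AAAAAAAAA", primer, payload),
    onemm = paste0("AAAAAAAAT", primer, payload),   # 1 mismatch -> sA
    twomm = paste0("AAAAAAATT", primer, payload),   # 2 mismatches -> bin
    short = "AAAAAAAAAACG")
  dm <- demultiplex(reads, map, primer = primer)
  expect_setequal(dm$reads$read_id, c("exact", "onemm"))
  expect_true(all(dm$reads$sample_id == "sA"))
  expect_true(all(dm$reads$seq == payload))
  expect_equal(dm$reads$raw_length,
               rep(9 + nchar(primer) + nchar(payload), 2))
  expect_setequal(dm$unassigned, c("twomm", "short"))
})

test_that("length filter applies to raw length and rejects ambiguity", {
  df <- data.frame(
    read_id = c("a", "b", "c", "d"),
    sample_id = "s",
    seq = c(strrep("A", 170), strrep("A", 171),
            paste0(strrep("A", 100), "N", strrep("A", 150)),
            strrep("A", 250)),
    raw_length = c(199L, 200L, 280L, 279L), stringsAsFactors = FALSE)
  kept <- length_ambiguity_filter(df, min_len = 200)
  expect_setequal(kept$read_id, c("b", "d"))    # 199 bp out, N out
  # trimmed-length variant
  kept2 <- length_ambiguity_filter(df, min_len = 200,
                                   length_includes_prefix = FALSE)
  expect_setequal(kept2$read_id, "d")
})

screened_from <- function(cfg_seed = 19, ...) {
  cfg <- small_sim_config(seed = cfg_seed, ...)
  rsim <- simulate_reference_set(cfg)
  sim <- simulate_community_reads(cfg, rsim)
  dm <- demultiplex(sim$reads, sim$sample_map)
  lf <- length_ambiguity_filter(dm$reads)
  list(cfg = cfg, rsim = rsim, sim = sim, lf = lf,
       sc = alignment_screen(lf, rsim$refset))
}

test_that("alignment screen keeps target reads and discards random DNA", {
  x <- screened_from()
  expect_equal(nrow(x$sc$reads), nrow(x$lf))      # clean reads all pass
  expect_true(all(x$sc$reads$identity == 1))
  # projection: error-free reads match their reference over covered cols
  r1 <- x$sc$reads$read_id[[1]]
  al <- strsplit(x$sc$aligned[[r1]], "")[[1]]
  ref <- strsplit(x$rsim$refset$seqs[[x$sc$reads$best_ref[[1]]]],
                  "")[[1]]
  cov <- al != "."
  expect_true(all(al[cov] == ref[cov]))

  set.seed(77)
  rnd <- data.frame(
    read_id = sprintf("r%03d", 1:100), sample_id = "s",
    seq = replicate(100, random_dna(250)), raw_length = 279L,
    stringsAsFactors = FALSE)
  sc_rnd <- alignment_screen(rnd, x$rsim$refset)
  expect_equal(nrow(sc_rnd$reads), 0L)

  # a read with ~5% substitution errors is still kept
  tpl <- substr(x$sim$amplicons[[1]], 1, 300)
  v <- strsplit(tpl, "")[[1]]
  pos <- sample(300, 15)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  noisy <- data.frame(read_id = "noisy", sample_id = "s",
                      seq = paste(v, collapse = ""), raw_length = 329L,
                      stringsAsFactors = FALSE)
  sc_n <- alignment_screen(noisy, x$rsim$refset)
  expect_equal(nrow(sc_n$reads), 1L)
  expect_gt(sc_n$reads$identity, 0.9)
})

test_that("preclustering merges identical reads and conserves abundance", {
  x <- screened_from()
  cent <- precluster(x$sc)
  expect_equal(sum(cent$abundance), nrow(x$sc$reads))       # conservation
  expect_equal(sum(cent$counts), nrow(x$sc$reads))
  expect_equal(unname(lengths(cent$members)),
               unname(cent$abundance))
  # clean data: one centroid per isolate actually present
  expect_lte(length(cent$seqs),
             length(x$rsim$refset$seqs))

  # two sequences at ~1% divergence stay apart at the 99.7% threshold
  L <- 400
  a <- random_dna(L)
  bv <- strsplit(a, "")[[1]]
  for (p in seq(10, 400, by = 100)) bv[p] <- chartr("ACGT", "GTAC", bv[p])
  scr <- list(
    reads = data.frame(read_id = c("q1", "q2", "q3"),
                       sample_id = "s", seq = "x", raw_length = L,
                       best_ref = "r", identity = 1,
                       stringsAsFactors = FALSE),
    aligned = c(q1 = a, q2 = a, q3 = paste(bv, collapse = "")),
    insertions = list())
  cent2 <- precluster(scr, min_overlap = 50)
  expect_equal(length(cent2$seqs), 2L)
  expect_equal(sort(cent2$abundance), c(1L, 2L))
})

test_that("a constructed two-parent crossover is flagged, absent parents
          are an acknowledged miss", {
  set.seed(41)
  L <- 400
  a <- random_dna(L)
  bv <- strsplit(a, "")[[1]]
  mut <- sample(L, 12)  # ~3% divergence between the parents
  for (p in mut) bv[p] <- sample(setdiff(c("A", "C", "G", "T"), bv[p]), 1)
  b <- paste(bv, collapse = "")
  chim <- paste0(substr(a, 1, 200), substr(b, 201, L))
  cents <- structure(list(
    seqs = c(pa = a, pb = b, q = chim),
    insertions = list(pa = NULL, pb = NULL, q = NULL),
    seed_read = c("pa", "pb", "q"), best_ref = c("r", "r", "r"),
    abundance = c(50L, 40L, 2L),
    counts = matrix(c(50L, 40L, 2L), 3, 1,
                    dimnames = list(NULL, "s")),
    members = list("pa", "pb", "q")), class = "gp_centroids")
  v <- detect_chimeras(cents)
  expect_true(v$flagged[v$seed_read == "q"])
  expect_false(any(v$flagged[v$seed_read != "q"]))
  expect_setequal(c(v$parent_a[3], v$parent_b[3]), c("pa", "pb"))

  # remove one parent: the model cannot be built -> acknowledged miss
  cents2 <- glompipe:::.drop_centroids(cents, 2L)
  v2 <- detect_chimeras(cents2)
  expect_false(any(v2$flagged))

  # error-free simulation without recombinants: nothing is flagged
  x <- screened_from(cfg_seed = 23)
  cent <- precluster(x$sc)
  expect_false(any(detect_chimeras(cent)$flagged))
})

# a small hand-built reference for frame correction: one exon with an AAA
# homopolymer, an intron, and a second exon
frame_fixture <- function() {
  exon1 <- "ATGGCTAAAGCTTGG"          # 15 nt, contains run AAA
  intron <- "GTTTGTGCA"               # 9 nt
  exon2 <- "GCTGATATCGAT"             # 12 nt
  ref <- paste0(exon1, intron, exon2)
  ann <- region_annotation(c(0, 15, 24), c(15, 24, 36),
                           c("exon", "intron", "exon"), frame = 0)
  refset <- reference_set(c(R1 = ref), c(R1 = "SpR"), annotation = ann)
  list(ref = ref, ann = ann, refset = refset)
}

as_centroid <- function(seq, insertions = NULL) {
  structure(list(
    seqs = c(c1 = seq), insertions = list(c1 = insertions),
    seed_read = "c1", best_ref = "R1", abundance = 5L,
    counts = matrix(5L, 1, 1, dimnames = list(NULL, "s")),
    members = list("c1")), class = "gp_centroids")
}

test_that("frame correction repairs single-base homopolymer indels and
          flags stops and uncorrectable shifts", {
  fx <- frame_fixture()
  # error-free read passes unmodified
  fc0 <- frame_correct(as_centroid(fx$ref), fx$refset)
  expect_equal(fc0$flags$status, "ok")
  expect_identical(unname(fc0$centroids$seqs[[1]]), fx$ref)
  expect_equal(fc0$flags$n_inserted + fc0$flags$n_deleted, 0L)

  # deletion inside the AAA run -> re-inserted (net +1 base)
  del <- sub("AAA", "AA-", fx$ref)
  fc1 <- frame_correct(as_centroid(del), fx$refset)
  expect_equal(fc1$flags$status, "ok")
  expect_equal(fc1$flags$n_inserted, 1L)
  expect_identical(unname(fc1$centroids$seqs[[1]]), fx$ref)

  # surplus base next to the run -> removed
  fc2 <- frame_correct(as_centroid(fx$ref, data.frame(col = 9,
                                                      base = "A")),
                       fx$refset)
  expect_equal(fc2$flags$status, "ok")
  expect_equal(fc2$flags$n_deleted, 1L)
  expect_null(fc2$centroids$insertions[[1]])

  # substitution creating an in-frame TAA stop -> discarded
  stopseq <- paste0("ATGGCTAAAGCTTAA", substr(fx$ref, 16, 36))
  fc3 <- frame_correct(as_centroid(stopseq), fx$refset)
  expect_equal(fc3$flags$status, "stop_codon")
  expect_equal(length(fc3$centroids$seqs), 0L)
  expect_equal(sum(fc3$discarded$abundance), 5L)

  # a deletion outside any >= 3 run cannot be repaired -> frameshift
  shift <- sub("GCTGAT", "GCTG-T", fx$ref)
  fc4 <- frame_correct(as_centroid(shift), fx$refset)
  expect_equal(fc4$flags$status, "frameshift")

  # intron columns are never edited: a gap in the intron stays
  intron_del <- sub("GTTTGTGCA", "GTTT-TGCA", fx$ref)
  expect_false(intron_del == fx$ref)
  fc5 <- frame_correct(as_centroid(intron_del), fx$refset)
  expect_equal(fc5$flags$status, "ok")
  expect_identical(unname(fc5$centroids$seqs[[1]]), intron_del)

  # no exon overlap -> passed through with its own flag
  tail_only <- paste0(strrep(".", 24), substr(fx$ref, 25, 26),
                      strrep(".", 10))
  fc6 <- frame_correct(as_centroid(tail_only), fx$refset)
  expect_equal(fc6$flags$status, "no_exon")
  expect_equal(length(fc6$centroids$seqs), 1L)
})

test_that("simulated homopolymer errors are corrected against ground
          truth", {
  cfg <- small_sim_config(seed = 29,
                          homopolymer_indel_base_rate = 0.004)
  rsim <- simulate_reference_set(cfg)
  sim <- simulate_community_reads(cfg, rsim)
  dm <- demultiplex(sim$reads, sim$sample_map)
  lf <- length_ambiguity_filter(dm$reads)
  sc <- alignment_screen(lf, rsim$refset)
  cent <- precluster(sc)
  fc <- frame_correct(cent, rsim$refset)
  gt <- sim$ground_truth
  edited <- fc$flags$n_inserted + fc$flags$n_deleted
  expect_gt(sum(edited), 0)
  # every edited or frame-shift-flagged centroid contains at least one
  # indel-carrying member read (no other error source is simulated)
  has_indel <- vapply(cent$members, function(ids)
    any(gt$n_indels[match(ids, gt$read_id)] > 0), logical(1))
  expect_true(all(has_indel[edited > 0]))
  expect_true(all(has_indel[fc$flags$status == "frameshift"]))
})
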