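# OTU picking, three-way taxonomy, consensus and molecular taxa

cent_fixture <- function() {
  set.seed(55)
  L <- 400
  a <- random_dna(L)
  near <- strsplit(a, "")[[1]]
  near[50] <- chartr("ACGT", "GTAC", near[50])      # 0.25% away -> merges
  bv <- strsplit(a, "")[[1]]
  for (p in seq(5, 400, by = 50)) bv[p] <- chartr("ACGT", "GTAC", bv[p])
  b <- paste(bv, collapse = "")                      # ~2% away -> separate
  structure(list(
    seqs = c(r1 = a, r2 = paste(near, collapse = ""), r3 = b),
    insertions = list(r1 = NULL, r2 = NULL, r3 = NULL),
    seed_read = c("r1", "r2", "r3"), best_ref = rep("R", 3),
    abundance = c(10L, 4L, 6L),
    counts = matrix(c(6L, 2L, 4L, 4L, 2L, 2L), 3, 2,
                    dimnames = list(NULL, c("s1", "s2"))),
    members = list(paste0("a", 1:10), paste0("b", 1:4), paste0("c", 1:6))),
    class = "gp_centroids")
}

test_that("greedy OTU picking merges within the K2P threshold and
          conserves counts", {
  cent <- cent_fixture()
  otus <- cluster_otus(cent, distance_threshold = 0.008)
  expect_equal(length(otus$otu_id), 2L)
  expect_equal(sum(otus$counts), sum(cent$counts))          # conservation
  expect_equal(sum(otus$abundance), 20L)
  # representative is the most abundant member's sequence
  expect_identical(unname(otus$rep_seq[["OTU_0001"]]),
                   unname(cent$seqs[["r1"]]))
  expect_setequal(otus$members[["OTU_0001"]], c(paste0("a", 1:10),
                                                paste0("b", 1:4)))
  # all identical -> one OTU
  cent1 <- cent_fixture()
  cent1$seqs[] <- cent1$seqs[[1]]
  expect_equal(length(cluster_otus(cent1)$otu_id), 1L)
  # empty input -> empty list
  empty <- glompipe:::.drop_centroids(cent, 1:3)
  expect_equal(length(cluster_otus(empty)$otu_id), 0L)
})

test_that("singleton, chimeric and off-target OTUs are removed with an
          accounting report", {
  cent <- cent_fixture()
  cent$abundance <- c(10L, 4L, 1L)
  cent$counts[3, ] <- c(1L, 0L)
  cent$members[[3]] <- "c1"
  otus <- cluster_otus(cent)
  lin <- list(OTU_0001 = parse_lineage("Glomeromycota;C;O;F;G;S1"),
              OTU_0002 = parse_lineage("Outgroupia;C2;O2;F2;G2;S2"))
  # rename: otus ordered by abundance; OTU_0002 is the singleton here
  names(lin) <- otus$otu_id[1:2]
  rs <- remove_singletons_and_offtarget(otus, lin)
  expect_equal(rs$report$n_otus[rs$report$reason == "singleton"], 1L)
  expect_equal(length(rs$otus$otu_id), 1L)

  # off-target phylum removed and reported with its reads
  lin2 <- list(parse_lineage("Glomeromycota;C;O;F;G;S1"),
               parse_lineage("Ascomycota;C2;O2;F2;G2;S2"))
  cent2 <- cent_fixture()
  otus2 <- cluster_otus(cent2)
  names(lin2) <- otus2$otu_id
  rs2 <- remove_singletons_and_offtarget(otus2, lin2)
  expect_equal(rs2$report$n_otus[rs2$report$reason == "offtarget"], 1L)
  expect_equal(rs2$report$n_reads[rs2$report$reason == "offtarget"], 6L)
  # chimera flags remove OTUs too
  rs3 <- remove_singletons_and_offtarget(otus2, lin2,
                                         chimera_flags = c(TRUE, FALSE))
  expect_equal(rs3$report$n_otus[rs3$report$reason == "chimera"], 1L)
})

test_that("the k-mer classifier assigns identical queries fully and
          abstains sensibly", {
  cfg <- sim_config(n_species = 6, isolates_per_species = 1, seed = 37)
  refset <- simulate_reference_set(cfg)$refset
  q <- refset$seqs[[3]]
  set.seed(1)
  a <- classify_kmer_bayes(q, refset)
  expect_identical(unname(a$lineage),
                   unname(refset$lineages[[3]]))
  expect_equal(a$confidence, 1.0)

  # random DNA shares no k-mers -> unassigned even at phylum
  set.seed(2)
  r <- classify_kmer_bayes(random_dna(300), refset)
  expect_length(r$lineage, 0L)
  # query shorter than k -> unassigned
  expect_length(classify_kmer_bayes("ACGT", refset)$lineage, 0L)
})

test_that("a query equidistant between two genera stops at family", {
  base <- random_dna(400)
  mk <- function(positions) {
    v <- strsplit(base, "")[[1]]
    for (p in positions) v[p] <- chartr("ACGT", "GTAC", v[p])
    paste(v, collapse = "")
  }
  set.seed(91)
  seqs <- c(g1 = mk(seq(3, 395, by = 16)), g2 = mk(seq(11, 395, by = 16)))
  lin <- list(
    g1 = parse_lineage("Glomeromycota;Cl;Or;FamX;GenA;SpA"),
    g2 = parse_lineage("Glomeromycota;Cl;Or;FamX;GenB;SpB"))
  refs <- reference_set(seqs, c(g1 = "SpA", g2 = "SpB"), lineages = lin)
  # query carries half of each genus's private mutations
  both <- c(seq(3, 395, by = 32), seq(11, 395, by = 32))
  q <- mk(both)
  set.seed(3)
  a <- classify_kmer_bayes(q, refs)
  expect_lte(length(a$lineage), 4L)             # no genus-level call
  if (length(a$lineage)) {
    expect_identical(unname(a$lineage[["phylum"]]), "Glomeromycota")
  }
})

test_that("parsimony placement identifies leaves, genera and falls back
          to enclosing labelled clades", {
  cfg <- sim_config(n_species = 4, isolates_per_species = 1, seed = 53)
  rsim <- simulate_reference_set(cfg)
  refset <- rsim$refset
  tree <- rsim$tree
  # identical to a leaf -> that species
  ids <- names(refset$seqs)
  a <- assign_by_placement(refset$seqs[[ids[2]]], tree, refset)
  expect_identical(unname(a$lineage),
                   unname(refset$lineages[[ids[2]]]))
  expect_gt(a$confidence, 0.9)

  # a 50/50 mixture of two references lands no deeper than their shared
  # lineage
  pick <- ids[refset$species %in% c("Species01", "Species02")]
  v1 <- strsplit(refset$seqs[[pick[1]]], "")[[1]]
  v2 <- strsplit(refset$seqs[[pick[2]]], "")[[1]]
  diff_cols <- which(v1 != v2)
  hyb <- v1
  take <- diff_cols[seq_along(diff_cols) %% 2 == 0]
  hyb[take] <- v2[take]
  ah <- assign_by_placement(paste(hyb, collapse = ""), tree, refset)
  shared <- glompipe:::.shared_lineage(refset$lineages[pick])
  # the hybrid lands inside the two parents clade: compatible with their
  # shared lineage, and never assigned outside it
  expect_gt(length(ah$lineage), 0L)
  expect_true(glompipe:::.prefix_compatible(ah$lineage, shared))
  if (length(ah$lineage) == 6L)
    expect_true(unname(ah$lineage[["species"]]) %in%
                  refset$species[pick])

  # too little overlap -> unassigned
  short <- paste0(substr(refset$seqs[[1]], 1, 30),
                  strrep(".", nchar(refset$seqs[[1]]) - 30))
  expect_length(assign_by_placement(short, tree, refset)$lineage, 0L)
})

test_that("NJ assignment recovers the generating quartet and abstains on
          noise", {
  # additive quartet ((A,B),(C,D)): build sequences with controlled
  # shared/private mutations
  base <- random_dna(600)
  mut <- function(s, positions) {
    v <- strsplit(s, "")[[1]]
    for (p in positions) v[p] <- chartr("ACGT", "GTAC", v[p])
    paste(v, collapse = "")
  }
  set.seed(61)
  ab <- mut(base, sample(600, 40))     # AB ancestor
  cd <- mut(base, sample(600, 40))     # CD ancestor
  seqs <- c(A = mut(ab, sample(600, 8)), B = mut(ab, sample(600, 8)),
            C = mut(cd, sample(600, 8)), D = mut(cd, sample(600, 8)))
  # oracle: choose the pairing minimising the four-point sums
  d <- pairwise_k2p(seqs)
  s_ab <- d["A", "B"] + d["C", "D"]
  s_ac <- d["A", "C"] + d["B", "D"]
  s_ad <- d["A", "D"] + d["B", "C"]
  expect_equal(which.min(c(s_ab, s_ac, s_ad)), 1L)
  tree <- ape::nj(as.dist(d))
  split_ok <- ape::is.monophyletic(ape::unroot(tree), c("A", "B"))
  expect_true(split_ok)

  lin <- list(
    A = parse_lineage("P;C;O;F1;G1;SpA"), B = parse_lineage("P;C;O;F1;G1;SpB"),
    C = parse_lineage("P;C;O;F2;G2;SpC"), D = parse_lineage("P;C;O;F2;G2;SpD"))
  refs <- reference_set(seqs, stats::setNames(c("SpA", "SpB", "SpC",
                                                "SpD"), names(seqs)),
                        lineages = lin)
  set.seed(8)
  a <- assign_by_nj(seqs[["A"]], refs)
  expect_identical(unname(a$lineage), unname(lin$A))
  expect_gte(a$confidence, 0.95)

  set.seed(9)
  w <- assign_by_nj(random_dna(600), refs)
  expect_lte(length(w$lineage), 3L)    # no family/genus/species call
})

test_that("consensus follows the preference rules", {
  asn <- function(lin, method = "x")
    list(method = method, lineage = if (nzchar(lin)) parse_lineage(lin)
         else character(0), confidence = 0.9)
  sp <- "P;C;O;F;G;S1"
  fam <- "P;C;O;F"
  # all three identical -> that lineage
  c1 <- consensus_assignment(asn(sp), asn(sp), asn(sp))
  expect_identical(lineage_string(c1$lineage), sp)
  # classifier shallower, trees deeper and agreeing -> refined to species
  c2 <- consensus_assignment(asn(fam), asn(sp), asn(sp))
  expect_identical(lineage_string(c2$lineage), sp)
  expect_equal(c2$rule, "tree")
  # three mutually incompatible genera in one family -> family level
  c3 <- consensus_assignment(asn("P;C;O;F;G1;Sa"), asn("P;C;O;F;G2;Sb"),
                             asn("P;C;O;F;G3;Sc"))
  expect_identical(lineage_string(c3$lineage), fam)
  expect_equal(c3$rule, "lca")
  # tree methods disagree -> placement wins
  c4 <- consensus_assignment(asn(""), asn("P;C;O;F;G1;Sa"),
                             asn("P;C;O;F;G2;Sb"))
  expect_identical(lineage_string(c4$lineage), "P;C;O;F;G1;Sa")
  expect_equal(c4$rule, "placement_over_nj")
  # all empty -> unassigned
  expect_length(consensus_assignment(asn(""), asn(""), asn(""))$lineage,
                0L)
  # classifier alone
  c5 <- consensus_assignment(asn(sp), asn(""), asn(""))
  expect_identical(lineage_string(c5$lineage), sp)
})

test_that("consensus is never deeper than its deepest input and never
          contradicts the preferred assignments", {
  ranks <- c("P", "C", "O", "F", "G", "S")
  set.seed(71)
  rand_lin <- function() {
    d <- sample(0:6, 1)
    if (d == 0) return(character(0))
    parse_lineage(paste(paste0(ranks[seq_len(d)],
                               sample(1:3, d, replace = TRUE)),
                        collapse = ";"))
  }
  for (i in 1:200) {
    a <- list(lineage = rand_lin()); b <- list(lineage = rand_lin())
    c_ <- list(lineage = rand_lin())
    cons <- consensus_assignment(a, b, c_)
    expect_lte(length(cons$lineage),
               max(lengths(list(a$lineage, b$lineage, c_$lineage))))
    # never contradicts the placement lineage where both are named
    if (length(b$lineage))
      expect_true(glompipe:::.prefix_compatible(cons$lineage, b$lineage))
    # when everything is mutually compatible it contradicts nothing
    if (glompipe:::.prefix_compatible(a$lineage, b$lineage) &&
        glompipe:::.prefix_compatible(b$lineage, c_$lineage) &&
        glompipe:::.prefix_compatible(a$lineage, c_$lineage)) {
      for (l in list(a$lineage, b$lineage, c_$lineage))
        expect_true(glompipe:::.prefix_compatible(cons$lineage, l))
    }
  }
})

test_that("molecular-taxon aggregation groups by deepest name, handles
          rank fallbacks and aliases, and partitions the OTUs", {
  otus <- structure(list(
    otu_id = sprintf("OTU_%04d", 1:17),
    abundance = rep(2L, 17)), class = "gp_otus")
  lin <- c(rep("P;C;O;F;G;Rh. irregularis", 14), "P;C;O;Glomeraceae",
           "P;C;O;F;G;Cl. etunicatum", "P;C;O;F;G;Cl. claroideum")
  lineages <- stats::setNames(lapply(lin, parse_lineage), otus$otu_id)
  ali <- c("Cl. etunicatum" = "Cl. etunicatum/Cl. claroideum",
           "Cl. claroideum" = "Cl. etunicatum/Cl. claroideum")
  mts <- aggregate_to_mts(otus, lineages, aliases = ali)
  expect_equal(nrow(mts$mts), 3L)
  expect_equal(mts$mts$n_otus[mts$mts$mt_name == "Rh. irregularis"], 14L)
  expect_true("Glomeraceae sp." %in% mts$mts$mt_name)
  expect_equal(mts$mts$n_otus[
    mts$mts$mt_name == "Cl. etunicatum/Cl. claroideum"], 2L)
  # partition: every OTU in exactly one MT
  expect_setequal(names(mts$mapping), otus$otu_id)
  expect_equal(sum(mts$mts$n_otus), 17L)
})

test_that("a clean simulated community collapses to one MT per species
          while OTUs oversplit", {
  cfg <- small_sim_config(seed = 33)   # 4 species, 2 isolates at 1.5%
  rsim <- simulate_reference_set(cfg)
  sim <- simulate_community_reads(cfg, rsim)
  rep <- run_pipeline(sim$reads, sim$sample_map, rsim$refset, rsim$tree,
                      config = pipeline_config(seed = 33))
  expect_equal(rep$mt_count, 4L)
  expect_gt(rep$otu_count, rep$mt_count)  # intraspecific splitting
  mts <- rep$state$mts$mts
  expect_setequal(mts$mt_name, sprintf("Species%02d", 1:4))
})
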