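# synthetic-data generator: calibration, ground truth, error models,
# determinism

test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(sim_config(chimera_rate = 1.5), "rates")
  expect_error(sim_config(read_length = c(300, 200, 500)), "read_length")
  expect_error(sim_config(intron_rate_multiplier = 0.5), "multiplier")
  bad_layout <- region_annotation(c(0, 100), c(100, 200),
                                  c("exon", "intron"), frame = 0)
  expect_error(sim_config(layout = bad_layout), "frame-consistent")
})

test_that("reference simulation hits the divergence targets", {
  cfg <- sim_config(n_species = 2, isolates_per_species = 1,
                    target_inter_species_divergence = 0.05, seed = 7)
  rsim <- simulate_reference_set(cfg)
  lab <- region_labels(cfg$layout, 677)
  ex <- which(lab == "exon")
  sp <- names(rsim$refset$seqs)[rsim$refset$species != "Outgroup01"]
  exseq <- vapply(rsim$refset$seqs[sp], function(s)
    paste(strsplit(s, "")[[1]][ex], collapse = ""), character(1))
  d <- k2p(exseq[[1]], exseq[[2]])
  expect_gte(d, 0.05 * 0.75)
  expect_lte(d, 0.05 * 1.25)
})

test_that("default references: mean exon divergence near target, no
          stop codons, faster introns", {
  cfg <- sim_config(seed = 42)
  rsim <- simulate_reference_set(cfg)
  rs <- rsim$refset
  lab <- region_labels(cfg$layout, 677)
  ex <- which(lab == "exon")
  intr <- which(lab == "intron")
  tgt <- names(rs$seqs)[rs$species != "Outgroup01"]
  sub <- function(s, idx) paste(strsplit(s, "")[[1]][idx], collapse = "")
  exseq <- vapply(rs$seqs[tgt], sub, character(1), idx = ex)
  inseq <- vapply(rs$seqs[tgt], sub, character(1), idx = intr)
  de <- pairwise_k2p(exseq)
  di <- pairwise_k2p(inseq)
  spv <- rs$species[tgt]
  inter <- outer(spv, spv, "!=") & upper.tri(de)
  expect_gte(mean(de[inter]), 0.08 * 0.75)
  expect_lte(mean(de[inter]), 0.08 * 1.25)
  expect_gt(mean(di[inter]), mean(de[inter]))  # introns evolve faster

  # stop-free translation in the declared frame for every reference
  for (s in rs$seqs) {
    exon_seq <- sub(s, ex)
    expect_false(glompipe:::.has_stop(exon_seq,
                                      attr(cfg$layout, "frame")))
  }
})

test_that("zero intraspecific divergence gives identical isolates", {
  cfg <- sim_config(n_species = 3, isolates_per_species = 3,
                    intra_species_divergence = 0, seed = 4)
  rs <- simulate_reference_set(cfg)$refset
  for (sp in unique(rs$species)) {
    seqs <- rs$seqs[names(rs$species)[rs$species == sp]]
    expect_length(unique(seqs), 1L)
  }
})

test_that("simulation is deterministic given seed and config", {
  cfg <- small_sim_config(seed = 12)
  r1 <- simulate_reference_set(cfg)
  r2 <- simulate_reference_set(cfg)
  expect_identical(r1$refset$seqs, r2$refset$seqs)
  s1 <- simulate_community_reads(cfg, r1)
  s2 <- simulate_community_reads(cfg, r2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("clean reads are exact amplicon prefixes carrying barcode and
          primer, one distinct sequence per species", {
  cfg <- small_sim_config(seed = 9, read_length = c(300L, 300L, 300L))
  rsim <- simulate_reference_set(cfg)
  sim <- simulate_community_reads(cfg, rsim)
  gt <- sim$ground_truth
  expect_equal(nrow(gt), length(sim$reads))
  expect_true(all(table(gt$sample_id) == cfg$reads_per_sample))
  bc <- sim$sample_map$barcode[match(gt$sample_id,
                                     sim$sample_map$sample_id)]
  expect_true(all(startsWith(
    unname(sim$reads), paste0(bc, glompipe:::GP_FWD_PRIMER))))
  # error-free, chimera-free reads are exact substrings of their source
  trimmed <- substr(sim$reads, 9 + 20 + 1, nchar(sim$reads))
  hit <- mapply(function(tr, ref) startsWith(sim$amplicons[[ref]], tr),
                trimmed, gt$ref_id)
  expect_true(all(hit))
  # fixed read length + zero divergence within species: the number of
  # distinct sequences per sample is the number of species present
  cfg0 <- small_sim_config(seed = 9, read_length = c(300L, 300L, 300L),
                           intra_species_divergence = 0)
  rsim0 <- simulate_reference_set(cfg0)
  sim0 <- simulate_community_reads(cfg0, rsim0)
  for (s in sim0$sample_map$sample_id) {
    sel <- sim0$ground_truth$sample_id == s
    expect_equal(length(unique(sim0$reads[sel])),
                 length(unique(sim0$ground_truth$species[sel])))
  }
})

test_that("chimera counts follow the binomial and parents precede their
          chimeras", {
  cfg <- sim_config(n_species = 4, reads_per_sample = 834L,
                    chimera_rate = 0.05, substitution_error_rate = 0,
                    homopolymer_indel_base_rate = 0, n_rate = 0,
                    seed = 13)
  rsim <- simulate_reference_set(cfg)
  sim <- simulate_community_reads(cfg, rsim)
  gt <- sim$ground_truth
  n <- nrow(gt)                       # 10008 reads
  expected <- n * 0.05
  tol <- 3 * sqrt(n * 0.05 * 0.95)
  expect_gte(sum(gt$is_chimera), expected - tol)
  expect_lte(sum(gt$is_chimera), expected + tol)
  chim <- gt[gt$is_chimera, ]
  ord <- match(gt$read_id, gt$read_id)
  expect_true(all(match(chim$parent_a, gt$read_id) <
                    match(chim$read_id, gt$read_id)))
  expect_true(all(match(chim$parent_b, gt$read_id) <
                    match(chim$read_id, gt$read_id)))
  # parents always from the same sample
  expect_true(all(gt$sample_id[match(chim$parent_a, gt$read_id)] ==
                    chim$sample_id))
})

test_that("homopolymer indels occur, sit in runs >= 2 and change run
          length by exactly one", {
  cfg <- sim_config(n_species = 4, reads_per_sample = 834L,
                    chimera_rate = 0, substitution_error_rate = 0,
                    n_rate = 0, homopolymer_indel_base_rate = 0.002,
                    seed = 17)
  rsim <- simulate_reference_set(cfg)
  sim <- simulate_community_reads(cfg, rsim)
  gt <- sim$ground_truth
  expect_gt(sum(gt$n_indels > 0), 0)  # >= one indel at 10k reads
  one <- gt[gt$n_indels == 1 & !gt$is_chimera, ]
  expect_gt(nrow(one), 10)
  for (i in seq_len(min(nrow(one), 40))) {
    read <- substr(sim$reads[[one$read_id[i]]], 30, 1e6)
    amp <- sim$amplicons[[one$ref_id[i]]]
    ok <- FALSE
    for (L0 in one$length[i] + c(-1L, 1L)) {  # insertion / deletion case
      tpl <- substr(amp, 1, L0)
      r1 <- rle(strsplit(read, "")[[1]])
      r2 <- rle(strsplit(tpl, "")[[1]])
      if (length(r1$values) == length(r2$values) &&
          all(r1$values == r2$values)) {
        dl <- r1$lengths - r2$lengths
        # exactly one run differs, by one base, in a template run >= 2
        if (sum(dl != 0) == 1 && abs(dl[dl != 0]) == 1 &&
            r2$lengths[which(dl != 0)] >= 2 - (dl[dl != 0] > 0))
          ok <- TRUE
      }
    }
    expect_true(ok, info = one$read_id[i])
  }
})

test_that("a reference without the primer site is rejected", {
  cfg <- small_sim_config(seed = 3)
  rsim <- simulate_reference_set(cfg)
  broken <- rsim
  s1 <- rsim$refset$seqs[[1]]
  broken$refset$seqs[[1]] <- paste0("T", substr(s1, 2, nchar(s1)))
  expect_error(simulate_community_reads(cfg, broken),
               "primer not found.*Species01")
})

test_that("chimera scoring against ground truth reports sane rates", {
  cfg <- sim_config(n_species = 4, reads_per_sample = 200L,
                    plots_per_treatment = 2L, chimera_rate = 0.10,
                    substitution_error_rate = 0, n_rate = 0,
                    homopolymer_indel_base_rate = 0, seed = 21)
  rsim <- simulate_reference_set(cfg)
  sim <- simulate_community_reads(cfg, rsim)
  dm <- demultiplex(sim$reads, sim$sample_map)
  lf <- length_ambiguity_filter(dm$reads)
  sc <- alignment_screen(lf, rsim$refset)
  cent <- precluster(sc)
  v <- detect_chimeras(cent)
  ev <- chimera_eval(cent, v, sim, min_parent_divergence = 0.05)
  expect_lte(ev$fpr_seq, 0.01)
  expect_gt(ev$recall_seq, 0.5)
  expect_gte(ev$n_chimeric_seq, 5)
})
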