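# Shared fixtures, built in code.

# a tiny aligned reference set: 2-3 species, optionally with gaps
tiny_refset <- function() {
  seqs <- c(
    A1 = "ATGGCTAAGGCTTGGACTGATATC",
    A2 = "ATGGCTAAGGCTTGGACTGATATT",
    B1 = "ATGGCTAAGGATTGGACTAATGTC",
    C1 = "ATGACTGAGGATTCGAGTAATGTC")
  species <- c(A1 = "SpA", A2 = "SpA", B1 = "SpB", C1 = "SpC")
  lineages <- list(
    A1 = parse_lineage("Glomeromycota;Glomeromycetes;Glomerales;Fam1;GenA;SpA"),
    A2 = parse_lineage("Glomeromycota;Glomeromycetes;Glomerales;Fam1;GenA;SpA"),
    B1 = parse_lineage("Glomeromycota;Glomeromycetes;Glomerales;Fam1;GenA;SpB"),
    C1 = parse_lineage("Glomeromycota;Glomeromycetes;Glomerales;Fam2;GenC;SpC"))
  reference_set(seqs, species, lineages = lineages)
}

# small, fast simulation scenario used by module tests; any sim_config
# argument can be overridden
small_sim_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_species = 4L, isolates_per_species = 2L,
         reads_per_sample = 120L, plots_per_treatment = 2L,
         chimera_rate = 0, substitution_error_rate = 0,
         n_rate = 0, homopolymer_indel_base_rate = 0, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# random DNA string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

expect_symmetric_zero_diag <- function(d) {
  expect_true(isSymmetric(unname(d)))
  expect_true(all(abs(diag(d)) < 1e-12))
}
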