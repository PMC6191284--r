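# Shared fixtures: small trees, simulation setups and hand-built
# alignments used across the test files.  Everything is generated in code.

# six-species tree with two candidate loss clades and an intact outgroup
fixture_tree6 <- function() {
  phy <- ape::read.tree(
    text = "(((A:10,B:10)ab:10,(C:15,D:15)cd:5)abcd:10,(E:12,F:12)ef:18)r;")
  time_tree(phy)
}

# the dating scenario: loss branch P(50 Mya) -> L(36 Mya)
fixture_tree_dating <- function() {
  phy <- ape::read.tree(
    text = "(((A:36,B:36)L:14,E:50)P:10,(C:45,D:45)Q:15)root;")
  time_tree(phy)
}

# eight intact species for omega-recovery fits
fixture_tree8 <- function() {
  phy <- ape::read.tree(text = paste0(
    "(((s1:10,s2:10):10,(s3:15,s4:15):5):10,",
    "((s5:12,s6:12):8,(s7:14,s8:14):6):10);"))
  time_tree(phy)
}

# small simulation with two loss events, lesions injected
fixture_sim6 <- function(seed = 11, n_codons = 400, ambiguity_runs = NULL) {
  tt <- fixture_tree6()
  cfg <- simulation_config(
    tt, n_codons = n_codons,
    loss_events = list(list(branch = "cd", loss_time_mya = 18),
                       list(branch = "E", loss_time_mya = 8)),
    ambiguity_runs = ambiguity_runs, seed = seed)
  inject_lesions(simulate_alignment(cfg))
}

# hand-built reference + species alignment over a 2-exon gene model:
# exons [0,30) and [40,70), intron [30,40) with GT..AG splice sites
fixture_toy_gene <- function() {
  model <- gene_model("toy", rbind(c(0L, 30L), c(40L, 70L)))
  # 10 intact codons per exon; reference CDS has no stops
  exon1 <- "ATGGCTGCTAGAGCTTTGGACTTGCAAGCT"
  exon2 <- "CCTGCTAGAGATATGTGGCTTATGGCTGCT"
  intron <- "GTAAGCCTAG" # GT...AG
  ref_seq <- paste0(exon1, intron, exon2)
  list(model = model, ref = species_alignment("ref", ref_seq),
       exon1 = exon1, exon2 = exon2, intron = intron)
}

# apply simple edits (by 0-based position) to a fixture sequence
edit_seq <- function(seq, at, replacement, len = nchar(replacement)) {
  paste0(substr(seq, 1, at), replacement,
         substr(seq, at + len + 1, nchar(seq)))
}

scan_statuses <- function(sim, missing_threshold = 0.2) {
  ref <- sim$alignments[[sim$truth$config$reference]]
  lapply(sim$alignments, function(a) {
    classify_status(scan_species(sim$model, a, ref), a, sim$model, ref,
                    missing_threshold = missing_threshold)
  })
}

mutation_key <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  sort(paste(df$mclass, df$position, df$size))
}
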