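# Codon simulator with regime switch: neutral limits, determinism,
# realized dN/dS from the event log, lesion injection, read pileups.

test_that("config validation rejects bad loss events and frequencies", {
  tt <- fixture_tree6()
  expect_error(simulation_config(tt, 100, loss_events = list(
    list(branch = "cd", loss_time_mya = 10))), "outside branch")
  expect_error(simulation_config(tt, 100, loss_events = list(
    list(branch = "cd", loss_time_mya = 17),
    list(branch = "C", loss_time_mya = 5))), "disjoint")
  expect_error(simulation_config(tt, 100, codon_frequencies = rep(1, 10)),
               "length 61 or 64")
  # reference must be intact
  expect_error(simulation_config(tt, 100, reference = "C", loss_events =
    list(list(branch = "cd", loss_time_mya = 17))), "reference")
})

test_that("simulation is reproducible and zero-duration branches copy the parent", {
  phy <- ape::read.tree(text = "((A:0,B:10)ab:5,C:15)r;")
  tt <- time_tree(phy)
  cfg <- simulation_config(tt, n_codons = 120, seed = 9)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  expect_identical(s1$alignments$A$aligned_seq, s2$alignments$A$aligned_seq)
  expect_identical(s1$truth$branch_stats, s2$truth$branch_stats)
  # A's branch has zero duration: its exonic sequence equals node ab's state
  expect_equal(s1$truth$branch_stats$n_syn[
    s1$truth$branch_stats$branch == "A"] +
      s1$truth$branch_stats$n_nonsyn[
        s1$truth$branch_stats$branch == "A"], 0)
})

test_that("neutral limit: omega_f = 1, c = 1 gives branch dN/dS near 1", {
  phy <- ape::read.tree(text = "(X:25,Y:25)r;")
  tt <- time_tree(phy)
  cfg <- simulation_config(tt, n_codons = 4000, omega_functional = 1,
                           syn_scaling = 1, seed = 21, n_exons = 1)
  sim <- simulate_alignment(cfg)
  om <- sim$truth$branch_stats$omega_realized
  expect_true(all(abs(om - 1) < 0.35)) # ~1 under mutational-opportunity norm
  # no stops in frame even though omega = 1 (functional regime forbids them)
  tb <- codon_tables()
  cds <- split_codons(sim$alignments$X$aligned_seq)
  expect_false(any(tb$aa[codon_index(cds)] == "*"))
})

test_that("pseudogene branch realized dN/dS is within sampling error of 1", {
  # oracle: count realized substitutions by type from the event log
  phy <- ape::read.tree(text = "(X:10,Y:10)r;")
  tt <- time_tree(phy)
  cfg <- simulation_config(tt, n_codons = 10000,
                           loss_events = list(list(branch = "X",
                                                   loss_time_mya = 10)),
                           seed = 3, n_exons = 1)
  sim <- simulate_alignment(cfg)
  bs <- sim$truth$branch_stats
  x <- bs[bs$branch == "X", ]
  se <- sqrt(1 / x$n_syn + 1 / x$n_nonsyn)
  expect_lt(abs(x$omega_realized - 1), 3 * se)
  # functional branch Y realizes omega near omega_f
  y <- bs[bs$branch == "Y", ]
  expect_lt(abs(y$omega_realized - 0.16), 3 * 0.16 *
              sqrt(1 / y$n_syn + 1 / y$n_nonsyn))
})

test_that("mixed branch realized dN/dS converges to the forward formula", {
  # cross-module consistency: half functional / half pseudogenic branch
  phy <- ape::read.tree(text = "(X:10,Y:10)r;")
  tt <- time_tree(phy)
  cfg <- simulation_config(tt, n_codons = 20000,
                           loss_events = list(list(branch = "X",
                                                   loss_time_mya = 5)),
                           seed = 8, n_exons = 1)
  sim <- simulate_alignment(cfg)
  x <- sim$truth$branch_stats[sim$truth$branch_stats$branch == "X", ]
  expected <- mixed_omega_forward(5, 5, 0.16, 0.7)
  se <- expected * sqrt(1 / x$n_syn + 1 / x$n_nonsyn)
  expect_lt(abs(x$omega_realized - expected), 3 * se)
})

test_that("pre-loss segments keep splice dinucleotides intact", {
  sim <- fixture_sim6(seed = 5)
  model <- sim$model
  for (sp in c("A", "B", "F")) { # intact species
    ch <- strsplit(sim$alignments[[sp]]$aligned_seq, "")[[1]]
    r2a <- alignment_maps(
      sim$alignments[[sim$truth$config$reference]]$aligned_seq)$ref2aln
    for (d in model$donor_sites) {
      expect_true(paste(ch[r2a[(d + 1):(d + 2)] + 1L], collapse = "") %in%
                    c("GT", "GC"))
    }
    for (a in model$acceptor_sites) {
      expect_equal(paste(ch[r2a[(a + 1):(a + 2)] + 1L], collapse = ""), "AG")
    }
  }
})

test_that("lesion injection respects class invariants and inheritance", {
  sim <- fixture_sim6(seed = 13)
  tr <- sim$truth$lesions
  fs <- tr[tr$mclass %in% c("frameshift_insertion", "frameshift_deletion"), ]
  expect_true(all(fs$size %% 3 != 0))
  sp <- tr[tr$mclass %in% c("splice_donor", "splice_acceptor"), ]
  expect_true(all(nchar(sp$ancestral_allele) == 2))
  # lesions shared on the ancestral cd segment are carried by both C and D
  shared <- tr[!is.na(tr$event_branch) & tr$event_branch == "cd", ]
  if (nrow(shared)) {
    for (id in unique(shared$event_id)) {
      carriers <- sort(shared$species[shared$event_id == id])
      expect_equal(carriers, c("C", "D"))
      pos <- unique(shared$position[shared$event_id == id])
      expect_length(pos, 1) # identical breakpoints
    }
  }
  # direct request to lesion an intact lineage is a config error
  expect_error(inject_lesions(simulate_alignment(sim$truth$config),
                              extra_lesions = list(list(
                                mclass = "nonsense", branch = "A"))),
               "intact")
})

test_that("frameshift of size 3 is rejected by the mutation constructor", {
  expect_error(inactivating_mutation("frameshift_insertion", 10, 3, "",
                                     "AAA"), "multiple of 3")
})

test_that("zero lesion rates leave the alignment unchanged", {
  tt <- fixture_tree6()
  cfg <- simulation_config(tt, n_codons = 150,
                           loss_events = list(list(branch = "E",
                                                   loss_time_mya = 8)),
                           lesion_rates = c(nonsense = 0), seed = 2)
  sim0 <- simulate_alignment(cfg)
  sim <- inject_lesions(sim0)
  expect_identical(sim$alignments$F$aligned_seq,
                   sim0$alignments$F$aligned_seq)
  # injected lesion table may still contain drift stops, but no indels
  expect_false(any(sim$truth$lesions$mclass %in%
                     c("frameshift_insertion", "frameshift_deletion",
                       "exon_deletion", "splice_donor", "splice_acceptor")))
})

test_that("simulated reads carry alleles at the requested fractions", {
  sim <- fixture_sim6(seed = 11)
  tr <- sim$truth$lesions
  m <- tr[tr$mclass == "frameshift_deletion" &
            tr$ancestral_allele != tr$derived_allele, ][1, ]
  aln <- sim$alignments[[m$species]]
  expect_length(simulate_reads(aln, m, depth = 0), 0)
  r1 <- simulate_reads(aln, m, depth = 40, derived_fraction = 1, seed = 1)
  s1 <- count_support(extract_context(aln, m), r1)
  expect_equal(s1$n_derived, 40)
  expect_equal(s1$n_ancestral, 0)
  r0 <- simulate_reads(aln, m, depth = 30, derived_fraction = 0, seed = 2)
  s0 <- count_support(extract_context(aln, m), r0)
  expect_equal(s0$n_derived, 0)
  # binomial oracle: derived fraction within 3 SDs at depth 1000
  r5 <- simulate_reads(aln, m, depth = 1000, derived_fraction = 0.5,
                       seed = 3)
  s5 <- count_support(extract_context(aln, m), r5)
  frac <- s5$n_derived / (s5$n_derived + s5$n_ancestral)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
  # determinism
  expect_identical(simulate_reads(aln, m, 20, seed = 9),
                   simulate_reads(aln, m, 20, seed = 9))
})
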