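# Probe extraction, read assignment and verdict classification.

test_that("SNV probes have symmetric flanks differing at the center", {
  aln <- species_alignment("sp", strrep("ACGTT", 40)) # 200 bp
  m <- inactivating_mutation("nonsense", 100, 3, "TTA", "TAA",
                             species = "sp")
  m$column <- 100L
  pr <- extract_context(aln, m, flank = 50)
  expect_equal(nchar(pr$derived_probe), 103)
  expect_equal(nchar(pr$ancestral_probe), 103)
  expect_equal(pr$offset, 50)
  d <- strsplit(pr$derived_probe, "")[[1]]
  a <- strsplit(pr$ancestral_probe, "")[[1]]
  expect_true(all(which(d != a) %in% (pr$offset + 1):(pr$offset + 3)))
})

test_that("insertion probes differ in length by the inserted bases", {
  sim <- fixture_sim6(seed = 11)
  tr <- sim$truth$lesions
  ins <- tr[tr$mclass == "frameshift_insertion", ][1, ]
  aln <- sim$alignments[[ins$species]]
  # locate the insertion columns from the reference row
  ref <- sim$alignments[[sim$truth$config$reference]]
  maps <- alignment_maps(ref$aligned_seq)
  ins$column <- maps$ref2aln[ins$position] + 0L # first inserted column
  pr <- extract_context(aln, ins, flank = 50)
  expect_equal(nchar(pr$derived_probe) - nchar(pr$ancestral_probe),
               ins$size)
})

test_that("deletion probes anchor across the breakpoint (toy oracle)", {
  # 200 bp toy with a 7 bp deletion at positions 100..106
  base <- strrep("ACGTTGCA", 25)
  ch <- strsplit(base, "")[[1]]
  deleted <- paste(ch[101:107], collapse = "")
  ch[101:107] <- "-"
  aln <- species_alignment("sp", paste(ch, collapse = ""))
  m <- inactivating_mutation("frameshift_deletion", 100, 7, deleted, "",
                             species = "sp")
  m$column <- 100L
  pr <- extract_context(aln, m, flank = 50)
  # manual construction
  expect_equal(pr$derived_probe,
               paste0(substr(base, 51, 100), substr(base, 108, 157)))
  expect_equal(pr$ancestral_probe, substr(base, 51, 157))
  expect_equal(pr$offset, 50)
})

test_that("too little flank is an error", {
  aln <- species_alignment("sp", strrep("ACGT", 10))
  m <- inactivating_mutation("nonsense", 3, 3, "TAC", "TAA",
                             species = "sp")
  m$column <- 3L
  expect_error(extract_context(aln, m), "10 bp of flanking")
})

test_that("reads are assigned by best match, both strands, ties to other", {
  set.seed(8)
  base <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  ch <- strsplit(base, "")[[1]]
  anc_codon <- paste(ch[97:99], collapse = "")
  ch[97:99] <- c("T", "A", "A")
  derived_hap <- paste(ch, collapse = "")
  m <- inactivating_mutation("nonsense", 96, 3, anc_codon, "TAA",
                             species = "sp")
  m$column <- 96L
  aln_d <- species_alignment("sp", derived_hap)
  pr <- extract_context(aln_d, m, flank = 50)
  derived_read <- substr(derived_hap, 60, 140)
  ancestral_read <- substr(base, 60, 140)
  sup <- count_support(pr, c(derived_read, ancestral_read))
  expect_equal(sup$n_derived, 1)
  expect_equal(sup$n_ancestral, 1)
  # reverse complement of a derived read still counts as derived
  sup_rc <- count_support(pr, revcomp(derived_read))
  expect_equal(sup_rc$n_derived, 1)
  # a read matching neither allele within budget is "other" if it spans the
  # site with equal mismatches to both
  garbled <- derived_read
  substr(garbled, 30, 45) <- strrep("T", 16)
  sup_g <- count_support(pr, garbled)
  expect_equal(sup_g$n_derived + sup_g$n_ancestral, 0)
  # empty read set: zero counts, low coverage verdict
  sup_e <- classify_support(count_support(pr, character(0)))
  expect_equal(sup_e$verdict, "low_coverage")
})

test_that("verdicts follow the confirmation and heterozygote rules", {
  mk <- function(d, a, o = 0) {
    structure(list(n_derived = d, n_ancestral = a, n_other = o),
              class = "read_support")
  }
  expect_equal(classify_support(mk(35, 0))$verdict, "confirmed")
  expect_equal(classify_support(mk(30, 0))$verdict, "confirmed")
  expect_equal(classify_support(mk(29, 0))$verdict, "low_coverage")
  expect_equal(classify_support(mk(18, 17))$verdict, "heterozygous")
  expect_equal(classify_support(mk(5, 40))$verdict, "unsupported")
  # a single ancestral read voids confirmation by default
  expect_equal(classify_support(mk(40, 1))$verdict, "unsupported")
  expect_equal(classify_support(mk(40, 1),
                                ancestral_tolerance = 1)$verdict,
               "confirmed")
})

test_that("classification is monotone in derived reads at zero ancestral", {
  mk <- function(d) structure(list(n_derived = d, n_ancestral = 0L,
                                   n_other = 0L), class = "read_support")
  ranks <- c(low_coverage = 0, confirmed = 1)
  verdicts <- vapply(seq(0, 60, by = 5), function(d) {
    classify_support(mk(d))$verdict
  }, character(1))
  expect_true(all(diff(ranks[verdicts]) >= 0))
})

test_that("reverse-complementing all reads leaves support unchanged", {
  sim <- fixture_sim6(seed = 11)
  tr <- sim$truth$lesions
  m <- tr[tr$mclass == "splice_donor", ][1, ]
  aln <- sim$alignments[[m$species]]
  reads <- simulate_reads(aln, m, depth = 30, derived_fraction = 0.5,
                          seed = 4)
  pr <- extract_context(aln, m)
  s1 <- count_support(pr, reads)
  s2 <- count_support(pr, vapply(reads, revcomp, character(1)))
  expect_equal(s1$n_derived, s2$n_derived)
  expect_equal(s1$n_ancestral, s2$n_ancestral)
  expect_equal(s1$n_other, s2$n_other)
})

test_that("confirmed whenever depth >= min_reads with clean derived reads", {
  sim <- fixture_sim6(seed = 11)
  tr <- sim$truth$lesions
  disc <- tr[tr$ancestral_allele != tr$derived_allele, ]
  for (k in seq_len(min(4, nrow(disc)))) {
    m <- disc[k, ]
    aln <- sim$alignments[[m$species]]
    reads <- simulate_reads(aln, m, depth = 30, derived_fraction = 1,
                            error_rate = 0, seed = 100 + k)
    sup <- classify_support(count_support(extract_context(aln, m), reads))
    expect_equal(sup$verdict, "confirmed", info = paste(m$mclass, m$position))
  }
})

test_that("reads round-trip through FASTA", {
  reads <- c(read1 = "ACGTACGTACGTACGTACGTACGTACGTACGT",
             read2 = "TTGCATTGCATTGCATTGCATTGCATTGCATT")
  path <- withr::local_tempfile(fileext = ".fa")
  write_reads_fasta(reads, path)
  back <- read_reads(path)
  expect_equal(unname(back), unname(reads))
})
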