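# Domain types and readers/writers: gene models, alignments, time trees,
# coordinate maps, and the combined results writer.

test_that("gene_model derives phases and splice sites and enforces invariants", {
  gm <- gene_model("g", rbind(c(0, 9), c(20, 32), c(40, 52)))
  expect_equal(gm$phases, c(0L, 0L, 0L))
  expect_equal(gm$donor_sites, c(9L, 32L))
  expect_equal(gm$acceptor_sites, c(18L, 38L))
  # every internal exon has exactly one donor and one acceptor
  expect_length(gm$donor_sites, nrow(gm$exons) - 1)
  gm2 <- gene_model("g", rbind(c(0, 10), c(20, 31))) # 10 + 11 = 21
  expect_equal(gm2$phases, c(0L, 1L))
  expect_error(gene_model("g", rbind(c(0, 10), c(5, 20))), "overlap")
  expect_error(gene_model("g", rbind(c(0, 10), c(20, 30))), "multiple of 3")
})

test_that("gene model round-trips through BED-like records, with strand flip", {
  gm <- gene_model("g", rbind(c(0, 9), c(20, 32), c(40, 52)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_model(gm, path)
  gm2 <- read_gene_model(path)
  expect_equal(gm2$exons, gm$exons)
  expect_equal(gm2$phases, gm$phases)
  # minus-strand records are normalized onto the plus strand
  df <- utils::read.table(path, sep = "\t")
  df$V6 <- "-"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gm3 <- read_gene_model(path2, region_length = 100)
  expect_equal(unname(gm3$exons[, "start"]), c(100 - 52, 100 - 32, 100 - 9))
  expect_error(read_gene_model(path2), "region_length")
})

test_that("read_alignment validates lengths and names, preserves gaps, uppercases", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">sp1", "acgT--ACGTNNNN", ">sp2", "ACGTAAACGTACGT"), path)
  alns <- read_alignment(path)
  expect_length(alns, 2)
  expect_equal(alns$sp1$aligned_seq, "ACGT--ACGTNNNN")
  expect_equal(unname(alns$sp1$ambiguity_runs[1, ]), c(10L, 14L))
  expect_equal(nrow(alns$sp2$ambiguity_runs), 0)
  writeLines(c(">a", "ACGTAA", ">b", "ACGT"), path)
  expect_error(read_alignment(path), "unequal")
  writeLines(c(">a", "ACGTAA", ">a", "ACGTAA"), path)
  expect_error(read_alignment(path), "duplicate")
})

test_that("alignment FASTA round-trip is lossless", {
  alns <- list(x = species_alignment("x", "ACGT--NNAC"),
               y = species_alignment("y", "ACGTAAACAC"))
  path <- withr::local_tempfile(fileext = ".fa")
  write_alignment(alns, path)
  back <- read_alignment(path)
  expect_equal(back$x$aligned_seq, alns$x$aligned_seq)
  expect_equal(back$y$aligned_seq, alns$y$aligned_seq)
})

test_that("coordinate maps are a bijection outside gap columns", {
  maps <- alignment_maps("AC--GT-A")
  expect_equal(maps$ref2aln, c(0L, 1L, 4L, 5L, 7L))
  expect_equal(maps$aln2ref[c(1, 2, 5, 6, 8)], c(0L, 1L, 2L, 3L, 4L))
  expect_true(all(is.na(maps$aln2ref[c(3, 4, 7)])))
  # round trip: ref -> column -> ref
  expect_equal(maps$aln2ref[maps$ref2aln + 1L], 0:4)
})

test_that("time_tree computes node dates and validates calibrations", {
  phy <- ape::read.tree(text = "((A:10,B:10)ab:5,C:15)r;")
  tt <- time_tree(phy)
  expect_equal(node_date(tt, "ab"), 10)
  expect_equal(node_date(tt, "r"), 15)
  expect_equal(branch_duration(tt, "ab"), 5)
  expect_equal(sort(descendant_tips(tt, "ab")), c("A", "B"))
  cal <- data.frame(label = "ab", older_bound = 12, younger_bound = 9)
  tt2 <- time_tree(phy, calibrations = cal)
  expect_equal(node_date(tt2, "ab", "older"), 12)
  expect_equal(node_date(tt2, "ab", "younger"), 9)
  bad <- data.frame(label = "ab", older_bound = 8, younger_bound = 9)
  expect_error(time_tree(phy, calibrations = bad), "calibration error")
  # child dated older than parent
  bad2 <- data.frame(label = "ab", older_bound = 20, younger_bound = 20)
  expect_error(time_tree(phy, calibrations = bad2), "older than")
})

test_that("zero-length branches are accepted with duration 0", {
  phy <- ape::read.tree(text = "((A:0,B:0)ab:5,C:5)r;")
  tt <- time_tree(phy)
  expect_equal(branch_duration(tt, "A"), 0)
  expect_equal(node_date(tt, "ab"), 0)
})

test_that("newick round trip preserves the time tree", {
  tt <- fixture_tree6()
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tt$phy, path)
  tt2 <- read_time_tree(path)
  expect_equal(sort(tt2$phy$tip.label), sort(tt$phy$tip.label))
  expect_equal(node_date(tt2, "cd"), node_date(tt, "cd"))
})

test_that("write_results is deterministic and handles empty input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(list(), list(), path, seed = 7)
  lines <- readLines(path)
  expect_length(lines, 2) # header comment + column header
  sim <- fixture_sim6(seed = 3, n_codons = 200)
  statuses <- scan_statuses(sim)
  path1 <- withr::local_tempfile(fileext = ".tsv")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(statuses, list(), path1, seed = 7)
  write_results(statuses, list(), path2, seed = 7)
  expect_identical(readLines(path1), readLines(path2))
  df <- utils::read.table(path1, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(df), length(statuses))
})
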