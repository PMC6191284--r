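# Inactivating-mutation scanner on hand-built alignments, status
# classification, and Dollo-parsimony placement.

test_that("an in-frame premature stop is called as nonsense", {
  toy <- fixture_toy_gene()
  # codon 4 of exon 1 (positions 9-11, 'AGA') -> TAA
  sp_seq <- edit_seq(toy$ref$aligned_seq, 9, "TAA")
  muts <- scan_species(toy$model, species_alignment("sp", sp_seq), toy$ref)
  expect_equal(nrow(muts), 1)
  expect_equal(muts$mclass, "nonsense")
  expect_equal(muts$position, 9)
  expect_equal(muts$derived_allele, "TAA")
})

test_that("a stop out of the reading frame is not called", {
  toy <- fixture_toy_gene()
  # 'TAA' written across a codon boundary (positions 10-12) must not make
  # an in-frame stop call unless it lands at a codon start
  sp_seq <- edit_seq(toy$ref$aligned_seq, 10, "TAA")
  muts <- scan_species(toy$model, species_alignment("sp", sp_seq), toy$ref)
  expect_false(any(muts$mclass == "nonsense" & muts$position == 10))
})

test_that("frameshifting deletions are called with size and position", {
  toy <- fixture_toy_gene()
  ch <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch[16:17] <- "-" # 2 bp deletion at positions 15-16 in exon 1
  muts <- scan_species(toy$model, species_alignment("sp",
                                                    paste(ch, collapse = "")),
                       toy$ref)
  del <- muts[muts$mclass == "frameshift_deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$position, 15)
  expect_equal(del$size, 2)
  # in-frame 3 bp deletion is not inactivating
  ch2 <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch2[16:18] <- "-"
  muts2 <- scan_species(toy$model,
                        species_alignment("sp", paste(ch2, collapse = "")),
                        toy$ref)
  expect_false(any(muts2$mclass == "frameshift_deletion"))
})

test_that("a 2 bp insertion is called as frameshift_insertion", {
  toy <- fixture_toy_gene()
  # insertion before reference position 50 (inside exon 2): add a gap
  # column block to the reference, bases in the species
  ref_g <- edit_seq(toy$ref$aligned_seq, 50, "--", len = 0)
  sp_g <- edit_seq(toy$ref$aligned_seq, 50, "CA", len = 0)
  muts <- scan_species(toy$model, species_alignment("sp", sp_g),
                       species_alignment("ref", ref_g))
  ins <- muts[muts$mclass == "frameshift_insertion", ]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$position, 50)
  expect_equal(ins$size, 2)
  expect_equal(ins$derived_allele, "CA")
})

test_that("donor GT->GC is tolerated, GT->AT is a splice mutation", {
  toy <- fixture_toy_gene()
  d <- toy$model$donor_sites[1] # position 30
  gc_seq <- edit_seq(toy$ref$aligned_seq, d, "GC")
  muts <- scan_species(toy$model, species_alignment("sp", gc_seq), toy$ref)
  expect_false(any(muts$mclass == "splice_donor"))
  at_seq <- edit_seq(toy$ref$aligned_seq, d, "AT")
  muts2 <- scan_species(toy$model, species_alignment("sp", at_seq), toy$ref)
  sd <- muts2[muts2$mclass == "splice_donor", ]
  expect_equal(nrow(sd), 1)
  expect_equal(sd$position, d)
  expect_equal(sd$derived_allele, "AT")
  # acceptor AG -> AC
  a <- toy$model$acceptor_sites[1]
  ac_seq <- edit_seq(toy$ref$aligned_seq, a, "AC")
  muts3 <- scan_species(toy$model, species_alignment("sp", ac_seq), toy$ref)
  expect_true(any(muts3$mclass == "splice_acceptor"))
})

test_that("exon deletions are called, but not across assembly gaps", {
  toy <- fixture_toy_gene()
  ch <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch[41:70] <- "-" # whole exon 2 deleted
  muts <- scan_species(toy$model,
                       species_alignment("sp", paste(ch, collapse = "")),
                       toy$ref)
  ed <- muts[muts$mclass == "exon_deletion", ]
  expect_equal(nrow(ed), 1)
  expect_equal(ed$position, 40)
  expect_equal(ed$size, 30)
  # exon aligned entirely to N: no exon_deletion call
  ch2 <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch2[41:70] <- "N"
  muts2 <- scan_species(toy$model,
                        species_alignment("sp", paste(ch2, collapse = "")),
                        toy$ref)
  expect_false(any(muts2$mclass == "exon_deletion"))
  # gap run bordered by N is ambiguous, also not called
  ch3 <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch3[41:60] <- "-"; ch3[61:70] <- "N"
  muts3 <- scan_species(toy$model,
                        species_alignment("sp", paste(ch3, collapse = "")),
                        toy$ref)
  expect_false(any(muts3$mclass %in% c("exon_deletion",
                                       "frameshift_deletion")))
})

test_that("nonsense scanning uses the frame implied by upstream indels", {
  toy <- fixture_toy_gene()
  # oracle: translate the edited sequence and locate stop positions
  ch <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch[7] <- "-"   # -1 bp at position 6 (exon 1): frame shifts by 2 downstream
  seq1 <- paste(ch, collapse = "")
  spliced <- function(s) {
    cset <- strsplit(s, "")[[1]]
    paste(c(cset[1:30][cset[1:30] != "-"],
            cset[41:70][cset[41:70] != "-"]), collapse = "")
  }
  cds <- spliced(seq1)
  tb <- codon_tables()
  n <- nchar(cds) %/% 3
  stops_oracle <- which(tb$aa[codon_index(split_codons(
    substr(cds, 1, 3 * n)))] == "*")
  muts <- scan_species(toy$model, species_alignment("sp", seq1), toy$ref)
  expect_equal(sum(muts$mclass == "nonsense"), length(stops_oracle))
  # two indels of +1 and -1 restore the frame between them
  ref_g <- edit_seq(toy$ref$aligned_seq, 20, "-", len = 0) # gap col for ins
  ch <- strsplit(edit_seq(toy$ref$aligned_seq, 20, "G", len = 0), "")[[1]]
  ch[8] <- "-" # deletion upstream of the insertion
  seq2 <- paste(ch, collapse = "")
  muts2 <- scan_species(toy$model, species_alignment("sp", seq2),
                        species_alignment("ref", ref_g))
  expect_equal(sum(muts2$mclass %in% c("frameshift_insertion",
                                       "frameshift_deletion")), 2)
})

test_that("native terminal stop of the reference is not called", {
  # gene whose reference ends in TAA: the species shares it silently
  model <- gene_model("t", rbind(c(0L, 12L)))
  ref <- species_alignment("ref", "ATGGCTGCTTAA")
  sp <- species_alignment("sp", "ATGGCTGCTTAA")
  expect_equal(nrow(scan_species(model, sp, ref)), 0)
})

test_that("scan errors on a broken reference frame", {
  model <- gene_model("t", rbind(c(0L, 12L)))
  ref <- species_alignment("ref", "ATGTAAGCTGCT") # internal stop
  sp <- species_alignment("sp", "ATGGCTGCTGCT")
  expect_error(scan_species(model, sp, ref), "reference frame")
})

test_that("classify_status follows the missing threshold rules", {
  toy <- fixture_toy_gene()
  # 25% of coding bases ambiguous -> missing even with a lesion present
  ch <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch[9:23] <- "N" # 15 of 60 coding bases
  ch[50] <- "T"
  aln <- species_alignment("sp", paste(ch, collapse = ""))
  muts <- scan_species(toy$model, aln, toy$ref)
  st <- classify_status(muts, aln, toy$model, toy$ref)
  expect_equal(st$status, "missing")
  # intact: no mutations, no ambiguity
  st2 <- classify_status(scan_species(toy$model, toy$ref, toy$ref),
                         toy$ref, toy$model, toy$ref)
  expect_equal(st2$status, "intact")
  expect_equal(nrow(st2$mutations), 0)
  # lost: one frameshift, 5% ambiguous
  ch3 <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch3[16:17] <- "-"; ch3[1:3] <- "N"
  aln3 <- species_alignment("sp", paste(ch3, collapse = ""))
  st3 <- classify_status(scan_species(toy$model, aln3, toy$ref), aln3,
                         toy$model, toy$ref)
  expect_equal(st3$status, "lost")
})

test_that("classify_status is monotone in added ambiguity", {
  toy <- fixture_toy_gene()
  ch <- strsplit(toy$ref$aligned_seq, "")[[1]]
  ch[16:17] <- "-"
  ranks <- c(intact = 0, lost = 1, missing = 2)
  prev <- 0
  for (n_amb in c(0, 6, 12, 18, 24)) {
    ch2 <- ch
    if (n_amb > 0) ch2[40 + seq_len(n_amb)] <- "N"
    aln <- species_alignment("sp", paste(ch2, collapse = ""))
    st <- classify_status(scan_species(toy$model, aln, toy$ref), aln,
                          toy$model, toy$ref)
    expect_gte(ranks[[st$status]], prev)
    prev <- max(prev, ranks[[st$status]])
  }
})

test_that("scanner is complete and exact against simulation truth", {
  for (seed in c(4, 9)) {
    sim <- fixture_sim6(seed = seed, ambiguity_runs = list(
      C = rbind(c(120, 250)), F = rbind(c(0, 400))))
    ref <- sim$alignments[[sim$truth$config$reference]]
    for (sp in names(sim$alignments)) {
      found <- scan_species(sim$model, sim$alignments[[sp]], ref)
      truth <- sim$truth$lesions
      truth <- truth[!is.na(truth$species) & truth$species == sp, ,
                     drop = FALSE]
      expect_identical(mutation_key(found), mutation_key(truth),
                       info = paste("seed", seed, sp))
    }
  }
})

test_that("loss placement: shared lesions map to the ancestral branch", {
  sim <- fixture_sim6(seed = 42)
  statuses <- scan_statuses(sim)
  placements <- suppressWarnings(place_loss_events(statuses,
                                                   sim$truth$config$tree))
  branches <- vapply(placements, `[[`, character(1), "event_branch")
  expect_setequal(branches, c("cd", "E"))
  cd <- placements[[match("cd", branches)]]
  expect_setequal(cd$species, c("C", "D"))
  expect_false(cd$independent)
  e <- placements[[match("E", branches)]]
  expect_true(e$independent)
})

test_that("placement count matches the Dollo-minimal oracle", {
  # oracle: exhaustive enumeration over subsets of branches of the 6-tip
  # tree, minimizing the number of events whose union of descendant tips
  # equals the lost set exactly
  tt <- fixture_tree6()
  labels <- tt_labels(tt)
  non_root <- setdiff(labels, "r")
  oracle_min_events <- function(lost) {
    best <- Inf
    n <- length(non_root)
    for (k in 1:min(3, n)) {
      for (comb in utils::combn(n, k, simplify = FALSE)) {
        tips <- unlist(lapply(non_root[comb], function(b) {
          descendant_tips(tt, b)
        }))
        if (length(tips) == length(lost) && setequal(tips, lost)) {
          best <- min(best, k)
        }
      }
      if (is.finite(best)) break
    }
    best
  }
  fake_status <- function(sp, status) {
    structure(list(species = sp, status = status,
                   mutations = empty_lesion_table(),
                   fraction_ambiguous = 0), class = "gene_status")
  }
  for (lost in list(c("C", "D", "E"), c("A", "C"), c("A", "B", "C", "D"),
                    c("E", "F"))) {
    statuses <- lapply(tt$phy$tip.label, function(sp) {
      fake_status(sp, if (sp %in% lost) "lost" else "intact")
    })
    names(statuses) <- tt$phy$tip.label
    placements <- place_loss_events(statuses, tt)
    expect_equal(length(placements), oracle_min_events(lost),
                 info = paste(lost, collapse = ","))
    # parsimony bound: events never exceed lost species
    expect_lte(length(placements), length(lost))
  }
})

test_that("placement is invariant under species reordering and rotation", {
  sim <- fixture_sim6(seed = 15)
  statuses <- scan_statuses(sim)
  p1 <- suppressWarnings(place_loss_events(statuses, sim$truth$config$tree))
  p2 <- suppressWarnings(place_loss_events(rev(statuses),
                                           sim$truth$config$tree))
  rot <- sim$truth$config$tree
  rot$phy <- ape::rotate(rot$phy, node = length(rot$phy$tip.label) + 1L)
  # re-derive helper fields after rotation
  rot <- time_tree(rot$phy)
  p3 <- suppressWarnings(place_loss_events(statuses, rot))
  key <- function(p) vapply(p, `[[`, character(1), "event_branch")
  expect_identical(key(p1), key(p2))
  expect_identical(key(p1), key(p3))
})

test_that("missing species do not break a lost clade", {
  tt <- fixture_tree6()
  fake <- function(sp, status) {
    structure(list(species = sp, status = status,
                   mutations = empty_lesion_table(),
                   fraction_ambiguous = 0), class = "gene_status")
  }
  statuses <- list(A = fake("A", "intact"), B = fake("B", "intact"),
                   C = fake("C", "lost"), D = fake("D", "missing"),
                   E = fake("E", "lost"), F = fake("F", "intact"))
  placements <- place_loss_events(statuses, tt)
  branches <- vapply(placements, `[[`, character(1), "event_branch")
  # D (missing) is compatible with loss, so the cd clade hosts one event
  expect_setequal(branches, c("cd", "E"))
})
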