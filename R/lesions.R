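# Injection of gene-inactivating lesions into post-loss lineages, and
# generator-side finalization of the ground truth.
#
# Lesions are sampled per post-loss tree segment (the neutral part of the
# loss branch, then every branch below it, in preorder).  A lesion placed on
# an ancestral segment is inherited by all descendant species with identical
# coordinates and alleles -- the shared-breakpoint signal that Dollo
# parsimony exploits.  Ground truth for nonsense mutations is finalized by
# translating each species' edited sequence with the generator's own edit
# records (frameshift-aware, ungapped arithmetic): neutral drift can create
# stop codons on its own, and injected lesions can be masked by later
# overlapping deletions, so the injected list alone is not the truth.

#' Construct an inactivating-mutation record
#'
#' @param mclass One of `r paste(LESION_CLASSES, collapse = ", ")`.
#' @param position 0-based reference coordinate of the first affected base
#'   (for insertions, the host coordinate the bases precede).
#' @param size Affected length in bp (3 for nonsense, 2 for splice classes,
#'   indel length for indels, exon span for exon deletions).
#' @param ancestral_allele,derived_allele Allele strings (`""` for the
#'   absent side of an indel).
#' @param exon_index 1-based index of the affected exon (intron index for
#'   splice classes).
#' @param species Carrier species (optional until assigned).
#' @return A one-row data.frame.
#' @export
inactivating_mutation <- function(mclass, position, size, ancestral_allele,
                                  derived_allele, exon_index = NA_integer_,
                                  species = NA_character_) {
  mclass <- match.arg(mclass, LESION_CLASSES)
  if (mclass %in% c("frameshift_insertion", "frameshift_deletion") &&
      size %% 3 == 0) {
    stop("frameshift indel size must not be a multiple of 3")
  }
  if (mclass %in% c("splice_donor", "splice_acceptor") &&
      nchar(ancestral_allele) != 2) {
    stop("splice classes carry a 2 bp ancestral dinucleotide")
  }
  data.frame(species = species, mclass = mclass,
             exon_index = as.integer(exon_index),
             position = as.integer(position), size = as.integer(size),
             ancestral_allele = ancestral_allele,
             derived_allele = derived_allele,
             event_branch = NA_character_, event_id = NA_integer_,
             shared = NA, stringsAsFactors = FALSE)
}

# spans (0-based half-open) touched by a lesion row
lesion_span <- function(row) {
  if (row$mclass == "frameshift_insertion") {
    c(row$position - 1L, row$position + 1L)
  } else {
    c(row$position, row$position + row$size)
  }
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

#' Inject inactivating lesions into a simulated alignment
#'
#' Samples lesions of the six classes on the post-loss segments of each loss
#' event (Poisson counts with the configured per-Myr class rates), inherits
#' ancestral-segment lesions identically in all descendants, materializes
#' the gapped alignment (insertion columns, deletion gaps, assembly-N runs)
#' and finalizes the ground-truth lesion table.
#'
#' @param sim Result of [simulate_alignment()].
#' @param extra_lesions Optional list of `list(mclass =, branch =)` entries
#'   forcing one lesion of a class onto a specific post-loss segment
#'   (placement still sampled).  A branch outside every loss subtree is a
#'   config error.
#' @param seed Seed for lesion sampling (default: config seed + 101).
#' @return The updated `list(alignments, truth, model)`; `truth$lesions` now
#'   holds one row per (species, visible lesion).
#' @export
inject_lesions <- function(sim, extra_lesions = NULL, seed = NULL) {
  config <- sim$truth$config
  tree <- config$tree
  model <- sim$model
  if (is.null(seed)) seed <- config$seed + 101L
  set.seed(seed)
  L0 <- max(model$exons[, "end"])
  exons <- model$exons
  n_exons <- nrow(exons)

  # post-loss segments, preorder within each loss event
  segments <- list()
  for (e in seq_along(config$loss_events)) {
    ev <- config$loss_events[[e]]
    cd <- node_date(tree, ev$branch)
    segments[[length(segments) + 1L]] <- list(
      label = ev$branch, event = e, duration = ev$loss_time_mya - cd,
      path = ev$branch)
    for (lab in descendant_labels(tree, ev$branch)) {
      pathup <- lab
      p <- lab
      while (p != ev$branch) {
        p <- parent_label(tree, p)
        pathup <- c(p, pathup)
      }
      segments[[length(segments) + 1L]] <- list(
        label = lab, event = e, duration = branch_duration(tree, lab),
        path = pathup)
    }
  }
  seg_labels <- vapply(segments, `[[`, character(1), "label")

  if (!is.null(extra_lesions)) {
    for (xl in extra_lesions) {
      if (!xl$branch %in% seg_labels) {
        stop("inject_lesions: branch '", xl$branch,
             "' is not on a post-loss lineage (lesion injection requested ",
             "for an intact lineage)")
      }
    }
  }

  # genomic chars of a node's sequence (tips: from alignments; internals:
  # codon states + reference introns as proxy)
  tb <- codon_tables()
  cpos <- coding_positions(model)
  ref_chars <- strsplit(sim$alignments[[config$reference]]$aligned_seq,
                        "")[[1]]
  node_exon_chars <- function(label) {
    id <- tt_node_id(tree, label)
    if (label %in% tree$phy$tip.label) {
      strsplit(sim$alignments[[label]]$aligned_seq, "")[[1]]
    } else {
      ch <- ref_chars
      cod <- tb$codons[sim$truth$node_codon_states[[id]]]
      ch[cpos + 1L] <- unlist(strsplit(cod, ""), use.names = FALSE)
      ch
    }
  }

  occupied <- list() # list of c(start, end, event, mclass)
  pad <- 6L
  is_free <- function(s, e, event, allow_cover = FALSE) {
    for (oc in occupied) {
      if (overlaps(s - pad, e + pad, oc[[1]], oc[[2]])) {
        if (allow_cover && oc[[3]] == event && oc[[4]] != "exon_deletion" &&
            s <= oc[[1]] && oc[[2]] <= e) next # exon deletion may cover
        return(FALSE)
      }
    }
    TRUE
  }

  rows <- list()
  event_id <- 0L
  draw_fs_size <- function() {
    repeat {
      sz <- stats::rgeom(1, 0.6) + 1L
      if (sz %% 3 != 0) return(sz)
    }
  }
  # net coding-frame index of reference coding position p for a lineage with
  # the given path lesions (insertions add, deletions subtract)
  coding_idx <- stats::setNames(seq_along(cpos) - 1L, cpos)
  frame_index <- function(p, path_rows) {
    base <- coding_idx[[as.character(p)]]
    shift <- 0L
    if (length(path_rows)) {
      for (r in path_rows) {
        if (r$mclass == "frameshift_insertion" && r$position <= p) {
          shift <- shift + r$size
        } else if (r$mclass %in% c("frameshift_deletion", "exon_deletion")) {
          del <- intersect_len(r$position, r$position + r$size, cpos, p)
          shift <- shift - del
        }
      }
    }
    base + shift
  }

  sample_lesion <- function(mclass, seg, path_rows) {
    anc_chars <- node_exon_chars(parent_label(tree, seg$label))
    for (try in 1:60) {
      if (mclass == "exon_deletion") {
        ei <- sample.int(n_exons, 1)
        s <- exons[ei, "start"]; e <- exons[ei, "end"]
        if (!is_free(s, e, seg$event, allow_cover = TRUE)) next
        anc <- paste(anc_chars[(s + 1):e], collapse = "")
        return(list(row = inactivating_mutation("exon_deletion", s, e - s,
                                                anc, "", ei),
                    span = c(s, e)))
      } else if (mclass == "nonsense") {
        ei <- sample.int(n_exons, 1, prob = exons[, "end"] - exons[, "start"])
        lo <- exons[ei, "start"]; hi <- exons[ei, "end"] - 3L
        if (hi < lo) next
        p <- sample(lo:hi, 1)
        if (frame_index(p, path_rows) %% 3 != 0) next
        if (!is_free(p, p + 3L, seg$event)) next
        anc <- paste(anc_chars[(p + 1):(p + 3)], collapse = "")
        if (tb$aa[codon_index(anc)] %in% c(NA, "*")) next
        stopc <- sample(c("TAA", "TAG", "TGA"), 1)
        return(list(row = inactivating_mutation("nonsense", p, 3L, anc,
                                                stopc, ei),
                    span = c(p, p + 3L)))
      } else if (mclass == "frameshift_insertion") {
        ei <- sample.int(n_exons, 1, prob = exons[, "end"] - exons[, "start"])
        lo <- exons[ei, "start"] + 1L; hi <- exons[ei, "end"] - 1L
        if (hi < lo) next
        p <- sample(lo:hi, 1)
        if (!is_free(p - 1L, p + 1L, seg$event)) next
        sz <- draw_fs_size()
        bases <- paste(sample(NUC, sz, replace = TRUE), collapse = "")
        return(list(row = inactivating_mutation("frameshift_insertion", p,
                                                sz, "", bases, ei),
                    span = c(p - 1L, p + 1L)))
      } else if (mclass == "frameshift_deletion") {
        ei <- sample.int(n_exons, 1, prob = exons[, "end"] - exons[, "start"])
        sz <- draw_fs_size()
        lo <- exons[ei, "start"]; hi <- exons[ei, "end"] - sz
        if (hi < lo) next
        s <- sample(lo:hi, 1)
        if (!is_free(s, s + sz, seg$event)) next
        anc <- paste(anc_chars[(s + 1):(s + sz)], collapse = "")
        return(list(row = inactivating_mutation("frameshift_deletion", s,
                                                sz, anc, "", ei),
                    span = c(s, s + sz)))
      } else if (mclass == "splice_donor") {
        if (!length(model$donor_sites)) return(NULL)
        ii <- sample.int(length(model$donor_sites), 1)
        d <- model$donor_sites[ii]
        if (!is_free(d, d + 2L, seg$event)) next
        return(list(row = inactivating_mutation(
          "splice_donor", d, 2L, "GT", sample(c("AT", "CT", "TT", "GA"), 1),
          ii), span = c(d, d + 2L)))
      } else { # splice_acceptor
        if (!length(model$acceptor_sites)) return(NULL)
        ii <- sample.int(length(model$acceptor_sites), 1)
        a <- model$acceptor_sites[ii]
        if (!is_free(a, a + 2L, seg$event)) next
        return(list(row = inactivating_mutation(
          "splice_acceptor", a, 2L, "AG", sample(c("AC", "GG", "TG", "CG"), 1),
          ii), span = c(a, a + 2L)))
      }
    }
    NULL
  }

  seg_rows <- stats::setNames(vector("list", length(segments)), seg_labels)
  want <- list()
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    for (cl in LESION_CLASSES) {
      n <- stats::rpois(1, config$lesion_rates[[cl]] * seg$duration)
      if (n > 0) want[[length(want) + 1L]] <- list(si = si, mclass = cl, n = n)
    }
  }
  if (!is.null(extra_lesions)) {
    for (xl in extra_lesions) {
      want[[length(want) + 1L]] <- list(si = match(xl$branch, seg_labels),
                                        mclass = xl$mclass, n = 1L)
    }
  }
  # sample in segment preorder so path lesions are known
  for (w in want[order(vapply(want, `[[`, numeric(1), "si"))]) {
    seg <- segments[[w$si]]
    path_rows <- unlist(lapply(seg$path, function(lb) seg_rows[[lb]]),
                        recursive = FALSE)
    for (i in seq_len(w$n)) {
      les <- sample_lesion(w$mclass, seg, path_rows)
      if (is.null(les)) next
      event_id <- event_id + 1L
      les$row$event_branch <- seg$label
      les$row$event_id <- event_id
      occupied[[length(occupied) + 1L]] <-
        list(les$span[1], les$span[2], seg$event, w$mclass)
      seg_rows[[seg$label]] <- c(seg_rows[[seg$label]], list(les$row))
      path_rows <- c(path_rows, list(les$row))
    }
  }

  # expand to per-species rows
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    carriers <- descendant_tips(tree, seg$label)
    for (r in seg_rows[[seg$label]]) {
      for (sp in carriers) {
        rr <- r
        rr$species <- sp
        rr$shared <- length(carriers) > 1
        rows[[length(rows) + 1L]] <- rr
      }
    }
  }
  lesions <- if (length(rows)) do.call(rbind, rows) else empty_lesion_table()

  out <- materialize_alignment(sim$alignments, lesions, model,
                               config$ambiguity_runs, config$reference)
  lost_tips <- unique(unlist(lapply(loss_branches(config), function(b) {
    descendant_tips(tree, b)
  })))
  truth <- sim$truth
  truth$lesions <- finalize_truth(sim$alignments, lesions, model,
                                  config, ref_chars, lost_tips)
  list(alignments = out, truth = truth, model = model)
}

# total overlap of [s,e) with coding positions strictly upstream of p
intersect_len <- function(s, e, cpos, p) {
  sum(cpos >= s & cpos < e & cpos < p)
}

# Build the gapped alignment: deletions as "-", insertion columns shared by
# carrier species, assembly-gap runs as "N".
materialize_alignment <- function(alignments, lesions, model,
                                  ambiguity_runs, reference) {
  L0 <- max(model$exons[, "end"])
  species <- names(alignments)
  chars <- lapply(alignments, function(a) strsplit(a$aligned_seq, "")[[1]])
  if (nrow(lesions)) {
    subs <- lesions[lesions$mclass %in%
                      c("nonsense", "splice_donor", "splice_acceptor"), ]
    for (k in seq_len(nrow(subs))) {
      r <- subs[k, ]
      chars[[r$species]][(r$position + 1):(r$position + r$size)] <-
        strsplit(r$derived_allele, "")[[1]]
    }
    dels <- lesions[lesions$mclass %in%
                      c("frameshift_deletion", "exon_deletion"), ]
    for (k in seq_len(nrow(dels))) {
      r <- dels[k, ]
      chars[[r$species]][(r$position + 1):(r$position + r$size)] <- "-"
    }
  }
  # assembly gaps hide whatever is underneath, including true deletions:
  # an N run is stamped over bases and gap characters alike
  if (!is.null(ambiguity_runs)) {
    for (sp in names(ambiguity_runs)) {
      runs <- ambiguity_runs[[sp]]
      for (k in seq_len(nrow(runs))) {
        chars[[sp]][(runs[k, 1] + 1):runs[k, 2]] <- "N"
      }
    }
  }
  # insertion columns
  ins <- if (nrow(lesions)) {
    lesions[lesions$mclass == "frameshift_insertion", ]
  } else lesions
  if (nrow(ins)) {
    evs <- unique(ins[, c("event_id", "position", "size", "derived_allele")])
    evs <- evs[order(evs$position, evs$event_id), ]
    carriers_of <- split(ins$species, ins$event_id)
    # assemble per species in one pass over reference positions
    pieces <- lapply(species, function(sp) character(0))
    names(pieces) <- species
    cut_at <- c(0L, evs$position, L0) # segments between insertion points
    for (sp in species) {
      segs <- character(nrow(evs) + 1L)
      for (i in seq_len(nrow(evs) + 1L)) {
        s <- cut_at[i]; e <- cut_at[i + 1L]
        segs[i] <- if (e > s) paste(chars[[sp]][(s + 1):e], collapse = "") else ""
      }
      insblocks <- vapply(seq_len(nrow(evs)), function(i) {
        ev <- evs[i, ]
        host <- chars[[sp]][c(ev$position, ev$position + 1L)]
        # a deleted host removes the insertion with it; an N host means the
        # assembly gap swallowed it -- either way nothing is observed
        host_hidden <- all(host == "-") || any(host == "N")
        if (sp %in% carriers_of[[as.character(ev$event_id)]] &&
            !host_hidden) {
          ev$derived_allele
        } else {
          strrep("-", ev$size)
        }
      }, character(1))
      woven <- character(2 * nrow(evs) + 1L)
      woven[seq(1, length(woven), 2)] <- segs
      woven[seq(2, length(woven), 2)] <- insblocks
      pieces[[sp]] <- paste(woven, collapse = "")
    }
    out <- lapply(species, function(sp) species_alignment(sp, pieces[[sp]]))
  } else {
    out <- lapply(species, function(sp) {
      species_alignment(sp, paste(chars[[sp]], collapse = ""))
    })
  }
  names(out) <- species
  out
}

loss_branches <- function(config) {
  vapply(config$loss_events, `[[`, character(1), "branch")
}

# Generator-side truth: per species, the visible lesions after masking by
# larger deletions and assembly gaps, with nonsense truth recomputed by
# frame-aware translation of the edited sequence.  Every post-loss species
# is finalized, whether or not it carries injected lesions: neutral drift
# alone can create in-frame stop codons.
finalize_truth <- function(raw_alignments, lesions, model, config,
                           ref_chars, lost_tips) {
  exons <- model$exons
  out <- list()
  for (sp in lost_tips) {
    mine <- lesions[lesions$species == sp, , drop = FALSE]
    amb <- if (!is.null(config$ambiguity_runs) &&
               sp %in% names(config$ambiguity_runs)) {
      config$ambiguity_runs[[sp]]
    } else matrix(integer(0), ncol = 2)
    # pass 1: assembly gaps suppress lesions they cover or (for deletion
    # classes) touch -- the scanner cannot distinguish a deletion run that
    # borders an N run from an artifact, and skips it
    amb_hides <- function(r) {
      sp_span <- lesion_span(r)
      for (j in seq_len(nrow(amb))) {
        a1 <- amb[j, 1]; a2 <- amb[j, 2]
        hit <- if (r$mclass %in% c("frameshift_deletion", "exon_deletion")) {
          a1 <= sp_span[2] && a2 >= sp_span[1] # overlap or abut
        } else {
          a1 < sp_span[2] && a2 > sp_span[1]
        }
        if (hit) return(TRUE)
      }
      FALSE
    }
    visible <- !vapply(seq_len(nrow(mine)), function(k) amb_hides(mine[k, ]),
                       logical(1))
    mine <- mine[visible, ]
    # pass 2: a (still visible) larger deletion masks lesions inside it
    dels <- mine[mine$mclass %in% c("frameshift_deletion", "exon_deletion"), ]
    visible <- vapply(seq_len(nrow(mine)), function(k) {
      r <- mine[k, ]
      sp_span <- lesion_span(r)
      for (j in seq_len(nrow(dels))) {
        d <- dels[j, ]
        if (d$event_id == r$event_id) next
        if (d$position <= sp_span[1] && sp_span[2] <= d$position + d$size) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    mine <- mine[visible, ]
    # rebuild edited exonic sequence with anchors, translate for stops
    chars <- strsplit(raw_alignments[[sp]]$aligned_seq, "")[[1]]
    subs <- mine[mine$mclass == "nonsense", ]
    for (k in seq_len(nrow(subs))) {
      r <- subs[k, ]
      chars[(r$position + 1):(r$position + r$size)] <-
        strsplit(r$derived_allele, "")[[1]]
    }
    # deletions are real absences whether or not their row is callable;
    # N runs then override: an assembly gap shows N, never a deletion
    deleted <- rep(FALSE, length(chars))
    all_dels <- lesions[lesions$species == sp &
                          lesions$mclass %in% c("frameshift_deletion",
                                                "exon_deletion"), ,
                        drop = FALSE]
    for (k in seq_len(nrow(all_dels))) {
      r <- all_dels[k, ]
      deleted[(r$position + 1):(r$position + r$size)] <- TRUE
    }
    for (j in seq_len(nrow(amb))) {
      chars[(amb[j, 1] + 1):amb[j, 2]] <- "N"
      deleted[(amb[j, 1] + 1):amb[j, 2]] <- FALSE
    }
    ins <- mine[mine$mclass == "frameshift_insertion", ]
    ins <- ins[order(ins$position, ins$event_id), ]
    cds <- character(0); anchor <- integer(0)
    for (ei in seq_len(nrow(exons))) {
      s <- exons[ei, "start"]; e <- exons[ei, "end"]
      for (p in s:(e - 1L)) {
        hit <- ins[ins$position == p & ins$position > s & ins$position < e, ]
        for (k in seq_len(nrow(hit))) {
          b <- strsplit(hit$derived_allele[k], "")[[1]]
          cds <- c(cds, b); anchor <- c(anchor, rep(p, length(b)))
        }
        if (!deleted[p + 1L]) {
          cds <- c(cds, chars[p + 1L]); anchor <- c(anchor, p)
        }
      }
    }
    tb <- codon_tables()
    keep <- mine[mine$mclass != "nonsense", ]
    ncod <- length(cds) %/% 3
    for (k in seq_len(ncod)) {
      codon <- paste(cds[(3 * k - 2):(3 * k)], collapse = "")
      ci <- codon_index(codon)
      if (!is.na(ci) && tb$aa[ci] == "*") {
        a <- anchor[3 * k - 2]
        ref_codon <- paste(ref_chars[(a + 1):(a + 3)], collapse = "")
        ei <- which(exons[, "start"] <= a & a < exons[, "end"])[1]
        row <- inactivating_mutation("nonsense", a, 3L, ref_codon, codon,
                                     ei, species = sp)
        row$event_branch <- NA_character_
        row$shared <- NA
        keep <- rbind(keep, row)
      }
    }
    out[[sp]] <- keep
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
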