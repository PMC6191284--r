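# Scanning aligned coding sequences for gene-inactivating mutations,
# classifying per-species gene status, and placing loss events on the tree
# by shared-mutation Dollo parsimony.
#
# The scanner works purely from the gapped alignment (columns), while the
# simulator's truth is finalized from its edit records (ungapped
# arithmetic); agreement between the two is the package's core
# completeness check.  Observability rules: a deletion run that overlaps or
# borders an assembly-gap N run is not called (an assembly gap could mimic
# or hide a deletion); an insertion is not called when either host base is
# N; a codon or splice dinucleotide containing N is never a mutation call.

#' Scan one species for gene-inactivating mutations
#'
#' Detects the six lesion classes -- premature stop codons (in the reading
#' frame implied by all upstream indels of that species), frameshifting
#' insertions and deletions, disrupted splice-site dinucleotides (donor
#' GT/GC, acceptor AG), and whole-exon deletions -- in a species' aligned
#' sequence relative to the reference gene model.
#'
#' @param model A [gene_model()] in reference coordinates.
#' @param aln [species_alignment()] of the species to scan.
#' @param reference [species_alignment()] of the reference species (intact
#'   reading frame, no gaps except at insertion columns).
#' @return A data.frame of mutations (possibly 0-row) with the
#'   [inactivating_mutation()] columns plus `column` (0-based alignment
#'   column anchor).
#' @export
scan_species <- function(model, aln, reference) {
  if (nchar(aln$aligned_seq) != nchar(reference$aligned_seq)) {
    stop("scan_species: species and reference alignment lengths differ")
  }
  rc <- strsplit(reference$aligned_seq, "")[[1]]
  sc <- strsplit(aln$aligned_seq, "")[[1]]
  maps <- alignment_maps(reference$aligned_seq)
  r2a <- maps$ref2aln  # 0-based ref -> 0-based column
  exons <- model$exons
  n_ex <- nrow(exons)
  # reference frame must be intact
  ref_cds <- unlist(lapply(seq_len(n_ex), function(i) {
    rc[r2a[(exons[i, "start"] + 1):exons[i, "end"]] + 1L]
  }))
  if (length(ref_cds) %% 3 != 0) {
    stop("scan_species: reference frame broken (coding length not multiple of 3)")
  }
  tb <- codon_tables()
  ref_cod <- codon_index(vapply(seq_len(length(ref_cds) %/% 3), function(k) {
    paste(ref_cds[(3 * k - 2):(3 * k)], collapse = "")
  }, character(1)))
  internal_stops <- which(!is.na(ref_cod) & tb$aa[ref_cod] == "*")
  internal_stops <- internal_stops[internal_stops < length(ref_cod)]
  if (length(internal_stops)) {
    stop("scan_species: reference frame broken (internal stop codon)")
  }
  # native terminal stop of the reference, to be excluded from calls
  term_stop_anchor <- NA_integer_
  last <- length(ref_cod)
  if (!is.na(ref_cod[last]) && tb$aa[ref_cod[last]] == "*") {
    cpos_all <- coding_positions(model)
    term_stop_anchor <- cpos_all[3 * last - 2]
  }

  muts <- list()
  add <- function(row, column) {
    row$column <- as.integer(column)
    muts[[length(muts) + 1L]] <<- row
  }

  # --- exon deletions ---------------------------------------------------
  exon_deleted <- logical(n_ex)
  for (ei in seq_len(n_ex)) {
    cols <- r2a[(exons[ei, "start"] + 1):exons[ei, "end"]] + 1L
    spch <- sc[cols]
    if (all(spch == "-")) {
      # bordering N means the locus overlaps an assembly gap: do not call
      lo <- min(cols); hi <- max(cols)
      border <- c(if (lo > 1) sc[lo - 1L], if (hi < length(sc)) sc[hi + 1L])
      if (!any(border == "N", na.rm = TRUE)) {
        exon_deleted[ei] <- TRUE
        anc <- paste(rc[cols], collapse = "")
        row <- inactivating_mutation("exon_deletion", exons[ei, "start"],
                                     exons[ei, "end"] - exons[ei, "start"],
                                     anc, "", ei, species = aln$species)
        add(row, lo - 1L)
      }
    }
  }

  # --- frameshifting indels within exons --------------------------------
  for (ei in seq_len(n_ex)) {
    if (exon_deleted[ei]) next
    s <- exons[ei, "start"]; e <- exons[ei, "end"]
    cols <- r2a[(s + 1):e] + 1L # 1-based columns of the exon's ref bases
    # deletions: maximal runs of '-'/'N' over ref-base columns; runs that
    # contain N are ambiguous, pure-gap runs are deletions
    ch <- sc[cols]
    r <- rle(ch %in% c("-", "N"))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- ch[starts[k]:ends[k]]
      if (any(seg == "N")) next
      sz <- length(seg)
      if (sz == length(ch)) next # whole exon: handled (or suppressed) above
      # a run bordered by N overlaps an assembly gap: not callable
      lo <- cols[starts[k]]; hi <- cols[ends[k]]
      border <- c(if (lo > 1) sc[lo - 1L], if (hi < length(sc)) sc[hi + 1L])
      if (any(border == "N", na.rm = TRUE)) next
      if (sz %% 3 == 0) next     # in-frame deletion is not inactivating
      pos0 <- s + starts[k] - 1L
      anc <- paste(rc[cols[starts[k]:ends[k]]], collapse = "")
      row <- inactivating_mutation("frameshift_deletion", pos0, sz, anc, "",
                                   ei, species = aln$species)
      add(row, cols[starts[k]] - 1L)
    }
    # insertions: reference-gap column blocks between consecutive exon-
    # internal ref bases; species bases inside the block are inserted
    if (e - s < 2L) next
    for (p in (s + 1):(e - 1L)) { # host coordinate: insertion before base p
      c_prev <- r2a[p] + 1L       # column of ref base p-1
      c_here <- r2a[p + 1L] + 1L  # column of ref base p
      if (c_here - c_prev <= 1L) next
      block <- sc[(c_prev + 1L):(c_here - 1L)]
      ins <- block[block != "-"]
      if (!length(ins)) next
      if (sc[c_prev] == "N" || sc[c_here] == "N") next # host base ambiguous
      if (length(ins) %% 3 == 0) next
      row <- inactivating_mutation("frameshift_insertion", p, length(ins),
                                   "", paste(ins, collapse = ""), ei,
                                   species = aln$species)
      first_col <- (c_prev + 1L:length(block))[block != "-"][1]
      add(row, first_col - 1L)
    }
  }

  # --- splice-site dinucleotides ----------------------------------------
  for (ii in seq_along(model$donor_sites)) {
    if (exon_deleted[ii]) next # junction belongs to a deleted exon
    d <- model$donor_sites[ii]
    colp <- r2a[(d + 1):(d + 2)] + 1L
    dinuc <- paste(sc[colp], collapse = "")
    if (grepl("[N-]", dinuc)) next
    if (!dinuc %in% c("GT", "GC")) {
      row <- inactivating_mutation("splice_donor", d, 2L,
                                   paste(rc[colp], collapse = ""), dinuc, ii,
                                   species = aln$species)
      add(row, colp[1] - 1L)
    }
  }
  for (ii in seq_along(model$acceptor_sites)) {
    if (exon_deleted[ii + 1L]) next
    a <- model$acceptor_sites[ii]
    colp <- r2a[(a + 1):(a + 2)] + 1L
    dinuc <- paste(sc[colp], collapse = "")
    if (grepl("[N-]", dinuc)) next
    if (dinuc != "AG") {
      row <- inactivating_mutation("splice_acceptor", a, 2L,
                                   paste(rc[colp], collapse = ""), dinuc, ii,
                                   species = aln$species)
      add(row, colp[1] - 1L)
    }
  }

  # --- nonsense codons in the indel-implied frame -----------------------
  # assemble the species CDS: species bases at exon ref columns (skipping
  # deletions) plus inserted bases hosted strictly inside an exon
  cds_ch <- character(0); cds_anchor <- integer(0); cds_col <- integer(0)
  for (ei in seq_len(n_ex)) {
    if (exon_deleted[ei]) next
    s <- exons[ei, "start"]; e <- exons[ei, "end"]
    prev_col <- r2a[s + 1L] # 0-based column of first exon base
    for (p in s:(e - 1L)) {
      cc <- r2a[p + 1L] + 1L
      if (p > s && cc - prev_col > 1L) {
        # insertion block before ref base p (host strictly inside exon)
        block_cols <- (prev_col + 1L):(cc - 1L)
        bl <- sc[block_cols]
        keepb <- bl != "-" & bl != "N"
        cds_ch <- c(cds_ch, bl[keepb])
        cds_anchor <- c(cds_anchor, rep(p, sum(keepb)))
        cds_col <- c(cds_col, block_cols[keepb] - 1L)
      }
      if (sc[cc] != "-") {
        cds_ch <- c(cds_ch, sc[cc])
        cds_anchor <- c(cds_anchor, p)
        cds_col <- c(cds_col, cc - 1L)
      }
      prev_col <- cc
    }
  }
  ncod <- length(cds_ch) %/% 3
  for (k in seq_len(ncod)) {
    idx <- (3 * k - 2):(3 * k)
    codon <- paste(cds_ch[idx], collapse = "")
    ci <- codon_index(codon)
    if (is.na(ci) || tb$aa[ci] != "*") next
    anchor <- cds_anchor[idx[1]]
    if (!is.na(term_stop_anchor) && anchor == term_stop_anchor &&
        k == ncod) next # native terminal stop
    acols <- r2a[(anchor + 1):(anchor + 3)] + 1L
    anc <- paste(rc[acols[!is.na(acols)]], collapse = "")
    ei <- which(exons[, "start"] <= anchor & anchor < exons[, "end"])[1]
    row <- inactivating_mutation("nonsense", anchor, 3L, anc, codon, ei,
                                 species = aln$species)
    add(row, cds_col[idx[1]])
  }

  if (!length(muts)) {
    out <- empty_lesion_table()
    out$column <- integer(0)
    return(out)
  }
  out <- do.call(rbind, muts)
  out <- out[order(out$position, out$mclass), ]
  rownames(out) <- NULL
  out
}

#' Classify a species' gene status
#'
#' A species is `missing` when more than `missing_threshold` of the coding
#' region is ambiguous (N) -- checked before anything else; `lost` when it
#' carries at least one inactivating mutation; `intact` otherwise.
#'
#' @param mutations Mutation table from [scan_species()].
#' @param aln The species' [species_alignment()].
#' @param model The reference [gene_model()].
#' @param reference The reference [species_alignment()] (for coordinate
#'   mapping).
#' @param missing_threshold Fraction of ambiguous coding bases above which
#'   the species is classified missing (default 0.2).
#' @return An object of class `gene_status`.
#' @export
classify_status <- function(mutations, aln, model, reference,
                            missing_threshold = 0.2) {
  r2a <- alignment_maps(reference$aligned_seq)$ref2aln
  sc <- strsplit(aln$aligned_seq, "")[[1]]
  exon_cols <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    r2a[(model$exons[i, "start"] + 1):model$exons[i, "end"]] + 1L
  }))
  frac_amb <- sum(sc[exon_cols] == "N") / length(exon_cols)
  status <- if (frac_amb > missing_threshold) {
    "missing"
  } else if (nrow(mutations) > 0) {
    "lost"
  } else "intact"
  structure(list(species = aln$species, status = status,
                 mutations = if (status == "missing") {
                   mutations[0, , drop = FALSE]
                 } else mutations,
                 fraction_ambiguous = frac_amb),
            class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("%s: %s (%d inactivating mutations, %.1f%% ambiguous)\n",
              x$species, x$status, nrow(x$mutations),
              100 * x$fraction_ambiguous))
  invisible(x)
}

#' Place gene-loss events on the tree by Dollo parsimony
#'
#' Finds the minimal set of loss events consistent with the per-species
#' statuses: one event per maximal clade whose non-missing members are all
#' lost (missing species are compatible with either state), placed on the
#' branch above that clade.  Mutations shared -- same class, coordinates
#' within `tolerance` alignment columns -- by all non-missing descendants of
#' the event branch attach as supporting evidence; a species missing the
#' mutation is excused when an overlapping larger deletion removed the
#' site.  A mutation shared by species in disjoint lost clades triggers a
#' homoplasy warning and does not support either event.
#'
#' @param statuses Named list of [classify_status()] results covering all
#'   tips.
#' @param tree A [time_tree()].
#' @param tolerance Breakpoint tolerance in columns for calling two
#'   mutations "the same" (default 2).
#' @return List of loss placements: `event_branch` (child-node label),
#'   `species`, `supporting_mutations` (data.frame), `n_shared`,
#'   `independent`.
#' @export
place_loss_events <- function(statuses, tree, tolerance = 2) {
  tips <- tree$phy$tip.label
  if (!all(tips %in% names(statuses))) {
    stop("place_loss_events: statuses must cover every tip of the tree")
  }
  st <- vapply(tips, function(s) statuses[[s]]$status, character(1))
  lost <- names(st)[st == "lost"]
  if (!length(lost)) return(list())
  labels <- tt_labels(tree)
  all_lost <- function(lab) {
    dt <- descendant_tips(tree, lab)
    sub <- st[dt]
    any(sub == "lost") && all(sub != "intact")
  }
  is_event <- vapply(labels, function(lab) {
    if (!all_lost(lab)) return(FALSE)
    pa <- parent_label(tree, lab)
    is.na(pa) || !all_lost(pa)
  }, logical(1))
  event_branches <- labels[is_event]

  # group mutations across lost species by (class, position +/- tolerance)
  all_m <- do.call(rbind, lapply(lost, function(s) statuses[[s]]$mutations))
  groups <- list()
  if (!is.null(all_m) && nrow(all_m)) {
    all_m <- all_m[order(all_m$mclass, all_m$position), ]
    gid <- integer(nrow(all_m))
    cur <- 0L
    for (i in seq_len(nrow(all_m))) {
      if (i == 1L || all_m$mclass[i] != all_m$mclass[i - 1L] ||
          all_m$position[i] - all_m$position[i - 1L] > tolerance) {
        cur <- cur + 1L
      }
      gid[i] <- cur
    }
    groups <- split(all_m, gid)
  }

  placements <- lapply(event_branches, function(br) {
    dt <- descendant_tips(tree, br)
    members <- dt[st[dt] == "lost"]
    checkset <- dt[st[dt] != "missing"]
    supporting <- list()
    for (g in groups) {
      carriers <- unique(g$species)
      if (!all(carriers %in% dt)) next # spans other clades: not ours
      if (length(carriers) < 2 && length(checkset) > 1) next
      ok <- vapply(checkset, function(s) {
        if (s %in% carriers) return(TRUE)
        # excused if an explicit overlapping larger deletion removed the site
        m <- statuses[[s]]$mutations
        dl <- m[m$mclass %in% c("frameshift_deletion", "exon_deletion"), ,
                drop = FALSE]
        span <- c(min(g$position), max(g$position) + g$size[1])
        any(dl$position <= span[1] & span[2] <= dl$position + dl$size)
      }, logical(1))
      if (all(ok)) supporting[[length(supporting) + 1L]] <- g
    }
    supp <- if (length(supporting)) do.call(rbind, supporting) else NULL
    list(event_branch = br, species = sort(members),
         supporting_mutations = supp,
         n_shared = length(supporting),
         independent = length(members) == 1L)
  })

  # homoplasy: a group whose carriers span multiple event clades
  for (g in groups) {
    carriers <- unique(g$species)
    n_in <- vapply(event_branches, function(br) {
      length(intersect(carriers, descendant_tips(tree, br))) > 0
    }, logical(1))
    if (sum(n_in) > 1) {
      warning("place_loss_events: mutation (", g$mclass[1], " @ ",
              g$position[1], ") shared across disjoint loss clades; ",
              "treated as homoplasy", call. = FALSE)
    }
  }
  placements[order(vapply(placements, `[[`, character(1), "event_branch"))]
}
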