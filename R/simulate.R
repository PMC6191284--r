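# Codon substitution simulator with a functional-to-neutral regime switch.
#
# Sequences evolve along a time tree under a Muse-Gaut style codon model:
# the rate of a single-nucleotide codon change is proportional to the
# position-specific frequency of the target nucleotide, multiplied by kappa
# for transitions and by omega_functional for nonsynonymous changes.  On a
# functional branch both synonymous and nonsynonymous rates are additionally
# scaled by c = syn_scaling (< 1: constraints on splicing/translation slow
# even synonymous evolution), and changes into stop codons are forbidden.
# After a gene-loss event the sequence evolves fully neutrally (omega = 1,
# no c scaling, stop codons permitted and retained).  The branch carrying a
# loss event is split at the loss time into two constant-rate segments.
# Every substitution event is logged, giving per-branch realized dN/dS with
# mutational-opportunity site normalization.

LESION_CLASSES <- c("nonsense", "frameshift_insertion", "frameshift_deletion",
                    "splice_donor", "splice_acceptor", "exon_deletion")

#' Configuration for the gene-loss simulator
#'
#' @param tree A [time_tree()]; branch lengths in Myr.
#' @param n_codons Number of codons in the coding sequence.
#' @param omega_functional dN/dS of functional branches (0 < omega_f <= 1).
#' @param kappa Transition/transversion rate ratio.
#' @param codon_frequencies Optional codon frequency vector (length 61 over
#'   sense codons in lexicographic ACGT order, or length 64 with stop slots).
#'   Defaults to uniform sense-codon frequencies.  Position-specific
#'   nucleotide frequencies for the rate model are derived from it.
#' @param syn_scaling Functional-to-neutral synonymous rate ratio c
#'   (default 0.7).
#' @param neutral_rate Fully neutral nucleotide substitution rate, in
#'   substitutions per site per Myr (default 0.002).
#' @param loss_events List of `list(branch = <child node label>,
#'   loss_time_mya = <date>)`; each loss time must lie within its branch's
#'   date span, and loss subtrees must be disjoint.
#' @param lesion_rates Named vector of per-class lesion injection rates
#'   (expected events per Myr of post-loss lineage time) for
#'   [inject_lesions()]; names among
#'   `r paste(LESION_CLASSES, collapse = ", ")`.
#' @param n_exons Number of coding exons in the synthetic gene model.
#' @param intron_length Length (bp) of each simulated intron.
#' @param reference Tip label used as the coordinate reference; must not be
#'   below any loss event.  Default: first intact tip.
#' @param ambiguity_runs Optional named list (species -> two-column matrix of
#'   0-based half-open spans) of assembly-gap N runs to stamp into the
#'   output, emulating incomplete assemblies.
#' @param seed Integer seed; the simulation is fully reproducible given the
#'   config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(tree, n_codons, omega_functional = 0.16,
                              kappa = 2, codon_frequencies = NULL,
                              syn_scaling = 0.7, neutral_rate = 0.002,
                              loss_events = list(),
                              lesion_rates = c(nonsense = 0.10,
                                               frameshift_insertion = 0.05,
                                               frameshift_deletion = 0.05,
                                               splice_donor = 0.03,
                                               splice_acceptor = 0.03,
                                               exon_deletion = 0.02),
                              n_exons = 5, intron_length = 30,
                              reference = NULL, ambiguity_runs = NULL,
                              seed = 1) {
  stopifnot(inherits(tree, "time_tree"), n_codons >= n_exons,
            omega_functional > 0, omega_functional <= 1,
            syn_scaling > 0, syn_scaling <= 1, kappa > 0, neutral_rate > 0)
  tb <- codon_tables()
  if (is.null(codon_frequencies)) {
    pi64 <- uniform_codon_frequencies()
  } else if (length(codon_frequencies) == 61) {
    pi64 <- numeric(64)
    pi64[tb$sense] <- codon_frequencies
  } else if (length(codon_frequencies) == 64) {
    pi64 <- codon_frequencies
    pi64[tb$stops] <- 0
  } else stop("codon_frequencies must have length 61 or 64")
  if (abs(sum(pi64) - 1) > 1e-6) stop("codon frequencies must sum to 1")
  bad <- setdiff(names(lesion_rates), LESION_CLASSES)
  if (length(bad)) stop("unknown lesion class(es): ", paste(bad, collapse = ", "))
  lr <- stats::setNames(numeric(length(LESION_CLASSES)), LESION_CLASSES)
  lr[names(lesion_rates)] <- lesion_rates
  # validate loss events: time inside branch span, disjoint subtrees
  seen_tips <- character(0)
  for (ev in loss_events) {
    if (!all(c("branch", "loss_time_mya") %in% names(ev))) {
      stop("each loss event needs fields 'branch' and 'loss_time_mya'")
    }
    pd <- node_date(tree, parent_label(tree, ev$branch))
    cd <- node_date(tree, ev$branch)
    if (is.na(pd)) stop("loss event cannot be placed above the root")
    if (ev$loss_time_mya > pd + 1e-9 || ev$loss_time_mya < cd - 1e-9) {
      stop(sprintf(
        "loss time %.2f Mya outside branch '%s' span [%.2f, %.2f] Mya",
        ev$loss_time_mya, ev$branch, cd, pd))
    }
    tips <- descendant_tips(tree, ev$branch)
    if (length(intersect(tips, seen_tips))) {
      stop("loss-event subtrees must be disjoint")
    }
    seen_tips <- c(seen_tips, tips)
  }
  if (is.null(reference)) {
    reference <- setdiff(tree$phy$tip.label, seen_tips)[1]
    if (is.na(reference)) stop("no intact tip available as reference")
  } else if (reference %in% seen_tips) {
    stop("reference species must not descend from a loss event")
  }
  structure(list(tree = tree, n_codons = as.integer(n_codons),
                 omega_functional = omega_functional, kappa = kappa,
                 pi64 = pi64, syn_scaling = syn_scaling,
                 neutral_rate = neutral_rate, loss_events = loss_events,
                 lesion_rates = lr, n_exons = as.integer(n_exons),
                 intron_length = as.integer(intron_length),
                 reference = reference, ambiguity_runs = ambiguity_runs,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# position-specific nucleotide frequencies (3 x 4) implied by codon freqs
position_nt_freqs <- function(pi64) {
  tb <- codon_tables()
  cmat <- do.call(rbind, strsplit(tb$codons, ""))
  out <- matrix(0, 3, 4, dimnames = list(NULL, NUC))
  for (p in 1:3) {
    for (n in NUC) out[p, n] <- sum(pi64[cmat[, p] == n])
  }
  out / rowSums(out)
}

# Build the two regime rate matrices (64 x 64) plus per-codon neutral
# opportunity rates used for realized-omega normalization.
build_regimes <- function(config) {
  tb <- codon_tables()
  posf <- position_nt_freqs(config$pi64)
  single <- tb$chg_pos > 0
  q0 <- matrix(0, 64, 64)
  q0[single] <- posf[cbind(tb$chg_pos[single], tb$target_nt[single])]
  is_ts <- tb$type %in% c(1L, 3L)
  q0[single & is_ts] <- q0[single & is_ts] * config$kappa
  # stationary distribution of q0 is the F3x4 product measure incl. stops
  cmat <- do.call(rbind, strsplit(tb$codons, ""))
  pi_prod <- posf[1, cmat[, 1]] * posf[2, cmat[, 2]] * posf[3, cmat[, 3]]
  pi_prod <- pi_prod / sum(pi_prod)
  mean_rate <- sum(pi_prod * rowSums(q0))
  scale <- 3 * config$neutral_rate / mean_rate
  q0 <- q0 * scale
  syn <- matrix(tb$type %in% c(1L, 2L), 64, 64)
  nonsyn <- matrix(tb$type %in% c(3L, 4L), 64, 64)
  Qn <- q0 # neutral: omega = 1, stops reachable
  Qf <- q0 * config$syn_scaling
  Qf[nonsyn] <- Qf[nonsyn] * config$omega_functional
  Qf[, tb$stops] <- 0  # stop codons forbidden while functional
  Qf[tb$stops, ] <- 0
  regime <- function(Q) {
    Rtot <- rowSums(Q)
    P <- Q / ifelse(Rtot > 0, Rtot, 1)
    cumP <- t(apply(P, 1, cumsum))
    cumP[Rtot == 0, ] <- 0
    list(Q = Q, Rtot = Rtot, cumP = cumP)
  }
  q0syn <- q0; q0syn[!syn] <- 0
  q0non <- q0; q0non[!nonsyn] <- 0
  list(functional = regime(Qf), neutral = regime(Qn),
       synrate0 = rowSums(q0syn), nonsynrate0 = rowSums(q0non),
       syn_type = syn, posf = posf)
}

# Vectorized per-site Gillespie simulation of one constant-rate segment.
# Returns new states and the event log (site, from, to).
evolve_segment <- function(states, duration, regime) {
  n <- length(states)
  ev_site <- integer(0); ev_from <- integer(0); ev_to <- integer(0)
  if (duration <= 0) {
    return(list(states = states,
                events = data.frame(site = ev_site, from = ev_from,
                                    to = ev_to)))
  }
  tleft <- rep(duration, n)
  active <- which(regime$Rtot[states] > 0)
  while (length(active)) {
    dt <- stats::rexp(length(active), regime$Rtot[states[active]])
    tleft[active] <- tleft[active] - dt
    idx <- active[tleft[active] > 0]
    if (length(idx)) {
      u <- stats::runif(length(idx))
      rows <- regime$cumP[states[idx], , drop = FALSE]
      newst <- as.integer(rowSums(rows < u) + 1L)
      ev_site <- c(ev_site, idx)
      ev_from <- c(ev_from, states[idx])
      ev_to <- c(ev_to, newst)
      states[idx] <- newst
    }
    active <- idx[regime$Rtot[states[idx]] > 0]
  }
  list(states = states,
       events = data.frame(site = ev_site, from = ev_from, to = ev_to))
}

# 4x4 HKY transition probabilities (neutral introns), via eigendecomposition
hky_pmat <- function(ntfreq, kappa, rate, t) {
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- (NUC[i] %in% c("A", "G") && NUC[j] %in% c("A", "G")) ||
      (NUC[i] %in% c("C", "T") && NUC[j] %in% c("C", "T"))
    Q[i, j] <- ntfreq[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mr <- -sum(ntfreq * diag(Q))
  Q <- Q * rate / mr
  d <- sqrt(ntfreq)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / d) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(d)
  P[P < 0] <- 0
  P / rowSums(P)
}

# synthetic gene layout: exon spans + introns on a reference region
synthetic_gene_model <- function(n_codons, n_exons, intron_length,
                                 gene_id = "simgene") {
  cds_len <- 3L * n_codons
  base <- cds_len %/% n_exons
  lens <- rep(base, n_exons)
  lens[n_exons] <- lens[n_exons] + cds_len - sum(lens)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + lens[i]
    pos <- ends[i] + if (i < n_exons) intron_length else 0L
  }
  gene_model(gene_id, cbind(starts, ends))
}

# genomic positions (0-based) of the coding bases, in coding order
coding_positions <- function(model) {
  unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    seq(model$exons[i, "start"], model$exons[i, "end"] - 1L)
  }))
}

#' Simulate a codon alignment with gene-loss events
#'
#' Evolves a coding sequence (plus short neutral introns with pinned splice
#' dinucleotides) along the configured time tree.  Branches below a loss
#' event, and the post-loss portion of the loss branch itself, evolve
#' neutrally; all other branches evolve under purifying selection with the
#' synonymous-rate scaling c.  Every codon substitution is logged.
#'
#' @param config A [simulation_config()].
#' @return A list with `alignments` (named list of [species_alignment()],
#'   ungapped, all of reference length), `truth` (class `simulation_truth`:
#'   per-branch realized substitution counts and dN/dS, loss events, the
#'   synthetic [gene_model()], and an empty lesion table filled in by
#'   [inject_lesions()]), and `model` (the gene model).
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tb <- codon_tables()
  tree <- config$tree
  phy <- tree$phy
  labels <- tt_labels(tree)
  reg <- build_regimes(config)
  model <- synthetic_gene_model(config$n_codons, config$n_exons,
                                config$intron_length)
  L0 <- max(model$exons[, "end"])
  cpos <- coding_positions(model)

  # root states: sense codons from pi
  pi_sense <- config$pi64 / sum(config$pi64)
  root_states <- sample.int(64, config$n_codons, replace = TRUE,
                            prob = pi_sense)
  # intron template with pinned splice dinucleotides
  ntf <- colSums(position_nt_freqs(config$pi64)) / 3
  intron_pos <- setdiff(seq_len(L0) - 1L, cpos)
  intron_root <- sample(NUC, length(intron_pos), replace = TRUE, prob = ntf)
  names(intron_root) <- intron_pos
  pin_pos <- c(model$donor_sites, model$donor_sites + 1L,
               model$acceptor_sites, model$acceptor_sites + 1L)
  pin_val <- c(rep(c("G", "T"), each = length(model$donor_sites)),
               rep(c("A", "G"), each = length(model$acceptor_sites)))
  intron_root[as.character(pin_pos)] <- pin_val

  nnode <- length(labels)
  root_id <- length(phy$tip.label) + 1L
  codon_states <- vector("list", nnode)
  intron_seqs <- vector("list", nnode)
  codon_states[[root_id]] <- root_states
  intron_seqs[[root_id]] <- intron_root

  loss_branch <- vapply(config$loss_events, `[[`, character(1), "branch")
  loss_time <- vapply(config$loss_events, `[[`, numeric(1), "loss_time_mya")
  lost_below <- unique(unlist(lapply(loss_branch, function(b) {
    c(b, descendant_labels(tree, b))
  })))

  edges <- ape::reorder.phylo(phy, "cladewise")$edge # preorder
  branch_rows <- list()
  for (k in seq_len(nrow(edges))) {
    pa <- edges[k, 1]; ch <- edges[k, 2]
    ch_lab <- labels[ch]
    pd <- tree$node_dates[labels[pa]]
    cd <- tree$node_dates[ch_lab]
    dur <- pd - cd
    if (ch_lab %in% loss_branch) {
      lt <- loss_time[match(ch_lab, loss_branch)]
      t_func <- pd - lt; t_pseu <- lt - cd
    } else if (ch_lab %in% lost_below) {
      t_func <- 0; t_pseu <- dur
    } else {
      t_func <- dur; t_pseu <- 0
    }
    st <- codon_states[[pa]]
    opp_syn <- sum(reg$synrate0[st])
    opp_nonsyn <- sum(reg$nonsynrate0[st])
    r1 <- evolve_segment(st, t_func, reg$functional)
    r2 <- evolve_segment(r1$states, t_pseu, reg$neutral)
    codon_states[[ch]] <- r2$states
    ev <- rbind(cbind(r1$events, regime = rep("functional", nrow(r1$events))),
                cbind(r2$events, regime = rep("neutral", nrow(r2$events))))
    n_syn <- sum(reg$syn_type[cbind(ev$from, ev$to)])
    n_nonsyn <- nrow(ev) - n_syn
    # realized omega with mutational-opportunity normalization
    omega_real <- if (n_syn > 0 && opp_syn > 0) {
      (n_nonsyn / opp_nonsyn) / (n_syn / opp_syn)
    } else NA_real_
    branch_rows[[ch_lab]] <- data.frame(
      branch = ch_lab, duration = dur, t_functional = t_func,
      t_pseudogenic = t_pseu, n_syn = n_syn, n_nonsyn = n_nonsyn,
      opp_syn = opp_syn, opp_nonsyn = opp_nonsyn,
      dn = n_nonsyn / opp_nonsyn, ds = if (opp_syn > 0) n_syn / opp_syn else NA,
      omega_realized = omega_real, stringsAsFactors = FALSE)
    if (nrow(ev)) {
      ev$branch <- ch_lab
      attr(branch_rows[[ch_lab]], "events") <- ev
    }
    # introns: neutral HKY endpoint sampling, splice dinucleotides pinned
    par_intron <- intron_seqs[[pa]]
    if (dur > 0 && length(par_intron)) {
      P <- hky_pmat(stats::setNames(ntf, NUC), config$kappa,
                    config$neutral_rate, dur)
      cum <- t(apply(P, 1, cumsum))
      si <- match(par_intron, NUC)
      u <- stats::runif(length(si))
      newnt <- NUC[rowSums(cum[si, , drop = FALSE] < u) + 1L]
      names(newnt) <- names(par_intron)
      newnt[as.character(pin_pos)] <- pin_val
      intron_seqs[[ch]] <- newnt
    } else {
      intron_seqs[[ch]] <- par_intron
    }
  }

  # materialize tip genomic sequences
  tips <- phy$tip.label
  alignments <- lapply(seq_along(tips), function(i) {
    chars <- character(L0)
    codseq <- tb$codons[codon_states[[i]]]
    chars[cpos + 1L] <- unlist(strsplit(codseq, ""), use.names = FALSE)
    intr <- intron_seqs[[i]]
    chars[as.integer(names(intr)) + 1L] <- intr
    species_alignment(tips[i], paste(chars, collapse = ""))
  })
  names(alignments) <- tips

  branch_stats <- do.call(rbind, lapply(branch_rows, function(x) x))
  rownames(branch_stats) <- NULL
  events <- do.call(rbind, lapply(branch_rows, function(x) attr(x, "events")))
  truth <- structure(list(
    branch_stats = branch_stats, events = events,
    loss_events = config$loss_events,
    lesions = empty_lesion_table(),
    gene_model = model, config = config,
    node_codon_states = codon_states, labels = labels),
    class = "simulation_truth")
  list(alignments = alignments, truth = truth, model = model)
}

# all labels (tips + internals) strictly below node `label`
descendant_labels <- function(tree, label) {
  phy <- tree$phy
  labels <- tt_labels(tree)
  id <- tt_node_id(tree, label)
  ntip <- length(phy$tip.label)
  out <- integer(0)
  stack <- id
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ntip])
  }
  labels[out]
}

empty_lesion_table <- function() {
  data.frame(species = character(0), mclass = character(0),
             exon_index = integer(0), position = integer(0),
             size = integer(0), ancestral_allele = character(0),
             derived_allele = character(0), event_branch = character(0),
             event_id = integer(0), shared = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d branches, %d substitution events, %d lesions\n",
              nrow(x$branch_stats),
              if (is.null(x$events)) 0L else nrow(x$events),
              nrow(x$lesions)))
  invisible(x)
}
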