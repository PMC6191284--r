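# Maximum-likelihood dN/dS estimation under a branch model: each branch is
# assigned a dN/dS class (e.g. functional background, one class per loss
# branch, a pseudogene class fixed at omega = 1), and branch lengths, kappa
# and the free class omegas are optimized by Felsenstein-pruning likelihood
# (compiled kernel) with nlminb.  Codon frequencies are F3x4 computed from
# the data; in-frame stop codons are masked to NNN before fitting and
# alignment columns containing gaps or ambiguity in any analyzed species
# are excluded (complete deletion).

# sense-codon data structures shared by the likelihood wrapper
sense_tables <- function() {
  tb <- codon_tables()
  list(type = tb$type[tb$sense, tb$sense], codons = tb$codons[tb$sense],
       aa = tb$aa[tb$sense])
}

# Convert aligned CDS strings to tip-state patterns.  Stop codons are
# masked to missing.  `missing = "complete"` drops any column with a
# gap/N/stop in any species (complete deletion); `missing = "mask"` keeps
# the column and marginalizes the affected tip (state 0) in the pruning
# likelihood.  Returns NULL if no usable columns remain.
codon_patterns <- function(seqs, missing = c("mask", "complete")) {
  missing <- match.arg(missing)
  stopifnot(length(seqs) >= 2)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) stop("aligned sequences must have equal length")
  if (lens %% 3 != 0) stop("alignment length must be a multiple of 3")
  st <- sense_tables()
  tb <- codon_tables()
  idx <- vapply(seqs, function(s) {
    ci <- codon_index(split_codons(toupper(s)))
    ci[!is.na(ci) & tb$aa[ifelse(is.na(ci), 1L, ci)] == "*"] <- NA # mask stops
    match(tb$codons[ci], st$codons)
  }, integer(lens %/% 3))
  idx <- t(idx) # ntip x ncodon
  keep <- if (missing == "complete") {
    colSums(is.na(idx)) == 0
  } else {
    colSums(!is.na(idx)) >= 2 # a column informs only with 2+ states
  }
  if (!any(keep)) return(NULL)
  idx <- idx[, keep, drop = FALSE]
  idx[is.na(idx)] <- 0L
  key <- apply(idx, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = idx[, first, drop = FALSE], weights = as.numeric(tab),
       n_codons_used = sum(keep))
}

# per-edge class indices from a child-label -> class-name map
edge_classes <- function(phy, class_of_branch, default_class = "background") {
  labels <- c(phy$tip.label, phy$node.label)
  child <- labels[phy$edge[, 2]]
  cls <- rep(default_class, length(child))
  if (!is.null(class_of_branch)) {
    hit <- child %in% names(class_of_branch)
    cls[hit] <- unname(class_of_branch[child[hit]])
  }
  cls
}

#' Fit a branch model with dN/dS classes
#'
#' Maximizes the codon-model likelihood over branch lengths, kappa and the
#' free class omegas.  Classes named in `fixed_omegas` (by default the
#' `pseudogene` class, fixed at dN/dS = 1) are never optimized.
#' Optimization is multi-start over spread initial omega values; starts
#' after the first are warm-started from the best previous optimum.
#'
#' @param seqs Named character vector of aligned, in-frame CDS sequences
#'   (gaps `-`/`N` allowed; stop codons are masked).
#' @param tree A [time_tree()] or `ape::phylo` covering the sequence names.
#' @param class_of_branch Named character vector: child-node label ->
#'   class name.  Unlisted branches get `"background"`.
#' @param fixed_omegas Named numeric vector of class omegas that are fixed
#'   (default `c(pseudogene = 1)`).
#' @param kappa_init Initial kappa.
#' @param omega_starts Initial values for free omegas across starts.
#' @param n_starts Number of optimizer starts (default 3).
#' @param missing How to treat columns with gaps, N or masked stops:
#'   `"mask"` (default) marginalizes the affected species only;
#'   `"complete"` drops the whole column.
#' @param control Passed to [stats::nlminb()] (default: lnL tolerance 1e-6).
#' @return Object of class `branch_class_model`: `omegas` (all classes),
#'   `kappa`, `log_likelihood`, `edge_table`, `degenerate`, `convergence`.
#' @export
fit_branch_model <- function(seqs, tree, class_of_branch = NULL,
                             fixed_omegas = c(pseudogene = 1),
                             kappa_init = 2,
                             omega_starts = c(0.2, 0.6, 1.5),
                             n_starts = 3,
                             missing = c("mask", "complete"),
                             control = list(rel.tol = 1e-10)) {
  missing <- match.arg(missing)
  phy <- if (inherits(tree, "time_tree")) tree$phy else tree
  if (is.null(phy$node.label)) {
    phy$node.label <- paste0("node", seq_len(phy$Nnode))
  }
  stopifnot(all(phy$tip.label %in% names(seqs)))
  if (length(phy$tip.label) < 3) {
    stop("fit_branch_model: need at least 3 species")
  }
  seqs <- seqs[phy$tip.label]
  pats <- codon_patterns(seqs, missing = missing)
  if (is.null(pats)) stop("fit_branch_model: no usable codon columns")
  if (all(apply(pats$states, 2, function(x) length(unique(x)) == 1))) {
    return(structure(list(omegas = NA, kappa = NA, log_likelihood = NA,
                          degenerate = TRUE,
                          message = "no variable sites; omega undefined"),
                     class = "branch_class_model"))
  }
  # F3x4: position-specific nucleotide frequencies drive both the rate
  # factors (Muse-Gaut) and the stationary codon frequencies
  tb <- codon_tables()
  pi64 <- f3x4_frequencies(gsub("[-N]", "", seqs))
  posf <- position_nt_freqs(pi64)
  pi61 <- pi64[tb$sense]
  pi61 <- pmax(pi61, 1e-8); pi61 <- pi61 / sum(pi61)
  sense <- tb$sense
  fac61 <- matrix(0, 61, 61)
  chg <- tb$chg_pos[sense, sense]; tgt <- tb$target_nt[sense, sense]
  single <- chg > 0
  fac61[single] <- posf[cbind(chg[single], tgt[single])]
  phy_po <- ape::reorder.phylo(phy, "postorder")
  cls <- edge_classes(phy_po, class_of_branch)
  class_names <- unique(cls)
  fixed <- class_names[class_names %in% names(fixed_omegas)]
  free <- setdiff(class_names, fixed)
  cls_idx <- match(cls, class_names)
  st <- sense_tables()
  n_tip <- length(phy_po$tip.label)
  n_node <- n_tip + phy_po$Nnode
  n_edge <- nrow(phy_po$edge)

  omega_vec <- function(free_omegas) {
    o <- numeric(length(class_names))
    names(o) <- class_names
    o[fixed] <- fixed_omegas[fixed]
    o[free] <- free_omegas
    o
  }
  # cache the class eigensystems: most optimizer moves change only branch
  # lengths, for which the (kappa, omega) decomposition is unchanged
  eig_cache <- new.env(parent = emptyenv())
  eig_cache$key <- NULL
  get_eigens <- function(kap, om) {
    key <- c(kap, om)
    if (!identical(key, eig_cache$key)) {
      eig_cache$eig <- codon_eigens(st$type, fac61, pi61, kap, om)
      eig_cache$key <- key
    }
    eig_cache$eig
  }
  negll <- function(par) {
    bl <- par[seq_len(n_edge)]
    kap <- par[n_edge + 1L]
    om <- omega_vec(par[n_edge + 1L + seq_along(free)])
    v <- codon_lnL(phy_po$edge, bl, cls_idx, get_eigens(kap, om), pi61,
                   pats$states, pats$weights, n_tip, n_node)
    if (!is.finite(v)) return(1e10)
    -v
  }
  # starting branch lengths from the weighted fraction of variable columns
  varpat <- vapply(seq_len(ncol(pats$states)), function(j) {
    length(unique(pats$states[, j])) > 1
  }, logical(1))
  pdiff <- sum(pats$weights[varpat]) / sum(pats$weights)
  bl0 <- rep(max(0.005, pdiff / max(1, log2(n_tip)) / 2), n_edge)
  lower <- c(rep(1e-7, n_edge), 0.05, rep(1e-4, length(free)))
  upper <- c(rep(20, n_edge), 100, rep(50, length(free)))

  # multi-start: the first start optimizes everything; later starts probe
  # other omega basins with branch lengths held at the best optimum (cheap),
  # and trigger a full refit only if they find a better basin
  best <- NULL
  n_starts <- max(1L, min(n_starts, length(omega_starts)))
  oidx <- n_edge + 1L + seq_along(free)
  for (s in seq_len(n_starts)) {
    if (is.null(best)) {
      par0 <- c(bl0, kappa_init, rep(omega_starts[s], length(free)))
      fit <- stats::nlminb(par0, negll, lower = lower, upper = upper,
                           control = control)
      best <- fit
    } else {
      bl_fix <- best$par[seq_len(n_edge)]
      probe <- stats::nlminb(
        c(best$par[n_edge + 1L], rep(omega_starts[s], length(free))),
        function(ko) negll(c(bl_fix, ko)),
        lower = lower[c(n_edge + 1L, oidx)],
        upper = upper[c(n_edge + 1L, oidx)], control = control)
      if (probe$objective < best$objective - 0.1) {
        par0 <- c(bl_fix, probe$par)
        fit <- stats::nlminb(par0, negll, lower = lower, upper = upper,
                             control = control)
        if (fit$objective < best$objective - 1e-9) best <- fit
      }
    }
    if (!length(free)) break
  }
  om <- omega_vec(best$par[n_edge + 1L + seq_along(free)])
  labels <- c(phy_po$tip.label, phy_po$node.label)
  edge_table <- data.frame(
    branch = labels[phy_po$edge[, 2]], class = cls,
    length = best$par[seq_len(n_edge)], stringsAsFactors = FALSE)
  structure(list(omegas = om, kappa = best$par[n_edge + 1L],
                 log_likelihood = -best$objective,
                 edge_table = edge_table, degenerate = FALSE,
                 convergence = best$convergence,
                 n_patterns = length(pats$weights),
                 n_codons_used = pats$n_codons_used,
                 pi = pi61, tree = phy_po),
            class = "branch_class_model")
}

#' @export
print.branch_class_model <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("branch_class_model: degenerate (", x$message, ")\n")
    return(invisible(x))
  }
  cat("branch_class_model: lnL =", format(x$log_likelihood, digits = 8),
      "kappa =", round(x$kappa, 3), "\n omegas:",
      paste(names(x$omegas), round(x$omegas, 4), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Two-ratio likelihood-ratio test for relaxed selection
#'
#' Fits a null model (one omega for all branches) and an alternative with
#' separate foreground and background omegas; the statistic
#' `2 * (lnL_alt - lnL_null)` is compared to a chi-square with 1 df.
#' Relaxation is indicated when `omega_fg > omega_bg` at a small p-value.
#' The alternative fit is warm-started from the null optimum, which also
#' enforces the nesting inequality `lnL_alt >= lnL_null`.
#'
#' @param seqs Aligned CDS as in [fit_branch_model()].
#' @param tree Tree as in [fit_branch_model()].
#' @param foreground Character vector of child-node labels: a non-empty
#'   proper subset of branches.
#' @param ... Passed to [fit_branch_model()].
#' @return Object of class `relaxation_test` with `omega_fg`, `omega_bg`,
#'   `lnL_null`, `lnL_alt`, `lr_statistic`, `p_value`.
#' @export
relaxation_test <- function(seqs, tree, foreground, ...) {
  phy <- if (inherits(tree, "time_tree")) tree$phy else tree
  if (is.null(phy$node.label)) {
    phy$node.label <- paste0("node", seq_len(phy$Nnode))
  }
  labels <- c(phy$tip.label, phy$node.label)
  branches <- labels[phy$edge[, 2]]
  if (!length(foreground)) stop("relaxation_test: foreground is empty")
  bad <- setdiff(foreground, branches)
  if (length(bad)) {
    stop("relaxation_test: unknown branches: ", paste(bad, collapse = ", "))
  }
  if (all(branches %in% foreground)) {
    stop("relaxation_test: foreground must be a proper subset of branches")
  }
  null_fit <- fit_branch_model(seqs, phy, class_of_branch = NULL,
                               fixed_omegas = numeric(0), ...)
  cob <- stats::setNames(rep("foreground", length(foreground)), foreground)
  # warm start: both omegas at the null optimum
  o0 <- unname(null_fit$omegas["background"])
  alt_fit <- fit_branch_model(seqs, phy, class_of_branch = cob,
                              fixed_omegas = numeric(0),
                              omega_starts = c(o0, 0.2, 1.5),
                              kappa_init = null_fit$kappa, ...)
  lr <- max(0, 2 * (alt_fit$log_likelihood - null_fit$log_likelihood))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(foreground = foreground,
                 omega_fg = unname(alt_fit$omegas["foreground"]),
                 omega_bg = unname(alt_fit$omegas["background"]),
                 omega_null = o0,
                 lnL_null = null_fit$log_likelihood,
                 lnL_alt = alt_fit$log_likelihood,
                 lr_statistic = lr, p_value = p,
                 null_fit = null_fit, alt_fit = alt_fit),
            class = "relaxation_test")
}

#' @export
print.relaxation_test <- function(x, ...) {
  cat(sprintf(
    "relaxation_test: omega_fg = %.4f, omega_bg = %.4f, LR = %.3f, p = %.4g\n",
    x$omega_fg, x$omega_bg, x$lr_statistic, x$p_value))
  invisible(x)
}

#' Extract the aligned CDS of every species from a gapped alignment
#'
#' Pulls the exon columns of the reference gene model out of the alignment
#' frame (insertions relative to the reference are dropped, deletions
#' become `-`), giving an in-frame aligned CDS suitable for
#' [fit_branch_model()].
#'
#' @param alignments Named list of [species_alignment()].
#' @param model The reference [gene_model()].
#' @param reference Name of the reference species in `alignments`.
#' @return Named character vector of aligned CDS strings.
#' @export
cds_alignment <- function(alignments, model, reference) {
  ref <- alignments[[reference]]
  if (is.null(ref)) stop("reference species not in alignment")
  r2a <- alignment_maps(ref$aligned_seq)$ref2aln
  cols <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    r2a[(model$exons[i, "start"] + 1):model$exons[i, "end"]] + 1L
  }))
  vapply(alignments, function(a) {
    paste(strsplit(a$aligned_seq, "")[[1]][cols], collapse = "")
  }, character(1))
}
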