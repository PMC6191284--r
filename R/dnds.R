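# Nei-Gojobori (1986) style pairwise dN/dS counting.  This is deliberately a
# simple, fully specified counting estimator: it serves as the independent
# cross-check for the maximum-likelihood branch model and as the normalizer
# for realized substitution counts in the simulator.

# Per-codon synonymous site count: at each position, the fraction of the three
# possible nucleotide changes that are synonymous.  Changes creating a stop
# codon count as nonsynonymous.
codon_syn_sites <- function(codon_idx) {
  tb <- codon_tables()
  syn <- tb$type[codon_idx, ] %in% c(1L, 2L)
  sum(syn) / 3
}

# Enumerate mutational pathways between two codons and average the number of
# synonymous and nonsynonymous steps.  Pathways through stop codons are
# excluded; if every pathway passes through a stop, all are used.
codon_path_diffs <- function(ci, cj) {
  tb <- codon_tables()
  a <- strsplit(tb$codons[ci], "")[[1]]
  b <- strsplit(tb$codons[cj], "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- list(1L)
  if (k == 2L) perms <- list(c(1L, 2L), c(2L, 1L))
  if (k == 3L) perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                             c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  step_counts <- function(order) {
    cur <- a
    syn <- 0; nonsyn <- 0; through_stop <- FALSE
    for (p in pos[order]) {
      nxt <- cur
      nxt[p] <- b[p]
      i1 <- codon_index(paste(cur, collapse = ""))
      i2 <- codon_index(paste(nxt, collapse = ""))
      if (tb$aa[i2] == "*" && !identical(p, pos[order][k])) through_stop <- TRUE
      if (tb$aa[i2] == "*" || tb$aa[i1] == "*") {
        # a step to or from a stop codon is nonsense -> nonsynonymous
        nonsyn <- nonsyn + 1
      } else if (tb$aa[i1] == tb$aa[i2]) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, stop = as.numeric(through_stop))
  }
  res <- vapply(perms, step_counts, numeric(3))
  valid <- res["stop", ] == 0
  if (!any(valid)) valid <- rep(TRUE, ncol(res))
  c(syn = mean(res["syn", valid]), nonsyn = mean(res["nonsyn", valid]))
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' in-frame coding sequences, averaging over equally weighted mutational
#' pathways for codons differing at more than one position, and applies the
#' Jukes-Cantor multiple-hit correction.  Codon pairs containing a stop codon
#' or ambiguous/gap characters are skipped.
#'
#' @param seq_a,seq_b Ungapped nucleotide strings of equal length, a multiple
#'   of 3.
#' @return A list with `N_sites`, `S_sites`, `N_diffs`, `S_diffs`, `pN`, `pS`,
#'   `dN`, `dS` and `dnds` (`NA` when `dS` is 0 or a correction is undefined).
#' @export
count_dn_ds <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("count_dn_ds: sequences must have equal length")
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("count_dn_ds: sequence length must be a multiple of 3")
  }
  tb <- codon_tables()
  ca <- codon_index(split_codons(seq_a))
  cb <- codon_index(split_codons(seq_b))
  usable <- !is.na(ca) & !is.na(cb) &
    tb$aa[ifelse(is.na(ca), 1L, ca)] != "*" &
    tb$aa[ifelse(is.na(cb), 1L, cb)] != "*"
  ca <- ca[usable]; cb <- cb[usable]
  S_sites <- 0; N_sites <- 0; S_diffs <- 0; N_diffs <- 0
  for (i in seq_along(ca)) {
    sa <- codon_syn_sites(ca[i]); sb <- codon_syn_sites(cb[i])
    S_sites <- S_sites + (sa + sb) / 2
    N_sites <- N_sites + 3 - (sa + sb) / 2
    if (ca[i] != cb[i]) {
      d <- codon_path_diffs(ca[i], cb[i])
      S_diffs <- S_diffs + d[["syn"]]
      N_diffs <- N_diffs + d[["nonsyn"]]
    }
  }
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  pS <- if (S_sites > 0) S_diffs / S_sites else NA_real_
  pN <- if (N_sites > 0) N_diffs / N_sites else NA_real_
  dS <- jc(pS); dN <- jc(pN)
  dnds <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  list(N_sites = N_sites, S_sites = S_sites,
       N_diffs = N_diffs, S_diffs = S_diffs,
       pN = pN, pS = pS, dN = dN, dS = dS, dnds = dnds)
}
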