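# Shared codon machinery: the universal genetic code, single-nucleotide
# neighbour classification (synonymous/nonsynonymous x transition/transversion)
# and F3x4 codon frequencies.  Everything downstream (simulator, Nei-Gojobori
# counter, branch-model likelihood) indexes codons against these tables.

.geneloss_cache <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

#' Codon lookup tables
#'
#' Returns (and memoizes) the codon tables used throughout the package:
#' the 64 codons in lexicographic ACGT order, their amino-acid translations,
#' the indices of the three stop codons, and a 64 x 64 integer matrix
#' classifying each single-nucleotide codon change as a synonymous or
#' nonsynonymous transition or transversion.
#'
#' @return A list with elements `codons` (character 64), `aa` (character 64,
#'   `"*"` for stops), `sense` (integer indices of the 61 sense codons),
#'   `stops` (integer indices of stop codons), and `type` (64 x 64 integer:
#'   0 = not a single-nucleotide change, 1 = synonymous transition,
#'   2 = synonymous transversion, 3 = nonsynonymous transition,
#'   4 = nonsynonymous transversion).
#' @export
codon_tables <- function() {
  if (!is.null(.geneloss_cache$tables)) return(.geneloss_cache$tables)
  codons <- as.vector(outer(outer(NUC, NUC, paste0), NUC, paste0))
  codons <- sort(codons) # lexicographic ACGT
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  stops <- which(aa == "*")
  sense <- which(aa != "*")
  cmat <- do.call(rbind, strsplit(codons, ""))
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  type <- matrix(0L, 64, 64)
  chg_pos <- matrix(0L, 64, 64)    # which codon position differs (single-nt pairs)
  target_nt <- matrix(0L, 64, 64)  # index into NUC of the new nucleotide
  for (pos in 1:3) {
    same_other <- matrix(TRUE, 64, 64)
    for (q in setdiff(1:3, pos)) {
      same_other <- same_other & outer(cmat[, q], cmat[, q], "==")
    }
    differ_here <- outer(cmat[, pos], cmat[, pos], "!=")
    single <- same_other & differ_here
    ts <- outer(cmat[, pos], cmat[, pos], is_ts)
    syn <- outer(aa, aa, "==")
    type[single & ts & syn] <- 1L
    type[single & !ts & syn] <- 2L
    type[single & ts & !syn] <- 3L
    type[single & !ts & !syn] <- 4L
    chg_pos[single] <- pos
    tgt <- matrix(rep(match(cmat[, pos], NUC), each = 64), 64, 64)
    target_nt[single] <- tgt[single]
  }
  .geneloss_cache$tables <- list(codons = codons, aa = aa, sense = sense,
                                 stops = stops, type = type,
                                 chg_pos = chg_pos, target_nt = target_nt)
  .geneloss_cache$tables
}

# codon strings -> 1..64 indices (NA for codons containing non-ACGT)
codon_index <- function(x) {
  match(x, codon_tables()$codons)
}

# split an ungapped nucleotide string into codon strings
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' F3x4 codon frequencies
#'
#' Computes codon frequencies from position-specific nucleotide frequencies
#' (the F3x4 convention): the frequency of a codon is the product of its
#' nucleotides' frequencies at codon positions 1-3, with stop codons zeroed
#' and the rest renormalized.
#'
#' @param seqs Character vector of ungapped coding nucleotide sequences
#'   (lengths multiples of 3).  Non-ACGT characters are ignored.
#' @param include_stops If `TRUE`, stop-codon frequencies are retained
#'   (used by the neutral post-loss regime of the simulator).
#' @return Numeric vector of length 64 summing to 1 (over sense codons when
#'   `include_stops = FALSE`).
#' @export
f3x4_frequencies <- function(seqs, include_stops = FALSE) {
  tb <- codon_tables()
  counts <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, NUC))
  for (s in seqs) {
    ch <- strsplit(toupper(s), "")[[1]]
    ok <- ch %in% NUC
    pos <- ((seq_along(ch) - 1L) %% 3L) + 1L
    t3 <- table(factor(pos[ok], 1:3), factor(ch[ok], NUC))
    counts <- counts + as.matrix(t3)
  }
  if (any(rowSums(counts) == 0)) {
    counts <- counts + 1 # uninformative fallback for empty positions
  }
  fr <- counts / rowSums(counts)
  cmat <- do.call(rbind, strsplit(tb$codons, ""))
  pi <- fr[1, cmat[, 1]] * fr[2, cmat[, 2]] * fr[3, cmat[, 3]]
  if (!include_stops) pi[tb$stops] <- 0
  pi / sum(pi)
}

# uniform sense-codon frequencies (64-vector, stops zero)
uniform_codon_frequencies <- function() {
  tb <- codon_tables()
  pi <- numeric(64)
  pi[tb$sense] <- 1 / length(tb$sense)
  pi
}

# reverse complement of a plain character string (keeps - and N sensible)
revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  ch <- rev(strsplit(toupper(x), "")[[1]])
  out <- map[ch]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}
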