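# Validation of candidate inactivating mutations against unassembled
# sequencing reads: build a derived and an ancestral probe from the genomic
# context around the mutation, assign each read to the allele it matches
# best over the discriminating window (both strands), and classify the
# outcome.  A mutation is confirmed by >= min_reads derived reads with no
# ancestral support; a ~50:50 split marks a heterozygous lesion.

#' Extract derived and ancestral probes around a mutation
#'
#' Builds two ungapped probe sequences from the species' aligned sequence:
#' the derived probe is the species' own context, the ancestral probe has
#' the mutation reverted (deletion restored, insertion removed, or the
#' ancestral base(s) substituted).  For deletions the probes anchor on the
#' flanking sequence across the breakpoint.
#'
#' @param aln The species' [species_alignment()].
#' @param mutation One-row mutation data.frame (from [scan_species()] or
#'   the simulation truth) with a `column` anchor; if `column` is absent it
#'   is taken to equal `position` (ungapped reference frame).
#' @param flank Flank length in bp (default 50, truncated at sequence
#'   ends; less than 10 bp of flank on either side is an error).
#' @return List with `derived_probe`, `ancestral_probe`, and `offset` (0-based
#'   position of the first mutation base within the derived probe).
#' @export
extract_context <- function(aln, mutation, flank = 50) {
  sc <- strsplit(aln$aligned_seq, "")[[1]]
  col <- if (!is.null(mutation$column) && !is.na(mutation$column)) {
    mutation$column
  } else mutation$position
  if (col < 0 || col >= length(sc)) {
    stop("extract_context: mutation position outside the sequence")
  }
  mclass <- mutation$mclass
  # columns of the species' own bases (the derived haplotype)
  base_cols <- which(sc != "-")
  at_or_after <- function(c0) base_cols[base_cols >= c0 + 1L]
  if (mclass %in% c("frameshift_deletion", "exon_deletion")) {
    left_cols <- base_cols[base_cols <= col] # deletion: species has no bases
    right_cols <- at_or_after(col)
    mid_derived <- ""
    mid_ancestral <- mutation$ancestral_allele
  } else if (mclass == "frameshift_insertion") {
    ins_cols <- (col + 1L):(col + mutation$size)
    left_cols <- base_cols[base_cols <= col]
    right_cols <- base_cols[base_cols > col + mutation$size]
    mid_derived <- paste(sc[ins_cols], collapse = "")
    mid_ancestral <- ""
  } else { # substitution classes: nonsense, splice
    span <- (col + 1L):(col + mutation$size)
    left_cols <- base_cols[base_cols < span[1]]
    right_cols <- base_cols[base_cols > span[length(span)]]
    mid_derived <- paste(sc[span], collapse = "")
    mid_ancestral <- mutation$ancestral_allele
  }
  lf <- utils::tail(left_cols, flank)
  rf <- utils::head(right_cols, flank)
  if (length(lf) < 10 || length(rf) < 10) {
    stop("extract_context: less than 10 bp of flanking sequence available")
  }
  left <- paste(sc[lf], collapse = "")
  right <- paste(sc[rf], collapse = "")
  list(derived_probe = paste0(left, mid_derived, right),
       ancestral_probe = paste0(left, mid_ancestral, right),
       offset = nchar(left))
}

# Discriminating windows: the mutation core plus up to `wing` bp each side.
# When an allele's core is longer than a read could span (e.g. the
# restored sequence of an exon-scale deletion), a read supports that
# allele by matching either breakpoint edge, so two edge windows are
# returned for it.
probe_windows <- function(probes, wing = 12) {
  dp <- probes$derived_probe; ap <- probes$ancestral_probe
  off <- probes$offset
  allele_windows <- function(this, other) {
    core <- core_len(this, other, off)
    if (core <= 2 * wing) {
      return(substr(this, max(1, off + 1 - wing),
                    min(nchar(this), off + core + wing)))
    }
    c(substr(this, max(1, off + 1 - wing), off + wing),
      substr(this, off + core - wing + 1,
             min(nchar(this), off + core + wing)))
  }
  list(derived = allele_windows(dp, ap),
       ancestral = allele_windows(ap, dp))
}

# length of the allele-specific core on `this` probe (0 at a clean junction)
core_len <- function(this, other, off) {
  d <- nchar(this) - nchar(other)
  if (d > 0) return(d)
  if (d < 0) return(0L)
  a <- strsplit(this, "")[[1]]; b <- strsplit(other, "")[[1]]
  diffs <- which(a != b)
  if (length(diffs)) max(diffs) - off else 1L
}

#' Count read support for the derived and ancestral allele
#'
#' Each read (either strand) is assigned to the allele whose discriminating
#' window it matches with fewer mismatches, within a mismatch budget of 1
#' per 50 bp of window length; reads matching neither or tying are counted
#' as `n_other`, reads not overlapping the mutation window are
#' uninformative.
#'
#' @param probes Result of [extract_context()].
#' @param reads Character vector (or `Biostrings::DNAStringSet`) of read
#'   sequences.
#' @param wing Window half-width around the mutation (default 12 bp).
#' @param mismatch_per_50bp Mismatch budget per 50 bp of window.
#' @return A list of class `read_support` with `n_derived`, `n_ancestral`,
#'   `n_other` and the window strings.
#' @export
count_support <- function(probes, reads, wing = 12, mismatch_per_50bp = 1) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- as.character(reads)
  }
  reads <- toupper(reads)
  w <- probe_windows(probes, wing)
  if (length(reads) == 0) {
    return(structure(list(n_derived = 0L, n_ancestral = 0L, n_other = 0L,
                          windows = w), class = "read_support"))
  }
  rs <- Biostrings::DNAStringSet(reads)
  rs_rc <- Biostrings::reverseComplement(rs)
  budget <- function(win) max(0L, as.integer(ceiling(nchar(win) / 50 *
                                                       mismatch_per_50bp)))
  min_mm_one <- function(win) {
    # minimum mismatches of `win` against each read (either strand), capped
    b <- budget(win)
    out <- rep(NA_integer_, length(reads))
    for (m in 0:b) {
      hit <- Biostrings::vcountPattern(win, rs, max.mismatch = m) > 0 |
        Biostrings::vcountPattern(win, rs_rc, max.mismatch = m) > 0
      fill <- is.na(out) & hit
      out[fill] <- m
      if (!anyNA(out)) break
    }
    out
  }
  min_mm <- function(wins) {
    # an allele with several (edge) windows is supported by its best one
    do.call(pmin, c(lapply(wins, min_mm_one), list(na.rm = TRUE)))
  }
  mm_d <- min_mm(w$derived)
  mm_a <- min_mm(w$ancestral)
  informative <- !(is.na(mm_d) & is.na(mm_a))
  md <- ifelse(is.na(mm_d), Inf, mm_d)
  ma <- ifelse(is.na(mm_a), Inf, mm_a)
  n_derived <- sum(informative & md < ma)
  n_ancestral <- sum(informative & ma < md)
  n_other <- sum(informative & ma == md)
  structure(list(n_derived = as.integer(n_derived),
                 n_ancestral = as.integer(n_ancestral),
                 n_other = as.integer(n_other), windows = w),
            class = "read_support")
}

#' Classify read support for a mutation
#'
#' `confirmed`: at least `min_reads` derived reads and zero ancestral
#' support.  `heterozygous`: at least `min_reads` informative reads with
#' the derived fraction inside `het_band` (operationalizing a ~50:50
#' derived:ancestral split).  `low_coverage`: fewer than `min_reads`
#' informative reads.  `unsupported` otherwise.
#'
#' @param support A [count_support()] result.
#' @param min_reads Minimum read count (default 30).
#' @param het_band Two-element derived-fraction interval for heterozygote
#'   calls (default `c(0.35, 0.65)`).
#' @param ancestral_tolerance Maximum ancestral reads still compatible with
#'   a confirmed call (default 0: taken literally).
#' @return The support object with a `verdict` field added.
#' @export
classify_support <- function(support, min_reads = 30,
                             het_band = c(0.35, 0.65),
                             ancestral_tolerance = 0) {
  tot <- support$n_derived + support$n_ancestral + support$n_other
  frac <- if (tot > 0) support$n_derived / tot else NA_real_
  verdict <- if (support$n_derived >= min_reads &&
                 support$n_ancestral <= ancestral_tolerance) {
    "confirmed"
  } else if (tot >= min_reads && !is.na(frac) &&
             frac >= het_band[1] && frac <= het_band[2]) {
    "heterozygous"
  } else if (tot < min_reads) {
    "low_coverage"
  } else {
    "unsupported"
  }
  support$verdict <- verdict
  support
}

#' @export
print.read_support <- function(x, ...) {
  cat(sprintf("read_support: %d derived / %d ancestral / %d other%s\n",
              x$n_derived, x$n_ancestral, x$n_other,
              if (!is.null(x$verdict)) paste0(" -> ", x$verdict) else ""))
  invisible(x)
}
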