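# Simulated read pileups over mutation sites, emulating the unassembled
# archive reads used to confirm inactivating mutations.  Reads are drawn
# from the derived haplotype with probability derived_fraction (1 for a
# fixed lesion, ~0.5 for a heterozygous one) and overlap the discriminating
# site; strands alternate; sequencing errors are uniform substitutions.

#' Simulate reads over a mutation site
#'
#' @param aln The species' [species_alignment()] (derived haplotype
#'   source).
#' @param mutation One-row mutation data.frame (see [extract_context()]).
#' @param depth Number of reads (0 gives an empty set).
#' @param derived_fraction Probability a read comes from the derived
#'   haplotype.
#' @param error_rate Per-base substitution error probability.
#' @param read_length Read length in bp.
#' @param seed Optional seed for reproducibility.
#' @return Character vector of read sequences (named `read1`, `read2`, ...).
#' @export
simulate_reads <- function(aln, mutation, depth, derived_fraction = 1,
                           error_rate = 0, read_length = 100, seed = NULL) {
  stopifnot(depth >= 0, derived_fraction >= 0, derived_fraction <= 1,
            error_rate >= 0, error_rate < 1, read_length >= 30)
  if (!is.null(seed)) set.seed(seed)
  if (depth == 0) return(character(0))
  probes <- extract_context(aln, mutation, flank = read_length)
  haps <- c(derived = probes$derived_probe,
            ancestral = probes$ancestral_probe)
  off <- probes$offset
  reads <- character(depth)
  for (i in seq_len(depth)) {
    use_derived <- stats::runif(1) < derived_fraction
    hap <- if (use_derived) haps[["derived"]] else haps[["ancestral"]]
    core <- core_len(hap, if (use_derived) haps[["ancestral"]] else
      haps[["derived"]], off)
    # the read must contain a discriminating window (+/- 15 bp around the
    # mutation core) so that every read at the site is informative; when
    # the core is longer than a read (e.g. the restored side of an
    # exon-scale deletion) the read covers one breakpoint edge instead
    if (core + 30L <= read_length) {
      lo <- max(1L, off + core + 16L - read_length)
      hi <- max(lo, min(nchar(hap) - read_length + 1L, off - 14L))
    } else {
      edge <- if (stats::runif(1) < 0.5) off else off + core
      lo <- max(1L, edge + 16L - read_length)
      hi <- max(lo, min(nchar(hap) - read_length + 1L, edge - 14L))
    }
    start <- if (hi > lo) sample(lo:hi, 1) else lo
    rd <- substr(hap, start, start + read_length - 1L)
    if (error_rate > 0) {
      ch <- strsplit(rd, "")[[1]]
      err <- which(stats::runif(length(ch)) < error_rate)
      for (j in err) {
        ch[j] <- sample(setdiff(NUC, ch[j]), 1)
      }
      rd <- paste(ch, collapse = "")
    }
    if (i %% 2 == 0) rd <- revcomp(rd)
    reads[i] <- rd
  }
  names(reads) <- paste0("read", seq_len(depth))
  reads
}

#' Write reads to FASTA
#'
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @export
write_reads_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read reads from FASTA or FASTQ
#'
#' @param path Input path; format chosen by extension (`.fq`/`.fastq` =
#'   FASTQ, otherwise FASTA).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(ss), names(ss))
}
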