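# Species alignments: one gapped sequence per species over the reference
# alignment frame, with assembly-ambiguity (N) runs tracked separately from
# alignment gaps ("-").  The two characters are never interchangeable: "-"
# records absent sequence (deletion/insertion bookkeeping), "N" records
# sequence that is present but unknown (assembly gaps).

#' Construct a species alignment record
#'
#' @param species Species name.
#' @param aligned_seq Gapped, uppercase nucleotide string over the reference
#'   alignment frame.
#' @param flank_left,flank_right Ungapped context sequence outside the
#'   aligned region (used for read-probe extraction at the edges).
#' @return An object of class `species_alignment` with `ambiguity_runs`, a
#'   two-column matrix of 0-based half-open `(start, end)` alignment spans
#'   of N runs.
#' @export
species_alignment <- function(species, aligned_seq,
                              flank_left = "", flank_right = "") {
  aligned_seq <- toupper(aligned_seq)
  runs <- n_runs(aligned_seq)
  structure(list(species = species, aligned_seq = aligned_seq,
                 ambiguity_runs = runs,
                 flank_left = toupper(flank_left),
                 flank_right = toupper(flank_right)),
            class = "species_alignment")
}

# 0-based half-open (start, end) spans of maximal N runs in a string
n_runs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  isn <- ch == "N"
  if (!any(isn)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(isn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  m <- cbind(start = starts[r$values], end = ends[r$values])
  storage.mode(m) <- "integer"
  m
}

#' Read a multiple alignment from FASTA
#'
#' @param path FASTA file; all records must have equal gapped length and
#'   unique names.
#' @return Named list of [species_alignment()] objects.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) > 1) {
    stop("read_alignment: records have unequal gapped lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("read_alignment: duplicate species names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- lapply(seq_along(ss), function(i) {
    species_alignment(nm[i], as.character(ss[[i]]))
  })
  names(out) <- nm
  out
}

#' Write a list of species alignments to FASTA
#'
#' @param alns Named list of [species_alignment()] objects.
#' @param path Output path.
#' @export
write_alignment <- function(alns, path) {
  seqs <- vapply(alns, function(a) a$aligned_seq, character(1))
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- vapply(alns, function(a) a$species, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Coordinate maps between the ungapped reference sequence and alignment
# columns.  Returns 0-based maps: ref2aln[i+1] is the alignment column of
# reference base i; aln2ref[j+1] is the reference base at column j, or NA
# inside reference-gap (insertion) columns.  The map is a bijection outside
# gap columns.
alignment_maps <- function(reference_aligned) {
  ch <- strsplit(reference_aligned, "")[[1]]
  notgap <- ch != "-"
  ref2aln <- which(notgap) - 1L
  aln2ref <- rep(NA_integer_, length(ch))
  aln2ref[notgap] <- seq_len(sum(notgap)) - 1L
  list(ref2aln = ref2aln, aln2ref = aln2ref)
}

# ungapped sequence of a species_alignment
ungapped <- function(aln) {
  gsub("-", "", aln$aligned_seq, fixed = TRUE)
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("species_alignment '%s': %d columns, %d N runs\n",
              x$species, nchar(x$aligned_seq), nrow(x$ambiguity_runs)))
  invisible(x)
}
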