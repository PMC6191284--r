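# Gene models: exon coordinates, reading-frame phases and splice-site
# positions of the reference gene, in 0-based half-open coordinates on the
# reference frame.  Minus-strand models are flipped onto the plus strand at
# read time so every downstream stage is strand-free.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param exons Two-column matrix or data.frame of exon `(start, end)` in
#'   0-based half-open reference coordinates, plus strand, sorted by start.
#' @param strand `"+"` or `"-"`.  Minus-strand input must be normalized with
#'   [read_gene_model()] before construction; `gene_model()` itself only
#'   accepts plus-strand coordinates.
#' @return An object of class `gene_model` with derived `phases` (per-exon
#'   reading-frame offset), `donor_sites` and `acceptor_sites` (0-based
#'   positions of the first base of each intron-edge dinucleotide).
#' @export
gene_model <- function(gene_id, exons, strand = "+") {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (strand != "+") {
    stop("gene_model: construct minus-strand models via read_gene_model()")
  }
  if (nrow(exons) == 0) stop("gene_model: no exons")
  if (any(exons[, "end"] <= exons[, "start"])) {
    stop("gene_model: empty or inverted exon")
  }
  ord <- order(exons[, "start"])
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, "start"] < exons[-nrow(exons), "end"])) {
    stop("gene_model: exons overlap")
  }
  lens <- exons[, "end"] - exons[, "start"]
  if (sum(lens) %% 3 != 0) {
    stop("gene_model: total exonic length is not a multiple of 3")
  }
  phases <- as.integer(c(0, cumsum(lens)[-length(lens)]) %% 3)
  n <- nrow(exons)
  donor <- if (n > 1) exons[-n, "end"] else integer(0)
  acceptor <- if (n > 1) exons[-1, "start"] - 2L else integer(0)
  structure(list(gene_id = gene_id, exons = exons, phases = phases,
                 strand = "+", donor_sites = as.integer(donor),
                 acceptor_sites = as.integer(acceptor)),
            class = "gene_model")
}

coding_length <- function(model) {
  sum(model$exons[, "end"] - model$exons[, "start"])
}

#' Read a gene model from BED-like records
#'
#' Expects a tab-delimited file with six columns per exon:
#' `region  start  end  gene_id  exon_rank  strand` (0-based half-open,
#' BED-style).  Minus-strand models are reverse-complement-normalized onto
#' the plus strand of the reference frame, which requires `region_length`.
#'
#' @param path Path to the record file.
#' @param region_length Total length of the reference region; required for
#'   minus-strand models.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, region_length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("region", "start", "end",
                                        "gene_id", "exon_rank", "strand"))
  strand <- unique(df$strand)
  if (length(strand) != 1 || !strand %in% c("+", "-")) {
    stop("read_gene_model: exons must share one strand (+ or -)")
  }
  if (strand == "-") {
    if (is.null(region_length)) {
      stop("read_gene_model: region_length required for minus-strand models")
    }
    new_start <- region_length - df$end
    new_end <- region_length - df$start
    df$start <- new_start
    df$end <- new_end
  }
  gene_model(df$gene_id[1], df[, c("start", "end")], strand = "+")
}

#' Write a gene model as BED-like records
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @param region Region name for column 1.
#' @export
write_gene_model <- function(model, path, region = "ref") {
  df <- data.frame(region = region,
                   start = model$exons[, "start"],
                   end = model$exons[, "end"],
                   gene_id = model$gene_id,
                   exon_rank = seq_len(nrow(model$exons)),
                   strand = model$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s': %d exons, %d coding bp\n",
              x$gene_id, nrow(x$exons), coding_length(x)))
  invisible(x)
}
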