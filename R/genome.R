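#' Reference genome container
#'
#' A `ReferenceGenome` is a named list of uppercase chromosome sequences
#' (character strings over the alphabet A/C/G/T/N) with cached lengths.
#' All coordinates used throughout the package are 0-based half-open on the
#' plus strand; SAM output converts to 1-based at the boundary.
#'
#' @param sequences named character vector or list of chromosome sequences.
#' @return An object of class `ReferenceGenome` with fields
#'   `chrom_names`, `sequences` (named character vector), `lengths`.
#' @export
reference_genome <- function(sequences) {
  sequences <- unlist(sequences)
  if (length(sequences) == 0L || any(nchar(sequences) == 0L))
    stop("empty genome")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome names must be present and unique")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence alphabet restricted to A/C/G/T/N (offending: ",
         paste(names(sequences)[bad], collapse = ", "), ")")
  structure(list(chrom_names = names(sequences),
                 sequences   = sequences,
                 lengths     = stats::setNames(nchar(sequences), names(sequences))),
            class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$chrom_names), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a (multi-record, possibly line-wrapped) FASTA file
#'
#' @param path path to an uncompressed or gzipped FASTA file.
#' @return A [reference_genome()] object.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # drop FASTA description after first whitespace, as aligners conventionally do
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_genome(seqs)
}

#' Write a ReferenceGenome to FASTA
#' @param genome a [reference_genome()].
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string (N-safe)
#' @param seq character vector of sequences.
#' @return reverse complement, same length.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Three-letter conversion of a genome for bisulfite alignment
#'
#' Bisulfite treatment converts unmethylated cytosine to uracil, sequenced
#' as T; after conversion the two genomic strands are no longer reverse
#' complements of each other, so two converted genome views are kept.  The
#' plus-strand view replaces every C by T; the minus-strand view is
#' represented as G->A substitution *in plus-strand coordinates* (which is
#' what a C->T conversion of the minus strand looks like when read back on
#' the plus strand), so that hit coordinates from both views live in a
#' single coordinate system.
#'
#' @param genome a [reference_genome()].
#' @return A `ConvertedGenomePair`: list with `c2t_view`, `g2a_view`
#'   (named character vectors, same lengths as the source) and `source`.
#' @export
convert_genome <- function(genome) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  if (length(genome$sequences) == 0L) stop("empty genome")
  structure(list(c2t_view = chartr("C", "T", genome$sequences),
                 g2a_view = chartr("G", "A", genome$sequences),
                 source   = genome),
            class = "ConvertedGenomePair")
}

#' @export
print.ConvertedGenomePair <- function(x, ...) {
  cat("ConvertedGenomePair over", length(x$c2t_view), "sequence(s)\n")
  invisible(x)
}
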