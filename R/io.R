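# FASTQ / SAM plumbing and CIGAR utilities.
# SAM is emitted and parsed as text (BAM conversion is left to samtools);
# all internal coordinates are 0-based half-open, converted at this boundary.

#' Read a FASTQ file (plain or gzip)
#' @param path FASTQ path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  ids <- lines[seq(1L, length(lines), 4L)]
  if (!all(startsWith(ids, "@")))
    stop("malformed FASTQ: missing @ header in ", path)
  seqs <- toupper(lines[seq(2L, length(lines), 4L)])
  quals <- lines[seq(4L, length(lines), 4L)]
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1]
    stop("malformed FASTQ record '", ids[bad], "': seq/qual length mismatch")
  }
  data.frame(id = sub("\\s.*$", "", sub("^@", "", ids)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path (gzipped if it ends in .gz).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

# ---- CIGAR ----

#' Split a CIGAR string into operation lengths and codes
#' @param cigar CIGAR string (ops over M/I/D/S) or "*".
#' @return list with integer `len` and character `op` vectors.
#' @export
cigar_ops <- function(cigar) {
  if (cigar == "*" || cigar == "") return(list(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

#' Read length implied by a CIGAR (sum of M+I+S)
#' @param cigar CIGAR string.
#' @export
cigar_read_len <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "I", "S")])
}

#' Reference span implied by a CIGAR (sum of M+D)
#' @param cigar CIGAR string.
#' @export
cigar_ref_len <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "D")])
}

# indels of a CIGAR as read-offset records: (read_offset, length, type)
# read_offset = number of read bases consumed before the event (soft clips
# included, matching the simulator's truth convention).
cigar_indels <- function(cigar) {
  co <- cigar_ops(cigar)
  out <- list()
  roff <- 0L
  for (i in seq_along(co$op)) {
    if (co$op[i] == "I") {
      out[[length(out) + 1L]] <- c(offset = roff, len = co$len[i], ins = 1L)
      roff <- roff + co$len[i]
    } else if (co$op[i] == "D") {
      out[[length(out) + 1L]] <- c(offset = roff, len = co$len[i], ins = 0L)
    } else {
      roff <- roff + co$len[i]
    }
  }
  if (length(out) == 0L)
    return(data.frame(offset = integer(0), len = integer(0), ins = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# ---- SAM ----

.sam_header <- function(genome, pg_args = "") {
  c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", genome$chrom_names, "\tLN:", genome$lengths),
    paste0("@PG\tID:bsmeth\tPN:bsmeth\tVN:",
           as.character(utils::packageVersion("bsmeth")),
           if (nzchar(pg_args)) paste0("\tCL:", pg_args) else ""))
}

#' Write alignments to a SAM file
#' @param aln data.frame of alignment records as produced by [align_reads()]
#'   (columns `qname`, `flag`, `chrom`, `pos` 0-based, `mapq`, `cigar`,
#'   `rnext`, `pnext`, `tlen`, `seq`, `qual`, `nm`, `as`, `xb`).
#' @param genome the [reference_genome()] aligned against.
#' @param path output SAM path.
#' @export
write_sam <- function(aln, genome, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(.sam_header(genome), con)
  if (nrow(aln)) {
    tags <- paste0("NM:i:", aln$nm, "\tAS:i:", aln$as, "\tXB:Z:", aln$xb)
    tags[is.na(aln$nm)] <- ""
    body <- paste(aln$qname, aln$flag, aln$chrom, aln$pos + 1L, aln$mapq,
                  aln$cigar, aln$rnext, aln$pnext + 1L, aln$tlen,
                  aln$seq, aln$qual, tags, sep = "\t")
    body <- sub("\t$", "", body)
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a SAM file into a data.frame
#'
#' Minimal text parser for the records this package emits (and any SAM with
#' the mandatory 11 columns).  Positions are converted back to 0-based.
#' @param path SAM path.
#' @return data.frame with the 11 mandatory fields plus `nm`, `as`, `xb`
#'   tags when present.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(qname = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), nm = integer(0),
                      as = numeric(0), xb = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  tagval <- function(tag, conv = identity) {
    vapply(f, function(x) {
      hit <- grep(paste0("^", tag, ":"), x[-(1:11)], value = TRUE)
      if (length(hit)) sub(paste0("^", tag, ":[A-Za-z]:"), "", hit[1]) else NA_character_
    }, character(1))
  }
  data.frame(qname = get(1), flag = as.integer(get(2)), chrom = get(3),
             pos = as.integer(get(4)) - 1L, mapq = as.integer(get(5)),
             cigar = get(6), rnext = get(7), pnext = as.integer(get(8)) - 1L,
             tlen = as.integer(get(9)), seq = get(10), qual = get(11),
             nm = suppressWarnings(as.integer(tagval("NM"))),
             as = suppressWarnings(as.numeric(tagval("AS"))),
             xb = tagval("XB"), stringsAsFactors = FALSE)
}
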