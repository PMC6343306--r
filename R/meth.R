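# Per-cytosine methylation calling: strand-aware pileup over the SAM
# stream, reverse-strand SNP-corrected methylation level, context
# assignment and depth filtering.
#
# Strand bookkeeping (all bases in reference-forward SAM orientation):
#   plus-strand cytosine  (ref C): C2T-space reads give C (methylated) or
#     T (converted); G2A-space reads at the same position show C (bottom-
#     strand G -> rev_G) or T (bottom-strand A, i.e. a C->T SNP -> rev_A).
#   minus-strand cytosine (ref G): G2A-space reads give G (methylated
#     bottom C) or A (converted); C2T-space reads show G (rev_G) or A
#     (rev_A).

#' Pile up aligned reads over every cytosine
#'
#' Walks each primary alignment's CIGAR (M consumes read and reference, I
#' and S consume read only, D consumes reference only -- bases under a
#' deletion contribute nothing) and counts, at every reference C (plus
#' strand) and G (minus-strand cytosine), the supporting methylated /
#' unmethylated bases from strand-informative reads and the opposite-strand
#' G/A coverage used for SNP correction.
#'
#' @param aln alignment records ([align_reads()] output or [read_sam()]).
#' @param genome the [reference_genome()] aligned against.
#' @param min_qual bases with Phred quality below this are excluded
#'   (default 20).
#' @param min_mapq alignments with MAPQ below this are excluded; the
#'   default 1 drops ambiguous (MAPQ 0) placements.
#' @param dedupe_mates count overlapping proper-pair mate bases once
#'   (mate 1 wins; default TRUE).
#' @return data.table with one row per covered cytosine: `chrom`, `pos`
#'   (0-based), `strand`, `context`, `count_C`, `count_T`, `rev_G`,
#'   `rev_A`.
#' @export
pileup <- function(aln, genome, min_qual = 20L, min_mapq = 1L,
                   dedupe_mates = TRUE) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  use <- !bitwAnd(aln$flag, 4L) & !bitwAnd(aln$flag, 2048L) &
    aln$mapq >= min_mapq & !is.na(aln$xb)
  aln <- aln[use, , drop = FALSE]
  pieces <- vector("list", nrow(aln))
  for (r in seq_len(nrow(aln))) {
    co <- cigar_ops(aln$cigar[r])
    if (sum(co$len[co$op %in% c("M", "I", "S")]) != nchar(aln$seq[r]))
      stop("record '", aln$qname[r], "': CIGAR/sequence length mismatch")
    bases <- strsplit(aln$seq[r], "", fixed = TRUE)[[1]]
    quals <- .phred(aln$qual[r])
    roff <- 0L; rpos <- aln$pos[r]
    refpos <- integer(0); ridx <- integer(0)
    for (i in seq_along(co$op)) {
      op <- co$op[i]; ln <- co$len[i]
      if (op == "M") {
        refpos <- c(refpos, rpos + seq_len(ln) - 1L)
        ridx <- c(ridx, roff + seq_len(ln))
        roff <- roff + ln; rpos <- rpos + ln
      } else if (op == "D") {
        rpos <- rpos + ln
      } else {
        roff <- roff + ln            # I and S consume read only
      }
    }
    keep <- quals[ridx] >= min_qual
    if (!any(keep)) next
    pieces[[r]] <- data.table::data.table(
      qname = aln$qname[r], chrom = aln$chrom[r], pos = refpos[keep],
      base = bases[ridx[keep]], space = aln$xb[r],
      mate = if (bitwAnd(aln$flag[r], 128L)) 2L else 1L)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L)
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  strand = character(0), context = character(0),
                                  count_C = integer(0), count_T = integer(0),
                                  rev_G = integer(0), rev_A = integer(0)))
  pp <- data.table::rbindlist(pieces)
  if (dedupe_mates) {
    data.table::setorder(pp, qname, chrom, pos, mate)
    pp <- unique(pp, by = c("qname", "chrom", "pos"))
  }
  base <- space <- count_C <- count_T <- rev_G <- rev_A <- NULL # R CMD check
  cnt <- pp[, list(
    cC = sum(space == "C2T" & base == "C"),
    cT = sum(space == "C2T" & base == "T"),
    cG = sum(space == "C2T" & base == "G"),
    cA = sum(space == "C2T" & base == "A"),
    gC = sum(space == "G2A" & base == "C"),
    gT = sum(space == "G2A" & base == "T"),
    gG = sum(space == "G2A" & base == "G"),
    gA = sum(space == "G2A" & base == "A")), by = c("chrom", "pos")]
  # classify sites by the reference base
  refb <- mapply(function(ch, p) substr(genome$sequences[[ch]], p + 1L, p + 1L),
                 cnt$chrom, cnt$pos, USE.NAMES = FALSE)
  plusC <- refb == "C"; minusC <- refb == "G"
  res <- data.table::rbindlist(list(
    data.table::data.table(chrom = cnt$chrom[plusC], pos = cnt$pos[plusC],
                           strand = "+",
                           count_C = cnt$cC[plusC], count_T = cnt$cT[plusC],
                           rev_G = cnt$gC[plusC], rev_A = cnt$gT[plusC]),
    data.table::data.table(chrom = cnt$chrom[minusC], pos = cnt$pos[minusC],
                           strand = "-",
                           count_C = cnt$gG[minusC], count_T = cnt$gA[minusC],
                           rev_G = cnt$cG[minusC], rev_A = cnt$cA[minusC])))
  res <- res[count_C + count_T + rev_G + rev_A > 0L]
  res[, "context" := assign_context(genome, res$chrom, res$pos, res$strand)]
  data.table::setorder(res, chrom, pos, strand)
  data.table::setcolorder(res, c("chrom", "pos", "strand", "context",
                                 "count_C", "count_T", "rev_G", "rev_A"))
  res[]
}

#' Reverse-strand-corrected methylation level
#'
#' When the opposite-strand coverage `rev_G + rev_A` reaches
#' `rev_threshold`, the level is corrected for putative C->T SNPs:
#' `ML = min(C / ((C+T) * rev_G / (rev_G + rev_A)), 1) * 100`; below the
#' threshold the plain `C / (C+T) * 100` is used.  A site with sufficient
#' reverse coverage but `rev_G == 0` looks like a homozygous C->T SNP: it
#' is flagged and no level is reported (the corrected formula would divide
#' by zero, and the capped value of 100 would be maximally wrong).
#'
#' @param count_C,count_T,rev_G,rev_A integer count vectors (recycled).
#' @param rev_threshold reverse-strand coverage needed to apply the
#'   correction (default 10).
#' @return data.frame with `ml` (percentage in [0, 100], NA when flagged)
#'   and `snp_flag`.
#' @export
methylation_level <- function(count_C, count_T, rev_G, rev_A,
                              rev_threshold = 10L) {
  n <- max(length(count_C), length(count_T), length(rev_G), length(rev_A))
  count_C <- rep_len(count_C, n); count_T <- rep_len(count_T, n)
  rev_G <- rep_len(rev_G, n); rev_A <- rep_len(rev_A, n)
  depth <- count_C + count_T
  if (any(depth == 0L)) stop("methylation level undefined at zero depth")
  revcov <- rev_G + rev_A
  use_corr <- revcov >= rev_threshold
  snp_flag <- use_corr & rev_G == 0L
  ml <- ifelse(use_corr,
               pmin(count_C / (depth * rev_G / pmax(revcov, 1L)), 1.0) * 100,
               count_C / depth * 100)
  ml[snp_flag] <- NA_real_
  data.frame(ml = ml, snp_flag = snp_flag)
}

#' Sequence context of a cytosine (CpG / CHG / CHH)
#'
#' Reads the two bases downstream of the cytosine on its own strand:
#' CG... is CpG, C-H-G is CHG, C-H-H is CHH (H = A, C or T).  For
#' minus-strand cytosines (reference G) the downstream bases are the
#' complemented bases at pos-1 and pos-2.  Insufficient downstream sequence
#' or an N yields CHH (the conservative catch-all class).
#'
#' @param genome a [reference_genome()].
#' @param chrom,pos,strand site vectors (0-based positions).
#' @return character vector of contexts.
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- genome$sequences[[chrom[i]]]
    L <- nchar(s)
    if (strand[i] == "+") {
      if (substr(s, pos[i] + 1L, pos[i] + 1L) != "C")
        stop("reference base at ", chrom[i], ":", pos[i], " (+) is not C")
      b1 <- if (pos[i] + 2L <= L) substr(s, pos[i] + 2L, pos[i] + 2L) else "N"
      b2 <- if (pos[i] + 3L <= L) substr(s, pos[i] + 3L, pos[i] + 3L) else "N"
    } else {
      if (substr(s, pos[i] + 1L, pos[i] + 1L) != "G")
        stop("reference base at ", chrom[i], ":", pos[i], " (-) is not G")
      b1 <- if (pos[i] >= 1L) chartr("ACGTN", "TGCAN", substr(s, pos[i], pos[i])) else "N"
      b2 <- if (pos[i] >= 2L) chartr("ACGTN", "TGCAN", substr(s, pos[i] - 1L, pos[i] - 1L)) else "N"
    }
    out[i] <- if (b1 == "G") "CpG" else if (b2 == "G") "CHG" else "CHH"
  }
  out
}

#' Depth filter for cytosine records
#'
#' Keeps sites whose informative depth `count_C + count_T` is strictly
#' greater than `min_depth` (the default 5 means at least 6 reads).
#'
#' @param records cytosine table ([pileup()] output).
#' @param min_depth depth threshold (default 5, strict).
#' @export
filter_depth <- function(records, min_depth = 5L) {
  records[records$count_C + records$count_T > min_depth, , drop = FALSE]
}

#' Call per-cytosine methylation from alignments
#'
#' Convenience orchestration: [pileup()], [filter_depth()],
#' [methylation_level()].
#'
#' @inheritParams pileup
#' @param min_depth depth filter (strict, default 5).
#' @param rev_threshold reverse-coverage threshold for SNP correction.
#' @return data.table of cytosine records with `ml` and `snp_flag`.
#' @export
call_methylation <- function(aln, genome, min_depth = 5L, rev_threshold = 10L,
                             min_qual = 20L, min_mapq = 1L,
                             dedupe_mates = TRUE) {
  rec <- pileup(aln, genome, min_qual = min_qual, min_mapq = min_mapq,
                dedupe_mates = dedupe_mates)
  rec <- filter_depth(rec, min_depth)
  if (nrow(rec) == 0L) {
    rec$ml <- numeric(0); rec$snp_flag <- logical(0)
    return(rec)
  }
  mlres <- methylation_level(rec$count_C, rec$count_T, rec$rev_G, rec$rev_A,
                             rev_threshold)
  rec$ml <- mlres$ml
  rec$snp_flag <- mlres$snp_flag
  rec
}

#' Write a per-site methylation table
#' @param records cytosine records ([call_methylation()] output).
#' @param path output TSV path.
#' @export
write_meth_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_table
#' @export
read_meth_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE,
                    colClasses = list(character = "chrom"))
}

#' Write bedGraph tracks of methylation levels (one file per context)
#'
#' Intervals are 0-based half-open single-base records with the methylation
#' level on the 0-1 scale; output is sorted and non-overlapping per strand.
#' @param records cytosine records with `ml`.
#' @param prefix output prefix; writes `<prefix>.<context>.bedGraph`.
#' @return paths written, invisibly.
#' @export
write_bedgraph <- function(records, prefix) {
  records <- records[!is.na(records$ml), , drop = FALSE]
  paths <- character(0)
  for (ctx in c("CpG", "CHG", "CHH")) {
    rr <- records[records$context == ctx, , drop = FALSE]
    if (nrow(rr) == 0L) next
    rr <- rr[order(rr$chrom, rr$pos), , drop = FALSE]
    path <- paste0(prefix, ".", ctx, ".bedGraph")
    lines <- c(paste0("track type=bedGraph name=\"bsmeth_", ctx, "\""),
               sprintf("%s\t%d\t%d\t%.6g", rr$chrom, rr$pos, rr$pos + 1L,
                       rr$ml / 100))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
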