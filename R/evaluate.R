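# Scoring alignment output against simulation truth: the three-criterion
# correctness rule (unique strand-matched mapping with positive MAPQ,
# start within 10 bp, similar indels/mismatches) and the 500-bp paired
# concordance construction.

# do truth and called indels match: same type, length within +-1, read
# offset within +-5, bidirectionally
.indels_similar <- function(truth_ind, called_ind,
                            len_tol = 1L, off_tol = 5L) {
  match_one <- function(a, b) {
    any(b$ins == a$ins & abs(b$len - a$len) <= len_tol &
          abs(b$offset - a$offset) <= off_tol)
  }
  for (i in seq_len(nrow(truth_ind)))
    if (!match_one(truth_ind[i, ], called_ind)) return(FALSE)
  for (i in seq_len(nrow(called_ind)))
    if (!match_one(called_ind[i, ], truth_ind)) return(FALSE)
  TRUE
}

#' Score alignments against simulation truth
#'
#' A read is scored correct iff (1) it is uniquely mapped (MAPQ > 0) on
#' the strand it was simulated from; (2) the reported start is within
#' `pos_tol` (default 10) bases of the true start; (3) its indels and
#' mismatches are similar to the simulated ones -- every truth indel must
#' be matched by a CIGAR indel of the same type with length within 1 and
#' read offset within 5 (and vice versa), and the reported mismatch count
#' must be within `mm_tol` of the injected error count.  Any violation
#' scores the read wrong; unmapped reads are counted separately.
#'
#' @param truth truth table from [simulate_reads()].
#' @param aln alignment records ([align_reads()] output or [read_sam()]).
#' @param pos_tol start-position tolerance in bp (default 10).
#' @param mm_tol mismatch-count tolerance (default 2, conversion-aware).
#' @return list of class `EvalReport`: `n_reads`, `n_correct`, `n_wrong`,
#'   `n_unmapped`, `failures` (named counts per criterion), `per_read`
#'   (data.frame with the verdict for each read).
#' @export
evaluate_alignments <- function(truth, aln, pos_tol = 10L, mm_tol = 2L) {
  primary <- aln[!bitwAnd(aln$flag, 2048L), , drop = FALSE]
  ix <- match(truth$read_id, primary$qname)
  if (anyNA(ix) && any(!truth$read_id %in% primary$qname))
    stop("truth read ids missing from alignment output: ",
         truth$read_id[which(is.na(ix))[1]])
  fails <- c(unmapped = 0L, unique_strand = 0L, position = 0L,
             indel_mismatch = 0L)
  verdict <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    a <- primary[ix[i], ]
    if (bitwAnd(a$flag, 4L)) {
      verdict[i] <- "unmapped"; fails["unmapped"] <- fails["unmapped"] + 1L
      next
    }
    strand <- if (bitwAnd(a$flag, 16L)) "-" else "+"
    if (a$mapq <= 0L || strand != truth$strand[i]) {
      verdict[i] <- "wrong"
      fails["unique_strand"] <- fails["unique_strand"] + 1L
      next
    }
    if (a$chrom != truth$chrom[i] ||
        abs(a$pos - truth$true_start[i]) > pos_tol) {
      verdict[i] <- "wrong"
      fails["position"] <- fails["position"] + 1L
      next
    }
    t_ind <- parse_indel_string(truth$indels[i])
    c_ind <- cigar_indels(a$cigar)
    mm_ok <- is.na(a$nm) || abs(a$nm - truth$n_errors[i]) <= mm_tol
    if (!.indels_similar(t_ind, c_ind) || !mm_ok) {
      verdict[i] <- "wrong"
      fails["indel_mismatch"] <- fails["indel_mismatch"] + 1L
      next
    }
    verdict[i] <- "correct"
  }
  structure(list(n_reads = nrow(truth),
                 n_correct = sum(verdict == "correct"),
                 n_wrong = sum(verdict == "wrong"),
                 n_unmapped = sum(verdict == "unmapped"),
                 failures = fails,
                 per_read = data.frame(read_id = truth$read_id,
                                       verdict = verdict,
                                       stringsAsFactors = FALSE)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d reads | correct %d (%.2f%%) | wrong %d | unmapped %d\n",
              x$n_reads, x$n_correct, 100 * x$n_correct / max(1, x$n_reads),
              x$n_wrong, x$n_unmapped))
  invisible(x)
}

#' Paired concordance of independently aligned mates
#'
#' Mates aligned single-end are paired back by read name; a pair is
#' concordant iff both mates are mapped to the same chromosome within
#' `max_dist` bases (start-to-start), otherwise discordant.  Counts are
#' reported cumulatively from high to low mapping quality (a pair's MAPQ
#' is the smaller of its mates'); pairs with an unmapped mate are excluded
#' from both counts and reported separately.
#'
#' @param aln1,aln2 alignment records of mate 1 and mate 2 (read ids with
#'   or without `/1`, `/2` suffixes).
#' @param max_dist nominal concordance distance (default 500).
#' @return list(`by_mapq` data.frame with cumulative `n_concordant`,
#'   `n_discordant` per MAPQ threshold, `n_half_mapped`, `n_pairs`).
#' @export
concordance_eval <- function(aln1, aln2, max_dist = 500L) {
  strip <- function(x) sub("/[12]$", "", x)
  p1 <- aln1[!bitwAnd(aln1$flag, 2048L), , drop = FALSE]
  p2 <- aln2[!bitwAnd(aln2$flag, 2048L), , drop = FALSE]
  ids <- intersect(strip(p1$qname), strip(p2$qname))
  i1 <- match(ids, strip(p1$qname)); i2 <- match(ids, strip(p2$qname))
  m1 <- !bitwAnd(p1$flag[i1], 4L); m2 <- !bitwAnd(p2$flag[i2], 4L)
  both <- m1 & m2
  half <- xor(m1, m2)
  conc <- both & p1$chrom[i1] == p2$chrom[i2] &
    abs(p1$pos[i1] - p2$pos[i2]) <= max_dist
  mq <- pmin(p1$mapq[i1], p2$mapq[i2])
  thresholds <- sort(unique(mq[both]), decreasing = TRUE)
  by_mapq <- data.frame(
    mapq = thresholds,
    n_concordant = vapply(thresholds, function(t)
      sum(conc[both] & mq[both] >= t), integer(1)),
    n_discordant = vapply(thresholds, function(t)
      sum(!conc[both] & mq[both] >= t), integer(1)))
  list(by_mapq = by_mapq, n_half_mapped = sum(half),
       n_pairs = length(ids))
}

#' Machine-readable pipeline summary
#'
#' Aggregates whatever stages are available -- read counts and mapping
#' rate, per-context global methylation, the five-category distribution,
#' DMC/DMR counts -- into one structured summary (written as JSON plus a
#' plain-text rendering).  Missing stages leave explicit NA gaps rather
#' than failing.
#'
#' @param n_reads total reads, if known.
#' @param eval an `EvalReport`, optional.
#' @param aln alignment records, optional (for the mapping rate).
#' @param meth cytosine records with `ml`, optional.
#' @param dmc,dmr differential result tables with `significant`, optional.
#' @param path optional output prefix; writes `<path>.json` and
#'   `<path>.txt`.
#' @return the summary as a named list, invisibly if written.
#' @export
run_pipeline_report <- function(n_reads = NA_integer_, eval = NULL,
                                aln = NULL, meth = NULL, dmc = NULL,
                                dmr = NULL, path = NULL) {
  rep <- list(
    n_reads = n_reads,
    mapping = if (!is.null(aln)) {
      primary <- aln[!bitwAnd(aln$flag, 2048L), , drop = FALSE]
      list(n_records = nrow(primary),
           n_mapped = sum(!bitwAnd(primary$flag, 4L)),
           mapping_rate = mean(!bitwAnd(primary$flag, 4L)))
    } else NA,
    accuracy = if (!is.null(eval))
      list(n_correct = eval$n_correct, n_wrong = eval$n_wrong,
           n_unmapped = eval$n_unmapped,
           rate_correct = eval$n_correct / max(1, eval$n_reads))
    else NA,
    methylation = if (!is.null(meth) && nrow(meth) > 0) {
      ok <- !is.na(meth$ml)
      by_ctx <- tapply(meth$ml[ok], meth$context[ok], mean)
      cats <- table(categorize_ml(meth$ml[ok]))
      list(n_sites = nrow(meth), mean_ml_by_context = as.list(by_ctx),
           category_counts = as.list(cats))
    } else NA,
    dmc = if (!is.null(dmc)) list(n_tested = nrow(dmc),
                                  n_significant = sum(dmc$significant))
          else NA,
    dmr = if (!is.null(dmr)) list(n_tested = nrow(dmr),
                                  n_significant = sum(dmr$significant))
          else NA,
    note = paste("indel similarity criterion: type equal, length within 1,",
                 "read offset within 5"))
  if (is.null(path)) return(rep)
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                              na = "null", pretty = TRUE),
             paste0(path, ".json"))
  txt <- utils::capture.output(utils::str(rep, give.attr = FALSE))
  writeLines(txt, paste0(path, ".txt"))
  invisible(rep)
}
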