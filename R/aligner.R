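# Bisulfite read alignment: long-seed candidate search on the converted
# genome views, affine-gap extension on the original sequences with
# bisulfite-aware matching, mismatch-gated indel detection, soft-clip
# realignment and paired-end deep-scan selection.

.c2t <- function(s) chartr("C", "T", s)
.g2a <- function(s) chartr("G", "A", s)
.phred <- function(qual) utf8ToInt(qual) - 33L

#' Alignment parameter set
#'
#' @param seed_len long-seed length used for candidate search (default 75).
#'   Reads shorter than `seed_len` use the whole read as the seed, with the
#'   mismatch budget scaled down proportionally (`floor(max_mm * len / 75)`).
#' @param max_mm mismatches allowed in the seed (default 5).
#' @param max_gap gaps allowed in the seed (default 1); the cost of a gap
#'   equals 1.5 mismatches when ranking seed hits.
#' @param max_gap_len maximum length of a single indel the seed search and
#'   the default extension band are sized for (default 10).
#' @param gap_open,gap_extend affine gap penalties (defaults 40 and 6; the
#'   first gap base costs `gap_open + gap_extend`).
#' @param mismatch_threshold indel gate: if the best ungapped alignment of a
#'   read has fewer mismatches than this, gapped extension is skipped
#'   (default 2).
#' @param min_clip soft clips longer than this are realigned exactly and
#'   attached as supplementary alignments (default 20).
#' @param max_insert maximum proper-pair insert size (default 500).
#' @param band bases of reference context added on both sides of the
#'   extension window (default `2 * max_gap_len + 8`, doubled once if the
#'   optimum touches the window edge).
#' @param indels if FALSE, gapped alignment is disabled entirely
#'   (the `--no-indel` mode).
#' @param library `"directional"` (two searched conversion spaces) or
#'   `"non_directional"` (four).
#' @param max_read_mm maximum bisulfite-aware mismatches for an acceptable
#'   ungapped alignment; `NULL` scales as `floor(5 * len / 75)` with floor 2.
#' @param max_candidates seed hits extended per conversion space (default 16).
#' @return list of validated parameters, class `bs_align_params`.
#' @export
align_params <- function(seed_len = 75L, max_mm = 5L, max_gap = 1L,
                         max_gap_len = 10L, gap_open = 40L, gap_extend = 6L,
                         mismatch_threshold = 2L, min_clip = 20L,
                         max_insert = 500L, band = NULL, indels = TRUE,
                         library = c("directional", "non_directional"),
                         max_read_mm = NULL, max_candidates = 16L) {
  library <- match.arg(library)
  if (is.null(band)) band <- 2L * max_gap_len + 8L
  structure(list(seed_len = as.integer(seed_len), max_mm = as.integer(max_mm),
                 max_gap = as.integer(max_gap),
                 max_gap_len = as.integer(max_gap_len),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 mismatch_threshold = as.integer(mismatch_threshold),
                 min_clip = as.integer(min_clip),
                 max_insert = as.integer(max_insert), band = as.integer(band),
                 indels = isTRUE(indels), library = library,
                 max_read_mm = max_read_mm,
                 max_candidates = as.integer(max_candidates)),
            class = "bs_align_params")
}

#' Bisulfite conversions of a read for candidate search
#'
#' A directional library yields two search tasks: the C->T converted read
#' against the C->T genome view (original top strand) and the G->A
#' converted reverse complement against the G->A view (original bottom
#' strand, reported on the minus strand).  A non-directional library
#' additionally searches the two complementary-strand conversions.  The
#' original sequence is retained for scoring.
#'
#' @param seq read sequence.
#' @param library `"directional"` or `"non_directional"`.
#' @return list of tasks: `query` (converted search string), `view`
#'   (genome view), `bs_mode` (1 = C2T, 2 = G2A matching rule), `strand`,
#'   `orient` (`"fwd"`/`"rev"`: orientation of the scoring sequence
#'   relative to the original read).
#' @export
convert_read <- function(seq, library = c("directional", "non_directional")) {
  library <- match.arg(library)
  if (nchar(seq) == 0L) stop("empty read")
  rc <- revcomp(seq)
  tasks <- list(
    list(query = .c2t(seq), view = "c2t", bs_mode = 1L, strand = "+",
         orient = "fwd", space = "C2T"),
    list(query = .g2a(rc), view = "g2a", bs_mode = 2L, strand = "-",
         orient = "rev", space = "G2A"))
  if (library == "non_directional") {
    tasks <- c(tasks, list(
      list(query = .g2a(seq), view = "g2a", bs_mode = 2L, strand = "+",
           orient = "fwd", space = "G2A"),
      list(query = .c2t(rc), view = "c2t", bs_mode = 1L, strand = "-",
           orient = "rev", space = "C2T")))
  }
  tasks
}

# k-mer codes of q_enc at 0-based offsets; NA where the window has an N
.codes_at <- function(q_enc, offs, k) {
  pw <- 4^((k - 1):0)
  vapply(offs, function(o) {
    w <- q_enc[(o + 1L):(o + k)]
    if (any(w > 3L)) NA_real_ else sum(w * pw)
  }, numeric(1))
}

# positions of code in a sorted view table -> list(pos, chrom_id)
.table_lookup <- function(idx, code) {
  if (is.na(code) || length(idx$codes) == 0L)
    return(list(pos = integer(0), chrom_id = integer(0)))
  lo <- findInterval(code - 0.5, idx$codes)
  hi <- findInterval(code + 0.5, idx$codes)
  if (hi <= lo) return(list(pos = integer(0), chrom_id = integer(0)))
  sel <- (lo + 1L):hi
  list(pos = idx$pos[sel], chrom_id = idx$chrom_id[sel])
}

.empty_hits <- function() {
  data.frame(chrom = character(0), chrom_id = integer(0), start = integer(0),
             mm = integer(0), ngap = integer(0), gap_off = integer(0),
             gap_len = integer(0), gap_type = integer(0), cost = numeric(0),
             stringsAsFactors = FALSE)
}

#' Long-seed candidate search in one converted view
#'
#' Finds all positions where the leading `seed_len` bases of the
#' (converted) query align with at most `max_mm` mismatches and `max_gap`
#' gaps.  Candidates are generated by exact sub-seed lookups in the k-mer
#' index and verified by a single-gap scan; hit cost is
#' `mismatches + 1.5 * gaps` (a gap is charged like 1.5 mismatches), and
#' hits are returned sorted by ascending cost, ties broken by
#' (chromosome order, position).
#'
#' @param query converted read sequence (same space as `view`).
#' @param index a [build_index()] result.
#' @param view `"c2t"` or `"g2a"`.
#' @param seed_len,max_mm,max_gap,max_gap_len see [align_params()].
#' @return data.frame of seed hits: `chrom`, `chrom_id`, `start` (0-based
#'   position of the query's first base), `mm`, `ngap`, `gap_off`,
#'   `gap_len`, `gap_type` (1 insertion, 2 deletion), `cost`.
#' @export
seed_align <- function(query, index, view = c("c2t", "g2a"), seed_len = 75L,
                       max_mm = 5L, max_gap = 1L, max_gap_len = 10L) {
  view <- match.arg(view)
  L <- nchar(query)
  sl <- min(seed_len, L)
  k <- index$k
  if (sl < k) return(.empty_hits())
  mm_eff <- if (sl < seed_len) max(1L, floor(max_mm * sl / seed_len)) else max_mm
  q_enc <- .enc_string(query)
  seed_enc <- q_enc[seq_len(sl)]
  clusters <- .seed_clusters(q_enc, index, view, sl, max_gap_len)
  if (nrow(clusters) == 0L) return(.empty_hits())
  enc_view <- index[[paste0("enc_", view)]]
  gap_len_cap <- if (max_gap > 0L) max_gap_len else 0L
  out <- list()
  for (i in seq_len(nrow(clusters))) {
    ci <- clusters$chrom_id[i]
    v <- cpp_seed_verify(seed_enc, enc_view[[ci]], clusters$c0[i],
                         -gap_len_cap, clusters$spread[i] + gap_len_cap,
                         mm_eff, max(1L, gap_len_cap), max_gap > 0L)
    if (v[1] == 1L)
      out[[length(out) + 1L]] <-
        data.frame(chrom = index$chrom_names[ci], chrom_id = ci,
                   start = v[2], mm = v[3], ngap = v[4], gap_off = v[5],
                   gap_len = v[6], gap_type = v[7],
                   cost = v[3] + 1.5 * v[4], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[!duplicated(hits[, c("chrom_id", "start")]), , drop = FALSE]
  hits[order(hits$cost, hits$chrom_id, hits$start), , drop = FALSE]
}

# raw candidate clusters from exact sub-seed lookups of the leading sl
# bases: data.frame(chrom_id, c0 = leftmost implied start, spread)
.seed_clusters <- function(q_enc, index, view, sl, max_gap_len) {
  k <- index$k
  offs <- unique(c(seq(0L, sl - k, by = k), sl - k))
  codes <- .codes_at(q_enc, offs, k)
  idx <- index[[view]]
  starts <- integer(0); chrom_id <- integer(0)
  for (i in seq_along(offs)) {
    hit <- .table_lookup(idx, codes[i])
    if (length(hit$pos)) {
      starts <- c(starts, hit$pos - offs[i])
      chrom_id <- c(chrom_id, hit$chrom_id)
    }
  }
  if (length(starts) == 0L)
    return(data.frame(chrom_id = integer(0), c0 = integer(0),
                      spread = integer(0)))
  out <- list()
  for (ci in sort(unique(chrom_id))) {
    s <- sort(unique(starts[chrom_id == ci]))
    grp <- cumsum(c(TRUE, diff(s) > max_gap_len + 2L))
    for (g in unique(grp)) {
      cl <- s[grp == g]
      out[[length(out) + 1L]] <-
        data.frame(chrom_id = ci, c0 = cl[1],
                   spread = cl[length(cl)] - cl[1])
    }
  }
  do.call(rbind, out)
}

#' Multi-seed candidate search for long reads
#'
#' For reads longer than 150 bp, every nonoverlapping `seed_len` window of
#' the read is searched independently; hit positions are shifted to the
#' implied read start and duplicates (within one indel length) merged,
#' keeping the lowest cost.
#'
#' @inheritParams seed_align
#' @export
multi_seed <- function(query, index, view = c("c2t", "g2a"), seed_len = 75L,
                       max_mm = 5L, max_gap = 1L, max_gap_len = 10L) {
  view <- match.arg(view)
  L <- nchar(query)
  offs <- seq(0L, L - seed_len, by = seed_len)
  out <- list()
  for (o in offs) {
    sub <- substr(query, o + 1L, o + seed_len)
    h <- seed_align(sub, index, view, seed_len, max_mm, max_gap, max_gap_len)
    if (nrow(h)) {
      h$start <- h$start - o
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$chrom_id, hits$start, hits$cost), , drop = FALSE]
  # merge hits whose implied starts differ by at most one indel length
  keep <- rep(TRUE, nrow(hits))
  last_ci <- -1L; last_start <- -1e9
  for (i in seq_len(nrow(hits))) {
    if (hits$chrom_id[i] == last_ci &&
        hits$start[i] - last_start <= max_gap_len) {
      keep[i] <- FALSE
    } else {
      last_ci <- hits$chrom_id[i]; last_start <- hits$start[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$cost, hits$chrom_id, hits$start), , drop = FALSE]
}

#' Affine-gap extension of a seed hit
#'
#' Runs the full-read affine-gap dynamic program between the original-space
#' read and the reference window around the hit.  A match contributes +Q,
#' a mismatch -Q (Q = Phred quality of the read base), a gap costs
#' `gap_open + gap_extend` for its first base and `gap_extend` for each
#' further base.  Matching is bisulfite-aware: in C2T space a read T over a
#' reference C is a match (read C over reference T is not); in G2A space a
#' read A over a reference G is a match.  If the optimum touches the window
#' edge the window is widened once; if it still touches, the hit fails.
#'
#' @param hit one row of a [seed_align()] result (list or data.frame row
#'   with `chrom_id`, `start`).
#' @param rseq_enc integer-coded scoring sequence (the read, or its reverse
#'   complement for minus-strand hits).
#' @param quals integer Phred qualities, same orientation as `rseq_enc`.
#' @param index the [build_index()] used for the search.
#' @param bs_mode 1 for C2T space, 2 for G2A space, 0 exact.
#' @param params an [align_params()] set.
#' @param clip allow soft-clipping of read ends whose inclusion drives the
#'   score negative (default TRUE; FALSE gives a strictly global-in-read
#'   alignment).
#' @param max_gap_events cap on the number of gap openings along the path;
#'   0 (default) means unrestricted, the exhaustive affine-gap DP.  The
#'   alignment pipeline passes the seed model's gap allowance (one), which
#'   stops chains of short score-positive gaps across unrelated sequence.
#' @return list(`valid`, `pos`, `cigar`, `score`, `n_mismatch`) or
#'   `list(valid = FALSE)`.
#' @export
extend_hit <- function(hit, rseq_enc, quals, index, bs_mode, params,
                       clip = TRUE, max_gap_events = 0L) {
  ref <- index$enc_src[[hit$chrom_id]]
  m <- length(rseq_enc)
  band <- params$band
  for (attempt in 1:2) {
    res <- cpp_affine_extend(rseq_enc, quals, ref,
                             hit$start - band, hit$start + m + band,
                             bs_mode, params$gap_open, params$gap_extend,
                             clip, max_gap_events)
    if (!isTRUE(res$valid)) return(list(valid = FALSE))
    if (!isTRUE(res$touched_left) && !isTRUE(res$touched_right))
      return(res)
    band <- band * 2L  # widen once on band-edge contact
  }
  list(valid = FALSE)
}

#' Mismatch-gated indel detection
#'
#' If the best ungapped alignment of the read has fewer than
#' `mismatch_threshold` bisulfite-aware mismatches, it is returned as-is
#' and the gapped dynamic program is skipped; otherwise (or when no
#' acceptable ungapped alignment exists) gapped extension is run and the
#' better-scoring result returned.
#'
#' @inheritParams extend_hit
#' @return list(`valid`, `pos`, `cigar`, `score`, `n_mismatch`, `gapped`).
#' @export
gate_indel <- function(hit, rseq_enc, quals, index, bs_mode, params) {
  ref <- index$enc_src[[hit$chrom_id]]
  m <- length(rseq_enc)
  max_read_mm <- params$max_read_mm
  if (is.null(max_read_mm)) max_read_mm <- max(2L, floor(5L * m / 75))
  ug <- NULL
  if (hit$ngap == 0L) {
    u <- cpp_ungapped_extend(rseq_enc, quals, ref, hit$start, bs_mode, FALSE)
    if (isTRUE(u$valid) && u$n_mismatch <= max_read_mm)
      ug <- list(valid = TRUE, pos = u$pos, cigar = paste0(m, "M"),
                 score = u$score, n_mismatch = u$n_mismatch, gapped = FALSE)
  }
  if (!is.null(ug) && ug$n_mismatch < params$mismatch_threshold)
    return(ug)                       # gate closed: no gapped DP
  if (!params$indels) {
    if (!is.null(ug)) return(ug)
    # clipped ungapped fallback so that structural reads still map partially
    u <- cpp_ungapped_extend(rseq_enc, quals, ref, hit$start, bs_mode, TRUE)
    if (isTRUE(u$valid) && u$match_len >= index$k) {
      cig <- paste0(if (u$clip_left > 0) paste0(u$clip_left, "S"),
                    u$match_len, "M",
                    if (u$clip_right > 0) paste0(u$clip_right, "S"))
      return(list(valid = TRUE, pos = u$pos, cigar = cig, score = u$score,
                  n_mismatch = u$n_mismatch, gapped = FALSE))
    }
    return(list(valid = FALSE))
  }
  g <- extend_hit(hit, rseq_enc, quals, index, bs_mode, params, clip = TRUE,
                  max_gap_events = max(1L, params$max_gap))
  if (isTRUE(g$valid)) g$gapped <- TRUE
  if (!is.null(ug) && (!isTRUE(g$valid) || ug$score >= g$score)) return(ug)
  if (isTRUE(g$valid)) return(g)
  if (!is.null(ug)) return(ug)
  list(valid = FALSE)
}

#' Mapping quality from the score gap to the second-best hit
#'
#' A unique hit with no scoring alternative gets MAPQ 60; co-optimal hits
#' get 0 (reported as ambiguous); otherwise
#' `min(60, round(0.4 * (best - second) / mean base quality))`, floored at
#' 0.  The formula is this package's own; the underlying method only
#' requires that alignments carry a mapping-quality report.
#'
#' @param best_score score of the selected alignment.
#' @param second_best_score score of the best alternative locus, or NULL.
#' @param mean_qual mean Phred quality of the read (default 30).
#' @return integer MAPQ in [0, 60].
#' @export
compute_mapq <- function(best_score, second_best_score = NULL,
                         mean_qual = 30) {
  if (is.null(second_best_score) || is.na(second_best_score)) return(60L)
  if (second_best_score >= best_score) return(0L)
  mq <- round(0.4 * (best_score - second_best_score) / max(mean_qual, 1))
  as.integer(max(0L, min(60L, mq)))
}

# all candidate alignments of one read across its conversion spaces
.read_candidates <- function(seq, qual, index, params) {
  tasks <- convert_read(seq, params$library)
  quals_f <- .phred(qual)
  enc_f <- .enc_string(seq)
  enc_r <- .enc_string(revcomp(seq))
  quals_r <- rev(quals_f)
  rows <- list()
  for (tk in tasks) {
    L <- nchar(tk$query)
    hits <- if (L > 150L)
      multi_seed(tk$query, index, tk$view, params$seed_len, params$max_mm,
                 if (params$indels) params$max_gap else 0L, params$max_gap_len)
    else
      seed_align(tk$query, index, tk$view, params$seed_len, params$max_mm,
                 if (params$indels) params$max_gap else 0L, params$max_gap_len)
    if (nrow(hits) == 0L) next
    hits <- utils::head(hits, params$max_candidates)
    rseq_enc <- if (tk$orient == "fwd") enc_f else enc_r
    qq <- if (tk$orient == "fwd") quals_f else quals_r
    for (i in seq_len(nrow(hits))) {
      a <- gate_indel(hits[i, ], rseq_enc, qq, index, tk$bs_mode, params)
      if (!isTRUE(a$valid) || a$score <= 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = hits$chrom[i], chrom_id = hits$chrom_id[i],
                   pos = a$pos, strand = tk$strand, space = tk$space,
                   orient = tk$orient, bs_mode = tk$bs_mode,
                   cigar = a$cigar, score = a$score,
                   n_mismatch = a$n_mismatch, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    # rescue: no seed passed the mismatch/gap budget (e.g. a read spanning
    # a breakpoint); extend the raw candidate clusters with clipping so a
    # partial (soft-clipped) alignment can still be reported
    for (tk in tasks) {
      sl <- min(params$seed_len, nchar(tk$query))
      if (sl < index$k) next
      cl <- .seed_clusters(.enc_string(tk$query), index, tk$view, sl,
                           params$max_gap_len)
      if (nrow(cl) == 0L) next
      cl <- utils::head(cl, params$max_candidates)
      rseq_enc <- if (tk$orient == "fwd") enc_f else enc_r
      qq <- if (tk$orient == "fwd") quals_f else quals_r
      for (i in seq_len(nrow(cl))) {
        hit <- list(chrom_id = cl$chrom_id[i], start = cl$c0[i], ngap = 0L)
        a <- gate_indel(hit, rseq_enc, qq, index, tk$bs_mode, params)
        if (!isTRUE(a$valid) || a$score <= 0) next
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = index$chrom_names[cl$chrom_id[i]],
                     chrom_id = cl$chrom_id[i],
                     pos = a$pos, strand = tk$strand, space = tk$space,
                     orient = tk$orient, bs_mode = tk$bs_mode,
                     cigar = a$cigar, score = a$score,
                     n_mismatch = a$n_mismatch, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$chrom_id, cand$pos, cand$strand, -cand$score), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand[, c("chrom_id", "pos", "strand")]), ,
               drop = FALSE]
  cand[order(-cand$score, cand$chrom_id, cand$pos, cand$strand), ,
       drop = FALSE]
}

#' Exact realignment of a long soft-clipped segment
#'
#' When the primary alignment soft-clips more than `min_clip` bases, the
#' clipped substring is searched for an exact (0-mismatch) occurrence in
#' the read's own converted space; a unique occurrence is attached as an
#' auxiliary (supplementary) alignment, so that primary plus auxiliary
#' together represent a complete alignment of the original read.
#'
#' @param aln one primary alignment row (needs `cigar`, `space`, `orient`).
#' @param rseq the reference-forward scoring sequence of the alignment.
#' @param index a [build_index()] result.
#' @param min_clip minimum clip length to attempt realignment (default 20).
#' @return NULL, or list(`chrom`, `pos`, `cigar`) for the clipped segment.
#' @export
soft_clip_realign <- function(aln, rseq, index, min_clip = 20L) {
  co <- cigar_ops(aln$cigar)
  n <- length(co$op)
  lead <- if (n > 0 && co$op[1] == "S") co$len[1] else 0L
  trail <- if (n > 1 && co$op[n] == "S") co$len[n] else 0L
  side <- if (lead > trail) "lead" else "trail"
  clen <- max(lead, trail)
  if (clen <= min_clip) return(NULL)
  sub <- if (side == "lead") substr(rseq, 1L, lead)
         else substr(rseq, nchar(rseq) - trail + 1L, nchar(rseq))
  conv <- if (aln$space == "C2T") .c2t(sub) else .g2a(sub)
  view <- if (aln$space == "C2T") "enc_c2t" else "enc_g2a"
  pe <- .enc_string(conv)
  found <- NULL
  for (ci in seq_along(index$chrom_names)) {
    occ <- cpp_exact_scan(pe, index[[view]][[ci]])
    for (p in occ) {
      if (!is.null(found)) return(NULL)  # ambiguous
      found <- list(chrom = index$chrom_names[ci], pos = p)
    }
  }
  if (is.null(found)) return(NULL)
  m <- nchar(rseq)
  found$cigar <- if (side == "lead") paste0(clen, "M", m - clen, "S")
                 else paste0(m - clen, "S", clen, "M")
  found
}

.rev_qual <- function(q) paste(rev(strsplit(q, "", fixed = TRUE)[[1]]),
                               collapse = "")

# SAM row constructors ------------------------------------------------------

.sam_unmapped <- function(id, seq, qual) {
  data.frame(qname = id, flag = 4L, chrom = "*", pos = -1L, mapq = 0L,
             cigar = "*", rnext = "*", pnext = -1L, tlen = 0L, seq = seq,
             qual = qual, nm = NA_integer_, as = NA_real_,
             xb = NA_character_, stringsAsFactors = FALSE)
}

.sam_row <- function(id, aln, seq, qual, mapq, flag_extra = 0L) {
  rev <- aln$strand == "-"
  data.frame(qname = id,
             flag = flag_extra + if (rev) 16L else 0L,
             chrom = aln$chrom, pos = aln$pos, mapq = mapq,
             cigar = aln$cigar, rnext = "*", pnext = -1L, tlen = 0L,
             seq = if (rev) revcomp(seq) else seq,
             qual = if (rev) .rev_qual(qual) else qual,
             nm = aln$n_mismatch, as = round(aln$score),
             xb = aln$space, stringsAsFactors = FALSE)
}

#' Align single-end bisulfite reads
#'
#' Orchestrates conversion, long-seed search, gated extension, soft-clip
#' realignment and mapping-quality assignment, and returns SAM-style
#' records (one primary per read; auxiliary clip alignments as
#' supplementary records; unmapped reads flagged 4).  Deterministic: ties
#' are broken by (chromosome order, position, strand).
#'
#' @param reads data.frame with `id`, `seq`, `qual` (see [read_fastq()]).
#' @param index a [build_index()] result.
#' @param params an [align_params()] set.
#' @return data.frame of SAM records (0-based `pos`); write with
#'   [write_sam()].
#' @export
align_reads <- function(reads, index, params = align_params()) {
  out <- vector("list", nrow(reads))
  for (r in seq_len(nrow(reads))) {
    id <- reads$id[r]; seq <- reads$seq[r]; qual <- reads$qual[r]
    if (nchar(seq) != nchar(qual))
      stop("read '", id, "': seq/qual length mismatch")
    cand <- .read_candidates(seq, qual, index, params)
    if (is.null(cand)) { out[[r]] <- .sam_unmapped(id, seq, qual); next }
    best <- cand[1, ]
    second <- if (nrow(cand) > 1L) cand$score[2] else NULL
    mapq <- compute_mapq(best$score, second, mean(.phred(qual)))
    rows <- .sam_row(id, best, seq, qual, mapq)
    rseq <- if (best$strand == "-") revcomp(seq) else seq
    aux <- soft_clip_realign(best, rseq, index, params$min_clip)
    if (!is.null(aux)) {
      arow <- .sam_row(id, list(strand = best$strand, chrom = aux$chrom,
                                pos = aux$pos, cigar = aux$cigar,
                                n_mismatch = 0L, score = 0,
                                space = best$space),
                       seq, qual, mapq, flag_extra = 2048L)
      rows <- rbind(rows, arow)
    }
    out[[r]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deep-scan selection of the best paired alignment
#'
#' The best hit of an individual mate is not necessarily the best result
#' for the pair, so all retained candidate alignments of both mates are
#' considered jointly: a proper pair requires the same chromosome, opposite
#' strands, forward-reverse orientation and an outer insert of at most
#' `max_insert`; among proper pairs the one maximizing the summed alignment
#' score is chosen.  If no proper pair exists the individually best hits
#' are returned flagged improper; if one mate has no candidates a
#' single-mapped pair is returned.
#'
#' @param hits1,hits2 candidate data.frames (columns `chrom`, `chrom_id`,
#'   `pos`, `strand`, `cigar`, `score`) for mate 1 and mate 2; NULL or
#'   zero rows mean the mate is unaligned.
#' @param max_insert maximum proper insert size (default 500).
#' @return list(`a1`, `a2` (rows or NULL), `insert`, `proper`).
#' @export
deep_scan_pair <- function(hits1, hits2, max_insert = 500L) {
  n1 <- if (is.null(hits1)) 0L else nrow(hits1)
  n2 <- if (is.null(hits2)) 0L else nrow(hits2)
  if (n1 == 0L && n2 == 0L)
    return(list(a1 = NULL, a2 = NULL, insert = NA_integer_, proper = FALSE))
  if (n1 == 0L || n2 == 0L) {
    one <- if (n1 > 0L) hits1[1, ] else hits2[1, ]
    return(list(a1 = if (n1 > 0L) one else NULL,
                a2 = if (n2 > 0L) one else NULL,
                insert = NA_integer_, proper = FALSE))
  }
  best <- NULL; best_score <- -Inf
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    a <- hits1[i, ]; b <- hits2[j, ]
    if (a$chrom_id != b$chrom_id || a$strand == b$strand) next
    fwd <- if (a$strand == "+") a else b
    rev <- if (a$strand == "+") b else a
    if (fwd$pos > rev$pos) next                  # FR orientation only
    ins <- (rev$pos + cigar_ref_len(rev$cigar)) - fwd$pos
    if (ins > max_insert) next
    sc <- a$score + b$score
    if (sc > best_score) { best_score <- sc; best <- list(a, b, ins) }
  }
  if (is.null(best))
    return(list(a1 = hits1[1, ], a2 = hits2[1, ],
                insert = NA_integer_, proper = FALSE))
  list(a1 = best[[1]], a2 = best[[2]],
       insert = as.integer(best[[3]]), proper = TRUE)
}

#' Align paired-end bisulfite reads
#'
#' Each mate is searched independently (mate 2 with the roles of the two
#' conversion spaces exchanged, as in a directional paired library), then
#' [deep_scan_pair()] selects the jointly best pair.
#'
#' @param reads1,reads2 data.frames with `id`, `seq`, `qual`; row i of
#'   `reads2` is the mate of row i of `reads1`.
#' @inheritParams align_reads
#' @return data.frame of SAM records.
#' @export
align_pairs <- function(reads1, reads2, index, params = align_params()) {
  stopifnot(nrow(reads1) == nrow(reads2))
  out <- vector("list", nrow(reads1))
  for (r in seq_len(nrow(reads1))) {
    id <- sub("/[12]$", "", reads1$id[r])
    # mate 2 of a directional library is the complement protocol: its
    # candidates come from the same machinery on the reverse complement,
    # and its reported strand is the opposite of the searched orientation
    c1 <- .read_candidates(reads1$seq[r], reads1$qual[r], index, params)
    c2 <- .read_candidates(revcomp(reads2$seq[r]),
                           .rev_qual(reads2$qual[r]), index, params)
    if (!is.null(c2))
      c2$strand <- ifelse(c2$strand == "+", "-", "+")
    pr <- deep_scan_pair(c1, c2, params$max_insert)
    mk <- function(aln, cand, seq, qual, mate_flag, other) {
      if (is.null(aln)) return(.sam_unmapped(paste0(id), seq, qual))
      second <- if (!is.null(cand) && nrow(cand) > 1L) {
        alt <- cand[!(cand$chrom_id == aln$chrom_id & cand$pos == aln$pos &
                      cand$strand == aln$strand), , drop = FALSE]
        if (nrow(alt)) alt$score[1] else NULL
      } else NULL
      mapq <- compute_mapq(aln$score, second, mean(.phred(qual)))
      row <- .sam_row(id, aln, seq, qual, mapq,
                      flag_extra = 1L + (if (pr$proper) 2L else 0L) + mate_flag)
      if (!is.null(other)) {
        row$rnext <- "="; row$pnext <- other$pos
        row$flag <- row$flag + (if (other$strand == "-") 32L else 0L)
        if (pr$proper)
          row$tlen <- if (aln$pos <= other$pos) pr$insert else -pr$insert
      }
      row
    }
    r1 <- mk(pr$a1, c1, reads1$seq[r], reads1$qual[r], 64L, pr$a2)
    r2 <- mk(pr$a2, c2, reads2$seq[r], reads2$qual[r], 128L, pr$a1)
    out[[r]] <- rbind(r1, r2)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
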