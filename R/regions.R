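# Region-level methylation: the region-ML statistic, chromosome sliding
# windows, gene meta-profiles with flanks, the five-category partition of
# methylation levels and feature annotation of cytosine sites.

#' Methylation level of a genomic region
#'
#' The region ML is the pooled-count statistic
#' `100 * sum(C) / sum(C + T)` over all cytosines in the region whose
#' coverage exceeds `min_cov` -- not the mean of per-site levels, so deep
#' sites weigh more.  Counts are additive, so the ML of a union of disjoint
#' regions is the count-weighted combination of the parts.
#'
#' @param records cytosine records ([pileup()]/[call_methylation()] output).
#' @param chrom,start,end region (0-based half-open).
#' @param min_cov per-site coverage must be strictly greater (default 0).
#' @param strand optional: restrict to one strand; default both.
#' @param context optional: restrict to one context; default all.
#' @return percentage in [0, 100], or NA if no qualifying cytosine.
#' @export
region_ml <- function(records, chrom, start, end, min_cov = 0L,
                      strand = NULL, context = NULL) {
  sel <- records$chrom == chrom & records$pos >= start & records$pos < end &
    (records$count_C + records$count_T) > min_cov
  if (!is.null(strand)) sel <- sel & records$strand == strand
  if (!is.null(context)) sel <- sel & records$context == context
  if (!any(sel)) return(NA_real_)
  100 * sum(records$count_C[sel]) /
    sum(records$count_C[sel] + records$count_T[sel])
}

#' Sliding windows over a chromosome
#'
#' Windows `[k*step, k*step + window)` clipped at the chromosome end
#' (default 100 kb windows with a 50 kb step, the chromosome-scale
#' methylation-density view).
#'
#' @param chrom chromosome name.
#' @param chrom_len chromosome length.
#' @param window,step window size and step (`window >= step > 0`).
#' @return data.frame of regions (`chrom`, `start`, `end`).
#' @export
sliding_windows <- function(chrom, chrom_len, window = 100000L, step = 50000L) {
  stopifnot(window >= step, step > 0)
  starts <- seq(0L, max(0L, chrom_len - 1L), by = step)
  starts <- starts[starts < chrom_len]
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + window, chrom_len),
             stringsAsFactors = FALSE)
}

#' Per-window methylation levels (per strand)
#'
#' @param records cytosine records.
#' @param genome a [reference_genome()] (for chromosome lengths).
#' @param window,step see [sliding_windows()].
#' @param min_cov per-site coverage filter (strict).
#' @param by_strand compute plus and minus strand levels separately
#'   (default TRUE, as in the chromosome-scale dot plots).
#' @return data.frame of windows with `ml` (and `strand` if `by_strand`).
#' @export
window_ml <- function(records, genome, window = 100000L, step = 50000L,
                      min_cov = 0L, by_strand = TRUE) {
  out <- list()
  for (ch in genome$chrom_names) {
    w <- sliding_windows(ch, genome$lengths[[ch]], window, step)
    strands <- if (by_strand) c("+", "-") else list(NULL)
    for (s in strands) {
      ml <- vapply(seq_len(nrow(w)), function(i)
        region_ml(records, ch, w$start[i], w$end[i], min_cov,
                  strand = if (is.null(s) || !nzchar(s)) NULL else s),
        numeric(1))
      ww <- w
      ww$strand <- if (is.null(s)) "." else s
      ww$ml <- ml
      out[[length(out) + 1L]] <- ww
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Meta-gene methylation profile (upstream flank, body, downstream flank)
#'
#' Each gene is split into an upstream flank, the length-normalized body
#' and a downstream flank (default 2 kb flanks), each divided into
#' `bins` bins; minus-strand genes are flipped so bin 1 is always
#' biologically upstream.  Cytosine counts are assigned to bins by
#' fractional overlap of the 1-bp site with the bin interval; each bin's
#' level is the pooled-count region ML, aggregated across genes as the
#' across-gene mean.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `strand` (and
#'   optionally `name`).
#' @param records cytosine records.
#' @param flank flank length in bp (default 2000).
#' @param bins bins per segment (default 50).
#' @param min_cov per-site coverage filter (strict, default 0).
#' @return list with `profile` (data.frame: `segment`, `bin`, `ml`,
#'   `n_sites`) and `matrix` (genes x 3*bins matrix of per-gene levels for
#'   heat-mapping).
#' @export
gene_profile <- function(genes, records, flank = 2000L, bins = 50L,
                         min_cov = 0L) {
  nb <- 3L * bins
  ng <- nrow(genes)
  sumC <- matrix(0, ng, nb)
  sumT <- matrix(0, ng, nb)
  nsit <- matrix(0L, ng, nb)
  dep <- records$count_C + records$count_T
  for (g in seq_len(ng)) {
    ch <- genes$chrom[g]; gs <- genes$start[g]; ge <- genes$end[g]
    minus <- identical(genes$strand[g], "-")
    lo <- gs - flank; hi <- ge + flank
    sel <- which(records$chrom == ch & records$pos >= lo & records$pos < hi &
                   dep > min_cov)
    if (length(sel) == 0L) next
    pos <- records$pos[sel]
    # map a genomic position to a fractional coordinate in [0, 3) :
    # [0,1) upstream flank, [1,2) body, [2,3) downstream flank
    px <- numeric(length(pos))
    up <- pos < gs; dn <- pos >= ge; bd <- !up & !dn
    px[up] <- (pos[up] - lo) / flank
    px[bd] <- 1 + (pos[bd] - gs) / (ge - gs)
    px[dn] <- 2 + (pos[dn] - ge) / flank
    # fractional width of one base in segment units
    wd <- numeric(length(pos))
    wd[up | dn] <- 1 / flank
    wd[bd] <- 1 / (ge - gs)
    # flip the whole 1-bp interval [px, px+wd) so bin 1 is upstream
    if (minus) px <- 3 - px - wd
    b0 <- px * bins            # continuous bin coordinate, site spans wd*bins
    wspan <- wd * bins
    for (i in seq_along(pos)) {
      a <- b0[i]; b <- min(a + wspan[i], nb)
      j1 <- floor(a); j2 <- min(floor(b - 1e-12), nb - 1)
      for (j in j1:j2) {
        frac <- (min(b, j + 1) - max(a, j)) / (b - a)
        sumC[g, j + 1] <- sumC[g, j + 1] + records$count_C[sel[i]] * frac
        sumT[g, j + 1] <- sumT[g, j + 1] + records$count_T[sel[i]] * frac
        nsit[g, j + 1] <- nsit[g, j + 1] + 1L
      }
    }
  }
  per_gene <- 100 * sumC / (sumC + sumT)
  colnames(per_gene) <- paste0(rep(c("up", "body", "down"), each = bins),
                               ".", rep(seq_len(bins), 3L))
  rownames(per_gene) <- if (!is.null(genes$name)) genes$name else
    paste0("gene", seq_len(ng))
  prof <- data.frame(
    segment = rep(c("upstream", "body", "downstream"), each = bins),
    bin = rep(seq_len(bins), 3L),
    ml = colMeans(per_gene, na.rm = TRUE),
    n_sites = colSums(nsit), row.names = NULL)
  prof$ml[is.nan(prof$ml)] <- NA_real_
  list(profile = prof, matrix = per_gene)
}

#' Five-category partition of methylation levels
#'
#' M (> 80), Mh (60-80], H (40-60], hU [20-40], U (< 20).  Upper bounds
#' are inclusive so the partition is exhaustive and disjoint.
#'
#' @param ml numeric vector of levels in [0, 100].
#' @return factor with levels M, Mh, H, hU, U.
#' @export
categorize_ml <- function(ml) {
  if (any(is.na(ml)) || any(ml < 0 | ml > 100))
    stop("ml must be within [0, 100]")
  out <- ifelse(ml > 80, "M",
         ifelse(ml > 60, "Mh",
         ifelse(ml > 40, "H",
         ifelse(ml >= 20, "hU", "U"))))
  factor(out, levels = c("M", "Mh", "H", "hU", "U"))
}

#' Annotate sites with overlapping feature classes
#'
#' For each feature class (gene, CDS, intron, ...), counts the sites
#' overlapping at least one feature of that class; a site inside nested
#' features is counted once per class.  Implemented with a sorted interval
#' join.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based positions).
#' @param features data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `label` (feature class).
#' @return data.frame per class: `label`, `count`, `proportion` (of all
#'   sites).
#' @export
annotate_sites <- function(sites, features) {
  n <- nrow(sites)
  classes <- unique(features$label)
  if (n == 0L)
    return(data.frame(label = classes, count = 0L, proportion = NA_real_))
  # foverlaps uses closed intervals; represent the 1-bp site as [pos, pos]
  # and the half-open feature [start, end) as [start, end - 1]
  st <- data.table::data.table(chrom = sites$chrom, start = sites$pos,
                               end = sites$pos, site_id = seq_len(n))
  ft <- data.table::data.table(chrom = features$chrom,
                               start = features$start,
                               end = features$end - 1L,
                               label = features$label)
  data.table::setkey(ft, chrom, start, end)
  ov <- data.table::foverlaps(st, ft, type = "any", nomatch = NULL)
  counts <- vapply(classes, function(cl)
    data.table::uniqueN(ov$site_id[ov$label == cl]), integer(1))
  data.frame(label = classes, count = counts, proportion = counts / n,
             row.names = NULL)
}
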