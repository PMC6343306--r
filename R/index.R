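# Seed index: exact k-mer lookup over the two converted genome views.
#
# Each view is encoded 2-bit per base (N = sentinel, never matches) and all
# k-mer codes are stored sorted together with their 0-based positions; a
# lookup is two binary searches.  This is deliberately a plain hashed/sorted
# k-mer table, not a compressed FM-index: the contract is exact-substring
# lookup only, and desk-scale genomes do not need more.

# integer codes for the C++ core: A=0 C=1 G=2 T=3, N/other=4
.enc_string <- function(seq) {
  code <- .encode_bases(seq)
  code[is.na(code)] <- 4L
  code
}

.encode_bases <- function(seq) {
  # A=0 C=1 G=2 T=3, N (and anything else) = NA
  v <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L   # A
  code[v == 67L] <- 1L   # C
  code[v == 71L] <- 2L   # G
  code[v == 84L] <- 3L   # T
  code
}

# rolling k-mer codes (base-4); positions containing N get NA
.kmer_codes <- function(seq, k) {
  b <- .encode_bases(seq)
  n <- length(b)
  if (n < k) return(numeric(0))
  # use doubles: 4^k fits exactly in a double for k <= 26
  x <- numeric(n - k + 1L)
  bad <- integer(0)
  cur <- 0
  nbad <- 0L                     # N count inside current window
  pow <- 4^(k - 1)
  for (i in seq_len(n)) {
    bi <- b[i]
    if (is.na(bi)) { bi <- 0L; nbad <- nbad + 1L }
    if (i <= k) {
      cur <- cur * 4 + bi
      if (i == k) {
        x[1L] <- if (nbad > 0L) NA_real_ else cur
      }
    } else {
      bo <- b[i - k]
      if (is.na(bo)) { bo <- 0L; nbad <- nbad - 1L }
      cur <- (cur - bo * pow) * 4 + bi
      x[i - k + 1L] <- if (nbad > 0L) NA_real_ else cur
    }
  }
  x
}

.index_one_view <- function(view_seqs, k, regions = NULL) {
  chroms <- names(view_seqs)
  codes <- numeric(0); pos <- integer(0); chrom_id <- integer(0)
  for (ci in seq_along(chroms)) {
    x <- .kmer_codes(view_seqs[[ci]], k)
    keep <- !is.na(x)
    if (!is.null(regions)) {
      rr <- regions[regions$chrom == chroms[ci], , drop = FALSE]
      if (nrow(rr) == 0L) keep[] <- FALSE
      else {
        p0 <- seq_along(x) - 1L
        inside <- rep(FALSE, length(x))
        for (j in seq_len(nrow(rr)))
          inside <- inside | (p0 >= rr$start[j] & (p0 + k) <= rr$end[j])
        keep <- keep & inside
      }
    }
    w <- which(keep)
    codes <- c(codes, x[w])
    pos <- c(pos, w - 1L)
    chrom_id <- c(chrom_id, rep.int(ci, length(w)))
  }
  o <- order(codes, chrom_id, pos)
  list(codes = codes[o], pos = pos[o], chrom_id = chrom_id[o])
}

#' Build a seed lookup index over a converted genome pair
#'
#' Indexes every `seed_len`-mer of both converted views (C->T and G->A, plus
#' coordinates).  k-mers overlapping an N are never indexed and never match.
#'
#' @param pair a [convert_genome()] result.
#' @param seed_len k-mer length of the exact-lookup seeds (>= 12).
#' @param regions optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) restricting indexed positions, e.g. RRBS fragments from
#'   [digest_rrbs()].
#' @return A `SeedIndex` object.
#' @export
build_index <- function(pair, seed_len = 12L, regions = NULL) {
  stopifnot(inherits(pair, "ConvertedGenomePair"))
  seed_len <- as.integer(seed_len)
  if (seed_len < 12L) stop("seed_len must be >= 12")
  if (seed_len > min(nchar(pair$c2t_view)))
    stop("seed_len longer than shortest chromosome")
  structure(list(k = seed_len,
                 chrom_names = names(pair$c2t_view),
                 c2t = .index_one_view(pair$c2t_view, seed_len, regions),
                 g2a = .index_one_view(pair$g2a_view, seed_len, regions),
                 regions = regions,
                 pair = pair,
                 # integer-coded sequences (A0 C1 G2 T3, N4) for the C++ core
                 enc_c2t = lapply(pair$c2t_view, .enc_string),
                 enc_g2a = lapply(pair$g2a_view, .enc_string),
                 enc_src = lapply(pair$source$sequences, .enc_string)),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat("SeedIndex: k =", x$k, "over", length(x$chrom_names), "sequence(s)",
      if (!is.null(x$regions)) "(RRBS-reduced)" else "", "\n")
  invisible(x)
}

#' Look up the exact positions of a query's seed prefix
#'
#' @param index a [build_index()] result.
#' @param query query sequence (length >= `index$k`; only the first
#'   `index$k` bases are used).
#' @param view `"c2t"` or `"g2a"`.
#' @return data.frame with columns `chrom`, `pos` (0-based) of all exact
#'   matches of the `k`-prefix in the requested view; zero rows if absent.
#' @export
index_lookup <- function(index, query, view = c("c2t", "g2a")) {
  view <- match.arg(view)
  k <- index$k
  if (nchar(query) < k)
    stop("query shorter than index seed length")
  code <- .kmer_codes(substr(query, 1L, k), k)
  idx <- index[[view]]
  if (is.na(code) || length(idx$codes) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0)))
  lo <- findInterval(code - 0.5, idx$codes)
  hi <- findInterval(code + 0.5, idx$codes)
  if (hi <= lo)
    return(data.frame(chrom = character(0), pos = integer(0)))
  sel <- (lo + 1L):hi
  data.frame(chrom = index$chrom_names[idx$chrom_id[sel]],
             pos = idx$pos[sel], stringsAsFactors = FALSE)
}

#' Persist / restore a seed index (versioned plain-text format)
#'
#' The on-disk format (version 1) stores the seed length, optional RRBS
#' regions and the source genome; the k-mer tables are rebuilt on load,
#' which keeps the file small, text-only and forward compatible.
#'
#' @param index a `SeedIndex`.
#' @param prefix output path prefix; writes `<prefix>.bsidx` and
#'   `<prefix>.fa`.
#' @return `prefix`, invisibly.
#' @export
save_index <- function(index, prefix) {
  meta <- list(format = "bsmeth-seed-index", version = 1L, k = index$k,
               chrom_names = index$chrom_names,
               rrbs = !is.null(index$regions))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             paste0(prefix, ".bsidx"))
  if (!is.null(index$regions))
    utils::write.table(index$regions, paste0(prefix, ".regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_genome_fasta(index$pair$source, paste0(prefix, ".fa"))
  invisible(prefix)
}

#' @rdname save_index
#' @export
load_index <- function(prefix) {
  meta <- jsonlite::fromJSON(readLines(paste0(prefix, ".bsidx")))
  if (!identical(meta$format, "bsmeth-seed-index"))
    stop("not a bsmeth seed index: ", prefix)
  genome <- read_genome_fasta(paste0(prefix, ".fa"))
  regions <- NULL
  if (isTRUE(meta$rrbs))
    regions <- utils::read.table(paste0(prefix, ".regions.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  build_index(convert_genome(genome), meta$k, regions = regions)
}

#' In-silico RRBS digestion of a genome
#'
#' Cuts the (undigested, plus-strand) genome at every occurrence of the
#' enzyme recognition site -- by default C^CGG for MspI, i.e. the cut falls
#' one base into the site -- and retains fragments no longer than
#' `max_len` bases (RRBS size selection).  Chromosome ends close terminal
#' fragments, which are subject to the same length filter.
#'
#' @param genome a [reference_genome()].
#' @param site recognition sequence over A/C/G/T (no IUPAC codes).
#' @param cut_offset 0-based cut position within `site`.
#' @param max_len maximum retained fragment length (default 600).
#' @param keep_all if TRUE, skip the length filter (pre-selection tiling).
#' @return A `ReducedGenome`: data.frame `fragments` (`chrom`, `start`,
#'   `end`; 0-based half-open, disjoint, sorted) plus the digestion
#'   parameters as attributes.
#' @export
digest_rrbs <- function(genome, site = "CCGG", cut_offset = 1L,
                        max_len = 600L, keep_all = FALSE) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  site <- toupper(site)
  if (grepl("[^ACGT]", site)) stop("site must contain only A/C/G/T")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset >= nchar(site))
    stop("cut_offset out of range")
  out <- list()
  for (ch in genome$chrom_names) {
    s <- genome$sequences[[ch]]
    occ <- gregexpr(site, s, fixed = TRUE)[[1]]
    cuts <- if (occ[1] == -1L) integer(0) else as.integer(occ) - 1L + cut_offset
    bounds <- unique(sort(c(0L, cuts, nchar(s))))
    st <- bounds[-length(bounds)]
    en <- bounds[-1]
    out[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                            stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  if (!keep_all)
    frags <- frags[frags$end - frags$start <= max_len, , drop = FALSE]
  structure(list(fragments = frags, enzyme_site = site,
                 cut_offset = cut_offset, max_fragment_len = max_len),
            class = "ReducedGenome")
}

#' @export
print.ReducedGenome <- function(x, ...) {
  cat("ReducedGenome:", nrow(x$fragments), "fragment(s) <=",
      x$max_fragment_len, "bp (site", x$enzyme_site, ")\n")
  invisible(x)
}
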