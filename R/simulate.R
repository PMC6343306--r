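# Synthetic data with known truth: random genomes, methylomes and
# bisulfite reads (conversion, substitution errors, indels), the test bed
# for the aligner and the methylation caller.

#' Simulate a random genome
#'
#' I.i.d. bases with the requested GC fraction; deterministic per seed.
#' The default GC of 0.42 is human-like.
#'
#' @param length total bases (single chromosome), or a named vector of
#'   chromosome lengths.
#' @param gc_fraction P(G) + P(C) (default 0.42).
#' @param seed RNG seed.
#' @return a [reference_genome()].
#' @export
simulate_genome <- function(length, gc_fraction = 0.42, seed = 1L) {
  set.seed(seed)
  if (is.null(names(length)))
    names(length) <- if (base::length(length) == 1L) "chr1"
      else paste0("chr", seq_along(length))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(length, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
    character(1))
  reference_genome(seqs)
}

#' Simulate a methylome
#'
#' Every cytosine (both strands) is independently methylated with its
#' context's probability.  Defaults emulate a mammalian methylome: CpG
#' sites mostly methylated, non-CpG methylation rare.
#'
#' @param genome a [reference_genome()].
#' @param p_cpg,p_chg,p_chh per-context methylation probabilities
#'   (defaults 0.8, 0.02, 0.02).
#' @param seed RNG seed.
#' @return data.table with `chrom`, `pos`, `strand`, `context`,
#'   `methylated` (logical) for every cytosine.
#' @export
simulate_methylome <- function(genome, p_cpg = 0.8, p_chg = 0.02,
                               p_chh = 0.02, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (ch in genome$chrom_names) {
    b <- strsplit(genome$sequences[[ch]], "", fixed = TRUE)[[1]]
    posC <- which(b == "C") - 1L
    posG <- which(b == "G") - 1L
    sites <- data.table::data.table(
      chrom = ch,
      pos = c(posC, posG),
      strand = rep(c("+", "-"), c(length(posC), length(posG))))
    sites$context <- assign_context(genome, sites$chrom, sites$pos,
                                    sites$strand)
    out[[ch]] <- sites
  }
  res <- data.table::rbindlist(out)
  p <- c(CpG = p_cpg, CHG = p_chg, CHH = p_chh)[res$context]
  res$methylated <- stats::runif(nrow(res)) < p
  data.table::setorder(res, chrom, pos, strand)
  res[]
}

# per-chromosome lookup vectors: is this position a methylated cytosine of
# the given strand?
.meth_lookup <- function(genome, methylome) {
  out <- list()
  for (ch in genome$chrom_names) {
    L <- genome$lengths[[ch]]
    mp <- logical(L); mm <- logical(L)
    sub <- methylome[methylome$chrom == ch, ]
    mp[sub$pos[sub$strand == "+" & sub$methylated] + 1L] <- TRUE
    mm[sub$pos[sub$strand == "-" & sub$methylated] + 1L] <- TRUE
    out[[ch]] <- list(plus = mp, minus = mm)
  }
  out
}

# build one ref-forward read: emitted genome positions, with indels
# returns list(bases, refpos (0-based, NA for insertions), indels df)
.sim_skeleton <- function(chars, g0, read_len, events) {
  bases <- character(read_len)
  refpos <- integer(read_len)
  rpos <- 0L; gpos <- g0
  ev_i <- 1L
  indels <- list()
  while (rpos < read_len) {
    if (ev_i <= nrow(events) && events$offset[ev_i] == rpos) {
      if (events$ins[ev_i] == 1L) {
        ln <- min(events$len[ev_i], read_len - rpos)
        bases[rpos + seq_len(ln)] <- sample(c("A", "C", "G", "T"), ln,
                                            replace = TRUE)
        refpos[rpos + seq_len(ln)] <- NA_integer_
        indels[[length(indels) + 1L]] <- c(rpos, ln, 1L)
        rpos <- rpos + ln
      } else {
        gpos <- gpos + events$len[ev_i]
        indels[[length(indels) + 1L]] <- c(rpos, events$len[ev_i], 0L)
      }
      ev_i <- ev_i + 1L
    } else {
      bases[rpos + 1L] <- chars[gpos + 1L]
      refpos[rpos + 1L] <- gpos
      rpos <- rpos + 1L; gpos <- gpos + 1L
    }
  }
  ind <- if (length(indels))
    data.frame(offset = as.integer(vapply(indels, `[`, 0, 1)),
               len = as.integer(vapply(indels, `[`, 0, 2)),
               ins = as.integer(vapply(indels, `[`, 0, 3)))
  else data.frame(offset = integer(0), len = integer(0), ins = integer(0))
  list(bases = bases, refpos = refpos, indels = ind, ref_end = gpos)
}

.indel_string <- function(ind) {
  if (nrow(ind) == 0L) return("")
  paste(sprintf("%d:%d:%s", ind$offset, ind$len,
                ifelse(ind$ins == 1L, "I", "D")), collapse = ";")
}

#' Parse a truth indel string back into a data.frame
#' @param s string like `"12:3:D;40:1:I"` (offset:length:type).
#' @export
parse_indel_string <- function(s) {
  if (is.na(s) || s == "")
    return(data.frame(offset = integer(0), len = integer(0), ins = integer(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(offset = vapply(parts, function(x) as.integer(x[1]), 0L),
             len = vapply(parts, function(x) as.integer(x[2]), 0L),
             ins = vapply(parts, function(x) as.integer(x[3] == "I"), 0L))
}

#' Simulate bisulfite reads with known truth
#'
#' Reads are drawn from uniform random loci and strands of a directional
#' library.  On the read's bisulfite strand every unmethylated cytosine
#' converts to T with probability `conversion_rate`; methylated cytosines
#' never convert.  Substitution errors are injected per base at
#' `error_rate`, capped at `max_errors` per read (mirroring simulations
#' that allow a 1 percent error rate with at most two mismatches per
#' read); indels start per base at `indel_rate` with length uniform on
#' 1..`max_indel_len`.  Paired mode draws the insert from
#' Normal(`insert_mean`, `insert_mean`/10), truncated to at least
#' `read_len`.
#'
#' @param genome a [reference_genome()].
#' @param methylome a [simulate_methylome()] table.
#' @param n_reads number of reads (or pairs).
#' @param read_len read length (default 100).
#' @param paired simulate read pairs (default FALSE).
#' @param insert_mean mean outer insert size for pairs (default 500).
#' @param conversion_rate probability an unmethylated C reads as T
#'   (default 0.99; a realistic conversion efficiency).
#' @param error_rate per-base substitution error rate (default 0.01).
#' @param indel_rate per-base indel initiation rate (default 3e-4).
#' @param max_indel_len maximum indel length (default 3).
#' @param max_errors substitution cap per read (default 2; `Inf` uncaps).
#' @param force_indel if TRUE every read carries exactly one indel with
#'   length uniform on 1..`max_indel_len` at a read offset uniform on
#'   `[10, read_len - 10]` (indels closer to a read end than 10 bp leave
#'   too little anchor to be detectable even in principle).
#' @param base_qual constant Phred quality of simulated bases (default 30).
#' @param seed RNG seed.
#' @return list(`reads` (data.frame id/seq/qual; for pairs `reads1` and
#'   `reads2`), `truth` (data.frame: `read_id`, `chrom`, `true_start`,
#'   `strand`, `bs`, `indels`, `n_errors`, `n_meth_c`)).  Truth indel
#'   offsets are in reference-forward read coordinates, matching SAM CIGAR.
#' @export
simulate_reads <- function(genome, methylome, n_reads, read_len = 100L,
                           paired = FALSE, insert_mean = 500L,
                           conversion_rate = 0.99, error_rate = 0.01,
                           indel_rate = 3e-4, max_indel_len = 3L,
                           max_errors = 2L, force_indel = FALSE,
                           base_qual = 30L, seed = 1L) {
  set.seed(seed)
  if (read_len > min(genome$lengths)) stop("read_len exceeds genome length")
  if (paired && read_len > insert_mean) stop("read_len exceeds insert_mean")
  lk <- .meth_lookup(genome, methylome)
  chars_by_ch <- lapply(genome$sequences, function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  qual_str <- strrep(intToUtf8(base_qual + 33L), read_len)
  margin <- max_indel_len * 4L + 4L

  draw_events <- function() {
    if (force_indel) {
      off <- sample(10:(read_len - 10L), 1L)
      data.frame(offset = off, len = sample.int(max_indel_len, 1L),
                 ins = sample(0:1, 1L))
    } else {
      hit <- which(stats::runif(read_len - 2L) < indel_rate) # offsets 1..L-2
      if (length(hit) == 0L)
        return(data.frame(offset = integer(0), len = integer(0),
                          ins = integer(0)))
      data.frame(offset = hit,
                 len = sample.int(max_indel_len, length(hit), replace = TRUE),
                 ins = sample(0:1, length(hit), replace = TRUE))
    }
  }

  # one ref-forward converted read in space ("C2T" plus / "G2A" minus)
  build <- function(ch, g0, space) {
    sk <- .sim_skeleton(chars_by_ch[[ch]], g0, read_len, draw_events())
    bases <- sk$bases
    real <- !is.na(sk$refpos)
    if (space == "C2T") {
      isC <- real & bases == "C"
      meth <- isC & lk[[ch]]$plus[sk$refpos + 1L]
      conv <- isC & !meth & stats::runif(read_len) < conversion_rate
      bases[conv] <- "T"
      nm <- sum(meth[isC])
    } else {
      isG <- real & bases == "G"   # bottom-strand cytosine, ref-forward G
      meth <- isG & lk[[ch]]$minus[sk$refpos + 1L]
      conv <- isG & !meth & stats::runif(read_len) < conversion_rate
      bases[conv] <- "A"
      nm <- sum(meth[isG])
    }
    # substitution errors (after conversion), capped
    err <- which(stats::runif(read_len) < error_rate)
    if (length(err) > max_errors) err <- sort(sample(err, max_errors))
    for (e in err) {
      bases[e] <- sample(setdiff(c("A", "C", "G", "T"), bases[e]), 1L)
    }
    list(bases = bases, indels = sk$indels, n_errors = length(err),
         n_meth = nm, ref_end = sk$ref_end)
  }

  chrom_prob <- genome$lengths / sum(genome$lengths)
  ids <- sprintf("simr%06d", seq_len(n_reads))
  if (!paired) {
    seqs <- character(n_reads); truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      ch <- sample(genome$chrom_names, 1L, prob = chrom_prob)
      g0 <- sample.int(genome$lengths[[ch]] - read_len - margin, 1L) - 1L
      minus <- stats::runif(1) < 0.5
      space <- if (minus) "G2A" else "C2T"
      b <- build(ch, g0, space)
      seqs[i] <- paste(b$bases, collapse = "")
      if (minus) seqs[i] <- revcomp(seqs[i])
      truth[[i]] <- data.frame(
        read_id = ids[i], chrom = ch, true_start = g0,
        strand = if (minus) "-" else "+", bs = space,
        indels = .indel_string(b$indels), n_errors = b$n_errors,
        n_meth_c = b$n_meth, stringsAsFactors = FALSE)
    }
    return(list(reads = data.frame(id = ids, seq = seqs, qual = qual_str,
                                   stringsAsFactors = FALSE),
                truth = do.call(rbind, truth)))
  }
  # paired mode: fragment of length ~insert_mean, directional protocol
  s1 <- character(n_reads); s2 <- character(n_reads)
  truth <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    ch <- sample(genome$chrom_names, 1L, prob = chrom_prob)
    ins <- round(stats::rnorm(1, insert_mean, insert_mean / 10))
    ins <- max(read_len, min(ins, genome$lengths[[ch]] - margin - 1L))
    g0 <- sample.int(genome$lengths[[ch]] - ins - margin, 1L) - 1L
    minus <- stats::runif(1) < 0.5
    space <- if (minus) "G2A" else "C2T"
    gL <- g0; gR <- g0 + ins - read_len
    bL <- build(ch, gL, space)
    bR <- build(ch, gR, space)
    sL <- paste(bL$bases, collapse = ""); sR <- paste(bR$bases, collapse = "")
    if (!minus) { s1[i] <- sL; s2[i] <- revcomp(sR) }
    else        { s1[i] <- revcomp(sR); s2[i] <- sL }
    truth[[i]] <- data.frame(
      read_id = rep(ids[i], 2L), mate = 1:2, chrom = ch,
      true_start = if (!minus) c(gL, gR) else c(gR, gL),
      strand = if (!minus) c("+", "-") else c("-", "+"),
      bs = space,
      indels = if (!minus) c(.indel_string(bL$indels), .indel_string(bR$indels))
               else c(.indel_string(bR$indels), .indel_string(bL$indels)),
      n_errors = if (!minus) c(bL$n_errors, bR$n_errors)
                 else c(bR$n_errors, bL$n_errors),
      n_meth_c = if (!minus) c(bL$n_meth, bR$n_meth)
                 else c(bR$n_meth, bL$n_meth),
      stringsAsFactors = FALSE)
  }
  list(reads1 = data.frame(id = paste0(ids, "/1"), seq = s1, qual = qual_str,
                           stringsAsFactors = FALSE),
       reads2 = data.frame(id = paste0(ids, "/2"), seq = s2, qual = qual_str,
                           stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}
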