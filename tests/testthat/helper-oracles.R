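# Independent oracles and fixture builders shared across the suite.
# Each oracle is a deliberately naive re-derivation (exhaustive DP,
# enumeration, quadratic scans) kept free of the code paths it checks.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

enc <- function(s) {
  v <- utf8ToInt(s)
  out <- rep(4L, length(v))
  out[v == 65L] <- 0L; out[v == 67L] <- 1L
  out[v == 71L] <- 2L; out[v == 84L] <- 3L
  out
}

# exhaustive (unbanded) affine-gap DP: global in the read, free start/end in
# the window; match +Q, mismatch -Q, first gap base -(open+ext), then -ext.
# bs_mode: 0 exact, 1 C2T (ref C ~ read T), 2 G2A (ref G ~ read A).
oracle_affine_score <- function(read, quals, win, gap_open = 40,
                                gap_extend = 6, bs_mode = 0) {
  rb <- enc(read); wb <- enc(win)
  m <- length(rb); w <- length(wb)
  NEG <- -1e15
  open1 <- -(gap_open + gap_extend); ext <- -gap_extend
  H <- matrix(NEG, m + 1, w + 1); E <- matrix(NEG, m + 1, w + 1)
  F <- matrix(NEG, m + 1, w + 1)
  H[1, ] <- 0
  for (i in 1:m) {
    F[i + 1, 1] <- if (i == 1) open1 else F[i, 1] + ext
    H[i + 1, 1] <- F[i + 1, 1]
    for (j in 1:w) {
      ok <- rb[i] < 4 && wb[j] < 4 &&
        (rb[i] == wb[j] ||
           (bs_mode == 1 && wb[j] == 1 && rb[i] == 3) ||
           (bs_mode == 2 && wb[j] == 2 && rb[i] == 0))
      sub <- if (ok) quals[i] else -quals[i]
      E[i + 1, j + 1] <- max(H[i + 1, j] + open1, E[i + 1, j] + ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] + open1, F[i, j + 1] + ext)
      H[i + 1, j + 1] <- max(H[i, j] + sub, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  max(H[m + 1, ])
}

# brute-force two-sided Fisher p by hypergeometric enumeration (log pmf
# from lchoose; no dhyper)
oracle_fisher <- function(c1, t1, c2, t2) {
  m <- c1 + t1; n <- c2 + t2; k <- c1 + c2
  if (m == 0 || n == 0 || k == 0 || (t1 + t2) == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[supp == c1]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# all positions (0-based) of pattern in text by naive scan
oracle_positions <- function(pattern, text) {
  L <- nchar(pattern); n <- nchar(text)
  if (L > n) return(integer(0))
  hits <- integer(0)
  for (i in 0:(n - L))
    if (substr(text, i + 1, i + L) == pattern &&
        !grepl("N", substr(text, i + 1, i + L), fixed = TRUE))
      hits <- c(hits, i)
  hits
}

# quadratic per-site interval overlap counts per feature class
oracle_annotate <- function(sites, features) {
  classes <- unique(features$label)
  counts <- sapply(classes, function(cl) {
    ff <- features[features$label == cl, , drop = FALSE]
    sum(vapply(seq_len(nrow(sites)), function(i) {
      any(ff$chrom == sites$chrom[i] & ff$start <= sites$pos[i] &
            sites$pos[i] < ff$end)
    }, logical(1)))
  })
  data.frame(label = classes, count = as.integer(counts),
             proportion = counts / nrow(sites), row.names = NULL)
}

# a tiny single-chromosome genome plus its index
make_toy <- function(len = 6000, seed = 42, gc = 0.5, k = 12L) {
  set.seed(seed)
  g <- reference_genome(c(chrT = rand_dna(len, gc)))
  list(genome = g, index = build_index(convert_genome(g), k))
}

# hand-built SAM-style alignment record (0-based pos)
sam_rec <- function(qname, chrom, pos, seq, cigar, flag = 0L, mapq = 60L,
                    qual = strrep("?", nchar(seq)), nm = 0L, as = 0,
                    xb = "C2T") {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = -1L,
             tlen = 0L, seq = seq, qual = qual, nm = nm, as = as, xb = xb,
             stringsAsFactors = FALSE)
}
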