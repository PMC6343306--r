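Q30 <- function(n) rep(30L, n)

test_that("convert_read produces the protocol's conversion spaces", {
  expect_identical(convert_read("ACGT")[[1]]$query, "ATGT")
  expect_identical(convert_read("AAAA")[[1]]$query, "AAAA")
  expect_identical(convert_read("AAAA")[[2]]$query, "TTTT")
  # reverse complement then convert: revcomp("ACGT") = "ACGT",
  # G->A of that = "ACAT" searched on the g2a view
  t2 <- convert_read("ACGT")[[2]]
  expect_identical(t2$query, "ACAT")
  expect_identical(t2$view, "g2a")
  expect_identical(t2$strand, "-")
  expect_length(convert_read("ACGT", "directional"), 2L)
  expect_length(convert_read("ACGT", "non_directional"), 4L)
  expect_error(convert_read(""), "empty")
})

test_that("seed_align finds exact, mismatched and gapped seeds with stated costs", {
  toy <- make_toy(len = 6000, seed = 101)
  view <- unname(toy$index$pair$c2t_view[[1]])
  P <- 1000L
  seed <- substr(view, P + 1, P + 75)
  h <- seed_align(seed, toy$index, "c2t")
  expect_identical(h$start[1], P)
  expect_identical(h$cost[1], 0)
  # 3 mismatches + one 2-base deletion -> cost 4.5 (gap = 1.5 mismatches)
  raw <- substr(view, P + 1, P + 77)
  delq <- paste0(substr(raw, 1, 40), substr(raw, 43, 77))   # drop 2 ref bases
  mut <- function(s, i) {
    cur <- substr(s, i, i)
    repl <- setdiff(c("A", "G", "T"), cur)[1]   # stay in converted space
    paste0(substr(s, 1, i - 1), repl, substr(s, i + 1, nchar(s)))
  }
  q <- mut(mut(mut(delq, 5), 20), 60)
  h <- seed_align(q, toy$index, "c2t")
  expect_identical(h$start[1], P)
  expect_identical(h$cost[1], 4.5)
  expect_identical(h$gap_type[1], 2L)  # deletion
  expect_identical(h$gap_len[1], 2L)
  # 6 substitutions exceed the budget -> no hit at that locus
  q6 <- Reduce(mut, c(5L, 18L, 31L, 44L, 57L, 70L), accumulate = FALSE,
               init = substr(view, P + 1, P + 75))
  h6 <- seed_align(q6, toy$index, "c2t")
  expect_false(any(h6$start == P))
  # random query absent from the genome -> empty
  set.seed(5)
  expect_identical(nrow(seed_align(strrep("GATTACA", 11), toy$index, "c2t")), 0L)
})

test_that("multi_seed recovers long reads whose first seed is destroyed", {
  toy <- make_toy(len = 9000, seed = 102)
  view <- unname(toy$index$pair$c2t_view[[1]])
  P <- 3000L
  q <- substr(view, P + 1, P + 160)
  mut <- function(s, i) {
    repl <- setdiff(c("A", "G", "T"), substr(s, i, i))[1]
    paste0(substr(s, 1, i - 1), repl, substr(s, i + 1, nchar(s)))
  }
  # both windows clean: one merged candidate at the true start
  h <- multi_seed(q, toy$index, "c2t")
  expect_identical(h$start[1], P)
  expect_identical(nrow(h[h$chrom_id == 1 & abs(h$start - P) < 5, ]), 1L)
  # destroy the first 75 bp window with 6 spread substitutions
  qq <- Reduce(mut, c(5L, 18L, 31L, 44L, 57L, 70L), init = q)
  h2 <- multi_seed(qq, toy$index, "c2t")
  expect_true(any(h2$start == P))
  # a 150-bp read has a single seed: the same damage leaves no full hit
  q150 <- Reduce(mut, c(5L, 18L, 31L, 44L, 57L, 70L),
                 init = substr(view, P + 1, P + 150))
  expect_false(any(seed_align(q150, toy$index, "c2t")$start == P))
})

test_that("extend_hit reproduces the worked affine-gap scores", {
  toy <- make_toy(len = 3000, seed = 103)
  src <- unname(toy$genome$sequences[[1]])
  P <- 500L
  hit <- list(chrom_id = 1L, start = P, ngap = 0L)
  pars <- align_params()
  # exact 75-mer, Q30: 75M, score 2250, no mismatch (exact-space mode 0)
  r <- substr(src, P + 1, P + 75)
  a <- extend_hit(hit, enc(r), Q30(75), toy$index, 0L, pars, clip = FALSE)
  expect_identical(a$cigar, "75M")
  expect_identical(a$score, 2250)
  expect_identical(a$n_mismatch, 0L)
  # one reference base deleted: 74 read bases over 75 reference bases,
  # score 74*30 - (40 + 6) = 2174, CIGAR contains 1D
  rdel <- paste0(substr(src, P + 1, P + 30), substr(src, P + 32, P + 75))
  a <- extend_hit(hit, enc(rdel), Q30(74), toy$index, 0L, pars, clip = FALSE)
  expect_match(a$cigar, "1D")
  expect_identical(a$score, 2174)
})

test_that("bisulfite matching is asymmetric in C2T space", {
  g <- reference_genome(c(c1 = paste0(strrep("ATGGATTGAG", 3), "ACGTACCTAG",
                                      strrep("TTGGATAGAT", 3))))
  idx <- build_index(convert_genome(g), 12L)
  pars <- align_params()
  hit <- list(chrom_id = 1L, start = 30L, ngap = 0L)
  ref10 <- "ACGTACCTAG"
  # read T over the reference C at offset 5 (C->T conversion): match
  conv <- sub("ACGTAC", "ACGTAT", ref10)
  a <- extend_hit(hit, enc(conv), Q30(10), idx, 1L, pars, clip = FALSE)
  expect_identical(a$score, 300)
  expect_identical(a$n_mismatch, 0L)
  # read C over a reference T: mismatch (the asymmetric direction)
  mis <- sub("ACGTACCTAG", "ACGCACCTAG", ref10)
  a <- extend_hit(hit, enc(mis), Q30(10), idx, 1L, pars, clip = FALSE)
  expect_identical(a$score, 240)   # 9*30 - 30
  expect_identical(a$n_mismatch, 1L)
})

test_that("extend_hit equals the exhaustive affine DP oracle on random instances", {
  set.seed(201)
  pars <- align_params(band = 70L)
  for (trial in 1:100) {
    m <- sample(5:30, 1); w <- sample(m:60, 1)
    read <- rand_dna(m); win <- rand_dna(w)
    quals <- sample(2:40, m, replace = TRUE)
    bs <- sample(0:2, 1)
    g <- reference_genome(c(c1 = win))
    idx <- suppressWarnings(tryCatch(build_index(convert_genome(g), 12L),
                                     error = function(e) NULL))
    if (is.null(idx)) next  # window shorter than the index k-mer
    a <- extend_hit(list(chrom_id = 1L, start = 0L, ngap = 0L),
                    enc(read), quals, idx, bs, pars, clip = FALSE)
    expect_identical(a$score, oracle_affine_score(read, quals, win,
                                                  bs_mode = bs))
  }
})

test_that("the indel gate skips gapped DP below threshold and opens above", {
  toy <- make_toy(len = 4000, seed = 104)
  src <- unname(toy$genome$sequences[[1]])
  P <- 800L
  pars <- align_params()
  hit <- list(chrom_id = 1L, start = P, ngap = 0L)
  mut <- function(s, i) {
    repl <- setdiff(c("A", "C", "G", "T"), substr(s, i, i))[1]
    paste0(substr(s, 1, i - 1), repl, substr(s, i + 1, nchar(s)))
  }
  # 1 mismatch < threshold 2: ungapped returned unchanged, no DP
  r1 <- mut(substr(src, P + 1, P + 80), 40)
  a <- gate_indel(hit, enc(r1), Q30(80), toy$index, 0L, pars)
  expect_identical(a$cigar, "80M")
  expect_false(a$gapped)
  # deletion read: no acceptable ungapped alignment -> gapped result
  rdel <- paste0(substr(src, P + 1, P + 40), substr(src, P + 44, P + 83))
  a <- gate_indel(hit, enc(rdel), Q30(80), toy$index, 0L, pars)
  expect_true(a$gapped)
  expect_match(a$cigar, "3D")
  # indels disabled: the same read gets a clipped ungapped alignment
  a <- gate_indel(hit, enc(rdel), Q30(80), toy$index, 0L,
                  align_params(indels = FALSE))
  expect_false(grepl("[ID]", a$cigar))
})

test_that("soft-clipped segments over 20 bp are realigned as auxiliary hits", {
  # explicit construction: locus A is followed by poly-A, and locus B
  # contains no A, so no shifted diagonal can rescue the chimeric tail and
  # clipping it is provably optimal
  set.seed(105)
  locusB <- paste(sample(c("C", "G", "T"), 30, replace = TRUE), collapse = "")
  src <- paste0(rand_dna(1000), rand_dna(60), strrep("A", 80),
                rand_dna(3860), locusB, rand_dna(2970))
  toy <- list(genome = reference_genome(c(chrT = src)))
  toy$index <- build_index(convert_genome(toy$genome), 12L)
  A <- 1000L; B <- 5000L
  stopifnot(substr(src, B + 1, B + 30) == locusB)
  chim <- paste0(substr(src, A + 1, A + 60), locusB)
  reads <- data.frame(id = "chim1", seq = chim, qual = strrep("?", 90))
  aln <- align_reads(reads, toy$index)
  prim <- aln[!bitwAnd(aln$flag, 2048L), ]
  aux <- aln[bitwAnd(aln$flag, 2048L) > 0, ]
  expect_identical(prim$pos, A)
  expect_identical(prim$cigar, "60M30S")
  expect_identical(nrow(aux), 1L)
  expect_identical(aux$pos, B)
  expect_identical(aux$cigar, "60S30M")
  # a 15-bp clip is below the realignment threshold: no auxiliary record
  chim15 <- paste0(substr(src, A + 1, A + 75), substr(src, B + 1, B + 15))
  aln15 <- align_reads(data.frame(id = "chim2", seq = chim15,
                                  qual = strrep("?", 90)), toy$index)
  expect_false(any(bitwAnd(aln15$flag, 2048L) > 0))
  # fully matching read: no clips, no auxiliary record
  full <- align_reads(data.frame(id = "full", seq = substr(src, A + 1, A + 90),
                                 qual = strrep("?", 90)), toy$index)
  expect_identical(full$cigar, "90M")
})

test_that("compute_mapq follows the decision rule and is monotone", {
  expect_identical(compute_mapq(1000, NULL), 60L)
  expect_identical(compute_mapq(1000, 1000), 0L)
  expect_identical(compute_mapq(1000, 1200), 0L)
  set.seed(31)
  for (i in 1:200) {
    s1 <- runif(1, 500, 3000)
    g1 <- runif(1, 0, s1); g2 <- runif(1, 0, g1)   # gap g1 >= gap g2
    expect_gte(compute_mapq(s1, s1 - g1), compute_mapq(s1, s1 - g2))
  }
})

test_that("deep_scan_pair prefers the jointly best proper pair", {
  mk <- function(pos, strand, score, chrom_id = 1L)
    data.frame(chrom = "c1", chrom_id = chrom_id, pos = pos, strand = strand,
               cigar = "80M", score = score, stringsAsFactors = FALSE)
  # unique proper hits
  pr <- deep_scan_pair(mk(1000, "+", 2000), mk(1300, "-", 2000))
  expect_true(pr$proper)
  expect_identical(pr$insert, 380L)
  # mate1's individually best hit is 3 Mb away; its second-best (one more
  # mismatch, lower score) is 300 bp from mate2 -> second-best chosen
  h1 <- rbind(mk(3e6, "+", 2000), mk(1000, "+", 1940))
  pr <- deep_scan_pair(h1, mk(1300, "-", 2000))
  expect_true(pr$proper)
  expect_identical(pr$a1$pos, 1000)
  # no hits within the insert limit -> improper pair of individual bests
  pr <- deep_scan_pair(mk(1000, "+", 2000), mk(9000, "-", 2000))
  expect_false(pr$proper)
  expect_identical(pr$a1$pos, 1000)
  # one mate unaligned
  pr <- deep_scan_pair(mk(1000, "+", 2000), NULL)
  expect_false(pr$proper)
  expect_null(pr$a2)
  # same strand is never proper
  pr <- deep_scan_pair(mk(1000, "+", 2000), mk(1300, "+", 2000))
  expect_false(pr$proper)
})

test_that("alignment output satisfies CIGAR conservation and determinism", {
  toy <- make_toy(len = 20000, seed = 106)
  me <- simulate_methylome(toy$genome, seed = 107)
  sim <- simulate_reads(toy$genome, me, n_reads = 60, read_len = 100,
                        conversion_rate = 0.5, error_rate = 0.01,
                        indel_rate = 0.005, seed = 108)
  aln <- align_reads(sim$reads, toy$index)
  mapped <- aln[!bitwAnd(aln$flag, 4L), ]
  for (i in seq_len(nrow(mapped)))
    expect_identical(cigar_read_len(mapped$cigar[i]), nchar(mapped$seq[i]))
  # byte-identical SAM on a rerun
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(aln, toy$genome, f1)
  write_sam(align_reads(sim$reads, toy$index), toy$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a pure-N read is unmapped
  alnN <- align_reads(data.frame(id = "nn", seq = strrep("N", 80),
                                 qual = strrep("?", 80)), toy$index)
  expect_identical(alnN$flag, 4L)
})

test_that("enabling indel detection never lowers a read's score", {
  toy <- make_toy(len = 15000, seed = 109)
  me <- simulate_methylome(toy$genome, seed = 110)
  sim <- simulate_reads(toy$genome, me, n_reads = 40, read_len = 100,
                        conversion_rate = 0.5, error_rate = 0.01,
                        indel_rate = 0.01, seed = 111)
  a_with <- align_reads(sim$reads, toy$index, align_params(indels = TRUE))
  a_without <- align_reads(sim$reads, toy$index, align_params(indels = FALSE))
  pw <- a_with[!bitwAnd(a_with$flag, 2048L), ]
  po <- a_without[!bitwAnd(a_without$flag, 2048L), ]
  s_with <- ifelse(is.na(pw$as), -Inf, pw$as)
  s_without <- ifelse(is.na(po$as[match(pw$qname, po$qname)]), -Inf,
                      po$as[match(pw$qname, po$qname)])
  expect_true(all(s_with >= s_without))
})

test_that("align_pairs reports proper FR pairs with consistent mate fields", {
  toy <- make_toy(len = 12000, seed = 112)
  me <- simulate_methylome(toy$genome, seed = 113)
  sim <- simulate_reads(toy$genome, me, n_reads = 15, read_len = 80,
                        paired = TRUE, insert_mean = 300, seed = 114)
  aln <- align_pairs(sim$reads1, sim$reads2, toy$index)
  expect_identical(nrow(aln), 30L)
  expect_true(all(bitwAnd(aln$flag, 1L) > 0))
  proper <- aln[bitwAnd(aln$flag, 2L) > 0, ]
  expect_gt(nrow(proper), 24L)
  m1 <- proper[bitwAnd(proper$flag, 64L) > 0, ]
  m2 <- proper[bitwAnd(proper$flag, 128L) > 0, ]
  ix <- match(m1$qname, m2$qname)
  expect_true(all(abs(m1$tlen) <= 500))
  expect_identical(m1$tlen, -m2$tlen[ix])
  expect_identical(m1$pnext, m2$pos[ix])
  ev <- evaluate_alignments(sim$truth[sim$truth$mate == 1, ],
                            aln[bitwAnd(aln$flag, 64L) > 0, ])
  expect_gte(ev$n_correct / ev$n_reads, 0.9)
})
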