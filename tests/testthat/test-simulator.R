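test_that("simulate_genome is seed-deterministic with the requested composition", {
  g1 <- simulate_genome(1000, seed = 5)
  g2 <- simulate_genome(1000, seed = 5)
  expect_identical(g1$sequences, g2$sequences)
  gAT <- simulate_genome(2000, gc_fraction = 0, seed = 6)
  expect_false(grepl("[CG]", gAT$sequences[[1]]))
  g <- simulate_genome(100000, gc_fraction = 0.5, seed = 7)
  gc <- sum(strsplit(g$sequences[[1]], "")[[1]] %in% c("C", "G")) / 1e5
  expect_lte(abs(gc - 0.5), 0.01)
  gm <- simulate_genome(c(a = 500, b = 700), seed = 8)
  expect_identical(unname(gm$lengths), c(500L, 700L))
})

test_that("simulate_methylome respects the per-context probabilities", {
  g <- simulate_genome(3000, seed = 9)
  all1 <- simulate_methylome(g, 1, 1, 1, seed = 10)
  expect_true(all(all1$methylated))
  none <- simulate_methylome(g, 0, 0, 0, seed = 10)
  expect_false(any(none$methylated))
  # every cytosine on both strands appears exactly once
  b <- strsplit(g$sequences[[1]], "")[[1]]
  expect_identical(nrow(none), sum(b == "C") + sum(b == "G"))
  big <- simulate_genome(60000, gc_fraction = 0.55, seed = 11)
  me <- simulate_methylome(big, p_cpg = 0.8, seed = 12)
  cpg <- me[me$context == "CpG", ]
  expect_gt(nrow(cpg), 5000)
  expect_lte(abs(mean(cpg$methylated) - 0.8), 0.02)
})

test_that("simulated reads honour conversion, error and indel settings", {
  g <- simulate_genome(5000, seed = 13)
  me0 <- simulate_methylome(g, 0, 0, 0, seed = 14)
  # no conversion, no errors, no indels: exact genome substrings
  clean <- simulate_reads(g, me0, 30, read_len = 60, conversion_rate = 0,
                          error_rate = 0, indel_rate = 0, seed = 15)
  src <- g$sequences[[1]]
  for (i in 1:30) {
    t <- clean$truth[i, ]
    want <- substr(src, t$true_start + 1, t$true_start + 60)
    got <- if (t$strand == "-") revcomp(clean$reads$seq[i]) else
      clean$reads$seq[i]
    expect_identical(got, want)
  }
  # full conversion of an unmethylated genome: no C on the bisulfite strand
  conv <- simulate_reads(g, me0, 30, read_len = 60, conversion_rate = 1,
                         error_rate = 0, indel_rate = 0, seed = 16)
  fwd <- ifelse(conv$truth$strand == "-", revcomp(conv$reads$seq),
                conv$reads$seq)
  expect_false(any(grepl("C", fwd[conv$truth$strand == "+"])))
  expect_false(any(grepl("G", fwd[conv$truth$strand == "-"])))
  # conversion fraction approaches the requested rate
  half <- simulate_reads(g, me0, 800, read_len = 60, conversion_rate = 0.5,
                         error_rate = 0, indel_rate = 0, seed = 17)
  fwd <- ifelse(half$truth$strand == "-", revcomp(half$reads$seq),
                half$reads$seq)
  nC <- nT <- 0L
  for (i in seq_len(800)) {
    t <- half$truth[i, ]
    ref <- strsplit(substr(src, t$true_start + 1, t$true_start + 60), "")[[1]]
    rd <- strsplit(fwd[i], "")[[1]]
    tgt <- if (t$strand == "+") "C" else "G"
    cnv <- if (t$strand == "+") "T" else "A"
    nC <- nC + sum(ref == tgt & rd == tgt)
    nT <- nT + sum(ref == tgt & rd == cnv)
  }
  expect_lte(abs(nT / (nC + nT) - 0.5), 0.02)
  # error cap: no read carries more than max_errors substitutions
  errs <- simulate_reads(g, me0, 200, read_len = 100, conversion_rate = 0,
                         error_rate = 0.05, indel_rate = 0, max_errors = 2L,
                         seed = 18)
  expect_lte(max(errs$truth$n_errors), 2L)
  expect_gt(sum(errs$truth$n_errors), 0L)
  # forced indels: exactly one per read, length within range, interior
  pl <- simulate_reads(g, me0, 50, read_len = 100, conversion_rate = 0,
                       error_rate = 0, force_indel = TRUE,
                       max_indel_len = 10L, seed = 19)
  ind <- lapply(pl$truth$indels, parse_indel_string)
  expect_true(all(vapply(ind, nrow, 0L) == 1L))
  lens <- vapply(ind, function(x) x$len, 0L)
  offs <- vapply(ind, function(x) x$offset, 0L)
  expect_true(all(lens >= 1L & lens <= 10L))
  expect_true(all(offs >= 10L & offs <= 90L))
  # determinism
  a <- simulate_reads(g, me0, 20, seed = 20)
  b <- simulate_reads(g, me0, 20, seed = 20)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("evaluate_alignments applies the three criteria in order", {
  truth <- data.frame(read_id = paste0("r", 1:7), chrom = "c1",
                      true_start = 1000L,
                      strand = c("+", "+", "+", "+", "-", "+", "+"),
                      bs = "C2T",
                      indels = c("", "", "", "", "", "20:2:D", ""),
                      n_errors = 0L, n_meth_c = 0L,
                      stringsAsFactors = FALSE)
  seq60 <- strrep("A", 60)
  aln <- rbind(
    sam_rec("r1", "c1", 1000L, seq60, "60M"),                  # exact
    sam_rec("r2", "c1", 1010L, seq60, "60M"),                  # 10 bp off: ok
    sam_rec("r3", "c1", 1011L, seq60, "60M"),                  # 11 bp: wrong
    sam_rec("r4", "c1", 1000L, seq60, "60M", mapq = 0L),       # ambiguous
    sam_rec("r5", "c1", 1000L, seq60, "60M", flag = 0L),       # strand wrong
    sam_rec("r6", "c1", 1000L, seq60, "20M2D40M"),             # indel match
    sam_rec("r7", "c1", 1000L, seq60, "60M", flag = 4L))       # unmapped
  ev <- evaluate_alignments(truth, aln)
  expect_identical(ev$per_read$verdict,
                   c("correct", "correct", "wrong", "wrong", "wrong",
                     "correct", "unmapped"))
  expect_identical(ev$n_correct + ev$n_wrong + ev$n_unmapped, ev$n_reads)
  # indel similarity tolerances: length within 1, offset within 5
  t6 <- truth[truth$read_id == "r6", ]
  near <- sam_rec("r6", "c1", 1000L, seq60, "24M3D36M")
  expect_identical(evaluate_alignments(t6, near)$n_correct, 1L)
  far <- sam_rec("r6", "c1", 1000L, seq60, "26M2D34M")   # offset off by 6
  expect_identical(evaluate_alignments(t6, far)$n_correct, 0L)
  wrongtype <- sam_rec("r6", "c1", 1000L, seq60, "20M2I38M")
  expect_identical(evaluate_alignments(t6, wrongtype)$n_correct, 0L)
  # a called indel absent from the truth is also a violation
  t1 <- truth[truth$read_id == "r1", ]
  spurious <- sam_rec("r1", "c1", 1000L, seq60, "30M1I29M")
  expect_identical(evaluate_alignments(t1, spurious)$n_correct, 0L)
  # reported mismatches must be within tolerance of injected errors
  t1e <- transform(t1, n_errors = 0L)
  noisy <- sam_rec("r1", "c1", 1000L, seq60, "60M", nm = 3L)
  expect_identical(evaluate_alignments(t1e, noisy)$n_correct, 0L)
  expect_error(evaluate_alignments(transform(t1, read_id = "zz"), aln),
               "missing")
})

test_that("concordance_eval applies the 500-bp rule cumulatively by MAPQ", {
  mk <- function(id, pos, mapq = 60L, flag = 0L)
    sam_rec(id, "c1", pos, strrep("A", 50), "50M", flag = flag, mapq = mapq)
  a1 <- rbind(mk("p1/1", 1000L), mk("p2/1", 2000L, mapq = 30L),
              mk("p3/1", 3000L), mk("p4/1", 5000L))
  a2 <- rbind(mk("p1/2", 1300L), mk("p2/2", 2501L, mapq = 20L),
              mk("p3/2", 3400L, mapq = 10L),
              mk("p4/2", 5100L, flag = 4L))
  ce <- concordance_eval(a1, a2)
  # p1 conc @60; p2 disc (501 apart) @20; p3 conc @10; p4 half-mapped
  expect_identical(ce$n_half_mapped, 1L)
  expect_identical(ce$by_mapq$n_concordant[ce$by_mapq$mapq == 60], 1L)
  expect_identical(ce$by_mapq$n_concordant[ce$by_mapq$mapq == 10], 2L)
  expect_identical(ce$by_mapq$n_discordant[ce$by_mapq$mapq == 10], 1L)
  expect_identical(ce$by_mapq$n_discordant[ce$by_mapq$mapq == 60], 0L)
})

test_that("pipeline report aggregates stages and tolerates missing ones", {
  rep0 <- run_pipeline_report()
  expect_true(is.na(rep0$mapping) && is.na(rep0$dmc))
  aln <- rbind(sam_rec("a", "c1", 0L, "ACGT", "4M"),
               sam_rec("b", "c1", 0L, "ACGT", "4M", flag = 4L))
  path <- file.path(tempdir(), "rep")
  rep <- run_pipeline_report(n_reads = 2L, aln = aln, path = path)
  expect_equal(rep$mapping$mapping_rate, 0.5)
  expect_true(file.exists(paste0(path, ".json")))
  back <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(back$mapping$n_mapped, 1L)
})
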