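mk_rec <- function(pos, cC, cT, chrom = "c1", strand = "+", context = "CpG") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             count_C = cC, count_T = cT, stringsAsFactors = FALSE)
}

test_that("region_ml is the pooled-count statistic with coverage filter", {
  rec <- mk_rec(c(10L, 20L), c(3L, 1L), c(1L, 3L))
  expect_equal(region_ml(rec, "c1", 0L, 100L, 0L), 50.0)
  expect_equal(region_ml(mk_rec(5L, 5L, 0L), "c1", 0L, 100L, 0L), 100.0)
  expect_true(is.na(region_ml(rec, "c1", 50L, 100L, 0L)))
  # strict coverage: a depth-4 site is excluded at min_cov 4
  rec2 <- mk_rec(c(10L, 20L), c(4L, 10L), c(0L, 0L))
  expect_equal(region_ml(rec2, "c1", 0L, 100L, 4L), 100.0)
  expect_equal(region_ml(rec2, "c1", 0L, 100L, 3L), 100.0)
  expect_true(is.na(region_ml(rec2, "c1", 0L, 100L, 10L)))
})

test_that("region ML of a union equals the count-weighted combination", {
  set.seed(81)
  for (i in 1:20) {
    n <- 30
    rec <- mk_rec(sort(sample(0:999, n)), sample(0:20, n, TRUE),
                  sample(0:20, n, TRUE))
    rec <- rec[rec$count_C + rec$count_T > 0, ]
    whole <- region_ml(rec, "c1", 0L, 1000L, 0L)
    a <- rec[rec$pos < 500, ]; b <- rec[rec$pos >= 500, ]
    sc <- sum(rec$count_C); sn <- sum(rec$count_C + rec$count_T)
    expect_equal(whole, 100 * sc / sn)
    expect_equal(100 * (sum(a$count_C) + sum(b$count_C)) / sn, whole)
  }
})

test_that("sliding windows follow the stated start/clip arithmetic", {
  w <- sliding_windows("c1", 250000L)
  expect_identical(w$start, c(0L, 50000L, 100000L, 150000L, 200000L))
  expect_identical(w$end[5], 250000L)
  w2 <- sliding_windows("c1", 100000L)
  expect_identical(w2$start, c(0L, 50000L))
  expect_identical(w2$end, c(100000L, 100000L))
  # window == step: disjoint tiling
  w3 <- sliding_windows("c1", 1000L, window = 100L, step = 100L)
  expect_identical(w3$start, seq(0L, 900L, 100L))
  expect_true(all(w3$end - w3$start == 100L))
  # coverage: interior positions fall in exactly ceil(window/step) windows
  w4 <- sliding_windows("c1", 10000L, window = 300L, step = 100L)
  for (p in c(5000L, 7777L)) {
    n_cover <- sum(w4$start <= p & p < w4$end)
    expect_identical(n_cover, 3L)
  }
})

test_that("window_ml computes per-strand levels", {
  rec <- rbind(mk_rec(c(10L, 30L), c(8L, 0L), c(0L, 8L), strand = "+"),
               mk_rec(c(20L, 40L), c(4L, 4L), c(4L, 4L), strand = "-"))
  g <- reference_genome(c(c1 = strrep("ACGT", 25)))
  wm <- window_ml(rec, g, window = 100L, step = 100L, by_strand = TRUE)
  expect_equal(wm$ml[wm$strand == "+"], 50.0)
  expect_equal(wm$ml[wm$strand == "-"], 50.0)
})

test_that("categorize_ml partitions [0,100] with the stated boundaries", {
  expect_identical(as.character(categorize_ml(85)), "M")
  expect_identical(as.character(categorize_ml(80)), "Mh")  # M needs > 80
  expect_identical(as.character(categorize_ml(0)), "U")
  expect_identical(as.character(categorize_ml(c(100, 60.5, 60, 40.5, 40,
                                                20, 19.99))),
                   c("M", "Mh", "H", "H", "hU", "hU", "U"))
  # exhaustive partition: every value maps to exactly one category
  grid <- c(seq(0, 100, by = 0.25), 20, 40, 60, 80)
  expect_false(anyNA(categorize_ml(grid)))
  expect_error(categorize_ml(101), "within")
  expect_error(categorize_ml(-1), "within")
})

test_that("gene_profile is flat on uniform methylomes and mirrors minus genes", {
  set.seed(83)
  pos <- seq(0L, 9999L, by = 7L)
  rec <- mk_rec(pos, 1L, 1L)                       # ml = 50 everywhere
  genes <- data.frame(chrom = "c1", start = 4000L, end = 6000L,
                      strand = "+", name = "g1")
  gp <- gene_profile(genes, rec, flank = 2000L, bins = 10L)
  expect_true(all(abs(gp$profile$ml - 50) < 1e-9, na.rm = TRUE))
  # methylation only inside the body: body bins exceed flank bins
  rec2 <- rec
  rec2$count_C <- ifelse(rec2$pos >= 4000 & rec2$pos < 6000, 9L, 0L)
  rec2$count_T <- ifelse(rec2$pos >= 4000 & rec2$pos < 6000, 1L, 9L)
  gp2 <- gene_profile(genes, rec2, flank = 2000L, bins = 10L)
  body <- gp2$profile$ml[gp2$profile$segment == "body"]
  flank <- gp2$profile$ml[gp2$profile$segment != "body"]
  expect_gt(min(body, na.rm = TRUE), max(flank, na.rm = TRUE))
  # a single minus-strand gene gives the plus gene's profile mirrored
  rec3 <- rec
  rec3$count_C <- pmax(0L, as.integer(round(9 * (rec3$pos / 10000))))
  rec3$count_T <- 9L - rec3$count_C
  gplus <- gene_profile(genes, rec3, flank = 2000L, bins = 10L)
  gminus <- gene_profile(transform(genes, strand = "-"), rec3,
                         flank = 2000L, bins = 10L)
  expect_equal(unname(gminus$matrix[1, ]), unname(rev(gplus$matrix[1, ])),
               tolerance = 1e-9)
})

test_that("annotate_sites matches the quadratic overlap oracle", {
  feats <- data.frame(
    chrom = "c1",
    start = c(100L, 150L, 300L, 100L),
    end = c(200L, 180L, 400L, 200L),
    label = c("gene", "intron", "TE", "CDS"), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "c1", pos = c(160L, 350L, 50L, 199L, 200L))
  got <- annotate_sites(sites, feats)
  # site 160 is in the intron nested in the gene: counted for both
  expect_identical(got$count[got$label == "gene"], 2L)
  expect_identical(got$count[got$label == "intron"], 1L)
  # half-open ends: pos 200 is outside [100, 200)
  expect_identical(got$count[got$label == "CDS"], 2L)
  expect_equal(got$proportion[got$label == "TE"], 1 / 5)
  # all sites inside one feature
  one <- annotate_sites(data.frame(chrom = "c1", pos = c(110L, 120L)),
                        feats[1, ])
  expect_equal(one$proportion, 1.0)
  # random fixtures vs the brute-force oracle
  set.seed(84)
  for (i in 1:10) {
    nf <- 15
    st <- sample(0:900, nf, TRUE)
    rf <- data.frame(chrom = sample(c("c1", "c2"), nf, TRUE), start = st,
                     end = st + sample(10:120, nf, TRUE),
                     label = sample(c("gene", "TE", "UTR"), nf, TRUE),
                     stringsAsFactors = FALSE)
    rs <- data.frame(chrom = sample(c("c1", "c2"), 40, TRUE),
                     pos = sample(0:1000, 40, TRUE))
    got <- annotate_sites(rs, rf)
    want <- oracle_annotate(rs, rf)
    expect_equal(got[order(got$label), ], want[order(want$label), ],
                 ignore_attr = TRUE)
  }
})
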