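# Differential methylation: Fisher's exact test (no replicates), a
# beta-binomial likelihood-ratio test (replicates), window validity
# criteria, Benjamini-Hochberg FDR and the significance call combining the
# adjusted p-value with a methylation-difference threshold.

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' The p-value is the sum of hypergeometric probabilities (margins fixed)
#' of all tables at most as probable as the observed one, with a relative
#' tolerance of 1e-7 on the comparison (the standard guard against ties
#' lost to floating point).  A zero margin carries no information and
#' returns p = 1.
#'
#' @param c1,t1 methylated / unmethylated counts in sample 1.
#' @param c2,t2 counts in sample 2.
#' @return p-value in (0, 1].
#' @export
fisher_dmc <- function(c1, t1, c2, t2) {
  stopifnot(c1 >= 0, t1 >= 0, c2 >= 0, t2 >= 0)
  m <- c1 + t1; n <- c2 + t2; k <- c1 + c2
  if (m == 0 || n == 0 || k == 0 || (t1 + t2) == 0) return(1)
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(c1, m, n, k)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

# beta-binomial log-likelihood; mu = mean, phi = dispersion in (0,1)
# (a = mu(1-phi)/phi, b = (1-mu)(1-phi)/phi; phi -> 0 recovers binomial)
.bb_loglik <- function(c, n, mu, phi) {
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  sum(lchoose(n, c) + lbeta(c + a, n - c + b) - lbeta(a, b))
}

.bb_fit_mu <- function(c, n, phi) {
  # bounded one-dimensional ML for the mean at fixed dispersion
  opt <- stats::optimize(function(mu) .bb_loglik(c, n, mu, phi),
                         interval = c(1e-6, 1 - 1e-6), maximum = TRUE,
                         tol = 1e-8)
  list(mu = opt$maximum, ll = opt$objective)
}

#' Fit a beta-binomial distribution by maximum likelihood
#'
#' @param c,n methylated counts and coverages across replicates.
#' @param phi fixed dispersion; NULL (default) profiles it numerically on
#'   (1e-6, 1 - 1e-6).
#' @return list(`mu`, `phi`, `loglik`).
#' @export
betabinom_fit <- function(c, n, phi = NULL) {
  keep <- n > 0
  c <- c[keep]; n <- n[keep]
  if (length(n) == 0L) return(list(mu = NA_real_, phi = NA_real_,
                                   loglik = NA_real_))
  if (!is.null(phi)) {
    f <- .bb_fit_mu(c, n, phi)
    return(list(mu = f$mu, phi = phi, loglik = f$ll))
  }
  prof <- function(lphi) .bb_fit_mu(c, n, stats::plogis(lphi))$ll
  opt <- stats::optimize(prof, interval = stats::qlogis(c(1e-6, 1 - 1e-6)),
                         maximum = TRUE, tol = 1e-6)
  phi_hat <- stats::plogis(opt$maximum)
  f <- .bb_fit_mu(c, n, phi_hat)
  list(mu = f$mu, phi = phi_hat, loglik = f$ll)
}

#' Beta-binomial likelihood-ratio test for two groups of replicates
#'
#' Null model: one beta-binomial (mean mu, dispersion phi) for all
#' replicates.  Alternative: separate means per group with a shared
#' dispersion.  The p-value comes from the chi-square distribution with
#' one degree of freedom on twice the log-likelihood ratio.
#'
#' @param cA,nA methylated counts and coverages, group A replicates.
#' @param cB,nB group B replicates.
#' @return p-value in (0, 1], with the LRT statistic attached as
#'   attribute `"stat"`.
#' @export
betabinom_test <- function(cA, nA, cB, nB) {
  kA <- nA > 0; kB <- nB > 0
  cA <- cA[kA]; nA <- nA[kA]; cB <- cB[kB]; nB <- nB[kB]
  if (length(nA) == 0L || length(nB) == 0L)
    return(structure(1, stat = 0))
  null <- betabinom_fit(c(cA, cB), c(nA, nB))
  # alternative: shared dispersion, profiled; separate means
  prof_alt <- function(lphi) {
    phi <- stats::plogis(lphi)
    .bb_fit_mu(cA, nA, phi)$ll + .bb_fit_mu(cB, nB, phi)$ll
  }
  opt <- stats::optimize(prof_alt, interval = stats::qlogis(c(1e-6, 1 - 1e-6)),
                         maximum = TRUE, tol = 1e-6)
  stat <- max(0, 2 * (opt$objective - null$loglik))
  structure(stats::pchisq(stat, df = 1, lower.tail = FALSE), stat = stat)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: `q(i) = min over j with p(j) >= p(i) of
#' m * p(j) / rank(j)`, capped at 1; order-preserving.
#'
#' @param pvals vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
  q
}

#' Flag significant differential results
#'
#' Significant iff the adjusted p-value is strictly below `q_threshold`
#' and the absolute methylation difference (0-1 scale) is at least
#' `diff_threshold`.
#'
#' @param results data.frame with `q` and `meth_diff`.
#' @param q_threshold adjusted-p cutoff (strict, default 0.05).
#' @param diff_threshold |meth difference| cutoff (inclusive, default 0.6).
#' @return `results` with a logical `significant` column.
#' @export
call_significant <- function(results, q_threshold = 0.05,
                             diff_threshold = 0.6) {
  results$significant <- !is.na(results$q) & results$q < q_threshold &
    abs(results$meth_diff) >= diff_threshold
  results
}

# pooled per-condition counts of the valid sites in one window
.window_counts <- function(reps, chrom, start, end, context, n_min) {
  # reps: list of data.frames/data.tables with chrom,pos,strand,context,
  # count_C,count_T.  A site is valid iff total coverage across the
  # replicates considered is >= n_min.
  per_rep <- lapply(reps, function(rp) {
    sel <- rp$chrom == chrom & rp$pos >= start & rp$pos < end
    if (!is.null(context)) sel <- sel & rp$context == context
    rp[sel, , drop = FALSE]
  })
  all_sites <- unique(do.call(rbind, lapply(per_rep, function(x)
    data.frame(pos = x$pos, strand = x$strand))))
  if (nrow(all_sites) == 0L)
    return(list(n_valid = 0L, c = rep(0L, length(reps)),
                n = rep(0L, length(reps))))
  cov_tot <- rep(0L, nrow(all_sites))
  for (x in per_rep) {
    ix <- match(paste(all_sites$pos, all_sites$strand),
                paste(x$pos, x$strand))
    hit <- !is.na(ix)
    cov_tot[hit] <- cov_tot[hit] + x$count_C[ix[hit]] + x$count_T[ix[hit]]
  }
  valid <- cov_tot >= n_min
  cc <- nn <- integer(length(reps))
  for (i in seq_along(per_rep)) {
    x <- per_rep[[i]]
    ix <- match(paste(all_sites$pos[valid], all_sites$strand[valid]),
                paste(x$pos, x$strand))
    hit <- !is.na(ix)
    cc[i] <- sum(x$count_C[ix[hit]])
    nn[i] <- sum(x$count_C[ix[hit]] + x$count_T[ix[hit]])
  }
  list(n_valid = sum(valid), c = cc, n = nn)
}

#' Scan windows for differential methylation between two conditions
#'
#' A window is tested only if it contains at least `m` valid sites in both
#' samples, a site being valid when covered by at least `n` reads; windows
#' failing the criterion are skipped (no p-value).  Without replicates the
#' pooled counts go into Fisher's exact test; with replicates (either
#' condition having more than one table) the per-replicate sums go into
#' the beta-binomial likelihood-ratio test.  The methylation difference is
#' the pooled-count level difference (condition B minus condition A) on
#' the 0-1 scale.
#'
#' @param sampleA,sampleB lists of per-site tables (one per replicate; a
#'   single data.frame is treated as one replicate) with columns `chrom`,
#'   `pos`, `strand`, `context`, `count_C`, `count_T`.
#' @param windows data.frame with `chrom`, `start`, `end` -- either
#'   genome-wide sliding windows (see [sliding_windows()]; a 1 kb window
#'   with 500 bp step is the conventional genome scan) or predefined
#'   regions (gene bodies, TEs, UTRs, CpG islands, single sites).
#' @param m minimum valid sites per window in both samples (default 5).
#' @param n minimum reads covering a valid site (default 5).
#' @param context restrict to one context (default `"CpG"`; NULL = all).
#' @param test `"auto"` (Fisher without replicates, beta-binomial with),
#'   `"fisher"` or `"betabinom"`.
#' @return data.frame of tested windows: region, `n_valid_A`, `n_valid_B`,
#'   pooled counts, `p`, `q` (BH-adjusted), `meth_diff`.
#' @export
window_scan <- function(sampleA, sampleB, windows, m = 5L, n = 5L,
                        context = "CpG",
                        test = c("auto", "fisher", "betabinom")) {
  test <- match.arg(test)
  if (is.data.frame(sampleA)) sampleA <- list(sampleA)
  if (is.data.frame(sampleB)) sampleB <- list(sampleB)
  if (test == "auto")
    test <- if (length(sampleA) > 1L || length(sampleB) > 1L)
      "betabinom" else "fisher"
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    wa <- .window_counts(sampleA, windows$chrom[w], windows$start[w],
                         windows$end[w], context, n)
    wb <- .window_counts(sampleB, windows$chrom[w], windows$start[w],
                         windows$end[w], context, n)
    if (wa$n_valid < m || wb$n_valid < m) next   # criterion (1) fails
    cA <- sum(wa$c); nA <- sum(wa$n); cB <- sum(wb$c); nB <- sum(wb$n)
    if (nA == 0L || nB == 0L) next
    p <- if (test == "fisher") fisher_dmc(cA, nA - cA, cB, nB - cB)
         else betabinom_test(wa$c, wa$n, wb$c, wb$n)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = windows$chrom[w], start = windows$start[w],
      end = windows$end[w], n_valid_A = wa$n_valid, n_valid_B = wb$n_valid,
      c_A = cA, cov_A = nA, c_B = cB, cov_B = nB, p = p,
      meth_diff = cB / nB - cA / nA, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_valid_A = integer(0),
                      n_valid_B = integer(0), c_A = integer(0),
                      cov_A = integer(0), c_B = integer(0),
                      cov_B = integer(0), p = numeric(0), q = numeric(0),
                      meth_diff = numeric(0)))
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res
}

#' Detect DMCs: single-site differential methylation
#'
#' Uses the window machinery with one-site windows (m = 1), so the same
#' tests, FDR adjustment and thresholds apply at the cytosine level.
#'
#' @inheritParams window_scan
#' @param q_threshold,diff_threshold see [call_significant()].
#' @export
dmc_scan <- function(sampleA, sampleB, n = 5L, context = "CpG",
                     test = c("auto", "fisher", "betabinom"),
                     q_threshold = 0.05, diff_threshold = 0.6) {
  if (is.data.frame(sampleA)) sampleA <- list(sampleA)
  if (is.data.frame(sampleB)) sampleB <- list(sampleB)
  first <- sampleA[[1]]
  sel <- if (!is.null(context)) first$context == context else
    rep(TRUE, nrow(first))
  sites <- data.frame(chrom = first$chrom[sel], start = first$pos[sel],
                      end = first$pos[sel] + 1L)
  res <- window_scan(sampleA, sampleB, sites, m = 1L, n = n,
                     context = context, test = test)
  call_significant(res, q_threshold, diff_threshold)
}
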