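#' Assign %dfi values to flexibility categories
#'
#' Default categories follow the five-bin scheme: %dfi < 20, 20 <= %dfi < 40,
#' 40 <= %dfi < 60, 60 <= %dfi < 80, %dfi >= 80. Bins are left-closed /
#' right-open except the last, which is closed at 100.
#'
#' @param pct numeric %dfi values in (0, 100].
#' @param edges strictly increasing interior boundaries inside (0, 100).
#' @return integer bin index per value (1 = least flexible category).
#' @examples
#' binByPctDfi(c(19.999, 20, 100))   # 1 2 5
#' @export
binByPctDfi <- function(pct, edges = c(20, 40, 60, 80)) {
  if (any(!is.finite(pct)) || any(pct <= 0) || any(pct > 100)) {
    stop("%dfi values must lie in (0, 100]")
  }
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0) ||
      any(edges >= 100)) {
    stop("edges must be strictly increasing inside (0, 100)")
  }
  findInterval(pct, edges) + 1L
}

#' Variant enrichment across %dfi categories
#'
#' Compares the observed number of variants per %dfi bin with the expectation
#' under uniform placement, `E_i = (n_i / N) * M` (n_i positions in bin i, N
#' total positions, M total variants), reporting the observed/expected ratio
#' per bin and a chi-squared goodness-of-fit test, `chi2 = sum (O_i - E_i)^2 /
#' E_i` over bins with E_i > 0, dof = (such bins) - 1, upper-tail p.
#'
#' A ratio above 1 in the low-%dfi bins means variants concentrate on
#' dynamically robust (hinge-like) positions; below 1 in the high-%dfi bins,
#' that flexible positions are depleted of them.
#'
#' @param pct %dfi value per profiled residue position (pooled across proteins
#'   when analysing several; %dfi is a per-protein percentile, so pooling is a
#'   plain concatenation).
#' @param variantPositions integer indices into `pct`, one per variant; a
#'   position may recur (several variants at one site).
#' @param edges bin boundaries, as in [binByPctDfi()].
#' @return an [EnrichmentResult-class] object.
#' @examples
#' pct <- percentileRank(seq_len(10))
#' enrichment(pct, variantPositions = c(1, 2, 2, 9), edges = c(50))
#' @export
enrichment <- function(pct, variantPositions, edges = c(20, 40, 60, 80)) {
  if (length(variantPositions) < 1) stop("need at least one variant (M >= 1)")
  bad <- variantPositions[variantPositions < 1 |
                            variantPositions > length(pct) |
                            variantPositions != round(variantPositions)]
  if (length(bad)) {
    stop("variant positions outside the profiled residues: ",
         paste(unique(bad), collapse = ", "))
  }
  nb <- length(edges) + 1L
  bins <- binByPctDfi(pct, edges)
  n_i <- tabulate(bins, nbins = nb)
  o_i <- tabulate(bins[variantPositions], nbins = nb)
  M <- length(variantPositions)
  e_i <- n_i / length(pct) * M

  pos <- e_i > 0
  if (any(o_i[!pos] > 0)) {
    stop("observed variants in a bin with zero expected count")
  }
  if (!all(pos)) {
    warning(sum(!pos), " bin(s) with E_i = 0 excluded from the chi-squared test")
  }
  chi2 <- sum((o_i[pos] - e_i[pos])^2 / e_i[pos])
  dof <- as.integer(sum(pos) - 1L)
  ratio <- ifelse(pos, o_i / e_i, NA_real_)
  new("EnrichmentResult", binEdges = as.numeric(edges),
      nPerBin = as.numeric(n_i), observed = as.numeric(o_i),
      expected = e_i, ratio = ratio, chi2 = chi2, dof = dof,
      p = stats::pchisq(chi2, dof, lower.tail = FALSE))
}

#' Flexibility distribution of a labeled residue subset
#'
#' Histogram of %dfi over a subset of residues (e.g. catalytic or binding
#' sites), normalized to frequencies, plus the fraction of the subset at or
#' below a %dfi threshold (e.g. the share of catalytic residues with
#' %dfi <= 25).
#'
#' @param pct %dfi per residue.
#' @param labelIdx integer indices of the labeled residues.
#' @param binWidth histogram bin width in %dfi units (default 5).
#' @param threshold report the fraction of labeled residues with
#'   %dfi <= `threshold` (default 25).
#' @return list with `breaks`, `mid`, `frequency` (sums to 1), and
#'   `fractionAtOrBelow`.
#' @export
flexibilityDistribution <- function(pct, labelIdx, binWidth = 5,
                                    threshold = 25) {
  if (!length(labelIdx)) stop("empty label set")
  if (any(labelIdx < 1 | labelIdx > length(pct))) {
    stop("label indices outside the profiled residues")
  }
  v <- pct[labelIdx]
  breaks <- seq(0, 100, by = binWidth)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  cnt <- tabulate(findInterval(v, breaks[-length(breaks)]),
                  nbins = length(breaks) - 1L)
  list(breaks = breaks,
       mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
       frequency = cnt / length(v),
       fractionAtOrBelow = mean(v <= threshold))
}

#' Sliding-window correlation of %dfi with evolutionary rate
#'
#' Residues are sorted by %dfi; windows of `window` residues advanced by
#' `step` yield per-window means of %dfi and of the per-site evolutionary
#' rate, and the Pearson correlation of the two window-mean series measures
#' how substitution rates track flexibility. Because the sort key enters only
#' through the ordering and within-window means of its own values, the
#' correlation is insensitive to noise in individual residues.
#'
#' @param pct %dfi per residue.
#' @param rates per-site evolutionary rates (substitutions/site/Byr), joined
#'   1:1 with `pct`.
#' @param window window size in residues; default `max(50, round(N / 20))`.
#' @param step advance in residues; default `max(1, round(window / 2))`.
#' @return list with `windowPct`, `windowRate` (the window-mean series),
#'   `correlation`, `window`, `step`.
#' @export
rateDfiSliding <- function(pct, rates, window = NULL, step = NULL) {
  n <- length(pct)
  if (length(rates) != n) stop("rates must join 1:1 with %dfi values")
  if (any(rates < 0, na.rm = TRUE)) stop("rates must be >= 0")
  if (is.null(window)) window <- max(50, round(n / 20))
  if (is.null(step)) step <- max(1, round(window / 2))
  if (window > n) stop("window size (", window, ") exceeds residue count (",
                       n, ")")
  ord <- order(pct)
  p <- pct[ord]
  r <- rates[ord]
  starts <- seq(1, n - window + 1, by = step)
  if (length(starts) < 2) {
    stop("fewer than 2 windows; decrease window or step")
  }
  wp <- vapply(starts, function(s) mean(p[s:(s + window - 1)]), numeric(1))
  wr <- vapply(starts, function(s) mean(r[s:(s + window - 1)]), numeric(1))
  list(windowPct = wp, windowRate = wr,
       correlation = stats::cor(wp, wr),
       window = window, step = step)
}

#' %dfi summaries by evolutionary-conservation category
#'
#' Partitions residues into ultra-conserved (r = 0), well-conserved
#' (0 < r <= 1) and less-conserved (r > 1) by their substitution rate, and
#' returns a five-number %dfi summary per non-empty group.
#'
#' @param pct %dfi per residue.
#' @param rates per-site rates (substitutions/site/Byr), joined 1:1.
#' @return data.frame with one row per populated group: group, n, min, q1,
#'   median, q3, max. Empty groups are absent.
#' @export
conservationGroups <- function(pct, rates) {
  if (length(rates) != length(pct)) stop("rates must join 1:1 with %dfi")
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be finite and >= 0")
  grp <- ifelse(rates == 0, "ultra_conserved",
                ifelse(rates <= 1, "well_conserved", "less_conserved"))
  grp <- factor(grp, levels = c("ultra_conserved", "well_conserved",
                                "less_conserved"))
  out <- lapply(levels(grp), function(g) {
    v <- pct[grp == g]
    if (!length(v)) return(NULL)
    fn <- stats::fivenum(v)
    data.frame(group = g, n = length(v), min = fn[1], q1 = fn[2],
               median = fn[3], q3 = fn[4], max = fn[5])
  })
  do.call(rbind, out)
}

#' Welch two-sample test for a flexibility difference between groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p, via [stats::t.test()]. Degenerate inputs (zero variance in
#' both groups) fall back to the conventions t = 0, p = 1 on equal means and
#' p = 0 otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
groupDifferenceTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 observations")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = NA_real_, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
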