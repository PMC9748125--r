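# Constituent per-SNP selection statistics contrasting the selected
# cohort against the non-selected reference: allele-frequency
# differentiation (Fst), the change in selected allele frequency
# (dSAF), and cross-population extended haplotype homozygosity
# (XP-EHH).

.split_panel <- function(panel) {
  sel <- panel$pop_labels == "selected"
  if (!any(sel) || all(sel))
    stop("panel must contain both 'selected' and 'non_selected' haplotypes")
  list(sel = panel$alleles[sel, , drop = FALSE],
       ns = panel$alleles[!sel, , drop = FALSE])
}

#' Hudson's Fst estimator with sample-size correction
#'
#' Per-site estimator for two cohorts with `n1`, `n2` sampled
#' haplotypes at alternate-allele frequencies `p1`, `p2`:
#' numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`. Sites with zero denominator
#' (monomorphic in both, same allele) or `n < 2` in either cohort
#' return `NA`.
#'
#' @param p1,p2 Allele frequencies per site in each cohort.
#' @param n1,n2 Haplotype (allele) counts used.
#' @return Numeric vector of per-site Fst values.
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- ifelse(den == 0 | n1 < 2 | n2 < 2, NA_real_, num / den)
  out
}

# Weir & Cockerham (1984) theta for haploid allele counts, two cohorts.
.wc_fst <- function(p1, p2, n1, n2) {
  r <- 2
  N <- n1 + n2
  nbar <- N / r
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / N
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1)
  b <- (nc - 1) / (nbar - 1) * pbar * (1 - pbar) +
    (1 + (r - 1) * (nbar - nc) / (nbar - 1)) * s2 / r
  ifelse(b == 0 | n1 < 2 | n2 < 2, NA_real_, (nbar / nc) * a / b)
}

#' Per-SNP Fst between the selected and non-selected cohorts
#'
#' @param panel A [haplotype_panel()].
#' @param estimator `"hudson"` (default, the two-cohort scan standard)
#'   or `"wc"` (Weir-Cockerham).
#' @return Numeric vector, one value per site (`NA` where undefined).
#' @export
fst_per_snp <- function(panel, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  sp <- .split_panel(panel)
  p1 <- colMeans(sp$sel); n1 <- nrow(sp$sel)
  p2 <- colMeans(sp$ns);  n2 <- nrow(sp$ns)
  if (estimator == "hudson") hudson_fst(p1, p2, n1, n2)
  else .wc_fst(p1, p2, n1, n2)
}

#' Per-SNP change in selected allele frequency (dSAF)
#'
#' Signed difference `p_sel - p_ns` of the alternate-allele frequency
#' (selected minus non-selected); with `absolute = TRUE` the magnitude
#' is returned instead. The signed default, ranked ascending, makes
#' frequency gain in the selected cohort rank high in the composite
#' score.
#'
#' @param panel A [haplotype_panel()].
#' @param absolute Return `abs(p_sel - p_ns)` instead of the signed
#'   difference.
#' @return Numeric vector, one value per site.
#' @export
delta_saf_per_snp <- function(panel, absolute = FALSE) {
  sp <- .split_panel(panel)
  d <- colMeans(sp$sel) - colMeans(sp$ns)
  if (absolute) abs(d) else d
}

#' Extended haplotype homozygosity curve from a core site
#'
#' Haplotypes are grouped by identity over the interval extending
#' site-by-site from the core (the core itself is excluded; EHH is
#' computed over all haplotypes of the population, unconditioned on a
#' core allele, as the XP-EHH site statistic requires). At each
#' extension, `EHH = sum_g C(n_g, 2) / C(n, 2)` over identity groups
#' g. The curve starts at 1 at zero extension and is non-increasing.
#'
#' @param alleles Binary haplotype x site matrix for one population.
#' @param positions bp positions of the sites.
#' @param core_index Column index of the core site.
#' @param direction `"right"` or `"left"`.
#' @param stop_below Stop extending once EHH falls below this value
#'   (the first sub-threshold point is retained); 0 extends to the
#'   chromosome end.
#' @return data.frame with `site` (column index), `distance` (bp from
#'   the core) and `ehh`, starting with the zero-extension anchor row
#'   (`distance = 0`, `ehh = 1`). A core at the chromosome edge in the
#'   requested direction yields only the anchor row.
#' @export
ehh_curve <- function(alleles, positions, core_index,
                      direction = c("right", "left"), stop_below = 0) {
  direction <- match.arg(direction)
  n <- nrow(alleles)
  if (n < 2L) stop("need >= 2 haplotypes")
  m <- ncol(alleles)
  if (core_index < 1L || core_index > m) stop("core site out of bounds")
  sites <- if (direction == "right") {
    if (core_index == m) integer(0) else seq.int(core_index + 1L, m)
  } else {
    if (core_index == 1L) integer(0) else seq.int(core_index - 1L, 1L)
  }
  denom <- n * (n - 1) / 2
  grp <- rep(1L, n)
  ehh <- numeric(length(sites))
  used <- 0L
  for (s in sites) {
    key <- grp * 2L + alleles[, s]
    grp <- match(key, key)            # group id = first occurrence index
    tab <- tabulate(grp, nbins = n)
    used <- used + 1L
    ehh[used] <- sum(tab * (tab - 1) / 2) / denom
    if (ehh[used] < stop_below || ehh[used] == 0) break
  }
  sites <- sites[seq_len(used)]
  data.frame(site = c(core_index, sites),
             distance = c(0, abs(positions[sites] - positions[core_index])),
             ehh = c(1, ehh[seq_len(used)]))
}

# Trapezoid integral of an EHH curve over physical distance.
.ehh_integral <- function(curve) {
  if (nrow(curve) < 2L) return(0)
  d <- curve$distance
  e <- curve$ehh
  sum(diff(d) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
}

#' Per-SNP cross-population EHH (XP-EHH)
#'
#' For each core SNP, each population's EHH curve is integrated over
#' physical distance (trapezoid rule) in both directions until EHH
#' falls below `ehh_cutoff` or the chromosome end; the two directional
#' integrals are summed and `XP-EHH = ln(I_sel / I_ns)`. Positive
#' values indicate longer haplotype homozygosity in the selected
#' population. Values are left unstandardised: the composite score
#' ranks them, and fractional ranks are invariant to any monotone
#' standardisation.
#'
#' @param panel A [haplotype_panel()].
#' @param ehh_cutoff EHH level below which integration stops
#'   (default 0.05).
#' @return data.frame with `xpehh` (`NA` where the reference integral
#'   is zero) and `truncated` (TRUE where either population's curve
#'   never fell below the cutoff before a chromosome end).
#' @export
xpehh_per_snp <- function(panel, ehh_cutoff = 0.05) {
  sp <- .split_panel(panel)
  m <- ncol(panel$alleles)
  pos <- panel$positions
  integrate_pop <- function(alleles, core) {
    trunc <- FALSE
    tot <- 0
    for (dir in c("left", "right")) {
      cv <- ehh_curve(alleles, pos, core, dir, stop_below = ehh_cutoff)
      tot <- tot + .ehh_integral(cv)
      if (cv$ehh[nrow(cv)] >= ehh_cutoff &&
          cv$site[nrow(cv)] %in% c(1L, m) && m > 1L)
        trunc <- TRUE
    }
    list(I = tot, truncated = trunc)
  }
  xpehh <- numeric(m)
  truncated <- logical(m)
  n_missing <- 0L
  for (i in seq_len(m)) {
    a <- integrate_pop(sp$sel, i)
    b <- integrate_pop(sp$ns, i)
    truncated[i] <- a$truncated || b$truncated
    if (b$I == 0 || a$I == 0) {
      xpehh[i] <- NA_real_
      n_missing <- n_missing + 1L
    } else {
      xpehh[i] <- log(a$I / b$I)
    }
  }
  if (n_missing > 0L)
    message(n_missing, " site(s) with a zero EHH integral flagged missing")
  data.frame(xpehh = xpehh, truncated = truncated)
}

#' Per-SNP constituent selection statistics for a haplotype panel
#'
#' Computes Fst, dSAF and XP-EHH at every polymorphic site of the
#' panel, contrasting the selected against the non-selected cohort.
#' Sites monomorphic in both populations are excluded (the panel flags
#' them); the returned table has one row per polymorphic site.
#'
#' @param panel A [haplotype_panel()].
#' @param ehh_cutoff Passed to [xpehh_per_snp()].
#' @param fst_estimator Passed to [fst_per_snp()].
#' @param dsaf_absolute Passed to [delta_saf_per_snp()].
#' @return data.frame with columns `chrom`, `pos`, `p_sel`, `p_ns`,
#'   `n_sel`, `n_ns`, `fst`, `dsaf`, `xpehh`, `xpehh_truncated`.
#' @export
snp_stats <- function(panel, ehh_cutoff = 0.05,
                      fst_estimator = "hudson", dsaf_absolute = FALSE) {
  sp <- .split_panel(panel)
  keep <- !panel$monomorphic
  xp <- xpehh_per_snp(panel, ehh_cutoff)
  out <- data.frame(
    chrom = panel$chrom,
    pos = panel$positions,
    p_sel = colMeans(sp$sel),
    p_ns = colMeans(sp$ns),
    n_sel = nrow(sp$sel),
    n_ns = nrow(sp$ns),
    fst = fst_per_snp(panel, fst_estimator),
    dsaf = delta_saf_per_snp(panel, dsaf_absolute),
    xpehh = xp$xpehh,
    xpehh_truncated = xp$truncated,
    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}
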