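# Composite selection signals: genome-wide fractional ranks of each
# constituent statistic are mapped through the inverse normal CDF,
# averaged per SNP, converted to a one-sided P under N(0, 1/m), and
# -log10-transformed. Smoothing over bp windows and top-percentile
# cluster calling turn the per-SNP track into called selection signals.

#' Fractional ranks of a statistic vector
#'
#' Values are ranked ascending genome-wide (rank 1 ... n, largest value
#' highest) and converted to fractional ranks `r' = rank / (n + 1)`,
#' which lie strictly inside (0, 1). Ties receive average ranks.
#' Missing values are excluded before ranking and returned as `NA`.
#'
#' @param x Numeric vector of per-SNP statistics.
#' @return Numeric vector of fractional ranks, `NA` where `x` was.
#' @export
fractional_ranks <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) stop("all values missing; nothing to rank")
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  out[ok] <- rank(x[ok], ties.method = "average") / (n + 1)
  out
}

#' Composite selection signal per SNP
#'
#' For each constituent statistic column, fractional ranks `r'` are
#' converted to z-values `z = qnorm(r')`; the mean z across the m
#' constituent tests at each SNP is referred to its sampling
#' distribution under the null, N(0, 1/m), giving the one-sided
#' upper-tail `P = 1 - pnorm(zbar * sqrt(m))`; `CSS = -log10(P)`.
#' SNPs missing some (but not all) constituent statistics use the mean
#' over the available tests with the matching null variance `1/m_avail`
#' (set `require_complete = TRUE` to drop them instead). SNPs with no
#' available statistic are dropped with a message.
#'
#' @param stat_table data.frame from [snp_stats()] (or any table with
#'   `chrom`, `pos` and the constituent columns).
#' @param stats Character vector naming the constituent statistic
#'   columns (default `c("fst", "dsaf", "xpehh")`).
#' @param require_complete Drop SNPs missing any constituent statistic
#'   instead of averaging over the available ones.
#' @return data.frame of class `"css_table"`: `chrom`, `pos`, one
#'   `r_<stat>` column per constituent, `z_mean`, `m`, `p`, `css`.
#' @export
css_scores <- function(stat_table, stats = c("fst", "dsaf", "xpehh"),
                       require_complete = FALSE) {
  miss <- setdiff(stats, names(stat_table))
  if (length(miss)) stop("missing constituent column(s): ",
                         paste(miss, collapse = ", "))
  if (length(stats) < 1L) stop("need at least one constituent statistic")
  Z <- sapply(stats, function(s) stats::qnorm(fractional_ranks(stat_table[[s]])))
  Z <- matrix(Z, ncol = length(stats),
              dimnames = list(NULL, paste0("r_", stats)))
  m_avail <- rowSums(!is.na(Z))
  if (require_complete) {
    drop <- m_avail < length(stats)
  } else {
    drop <- m_avail == 0L
  }
  if (any(drop))
    message(sum(drop), " SNP(s) dropped: no usable constituent statistic")
  z_mean <- rowMeans(Z, na.rm = TRUE)
  p <- stats::pnorm(z_mean * sqrt(m_avail), lower.tail = FALSE)
  out <- data.frame(chrom = stat_table$chrom, pos = stat_table$pos,
                    stringsAsFactors = FALSE)
  for (j in seq_along(stats))
    out[[paste0("r_", stats[j])]] <- stats::pnorm(Z[, j])
  out$z_mean <- z_mean
  out$m <- m_avail
  out$p <- p
  out$css <- -log10(p)
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("css_table", "data.frame")
  out
}

#' Window-smoothed CSS score
#'
#' For each SNP, the smoothed CSS is the mean CSS of all SNPs on the
#' same chromosome whose position lies within `window_bp / 2` of it
#' (SNP-centred window, boundaries inclusive). A SNP with no
#' neighbours keeps its own CSS. The default window is 1 Mb; 100 kb is
#' a common alternative for denser panels.
#'
#' @param css_table A `css_table` from [css_scores()], positions sorted
#'   within chromosome.
#' @param window_bp Full window width in bp.
#' @return The input with a `css_smooth` column appended.
#' @export
smooth_css <- function(css_table, window_bp = 1e6) {
  h <- window_bp / 2
  out <- css_table
  out$css_smooth <- NA_real_
  for (ch in unique(css_table$chrom)) {
    i <- which(css_table$chrom == ch)
    pos <- css_table$pos[i]
    if (is.unsorted(pos)) stop("positions must be sorted within chromosome")
    v <- css_table$css[i]
    cs <- c(0, cumsum(v))
    lo <- findInterval(pos - h, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + h, pos)
    out$css_smooth[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Call selection-signal clusters from the smoothed CSS track
#'
#' The genome-wide top-`top_fraction` threshold is the empirical
#' `1 - top_fraction` quantile of the smoothed CSS. Top SNPs on the
#' same chromosome are merged into a cluster while consecutive top
#' SNPs are at most `merge_gap_bp` apart; clusters with strictly more
#' than `min_snps` members are reported, ranked by peak smoothed CSS.
#'
#' @param css_table Output of [smooth_css()].
#' @param top_fraction Fraction of SNPs declared "top" (default 0.01).
#' @param min_snps Minimum member count, exclusive (default 5: clusters
#'   must contain more than 5 top SNPs).
#' @param merge_gap_bp Maximum gap between consecutive top SNPs in one
#'   cluster; defaults to the smoothing window (1 Mb).
#' @param use_raw Rank and threshold the raw CSS instead of the
#'   smoothed track.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`,
#'   `peak_css`, `mean_css`, `rank` and a list column `members` of
#'   member positions. Zero rows when no cluster qualifies.
#' @export
call_clusters <- function(css_table, top_fraction = 0.01, min_snps = 5,
                          merge_gap_bp = 1e6, use_raw = FALSE) {
  score <- if (use_raw) css_table$css else css_table$css_smooth
  if (is.null(score)) stop("smoothed CSS not found; run smooth_css() first")
  if (nrow(css_table) < 1 / top_fraction)
    stop("fewer than 1/top_fraction SNPs; top quantile undefined")
  thr <- stats::quantile(score, 1 - top_fraction, names = FALSE)
  top <- which(score >= thr)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      peak_css = numeric(0), mean_css = numeric(0),
                      rank = integer(0))
  empty$members <- list()
  if (length(top) == 0L) return(empty)
  df <- data.frame(i = top, chrom = css_table$chrom[top],
                   pos = css_table$pos[top], s = score[top],
                   stringsAsFactors = FALSE)
  new_cluster <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                     diff(df$pos) > merge_gap_bp)
  cl <- cumsum(new_cluster)
  parts <- split(df, cl)
  keep <- vapply(parts, nrow, 0L) > min_snps
  parts <- parts[keep]
  if (length(parts) == 0L) return(empty)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(chrom = p$chrom[1L], start = min(p$pos), end = max(p$pos),
               n_snps = nrow(p), peak_css = max(p$s), mean_css = mean(p$s),
               stringsAsFactors = FALSE)
  }))
  ord <- order(-out$peak_css)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$members <- lapply(parts[ord], function(p) p$pos)
  attr(out, "threshold") <- thr
  rownames(out) <- NULL
  out
}

#' Intersect called clusters with external regions
#'
#' Standard interval intersection (1-based inclusive internally; BED
#' input is converted at the read boundary). Reports the overlapping
#' bp for every cluster/region pair that overlaps.
#'
#' @param clusters data.frame with `chrom`, `start`, `end` (e.g. from
#'   [call_clusters()]).
#' @param regions data.frame with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @return data.frame with one row per overlapping pair: cluster and
#'   region coordinates plus `overlap_bp`.
#' @export
intersect_regions <- function(clusters, regions) {
  for (d in list(clusters, regions))
    if (any(d$start > d$end)) stop("malformed interval: start > end")
  a <- GenomicRanges::GRanges(clusters$chrom,
                              IRanges::IRanges(clusters$start, clusters$end))
  b <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  ov <- GenomicRanges::findOverlaps(a, b)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(a[qi], b[si]))
  data.frame(cluster_chrom = clusters$chrom[qi],
             cluster_start = clusters$start[qi],
             cluster_end = clusters$end[qi],
             region_chrom = regions$chrom[si],
             region_start = regions$start[si],
             region_end = regions$end[si],
             region_name = (if (!is.null(regions$name)) regions$name
                            else rep(NA_character_, nrow(regions)))[si],
             overlap_bp = w,
             stringsAsFactors = FALSE)
}
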