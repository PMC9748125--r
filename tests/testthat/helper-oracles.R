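# Independent brute-force oracles and small panel builders used across
# the suite. These deliberately avoid the implementation's code paths.

# EHH by explicit enumeration: haplotypes are grouped by the string of
# alleles over the extended interval; EHH = sum over groups of
# C(n_g, 2) / C(n, 2).
brute_ehh <- function(alleles, core, k, direction = "right") {
  n <- nrow(alleles)
  cols <- if (direction == "right") core + seq_len(k) else core - seq_len(k)
  keys <- apply(alleles[, cols, drop = FALSE], 1, paste, collapse = "")
  tab <- table(keys)
  sum(choose(tab, 2)) / choose(n, 2)
}

# Hudson Fst evaluated directly from the published formula.
brute_hudson <- function(p1, p2, n1, n2) {
  ((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)) /
    (p1 * (1 - p2) + p2 * (1 - p1))
}

# Build a haplotype panel from two explicit allele matrices.
toy_panel <- function(sel, ns, positions = NULL, chrom = "1") {
  if (is.null(positions)) positions <- seq_len(ncol(sel))
  n1 <- nrow(sel); n2 <- nrow(ns)
  ids <- c(rep(sprintf("s%02d", seq_len(ceiling(n1 / 2))), each = 2)[seq_len(n1)],
           rep(sprintf("n%02d", seq_len(ceiling(n2 / 2))), each = 2)[seq_len(n2)])
  haplotype_panel(chrom = chrom, positions = positions,
                  alleles = rbind(sel, ns),
                  pop_labels = c(rep("selected", n1), rep("non_selected", n2)),
                  sample_ids = ids)
}

# A minimal css_table-like data.frame for smoothing/cluster tests.
toy_css_table <- function(pos, css, chrom = "1") {
  structure(data.frame(chrom = chrom, pos = pos, css = css,
                       stringsAsFactors = FALSE),
            class = c("css_table", "data.frame"))
}
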