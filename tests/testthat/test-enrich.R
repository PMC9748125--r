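make_scan <- function(n = 200, seed = 97) {
  set.seed(seed)
  structure(data.frame(chrom = "1", pos = sort(sample(1e7, n)),
                       p = runif(n), stringsAsFactors = FALSE),
            class = c("css_table", "data.frame"))
}

test_that("target SNP collection respects inclusive window boundaries", {
  tab <- structure(data.frame(chrom = "1", pos = c(5000, 9999, 30100),
                              p = c(0.5, 0.5, 0.5)),
                   class = c("css_table", "data.frame"))
  gene <- data.frame(gene_id = "G1", chrom = "1", start = 10000, end = 20000)
  t0 <- collect_target_snps(tab, gene, 0)
  expect_equal(nrow(t0$snps), 0)
  t10 <- collect_target_snps(tab, gene, 1e4)
  expect_equal(t10$snps$pos, c(5000, 9999))   # 30100 beyond boundary 30000
  t_edge <- collect_target_snps(
    structure(data.frame(chrom = "1", pos = 30000, p = 0.5),
              class = c("css_table", "data.frame")), gene, 1e4)
  expect_equal(nrow(t_edge$snps), 1)          # boundary itself is in
})

test_that("a SNP in two gene windows is one target SNP but two memberships", {
  tab <- structure(data.frame(chrom = "1", pos = 15000, p = 0.5),
                   class = c("css_table", "data.frame"))
  genes <- data.frame(gene_id = c("A", "B"), chrom = "1",
                      start = c(10000, 14000), end = c(16000, 20000))
  tg <- collect_target_snps(tab, genes, 0)
  expect_equal(nrow(tg$snps), 1)
  expect_equal(nrow(tg$membership), 2)
  expect_setequal(tg$membership$gene_id, c("A", "B"))
})

test_that("an empty DEG set gives an empty target with a warning", {
  tab <- make_scan()
  expect_warning(tg <- collect_target_snps(tab, tab[0, ], 1e4), "empty")
  expect_equal(nrow(tg$snps), 0)
})

test_that("local FDR is 1 on degenerate input and warns on small sets", {
  expect_warning(q <- local_fdr(rep(0.5, 100)), "degenerate")
  expect_true(all(q == 1))
  expect_warning(local_fdr(runif(20)), "fewer than 50")
  expect_error(local_fdr(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("q never increases as the nominal P decreases", {
  set.seed(101)
  for (rep in 1:5) {
    p <- runif(300)
    q <- suppressWarnings(local_fdr(p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("the empirical-null fit recovers the null fraction and flags signals", {
  set.seed(103)
  n <- 5000
  is_alt <- seq_len(n) <= 0.05 * n
  p <- ifelse(is_alt, 10^runif(n, -6, -4), runif(n))
  q <- local_fdr(p)
  expect_lt(abs(attr(q, "eta0") - 0.95), 0.05)
  expect_gte(mean(q[is_alt] < 0.05), 0.8)          # sensitivity
  expect_lt(mean(q[!is_alt] < 0.05), 0.02)         # specificity
})

test_that("an observed count of zero gives a permutation P of exactly 1", {
  tab <- make_scan()
  tg <- collect_target_snps(tab, data.frame(gene_id = "G", chrom = "1",
                                            start = 1, end = 2e6), 0)
  res <- permutation_enrichment(tab, tg, q_threshold = 1e-9, n_null = 50,
                                seed = 5, q_fun = function(p) p)
  expect_equal(res$observed, 0L)
  expect_equal(res$p_perm, 1)
})

test_that("the permutation P matches the binomial oracle on the 10-SNP toy", {
  # 10-SNP scan, 2 significant under the fixed rule q = p < 0.05;
  # target of 3 SNPs containing both significant ones.
  tab <- structure(data.frame(chrom = "1", pos = (1:10) * 1000,
                              p = c(0.01, 0.02, seq(0.2, 0.9, length.out = 8))),
                   class = c("css_table", "data.frame"))
  tg <- list(snps = cbind(tab[1:3, ], snp_idx = 1:3),
             membership = data.frame(gene_id = "G", snp_idx = 1:3,
                                     pos = tab$pos[1:3]))
  res <- permutation_enrichment(tab, tg, q_threshold = 0.05, n_null = 2000,
                                seed = 9, q_fun = function(p) p)
  p_exact <- pbinom(1, 3, 0.2, lower.tail = FALSE)   # P(X >= 2), X~B(3, 0.2)
  expect_equal(res$observed, 2L)
  expect_lt(abs(res$p_perm - p_exact), 0.025)
})

test_that("a target equal to the whole scan is unenriched (exchangeability)", {
  tab <- make_scan(n = 300, seed = 107)
  tg <- list(snps = cbind(tab, snp_idx = seq_len(nrow(tab))),
             membership = data.frame(gene_id = "all",
                                     snp_idx = seq_len(nrow(tab)),
                                     pos = tab$pos))
  res <- permutation_enrichment(tab, tg, q_threshold = 0.05, n_null = 500,
                                seed = 11, q_fun = function(p) p)
  expect_gt(res$p_perm, 0.2)
  expect_lt(res$p_perm, 0.8)
})

test_that("permutation results are reproducible and per-gene counts reported", {
  tab <- make_scan(n = 150, seed = 109)
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "1",
                      start = c(1e6, 6e6), end = c(2e6, 7e6))
  tg <- collect_target_snps(tab, genes, 1e5)
  r1 <- permutation_enrichment(tab, tg, n_null = 100, seed = 13,
                               q_fun = function(p) p, q_threshold = 0.2)
  r2 <- permutation_enrichment(tab, tg, n_null = 100, seed = 13,
                               q_fun = function(p) p, q_threshold = 0.2)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$null_counts, r2$null_counts)
  if (r1$observed > 0) expect_gt(nrow(r1$per_gene), 0)
  # every null set has the target size by construction; counts bounded by it
  expect_true(all(r1$null_counts <= r1$n_target))
})

test_that("the width sweep prefers the smallest width on ties", {
  # a single gene in a SNP desert: no width ever gains a SNP beyond
  # those in the gene body, so all widths tie and the smallest wins
  tab <- structure(data.frame(chrom = "1",
                              pos = c(5e5 + (1:20) * 1e3, (1:30) * 1e5 + 7e6),
                              p = runif(50)),
                   class = c("css_table", "data.frame"))
  gene <- data.frame(gene_id = "G", chrom = "1", start = 5e5, end = 5.3e5)
  sw <- window_sweep(tab, gene, widths = c(1e4, 2e4, 3e4), n_null = 50,
                     seed = 17, q_fun = function(p) p)
  expect_equal(length(unique(sw$per_width$observed)), 1L)
  expect_equal(length(unique(sw$per_width$p_perm)), 1L)
  expect_equal(sw$selected_width, 1e4)
})

test_that("the width sweep aborts on an empty DEG set", {
  tab <- make_scan()
  expect_warning(sw <- window_sweep(tab, tab[0, ], seed = 19), "empty")
  expect_null(sw)
})
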