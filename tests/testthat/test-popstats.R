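test_that("Hudson Fst matches its closed form on hand cases", {
  # no differentiation in the large-sample limit
  expect_lt(abs(hudson_fst(0.5, 0.5, 1e7, 1e7)), 1e-6)
  # fixed difference gives exactly 1 at any n >= 2
  expect_equal(hudson_fst(1, 0, 4, 4), 1)
  expect_equal(hudson_fst(1, 0, 2, 113), 1)
  # 4 + 4 haplotypes with allele counts 3/4 and 1/4
  sel <- matrix(c(1, 1, 1, 0), ncol = 1)
  ns <- matrix(c(1, 0, 0, 0), ncol = 1)
  p <- toy_panel(sel, ns)
  val <- fst_per_snp(p)
  # by hand: num = 0.25 - 2 * (0.1875/3) = 0.125; den = 0.5625 + 0.0625
  expect_equal(val, 0.125 / 0.625, tolerance = 1e-15)
  expect_equal(val, brute_hudson(0.75, 0.25, 4, 4), tolerance = 1e-15)
})

test_that("Fst agrees with the plug-in oracle on random small panels", {
  set.seed(41)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1) * 2; n2 <- sample(2:5, 1) * 2
    sel <- matrix(rbinom(n1 * 6, 1, 0.5), nrow = n1)
    ns <- matrix(rbinom(n2 * 6, 1, 0.5), nrow = n2)
    p <- toy_panel(sel, ns)
    expect_equal(fst_per_snp(p),
                 brute_hudson(colMeans(sel), colMeans(ns), n1, n2),
                 tolerance = 1e-14)
  }
})

test_that("the Weir-Cockerham variant is available and sane", {
  set.seed(43)
  sel <- matrix(rbinom(80, 1, 0.8), nrow = 10)
  ns <- matrix(rbinom(80, 1, 0.2), nrow = 10)
  p <- toy_panel(sel, ns)
  wc <- fst_per_snp(p, estimator = "wc")
  expect_true(all(is.finite(wc) | is.na(wc)))
  expect_equal(fst_per_snp(toy_panel(matrix(1, 4, 1), matrix(0, 4, 1)),
                           estimator = "wc"), 1)
})

test_that("dSAF is the signed selected-minus-reference frequency difference", {
  same <- toy_panel(matrix(c(1, 0), 2, 1), matrix(c(1, 0), 2, 1))
  expect_equal(delta_saf_per_snp(same), 0)
  fixed <- toy_panel(matrix(1, 2, 1), matrix(0, 2, 1))
  expect_equal(delta_saf_per_snp(fixed), 1)
  # frequencies 0.1873 vs 0.3956 -> -0.2083
  sel <- matrix(c(rep(1L, 1873), rep(0L, 10000 - 1873)), ncol = 1)
  ns <- matrix(c(rep(1L, 3956), rep(0L, 10000 - 3956)), ncol = 1)
  p <- toy_panel(sel, ns)
  expect_equal(delta_saf_per_snp(p), -0.2083, tolerance = 1e-12)
  expect_equal(delta_saf_per_snp(p, absolute = TRUE), 0.2083,
               tolerance = 1e-12)
})

test_that("EHH reproduces the pair-counting example 000/000/010/011", {
  # core at column 1, extension right over columns 2-4
  H <- rbind(c(0, 0, 0, 0),
             c(0, 0, 0, 0),
             c(1, 0, 1, 0),
             c(0, 0, 1, 1))
  cv <- ehh_curve(H, positions = 1:4, core_index = 1, direction = "right")
  expect_equal(cv$ehh, c(1, 1, 2 / 6, 1 / 6))
  for (k in 1:3)
    expect_equal(cv$ehh[k + 1], brute_ehh(H, 1, k))
})

test_that("EHH handles degenerate cases", {
  # identical haplotypes: EHH = 1 at every distance
  H <- matrix(0L, 4, 5)
  cv <- ehh_curve(H, 1:5, 3, "right")
  expect_true(all(cv$ehh == 1))
  # two haplotypes differing at the first extended site: 0 onward
  H2 <- rbind(c(0, 1, 0), c(0, 0, 0))
  cv2 <- ehh_curve(H2, 1:3, 1, "right")
  expect_equal(cv2$ehh, c(1, 0))
  # core at the edge: only the anchor row
  expect_equal(nrow(ehh_curve(H, 1:5, 5, "right")), 1)
})

test_that("EHH curves are non-increasing, bounded, and match brute force", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    H <- matrix(rbinom(n * 8, 1, 0.5), nrow = n)
    core <- sample(1:8, 1)
    for (dir in c("left", "right")) {
      cv <- ehh_curve(H, (1:8) * 100, core, dir)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
      k_max <- nrow(cv) - 1L
      for (k in seq_len(k_max))
        expect_equal(cv$ehh[k + 1], brute_ehh(H, core, k, dir),
                     tolerance = 1e-14)
    }
  }
})

test_that("XP-EHH is zero for identical panels and positive for a selected sweep", {
  set.seed(53)
  H <- matrix(rbinom(60, 1, 0.5), nrow = 6)
  p_same <- toy_panel(H, H, positions = (1:10) * 1000)
  xp <- xpehh_per_snp(p_same)
  expect_true(all(abs(xp$xpehh) < 1e-12, na.rm = TRUE))
  # selected population fixed on one haplotype, reference diverse
  sel <- matrix(rep(H[1, ], each = 6), nrow = 6)
  p_sweep <- toy_panel(sel, H, positions = (1:10) * 1000)
  xp2 <- xpehh_per_snp(p_sweep, ehh_cutoff = 0)
  expect_gt(xp2$xpehh[5], 0)
})

test_that("XP-EHH integral equals the trapezoid over the oracle EHH curve", {
  set.seed(59)
  sel <- matrix(rbinom(36, 1, 0.5), nrow = 6)
  ns <- matrix(rbinom(36, 1, 0.5), nrow = 6)
  pos <- c(100, 1500, 2100, 4800, 5200, 9000)
  p <- toy_panel(sel, ns, positions = pos)
  core <- 3
  trap <- function(H) {
    tot <- 0
    for (dir in c("left", "right")) {
      ks <- if (dir == "right") seq_len(6 - core) else seq_len(core - 1)
      d <- c(0, abs(pos[if (dir == "right") core + ks else core - ks] -
                      pos[core]))
      e <- c(1, sapply(ks, function(k) brute_ehh(H, core, k, dir)))
      # integrate until the curve drops below the cutoff (first
      # sub-threshold point included), as the implementation does
      stop_at <- which(e < 0.05)
      last <- if (length(stop_at)) min(stop_at) else length(e)
      # a curve that reaches zero stops there too
      zero_at <- which(e == 0)
      if (length(zero_at)) last <- min(last, min(zero_at))
      idx <- seq_len(last)
      tot <- tot + sum(diff(d[idx]) * (head(e[idx], -1) + tail(e[idx], -1)) / 2)
    }
    tot
  }
  expected <- log(trap(sel) / trap(ns))
  got <- xpehh_per_snp(p)$xpehh[core]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("XP-EHH is antisymmetric under population swap", {
  set.seed(61)
  sel <- matrix(rbinom(50, 1, 0.6), nrow = 5)
  ns <- matrix(rbinom(50, 1, 0.4), nrow = 5)
  p <- toy_panel(sel, ns, positions = (1:10) * 500)
  q <- toy_panel(ns, sel, positions = (1:10) * 500)
  a <- xpehh_per_snp(p)$xpehh
  b <- xpehh_per_snp(q)$xpehh
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("sweep windows show elevated Fst and XP-EHH over replicates", {
  hits_fst <- hits_xp <- logical(10)
  for (s in 1:10) {
    cfg <- sim_config(seed = 100 + s, n_hap_sel = 50, n_hap_ns = 50,
                      n_snp = 500, chrom_length = 5e6, sweep_pos = 2.5e6,
                      sweep_halfwidth = 4e5)
    p <- simulate_two_pop_sweep(cfg)
    st <- snp_stats(p)
    inw <- abs(st$pos - 2.5e6) <= 4e5
    hits_fst[s] <- mean(st$fst[inw], na.rm = TRUE) >
      mean(st$fst[!inw], na.rm = TRUE)
    hits_xp[s] <- mean(st$xpehh[inw], na.rm = TRUE) >
      mean(st$xpehh[!inw], na.rm = TRUE)
  }
  expect_true(all(hits_fst))
  expect_true(all(hits_xp))
})

test_that("snp_stats drops monomorphic-in-both sites and keeps one row per site", {
  sel <- cbind(c(0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L))
  ns <- cbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L))
  p <- toy_panel(sel, ns, positions = c(100, 200))
  st <- snp_stats(p)
  expect_equal(nrow(st), 1)
  expect_equal(st$pos, 200)
})
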