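# Validation-stage association analysis: genotype QC, the 1-df allelic
# chi-square test with odds ratio, a quantitative-trait Wald test with
# a sex covariate, and Bonferroni multiplicity control.

#' Genotype quality control
#'
#' Filters a diploid genotype matrix (samples x SNPs, values 0/1/2
#' copies of allele 1, `NA` = missing) in a fixed order: samples by
#' call rate, then SNPs by call rate, then SNPs by minor allele
#' frequency computed on the surviving samples. Two presets mirror
#' common practice: a scan preset (SNP missingness <= 10%, MAF >=
#' 0.01, no sample filter) and a validation preset (SNP call rate >=
#' 80%, sample call rate >= 90%).
#'
#' @param geno Integer matrix, samples x SNPs, entries 0/1/2/NA.
#' @param snp_call_rate_min Minimum SNP call rate (fraction non-missing).
#' @param sample_call_rate_min Minimum sample call rate.
#' @param maf_min Minimum minor allele frequency.
#' @param preset `"none"`, `"scan"` or `"validation"`; a preset
#'   overrides the three thresholds.
#' @return List with `geno` (filtered matrix) and `report`, a one-row
#'   data.frame: `snps_removed_call_rate`, `samples_removed_call_rate`,
#'   `snps_removed_maf`, `snps_kept`, `samples_kept`.
#' @export
qc_filter <- function(geno, snp_call_rate_min = 0.9,
                      sample_call_rate_min = 0,
                      maf_min = 0.01,
                      preset = c("none", "scan", "validation")) {
  preset <- match.arg(preset)
  if (preset == "scan") {
    snp_call_rate_min <- 0.9; sample_call_rate_min <- 0; maf_min <- 0.01
  } else if (preset == "validation") {
    snp_call_rate_min <- 0.8; sample_call_rate_min <- 0.9; maf_min <- 0
  }
  stopifnot(is.matrix(geno))
  sample_cr <- rowMeans(!is.na(geno))
  keep_sam <- sample_cr >= sample_call_rate_min
  g <- geno[keep_sam, , drop = FALSE]
  snp_cr <- colMeans(!is.na(g))
  keep_cr <- snp_cr >= snp_call_rate_min
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  keep_maf <- maf >= maf_min
  keep_snp <- keep_cr & keep_maf
  if (!any(keep_snp)) stop("QC removed every SNP")
  report <- data.frame(
    snps_removed_call_rate = sum(!keep_cr),
    samples_removed_call_rate = sum(!keep_sam),
    snps_removed_maf = sum(keep_cr & !keep_maf),
    snps_kept = sum(keep_snp),
    samples_kept = sum(keep_sam))
  list(geno = g[, keep_snp, drop = FALSE], report = report)
}

# Core 2x2 allelic chi-square from allele counts
# a = allele 1 in cases, b = allele 2 in cases,
# c = allele 1 in controls, d = allele 2 in controls.
.allelic_core <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chisq <- ifelse(den == 0, NA_real_, num / den)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  # Haldane-Anscombe correction only when a cell is empty
  or <- ifelse(zero,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
               (a * d) / (b * c))
  data.frame(a = a, b = b, c = c, d = d,
             F_A = a / (a + b), F_U = c / (c + d),
             chisq = chisq, p = p, odds_ratio = or,
             or_corrected = zero)
}

#' Allelic case-control association test
#'
#' Builds the 2x2 table of allele counts (each non-missing diploid
#' genotype contributes two alleles), computes the Pearson chi-square
#' without continuity correction, its upper-tail P on 1 df, and the
#' odds ratio `OR = ad/bc` with allele 1 as the exposure allele. When
#' any cell is zero the Haldane-Anscombe +0.5 correction is applied to
#' all four cells for the OR (flagged in `or_corrected`).
#'
#' Counts can be supplied three ways: genotype matrices (`case_geno`,
#' `control_geno`), direct allele counts (`counts`, a 4-column matrix
#' a, b, c, d), or published allele-1 frequencies with cohort sizes
#' (`freq_pairs` with `n_cases`/`n_controls`, counts rounded to the
#' nearest integer).
#'
#' @param case_geno,control_geno Optional genotype matrices
#'   (samples x SNPs, 0/1/2 copies of allele 1, NA allowed).
#' @param counts Optional matrix/data.frame with columns `a`, `b`,
#'   `c`, `d`.
#' @param freq_pairs Optional 2-column matrix of allele-1 frequencies
#'   (cases, controls).
#' @param n_cases,n_controls Diploid cohort sizes (used with
#'   `freq_pairs`).
#' @return data.frame with columns `a`, `b`, `c`, `d`, `F_A`, `F_U`,
#'   `chisq`, `p`, `odds_ratio`, `or_corrected`, one row per SNP.
#' @export
allelic_test <- function(case_geno = NULL, control_geno = NULL,
                         counts = NULL, freq_pairs = NULL,
                         n_cases = NULL, n_controls = NULL) {
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    return(.allelic_core(counts[, 1], counts[, 2], counts[, 3], counts[, 4]))
  }
  if (!is.null(freq_pairs)) {
    if (is.null(n_cases) || is.null(n_controls))
      stop("n_cases and n_controls are required with freq_pairs")
    fp <- as.matrix(freq_pairs)
    a <- round(fp[, 1] * 2 * n_cases)
    c <- round(fp[, 2] * 2 * n_controls)
    return(.allelic_core(a, 2 * n_cases - a, c, 2 * n_controls - c))
  }
  if (is.null(case_geno) || is.null(control_geno))
    stop("supply genotype matrices, counts, or freq_pairs")
  a <- colSums(case_geno, na.rm = TRUE)
  b <- 2 * colSums(!is.na(case_geno)) - a
  c <- colSums(control_geno, na.rm = TRUE)
  d <- 2 * colSums(!is.na(control_geno)) - c
  if (any(a + b == 0) || any(c + d == 0))
    warning("SNP(s) with zero non-missing alleles in a cohort flagged NA")
  .allelic_core(a, b, c, d)
}

#' Quantitative-trait association by Wald test with a sex covariate
#'
#' Ordinary least squares of the trait on the additive genotype
#' (0/1/2) with sex as a covariate; the Wald statistic
#' `(beta / SE)^2` is referred to the chi-square distribution on 1 df
#' (large-sample convention of the standard association tools). A
#' single-sex cohort (collinear covariate) drops the covariate with a
#' warning.
#'
#' @param geno Genotype vector (0/1/2) or samples x SNPs matrix.
#' @param trait Numeric trait vector.
#' @param sex Covariate vector (factor or coded numeric); `NULL` to
#'   omit.
#' @return data.frame with `beta`, `se`, `wald`, `p`, one row per SNP.
#' @export
quantitative_wald <- function(geno, trait, sex = NULL) {
  if (is.vector(geno)) geno <- matrix(geno, ncol = 1)
  res <- lapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    keep <- !is.na(g) & !is.na(trait)
    if (!is.null(sex)) keep <- keep & !is.na(sex)
    if (sum(keep) < 3) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    use_sex <- !is.null(sex)
    if (use_sex && length(unique(sex[keep])) < 2L) {
      warning("sex covariate constant in complete cases; dropped")
      use_sex <- FALSE
    }
    fit <- if (use_sex)
      stats::lm(trait[keep] ~ g[keep] + factor(sex[keep]))
    else stats::lm(trait[keep] ~ g[keep])
    cf <- summary(fit)$coefficients
    if (!"g[keep]" %in% rownames(cf))
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    beta <- cf["g[keep]", 1]; se <- cf["g[keep]", 2]
    w <- (beta / se)^2
    c(beta, se, w, stats::pchisq(w, 1, lower.tail = FALSE))
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("beta", "se", "wald", "p")
  out
}

#' Infer allele counts consistent with a published rounded frequency
#'
#' Published association tables report allele frequencies rounded to a
#' few decimals, computed on the non-missing genotypes at each SNP.
#' Given the frequency and the maximum possible allele count (twice
#' the cohort size), this searches downwards in steps of two alleles
#' (one diploid genotype) for the largest effective count `N` such
#' that `round(round(freq * N) / N, digits)` reproduces the printed
#' frequency exactly; the 2x2 table rebuilt from these counts then
#' reproduces the published odds ratio and chi-square to rounding
#' error. Falls back to plain rounding at `n_max` when no consistent
#' count exists within `max_drop` alleles.
#'
#' @param freq Printed allele-1 frequency.
#' @param n_max Maximum allele count (2 x diploid cohort size).
#' @param digits Decimals the frequency was printed with (default 4).
#' @param max_drop Largest number of alleles assumed missing.
#' @return Named vector `c(k, N)`: allele-1 count and effective total.
#' @export
infer_allele_counts <- function(freq, n_max, digits = 4, max_drop = 60) {
  for (N in seq(n_max, max(n_max - max_drop, 2), by = -2)) {
    k <- round(freq * N)
    if (round(k / N, digits) == freq) return(c(k = k, N = N))
  }
  c(k = round(freq * n_max), N = n_max)
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests in the family (>= 1).
#' @return List with `threshold` (`alpha / n_tests`, full precision)
#'   and `threshold_3sig` (rounded to 3 significant figures, the
#'   conventional reporting precision).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (missing(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha / n_tests
  list(threshold = thr, threshold_3sig = signif(thr, 3))
}
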