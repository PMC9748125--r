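# Synthetic two-population haplotype data with planted sweeps, plus
# case-control panels and differential-expression tables, so the full
# scan -> CSS -> enrichment -> association pipeline can be exercised
# without any external genotype resource.

#' Simulation configuration for the two-population haplotype generator
#'
#' Collects and validates every parameter of [simulate_two_pop_sweep()].
#' All randomness is governed by `seed`; there is no implicit global RNG
#' state.
#'
#' @param n_hap_sel Number of haplotypes in the selected population
#'   (must be even: two phased haplotypes per diploid sample).
#' @param n_hap_ns Number of haplotypes in the non-selected (reference)
#'   population (even).
#' @param n_snp Number of biallelic sites on the single simulated
#'   chromosome (>= 2).
#' @param chrom_length Chromosome length in bp.
#' @param divergence_F Balding-Nichols differentiation parameter in
#'   `[0, 1)`. Population allele frequencies are drawn around a shared
#'   ancestral frequency with variance `p(1-p)*F`, so the expected
#'   Hudson Fst between the populations is approximately `F`.
#' @param ld_copy_prob Probability in `[0, 1]` that, as a haplotype is
#'   generated left to right, a site keeps copying the previously
#'   generated haplotype rather than drawing a fresh allele. Controls
#'   both the amount of haplotype sharing and the decay of linkage
#'   disequilibrium; 0 gives independent sites, 1 makes every haplotype
#'   identical to the first.
#' @param sweep_pos bp position of the planted hard-sweep core, or
#'   `NULL` for no sweep.
#' @param sweep_fraction Fraction in `[0, 1]` of selected-population
#'   haplotypes whose alleles near the core are overwritten by one
#'   founder haplotype.
#' @param sweep_halfwidth Half-width in bp of the overwritten segment
#'   around `sweep_pos`.
#' @param seed Integer random seed (mandatory).
#' @param chrom Chromosome name used in output files.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_hap_sel = 100L, n_hap_ns = 100L, n_snp = 2000L,
                       chrom_length = 1e7, divergence_F = 0.05,
                       ld_copy_prob = 0.3, sweep_pos = NULL,
                       sweep_fraction = 0.9, sweep_halfwidth = 5e5,
                       seed, chrom = "1") {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory and must be a single integer")
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(n_hap_sel >= 2 && n_hap_ns >= 2, "need >= 2 haplotypes per population")
  chk(n_hap_sel %% 2 == 0 && n_hap_ns %% 2 == 0,
      "haplotype counts must be even (diploid samples)")
  chk(n_snp >= 2, "n_snp must be >= 2")
  chk(chrom_length >= n_snp, "chrom_length must be >= n_snp")
  chk(divergence_F >= 0 && divergence_F < 1, "divergence_F must be in [0, 1)")
  chk(ld_copy_prob >= 0 && ld_copy_prob <= 1, "ld_copy_prob must be in [0, 1]")
  chk(sweep_fraction >= 0 && sweep_fraction <= 1,
      "sweep_fraction must be in [0, 1]")
  chk(sweep_halfwidth >= 0, "sweep_halfwidth must be >= 0")
  if (!is.null(sweep_pos))
    chk(sweep_pos >= 1 && sweep_pos <= chrom_length,
        "sweep_pos must lie within [1, chrom_length]")
  structure(list(n_hap_sel = as.integer(n_hap_sel),
                 n_hap_ns = as.integer(n_hap_ns),
                 n_snp = as.integer(n_snp),
                 chrom_length = chrom_length,
                 divergence_F = divergence_F,
                 ld_copy_prob = ld_copy_prob,
                 sweep_pos = sweep_pos,
                 sweep_fraction = sweep_fraction,
                 sweep_halfwidth = sweep_halfwidth,
                 seed = as.integer(seed),
                 chrom = as.character(chrom)),
            class = "sim_config")
}

#' Construct a phased haplotype panel
#'
#' The panel is the substrate for allele-frequency statistics and
#' EHH/XP-EHH: a binary haplotype-by-site matrix with strictly
#' increasing bp positions and a population label per haplotype.
#' Sites monomorphic in both populations are flagged, never dropped.
#'
#' @param chrom Chromosome identifier (scalar).
#' @param positions Integer bp positions, strictly increasing (1-based).
#' @param alleles Binary matrix, haplotypes x sites (0 = reference,
#'   1 = alternate).
#' @param pop_labels Character vector, one of `"selected"` /
#'   `"non_selected"` per haplotype row.
#' @param sample_ids Originating diploid sample id per haplotype
#'   (two consecutive haplotypes share one id by convention).
#'
#' @return An object of class `"haplotype_panel"`: a list with the
#'   fields above plus `monomorphic`, a per-site logical flag.
#' @export
haplotype_panel <- function(chrom, positions, alleles, pop_labels, sample_ids) {
  if (!is.matrix(alleles) || !all(alleles %in% c(0L, 1L)))
    stop("'alleles' must be a strictly binary haplotype x site matrix")
  if (length(positions) != ncol(alleles))
    stop("length(positions) must equal ncol(alleles)")
  if (any(diff(positions) <= 0))
    stop("'positions' must be strictly increasing")
  if (length(pop_labels) != nrow(alleles))
    stop("one population label per haplotype row required")
  if (!all(pop_labels %in% c("selected", "non_selected")))
    stop("pop_labels must be 'selected' or 'non_selected'")
  if (length(sample_ids) != nrow(alleles))
    stop("one sample id per haplotype row required")
  storage.mode(alleles) <- "integer"
  ac <- colSums(alleles)
  mono <- ac == 0L | ac == nrow(alleles)
  structure(list(chrom = as.character(chrom),
                 positions = as.integer(positions),
                 alleles = alleles,
                 pop_labels = as.character(pop_labels),
                 sample_ids = as.character(sample_ids),
                 monomorphic = mono),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel: chrom", x$chrom, "-",
      nrow(x$alleles), "haplotypes x", ncol(x$alleles), "sites\n")
  cat("  selected:", sum(x$pop_labels == "selected"),
      " non_selected:", sum(x$pop_labels == "non_selected"), "\n")
  cat("  positions:", min(x$positions), "-", max(x$positions),
      "bp;", sum(x$monomorphic), "monomorphic site(s)\n")
  invisible(x)
}

# Generate one haplotype as a mosaic of the template (previous
# haplotype) and fresh Bernoulli(p) draws. Copy/fresh mode persists
# along the chromosome with probability `copy_prob` per step, which is
# what induces linkage disequilibrium and haplotype sharing.
.mosaic_hap <- function(template, p, copy_prob) {
  n <- length(p)
  brk <- c(TRUE, stats::runif(n - 1L) >= copy_prob)
  bi <- which(brk)
  mode_copy <- stats::runif(length(bi)) < copy_prob
  copy <- mode_copy[findInterval(seq_len(n), bi)]
  fresh <- stats::rbinom(n, 1L, p)
  ifelse(copy, template, fresh)
}

.sim_population <- function(n_hap, p, copy_prob) {
  H <- matrix(0L, nrow = n_hap, ncol = length(p))
  H[1L, ] <- stats::rbinom(length(p), 1L, p)
  if (n_hap > 1L)
    for (i in 2:n_hap)
      H[i, ] <- .mosaic_hap(H[i - 1L, ], p, copy_prob)
  storage.mode(H) <- "integer"
  H
}

#' Simulate two diverged populations with an optional planted hard sweep
#'
#' Ancestral allele frequencies are drawn uniformly on `[0.05, 0.95]`
#' per site; each population's site frequency follows the
#' Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` when `F > 0` (and equals the
#' ancestral frequency when `F = 0`). Haplotypes are generated left to
#' right with first-order Markov copying from the previously generated
#' haplotype at rate `ld_copy_prob`, which induces linkage
#' disequilibrium. If `sweep_pos` is set, a fraction `sweep_fraction`
#' of selected-population haplotypes have their alleles within
#' `sweep_pos +/- sweep_halfwidth` overwritten by a single founder
#' haplotype ("star-like" hard sweep), creating the long shared
#' haplotype and frequency differential that Fst, dSAF and XP-EHH
#' detect.
#'
#' @param config A [sim_config()] object.
#' @return A [haplotype_panel()]. The drawn ancestral and per-population
#'   frequencies are attached as attributes `p_anc`, `p_sel`, `p_ns`;
#'   the sweep site index range, when a sweep was planted, as
#'   `sweep_sites`.
#' @export
simulate_two_pop_sweep <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  n_snp <- config$n_snp
  positions <- sort(sample.int(config$chrom_length, n_snp))
  p_anc <- stats::runif(n_snp, 0.05, 0.95)
  F <- config$divergence_F
  if (F > 0) {
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    p_sel <- stats::rbeta(n_snp, a, b)
    p_ns  <- stats::rbeta(n_snp, a, b)
  } else {
    p_sel <- p_anc
    p_ns  <- p_anc
  }
  H_sel <- .sim_population(config$n_hap_sel, p_sel, config$ld_copy_prob)
  H_ns  <- .sim_population(config$n_hap_ns,  p_ns,  config$ld_copy_prob)

  sweep_sites <- NULL
  if (!is.null(config$sweep_pos)) {
    in_win <- which(abs(positions - config$sweep_pos) <= config$sweep_halfwidth)
    if (length(in_win) == 0L) {
      warning("sweep window covers zero SNPs; panel returned without sweep")
    } else {
      n_rep <- ceiling(config$sweep_fraction * config$n_hap_sel)
      if (n_rep > 0L) {
        founder <- H_sel[1L, in_win]
        carriers <- sample.int(config$n_hap_sel, n_rep)
        H_sel[carriers, in_win] <- rep(founder, each = n_rep)
        sweep_sites <- range(in_win)
      }
    }
  }

  n_sam_sel <- config$n_hap_sel %/% 2L
  n_sam_ns <- config$n_hap_ns %/% 2L
  sample_ids <- c(rep(sprintf("sel_%03d", seq_len(n_sam_sel)), each = 2L),
                  rep(sprintf("ns_%03d", seq_len(n_sam_ns)), each = 2L))
  panel <- haplotype_panel(
    chrom = config$chrom,
    positions = positions,
    alleles = rbind(H_sel, H_ns),
    pop_labels = c(rep("selected", config$n_hap_sel),
                   rep("non_selected", config$n_hap_ns)),
    sample_ids = sample_ids)
  attr(panel, "p_anc") <- p_anc
  attr(panel, "p_sel") <- p_sel
  attr(panel, "p_ns") <- p_ns
  attr(panel, "sweep_sites") <- sweep_sites
  panel
}

#' Simulate case-control genotype panels at specified allele frequencies
#'
#' Emulates a validation-cohort genotyping panel: for each SNP, an
#' allele-1 frequency is specified separately for cases and controls.
#' In `"stochastic"` mode diploid genotypes are drawn binomially under
#' Hardy-Weinberg at the stated frequency; in `"exact"` mode allele
#' counts match `round(freq * 2n)` as closely as integer genotypes
#' allow (useful to reconstruct 2x2 allele tables from published
#' frequencies).
#'
#' @param freq_pairs Two-column matrix or data.frame: allele-1
#'   frequency in cases and in controls, one row per SNP.
#' @param n_cases,n_controls Diploid sample counts (> 0).
#' @param seed Integer seed (used in stochastic mode).
#' @param mode `"stochastic"` or `"exact"`.
#' @return List of class `"case_control_panel"` with integer genotype
#'   matrices `cases` (`n_cases` x SNPs) and `controls`, values 0/1/2 =
#'   copies of allele 1.
#' @export
simulate_case_control <- function(freq_pairs, n_cases, n_controls, seed = NULL,
                                  mode = c("stochastic", "exact")) {
  mode <- match.arg(mode)
  fp <- as.matrix(freq_pairs)
  if (ncol(fp) != 2L) stop("freq_pairs must have two columns (cases, controls)")
  if (any(fp < 0 | fp > 1)) stop("frequencies must lie in [0, 1]")
  if (n_cases <= 0 || n_controls <= 0) stop("cohort sizes must be positive")
  if (mode == "stochastic") {
    if (is.null(seed)) stop("seed is required in stochastic mode")
    set.seed(seed)
  }
  draw <- function(f, n) {
    if (mode == "stochastic") return(stats::rbinom(n, 2L, f))
    k <- round(f * 2L * n)              # target allele-1 count
    g <- integer(n)
    g[seq_len(k %/% 2L)] <- 2L
    if (k %% 2L == 1L) g[k %/% 2L + 1L] <- 1L
    g
  }
  cases <- vapply(seq_len(nrow(fp)), function(i) draw(fp[i, 1L], n_cases),
                  integer(n_cases))
  controls <- vapply(seq_len(nrow(fp)), function(i) draw(fp[i, 2L], n_controls),
                     integer(n_controls))
  cases <- matrix(as.integer(cases), nrow = n_cases)
  controls <- matrix(as.integer(controls), nrow = n_controls)
  structure(list(cases = cases, controls = controls,
                 freq_pairs = fp, mode = mode),
            class = "case_control_panel")
}

#' Simulate a gene annotation set on one chromosome
#'
#' Uniformly placed, fixed-length-range genes used as the coordinate
#' backbone for DEG tables and enrichment windows.
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param length_range Min/max gene length in bp.
#' @param seed Integer seed.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive).
#' @export
simulate_genes <- function(n_genes, chrom = "1", chrom_length = 1e7,
                           length_range = c(5e3, 5e4), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  len <- round(stats::runif(n_genes, length_range[1L], length_range[2L]))
  start <- sapply(len, function(l) sample.int(max(chrom_length - l, 1L), 1L))
  df <- data.frame(gene_id = sprintf("GENE%04d", seq_len(n_genes)),
                   chrom = chrom, start = as.integer(start),
                   end = as.integer(start + len - 1L),
                   stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

#' Simulate a differentially-expressed-gene table
#'
#' Emits `gene_id`, `padj`, `log2fc` rows for a random subset of the
#' supplied genes. Adjusted P values are drawn log-uniformly within
#' `p_range`, so setting the upper bound to a filtering threshold
#' (e.g. 1e-4) guarantees every emitted gene passes that filter. A
#' subset of the DEGs can be forced to overlap a genomic interval to
#' plant true enrichment for downstream testing.
#'
#' @param genes Gene table from [simulate_genes()] (or any data.frame
#'   with `gene_id`, `chrom`, `start`, `end`).
#' @param n_deg Number of DEGs to emit (<= number of genes).
#' @param p_range Length-2 numeric: min/max adjusted P.
#' @param seed Integer seed.
#' @param force_interval Optional `c(start, end)` bp interval; DEGs are
#'   preferentially chosen among genes overlapping it.
#' @param n_force How many DEGs to place inside `force_interval`
#'   (default: as many as possible, capped at `n_deg`).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `padj`,
#'   `log2fc`.
#' @export
simulate_deg_table <- function(genes, n_deg, p_range = c(1e-8, 1e-4), seed,
                               force_interval = NULL, n_force = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_deg > nrow(genes)) stop("n_deg exceeds the number of genes")
  set.seed(seed)
  if (n_deg == 0L) {
    out <- genes[0, , drop = FALSE]
    out$padj <- numeric(0)
    out$log2fc <- numeric(0)
    return(out)
  }
  idx <- seq_len(nrow(genes))
  if (!is.null(force_interval)) {
    inside <- which(genes$end >= force_interval[1L] &
                    genes$start <= force_interval[2L])
    k <- min(length(inside), n_deg,
             if (is.null(n_force)) n_deg else n_force)
    take_in <- utils::head(sample(inside), k)
    rest <- setdiff(setdiff(idx, take_in),
                    if (is.null(n_force)) integer(0) else inside)
    take <- c(take_in, utils::head(sample(rest), n_deg - length(take_in)))
  } else {
    take <- sample(idx, n_deg)
  }
  out <- genes[sort(take), , drop = FALSE]
  lp <- stats::runif(n_deg, log10(p_range[1L]), log10(p_range[2L]))
  out$padj <- 10^lp * (1 - 1e-12)     # strictly below the upper bound
  out$log2fc <- stats::rnorm(n_deg, 2, 1) * sample(c(-1, 1), n_deg, TRUE)
  rownames(out) <- NULL
  out
}
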