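# Prioritisation of protein-coding variants within candidate regions
# from VEP-style annotated variant tables.

.high_terms <- c("splice_acceptor_variant&intron_variant",
                 "frameshift_variant",
                 "splice_acceptor_variant",
                 "stop_gained")
.moderate_terms <- c("missense_variant", "inframe_deletion")

#' Classify VEP-style consequence terms into effect classes
#'
#' `"high"` covers splice-acceptor (including the combined
#' splice_acceptor_variant&intron_variant annotation), frameshift and
#' stop-gained terms; `"moderate"` covers missense and in-frame
#' deletions; everything else (or an unrecognised term) is `"other"`,
#' with a message for terms never seen in the recognised lists. A
#' variant annotated with several `&`-joined terms is classed by its
#' most severe term.
#'
#' @param terms Character vector of consequence annotations.
#' @return Character vector: `"high"`, `"moderate"` or `"other"`.
#' @export
classify_effect <- function(terms) {
  known <- c(.high_terms, .moderate_terms,
             "synonymous_variant", "intron_variant", "intergenic_variant",
             "upstream_gene_variant", "downstream_gene_variant",
             "3_prime_UTR_variant", "5_prime_UTR_variant",
             "splice_region_variant", "stop_retained_variant",
             "non_coding_transcript_exon_variant")
  one <- function(term) {
    if (is.na(term) || term == "") return("other")
    if (term %in% .high_terms) return("high")      # combined terms first
    parts <- strsplit(term, "&", fixed = TRUE)[[1L]]
    if (any(parts %in% .high_terms)) return("high")
    if (any(parts %in% .moderate_terms)) return("moderate")
    if (!all(parts %in% known))
      message("unrecognised consequence term '", term, "' classed as other")
    "other"
  }
  vapply(terms, one, character(1), USE.NAMES = FALSE)
}

#' Prioritise protein-coding variants within candidate regions
#'
#' A variant passes when every rule holds: it overlaps a candidate
#' region, its effect class is among `classes`, its minor allele
#' frequency is at least `maf_min`, its quality score is at least
#' `qual_min`, it lies in a known gene when `require_known_gene`, and
#' (for indels) the indel is shorter than `max_indel_bp`. The filter
#' is a pure conjunction, so the survivor set does not depend on rule
#' order.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `maf`, `consequence`, `gene_id` (NA/"" for none).
#' @param regions data.frame with `chrom`, `start`, `end` and
#'   optionally `name` (1-based inclusive; use [read_genes_bed()] for
#'   BED input).
#' @param maf_min Minimum minor allele frequency (inclusive,
#'   default 0.1).
#' @param qual_min Minimum variant quality score (default 999, the
#'   typical cap; lower it to admit retained lower-quality calls).
#' @param classes Admissible effect classes.
#' @param require_known_gene Require a gene id.
#' @param max_indel_bp Indels must be shorter than this (exclusive,
#'   default 50 bp).
#' @return List with `variants` (surviving rows plus `effect_class`
#'   and `region`) and `per_region` (region, n_high, n_moderate).
#'   Variants falling in two overlapping regions are counted in each
#'   and flagged in `multi_region`.
#' @export
prioritise_variants <- function(variants, regions, maf_min = 0.1,
                                qual_min = 999,
                                classes = c("high", "moderate"),
                                require_known_gene = TRUE,
                                max_indel_bp = 50) {
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stop("MAF must lie in [0, 0.5]")
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
  r_gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start, regions$end))
  ov <- GenomicRanges::findOverlaps(v_gr, r_gr)
  vi <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)
  region_name <- if (!is.null(regions$name)) regions$name
                 else paste0(regions$chrom, ":", regions$start, "-", regions$end)

  eff <- classify_effect(variants$consequence)
  indel_len <- abs(nchar(variants$alt) - nchar(variants$ref))
  pass <- eff %in% classes &
    variants$maf >= maf_min &
    variants$qual >= qual_min &
    indel_len < max_indel_bp
  if (require_known_gene)
    pass <- pass & !is.na(variants$gene_id) & variants$gene_id != ""

  hit <- pass[vi]
  vi <- vi[hit]; ri <- ri[hit]
  surv_idx <- sort(unique(vi))
  out <- variants[surv_idx, , drop = FALSE]
  out$effect_class <- eff[surv_idx]
  out$region <- vapply(surv_idx, function(i)
    paste(region_name[ri[vi == i]], collapse = ";"), character(1))
  out$multi_region <- vapply(surv_idx, function(i) sum(vi == i) > 1L, logical(1))
  rownames(out) <- NULL

  per_region <- data.frame(region = region_name,
                           n_high = 0L, n_moderate = 0L,
                           stringsAsFactors = FALSE)
  if (length(vi)) {
    tab <- table(factor(region_name[ri], levels = region_name),
                 factor(eff[vi], levels = c("high", "moderate")))
    per_region$n_high <- as.integer(tab[, "high"])
    per_region$n_moderate <- as.integer(tab[, "moderate"])
  }
  list(variants = out, per_region = per_region)
}
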