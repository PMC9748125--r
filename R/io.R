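# Readers and writers for the exchange formats (phased VCF, BED, TSV)
# plus the umbrella pipeline driver. Internal coordinates are 1-based
# inclusive (the R/Bioconductor convention); BED's 0-based half-open
# intervals are converted at the read/write boundary.

#' Write a haplotype panel as a phased diploid VCF
#'
#' One chromosome, biallelic SNVs, GT-only FORMAT with `|`-separated
#' phased genotypes; consecutive haplotype pairs form one diploid
#' sample.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  samples <- unique(panel$sample_ids)
  idx <- lapply(samples, function(s) which(panel$sample_ids == s))
  if (any(lengths(idx) != 2L))
    stop("each sample id must own exactly two haplotypes")
  H <- panel$alleles
  gt <- vapply(idx, function(i) paste0(H[i[1L], ], "|", H[i[2L], ]),
               character(ncol(H)))
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = 1L)
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", panel$chrom, ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(panel$chrom, panel$positions,
                paste0("snp", seq_along(panel$positions)),
                "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the per-sample population label table
#'
#' @param panel A [haplotype_panel()].
#' @param path Output TSV path (columns `sample_id`, `population`).
#' @return `path`, invisibly.
#' @export
write_pop_labels <- function(panel, path) {
  first <- !duplicated(panel$sample_ids)
  utils::write.table(
    data.frame(sample_id = panel$sample_ids[first],
               population = panel$pop_labels[first]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phased diploid VCF into a haplotype panel
#'
#' Keeps biallelic SNVs with fully phased, non-missing genotypes;
#' multiallelic, unphased or incomplete records are skipped and the
#' skip counts reported in a message. Every VCF sample must appear in
#' the population label table.
#'
#' @param path VCF file (one chromosome).
#' @param pop_label_path TSV with columns `sample_id`, `population`
#'   (`selected` / `non_selected`).
#' @return A [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, pop_label_path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  labels <- utils::read.table(pop_label_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stop("no records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  unlabelled <- setdiff(samples, labels$sample_id)
  if (length(unlabelled))
    stop("sample(s) without population label: ",
         paste(unlabelled, collapse = ", "))
  if (length(samples) == 0L) stop("no overlapping samples")

  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1L)
    stop("panel must span a single chromosome; found: ",
         paste(chroms, collapse = ", "))
  snv <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  phased <- apply(gt, 1L, function(r)
    all(grepl("^[01]\\|[01]$", r)))
  keep <- snv & phased
  n_skip_multi <- sum(!snv)
  n_skip_unphased <- sum(snv & !phased)
  if (n_skip_multi || n_skip_unphased)
    message("skipped ", n_skip_multi, " non-biallelic-SNV and ",
            n_skip_unphased, " unphased/incomplete record(s)")
  if (!any(keep)) stop("no usable phased biallelic SNV records")

  gt <- gt[keep, , drop = FALSE]
  pos <- as.integer(fix[keep, "POS"])
  o <- order(pos)
  gt <- gt[o, , drop = FALSE]; pos <- pos[o]
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  alleles <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(gt))
  alleles[seq(1L, by = 2L, length.out = length(samples)), ] <- t(h1)
  alleles[seq(2L, by = 2L, length.out = length(samples)), ] <- t(h2)
  pops <- labels$population[match(samples, labels$sample_id)]
  haplotype_panel(chrom = chroms,
                  positions = pos,
                  alleles = alleles,
                  pop_labels = rep(pops, each = 2L),
                  sample_ids = rep(samples, each = 2L))
}

#' Read a BED file of genes/regions into 1-based inclusive coordinates
#'
#' @param path BED path (0-based half-open; columns chrom, start, end,
#'   optionally name).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and `name`.
#' @export
read_genes_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns")
  data.frame(chrom = as.character(bed[[1L]]),
             start = bed[[2L]] + 1L,
             end = bed[[3L]],
             name = if (ncol(bed) >= 4L) as.character(bed[[4L]])
                    else paste0("region", seq_len(nrow(bed))),
             stringsAsFactors = FALSE)
}

#' Write genes/regions (1-based inclusive) as BED (0-based half-open)
#'
#' @param regions data.frame with `chrom`, `start`, `end` and an
#'   optional name column (`gene_id` or `name`).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(regions, path) {
  name <- if (!is.null(regions$gene_id)) regions$gene_id
          else if (!is.null(regions$name)) regions$name
          else paste0("region", seq_len(nrow(regions)))
  utils::write.table(
    data.frame(regions$chrom, regions$start - 1L, regions$end, name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a TSV with a header (shared tabular exchange format)
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.pipeline_defaults <- function() list(
  out_dir = ".",
  simulate = list(n_hap_sel = 100L, n_hap_ns = 100L, n_snp = 2000L,
                  chrom_length = 1e7, divergence_F = 0.05,
                  ld_copy_prob = 0.3, sweep_pos = NULL,
                  sweep_fraction = 0.9, sweep_halfwidth = 5e5,
                  seed = NULL, chrom = "1"),
  stats = list(ehh_cutoff = 0.05, fst_estimator = "hudson",
               dsaf_absolute = FALSE),
  css = list(window_bp = 1e6, top_fraction = 0.01, min_snps = 5),
  enrich = list(enabled = FALSE, n_genes = 100L, n_deg = 10L,
                deg_p_max = 1e-4, widths = seq(1e4, 1e5, 1e4),
                q_threshold = 0.05, n_null = 1000L, seed = NULL)
)

#' Read and validate a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; every stochastic stage must carry an
#' explicit seed.
#'
#' @param path YAML file, or a list with the same structure.
#' @return Validated configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  def <- .pipeline_defaults()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  for (sec in intersect(names(cfg), setdiff(names(def), "out_dir"))) {
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad)) stop("unknown key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
    def[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  if (!is.null(cfg$out_dir)) def$out_dir <- cfg$out_dir
  if (is.null(def$simulate$seed))
    stop("simulate stage requires an explicit seed")
  if (isTRUE(def$enrich$enabled) && is.null(def$enrich$seed))
    stop("enrich stage requires an explicit seed")
  structure(def, class = "pipeline_config")
}

#' Run the full pipeline: simulate, scan, CSS, clusters, enrichment
#'
#' Executes the enabled stages in order, writing each stage's tabular
#' outputs plus a JSON run manifest (parameters, seeds, input
#' checksums, package version) into `out_dir`. Rerunning with the same
#' configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()] (or path to its YAML file).
#' @return The output directory, invisibly; the manifest lists the
#'   files written.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  files <- character(0)

  sc <- do.call(sim_config, cfg$simulate)
  panel <- simulate_two_pop_sweep(sc)
  write_panel_vcf(panel, out("panel.vcf"))
  write_pop_labels(panel, out("pop_labels.tsv"))
  files <- c(files, "panel.vcf", "pop_labels.tsv")

  st <- snp_stats(panel, ehh_cutoff = cfg$stats$ehh_cutoff,
                  fst_estimator = cfg$stats$fst_estimator,
                  dsaf_absolute = cfg$stats$dsaf_absolute)
  write_tsv(st, out("snp_stats.tsv"))
  files <- c(files, "snp_stats.tsv")

  css <- smooth_css(css_scores(st), window_bp = cfg$css$window_bp)
  write_tsv(css, out("css.tsv"))
  cl <- call_clusters(css, top_fraction = cfg$css$top_fraction,
                      min_snps = cfg$css$min_snps,
                      merge_gap_bp = cfg$css$window_bp)
  write_tsv(cl[setdiff(names(cl), "members")], out("clusters.tsv"))
  if (nrow(cl)) write_genes_bed(cl, out("clusters.bed"))
  files <- c(files, "css.tsv", "clusters.tsv")

  if (isTRUE(cfg$enrich$enabled)) {
    genes <- simulate_genes(cfg$enrich$n_genes, chrom = sc$chrom,
                            chrom_length = sc$chrom_length,
                            seed = cfg$enrich$seed)
    force_int <- if (!is.null(sc$sweep_pos))
      c(sc$sweep_pos - sc$sweep_halfwidth, sc$sweep_pos + sc$sweep_halfwidth)
    deg <- simulate_deg_table(genes, cfg$enrich$n_deg,
                              p_range = c(1e-8, cfg$enrich$deg_p_max),
                              seed = cfg$enrich$seed,
                              force_interval = force_int)
    write_genes_bed(genes, out("genes.bed"))
    write_tsv(deg[c("gene_id", "padj", "log2fc")], out("deg.tsv"))
    sweep <- window_sweep(css, deg, widths = cfg$enrich$widths,
                          q_threshold = cfg$enrich$q_threshold,
                          n_null = cfg$enrich$n_null,
                          seed = cfg$enrich$seed)
    if (!is.null(sweep)) {
      write_tsv(sweep$per_width, out("enrichment_per_width.tsv"))
      sel <- sweep$selected
      sel_target <- collect_target_snps(css, deg, sweep$selected_width)
      snp_q <- sel_target$snps
      snp_q$q <- as.numeric(sel$q)
      write_tsv(snp_q[c("chrom", "pos", "p", "q")], out("enrichment_snps.tsv"))
      write_tsv(sel$per_gene, out("enrichment_per_gene.tsv"))
      files <- c(files, "enrichment_per_width.tsv", "enrichment_snps.tsv",
                 "enrichment_per_gene.tsv", "genes.bed", "deg.tsv")
    }
  }

  manifest <- list(
    package = "compsel",
    version = as.character(utils::packageVersion("compsel")),
    config = unclass(cfg),
    files = files,
    checksums = as.list(tools::md5sum(file.path(cfg$out_dir, files))))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(cfg$out_dir)
}
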