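#' Run the full ASE detection pipeline on a VCF file
#'
#' Reads a multi-sample VCF, runs [ase_detect()], and writes the standard
#' report files to an output directory: `accounting.tsv` (filter waterfall),
#' `informative.tsv` (one row per informative SNP with its testable-sample
#' count), `meta_ase.tsv` (per-variant meta-analysis), `mdfdr_variants.tsv`
#' and `mdfdr_samples.tsv` (two-stage mdFDR), and `ase_frequency.tsv`
#' (decile binning of per-variant ASE frequency; written only when the
#' mdFDR model runs). Outputs are deterministic: identical inputs and
#' configuration produce byte-identical files.
#'
#' @param vcf Path to a VCF file (or an `ase_vcf` object).
#' @param out_dir Output directory; created if absent.
#' @param cfg A [filter_config()].
#' @param alpha FDR level (default 0.05).
#' @param model `"both"` (default), `"meta"` or `"mdfdr"`.
#' @param screen mdFDR screening statistic (see [ase_mdfdr()]).
#' @param denominator ASE-frequency denominator (see [ase_frequency()]).
#' @return Invisibly, the `ase_fit` object.
#' @export
run_ase_pipeline <- function(vcf, out_dir, cfg = filter_config(),
                             alpha = 0.05,
                             model = c("both", "meta", "mdfdr"),
                             screen = c("sidak_min", "fisher"),
                             denominator = c("testable", "total")) {
  model <- match.arg(model)
  screen <- match.arg(screen)
  denominator <- match.arg(denominator)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fit <- ase_detect(vcf, cfg = cfg, alpha = alpha, model = model,
                    screen = screen)
  params <- c(alpha = alpha, model = model,
              indel_distance = cfg$indel_distance, min_qual = cfg$min_qual,
              min_depth = cfg$min_depth,
              min_minor_fraction = cfg$min_minor_fraction,
              prefilter = tolower(as.character(cfg$prefilter_enabled)))
  out <- function(name) file.path(out_dir, name)
  write_report(fit$accounting, out("accounting.tsv"), params = params)
  inf <- fit$informative
  inf_df <- data.frame(inf$sites[c("chrom", "pos", "id", "ref", "alt",
                                   "qual", "key")],
                       k = rowSums(inf$testable), stringsAsFactors = FALSE)
  write_report(inf_df, out("informative.tsv"), params = params)
  if (!is.null(fit$meta))
    write_report(as.data.frame(fit$meta), out("meta_ase.tsv"),
                 params = params)
  if (!is.null(fit$mdfdr)) {
    write_report(fit$mdfdr$variants, out("mdfdr_variants.tsv"),
                 params = params)
    write_report(fit$mdfdr$samples, out("mdfdr_samples.tsv"),
                 params = params)
    freq <- ase_frequency(fit$mdfdr, denominator = denominator,
                          n_total = length(inf$samples))
    write_report(freq$summary, out("ase_frequency.tsv"), params = params)
  }
  invisible(fit)
}

#' Combine per-tissue pipeline runs
#'
#' Takes two or more output directories of [run_ase_pipeline()] (one per
#' tissue, run independently as separate VCFs), computes overlap counts of
#' informative and ASE variant keys across runs (Venn-style region counts),
#' and, when an annotation table is supplied, per-tissue normalized gene ASE
#' scores plus the cross-tissue global score.
#'
#' @param run_dirs Named character vector of >= 2 run directories.
#' @param annotation Optional data.frame with `variant_key` and `gene_id`
#'   columns (see [gene_ase_scores()]).
#' @param out_dir Optional directory for `overlap.tsv` (and
#'   `global_gene_scores.tsv` when annotation is given).
#' @return A list with `overlap` (data.frame: region membership pattern and
#'   counts for informative and ASE sets), `gene_scores` (per-tissue list or
#'   NULL) and `global_scores` (or NULL).
#' @export
combine_runs <- function(run_dirs, annotation = NULL, out_dir = NULL) {
  stopifnot(length(run_dirs) >= 2L)
  if (is.null(names(run_dirs)))
    names(run_dirs) <- paste0("run", seq_along(run_dirs))
  inf_keys <- lapply(run_dirs, function(d)
    read_report(file.path(d, "informative.tsv"))$key)
  meta <- lapply(run_dirs, function(d)
    read_report(file.path(d, "meta_ase.tsv")))
  ase_keys <- lapply(meta, function(m) m$key[m$is_ase])
  region_counts <- function(key_sets) {
    all_keys <- unique(unlist(key_sets))
    member <- vapply(key_sets, function(k) all_keys %in% k,
                     logical(length(all_keys)))
    if (is.null(dim(member))) member <- matrix(member, nrow = 1)
    pattern <- apply(member, 1L, function(r)
      paste(names(key_sets)[r], collapse = "&"))
    tab <- table(pattern)
    data.frame(region = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  ov_inf <- region_counts(inf_keys)
  ov_ase <- region_counts(ase_keys)
  names(ov_inf)[2] <- "informative"
  names(ov_ase)[2] <- "ase"
  overlap <- merge(ov_inf, ov_ase, by = "region", all = TRUE)
  overlap[is.na(overlap)] <- 0L
  overlap <- overlap[order(overlap$region), , drop = FALSE]
  rownames(overlap) <- NULL
  gene_scores <- global_scores <- NULL
  if (!is.null(annotation)) {
    gene_scores <- Map(function(inf, ase)
      gene_ase_scores(annotation, inf, ase), inf_keys, ase_keys)
    global_scores <- global_gene_scores(gene_scores)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_report(overlap, file.path(out_dir, "overlap.tsv"))
    if (!is.null(global_scores))
      write_report(global_scores$scores,
                   file.path(out_dir, "global_gene_scores.tsv"))
  }
  list(overlap = overlap, gene_scores = gene_scores,
       global_scores = global_scores)
}
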