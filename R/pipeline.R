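# One-shot pipeline driver: detect + empirical -> merge -> validate ->
# boundaries (-> pseudosequences -> dS -> dating), with per-stage TSV
# outputs and a machine-readable run summary.

#' Default pipeline configuration
#'
#' Paths are `NULL` (stages needing them are skipped); parameters default to
#' the package's standard values (posterior threshold 0.6, clock
#' `mu = 7e-9`, the usual variant filters).
#'
#' @return a named list; override entries via [run_pipeline]'s `config`.
#' @export
default_config <- function() {
  list(vcf = NULL, design = NULL, panel_vcf = NULL, panel_design = NULL,
       fasta = NULL, gff = NULL, out_dir = ".",
       threshold = 0.6,
       het_varfreq_min = 0.25, het_varfreq_max = 0.75,
       max_cov_factor = 2, maf_min = 0.05, max_missing_rate = 0.2,
       max_missing_calls = 2,
       epsilon0 = 0.02, tol = 1e-8, max_iter = 500,
       mu = 7e-9, generation_time_years = c(5, 10, 52.5),
       restrict_empirical_to_locus = TRUE)
}

.read_config <- function(config) {
  base <- default_config()
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  modifyList(base, config)
}

#' Run the full sex-locus pipeline
#'
#' Executes, in order: load + filter the family VCF; probabilistic
#' detection (EM fit, posterior classification); empirical detection; merge
#' of the two SNP sets; panel validation (when a panel VCF is given); locus
#' boundary calling; and, when a reference FASTA and GFF3 are given,
#' pseudosequence construction, NG86 dS estimation and clock dating.
#' Per-stage TSVs and a JSON run summary are written to `out_dir`.
#'
#' @param config a named list overriding [default_config] entries, or the
#'   path to a YAML file of the same shape. `vcf` and `design` are
#'   required.
#' @return the run summary (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- .read_config(config)
  if (is.null(cfg$vcf) || is.null(cfg$design))
    stop("config must provide 'vcf' and 'design'", call. = FALSE)
  if (!is.null(cfg$gff) && is.null(cfg$fasta))
    stop("dS stage requested (gff set) but no reference fasta given",
         call. = FALSE)
  for (p in c("vcf", "design", "panel_vcf", "panel_design", "fasta",
              "gff")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input file not found: ", cfg[[p]], call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  summary <- list(package_version =
                    as.character(utils::packageVersion("xylink")),
                  config = cfg[!vapply(cfg, is.null, logical(1))])

  design <- read_sample_design(cfg$design)
  table <- read_family_vcf(cfg$vcf, design)
  summary$n_sites_loaded <- nrow(table$sites)
  table <- filter_variants(table, cfg$het_varfreq_min, cfg$het_varfreq_max,
                           cfg$max_cov_factor, cfg$maf_min,
                           cfg$max_missing_rate)
  summary$filter <- attr(table, "filter_log")

  fit <- fit_em(table, epsilon0 = cfg$epsilon0, tol = cfg$tol,
                max_iter = cfg$max_iter)
  write.table(fit$posterior, out("posteriors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$em <- list(epsilon = fit$epsilon, pi = as.list(fit$pi),
                     n_iter = fit$n_iter, converged = fit$converged)
  prob <- classify_sex_linked(fit, cfg$threshold)
  write_snp_table(prob, out("xy_probabilistic.tsv"))
  summary$n_probabilistic <- nrow(prob)

  region <- if (cfg$restrict_empirical_to_locus && nrow(prob) > 0) {
    b <- locus_boundaries(prob, validated_only = FALSE)
    b[which.max(tapply(prob$chrom, prob$chrom, length)[b$chrom]), ,
      drop = FALSE]
  } else NULL
  emp <- empirical_xy_filter(table, cfg$max_missing_calls, region)
  write_snp_table(emp, out("xy_empirical.tsv"))
  summary$n_empirical <- nrow(emp)

  merged <- merge_snp_sets(prob, emp)
  write_snp_table(merged, out("xy_merged.tsv"))
  summary$merge <- attr(merged, "merge_report")

  if (!is.null(cfg$panel_vcf)) {
    pdesign <- read_sample_design(cfg$panel_design)
    panel <- read_family_vcf(cfg$panel_vcf, pdesign)
    merged <- validate_xy_snps(merged, panel)
    write_snp_table(merged, out("xy_validated.tsv"))
    summary$n_validated <- sum(merged$validated)
    bounds <- locus_boundaries(merged, validated_only = TRUE)
  } else {
    bounds <- locus_boundaries(merged, validated_only = FALSE)
  }
  write.table(bounds, out("locus_boundaries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_locus_bed(bounds, out("locus_boundaries.bed"))
  summary$boundaries <- as.list(bounds[1, ])

  if (!is.null(cfg$gff)) {
    models <- read_cds_gff(cfg$gff)
    ref <- Biostrings::readDNAStringSet(cfg$fasta)
    use <- if (summary_has <- !is.null(summary$n_validated))
      merged[merged$validated, , drop = FALSE] else merged
    class(use) <- class(merged)
    estimates <- lapply(models, function(m) {
      pair <- build_pseudosequences(ref, m, use)
      ng86_divergence(pair)
    })
    est_df <- do.call(rbind, lapply(estimates, function(e)
      data.frame(gene_id = e$gene_id, dS = e$dS, se_dS = e$se_dS,
                 dN = e$dN, se_dN = e$se_dN, S = e$S, N = e$N,
                 Sd = e$Sd, Nd = e$Nd, saturated = e$saturated)))
    write.table(est_df, out("divergence.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ds <- summarize_ds(estimates)
    ages <- clock_age(ds$mean, cfg$generation_time_years, cfg$mu)
    summary$ds <- ds
    summary$ages_years <- as.list(setNames(
      ages, paste0("g", cfg$generation_time_years)))
  }

  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
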