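# Family-cross I/O: sample design, genotype tables, VCF reading and the
# post-call variant filters.

GT_STATES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)

#' Describe the samples of a cross / validation panel
#'
#' Builds and validates the sample-design table: one row per sample with its
#' role in the experiment and its sex.
#'
#' @param sample_id character vector of sample names (must match VCF header).
#' @param role one of `"mother"`, `"father"`, `"offspring"`, `"panel"` per
#'   sample.
#' @param sex one of `"female"`, `"male"`, `"hermaphrodite"`, `"unknown"` per
#'   sample. Offspring must be sexed (`"female"` or `"male"`).
#' @return a `data.frame` of class `sample_design`.
#' @examples
#' sample_design(
#'   c("mom", "dad", "d1", "s1"),
#'   c("mother", "father", "offspring", "offspring"),
#'   c("female", "male", "female", "male")
#' )
#' @export
sample_design <- function(sample_id, role, sex) {
  role <- match.arg(role, c("mother", "father", "offspring", "panel"),
                    several.ok = TRUE)
  sex <- match.arg(sex, c("female", "male", "hermaphrodite", "unknown"),
                   several.ok = TRUE)
  stopifnot(length(sample_id) == length(role), length(role) == length(sex))
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id in design")
  d <- data.frame(sample_id = as.character(sample_id), role = role, sex = sex,
                  stringsAsFactors = FALSE)
  if (any(d$role == "offspring")) {
    if (sum(d$role == "mother") != 1L || sum(d$role == "father") != 1L)
      stop("a cross with offspring needs exactly one mother and one father")
    if (!all(d$sex[d$role == "offspring"] %in% c("female", "male")))
      stop("every offspring must be sexed female or male")
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample design from a 3-column TSV
#'
#' Expects columns `sample_id`, `role`, `sex` (header optional comment
#' prefix `#` is stripped).
#'
#' @param path path to the TSV file.
#' @return a [sample_design] table.
#' @export
read_sample_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "")
  names(d)[1] <- sub("^#\\s*", "", names(d)[1])
  names(d) <- sub("^X\\.", "", names(d))
  stopifnot(all(c("sample_id", "role", "sex") %in% names(d)))
  sample_design(d$sample_id, d$role, d$sex)
}

#' Construct a genotype table
#'
#' The central container of the package: biallelic SNP sites by samples, with
#' four-state genotype calls and optional per-allele read depths.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` (single bases, ref != alt).
#' @param samples a [sample_design] table.
#' @param genotypes integer matrix, sites x samples, coded `0` = hom ref,
#'   `1` = het, `2` = hom alt, `NA` = missing.
#' @param ref_depth,alt_depth optional non-negative integer matrices of the
#'   same dimension with per-allele read depths.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(sites, samples, genotypes,
                           ref_depth = NULL, alt_depth = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases))
    stop("alleles must be single bases A/C/G/T")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(nrow(genotypes) == nrow(sites),
            ncol(genotypes) == nrow(samples))
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be coded 0/1/2/NA")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  genotypes <- genotypes[ord, , drop = FALSE]
  if (!is.null(ref_depth)) {
    ref_depth <- as.matrix(ref_depth)[ord, , drop = FALSE]
    alt_depth <- as.matrix(alt_depth)[ord, , drop = FALSE]
    storage.mode(ref_depth) <- "integer"
    storage.mode(alt_depth) <- "integer"
    stopifnot(all(dim(ref_depth) == dim(genotypes)),
              all(dim(alt_depth) == dim(genotypes)))
  }
  rownames(sites) <- NULL
  colnames(genotypes) <- samples$sample_id
  structure(list(sites = sites, samples = samples, genotypes = genotypes,
                 ref_depth = ref_depth, alt_depth = alt_depth),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples (%s depths)\n",
              nrow(x$sites), nrow(x$samples),
              if (is.null(x$ref_depth)) "no" else "with"))
  roles <- table(x$samples$role)
  cat("  samples:", paste(names(roles), roles, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$sites), nrow(x$samples))

.gt_code <- function(gt) {
  # map VCF GT strings to 0/1/2/NA (biallelic, unphased or phased)
  gt <- gsub("\\|", "/", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% "1/1"] <- 2L
  out
}

#' Read a family-cross VCF into a genotype table
#'
#' Loads biallelic SNP records from a VCF v4.x file with `GT` and (if
#' present) `AD` per-sample fields. Multiallelic and non-SNP records are
#' dropped and counted in a message.
#'
#' @param vcf_path path to a VCF file.
#' @param design a [sample_design]; every `sample_id` must be present in the
#'   VCF header.
#' @return a [genotype_table] restricted to the design samples, in design
#'   order.
#' @export
read_family_vcf <- function(vcf_path, design) {
  stopifnot(inherits(design, "sample_design"))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(design$sample_id, vcf_samples)
  if (length(missing))
    stop("design sample(s) absent from VCF: ", paste(missing, collapse = ", "))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  keep <- fix$REF %in% bases & fix$ALT %in% bases
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " non-biallelic-SNP record(s) dropped")
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  G <- apply(gt_raw[, design$sample_id, drop = FALSE], 2, .gt_code)
  G <- matrix(as.integer(G), nrow = nrow(fix),
              dimnames = list(NULL, design$sample_id))
  has_ad <- any(grepl("AD", unlist(strsplit(v@gt[, "FORMAT"], ":"))))
  rd <- ad <- NULL
  if (has_ad) {
    ad_raw <- vcfR::extract.gt(v, element = "AD")[, design$sample_id,
                                                  drop = FALSE]
    split2 <- function(x, i) {
      p <- vapply(strsplit(x, ","), function(z)
        suppressWarnings(as.integer(z[i])), integer(1))
      p[is.na(p)] <- 0L
      p
    }
    rd <- apply(ad_raw, 2, split2, i = 1L)
    ad <- apply(ad_raw, 2, split2, i = 2L)
    rd <- matrix(as.integer(rd), nrow = nrow(fix))
    ad <- matrix(as.integer(ad), nrow = nrow(fix))
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_table(sites, design, G, rd, ad)
}

#' Modal per-sample sequencing depth
#'
#' The per-sample coverage mode used by the maximum-coverage filter: the
#' argmax of the integer total-depth histogram (zero depths excluded) after
#' smoothing with a centered moving average.
#'
#' @param table a [genotype_table] with depths.
#' @param sample_id which sample.
#' @param window width of the centered moving-average smoother (odd integer).
#' @return the modal depth (positive number). Ties break toward the smaller
#'   depth.
#' @export
coverage_mode <- function(table, sample_id, window = 5L) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(table$ref_depth))
    stop("depth-dependent filter requested but the table has no depths ",
         "(VCF lacked an AD field?)")
  j <- match(sample_id, table$samples$sample_id)
  if (is.na(j)) stop("unknown sample: ", sample_id)
  tot <- table$ref_depth[, j] + table$alt_depth[, j]
  tot <- tot[!is.na(tot) & tot > 0]
  if (!length(tot)) stop("no coverage for sample ", sample_id)
  h <- tabulate(tot, nbins = max(tot))
  k <- (window - 1L) %/% 2L
  padded <- c(rep(0, k), h, rep(0, k))
  sm <- vapply(seq_along(h), function(i) mean(padded[i:(i + 2L * k)]),
               numeric(1))
  # smoothing can plateau around an isolated peak: break smoothed ties by
  # the raw count, then toward the smaller depth
  cand <- which(sm >= max(sm) - 1e-12)
  cand[which.max(h[cand])]
}

#' Post-call variant filters for a family genotype table
#'
#' Applies, in order: (1) heterozygous calls with an alt-read fraction
#' outside `[het_varfreq_min, het_varfreq_max]` are set to missing; (2) calls
#' with total depth above `max_cov_factor` times the per-sample
#' [coverage_mode] are set to missing; (3) sites with minor allele frequency
#' `<= maf_min` (alleles counted over called genotypes) are removed;
#' (4) sites with a missing-call rate `> max_missing_rate` are removed.
#'
#' @param table a [genotype_table] with depths.
#' @param het_varfreq_min,het_varfreq_max allowed alt-read fraction range for
#'   heterozygote calls (defaults 0.25 / 0.75).
#' @param max_cov_factor maximum total depth as a multiple of the per-sample
#'   coverage mode (default 2).
#' @param maf_min sites with minor allele frequency at or below this are
#'   dropped (default 0.05).
#' @param max_missing_rate maximum tolerated fraction of missing genotype
#'   calls per site (default 0.2).
#' @return the filtered [genotype_table]; per-rule removal counts are in
#'   `attr(, "filter_log")` and reported via `message()`.
#' @export
filter_variants <- function(table, het_varfreq_min = 0.25,
                            het_varfreq_max = 0.75, max_cov_factor = 2,
                            maf_min = 0.05, max_missing_rate = 0.2) {
  stopifnot(inherits(table, "genotype_table"),
            het_varfreq_min >= 0, het_varfreq_min < het_varfreq_max,
            het_varfreq_max <= 1, maf_min >= 0, maf_min <= 0.5,
            max_missing_rate >= 0, max_missing_rate <= 1)
  if (is.null(table$ref_depth))
    stop("depth-dependent filters need per-allele depths ",
         "(VCF lacked an AD field?)")
  G <- table$genotypes
  tot <- table$ref_depth + table$alt_depth

  # rule 1: het calls outside the allowed alt-read fraction become missing
  frac <- ifelse(tot > 0, table$alt_depth / tot, NA)
  bad_het <- !is.na(G) & G == 1L & !is.na(frac) &
    (frac < het_varfreq_min | frac > het_varfreq_max)
  G[bad_het] <- NA_integer_

  # rule 2: excessive coverage (> factor x per-sample mode) becomes missing
  modes <- vapply(table$samples$sample_id,
                  function(s) coverage_mode(table, s), numeric(1))
  too_deep <- sweep(tot, 2, max_cov_factor * modes, ">") & !is.na(G)
  too_deep[is.na(too_deep)] <- FALSE
  G[too_deep] <- NA_integer_

  # rule 3: minor allele frequency over called alleles
  called <- rowSums(!is.na(G))
  alt_count <- rowSums(G, na.rm = TRUE)
  f_alt <- ifelse(called > 0, alt_count / (2 * called), NA)
  maf <- pmin(f_alt, 1 - f_alt)
  keep_maf <- !is.na(maf) & maf > maf_min

  # rule 4: missing-call rate
  miss_rate <- rowMeans(is.na(G))
  keep_miss <- miss_rate <= max_missing_rate
  keep <- keep_maf & keep_miss

  log <- list(het_freq_masked = sum(bad_het),
              high_cov_masked = sum(too_deep),
              maf_removed = sum(!keep_maf),
              missing_removed = sum(keep_maf & !keep_miss),
              sites_kept = sum(keep))
  message(sprintf(
    "filter_variants: masked %d het-fraction + %d high-coverage calls; removed %d sites (MAF) + %d sites (missing); %d sites kept",
    log$het_freq_masked, log$high_cov_masked, log$maf_removed,
    log$missing_removed, log$sites_kept))
  out <- genotype_table(table$sites[keep, , drop = FALSE], table$samples,
                        G[keep, , drop = FALSE],
                        table$ref_depth[keep, , drop = FALSE],
                        table$alt_depth[keep, , drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

#' Write a genotype table or XY-SNP set to TSV
#'
#' Tab-separated with a `#`-prefixed header line; round-trips through
#' [read_snp_table].
#'
#' @param x a [genotype_table] or an [xy_snp_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(x, path) {
  if (inherits(x, "xy_snp_set")) {
    df <- as.data.frame(x)
    type <- "xy_snp_set"
  } else if (inherits(x, "genotype_table")) {
    gt_txt <- matrix(c("0/0", "0/1", "1/1")[x$genotypes + 1L],
                     nrow = nrow(x$sites))
    gt_txt[is.na(x$genotypes)] <- "./."
    colnames(gt_txt) <- x$samples$sample_id
    df <- cbind(x$sites, as.data.frame(gt_txt, stringsAsFactors = FALSE))
    type <- "genotype_table"
  } else stop("unsupported object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#xylink\ttype=", type), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_snp_table]
#'
#' @param path the TSV file.
#' @param design required to rebuild a `genotype_table` (ignored for SNP
#'   sets).
#' @return an [xy_snp_set] or [genotype_table], matching what was written.
#' @export
read_snp_table <- function(path, design = NULL) {
  lines <- readLines(path)
  type <- sub(".*type=", "", lines[1])
  header <- strsplit(sub("^#", "", lines[2]), "\t")[[1]]
  body <- lines[-(1:2)]
  if (length(body)) {
    df <- read.delim(text = body, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- header
  } else {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                 header))
  }
  if (type == "xy_snp_set") {
    df$pos <- as.integer(df$pos)
    if (nrow(df)) df$validated <- as.logical(df$validated)
    return(xy_snp_set(df))
  }
  if (is.null(design)) stop("a sample design is needed to rebuild a ",
                            "genotype_table")
  gcols <- as.matrix(df[, design$sample_id, drop = FALSE])
  G <- matrix(.gt_code(gcols), nrow = nrow(df))
  genotype_table(df[, c("chrom", "pos", "ref", "alt")], design, G)
}
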