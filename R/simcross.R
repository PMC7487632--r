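# Synthetic family crosses: diploid genotypes under autosomal, fully
# XY-linked and X-hemizygous segregation, with per-allele genotyping error,
# missing calls, read depths, and allele-specific expression counts.

#' Simulation configuration for a family cross
#'
#' Defaults emulate the study design the package targets: two parents plus
#' five offspring of each sex, a contiguous sex-linked region of 400 XY
#' SNPs, 100 X-hemizygous SNPs inside it, and 4500 autosomal SNPs, with a
#' 2\% per-allele genotyping-error rate.
#'
#' @param n_offspring_per_sex offspring of each sex (default 5).
#' @param n_autosomal_snps autosomal sites (default 4500), placed on
#'   `"chr1"`.
#' @param n_xy_snps fully sex-linked sites (default 400), contiguous on
#'   `xy_chrom` from `xy_start` with spacing `xy_spacing`.
#' @param n_xhemi_snps X-hemizygous sites (default 100), interleaved inside
#'   the sex-linked region.
#' @param epsilon_true per-allele genotyping-error probability
#'   (default 0.02).
#' @param missing_rate per-call missing probability (default 0.05).
#' @param allele_freq_distribution function(n) returning n alternate-allele
#'   frequencies for parental draws (default `runif(n, 0.1, 0.9)`).
#' @param xy_chrom,xy_start,xy_spacing placement of the sex-linked region
#'   (defaults chr2, 4,810,929 bp, 278 bp spacing: a ~111 kb locus).
#' @param depth_mean,depth_size negative-binomial read-depth model per call
#'   (defaults mean 20, size 10).
#' @param rng_seed mandatory integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_offspring_per_sex = 5L, n_autosomal_snps = 4500L,
                       n_xy_snps = 400L, n_xhemi_snps = 100L,
                       epsilon_true = 0.02, missing_rate = 0.05,
                       allele_freq_distribution = function(n)
                         runif(n, 0.1, 0.9),
                       xy_chrom = "chr2", xy_start = 4810929L,
                       xy_spacing = 278L, depth_mean = 20, depth_size = 10,
                       rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  stopifnot(n_offspring_per_sex >= 1, n_autosomal_snps >= 0,
            n_xy_snps >= 0, n_xhemi_snps >= 0,
            epsilon_true >= 0, epsilon_true < 0.5,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

.sim_design <- function(n_per_sex) {
  sample_design(
    c("mother", "father",
      paste0("daughter", seq_len(n_per_sex)),
      paste0("son", seq_len(n_per_sex))),
    c("mother", "father", rep("offspring", 2 * n_per_sex)),
    c("female", "male", rep("female", n_per_sex), rep("male", n_per_sex)))
}

#' Simulate a family cross with a sex-linked region
#'
#' Draws parental genotypes per segregation type, transmits alleles
#' Mendelianly to the offspring (sons hemizygous at X-hemizygous sites,
#' reported as homozygotes), flips each allele call independently with
#' `epsilon_true`, masks calls with `missing_rate`, and simulates
#' negative-binomial read depths consistent with each observed call.
#'
#' @param config a [sim_config].
#' @return list with `table` (a [genotype_table]) and `truth` (class
#'   `sim_truth`): per-site true type and parental configuration, true
#'   X/Y alleles, the sex-linked region interval, the pre-error genotype
#'   matrix, and the realised allele-flip tally (`n_flips`,
#'   `n_allele_draws`).
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  design <- .sim_design(config$n_offspring_per_sex)
  n_off <- 2L * config$n_offspring_per_sex
  sexes <- design$sex[design$role == "offspring"]

  n_auto <- config$n_autosomal_snps
  n_xy <- config$n_xy_snps
  n_xh <- config$n_xhemi_snps
  n <- n_auto + n_xy + n_xh
  if (n == 0) stop("no sites requested")

  # positions: autosomal on chr1; xy region contiguous on xy_chrom with
  # x-hemizygous sites interleaved between xy sites
  xy_pos <- config$xy_start + config$xy_spacing * (seq_len(n_xy) - 1L)
  xh_pos <- if (n_xh > 0 && n_xy > 1) {
    gaps <- seq_len(n_xy - 1L)
    at <- unique(round(seq(1L, n_xy - 1L, length.out = min(n_xh,
                                                           n_xy - 1L))))
    if (length(at) < n_xh)
      at <- c(at, sample(setdiff(gaps, at), n_xh - length(at)))
    as.integer(xy_pos[at] + config$xy_spacing %/% 2L)
  } else if (n_xh > 0) {
    config$xy_start + 10L * seq_len(n_xh)
  } else integer(0)
  sites <- data.frame(
    chrom = c(rep("chr1", n_auto), rep(config$xy_chrom, n_xy + n_xh)),
    pos = c(seq(1000L, by = 1000L, length.out = n_auto), xy_pos, xh_pos),
    stringsAsFactors = FALSE)
  ref_alt <- t(vapply(seq_len(n), function(i)
    sample(c("A", "C", "G", "T"), 2), character(2)))
  sites$ref <- ref_alt[, 1]
  sites$alt <- ref_alt[, 2]
  type <- c(rep("autosomal", n_auto), rep("xy", n_xy),
            rep("x_hemizygous", n_xh))

  freq <- config$allele_freq_distribution(n)
  mother <- integer(n); father <- rep(NA_integer_, n)
  father_x <- rep(NA_integer_, n); father_y <- rep(NA_integer_, n)
  auto <- type == "autosomal"
  mother[auto] <- rbinom(sum(auto), 2, freq[auto])
  father[auto] <- rbinom(sum(auto), 2, freq[auto])
  xy <- type == "xy"
  # fully sex-linked site: mother homozygous, father X = maternal allele,
  # father Y = the other allele; orientation drawn from the frequency
  y_is_alt <- rbinom(sum(xy), 1, freq[xy])
  mother[xy] <- ifelse(y_is_alt == 1L, 0L, 2L)
  father_x[xy] <- ifelse(y_is_alt == 1L, 0L, 1L)
  father_y[xy] <- ifelse(y_is_alt == 1L, 1L, 0L)
  xh <- type == "x_hemizygous"
  mother[xh] <- rbinom(sum(xh), 2, freq[xh])
  father_x[xh] <- rbinom(sum(xh), 1, freq[xh])

  # true genotypes: alleles coded as alt counts
  draw_maternal <- function() {
    # one maternal allele per site: 0/2 deterministic, het -> coin flip
    ifelse(mother == 1L, rbinom(n, 1, 0.5), mother %/% 2L)
  }
  G_true <- matrix(NA_integer_, n, nrow(design))
  G_true[, 1] <- mother
  G_true[, 2] <- ifelse(auto, father,
                        ifelse(xy, father_x + father_y,
                               2L * father_x))  # hemizygous father as hom
  for (k in seq_len(n_off)) {
    am <- draw_maternal()
    sex <- sexes[k]
    ap <- integer(n)
    ap[auto] <- ifelse(father[auto] == 1L, rbinom(sum(auto), 1, 0.5),
                       father[auto] %/% 2L)
    ap[xy] <- if (sex == "female") father_x[xy] else father_y[xy]
    g <- am + ap
    if (sex == "female") {
      g[xh] <- am[xh] + father_x[xh]
    } else {
      g[xh] <- 2L * am[xh]  # hemizygous son reported as homozygote
    }
    G_true[, 2L + k] <- g
  }

  # per-allele genotyping error: flip each of the two allele reads
  n_cells <- length(G_true)
  flips1 <- matrix(rbinom(n_cells, 1, config$epsilon_true), n)
  flips2 <- matrix(rbinom(n_cells, 1, config$epsilon_true), n)
  allele1 <- (G_true >= 1L) * 1L  # het coded as alleles (1, 0)
  allele2 <- (G_true == 2L) * 1L
  obs1 <- abs(allele1 - flips1)
  obs2 <- abs(allele2 - flips2)
  G_obs <- obs1 + obs2
  n_flips <- sum(flips1) + sum(flips2)

  # missing masking
  miss <- matrix(rbinom(n_cells, 1, config$missing_rate) == 1L, n)
  G_obs[miss] <- NA_integer_

  # read depths consistent with the observed call
  tot <- matrix(rnbinom(n_cells, mu = config$depth_mean,
                        size = config$depth_size), n) + 1L
  altfrac <- matrix(0, n, nrow(design))
  altfrac[which(G_obs == 1L)] <- 0.5
  altfrac[which(G_obs == 2L)] <- 1
  alt_d <- matrix(rbinom(n_cells, as.vector(tot), as.vector(altfrac)), n)
  # keep het calls inside the callable alt-fraction window
  het <- which(G_obs == 1L)
  alt_d[het] <- pmin(pmax(alt_d[het], ceiling(0.25 * tot[het])),
                     floor(0.75 * tot[het]))
  ref_d <- tot - alt_d
  ref_d[which(is.na(G_obs))] <- 0L
  alt_d[which(is.na(G_obs))] <- 0L

  table <- genotype_table(sites, design, G_obs, ref_d, alt_d)
  ord <- order(sites$chrom, sites$pos)
  x_allele <- ifelse(!is.na(father_x) & father_x == 1L, sites$alt,
                     ifelse(!is.na(father_x), sites$ref, NA))
  y_allele <- ifelse(!is.na(father_y) & father_y == 1L, sites$alt,
                     ifelse(!is.na(father_y), sites$ref, NA))
  truth <- structure(list(
    sites = data.frame(sites, type = type, mother = mother,
                       father = father, father_x = father_x,
                       father_y = father_y, x_allele = x_allele,
                       y_allele = y_allele,
                       stringsAsFactors = FALSE)[ord, , drop = FALSE],
    region = if (n_xy > 0)
      data.frame(chrom = config$xy_chrom, start = min(xy_pos),
                 end = max(xy_pos)) else NULL,
    G_true = G_true[ord, , drop = FALSE],
    n_flips = n_flips, n_allele_draws = 2L * n_cells,
    seed = config$rng_seed), class = "sim_truth")
  rownames(truth$sites) <- NULL
  list(table = table, truth = truth)
}

#' Write a simulated cross as VCF v4.2 plus a truth TSV
#'
#' The VCF carries `GT:AD` per sample and round-trips through
#' [read_family_vcf]; the truth table is keyed by `(chrom, pos)`.
#'
#' @param table the simulated [genotype_table].
#' @param truth the matching `sim_truth`.
#' @param vcf_path,truth_path output paths.
#' @return `vcf_path`, invisibly.
#' @export
write_sim_vcf <- function(table, truth, vcf_path, truth_path = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  gt_txt <- matrix(c("0/0", "0/1", "1/1")[table$genotypes + 1L],
                   nrow = nrow(table$sites))
  gt_txt[is.na(table$genotypes)] <- "./."
  ad_txt <- matrix(paste0(table$ref_depth, ",", table$alt_depth),
                   nrow = nrow(table$sites))
  cells <- matrix(paste0(gt_txt, ":", ad_txt), nrow = nrow(table$sites))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=xylink_simulate_cross seed=",
           if (inherits(truth, "sim_truth")) truth$seed else NA),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples$sample_id), collapse = "\t"))
  body <- paste(table$sites$chrom, table$sites$pos, ".", table$sites$ref,
                table$sites$alt, ".", "PASS", ".", "GT:AD",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  if (!is.null(truth_path) && inherits(truth, "sim_truth"))
    write.table(truth$sites, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(vcf_path)
}

#' Simulate allele-specific read counts at sex-linked sites
#'
#' Per site and library, a Poisson total depth is split binomially between
#' the X and Y alleles with the library's X fraction.
#'
#' @param truth a `sim_truth` from [simulate_cross] (its xy sites are
#'   used), or a data.frame with `chrom`, `pos`, `x_allele`, `y_allele`,
#'   and `ref` columns.
#' @param genes named assignment of sites to genes: either an integer
#'   number of genes to split the sites into (default 5) or a character
#'   vector, one gene id per xy site.
#' @param libraries character vector of library names.
#' @param mean_depth per-site mean total depth (default 50).
#' @param x_fraction expected fraction of reads from the X allele, recycled
#'   over libraries (default 0.5).
#' @param seed integer seed.
#' @return a data.frame in the [allele_specific_expression] input layout,
#'   with `attr(, "x_fraction")` recording the truth.
#' @export
simulate_allele_counts <- function(truth, genes = 5L,
                                   libraries = c("lib1", "lib2"),
                                   mean_depth = 50, x_fraction = 0.5,
                                   seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  sites <- if (inherits(truth, "sim_truth"))
    truth$sites[truth$sites$type == "xy", , drop = FALSE] else truth
  stopifnot(nrow(sites) > 0, all(x_fraction >= 0), all(x_fraction <= 1))
  x_fraction <- rep_len(x_fraction, length(libraries))
  gene_id <- if (is.numeric(genes)) {
    paste0("gene", cut(seq_len(nrow(sites)), genes, labels = FALSE))
  } else rep_len(genes, nrow(sites))
  out <- do.call(rbind, lapply(seq_along(libraries), function(l) {
    tot <- rpois(nrow(sites), mean_depth)
    xd <- rbinom(nrow(sites), tot, x_fraction[l])
    yd <- tot - xd
    x_is_ref <- sites$x_allele == sites$ref
    data.frame(library = libraries[l], chrom = sites$chrom,
               pos = sites$pos, gene_id = gene_id,
               ref_depth = ifelse(x_is_ref, xd, yd),
               alt_depth = ifelse(x_is_ref, yd, xd),
               x_allele = ifelse(x_is_ref, "ref", "alt"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "x_fraction") <- setNames(x_fraction, libraries)
  out
}
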