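# Total (RPKM) and allele-specific (X vs Y) expression summaries, and the
# tau organ-specificity index.

#' RPKM normalisation
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (library_total * length_bp)`.
#'
#' @param counts genes x libraries matrix of raw read counts.
#' @param lengths per-gene transcript length in bp (recycled down columns).
#' @param totals per-library total mapped reads.
#' @return matrix of the same shape.
#' @examples
#' rpkm(matrix(100), lengths = 2000, totals = 1e7)  # 5
#' @export
rpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts),
            length(totals) == ncol(counts),
            all(lengths > 0), all(counts >= 0))
  if (any(totals <= 0)) stop("zero (or negative) library total")
  sweep(counts / lengths, 2, totals, "/") * 1e9
}

#' Allele-specific (X vs Y) expression per gene and library
#'
#' Sums per-site allele depths by gene, oriented by the X/Y allele
#' assignment, and normalises RPKM-like by the library's total variant-file
#' reads and the transcript length:
#' `x_norm = x_count * 1e9 / (library_variant_total * length_bp)`.
#'
#' @param depths data.frame with columns `library`, `chrom`, `pos`,
#'   `gene_id`, `ref_depth`, `alt_depth`, `x_allele` (`"ref"` or `"alt"`:
#'   which VCF allele is the X allele; the other is Y).
#' @param lengths named vector of transcript lengths (bp) by gene id.
#' @param restrict_to optional [xy_snp_set] (or `data.frame(chrom, pos)`);
#'   only sites present in it are counted (e.g. variants shared by Y and Yh
#'   for hermaphrodite libraries).
#' @param aggregate `"sum"` (default) or `"mean"` of per-site depths per
#'   gene.
#' @return data.frame with one row per (gene, library): `x_count`,
#'   `y_count`, `x_norm`, `y_norm`. Genes with zero retained sites are
#'   absent (noted via `message`).
#' @export
allele_specific_expression <- function(depths, lengths,
                                       restrict_to = NULL,
                                       aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  need <- c("library", "chrom", "pos", "gene_id", "ref_depth", "alt_depth",
            "x_allele")
  stopifnot(is.data.frame(depths), all(need %in% names(depths)),
            all(depths$x_allele %in% c("ref", "alt")),
            all(depths$ref_depth >= 0), all(depths$alt_depth >= 0))
  all_genes <- unique(depths$gene_id)
  if (!is.null(restrict_to)) {
    keys <- paste(restrict_to$chrom, restrict_to$pos)
    depths <- depths[paste(depths$chrom, depths$pos) %in% keys, ,
                     drop = FALSE]
  }
  dropped <- setdiff(all_genes, unique(depths$gene_id))
  if (length(dropped))
    message(length(dropped), " gene(s) with zero retained sites omitted: ",
            paste(dropped, collapse = ", "))
  if (!nrow(depths))
    return(data.frame(gene_id = character(0), library = character(0),
                      x_count = numeric(0), y_count = numeric(0),
                      x_norm = numeric(0), y_norm = numeric(0)))
  # library total = all reads in the variant file for that library,
  # computed before any gene grouping
  lib_tot <- tapply(depths$ref_depth + depths$alt_depth, depths$library,
                    sum)
  x_depth <- ifelse(depths$x_allele == "ref", depths$ref_depth,
                    depths$alt_depth)
  y_depth <- ifelse(depths$x_allele == "ref", depths$alt_depth,
                    depths$ref_depth)
  fun <- if (aggregate == "sum") sum else mean
  agg <- function(v) tapply(v, list(depths$gene_id, depths$library), fun)
  X <- agg(x_depth); Y <- agg(y_depth)
  out <- expand.grid(gene_id = rownames(X), library = colnames(X),
                     stringsAsFactors = FALSE)
  out$x_count <- X[cbind(out$gene_id, out$library)]
  out$y_count <- Y[cbind(out$gene_id, out$library)]
  out <- out[!is.na(out$x_count), , drop = FALSE]
  if (!all(out$gene_id %in% names(lengths)))
    stop("transcript length missing for gene(s): ",
         paste(setdiff(out$gene_id, names(lengths)), collapse = ", "))
  len <- lengths[out$gene_id]
  tot <- lib_tot[out$library]
  out$x_norm <- out$x_count * 1e9 / (tot * len)
  out$y_norm <- out$y_count * 1e9 / (tot * len)
  rownames(out) <- NULL
  out
}

#' Tau organ-specificity index
#'
#' `tau = sum(1 - x_i / max(x)) / (N - 1)` on the transformed expression
#' profile; 0 for a uniformly expressed gene, 1 for single-organ
#' expression.
#'
#' @param profile non-negative expression values, one per organ (N >= 2).
#' @param transform `"log2p1"` (default, `log2(x + 1)`) or `"none"`.
#' @return tau in `[0, 1]`, or `NA` (with a warning) for an all-zero
#'   profile.
#' @examples
#' tau(c(1, 1, 1, 1), transform = "none")      # 0
#' tau(c(5, 0, 0), transform = "none")         # 1
#' tau(c(1, 0.5, 0.25, 0.25), transform = "none")  # 2/3
#' @export
tau <- function(profile, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (any(profile < 0)) stop("negative expression values")
  if (length(profile) < 2) stop("tau needs at least two organs")
  x <- switch(transform, log2p1 = log2(profile + 1), none = profile)
  mx <- max(x)
  if (mx == 0) {
    warning("all-zero profile; tau undefined")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1)
}
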