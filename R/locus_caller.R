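# Empirical XY-SNP detection, panel validation, sex-locus boundaries and
# XX/XY/YY genotype tracks.

#' Construct an XY-SNP set
#'
#' A data.frame of sex-linked SNPs with their X/Y allele assignment.
#' Required columns: `chrom`, `pos`, `ref`, `alt`, `x_allele`, `y_allele`,
#' `source` (`"probabilistic"`, `"empirical"` or `"both"`), `validated`.
#'
#' @param df the entries.
#' @return the same data.frame with class `xy_snp_set`, sorted by
#'   `(chrom, pos)`.
#' @export
xy_snp_set <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "x_allele", "y_allele",
            "source", "validated")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (nrow(df)) {
    if (anyDuplicated(df[, c("chrom", "pos")]))
      stop("duplicate (chrom, pos) in XY-SNP set")
    if (any(df$x_allele == df$y_allele))
      stop("x_allele and y_allele must differ")
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("xy_snp_set", "data.frame")
  df
}

#' @export
print.xy_snp_set <- function(x, ...) {
  cat(sprintf("xy_snp_set: %d SNPs (%d validated)\n",
              nrow(x), sum(x$validated)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

.cross_sex_groups <- function(samples) {
  cross <- samples$role %in% c("mother", "father", "offspring")
  females <- cross & ((samples$role == "mother") |
                        (samples$role == "offspring" &
                           samples$sex == "female"))
  males <- cross & ((samples$role == "father") |
                      (samples$role == "offspring" & samples$sex == "male"))
  list(cross = which(cross), females = which(females), males = which(males))
}

#' Empirical sex-linked SNP filter on a family cross
#'
#' Retains sites where every called female of the cross (mother and female
#' offspring) is homozygous for the same allele, every called male (father
#' and male offspring) is heterozygous, and at most `max_missing_calls`
#' genotype calls are missing across the cross. The Y allele is the allele
#' absent from the females.
#'
#' @param table a [genotype_table] containing the cross samples.
#' @param max_missing_calls maximum missing diploid genotype calls tolerated
#'   per site (default 2; use 1 for the stricter two-missing-alleles
#'   reading).
#' @param region optional `data.frame(chrom, start, end)` restriction
#'   applied before the pattern test.
#' @return an [xy_snp_set] with `source = "empirical"`.
#' @export
empirical_xy_filter <- function(table, max_missing_calls = 2L,
                                region = NULL) {
  stopifnot(inherits(table, "genotype_table"), max_missing_calls >= 0)
  grp <- .cross_sex_groups(table$samples)
  sites <- table$sites
  G <- table$genotypes
  keep_region <- rep(TRUE, nrow(sites))
  if (!is.null(region)) {
    keep_region <- rep(FALSE, nrow(sites))
    for (r in seq_len(nrow(region)))
      keep_region <- keep_region |
        (sites$chrom == region$chrom[r] & sites$pos >= region$start[r] &
           sites$pos <= region$end[r])
  }
  Gf <- G[, grp$females, drop = FALSE]
  Gm <- G[, grp$males, drop = FALSE]
  n_called_f <- rowSums(!is.na(Gf))
  n_called_m <- rowSums(!is.na(Gm))
  females_hom_ref <- rowSums(Gf == 0L, na.rm = TRUE) == n_called_f
  females_hom_alt <- rowSums(Gf == 2L, na.rm = TRUE) == n_called_f
  males_het <- rowSums(Gm == 1L, na.rm = TRUE) == n_called_m
  n_missing <- rowSums(is.na(G[, grp$cross, drop = FALSE]))
  keep <- keep_region & n_called_f > 0 & n_called_m > 0 &
    (females_hom_ref | females_hom_alt) & males_het &
    n_missing <= max_missing_calls
  y <- ifelse(females_hom_ref[keep], sites$alt[keep], sites$ref[keep])
  x <- ifelse(females_hom_ref[keep], sites$ref[keep], sites$alt[keep])
  xy_snp_set(data.frame(
    chrom = sites$chrom[keep], pos = sites$pos[keep],
    ref = sites$ref[keep], alt = sites$alt[keep],
    x_allele = x, y_allele = y, source = "empirical", validated = FALSE,
    stringsAsFactors = FALSE))
}

#' Merge probabilistic and empirical XY-SNP sets
#'
#' Union keyed by `(chrom, pos)`. The `source` column records provenance
#' (`both` for shared sites); a shared site whose X/Y assignment differs
#' between the two sets is flagged in column `conflict`. The merge report —
#' counts per source and the percent increase contributed by empirical-only
#' sites, `100 * n_empirical_only / n_probabilistic` — is attached as
#' `attr(, "merge_report")`.
#'
#' @param probabilistic,empirical two [xy_snp_set]s on the same assembly.
#' @return the merged [xy_snp_set].
#' @export
merge_snp_sets <- function(probabilistic, empirical) {
  stopifnot(inherits(probabilistic, "xy_snp_set"),
            inherits(empirical, "xy_snp_set"))
  key <- function(s) paste(s$chrom, s$pos)
  kp <- key(probabilistic); ke <- key(empirical)
  shared <- intersect(kp, ke)
  p <- as.data.frame(probabilistic)
  e <- as.data.frame(empirical)
  p$p_xy <- if ("p_xy" %in% names(p)) p$p_xy else NA_real_
  p$source <- ifelse(kp %in% shared, "both", "probabilistic")
  p$conflict <- FALSE
  if (length(shared)) {
    em <- e[match(shared, ke), ]
    pm <- match(shared, kp)
    p$conflict[pm] <- p$x_allele[pm] != em$x_allele |
      p$y_allele[pm] != em$y_allele
  }
  eo <- e[!(ke %in% shared), , drop = FALSE]
  eo$p_xy <- rep(NA_real_, nrow(eo))
  eo$conflict <- rep(FALSE, nrow(eo))
  out <- xy_snp_set(rbind(p, eo[, names(p), drop = FALSE]))
  n_p <- nrow(probabilistic); n_eo <- nrow(eo)
  report <- list(n_probabilistic = n_p, n_empirical = nrow(empirical),
                 n_empirical_only = n_eo, n_shared = length(shared),
                 n_union = nrow(out),
                 percent_increase = if (n_p > 0) 100 * n_eo / n_p else NA,
                 n_conflicts = sum(p$conflict))
  if (report$n_conflicts > 0)
    warning(report$n_conflicts,
            " shared site(s) with conflicting X/Y assignment")
  attr(out, "merge_report") <- report
  out
}

#' Validate candidate XY SNPs against an independent sexed panel
#'
#' A candidate is validated when, among called panel genotypes at its
#' position, every male is heterozygous and every female is homozygous for
#' the same allele. Missing panel calls are ignored, but at least one called
#' individual of each sex is required.
#'
#' @param candidates an [xy_snp_set].
#' @param panel a [genotype_table] whose samples have `role = "panel"` and
#'   sex `"female"` or `"male"` (other sexes are ignored).
#' @return `candidates` with the `validated` flag updated.
#' @export
validate_xy_snps <- function(candidates, panel) {
  stopifnot(inherits(candidates, "xy_snp_set"),
            inherits(panel, "genotype_table"))
  females <- which(panel$samples$role == "panel" &
                     panel$samples$sex == "female")
  males <- which(panel$samples$role == "panel" & panel$samples$sex == "male")
  key_c <- paste(candidates$chrom, candidates$pos)
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  i <- match(key_c, key_p)
  validated <- logical(nrow(candidates))
  ok <- !is.na(i)
  if (any(ok)) {
    Gf <- panel$genotypes[i[ok], females, drop = FALSE]
    Gm <- panel$genotypes[i[ok], males, drop = FALSE]
    ncf <- rowSums(!is.na(Gf))
    ncm <- rowSums(!is.na(Gm))
    f_hom_same <- (rowSums(Gf == 0L, na.rm = TRUE) == ncf) |
      (rowSums(Gf == 2L, na.rm = TRUE) == ncf)
    m_het <- rowSums(Gm == 1L, na.rm = TRUE) == ncm
    validated[ok] <- ncf > 0 & ncm > 0 & f_hom_same & m_het
  }
  candidates$validated <- validated
  candidates
}

#' Sex-locus boundaries from validated XY SNPs
#'
#' The locus interval per chromosome: minimum to maximum SNP position,
#' 1-based inclusive, with the span in bp and rounded kb.
#'
#' @param snps an [xy_snp_set]; by default only validated entries are used.
#' @param validated_only use only entries with `validated = TRUE`
#'   (default TRUE).
#' @return `data.frame(chrom, start, end, span_bp, span_kb)`, one row per
#'   chromosome (with a warning when more than one).
#' @export
locus_boundaries <- function(snps, validated_only = TRUE) {
  stopifnot(inherits(snps, "xy_snp_set"))
  s <- as.data.frame(snps)
  if (validated_only) s <- s[s$validated, , drop = FALSE]
  if (!nrow(s)) stop("no (validated) XY SNPs to bound")
  out <- do.call(rbind, lapply(split(s, s$chrom), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos))
  }))
  rownames(out) <- NULL
  out$span_bp <- out$end - out$start + 1L
  out$span_kb <- round(out$span_bp / 1000)
  if (nrow(out) > 1)
    warning("validated XY SNPs on ", nrow(out),
            " chromosomes; returning one interval per chromosome")
  out
}

#' Classify samples into XX / XY / YY at sex-linked sites
#'
#' At each XY site, a call homozygous for the X allele is `XX`, a
#' heterozygote is `XY`, a call homozygous for the Y allele is `YY`, and a
#' missing call is `missing`.
#'
#' @param table a [genotype_table] (e.g. a validation panel or cultivars).
#' @param xy an [xy_snp_set] with assigned alleles.
#' @return an object of class `sex_genotype_track`: the XY sites and a
#'   sites-by-samples character matrix of classes.
#' @export
classify_sex_genotypes <- function(table, xy) {
  stopifnot(inherits(table, "genotype_table"), inherits(xy, "xy_snp_set"))
  key_t <- paste(table$sites$chrom, table$sites$pos)
  key_x <- paste(xy$chrom, xy$pos)
  i <- match(key_x, key_t)
  present <- !is.na(i)
  sites <- as.data.frame(xy)[present, , drop = FALSE]
  G <- table$genotypes[i[present], , drop = FALSE]
  x_is_ref <- sites$x_allele == sites$ref
  cls <- matrix("missing", nrow(G), ncol(G),
                dimnames = list(NULL, table$samples$sample_id))
  cls[which(G == 1L)] <- "XY"
  hom_x <- (G == 0L & x_is_ref) | (G == 2L & !x_is_ref)
  hom_y <- (G == 2L & x_is_ref) | (G == 0L & !x_is_ref)
  cls[which(hom_x)] <- "XX"
  cls[which(hom_y)] <- "YY"
  structure(list(sites = sites, classes = cls,
                 samples = table$samples), class = "sex_genotype_track")
}

#' @export
print.sex_genotype_track <- function(x, ...) {
  cat(sprintf("sex_genotype_track: %d XY sites x %d samples\n",
              nrow(x$sites), ncol(x$classes)))
  invisible(x)
}

#' Recombinant block structure of one sample across the sex locus
#'
#' Maximal runs of identical non-missing XX/XY/YY class along the locus.
#' Missing sites are absorbed into the flanking run when both flanks agree,
#' otherwise left unassigned. A sample is recombinant when it shows at least
#' two blocks of different classes.
#'
#' @param track a `sex_genotype_track` from [classify_sex_genotypes].
#' @param sample sample id.
#' @return `data.frame(chrom, start, end, class, n_sites)` of blocks, with
#'   `attr(, "recombinant")` set.
#' @export
recombinant_blocks <- function(track, sample) {
  stopifnot(inherits(track, "sex_genotype_track"))
  j <- match(sample, colnames(track$classes))
  if (is.na(j)) stop("unknown sample: ", sample)
  cls <- track$classes[, j]
  pos <- track$sites$pos
  chrom <- track$sites$chrom
  ord <- order(chrom, pos)
  cls <- cls[ord]; pos <- pos[ord]; chrom <- chrom[ord]

  # absorb missing sites whose two non-missing flanks agree
  filled <- cls
  nonmiss <- which(cls != "missing")
  for (i in which(cls == "missing")) {
    li <- nonmiss[nonmiss < i]
    ri <- nonmiss[nonmiss > i]
    if (length(li) && length(ri)) {
      li <- max(li); ri <- min(ri)
      if (cls[li] == cls[ri] && chrom[li] == chrom[i] &&
          chrom[ri] == chrom[i])
        filled[i] <- cls[li]
    }
  }
  keep <- filled != "missing"
  f <- filled[keep]; p <- pos[keep]; ch <- chrom[keep]
  if (!length(f)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      n_sites = integer(0))
    attr(out, "recombinant") <- FALSE
    return(out)
  }
  runs <- rle(paste(ch, f))
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- data.frame(chrom = ch[starts], start = p[starts], end = p[ends],
                    class = f[starts], n_sites = runs$lengths,
                    stringsAsFactors = FALSE)
  attr(out, "recombinant") <- length(unique(out$class)) > 1
  out
}

#' Write a locus interval as BED
#'
#' Converts the 1-based inclusive interval to BED's 0-based half-open
#' convention.
#'
#' @param interval a `data.frame(chrom, start, end)` as returned by
#'   [locus_boundaries].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_bed <- function(interval, path) {
  bed <- data.frame(chrom = interval$chrom, start = interval$start - 1L,
                    end = interval$end)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
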