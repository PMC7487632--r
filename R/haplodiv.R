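# X/Y coding pseudosequences, Nei-Gojobori (1986) synonymous divergence
# with Jukes-Cantor correction, and molecular-clock dating.

#' Construct a CDS model
#'
#' A gene's coding structure: strand and ordered CDS segments in genomic
#' coordinates (1-based inclusive).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame(start, end)` of CDS segments, non-overlapping.
#' @return an object of class `cds_model`.
#' @export
cds_model <- function(gene_id, chrom, strand, exons) {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            all(exons$start <= exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping CDS segments in gene ", gene_id)
  rownames(exons) <- NULL
  len <- sum(exons$end - exons$start + 1)
  if (len %% 3 != 0)
    warning("CDS length of ", gene_id, " (", len,
            ") not divisible by 3; trailing partial codon will be dropped")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons), class = "cds_model")
}

#' Read CDS models from a GFF3 file
#'
#' Groups CDS features by their `Parent` (or `ID`) attribute; each group
#' becomes one [cds_model].
#'
#' @param path GFF3 file with CDS features.
#' @return named list of [cds_model] objects.
#' @export
read_cds_gff <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "CDS", , drop = FALSE]
  if (!nrow(g)) stop("no CDS features in ", path)
  att <- as.character(g$attributes)
  grab <- function(field) {
    m <- regmatches(att, regexpr(paste0(field, "=[^;]+"), att))
    out <- rep(NA_character_, length(att))
    out[grepl(paste0(field, "="), att)] <- sub(paste0(field, "="), "", m)
    out
  }
  parent <- grab("Parent")
  id <- grab("ID")
  key <- ifelse(is.na(parent), id, parent)
  if (anyNA(key)) stop("CDS feature without Parent or ID attribute")
  models <- lapply(split(seq_len(nrow(g)), key), function(i) {
    cds_model(gene_id = key[i[1]], chrom = as.character(g$seqid[i[1]]),
              strand = as.character(g$strand[i[1]]),
              exons = data.frame(start = g$start[i], end = g$end[i]))
  })
  models
}

#' Build haplotype pseudosequences for a gene
#'
#' Substitutes each in-CDS SNP position with the haplotype's allele (given
#' on the forward genome strand), concatenates the CDS segments and returns
#' both sequences in coding orientation (reverse-complemented for minus
#' strand genes). SNPs outside the CDS are ignored; a SNP whose `ref` allele
#' disagrees with the reference base is an error.
#'
#' @param ref a `Biostrings::DNAStringSet` (or path to a FASTA file) holding
#'   the chromosome sequences.
#' @param cds a [cds_model].
#' @param xy an [xy_snp_set] with `x_allele` / `y_allele` columns.
#' @param labels labels for the two haplotypes (default `c("X", "Y")`).
#' @return list of class `pseudoseq_pair`: `gene_id`, `seq_a`, `seq_b`
#'   (character, coding orientation, trimmed to whole codons), `label_a`,
#'   `label_b`, `n_snps` (substituted positions).
#' @export
build_pseudosequences <- function(ref, cds, xy, labels = c("X", "Y")) {
  stopifnot(inherits(cds, "cds_model"), inherits(xy, "xy_snp_set"),
            length(labels) == 2)
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  nm <- sub("\\s.*", "", names(ref))
  k <- match(cds$chrom, nm)
  if (is.na(k)) stop("chromosome ", cds$chrom, " absent from reference")
  chrom_seq <- ref[[k]]

  snps <- as.data.frame(xy)
  snps <- snps[snps$chrom == cds$chrom, , drop = FALSE]
  in_cds <- rep(FALSE, nrow(snps))
  for (e in seq_len(nrow(cds$exons)))
    in_cds <- in_cds | (snps$pos >= cds$exons$start[e] &
                          snps$pos <= cds$exons$end[e])
  snps <- snps[in_cds, , drop = FALSE]
  if (nrow(snps)) {
    ref_base <- as.character(Biostrings::extractAt(
      chrom_seq, IRanges::IRanges(snps$pos, snps$pos)))
    bad <- ref_base != snps$ref
    if (any(bad))
      stop("SNP ref allele disagrees with reference at ",
           paste(paste0(cds$chrom, ":", snps$pos[bad]), collapse = ", "))
  }

  substitute_build <- function(allele_col) {
    s <- chrom_seq
    if (nrow(snps))
      s <- Biostrings::replaceLetterAt(
        s, snps$pos, paste(snps[[allele_col]], collapse = ""))
    parts <- Biostrings::extractAt(
      s, IRanges::IRanges(cds$exons$start, cds$exons$end))
    joined <- Biostrings::DNAString(paste(as.character(parts),
                                          collapse = ""))
    if (cds$strand == "-") joined <- Biostrings::reverseComplement(joined)
    out <- as.character(joined)
    substr(out, 1, 3 * (nchar(out) %/% 3))
  }
  structure(list(gene_id = cds$gene_id,
                 seq_a = substitute_build("x_allele"),
                 seq_b = substitute_build("y_allele"),
                 label_a = labels[1], label_b = labels[2],
                 n_snps = nrow(snps)),
            class = "pseudoseq_pair")
}

#' Write pseudosequence pairs as FASTA
#'
#' @param pairs a `pseudoseq_pair` or list of them.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pseudoseq_fasta <- function(pairs, path) {
  if (inherits(pairs, "pseudoseq_pair")) pairs <- list(pairs)
  seqs <- unlist(lapply(pairs, function(p)
    setNames(c(p$seq_a, p$seq_b),
             paste(p$gene_id, c(p$label_a, p$label_b), sep = "_"))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# per-codon fraction of the 9 single-base changes that are synonymous;
# changes to stop codons count as nonsynonymous
.codon_syn_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(code)
    syn <- setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      if (code[[cd]] == "*") next
      s <- 0
      for (p in 1:3) for (b in bases) {
        if (substr(cd, p, p) == b) next
        mut <- cd
        substr(mut, p, p) <- b
        if (code[[mut]] == code[[cd]]) s <- s + 1 / 3
      }
      syn[cd] <- s
    }
    cache <<- syn
    cache
  }
})

# syn/nonsyn differences between two codons, averaged over all mutational
# pathways that avoid stop codons (all pathways if every one is blocked)
.codon_diff_counts <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1) list(pos) else {
    perms <- if (nd == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
    perms
  }
  eval_path <- function(p) {
    cur <- c1
    sd <- ndc <- 0
    blocked <- FALSE
    for (site in p) {
      nxt <- cur
      substr(nxt, site, site) <- substr(c2, site, site)
      if (code[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else ndc <- ndc + 1
      cur <- nxt
    }
    list(sd = sd, nd = ndc, blocked = blocked)
  }
  res <- lapply(paths, eval_path)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))  # all paths pass a stop
  sd <- mean(vapply(res[ok], `[[`, numeric(1), "sd"))
  ndm <- mean(vapply(res[ok], `[[`, numeric(1), "nd"))
  c(sd = sd, nd = ndm)
}

#' Nei-Gojobori (1986) divergence between two aligned coding sequences
#'
#' Counts synonymous and nonsynonymous sites per codon by mutation
#' enumeration, averages multi-difference codons over all mutational
#' pathways (pathways through stop codons excluded), applies the
#' Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` and the delta-method
#' standard error `Var(d) = 9 p (1 - p) / ((3 - 4p)^2 n)`. Codons containing
#' ambiguity codes, or that are stop codons in either sequence, are skipped
#' with a logged count. Proportions at or beyond 3/4 are flagged as
#' saturated (undefined distance).
#'
#' @param pair a `pseudoseq_pair`, or `seq_a` as a character string.
#' @param seq_b second sequence when `pair` is a string.
#' @return object of class `divergence_estimate`: `gene_id`, `dS`, `dN`,
#'   `se_dS`, `se_dN`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `saturated`,
#'   `n_codons_skipped`.
#' @export
ng86_divergence <- function(pair, seq_b = NULL) {
  if (is.character(pair)) {
    gene_id <- NA_character_
    a <- toupper(pair); b <- toupper(seq_b)
  } else {
    gene_id <- pair$gene_id
    a <- toupper(pair$seq_a); b <- toupper(pair$seq_b)
  }
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("sequence length must be a multiple of 3")
  nc <- nchar(a) %/% 3
  code <- Biostrings::GENETIC_CODE
  syn <- .codon_syn_sites()
  split_codons <- function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split_codons(a); cb <- split_codons(b)
  valid_codon <- function(cd) cd %in% names(code) && code[[cd]] != "*"
  ok <- vapply(seq_len(nc), function(i)
    valid_codon(ca[i]) && valid_codon(cb[i]), logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " codon(s) with ambiguity or stop skipped")
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no analysable codons")
  S <- mean(c(sum(syn[ca]), sum(syn[cb])))
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i)
    .codon_diff_counts(ca[i], cb[i], code), numeric(2))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  jc <- function(p, n) {
    if (p >= 0.75) return(list(d = NA_real_, se = NA_real_, sat = TRUE))
    d <- -0.75 * log(1 - 4 * p / 3)
    se <- sqrt(9 * p * (1 - p) / ((3 - 4 * p)^2 * n))
    list(d = d, se = se, sat = FALSE)
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  s_est <- if (is.na(pS)) list(d = NA_real_, se = NA_real_, sat = FALSE)
    else jc(pS, S)
  n_est <- if (is.na(pN)) list(d = NA_real_, se = NA_real_, sat = FALSE)
    else jc(pN, N)
  if (S == 0) warning("zero synonymous sites; dS undefined")
  structure(list(gene_id = gene_id, dS = s_est$d, dN = n_est$d,
                 se_dS = s_est$se, se_dN = n_est$se,
                 S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 saturated = isTRUE(s_est$sat) || isTRUE(n_est$sat),
                 n_codons_skipped = n_skipped),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "divergence_estimate%s: dS = %.4g +/- %.3g, dN = %.4g +/- %.3g (S = %.1f, N = %.1f)%s\n",
    if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
    x$dS, x$se_dS, x$dN, x$se_dN, x$S, x$N,
    if (x$saturated) " SATURATED" else ""))
  invisible(x)
}

#' Mean and median synonymous divergence over genes
#'
#' @param estimates list of `divergence_estimate` objects (or a numeric
#'   vector of dS values).
#' @param exclude gene ids to drop (explicit outlier list; no automatic
#'   rule).
#' @return list `mean`, `median`, `n` over defined, non-excluded dS values.
#' @export
summarize_ds <- function(estimates, exclude = character(0)) {
  if (is.numeric(estimates)) {
    ds <- estimates
  } else {
    ids <- vapply(estimates, `[[`, character(1), "gene_id")
    ds <- vapply(estimates, `[[`, numeric(1), "dS")
    ds <- ds[!(ids %in% exclude)]
  }
  ds <- ds[!is.na(ds)]
  if (!length(ds)) stop("no defined dS values after exclusion")
  list(mean = mean(ds), median = median(ds), n = length(ds))
}

#' Haplotype age from synonymous divergence under a molecular clock
#'
#' Divergence accrues on both lineages, so the age in generations is
#' `dS / (2 mu)` and the age in years is that times the generation time:
#' `age = dS / (2 mu) * g`.
#'
#' @param dS synonymous divergence (substitutions per synonymous site).
#' @param generation_time_years generation time g in years.
#' @param mu substitution rate per site per generation (default `7e-9`, a
#'   plant nuclear clock).
#' @return age in years.
#' @examples
#' clock_age(0.03, 5) / 1e6   # ~10.7 My
#' clock_age(0.03, 52.5) / 1e6  # ~112.5 My
#' @export
clock_age <- function(dS, generation_time_years, mu = 7e-9) {
  stopifnot(all(dS >= 0), mu > 0, all(generation_time_years > 0))
  dS / (2 * mu) * generation_time_years
}

#' Generation time implied by a divergence and an assumed age
#'
#' Inverse of [clock_age]: `g = age * 2 mu / dS`.
#'
#' @param dS synonymous divergence (> 0).
#' @param age_years assumed age in years.
#' @param mu substitution rate per site per generation.
#' @return generation time in years.
#' @export
clock_generation_time <- function(dS, age_years, mu = 7e-9) {
  stopifnot(all(dS > 0), mu > 0)
  age_years * 2 * mu / dS
}
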