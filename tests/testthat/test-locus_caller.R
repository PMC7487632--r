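# Empirical detection, merging, panel validation, boundaries and
# XX/XY/YY genotype tracks.

cross_design <- small_design(5, 5)

test_that("empirical_xy_filter retains the strict pattern and honours the
           missing-call allowance", {
  # sites: (1) perfect pattern, (2) pattern + 2 missing, (3) pattern + 3
  # missing, (4) one female het
  G <- rbind(
    c(0L, 1L, rep(0L, 5), rep(1L, 5)),
    c(0L, 1L, 0L, 0L, 0L, NA, 0L, 1L, 1L, NA, 1L, 1L),
    c(0L, 1L, 0L, NA, 0L, NA, 0L, 1L, 1L, NA, 1L, 1L),
    c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L))
  tab <- make_table(G, cross_design)
  got <- empirical_xy_filter(tab, max_missing_calls = 2)
  expect_equal(got$pos, c(100L, 200L))
  expect_equal(got$y_allele, c("G", "G"))  # females hom ref -> Y = alt
  expect_true(all(got$source == "empirical"))
  # mirrored orientation: females hom alt -> Y = ref
  Gm <- rbind(c(2L, 1L, rep(2L, 5), rep(1L, 5)))
  gotm <- empirical_xy_filter(make_table(Gm, cross_design))
  expect_equal(gotm$y_allele, "A")

  # retention is monotone in max_missing_calls, and strict-pattern sites
  # survive any allowance
  for (k in 0:3) {
    res <- empirical_xy_filter(tab, max_missing_calls = k)
    expect_true(100L %in% res$pos)
    if (k >= 1)
      expect_true(all(empirical_xy_filter(tab, k - 1)$pos %in% res$pos))
  }
  # region restriction applies first
  reg <- data.frame(chrom = "chr2", start = 150L, end = 250L)
  expect_equal(empirical_xy_filter(tab, 2, region = reg)$pos, 200L)
})

test_that("merge_snp_sets reports the union, provenance and the percent
           increase", {
  mk <- function(pos, src = "probabilistic") xy_snp_set(data.frame(
    chrom = "chr2", pos = pos, ref = "A", alt = "G", x_allele = "A",
    y_allele = "G", source = src, validated = FALSE,
    stringsAsFactors = FALSE))
  # the study's arithmetic: 1406 probabilistic, all shared, plus 459
  # empirical-only -> union 1865, +32.6%
  prob <- mk(seq_len(1406))
  emp <- mk(c(seq_len(1406), 10000L + seq_len(459)), "empirical")
  merged <- merge_snp_sets(prob, emp)
  rep <- attr(merged, "merge_report")
  expect_equal(rep$n_union, 1865L)
  expect_equal(rep$n_empirical_only, 459L)
  expect_equal(round(rep$percent_increase, 1), 32.6)
  expect_equal(sum(merged$source == "both"), 1406L)
  expect_equal(sum(merged$source == "empirical"), 459L)

  # disjoint sets of 3 and 2 -> union 5; identical sets -> 0% increase
  expect_equal(nrow(merge_snp_sets(mk(1:3), mk(11:12, "empirical"))), 5L)
  expect_equal(attr(merge_snp_sets(mk(1:3), mk(1:3, "empirical")),
                    "merge_report")$percent_increase, 0)

  # conflicting assignment at a shared site is flagged
  a <- mk(1:2)
  b <- xy_snp_set(data.frame(chrom = "chr2", pos = 1:2, ref = "A",
                             alt = "G", x_allele = c("G", "A"),
                             y_allele = c("A", "G"), source = "empirical",
                             validated = FALSE, stringsAsFactors = FALSE))
  expect_warning(m2 <- merge_snp_sets(a, b), "conflicting")
  expect_equal(sum(m2$conflict), 1L)
})

test_that("validate_xy_snps applies the panel pattern and ignores missing
           calls", {
  pd <- sample_design(paste0("p", 1:9), rep("panel", 9),
                      c(rep("male", 4), rep("female", 5)))
  cand <- xy_snp_set(data.frame(
    chrom = "chr2", pos = c(100L, 200L, 300L, 400L), ref = "A", alt = "G",
    x_allele = "A", y_allele = "G", source = "both", validated = FALSE,
    stringsAsFactors = FALSE))
  G <- rbind(
    c(rep(1L, 4), rep(0L, 5)),            # conforming -> validated
    c(0L, rep(1L, 3), rep(0L, 5)),        # one male hom -> not validated
    c(NA, rep(1L, 3), rep(0L, 5)),        # one male missing -> validated
    c(rep(NA, 4), rep(0L, 5)))            # no called male -> not validated
  panel <- make_table(G, pd, pos = c(100L, 200L, 300L, 400L))
  got <- validate_xy_snps(cand, panel)
  expect_equal(got$validated, c(TRUE, FALSE, TRUE, FALSE))
  # validated output is always a subset of the candidates
  expect_true(all(paste(got$chrom, got$pos) %in%
                    paste(cand$chrom, cand$pos)))
  # a candidate absent from the panel table stays unvalidated
  cand2 <- xy_snp_set(rbind(as.data.frame(cand),
                            data.frame(chrom = "chr9", pos = 1L, ref = "A",
                                       alt = "G", x_allele = "A",
                                       y_allele = "G", source = "both",
                                       validated = TRUE)))
  expect_false(validate_xy_snps(cand2, panel)$validated[
    cand2$chrom == "chr9"])
})

test_that("locus_boundaries reproduces span arithmetic and ignores input
           order", {
  mk <- function(pos) xy_snp_set(data.frame(
    chrom = "chr2", pos = pos, ref = "A", alt = "G", x_allele = "A",
    y_allele = "G", source = "both", validated = TRUE,
    stringsAsFactors = FALSE))
  b <- locus_boundaries(mk(c(4810929L, 4850000L, 4921949L)))
  expect_equal(b$start, 4810929L)
  expect_equal(b$end, 4921949L)
  expect_equal(b$span_bp, 111021L)
  expect_equal(b$span_kb, 111)
  # permutation invariance
  b2 <- locus_boundaries(mk(c(4921949L, 4810929L, 4850000L)))
  expect_equal(b2, b)
  # single SNP -> span 1 bp
  expect_equal(locus_boundaries(mk(4810929L))$span_bp, 1L)
  # span identity
  expect_equal(b$span_bp, b$end - b$start + 1L)
  # empty input errors
  empty <- mk(1L); empty$validated <- FALSE
  expect_error(locus_boundaries(empty), "no")
  # multi-chromosome input warns and returns one row per chromosome
  two <- xy_snp_set(data.frame(
    chrom = c("chr1", "chr2"), pos = c(5L, 9L), ref = "A", alt = "G",
    x_allele = "A", y_allele = "G", source = "both", validated = TRUE))
  expect_warning(bb <- locus_boundaries(two), "chromosome")
  expect_equal(nrow(bb), 2L)
})

test_that("classify_sex_genotypes respects the allele orientation", {
  pd <- sample_design(paste0("c", 1:3), rep("panel", 3),
                      rep("hermaphrodite", 3))
  G <- rbind(c(0L, 1L, 2L),
             c(0L, 1L, NA))
  tab <- make_table(G, pd, pos = c(10L, 20L))
  xy <- xy_snp_set(data.frame(
    chrom = "chr2", pos = c(10L, 20L), ref = "A", alt = "G",
    x_allele = c("A", "G"), y_allele = c("G", "A"),
    source = "both", validated = TRUE, stringsAsFactors = FALSE))
  track <- classify_sex_genotypes(tab, xy)
  expect_equal(unname(track$classes[1, ]), c("XX", "XY", "YY"))
  # swapped orientation at site 2: hom_ref is YY
  expect_equal(unname(track$classes[2, ]), c("YY", "XY", "missing"))
})

test_that("recombinant_blocks builds runs with missing-absorption", {
  pd <- sample_design("c1", "panel", "hermaphrodite")
  mktrack <- function(classes) {
    G <- matrix(match(classes, c("XX", "XY", "YY")) - 1L, ncol = 1)
    G[classes == "missing"] <- NA
    tab <- make_table(G, pd, pos = seq(10L, by = 10L,
                                       length.out = length(classes)))
    xy <- xy_snp_set(data.frame(
      chrom = "chr2", pos = tab$sites$pos, ref = "A", alt = "G",
      x_allele = "A", y_allele = "G", source = "both", validated = TRUE,
      stringsAsFactors = FALSE))
    classify_sex_genotypes(tab, xy)
  }
  # homogeneous track: one block, not recombinant
  b1 <- recombinant_blocks(mktrack(rep("XY", 3)), "c1")
  expect_equal(nrow(b1), 1L)
  expect_false(attr(b1, "recombinant"))
  # two-class track is recombinant
  b2 <- recombinant_blocks(mktrack(c(rep("XY", 20), rep("XX", 10))), "c1")
  expect_equal(b2$class, c("XY", "XX"))
  expect_true(attr(b2, "recombinant"))
  # missing absorbed when flanks agree
  b3 <- recombinant_blocks(mktrack(c("XY", "missing", "XY", "XX")), "c1")
  expect_equal(b3$n_sites, c(3L, 1L))
  expect_equal(b3$class, c("XY", "XX"))
  # missing between disagreeing flanks stays unassigned
  b4 <- recombinant_blocks(mktrack(c("XY", "missing", "XX")), "c1")
  expect_equal(b4$n_sites, c(1L, 1L))
})
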