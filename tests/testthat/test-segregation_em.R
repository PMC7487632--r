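# Transmission model, error model, site likelihoods against the
# brute-force oracle, EM fitting and sex-linked classification.

test_that("offspring genotype distributions are Mendelian", {
  # autosomal het x het
  d <- offspring_genotype_distribution(list(mother = 1, father = 1),
                                       "autosomal")
  expect_equal(unname(d), c(0.25, 0.5, 0.25))
  # strict XY pattern
  cfg <- list(mother = 0, father_x = 0, father_y = 1)
  expect_equal(unname(offspring_genotype_distribution(cfg, "xy", "female")),
               c(1, 0, 0))
  expect_equal(unname(offspring_genotype_distribution(cfg, "xy", "male")),
               c(0, 1, 0))
  # hemizygous son reported as homozygote
  dh <- offspring_genotype_distribution(list(mother = 1, father_x = 0),
                                        "x_hemizygous", "male")
  expect_equal(unname(dh), c(0.5, 0, 0.5))
  # distributions always sum to 1
  for (m in 0:2) for (fx in 0:1) for (s in c("female", "male")) {
    expect_equal(sum(offspring_genotype_distribution(
      list(mother = m, father_x = fx, father_y = 1 - fx), "xy", s)), 1)
  }
  expect_error(offspring_genotype_distribution(list(mother = 0), "zw"))
})

test_that("genotype error probabilities are independent allele flips", {
  e <- 0.03
  expect_equal(genotype_error_prob("hom_ref", "hom_ref", e), (1 - e)^2)
  expect_equal(genotype_error_prob("het", "hom_ref", e), 2 * e * (1 - e))
  expect_equal(genotype_error_prob("hom_alt", "het", e), e * (1 - e))
  # epsilon = 0 is the identity
  for (a in c("hom_ref", "het", "hom_alt")) for (b in c("hom_ref", "het",
                                                        "hom_alt"))
    expect_equal(genotype_error_prob(a, b, 0), as.numeric(a == b))
  # rows sum to 1 over observed states
  for (true in 0:2)
    expect_equal(sum(genotype_error_prob(0:2, rep(true, 3), e)), 1)
})

test_that("snp_loglik matches hand-derivable cases", {
  design <- small_design(2, 2)
  g <- setNames(c(0L, 0L, 0L, 0L, 0L, 0L), design$sample_id)
  # single consistent autosomal config at epsilon = 0: prior 1/9
  expect_equal(snp_loglik(g, design, "autosomal", 0), log(1 / 9),
               tolerance = 1e-12)
  # impossible without error
  g2 <- g; g2[3] <- 2L
  expect_equal(snp_loglik(g2, design, "autosomal", 0), -Inf)
  # no offspring errors
  d0 <- sample_design(c("m", "f"), c("mother", "father"),
                      c("female", "male"))
  expect_error(snp_loglik(g[1:2], d0, "autosomal", 0.01), "offspring")
})

test_that("snp_loglik equals the exhaustive-enumeration oracle", {
  set.seed(101)
  n_checked <- 0
  for (rep in 1:70) {
    nd <- sample(0:2, 1); ns <- sample(0:2, 1)
    if (nd + ns == 0) ns <- 1
    design <- small_design(nd, ns)
    g <- random_family_genotypes(design)
    for (eps in c(0, 0.01, 0.1)) {
      for (type in c("autosomal", "xy", "x_hemizygous")) {
        got <- snp_loglik(g, design, type, eps)
        want <- oracle_snp_loglik(g, design, type, eps)
        if (is.infinite(want)) expect_equal(got, want)
        else expect_equal(got, want, tolerance = 1e-12)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 200)
})

test_that("the xy likelihood dominates on data simulated under xy", {
  design <- small_design(5, 5)
  # error-free canonical xy site: mother and daughters hom_ref, males het
  g <- setNames(c(0L, 1L, rep(0L, 5), rep(1L, 5)), design$sample_id)
  expect_gt(snp_loglik(g, design, "xy", 0),
            snp_loglik(g, design, "autosomal", 0))
})

test_that("EM recovers parameters and its log-likelihood never decreases", {
  sim <- simulate_cross(sim_config(n_autosomal_snps = 1800,
                                   n_xy_snps = 160, n_xhemi_snps = 40,
                                   epsilon_true = 0.02, rng_seed = 21))
  fit <- fit_em(sim$table)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 *
                    abs(fit$loglik_trace[-1])))
  expect_lt(abs(fit$epsilon - 0.02), 0.01)
  truth_pi <- prop.table(table(factor(sim$truth$sites$type,
                                      c("autosomal", "xy",
                                        "x_hemizygous"))))
  expect_true(all(abs(fit$pi - as.numeric(truth_pi)) < 0.03))
  # posteriors normalised
  psum <- rowSums(fit$posterior[, c("autosomal", "xy", "x_hemizygous")])
  expect_equal(psum, rep(1, length(psum)), tolerance = 1e-9)
})

test_that("all-autosomal perfect data collapses the mixture", {
  sim <- simulate_cross(sim_config(n_autosomal_snps = 800, n_xy_snps = 0,
                                   n_xhemi_snps = 0, epsilon_true = 0,
                                   missing_rate = 0, rng_seed = 13))
  fit <- fit_em(sim$table)
  expect_gte(fit$pi["autosomal"], 0.99)
  expect_lte(fit$epsilon, 1e-3)
})

test_that("classification threshold is strict and allele calls match
           simulated truth", {
  sim <- simulate_cross(sim_config(n_autosomal_snps = 1500,
                                   n_xy_snps = 150, n_xhemi_snps = 30,
                                   epsilon_true = 0.01, rng_seed = 33))
  fit <- fit_em(sim$table)
  xy <- classify_sex_linked(fit, 0.6)
  truth <- sim$truth$sites
  tkey <- paste(truth$chrom, truth$pos)[truth$type == "xy"]
  ckey <- paste(xy$chrom, xy$pos)
  expect_gte(mean(tkey %in% ckey), 0.95)
  # assigned Y allele matches simulator truth at detected xy SNPs
  m <- match(ckey, paste(truth$chrom, truth$pos))
  true_y <- truth$y_allele[m]
  detected_true_xy <- !is.na(true_y)
  expect_gte(mean(xy$y_allele[detected_true_xy] ==
                    true_y[detected_true_xy]), 0.99)

  # strictness: a site at exactly the threshold is excluded
  fake <- fit
  fake$posterior$xy[] <- 0
  fake$posterior$xy[1:2] <- c(0.60, 0.61)
  fake$posterior$autosomal[] <- 1
  fake$posterior$autosomal[1:2] <- c(0.40, 0.39)
  fake$best_config$ambiguous[1:2] <- FALSE
  got <- classify_sex_linked(fake, 0.6)
  expect_equal(nrow(got), 1L)
  expect_equal(got$pos, fit$posterior$pos[2])
  # threshold 0 includes every site with p_xy > 0
  expect_gt(nrow(classify_sex_linked(fit, 0)), nrow(xy))
})

test_that("assign_xy_alleles follows the forced pattern and its mirror", {
  design <- small_design(3, 3)
  # father het, sons het, mother and daughters hom_ref -> Y = alt
  G <- matrix(c(0L, 1L, 0L, 0L, 0L, 1L, 1L, 1L), 1)
  tab <- make_table(G, design)
  fit <- fit_em(tab, max_iter = 50)
  site <- fit$posterior[1, ]
  al <- assign_xy_alleles(site, fit$best_config[1, ])
  expect_equal(al$y_allele, site$alt)
  expect_equal(al$x_allele, site$ref)
  # mirrored data swap the assignment
  Gm <- 2L - G
  fitm <- fit_em(make_table(Gm, design), max_iter = 50)
  alm <- assign_xy_alleles(fitm$posterior[1, ], fitm$best_config[1, ])
  expect_equal(alm$y_allele, site$ref)
})

test_that("ref/alt label symmetry: posteriors invariant, X/Y swapped", {
  sim <- simulate_cross(sim_config(n_autosomal_snps = 150, n_xy_snps = 40,
                                   n_xhemi_snps = 10, rng_seed = 55))
  tab <- sim$table
  fit <- fit_em(tab)
  sites2 <- tab$sites
  sites2$ref <- tab$sites$alt
  sites2$alt <- tab$sites$ref
  swapped <- genotype_table(sites2, tab$samples, 2L - tab$genotypes,
                            tab$alt_depth, tab$ref_depth)
  fit2 <- fit_em(swapped)
  for (t in c("autosomal", "xy", "x_hemizygous"))
    expect_equal(fit2$posterior[[t]], fit$posterior[[t]], tolerance = 1e-8)
  xy1 <- classify_sex_linked(fit, 0.6)
  xy2 <- classify_sex_linked(fit2, 0.6)
  m <- match(paste(xy1$chrom, xy1$pos), paste(xy2$chrom, xy2$pos))
  expect_true(all(!is.na(m)))
  # same base called as Y: alleles are labels on the same site, so the Y
  # base is unchanged while its ref/alt role swaps
  expect_equal(xy2$y_allele[m], xy1$y_allele)
})

test_that("posterior probabilities are approximately calibrated", {
  sim <- simulate_cross(sim_config(n_autosomal_snps = 6000,
                                   n_xy_snps = 700, n_xhemi_snps = 0,
                                   epsilon_true = 0.05, missing_rate = 0.15,
                                   rng_seed = 77))
  fit <- fit_em(sim$table)
  band <- fit$posterior$xy >= 0.55 & fit$posterior$xy <= 0.65
  expect_gte(sum(band), 10)  # the band is populated under these conditions
  truth_xy <- sim$truth$sites$type == "xy"
  expect_lt(abs(mean(truth_xy[band]) - 0.6), 0.15)
})
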