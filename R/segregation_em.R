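# Probabilistic classification of SNPs into segregation types (autosomal,
# fully XY-linked, X-hemizygous) from family genotypes, with a shared
# per-allele genotyping-error rate, fitted by EM over a SNP-level mixture.

SEG_TYPES <- c("autosomal", "xy", "x_hemizygous")

#' Genotype observation probability under per-allele error
#'
#' Each of the two allele reads of a diploid call is flipped independently
#' with probability `epsilon`. A hemizygous true state is observed as two
#' reads of its single allele, which gives the same row as the corresponding
#' homozygote.
#'
#' @param observed,true genotype states, `"hom_ref"`, `"het"` or `"hom_alt"`
#'   (or codes 0/1/2).
#' @param epsilon per-allele error probability in `[0, 0.5)`.
#' @return `P(observed | true, epsilon)`.
#' @examples
#' genotype_error_prob("hom_ref", "hom_ref", 0.01)  # (1 - 0.01)^2
#' genotype_error_prob("het", "hom_ref", 0.01)      # 2 * 0.01 * 0.99
#' @export
genotype_error_prob <- function(observed, true, epsilon) {
  E <- .error_matrix(epsilon)
  to_code <- function(x) {
    if (is.character(x)) unname(GT_STATES[x]) else as.integer(x)
  }
  E[cbind(to_code(true) + 1L, to_code(observed) + 1L)]
}

# rows = true genotype (0,1,2), cols = observed genotype
.error_matrix <- function(eps) {
  stopifnot(eps >= 0, eps < 0.5)
  matrix(c((1 - eps)^2, 2 * eps * (1 - eps), eps^2,
           eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps),
           eps^2, 2 * eps * (1 - eps), (1 - eps)^2),
         nrow = 3, byrow = TRUE)
}

# expected number of allele flips given (true, observed); only the
# het -> het pair is stochastic (0 or 2 flips)
.flip_matrix <- function(eps) {
  ehh <- 2 * eps^2 / ((1 - eps)^2 + eps^2)
  matrix(c(0, 1, 2,
           1, ehh, 1,
           2, 1, 0),
         nrow = 3, byrow = TRUE)
}

.allele_dist <- function(gt) {
  # P(transmitted allele is alt) for a diploid genotype 0/1/2
  c(0, 0.5, 1)[gt + 1L]
}

#' Distribution of an offspring's true genotype given the parental
#' configuration
#'
#' Mendelian transmission under the three segregation types. For
#' X-hemizygous sons the single maternal allele is reported as the
#' corresponding homozygote.
#'
#' @param config list with `mother` (genotype 0/1/2) and, depending on type,
#'   `father` (genotype, autosomal), or `father_x`/`father_y` (allele codes
#'   0 = ref, 1 = alt).
#' @param seg_type `"autosomal"`, `"xy"` or `"x_hemizygous"`.
#' @param offspring_sex `"female"` or `"male"` (required for the sex-linked
#'   types).
#' @return named probability vector over `hom_ref`, `het`, `hom_alt`.
#' @export
offspring_genotype_distribution <- function(config, seg_type,
                                            offspring_sex = NULL) {
  seg_type <- match.arg(seg_type, SEG_TYPES)
  pm <- .allele_dist(config$mother)  # P(maternal allele = alt)
  two_allele <- function(p1, p2) {
    c(hom_ref = (1 - p1) * (1 - p2),
      het = p1 * (1 - p2) + (1 - p1) * p2,
      hom_alt = p1 * p2)
  }
  if (seg_type == "autosomal")
    return(two_allele(pm, .allele_dist(config$father)))
  offspring_sex <- match.arg(offspring_sex, c("female", "male"))
  if (seg_type == "xy") {
    pf <- if (offspring_sex == "female") config$father_x else config$father_y
    return(two_allele(pm, pf))
  }
  # x_hemizygous
  if (offspring_sex == "female")
    return(two_allele(pm, config$father_x))
  c(hom_ref = 1 - pm, het = 0, hom_alt = pm)  # hemizygote as homozygote
}

# enumerate the parental configurations of a type; uniform prior over rows.
# At a fully sex-linked (XY) site the Y allele is private to the Y
# haplotype: the father is X/Y heterozygous and every X copy in the cross
# (both maternal alleles and the father's X) carries the other allele.
# Only the two orientations of that pattern exist; looser configurations
# (mother carrying the Y-type allele, or father X = Y) would duplicate
# autosomal patterns and siphon mixture weight.
.seg_configs <- function(seg_type) {
  switch(seg_type,
    autosomal = expand.grid(mother = 0:2, father = 0:2),
    xy = data.frame(mother = c(0L, 2L), father_x = c(0L, 1L),
                    father_y = c(1L, 0L)),
    x_hemizygous = expand.grid(mother = 0:2, father_x = 0:1),
    stop("unknown segregation type: ", seg_type))
}

# per-config lookup tables: for each family role, log P(obs) and expected
# flips indexed by observed genotype code + 1 (index 4 = missing: logp 0,
# flips 0, reads 0)
.config_tables <- function(cfg, seg_type, eps, E = .error_matrix(eps),
                           FL = .flip_matrix(eps)) {
  lp_from_true <- function(true_gt) {
    c(log(E[true_gt + 1L, ]), 0)
  }
  ef_from_true <- function(true_gt) c(FL[true_gt + 1L, ], 0)
  mix_obs <- function(tp) {
    # tp: distribution over true genotypes; returns log P(obs) and
    # posterior-expected flips per observed state
    pobs <- as.vector(tp %*% E)
    ef <- vapply(1:3, function(o) {
      w <- tp * E[, o]
      if (sum(w) == 0) 0 else sum(w * FL[, o]) / sum(w)
    }, numeric(1))
    list(lp = c(log(pobs), 0), ef = c(ef, 0))
  }
  cfg <- as.list(cfg)
  mother <- list(lp = lp_from_true(cfg$mother), ef = ef_from_true(cfg$mother))
  father <- switch(seg_type,
    autosomal = list(lp = lp_from_true(cfg$father),
                     ef = ef_from_true(cfg$father)),
    xy = {
      fgt <- cfg$father_x + cfg$father_y
      list(lp = lp_from_true(fgt), ef = ef_from_true(fgt))
    },
    x_hemizygous = {
      # father hemizygous for his X allele; observed as that homozygote
      fgt <- 2L * cfg$father_x
      list(lp = lp_from_true(fgt), ef = ef_from_true(fgt))
    })
  off <- lapply(c(female = "female", male = "male"), function(s) {
    tp <- offspring_genotype_distribution(cfg, seg_type, s)
    mix_obs(tp)
  })
  list(mother = mother, father = father,
       daughter = off$female, son = off$male)
}

# split a sample design into family member indices
.family_indices <- function(samples) {
  mi <- which(samples$role == "mother")
  fi <- which(samples$role == "father")
  oi <- which(samples$role == "offspring")
  if (length(oi) == 0) stop("no offspring in the design")
  if (length(mi) != 1 || length(fi) != 1)
    stop("need exactly one mother and one father")
  list(mother = mi, father = fi,
       daughters = oi[samples$sex[oi] == "female"],
       sons = oi[samples$sex[oi] == "male"])
}

# Core per-type sweep. G: n_sites x n_samples genotype code matrix
# (0/1/2/NA). Returns for each type the per-site log-likelihood, the
# posterior-expected allele flips, and (for xy) per-config posteriors.
.seg_type_stats <- function(G, fam, eps, want_flips = FALSE,
                            want_config = FALSE) {
  n <- nrow(G)
  idx <- G + 1L
  idx[is.na(idx)] <- 4L
  E <- .error_matrix(eps)
  FL <- .flip_matrix(eps)
  out <- list()
  for (type in SEG_TYPES) {
    cfgs <- .seg_configs(type)
    ncfg <- nrow(cfgs)
    L <- matrix(0, n, ncfg)
    FlipC <- if (want_flips) matrix(0, n, ncfg) else NULL
    for (k in seq_len(ncfg)) {
      tb <- .config_tables(cfgs[k, ], type, eps, E, FL)
      lk <- tb$mother$lp[idx[, fam$mother]] + tb$father$lp[idx[, fam$father]]
      for (j in fam$daughters) lk <- lk + tb$daughter$lp[idx[, j]]
      for (j in fam$sons) lk <- lk + tb$son$lp[idx[, j]]
      L[, k] <- lk
      if (want_flips) {
        fk <- tb$mother$ef[idx[, fam$mother]] + tb$father$ef[idx[, fam$father]]
        for (j in fam$daughters) fk <- fk + tb$daughter$ef[idx[, j]]
        for (j in fam$sons) fk <- fk + tb$son$ef[idx[, j]]
        FlipC[, k] <- fk
      }
    }
    lprior <- -log(ncfg)
    m <- apply(L, 1, max)
    m_safe <- ifelse(is.finite(m), m, 0)
    sumexp <- rowSums(exp(L - m_safe))
    loglik <- ifelse(is.finite(m), m + log(sumexp) + lprior, -Inf)
    res <- list(loglik = loglik)
    if (want_flips || want_config) {
      W <- exp(L - m_safe)
      W <- W / pmax(rowSums(W), .Machine$double.xmin)
      if (want_flips) res$flips <- rowSums(W * FlipC)
      if (want_config) {
        res$config_post <- W
        res$configs <- cfgs
      }
    }
    out[[type]] <- res
  }
  out
}

#' Log-likelihood of one SNP's family genotypes under a segregation type
#'
#' Marginalises over the type's parental configurations (uniform prior) and
#' over the offspring's true genotypes given Mendelian transmission, with
#' per-allele genotyping error `epsilon`. Missing genotypes contribute a
#' factor 1.
#'
#' @param genotypes named integer vector of observed genotype codes
#'   (0/1/2/NA), one per design sample, in design order.
#' @param design the family [sample_design].
#' @param seg_type `"autosomal"`, `"xy"` or `"x_hemizygous"`.
#' @param epsilon per-allele error probability.
#' @return the log-likelihood (can be `-Inf`).
#' @export
snp_loglik <- function(genotypes, design, seg_type, epsilon) {
  seg_type <- match.arg(seg_type, SEG_TYPES)
  fam <- .family_indices(design)
  G <- matrix(as.integer(genotypes), nrow = 1)
  .seg_type_stats(G, fam, epsilon)[[seg_type]]$loglik
}

#' Fit the segregation mixture model by EM
#'
#' SNP-level mixture over the three segregation types with shared mixture
#' weights `pi` and a single shared per-allele error rate `epsilon`. The
#' E-step computes per-site type responsibilities and expected allele-flip
#' counts; the M-step updates `pi` as the mean responsibility and `epsilon`
#' as expected flips over allele reads. The observed-data log-likelihood is
#' checked to be non-decreasing at every iteration.
#'
#' @param table a filtered [genotype_table] whose samples include the cross
#'   (one mother, one father, sexed offspring); panel samples are ignored.
#' @param epsilon0 initial error rate (default 0.02).
#' @param pi0 initial mixture weights over
#'   `c(autosomal, xy, x_hemizygous)` (default uniform).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @return an object of class `seg_fit`: fitted `epsilon`, `pi`, per-site
#'   posterior type probabilities, the best XY parental configuration per
#'   site, and the log-likelihood trace.
#' @export
fit_em <- function(table, epsilon0 = 0.02, pi0 = rep(1 / 3, 3),
                   tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(table, "genotype_table"),
            epsilon0 >= 0, epsilon0 < 0.5,
            length(pi0) == 3, abs(sum(pi0) - 1) < 1e-9)
  cross <- table$samples$role %in% c("mother", "father", "offspring")
  samples <- table$samples[cross, , drop = FALSE]
  G <- table$genotypes[, cross, drop = FALSE]
  fam <- .family_indices(samples)
  n <- nrow(G)
  if (n == 0) stop("empty genotype table")
  reads_total <- 2 * sum(!is.na(G))

  eps <- max(epsilon0, 1e-12)
  pi <- pi0
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- .seg_type_stats(G, fam, eps, want_flips = TRUE)
    L <- do.call(cbind, lapply(SEG_TYPES, function(t) st[[t]]$loglik))
    Flips <- do.call(cbind, lapply(SEG_TYPES, function(t) st[[t]]$flips))
    A <- sweep(L, 2, log(pi), "+")
    m <- apply(A, 1, max)
    m_safe <- ifelse(is.finite(m), m, 0)
    ll_i <- ifelse(is.finite(m), m + log(rowSums(exp(A - m_safe))), -Inf)
    ll <- sum(ll_i)
    if (!is.finite(ll))
      stop("zero likelihood for some site; data inconsistent with the model")
    if (ll < ll_old - 1e-6 * max(1, abs(ll_old)))
      stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
    ll_trace <- c(ll_trace, ll)
    gamma <- exp(A - ll_i)
    pi_new <- colMeans(gamma)
    eps_new <- max(sum(gamma * Flips) / reads_total, 1e-12)
    done <- is.finite(ll_old) &&
      abs(ll - ll_old) < tol * max(1, abs(ll_old))
    pi <- pi_new
    eps <- min(eps_new, 0.499)
    ll_old <- ll
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")

  # final posteriors and best xy configs at the fitted parameters
  st <- .seg_type_stats(G, fam, eps, want_config = TRUE)
  L <- do.call(cbind, lapply(SEG_TYPES, function(t) st[[t]]$loglik))
  A <- sweep(L, 2, log(pi), "+")
  m <- apply(A, 1, max)
  m_safe <- ifelse(is.finite(m), m, 0)
  ll_i <- ifelse(is.finite(m), m + log(rowSums(exp(A - m_safe))), -Inf)
  gamma <- exp(A - ll_i)
  colnames(gamma) <- SEG_TYPES

  W <- st$xy$config_post
  cfgs <- st$xy$configs
  best <- max.col(W, ties.method = "first")
  # a tie in config posterior, or X = Y in the best config, leaves the
  # allele orientation ambiguous
  best_p <- W[cbind(seq_len(n), best)]
  runner <- apply(W, 1, function(w) sort(w, decreasing = TRUE)[2])
  ambiguous <- (best_p - runner) < 1e-9 |
    cfgs$father_x[best] == cfgs$father_y[best]

  posterior <- cbind(table$sites[, c("chrom", "pos", "ref", "alt")],
                     as.data.frame(gamma))
  best_config <- data.frame(mother = cfgs$mother[best],
                            father_x = cfgs$father_x[best],
                            father_y = cfgs$father_y[best],
                            ambiguous = ambiguous)
  structure(list(epsilon = eps, pi = setNames(pi, SEG_TYPES),
                 posterior = posterior, best_config = best_config,
                 loglik_trace = ll_trace, converged = converged,
                 n_iter = length(ll_trace)),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf(
    "seg_fit: %d sites, epsilon = %.4g, pi = (%s), %d EM iterations%s\n",
    nrow(x$posterior), x$epsilon,
    paste(sprintf("%s %.3f", names(x$pi), x$pi), collapse = ", "),
    x$n_iter, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' X/Y allele assignment from the best parental configuration
#'
#' Under the XY type, the Y allele is the father's Y-haplotype allele of the
#' maximising configuration; the X allele is the other allele at the site.
#'
#' @param site one row of a sites table (`ref`, `alt` columns).
#' @param best_config one row of a `seg_fit$best_config` table.
#' @return list with `x_allele`, `y_allele` (bases) or `NULL` when the
#'   configuration is ambiguous.
#' @export
assign_xy_alleles <- function(site, best_config) {
  if (isTRUE(best_config$ambiguous)) return(NULL)
  y <- if (best_config$father_y == 1L) site$alt else site$ref
  x <- if (best_config$father_y == 1L) site$ref else site$alt
  list(x_allele = x, y_allele = y)
}

#' Call sex-linked SNPs from fitted posteriors
#'
#' Sites whose posterior probability of the XY type strictly exceeds the
#' threshold are returned with their X/Y allele assignment. Sites whose best
#' parental configuration is ambiguous (tied, or X = Y) are dropped with a
#' message, since downstream allele-specific analyses need an orientation.
#'
#' @param fit a `seg_fit` from [fit_em].
#' @param threshold posterior probability cutoff (default 0.6, strict `>`).
#' @return an [xy_snp_set] with `source = "probabilistic"` and the posterior
#'   in column `p_xy`.
#' @export
classify_sex_linked <- function(fit, threshold = 0.6) {
  stopifnot(inherits(fit, "seg_fit"), threshold >= 0, threshold <= 1)
  sel <- fit$posterior$xy > threshold
  amb <- sel & fit$best_config$ambiguous
  if (any(amb))
    message(sum(amb), " sex-linked site(s) with ambiguous X/Y orientation ",
            "dropped")
  sel <- sel & !amb
  sites <- fit$posterior[sel, , drop = FALSE]
  bc <- fit$best_config[sel, , drop = FALSE]
  y <- ifelse(bc$father_y == 1L, sites$alt, sites$ref)
  x <- ifelse(bc$father_y == 1L, sites$ref, sites$alt)
  xy_snp_set(data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    x_allele = x, y_allele = y, source = "probabilistic", validated = FALSE,
    p_xy = sites$xy, stringsAsFactors = FALSE))
}
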