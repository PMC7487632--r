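# Independent brute-force oracles. These deliberately share no code with
# the package internals: everything is enumerated at the allele level.

# P(observed genotype | true allele pair), enumerating the two flips
oracle_obs_prob <- function(obs, a1, a2, eps) {
  p <- 0
  for (f1 in 0:1) for (f2 in 0:1) {
    o1 <- if (f1) 1 - a1 else a1
    o2 <- if (f2) 1 - a2 else a2
    pf <- (if (f1) eps else 1 - eps) * (if (f2) eps else 1 - eps)
    if (o1 + o2 == obs) p <- p + pf
  }
  p
}

.gt_alleles <- function(gt) switch(as.character(gt),
                                   "0" = c(0, 0), "1" = c(0, 1),
                                   "2" = c(1, 1))

# exhaustive-enumeration log-likelihood of one site's family genotypes.
# genotypes: named vector in design order; configs enumerated explicitly,
# offspring transmissions enumerated allele by allele.
oracle_snp_loglik <- function(genotypes, design, type, eps) {
  gm <- genotypes[design$role == "mother"]
  gf <- genotypes[design$role == "father"]
  off <- which(design$role == "offspring")
  osex <- design$sex[off]
  og <- genotypes[off]

  obs_term <- function(obs, alleles) {
    if (is.na(obs)) 1 else oracle_obs_prob(obs, alleles[1], alleles[2], eps)
  }
  # offspring likelihood given the two possible maternal alleles and a
  # rule giving the paternal contribution
  child_lik <- function(obs, m_alleles, pat_alleles, hemi = FALSE) {
    tot <- 0
    for (am in m_alleles) {
      if (hemi) {
        # single maternal allele observed as two reads of itself
        tot <- tot + 0.5 * obs_term(obs, c(am, am))
      } else {
        for (ap in pat_alleles)
          tot <- tot + 0.5 * (1 / length(pat_alleles)) *
            obs_term(obs, c(am, ap))
      }
    }
    tot
  }

  lik <- 0
  if (type == "autosomal") {
    configs <- expand.grid(m = 0:2, f = 0:2)
    for (r in seq_len(nrow(configs))) {
      ma <- .gt_alleles(configs$m[r]); fa <- .gt_alleles(configs$f[r])
      term <- obs_term(gm, ma) * obs_term(gf, fa)
      for (k in seq_along(off))
        term <- term * child_lik(og[k], ma, fa)
      lik <- lik + term / nrow(configs)
    }
  } else if (type == "xy") {
    # Y allele private to the Y haplotype: only the two orientations
    configs <- data.frame(m = c(0, 2), fx = c(0, 1), fy = c(1, 0))
    for (r in seq_len(nrow(configs))) {
      ma <- .gt_alleles(configs$m[r])
      fx <- configs$fx[r]; fy <- configs$fy[r]
      term <- obs_term(gm, ma) * obs_term(gf, c(fx, fy))
      for (k in seq_along(off)) {
        pat <- if (osex[k] == "female") fx else fy
        term <- term * child_lik(og[k], ma, pat)
      }
      lik <- lik + term / nrow(configs)
    }
  } else if (type == "x_hemizygous") {
    configs <- expand.grid(m = 0:2, fx = 0:1)
    for (r in seq_len(nrow(configs))) {
      ma <- .gt_alleles(configs$m[r]); fx <- configs$fx[r]
      term <- obs_term(gm, ma) * obs_term(gf, c(fx, fx))
      for (k in seq_along(off)) {
        term <- term * if (osex[k] == "female")
          child_lik(og[k], ma, fx) else child_lik(og[k], ma, NULL,
                                                  hemi = TRUE)
      }
      lik <- lik + term / nrow(configs)
    }
  } else stop("bad type")
  log(lik)
}

# --- NG86 oracle: per-codon enumeration, recursive pathway walk ----------

oracle_codon_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

oracle_syn_sites <- function(codon) {
  code <- oracle_codon_table()
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# all mutation orderings between two codons; returns mean syn / nonsyn
# difference counts over stop-free paths (all paths when none are free)
oracle_codon_diffs <- function(c1, c2) {
  code <- oracle_codon_table()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  walk <- function(order) {
    cur <- c1; sd <- nd <- 0; stop_hit <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") stop_hit <- TRUE
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, stop_hit)
  }
  res <- t(sapply(perms(pos), walk))
  use <- res[, 3] == 0
  if (!any(use)) use <- rep(TRUE, nrow(res))
  c(mean(res[use, 1]), mean(res[use, 2]))
}

oracle_ng86 <- function(seq_a, seq_b) {
  code <- oracle_codon_table()
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  keep <- ca %in% names(code) & cb %in% names(code) &
    code[ca] != "*" & code[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(sapply(ca, oracle_syn_sites)) +
          sum(sapply(cb, oracle_syn_sites))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(sapply(seq_along(ca),
                      function(i) oracle_codon_diffs(ca[i], cb[i])))
  list(S = S, N = N, Sd = d[1], Nd = d[2])
}

# --- random fixtures -----------------------------------------------------

random_codon_pair <- function(n_codons, max_diff_per_codon = 2) {
  bases <- c("A", "C", "G", "T")
  code <- oracle_codon_table()
  non_stop <- names(code)[code != "*"]
  repeat {
    a <- sample(non_stop, n_codons, replace = TRUE)
    b <- vapply(a, function(cd) {
      k <- sample(0:max_diff_per_codon, 1, prob = c(0.6, 0.3, 0.1))
      if (k == 0) return(cd)
      pos <- sample(1:3, k)
      for (p in pos) {
        substr(cd, p, p) <- sample(setdiff(bases, substr(cd, p, p)), 1)
      }
      cd
    }, character(1))
    bad <- code[b] == "*"
    if (!any(bad)) break
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

random_family_genotypes <- function(design, p_missing = 0.1) {
  g <- sample(c(0:2, NA), nrow(design), replace = TRUE,
              prob = c((1 - p_missing) / 3, (1 - p_missing) / 3,
                       (1 - p_missing) / 3, p_missing))
  setNames(g, design$sample_id)
}

small_design <- function(n_daughters = 2, n_sons = 2) {
  sample_design(
    c("m", "f", paste0("d", seq_len(n_daughters), recycle0 = TRUE),
      paste0("s", seq_len(n_sons), recycle0 = TRUE)),
    c("mother", "father", rep("offspring", n_daughters + n_sons)),
    c("female", "male", rep("female", n_daughters), rep("male", n_sons)))
}

# hand-built genotype table; G is a sites x samples matrix of 0/1/2/NA
make_table <- function(G, design, chrom = "chr2",
                       pos = seq(100, by = 100, length.out = nrow(G)),
                       ref = "A", alt = "G", with_depth = TRUE) {
  n <- nrow(G)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  if (with_depth) {
    rd <- matrix(10L, n, ncol(G)); ad <- matrix(0L, n, ncol(G))
    ad[which(G == 1L)] <- 10L
    ad[which(G == 2L)] <- 20L; rd[which(G == 2L)] <- 0L
    rd[which(is.na(G))] <- 0L; ad[which(is.na(G))] <- 0L
    ad[which(G == 1L)] <- 10L; rd[which(G == 1L)] <- 10L
    genotype_table(sites, design, G, rd, ad)
  } else {
    genotype_table(sites, design, G)
  }
}
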