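#' Fixed relationship hypotheses
#'
#' IBD coefficients (k0, k1, k2) — the probabilities that a dyad shares 0, 1
#' or 2 alleles identical by descent at a locus — for the four canonical
#' non-inbred relationships: unrelated U = (1, 0, 0), half siblings
#' HS = (1/2, 1/2, 0), full siblings FS = (1/4, 1/2, 1/4) and
#' parent-offspring PO = (0, 1, 0). The coefficient of relatedness is
#' `r = k2 + k1/2`.
#'
#' @return 4 x 3 numeric matrix with rows U, HS, FS, PO and columns
#'   k0, k1, k2.
#' @export
relationship_hypotheses <- function() {
  matrix(c(1, 0, 0,
           0.5, 0.5, 0,
           0.25, 0.5, 0.25,
           0, 1, 0),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("U", "HS", "FS", "PO"), c("k0", "k1", "k2")))
}

# Vectorised genotype-pair probabilities conditional on sharing 0/1/2 alleles
# IBD. A1,A2 / B1,B2 are allele labels of the two unordered genotypes,
# PA1.. the matching frequencies. P0 is the product of the two Hardy-Weinberg
# genotype probabilities; P2 is HW(g1) when the genotypes are identical in
# state; P1 = HW(g1) * mean over the two alleles of g1 of the probability
# that g2 arises given that allele is the IBD copy.
case_probs_vec <- function(A1, A2, B1, B2, PA1, PA2, PB1, PB2) {
  hw1 <- ifelse(A1 == A2, PA1 * PA1, 2 * PA1 * PA2)
  hw2 <- ifelse(B1 == B2, PB1 * PB1, 2 * PB1 * PB2)
  P0 <- hw1 * hw2
  ibs2 <- (A1 == B1 & A2 == B2) | (A1 == B2 & A2 == B1)
  P2 <- ifelse(ibs2, hw1, 0)
  t1 <- ifelse(B1 == B2, (A1 == B1) * PB1,
               (A1 == B1) * PB2 + (A1 == B2) * PB1)
  t2 <- ifelse(B1 == B2, (A2 == B1) * PB1,
               (A2 == B1) * PB2 + (A2 == B2) * PB1)
  P1 <- hw1 * 0.5 * (t1 + t2)
  list(P0 = P0, P1 = P1, P2 = P2)
}

# frequency lookup for one locus; label 0 is the null allele
freq_of <- function(labels, f) {
  nullf <- attr(f, "null") %||% 0
  out <- ifelse(labels == 0L, nullf, unname(f[as.character(labels)]))
  if (anyNA(out))
    stop_ws("unknown allele(s) at a locus: ",
            paste(unique(labels[is.na(out)]), collapse = ", "))
  out
}

# candidate true genotypes for an observed genotype: an observed homozygote
# may hide a null heterozygote when the locus has a null allele frequency
interp_genotypes <- function(g, f) {
  nullf <- attr(f, "null") %||% 0
  if (nullf > 0 && g[1] == g[2]) list(g, c(g[1], 0L)) else list(g)
}

# (P0, P1, P2) for one locus of one pair, summing over null-allele
# interpretations when applicable
locus_case_probs <- function(g1, g2, f) {
  P <- c(P0 = 0, P1 = 0, P2 = 0)
  for (t1 in interp_genotypes(g1, f)) {
    for (t2 in interp_genotypes(g2, f)) {
      cp <- case_probs_vec(t1[1], t1[2], t2[1], t2[2],
                           freq_of(t1[1], f), freq_of(t1[2], f),
                           freq_of(t2[1], f), freq_of(t2[2], f))
      P <- P + c(cp$P0, cp$P1, cp$P2)
    }
  }
  P
}

#' Likelihood of a genotype pair at one locus under given IBD coefficients
#'
#' Probability of observing the unordered genotype pair `(g1, g2)` at a
#' single locus given allele frequencies and IBD coefficients
#' `k = (k0, k1, k2)`: `k2*P2 + k1*P1 + k0*P0` with the standard non-inbred
#' genotype-pair probabilities (e.g. for identical homozygotes AiAi/AiAi:
#' P2 = pi^2, P1 = pi^3, P0 = pi^4).
#'
#' @param g1,g2 length-2 integer vectors of allele labels (unordered).
#' @param freqs_locus named numeric vector of allele frequencies for the
#'   locus (may carry a `null` attribute).
#' @param k numeric length-3 vector (k0, k1, k2) summing to 1.
#' @return Probability (numeric scalar).
#' @export
locus_pair_likelihood <- function(g1, g2, freqs_locus, k) {
  if (length(g1) != 2 || length(g2) != 2)
    stop_ws("g1 and g2 must be length-2 allele vectors")
  if (any(g1 == 0L) || any(g2 == 0L))
    stop_ws("genotypes must be non-missing")
  if (abs(sum(k) - 1) > 1e-6 || any(k < -1e-12))
    stop_ws("k must be a probability vector (k0, k1, k2)")
  P <- locus_case_probs(as.integer(g1), as.integer(g2), freqs_locus)
  unname(k[1] * P["P0"] + k[2] * P["P1"] + k[3] * P["P2"])
}

# extract the pair's genotype vectors and haplotypes from a panel
#' Genotypes of a pair of individuals from a panel
#'
#' Convenience accessor returning the flat genotype vectors and mtDNA
#' haplotypes of two panel members, as consumed by the pair-level relatedness
#' functions.
#'
#' @param panel a [genotype_panel()].
#' @param id1,id2 individual ids present in the panel.
#' @return List with `g1`, `g2` (integer vectors, two entries per locus, 0 =
#'   missing), `hap1`, `hap2`.
#' @export
panel_pair <- function(panel, id1, id2) {
  stopifnot(inherits(panel, "genotype_panel"))
  i <- match(c(id1, id2), panel$ids)
  if (anyNA(i))
    stop_ws("unknown individual(s): ",
            paste(c(id1, id2)[is.na(i)], collapse = ", "))
  list(g1 = unname(panel$alleles[i[1], ]), g2 = unname(panel$alleles[i[2], ]),
       hap1 = panel$mtdna[i[1]], hap2 = panel$mtdna[i[2]])
}

# L x 3 matrix of (P0, P1, P2) over loci typed in both members
pair_probs_matrix <- function(g1, g2, freqs) {
  L <- length(freqs)
  if (length(g1) != 2 * L || length(g2) != 2 * L)
    stop_ws("genotype vectors must have two entries per locus")
  P <- matrix(NA_real_, nrow = 0, ncol = 3,
              dimnames = list(NULL, c("P0", "P1", "P2")))
  for (l in seq_len(L)) {
    a <- g1[c(2 * l - 1, 2 * l)]
    b <- g2[c(2 * l - 1, 2 * l)]
    if (any(a == 0L) || any(b == 0L)) next
    P <- rbind(P, locus_case_probs(a, b, freqs[[l]]))
  }
  P
}

#' Multilocus log-likelihood of a genotype pair under given IBD coefficients
#'
#' Sum of per-locus log likelihoods over the loci typed in both members.
#' Loci missing in either member are skipped (pairwise deletion); a pair must
#' share at least `min_loci` typed loci. `-Inf` is returned when some locus
#' is impossible under `k` (e.g. zero alleles shared under parent-offspring).
#'
#' @param g1,g2 flat genotype vectors (two entries per locus, 0 = missing).
#' @param freqs an `allele_freqs` object from
#'   [estimate_allele_frequencies()].
#' @param k numeric (k0, k1, k2).
#' @param min_loci minimum number of shared typed loci (default 6).
#' @return Log-likelihood (may be `-Inf`).
#' @export
pair_loglikelihood <- function(g1, g2, freqs, k, min_loci = 6) {
  P <- pair_probs_matrix(g1, g2, freqs)
  if (nrow(P) < min_loci)
    stop_ws("only ", nrow(P), " loci typed in both members (min_loci = ",
            min_loci, ")")
  lnl_at_k(P, k)
}

lnl_at_k <- function(P, k) {
  v <- as.vector(P %*% k)
  if (any(v <= 0)) return(-Inf)
  sum(log(v))
}

# grid over the k simplex at the given step, plus the four fixed hypotheses
k_grid <- function(step = 0.05) {
  k0 <- seq(0, 1, by = step)
  g <- do.call(rbind, lapply(k0, function(a) {
    k2 <- seq(0, 1 - a, by = step)
    cbind(k0 = a, k1 = 1 - a - k2, k2 = k2)
  }))
  rbind(g, relationship_hypotheses())
}

# maximise the pair log-likelihood over the k simplex: deterministic coarse
# grid then Nelder-Mead refinement on (k0, k2)
mle_k_core <- function(P, grid_step = 0.05, tol = 1e-8) {
  G <- k_grid(grid_step)
  M <- P %*% t(G)                      # loci x grid points
  lv <- colSums(log(M))                # log(0) = -Inf propagates
  lv[is.nan(lv)] <- -Inf
  best <- which.max(lv)
  k_best <- G[best, ]
  lnl_best <- lv[best]
  obj <- function(par) {
    k0 <- par[1]; k2 <- par[2]; k1 <- 1 - k0 - k2
    if (k0 < 0 || k2 < 0 || k1 < 0) return(1e18)
    v <- as.vector(P %*% c(k0, k1, k2))
    if (any(v <= 0)) return(1e18)
    -sum(log(v))
  }
  if (is.finite(lnl_best)) {
    opt <- stats::optim(c(k_best[1], k_best[3]), obj, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = 1000))
    if (-opt$value > lnl_best) {
      k0 <- max(0, opt$par[1]); k2 <- max(0, opt$par[2])
      k1 <- max(0, 1 - k0 - k2)
      k_ref <- c(k0, k1, k2) / sum(c(k0, k1, k2))
      lnl_ref <- lnl_at_k(P, k_ref)
      if (lnl_ref > lnl_best) {
        k_best <- k_ref
        lnl_best <- lnl_ref
      }
    }
  }
  names(k_best) <- c("k0", "k1", "k2")
  list(k = k_best, lnl = lnl_best)
}

#' Maximum likelihood IBD coefficients for a genotype pair
#'
#' Maximises the multilocus pair log-likelihood over the (k0, k1, k2)
#' simplex. The optimisation is deterministic: a coarse grid search (step
#' 0.05, always including the four fixed relationship hypotheses) followed
#' by Nelder-Mead refinement to relative tolerance 1e-8, so the returned
#' log-likelihood is never below any fixed hypothesis.
#'
#' @inheritParams pair_loglikelihood
#' @return List with `k` (named k0/k1/k2), `r` (`k2 + k1/2`), `lnl` and
#'   `n_loci`.
#' @export
mle_k <- function(g1, g2, freqs, min_loci = 6) {
  P <- pair_probs_matrix(g1, g2, freqs)
  if (nrow(P) < min_loci)
    stop_ws("only ", nrow(P), " loci typed in both members (min_loci = ",
            min_loci, ")")
  fit <- mle_k_core(P)
  list(k = fit$k, r = unname(fit$k["k2"] + fit$k["k1"] / 2), lnl = fit$lnl,
       n_loci = nrow(P))
}

#' Classify the relationship of a genotype pair
#'
#' Evaluates the pair log-likelihood at the four fixed relationship
#' hypotheses (U, HS, FS, PO) and at the unconstrained maximum, and reports
#' the best-supported fixed relationship. Ties are broken toward the less
#' related hypothesis (preference order U > HS > FS > PO), which is
#' conservative against false kinship claims.
#'
#' @inheritParams pair_loglikelihood
#' @return Object of class `relatedness_estimate`: list with `k_hat`,
#'   `r_hat`, `lnl` (named vector over U/HS/FS/PO/unconstrained), `best`,
#'   `n_loci`.
#' @export
classify_relationship <- function(g1, g2, freqs, min_loci = 6) {
  P <- pair_probs_matrix(g1, g2, freqs)
  if (nrow(P) < min_loci)
    stop_ws("only ", nrow(P), " loci typed in both members (min_loci = ",
            min_loci, ")")
  hyp <- relationship_hypotheses()
  lnl_h <- apply(hyp, 1, function(k) lnl_at_k(P, k))
  fit <- mle_k_core(P)
  best <- names(lnl_h)[1]
  for (h in names(lnl_h)[-1]) if (lnl_h[[h]] > lnl_h[[best]]) best <- h
  structure(list(
    k_hat = fit$k,
    r_hat = unname(fit$k["k2"] + fit$k["k1"] / 2),
    lnl = c(lnl_h, unconstrained = fit$lnl),
    best = best,
    n_loci = nrow(P)), class = "relatedness_estimate")
}

#' @export
print.relatedness_estimate <- function(x, ...) {
  cat("<relatedness_estimate> best:", x$best,
      " r_hat:", format(x$r_hat, digits = 3),
      " loci:", x$n_loci, "\n")
  cat("  k_hat:", paste(format(x$k_hat, digits = 3), collapse = " "), "\n")
  cat("  lnL:  ", paste(names(x$lnl), format(x$lnl, digits = 5),
                        sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Mendelian and mtDNA parent-offspring compatibility
#'
#' A pair is compatible with a parent-offspring relationship when the two
#' members share at least one allele at every locus typed in both, and —
#' when testing a maternal link and both haplotypes are known — their mtDNA
#' haplotypes match. Set `maternal = FALSE` for putative father-offspring
#' pairs, where the haplotypes need not match.
#'
#' @param g1,g2 flat genotype vectors (two entries per locus, 0 = missing).
#' @param hap1,hap2 mtDNA haplotypes (`NA` = unknown).
#' @param maternal require matching haplotypes when both known (default
#'   `TRUE`).
#' @return Logical scalar.
#' @export
po_compatibility <- function(g1, g2, hap1 = NA, hap2 = NA, maternal = TRUE) {
  L <- length(g1) / 2
  for (l in seq_len(L)) {
    a <- g1[c(2 * l - 1, 2 * l)]
    b <- g2[c(2 * l - 1, 2 * l)]
    if (any(a == 0L) || any(b == 0L)) next
    if (!any(a %in% b)) return(FALSE)
  }
  if (maternal && !is.na(hap1) && !is.na(hap2) && hap1 != hap2) return(FALSE)
  TRUE
}

#' Simulate genotype pairs under fixed IBD coefficients
#'
#' Draws `n` independent genotype pairs at the loci of `freqs` under IBD
#' coefficients `k`: at each locus the IBD sharing mode (0, 1 or 2 alleles)
#' is drawn from `k`, shared alleles are drawn once from the allele
#' frequencies and copied, remaining alleles are drawn independently.
#'
#' @param freqs an `allele_freqs` object (null-allele frequencies, if any,
#'   are ignored: simulated genotypes are fully observed).
#' @param k numeric (k0, k1, k2).
#' @param n number of pairs.
#' @param seed optional integer seed for reproducibility.
#' @return List with integer matrices `a1`, `a2`, `b1`, `b2` (`n` rows, one
#'   column per locus) of allele labels.
#' @export
simulate_genotype_pairs <- function(freqs, k, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    L <- length(freqs)
    a1 <- a2 <- b1 <- b2 <- matrix(0L, n, L)
    for (l in seq_len(L)) {
      f <- freqs[[l]]
      f <- f / sum(f)  # visible alleles only
      labs <- as.integer(names(f))
      draw <- function(m) labs[sample.int(length(labs), m, replace = TRUE,
                                          prob = f)]
      mode <- sample.int(3, n, replace = TRUE, prob = k) - 1L
      x1 <- draw(n); x2 <- draw(n); y1 <- draw(n); y2 <- draw(n)
      # mode 0: all independent; mode 1: one shared; mode 2: both shared
      s1 <- ifelse(mode >= 1, x1, y1)
      s2 <- ifelse(mode == 2, x2, y2)
      a1[, l] <- x1; a2[, l] <- x2
      b1[, l] <- s1; b2[, l] <- s2
    }
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
  })
}

# vectorised (P0, P1, P2) for simulated pairs: n x L matrices
sim_case_probs <- function(sim, freqs) {
  L <- length(freqs)
  n <- nrow(sim$a1)
  P0 <- P1 <- P2 <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    f <- freqs[[l]]
    f <- f / sum(f)
    lk <- function(lab) unname(f[as.character(lab)])
    cp <- case_probs_vec(sim$a1[, l], sim$a2[, l], sim$b1[, l], sim$b2[, l],
                         lk(sim$a1[, l]), lk(sim$a2[, l]),
                         lk(sim$b1[, l]), lk(sim$b2[, l]))
    P0[, l] <- cp$P0; P1[, l] <- cp$P1; P2[, l] <- cp$P2
  }
  list(P0 = P0, P1 = P1, P2 = P2)
}

# multilocus lnL of simulated pairs under k, vector of length n
sim_lnl <- function(cp, k) {
  v <- k[1] * cp$P0 + k[2] * cp$P1 + k[3] * cp$P2
  out <- rowSums(log(v))
  out[is.nan(out)] <- -Inf
  out
}

#' Simulation test of parent-offspring against the full-sibling alternative
#'
#' Both PO and FS imply r = 0.5, so a likelihood comparison is needed to
#' separate them. The statistic is `Lambda = lnL(PO) - lnL(FS)` for the
#' observed pair. `n_sim` genotype pairs are simulated under the FS
#' alternative at the loci typed in both members, and the p-value is the
#' fraction of simulated pairs whose statistic is at least the observed one.
#' A small p-value means the observed support for PO over FS would rarely
#' arise for true full siblings.
#'
#' @inheritParams pair_loglikelihood
#' @param n_sim number of simulated pairs (at least 100).
#' @param seed optional integer seed; the p-value is reproducible given the
#'   seed.
#' @return List with `p`, `lambda_obs`, `n_sim`.
#' @export
test_po_vs_fs <- function(g1, g2, freqs, n_sim = 10000, seed = NULL,
                          min_loci = 6) {
  if (n_sim < 100) stop_ws("n_sim must be at least 100")
  # restrict to loci typed in both, in panel order
  typed <- vapply(seq_along(freqs), function(l) {
    idx <- c(2 * l - 1, 2 * l)
    all(g1[idx] != 0L) && all(g2[idx] != 0L)
  }, TRUE)
  if (sum(typed) < min_loci)
    stop_ws("only ", sum(typed), " loci typed in both members (min_loci = ",
            min_loci, ")")
  fsub <- freqs[typed]
  class(fsub) <- "allele_freqs"
  hyp <- relationship_hypotheses()
  P <- pair_probs_matrix(g1, g2, freqs)
  lambda_obs <- lnl_at_k(P, hyp["PO", ]) - lnl_at_k(P, hyp["FS", ])
  sim <- simulate_genotype_pairs(fsub, hyp["FS", ], n_sim, seed = seed)
  cp <- sim_case_probs(sim, fsub)
  lambda_sim <- sim_lnl(cp, hyp["PO", ]) - sim_lnl(cp, hyp["FS", ])
  list(p = mean(lambda_sim >= lambda_obs), lambda_obs = lambda_obs,
       n_sim = n_sim)
}

#' Pairwise relatedness table over a genotype panel
#'
#' Runs the maximum likelihood relatedness estimate and relationship
#' classification for every unordered pair of panel members with at least
#' `min_loci` loci typed in both (other pairs are dropped).
#'
#' @param panel a [genotype_panel()].
#' @param freqs allele frequencies; default estimates them from the full
#'   panel (focal pairs included, as is conventional for likelihood
#'   relatedness estimators).
#' @param min_loci minimum shared typed loci (default 6).
#' @param maternal_mtdna require matching mtDNA for PO compatibility when
#'   both haplotypes are known (default `TRUE`).
#' @return data.frame with columns `id1`, `id2`, `n_loci`, `k0`, `k1`, `k2`,
#'   `r_hat`, `lnl_U`, `lnl_HS`, `lnl_FS`, `lnl_PO`, `lnl_max`, `best`,
#'   `po_compatible`, `mtdna_match`.
#' @export
relatedness_table <- function(panel, freqs = NULL, min_loci = 6,
                              maternal_mtdna = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  empty <- data.frame(id1 = character(), id2 = character(),
                      n_loci = integer(), k0 = numeric(), k1 = numeric(),
                      k2 = numeric(), r_hat = numeric(), lnl_U = numeric(),
                      lnl_HS = numeric(), lnl_FS = numeric(),
                      lnl_PO = numeric(), lnl_max = numeric(),
                      best = character(), po_compatible = logical(),
                      mtdna_match = logical())
  if (length(panel$ids) < 2) return(empty)
  freqs <- freqs %||% estimate_allele_frequencies(panel)
  ids <- panel$ids
  rows <- vector("list", choose(length(ids), 2))
  ri <- 0L
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq(i + 1, length(ids))) {
      pr <- panel_pair(panel, ids[i], ids[j])
      P <- pair_probs_matrix(pr$g1, pr$g2, freqs)
      if (nrow(P) < min_loci) next
      est <- classify_relationship(pr$g1, pr$g2, freqs, min_loci = min_loci)
      mt <- if (is.na(pr$hap1) || is.na(pr$hap2)) NA else pr$hap1 == pr$hap2
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        id1 = ids[i], id2 = ids[j], n_loci = est$n_loci,
        k0 = unname(est$k_hat["k0"]), k1 = unname(est$k_hat["k1"]),
        k2 = unname(est$k_hat["k2"]), r_hat = est$r_hat,
        lnl_U = unname(est$lnl["U"]), lnl_HS = unname(est$lnl["HS"]),
        lnl_FS = unname(est$lnl["FS"]), lnl_PO = unname(est$lnl["PO"]),
        lnl_max = unname(est$lnl["unconstrained"]), best = est$best,
        po_compatible = po_compatibility(pr$g1, pr$g2, pr$hap1, pr$hap2,
                                         maternal = maternal_mtdna),
        mtdna_match = mt)
    }
  }
  if (ri == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Census of parent-offspring pairs in a genotype panel
#'
#' Scans all unordered pairs, keeps those whose best-supported relationship
#' is PO *and* that are Mendelian/mtDNA compatible with parent-offspring,
#' and optionally attaches the simulation-based p-value of the PO-vs-FS
#' test. Pair classes (e.g. resighted / non-resighted / stranded) can be
#' attached for cross-tabulation.
#'
#' @inheritParams relatedness_table
#' @param classes optional named character vector mapping individual id to a
#'   class label; adds `class1`/`class2` columns.
#' @param n_sim when > 0, run [test_po_vs_fs()] with this many simulated
#'   pairs per PO pair and add a `p_po_vs_fs` column.
#' @param seed seed for the simulation test.
#' @return data.frame: the [relatedness_table()] columns restricted to the
#'   detected PO pairs, plus the optional class and p-value columns.
#' @export
po_census <- function(panel, freqs = NULL, classes = NULL, min_loci = 6,
                      maternal_mtdna = TRUE, n_sim = 0, seed = NULL) {
  tab <- relatedness_table(panel, freqs = freqs, min_loci = min_loci,
                           maternal_mtdna = maternal_mtdna)
  out <- tab[tab$best == "PO" & tab$po_compatible, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(classes)) {
    out$class1 <- unname(classes[out$id1])
    out$class2 <- unname(classes[out$id2])
  }
  if (n_sim > 0 && nrow(out)) {
    freqs <- freqs %||% estimate_allele_frequencies(panel)
    out$p_po_vs_fs <- NA_real_
    for (i in seq_len(nrow(out))) {
      pr <- panel_pair(panel, out$id1[i], out$id2[i])
      out$p_po_vs_fs[i] <- test_po_vs_fs(
        pr$g1, pr$g2, freqs, n_sim = n_sim,
        seed = if (is.null(seed)) NULL else seed + i,
        min_loci = min_loci)$p
    }
  }
  out
}
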