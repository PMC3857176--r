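biallelic_freqs <- function(p = 0.5) {
  f <- c(`1` = p, `2` = 1 - p)
  attr(f, "null") <- 0
  structure(list(L1 = f), class = "allele_freqs")
}

test_that("single-locus pair likelihood follows the seven-case table", {
  f <- biallelic_freqs(0.5)[[1]]
  hyp <- relationship_hypotheses()
  # identical homozygotes: P0 = p^4, P1 = p^3, P2 = p^2
  expect_equal(locus_pair_likelihood(c(1, 1), c(1, 1), f, hyp["U", ]), 0.0625)
  expect_equal(locus_pair_likelihood(c(1, 1), c(1, 1), f, hyp["PO", ]), 0.125)
  expect_equal(locus_pair_likelihood(c(1, 1), c(1, 1), f, c(0, 0, 1)), 0.25)
  # opposite homozygotes cannot share an allele IBD
  expect_equal(locus_pair_likelihood(c(1, 1), c(2, 2), f, hyp["PO", ]), 0)
  # seven-case spot checks at unequal frequencies, against hand algebra
  g <- c(`1` = 0.2, `2` = 0.3, `3` = 0.5); attr(g, "null") <- 0
  pi <- 0.2; pj <- 0.3; pk <- 0.5
  expect_equal(locus_pair_likelihood(c(1, 1), c(1, 2), g, c(0, 1, 0)),
               pi^2 * pj)
  expect_equal(locus_pair_likelihood(c(1, 1), c(2, 3), g, c(1, 0, 0)),
               2 * pi^2 * pj * pk)
  expect_equal(locus_pair_likelihood(c(1, 2), c(1, 2), g, c(0, 0, 1)),
               2 * pi * pj)
  expect_equal(locus_pair_likelihood(c(1, 2), c(1, 2), g, c(0, 1, 0)),
               pi * pj * (pi + pj))
  expect_equal(locus_pair_likelihood(c(1, 2), c(1, 3), g, c(0, 1, 0)),
               pi * pj * pk)
  # symmetry in the pair
  for (k in c("U", "HS", "FS", "PO"))
    expect_equal(locus_pair_likelihood(c(1, 2), c(1, 1), g, hyp[k, ]),
                 locus_pair_likelihood(c(1, 1), c(1, 2), g, hyp[k, ]))
  expect_error(locus_pair_likelihood(c(1, 9), c(1, 1), g, hyp["U", ]),
               "unknown allele")
})

test_that("the unrelated likelihood is the product of HW genotype probs", {
  set.seed(21)
  for (rep in 1:20) {
    A <- sample(2:6, 1)
    f <- stats::setNames(as.numeric(rdirmult <- {
      g <- stats::rgamma(A, 1); g / sum(g)
    }), seq_len(A))
    attr(f, "null") <- 0
    g1 <- sample(A, 2, replace = TRUE)
    g2 <- sample(A, 2, replace = TRUE)
    hw <- function(g) if (g[1] == g[2]) f[[g[1]]]^2 else
      2 * f[[g[1]]] * f[[g[2]]]
    expect_equal(locus_pair_likelihood(g1, g2, f, c(1, 0, 0)),
                 hw(g1) * hw(g2))
  }
})

test_that("genotype-pair probabilities conserve to one over all pairs", {
  # small version of the conservation property (full sweep in acceptance)
  set.seed(3)
  hyp <- relationship_hypotheses()
  for (rep in 1:5) {
    A <- sample(2:5, 1)
    g <- stats::rgamma(A, 1)
    f <- stats::setNames(g / sum(g), seq_len(A))
    attr(f, "null") <- 0
    gt <- expand.grid(i = seq_len(A), j = seq_len(A))
    gt <- gt[gt$i <= gt$j, ]
    for (h in rownames(hyp)) {
      tot <- 0
      for (a in seq_len(nrow(gt))) for (b in seq_len(nrow(gt)))
        tot <- tot + locus_pair_likelihood(c(gt$i[a], gt$j[a]),
                                           c(gt$i[b], gt$j[b]), f, hyp[h, ])
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("multilocus log-likelihood sums typed loci and guards min_loci", {
  fr <- uniform_freqs(2, 2)
  g1 <- c(1L, 1L, 1L, 1L)
  g2 <- c(1L, 1L, 1L, 2L)
  # locus 1: identical homozygotes p=0.5, PO -> 0.125; locus 2: p^2 * q
  expect_equal(pair_loglikelihood(g1, g2, fr, c(0, 1, 0), min_loci = 2),
               log(0.125) + log(0.125))
  # missing locus skipped
  g2m <- c(1L, 1L, 0L, 0L)
  expect_equal(pair_loglikelihood(g1, g2m, fr, c(0, 1, 0), min_loci = 1),
               log(0.125))
  expect_error(pair_loglikelihood(g1, g2m, fr, c(0, 1, 0), min_loci = 2),
               "min_loci")
  # impossible locus gives -Inf
  g3 <- c(2L, 2L, 1L, 1L)
  expect_identical(pair_loglikelihood(g1, g3, fr, c(0, 1, 0), min_loci = 2),
                   -Inf)
})

test_that("the unconstrained MLE dominates every fixed hypothesis", {
  fr <- uniform_freqs(10, 8)
  hyp <- relationship_hypotheses()
  set.seed(17)
  for (h in rownames(hyp)) {
    sim <- simulate_genotype_pairs(fr, hyp[h, ], 20)
    gg <- flat_genotypes(sim)
    for (i in 1:20) {
      est <- classify_relationship(gg$g1[i, ], gg$g2[i, ], fr)
      expect_gte(est$lnl[["unconstrained"]],
                 max(est$lnl[c("U", "HS", "FS", "PO")]) - 1e-9)
      expect_gte(est$r_hat, 0); expect_lte(est$r_hat, 1)
      expect_equal(sum(est$k_hat), 1, tolerance = 1e-9)
    }
  }
})

test_that("a zero-shared locus rules out PO but leaves the MLE finite", {
  # opposite homozygotes at locus 1: P1 = P2 = 0 there, so any k with
  # k0 = 0 has zero likelihood; PO is impossible while the MLE keeps k0 > 0
  fr <- uniform_freqs(6, 4)
  g1 <- rep(c(1L, 1L), 6)
  g2 <- c(2L, 2L, rep(c(1L, 1L), 5))  # locus 1 shares nothing
  fit <- mle_k(g1, g2, fr)
  expect_gt(unname(fit$k["k0"]), 0)
  expect_true(is.finite(fit$lnl))
  est <- classify_relationship(g1, g2, fr)
  expect_identical(est$lnl[["PO"]], -Inf)
  expect_true(est$best %in% c("U", "HS", "FS"))
})

test_that("identical genotypes are classified FS among the four hypotheses", {
  fr <- uniform_freqs(10, 8)
  set.seed(8)
  g <- as.integer(sample(8, 20, replace = TRUE))
  est <- classify_relationship(g, g, fr)
  # only FS puts mass on sharing both alleles IBD
  expect_equal(est$best, "FS")
  expect_gt(unname(est$k_hat["k2"]), 0.5)
})

test_that("classification ties break toward the less related hypothesis", {
  # a fixed (monomorphic) locus carries no information: every hypothesis has
  # identical likelihood, so the preference order must pick U
  f <- structure(list(L1 = structure(c(`1` = 1), null = 0)),
                 class = "allele_freqs")
  est <- classify_relationship(c(1L, 1L), c(1L, 1L), f, min_loci = 1)
  expect_true(all(abs(est$lnl[c("U", "HS", "FS", "PO")]) < 1e-12))
  expect_equal(est$best, "U")
})

test_that("PO compatibility needs a shared allele everywhere and mtDNA match", {
  p <- trio_panel()
  pr <- panel_pair(p, "mom", "child")
  expect_true(po_compatibility(pr$g1, pr$g2, pr$hap1, pr$hap2))
  # father shares alleles but not the haplotype: fails maternal mode only
  prf <- panel_pair(p, "dad", "child")
  expect_false(po_compatibility(prf$g1, prf$g2, prf$hap1, prf$hap2,
                                maternal = TRUE))
  expect_true(po_compatibility(prf$g1, prf$g2, prf$hap1, prf$hap2,
                               maternal = FALSE))
  # one zero-shared locus kills compatibility
  g1 <- pr$g1; g2 <- pr$g2
  g2[1:2] <- setdiff(1:8, g1[1:2])[1:2]
  expect_false(po_compatibility(g1, g2, "H1", "H1"))
  # missing loci are skipped
  g2b <- pr$g2; g2b[1:2] <- 0L
  expect_true(po_compatibility(pr$g1, g2b, "H1", "H1"))
})

test_that("the PO-vs-FS simulation test is seeded and rejects for PO pairs", {
  fr <- uniform_freqs(10, 8)
  sim <- simulate_genotype_pairs(fr, c(0, 1, 0), 30, seed = 55)
  gg <- flat_genotypes(sim)
  p1 <- test_po_vs_fs(gg$g1[1, ], gg$g2[1, ], fr, n_sim = 500, seed = 9)
  p2 <- test_po_vs_fs(gg$g1[1, ], gg$g2[1, ], fr, n_sim = 500, seed = 9)
  expect_identical(p1$p, p2$p)
  expect_error(test_po_vs_fs(gg$g1[1, ], gg$g2[1, ], fr, n_sim = 50),
               "at least 100")
  # power: most PO pairs at this panel reject FS at the 5% level
  ps <- vapply(1:30, function(i)
    test_po_vs_fs(gg$g1[i, ], gg$g2[i, ], fr, n_sim = 1000,
                  seed = 100 + i)$p, 0)
  expect_gt(mean(ps < 0.05), 0.5)
})

test_that("the PO census finds the trio's two parent-offspring pairs", {
  p <- trio_panel(seed = 23)
  # stabilise frequencies with unrelated background individuals
  set.seed(71)
  bg <- matrix(sample.int(8, 40 * 20, replace = TRUE), nrow = 40)
  panel <- genotype_panel(c(p$ids, sprintf("bg%02d", 1:40)),
                          rbind(p$alleles, bg),
                          mtdna = c(p$mtdna, rep(NA, 40)))
  cen <- po_census(panel, maternal_mtdna = TRUE)
  pairs <- paste(cen$id1, cen$id2)
  expect_true(any(grepl("mom", pairs) & grepl("child", pairs)))
  expect_false(any(grepl("^mom dad$|^dad mom$", pairs)))
  # single individual: empty table
  single <- genotype_panel("x", matrix(1L, 1, 20))
  expect_equal(nrow(relatedness_table(single)), 0)
})
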