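test_that("phased r2 matches hand counts and indicator correlation", {
  # perfectly correlated loci
  H <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  h <- toy_haplotypes(H)
  expect_equal(haplotype_r2(h, 1, 2)$r2, 1)

  # haplotypes {AB, AB, ab, aB}: D = 0.125, r2 = 1/3
  H2 <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 1))
  h2 <- toy_haplotypes(H2)
  r <- haplotype_r2(h2, "m1", "m2")
  expect_equal(r$D, 0.125)
  expect_equal(r$r2, 1 / 3)

  # allele relabeling invariance
  h2b <- toy_haplotypes(cbind(1 - H2[, 1], H2[, 2]))
  expect_equal(haplotype_r2(h2b, 1, 2)$r2, r$r2)

  # r2 equals squared Pearson correlation of allele indicators
  set.seed(5)
  H3 <- matrix(rbinom(200, 1, 0.4), 20, 10)
  h3 <- toy_haplotypes(H3)
  for (pair in list(c(1, 2), c(3, 7), c(5, 10))) {
    x <- H3[, pair[1]]; y <- H3[, pair[2]]
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(haplotype_r2(h3, pair[1], pair[2])$r2, cor(x, y)^2)
  }
  # monomorphic marker errors
  h4 <- toy_haplotypes(cbind(c(1, 1, 1, 1), c(0, 1, 0, 1)))
  expect_error(haplotype_r2(h4, 1, 2), "monomorphic")
})

test_that("EM genotype r2 agrees with counting and with phased truth", {
  # no double heterozygotes: EM fixed point is direct counting
  H <- cbind(c(1, 1, 1, 0, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0, 0, 0))
  h <- toy_haplotypes(H)
  g <- as_genotypes(h)
  expect_equal(genotype_r2_em(g, 1, 2)$r2, haplotype_r2(h, 1, 2)$r2,
               tolerance = 1e-8)

  # EM equals direct numerical maximum likelihood (independent oracle)
  ml_r2 <- function(g) {
    gx <- dosage(g)[, 1]; gy <- dosage(g)[, 2]
    nll <- function(par) {
      e <- exp(c(par, 0)); hf <- e / sum(e)        # softmax over 4 freqs
      pr <- 0
      gprob <- function(h1, h2) hf[h1] * hf[h2] * (2 - (h1 == h2))
      # enumerate compatible haplotype pairs per genotype class
      ll <- 0
      for (s in seq_along(gx)) {
        hps <- expand.grid(a = 1:4, b = 1:4)
        xa <- c(0, 0, 1, 1); yb <- c(0, 1, 0, 1)
        keep <- (xa[hps$a] + xa[hps$b]) == gx[s] &
          (yb[hps$a] + yb[hps$b]) == gy[s] & hps$a <= hps$b
        p <- sum(vapply(which(keep), function(k) {
          gprob(hps$a[k], hps$b[k])
        }, 0))
        ll <- ll + log(max(p, 1e-300))
      }
      -ll
    }
    fit <- optim(c(0, 0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 5000))
    fit <- optim(fit$par, nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 20000))
    e <- exp(c(fit$par, 0)); hf <- e / sum(e)
    pA <- hf[3] + hf[4]; pB <- hf[2] + hf[4]
    D <- hf[4] - pA * pB
    D^2 / (pA * (1 - pA) * pB * (1 - pB))
  }
  set.seed(8)
  n <- 120
  x <- rbinom(2 * n, 1, 0.5)
  y <- ifelse(runif(2 * n) < 0.85, x, rbinom(2 * n, 1, 0.5))
  h2 <- toy_haplotypes(cbind(x, y))
  g2 <- as_genotypes(h2)
  r_em <- genotype_r2_em(g2, 1, 2, tol = 1e-14, max_iter = 10000L)$r2
  expect_lt(abs(r_em - ml_r2(g2)), 1e-6)
  # and approaches the phased value as the ML estimator is consistent
  r_ph <- haplotype_r2(h2, 1, 2)$r2
  expect_lt(abs(r_ph - r_em), 0.05)

  g3 <- toy_genotypes(cbind(rep("0/0", 4), c("0/1", "1/1", "0/0", "0/1")))
  expect_error(genotype_r2_em(g3, 1, 2), "monomorphic")
})

test_that("ld_matrix equals the brute-force nested loop", {
  set.seed(12)
  H <- matrix(rbinom(160, 1, 0.5), 16, 10)
  h <- toy_haplotypes(H)
  res <- ld_matrix(h)
  p <- colMeans(H)
  poly <- which(p > 0 & p < 1)
  n_pairs <- choose(length(poly), 2)
  expect_equal(nrow(res), n_pairs)
  for (k in sample(nrow(res), 5)) {
    direct <- haplotype_r2(h, res$marker_i[k], res$marker_j[k])
    expect_equal(res$r2[k], direct$r2)
    expect_equal(res$D[k], direct$D)
    expect_equal(res$dist_bp[k], direct$dist_bp)
  }
  # 3 polymorphic markers -> 3 pairs; distance cap respected
  h3 <- toy_haplotypes(matrix(rbinom(30, 1, 0.5), 10, 3),
                       pos = c(1000L, 2000L, 9000L))
  expect_lte(nrow(ld_matrix(h3)), 3L)
  res_cap <- ld_matrix(h3, max_distance = 1500)
  expect_true(all(res_cap$dist_bp <= 1500))
  # r2 always within [0, 1]
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
})

test_that("LD classes count and span correctly", {
  map <- marker_map(paste0("m", 1:4), rep("c1", 4),
                    c(1e4, 2e4, 3e4, 8e4))
  res <- data.frame(marker_i = c("m1", "m2", "m3"),
                    marker_j = c("m2", "m3", "m4"),
                    dist_bp = c(1e4, 1e4, 5e4),
                    r2 = c(0.9, 0.85, 0.3), D = 0, mode = "phased_count",
                    converged = TRUE)
  cl <- ld_block_classes(res, map)
  expect_equal(unname(cl$counts), c(2L, 0L, 1L))
  expect_equal(unname(cl$spans[["strong"]]), 2e4)  # m1-m2 and m2-m3 merge
  empty <- res[0, ]
  cl0 <- ld_block_classes(empty, map)
  expect_equal(unname(cl0$counts), c(0L, 0L, 0L))
  bad <- data.frame(name = c("a", "b"), lo = c(0.2, 0.4), hi = c(0.5, 0.6))
  expect_error(ld_block_classes(res, map, bad), "disjoint")
})

test_that("the decay curve has the right analytic limits", {
  for (n in c(10, 50, 200)) {
    expect_equal(hill_expected_r2(0, n), (10 / 22) * (1 + 18 / (11 * n)))
    expect_equal(hill_expected_r2(1e9, n), 1 / n, tolerance = 1e-6)
  }
  # monotone decreasing in C
  C <- seq(0, 100, by = 0.5)
  expect_true(all(diff(hill_expected_r2(C, 50)) < 0))
})

test_that("rho is recovered within 1% from noiseless curve data", {
  rho <- 1e-4; n <- 50
  d <- seq(500, 2e5, length.out = 150)
  res <- data.frame(dist_bp = d, r2 = hill_expected_r2(rho * d, n))
  fit <- ld_decay_fit(res, n)
  expect_true(fit$converged)
  expect_lt(abs(fit$rho - rho) / rho, 0.01)
  # degenerate input guards
  expect_error(ld_decay_fit(res[1:2, ], n), "3 distinct")
  expect_error(ld_decay_fit(res, 3), "n >= 4")
})

test_that("VIF pruning drops predictable markers deterministically", {
  set.seed(9)
  X <- matrix(rbinom(600, 1, 0.5), 60, 10)
  h <- toy_haplotypes(X)
  kept <- vif_prune(h, window_snps = 10, step_snps = 5, vif_threshold = 2)
  expect_setequal(kept, h$map$id)          # independent markers all retained

  X2 <- cbind(X[, 1:5], X[, 5], X[, 6:10]) # duplicated marker
  h2 <- toy_haplotypes(X2)
  kept2 <- vif_prune(h2, window_snps = 11, step_snps = 5, vif_threshold = 2)
  expect_lt(length(kept2), ncol(X2))
  expect_false(all(c("m5", "m6") %in% kept2))

  # threshold 2 equals the R2 > 0.5 rule in a pairwise-only toy set
  set.seed(21)
  a <- rbinom(400, 1, 0.5)
  b <- ifelse(runif(400) < 0.95, a, 1 - a)  # R2 ~ 0.81 > 0.5 -> prune one
  c_ <- rbinom(400, 1, 0.5)                 # independent -> keep
  h3 <- toy_haplotypes(cbind(a, b, c_))
  kept3 <- vif_prune(h3, window_snps = 3, step_snps = 1, vif_threshold = 2)
  expect_equal(sort(kept3), c("m2", "m3"))  # left-to-right sweep drops m1
  r2_ab <- cor(a, b)^2
  expect_gt(r2_ab, 0.5)
})
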