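test_that("Jaccard dissimilarities satisfy the defining identities", {
  m <- matrix(c(1, 2, 0, 1, 2, 0, 0, 0, 3), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  d <- as.matrix(jaccard(m, binary = TRUE))
  expect_equal(d["S1", "S2"], 0)          # identical composition
  expect_equal(d["S1", "S3"], 1)          # disjoint
  expect_equal(diag(d), c(S1 = 0, S2 = 0, S3 = 0))
  expect_equal(d, t(d))

  # binary sets {1,2,3} vs {2,3,4} -> 1 - 2/4 = 0.5
  mb <- matrix(c(1, 1, 1, 0, 0, 1, 1, 1), nrow = 4,
               dimnames = list(paste0("sp", 1:4), c("A", "B")))
  expect_equal(as.numeric(jaccard(mb, binary = TRUE)), 0.5)

  # quantitative (Ruzicka): (2,1) vs (1,1): B = 1/5, d = 2B/(1+B) = 1/3
  mq <- matrix(c(2, 1, 1, 1), nrow = 2,
               dimnames = list(c("x", "y"), c("A", "B")))
  expect_equal(as.numeric(jaccard(mq, binary = FALSE)), 1 / 3)

  # the two variants coincide on 0/1 data
  m01 <- (matrix(with_seed(3, runif(40)), nrow = 8,
                 dimnames = list(paste0("s", 1:8), paste0("S", 1:5))) > 0.4) * 1
  expect_equal(as.numeric(jaccard(m01, TRUE)), as.numeric(jaccard(m01, FALSE)))

  mz <- m; mz[, 2] <- 0
  expect_error(jaccard(mz), "S2")
})

test_that("NMDS embeds exactly embeddable dissimilarities at ~zero stress", {
  d3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), nrow = 3,
                       dimnames = list(paste0("S", 1:3), paste0("S", 1:3))))
  fit3 <- nmds(d3, k = 2, seed = 2)
  expect_lt(fit3$stress, 1e-6)

  pts <- with_seed(8, matrix(rnorm(12), ncol = 2))
  rownames(pts) <- paste0("S", 1:6)
  fit6 <- nmds(dist(pts), k = 2, seed = 3)
  expect_lt(fit6$stress, 1e-4)
  expect_equal(colMeans(fit6$configuration), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Procrustes r is exact for rigid rotations and invariant to joint permutation", {
  X <- with_seed(4, matrix(rnorm(20), ncol = 2))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Y <- X %*% R
  res <- procrustes_protest(X, Y, n_permutations = 999, seed = 5)
  expect_equal(res$correlation_r, 1, tolerance = 1e-10)
  expect_equal(res$m_squared, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1 / (res$n_permutations + 1))

  Z <- with_seed(6, matrix(rnorm(20), ncol = 2))
  r1 <- procrustes_protest(X, Z, n_permutations = 99, seed = 7)$correlation_r
  perm <- c(3, 1, 2, 10, 4, 6, 5, 9, 7, 8)
  r2 <- procrustes_protest(X[perm, ], Z[perm, ],
                           n_permutations = 99, seed = 7)$correlation_r
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_true(r1 >= 0 && r1 <= 1)
})

test_that("Chao2 follows the bias-corrected formula and variance", {
  # S_obs = 20, Q1 = 4, Q2 = 2, m = 10 -> 20 + (9/10) * 4*3 / (2*3) = 21.8
  inc <- matrix(0L, nrow = 20, ncol = 10,
                dimnames = list(sprintf("sp%02d", 1:20), sprintf("S%02d", 1:10)))
  for (i in 1:14) inc[i, seq_len(3 + (i %% 3))] <- 1L  # >= 3 samples
  inc[15:18, 1] <- 1L                                  # four uniques
  inc[19, 1:2] <- 1L; inc[20, 1:2] <- 1L               # two duplicates
  est <- chao2(inc)
  expect_equal(est$s_obs, 20L)
  expect_equal(est$q1, 4L)
  expect_equal(est$q2, 2L)
  expect_equal(est$chao2, 21.8)

  # no uniques -> no extrapolation, zero variance
  inc3 <- inc[1:14, ]
  est3 <- chao2(inc3)
  expect_equal(est3$chao2, est3$s_obs)
  expect_equal(est3$se, 0)

  # always >= observed richness
  for (s in 1:10) {
    r <- with_seed(s, matrix(rbinom(60, 1, 0.3), nrow = 12))
    r <- r[, colSums(r) >= 0, drop = FALSE]
    expect_gte(chao2(r)$chao2, sum(rowSums(r) > 0))
  }
})

test_that("Chao2 matches vegan::specpool on random incidence matrices", {
  # vegan uses the classic estimator when Q2 > 0 and the bias-corrected one
  # when Q2 = 0, so each variant is cross-checked in its regime
  for (s in 1:5) {
    inc <- with_seed(40 + s, matrix(rbinom(120, 1, 0.25), nrow = 24))
    inc <- inc[rowSums(inc) > 0, , drop = FALSE]
    dimnames(inc) <- list(paste0("sp", seq_len(nrow(inc))),
                          paste0("S", 1:5))
    mine <- chao2(inc, bias_corrected = FALSE)
    ref <- vegan::specpool(t(inc))
    expect_equal(mine$chao2, ref$chao, tolerance = 1e-10)
    expect_equal(mine$se, ref$chao.se, tolerance = 1e-10)
  }
  inc0 <- matrix(0L, nrow = 8, ncol = 4,
                 dimnames = list(paste0("sp", 1:8), paste0("S", 1:4)))
  inc0[1:5, ] <- 1L
  inc0[6:8, 1] <- 1L  # three uniques, no duplicates
  ref0 <- vegan::specpool(t(inc0))
  mine0 <- chao2(inc0)
  expect_equal(mine0$chao2, ref0$chao, tolerance = 1e-10)
  # variances are not compared at q2 = 0: vegan switches to a special-case
  # formula there, while this implementation keeps the general
  # bias-corrected variance
})

test_that("Welch comparison from estimates matches t.test on raw groups", {
  with_seed(50, {
    x <- rnorm(12, 10, 2); y <- rnorm(9, 8, 3)
  })
  ref <- t.test(x, y)
  mine <- welch_from_estimates(mean(x), sd(x) / sqrt(12), 12,
                               mean(y), sd(y) / sqrt(9), 9)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

  eq <- welch_from_estimates(5, 1, 10, 5, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})
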