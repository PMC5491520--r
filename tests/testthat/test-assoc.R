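# dense matrix square root used only by the brute-force kernel oracle
expm_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
}

test_that("the intercept-only null model reproduces the case fraction", {
  y <- rep(c(1, 0), c(2548, 1117))
  nm <- fit_null_model(y)
  expect_equal(unique(round(nm$mu, 10)), round(2548 / 3665, 10))
  expect_equal(sum(y - nm$mu), 0, tolerance = 1e-8)
  expect_error(fit_null_model(rep(1, 10)), "both")
  expect_error(fit_null_model(c(0, 1, 2)), "binary")
})

test_that("covariate-adjusted null model matches the reference fit", {
  withr::local_seed(60)
  n <- 400
  x <- rep(c(0, 1), n / 2)
  y <- rbinom(n, 1, 0.4)
  nm <- fit_null_model(y, covariates = cbind(x = x))
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(nm$mu), unname(fitted(ref)), tolerance = 1e-8)
})

test_that("Beta weights follow the closed-form density", {
  expect_equal(variant_weights(c(0.1, 0.3, 0.5), c(1, 1)), rep(1, 3))
  w <- variant_weights(c(0.001, 0.01), c(1, 25))
  expect_gt(w[1], w[2])
  expect_equal(variant_weights(0.01, c(1, 25)), 25 * 0.99^24)
  expect_error(variant_weights(0), "MAF")
  expect_error(variant_weights(0.6), "MAF")
})

test_that("score statistic matches a brute-force recomputation", {
  withr::local_seed(61)
  n <- 20; m <- 3
  G <- matrix(rbinom(n * m, 2, 0.3), n)
  y <- rep(c(1, 0), c(12, 8))
  nm <- fit_null_model(y)
  w <- c(1.5, 0.7, 2.1)
  S <- as.numeric(t(G) %*% (y - mean(y))) * w
  for (rho in c(0, 0.3, 1)) {
    st <- score_statistic(G, nm, w, rho)
    expect_equal(st$Q, (1 - rho) * sum(S^2) + rho * sum(S)^2)
    # eigenvalues against the explicit n x n kernel
    mu <- mean(y); v <- mu * (1 - mu)
    P0 <- diag(rep(v, n)) - (v * v / (n * v)) * matrix(1, n, n)
    R <- (1 - rho) * diag(m) + rho * matrix(1, m, m)
    A <- G %*% diag(w)
    big <- t(A) %*% P0 %*% A
    es <- eigen(expm_sqrt(R) %*% big %*% expm_sqrt(R), symmetric = TRUE,
                only.values = TRUE)$values
    es <- es[es > max(es) * 1e-10]
    expect_equal(sort(st$lambda), sort(es), tolerance = 1e-8)
  }
})

test_that("single-variant statistics are rho-invariant and burden collapses", {
  withr::local_seed(62)
  G <- matrix(rbinom(50, 2, 0.2), 50, 1)
  y <- rep(c(1, 0), 25)
  nm <- fit_null_model(y)
  qs <- vapply(c(0, 0.5, 1),
               function(r) score_statistic(G, nm, 2, r)$Q, 1)
  expect_equal(qs[1], qs[2])
  expect_equal(qs[1], qs[3])
  # rho = 1 equals the squared weighted-sum collapsing score
  G3 <- matrix(rbinom(150, 2, 0.2), 50, 3)
  w <- c(1, 2, 3)
  st1 <- score_statistic(G3, nm, w, 1)
  collapsed <- as.numeric(G3 %*% w)
  expect_equal(st1$Q, sum(collapsed * (y - nm$mu))^2)
  bt <- burden_test(G3, nm, w)
  expect_equal(bt$Q, st1$Q)
  expect_equal(bt$lambda, sum(st1$lambda), tolerance = 1e-8)
})

test_that("a monomorphic gene yields a flagged no-test, not an error", {
  y <- rep(c(1, 0), 10)
  nm <- fit_null_model(y)
  G0 <- matrix(0L, 20, 2)
  expect_true(score_statistic(G0, nm, c(1, 1), 0)$no_test)
  expect_true(burden_test(G0, nm, c(1, 1))$no_test)
  expect_true(skato_test(G0, nm, c(1, 1))$no_test)
})

test_that("mixture-of-chi-square tail probabilities are exact where known", {
  expect_equal(mixture_chisq_pvalue(3.841459, 1),
               pchisq(3.841459, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(mixture_chisq_pvalue(5.991465, c(1, 1)), 0.05,
               tolerance = 1e-4)
  expect_equal(mixture_chisq_pvalue(25, c(1, 1, 1)),
               pchisq(25, 3, lower.tail = FALSE), tolerance = 1e-4)
  expect_error(mixture_chisq_pvalue(1, c(0, 0)), "zero")
})

test_that("mixture tail matches a large Monte-Carlo simulation", {
  withr::local_seed(63)
  lam <- c(3.2, 1.1, 0.4, 0.1)
  draws <- colSums(lam * matrix(rchisq(4 * 1e6, 1), 4))
  for (q in c(3, 9, 15)) {
    mc <- mean(draws > q)
    band <- 2.58 * sqrt(mc * (1 - mc) / 1e6)
    expect_lt(abs(mixture_chisq_pvalue(q, lam) - mc), band + 1e-4)
  }
})

test_that("SKAT-O degenerates correctly and dominates its minimum p", {
  withr::local_seed(64)
  y <- rep(c(1, 0), c(60, 40))
  nm <- fit_null_model(y)
  G1 <- matrix(rbinom(100, 2, 0.15), 100, 1)
  so1 <- skato_test(G1, nm, 1.2)
  expect_equal(length(unique(round(so1$p_rho, 12))), 1L)
  expect_equal(so1$p_value, so1$p_rho[1])
  expect_equal(so1$p_value, burden_test(G1, nm, 1.2)$p_value,
               tolerance = 1e-6)

  for (k in 1:5) {
    G <- matrix(rbinom(100 * 4, 2, runif(4, 0.05, 0.3)), 100, 4,
                byrow = TRUE)
    if (all(G == 0)) next
    w <- variant_weights(pmin(colMeans(G) / 2 + 1e-9, 0.5))
    so <- skato_test(G, nm, w)
    expect_gte(so$p_value, so$min_p)
    expect_lte(so$p_value, 1)
    # skat_test agrees with the rho = 0 grid point
    expect_equal(skat_test(G, nm, w)$p_value, so$p_rho[1],
                 tolerance = 1e-6)
  }
  expect_error(skato_test(G1, nm, 1, rho_grid = c(0, 0.5)), "0 and 1")
})

test_that("p_rho varies continuously in rho on fixed data", {
  withr::local_seed(65)
  G <- matrix(rbinom(200 * 5, 2, 0.1), 200, 5)
  nm <- fit_null_model(rep(c(1, 0), 100))
  w <- variant_weights(pmin(colMeans(G) / 2 + 1e-9, 0.5))
  grid <- seq(0, 1, by = 0.05)
  ps <- vapply(grid, function(r) {
    st <- score_statistic(G, nm, w, r)
    mixture_chisq_pvalue(st$Q, st$lambda)
  }, 1)
  expect_true(all(abs(diff(ps)) < 0.08))
})

test_that("asymptotic SKAT-O agrees with a permutation oracle", {
  # moderately sized fixture so the asymptotics have kicked in
  withr::local_seed(66)
  n <- 500
  y <- rep(c(1, 0), c(300, 200))
  nm <- fit_null_model(y)
  rho_grid <- c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)
  for (k in 1:2) {
    G <- vapply(runif(5, 0.05, 0.25), function(p) rbinom(n, 2, p),
                integer(n))
    if (k == 2) {  # plant a mild signal
      i <- which(y == 1)[1:50]
      G[i, 1] <- pmin(G[i, 1] + 1L, 2L)
    }
    w <- variant_weights(pmin(colMeans(G) / 2 + 1e-9, 0.5))
    so <- skato_test(G, nm, w, rho_grid)

    A <- sweep(G, 2, w, `*`)
    lam_rho <- lapply(rho_grid, function(r) {
      K <- crossprod(A, rvtiers:::null_project(nm, A))
      rvtiers:::kernel_eigenvalues(K, r)
    })
    minp_of <- function(yv) {
      S <- as.numeric(crossprod(A, yv - mean(yv)))
      Q <- (1 - rho_grid) * sum(S^2) + rho_grid * sum(S)^2
      min(vapply(seq_along(rho_grid),
                 function(i) rvtiers:::liu_pvalue(Q[i], lam_rho[[i]]), 1))
    }
    B <- 20000
    perm <- vapply(seq_len(B), function(b) minp_of(sample(y)), 1)
    p_perm <- mean(perm <= minp_of(y))
    mc_err <- 2.58 * sqrt(max(p_perm * (1 - p_perm), 1e-4) / B)
    # Monte-Carlo error plus a finite-sample asymptotics allowance
    expect_lt(abs(so$p_value - p_perm), mc_err + 0.025)
  }
})

test_that("mean imputation preserves the expected score under MCAR", {
  withr::local_seed(67)
  n <- 2000
  y <- rep(c(1, 0), n / 2)
  nm <- fit_null_model(y)
  diffs <- replicate(200, {
    g <- rbinom(n, 2, 0.2)
    s_full <- sum(g * (y - nm$mu))
    gm <- g
    gm[sample(n, n * 0.2)] <- NA  # MCAR holes
    gi <- impute_dosage(matrix(gm, ncol = 1))
    sum(gi * (y - nm$mu)) - s_full
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.5)
})
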