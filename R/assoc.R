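#' Fit the logistic null model for score-based association tests
#'
#' Fits `logit P(y = 1) = X gamma` by maximum likelihood (intercept-only
#' by default) and precomputes the fitted means and variance terms the
#' score tests need. With no covariates the fitted mean is the sample
#' case fraction for every individual.
#'
#' @param phenotypes binary 0/1 vector; both classes must be present.
#' @param covariates optional numeric matrix (without intercept column).
#' @return An object of class `null_model`: list with `y`, `X`, `mu`
#'   (fitted probabilities), `v` (`mu * (1 - mu)`).
#' @examples
#' nm <- fit_null_model(rep(c(1, 0), c(25, 11)))
#' unique(round(nm$mu, 4))
#' @export
fit_null_model <- function(phenotypes, covariates = NULL) {
  y <- as.numeric(phenotypes)
  if (any(is.na(y)) || !all(y %in% c(0, 1))) {
    stop_invalid("phenotypes must be binary 0/1 without missing values")
  }
  if (length(unique(y)) < 2L) {
    stop_invalid("both phenotype classes must be present")
  }
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10)) {
    stop_invalid("null model fit is degenerate (separation?)")
  }
  structure(list(y = y, X = X, mu = mu, v = mu * (1 - mu)),
            class = "null_model")
}

#' Beta-density variant weights
#'
#' The rare-variant up-weighting convention: weight each variant by the
#' Beta(a1, a2) density evaluated at its minor-allele frequency. The
#' default Beta(1, 25) strongly up-weights rarer variants; Beta(1, 1)
#' gives flat weights.
#'
#' @param mafs minor-allele frequencies, all in (0, 0.5].
#' @param beta_params shape parameters `c(a1, a2)`.
#' @return numeric weight vector.
#' @examples
#' variant_weights(c(0.001, 0.01), c(1, 25))
#' @export
variant_weights <- function(mafs, beta_params = c(1, 25)) {
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop_invalid("MAFs must lie in (0, 0.5]; unobserved variants cannot be weighted")
  }
  dbeta(mafs, beta_params[1], beta_params[2])
}

#' Mean-impute missing dosages
#'
#' Replaces missing genotype dosages by the per-variant mean of the
#' observed dosages, which leaves the expected score contribution
#' unchanged under data missing completely at random.
#'
#' @param G samples x variants dosage matrix with `NA` for missing.
#' @return numeric matrix without missing values.
#' @export
impute_dosage <- function(G) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    cm <- colMeans(G, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- cm[na_idx[, 2]]
  }
  G
}

# projection of columns of A through the null-model variance structure:
# returns P0 %*% A with P0 = V - V X (X'VX)^-1 X'V
null_project <- function(null, A) {
  VA <- null$v * A
  VX <- null$v * null$X
  XtVX <- crossprod(null$X, VX)
  VA - VX %*% solve(XtVX, crossprod(VX, A))
}

#' Score statistic and kernel eigenvalues for a rho-indexed test
#'
#' Computes the SKAT-family statistic
#' `Q_rho = (1 - rho) * sum(w_j^2 S_j^2) + rho * (sum(w_j S_j))^2` with
#' `S_j = sum_i G_ij (y_i - mu_i)`, together with the eigenvalues of the
#' projected weighted kernel that give its null distribution as a
#' mixture of 1-df chi-squares. `rho = 1` is the weighted burden
#' (collapsing) test; `rho = 0` is SKAT.
#'
#' @param G samples x variants dosage matrix (missing dosages are
#'   mean-imputed).
#' @param null a [fit_null_model()] object.
#' @param weights per-variant weights (see [variant_weights()]).
#' @param rho effect-correlation parameter in `[0, 1]`.
#' @return list with `Q`, `lambda` (kernel eigenvalues), `rho`,
#'   `n_variants`, and `no_test` (TRUE when the gene carries no
#'   alternate alleles, in which case no statistic is defined).
#' @export
score_statistic <- function(G, null, weights, rho) {
  stopifnot(inherits(null, "null_model"))
  G <- impute_dosage(G)
  m <- ncol(G)
  if (length(weights) != m) {
    stop_invalid("need one weight per variant (%d != %d)",
                 length(weights), m)
  }
  if (rho < 0 || rho > 1) stop_invalid("`rho` must lie in [0, 1]")
  if (m == 0 || all(G == 0)) {
    return(list(Q = NA_real_, lambda = numeric(), rho = rho,
                n_variants = m, no_test = TRUE))
  }
  A <- sweep(G, 2, weights, `*`)
  S <- as.numeric(crossprod(A, null$y - null$mu))
  Q <- (1 - rho) * sum(S^2) + rho * sum(S)^2
  K <- crossprod(A, null_project(null, A))
  lambda <- kernel_eigenvalues(K, rho)
  list(Q = Q, lambda = lambda, rho = rho, n_variants = m, no_test = FALSE)
}

# eigenvalues of R_rho^{1/2} K R_rho^{1/2}, R_rho the compound-symmetry
# correlation matrix; closed-form matrix square root of R_rho
kernel_eigenvalues <- function(K, rho) {
  m <- ncol(K)
  if (m == 1L) return(max(as.numeric(K), 0))
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  # R^{1/2} = a I + b 11'
  Kr <- a^2 * K
  k1 <- rowSums(K)
  Kr <- Kr + a * b * (outer(k1, rep(1, m)) + outer(rep(1, m), k1)) +
    b^2 * sum(K)
  ev <- eigen(Kr, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev) * 1e-10]
}

#' Tail probability of a mixture of one-degree chi-squares
#'
#' Computes `P(sum_k lambda_k chi^2_1 > q)` by numerical inversion of
#' the characteristic function (Imhof's integral), falling back to
#' moment matching (mean, variance, kurtosis matched to a non-central
#' chi-square, the modified Liu approximation) when the inversion fails
#' or returns an unusable value. The returned p is clamped to (0, 1].
#'
#' @param q observed statistic.
#' @param lambdas non-negative mixture weights, not all zero.
#' @return p-value in (0, 1].
#' @examples
#' mixture_chisq_pvalue(5.991, c(1, 1))  # ~0.05 (chi-square, 2 df)
#' @export
mixture_chisq_pvalue <- function(q, lambdas) {
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0) {
    stop_invalid("all mixture weights are zero; no distribution to invert")
  }
  slam <- sum(lambdas)
  p <- vapply(q, function(qi) {
    if (length(lambdas) == 1L) {
      return(pchisq(qi / lambdas, df = 1, lower.tail = FALSE))
    }
    if (qi <= 0.05 * slam) {
      # extreme left edge: p ~ 1, the oscillatory integral converges
      # slowly, and moment matching is ample
      return(liu_pvalue(qi, lambdas))
    }
    pi_ <- tryCatch(imhof_pvalue(qi, lambdas), error = function(e) NA_real_)
    if (is.na(pi_) || pi_ <= 0 || pi_ > 1) pi_ <- liu_pvalue(qi, lambdas)
    pi_
  }, numeric(1))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# Imhof's characteristic-function inversion on a fixed oscillation-aware
# grid: P(sum lambda_k chi2_1 > q) = 1/2 + (1/pi) Int_0^Inf
# sin(theta(u)) / (u rho(u)) du. The truncation point U is chosen from
# the integrand envelope (with an integration-by-parts refinement for
# the oscillatory tail) and the step from the oscillation frequency
# (q + sum lambda)/2. Returns NA when the required grid would be
# excessive (very small q), signalling the moment-matching fallback.
imhof_pvalue <- function(q, lambdas, eps = 1e-8) {
  m <- length(lambdas)
  slam <- sum(lambdas)
  if (q <= 0) return(1)
  envelope <- function(U) {
    exp(-(log(U) + 0.25 * sum(log1p(lambdas^2 * U^2))))
  }
  U <- 8 / min(lambdas)
  while (min(2 / m * U, 4 / q) * envelope(U) / pi > eps && U < 1e8) {
    U <- U * 1.4
  }
  h <- pi / (2 * (q + slam))
  n <- ceiling(U / h)
  if (n < 2048) {
    n <- 2048L
  } else if (n > 2e5) {
    return(NA_real_)
  }
  h <- U / n
  acc <- 0
  block_size <- 2e5
  for (b in seq_len(ceiling(n / block_size))) {
    lo <- (b - 1) * block_size + 1
    u <- (lo:min(n, b * block_size)) * h
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(outer(lambdas^2, u^2)))
    acc <- acc + sum(sin(theta) / (u * exp(lrho)))
  }
  f0 <- 0.5 * (slam - q)
  fU_half <- {  # subtract half the last point for the trapezoid rule
    theta <- 0.5 * sum(atan(lambdas * U)) - 0.5 * q * U
    0.5 * sin(theta) * envelope(U)
  }
  integral <- h * (0.5 * f0 + acc - fU_half)
  0.5 + integral / pi
}

liu_params <- function(lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  list(mu_q = c1, sigma_q = sqrt(2 * c2), l = l, d = d,
       mu_x = l + d, sigma_x = sqrt(2 * (l + 2 * d)))
}

liu_pvalue <- function(q, lambdas) {
  p <- liu_params(lambdas)
  tstar <- (q - p$mu_q) / p$sigma_q
  pchisq(tstar * p$sigma_x + p$mu_x, df = p$l, ncp = p$d,
         lower.tail = FALSE)
}

# statistic value whose moment-matched tail probability equals `prob`
liu_quantile <- function(prob, lambdas) {
  p <- liu_params(lambdas)
  qx <- qchisq(prob, df = p$l, ncp = p$d, lower.tail = FALSE)
  (qx - p$mu_x) / p$sigma_x * p$sigma_q + p$mu_q
}

#' Weighted burden and SKAT single-rho tests
#'
#' Convenience wrappers around [score_statistic()] and
#' [mixture_chisq_pvalue()] for the two ends of the rho family:
#' `burden_test()` is the weighted collapsing score test (`rho = 1`),
#' `skat_test()` the variance-component kernel test (`rho = 0`).
#'
#' @inheritParams score_statistic
#' @return list with `Q`, `p_value`, `lambda`, `rho`, `n_variants`,
#'   `no_test`.
#' @export
burden_test <- function(G, null, weights) {
  G <- impute_dosage(G)
  m <- ncol(G)
  if (m == 0 || all(G == 0)) {
    return(list(Q = NA_real_, p_value = NA_real_, lambda = numeric(),
                rho = 1, n_variants = m, no_test = TRUE))
  }
  # burden collapses to a single weighted-sum score: only the collapsed
  # dosage vector is needed, which keeps the power simulation cheap
  a <- as.numeric(G %*% weights)
  Q <- sum(a * (null$y - null$mu))^2
  lam <- sum(a * null_project(null, matrix(a, ncol = 1)))
  p <- if (lam <= 0) NA_real_ else
    pchisq(Q / lam, df = 1, lower.tail = FALSE)
  list(Q = Q, p_value = min(max(p, .Machine$double.xmin), 1),
       lambda = lam, rho = 1, n_variants = m, no_test = FALSE)
}

#' @rdname burden_test
#' @export
skat_test <- function(G, null, weights) {
  st <- score_statistic(G, null, weights, rho = 0)
  st$p_value <- if (st$no_test) NA_real_ else
    mixture_chisq_pvalue(st$Q, st$lambda)
  st
}

#' SKAT-O: the optimal rho-combined association test
#'
#' Computes the rho-indexed statistic over a grid, takes the minimum of
#' the per-rho p-values, and converts it into a single p-value by
#' one-dimensional integration of the null distribution of the minimum
#' (the optimal-test construction). For a single-variant unit all rho
#' values coincide and the single-rho p is returned.
#'
#' @inheritParams score_statistic
#' @param rho_grid grid of rho values; must contain 0 and 1.
#' @return An object of class `skato_result`: list with `p_value`,
#'   `min_p` (smallest per-rho p), `rho_min` (grid point attaining it),
#'   `p_rho`, `Q_rho`, `rho_grid`, `lambda` (eigenvalues of the SKAT
#'   component), `n_variants`, `no_test`.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(300, 2, 0.1), nrow = 100)
#' nm <- fit_null_model(rep(c(1, 0), 50))
#' skato_test(G, nm, variant_weights(colMeans(G) / 2))$p_value
#' @export
skato_test <- function(G, null, weights,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                    0.5, 1)) {
  if (!all(c(0, 1) %in% rho_grid)) {
    stop_invalid("`rho_grid` must contain both 0 and 1")
  }
  rho_grid <- sort(unique(rho_grid))
  G <- impute_dosage(G)
  m <- ncol(G)
  if (m == 0 || all(G == 0)) {
    return(structure(list(p_value = NA_real_, min_p = NA_real_,
                          rho_min = NA_real_, p_rho = NULL, Q_rho = NULL,
                          rho_grid = rho_grid, lambda = numeric(),
                          n_variants = m, no_test = TRUE),
                     class = "skato_result"))
  }

  A <- sweep(G, 2, weights, `*`)
  S <- as.numeric(crossprod(A, null$y - null$mu))
  K <- crossprod(A, null_project(null, A))

  Q_rho <- (1 - rho_grid) * sum(S^2) + rho_grid * sum(S)^2
  lam_rho <- lapply(rho_grid, function(r) kernel_eigenvalues(K, r))
  p_rho <- vapply(seq_along(rho_grid), function(i) {
    mixture_chisq_pvalue(Q_rho[i], lam_rho[[i]])
  }, numeric(1))

  min_p <- min(p_rho)
  rho_min <- rho_grid[which.min(p_rho)]

  if (m == 1L) {
    # all rho coincide for one variant
    return(structure(list(p_value = p_rho[1], min_p = p_rho[1],
                          rho_min = rho_min, p_rho = p_rho, Q_rho = Q_rho,
                          rho_grid = rho_grid, lambda = lam_rho[[1]],
                          n_variants = 1L, no_test = FALSE),
                     class = "skato_result"))
  }

  # Lee-style optimal-test null parameters, all derived from K
  k1 <- rowSums(K)                # K %*% 1
  zz <- sum(K) / m^2              # |zbar|^2 under the projected kernel
  v <- k1 / m                     # Z1' zbar
  Ktilde <- K - outer(v, v) / zz  # SKAT component after removing burden dir
  lambda <- eigen(Ktilde, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (length(lambda) == 0) lambda <- 1e-12
  var_remain <- 4 * sum((outer(v, v) / zz) * Ktilde)
  mu_q <- sum(lambda)
  var_q <- 2 * sum(lambda^2) + var_remain
  tau <- m^2 * rho_grid * zz + (1 - rho_grid) * sum(v^2) / zz

  # per-rho quantiles of Q_rho at level min_p (moment-matched scale)
  q_min <- vapply(seq_along(rho_grid), function(i) {
    liu_quantile(min_p, lam_rho[[i]])
  }, numeric(1))

  rho_capped <- pmin(rho_grid, 0.999)
  sd_adj <- if (var_q > 0) sqrt(max(var_q - var_remain, 0) / var_q) else 1
  mm <- liu_params(lambda)  # moment-matched SKAT-component tail, closed form
  integrand <- function(x) {
    dmin <- vapply(x, function(xi) {
      min((q_min - tau * xi) / (1 - rho_capped))
    }, numeric(1))
    q_std <- (dmin - mu_q) * sd_adj + mu_q
    tailp <- pchisq((q_std - mm$mu_q) / mm$sigma_q * mm$sigma_x + mm$mu_x,
                    df = mm$l, ncp = mm$d, lower.tail = FALSE)
    (1 - tailp) * dchisq(x, df = 1)
  }
  it <- integrate(integrand, 0, 40, subdivisions = 1000L,
                  abs.tol = 1e-10, stop.on.error = FALSE)
  p <- 1 - it$value
  # the combined p pays for the selection over the grid but can never
  # exceed the Bonferroni bound over it
  p <- min(p, min_p * length(rho_grid))
  p <- max(p, min_p, .Machine$double.xmin)
  structure(list(p_value = min(p, 1), min_p = min_p, rho_min = rho_min,
                 p_rho = p_rho, Q_rho = Q_rho, rho_grid = rho_grid,
                 lambda = lambda, n_variants = m, no_test = FALSE),
            class = "skato_result")
}

#' @export
print.skato_result <- function(x, ...) {
  if (x$no_test) {
    cat("SKAT-O: no test (no alternate alleles)\n")
  } else {
    cat(sprintf("SKAT-O over %d variants: p = %.3g (min per-rho p %.3g at rho = %g)\n",
                x$n_variants, x$p_value, x$min_p, x$rho_min))
  }
  invisible(x)
}
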