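#' MAF-dependent log-odds effect size
#'
#' The effect model of the power analysis: a causal variant with minor-
#' allele frequency `maf` receives the log-odds effect
#' `min(c * |log10(maf)|, beta_max)`. With the default scale `c = 0.4`
#' the cap of 1.6 is attained exactly at MAF 1e-4, and rarer variants
#' stay at the cap.
#'
#' @param maf minor-allele frequency in (0, 0.5].
#' @param c log-odds per unit of `|log10(maf)|`.
#' @param beta_max effect cap.
#' @return log-odds effect (vectorized over `maf`).
#' @examples
#' effect_size(1e-4)      # 1.6, the cap
#' effect_size(0.01)      # 0.8
#' @export
effect_size <- function(maf, c = 0.4, beta_max = 1.6) {
  if (any(maf <= 0 | maf > 0.5)) {
    stop_invalid("`maf` must lie in (0, 0.5]")
  }
  pmin(c * abs(log10(maf)), beta_max)
}

#' Power-simulation configuration
#'
#' Design of the burden-test power analysis: per replicate a random
#' subregion of the haplotype pool is chosen, a fraction of its
#' sufficiently rare sites is designated causal with
#' [effect_size()] effects of a common sign, an ascertained case-control
#' cohort is drawn, and the weighted burden test is run; power is the
#' fraction of replicates rejecting at `alpha`.
#'
#' @param n_cases,n_controls cohort sizes (defaults 2548 / 1117).
#' @param region_length subregion length in bp (default 2000).
#' @param causal_maf_threshold only sites at or below this MAF may be
#'   causal (0.01, 0.001 or 0.0005 in the standard sweep).
#' @param causal_fraction fraction of eligible sites made causal
#'   (swept over 0.1-0.9).
#' @param effect_scale,effect_cap see [effect_size()].
#' @param alpha rejection level (default 2e-4, the experiment-wide
#'   threshold).
#' @param n_replicates simulation replicates (default 500).
#' @param baseline_prevalence population prevalence for ascertainment.
#' @param seed integer RNG seed.
#' @return An object of class `power_config`.
#' @export
power_config <- function(n_cases = 2548, n_controls = 1117,
                         region_length = 2000,
                         causal_maf_threshold = 0.01,
                         causal_fraction = 0.3, effect_scale = 0.4,
                         effect_cap = 1.6, alpha = 2e-4,
                         n_replicates = 500,
                         baseline_prevalence = 0.01, seed = 1) {
  cfg <- list(
    n_cases = check_count(n_cases, "n_cases"),
    n_controls = check_count(n_controls, "n_controls"),
    region_length = check_count(region_length, "region_length", min = 100L),
    causal_maf_threshold = check_prob(causal_maf_threshold,
                                      "causal_maf_threshold", open = TRUE),
    causal_fraction = check_prob(causal_fraction, "causal_fraction"),
    effect_scale = effect_scale,
    effect_cap = effect_cap,
    alpha = check_prob(alpha, "alpha", open = TRUE),
    n_replicates = check_count(n_replicates, "n_replicates"),
    baseline_prevalence = check_prob(baseline_prevalence,
                                     "baseline_prevalence", open = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "power_config")
}

#' Estimate burden-test power by simulation
#'
#' Runs the design of a [power_config()] against a haplotype pool and
#' returns the empirical rejection rate of the weighted burden test.
#' Subregions with no causal-eligible site are redrawn (and counted).
#'
#' @param config a [power_config()].
#' @param pool a [simulate_haplotype_pool()] object; its region must be
#'   at least as long as `config$region_length`.
#' @param beta_params Beta weight parameters for the burden test.
#' @return An object of class `power_result`: list with `power`
#'   (rejection fraction), `se` (binomial Monte-Carlo standard error),
#'   `p_values` (per replicate), `n_replicates`, `n_redraws` and
#'   `config`.
#' @examples
#' pool <- simulate_haplotype_pool(500, 6000, seed = 1)
#' cfg <- power_config(n_cases = 60, n_controls = 40, n_replicates = 5,
#'                     alpha = 0.05, seed = 2)
#' simulate_power(cfg, pool)$power
#' @export
simulate_power <- function(config, pool, beta_params = c(1, 25)) {
  stopifnot(inherits(config, "power_config"),
            inherits(pool, "haplotype_pool"))
  if (pool$region_length < config$region_length) {
    stop_invalid("pool region (%d bp) shorter than subregion (%d bp)",
                 pool$region_length, config$region_length)
  }
  design <- cohort_design(n_cases_ts = config$n_cases, n_cases_wes = 1,
                          n_controls = config$n_controls)
  # the WES stratum is a label; keep the case total exact
  design$n_cases_ts <- config$n_cases - 1L

  model <- phenotype_model(
    baseline_prevalence = config$baseline_prevalence,
    causal_fraction = config$causal_fraction,
    causal_maf_threshold = config$causal_maf_threshold,
    effect_scale = config$effect_scale,
    effect_cap = config$effect_cap)

  p_values <- numeric(config$n_replicates)
  n_redraws <- 0L
  null <- NULL
  withr::with_seed(config$seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L,
                            config$n_replicates)
  })
  for (r in seq_len(config$n_replicates)) {
    repeat {
      sub <- withr::with_seed(rep_seeds[r] %% (2^31 - 2L) + n_redraws, {
        draw_subregion(pool, config$region_length)
      })
      eligible <- sum(sub$maf <= config$causal_maf_threshold)
      if (eligible > 0) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100L * config$n_replicates) {
        stop_invalid("no causal-eligible sites found after many redraws")
      }
    }
    cc <- simulate_case_control(sub, model, design, seed = rep_seeds[r])
    if (is.null(null)) null <- fit_null_model(cc$samples$status)
    w <- gene_weights(cc$G, beta_params)
    poly <- w > 0
    p_values[r] <- if (!any(poly)) 1 else
      burden_test(cc$G[, poly, drop = FALSE], null, w[poly])$p_value
  }
  power <- mean(p_values < config$alpha)
  structure(list(
    power = power,
    se = sqrt(power * (1 - power) / config$n_replicates),
    p_values = p_values,
    n_replicates = config$n_replicates,
    n_redraws = n_redraws,
    config = config
  ), class = "power_result")
}

# restrict a pool to a random window of the given length
draw_subregion <- function(pool, window) {
  start <- sample.int(pool$region_length - window + 1L, 1L)
  keep <- which(pool$positions >= start & pool$positions < start + window)
  sub <- pool
  sub$positions <- pool$positions[keep] - start + 1L
  sub$region_length <- as.integer(window)
  sub$ref <- pool$ref[keep]
  sub$alt <- pool$alt[keep]
  sub$H <- pool$H[, keep, drop = FALSE]
  sub$maf <- pool$maf[keep]
  sub
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "burden-test power: %.1f%% (MC SE %.1f%%) over %d replicates at alpha = %g\n",
    100 * x$power, 100 * x$se, x$n_replicates, x$config$alpha))
  invisible(x)
}
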