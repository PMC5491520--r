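#' Phenotype model for case-control simulation
#'
#' Defines the logistic disease model used by [simulate_case_control()] and
#' [simulate_power()]. A configured fraction of sufficiently rare sites is
#' designated causal; each causal site j receives the log-odds effect
#' `min(effect_scale * |log10(maf_j)|, effect_cap)`, all with the same
#' sign. The default scale 0.4 makes the cap of 1.6 bind exactly at
#' MAF 1e-4.
#'
#' @param baseline_prevalence population disease prevalence in (0, 1).
#' @param causal_fraction fraction of eligible (rare) sites made causal.
#' @param causal_maf_threshold only sites with MAF at or below this can be
#'   causal.
#' @param effect_scale log-odds per unit of `|log10(MAF)|`.
#' @param effect_cap maximum log-odds effect.
#' @param direction sign of the effects (+1 or -1); all effects share it.
#' @return An object of class `phenotype_model`.
#' @examples
#' phenotype_model(causal_fraction = 0.3)
#' @export
phenotype_model <- function(baseline_prevalence = 0.01,
                            causal_fraction = 0,
                            causal_maf_threshold = 0.01,
                            effect_scale = 0.4,
                            effect_cap = 1.6,
                            direction = 1) {
  baseline_prevalence <- check_prob(baseline_prevalence,
                                    "baseline_prevalence", open = TRUE)
  causal_fraction <- check_prob(causal_fraction, "causal_fraction")
  causal_maf_threshold <- check_prob(causal_maf_threshold,
                                     "causal_maf_threshold")
  if (!direction %in% c(-1, 1)) {
    stop_invalid("`direction` must be +1 or -1")
  }
  if (effect_scale < 0 || effect_cap < 0) {
    stop_invalid("effect scale and cap must be non-negative")
  }
  structure(list(
    baseline_prevalence = baseline_prevalence,
    causal_fraction = causal_fraction,
    causal_maf_threshold = causal_maf_threshold,
    effect_scale = effect_scale,
    effect_cap = effect_cap,
    direction = direction
  ), class = "phenotype_model")
}

#' Case-control cohort design
#'
#' Sample-size layout of the study: cases split between a targeted-
#' sequencing (TS) and a whole-exome (WES) stratum, plus WES controls.
#' The strata are labels only; no platform effect is simulated. Defaults
#' are the sizes of the severe childhood obesity cohort this pipeline was
#' built around (1,811 TS cases, 737 WES cases, 1,117 WES controls).
#'
#' @param n_cases_ts,n_cases_wes,n_controls stratum sizes (all > 0).
#' @param genes optional data.frame (gene, tier, start, end) assigning
#'   gene regions; each gene belongs to exactly one tier.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_cases_ts = 1811, n_cases_wes = 737,
                          n_controls = 1117, genes = NULL) {
  n_cases_ts <- check_count(n_cases_ts, "n_cases_ts")
  n_cases_wes <- check_count(n_cases_wes, "n_cases_wes")
  n_controls <- check_count(n_controls, "n_controls")
  if (!is.null(genes)) {
    stopifnot(is.data.frame(genes),
              all(c("gene", "tier") %in% names(genes)))
    if (anyDuplicated(genes$gene)) {
      stop_invalid("each gene must be assigned exactly one tier")
    }
  }
  structure(list(n_cases_ts = n_cases_ts, n_cases_wes = n_cases_wes,
                 n_controls = n_controls, genes = genes),
            class = "cohort_design")
}

#' Simulate an ascertained case-control cohort from a haplotype pool
#'
#' Individuals are formed by pairing haplotypes drawn at random (with
#' replacement) from the pool. Disease status follows the logistic model
#' `logit P(case) = alpha + sum_j beta_j g_ij` over the causal sites of
#' `model`; the intercept `alpha` is solved by bisection so the population
#' prevalence matches `model$baseline_prevalence` under the realized
#' genotype distribution. Cases and controls are then rejection-sampled
#' until the exact stratum counts of `design` are met.
#'
#' @param pool a [simulate_haplotype_pool()] object.
#' @param model a [phenotype_model()].
#' @param design a [cohort_design()].
#' @param seed integer RNG seed.
#' @param max_draws safety cap on the number of candidate individuals
#'   drawn before the sampler gives up with a simulation-failure error.
#' @return A list with `G` (samples x sites dosage matrix, 0/1/2),
#'   `samples` (data.frame: id, cohort, group, status), `causal_sites`
#'   (column indices), `beta` (their log-odds effects) and `alpha`.
#' @examples
#' pool <- simulate_haplotype_pool(400, 2000, seed = 1)
#' cc <- simulate_case_control(pool, phenotype_model(),
#'                             cohort_design(30, 10, 20), seed = 2)
#' table(cc$samples$status)
#' @export
simulate_case_control <- function(pool, model, design, seed,
                                  max_draws = 5e7) {
  stopifnot(inherits(pool, "haplotype_pool"),
            inherits(model, "phenotype_model"),
            inherits(design, "cohort_design"))
  seed <- check_count(seed, "seed", min = 0L)

  withr::with_seed(seed, {
    m <- ncol(pool$H)
    eligible <- which(pool$maf <= model$causal_maf_threshold)
    n_causal <- round(model$causal_fraction * length(eligible))
    causal <- if (n_causal > 0) sort(sample(eligible, n_causal)) else integer()
    beta <- model$direction *
      effect_size(pool$maf[causal], model$effect_scale, model$effect_cap)
    alpha <- solve_intercept(pool, causal, beta, model$baseline_prevalence)

    n_cases <- design$n_cases_ts + design$n_cases_wes
    n_controls <- design$n_controls
    Hc <- pool$H[, causal, drop = FALSE]

    case_idx <- matrix(integer(), nrow = 0, ncol = 2)
    ctrl_idx <- matrix(integer(), nrow = 0, ncol = 2)
    drawn <- 0L
    chunk <- max(2000L, min(50000L, as.integer(4 * n_cases)))
    while (nrow(case_idx) < n_cases || nrow(ctrl_idx) < n_controls) {
      if (drawn >= max_draws) {
        stop_invalid(paste(
          "simulation failure: case/control quotas not met after",
          "%d candidate draws (prevalence too extreme?)"), drawn)
      }
      i1 <- sample.int(pool$n_haplotypes, chunk, replace = TRUE)
      i2 <- sample.int(pool$n_haplotypes, chunk, replace = TRUE)
      eta <- if (length(causal)) {
        (Hc[i1, , drop = FALSE] + Hc[i2, , drop = FALSE]) %*% beta
      } else {
        numeric(chunk)
      }
      is_case <- runif(chunk) < plogis(alpha + as.numeric(eta))
      drawn <- drawn + chunk
      need_cases <- n_cases - nrow(case_idx)
      need_ctrls <- n_controls - nrow(ctrl_idx)
      new_cases <- which(is_case)[seq_len(min(need_cases, sum(is_case)))]
      new_ctrls <- which(!is_case)[seq_len(min(need_ctrls, sum(!is_case)))]
      case_idx <- rbind(case_idx, cbind(i1[new_cases], i2[new_cases]))
      ctrl_idx <- rbind(ctrl_idx, cbind(i1[new_ctrls], i2[new_ctrls]))
    }

    idx <- rbind(case_idx, ctrl_idx)
    G <- pool$H[idx[, 1], , drop = FALSE] + pool$H[idx[, 2], , drop = FALSE]
    storage.mode(G) <- "integer"
    n <- nrow(G)
    cohort <- c(rep("CASE_TS", design$n_cases_ts),
                rep("CASE_WES", design$n_cases_wes),
                rep("CONTROL_WES", n_controls))
    samples <- data.frame(
      id = sprintf("S%05d", seq_len(n)),
      cohort = cohort,
      group = ifelse(cohort == "CONTROL_WES", "diseased_control", "case"),
      status = rep(c(1L, 0L), c(n_cases, n_controls)),
      stringsAsFactors = FALSE
    )
    rownames(G) <- samples$id
    colnames(G) <- variant_ids(pool)

    list(G = G, samples = samples, causal_sites = causal, beta = beta,
         alpha = alpha)
  })
}

variant_ids <- function(pool, chrom = "1") {
  sprintf("%s:%d:%s:%s", chrom, pool$positions, pool$ref, pool$alt)
}

# Solve the logistic intercept so the population prevalence matches the
# target, using a fixed Monte-Carlo batch of genotype draws (common random
# numbers make the bisection smooth and deterministic).
solve_intercept <- function(pool, causal, beta, prevalence,
                            n_calib = 20000L) {
  if (length(causal) == 0) return(qlogis(prevalence))
  i1 <- sample.int(pool$n_haplotypes, n_calib, replace = TRUE)
  i2 <- sample.int(pool$n_haplotypes, n_calib, replace = TRUE)
  Hc <- pool$H[, causal, drop = FALSE]
  eta <- as.numeric((Hc[i1, , drop = FALSE] + Hc[i2, , drop = FALSE]) %*% beta)
  f <- function(a) mean(plogis(a + eta)) - prevalence
  lo <- qlogis(prevalence) - sum(abs(beta)) - 1
  hi <- qlogis(prevalence) + sum(abs(beta)) + 1
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}
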