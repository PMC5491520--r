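#' Default candidate-gene tier skeleton
#'
#' The six candidate-gene tiers with their canonical sizes (6, 26, 51,
#' 5, 7 and 24 genes; 119 in total): genes causing human obesity alone,
#' obesity with developmental delay and/or dysmorphology, mouse
#' loss-of-function obesity genes, mouse gain-of-function obesity genes,
#' anorectic molecules, and genes with complex metabolic effects.
#' Placeholder gene symbols are used (the tier structure, not the gene
#' identities, is what the pipeline needs); supply your own data.frame
#' to analyse real gene lists.
#'
#' @return data.frame with columns `gene` and `tier`.
#' @export
default_gene_tiers <- function() {
  sizes <- c(ObesityAlone = 6L, ObesityAndDelay = 26L, LoFMice = 51L,
             GoFMice = 5L, AnorecticMolecules = 7L,
             ComplexMetabolicEffects = 24L)
  prefix <- c(ObesityAlone = "OA", ObesityAndDelay = "OD", LoFMice = "LM",
              GoFMice = "GM", AnorecticMolecules = "AM",
              ComplexMetabolicEffects = "CM")
  do.call(rbind, lapply(names(sizes), function(t) {
    data.frame(gene = sprintf("%s%02d", prefix[[t]], seq_len(sizes[[t]])),
               tier = t, stringsAsFactors = FALSE)
  }))
}

#' Bonferroni-adjusted significance threshold
#'
#' `0.05 / (n_tests_per_unit * n_units)`. With 125 units (119 genes +
#' 6 tiers) and the 2 primary tests this gives 2.0e-4; adding the ten
#' secondary tests (12 per unit) gives 3.3e-5.
#'
#' @param n_units number of tested units (genes + gene sets).
#' @param n_tests_per_unit tests per unit.
#' @param alpha family-wise error rate (default 0.05).
#' @return significance level.
#' @examples
#' bonferroni_threshold(125, 2)
#' @export
bonferroni_threshold <- function(n_units, n_tests_per_unit, alpha = 0.05) {
  n_units <- check_count(n_units, "n_units")
  n_tests_per_unit <- check_count(n_tests_per_unit, "n_tests_per_unit")
  alpha / (n_tests_per_unit * n_units)
}

#' Carrier prevalence among cases
#'
#' Fraction of cases carrying a qualifying variant, as a percentage.
#'
#' @param n_carriers number of carrier cases.
#' @param n_cases total cases.
#' @param digits rounding for the reported percentage.
#' @return percentage.
#' @examples
#' carrier_prevalence(52, 2548)
#' @export
carrier_prevalence <- function(n_carriers, n_cases, digits = 0) {
  round(100 * n_carriers / n_cases, digits)
}

# run one scenario for one unit (a gene or a pooled tier)
test_unit <- function(unit_id, tier, scenario, variant_ids, G, samples,
                      null, weights_all, rho_grid, thresholds) {
  base <- data.frame(
    unit = unit_id, tier = tier, rarity = scenario$rarity,
    function_class = scenario$function_class,
    n_variants = length(variant_ids),
    case_ts_alleles = NA_real_, case_wes_alleles = NA_real_,
    control_alleles = NA_real_, or = NA_real_, or_adjusted = NA_real_,
    ci_lower = NA_real_, ci_upper = NA_real_,
    p_burden = NA_real_, p_skat = NA_real_, p_skato = NA_real_,
    sig_primary = NA, sig_secondary = NA, no_test = TRUE,
    stringsAsFactors = FALSE)
  if (length(variant_ids) == 0) return(base)
  Gs <- G[, variant_ids, drop = FALSE]
  if (all(Gs == 0, na.rm = TRUE)) return(base)

  w <- weights_all[variant_ids]
  tab <- allele_count_table(G, samples$status, variant_ids,
                            cohort = samples$cohort)
  ors <- odds_ratio(tab)
  bt <- burden_test(Gs, null, w)
  so <- skato_test(Gs, null, w, rho_grid)
  by_cohort <- tab$alleles_by_cohort

  base$case_ts_alleles <- by_cohort[["CASE_TS"]] %||% 0
  base$case_wes_alleles <- by_cohort[["CASE_WES"]] %||% 0
  base$control_alleles <- by_cohort[["CONTROL_WES"]] %||% 0
  base$or <- ors$or
  base$or_adjusted <- ors$or_adjusted
  base$ci_lower <- ors$ci_lower
  base$ci_upper <- ors$ci_upper
  base$p_burden <- bt$p_value
  base$p_skat <- so$p_rho[which(so$rho_grid == 0)] %||% NA_real_
  base$p_skato <- so$p_value
  base$sig_primary <- min(bt$p_value, so$p_value) < thresholds[["primary"]]
  base$sig_secondary <- min(bt$p_value, so$p_value) < thresholds[["secondary"]]
  base$no_test <- FALSE
  base
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x

#' Per-gene association tests across filtering scenarios
#'
#' For each scenario, selects the gene's qualifying variants, runs the
#' weighted burden and SKAT-O tests, and builds the allele-count table
#' with raw and adjusted odds ratios. Genes with no surviving variants
#' (or no alternate alleles among them) yield a no-test record.
#'
#' @param G samples x variants dosage matrix (column names are variant
#'   ids).
#' @param samples sample table with `status` (0/1) and `cohort`.
#' @param classified per-variant classification from
#'   [classify_variants()].
#' @param gene gene symbol.
#' @param tier tier label for the report row.
#' @param scenarios data.frame of scenarios (see [filter_scenarios()]).
#' @param null optional pre-fitted [fit_null_model()]; fitted from
#'   `samples$status` when `NULL`.
#' @param beta_params Beta weight parameters.
#' @param rho_grid SKAT-O rho grid.
#' @param thresholds named vector with `primary` and `secondary`
#'   significance levels.
#' @return data.frame with one row per scenario.
#' @export
run_gene_tests <- function(G, samples, classified, gene, tier = NA,
                           scenarios = filter_scenarios(), null = NULL,
                           beta_params = c(1, 25),
                           rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                        0.5, 1),
                           thresholds = c(primary = 2e-4,
                                          secondary = 3.3e-5)) {
  if (is.null(null)) null <- fit_null_model(samples$status)
  weights_all <- gene_weights(G, beta_params)
  cls <- classified[classified$gene == gene, , drop = FALSE]
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    vids <- intersect(select_scenario_variants(cls, sc$rarity,
                                               sc$function_class),
                      colnames(G))
    test_unit(gene, tier, sc, vids, G, samples, null, weights_all,
              rho_grid, thresholds)
  })
  do.call(rbind, rows)
}

#' Per-tier (pooled) association tests
#'
#' Pools all qualifying variants across a tier's genes into one unit and
#' tests it like a gene. `run_all_tiers()` runs every gene, every tier
#' and the all-genes-combined unit across all scenarios.
#'
#' @inheritParams run_gene_tests
#' @param genes character vector of the tier's gene symbols.
#' @param tier_id label for the pooled unit.
#' @return data.frame with one row per scenario.
#' @export
run_tier_tests <- function(G, samples, classified, genes,
                           tier_id = "tier", scenarios = filter_scenarios(),
                           null = NULL, beta_params = c(1, 25),
                           rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                        0.5, 1),
                           thresholds = c(primary = 2e-4,
                                          secondary = 3.3e-5)) {
  if (length(genes) == 0) stop_invalid("tier must contain genes")
  if (is.null(null)) null <- fit_null_model(samples$status)
  weights_all <- gene_weights(G, beta_params)
  cls <- classified[classified$gene %in% genes, , drop = FALSE]
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    vids <- intersect(select_scenario_variants(cls, sc$rarity,
                                               sc$function_class),
                      colnames(G))
    test_unit(tier_id, tier_id, sc, vids, G, samples, null, weights_all,
              rho_grid, thresholds)
  })
  do.call(rbind, rows)
}

# Beta-density weights from the combined case+control sample MAF;
# monomorphic columns get weight 0 so they never contribute
gene_weights <- function(G, beta_params) {
  af <- colMeans(impute_dosage(G)) / 2
  maf <- pmin(af, 1 - af)
  w <- numeric(length(maf))
  pos <- maf > 0
  w[pos] <- variant_weights(maf[pos], beta_params)
  setNames(w, colnames(G))
}

#' @rdname run_tier_tests
#' @param gene_tiers data.frame `gene`, `tier` (see
#'   [default_gene_tiers()]).
#' @export
run_all_tiers <- function(G, samples, classified,
                          gene_tiers = default_gene_tiers(),
                          scenarios = filter_scenarios(), null = NULL,
                          beta_params = c(1, 25),
                          rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                       0.5, 1),
                          thresholds = c(primary = 2e-4,
                                         secondary = 3.3e-5)) {
  if (is.null(null)) null <- fit_null_model(samples$status)
  genes_present <- intersect(gene_tiers$gene, unique(classified$gene))
  gene_rows <- lapply(genes_present, function(g) {
    run_gene_tests(G, samples, classified, g,
                   tier = gene_tiers$tier[match(g, gene_tiers$gene)],
                   scenarios, null, beta_params, rho_grid, thresholds)
  })
  tier_rows <- lapply(unique(gene_tiers$tier), function(t) {
    run_tier_tests(G, samples, classified,
                   gene_tiers$gene[gene_tiers$tier == t], tier_id = t,
                   scenarios = scenarios, null = null,
                   beta_params = beta_params, rho_grid = rho_grid,
                   thresholds = thresholds)
  })
  combined <- run_tier_tests(G, samples, classified, gene_tiers$gene,
                             tier_id = "AllGenesCombined",
                             scenarios = scenarios, null = null,
                             beta_params = beta_params,
                             rho_grid = rho_grid, thresholds = thresholds)
  do.call(rbind, c(gene_rows, tier_rows, list(combined)))
}

#' Summarize association results into report tables
#'
#' Produces the two standard reports: a nominal-hits table restricted to
#' units with burden or SKAT-O p below 0.05, and the full odds-ratio /
#' confidence-interval table across all scenarios (the forest-plot
#' table). Rows are ordered deterministically by tier, then unit, then
#' scenario.
#'
#' @param results data.frame from [run_all_tiers()] (or bound rows from
#'   the per-unit runners).
#' @param nominal_alpha nominal significance level for the hits table.
#' @return list with `hits` and `forest` data.frames.
#' @export
summarize_results <- function(results, nominal_alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) {
    stop_invalid("no association results to summarize")
  }
  ord <- order(results$tier, results$unit, results$rarity,
               results$function_class)
  results <- results[ord, , drop = FALSE]
  tested <- !results$no_test
  nominal <- tested & (pmin(results$p_burden, results$p_skato,
                            na.rm = TRUE) < nominal_alpha)
  hits <- results[nominal, c("unit", "tier", "rarity", "function_class",
                             "n_variants", "case_ts_alleles",
                             "case_wes_alleles", "control_alleles", "or",
                             "or_adjusted", "p_skato", "p_burden"),
                  drop = FALSE]
  forest <- results[, c("unit", "tier", "rarity", "function_class",
                        "n_variants", "or", "or_adjusted", "ci_lower",
                        "ci_upper", "p_burden", "p_skat", "p_skato",
                        "no_test"), drop = FALSE]
  rownames(hits) <- rownames(forest) <- NULL
  list(hits = hits, forest = forest)
}
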