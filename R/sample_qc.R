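#' Sample exclusion rules
#'
#' Individual exclusion rules of the sample QC cascade. Each takes the
#' per-sample metrics table (columns as produced by
#' [simulate_qc_metrics()]) and returns the character vector of excluded
#' sample ids. [run_sample_qc()] applies them in the documented order.
#'
#' @param metrics per-sample QC metrics data.frame (must contain `id`
#'   plus the columns each rule reads).
#' @name qc_rules
NULL

#' @describeIn qc_rules excludes samples whose mean read depth is more
#'   than 3 SD below the cohort mean, both computed over the input table
#'   before any exclusion. With fewer than 2 samples this is an error;
#'   with zero depth variance nobody is excluded (a warning is issued).
#' @param sd_multiplier how many SDs below the mean the cutoff sits.
#' @export
exclude_low_depth <- function(metrics, sd_multiplier = 3) {
  if (nrow(metrics) < 2L) {
    stop_invalid("depth screening needs at least 2 samples")
  }
  s <- sd(metrics$mean_depth)
  if (s == 0) {
    warning("zero depth variance; no depth exclusions", call. = FALSE)
    return(character())
  }
  cutoff <- mean(metrics$mean_depth) - sd_multiplier * s
  metrics$id[metrics$mean_depth < cutoff]
}

#' @describeIn qc_rules excludes samples with array concordance below
#'   90%; samples without array data (`NA`) pass.
#' @export
exclude_discordant <- function(metrics) {
  metrics$id[!is.na(metrics$concordance) & metrics$concordance < 0.90]
}

#' @describeIn qc_rules excludes samples with genotype missing rate
#'   above 50% (strictly).
#' @export
exclude_high_missingness <- function(metrics) {
  metrics$id[metrics$missing_rate > 0.50]
}

#' @describeIn qc_rules excludes samples flagged as contaminated:
#'   FREEMIX at or above the threshold, or the skewed-hets flag set.
#' @param freemix_threshold contamination fraction cutoff (default 0.03).
#' @export
exclude_contaminated <- function(metrics, freemix_threshold = 0.03) {
  flag <- if ("skewed_hets" %in% names(metrics)) metrics$skewed_hets else FALSE
  metrics$id[metrics$freemix >= freemix_threshold | flag]
}

#' Assign continental ancestry from principal components
#'
#' Labels a sample European when its first two principal-component
#' coordinates lie within `k_sd` robust standard deviations (MAD-based)
#' of the European reference centroid on both axes. Samples that are
#' non-European by genetics, or that carry a reported non-European
#' ancestry regardless of genetics, are excluded.
#'
#' @param metrics per-sample table with `id`, `pc1`, `pc2` and optional
#'   `reported_ancestry`.
#' @param reference_pcs labelled reference coordinates as from
#'   [simulate_reference_pcs()] (columns `population`, `pc1`, `pc2`);
#'   must contain a `EUR` cluster.
#' @param k_sd dispersion multiplier (default 6 robust SDs).
#' @return list with `labels` (character vector, `"European"` /
#'   `"non-European"`, named by id) and `excluded` (ids).
#' @export
assign_ancestry <- function(metrics, reference_pcs, k_sd = 6) {
  if (is.null(reference_pcs) || nrow(reference_pcs) == 0 ||
      !"EUR" %in% reference_pcs$population) {
    stop_invalid("reference PCs must contain a labelled EUR cluster")
  }
  eur <- reference_pcs[reference_pcs$population == "EUR", ]
  ctr <- c(stats::median(eur$pc1), stats::median(eur$pc2))
  disp <- c(stats::mad(eur$pc1), stats::mad(eur$pc2))
  disp[disp == 0] <- 1e-12
  genetic_eur <- abs(metrics$pc1 - ctr[1]) <= k_sd * disp[1] &
    abs(metrics$pc2 - ctr[2]) <= k_sd * disp[2]
  reported_noneur <- if ("reported_ancestry" %in% names(metrics)) {
    !is.na(metrics$reported_ancestry) &
      metrics$reported_ancestry != "European"
  } else FALSE
  labels <- setNames(ifelse(genetic_eur, "European", "non-European"),
                     metrics$id)
  list(labels = labels,
       excluded = metrics$id[!genetic_eur | reported_noneur])
}

#' Sequential relatedness pruning
#'
#' Iteratively removes one individual at a time from the graph of sample
#' pairs whose identity-by-descent estimate exceeds `ibd_threshold`,
#' until no such pair remains. At each step the removed individual is
#' chosen by (1) largest number of remaining relationships, tie-broken by
#' (2) group priority for removal - diseased controls first, then
#' non-diseased controls, then cases - then by (3) lower mean sequencing
#' depth, and finally (4) sample id (logged as a residual tie-break).
#'
#' @param pairs data.frame `id_a`, `id_b`, `pi_hat`.
#' @param metrics per-sample table with `id`, `group`, `mean_depth`.
#' @param ibd_threshold pairs above this estimate count as related
#'   (default 0.1875, midway between 2nd- and 3rd-degree expectations).
#' @return list with `retained` ids, `removed` ids (in removal order)
#'   and `residual_tie` (logical, whether rule (4) was ever needed).
#' @export
prune_related <- function(pairs, metrics, ibd_threshold = 0.1875) {
  removal_priority <- c(diseased_control = 1, non_diseased_control = 2,
                        case = 3)
  active <- pairs[pairs$pi_hat > ibd_threshold, c("id_a", "id_b")]
  unknown <- setdiff(unique(c(active$id_a, active$id_b)), metrics$id)
  if (length(unknown)) {
    stop_invalid("IBD pairs reference unknown samples: %s",
                 paste(unknown, collapse = ", "))
  }
  removed <- character()
  residual_tie <- FALSE
  while (nrow(active) > 0) {
    deg <- table(c(active$id_a, active$id_b))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      pri <- removal_priority[metrics$group[match(cand, metrics$id)]]
      cand <- cand[pri == min(pri)]
    }
    if (length(cand) > 1) {
      dep <- metrics$mean_depth[match(cand, metrics$id)]
      cand <- cand[dep == min(dep)]
    }
    if (length(cand) > 1) {
      residual_tie <- TRUE
      cand <- sort(cand)[1]
    }
    removed <- c(removed, cand)
    active <- active[active$id_a != cand & active$id_b != cand, ,
                     drop = FALSE]
  }
  list(retained = setdiff(metrics$id, removed), removed = removed,
       residual_tie = residual_tie)
}

#' Run the full sample QC cascade
#'
#' Applies the exclusion rules in the study's order - contamination,
#' depth, concordance, missingness, ancestry, relatedness - recording
#' per-stage exclusions. Each stage's statistics are computed over the
#' samples still retained when it runs, and the relatedness graph is
#' restricted to retained samples.
#'
#' @param metrics per-sample QC metrics (see [simulate_qc_metrics()]).
#' @param ibd IBD pair table (`id_a`, `id_b`, `pi_hat`).
#' @param reference_pcs labelled PC reference for [assign_ancestry()];
#'   `NULL` skips the ancestry stage.
#' @param freemix_threshold,depth_sd_multiplier,k_sd,ibd_threshold
#'   stage parameters (see the individual rules).
#' @return list with `retained` ids, `exclusions` (data.frame id, stage,
#'   reason) and `stage_counts` (data.frame stage, n_excluded,
#'   n_retained_after).
#' @examples
#' s <- data.frame(id = sprintf("S%02d", 1:30))
#' qc <- simulate_qc_metrics(s, list(low_depth = 2), seed = 1)
#' run_sample_qc(qc$metrics, qc$ibd)$stage_counts
#' @export
run_sample_qc <- function(metrics, ibd = NULL, reference_pcs = NULL,
                          freemix_threshold = 0.03,
                          depth_sd_multiplier = 3, k_sd = 6,
                          ibd_threshold = 0.1875) {
  exclusions <- data.frame(id = character(), stage = character(),
                           reason = character(), stringsAsFactors = FALSE)
  note <- function(ids, stage, reason) {
    if (length(ids)) {
      exclusions <<- rbind(exclusions,
                           data.frame(id = ids, stage = stage,
                                      reason = reason,
                                      stringsAsFactors = FALSE))
    }
  }
  cur <- metrics
  stages <- list()
  drop_ids <- function(ids, stage, reason) {
    note(ids, stage, reason)
    cur <<- cur[!cur$id %in% ids, , drop = FALSE]
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, n_excluded = length(ids), n_retained_after = nrow(cur))
  }

  drop_ids(exclude_contaminated(cur, freemix_threshold), "contamination",
           sprintf("FREEMIX >= %g or skewed hets", freemix_threshold))
  drop_ids(exclude_low_depth(cur, depth_sd_multiplier), "depth",
           sprintf("mean depth < mean - %g SD", depth_sd_multiplier))
  drop_ids(exclude_discordant(cur), "concordance",
           "array concordance < 90%")
  drop_ids(exclude_high_missingness(cur), "missingness",
           "genotype missing rate > 50%")
  if (!is.null(reference_pcs)) {
    anc <- assign_ancestry(cur, reference_pcs, k_sd)
    drop_ids(anc$excluded, "ancestry",
             "non-European by genetics or report")
  }
  if (!is.null(ibd) && nrow(ibd) > 0) {
    sub <- ibd[ibd$id_a %in% cur$id & ibd$id_b %in% cur$id, , drop = FALSE]
    pr <- prune_related(sub, cur, ibd_threshold)
    drop_ids(pr$removed, "relatedness",
             sprintf("IBD > %g, sequential pruning", ibd_threshold))
  }

  list(retained = cur$id, exclusions = exclusions,
       stage_counts = do.call(rbind, stages))
}
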