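#' Simulate a labelled principal-component reference
#'
#' Generates continental reference clusters on the first two genotype
#' principal components, the coordinate system [assign_ancestry()] uses.
#' European, African and East-Asian clusters are placed at well-separated
#' centroids with modest within-cluster spread.
#'
#' @param n_per_pop reference individuals per population.
#' @param seed integer RNG seed.
#' @return data.frame: `id`, `population`, `pc1`, `pc2`.
#' @export
simulate_reference_pcs <- function(n_per_pop = 100, seed) {
  n_per_pop <- check_count(n_per_pop, "n_per_pop")
  seed <- check_count(seed, "seed", min = 0L)
  centroids <- rbind(EUR = c(0, 0), AFR = c(0.12, 0.01),
                     EAS = c(0.02, 0.10))
  withr::with_seed(seed, {
    do.call(rbind, lapply(rownames(centroids), function(p) {
      data.frame(id = sprintf("%s%03d", p, seq_len(n_per_pop)),
                 population = p,
                 pc1 = rnorm(n_per_pop, centroids[p, 1], 0.004),
                 pc2 = rnorm(n_per_pop, centroids[p, 2], 0.004),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate per-sample QC metrics with planted failures
#'
#' Draws baseline contamination (FREEMIX), mean read depth, array
#' concordance, genotype missingness and principal-component coordinates
#' for every sample, then plants exactly the requested number of failures
#' of each kind, recording them in a truth table so downstream QC can be
#' validated exactly. Planted failures are assigned to disjoint sample
#' sets. Relatedness failures are planted as high identity-by-descent
#' (IBD) pairs; `related_trios` plants one individual related to two
#' others (three pairwise relationships).
#'
#' @param samples data.frame with at least `id` (and optionally `cohort`,
#'   `group` which are carried through).
#' @param outlier_spec named list of planted failure counts:
#'   `contamination`, `low_depth`, `discordant`, `high_missing`,
#'   `non_european_genetic`, `non_european_reported`, `related_pairs`,
#'   `related_trios` (all default 0).
#' @param depth_mean,depth_sd baseline depth distribution.
#' @param seed integer RNG seed.
#' @return A list with `metrics` (per-sample QC table with columns id,
#'   cohort, group, freemix, skewed_hets, mean_depth, concordance,
#'   missing_rate, pc1, pc2, reported_ancestry), `ibd` (data.frame id_a,
#'   id_b, pi_hat) and `truth` (data.frame id, failure).
#' @examples
#' s <- data.frame(id = sprintf("S%02d", 1:20))
#' qc <- simulate_qc_metrics(s, list(low_depth = 2), seed = 1)
#' qc$truth
#' @export
simulate_qc_metrics <- function(samples, outlier_spec = list(),
                                depth_mean = 30, depth_sd = 2, seed) {
  stopifnot(is.data.frame(samples), "id" %in% names(samples))
  seed <- check_count(seed, "seed", min = 0L)
  spec <- utils::modifyList(
    list(contamination = 0L, low_depth = 0L, discordant = 0L,
         high_missing = 0L, non_european_genetic = 0L,
         non_european_reported = 0L, related_pairs = 0L,
         related_trios = 0L),
    as.list(outlier_spec))
  n <- nrow(samples)
  n_planted <- spec$contamination + spec$low_depth + spec$discordant +
    spec$high_missing + spec$non_european_genetic +
    spec$non_european_reported + 2L * spec$related_pairs +
    3L * spec$related_trios
  if (n_planted > n) {
    stop_invalid("planted failure counts (%d) exceed sample count (%d)",
                 n_planted, n)
  }

  withr::with_seed(seed, {
    metrics <- data.frame(
      id = samples$id,
      cohort = if ("cohort" %in% names(samples)) samples$cohort else "CASE_TS",
      group = if ("group" %in% names(samples)) samples$group else "case",
      freemix = rbeta(n, 1, 400),
      skewed_hets = FALSE,
      mean_depth = rnorm(n, depth_mean, depth_sd),
      concordance = 1 - rbeta(n, 1, 500),
      missing_rate = rbeta(n, 2, 200),
      pc1 = rnorm(n, 0, 0.004),
      pc2 = rnorm(n, 0, 0.004),
      reported_ancestry = "European",
      stringsAsFactors = FALSE
    )
    metrics$freemix <- pmin(metrics$freemix, 0.02)  # keep baseline clean

    pool_ids <- sample(samples$id)  # random disjoint assignment
    take <- function(k) {
      if (k == 0L) return(character(0))
      ids <- utils::head(pool_ids, k)
      pool_ids <<- pool_ids[-seq_len(length(ids))]
      ids
    }
    truth <- list()
    plant <- function(ids, failure) {
      if (length(ids)) {
        truth[[length(truth) + 1L]] <<- data.frame(
          id = ids, failure = failure, stringsAsFactors = FALSE)
      }
      ids
    }

    i <- match(plant(take(spec$contamination), "contamination"), metrics$id)
    metrics$freemix[i] <- runif(length(i), 0.08, 0.2)
    metrics$skewed_hets[i] <- TRUE

    i <- match(plant(take(spec$low_depth), "low_depth"), metrics$id)
    metrics$mean_depth[i] <- depth_mean - 6 * depth_sd

    i <- match(plant(take(spec$discordant), "discordant"), metrics$id)
    metrics$concordance[i] <- runif(length(i), 0.6, 0.85)

    i <- match(plant(take(spec$high_missing), "high_missing"), metrics$id)
    metrics$missing_rate[i] <- runif(length(i), 0.6, 0.9)

    i <- match(plant(take(spec$non_european_genetic), "non_european_genetic"),
               metrics$id)
    metrics$pc1[i] <- rnorm(length(i), 0.12, 0.004)  # African centroid

    i <- match(plant(take(spec$non_european_reported),
                     "non_european_reported"), metrics$id)
    metrics$reported_ancestry[i] <- "non-European"

    ibd <- data.frame(id_a = character(), id_b = character(),
                      pi_hat = numeric(), stringsAsFactors = FALSE)
    for (k in seq_len(spec$related_pairs)) {
      ids <- plant(take(2L), "related")
      ibd <- rbind(ibd, data.frame(id_a = ids[1], id_b = ids[2],
                                   pi_hat = 0.5))
    }
    for (k in seq_len(spec$related_trios)) {
      ids <- plant(take(3L), "related")
      ibd <- rbind(ibd,
                   data.frame(id_a = ids[c(1, 1, 2)], id_b = ids[c(2, 3, 3)],
                              pi_hat = c(0.5, 0.5, 0.25)))
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = character(), failure = character(),
                 stringsAsFactors = FALSE)
    list(metrics = metrics, ibd = ibd, truth = truth)
  })
}
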