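base_metrics <- function(n = 20, depth = 30) {
  data.frame(id = sprintf("S%02d", seq_len(n)), cohort = "CASE_TS",
             group = "case", freemix = 0.001, skewed_hets = FALSE,
             mean_depth = depth, concordance = 0.99, missing_rate = 0.01,
             pc1 = 0, pc2 = 0, reported_ancestry = "European",
             stringsAsFactors = FALSE)
}

test_that("depth exclusion applies the 3-SD rule over the input cohort", {
  withr::local_seed(50)
  m <- base_metrics(100)
  m$mean_depth <- rnorm(100, 20, 2)
  m$mean_depth[1] <- 13  # below mean - 3 SD ~ 14
  out <- exclude_low_depth(m)
  expect_true("S01" %in% out)
  cutoff <- mean(m$mean_depth) - 3 * sd(m$mean_depth)
  expect_setequal(out, m$id[m$mean_depth < cutoff])
  # degenerate zero-variance input excludes nobody, with a warning
  expect_warning(none <- exclude_low_depth(base_metrics(5)), "variance")
  expect_length(none, 0)
  expect_error(exclude_low_depth(base_metrics(1)), "at least 2")
})

test_that("concordance, missingness and contamination rules hit their edges", {
  m <- base_metrics(4)
  m$concordance <- c(0.89, 0.90, NA, 0.99)
  expect_identical(exclude_discordant(m), "S01")

  m <- base_metrics(3)
  m$missing_rate <- c(0.51, 0.50, 0)
  expect_identical(exclude_high_missingness(m), "S01")

  m <- base_metrics(4)
  m$freemix <- c(0.10, 0.0, 0.03, 0.0)
  m$skewed_hets <- c(FALSE, FALSE, FALSE, TRUE)
  expect_setequal(exclude_contaminated(m, 0.03), c("S01", "S03", "S04"))
})

test_that("ancestry assignment combines genetics with reported ancestry", {
  ref <- simulate_reference_pcs(seed = 51)
  afr <- ref[ref$population == "AFR", ]
  m <- base_metrics(3)
  m$pc1 <- c(0, median(afr$pc1), 0.001)
  m$pc2 <- c(0, median(afr$pc2), -0.001)
  m$reported_ancestry <- c("European", "European", "non-European")
  anc <- assign_ancestry(m, ref)
  expect_identical(unname(anc$labels),
                   c("European", "non-European", "European"))
  # genetic outlier and reported non-European both excluded
  expect_setequal(anc$excluded, c("S02", "S03"))
  expect_error(assign_ancestry(m, ref[ref$population != "EUR", ]), "EUR")
})

test_that("relatedness pruning follows degree, group priority, then depth", {
  m <- base_metrics(6)
  m$group <- c("case", "diseased_control", "case", "case", "case", "case")
  m$mean_depth <- c(30, 30, 30, 30, 20, 30)
  # case-control pair: the control goes
  pr <- prune_related(data.frame(id_a = "S01", id_b = "S02", pi_hat = 0.5),
                      m)
  expect_identical(pr$removed, "S02")
  # chain A-B-C: the middle (degree 2) goes
  pairs <- data.frame(id_a = c("S03", "S04"), id_b = c("S04", "S05"),
                      pi_hat = 0.5)
  pr <- prune_related(pairs, m)
  expect_identical(pr$removed, "S04")
  # two related cases: the lower-depth one goes
  pr <- prune_related(data.frame(id_a = "S05", id_b = "S06", pi_hat = 0.3),
                      m)
  expect_identical(pr$removed, "S05")
  # sub-threshold pairs are not pruned at all
  pr <- prune_related(data.frame(id_a = "S01", id_b = "S02",
                                 pi_hat = 0.12), m)
  expect_length(pr$removed, 0)
  expect_error(prune_related(data.frame(id_a = "S01", id_b = "ZZZ",
                                        pi_hat = 0.5), m), "unknown")
})

test_that("no retained pair exceeds the IBD threshold after pruning", {
  withr::local_seed(52)
  for (rep in 1:10) {
    n <- 15
    m <- base_metrics(n)
    m$group <- sample(c("case", "diseased_control", "non_diseased_control"),
                      n, replace = TRUE)
    m$mean_depth <- rnorm(n, 30, 3)
    k <- 12
    pairs <- data.frame(
      id_a = sample(m$id, k, replace = TRUE),
      id_b = sample(m$id, k, replace = TRUE),
      pi_hat = runif(k, 0, 0.6), stringsAsFactors = FALSE)
    pairs <- pairs[pairs$id_a != pairs$id_b, ]
    pr <- prune_related(pairs, m, ibd_threshold = 0.1875)
    live <- pairs$id_a %in% pr$retained & pairs$id_b %in% pr$retained
    expect_true(all(pairs$pi_hat[live] <= 0.1875))
  }
})

test_that("planted QC failures are recovered exactly and the cascade is idempotent", {
  samples <- data.frame(id = sprintf("P%03d", 1:120))
  spec <- list(contamination = 3, low_depth = 5, discordant = 2,
               high_missing = 2, non_european_genetic = 3,
               non_european_reported = 1)
  qc <- simulate_qc_metrics(samples, spec, seed = 53)
  ref <- simulate_reference_pcs(seed = 54)
  res <- run_sample_qc(qc$metrics, qc$ibd, ref)
  stage_of <- c(contamination = "contamination", low_depth = "depth",
                discordant = "concordance", high_missing = "missingness",
                non_european_genetic = "ancestry",
                non_european_reported = "ancestry")
  for (f in names(spec)) {
    planted <- qc$truth$id[qc$truth$failure == f]
    found <- res$exclusions$id[res$exclusions$stage == stage_of[[f]]]
    expect_setequal(intersect(planted, found), planted)
  }
  expect_identical(sort(res$exclusions$id), sort(qc$truth$id))
  # idempotence: re-running on the retained set excludes nobody new
  again <- run_sample_qc(
    qc$metrics[qc$metrics$id %in% res$retained, ],
    qc$ibd, ref)
  expect_setequal(again$retained, res$retained)
})

test_that("zero planted outliers means zero exclusions at default thresholds", {
  qc <- simulate_qc_metrics(data.frame(id = sprintf("P%03d", 1:60)),
                            seed = 55)
  res <- run_sample_qc(qc$metrics, qc$ibd, simulate_reference_pcs(seed = 56))
  expect_length(res$exclusions$id, 0)
  expect_setequal(res$retained, sprintf("P%03d", 1:60))
})

test_that("a planted related trio yields three IBD pairs and is pruned", {
  qc <- simulate_qc_metrics(data.frame(id = sprintf("P%03d", 1:30)),
                            list(related_trios = 1), seed = 57)
  expect_identical(nrow(qc$ibd), 3L)
  res <- run_sample_qc(qc$metrics, qc$ibd)
  live <- qc$ibd$id_a %in% res$retained & qc$ibd$id_b %in% res$retained
  expect_true(all(qc$ibd$pi_hat[live] <= 0.1875))
})
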