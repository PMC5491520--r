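#' Default reference-panel layout
#'
#' Thirteen "internal" panels (cohorts sequenced and processed in parallel
#' with the study samples) and seven "external" public panels, with sizes
#' (in individuals) loosely modelled on the mix of disease-cohort exome
#' sets and public whole-genome/exome resources a resequencing study
#' filters against.
#'
#' @return Named integer vector of 20 panel sizes; names carry an
#'   `INT`/`EXT` prefix.
#' @export
default_panel_sizes <- function() {
  sizes <- c(rep(160L, 13),           # internal exome sets
             3781L,                   # external WGS
             2203L, 1088L,            # exome project, two ancestries
             246L, 181L, 286L, 379L)  # four continental panels
  names(sizes) <- c(sprintf("INT%02d", 1:13), sprintf("EXT%02d", 1:7))
  sizes
}

#' Simulate allele-frequency reference panels
#'
#' Draws per-panel allele counts binomially from the pool frequencies.
#' Sites with zero sampled copies in a panel are marked unobserved there,
#' so genuinely "novel" sites (unseen in every panel) arise naturally.
#' An optional per-site, per-panel `dropout` probability forces a site to
#' be unascertained regardless of its frequency, mimicking patchy panel
#' coverage.
#'
#' @param pool a [simulate_haplotype_pool()] object supplying true
#'   frequencies.
#' @param panel_sizes named vector of 20 panel sizes (13 `INT*`, 7
#'   `EXT*`); see [default_panel_sizes()].
#' @param dropout probability a site is unascertained in a given panel.
#' @param seed integer RNG seed.
#' @return A data.frame with one row per (panel, site): `panel_id`,
#'   `panel_type` ("internal"/"external"), `variant_id`, `allele_count`,
#'   `allele_number`, `maf`, `observed`. Unobserved sites keep
#'   `allele_count` 0 and `maf` `NA`.
#' @examples
#' pool <- simulate_haplotype_pool(200, 1000, seed = 1)
#' panels <- simulate_reference_panels(pool, seed = 2)
#' head(panels)
#' @export
simulate_reference_panels <- function(pool,
                                      panel_sizes = default_panel_sizes(),
                                      dropout = 0, seed) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (length(panel_sizes) != 20L || any(panel_sizes <= 0)) {
    stop_invalid("`panel_sizes` must give 20 positive sizes (13 internal + 7 external)")
  }
  dropout <- check_prob(dropout, "dropout")
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(names(panel_sizes))) {
    names(panel_sizes) <- c(sprintf("INT%02d", 1:13), sprintf("EXT%02d", 1:7))
  }

  vids <- variant_ids(pool)
  m <- length(vids)
  withr::with_seed(seed, {
    rows <- lapply(names(panel_sizes), function(pid) {
      an <- 2L * as.integer(panel_sizes[[pid]])
      ac <- rbinom(m, an, pool$maf)
      if (dropout > 0) ac[runif(m) < dropout] <- 0L
      observed <- ac > 0L
      data.frame(
        panel_id = pid,
        panel_type = if (grepl("^INT", pid)) "internal" else "external",
        variant_id = vids,
        allele_count = ac,
        allele_number = an,
        maf = ifelse(observed, ac / an, NA_real_),
        observed = observed,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
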