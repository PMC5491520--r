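# shared fixture builders; everything is generated in code

# a small pool cached per session (deterministic)
small_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_haplotype_pool(500, 5000, seed = 101)
    }
    cache
  }
})

# hand-built panel rows for one variant: 13 internal + 7 external
make_panel_rows <- function(int_ac = rep(0L, 13), int_an = rep(320L, 13),
                            ext_ac = rep(0L, 7), ext_an = rep(2000L, 7)) {
  ac <- c(int_ac, ext_ac)
  an <- c(int_an, ext_an)
  data.frame(
    panel_id = c(sprintf("INT%02d", 1:13), sprintf("EXT%02d", 1:7)),
    panel_type = rep(c("internal", "external"), c(13, 7)),
    variant_id = "1:1:A:T",
    allele_count = ac,
    allele_number = an,
    maf = ifelse(ac > 0, ac / an, NA_real_),
    observed = ac > 0,
    stringsAsFactors = FALSE
  )
}

# a full 20-panel table for a set of variant ids with given pool mafs
make_panel_table <- function(variant_ids, mafs, seed = 1) {
  stopifnot(length(variant_ids) == length(mafs))
  pseudo <- structure(
    list(positions = seq_along(mafs), ref = rep("A", length(mafs)),
         alt = rep("T", length(mafs)), maf = mafs),
    class = "haplotype_pool")
  tab <- simulate_reference_panels(pseudo, seed = seed)
  native <- sprintf("1:%d:A:T", seq_along(mafs))
  tab$variant_id <- variant_ids[match(tab$variant_id, native)]
  tab
}

# independent brute-force re-implementation of the classification rules,
# written directly from the stated rules (the oracle for the cascade)
oracle_classify <- function(ann_one, panel_rows, known_gene, crt,
                            severity = default_severity_order()) {
  functional_set <- c("essential splice site", "stop gained", "stop lost",
                      "complex indel", "frameshift coding",
                      "non synonymous coding", "within mature miRNA",
                      "partial codon")
  cons <- if (known_gene) {
    ann_one$consequence[ann_one$transcript == crt]
  } else {
    ranks <- match(ann_one$consequence, severity)
    ranks[is.na(ranks)] <- length(severity) + 1
    ann_one$consequence[order(ranks)][1]
  }
  fc <- if (cons %in% functional_set) "functional"
        else if (cons == "synonymous coding") "synonymous" else "other"

  int <- panel_rows[panel_rows$panel_type == "internal", ]
  ext <- panel_rows[panel_rows$panel_type == "external", ]
  rar <- if (!any(panel_rows$observed)) {
    "novel"
  } else if (sum(int$allele_count) / sum(int$allele_number) > 0.01 ||
             any(int$observed & int$maf > 0.10) ||
             any(ext$observed & ext$maf > 0.01)) {
    "excluded"
  } else {
    "rare"
  }

  del_calls <- c(identical(ann_one$sift_label[1], "deleterious"),
                 ann_one$polyphen_label[1] %in% c("probably damaging",
                                                  "damaging"),
                 identical(ann_one$condel_label[1], "deleterious"))
  del_calls[is.na(del_calls)] <- FALSE
  ds <- if (all(del_calls)) "all_three"
        else if (any(del_calls)) "one_plus" else "none"
  list(function_class = fc, rarity = rar, del_stratum = ds)
}

# random classified table for scenario / nesting properties
random_classified <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(
      variant_id = sprintf("v%03d", seq_len(n)),
      gene = sample(c("G1", "G2"), n, replace = TRUE),
      function_class = sample(c("functional", "synonymous", "other"), n,
                              replace = TRUE),
      rarity = sample(c("rare", "novel", "excluded"), n, replace = TRUE),
      del_stratum = sample(c("none", "one_plus", "all_three"), n,
                           replace = TRUE),
      clinvar_status = sample(c(NA, "Pathogenic", "Likely pathogenic",
                                "Benign"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
enumerate_fisher <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# vectorized Liu moment-matched tail over many statistics, one lambda set
liu_batch <- function(q, lambdas) {
  p <- rvtiers:::liu_params(lambdas)
  pchisq((q - p$mu_q) / p$sigma_q * p$sigma_x + p$mu_x, df = p$l,
         ncp = p$d, lower.tail = FALSE)
}

# small case-control genotype fixture with named columns
random_genotypes <- function(n, m, mafs = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(mafs)) mafs <- runif(m, 0.02, 0.2)
    G <- vapply(mafs, function(p) rbinom(n, 2L, p), integer(n))
    colnames(G) <- sprintf("v%03d", seq_len(m))
    rownames(G) <- sprintf("S%03d", seq_len(n))
    G
  })
}
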