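#' Allele-count 2x2 table for a variant subset
#'
#' Builds the case/control allele-count table for a set of variants:
#' cell `a` sums alternate-allele dosages over the subset in cases, and
#' the case margin is twice the number of non-missing genotype calls
#' over the subset in cases (so missing genotypes drop out of the
#' denominator per variant); controls likewise.
#'
#' @param G samples x variants dosage matrix (`NA` = missing call).
#' @param status binary case indicator per sample.
#' @param variants column names (or indices) of the subset; must be
#'   non-empty.
#' @param cohort optional per-sample cohort labels; when given, per-
#'   cohort case allele counts are attached.
#' @return An object of class `contingency_table`: list with integer
#'   cells `a` (case alt alleles), `b` (case ref alleles), `c` (control
#'   alt), `d` (control ref), and optionally `alleles_by_cohort`.
#' @examples
#' G <- rbind(c(1, 0), c(0, 0), c(0, 1))
#' colnames(G) <- c("v1", "v2")
#' allele_count_table(G, c(1, 1, 0), c("v1", "v2"))
#' @export
allele_count_table <- function(G, status, variants, cohort = NULL) {
  if (length(variants) == 0) stop_invalid("variant subset must be non-empty")
  Gs <- G[, variants, drop = FALSE]
  case <- status == 1
  alt <- function(rows) sum(Gs[rows, , drop = FALSE], na.rm = TRUE)
  margin <- function(rows) 2L * sum(!is.na(Gs[rows, , drop = FALSE]))
  a <- alt(case); mc <- margin(case)
  c_ <- alt(!case); mctl <- margin(!case)
  out <- list(a = a, b = mc - a, c = c_, d = mctl - c_,
              n_variants = ncol(Gs))
  if (!is.null(cohort)) {
    out$alleles_by_cohort <- vapply(split(seq_along(status), cohort),
                                    function(i) alt(seq_along(status) %in% i),
                                    numeric(1))
  }
  structure(out, class = "contingency_table")
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2,
         dimnames = list(c("case", "control"), c("alt", "ref")))
}

#' Odds ratio with zero-cell adjustment
#'
#' Cross-product odds ratio `ad / (bc)`, reported as infinite when the
#' variant is absent from controls (`c = 0`). Whenever any cell is zero
#' an adjusted odds ratio is also computed by adding 0.5 to every cell
#' (the Haldane-Anscombe correction); the 95% confidence interval uses
#' the log-OR normal approximation on the (possibly adjusted) table.
#'
#' @param tab a [allele_count_table()] result (or list with `a`-`d`).
#' @param continuity `"auto"` adds 0.5 only when a zero cell exists,
#'   `"always"`/`"never"` force the behaviour.
#' @return list with `or`, `or_adjusted`, `ci_lower`, `ci_upper`,
#'   `adjusted` (flag).
#' @examples
#' odds_ratio(list(a = 15, b = 5081, c = 0, d = 2234))$or_adjusted
#' @export
odds_ratio <- function(tab, continuity = c("auto", "always", "never")) {
  continuity <- match.arg(continuity)
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(is.na(cells)) || any(cells < 0) || sum(cells) == 0) {
    stop_invalid("invalid or empty 2x2 table")
  }
  or <- (tab$a * tab$d) / (tab$b * tab$c)
  if (tab$c == 0 || tab$b == 0) or <- Inf
  if (tab$a == 0 || tab$d == 0) {
    or <- if (is.infinite(or)) NaN else 0
  }
  adjust <- switch(continuity,
                   auto = any(cells == 0),
                   always = TRUE,
                   never = FALSE)
  adj <- cells + if (adjust) 0.5 else 0
  or_adj <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  se <- sqrt(sum(1 / adj))
  ci <- exp(log(or_adj) + c(-1, 1) * qnorm(0.975) * se)
  list(or = or, or_adjusted = or_adj, ci_lower = ci[1], ci_upper = ci[2],
       adjusted = adjust)
}

#' Fisher's exact test on a 2x2 allele table
#'
#' Two-sided exact p-value: the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param tab list with cells `a`, `b`, `c`, `d`.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  fisher.test(as_matrix_2x2(tab))$p.value
}

#' Pearson chi-squared test on a 2x2 allele table
#'
#' Without continuity correction by default (1 df); the Yates-corrected
#' variant is available behind `correct`.
#'
#' @param tab list with cells `a`, `b`, `c`, `d`.
#' @param correct apply the continuity correction?
#' @return p-value.
#' @export
chisq_test <- function(tab, correct = FALSE) {
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_invalid("chi-squared test undefined for a zero margin")
  }
  suppressWarnings(chisq.test(m, correct = correct))$p.value
}
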