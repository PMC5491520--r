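#' Default consequence-class sampling probabilities
#'
#' A plausible mix of coding-region consequence terms for a candidate-gene
#' resequencing panel, expressed in the classic Ensembl consequence
#' vocabulary used throughout the classification cascade.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_class_probabilities <- function() {
  c("non synonymous coding" = 0.42,
    "synonymous coding"     = 0.30,
    "stop gained"           = 0.04,
    "stop lost"             = 0.005,
    "essential splice site" = 0.02,
    "frameshift coding"     = 0.03,
    "complex indel"         = 0.005,
    "within mature miRNA"   = 0.005,
    "partial codon"         = 0.005,
    "intronic"              = 0.10,
    "5prime utr"            = 0.03,
    "3prime utr"            = 0.03,
    "upstream"              = 0.01)
}

#' Simulate a variant annotation table
#'
#' Fabricates the transcript-consequence and in-silico predictor labels
#' the classification cascade consumes: one worst-consequence term per
#' transcript, SIFT/PolyPhen/Condel labels for missense variants, and an
#' optional ClinVar status. The first transcript of each gene is treated
#' as its clinically relevant transcript.
#'
#' @param variants data.frame with at least `variant_id` and `gene`.
#' @param class_probabilities named probability vector over consequence
#'   terms (must sum to 1); drawn independently per transcript.
#' @param deleterious_probabilities named vector with elements `sift`,
#'   `polyphen`, `condel`: probability each predictor calls a missense
#'   variant deleterious.
#' @param clinvar_probabilities named probability vector over ClinVar
#'   statuses (use `"none"` for no entry); must sum to 1.
#' @param n_transcripts transcripts per gene.
#' @param seed integer RNG seed.
#' @return data.frame with one row per (variant, transcript):
#'   `variant_id`, `gene`, `transcript`, `consequence`, `sift_label`,
#'   `polyphen_label`, `condel_label`, `clinvar_status` (predictor and
#'   ClinVar columns repeat across a variant's transcripts).
#' @examples
#' v <- data.frame(variant_id = c("1:10:A:T", "1:20:C:G"),
#'                 gene = c("G1", "G1"))
#' simulate_annotations(v, seed = 1)
#' @export
simulate_annotations <- function(variants,
                                 class_probabilities =
                                   default_class_probabilities(),
                                 deleterious_probabilities =
                                   c(sift = 0.5, polyphen = 0.5,
                                     condel = 0.5),
                                 clinvar_probabilities =
                                   c(none = 0.95, Pathogenic = 0.01,
                                     `Likely pathogenic` = 0.01,
                                     Benign = 0.02,
                                     `Uncertain significance` = 0.01),
                                 n_transcripts = 2, seed) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "gene") %in% names(variants)))
  check_prob_vector(class_probabilities, "class_probabilities")
  check_prob_vector(clinvar_probabilities, "clinvar_probabilities")
  if (!all(c("sift", "polyphen", "condel") %in%
           names(deleterious_probabilities)) ||
      any(deleterious_probabilities < 0 | deleterious_probabilities > 1)) {
    stop_invalid(
      "`deleterious_probabilities` needs sift/polyphen/condel in [0, 1]")
  }
  n_transcripts <- check_count(n_transcripts, "n_transcripts")
  seed <- check_count(seed, "seed", min = 0L)

  n <- nrow(variants)
  withr::with_seed(seed, {
    cons <- sample(names(class_probabilities), n * n_transcripts,
                   replace = TRUE, prob = class_probabilities)
    ann <- data.frame(
      variant_id = rep(variants$variant_id, each = n_transcripts),
      gene = rep(variants$gene, each = n_transcripts),
      transcript = paste0(rep(variants$gene, each = n_transcripts), ".t",
                          rep(seq_len(n_transcripts), n)),
      consequence = cons,
      stringsAsFactors = FALSE
    )
    # predictor labels attach to the variant, not the transcript; only
    # missense (on any transcript) variants get scores
    missense <- tapply(ann$consequence == "non synonymous coding",
                       ann$variant_id, any)[variants$variant_id]
    lab <- function(p, yes, no) {
      ifelse(missense, ifelse(runif(n) < p, yes, no), NA_character_)
    }
    per_var <- data.frame(
      variant_id = variants$variant_id,
      sift_label = lab(deleterious_probabilities[["sift"]],
                       "deleterious", "tolerated"),
      polyphen_label = lab(deleterious_probabilities[["polyphen"]],
                           "probably damaging", "benign"),
      condel_label = lab(deleterious_probabilities[["condel"]],
                         "deleterious", "neutral"),
      clinvar_status = sample(names(clinvar_probabilities), n,
                              replace = TRUE,
                              prob = clinvar_probabilities),
      stringsAsFactors = FALSE
    )
    per_var$clinvar_status[per_var$clinvar_status == "none"] <- NA_character_
    merge(ann, per_var, by = "variant_id", sort = FALSE)
  })
}

check_prob_vector <- function(p, name) {
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop_invalid("`%s` must be a named probability vector summing to 1",
                 name)
  }
  invisible(p)
}
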