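#' Functional consequence terms and severity ranking
#'
#' The fixed set of consequence terms treated as functional (protein- or
#' splicing-altering), and the default severity ranking used to pick the
#' most severe consequence across transcripts. Both use the classic
#' Ensembl consequence vocabulary. The ranking is a documented default
#' and can be overridden wherever it is consumed; terms absent from the
#' ranking sort last.
#'
#' @return Character vectors.
#' @export
functional_consequences <- function() {
  c("essential splice site", "stop gained", "stop lost", "complex indel",
    "frameshift coding", "non synonymous coding", "within mature miRNA",
    "partial codon")
}

#' @rdname functional_consequences
#' @export
default_severity_order <- function() {
  c("essential splice site", "stop gained", "stop lost",
    "frameshift coding", "complex indel", "non synonymous coding",
    "partial codon", "within mature miRNA", "synonymous coding")
}

severity_rank <- function(terms, severity_order) {
  r <- match(terms, severity_order)
  r[is.na(r)] <- length(severity_order) + 1L
  r
}

#' Classify a variant's functional consequence
#'
#' Determines the governing consequence of a variant and buckets it as
#' `functional`, `synonymous` or `other`. For genes on the known-gene
#' list (genes with established disease-causing variants and a curated
#' clinically relevant transcript) only the consequence on that
#' transcript governs; for all other genes the most severe consequence
#' on any transcript governs.
#'
#' @param consequences character vector of per-transcript consequence
#'   terms, named by transcript id.
#' @param known_gene is the gene on the known-gene list?
#' @param clinically_relevant_transcript transcript id to use for known
#'   genes; required (configuration error if missing or not annotated).
#' @param severity_order ranking used for "most severe"; see
#'   [default_severity_order()].
#' @return `"functional"`, `"synonymous"` or `"other"`.
#' @examples
#' classify_consequence(c(t1 = "stop gained", t2 = "intronic"),
#'                      known_gene = FALSE)
#' @export
classify_consequence <- function(consequences, known_gene = FALSE,
                                 clinically_relevant_transcript = NULL,
                                 severity_order = default_severity_order()) {
  if (length(consequences) == 0) {
    stop_invalid("variant must carry at least one transcript consequence")
  }
  if (known_gene) {
    if (is.null(clinically_relevant_transcript) ||
        !clinically_relevant_transcript %in% names(consequences)) {
      stop_invalid(paste("known-gene variant lacks a configured clinically",
                         "relevant transcript annotation"))
    }
    governing <- consequences[[clinically_relevant_transcript]]
  } else {
    governing <- consequences[which.min(severity_rank(consequences,
                                                      severity_order))]
  }
  if (governing %in% functional_consequences()) {
    "functional"
  } else if (governing == "synonymous coding") {
    "synonymous"
  } else {
    "other"
  }
}

#' Classify a variant's rarity against the reference panels
#'
#' A variant is `excluded` (too common) if its pooled minor-allele
#' frequency across the 13 internal panels exceeds 1%, if any single
#' internal panel has MAF above 10%, or if any of the 7 external panels
#' has MAF above 1%. A variant unobserved in all 20 panels is `novel`;
#' anything else is `rare`.
#'
#' @param panel_rows data.frame of this variant's rows from a
#'   [simulate_reference_panels()]-style table (columns `panel_id`,
#'   `panel_type`, `allele_count`, `allele_number`, `maf`, `observed`);
#'   all 20 configured panels must be present.
#' @param internal_pooling `"counts"` pools allele counts across the
#'   internal panels (default, matching how jointly-called cohorts are
#'   summarized); `"mean_maf"` averages the observed per-panel MAFs.
#' @param n_internal,n_external expected panel counts (configuration
#'   check).
#' @param maf_internal_pooled,maf_internal_single,maf_external the three
#'   MAF cutoffs (defaults 1%, 10%, 1%); relaxing any of them can only
#'   grow the rare set.
#' @return `"rare"`, `"novel"` or `"excluded"`.
#' @export
classify_rarity <- function(panel_rows,
                            internal_pooling = c("counts", "mean_maf"),
                            n_internal = 13L, n_external = 7L,
                            maf_internal_pooled = 0.01,
                            maf_internal_single = 0.10,
                            maf_external = 0.01) {
  internal_pooling <- match.arg(internal_pooling)
  int <- panel_rows[panel_rows$panel_type == "internal", , drop = FALSE]
  ext <- panel_rows[panel_rows$panel_type == "external", , drop = FALSE]
  if (nrow(int) != n_internal || nrow(ext) != n_external) {
    stop_invalid("expected %d internal and %d external panels, got %d/%d",
                 n_internal, n_external, nrow(int), nrow(ext))
  }
  if (!any(panel_rows$observed)) return("novel")
  pooled <- if (internal_pooling == "counts") {
    sum(int$allele_count) / sum(int$allele_number)
  } else {
    if (any(int$observed)) mean(int$maf[int$observed]) else 0
  }
  single_int <- any(int$observed & int$maf > maf_internal_single)
  any_ext <- any(ext$observed & ext$maf > maf_external)
  if (pooled > maf_internal_pooled || single_int || any_ext) {
    "excluded"
  } else {
    "rare"
  }
}

#' Deleteriousness stratum from the three in-silico predictors
#'
#' SIFT and Condel calls count as deleterious only when labelled
#' "deleterious"; PolyPhen when labelled "probably damaging" or
#' "damaging" (note "possibly damaging" does not count). Missing labels
#' (e.g. non-missense variants) count as not deleterious.
#'
#' @param sift,polyphen,condel predictor labels (or `NA`).
#' @return `"none"`, `"one_plus"` (at least one deleterious call) or
#'   `"all_three"`.
#' @examples
#' deleteriousness_stratum("deleterious", "benign", "neutral")
#' @export
deleteriousness_stratum <- function(sift, polyphen, condel) {
  del <- c(isTRUE(sift == "deleterious"),
           isTRUE(polyphen %in% c("probably damaging", "damaging")),
           isTRUE(condel == "deleterious"))
  if (all(del)) "all_three" else if (any(del)) "one_plus" else "none"
}

#' Run the full per-variant classification cascade
#'
#' Applies [classify_consequence()], [classify_rarity()] and
#' [deleteriousness_stratum()] to every variant of an annotation table.
#'
#' @param annotations data.frame as from [simulate_annotations()]: one
#'   row per (variant, transcript) with predictor and ClinVar columns.
#' @param panels reference-panel frequency table as from
#'   [simulate_reference_panels()]. Variants absent from the table are
#'   treated as unobserved in every panel (novel).
#' @param known_genes character vector of genes whose clinically relevant
#'   transcript governs the consequence.
#' @param clinically_relevant_transcripts named character vector mapping
#'   each known gene to its transcript id; defaults to each gene's first
#'   annotated transcript.
#' @param severity_order,internal_pooling passed through.
#' @return data.frame with one row per variant: `variant_id`, `gene`,
#'   `function_class`, `rarity`, `del_stratum`, `clinvar_status`.
#' @export
classify_variants <- function(annotations, panels,
                              known_genes = character(),
                              clinically_relevant_transcripts = NULL,
                              severity_order = default_severity_order(),
                              internal_pooling = "counts") {
  stopifnot(is.data.frame(annotations),
            all(c("variant_id", "gene", "transcript", "consequence") %in%
                  names(annotations)))
  vids <- unique(annotations$variant_id)
  panel_split <- split(panels, panels$variant_id)
  ann_split <- split(annotations, annotations$variant_id)

  if (is.null(clinically_relevant_transcripts) && length(known_genes)) {
    first_tx <- annotations[!duplicated(annotations$gene), ]
    clinically_relevant_transcripts <-
      setNames(first_tx$transcript, first_tx$gene)[known_genes]
  }

  rows <- lapply(vids, function(v) {
    a <- ann_split[[v]]
    gene <- a$gene[1]
    known <- gene %in% known_genes
    fc <- classify_consequence(
      setNames(a$consequence, a$transcript),
      known_gene = known,
      clinically_relevant_transcript =
        if (known) clinically_relevant_transcripts[[gene]] else NULL,
      severity_order = severity_order)
    pr <- panel_split[[v]]
    rar <- if (is.null(pr)) "novel" else
      classify_rarity(pr, internal_pooling = internal_pooling)
    data.frame(
      variant_id = v, gene = gene, function_class = fc, rarity = rar,
      del_stratum = deleteriousness_stratum(a$sift_label[1],
                                            a$polyphen_label[1],
                                            a$condel_label[1]),
      clinvar_status = a$clinvar_status[1],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The eight filtering scenarios
#'
#' Cross of rarity stratum (`rare`, `novel`) and function class
#' (`synonymous`, `functional`, `functional_1plus_del`,
#' `functional_all_del`). `novel` is its own stratum, not a subset of
#' `rare`; the synonymous scenarios serve as a negative-control stratum.
#'
#' @return data.frame with columns `rarity` and `function_class`, 8 rows.
#' @export
filter_scenarios <- function() {
  expand.grid(
    rarity = c("rare", "novel"),
    function_class = c("synonymous", "functional", "functional_1plus_del",
                       "functional_all_del"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Select the variants matching a filtering scenario
#'
#' @param classified output of [classify_variants()].
#' @param rarity `"rare"` or `"novel"`.
#' @param function_class one of `"synonymous"`, `"functional"`,
#'   `"functional_1plus_del"`, `"functional_all_del"`. The two
#'   deleteriousness-restricted classes are nested inside `functional`.
#' @return character vector of variant ids.
#' @export
select_scenario_variants <- function(classified, rarity, function_class) {
  if (!rarity %in% c("rare", "novel")) {
    stop_invalid("unknown rarity stratum `%s`", rarity)
  }
  keep <- classified$rarity == rarity
  keep <- keep & switch(
    function_class,
    synonymous = classified$function_class == "synonymous",
    functional = classified$function_class == "functional",
    functional_1plus_del = classified$function_class == "functional" &
      classified$del_stratum %in% c("one_plus", "all_three"),
    functional_all_del = classified$function_class == "functional" &
      classified$del_stratum == "all_three",
    stop_invalid("unknown function class `%s`", function_class))
  classified$variant_id[keep]
}

#' Clinical-variant triage
#'
#' Retains the variants carried forward for clinical interpretation:
#' novel functional variants, plus rare functional variants with a
#' ClinVar status of Pathogenic or Likely pathogenic. Everything else is
#' dropped.
#'
#' @param classified output of [classify_variants()].
#' @return The retained rows of `classified`, with a `triage_reason`
#'   column (`"novel_functional"` or `"rare_clinvar_pathogenic"`).
#' @export
clinvar_triage <- function(classified) {
  func <- classified$function_class == "functional"
  novel <- func & classified$rarity == "novel"
  rare_path <- func & classified$rarity == "rare" &
    !is.na(classified$clinvar_status) &
    classified$clinvar_status %in% c("Pathogenic", "Likely pathogenic")
  out <- classified[novel | rare_path, , drop = FALSE]
  out$triage_reason <- ifelse(out$rarity == "novel", "novel_functional",
                              "rare_clinvar_pathogenic")
  out
}
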