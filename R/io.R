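#' Read genotypes from a VCF file
#'
#' Reads a VCF 4.x file with GT fields into a variant table and a
#' samples x variants dosage matrix. Multi-allelic records are
#' decomposed into one bi-allelic record per alternate allele, each
#' classified and tested independently; the dosage counts copies of that
#' specific allele. Missing genotypes (`./.` or `.`) become `NA`.
#' 1-based coordinates are preserved.
#'
#' @param path VCF file (plain text or gzipped).
#' @return list with `variants` (data.frame: chrom, pos, id, ref, alt,
#'   variant_id) and `G` (samples x variants integer dosage matrix;
#'   columns named by `variant_id` = `chrom:pos:ref:alt`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_invalid("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop_invalid("no variant records in %s", path)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2 ||
      colnames(gt_raw)[1] != "FORMAT") {
    stop_invalid("VCF %s lacks genotype (GT) columns", path)
  }
  if (!all(grepl("^GT(:|$)", gt_raw[, "FORMAT"]))) {
    stop_invalid("VCF %s: GT must lead the FORMAT field", path)
  }
  sample_ids <- setdiff(colnames(gt_raw), "FORMAT")
  gt <- sub(":.*$", "", gt_raw[, sample_ids, drop = FALSE])

  out_var <- list(); out_dos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = TRUE)
    for (k in seq_along(alts)) {
      dos <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) {
          return(NA_integer_)
        }
        sum(a == as.character(k))
      }, integer(1))
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        id = fix$ID[i], ref = fix$REF[i], alt = alts[k],
        stringsAsFactors = FALSE)
      out_dos[[length(out_dos) + 1L]] <- dos
    }
  }
  variants <- do.call(rbind, out_var)
  variants$id[is.na(variants$id)] <- "."  # vcfR reads "." as NA
  variants$variant_id <- sprintf("%s:%d:%s:%s", variants$chrom,
                                 variants$pos, variants$ref, variants$alt)
  G <- do.call(cbind, out_dos)
  dimnames(G) <- list(sample_ids, variants$variant_id)
  list(variants = variants, G = G)
}

#' Write a minimal VCF 4.2 file
#'
#' Emits a deterministic, plain-text, GT-only VCF: dosage 0/1/2 becomes
#' `0/0`, `0/1`, `1/1`; `NA` becomes `./.`. The header carries no
#' timestamp, so identical inputs produce byte-identical files and a
#' read/write round trip is stable.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id`.
#' @param G samples x variants dosage matrix (rows named by sample id).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, G, path) {
  stopifnot(nrow(variants) == ncol(G))
  ids <- if ("id" %in% names(variants)) variants$id else "."
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=rvtiers",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    g <- G[, i]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(variants$chrom[i], variants$pos[i],
            if (length(ids) > 1) ids[i] else ids, variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Tab-separated table I/O
#'
#' All pipeline tables are plain UTF-8 TSV with a header row, no
#' quoting and no row names; `NA` is written literally.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns
#'   `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a pipeline configuration file
#'
#' YAML configuration with `paths` (vcf, annotations, panels, qc, ibd,
#' gene_tiers, out_dir), optional `thresholds`, `scenarios` and `seed`.
#' Missing optional keys fall back to package defaults; referenced input
#' files are checked for existence up front.
#'
#' @param path YAML file.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    thresholds = list(freemix = 0.03, depth_sd = 3, ibd = 0.1875,
                      k_sd = 6, primary = 2e-4, secondary = 3.3e-5),
    seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  required <- c("vcf", "annotations", "panels", "qc", "out_dir")
  missing <- setdiff(required, names(cfg$paths))
  if (length(missing)) {
    stop_invalid("config lacks paths: %s", paste(missing, collapse = ", "))
  }
  inputs <- unlist(cfg$paths[setdiff(names(cfg$paths), "out_dir")])
  absent <- inputs[!file.exists(inputs)]
  if (length(absent)) {
    stop_invalid("input files missing: %s", paste(absent, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}
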