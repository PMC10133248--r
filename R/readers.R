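#' Read assay measurement tables from CSV
#'
#' Thin validating readers for the documented long-format schemas.
#' Columns: foci — `explant_id, nucleus_id, condition, gH2AX_foci,
#' rad51_foci`; reporter — `explant_id, conformation, timepoint_h,
#' cell_id, gfp_positive`; comet — `explant_id, pathway, condition,
#' comet_id, tail_pct_dna`; viability — `explant_id, dose_uM, replicate,
#' count, x0`; fluorescence — `explant_id, dose_uM|dose_mM, replicate,
#' [channel,] fluorescence_au`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @name assay_readers
NULL

read_assay_csv <- function(path, cols, what) {
  if (!file.exists(path)) {
    stop_ddr(what, " file not found: ", path, class = "ddr_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, cols, what)
  df
}

#' @rdname assay_readers
#' @export
read_foci_csv <- function(path) {
  read_assay_csv(path, c("explant_id", "condition", "gH2AX_foci", "rad51_foci"), "foci")
}

#' @rdname assay_readers
#' @export
read_reporter_csv <- function(path) {
  df <- read_assay_csv(path, c("explant_id", "conformation", "timepoint_h",
                               "gfp_positive"), "reporter")
  df$gfp_positive <- as.logical(df$gfp_positive)
  df
}

#' @rdname assay_readers
#' @export
read_comet_csv <- function(path) {
  read_assay_csv(path, c("explant_id", "pathway", "condition", "tail_pct_dna"), "comet")
}

#' @rdname assay_readers
#' @export
read_viability_csv <- function(path) {
  read_assay_csv(path, c("explant_id", "dose_uM", "replicate", "count"), "viability")
}

#' @rdname assay_readers
#' @export
read_fluorescence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!any(c("dose_uM", "dose_mM") %in% names(df)) ||
      !"fluorescence_au" %in% names(df)) {
    stop_ddr("fluorescence table needs dose_uM/dose_mM and fluorescence_au columns",
             class = "ddr_schema_error")
  }
  df
}

#' Read an impact-annotated variant table
#'
#' `read_variant_tsv()` reads the simplified tab-separated schema
#' (`explant_id, gene, impact_snpeff, impact_vep, consequence`).
#' `read_variant_vcf()` reads a VCF 4.x file and extracts SnpEff impacts
#' from `ANN` and VEP impacts from `CSQ` INFO fields (the CSQ field order
#' is taken from the header); one row per annotated gene per record.
#'
#' @param path File path.
#' @param explant_id Explant identifier attached to VCF-derived rows.
#' @return Data frame in the simplified schema.
#' @export
read_variant_tsv <- function(path) {
  if (!file.exists(path)) stop_ddr("variant file not found: ", path, class = "ddr_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("gene", "impact_snpeff", "impact_vep"), "variant")
  df
}

#' @rdname read_variant_tsv
#' @export
read_variant_vcf <- function(path, explant_id = NA_character_) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_ddr("reading VCF requires the vcfR package; use read_variant_tsv() otherwise",
             class = "ddr_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ann <- vcfR::extract.info(v, "ANN")
  csq <- vcfR::extract.info(v, "CSQ")
  # CSQ sub-field order from the header description
  meta <- v@meta
  csq_line <- grep("ID=CSQ", meta, value = TRUE)
  csq_fields <- if (length(csq_line)) {
    fmt <- sub('.*Format: *([^">]+).*', "\\1", csq_line[1])
    strsplit(fmt, "\\|")[[1]]
  } else c("Allele", "Consequence", "IMPACT", "SYMBOL")
  rows <- list()
  for (i in seq_along(ann)) {
    snp_map <- list(); gene_cons <- list()
    if (!is.na(ann[i])) {
      for (entry in strsplit(ann[i], ",")[[1]]) {
        f <- strsplit(entry, "\\|")[[1]]
        if (length(f) >= 4) {
          snp_map[[f[4]]] <- f[3]
          gene_cons[[f[4]]] <- f[2]
        }
      }
    }
    vep_map <- list()
    if (!is.na(csq[i])) {
      for (entry in strsplit(csq[i], ",")[[1]]) {
        f <- strsplit(entry, "\\|")[[1]]
        gene <- f[match("SYMBOL", csq_fields)]
        imp <- f[match("IMPACT", csq_fields)]
        if (!is.na(gene) && nzchar(gene)) vep_map[[gene]] <- imp
      }
    }
    for (g in union(names(snp_map), names(vep_map))) {
      rows[[length(rows) + 1]] <- data.frame(
        explant_id = explant_id, gene = g,
        impact_snpeff = snp_map[[g]] %||% "MODIFIER",
        impact_vep = vep_map[[g]] %||% "MODIFIER",
        consequence = gene_cons[[g]] %||% NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(explant_id = character(0), gene = character(0),
                      impact_snpeff = character(0), impact_vep = character(0),
                      consequence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
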