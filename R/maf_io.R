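#' Parse an amino-acid position from an HGVS short protein change
#'
#' Extracts the first integer amino-acid position from an `HGVSp_Short`
#' string.  Missense changes (`p.L858R`) yield the substituted position,
#' multi-residue events (`p.E746_A750del`) their start position,
#' frameshifts (`p.G96Wfs*12`) the first altered residue, and synonymous
#' changes (`p.L123=`) the conserved position.  Strings carrying no
#' positional digits (e.g. `p.=`) yield `NA`.
#'
#' @param hgvsp character vector of HGVS short protein-change strings.
#' @return integer vector of amino-acid positions (`NA` where no
#'   position is encoded).  Never 0 or negative.
#' @examples
#' parse_hgvsp(c("p.L858R", "p.E746_A750del", "p.G96Wfs*12", "p.L123=", "p.="))
#' @export
parse_hgvsp <- function(hgvsp) {
  hgvsp <- as.character(hgvsp)
  m <- regmatches(hgvsp, regexpr("[0-9]+", hgvsp))
  out <- rep(NA_integer_, length(hgvsp))
  has <- regexpr("[0-9]+", hgvsp) > 0L
  pos <- suppressWarnings(as.integer(m))
  out[has] <- pos
  out[!is.na(out) & out < 1L] <- NA_integer_
  out
}

#' Derive the patient identifier from a tumor sample barcode
#'
#' TCGA-style barcodes identify the patient by their first 12
#' characters (`TCGA-XX-YYYY`); longer barcodes append sample/portion
#' fields.  Identifiers shorter than 12 characters are returned
#' unchanged, so the function is idempotent.
#'
#' @param sample_id character vector of sample barcodes (non-empty).
#' @return character vector of patient identifiers.
#' @examples
#' patient_of_sample("TCGA-AB-1234-01A-11D-A123-09")
#' @export
patient_of_sample <- function(sample_id) {
  sample_id <- as.character(sample_id)
  if (any(is.na(sample_id) | !nzchar(sample_id)))
    stop("empty sample barcode")
  ifelse(nchar(sample_id) >= 12L, substr(sample_id, 1L, 12L), sample_id)
}

# sample-type code from a TCGA-style barcode ("01" primary, "06" metastatic);
# NA when the barcode carries no type field
sample_type_code <- function(sample_id) {
  ifelse(nchar(sample_id) >= 15L, substr(sample_id, 14L, 15L), NA_character_)
}

.maf_default_cols <- c(
  sample_id              = "Tumor_Sample_Barcode",
  gene                   = "Hugo_Symbol",
  transcript_id          = "Transcript_ID",
  hgvsp_short            = "HGVSp_Short",
  variant_type           = "Variant_Type",
  variant_classification = "Variant_Classification"
)

.variant_types <- c("SNP", "DNP", "TNP", "INS", "DEL")

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-separated mutation annotation file (lines starting with
#' `#` are comments), keeps only rows annotated with a non-empty
#' `HGVSp_Short` protein change, and normalizes them to one row per
#' retained mutation call.  Silent (synonymous) mutations are retained:
#' they mark the same recurrent positions and may be functional.
#' Samples can be restricted by TCGA sample-type code (the 14th-15th
#' barcode characters); barcodes without a type field are kept.
#'
#' @param path path to a tab-separated MAF-dialect file.
#' @param sample_type_whitelist character vector of 2-character sample
#'   type codes to keep (default `"01"`, primary tumor; include `"06"`
#'   for metastatic cohorts such as melanoma).  `NULL` keeps all
#'   samples.
#' @param col_map named character vector mapping the internal field
#'   names `sample_id`, `gene`, `transcript_id`, `hgvsp_short`,
#'   `variant_type`, `variant_classification` to the column names used
#'   in the file.  Defaults to GDC MAF column names.
#' @param quiet suppress messages about dropped rows.
#' @return a `data.frame` of mutation records with columns `sample_id`,
#'   `patient_id`, `gene`, `transcript_id`, `hgvsp_short`,
#'   `variant_type` (one of SNP, DNP, TNP, INS, DEL, other),
#'   `variant_classification` and `aa_position` (integer, `NA` when the
#'   protein change encodes no position).
#' @seealso [parse_hgvsp()], [read_clinical()]
#' @export
read_maf <- function(path, sample_type_whitelist = "01",
                     col_map = NULL, quiet = FALSE) {
  raw <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  maf_records(raw, sample_type_whitelist = sample_type_whitelist,
              col_map = col_map, quiet = quiet, origin = path)
}

#' Normalize an in-memory MAF-style table to mutation records
#'
#' The normalization step of [read_maf()] exposed for tables already in
#' memory (e.g. from [generate_cohort()]): same retained-row rules,
#' sample-type filtering and position parsing.
#'
#' @param raw `data.frame` with MAF-dialect columns.
#' @inheritParams read_maf
#' @param origin label used in error messages.
#' @return see [read_maf()].
#' @export
maf_records <- function(raw, sample_type_whitelist = "01",
                        col_map = NULL, quiet = FALSE, origin = "input") {
  cols <- .maf_default_cols
  if (!is.null(col_map)) cols[names(col_map)] <- col_map
  required <- setdiff(names(cols), "variant_classification")
  for (f in required) {
    if (!cols[[f]] %in% names(raw))
      stop("required column '", cols[[f]], "' (", f, ") not found in ",
           origin)
  }
  n0 <- nrow(raw)
  out <- data.frame(
    sample_id     = raw[[cols[["sample_id"]]]],
    gene          = raw[[cols[["gene"]]]],
    transcript_id = raw[[cols[["transcript_id"]]]],
    hgvsp_short   = raw[[cols[["hgvsp_short"]]]],
    variant_type  = toupper(raw[[cols[["variant_type"]]]]),
    variant_classification =
      if (cols[["variant_classification"]] %in% names(raw))
        raw[[cols[["variant_classification"]]]] else NA_character_,
    stringsAsFactors = FALSE
  )
  # only calls annotated with a protein change are usable for pooling
  keep <- !is.na(out$hgvsp_short) & out$hgvsp_short != "" &
    out$hgvsp_short != "."
  if (!quiet && sum(!keep) > 0)
    message("read_maf: dropped ", sum(!keep), " of ", n0,
            " rows without HGVSp_Short")
  out <- out[keep, , drop = FALSE]
  if (!is.null(sample_type_whitelist) && nrow(out) > 0) {
    tc <- sample_type_code(out$sample_id)
    keep <- is.na(tc) | tc %in% sample_type_whitelist
    if (!quiet && sum(!keep) > 0)
      message("read_maf: dropped ", sum(!keep),
              " rows from samples outside types {",
              paste(sample_type_whitelist, collapse = ","), "}")
    out <- out[keep, , drop = FALSE]
  }
  out$variant_type[!out$variant_type %in% .variant_types] <- "other"
  out$patient_id <- if (nrow(out)) patient_of_sample(out$sample_id)
                    else character(0)
  out$aa_position <- parse_hgvsp(out$hgvsp_short)
  rownames(out) <- NULL
  out[, c("sample_id", "patient_id", "gene", "transcript_id",
          "hgvsp_short", "variant_type", "variant_classification",
          "aa_position")]
}

.clin_patient_cols <- c("bcr_patient_barcode", "case_submitter_id",
                        "patient_id", "case_id")
.clin_death_cols <- c("days_to_death", "death_days_to")
.clin_fu_cols <- c("days_to_last_follow_up", "days_to_last_followup",
                   "last_contact_days_to")
.dead_strings <- c("dead", "deceased")
.alive_strings <- c("alive", "living")

#' Read a clinical table into overall-survival records
#'
#' Builds one overall-survival observation per patient from a clinical
#' TSV: patients whose vital status indicates death contribute
#' `days_to_death` with an observed event, all others contribute
#' `days_to_last_follow_up` as a censored time.  Vital-status strings
#' that indicate neither are treated as censored (and counted in a
#' message, not dropped silently).  Patients with missing or negative
#' time are dropped; when a patient appears several times the first
#' usable row wins.
#'
#' @param path path to a tab-separated clinical file.
#' @param col_map optional named character vector overriding the column
#'   names for fields `patient_id`, `vital_status`, `days_to_death`,
#'   `days_to_last_follow_up`.
#' @param quiet suppress messages about dropped/unknown rows.
#' @return a `data.frame` with columns `patient_id`, `time_days`
#'   (non-negative) and `event` (logical, `TRUE` = death observed), one
#'   row per patient.
#' @export
read_clinical <- function(path, col_map = NULL, quiet = FALSE) {
  raw <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  pick <- function(field, candidates) {
    if (!is.null(col_map) && field %in% names(col_map)) {
      if (!col_map[[field]] %in% names(raw))
        stop("required column '", col_map[[field]], "' (", field,
             ") not found in ", path)
      return(col_map[[field]])
    }
    hit <- candidates[candidates %in% names(raw)]
    if (!length(hit))
      stop("required column for '", field, "' not found in ", path,
           " (looked for: ", paste(candidates, collapse = ", "), ")")
    hit[[1]]
  }
  pcol <- pick("patient_id", .clin_patient_cols)
  vcol <- pick("vital_status", "vital_status")
  dcol <- pick("days_to_death", .clin_death_cols)
  fcol <- pick("days_to_last_follow_up", .clin_fu_cols)

  num <- function(x) suppressWarnings(as.numeric(x))
  status <- tolower(trimws(raw[[vcol]]))
  dead <- status %in% .dead_strings
  unknown <- !dead & !status %in% .alive_strings
  if (!quiet && any(unknown))
    message("read_clinical: ", sum(unknown),
            " rows with unrecognized vital status treated as censored")
  time <- ifelse(dead, num(raw[[dcol]]), num(raw[[fcol]]))
  rec <- data.frame(patient_id = raw[[pcol]], time_days = time,
                    event = dead, stringsAsFactors = FALSE)
  usable <- !is.na(rec$patient_id) & nzchar(rec$patient_id) &
    !is.na(rec$time_days) & rec$time_days >= 0
  if (!quiet && sum(!usable) > 0)
    message("read_clinical: dropped ", sum(!usable),
            " rows with missing or negative survival time")
  rec <- rec[usable, , drop = FALSE]
  rec <- rec[!duplicated(rec$patient_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# shared TSV writer: deterministic, tab-separated, no quoting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
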