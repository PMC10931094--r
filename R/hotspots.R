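#' Pool mutations by transcript and amino-acid position
#'
#' Groups parsed mutation records by `(gene, transcript_id,
#' aa_position)` and collects, for each position, the set of *patients
#' with clinical data* carrying any mutation there.  A patient counts
#' once per position no matter how many samples or calls support the
#' mutation; patients without a survival record are excluded because
#' they cannot enter any comparison.
#'
#' @param mutations mutation `data.frame` as returned by [read_maf()];
#'   rows without a parsed `aa_position` are ignored.
#' @param clinical survival `data.frame` as returned by
#'   [read_clinical()].
#' @return a `data.frame` with columns `gene`, `transcript_id`,
#'   `aa_position`, `n_carriers` and a list-column `carriers` (sorted
#'   patient identifiers), one row per mutated position, sorted by
#'   `(gene, transcript_id, aa_position)`.
#' @seealso [call_hotspots()]
#' @export
pool_positions <- function(mutations, clinical) {
  m <- mutations[!is.na(mutations$aa_position) &
                   mutations$patient_id %in% clinical$patient_id, ,
                 drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(gene = character(0), transcript_id = character(0),
                      aa_position = integer(0), n_carriers = integer(0),
                      carriers = I(list())))
  }
  key <- paste(m$gene, m$transcript_id, m$aa_position, sep = "\r")
  carriers <- lapply(split(m$patient_id, key), function(p) sort(unique(p)))
  parts <- strsplit(names(carriers), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[[`, "", 1L),
    transcript_id = vapply(parts, `[[`, "", 2L),
    aa_position = as.integer(vapply(parts, `[[`, "", 3L)),
    n_carriers = vapply(carriers, length, 0L),
    stringsAsFactors = FALSE
  )
  out$carriers <- I(unname(carriers))
  ord <- order(out$gene, out$transcript_id, out$aa_position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call hotspots at a minimum-recurrence threshold
#'
#' A hotspot is an amino-acid position carried by at least
#' `min_patients` patients with clinical data (default 4) within one
#' cancer type.
#'
#' @param pooled output of [pool_positions()].
#' @param min_patients minimum carrier count (>= 2).
#' @return the subset of `pooled` with `n_carriers >= min_patients`,
#'   sorted by `(gene, aa_position)`.
#' @export
call_hotspots <- function(pooled, min_patients = 4) {
  stopifnot(min_patients >= 2)
  out <- pooled[pooled$n_carriers >= min_patients, , drop = FALSE]
  ord <- order(out$gene, out$aa_position, out$transcript_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patients with any retained mutation in a gene
#'
#' The gene-level comparison universe: every patient with at least one
#' retained mutation record in the gene, at any position (hotspot or
#' not, parseable position or not).
#'
#' @param mutations mutation `data.frame` as returned by [read_maf()].
#' @param gene gene symbol.
#' @return sorted character vector of patient identifiers.
#' @export
gene_mutated_patients <- function(mutations, gene) {
  sort(unique(mutations$patient_id[mutations$gene == gene]))
}

#' Export called hotspots as a flat table
#'
#' @param hotspots output of [call_hotspots()] (or [pool_positions()]).
#' @param cancer_type optional cohort label recycled into a column.
#' @param path optional file path; when given the table is written as
#'   TSV (carrier sets comma-joined) and the path returned invisibly.
#' @return the flat `data.frame` (or, with `path`, invisibly the path).
#' @export
hotspot_table <- function(hotspots, cancer_type = NA_character_,
                          path = NULL) {
  flat <- data.frame(
    cancer_type = rep(cancer_type, nrow(hotspots)),
    gene = hotspots$gene,
    transcript_id = hotspots$transcript_id,
    aa_position = hotspots$aa_position,
    n_carriers = hotspots$n_carriers,
    carriers = vapply(hotspots$carriers, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write_tsv(flat, path)
    return(invisible(path))
  }
  flat
}
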