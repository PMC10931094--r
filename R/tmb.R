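#' Per-sample tumor mutation burden
#'
#' Tumor mutation burden (TMB) is the total count of single-nucleotide
#' variants (`variant_type == "SNP"`) per tumor sample.  Samples that
#' appear in the cohort only with non-SNV calls get a count of 0, so
#' the profile covers every sample in the input.
#'
#' @param mutations mutation `data.frame` as returned by [read_maf()].
#' @param scale_mad logical; if `TRUE` the median absolute deviation is
#'   multiplied by the usual 1.4826 normal-consistency constant.  The
#'   default (`FALSE`) is the plain median of absolute deviations used
#'   by the hypermutation rule.
#' @return an object of class `tmb_profile`: a list with `counts`
#'   (named integer vector, one entry per sample), `median`, `mad`,
#'   `q90` (nearest-rank 90th percentile) and `scale_mad`.
#' @seealso [flag_hypermutated()], [remove_hypermutated()]
#' @export
compute_tmb <- function(mutations, scale_mad = FALSE) {
  if (is.null(mutations) || nrow(mutations) == 0)
    stop("compute_tmb: empty cohort")
  samples <- unique(mutations$sample_id)
  snv <- table(factor(mutations$sample_id[mutations$variant_type == "SNP"],
                      levels = samples))
  counts <- as.integer(snv)
  names(counts) <- samples
  med <- stats::median(counts)
  mad_raw <- stats::median(abs(counts - med))
  structure(list(
    counts = counts,
    median = med,
    mad = if (scale_mad) 1.4826 * mad_raw else mad_raw,
    q90 = as.numeric(stats::quantile(counts, 0.9, type = 1, names = FALSE)),
    scale_mad = scale_mad
  ), class = "tmb_profile")
}

#' @export
print.tmb_profile <- function(x, ...) {
  cat("TMB profile:", length(x$counts), "samples\n")
  cat(sprintf("  median %.1f, MAD %.1f%s, 90th percentile %.1f\n",
              x$median, x$mad,
              if (x$scale_mad) " (scaled)" else "", x$q90))
  cat(sprintf("  range [%d, %d]\n", min(x$counts), max(x$counts)))
  invisible(x)
}

#' Flag hypermutated samples
#'
#' A sample is flagged as hypermutated if it satisfies either rule:
#' * Rule A: TMB exceeds `tmb_cutoff` (default 500 mutations) *and*
#'   ranks within the top 10% of the cohort (TMB at or above the
#'   nearest-rank 90th percentile);
#' * Rule B: TMB exceeds the cohort median plus `mad_multiplier`
#'   (default 4) times the median absolute deviation.
#'
#' Such samples inflate positional recurrence by chance and bias
#' hotspot-survival screens, so they are typically excluded before
#' hotspot calling.
#'
#' @param profile a `tmb_profile` from [compute_tmb()] (at least 2
#'   samples).
#' @param tmb_cutoff absolute TMB threshold of Rule A.
#' @param mad_multiplier MAD multiplier of Rule B.
#' @return character vector of flagged sample identifiers (sorted).
#' @export
flag_hypermutated <- function(profile, tmb_cutoff = 500, mad_multiplier = 4) {
  stopifnot(inherits(profile, "tmb_profile"))
  if (length(profile$counts) < 2)
    stop("flag_hypermutated: need at least 2 samples")
  tab <- tmb_table(profile, tmb_cutoff, mad_multiplier)
  sort(tab$sample_id[tab$flagged])
}

#' Per-sample TMB and hypermutation flags as a table
#'
#' @inheritParams flag_hypermutated
#' @return `data.frame` with columns `sample_id`, `tmb`, `rule_a`
#'   (high absolute TMB in the top decile), `rule_b` (TMB above
#'   median + 4 MAD) and `flagged` (either rule).
#' @export
tmb_table <- function(profile, tmb_cutoff = 500, mad_multiplier = 4) {
  stopifnot(inherits(profile, "tmb_profile"))
  counts <- profile$counts
  rule_a <- counts > tmb_cutoff & counts >= profile$q90
  rule_b <- counts > profile$median + mad_multiplier * profile$mad
  data.frame(sample_id = names(counts), tmb = as.integer(counts),
             rule_a = unname(rule_a), rule_b = unname(rule_b),
             flagged = unname(rule_a | rule_b),
             stringsAsFactors = FALSE)
}

#' Drop mutation records from hypermutated samples
#'
#' @param mutations mutation `data.frame` as returned by [read_maf()].
#' @param flagged character vector of sample identifiers to remove
#'   (e.g. from [flag_hypermutated()]).
#' @return the mutation records whose `sample_id` is not flagged.
#' @export
remove_hypermutated <- function(mutations, flagged) {
  out <- mutations[!mutations$sample_id %in% flagged, , drop = FALSE]
  rownames(out) <- NULL
  out
}
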