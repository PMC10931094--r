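# Independent oracles used to validate the statistical core.  These
# deliberately avoid the package's additive-score shortcut: the signed
# log-rank statistic is recomputed from the two-group definition at
# every event time, and the null distribution by direct iteration over
# all subsets.

naive_logrank_L <- function(time, event, group) {
  L <- 0
  for (t in sort(unique(time[event]))) {
    d <- sum(event & time == t)
    r <- sum(time >= t)
    o1 <- sum(group & event & time == t)
    r1 <- sum(group & time >= t)
    L <- L + o1 - d * r1 / r
  }
  L
}

# brute-force conditional null: every assignment of n1 patients to the
# carrier group, statistic recomputed naively per subset
brute_null <- function(time, event, n1) {
  n <- length(time)
  cmb <- utils::combn(n, n1)
  L <- apply(cmb, 2, function(idx)
    naive_logrank_L(time, event, seq_len(n) %in% idx))
  k <- apply(cmb, 2, function(idx) sum(event[idx]))
  structure(list(
    support = L, weights = rep(1 / ncol(cmb), ncol(cmb)),
    stratum = as.integer(k), mode = "exact-enumeration",
    n = n, n1 = as.integer(n1), d = as.integer(sum(event)),
    n_subsets = ncol(cmb), n_perm_per_stratum = NA_integer_, seed = NULL
  ), class = "logrank_null")
}

# two-sided tail rule applied to a brute-force distribution
oracle_two_sided_p <- function(support, weights, L_obs) {
  tol <- 1e-8 * max(1, max(abs(support)))
  lo <- sum(weights[support <= L_obs + tol])
  hi <- sum(weights[support >= L_obs - tol])
  min(1, 2 * min(lo, hi))
}

# a small random survival instance with mixed censoring
rand_instance <- function(n, cens_prob = 0.3, rate = 1 / 1000) {
  list(time = stats::rexp(n, rate), event = stats::runif(n) > cens_prob)
}

# minimal normalized mutation-record table
make_mutations <- function(sample_id, gene, position,
                           variant_type = "SNP",
                           transcript_id = "ENST00000001",
                           classification = "Missense_Mutation") {
  hg <- ifelse(is.na(position), "p.=", sprintf("p.L%dR", position))
  data.frame(sample_id = sample_id,
             patient_id = patient_of_sample(sample_id),
             gene = gene, transcript_id = transcript_id,
             hgvsp_short = hg, variant_type = variant_type,
             variant_classification = classification,
             aa_position = as.integer(position),
             stringsAsFactors = FALSE)
}

make_clinical <- function(patient_id, time_days = NULL, event = NULL) {
  n <- length(patient_id)
  data.frame(patient_id = patient_id,
             time_days = if (is.null(time_days)) 100 + 10 * seq_len(n)
                         else time_days,
             event = if (is.null(event)) rep(c(TRUE, FALSE),
                                             length.out = n) else event,
             stringsAsFactors = FALSE)
}

# write a MAF-dialect TSV (with comment lines) and return its path
write_maf_fixture <- function(rows, path = tempfile(fileext = ".maf")) {
  hdr <- paste(c("Hugo_Symbol", "Transcript_ID", "HGVSp_Short",
                 "Variant_Type", "Variant_Classification",
                 "Tumor_Sample_Barcode"), collapse = "\t")
  writeLines(c("#filedate fixture", "#annotation.spec test", hdr,
               rows), path)
  path
}

maf_row <- function(gene = "GENE1", tx = "ENST00000001", hgvsp = "p.L100R",
                    vt = "SNP", vc = "Missense_Mutation",
                    barcode = "TCGA-AA-0001-01A") {
  paste(gene, tx, hgvsp, vt, vc, barcode, sep = "\t")
}
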