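#' Specification of a synthetic cancer cohort
#'
#' Describes a cohort with known ground truth: exponential overall
#' survival with independent exponential plus administrative censoring,
#' a configurable fraction of hypermutated samples, per-gene background
#' mutation rates and planted recurrent amino-acid positions whose
#' carriers experience a chosen hazard ratio.  The exponential model
#' satisfies proportional hazards exactly, so Cox estimates have a
#' known truth.
#'
#' Defaults describe a mid-sized cohort: 400 patients, baseline hazard
#' 1/1500 per day (median survival around 1040 days), light random
#' censoring (rate 1/4000 per day) plus a 10-year administrative
#' cutoff, 5% hypermutated samples at a mean of 1000 SNVs against a
#' background of 50, three genes with background mutation
#' probabilities 0.15/0.10/0.08, and three planted hotspots: a
#' deleterious one (20 carriers, HR 2.5), a null one (8 carriers,
#' HR 1) and a protective one (12 carriers, HR 0.5).
#'
#' @param n_patients cohort size.
#' @param baseline_hazard event rate per day for non-carriers.
#' @param censoring_rate rate per day of the independent exponential
#'   censoring process.
#' @param admin_censor_days administrative censoring horizon (days).
#' @param genes `data.frame` with columns `name`, `mut_prob`
#'   (per-patient probability of a background mutation in the gene)
#'   and `n_positions` (protein length in amino acids).
#' @param planted `data.frame` with columns `gene`, `position`,
#'   `n_carriers`, `hazard_ratio`; positions must be distinct within a
#'   gene and carrier counts cannot exceed the cohort size.
#' @param hyper_fraction fraction of hypermutated samples.
#' @param hyper_tmb,background_tmb mean SNV counts of hypermutated and
#'   background samples.
#' @param cancer_type cohort label.
#' @param seed integer seed; generation is fully reproducible.
#' @return a list of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 400,
                        baseline_hazard = 1 / 1500,
                        censoring_rate = 1 / 4000,
                        admin_censor_days = 3650,
                        genes = data.frame(
                          name = c("GENE1", "GENE2", "GENE3"),
                          mut_prob = c(0.15, 0.10, 0.08),
                          n_positions = c(400L, 600L, 300L)),
                        planted = data.frame(
                          gene = c("GENE1", "GENE1", "GENE2"),
                          position = c(100L, 250L, 50L),
                          n_carriers = c(20L, 8L, 12L),
                          hazard_ratio = c(2.5, 1, 0.5)),
                        hyper_fraction = 0.05,
                        hyper_tmb = 1000,
                        background_tmb = 50,
                        cancer_type = "SYNTH",
                        seed = 1L) {
  stopifnot(n_patients >= 2, baseline_hazard > 0, censoring_rate > 0,
            admin_censor_days > 0, hyper_fraction >= 0, hyper_fraction < 1,
            hyper_tmb > 0, background_tmb > 0)
  if (nrow(planted)) {
    stopifnot(all(planted$hazard_ratio > 0))
    if (any(planted$n_carriers > n_patients))
      stop("infeasible spec: more carriers than patients")
    dup <- duplicated(planted[, c("gene", "position")])
    if (any(dup)) stop("planted positions must be distinct within a gene")
    if (!all(planted$gene %in% genes$name))
      stop("planted hotspots must lie in declared genes")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    admin_censor_days = admin_censor_days,
    genes = genes, planted = planted,
    hyper_fraction = hyper_fraction,
    hyper_tmb = hyper_tmb, background_tmb = background_tmb,
    cancer_type = cancer_type, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# HGVSp grammar of the generator: the four shapes the parser must
# handle in real MAFs
.aa3 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
synth_hgvsp <- function(position, kind) {
  a1 <- sample(.aa3, length(position), replace = TRUE)
  a2 <- sample(.aa3, length(position), replace = TRUE)
  out <- character(length(position))
  mis <- kind == "missense"
  out[mis] <- sprintf("p.%s%d%s", a1[mis], position[mis], a2[mis])
  sil <- kind == "silent"
  out[sil] <- sprintf("p.%s%d=", a1[sil], position[sil])
  fs <- kind == "frameshift"
  out[fs] <- sprintf("p.%s%dWfs*%d", a1[fs], position[fs],
                     sample(2:30, sum(fs), replace = TRUE))
  rd <- kind == "range_del"
  out[rd] <- sprintf("p.%s%d_%s%ddel", a1[rd], position[rd], a2[rd],
                     position[rd] + sample(1:5, sum(rd), replace = TRUE))
  out
}

.kind_levels <- c("missense", "silent", "frameshift", "range_del")
.kind_probs <- c(0.70, 0.15, 0.10, 0.05)
.kind_vt <- c(missense = "SNP", silent = "SNP",
              frameshift = "DEL", range_del = "DEL")
.kind_vc <- c(missense = "Missense_Mutation", silent = "Silent",
              frameshift = "Frame_Shift_Del", range_del = "In_Frame_Del")

#' Generate a synthetic cohort with known ground truth
#'
#' Emits a MAF-style mutation table and a clinical table in exactly the
#' dialect that [read_maf()] and [read_clinical()] consume, together
#' with a truth record listing the planted carriers, hazard ratios and
#' hypermutated samples.  Survival times are exponential with rate
#' `baseline_hazard` times the product of the hazard ratios of the
#' hotspots a patient carries; censoring is the minimum of an
#' independent exponential and the administrative horizon.  Planted
#' carriers are drawn without replacement among the non-hypermutated
#' patients, so that hypermutation filtering leaves the planted truth
#' intact.  Per-sample SNV counts are Poisson with mean
#' `background_tmb` (or `hyper_tmb`), realized as filler records on a
#' synthetic background gene set; per-gene background mutations are
#' Bernoulli per patient at the declared probabilities, at uniform
#' random positions.  Protein-change strings cover the grammar shapes
#' the parser supports (missense, synonymous, frameshift, in-frame
#' deletion).
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `mutations` (data.frame in MAF layout,
#'   see [read_maf()] for the normalized form), `clinical` (patient_id,
#'   time_days, event), `truth` (planted carriers per hotspot, hazard
#'   ratios, hypermutated sample ids) and `cancer_type`.  Identifiers
#'   are synthetic TCGA-style barcodes.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  patients <- sprintf("TCGA-SY-%04d", seq_len(n))
  samples <- paste0(patients, "-01A")

  n_hyper <- round(spec$hyper_fraction * n)
  hyper <- if (n_hyper > 0) sort(sample.int(n, n_hyper)) else integer(0)
  normal <- setdiff(seq_len(n), hyper)

  planted <- spec$planted
  carriers <- vector("list", nrow(planted))
  hr <- rep(1, n)
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      if (planted$n_carriers[i] > length(normal))
        stop("infeasible spec: more carriers than non-hypermutated patients")
      idx <- sort(sample(normal, planted$n_carriers[i]))
      carriers[[i]] <- patients[idx]
      hr[idx] <- hr[idx] * planted$hazard_ratio[i]
    }
    names(carriers) <- paste0(planted$gene, "-", planted$position)
  }

  t_event <- stats::rexp(n, rate = spec$baseline_hazard * hr)
  t_cens <- pmin(stats::rexp(n, rate = spec$censoring_rate),
                 spec$admin_censor_days)
  clinical <- data.frame(
    patient_id = patients,
    time_days = round(pmin(t_event, t_cens), 1),
    event = t_event <= t_cens,
    stringsAsFactors = FALSE
  )

  rows <- list()
  add <- function(pat_idx, gene, transcript, position, kind) {
    if (!length(pat_idx)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      Tumor_Sample_Barcode = samples[pat_idx],
      Hugo_Symbol = gene,
      Transcript_ID = transcript,
      HGVSp_Short = synth_hgvsp(position, kind),
      Variant_Type = unname(.kind_vt[kind]),
      Variant_Classification = unname(.kind_vc[kind]),
      stringsAsFactors = FALSE
    )
  }
  tx_of <- function(g) sprintf("ENST%08d", match(g, spec$genes$name))

  # planted hotspot calls
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      idx <- match(carriers[[i]], patients)
      kind <- sample(.kind_levels, length(idx), replace = TRUE,
                     prob = .kind_probs)
      add(idx, planted$gene[i], tx_of(planted$gene[i]),
          rep(planted$position[i], length(idx)), kind)
    }
  }
  # per-gene background mutations
  for (g in seq_len(nrow(spec$genes))) {
    idx <- which(stats::runif(n) < spec$genes$mut_prob[g])
    if (!length(idx)) next
    pos <- sample.int(spec$genes$n_positions[g], length(idx),
                      replace = TRUE)
    kind <- sample(.kind_levels, length(idx), replace = TRUE,
                   prob = .kind_probs)
    add(idx, spec$genes$name[g], tx_of(spec$genes$name[g]), pos, kind)
  }
  # TMB filler: per-sample SNV counts scattered over a wide synthetic
  # background gene set so positional recurrence stays negligible
  mu <- ifelse(seq_len(n) %in% hyper, spec$hyper_tmb, spec$background_tmb)
  tmb_n <- stats::rpois(n, mu)
  tot <- sum(tmb_n)
  if (tot > 0) {
    pat_idx <- rep.int(seq_len(n), tmb_n)
    bg_gene <- sprintf("BG%04d", sample.int(500, tot, replace = TRUE))
    pos <- sample.int(5000, tot, replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      Tumor_Sample_Barcode = samples[pat_idx],
      Hugo_Symbol = bg_gene,
      Transcript_ID = paste0("ENSTBG", substr(bg_gene, 3, 6)),
      HGVSp_Short = synth_hgvsp(pos, rep("missense", tot)),
      Variant_Type = "SNP",
      Variant_Classification = "Missense_Mutation",
      stringsAsFactors = FALSE
    )
  }
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL

  list(
    mutations = mutations,
    clinical = clinical,
    truth = list(
      carriers = carriers,
      hazard_ratios = if (nrow(planted))
        stats::setNames(planted$hazard_ratio, names(carriers))
        else stats::setNames(numeric(0), character(0)),
      hypermutated = samples[hyper],
      spec = spec
    ),
    cancer_type = spec$cancer_type
  )
}

#' Generate a null cohort (all hazard ratios forced to 1)
#'
#' Identical to [generate_cohort()] except that every planted hotspot
#' gets hazard ratio 1, so carriers and non-carriers share the same
#' survival law.  Used for type-I-error simulations.
#'
#' @param spec a [cohort_spec()].
#' @return see [generate_cohort()].
#' @export
generate_null_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(spec$planted)) spec$planted$hazard_ratio <- 1
  generate_cohort(spec)
}

#' Deterministic 54-patient documentation cohort
#'
#' A fixed toy cohort used in the documentation walkthrough: one gene,
#' 54 patients of whom 34 carry a mutation in the gene, with four
#' recurrent amino-acid positions (carrier counts 6, 5, 4 and 3 at
#' positions 100, 200, 300 and 400) and 16 patients mutated at
#' singleton positions.  At the toy recurrence threshold of 3 carriers
#' this gives exactly 4 hotspots.  Survival times and events follow a
#' fixed deterministic pattern; every patient has clinical data.
#'
#' @return a list with `mutations`, `clinical`, `truth` and
#'   `cancer_type` in the same layout as [generate_cohort()].
#' @export
figure1_toy <- function() {
  patients <- sprintf("TCGA-SY-%04d", 1:54)
  samples <- paste0(patients, "-01A")
  hs_pos <- c(100L, 200L, 300L, 400L)
  hs_n <- c(6L, 5L, 4L, 3L)
  carrier_idx <- split(seq_len(sum(hs_n)),
                       rep(seq_along(hs_pos), hs_n))
  single_idx <- sum(hs_n) + seq_len(16)          # patients 19..34
  pos <- c(rep(hs_pos, hs_n), 10L + seq_len(16))
  idx <- c(unlist(carrier_idx), single_idx)
  aa <- rep(c("L", "R", "G", "E"), length.out = length(idx))
  mutations <- data.frame(
    Tumor_Sample_Barcode = samples[idx],
    Hugo_Symbol = "GENE1",
    Transcript_ID = "ENST00000001",
    HGVSp_Short = sprintf("p.%s%dK", aa, pos),
    Variant_Type = "SNP",
    Variant_Classification = "Missense_Mutation",
    stringsAsFactors = FALSE
  )
  clinical <- data.frame(
    patient_id = patients,
    time_days = 120 + 37 * (seq_len(54) %% 18) + 11 * (seq_len(54) %% 7),
    event = (seq_len(54) %% 3) != 0,
    stringsAsFactors = FALSE
  )
  list(
    mutations = mutations,
    clinical = clinical,
    truth = list(
      carriers = stats::setNames(
        lapply(carrier_idx, function(i) patients[i]),
        paste0("GENE1-", hs_pos)),
      hazard_ratios = stats::setNames(rep(1, 4), paste0("GENE1-", hs_pos)),
      hypermutated = character(0)
    ),
    cancer_type = "TOY"
  )
}
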