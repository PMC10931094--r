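#' Bundle a cohort's mutation and clinical tables
#'
#' Light container for one cancer type's data.  Mutation tables in raw
#' MAF column layout (e.g. from [generate_cohort()]) are normalized via
#' [maf_records()]; tables already normalized by [read_maf()] are used
#' as is.
#'
#' @param mutations mutation table (raw MAF layout or normalized
#'   records).
#' @param clinical survival records as from [read_clinical()].
#' @param cancer_type cohort label.
#' @param ... passed to [maf_records()] when normalization is needed.
#' @return a list of class `spot_cohort` with elements `mutations`,
#'   `clinical`, `cancer_type`.
#' @export
cohort <- function(mutations, clinical, cancer_type = "COHORT", ...) {
  if (!"patient_id" %in% names(mutations))
    mutations <- maf_records(mutations, ...)
  stopifnot(all(c("patient_id", "time_days", "event") %in% names(clinical)))
  structure(list(mutations = mutations, clinical = clinical,
                 cancer_type = cancer_type), class = "spot_cohort")
}

# assemble the survival sample for a carrier/comparison split
make_surv_sample <- function(clinical, with_ids, without_ids) {
  keep <- clinical[clinical$patient_id %in% c(with_ids, without_ids), ,
                   drop = FALSE]
  list(time = keep$time_days, event = keep$event,
       group = keep$patient_id %in% with_ids,
       patient_id = keep$patient_id)
}

#' Build the comparison groups of the four screening tests
#'
#' The four universes a hotspot X's carriers are compared against:
#' * `groups_x_vs_all()` -- every other patient with clinical data in
#'   the cancer type (only the carrier side is thresholded);
#' * `groups_x_vs_gene()` -- patients mutated in the same gene but not
#'   at X;
#' * `groups_x_vs_spots()` -- carriers of any *other* called hotspot of
#'   the gene, excluding X carriers;
#' * `groups_x_vs_y()` -- carriers of one specific other hotspot Y;
#'   patients carrying both X and Y are excluded from both sides.
#'
#' Groups are always disjoint: a carrier of X is never placed in the
#' comparison group.  For the last three tests a comparison (and for
#' `x_vs_y` the carrier side too) below `min_patients` leads to a skip,
#' signalled by returning a marker object carrying the reason.
#'
#' @param hotspot one row of [call_hotspots()] output (or an
#'   equivalent list with `gene` and `carriers`).
#' @param cohort a [cohort()] object (mutations already filtered for
#'   hypermutated samples if desired).
#' @param min_patients minimum group size (default 4).
#' @return a survival sample: list with `time`, `event`, `group`
#'   (`TRUE` = carrier), `patient_id`; or a skip marker (see
#'   [is_skip()]) carrying the reason.
#' @name screen_groups
NULL

#' @rdname screen_groups
#' @export
groups_x_vs_all <- function(hotspot, cohort, min_patients = 4) {
  carriers <- hotspot$carriers[[1]]
  rest <- setdiff(cohort$clinical$patient_id, carriers)
  if (length(carriers) < min_patients)
    return(skip_group("carrier group below threshold"))
  if (length(rest) == 0)
    return(skip_group("empty comparison group"))
  make_surv_sample(cohort$clinical, carriers, rest)
}

#' @rdname screen_groups
#' @export
groups_x_vs_gene <- function(hotspot, cohort, min_patients = 4) {
  carriers <- hotspot$carriers[[1]]
  gene_pat <- intersect(gene_mutated_patients(cohort$mutations,
                                              hotspot$gene[[1]]),
                        cohort$clinical$patient_id)
  comp <- setdiff(gene_pat, carriers)
  if (length(carriers) < min_patients)
    return(skip_group("carrier group below threshold"))
  if (length(comp) < min_patients)
    return(skip_group("gene comparison group below threshold"))
  make_surv_sample(cohort$clinical, carriers, comp)
}

#' @rdname screen_groups
#' @param all_hotspots_in_gene all called hotspots of the same gene
#'   (the rows of [call_hotspots()] for that gene, including X).
#' @export
groups_x_vs_spots <- function(hotspot, all_hotspots_in_gene, cohort,
                              min_patients = 4) {
  carriers <- hotspot$carriers[[1]]
  others <- setdiff(unique(unlist(all_hotspots_in_gene$carriers)), carriers)
  if (nrow(all_hotspots_in_gene) < 2)
    return(skip_group("gene has a single called hotspot"))
  if (length(carriers) < min_patients)
    return(skip_group("carrier group below threshold"))
  if (length(others) < min_patients)
    return(skip_group("other-hotspot comparison group below threshold"))
  make_surv_sample(cohort$clinical, carriers, others)
}

#' @rdname screen_groups
#' @param hotspot_x,hotspot_y the two hotspots of the pair (same gene).
#' @export
groups_x_vs_y <- function(hotspot_x, hotspot_y, cohort, min_patients = 4) {
  cx <- hotspot_x$carriers[[1]]
  cy <- hotspot_y$carriers[[1]]
  both <- intersect(cx, cy)
  x_only <- setdiff(cx, both)
  y_only <- setdiff(cy, both)
  if (length(x_only) < min_patients || length(y_only) < min_patients)
    return(skip_group("a side of the pair below threshold"))
  make_surv_sample(cohort$clinical, x_only, y_only)
}

skip_group <- function(reason) {
  structure(list(reason = reason), class = "screen_skip")
}

#' Test whether a group construction was skipped
#'
#' @param x result of one of the [screen_groups] builders.
#' @return `TRUE` when the builder skipped the comparison; the skip
#'   reason is in `x$reason`.
#' @export
is_skip <- function(x) inherits(x, "screen_skip")

.screen_tests <- c("X_vs_All", "X_vs_Gene", "X_vs_Spots", "X_vs_Y")

#' Screen all called hotspots of one or more cohorts for survival association
#'
#' For each cancer type independently: computes per-sample tumor
#' mutation burden and (by default) removes hypermutated samples,
#' pools mutations by transcript and amino-acid position, calls
#' hotspots at the `min_patients` threshold, builds the four
#' carrier-versus-comparison group structures
#' (see [screen_groups]) and evaluates every comparison with
#' [hotspot_surv_test()]: the empirical p-value of the signed log-rank
#' statistic under its exact conditional null (`p_valorate`), the
#' classical chi-squared log-rank p (`p_logrank`) and the Cox Wald p
#' with the hazard ratio.  A comparison is called significant when
#' `p_valorate <= alpha`; the other p-values are reported but never
#' used for calling.
#'
#' @param cohorts a [cohort()] or list of cohorts.
#' @param alpha screening threshold on the empirical p-value (default
#'   0.05).
#' @param min_patients minimum carrier count for a hotspot and minimum
#'   group size for the restricted comparisons (default 4).
#' @param filter_hypermutated remove hypermutated samples before
#'   pooling (default `TRUE`; set `FALSE` to reproduce the biased
#'   unfiltered screen).
#' @param scale_mad see [compute_tmb()].
#' @param enum_limit,n_perm_per_stratum see [exact_null()].
#' @param seed integer master seed; every comparison gets a
#'   deterministic sub-seed, so re-running reproduces all
#'   `p_valorate` values exactly.
#' @param collect_curves keep per-comparison Kaplan-Meier curves and
#'   null-distribution tables for export (default `FALSE`).
#' @param quiet suppress progress messages.
#' @return an object of class `hotspot_screen`: a list with `rows`
#'   (one row per performed comparison), `summary` (per-cancer-type
#'   counts of potential hotspots, comparisons and significant calls
#'   per test), `hotspots`, `skips` (log of skipped comparisons with
#'   reasons), `hypermutated` (flagged sample ids per cohort),
#'   `curves` (when collected) and the screen parameters.
#' @export
run_screen <- function(cohorts, alpha = 0.05, min_patients = 4,
                       filter_hypermutated = TRUE, scale_mad = FALSE,
                       enum_limit = 1e5, n_perm_per_stratum = 1e4,
                       seed = 1L, collect_curves = FALSE, quiet = TRUE) {
  if (inherits(cohorts, "spot_cohort")) cohorts <- list(cohorts)
  stopifnot(all(vapply(cohorts, inherits, TRUE, "spot_cohort")))

  rows <- list(); skips <- list(); curves <- list()
  hs_all <- list(); hyper_all <- list()
  tasks <- list()

  for (co in cohorts) {
    ct <- co$cancer_type
    if (nrow(co$clinical) < min_patients) {
      skips[[length(skips) + 1L]] <- skip_row(ct, "cohort", NA, NA, NA,
        "fewer clinical records than min_patients")
      next
    }
    mut <- co$mutations
    flagged <- character(0)
    if (filter_hypermutated && nrow(mut) > 0 &&
        length(unique(mut$sample_id)) >= 2) {
      prof <- compute_tmb(mut, scale_mad = scale_mad)
      flagged <- flag_hypermutated(prof)
      mut <- remove_hypermutated(mut, flagged)
    }
    hyper_all[[ct]] <- flagged
    fco <- structure(list(mutations = mut, clinical = co$clinical,
                          cancer_type = ct), class = "spot_cohort")
    hs <- call_hotspots(pool_positions(mut, co$clinical), min_patients)
    hs_all[[ct]] <- hs
    if (nrow(hs) == 0) next

    for (i in seq_len(nrow(hs))) {
      hx <- hs[i, , drop = FALSE]
      in_gene <- hs[hs$gene == hx$gene[[1]], , drop = FALSE]
      cand <- list(
        X_vs_All   = groups_x_vs_all(hx, fco, min_patients),
        X_vs_Gene  = groups_x_vs_gene(hx, fco, min_patients),
        X_vs_Spots = groups_x_vs_spots(hx, in_gene, fco, min_patients)
      )
      for (test in names(cand)) {
        s <- cand[[test]]
        if (is_skip(s)) {
          skips[[length(skips) + 1L]] <- skip_row(
            ct, test, hx$gene[[1]], hx$aa_position[[1]], NA, s$reason)
        } else {
          tasks[[length(tasks) + 1L]] <- list(
            cancer_type = ct, test = test, hx = hx, sample = s)
        }
      }
      # unordered pairs, each tested once, X = lower position
      if (nrow(in_gene) >= 2) {
        j_after <- which(hs$gene == hx$gene[[1]] & seq_len(nrow(hs)) > i)
        for (j in j_after) {
          hy <- hs[j, , drop = FALSE]
          s <- groups_x_vs_y(hx, hy, fco, min_patients)
          if (is_skip(s)) {
            skips[[length(skips) + 1L]] <- skip_row(
              ct, "X_vs_Y", hx$gene[[1]], hx$aa_position[[1]],
              hy$aa_position[[1]], s$reason)
          } else {
            tasks[[length(tasks) + 1L]] <- list(
              cancer_type = ct, test = "X_vs_Y", hx = hx, hy = hy,
              sample = s)
          }
        }
      }
    }
  }

  sub_seeds <- if (length(tasks))
    with_seed(seed, sample.int(.Machine$integer.max - 1L, length(tasks)))
    else integer(0)

  for (ti in seq_along(tasks)) {
    tk <- tasks[[ti]]
    s <- tk$sample
    fit <- hotspot_surv_test(s$time, event = s$event, group = s$group,
                             enum_limit = enum_limit,
                             n_perm_per_stratum = n_perm_per_stratum,
                             seed = sub_seeds[[ti]])
    pos_y <- if (!is.null(tk$hy)) tk$hy$aa_position[[1]] else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      test = tk$test, cancer_type = tk$cancer_type,
      gene = tk$hx$gene[[1]], transcript_id = tk$hx$transcript_id[[1]],
      position_x = tk$hx$aa_position[[1]], position_y = pos_y,
      n_with = fit$n1, n_without = fit$n - fit$n1,
      events_with = fit$events[["with"]],
      events_without = fit$events[["without"]],
      median_with = fit$km$with$median,
      median_without = fit$km$without$median,
      L = fit$L,
      p_valorate = fit$p_empirical,
      p_logrank = fit$p_asymptotic,
      p_cox = fit$cox$p,
      hr = fit$cox$hr,
      hr_label = fit$cox$hr_label,
      degenerate = fit$cox$degenerate,
      significant = fit$p_empirical <= alpha,
      stringsAsFactors = FALSE
    )
    if (collect_curves) {
      id <- comparison_id(tk$cancer_type, tk$hx$gene[[1]],
                          tk$hx$aa_position[[1]], tk$test, pos_y)
      curves[[id]] <- list(km_with = fit$km$with,
                           km_without = fit$km$without,
                           null = as.data.frame(fit$null),
                           L = fit$L)
    }
    if (!quiet)
      message(sprintf("[%d/%d] %s %s %s-%s", ti, length(tasks),
                      tk$cancer_type, tk$test, tk$hx$gene[[1]],
                      tk$hx$aa_position[[1]]))
  }

  rows <- if (length(rows)) do.call(rbind, rows) else empty_rows()
  skips <- if (length(skips)) do.call(rbind, skips) else empty_skips()
  out <- structure(list(
    rows = rows, skips = skips, hotspots = hs_all,
    hypermutated = hyper_all,
    summary = screen_summary_impl(rows, hs_all),
    curves = if (collect_curves) curves else NULL,
    alpha = alpha, min_patients = min_patients, seed = seed,
    n_perm_per_stratum = n_perm_per_stratum, enum_limit = enum_limit,
    filter_hypermutated = filter_hypermutated
  ), class = "hotspot_screen")
  out
}

skip_row <- function(ct, test, gene, px, py, reason) {
  data.frame(cancer_type = ct, test = test, gene = gene,
             position_x = px, position_y = py, reason = reason,
             stringsAsFactors = FALSE)
}

empty_rows <- function() {
  data.frame(test = character(0), cancer_type = character(0),
             gene = character(0), transcript_id = character(0),
             position_x = integer(0), position_y = integer(0),
             n_with = integer(0), n_without = integer(0),
             events_with = integer(0), events_without = integer(0),
             median_with = numeric(0), median_without = numeric(0),
             L = numeric(0), p_valorate = numeric(0),
             p_logrank = numeric(0), p_cox = numeric(0),
             hr = numeric(0), hr_label = character(0),
             degenerate = character(0), significant = logical(0),
             stringsAsFactors = FALSE)
}

empty_skips <- function() {
  data.frame(cancer_type = character(0), test = character(0),
             gene = character(0), position_x = integer(0),
             position_y = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

comparison_id <- function(ct, gene, pos, test, pos_y = NA) {
  paste0(ct, "_", gene, "_", pos,
         if (!is.na(pos_y)) paste0("_vs_", pos_y) else "", "_", test)
}

# per-cancer-type counts: potential hotspots, comparisons performed and
# significant calls per test
screen_summary_impl <- function(rows, hs_all) {
  cts <- union(names(hs_all), unique(rows$cancer_type))
  do.call(rbind, lapply(cts, function(ct) {
    r <- rows[rows$cancer_type == ct, , drop = FALSE]
    counts <- lapply(.screen_tests, function(tst) {
      rt <- r[r$test == tst, , drop = FALSE]
      c(nrow(rt), sum(rt$significant))
    })
    out <- data.frame(cancer_type = ct,
                      potential_hotspots =
                        if (ct %in% names(hs_all)) nrow(hs_all[[ct]])
                        else NA_integer_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(.screen_tests)) {
      out[[paste0("comparisons_", .screen_tests[i])]] <- counts[[i]][1]
      out[[paste0("significant_", .screen_tests[i])]] <- counts[[i]][2]
    }
    out
  }))
}

#' Per-cancer-type summary of a hotspot screen
#'
#' @param screen a `hotspot_screen` from [run_screen()].
#' @return `data.frame` with one row per cancer type: number of
#'   potential hotspots and, per test, comparisons performed and
#'   significant calls.
#' @export
screen_summary <- function(screen) {
  stopifnot(inherits(screen, "hotspot_screen"))
  screen$summary
}

#' @export
print.hotspot_screen <- function(x, ...) {
  cat("Hotspot survival screen\n")
  nh <- sum(vapply(x$hotspots, nrow, 0L))
  cat(sprintf("  %d called hotspots in %d cohort(s); alpha = %g on the empirical p\n",
              nh, length(x$hotspots), x$alpha))
  cat(sprintf("  %d comparisons performed, %d significant, %d skipped\n",
              nrow(x$rows), sum(x$rows$significant), nrow(x$skips)))
  for (tst in .screen_tests) {
    r <- x$rows[x$rows$test == tst, , drop = FALSE]
    if (nrow(r))
      cat(sprintf("    %-10s %4d comparisons, %3d significant\n",
                  tst, nrow(r), sum(r$significant)))
  }
  invisible(x)
}

#' Export screen results as TSV tables and curve data
#'
#' Writes, under `out_dir`: one TSV per test with the result-table
#' schema (`screen_<test>.tsv`), the merged all-tests table
#' (`screen_all_tests.tsv`), the per-cancer summary (`summary.tsv` and
#' `summary.json`), the called hotspots (`hotspots.tsv`), the skip log
#' (`skipped.tsv`) and, when the screen collected curves, a `curves/`
#' directory with per-comparison Kaplan-Meier step functions
#' (`<id>_km.tsv`) and null-distribution tables (`<id>_null.tsv`),
#' where `<id>` is `cancer_gene_position[_vs_y]_test`.  Re-exporting
#' the same screen yields byte-identical files.
#'
#' @param screen a `hotspot_screen` from [run_screen()].
#' @param out_dir output directory (created if needed).
#' @return invisibly the vector of files written.
#' @export
export_results <- function(screen, out_dir) {
  stopifnot(inherits(screen, "hotspot_screen"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }
  for (tst in .screen_tests)
    put(screen$rows[screen$rows$test == tst, , drop = FALSE],
        paste0("screen_", tst, ".tsv"))
  put(screen$rows, "screen_all_tests.tsv")
  put(screen$summary, "summary.tsv")
  put(screen$skips, "skipped.tsv")
  hs_flat <- do.call(rbind, lapply(names(screen$hotspots), function(ct)
    hotspot_table(screen$hotspots[[ct]], cancer_type = ct)))
  if (is.null(hs_flat))
    hs_flat <- hotspot_table(call_hotspots(
      pool_positions(empty_mutations(), empty_clinical()), 4))
  put(hs_flat, "hotspots.tsv")
  jsonlite::write_json(
    list(alpha = screen$alpha, min_patients = screen$min_patients,
         seed = screen$seed,
         hypermutated = screen$hypermutated,
         summary = screen$summary),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "summary.json"))
  if (!is.null(screen$curves)) {
    cdir <- file.path(out_dir, "curves")
    dir.create(cdir, showWarnings = FALSE)
    for (id in names(screen$curves)) {
      cv <- screen$curves[[id]]
      km <- rbind(
        cbind(as.data.frame(cv$km_with), group = "with"),
        cbind(as.data.frame(cv$km_without), group = "without"))
      p1 <- file.path(cdir, paste0(id, "_km.tsv"))
      p2 <- file.path(cdir, paste0(id, "_null.tsv"))
      write_tsv(km, p1)
      write_tsv(cv$null, p2)
      files <- c(files, p1, p2)
    }
  }
  invisible(files)
}

empty_mutations <- function() {
  data.frame(sample_id = character(0), patient_id = character(0),
             gene = character(0), transcript_id = character(0),
             hgvsp_short = character(0), variant_type = character(0),
             variant_classification = character(0),
             aa_position = integer(0), stringsAsFactors = FALSE)
}

empty_clinical <- function() {
  data.frame(patient_id = character(0), time_days = numeric(0),
             event = logical(0), stringsAsFactors = FALSE)
}
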