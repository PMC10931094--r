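toy_cohort <- function() {
  toy <- figure1_toy()
  cohort(toy$mutations, toy$clinical, toy$cancer_type)
}

toy_hotspots <- function(cc) {
  call_hotspots(pool_positions(cc$mutations, cc$clinical),
                min_patients = 3)
}

test_that("the four group builders produce the documented toy sizes", {
  cc <- toy_cohort()
  hs <- toy_hotspots(cc)
  hx <- hs[hs$aa_position == 100, , drop = FALSE]   # 6 carriers
  hy <- hs[hs$aa_position == 200, , drop = FALSE]   # 5 carriers
  s_all <- groups_x_vs_all(hx, cc, 3)
  expect_identical(c(sum(s_all$group), sum(!s_all$group)), c(6L, 48L))
  s_gene <- groups_x_vs_gene(hx, cc, 3)
  expect_identical(c(sum(s_gene$group), sum(!s_gene$group)), c(6L, 28L))
  s_spots <- groups_x_vs_spots(hx, hs, cc, 3)
  expect_identical(c(sum(s_spots$group), sum(!s_spots$group)), c(6L, 12L))
  s_xy <- groups_x_vs_y(hx, hy, cc, 3)
  expect_identical(c(sum(s_xy$group), sum(!s_xy$group)), c(6L, 5L))
})

test_that("group universes nest: spots within gene within all", {
  cc <- toy_cohort()
  hs <- toy_hotspots(cc)
  hx <- hs[1, , drop = FALSE]
  comp <- function(s) s$patient_id[!s$group]
  c_all <- comp(groups_x_vs_all(hx, cc, 3))
  c_gene <- comp(groups_x_vs_gene(hx, cc, 3))
  c_spots <- comp(groups_x_vs_spots(hx, hs, cc, 3))
  expect_true(all(c_gene %in% c_all))
  expect_true(all(c_spots %in% c_gene))
  gene_pat <- gene_mutated_patients(cc$mutations, "GENE1")
  expect_true(all(c_gene %in% gene_pat))
})

test_that("small comparison universes are skipped, not tested", {
  # gene with 6 mutated patients, 4 at the hotspot: 4 vs 2 is skipped
  mut <- rbind(
    make_mutations(sprintf("TCGA-AA-%04d-01A", 1:4), "G1", 100),
    make_mutations(sprintf("TCGA-AA-%04d-01A", 5:6), "G1", c(7, 8))
  )
  clin <- make_clinical(sprintf("TCGA-AA-%04d", 1:60))
  cc <- cohort(mut, clin, "TST")
  hs <- call_hotspots(pool_positions(mut, clin), 4)
  expect_true(is_skip(groups_x_vs_gene(hs[1, ], cc, 4)))
  # with 10 mutated patients, 6 at hotspot: 6 vs 4 is tested
  mut2 <- rbind(
    make_mutations(sprintf("TCGA-AA-%04d-01A", 1:6), "G1", 100),
    make_mutations(sprintf("TCGA-AA-%04d-01A", 7:10), "G1", 11:14)
  )
  cc2 <- cohort(mut2, clin, "TST")
  hs2 <- call_hotspots(pool_positions(mut2, clin), 4)
  s <- groups_x_vs_gene(hs2[1, ], cc2, 4)
  expect_identical(c(sum(s$group), sum(!s$group)), c(6L, 4L))
  # single hotspot in the gene: no other-hotspot universe
  expect_true(is_skip(groups_x_vs_spots(hs2[1, ], hs2, cc2, 4)))
})

test_that("dual carriers are excluded from pairwise comparisons", {
  mk <- function(ids, pos)
    make_mutations(paste0(ids, "-01A"), "G1", pos)
  x_ids <- sprintf("TCGA-AA-%04d", 1:6)
  y_ids <- sprintf("TCGA-AA-%04d", 5:10)   # patients 5,6 carry both
  mut <- rbind(mk(x_ids, 100), mk(y_ids, 200))
  clin <- make_clinical(sprintf("TCGA-AA-%04d", 1:10))
  cc <- cohort(mut, clin, "TST")
  hs <- call_hotspots(pool_positions(mut, clin), 4)
  s <- groups_x_vs_y(hs[1, ], hs[2, ], cc, 4)
  expect_identical(sum(s$group), 4L)        # X-only
  expect_identical(sum(!s$group), 4L)       # Y-only
  expect_false(any(c("TCGA-AA-0005", "TCGA-AA-0006") %in% s$patient_id))
  # fully overlapping carrier sets leave nothing to compare
  mut2 <- rbind(mk(x_ids, 100), mk(x_ids, 200))
  cc2 <- cohort(mut2, clin, "TST")
  hs2 <- call_hotspots(pool_positions(mut2, clin), 4)
  expect_true(is_skip(groups_x_vs_y(hs2[1, ], hs2[2, ], cc2, 4)))
})

test_that("a gene with four hotspots yields six unordered pairs", {
  mut <- do.call(rbind, lapply(1:4, function(j)
    make_mutations(sprintf("TCGA-AA-%04d-01A", (j - 1) * 5 + 1:5),
                   "G1", j * 100)))
  clin <- make_clinical(sprintf("TCGA-AA-%04d", 1:20),
                        time_days = 50 * (1:20),
                        event = rep(c(TRUE, TRUE, FALSE), length.out = 20))
  scr <- run_screen(cohort(mut, clin, "TST"), seed = 5,
                    filter_hypermutated = FALSE,
                    n_perm_per_stratum = 100)
  xy <- scr$rows[scr$rows$test == "X_vs_Y", ]
  expect_identical(nrow(xy), 6L)  # choose(4, 2) unordered pairs
  expect_true(all(xy$position_x < xy$position_y))
})

test_that("carrier and comparison groups are always disjoint", {
  set.seed(61)
  co <- generate_cohort(cohort_spec(n_patients = 150, seed = 13))
  cc <- cohort(co$mutations, co$clinical, "SYN")
  hs <- call_hotspots(pool_positions(cc$mutations, cc$clinical), 4)
  for (i in seq_len(nrow(hs))) {
    for (s in list(groups_x_vs_all(hs[i, ], cc),
                   groups_x_vs_gene(hs[i, ], cc),
                   groups_x_vs_spots(hs[i, ], hs[hs$gene == hs$gene[i], ],
                                     cc))) {
      if (is_skip(s)) next
      expect_identical(intersect(s$patient_id[s$group],
                                 s$patient_id[!s$group]), character(0))
    }
  }
})

test_that("run_screen is reproducible and its summary counts are coherent", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 17))
  cc <- cohort(co$mutations, co$clinical, "SYN")
  s1 <- run_screen(cc, seed = 7, n_perm_per_stratum = 300)
  s2 <- run_screen(cc, seed = 7, n_perm_per_stratum = 300)
  expect_identical(s1$rows$p_valorate, s2$rows$p_valorate)
  sm <- screen_summary(s1)
  for (tst in c("X_vs_All", "X_vs_Gene", "X_vs_Spots", "X_vs_Y")) {
    comp <- sm[[paste0("comparisons_", tst)]]
    sig <- sm[[paste0("significant_", tst)]]
    expect_true(all(sig <= comp))
  }
  expect_true(all(sm$comparisons_X_vs_Gene <= sm$potential_hotspots))
  expect_true(all(s1$rows$n_with >= 4))
})

test_that("a cohort with no called hotspots yields zero rows plus summary", {
  mut <- make_mutations(sprintf("TCGA-AA-%04d-01A", 1:3), "G1", 100)
  clin <- make_clinical(sprintf("TCGA-AA-%04d", 1:30))
  scr <- run_screen(cohort(mut, clin, "EMPTYISH"), seed = 1,
                    filter_hypermutated = FALSE)
  expect_identical(nrow(scr$rows), 0L)
  expect_identical(scr$summary$potential_hotspots, 0L)
  expect_output(print(scr), "0 comparisons")
})

test_that("export writes per-test, merged and curve files deterministically", {
  co <- generate_cohort(cohort_spec(n_patients = 120, seed = 19))
  scr <- run_screen(cohort(co$mutations, co$clinical, "SYN"), seed = 3,
                    n_perm_per_stratum = 100, collect_curves = TRUE)
  d1 <- file.path(tempfile(), "a")
  files <- export_results(scr, d1)
  expect_true(all(file.exists(files)))
  base <- c("screen_X_vs_All.tsv", "screen_X_vs_Gene.tsv",
            "screen_X_vs_Spots.tsv", "screen_X_vs_Y.tsv",
            "screen_all_tests.tsv", "summary.tsv", "skipped.tsv",
            "hotspots.tsv", "summary.json")
  expect_true(all(base %in% basename(files)))
  expect_true(any(grepl("_km.tsv$", files)))
  expect_true(any(grepl("_null.tsv$", files)))
  merged <- read.delim(file.path(d1, "screen_all_tests.tsv"))
  expect_identical(nrow(merged), nrow(scr$rows))
  # byte-identical re-export
  d2 <- file.path(tempfile(), "b")
  export_results(scr, d2)
  f1 <- file.path(d1, "screen_all_tests.tsv")
  f2 <- file.path(d2, "screen_all_tests.tsv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empty screens export headers-only tables", {
  mut <- make_mutations(sprintf("TCGA-AA-%04d-01A", 1:3), "G1", 100)
  clin <- make_clinical(sprintf("TCGA-AA-%04d", 1:30))
  scr <- run_screen(cohort(mut, clin, "NONE"), seed = 1,
                    filter_hypermutated = FALSE)
  d <- tempfile()
  export_results(scr, d)
  lines <- readLines(file.path(d, "screen_all_tests.tsv"))
  expect_length(lines, 1L)
  expect_match(lines, "p_valorate")
})
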