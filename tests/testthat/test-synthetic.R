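test_that("generation is fully reproducible from the seed", {
  sp <- cohort_spec(n_patients = 80, seed = 71)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n_patients = 80, seed = 72))
  expect_false(identical(a$clinical, c$clinical))
})

test_that("planted carrier sets round-trip through pooling exactly", {
  # noise-free genes so no background call can land on a planted position
  sp <- cohort_spec(
    n_patients = 100,
    genes = data.frame(name = "GENE1", mut_prob = 0, n_positions = 500L),
    planted = data.frame(gene = "GENE1", position = 100L,
                         n_carriers = 20L, hazard_ratio = 1),
    hyper_fraction = 0, seed = 73)
  co <- generate_cohort(sp)
  cc <- cohort(co$mutations, co$clinical)
  hs <- call_hotspots(pool_positions(cc$mutations, cc$clinical), 4)
  called <- hs[hs$gene == "GENE1", ]
  expect_identical(nrow(called), 1L)
  expect_identical(called$aa_position, 100L)
  expect_identical(called$n_carriers, 20L)
  expect_identical(called$carriers[[1]], co$truth$carriers[["GENE1-100"]])
})

test_that("planted hypermutated samples are flagged and background rarely is", {
  co <- generate_cohort(cohort_spec(n_patients = 400, seed = 74))
  prof <- compute_tmb(cohort(co$mutations, co$clinical)$mutations)
  flagged <- flag_hypermutated(prof)
  expect_true(all(co$truth$hypermutated %in% flagged))
  false_pos <- setdiff(flagged, co$truth$hypermutated)
  expect_lte(length(false_pos), ceiling(0.01 * 400))
  # without a hypermutated subpopulation the filter stays near-silent
  co0 <- generate_cohort(cohort_spec(n_patients = 400, hyper_fraction = 0,
                                     seed = 75))
  f0 <- flag_hypermutated(compute_tmb(
    cohort(co0$mutations, co0$clinical)$mutations))
  expect_lte(length(f0), ceiling(0.01 * 400))
})

test_that("event rate rises with the baseline hazard", {
  rates <- c(1 / 4000, 1 / 1500, 1 / 400)
  frac <- vapply(seq_along(rates), function(i) {
    co <- generate_cohort(cohort_spec(n_patients = 300,
                                      baseline_hazard = rates[i],
                                      seed = 76))
    mean(co$clinical$event)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("a deleterious hotspot shortens carrier median survival", {
  sp <- cohort_spec(
    n_patients = 2000,
    genes = data.frame(name = "GENE1", mut_prob = 0, n_positions = 500L),
    planted = data.frame(gene = "GENE1", position = 100L,
                         n_carriers = 500L, hazard_ratio = 3),
    hyper_fraction = 0, seed = 77)
  co <- generate_cohort(sp)
  carr <- co$clinical$patient_id %in% co$truth$carriers[["GENE1-100"]]
  km_c <- km_estimate(co$clinical$time_days[carr], co$clinical$event[carr])
  km_n <- km_estimate(co$clinical$time_days[!carr],
                      co$clinical$event[!carr])
  expect_lt(km_c$median, km_n$median)
})

test_that("null cohorts equalize the survival law across carriers", {
  sp <- cohort_spec(
    n_patients = 1500,
    genes = data.frame(name = "GENE1", mut_prob = 0, n_positions = 500L),
    planted = data.frame(gene = "GENE1", position = 100L,
                         n_carriers = 700L, hazard_ratio = 5),
    hyper_fraction = 0, seed = 78)
  co <- generate_null_cohort(sp)
  carr <- co$clinical$patient_id %in% co$truth$carriers[["GENE1-100"]]
  fit <- cox_fit(co$clinical$time_days, co$clinical$event, carr)
  expect_lt(abs(fit$log_hr), 0.2)
})

test_that("generated tables survive a write/read round trip through the parsers", {
  co <- generate_cohort(cohort_spec(n_patients = 60, seed = 79))
  mp <- tempfile(fileext = ".maf")
  write.table(co$mutations, mp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rec <- suppressMessages(read_maf(mp))
  direct <- maf_records(co$mutations)
  expect_identical(nrow(rec), nrow(direct))
  expect_identical(sort(unique(rec$patient_id)),
                   sort(unique(direct$patient_id)))
  expect_false(any(is.na(rec$aa_position[rec$variant_type == "SNP"])))
})

test_that("infeasible specifications are rejected", {
  expect_error(cohort_spec(n_patients = 10,
                           planted = data.frame(gene = "GENE1",
                                                position = 1L,
                                                n_carriers = 11L,
                                                hazard_ratio = 1)),
               "carriers")
  expect_error(cohort_spec(planted = data.frame(
    gene = c("GENE1", "GENE1"), position = c(5L, 5L),
    n_carriers = c(4L, 4L), hazard_ratio = c(1, 2))), "distinct")
  expect_error(cohort_spec(genes = data.frame(name = "GENE1",
                                              mut_prob = 0.1,
                                              n_positions = 100L),
                           planted = data.frame(gene = "GENEX",
                                                position = 1L,
                                                n_carriers = 4L,
                                                hazard_ratio = 1)),
               "declared genes")
})

test_that("the documentation toy has the documented structure", {
  toy <- figure1_toy()
  expect_identical(nrow(toy$clinical), 54L)
  rec <- maf_records(toy$mutations)
  expect_length(gene_mutated_patients(rec, "GENE1"), 34L)
  hs <- call_hotspots(pool_positions(rec, toy$clinical), min_patients = 3)
  expect_identical(nrow(hs), 4L)
  expect_identical(hs$n_carriers, c(6L, 5L, 4L, 3L))
  expect_identical(figure1_toy(), toy)  # deterministic
})
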