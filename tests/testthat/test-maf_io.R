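test_that("parse_hgvsp extracts the first amino-acid position", {
  cases <- c("p.L858R" = 858, "p.E746_A750del" = 746,
             "p.G96Wfs*12" = 96, "p.L123=" = 123,
             "p.R132H" = 132, "p.T41_E46delinsK" = 41)
  expect_identical(parse_hgvsp(names(cases)), as.integer(unname(cases)))
  expect_true(is.na(parse_hgvsp("p.=")))
  expect_true(is.na(parse_hgvsp("")))
})

test_that("parse_hgvsp never yields a nonpositive position", {
  set.seed(42)
  strings <- c(sprintf("p.A%dV", sample(1:5000, 50)),
               sprintf("p.K%d=", sample(1:5000, 20)),
               sprintf("p.Q%dRfs*%d", sample(1:5000, 20), sample(2:40, 20)),
               "p.0?", "p.=", "junk")
  pos <- parse_hgvsp(strings)
  expect_true(all(is.na(pos) | pos >= 1))
})

test_that("patient_of_sample truncates barcodes and is idempotent", {
  expect_identical(patient_of_sample("TCGA-AB-1234-01A-11D-A123-09"),
                   "TCGA-AB-1234")
  expect_identical(patient_of_sample("TCGA-AB-1234"), "TCGA-AB-1234")
  expect_identical(patient_of_sample(patient_of_sample("TCGA-AB-1234-01A")),
                   "TCGA-AB-1234")
  expect_identical(patient_of_sample("SHORT-ID"), "SHORT-ID")
  expect_error(patient_of_sample(""), "empty")
})

test_that("read_maf retains silent mutations and drops rows without HGVSp", {
  p <- write_maf_fixture(c(
    maf_row(hgvsp = "p.L858R"),
    maf_row(hgvsp = "p.L123=", vc = "Silent",
            barcode = "TCGA-AA-0002-01A"),
    maf_row(hgvsp = "", barcode = "TCGA-AA-0003-01A"),
    maf_row(hgvsp = ".", barcode = "TCGA-AA-0004-01A")
  ))
  rec <- suppressMessages(read_maf(p))
  expect_identical(nrow(rec), 2L)
  expect_true("Silent" %in% rec$variant_classification)
  expect_identical(rec$aa_position, c(858L, 123L))
  expect_identical(rec$patient_id, c("TCGA-AA-0001", "TCGA-AA-0002"))
})

test_that("read_maf filters samples by type code and keeps typeless barcodes", {
  p <- write_maf_fixture(c(
    maf_row(barcode = "TCGA-AA-0001-01A"),
    maf_row(barcode = "TCGA-AA-0002-06A"),
    maf_row(barcode = "SYNTH-PATIENT")
  ))
  primary <- suppressMessages(read_maf(p))
  expect_identical(sort(primary$sample_id),
                   c("SYNTH-PATIENT", "TCGA-AA-0001-01A"))
  both <- suppressMessages(read_maf(p, sample_type_whitelist = c("01", "06")))
  expect_identical(nrow(both), 3L)
  all_in <- suppressMessages(read_maf(p, sample_type_whitelist = NULL))
  expect_identical(nrow(all_in), 3L)
})

test_that("read_maf normalizes variant types and reads deterministically", {
  p <- write_maf_fixture(c(
    maf_row(vt = "SNP"), maf_row(vt = "DEL", hgvsp = "p.E746_A750del",
                                 barcode = "TCGA-AA-0002-01A"),
    maf_row(vt = "Weird", barcode = "TCGA-AA-0003-01A")
  ))
  rec <- read_maf(p)
  expect_setequal(rec$variant_type, c("SNP", "DEL", "other"))
  expect_identical(rec, read_maf(p))
})

test_that("read_maf errors on a missing required column", {
  p <- tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tHGVSp_Short", "G1\tp.L1R"), p)
  expect_error(read_maf(p), "Tumor_Sample_Barcode")
})

test_that("read_maf on an empty body returns an empty record set", {
  p <- write_maf_fixture(character(0))
  rec <- read_maf(p)
  expect_identical(nrow(rec), 0L)
  expect_true(all(c("sample_id", "patient_id", "aa_position") %in%
                    names(rec)))
})

write_clin_fixture <- function(rows) {
  p <- tempfile(fileext = ".tsv")
  hdr <- paste(c("bcr_patient_barcode", "vital_status", "days_to_death",
                 "days_to_last_follow_up"), collapse = "\t")
  writeLines(c(hdr, rows), p)
  p
}

test_that("read_clinical applies the vital-status time rule", {
  p <- write_clin_fixture(c(
    "TCGA-AA-0001\tDead\t400\t100",
    "TCGA-AA-0002\tAlive\t\t1000",
    "TCGA-AA-0003\tAlive\t\t",          # unusable: no time
    "TCGA-AA-0004\tDead\t-5\t",         # negative time
    "TCGA-AA-0005\tNot Reported\t\t250" # unknown status -> censored
  ))
  rec <- suppressMessages(read_clinical(p))
  expect_identical(rec$patient_id,
                   c("TCGA-AA-0001", "TCGA-AA-0002", "TCGA-AA-0005"))
  expect_identical(rec$time_days, c(400, 1000, 250))
  expect_identical(rec$event, c(TRUE, FALSE, FALSE))
})

test_that("read_clinical keeps the first usable record per patient", {
  p <- write_clin_fixture(c(
    "TCGA-AA-0001\tDead\t\t100",   # dead but no death time: unusable
    "TCGA-AA-0001\tDead\t300\t",
    "TCGA-AA-0001\tAlive\t\t999"
  ))
  rec <- suppressMessages(read_clinical(p))
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$time_days, 300)
  expect_true(rec$event)
})

test_that("read_clinical errors when a required column is absent", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("bcr_patient_barcode\tvital_status\tdays_to_death",
               "TCGA-AA-0001\tDead\t100"), p)
  expect_error(read_clinical(p), "days_to_last_follow_up")
})
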