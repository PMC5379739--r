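write_tiny_csvs <- function(dir, mutate_fun = identity) {
  co <- tiny_cohort()
  co <- mutate_fun(co)
  write_cohort(co, dir)
  dir
}

test_that("a written cohort reads back with equal values (round trip)", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$dispensing$dispense_date, co$dispensing$dispense_date)
  expect_equal(back$dispensing$days_supplied, co$dispensing$days_supplied)
  expect_equal(back$eamd_events$timestamp, co$eamd_events$timestamp)
  expect_equal(back$labs$hiv_rna_copies_per_ml, co$labs$hiv_rna_copies_per_ml)
  expect_equal(back$self_report$took_day2, co$self_report$took_day2)
  expect_equal(nrow(back$issues), 0)
})

test_that("exact dispensing duplicates collapse to one retained row, idempotently", {
  dir <- withr::local_tempdir()
  write_tiny_csvs(dir, function(co) {
    co$dispensing <- dplyr::bind_rows(co$dispensing, co$dispensing[2, ])
    co
  })
  back <- read_cohort(dir)
  expect_equal(nrow(back$dispensing), 4)
  expect_equal(sum(back$issues$problem == "duplicate dispensing removed"), 1)
  d2 <- dedupe_dispensing(back$dispensing)
  expect_equal(d2$records, back$dispensing)  # already deduplicated
})

test_that("invalid rows are rejected with logged row numbers, not silently kept", {
  dir <- withr::local_tempdir()
  write_tiny_csvs(dir)
  disp <- readr::read_csv(file.path(dir, "dispensing.csv"),
                          show_col_types = FALSE)
  disp$days_supplied[2] <- -5
  disp$dispense_date <- as.character(disp$dispense_date)
  disp$dispense_date[3] <- "not-a-date"
  readr::write_csv(disp, file.path(dir, "dispensing.csv"))
  back <- read_cohort(dir)
  expect_equal(nrow(back$dispensing), 2)
  bad <- back$issues[back$issues$file == "dispensing", ]
  expect_setequal(bad$row, c(2, 3))
})

test_that("schema violations and duplicate participants are hard errors", {
  dir <- withr::local_tempdir()
  write_tiny_csvs(dir)
  labs <- readr::read_csv(file.path(dir, "labs.csv"), show_col_types = FALSE)
  readr::write_csv(labs[, -3], file.path(dir, "labs.csv"))
  expect_error(read_cohort(dir), "hiv_rna_copies_per_ml")

  dir2 <- withr::local_tempdir()
  write_tiny_csvs(dir2, function(co) {
    co$participants <- dplyr::bind_rows(co$participants, co$participants)
    co
  })
  expect_error(read_cohort(dir2), "duplicate participant_id")
  expect_error(read_cohort(withr::local_tempdir()), "missing input file")
})

test_that("an empty monitor stream loads as an empty, not broken, stream", {
  dir <- withr::local_tempdir()
  write_tiny_csvs(dir, function(co) {
    co$eamd_events <- co$eamd_events[0, ]
    co
  })
  back <- read_cohort(dir)
  expect_equal(nrow(back$eamd_events), 0)
  est <- compute_adherence(back, "week16")
  expect_false("EAMD" %in% est$method)
  expect_true(all(c("SR", "CPC", "PR_AVERAGE", "PR_GAPS", "TDM") %in% est$method))
})
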