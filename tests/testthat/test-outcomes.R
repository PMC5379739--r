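test_that("failure thresholds are landmark-specific: >400 at week 16, >40 at week 48", {
  epoch <- as.Date("2013-01-01")
  co <- tiny_cohort()
  co$labs <- tibble::tibble(
    participant_id = "P1", sample_date = epoch + c(112, 336),
    hiv_rna_copies_per_ml = c(60, 60), cd4 = NA_real_)
  o16 <- derive_outcomes(co, "week16")
  o48 <- derive_outcomes(co, "week48")
  expect_false(o16$failed)
  expect_true(o48$failed)
  expect_false(o16$genotype_eligible)  # 60 < 500 amplification minimum
  co$labs$hiv_rna_copies_per_ml <- c(600, 600)
  expect_true(derive_outcomes(co, "week16")$genotype_eligible)
})

test_that("resistance requires a major mutation hitting a regimen drug", {
  rule <- resistance_rule()
  expect_true(is_resistant("K65R", rule))                    # tenofovir
  expect_true(is_resistant(c("M184V", "V90I"), rule))        # lamivudine
  expect_true(is_resistant("K103N", rule))                   # efavirenz
  expect_false(is_resistant("V90I", rule))                   # not in major table
  expect_false(is_resistant(character(), rule))
  # mutation whose drug is not in the regimen does not classify
  pi_rule <- resistance_rule(regimen = c("zidovudine", "lamivudine", "nevirapine"))
  expect_false(is_resistant("K65R", pi_rule))
  expect_true(is_resistant("M184V", pi_rule))
})

test_that("resistance is defined only for amplified genotyped samples", {
  epoch <- as.Date("2013-01-01")
  co <- tiny_cohort()
  co$labs <- tibble::tibble(
    participant_id = "P1", sample_date = epoch + 112,
    hiv_rna_copies_per_ml = 12000, cd4 = NA_real_)
  co$genotypes <- tibble::tibble(
    participant_id = "P1", sample_date = epoch + 120,
    mutations = list(c("K65R", "K103N")), amplified = TRUE)
  o <- derive_outcomes(co, "week16")
  expect_true(o$genotyped)
  expect_true(o$resistant)
  co$genotypes$amplified <- FALSE
  co$genotypes$mutations <- list(character())
  o2 <- derive_outcomes(co, "week16")
  expect_false(o2$genotyped)
  expect_true(is.na(o2$resistant))
})

test_that("a genotype with no in-window viral load raises a warning and stays absent", {
  epoch <- as.Date("2013-01-01")
  co <- tiny_cohort()
  co$labs <- co$labs[0, ]
  co$genotypes <- tibble::tibble(
    participant_id = "P1", sample_date = epoch + 120,
    mutations = list("K65R"), amplified = TRUE)
  expect_warning(o <- derive_outcomes(co, "week16"), "without a matching")
  expect_equal(nrow(o), 0)
})
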