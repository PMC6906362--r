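# Cohort I/O, validation, and the sex-confound filter.

test_that("cohort CSV round-trips field by field", {
  sets <- list(c("A", "B"), "C", c("B", "D"))
  coh <- fixture_cohort(sets, catalog = fixture_catalog())
  path <- withr::local_tempfile(fileext = ".csv")
  catp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  write_catalog(coh$catalog, catp)
  back <- read_cohort(path, catp)
  expect_equal(back$data$child_id, coh$data$child_id)
  expect_equal(back$characteristics, coh$characteristics)
  expect_equal(back$data$z_bmi_entry, coh$data$z_bmi_entry)
  expect_equal(back$data$z_bmi_exit, coh$data$z_bmi_exit)
  expect_false(any(has_labs(back)))  # labs never written, absent on read
  expect_null(back$outcome)

  # labeled round trip carries the outcome column
  lab <- set_outcome_labels(coh, setNames(c("IMPV", "MC", "MC"),
                                          coh$data$child_id))
  write_cohort(lab, path)
  back2 <- read_cohort(path, catp)
  expect_equal(back2$outcome[coh$data$child_id],
               lab$outcome[coh$data$child_id])

  # generated cohorts round-trip too (property over a seeded case)
  gen <- generate_cohort(small_scenario(seed = 5L))$cohort
  write_cohort(gen, path)
  write_catalog(gen$catalog, catp)
  gback <- read_cohort(path, catp)
  expect_equal(gback$characteristics, gen$characteristics)
  expect_equal(gback$outcome[gen$data$child_id],
               gen$outcome[gen$data$child_id])
  expect_equal(has_labs(gback), has_labs(gen))
})

test_that("validation failures are distinct and name the offender", {
  catalog <- fixture_catalog()
  base <- data.frame(child_id = c("k1", "k2"), sex = c("male", "female"),
                     age_years = c(5, 6), z_bmi_entry = c(3, 3),
                     z_bmi_exit = c(2, 2), stringsAsFactors = FALSE)
  X <- matrix(0L, 2, 4, dimnames = list(NULL, catalog$id))

  Xbad <- X; Xbad[2, "C"] <- 2L
  err <- expect_error(cohort(catalog, base, Xbad),
                      class = "pc_nonbinary_cell_error")
  expect_match(conditionMessage(err), "k2")
  expect_match(conditionMessage(err), "C")

  dup <- base; dup$child_id <- c("k1", "k1")
  expect_error(cohort(catalog, dup, X), class = "pc_duplicate_id_error")

  expect_error(cohort(catalog, base[, -2], X),
               class = "pc_missing_column_error")

  # unknown characteristic column in a file is rejected
  path <- withr::local_tempfile(fileext = ".csv")
  catp <- withr::local_tempfile(fileext = ".csv")
  coh <- fixture_cohort(list(c("A", "B"), "C", "D"),
                        catalog = fixture_catalog())
  write_cohort(coh, path)
  write_catalog(fixture_catalog(ids = c("A", "B", "C")), catp)
  expect_error(read_cohort(path, catp), class = "pc_unknown_column_error")
})

# two-sided Fisher p by explicit hypergeometric enumeration
enumerate_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("sex filter applies an exact two-sided test per characteristic", {
  # 50 males, 50 females; E1 balanced 20/20, E2 imbalanced 30/5, E3 absent
  sets <- c(lapply(1:20, function(i) c("E1", "E2")),
            lapply(21:30, function(i) "E2"),
            lapply(31:50, function(i) character(0)),
            lapply(1:20, function(i) "E1"),
            lapply(21:25, function(i) "E2"),
            lapply(26:50, function(i) character(0)))
  catalog <- characteristic_catalog(id = c("E1", "E2", "E3"),
                                    source = rep("child", 3))
  coh <- fixture_cohort(sets, sex = rep(c("male", "female"), each = 50),
                        catalog = catalog)
  filt <- sex_association_filter(coh, alpha = 0.05)
  expect_equal(unname(filt$p_values["E1"]), 1)
  expect_true("E1" %in% filt$retained$id)
  expect_equal(filt$removed$id, "E2")
  expect_equal(filt$removed$p_value, enumerate_fisher_p(30, 20, 5, 45),
               tolerance = 1e-10)
  # zero-expression characteristic: retained with p = 1 and a warning note
  expect_equal(unname(filt$p_values["E3"]), 1)
  expect_true("E3" %in% filt$retained$id)
  expect_match(filt$warnings, "E3", all = FALSE)

  # tiny alpha removes nothing; alpha near 1 removes any imbalance (p < 1)
  expect_equal(nrow(sex_association_filter(coh, alpha = 1e-12)$removed), 0)
  loose <- sex_association_filter(coh, alpha = 0.999999)
  expect_true("E2" %in% loose$removed$id)

  # record order must not matter
  perm <- sample(length(sets))
  coh2 <- fixture_cohort(sets[perm],
                         sex = rep(c("male", "female"), each = 50)[perm],
                         catalog = catalog)
  filt2 <- sex_association_filter(coh2, alpha = 0.05)
  expect_equal(filt2$p_values, filt$p_values)

  # single-sex cohorts are rejected
  allm <- fixture_cohort(sets[1:10], sex = rep("male", 10), catalog = catalog)
  expect_error(sex_association_filter(allm), class = "pc_single_sex_error")
})

test_that("catalog constructor enforces unique ids and source levels", {
  expect_error(characteristic_catalog(c("a", "a"), source = c("child", "child")),
               "duplicate")
  expect_error(characteristic_catalog("a", source = "parent"), "source")
  counts <- catalog_counts(default_scenario()$catalog)
  expect_equal(unname(counts), c(28, 49, 77))
})
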