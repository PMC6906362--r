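# In-code fixtures shared across test files.

fixture_catalog <- function(ids = c("A", "B", "C", "D"),
                            source = c("child", "child", "guardian",
                                       "guardian")) {
  characteristic_catalog(id = ids, source = source[seq_along(ids)])
}

# cohort from explicit per-child characteristic sets
fixture_cohort <- function(sets, groups = NULL,
                           sex = rep(c("male", "female"),
                                     length.out = length(sets)),
                           dz = rep(1, length(sets)),
                           catalog = NULL) {
  ids <- sprintf("k%02d", seq_along(sets))
  all_chars <- sort(unique(unlist(sets)))
  if (is.null(catalog)) {
    catalog <- characteristic_catalog(
      id = all_chars, source = rep("child", length(all_chars)))
  }
  X <- matrix(0L, length(sets), nrow(catalog),
              dimnames = list(NULL, catalog$id))
  for (i in seq_along(sets)) X[i, sets[[i]]] <- 1L
  # z_entry = dz and z_exit = 0 keeps delta-z exact in floating point,
  # which the threshold boundary tests rely on
  data <- data.frame(child_id = ids, sex = sex,
                     age_years = 6, z_bmi_entry = dz,
                     z_bmi_exit = 0, stringsAsFactors = FALSE)
  outcome <- if (!is.null(groups)) stats::setNames(groups, ids)
  cohort(catalog, data, X, outcome = outcome)
}

# small scenario for fast generator-driven tests
small_scenario <- function(n_impv = 40, n_mc = 80, seed = 1L, ...) {
  ids <- sprintf("x%02d", 1:6)
  catalog <- characteristic_catalog(id = ids,
                                    source = rep(c("child", "guardian"), 3))
  simulation_scenario(
    catalog = catalog, n_impv = n_impv, n_mc = n_mc,
    marginal_prevalence = data.frame(
      id = ids,
      p_impv = c(0.4, 0.2, 0.3, 0.25, 0.1, 0.05),
      p_mc = c(0.1, 0.2, 0.3, 0.25, 0.35, 0.05)),
    rng_seed = seed, ...)
}
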