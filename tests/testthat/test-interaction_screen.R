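# Seed selection, tuple prevalence, and the Stay/Swap designation.

test_that("seeds are exactly the characteristics beyond the 90% rule", {
  base <- data.frame(id = c("a", "b", "c", "d"),
                     p_higher_impv = c(0.95, 0.05, 0.6, 0.9),
                     stringsAsFactors = FALSE)
  seeds <- select_seeds(base, min_prob = 0.9)
  expect_equal(seeds$id, c("a", "b", "d"))
  expect_equal(seeds$direction, c("IMPV", "MC", "IMPV"))
  expect_equal(seeds$baseline_prob, c(0.95, 0.05, 0.9))
})

test_that("tuple prevalence counts children expressing every member", {
  catalog <- characteristic_catalog(c("A", "B", "C", "Z"),
                                    source = rep("child", 4))
  sets <- list(c("A", "B"), c("A", "B", "C"), "A", "B",  # IMPV group of 4
               c("A", "B"), "C")                          # MC group of 2
  coh <- fixture_cohort(sets, groups = c(rep("IMPV", 4), rep("MC", 2)),
                        catalog = catalog)
  cnt <- tuple_prevalence(coh, c("A", "B"))
  expect_equal(cnt, list(k_impv = 2, n_impv = 4, k_mc = 1, n_mc = 2))
  # singleton tuple reduces to the baseline count
  expect_equal(tuple_prevalence(coh, "A")$k_impv, 3)
  # a never-expressed member forces zero in both groups
  z <- tuple_prevalence(coh, c("A", "Z"))
  expect_equal(c(z$k_impv, z$k_mc), c(0, 0))
  expect_error(tuple_prevalence(coh, c("A", "missing")),
               class = "pc_validation_error")
})

test_that("designation follows the seed direction, threshold and rarity", {
  seed_impv <- list(id = "s", direction = "IMPV")
  seed_mc <- list(id = "s", direction = "MC")
  strong_impv <- list(k_impv = 30, n_impv = 128, k_mc = 10, n_mc = 372)
  strong_mc <- list(k_impv = 1, n_impv = 128, k_mc = 40, n_mc = 372)
  balanced <- list(k_impv = 10, n_impv = 128, k_mc = 29, n_mc = 372)

  expect_equal(classify_interaction(seed_impv, strong_impv)$designation,
               "Stay")
  expect_equal(classify_interaction(seed_impv, strong_mc)$designation,
               "Swap")
  expect_equal(classify_interaction(seed_mc, strong_mc)$designation, "Stay")
  expect_equal(classify_interaction(seed_mc, strong_impv)$designation,
               "Swap")
  ind <- classify_interaction(seed_impv, balanced)
  expect_equal(ind$designation, "Discarded")
  expect_equal(ind$discard_reason, "indeterminate")

  # five or fewer total occurrences: always rarity-discarded, whatever the
  # split between groups
  for (k1 in 0:5) for (k2 in 0:(5 - k1)) {
    r <- classify_interaction(seed_impv,
                              list(k_impv = k1, n_impv = 128,
                                   k_mc = k2, n_mc = 372))
    expect_equal(r$designation, "Discarded")
    expect_equal(r$discard_reason, "rarity")
  }
  # six occurrences clear the rarity filter
  r6 <- classify_interaction(seed_impv,
                             list(k_impv = 6, n_impv = 128,
                                  k_mc = 0, n_mc = 372))
  expect_false(identical(r6$discard_reason, "rarity"))

  # the tuple entity probability is exactly prob_greater on its posteriors
  expect_equal(classify_interaction(seed_impv, strong_impv)$p_higher_impv,
               prob_greater(beta_posterior(30, 128), beta_posterior(10, 372)))
})

test_that("dyad_scan enumerates seed-partner pairs and is order-invariant", {
  set.seed(40)
  g <- generate_cohort(default_scenario(), seed = 40L)
  coh <- g$cohort
  base <- baseline_scan(coh)
  seeds <- select_seeds(base)
  expect_gt(nrow(seeds), 0)
  scan <- dyad_scan(coh, base)
  expect_equal(nrow(scan), nrow(seeds) * 76)
  # a seed never pairs with itself
  for (i in seq_len(nrow(scan))) {
    m <- strsplit(scan$members[i], "+", fixed = TRUE)[[1]]
    expect_equal(anyDuplicated(m), 0)
  }
  # vectorized scan agrees with the single-tuple classifier row by row
  pick <- seq(1, nrow(scan), length.out = 12)
  for (i in round(pick)) {
    m <- strsplit(scan$members[i], "+", fixed = TRUE)[[1]]
    seed <- list(id = scan$seed[i], direction = scan$seed_direction[i])
    ref <- classify_interaction(seed, tuple_prevalence(coh, m))
    expect_equal(scan$p_higher_impv[i], ref$p_higher_impv)
    expect_equal(scan$designation[i], ref$designation)
    expect_equal(scan$odds_ratio[i], ref$odds_ratio)
    expect_equal(scan$k_impv[i], unname(ref$k_impv))
  }
  # shuffling records leaves every designation unchanged
  perm <- sample(n_records <- nrow(coh$data))
  coh2 <- cohort(coh$catalog, coh$data[perm, ],
                 coh$characteristics[perm, ],
                 outcome = coh$outcome)
  scan2 <- dyad_scan(coh2, baseline_scan(coh2))
  expect_equal(scan2$designation[match(scan$members, scan2$members)],
               scan$designation)
})

test_that("triad_scan extends the dyad rules to three-member entities", {
  sc <- small_scenario(n_impv = 60, n_mc = 140, seed = 2L)
  coh <- generate_cohort(sc)$cohort
  base <- baseline_scan(coh)
  seeds <- select_seeds(base)
  expect_gt(nrow(seeds), 0)  # deterministic for this scenario seed
  tri <- triad_scan(coh, base)
  expect_equal(nrow(tri), nrow(seeds) * choose(5, 2))
  m <- strsplit(tri$members, "+", fixed = TRUE)
  expect_true(all(lengths(m) == 3))
  expect_true(all(vapply(m, anyDuplicated, integer(1)) == 0))
  # spot-check one triad against the single-tuple classifier
  i <- which(tri$total_occurrences > 0)[1]
  ref <- classify_interaction(list(id = tri$seed[i],
                                   direction = tri$seed_direction[i]),
                              tuple_prevalence(coh, m[[i]]))
  expect_equal(tri$p_higher_impv[i], ref$p_higher_impv)
  expect_equal(tri$designation[i], ref$designation)
})

test_that("scans without seeds return empty results with a warning", {
  base <- data.frame(id = c("a", "b"), p_higher_impv = c(0.5, 0.6),
                     stringsAsFactors = FALSE)
  coh <- generate_cohort(small_scenario(seed = 3L))$cohort
  expect_warning(res <- dyad_scan(coh, base), "no seed")
  expect_equal(nrow(res), 0)
})

test_that("edge export keeps only threshold-reaching dyads", {
  g <- generate_cohort(default_scenario(), seed = 40L)
  scan <- dyad_scan(g$cohort, baseline_scan(g$cohort))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  edges <- export_interaction_edges(scan, tsv_path = tsv, graphml_path = gml)
  expect_true(all(edges$designation %in% c("Stay", "Swap")))
  expect_equal(nrow(edges), sum(scan$designation %in% c("Stay", "Swap")))
  expect_true(file.exists(tsv))
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(edges))
})
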