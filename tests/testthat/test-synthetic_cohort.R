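# Synthetic cohort generator: determinism, target prevalences, planted
# structure, ground-truth consistency.

test_that("zero prevalence yields empty characteristic sets", {
  sc <- small_scenario()
  sc$marginal_prevalence$p_impv[] <- 0
  sc$marginal_prevalence$p_mc[] <- 0
  g <- generate_cohort(sc)
  expect_true(all(g$cohort$characteristics == 0L))
})

test_that("generation is deterministic given the seed", {
  sc <- small_scenario(seed = 9L)
  g1 <- generate_cohort(sc)
  g2 <- generate_cohort(sc)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$ground_truth, g2$ground_truth)
  g3 <- generate_cohort(sc, seed = 10L)
  expect_false(identical(g1$cohort$characteristics,
                         g3$cohort$characteristics))
})

test_that("empirical prevalences stay within 3 binomial SDs of targets", {
  sc <- small_scenario(n_impv = 128, n_mc = 372, seed = 3L)
  g <- generate_cohort(sc)
  rp <- g$ground_truth$realized_prevalence
  for (i in seq_len(nrow(rp))) {
    for (grp in c("impv", "mc")) {
      p <- sc$marginal_prevalence[[paste0("p_", grp)]][i]
      n <- if (grp == "impv") 128 else 372
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(rp[[paste0("p_", grp)]][i] - p), 3 * se + 1e-12)
    }
  }
})

test_that("infeasible joint prevalence raises a named Frechet error", {
  ids <- c("u", "v")
  catalog <- characteristic_catalog(ids, source = c("child", "child"))
  expect_error(
    simulation_scenario(
      catalog, 10, 10,
      data.frame(id = ids, p_impv = c(0.2, 0.3), p_mc = c(0.2, 0.3)),
      planted_dyads = list(list(pair = ids, q_impv = 0.25, q_mc = 0.1))),
    class = "pc_frechet_error")
  # joint below the lower Frechet bound is equally infeasible
  expect_error(
    simulation_scenario(
      catalog, 10, 10,
      data.frame(id = ids, p_impv = c(0.9, 0.9), p_mc = c(0.2, 0.3)),
      planted_dyads = list(list(pair = ids, q_impv = 0.5, q_mc = 0.1))),
    class = "pc_frechet_error")
})

test_that("default scenario mirrors the emulated study design", {
  sc <- default_scenario()
  expect_s3_class(sc, "simulation_scenario")  # constructor validates
  expect_equal(sc$n_impv, 128L)
  expect_equal(sc$n_mc, 372L)
  expect_equal(unname(catalog_counts(sc$catalog)), c(28, 49, 77))
  expect_equal(sc$lab_model$threshold, 0.747)
  roles <- vapply(sc$planted_dyads, `[[`, character(1), "role")
  expect_true("stay" %in% roles && "swap" %in% roles)
  # strong baseline characteristics exist in both directions
  mp <- sc$marginal_prevalence
  expect_true(any(mp$p_impv - mp$p_mc >= 0.2))
  expect_true(any(mp$p_mc - mp$p_impv >= 0.2))
  # swap dyad members lean IMPV marginally while the joint leans MC
  swap <- sc$planted_dyads[[which(roles == "swap")]]
  for (m in swap$pair) {
    expect_gt(mp$p_impv[mp$id == m], mp$p_mc[mp$id == m])
  }
  expect_lt(swap$q_impv, swap$q_mc)
})

test_that("ground truth recounts match the emitted cohort exactly", {
  g <- generate_cohort(default_scenario(), seed = 21L)
  X <- g$cohort$characteristics
  impv <- group_ids(g$cohort, "IMPV"); mc <- group_ids(g$cohort, "MC")
  rp <- g$ground_truth$realized_prevalence
  expect_equal(rp$k_impv, unname(colSums(X[impv, ])))
  expect_equal(rp$k_mc, unname(colSums(X[mc, ])))
  for (d in g$ground_truth$planted_dyads) {
    joint <- X[, d$pair[1]] & X[, d$pair[2]]
    expect_equal(d$k_impv, sum(joint[impv]))
    expect_equal(d$k_mc, sum(joint[mc]))
  }
  # latent class assignment covers every child and respects the group
  cls <- g$ground_truth$latent_class
  expect_equal(sort(names(cls)), sort(g$cohort$data$child_id))
  expect_true(all(startsWith(cls[impv], "IMPV")))
  # outcome labels agree with the labeling rule at the generating threshold
  relabel <- classify_outcomes(g$cohort, g$ground_truth$threshold)
  expect_equal(relabel[names(g$cohort$outcome)], g$cohort$outcome)
})

test_that("marginals and planted joints converge at n = 10,000 within 2%", {
  sc <- default_scenario(rng_seed = 77L)
  sc$n_impv <- 3000L; sc$n_mc <- 7000L
  g <- generate_cohort(sc)
  rp <- g$ground_truth$realized_prevalence
  mp <- sc$marginal_prevalence
  expect_true(all(abs(rp$p_impv - mp$p_impv) < 0.02))
  expect_true(all(abs(rp$p_mc - mp$p_mc) < 0.02))
  for (d in g$ground_truth$planted_dyads) {
    expect_lt(abs(d$k_impv / sc$n_impv - d$q_impv), 0.02)
    expect_lt(abs(d$k_mc / sc$n_mc - d$q_mc), 0.02)
  }
  # latent classes preserve marginals while inducing co-occurrence: within
  # the clustered block, pairwise joint prevalence exceeds independence
  blk <- sprintf("g%02d", 20:24)
  X <- g$cohort$characteristics[group_ids(g$cohort, "MC"), blk]
  joint <- mean(X[, 1] & X[, 2])
  expect_gt(joint, 0.3 * 0.3 * 1.5)
})

test_that("lab panels are complete-or-absent and strictly positive", {
  g <- generate_cohort(default_scenario(), seed = 4L)
  hl <- has_labs(g$cohort)
  labcols <- g$cohort$data[paste0(rep(c("insulin", "triglycerides", "homa_ir"),
                                      each = 2), c("_first", "_last"))]
  expect_true(all(is.na(labcols[!hl, ])))
  expect_true(all(labcols[hl, ] > 0))
  expect_gt(sum(hl), 0)
})
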