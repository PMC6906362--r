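# Synthetic cohort generator.
#
# The study's clinical records are private, so every downstream stage is
# exercised on simulated cohorts with known ground truth. A scenario states
# per-group marginal prevalences for every characteristic, planted dyads
# with explicit joint prevalences (bivariate Bernoulli cells), per-group
# latent classes that create co-occurrence clustering while preserving the
# stated marginals, and a lab/delta-z model tying biomarker improvement to
# BMI z-score change.

#' Specify a simulation scenario
#'
#' @param catalog a [characteristic_catalog()].
#' @param n_impv,n_mc group sizes (the emulated study had 128 and 372).
#' @param marginal_prevalence data.frame with columns `id`, `p_impv`, `p_mc`
#'   covering every catalog id; probabilities in `[0, 1]`.
#' @param planted_dyads list of `list(pair = c(id, id), q_impv, q_mc)`; each
#'   joint prevalence must satisfy the Frechet bounds
#'   `max(0, p_i + p_j - 1) <= q <= min(p_i, p_j)` within each group, and a
#'   characteristic may belong to at most one planted dyad.
#' @param latent_classes list with elements `IMPV` and `MC`; each a list of
#'   classes `list(weight, override = named numeric)` whose weights sum to 1.
#'   Overrides give class-conditional prevalences for a subset of ids; their
#'   weighted average must equal the stated marginal (so latent structure
#'   adds co-occurrence, not marginal drift). Override ids must not appear in
#'   planted dyads.
#' @param lab_model list: `completeness` (probability a child has a lab
#'   panel), `rate_above`/`rate_below` (probability all three labs improve
#'   given delta-z at/above vs below the generating threshold), `threshold`
#'   (generating delta-z threshold), `dz` (per group `mean`, `sd` of the
#'   latent normal delta-z, truncated at the threshold so group membership
#'   and delta-z agree), `baseline` (per analyte `meanlog`, `sdlog` of the
#'   first measurement), `improve` / `worsen` multiplicative factor ranges.
#' @param sex_ratio named numeric `c(IMPV = , MC = )`, proportion male.
#' @param age per group `list(mean, sd)` for a truncated-normal age in years.
#' @param rng_seed integer seed; generation is deterministic given the seed.
#' @return Validated list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(catalog, n_impv, n_mc, marginal_prevalence,
                                planted_dyads = list(),
                                latent_classes = list(IMPV = list(), MC = list()),
                                lab_model = default_lab_model(),
                                sex_ratio = c(IMPV = 0.5, MC = 0.5),
                                age = list(IMPV = list(mean = 6, sd = 2),
                                           MC = list(mean = 7, sd = 2)),
                                rng_seed = 42L) {
  stopifnot(inherits(catalog, "characteristic_catalog"))
  if (n_impv + n_mc < 2L || n_impv < 0L || n_mc < 0L) {
    stop("need n_impv + n_mc >= 2")
  }
  mp <- as.data.frame(marginal_prevalence)
  stopifnot(all(c("id", "p_impv", "p_mc") %in% names(mp)))
  if (!setequal(mp$id, catalog$id)) {
    stop("marginal_prevalence must cover exactly the catalog ids")
  }
  mp <- mp[match(catalog$id, mp$id), ]
  if (any(mp$p_impv < 0 | mp$p_impv > 1 | mp$p_mc < 0 | mp$p_mc > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  p_of <- function(id, grp) {
    if (grp == "IMPV") mp$p_impv[mp$id == id] else mp$p_mc[mp$id == id]
  }
  dyad_members <- unlist(lapply(planted_dyads, `[[`, "pair"))
  if (anyDuplicated(dyad_members)) {
    stop("a characteristic may belong to at most one planted dyad")
  }
  for (d in planted_dyads) {
    stopifnot(length(d$pair) == 2L, all(d$pair %in% catalog$id))
    for (grp in c("IMPV", "MC")) {
      pi <- p_of(d$pair[1], grp); pj <- p_of(d$pair[2], grp)
      q <- if (grp == "IMPV") d$q_impv else d$q_mc
      if (q < max(0, pi + pj - 1) - 1e-12 || q > min(pi, pj) + 1e-12) {
        pc_error("pc_frechet_error",
                 "joint prevalence %.4f for dyad (%s, %s) violates Frechet bounds in %s",
                 q, d$pair[1], d$pair[2], grp)
      }
    }
  }
  for (grp in c("IMPV", "MC")) {
    cls <- latent_classes[[grp]]
    if (length(cls)) {
      w <- vapply(cls, `[[`, numeric(1), "weight")
      if (abs(sum(w) - 1) > 1e-8) stop("class weights must sum to 1 in ", grp)
      ov_ids <- unique(unlist(lapply(cls, function(cl) names(cl$override))))
      if (length(intersect(ov_ids, dyad_members))) {
        stop("latent-class overrides may not touch planted dyad members")
      }
      for (id in ov_ids) {
        vals <- vapply(cls, function(cl) {
          if (id %in% names(cl$override)) cl$override[[id]] else p_of(id, grp)
        }, numeric(1))
        if (any(vals < 0 | vals > 1)) stop("override out of [0,1] for ", id)
        if (abs(sum(w * vals) - p_of(id, grp)) > 1e-6) {
          stop(sprintf(
            "class overrides for '%s' in %s average to %.4f, marginal is %.4f",
            id, grp, sum(w * vals), p_of(id, grp)))
        }
      }
    }
  }
  structure(list(catalog = catalog, n_impv = n_impv, n_mc = n_mc,
                 marginal_prevalence = mp, planted_dyads = planted_dyads,
                 latent_classes = latent_classes, lab_model = lab_model,
                 sex_ratio = sex_ratio, age = age,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_scenario")
}

#' Default lab / delta-z generating model
#'
#' Reflects a severely obese pediatric cohort: elevated fasting insulin
#' (uIU/mL), triglycerides (mg/dL) and HOMA-IR at entry, all improving
#' (decreasing) when treatment succeeds. About 15% of children carry a
#' complete first/last lab panel (the emulated study derived its threshold
#' from 72 of ~500). Children whose delta-z reaches the generating threshold
#' improve all three labs with probability 0.8; others with probability
#' 0.08 — labs lag nutritional status, so agreement is strong but imperfect.
#'
#' @return List consumed by [simulation_scenario()].
#' @export
default_lab_model <- function() {
  list(completeness = 0.15,
       rate_above = 0.80,
       rate_below = 0.08,
       threshold = 0.747,
       dz = list(IMPV = list(mean = 1.05, sd = 0.35),
                 MC = list(mean = 0.15, sd = 0.35)),
       z_entry = list(mean = 3.2, sd = 0.7),
       baseline = list(insulin = list(meanlog = log(25), sdlog = 0.30),
                       triglycerides = list(meanlog = log(140), sdlog = 0.30),
                       homa_ir = list(meanlog = log(4.5), sdlog = 0.35)),
       improve = c(0.55, 0.90),
       worsen = c(1.00, 1.35))
}

#' The default paper-mirroring scenario
#'
#' 128 IMPV / 372 MC children over 28 child + 49 guardian characteristics,
#' with: strong baseline characteristics in each direction (c01/c02 lean
#' IMPV at prevalence 0.40/0.35 vs 0.10; g01/g02 lean MC), eight null
#' characteristics at equal prevalence 0.25, a planted swap dyad
#' (c01, c03) whose members lean IMPV marginally but whose joint favors MC,
#' a planted stay dyad (g01, g03) jointly MC-leaning like its seed, a block
#' of fifteen guardian characteristics clustered by latent classes (one
#' split in IMPV, three smaller classes in MC, marginals preserved), and a
#' tail of rare characteristics so that — as in real cohorts — not every
#' characteristic is expressed in both groups. Sex ratios (64% / 47% male)
#' and ages (6.07 / 7.04 +- 2.24 y) mirror the emulated study; the
#' generating delta-z threshold is 0.747.
#'
#' @param rng_seed integer seed, default 42.
#' @return A `simulation_scenario`.
#' @export
default_scenario <- function(rng_seed = 42L) {
  ids_c <- sprintf("c%02d", 1:28)
  ids_g <- sprintf("g%02d", 1:49)
  catalog <- characteristic_catalog(
    id = c(ids_c, ids_g),
    label = c(sprintf("child characteristic %02d", 1:28),
              sprintf("guardian characteristic %02d", 1:49)),
    source = rep(c("child", "guardian"), c(28, 49)))

  p_impv <- stats::setNames(numeric(77), catalog$id)
  p_mc <- p_impv
  # strong baseline leans
  p_impv[c("c01", "c02")] <- c(0.40, 0.35); p_mc[c("c01", "c02")] <- 0.10
  p_impv[c("g01", "g02")] <- c(0.10, 0.08); p_mc[c("g01", "g02")] <- c(0.40, 0.30)
  # dyad partners: mild leans
  p_impv["c03"] <- 0.30; p_mc["c03"] <- 0.22
  p_impv["g03"] <- 0.25; p_mc["g03"] <- 0.30
  # null characteristics, equal prevalence
  nulls <- c(sprintf("c%02d", 5:8), sprintf("g%02d", 5:8))
  p_impv[nulls] <- 0.25; p_mc[nulls] <- 0.25
  # latent-class clustering block (guardian g20..g34), marginal 0.30
  block <- sprintf("g%02d", 20:34)
  p_impv[block] <- 0.30; p_mc[block] <- 0.30
  # rare tail: expressed too seldom to appear in both groups every time
  rare <- c(sprintf("c%02d", 25:28), sprintf("g%02d", 44:49))
  p_impv[rare] <- 0.008; p_mc[rare] <- 0.008
  # everything else: moderate prevalence with small alternating group offsets
  rest <- setdiff(catalog$id, c("c01", "c02", "c03", "g01", "g02", "g03",
                                nulls, block, rare))
  base <- 0.10 + 0.25 * (seq_along(rest) %% 7) / 7
  off <- 0.03 * rep_len(c(1, -1), length(rest))
  p_impv[rest] <- pmin(pmax(base + off / 2, 0.02), 0.98)
  p_mc[rest] <- pmin(pmax(base - off / 2, 0.02), 0.98)

  planted <- list(
    list(pair = c("c01", "c03"), q_impv = 0.01, q_mc = 0.09,
         role = "swap"),
    list(pair = c("g01", "g03"), q_impv = 0.02, q_mc = 0.25,
         role = "stay"))

  sub1 <- block[1:5]; sub2 <- block[6:10]; sub3 <- block[11:15]
  ov <- function(ids, val) stats::setNames(rep(val, length(ids)), ids)
  # IMPV: one split (two classes), MC: three smaller classes; weighted class
  # prevalences reproduce the 0.30 marginal exactly
  latent <- list(
    IMPV = list(list(weight = 0.5, override = ov(block, 0.45)),
                list(weight = 0.5, override = ov(block, 0.15))),
    MC = list(
      list(weight = 0.4, override = c(ov(sub1, 0.55),
                                      ov(sub2, (0.30 - 0.3 * 0.55) / 0.7),
                                      ov(sub3, (0.30 - 0.3 * 0.55) / 0.7))),
      list(weight = 0.3, override = c(ov(sub1, (0.30 - 0.4 * 0.55) / 0.6),
                                      ov(sub2, 0.55),
                                      ov(sub3, (0.30 - 0.3 * 0.55) / 0.7))),
      list(weight = 0.3, override = c(ov(sub1, (0.30 - 0.4 * 0.55) / 0.6),
                                      ov(sub2, (0.30 - 0.3 * 0.55) / 0.7),
                                      ov(sub3, 0.55)))))

  simulation_scenario(
    catalog = catalog, n_impv = 128L, n_mc = 372L,
    marginal_prevalence = data.frame(id = catalog$id,
                                     p_impv = unname(p_impv),
                                     p_mc = unname(p_mc),
                                     stringsAsFactors = FALSE),
    planted_dyads = planted, latent_classes = latent,
    lab_model = default_lab_model(),
    sex_ratio = c(IMPV = 0.64, MC = 0.47),
    age = list(IMPV = list(mean = 6.07, sd = 2.24),
               MC = list(mean = 7.04, sd = 2.24)),
    rng_seed = rng_seed)
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a cohort from a scenario
#'
#' Deterministic given `scenario$rng_seed` (or the `seed` override).
#' Characteristics are drawn per latent class; planted dyad pairs are drawn
#' jointly from the bivariate Bernoulli cell probabilities implied by their
#' marginals and joint prevalence. Delta-z is drawn per group from a normal
#' truncated at the generating threshold (so group membership and the
#' labeling rule agree), z_exit = z_entry - delta_z, and lab panels are
#' drawn for a random subset with all-three-improvement tied to delta-z.
#'
#' @param scenario a `simulation_scenario`.
#' @param seed optional integer overriding `scenario$rng_seed`.
#' @return List with `cohort` (labeled) and `ground_truth` (class
#'   `ground_truth`): realized per-group prevalences and dyad joint counts
#'   (by direct recount of the emitted cohort), planted dyad directions and
#'   expected designations, the generating threshold, and per-child latent
#'   class assignments.
#' @export
generate_cohort <- function(scenario, seed = scenario$rng_seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(as.integer(seed))
  catalog <- scenario$catalog
  mp <- scenario$marginal_prevalence
  groups <- rep(c("IMPV", "MC"), c(scenario$n_impv, scenario$n_mc))
  n <- length(groups)
  ids <- sprintf("child_%04d", seq_len(n))

  # latent class assignment, then per-child prevalence rows
  class_of <- character(n)
  P <- matrix(0, n, nrow(catalog), dimnames = list(ids, catalog$id))
  for (grp in c("IMPV", "MC")) {
    sel <- which(groups == grp)
    marg <- if (grp == "IMPV") mp$p_impv else mp$p_mc
    Pg <- matrix(marg, length(sel), nrow(catalog), byrow = TRUE)
    colnames(Pg) <- catalog$id
    cls <- scenario$latent_classes[[grp]]
    if (length(cls)) {
      w <- vapply(cls, `[[`, numeric(1), "weight")
      assign_cl <- sample.int(length(cls), length(sel), replace = TRUE, prob = w)
      class_of[sel] <- sprintf("%s_class%d", grp, assign_cl)
      for (ci in seq_along(cls)) {
        ov <- cls[[ci]]$override
        if (length(ov)) {
          rows <- which(assign_cl == ci)
          for (id in names(ov)) Pg[rows, id] <- ov[[id]]
        }
      }
    } else {
      class_of[sel] <- sprintf("%s_class1", grp)
    }
    P[sel, ] <- Pg
  }

  X <- matrix(0L, n, nrow(catalog), dimnames = list(ids, catalog$id))
  X[] <- as.integer(stats::runif(length(P)) < P)

  # impose planted dyads by joint cell draws (common-cause construction)
  for (d in scenario$planted_dyads) {
    i <- d$pair[1]; j <- d$pair[2]
    for (grp in c("IMPV", "MC")) {
      sel <- which(groups == grp)
      pi <- if (grp == "IMPV") mp$p_impv[mp$id == i] else mp$p_mc[mp$id == i]
      pj <- if (grp == "IMPV") mp$p_impv[mp$id == j] else mp$p_mc[mp$id == j]
      q <- if (grp == "IMPV") d$q_impv else d$q_mc
      cells <- c(q, pi - q, pj - q, 1 - pi - pj + q)  # 11, 10, 01, 00
      cells <- pmax(cells, 0)
      draw <- sample.int(4L, length(sel), replace = TRUE, prob = cells)
      X[sel, i] <- as.integer(draw %in% c(1L, 2L))
      X[sel, j] <- as.integer(draw %in% c(1L, 3L))
    }
  }

  # demographics
  sex <- character(n); age <- numeric(n)
  for (grp in c("IMPV", "MC")) {
    sel <- which(groups == grp)
    pm <- scenario$sex_ratio[[grp]]
    sex[sel] <- ifelse(stats::runif(length(sel)) < pm, "male", "female")
    ag <- scenario$age[[grp]]
    age[sel] <- rtruncnorm(length(sel), ag$mean, ag$sd, lower = 0.5)
  }

  # delta-z and z-scores; truncation at the generating threshold keeps group
  # membership consistent with the labeling rule (IMPV iff dz >= threshold)
  lm <- scenario$lab_model
  thr <- lm$threshold
  dz <- numeric(n)
  i1 <- which(groups == "IMPV"); i2 <- which(groups == "MC")
  dz[i1] <- rtruncnorm(length(i1), lm$dz$IMPV$mean, lm$dz$IMPV$sd, lower = thr)
  dz[i2] <- rtruncnorm(length(i2), lm$dz$MC$mean, lm$dz$MC$sd,
                       upper = thr - 1e-9)
  z_entry <- stats::rnorm(n, lm$z_entry$mean, lm$z_entry$sd)
  z_exit <- z_entry - dz

  # labs for a random subset; improvement tied to delta-z
  labs <- matrix(NA_real_, n, 6, dimnames = list(NULL, LAB_COLUMNS))
  with_labs <- stats::runif(n) < lm$completeness
  improved <- rep(NA, n)
  for (k in which(with_labs)) {
    rate <- if (dz[k] >= thr) lm$rate_above else lm$rate_below
    imp <- stats::runif(1) < rate
    improved[k] <- imp
    worsen_analyte <- if (!imp) sample(LAB_ANALYTES, 1) else ""
    for (an in LAB_ANALYTES) {
      b <- lm$baseline[[an]]
      first <- stats::rlnorm(1, b$meanlog, b$sdlog)
      fac <- if (imp) {
        stats::runif(1, lm$improve[1], lm$improve[2])
      } else if (an == worsen_analyte) {
        stats::runif(1, lm$worsen[1], lm$worsen[2])
      } else {
        stats::runif(1, lm$improve[1], lm$worsen[2])
      }
      labs[k, paste0(an, "_first")] <- first
      labs[k, paste0(an, "_last")] <- first * fac
    }
  }

  data <- data.frame(child_id = ids, sex = sex, age_years = age,
                     z_bmi_entry = z_entry, z_bmi_exit = z_exit,
                     stringsAsFactors = FALSE)
  data <- cbind(data, as.data.frame(labs))
  coh <- cohort(catalog, data, X,
                outcome = stats::setNames(groups, ids))

  # ground truth by direct recount of the emitted cohort
  k_impv <- colSums(X[i1, , drop = FALSE])
  k_mc <- colSums(X[i2, , drop = FALSE])
  dyads <- lapply(scenario$planted_dyads, function(d) {
    joint <- X[, d$pair[1]] & X[, d$pair[2]]
    dir <- if (d$q_impv > d$q_mc) "IMPV" else "MC"
    list(pair = d$pair, q_impv = d$q_impv, q_mc = d$q_mc,
         direction = dir, role = d$role %||% NA_character_,
         k_impv = sum(joint[i1]), k_mc = sum(joint[i2]))
  })
  gt <- structure(list(
    n_impv = scenario$n_impv, n_mc = scenario$n_mc,
    realized_prevalence = data.frame(
      id = catalog$id,
      k_impv = unname(k_impv), k_mc = unname(k_mc),
      p_impv = unname(k_impv) / max(scenario$n_impv, 1),
      p_mc = unname(k_mc) / max(scenario$n_mc, 1),
      stringsAsFactors = FALSE),
    planted_dyads = dyads,
    threshold = thr,
    latent_class = stats::setNames(class_of, ids),
    seed = as.integer(seed)), class = "ground_truth")
  list(cohort = coh, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write scenario / ground truth as JSON
#' @param x a `simulation_scenario` or `ground_truth`.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
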