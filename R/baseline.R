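# Baseline prevalence comparison.
#
# For each characteristic the prevalence within each outcome group is given
# a Beta posterior; the probability that the IMPV prevalence exceeds the MC
# prevalence is the definite integral of the IMPV density against the MC
# distribution function. A standard 2x2-table battery (odds ratio, absolute
# risk reduction, population attributable risk percent) accompanies every
# comparison, oriented so that "exposure" is expression of the characteristic
# and "outcome" is membership in the IMPV group.

#' Beta posterior for a group prevalence
#'
#' Conjugate update of a Beta(a0, b0) prior with k expressed children out of
#' n. The default prior (1, 1) adds one pseudo-count to each cell so the
#' posterior stays proper when a count is zero; Jeffreys (0.5, 0.5) is a
#' common alternative.
#'
#' @param k number of children expressing the characteristic (0 <= k <= n).
#' @param n group size.
#' @param prior length-2 positive numeric `(a0, b0)`.
#' @return Named numeric vector `c(alpha = k + a0, beta = n - k + b0)`.
#' @export
beta_posterior <- function(k, n, prior = c(1, 1)) {
  if (length(prior) != 2L || any(prior <= 0)) {
    stop("prior must be two strictly positive values")
  }
  if (k < 0 || n < 0 || k > n) stop("require 0 <= k <= n")
  c(alpha = unname(k + prior[1]), beta = unname(n - k + prior[2]))
}

#' Probability that one Beta variate exceeds another
#'
#' Computes P(X > Y) for X ~ Beta(a) and Y ~ Beta(b) as
#' the integral over (0, 1) of dbeta(x; a) * pbeta(x; b), by adaptive
#' quadrature (absolute accuracy <= 1e-6). This is the probability that a
#' characteristic occurs at higher prevalence in the group whose posterior
#' is `a`.
#'
#' @param a,b length-2 numeric `(alpha, beta)` with both entries positive
#'   and finite.
#' @return Probability in `[0, 1]`.
#' @examples
#' prob_greater(c(2, 1), c(1, 1))  # 2/3 analytically
#' @export
prob_greater <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 2L || length(b) != 2L ||
      any(!is.finite(c(a, b))) || any(c(a, b) <= 0)) {
    stop("prob_greater needs finite positive (alpha, beta) pairs")
  }
  f <- function(x) stats::dbeta(x, a[1], a[2]) * stats::pbeta(x, b[1], b[2])
  # bracket to where dbeta(a) carries mass so adaptive quadrature cannot
  # step over a sharp posterior peak at large n; the discarded tails hold
  # < 2e-14 of the integral
  lo <- stats::qbeta(1e-14, a[1], a[2])
  hi <- stats::qbeta(1e-14, a[1], a[2], lower.tail = FALSE)
  val <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-9,
                          subdivisions = 1000L, stop.on.error = FALSE)$value
  # mass of A below lo counts (almost surely) as X < Y only when B sits
  # above it; the correction is bounded by 1e-14 either way — ignore
  min(max(val, 0), 1)
}

#' 2x2 contingency table for one characteristic against outcome
#'
#' @param a expressed and IMPV; @param b expressed and MC;
#' @param c_ not expressed and IMPV; @param d not expressed and MC.
#' @return Named integer vector of class `pc_contingency`.
#' @export
contingency_table <- function(a, b, c_, d) {
  v <- c(a = a, b = b, c = c_, d = d)
  if (any(v < 0) || any(v != round(v))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(v, class = "pc_contingency")
}

#' Epidemiological statistics from a 2x2 table
#'
#' Exposure = characteristic expressed; outcome = IMPV. Reports the odds
#' ratio (a*d)/(b*c), the absolute risk reduction
#' ARR = a/(a+b) - c/(c+d) (risk of IMPV among expressed minus among
#' not-expressed), and the population attributable risk percent
#' PAR% = 100 * (overall - risk_unexposed)/overall with
#' overall = (a+c)/(a+b+c+d). When any cell is zero the Haldane-Anscombe
#' correction (+0.5 to every cell) is applied before all three statistics and
#' flagged.
#'
#' @param t a `pc_contingency` from [contingency_table()].
#' @return List `odds_ratio`, `arr`, `par_pct`, `correction_applied`.
#' @export
epi_stats <- function(t) {
  stopifnot(inherits(t, "pc_contingency"))
  v <- as.numeric(t)
  if (v[1] + v[3] == 0) {
    pc_error("pc_undefined_par_error",
             "no IMPV children at all: PAR%% undefined")
  }
  correction <- any(v == 0)
  if (correction) v <- v + 0.5
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  risk_exposed <- a / (a + b)
  risk_unexposed <- cc / (cc + d)
  overall <- (a + cc) / sum(v)
  list(odds_ratio = (a * d) / (b * cc),
       arr = risk_exposed - risk_unexposed,
       par_pct = 100 * (overall - risk_unexposed) / overall,
       correction_applied = correction)
}

#' Bayesian baseline scan over all characteristics
#'
#' For every catalog characteristic of a labeled cohort, computes the
#' per-group Beta posteriors, the probability of higher prevalence in the
#' IMPV group, and the epidemiological statistics. Characteristics whose
#' probability reaches `min_prob` toward IMPV or `1 - min_prob` toward MC
#' are flagged as baseline-leaning.
#'
#' @param x a labeled `cohort` with both groups nonempty.
#' @param prior Beta prior, default `c(1, 1)`.
#' @param min_prob flagging threshold, default 0.9 (so probabilities <= 0.1
#'   flag an MC lean by conservation of probability).
#' @return data.frame of class `baseline_result`, one row per characteristic:
#'   counts `a`,`b`,`c`,`d`, posterior parameters, `p_higher_impv`,
#'   `odds_ratio`, `arr`, `par_pct`, `correction_applied`, `flag`
#'   (`"IMPV"`, `"MC"` or `""`).
#' @export
baseline_scan <- function(x, prior = c(1, 1), min_prob = 0.9) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$outcome)) pc_error("pc_unlabeled_error", "cohort is unlabeled")
  impv <- x$characteristics[group_ids(x, "IMPV"), , drop = FALSE]
  mc <- x$characteristics[group_ids(x, "MC"), , drop = FALSE]
  n1 <- nrow(impv); n2 <- nrow(mc)
  if (n1 == 0L || n2 == 0L) {
    pc_error("pc_validation_error", "both outcome groups must be nonempty")
  }
  k1 <- colSums(impv); k2 <- colSums(mc)
  rows <- lapply(seq_along(x$catalog$id), function(i) {
    pa <- beta_posterior(k1[i], n1, prior)
    pb <- beta_posterior(k2[i], n2, prior)
    p <- prob_greater(pa, pb)
    tab <- contingency_table(k1[i], k2[i], n1 - k1[i], n2 - k2[i])
    e <- epi_stats(tab)
    data.frame(id = x$catalog$id[i], source = x$catalog$source[i],
               a = k1[i], b = k2[i], c = n1 - k1[i], d = n2 - k2[i],
               alpha_impv = pa[["alpha"]], beta_impv = pa[["beta"]],
               alpha_mc = pb[["alpha"]], beta_mc = pb[["beta"]],
               p_higher_impv = p,
               odds_ratio = e$odds_ratio, arr = e$arr, par_pct = e$par_pct,
               correction_applied = e$correction_applied,
               flag = if (p >= min_prob) "IMPV"
                      else if (p <= 1 - min_prob) "MC" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_impv") <- n1
  attr(out, "n_mc") <- n2
  attr(out, "prior") <- prior
  attr(out, "min_prob") <- min_prob
  class(out) <- c("baseline_result", "data.frame")
  out
}

#' Write a baseline (or interaction) result table
#'
#' @param x a data.frame result.
#' @param path destination; `.json` selects JSON, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  df <- as.data.frame(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
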