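# Seeded dyadic and triadic interaction screening.
#
# Screening is restricted to tuples containing a seed — a characteristic
# whose baseline probability of higher prevalence in one outcome reaches the
# 90% rule — to limit spurious relations. Each tuple is treated as a single
# entity (a child expresses it only by expressing every member), compared
# between groups exactly as in the baseline scan, and designated Stay when
# the entity leans the same way as its seed at the probability threshold,
# Swap when it leans the opposite way, and Discarded otherwise: either for
# rarity — five or fewer total occurrences summed across both groups — or
# as indeterminate when neither direction reaches the threshold.

#' Select seed characteristics from a baseline scan
#'
#' @param baseline a `baseline_result` from [baseline_scan()].
#' @param min_prob probability threshold, default 0.9; a characteristic
#'   seeds toward IMPV when `p_higher_impv >= min_prob` and toward MC when
#'   `p_higher_impv <= 1 - min_prob` (by conservation of probability a 10%
#'   IMPV probability is a 90% MC probability).
#' @return data.frame `id`, `direction`, `baseline_prob`.
#' @export
select_seeds <- function(baseline, min_prob = 0.9) {
  stopifnot(is.data.frame(baseline), nrow(baseline) > 0)
  p <- baseline$p_higher_impv
  sel <- p >= min_prob | p <= 1 - min_prob
  data.frame(id = baseline$id[sel],
             direction = ifelse(p[sel] >= min_prob, "IMPV", "MC"),
             baseline_prob = p[sel],
             stringsAsFactors = FALSE)
}

#' Per-group co-occurrence counts for a characteristic tuple
#'
#' @param x a labeled `cohort`.
#' @param members character vector of 1-3 catalog ids; a child counts when
#'   expressing every member (child and guardian characteristics may mix).
#' @return List `k_impv`, `n_impv`, `k_mc`, `n_mc`.
#' @export
tuple_prevalence <- function(x, members) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$outcome)) pc_error("pc_unlabeled_error", "cohort is unlabeled")
  unknown <- setdiff(members, x$catalog$id)
  if (length(unknown)) {
    pc_error("pc_validation_error", "unknown characteristic id: %s",
             paste(unknown, collapse = ", "))
  }
  expr <- rowSums(x$characteristics[, members, drop = FALSE]) == length(members)
  impv <- group_ids(x, "IMPV"); mc <- group_ids(x, "MC")
  list(k_impv = sum(expr[impv]), n_impv = length(impv),
       k_mc = sum(expr[mc]), n_mc = length(mc))
}

#' Classify one seeded tuple as Stay / Swap / Discarded
#'
#' @param seed one row of a [select_seeds()] result (or a list with `id`,
#'   `direction`).
#' @param counts output of [tuple_prevalence()].
#' @param prior Beta prior shared with the baseline scan.
#' @param min_prob probability threshold, default 0.9.
#' @param min_occurrences minimum total occurrences to keep a tuple,
#'   default 6: a tuple occurring five or fewer times across both groups is
#'   discarded as too rare to trust.
#' @return List of class `interaction_result` with the tuple's counts,
#'   `p_higher_impv`, `designation` (`"Stay"`, `"Swap"`, `"Discarded"`),
#'   `discard_reason` (`"rarity"`, `"indeterminate"` or `NA`) and the
#'   epidemiological statistics of the tuple entity.
#' @export
classify_interaction <- function(seed, counts, prior = c(1, 1),
                                 min_prob = 0.9, min_occurrences = 6L) {
  total <- counts$k_impv + counts$k_mc
  tab <- contingency_table(counts$k_impv, counts$k_mc,
                           counts$n_impv - counts$k_impv,
                           counts$n_mc - counts$k_mc)
  e <- epi_stats(tab)
  p <- prob_greater(beta_posterior(counts$k_impv, counts$n_impv, prior),
                    beta_posterior(counts$k_mc, counts$n_mc, prior))
  if (total < min_occurrences) {
    desig <- "Discarded"; reason <- "rarity"
  } else if (p >= min_prob || p <= 1 - min_prob) {
    tuple_dir <- if (p >= min_prob) "IMPV" else "MC"
    desig <- if (tuple_dir == seed$direction) "Stay" else "Swap"
    reason <- NA_character_
  } else {
    desig <- "Discarded"; reason <- "indeterminate"
  }
  structure(list(seed_id = seed$id, seed_direction = seed$direction,
                 k_impv = counts$k_impv, k_mc = counts$k_mc,
                 n_impv = counts$n_impv, n_mc = counts$n_mc,
                 total_occurrences = total, p_higher_impv = p,
                 designation = desig, discard_reason = reason,
                 odds_ratio = e$odds_ratio, arr = e$arr,
                 par_pct = e$par_pct,
                 correction_applied = e$correction_applied),
            class = "interaction_result")
}

# vectorized classification shared by dyad_scan / triad_scan; must agree
# with classify_interaction row by row (asserted in the test suite)
classify_scan <- function(members, seed_id, seed_dir, k1, k2, n1, n2,
                          prior, min_prob, min_occurrences) {
  p <- vapply(seq_along(k1), function(i) {
    prob_greater(beta_posterior(k1[i], n1, prior),
                 beta_posterior(k2[i], n2, prior))
  }, numeric(1))
  total <- k1 + k2
  a <- k1; b <- k2; cc <- n1 - k1; d <- n2 - k2
  corr <- a == 0 | b == 0 | cc == 0 | d == 0
  a <- a + 0.5 * corr; b <- b + 0.5 * corr
  cc <- cc + 0.5 * corr; d <- d + 0.5 * corr
  risk_exp <- a / (a + b); risk_unexp <- cc / (cc + d)
  overall <- (a + cc) / (a + b + cc + d)
  desig <- ifelse(total < min_occurrences, "Discarded",
           ifelse(p >= min_prob,
                  ifelse(seed_dir == "IMPV", "Stay", "Swap"),
           ifelse(p <= 1 - min_prob,
                  ifelse(seed_dir == "MC", "Stay", "Swap"),
                  "Discarded")))
  reason <- ifelse(total < min_occurrences, "rarity",
            ifelse(desig == "Discarded", "indeterminate", ""))
  out <- data.frame(members = members, seed = seed_id,
                    seed_direction = seed_dir,
                    k_impv = k1, k_mc = k2,
                    total_occurrences = total, p_higher_impv = p,
                    designation = desig, discard_reason = reason,
                    odds_ratio = (a * d) / (b * cc),
                    arr = risk_exp - risk_unexp,
                    par_pct = 100 * (overall - risk_unexp) / overall,
                    correction_applied = corr,
                    stringsAsFactors = FALSE)
  key <- vapply(strsplit(out$members, "+", fixed = TRUE),
                function(m) paste(sort(m), collapse = "+"), character(1))
  out$duplicate_set <- duplicated(key)
  rownames(out) <- NULL
  class(out) <- c("interaction_scan", "data.frame")
  out
}

scan_groups <- function(x) {
  list(X1 = x$characteristics[group_ids(x, "IMPV"), , drop = FALSE],
       X2 = x$characteristics[group_ids(x, "MC"), , drop = FALSE])
}

#' Dyadic interaction scan
#'
#' Enumerates every (seed, partner) pair, the partner ranging over all other
#' catalog characteristics, and classifies each dyad entity. A seed paired
#' with itself is excluded; when two seeds produce the same member set both
#' rows are kept and the later one is flagged `duplicate_set`.
#'
#' @param x a labeled `cohort`.
#' @param baseline a `baseline_result` for the same cohort.
#' @param prior,min_prob,min_occurrences see [classify_interaction()].
#' @return data.frame of class `interaction_scan`, one row per (seed,
#'   partner), members encoded `"seed+partner"`.
#' @export
dyad_scan <- function(x, baseline, prior = c(1, 1), min_prob = 0.9,
                      min_occurrences = 6L) {
  seeds <- select_seeds(baseline, min_prob)
  if (nrow(seeds) == 0L) {
    warning("no seed characteristics: empty interaction scan")
    return(classify_scan(character(0), character(0), character(0),
                         integer(0), integer(0), 1L, 1L,
                         prior, min_prob, min_occurrences))
  }
  gs <- scan_groups(x)
  C1 <- crossprod(gs$X1); C2 <- crossprod(gs$X2)
  rows <- lapply(seq_len(nrow(seeds)), function(si) {
    sid <- seeds$id[si]
    partners <- setdiff(x$catalog$id, sid)
    list(members = paste(sid, partners, sep = "+"),
         seed = rep(sid, length(partners)),
         dir = rep(seeds$direction[si], length(partners)),
         k1 = C1[sid, partners], k2 = C2[sid, partners])
  })
  classify_scan(unlist(lapply(rows, `[[`, "members")),
                unlist(lapply(rows, `[[`, "seed")),
                unlist(lapply(rows, `[[`, "dir")),
                unname(unlist(lapply(rows, `[[`, "k1"))),
                unname(unlist(lapply(rows, `[[`, "k2"))),
                nrow(gs$X1), nrow(gs$X2),
                prior, min_prob, min_occurrences)
}

#' Triadic interaction scan
#'
#' Extension of the dyad screen to three-characteristic entities: for each
#' seed, every unordered pair of distinct partners is appended and the
#' triple entity is classified under the same probability and rarity rules.
#' (The source analysis describes triads only at a high level; this scan is
#' the natural generalization of its dyad procedure.)
#'
#' @inheritParams dyad_scan
#' @return data.frame of class `interaction_scan`, members encoded
#'   `"seed+p1+p2"`.
#' @export
triad_scan <- function(x, baseline, prior = c(1, 1), min_prob = 0.9,
                       min_occurrences = 6L) {
  seeds <- select_seeds(baseline, min_prob)
  if (nrow(seeds) == 0L) {
    warning("no seed characteristics: empty interaction scan")
    return(classify_scan(character(0), character(0), character(0),
                         integer(0), integer(0), 1L, 1L,
                         prior, min_prob, min_occurrences))
  }
  gs <- scan_groups(x)
  rows <- lapply(seq_len(nrow(seeds)), function(si) {
    sid <- seeds$id[si]
    partners <- setdiff(x$catalog$id, sid)
    if (length(partners) < 2L) return(NULL)
    # co-occurrence of (seed, p1, p2) = pair counts within the children
    # expressing the seed
    T1 <- crossprod(gs$X1[gs$X1[, sid] == 1L, partners, drop = FALSE])
    T2 <- crossprod(gs$X2[gs$X2[, sid] == 1L, partners, drop = FALSE])
    ut <- which(upper.tri(T1), arr.ind = TRUE)
    list(members = paste(sid, partners[ut[, 1]], partners[ut[, 2]],
                         sep = "+"),
         seed = rep(sid, nrow(ut)),
         dir = rep(seeds$direction[si], nrow(ut)),
         k1 = T1[ut], k2 = T2[ut])
  })
  rows <- Filter(Negate(is.null), rows)
  classify_scan(unlist(lapply(rows, `[[`, "members")),
                unlist(lapply(rows, `[[`, "seed")),
                unlist(lapply(rows, `[[`, "dir")),
                unname(unlist(lapply(rows, `[[`, "k1"))),
                unname(unlist(lapply(rows, `[[`, "k2"))),
                nrow(gs$X1), nrow(gs$X2),
                prior, min_prob, min_occurrences)
}

#' Export an interaction scan as an edge list
#'
#' Writes seed-partner edges (dyad scans only) with the Stay/Swap
#' designation as an edge attribute, for external plotting: a tab-separated
#' table and, optionally, GraphML via igraph. By default only tuples that
#' reached the probability threshold are exported, mirroring the inclusion
#' rule of the published dyad figure.
#'
#' @param scan an `interaction_scan` from [dyad_scan()].
#' @param tsv_path destination TSV path (or `NULL` to skip).
#' @param graphml_path destination GraphML path (or `NULL` to skip).
#' @param keep designations to export, default `c("Stay", "Swap")`.
#' @return The exported edge data.frame, invisibly.
#' @export
export_interaction_edges <- function(scan, tsv_path = NULL,
                                     graphml_path = NULL,
                                     keep = c("Stay", "Swap")) {
  stopifnot(inherits(scan, "interaction_scan"))
  rows <- scan[scan$designation %in% keep, , drop = FALSE]
  parts <- strsplit(rows$members, "+", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("edge export is defined for dyad scans only")
  }
  edges <- data.frame(seed = vapply(parts, `[`, character(1), 1L),
                      partner = vapply(parts, `[`, character(1), 2L),
                      designation = rows$designation,
                      p_higher_impv = rows$p_higher_impv,
                      stringsAsFactors = FALSE)
  if (!is.null(tsv_path)) {
    utils::write.table(edges, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(graphml_path) && nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edges)
}
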