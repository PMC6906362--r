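# Cohort container and CSV round-trip.
#
# A cohort is one row per child: demographics, the binary characteristic
# vector from the child's first psychological assessment, entry/exit
# BMI-for-age z-scores, and an optional first/last lab panel (insulin,
# triglycerides, HOMA-IR). Characteristics are stored as a 0/1 matrix with
# one column per catalog id.

LAB_ANALYTES <- c("insulin", "triglycerides", "homa_ir")
LAB_COLUMNS <- as.vector(t(outer(LAB_ANALYTES, c("first", "last"),
                                 paste, sep = "_")))
MANDATORY_COLUMNS <- c("child_id", "sex", "age_years",
                       "z_bmi_entry", "z_bmi_exit")

pc_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "psychcooccur_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Construct a cohort
#'
#' @param catalog a [characteristic_catalog()].
#' @param data data.frame with columns `child_id`, `sex` (`"male"`/`"female"`),
#'   `age_years`, `z_bmi_entry`, `z_bmi_exit`, and (optionally) the six lab
#'   columns `insulin_first`, `insulin_last`, `triglycerides_first`,
#'   `triglycerides_last`, `homa_ir_first`, `homa_ir_last`. A child "has labs"
#'   only when all six values are present and strictly positive.
#' @param characteristics 0/1 matrix, one row per child in `data` order, one
#'   column per catalog id (column names must equal the catalog ids).
#' @param outcome optional named character vector mapping child_id to
#'   `"IMPV"` or `"MC"`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(catalog, data, characteristics, outcome = NULL) {
  stopifnot(inherits(catalog, "characteristic_catalog"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  miss <- setdiff(MANDATORY_COLUMNS, names(data))
  if (length(miss)) {
    pc_error("pc_missing_column_error",
             "cohort data is missing mandatory column(s): %s",
             paste(miss, collapse = ", "))
  }
  data$child_id <- as.character(data$child_id)
  if (anyDuplicated(data$child_id)) {
    pc_error("pc_duplicate_id_error", "duplicate child_id: %s",
             paste(unique(data$child_id[duplicated(data$child_id)]),
                   collapse = ", "))
  }
  if (any(!data$sex %in% c("male", "female"))) {
    pc_error("pc_validation_error", "sex must be 'male' or 'female'")
  }
  if (any(!is.finite(data$age_years)) || any(data$age_years < 0)) {
    pc_error("pc_validation_error", "age_years must be finite and >= 0")
  }
  for (zc in c("z_bmi_entry", "z_bmi_exit")) {
    if (any(!is.finite(data[[zc]]))) {
      pc_error("pc_validation_error", "%s must be finite for every child", zc)
    }
  }
  for (lc in LAB_COLUMNS) if (is.null(data[[lc]])) data[[lc]] <- NA_real_
  lab_vals <- as.matrix(data[LAB_COLUMNS])
  if (any(!is.na(lab_vals) & lab_vals <= 0)) {
    pc_error("pc_validation_error", "lab values must be strictly positive")
  }

  characteristics <- as.matrix(characteristics)
  if (nrow(characteristics) != nrow(data)) {
    pc_error("pc_validation_error",
             "characteristic matrix has %d rows but cohort has %d children",
             nrow(characteristics), nrow(data))
  }
  if (!identical(colnames(characteristics), catalog$id)) {
    extra <- setdiff(colnames(characteristics), catalog$id)
    if (length(extra)) {
      pc_error("pc_unknown_column_error",
               "characteristic column(s) not in catalog: %s",
               paste(extra, collapse = ", "))
    }
    missc <- setdiff(catalog$id, colnames(characteristics))
    if (length(missc)) {
      pc_error("pc_missing_column_error",
               "missing characteristic column(s): %s",
               paste(missc, collapse = ", "))
    }
    characteristics <- characteristics[, catalog$id, drop = FALSE]
  }
  bad <- !(characteristics == 0 | characteristics == 1) | is.na(characteristics)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    pc_error("pc_nonbinary_cell_error",
             "non-binary characteristic cell at child '%s', column '%s'",
             data$child_id[idx[1]], colnames(characteristics)[idx[2]])
  }
  storage.mode(characteristics) <- "integer"
  rownames(characteristics) <- data$child_id

  obj <- structure(list(catalog = catalog, data = data,
                        characteristics = characteristics, outcome = NULL),
                   class = "cohort")
  if (!is.null(outcome)) obj <- set_outcome_labels(obj, outcome)
  obj
}

#' Attach outcome labels to a cohort
#'
#' @param x a `cohort`.
#' @param labels named character vector (names = child ids, values `"IMPV"`
#'   or `"MC"`); every labeled id must exist in the cohort.
#' @return The labeled cohort.
#' @export
set_outcome_labels <- function(x, labels) {
  stopifnot(inherits(x, "cohort"))
  labels <- stats::setNames(as.character(labels), names(labels))
  unknown <- setdiff(names(labels), x$data$child_id)
  if (length(unknown)) {
    pc_error("pc_validation_error", "labels refer to unknown child_id: %s",
             paste(unknown, collapse = ", "))
  }
  if (any(!labels %in% c("IMPV", "MC"))) {
    pc_error("pc_validation_error", "outcome labels must be 'IMPV' or 'MC'")
  }
  x$outcome <- labels
  x
}

#' Number of children in a cohort
#' @param x a `cohort`.
#' @return Integer count.
#' @export
n_records <- function(x) nrow(x$data)

#' Does each child have a complete lab panel?
#' @param x a `cohort`.
#' @return Logical vector, one element per child.
#' @export
has_labs <- function(x) {
  stopifnot(inherits(x, "cohort"))
  stats::complete.cases(x$data[LAB_COLUMNS])
}

#' Child ids belonging to one outcome group
#' @param x a labeled `cohort`.
#' @param group `"IMPV"` or `"MC"`.
#' @return Character vector of child ids.
#' @export
group_ids <- function(x, group) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$outcome)) pc_error("pc_unlabeled_error", "cohort is unlabeled")
  names(x$outcome)[x$outcome == match.arg(group, c("IMPV", "MC"))]
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d children, %d characteristics%s\n",
              n_records(x), nrow(x$catalog),
              if (is.null(x$outcome)) " (unlabeled)" else
                sprintf(" (IMPV %d / MC %d)", sum(x$outcome == "IMPV"),
                        sum(x$outcome == "MC"))))
  invisible(x)
}

#' Read a cohort from a delimited file
#'
#' The file must have a header naming `child_id`, `sex`, `age_years`,
#' `z_bmi_entry`, `z_bmi_exit`, one 0/1 column for every catalog id, and may
#' carry the six lab columns and an `outcome` column. Any other column is
#' rejected as an unknown characteristic. `.tsv` files are tab-separated,
#' everything else comma-separated (UTF-8, header mandatory).
#'
#' @param path cohort file.
#' @param catalog_path catalog file (see [read_catalog()]), or an already
#'   constructed `characteristic_catalog`.
#' @return A validated `cohort` (labeled when an `outcome` column is present).
#' @export
read_cohort <- function(path, catalog_path) {
  catalog <- if (inherits(catalog_path, "characteristic_catalog"))
    catalog_path else read_catalog(catalog_path)
  if (!file.exists(path)) pc_error("pc_io_error", "cohort file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  known <- c(MANDATORY_COLUMNS, LAB_COLUMNS, "outcome", catalog$id)
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    pc_error("pc_unknown_column_error",
             "unknown characteristic column(s): %s",
             paste(extra, collapse = ", "))
  }
  miss <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(miss)) {
    pc_error("pc_missing_column_error", "missing mandatory column(s): %s",
             paste(miss, collapse = ", "))
  }
  missc <- setdiff(catalog$id, names(df))
  if (length(missc)) {
    pc_error("pc_missing_column_error",
             "missing characteristic column(s): %s",
             paste(missc, collapse = ", "))
  }
  X <- as.matrix(df[catalog$id])
  outcome <- NULL
  if (!is.null(df$outcome)) {
    outcome <- stats::setNames(as.character(df$outcome),
                               as.character(df$child_id))
    outcome <- outcome[!is.na(outcome) & nzchar(outcome)]
    if (length(outcome) == 0L) outcome <- NULL
  }
  cohort(catalog, df[intersect(names(df), c(MANDATORY_COLUMNS, LAB_COLUMNS))],
         X, outcome)
}

#' Write a cohort to a delimited file
#'
#' Inverse of [read_cohort()]: writes demographics, labs (only when at least
#' one child has any lab value), the 0/1 characteristic columns, and an
#' `outcome` column when the cohort is labeled.
#'
#' @param x a `cohort`.
#' @param path destination; `.tsv` selects tabs, otherwise commas.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- x$data[MANDATORY_COLUMNS]
  if (any(!is.na(as.matrix(x$data[LAB_COLUMNS])))) {
    df <- cbind(df, x$data[LAB_COLUMNS])
  }
  if (!is.null(x$outcome)) {
    df$outcome <- unname(x$outcome[x$data$child_id])
  }
  df <- cbind(df, as.data.frame(x$characteristics))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove characteristics statistically associated with sex
#'
#' Confound control for cohorts where sex is imbalanced between outcome
#' groups: each characteristic's 2x2 table (expressed x sex) is tested with a
#' two-sided Fisher exact test and characteristics with p <= alpha are
#' dropped from the catalog. Characteristics expressed by no child (or by
#' every child) yield a degenerate table; they are retained with p = 1 and
#' listed in the `warnings` element.
#'
#' @param x a `cohort` containing at least one child of each sex.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return List with `retained` (filtered `characteristic_catalog`, original
#'   order preserved), `removed` (data.frame `id`, `p_value`), `p_values`
#'   (named vector over all characteristics) and `warnings` (character).
#' @export
sex_association_filter <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cohort"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  sex <- x$data$sex
  if (length(unique(sex)) < 2L) {
    pc_error("pc_single_sex_error",
             "sex association filter is inapplicable to a single-sex cohort")
  }
  male <- sex == "male"
  warnings <- character()
  p <- vapply(x$catalog$id, function(id) {
    expressed <- x$characteristics[, id] == 1L
    if (all(expressed) || !any(expressed)) {
      warnings <<- c(warnings, sprintf(
        "characteristic '%s' expressed by %s children: degenerate table, p = 1",
        id, if (any(expressed)) "all" else "no"))
      return(1)
    }
    tab <- table(factor(expressed, c(FALSE, TRUE)),
                 factor(male, c(FALSE, TRUE)))
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  removed <- p <= alpha
  list(retained = x$catalog[!removed, , drop = FALSE],
       removed = data.frame(id = x$catalog$id[removed],
                            p_value = unname(p[removed]),
                            stringsAsFactors = FALSE),
       p_values = p,
       warnings = warnings)
}

#' Restrict a cohort to a sub-catalog
#'
#' Drops characteristic columns not present in `catalog` (used after
#' [sex_association_filter()]).
#'
#' @param x a `cohort`.
#' @param catalog a `characteristic_catalog` whose ids are a subset of the
#'   cohort's.
#' @return The restricted `cohort`.
#' @export
restrict_catalog <- function(x, catalog) {
  stopifnot(inherits(x, "cohort"), inherits(catalog, "characteristic_catalog"))
  unknown <- setdiff(catalog$id, x$catalog$id)
  if (length(unknown)) {
    pc_error("pc_validation_error", "catalog ids not in cohort: %s",
             paste(unknown, collapse = ", "))
  }
  x$characteristics <- x$characteristics[, catalog$id, drop = FALSE]
  x$catalog <- catalog
  x
}
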