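#' Characteristic catalog
#'
#' A catalog enumerates the binary psychological characteristics a cohort may
#' express. Each entry has a short unique id, a free-text label, and a source
#' indicating whether the characteristic is expressed by the child or by the
#' child's guardian. The study configuration this package emulates uses 77
#' characteristics: 28 child-expressed and 49 guardian-expressed.
#'
#' @param id character vector of unique, non-empty characteristic ids.
#' @param label character vector of human-readable labels (recycled from id
#'   when omitted).
#' @param source character vector, each element `"child"` or `"guardian"`.
#' @return An object of class `characteristic_catalog`: a data.frame with
#'   columns `id`, `label`, `source`.
#' @examples
#' cat4 <- characteristic_catalog(
#'   id = c("c01", "c02", "g01", "g02"),
#'   source = c("child", "child", "guardian", "guardian")
#' )
#' catalog_counts(cat4)
#' @export
characteristic_catalog <- function(id, label = id, source) {
  id <- as.character(id)
  label <- as.character(label)
  source <- as.character(source)
  if (length(id) == 0L) stop("catalog must contain at least one characteristic")
  if (anyDuplicated(id)) {
    stop("duplicate characteristic ids in catalog: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(id))) stop("catalog ids must be non-empty strings")
  if (length(label) != length(id) || length(source) != length(id)) {
    stop("id, label and source must have equal length")
  }
  bad <- !source %in% c("child", "guardian")
  if (any(bad)) {
    stop("catalog source must be 'child' or 'guardian'; offending ids: ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, label = label, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("characteristic_catalog", "data.frame")
  out
}

#' Count catalog entries by source
#'
#' @param catalog a `characteristic_catalog`.
#' @return Named integer vector with elements `child`, `guardian`, `total`.
#' @export
catalog_counts <- function(catalog) {
  stopifnot(inherits(catalog, "characteristic_catalog"))
  c(child = sum(catalog$source == "child"),
    guardian = sum(catalog$source == "guardian"),
    total = nrow(catalog))
}

#' Read a characteristic catalog from CSV or JSON
#'
#' CSV catalogs need columns `id` and `source` (`label` optional); JSON
#' catalogs are an array of objects with the same fields.
#'
#' @param path file path ending in `.json` for JSON, otherwise parsed as CSV.
#' @return A `characteristic_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  need <- c("id", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$label)) df$label <- df$id
  characteristic_catalog(df$id, df$label, df$source)
}

#' Write a characteristic catalog
#'
#' @param catalog a `characteristic_catalog`.
#' @param path destination path; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "characteristic_catalog"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(catalog), path, auto_unbox = FALSE)
  } else {
    utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.characteristic_catalog <- function(x, ...) {
  n <- catalog_counts(x)
  cat(sprintf("characteristic catalog: %d entries (%d child, %d guardian)\n",
              n[["total"]], n[["child"]], n[["guardian"]]))
  invisible(x)
}
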