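#' Load a condition catalog
#'
#' The catalog is a versioned YAML list of the risk-assessed condition codes
#' plus an "other" extension code for conditions outside the risk set.
#' Conditions entered with the extension code are preserved through parsing
#' and serialization but never drive a rule or a calculator.
#'
#' @param path Path to a catalog YAML file; defaults to the catalog shipped
#'   with the package (27 conditions).
#' @return An object of class `condition_catalog`.
#' @export
load_condition_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "conditions.yaml", package = "fhhrisk", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$conditions) || !length(raw$conditions))
    stop("condition catalog has no conditions: ", path, call. = FALSE)
  df <- do.call(rbind, lapply(raw$conditions, function(x) {
    data.frame(code = x$code, label = x$label,
               sex = if (is.null(x$sex)) "any" else x$sex,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(df$code))
    stop("duplicate condition codes in catalog", call. = FALSE)
  structure(list(version = as.character(raw$version %||% "0"),
                 conditions = df,
                 other_code = raw$other_code %||% "other"),
            class = "condition_catalog")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.condition_catalog <- function(x, ...) {
  cat("<condition_catalog v", x$version, "> ", nrow(x$conditions),
      " conditions (+ extension code '", x$other_code, "')\n", sep = "")
  invisible(x)
}

# Resolve a condition code against the catalog; extension code allowed.
.check_condition <- function(code, catalog) {
  ok <- code %in% c(catalog$conditions$code, catalog$other_code)
  if (!all(ok))
    stop("condition code(s) not in catalog: ",
         paste(unique(code[!ok]), collapse = ", "), call. = FALSE)
  invisible(code)
}

# Default catalog, loaded once per session.
.catalog_cache <- new.env(parent = emptyenv())
default_catalog <- function() {
  if (is.null(.catalog_cache$cat)) .catalog_cache$cat <- load_condition_catalog()
  .catalog_cache$cat
}
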