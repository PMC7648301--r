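#' Relationship vocabulary
#'
#' The closed controlled vocabulary of relationship codes accepted in a
#' pedigree document. Every code maps deterministically to a degree of
#' relationship, a side of the family, a generation index and (for most
#' codes) an implied sex, which is what makes Mendelian expansion of a
#' relationship-coded history unambiguous. Free-text or "other" relatives
#' are rejected rather than guessed.
#'
#' @return Character vector of valid relation codes.
#' @export
relation_codes <- function() rownames(.relation_table)

# One row per code: degree, side, generation (proband = 1, parents = 2,
# grandparents = 3, children = 0, grandchildren = -1), implied sex
# ("" = not implied by the code).
.relation_table <- local({
  m <- rbind(
    self                  = c("SELF", NA,         1L, ""),
    mother                = c("FDR", "maternal",  2L, "female"),
    father                = c("FDR", "paternal",  2L, "male"),
    sister                = c("FDR", NA,          1L, "female"),
    brother               = c("FDR", NA,          1L, "male"),
    daughter              = c("FDR", NA,          0L, "female"),
    son                   = c("FDR", NA,          0L, "male"),
    maternal_grandmother  = c("SDR", "maternal",  3L, "female"),
    maternal_grandfather  = c("SDR", "maternal",  3L, "male"),
    paternal_grandmother  = c("SDR", "paternal",  3L, "female"),
    paternal_grandfather  = c("SDR", "paternal",  3L, "male"),
    maternal_aunt         = c("SDR", "maternal",  2L, "female"),
    maternal_uncle        = c("SDR", "maternal",  2L, "male"),
    paternal_aunt         = c("SDR", "paternal",  2L, "female"),
    paternal_uncle        = c("SDR", "paternal",  2L, "male"),
    niece                 = c("SDR", NA,          0L, "female"),
    nephew                = c("SDR", NA,          0L, "male"),
    granddaughter         = c("SDR", NA,         -1L, "female"),
    grandson              = c("SDR", NA,         -1L, "male"),
    maternal_half_sister  = c("SDR", "maternal",  1L, "female"),
    maternal_half_brother = c("SDR", "maternal",  1L, "male"),
    paternal_half_sister  = c("SDR", "paternal",  1L, "female"),
    paternal_half_brother = c("SDR", "paternal",  1L, "male"),
    maternal_cousin       = c("TDR", "maternal",  1L, ""),
    paternal_cousin       = c("TDR", "paternal",  1L, "")
  )
  data.frame(degree = m[, 1], side = m[, 2],
             generation = as.integer(m[, 3]), implied_sex = m[, 4],
             stringsAsFactors = FALSE)
})

.check_relation <- function(code) {
  if (length(code) != 1L || !is.character(code) || !code %in% rownames(.relation_table))
    stop("unknown relation code: ", paste(code, collapse = ", "), call. = FALSE)
  invisible(code)
}

#' Degree of relationship for a relation code
#'
#' First-degree relatives (FDR) are parents, siblings and children;
#' second-degree (SDR) aunts, uncles, grandparents, nieces, nephews,
#' grandchildren and half-siblings; third-degree (TDR) cousins.
#'
#' @param relation_code A code from [relation_codes()].
#' @return One of `"SELF"`, `"FDR"`, `"SDR"`, `"TDR"`.
#' @export
#' @examples
#' classify_degree("maternal_aunt")  # "SDR"
#' classify_degree("daughter")       # "FDR"
classify_degree <- function(relation_code) {
  .check_relation(relation_code)
  .relation_table[relation_code, "degree"]
}

#' Side of the family implied by a relation code
#'
#' Pure function of the code: `"maternal"`, `"paternal"`, or `NA` when the
#' code does not determine a side (siblings, children, nieces/nephews,
#' grandchildren, self).
#'
#' @inheritParams classify_degree
#' @return `"maternal"`, `"paternal"` or `NA_character_`.
#' @export
relation_side <- function(relation_code) {
  .check_relation(relation_code)
  .relation_table[relation_code, "side"]
}

#' Generation index implied by a relation code
#'
#' Proband = 1, parents/aunts/uncles = 2, grandparents = 3, children and
#' nieces/nephews = 0, grandchildren = -1. Siblings, half-siblings and
#' cousins share the proband's generation.
#'
#' @inheritParams classify_degree
#' @return Integer generation index.
#' @export
relation_generation <- function(relation_code) {
  .check_relation(relation_code)
  .relation_table[relation_code, "generation"]
}

.implied_sex <- function(relation_code) {
  s <- .relation_table[relation_code, "implied_sex"]
  if (identical(s, "")) NA_character_ else s
}

# Singleton slots: at most one record per pedigree may carry these codes.
.singleton_codes <- c("self", "mother", "father",
                      "maternal_grandmother", "maternal_grandfather",
                      "paternal_grandmother", "paternal_grandfather")

# The six relatives every pedigree must contain (parents + grandparents).
.required_codes <- setdiff(.singleton_codes, "self")
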