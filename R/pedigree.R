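#' Build a single relative record
#'
#' One relationship-coded entry in a family health history: who the person
#' is relative to the proband, vital status and ages, twin status, whether
#' their medical history is known, and their conditions with ages of onset.
#'
#' @param relation A code from [relation_codes()].
#' @param sex `"male"`, `"female"` or `NA` (unknown). Codes that imply a sex
#'   (e.g. `mother`) must agree with it; sex is required for entered
#'   relatives whose code does not imply it.
#' @param alive `TRUE`, `FALSE` or `NA` (vital status unknown).
#' @param current_age Age in years if alive (0-120).
#' @param age_at_death,cause_of_death Age and cause if deceased.
#' @param twin_status `"none"`, `"identical"` or `"fraternal"`.
#' @param history_known Whether the relative's medical history is known;
#'   relatives with `history_known = FALSE` carry no phenotype information
#'   in the Mendelian likelihood but preserve transmission structure.
#' @param conditions A list of entries `list(condition = <code>,
#'   age_of_onset = <years or NULL>)`.
#' @param race_ethnicity,ashkenazi,consanguinity Proband-only intake extras.
#' @param catalog Condition catalog used to resolve condition codes.
#' @param extra Named list of unknown fields to preserve on round trip.
#' @return A `relative_record` object.
#' @export
relative_record <- function(relation, sex = NULL, alive = NA,
                            current_age = NULL, age_at_death = NULL,
                            cause_of_death = NULL, twin_status = "none",
                            history_known = TRUE, conditions = list(),
                            race_ethnicity = NULL, ashkenazi = NULL,
                            consanguinity = NULL,
                            catalog = default_catalog(), extra = list()) {
  .check_relation(relation)
  if (is.null(sex)) sex <- NA_character_
  imp <- .implied_sex(relation)
  if (!is.na(imp)) {
    if (is.na(sex)) sex <- imp
    else if (!identical(sex, imp))
      stop("sex '", sex, "' contradicts relation '", relation, "'", call. = FALSE)
  }
  if (!is.na(sex) && !sex %in% c("male", "female"))
    stop("sex must be 'male', 'female' or NA", call. = FALSE)
  if (!twin_status %in% c("none", "identical", "fraternal"))
    stop("invalid twin_status: ", twin_status, call. = FALSE)
  .chk_age <- function(a, what) {
    if (!is.null(a) && (!is.numeric(a) || is.na(a) || a < 0 || a > 120))
      stop(what, " must be in [0, 120]", call. = FALSE)
  }
  .chk_age(current_age, "current_age")
  .chk_age(age_at_death, "age_at_death")
  if (isTRUE(alive) && !is.null(age_at_death))
    stop("living relative cannot have age_at_death", call. = FALSE)
  if (isFALSE(alive) && !is.null(current_age))
    stop("deceased relative cannot have current_age", call. = FALSE)
  if (isTRUE(alive) && is.null(current_age))
    stop("living relative requires current_age", call. = FALSE)
  if (isFALSE(alive) && is.null(age_at_death))
    stop("deceased relative requires age_at_death", call. = FALSE)
  cens <- current_age %||% age_at_death
  conditions <- lapply(conditions, function(ce) {
    if (is.null(ce$condition)) stop("condition entry lacks a code", call. = FALSE)
    .check_condition(ce$condition, catalog)
    onset <- ce$age_of_onset
    if (!is.null(onset)) {
      if (!is.numeric(onset) || is.na(onset) || onset < 0 || onset > 120)
        stop("age_of_onset must be in [0, 120]", call. = FALSE)
      if (!is.null(cens) && onset > cens)
        stop("age_of_onset ", onset, " exceeds age ", cens,
             " for relation '", relation, "'", call. = FALSE)
    }
    list(condition = ce$condition, age_of_onset = onset, label = ce$label)
  })
  structure(list(relation = relation, sex = sex, alive = alive,
                 current_age = current_age, age_at_death = age_at_death,
                 cause_of_death = cause_of_death, twin_status = twin_status,
                 history_known = isTRUE(history_known), conditions = conditions,
                 race_ethnicity = race_ethnicity, ashkenazi = ashkenazi,
                 consanguinity = consanguinity, extra = extra),
            class = "relative_record")
}

#' Assemble a pedigree from a proband record and relatives
#'
#' @param proband A `relative_record` with relation `"self"`.
#' @param relatives List of `relative_record`s.
#' @param version Interchange format version string.
#' @param extra Unknown top-level fields preserved on round trip.
#' @return A `pedigree` object.
#' @export
pedigree <- function(proband, relatives = list(), version = "1.0", extra = list()) {
  stopifnot(inherits(proband, "relative_record"))
  if (!identical(proband$relation, "self"))
    stop("proband record must have relation 'self'", call. = FALSE)
  for (r in relatives) {
    stopifnot(inherits(r, "relative_record"))
    if (identical(r$relation, "self"))
      stop("duplicate 'self' record", call. = FALSE)
  }
  codes <- vapply(relatives, `[[`, "", "relation")
  dup <- intersect(.singleton_codes, codes[duplicated(codes)])
  if (length(dup))
    stop("duplicate singleton slot(s): ", paste(dup, collapse = ", "), call. = FALSE)
  structure(list(proband = proband, relatives = relatives,
                 version = version, extra = extra),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> proband +", length(x$relatives), "relatives\n")
  invisible(x)
}

#' Number of individuals in a pedigree (proband included)
#' @param p A `pedigree`.
#' @return Integer count.
#' @export
pedigree_size <- function(p) 1L + length(p$relatives)

.all_records <- function(p) c(list(p$proband), p$relatives)

# ---- interchange format ----------------------------------------------------

.record_from_json <- function(x, path, catalog) {
  known <- c("relation", "sex", "alive", "current_age", "age_at_death",
             "cause_of_death", "twin_status", "history_known", "conditions",
             "race_ethnicity", "ashkenazi", "consanguinity")
  if (is.null(x$relation))
    stop("schema violation at ", path, ": missing 'relation'", call. = FALSE)
  if (!x$relation %in% relation_codes())
    stop("vocabulary error at ", path, ": unknown relation code '",
         x$relation, "'", call. = FALSE)
  conds <- lapply(x$conditions, function(ce) {
    if (is.null(ce$condition))
      stop("schema violation at ", path, "/conditions: missing 'condition'",
           call. = FALSE)
    ce[intersect(names(ce), c("condition", "age_of_onset", "label"))]
  })
  tryCatch(
    relative_record(
      relation = x$relation,
      sex = x$sex %||% NA_character_,
      alive = if (is.null(x$alive)) NA else isTRUE(x$alive),
      current_age = x$current_age, age_at_death = x$age_at_death,
      cause_of_death = x$cause_of_death,
      twin_status = x$twin_status %||% "none",
      history_known = x$history_known %||% TRUE,
      conditions = conds,
      race_ethnicity = x$race_ethnicity, ashkenazi = x$ashkenazi,
      consanguinity = x$consanguinity, catalog = catalog,
      extra = x[setdiff(names(x), known)]),
    error = function(e)
      stop("schema violation at ", path, ": ", conditionMessage(e), call. = FALSE))
}

#' Parse a pedigree interchange document
#'
#' One JSON document per proband: a `proband` record with relation `"self"`
#' plus a `relatives` array of relationship-coded records. The schema ships
#' with the package (`inst/schema/pedigree-1.0.json`). Parsing is lossless:
#' unknown fields are preserved and `serialize_pedigree(parse_pedigree(d))`
#' is semantically equal to `d`.
#'
#' @param x Path to a JSON file, or a JSON string.
#' @param catalog Condition catalog for resolving condition codes.
#' @return A `pedigree` object.
#' @export
parse_pedigree <- function(x, catalog = default_catalog()) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (is.null(doc$proband))
    stop("schema violation at /proband: missing proband record", call. = FALSE)
  proband <- .record_from_json(doc$proband, "/proband", catalog)
  if (!identical(proband$relation, "self"))
    stop("schema violation at /proband: relation must be 'self'", call. = FALSE)
  rels <- lapply(seq_along(doc$relatives), function(i)
    .record_from_json(doc$relatives[[i]], paste0("/relatives/", i - 1L), catalog))
  known <- c("format", "version", "proband", "relatives")
  pedigree(proband, rels, version = as.character(doc$version %||% "1.0"),
           extra = doc[setdiff(names(doc), known)])
}

.record_to_list <- function(r) {
  out <- list(relation = r$relation)
  if (!is.na(r$sex)) out$sex <- r$sex
  if (!is.na(r$alive)) out$alive <- r$alive
  for (f in c("current_age", "age_at_death", "cause_of_death",
              "race_ethnicity", "ashkenazi", "consanguinity"))
    if (!is.null(r[[f]])) out[[f]] <- r[[f]]
  if (!identical(r$twin_status, "none")) out$twin_status <- r$twin_status
  if (!isTRUE(r$history_known)) out$history_known <- FALSE
  if (length(r$conditions))
    out$conditions <- lapply(r$conditions, function(ce)
      Filter(Negate(is.null), ce))
  c(out, r$extra)
}

#' Serialize a pedigree to interchange JSON
#'
#' @param p A `pedigree`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param pretty Pretty-print the JSON.
#' @return JSON string (invisibly, if written to `path`).
#' @export
serialize_pedigree <- function(p, path = NULL, pretty = TRUE) {
  doc <- c(list(format = "fhh-pedigree", version = p$version,
                proband = .record_to_list(p$proband),
                relatives = lapply(p$relatives, .record_to_list)),
           p$extra)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# ---- validation and quality ------------------------------------------------

#' Check a pedigree against the required-relative contract
#'
#' A pedigree passes when the mother, father and all four grandparents (the
#' six required relatives) are present and all field invariants hold.
#' Missing slots and field errors are the report's content, not exceptions.
#'
#' @param p A `pedigree`.
#' @return A `validation_report`: `passed`, `missing_required_slots`,
#'   `field_errors`.
#' @export
validate_required <- function(p) {
  codes <- vapply(p$relatives, `[[`, "", "relation")
  missing <- setdiff(.required_codes, codes)
  errs <- character()
  for (r in .all_records(p)) {
    if (is.na(r$alive) && is.null(r$current_age) && is.null(r$age_at_death) &&
        isTRUE(r$history_known) && length(r$conditions))
      errs <- c(errs, paste0(r$relation, ": conditions entered without any age/vital status"))
    if (is.na(r$sex))
      errs <- c(errs, paste0(r$relation, ": sex unknown for an entered relative"))
  }
  structure(list(passed = !length(missing) && !length(errs),
                 missing_required_slots = missing, field_errors = errs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> passed:", x$passed, "\n")
  if (length(x$missing_required_slots))
    cat("  missing:", paste(x$missing_required_slots, collapse = ", "), "\n")
  if (length(x$field_errors))
    cat("  errors:", paste(x$field_errors, collapse = "; "), "\n")
  invisible(x)
}

#' Score a family health history against the five quality elements
#'
#' A high-quality history records, for every relative: (1) relationship and
#' sex, (2) side of the family derivable from the relationship, (3) vital
#' status with current age or age and cause of death, (4) all conditions
#' with an age of onset for each, and (5) spans at least three generations
#' (at a minimum parents and grandparents). Each element is evaluated
#' independently; removing information can never turn a false element true.
#'
#' @param p A `pedigree`.
#' @return A `quality_report` with one logical per element plus
#'   `generations_present`.
#' @export
score_quality <- function(p) {
  recs <- .all_records(p)
  rels <- p$relatives
  e1 <- all(vapply(recs, function(r) !is.na(r$sex), TRUE))
  # element 2: every relative whose code can carry a side has one; codes with
  # side NA (siblings, children, ...) do not block it
  e2 <- length(rels) > 0 &&
    any(!is.na(vapply(rels, function(r) relation_side(r$relation), "")))
  e3 <- all(vapply(recs, function(r)
    (isTRUE(r$alive) && !is.null(r$current_age)) ||
    (isFALSE(r$alive) && !is.null(r$age_at_death) && !is.null(r$cause_of_death)),
    TRUE))
  n_cond <- sum(vapply(recs, function(r) length(r$conditions), 0L))
  e4 <- n_cond > 0 && all(vapply(recs, function(r)
    all(vapply(r$conditions, function(ce) !is.null(ce$age_of_onset), TRUE)), TRUE))
  gens <- unique(vapply(recs, function(r) relation_generation(r$relation), 0L))
  structure(list(element_1_relationship_and_gender = e1,
                 element_2_side_of_family = e2,
                 element_3_vital_status_and_ages = e3,
                 element_4_conditions_with_onset = e4,
                 element_5_three_generations = length(gens) >= 3L,
                 generations_present = length(gens)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  for (n in names(x)) cat(" ", n, ":", x[[n]], "\n")
  invisible(x)
}
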