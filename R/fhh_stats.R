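# Cohort-level family-health-history descriptive statistics: the two
# clustering measures (proportion of affected families; mean within-family
# affected proportion among affected families), relative-count profiles by
# degree, data-completeness fractions, and Patient Activation Measure
# levels.

.family_affected <- function(p, condition) {
  vapply(.all_records(p), function(r)
    any(vapply(r$conditions, function(ce)
      identical(ce$condition, condition), TRUE)), TRUE)
}

#' Proportion of families with at least one affected member
#'
#' A family counts as affected when any individual — proband included —
#' carries the condition.
#'
#' @param cohort List of `pedigree`s.
#' @param condition Condition code.
#' @param catalog Condition catalog (code resolution).
#' @return Proportion in `[0, 1]`.
#' @export
affected_families <- function(cohort, condition, catalog = default_catalog()) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  .check_condition(condition, catalog)
  mean(vapply(cohort, function(p) any(.family_affected(p, condition)), TRUE))
}

#' Within-family affected proportion among affected families
#'
#' For each family with at least one affected member, the proportion of
#' its members (proband included in the denominator) with the condition;
#' summarised as mean and SD across those families. With no affected
#' family the result is flagged undefined rather than returned as a
#' number.
#'
#' @inheritParams affected_families
#' @return List: `mean`, `sd` (0 for a single affected family),
#'   `n_affected_families`, `defined`.
#' @export
within_family <- function(cohort, condition, catalog = default_catalog()) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  .check_condition(condition, catalog)
  props <- unlist(lapply(cohort, function(p) {
    aff <- .family_affected(p, condition)
    if (!any(aff)) return(NULL)
    sum(aff) / length(aff)
  }))
  if (!length(props))
    return(list(mean = NA_real_, sd = NA_real_, n_affected_families = 0L,
                defined = FALSE))
  list(mean = mean(props),
       sd = if (length(props) > 1L) stats::sd(props) else 0,
       n_affected_families = length(props), defined = TRUE)
}

#' Relative-count profile of a cohort by degree
#'
#' Per-family counts of first-, second- and third-degree relatives, with
#' cohort mean/SD/range of family size (proband included), the percentage
#' of entered relatives at each degree, conditions per relative by degree,
#' and the fraction of relatives with known history by degree.
#'
#' @param cohort List of `pedigree`s.
#' @return List of summaries; `per_family` holds the raw count table.
#' @export
relative_profile <- function(cohort) {
  per <- do.call(rbind, lapply(cohort, function(p) {
    degs <- vapply(p$relatives, function(r) classify_degree(r$relation), "")
    data.frame(size = pedigree_size(p),
               FDR = sum(degs == "FDR"), SDR = sum(degs == "SDR"),
               TDR = sum(degs == "TDR"))
  }))
  by_degree <- function(f) {
    vals <- list(FDR = c(), SDR = c(), TDR = c())
    for (p in cohort) for (r in p$relatives) {
      d <- classify_degree(r$relation)
      vals[[d]] <- c(vals[[d]], f(r))
    }
    vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 0)
  }
  n_rel <- sum(per$FDR + per$SDR + per$TDR)
  list(per_family = per,
       family_size = list(mean = mean(per$size), sd = stats::sd(per$size),
                          range = range(per$size)),
       degree_means = list(
         FDR = c(mean = mean(per$FDR), sd = stats::sd(per$FDR)),
         SDR = c(mean = mean(per$SDR), sd = stats::sd(per$SDR)),
         TDR = c(mean = mean(per$TDR), sd = stats::sd(per$TDR))),
       degree_percent = if (n_rel > 0)
         100 * c(FDR = sum(per$FDR), SDR = sum(per$SDR), TDR = sum(per$TDR)) / n_rel
       else c(FDR = 0, SDR = 0, TDR = 0),
       history_known_fraction = by_degree(function(r) as.numeric(r$history_known)),
       conditions_per_relative = by_degree(function(r)
         if (r$history_known) length(r$conditions) else NA_real_))
}

.pam_cache <- new.env(parent = emptyenv())
.pam_cuts <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pam_cache$cuts))
      .pam_cache$cuts <- unlist(yaml::read_yaml(system.file(
        "extdata", "pam_levels.yaml", package = "fhhrisk",
        mustWork = TRUE))$cut_points)
    .pam_cache$cuts
  } else unlist(yaml::read_yaml(path)$cut_points)
}

#' Patient Activation Measure ordinal level
#'
#' Converts a raw 0-100 activation score to the 4-level ordinal scale
#' (1 = least activated, 4 = most activated) using configured cut points
#' with inclusive upper bounds.
#'
#' @param raw_score Numeric score(s) in `[0, 100]`.
#' @param cut_points Three increasing upper bounds for levels 1-3.
#' @return Integer level(s) in 1-4.
#' @export
pam_level <- function(raw_score, cut_points = .pam_cuts()) {
  if (any(is.na(raw_score)) || any(raw_score < 0 | raw_score > 100))
    stop("PAM raw score out of [0, 100]", call. = FALSE)
  vapply(raw_score, function(s) 1L + sum(s > cut_points), 0L)
}

#' Cohort summary of family-health-history structure and clustering
#'
#' Assembles, for a cohort of pedigrees: the affected-families and
#' within-family clustering statistics per condition, the relative-count
#' profile by degree, the fraction of condition entries with a recorded
#' onset, and (optionally) the PAM level distribution.
#'
#' @param cohort List of `pedigree`s.
#' @param conditions Condition codes to summarise (default: all catalog
#'   codes present in the cohort).
#' @param pam_scores Optional numeric vector of raw PAM scores.
#' @param catalog Condition catalog.
#' @return A `cohort_summary` object; `$conditions` is a per-condition
#'   data frame with `affected_families`, `within_family_mean`,
#'   `within_family_sd`.
#' @export
cohort_summary <- function(cohort, conditions = NULL, pam_scores = NULL,
                           catalog = default_catalog()) {
  if (is.null(conditions)) {
    present <- unique(unlist(lapply(cohort, function(p)
      unlist(lapply(.all_records(p), function(r)
        vapply(r$conditions, `[[`, "", "condition"))))))
    conditions <- intersect(catalog$conditions$code, present)
  }
  cond_tab <- do.call(rbind, lapply(conditions, function(cc) {
    wf <- within_family(cohort, cc, catalog)
    data.frame(condition = cc,
               affected_families = affected_families(cohort, cc, catalog),
               within_family_mean = wf$mean, within_family_sd = wf$sd,
               stringsAsFactors = FALSE)
  }))
  onsets <- unlist(lapply(cohort, function(p)
    unlist(lapply(.all_records(p), function(r)
      vapply(r$conditions, function(ce) !is.null(ce$age_of_onset), TRUE)))))
  pam <- if (!is.null(pam_scores)) {
    lv <- pam_level(pam_scores)
    tabulate(lv, nbins = 4L)
  }
  structure(list(n_families = length(cohort),
                 conditions = cond_tab,
                 relatives = relative_profile(cohort),
                 onset_recorded_fraction =
                   if (length(onsets)) mean(onsets) else NA_real_,
                 pam_level_counts = pam),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_families, "families; family size mean",
      round(x$relatives$family_size$mean, 1), "\n")
  if (!is.null(x$conditions)) print(x$conditions, row.names = FALSE)
  invisible(x)
}
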