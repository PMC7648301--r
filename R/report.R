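#' Render a structured risk-assessment report
#'
#' Produces the machine-readable (JSON) and human-readable (text) report
#' for one proband: every calculator's score or its not-calculated reason,
#' every triggered recommendation with tier, citation and evidence, and
#' the rules that could not be evaluated. Field order is stable and the
#' output is byte-identical for identical inputs.
#'
#' @param profile A `risk_profile`.
#' @param scores Named list of `risk_score`s (as from [assess_all()]).
#' @param evaluation A `rule_evaluation` (from [evaluate_rules()]).
#' @param catalog_version Rule catalog version string to stamp.
#' @return An `assessment_report`: list with `json` (string) and `text`
#'   (character vector of lines).
#' @export
render_report <- function(profile, scores, evaluation,
                          catalog_version = evaluation$catalog_version) {
  score_block <- lapply(scores, function(s) {
    if (identical(s$status, "computed"))
      list(status = "computed", value_percent = s$value, horizon = s$horizon)
    else
      list(status = "not_calculated", horizon = s$horizon,
           missing_inputs = as.list(s$missing_inputs),
           reason = s$reason %||% "missing_inputs")
  })
  rec_block <- lapply(evaluation$recommendations, function(r)
    list(rule_id = r$rule_id, tier = r$tier, title = r$title,
         recommendation = r$recommendation, citation = r$citation,
         evidence = lapply(r$evidence, function(e)
           list(variable = e$variable, observed = e$observed,
                comparator = e$comparator, threshold = e$threshold))))
  ts <- tier_summary(evaluation)
  doc <- list(
    report_version = "1.0",
    catalog_version = catalog_version,
    proband = list(age = profile$age, sex = profile$sex),
    risk_scores = score_block,
    recommendations = rec_block,
    not_evaluable_rules = as.list(evaluation$not_evaluable),
    tier_counts = as.list(ts$counts),
    total_recommendations = ts$total)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")

  txt <- c("RISK ASSESSMENT REPORT",
           sprintf("Proband: %s, age %s", profile$sex %||% "?",
                   format(profile$age)),
           "", "Risk calculator results:")
  for (nm in names(scores)) {
    s <- scores[[nm]]
    txt <- c(txt, if (identical(s$status, "computed"))
      sprintf("  %-14s %6.2f%%  (%s)", nm, s$value, s$horizon)
    else
      sprintf("  %-14s not calculated (%s)", nm,
              if (length(s$missing_inputs))
                paste("missing:", paste(s$missing_inputs, collapse = ", "))
              else s$reason %||% "ineligible"))
  }
  txt <- c(txt, "", "Recommendations:")
  if (!length(evaluation$recommendations)) {
    txt <- c(txt, "  None of the elevated-risk criteria were met.")
  } else {
    for (r in evaluation$recommendations) {
      txt <- c(txt, sprintf("  [%s] %s", r$tier, r$title),
               sprintf("      %s", r$recommendation),
               sprintf("      Why: %s", paste(vapply(r$evidence, function(e)
                 sprintf("%s %s %s (observed %s)", e$variable, e$comparator,
                         format(e$threshold), format(e$observed)), ""),
                 collapse = "; ")))
    }
  }
  if (length(evaluation$not_evaluable))
    txt <- c(txt, "", paste("Not evaluable (missing inputs):",
                            paste(evaluation$not_evaluable, collapse = ", ")))
  structure(list(json = js, text = txt), class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
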