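# Three-tier guideline rule engine. Predicates are a small declarative
# condition language (nested all:/any: over comparison leaves on declared
# variables and pedigree aggregate counts) — no general scripting, so every
# fired rule can replay its evidence. Evaluation is three-valued: a leaf on
# an unknown input is "unknown", and a rule that cannot be decided is
# reported "not evaluable", distinct from "not met".

.rule_tiers <- c("monogenic", "familial", "common")
.rule_ops <- c(">", ">=", "<", "<=", "==", "!=")
.score_ids <- c("gail", "tyrer_cuzick", "brcapro", "framingham", "reynolds", "pce")

.declared_vars <- function() {
  c(paste0("profile.", setdiff(names(formals(risk_profile)), "")),
    "derived.bmi", "pedigree.ashkenazi", "pedigree.consanguinity",
    paste0("score.", .score_ids))
}

.validate_predicate <- function(pred, rule_id, catalog_conditions) {
  err <- function(...) stop("rule '", rule_id, "': ", ..., call. = FALSE)
  if (!is.list(pred)) err("predicate is not a mapping")
  keys <- names(pred)
  if ("all" %in% keys || "any" %in% keys) {
    if (length(keys) != 1L) err("combinator node must have exactly one key")
    kids <- pred[[keys]]
    if (!is.list(kids) || !length(kids)) err("empty '", keys, "' node")
    for (k in kids) .validate_predicate(k, rule_id, catalog_conditions)
    return(invisible(TRUE))
  }
  if (!all(c("op", "value") %in% keys)) err("leaf lacks op/value")
  if (!pred$op %in% .rule_ops)
    err("unknown comparator token '", pred$op, "'")
  if (!is.null(pred$var)) {
    if (!pred$var %in% .declared_vars())
      err("undeclared variable '", pred$var, "'")
  } else if (!is.null(pred$count)) {
    cnt <- pred$count
    bad <- setdiff(names(cnt), c("conditions", "degrees", "sides", "sexes",
                                 "onset_max", "onset_min"))
    if (length(bad)) err("unknown aggregate field '", bad[1], "'")
    if (is.null(cnt$conditions)) err("aggregate lacks conditions")
    unknown <- setdiff(unlist(cnt$conditions), catalog_conditions)
    if (length(unknown)) err("undeclared condition '", unknown[1], "'")
    if (!is.null(cnt$degrees) &&
        length(setdiff(unlist(cnt$degrees), c("SELF", "FDR", "SDR", "TDR"))))
      err("invalid degree filter")
    if (!is.null(cnt$sides) &&
        length(setdiff(unlist(cnt$sides), c("maternal", "paternal"))))
      err("invalid side filter")
  } else err("leaf lacks var/count")
  invisible(TRUE)
}

#' Load and validate a rule catalog
#'
#' Parses a YAML rule catalog, checks tier labels, unique rule ids, and the
#' predicate language (comparators, declared variables, aggregate filters,
#' condition codes) at load time — an undeclared variable is a load error,
#' never an evaluation-time surprise.
#'
#' @param path Catalog YAML; default is the shipped three-tier catalog
#'   covering genetic-counseling referrals (hereditary cardiac, HBOC,
#'   Lynch, FAP, PTEN, thrombophilia, FH, hemochromatosis, Wilson's,
#'   alpha-1), familial surveillance (ovarian discussion, breast MRI,
#'   chemoprevention, early colonoscopy) and common-disease screening
#'   (aspirin, diabetes, AAA, calcium-score CT, lung cancer).
#' @param catalog Condition catalog used to resolve condition codes.
#' @return A `rule_catalog`.
#' @export
load_rule_catalog <- function(path = NULL, catalog = default_catalog()) {
  if (is.null(path))
    path <- system.file("extdata", "rules_default.yaml", package = "fhhrisk",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  rules <- raw$rules
  if (!length(rules)) rules <- list()
  ids <- vapply(rules, function(r) r$id %||% "", "")
  if (any(ids == "")) stop("rule without id in ", path, call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate rule id: ", ids[duplicated(ids)][1], call. = FALSE)
  cond_codes <- catalog$conditions$code
  for (r in rules) {
    if (is.null(r$tier) || !r$tier %in% .rule_tiers)
      stop("rule '", r$id, "': invalid tier", call. = FALSE)
    if (is.null(r$predicate))
      stop("rule '", r$id, "': missing predicate", call. = FALSE)
    .validate_predicate(r$predicate, r$id, cond_codes)
  }
  structure(list(version = as.character(raw$version %||% "0"),
                 name = raw$name %||% "catalog",
                 strategy_count = raw$strategy_count,
                 rules = rules),
            class = "rule_catalog")
}

#' @export
print.rule_catalog <- function(x, ...) {
  tiers <- table(factor(vapply(x$rules, `[[`, "", "tier"), .rule_tiers))
  cat("<rule_catalog '", x$name, "' v", x$version, "> ", length(x$rules),
      " rules (", paste(names(tiers), tiers, sep = ": ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# ---- evaluation ------------------------------------------------------------

#' Does an observed value satisfy a comparison?
#'
#' The single comparison primitive of the rule language; exposed so
#' threshold boundary semantics (strict `>` vs inclusive `>=` etc.) can be
#' probed directly at cutoff - eps / cutoff / cutoff + eps.
#'
#' @param op Comparator token (`>`, `>=`, `<`, `<=`, `==`, `!=`).
#' @param observed Observed value (`NA` = unknown).
#' @param threshold Threshold from the rule.
#' @return `TRUE`, `FALSE`, or `NA` when the input is unknown.
#' @export
leaf_satisfied <- function(op, observed, threshold) {
  if (is.null(observed) || (length(observed) == 1L && is.na(observed)))
    return(NA)
  switch(op,
    ">"  = observed >  threshold,
    ">=" = observed >= threshold,
    "<"  = observed <  threshold,
    "<=" = observed <= threshold,
    "==" = identical(observed, threshold) || isTRUE(observed == threshold),
    "!=" = !(identical(observed, threshold) || isTRUE(observed == threshold)),
    stop("unknown comparator: ", op, call. = FALSE))
}

#' Aggregate count of affected individuals in a pedigree
#'
#' Counts individuals (the proband counts only under the `SELF` degree)
#' affected by any of the given conditions, filtered by degree, side of
#' family, sex, and onset bounds. Condition entries without a recorded
#' onset are excluded from onset-filtered counts; an individual is counted
#' once however many qualifying entries they carry.
#'
#' @param pedigree A `pedigree`.
#' @param conditions Condition codes (any-of).
#' @param degrees,sides,sexes Optional filters.
#' @param onset_max,onset_min Optional onset bounds (inclusive).
#' @return Integer count.
#' @export
count_affected <- function(pedigree, conditions, degrees = NULL, sides = NULL,
                           sexes = NULL, onset_max = NULL, onset_min = NULL) {
  hits <- vapply(.all_records(pedigree), function(r) {
    deg <- classify_degree(r$relation)
    if (!is.null(degrees) && !deg %in% degrees) return(FALSE)
    if (!is.null(sides)) {
      sd <- relation_side(r$relation)
      if (is.na(sd) || !sd %in% sides) return(FALSE)
    }
    if (!is.null(sexes) && (is.na(r$sex) || !r$sex %in% sexes)) return(FALSE)
    any(vapply(r$conditions, function(ce) {
      if (!ce$condition %in% conditions) return(FALSE)
      if (!is.null(onset_max) || !is.null(onset_min)) {
        if (is.null(ce$age_of_onset)) return(FALSE)
        if (!is.null(onset_max) && ce$age_of_onset > onset_max) return(FALSE)
        if (!is.null(onset_min) && ce$age_of_onset < onset_min) return(FALSE)
      }
      TRUE
    }, TRUE))
  }, TRUE)
  sum(hits)
}

.lookup_var <- function(var, profile, pedigree, scores) {
  parts <- strsplit(var, ".", fixed = TRUE)[[1]]
  switch(parts[1],
    profile = profile[[parts[2]]],
    derived = profile_bmi(profile),
    pedigree = switch(parts[2],
      ashkenazi = isTRUE(pedigree$proband$ashkenazi),
      consanguinity = isTRUE(pedigree$proband$consanguinity)),
    score = {
      s <- scores[[parts[2]]]
      if (is.null(s) || !identical(s$status, "computed")) NA_real_ else s$value
    })
}

# returns list(value = TRUE/FALSE/NA, evidence = list of satisfied leaves)
.eval_pred <- function(pred, profile, pedigree, scores) {
  keys <- names(pred)
  if ("all" %in% keys || "any" %in% keys) {
    comb <- keys[keys %in% c("all", "any")][1]
    res <- lapply(pred[[comb]], .eval_pred, profile = profile,
                  pedigree = pedigree, scores = scores)
    vals <- vapply(res, function(r) {
      v <- r$value
      if (is.na(v)) NA else v
    }, NA)
    ev <- do.call(c, lapply(res, `[[`, "evidence"))
    if (comb == "all") {
      v <- if (any(!vals, na.rm = TRUE)) FALSE
           else if (anyNA(vals)) NA else TRUE
      list(value = v, evidence = if (isTRUE(v)) ev else list())
    } else {
      v <- if (any(vals, na.rm = TRUE)) TRUE
           else if (anyNA(vals)) NA else FALSE
      ev_true <- do.call(c, lapply(res[which(vapply(res, function(r)
        isTRUE(r$value), TRUE))], `[[`, "evidence"))
      list(value = v, evidence = if (isTRUE(v)) ev_true else list())
    }
  } else {
    if (!is.null(pred$var)) {
      obs <- .lookup_var(pred$var, profile, pedigree, scores)
      label <- pred$var
    } else {
      cnt <- pred$count
      obs <- count_affected(pedigree,
                            conditions = unlist(cnt$conditions),
                            degrees = unlist(cnt$degrees),
                            sides = unlist(cnt$sides),
                            sexes = unlist(cnt$sexes),
                            onset_max = cnt$onset_max,
                            onset_min = cnt$onset_min)
      label <- paste0("count(", paste(unlist(cnt$conditions), collapse = "|"),
                      if (!is.null(cnt$degrees))
                        paste0("; ", paste(unlist(cnt$degrees), collapse = ",")),
                      if (!is.null(cnt$sides))
                        paste0("; ", paste(unlist(cnt$sides), collapse = ",")),
                      if (!is.null(cnt$onset_max))
                        paste0("; onset<=", cnt$onset_max), ")")
    }
    sat <- leaf_satisfied(pred$op, obs, pred$value)
    ev <- if (isTRUE(sat))
      list(list(variable = label, observed = obs,
                comparator = pred$op, threshold = pred$value))
    else list()
    list(value = sat, evidence = ev)
  }
}

#' Evaluate a rule catalog against one proband
#'
#' Deterministic evaluation of every rule. A rule fires when its predicate
#' is true; its recommendation carries the evidence leaves (variable,
#' observed value, comparator, threshold) that satisfied the predicate, so
#' the decision can be replayed. Rules whose required inputs are unknown
#' are reported as `"not_evaluable"`, distinct from `"not_met"`.
#'
#' @param catalog A `rule_catalog`.
#' @param profile A `risk_profile`.
#' @param pedigree A `pedigree`.
#' @param scores Named list of `risk_score`s (as from [assess_all()]).
#' @return A `rule_evaluation`: list with `recommendations` (fired rules
#'   with evidence) and `not_evaluable` (rule ids).
#' @export
evaluate_rules <- function(catalog, profile, pedigree, scores = list()) {
  recs <- list(); ne <- character()
  for (r in catalog$rules) {
    res <- .eval_pred(r$predicate, profile, pedigree, scores)
    if (isTRUE(res$value)) {
      recs[[length(recs) + 1L]] <-
        structure(list(rule_id = r$id, tier = r$tier, title = r$title,
                       recommendation = trimws(r$recommendation %||% r$title),
                       citation = r$citation, evidence = res$evidence),
                  class = "recommendation")
    } else if (is.na(res$value)) ne <- c(ne, r$id)
  }
  structure(list(recommendations = recs, not_evaluable = ne,
                 catalog_version = catalog$version),
            class = "rule_evaluation")
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat("<rule_evaluation>", length(x$recommendations), "fired,",
      length(x$not_evaluable), "not evaluable\n")
  for (r in x$recommendations)
    cat(" -", r$tier, "/", r$rule_id, "\n")
  invisible(x)
}

#' Replay a recommendation's evidence against its rule predicate
#'
#' Every evidence leaf must still satisfy its stored comparator.
#'
#' @param rec A `recommendation`.
#' @return `TRUE` iff every stored evidence triple re-satisfies itself.
#' @export
replay_evidence <- function(rec) {
  length(rec$evidence) > 0 &&
    all(vapply(rec$evidence, function(e)
      isTRUE(leaf_satisfied(e$comparator, e$observed, e$threshold)), TRUE))
}

#' Per-tier summary of recommendations
#'
#' For one participant: presence flag and count per tier plus the total.
#' A participant can appear in several tiers, so tier percentages over a
#' cohort do not sum to 100.
#'
#' @param recs A `rule_evaluation`, or a bare list of `recommendation`s.
#' @return List with `counts` (named per tier), `flags`, `total`.
#' @export
tier_summary <- function(recs) {
  if (inherits(recs, "rule_evaluation")) recs <- recs$recommendations
  tiers <- vapply(recs, `[[`, "", "tier")
  counts <- vapply(.rule_tiers, function(t) sum(tiers == t), 0L)
  list(counts = counts, flags = counts > 0L, total = length(recs))
}

#' Cohort tally of participants with recommendations per tier
#'
#' @param eval_list List of `rule_evaluation`s, one per participant.
#' @return List with `n`, per-tier participant counts and proportions, and
#'   `any_recommendation` count/proportion.
#' @export
cohort_tier_summary <- function(eval_list) {
  flags <- t(vapply(eval_list, function(ev) tier_summary(ev)$flags,
                    logical(length(.rule_tiers))))
  n <- length(eval_list)
  counts <- colSums(flags)
  any_rec <- sum(rowSums(flags) > 0)
  list(n = n, tier_counts = counts, tier_proportions = counts / n,
       any_recommendation = any_rec, any_recommendation_proportion = any_rec / n)
}

#' All numeric thresholds in a catalog
#'
#' Flattens every comparison leaf with a numeric threshold, for boundary
#' audits of strict vs inclusive semantics.
#'
#' @param catalog A `rule_catalog`.
#' @return Data frame: `rule_id`, `variable`, `op`, `threshold`.
#' @export
rule_thresholds <- function(catalog) {
  out <- list()
  walk <- function(pred, id) {
    keys <- names(pred)
    if ("all" %in% keys || "any" %in% keys) {
      for (k in pred[[keys[keys %in% c("all", "any")][1]]]) walk(k, id)
    } else if (is.numeric(pred$value)) {
      out[[length(out) + 1L]] <<- data.frame(
        rule_id = id, variable = pred$var %||% "count",
        op = pred$op, threshold = pred$value, stringsAsFactors = FALSE)
    }
  }
  for (r in catalog$rules) walk(r$predicate, r$id)
  do.call(rbind, out)
}
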