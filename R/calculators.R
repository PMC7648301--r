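.config_cache <- new.env(parent = emptyenv())

#' Load a calculator coefficient configuration
#'
#' Each calculator ships a versioned YAML config with its eligibility
#' window, required inputs and coefficient set. Configs are cached per
#' session; pass a path to substitute a custom set.
#'
#' @param name One of `"gail"`, `"framingham"`, `"reynolds"`, `"pce"`,
#'   `"tyrer_cuzick"`.
#' @param path Optional YAML path overriding the shipped config.
#' @return Parsed config list.
#' @export
load_calculator_config <- function(name, path = NULL) {
  if (is.null(path)) {
    if (!is.null(.config_cache[[name]])) return(.config_cache[[name]])
    path <- system.file("extdata", paste0("calc_", name, ".yaml"),
                        package = "fhhrisk", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$calculator, name))
    stop("config at ", path, " is for '", cfg$calculator, "', not '", name, "'",
         call. = FALSE)
  .config_cache[[name]] <- cfg
  cfg
}

# ---- RiskScore -------------------------------------------------------------

.risk_score <- function(calculator, value = NULL, horizon, status = "computed",
                        missing_inputs = character(), reason = NULL) {
  if (identical(status, "computed")) {
    stopifnot(is.numeric(value), value >= 0, value <= 100)
    value <- round(value, 2)  # percent, display precision
  } else value <- NULL
  structure(list(calculator = calculator, value = value, horizon = horizon,
                 status = status, missing_inputs = missing_inputs,
                 reason = reason),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  if (identical(x$status, "computed"))
    cat(sprintf("<risk_score> %s (%s): %.2f%%\n", x$calculator, x$horizon, x$value))
  else
    cat("<risk_score>", x$calculator, "(", x$horizon, "): not calculated",
        if (length(x$missing_inputs))
          paste0("[missing: ", paste(x$missing_inputs, collapse = ", "), "]")
        else paste0("[", x$reason %||% "ineligible", "]"), "\n")
  invisible(x)
}

# requirement tokens -> is the input known in this profile?
.input_known <- function(token, profile) {
  switch(token,
    first_birth = isTRUE(profile$no_live_births) ||
                  !is.na(profile$age_first_live_birth),
    !is.na(profile[[token]]))
}

.missing_inputs <- function(required, profile) {
  required[!vapply(required, .input_known, TRUE, profile = profile)]
}

# ---- eligibility -----------------------------------------------------------

.had_condition <- function(p, code) {
  any(vapply(.all_records(p), function(r)
    any(vapply(r$conditions, function(ce)
      identical(ce$condition, code), TRUE)), TRUE))
}

.proband_has <- function(p, code) {
  any(vapply(p$proband$conditions, function(ce)
    identical(ce$condition, code), TRUE))
}

#' Which calculators apply to a proband
#'
#' Deterministic eligibility from each calculator's published window:
#' breast-cancer calculators apply to women without a prior breast cancer
#' inside their age windows; cardiovascular calculators apply inside their
#' age windows regardless of sex. Missing age or sex makes no calculator
#' applicable.
#'
#' @param profile A `risk_profile`.
#' @param pedigree A `pedigree` (used for the proband's cancer history).
#' @return Character vector of applicable calculator ids, a subset of
#'   `c("gail", "tyrer_cuzick", "brcapro", "framingham", "reynolds", "pce")`.
#' @export
eligibility <- function(profile, pedigree = NULL) {
  out <- character()
  age <- profile$age; sex <- profile$sex
  if (is.na(age) || is.na(sex)) return(out)
  prior_bc <- !is.null(pedigree) && .proband_has(pedigree, "breast_cancer")
  win <- function(name) {
    e <- load_calculator_config(name)$eligibility
    age >= e$min_age && age <= e$max_age &&
      (is.null(e$sex) || identical(sex, e$sex))
  }
  if (sex == "female" && !prior_bc) {
    if (win("gail")) out <- c(out, "gail")
    if (win("tyrer_cuzick")) out <- c(out, "tyrer_cuzick")
    if (age >= 20 && age <= 85) out <- c(out, "brcapro")
  }
  for (cv in c("framingham", "reynolds", "pce"))
    if (win(cv)) out <- c(out, cv)
  out
}

# ---- Gail ------------------------------------------------------------------

#' Number of first-degree relatives with breast cancer
#' @param pedigree A `pedigree`.
#' @return Integer count over relatives whose degree is FDR.
#' @export
fdr_breast_count <- function(pedigree) {
  sum(vapply(pedigree$relatives, function(r)
    classify_degree(r$relation) == "FDR" &&
      any(vapply(r$conditions, function(ce)
        identical(ce$condition, "breast_cancer"), TRUE)), TRUE))
}

.band_rr <- function(bands, value) {
  # bands: list of {min, rr}, any order; pick the largest min <= value
  mins <- vapply(bands, `[[`, 0, "min")
  rrs <- vapply(bands, `[[`, 0, "rr")
  rrs[order(mins, decreasing = TRUE)][which(sort(mins, decreasing = TRUE) <= value)[1]]
}

#' Gail composite relative risk
#'
#' Product of category relative risks: age at menarche, age at first live
#' birth crossed with the number of affected first-degree relatives, and
#' breast biopsies (age-split at 50) with the atypical-hyperplasia
#' multiplier. All factors at their reference category give exactly 1.
#'
#' @param profile A `risk_profile` (menarche, first-birth and biopsy fields).
#' @param fdr_count Number of first-degree relatives with breast cancer.
#' @param attained_age Age at which the biopsy factor's age-50 split is
#'   evaluated; defaults to the profile age.
#' @return Unitless relative risk.
#' @export
gail_relative_risk <- function(profile, fdr_count = 0,
                               attained_age = profile$age) {
  cfg <- load_calculator_config("gail")
  miss <- .missing_inputs(cfg$required, profile)
  if (length(miss))
    stop("missing Gail inputs: ", paste(miss, collapse = ", "), call. = FALSE)
  rr <- .band_rr(cfg$relative_risks$menarche_age, profile$menarche_age)
  # first live birth x FDR interaction; nulliparous sits in the 25-29 band
  row <- if (isTRUE(profile$no_live_births)) 3L
         else findInterval(profile$age_first_live_birth,
                           unlist(cfg$relative_risks$first_birth_fdr$bands)) + 1L
  col <- min(fdr_count, 2L) + 1L
  rr <- rr * cfg$relative_risks$first_birth_fdr$table[[row]][[col]]
  nb <- min(profile$breast_biopsy_count, 2)
  btab <- if (attained_age < 50) cfg$relative_risks$biopsy_under50
          else cfg$relative_risks$biopsy_50plus
  rr <- rr * btab[[nb + 1L]]
  if (nb >= 1) {
    ah <- profile$atypical_hyperplasia
    if (is.na(ah)) ah <- "unknown"
    rr <- rr * cfg$relative_risks$atypical_hyperplasia[[ah]]
  }
  rr
}

.gail_stratum <- function(cfg, race) {
  strata <- names(cfg$baseline$strata)
  if (is.na(race) || !race %in% strata) {
    if (!is.na(race))
      warning("race/ethnicity stratum '", race, "' not in Gail baseline set; ",
              "using default '", cfg$baseline$default_stratum, "'", call. = FALSE)
    cfg$baseline$default_stratum
  } else race
}

#' Gail absolute 5-year breast-cancer risk
#'
#' Composes the relative risk with the race-stratified baseline breast
#' cancer incidence, the attributable-risk deflator and competing
#' mortality in a piecewise-exponential annual projection:
#' `P = sum_t S(t) * h1*(t) / (h1*(t) + h2(t)) * (1 - exp(-(h1* + h2)))`
#' with `h1* = h1 (1 - AR) RR(t)`. The affected-FDR count is taken from
#' the pedigree. Missing required inputs yield a `not_calculated` score
#' naming them.
#'
#' @param profile A `risk_profile`.
#' @param pedigree A `pedigree` (affected-FDR count).
#' @param horizon Projection horizon in years (default 5).
#' @return A `risk_score` (percent).
#' @export
gail_absolute_risk <- function(profile, pedigree, horizon = NULL) {
  cfg <- load_calculator_config("gail")
  if (is.null(horizon)) horizon <- cfg$horizon_years
  hlab <- paste0(horizon, "y")
  miss <- .missing_inputs(cfg$required, profile)
  if (length(miss))
    return(.risk_score("gail", horizon = hlab, status = "not_calculated",
                       missing_inputs = miss))
  if (!"gail" %in% eligibility(profile, pedigree))
    return(.risk_score("gail", horizon = hlab, status = "not_calculated",
                       reason = "ineligible"))
  fdr <- fdr_breast_count(pedigree)
  st <- cfg$baseline$strata[[.gail_stratum(cfg, profile$race_ethnicity)]]
  band <- function(age) max(findInterval(age, unlist(st$ages)), 1L)
  ar <- cfg$baseline$one_minus_ar
  S <- 1; P <- 0
  for (t in seq_len(max(horizon, 0)) - 1L) {
    a <- profile$age + t
    h1 <- st$h1[[band(a)]] / 1e5 *
      (if (a < 50) ar$under50 else ar$from50) *
      gail_relative_risk(profile, fdr, attained_age = a)
    h2 <- st$h2[[band(a)]] / 1e5
    tot <- h1 + h2
    if (tot > 0) P <- P + S * h1 / tot * (1 - exp(-tot))
    S <- S * exp(-tot)
  }
  .risk_score("gail", value = 100 * P, horizon = hlab)
}

# ---- proportional-hazards CVD equations ------------------------------------

.term_value <- function(name, v) {
  lnA <- function() log(v$age)
  switch(name,
    age = v$age,
    ln_age = lnA(),
    ln_age_sq = lnA()^2,
    ln_tc = log(v$total_cholesterol),
    ln_age_ln_tc = lnA() * log(v$total_cholesterol),
    ln_hdl = log(v$HDL),
    ln_age_ln_hdl = lnA() * log(v$HDL),
    ln_sbp = log(v$systolic_bp),
    ln_sbp_treated = if (isTRUE(v$treated_hypertension)) log(v$systolic_bp) else 0,
    ln_sbp_untreated = if (isTRUE(v$treated_hypertension)) 0 else log(v$systolic_bp),
    ln_age_ln_sbp_treated = if (isTRUE(v$treated_hypertension)) lnA() * log(v$systolic_bp) else 0,
    ln_age_ln_sbp_untreated = if (isTRUE(v$treated_hypertension)) 0 else lnA() * log(v$systolic_bp),
    smoker = as.numeric(isTRUE(v$smoker)),
    ln_age_smoker = if (isTRUE(v$smoker)) lnA() else 0,
    diabetes = as.numeric(isTRUE(v$diabetes)),
    ln_hscrp = log(v$hsCRP),
    parental_mi = as.numeric(isTRUE(v$parental_MI_before_60)),
    stop("unknown model term: ", name, call. = FALSE))
}

.lp <- function(coefs, v) {
  s <- 0
  for (nm in names(coefs)) s <- s + coefs[[nm]] * .term_value(nm, v)
  s
}

# reference linear predictor: stratum mean continuous inputs, binary
# factors off, untreated blood pressure
.ref_lp <- function(stratum) {
  v <- c(stratum$reference,
         list(treated_hypertension = FALSE, smoker = FALSE, diabetes = FALSE,
              parental_MI_before_60 = FALSE))
  .lp(stratum$coefficients, v)
}

.cox_risk <- function(name, profile, stratum_key, extra_vals = list()) {
  cfg <- load_calculator_config(name)
  hlab <- paste0(cfg$horizon_years, "y")
  miss <- .missing_inputs(cfg$required, profile)
  if (length(miss))
    return(.risk_score(name, horizon = hlab, status = "not_calculated",
                       missing_inputs = miss))
  if (!name %in% eligibility(profile))
    return(.risk_score(name, horizon = hlab, status = "not_calculated",
                       reason = "ineligible"))
  st <- cfg$strata[[stratum_key]]
  if (is.null(st)) stop("no stratum '", stratum_key, "' in ", name, call. = FALSE)
  v <- utils::modifyList(unclass(profile), extra_vals)
  lp <- .lp(st$coefficients, v)
  risk <- 1 - st$baseline_survival^exp(lp - .ref_lp(st))
  .risk_score(name, value = 100 * max(0, min(1, risk)), horizon = hlab)
}

#' Framingham 10-year general cardiovascular risk
#'
#' Sex-stratified 2008 general-CVD proportional-hazards equation
#' (`1 - S0^exp(sum(beta x) - sum(beta x_ref))`) over log age, lipids and
#' systolic blood pressure (treatment-specific), smoking and diabetes.
#'
#' @param profile A `risk_profile`.
#' @return A `risk_score` (percent, 10-year horizon).
#' @export
framingham_cvd_risk <- function(profile) {
  .cox_risk("framingham", profile, profile$sex %||% NA_character_)
}

#' Reynolds 10-year cardiovascular risk
#'
#' Sex-specific equation including high-sensitivity C-reactive protein and
#' parental premature myocardial infarction. When
#' `profile$parental_MI_before_60` is unknown and a pedigree is supplied,
#' the flag is derived from the parents' coronary-disease onsets.
#'
#' @param profile A `risk_profile`.
#' @param pedigree Optional `pedigree` for deriving the parental-MI flag.
#' @return A `risk_score` (percent, 10-year horizon).
#' @export
reynolds_risk <- function(profile, pedigree = NULL) {
  extra <- list()
  if (is.na(profile$parental_MI_before_60) && !is.null(pedigree)) {
    pm <- .parental_mi_from_pedigree(pedigree)
    if (!is.na(pm)) extra$parental_MI_before_60 <- pm
  }
  if (length(extra)) {
    profile$parental_MI_before_60 <- extra$parental_MI_before_60
  }
  .cox_risk("reynolds", profile, profile$sex %||% NA_character_)
}

.parental_mi_from_pedigree <- function(p) {
  parents <- Filter(function(r) r$relation %in% c("mother", "father"), p$relatives)
  if (!length(parents)) return(NA)
  hit <- vapply(parents, function(r)
    any(vapply(r$conditions, function(ce)
      identical(ce$condition, "coronary_artery_disease") &&
        !is.null(ce$age_of_onset) && ce$age_of_onset < 60, TRUE)), TRUE)
  any(hit)
}

#' Pooled cohort equations 10-year ASCVD risk
#'
#' Race- and sex-stratified ACC/AHA equations with age interactions.
#' Race labels outside the published `white`/`black` strata map to the
#' default stratum with a warning.
#'
#' @param profile A `risk_profile`.
#' @return A `risk_score` (percent, 10-year horizon).
#' @export
pce_ascvd_risk <- function(profile) {
  cfg <- load_calculator_config("pce")
  race <- profile$race_ethnicity
  race_key <- if (!is.na(race) && race %in% c("black", "african_american")) "black"
              else {
                if (!is.na(race) && !race %in% c("white", "caucasian"))
                  warning("race/ethnicity stratum '", race, "' not in the pooled-",
                          "cohort set; using default '", cfg$default_race, "'",
                          call. = FALSE)
                cfg$default_race
              }
  if (is.na(profile$sex))
    return(.risk_score("pce", horizon = "10y", status = "not_calculated",
                       missing_inputs = "sex"))
  .cox_risk("pce", profile, paste0(race_key, "_", profile$sex))
}

# ---- Tyrer-Cuzick simplification -------------------------------------------

.tc_model_cache <- new.env(parent = emptyenv())
.tc_gene_model <- function(cfg) {
  if (is.null(.tc_model_cache$m))
    .tc_model_cache$m <- load_gene_model(
      system.file("extdata", cfg$gene_model, package = "fhhrisk", mustWork = TRUE))
  .tc_model_cache$m
}

.tc_hormonal_rr <- function(cfg, profile) {
  h <- cfg$hormonal_relative_risks
  rr <- .band_rr(h$menarche_age, profile$menarche_age)
  rr <- rr * if (isTRUE(profile$no_live_births)) h$first_birth$nulliparous
             else .band_rr(h$first_birth$bands, profile$age_first_live_birth)
  rr <- rr * h$hrt_use[[profile$hrt_use]]
  if (!is.na(profile$breast_biopsy_count) && profile$breast_biopsy_count >= 1) {
    ah <- profile$atypical_hyperplasia
    rr <- rr * h$atypical_hyperplasia[[if (is.na(ah)) "unknown" else ah]]
  }
  bmi <- profile_bmi(profile)
  if (!is.na(bmi)) rr <- rr * .band_rr(h$bmi, bmi)
  rr
}

#' Tyrer-Cuzick lifetime breast-cancer risk (single-locus simplification)
#'
#' Lifetime (to age 85) breast-cancer probability mixing (a) the Mendelian
#' carrier posterior over BRCA1/BRCA2 extended with one hypothetical
#' dominant low-penetrance locus and (b) hormonal/benign-disease relative
#' risks applied proportional-hazards-style to the non-high-risk-gene
#' component of the mixture. An approximation of the commercial IBIS
#' program; see the methods vignette.
#'
#' @param profile A `risk_profile`.
#' @param graph A `pedigree_graph` (from [expand_to_graph()]).
#' @param pedigree Optional `pedigree` for eligibility screening (prior
#'   breast cancer).
#' @return A `risk_score` (percent, lifetime horizon).
#' @export
tyrer_cuzick_lifetime_risk <- function(profile, graph, pedigree = NULL) {
  cfg <- load_calculator_config("tyrer_cuzick")
  miss <- .missing_inputs(cfg$required, profile)
  if (length(miss))
    return(.risk_score("tyrer_cuzick", horizon = "lifetime",
                       status = "not_calculated", missing_inputs = miss))
  if (!identical(profile$sex, "female") ||
      profile$age < cfg$eligibility$min_age || profile$age > cfg$eligibility$max_age ||
      (!is.null(pedigree) && .proband_has(pedigree, "breast_cancer")))
    return(.risk_score("tyrer_cuzick", horizon = "lifetime",
                       status = "not_calculated", reason = "ineligible"))
  model <- .tc_gene_model(cfg)
  post <- carrier_posterior(graph, model)
  rr <- .tc_hormonal_rr(cfg, profile)
  to_age <- cfg$lifetime_to_age
  F0 <- .class_F(model, "breast", "female", profile$age)
  F1 <- .class_F(model, "breast", "female", to_age)
  cond <- ifelse(F0 < 1, (F1 - F0) / (1 - F0), 0)
  scaled <- names(cond) %in% c("noncarrier", "LOWPEN")
  cond[scaled] <- 1 - (1 - cond[scaled])^rr
  p <- sum(post$probabilities * cond[model$classes])
  .risk_score("tyrer_cuzick", value = 100 * max(0, min(1, p)),
              horizon = "lifetime")
}

#' BRCAPro-style lifetime breast-cancer risk score
#'
#' The Mendelian carrier posterior under the two-gene model, converted to
#' a residual lifetime (to age 85) breast-cancer probability.
#'
#' @param profile A `risk_profile` (age and sex).
#' @param graph A `pedigree_graph`.
#' @param pedigree Optional `pedigree` for eligibility screening.
#' @param model Gene model (default the shipped two-gene model).
#' @return A `risk_score` (percent, lifetime horizon).
#' @export
brcapro_lifetime_risk <- function(profile, graph, pedigree = NULL,
                                  model = load_gene_model()) {
  if (!identical(profile$sex, "female") || is.na(profile$age) ||
      profile$age < 20 || profile$age > 85 ||
      (!is.null(pedigree) && .proband_has(pedigree, "breast_cancer")))
    return(.risk_score("brcapro", horizon = "lifetime",
                       status = "not_calculated", reason = "ineligible"))
  post <- carrier_posterior(graph, model)
  ar <- future_cancer_risk(post, model, current_age = profile$age,
                           to_age = 85, cancer = "breast", sex = "female")
  .risk_score("brcapro", value = 100 * ar$probability, horizon = "lifetime")
}

#' Run all six calculators on one proband
#'
#' Applies the uniform eligibility and missing-data contract: every
#' calculator returns either a computed score or a `not_calculated` score
#' naming the missing inputs — never an imputed number.
#'
#' @param profile A `risk_profile`.
#' @param pedigree A `pedigree`.
#' @param graph Optional pre-expanded `pedigree_graph` (expanded on demand).
#' @return Named list of six `risk_score`s.
#' @export
assess_all <- function(profile, pedigree, graph = NULL) {
  if (is.null(graph)) graph <- expand_to_graph(pedigree)
  list(gail = gail_absolute_risk(profile, pedigree),
       tyrer_cuzick = tyrer_cuzick_lifetime_risk(profile, graph, pedigree),
       brcapro = brcapro_lifetime_risk(profile, graph, pedigree),
       framingham = framingham_cvd_risk(profile),
       reynolds = reynolds_risk(profile, pedigree),
       pce = pce_ascvd_risk(profile))
}
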