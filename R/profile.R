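#' Build a personal risk-factor profile
#'
#' The proband's personal variables feeding the risk calculators. Every
#' field may be left `NA` (unknown); calculators whose required inputs are
#' unknown return a `not_calculated` score naming them rather than imputing.
#' Physiological ranges are enforced on entry.
#'
#' @param age Years, 18-120.
#' @param sex `"male"` or `"female"`.
#' @param race_ethnicity Free stratum label (e.g. `"white"`, `"black"`);
#'   calculators map labels outside their published set to their default
#'   stratum with a warning.
#' @param menarche_age Age at menarche, years.
#' @param age_first_live_birth Age at first live birth, years;
#'   `no_live_births = TRUE` marks a nulliparous woman (distinct from
#'   unknown).
#' @param no_live_births Logical; nulliparity.
#' @param breast_biopsy_count Number of breast biopsies.
#' @param atypical_hyperplasia `"ah"`, `"no_ah"` or `"unknown"` (biopsy
#'   histology).
#' @param hrt_use `"never"`, `"former"` or `"current"`.
#' @param height_cm,weight_kg Anthropometrics (SI); BMI is derived.
#' @param systolic_bp Systolic blood pressure, mmHg (60-250).
#' @param treated_hypertension Logical; on antihypertensive treatment.
#' @param total_cholesterol,HDL mg/dL (50-500 / 10-150).
#' @param smoker,diabetes Logicals.
#' @param hsCRP High-sensitivity C-reactive protein, mg/L (>= 0).
#' @param parental_MI_before_60 Logical; derivable from the pedigree when
#'   `NA` (a parent with coronary artery disease onset before 60).
#' @return A `risk_profile` object.
#' @export
risk_profile <- function(age = NA, sex = NA_character_,
                         race_ethnicity = NA_character_,
                         menarche_age = NA, age_first_live_birth = NA,
                         no_live_births = NA, breast_biopsy_count = NA,
                         atypical_hyperplasia = NA_character_,
                         hrt_use = NA_character_,
                         height_cm = NA, weight_kg = NA,
                         systolic_bp = NA, treated_hypertension = NA,
                         total_cholesterol = NA, HDL = NA,
                         smoker = NA, diabetes = NA, hsCRP = NA,
                         parental_MI_before_60 = NA) {
  rng <- function(x, lo, hi, what) {
    if (is.null(x) || is.na(x)) return(NA_real_)
    if (!is.numeric(x) || x < lo || x > hi)
      stop(what, " out of range [", lo, ", ", hi, "]: ", x, call. = FALSE)
    as.numeric(x)
  }
  chr <- function(x, allowed, what) {
    if (is.null(x) || is.na(x)) return(NA_character_)
    if (!x %in% allowed)
      stop(what, " must be one of ", paste(allowed, collapse = "/"), call. = FALSE)
    x
  }
  lgl <- function(x) if (is.null(x) || is.na(x)) NA else isTRUE(x)
  structure(list(
    age = rng(age, 18, 120, "age"),
    sex = chr(sex, c("male", "female"), "sex"),
    race_ethnicity = race_ethnicity,
    menarche_age = rng(menarche_age, 5, 30, "menarche_age"),
    age_first_live_birth = rng(age_first_live_birth, 10, 60, "age_first_live_birth"),
    no_live_births = lgl(no_live_births),
    breast_biopsy_count = rng(breast_biopsy_count, 0, 50, "breast_biopsy_count"),
    atypical_hyperplasia = chr(atypical_hyperplasia, c("ah", "no_ah", "unknown"),
                               "atypical_hyperplasia"),
    hrt_use = chr(hrt_use, c("never", "former", "current"), "hrt_use"),
    height_cm = rng(height_cm, 100, 250, "height_cm"),
    weight_kg = rng(weight_kg, 25, 350, "weight_kg"),
    systolic_bp = rng(systolic_bp, 60, 250, "systolic_bp"),
    treated_hypertension = lgl(treated_hypertension),
    total_cholesterol = rng(total_cholesterol, 50, 500, "total_cholesterol"),
    HDL = rng(HDL, 10, 150, "HDL"),
    smoker = lgl(smoker), diabetes = lgl(diabetes),
    hsCRP = rng(hsCRP, 0, 200, "hsCRP"),
    parental_MI_before_60 = lgl(parental_MI_before_60)),
    class = "risk_profile")
}

#' Body-mass index derived from a profile
#' @param profile A `risk_profile`.
#' @return kg/m^2 or `NA` when height or weight is unknown.
#' @export
profile_bmi <- function(profile) {
  h <- profile$height_cm; w <- profile$weight_kg
  if (is.na(h) || is.na(w)) return(NA_real_)
  w / (h / 100)^2
}

#' Parse a risk-factor profile from JSON
#' @param x Path to a JSON file or a JSON string with `risk_profile` fields.
#' @return A `risk_profile`.
#' @export
parse_profile <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  args <- doc[intersect(names(doc), names(formals(risk_profile)))]
  do.call(risk_profile, args)
}

#' Serialize a risk-factor profile to JSON
#' @param profile A `risk_profile`.
#' @param path Optional output path.
#' @return JSON string.
#' @export
serialize_profile <- function(profile, path = NULL) {
  js <- jsonlite::toJSON(Filter(function(v) !is.null(v) && !is.na(v),
                                unclass(profile)),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.risk_profile <- function(x, ...) {
  known <- !vapply(unclass(x), function(v) is.na(v), TRUE)
  cat("<risk_profile>", sum(known), "of", length(known), "fields known\n")
  invisible(x)
}
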