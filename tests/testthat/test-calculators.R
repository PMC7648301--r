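# independent fine-grid integration oracle for the Gail absolute-risk
# projection, built directly from the shipped config
gail_integration_oracle <- function(profile, fdr, horizon) {
  cfg <- load_calculator_config("gail")
  st <- cfg$baseline$strata$white
  ages <- unlist(st$ages)
  h1 <- function(a) unlist(st$h1)[max(findInterval(a, ages), 1)] / 1e5
  h2 <- function(a) unlist(st$h2)[max(findInterval(a, ages), 1)] / 1e5
  omar <- function(a) if (a < 50) cfg$baseline$one_minus_ar$under50
                      else cfg$baseline$one_minus_ar$from50
  dt <- 1 / 400
  tt <- seq(0, horizon - dt, by = dt)
  P <- 0; H <- 0
  for (t in tt) {
    a <- profile$age + t
    rr <- gail_relative_risk(profile, fdr, attained_age = a)
    hs <- h1(a) * omar(a) * rr
    P <- P + exp(-H) * hs * dt
    H <- H + (hs + h2(a)) * dt
  }
  100 * P
}

test_that("eligibility windows match the published calculator sets", {
  p <- required_pedigree()
  ok45 <- baseline_profile(age = 45)
  expect_setequal(eligibility(ok45, p),
                  c("gail", "tyrer_cuzick", "brcapro",
                    "framingham", "reynolds", "pce"))
  # male proband: breast calculators excluded
  man <- baseline_profile(age = 55, sex = "male", menarche_age = NA,
                          age_first_live_birth = NA, no_live_births = NA)
  expect_setequal(eligibility(man, p), c("framingham", "reynolds", "pce"))
  # age 25: no 10-year CVD calculator applies
  young <- baseline_profile(age = 25)
  expect_false(any(c("framingham", "reynolds", "pce") %in% eligibility(young, p)))
  # prior breast cancer excludes the breast models
  bc_ped <- pedigree(rec("self", sex = "female", alive = TRUE, current_age = 50,
                         conditions = list(cond("breast_cancer", 44))),
                     required_pedigree()$relatives)
  expect_false(any(c("gail", "tyrer_cuzick", "brcapro") %in%
                     eligibility(baseline_profile(age = 50), bc_ped)))
  # unknown age or sex: nothing applies
  expect_length(eligibility(risk_profile(), p), 0L)
})

test_that("Gail relative risk is 1 at the reference categories and multiplies", {
  ref <- baseline_profile(menarche_age = 15, age_first_live_birth = 19,
                          breast_biopsy_count = 0)
  expect_identical(gail_relative_risk(ref, 0), 1)
  # single non-reference factor equals its published coefficient alone
  men <- baseline_profile(menarche_age = 11, age_first_live_birth = 19,
                          breast_biopsy_count = 0)
  expect_equal(gail_relative_risk(men, 0), 1.207)
  # multi-factor hand product: menarche 12-13 x first birth 25-29 with one
  # affected FDR x one biopsy (<50) with atypical hyperplasia
  multi <- baseline_profile(age = 45, menarche_age = 12,
                            age_first_live_birth = 27,
                            breast_biopsy_count = 1,
                            atypical_hyperplasia = "ah")
  expect_equal(gail_relative_risk(multi, 1),
               1.099 * 2.756 * 1.70 * 1.82, tolerance = 1e-12)
  # nulliparous sits in the 25-29 band
  np <- baseline_profile(no_live_births = TRUE, age_first_live_birth = NA,
                         menarche_age = 15, breast_biopsy_count = 0)
  expect_equal(gail_relative_risk(np, 0), 1.548)
  # biopsy factor switches at age 50
  bx <- baseline_profile(age = 55, menarche_age = 15,
                         age_first_live_birth = 19, breast_biopsy_count = 2)
  expect_equal(gail_relative_risk(bx, 0, attained_age = 55), 1.62)
  expect_equal(gail_relative_risk(bx, 0, attained_age = 45), 2.88)
})

test_that("Gail absolute risk: zero horizon, and agreement with integration oracle", {
  ped <- required_pedigree(mother_conditions = list(cond("breast_cancer", 45)))
  prof <- baseline_profile(age = 45, menarche_age = 12,
                           age_first_live_birth = 27, breast_biopsy_count = 1,
                           atypical_hyperplasia = "no_ah")
  expect_equal(gail_absolute_risk(prof, ped, horizon = 0)$value, 0)
  got <- gail_absolute_risk(prof, ped)
  expect_equal(got$status, "computed")
  oracle <- gail_integration_oracle(prof, fdr_breast_count(ped), 5)
  expect_lt(abs(got$value - oracle), 0.02)
  # reference-profile risk equals the baseline integral alone (RR = 1)
  ref <- baseline_profile(age = 45, menarche_age = 15,
                          age_first_live_birth = 19, breast_biopsy_count = 0)
  ped0 <- required_pedigree()
  expect_lt(abs(gail_absolute_risk(ref, ped0)$value -
                gail_integration_oracle(ref, 0, 5)), 0.02)
})

test_that("each CVD equation returns 1 - S0 at its reference inputs", {
  for (nm in c("framingham", "reynolds", "pce")) {
    cfg <- load_calculator_config(nm)
    for (key in names(cfg$strata)) {
      st <- cfg$strata[[key]]
      sex <- if (grepl("female", key)) "female" else "male"
      race <- if (grepl("black", key)) "black" else "white"
      age <- max(st$reference$age, cfg$eligibility$min_age)
      prof <- baseline_profile(
        age = st$reference$age, sex = sex, race_ethnicity = race,
        total_cholesterol = st$reference$total_cholesterol,
        HDL = st$reference$HDL, systolic_bp = st$reference$systolic_bp,
        hsCRP = st$reference$hsCRP %||% 1.5,
        treated_hypertension = FALSE, smoker = FALSE, diabetes = FALSE,
        parental_MI_before_60 = FALSE,
        menarche_age = NA, age_first_live_birth = NA, no_live_births = NA)
      score <- switch(nm, framingham = framingham_cvd_risk(prof),
                      reynolds = reynolds_risk(prof),
                      pce = pce_ascvd_risk(prof))
      expect_equal(score$status, "computed", info = paste(nm, key))
      expect_equal(score$value, round(100 * (1 - st$baseline_survival), 2),
                   tolerance = 1e-8, info = paste(nm, key))
    }
  }
})

test_that("computed risks stay in [0,100] and rise along adverse-factor grids", {
  base <- baseline_profile(age = 60, menarche_age = NA,
                           age_first_live_birth = NA, no_live_births = NA)
  grids <- list(
    systolic_bp = seq(100, 200, by = 10),
    total_cholesterol = seq(150, 320, by = 10),
    age = seq(45, 74, by = 1))
  for (fld in names(grids)) {
    for (nm in c("framingham", "reynolds", "pce")) {
      vals <- vapply(grids[[fld]], function(v) {
        pr <- base; pr[[fld]] <- v
        s <- switch(nm, framingham = framingham_cvd_risk(pr),
                    reynolds = reynolds_risk(pr), pce = pce_ascvd_risk(pr))
        s$value
      }, 0)
      expect_true(all(vals >= 0 & vals <= 100), info = paste(nm, fld))
      expect_true(all(diff(vals) >= 0), info = paste(nm, fld))
    }
  }
  # smoking and diabetes raise every CVD score
  for (fld in c("smoker", "diabetes")) {
    on <- base; on[[fld]] <- TRUE
    for (nm in c("framingham", "pce")) {
      f <- switch(nm, framingham = framingham_cvd_risk, pce = pce_ascvd_risk)
      expect_gte(f(on)$value, f(base)$value)
    }
  }
  # Gail absolute risk rises with the affected-FDR count
  ped0 <- required_pedigree()
  ped1 <- required_pedigree(mother_conditions = list(cond("breast_cancer", 45)))
  prof <- baseline_profile(age = 45)
  expect_gt(gail_absolute_risk(prof, ped1)$value,
            gail_absolute_risk(prof, ped0)$value)
})

test_that("deleting any single required input flips its calculator to not_calculated", {
  ped <- required_pedigree()
  complete <- baseline_profile(age = 50)
  blank <- function(prof, token) {
    if (token == "first_birth") {
      prof$age_first_live_birth <- NA_real_; prof$no_live_births <- NA
    } else if (token %in% c("smoker", "diabetes", "treated_hypertension",
                            "parental_MI_before_60", "no_live_births")) {
      prof[[token]] <- NA
    } else if (token %in% c("sex", "race_ethnicity", "hrt_use",
                            "atypical_hyperplasia")) {
      prof[[token]] <- NA_character_
    } else prof[[token]] <- NA_real_
    prof
  }
  run <- function(nm, prof) switch(nm,
    gail = gail_absolute_risk(prof, ped),
    tyrer_cuzick = tyrer_cuzick_lifetime_risk(prof, expand_to_graph(ped), ped),
    framingham = framingham_cvd_risk(prof),
    reynolds = reynolds_risk(prof),
    pce = pce_ascvd_risk(prof))
  for (nm in c("gail", "tyrer_cuzick", "framingham", "reynolds", "pce")) {
    req <- load_calculator_config(nm)$required
    expect_equal(run(nm, complete)$status, "computed", info = nm)
    for (token in req) {
      s <- run(nm, blank(complete, token))
      expect_equal(s$status, "not_calculated", info = paste(nm, token))
      expect_true(token %in% s$missing_inputs, info = paste(nm, token))
      expect_null(s$value)
    }
  }
})

test_that("a profile lacking hsCRP leaves Reynolds (and only Reynolds) uncomputed", {
  prof <- baseline_profile(age = 55, hsCRP = NA)
  s <- reynolds_risk(prof)
  expect_equal(s$status, "not_calculated")
  expect_equal(s$missing_inputs, "hsCRP")
  expect_equal(framingham_cvd_risk(prof)$status, "computed")
  expect_equal(pce_ascvd_risk(prof)$status, "computed")
})

test_that("Tyrer-Cuzick: neutral inputs give the baseline mixture; affected FDR raises it", {
  ped0 <- required_pedigree(proband_age = 40)
  g0 <- expand_to_graph(ped0)
  neutral <- baseline_profile(age = 40, menarche_age = 15,
                              age_first_live_birth = 19,
                              breast_biopsy_count = 0, hrt_use = "never",
                              height_cm = NA, weight_kg = NA)
  s0 <- tyrer_cuzick_lifetime_risk(neutral, g0, ped0)
  expect_equal(s0$status, "computed")
  ped1 <- required_pedigree(proband_age = 40,
                            mother_conditions = list(cond("breast_cancer", 38)))
  s1 <- tyrer_cuzick_lifetime_risk(neutral, expand_to_graph(ped1), ped1)
  expect_gt(s1$value, s0$value)
  # hormonal factors raise the non-genetic component
  horm <- baseline_profile(age = 40, menarche_age = 11,
                           age_first_live_birth = 33, breast_biopsy_count = 0,
                           hrt_use = "current", height_cm = NA, weight_kg = NA)
  expect_gt(tyrer_cuzick_lifetime_risk(horm, g0, ped0)$value, s0$value)
})

test_that("Tyrer-Cuzick mixture matches a direct posterior-weighted hand computation", {
  cfg <- load_calculator_config("tyrer_cuzick")
  model <- fhhrisk:::.tc_gene_model(cfg)
  ped <- required_pedigree(proband_age = 40,
                           mother_conditions = list(cond("breast_cancer", 38)))
  g <- expand_to_graph(ped)
  prof <- baseline_profile(age = 40, menarche_age = 15,
                           age_first_live_birth = 19, breast_biopsy_count = 0,
                           hrt_use = "never", height_cm = NA, weight_kg = NA)
  got <- tyrer_cuzick_lifetime_risk(prof, g, ped)$value
  post <- carrier_posterior(g, model)
  F0 <- vapply(model$classes, function(cl) {
    i <- which(model$class_of == cl)[1]
    stats::approx(model$ages, model$state_pen$breast$female[, i], xout = 40)$y
  }, 0)
  F1 <- vapply(model$classes, function(cl) {
    i <- which(model$class_of == cl)[1]
    stats::approx(model$ages, model$state_pen$breast$female[, i], xout = 85)$y
  }, 0)
  condr <- (F1 - F0) / (1 - F0)
  rr <- 1  # all hormonal factors at reference
  scaled <- names(condr) %in% c("noncarrier", "LOWPEN")
  condr[scaled] <- 1 - (1 - condr[scaled])^rr
  hand <- 100 * sum(post$probabilities * condr)
  expect_equal(got, round(hand, 2), tolerance = 1e-8)
})

test_that("identical profiles give bit-identical scores", {
  ped <- required_pedigree()
  prof <- baseline_profile(age = 52)
  s1 <- assess_all(prof, ped)
  s2 <- assess_all(prof, ped)
  expect_identical(s1, s2)
})

test_that("unpublished race strata fall back to the default with a warning", {
  prof <- baseline_profile(age = 55, race_ethnicity = "asian",
                           menarche_age = NA, age_first_live_birth = NA,
                           no_live_births = NA)
  expect_warning(s <- pce_ascvd_risk(prof), "default")
  ref <- baseline_profile(age = 55, race_ethnicity = "white",
                          menarche_age = NA, age_first_live_birth = NA,
                          no_live_births = NA)
  expect_identical(s$value, pce_ascvd_risk(ref)$value)
})
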