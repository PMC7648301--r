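expected_default_rules <- c(
  # monogenic: hereditary cardiac + the four cancer-syndrome referrals +
  # thrombophilia, FH, hemochromatosis, Wilson's, alpha-1
  "hereditary_cardiac_gc", "hboc_gc", "lynch_gc", "fap_gc", "pten_gc",
  "thrombophilia_gc", "fh_testing", "hemochromatosis_testing",
  "wilsons_testing", "a1at_testing",
  # familial
  "ovarian_screening_discussion", "breast_mri", "breast_chemoprevention",
  "early_colonoscopy",
  # common
  "aspirin_stroke_prevention", "diabetes_screening", "aaa_screening",
  "calcium_score_ct", "lung_cancer_screening")

healthy_scores <- function(ped, prof) assess_all(prof, ped)

test_that("the default catalog loads with every line item present", {
  cat_r <- load_rule_catalog()
  ids <- vapply(cat_r$rules, `[[`, "", "id")
  expect_setequal(ids, expected_default_rules)
  tiers <- vapply(cat_r$rules, `[[`, "", "tier")
  expect_equal(unname(table(factor(tiers, c("monogenic", "familial", "common")))),
               c(10L, 4L, 5L), ignore_attr = TRUE)
})

test_that("catalogs with undeclared variables or bad predicates fail at load", {
  bad_var <- tempfile(fileext = ".yaml")
  writeLines('
version: "0"
rules:
  - id: r1
    tier: common
    predicate: {var: profile.shoe_size, op: ">=", value: 10}
', bad_var)
  expect_error(load_rule_catalog(bad_var), "undeclared variable")
  expect_error(load_rule_catalog(bad_var), "r1")

  bad_op <- tempfile(fileext = ".yaml")
  writeLines('
version: "0"
rules:
  - id: r2
    tier: common
    predicate: {var: profile.age, op: "~", value: 10}
', bad_op)
  expect_error(load_rule_catalog(bad_op), "comparator token")

  bad_cond <- tempfile(fileext = ".yaml")
  writeLines('
version: "0"
rules:
  - id: r3
    tier: familial
    predicate: {count: {conditions: [dragon_pox]}, op: ">=", value: 1}
', bad_cond)
  expect_error(load_rule_catalog(bad_cond), "undeclared condition")

  dup <- tempfile(fileext = ".yaml")
  writeLines('
version: "0"
rules:
  - id: r4
    tier: common
    predicate: {var: profile.age, op: ">", value: 1}
  - id: r4
    tier: common
    predicate: {var: profile.age, op: ">", value: 2}
', dup)
  expect_error(load_rule_catalog(dup), "duplicate rule id")
})

test_that("an empty catalog is valid and fires nothing", {
  empty <- tempfile(fileext = ".yaml")
  writeLines('version: "0"\nrules: []', empty)
  cat_r <- load_rule_catalog(empty)
  expect_length(cat_r$rules, 0L)
  ev <- evaluate_rules(cat_r, baseline_profile(), required_pedigree())
  expect_length(ev$recommendations, 0L)
  expect_length(ev$not_evaluable, 0L)
})

test_that("a healthy proband with empty FHH fires no monogenic or familial rule", {
  ped <- required_pedigree(proband_age = 45)
  prof <- baseline_profile(age = 45, height_cm = 170, weight_kg = 60)
  ev <- evaluate_rules(load_rule_catalog(), prof, ped, healthy_scores(ped, prof))
  tiers <- vapply(ev$recommendations, `[[`, "", "tier")
  expect_false(any(tiers %in% c("monogenic", "familial")))
})

test_that("a lifetime breast risk above the MRI cutoff triggers breast MRI with score evidence", {
  ped <- required_pedigree()
  prof <- baseline_profile()
  scores <- assess_all(prof, ped)
  scores$tyrer_cuzick <- structure(
    list(calculator = "tyrer_cuzick", value = 24.5, horizon = "lifetime",
         status = "computed", missing_inputs = character(), reason = NULL),
    class = "risk_score")
  ev <- evaluate_rules(load_rule_catalog(), prof, ped, scores)
  ids <- vapply(ev$recommendations, `[[`, "", "rule_id")
  expect_true("breast_mri" %in% ids)
  mri <- ev$recommendations[[which(ids == "breast_mri")]]
  expect_equal(mri$tier, "familial")
  vars <- vapply(mri$evidence, `[[`, "", "variable")
  expect_true("score.tyrer_cuzick" %in% vars)
  expect_equal(mri$evidence[[1]]$observed, 24.5)
})

test_that("an HBOC-pattern pedigree triggers the hereditary-cancer referral", {
  # multiple early-onset breast + ovarian cancers in the maternal lineage
  ped <- pedigree(
    rec("self", sex = "female", alive = TRUE, current_age = 38),
    list(rec("mother", alive = FALSE, age_at_death = 52,
             cause_of_death = "ovarian cancer",
             conditions = list(cond("breast_cancer", 41),
                               cond("ovarian_cancer", 50))),
         rec("father", alive = TRUE, current_age = 70),
         rec("maternal_grandmother", alive = FALSE, age_at_death = 60,
             cause_of_death = "breast cancer",
             conditions = list(cond("breast_cancer", 44))),
         rec("maternal_grandfather", alive = FALSE, age_at_death = 80,
             cause_of_death = "natural causes"),
         rec("paternal_grandmother", alive = TRUE, current_age = 90),
         rec("paternal_grandfather", alive = TRUE, current_age = 92)))
  prof <- baseline_profile(age = 38)
  ev <- evaluate_rules(load_rule_catalog(), prof, ped, assess_all(prof, ped))
  ids <- vapply(ev$recommendations, `[[`, "", "rule_id")
  expect_true("hboc_gc" %in% ids)
  hboc <- ev$recommendations[[which(ids == "hboc_gc")]]
  expect_equal(hboc$tier, "monogenic")
  expect_true(replay_evidence(hboc))
})

test_that("rules with unknown inputs are reported not evaluable, never silently skipped", {
  ped <- required_pedigree(proband_age = 60)
  prof <- baseline_profile(age = 60, smoker = NA, height_cm = NA, weight_kg = NA,
                           total_cholesterol = NA, HDL = NA)
  scores <- assess_all(prof, ped)  # pce not computed -> score unknown
  ev <- evaluate_rules(load_rule_catalog(), prof, ped, scores)
  expect_true("lung_cancer_screening" %in% ev$not_evaluable)  # smoker unknown
  expect_true("calcium_score_ct" %in% ev$not_evaluable)       # score missing
  expect_true("fh_testing" %in% ev$not_evaluable)             # cholesterol missing
  expect_false("lung_cancer_screening" %in%
                 vapply(ev$recommendations, `[[`, "", "rule_id"))
})

test_that("threshold boundaries respect each rule's strict/inclusive comparator", {
  thr <- rule_thresholds(load_rule_catalog())
  expect_gt(nrow(thr), 10)
  eps <- 1e-9
  for (k in seq_len(nrow(thr))) {
    op <- thr$op[k]; cut <- thr$threshold[k]
    below <- leaf_satisfied(op, cut - eps, cut)
    at <- leaf_satisfied(op, cut, cut)
    above <- leaf_satisfied(op, cut + eps, cut)
    if (op == ">")  expect_equal(c(below, at, above), c(FALSE, FALSE, TRUE))
    if (op == ">=") expect_equal(c(below, at, above), c(FALSE, TRUE, TRUE))
    if (op == "<")  expect_equal(c(below, at, above), c(TRUE, FALSE, FALSE))
    if (op == "<=") expect_equal(c(below, at, above), c(TRUE, TRUE, FALSE))
    if (op == "==") expect_equal(c(below, at, above), c(FALSE, TRUE, FALSE))
  }
  # the two paper-printed cutoffs keep their printed semantics
  mri <- thr[thr$rule_id == "breast_mri", ]
  expect_true(all(mri$op == ">") && all(mri$threshold == 20))
  ct <- thr[thr$rule_id == "calcium_score_ct", ]
  expect_true(all(ct$op == ">=") && all(ct$threshold == 7.5))
})

test_that("strengthening FHH evidence never un-fires a fired FHH rule", {
  ped <- required_pedigree(mother_conditions = list(cond("breast_cancer", 40)))
  prof <- baseline_profile()
  cat_r <- load_rule_catalog()
  ev1 <- evaluate_rules(cat_r, prof, ped, assess_all(prof, ped))
  fired1 <- vapply(ev1$recommendations, `[[`, "", "rule_id")
  stronger <- pedigree(ped$proband,
                       c(ped$relatives,
                         list(rec("sister", alive = TRUE, current_age = 42,
                                  conditions = list(cond("breast_cancer", 39),
                                                    cond("ovarian_cancer", 41))))))
  ev2 <- evaluate_rules(cat_r, prof, stronger, assess_all(prof, stronger))
  fired2 <- vapply(ev2$recommendations, `[[`, "", "rule_id")
  fhh_rules <- c("hboc_gc", "lynch_gc", "thrombophilia_gc",
                 "ovarian_screening_discussion", "early_colonoscopy")
  expect_true(all(intersect(fired1, fhh_rules) %in% fired2))
})

test_that("tier summaries count participants, not recommendations", {
  ev <- list(recommendations = list(
    structure(list(rule_id = "a", tier = "monogenic", evidence = list()),
              class = "recommendation"),
    structure(list(rule_id = "b", tier = "familial", evidence = list()),
              class = "recommendation"),
    structure(list(rule_id = "c", tier = "common", evidence = list()),
              class = "recommendation")),
    not_evaluable = character())
  class(ev) <- "rule_evaluation"
  ts <- tier_summary(ev)
  expect_equal(unname(ts$counts), c(1L, 1L, 1L))
  expect_true(all(ts$flags))
  expect_equal(ts$total, 3L)
  empty <- structure(list(recommendations = list(), not_evaluable = character()),
                     class = "rule_evaluation")
  expect_equal(tier_summary(empty)$total, 0L)
  cs <- cohort_tier_summary(list(ev, empty, ev))
  expect_equal(cs$n, 3L)
  expect_equal(unname(cs$tier_counts), c(2L, 2L, 2L))
  expect_equal(cs$any_recommendation, 2L)
})

test_that("reports are deterministic and list every score and recommendation", {
  ped <- required_pedigree(mother_conditions = list(cond("breast_cancer", 40)))
  prof <- baseline_profile(age = 52, hsCRP = NA)
  scores <- assess_all(prof, ped)
  ev <- evaluate_rules(load_rule_catalog(), prof, ped, scores)
  r1 <- render_report(prof, scores, ev)
  r2 <- render_report(prof, scores, ev)
  expect_identical(r1$json, r2$json)
  expect_identical(r1$text, r2$text)
  js <- jsonlite::fromJSON(r1$json, simplifyVector = FALSE)
  expect_setequal(names(js$risk_scores),
                  c("gail", "tyrer_cuzick", "brcapro", "framingham",
                    "reynolds", "pce"))
  expect_equal(js$risk_scores$reynolds$status, "not_calculated")
  expect_equal(unlist(js$risk_scores$reynolds$missing_inputs), "hsCRP")
  expect_length(js$recommendations, length(ev$recommendations))
  # zero-recommendation report says so in prose
  ped0 <- required_pedigree()
  prof0 <- baseline_profile(age = 45, height_cm = 170, weight_kg = 55,
                            systolic_bp = 105, total_cholesterol = 150,
                            HDL = 70)
  empty_cat <- tempfile(fileext = ".yaml")
  writeLines('version: "0"\nrules: []', empty_cat)
  ev0 <- evaluate_rules(load_rule_catalog(empty_cat), prof0, ped0,
                        assess_all(prof0, ped0))
  r0 <- render_report(prof0, assess_all(prof0, ped0), ev0)
  expect_true(any(grepl("None of the elevated-risk criteria", r0$text)))
})

test_that("evidence replay succeeds for every fired rule on a simulated cohort", {
  co <- simulate_cohort(sim_params(n_families = 25), seed = 77)
  cat_r <- load_rule_catalog()
  n_fired <- 0L
  for (i in seq_along(co$pedigrees)) {
    ped <- co$pedigrees[[i]]; prof <- co$profiles[[i]]
    # stratum-fallback warnings for simulated "other"/"black" labels are
    # expected behaviour, tested elsewhere
    scores <- suppressWarnings(assess_all(prof, ped))
    ev <- evaluate_rules(cat_r, prof, ped, scores)
    for (rcm in ev$recommendations) {
      n_fired <- n_fired + 1L
      expect_true(replay_evidence(rcm), info = rcm$rule_id)
    }
  }
  expect_gt(n_fired, 0L)
})
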