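# Seeded generator of realistic primary-care risk-assessment cohorts:
# relationship-coded families of 7+ relatives across three or more
# generations with age-coherent structure, per-condition sporadic hazards,
# optional autosomal-dominant subfamilies (gene dropping), family-level
# shared-environment frailty, and the missing-data patterns of
# patient-entered histories (unknown histories for distant relatives,
# unrecorded onsets, rarely-available labs). Truth tables (genotypes,
# frailties) are emitted for parameter-recovery tests but are never read
# by the assessment pipeline.

#' Default simulation parameters
#'
#' The defaults are the study conditions the generator emulates: family
#' sizes with mean ~13.7 (SD ~7.9) on support 7-74; history known for 95%
#' of first-, 70% of second- and 54% of third-degree relatives; 89.5% of
#' condition entries with a recorded onset; lipids available for about
#' two-thirds of probands and hsCRP for very few; PAM scores centred at
#' 70.8 (SD 13.9). Conditions mix common sporadic disease with one rare
#' highly-penetrant dominant syndrome so that both clustering regimes of
#' real family data (common-disease "affected families" vs monogenic
#' "within family") arise.
#'
#' @param n_families Number of families to simulate.
#' @param size_nbinom `list(mu, size)` of the negative-binomial excess over
#'   the 7 required members; draws are truncated to the 7-74 support.
#' @param conditions Named list; each entry has `annual_hazard` (sporadic,
#'   from `onset_from`), optional `sex`, `onset_from`, and optional `locus`
#'   (`allele_frequency`, `carrier_annual_hazard`).
#' @param shared_frailty_sd SD of the family-level log-normal frailty
#'   multiplying every member's hazard (0 = no shared environment).
#' @param history_known_prob Named probabilities by degree.
#' @param onset_recorded_prob Probability an entered condition carries an
#'   onset age.
#' @param lab_availability Named probabilities that lab/anthropometric
#'   blocks are present in the proband profile.
#' @param pam `list(mean, sd)` of the raw activation-score distribution.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_families = 100,
                       size_nbinom = list(mu = 6.7, size = 0.85),
                       conditions = default_sim_conditions(),
                       shared_frailty_sd = 0.3,
                       history_known_prob = c(FDR = 0.95, SDR = 0.70, TDR = 0.54),
                       onset_recorded_prob = 0.895,
                       lab_availability = c(lipids = 0.65, bp = 0.90,
                                            hscrp = 0.04, anthro = 0.95),
                       pam = list(mean = 70.8, sd = 13.9)) {
  stopifnot(n_families >= 1,
            all(unlist(history_known_prob) >= 0 & unlist(history_known_prob) <= 1),
            onset_recorded_prob >= 0, onset_recorded_prob <= 1,
            all(unlist(lab_availability) >= 0 & unlist(lab_availability) <= 1))
  structure(list(n_families = n_families, size_nbinom = size_nbinom,
                 conditions = conditions, shared_frailty_sd = shared_frailty_sd,
                 history_known_prob = history_known_prob,
                 onset_recorded_prob = onset_recorded_prob,
                 lab_availability = lab_availability, pam = pam),
            class = "sim_params")
}

#' @rdname sim_params
#' @export
default_sim_conditions <- function() {
  list(
    breast_cancer = list(annual_hazard = 0.0018, sex = "female", onset_from = 25,
                         locus = list(allele_frequency = 0.003,
                                      carrier_annual_hazard = 0.025)),
    ovarian_cancer = list(annual_hazard = 0.0002, sex = "female", onset_from = 30),
    colon_cancer = list(annual_hazard = 0.0009, onset_from = 30),
    coronary_artery_disease = list(annual_hazard = 0.0035, onset_from = 35),
    type_2_diabetes = list(annual_hazard = 0.0048, onset_from = 30),
    marfan_syndrome = list(annual_hazard = 0.000005, onset_from = 0,
                           locus = list(allele_frequency = 0.002,
                                        carrier_annual_hazard = 0.06)))
}

# ---- structure -------------------------------------------------------------

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample one family's relationship structure
#'
#' Proband, parents and all four grandparents are always present; further
#' relatives (siblings, children, aunts/uncles, cousins, nieces/nephews,
#' grandchildren) are added until the drawn target size is reached.
#' Attained ages are coherent across generations: every parent is at least
#' 15 years older than each child (asserted internally and exported via
#' the `"attained_ages"` attribute — a deceased relative's record keeps
#' only the age at death, which can be lower). Deterministic given the
#' seed.
#'
#' @param params A `sim_params`.
#' @param seed Integer seed for this family.
#' @return A skeleton `pedigree` (records without conditions), with an
#'   `"attained_ages"` attribute naming each individual's attained age.
#' @export
sample_family_structure <- function(params, seed) {
  set.seed(seed)
  target <- 7L + stats::rnbinom(1, mu = params$size_nbinom$mu,
                                size = params$size_nbinom$size)
  target <- min(target, 74L)
  P <- round(.clamp(stats::rnorm(1, 57, 12), 25, 88))
  proband_sex <- sample(c("female", "male"), 1, prob = c(0.69, 0.31))
  # generation anchor ages (attained, possibly past any survivable age --
  # such relatives are recorded as deceased), built parent-before-child so
  # every gap is >= 16
  mother_age <- round(P + 22 + stats::rpois(1, 6))
  father_age <- round(P + 22 + stats::rpois(1, 6))
  mgp <- round(mother_age + 22 + stats::rpois(1, 6))
  mgp2 <- round(mother_age + 22 + stats::rpois(1, 6))
  pgp <- round(father_age + 22 + stats::rpois(1, 6))
  pgp2 <- round(father_age + 22 + stats::rpois(1, 6))
  first_sib_age <- NULL; first_child_age <- NULL
  role_age <- function(role) {
    a <- switch(role,
      self = P, mother = mother_age, father = father_age,
      maternal_grandmother = mgp, maternal_grandfather = mgp2,
      paternal_grandmother = pgp, paternal_grandfather = pgp2,
      sister = , brother =
        .clamp(P + sample(-10:10, 1), 16, min(mother_age, father_age) - 16),
      maternal_aunt = , maternal_uncle =
        .clamp(min(mgp, mgp2) - 22 + sample(-6:6, 1), 16, 110),
      paternal_aunt = , paternal_uncle =
        .clamp(min(pgp, pgp2) - 22 + sample(-6:6, 1), 16, 110),
      maternal_cousin = , paternal_cousin = .clamp(P + sample(-12:12, 1), 16, 100),
      daughter = , son = max(P - 25 - sample(0:8, 1), 1),
      niece = , nephew = max((first_sib_age %||% P) - 22 - sample(0:8, 1), 1),
      granddaughter = , grandson =
        max((first_child_age %||% (P - 25)) - 22 - sample(0:6, 1), 1))
    round(a)
  }
  mk <- function(role, sex = NULL) {
    A <- role_age(role)
    # death-age draw; older relatives more likely deceased
    D <- round(.clamp(stats::rnorm(1, 80, 12), 40, 108))
    rec <- if (role == "self")
      list(relation = role, sex = sex, alive = TRUE, current_age = A,
           ashkenazi = stats::runif(1) < 0.04)
    else if (A < D)
      list(relation = role, sex = sex, alive = TRUE, current_age = A)
    else
      list(relation = role, sex = sex, alive = FALSE,
           age_at_death = D, cause_of_death = "natural causes")
    attr(rec, "attained_age") <- A
    rec
  }
  roles <- list(mk("self", proband_sex), mk("mother"), mk("father"),
                mk("maternal_grandmother"), mk("maternal_grandfather"),
                mk("paternal_grandmother"), mk("paternal_grandfather"))
  pool <- c("sister", "brother", "maternal_aunt", "maternal_uncle",
            "paternal_aunt", "paternal_uncle", "maternal_cousin",
            "paternal_cousin", "niece", "nephew")
  w <- c(2, 2, 1.6, 1.6, 1.6, 1.6, 0.8, 0.8, 0.9, 0.9)
  if (P >= 28) { pool <- c(pool, "daughter", "son"); w <- c(w, 2, 2) }
  if (P >= 60) { pool <- c(pool, "granddaughter", "grandson"); w <- c(w, 0.7, 0.7) }
  n_extra <- max(target - 7L, 0L)
  sibs <- 0L; kids <- 0L
  for (k in seq_len(n_extra)) {
    role <- sample(pool, 1, prob = w)
    # nieces/nephews and grandchildren need their connecting relative
    if (role %in% c("niece", "nephew") && sibs == 0L) role <- "sister"
    if (role %in% c("granddaughter", "grandson") && kids == 0L) role <- "daughter"
    sex <- if (role %in% c("maternal_cousin", "paternal_cousin"))
      sample(c("female", "male"), 1) else NULL
    rec <- mk(role, sex)
    if (role %in% c("sister", "brother")) {
      sibs <- sibs + 1L
      if (is.null(first_sib_age)) first_sib_age <- attr(rec, "attained_age")
    }
    if (role %in% c("daughter", "son")) {
      kids <- kids + 1L
      if (is.null(first_child_age)) first_child_age <- attr(rec, "attained_age")
    }
    roles[[length(roles) + 1L]] <- rec
  }
  ages <- vapply(roles, function(x) attr(x, "attained_age"), 0)
  recs <- lapply(roles, function(x) {
    attr(x, "attained_age") <- NULL
    do.call(relative_record, x)
  })
  ped <- pedigree(recs[[1]], recs[-1])
  names(ages) <- .record_ids(recs)
  attr(ped, "attained_ages") <- ages
  ped
}

# ---- gene dropping ---------------------------------------------------------

#' Drop genotypes down a pedigree graph
#'
#' Founders draw mutant-allele copies from Hardy-Weinberg proportions at
#' the locus allele frequency; non-founders inherit one allele from each
#' parent with probability copies/2 (standard gene dropping).
#'
#' @param graph A `pedigree_graph`.
#' @param locus_spec List with `allele_frequency`.
#' @param seed Integer seed.
#' @return Named integer vector of mutant-allele copies (0/1/2) per
#'   individual id.
#' @export
drop_genotypes <- function(graph, locus_spec, seed) {
  set.seed(seed)
  f <- locus_spec$allele_frequency
  stopifnot(f >= 0, f <= 0.5)
  ind <- graph$individuals
  copies <- setNames(rep(NA_integer_, nrow(ind)), ind$id)
  assign_copies <- function(id) {
    if (!is.na(copies[[id]])) return(copies[[id]])
    i <- match(id, ind$id)
    if (is.na(ind$father[i])) {
      g <- sample(0:2, 1, prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    } else {
      gm <- assign_copies(ind$mother[i]); gf <- assign_copies(ind$father[i])
      g <- stats::rbinom(1, 1, gm / 2) + stats::rbinom(1, 1, gf / 2)
    }
    copies[[id]] <<- g
    g
  }
  for (id in ind$id) assign_copies(id)
  copies
}

# ---- phenotypes ------------------------------------------------------------

# exponential onset sampling from `from` with constant annual hazard
.sample_onset <- function(hazard, from) {
  if (hazard <= 0) return(Inf)
  from + stats::rexp(1, rate = hazard)
}

#' Assign phenotypes, missingness masks and a truth table to a skeleton
#'
#' For each condition, each individual's hazard is the sporadic annual
#' hazard (or the carrier hazard where a dominant locus is specified and
#' the individual carries it) multiplied by the family's shared log-normal
#' frailty; onset is sampled from the resulting exponential clock and the
#' individual is affected if onset precedes the censoring age. Missingness
#' is then applied: relatives lose their whole history with the
#' degree-specific probability, and recorded onsets are dropped at the
#' configured rate.
#'
#' @param skeleton A skeleton `pedigree` from [sample_family_structure()].
#' @param params A `sim_params`.
#' @param seed Integer seed for this family.
#' @return List: `pedigree` (completed), `truth` (data frame of carrier
#'   copies per locus condition and the family frailty), `frailty`.
#' @export
assign_phenotypes <- function(skeleton, params, seed) {
  set.seed(seed)
  graph <- expand_to_graph(skeleton)
  ind <- graph$individuals
  frailty <- exp(stats::rnorm(1, 0, params$shared_frailty_sd))
  recs <- .all_records(skeleton)
  ids <- .record_ids(recs)

  genos <- list()
  for (cc in names(params$conditions)) {
    loc <- params$conditions[[cc]]$locus
    if (!is.null(loc))
      genos[[cc]] <- drop_genotypes(graph, loc,
                                    seed = seed + match(cc, names(params$conditions)))
  }

  onsets <- list()  # per record index: list of condition -> onset age
  for (j in seq_along(recs)) {
    r <- recs[[j]]; id <- ids[j]
    cens <- r$current_age %||% r$age_at_death
    if (is.null(cens)) next
    for (cc in names(params$conditions)) {
      spec <- params$conditions[[cc]]
      if (!is.null(spec$sex) && !identical(spec$sex, "any") &&
          !identical(r$sex, spec$sex)) next
      hz <- spec$annual_hazard
      if (!is.null(spec$locus) && genos[[cc]][[id]] > 0)
        hz <- spec$locus$carrier_annual_hazard
      onset <- .sample_onset(hz * frailty, spec$onset_from %||% 20)
      if (onset <= cens)
        onsets[[as.character(j)]] <- c(onsets[[as.character(j)]] %||% list(),
                                       setNames(list(round(onset)), cc))
    }
  }

  # rebuild records with conditions + missingness masks
  new_recs <- vector("list", length(recs))
  for (j in seq_along(recs)) {
    r <- recs[[j]]
    deg <- classify_degree(r$relation)
    known <- if (deg == "SELF") TRUE
             else stats::runif(1) < params$history_known_prob[[deg]]
    conds <- list()
    if (known) {
      for (cc in names(onsets[[as.character(j)]] %||% list())) {
        onset <- onsets[[as.character(j)]][[cc]]
        if (stats::runif(1) >= params$onset_recorded_prob) onset <- NULL
        conds[[length(conds) + 1L]] <- list(condition = cc, age_of_onset = onset)
      }
    }
    new_recs[[j]] <- relative_record(
      relation = r$relation, sex = r$sex, alive = r$alive,
      current_age = r$current_age, age_at_death = r$age_at_death,
      cause_of_death = r$cause_of_death, history_known = known,
      conditions = conds, race_ethnicity = r$race_ethnicity,
      ashkenazi = r$ashkenazi, consanguinity = r$consanguinity)
  }
  truth <- data.frame(id = ind$id, stringsAsFactors = FALSE)
  for (cc in names(genos)) truth[[paste0("copies_", cc)]] <- genos[[cc]][ind$id]
  truth$frailty <- frailty
  list(pedigree = pedigree(new_recs[[1]], new_recs[-1]),
       truth = truth, frailty = frailty)
}

# ---- proband profile -------------------------------------------------------

.sim_profile <- function(ped, params) {
  pr <- ped$proband
  lab <- params$lab_availability
  has <- function(p) stats::runif(1) < p
  lipids <- has(lab[["lipids"]]); bp <- has(lab[["bp"]])
  crp <- has(lab[["hscrp"]]); anthro <- has(lab[["anthro"]])
  female <- identical(pr$sex, "female")
  parous <- female && has(0.8)
  risk_profile(
    age = pr$current_age %||% pr$age_at_death, sex = pr$sex,
    race_ethnicity = sample(c("white", "black", "other"), 1,
                            prob = c(0.85, 0.08, 0.07)),
    menarche_age = if (female) round(.clamp(stats::rnorm(1, 13, 1.4), 9, 17)),
    age_first_live_birth = if (parous) round(.clamp(stats::rnorm(1, 26, 5), 15, 42)),
    no_live_births = if (female) !parous,
    breast_biopsy_count = if (female) stats::rbinom(1, 2, 0.08),
    atypical_hyperplasia = if (female) "unknown",
    hrt_use = if (female) sample(c("never", "former", "current"), 1,
                                 prob = c(0.8, 0.12, 0.08)),
    height_cm = if (anthro) round(stats::rnorm(1, if (female) 163 else 177, 7)),
    weight_kg = if (anthro) round(.clamp(stats::rnorm(1, if (female) 74 else 88, 16), 45, 180)),
    systolic_bp = if (bp) round(.clamp(stats::rnorm(1, 126, 15), 90, 200)),
    treated_hypertension = if (bp) has(0.25),
    total_cholesterol = if (lipids) round(.clamp(stats::rnorm(1, 205, 35), 110, 400)),
    HDL = if (lipids) round(.clamp(stats::rnorm(1, 55, 14), 25, 110)),
    smoker = has(0.15), diabetes = has(0.10),
    hsCRP = if (crp) round(stats::rlnorm(1, log(1.8), 0.7), 2),
    parental_MI_before_60 = NA)
}

#' Simulate a complete risk-assessment cohort
#'
#' Generates `params$n_families` families (structure, genotypes,
#' phenotypes, missingness), one personal risk-factor profile per proband,
#' and raw PAM scores. Each family uses an independent seed substream
#' derived from the master seed, so cohorts are fully reproducible and
#' per-family output does not depend on generation order.
#'
#' @param params A `sim_params`.
#' @param seed Master integer seed (mandatory).
#' @return A `sim_cohort`: `pedigrees`, `profiles`, `truth` (row-bound
#'   per-family truth tables with a `family` column), `pam_scores`,
#'   `params`, `seed`.
#' @export
simulate_cohort <- function(params = sim_params(), seed) {
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  peds <- vector("list", params$n_families)
  profs <- vector("list", params$n_families)
  truths <- vector("list", params$n_families)
  for (i in seq_len(params$n_families)) {
    fam_seed <- seed + 7919L * i
    skel <- sample_family_structure(params, fam_seed)
    ph <- assign_phenotypes(skel, params, fam_seed + 1L)
    peds[[i]] <- ph$pedigree
    tr <- ph$truth; tr$family <- i
    truths[[i]] <- tr
    set.seed(fam_seed + 2L)
    profs[[i]] <- .sim_profile(ph$pedigree, params)
  }
  set.seed(seed)
  pam <- .clamp(stats::rnorm(params$n_families, params$pam$mean, params$pam$sd),
                0, 100)
  structure(list(pedigrees = peds, profiles = profs,
                 truth = do.call(rbind, truths), pam_scores = pam,
                 params = params, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  sizes <- vapply(x$pedigrees, pedigree_size, 0L)
  cat("<sim_cohort>", length(x$pedigrees), "families; size mean",
      round(mean(sizes), 1), "range", paste(range(sizes), collapse = "-"), "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One interchange-format pedigree JSON and one profile JSON per proband,
#' plus a truth-table CSV and a PAM score CSV.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$pedigrees)) {
    serialize_pedigree(cohort$pedigrees[[i]],
                       file.path(dir, sprintf("family_%04d.json", i)))
    serialize_profile(cohort$profiles[[i]],
                      file.path(dir, sprintf("profile_%04d.json", i)))
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(data.frame(family = seq_along(cohort$pam_scores),
                              pam = cohort$pam_scores),
                   file.path(dir, "pam.csv"), row.names = FALSE)
  invisible(dir)
}
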