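# Fixtures are built in code; nothing is read from disk except the
# package's own shipped configs.

rec <- function(relation, ..., conditions = list()) {
  relative_record(relation, ..., conditions = conditions)
}

cond <- function(code, onset = NULL) list(condition = code, age_of_onset = onset)

# the seven-member pedigree every proband must complete (parents and all
# four grandparents)
required_pedigree <- function(proband_age = 45, proband_sex = "female",
                              mother_conditions = list(), ashkenazi = FALSE) {
  pedigree(
    rec("self", sex = proband_sex, alive = TRUE, current_age = proband_age,
        ashkenazi = ashkenazi),
    list(rec("mother", alive = FALSE, age_at_death = 70,
             cause_of_death = "natural causes", conditions = mother_conditions),
         rec("father", alive = TRUE, current_age = 75),
         rec("maternal_grandmother", alive = FALSE, age_at_death = 82,
             cause_of_death = "natural causes"),
         rec("maternal_grandfather", alive = FALSE, age_at_death = 78,
             cause_of_death = "natural causes"),
         rec("paternal_grandmother", alive = TRUE, current_age = 96),
         rec("paternal_grandfather", alive = FALSE, age_at_death = 60,
             cause_of_death = "natural causes")))
}

baseline_profile <- function(...) {
  args <- utils::modifyList(
    list(age = 45, sex = "female", race_ethnicity = "white",
         menarche_age = 13, age_first_live_birth = 26, no_live_births = FALSE,
         breast_biopsy_count = 0, hrt_use = "never",
         height_cm = 165, weight_kg = 68,
         systolic_bp = 120, treated_hypertension = FALSE,
         total_cholesterol = 200, HDL = 55, smoker = FALSE, diabetes = FALSE,
         hsCRP = 1.5, parental_MI_before_60 = FALSE),
    list(...))
  do.call(risk_profile, args)
}

# build a pedigree_graph directly (bypassing relation codes) for
# Mendelian-model tests
make_graph <- function(individuals, conditions = NULL, ashkenazi = FALSE) {
  ind <- do.call(rbind, lapply(individuals, function(x)
    data.frame(id = x$id,
               father = x$father %||% NA_character_,
               mother = x$mother %||% NA_character_,
               sex = x$sex, generation = x$generation %||% 1L,
               relation = NA_character_,
               alive = x$alive %||% NA,
               censor_age = x$censor %||% NA_real_,
               history_known = x$known %||% TRUE,
               placeholder = FALSE, stringsAsFactors = FALSE)))
  conds <- if (is.null(conditions))
    data.frame(id = character(), condition = character(),
               age_of_onset = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, lapply(conditions, function(x)
    data.frame(id = x$id, condition = x$condition,
               age_of_onset = x$onset %||% NA_real_, stringsAsFactors = FALSE)))
  structure(list(individuals = ind, conditions = conds,
                 proband_id = individuals[[1]]$id,
                 ashkenazi = ashkenazi, consanguinity = FALSE),
            class = "pedigree_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-gene model config (3 genotype states), written once per session;
# used where exhaustive enumeration must stay cheap
single_gene_model <- local({
  m <- NULL
  function() {
    if (!is.null(m)) return(m)
    path <- tempfile(fileext = ".yaml")
    writeLines("
model: single_gene_test
version: '0.1'
genes:
  GENE1:
    allele_frequency: {general: 0.01, ashkenazi: 0.05}
cancers:
  breast:
    condition: breast_cancer
    female:
      ages:       [20, 40, 60, 80, 110]
      noncarrier: [0.001, 0.02, 0.07, 0.12, 0.135]
      GENE1:      [0.005, 0.20, 0.50, 0.65, 0.70]
    male:
      ages:       [20, 110]
      noncarrier: [0.0, 0.001]
      GENE1:      [0.0, 0.05]
  ovarian:
    condition: ovarian_cancer
    female:
      ages:       [20, 50, 80, 110]
      noncarrier: [0.0, 0.005, 0.014, 0.015]
      GENE1:      [0.0, 0.15, 0.40, 0.45]
    male:
      ages:       [20, 110]
      noncarrier: [0.0, 0.0]
      GENE1:      [0.0, 0.0]
", path)
    m <<- load_gene_model(path)
    m
  }
})

# random pedigree-graph generator for oracle batteries: individuals are
# added either as founders or as children of an existing couple (spouse
# founders created on demand), then given random censoring ages and
# phenotypes
random_graph <- function(n, model, p_affected = 0.25, p_unknown = 0.1) {
  stopifnot(n >= 1)
  inds <- list(list(id = "i1", sex = sample(c("female", "male"), 1),
                    generation = 1L, censor = sample(30:80, 1), known = TRUE))
  couples <- list()
  while (length(inds) < n) {
    i <- length(inds) + 1L
    id <- paste0("i", i)
    if (length(inds) >= 2 && stats::runif(1) < 0.75) {
      # child of an existing or new couple
      if (length(couples) && stats::runif(1) < 0.6) {
        cp <- couples[[sample(length(couples), 1)]]
      } else {
        par <- inds[[sample(length(inds), 1)]]
        sp_id <- paste0("i", i, "s")
        sp <- list(id = sp_id,
                   sex = if (par$sex == "female") "male" else "female",
                   generation = par$generation,
                   censor = sample(30:90, 1), known = TRUE)
        inds[[length(inds) + 1L]] <- sp
        cp <- if (par$sex == "female") list(mother = par$id, father = sp_id)
              else list(mother = sp_id, father = par$id)
        couples[[length(couples) + 1L]] <- cp
        if (length(inds) >= n) break
        i <- length(inds) + 1L
        id <- paste0("i", i)
      }
      inds[[length(inds) + 1L]] <-
        list(id = id, sex = sample(c("female", "male"), 1),
             mother = cp$mother, father = cp$father,
             generation = 0L, censor = sample(20:70, 1), known = TRUE)
    } else {
      inds[[length(inds) + 1L]] <-
        list(id = id, sex = sample(c("female", "male"), 1),
             generation = 1L, censor = sample(30:90, 1), known = TRUE)
    }
  }
  inds <- inds[seq_len(n)]
  # drop parent links pointing outside the kept set
  kept <- vapply(inds, `[[`, "", "id")
  inds <- lapply(inds, function(x) {
    if (!is.null(x$mother) && !(x$mother %in% kept && x$father %in% kept)) {
      x$mother <- NULL; x$father <- NULL
    }
    x
  })
  conds <- list()
  for (x in inds) {
    if (stats::runif(1) < p_unknown) next
    if (stats::runif(1) < p_affected && x$sex == "female") {
      onset <- sample(25:min(x$censor, 75), 1)
      conds[[length(conds) + 1L]] <-
        list(id = x$id, condition = "breast_cancer", onset = onset)
    }
  }
  inds <- lapply(inds, function(x) {
    if (stats::runif(1) < p_unknown) x$known <- FALSE
    x
  })
  make_graph(inds, if (length(conds)) conds)
}
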