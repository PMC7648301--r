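# Independent oracle: exhaustive enumeration over every joint genotype
# assignment. Shares only the model *parameters* (frequencies, penetrance
# grids, transmission kernel by Mendelian law) with the implementation;
# the summation path and the phenotype-term computation are written from
# scratch here.

# cumulative penetrance at an age, recomputed by direct interpolation on
# the model's annual grid
oracle_F <- function(model, cancer, sex, age) {
  m <- model$state_pen[[cancer]][[sex]]
  ages <- model$ages
  if (age <= ages[1] - 1) return(rep(0, ncol(m)))
  age <- min(max(age, ages[1]), ages[length(ages)])
  vapply(seq_len(ncol(m)), function(s)
    stats::approx(ages, m[, s], xout = age)$y, 0)
}

oracle_phenotype <- function(model, row, cond_df) {
  S <- model$n_states
  v <- rep(1, S)
  if (!isTRUE(row$history_known)) return(v)
  if (is.na(row$sex) || !row$sex %in% c("male", "female")) return(v)
  for (cn in names(model$pen)) {
    code <- model$cond_map[[cn]]
    hit <- which(cond_df$condition == code & cond_df$id == row$id)
    if (length(hit)) {
      onset <- cond_df$age_of_onset[hit[1]]
      if (is.na(onset)) {
        if (!is.na(row$censor_age))
          v <- v * oracle_F(model, cn, row$sex, row$censor_age)
      } else {
        v <- v * pmax(oracle_F(model, cn, row$sex, onset) -
                      oracle_F(model, cn, row$sex, onset - 1), 1e-300)
      }
    } else if (!is.na(row$censor_age)) {
      v <- v * (1 - oracle_F(model, cn, row$sex, row$censor_age))
    }
  }
  v
}

# returns list(joint = P(data, G_c) over states, prior = P(G_c) over
# states), both by full enumeration (S^n assignments)
oracle_enumerate <- function(g, model, counselee = g$proband_id,
                             stratum = "general") {
  ind <- g$individuals
  n <- nrow(ind); S <- model$n_states
  stopifnot(S^n <= 4e6)
  prior <- model$prior[, stratum]
  ph <- vapply(seq_len(n), function(i)
    oracle_phenotype(model, ind[i, ], g$conditions), numeric(S))
  idx <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  w_struct <- rep(1, nrow(idx))   # prior x transmission only
  for (i in seq_len(n)) {
    if (is.na(ind$father[i])) {
      w_struct <- w_struct * prior[idx[, i]]
    } else {
      mi <- match(ind$mother[i], ind$id); fi <- match(ind$father[i], ind$id)
      w_struct <- w_struct * model$trans[cbind(idx[, i], idx[, mi], idx[, fi])]
    }
  }
  w_pheno <- w_struct
  for (i in seq_len(n)) w_pheno <- w_pheno * ph[idx[, i], i]
  ci <- match(counselee, ind$id)
  joint <- vapply(seq_len(S), function(s) sum(w_pheno[idx[, ci] == s]), 0)
  pri <- vapply(seq_len(S), function(s) sum(w_struct[idx[, ci] == s]), 0)
  list(joint = joint, prior = pri)
}

# class-aggregated posterior and per-class likelihood from an enumeration
oracle_posterior <- function(enum, model) {
  post <- enum$joint / sum(enum$joint)
  vapply(model$classes, function(cl) sum(post[model$class_of == cl]), 0)
}

oracle_likelihood <- function(enum, model) {
  vapply(model$classes, function(cl) {
    idx <- model$class_of == cl
    den <- sum(enum$prior[idx])
    if (den == 0) 0 else sum(enum$joint[idx]) / den
  }, 0)
}
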