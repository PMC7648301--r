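# Exact pedigree likelihood by variable elimination over the genotype
# factor graph (Elston-Stewart peeling generalised to an arbitrary
# loop-free elimination order). Factors are dense arrays over joint
# genotype states; intermediate factors are rescaled to unit maximum with
# the log-constant accumulated, so deep pedigrees do not underflow.

.fexpand <- function(f, vars, S) {
  extra <- setdiff(vars, f$vars)
  a <- f$a
  if (length(extra))
    a <- array(a, dim = c(rep(S, length(f$vars)), rep(S, length(extra))))
  ord <- match(vars, c(f$vars, extra))
  if (length(vars) > 1L) a <- aperm(a, ord)
  a
}

.fmul <- function(f1, f2, S) {
  vars <- union(f1$vars, f2$vars)
  list(vars = vars, a = .fexpand(f1, vars, S) * .fexpand(f2, vars, S))
}

.fmarg <- function(f, var, S) {
  if (length(f$vars) == 1L)
    return(list(vars = character(0), a = sum(f$a)))
  i <- match(var, f$vars)
  keep <- setdiff(seq_along(f$vars), i)
  a <- aperm(f$a, c(keep, i))
  m <- rowSums(matrix(a, ncol = S))
  list(vars = f$vars[keep], a = array(m, dim = rep(S, length(keep))))
}

# phenotype factor for one individual: product over modelled cancers of
# - affected at onset a: annual increment F(a) - F(a-1)   (density on the
#   annual grid); affected with onset unknown: F(censor age);
# - unaffected to censor age c: 1 - F(c);
# - history unknown or no censoring age: 1.
.phenotype_vec <- function(model, row, cond_df) {
  S <- model$n_states
  v <- rep(1, S)
  if (!isTRUE(row$history_known)) return(v)
  sex <- row$sex
  if (is.na(sex) || !sex %in% c("male", "female")) return(v)
  cens <- row$censor_age
  for (cn in names(model$pen)) {
    code <- model$cond_map[[cn]]
    hit <- cond_df$condition == code & cond_df$id == row$id
    if (any(hit)) {
      onset <- cond_df$age_of_onset[hit][1]
      if (is.na(onset)) {
        if (!is.na(cens)) v <- v * .state_F(model, cn, sex, cens)
      } else {
        inc <- .state_F(model, cn, sex, onset) -
               .state_F(model, cn, sex, onset - 1)
        v <- v * pmax(inc, 1e-300)
      }
    } else if (!is.na(cens)) {
      v <- v * (1 - .state_F(model, cn, sex, cens))
    }
  }
  v
}

# joint distribution P(phenotypes, G_counselee) over genotype states;
# with use_phenotypes = FALSE this is the prior marginal of the counselee.
.peel_joint <- function(g, model, counselee, stratum, use_phenotypes = TRUE) {
  ind <- g$individuals
  if (!counselee %in% ind$id)
    stop("counselee not in graph: ", counselee, call. = FALSE)
  if (!stratum %in% model$strata)
    stop("unknown ancestry stratum: ", stratum, call. = FALSE)
  .assert_acyclic(g)
  .assert_no_loops(g)
  S <- model$n_states
  prior <- model$prior[, stratum]
  factors <- list()
  for (i in seq_len(nrow(ind))) {
    id <- ind$id[i]
    if (is.na(ind$father[i])) {
      factors[[length(factors) + 1L]] <- list(vars = id, a = prior)
    } else {
      factors[[length(factors) + 1L]] <-
        list(vars = c(id, ind$mother[i], ind$father[i]), a = model$trans)
    }
    if (use_phenotypes) {
      ph <- .phenotype_vec(model, ind[i, ], g$conditions)
      if (any(ph != 1))
        factors[[length(factors) + 1L]] <- list(vars = id, a = ph)
    }
  }
  logc <- 0
  elim <- setdiff(ind$id, counselee)
  while (length(elim)) {
    # greedy min-width: eliminate the variable whose combined factor is smallest
    widths <- vapply(elim, function(v) {
      inv <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars)))
      length(inv)
    }, 0L)
    v <- elim[which.min(widths)]
    inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
    fs <- factors[inv]
    factors <- factors[!inv]
    acc <- fs[[1]]
    for (f in fs[-1]) acc <- .fmul(acc, f, S)
    acc <- .fmarg(acc, v, S)
    mx <- max(acc$a)
    if (mx > 0) { acc$a <- acc$a / mx; logc <- logc + log(mx) }
    factors[[length(factors) + 1L]] <- acc
    elim <- setdiff(elim, v)
  }
  out <- factors[[1]]
  for (f in factors[-1]) out <- .fmul(out, f, S)
  stopifnot(identical(out$vars, counselee))
  list(joint = as.numeric(out$a), log_const = logc)
}

# marriage loops / inbreeding are unsupported: no two individuals may share
# both a child and an ancestor path (detected as a parent pair appearing
# with individuals already related). A cheap sufficient check: the factor
# graph must stay a tree over nuclear families, i.e. each individual is a
# child in at most one family (guaranteed) and no ancestor is reachable
# from both members of any parent pair.
.assert_no_loops <- function(g) {
  ind <- g$individuals
  anc <- function(id) {
    out <- character(); stack <- id
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      i <- match(x, ind$id)
      for (p in c(ind$father[i], ind$mother[i]))
        if (!is.na(p) && !p %in% out) { out <- c(out, p); stack <- c(stack, p) }
    }
    out
  }
  pairs <- unique(stats::na.omit(
    data.frame(f = ind$father, m = ind$mother, stringsAsFactors = FALSE)))
  for (k in seq_len(nrow(pairs)))
    if (length(intersect(c(pairs$f[k], anc(pairs$f[k])),
                         c(pairs$m[k], anc(pairs$m[k])))))
      stop("unsupported pedigree structure: consanguinity loop between ",
           pairs$f[k], " and ", pairs$m[k], call. = FALSE)
  invisible(TRUE)
}

#' Pedigree likelihood given the counselee's genotype
#'
#' Computes `P(all observed phenotypes | counselee carrier class)` by exact
#' peeling: the product of founder Hardy-Weinberg priors, Mendelian
#' transmission terms and per-individual phenotype terms, summed over all
#' genotypes except the counselee's. Affected individuals contribute the
#' annual increment of the cumulative penetrance at their onset age;
#' unaffected individuals the survival to their censoring age; relatives
#' with unknown history contribute 1 (they preserve transmission structure
#' only).
#'
#' @param g A `pedigree_graph`.
#' @param model A `gene_model`.
#' @param counselee_genotype Carrier class: `"noncarrier"`, a gene name,
#'   or `"multiple"`; `NULL` returns the likelihood for every class.
#' @param counselee Individual id (default the proband).
#' @param stratum Ancestry stratum; default follows the proband's
#'   Ashkenazi flag.
#' @return Named numeric of likelihood values (one per requested class).
#' @export
pedigree_likelihood <- function(g, model, counselee_genotype = NULL,
                                counselee = g$proband_id,
                                stratum = if (isTRUE(g$ashkenazi)) "ashkenazi" else "general") {
  jt <- .peel_joint(g, model, counselee, stratum, use_phenotypes = TRUE)
  pr <- .peel_joint(g, model, counselee, stratum, use_phenotypes = FALSE)
  classes <- if (is.null(counselee_genotype)) model$classes else counselee_genotype
  out <- vapply(classes, function(cl) {
    if (!cl %in% model$classes) stop("unknown carrier class: ", cl, call. = FALSE)
    idx <- model$class_of == cl
    num <- sum(jt$joint[idx]); den <- sum(pr$joint[idx]) * exp(pr$log_const)
    if (den == 0) return(0)
    num * exp(jt$log_const) / den
  }, 0)
  names(out) <- classes
  out
}

#' Carrier posterior for the counselee
#'
#' Bayesian posterior over carrier classes: prior times peeled pedigree
#' likelihood, normalised. The class `carrier_probability` aggregate is
#' `1 - P(noncarrier)`.
#'
#' @inheritParams pedigree_likelihood
#' @return A `genotype_posterior`: named probabilities per carrier class
#'   (summing to 1), plus `carrier_probability` and the stratum used.
#' @export
carrier_posterior <- function(g, model, counselee = g$proband_id,
                              stratum = if (isTRUE(g$ashkenazi)) "ashkenazi" else "general") {
  jt <- .peel_joint(g, model, counselee, stratum, use_phenotypes = TRUE)
  tot <- sum(jt$joint)
  post_states <- if (tot > 0) jt$joint / tot else model$prior[, stratum] / sum(model$prior[, stratum])
  probs <- vapply(model$classes, function(cl)
    sum(post_states[model$class_of == cl]), 0)
  structure(list(probabilities = probs,
                 carrier_probability = unname(1 - probs[["noncarrier"]]),
                 counselee = counselee, stratum = stratum,
                 model = model$name),
            class = "genotype_posterior")
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat("<genotype_posterior> counselee:", x$counselee,
      " P(carrier) =", signif(x$carrier_probability, 4), "\n")
  print(signif(x$probabilities, 4))
  invisible(x)
}

#' Residual absolute cancer risk from a carrier posterior
#'
#' Mixture over carrier classes of the conditional cumulative risk
#' `(F_G(a + h) - F_G(a)) / (1 - F_G(a))`, weighted by the posterior;
#' requires the counselee to be unaffected for the target cancer at the
#' current age.
#'
#' @param post A `genotype_posterior`.
#' @param model The `gene_model` the posterior was computed under.
#' @param current_age Counselee age in years.
#' @param horizon Years ahead (use `to_age` for a lifetime-to-age horizon).
#' @param cancer Modelled cancer name (e.g. `"breast"`).
#' @param sex Counselee sex.
#' @param to_age If given, overrides `horizon` with `to_age - current_age`.
#' @return An `absolute_risk`: condition, horizon, probability in `[0, 1]`.
#' @export
future_cancer_risk <- function(post, model, current_age, horizon = NULL,
                               cancer = "breast", sex = "female",
                               to_age = NULL) {
  if (!is.null(to_age)) horizon <- to_age - current_age
  if (is.null(horizon) || horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  F0 <- .class_F(model, cancer, sex, current_age)
  F1 <- .class_F(model, cancer, sex, current_age + horizon)
  cond <- ifelse(F0 < 1, (F1 - F0) / (1 - F0), 0)
  p <- sum(post$probabilities * cond[model$classes])
  structure(list(condition = model$cond_map[[cancer]],
                 horizon_years = horizon, to_age = current_age + horizon,
                 probability = max(0, min(1, p))),
            class = "absolute_risk")
}

#' @export
print.absolute_risk <- function(x, ...) {
  cat("<absolute_risk>", x$condition, "to age", x$to_age, ":",
      sprintf("%.2f%%", 100 * x$probability), "\n")
  invisible(x)
}
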