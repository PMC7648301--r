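#' Load a Mendelian gene model from YAML
#'
#' A gene model names one or more autosomal-dominant susceptibility genes
#' with per-ancestry-stratum allele frequencies, and per-cancer, per-sex
#' cumulative penetrance curves for noncarriers and for carriers of each
#' gene. Anchor points are interpolated to an annual age grid (20-110) and
#' validated: frequencies in (0, 0.5], curves nondecreasing and bounded by
#' 1, noncarrier curve never above any carrier curve.
#'
#' Per-gene genotypes are counted in mutant-allele copies (0/1/2); the
#' joint genotype space is the product over genes. For penetrance, joint
#' genotypes collapse to carrier classes: `noncarrier`, one class per gene
#' (sole carried gene), and `multiple` (carrier of more than one gene,
#' penetrance the pointwise maximum of the carried genes' curves).
#'
#' @param path YAML file; default is the two-gene (BRCA1/BRCA2) model
#'   shipped with the package.
#' @return A `gene_model` object.
#' @export
load_gene_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_model_brca.yaml", package = "fhhrisk",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  genes <- names(raw$genes)
  if (!length(genes)) stop("gene model declares no genes", call. = FALSE)
  freqs <- lapply(raw$genes, function(g) {
    f <- unlist(g$allele_frequency)
    if (any(f < 0 | f > 0.5))
      stop("allele frequencies must be in [0, 0.5]", call. = FALSE)
    f
  })
  strata <- Reduce(intersect, lapply(freqs, names))
  if (!length(strata)) stop("no common ancestry strata across genes", call. = FALSE)

  ages <- 20:110
  interp <- function(x, y) {
    v <- stats::approx(x, y, xout = ages, method = "linear", rule = 2)$y
    if (any(diff(v) < -1e-12) || any(v < 0 | v > 1))
      stop("penetrance curve not a valid nondecreasing CDF segment", call. = FALSE)
    cummax(v)
  }
  pen <- list(); cond_map <- character()
  for (cn in names(raw$cancers)) {
    cc <- raw$cancers[[cn]]
    cond_map[cn] <- cc$condition %||% cn
    pen[[cn]] <- list()
    for (sx in c("female", "male")) {
      blk <- cc[[sx]]
      if (is.null(blk)) stop("missing ", sx, " penetrance for ", cn, call. = FALSE)
      m <- sapply(c("noncarrier", genes), function(k) {
        if (is.null(blk[[k]]))
          stop("missing curve '", k, "' for ", cn, "/", sx, call. = FALSE)
        interp(unlist(blk$ages), unlist(blk[[k]]))
      })
      for (g in genes)
        if (any(m[, "noncarrier"] > m[, g] + 1e-12))
          stop("noncarrier curve exceeds ", g, " curve for ", cn, "/", sx,
               call. = FALSE)
      pen[[cn]][[sx]] <- m
    }
  }

  n <- length(genes)
  # joint genotype states: copies per gene, states as rows
  states <- as.matrix(expand.grid(rep(list(0:2), n)))
  colnames(states) <- genes
  carrier <- states > 0
  class_of <- apply(carrier, 1, function(cr) {
    k <- sum(cr)
    if (k == 0) "noncarrier" else if (k == 1) genes[cr] else "multiple"
  })
  classes <- c("noncarrier", genes, if (n > 1) "multiple")
  # per-state penetrance: pointwise max over carried genes' curves
  state_pen <- lapply(pen, function(bysex) lapply(bysex, function(m) {
    sapply(seq_len(nrow(states)), function(s) {
      cr <- carrier[s, ]
      if (!any(cr)) m[, "noncarrier"]
      else if (sum(cr) == 1) m[, genes[cr]]
      else do.call(pmax, lapply(genes[cr], function(g) m[, g]))
    })
  }))
  # single-gene transmission kernel: P(child copies | mother, father copies)
  tr1 <- array(0, dim = c(3, 3, 3))
  for (mg in 0:2) for (fg in 0:2) {
    pm <- mg / 2; pf <- fg / 2
    tr1[1, mg + 1, fg + 1] <- (1 - pm) * (1 - pf)
    tr1[2, mg + 1, fg + 1] <- pm * (1 - pf) + (1 - pm) * pf
    tr1[3, mg + 1, fg + 1] <- pm * pf
  }
  S <- 3^n
  trans <- array(1, dim = c(S, S, S))
  for (ci in seq_len(S)) for (mi in seq_len(S)) for (fi in seq_len(S)) {
    p <- 1
    for (k in seq_len(n))
      p <- p * tr1[states[ci, k] + 1, states[mi, k] + 1, states[fi, k] + 1]
    trans[ci, mi, fi] <- p
  }
  prior <- sapply(strata, function(st) {
    pv <- rep(1, S)
    for (k in seq_len(n)) {
      f <- freqs[[k]][[st]]
      hw <- c((1 - f)^2, 2 * f * (1 - f), f^2)
      pv <- pv * hw[states[, k] + 1]
    }
    pv
  })
  structure(list(name = raw$model %||% "gene_model",
                 version = as.character(raw$version %||% "0"),
                 genes = genes, strata = strata, freqs = freqs,
                 ages = ages, pen = pen, cond_map = cond_map,
                 states = states, n_states = S, class_of = class_of,
                 classes = classes, state_pen = state_pen,
                 trans = trans, prior = prior),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model '", x$name, "' v", x$version, "> genes: ",
      paste(x$genes, collapse = ", "), "; strata: ",
      paste(x$strata, collapse = ", "), "; cancers: ",
      paste(names(x$pen), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Founder genotype prior under Hardy-Weinberg equilibrium
#'
#' Joint distribution over founder genotype states, assuming independence
#' across genes and Hardy-Weinberg proportions within each gene for the
#' requested ancestry stratum. Per gene, the carrier probability is
#' `2f(1-f) + f^2`.
#'
#' @param model A `gene_model`.
#' @param ancestry Stratum name (e.g. `"general"`, `"ashkenazi"`).
#' @return Named numeric vector over joint genotype states (names encode
#'   copies per gene), with a `"classes"` attribute giving the carrier
#'   class of each state.
#' @export
genotype_prior <- function(model, ancestry = "general") {
  if (!ancestry %in% model$strata)
    stop("unknown ancestry stratum: ", ancestry, call. = FALSE)
  p <- model$prior[, ancestry]
  names(p) <- apply(model$states, 1, function(r)
    paste(paste0(model$genes, "=", r), collapse = "|"))
  attr(p, "classes") <- model$class_of
  p
}

# cumulative penetrance at (possibly fractional) age for each state;
# ages below the grid floor carry zero risk
.state_F <- function(model, cancer, sex, age) {
  m <- model$state_pen[[cancer]][[sex]]
  if (is.null(m)) stop("cancer not in model: ", cancer, call. = FALSE)
  a0 <- model$ages[1]; a1 <- model$ages[length(model$ages)]
  if (age <= a0 - 1) return(rep(0, ncol(m)))
  age <- min(max(age, a0), a1)
  i <- floor(age) - a0 + 1L
  frac <- age - floor(age)
  lo <- m[i, ]
  if (frac > 0 && i < nrow(m)) lo + frac * (m[i + 1L, ] - lo) else lo
}

# class-level cumulative penetrance (classes in model$classes order)
.class_F <- function(model, cancer, sex, age) {
  Fs <- .state_F(model, cancer, sex, age)
  vapply(model$classes, function(cl) {
    idx <- which(model$class_of == cl)[1]
    if (is.na(idx)) 0 else Fs[idx]
  }, 0)
}
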