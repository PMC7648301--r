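#' Expand a relationship-coded pedigree to an explicit parent-linked graph
#'
#' Relation codes are resolved into explicit mother/father links. Where a
#' relationship implies a connecting individual who was never entered, a
#' placeholder founder or connector is inserted (e.g. a maternal aunt
#' implies the maternal grandparent couple and the mother; a cousin implies
#' an aunt/uncle connector and their co-parent). Placeholders carry
#' `history_known = FALSE` and contribute no phenotype information
#' downstream. Conventions, chosen for determinism and documented in the
#' methods vignette:
#' * all full siblings share the entered (or placeholder) mother and father;
#' * half-siblings of a side share that parent plus one placeholder
#'   co-parent per side, distinct from the other parent;
#' * all children of the proband share a single placeholder partner;
#' * nieces/nephews attach to the first entered full sibling, else to one
#'   placeholder sibling connector; grandchildren likewise to the first
#'   entered child, else one placeholder child connector;
#' * cousins of a side attach to one placeholder aunt/uncle connector per
#'   side (never to an entered aunt or uncle, whose parenthood of the
#'   cousin is not asserted by the relation code) plus a placeholder
#'   co-parent.
#'
#' @param p A `pedigree`.
#' @return A `pedigree_graph`: list with `individuals` (data frame: `id`,
#'   `father`, `mother`, `sex`, `generation`, `relation`, `alive`,
#'   `censor_age`, `history_known`, `placeholder`) and `conditions`
#'   (data frame: `id`, `condition`, `age_of_onset`).
#' @export
expand_to_graph <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  recs <- .all_records(p)
  codes <- vapply(recs, `[[`, "", "relation")
  ids <- .record_ids(recs)
  if (anyDuplicated(ids)) stop("expansion error: duplicate individual ids", call. = FALSE)

  env <- new.env(parent = emptyenv())
  env$rows <- list(); env$conds <- list()
  has <- function(id) !is.null(env$rows[[id]])
  add <- function(id, sex, gen, relation = NA_character_, alive = NA,
                  censor = NA_real_, known = FALSE, placeholder = TRUE) {
    if (has(id)) return(invisible(id))
    env$rows[[id]] <- list(id = id, father = NA_character_, mother = NA_character_,
                           sex = sex, generation = gen, relation = relation,
                           alive = alive, censor_age = censor,
                           history_known = known, placeholder = placeholder)
    invisible(id)
  }
  link <- function(id, father, mother) {
    r <- env$rows[[id]]
    if ((!is.na(r$father) && r$father != father) ||
        (!is.na(r$mother) && r$mother != mother))
      stop("expansion error: conflicting parent links for ", id, call. = FALSE)
    r$father <- father; r$mother <- mother
    env$rows[[id]] <- r
  }

  # entered individuals first, in input order
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    add(ids[i], sex = r$sex, gen = relation_generation(r$relation),
        relation = r$relation, alive = r$alive,
        censor = (r$current_age %||% r$age_at_death) %||% NA_real_,
        known = r$history_known, placeholder = FALSE)
    for (ce in r$conditions)
      env$conds[[length(env$conds) + 1L]] <-
        list(id = ids[i], condition = ce$condition,
             age_of_onset = ce$age_of_onset %||% NA_real_)
  }

  need <- function(code) any(codes == code)
  ensure_parents <- function() {
    add("mother", "female", 2L); add("father", "male", 2L)
  }
  ensure_side <- function(s) {  # s = "maternal"/"paternal"
    par <- if (s == "maternal") "mother" else "father"
    add(par, if (s == "maternal") "female" else "male", 2L)
    gm <- paste0(s, "_grandmother"); gf <- paste0(s, "_grandfather")
    add(gm, "female", 3L); add(gf, "male", 3L)
    link(par, gf, gm)
  }

  # connectors implied by entered codes: a grandparent, aunt, uncle or
  # cousin on a side implies that side's parent and grandparent couple
  if (need("sister") || need("brother")) ensure_parents()
  for (s in c("maternal", "paternal"))
    if (any(codes %in% paste0(s, c("_grandmother", "_grandfather",
                                   "_aunt", "_uncle", "_cousin"))))
      ensure_side(s)

  # half-siblings: shared parent + one placeholder co-parent per side
  for (s in c("maternal", "paternal")) {
    hs <- ids[codes %in% paste0(s, c("_half_sister", "_half_brother"))]
    if (length(hs)) {
      par <- if (s == "maternal") "mother" else "father"
      add(par, if (s == "maternal") "female" else "male", 2L)
      cop <- paste0(s, "_coparent")
      add(cop, if (s == "maternal") "male" else "female", 2L)
      for (id in hs)
        if (s == "maternal") link(id, cop, "mother") else link(id, "father", cop)
    }
  }

  # aunts/uncles: children of the side's grandparent couple
  for (s in c("maternal", "paternal")) {
    au <- ids[codes %in% paste0(s, c("_aunt", "_uncle"))]
    for (id in au)
      link(id, paste0(s, "_grandfather"), paste0(s, "_grandmother"))
  }

  # cousins: one placeholder aunt/uncle connector (+ co-parent) per side
  for (s in c("maternal", "paternal")) {
    cz <- ids[codes == paste0(s, "_cousin")]
    if (length(cz)) {
      conn <- paste0(s, "_auntuncle_connector")
      sp <- paste0("spouse_of_", conn)
      add(conn, "female", 2L); add(sp, "male", 2L)
      link(conn, paste0(s, "_grandfather"), paste0(s, "_grandmother"))
      for (id in cz) link(id, sp, conn)
    }
  }

  # proband and full siblings
  if (has("mother") || has("father")) {
    ensure_parents()
    link("self", "father", "mother")
  }
  for (id in ids[codes %in% c("sister", "brother")]) link(id, "father", "mother")
  # parents' own parents
  if (has("maternal_grandmother")) link("mother", "maternal_grandfather", "maternal_grandmother")
  if (has("paternal_grandmother")) link("father", "paternal_grandfather", "paternal_grandmother")

  # children of the proband: shared placeholder partner
  kids <- ids[codes %in% c("daughter", "son")]
  proband_sex <- recs[[1]]$sex
  if (length(kids) || any(codes %in% c("granddaughter", "grandson"))) {
    add("partner", if (identical(proband_sex, "female")) "male" else "female", 1L)
    if (!length(kids) && any(codes %in% c("granddaughter", "grandson"))) {
      add("child_connector", "female", 0L)
      kids_conn <- "child_connector"
    } else kids_conn <- kids[1]
    for (id in kids)
      if (identical(proband_sex, "female")) link(id, "partner", "self")
      else link(id, "self", "partner")
    if (has("child_connector"))
      if (identical(proband_sex, "female")) link("child_connector", "partner", "self")
      else link("child_connector", "self", "partner")
    gk <- ids[codes %in% c("granddaughter", "grandson")]
    if (length(gk)) {
      sp <- paste0("spouse_of_", kids_conn)
      ksex <- env$rows[[kids_conn]]$sex
      add(sp, if (identical(ksex, "female")) "male" else "female", 0L)
      for (id in gk)
        if (identical(ksex, "female")) link(id, sp, kids_conn)
        else link(id, kids_conn, sp)
    }
  }

  # nieces/nephews: first entered full sibling, else a placeholder sibling
  nn <- ids[codes %in% c("niece", "nephew")]
  if (length(nn)) {
    sib <- ids[codes %in% c("sister", "brother")]
    if (length(sib)) sib <- sib[1]
    else {
      ensure_parents()
      sib <- add("sibling_connector", "female", 1L)
      link("sibling_connector", "father", "mother")
      link("self", "father", "mother")
    }
    sp <- paste0("spouse_of_", sib)
    ssex <- env$rows[[sib]]$sex
    add(sp, if (identical(ssex, "female")) "male" else "female", 1L)
    for (id in nn)
      if (identical(ssex, "female")) link(id, sp, sib)
      else link(id, sib, sp)
  }

  rows <- env$rows
  ind <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id, father = r$father, mother = r$mother, sex = r$sex,
               generation = r$generation, relation = r$relation,
               alive = r$alive, censor_age = r$censor_age,
               history_known = r$history_known, placeholder = r$placeholder,
               stringsAsFactors = FALSE)))
  rownames(ind) <- NULL
  # both-or-neither parent links
  bad <- xor(is.na(ind$father), is.na(ind$mother))
  if (any(bad))
    stop("expansion error: individual with a single parent link: ",
         paste(ind$id[bad], collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(ind))) {
    f <- ind$father[i]; m <- ind$mother[i]
    if (!is.na(f) && !identical(ind$sex[match(f, ind$id)], "male"))
      stop("expansion error: linked father not male: ", f, call. = FALSE)
    if (!is.na(m) && !identical(ind$sex[match(m, ind$id)], "female"))
      stop("expansion error: linked mother not female: ", m, call. = FALSE)
  }
  conds <- if (length(env$conds))
    do.call(rbind, lapply(env$conds, function(x)
      data.frame(id = x$id, condition = x$condition,
                 age_of_onset = x$age_of_onset, stringsAsFactors = FALSE)))
  else data.frame(id = character(), condition = character(),
                  age_of_onset = numeric(), stringsAsFactors = FALSE)
  g <- structure(list(individuals = ind, conditions = conds,
                      proband_id = "self",
                      ashkenazi = isTRUE(recs[[1]]$ashkenazi),
                      consanguinity = isTRUE(recs[[1]]$consanguinity)),
                 class = "pedigree_graph")
  .assert_acyclic(g)
  g
}

# deterministic ids: singleton codes keep their code, others are indexed
# in input order ("sister_1", "sister_2", ...)
.record_ids <- function(recs) {
  codes <- vapply(recs, `[[`, "", "relation")
  ids <- character(length(recs))
  seen <- list()
  for (i in seq_along(recs)) {
    code <- codes[i]
    if (code %in% .singleton_codes) ids[i] <- code
    else {
      k <- (seen[[code]] %||% 0L) + 1L
      seen[[code]] <- k
      ids[i] <- paste0(code, "_", k)
    }
  }
  ids
}

.assert_acyclic <- function(g) {
  ind <- g$individuals
  state <- setNames(integer(nrow(ind)), ind$id)  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return()
    if (state[[id]] == 1L) stop("pedigree graph contains a cycle", call. = FALSE)
    state[[id]] <<- 1L
    i <- match(id, ind$id)
    for (pid in c(ind$father[i], ind$mother[i]))
      if (!is.na(pid)) visit(pid)
    state[[id]] <<- 2L
  }
  for (id in ind$id) visit(id)
  invisible(TRUE)
}

#' @export
print.pedigree_graph <- function(x, ...) {
  cat("<pedigree_graph>", nrow(x$individuals), "individuals (",
      sum(x$individuals$placeholder), "placeholders ),",
      nrow(x$conditions), "condition entries\n")
  invisible(x)
}

#' Write a pedigree graph as LINKAGE/PED text
#'
#' One whitespace-delimited row per individual: family id, individual id,
#' father id, mother id (0 = missing parent), sex (1 = male, 2 = female,
#' 0 = unknown), affection status for `condition` (2 = affected,
#' 1 = unaffected, 0 = unknown, i.e. placeholder or history unknown).
#'
#' @param g A `pedigree_graph`.
#' @param condition Condition code used for the affection column.
#' @param path Optional file path; if `NULL`, the text is returned.
#' @param family_id Family identifier written in column 1.
#' @return The PED text lines (invisibly when written to a file).
#' @export
write_ped <- function(g, condition, path = NULL, family_id = "FAM1") {
  ind <- g$individuals
  affected <- unique(g$conditions$id[g$conditions$condition == condition])
  sexcode <- c(male = 1L, female = 2L)[ind$sex]
  sexcode[is.na(sexcode)] <- 0L
  aff <- ifelse(ind$id %in% affected, 2L,
                ifelse(ind$history_known & !is.na(ind$censor_age), 1L, 0L))
  lines <- paste(family_id, ind$id,
                 ifelse(is.na(ind$father), "0", ind$father),
                 ifelse(is.na(ind$mother), "0", ind$mother),
                 sexcode, aff)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Read LINKAGE/PED text into a structural pedigree table
#'
#' Independent of [write_ped()]: parses the six standard columns via
#' `read.table` and rebuilds parent links, so a write/read round trip is a
#' genuine structural check.
#'
#' @param path File path or a character vector of PED lines.
#' @return Data frame with columns `family`, `id`, `father`, `mother`,
#'   `sex`, `affection` (`father`/`mother` are `NA` where the file has 0).
#' @export
read_ped <- function(path) {
  df <- utils::read.table(text = if (length(path) == 1L && file.exists(path))
    readLines(path) else path,
    col.names = c("family", "id", "father", "mother", "sex", "affection"),
    colClasses = c("character", "character", "character", "character",
                   "integer", "integer"))
  df$father[df$father == "0"] <- NA_character_
  df$mother[df$mother == "0"] <- NA_character_
  df
}
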