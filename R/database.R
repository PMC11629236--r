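#' Read a biochemistry reaction database
#'
#' Loads a reaction database in one of two dialects: a ModelSEED-style
#' tab-separated table or a BiGG-style JSON file.  The database supplies
#' the candidate reaction set for gap-filling and the stoichiometry used
#' to assemble flux-balance models.
#'
#' The ModelSEED dialect expects columns `id`, `stoichiometry` and
#' `reversibility`.  `stoichiometry` is a semicolon-separated list of
#' `coefficient:metabolite:compartment` entries (signed coefficients,
#' negative = consumed); `reversibility` is one of `=` (reversible), `>`
#' (forward only) or `<` (backward only).  The BiGG dialect is the JSON
#' layout used by COBRA universal models: a `reactions` array with
#' `id`, `metabolites` (id to signed coefficient), `lower_bound` and
#' `upper_bound`, plus a `metabolites` array.
#'
#' @param path path to the database file.
#' @param dialect `"modelseed_tsv"` or `"bigg_json"`.
#' @return a `reaction_db` object: a list with `reactions` (data frame of
#'   `id`, `namespace`, `reversible`, `lb`, `ub`), `stoich` (named list of
#'   named coefficient vectors) and `metabolites` (data frame of `id`,
#'   `compartment`).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tstoichiometry\treversibility",
#'              "rxn1\t-1:A:c;1:B:c\t>",
#'              "rxn2\t-1:B:c;1:C:c\t="), tsv)
#' db <- read_reaction_database(tsv, "modelseed_tsv")
#' db$reactions
#' @export
read_reaction_database <- function(path, dialect = c("modelseed_tsv", "bigg_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  db <- switch(dialect,
               modelseed_tsv = read_modelseed_tsv(path),
               bigg_json = read_bigg_json(path))
  message(sprintf("loaded %d reactions (%s)", nrow(db$reactions), dialect))
  db
}

new_reaction_db <- function(reactions, stoich, metabolites) {
  stopifnot(is.data.frame(reactions), nrow(reactions) == length(stoich))
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids in database")
  names(stoich) <- reactions$id
  unknown <- setdiff(unlist(lapply(stoich, names)), metabolites$id)
  if (length(unknown)) stop("stoichiometry references undeclared metabolites: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  if (any(reactions$lb > reactions$ub)) stop("reaction with lower bound > upper bound")
  structure(list(reactions = reactions, stoich = stoich,
                 metabolites = metabolites),
            class = "reaction_db")
}

read_modelseed_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) stop("parse error: ", path, " contains no reactions")
  need <- c("id", "stoichiometry", "reversibility")
  if (!all(need %in% names(tab)))
    stop("parse error: expected columns ", paste(need, collapse = ", "))
  stoich <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parts <- strsplit(tab$stoichiometry[i], ";", fixed = TRUE)[[1]]
    fields <- strsplit(parts, ":", fixed = TRUE)
    if (any(lengths(fields) < 2))
      stop(sprintf("parse error in %s line %d: malformed stoichiometry '%s'",
                   path, i + 1L, tab$stoichiometry[i]))
    coef <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    if (anyNA(coef))
      stop(sprintf("parse error in %s line %d: non-numeric coefficient", path, i + 1L))
    met <- vapply(fields, function(f) {
      if (length(f) >= 3 && nzchar(f[3])) paste0(f[2], "_", f[3]) else f[2]
    }, "")
    s <- tapply(coef, met, sum)  # merge duplicated metabolites
    stoich[[i]] <- stats::setNames(as.numeric(s), names(s))
  }
  rev_tag <- as.character(tab$reversibility)
  if (!all(rev_tag %in% c("=", ">", "<")))
    stop("parse error: reversibility must be one of '=', '>', '<'")
  lb <- ifelse(rev_tag == ">", 0, -1000)
  ub <- ifelse(rev_tag == "<", 0, 1000)
  mets <- sort(unique(unlist(lapply(stoich, names))))
  comp <- sub("^.*_", "", mets)
  comp[comp == mets] <- "c"
  reactions <- data.frame(id = as.character(tab$id), namespace = "modelseed",
                          reversible = rev_tag == "=", lb = lb, ub = ub,
                          stringsAsFactors = FALSE)
  new_reaction_db(reactions, stoich,
                  data.frame(id = mets, compartment = comp, stringsAsFactors = FALSE))
}

read_bigg_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$reactions) || length(obj$reactions) == 0)
    stop("parse error: no reactions in ", path)
  n <- length(obj$reactions)
  ids <- character(n); lb <- numeric(n); ub <- numeric(n)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    r <- obj$reactions[[i]]
    if (is.null(r$id) || is.null(r$metabolites))
      stop("parse error: reaction entry ", i, " lacks id or metabolites")
    ids[i] <- r$id
    stoich[[i]] <- stats::setNames(as.numeric(unlist(r$metabolites)),
                                   names(r$metabolites))
    lb[i] <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub[i] <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
  }
  if (!is.null(obj$metabolites) && length(obj$metabolites)) {
    mets <- data.frame(
      id = vapply(obj$metabolites, function(m) m$id, ""),
      compartment = vapply(obj$metabolites, function(m)
        if (is.null(m$compartment)) "c" else m$compartment, ""),
      stringsAsFactors = FALSE)
  } else {
    mid <- sort(unique(unlist(lapply(stoich, names))))
    mets <- data.frame(id = mid, compartment = "c", stringsAsFactors = FALSE)
  }
  reactions <- data.frame(id = ids, namespace = "bigg",
                          reversible = lb < 0 & ub > 0, lb = lb, ub = ub,
                          stringsAsFactors = FALSE)
  new_reaction_db(reactions, stoich, mets)
}

#' @export
print.reaction_db <- function(x, ...) {
  cat(sprintf("<reaction_db> %d reactions, %d metabolites (%s)\n",
              nrow(x$reactions), nrow(x$metabolites),
              x$reactions$namespace[1]))
  invisible(x)
}

#' Prepare a reaction database for gap-filling
#'
#' Removes biomass-class reactions (artificial constructs that should
#' never be candidates) and splits every reversible reaction into two
#' irreversible ones: `<id>_f` with the original stoichiometry and
#' `<id>_b` with all coefficients negated.  After preparation every
#' reaction has bounds `[0, ub]`, which is the form the half-interval
#' gap-filler expects.
#'
#' @param db a `reaction_db`.
#' @param biomass_ids reaction ids (or id prefixes, e.g. `"bio"`)
#'   identifying biomass reactions to drop.
#' @return a prepared `reaction_db`; split reactions carry their base id
#'   in the `base_id` column so scores and frequencies defined on the
#'   original ids can be mapped onto both directions.
#' @export
prepare_database <- function(db, biomass_ids = c("bio1", "Growth")) {
  stopifnot(inherits(db, "reaction_db"))
  rx <- db$reactions
  rx$base_id <- if (is.null(rx$base_id)) rx$id else rx$base_id
  is_bio <- rx$id %in% biomass_ids |
    grepl("^(bio\\d+|biomass)", rx$id, ignore.case = TRUE)
  keep <- which(!is_bio)
  rows <- list(); stoich <- list()
  for (i in keep) {
    r <- rx[i, , drop = FALSE]
    s <- db$stoich[[i]]
    if (isTRUE(r$reversible) || r$lb < 0) {
      f <- r; f$id <- paste0(r$id, "_f"); f$reversible <- FALSE
      f$lb <- 0; f$ub <- max(r$ub, 0)
      b <- r; b$id <- paste0(r$id, "_b"); b$reversible <- FALSE
      b$lb <- 0; b$ub <- abs(min(r$lb, 0))
      rows <- c(rows, list(f, b))
      stoich <- c(stoich, list(s, -s))
    } else {
      rows <- c(rows, list(r))
      stoich <- c(stoich, list(s))
    }
  }
  if (!length(rows)) {
    reactions <- rx[0, , drop = FALSE]
  } else {
    reactions <- do.call(rbind, rows)
  }
  rownames(reactions) <- NULL
  out <- new_reaction_db(reactions, stoich, db$metabolites)
  attr(out, "prepared") <- TRUE
  out
}
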