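#' Construct a metabolic model object
#'
#' A `metabolic_model` is the unit that flux balance analysis and
#' gap-filling operate on: a set of reactions with stoichiometry and flux
#' bounds, exactly one (optional) biomass reaction, and an origin tag per
#' reaction (`"annotation"` for genome-derived reactions, `"gapfill"` for
#' reactions added later).  Exchange reactions follow the COBRA sign
#' convention: `EX_x` drains metabolite `x` (coefficient -1), so uptake
#' is negative flux and a medium opens uptake by setting a negative lower
#' bound.
#'
#' @param id model identifier.
#' @param reactions data frame with columns `id`, `lb`, `ub` and
#'   optionally `origin`.
#' @param stoich named list (by reaction id) of named coefficient vectors.
#' @param biomass_id id of the biomass reaction, or `NA`.
#' @return a `metabolic_model`.
#' @export
metabolic_model <- function(id, reactions, stoich, biomass_id = NA_character_) {
  stopifnot(is.data.frame(reactions),
            all(c("id", "lb", "ub") %in% names(reactions)))
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids in model")
  if (is.null(reactions$origin)) reactions$origin <- "annotation"
  stoich <- stoich[reactions$id]
  if (any(vapply(stoich, is.null, TRUE))) stop("missing stoichiometry for some reactions")
  if (!is.na(biomass_id) && !biomass_id %in% reactions$id)
    stop("biomass reaction '", biomass_id, "' not in model")
  structure(list(id = id, reactions = reactions, stoich = stoich,
                 biomass_id = biomass_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> '%s': %d reactions (%d gap-filled), biomass = %s\n",
              x$id, nrow(x$reactions), sum(x$reactions$origin == "gapfill"),
              ifelse(is.na(x$biomass_id), "<unset>", x$biomass_id)))
  invisible(x)
}

#' Read a metabolic model from SBML or COBRA JSON
#'
#' SBML Level 3 documents are parsed with namespace-agnostic XPath, so
#' plain core models and fbc-flavoured ones both load; flux bounds are
#' resolved from fbc bound parameters when present, otherwise from the
#' `reversible` attribute (reversible: -1000..1000, irreversible:
#' 0..1000).  COBRA JSON follows the COBRApy schema.  The biomass
#' reaction is identified by the first matching id in `biomass_ids`, or
#' by a JSON `objective_coefficient` of 1; if none matches, the model is
#' returned with biomass unset and a warning.
#'
#' @param path path to the model file.
#' @param format `"sbml"` or `"cobra_json"`.
#' @param biomass_ids candidate biomass reaction ids, first match wins.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("sbml", "cobra_json"),
                       biomass_ids = c("bio1", "Growth")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  m <- switch(format, sbml = read_sbml_model(path),
              cobra_json = read_cobra_json_model(path))
  if (nrow(m$reactions) == 0) stop("format error: no parsable reactions in ", path)
  if (is.na(m$biomass_id)) {
    hit <- intersect(biomass_ids, m$reactions$id)
    if (length(hit)) {
      m$biomass_id <- hit[1]
    } else {
      warning("no biomass reaction found among: ",
              paste(biomass_ids, collapse = ", "))
    }
  }
  m
}

read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  mid <- xml2::xml_attr(model_node, "id")
  if (is.na(mid)) mid <- basename(path)
  # fbc flux-bound parameters
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  n <- length(rnodes)
  ids <- character(n); lb <- numeric(n); ub <- numeric(n)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    rn <- rnodes[[i]]
    ids[i] <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    attrs <- xml2::xml_attrs(rn)
    lbp <- attrs[grepl("lowerFluxBound", names(attrs))]
    ubp <- attrs[grepl("upperFluxBound", names(attrs))]
    lb[i] <- if (length(lbp) && lbp[[1]] %in% names(pval)) pval[[lbp[[1]]]]
             else if (rev) -1000 else 0
    ub[i] <- if (length(ubp) && ubp[[1]] %in% names(pval)) pval[[ubp[[1]]]]
             else 1000
    sp <- function(xp, sign) {
      refs <- xml2::xml_find_all(rn, xp)
      if (!length(refs)) return(NULL)
      co <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      co[is.na(co)] <- 1
      stats::setNames(sign * co, xml2::xml_attr(refs, "species"))
    }
    reac <- sp(".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1)
    prod <- sp(".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']", 1)
    both <- c(reac, prod)
    if (is.null(both)) both <- stats::setNames(numeric(0), character(0))
    s <- tapply(both, names(both), sum)
    stoich[[i]] <- stats::setNames(as.numeric(s), names(s))
  }
  reactions <- data.frame(id = ids, lb = lb, ub = ub, origin = "annotation",
                          stringsAsFactors = FALSE)
  metabolic_model(mid, reactions, stats::setNames(stoich, ids))
}

read_cobra_json_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$reactions) || !length(obj$reactions))
    stop("format error: no reactions in ", path)
  n <- length(obj$reactions)
  ids <- character(n); lb <- numeric(n); ub <- numeric(n)
  origin <- character(n); objc <- numeric(n)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    r <- obj$reactions[[i]]
    ids[i] <- r$id
    s <- stats::setNames(as.numeric(unlist(r$metabolites)), names(r$metabolites))
    stoich[[i]] <- if (length(s)) s else stats::setNames(numeric(0), character(0))
    lb[i] <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub[i] <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    origin[i] <- if (!is.null(r$notes$origin)) r$notes$origin else "annotation"
    objc[i] <- if (is.null(r$objective_coefficient)) 0 else r$objective_coefficient
  }
  biomass <- if (any(objc != 0)) ids[which(objc != 0)[1]] else NA_character_
  mid <- if (is.null(obj$id)) basename(path) else obj$id
  reactions <- data.frame(id = ids, lb = lb, ub = ub, origin = origin,
                          stringsAsFactors = FALSE)
  metabolic_model(mid, reactions, stats::setNames(stoich, ids), biomass)
}

#' Write a metabolic model as COBRA JSON
#'
#' The biomass reaction is tagged with `objective_coefficient = 1` and
#' each reaction's origin (`annotation`/`gapfill`) is stored under
#' `notes`, so [read_model()] round-trips both.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    list(id = r$id,
         metabolites = as.list(model$stoich[[r$id]]),
         lower_bound = r$lb, upper_bound = r$ub,
         objective_coefficient = as.numeric(identical(r$id, model$biomass_id)),
         notes = list(origin = r$origin))
  })
  mets <- sort(unique(unlist(lapply(model$stoich, names))))
  obj <- list(id = model$id,
              reactions = rxns,
              metabolites = lapply(mets, function(m) list(id = m, compartment = "c")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Exchange reactions of a model
#'
#' Exchange reactions are recognised as reactions whose stoichiometry
#' touches exactly one metabolite (boundary drains/sources).
#'
#' @param model a [metabolic_model()].
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[vapply(model$stoich, length, 1L) == 1L]
}

#' Read / write a growth medium
#'
#' A medium is a named non-negative vector: maximum uptake rate per
#' exchange metabolite.  The file format is a two-column TSV
#' (`metabolite`, `max_uptake`).
#'
#' @param path file path.
#' @return named numeric vector (class `medium`).
#' @export
read_medium <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "max_uptake") %in% names(tab)))
    stop("medium file needs columns 'metabolite' and 'max_uptake'")
  medium(stats::setNames(as.numeric(tab$max_uptake), tab$metabolite))
}

#' @rdname read_medium
#' @param med named numeric vector of uptake bounds.
#' @export
write_medium <- function(med, path) {
  utils::write.table(data.frame(metabolite = names(med),
                                max_uptake = as.numeric(med)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_medium
#' @export
medium <- function(med) {
  stopifnot(is.numeric(med), !is.null(names(med)), all(med >= 0))
  structure(med, class = "medium")
}

# Close all exchange uptakes, then open those listed in the medium.
apply_medium <- function(model, med) {
  ex <- exchange_reactions(model)
  for (rid in ex) {
    met <- names(model$stoich[[rid]])
    i <- match(rid, model$reactions$id)
    coef <- model$stoich[[rid]][[1]]
    # drain convention (coef < 0): uptake is negative flux
    if (coef < 0) {
      model$reactions$lb[i] <- if (met %in% names(med)) -med[[met]] else 0
    } else {
      model$reactions$ub[i] <- if (met %in% names(med)) med[[met]] else 0
    }
  }
  model
}
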