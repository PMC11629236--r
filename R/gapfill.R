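#' Gap-filling cost schemes
#'
#' Four ways to price candidate reactions for the half-interval
#' gap-filler, plus the negative-cost variant:
#'
#' * `W1`: every database reaction costs `default_cost` (50).
#' * `W2`: reactions seen in the training pan-reactome cost `low_cost`
#'   (1), all others `default_cost`.
#' * `W3`: `1 - frac_r` for pan-reactome reactions (frequent reactions
#'   are nearly free), `default_cost` outside the pan-reactome.
#' * `W4`: `1 - p_NN` from the imputer's scores, `default_cost` for
#'   unscored reactions.
#' * `W4neg`: affine map `1 - 2 * p_NN`, so confident predictions
#'   (`p_NN > 0.5`) get negative costs and are actively pulled into the
#'   solution, not merely tolerated.
#'
#' @param kind one of `"W1"`, `"W2"`, `"W3"`, `"W4"`, `"W4neg"`.
#' @param default_cost cost of reactions with no supporting evidence.
#' @param low_cost cost of pan-reactome reactions under `W2`.
#' @return a `cost_scheme` object.
#' @export
cost_scheme <- function(kind = c("W1", "W2", "W3", "W4", "W4neg"),
                        default_cost = 50, low_cost = 1) {
  kind <- match.arg(kind)
  stopifnot(default_cost > low_cost, low_cost > 0)
  structure(list(kind = kind, default_cost = default_cost,
                 low_cost = low_cost),
            class = "cost_scheme")
}

#' Compute per-reaction gap-filling costs
#'
#' Applies a [cost_scheme()] to every reaction of a (prepared) candidate
#' database.  Split reaction pairs (`_f`/`_b`) inherit the cost of their
#' base reaction, so frequencies and scores defined on original ids
#' cover both directions.
#'
#' @param scheme a [cost_scheme()].
#' @param db the candidate `reaction_db` (ideally after
#'   [prepare_database()]).
#' @param pan a `pan_reactome` (needed for `W2`/`W3`), or NULL.
#' @param scores named score vector `p_NN` over pan-reactome ids (needed
#'   for `W4`/`W4neg`).
#' @return named numeric cost vector over `db$reactions$id`.
#' @export
make_costs <- function(scheme, db, pan = NULL, scores = NULL) {
  stopifnot(inherits(scheme, "cost_scheme"), inherits(db, "reaction_db"))
  ids <- db$reactions$id
  base <- if (!is.null(db$reactions$base_id)) db$reactions$base_id else ids
  costs <- rep(scheme$default_cost, length(ids))
  names(costs) <- ids
  if (scheme$kind %in% c("W2", "W3")) {
    if (is.null(pan)) stop(scheme$kind, " needs a pan_reactome")
    hit <- base %in% pan$reactions
    if (scheme$kind == "W2") {
      costs[hit] <- scheme$low_cost
    } else {
      costs[hit] <- 1 - pan$frequency[base[hit]]
    }
  } else if (scheme$kind %in% c("W4", "W4neg")) {
    if (is.null(scores)) stop(scheme$kind, " needs imputer scores")
    if (is.null(names(scores))) stop("scores must be named by reaction id")
    hit <- base %in% names(scores)
    p <- scores[base[hit]]
    costs[hit] <- if (scheme$kind == "W4") 1 - p else 1 - 2 * p
  }
  costs
}

# stoichiometric matrix (metabolites x reactions) of a model
stoich_matrix <- function(stoich, rxn_ids) {
  mets <- sort(unique(unlist(lapply(stoich[rxn_ids], names))))
  S <- matrix(0, length(mets), length(rxn_ids),
              dimnames = list(mets, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    s <- stoich[[rxn_ids[j]]]
    if (length(s)) S[names(s), j] <- s
  }
  S
}

#' Maximal biomass flux of a model on a medium
#'
#' Flux balance analysis: maximise flux through the biomass reaction
#' subject to steady-state mass balance and the model's flux bounds,
#' with exchange uptake bounds set from the medium (uptakes not listed
#' in the medium are closed).
#'
#' @param model a [metabolic_model()] with a biomass reaction.
#' @param med a [medium()], or NULL to use the model's bounds as-is.
#' @return maximal biomass flux (0 if the LP is infeasible), with the
#'   solver status in `attr(, "status")` and the flux vector in
#'   `attr(, "fluxes")`.
#' @export
check_growth <- function(model, med = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.na(model$biomass_id)) stop("model has no biomass reaction")
  if (!is.null(med)) model <- apply_medium(model, med)
  rx <- model$reactions
  S <- stoich_matrix(model$stoich, rx$id)
  obj <- as.numeric(rx$id == model$biomass_id)
  sol <- solve_lp(obj, S, numeric(nrow(S)), lb = rx$lb, ub = rx$ub,
                  maximize = TRUE)
  if (sol$status != "optimal") {
    out <- 0
    attr(out, "status") <- sol$status
    return(out)
  }
  out <- sol$objval
  attr(out, "status") <- "optimal"
  attr(out, "fluxes") <- stats::setNames(sol$x, rx$id)
  out
}

#' Half-interval gap-filling
#'
#' Completes a non-growing model by adding reactions from a prepared
#' candidate database so that biomass flux reaches at least `epsilon`,
#' while keeping the flux-weighted cost of additions low.  The LP
#' \deqn{\max \alpha f_b - \sum_{r \in M} c_r f_r}
#' (mass balance, bounds, annotation reactions cost-free) is solved for
#' a scalar trade-off \eqn{\alpha} found by half-interval search: the
#' smallest \eqn{\alpha} whose optimum carries \eqn{f_b \ge \epsilon}.
#' At that point the optimum funnels biomass through the cheapest
#' available route, and candidates carrying flux above `flux_tol` are
#' the gap-fill set.  Annotation-origin reactions are never removed;
#' gap-filling is strictly additive.
#'
#' @param model a [metabolic_model()] (biomass reaction required).
#' @param db candidate `reaction_db`, after [prepare_database()]
#'   (irreversible, biomass-free).
#' @param costs named cost vector from [make_costs()].
#' @param med a [medium()] applied to the model's exchanges.
#' @param epsilon minimal biomass flux counting as growth.
#' @param flux_tol candidates with `|f_r|` above this in the final LP
#'   count as added.
#' @param alpha_tol relative width at which the bisection stops.
#' @param candidate_ub flux cap per candidate reaction; bounds the LP
#'   when costs are negative (`W4neg`) and is harmless otherwise.
#' @param seed optional integer; when given, candidate column order is
#'   permuted so that ties between equal-cost alternatives are broken
#'   randomly rather than by database order.
#' @return a `gapfill_result`: `added_reactions`, `biomass_flux`,
#'   `iterations` (LP solves), `objective` (sum of `c_r f_r` at the
#'   solution), `added_costs`, and `model` (the completed model with
#'   added reactions tagged `origin = "gapfill"`).
#' @export
halfinterval_gapfill <- function(model, db, costs, med = NULL,
                                 epsilon = 1e-6, flux_tol = 1e-9,
                                 alpha_tol = 0.05, candidate_ub = 1000,
                                 seed = NULL) {
  stopifnot(inherits(model, "metabolic_model"), inherits(db, "reaction_db"))
  if (is.na(model$biomass_id)) stop("model has no biomass reaction")
  if (!is.null(med)) model <- apply_medium(model, med)
  base_flux <- check_growth(model)
  if (base_flux >= epsilon) {
    return(new_gapfill_result(character(0), as.numeric(base_flux), 1L, 0,
                              numeric(0), model))
  }
  cand_ids <- setdiff(db$reactions$id, model$reactions$id)
  if (!is.null(seed)) {
    rs <- local_rng(seed)
    cand_ids <- sample(cand_ids)
    rs()
  }
  missing_cost <- setdiff(cand_ids, names(costs))
  if (length(missing_cost))
    stop("costs missing for candidates: ",
         paste(utils::head(missing_cost, 5), collapse = ", "))
  cand <- db$reactions[match(cand_ids, db$reactions$id), , drop = FALSE]
  if (any(cand$lb < 0))
    stop("candidate database must be prepared (irreversible); run prepare_database()")
  all_ids <- c(model$reactions$id, cand_ids)
  stoich <- c(model$stoich, db$stoich[cand_ids])
  S <- stoich_matrix(stoich, all_ids)
  nm <- nrow(model$reactions); nc <- length(cand_ids)
  lb <- c(model$reactions$lb, rep(0, nc))
  ub <- c(model$reactions$ub, pmin(cand$ub, candidate_ub))
  cvec <- c(rep(0, nm), as.numeric(costs[cand_ids]))
  bio <- match(model$biomass_id, all_ids)
  solves <- 0L
  lp_at <- function(alpha) {
    obj <- -cvec
    obj[bio] <- obj[bio] + alpha
    solves <<- solves + 1L
    solve_lp(obj, S, numeric(nrow(S)), lb = lb, ub = ub, maximize = TRUE)
  }
  fb_of <- function(sol) if (sol$status == "optimal") sol$x[bio] else 0
  # grow alpha until biomass is attainable
  alpha_hi <- 1
  repeat {
    sol_hi <- lp_at(alpha_hi)
    if (fb_of(sol_hi) >= epsilon) break
    alpha_hi <- alpha_hi * 4
    if (alpha_hi > 1e7) {
      blocked <- blocked_precursors(model, db, med = NULL)
      stop("gap-filling infeasible: no candidate superset reaches biomass flux ",
           epsilon,
           if (length(blocked))
             paste0("; blocked biomass precursors: ",
                    paste(blocked, collapse = ", "))
           else "")
    }
  }
  alpha_lo <- 0
  while ((alpha_hi - alpha_lo) > alpha_tol * alpha_hi) {
    mid <- (alpha_hi + alpha_lo) / 2
    sol <- lp_at(mid)
    if (fb_of(sol) >= epsilon) {
      alpha_hi <- mid; sol_hi <- sol
    } else {
      alpha_lo <- mid
    }
  }
  flux <- sol_hi$x
  added_idx <- which(abs(flux[nm + seq_len(nc)]) > flux_tol)
  added <- cand_ids[added_idx]
  objective <- sum(cvec[nm + added_idx] * flux[nm + added_idx])
  # merge additions into the model
  if (length(added)) {
    add_rx <- data.frame(id = added,
                         lb = 0, ub = pmin(cand$ub[added_idx], candidate_ub),
                         origin = "gapfill", stringsAsFactors = FALSE)
    filled <- metabolic_model(model$id,
                              rbind(model$reactions[, c("id", "lb", "ub", "origin")],
                                    add_rx),
                              c(model$stoich, db$stoich[added]),
                              model$biomass_id)
  } else {
    filled <- model
  }
  new_gapfill_result(added, flux[bio], solves, objective,
                     stats::setNames(as.numeric(costs[added]), added), filled)
}

new_gapfill_result <- function(added, fb, iterations, objective,
                               added_costs, model) {
  structure(list(added_reactions = added, biomass_flux = fb,
                 iterations = iterations, objective = objective,
                 added_costs = added_costs, model = model),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat(sprintf("<gapfill_result> %d reactions added, f_b = %.4g (%d LP solves, obj %.4g)\n",
              length(x$added_reactions), x$biomass_flux, x$iterations,
              x$objective))
  invisible(x)
}

# Which biomass precursors cannot be produced even with every candidate
# reaction available?  Used for infeasibility diagnostics.
blocked_precursors <- function(model, db, med = NULL) {
  if (!is.null(med)) model <- apply_medium(model, med)
  bio_s <- model$stoich[[model$biomass_id]]
  precursors <- names(bio_s)[bio_s < 0]
  cand_ids <- setdiff(db$reactions$id, model$reactions$id)
  all_ids <- c(model$reactions$id, cand_ids)
  stoich <- c(model$stoich, db$stoich[cand_ids])
  blocked <- character(0)
  for (m in precursors) {
    sink_id <- paste0(".sink_", m)
    st <- c(stoich, stats::setNames(list(stats::setNames(-1, m)), sink_id))
    ids <- c(all_ids, sink_id)
    S <- stoich_matrix(st, ids)
    lb <- c(model$reactions$lb, rep(0, length(cand_ids)), 0)
    ub <- c(model$reactions$ub, db$reactions$ub[match(cand_ids, db$reactions$id)],
            1000)
    obj <- as.numeric(ids == sink_id)
    sol <- solve_lp(obj, S, numeric(nrow(S)), lb = lb, ub = ub, maximize = TRUE)
    if (sol$status != "optimal" || sol$objval < 1e-6) blocked <- c(blocked, m)
  }
  blocked
}

#' Write a gap-fill report as JSON
#'
#' @param result a `gapfill_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gapfill_report <- function(result, path) {
  stopifnot(inherits(result, "gapfill_result"))
  jsonlite::write_json(
    list(added_reactions = result$added_reactions,
         added_costs = as.list(result$added_costs),
         biomass_flux = result$biomass_flux,
         iterations = result$iterations,
         objective = result$objective),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
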