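#' @useDynLib panfill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Solve a bounded linear program
#'
#' Internal LP interface used by flux balance analysis and the
#' half-interval gap-filler: optimise `obj %*% x` subject to
#' `Aeq %*% x = beq` and `lb <= x <= ub`.  Finite lower bounds are handled
#' by variable shifting, finite upper bounds as inequality rows; the core
#' is a dense two-phase primal simplex, so solutions are always vertices
#' of the feasible polytope (no flux splitting across alternative optima).
#'
#' @param obj objective coefficients.
#' @param Aeq,beq equality constraints (steady-state mass balance).
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param maximize optimise direction.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x`, and `objval` (on the original scale).
#' @keywords internal
solve_lp <- function(obj, Aeq, beq, lb = NULL, ub = NULL, maximize = FALSE) {
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), nrow = length(beq), ncol = n)
  if (is.null(lb)) lb <- numeric(n)
  if (is.null(ub)) ub <- rep(Inf, n)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(ub >= lb))
  # shift so that all variables are >= 0
  beq_s <- beq - as.numeric(Aeq %*% lb)
  ub_s <- ub - lb
  fin <- which(is.finite(ub_s))
  if (length(fin)) {
    Aub <- matrix(0, length(fin), n)
    Aub[cbind(seq_along(fin), fin)] <- 1
    bub <- ub_s[fin]
  } else {
    Aub <- matrix(0, 0, n)
    bub <- numeric(0)
  }
  cc <- if (maximize) -obj else obj
  res <- .simplex_core(cc, Aeq, beq_s, Aub, bub)
  status <- c("optimal", "infeasible", "unbounded",
              "iteration_limit")[res$status + 1L]
  if (status != "optimal") {
    return(list(status = status, x = rep(NA_real_, n), objval = NA_real_))
  }
  x <- as.numeric(res$x) + lb
  list(status = "optimal", x = x,
       objval = sum(obj * x))
}
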