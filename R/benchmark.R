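#' Imputation performance over corrupted test genomes
#'
#' Reproduces the prediction benchmark: every genome of `im` is
#' corrupted `n_replicates` times under `scheme`, scored with the
#' trained imputer, and evaluated on masked positions only.  Returns
#' per-sample metrics, per-reaction pooled confusion counts (the input
#' for [frequency_binned_metrics()]), and the grand mean F1.
#'
#' @param ti a `trained_imputer`.
#' @param im the test `incidence_matrix` (columns must match the
#'   imputer's pan-reactome order).
#' @param n_replicates corruption replicates per genome.
#' @param scheme a [deletion_scheme()].
#' @param base_seed seed for the corruption stream.
#' @param threshold score binarisation threshold.
#' @return list with `per_sample` (data frame: genome_id, replicate,
#'   confusion counts and metrics), `per_reaction` (reaction, occurrence,
#'   TP/FP/FN/TN pooled over samples), `mean_F1`.
#' @export
imputation_performance <- function(ti, im, n_replicates = 10,
                                   scheme = deletion_scheme("uniform"),
                                   base_seed = 1L, threshold = 0.5) {
  stopifnot(inherits(ti, "trained_imputer"), inherits(im, "incidence_matrix"))
  samples <- make_replicates(im, n_replicates, scheme, base_seed)
  X <- do.call(rbind, lapply(samples, `[[`, "input"))
  Tm <- do.call(rbind, lapply(samples, `[[`, "truth"))
  S <- predict(ti, X)
  mask <- X == 0
  pos <- S >= threshold
  per_sample <- do.call(rbind, lapply(seq_along(samples), function(i) {
    cc <- confusion_from_predictions(S[i, ], Tm[i, ], X[i, ], threshold)
    cbind(data.frame(genome_id = samples[[i]]$genome_id,
                     replicate = samples[[i]]$replicate,
                     TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN),
          metrics(cc))
  }))
  per_reaction <- data.frame(
    reaction = colnames(im$presence),
    occurrence = colSums(im$presence),
    TP = colSums(mask & Tm == 1 & pos),
    FP = colSums(mask & Tm == 0 & pos),
    FN = colSums(mask & Tm == 1 & !pos),
    TN = colSums(mask & Tm == 0 & !pos),
    row.names = NULL)
  list(per_sample = per_sample, per_reaction = per_reaction,
       mean_F1 = mean(per_sample$F1))
}

#' Gap-fill recovery benchmark across weighting schemes
#'
#' The full recovery protocol on the synthetic world: for each listed
#' genome and replicate, delete reactions under `scheme`, build the
#' corrupted genome model, gap-fill it under each cost scheme (W4
#' variants score the corrupted input with the imputer), and count which
#' deleted reactions were recovered.
#'
#' @param world a [world_biochemistry()] result.
#' @param im the matching [generate_incidence()] matrix.
#' @param ti a `trained_imputer` (needed for W4/W4neg schemes).
#' @param genomes genome ids to benchmark.
#' @param n_replicates deletion replicates per genome.
#' @param schemes character vector of [cost_scheme()] kinds.
#' @param pan pan-reactome defining `R_train` frequencies for W2/W3
#'   (typically of the training split).
#' @param scheme deletion scheme for the corruption step.
#' @param base_seed governs corruption and LP tie-breaking.
#' @param epsilon growth threshold passed to the gap-filler.
#' @return data frame: genome_id, replicate, scheme, TP/FP/FN, the five
#'   metrics, n_added, biomass_flux.
#' @export
benchmark_gapfill_schemes <- function(world, im, ti = NULL, genomes,
                                      n_replicates = 3,
                                      schemes = c("W1", "W2", "W3", "W4"),
                                      pan = NULL,
                                      scheme = deletion_scheme("uniform"),
                                      base_seed = 1L, epsilon = 1e-6) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(im, "incidence_matrix"))
  if (any(schemes %in% c("W4", "W4neg")) && is.null(ti))
    stop("W4 schemes need a trained imputer")
  if (is.null(pan)) pan <- im$pan
  candidates <- world$db$reactions$id
  rows <- list()
  for (g in genomes) {
    truth <- im$presence[g, ]
    for (r in seq_len(n_replicates)) {
      s <- corrupt(truth, scheme, seed = derive_seed(base_seed, g, r),
                   frequencies = im$pan$frequency, genome_id = g,
                   replicate = r)
      model <- genome_model(world, im, g, presence = s$input)
      scores <- if (!is.null(ti)) predict(ti, s$input) else NULL
      deleted <- names(truth)[s$deleted]
      original <- names(truth)[truth == 1]
      for (k in schemes) {
        costs <- make_costs(cost_scheme(k), world$db, pan = pan,
                            scores = scores)
        res <- halfinterval_gapfill(model, world$db, costs,
                                    epsilon = epsilon,
                                    seed = derive_seed(base_seed + 13L, g, r))
        cc <- confusion_from_gapfill(original, deleted, res$added_reactions,
                                     candidates = candidates)
        rows[[length(rows) + 1]] <-
          cbind(data.frame(genome_id = g, replicate = r, scheme = k,
                           TP = cc$TP, FP = cc$FP, FN = cc$FN),
                metrics(cc),
                data.frame(n_added = length(res$added_reactions),
                           biomass_flux = res$biomass_flux))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
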