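#' Confusion counts for imputer predictions
#'
#' Counts are taken over masked positions only (`I = 0`): reactions that
#' were given to the network as input are ignored, mirroring the masked
#' training loss.  A reaction counts as predicted present when its score
#' reaches `threshold`.
#'
#' @param scores score vector in \[0,1\].
#' @param truth,input binary vectors aligned with `scores`.
#' @param threshold binarisation threshold in (0,1).
#' @return a `confusion_counts` list: `TP`, `FP`, `FN`, `TN`, `context`.
#' @export
confusion_from_predictions <- function(scores, truth, input, threshold = 0.5) {
  if (length(scores) != length(truth) || length(scores) != length(input))
    stop("scores, truth and input must have the same length")
  stopifnot(threshold > 0, threshold < 1)
  m <- input == 0
  pos <- scores >= threshold
  new_confusion(TP = sum(m & truth == 1 & pos),
                FN = sum(m & truth == 1 & !pos),
                FP = sum(m & truth == 0 & pos),
                TN = sum(m & truth == 0 & !pos),
                context = "prediction")
}

#' Confusion counts for gap-filling recovery
#'
#' After deleting reactions from a model and gap-filling it, a deleted
#' reaction that was re-added is a true positive, a deleted reaction not
#' re-added is a false negative, and an added reaction that was never in
#' the original model is a false positive.  True negatives are the
#' candidate universe reactions that were neither in the original model
#' nor added (0 when no universe is given).
#'
#' @param original reaction ids of the intact model.
#' @param deleted ids removed before gap-filling (subset of `original`).
#' @param added ids added by the gap-filler.
#' @param candidates optional candidate universe (ids) defining TNs.
#' @return a `confusion_counts` list.
#' @export
confusion_from_gapfill <- function(original, deleted, added,
                                   candidates = NULL) {
  if (!all(deleted %in% original)) stop("deleted must be a subset of original")
  if (length(intersect(added, setdiff(original, deleted))))
    stop("added reactions overlap the retained annotation")
  TN <- if (is.null(candidates)) 0L else
    length(setdiff(setdiff(candidates, original), added))
  new_confusion(TP = length(intersect(added, deleted)),
                FN = length(setdiff(deleted, added)),
                FP = length(setdiff(added, original)),
                TN = TN, context = "gapfill")
}

new_confusion <- function(TP, FP, FN, TN, context) {
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), TN = as.integer(TN),
                 context = context),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Precision, recall, F1, specificity and balanced accuracy
#' (`(specificity + recall) / 2`).  Zero denominators yield 0 by
#' convention.
#'
#' @param counts a `confusion_counts` (or list with TP/FP/FN/TN).
#' @return a one-row data frame of the five metrics.
#' @export
metrics <- function(counts) {
  safe <- function(num, den) if (den > 0) num / den else 0
  precision <- safe(counts$TP, counts$TP + counts$FP)
  recall <- safe(counts$TP, counts$TP + counts$FN)
  f1 <- safe(2 * precision * recall, precision + recall)
  specificity <- safe(counts$TN, counts$TN + counts$FP)
  data.frame(precision = precision, recall = recall, F1 = f1,
             specificity = specificity,
             balanced_accuracy = (specificity + recall) / 2)
}

#' Pool per-reaction confusion counts into frequency bins
#'
#' Reactions are grouped by their occurrence count (number of genomes
#' carrying them) in bins of `bin_width` genomes; recall and precision
#' are pooled within each bin (summed counts, then the ratio).  Empty
#' bins are omitted.
#'
#' @param per_reaction data frame with columns `reaction`, `occurrence`,
#'   `TP`, `FP`, `FN` (and optionally `TN`).
#' @param bin_width bin width in genomes.
#' @return data frame with `bin` (lower edge), `recall`, `precision`,
#'   `n_reactions`.
#' @export
frequency_binned_metrics <- function(per_reaction, bin_width = 50) {
  stopifnot(all(c("reaction", "occurrence", "TP", "FP", "FN") %in%
                  names(per_reaction)))
  bin <- floor(per_reaction$occurrence / bin_width) * bin_width
  agg <- lapply(split(per_reaction, bin), function(d) {
    tp <- sum(d$TP); fp <- sum(d$FP); fn <- sum(d$FN)
    data.frame(bin = floor(d$occurrence[1] / bin_width) * bin_width,
               recall = if (tp + fn > 0) tp / (tp + fn) else 0,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               n_reactions = nrow(d))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard distance to the nearest training genome
#'
#' `min over training rows of 1 - |A intersect B| / |A union B|`, on
#' binary reaction vectors aligned to the same pan-reactome.  Used to
#' relate prediction quality to how close a query genome is to the
#' training collection.
#'
#' @param query binary vector over the pan-reactome.
#' @param training an `incidence_matrix` (or binary matrix) of training
#'   genomes.
#' @return distance in \[0,1\].
#' @export
nearest_neighbor_distance <- function(query, training) {
  M <- if (inherits(training, "incidence_matrix")) training$presence
       else as.matrix(training)
  query <- as.integer(query >= 1)
  if (length(query) != ncol(M)) stop("query length must match pan-reactome")
  if (sum(query) == 0) stop("query has no present reactions")
  inter <- as.numeric(M %*% query)
  uni <- rowSums(M) + sum(query) - inter
  min(1 - inter / uni)
}

#' Essential reactions of a growing model
#'
#' Single-reaction deletion screen: a reaction is essential when closing
#' it (bounds to zero) drops maximal biomass flux below `epsilon`.
#'
#' @param model a growing [metabolic_model()].
#' @param med a [medium()] (or NULL).
#' @param epsilon growth threshold.
#' @return character vector of essential reaction ids (always includes
#'   the biomass reaction).
#' @export
essential_reactions <- function(model, med = NULL, epsilon = 1e-6) {
  if (!is.null(med)) model <- apply_medium(model, med)
  if (check_growth(model) < epsilon)
    stop("model does not grow on this medium; essentiality is undefined")
  ess <- character(0)
  for (rid in model$reactions$id) {
    m2 <- model
    i <- match(rid, m2$reactions$id)
    m2$reactions$lb[i] <- 0; m2$reactions$ub[i] <- 0
    if (check_growth(m2) < epsilon) ess <- c(ess, rid)
  }
  ess
}

#' Simulated carbon utilisation profile
#'
#' For each carbon source, the base medium is modified by removing the
#' default carbon source and opening uptake of the tested source; growth
#' is called when maximal biomass flux reaches `epsilon`.  Models that
#' grow with no carbon source at all are flagged invalid (`valid =
#' FALSE`) since their profile is uninformative.  When an observed
#' binary profile is supplied, the simulated profile is scored against
#' it with balanced accuracy.
#'
#' @param model a [metabolic_model()].
#' @param base_medium the base [medium()].
#' @param carbon_sources character vector of exchange metabolite ids to
#'   test.
#' @param default_carbon metabolite id of the base medium's carbon
#'   source, removed before each test (NULL if none).
#' @param epsilon growth threshold.
#' @param observed optional named binary vector of measured growth.
#' @param uptake_rate uptake bound given to each tested source.
#' @return list with `growth` (named 0/1 vector), `valid`, and (when
#'   `observed` is given) `metrics` from [metrics()].
#' @export
carbon_profile <- function(model, base_medium, carbon_sources,
                           default_carbon = NULL, epsilon = 1e-6,
                           observed = NULL, uptake_rate = 10) {
  stopifnot(inherits(model, "metabolic_model"))
  base <- as.numeric(base_medium)
  names(base) <- names(base_medium)
  if (!is.null(default_carbon)) base <- base[setdiff(names(base), default_carbon)]
  ex_mets <- unlist(lapply(model$stoich[exchange_reactions(model)], names))
  # no-carbon control: growth here invalidates the whole profile
  blank <- check_growth(model, medium(base))
  growth <- stats::setNames(integer(length(carbon_sources)), carbon_sources)
  for (src in carbon_sources) {
    if (!src %in% ex_mets) {
      warning("no exchange reaction for carbon source '", src,
              "'; recorded as no growth")
      growth[src] <- 0L
      next
    }
    med_src <- medium(c(base[setdiff(names(base), src)],
                        stats::setNames(uptake_rate, src)))
    growth[src] <- as.integer(check_growth(model, med_src) >= epsilon)
  }
  out <- list(growth = growth, valid = blank < epsilon)
  if (!out$valid)
    warning("model grows without any carbon source; profile flagged invalid")
  if (!is.null(observed)) {
    observed <- observed[carbon_sources]
    cc <- new_confusion(TP = sum(growth == 1 & observed == 1),
                        FP = sum(growth == 1 & observed == 0),
                        FN = sum(growth == 0 & observed == 1),
                        TN = sum(growth == 0 & observed == 0),
                        context = "prediction")
    out$metrics <- metrics(cc)
  }
  out
}
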