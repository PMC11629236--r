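#' Build a reaction incidence matrix
#'
#' Given one reaction set per genome, constructs the binary genomes x
#' reactions incidence matrix that is the substrate for training and
#' testing the imputer.  The pan-reactome is the union of all reaction
#' sets, ordered (sorted ids); its per-reaction frequency `frac_r` is the
#' column mean of the matrix.
#'
#' @param reaction_sets named list (by genome id) of character vectors of
#'   reaction ids.
#' @param genomes data frame of genome metadata with at least a
#'   `genome_id` column matching `names(reaction_sets)`; typically also
#'   `species`, `genus`, `completeness`, `contamination`,
#'   `coarse_consistency`.
#' @return an `incidence_matrix`: list with `presence` (integer matrix,
#'   dimnames genome x reaction), `genomes` (metadata data frame) and
#'   `pan` (a `pan_reactome`: `reactions`, `frequency`, `n_genomes`).
#' @examples
#' im <- build_incidence_matrix(
#'   list(g1 = c("A", "B"), g2 = "B", g3 = c("B", "C")),
#'   data.frame(genome_id = c("g1", "g2", "g3")))
#' im$pan$frequency
#' @export
build_incidence_matrix <- function(reaction_sets, genomes = NULL) {
  if (!length(reaction_sets)) stop("need at least one genome")
  if (is.null(names(reaction_sets)) || any(!nzchar(names(reaction_sets))))
    stop("reaction_sets must be named by genome id")
  if (anyDuplicated(names(reaction_sets)))
    stop("duplicate genome_id in reaction_sets")
  if (any(lengths(reaction_sets) == 0)) stop("empty reaction set for some genome")
  if (is.null(genomes))
    genomes <- data.frame(genome_id = names(reaction_sets),
                          stringsAsFactors = FALSE)
  stopifnot("genome_id" %in% names(genomes))
  genomes <- genomes[match(names(reaction_sets), genomes$genome_id), , drop = FALSE]
  if (anyNA(genomes$genome_id)) stop("metadata missing for some genomes")
  rownames(genomes) <- NULL
  rxns <- sort(unique(unlist(reaction_sets)))
  presence <- matrix(0L, length(reaction_sets), length(rxns),
                     dimnames = list(names(reaction_sets), rxns))
  for (g in names(reaction_sets))
    presence[g, unique(reaction_sets[[g]])] <- 1L
  new_incidence_matrix(presence, genomes)
}

new_incidence_matrix <- function(presence, genomes) {
  stopifnot(all(presence %in% c(0L, 1L)),
            nrow(presence) == nrow(genomes))
  pan <- list(reactions = colnames(presence),
              frequency = colMeans(presence),
              n_genomes = nrow(presence))
  class(pan) <- "pan_reactome"
  structure(list(presence = presence, genomes = genomes, pan = pan),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d genomes x %d reactions (fill %.1f%%)\n",
              nrow(x$presence), ncol(x$presence), 100 * mean(x$presence)))
  invisible(x)
}

#' @export
print.pan_reactome <- function(x, ...) {
  cat(sprintf("<pan_reactome> %d reactions over %d genomes, frac_r in [%.3f, %.3f]\n",
              length(x$reactions), x$n_genomes,
              min(x$frequency), max(x$frequency)))
  invisible(x)
}

#' Pan-reactome accessor
#' @param x an `incidence_matrix`.
#' @return the `pan_reactome` of `x`.
#' @export
pan_reactome <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  x$pan
}

#' Read / write an incidence matrix as TSV
#'
#' Dialect: first column `genome_id`, remaining header fields are
#' reaction ids, cell values 0/1, tab-separated, no quoting.  Metadata
#' can be written/read alongside as a second TSV.
#'
#' @param x an `incidence_matrix`.
#' @param path output TSV path.
#' @param metadata_path optional path for the genome metadata TSV.
#' @return `path`, invisibly (write); an `incidence_matrix` (read).
#' @export
write_incidence_tsv <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  tab <- data.frame(genome_id = rownames(x$presence), x$presence,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(x$genomes, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence_tsv
#' @export
read_incidence_tsv <- function(path, metadata_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "genome_id") stop("first column must be genome_id")
  presence <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(presence) <- "integer"
  rownames(presence) <- tab$genome_id
  genomes <- if (!is.null(metadata_path)) {
    utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  } else {
    data.frame(genome_id = tab$genome_id, stringsAsFactors = FALSE)
  }
  new_incidence_matrix(presence, genomes)
}

# sequencing-quality score used for genome selection
quality_score <- function(records) {
  records$completeness - 5 * records$contamination
}

#' Select the best genome per taxon
#'
#' Within each species (or genus) keeps the single genome maximising the
#' sequencing quality score `completeness - 5 * contamination`.  Ties are
#' broken by the highest coarse consistency, remaining ties
#' lexicographically by `genome_id` so selection is deterministic.
#'
#' @param records data frame of genome metadata (`genome_id`, `species`,
#'   `genus`, `completeness`, `contamination`, `coarse_consistency`).
#' @param level `"species"` or `"genus"`: the grouping label.
#' @return the selected rows of `records`, one per group, in input order
#'   of first group appearance.
#' @export
select_best_genomes <- function(records, level = c("species", "genus")) {
  level <- match.arg(level)
  stopifnot(level %in% names(records))
  need <- c("genome_id", "completeness", "contamination", "coarse_consistency")
  stopifnot(all(need %in% names(records)))
  groups <- split(seq_len(nrow(records)), records[[level]])
  pick <- vapply(groups, function(idx) {
    r <- records[idx, , drop = FALSE]
    ord <- order(-quality_score(r), -r$coarse_consistency, r$genome_id)
    idx[ord[1]]
  }, 1L)
  records[sort(pick), , drop = FALSE]
}

#' Split an incidence matrix into train and test sets
#'
#' The test set takes the best genome of each genus (same quality rule as
#' [select_best_genomes()]); the training set keeps all remaining
#' genomes.  The partition is exact and both halves keep the full input's
#' pan-reactome as their coordinate system (column order unchanged;
#' frequencies are recomputed per half and stored in `$pan$frequency`,
#' with the parent frequencies in `attr(, "parent_frequency")`).
#'
#' @param x an `incidence_matrix` whose metadata has a `genus` column.
#' @return list with elements `train` and `test` (both `incidence_matrix`).
#' @export
split_train_test <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"), "genus" %in% names(x$genomes))
  best <- select_best_genomes(x$genomes, level = "genus")
  test_ids <- best$genome_id
  singleton <- names(which(table(x$genomes$genus) == 1))
  if (length(singleton))
    message(length(singleton),
            " genera have a single genome; they contribute to test only")
  in_test <- x$genomes$genome_id %in% test_ids
  mk <- function(sel) {
    im <- new_incidence_matrix(x$presence[sel, , drop = FALSE],
                               x$genomes[sel, , drop = FALSE])
    # keep the full pan-reactome as coordinate system
    im$pan$reactions <- x$pan$reactions
    attr(im, "parent_frequency") <- x$pan$frequency
    im
  }
  list(train = mk(!in_test), test = mk(in_test))
}

#' Drop genomes carrying a taxon label
#'
#' Removes all genomes whose metadata `column` equals `label`, keeping
#' pan-reactome order and recomputing frequencies.  Used for
#' leave-a-clade-out experiments.
#'
#' @param x an `incidence_matrix`.
#' @param label taxon name to exclude.
#' @param column metadata column holding the label (default `"genus"`).
#' @return the reduced `incidence_matrix`.
#' @export
exclude_partition <- function(x, label, column = "genus") {
  stopifnot(inherits(x, "incidence_matrix"))
  if (!column %in% names(x$genomes)) {
    warning("metadata has no column '", column, "'; returning input unchanged")
    return(x)
  }
  drop <- x$genomes[[column]] %in% label
  if (!any(drop)) {
    warning("label '", paste(label, collapse = ","),
            "' not present; returning input unchanged")
    return(x)
  }
  if (all(drop)) stop("excluding '", paste(label, collapse = ","),
                      "' would remove every genome")
  im <- new_incidence_matrix(x$presence[!drop, , drop = FALSE],
                             x$genomes[!drop, , drop = FALSE])
  im$pan$reactions <- x$pan$reactions
  im
}
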