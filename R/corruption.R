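#' Define a reaction deletion scheme
#'
#' Corruption simulates incomplete genomes by deleting reactions from a
#' complete reaction set.  Two schemes are supported:
#'
#' * `uniform`: every present reaction is equally likely to go; exactly
#'   `round(target_fraction * n_present)` reactions are deleted, which
#'   matches the "delete 30%" protocol and keeps tests deterministic.
#' * `rare_biased`: each present reaction is deleted independently with a
#'   logistic probability of its pan-reactome frequency, biased toward
#'   rare reactions:
#'   `D(frac) = 1 - 1/(1 + exp(-steepness * (frac - midpoint)))`,
#'   which decreases from ~1 at `frac = 0` to ~0 at `frac = 1`.
#'
#' The frequency-biased deletion probability is also published with the
#' opposite sign in the exponent (increasing in `frac`); that orientation
#' contradicts the stated goal of deleting rarer reactions more often, so
#' the decreasing form is the default and the increasing one is available
#' via `as_printed = TRUE`.  With `rescale = TRUE` the probabilities are
#' multiplied by a constant so that the expected overall deletion equals
#' `target_fraction` (off by default).
#'
#' @param kind `"uniform"` or `"rare_biased"`.
#' @param target_fraction fraction of present reactions to delete
#'   (uniform mode), in (0,1).
#' @param steepness,midpoint logistic parameters for `rare_biased`.
#' @param as_printed use the increasing-orientation logistic.
#' @param rescale rescale rare-biased probabilities to expected
#'   `target_fraction` deletion.
#' @return a `deletion_scheme` object.
#' @export
deletion_scheme <- function(kind = c("uniform", "rare_biased"),
                            target_fraction = 0.3, steepness = 10,
                            midpoint = 0.5, as_printed = FALSE,
                            rescale = FALSE) {
  kind <- match.arg(kind)
  stopifnot(target_fraction > 0, target_fraction < 1)
  structure(list(kind = kind, target_fraction = target_fraction,
                 steepness = steepness, midpoint = midpoint,
                 as_printed = as_printed, rescale = rescale),
            class = "deletion_scheme")
}

#' Per-reaction deletion probability
#'
#' @param frac reaction frequency `frac_r` in \[0,1\] (vectorised).
#' @param scheme a [deletion_scheme()].
#' @return deletion probabilities, same length as `frac`.
#' @examples
#' deletion_probability(0.7, deletion_scheme("uniform"))      # 0.3
#' deletion_probability(0.5, deletion_scheme("rare_biased"))  # 0.5
#' @export
deletion_probability <- function(frac, scheme) {
  stopifnot(inherits(scheme, "deletion_scheme"))
  if (any(frac < 0 | frac > 1)) stop("frac must be in [0, 1]")
  if (scheme$kind == "uniform") return(rep(scheme$target_fraction, length(frac)))
  s <- if (scheme$as_printed) scheme$steepness else -scheme$steepness
  1 - 1 / (1 + exp(s * (frac - scheme$midpoint)))
}

#' Corrupt one genome's reaction vector
#'
#' Produces a paired (input, truth) sample: the truth vector `T` is the
#' genome's incidence row and the input vector `I` is the same row after
#' deletion, so `I <= T` element-wise.  If a draw would delete every
#' present reaction, it is redrawn retaining at least one.
#'
#' @param truth binary (0/1) named or unnamed vector over the
#'   pan-reactome.
#' @param scheme a [deletion_scheme()].
#' @param seed integer seed; identical arguments give identical samples.
#' @param frequencies pan-reactome frequencies `frac_r`, required for
#'   `rare_biased`.
#' @param genome_id,replicate bookkeeping fields stored on the sample.
#' @return a `corrupted_sample`: list with `input`, `truth`, `deleted`
#'   (indices), `genome_id`, `replicate`, `seed`.
#' @export
corrupt <- function(truth, scheme, seed, frequencies = NULL,
                    genome_id = NA_character_, replicate = 1L) {
  stopifnot(inherits(scheme, "deletion_scheme"))
  nm <- names(truth)
  truth <- as.integer(truth >= 1)
  names(truth) <- nm
  present <- which(truth == 1L)
  if (!length(present)) stop("truth vector has no present reactions")
  rs <- local_rng(seed)
  on.exit(rs())
  if (scheme$kind == "uniform") {
    k <- round(scheme$target_fraction * length(present))
    k <- min(k, length(present) - 1L)  # always retain >= 1
    del <- if (k > 0) sample(present, k) else integer(0)
  } else {
    if (is.null(frequencies)) stop("rare_biased corruption needs frequencies")
    stopifnot(length(frequencies) == length(truth))
    p <- deletion_probability(frequencies[present], scheme)
    if (scheme$rescale) {
      p <- p * (scheme$target_fraction / mean(p))
      p <- pmin(p, 1)
    }
    repeat {
      del <- present[stats::runif(length(present)) < p]
      if (length(del) < length(present)) break
      message("corrupt(): draw deleted all reactions; resampling")
    }
  }
  input <- truth
  input[del] <- 0L
  structure(list(genome_id = genome_id, replicate = as.integer(replicate),
                 seed = seed, input = input, truth = truth,
                 deleted = sort(del)),
            class = "corrupted_sample")
}

#' Generate corruption replicates for a whole incidence matrix
#'
#' Emits `n_genomes * n_replicates` corrupted samples.  Each sample's
#' seed is derived deterministically from `(base_seed, genome_id,
#' replicate)`, so any sample can be regenerated in isolation.
#'
#' @param x an `incidence_matrix`.
#' @param n_replicates replicates per genome.
#' @param scheme a [deletion_scheme()].
#' @param base_seed integer base seed.
#' @return list of `corrupted_sample` objects (genome-major order).
#' @export
make_replicates <- function(x, n_replicates, scheme, base_seed) {
  stopifnot(inherits(x, "incidence_matrix"), n_replicates >= 1)
  freq <- x$pan$frequency
  out <- vector("list", nrow(x$presence) * n_replicates)
  k <- 0L
  for (g in rownames(x$presence)) {
    row <- x$presence[g, ]
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      out[[k]] <- corrupt(row, scheme,
                          seed = derive_seed(base_seed, g, r),
                          frequencies = freq, genome_id = g, replicate = r)
    }
  }
  out
}

# Deterministic 31-bit seed from (base_seed, genome_id, replicate).
derive_seed <- function(base_seed, genome_id, replicate) {
  h <- as.double(base_seed %% 2147483647L)
  for (ch in utf8ToInt(paste0(genome_id, "#", replicate)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Run code under a private RNG state, restoring the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
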