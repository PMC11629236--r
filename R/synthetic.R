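#' Configuration of the synthetic benchmark world
#'
#' The synthetic world emulates the structure that makes reaction
#' imputation learnable in real pan-reactomes: a universally shared core,
#' pathway modules gained and lost as blocks with clade structure (the
#' co-occurrence signal), and rarer accessory reactions spanning a range
#' of frequencies.  Defaults: 400 reactions = 100 core + 30 modules x 8 +
#' 60 accessory, 6 clades x 40 genomes, per-module home-clade gain
#' probabilities evenly spaced over 0.35-0.95 (so module frequencies form
#' a genuine gradient, as pathway frequencies do across real bacteria),
#' leak probability 0.02 outside the home clade, accessory carry
#' probabilities 0.02-0.12, and flip noise 0.01 on non-core entries.
#'
#' @param n_reactions total pan-reactome size.
#' @param n_core reactions present in every genome.
#' @param n_modules,module_size pathway modules (gained/lost as blocks).
#' @param n_clades,genomes_per_clade population structure; each clade is
#'   split into 10 genera for train/test splitting.
#' @param module_gain_prob probability a genome carries a module of its
#'   own clade; length 2 = range spread evenly across modules.
#' @param module_leak_prob probability of carrying another clade's
#'   module.
#' @param noise_flip_prob independent flip probability for non-core
#'   entries.
#' @param seed integer seed; the whole world is a deterministic function
#'   of the config.
#' @return a `synthetic_world_config`.
#' @export
synthetic_world_config <- function(n_reactions = 400L, n_core = 100L,
                                   n_modules = 30L, module_size = 8L,
                                   n_clades = 6L, genomes_per_clade = 40L,
                                   module_gain_prob = c(0.35, 0.95),
                                   module_leak_prob = 0.02,
                                   noise_flip_prob = 0.01, seed = 1L) {
  stopifnot(n_core + n_modules * module_size <= n_reactions,
            n_modules %% 2 == 0,
            length(module_gain_prob) %in% 1:2,
            all(module_gain_prob >= 0), all(module_gain_prob <= 1),
            module_leak_prob >= 0, module_leak_prob <= 1,
            noise_flip_prob >= 0, noise_flip_prob <= 1)
  structure(list(n_reactions = as.integer(n_reactions),
                 n_core = as.integer(n_core),
                 n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 n_clades = as.integer(n_clades),
                 genomes_per_clade = as.integer(genomes_per_clade),
                 module_gain_prob = module_gain_prob,
                 module_leak_prob = module_leak_prob,
                 noise_flip_prob = noise_flip_prob,
                 seed = as.integer(seed)),
            class = "synthetic_world_config")
}

# shared layout: reaction ids, module/pair/clade assignment
world_layout <- function(config) {
  n_acc <- config$n_reactions - config$n_core -
    config$n_modules * config$module_size
  core_ids <- sprintf("rxn_core%03d", seq_len(config$n_core))
  mod_tab <- expand.grid(pos = seq_len(config$module_size),
                         module = seq_len(config$n_modules))
  mod_ids <- sprintf("rxn_m%02d_p%d", mod_tab$module, mod_tab$pos)
  acc_ids <- if (n_acc > 0) sprintf("rxn_acc%02d", seq_len(n_acc)) else character(0)
  # module m belongs to clade ((m-1) mod n_clades)+1; pair partners
  # (2j-1, 2j) therefore sit in different clades and share stoichiometry.
  # Home-clade gain probabilities span a gradient so that module
  # frequencies, and hence frequency-based costs, are informative.
  gp <- config$module_gain_prob
  gains <- if (length(gp) == 2) seq(gp[1], gp[2], length.out = config$n_modules)
           else rep(gp, config$n_modules)
  modules <- data.frame(module = seq_len(config$n_modules),
                        clade = (seq_len(config$n_modules) - 1L) %%
                          config$n_clades + 1L,
                        pair = ceiling(seq_len(config$n_modules) / 2),
                        gain = gains)
  # accessory frequency gradient + the core position each accessory twins
  acc <- data.frame(id = acc_ids,
                    prob = if (n_acc > 0) seq(0.02, 0.12, length.out = n_acc)
                           else numeric(0),
                    core_pos = if (n_acc > 0)
                      (seq_len(n_acc) - 1L) %% config$n_core + 1L else integer(0))
  list(core_ids = core_ids, mod_ids = mod_ids, mod_tab = mod_tab,
       acc = acc, modules = modules,
       all_ids = c(core_ids, mod_ids, acc_ids),
       n_pairs = config$n_modules %/% 2L)
}

#' Generate a clade-structured synthetic incidence matrix
#'
#' Core reactions are present in every genome (frequency exactly 1);
#' each module is carried as a block with probability
#' `module_gain_prob` by genomes of its home clade and
#' `module_leak_prob` elsewhere; accessory reactions are carried
#' independently with a per-reaction probability spanning 0.02-0.30;
#' finally non-core entries are flipped with `noise_flip_prob`.  Genomes
#' get species (unique), genus (10 per clade), clade labels, and
#' plausible completeness/contamination/coarse-consistency scores.
#'
#' @param config a [synthetic_world_config()].
#' @return an `incidence_matrix`; the pre-noise module block assignment
#'   (genomes x modules logical matrix) is in `attr(, "module_carried")`
#'   and the config in `attr(, "config")`.
#' @export
generate_incidence <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  lay <- world_layout(config)
  rs <- local_rng(config$seed)
  on.exit(rs())
  n_gen <- config$n_clades * config$genomes_per_clade
  genome_clade <- rep(seq_len(config$n_clades), each = config$genomes_per_clade)
  ids <- sprintf("G%d_%02d", genome_clade,
                 sequence(rep(config$genomes_per_clade, config$n_clades)))
  presence <- matrix(0L, n_gen, length(lay$all_ids),
                     dimnames = list(ids, lay$all_ids))
  presence[, lay$core_ids] <- 1L
  carried <- matrix(FALSE, n_gen, config$n_modules,
                    dimnames = list(ids, NULL))
  for (g in seq_len(n_gen)) {
    p_mod <- ifelse(lay$modules$clade == genome_clade[g],
                    lay$modules$gain, config$module_leak_prob)
    carried[g, ] <- stats::runif(config$n_modules) < p_mod
    for (m in which(carried[g, ]))
      presence[g, lay$mod_ids[lay$mod_tab$module == m]] <- 1L
    if (nrow(lay$acc))
      presence[g, lay$acc$id] <- as.integer(stats::runif(nrow(lay$acc)) <
                                              lay$acc$prob)
  }
  if (config$noise_flip_prob > 0) {
    noncore <- setdiff(lay$all_ids, lay$core_ids)
    flip <- matrix(stats::runif(n_gen * length(noncore)) <
                     config$noise_flip_prob, n_gen, length(noncore))
    presence[, noncore] <- ifelse(flip, 1L - presence[, noncore],
                                  presence[, noncore])
  }
  # every reaction must occur at least once; give orphans one carrier
  orphan <- which(colSums(presence) == 0)
  for (j in orphan) presence[sample.int(n_gen, 1), j] <- 1L
  genera_per_clade <- 10L
  per_genus <- ceiling(config$genomes_per_clade / genera_per_clade)
  genus <- sprintf("g%d_%d", genome_clade,
                   (sequence(rep(config$genomes_per_clade, config$n_clades)) - 1L) %/%
                     per_genus + 1L)
  genomes <- data.frame(genome_id = ids,
                        species = paste0("s_", ids),
                        genus = genus,
                        clade = paste0("clade", genome_clade),
                        completeness = round(stats::runif(n_gen, 90, 100), 2),
                        contamination = round(stats::runif(n_gen, 0, 2), 2),
                        coarse_consistency = round(stats::runif(n_gen, 85, 100), 2),
                        stringsAsFactors = FALSE)
  im <- new_incidence_matrix(presence, genomes)
  attr(im, "module_carried") <- carried
  attr(im, "config") <- config
  im
}

#' Stoichiometric layer of the synthetic world
#'
#' Gives every pan-reactome reaction a mass-balanced stoichiometry so
#' genome models can be flux-analysed and gap-filled:
#'
#' * core reactions form a linear chain from the exchanged nutrient to
#'   the terminal biomass precursor;
#' * the two modules of a pair are twin pathways converting a shared
#'   exchanged substrate to a shared product through shared
#'   intermediates, so either twin can carry the flux -- only frequency
#'   or learned co-occurrence can tell which one a genome actually has;
#' * accessory reactions duplicate core chain steps (isozyme-like);
#' * the candidate database additionally carries non-pan decoys: twins
#'   of core and module steps plus two-step shortcuts, which an
#'   unweighted gap-filler cannot distinguish from genuine reactions.
#'
#' @param config a [synthetic_world_config()].
#' @param n_decoys named integer vector with elements `core_twin`,
#'   `shortcut`, `module_twin`.
#' @return a `synthetic_world`: list with `config`, `db` (prepared
#'   candidate `reaction_db`: pan reactions + decoys), `medium` (all
#'   exchanged substrates open at 10), and internals used by
#'   [genome_model()].
#' @export
world_biochemistry <- function(config,
                               n_decoys = c(core_twin = 40, shortcut = 20,
                                            module_twin = 20)) {
  stopifnot(inherits(config, "synthetic_world_config"))
  lay <- world_layout(config)
  ms <- config$module_size
  core_met <- function(i) if (i == 0) "nut_e" else sprintf("cm%03d", i)
  stoich <- list()
  for (i in seq_len(config$n_core))
    stoich[[lay$core_ids[i]]] <- stats::setNames(c(-1, 1),
                                                 c(core_met(i - 1), core_met(i)))
  mod_met <- function(pair, p) {
    if (p == 0) sprintf("sub%02d_e", pair)
    else if (p == ms) sprintf("prod%02d", pair)
    else sprintf("im%02d_%d", pair, p)
  }
  for (k in seq_along(lay$mod_ids)) {
    m <- lay$mod_tab$module[k]; p <- lay$mod_tab$pos[k]
    pair <- lay$modules$pair[m]
    stoich[[lay$mod_ids[k]]] <- stats::setNames(c(-1, 1),
                                                c(mod_met(pair, p - 1),
                                                  mod_met(pair, p)))
  }
  for (a in seq_len(nrow(lay$acc))) {
    i <- lay$acc$core_pos[a]
    stoich[[lay$acc$id[a]]] <- stats::setNames(c(-1, 1),
                                               c(core_met(i - 1), core_met(i)))
  }
  # decoys (deterministic under the world seed)
  rs <- local_rng(config$seed + 7L)
  on.exit(rs())
  nd <- n_decoys
  nd["core_twin"] <- min(nd["core_twin"], config$n_core)
  nd["shortcut"] <- min(nd["shortcut"], max(config$n_core - 2, 0))
  nd["module_twin"] <- min(nd["module_twin"], length(lay$mod_ids))
  if (nd["core_twin"] > 0)
    for (i in sample.int(config$n_core, nd["core_twin"])) {
      id <- sprintf("dec_core%03d", i)
      stoich[[id]] <- stats::setNames(c(-1, 1), c(core_met(i - 1), core_met(i)))
    }
  if (nd["shortcut"] > 0)
    for (i in sample(2:config$n_core, nd["shortcut"])) {
      id <- sprintf("dec_short%03d", i)
      stoich[[id]] <- stats::setNames(c(-1, 1), c(core_met(i - 2), core_met(i)))
    }
  if (nd["module_twin"] > 0)
    for (k in sample(seq_along(lay$mod_ids), nd["module_twin"])) {
      m <- lay$mod_tab$module[k]; p <- lay$mod_tab$pos[k]
      pair <- lay$modules$pair[m]
      id <- sprintf("dec_m%02d_p%d", m, p)
      stoich[[id]] <- stats::setNames(c(-1, 1),
                                      c(mod_met(pair, p - 1), mod_met(pair, p)))
    }
  ids <- names(stoich)
  mets <- sort(unique(unlist(lapply(stoich, names))))
  db <- new_reaction_db(
    data.frame(id = ids, namespace = "synthetic", reversible = FALSE,
               lb = 0, ub = 1000, stringsAsFactors = FALSE),
    stoich,
    data.frame(id = mets,
               compartment = ifelse(grepl("_e$", mets), "e", "c"),
               stringsAsFactors = FALSE))
  db <- prepare_database(db)
  med <- medium(stats::setNames(rep(10, lay$n_pairs + 1),
                                c("nut_e", sprintf("sub%02d_e", seq_len(lay$n_pairs)))))
  structure(list(config = config, layout = lay, db = db, medium = med,
                 stoich = db$stoich, core_final = core_met(config$n_core)),
            class = "synthetic_world")
}

#' Build one genome's metabolic model from the synthetic world
#'
#' The model holds the genome's present pan-reactome reactions, exchange
#' reactions for every world substrate, and a biomass reaction that
#' consumes the terminal core precursor plus the product of every module
#' pair the genome carries (per the pre-noise block assignment).  Pass a
#' corrupted presence vector via `presence` to build the model of an
#' artificially incomplete genome.
#'
#' @param world a [world_biochemistry()] result.
#' @param incidence the matching [generate_incidence()] matrix.
#' @param genome_id genome to build.
#' @param presence optional named 0/1 vector overriding the genome's
#'   incidence row.
#' @return a [metabolic_model()] (biomass id `"bio1"`).
#' @export
genome_model <- function(world, incidence, genome_id, presence = NULL) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(incidence, "incidence_matrix"))
  row <- if (is.null(presence)) incidence$presence[genome_id, ] else presence
  if (is.null(names(row))) {
    stopifnot(length(row) == ncol(incidence$presence))
    names(row) <- colnames(incidence$presence)
  }
  carried <- attr(incidence, "module_carried")[genome_id, ]
  lay <- world$layout
  pairs_needed <- sort(unique(lay$modules$pair[which(carried)]))
  present_ids <- names(row)[row == 1]
  present_ids <- intersect(present_ids, names(world$stoich))
  stoich <- world$stoich[present_ids]
  ex_mets <- names(world$medium)
  ex_ids <- paste0("EX_", sub("_e$", "", ex_mets))
  for (i in seq_along(ex_ids))
    stoich[[ex_ids[i]]] <- stats::setNames(-1, ex_mets[i])
  bio_prec <- c(world$core_final, sprintf("prod%02d", pairs_needed))
  stoich[["bio1"]] <- stats::setNames(rep(-1, length(bio_prec)), bio_prec)
  reactions <- data.frame(
    id = c(present_ids, ex_ids, "bio1"),
    lb = c(rep(0, length(present_ids)), rep(-10, length(ex_ids)), 0),
    ub = 1000,
    origin = "annotation", stringsAsFactors = FALSE)
  m <- metabolic_model(genome_id, reactions, stoich, "bio1")
  apply_medium(m, world$medium)
}

#' Deterministic toy gap-filling networks
#'
#' Small mass-balanced fixtures with known minimal gap-fill sets,
#' verified by exhaustive subset enumeration at generation time:
#'
#' * `linear_chain`: a nutrient-to-biomass chain with the middle step
#'   moved to the database (unique 1-reaction completion) plus
#'   disconnected decoys;
#' * `branched_cheap_expensive`: biomass reachable through a cheap
#'   1-reaction route or an expensive 2-reaction route;
#' * `parallel_paths`: two redundant complete routes (no gap-filling
#'   needed; neither route essential).
#'
#' @param template fixture name.
#' @param size chain length for `linear_chain` (>= 3).
#' @return list with `model`, `db` (prepared), `costs`, `medium`,
#'   `minimal_sets` (list of minimal-cost completions) and
#'   `minimal_cost`.
#' @export
generate_toy_network <- function(template = c("linear_chain",
                                              "branched_cheap_expensive",
                                              "parallel_paths"),
                                 size = 4L) {
  template <- match.arg(template)
  mk_db <- function(stoich, costs) {
    ids <- names(stoich)
    mets <- sort(unique(unlist(lapply(stoich, names))))
    prepare_database(new_reaction_db(
      data.frame(id = ids, namespace = "synthetic", reversible = FALSE,
                 lb = 0, ub = 1000, stringsAsFactors = FALSE),
      stoich,
      data.frame(id = mets, compartment = "c", stringsAsFactors = FALSE)))
  }
  mk_model <- function(id, stoich, biomass_met) {
    stoich <- c(stoich,
                list(EX_A = stats::setNames(-1, "A_e"),
                     bio1 = stats::setNames(-1, biomass_met)))
    n <- length(stoich)
    reactions <- data.frame(id = names(stoich),
                            lb = c(rep(0, n - 2), -10, 0), ub = 1000,
                            origin = "annotation", stringsAsFactors = FALSE)
    metabolic_model(id, reactions, stoich, "bio1")
  }
  med <- medium(c(A_e = 10))
  if (template == "linear_chain") {
    stopifnot(size >= 3)
    met <- function(i) if (i == 0) "A_e" else sprintf("t%d", i)
    chain <- lapply(seq_len(size), function(i)
      stats::setNames(c(-1, 1), c(met(i - 1), met(i))))
    names(chain) <- sprintf("step%d", seq_len(size))
    gap <- ceiling(size / 2)
    model <- mk_model("toy_chain", chain[-gap], met(size))
    dbs <- c(chain[gap],
             list(dec1 = stats::setNames(c(-1, 1), c("x1", "x2")),
                  dec2 = stats::setNames(c(-1, 1), c("x2", "x3"))))
    costs <- stats::setNames(c(1, 50, 50), names(dbs))
    db <- mk_db(dbs, costs)
  } else if (template == "branched_cheap_expensive") {
    model <- mk_model("toy_branched", list(), "B")
    dbs <- list(cheap = stats::setNames(c(-1, 1), c("A_e", "B")),
                exp1 = stats::setNames(c(-1, 1), c("A_e", "X")),
                exp2 = stats::setNames(c(-1, 1), c("X", "B")))
    costs <- stats::setNames(c(0.1, 50, 50), names(dbs))
    db <- mk_db(dbs, costs)
  } else {
    paths <- list(p1 = stats::setNames(c(-1, 1), c("A_e", "B")),
                  p2 = stats::setNames(c(-1, 1), c("A_e", "B")))
    model <- mk_model("toy_parallel", paths, "B")
    dbs <- list(dec1 = stats::setNames(c(-1, 1), c("x1", "x2")))
    costs <- stats::setNames(50, names(dbs))
    db <- mk_db(dbs, costs)
  }
  bf <- bruteforce_gapfill(model, db, costs, med)
  list(model = model, db = db, costs = costs, medium = med,
       minimal_sets = bf$minimal_sets, minimal_cost = bf$minimal_cost)
}

#' Exhaustive minimal-cost gap-fill oracle
#'
#' Enumerates every subset of the candidate reactions (database entries
#' absent from the model), checks growth of each augmented model with
#' plain flux balance analysis, and returns the cheapest growth-
#' sufficient subsets.  Exponential in the candidate count -- intended
#' as an independent reference for small instances.
#'
#' @param model a [metabolic_model()].
#' @param db prepared candidate `reaction_db` (<= ~14 candidates).
#' @param costs named candidate costs.
#' @param med a [medium()] or NULL.
#' @param epsilon growth threshold.
#' @return list: `feasible`, `minimal_cost`, `minimal_sets` (all subsets
#'   attaining it, as character vectors).
#' @export
bruteforce_gapfill <- function(model, db, costs, med = NULL, epsilon = 1e-6) {
  if (!is.null(med)) model <- apply_medium(model, med)
  cand <- setdiff(db$reactions$id, model$reactions$id)
  n <- length(cand)
  if (n > 16) stop("bruteforce_gapfill is limited to 16 candidates")
  best_cost <- Inf; best_sets <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- cand[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    cost <- sum(costs[sel])
    if (cost > best_cost + 1e-12) next
    m2 <- model
    if (length(sel)) {
      idx <- match(sel, db$reactions$id)
      add_rx <- data.frame(id = sel, lb = 0, ub = db$reactions$ub[idx],
                           origin = "gapfill", stringsAsFactors = FALSE)
      m2 <- metabolic_model(model$id,
                            rbind(model$reactions[, c("id", "lb", "ub", "origin")],
                                  add_rx),
                            c(model$stoich, db$stoich[sel]),
                            model$biomass_id)
    }
    if (check_growth(m2) >= epsilon) {
      if (cost < best_cost - 1e-12) {
        best_cost <- cost; best_sets <- list(sort(sel))
      } else {
        best_sets <- c(best_sets, list(sort(sel)))
      }
    }
  }
  list(feasible = is.finite(best_cost), minimal_cost = best_cost,
       minimal_sets = best_sets)
}

#' Random small gap-filling instances
#'
#' Generates a random layered toy network: a nutrient-to-biomass chain
#' with a random subset of steps removed to the candidate database, plus
#' random forward shortcut edges and disconnected decoys, with random
#' positive costs.  Always feasible (the full chain is available).
#'
#' @param seed integer seed.
#' @param n_candidates total candidate reactions (<= 12).
#' @return list with `model`, `db`, `costs`, `medium`.
#' @export
random_gapfill_instance <- function(seed, n_candidates = 8L) {
  stopifnot(n_candidates >= 2, n_candidates <= 12)
  rs <- local_rng(seed)
  on.exit(rs())
  L <- sample(3:5, 1)
  met <- function(i) if (i == 0) "A_e" else sprintf("t%d", i)
  chain <- lapply(seq_len(L), function(i)
    stats::setNames(c(-1, 1), c(met(i - 1), met(i))))
  names(chain) <- sprintf("step%d", seq_len(L))
  n_gap <- sample(1:min(3, L - 1), 1)
  gaps <- sample(seq_len(L), n_gap)
  model_stoich <- c(chain[-gaps],
                    list(EX_A = stats::setNames(-1, "A_e"),
                         bio1 = stats::setNames(-1, met(L))))
  nm <- length(model_stoich)
  model <- metabolic_model(
    paste0("rand", seed),
    data.frame(id = names(model_stoich),
               lb = c(rep(0, nm - 2), -10, 0), ub = 1000,
               origin = "annotation", stringsAsFactors = FALSE),
    model_stoich, "bio1")
  cand <- chain[gaps]
  # shortcut edges jumping forward over >= 2 levels
  n_extra <- n_candidates - n_gap
  k <- 0
  while (k < n_extra) {
    k <- k + 1
    if (stats::runif(1) < 0.6 && L >= 2) {
      i <- sample(0:(L - 2), 1); j <- sample((i + 2):L, 1)
      cand[[sprintf("alt%d_%d_%d", k, i, j)]] <-
        stats::setNames(c(-1, 1), c(met(i), met(j)))
    } else {
      cand[[sprintf("dec%d", k)]] <-
        stats::setNames(c(-1, 1), sprintf("x%d_%d", k, 1:2))
    }
  }
  mets <- sort(unique(unlist(lapply(cand, names))))
  db <- prepare_database(new_reaction_db(
    data.frame(id = names(cand), namespace = "synthetic", reversible = FALSE,
               lb = 0, ub = 1000, stringsAsFactors = FALSE),
    cand,
    data.frame(id = mets, compartment = "c", stringsAsFactors = FALSE)))
  costs <- stats::setNames(round(stats::runif(length(cand), 0.1, 5), 3),
                           names(cand))
  list(model = model, db = db, costs = costs, medium = medium(c(A_e = 10)))
}

#' Observed carbon-usage phenotypes of the synthetic world
#'
#' One column per module pair substrate: a genome grows on substrate
#' `subXX_e` exactly when its presence row carries all steps of at least
#' one twin module of that pair.  With zero flip noise the table is
#' fully determined by reaction content.
#'
#' @param incidence a [generate_incidence()] matrix.
#' @param world the matching [world_biochemistry()].
#' @return binary genomes x substrates matrix.
#' @export
generate_phenotypes <- function(incidence, world) {
  stopifnot(inherits(world, "synthetic_world"))
  lay <- world$layout
  sources <- sprintf("sub%02d_e", seq_len(lay$n_pairs))
  out <- matrix(0L, nrow(incidence$presence), lay$n_pairs,
                dimnames = list(rownames(incidence$presence), sources))
  for (m in seq_len(world$config$n_modules)) {
    ids <- lay$mod_ids[lay$mod_tab$module == m]
    complete <- rowSums(incidence$presence[, ids, drop = FALSE]) == length(ids)
    pair <- lay$modules$pair[m]
    out[, pair] <- pmax(out[, pair], as.integer(complete))
  }
  out
}
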