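test_that("cost schemes price reactions per their evidence", {
  toy <- generate_toy_network("linear_chain")
  db <- toy$db
  pan <- list(reactions = c("step2", "other"),
              frequency = c(step2 = 1, other = 0.25), n_genomes = 4)
  class(pan) <- "pan_reactome"
  w1 <- make_costs(cost_scheme("W1"), db)
  expect_true(all(w1 == 50))
  w2 <- make_costs(cost_scheme("W2"), db, pan = pan)
  expect_equal(unname(w2[c("step2", "dec1")]), c(1, 50))
  w3 <- make_costs(cost_scheme("W3"), db, pan = pan)
  expect_equal(unname(w3["step2"]), 0)       # frac 1 -> cost 0
  expect_equal(unname(w3["dec1"]), 50)       # outside the pan-reactome
  sc <- c(step2 = 0.25, dec1 = 0.9)
  w4 <- make_costs(cost_scheme("W4"), db, scores = sc)
  expect_equal(unname(w4["step2"]), 0.75)    # 1 - p
  w4n <- make_costs(cost_scheme("W4neg"), db, scores = sc)
  expect_equal(unname(w4n[c("step2", "dec1")]), c(0.5, -0.8))  # 1 - 2p
  expect_error(make_costs(cost_scheme("W4"), db), "scores")
  expect_error(make_costs(cost_scheme("W3"), db), "pan_reactome")
})

test_that("flux balance growth matches the hand-solved chain LP", {
  toy <- generate_toy_network("parallel_paths")
  # uptake bound 10 with unit stoichiometry caps biomass at 10
  fb <- check_growth(toy$model, toy$medium)
  expect_equal(as.numeric(fb), 10)
  expect_identical(attr(fb, "status"), "optimal")
  # closed medium: no growth
  fb0 <- check_growth(toy$model, medium(c(A_e = 0)))
  expect_equal(as.numeric(fb0), 0)
  m <- toy$model; m$biomass_id <- NA_character_
  expect_error(check_growth(m), "biomass")
})

test_that("half-interval gap-filling picks the cheap route over the expensive one", {
  toy <- generate_toy_network("branched_cheap_expensive")
  res <- halfinterval_gapfill(toy$model, toy$db, toy$costs, toy$medium)
  expect_equal(res$added_reactions, "cheap")
  expect_gte(res$biomass_flux, 1e-6)
  expect_true(res$iterations > 1)
  # the result matches the exhaustively enumerated optimum
  expect_equal(sum(toy$costs[res$added_reactions]), toy$minimal_cost)
  # the completed model still grows when re-checked independently
  expect_gte(as.numeric(check_growth(res$model, toy$medium)), 1e-6)
  expect_true(all(res$model$reactions$origin[
    res$model$reactions$id %in% res$added_reactions] == "gapfill"))
})

test_that("already-growing models and hopeless models are handled", {
  toy <- generate_toy_network("parallel_paths")
  res <- halfinterval_gapfill(toy$model, toy$db, toy$costs, toy$medium)
  expect_length(res$added_reactions, 0)
  expect_equal(res$iterations, 1)
  # empty candidate set + non-growing model -> infeasibility with diagnosis
  broken <- generate_toy_network("branched_cheap_expensive")
  empty_db <- broken$db
  keep <- empty_db$reactions$id == "exp1"   # cannot reach biomass alone
  empty_db$reactions <- empty_db$reactions[keep, , drop = FALSE]
  empty_db$stoich <- empty_db$stoich[keep]
  expect_error(
    halfinterval_gapfill(broken$model, empty_db,
                         c(exp1 = 50), broken$medium),
    "infeasible")
})

test_that("gap-filled models always grow and costs match brute force on random toys", {
  worst <- 1
  for (k in 1:25) {
    inst <- random_gapfill_instance(seed = 900 + k, n_candidates = 8)
    res <- halfinterval_gapfill(inst$model, inst$db, inst$costs, inst$medium,
                                seed = k)
    expect_gte(as.numeric(check_growth(res$model, inst$medium)), 1e-6)
    bf <- bruteforce_gapfill(inst$model, inst$db, inst$costs, inst$medium)
    expect_true(bf$feasible)
    added_cost <- sum(inst$costs[res$added_reactions])
    if (bf$minimal_cost > 0)
      worst <- max(worst, added_cost / bf$minimal_cost)
  }
  expect_lte(worst, 1.05)
})

test_that("lowering the cost of a chosen reaction never drops it", {
  for (k in 1:10) {
    inst <- random_gapfill_instance(seed = 700 + k, n_candidates = 6)
    res <- halfinterval_gapfill(inst$model, inst$db, inst$costs, inst$medium)
    if (!length(res$added_reactions)) next
    pick <- res$added_reactions[1]
    costs2 <- inst$costs
    costs2[pick] <- costs2[pick] / 2
    res2 <- halfinterval_gapfill(inst$model, inst$db, costs2, inst$medium)
    expect_true(pick %in% res2$added_reactions)
  }
})

test_that("negative costs pull confident reactions in without unbounded flux", {
  toy <- generate_toy_network("branched_cheap_expensive")
  costs <- toy$costs
  costs["cheap"] <- -0.5      # as if p_NN = 0.75 under W4neg
  res <- halfinterval_gapfill(toy$model, toy$db, costs, toy$medium,
                              candidate_ub = 100)
  expect_true("cheap" %in% res$added_reactions)
  expect_lte(res$biomass_flux, 100)
  expect_gte(res$biomass_flux, 1e-6)
})

test_that("gap-fill reports serialise to JSON", {
  toy <- generate_toy_network("linear_chain")
  res <- halfinterval_gapfill(toy$model, toy$db, toy$costs, toy$medium)
  path <- tempfile(fileext = ".json")
  write_gapfill_report(res, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$added_reactions, res$added_reactions)
  expect_equal(rep$biomass_flux, res$biomass_flux)
})
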