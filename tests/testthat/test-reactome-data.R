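test_that("ModelSEED TSV databases parse with signed stoichiometry", {
  db <- suppressMessages(
    read_reaction_database(write_toy_modelseed_tsv(), "modelseed_tsv"))
  expect_s3_class(db, "reaction_db")
  expect_equal(nrow(db$reactions), 3)
  expect_equal(db$stoich[["rxn00001"]],
               c(cpd00001_c = -1, cpd00002_c = -2, cpd00003_c = 1))
  expect_false(db$reactions$reversible[db$reactions$id == "rxn00001"])
  expect_true(db$reactions$reversible[db$reactions$id == "rxn00002"])
  # '<' means backward-only: bounds [-1000, 0]
  expect_equal(db$reactions$lb[db$reactions$id == "rxn00003"], -1000)
  expect_equal(db$reactions$ub[db$reactions$id == "rxn00003"], 0)
})

test_that("degenerate and malformed database files are rejected", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("id\tstoichiometry\treversibility", empty)
  expect_error(read_reaction_database(empty, "modelseed_tsv"), "parse error")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tstoichiometry\treversibility",
               "rxn1\tnot-a-stoichiometry\t>"), bad)
  expect_error(read_reaction_database(bad, "modelseed_tsv"), "line 2")
  expect_error(read_reaction_database(tempfile(), "modelseed_tsv"),
               "no such file")
})

test_that("BiGG JSON databases parse and reversibility follows bounds", {
  db <- suppressMessages(
    read_reaction_database(write_toy_bigg_json(), "bigg_json"))
  expect_equal(sort(db$reactions$id), c("RXA", "RXB"))
  expect_false(db$reactions$reversible[db$reactions$id == "RXA"])
  expect_true(db$reactions$reversible[db$reactions$id == "RXB"])
  expect_equal(db$stoich[["RXA"]], c(A_c = -1, B_c = 1))
})

test_that("prepare_database splits reversibles and drops biomass", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tstoichiometry\treversibility",
               "rxnrev\t-1:A:c;1:B:c\t=",
               "rxnfwd\t-1:B:c;1:C:c\t>",
               "bio1\t-1:C:c\t>"), tsv)
  db <- suppressMessages(read_reaction_database(tsv, "modelseed_tsv"))
  prep <- prepare_database(db)
  # 1 reversible -> 2, 1 irreversible untouched, biomass gone
  expect_setequal(prep$reactions$id, c("rxnrev_f", "rxnrev_b", "rxnfwd"))
  expect_true(all(prep$reactions$lb == 0))
  # split pair stoichiometries sum to the zero vector
  expect_equal(prep$stoich[["rxnrev_f"]] + prep$stoich[["rxnrev_b"]],
               c(A_c = 0, B_c = 0))
  expect_equal(prep$reactions$base_id[prep$reactions$id == "rxnrev_f"],
               "rxnrev")
  # already-prepared databases pass through unchanged
  prep2 <- prepare_database(prep)
  expect_equal(prep2$reactions$id, prep$reactions$id)
  expect_equal(prep2$stoich, prep$stoich)
})

test_that("SBML and COBRA JSON loads of the same toy agree", {
  m_sbml <- read_model(write_toy_sbml(), "sbml")
  expect_s3_class(m_sbml, "metabolic_model")
  expect_equal(nrow(m_sbml$reactions), 4)
  expect_equal(m_sbml$biomass_id, "bio1")
  expect_equal(m_sbml$stoich[["CONV"]], c(A_c = -1, B_c = 1))
  # EX_A is reversible with no fbc bounds: defaults -1000..1000
  expect_equal(m_sbml$reactions$lb[m_sbml$reactions$id == "EX_A"], -1000)
  json <- tempfile(fileext = ".json")
  write_model_json(m_sbml, json)
  m_json <- read_model(json, "cobra_json")
  expect_setequal(m_json$reactions$id, m_sbml$reactions$id)
  expect_equal(m_json$biomass_id, "bio1")
  expect_equal(m_json$stoich[m_sbml$reactions$id],
               m_sbml$stoich[m_sbml$reactions$id])
})

test_that("models without a recognised biomass id load with a warning", {
  p <- write_toy_sbml(biomass_id = "some_sink")
  expect_warning(m <- read_model(p, "sbml"), "no biomass reaction")
  expect_true(is.na(m$biomass_id))
})

test_that("incidence matrices build with correct frequencies", {
  im <- build_incidence_matrix(
    list(g1 = c("A", "B"), g2 = "B", g3 = c("B", "C")),
    data.frame(genome_id = c("g1", "g2", "g3")))
  expect_equal(unname(im$pan$frequency[c("A", "B", "C")]), c(1/3, 1, 1/3))
  expect_equal(im$pan$n_genomes, 3)
  # a reaction in all genomes has frequency exactly 1
  expect_equal(unname(im$pan$frequency["B"]), 1)
  expect_error(build_incidence_matrix(list(g1 = "A", g1 = "B")), "duplicate")
  expect_error(build_incidence_matrix(list()), "at least one")
})

test_that("incidence TSV round trip is exact", {
  im <- generate_incidence(tiny_world_config())
  tsv <- tempfile(fileext = ".tsv"); meta <- tempfile(fileext = ".tsv")
  write_incidence_tsv(im, tsv, meta)
  back <- read_incidence_tsv(tsv, meta)
  expect_identical(back$presence, im$presence)
  expect_equal(back$pan$frequency, im$pan$frequency)
  expect_equal(back$genomes$genus, im$genomes$genus)
})

test_that("best-genome selection follows quality score then tie-breaks", {
  rec <- data.frame(genome_id = c("a", "b"), species = "s",
                    completeness = c(95, 99), contamination = c(1, 3),
                    coarse_consistency = c(90, 95))
  # scores 95 - 5 = 90 vs 99 - 15 = 84
  expect_equal(select_best_genomes(rec, "species")$genome_id, "a")
  rec2 <- data.frame(genome_id = c("a", "b"), species = "s",
                     completeness = c(95, 95), contamination = c(1, 1),
                     coarse_consistency = c(98, 91))
  expect_equal(select_best_genomes(rec2, "species")$genome_id, "a")
  rec3 <- rec2; rec3$coarse_consistency <- c(90, 90)
  expect_equal(select_best_genomes(rec3, "species")$genome_id, "a")  # lexicographic
  # single-member groups pass through; selection is idempotent
  sel <- select_best_genomes(toy_records(), "species")
  expect_equal(nrow(sel), length(unique(toy_records()$species)))
  expect_equal(select_best_genomes(sel, "species"), sel)
})

test_that("train/test split takes the best genome per genus exactly once", {
  rec <- toy_records()
  sets <- lapply(rec$genome_id, function(g) c("R1", sample(LETTERS, 5)))
  names(sets) <- rec$genome_id
  set.seed(1)
  im <- build_incidence_matrix(sets, rec)
  sp <- suppressMessages(split_train_test(im))
  expect_equal(nrow(sp$test$presence), 3)   # 3 genera
  expect_equal(nrow(sp$train$presence), 7)
  expect_length(intersect(rownames(sp$test$presence),
                          rownames(sp$train$presence)), 0)
  expect_setequal(c(rownames(sp$test$presence), rownames(sp$train$presence)),
                  rec$genome_id)
  # frequency of the full matrix = genome-count-weighted mean of the halves
  ntr <- nrow(sp$train$presence); nte <- nrow(sp$test$presence)
  recombined <- (sp$train$pan$frequency * ntr + sp$test$pan$frequency * nte) /
    (ntr + nte)
  expect_equal(recombined, im$pan$frequency)
})

test_that("single-genus matrices split into 1 test + rest train", {
  rec <- toy_records(); rec$genus <- "only"
  sets <- stats::setNames(lapply(rec$genome_id, function(g) "R1"), rec$genome_id)
  im <- build_incidence_matrix(sets, rec)
  sp <- suppressMessages(split_train_test(im))
  expect_equal(nrow(sp$test$presence), 1)
  expect_equal(nrow(sp$train$presence), 9)
})

test_that("exclude_partition drops labelled genomes and keeps column order", {
  im <- generate_incidence(tiny_world_config())
  ex <- exclude_partition(im, "clade1", column = "clade")
  expect_equal(nrow(ex$presence), 10)
  expect_identical(colnames(ex$presence), colnames(im$presence))
  expect_warning(same <- exclude_partition(im, "nosuch", column = "clade"),
                 "not present")
  expect_identical(same$presence, im$presence)
  expect_error(exclude_partition(im, c("clade1", "clade2"), column = "clade"),
               "every genome")
})
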