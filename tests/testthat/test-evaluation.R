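test_that("prediction confusion counts only masked positions", {
  # 4 masked positions, truth (1,1,0,0), scores (.9,.2,.8,.1)
  cc <- confusion_from_predictions(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0),
                                   c(0, 0, 0, 0))
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]),
               c(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  # perfect scores leave no errors
  cc2 <- confusion_from_predictions(c(1, 1, 0, 0) * 0.9 + 0.05,
                                    c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_equal(cc2$FP + cc2$FN, 0L)
  # fully masked input contributes nothing
  cc3 <- confusion_from_predictions(c(0.9, 0.1), c(1, 1), c(1, 1))
  expect_equal(cc3$TP + cc3$FP + cc3$FN + cc3$TN, 0L)
  # counts partition the masked positions
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 4L)
})

test_that("gap-fill confusion follows set arithmetic", {
  cc <- confusion_from_gapfill(original = c("A", "B", "C", "D"),
                               deleted = c("C", "D"),
                               added = c("C", "E"))
  expect_equal(unlist(cc[c("TP", "FN", "FP")]), c(TP = 1L, FN = 1L, FP = 1L))
  perfect <- confusion_from_gapfill(c("A", "B"), "B", "B")
  expect_equal(metrics(perfect)$recall, 1)
  expect_equal(perfect$FP, 0L)
  nothing <- confusion_from_gapfill(c("A", "B"), c("A", "B"), character(0))
  expect_equal(nothing$FN, 2L)
  expect_equal(nothing$TP, 0L)
  cc_tn <- confusion_from_gapfill(c("A", "B"), "B", "B",
                                  candidates = c("B", "X", "Y"))
  expect_equal(cc_tn$TN, 2L)
  expect_error(confusion_from_gapfill("A", "B", "B"), "subset")
  expect_error(confusion_from_gapfill(c("A", "B"), "B", c("A", "B")),
               "overlap")
})

test_that("metric formulas and zero conventions hold", {
  m <- metrics(list(TP = 3L, FP = 1L, FN = 2L, TN = 4L))
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 5)
  expect_equal(m$F1, 2 * (3/4) * (3/5) / (3/4 + 3/5))
  expect_equal(m$specificity, 4 / 5)
  expect_equal(m$balanced_accuracy, (4/5 + 3/5) / 2)
  expect_equal(metrics(list(TP = 0L, FP = 0L, FN = 0L, TN = 0L))$F1, 0)
  expect_equal(metrics(list(TP = 1L, FP = 0L, FN = 0L, TN = 1L))$balanced_accuracy, 1)
  expect_equal(metrics(list(TP = 3L, FP = 1L, FN = 2L, TN = 4L))$balanced_accuracy,
               0.7)
})

test_that("binned metrics pool counts, omit empty bins, and are consistent", {
  per <- data.frame(reaction = c("a", "b", "c"),
                    occurrence = c(10, 12, 160),
                    TP = c(5, 0, 50), FP = c(0, 0, 5),
                    FN = c(0, 5, 0), TN = c(0, 0, 0))
  fb <- frequency_binned_metrics(per, bin_width = 50)
  expect_equal(fb$bin, c(0, 150))
  # two reactions with recall 1 and 0 and equal deletion counts pool to 0.5
  expect_equal(fb$recall[fb$bin == 0], 0.5)
  expect_equal(fb$n_reactions, c(2, 1))
  # one bin swallows everything when wider than the genome count
  fb1 <- frequency_binned_metrics(per, bin_width = 1000)
  expect_equal(nrow(fb1), 1)
  # pooling consistency: global recall equals recall of summed counts
  expect_equal(fb1$recall, sum(per$TP) / sum(per$TP + per$FN))
})

test_that("nearest-neighbour Jaccard distance behaves as a metric", {
  M <- rbind(g1 = c(1, 1, 0), g2 = c(0, 1, 1))
  colnames(M) <- c("A", "B", "C")
  expect_equal(nearest_neighbor_distance(c(1, 1, 0), M), 0)   # identical row
  expect_equal(nearest_neighbor_distance(c(1, 0, 0), rbind(c(0, 1, 1))), 1)
  expect_equal(nearest_neighbor_distance(c(1, 1, 0), rbind(c(0, 1, 1))),
               1 - 1/3)
  expect_error(nearest_neighbor_distance(c(0, 0, 0), M), "no present")
  # identity, symmetry, boundedness on random binary vectors
  set.seed(31)
  for (k in 1:20) {
    a <- rbinom(12, 1, 0.5); b <- rbinom(12, 1, 0.5)
    if (sum(a) == 0 || sum(b) == 0) next
    dab <- nearest_neighbor_distance(a, rbind(b))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(dab, nearest_neighbor_distance(b, rbind(a)))
    expect_equal(nearest_neighbor_distance(a, rbind(a)), 0)
  }
})

test_that("essentiality screens distinguish chains from parallel routes", {
  chain <- generate_toy_network("linear_chain")
  # complete the chain first
  filled <- halfinterval_gapfill(chain$model, chain$db, chain$costs,
                                 chain$medium)$model
  ess <- essential_reactions(filled, chain$medium)
  interior <- setdiff(filled$reactions$id, "EX_A")
  # single path: every interior conversion is essential, and so is biomass
  expect_true(all(interior %in% ess))
  expect_true("bio1" %in% ess)
  par <- generate_toy_network("parallel_paths")
  ess_par <- essential_reactions(par$model, par$medium)
  expect_false("p1" %in% ess_par)
  expect_false("p2" %in% ess_par)
  expect_true("bio1" %in% ess_par)
  closed <- medium(c(A_e = 0))
  expect_error(essential_reactions(par$model, closed), "does not grow")
})

test_that("carbon profiles call growth per source and score against observations", {
  toy <- generate_toy_network("parallel_paths")
  base <- medium(c(A_e = 10))
  expect_warning(
    prof <- carbon_profile(toy$model, base, carbon_sources = c("A_e", "Z_e"),
                           default_carbon = "A_e",
                           observed = c(A_e = 1, Z_e = 0)),
    "no exchange reaction")
  expect_equal(unname(prof$growth), c(1L, 0L))
  expect_true(prof$valid)
  expect_equal(prof$metrics$balanced_accuracy, 1)
})
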