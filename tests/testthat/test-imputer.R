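test_that("masked loss reproduces hand-computed values", {
  # present, masked-out position: (1 - b0) * -log(O)
  expect_equal(masked_loss(0.5, 1, 0, b0 = 0.3), 0.7 * -log(0.5),
               tolerance = 1e-6)
  expect_equal(masked_loss(0.5, 1, 0, b0 = 0.3), 0.4852030, tolerance = 1e-6)
  # absent position: b0 * -log(1 - O)
  expect_equal(masked_loss(0.5, 0, 0, b0 = 0.3), 0.2079442, tolerance = 1e-6)
  # input positions contribute exactly zero, whatever the score
  expect_equal(masked_loss(c(0.9, 0.01), c(1, 1), c(1, 1), 0.3), 0)
  expect_error(masked_loss(0.5, c(1, 0), 0, 0.3), "same length")
  expect_error(masked_loss(0.5, 0, 1, 0.3), "I <= T")
})

test_that("loss masking is invariant to perturbations at input positions", {
  set.seed(9)
  for (k in 1:20) {
    n <- 30
    truth <- rbinom(n, 1, 0.5)
    input <- truth * rbinom(n, 1, 0.6)
    O <- runif(n)
    base <- masked_loss(O, truth, input, 0.3)
    O2 <- O
    O2[input == 1] <- runif(sum(input == 1))
    expect_equal(masked_loss(O2, truth, input, 0.3), base)
  }
})

test_that("class weight limits silence one class at a time", {
  O <- c(0.3, 0.8); truth <- c(1, 0); input <- c(0, 0)
  # b0 = 0: absent positions contribute nothing
  expect_equal(masked_loss(O, truth, input, b0 = 0),
               mean(c(-log(0.3), 0)))
  # b0 = 1: present positions contribute nothing
  expect_equal(masked_loss(O, truth, input, b0 = 1),
               mean(c(0, -log(1 - 0.8))))
  # exact 0/1 scores are clipped, never NaN
  expect_true(is.finite(masked_loss(c(0, 1), truth, input, 0.3)))
})

test_that("network topology and parameter counts follow the config", {
  net <- build_network(network_config(io_size = 4, hidden_layers = 1,
                                      hidden_nodes = 2))
  expect_equal(n_parameters(net), 4 * 2 + 2 + 2 * 4 + 4)  # 22
  expect_equal(dim(net$W[[1]]), c(4, 2))
  expect_equal(dim(net$W[[2]]), c(2, 4))
  big <- build_network(network_config(io_size = 2453))
  expect_equal(vapply(big$W, dim, c(1L, 1L)),
               matrix(c(2453, 256, 256, 256, 256, 256, 256, 2453), 2))
  # degenerate single sigmoid unit
  tiny <- build_network(network_config(io_size = 1, hidden_layers = 0))
  expect_equal(n_parameters(tiny), 2)
})

test_that("training learns planted co-occurrence and is reproducible", {
  # reactions A,B always co-occur; C,D are independent noise
  set.seed(4)
  n <- 300
  ab <- rbinom(n, 1, 0.5)
  presence <- cbind(A = ab, B = ab,
                    C = rbinom(n, 1, 0.5), D = rbinom(n, 1, 0.5),
                    E = 1L)
  rownames(presence) <- sprintf("g%03d", 1:n)
  samples <- lapply(1:n, function(i) {
    truth <- presence[i, ]
    input <- truth
    input["B"] <- 0L  # B always masked out
    structure(list(genome_id = rownames(presence)[i], replicate = 1L,
                   seed = i, input = input, truth = truth,
                   deleted = which(truth == 1 & input == 0)),
              class = "corrupted_sample")
  })
  cfg <- network_config(io_size = 5, hidden_layers = 1, hidden_nodes = 8,
                        dropout = 0, epochs = 40)
  ti <- train_imputer(samples, cfg, seed = 2, pan = colnames(presence))
  # validation loss decreases from initialisation to the final epoch
  expect_lt(ti$history[length(ti$history)], ti$history[1])
  # with A present, masked B scores above 0.5; with A absent, below
  expect_gt(predict(ti, c(1, 0, 0, 0, 1))["B"], 0.5)
  expect_lt(predict(ti, c(0, 0, 1, 0, 1))["B"], 0.5)
  ti2 <- train_imputer(samples, cfg, seed = 2, pan = colnames(presence))
  expect_identical(ti$history, ti2$history)
  expect_identical(ti$W, ti2$W)
  # zero epochs returns the untouched initialisation
  ti0 <- train_imputer(samples, network_config(io_size = 5, hidden_layers = 1,
                                               hidden_nodes = 8, epochs = 0),
                       seed = 2)
  net0 <- build_network(network_config(io_size = 5, hidden_layers = 1,
                                       hidden_nodes = 8, epochs = 0), seed = 2)
  expect_identical(ti0$W, net0$W)
})

test_that("inference is deterministic, bounded and width-checked", {
  cfg <- network_config(io_size = 6, hidden_layers = 2, hidden_nodes = 4)
  net <- build_network(cfg, seed = 1)
  ti <- structure(c(net, list(pan = letters[1:6], history = NA_real_)),
                  class = c("trained_imputer", "imputer_network"))
  x <- rep(0, 6)
  s1 <- predict(ti, x); s2 <- predict(ti, x)
  expect_identical(s1, s2)          # dropout off at inference
  expect_true(all(s1 > 0 & s1 < 1))  # prior-like scores for all-zero input
  expect_named(s1, letters[1:6])
  expect_error(predict(ti, rep(0, 5)), "io_size")
})

test_that("imputer archives round-trip through JSON", {
  cfg <- network_config(io_size = 5, hidden_layers = 1, hidden_nodes = 3)
  net <- build_network(cfg, seed = 8)
  ti <- structure(c(net, list(pan = letters[1:5], history = c(1, 0.5),
                              fingerprint = list(seed = 8))),
                  class = c("trained_imputer", "imputer_network"))
  path <- tempfile(fileext = ".json")
  save_imputer(ti, path)
  back <- load_imputer(path)
  expect_equal(back$W, ti$W)
  expect_equal(back$b, ti$b)
  expect_equal(back$config$io_size, 5)
  expect_identical(predict(back, c(1, 0, 1, 0, 0)),
                   predict(ti, c(1, 0, 1, 0, 0)))
})
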