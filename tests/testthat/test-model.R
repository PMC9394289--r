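make_toy <- function(n = 24, N = 4, F = 3, seed = 42) {
  set.seed(seed)
  list(values = array(rnorm(n * N * F), c(n, N, F)),
       labels = rep(c(0L, 1L), n / 2),
       graph = random_graph(N, seed))
}

test_that("softmax output rows sum to one and zero weights give 0.5/0.5", {
  toy <- make_toy()
  cfg <- model_config(K = 2, hidden_width = 6, dropout = 0, seed = 3)
  set.seed(3)
  params <- init_params(cfg, 4, 3)
  probs <- crgcn_forward(toy$values, toy$graph, params, cfg)
  expect_equal(rowSums(probs), rep(1, 24), tolerance = 1e-6)

  zero <- params
  zero$theta <- lapply(zero$theta, function(t) t * 0)
  zero$W <- zero$W * 0
  probs0 <- crgcn_forward(toy$values, toy$graph, zero, cfg)
  expect_equal(as.vector(probs0), rep(0.5, 48))
})

test_that("a single-node K = 1 model reduces to a dense network", {
  set.seed(9)
  n <- 10; F <- 3; h <- 4
  vals <- array(rnorm(n * F), c(n, 1, F))
  g <- laplacian(matrix(1, 1, 1))
  cfg <- model_config(K = 1, hidden_width = h, dropout = 0, seed = 2)
  set.seed(2)
  params <- init_params(cfg, 1, F)
  probs <- crgcn_forward(vals, g, params, cfg)
  # oracle: direct matrix arithmetic on the single node's features
  x <- matrix(vals, n, F)
  hid <- pmax(x %*% params$theta[[1]], 0)
  logits <- hid %*% params$W + rep(params$b, each = n)
  ref <- exp(logits) / rowSums(exp(logits))
  expect_equal(probs, ref, tolerance = 1e-8)
})

test_that("loss matches closed forms and the penalty is strictly positive", {
  params <- list(theta = list(matrix(0.5, 2, 2)), W = matrix(0.5, 4, 2),
                 b = c(0, 0))
  perfect <- rbind(c(1, 0), c(0, 1))
  labs <- c(0L, 1L)
  expect_equal(crgcn_loss(perfect, labs, params, alpha = 0), 0)
  uniform <- matrix(0.5, 2, 2)
  expect_equal(crgcn_loss(uniform, labs, params, alpha = 0), log(2))
  expect_gt(crgcn_loss(uniform, labs, params, alpha = 1e-3), log(2))
  # certainty in the wrong class is clamped, not infinite
  wrong <- rbind(c(0, 1), c(1, 0))
  expect_true(is.finite(crgcn_loss(wrong, labs, params, alpha = 0)))
})

test_that("analytic gradients match finite differences", {
  toy <- make_toy(n = 16, N = 4, F = 3, seed = 11)
  cfg <- model_config(K = 3, hidden_width = 5, dropout = 0, alpha = 1e-3,
                      seed = 11)
  set.seed(11)
  params <- init_params(cfg, 4, 3)
  terms <- crgcn:::precompute_cheb(toy$graph, toy$values, cfg$K)
  fwd <- crgcn:::model_forward(terms, 1:16, params, cfg, 4)
  grad <- crgcn:::model_backward(fwd, terms, toy$labels, params, cfg)
  lossfn <- function(p)
    crgcn_loss(crgcn:::model_forward(terms, 1:16, p, cfg, 4)$probs,
               toy$labels, p, cfg$alpha)
  eps <- 1e-6
  check <- function(get, set, g) {
    for (ii in sample(length(get(params)), min(4, length(get(params))))) {
      p1 <- set(params, ii, eps); p2 <- set(params, ii, -eps)
      num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      expect_lt(abs(num - get(g)[ii]) / max(abs(num), 1e-6), 1e-4)
    }
  }
  for (k in 1:cfg$K)
    check(function(p) p$theta[[k]],
          function(p, i, e) { p$theta[[k]][i] <- p$theta[[k]][i] + e; p },
          grad)
  check(function(p) p$W,
        function(p, i, e) { p$W[i] <- p$W[i] + e; p }, grad)
  check(function(p) p$b,
        function(p, i, e) { p$b[i] <- p$b[i] + e; p }, grad)
})

test_that("precomputed Chebyshev terms equal per-segment recomputation", {
  toy <- make_toy(n = 6, N = 5, F = 2, seed = 21)
  K <- 3
  big <- crgcn:::precompute_cheb(toy$graph, toy$values, K)
  for (s in 1:6) {
    single <- chebyshev_terms(toy$graph, toy$values[s, , ], K)
    rows <- (s - 1) * 5 + 1:5
    for (k in 1:K)
      expect_identical(big[[k]][rows, ], single[[k]])
  }
})

test_that("training fits linearly separable synthetic features", {
  set.seed(70)
  n <- 200; N <- 6; F <- 3
  labels <- rep(c(0L, 1L), n / 2)
  vals <- array(rnorm(n * N * F, sd = 0.5), c(n, N, F))
  vals[, 2, 1] <- vals[, 2, 1] + 2 * labels          # planted separation
  g <- random_graph(N, 70)
  cfg <- model_config(hidden_width = 8, max_epochs = 200, batch_size = 64,
                      seed = 5)
  model <- train_crgcn(vals, labels, g, cfg)
  expect_gte(tail(model$history$train_accuracy, 1), 0.95)
  expect_lte(nrow(model$history), 200)
  # loss trend nonincreasing on the 10-epoch moving average
  ma <- stats::filter(model$history$loss, rep(0.1, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(tail(ma, 1), ma[1])
})

test_that("the stop rule halts immediately for a huge threshold and training is seeded", {
  toy <- make_toy(n = 32, seed = 31)
  cfg <- model_config(hidden_width = 4, stop_threshold = 1e6,
                      max_epochs = 100, seed = 8)
  model <- train_crgcn(toy$values, toy$labels, toy$graph, cfg)
  expect_equal(nrow(model$history), 1)

  cfg2 <- model_config(hidden_width = 4, max_epochs = 10, seed = 8)
  m1 <- train_crgcn(toy$values, toy$labels, toy$graph, cfg2)
  m2 <- train_crgcn(toy$values, toy$labels, toy$graph, cfg2)
  expect_lt(abs(tail(m1$history$loss, 1) - tail(m2$history$loss, 1)), 1e-10)
  expect_identical(m1$params, m2$params)
})

test_that("degenerate training inputs are rejected", {
  toy <- make_toy(n = 12, seed = 41)
  expect_error(train_crgcn(toy$values, rep(0L, 12), toy$graph,
                           model_config()),
               "single class")
  expect_error(train_crgcn(toy$values, toy$labels[1:5], toy$graph,
                           model_config()),
               "labels")
  expect_error(crgcn_forward(toy$values, random_graph(7, 1),
                             init_params(model_config(), 4, 3),
                             model_config()),
               "nodes")
})

test_that("checkpoints round-trip the fitted model", {
  toy <- make_toy(n = 16, seed = 51)
  cfg <- model_config(hidden_width = 4, max_epochs = 3, seed = 1)
  model <- train_crgcn(toy$values, toy$labels, toy$graph, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(model, path)
  back <- read_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(predict(back, toy$values), predict(model, toy$values))
})
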