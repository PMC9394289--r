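test_that("distance adjacency follows the capped inverse-square law", {
  m <- montage(c("a", "b", "c"),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)))
  delta <- 1                                  # d_ab^2 = 1 = delta -> capped
  g <- distance_adjacency(m, delta)
  expect_equal(g$adjacency["a", "b"], 1)      # min cap boundary
  expect_equal(g$adjacency["a", "c"], 0.25)   # d^2 = 4 delta
  expect_equal(g$adjacency, t(g$adjacency))
  expect_equal(diag(g$adjacency), c(a = 1, b = 1, c = 1))
  g0 <- distance_adjacency(m, delta, diag_value = 0)
  expect_true(all(diag(g0$adjacency) == 0))
  expect_error(montage(c("a", "b"), rbind(c(0, 0, 0), c(0, 0, 0))),
               "coincident")
})

test_that("delta calibration reaches the smallest achievable fraction >= target", {
  m <- default_montage()
  n_off <- 32 * 31
  a1 <- distance_adjacency(m, calibrate_delta(m, 1.0))$adjacency
  expect_true(all(a1[row(a1) != col(a1)] > 0.1))        # saturation

  # vanishing target: at most the single nearest pair (one step above zero)
  a0 <- distance_adjacency(m, calibrate_delta(m, 1e-9))$adjacency
  expect_lte(sum(a0[row(a0) != col(a0)] > 0.1), 2)

  # oracle: sorted off-diagonal squared distances give the exact step
  d2 <- sort(electrode_dist2(m)[upper.tri(matrix(0, 32, 32))])
  a2 <- distance_adjacency(m, calibrate_delta(m, 0.2))$adjacency
  frac <- mean(a2[row(a2) != col(a2)] > 0.1)
  expect_gte(frac, 0.2)
  expect_lte(frac, 0.2 + 2 / n_off + 1e-12)             # one edge-count step
})

test_that("retained fraction is nondecreasing in delta", {
  m <- default_montage()
  deltas <- seq(0.005, 0.3, length.out = 20)
  fracs <- vapply(deltas, function(d) {
    a <- distance_adjacency(m, d)$adjacency
    mean(a[row(a) != col(a)] > 0.1)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("connectivity adjacency keeps only correlations above lambda, signed", {
  set.seed(30)
  x <- rnorm(1000)
  obs <- cbind(x, x, -x, rnorm(1000), rnorm(1000))
  g <- connectivity_adjacency(obs, lambda = 0.98)
  b <- g$adjacency
  expect_equal(b[1, 2], 1)
  expect_equal(b[1, 3], -1)                    # anticorrelation retained
  expect_equal(b[4, 5], 0)                     # independent noise dropped
  expect_equal(b[1, 4], 0)
  expect_equal(b, t(b))
  off <- b[row(b) != col(b)]
  expect_true(all(off == 0 | abs(off) > 0.98))
  expect_error(connectivity_adjacency(cbind(x, rep(1, 1000))),
               "zero-variance")
  expect_error(connectivity_adjacency(obs[1, , drop = FALSE]),
               ">= 2 observations")
})

test_that("retained connectivity edges are nonincreasing in lambda", {
  set.seed(31)
  obs <- matrix(rnorm(50 * 8), 50, 8)
  counts <- vapply(c(0, 0.2, 0.5, 0.8, 0.98), function(l) {
    b <- connectivity_adjacency(obs, lambda = l)$adjacency
    sum(b[row(b) != col(b)] != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fusion is an entrywise sum, commutative, edge-preserving", {
  set.seed(32)
  m <- subset_montage(default_montage(), 1:6)
  a <- distance_adjacency(m, 0.05)
  obs <- matrix(rnorm(200 * 6), 200, 6)
  obs[, 2] <- obs[, 1] + 0.01 * rnorm(200)
  b <- connectivity_adjacency(obs, lambda = 0.98)
  fused <- fuse_adjacency(a, b)
  expect_equal(fused$adjacency, a$adjacency + b$adjacency)
  expect_equal(fused$provenance, "fused")
  expect_equal(unname(fuse_adjacency(b, a)$adjacency),
               unname(fused$adjacency))
  # no retained edge from either parent is lost
  expect_true(all(fused$adjacency[a$adjacency != 0 & b$adjacency == 0] != 0))
  expect_equal(fused$adjacency[1, 2], a$adjacency[1, 2] + b$adjacency[1, 2])
  # additive identity
  zero <- crgcn:::new_channel_graph(matrix(0, 6, 6), "connectivity")
  az <- fuse_adjacency(a, zero)
  expect_equal(unname(az$adjacency), unname(a$adjacency))
  small <- crgcn:::new_channel_graph(diag(3), "distance")
  expect_error(fuse_adjacency(a, small), "dimension mismatch")
})

test_that("the normalized Laplacian matches hand computation", {
  # two nodes, single edge weight w, zero diagonal: normalization cancels w
  for (w in c(0.3, 1, 2.5)) {
    g <- laplacian(matrix(c(0, w, w, 0), 2))
    expect_equal(g$laplacian, matrix(c(1, -1, -1, 1), 2))
  }
  # self-loops only: D = C, fully normalized away
  gl <- laplacian(diag(c(1, 2, 3)))
  expect_equal(gl$laplacian, matrix(0, 3, 3))
})

test_that("Laplacian eigenvalues of nonnegative graphs lie in [0, 2]", {
  for (s in 1:10) {
    g <- laplacian(random_adjacency(7, s))
    ev <- eigen(g$laplacian, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
    expect_lte(max(ev), 2 + 1e-12)
    # shifted scaling maps the spectrum into the Chebyshev domain
    evs <- eigen(g$scaled_laplacian, symmetric = TRUE,
                 only.values = TRUE)$values
    expect_gte(min(evs), -1 - 1e-12)
    expect_lte(max(evs), 1e-12)
  }
  expect_error(laplacian(matrix(0, 3, 3)), "degree")
})

test_that("Chebyshev recursion: K = 1 returns the signal itself", {
  g <- random_graph(5, 1)
  x <- matrix(rnorm(10), 5, 2)
  expect_identical(chebyshev_terms(g, x, 1)[[1]], x)
  expect_error(chebyshev_terms(g, x, 0), "K")
})

test_that("scalar Chebyshev terms match the trigonometric closed form", {
  # 1x1 graph: terms are the classical polynomials T_k(x) = cos(k acos x)
  for (x0 in c(-1, -0.5, 0, 0.25, 1)) {
    lt <- matrix(x0, 1, 1)
    terms <- chebyshev_terms(lt, matrix(1, 1, 1), 11)
    tk <- vapply(terms, function(t) t[1, 1], numeric(1))
    expect_equal(tk, cos((0:10) * acos(x0)), tolerance = 1e-10)
  }
  # scalar example: Lt = 0.5, terms 1, 0.5, -0.5
  terms <- chebyshev_terms(matrix(0.5, 1, 1), matrix(1, 1, 1), 3)
  expect_equal(unlist(terms), c(1, 0.5, -0.5))
})

test_that("Chebyshev filtering equals direct eigendecomposition filtering", {
  set.seed(60)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    K <- sample(1:6, 1)
    g <- random_graph(n, 600 + i)
    theta <- rnorm(K)
    x <- rnorm(n)
    terms <- chebyshev_terms(g, x, K)
    y_cheb <- Reduce(`+`, Map(function(th, t) th * t, theta, terms))
    y_direct <- eigenfilter(g, theta, x)
    expect_lt(max(abs(y_cheb - y_direct)), 1e-8)
  }
})

test_that("edge lists round-trip the adjacency support", {
  g <- distance_adjacency(subset_montage(default_montage(), 1:5), 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(g, path)
  el <- read.delim(path)
  expect_equal(nrow(el), sum(g$adjacency[upper.tri(g$adjacency)] != 0))
  expect_true(all(el$weight > 0))
})
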