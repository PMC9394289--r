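# shared fixture builders (everything generated in code at test time)

# short synthetic session: 12 s stimulus keeps unit tests fast while
# preserving the 3 s baseline and integer replication structure
quick_config <- function(n_trials = 4, seed = 1, ...) {
  synth_config(n_subjects = 1, n_trials_per_subject = n_trials,
               stimulus_seconds = 12, seed = seed, ...)
}

quick_trialset <- function(n_trials = 4, seed = 1, ...) {
  labels <- rep(c(0L, 1L), length.out = n_trials)
  generate_trialset(quick_config(n_trials, seed, ...), labels)
}

# random connected symmetric adjacency with positive weights
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0.05, 1), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

random_graph <- function(n, seed, scaling = "shifted") {
  laplacian(crgcn:::new_channel_graph(random_adjacency(n, seed), "fused"),
            scaling = scaling)
}

# direct spectral filtering through the eigendecomposition: the
# independent oracle for the Chebyshev recursion path
eigenfilter <- function(graph, theta, x) {
  ev <- eigen(graph$laplacian, symmetric = TRUE)
  lam_scaled <- ev$values / graph$lambda_max - 1
  g_lam <- vapply(lam_scaled, function(l) {
    l <- min(max(l, -1), 1)
    sum(theta * cos((seq_along(theta) - 1) * acos(l)))
  }, numeric(1))
  ev$vectors %*% (g_lam * crossprod(ev$vectors, x))
}
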