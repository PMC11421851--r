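# Shared fixtures, built lazily and cached for the duration of a test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small stabilized E/I network used across modules (fast to build).
small_isn <- function() fixture("small_isn", function() {
  generate_isn(N = 60, seed = 7, exc_scale = 5, max_iter = 3000)
})

# Same network, prepared with readout and baseline.
small_plant <- function() fixture("small_plant", function() {
  prepare_plant(small_isn(), seed = 7)
})

# Random stable matrix (abscissa pushed below a margin by diagonal shift).
random_stable <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n) / sqrt(n)
  A - (max(Re(eigen(A, only.values = TRUE)$values)) + 0.3) * diag(n)
}

# Finite-difference gradient of f: R^n -> R at x.
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# Finite-difference Jacobian of f: R^n -> R^m at x.
fd_jac <- function(f, x, eps = 1e-6) {
  cols <- lapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  })
  do.call(cbind, cols)
}
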