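test_that("latent_model validates shapes, stochasticity and hardness", {
  g <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  l <- cbind(c(0.5, 0.5, 0), c(0, 0, 1))
  m <- latent_model(g, l)
  expect_true(m$hard)
  expect_equal(m$K, 2L)
  expect_equal(m$n, 3L)
  expect_error(latent_model(g * 0.9, l), class = "lmm_input_error")
  expect_error(latent_model(g, l[1:2, ]), class = "lmm_input_error")
  expect_error(latent_model(g, -l), class = "lmm_input_error")
})

test_that("reduced operator is the K x K product, column-stochastic", {
  # identity aggregation: gamma = I, lam = Lambda gives P = Lambda
  L <- random_stochastic(4, 1)
  m <- latent_model(diag(4), L)
  expect_equal(reduced_operator(m), L, tolerance = 1e-14)

  # K = 1 gives the stochastic scalar
  m1 <- latent_model(matrix(1, 1, 3), matrix(c(0.2, 0.3, 0.5), 3, 1))
  expect_equal(reduced_operator(m1), matrix(1, 1, 1))

  # hand-computed 2x3 * 3x2 product
  g <- rbind(c(1, 1, 0), c(0, 0, 1))
  l <- cbind(c(0.5, 0.5, 0), c(0, 0, 1))
  expect_equal(reduced_operator(latent_model(g, l)), diag(2))
})

test_that("propagate applies the factorized master equation", {
  m <- random_latent_model(12, 3, seed = 2)
  full <- m$lam %*% m$gamma
  # unit mass on state j returns column j of the induced operator
  for (j in c(1, 5, 12)) {
    e <- numeric(12); e[j] <- 1
    expect_equal(propagate(m, e), as.numeric(full[, j]), tolerance = 1e-14)
  }
  set.seed(3)
  pi0 <- stats::runif(12); pi0 <- pi0 / sum(pi0)
  expect_lt(abs(sum(propagate(m, pi0)) - 1), 1e-12)
  expect_error(propagate(m, pi0[-1]), class = "lmm_input_error")
  expect_error(propagate(m, pi0 * 2), class = "lmm_input_error")
})

test_that("lifted invariant measure equals full-space power iteration", {
  # the reduced-eigenproblem route must agree with iterating the full
  # n x n product lam %*% gamma from the uniform vector
  set.seed(10)
  for (rep in 1:12) {
    n <- sample(10:100, 1)
    K <- sample(2:10, 1)
    m <- random_latent_model(n, K, seed = 1000 + rep)
    res <- latent_invariant_measure(m)
    full <- m$lam %*% m$gamma
    v <- rep(1 / n, n)
    for (i in 1:20000) {
      v2 <- as.numeric(full %*% v)
      if (sum(abs(v2 - v)) < 1e-15) { v <- v2; break }
      v <- v2
    }
    v <- v / sum(v)
    expect_lt(sum(abs(res$measure - v)), 1e-10)
    expect_prob_vector(res$measure)
    # fixed point of the factorized propagation
    expect_lt(sum(abs(propagate(m, res$measure) - res$measure)), 1e-10)
    # reduced measure is stationary for the reduced operator
    P <- reduced_operator(m)
    expect_lt(sum(abs(as.numeric(P %*% res$reduced) - res$reduced)), 1e-12)
  }
})

test_that("a reducible reduced operator is refused naming latent blocks", {
  g <- rbind(c(1, 1, 0), c(0, 0, 1))
  l <- cbind(c(0.5, 0.5, 0), c(0, 0, 1))
  m <- latent_model(g, l)     # P = I: two disconnected latent states
  err <- tryCatch(latent_invariant_measure(m),
                  lmm_numerical_error = function(e) e)
  expect_s3_class(err, "lmm_numerical_error")
  expect_match(conditionMessage(err), "reducible")
})

test_that("spectrum lifts eigenvectors with small eigen-residual", {
  for (rep in 1:6) {
    n <- sample(20:200, 1)
    K <- sample(3:8, 1)
    m <- random_latent_model(n, K, seed = 500 + rep)
    # random models routinely have complex subdominant pairs; the warning
    # about skipped realification is expected here
    sp <- suppressWarnings(spectrum(m, n_components = K))
    expect_equal(Re(sp$values[1]), 1, tolerance = 1e-9)
    full <- m$lam %*% m$gamma
    for (comp in seq_len(K)) {
      if (Mod(sp$values[comp]) < 1e-8) next
      v <- sp$vectors[, comp]
      resid <- max(Mod(full %*% v - sp$values[comp] * v))
      expect_lt(resid, 1e-8)
    }
    # sign convention: largest-modulus entry is positive real
    v2 <- sp$vectors[, 2]
    top <- v2[which.max(Mod(v2))]
    expect_gt(Re(top), 0)
    expect_lt(abs(Im(top)), 1e-9)
  }
})

test_that("two weakly coupled blocks give second eigenvalue 1 - e1 - e2", {
  e1 <- 0.03; e2 <- 0.05
  gamma <- rbind(c(1, 1, 1, 0, 0), c(0, 0, 1 - 1, 1, 1))
  gamma[2, 3] <- 0   # states 1:3 -> latent 1, states 4:5 -> latent 2
  lam <- cbind(c(rep((1 - e1) / 3, 3), rep(e1 / 2, 2)),
               c(rep(e2 / 3, 3), rep((1 - e2) / 2, 2)))
  m <- latent_model(gamma, lam)
  sp <- spectrum(m, 2)
  expect_equal(Re(sp$values[2]), 1 - e1 - e2, tolerance = 1e-12)
  # psi2 changes sign exactly between the two blocks
  expect_true(all(sign(sp$psi2[1:3]) == sign(sp$psi2[1])))
  expect_true(all(sign(sp$psi2[4:5]) != sign(sp$psi2[1])))
})

test_that("spectrum enforces the component bound", {
  m1 <- latent_model(matrix(1, 1, 3), matrix(c(0.2, 0.3, 0.5), 3, 1))
  expect_error(spectrum(m1, 2), class = "lmm_input_error")
  expect_equal(spectrum(m1, 1)$values, 1)
})
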