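test_that("the origin is a fixed point of the Lorenz field", {
  xyz <- simulate_lorenz(200, burn_in = 0, init = c(0, 0, 0))
  expect_true(all(xyz == 0))
})

test_that("the chaotic regime stays on the bounded attractor", {
  xyz <- simulate_lorenz(100000, burn_in = 0, init = c(1, 1, 1))
  expect_true(all(is.finite(xyz)))
  expect_lt(max(abs(xyz[, "z"])), 60)
  expect_lt(max(abs(xyz[, "x"])), 25)
})

test_that("step-halving confirms fourth-order accuracy on [0, 1]", {
  at_t1 <- function(dt) {
    n <- round(1 / dt)
    simulate_lorenz(n, dt = dt, burn_in = 0, init = c(1, 1, 1))[n, ]
  }
  x1 <- at_t1(2e-3)
  x2 <- at_t1(1e-3)
  x3 <- at_t1(5e-4)
  # halving dt changes the endpoint by < 1e-5 per coordinate
  expect_lt(max(abs(x2 - x1)), 1e-5)
  # error ratio between successive halvings ~ 2^4
  ratio <- max(abs(x1 - x3)) / max(abs(x2 - x3))
  expect_gt(ratio, 8)
})

test_that("sample_markov_chain realizes deterministic operators exactly", {
  expect_equal(sample_markov_chain(diag(4), 10, start = 3, seed = 1)$labels,
               rep(3L, 10))
  swap <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(sample_markov_chain(swap, 6, start = 0, seed = 1)$labels,
               c(0L, 1L, 0L, 1L, 0L, 1L))
})

test_that("chain samples reproduce the stationary frequencies", {
  L <- random_stochastic(3, seed = 77)
  mu <- as.numeric(invariant_measure_full(transfer_operator(L)))
  tr <- sample_markov_chain(L, 1e5, seed = 8)
  freq <- tabulate(tr$labels + 1L, 3) / length(tr$labels)
  # 3-sigma multinomial bands around the true stationary vector
  expect_true(all(abs(freq - mu) < 3 * sqrt(mu * (1 - mu) / 1e5) + 1e-3))
})

test_that("latent chain samples reproduce the induced operator", {
  m <- random_latent_model(5, 2, seed = 30)
  tr <- sample_latent_chain(m, 2e5, seed = 31)
  cts <- count_transitions(tr)
  emp <- as.matrix(empirical_estimator(cts)$Lambda)
  full <- m$lam %*% m$gamma
  src_tot <- as.numeric(Matrix::colSums(cts$N))
  # entrywise 4-sigma binomial bands given the per-source sample sizes
  band <- 4 * sqrt(full * (1 - full) / rep(pmax(src_tot, 1), each = 5))
  expect_true(all(abs(emp - full) <= band + 1e-6))
})

test_that("samplers are bit-identical under a fixed seed and differ across seeds", {
  L <- random_stochastic(6, seed = 50)
  a <- sample_markov_chain(L, 3000, seed = 9)
  b <- sample_markov_chain(L, 3000, seed = 9)
  c <- sample_markov_chain(L, 3000, seed = 10)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
  m <- random_latent_model(6, 2, seed = 51)
  expect_identical(sample_latent_chain(m, 1000, seed = 1)$labels,
                   sample_latent_chain(m, 1000, seed = 1)$labels)
  expect_false(identical(sample_latent_chain(m, 1000, seed = 1)$labels,
                         sample_latent_chain(m, 1000, seed = 2)$labels))
})

test_that("planted models satisfy the latent-model contract", {
  for (seed in 1:5) {
    n <- sample(10:80, 1)
    K <- sample(1:5, 1)
    m <- make_planted_model(n, K, separation = 0.9, seed = seed)
    expect_s3_class(m, "latent_model")
    expect_true(m$hard)
    expect_length(attr(m, "assignments"), n)
  }
  # separation = 1 gives disjoint emission supports
  m1 <- make_planted_model(12, 3, separation = 1, seed = 2)
  supp <- m1$lam > 0
  expect_true(all(colSums(supp) == 4) && all(rowSums(supp) == 1))
  expect_error(make_planted_model(3, 5), class = "lmm_input_error")
})

test_that("the planted partition maximizes the assignment likelihood", {
  m <- make_planted_model(60, 3, separation = 0.9, seed = 21)
  tr <- sample_latent_chain(m, 50000, seed = 22)
  N <- as.matrix(count_transitions(tr)$N)
  truth <- attr(m, "assignments")
  ll_true <- hard_assignment_loglik(N, truth, 3)
  set.seed(23)
  # randomized oracle: the planted partition beats random alternatives
  beaten <- replicate(200, {
    hard_assignment_loglik(N, sample(truth), 3) < ll_true
  })
  expect_true(all(beaten))
})

test_that("block chain operators are metastable latent aggregates", {
  op <- block_chain_operator(c(3, 4), eps = 0.1)
  expect_s3_class(op, "transfer_operator")
  blocks <- attr(op, "blocks")
  L <- as.matrix(op$Lambda)
  # columns are identical within a block
  expect_equal(L[, 1], L[, 2])
  expect_equal(L[, 4], L[, 7])
  expect_gt(min(L[1:3, 1]), max(L[4:7, 1]))
})
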