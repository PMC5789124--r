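test_that("dbmr attains the exhaustive optimum on a two-block instance", {
  cts <- block_diag_counts()
  # independent oracle: enumerate all 2^6 hard assignments
  best_ll <- -Inf
  best_assign <- NULL
  for (code in 0:63) {
    assign <- as.integer(intToBits(code)[1:6]) + 1L
    ll <- hard_assignment_loglik(cts$N, assign, 2)
    if (ll > best_ll && length(unique(assign)) == 2L) {
      best_ll <- ll
      best_assign <- assign
    }
  }
  # the exhaustive optimum is the block partition (up to label swap)
  expect_true(all(best_assign[1:3] == best_assign[1]) &&
                all(best_assign[4:6] == best_assign[4]) &&
                best_assign[1] != best_assign[4])

  fit <- fit_dbmr(cts, K = 2, seed = 7)
  expect_equal(fit$diagnostics$loglik, best_ll, tolerance = 1e-12)
  est <- attr(fit$model, "assignments")
  expect_equal(adjusted_rand(est, best_assign), 1)
  expect_true(fit$model$hard)
  # likelihood accessor agrees with the internal objective
  expect_equal(log_likelihood(cts, fit$model), best_ll, tolerance = 1e-10)
})

test_that("K = 1 reduces to the destination-marginal Bernoulli model", {
  cts <- block_diag_counts()
  fit <- fit_dbmr(cts, K = 1, seed = 1)
  marginal <- Matrix::rowSums(cts$N) / cts$total
  expect_equal(unname(fit$model$gamma), matrix(1, 1, 6))
  expect_equal(unname(fit$model$lam[, 1]), unname(marginal), tolerance = 1e-14)
})

test_that("K = n reproduces the empirical frequency estimator exactly", {
  set.seed(31)
  N <- matrix(stats::rpois(100, 5) + 1, 10)
  cts <- transition_counts(N)
  fit <- fit_dbmr(cts, K = 10, seed = 1)
  emp <- empirical_estimator(cts)
  expect_identical(fit$diagnostics$loglik, log_likelihood(cts, emp))
})

test_that("likelihood traces are monotone and runs are seed-deterministic", {
  set.seed(5)
  pm <- make_planted_model(20, 4, separation = 0.8, seed = 2)
  tr <- sample_latent_chain(pm, 20000, seed = 3)
  cts <- count_transitions(tr)
  f1 <- fit_dbmr(cts, K = 4, restarts = 5, seed = 11)
  f2 <- fit_dbmr(cts, K = 4, restarts = 5, seed = 11)
  expect_identical(f1$model$lam, f2$model$lam)
  expect_identical(f1$model$gamma, f2$model$gamma)
  expect_true(all(diff(f1$diagnostics$trace) >= -1e-9))
})

test_that("empty clusters are repaired keeping K fixed", {
  # K = 3 on a 2-block instance forces at least one split/repair cycle
  cts <- block_diag_counts()
  fit <- fit_dbmr(cts, K = 3, restarts = 4, seed = 9)
  expect_length(unique(attr(fit$model, "assignments")), 3L)
  expect_true(all(colSums(fit$model$lam) > 0.999999))
  expect_true(all(diff(fit$diagnostics$trace) >= -1e-9))
})

test_that("dbmr rejects invalid K and empty counts", {
  cts <- block_diag_counts()
  expect_error(fit_dbmr(cts, K = 7), class = "lmm_input_error")
  expect_error(fit_dbmr(cts, K = 0), class = "lmm_input_error")
})

test_that("fitting cost scales no worse than quadratically in n at fixed K", {
  # coarse two-point timing on planted instances (generous margin; the
  # assignment step touches only nonzero count entries)
  time_fit <- function(n) {
    pm <- make_planted_model(n, 3, separation = 0.9, seed = 1)
    tr <- sample_latent_chain(pm, 50000, seed = 2)
    cts <- count_transitions(tr)
    t0 <- proc.time()["elapsed"]
    fit_dbmr(cts, K = 3, restarts = 3, seed = 3)
    proc.time()["elapsed"] - t0
  }
  t100 <- time_fit(100)
  t200 <- time_fit(200)
  # quadratic growth predicts a factor of 4; allow a wide scheduling margin
  expect_lt(t200, pmax(t100, 0.05) * 25)
})

test_that("refinement-seeded nested fits have non-decreasing training likelihood", {
  cts <- local({
    pm <- make_planted_model(30, 4, separation = 0.85, seed = 71)
    count_transitions(sample_latent_chain(pm, 40000, seed = 72))
  })
  prev <- fit_dbmr(cts, K = 1, seed = 30)
  lls <- prev$diagnostics$loglik
  for (K in 2:6) {
    assign <- attr(prev$model, "assignments")
    # refine the previous partition: move half of the largest cluster
    # into the new latent index K
    big <- as.integer(names(which.max(table(assign))))
    members <- which(assign == big)
    assign[members[seq_len(ceiling(length(members) / 2))]] <- K
    prev <- fit_dbmr(cts, K = K, seed = 30 + K, init = assign)
    lls <- c(lls, prev$diagnostics$loglik)
  }
  expect_true(all(diff(lls) >= -1e-9))
})
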