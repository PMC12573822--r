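test_that("K=1 training reduces to empirical mark frequencies", {
  set.seed(2)
  X <- matrix(rbinom(200 * 3, 1, c(0.2, 0.5, 0.8)), 200, 3, byrow = TRUE)
  m <- baum_welch_train(X, K = 1, seed = 1, n_restarts = 1)
  expect_equal(as.numeric(m$emission), colMeans(X), tolerance = 1e-6)
  expect_equal(m$transition, matrix(1, 1, 1))
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  set.seed(3)
  for (i in 1:5) {
    emission <- matrix(runif(2 * 2, 0.1, 0.9), 2, 2)
    transition <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
    initial <- c(0.5, 0.5)
    X <- matrix(rbinom(8, 1, 0.5), 4, 2)
    model <- structure(list(K = 2, emission = emission,
                            transition = transition, initial = initial,
                            marks = NULL), class = "chromhmm_model")
    expect_equal(hmm_loglik(model, X),
                 oracle_hmm_loglik(X, emission, transition, initial),
                 tolerance = 1e-10)
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(4)
  X <- matrix(rbinom(300 * 4, 1, 0.3), 300, 4)
  m <- baum_welch_train(X, K = 3, seed = 9, n_restarts = 2, max_iter = 40)
  expect_true(all(diff(m$ll_trace) >= -1e-8 * (abs(m$ll_trace[-1]) + 1)))
})

test_that("deterministic alternating blocks are recovered", {
  blk <- 25
  X <- do.call(rbind, rep(list(matrix(rep(c(1, 0), each = blk), blk, 2),
                               matrix(rep(c(0, 1), each = blk), blk, 2)), 10))
  m <- baum_welch_train(X, K = 2, seed = 1, n_restarts = 3)
  em <- m$emission[order(m$emission[, 1], decreasing = TRUE), ]
  expect_lt(max(abs(em - rbind(c(1, 0), c(0, 1)))), 0.02)
})

test_that("posterior decoding normalizes and recovers simulated paths", {
  truth <- structure(list(
    K = 3,
    emission = rbind(c(0.95, 0.05, 0.05, 0.05),
                     c(0.05, 0.95, 0.05, 0.95),
                     c(0.05, 0.05, 0.95, 0.05)),
    transition = matrix(c(0.9, 0.05, 0.05,
                          0.05, 0.9, 0.05,
                          0.05, 0.05, 0.9), 3, 3, byrow = TRUE),
    initial = rep(1 / 3, 3), marks = paste0("m", 1:4)),
    class = "chromhmm_model")
  sim <- simulate_hmm(truth, T = 4000, seed = 5)
  dec <- decode(truth, sim$X, return_posterior = TRUE)
  expect_equal(rowSums(dec$posterior), rep(1, 4000), tolerance = 1e-9)
  expect_gt(mean(dec$state == sim$path), 0.99)

  one <- baum_welch_train(sim$X[1:50, ], K = 1, seed = 1, n_restarts = 1)
  expect_true(all(decode(one, sim$X[1:50, ]) == 1L))
})

test_that("decode rejects mismatched marks", {
  m <- baum_welch_train(matrix(rbinom(40, 1, 0.5), 20, 2), K = 2, seed = 1)
  expect_error(decode(m, matrix(rbinom(60, 1, 0.5), 20, 3)), "mismatch")
})

test_that("model correlation matches identity and permuted copies", {
  set.seed(6)
  em <- matrix(runif(5 * 8), 5, 8)
  mk <- paste0("m", 1:8)
  a <- structure(list(K = 5, emission = em, marks = mk),
                 class = "chromhmm_model")
  self <- model_correlation(a, a)
  expect_equal(self$matching$r, rep(1, 5), tolerance = 1e-12)
  expect_equal(self$summary, 1)

  perm <- sample(5)
  b <- structure(list(K = 5, emission = em[perm, ], marks = mk),
                 class = "chromhmm_model")
  mc <- model_correlation(a, b)
  # b's row j equals a's row perm[j], so each match pairs a-state perm[j]
  expect_equal(mc$matching$state_a, perm[mc$matching$state_b])
})

test_that("a larger-K model correlates highly with the generating model", {
  truth <- structure(list(
    K = 4,
    emission = rbind(c(0.9, 0.9, 0.1, 0.1, 0.1, 0.1),
                     c(0.1, 0.1, 0.9, 0.9, 0.1, 0.1),
                     c(0.1, 0.1, 0.1, 0.1, 0.9, 0.9),
                     c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1)),
    transition = 0.85 * diag(4) + 0.05, initial = rep(0.25, 4),
    marks = paste0("m", 1:6)), class = "chromhmm_model")
  sim <- simulate_hmm(truth, T = 8000, seed = 11)
  m4 <- baum_welch_train(sim$X, K = 4, seed = 2, n_restarts = 2)
  m6 <- baum_welch_train(sim$X, K = 6, seed = 2, n_restarts = 2)
  expect_gt(model_correlation(m4, m6)$summary, 0.9)
})

test_that("model JSON serialization round-trips", {
  m <- baum_welch_train(matrix(rbinom(100, 1, 0.4), 50, 2), K = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(unname(m2$emission), unname(m$emission), tolerance = 1e-9)
  expect_equal(unname(m2$transition), unname(m$transition), tolerance = 1e-9)
})

test_that("training rejects invalid inputs", {
  expect_error(baum_welch_train(matrix(2, 5, 2), K = 2), "0/1")
  expect_error(baum_welch_train(matrix(rbinom(10, 1, .5), 5, 2), K = 9),
               "exceeds")
})
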