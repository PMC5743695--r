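test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_equal(adjusted_r2(0, 100, 5), -5 / 94)
  expect_equal(adjusted_r2(0.42, 80, 0), 0.42)
  expect_error(adjusted_r2(0.5, 6, 5), "n must exceed")
})

test_that("forward selection keeps a perfect single candidate", {
  set.seed(91)
  y <- rnorm(40)
  X <- matrix(y, 40, 1, dimnames = list(NULL, "x1"))
  fs <- forward_select(y, X, alpha = 0.05, n_perm = 199, seed = 1)
  expect_equal(fs$variable, "x1")
  expect_lte(fs$p_enter, 1 / 200 + 1e-9)
})

test_that("forward selection drops exactly collinear candidates with a warning", {
  set.seed(93)
  x1 <- rnorm(50)
  X <- cbind(x1 = x1, dup = 2 * x1, x2 = rnorm(50))
  y <- x1 + rnorm(50, sd = 0.2)
  expect_warning(fs <- forward_select(y, X, n_perm = 199, seed = 2), "dup")
  expect_true("x1" %in% fs$variable)
})

test_that("forward selection controls type-I error and finds strong signals", {
  set.seed(95)
  empty <- 0
  for (i in 1:60) {
    X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("x", 1:6)))
    fs <- forward_select(rnorm(60), X, alpha = 0.05, n_perm = 199, seed = i)
    if (nrow(fs) == 0) empty <- empty + 1
  }
  expect_gte(empty / 60, 0.85)
  hit <- 0
  for (i in 1:60) {
    X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("x", 1:6)))
    y <- 2 * X[, 1] + rnorm(60, sd = 0.5)
    fs <- forward_select(y, X, alpha = 0.05, n_perm = 199, seed = 300 + i)
    if ("x1" %in% fs$variable) hit <- hit + 1
  }
  expect_gte(hit / 60, 0.95)
})

test_that("variance partitioning satisfies the fraction-sum identity on any input", {
  set.seed(97)
  for (rep in 1:10) {
    n <- 60
    E <- matrix(rnorm(n * 3), n, 3)
    S <- matrix(rnorm(n * 2), n, 2)
    P <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n) + 0.5 * E[, 1] + 0.3 * S[, 1]
    vp <- variance_partition3(y, E, S, P, n_perm = 9, seed = rep)
    fr <- vp$fractions
    expect_lt(abs(sum(fr[1:7]) - vp$model_r2adj[["ESP"]]), 1e-10)
    expect_equal(fr[["residual"]], 1 - vp$model_r2adj[["ESP"]], tolerance = 1e-12)
  }
})

test_that("orthogonal construction recovers pure fractions and near-zero shares", {
  set.seed(101)
  n <- 500
  e <- rnorm(n); s <- rnorm(n); p <- rnorm(n)
  y <- e + s  # equal variance from E and S, none from P
  vp <- variance_partition3(y, cbind(E1 = e), cbind(S1 = s), cbind(P1 = p),
                            n_perm = 99, seed = 1)
  fr <- vp$fractions
  expect_lt(abs(fr[["pure_E"]] - fr[["pure_S"]]), 0.05)
  expect_lt(abs(fr[["pure_P"]]), 0.05)
  for (nm in c("shared_ES", "shared_EP", "shared_SP", "shared_ESP")) {
    expect_lt(abs(fr[[nm]]), 0.05)
  }
})

test_that("a response equal to a predictor saturates the partition", {
  set.seed(103)
  n <- 80
  E <- cbind(e1 = rnorm(n))
  y <- E[, 1]
  vp <- variance_partition3(y, E, cbind(s1 = rnorm(n)), cbind(p1 = rnorm(n)),
                            n_perm = 49, seed = 2)
  expect_equal(vp$model_r2adj[["ESP"]], 1, tolerance = 1e-10)
  expect_lt(abs(vp$fractions[["residual"]]), 1e-10)
})

test_that("partitioning is invariant to affine predictor rescaling", {
  set.seed(105)
  n <- 70
  E <- matrix(rnorm(n * 2), n, 2); S <- matrix(rnorm(n * 2), n, 2)
  P <- matrix(rnorm(n * 2), n, 2)
  y <- E[, 1] - S[, 2] + rnorm(n, sd = 0.5)
  v1 <- variance_partition3(y, E, S, P, n_perm = 9, seed = 3)
  E2 <- sweep(sweep(E, 2, c(3, -0.5), "*"), 2, c(10, -2), "+")
  v2 <- variance_partition3(y, E2, S, P, n_perm = 9, seed = 3)
  expect_equal(v1$fractions, v2$fractions, tolerance = 1e-10)
})

test_that("fractions agree with vegan::varpart", {
  set.seed(107)
  n <- 90
  E <- matrix(rnorm(n * 2), n, 2); S <- matrix(rnorm(n * 2), n, 2)
  P <- matrix(rnorm(n * 2), n, 2)
  y <- E[, 1] + 0.5 * S[, 1] + rnorm(n)
  vp <- variance_partition3(y, E, S, P, n_perm = 9, seed = 4)
  ref <- vegan::varpart(y, E, S, P)$part
  ind <- ref$indfract$Adj.R.square
  # vegan order: pure X1, X2, X3; X1^X2, X2^X3, X1^X3; triple; residual
  expect_equal(unname(vp$fractions[c("pure_E", "pure_S", "pure_P")]),
               ind[1:3], tolerance = 1e-10)
  expect_equal(unname(vp$fractions[c("shared_ES", "shared_SP", "shared_EP")]),
               ind[4:6], tolerance = 1e-10)
  expect_equal(unname(vp$fractions[["shared_ESP"]]), ind[7], tolerance = 1e-10)
  expect_equal(unname(vp$fractions[["residual"]]), ind[8], tolerance = 1e-10)
})

test_that("overparameterized sets abort with a clear message", {
  set.seed(109)
  n <- 10
  E <- matrix(rnorm(n * 9), n, 9)
  expect_error(variance_partition3(rnorm(n), E, cbind(rnorm(n)),
                                   cbind(rnorm(n)), n_perm = 9),
               "reduce predictors")
})

test_that("tidy and glance return the documented shapes", {
  set.seed(111)
  n <- 50
  vp <- variance_partition3(rnorm(n), cbind(e = rnorm(n)),
                            cbind(s = rnorm(n)), cbind(p = rnorm(n)),
                            n_perm = 19, seed = 5, response_name = "toy")
  td <- tidy(vp)
  expect_equal(nrow(td), 8)
  expect_named(td, c("response", "fraction", "adj_r2", "p_value"))
  expect_equal(sum(!is.na(td$p_value)), 3)
  gl <- glance(vp)
  expect_equal(gl$response, "toy")
  expect_equal(gl$n_sites, n)
})
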