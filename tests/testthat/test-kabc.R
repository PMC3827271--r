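toy_table <- function(n, d = 5, p = 3, seed = 1) {
  set.seed(seed)
  s <- matrix(rnorm(n * d), n, d)
  theta <- cbind(a = s[, 1] + 0.5 * s[, 2] + rnorm(n, sd = 0.1),
                 b = s[, 3]^2 + rnorm(n, sd = 0.1),
                 c = rnorm(n))[, seq_len(p), drop = FALSE]
  sim_table(theta, s)
}

test_that("the RBF kernel has its closed-form values and symmetry", {
  u <- c(0, 0); v <- c(1, 1)
  expect_equal(rbf_kernel(u, u, 1), 1)
  expect_equal(rbf_kernel(u, v, 1), exp(-1))
  expect_equal(rbf_kernel(u, v, 2.5), rbf_kernel(v, u, 2.5))
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1))
})

test_that("kernel ridge regression matches an independent naive solver", {
  tab <- toy_table(50, d = 5, p = 3)
  s_obs <- rnorm(5)
  cfg <- kernel_config(sigma2 = 3, lambda = 1e-3, standardize = FALSE)
  ours <- krr_posterior_mean(tab, s_obs, cfg)
  naive <- naive_krr(tab$theta, tab$s, s_obs, sigma2 = 3, lambda = 1e-3)
  expect_equal(unname(ours), unname(naive), tolerance = 1e-8)
})

test_that("KRR interpolates as lambda -> 0 and shrinks to the mean as lambda -> Inf", {
  tab <- toy_table(40)
  cfg0 <- kernel_config(sigma2 = 2, lambda = 1e-10, standardize = FALSE)
  pred <- krr_posterior_mean(tab, tab$s[7, ], cfg0)
  expect_equal(unname(pred), unname(tab$theta[7, ]), tolerance = 1e-4)
  cfgInf <- kernel_config(sigma2 = 2, lambda = 1e12, standardize = FALSE)
  predInf <- krr_posterior_mean(tab, rnorm(5), cfgInf)
  expect_equal(unname(predInf), unname(colMeans(tab$theta)), tolerance = 1e-6)
  # duplicate rows at lambda = 0 are a singular system
  dup <- sim_table(tab$theta[c(1, 1, 2), ], tab$s[c(1, 1, 2), ])
  expect_error(krr_posterior_mean(dup, tab$s[1, ],
                                  kernel_config(2, 0, standardize = FALSE)),
               "lambda")
})

test_that("the Gram matrix is symmetric positive semi-definite", {
  for (seed in 1:5) {
    tab <- toy_table(30, seed = seed)
    X <- scale(tab$s)
    D <- as.matrix(dist(X))^2
    G <- exp(-D / (2 * 1.5))
    expect_equal(G, t(G), tolerance = 1e-12)
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("predictions are invariant to row permutation and affine summary rescaling", {
  tab <- toy_table(60)
  s_obs <- rnorm(5)
  cfg <- kernel_config(sigma2 = 2, lambda = 1e-4, standardize = TRUE)
  base <- krr_posterior_mean(tab, s_obs, cfg)
  perm <- sample(60)
  tab_p <- sim_table(tab$theta[perm, ], tab$s[perm, ])
  expect_equal(krr_posterior_mean(tab_p, s_obs, cfg), base, tolerance = 1e-10)
  # rescale one summary coordinate (and the observation consistently)
  s2 <- tab$s; s2[, 2] <- 100 * s2[, 2] + 7
  o2 <- s_obs; o2[2] <- 100 * o2[2] + 7
  tab_r <- sim_table(tab$theta, s2)
  expect_equal(krr_posterior_mean(tab_r, o2, cfg), base, tolerance = 1e-8)
})

test_that("cross-validation selects sensible hyperparameters deterministically", {
  tab <- toy_table(120)
  one <- select_hyperparams_cv(tab, sigma2_grid = 2, lambda_grid = 1e-3,
                               seed = 4)
  expect_equal(one$sigma2, 2); expect_equal(one$lambda, 1e-3)
  expect_error(select_hyperparams_cv(tab, sigma2_grid = numeric(0),
                                     lambda_grid = numeric(0)), "empty")

  grid <- c(0.01, 5, 5000)  # absurdly narrow / plausible / absurdly wide
  sel1 <- select_hyperparams_cv(tab, sigma2_grid = grid, seed = 11)
  sel2 <- select_hyperparams_cv(tab, sigma2_grid = grid, seed = 11)
  expect_identical(sel1$sigma2, sel2$sigma2)
  expect_identical(sel1$lambda, sel2$lambda)
  # theta is smooth in s here, so the middle bandwidth must beat the
  # extreme endpoints on held-out error
  cv <- attr(sel1, "cv")
  expect_equal(sel1$sigma2, 5)
  expect_lt(min(cv["5", ]), min(cv["0.01", ]))
  expect_lt(min(cv["5", ]), min(cv["5000", ]))
})

test_that("run_abc handles degenerate priors and is seed-reproducible", {
  toy_sim <- function(theta, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    c(theta[1] + rnorm(1, sd = 0.05), theta[2] - theta[1] + rnorm(1, sd = 0.05))
  }
  point_prior <- function(n, seed = NULL)
    matrix(rep(c(3, 7), each = n), n, 2, dimnames = list(NULL, c("x", "y")))
  est <- run_abc(c(0, 0), point_prior, toy_sim, n = 50, seed = 2,
                 config = kernel_config(1, 1e-3))
  expect_equal(as.numeric(est), c(3, 7), tolerance = 1e-9)

  prior <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(runif(2 * n, 1, 5), n, 2, dimnames = list(NULL, c("x", "y")))
  }
  e1 <- run_abc(c(2, 1), prior, toy_sim, n = 120, seed = 9)
  e2 <- run_abc(c(2, 1), prior, toy_sim, n = 120, seed = 9)
  expect_identical(as.numeric(e1), as.numeric(e2))
})

test_that("replication dispersion shrinks as the table grows", {
  toy_sim <- function(theta, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    theta[1] + rnorm(3, sd = 0.3)
  }
  prior <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(runif(n, 0, 10), n, 1, dimnames = list(NULL, "x"))
  }
  cfg <- kernel_config(1, 1e-3)
  expect_warning(replicate_abc(c(5, 5, 5), prior, toy_sim, n = 60, R = 1,
                               seed = 1, config = cfg), "R = 1")
  small <- replicate_abc(c(5, 5, 5), prior, toy_sim, n = 60, R = 8, seed = 3,
                         config = cfg)
  big <- replicate_abc(c(5, 5, 5), prior, toy_sim, n = 600, R = 8, seed = 3,
                       config = cfg)
  expect_lt(big$sd[["x"]], small$sd[["x"]])
  expect_true(all(small$sd >= 0))
})

test_that("simulation tables round-trip through TSV", {
  tab <- toy_table(25)
  f <- tempfile(fileext = ".tsv")
  write_sim_table(tab, f)
  back <- read_sim_table(f)
  expect_equal(back$theta, tab$theta, tolerance = 1e-12)
  expect_equal(unname(back$s), unname(tab$s), tolerance = 1e-12)
})
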