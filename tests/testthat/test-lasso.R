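test_that("lambda_max matches hand arithmetic and grid endpoints are exact", {
  # 2-column toy: inner products computable by hand
  X <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  y <- c(1, 1, 0, 0)
  st <- sniffsel:::standardize_columns(X)
  lam_hand <- max(abs(crossprod(st$Xs, y - mean(y)))) / 4
  g <- lambda_grid(X, y, n_lambda = 7, ratio = 0.01)
  expect_equal(g[1], lam_hand)
  expect_equal(g[7], 0.01 * lam_hand)
  expect_length(g, 7)
  # column a is perfectly aligned: standardized inner product = n/2 -> lambda 0.5
  expect_equal(g[1], 0.5)
})

test_that("degenerate designs are rejected with classed errors", {
  X <- cbind(c(1, 0, 1, 0))
  expect_error(lambda_grid(X, c(1, 1, 1, 1)), class = "sniffsel_degeneracy_error")
  # single column orthogonal to the centered labels
  expect_error(lambda_grid(cbind(c(1, 0, 1, 0)), c(1, 1, 0, 0)),
               class = "sniffsel_degeneracy_error")
  expect_error(lasso_path(cbind(c(1, 2, 0)), c(1, 0, 1)),
               class = "sniffsel_value_error")
})

test_that("at lambda_max the model is intercept-only", {
  set.seed(2)
  X <- matrix(rbinom(200, 1, 0.5), 50, 4)
  y <- rbinom(50, 1, plogis(X %*% c(1, -1, 0, 0) - 0.2))
  fit <- lasso_path(X, y, n_lambda = 20, ratio = 0.05)
  expect_true(all(fit$coefficients[, 1] == 0))
  expect_equal(fit$intercepts[1], qlogis(mean(y)), tolerance = 1e-6)
})

test_that("solutions at tiny lambda match the unpenalized Newton oracle", {
  set.seed(40)
  X <- matrix(rbinom(160, 1, 0.5), 40, 4)
  y <- rbinom(40, 1, plogis(X %*% c(1.2, -0.8, 0.5, 0)))
  lam <- lambda_grid(X, y, n_lambda = 5, ratio = 0.1)
  fit <- lasso_path(X, y, lambda = c(lam, 1e-9), tol = 1e-12)
  ml <- glm_logistic_coefs(X, y)
  got <- coef(fit, index = length(fit$lambda))
  expect_lt(max(abs(got - ml)), 1e-4)
})

test_that("every converged solution passes the KKT subgradient check", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 80; p <- 6
    X <- matrix(rbinom(n * p, 1, runif(p, 0.3, 0.7)[rep(1:p, each = n)]), n, p)
    y <- rbinom(n, 1, plogis(X %*% rnorm(p)))
    if (length(unique(y)) < 2 ||
        inherits(try(lambda_grid(X, y), silent = TRUE), "try-error")) next
    fit <- lasso_path(X, y, n_lambda = 25, ratio = 1e-2, tol = 1e-9)
    expect_lt(max(kkt_check(fit, X, y)[fit$converged]), 1e-6)
  }
})

test_that("coefficient paths agree with the reference solver on random instances", {
  skip_if_not_installed("glmnet")
  for (seed in c(3, 17, 31)) {
    set.seed(seed)
    n <- sample(60:200, 1); p <- sample(4:16, 1)
    X <- matrix(rbinom(n * p, 1, runif(p, 0.2, 0.8)[rep(1:p, each = n)]), n, p)
    y <- rbinom(n, 1, plogis(-0.3 + X %*% rnorm(p, 0, 0.8)))
    if (length(unique(y)) < 2) next
    lam <- lambda_grid(X, y, n_lambda = 25, ratio = 1e-2)
    fit <- lasso_path(X, y, lambda = lam, tol = 1e-10)
    ref <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                          standardize = TRUE, thresh = 1e-14)
    expect_lt(max(abs(fit$coefficients - as.matrix(ref$beta))), 1e-3)
  }
})

test_that("the penalized objective never increases within a grid point", {
  # run the solver sweep-by-sweep via tight max_iter and watch the objective
  set.seed(8)
  n <- 60
  X <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  y <- rbinom(n, 1, plogis(X %*% c(2, -2, 1, 0, 0) - 0.5))
  lam <- lambda_grid(X, y, n_lambda = 3, ratio = 0.05)
  st <- sniffsel:::standardize_columns(X)
  obj <- function(fit, l) sniffsel:::lasso_objective(
    fit$intercepts_std[l] + drop(st$Xs %*% fit$coefficients_std[, l]),
    y, fit$coefficients_std[, l], fit$lambda[l])
  prev <- Inf
  for (iters in 1:15) {
    fit <- suppressWarnings(lasso_path(X, y, lambda = lam[3], tol = 0,
                                       max_iter = iters))
    cur <- obj(fit, 1)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("solutions are invariant to row order", {
  set.seed(12)
  n <- 70
  X <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  y <- rbinom(n, 1, plogis(X %*% c(1, -1, 0.5, 0, 0, 0)))
  fit1 <- lasso_path(X, y, n_lambda = 15, ratio = 0.05)
  perm <- sample(n)
  fit2 <- lasso_path(X[perm, ], y[perm], n_lambda = 15, ratio = 0.05)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-6)
})

test_that("entry order: ties, perfect separators, and full-panel prefix", {
  # duplicated column: tie broken by larger |coef| at entry, then index
  X <- cbind(a = c(1, 1, 1, 0, 0, 0), b = c(1, 1, 1, 0, 0, 0),
             c = c(1, 0, 1, 0, 1, 0))
  y <- c(1, 1, 0, 1, 0, 0)
  fit <- lasso_path(X, y, n_lambda = 10, ratio = 0.1)
  eo <- entry_order(fit)
  expect_setequal(as.character(eo), colnames(X))
  ia <- which(as.character(eo) == "a"); ib <- which(as.character(eo) == "b")
  expect_lt(ia, ib)   # identical columns: panel index decides

  # an item that separates classes perfectly enters first
  set.seed(3)
  Xs <- matrix(rbinom(40 * 4, 1, 0.5), 40, 4)
  ys <- Xs[, 3]
  eo2 <- entry_order(lasso_path(Xs, ys, n_lambda = 30, ratio = 1e-2))
  expect_equal(as.character(eo2)[1], "item3")

  # prefix of length = panel size is the whole panel
  expect_setequal(as.character(eo2), paste0("item", 1:4))
})

test_that("planted informative items dominate the early path", {
  p <- ss16_panel()
  hits <- 0L
  for (seed in 1:5) {
    d <- planted_design(600, p, seed = 100 + seed)
    eo <- entry_order(lasso_path(d$X, d$y, n_lambda = 50, ratio = 1e-2))
    hits <- hits + (sum(head(as.character(eo), 8) %in% d$informative) >= 7L)
  }
  expect_gte(hits, 4L)
})
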