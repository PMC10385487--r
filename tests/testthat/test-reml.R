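test_that("ar1_matrix matches the exponential-decay formula and its inverse is tridiagonal", {
  expect_equal(ar1_matrix(4, 0), diag(4))
  expect_equal(ar1_matrix(3, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  Ai <- solve(ar1_matrix(8, 0.7))
  off <- abs(row(Ai) - col(Ai)) > 1
  expect_lt(max(abs(Ai[off])), 1e-10)
  expect_error(ar1_matrix(3, 1), "rho")
  expect_error(ar1_matrix(0, 0.5), "positive integer")
})

test_that("balanced one-way REML reproduces the ANOVA closed form", {
  y <- c(1, 2, 3, 5, 9, 11)
  grp <- rep(c("A", "B", "C"), each = 2)
  fit <- reml_fit(y, matrix(1, 6, 1, dimnames = list(NULL, "mu")),
                  random = list(rand_term(incidence(grp), name = "b")))
  ## MSW = 1.5, MSB = 38.1667, sigma2_b = (MSB - MSW) / 2
  expect_equal(fit$estimates[["sigma2_e"]], 1.5, tolerance = 1e-4)
  expect_equal(fit$estimates[["sigma2_b"]], (229 / 6 - 1.5) / 2,
               tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
})

test_that("with no random terms BLUEs equal least squares, weighted and not", {
  set.seed(1)
  x <- 1:12
  y <- 3 + 0.5 * x + rnorm(12)
  X <- cbind(mu = 1, x = x)
  fit <- reml_fit(y, X)
  expect_equal(unname(fit$beta), unname(coef(lm(y ~ x))), tolerance = 1e-8)
  w <- c(rep(1, 6), rep(4, 6))
  gfit <- reml_fit(y, X, residual = resid_known(w))
  gls <- lm(y ~ x, weights = 1 / w)
  expect_equal(unname(gfit$beta), unname(coef(gls)), tolerance = 1e-8)
  ## with known weights the SEs come straight from (X' R^-1 X)^-1
  expect_equal(unname(gfit$beta_se),
               unname(sqrt(diag(vcov(gls))) / summary(gls)$sigma),
               tolerance = 1e-8)
})

test_that("fits are deterministic and fixed variance parameters are honoured", {
  sim <- tiny_sim()
  dat <- sim$plots[sim$plots$trial == "E19", ]
  X <- cbind(mu = rep(1, nrow(dat)))
  f1 <- reml_fit(dat$TY, X, residual = resid_ar1_col(dat$row, dat$col))
  f2 <- reml_fit(dat$TY, X, residual = resid_ar1_col(dat$row, dat$col))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loglik, f2$loglik)
  ## AR1xAR1+nugget pinned at rho = 0, nugget = 0 collapses to IID
  f_iid <- reml_fit(dat$TY, X, residual = resid_iid())
  f_pin <- reml_fit(dat$TY, X, residual = resid_ar1_rowcol_nugget(
    dat$row, dat$col,
    fixed = list(rho_r = 0, rho_c = 0, sigma2_nugget = 0)))
  expect_equal(f_pin$loglik, f_iid$loglik, tolerance = 1e-6)
  expect_equal(f_pin$estimates[["sigma2_e"]], f_iid$estimates[["sigma2_e"]],
               tolerance = 1e-5)
  ## pinned parameters are excluded from the AIC count
  expect_equal(f_pin$n_params, 1L)
})

test_that("REML optimum matches an independent grid search on small instances", {
  set.seed(42)
  for (case in 1:3) {
    n <- 24
    grp <- rep(letters[1:6], each = 4)
    Z <- incidence(grp)
    y <- rnorm(n, 0, 1) + rep(rnorm(6, 0, 1.2), each = 4)
    X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
    fit <- reml_fit(y, X, random = list(rand_term(Z, name = "b")))
    vy <- var(y)
    gmax <- grid_max_ll(y, X,
                        function(p) exp(p[1]) * tcrossprod(Z) + exp(p[2]) * diag(n),
                        lower = log(c(vy, vy)) - 8, upper = log(c(vy, vy)) + 3)
    expect_lt(abs(fit$loglik - gmax), 1e-4)
  }
})

test_that("AIC ranking prefers the smallest AIC with ties to fewer parameters", {
  mk <- function(ll, k, sig = "1|mu") {
    f <- list(loglik = ll, n_params = k, aic = -2 * ll + 2 * k,
              converged = TRUE, fixed_signature = sig)
    class(f) <- "reml_fit"
    f
  }
  expect_equal(mk(-10, 2)$aic, 24)
  cmp <- compare_aic(list(a = mk(-10, 2), b = mk(-10, 3)))
  expect_equal(cmp$best_name, "a")
  cmp2 <- compare_aic(list(a = mk(-12, 1), b = mk(-10, 2)))
  expect_equal(cmp2$best_name, "b")
  expect_error(compare_aic(list(a = mk(-10, 2), b = mk(-10, 2, sig = "2|mu|x"))),
               "fixed-effect")
})

test_that("kernel BLUPs for unobserved levels equal the conditional expectation", {
  set.seed(9)
  K <- crossprod(matrix(rnorm(25), 5)) + diag(0.5, 5)
  dimnames(K) <- list(letters[1:5], letters[1:5])
  obs <- rep(letters[1:3], each = 4)
  Z <- incidence(obs, levels = letters[1:5])
  u <- drop(t(chol(K)) %*% rnorm(5))
  y <- u[obs] + rnorm(12, 0, 0.5)
  X <- matrix(1, 12, 1, dimnames = list(NULL, "mu"))
  fit <- reml_fit(y, X, random = list(rand_term(Z, K, name = "u")))
  uhat <- predict_random(fit, "u")
  oracle <- drop(K[4:5, 1:3] %*% solve(K[1:3, 1:3], uhat[1:3]))
  expect_equal(unname(uhat[4:5]), unname(oracle), tolerance = 1e-10)
  ## identity kernel: unobserved levels are predicted at zero
  fit_i <- reml_fit(y, X, random = list(rand_term(Z, NULL, name = "u")))
  expect_equal(unname(predict_random(fit_i, "u")[4:5]), c(0, 0))
  ## perfectly correlated kernel levels share one BLUP
  K2 <- matrix(1, 2, 2) + diag(1e-8, 2)
  dimnames(K2) <- list(c("p", "q"), c("p", "q"))
  Z2 <- incidence(rep("p", 6), levels = c("p", "q"))
  y2 <- rnorm(6, 2, 1)
  fit2 <- reml_fit(y2, matrix(1, 6, 1, dimnames = list(NULL, "mu")),
                   random = list(rand_term(Z2, K2, name = "u")))
  u2 <- predict_random(fit2, "u")
  expect_equal(unname(u2["p"]), unname(u2["q"]), tolerance = 1e-6)
  expect_error(predict_random(fit, "u", "zzz"), "absent")
})

test_that("fits serialize to JSON and back with their key quantities", {
  y <- c(1, 2, 3, 5, 9, 11)
  grp <- rep(c("A", "B", "C"), each = 2)
  fit <- reml_fit(y, matrix(1, 6, 1, dimnames = list(NULL, "mu")),
                  random = list(rand_term(incidence(grp), name = "b")))
  js <- reml_fit_json(fit)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$aic, fit$aic)
  expect_equal(back$estimates$sigma2_e, fit$estimates[["sigma2_e"]])
  expect_true(back$converged)
  path <- withr::local_tempfile(fileext = ".json")
  reml_fit_json(fit, path)
  expect_equal(jsonlite::fromJSON(path)$loglik, fit$loglik)
})

test_that("a variance simulated at zero is estimated near the boundary", {
  set.seed(3)
  y <- rnorm(100, 5, 1)           # no group structure at all
  grp <- rep(letters[1:20], each = 5)
  fit <- reml_fit(y, matrix(1, 100, 1, dimnames = list(NULL, "mu")),
                  random = list(rand_term(incidence(grp), name = "b")))
  expect_lt(fit$estimates[["sigma2_b"]], 0.2)
  expect_true(fit$converged)
})
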