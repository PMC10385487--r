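test_that("stage-1 standard errors become a fixed diagonal residual", {
  b <- data.frame(trial = "T1", hybrid_id = c("a", "b"), blue = c(1, 2),
                  se = c(1, 1))
  r <- build_weights(b)
  expect_s3_class(r, "hgp_resid")
  expect_equal(r$weights, c(1, 1))
  b2 <- b
  b2$se[2] <- 2                       # doubling an SE quadruples its weight
  expect_equal(build_weights(b2)$weights, c(1, 4))
  b3 <- b
  b3$se[1] <- NA
  expect_error(build_weights(b3), "complete")
  b4 <- b
  b4$se[1] <- 0
  expect_error(build_weights(b4), "positive")
})

test_that("a weighted fixed-effects fit reproduces the GLS closed form", {
  set.seed(7)
  tr <- rep(c("T1", "T2"), each = 6)
  y <- ifelse(tr == "T1", 10, 14) + rnorm(12)
  se <- runif(12, 0.5, 2)
  blues <- data.frame(trial = tr, hybrid_id = paste0("h", 1:12), blue = y,
                      se = se)
  X <- incidence(tr)
  fit <- reml_fit(y, X, residual = build_weights(blues))
  W <- diag(1 / se^2)
  beta_gls <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(fit$beta), unname(drop(beta_gls)), tolerance = 1e-10)
})

test_that("the GCA+SCA model holds first-step components exactly fixed", {
  ks <- kernel_set()
  sb <- simulate_blues(ks$cp, ks$Gp, ks$Gh, ks$D,
                       trials = c("T1", "T2"),
                       varcomps = list(sigma2_gca = 1, sigma2_gxt = 0.4,
                                       sigma2_sca = 0.4, sigma2_delta = 0.3),
                       beta = c(10, 12), se = 0.7, seed = 8)
  g1 <- fit_gca(sb$blues, ks$cp, ks$Gp, ks$Gh)
  g2 <- fit_gca_sca(sb$blues, ks$cp, ks$Gp, ks$Gh, ks$D, g1)
  expect_identical(unname(g2$varcomps["sigma2_gca"]),
                   unname(g1$varcomps["sigma2_gca"]))
  expect_identical(unname(g2$varcomps["sigma2_gxt"]),
                   unname(g1$varcomps["sigma2_gxt"]))
  expect_true(g2$fixed[["sigma2_gca"]])
  expect_true(g2$fixed[["sigma2_gxt"]])
  expect_false(g2$fixed[["sigma2_sca"]])
  expect_true(all(g2$varcomps >= 0))
})

test_that("without simulated dominance the GCA+SCA model collapses onto GCA", {
  ks <- kernel_set()
  sb <- simulate_blues(ks$cp, ks$Gp, ks$Gh, D = NULL,
                       trials = c("T1", "T2"),
                       varcomps = list(sigma2_gca = 1, sigma2_gxt = 0.3,
                                       sigma2_sca = 0, sigma2_delta = 0.4),
                       beta = c(10, 12), se = 0.7, seed = 9)
  g1 <- fit_gca(sb$blues, ks$cp, ks$Gp, ks$Gh)
  g2 <- fit_gca_sca(sb$blues, ks$cp, ks$Gp, ks$Gh, ks$D, g1)
  expect_lt(unname(g2$varcomps["sigma2_sca"]), 0.1)
  p1 <- predict_hybrids(g1, ks$cp, target = "AVG")
  p2 <- predict_hybrids(g2, ks$cp, target = "AVG")
  expect_gt(cor(p1, p2), 0.99)
  expect_lt(mean(abs(p1 - p2)), 0.15 * sd(p1))
})

test_that("variance partitioning follows the combining-ability bookkeeping", {
  ## pure additive edge case
  p0 <- partition_variance(list(sigma2_gca = 2, sigma2_sca = 0,
                                sigma2_delta = 0))
  expect_equal(c(p0$prop_gca, p0$prop_sca, p0$prop_delta), c(1, 0, 0))
  p1 <- partition_variance(list(sigma2_gca = 3, sigma2_sca = 2,
                                sigma2_delta = 1))
  expect_equal(p1$prop_gca + p1$prop_sca + p1$prop_delta, 1)
  expect_equal(p1$prop_gca, 6 / 9)
  expect_error(partition_variance(list(sigma2_gca = 0, sigma2_delta = 0)),
               "zero")
  expect_error(partition_variance(list(sigma2_gca = 1)), "sigma2_delta")
  ## the fit method agrees with the numeric interface
  ks <- kernel_set()
  sb <- simulate_blues(ks$cp, ks$Gp, ks$Gh, ks$D, trials = c("T1", "T2"),
                       varcomps = list(sigma2_gca = 1, sigma2_gxt = 0.3,
                                       sigma2_sca = 0.3, sigma2_delta = 0.3),
                       beta = c(10, 12), se = 0.7, seed = 10)
  g1 <- fit_gca(sb$blues, ks$cp, ks$Gp, ks$Gh)
  pv <- partition_variance(g1)
  pv2 <- partition_variance(list(sigma2_gca = g1$varcomps[["sigma2_gca"]],
                                 sigma2_delta = g1$varcomps[["sigma2_delta"]]))
  expect_equal(pv$prop_gca, pv2$prop_gca)
  expect_equal(pv$model, "GCA")
})

test_that("hybrid predictions are parent-symmetric and match the kernel algebra", {
  ks <- kernel_set()
  sb <- simulate_blues(ks$cp, ks$Gp, ks$Gh, ks$D, trials = c("T1", "T2"),
                       varcomps = list(sigma2_gca = 1, sigma2_gxt = 0.3,
                                       sigma2_sca = 0.3, sigma2_delta = 0.3),
                       beta = c(10, 12), se = 0.7, seed = 12)
  g1 <- fit_gca(sb$blues, ks$cp, ks$Gp, ks$Gh)
  pr <- predict_hybrids(g1, ks$cp, target = "AVG")
  swapped <- ks$cp
  tmp <- swapped$parent1
  swapped$parent1 <- swapped$parent2
  swapped$parent2 <- tmp
  expect_equal(predict_hybrids(g1, swapped, target = "AVG"), pr)
  ## per-trial target adds intercept and interaction BLUP
  pt <- predict_hybrids(g1, ks$cp, target = "T1")
  h <- ks$cp$hybrid_id[3]
  expect_equal(unname(pt[h]),
               unname(g1$beta["trial:T1"] + g1$gca[ks$cp$parent1[3]] +
                        g1$gca[ks$cp$parent2[3]] + g1$gxt[h, "T1"]))
  expect_error(predict_hybrids(g1, ks$cp, target = "T9"), "unknown trial")
})

test_that("BLUPs from a toy combining model match the direct mixed-model algebra", {
  ## 4 parents, 3 hybrids, 1 trial, every variance pinned: the fit reduces
  ## to linear algebra we can replicate independently
  parents <- c("P1", "P2", "P3", "P4")
  Gp <- diag(4) * 2
  dimnames(Gp) <- list(parents, parents)
  cp <- data.frame(hybrid_id = c("h12", "h13", "h24"),
                   parent1 = c("P1", "P1", "P2"),
                   parent2 = c("P2", "P3", "P4"),
                   nursery = 2019, shared = FALSE)
  Gh <- diag(3)
  dimnames(Gh) <- list(cp$hybrid_id, cp$hybrid_id)
  blues <- data.frame(trial = "T1", hybrid_id = cp$hybrid_id,
                      blue = c(3, 5, 9), se = c(1, 1, 1))
  s2g <- 0.8; s2t <- 0.2; s2d <- 0.3
  parts <- hybridgp:::.stage2_parts(blues, cp, Gp, Gh)
  random <- list(rand_term(parts$Zg, Gp, name = "gca", fixed = s2g),
                 rand_term(parts$Zd, NULL, name = "delta", fixed = s2d),
                 rand_term(parts$Zt, parts$Kt, name = "gxt", fixed = s2t))
  fit <- reml_fit(blues$blue, parts$X, random = random,
                  residual = build_weights(blues))
  ## independent construction of V, beta-hat and the GCA BLUPs
  Zg <- parts$Zg
  V <- s2g * Zg %*% Gp %*% t(Zg) + s2t * Gh + s2d * diag(3) + diag(3)
  X <- matrix(1, 3, 1)
  beta <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% blues$blue)
  ghat <- s2g * Gp %*% t(Zg) %*% solve(V, blues$blue - drop(beta))
  expect_equal(unname(fit$beta), unname(drop(beta)), tolerance = 1e-8)
  expect_equal(unname(fit$u$gca), unname(drop(ghat)), tolerance = 1e-8)
})

test_that("null genetic effects give null average predictions", {
  fake <- structure(list(model = "GCA",
                         gca = c(P1 = 0, P2 = 0), sca = NULL,
                         beta = c("trial:T1" = 7),
                         gxt = matrix(0, 1, 1, dimnames = list("h", "T1")),
                         trials = "T1"),
                    class = "combining_fit")
  cp <- data.frame(hybrid_id = "h", parent1 = "P1", parent2 = "P2")
  expect_equal(unname(predict_hybrids(fake, cp, target = "AVG")), 0)
  expect_error(predict_hybrids(fake,
                               data.frame(hybrid_id = "x", parent1 = "P9",
                                          parent2 = "P2")),
               "P9")
})
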