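test_that("founder simulation is deterministic, polymorphic, and frequency-bounded", {
  cfg <- sim_config(n_founders = 2, n_parents = 2, n_snps = 1, n_hybrids = 1,
                    seed = 1)
  f <- simulate_founders(cfg)
  expect_equal(dim(f$haplotypes), c(4L, 1L))
  expect_true(sum(f$haplotypes) %in% 1:3)   # polymorphic among founders
  f2 <- simulate_founders(cfg)
  expect_identical(f$haplotypes, f2$haplotypes)
  cfg3 <- sim_config(n_founders = 16, n_parents = 10, n_snps = 704,
                     n_hybrids = 10, seed = 3)
  f3 <- simulate_founders(cfg3)
  expect_true(all(f3$freq >= 0.1 & f3$freq <= 0.9))
  ## realized haplotype frequencies track the drawn ones up to binomial noise
  emp <- colMeans(f3$haplotypes)
  expect_lt(max(abs(emp - f3$freq)), 4 * sqrt(0.25 / 32) + 0.05)
  mono <- colSums(f3$haplotypes) %in% c(0L, 32L)
  expect_false(any(mono))
  expect_error(sim_config(n_founders = 1, seed = 1), "counts")
})

test_that("inbred lines are homozygous founder mosaics with geometric segments", {
  cfg <- sim_config(n_founders = 6, n_parents = 300, n_snps = 100,
                    n_chromosomes = 1, mosaic_switch_prob = 0.1,
                    n_hybrids = 10, seed = 5)
  f <- simulate_founders(cfg)
  g <- simulate_inbreds(f, cfg)
  expect_true(all(g %in% c(0L, 2L)))        # fully homozygous
  ## expected switches per line: (n_snps - 1) * p = 9.9
  nsw <- attr(g, "n_switches")
  expect_equal(mean(nsw), 9.9, tolerance = 3 * sqrt(99 * 0.1 * 0.9 / 300) / 9.9)
  ## zero switch probability doubles a single founder haplotype
  cfg0 <- sim_config(n_founders = 6, n_parents = 20, n_snps = 50,
                     n_chromosomes = 1, mosaic_switch_prob = 0,
                     n_hybrids = 10, seed = 6)
  f0 <- simulate_founders(cfg0)
  g0 <- simulate_inbreds(f0, cfg0)
  H2 <- 2 * f0$haplotypes
  for (i in seq_len(nrow(g0))) {
    match_any <- any(apply(H2, 1, function(h) all(h == g0[i, ])))
    expect_true(match_any)
  }
})

test_that("the crossing plan samples distinct non-self pairs with sane usage rates", {
  cfg <- sim_config(n_founders = 2, n_parents = 3, n_snps = 4, n_hybrids = 3,
                    seed = 2)
  cp <- simulate_crossplan(c("A", "B", "C"), cfg)
  key <- paste(pmin(cp$parent1, cp$parent2), pmax(cp$parent1, cp$parent2))
  expect_setequal(key, c("A B", "A C", "B C"))   # complete diallel edge case
  expect_error(simulate_crossplan(c("A", "B", "C"),
                                  sim_config(n_parents = 3, n_hybrids = 4,
                                             seed = 2)),
               "distinct parent pairs")
  sim <- tiny_sim()
  cp2 <- sim$crossplan
  expect_false(any(cp2$parent1 == cp2$parent2))
  expect_false(anyDuplicated(paste(pmin(cp2$parent1, cp2$parent2),
                                   pmax(cp2$parent1, cp2$parent2))) > 0)
  used <- table(c(cp2$parent1, cp2$parent2))
  expect_equal(mean(used), 2 * nrow(cp2) / length(used))
})

test_that("phenotype generation is reproducible and its bookkeeping is exact", {
  sim <- tiny_sim()
  cfg <- sim$config
  ## same seed regenerates the plot table bit for bit
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$plots, sim2$plots)
  ## two replicate plots per hybrid in every trial where planted
  counts <- table(sim$plots$hybrid_id, sim$plots$trial)
  expect_true(all(counts %in% c(0L, 2L)))
  yrs <- with(sim$crossplan, ifelse(shared, 4L, 2L))
  expect_equal(unname(rowSums(counts)[sim$crossplan$hybrid_id]), 2L * yrs)
  ## realized truth variances are pinned exactly by construction
  expect_equal(unname(var(sim$truth$gca)), cfg$var_gca, tolerance = 1e-10)
  expect_equal(unname(var(sim$truth$sca)), cfg$var_sca, tolerance = 1e-10)
  expect_equal(unname(apply(sim$truth$gxt, 2, var)),
               rep(cfg$var_gxt, 4), tolerance = 1e-10)
})

test_that("with only additive effects, replicate plots differ by block effects alone", {
  cfg <- sim_config(n_founders = 6, n_parents = 20, n_snps = 40,
                    n_chromosomes = 2, n_hybrids = 30, shared_fraction = 0,
                    var_gca = 1, var_sca = 0, var_gxt = 0, var_delta = 0,
                    var_block = 0.5, var_trial = 0,
                    spatial = list(sigma2_e = 0, rho_row = 0, rho_col = 0,
                                   sigma2_nugget = 0),
                    trait_mean = 10, seed = 9)
  sim <- simulate_dataset(cfg)
  tr <- sim$plots[sim$plots$trial == "E19", ]
  be <- sim$truth$block_effects[["E19"]]
  for (h in unique(tr$hybrid_id)) {
    rows <- tr[tr$hybrid_id == h, ]
    expect_equal(diff(rows$TY[order(rows$block)]), be[2] - be[1],
                 tolerance = 1e-10)
  }
})

test_that("with no genetic variance, neighbouring plots covary like the AR1 field", {
  ## many small single-trial fields; adjacent same-row plots should have
  ## covariance sigma2_e * rho_col
  covs <- numeric(0)
  vars <- numeric(0)
  for (s in 1:60) {
    cfg <- sim_config(n_founders = 4, n_parents = 8, n_snps = 10,
                      n_chromosomes = 1, n_hybrids = 18, shared_fraction = 0,
                      var_gca = 0, var_sca = 0, var_gxt = 0, var_delta = 0,
                      var_block = 0, var_trial = 0,
                      trials = data.frame(location = "Est", year = 2019),
                      spatial = list(sigma2_e = 2, rho_row = 0.6,
                                     rho_col = 0.6, sigma2_nugget = 0),
                      trait_mean = 0, seed = 100 + s)
    sim <- simulate_dataset(cfg)
    p <- sim$plots
    idx <- match(paste(p$row, p$col + 1), paste(p$row, p$col))
    ok <- !is.na(idx)
    covs <- c(covs, p$TY[ok] * p$TY[idx[ok]])
    vars <- c(vars, p$TY^2)
  }
  expect_equal(mean(covs), 2 * 0.6, tolerance = 0.15)
  expect_equal(mean(vars), 2, tolerance = 0.15)
})

test_that("hybrid dosages are determined by the cross plan", {
  ks <- kernel_set()
  X1 <- hybrid_dosages(ks$geno, ks$cp)
  X2 <- hybrid_dosages(ks$geno, ks$cp)
  expect_identical(X1, X2)
  i <- 5
  expect_equal(unname(X1[i, ]),
               unname((ks$geno[ks$cp$parent1[i], ] +
                         ks$geno[ks$cp$parent2[i], ]) / 2))
  bad <- ks$cp
  bad$parent1[1] <- "NOPE"
  expect_error(hybrid_dosages(ks$geno, bad), "NOPE")
})

test_that("model-scale BLUE simulation reproduces its own bookkeeping", {
  ks <- kernel_set()
  sb <- simulate_blues(ks$cp, ks$Gp, ks$Gh, ks$D, trials = c("T1", "T2"),
                       varcomps = list(sigma2_gca = 1, sigma2_gxt = 0.3,
                                       sigma2_sca = 0.2, sigma2_delta = 0.2),
                       beta = c(5, 7), se = 0.5, seed = 4)
  expect_equal(nrow(sb$blues), 2L * nrow(ks$cp))
  expect_true(all(sb$blues$se == 0.5))
  sb2 <- simulate_blues(ks$cp, ks$Gp, ks$Gh, ks$D, trials = c("T1", "T2"),
                        varcomps = list(sigma2_gca = 1, sigma2_gxt = 0.3,
                                        sigma2_sca = 0.2, sigma2_delta = 0.2),
                        beta = c(5, 7), se = 0.5, seed = 4)
  expect_identical(sb$blues, sb2$blues)
})
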