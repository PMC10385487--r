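## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

## Small full dataset: 40 parents, 60 hybrids, 4 trials, all variance
## components active.
tiny_sim <- function() {
  if (is.null(.fixtures$tiny_sim)) {
    cfg <- sim_config(n_founders = 8, n_parents = 40, n_snps = 120,
                      n_chromosomes = 4, n_hybrids = 60,
                      var_gca = 1, var_sca = 0.3, var_gxt = 0.2,
                      var_delta = 0.3, var_block = 0.2, var_trial = 1,
                      spatial = list(sigma2_e = 0.4, rho_row = 0.4,
                                     rho_col = 0.4, sigma2_nugget = 0.3),
                      trait_mean = 45, seed = 7)
    .fixtures$tiny_sim <- simulate_dataset(cfg)
  }
  .fixtures$tiny_sim
}

## Kernel set for stage-2 tests: 24 parents, 60 hybrids.
kernel_set <- function() {
  if (is.null(.fixtures$kernel_set)) {
    cfg <- sim_config(n_founders = 8, n_parents = 24, n_snps = 80,
                      n_chromosomes = 4, n_hybrids = 60, seed = 21)
    founders <- simulate_founders(cfg)
    geno <- simulate_inbreds(founders, cfg)
    cp <- simulate_crossplan(geno, cfg)
    Xh <- hybrid_dosages(geno, cp)
    .fixtures$kernel_set <- list(
      geno = geno, cp = cp, Xh = Xh,
      Gp = grm_vanraden(geno), Gh = grm_vanraden(Xh),
      D = dominance_matrix(Xh))
  }
  .fixtures$kernel_set
}

## Independent REML log-likelihood evaluator used as a grid-search oracle:
## direct dense formula with base solve()/determinant(), sharing no code
## with the package's engine.
reml_ll_direct <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ldX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  -0.5 * ((n - p) * log(2 * pi) + ldV + ldX +
            as.numeric(t(r) %*% Vi %*% r))
}

## Iteratively refined grid maximization of a 1- or 2-parameter REML
## surface; `Vfun(par)` builds V from the natural parameter vector and
## `trans` marks each parameter as "log" or "rho".
grid_max_ll <- function(y, X, Vfun, lower, upper, rounds = 4, npts = 31) {
  k <- length(lower)
  best <- -Inf
  lo <- lower
  hi <- upper
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(k), function(j) seq(lo[j], hi[j], length.out = npts))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, function(p) {
      V <- Vfun(p)
      out <- tryCatch(reml_ll_direct(y, X, V), error = function(e) -Inf)
      if (!is.finite(out)) -Inf else out
    })
    i <- which.max(vals)
    best <- max(best, vals[i])
    centre <- pts[i, ]
    span <- (hi - lo) / (npts - 1)
    lo <- pmax(lower, centre - 2 * span)
    hi <- pmin(upper, centre + 2 * span)
  }
  best
}
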