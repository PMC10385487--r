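## Synthetic hybrid-breeding data generator.
##
## Emulates a diploid hybrid breeding population: a small founder set, fully
## homozygous inbred parent lines built as founder mosaics, a sparse crossing
## plan over two nursery years, and multi-trial plot phenotypes with additive
## (GCA), dominance (SCA), genotype-by-trial and spatially correlated
## residual components, all with recorded ground truth.

#' Configuration for the synthetic data generator
#'
#' Default values describe the emulated study population: 16 founders,
#' 456 genotyped homozygous inbred parents scored at 704 biallelic SNPs on
#' 12 chromosomes, 769 hybrids from a sparse mating design with a thin
#' intersect of hybrids shared between the two trial years, and four field
#' trials (two locations by two years), each a randomized complete block
#' design with two replicates per hybrid. Variance defaults are on the scale
#' of the total-yield trait (Mg/ha).
#'
#' @param n_founders Number of founder genotypes.
#' @param n_parents Number of homozygous inbred parent lines.
#' @param n_snps Number of biallelic SNPs.
#' @param n_chromosomes Number of chromosomes the SNPs are split across.
#' @param mosaic_switch_prob Per-adjacent-SNP probability that an inbred's
#'   founder-haplotype donor switches (geometric mosaic segment lengths).
#' @param n_hybrids Number of hybrid crosses.
#' @param shared_fraction Fraction of hybrids planted in both trial years.
#' @param trials Data frame with columns `location`, `year`, and optionally
#'   `n_rows`, `n_cols` (field grid; near-square by default) and `n_blocks`.
#' @param var_gca Variance of true parental GCA values.
#' @param var_sca Variance of true hybrid SCA values.
#' @param var_gxt Variance of true hybrid-by-trial deviations.
#' @param var_delta Variance of the IID genetic residual per hybrid.
#' @param var_block Variance of random block effects within trials.
#' @param var_trial Variance of trial mean deviations around `trait_mean`.
#' @param spatial List with `sigma2_e`, `rho_row`, `rho_col`,
#'   `sigma2_nugget` describing the AR1xAR1-plus-nugget plot error.
#' @param trait_mean Grand mean of the simulated trait.
#' @param trait Trait label used for the phenotype column.
#' @param seed Integer seed; every generator operation derives its stream
#'   from it, so a configuration regenerates identical data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 16L, n_parents = 456L, n_snps = 704L,
                       n_chromosomes = 12L, mosaic_switch_prob = 0.05,
                       n_hybrids = 769L, shared_fraction = 0.056,
                       trials = default_trials(),
                       var_gca = 7.4, var_sca = 3.0, var_gxt = 7.8,
                       var_delta = 5.3, var_block = 2, var_trial = 10,
                       spatial = list(sigma2_e = 8, rho_row = 0.5,
                                      rho_col = 0.5, sigma2_nugget = 4),
                       trait_mean = 45, trait = "TY", seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_parents = as.integer(n_parents),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              mosaic_switch_prob = mosaic_switch_prob,
              n_hybrids = as.integer(n_hybrids),
              shared_fraction = shared_fraction, trials = trials,
              var_gca = var_gca, var_sca = var_sca, var_gxt = var_gxt,
              var_delta = var_delta, var_block = var_block,
              var_trial = var_trial, spatial = spatial,
              trait_mean = trait_mean, trait = trait,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  vars <- c(cfg$var_gca, cfg$var_sca, cfg$var_gxt, cfg$var_delta,
            cfg$var_block, cfg$var_trial, spatial$sigma2_e,
            spatial$sigma2_nugget)
  if (any(vars < 0)) stop("all variance components must be non-negative")
  if (abs(spatial$rho_row) >= 1 || abs(spatial$rho_col) >= 1)
    stop("spatial autocorrelations must satisfy |rho| < 1")
  if (cfg$mosaic_switch_prob < 0 || cfg$mosaic_switch_prob > 1)
    stop("mosaic_switch_prob must lie in [0, 1]")
  if (cfg$n_founders < 2L || cfg$n_snps < 1L || cfg$n_parents < 2L)
    stop("invalid population counts")
  if (cfg$n_hybrids > cfg$n_parents * (cfg$n_parents - 1) / 2)
    stop("n_hybrids exceeds the number of distinct parent pairs")
  if (!all(c("location", "year") %in% names(cfg$trials)))
    stop("trials must have 'location' and 'year' columns")
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_trials <- function() {
  data.frame(location = rep(c("Est", "Heelsum"), 2),
             year = rep(c(2019L, 2020L), each = 2),
             stringsAsFactors = FALSE)
}

.seed_stage <- function(cfg, offset)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + offset)

#' Simulate founder haplotypes
#'
#' Draws per-SNP alternate allele frequencies uniformly on `[0.1, 0.9]` and
#' samples two haplotypes per founder; any SNP monomorphic across the founder
#' haplotypes is resampled so every marker segregates in the founder pool.
#'
#' @param cfg A [sim_config()].
#' @return List with `haplotypes` (a `2*n_founders x n_snps` 0/1 matrix),
#'   `freq`, `chrom` (chromosome index per SNP) and `snp_ids`.
#' @export
simulate_founders <- function(cfg) {
  .seed_stage(cfg, 0L)
  nf <- cfg$n_founders; ns <- cfg$n_snps
  freq <- stats::runif(ns, 0.1, 0.9)
  H <- matrix(stats::rbinom(2L * nf * ns, 1L, rep(freq, each = 2L * nf)),
              nrow = 2L * nf)
  mono <- which(colSums(H) %in% c(0L, 2L * nf))
  guard <- 0L
  while (length(mono)) {
    guard <- guard + 1L
    if (guard > 1000L) stop("could not make all founder SNPs polymorphic")
    freq[mono] <- stats::runif(length(mono), 0.1, 0.9)
    H[, mono] <- stats::rbinom(2L * nf * length(mono), 1L,
                               rep(freq[mono], each = 2L * nf))
    mono <- which(colSums(H) %in% c(0L, 2L * nf))
  }
  snp_ids <- sprintf("S%04d", seq_len(ns))
  colnames(H) <- snp_ids
  rownames(H) <- paste0("F", rep(seq_len(nf), each = 2L), "_h", rep(1:2, nf))
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), ns))
  list(haplotypes = H, freq = freq, chrom = chrom, snp_ids = snp_ids)
}

#' Simulate fully homozygous inbred parent lines
#'
#' Each parent is a homozygous mosaic of founder haplotypes: along every
#' chromosome the donor haplotype follows a first-order Markov chain that
#' switches to a different donor with probability `mosaic_switch_prob` per
#' adjacent SNP, and the line carries two identical copies of the mosaic.
#' All dosages are therefore 0 or 2.
#'
#' @param founders Output of [simulate_founders()].
#' @param cfg A [sim_config()].
#' @return Dosage matrix (`n_parents x n_snps`, values 0/2) with the number
#'   of realized donor switches per line in attribute `n_switches`.
#' @export
simulate_inbreds <- function(founders, cfg) {
  .seed_stage(cfg, 1L)
  H <- founders$haplotypes
  nh <- nrow(H); ns <- ncol(H)
  chrom <- founders$chrom
  g <- matrix(0L, cfg$n_parents, ns,
              dimnames = list(sprintf("P%04d", seq_len(cfg$n_parents)),
                              colnames(H)))
  nsw <- integer(cfg$n_parents)
  p <- cfg$mosaic_switch_prob
  for (i in seq_len(cfg$n_parents)) {
    donor <- integer(ns)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      d <- sample.int(nh, 1L)
      sw <- stats::runif(length(idx) - 1L) < p
      for (j in seq_along(idx)) {
        if (j > 1L && sw[j - 1L]) {
          d_new <- sample.int(nh - 1L, 1L)
          d <- if (d_new >= d) d_new + 1L else d_new
          nsw[i] <- nsw[i] + 1L
        }
        donor[idx[j]] <- d
      }
    }
    g[i, ] <- 2L * H[cbind(donor, seq_len(ns))]
  }
  attr(g, "n_switches") <- nsw
  g
}

#' Simulate a sparse crossing plan
#'
#' Samples distinct unordered parent pairs (no self-crosses) from the full
#' crossing space and assigns each hybrid a nursery year; a configurable
#' fraction of hybrids is shared between the two trial years, emulating a
#' thin between-year intersect.
#'
#' @param parents Parent dosage matrix or character vector of parent IDs.
#' @param cfg A [sim_config()].
#' @return Data frame of class `crossplan` with columns `hybrid_id`,
#'   `parent1`, `parent2`, `nursery` and `shared`.
#' @export
simulate_crossplan <- function(parents, cfg) {
  .seed_stage(cfg, 2L)
  ids <- if (is.matrix(parents)) rownames(parents) else as.character(parents)
  np <- length(ids)
  n_pairs <- np * (np - 1) / 2
  if (cfg$n_hybrids > n_pairs)
    stop("requested ", cfg$n_hybrids, " hybrids but only ", n_pairs,
         " distinct parent pairs exist")
  sel <- sample.int(n_pairs, cfg$n_hybrids)
  ## map linear index to (i, j), i < j, in column-major pair order
  j <- ceiling((1 + sqrt(1 + 8 * sel)) / 2)
  i <- sel - (j - 1) * (j - 2) / 2
  low <- which(i < 1)                      # floating-point boundary guards
  if (length(low)) {
    j[low] <- j[low] - 1
    i[low] <- sel[low] - (j[low] - 1) * (j[low] - 2) / 2
  }
  high <- which(i > j - 1)
  if (length(high)) {
    j[high] <- j[high] + 1
    i[high] <- sel[high] - (j[high] - 1) * (j[high] - 2) / 2
  }
  years <- sort(unique(cfg$trials$year))
  nursery <- sample(rep_len(years, cfg$n_hybrids))
  shared <- logical(cfg$n_hybrids)
  n_shared <- round(cfg$shared_fraction * cfg$n_hybrids)
  if (n_shared > 0L && length(years) > 1L)
    shared[sample.int(cfg$n_hybrids, n_shared)] <- TRUE
  cp <- data.frame(hybrid_id = sprintf("H%04d", seq_len(cfg$n_hybrids)),
                   parent1 = ids[i], parent2 = ids[j],
                   nursery = nursery, shared = shared,
                   stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(paste(pmin(cp$parent1, cp$parent2),
                                 pmax(cp$parent1, cp$parent2))),
            all(cp$parent1 != cp$parent2))
  class(cp) <- c("crossplan", "data.frame")
  cp
}

#' Hybrid SNP dosages from homozygous parents
#'
#' With fully homozygous parents a hybrid's genotype is determined by the
#' cross: its dosage at each SNP is the mean of the two parental dosages.
#'
#' @param genotypes Parent dosage matrix.
#' @param crossplan A crossplan data frame.
#' @return Dosage matrix (hybrids x SNPs).
#' @export
hybrid_dosages <- function(genotypes, crossplan) {
  miss <- setdiff(unique(c(crossplan$parent1, crossplan$parent2)),
                  rownames(genotypes))
  if (length(miss))
    stop("parents missing from the genotype matrix: ",
         paste(miss, collapse = ", "))
  X <- (genotypes[crossplan$parent1, , drop = FALSE] +
          genotypes[crossplan$parent2, , drop = FALSE]) / 2
  rownames(X) <- crossplan$hybrid_id
  X
}

## Internal: rescale a vector so its sample variance is exactly v (zero out
## when v == 0); makes parameter-recovery checks on realized components sharp.
.rescale_var <- function(x, v) {
  if (v <= 0 || length(x) < 2L) return(rep(0, length(x)))
  sdx <- stats::sd(x)
  if (sdx == 0) return(rep(0, length(x)))
  (x - mean(x)) * sqrt(v) / sdx
}

## Internal: draw one AR1xAR1 field surface (rows x cols), unit marginal
## variance scaled by sqrt(sigma2).
.sim_field <- function(n_rows, n_cols, sigma2, rho_r, rho_c) {
  if (sigma2 <= 0) return(matrix(0, n_rows, n_cols))
  Lr <- t(chol(ar1_matrix(n_rows, rho_r)))
  Lc <- chol(ar1_matrix(n_cols, rho_c))
  sqrt(sigma2) * (Lr %*% matrix(stats::rnorm(n_rows * n_cols), n_rows) %*% Lc)
}

#' Simulate plot-level phenotypes with known ground truth
#'
#' Generates per-plot trait values for every trial in the configuration.
#' True parental GCA values come from Gaussian per-SNP additive effects
#' rescaled so their realized variance equals `var_gca` exactly; true hybrid
#' SCA values come from per-SNP dominance effects (Vitezica coding) rescaled
#' to `var_sca`; hybrid-by-trial deviations are drawn from
#' `N(0, var_gxt * Gh)` with `Gh` the simulated hybrids' own additive
#' kinship, then rescaled per trial. Each trial is laid out as a randomized
#' complete block design with two replicates on a row-by-column grid, with
#' random block effects, an AR1xAR1 spatial error surface, and an
#' independent nugget.
#'
#' Hybrids whose parents are absent from the genotype matrix are dropped
#' with a warning (emulating partially genotyped parent panels).
#'
#' @param genotypes Parent dosage matrix.
#' @param crossplan A crossplan data frame.
#' @param cfg A [sim_config()].
#' @return List with `plots` (the plot table: trial, location, year, row,
#'   col, block, hybrid_id, trait value) and `truth` (true GCA/SCA/GxT
#'   values, block and trial effects, realized variance components, seed).
#' @export
simulate_phenotypes <- function(genotypes, crossplan, cfg) {
  .seed_stage(cfg, 3L)
  have <- crossplan$parent1 %in% rownames(genotypes) &
    crossplan$parent2 %in% rownames(genotypes)
  if (!all(have)) {
    warning(sum(!have), " hybrid(s) dropped: parent genotypes missing")
    crossplan <- crossplan[have, , drop = FALSE]
  }
  if (!nrow(crossplan)) stop("no hybrids with complete parent genotypes")
  Xh <- hybrid_dosages(genotypes, crossplan)
  hybrids <- crossplan$hybrid_id
  parents <- rownames(genotypes)

  ## true GCA: marker additive effects, realized variance pinned at var_gca
  a_eff <- stats::rnorm(ncol(genotypes))
  pbar <- colMeans(genotypes) / 2
  g_raw <- drop(sweep(genotypes, 2, 2 * pbar) %*% a_eff) / 2
  gca <- stats::setNames(.rescale_var(g_raw, cfg$var_gca), parents)

  ## true SCA: per-locus dominance effects on the hybrids' dosages
  ph <- colMeans(Xh) / 2
  W <- matrix(0, nrow(Xh), ncol(Xh))
  Xr <- round(Xh)
  for (dose in 0:2) {
    code <- switch(as.character(dose), "0" = -2 * ph^2,
                   "1" = 2 * ph * (1 - ph), "2" = -2 * (1 - ph)^2)
    idx <- Xr == dose
    W[idx] <- matrix(code, nrow(Xh), ncol(Xh), byrow = TRUE)[idx]
  }
  d_eff <- stats::rnorm(ncol(Xh))
  sca <- stats::setNames(.rescale_var(drop(W %*% d_eff), cfg$var_sca), hybrids)

  ## hybrid-by-trial deviations ~ N(0, var_gxt * Gh), rescaled per trial
  trials <- cfg$trials
  trial_id <- paste0(substr(trials$location, 1, 1), trials$year %% 100)
  n_tr <- nrow(trials)
  gxt <- matrix(0, length(hybrids), n_tr, dimnames = list(hybrids, trial_id))
  if (cfg$var_gxt > 0) {
    Gh <- grm_vanraden(Xh)
    Lh <- t(chol(Gh + diag(1e-6, nrow(Gh))))
    for (f in seq_len(n_tr))
      gxt[, f] <- .rescale_var(drop(Lh %*% stats::rnorm(length(hybrids))),
                               cfg$var_gxt)
  }

  ## IID genetic residual per hybrid (shared across that hybrid's trials)
  delta <- stats::setNames(.rescale_var(stats::rnorm(length(hybrids)),
                                        cfg$var_delta), hybrids)

  trial_mean <- cfg$trait_mean +
    .rescale_var(stats::rnorm(n_tr), cfg$var_trial)
  names(trial_mean) <- trial_id

  plot_rows <- list()
  block_eff <- list()
  for (f in seq_len(n_tr)) {
    in_trial <- crossplan$nursery == trials$year[f] | crossplan$shared
    ht <- hybrids[in_trial]
    if (!length(ht)) next
    n_blocks <- if (!is.null(trials$n_blocks)) trials$n_blocks[f] else 2L
    n_plots <- n_blocks * length(ht)
    nc <- if (!is.null(trials$n_cols) && !is.na(trials$n_cols[f]))
      trials$n_cols[f] else ceiling(sqrt(n_plots))
    nr <- if (!is.null(trials$n_rows) && !is.na(trials$n_rows[f]))
      trials$n_rows[f] else ceiling(n_plots / nc)
    if (nr * nc < n_plots) stop("field grid too small for trial ", trial_id[f])
    cells <- data.frame(row = rep(seq_len(nr), each = nc),
                        col = rep(seq_len(nc), nr))[seq_len(n_plots), ]
    block <- rep(seq_len(n_blocks), each = length(ht))
    hyb <- unlist(lapply(seq_len(n_blocks), function(b) sample(ht)))
    be <- stats::rnorm(n_blocks, 0, sqrt(cfg$var_block))
    block_eff[[trial_id[f]]] <- be
    E <- .sim_field(nr, nc, cfg$spatial$sigma2_e, cfg$spatial$rho_row,
                    cfg$spatial$rho_col)
    nug <- stats::rnorm(n_plots, 0, sqrt(cfg$spatial$sigma2_nugget))
    gi <- gca[crossplan$parent1[match(hyb, hybrids)]] +
      gca[crossplan$parent2[match(hyb, hybrids)]]
    y <- trial_mean[f] + be[block] + unname(gi) + sca[hyb] + delta[hyb] +
      gxt[hyb, f] + E[cbind(cells$row, cells$col)] + nug
    plot_rows[[trial_id[f]]] <- data.frame(
      trial = trial_id[f], location = trials$location[f],
      year = trials$year[f], row = cells$row, col = cells$col,
      block = block, hybrid_id = hyb, value = unname(y),
      stringsAsFactors = FALSE)
  }
  plots <- do.call(rbind, plot_rows)
  rownames(plots) <- NULL
  names(plots)[names(plots) == "value"] <- cfg$trait

  truth <- list(gca = gca, sca = sca, gxt = gxt, delta = delta,
                trial_mean = trial_mean, block_effects = block_eff,
                realized = c(var_gca = stats::var(gca),
                             var_sca = stats::var(sca),
                             var_delta = stats::var(delta)),
                dropped = sum(!have), seed = cfg$seed, trait = cfg$trait)
  list(plots = plots, truth = truth)
}

#' Run the whole generator
#'
#' Convenience wrapper chaining founders, inbred parents, crossing plan and
#' phenotypes.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes`, `crossplan`, `plots`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  founders <- simulate_founders(cfg)
  genotypes <- simulate_inbreds(founders, cfg)
  crossplan <- simulate_crossplan(genotypes, cfg)
  ph <- simulate_phenotypes(genotypes, crossplan, cfg)
  list(genotypes = genotypes, crossplan = crossplan, plots = ph$plots,
       truth = ph$truth, config = cfg)
}

#' Simulate second-stage observations directly from the combining-ability model
#'
#' Draws true effects exactly from the model used by the second stage:
#' `g ~ N(0, s2_gca * Gp)`, `s ~ N(0, s2_sca * D)`,
#' `delta ~ N(0, s2_delta * I)`, independent per-trial
#' `t_f ~ N(0, s2_gxt * Gh)`, and an observation per hybrid-by-trial cell
#' `y = beta_f + g_i + g_j + s + delta + t_f + e` with `e ~ N(0, se^2)`.
#' Intended for parameter-recovery studies, where the realized effects must
#' be genuine draws from the assumed kernels.
#'
#' @param crossplan Crossplan data frame (hybrids and their parents).
#' @param Gp,Gh Additive relationship matrices of parents and hybrids.
#' @param D Optional dominance relationship matrix (NULL means no SCA).
#' @param trials Character vector of trial labels.
#' @param varcomps Named list/vector with `sigma2_gca`, `sigma2_gxt`,
#'   `sigma2_sca`, `sigma2_delta`.
#' @param beta Trial intercepts (recycled to the number of trials).
#' @param se Residual standard error attached to every observation.
#' @param seed Integer seed.
#' @return List with `blues` (trial, hybrid, blue, se) and `truth`.
#' @export
simulate_blues <- function(crossplan, Gp, Gh, D = NULL,
                           trials = c("E19", "H19", "E20", "H20"),
                           varcomps = list(sigma2_gca = 1, sigma2_gxt = 0.5,
                                           sigma2_sca = 0, sigma2_delta = 0.5),
                           beta = 0, se = 1, seed = 1L) {
  set.seed(seed)
  vc <- varcomps
  hybrids <- crossplan$hybrid_id
  parents <- rownames(Gp)
  rmvk <- function(K, s2) {
    if (s2 <= 0) return(rep(0, nrow(K)))
    drop(t(chol(K + diag(1e-8, nrow(K)))) %*% stats::rnorm(nrow(K))) * sqrt(s2)
  }
  g <- stats::setNames(rmvk(Gp, vc$sigma2_gca), parents)
  s <- if (!is.null(D)) stats::setNames(rmvk(D, vc$sigma2_sca), rownames(D))
  else stats::setNames(rep(0, length(hybrids)), hybrids)
  delta <- stats::setNames(stats::rnorm(length(hybrids), 0,
                                        sqrt(vc$sigma2_delta)), hybrids)
  tmat <- vapply(trials, function(f) rmvk(Gh, vc$sigma2_gxt),
                 numeric(nrow(Gh)))
  rownames(tmat) <- rownames(Gh)
  beta <- rep_len(beta, length(trials))
  names(beta) <- trials
  obs <- expand.grid(hybrid_id = hybrids, trial = trials,
                     stringsAsFactors = FALSE)
  i <- match(obs$hybrid_id, hybrids)
  se_v <- rep_len(se, nrow(obs))
  mu <- beta[obs$trial] + g[crossplan$parent1[i]] + g[crossplan$parent2[i]] +
    s[obs$hybrid_id] + delta[obs$hybrid_id] +
    tmat[cbind(obs$hybrid_id, obs$trial)]
  blues <- data.frame(trial = obs$trial, hybrid_id = obs$hybrid_id,
                      blue = unname(mu) + stats::rnorm(nrow(obs), 0, se_v),
                      se = se_v, stringsAsFactors = FALSE)
  list(blues = blues,
       truth = list(gca = g, sca = s, delta = delta, gxt = tmat,
                    beta = beta, varcomps = vc))
}
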