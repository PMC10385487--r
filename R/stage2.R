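## Stage 2: weighted combining-ability models on stage-1 BLUEs.
##
## GCA model: trial intercepts + parental GCA (kernel Gp, entering once per
## parent of each cross), an IID genetic residual per hybrid, a
## hybrid-by-trial term with kernel I_t (x) Gh, and a known-diagonal
## residual fixed at the squared stage-1 standard errors.  The GCA+SCA model
## adds an SCA term with the dominance kernel D while holding sigma2_gca and
## sigma2_gxt at the GCA model's estimates (two-step constrained
## estimation), so the extra dominance variance is partitioned out of the
## genetic residual rather than absorbed from the additive terms.

#' Known-diagonal residual structure from stage-1 standard errors
#'
#' Each second-stage observation's residual variance is fixed at the squared
#' standard error of its stage-1 BLUE; nothing is rescaled, the residual
#' variance is treated as known.
#'
#' @param blues BLUE table with a positive `se` column.
#' @return A `resid_known` structure.
#' @export
build_weights <- function(blues) {
  if (!"se" %in% names(blues) || anyNA(blues$se))
    stop("BLUE table must carry a complete 'se' column")
  if (any(blues$se <= 0)) stop("stage-1 standard errors must be positive")
  resid_known(blues$se^2)
}

## Internal: design pieces shared by the two combining models.
.stage2_parts <- function(blues, crossplan, Gp, Gh) {
  idx <- match(blues$hybrid_id, crossplan$hybrid_id)
  if (anyNA(idx))
    stop("BLUE table hybrids missing from the cross plan: ",
         paste(unique(blues$hybrid_id[is.na(idx)]), collapse = ", "))
  p1 <- crossplan$parent1[idx]
  p2 <- crossplan$parent2[idx]
  parents <- rownames(Gp)
  genotyped <- p1 %in% parents & p2 %in% parents
  if (!all(genotyped)) {
    message(sum(!genotyped), " observation(s) excluded: ungenotyped parent")
    blues <- blues[genotyped, , drop = FALSE]
    p1 <- p1[genotyped]; p2 <- p2[genotyped]
  }
  if (!nrow(blues)) stop("no observations with genotyped parents")
  n <- nrow(blues)
  Zg <- matrix(0, n, length(parents), dimnames = list(NULL, parents))
  Zg[cbind(seq_len(n), match(p1, parents))] <-
    Zg[cbind(seq_len(n), match(p1, parents))] + 1
  Zg[cbind(seq_len(n), match(p2, parents))] <-
    Zg[cbind(seq_len(n), match(p2, parents))] + 1
  hybs <- rownames(Gh)
  miss_h <- setdiff(unique(blues$hybrid_id), hybs)
  if (length(miss_h))
    stop("hybrids missing from the hybrid kernel: ",
         paste(miss_h, collapse = ", "))
  trials <- sort(unique(blues$trial))
  tlev <- as.vector(outer(hybs, trials, function(h, f) paste(f, h, sep = ":")))
  Zt <- incidence(paste(blues$trial, blues$hybrid_id, sep = ":"), levels = tlev)
  Kt <- kronecker(diag(length(trials)), Gh)
  dimnames(Kt) <- list(tlev, tlev)
  X <- incidence(blues$trial, levels = trials)
  colnames(X) <- paste0("trial:", trials)
  all_h <- crossplan$hybrid_id
  Zd <- incidence(blues$hybrid_id, levels = all_h)
  list(blues = blues, X = X, Zg = Zg, Zd = Zd, Zt = Zt, Kt = Kt,
       trials = trials, hybs = hybs)
}

## Internal: package a combining fit.
.combining_fit <- function(fit, parts, model) {
  est <- fit$estimates
  tmat <- matrix(fit$u$gxt[as.vector(outer(parts$hybs, parts$trials,
                                           function(h, f) paste(f, h, sep = ":")))],
                 nrow = length(parts$hybs),
                 dimnames = list(parts$hybs, parts$trials))
  vc <- c(sigma2_gca = est[["sigma2_gca"]],
          sigma2_gxt = est[["sigma2_gxt"]],
          sigma2_sca = if ("sigma2_sca" %in% names(est)) est[["sigma2_sca"]] else 0,
          sigma2_delta = est[["sigma2_delta"]])
  structure(list(fit = fit, model = model, varcomps = vc,
                 fixed = attr(est, "fixed"),
                 beta = fit$beta, gca = fit$u$gca,
                 sca = if (model == "GCA+SCA") fit$u$sca else NULL,
                 delta = fit$u$delta, gxt = tmat,
                 trials = parts$trials, loglik = fit$loglik,
                 converged = fit$converged),
            class = "combining_fit")
}

#' Fit the GCA combining-ability model on stage-1 BLUEs
#'
#' @param blues BLUE table (`trial`, `hybrid_id`, `blue`, `se`).
#' @param crossplan Cross plan mapping hybrids to parent pairs.
#' @param Gp Additive relationship matrix of the parents (the GCA kernel; a
#'   single parent-effect vector enters additively, once per parent of each
#'   cross).
#' @param Gh Additive relationship matrix of the hybrids (the
#'   genotype-by-trial kernel is `I_t` Kronecker `Gh`).
#' @param control Optimizer control.
#' @return A `combining_fit` with GCA BLUPs for every parent in `Gp`
#'   (including unphenotyped ones), hybrid-by-trial BLUPs for every hybrid
#'   in `Gh`, genetic-residual BLUPs, trial intercepts and variance
#'   components.
#' @export
fit_gca <- function(blues, crossplan, Gp, Gh, control = reml_control()) {
  parts <- .stage2_parts(blues, crossplan, Gp, Gh)
  random <- list(rand_term(parts$Zg, Gp, name = "gca"),
                 rand_term(parts$Zd, NULL, name = "delta"),
                 rand_term(parts$Zt, parts$Kt, name = "gxt"))
  fit <- reml_fit(parts$blues$blue, parts$X, random = random,
                  residual = build_weights(parts$blues), control = control)
  .combining_fit(fit, parts, "GCA")
}

#' Fit the GCA+SCA combining-ability model
#'
#' Adds a specific combining ability term with the dominance kernel `D` to
#' the GCA model, holding `sigma2_gca` and `sigma2_gxt` fixed at the GCA
#' model's estimates (the constrained two-step procedure); only the SCA and
#' genetic-residual variances are re-estimated.
#'
#' @inheritParams fit_gca
#' @param D Dominance relationship matrix over the hybrids.
#' @param gca_fit The converged `combining_fit` from [fit_gca()].
#' @return A `combining_fit` whose `sigma2_gca` and `sigma2_gxt` equal the
#'   first-step estimates exactly.
#' @export
fit_gca_sca <- function(blues, crossplan, Gp, Gh, D, gca_fit,
                        control = reml_control()) {
  if (!inherits(gca_fit, "combining_fit") || gca_fit$model != "GCA")
    stop("'gca_fit' must be a fitted GCA model")
  if (!isTRUE(gca_fit$converged))
    stop("the first-step GCA fit did not converge")
  parts <- .stage2_parts(blues, crossplan, Gp, Gh)
  miss_d <- setdiff(unique(parts$blues$hybrid_id), rownames(D))
  if (length(miss_d))
    stop("dominance kernel does not cover hybrids: ",
         paste(miss_d, collapse = ", "))
  Zs <- incidence(parts$blues$hybrid_id, levels = rownames(D))
  random <- list(rand_term(parts$Zg, Gp, name = "gca",
                           fixed = unname(gca_fit$varcomps["sigma2_gca"])),
                 rand_term(Zs, D, name = "sca"),
                 rand_term(parts$Zd, NULL, name = "delta"),
                 rand_term(parts$Zt, parts$Kt, name = "gxt",
                           fixed = unname(gca_fit$varcomps["sigma2_gxt"])))
  fit <- reml_fit(parts$blues$blue, parts$X, random = random,
                  residual = build_weights(parts$blues), control = control)
  .combining_fit(fit, parts, "GCA+SCA")
}

#' Partition of the total genetic variance
#'
#' Computes the proportions of the total genetic variance
#' `sigma2_G = 2 * sigma2_gca + sigma2_sca + sigma2_delta` attributable to
#' additive (GCA), dominance (SCA) and residual genetic effects; the scalar
#' `2 * sigma2_gca` bookkeeping follows the standard combining-ability
#' convention of counting the parental variance once per parent of a cross.
#'
#' @param x A `combining_fit`, or a named list/vector with `sigma2_gca`,
#'   `sigma2_delta` and optionally `sigma2_sca`.
#' @param ... Unused.
#' @return Data frame with `model`, `prop_gca`, `prop_sca`, `prop_delta`
#'   and `sigma2_G`; proportions sum to one.
#' @export
partition_variance <- function(x, ...) UseMethod("partition_variance")

#' @export
partition_variance.combining_fit <- function(x, ...) {
  out <- partition_variance(as.list(x$varcomps))
  out$model <- x$model
  out
}

#' @export
partition_variance.default <- function(x, ...) {
  x <- as.list(x)
  if (is.null(x$sigma2_gca) || is.null(x$sigma2_delta))
    stop("need at least 'sigma2_gca' and 'sigma2_delta'")
  s_sca <- if (is.null(x$sigma2_sca)) 0 else x$sigma2_sca
  sG <- 2 * x$sigma2_gca + s_sca + x$sigma2_delta
  if (sG <= 0) stop("total genetic variance is zero: partition undefined")
  data.frame(model = if (s_sca > 0) "GCA+SCA" else "GCA",
             prop_gca = 2 * x$sigma2_gca / sG,
             prop_sca = s_sca / sG,
             prop_delta = x$sigma2_delta / sG,
             sigma2_G = sG, stringsAsFactors = FALSE)
}

#' Predicted hybrid performance
#'
#' For the AVG target the prediction is the genetic cross value
#' `g_i + g_j (+ s_ij)`; for a per-trial target it is
#' `beta_f + g_i + g_j (+ s_ij) + t_ijf`, with every BLUP available for
#' unphenotyped parents and hybrids through the genomic kernels.
#' Predictions are symmetric in the parent order.
#'
#' @param fit A `combining_fit`.
#' @param crossplan Cross plan rows for the hybrids to predict.
#' @param target `"AVG"` or one of the fitted trial labels.
#' @param hybrids Optional subset of `crossplan$hybrid_id`.
#' @return Named numeric vector of predictions.
#' @export
predict_hybrids <- function(fit, crossplan, target = "AVG", hybrids = NULL) {
  cp <- crossplan
  if (!is.null(hybrids)) {
    cp <- cp[cp$hybrid_id %in% hybrids, , drop = FALSE]
    if (!nrow(cp)) stop("none of the requested hybrids are in the cross plan")
  }
  unknown <- setdiff(unique(c(cp$parent1, cp$parent2)), names(fit$gca))
  if (length(unknown))
    stop("parents absent from the GCA kernel: ",
         paste(unknown, collapse = ", "))
  pred <- unname(fit$gca[cp$parent1] + fit$gca[cp$parent2])
  if (!is.null(fit$sca)) {
    miss <- setdiff(cp$hybrid_id, names(fit$sca))
    if (length(miss))
      stop("hybrids absent from the SCA kernel: ", paste(miss, collapse = ", "))
    pred <- pred + unname(fit$sca[cp$hybrid_id])
  }
  if (!identical(target, "AVG")) {
    if (!target %in% fit$trials)
      stop("unknown trial target '", target, "'")
    miss <- setdiff(cp$hybrid_id, rownames(fit$gxt))
    if (length(miss))
      stop("hybrids absent from the hybrid-by-trial kernel: ",
           paste(miss, collapse = ", "))
    pred <- pred + unname(fit$beta[paste0("trial:", target)]) +
      unname(fit$gxt[cp$hybrid_id, target])
  }
  stats::setNames(pred, cp$hybrid_id)
}
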