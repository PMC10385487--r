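## Raw-data multi-trial model: fixed trial intercepts and within-trial
## blocks, a hybrid-by-location term with unstructured covariance across
## locations, and IID residual.  Supplies across-trial hybrid BLUPs (the
## AVG prediction target), broad-sense heritabilities and coefficients of
## variation per location.

#' Fit the multi-trial hybrid model
#'
#' Models plot values on fixed trial intercepts and within-trial block
#' contrasts, a random hybrid-by-location effect with an unstructured
#' covariance across locations (separate hybrid variance per location plus
#' their covariance), and an IID residual.
#'
#' @param plots Plot table with columns `trial`, `location`, `block`,
#'   `hybrid_id` and the trait.
#' @param trait Name of the trait column.
#' @param control Optimizer control, see [reml_control()].
#' @return List of class `multitrial_fit`: `fit` (the underlying
#'   `reml_fit`), `Sigma_a` (location covariance of hybrid effects),
#'   `sigma2_eps`, `loc_means`, `grand_mean`, `blups` (hybrids x locations),
#'   `avg_blup` (across-location mean BLUP per hybrid), `intercept` (mean
#'   trial intercept).
#' @export
fit_multitrial <- function(plots, trait, control = reml_control()) {
  locs <- sort(unique(plots$location))
  if (length(locs) < 2L)
    stop("multi-trial model needs at least two locations; ",
         "use the single-trial path instead")
  y <- plots[[trait]]
  Xf <- incidence(plots$trial)
  colnames(Xf) <- paste0("trial:", colnames(Xf))
  Xb_parts <- lapply(sort(unique(plots$trial)), function(tr) {
    sel <- which(plots$trial == tr)
    blocks <- sort(unique(plots$block[sel]))
    if (length(blocks) < 2L) return(NULL)
    C <- stats::contr.sum(length(blocks))
    Zb <- matrix(0, nrow(plots), length(blocks))
    Zb[sel, ] <- incidence(plots$block[sel], levels = as.character(blocks))
    M <- Zb %*% C
    colnames(M) <- paste0("block:", tr, ":", blocks[-length(blocks)])
    M
  })
  X <- do.call(cbind, c(list(Xf), Xb_parts[!vapply(Xb_parts, is.null, TRUE)]))
  hybrids <- sort(unique(plots$hybrid_id))
  term <- rand_us(group = factor(plots$location, levels = locs),
                  unit = plots$hybrid_id, units = hybrids, name = "a")
  fit <- reml_fit(y, X, random = list(term), residual = resid_iid(),
                  control = control)
  Sigma_a <- attr(fit$u$a, "Sigma")
  blups <- fit$u$a
  avg_blup <- rowMeans(blups)
  loc_means <- tapply(y, plots$location, mean)[locs]
  beta_tr <- fit$beta[grepl("^trial:", names(fit$beta))]
  structure(list(fit = fit, Sigma_a = Sigma_a,
                 sigma2_eps = fit$estimates[["sigma2_e"]],
                 loc_means = loc_means, grand_mean = mean(y),
                 blups = blups, avg_blup = avg_blup,
                 intercept = mean(beta_tr), trait = trait),
            class = "multitrial_fit")
}

#' Broad-sense heritability per trial location
#'
#' `H^2 = sigma2_a(loc) / (sigma2_a(loc) + sigma2_eps)` with the location's
#' hybrid variance taken from the unstructured covariance.
#'
#' @param fit A `multitrial_fit`.
#' @param location Location label.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(fit, location) {
  if (!location %in% rownames(fit$Sigma_a))
    stop("unknown location '", location, "'")
  s2a <- fit$Sigma_a[location, location]
  tot <- s2a + fit$sigma2_eps
  if (tot <= 0) stop("total variance is zero: heritability undefined")
  s2a / tot
}

#' Genetic and residual coefficients of variation
#'
#' Inter-genotype coefficients `CVG(loc) = 100 * sigma_a(loc) / mean(loc)`
#' (location mean) and the intra-genotype coefficient
#' `CVeps = 100 * sigma_eps / grand mean`.
#'
#' @param fit A `multitrial_fit`.
#' @return List with `CVG` (named per location, percent) and `CVeps`
#'   (percent).
#' @export
coefficients_of_variation <- function(fit) {
  if (any(fit$loc_means <= 0) || fit$grand_mean <= 0)
    stop("coefficients of variation need positive trait means")
  CVG <- 100 * sqrt(diag(fit$Sigma_a)) / fit$loc_means
  list(CVG = CVG, CVeps = 100 * sqrt(fit$sigma2_eps) / fit$grand_mean)
}

#' Across-trial prediction targets from the multi-trial model
#'
#' The AVG target of the cross-validation scheme: each hybrid's
#' across-location BLUP plus the mean trial intercept, placing the target on
#' the observed trait scale.
#'
#' @param fit A `multitrial_fit`.
#' @return Data frame (`hybrid_id`, `avg`).
#' @export
avg_targets <- function(fit) {
  data.frame(hybrid_id = names(fit$avg_blup),
             avg = unname(fit$avg_blup) + fit$intercept,
             stringsAsFactors = FALSE)
}
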