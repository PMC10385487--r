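## Stage 1: per-trial spatial mixed models, AIC selection, hybrid BLUEs.
##
## The ladder crosses two base models (fixed hybrid + fixed block, optionally
## plus a random column effect) with four residual structures (IID, AR1 along
## columns, AR1 along columns + nugget, AR1 along rows and columns + nugget).

.ladder_bases <- c("1", "2")
.ladder_resids <- c("3", "4", "5", "6")

#' The spatial model ladder
#'
#' @return Data frame enumerating the eight base-by-residual combinations,
#'   labelled `"(base)+(residual)"`: base (1) fixed hybrid and block effects,
#'   base (2) adds a random column effect; residuals (3) IID, (4) AR1 along
#'   columns, (5) AR1 along columns plus nugget, (6) AR1 along rows and
#'   columns plus nugget.
#' @export
ladder_entries <- function() {
  e <- expand.grid(base = .ladder_bases, resid = .ladder_resids,
                   stringsAsFactors = FALSE)
  e$label <- sprintf("(%s)+(%s)", e$base, e$resid)
  e
}

## Internal: fixed-effect design for a single trial: hybrid cell means plus
## sum-to-zero block contrasts, so each hybrid coefficient is its mean over
## blocks.
.stage1_design <- function(dat) {
  Xh <- incidence(dat$hybrid_id)
  colnames(Xh) <- paste0("hybrid:", colnames(Xh))
  blocks <- sort(unique(dat$block))
  if (length(blocks) > 1L) {
    C <- stats::contr.sum(length(blocks))
    Xb <- incidence(dat$block, levels = as.character(blocks)) %*% C
    colnames(Xb) <- paste0("block:", blocks[-length(blocks)])
    X <- cbind(Xh, Xb)
  } else X <- Xh
  X
}

## Internal: residual structure for one ladder entry.
.stage1_residual <- function(resid, dat, fixed = list()) {
  switch(resid,
         "3" = resid_iid(fixed = fixed),
         "4" = resid_ar1_col(dat$row, dat$col, fixed = fixed),
         "5" = resid_ar1_col_nugget(dat$row, dat$col, fixed = fixed),
         "6" = resid_ar1_rowcol_nugget(dat$row, dat$col, fixed = fixed),
         stop("unknown residual structure '", resid, "'"))
}

#' Fit the spatial model ladder for one trial and trait
#'
#' Attempts every requested base-by-residual combination on the plots of a
#' single trial. Entries whose optimizer fails outright are kept with a
#' `NULL` fit and flagged; entries that fit but do not converge are flagged
#' via the fit's `converged` field and excluded later by
#' [select_and_extract()].
#'
#' @param plots Plot table (columns `trial`, `row`, `col`, `block`,
#'   `hybrid_id` and the trait).
#' @param trial Trial label to subset on.
#' @param trait Name of the trait column.
#' @param entries Character vector of ladder labels to fit (default all 8).
#' @param control Optimizer control, see [reml_control()].
#' @return Named list of `reml_fit` objects (or `NULL` for failed entries)
#'   with attribute `trial`/`trait`.
#' @export
fit_ladder <- function(plots, trial, trait, entries = ladder_entries()$label,
                       control = reml_control()) {
  dat <- plots[plots$trial == trial, , drop = FALSE]
  if (!nrow(dat)) stop("no plots for trial '", trial, "'")
  if (!trait %in% names(dat)) stop("no trait column '", trait, "'")
  y <- dat[[trait]]
  X <- .stage1_design(dat)
  lad <- ladder_entries()
  lad <- lad[lad$label %in% entries, , drop = FALSE]
  if (!nrow(lad)) stop("no ladder entries requested")
  fits <- vector("list", nrow(lad))
  names(fits) <- lad$label
  for (k in seq_len(nrow(lad))) {
    random <- list()
    if (lad$base[k] == "2")
      random <- list(rand_term(incidence(dat$col), name = "col"))
    res <- .stage1_residual(lad$resid[k], dat)
    fits[[k]] <- tryCatch(
      reml_fit(y, X, random = random, residual = res, control = control),
      error = function(e) NULL)
  }
  if (all(vapply(fits, is.null, TRUE)))
    stop("all ladder entries failed for trial '", trial, "', trait '",
         trait, "'")
  attr(fits, "trial") <- trial
  attr(fits, "trait") <- trait
  fits
}

#' Select the best ladder entry and extract hybrid BLUEs
#'
#' Drops failed or non-converged entries, picks the remaining fit with the
#' smallest AIC (ties to fewer variance parameters), and returns the hybrid
#' BLUEs with their standard errors from that fit.
#'
#' @param fits Output of [fit_ladder()].
#' @return Data frame (`trial`, `hybrid_id`, `blue`, `se`, `model`).
#' @export
select_and_extract <- function(fits) {
  ok <- !vapply(fits, is.null, TRUE)
  ok[ok] <- vapply(fits[ok], function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("no converged ladder entries to select from")
  cmp <- compare_aic(fits[ok])
  best <- cmp$best
  hsel <- grepl("^hybrid:", names(best$beta))
  data.frame(trial = attr(fits, "trial"),
             hybrid_id = sub("^hybrid:", "", names(best$beta)[hsel]),
             blue = unname(best$beta[hsel]),
             se = unname(best$beta_se[hsel]),
             model = cmp$best_name,
             stringsAsFactors = FALSE)
}

#' Stage-1 BLUEs for every trial
#'
#' Runs [fit_ladder()] and [select_and_extract()] on each trial present in
#' the plot table.
#'
#' @inheritParams fit_ladder
#' @return List with `blues` (stacked BLUE table) and `selection` (the AIC
#'   ranking winner per trial).
#' @export
stage1_blues <- function(plots, trait, entries = ladder_entries()$label,
                         control = reml_control()) {
  trials <- unique(plots$trial)
  out <- lapply(trials, function(tr) {
    fits <- fit_ladder(plots, tr, trait, entries = entries, control = control)
    select_and_extract(fits)
  })
  blues <- do.call(rbind, out)
  rownames(blues) <- NULL
  sel <- unique(blues[, c("trial", "model")])
  rownames(sel) <- NULL
  list(blues = blues, selection = sel)
}

#' Empirical semivariogram of spatial residuals
#'
#' Computes the classical estimator `gamma(h) = mean((r_i - r_j)^2) / 2`
#' over plot pairs grouped by rounded Euclidean distance between field
#' coordinates, a standard diagnostic for remaining spatial trend.
#'
#' @param residuals Numeric residuals, one per plot.
#' @param coords Two-column matrix or data frame of `row`, `col` plot
#'   coordinates.
#' @param max_lag Largest lag distance reported.
#' @return Data frame (`lag`, `gamma`, `n_pairs`); empty lag bins are kept
#'   with `n_pairs = 0` and `gamma = NA`.
#' @export
semivariogram <- function(residuals, coords, max_lag = 10) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(residuals))
    stop("residuals and coordinates differ in length")
  d <- as.matrix(stats::dist(coords))
  lag <- round(d)
  sq <- outer(residuals, residuals, "-")^2 / 2
  ut <- upper.tri(d)
  lags <- seq_len(max_lag)
  gamma <- vapply(lags, function(h) {
    sel <- ut & lag == h
    if (!any(sel)) NA_real_ else mean(sq[sel])
  }, 0)
  n_pairs <- vapply(lags, function(h) sum(ut & lag == h), 0L)
  data.frame(lag = lags, gamma = gamma, n_pairs = n_pairs)
}
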