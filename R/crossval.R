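## Evaluated-parent cross-validation (0EP / 1EP) of the combining models.
##
## Parents are split at random into evaluated and unevaluated sets; hybrids
## inherit their scenario from the number of evaluated parents (two:
## training, one: 1EP test, zero: 0EP test).  The two genetic models are
## refit on the training hybrids only and scored on identical splits, so
## GCA-versus-GCA+SCA comparisons are paired within repetition.

#' Split hybrids by number of evaluated parents
#'
#' Assigns every parent appearing in the cross plan to the evaluated set
#' independently with probability `evaluated_fraction`, then classifies each
#' hybrid by its count of evaluated parents. With a fraction of one half the
#' expected test-to-training size ratios are 1 (0EP) and 0.5 (1EP, per test
#' half).
#'
#' @param crossplan Cross plan data frame.
#' @param seed Integer seed (the split is deterministic given it).
#' @param evaluated_fraction Probability a parent is evaluated.
#' @return List with `evaluated`, `unevaluated` (parent IDs), and hybrid ID
#'   vectors `train`, `ep1`, `ep0`.
#' @export
split_hybrids <- function(crossplan, seed, evaluated_fraction = 0.5) {
  set.seed(seed)
  parents <- sort(unique(c(crossplan$parent1, crossplan$parent2)))
  ev <- parents[stats::runif(length(parents)) < evaluated_fraction]
  n_ev <- (crossplan$parent1 %in% ev) + (crossplan$parent2 %in% ev)
  list(evaluated = ev, unevaluated = setdiff(parents, ev),
       train = crossplan$hybrid_id[n_ev == 2L],
       ep1 = crossplan$hybrid_id[n_ev == 1L],
       ep0 = crossplan$hybrid_id[n_ev == 0L])
}

#' Prediction accuracy
#'
#' Pearson's correlation between true and predicted performance.
#'
#' @param truth,pred Numeric vectors of equal length (at least 3 pairs).
#' @return Correlation coefficient, or `NA` with a warning when either
#'   vector has zero variance.
#' @export
accuracy <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  ok <- is.finite(truth) & is.finite(pred)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(truth[ok]) == 0 || stats::sd(pred[ok]) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(truth[ok], pred[ok])
}

#' Root mean square error scaled by the trait mean
#'
#' `100 * sqrt(mean((y - yhat)^2)) / mu`, reported in percent; `mu` is the
#' mean of the prediction target over all hybrids, so errors are comparable
#' across traits.
#'
#' @param truth,pred Numeric vectors of equal length.
#' @param mu Positive trait mean of the target.
#' @return Scaled RMSE in percent.
#' @export
scaled_rmse <- function(truth, pred, mu) {
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  if (!is.finite(mu) || mu <= 0) stop("'mu' must be positive")
  ok <- is.finite(truth) & is.finite(pred)
  100 * sqrt(mean((truth[ok] - pred[ok])^2)) / mu
}

#' Evaluated-parent cross-validation of the combining models
#'
#' Repeats the parent split `n_reps` times. In every repetition the GCA
#' model (and, if requested, the GCA+SCA model on the same split) is refit
#' on the training hybrids' stage-1 BLUEs only, test hybrids are predicted
#' for each target, and accuracy plus scaled RMSE are recorded. Per-trial
#' targets are scored against the stage-1 BLUEs of the test hybrids in that
#' trial; the AVG target is scored against the across-trial BLUPs (on the
#' observed scale), with the mean trial intercept added to the predictions
#' so errors are computed on a common scale. Degenerate splits (an empty
#' training or test set, or a failed fit) are resampled with a logged note;
#' more than 10 percent failed repetitions aborts.
#'
#' @param blues Stage-1 BLUE table (`trial`, `hybrid_id`, `blue`, `se`).
#' @param avg AVG target table from [avg_targets()].
#' @param crossplan Cross plan data frame.
#' @param Gp,Gh,D Relationship matrices (D needed for the GCA+SCA model).
#' @param trait Trait label recorded in the output.
#' @param n_reps Number of repetitions.
#' @param models Character subset of `c("GCA", "GCA+SCA")`.
#' @param targets Targets to score: `"AVG"` and/or trial labels (default all).
#' @param evaluated_fraction Probability a parent is evaluated.
#' @param seed Integer seed; repetition `r` uses `seed + r`.
#' @param control Optimizer control.
#' @return List with `results` (one row per repetition, scenario, model and
#'   target) and `summary` (medians per cell).
#' @export
run_crossval <- function(blues, avg, crossplan, Gp, Gh, D = NULL,
                         trait = "trait", n_reps = 100L,
                         models = c("GCA", "GCA+SCA"), targets = NULL,
                         evaluated_fraction = 0.5, seed = 1L,
                         control = reml_control()) {
  models <- match.arg(models, c("GCA", "GCA+SCA"), several.ok = TRUE)
  if ("GCA+SCA" %in% models && is.null(D))
    stop("the GCA+SCA model needs the dominance kernel 'D'")
  trials <- sort(unique(blues$trial))
  if (is.null(targets)) targets <- c("AVG", trials)
  mu_target <- vapply(targets, function(tg) {
    if (tg == "AVG") mean(avg$avg) else mean(blues$blue[blues$trial == tg])
  }, 0)
  results <- list()
  failures <- 0L
  rep_done <- 0L
  attempt <- 0L
  while (rep_done < n_reps) {
    attempt <- attempt + 1L
    if (failures > max(2L, ceiling(0.1 * n_reps)))
      stop("more than 10% of cross-validation repetitions failed")
    sp <- split_hybrids(crossplan, seed = seed + attempt,
                        evaluated_fraction = evaluated_fraction)
    if (length(sp$train) < 5L || (!length(sp$ep1) && !length(sp$ep0))) {
      message("degenerate split at attempt ", attempt, "; resampling")
      failures <- failures + 1L
      next
    }
    stopifnot(length(intersect(sp$train, c(sp$ep1, sp$ep0))) == 0L)
    train_blues <- blues[blues$hybrid_id %in% sp$train, , drop = FALSE]
    rep_res <- tryCatch({
      fits <- list()
      fits$GCA <- fit_gca(train_blues, crossplan, Gp, Gh, control = control)
      if ("GCA+SCA" %in% models)
        fits[["GCA+SCA"]] <- fit_gca_sca(train_blues, crossplan, Gp, Gh, D,
                                         fits$GCA, control = control)
      rows <- list()
      for (model in models) {
        fit <- fits[[model]]
        for (scen in c("0EP", "1EP")) {
          test_h <- if (scen == "0EP") sp$ep0 else sp$ep1
          for (tg in targets) {
            if (tg == "AVG") {
              tr_tab <- avg[avg$hybrid_id %in% test_h, , drop = FALSE]
              truth <- tr_tab$avg
              hh <- tr_tab$hybrid_id
            } else {
              tr_tab <- blues[blues$trial == tg &
                                blues$hybrid_id %in% test_h, , drop = FALSE]
              truth <- tr_tab$blue
              hh <- tr_tab$hybrid_id
            }
            if (length(hh) < 3L) next
            pred <- predict_hybrids(fit, crossplan, target = tg, hybrids = hh)
            pred <- pred[hh]
            if (tg == "AVG") pred <- pred + mean(fit$beta)
            rows[[length(rows) + 1L]] <- data.frame(
              rep = rep_done + 1L, scenario = scen, model = model,
              trait = trait, target = tg,
              accuracy = accuracy(truth, pred),
              rmse = scaled_rmse(truth, pred, mu_target[[tg]]),
              n_test = length(hh), stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, rows)
    }, error = function(e) {
      message("repetition failed (", conditionMessage(e), "); resampling")
      NULL
    })
    if (is.null(rep_res)) {
      failures <- failures + 1L
      next
    }
    rep_done <- rep_done + 1L
    results[[rep_done]] <- rep_res
  }
  results <- do.call(rbind, results)
  agg <- stats::aggregate(cbind(accuracy, rmse) ~ scenario + model + trait +
                            target, data = results, FUN = stats::median)
  names(agg)[names(agg) == "accuracy"] <- "median_accuracy"
  names(agg)[names(agg) == "rmse"] <- "median_rmse"
  list(results = results, summary = agg,
       meta = list(seed = seed, n_reps = n_reps,
                   evaluated_fraction = evaluated_fraction,
                   avg_prediction = "genetic value + mean trial intercept"))
}
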