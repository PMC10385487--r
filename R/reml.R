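#' First-order autoregressive correlation matrix
#'
#' Builds the AR1 correlation matrix whose entries decline exponentially with
#' index distance, `rho^|i-j|`. This is the building block for the spatial
#' residual structures used in the single-trial models, where plot errors are
#' correlated along field rows and/or columns.
#'
#' @param n Dimension (number of rows or columns of the field grid).
#' @param rho Autocorrelation parameter, must satisfy `|rho| < 1`.
#' @return An `n x n` correlation matrix with unit diagonal.
#' @examples
#' ar1_matrix(3, 0.5)
#' @export
ar1_matrix <- function(n, rho) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
    stop("'rho' must satisfy |rho| < 1")
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

## --------------------------------------------------------------------------
## Residual structure constructors
##
## Each returns an object describing the residual covariance R(theta) of the
## observation vector together with the parameters it owns.  The AR1 family is
## evaluated directly on observed plot coordinates, so incomplete grids
## (missing plots) are handled by construction: R is the full-grid covariance
## marginalized to observed cells.
## --------------------------------------------------------------------------

#' @rdname residual-structures
#' @export
resid_iid <- function(fixed = list()) {
  structure(list(type = "iid", fixed = fixed), class = "hgp_resid")
}

#' Residual covariance structures for the mixed-model engine
#'
#' Constructors for the residual structures supported by [reml_fit()]:
#' independent errors (`resid_iid`), AR1 correlation along field columns
#' without (`resid_ar1_col`) and with (`resid_ar1_col_nugget`) a spatially
#' independent nugget, separable AR1xAR1 correlation along rows and columns
#' plus nugget (`resid_ar1_rowcol_nugget`), and a known heteroscedastic
#' diagonal (`resid_known`) used when second-stage observations carry
#' first-stage squared standard errors. The `fixed` list may pin any of the
#' structure's parameters (`sigma2_e`, `rho_c`, `rho_r`, `sigma2_nugget`) at
#' a supplied value instead of estimating it.
#'
#' @param row,col Integer plot coordinates, one per observation.
#' @param weights Known residual variances (one per observation), e.g.
#'   squared standard errors of stage-1 BLUEs. Never rescaled.
#' @param fixed Named list of parameters to hold fixed.
#' @return An object of class `hgp_resid`.
#' @name residual-structures
#' @export
resid_ar1_col <- function(row, col, fixed = list()) {
  structure(list(type = "ar1_col", row = as.integer(row), col = as.integer(col),
                 fixed = fixed), class = "hgp_resid")
}

#' @rdname residual-structures
#' @export
resid_ar1_col_nugget <- function(row, col, fixed = list()) {
  structure(list(type = "ar1_col_nugget", row = as.integer(row),
                 col = as.integer(col), fixed = fixed), class = "hgp_resid")
}

#' @rdname residual-structures
#' @export
resid_ar1_rowcol_nugget <- function(row, col, fixed = list()) {
  structure(list(type = "ar1_rowcol_nugget", row = as.integer(row),
                 col = as.integer(col), fixed = fixed), class = "hgp_resid")
}

#' @rdname residual-structures
#' @export
resid_known <- function(weights) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("known residual weights must be positive and finite")
  structure(list(type = "known", weights = as.numeric(weights)),
            class = "hgp_resid")
}

#' Random term with a (possibly genomic) covariance kernel
#'
#' Describes a random effect `u ~ N(0, sigma2 * K)` entering the model as
#' `Z u`. The kernel `K` may cover more levels than appear in the data
#' (columns of `Z` with no observations); BLUPs for those levels are then the
#' kernel-conditional expectations given the observed levels, which is how
#' unphenotyped parents and hybrids are predicted.
#'
#' @param Z Incidence matrix (observations x levels). Column names label the
#'   levels.
#' @param K Covariance kernel over the levels (defaults to identity).
#' @param name Variance-parameter label (e.g. `"gca"` gives `sigma2_gca`).
#' @param fixed Optional value at which the variance is held fixed rather
#'   than estimated (used when the GCA+SCA model inherits first-step
#'   estimates).
#' @return An object of class `hgp_rand`.
#' @export
rand_term <- function(Z, K = NULL, name, fixed = NULL) {
  Z <- as.matrix(Z)
  if (!is.null(K)) {
    K <- as.matrix(K)
    if (ncol(Z) != nrow(K)) stop("ncol(Z) must match dim(K) for term '", name, "'")
    if (is.null(colnames(Z)) && !is.null(rownames(K))) colnames(Z) <- rownames(K)
  }
  structure(list(type = "scaled", Z = Z, K = K, name = name, fixed = fixed),
            class = "hgp_rand")
}

#' Unstructured group-by-unit random term
#'
#' Random effect for unit `u` (hybrid) in group `g` (trial location) with an
#' unstructured covariance across groups: `cov(a[g,u], a[h,u]) = Sigma[g,h]`
#' and independence across units. Parameters are one variance per group plus
#' one correlation per group pair. With two locations this is the
#' hybrid-by-location term of the multi-trial model.
#'
#' @param group Factor of group membership, one per observation.
#' @param unit Factor of unit membership, one per observation.
#' @param units Optional character vector of all unit levels (defaults to the
#'   levels present).
#' @param name Label prefix for the parameters.
#' @return An object of class `hgp_rand`.
#' @export
rand_us <- function(group, unit, units = NULL, name = "G") {
  group <- as.factor(group)
  unit <- as.character(unit)
  if (is.null(units)) units <- sort(unique(unit))
  structure(list(type = "us", group = group, unit = unit, units = units,
                 name = name), class = "hgp_rand")
}

#' Incidence matrix of a factor
#'
#' @param f Vector interpreted as factor levels, one per observation.
#' @param levels Column levels (defaults to the sorted unique values).
#' @return A 0/1 matrix (observations x levels).
#' @export
incidence <- function(f, levels = NULL) {
  f <- as.character(f)
  if (is.null(levels)) levels <- sort(unique(f))
  Z <- matrix(0, length(f), length(levels), dimnames = list(NULL, levels))
  idx <- match(f, levels)
  if (anyNA(idx)) stop("values not in 'levels': ",
                       paste(unique(f[is.na(idx)]), collapse = ", "))
  Z[cbind(seq_along(f), idx)] <- 1
  Z
}

#' Control settings for the REML optimizer
#'
#' @param maxit Maximum number of quasi-Newton iterations.
#' @param factr Convergence tolerance passed to `optim`'s L-BFGS-B
#'   (relative reduction in the objective).
#' @param rho_max Bound kept on autocorrelation magnitudes.
#' @param var_floor Lower bound on variance components, as a fraction of the
#'   phenotypic variance.
#' @return A list of control values.
#' @export
reml_control <- function(maxit = 200L, factr = 1e7, rho_max = 0.999,
                         var_floor = 1e-10) {
  list(maxit = maxit, factr = factr, rho_max = rho_max, var_floor = var_floor)
}

## Parameter bookkeeping -----------------------------------------------------

## Internal: builds the parameter table for a model.  Each row: label,
## transform ("logvar" or "atanh"), init (natural scale), fixed value or NA.
.param_table <- function(residual, random, vy, n_var_components) {
  rows <- list()
  add <- function(label, trans, init, fixed = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(label = label, trans = trans,
                                             init = init, fixed = fixed,
                                             stringsAsFactors = FALSE)
  share <- vy / max(1L, n_var_components)
  fx <- function(lab, fl) if (!is.null(fl[[lab]])) fl[[lab]] else NA_real_
  rt <- residual$type
  if (rt == "iid") {
    add("sigma2_e", "logvar", share, fx("sigma2_e", residual$fixed))
  } else if (rt %in% c("ar1_col", "ar1_col_nugget", "ar1_rowcol_nugget")) {
    add("sigma2_e", "logvar", share, fx("sigma2_e", residual$fixed))
    if (rt == "ar1_rowcol_nugget")
      add("rho_r", "atanh", 0, fx("rho_r", residual$fixed))
    add("rho_c", "atanh", 0, fx("rho_c", residual$fixed))
    if (rt != "ar1_col")
      add("sigma2_nugget", "logvar", share, fx("sigma2_nugget", residual$fixed))
  } ## "known": no parameters
  for (tm in random) {
    if (tm$type == "scaled") {
      add(paste0("sigma2_", tm$name), "logvar", share,
          if (is.null(tm$fixed)) NA_real_ else tm$fixed)
    } else if (tm$type == "us") {
      gl <- levels(tm$group)
      for (g in gl) add(paste0("sigma2_", tm$name, "_", g), "logvar", share)
      if (length(gl) > 1L)
        for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl))
          add(paste0("rho_", tm$name, "_", gl[i], "_", gl[j]), "atanh", 0)
    }
  }
  do.call(rbind, rows)
}

## Internal: natural-scale values from the transformed free-parameter vector.
.natural <- function(theta_free, ptab) {
  v <- ptab$fixed
  free <- is.na(ptab$fixed)
  tr <- ptab$trans[free]
  v[free] <- ifelse(tr == "logvar", exp(theta_free), tanh(theta_free))
  names(v) <- ptab$label
  v
}

## Internal: attach precomputed distance structures to an AR1-family
## residual so each likelihood evaluation only does table lookups.
.prep_resid <- function(residual, n) {
  type <- residual$type
  if (!type %in% c("ar1_col", "ar1_col_nugget", "ar1_rowcol_nugget"))
    return(residual)
  col <- residual$col
  residual$Dc <- abs(outer(col, col, "-")) + 1L   # 1-based lag index
  residual$maxc <- max(residual$Dc)
  if (type == "ar1_rowcol_nugget") {
    residual$Dr <- abs(outer(residual$row, residual$row, "-")) + 1L
    residual$maxr <- max(residual$Dr)
  } else {
    residual$roweq <- (outer(residual$row, residual$row, "-") == 0) + 0
  }
  residual
}

## Internal: residual covariance and per-parameter derivatives (on the
## transformed scale) at natural parameter values `pv`.
.resid_V <- function(residual, pv, n, want_grad, free) {
  type <- residual$type
  if (type == "known")
    return(list(V = diag(residual$weights, n), dV = list()))
  if (type == "iid") {
    s2 <- pv[["sigma2_e"]]
    dV <- list()
    if (want_grad && free["sigma2_e"]) dV$sigma2_e <- diag(s2, n)
    return(list(V = diag(s2, n), dV = dV))
  }
  s2 <- pv[["sigma2_e"]]
  rc <- pv[["rho_c"]]
  lagc <- seq_len(residual$maxc) - 1L
  pwc <- rc^lagc
  Cc <- residual$Dc
  Cc[] <- pwc[residual$Dc]
  if (type == "ar1_rowcol_nugget") {
    rr <- pv[["rho_r"]]
    lagr <- seq_len(residual$maxr) - 1L
    pwr <- rr^lagr
    Cr <- residual$Dr
    Cr[] <- pwr[residual$Dr]
  } else {
    Cr <- residual$roweq
  }
  Corr <- Cr * Cc
  V <- s2 * Corr
  dV <- list()
  if (want_grad) {
    if (free["sigma2_e"]) dV$sigma2_e <- V  ## d/d log s2 = s2 * Corr
    if (free["rho_c"]) {
      dpwc <- c(0, lagc[-1] * rc^(lagc[-1] - 1))
      dCc <- residual$Dc
      dCc[] <- dpwc[residual$Dc]
      dV$rho_c <- s2 * Cr * dCc * (1 - rc^2)  ## chain through atanh
    }
    if (type == "ar1_rowcol_nugget" && free["rho_r"]) {
      dpwr <- c(0, lagr[-1] * rr^(lagr[-1] - 1))
      dCr <- residual$Dr
      dCr[] <- dpwr[residual$Dr]
      dV$rho_r <- s2 * dCr * Cc * (1 - rr^2)
    }
  }
  if (type %in% c("ar1_col_nugget", "ar1_rowcol_nugget")) {
    sn <- pv[["sigma2_nugget"]]
    diag(V) <- diag(V) + sn
    if (want_grad && free["sigma2_nugget"]) dV$sigma2_nugget <- diag(sn, n)
  }
  list(V = V, dV = dV)
}

## Internal: precompute fixed pieces of the random terms.
.prep_random <- function(random, n) {
  lapply(random, function(tm) {
    if (tm$type == "scaled") {
      A <- if (is.null(tm$K)) tcrossprod(tm$Z) else tm$Z %*% tm$K %*% t(tm$Z)
      tm$A <- (A + t(A)) / 2
    } else if (tm$type == "us") {
      gl <- levels(tm$group)
      M <- lapply(gl, function(g) {
        Z <- matrix(0, n, length(tm$units), dimnames = list(NULL, tm$units))
        sel <- which(tm$group == g)
        if (length(sel)) Z[sel, ] <- incidence(tm$unit[sel], levels = tm$units)
        Z
      })
      names(M) <- gl
      tm$M <- M
      B <- list()
      for (i in seq_along(gl)) for (j in i:length(gl)) {
        Bij <- tcrossprod(M[[i]], M[[j]])
        B[[paste(gl[i], gl[j], sep = "|")]] <-
          if (i == j) Bij else Bij + t(Bij)
      }
      tm$B <- B
    }
    tm
  })
}

## Internal: random-term covariance contributions and derivatives.
.random_V <- function(terms, pv, n, want_grad, free) {
  V <- matrix(0, n, n)
  dV <- list()
  for (tm in terms) {
    if (tm$type == "scaled") {
      lab <- paste0("sigma2_", tm$name)
      s2 <- pv[[lab]]
      V <- V + s2 * tm$A
      if (want_grad && free[lab]) dV[[lab]] <- s2 * tm$A
    } else if (tm$type == "us") {
      gl <- levels(tm$group)
      sg <- sqrt(vapply(gl, function(g) pv[[paste0("sigma2_", tm$name, "_", g)]],
                        0))
      vlab <- paste0("sigma2_", tm$name, "_", gl)
      for (i in seq_along(gl)) {
        Bii <- tm$B[[paste(gl[i], gl[i], sep = "|")]]
        V <- V + sg[i]^2 * Bii
        if (want_grad && free[vlab[i]]) dV[[vlab[i]]] <- sg[i]^2 * Bii
      }
      if (length(gl) > 1L)
        for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
          labr <- paste0("rho_", tm$name, "_", gl[i], "_", gl[j])
          r <- pv[[labr]]
          Bij <- tm$B[[paste(gl[i], gl[j], sep = "|")]]
          V <- V + r * sg[i] * sg[j] * Bij
          if (want_grad) {
            if (free[labr]) dV[[labr]] <- (1 - r^2) * sg[i] * sg[j] * Bij
            if (free[vlab[i]])
              dV[[vlab[i]]] <- dV[[vlab[i]]] + r * sg[i] * sg[j] / 2 * Bij
            if (free[vlab[j]])
              dV[[vlab[j]]] <- dV[[vlab[j]]] + r * sg[i] * sg[j] / 2 * Bij
          }
        }
    }
  }
  list(V = V, dV = dV)
}

#' Fit a linear mixed model by restricted maximum likelihood
#'
#' Dense-matrix REML solver for the covariance structures used throughout the
#' two-stage analysis: arbitrary scaled-kernel random terms (genomic BLUP),
#' an unstructured group-by-unit term, and IID / AR1 / AR1xAR1 / nugget /
#' known-diagonal residuals. Variance parameters are optimized on a
#' log scale and correlations on an `atanh` scale by a quasi-Newton method
#' with analytic gradients; initialization splits the phenotypic variance
#' equally across components with correlations started at zero, so fits are
#' deterministic. Parameters supplied as fixed (including the known-diagonal
#' residual) are held exactly and excluded from the AIC parameter count.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effects design matrix (aliased columns are dropped
#'   left-to-right with a warning).
#' @param random List of terms from [rand_term()] / [rand_us()].
#' @param residual Residual structure from the `resid_*` constructors.
#' @param control See [reml_control()].
#' @return An object of class `reml_fit` with elements `loglik`, `aic`,
#'   `estimates` (natural scale, with a `fixed` attribute), `beta`,
#'   `beta_se`, `beta_cov`, `u` (BLUPs per random term, covering every kernel
#'   level), `converged`, `iterations`, `n_params`.
#' @export
reml_fit <- function(y, X, random = list(), residual = resid_iid(),
                     control = reml_control()) {
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0L) stop("empty response")
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) != length(y)")
  if (inherits(random, "hgp_rand")) random <- list(random)
  ## drop aliased fixed-effect columns (left-to-right preference)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    warning("dropping aliased fixed-effect column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  ## phenotypic variance net of fixed effects: initializing variance
  ## components from var(y) overshoots badly when fixed effects (trial
  ## means) carry most of the spread, which strands the optimizer at a
  ## boundary corner where log-scale gradients vanish
  vy <- sum(qr.resid(qr(X), y)^2) / max(1L, n - p)
  if (!is.finite(vy) || vy <= 0) vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1

  terms <- .prep_random(random, n)
  residual <- .prep_resid(residual, n)
  n_vc <- sum(vapply(terms, function(tm)
    if (tm$type == "us") length(levels(tm$group)) else 1L, 0L)) +
    (residual$type != "known") + (residual$type %in% c("ar1_col_nugget",
                                                       "ar1_rowcol_nugget"))
  ptab <- .param_table(residual, terms, vy, n_vc)
  has_par <- !is.null(ptab) && nrow(ptab) > 0L
  free <- if (has_par) is.na(ptab$fixed) else logical(0)
  names(free) <- if (has_par) ptab$label else character(0)

  fsig <- paste(c(p, colnames(X)), collapse = "|")

  eval_model <- function(pv, want_grad) {
    rs <- .resid_V(residual, pv, n, want_grad, free)
    rn <- .random_V(terms, pv, n, want_grad, free)
    V <- rs$V + rn$V
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), n)),
                     error = function(e) NULL)
      if (is.null(ch)) return(NULL)
    }
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    XtViX_inv <- chol2inv(chX)
    beta <- drop(XtViX_inv %*% crossprod(ViX, y))
    r <- y - drop(X %*% beta)
    Vir <- drop(Vi %*% r)
    ll <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    2 * sum(log(diag(chX))) + sum(r * Vir))
    out <- list(ll = ll, beta = beta, Vir = Vir, Vi = Vi, ViX = ViX,
                XtViX_inv = XtViX_inv, V = V)
    if (want_grad) {
      ## tr(P dV) = tr(Vi dV) - tr((X'ViX)^-1 (ViX)' dV (ViX)) avoids
      ## forming the n x n projection matrix
      dVs <- c(rs$dV, rn$dV)
      g <- vapply(ptab$label[free], function(lab) {
        dV <- dVs[[lab]]
        if (is.null(dV)) return(0)
        dViX <- dV %*% ViX
        trP <- sum(Vi * dV) - sum(XtViX_inv * crossprod(ViX, dViX))
        -0.5 * (trP - drop(crossprod(Vir, dV %*% Vir)))
      }, 0)
      out$grad <- g
    }
    out
  }

  iterations <- 0L
  converged <- TRUE
  if (has_par && any(free)) {
    init_nat <- ptab$init
    theta0 <- ifelse(ptab$trans == "logvar", log(pmax(init_nat, 1e-12)),
                     atanh(pmin(pmax(init_nat, -0.9), 0.9)))[free]
    lower <- ifelse(ptab$trans == "logvar", log(control$var_floor * vy),
                    -atanh(control$rho_max))[free]
    upper <- ifelse(ptab$trans == "logvar", log(1e8 * vy),
                    atanh(control$rho_max))[free]
    theta0 <- pmin(pmax(theta0, lower), upper)
    cache <- new.env(parent = emptyenv())
    get_eval <- function(th) {
      key <- paste(format(th, digits = 17), collapse = ",")
      if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
      pv <- .natural(th, ptab)
      val <- eval_model(pv, want_grad = TRUE)
      cache$key <- key; cache$val <- val
      val
    }
    fn <- function(th) {
      e <- get_eval(th)
      if (is.null(e) || !is.finite(e$ll)) return(1e10)
      -e$ll
    }
    gr <- function(th) {
      e <- get_eval(th)
      if (is.null(e) || !is.finite(e$ll)) return(rep(0, length(th)))
      -e$grad
    }
    run_opt <- function(start) {
      tryCatch(
        stats::optim(start, fn, gr, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = control$maxit,
                                    factr = control$factr)),
        error = function(e) NULL)
    }
    opt <- run_opt(theta0)
    ## restart policy: a line-search failure, or a component parked at its
    ## floor, can signal the log-scale boundary trap (gradients vanish as
    ## variances approach zero, so a corner looks stationary); retry from
    ## deterministic alternative starts and keep the best optimum
    is_lv <- (ptab$trans == "logvar")[free]
    suspicious <- function(o)
      is.null(o) || o$convergence != 0 ||
      any(is_lv & o$par < lower + 1)
    if (suspicious(opt)) {
      starts <- list(theta0 - log(10) * is_lv)
      if (sum(is_lv) > 1L)
        for (j in which(is_lv)) {
          st <- theta0 - log(100) * is_lv
          st[j] <- theta0[j]
          starts[[length(starts) + 1L]] <- st
        }
      for (st in starts) {
        o2 <- run_opt(pmin(pmax(st, lower), upper))
        if (is.null(opt) || (!is.null(o2) && o2$value < opt$value)) opt <- o2
      }
    }
    if (is.null(opt)) {
      opt <- stats::optim(theta0, fn, method = "Nelder-Mead",
                          control = list(maxit = 2000L))
    }
    iterations <- if (!is.null(opt$counts)) unname(opt$counts[1]) else NA_integer_
    theta_hat <- opt$par
    ## a boundary optimum can abort the line search without being a failure:
    ## judge convergence by the projected gradient at the final point
    converged <- opt$convergence == 0
    if (!converged) {
      e_chk <- get_eval(theta_hat)
      if (!is.null(e_chk) && is.finite(e_chk$ll)) {
        gfn <- -e_chk$grad
        at_lo <- theta_hat <= lower + 1e-8
        at_hi <- theta_hat >= upper - 1e-8
        gfn[at_lo] <- pmin(gfn[at_lo], 0)
        gfn[at_hi] <- pmax(gfn[at_hi], 0)
        converged <- max(abs(gfn)) < 0.05
      }
    }
    pv <- .natural(theta_hat, ptab)
  } else {
    pv <- if (has_par) .natural(numeric(0), ptab) else
      stats::setNames(numeric(0), character(0))
  }

  final <- eval_model(pv, want_grad = FALSE)
  if (is.null(final)) stop("REML fit failed: covariance matrix not positive definite")
  if (!is.finite(final$ll)) converged <- FALSE

  k <- sum(free)
  aic <- -2 * final$ll + 2 * k

  ## BLUPs for every random term over all kernel levels
  u <- list()
  for (tm in terms) {
    if (tm$type == "scaled") {
      s2 <- pv[[paste0("sigma2_", tm$name)]]
      ZtVir <- drop(crossprod(tm$Z, final$Vir))
      ui <- if (is.null(tm$K)) s2 * ZtVir else s2 * drop(tm$K %*% ZtVir)
      names(ui) <- colnames(tm$Z)
      u[[tm$name]] <- ui
    } else if (tm$type == "us") {
      gl <- levels(tm$group)
      sg <- sqrt(vapply(gl, function(g) pv[[paste0("sigma2_", tm$name, "_", g)]], 0))
      Sg <- diag(sg^2, length(gl))
      if (length(gl) > 1L)
        for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
          r <- pv[[paste0("rho_", tm$name, "_", gl[i], "_", gl[j])]]
          Sg[i, j] <- Sg[j, i] <- r * sg[i] * sg[j]
        }
      MtVir <- vapply(gl, function(g) drop(crossprod(tm$M[[g]], final$Vir)),
                      numeric(length(tm$units)))
      ug <- MtVir %*% t(Sg)   ## units x groups
      dimnames(ug) <- list(tm$units, gl)
      u[[tm$name]] <- ug
      attr(u[[tm$name]], "Sigma") <- structure(Sg, dimnames = list(gl, gl))
    }
  }

  est <- pv
  attr(est, "fixed") <- if (has_par) !free else logical(0)
  fit <- list(loglik = final$ll, aic = aic, n_params = k, estimates = est,
              beta = stats::setNames(final$beta, colnames(X)),
              beta_se = stats::setNames(sqrt(diag(final$XtViX_inv)), colnames(X)),
              beta_cov = final$XtViX_inv,
              u = u, converged = converged, iterations = iterations,
              n_obs = n, fixed_signature = fsig,
              terms = terms, residual = residual,
              Vir = final$Vir, Vi = final$Vi, ViX = final$ViX,
              XtViX_inv = final$XtViX_inv, X = X, y = y)
  class(fit) <- "reml_fit"
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", x$n_obs, "observations,", length(x$beta), "fixed effects\n")
  cat("logLik:", format(x$loglik, digits = 6), " AIC:",
      format(x$aic, digits = 6), " (", x$n_params, "estimated variance parameters )\n")
  fx <- attr(x$estimates, "fixed")
  if (length(x$estimates)) {
    tag <- ifelse(fx, " (fixed)", "")
    cat("Variance parameters:\n")
    for (i in seq_along(x$estimates))
      cat("  ", names(x$estimates)[i], "=",
          format(x$estimates[i], digits = 5), tag[i], "\n")
  }
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' Rank model fits by AIC
#'
#' Compares REML fits that share the same fixed-effect specification (a
#' requirement for REML-based AIC comparison) and returns the fit with the
#' smallest AIC, with ties broken in favour of fewer estimated variance
#' parameters.
#'
#' @param fits Named list of `reml_fit` objects.
#' @return A list with `best` (the winning fit), `best_name`, and `ranking`
#'   (a data frame of logLik, AIC and parameter counts in AIC order).
#' @export
compare_aic <- function(fits) {
  if (length(fits) == 0L) stop("no fits to compare")
  sig <- vapply(fits, function(f) f$fixed_signature, "")
  if (length(unique(sig)) > 1L)
    stop("fits have different fixed-effect specifications; ",
         "REML AIC comparison is not valid across them")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("fit", seq_along(fits))
  tab <- data.frame(model = nm,
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    k = vapply(fits, function(f) as.numeric(f$n_params), 0),
                    aic = vapply(fits, function(f) f$aic, 0),
                    converged = vapply(fits, function(f) f$converged, TRUE),
                    stringsAsFactors = FALSE)
  ord <- order(tab$aic, tab$k)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(best = fits[[tab$model[1]]], best_name = tab$model[1], ranking = tab)
}

#' BLUPs for requested levels of a random term
#'
#' Returns predictions for any levels present in the term's covariance
#' kernel, including levels with no phenotypic records: those are the
#' kernel-conditional expectations given the observed-level effects, which is
#' how untested parents and hybrids obtain genomically estimated breeding
#' values.
#'
#' @param fit A `reml_fit` object.
#' @param term Name of the random term.
#' @param levels Character vector of levels to extract (default all).
#' @return Named numeric vector of BLUPs.
#' @export
predict_random <- function(fit, term, levels = NULL) {
  if (!term %in% names(fit$u)) stop("no random term named '", term, "'")
  u <- fit$u[[term]]
  if (is.matrix(u)) stop("use the matrix in fit$u[['", term,
                         "']] for unstructured terms")
  if (is.null(levels)) return(u)
  miss <- setdiff(levels, names(u))
  if (length(miss))
    stop("levels absent from the '", term, "' kernel: ",
         paste(miss, collapse = ", "))
  u[levels]
}

#' Serialize a REML fit to JSON
#'
#' Writes the fit's summary — variance parameter estimates with their fixed
#' flags, REML log-likelihood, AIC, fixed-effect estimates and standard
#' errors, convergence flag and iteration count — as a JSON object.
#'
#' @param fit A `reml_fit` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
reml_fit_json <- function(fit, path = NULL) {
  obj <- list(estimates = as.list(fit$estimates),
              fixed = as.list(attr(fit$estimates, "fixed")),
              loglik = fit$loglik, aic = fit$aic,
              n_params = fit$n_params, n_obs = fit$n_obs,
              beta = as.list(fit$beta), beta_se = as.list(fit$beta_se),
              converged = fit$converged, iterations = fit$iterations)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Prediction error variances of a random term
#'
#' Computes `diag(C - C Z' P Z C)` with `C` the term's scaled kernel and `P`
#' the REML projection matrix, i.e. the prediction error variance of each
#' level's BLUP.
#'
#' @param fit A `reml_fit` object.
#' @param term Name of a scaled-kernel random term.
#' @return Named vector of prediction error variances.
#' @export
ranef_pev <- function(fit, term) {
  tm <- NULL
  for (t in fit$terms) if (t$type == "scaled" && t$name == term) tm <- t
  if (is.null(tm)) stop("no scaled random term named '", term, "'")
  s2 <- fit$estimates[[paste0("sigma2_", term)]]
  P <- fit$Vi - fit$ViX %*% tcrossprod(fit$XtViX_inv, fit$ViX)
  K <- if (is.null(tm$K)) diag(ncol(tm$Z)) else tm$K
  CZt <- s2 * tcrossprod(K, tm$Z)          # C Z'
  pev <- s2 * diag(K) - rowSums((CZt %*% P) * CZt)
  stats::setNames(pev, colnames(tm$Z))
}
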