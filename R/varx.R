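#' Vector autoregression with exogenous inflow and outflow
#'
#' Fits the stock-flow dynamics of a waiting list: the pending stock in each
#' quarter is modelled as a linear function of the pending stock at selected
#' earlier quarters (the autoregressive lags), the contemporaneous number of
#' referrals added, and the number removed, plus Gaussian noise,
#'
#' \deqn{y_t = c + \sum_{l \in L} \Phi_l y_{t-l} + B x_t + \varepsilon_t,
#'       \quad \varepsilon_t \sim N(0, \Sigma),}
#'
#' where \eqn{y_t} is the vector of pending stocks (one series for an
#' aggregate analysis, or inpatient and outpatient jointly), \eqn{x_t}
#' stacks the additions and removals of the matching strata, and \eqn{L
#' \subseteq \{1,2,3,4\}} is the lag set (a maximum order of 4 captures
#' quarter-of-year seasonal dependence in quarterly data).
#'
#' Estimation maximises the conditional Gaussian likelihood (the first
#' `presample` quarters are conditioned on, not modelled). For this linear
#' model the ML coefficients coincide with least squares per equation, and
#' \eqn{\Sigma} is the ML residual covariance (divisor \eqn{n}). The
#' parameter count `k` includes every free coefficient plus the
#' \eqn{m(m+1)/2} free elements of \eqn{\Sigma}, so AIC \eqn{= 2k -
#' 2\log\hat L} is comparable across lag sets fitted on a common sample.
#'
#' @param panel a `waitlist_panel`. For `endog = "all"`-style aggregate
#'   fits, pass a single-stratum panel; for a joint inpatient/outpatient
#'   fit, pass a panel containing one stratum per type and set
#'   `endog = c("inpatient", "outpatient")`.
#' @param lags integer lag set, a non-empty subset of `1:4`.
#' @param endog elective types whose pending series form the endogenous
#'   block; the special value `"*"` (default) uses whatever single stratum
#'   the panel holds.
#' @param intercept include an intercept.
#' @param presample quarters conditioned on at the start (default
#'   `max(lags)`; set to 4 to align estimation samples when comparing lag
#'   sets by AIC).
#' @return an object of class `varx`: coefficient matrices per lag
#'   (`$phi`), exogenous coefficients (`$beta`), intercept (`$intercept`),
#'   residual covariance (`$sigma`), `$logLik`, `$k`, `$aic`, residuals,
#'   fitted values and the estimation sample.
#' @seealso [select_varx()] for AIC-based lag-set choice,
#'   [project_waitlist()] for scenario projections, [varx_model()] to build
#'   a model from known coefficients.
#' @export
varx <- function(panel, lags = c(1, 4), endog = "*", intercept = TRUE,
                 presample = max(lags)) {
  d <- build_design(panel, lags = lags, endog = endog,
                    intercept = intercept, presample = presample)
  X <- d$X
  Y <- d$Y
  n <- nrow(Y)
  m <- ncol(Y)
  p <- ncol(X)
  if (n < p + 2) {
    stop("estimation sample has ", n, " rows for ", p,
         " regressors; at least ", p + 2,
         " response quarters are required to estimate the model")
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  B <- qr.coef(qr_x, Y)                       # p x m
  fitted <- X %*% B
  E <- Y - fitted
  sigma <- crossprod(E) / n                   # ML divisor n
  ld <- determinant(sigma, logarithm = TRUE)
  loglik <- if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    Inf                                       # degenerate: perfect fit
  } else {
    -n * m / 2 * log(2 * pi) - n / 2 * as.numeric(ld$modulus) - n * m / 2
  }
  k <- m * p + m * (m + 1) / 2
  phi <- lapply(lags, function(l) {
    idx <- match(paste0(d$endog_names, ".l", l), rownames(B))
    t(B[idx, , drop = FALSE])                 # m x m: equation rows
  })
  names(phi) <- paste0("lag", lags)
  beta_idx <- match(d$exog_names, rownames(B))
  beta <- t(B[beta_idx, , drop = FALSE])      # m x 2m
  icpt <- if (intercept) as.numeric(B["(Intercept)", ]) else rep(0, m)
  out <- list(
    lags = as.integer(lags),
    endog = d$endog_names,
    exog = d$exog_names,
    intercept_included = intercept,
    coef = B,
    phi = phi,
    beta = beta,
    intercept = icpt,
    sigma = sigma,
    logLik = loglik,
    k = k,
    aic = 2 * k - 2 * loglik,
    nobs = n,
    residuals = E,
    fitted.values = fitted,
    y = Y,
    x = X,
    quarters = d$quarters,
    init = d$init,
    last_exog = d$last_exog,
    call = match.call()
  )
  class(out) <- "varx"
  out
}

#' Build the regression design for a waiting-list VARX
#'
#' Row `t` holds the response `pending[t]` (per endogenous series) and the
#' regressors: `pending[t - l]` for each lag `l`, the contemporaneous
#' additions and removals of each endogenous stratum, and an intercept. The
#' first `presample` quarters are consumed as presample.
#'
#' @inheritParams varx
#' @return list with response matrix `Y`, design matrix `X`, quarter codes
#'   of the response rows, series names, and the trailing endogenous values
#'   needed to initialise forward simulation.
#' @export
build_design <- function(panel, lags = c(1, 4), endog = "*",
                         intercept = TRUE, presample = max(lags)) {
  stopifnot(inherits(panel, "waitlist_panel"))
  lags <- sort(unique(as.integer(lags)))
  if (!length(lags) || any(lags < 1) || any(lags > 4)) {
    stop("lag set must be a non-empty subset of 1:4")
  }
  if (presample < max(lags)) stop("presample must cover max(lags)")
  if (identical(endog, "*")) {
    series <- list(panel_series(panel))
    names(series) <- "pending"
  } else {
    series <- lapply(endog, function(ty)
      panel_series(panel_subset(panel, elective_type = ty)))
    names(series) <- paste0("pending.", endog)
  }
  codes <- series[[1]]$code
  for (s in series) {
    if (!identical(s$code, codes)) stop("endogenous series cover different quarters")
  }
  Tn <- length(codes)
  m <- length(series)
  if (Tn < presample + 1) {
    stop("panel has ", Tn, " quarters; at least ", presample + 1,
         " are required for lag set {", paste(lags, collapse = ","), "}")
  }
  Ymat <- sapply(series, `[[`, "pending")
  if (is.null(dim(Ymat))) Ymat <- matrix(Ymat, ncol = m)
  rows <- (presample + 1):Tn
  Y <- Ymat[rows, , drop = FALSE]
  colnames(Y) <- names(series)
  lag_cols <- list()
  for (l in lags) {
    lagmat <- Ymat[rows - l, , drop = FALSE]
    colnames(lagmat) <- paste0(names(series), ".l", l)
    lag_cols[[length(lag_cols) + 1]] <- lagmat
  }
  exog_list <- lapply(seq_along(series), function(j) {
    ex <- cbind(series[[j]]$additions[rows], series[[j]]$removals[rows])
    prefix <- if (m == 1) "" else sub("^pending\\.", "", paste0(names(series)[j], "."))
    colnames(ex) <- paste0(prefix, c("additions", "removals"))
    ex
  })
  X <- do.call(cbind, c(lag_cols, exog_list))
  if (intercept) {
    X <- cbind(X, `(Intercept)` = 1)
  }
  maxlag <- max(lags)
  init <- Ymat[(Tn - maxlag + 1):Tn, , drop = FALSE]
  colnames(init) <- names(series)
  last_exog <- do.call(cbind, lapply(series, function(s)
    cbind(s$additions[Tn], s$removals[Tn])))
  list(Y = Y, X = X, quarters = codes[rows],
       endog_names = names(series),
       exog_names = unlist(lapply(exog_list, colnames)),
       init = init, last_exog = last_exog)
}

#' Build a VARX object from known coefficients
#'
#' Used for simulation studies with known truth and for analytically
#' specified systems such as the pure accounting identity (`phi = 1`,
#' `beta = c(1, -1)`, `intercept = 0`), which makes the model an exact
#' stock-flow bookkeeping recursion.
#'
#' @param lags integer lag set.
#' @param phi autoregressive coefficients: for one endogenous series a
#'   numeric vector (one per lag); generally a list of m x m matrices.
#' @param beta exogenous coefficients on (additions, removals): numeric
#'   length-2 vector for one series, or an m x 2m matrix.
#' @param intercept intercept vector (default 0).
#' @param sigma innovation variance (scalar) or covariance matrix.
#' @param endog endogenous series names.
#' @return an object of class `varx` usable with [predict()], [simulate()]
#'   and [project_waitlist()].
#' @export
varx_model <- function(lags, phi, beta, intercept = 0, sigma = 0,
                       endog = "pending") {
  lags <- sort(unique(as.integer(lags)))
  m <- length(endog)
  if (!is.list(phi)) phi <- lapply(phi, function(v) matrix(v, m, m))
  stopifnot(length(phi) == length(lags))
  names(phi) <- paste0("lag", lags)
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = m)
  if (!is.matrix(sigma)) sigma <- diag(sigma, m, m)
  out <- list(
    lags = lags, endog = endog,
    exog = if (m == 1) c("additions", "removals") else
      paste(rep(endog, each = 2), c("additions", "removals"), sep = "."),
    intercept_included = any(intercept != 0),
    phi = phi, beta = beta, intercept = rep(intercept, length.out = m),
    sigma = sigma, logLik = NA_real_, k = NA_real_, aic = NA_real_,
    nobs = 0L, call = match.call()
  )
  class(out) <- "varx"
  out
}

#' @export
print.varx <- function(x, digits = 4, ...) {
  cat("Waiting-list VARX: lag set {", paste(x$lags, collapse = ", "),
      "}, ", length(x$endog), " endogenous series\n", sep = "")
  for (l in seq_along(x$lags)) {
    cat("  Phi[", x$lags[l], "]: ",
        paste(signif(x$phi[[l]], digits), collapse = " "), "\n", sep = "")
  }
  cat("  B(", paste(x$exog, collapse = ", "), "): ",
      paste(signif(x$beta, digits), collapse = " "), "\n", sep = "")
  cat("  intercept: ", paste(signif(x$intercept, digits), collapse = " "),
      "\n", sep = "")
  if (is.finite(x$logLik)) {
    cat(sprintf("  logLik %.3f on %d obs, k = %d, AIC %.3f\n",
                x$logLik, x$nobs, as.integer(x$k), x$aic))
  } else if (identical(x$logLik, Inf)) {
    cat("  perfect fit (zero residual variance); AIC degenerate\n")
  }
  invisible(x)
}

#' @export
summary.varx <- function(object, ...) {
  x <- object
  out <- list(model = x)
  if (!is.null(x$x)) {
    # per-equation least-squares standard errors (unbiased divisor), for
    # display only; estimation itself is ML
    XtXi <- chol2inv(chol(crossprod(x$x)))
    n <- x$nobs; p <- ncol(x$x)
    tables <- lapply(seq_along(x$endog), function(j) {
      s2 <- sum(x$residuals[, j]^2) / max(1, n - p)
      se <- sqrt(diag(XtXi) * s2)
      est <- x$coef[, j]
      cbind(Estimate = est, `Std. Error` = se,
            `t value` = ifelse(se > 0, est / se, NA))
    })
    names(tables) <- x$endog
    out$coefficients <- tables
  }
  class(out) <- "summary.varx"
  out
}

#' @export
print.summary.varx <- function(x, ...) {
  print(x$model)
  for (nm in names(x$coefficients)) {
    cat("\nEquation ", nm, ":\n", sep = "")
    stats::printCoefmat(x$coefficients[[nm]])
  }
  invisible(x)
}

#' @export
coef.varx <- function(object, ...) object$coef

#' @export
residuals.varx <- function(object, ...) object$residuals

#' @export
fitted.varx <- function(object, ...) object$fitted.values

#' @export
nobs.varx <- function(object, ...) object$nobs

#' @export
logLik.varx <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$nobs,
            class = "logLik")
}

#' @export
plot.varx <- function(x, ...) {
  if (is.null(x$y)) stop("nothing to plot for a coefficient-only model")
  q <- x$quarters
  graphics::matplot(q, cbind(x$y[, 1], x$fitted.values[, 1]), type = "l",
                    lty = c(1, 2), col = c("black", "red3"),
                    xlab = "quarter code", ylab = x$endog[1],
                    main = "Observed (solid) vs fitted (dashed)", ...)
  invisible(x)
}

#' Deterministic forward recursion of a fitted VARX
#'
#' Iterates the fitted equation over a projection horizon with supplied
#' exogenous paths and no innovations. The pending stock is floored at zero.
#'
#' @param object a `varx` fit or [varx_model()].
#' @param additions,removals exogenous paths: vectors of length `n.ahead`
#'   (one endogenous series) or matrices `n.ahead x m`.
#' @param init matrix of the last `max(lags)` observed endogenous values
#'   (oldest row first); defaults to the fit's estimation sample tail.
#' @param floor floor the projected stock at zero (default `TRUE`).
#' @param ... unused.
#' @return matrix `n.ahead x m` of projected pending stocks.
#' @export
predict.varx <- function(object, additions, removals, init = NULL,
                         floor = TRUE, ...) {
  sim <- simulate_paths(object, additions, removals, init = init,
                        nsim = 1L, innovations = "none", floor = floor)
  sim[, 1, , drop = TRUE]
}

#' Monte Carlo paths from a fitted VARX
#'
#' @param object a `varx` object.
#' @param nsim number of simulated paths.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param additions,removals exogenous paths as in [predict.varx()].
#' @param init initial lags as in [predict.varx()].
#' @param innovations `"gaussian"` (draws from the fitted covariance),
#'   `"bootstrap"` (resampled fit residuals), `"none"`, or a numeric array
#'   `H x nsim x m` of pre-drawn innovations (for common random numbers
#'   across scenarios).
#' @param floor floor the stock at zero.
#' @param ... unused.
#' @return numeric array `H x nsim x m`.
#' @export
simulate.varx <- function(object, nsim = 1, seed = NULL, additions, removals,
                          init = NULL, innovations = "gaussian",
                          floor = TRUE, ...) {
  with_seed(seed,
            simulate_paths(object, additions, removals, init = init,
                           nsim = nsim, innovations = innovations,
                           floor = floor))
}

simulate_paths <- function(object, additions, removals, init, nsim,
                           innovations, floor) {
  m <- length(object$endog)
  as_mat <- function(v, nm) {
    if (is.null(dim(v))) v <- matrix(v, ncol = m)
    if (ncol(v) != m) stop(nm, " must have one column per endogenous series")
    v
  }
  additions <- as_mat(additions, "additions")
  removals <- as_mat(removals, "removals")
  H <- nrow(additions)
  if (nrow(removals) != H) stop("additions and removals paths differ in length")
  maxlag <- max(object$lags)
  if (is.null(init)) init <- object$init
  if (is.null(init)) stop("initial endogenous lags are required")
  init <- as_mat(init, "init")
  if (nrow(init) < maxlag) {
    stop("init must supply the last ", maxlag, " endogenous values")
  }
  init <- init[(nrow(init) - maxlag + 1):nrow(init), , drop = FALSE]

  eps <- NULL
  if (is.numeric(innovations)) {
    eps <- innovations
    if (length(dim(eps)) == 2 && m == 1) eps <- array(eps, c(dim(eps), 1))
    if (!all(dim(eps) == c(H, nsim, m))) {
      stop("innovation array must be H x nsim x m = ",
           paste(c(H, nsim, m), collapse = " x "))
    }
  } else if (identical(innovations, "gaussian")) {
    sig <- object$sigma
    if (all(sig == 0)) {
      eps <- array(0, c(H, nsim, m))
    } else {
      ev <- eigen(sig, symmetric = TRUE)
      if (any(ev$values < -1e-8 * max(abs(ev$values)))) {
        stop("residual covariance is not positive semi-definite")
      }
      rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m, m) %*% t(ev$vectors)
      z <- matrix(stats::rnorm(H * nsim * m), H * nsim, m)
      eps <- array(z %*% rt, c(H, nsim, m))
    }
  } else if (identical(innovations, "bootstrap")) {
    if (is.null(object$residuals)) stop("bootstrap innovations need fit residuals")
    idx <- matrix(sample.int(nrow(object$residuals), H * nsim, replace = TRUE),
                  H, nsim)
    eps <- array(object$residuals[as.vector(idx), , drop = FALSE], c(H, nsim, m))
  } else if (identical(innovations, "none")) {
    eps <- array(0, c(H, nsim, m))
  } else {
    stop("unknown innovations specification")
  }

  # state: nsim x m matrices for each of the last maxlag quarters
  state <- lapply(seq_len(maxlag), function(i)
    matrix(init[i, ], nsim, m, byrow = TRUE))
  out <- array(NA_real_, c(H, nsim, m))
  phi <- object$phi
  beta <- object$beta                         # m x 2m
  icpt <- object$intercept
  for (t in seq_len(H)) {
    acc <- matrix(icpt, nsim, m, byrow = TRUE)
    for (li in seq_along(object$lags)) {
      l <- object$lags[li]
      acc <- acc + state[[maxlag - l + 1]] %*% t(phi[[li]])
    }
    xrow <- as.vector(rbind(additions[t, ], removals[t, ]))  # per-series pairs
    acc <- acc + matrix(rep(drop(beta %*% xrow), each = nsim), nsim, m)
    acc <- acc + matrix(eps[t, , ], nsim, m)
    if (floor) acc <- pmax(acc, 0)
    if (maxlag > 1) state[seq_len(maxlag - 1)] <- state[2:maxlag]
    state[[maxlag]] <- acc
    out[t, , ] <- acc
  }
  dimnames(out) <- list(NULL, NULL, object$endog)
  out
}

#' Fit candidate lag sets and select by AIC
#'
#' Fits every candidate lag set on a common estimation sample (all
#' candidates are aligned on a presample of `max` over the candidates, so
#' the AICs compare the same response rows) and returns the fit with
#' minimal AIC together with the comparison table. Ties are broken toward
#' the smaller parameter count, then the smaller maximum lag. A candidate
#' that cannot be fitted is excluded from the comparison with its error
#' message recorded, never silently.
#'
#' @param panel a `waitlist_panel`.
#' @param candidates list of integer lag sets (default: the four structures
#'   `{1}`, `{4}`, `{1,4}`, `{1,2,3,4}`).
#' @param ... passed to [varx()] (e.g. `endog`).
#' @return a `varx_selection` list: `$best` (the chosen `varx` fit),
#'   `$table` (lag set, k, logLik, AIC, delta-AIC, error), `$fits`.
#' @export
select_varx <- function(panel,
                        candidates = list(1L, 4L, c(1L, 4L), 1:4),
                        ...) {
  presample <- max(unlist(candidates))
  fits <- vector("list", length(candidates))
  tab <- data.frame(
    lags = vapply(candidates, function(l) paste(l, collapse = ","), ""),
    k = NA_real_, logLik = NA_real_, AIC = NA_real_, nobs = NA_integer_,
    error = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_along(candidates)) {
    f <- try(varx(panel, lags = candidates[[i]], presample = presample, ...),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      tab$error[i] <- conditionMessage(attr(f, "condition"))
    } else {
      fits[[i]] <- f
      tab$k[i] <- f$k
      tab$logLik[i] <- f$logLik
      tab$AIC[i] <- f$aic
      tab$nobs[i] <- f$nobs
    }
  }
  ok <- which(!is.na(tab$AIC))
  if (!length(ok)) stop("no candidate lag set could be fitted")
  maxlags <- vapply(candidates, max, 0L)
  ord <- ok[order(tab$AIC[ok], tab$k[ok], maxlags[ok])]
  best <- fits[[ord[1]]]
  tab$delta_AIC <- tab$AIC - tab$AIC[ord[1]]
  out <- list(best = best, table = tab, fits = fits)
  class(out) <- "varx_selection"
  out
}

#' @export
print.varx_selection <- function(x, ...) {
  cat("Lag-set selection by AIC (common estimation sample):\n")
  print(x$table[, c("lags", "k", "logLik", "AIC", "delta_AIC", "error")],
        row.names = FALSE, digits = 6)
  cat("\nSelected lag set: {", paste(x$best$lags, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' Serialize a fitted VARX to JSON
#'
#' Writes everything needed to re-run projections without refitting:
#' lag set, coefficient matrices, intercept, residual covariance,
#' log-likelihood, parameter count, AIC, sample window and the trailing
#' state. [read_varx()] restores a `varx` object.
#'
#' @param fit a `varx` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_varx <- function(fit, path) {
  stopifnot(inherits(fit, "varx"))
  payload <- list(
    lags = fit$lags, endog = fit$endog, exog = fit$exog,
    intercept_included = fit$intercept_included,
    phi = lapply(fit$phi, function(m) unclass(as.matrix(m))),
    beta = unclass(as.matrix(fit$beta)),
    intercept = fit$intercept,
    sigma = unclass(as.matrix(fit$sigma)),
    logLik = fit$logLik, k = fit$k, aic = fit$aic, nobs = fit$nobs,
    quarters = fit$quarters,
    init = if (!is.null(fit$init)) unclass(as.matrix(fit$init))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_varx
#' @export
read_varx <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- length(p$endog)
  out <- list(
    lags = as.integer(p$lags), endog = p$endog, exog = p$exog,
    intercept_included = isTRUE(p$intercept_included),
    phi = lapply(p$phi, function(x) matrix(unlist(x), m, m, byrow = TRUE)),
    beta = matrix(unlist(p$beta), nrow = m, byrow = TRUE),
    intercept = as.numeric(p$intercept),
    sigma = matrix(unlist(p$sigma), m, m, byrow = TRUE),
    logLik = p$logLik, k = p$k, aic = p$aic, nobs = p$nobs,
    quarters = p$quarters,
    init = if (!is.null(p$init)) matrix(unlist(p$init), ncol = m, byrow = TRUE)
  )
  names(out$phi) <- paste0("lag", out$lags)
  class(out) <- "varx"
  out
}
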