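# Partial least squares (PLS1, NIPALS) with leave-one-out cross-validation,
# component-number scanning, and model statistics.

#' Fit a PLS regression model (NIPALS)
#'
#' Sequential NIPALS extraction with X-deflation for a single response.
#' Descriptors and response are mean-centered internally; no per-column
#' autoscaling is applied (field columns keep their energy units, the CoMFA
#' convention).
#'
#' @param X Descriptor matrix (n x p), e.g. from [descriptor_matrix()].
#' @param y Numeric response vector, length n.
#' @param n_components Number of latent components N (1 <= N, with
#'   n >= N + 2 rows and N no larger than the rank of centered X).
#' @return Object of class `pls_model`: weights `W`, loadings `P`,
#'   per-component regression loadings `C`, `x_mean`, `y_mean`,
#'   `coefficients` (original descriptor space), `coef_path` (p x N matrix
#'   of coefficients for every truncation), `n_components`, plus column
#'   standard deviations and block labels when present on `X`.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (sd(y) == 0) stop("response has zero variance")
  if (n_components < 1L) stop("n_components must be >= 1")
  if (n < n_components + 2L)
    stop("need at least n_components + 2 rows")
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Cvec <- numeric(n_components)
  Tmat <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12)
      stop("requested ", n_components, " components but the descriptor ",
           "matrix supports only ", a - 1L)
    w <- w / wn
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12)
      stop("requested ", n_components, " components but the descriptor ",
           "matrix supports only ", a - 1L)
    p_load <- crossprod(Xc, t_sc) / tt
    c_a <- sum(yc * t_sc) / tt
    Xc <- Xc - t_sc %*% t(p_load)
    W[, a] <- w; P[, a] <- p_load; Cvec[a] <- c_a; Tmat[, a] <- t_sc
  }
  # coefficients for every truncation a = 1..N (models are nested)
  coef_path <- matrix(0, p, n_components)
  for (a in seq_len(n_components)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    coef_path[, a] <- Wa %*% solve(crossprod(Pa, Wa), Cvec[seq_len(a)])
  }
  structure(list(W = W, P = P, C = Cvec, scores = Tmat,
                 x_mean = x_mean, y_mean = y_mean,
                 coefficients = coef_path[, n_components],
                 coef_path = coef_path, n_components = n_components,
                 x_sd = apply(X, 2, sd),
                 blocks = attr(X, "block"),
                 points = attr(X, "point")),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<PLS model: %d components over %d descriptors>\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A [pls_model][fit_pls].
#' @param newdata Descriptor matrix with the training column layout.
#' @param n_components Truncation to use (default: the fitted N).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  a <- n_components %||% object$n_components
  if (a < 1L || a > object$n_components)
    stop("n_components must lie in 1..", object$n_components)
  newdata <- matrix(newdata, ncol = length(object$x_mean))
  drop(sweep(newdata, 2, object$x_mean) %*% object$coef_path[, a] +
         object$y_mean)
}

# LOO predictions for every truncation 1..n_max in one pass: each held-out
# sample gets one refit with the maximum component count, and nested
# truncations are read off the coefficient path.
loo_prediction_matrix <- function(X, y, n_max) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  pred <- matrix(NA_real_, n, n_max)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_max)
    for (a in seq_len(n_max))
      pred[i, a] <- predict(fit, X[i, , drop = FALSE], n_components = a)
  }
  pred
}

#' Leave-one-out cross-validation of a PLS model
#'
#' Each sample in turn is held out, the model refitted on the remainder,
#' and the held-out activity predicted. q2 = 1 - PRESS_cv / total sum of
#' squares about the mean; SEP = sqrt(PRESS_cv / (n - N - 1)).
#'
#' @inheritParams fit_pls
#' @return List with `q2`, `sep`, `press_cv`, `n_components`.
#' @export
loo_cv <- function(X, y, n_components) {
  n <- length(y)
  if (n - n_components - 1L <= 0L)
    stop("n - N - 1 must be positive for SEP")
  pred <- loo_prediction_matrix(X, y, n_components)[, n_components]
  press_cv <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(q2 = 1 - press_cv / ss_tot,
       sep = sqrt(press_cv / (n - n_components - 1L)),
       press_cv = press_cv, n_components = n_components)
}

#' Scan the number of PLS components
#'
#' Runs leave-one-out cross-validation for N = 1..`n_max` (capping N at
#' what the sample size and SEP degrees of freedom allow) and applies a
#' selection rule via [select_components()].
#'
#' @inheritParams fit_pls
#' @param n_max Largest component count to scan (default 15).
#' @param rule,tol,n_fixed Passed to [select_components()].
#' @return Object of class `component_scan`: data frame with columns `N`,
#'   `sep`, `q2`, and attribute `selected`.
#' @export
scan_components <- function(X, y, n_max = 15L,
                            rule = c("max_q2", "first_plateau", "fixed"),
                            tol = 0.01, n_fixed = NULL) {
  rule <- match.arg(rule)
  n <- length(y)
  feasible <- min(n_max, n - 2L)  # keep n - N - 1 >= 1 and n >= N + 2
  if (feasible < 1L) stop("too few samples to scan components")
  pred <- loo_prediction_matrix(X, y, feasible)
  ss_tot <- sum((y - mean(y))^2)
  press <- colSums((y - pred)^2)
  Ns <- seq_len(feasible)
  scan <- data.frame(N = Ns,
                     sep = sqrt(press / (n - Ns - 1L)),
                     q2 = 1 - press / ss_tot)
  class(scan) <- c("component_scan", "data.frame")
  attr(scan, "selected") <- select_components(scan, rule = rule, tol = tol,
                                              n_fixed = n_fixed)
  scan
}

#' Select the component number from a q2 scan
#'
#' Rules: `"max_q2"` (default) takes the N maximizing q2 (smallest N on
#' ties); `"first_plateau"` takes the first N whose q2 is within `tol` of
#' the scan maximum; `"fixed"` returns `n_fixed` regardless of the scan
#' (the explicit override needed to reproduce published models chosen by
#' unstated criteria).
#'
#' @param scan Data frame with columns `N` and `q2` (e.g. a
#'   [scan_components()] result, or a published scan entered directly).
#' @param rule Selection rule.
#' @param tol Plateau tolerance on q2 (default 0.01).
#' @param n_fixed Component count for `rule = "fixed"`.
#' @return Selected integer N.
#' @export
select_components <- function(scan,
                              rule = c("max_q2", "first_plateau", "fixed"),
                              tol = 0.01, n_fixed = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (is.null(n_fixed)) stop("rule 'fixed' needs n_fixed")
    return(as.integer(n_fixed))
  }
  if (rule == "max_q2") return(scan$N[which.max(scan$q2)])
  best <- max(scan$q2)
  scan$N[which(scan$q2 >= best - tol)[1]]
}

#' Fit statistics of the non-cross-validated model
#'
#' r2 = 1 - RSS/TSS; SEE = sqrt(RSS / (n - N - 1));
#' F = (r2 / N) / ((1 - r2) / (n - N - 1)).
#'
#' @param model A [pls_model][fit_pls].
#' @param X,y The training descriptors and response.
#' @return List with `r2`, `see`, `f_stat`, `rss`, `n`, `n_components`.
#' @export
final_stats <- function(model, X, y) {
  n <- length(y); N <- model$n_components
  dof <- n - N - 1L
  if (dof <= 0L) stop("n - N - 1 must be positive")
  pred <- predict(model, as.matrix(X))
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(r2 = r2, see = sqrt(rss / dof),
       f_stat = (r2 / N) / ((1 - r2) / dof),
       rss = rss, n = n, n_components = N)
}

#' Steric/electrostatic percentage contributions
#'
#' Per-column contribution is |coefficient| x column standard deviation;
#' block percentages are the block sums normalized to 100.
#'
#' @param model A [pls_model][fit_pls] fitted on a descriptor matrix
#'   carrying block labels (see [descriptor_matrix()]).
#' @return Named numeric vector (`steric`, `electrostatic`) summing to 100.
#' @export
field_contributions <- function(model) {
  if (is.null(model$blocks))
    stop("model was not fitted on a block-labelled descriptor matrix")
  contrib <- abs(model$coefficients) * model$x_sd
  total <- sum(contrib)
  if (total == 0) stop("all coefficients are zero: contributions undefined")
  by_block <- tapply(contrib, factor(model$blocks,
                                     levels = c("steric", "electrostatic")),
                     sum, default = 0)
  pct <- 100 * as.numeric(by_block) / total
  setNames(pct, c("steric", "electrostatic"))
}
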