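# Numerically safe log(1 + exp(-t)).
log1pexp_neg <- function(t) pmax(-t, 0) + log1p(exp(-abs(t)))

# Newton solver for the reduced logistic ridge problem.
#
# Features enter through z = U D from the thin SVD X = U D V'; since the
# penalized optimum lies in the row space of X, beta = V w with ||beta|| =
# ||w||, and the fit runs in r = rank(X) dimensions. Objective (w-space):
#   (1/n) sum log(1 + exp(-y_i (z_i'w + b))) + lambda ||w||^2,
# intercept unpenalized. Damped Newton with step halving; strongly convex,
# so convergence to small gradient norms is fast.
newton_logistic_ridge <- function(z, y, lambda, b0 = 0, w0 = NULL,
                                  tol = 1e-8, max_iter = 100L) {
  n <- nrow(z); r <- ncol(z)
  w <- w0 %||% numeric(r)
  b <- b0
  eta <- drop(b + z %*% w)
  obj <- function(eta_, w_) mean(log1pexp_neg(y * eta_)) + lambda * sum(w_^2)
  f <- obj(eta, w)
  for (it in seq_len(max_iter)) {
    s <- -y * stats::plogis(-y * eta)
    g_b <- mean(s)
    g_w <- drop(crossprod(z, s)) / n + 2 * lambda * w
    gnorm <- sqrt(g_b^2 + sum(g_w^2))
    if (gnorm < tol) {
      return(list(intercept = b, w = w, grad_norm = gnorm, iterations = it - 1L,
                  converged = TRUE))
    }
    wt <- stats::plogis(eta) * stats::plogis(-eta)
    wt <- pmax(wt, 1e-10)
    zw <- z * wt
    H <- rbind(c(mean(wt), colSums(zw) / n),
               cbind(colSums(zw) / n, crossprod(z, zw) / n +
                       diag(2 * lambda, r)))
    step <- tryCatch(solve(H, c(g_b, g_w)),
                     error = function(e) c(g_b, g_w))  # fall back to gradient
    tstep <- 1
    repeat {
      b_new <- b - tstep * step[1]
      w_new <- w - tstep * step[-1]
      eta_new <- drop(b_new + z %*% w_new)
      f_new <- obj(eta_new, w_new)
      # non-increase up to float resolution: near the optimum the quadratic
      # improvement of a full Newton step falls below the precision of f
      if (f_new <= f + 1e-12 * (1 + abs(f)) || tstep < 1e-10) break
      tstep <- tstep / 2
    }
    b <- b_new; w <- w_new; eta <- eta_new; f <- f_new
  }
  s <- -y * stats::plogis(-y * eta)
  gnorm <- sqrt(mean(s)^2 + sum((drop(crossprod(z, s)) / n + 2 * lambda * w)^2))
  list(intercept = b, w = w, grad_norm = gnorm, iterations = max_iter,
       converged = gnorm < tol)
}

# Thin SVD of the design, with near-null directions dropped.
design_svd <- function(x) {
  sv <- svd(x)
  keep <- sv$d > max(sv$d[1], 1) * 1e-12
  list(z = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep)),
       v = sv$v[, keep, drop = FALSE])
}

# Normalize labels to +/-1 (case = +1).
as_pm1 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) {
    stop("validation error: labels must be two classes (+/-1, 0/1, logical or factor)",
         call. = FALSE)
  }
  y
}

#' L2-penalized logistic regression
#'
#' Fits the classifier at the heart of the pipeline: minimize
#' \deqn{\frac{1}{n}\sum_i \log(1 + e^{-y_i(\beta^\top x_i + b)}) +
#'   \lambda \lVert\beta\rVert_2^2}
#' with unpenalized intercept \eqn{b} and labels \eqn{y_i = \pm 1}. The
#' mean-scaled loss keeps \eqn{\lambda} comparable across sample sizes. The
#' problem is reduced to the row space of `x` through a thin SVD (exact for
#' this penalty) and solved by damped Newton iterations to gradient norm
#' below `tol`.
#'
#' @param x numeric feature matrix (subjects x features), typically
#'   z-normalized.
#' @param y labels: +/-1, 0/1, logical, or a two-level factor (second level
#'   = case).
#' @param lambda positive ridge penalty.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return Object of class `logistic_ridge` with `intercept`,
#'   `coefficients`, `lambda`, `grad_norm`, `iterations`.
#' @examples
#' x <- matrix(rnorm(60), 30, 2)
#' y <- sign(x[, 1] + rnorm(30, sd = .3))
#' fit <- fit_logistic_ridge(x, y, lambda = 0.01)
#' coef(fit)
#' @export
fit_logistic_ridge <- function(x, y, lambda, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- as_pm1(y)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("validation error: non-finite values in `x`", call. = FALSE)
  }
  stopifnot(length(y) == nrow(x))
  stop_if_not_scalar_number(lambda, "lambda")
  if (lambda <= 0) stop("validation error: `lambda` must be positive", call. = FALSE)
  dec <- design_svd(x)
  fit <- newton_logistic_ridge(dec$z, y, lambda, tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    stop(sprintf("non-convergence after %d iterations (gradient norm %.3g)",
                 fit$iterations, fit$grad_norm), call. = FALSE)
  }
  beta <- drop(dec$v %*% fit$w)
  names(beta) <- colnames(x)
  eta <- drop(fit$intercept + x %*% beta)
  structure(list(lambda = lambda,
                 intercept = fit$intercept,
                 coefficients = beta,
                 grad_norm = fit$grad_norm,
                 iterations = fit$iterations,
                 fitted = stats::plogis(eta),
                 y = y),
            class = "logistic_ridge")
}

#' @export
print.logistic_ridge <- function(x, ...) {
  cat(sprintf("Logistic ridge fit: %d features, lambda = %g\n",
              length(x$coefficients), x$lambda))
  cat(sprintf("  intercept %.4f, ||beta|| = %.4f, gradient norm %.2e (%d Newton steps)\n",
              x$intercept, sqrt(sum(x$coefficients^2)), x$grad_norm, x$iterations))
  invisible(x)
}

#' @export
coef.logistic_ridge <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict from a logistic ridge fit
#'
#' @param object a `logistic_ridge`.
#' @param newx feature matrix on the same columns the model was fitted on.
#'   If the model carries z-normalization statistics (as fits from
#'   [nested_ridge()] do), raw features are standardized first.
#' @param type `"link"`, `"prob"`, or `"class"` (+/-1).
#' @param ... unused.
#' @export
predict.logistic_ridge <- function(object, newx, type = c("link", "prob", "class"),
                                   ...) {
  type <- match.arg(type)
  newx <- if (inherits(newx, "feature_matrix")) newx$values else as.matrix(newx)
  if (!is.null(object$znorm)) newx <- apply_znorm(newx, object$znorm)
  eta <- drop(object$intercept + newx %*% object$coefficients)
  switch(type,
         link = eta,
         prob = stats::plogis(eta),
         class = ifelse(eta >= 0, 1, -1))
}

#' @export
residuals.logistic_ridge <- function(object,
                                     type = c("deviance", "pearson", "response"),
                                     ...) {
  type <- match.arg(type)
  y01 <- (object$y + 1) / 2
  p <- object$fitted
  switch(type,
         response = y01 - p,
         pearson = (y01 - p) / sqrt(p * (1 - p)),
         deviance = sign(y01 - p) *
           sqrt(-2 * (y01 * log(p) + (1 - y01) * log(1 - p))))
}

# Warm-started fits across a descending lambda path sharing one SVD.
# Returns w-space solutions; coefficients are materialized on demand.
ridge_path <- function(x, y, lambdas, tol = 1e-8, max_iter = 100L) {
  dec <- design_svd(x)
  ord <- order(lambdas, decreasing = TRUE)
  fits <- vector("list", length(lambdas))
  b <- 0; w <- numeric(ncol(dec$z))
  for (k in ord) {
    fit <- newton_logistic_ridge(dec$z, y, lambdas[k], b0 = b, w0 = w,
                                 tol = tol, max_iter = max_iter)
    if (!fit$converged) {
      stop(sprintf("non-convergence at lambda = %g after %d iterations",
                   lambdas[k], fit$iterations), call. = FALSE)
    }
    b <- fit$intercept; w <- fit$w
    fits[[k]] <- fit
  }
  list(v = dec$v, fits = fits, lambdas = lambdas)
}

path_beta <- function(path, k) drop(path$v %*% path$fits[[k]]$w)
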