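## Multinomial logistic regression by Newton-Raphson maximum likelihood.
##
## With K outcome levels and the reference level's coefficient row fixed at
## zero, the log-likelihood is sum_i log softmax(eta_i)[y_i] with
## eta_ik = x_i' b_k. The score for class k is X'(I[y = k] - p_k) and the
## observed information has blocks X' diag(p_k (delta_kl - p_l)) X, both
## assembled densely: designs here are small (tens of columns) even when n
## is large.

#' Fit a multinomial logistic regression by maximum likelihood
#'
#' Newton-Raphson with step-halving on the exact observed information.
#' The covariance of the vectorised coefficients is the inverse observed
#' information at the optimum. Complete separation (divergence) is detected
#' by coefficient-norm growth and flagged, never silently truncated; a small
#' ridge penalty can be supplied to obtain a finite shrunk fit in degenerate
#' cases.
#'
#' @param X Numeric design matrix with named columns, intercept first.
#' @param y Outcome: factor or character vector of category labels.
#' @param reference Reference level (coefficients fixed at zero). Default:
#'   first factor level of `y`.
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   and on the scaled score norm.
#' @param max_iter Maximum Newton iterations.
#' @param ridge Ridge penalty (per-coefficient Gaussian prior precision);
#'   0 = plain MLE.
#' @return Object of class `multinom_fit`: `coef` ((K-1) x P matrix, rows =
#'   non-reference levels), `se` (same shape), `vcov` (vectorised order:
#'   class varies slowest), `loglik`, `iterations`, `converged`, `ridge`,
#'   `levels`, `reference`, `n`.
#' @export
fit_multinomial <- function(X, y, reference = NULL, tol = 1e-8,
                            max_iter = 200, ridge = 0) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("y must take at least 2 levels", call. = FALSE)
  if (is.null(reference)) reference <- levels(y)[1L]
  if (!reference %in% levels(y)) {
    stop("reference level '", reference, "' not among outcome levels",
         call. = FALSE)
  }
  y <- stats::relevel(y, ref = reference)
  lv <- levels(y)
  K <- length(lv); P <- ncol(X); n <- nrow(X)
  if (n != length(y)) stop("nrow(X) != length(y)", call. = FALSE)

  qr_x <- qr(X)
  if (qr_x$rank < P) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):P]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  if (n <= P * (K - 1)) {
    warning("n <= P*(K-1); estimates may be unstable", call. = FALSE)
  }

  Yk <- matrix(0, n, K - 1L)  # indicator columns for non-reference classes
  yi <- as.integer(y)
  for (k in 2:K) Yk[yi == k, k - 1L] <- 1

  B <- matrix(0, K - 1L, P, dimnames = list(lv[-1L], colnames(X)))
  npar <- (K - 1L) * P

  loglik_at <- function(B) {
    eta <- X %*% t(B)
    m <- pmax(apply(eta, 1L, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    nonref <- yi > 1L
    ll <- sum(eta[cbind(which(nonref), yi[nonref] - 1L)]) -
      sum(m + log(denom))
    ll - 0.5 * ridge * sum(B^2)
  }
  probs_at <- function(B) {
    eta <- X %*% t(B)
    m <- pmax(apply(eta, 1L, max), 0)
    e <- exp(eta - m)
    denom <- exp(-m) + rowSums(e)
    e / denom  # n x (K-1), non-reference classes
  }

  ll <- loglik_at(B)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    Pmat <- probs_at(B)
    ## score: vectorised with class varying slowest
    G <- crossprod(X, Yk - Pmat)          # P x (K-1)
    g <- as.vector(G) - ridge * as.vector(t(B))
    ## observed information, (K-1)P x (K-1)P in blocks
    H <- matrix(0, npar, npar)
    for (k in seq_len(K - 1L)) {
      for (l in seq_len(k)) {
        w <- if (k == l) Pmat[, k] * (1 - Pmat[, k]) else -Pmat[, k] * Pmat[, l]
        blk <- crossprod(X, X * w)
        ri <- (k - 1L) * P + seq_len(P)
        ci <- (l - 1L) * P + seq_len(P)
        H[ri, ci] <- blk
        if (k != l) H[ci, ri] <- blk
      }
    }
    if (ridge > 0) H <- H + diag(ridge, npar)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(H + diag(1e-8 * max(diag(H)), npar), g)
    }
    ## step-halving line search
    sc <- 1
    repeat {
      Bnew <- B + sc * matrix(step, K - 1L, P, byrow = TRUE)
      llnew <- loglik_at(Bnew)
      if (is.finite(llnew) && llnew >= ll - 1e-12) break
      sc <- sc / 2
      if (sc < 1e-10) { Bnew <- B; llnew <- ll; break }
    }
    delta_ll <- llnew - ll
    B <- Bnew; ll <- llnew
    if (max(abs(B)) > 30) { diverged <- TRUE; break }
    if (abs(delta_ll) < tol * (abs(ll) + tol) &&
        max(abs(g)) < 1e-6 * max(1, n)) {
      converged <- TRUE
      break
    }
  }
  if (diverged) {
    warning("coefficients diverging (likely complete separation); ",
            "fit flagged non-converged", if (ridge == 0)
              " - consider a small ridge penalty" else "", call. = FALSE)
  }

  ## covariance at final estimate
  Pmat <- probs_at(B)
  H <- matrix(0, npar, npar)
  for (k in seq_len(K - 1L)) {
    for (l in seq_len(k)) {
      w <- if (k == l) Pmat[, k] * (1 - Pmat[, k]) else -Pmat[, k] * Pmat[, l]
      blk <- crossprod(X, X * w)
      ri <- (k - 1L) * P + seq_len(P)
      ci <- (l - 1L) * P + seq_len(P)
      H[ri, ci] <- blk
      if (k != l) H[ci, ri] <- blk
    }
  }
  if (ridge > 0) H <- H + diag(ridge, npar)
  V <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  par_names <- as.vector(t(outer(lv[-1L], colnames(X), paste, sep = ":")))
  dimnames(V) <- list(par_names, par_names)
  se <- matrix(sqrt(pmax(diag(V), 0)), K - 1L, P, byrow = TRUE,
               dimnames = dimnames(B))

  structure(list(coef = B, se = se, vcov = V, loglik = ll,
                 iterations = iter, converged = converged && !diverged,
                 ridge = ridge, levels = lv, reference = reference,
                 n = n, X = X, y = y),
            class = "multinom_fit")
}

#' Fitted class probabilities
#'
#' @param object A `multinom_fit`.
#' @param newdata Optional design matrix; defaults to the training design.
#' @param ... Unused.
#' @return n x K matrix of probabilities (columns in `object$levels` order,
#'   reference first); rows sum to 1.
#' @export
predict.multinom_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  eta <- cbind(0, X %*% t(object$coef))
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  p <- e / rowSums(e)
  colnames(p) <- object$levels
  p
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf(
    "Multinomial logit fit: %d obs, %d levels (ref = %s), logLik = %.3f\n%s in %d iterations%s\n",
    x$n, length(x$levels), x$reference, x$loglik,
    if (x$converged) "converged" else "DID NOT CONVERGE", x$iterations,
    if (x$ridge > 0) sprintf(" (ridge = %g)", x$ridge) else ""))
  print(round(x$coef, 4))
  invisible(x)
}

#' Wald odds-ratio intervals from a multinomial fit
#'
#' For each non-reference category and predictor, the odds ratio is
#' `exp(b)` with two-sided confidence bounds `exp(b +/- z * se)`, `z` the
#' standard-normal quantile of the two-sided `level`. An effect is flagged
#' significant when its interval excludes 1 (no multiplicity correction).
#'
#' @param fit A `multinom_fit`.
#' @param level Two-sided confidence level in (0.5, 1); default 0.975, i.e.
#'   z ~ 2.2414.
#' @return data.frame of class `odds_ratio_table`: `category`, `predictor`,
#'   `estimate`, `se`, `odds_ratio`, `lower`, `upper`, `significant`.
#' @export
wald_intervals <- function(fit, level = 0.975) {
  if (level <= 0.5 || level >= 1) {
    stop("confidence level must lie in (0.5, 1)", call. = FALSE)
  }
  if (!fit$converged && fit$ridge == 0) {
    warning("fit did not converge; intervals are unreliable", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  cats <- rownames(fit$coef)
  preds <- colnames(fit$coef)
  out <- data.frame(
    category = rep(cats, each = length(preds)),
    predictor = rep(preds, times = length(cats)),
    estimate = as.vector(t(fit$coef)),
    se = as.vector(t(fit$se)),
    stringsAsFactors = FALSE
  )
  out$odds_ratio <- exp(out$estimate)
  out$lower <- exp(out$estimate - z * out$se)
  out$upper <- exp(out$estimate + z * out$se)
  out$significant <- out$lower > 1 | out$upper < 1
  attr(out, "level") <- level
  attr(out, "z") <- z
  attr(out, "reference") <- fit$reference
  class(out) <- c("odds_ratio_table", "data.frame")
  out
}
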