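# Proportional-odds (cumulative logit) model of HVPG grade on serum
# markers, fitted by Newton's method with step-halving.
#
# Sign convention: logit P(Y <= k) = theta_k - beta.x, so a positive beta
# means higher predictor -> higher grade, and the per-unit odds ratio for
# the higher-grade direction is exp(beta).

# log-likelihood and analytic score for cumulative-logit data
.po_loglik_grad <- function(par, X, y, K) {
  p <- ncol(X)
  theta <- par[seq_len(K - 1)]
  beta <- par[K - 1 + seq_len(p)]
  if (is.unsorted(theta, strictly = TRUE))
    return(list(ll = -Inf, grad = rep(NA_real_, length(par))))
  eta <- drop(X %*% beta)
  upper <- ifelse(y < K, theta[pmin(y, K - 1)] - eta, Inf)
  lower <- ifelse(y > 1, theta[pmax(y - 1, 1)] - eta, -Inf)
  pr <- stats::plogis(upper) - stats::plogis(lower)
  if (any(pr <= 0) || any(!is.finite(pr)))
    return(list(ll = -Inf, grad = rep(NA_real_, length(par))))
  gu <- ifelse(is.finite(upper), stats::dlogis(upper), 0)
  gl <- ifelse(is.finite(lower), stats::dlogis(lower), 0)
  w_u <- gu / pr
  w_l <- gl / pr
  grad_theta <- vapply(seq_len(K - 1), function(j)
    sum(w_u[y == j]) - sum(w_l[y == j + 1]), 0)
  grad_beta <- -drop(crossprod(X, w_u - w_l))
  list(ll = sum(log(pr)), grad = c(grad_theta, grad_beta))
}

# central-difference Hessian of the analytic score
.po_hessian <- function(par, X, y, K, h = 1e-5) {
  np <- length(par)
  H <- matrix(0, np, np)
  for (j in seq_len(np)) {
    e <- numeric(np); e[j] <- h
    gp <- .po_loglik_grad(par + e, X, y, K)$grad
    gm <- .po_loglik_grad(par - e, X, y, K)$grad
    H[, j] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a proportional-odds model of HVPG grade on AST, PLT and albumin
#'
#' Maximum-likelihood fit of logit P(grade <= k) = theta_k - beta.x by
#' Newton's method with step-halving (predictors are standardised
#' internally; coefficients are reported per unit on the original scales).
#' Convergence: score norm < 1e-8 (standardised scale) within 100
#' iterations; a fit that does not converge (e.g. separation) is returned
#' with \code{converged = FALSE}, not an error.
#'
#' @param cohort \code{ph_cohort} (or data frame) with complete
#'   \code{ast}, \code{plt}, \code{albumin} and either \code{grade} or
#'   \code{hvpg} columns; all represented grades must appear.
#' @param predictors character vector of predictor column names.
#' @return object of class \code{ph_ordinal}: list with \code{beta}
#'   (named, per-unit), \code{or} (= exp(beta)), \code{se}, \code{ci95}
#'   (matrix), \code{p}, \code{thresholds}, \code{loglik},
#'   \code{loglik_trace}, \code{converged}, \code{vcov}, \code{n}.
#' @export
fit_proportional_odds <- function(cohort,
                                  predictors = c("ast", "plt", "albumin")) {
  df <- as.data.frame(cohort)
  if (!"grade" %in% names(df)) {
    if (!"hvpg" %in% names(df)) stop("need a grade or hvpg column")
    df$grade <- classify_hvpg(df$hvpg)$grade
  }
  if (any(!predictors %in% names(df)))
    stop("missing predictor column(s)")
  keep <- stats::complete.cases(df[, c(predictors, "grade")])
  df <- df[keep, , drop = FALSE]
  y <- as.integer(factor(df$grade, levels = sort(unique(df$grade))))
  K <- max(y)
  if (K < 2) stop("need at least two grade levels")
  X <- as.matrix(df[, predictors, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  # start: marginal cumulative logits, beta = 0
  cum <- cumsum(tabulate(y, K)) / length(y)
  par <- c(stats::qlogis(pmin(pmax(cum[seq_len(K - 1)], 1e-6), 1 - 1e-6)),
           rep(0, length(predictors)))
  cur <- .po_loglik_grad(par, Xs, y, K)
  trace <- cur$ll
  converged <- FALSE
  for (iter in seq_len(100)) {
    if (sqrt(sum(cur$grad^2)) < 1e-8) { converged <- TRUE; break }
    H <- .po_hessian(par, Xs, y, K)
    # ascent direction: -H^{-1} g (H negative-definite near the maximum);
    # fall back to plain gradient ascent if H is singular
    step <- tryCatch(-solve(H, cur$grad), error = function(e) NULL)
    if (is.null(step)) step <- cur$grad / max(abs(cur$grad), 1)
    lambda <- 1
    repeat {
      cand <- par + lambda * step
      new <- .po_loglik_grad(cand, Xs, y, K)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { new <- cur; cand <- par; break }
    }
    par <- cand
    cur <- new
    trace <- c(trace, cur$ll)
  }

  theta_s <- par[seq_len(K - 1)]
  beta_s <- par[K - 1 + seq_along(predictors)]
  beta <- beta_s / scl
  theta <- theta_s + sum(beta_s * ctr / scl)
  names(beta) <- predictors

  par_raw <- c(theta, beta)
  H_raw <- .po_hessian(par_raw, X, y, K)
  vcov <- tryCatch(solve(-H_raw), error = function(e)
    matrix(NA_real_, length(par_raw), length(par_raw)))
  idx <- K - 1 + seq_along(predictors)
  se <- sqrt(diag(vcov))[idx]
  names(se) <- predictors
  z <- beta / se
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  structure(list(beta = beta, or = exp(beta), se = se,
                 ci95 = ci, or_ci95 = exp(ci),
                 p = 2 * stats::pnorm(-abs(z)),
                 thresholds = theta, loglik = cur$ll,
                 loglik_trace = trace, converged = converged,
                 vcov = vcov, n = length(y), K = K,
                 predictors = predictors),
            class = "ph_ordinal")
}

#' @export
print.ph_ordinal <- function(x, ...) {
  cat(sprintf("Proportional-odds model (n = %d, %d grades)%s\n", x$n, x$K,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(beta = x$beta, OR = x$or,
                    OR_low = x$or_ci95[, 1], OR_high = x$or_ci95[, 2],
                    p = x$p)
  print(round(tab, 4))
  cat("thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " < "),
      sprintf("  loglik %.2f\n", x$loglik))
  invisible(x)
}

#' Fitted grade probabilities for new patients
#' @param model \code{ph_ordinal} fit.
#' @param newdata data frame with the model's predictor columns.
#' @return matrix (patients x grades) of probabilities summing to 1 per row.
#' @export
po_grade_probs <- function(model, newdata) {
  X <- as.matrix(as.data.frame(newdata)[, model$predictors, drop = FALSE])
  eta <- drop(X %*% model$beta)
  cum <- cbind(0, sapply(model$thresholds, function(t) stats::plogis(t - eta)),
               1)
  if (length(eta) == 1L) cum <- matrix(cum, nrow = 1)
  t(apply(cum, 1, diff))
}

#' Linear predictor score from a fitted ordinal model
#'
#' beta.x for each patient; higher score means higher predicted HVPG
#' grade, so the score can be fed to the ROC module as a CSPH/SPH
#' predictor. NA where a predictor is missing.
#' @param model \code{ph_ordinal} fit (must have converged).
#' @param newdata data frame with the model's predictor columns.
#' @return numeric score vector.
#' @export
linear_score <- function(model, newdata) {
  if (!isTRUE(model$converged))
    stop("model did not converge; linear score not usable")
  X <- as.matrix(as.data.frame(newdata)[, model$predictors, drop = FALSE])
  as.numeric(X %*% model$beta)
}

#' Simulate ordinal grades from a proportional-odds model
#'
#' Draws grade k with probability plogis(theta_k - beta.x) -
#' plogis(theta_{k-1} - beta.x); used for parameter-recovery and coverage
#' checks.
#' @param X numeric matrix of predictors (patients x variables).
#' @param beta coefficient vector (length ncol(X)).
#' @param theta strictly increasing thresholds (length K - 1).
#' @return integer grades in 1..K.
#' @export
simulate_ordinal_grades <- function(X, beta, theta) {
  stopifnot(!is.unsorted(theta, strictly = TRUE))
  eta <- drop(as.matrix(X) %*% beta)
  u <- stats::runif(length(eta))
  cum <- sapply(theta, function(t) stats::plogis(t - eta))
  if (length(eta) == 1L) cum <- matrix(cum, nrow = 1)
  1L + rowSums(u > cum)
}
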