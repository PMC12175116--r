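#' @title Mixed binomial / multinomial logit engine
#' @description
#' Shared estimation machinery for binomial and baseline-category
#' multinomial (three-state) logit models with crossed random intercepts,
#' used by the duration analyses and the time-specific trend models. The
#' reference state is `neutral` whenever it occurs; each non-reference state
#' gets its own fixed-effect coefficients, and every grouping factor
#' contributes independent random intercepts per non-reference state with a
#' single shared variance per factor.
#'
#' Estimation maximises the Laplace-approximated marginal likelihood: the
#' outer optimiser works on the log random-effect standard deviations while
#' the fixed effects and random-effect modes are profiled out jointly by a
#' penalised Newton iteration (the fast scheme popularised by lme4's
#' `nAGQ = 0`). Standard errors come from the fixed-effect block of the
#' inverse joint Hessian at the optimum.
#'
#' @name glmm_engine
NULL

#' Specify a mixed logit model
#'
#' @param response_kind `"binomial"` or `"multinomial3"`.
#' @param quadratic include a quadratic term in the continuous predictor?
#' @param random character vector naming the grouping-factor columns.
#' @param predictor name of the continuous predictor column (default
#'   `"year"`).
#' @param reference reference state (default `"neutral"`, used when present).
#' @return object of class `glmm_spec`.
#' @export
glmm_spec <- function(response_kind = c("multinomial3", "binomial"),
                      quadratic = FALSE, random = c("taxon_id", "station_id"),
                      predictor = "year", reference = "neutral") {
  structure(list(response_kind = match.arg(response_kind),
                 quadratic = isTRUE(quadratic), random = random,
                 predictor = predictor, reference = reference),
            class = "glmm_spec")
}

# Internal: assemble design matrices. Returns list with X (n x p dense),
# Z list of n x L_f indicator matrices, Y (n x K-1 indicator of non-reference
# states), state labels etc.
glmm_design <- function(spec, data, x_center = NULL, ref = NULL,
                        nonref = NULL) {
  st <- as.character(data$state)
  lev <- unique(st)
  if (is.null(ref))
    ref <- if (spec$reference %in% lev) spec$reference else sort(lev)[1L]
  if (is.null(nonref))
    nonref <- setdiff(if (spec$response_kind == "multinomial3")
      c("negative", "neutral", "positive") else sort(lev), ref)
  if (spec$response_kind == "binomial" && length(nonref) != 1L)
    stop("binomial response needs exactly two states (got: ",
         paste(lev, collapse = ", "), ")")
  x <- as.numeric(data[[spec$predictor]])
  if (is.null(x_center)) x_center <- mean(x)
  xc <- x - x_center
  X <- if (spec$quadratic) cbind(1, xc, xc^2) else cbind(1, xc)
  colnames(X) <- c("(Intercept)", spec$predictor,
                   if (spec$quadratic) paste0(spec$predictor, "^2"))
  Z <- lapply(spec$random, function(g) {
    f <- factor(as.character(data[[g]]))
    M <- matrix(0, nrow(data), nlevels(f),
                dimnames = list(NULL, levels(f)))
    M[cbind(seq_len(nrow(data)), as.integer(f))] <- 1
    M
  })
  names(Z) <- spec$random
  K1 <- length(nonref)
  Y <- matrix(0, nrow(data), K1)
  for (k in seq_len(K1)) Y[, k] <- as.numeric(st == nonref[k])
  list(X = X, Z = Z, Y = Y, ref = ref, nonref = nonref,
       x_center = x_center, n = nrow(data))
}

# Joint penalised log-likelihood, gradient and Hessian over theta, the
# stacked per-state coefficient vectors [beta_k, u_{1,k}, u_{2,k}, ...].
# M = cbind(X, Z_1, Z_2, ...); pen = per-column penalty (0 for beta,
# 1/sigma_f^2 for u columns of factor f).
glmm_joint <- function(theta, M, Y, pen, want_hessian = FALSE) {
  n <- nrow(M); m <- ncol(M); K1 <- ncol(Y)
  Th <- matrix(theta, m, K1)
  Eta <- M %*% Th                       # n x K1
  Emax <- pmax(0, Eta[, 1L], if (K1 > 1L) Eta[, 2L] else 0)
  denom <- exp(-Emax) + rowSums(exp(Eta - Emax))
  ll <- sum(Eta * Y) - sum(Emax + log(denom))
  P <- exp(Eta - Emax) / denom          # n x K1 probabilities
  penv <- rep(pen, K1)
  ll_pen <- ll - 0.5 * sum(penv * theta^2)
  G <- crossprod(M, Y - P)              # m x K1
  grad <- as.numeric(G) - penv * theta
  out <- list(ll = ll, ll_pen = ll_pen, grad = grad, P = P)
  if (want_hessian) {
    H <- matrix(0, m * K1, m * K1)
    for (k in seq_len(K1)) for (l in k:K1) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      blk <- crossprod(M, M * w)
      ri <- (k - 1L) * m + seq_len(m); ci <- (l - 1L) * m + seq_len(m)
      H[ri, ci] <- H[ri, ci] + blk
      if (l > k) H[ci, ri] <- H[ci, ri] + t(blk)
    }
    diag(H) <- diag(H) + penv
    out$H <- H                          # NEGATIVE Hessian of penalised ll
  }
  out
}

# Penalised Newton with step-halving; returns theta, joint pieces, neg-Hessian.
glmm_newton <- function(theta, M, Y, pen, free = NULL, max_iter = 60L,
                        tol = 1e-8) {
  m <- ncol(M); K1 <- ncol(Y)
  if (is.null(free)) free <- seq_len(m * K1)
  cur <- glmm_joint(theta, M, Y, pen, want_hessian = TRUE)
  for (it in seq_len(max_iter)) {
    g <- cur$grad[free]
    if (max(abs(g)) < tol) break
    H <- cur$H[free, free, drop = FALSE]
    step <- tryCatch(solve(H + diag(1e-10, length(free)), g),
                     error = function(e) NULL)
    if (is.null(step)) step <- g / (diag(H) + 1e-6)
    alpha <- 1
    improved <- FALSE
    while (alpha >= 1e-4) {
      cand <- theta
      cand[free] <- theta[free] + alpha * step
      nxt <- glmm_joint(cand, M, Y, pen, want_hessian = FALSE)
      if (is.finite(nxt$ll_pen) && nxt$ll_pen > cur$ll_pen - 1e-12) {
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    theta <- cand
    cur <- glmm_joint(theta, M, Y, pen, want_hessian = TRUE)
  }
  list(theta = theta, joint = cur)
}

# Laplace marginal log-likelihood at given fixed effects and sigmas; theta
# supplies a warm start for the random-effect modes.
glmm_laplace_ll <- function(theta, M, Y, pen, sigma, L, p) {
  m <- ncol(M); K1 <- ncol(Y)
  uidx <- as.integer(outer((p + 1L):m, (seq_len(K1) - 1L) * m, `+`))
  ns <- glmm_newton(theta, M, Y, pen, free = uidx)
  cur <- ns$joint
  Hu <- cur$H[uidx, uidx, drop = FALSE]
  ld <- as.numeric(determinant(Hu, logarithm = TRUE)$modulus)
  # log prior normalisation: each factor f has L_f * K1 effects of sd sigma_f
  logprior_norm <- -0.5 * sum(K1 * L * log(sigma^2))
  upen <- rep(pen, K1)[uidx]  # exclude the fixed-effect ridge from the ll
  list(ll = cur$ll - 0.5 * sum(upen * ns$theta[uidx]^2) +
         logprior_norm - 0.5 * ld,
       theta = ns$theta)
}

#' Fit a mixed binomial or multinomial logit model
#'
#' @param data data frame with a `state` column (values among `negative`,
#'   `neutral`, `positive` for `multinomial3`; any two labels for
#'   `binomial`), the continuous predictor named in the spec, and one column
#'   per grouping factor.
#' @param spec a [glmm_spec()].
#' @param sigma_fixed optional numeric vector fixing the random-effect
#'   standard deviation of each grouping factor (use `0` to reduce the model
#'   to an ordinary fixed-effects logit).
#' @param x_center optional centring constant for the predictor (defaults to
#'   its mean); bootstrap refits reuse the original centring.
#' @return object of class `glmm_fit`: coefficient matrix `B`
#'   (non-reference states x terms, predictor terms on the centred scale —
#'   slopes are unaffected by centring), `se` (same shape), `sigma2` (named
#'   per-factor random-intercept variances), `loglik` (Laplace), `aic`,
#'   `year_p` (likelihood-ratio p for the predictor block), `converged`,
#'   `separation`, plus the design metadata needed for prediction and
#'   bootstrap refits.
#' @export
fit_glmm <- function(data, spec, sigma_fixed = NULL, x_center = NULL) {
  des <- glmm_design(spec, data, x_center = x_center)
  fit <- fit_glmm_core(des, spec, sigma_fixed)
  # likelihood-ratio test for the predictor block (linear [+ quadratic])
  null_spec <- spec
  null_spec$quadratic <- FALSE
  null_des <- des
  null_des$X <- des$X[, 1L, drop = FALSE]
  null_fit <- fit_glmm_core(null_des, null_spec, sigma_fixed)
  df <- (ncol(des$X) - 1L) * ncol(des$Y)
  lr <- max(0, 2 * (fit$loglik - null_fit$loglik))
  fit$year_p <- pchisq(lr, df, lower.tail = FALSE)
  fit$null_loglik <- null_fit$loglik
  fit$spec <- spec
  fit$data_n <- nrow(data)
  fit
}

fit_glmm_core <- function(des, spec, sigma_fixed = NULL) {
  X <- des$X; Z <- des$Z; Y <- des$Y
  p <- ncol(X); K1 <- ncol(Y)
  L <- vapply(Z, ncol, integer(1))
  M <- do.call(cbind, c(list(X), Z))
  m <- ncol(M)
  nf <- length(Z)
  theta0 <- rep(0, m * K1)
  # weak L2 ridge on the fixed effects: invisible for identified fits,
  # bounds divergence under complete separation
  ridge <- 1e-4
  pen_for <- function(sigma) {
    pen <- numeric(m)
    pen[seq_len(p)] <- ridge
    off <- p
    for (f in seq_len(nf)) {
      pen[off + seq_len(L[f])] <- 1 / sigma[f]^2
      off <- off + L[f]
    }
    pen
  }
  warm <- theta0
  obj <- function(logsig) {
    sigma <- exp(logsig)
    ns <- glmm_newton(warm, M, Y, pen_for(sigma))
    warm <<- ns$theta
    lap <- glmm_laplace_ll(ns$theta, M, Y, pen_for(sigma), sigma, L, p)
    -lap$ll
  }
  if (!is.null(sigma_fixed)) {
    sigma <- pmax(sigma_fixed, 1e-5)
    sigma_hat <- sigma_fixed
  } else {
    lo <- rep(log(1e-4), nf); hi <- rep(log(20), nf)
    op <- tryCatch(
      optim(rep(log(0.5), nf), obj, method = "L-BFGS-B", lower = lo,
            upper = hi, control = list(factr = 1e9)),
      error = function(e) NULL)
    if (is.null(op)) {  # fall back to coarse grid on first factor
      grid <- log(c(1e-4, 0.05, 0.1, 0.25, 0.5, 1, 2, 4))
      vals <- vapply(grid, function(g) obj(rep(g, nf)), numeric(1))
      op <- list(par = rep(grid[which.min(vals)], nf), convergence = 0L)
    }
    sigma <- exp(op$par)
    sigma_hat <- ifelse(sigma < 2e-4, 0, sigma)
  }
  pen <- pen_for(sigma)
  ns <- glmm_newton(warm, M, Y, pen)
  lap <- glmm_laplace_ll(ns$theta, M, Y, pen, sigma, L, p)
  joint <- glmm_joint(ns$theta, M, Y, pen, want_hessian = TRUE)
  # fixed-effect block of the inverse joint Hessian
  bidx <- as.integer(outer(seq_len(p), (seq_len(K1) - 1L) * m, `+`))
  Vb <- tryCatch(solve(joint$H)[bidx, bidx, drop = FALSE],
                 error = function(e) matrix(NA_real_, length(bidx),
                                            length(bidx)))
  Th <- matrix(ns$theta, m, K1)
  B <- t(Th[seq_len(p), , drop = FALSE])
  SE <- t(matrix(sqrt(pmax(diag(Vb), 0)), p, K1))
  dimnames(B) <- dimnames(SE) <- list(des$nonref, colnames(X))
  npar <- p * K1 + if (is.null(sigma_fixed)) nf else 0L
  separation <- any(abs(B) > 15)
  structure(list(B = B, se = SE, vcov_fixed = Vb, sigma2 = setNames(
    sigma_hat^2, names(Z)), loglik = lap$ll, aic = -2 * lap$ll + 2 * npar,
    converged = TRUE, separation = separation,
    nonref = des$nonref, ref = des$ref, x_center = des$x_center,
    random_levels = lapply(Z, colnames), theta = ns$theta, p = p,
    quadratic = ncol(X) == 3L),
    class = "glmm_fit")
}

#' @exportS3Method base::print
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> states vs '%s'; logLik(Laplace) = %.3f, AIC = %.2f\n",
              x$ref, x$loglik, x$aic))
  cat("sigma^2:", paste(sprintf("%s=%.4g", names(x$sigma2), x$sigma2),
                        collapse = ", "), "\n")
  print(round(x$B, 4))
  invisible(x)
}

#' Choose between linear and quadratic year terms by AIC
#'
#' Fits the model with and without the quadratic term and returns the spec
#' whose fit has the lower AIC; exact ties go to the linear (more
#' parsimonious) model.
#'
#' @inheritParams fit_glmm
#' @return the selected [glmm_spec()], with attribute `"fits"` carrying both
#'   fitted models (`linear`, `quadratic`).
#' @export
select_polynomial <- function(data, spec) {
  lin <- spec; lin$quadratic <- FALSE
  qua <- spec; qua$quadratic <- TRUE
  f_lin <- tryCatch(fit_glmm(data, lin), error = function(e) NULL)
  f_qua <- tryCatch(fit_glmm(data, qua), error = function(e) NULL)
  if (is.null(f_lin) && is.null(f_qua)) stop("neither polynomial fit converged")
  out <- if (is.null(f_qua)) lin
  else if (is.null(f_lin)) qua
  else if (f_qua$aic < f_lin$aic - 1e-12) qua else lin
  attr(out, "fits") <- list(linear = f_lin, quadratic = f_qua)
  out
}

#' Population-level state probabilities over time
#'
#' Evaluates the fitted fixed effects (random intercepts at zero) at the
#' requested predictor values and maps them through the softmax; the
#' probabilities over all states sum to one.
#'
#' @param fit a [fit_glmm()] result.
#' @param years numeric predictor values (calendar years for timeline fits).
#' @return data.frame with a `year` column and one probability column per
#'   state (`pi_negative`, `pi_neutral`, `pi_positive` for trend-state
#'   models; absent states get probability zero columns when the canonical
#'   three states apply).
#' @export
predict_state_probabilities <- function(fit, years) {
  xc <- years - fit$x_center
  X <- if (fit$quadratic) cbind(1, xc, xc^2) else cbind(1, xc)
  Eta <- X %*% t(fit$B)                 # n x K1
  Emax <- pmax(0, Eta[, 1L], if (ncol(Eta) > 1L) Eta[, 2L] else 0)
  denom <- exp(-Emax) + rowSums(exp(Eta - Emax))
  P <- exp(Eta - Emax) / denom
  Pref <- exp(-Emax) / denom
  out <- data.frame(year = years)
  all_states <- c(fit$ref, fit$nonref)
  canonical <- c("negative", "neutral", "positive")
  states <- if (all(all_states %in% canonical)) canonical else all_states
  for (s in states) {
    out[[paste0("pi_", s)]] <- if (s == fit$ref) as.numeric(Pref)
    else if (s %in% fit$nonref) as.numeric(P[, match(s, fit$nonref)])
    else 0
  }
  out
}

# Fast refit for bootstrap replicates: random-effect variances held at the
# full-data estimates, (beta, u) re-maximised by penalised Newton on the
# resampled data, predictor centring inherited from the original fit.
refit_glmm_fixed_sigma <- function(fit, data, spec) {
  sigma <- sqrt(pmax(fit$sigma2, 0))
  des <- glmm_design(spec, data, x_center = fit$x_center, ref = fit$ref,
                     nonref = fit$nonref)
  fit_glmm_core(des, spec, sigma_fixed = sigma)
}
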