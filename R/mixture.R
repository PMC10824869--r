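#' Compress proportions away from 0 and 1
#'
#' The standard linear compression for beta-distributed responses observed
#' on the closed unit interval: `y* = (y * (n - 1) + 0.5) / n`, where `n` is
#' the number of observations in the analysed table. Maps 0 to `0.5/n`,
#' 1 to `1 - 0.5/n`, and leaves 0.5 fixed.
#'
#' @param y Proportions in `[0, 1]`.
#' @param n_obs Number of observations (defaults to `length(y)`).
#' @return Compressed proportions in `(0, 1)`.
#' @examples
#' compress_proportions(c(0, 0.5, 1), n_obs = 100)
#' @export
compress_proportions <- function(y, n_obs = length(y)) {
  if (n_obs < 2) stop("n_obs must be >= 2", call. = FALSE)
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  (y * (n_obs - 1) + 0.5) / n_obs
}

# Log-density of the mean-precision beta: shape1 = mu*phi, shape2 = (1-mu)*phi.
.ldbeta <- function(y, mu, phi) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

# Weighted beta regression: maximise sum(w * ldbeta(y; plogis(X b), phi))
# over (b, log phi) by BFGS with analytic gradient.
.fit_wbeta <- function(X, y, w, start = NULL, maxit = 200) {
  p <- ncol(X)
  ly <- log(y); l1y <- log1p(-y)
  if (is.null(start)) {
    # logit-scale weighted least squares + moment estimate of phi
    z <- qlogis(pmin(pmax(y, 1e-6), 1 - 1e-6))
    W <- w / sum(w)
    b0 <- tryCatch(
      solve(crossprod(X * sqrt(W)), crossprod(X * W, z))[, 1],
      error = function(e) c(qlogis(mean(pmin(pmax(
        sum(W * y), 1e-6), 1 - 1e-6))), rep(0, p - 1))
    )
    mu0 <- plogis(drop(X %*% b0))
    v <- sum(W * (y - mu0)^2)
    phi0 <- max(min(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1e4), 1)
    start <- c(b0, log(phi0))
  }
  nll <- function(theta) {
    mu <- plogis(drop(X %*% theta[1:p]))
    phi <- exp(theta[p + 1])
    -sum(w * .ldbeta(y, mu, phi))
  }
  gr <- function(theta) {
    eta <- drop(X %*% theta[1:p])
    mu <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    phi <- exp(theta[p + 1])
    dmu <- phi * (-digamma(mu * phi) + digamma((1 - mu) * phi) + ly - l1y)
    deta <- dmu * mu * (1 - mu)
    gb <- -drop(crossprod(X, w * deta))
    dlphi <- phi * (digamma(phi) - mu * digamma(mu * phi) -
                      (1 - mu) * digamma((1 - mu) * phi) +
                      mu * ly + (1 - mu) * l1y)
    c(gb, -sum(w * dlphi))
  }
  fit <- optim(start, nll, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  list(beta = fit$par[1:p], phi = exp(fit$par[p + 1]),
       loglik = -fit$value, par = fit$par)
}

# Observed-data log-likelihood of the 2-component mixture.
.mix_loglik <- function(y, X, beta1, beta2, phi, pi1) {
  l1 <- log(pi1) + .ldbeta(y, plogis(drop(X %*% beta1)), phi[1])
  l2 <- log(1 - pi1) + .ldbeta(y, plogis(drop(X %*% beta2)), phi[2])
  m <- pmax(l1, l2)
  sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

# One EM pass from given responsibilities; returns fitted state.
.em_run <- function(y, X, r1, max_iter, tol, warm = NULL) {
  trace <- numeric(0)
  beta1 <- beta2 <- NULL
  st1 <- if (!is.null(warm)) warm$par1 else NULL
  st2 <- if (!is.null(warm)) warm$par2 else NULL
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    pi1 <- min(max(mean(r1), 1e-6), 1 - 1e-6)
    f1 <- .fit_wbeta(X, y, r1, start = st1)
    f2 <- .fit_wbeta(X, y, 1 - r1, start = st2)
    st1 <- f1$par; st2 <- f2$par
    beta1 <- f1$beta; beta2 <- f2$beta
    phi <- c(f1$phi, f2$phi)
    ll <- .mix_loglik(y, X, beta1, beta2, phi, pi1)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll < ll_old - 1e-6 * (abs(ll_old) + 1)) {
      warning("EM log-likelihood decreased at iteration ", it)
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      break
    }
    ll_old <- ll
    # E-step
    l1 <- log(pi1) + .ldbeta(y, plogis(drop(X %*% beta1)), phi[1])
    l2 <- log(1 - pi1) + .ldbeta(y, plogis(drop(X %*% beta2)), phi[2])
    r1 <- 1 / (1 + exp(l2 - l1))
  }
  list(beta1 = beta1, beta2 = beta2, phi = phi, pi1 = pi1, r1 = r1,
       loglik = trace[length(trace)], trace = trace, n_iter = length(trace),
       par1 = st1, par2 = st2,
       converged = length(trace) < max_iter)
}

#' Fit a two-component beta-regression mixture by EM
#'
#' Maximises the mixture log-likelihood
#' `sum(log(pi * Beta(y; mu1, phi1) + (1 - pi) * Beta(y; mu2, phi2)))`
#' with `logit(mu_k) = X beta_k`, where the design codes depth class
#' (reference shallow) and aspect class (reference N) as dummies. The EM
#' algorithm alternates posterior responsibilities (E-step) with weighted
#' beta-regression updates of each component and the mixing weight (M-step).
#' Initialisation is k-means on the logit responses plus seeded random
#' restarts; the best short run is iterated to convergence. Components are
#' reported sorted by intercept (component 1 = smaller intercept). Wald
#' `z = beta / SE` uses standard errors from the observed information
#' (numerical Hessian of the full mixture likelihood).
#'
#' @param table data.frame with columns `proportion`, `depth_class`
#'   (`"shallow"`/`"deep"`), `aspect_class` (`"N"/"E"/"S"/"W"`).
#' @param seed Integer seed for restarts.
#' @param compress Apply [compress_proportions()] to the responses (set
#'   FALSE when the responses are already strictly inside (0,1), e.g.
#'   simulated draws).
#' @param interaction Include depth x aspect interaction terms.
#' @param n_restarts Number of initialisations (k-means plus random).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `beta_mixture_fit`: `coefficients` (per-component
#'   matrix of estimate/se/z/p), `phi`, `pi1`, `posterior` (n x 2, rows sum
#'   to 1), `loglik`, `loglik_trace`, `converged`, `n_iter`, `design`.
#' @export
fit_beta_mixture <- function(table, seed = 1L, compress = TRUE,
                             interaction = FALSE, n_restarts = 10,
                             tol = 1e-8, max_iter = 1000) {
  req <- c("proportion", "depth_class", "aspect_class")
  if (!all(req %in% names(table))) {
    stop("table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  y <- table$proportion
  if (compress) y <- compress_proportions(y)
  if (any(y <= 0 | y >= 1)) {
    stop("responses must lie strictly in (0,1); use compress = TRUE",
         call. = FALSE)
  }
  X <- mixture_design(table$depth_class, table$aspect_class, interaction)
  n <- length(y)
  if (n < ncol(X) * 2 + 3) stop("too few observations", call. = FALSE)

  # candidate initial responsibilities
  inits <- with_seed(seed, {
    z <- qlogis(y)
    km <- tryCatch(kmeans(z, centers = 2, nstart = 5),
                   error = function(e) NULL)
    cand <- list()
    if (!is.null(km)) {
      cand[[1]] <- as.numeric(km$cluster == which.min(km$centers)) * 0.9 + 0.05
    }
    while (length(cand) < n_restarts) {
      cand[[length(cand) + 1]] <- runif(n, 0.05, 0.95)
    }
    cand
  })

  short <- lapply(inits, function(r1) {
    tryCatch(.em_run(y, X, r1, max_iter = 15, tol = tol),
             error = function(e) NULL)
  })
  short <- Filter(function(s) !is.null(s) && is.finite(s$loglik), short)
  if (length(short) == 0) stop("all EM initialisations failed", call. = FALSE)
  best <- short[[which.max(vapply(short, `[[`, numeric(1), "loglik"))]]
  fit <- .em_run(y, X, best$r1, max_iter = max_iter, tol = tol, warm = best)
  if (!fit$converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }

  # identifiability: component 1 = smaller intercept
  if (fit$beta1[1] > fit$beta2[1]) {
    fit[c("beta1", "beta2")] <- fit[c("beta2", "beta1")]
    fit$phi <- rev(fit$phi)
    fit$pi1 <- 1 - fit$pi1
    fit$r1 <- 1 - fit$r1
  }
  if (fit$pi1 < 1e-3 || fit$pi1 > 1 - 1e-3) {
    warning("degenerate mixture: a component weight is near the boundary")
  }

  p <- ncol(X)
  theta <- c(fit$beta1, log(fit$phi[1]), fit$beta2, log(fit$phi[2]),
             qlogis(fit$pi1))
  negll <- function(th) {
    -.mix_loglik(y, X, th[1:p], th[(p + 2):(2 * p + 1)],
                 exp(th[c(p + 1, 2 * p + 2)]), plogis(th[2 * p + 3]))
  }
  se <- rep(NA_real_, length(theta))
  H <- tryCatch(pracma::hessian(negll, theta), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  if (anyNA(se)) warning("observed information is singular for some ",
                         "parameters; their SEs are NA")
  coef_tab <- function(beta, se_beta) {
    z <- beta / se_beta
    cbind(estimate = beta, se = se_beta, z = z,
          p = 2 * pnorm(-abs(z)))
  }
  co1 <- coef_tab(fit$beta1, se[1:p])
  co2 <- coef_tab(fit$beta2, se[(p + 2):(2 * p + 1)])
  rownames(co1) <- rownames(co2) <- colnames(X)

  structure(
    list(coefficients = list(component1 = co1, component2 = co2),
         phi = fit$phi, pi1 = fit$pi1,
         posterior = cbind(comp1 = fit$r1, comp2 = 1 - fit$r1),
         loglik = fit$loglik, loglik_trace = fit$trace,
         converged = fit$converged, n_iter = fit$n_iter,
         design = colnames(X), n = n, compress = compress),
    class = "beta_mixture_fit"
  )
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Two-component beta regression mixture (n = %d, logLik = %.2f)\n",
    x$n, x$loglik))
  cat(sprintf("  pi1 = %.3f, phi = (%.2f, %.2f), %d EM iterations\n",
              x$pi1, x$phi[1], x$phi[2], x$n_iter))
  for (k in 1:2) {
    cat("  component ", k, ":\n", sep = "")
    print(round(x$coefficients[[k]], 4))
  }
  invisible(x)
}

#' Assign observations to mixture components
#'
#' Hard assignment by maximum posterior probability; an exact tie goes to
#' component 1.
#'
#' @param fit A [fit_beta_mixture()] result.
#' @return Integer vector of 1s and 2s.
#' @export
assign_components <- function(fit) {
  stopifnot(inherits(fit, "beta_mixture_fit"))
  ifelse(fit$posterior[, 1] >= fit$posterior[, 2], 1L, 2L)
}

#' Likelihood-ratio test for a depth x aspect interaction
#'
#' Within each mixture component's observations (hard-assigned by posterior
#' probability, or given explicitly), compares beta regressions with and
#' without depth x aspect interaction terms by a likelihood-ratio test with
#' 3 degrees of freedom. The full model is warm-started from the reduced
#' fit, so its log-likelihood can never fall below the reduced one.
#'
#' @param table Observation table as in [fit_beta_mixture()].
#' @param fit Optional existing mixture fit for `table` (fitted if absent).
#' @param groups Optional explicit component labels (overrides `fit`).
#' @param compress Apply the zero/one compression to responses.
#' @param seed Seed for the mixture fit when one is needed.
#' @return data.frame: `component`, `df`, `statistic`, `p_value`,
#'   `loglik_reduced`, `loglik_full`.
#' @export
interaction_test <- function(table, fit = NULL, groups = NULL,
                             compress = TRUE, seed = 1L) {
  y <- table$proportion
  if (compress) y <- compress_proportions(y)
  if (is.null(groups)) {
    if (is.null(fit)) {
      fit <- fit_beta_mixture(table, seed = seed, compress = compress)
    }
    groups <- assign_components(fit)
  }
  out <- lapply(sort(unique(groups)), function(k) {
    sel <- groups == k
    Xr <- mixture_design(table$depth_class[sel], table$aspect_class[sel])
    Xf <- mixture_design(table$depth_class[sel], table$aspect_class[sel],
                         interaction = TRUE)
    n_int <- ncol(Xf) - ncol(Xr)
    w <- rep(1, sum(sel))
    fr <- .fit_wbeta(Xr, y[sel], w)
    ff <- .fit_wbeta(Xf, y[sel], w,
                     start = c(fr$beta, rep(0, n_int), log(fr$phi)))
    if (ff$loglik < fr$loglik - 1e-6) {
      stop("nested-model likelihood ordering violated: numerical failure",
           call. = FALSE)
    }
    stat <- max(2 * (ff$loglik - fr$loglik), 0)
    data.frame(component = k, df = n_int, statistic = stat,
               p_value = stats::pchisq(stat, df = n_int, lower.tail = FALSE),
               loglik_reduced = fr$loglik, loglik_full = ff$loglik)
  })
  do.call(rbind, out)
}
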