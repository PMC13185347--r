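#' Restricted maximum likelihood fit of a multi-kernel mixed model
#'
#' Fits `y = X a + sum_k u_k + e` with `u_k ~ N(0, sigma2_k K_k)` and
#' `e ~ N(0, sigma2_e I)` by maximizing the restricted likelihood over the
#' variance components. Updates are average-information (AI) steps with
#' step-halving; when an AI step fails to improve the restricted
#' log-likelihood an expectation-maximization step is taken instead, so
#' accepted iterations never decrease the likelihood. Components whose
#' update goes negative are pinned at a small floor (`1e-6` of the current
#' phenotypic variance).
#'
#' With a single genomic kernel the genetic ratio is the SNP heritability;
#' with a genomic kernel plus per-segment microbial kernels the ratios are
#' the omics-explainabilities of the phenotype.
#'
#' @param y numeric trait vector.
#' @param covariates numeric matrix of fixed covariates (an intercept is
#'   always added), or `NULL` for intercept only.
#' @param kernels a single [kernel_matrix()] or a named list of them (plain
#'   symmetric matrices are accepted); all must share the sample ordering of
#'   `y`.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on successive restricted
#'   log-likelihoods (default 1e-8).
#' @return An object of class `variance_decomposition`: list with
#'   `components` (data.frame: component, variance, se, ratio), `loglik`,
#'   `converged`, `iterations`, `n`, `vcov` (inverse AI at the optimum), and
#'   the data (`y`, `X`) the model was fit to.
#' @export
reml_fit <- function(y, covariates = NULL, kernels, max_iter = 200,
                     tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y must not contain missing values")
  if (inherits(kernels, "kernel_matrix") || is.matrix(kernels)) {
    kernels <- list(genetic = kernels)
  }
  if (is.null(names(kernels)) || any(names(kernels) == "")) {
    names(kernels) <- paste0("kernel", seq_along(kernels))
  }
  if ("residual" %in% names(kernels)) stop("'residual' is a reserved label")
  K <- lapply(kernels, function(k) {
    v <- if (inherits(k, "kernel_matrix")) k$values else as.matrix(k)
    if (nrow(v) != n || ncol(v) != n) {
      stop("kernel dimension does not match length(y)")
    }
    if (max(abs(v - t(v))) > 1e-8) stop("kernel is not symmetric")
    (v + t(v)) / 2
  })
  X <- cbind(Intercept = rep(1, n), covariates)
  q <- qr(X)$rank
  if (q < ncol(X)) stop("covariate matrix is rank deficient")
  if (n <= q + 1) stop("need n > rank(covariates) + 1 observations")
  labels <- c(names(K), "residual")
  m <- length(labels)
  Kfull <- c(K, list(residual = diag(n)))

  # restricted log-likelihood and the P-projections at a parameter point
  eval_point <- function(sigma, need_P = TRUE) {
    V <- matrix(0, n, n)
    for (k in seq_len(m)) V <- V + sigma[k] * Kfull[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    B <- solve(XtVinvX, t(VinvX))      # (X'V^-1X)^-1 X'V^-1
    Py <- Vinv %*% y - VinvX %*% (B %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py) + (n - q) * log(2 * pi))
    out <- list(ll = ll, Py = as.numeric(Py))
    if (need_P) {
      out$P <- Vinv - VinvX %*% B
    }
    out
  }

  score_and_ai <- function(st) {
    Py <- st$Py
    KPy <- vapply(Kfull, function(Kk) as.numeric(Kk %*% Py), numeric(n))
    # tr(P K) via elementwise product (both symmetric)
    trPK <- vapply(Kfull, function(Kk) sum(st$P * Kk), numeric(1))
    yPKPy <- as.numeric(crossprod(KPy, Py))
    score <- -0.5 * (trPK - yPKPy)
    PKPy <- st$P %*% KPy
    ai <- 0.5 * crossprod(KPy, PKPy)
    list(score = score, ai = (ai + t(ai)) / 2, yPKPy = yPKPy, trPK = trPK)
  }

  # starting values: equal split of the residual variance of the fixed model
  s0 <- sum(lm.fit(X, y)$residuals^2) / (n - q)
  sigma <- rep(s0 / m, m)
  st <- eval_point(sigma)
  if (is.null(st)) stop("initial variance point is not positive definite")
  ll <- st$ll
  converged <- FALSE
  iter <- 0
  sa <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    sa <- score_and_ai(st)
    floor_k <- 1e-6 * sum(sigma)
    step <- tryCatch(solve(sa$ai, sa$score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      frac <- 1
      for (h in 1:6) {                       # step-halving on the AI update
        cand <- pmax(sigma + frac * step, floor_k)
        st_new <- eval_point(cand)
        if (!is.null(st_new) && is.finite(st_new$ll) &&
            st_new$ll >= ll - 1e-12) {
          accepted <- TRUE; break
        }
        frac <- frac / 2
      }
    }
    if (!accepted) {                         # EM fallback (guaranteed ascent)
      cand <- pmax(sigma + sigma^2 / n * (sa$yPKPy - sa$trPK), floor_k)
      st_new <- eval_point(cand)
      if (is.null(st_new) || !is.finite(st_new$ll) || st_new$ll < ll - 1e-9) {
        break                                # numerically stuck: stop here
      }
    }
    delta <- st_new$ll - ll
    sigma <- cand; st <- st_new; ll <- st_new$ll
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  sa <- score_and_ai(st)
  vcov <- tryCatch(solve(sa$ai), error = function(e) {
    matrix(NA_real_, m, m)
  })
  se <- suppressWarnings(sqrt(pmax(diag(vcov), 0)))
  sigma_p <- sum(sigma)
  out <- list(components = data.frame(component = labels, variance = sigma,
                                      se = se, ratio = sigma / sigma_p,
                                      stringsAsFactors = FALSE),
              loglik = ll, converged = converged, iterations = iter,
              n = n, q = q, sigma_p = sigma_p, vcov = vcov, y = y, X = X)
  if (!converged) {
    warning("REML did not converge in ", iter, " iterations")
  }
  class(out) <- "variance_decomposition"
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition> n=%d, logLik=%.4f, %s in %d iter\n",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(transform(x$components, variance = signif(variance, 4),
                  se = signif(se, 4), ratio = signif(ratio, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Variance ratio (heritability / explainability) of one component
#'
#' Returns `sigma2_component / sigma2_p` with a delta-method standard error
#' from the inverse average-information matrix.
#'
#' @param d a `variance_decomposition` from [reml_fit()].
#' @param component component label (default `"genetic"`).
#' @return list with `ratio`, `se`, `variance`, `sigma_p`.
#' @export
heritability <- function(d, component = "genetic") {
  stopifnot(inherits(d, "variance_decomposition"))
  comp <- d$components
  k <- match(component, comp$component)
  if (is.na(k)) stop("component not in the decomposition: ", component)
  s <- comp$variance
  sp <- sum(s)
  if (sp <= 0) stop("total phenotypic variance is zero")
  grad <- -s[k] / sp^2 + (seq_along(s) == k) / sp
  se <- if (all(is.finite(d$vcov))) {
    sqrt(max(0, drop(t(grad) %*% d$vcov %*% grad)))
  } else NA_real_
  list(ratio = s[k] / sp, se = se, variance = s[k], sigma_p = sp)
}

#' Likelihood-ratio test for one variance component
#'
#' `LRT = 2 (ll_full - ll_reduced)`, clipped at zero. Because the null value
#' of a variance component lies on the boundary of its parameter space, the
#' default null distribution is the equal mixture `0.5 chi2_0 + 0.5 chi2_1`
#' (so `p = 0.5 P(chi2_1 >= LRT)`, and `p = 0.5` at LRT = 0);
#' `mixture = FALSE` restores the plain chi-square with 1 df.
#'
#' @param full,reduced `variance_decomposition` objects fit to the same data;
#'   `reduced` must omit exactly one non-residual component of `full`.
#' @param mixture use the boundary mixture null (default `TRUE`).
#' @return list with `lrt` and `p`.
#' @export
lrt_component <- function(full, reduced, mixture = TRUE) {
  stopifnot(inherits(full, "variance_decomposition"),
            inherits(reduced, "variance_decomposition"))
  if (full$n != reduced$n || !isTRUE(all.equal(full$y, reduced$y))) {
    stop("full and reduced models were fit to different data")
  }
  dropped <- setdiff(full$components$component, reduced$components$component)
  if (length(dropped) != 1) {
    stop("reduced model must omit exactly one component of the full model")
  }
  lrt <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  if (mixture) p <- 0.5 * p
  list(lrt = lrt, p = p, dropped = dropped)
}

# ---- fast spectral path for repeated single-kernel fits -------------------

# Restricted log-likelihood of the no-kernel model y = Xa + e, on the same
# scale as reml_fit()'s objective.
reml_null_loglik <- function(y, X) {
  n <- length(y); q <- ncol(X)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - q)
  -0.5 * ((n - q) * (log(2 * pi * s2) + 1) + 2 * sum(log(abs(diag(qr.R(qr(X)))))))
}

# Profiled restricted log-likelihood for V = sigma2 (lambda D + I) in the
# eigenbasis of a single kernel; returns the fit at the profiled optimum.
spectral_profile <- function(ystar, Xstar, d, log_lambda) {
  lambda <- exp(log_lambda)
  n <- length(ystar); q <- ncol(Xstar)
  h <- lambda * d + 1
  w <- 1 / h
  XtWX <- crossprod(Xstar, Xstar * w)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xstar, ystar * w)))
  r <- ystar - Xstar %*% beta
  rss <- sum(w * r^2)
  s2 <- rss / (n - q)
  ll <- -0.5 * ((n - q) * (log(2 * pi * s2) + 1) + sum(log(h)) +
                  2 * sum(log(diag(ch))))
  list(ll = ll, lambda = lambda, sigma_e = s2, sigma_g = lambda * s2)
}

# Single-kernel REML via one shared eigendecomposition. `eig` is
# eigen(K, symmetric = TRUE). Returns estimates, h2 with an
# average-information SE, and the restricted log-likelihoods of the full
# and the no-kernel model (for the LRT).
reml_single_spectral <- function(y, X, eig, interval = c(-12, 12)) {
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  ystar <- as.numeric(crossprod(U, y))
  Xstar <- crossprod(U, X)
  n <- length(y); q <- ncol(X)
  obj <- function(ll) spectral_profile(ystar, Xstar, d, ll)$ll
  opt <- optimize(obj, interval = interval, maximum = TRUE, tol = 1e-9)
  ll0 <- reml_null_loglik(y, X)
  if (opt$objective <= ll0 + 1e-12) {    # boundary: no kernel variance
    fit0 <- list(sigma_g = 0, sigma_e = sum(lm.fit(X, y)$residuals^2) / (n - q))
    return(list(sigma_g = 0, sigma_e = fit0$sigma_e, h2 = 0, se = NA_real_,
                loglik = ll0, loglik_null = ll0, lambda = 0))
  }
  fit <- spectral_profile(ystar, Xstar, d, opt$maximum)
  sg <- fit$sigma_g; se_ <- fit$sigma_e
  # AI-based covariance of (sigma_g, sigma_e) in the eigenbasis
  v <- sg * d + se_
  w <- 1 / v
  XtWX <- crossprod(Xstar, Xstar * w)
  applyP <- function(u) {
    wu <- w * u
    wu - (Xstar * w) %*% solve(XtWX, crossprod(Xstar, wu))
  }
  Py <- as.numeric(applyP(ystar))
  u1 <- d * Py; u2 <- Py
  Pu1 <- as.numeric(applyP(u1)); Pu2 <- as.numeric(applyP(u2))
  ai <- 0.5 * matrix(c(sum(u1 * Pu1), sum(u1 * Pu2),
                       sum(u2 * Pu1), sum(u2 * Pu2)), 2, 2)
  vc <- tryCatch(solve(ai), error = function(e) matrix(NA_real_, 2, 2))
  sp <- sg + se_
  grad <- c(se_, -sg) / sp^2
  se_h2 <- if (all(is.finite(vc))) sqrt(max(0, drop(t(grad) %*% vc %*% grad)))
           else NA_real_
  list(sigma_g = sg, sigma_e = se_, h2 = sg / sp, se = se_h2,
       loglik = fit$ll, loglik_null = ll0, lambda = fit$lambda)
}

#' Screen taxa for significant heritability
#'
#' Fits a single-kernel animal model to each taxon's CLR abundance (per
#' segment), tests the genetic variance by likelihood-ratio test against the
#' no-kernel model, and flags taxa as heritable when `h2 > h2_threshold` and
#' `p < alpha` jointly. One eigendecomposition of the GRM is shared across
#' all taxa, so the per-taxon fit is a one-dimensional profiled
#' optimization.
#'
#' @param tables an [abundance_table()] or named list of them (one per
#'   segment). Counts/relative tables are CLR-transformed first; `clr` or
#'   `zscore` tables are used as given.
#' @param grm a [kernel_matrix()] of kind `"GRM"`.
#' @param covariates fixed covariates (e.g. the top genetic PCs), or `NULL`.
#' @param h2_threshold heritable-taxon ratio cut-off (default 0.2).
#' @param alpha heritable-taxon LRT p cut-off (default 0.05).
#' @param mixture boundary-mixture LRT null (default `TRUE`), see
#'   [lrt_component()].
#' @return data.frame with one row per taxon per segment: `segment`,
#'   `taxon`, `sigma2_g`, `sigma2_e`, `h2`, `se`, `lrt`, `p`, `heritable`,
#'   `ok` (FALSE rows mark fit failures, e.g. constant taxa; they are kept,
#'   never dropped).
#' @export
screen_heritable_taxa <- function(tables, grm, covariates = NULL,
                                  h2_threshold = 0.2, alpha = 0.05,
                                  mixture = TRUE) {
  stopifnot(inherits(grm, "kernel_matrix"))
  if (inherits(tables, "abundance_table")) {
    tables <- setNames(list(tables), tables$segment)
  }
  eig <- eigen(grm$values, symmetric = TRUE)
  n <- nrow(grm$values)
  X <- cbind(Intercept = rep(1, n), covariates)
  rows <- list()
  for (seg_name in names(tables)) {
    t <- tables[[seg_name]]
    if (t$scale %in% c("counts", "relative")) t <- clr_transform(t)
    if (nrow(t$values) != n) stop("table/GRM sample mismatch in ", seg_name)
    for (a in colnames(t$values)) {
      ya <- t$values[, a]
      row <- data.frame(segment = t$segment, taxon = a,
                        sigma2_g = NA_real_, sigma2_e = NA_real_,
                        h2 = NA_real_, se = NA_real_, lrt = NA_real_,
                        p = NA_real_, heritable = NA, ok = FALSE,
                        stringsAsFactors = FALSE)
      fit <- tryCatch(reml_single_spectral(ya, X, eig), error = function(e) NULL)
      if (!is.null(fit)) {
        lrt <- max(0, 2 * (fit$loglik - fit$loglik_null))
        p <- pchisq(lrt, 1, lower.tail = FALSE)
        if (mixture) p <- 0.5 * p
        row$sigma2_g <- fit$sigma_g; row$sigma2_e <- fit$sigma_e
        row$h2 <- fit$h2; row$se <- fit$se
        row$lrt <- lrt; row$p <- p
        row$heritable <- fit$h2 > h2_threshold & p < alpha
        row$ok <- TRUE
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  res <- do.call(rbind, rows)
  for (s in unique(res$segment)) {
    sel <- res$segment == s & res$ok
    message(sprintf("screen_heritable_taxa [%s]: %d/%d heritable (%.1f%%)",
                    s, sum(res$heritable[sel], na.rm = TRUE), sum(sel),
                    100 * mean(res$heritable[sel], na.rm = TRUE)))
  }
  rownames(res) <- NULL
  res
}
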