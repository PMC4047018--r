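#' Fit a univariate Gaussian mixture model by expectation-maximization
#'
#' Fits a `G`-component normal mixture to a numeric vector by EM, in either
#' the equal-variance family (one common variance across components) or the
#' free-variance family (one variance per component).  Initialization is
#' deterministic by default: the sorted values are cut into `G` contiguous
#' blocks of near-equal size, so repeated fits of the same data are
#' identical without any stored random state.  An agglomerative alternative
#' (`init = "hclust"`, Ward linkage on the raw values) is available.
#'
#' The number of free parameters is `2G` for the equal-variance family
#' (`G` means, one variance, `G - 1` weights) and `3G - 1` for the
#' free-variance family.  Component variances are floored at
#' `1e-6 * var(x)` (or `1e-12` for constant data) to prevent spike
#' components from collapsing onto single observations.
#'
#' @param x numeric vector of observations (finite, length >= `G`).
#' @param G integer, number of mixture components.
#' @param family `"free_variance"` or `"equal_variance"`.
#' @param init initialization strategy, `"quantile"` (default) or `"hclust"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return an object of class `"gmm1d"`: a list with elements `family`, `G`,
#'   `weights`, `means`, `variances`, `loglik`, `loglik_trace`, `n`, `df`,
#'   `BIC`, `z` (responsibility matrix) and `x` (the data).
#' @seealso [bic()], [select_gmm()], [partition_to_intervals()]
#' @examples
#' m <- fit_gmm1d(c(rnorm(50), rnorm(50, 8)), G = 2)
#' coef(m)
#' @export
fit_gmm1d <- function(x, G, family = c("free_variance", "equal_variance"),
                      init = c("quantile", "hclust"),
                      tol = 1e-8, max_iter = 500L) {
  family <- match.arg(family)
  init <- match.arg(init)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop2("'x' must be finite and non-missing")
  n <- length(x)
  if (!is_count(G)) stop2("'G' must be a positive integer")
  G <- as.integer(G)
  if (n < G) stop2("need at least G = ", G, " observations, got ", n)

  vx <- stats::var(x)
  vfloor <- if (is.na(vx) || vx <= 0) 1e-12 else 1e-6 * vx

  assign0 <- switch(init,
    quantile = {
      if (G == 1L) rep(1L, n)
      else {
        grp <- integer(n)
        grp[order(x)] <- as.integer(cut(seq_len(n), breaks = G,
                                        labels = FALSE))
        grp
      }
    },
    hclust = {
      if (G == 1L) rep(1L, n)
      else stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = G)
    })

  fit <- em_run(x, G, family, assign0, tol, max_iter, vfloor)
  tries <- 0L
  while (is.null(fit) && tries < 3L) {
    tries <- tries + 1L
    # deterministic restart: re-cut with jittered block boundaries
    grp <- integer(n)
    grp[order(x)] <- 1L + (seq_len(n) + tries) %% G
    fit <- em_run(x, G, family, grp, tol, max_iter, vfloor)
  }
  if (is.null(fit))
    stop2("EM degenerated (empty component) after bounded retries; ",
          "reduce G or use more data")

  df <- if (family == "equal_variance") 2L * G else 3L * G - 1L
  structure(
    list(family = family, G = G,
         weights = fit$w, means = fit$mu, variances = fit$s2,
         loglik = fit$ll, loglik_trace = fit$trace,
         n = n, df = df, BIC = 2 * fit$ll - df * log(n),
         z = fit$z, x = x, init = init, iterations = fit$iter,
         converged = fit$converged),
    class = "gmm1d")
}

# One EM run from a hard initial assignment; returns NULL on degeneracy.
em_run <- function(x, G, family, assign0, tol, max_iter, vfloor) {
  n <- length(x)
  z <- matrix(0, n, G)
  z[cbind(seq_len(n), assign0)] <- 1
  ll_old <- -Inf
  trace <- numeric(0)
  w <- mu <- s2 <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # M step
    nk <- colSums(z)
    if (any(nk < 1e-10)) return(NULL)
    w <- nk / n
    mu <- colSums(z * x) / nk
    dev2 <- (matrix(x, n, G) - matrix(mu, n, G, byrow = TRUE))^2
    if (family == "equal_variance") {
      s2 <- rep(max(sum(z * dev2) / n, vfloor), G)
    } else {
      s2 <- pmax(colSums(z * dev2) / nk, vfloor)
    }
    # E step (log domain)
    lg <- matrix(log(w), n, G, byrow = TRUE) -
      0.5 * (log(2 * pi * matrix(s2, n, G, byrow = TRUE)) +
             dev2 / matrix(s2, n, G, byrow = TRUE))
    lse <- row_logsumexp(lg)
    ll <- sum(lse)
    trace <- c(trace, ll)
    z <- exp(lg - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(w = w, mu = mu, s2 = s2, ll = trace[length(trace)], trace = trace,
       z = z, iter = iter, converged = converged)
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' Computed as `2 * loglik - df * log(n)` so that larger values indicate
#' better models (the convention of model-based clustering software).
#'
#' @param object a fitted [`fit_gmm1d()`] model, or any list with numeric
#'   elements `loglik`, `df` and `n`.
#' @return a single number.
#' @export
bic <- function(object) {
  2 * object$loglik - object$df * log(object$n)
}

#' Select a mixture model over a grid of component counts and families
#'
#' Fits every combination of family and `G` in the requested grid and
#' returns the fit with the highest BIC together with the full BIC table
#' (the data behind a BIC-curve plot).  Ties are broken toward smaller `G`,
#' then toward the equal-variance family.
#'
#' @param x numeric vector of observations (length >= 2).
#' @param G_range integer vector of component counts to try (default 1:9).
#' @param families character vector of families to try.
#' @param ... passed to [fit_gmm1d()].
#' @return an object of class `"gmm_selection"`: list with `best` (a
#'   `"gmm1d"`), `table` (data.frame of family, G, df, loglik, BIC) and
#'   `models` (all successful fits).
#' @export
select_gmm <- function(x, G_range = 1:9,
                       families = c("equal_variance", "free_variance"), ...) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop2("need at least 2 observations")
  families <- match.arg(families, c("equal_variance", "free_variance"),
                        several.ok = TRUE)
  grid <- expand.grid(G = as.integer(G_range), family = families,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$G <= length(x), , drop = FALSE]
  models <- vector("list", nrow(grid))
  tab <- data.frame(family = grid$family, G = grid$G, df = NA_integer_,
                    loglik = NA_real_, BIC = NA_real_)
  for (i in seq_len(nrow(grid))) {
    m <- tryCatch(fit_gmm1d(x, grid$G[i], family = grid$family[i], ...),
                  error = function(e) NULL)
    if (!is.null(m)) {
      models[[i]] <- m
      tab$df[i] <- m$df
      tab$loglik[i] <- m$loglik
      tab$BIC[i] <- m$BIC
    }
  }
  ok <- which(!is.na(tab$BIC))
  if (!length(ok)) stop2("all mixture fits failed or degenerated")
  # argmax BIC; ties -> smaller G, then equal_variance
  o <- ok[order(-tab$BIC[ok], tab$G[ok],
                tab$family[ok] != "equal_variance")]
  best <- models[[o[1L]]]
  structure(list(best = best, table = tab, models = models),
            class = "gmm_selection")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat(sprintf("Univariate Gaussian mixture (%s), G = %d, n = %d\n",
              x$family, x$G, x$n))
  print(coef(x), digits = 4)
  cat(sprintf("logLik %.4f  df %d  BIC %.4f\n", x$loglik, x$df, x$BIC))
  invisible(x)
}

#' @export
coef.gmm1d <- function(object, ...) {
  cbind(weight = object$weights, mean = object$means,
        variance = object$variances)
}

#' @export
logLik.gmm1d <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
summary.gmm1d <- function(object, ...) {
  structure(list(model = object, bic = bic(object)), class = "summary.gmm1d")
}

#' @export
print.summary.gmm1d <- function(x, ...) {
  print(x$model)
  cat(sprintf("converged after %d iterations: %s\n",
              x$model$iterations, x$model$converged))
  invisible(x)
}

#' Posterior component membership for a fitted mixture
#'
#' @param object a `"gmm1d"` fit.
#' @param newdata numeric values to classify; defaults to the training data.
#' @param type `"class"` for MAP component indices, `"posterior"` for the
#'   full responsibility matrix.
#' @param ... unused.
#' @return integer vector or numeric matrix.
#' @export
predict.gmm1d <- function(object, newdata = NULL,
                          type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  xx <- if (is.null(newdata)) object$x else as.numeric(newdata)
  n <- length(xx)
  G <- object$G
  lg <- matrix(log(object$weights), n, G, byrow = TRUE) +
    stats::dnorm(matrix(xx, n, G),
                 matrix(object$means, n, G, byrow = TRUE),
                 sqrt(matrix(object$variances, n, G, byrow = TRUE)),
                 log = TRUE)
  if (type == "class") return(max.col(lg, ties.method = "first"))
  exp(lg - row_logsumexp(lg))
}

#' @export
simulate.gmm1d <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    g <- sample.int(object$G, nsim, replace = TRUE, prob = object$weights)
    stats::rnorm(nsim, object$means[g], sqrt(object$variances[g]))
  })
}

#' @export
plot.gmm1d <- function(x, ...) {
  xs <- seq(min(x$x) - 2 * sqrt(max(x$variances)),
            max(x$x) + 2 * sqrt(max(x$variances)), length.out = 400)
  dens <- sapply(seq_len(x$G), function(g)
    x$weights[g] * stats::dnorm(xs, x$means[g], sqrt(x$variances[g])))
  graphics::hist(x$x, freq = FALSE, main = "Mixture fit", xlab = "value",
                 border = "grey", ...)
  graphics::matlines(xs, dens, lty = 2)
  graphics::lines(xs, rowSums(dens), lwd = 2)
  invisible(x)
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat("BIC model selection over", nrow(x$table), "fits\n")
  cat("best:", x$best$family, "G =", x$best$G,
      sprintf("(BIC %.3f)\n", x$best$BIC))
  invisible(x)
}

#' @export
plot.gmm_selection <- function(x, ...) {
  tab <- x$table
  fams <- unique(tab$family)
  graphics::plot(range(tab$G), range(tab$BIC, na.rm = TRUE), type = "n",
                 xlab = "number of components G", ylab = "BIC", ...)
  for (i in seq_along(fams)) {
    sub <- tab[tab$family == fams[i], ]
    graphics::lines(sub$G, sub$BIC, type = "b", pch = i, lty = i)
  }
  graphics::legend("bottomright", legend = fams, pch = seq_along(fams),
                   lty = seq_along(fams), bty = "n")
  invisible(x)
}
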