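#' Fit the 6mA IPD-ratio threshold by deconvolution of a bimodal distribution
#'
#' Fits a two-component Gaussian mixture to `ln(IPD ratio)` over adenine
#' positions by expectation-maximisation (k-means initialisation from fixed
#' quantile centres, so the fit is deterministic given the data and seed).
#' The calling threshold is the equal-posterior point between the two
#' component means — the IPD ratio at which a site is equally likely to come
#' from the unmethylated and methylated components. When the fit is not
#' credibly bimodal (component means closer than one pooled scale, or minor
#' weight below `min_weight`), the fixed working cutoff `fallback_cutoff` is
#' returned with `bimodal = FALSE`. A two-component fit must also beat a
#' single-Gaussian fit decisively by BIC, so unimodal inputs that EM happens
#' to split in half still fall back.
#'
#' @param adenine_ipds numeric vector of adenine IPD ratios (>= 100 finite
#'   non-negative values).
#' @param seed integer seed used when subsampling large inputs.
#' @param fallback_cutoff cutoff used when no bimodal structure is found
#'   (default 2.8, the working bound below which adenines are treated as
#'   unmethylated).
#' @param min_weight minimum mixture weight of the minor component for the
#'   fit to count as bimodal (default 0.01).
#' @param min_separation minimum separation of component means in pooled
#'   scale units (default 1).
#' @param max_points subsample size for the EM fit (default 5e5); the fit is
#'   performed on a seeded subsample when more values are supplied.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#'
#' @return Object of class `ipd_threshold`: list with `cutoff` (IPD-ratio
#'   scale), `components` (data.table: weight, meanlog, sdlog, ordered by
#'   mean), `loglik`, `bimodal`, `n_used`.
#' @export
fit_ipd_threshold <- function(adenine_ipds, seed = 1L, fallback_cutoff = 2.8,
                              min_weight = 0.01, min_separation = 1,
                              max_points = 5e5, max_iter = 500L, tol = 1e-8) {
  x <- adenine_ipds
  if (length(x) < 100L) stopf("need >= 100 adenine IPD values, got %d", length(x))
  if (any(!is.finite(x))) stopf("adenine IPD ratios must all be finite")
  if (any(x < 0)) stopf("adenine IPD ratios must be >= 0")

  with_seed(seed, {
    if (length(x) > max_points) x <- x[sample.int(length(x), max_points)]
    lx <- log(pmax(x, 1e-8))

    fit <- em_two_gaussians(lx, max_iter = max_iter, tol = tol)

    bimodal <- FALSE
    cutoff <- fallback_cutoff
    if (!is.null(fit)) {
      mu <- fit$mu; sg <- fit$sigma; w <- fit$w
      pooled <- sqrt(mean(sg^2))
      # the mixture must beat a single Gaussian decisively (BIC), otherwise
      # the EM has merely split a unimodal distribution in two
      n <- length(lx)
      ll1 <- sum(dnorm(lx, mean(lx), sd(lx), log = TRUE))
      bic1 <- -2 * ll1 + 2 * log(n)
      bic2 <- -2 * fit$loglik + 5 * log(n)
      if (bic2 < bic1 - 10 &&
          (mu[2] - mu[1]) >= min_separation * pooled && min(w) >= min_weight) {
        root <- equal_posterior_point(w, mu, sg)
        if (!is.na(root)) {
          bimodal <- TRUE
          cutoff <- exp(root)
        }
      }
    }
    structure(list(
      cutoff = cutoff,
      components = if (is.null(fit)) NULL else data.table::data.table(
        weight = fit$w, meanlog = fit$mu, sdlog = fit$sigma),
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      bimodal = bimodal, n_used = length(lx)
    ), class = "ipd_threshold")
  })
}

# Plain EM for a 2-component univariate Gaussian mixture; components are
# returned ordered by mean. NULL when the fit degenerates.
em_two_gaussians <- function(lx, max_iter = 500L, tol = 1e-8) {
  q <- quantile(lx, c(0.02, 0.98), names = FALSE)
  if (diff(q) < 1e-8) return(NULL)
  km <- suppressWarnings(kmeans(lx, centers = matrix(q, ncol = 1)))
  cl <- km$cluster
  mu <- c(mean(lx[cl == 1L]), mean(lx[cl == 2L]))
  sigma <- c(sd(lx[cl == 1L]), sd(lx[cl == 2L]))
  sigma[!is.finite(sigma) | sigma < 1e-4] <- sd(lx) / 2
  w <- c(mean(cl == 1L), mean(cl == 2L))
  w <- pmax(w, 1e-6); w <- w / sum(w)

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(lx, mu[1], sigma[1])
    d2 <- w[2] * dnorm(lx, mu[2], sigma[2])
    tot <- d1 + d2
    bad <- tot <= 0 | !is.finite(tot)
    if (any(bad)) { d1[bad] <- 0.5; d2[bad] <- 0.5; tot[bad] <- 1 }
    r <- d1 / tot
    n1 <- sum(r); n2 <- length(lx) - n1
    if (n1 < 2 || n2 < 2) return(NULL)
    mu <- c(sum(r * lx) / n1, sum((1 - r) * lx) / n2)
    sigma <- sqrt(c(sum(r * (lx - mu[1])^2) / n1,
                    sum((1 - r) * (lx - mu[2])^2) / n2))
    if (any(!is.finite(sigma)) || any(sigma < 1e-6)) return(NULL)
    w <- c(n1, n2) / length(lx)
    ll <- sum(log(tot[!bad]))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  o <- order(mu)
  list(w = w[o], mu = mu[o], sigma = sigma[o], loglik = ll, iterations = it)
}

# Solve w1 N(x|mu1,s1) = w2 N(x|mu2,s2) for the crossing between the means
# (posterior responsibilities equal). Closed-form quadratic on the log scale.
equal_posterior_point <- function(w, mu, sigma) {
  a <- 1 / (2 * sigma[2]^2) - 1 / (2 * sigma[1]^2)
  b <- mu[1] / sigma[1]^2 - mu[2] / sigma[2]^2
  cc <- mu[2]^2 / (2 * sigma[2]^2) - mu[1]^2 / (2 * sigma[1]^2) +
    log(w[1] / sigma[1]) - log(w[2] / sigma[2])
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return(NA_real_)
    root <- -cc / b
    return(if (root > mu[1] && root < mu[2]) root else NA_real_)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (!length(inside)) return(NA_real_)
  inside[1]
}

#' @export
print.ipd_threshold <- function(x, ...) {
  cat(sprintf("ipd_threshold: cutoff %.3f (%s)\n", x$cutoff,
              if (x$bimodal) "bimodal deconvolution" else "fallback"))
  if (!is.null(x$components)) print(x$components)
  invisible(x)
}
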