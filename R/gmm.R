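#' Bivariate Gaussian mixture density
#'
#' Evaluates `p(x) = sum_i f_i N(x; mu_i, Sigma_i)` — the mixture model
#' fitted to the (g, s) phasor cloud — at one or more points.
#'
#' @param x Numeric length-2 vector or a two-column matrix of (g, s) points.
#' @param params A list with elements `k`, `fractions` (length k, summing to
#'   1), `means` (k x 2 matrix), `covariances` (list of k symmetric
#'   positive-definite 2 x 2 matrices), as stored in a [fit_gmm()] result.
#' @return Numeric vector of densities.
#' @export
gmm_density <- function(x, params) {
  validate_gmm_params(params)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  dens <- rep(0, nrow(x))
  for (i in seq_len(params$k)) {
    dens <- dens + params$fractions[i] *
      dmvnorm2(x, params$means[i, ], params$covariances[[i]])
  }
  dens
}

validate_gmm_params <- function(params) {
  stopifnot(is.list(params),
            length(params$fractions) == params$k,
            nrow(params$means) == params$k,
            length(params$covariances) == params$k)
  if (abs(sum(params$fractions) - 1) > 1e-12 || any(params$fractions < 0)) {
    stop("Mixture fractions must be non-negative and sum to 1.",
         call. = FALSE)
  }
  for (S in params$covariances) {
    if (any(abs(S - t(S)) > 1e-12) || any(eigen(S, symmetric = TRUE,
                                                only.values = TRUE)$values <= 0)) {
      stop("Each covariance must be symmetric positive-definite.",
           call. = FALSE)
    }
  }
  invisible(params)
}

# Bivariate normal density via the explicit 2x2 closed form.
dmvnorm2 <- function(x, mu, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]),
                2, 2) / det_s
  dx <- sweep(x, 2, mu)
  q <- inv[1, 1] * dx[, 1]^2 + (inv[1, 2] + inv[2, 1]) * dx[, 1] * dx[, 2] +
    inv[2, 2] * dx[, 2]^2
  exp(-0.5 * q) / (2 * pi * sqrt(det_s))
}

# log of the same, numerically safer inside EM
log_dmvnorm2 <- function(x, mu, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]),
                2, 2) / det_s
  dx <- sweep(x, 2, mu)
  q <- inv[1, 1] * dx[, 1]^2 + (inv[1, 2] + inv[2, 1]) * dx[, 1] * dx[, 2] +
    inv[2, 2] * dx[, 2]^2
  -0.5 * q - log(2 * pi) - 0.5 * log(det_s)
}

#' Fit a Gaussian mixture to a phasor cloud by expectation-maximization
#'
#' Models the (g, s) cloud as a K-component bivariate Gaussian mixture and
#' fits it with the standard EM iteration: the E-step computes each phasor's
#' responsibility (posterior probability) under the current parameters; the
#' M-step re-estimates the fractions (mean responsibility), means
#' (responsibility-weighted averages) and full covariances
#' (responsibility-weighted second moments, plus a tiny diagonal ridge that
#' prevents singular collapse on near-noiseless clusters). Iteration stops
#' when the relative log-likelihood change drops below `tol` or after
#' `max_iter` iterations. Each of `n_starts` restarts is seeded with a
#' farthest-point initialization from a different seeded draw and the fit
#' with the best final log-likelihood is kept, so results are deterministic
#' given `seed`.
#'
#' @param cloud A `phasor_cloud`, or any data frame with numeric columns
#'   `g` and `s`.
#' @param k Number of mixture components (default 2: one per population at a
#'   two-mixture interface).
#' @param seed Integer seed controlling initialization.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param n_starts Number of seeded restarts (default 5).
#' @param ridge Diagonal regularization added to each covariance update
#'   (default 1e-10).
#' @return An object of class `phasor_gmm`: a list with `params` (`k`,
#'   `fractions`, `means`, `covariances`), `responsibilities` (n x k),
#'   `log_lik_trace`, `n_iter`, `converged`, `n`.
#' @seealso [hard_assign()], [order_clusters()], [cluster_summary()]
#' @export
fit_gmm <- function(cloud, k = 2L, seed = 0L, tol = 1e-8, max_iter = 500L,
                    n_starts = 5L, ridge = 1e-10) {
  x <- as.matrix(cbind(cloud$g, cloud$s))
  n <- nrow(x)
  if (k < 1) stop("`k` must be >= 1.", call. = FALSE)
  if (n < 3 * k) {
    stop(sprintf("Insufficient data: %d phasors for k = %d (need >= %d).",
                 n, k, 3 * k), call. = FALSE)
  }
  if (all(apply(x, 2, function(v) diff(range(v))) == 0)) {
    stop("Degenerate data: all phasors identical.", call. = FALSE)
  }
  best <- NULL
  for (start in seq_len(n_starts)) {
    fit <- em_single_start(x, k, seed = as.integer(seed) + start - 1L,
                           tol = tol, max_iter = max_iter, ridge = ridge)
    if (is.null(best) ||
        fit$log_lik_trace[fit$n_iter] > best$log_lik_trace[best$n_iter]) {
      best <- fit
    }
  }
  best$n <- n
  class(best) <- "phasor_gmm"
  best
}

# One EM run from a farthest-point initialization.
em_single_start <- function(x, k, seed, tol, max_iter, ridge) {
  n <- nrow(x)
  centers <- farthest_point_centers(x, k, seed)
  # hard nearest-centre responsibilities as the initial E-step
  d2 <- vapply(seq_len(k), function(i) {
    (x[, 1] - centers[i, 1])^2 + (x[, 2] - centers[i, 2])^2
  }, numeric(n))
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), max.col(-d2, ties.method = "first"))] <- 1
  params <- m_step(x, resp, ridge)

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    e <- e_step(x, params)
    trace <- c(trace, e$log_lik)
    params <- m_step(x, e$resp, ridge)
    if (iter > 1) {
      prev <- trace[iter - 1]
      if (abs(trace[iter] - prev) <= tol * max(1, abs(prev))) {
        converged <- TRUE
        break
      }
    }
  }
  e <- e_step(x, params)
  list(params = params, responsibilities = e$resp,
       log_lik_trace = c(trace, e$log_lik),
       n_iter = length(trace) + 1L, converged = converged)
}

# Deterministic farthest-point seeding: first centre from a seeded uniform
# draw, each further centre the point farthest from all chosen centres.
farthest_point_centers <- function(x, k, seed) {
  n <- nrow(x)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  idx <- sample.int(n, 1)
  for (i in seq_len(k - 1)) {
    d2 <- rep(Inf, n)
    for (j in idx) {
      d2 <- pmin(d2, (x[, 1] - x[j, 1])^2 + (x[, 2] - x[j, 2])^2)
    }
    idx <- c(idx, which.max(d2))
  }
  x[idx, , drop = FALSE]
}

e_step <- function(x, params) {
  n <- nrow(x)
  k <- params$k
  logp <- matrix(0, n, k)
  for (i in seq_len(k)) {
    logp[, i] <- log(params$fractions[i]) +
      log_dmvnorm2(x, params$means[i, ], params$covariances[[i]])
  }
  m <- apply(logp, 1, max)
  lse <- m + log(rowSums(exp(logp - m)))
  list(resp = exp(logp - lse), log_lik = sum(lse))
}

m_step <- function(x, resp, ridge) {
  k <- ncol(resp)
  nk <- colSums(resp)
  means <- matrix(0, k, 2)
  covs <- vector("list", k)
  for (i in seq_len(k)) {
    w <- resp[, i] / nk[i]
    mu <- c(sum(w * x[, 1]), sum(w * x[, 2]))
    dx <- sweep(x, 2, mu)
    S <- crossprod(dx * sqrt(w), dx * sqrt(w))
    covs[[i]] <- S + diag(ridge, 2)
    means[i, ] <- mu
  }
  list(k = k, fractions = nk / nrow(x), means = means, covariances = covs)
}

#' @export
print.phasor_gmm <- function(x, ...) {
  cat(sprintf("<phasor_gmm> K = %d on %d phasors; log-lik %.4f after %d iterations%s\n",
              x$params$k, x$n, x$log_lik_trace[length(x$log_lik_trace)],
              x$n_iter, if (x$converged) " (converged)" else ""))
  for (i in seq_len(x$params$k)) {
    cat(sprintf("  cluster %d: f = %.3f, mean (g, s) = (%.4f, %.4f)\n",
                i, x$params$fractions[i], x$params$means[i, 1],
                x$params$means[i, 2]))
  }
  invisible(x)
}

#' Hard-edge cluster assignment
#'
#' Assigns every phasor to the cluster with the highest posterior
#' responsibility ("cutting hard edges" through the soft mixture
#' memberships). Exact ties go to the lower cluster index.
#'
#' @param fit A [fit_gmm()] result.
#' @return Integer vector of labels in `1..K`, one per phasor.
#' @export
hard_assign <- function(fit) {
  stopifnot(inherits(fit, "phasor_gmm"))
  max.col(fit$responsibilities, ties.method = "first")
}

#' Canonical cluster ordering
#'
#' Renumbers mixture components in descending order of the phase lifetime of
#' their mean phasor, so cluster 1 is always the longest-lived population
#' regardless of the arbitrary ordering EM converged to. Ties are broken by
#' descending mixture fraction, then by mean g. Deterministic for a given
#' set of fitted parameters.
#'
#' @param fit A [fit_gmm()] result.
#' @param cloud The `phasor_cloud` the fit was computed on (used for the
#'   repetition rate; defaults to 20 MHz when absent).
#' @return The same `phasor_gmm` with components, responsibilities and trace
#'   permuted into canonical order.
#' @export
order_clusters <- function(fit, cloud = NULL) {
  stopifnot(inherits(fit, "phasor_gmm"))
  f_rep <- if (!is.null(cloud)) attr(cloud, "config")$rep_rate_hz else 2e7
  mu <- fit$params$means
  tau_mu <- ifelse(mu[, 1] > 0,
                   mu[, 2] / (2 * pi * f_rep * mu[, 1]) * 1e9, -Inf)
  ord <- order(-tau_mu, -fit$params$fractions, mu[, 1])
  fit$params$fractions <- fit$params$fractions[ord]
  fit$params$means <- fit$params$means[ord, , drop = FALSE]
  fit$params$covariances <- fit$params$covariances[ord]
  fit$responsibilities <- fit$responsibilities[, ord, drop = FALSE]
  fit
}

#' Per-cluster phase-lifetime summaries
#'
#' Summarizes each cluster of a segmented phasor cloud: member count,
#' fraction of the cloud, mean and standard deviation of the members' phase
#' lifetimes (population SD, n in the denominator), and the mean phasor
#' coordinates. Pixels with undefined phase lifetime (g <= 0) stay in the
#' cluster but are excluded from the lifetime statistics; a cluster with no
#' finite lifetimes reports `NA` statistics.
#'
#' @param cloud A `phasor_cloud`.
#' @param labels Integer labels aligned with `cloud` rows (from
#'   [hard_assign()]).
#' @return A tibble with columns `cluster`, `n`, `fraction`, `mean_tau_ns`,
#'   `sd_tau_ns`, `mean_g`, `mean_s`.
#' @export
cluster_summary <- function(cloud, labels) {
  if (length(labels) != nrow(cloud)) {
    stop("`labels` must align with the cloud rows.", call. = FALSE)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  dplyr::tibble(cluster = labels, g = cloud$g, s = cloud$s,
                tau_ns = cloud$tau_ns) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      fraction = dplyr::n() / nrow(cloud),
      mean_tau_ns = if (any(is.finite(.data$tau_ns)))
        mean(.data$tau_ns[is.finite(.data$tau_ns)]) else NA_real_,
      sd_tau_ns = if (any(is.finite(.data$tau_ns)))
        pop_sd(.data$tau_ns[is.finite(.data$tau_ns)]) else NA_real_,
      mean_g = mean(.data$g),
      mean_s = mean(.data$s),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
}

#' @export
tidy.phasor_gmm <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    cluster = seq_len(p$k),
    fraction = p$fractions,
    mean_g = p$means[, 1],
    mean_s = p$means[, 2],
    var_g = vapply(p$covariances, function(S) S[1, 1], numeric(1)),
    var_s = vapply(p$covariances, function(S) S[2, 2], numeric(1)),
    cov_gs = vapply(p$covariances, function(S) S[1, 2], numeric(1))
  )
}

#' @export
glance.phasor_gmm <- function(x, ...) {
  tibble::tibble(
    k = x$params$k,
    n = x$n,
    log_lik = x$log_lik_trace[length(x$log_lik_trace)],
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Serialize a mixture fit as a flat key-value report
#'
#' @param fit A [fit_gmm()] result.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "phasor_gmm"))
  p <- fit$params
  lines <- c(
    sprintf("k = %d", p$k),
    sprintf("n = %d", fit$n),
    sprintf("log_likelihood = %.10g",
            fit$log_lik_trace[length(fit$log_lik_trace)]),
    sprintf("n_iter = %d", fit$n_iter),
    sprintf("converged = %s", tolower(as.character(fit$converged)))
  )
  for (i in seq_len(p$k)) {
    S <- p$covariances[[i]]
    lines <- c(lines,
               sprintf("cluster%d.fraction = %.10g", i, p$fractions[i]),
               sprintf("cluster%d.mean_g = %.10g", i, p$means[i, 1]),
               sprintf("cluster%d.mean_s = %.10g", i, p$means[i, 2]),
               sprintf("cluster%d.cov = %.10g %.10g %.10g", i,
                       S[1, 1], S[1, 2], S[2, 2]))
  }
  writeLines(lines, path)
  invisible(path)
}
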