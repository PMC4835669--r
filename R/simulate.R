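#' Specification for the rating simulator
#'
#' Describes the synthetic stand-in for the study's unreleased raw data: a
#' participants x emotions x aspects tensor of truncated-normal draws on
#' \[0, 100\] whose per-cell mean and SD target the supplied values (defaults:
#' the published summary table, n = 187). For each cell the parent normal's
#' parameters are solved so that the *truncated* distribution has the target
#' moments; cells whose target SD exceeds what any truncated normal on
#' \[0, 100\] can attain (about 28.9 mm) get the closest attainable spread
#' with the mean preserved and are listed in `sd_capped`. Optionally a latent
#' low-dimensional configuration can be planted: inter-emotion correlations
#' then follow 1 - distance / max(distance), realized through a Gaussian
#' copula, so the planted geometry survives the d = 1 - r pipeline.
#'
#' @param summary an `aspect_summary` of target means/SDs (default
#'   [study_aspect_summary()]).
#' @param n_participants number of simulated raters (default 187).
#' @param seed mandatory seed for all draws.
#' @param planted optional latent coordinate matrix (emotions x p, rownames
#'   matching the summary's emotions).
#' @return a `generator_spec` list, including the solved per-cell parent
#'   parameters (`parent_mu`, `parent_sigma`) and the `sd_capped` flags.
#' @export
generator_spec <- function(summary = study_aspect_summary(),
                           n_participants = 187L, seed, planted = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(inherits(summary, "aspect_summary"))
  if (any(summary$mean < 0 | summary$mean > 100)) stop("target means must lie in [0, 100]")
  if (any(summary$sd < 0)) stop("target SDs must be nonnegative")
  emotions <- attr(summary, "emotions"); aspects <- attr(summary, "aspects")
  if (!is.null(planted)) {
    planted <- as.matrix(planted)
    if (is.null(rownames(planted)) || !setequal(rownames(planted), emotions))
      stop("planted configuration must have the summary's emotions as rownames")
    planted <- planted[emotions, , drop = FALSE]
  }
  k <- nrow(summary)
  mu0 <- sig0 <- numeric(k); capped <- logical(k)
  for (i in seq_len(k)) {
    # a spread at an exact scale boundary needs all mass at the endpoint:
    # rejection sampling cannot approach it at any acceptance rate
    if (summary$sd[i] > 0 &&
        (summary$mean[i] <= 0 || summary$mean[i] >= 100))
      stop(sprintf("infeasible cell (%s, %s): mean %.1f at the scale boundary with SD %.1f needs a rejection rate above 99%%",
                   summary$emotion[i], summary$aspect[i],
                   summary$mean[i], summary$sd[i]))
    sol <- solve_truncnorm(summary$mean[i], summary$sd[i])
    mu0[i] <- sol$mu; sig0[i] <- sol$sigma; capped[i] <- sol$capped
    if (sol$accept_prob < 0.01)
      stop(sprintf("infeasible cell (%s, %s): mean %.1f / SD %.1f needs a rejection rate above 99%%",
                   summary$emotion[i], summary$aspect[i],
                   summary$mean[i], summary$sd[i]))
  }
  structure(list(summary = summary, emotions = emotions, aspects = aspects,
                 n_participants = as.integer(n_participants), seed = seed,
                 planted = planted, parent_mu = mu0, parent_sigma = sig0,
                 sd_capped = capped),
            class = "generator_spec")
}

# moments of a normal(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a = 0, b = 100) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  if (z < 1e-300) return(list(mean = NA_real_, sd = NA_real_, accept = 0))
  dphi <- stats::dnorm(al) - stats::dnorm(be)
  m <- mu + sigma * dphi / z
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z -
                    (dphi / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)), accept = z)
}

# Solve parent (mu, sigma) so the [0,100]-truncated moments hit the target.
# Targets with unattainable SD fall back to mean-matching at the largest
# attainable spread; the heavy weight on the mean keeps it exact to well
# under measurement precision. Solutions needing a rejection-sampling
# acceptance probability below 2% are penalized so the solver stays in the
# samplable region (a target that forces it below 1% anyway is infeasible).
solve_truncnorm <- function(target_mean, target_sd, a = 0, b = 100,
                            sigma_cap = 150) {
  if (target_sd == 0)
    return(list(mu = target_mean, sigma = 0, capped = FALSE, accept_prob = 1))
  obj <- function(par) {
    mu <- par[1L]; sigma <- min(exp(par[2L]), sigma_cap)
    mom <- truncnorm_moments(mu, sigma, a, b)
    if (!is.finite(mom$mean)) return(1e10)
    pen <- if (mom$accept < 0.02) 1e5 * (0.02 - mom$accept) / 0.02 else 0
    100 * (mom$mean - target_mean)^2 + (mom$sd - target_sd)^2 + pen
  }
  start <- c(target_mean, log(min(max(target_sd, 1e-3), sigma_cap)))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- fit$par[1L]; sigma <- min(exp(fit$par[2L]), sigma_cap)
  mom <- truncnorm_moments(mu, sigma, a, b)
  list(mu = mu, sigma = sigma,
       capped = (target_sd - mom$sd) > 0.5,
       accept_prob = mom$accept)
}

# truncated-normal draws by rejection (never clipping)
rtrunc_reject <- function(n, mu, sigma, a = 0, b = 100, max_tries = 10000L) {
  if (sigma == 0) return(rep(mu, n))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("rejection sampling failed to accept enough draws")
    cand <- stats::rnorm(max(n - length(out), 1L) * 2L, mu, sigma)
    out <- c(out, cand[cand >= a & cand <= b])
  }
  out[seq_len(n)]
}

# truncated-normal quantile function (for the copula path)
qtrunc <- function(u, mu, sigma, a = 0, b = 100) {
  pa <- stats::pnorm(a, mu, sigma); pb <- stats::pnorm(b, mu, sigma)
  stats::qnorm(pa + u * (pb - pa), mu, sigma)
}

#' Simulate a rating dataset
#'
#' Draws the tensor described by a [generator_spec()]. Without planted
#' structure every cell is an independent truncated-normal sample (rejection
#' sampling, so there is no point mass at the scale ends). With planted
#' structure, per-participant latent factors with the requested inter-emotion
#' correlation pattern are pushed through a Gaussian copula onto the same
#' truncated-normal margins, independently per aspect. Fully reproducible
#' from the spec's seed.
#'
#' @param spec a `generator_spec`.
#' @return a `rating_dataset` (n_participants x emotions x aspects).
#' @export
simulate_ratings <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  ne <- length(spec$emotions); na <- length(spec$aspects)
  arr <- array(NA_real_, dim = c(n, ne, na),
               dimnames = list(participant = sprintf("p%03d", seq_len(n)),
                               emotion = spec$emotions, aspect = spec$aspects))
  idx <- function(e, a) which(spec$summary$emotion == e & spec$summary$aspect == a)
  if (is.null(spec$planted)) {
    for (a in spec$aspects) for (e in spec$emotions) {
      i <- idx(e, a)
      arr[, e, a] <- rtrunc_reject(n, spec$parent_mu[i], spec$parent_sigma[i])
    }
  } else {
    r_target <- planted_correlations(spec$planted)
    ev <- eigen(r_target, symmetric = TRUE)
    l <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), ne)  # nearest-PSD factor
    for (a in spec$aspects) {
      z <- matrix(stats::rnorm(n * ne), n, ne) %*% t(l)
      z <- z / sqrt(pmax(rowSums(l^2), 1e-12))[col(z)]  # unit marginal variance
      u <- stats::pnorm(z)
      for (j in seq_len(ne)) {
        i <- idx(spec$emotions[j], a)
        arr[, j, a] <- if (spec$parent_sigma[i] == 0) spec$parent_mu[i] else
          qtrunc(u[, j], spec$parent_mu[i], spec$parent_sigma[i])
      }
    }
  }
  rating_dataset(arr)
}

# loading rule: target correlation = 1 - d / max(d), clamped to [-1, 1]
planted_correlations <- function(config) {
  d <- as.matrix(stats::dist(config))
  r <- 1 - d / max(d)
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

#' Simulate noisy proximity sources from a known configuration
#'
#' Recovery fixture for the MDS engine: each source is the configuration's
#' Euclidean distance matrix with independent multiplicative noise,
#' entry = d * (1 + eps), eps ~ N(0, noise_sd), truncated at zero,
#' symmetrized, zero diagonal.
#'
#' @param config planted coordinate matrix with rownames.
#' @param n_sources number of sources (default 4).
#' @param noise_sd multiplicative noise SD (>= 0; default 0.05).
#' @param seed mandatory seed.
#' @return list of `proximity_matrix` objects sharing the planted labels.
#' @export
simulate_sources <- function(config, n_sources = 4L, noise_sd = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  config <- as.matrix(config)
  d0 <- as.matrix(stats::dist(config))
  set.seed(seed)
  lapply(seq_len(n_sources), function(k) {
    d <- d0
    ut <- upper.tri(d)
    eps <- stats::rnorm(sum(ut), 0, noise_sd)
    d[ut] <- pmax(d0[ut] * (1 + eps), 0)
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    diag(d) <- 0
    proximity_matrix(d, kind = "configuration_distance")
  })
}
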