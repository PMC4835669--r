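#' Normalized raw stress of a configuration against one or more sources
#'
#' The loss minimized by the engine:
#' sigma(X) = sum_k sum_(i<j) w_ijk (delta_ijk - d_ij(X))^2 /
#'            sum_k sum_(i<j) w_ijk delta_ijk^2,
#' where delta_ijk are the source dissimilarities and d_ij(X) the Euclidean
#' distances between configuration rows. With default unit weights sigma is 0
#' iff every distance matches every dissimilarity, and equals 1 for the
#' degenerate all-coincident configuration (d = 0). Missing source entries
#' get weight 0.
#'
#' @param sources a `proximity_matrix`, plain symmetric matrix, `dist`, or a
#'   list of these sharing the same labels.
#' @param config numeric matrix of coordinates (objects x ndim), rownames
#'   matching the source labels (unlabelled inputs are matched by position).
#' @param weights optional list (or single matrix) of nonnegative weights,
#'   same shapes as `sources`.
#' @return the stress value in \[0, 1\] (for configurations no worse than the
#'   zero configuration).
#' @export
mds_stress <- function(sources, config, weights = NULL) {
  sources <- as_source_list(sources, rownames(config))
  weights <- as_weight_list(weights, sources)
  sources <- zero_unweighted(sources, weights)
  config <- as.matrix(config)
  d <- as.matrix(stats::dist(config))
  ut <- upper.tri(d)
  num <- 0; den <- 0
  for (k in seq_along(sources)) {
    delta <- sources[[k]][ut]; w <- weights[[k]][ut]; dd <- d[ut]
    num <- num + sum(w * (delta - dd)^2)
    den <- den + sum(w * delta^2)
  }
  if (den <= 0) stop("degenerate input: all source dissimilarities are zero")
  num / den
}

as_source_list <- function(sources, labels = NULL) {
  if (inherits(sources, "dist")) sources <- as.matrix(sources)
  if (is.matrix(sources)) sources <- list(sources)
  if (!is.list(sources) || length(sources) == 0L)
    stop("`sources` must be a nonempty list of square dissimilarity matrices")
  sources <- lapply(sources, function(s) {
    s <- as.matrix(if (inherits(s, "dist")) as.matrix(s) else s)
    if (nrow(s) != ncol(s)) stop("each source must be square")
    s
  })
  ref <- rownames(sources[[1L]])
  for (k in seq_along(sources)) {
    rk <- rownames(sources[[k]])
    if (!is.null(ref) && !is.null(rk) && !identical(ref, rk)) {
      if (!setequal(ref, rk))
        stop("sources have mismatched labels")
      sources[[k]] <- sources[[k]][ref, ref]
    }
    if (nrow(sources[[k]]) != nrow(sources[[1L]]))
      stop("sources have mismatched sizes")
  }
  if (!is.null(labels) && !is.null(ref)) {
    if (!setequal(labels, ref)) stop("configuration labels do not match sources")
    sources <- lapply(sources, function(s) s[labels, labels])
  }
  lapply(sources, unclass)
}

as_weight_list <- function(weights, sources) {
  if (is.null(weights))
    return(lapply(sources, function(s) {
      w <- matrix(1, nrow(s), ncol(s)); w[is.na(s)] <- 0; w
    }))
  if (is.matrix(weights)) weights <- rep(list(weights), length(sources))
  stopifnot(length(weights) == length(sources))
  lapply(seq_along(weights), function(k) {
    w <- as.matrix(weights[[k]])
    if (any(w < 0)) stop("weights must be nonnegative")
    w[is.na(sources[[k]])] <- 0
    w
  })
}

# zero-weight entries (including NA dissimilarities) contribute nothing;
# blank them so arithmetic stays finite
zero_unweighted <- function(sources, weights) {
  lapply(seq_along(sources), function(k) {
    s <- sources[[k]]
    s[weights[[k]] == 0] <- 0
    s
  })
}

#' Initial configurations for the MDS engine
#'
#' * `classical` — Torgerson scaling (double-centering eigendecomposition,
#'   via [stats::cmdscale()]) of the element-wise mean of the sources; exact
#'   when the mean source is Euclidean of rank <= ndim.
#' * `simplex` — vertices of a regular simplex (all pairwise distances
#'   equal), projected to `ndim` dimensions and centered; mirrors the
#'   "simplex start" of the reference analysis.
#' * `random` — seeded standard-normal coordinates, centered.
#'
#' @param n_objects number of points (>= ndim + 1 for classical).
#' @param ndim target dimensionality.
#' @param method `"classical"`, `"simplex"` or `"random"`.
#' @param sources required for `classical`: dissimilarity source(s).
#' @param seed required for `random`.
#' @return a centered n x ndim coordinate matrix.
#' @export
mds_init <- function(n_objects, ndim, method = c("classical", "simplex", "random"),
                     sources = NULL, seed = NULL) {
  method <- match.arg(method)
  if (ndim < 1L) stop("ndim must be >= 1")
  x <- switch(method,
    classical = {
      if (is.null(sources)) stop("classical initialization needs `sources`")
      if (ndim >= n_objects)
        stop("classical initialization needs ndim < n_objects")
      sources <- as_source_list(sources)
      mean_delta <- Reduce(`+`, sources) / length(sources)
      xx <- suppressWarnings(stats::cmdscale(mean_delta, k = ndim))
      if (ncol(xx) < ndim)  # nonpositive eigenvalues: pad with zero columns
        xx <- cbind(xx, matrix(0, n_objects, ndim - ncol(xx)))
      xx
    },
    simplex = {
      h <- diag(n_objects) - 1 / n_objects  # centered regular simplex, edge sqrt(2)
      sv <- svd(h, nu = min(ndim, n_objects - 1L), nv = 0)
      xx <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
      if (ncol(xx) < ndim) xx <- cbind(xx, matrix(0, n_objects, ndim - ncol(xx)))
      xx
    },
    random = {
      if (is.null(seed)) stop("random initialization needs a seed")
      set.seed(seed)
      matrix(stats::rnorm(n_objects * ndim), n_objects, ndim)
    })
  scale(x, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Fit a common configuration to multiple proximity sources
#'
#' Multi-source metric MDS in the identity (unweighted common-space) model:
#' one configuration X of `ndim` dimensions is fitted to all sources at once
#' by minimizing normalized raw stress (see [mds_stress()]) with SMACOF
#' majorization. Each iteration applies the Guttman transform of the pooled
#' objective, which never increases stress; iteration stops when the stress
#' improvement falls below `tol` or at `max_iter`. The returned configuration
#' is mean-centered. Solutions are unique only up to rotation, reflection and
#' translation; compare fits via [procrustes_align()] or distance matrices.
#'
#' @param sources list of `proximity_matrix` objects (or matrices / `dist`)
#'   sharing labels, e.g. from [mds_sources()]; a single matrix is accepted.
#' @param ndim dimensionality of the solution (default 3).
#' @param init `"classical"` (default), `"simplex"`, `"random"`, or an
#'   explicit coordinate matrix.
#' @param tol minimum stress improvement to continue iterating (default 1e-4,
#'   the conventional PROXSCAL criterion).
#' @param max_iter iteration cap (default 1000).
#' @param restarts number of additional seeded random starts; the
#'   best-stress solution is kept (default 0).
#' @param seed seed for random initialization / restarts.
#' @param weights optional nonnegative weights per source entry.
#' @return an object of class `mds_fit`: list with elements `configuration`
#'   (centered matrix with emotion rownames), `stress` (normalized raw
#'   stress), `fit` (= 1 - stress), `stress1` (= sqrt(stress), Stress-1, for
#'   reference), `trajectory` (data frame iteration/stress/improvement,
#'   iteration 0 = initial stress), `converged`, `n_iterations`, `ndim`,
#'   `settings`, `sources`, `call`.
#' @examples
#' set.seed(1)
#' x0 <- scale(matrix(rnorm(16 * 3), 16, 3), scale = FALSE)
#' rownames(x0) <- emotion_lexicon
#' fit <- mds_fit(simulate_sources(x0, noise_sd = 0, seed = 1), ndim = 3)
#' fit$stress < 1e-6
#' @export
mds_fit <- function(sources, ndim = 3L, init = "classical", tol = 1e-4,
                    max_iter = 1000L, restarts = 0L, seed = NULL,
                    weights = NULL) {
  cl <- match.call()
  sources <- as_source_list(sources)
  n <- nrow(sources[[1L]])
  if (n < 3L) stop("need at least 3 objects")
  if (ndim < 1L) stop("ndim must be >= 1")
  labels <- rownames(sources[[1L]]) %||% paste0("e", seq_len(n))
  weights <- as_weight_list(weights, sources)
  sources <- zero_unweighted(sources, weights)
  unit_w <- all(vapply(weights, function(w) all(w[upper.tri(w)] == 1), logical(1L)))

  starts <- list()
  if (is.matrix(init) || is.data.frame(init)) {
    x0 <- as.matrix(init)
    if (nrow(x0) != n || ncol(x0) != ndim)
      stop("explicit init must be a ", n, " x ", ndim, " matrix")
    starts[[1L]] <- scale(x0, center = TRUE, scale = FALSE)
    init_name <- "explicit"
  } else {
    init_name <- match.arg(init, c("classical", "simplex", "random"))
    starts[[1L]] <- mds_init(n, ndim, init_name, sources = sources, seed = seed)
  }
  if (restarts > 0L) {
    if (is.null(seed)) stop("restarts need a seed")
    for (r in seq_len(restarts))
      starts[[length(starts) + 1L]] <- mds_init(n, ndim, "random",
                                                seed = seed + r)
  }

  best <- NULL
  for (x0 in starts) {
    run <- smacof_engine(sources, weights, x0, tol, max_iter, unit_w)
    if (is.null(best) || run$stress < best$stress) best <- run
  }

  config <- scale(best$config, center = TRUE, scale = FALSE)
  attr(config, "scaled:center") <- NULL
  dimnames(config) <- list(labels, paste0("dim", seq_len(ndim)))
  structure(list(
    configuration = config,
    stress = best$stress,
    fit = 1 - best$stress,
    stress1 = sqrt(best$stress),
    trajectory = best$trajectory,
    converged = best$converged,
    n_iterations = best$n_iterations,
    ndim = ndim,
    settings = list(init = init_name, tol = tol, max_iter = max_iter,
                    restarts = restarts, seed = seed),
    sources = sources,
    weights = if (unit_w) NULL else weights,
    call = cl), class = "mds_fit")
}

# Guttman-transform majorization for the pooled multi-source stress.
# With unit weights V = K (n I - 11') and V^+ X = X / (n K) for centered X;
# general weights use the Moore-Penrose inverse of the pooled weight
# Laplacian (computed once).
smacof_engine <- function(sources, weights, x, tol, max_iter, unit_w) {
  n <- nrow(x); K <- length(sources)
  den <- 0
  for (k in seq_len(K)) {
    ut <- upper.tri(sources[[k]])
    den <- den + sum(weights[[k]][ut] * sources[[k]][ut]^2)
  }
  if (den <= 0) stop("degenerate input: all source dissimilarities are zero")
  if (!unit_w) {
    v <- matrix(0, n, n)
    for (k in seq_len(K)) {
      wk <- weights[[k]]; diag(wk) <- 0
      v <- v - wk
    }
    diag(v) <- -rowSums(v)
    v_pinv <- MASS::ginv(v)
  }
  stress_of <- function(xx) {
    d <- as.matrix(stats::dist(xx)); num <- 0
    for (k in seq_len(K)) {
      ut <- upper.tri(d)
      num <- num + sum(weights[[k]][ut] * (sources[[k]][ut] - d[ut])^2)
    }
    num / den
  }
  s_old <- stress_of(x)
  traj_it <- 0L; traj_s <- s_old; traj_imp <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- as.matrix(stats::dist(x))
    b <- matrix(0, n, n)
    for (k in seq_len(K)) {
      ratio <- ifelse(d > 0, sources[[k]] * weights[[k]] / d, 0)
      b <- b - ratio
    }
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x_new <- if (unit_w) (b %*% x) / (n * K) else v_pinv %*% (b %*% x)
    if (any(!is.finite(x_new)))
      stop("non-finite coordinates at iteration ", iter)
    s_new <- stress_of(x_new)
    imp <- s_old - s_new
    traj_it <- c(traj_it, iter); traj_s <- c(traj_s, s_new)
    traj_imp <- c(traj_imp, imp)
    x <- x_new; s_old <- s_new
    if (imp < tol) { converged <- TRUE; break }
  }
  list(config = x, stress = s_old,
       trajectory = data.frame(iteration = traj_it, stress = traj_s,
                               improvement = traj_imp),
       converged = converged, n_iterations = iter)
}

#' Total fit of an MDS solution
#'
#' Total fit = 1 - normalized raw stress; the quantity used on scree plots
#' for dimensionality selection.
#'
#' @param stress normalized raw stress in \[0, 1\].
#' @export
total_fit <- function(stress) {
  if (any(!is.finite(stress)) || any(stress < 0 | stress > 1))
    stop("stress must lie in [0, 1]")
  1 - stress
}

#' Qualitative stress label (Kruskal rule of thumb)
#'
#' Half-open bins anchored at the conventional thresholds: 0 = perfect,
#' (0, 0.025\] excellent, (0.025, 0.05\] good, (0.05, 0.1\] fair,
#' (0.1, 0.2\] poor, above 0.2 unacceptable.
#'
#' @param stress nonnegative stress value(s).
#' @return character vector of labels.
#' @export
kruskal_label <- function(stress) {
  if (any(stress < 0)) stop("stress must be nonnegative")
  cut(stress, breaks = c(-Inf, 0, 0.025, 0.05, 0.1, 0.2, Inf),
      labels = c("perfect", "excellent", "good", "fair", "poor", "unacceptable"),
      right = TRUE) |> as.character()
}

#' Stress/fit across a range of dimensionalities (scree table)
#'
#' Runs [mds_fit()] once per dimensionality. By default each run uses an
#' independent classical start; with `warm_start = TRUE` each solution is
#' initialized from the previous one padded with a zero column, which makes
#' fit non-decreasing in ndim.
#'
#' @param sources as in [mds_fit()].
#' @param dims integer vector of dimensionalities (default 1:12).
#' @param warm_start initialize each ndim from the previous solution.
#' @param ... passed to [mds_fit()].
#' @return an `mds_scree` data frame: `ndim`, `stress`, `fit`, `gain`
#'   (fit minus the fit at ndim - 1, where present).
#' @export
mds_scree <- function(sources, dims = 1:12, warm_start = FALSE, ...) {
  sources <- as_source_list(sources)
  dims <- sort(unique(as.integer(dims)))
  if (max(dims) >= nrow(sources[[1L]]))
    stop("max(dims) must be below the number of objects")
  fits <- vector("list", length(dims))
  prev <- NULL
  for (i in seq_along(dims)) {
    p <- dims[i]
    if (warm_start && !is.null(prev)) {
      x0 <- cbind(prev$configuration,
                  matrix(0, nrow(prev$configuration), p - prev$ndim))
      fits[[i]] <- mds_fit(sources, ndim = p, init = x0, ...)
    } else {
      fits[[i]] <- mds_fit(sources, ndim = p, ...)
    }
    prev <- fits[[i]]
  }
  stress <- vapply(fits, `[[`, numeric(1L), "stress")
  fit <- 1 - stress
  gain <- c(NA_real_, diff(fit))
  step <- c(NA_integer_, diff(dims))
  gain[!is.na(step) & step != 1L] <- NA_real_  # gains only for contiguous steps
  if (dims[1L] == 1L) gain[1L] <- fit[1L]  # 1D gain is over the 0-dim model
  structure(data.frame(ndim = dims, stress = stress, fit = fit, gain = gain),
            class = c("mds_scree", "data.frame"))
}

#' Choose a dimensionality from a scree table
#'
#' Returns the smallest ndim whose successor adds less than `gain_threshold`
#' to the total fit (the elbow rule used to justify a 3D solution). If every
#' gain is at or above the threshold, the largest ndim is returned with a
#' warning and attribute `all_gains_above_threshold = TRUE`.
#'
#' @param scree an `mds_scree` covering a contiguous ndim range.
#' @param gain_threshold marginal fit gain below which an extra dimension is
#'   judged not worthwhile (default 0.01).
#' @return chosen ndim (integer) with attribute `all_gains_above_threshold`.
#' @export
select_ndim <- function(scree, gain_threshold = 0.01) {
  if (!nrow(scree)) stop("empty scree table")
  if (nrow(scree) > 1L && any(diff(scree$ndim) != 1L))
    stop("scree must cover a contiguous ndim range")
  for (i in seq_len(nrow(scree) - 1L)) {
    if (!is.na(scree$gain[i + 1L]) && scree$gain[i + 1L] < gain_threshold)
      return(structure(scree$ndim[i], all_gains_above_threshold = FALSE))
  }
  warning("no dimensionality has a sub-threshold successor gain; returning max")
  structure(scree$ndim[nrow(scree)], all_gains_above_threshold = TRUE)
}
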