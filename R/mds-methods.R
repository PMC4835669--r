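#' @export
print.mds_fit <- function(x, ...) {
  cat(sprintf("Multi-source metric MDS fit (%d objects, %d source%s, ndim = %d)\n",
              nrow(x$configuration), length(x$sources),
              if (length(x$sources) > 1L) "s" else "", x$ndim))
  cat(sprintf("normalized raw stress: %.5f (%s), total fit: %.5f\n",
              x$stress, kruskal_label(x$stress), x$fit))
  cat(sprintf("%s after %d iteration(s) (init: %s, tol: %g)\n",
              if (x$converged) "converged" else "iteration cap reached",
              x$n_iterations, x$settings$init, x$settings$tol))
  invisible(x)
}

#' @export
summary.mds_fit <- function(object, ...) {
  structure(list(fit = object,
                 distances = fitted(object),
                 frontier = frontiers(object$configuration)),
            class = "summary.mds_fit")
}

#' @export
print.summary.mds_fit <- function(x, ...) {
  print(x$fit)
  cat("\nConfiguration (mean-centered):\n")
  print(round(x$fit$configuration, 3))
  cat("\nFrontier emotions per dimension:\n")
  print(x$frontier)
  invisible(x)
}

#' @export
coef.mds_fit <- function(object, ...) object$configuration

#' Fitted inter-object distances of an MDS solution
#'
#' @param object an `mds_fit`.
#' @param ... unused.
#' @return a `proximity_matrix` of kind `configuration_distance`.
#' @export
fitted.mds_fit <- function(object, ...) config_distances(object$configuration)

#' Residual dissimilarities of an MDS solution
#'
#' One matrix per source: source dissimilarity minus fitted configuration
#' distance (positive where the solution under-represents a dissimilarity).
#'
#' @param object an `mds_fit`.
#' @param ... unused.
#' @return a named list of matrices (a single matrix if one source).
#' @export
residuals.mds_fit <- function(object, ...) {
  d <- as.matrix(stats::dist(object$configuration))
  res <- lapply(object$sources, function(s) s - d)
  if (length(res) == 1L) res[[1L]] else res
}

#' Plot an MDS solution
#'
#' Scatter plot of a two-dimensional projection of the configuration with
#' emotion labels (projections are views of the same space, not re-fits).
#'
#' @param x an `mds_fit`.
#' @param dims pair of distinct dimension indices (default c(1, 2)).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mds_fit <- function(x, dims = c(1, 2), ...) {
  pr <- project_config(x$configuration, dims)
  lim <- range(pr) * 1.15
  graphics::plot(pr[, 1L], pr[, 2L], xlim = lim, ylim = lim, asp = 1,
                 xlab = colnames(pr)[1L], ylab = colnames(pr)[2L],
                 pch = 19, col = "grey40", ...)
  graphics::abline(h = 0, v = 0, col = "grey85")
  graphics::text(pr[, 1L], pr[, 2L], rownames(pr), pos = 3, cex = 0.8)
  invisible(x)
}

#' Plot a scree table
#'
#' Total fit against dimensionality.
#'
#' @param x an `mds_scree`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mds_scree <- function(x, ...) {
  graphics::plot(x$ndim, x$fit, type = "b", pch = 19,
                 xlab = "dimensions", ylab = "total fit (1 - stress)", ...)
  invisible(x)
}
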