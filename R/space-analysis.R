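#' Pairwise distances of a configuration
#'
#' Euclidean distances between configuration rows: the aggregated-space
#' counterpart of the four-aspect profile distances, computed from the final
#' coordinates on the solution axes.
#'
#' @param config coordinate matrix (objects x ndim) with rownames.
#' @return a `proximity_matrix` of kind `configuration_distance`.
#' @export
config_distances <- function(config) {
  config <- as.matrix(config)
  proximity_matrix(as.matrix(stats::dist(config)),
                   kind = "configuration_distance")
}

#' Correlation between two distance matrices
#'
#' Correlates the strict lower triangles of two aligned proximity matrices
#' (k(k-1)/2 pairs for k shared labels): the contrast used to quantify how
#' much inter-emotion structure survives the reduction from the 4D profile
#' space to the fitted 3D space. The naive p-value treats the pairs as
#' independent, which distance-matrix entries are not; with
#' `permutations > 0` a Mantel-style permutation p-value (simultaneous
#' row/column permutations of `b`, one-sided for positive association) is
#' also computed and is the one to prefer.
#'
#' @param a,b `proximity_matrix` objects (or plain symmetric matrices) with
#'   the same label set; `b` is re-aligned to `a`'s order.
#' @param method `"pearson"` or `"spearman"`.
#' @param permutations Mantel permutation count (0 = skip).
#' @param seed seed for the permutations.
#' @return a `matrix_cor` list: `r`, `n_pairs`, `method`, `p_naive`, and when
#'   permuted `p_mantel`, `permutations`, `seed`.
#' @export
matrix_cor <- function(a, b, method = c("pearson", "spearman"),
                       permutations = 0L, seed = NULL) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b)))
      stop("matrices do not share a label set")
    b <- b[rownames(a), rownames(a)]
  } else if (nrow(a) != nrow(b)) stop("matrices differ in size")
  lt <- lower.tri(a)
  va <- a[lt]; vb <- b[lt]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant lower triangle: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(va, vb, method = method))
  out <- list(r = unname(ct$estimate), n_pairs = length(va), method = method,
              p_naive = ct$p.value)
  if (permutations > 0L) {
    if (is.null(seed)) stop("Mantel permutations need a seed")
    set.seed(seed)
    n <- nrow(a)
    r_obs <- out$r
    r_perm <- replicate(permutations, {
      idx <- sample.int(n)
      stats::cor(va, b[idx, idx][lt], method = method)
    })
    out$p_mantel <- (1 + sum(r_perm >= r_obs)) / (permutations + 1)
    out$permutations <- permutations
    out$seed <- seed
  }
  structure(out, class = "matrix_cor")
}

#' @export
print.matrix_cor <- function(x, ...) {
  cat(sprintf("Distance-matrix correlation (%s): r = %.3f, N = %d pairs\n",
              x$method, x$r, x$n_pairs))
  cat(sprintf("naive p = %.3g", x$p_naive))
  if (!is.null(x$p_mantel))
    cat(sprintf("; Mantel p = %.3g (%d permutations)", x$p_mantel, x$permutations))
  cat("\n")
  invisible(x)
}

#' Frontier emotions of a configuration
#'
#' For each dimension, the emotions with the most positive and most negative
#' coordinates — the points that border the semantic space in that direction.
#' Runner-ups whose coordinate lies within `margin` of the extreme are listed
#' with it (so jointly-bordering trios are reported together); exact ties are
#' broken by label order and flagged.
#'
#' @param config coordinate matrix with rownames.
#' @param margin closeness margin for runner-ups (default 0.05).
#' @return a `frontier_report` data frame: `dimension`, `direction`
#'   (`"positive"`/`"negative"`), `rank` (1 = extreme), `emotion`,
#'   `coordinate`, `tie`.
#' @export
frontiers <- function(config, margin = 0.05) {
  config <- as.matrix(config)
  if (nrow(config) < 1L) stop("empty configuration")
  labs <- rownames(config) %||% paste0("e", seq_len(nrow(config)))
  rows <- list()
  for (j in seq_len(ncol(config))) {
    v <- config[, j]
    for (direction in c("positive", "negative")) {
      s <- if (direction == "positive") v else -v
      ord <- order(-s, labs)
      ext <- s[ord[1L]]
      keep <- ord[s[ord] >= ext - margin]
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = j, direction = direction,
        rank = seq_along(keep), emotion = labs[keep],
        coordinate = v[keep],
        tie = s[keep] == ext & length(which(s == ext)) > 1L,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("frontier_report", "data.frame"), margin = margin)
}

#' Is the central area of the space occupied?
#'
#' The central area is an origin-centered ball whose radius is
#' `radius_fraction` times the largest object norm (the space has no
#' intrinsic scale, so the radius is relative). Requires a mean-centered
#' configuration; reports whether any emotion lies inside and which one is
#' closest to the origin.
#'
#' @param config mean-centered coordinate matrix.
#' @param radius_fraction ball radius as a fraction of the largest norm
#'   (default 0.25).
#' @param center_tol tolerance on column means for the centering check.
#' @return list with `occupied`, `closest_emotion`, `min_norm`, `max_norm`,
#'   `radius`, `radius_fraction`, plus the inside emotions if any.
#' @export
central_area_check <- function(config, radius_fraction = 0.25,
                               center_tol = 1e-3) {
  config <- as.matrix(config)
  if (max(abs(colMeans(config))) > center_tol)
    stop("configuration is not mean-centered; center it first")
  if (radius_fraction < 0) stop("radius_fraction must be nonnegative")
  norms <- sqrt(rowSums(config^2))
  radius <- radius_fraction * max(norms)
  inside <- norms < radius | norms == 0  # radius 0: only an exact origin point
  structure(list(occupied = any(inside),
                 emotions_inside = rownames(config)[inside],
                 closest_emotion = rownames(config)[which.min(norms)],
                 min_norm = min(norms), max_norm = max(norms),
                 radius = radius, radius_fraction = radius_fraction),
            class = "central_area_report")
}

#' @export
print.central_area_report <- function(x, ...) {
  cat(sprintf("Central ball radius %.3f (%.0f%% of max norm %.3f): %s\n",
              x$radius, 100 * x$radius_fraction, x$max_norm,
              if (x$occupied) paste("occupied by",
                                    paste(x$emotions_inside, collapse = ", "))
              else "unoccupied"))
  cat(sprintf("closest emotion to the origin: %s (norm %.3f)\n",
              x$closest_emotion, x$min_norm))
  invisible(x)
}

#' Two-dimensional projection of a configuration
#'
#' Selects two coordinate columns; no re-fitting happens — a projection is
#' just another view of the same space.
#'
#' @param config coordinate matrix.
#' @param dims pair of distinct, valid dimension indices.
#' @return the objects x 2 coordinate matrix.
#' @export
project_config <- function(config, dims = c(1, 2)) {
  config <- as.matrix(config)
  dims <- as.integer(dims)
  if (length(dims) != 2L || anyNA(dims) || any(dims < 1L | dims > ncol(config)))
    stop("dims must be two valid dimension indices")
  if (dims[1L] == dims[2L]) stop("dims must be distinct")
  config[, dims, drop = FALSE]
}

#' Procrustes alignment of two configurations
#'
#' Finds the translation, orthogonal transform (rotation/reflection) and
#' optionally uniform scale of `b` minimizing the sum of squared coordinate
#' differences to `a`. MDS solutions are defined only up to these isometries,
#' so this is the canonical way to compare them. The reported disparity is
#' the minimized sum of squares divided by the centered sum of squares of
#' `a`; with scaling allowed it lies in \[0, 1\].
#'
#' @param a target configuration (matrix with rownames).
#' @param b configuration to align; re-ordered to `a`'s labels when both are
#'   labelled.
#' @param scale allow uniform scaling (default TRUE).
#' @return a `procrustes_fit` list: `aligned` (transformed `b`), `rotation`,
#'   `scale`, `translation`, `disparity`.
#' @export
procrustes_align <- function(a, b, scale = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) stop("configurations do not share labels")
    b <- b[rownames(a), , drop = FALSE]
  }
  if (!all(dim(a) == dim(b))) stop("configurations differ in shape")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2L, ca); bc <- sweep(b, 2L, cb)
  ssa <- sum(ac^2); ssb <- sum(bc^2)
  if (ssa == 0 || ssb == 0) stop("degenerate (all-coincident) configuration")
  sv <- svd(crossprod(bc, ac))        # rotation maximizing tr(R' B' A)
  rot <- sv$u %*% t(sv$v)
  s <- if (scale) sum(sv$d) / ssb else 1
  aligned <- s * bc %*% rot
  disparity <- sum((ac - aligned)^2) / ssa
  aligned <- sweep(aligned, 2L, ca, `+`)
  rownames(aligned) <- rownames(a)
  structure(list(aligned = aligned, rotation = rot, scale = s,
                 translation = ca - s * as.vector(cb %*% rot),
                 disparity = disparity),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Procrustes alignment: disparity %.6g (scale %.4f)\n",
              x$disparity, x$scale))
  invisible(x)
}

#' @rdname procrustes_align
#' @export
procrustes_disparity <- function(a, b, scale = TRUE)
  procrustes_align(a, b, scale = scale)$disparity
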