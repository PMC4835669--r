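#' Labelled dissimilarity matrices
#'
#' A `proximity_matrix` is a square, symmetric, nonnegative, zero-diagonal
#' matrix of dissimilarities between emotion words, with a `kind` recording
#' how it was built:
#' * `profile_distance` — Euclidean distance between four-aspect mean
#'   profiles (theoretical range 0-200 = 100 * sqrt(4));
#' * `correlation_derived` — d = 1 - r from an inter-emotion correlation
#'   matrix (range 0-2), the MDS source family;
#' * `configuration_distance` — Euclidean distances of a fitted configuration.
#'
#' @param values square numeric matrix (labels from dimnames or `labels`).
#' @param kind one of `"profile_distance"`, `"correlation_derived"`,
#'   `"configuration_distance"`.
#' @param labels optional label vector.
#' @param aspect optional aspect tag (for correlation-derived matrices).
#' @param scale_max documented theoretical maximum entry, or `NA`.
#' @param check validate invariants (symmetry, nonnegativity, zero diagonal).
#' @export
proximity_matrix <- function(values, kind = c("profile_distance",
                                              "correlation_derived",
                                              "configuration_distance"),
                             labels = NULL, aspect = NULL, scale_max = NA_real_,
                             check = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("proximity matrix must be square")
  labels <- labels %||% rownames(values) %||% paste0("e", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  if (check) {
    if (anyNA(values)) stop("proximity matrix contains missing values")
    if (max(abs(values - t(values))) > 1e-8) stop("proximity matrix must be symmetric")
    if (any(diag(values) != 0)) stop("proximity matrix must have a zero diagonal")
    if (any(values < 0)) stop("proximities must be nonnegative")
    if (!is.na(scale_max) && any(values > scale_max + 1e-8))
      stop("proximities exceed the declared scale maximum ", scale_max)
  }
  structure(values, class = c("proximity_matrix", "matrix", "array"),
            kind = kind, aspect = aspect, scale_max = scale_max)
}

#' @export
print.proximity_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Proximity matrix (%s%s): %d x %d, range [%.3g, %.3g]",
              attr(x, "kind"),
              if (!is.null(attr(x, "aspect"))) paste0(", aspect ", attr(x, "aspect")) else "",
              nrow(x), ncol(x), min(x), max(x[upper.tri(x)])))
  if (!is.na(attr(x, "scale_max")))
    cat(sprintf(", scale max %g", attr(x, "scale_max")))
  cat("\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Read / write a proximity matrix as labelled square CSV
#'
#' Full square matrix (both triangles), first column `emotion` carrying the
#' labels; `kind` and `scale_max` are stored as a `#` comment header line.
#'
#' @param x a `proximity_matrix`; `path` a file path.
#' @param digits decimal places written (default 6).
#' @param kind,scale_max overrides used when the file has no comment header.
#' @export
write_proximity <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "proximity_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s scale_max=%s%s", attr(x, "kind"),
                     format(attr(x, "scale_max")),
                     if (!is.null(attr(x, "aspect")))
                       paste0(" aspect=", attr(x, "aspect")) else ""), con)
  writeLines(paste(c("emotion", rownames(x)), collapse = ","), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(c(rownames(x)[i], sprintf(paste0("%.", digits, "g"), x[i, ])),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname write_proximity
#' @export
read_proximity <- function(path, kind = NULL, scale_max = NULL) {
  lines <- readLines(path)
  aspect <- NULL
  if (startsWith(lines[1L], "#")) {
    hdr <- lines[1L]
    get <- function(key) {
      m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1L]]
      if (length(m) == 2L) m[2L] else NULL
    }
    kind <- kind %||% get("kind")
    sm <- get("scale_max")
    scale_max <- scale_max %||% (if (!is.null(sm)) suppressWarnings(as.numeric(sm)) else NULL)
    aspect <- get("aspect")
    lines <- lines[-1L]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df[[1L]]
  proximity_matrix(m, kind = kind %||% "profile_distance",
                   aspect = aspect, scale_max = scale_max %||% NA_real_)
}

#' Four-aspect mean-profile distance matrix
#'
#' For each pair of emotions, the Euclidean distance between their vectors of
#' per-aspect mean ratings: with differences w, x, y, z on the four aspects,
#' s = sqrt(w^2 + x^2 + y^2 + z^2). With all four aspects on the 0-100 mm
#' scale the possible range is 0-200 (the main diagonal of a hypercube of
#' side 100). The formula is stated for exactly four aspects; other aspect
#' counts require `generalized = TRUE`, which uses sqrt of the sum of squares
#' over however many aspects are present (scale max 100 * sqrt(k)).
#'
#' @param summary an `aspect_summary`.
#' @param generalized allow aspect counts other than 4.
#' @return a `proximity_matrix` of kind `profile_distance`.
#' @export
profile_distances <- function(summary, generalized = FALSE) {
  m <- summary_means(summary)
  k <- ncol(m)
  if (k != 4L && !generalized)
    stop("the profile-distance formula is defined for exactly 4 aspects (got ",
         k, "); pass generalized = TRUE for the sqrt-sum-of-squares extension")
  d <- as.matrix(stats::dist(m))
  proximity_matrix(d, kind = "profile_distance", scale_max = 100 * sqrt(k))
}

#' Inter-emotion correlation matrix for one aspect
#'
#' Correlates the emotions' rating vectors across participants for a fixed
#' aspect (one value per participant and emotion), using pairwise-complete
#' observations. Spearman (the default) uses average ranks for ties.
#'
#' @param x a `rating_dataset`.
#' @param aspect aspect label.
#' @param method `"spearman"` or `"pearson"`.
#' @return a `correlation_matrix`: k x k matrix with attributes `method` and
#'   `n_pairs` (matrix of pairwise-complete counts).
#' @export
aspect_correlations <- function(x, aspect, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "rating_dataset"))
  if (!aspect %in% dimnames(x)$aspect)
    stop("unknown aspect: ", aspect)
  mat <- x[, , aspect]
  sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    stop("zero variance for emotion '",
         dimnames(x)$emotion[which(sds == 0)[1L]],
         "' in aspect '", aspect, "': correlation undefined")
  n_pairs <- crossprod(!is.na(mat))
  if (any(n_pairs < 3L))
    stop("fewer than 3 complete participant pairs for some emotion pair in aspect '",
         aspect, "'")
  r <- stats::cor(mat, use = "pairwise.complete.obs", method = method)
  structure(r, class = c("correlation_matrix", "matrix", "array"),
            method = method, aspect = aspect, n_pairs = n_pairs)
}

#' Transform correlations to proximities
#'
#' The linear map d = 1 - r: perfect positive correlation becomes distance 0,
#' zero correlation distance 1, perfect negative correlation distance 2. The
#' diagonal is forced to exactly 0.
#'
#' @param corr a `correlation_matrix` (or plain correlation matrix).
#' @return a `proximity_matrix` of kind `correlation_derived` (scale max 2).
#' @export
cor_to_prox <- function(corr) {
  r <- unclass(corr)
  if (anyNA(r) || max(abs(r), na.rm = TRUE) > 1 + 1e-8)
    stop("input is not a valid correlation matrix")
  d <- 1 - r
  diag(d) <- 0
  proximity_matrix(d, kind = "correlation_derived",
                   aspect = attr(corr, "aspect"), scale_max = 2)
}

#' Build the per-aspect MDS source matrices
#'
#' One correlation-derived proximity matrix per aspect, in dataset aspect
#' order, all sharing the same emotion label order: the multi-source input of
#' [mds_fit()].
#'
#' @param x a `rating_dataset`.
#' @param method correlation method, passed to [aspect_correlations()].
#' @return named list of `proximity_matrix` objects, one per aspect.
#' @export
mds_sources <- function(x, method = "spearman") {
  stopifnot(inherits(x, "rating_dataset"))
  aspects <- dimnames(x)$aspect
  out <- lapply(aspects, function(a) cor_to_prox(aspect_correlations(x, a, method)))
  names(out) <- aspects
  out
}

#' Pairwise independence of the four rating aspects
#'
#' Correlates every pair of aspects and Bonferroni-adjusts the p-values
#' (adjusted p = min(1, 6 * raw p) for four aspects). The study's claim of
#' uncorrelated aspects does not state its unit of analysis, so both are
#' offered: `pooled_observations` correlates the flattened participant x
#' emotion vectors; `emotion_means` correlates the per-emotion mean profiles.
#'
#' @param x a `rating_dataset`.
#' @param alpha significance level (default 0.05).
#' @param unit `"pooled_observations"` (default) or `"emotion_means"`.
#' @param method `"pearson"` (t-test p-values) or `"spearman"`
#'   (large-sample approximation).
#' @return an `independence_report` data frame: one row per aspect pair with
#'   `r`, `p`, `p_adjusted`, `significant`; attributes `alpha` and `unit`.
#' @export
aspect_independence <- function(x, alpha = 0.05,
                                unit = c("pooled_observations", "emotion_means"),
                                method = c("pearson", "spearman")) {
  unit <- match.arg(unit)
  method <- match.arg(method)
  stopifnot(inherits(x, "rating_dataset"))
  aspects <- dimnames(x)$aspect
  vecs <- if (unit == "pooled_observations")
    lapply(aspects, function(a) as.vector(x[, , a]))
  else {
    s <- summary_means(aspect_summary(x))
    lapply(aspects, function(a) s[, a])
  }
  names(vecs) <- aspects
  pairs <- utils::combn(aspects, 2L)
  n_tests <- ncol(pairs)
  rows <- lapply(seq_len(n_tests), function(i) {
    a <- vecs[[pairs[1L, i]]]; b <- vecs[[pairs[2L, i]]]
    ok <- stats::complete.cases(a, b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      stop("zero variance in aspect '",
           if (stats::sd(a[ok]) == 0) pairs[1L, i] else pairs[2L, i],
           "': correlation undefined")
    ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = method))
    data.frame(aspect_a = pairs[1L, i], aspect_b = pairs[2L, i],
               r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * n_tests)
  out$significant <- out$p_adjusted < alpha
  structure(out, class = c("independence_report", "data.frame"),
            alpha = alpha, unit = unit, method = method)
}

#' @export
print.independence_report <- function(x, ...) {
  cat(sprintf("Aspect independence (unit: %s, %s, Bonferroni, alpha = %g)\n",
              attr(x, "unit"), attr(x, "method"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$r <- round(df$r, 3); df$p <- signif(df$p, 3); df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df, row.names = FALSE)
  if (!any(x$significant))
    cat("No aspect pair significantly correlated after correction.\n")
  invisible(x)
}
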