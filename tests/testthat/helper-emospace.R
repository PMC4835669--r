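# shared fixtures and independent oracles, built in code

# tiny long-format ratings file: 2 participants x 2 emotions x 1 aspect
write_toy_long <- function(path, values = c(10, 20, 30, 40)) {
  lines <- c("participant_id,emotion,aspect,value_mm",
             paste("p1,joy,valence", values[1], sep = ","),
             paste("p1,dread,valence", values[2], sep = ","),
             paste("p2,joy,valence", values[3], sep = ","),
             paste("p2,dread,valence", values[4], sep = ","))
  writeLines(lines, path)
  path
}

# small complete dataset with all four aspects, deterministic values
toy_dataset <- function(n = 6, emotions = c("joy", "dread", "calm", "ire"),
                        seed = 7) {
  set.seed(seed)
  arr <- array(runif(n * length(emotions) * 4, 5, 95),
               dim = c(n, length(emotions), 4),
               dimnames = list(participant = paste0("p", seq_len(n)),
                               emotion = emotions,
                               aspect = c("valence", "arousal", "control", "utility")))
  rating_dataset(arr)
}

# centered random planted configuration with the 16-emotion lexicon
planted_config <- function(ndim = 3, seed = 1, labels = emotion_lexicon) {
  set.seed(seed)
  x <- matrix(rnorm(length(labels) * ndim), length(labels), ndim)
  x <- scale(x, center = TRUE, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  rownames(x) <- labels
  x
}

# --- independent oracles -------------------------------------------------

# average ranks computed from first principles (no rank())
oracle_ranks <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v))
    r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  r
}

# Spearman correlation as Pearson on oracle ranks, by explicit sums
oracle_spearman <- function(a, b) {
  ra <- oracle_ranks(a); rb <- oracle_ranks(b)
  n <- length(ra)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# normalized raw stress by plain double loops over pairs and sources
oracle_stress <- function(sources, config) {
  if (is.matrix(sources)) sources <- list(sources)
  n <- nrow(config)
  num <- 0; den <- 0
  for (s in sources) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt(sum((config[i, ] - config[j, ])^2))
    num <- num + (s[i, j] - dij)^2
    den <- den + s[i, j]^2
  }
  num / den
}

# direct numerical stress minimization over all coordinates (multistart BFGS)
oracle_min_stress <- function(sources, ndim, n_starts = 50, seed = 99) {
  if (is.matrix(sources)) sources <- list(sources)
  n <- nrow(sources[[1]])
  f <- function(par) mds_stress(sources, matrix(par, n, ndim))
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    par0 <- rnorm(n * ndim)
    fit <- optim(par0, f, method = "BFGS", control = list(maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

# closed-form Procrustes disparity recomputed independently of the package
oracle_procrustes_disparity <- function(a, b, scale = TRUE) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  sv <- svd(t(ac) %*% bc)
  trace <- sum(sv$d)
  if (scale) {
    # minimized SS = ||A||^2 - trace^2 / ||B||^2
    (sum(ac^2) - trace^2 / sum(bc^2)) / sum(ac^2)
  } else {
    (sum(ac^2) + sum(bc^2) - 2 * trace) / sum(ac^2)
  }
}
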