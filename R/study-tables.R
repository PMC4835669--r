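#' The 16-emotion lexicon
#'
#' Canonical order of the sixteen emotion words used in the reference study:
#' five basic emotions (anger, fear, sadness, happiness, disgust) and eleven
#' complex ones. Loaders and simulators default to this order so that
#' reproduced tables line up with the published ones.
#'
#' @export
emotion_lexicon <- c("anger", "fear", "sadness", "happiness", "disgust",
                     "hope", "love", "hate", "contempt", "guilt",
                     "compassion", "shame", "gratefulness", "envy",
                     "disappointment", "jealousy")

#' The four rating aspects
#'
#' Valence (unpleasant-pleasant), arousal (calm-aroused), control
#' (uncontrolled-controlled) and utility (harmful-beneficial), each judged on
#' a 0-100 mm line.
#'
#' @export
aspect_lexicon <- c("valence", "arousal", "control", "utility")

study_file <- function(name) {
  f <- system.file("extdata", name, package = "emospace")
  if (!nzchar(f)) stop("packaged table not found: ", name)
  f
}

#' Published summary statistics of the 187-participant emotion-rating study
#'
#' Per-cell mean and standard deviation of the ratings of 16 emotion words on
#' the four aspects, as printed in the study's descriptive table (1 decimal,
#' n = 187). Three arousal/control SDs (envy arousal 49.3, contempt arousal
#' 43.8, happiness control 62.2) are implausibly large relative to their
#' neighbours — no distribution bounded on \[0, 100\] with those means can
#' even attain the last two — and are probably transcription errors in the
#' source; they are shipped verbatim, not corrected.
#'
#' @return an `aspect_summary` data frame (64 rows).
#' @export
study_aspect_summary <- function() {
  read_aspect_summary(study_file("study_aspect_summary.csv"))
}

#' Published mean-centered 3D configuration of the 16 emotions
#'
#' The final coordinates of the study's three-dimensional multi-source MDS
#' solution (3 decimals). Shipped as a fixture for the space-analysis
#' operations; it cannot be recomputed here because the underlying
#' per-participant correlation matrices were never released.
#'
#' @return 16 x 3 numeric matrix with emotion rownames and columns
#'   `dim1, dim2, dim3`.
#' @export
study_configuration <- function() {
  df <- utils::read.csv(study_file("study_configuration_3d.csv"),
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$emotion
  m
}

#' Published inter-emotion distance matrices
#'
#' `space = "4d"`: the distances between the 16 emotions' four-aspect mean
#' profiles as printed (1 decimal; theoretical range 0-200). The printed envy
#' column is internally inconsistent with the printed means (e.g. love-envy
#' prints 114.2 but recomputes to about 97.1) and is kept verbatim.
#' `space = "3d"`: the Euclidean distances in the published 3D configuration
#' as printed (3 decimals).
#'
#' @param space `"4d"` (profile distances) or `"3d"` (configuration distances).
#' @return a `proximity_matrix` (16 x 16).
#' @export
study_distances <- function(space = c("4d", "3d")) {
  space <- match.arg(space)
  if (space == "4d")
    read_proximity(study_file("study_distances_4d.csv"),
                   kind = "profile_distance", scale_max = 200)
  else
    read_proximity(study_file("study_distances_3d.csv"),
                   kind = "configuration_distance")
}
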