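#' Rating datasets: participant x emotion x aspect tensors of 0-100 mm marks
#'
#' A rating dataset holds one visual-analogue judgment per participant,
#' emotion word and aspect, measured as the mark position in millimeters from
#' the left end of a 10 cm line (so every value lies in \[0, 100\]; the left
#' pole is the low anchor: unpleasant / calm / uncontrolled / harmful).
#' Missing entries are allowed and stored as `NA`.
#'
#' @param values numeric 3-d array, dimensions (participant, emotion, aspect).
#' @param participants,emotions,aspects label vectors; taken from `dimnames(values)`
#'   when omitted.
#' @param check validate invariants and fail on violation (default). With
#'   `check = FALSE` an invalid object can be built and inspected with
#'   [validate_ratings()].
#' @return an object of class `rating_dataset`: the array with dimnames and
#'   class attached.
#' @seealso [read_ratings()], [aspect_summary()], [simulate_ratings()]
#' @export
rating_dataset <- function(values, participants = NULL, emotions = NULL,
                           aspects = NULL, check = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (participant x emotion x aspect)")
  dn <- dimnames(values)
  participants <- participants %||% dn[[1L]] %||% paste0("p", seq_len(dim(values)[1L]))
  emotions     <- emotions     %||% dn[[2L]] %||% paste0("e", seq_len(dim(values)[2L]))
  aspects      <- aspects      %||% dn[[3L]] %||% paste0("a", seq_len(dim(values)[3L]))
  if (length(participants) != dim(values)[1L] ||
      length(emotions) != dim(values)[2L] ||
      length(aspects) != dim(values)[3L])
    stop("label lengths do not match tensor dimensions")
  dimnames(values) <- list(participant = as.character(participants),
                           emotion = as.character(emotions),
                           aspect = as.character(aspects))
  x <- structure(values, class = "rating_dataset")
  if (check) {
    rep <- validate_ratings(x)
    if (!rep$ok)
      stop("invalid rating dataset: ", format_violations(rep$violations))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_violations <- function(v, max_show = 3L) {
  shown <- utils::head(v, max_show)
  msg <- paste(sprintf("[%s] participant=%s emotion=%s aspect=%s value=%s",
                       shown$rule, shown$participant, shown$emotion,
                       shown$aspect, shown$value), collapse = "; ")
  if (nrow(v) > max_show) msg <- paste0(msg, sprintf(" ... (%d total)", nrow(v)))
  msg
}

#' @export
print.rating_dataset <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Rating dataset: %d participants x %d emotions x %d aspects\n",
              d[1L], d[2L], d[3L]))
  cat("aspects:", paste(dimnames(x)$aspect, collapse = ", "), "\n")
  n_na <- sum(is.na(x))
  if (n_na) cat(sprintf("missing entries: %d (%.1f%%)\n", n_na, 100 * n_na / length(x)))
  invisible(x)
}

#' Validate a rating dataset
#'
#' Checks every invariant of the data model: values in \[0, 100\], unique and
#' non-empty emotion/aspect labels, label/dimension agreement. Violations are
#' reported as data, not raised as errors.
#'
#' @param x a `rating_dataset` (or bare 3-d array).
#' @return a `validation_report`: list with `ok` (logical) and `violations`
#'   (data frame with columns participant, emotion, aspect, rule, value);
#'   `ok` is `TRUE` iff there are no violations.
#' @export
validate_ratings <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  dn <- dimnames(x)
  viol <- list()
  add <- function(participant, emotion, aspect, rule, value) {
    viol[[length(viol) + 1L]] <<- data.frame(
      participant = participant, emotion = emotion, aspect = aspect,
      rule = rule, value = value, stringsAsFactors = FALSE)
  }
  for (field in c("emotion", "aspect")) {
    labs <- dn[[field]]
    if (any(!nzchar(labs)))
      add("-", "-", "-", paste0("empty_", field, "_label"), "")
    dups <- unique(labs[duplicated(labs)])
    for (d in dups) add("-", if (field == "emotion") d else "-",
                        if (field == "aspect") d else "-",
                        paste0("duplicate_", field, "_label"), d)
  }
  bad <- which(!is.na(x) & (x < 0 | x > 100), arr.ind = TRUE)
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad)))
      add(dn$participant[bad[i, 1L]], dn$emotion[bad[i, 2L]],
          dn$aspect[bad[i, 3L]], "value_out_of_range",
          as.character(x[bad[i, , drop = FALSE]]))
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(participant = character(), emotion = character(),
               aspect = character(), rule = character(), value = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("Rating dataset OK: no violations\n")
  else {
    cat(sprintf("Rating dataset INVALID: %d violation(s)\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' Convert a mark position on the 10 cm line to a rating value
#'
#' The instrument is a 10 cm horizontal line; the distance of the mark from
#' the left end in millimeters is the rating, giving a continuous 0-100 scale.
#' The left end is the low pole of each aspect (unpleasant, calm,
#' uncontrolled, harmful) and the right end the high pole. The map is the
#' identity; this function exists to make the convention explicit and to
#' range-check positions.
#'
#' @param mark_position numeric vector of mm positions in \[0, 100\].
#' @return the same values, validated.
#' @export
mm_to_score <- function(mark_position) {
  if (!is.numeric(mark_position))
    stop("mark position must be numeric")
  bad <- which(!is.na(mark_position) & (mark_position < 0 | mark_position > 100))
  if (length(bad))
    stop(sprintf("mark position outside [0, 100] at index %d: %g",
                 bad[1L], mark_position[bad[1L]]))
  mark_position
}

#' Descriptive summary per emotion and aspect
#'
#' Computes, for every (emotion, aspect) cell, the arithmetic mean M and the
#' sample standard deviation SD (n - 1 denominator) of the ratings over
#' participants, excluding missing values cell-wise, together with the number
#' of non-missing values used.
#'
#' @param x a `rating_dataset`.
#' @return an `aspect_summary`: data frame with columns `emotion`, `aspect`,
#'   `mean`, `sd`, `n`, one row per (emotion, aspect) pair in dataset order.
#' @export
aspect_summary <- function(x) {
  stopifnot(inherits(x, "rating_dataset"))
  dn <- dimnames(x)
  grid <- expand.grid(aspect = dn$aspect, emotion = dn$emotion,
                      stringsAsFactors = FALSE)[, c("emotion", "aspect")]
  # reorder: emotion-major to mirror the published summary layout
  grid <- grid[order(match(grid$emotion, dn$emotion), match(grid$aspect, dn$aspect)), ]
  res <- mapply(function(e, a) {
    v <- x[, e, a]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop(sprintf("no non-missing values for emotion '%s', aspect '%s'", e, a))
    c(mean(v), stats::sd(v), length(v))
  }, grid$emotion, grid$aspect)
  out <- data.frame(emotion = grid$emotion, aspect = grid$aspect,
                    mean = res[1L, ], sd = ifelse(is.na(res[2L, ]), 0, res[2L, ]),
                    n = as.integer(res[3L, ]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("aspect_summary", "data.frame"),
            emotions = dn$emotion, aspects = dn$aspect)
}

#' @export
summary.rating_dataset <- function(object, ...) aspect_summary(object)

#' Read ratings from CSV
#'
#' Long layout expects columns `participant_id,emotion,aspect,value_mm`; wide
#' layout expects one row per participant x aspect with columns
#' `participant_id,aspect,<emotion>,...`. Labels keep their order of first
#' appearance in the file. Values outside \[0, 100\] are an error unless
#' `clip = TRUE`, which clamps them to the scale with a warning (useful for
#' digitization overshoot, but off by default so instrument errors surface).
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @param clip clamp out-of-range values to \[0, 100\] instead of failing.
#' @return a `rating_dataset`.
#' @export
read_ratings <- function(path, layout = c("long", "wide"), clip = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (layout == "long") {
    need <- c("participant_id", "emotion", "aspect", "value_mm")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    long <- df[need]
  } else {
    need <- c("participant_id", "aspect")
    if (!all(need %in% names(df)))
      stop("wide layout requires columns participant_id, aspect")
    emo_cols <- setdiff(names(df), need)
    if (length(emo_cols) == 0L) stop("wide layout has no emotion columns")
    long <- do.call(rbind, lapply(emo_cols, function(e)
      data.frame(participant_id = df$participant_id, emotion = e,
                 aspect = df$aspect, value_mm = df[[e]],
                 stringsAsFactors = FALSE)))
    # keep file row order within each emotion; emotions in column order
    long <- long[order(match(long$emotion, emo_cols)), ]
  }
  raw <- long$value_mm
  vals <- suppressWarnings(as.numeric(raw))
  bad_parse <- which(is.na(vals) & !is.na(raw) & nzchar(trimws(raw)))
  if (length(bad_parse))
    stop(sprintf("unparseable value '%s' (entry %d of %s)",
                 raw[bad_parse[1L]], bad_parse[1L], path))
  oob <- which(!is.na(vals) & (vals < 0 | vals > 100))
  if (length(oob)) {
    if (clip) {
      warning(sprintf("%d value(s) outside [0, 100] clipped to the scale", length(oob)))
      vals <- pmin(pmax(vals, 0), 100)
    } else {
      stop(sprintf("value %g outside [0, 100] (entry %d: participant %s, emotion %s, aspect %s)",
                   vals[oob[1L]], oob[1L], long$participant_id[oob[1L]],
                   long$emotion[oob[1L]], long$aspect[oob[1L]]))
    }
  }
  key <- paste(long$participant_id, long$emotion, long$aspect, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate rating for participant %s, emotion %s, aspect %s",
                 long$participant_id[dup[1L]], long$emotion[dup[1L]],
                 long$aspect[dup[1L]]))
  participants <- unique(long$participant_id)
  emotions <- unique(long$emotion)
  aspects <- unique(long$aspect)
  arr <- array(NA_real_, dim = c(length(participants), length(emotions), length(aspects)),
               dimnames = list(participant = participants, emotion = emotions,
                               aspect = aspects))
  arr[cbind(match(long$participant_id, participants),
            match(long$emotion, emotions),
            match(long$aspect, aspects))] <- vals
  rating_dataset(arr)
}

#' Write ratings to CSV
#'
#' Long output is canonical: rows ordered participant-major, then emotion,
#' then aspect (dataset order), values formatted with `%.10g` so that a
#' save -> load -> save round trip is byte-identical. Missing entries are
#' omitted from long files and written as empty fields in wide files.
#'
#' @param x a `rating_dataset`.
#' @param path output file.
#' @param layout `"long"` or `"wide"`.
#' @export
write_ratings <- function(x, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "rating_dataset"))
  dn <- dimnames(x)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.10g", v))
  con <- file(path, open = "wb")  # binary: fixed \n endings for byte identity
  on.exit(close(con))
  if (layout == "long") {
    writeLines("participant_id,emotion,aspect,value_mm", con)
    for (p in dn$participant) for (e in dn$emotion) for (a in dn$aspect) {
      v <- x[p, e, a]
      if (!is.na(v))
        writeLines(paste(p, e, a, fmt(v), sep = ","), con)
    }
  } else {
    writeLines(paste(c("participant_id", "aspect", dn$emotion), collapse = ","), con)
    for (p in dn$participant) for (a in dn$aspect)
      writeLines(paste(c(p, a, fmt(x[p, , a])), collapse = ","), con)
  }
  invisible(path)
}

#' Write / read an aspect summary table
#'
#' CSV with header `emotion,aspect,mean,sd,n`, mirroring the shape of the
#' published descriptive table.
#'
#' @param x an `aspect_summary`.
#' @param path file path.
#' @param digits decimal places for mean and sd (`NULL` = full precision).
#' @export
write_aspect_summary <- function(x, path, digits = NULL) {
  stopifnot(inherits(x, "aspect_summary"))
  out <- as.data.frame(x)
  if (!is.null(digits)) {
    out$mean <- round(out$mean, digits)
    out$sd <- round(out$sd, digits)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aspect_summary
#' @export
read_aspect_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("emotion", "aspect", "mean", "sd", "n")
  if (!all(need %in% names(df)))
    stop("summary CSV requires columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (any(df$mean < 0 | df$mean > 100)) stop("summary means must lie in [0, 100]")
  if (any(df$sd < 0)) stop("summary SDs must be nonnegative")
  if (anyDuplicated(paste(df$emotion, df$aspect, sep = "\r")))
    stop("duplicate (emotion, aspect) rows in summary")
  structure(df, class = c("aspect_summary", "data.frame"),
            emotions = unique(df$emotion), aspects = unique(df$aspect))
}

#' Matrix of cell means from an aspect summary
#'
#' @param x an `aspect_summary`.
#' @return numeric matrix, emotions x aspects, in summary order.
#' @export
summary_means <- function(x) {
  stopifnot(inherits(x, "aspect_summary"))
  emotions <- attr(x, "emotions") %||% unique(x$emotion)
  aspects <- attr(x, "aspects") %||% unique(x$aspect)
  m <- matrix(NA_real_, length(emotions), length(aspects),
              dimnames = list(emotions, aspects))
  m[cbind(match(x$emotion, emotions), match(x$aspect, aspects))] <- x$mean
  if (anyNA(m)) stop("summary is missing (emotion, aspect) cells")
  m
}
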