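## canonical schema tag for session files
SESSION_SCHEMA <- "gazecue-session/1"

## app presentation constants carried in session metadata (the
## attention-getter enlarges pupils to 130% at 75% opacity for 0.3 s; an
## audio prompt repeats if no response arrives within 5 s)
default_app_params <- function() {
  list(
    attention_getter = list(pupil_scale = 1.3, opacity = 0.75,
                            duration_s = 0.3),
    response_prompt_timeout_s = 5
  )
}

#' Assemble a session file object
#'
#' A session file mirrors the task app's output: a single JSON document
#' holding metadata (subject, version, device, app presentation
#' constants), the full trial specification list, and the participant's
#' responses (click coordinates or chosen boxes, possibly missing). This
#' package defines one canonical schema (`gazecue-session/1`) rather than
#' reverse-engineering any particular app build.
#'
#' @param trials Trial tibble from [generate_session()].
#' @param responses Optional response tibble with `trial_index` and
#'   `click_x` (hedge) or `chosen_box` (box); may include `click_y` and
#'   `response_time_s`. Missing responses are stored as JSON `null`.
#' @param metadata Named list; `subject_id`, `age_months`, `mode`,
#'   `version`, `device`, `timestamp` are recognized. App presentation
#'   constants are filled in automatically.
#' @return An object of class `session_file`.
#' @export
session_file <- function(trials, responses = NULL, metadata = list()) {
  metadata$app <- metadata$app %||% default_app_params()
  metadata$version <- metadata$version %||%
    (if (all(is.na(trials$box))) "hedge" else "box")
  trials <- as_tibble(trials)
  attr(trials, "config") <- NULL
  x <- structure(
    list(schema = SESSION_SCHEMA, metadata = metadata,
         trials = trials,
         responses = if (is.null(responses)) NULL else as_tibble(responses)),
    class = "session_file"
  )
  validate_session(x)
  x
}

#' @export
print.session_file <- function(x, ...) {
  cat(sprintf("<session_file> %s, %d trials, %s responses\n",
              x$metadata$version, nrow(x$trials),
              if (is.null(x$responses)) "no" else nrow(x$responses)))
  invisible(x)
}

validate_session <- function(x) {
  if (!identical(x$schema, SESSION_SCHEMA)) {
    abort(sprintf("Unknown session schema tag: %s (expected %s).",
                  x$schema %||% "<missing>", SESSION_SCHEMA))
  }
  if (!x$metadata$version %in% c("hedge", "box")) {
    abort(sprintf("metadata.version: unknown study version \"%s\".",
                  x$metadata$version))
  }
  needed <- c("index", "phase", "agent", "color", "bin", "box",
              "target_x", "visibility", "voiceover")
  missing <- setdiff(needed, names(x$trials))
  if (length(missing) > 0) {
    abort(paste0("trials: missing field(s) ", paste(missing, collapse = ", "), "."))
  }
  if (any(duplicated(x$trials$index))) {
    abort("trials.index: duplicate trial indices.")
  }
  if (!is.null(x$responses)) {
    if (!"trial_index" %in% names(x$responses)) {
      abort("responses: missing field trial_index.")
    }
    bad <- setdiff(x$responses$trial_index, x$trials$index)
    if (length(bad) > 0) {
      abort(sprintf("responses.trial_index: no such trial(s): %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write a session file to JSON
#'
#' Serializes a [session_file()] to a UTF-8 JSON document with full
#' numeric precision; missing responses become JSON `null`.
#'
#' @param session A `session_file`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_file"))
  validate_session(session)
  jsonlite::write_json(
    list(schema = session$schema,
         metadata = session$metadata,
         trials = session$trials,
         responses = session$responses),
    path, auto_unbox = TRUE, digits = NA, na = "null", null = "null",
    pretty = TRUE
  )
  invisible(path)
}

## restore the schema's column types after JSON round trip (all-null
## columns come back untyped)
retype <- function(df, spec) {
  for (nm in names(spec)) {
    if (!nm %in% names(df)) next
    df[[nm]] <- switch(spec[[nm]],
                       integer = as.integer(df[[nm]]),
                       double = as.numeric(df[[nm]]),
                       character = as.character(df[[nm]]),
                       logical = as.logical(df[[nm]]))
  }
  df
}

#' Read and validate a session file
#'
#' Parses a JSON session document, checks it against the
#' `gazecue-session/1` schema (known version tag, complete trial fields,
#' responses referencing existing trials) and restores column types.
#' Missing clicks load as `NA` and are excluded by [score_responses()].
#'
#' @param path Path to a JSON session file.
#' @return A `session_file` object; `read_session(write_session(x))`
#'   reproduces `x`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  trials <- retype(as_tibble(raw$trials), list(
    index = "integer", phase = "character", agent = "character",
    color = "character", bin = "integer", box = "integer",
    target_x = "double", visibility = "character", voiceover = "logical"
  ))
  responses <- if (!is.null(raw$responses)) {
    retype(as_tibble(raw$responses), list(
      trial_index = "integer", click_x = "double", click_y = "double",
      chosen_box = "integer", response_time_s = "double"
    ))
  } else NULL
  x <- structure(
    list(schema = raw$schema, metadata = raw$metadata,
         trials = trials, responses = responses),
    class = "session_file"
  )
  validate_session(x)
  x
}

#' Export scored records as tidy CSV
#'
#' Writes one row per subject x day x trial, deterministically ordered
#' by subject, day and trial index, UTF-8 encoded, with full numeric
#' precision (values survive a CSV round trip).
#'
#' @param data Scored response tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_tidy <- function(data, path) {
  ord <- intersect(c("subject_id", "day", "trial_index"), names(data))
  data <- dplyr::arrange(data, dplyr::across(dplyr::all_of(ord)))
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
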