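#' Click imprecision in target widths
#'
#' The continuous (hedge) outcome: the absolute horizontal distance
#' between the target center and the click, scaled by the target width.
#' An imprecision of 1 means the click was, on average, one target width
#' to the left or right of the true target center.
#'
#' @param click_x,target_x Click and target-center x-coordinates
#'   (viewport units); vectorized.
#' @param target_width Target width in the same units (> 0).
#' @return Non-negative imprecision values.
#' @examples
#' imprecision(0.55, 0.50, 0.05) # exactly one target width off
#' @export
imprecision <- function(click_x, target_x, target_width) {
  if (any(target_width <= 0)) abort("`target_width` must be positive.")
  abs(click_x - target_x) / target_width
}

#' Chance level of the box version
#'
#' With `k` equally likely boxes, a cue-blind responder is correct with
#' probability `1 / k`: 20% for the five-box child design, 12.5% for the
#' eight-box adult design.
#'
#' @param n_boxes Number of boxes (>= 1); vectorized.
#' @return Chance proportion correct.
#' @examples
#' chance_level(c(5, 8))
#' @export
chance_level <- function(n_boxes) {
  if (any(n_boxes < 1)) abort("`n_boxes` must be at least 1.")
  1 / n_boxes
}

#' Proportion of correct box choices
#'
#' The discrete (box) outcome: how often the chosen box contained the
#' target, aggregated by the given grouping (per subject by default).
#'
#' @param records Scored box-version records with a `correct` column (see
#'   [score_responses()]), or raw records with `chosen_box` and `box`.
#' @param ... Grouping columns (tidy-select), default `subject_id`.
#' @return A tibble with the grouping columns and `proportion_correct`.
#' @export
proportion_correct <- function(records, ...) {
  if (!"correct" %in% names(records)) {
    if (!all(c("chosen_box", "box") %in% names(records))) {
      abort("Need a `correct` column or `chosen_box` and `box` columns.")
    }
    records <- dplyr::mutate(records,
                             correct = as.integer(.data$chosen_box == .data$box))
  }
  groups <- rlang::enquos(...)
  if (length(groups) == 0) groups <- rlang::quos(.data$subject_id)
  records |>
    dplyr::filter(!is.na(.data$correct)) |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(proportion_correct = mean(.data$correct),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Score response records
#'
#' Derives the version-appropriate `performance` column: imprecision in
#' target widths for hedge-version records (from `click_x`), a 0/1
#' `correct` indicator for box-version records (from `chosen_box`).
#' Rows with a missing response are dropped, as are voice-over trials
#' when `drop_voiceover = TRUE` (the convention of the published
#' analyses, which include all test trials without voice-over
#' descriptions).
#'
#' @param records A response tibble, e.g. from [simulate_cohort()] or
#'   [read_session()] + bookkeeping. Must carry a `version` column.
#' @param drop_voiceover Drop trials flagged `voiceover` before scoring?
#' @return The records with `performance` (and `correct` for box
#'   records), one row per scoreable response.
#' @export
score_responses <- function(records, drop_voiceover = FALSE) {
  if (!"version" %in% names(records)) {
    abort("`records` must carry a `version` column (\"hedge\" or \"box\").")
  }
  if (drop_voiceover && "voiceover" %in% names(records)) {
    records <- dplyr::filter(records, !.data$voiceover)
  }
  hedge <- records$version == "hedge"
  if (any(hedge)) {
    keep <- !hedge | !is.na(records$click_x)
    records <- records[keep, ]
    hedge <- records$version == "hedge"
  }
  if (any(!hedge)) {
    keep <- hedge | !is.na(records$chosen_box)
    records <- records[keep, ]
    hedge <- records$version == "hedge"
  }
  records$performance <- NA_real_
  if (any(hedge)) {
    records$performance[hedge] <- imprecision(
      records$click_x[hedge], records$target_x[hedge],
      records$target_width[hedge])
  }
  if (any(!hedge)) {
    correct <- as.integer(records$chosen_box[!hedge] == records$box[!hedge])
    records$correct <- NA_integer_
    records$correct[!hedge] <- correct
    records$performance[!hedge] <- as.numeric(correct)
  }
  records
}

#' Add analysis covariates
#'
#' Computes the trial- and subject-level covariates entering the
#' developmental models: `symmetric_position`, the absolute distance of
#' the target center from the horizontal screen center (smaller = more
#' central target, easier trial); `age_z`, age in months z-scored over
#' the analysis sample's subjects; and `trial_z`, the z-scored 0-based
#' trial index. The age mean/SD used for the transform are attached as
#' attributes `age_center` / `age_scale` so fits are reproducible.
#'
#' @param records A response tibble with `target_x`, `age_months` and
#'   `trial_index` columns.
#' @return The records with `symmetric_position`, `age_z` and `trial_z`
#'   columns added.
#' @examples
#' add_covariates(tibble::tibble(
#'   subject_id = c("a", "b"), target_x = c(0.5, 0.9),
#'   age_months = c(40, 60), trial_index = 0:1
#' ))
#' @export
add_covariates <- function(records) {
  stopifnot(all(c("target_x", "age_months", "trial_index") %in% names(records)))
  subj_ages <- records |>
    dplyr::distinct(.data$subject_id, .data$age_months)
  center <- mean(subj_ages$age_months)
  scale_ <- sd(subj_ages$age_months)
  if (!is.finite(scale_) || scale_ == 0) scale_ <- 1
  out <- records |>
    dplyr::mutate(
      symmetric_position = abs(.data$target_x - 0.5),
      age_z = (.data$age_months - center) / scale_,
      trial_z = if (sd(.data$trial_index) > 0) {
        (.data$trial_index - mean(.data$trial_index)) / sd(.data$trial_index)
      } else 0
    )
  attr(out, "age_center") <- center
  attr(out, "age_scale") <- scale_
  out
}
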