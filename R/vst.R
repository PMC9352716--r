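#' Score the Virtual Supermarket Test
#'
#' The VST shows 14 first-person videos of a trolley moving through a virtual
#' supermarket; after each trial the participant answers three questions:
#' the direction of the start location relative to the destination
#' (egocentric), the destination's position on a blank map (allocentric), and
#' the direction they were facing at the end (heading). This function turns
#' one participant's per-trial responses into the three component scores.
#'
#' Allocentric answers are 2-D points in normalized map units
#' (`[0,1] x [0,1]`); the displacement from the true location is expressed as
#' a percentage of map size. By default the normalizer is the map diagonal,
#' so 100 is the largest possible error; `normalizer = "width"` divides by
#' the map width instead.
#'
#' @param responses data frame with one row per trial and columns `trial_id`,
#'   `ego_choice`, `ego_truth`, `allo_x`, `allo_y`, `allo_truth_x`,
#'   `allo_truth_y`, `head_choice`, `head_truth`.
#' @param map_width,map_height physical map dimensions (any positive unit).
#' @param normalizer `"diagonal"` (default) or `"width"`.
#' @return object of class `vst_score`: list with `egocentric_pct`,
#'   `allocentric_displacement_pct`, `heading_pct`, `n_trials_scored`.
#' @examples
#' resp <- gen_vst_responses(p_ego = 1, disp_sigma = 0, p_head = 0.5, seed = 1)
#' score_vst(resp)
#' @export
score_vst <- function(responses, map_width = 1, map_height = 1,
                      normalizer = c("diagonal", "width")) {
  normalizer <- match.arg(normalizer)
  if (is.null(responses) || nrow(responses) == 0) stop_navdis("no trials")
  stopifnot(map_width > 0, map_height > 0)
  req <- c("trial_id", "ego_choice", "ego_truth", "allo_x", "allo_y",
           "allo_truth_x", "allo_truth_y", "head_choice", "head_truth")
  miss <- setdiff(req, names(responses))
  if (length(miss)) stop_navdis("missing VST columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(responses$trial_id)) {
    stop_navdis("duplicate trial_id: %s",
                paste(unique(responses$trial_id[duplicated(responses$trial_id)]),
                      collapse = ", "))
  }
  coords <- c("allo_x", "allo_y", "allo_truth_x", "allo_truth_y")
  for (cc in coords) {
    bad <- which(responses[[cc]] < 0 | responses[[cc]] > 1)
    if (length(bad)) {
      stop_navdis("coordinate %s outside unit map in trial %s",
                  cc, paste(responses$trial_id[bad], collapse = ", "))
    }
  }
  n <- nrow(responses)
  dx <- (responses$allo_x - responses$allo_truth_x) * map_width
  dy <- (responses$allo_y - responses$allo_truth_y) * map_height
  dist <- sqrt(dx^2 + dy^2)
  norm <- switch(normalizer,
                 diagonal = sqrt(map_width^2 + map_height^2),
                 width = map_width)
  out <- list(
    egocentric_pct = 100 * mean(responses$ego_choice == responses$ego_truth),
    allocentric_displacement_pct = 100 * mean(dist / norm),
    heading_pct = 100 * mean(responses$head_choice == responses$head_truth),
    n_trials_scored = n
  )
  class(out) <- "vst_score"
  out
}

#' @export
print.vst_score <- function(x, ...) {
  cat(sprintf(
    "VST score (%d trials): egocentric %.1f%% | allocentric displacement %.2f%% of map | heading %.1f%%\n",
    x$n_trials_scored, x$egocentric_pct, x$allocentric_displacement_pct,
    x$heading_pct))
  invisible(x)
}

#' Read per-trial VST responses from CSV
#'
#' One row per `(participant_id, trial_id)`; the remaining columns follow
#' [score_vst()]'s contract.
#'
#' @param path CSV file path.
#' @return tibble of responses (all participants).
#' @export
read_vst_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "trial_id", "ego_choice", "ego_truth", "allo_x",
           "allo_y", "allo_truth_x", "allo_truth_y", "head_choice", "head_truth")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_navdis("file %s: missing column %s", path, paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Score all participants in a VST response table
#'
#' @param responses tibble as returned by [read_vst_csv()].
#' @inheritParams score_vst
#' @return tibble with one row per participant and the three component scores.
#' @export
score_vst_table <- function(responses, map_width = 1, map_height = 1,
                            normalizer = "diagonal") {
  ids <- sort(unique(responses$participant_id))
  rows <- lapply(ids, function(id) {
    s <- score_vst(responses[responses$participant_id == id, , drop = FALSE],
                   map_width, map_height, normalizer)
    tibble::tibble(participant_id = id,
                   ego_pct = s$egocentric_pct,
                   allo_disp_pct = s$allocentric_displacement_pct,
                   head_pct = s$heading_pct,
                   n_trials_scored = s$n_trials_scored)
  })
  dplyr::bind_rows(rows)
}
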