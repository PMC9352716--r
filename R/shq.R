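#' Sea Hero Quest wayfinding scores
#'
#' Wayfinding levels show a map with numbered checkpoints, then require the
#' player to steer a boat to them from memory. The two raw outcomes are the
#' total distance travelled and the level duration; both are normalized by
#' per-level reference constants so that higher values mean worse
#' performance. Reference constants default to 1 (raw values pass through),
#' which leaves every scale-invariant downstream comparison unchanged.
#'
#' @param distance_travelled path length for the level; `>= 0`.
#' @param duration_s level duration in seconds; `>= 0`.
#' @param reference_distance,reference_duration positive per-level reference
#'   constants (config keys `shq.reference_distance`, `shq.reference_duration`).
#' @param checkpoints_visited,expected_checkpoints checkpoint counts; an
#'   incomplete level cannot be scored and should be handled with
#'   [impute_worst()].
#' @return named numeric vector `c(wf_distance_score, wf_duration_score)`.
#' @export
shq_wayfinding_scores <- function(distance_travelled, duration_s,
                                  reference_distance = 1,
                                  reference_duration = 1,
                                  checkpoints_visited = expected_checkpoints,
                                  expected_checkpoints = 3) {
  stopifnot(reference_distance > 0, reference_duration > 0,
            distance_travelled >= 0, duration_s >= 0)
  if (checkpoints_visited < expected_checkpoints) {
    stop_navdis(paste0(
      "incomplete wayfinding level (%d of %d checkpoints); ",
      "use impute_worst() to assign a score"),
      checkpoints_visited, expected_checkpoints)
  }
  c(wf_distance_score = distance_travelled / reference_distance,
    wf_duration_score = duration_s / reference_duration)
}

#' Turn-weighted flare accuracy
#'
#' Flare levels ask the player to shoot a flare back toward the start after a
#' series of turns; the answer earns 1-3 stars. Each level's stars are
#' weighted by its number of turns (levels 9/14/19 have one 90-degree turn,
#' level 49 has four), so the score is `sum(stars * turns) / sum(turns)`.
#'
#' @param results data frame with columns `level_id`, `stars` (integer 1-3)
#'   and `n_turns` (integer >= 1).
#' @return weighted mean stars, in `[1, 3]`.
#' @examples
#' flare_accuracy(data.frame(level_id = c(9, 14, 19, 49),
#'                           stars = c(3, 2, 1, 2),
#'                           n_turns = c(1, 1, 1, 4)))  # 2
#' @export
flare_accuracy <- function(results) {
  stopifnot(nrow(results) >= 1)
  if (anyDuplicated(results$level_id)) {
    stop_navdis("duplicate flare level_id: %s",
                paste(unique(results$level_id[duplicated(results$level_id)]),
                      collapse = ", "))
  }
  if (any(!results$stars %in% 1:3)) stop_navdis("stars must be 1, 2 or 3")
  if (any(results$n_turns < 1 | results$n_turns != round(results$n_turns))) {
    stop_navdis("n_turns must be a positive integer")
  }
  sum(results$stars * results$n_turns) / sum(results$n_turns)
}

#' Worst-score imputation for non-completers
#'
#' Participants who never attempted a level receive the worst (largest,
#' scores being oriented so that larger = worse) score observed among those
#' who did, so they can enter regression models without inventing data more
#' favourable than any observation.
#'
#' @param observed named numeric vector of observed scores (names are
#'   participant ids).
#' @param missing character vector of participant ids to impute.
#' @return named numeric vector covering observed and imputed participants,
#'   with a logical attribute `imputed` marking the assigned entries.
#' @export
impute_worst <- function(observed, missing = character()) {
  stopifnot(length(observed) >= 1, !is.null(names(observed)))
  if (any(is.na(observed))) stop_navdis("observed scores contain NA")
  overlap <- intersect(names(observed), missing)
  if (length(overlap)) {
    stop_navdis("participants both observed and missing: %s",
                paste(overlap, collapse = ", "))
  }
  worst <- max(observed)
  out <- c(observed, setNames(rep(worst, length(missing)), missing))
  attr(out, "imputed") <- setNames(c(rep(FALSE, length(observed)),
                                     rep(TRUE, length(missing))), names(out))
  out
}

#' Read per-level SHQ results from CSV
#'
#' One row per `(participant_id, level_id, level_type)` with columns
#' `distance`, `duration_s`, `map_view_s`, `checkpoints`, `stars`, `n_turns`
#' (fields not applicable to the level type left empty).
#'
#' @param path CSV file path.
#' @return tibble of level results.
#' @export
read_shq_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "level_id", "level_type", "distance",
           "duration_s", "map_view_s", "checkpoints", "stars", "n_turns")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_navdis("file %s: missing column %s", path, paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Score SHQ level results for all participants
#'
#' Wayfinding scores come from level 6 only (the one level administered to
#' the whole cohort); other wayfinding levels are parsed but ignored. Flare
#' accuracy pools all flare levels with turn weighting. Participants without
#' a level-6 row get `NA` wayfinding scores, to be imputed at the regression
#' stage.
#'
#' @param shq tibble from [read_shq_csv()].
#' @param reference_distance,reference_duration per-level normalization
#'   constants for level 6.
#' @return tibble: `participant_id`, `wf_distance`, `wf_duration`,
#'   `map_view_s`, `flare_accuracy`.
#' @export
score_shq_table <- function(shq, reference_distance = 1, reference_duration = 1) {
  ids <- sort(unique(shq$participant_id))
  rows <- lapply(ids, function(id) {
    sub <- shq[shq$participant_id == id, , drop = FALSE]
    wf <- sub[sub$level_type == "wayfinding" & sub$level_id == 6, , drop = FALSE]
    if (nrow(wf) == 1 && !is.na(wf$distance)) {
      sc <- shq_wayfinding_scores(wf$distance, wf$duration_s,
                                  reference_distance, reference_duration,
                                  checkpoints_visited = wf$checkpoints)
      wfd <- sc[["wf_distance_score"]]; wfu <- sc[["wf_duration_score"]]
      mv <- wf$map_view_s
    } else {
      wfd <- NA_real_; wfu <- NA_real_; mv <- NA_real_
    }
    fl <- sub[sub$level_type == "flare", , drop = FALSE]
    fa <- if (nrow(fl)) flare_accuracy(fl) else NA_real_
    tibble::tibble(participant_id = id, wf_distance = wfd, wf_duration = wfu,
                   map_view_s = mv, flare_accuracy = fa)
  })
  dplyr::bind_rows(rows)
}
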