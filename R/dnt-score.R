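#' Detect wrong turns along a recorded walk
#'
#' A wrong turn is a movement at an intersection onto an edge that is
#' neither part of a viable route (the experimenter's map marking) nor an
#' exempted overlap with the original route (e.g. the only exit of a
#' cul-de-sac). Two consecutive wrong turns trigger a reset: the walker is
#' brought back to the intersection where the first of the two was made, and
#' subsequent moves are evaluated from there. In a recorded node sequence the
#' reset appears as a teleport back to that intersection, which this function
#' validates. An immediate backtrack along the edge just taken (the walker
#' correcting themselves) is never flagged as a new wrong turn.
#'
#' @param taken_path character vector of node ids actually walked.
#' @param graph a [street_graph()].
#' @param viable_paths list of node sequences marked viable on the map (the
#'   planned route and any acceptable alternatives).
#' @param allowed_overlap character vector of exempted edge keys (see
#'   [edge_keys()]), e.g. original-route edges that must be reused.
#' @return list with `events` (tibble: `kind`, `node_id`,
#'   `consecutive_index`) and `resets` (tibble: `at_node`, `resume_node`).
#' @export
detect_wrong_turns <- function(taken_path, graph, viable_paths,
                               allowed_overlap = character()) {
  stopifnot(length(taken_path) >= 1)
  gkeys <- graph_edge_keys(graph)
  viable <- unique(c(unlist(lapply(viable_paths, path_edge_keys)),
                     allowed_overlap))
  is_int <- setNames(graph$nodes$intersection, graph$nodes$id)
  unknown <- setdiff(taken_path, graph$nodes$id)
  if (length(unknown)) stop_navdis("walk visits unknown node: %s",
                                   paste(unknown, collapse = ", "))

  events <- list(); resets <- list()
  consec <- 0L
  reset_to <- NA_character_   # pending teleport target after a double error
  first_wrong_at <- NA_character_
  prev_key <- NA_character_
  for (s in seq_len(length(taken_path) - 1L)) {
    u <- taken_path[s]; v <- taken_path[s + 1L]
    if (!is.na(reset_to)) {
      if (!identical(v, reset_to)) {
        stop_navdis("step %d: walk does not resume from reset location %s", s, reset_to)
      }
      reset_to <- NA_character_
      prev_key <- NA_character_  # teleport, no edge traversed
      next
    }
    key <- edge_key(u, v)
    if (!key %in% gkeys) stop_navdis("step %d: edge %s absent from graph", s, key)
    backtrack <- identical(key, prev_key)
    if (isTRUE(is_int[[u]]) && !backtrack && !key %in% viable) {
      consec <- consec + 1L
      if (consec == 1L) first_wrong_at <- u
      events[[length(events) + 1L]] <- tibble::tibble(
        kind = "wrong_turn", node_id = u, consecutive_index = consec)
      if (consec == 2L) {
        resets[[length(resets) + 1L]] <- tibble::tibble(
          at_node = v, resume_node = first_wrong_at)
        reset_to <- first_wrong_at
        consec <- 0L
        first_wrong_at <- NA_character_
      }
    } else if (isTRUE(is_int[[u]]) && !backtrack) {
      consec <- 0L
      first_wrong_at <- NA_character_
    }
    prev_key <- key
  }
  list(events = if (length(events)) dplyr::bind_rows(events) else
         tibble::tibble(kind = character(), node_id = character(),
                        consecutive_index = integer()),
       resets = if (length(resets)) dplyr::bind_rows(resets) else
         tibble::tibble(at_node = character(), resume_node = character()))
}

#' Edge keys of a node path
#'
#' Canonical undirected edge identifiers (`"a|b"`, sorted endpoints) for use
#' in `allowed_overlap` sets.
#' @param path character vector of node ids.
#' @export
edge_keys <- function(path) path_edge_keys(path)

#' Per-route disorientation score
#'
#' Event counts are normalized by the route's opportunity structure: wrong
#' turns per intersection plus hesitations per km (`mode = "split"`, the
#' default, consistent with the published component rows summing to the
#' route score). `mode = "combined"` instead divides the total event count
#' by (distance x intersections).
#'
#' @param n_wrong_turns,n_hesitations non-negative event counts.
#' @param n_intersections number of decision points on the route (>= 1).
#' @param distance_km total route distance (> 0).
#' @param mode `"split"` or `"combined"` (config key `dnt.normalization`).
#' @return non-negative score; 0 iff both counts are 0.
#' @examples
#' route_disorientation_score(1, 2, 10, 2)  # 0.1 + 1.0 = 1.1
#' @export
route_disorientation_score <- function(n_wrong_turns, n_hesitations,
                                       n_intersections, distance_km,
                                       mode = c("split", "combined")) {
  mode <- match.arg(mode)
  if (n_wrong_turns < 0 || n_hesitations < 0) stop_navdis("negative event count")
  stopifnot(n_intersections >= 1, distance_km > 0)
  switch(mode,
         split = n_wrong_turns / n_intersections + n_hesitations / distance_km,
         combined = (n_wrong_turns + n_hesitations) / (distance_km * n_intersections))
}

#' Composite disorientation score
#'
#' Ratio of detour to original route disorientation with a +1 continuity
#' correction on both terms (so a disorientation-free original route does not
#' divide by zero): `(detour + 1) / (original + 1)`. A value of 1 means no
#' differential disorientation; > 1 means more disorientation on the detour.
#'
#' @param detour_score,original_score non-negative route disorientation scores.
#' @export
composite_score <- function(detour_score, original_score) {
  if (detour_score < 0 || original_score < 0) {
    stop_navdis("route disorientation scores must be >= 0")
  }
  (detour_score + 1) / (original_score + 1)
}

#' Dichotomize composite disorientation into risk groups
#'
#' Any departure of the composite score from 1 (beyond numerical tolerance;
#' the inputs are exact rationals of event counts) marks the participant as
#' high risk for community spatial disorientation.
#'
#' @param composite composite disorientation score (> 0).
#' @param tolerance numerical tolerance around 1 (config key
#'   `dnt.risk_tolerance`).
#' @return `"high"` or `"low"`.
#' @export
classify_risk <- function(composite, tolerance = 1e-9) {
  stopifnot(composite > 0, tolerance >= 0)
  if (abs(composite - 1) > tolerance) "high" else "low"
}

#' Score a pair of DNT walks
#'
#' Runs wrong-turn detection on the original and detour walks, counts
#' hesitation events, normalizes per route, and assembles the composite
#' score and risk label.
#'
#' @param original,detour walk objects: lists with `taken_path`, `events`
#'   (tibble with a `kind` column; hesitations counted from it),
#'   `planned_path`, `total_distance_km`, `n_intersections`, and optionally
#'   `viable_paths` / `allowed_overlap` for detection.
#' @param graph a [street_graph()].
#' @param mode normalization mode, see [route_disorientation_score()].
#' @param risk_tolerance see [classify_risk()].
#' @return object of class `dnt_score`: per-route normalized components and
#'   scores, `composite`, `risk`.
#' @export
score_dnt_walks <- function(original, detour, graph, mode = "split",
                            risk_tolerance = 1e-9) {
  one <- function(walk) {
    det <- detect_wrong_turns(walk$taken_path, graph,
                              viable_paths = walk$viable_paths %||% list(walk$planned_path),
                              allowed_overlap = walk$allowed_overlap %||% character())
    n_wt <- nrow(det$events)
    n_hes <- sum(walk$events$kind == "hesitation")
    list(n_wt = n_wt, n_hes = n_hes,
         wt_norm = n_wt / walk$n_intersections,
         hes_norm = n_hes / walk$total_distance_km,
         score = route_disorientation_score(n_wt, n_hes, walk$n_intersections,
                                            walk$total_distance_km, mode))
  }
  o <- one(original); d <- one(detour)
  comp <- composite_score(d$score, o$score)
  out <- list(
    original_wrong_turns = o$n_wt, original_hesitations = o$n_hes,
    original_wrong_turns_norm = o$wt_norm, original_hesitations_norm = o$hes_norm,
    original_score = o$score,
    detour_wrong_turns = d$n_wt, detour_hesitations = d$n_hes,
    detour_wrong_turns_norm = d$wt_norm, detour_hesitations_norm = d$hes_norm,
    detour_score = d$score,
    composite = comp, risk = classify_risk(comp, risk_tolerance))
  class(out) <- "dnt_score"
  out
}

#' @export
print.dnt_score <- function(x, ...) {
  cat(sprintf("DNT: original score %.3f | detour score %.3f | composite %.3f (%s risk)\n",
              x$original_score, x$detour_score, x$composite, x$risk))
  invisible(x)
}

#' Read a DNT event log from CSV
#'
#' One row per event: `participant_id`, `route_type` (original/detour),
#' `kind` (wrong_turn/hesitation), `node_id`, `timestamp`.
#' @param path CSV file path.
#' @export
read_dnt_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "route_type", "kind", "node_id", "timestamp")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_navdis("file %s: missing column %s", path, paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df)
}
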