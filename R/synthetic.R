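#' Parameters for a synthetic two-group cohort
#'
#' Defaults reproduce the reference study's conditions: 21 controls and 16
#' patients whose score distributions match the published group means/SDs
#' (see [reference_cohort_stats()]), two patients missing the wayfinding
#' level and one missing the detour route. Score variables are drawn from
#' truncated normals whose *truncated* mean equals the target mean exactly
#' and whose SD is matched where the family allows (see [fit_truncnorm()]).
#'
#' An optional Gaussian copula couples the two wayfinding scores with the
#' detour disorientation score (default correlation 0.55, the square root of
#' the reported R-squared between wayfinding distance and the composite
#' score; the true joint structure is unobserved, so this is an assumption).
#'
#' @param n_controls,n_patients group sizes.
#' @param seed integer seed; one global seed fans out into per-participant
#'   substreams so adding a participant never perturbs earlier draws.
#' @param variables tibble in the format of [reference_cohort_stats()].
#' @param copula_rho correlation coupling wayfinding scores to the detour
#'   score (0 disables the copula).
#' @param n_missing_wayfinding patients without the wayfinding level.
#' @param n_missing_detour patients without a detour walk.
#' @param zero_inflation named list: for zero-inflated variables (the DNT
#'   route scores, which are exact zeros for most participants), the
#'   per-group probability of an exact zero. The non-zero component is
#'   moment-matched so the *mixture* mean still equals the target mean.
#'   Defaults reproduce the reference study's split (all controls and 15/16
#'   patients free of original-route disorientation; 20/21 controls and 8/15
#'   patients free of detour disorientation, the published low-risk group).
#' @return validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_controls = 21, n_patients = 16, seed = 1,
                          variables = reference_cohort_stats(),
                          copula_rho = 0.55,
                          n_missing_wayfinding = 2, n_missing_detour = 1,
                          zero_inflation = list(
                            original_score = c(control = 1, patient = 15 / 16),
                            detour_score = c(control = 20 / 21, patient = 8 / 15))) {
  stopifnot(n_controls >= 1, n_patients >= 1,
            copula_rho >= 0, copula_rho < 1,
            n_missing_wayfinding <= n_patients,
            n_missing_detour <= n_patients)
  for (zi in zero_inflation) stopifnot(all(zi >= 0), all(zi <= 1))
  req <- c("variable", "controls_mean", "controls_sd", "patients_mean",
           "patients_sd", "lower", "upper")
  stopifnot(all(req %in% names(variables)))
  if (any(variables$controls_sd < 0 | variables$patients_sd < 0)) {
    stop_navdis("negative SD in variable parameters")
  }
  for (g in c("controls", "patients")) {
    m <- variables[[paste0(g, "_mean")]]; s <- variables[[paste0(g, "_sd")]]
    infeasible <- variables$lower > m + 6 * s | variables$upper < m - 6 * s
    if (any(infeasible)) {
      stop_navdis("infeasible truncation for %s: bounds exclude mean +/- 6 sd",
                  paste(variables$variable[infeasible], collapse = ", "))
    }
  }
  out <- list(n_controls = n_controls, n_patients = n_patients, seed = seed,
              variables = variables, copula_rho = copula_rho,
              n_missing_wayfinding = n_missing_wayfinding,
              n_missing_detour = n_missing_detour,
              zero_inflation = zero_inflation)
  class(out) <- "cohort_params"
  out
}

# fit truncated-normal generators for every variable x group; zero-inflated
# variables fit the non-zero component to the conditional moments implied by
# the target mixture moments, so the mixture mean is preserved exactly
cohort_generator_fits <- function(params) {
  v <- params$variables
  rows <- list()
  for (g in c("control", "patient")) {
    pre <- if (g == "control") "controls" else "patients"
    for (i in seq_len(nrow(v))) {
      tm <- v[[paste0(pre, "_mean")]][i]; ts <- v[[paste0(pre, "_sd")]][i]
      lo <- v$lower[i]; hi <- v$upper[i]
      p0 <- params$zero_inflation[[v$variable[i]]][[g]] %||% 0
      if (is.na(p0)) p0 <- 0
      fm <- tm; fs <- ts
      if (p0 > 0 && p0 < 1) {
        fm <- tm / (1 - p0)
        cvar <- (tm^2 + ts^2) / (1 - p0) - fm^2
        fs <- sqrt(max(cvar, 0))
      }
      if (p0 >= 1 || fs == 0 || fm <= lo) {
        fit <- list(mu = max(fm, lo), sigma = 0, mean = max(fm, lo), sd = 0,
                    sd_matched = ts == 0)
      } else {
        fit <- fit_truncnorm(fm, fs, lo, hi)
      }
      mix_mean <- if (p0 >= 1) 0 else (1 - p0) * fit$mean
      mix_sd <- if (p0 >= 1) 0 else
        sqrt(max((1 - p0) * (fit$sd^2 + fit$mean^2) - mix_mean^2, 0))
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v$variable[i], group = g, target_mean = tm, target_sd = ts,
        lower = lo, upper = hi, p_zero = p0, mu = fit$mu, sigma = fit$sigma,
        gen_mean = mix_mean, gen_sd = mix_sd,
        sd_matched = abs(mix_sd - ts) <= 0.01 * max(ts, 1e-12))
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic cohort score table
#'
#' Draws one row per participant with truncated-normal scores per variable,
#' computes each participant's composite disorientation score
#' (`(detour + 1) / (original + 1)`) and risk label, and applies the
#' configured missingness (wayfinding non-attempters, detour non-completer).
#' Deterministic given `params$seed`; each participant has an independent
#' substream.
#'
#' @param params a [cohort_params()] object.
#' @return tibble with `participant_id`, `group` (factor control/patient),
#'   one column per variable, `composite`, `risk`. The truncated-normal fits
#'   actually used are attached as attribute `"generator"`.
#' @export
gen_cohort_scores <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  fits <- cohort_generator_fits(params)
  vars <- params$variables$variable
  coupled <- intersect(c("wf_distance", "wf_duration", "detour_score"), vars)
  use_copula <- params$copula_rho > 0 && length(coupled) == 3
  if (use_copula) {
    rho <- params$copula_rho
    R <- matrix(c(1, 0.8, rho,
                  0.8, 1, rho,
                  rho, rho, 1), 3, 3,
                dimnames = list(coupled, coupled))
    L <- chol(R)
  }

  # per-group substream seeds: growing one group never perturbs the other,
  # nor earlier participants of the same group
  set.seed(params$seed);     ctrl_seeds <- sample.int(2^31 - 2, params$n_controls)
  set.seed(params$seed + 1); pat_seeds  <- sample.int(2^31 - 2, params$n_patients)

  fit_lookup <- split(fits, paste(fits$group, fits$variable, sep = "."))
  draw_participant <- function(sub_seed, group) {
    set.seed(sub_seed)
    z <- setNames(rnorm(length(vars)), vars)
    if (use_copula) z[coupled] <- as.numeric(crossprod(L, z[coupled]))
    vals <- vapply(vars, function(v) {
      f <- fit_lookup[[paste(group, v, sep = ".")]]
      u <- pnorm(z[[v]])
      if (f$p_zero >= 1 || u < f$p_zero) return(0)
      u <- (u - f$p_zero) / (1 - f$p_zero)  # conditional quantile, rank-preserving
      if (f$sigma == 0) return(f$mu)
      qtnorm(u, f$mu, f$sigma, f$lower, f$upper)
    }, numeric(1))
    vals
  }

  ctrl_mat <- t(vapply(seq_len(params$n_controls), function(i) {
    draw_participant(ctrl_seeds[i], "control")
  }, numeric(length(vars))))
  pat_mat <- t(vapply(seq_len(params$n_patients), function(i) {
    draw_participant(pat_seeds[i], "patient")
  }, numeric(length(vars))))
  cohort <- tibble::as_tibble(rbind(ctrl_mat, pat_mat))
  names(cohort) <- vars
  cohort <- tibble::add_column(
    cohort,
    participant_id = c(sprintf("C%02d", seq_len(params$n_controls)),
                       sprintf("P%02d", seq_len(params$n_patients))),
    group = factor(rep(c("control", "patient"),
                       c(params$n_controls, params$n_patients)),
                   levels = c("control", "patient")),
    .before = 1)

  # missingness (patients only), drawn from a dedicated substream
  set.seed(params$seed + 2)
  pats <- which(cohort$group == "patient")
  if (params$n_missing_wayfinding > 0) {
    miss_wf <- pats[sample.int(length(pats), params$n_missing_wayfinding)]
    cohort[miss_wf, intersect(c("wf_distance", "wf_duration", "map_view_s"),
                              names(cohort))] <- NA_real_
  }
  if (params$n_missing_detour > 0 && "detour_score" %in% names(cohort)) {
    miss_det <- pats[sample.int(length(pats), params$n_missing_detour)]
    cohort[miss_det, "detour_score"] <- NA_real_
  }

  if (all(c("original_score", "detour_score") %in% names(cohort))) {
    cohort$composite <- ifelse(
      is.na(cohort$detour_score) | is.na(cohort$original_score), NA_real_,
      (cohort$detour_score + 1) / (cohort$original_score + 1))
    cohort$risk <- vapply(cohort$composite, function(cmp) {
      if (is.na(cmp)) NA_character_ else classify_risk(cmp)
    }, character(1))
  }
  attr(cohort, "generator") <- fits
  cohort
}

#' Simulate one participant's VST trial responses
#'
#' Each trial's categorical answers are correct with the stated
#' probabilities; the allocentric map answer is the true location plus
#' isotropic Gaussian noise (SD `disp_sigma`, normalized map units), clipped
#' to the unit map.
#'
#' @param p_ego,p_head probabilities of a correct egocentric / heading answer.
#' @param disp_sigma allocentric noise SD in normalized map units (>= 0).
#' @param n_trials number of trials (1-14).
#' @param seed integer seed.
#' @return tibble of trial responses in [score_vst()] format.
#' @export
gen_vst_responses <- function(p_ego, disp_sigma, p_head, n_trials = 14, seed = 1) {
  stopifnot(p_ego >= 0, p_ego <= 1, p_head >= 0, p_head <= 1,
            disp_sigma >= 0, n_trials >= 1, n_trials <= 14)
  dirs <- c("front", "back", "left", "right")
  set.seed(seed)
  pick <- function(p, truth) {
    ok <- runif(length(truth)) < p
    wrong <- vapply(truth, function(tr) sample(setdiff(dirs, tr), 1), character(1))
    ifelse(ok, truth, wrong)
  }
  ego_truth <- sample(dirs, n_trials, replace = TRUE)
  head_truth <- sample(dirs, n_trials, replace = TRUE)
  tx <- runif(n_trials, 0.1, 0.9); ty <- runif(n_trials, 0.1, 0.9)
  tibble::tibble(
    trial_id = seq_len(n_trials),
    ego_choice = pick(p_ego, ego_truth), ego_truth = ego_truth,
    allo_x = pmin(pmax(tx + rnorm(n_trials, 0, disp_sigma), 0), 1),
    allo_y = pmin(pmax(ty + rnorm(n_trials, 0, disp_sigma), 0), 1),
    allo_truth_x = tx, allo_truth_y = ty,
    head_choice = pick(p_head, head_truth), head_truth = head_truth)
}

#' Event-rate profile for simulated DNT walks
#'
#' @param p_wrong_turn probability of deviating at each intersection.
#' @param hesitation_rate expected hesitations per km.
#' @export
walk_profile <- function(p_wrong_turn = 0, hesitation_rate = 0) {
  stopifnot(p_wrong_turn >= 0, p_wrong_turn <= 1, hesitation_rate >= 0)
  structure(list(p_wrong_turn = p_wrong_turn, hesitation_rate = hesitation_rate),
            class = "walk_profile")
}

# route pair on a graph: original = shortest path between the two most
# distant nodes (or given endpoints), detour = shortest path avoiding every
# original edge
plan_route_pair <- function(graph, origin = NULL, destination = NULL) {
  ig <- as_igraph(graph)
  if (is.null(origin) || is.null(destination)) {
    d <- igraph::distances(ig)
    far <- which(d == max(d), arr.ind = TRUE)[1, ]
    origin <- rownames(d)[far[1]]; destination <- colnames(d)[far[2]]
  }
  orig <- names(igraph::shortest_paths(ig, origin, destination)$vpath[[1]])
  keys <- path_edge_keys(orig)
  keep <- !graph_edge_keys(graph) %in% keys
  sub_edges <- graph$edges[keep, , drop = FALSE]
  ig2 <- igraph::graph_from_data_frame(
    cbind(sub_edges[, c("from", "to")], weight = sub_edges$length_km),
    directed = FALSE, vertices = graph$nodes$id)
  sp <- suppressWarnings(igraph::shortest_paths(ig2, destination, origin))
  det <- names(sp$vpath[[1]])
  if (length(det) < 2) {
    stop_navdis("no valid detour: removing the original route disconnects %s from %s",
                destination, origin)
  }
  list(original = orig, detour = det)
}

#' Simulate an original/detour walk pair with planted events
#'
#' Walks each planned route, deviating at intersections with probability
#' `p_wrong_turn` (onto a uniformly chosen non-viable edge, self-correcting
#' after one wrong turn, or resetting after two consecutive ones) and
#' planting `Poisson(hesitation_rate x route distance)` hesitations at nodes
#' along the route. The emitted walks re-detect exactly under
#' [detect_wrong_turns()] (round-trip property).
#'
#' @param graph a [street_graph()].
#' @param profile a [walk_profile()].
#' @param seed integer seed.
#' @param origin,destination optional route endpoints (default: the two most
#'   distant nodes in the graph).
#' @return list with `original` and `detour` walk objects (fields:
#'   `route_type`, `planned_path`, `taken_path`, `events`,
#'   `total_distance_km`, `n_intersections`, `viable_paths`,
#'   `allowed_overlap`).
#' @export
gen_dnt_walks <- function(graph, profile = walk_profile(), seed = 1,
                          origin = NULL, destination = NULL) {
  stopifnot(inherits(profile, "walk_profile"))
  routes <- plan_route_pair(graph, origin, destination)
  set.seed(seed)
  is_int <- setNames(graph$nodes$intersection, graph$nodes$id)
  gkeys <- graph_edge_keys(graph)
  nbrs <- function(u) {
    unique(c(graph$edges$to[graph$edges$from == u],
             graph$edges$from[graph$edges$to == u]))
  }
  wrong_candidates <- function(u, viable, exclude = character()) {
    w <- setdiff(nbrs(u), exclude)
    w[!edge_key(u, w) %in% viable]
  }

  sim_walk <- function(planned, route_type) {
    viable <- path_edge_keys(planned)
    taken <- planned[1]
    ev <- list()
    for (i in seq_len(length(planned) - 1L)) {
      u <- planned[i]; v <- planned[i + 1L]
      if (isTRUE(is_int[[u]]) && runif(1) < profile$p_wrong_turn) {
        cand <- wrong_candidates(u, viable)
        if (length(cand)) {
          w <- if (length(cand) == 1) cand else sample(cand, 1)
          taken <- c(taken, w)
          ev[[length(ev) + 1]] <- tibble::tibble(kind = "wrong_turn",
                                                node_id = u,
                                                consecutive_index = 1L)
          cand2 <- if (isTRUE(is_int[[w]]) && runif(1) < profile$p_wrong_turn) {
            wrong_candidates(w, viable, exclude = u)
          } else character()
          if (length(cand2)) {
            z <- if (length(cand2) == 1) cand2 else sample(cand2, 1)
            taken <- c(taken, z)
            ev[[length(ev) + 1]] <- tibble::tibble(kind = "wrong_turn",
                                                  node_id = w,
                                                  consecutive_index = 2L)
            taken <- c(taken, u)      # reset: brought back to first error site
          } else {
            taken <- c(taken, u)      # self-correct: backtrack
          }
        }
      }
      taken <- c(taken, v)
    }
    dist_km <- path_length_km(graph, planned)
    n_hes <- rpois(1, profile$hesitation_rate * dist_km)
    if (n_hes > 0) {
      where <- sample(planned, n_hes, replace = TRUE)
      ev[[length(ev) + 1]] <- tibble::tibble(kind = "hesitation",
                                            node_id = where,
                                            consecutive_index = NA_integer_)
    }
    events <- if (length(ev)) dplyr::bind_rows(ev) else
      tibble::tibble(kind = character(), node_id = character(),
                     consecutive_index = integer())
    list(route_type = route_type, planned_path = planned, taken_path = taken,
         events = events, total_distance_km = dist_km,
         n_intersections = max(1L, path_intersections(graph, planned)),
         viable_paths = list(planned), allowed_overlap = character())
  }
  list(original = sim_walk(routes$original, "original"),
       detour = sim_walk(routes$detour, "detour"))
}
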