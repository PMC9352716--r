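test_that("cohort generation is deterministic and substream-stable", {
  p <- cohort_params(seed = 13)
  expect_identical(gen_cohort_scores(p), gen_cohort_scores(p))
  # adding participants never perturbs earlier draws (per-group substreams)
  small <- gen_cohort_scores(cohort_params(n_controls = 5, n_patients = 4,
                                           seed = 13, n_missing_wayfinding = 0,
                                           n_missing_detour = 0))
  big <- gen_cohort_scores(cohort_params(n_controls = 8, n_patients = 6,
                                         seed = 13, n_missing_wayfinding = 0,
                                         n_missing_detour = 0))
  vars <- setdiff(names(small), c("participant_id", "group"))
  expect_equal(as.data.frame(small[small$group == "control", vars]),
               as.data.frame(big[big$group == "control", vars][1:5, ]))
  expect_equal(as.data.frame(small[small$group == "patient", vars]),
               as.data.frame(big[big$group == "patient", vars][1:4, ]))
})

test_that("degenerate and infeasible parameter sets are handled", {
  v <- reference_cohort_stats()
  v$controls_sd[v$variable == "ego_pct"] <- 0
  co <- gen_cohort_scores(cohort_params(n_controls = 6, n_patients = 3,
                                        variables = v, seed = 1))
  expect_true(all(co$ego_pct[co$group == "control"] == 81.49))
  v2 <- reference_cohort_stats()
  v2$lower[v2$variable == "flare_accuracy"] <- 10    # excludes mean + 6 sd
  expect_error(cohort_params(variables = v2), "infeasible truncation")
})

test_that("generated group means recover the published targets", {
  co <- gen_cohort_scores(cohort_params(n_controls = 5000, n_patients = 200,
                                        seed = 3, n_missing_wayfinding = 0,
                                        n_missing_detour = 0))
  # law of large numbers at n = 5000: controls' egocentric mean near 81.49
  expect_equal(mean(co$ego_pct[co$group == "control"]), 81.49, tolerance = 1.0 / 81.49)
  # bounded variables stay inside their bounds
  expect_true(all(co$ego_pct >= 0 & co$ego_pct <= 100))
  expect_true(all(co$flare_accuracy >= 1 & co$flare_accuracy <= 3))
  expect_true(all(co$detour_score >= 0))
})

test_that("zero inflation yields both risk classes and exact composites of 1", {
  co <- gen_cohort_scores(cohort_params(n_controls = 30, n_patients = 60,
                                        seed = 5, n_missing_detour = 0,
                                        n_missing_wayfinding = 0))
  pat <- co[co$group == "patient", ]
  expect_true(all(c("high", "low") %in% pat$risk))
  # low-risk patients have exactly composite 1 (zero events on both routes)
  expect_true(all(pat$composite[pat$risk == "low"] == 1))
  # patient low-risk fraction near the published 8/15 split
  expect_equal(mean(pat$risk == "low"), 8 / 15, tolerance = 0.25)
})

test_that("the copula couples wayfinding scores to detour disorientation", {
  co <- gen_cohort_scores(cohort_params(n_controls = 5, n_patients = 800,
                                        seed = 7, n_missing_wayfinding = 0,
                                        n_missing_detour = 0))
  pat <- co[co$group == "patient", ]
  r <- cor(pat$wf_distance, pat$detour_score, method = "spearman")
  expect_gt(r, 0.3)
  co0 <- gen_cohort_scores(cohort_params(n_controls = 5, n_patients = 800,
                                         seed = 7, copula_rho = 0,
                                         n_missing_wayfinding = 0,
                                         n_missing_detour = 0))
  p0 <- co0[co0$group == "patient", ]
  expect_lt(abs(cor(p0$wf_distance, p0$detour_score, method = "spearman")), 0.12)
})

test_that("missingness mirrors the study cohort and propagates to composites", {
  co <- gen_cohort_scores(cohort_params(seed = 23))
  pat <- co[co$group == "patient", ]
  expect_equal(sum(is.na(pat$wf_distance)), 2)
  expect_equal(sum(is.na(pat$wf_duration)), 2)
  expect_equal(sum(is.na(pat$detour_score)), 1)
  expect_equal(sum(is.na(pat$composite)), 1)
  expect_true(all(is.na(pat$risk) == is.na(pat$composite)))
  expect_true(all(!is.na(co[co$group == "control", "wf_distance"])))
})

test_that("event-free walk profiles give composite 1", {
  g <- make_grid_street_graph(4, 4)
  w <- gen_dnt_walks(g, walk_profile(0, 0), seed = 1)
  expect_equal(nrow(w$original$events), 0)
  expect_equal(nrow(w$detour$events), 0)
  s <- score_dnt_walks(w$original, w$detour, g)
  expect_identical(s$composite, 1)
  expect_equal(s$risk, "low")
})

test_that("planted events are exactly re-detected (round trip)", {
  g <- make_grid_street_graph(5, 4)
  for (seed in 1:40) {
    w <- gen_dnt_walks(g, walk_profile(p_wrong_turn = 0.4,
                                       hesitation_rate = 1.5), seed = seed)
    for (walk in list(w$original, w$detour)) {
      det <- detect_wrong_turns(walk$taken_path, g, walk$viable_paths)
      planted <- walk$events[walk$events$kind == "wrong_turn", ]
      expect_equal(nrow(det$events), nrow(planted))
      expect_equal(det$events$node_id, planted$node_id)
      expect_equal(det$events$consecutive_index, planted$consecutive_index)
      # hesitations are recorded at nodes actually on the walk
      hes <- walk$events$node_id[walk$events$kind == "hesitation"]
      expect_true(all(hes %in% walk$taken_path))
    }
  }
})

test_that("certain deviation at a single decision point yields the reset sequence", {
  g <- double_error_graph()
  w <- gen_dnt_walks(g, walk_profile(p_wrong_turn = 1, hesitation_rate = 0),
                     seed = 2, origin = "A", destination = "C")
  wt <- w$original$events[w$original$events$kind == "wrong_turn", ]
  expect_equal(wt$consecutive_index, c(1L, 2L))
  expect_equal(wt$node_id[1], "B")
  det <- detect_wrong_turns(w$original$taken_path, g, w$original$viable_paths)
  expect_equal(nrow(det$resets), 1)
  expect_equal(det$resets$resume_node, "B")
})

test_that("hesitation counts follow the configured Poisson rate", {
  g <- make_grid_street_graph(5, 5)
  rate <- 5
  total_hes <- 0; total_km <- 0
  for (seed in 1:3000) {
    w <- gen_dnt_walks(g, walk_profile(0, rate), seed = seed)
    for (walk in list(w$original, w$detour)) {
      total_hes <- total_hes + sum(walk$events$kind == "hesitation")
      total_km <- total_km + walk$total_distance_km
    }
  }
  expect_equal(total_hes / total_km, rate, tolerance = 0.02)
})

test_that("graphs without a non-overlapping detour are rejected", {
  # a single corridor: removing the original route disconnects the endpoints
  nodes <- tibble::tibble(id = c("a", "b", "c"), x = 0:2, y = 0,
                          intersection = c(FALSE, TRUE, FALSE))
  edges <- tibble::tibble(from = c("a", "b"), to = c("b", "c"), length_km = 1)
  g <- street_graph(nodes, edges)
  expect_error(gen_dnt_walks(g, walk_profile(0, 0), seed = 1,
                             origin = "a", destination = "c"),
               "no valid detour")
})
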