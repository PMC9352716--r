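# Routes on the toy graph: the habitual walk out is X1-A-B-C-D; the
# enforced detour home is D-C-G-F-E-A-X1 (sharing only nodes, no edges).
orig_route <- c("X1", "A", "B", "C", "D")
detour_route <- c("D", "C", "G", "F", "E", "A", "X1")

test_that("a walk along a viable route produces no wrong turns", {
  g <- toy_graph()
  det <- detect_wrong_turns(detour_route, g, viable_paths = list(detour_route))
  expect_equal(nrow(det$events), 0)
  det0 <- detect_wrong_turns(orig_route, g, viable_paths = list(orig_route))
  expect_equal(nrow(det0$events), 0)
})

test_that("re-entering the original route on a non-exempt edge is one wrong turn", {
  g <- toy_graph()
  taken <- c("D", "C", "B", "C", "G", "F", "E", "A", "X1")  # strays onto B-C
  det <- detect_wrong_turns(taken, g, viable_paths = list(detour_route))
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$node_id, "C")
  expect_equal(det$events$consecutive_index, 1L)
  expect_equal(nrow(det$resets), 0)
  # the same stray edge marked as an acceptable overlap is never flagged
  det2 <- detect_wrong_turns(taken, g, viable_paths = list(detour_route),
                             allowed_overlap = edge_keys(c("C", "B")))
  expect_equal(nrow(det2$events), 0)
})

test_that("two consecutive wrong turns reset the walk to the first error site", {
  g <- toy_graph()
  taken <- c("D", "C", "B", "A", "C", "G", "F", "E", "A", "X1")
  det <- detect_wrong_turns(taken, g, viable_paths = list(detour_route))
  expect_equal(det$events$consecutive_index, c(1L, 2L))
  expect_equal(det$events$node_id, c("C", "B"))
  expect_equal(det$resets$resume_node, "C")
  # a walk that fails to resume from the reset site is rejected
  bad <- c("D", "C", "B", "A", "B", "C", "G", "F", "E", "A", "X1")
  expect_error(detect_wrong_turns(bad, g, viable_paths = list(detour_route)),
               "reset location")
})

test_that("walks over unknown nodes or non-edges are rejected by step", {
  g <- toy_graph()
  expect_error(detect_wrong_turns(c("X1", "A", "C"), g, list(orig_route)),
               "step 2")
  expect_error(detect_wrong_turns(c("X1", "Q"), g, list(orig_route)),
               "unknown node")
})

test_that("route disorientation scores normalize the two event types separately", {
  expect_equal(route_disorientation_score(0, 0, 10, 2), 0)
  expect_equal(route_disorientation_score(1, 2, 10, 2), 1.1)
  # components add
  expect_equal(route_disorientation_score(3, 4, 7, 1.3),
               route_disorientation_score(3, 0, 7, 1.3) +
                 route_disorientation_score(0, 4, 7, 1.3))
  # pooled alternative divides the total count by distance x intersections
  expect_equal(route_disorientation_score(1, 2, 10, 2, mode = "combined"), 0.15)
  expect_error(route_disorientation_score(-1, 0, 10, 2), "negative")
})

test_that("composite score is the +1-corrected detour/original ratio", {
  expect_identical(composite_score(0, 0), 1)
  expect_equal(composite_score(0.25, 0), 1.25)
  expect_equal(composite_score(0, 0.5), 1 / 1.5)
  expect_error(composite_score(-0.1, 0), ">= 0")
  # equal disorientation on both routes is always neutral
  for (a in c(0, 0.2, 1, 7)) expect_equal(composite_score(a, a), 1)
})

test_that("risk classification flags any departure of the composite from 1", {
  expect_equal(classify_risk(1.0), "low")
  expect_equal(classify_risk(1.25), "high")
  expect_equal(classify_risk(0.8), "high")
  tol <- 1e-6
  expect_equal(classify_risk(1 + tol / 2, tolerance = tol), "low")
})

test_that("full walk scoring reproduces a hand-computed score sheet", {
  g <- toy_graph()
  original <- list(route_type = "original", planned_path = orig_route,
                   taken_path = orig_route,
                   events = tibble::tibble(kind = character(),
                                           node_id = character()),
                   total_distance_km = path_length_km(g, orig_route),
                   n_intersections = path_intersections(g, orig_route),
                   viable_paths = list(orig_route))
  detour <- list(route_type = "detour", planned_path = detour_route,
                 taken_path = c("D", "C", "B", "C", "G", "F", "E", "A", "X1"),
                 events = tibble::tibble(kind = c("hesitation", "hesitation"),
                                         node_id = c("G", "E")),
                 total_distance_km = path_length_km(g, detour_route),
                 n_intersections = path_intersections(g, detour_route),
                 viable_paths = list(detour_route))
  s <- score_dnt_walks(original, detour, g)
  # detour: 1 wrong turn / 4 intersections + 2 hesitations / 1.5 km
  expect_equal(s$detour_score, 1 / 4 + 2 / 1.5)
  expect_equal(s$original_score, 0)
  expect_equal(s$composite, (1 / 4 + 2 / 1.5 + 1) / 1)
  expect_equal(s$risk, "high")
})

test_that("extra detour events raise, extra original events lower the composite", {
  set.seed(42)
  for (i in 1:1000) {
    d <- runif(1, 0, 3); o <- runif(1, 0, 3); eps <- runif(1, 0.01, 1)
    expect_gt(composite_score(d + eps, o), composite_score(d, o))
    expect_lt(composite_score(d, o + eps), composite_score(d, o))
  }
})

test_that("street graphs survive a GeoJSON round trip", {
  g <- toy_graph()
  f <- tempfile(fileext = ".geojson")
  write_street_graph_geojson(g, f)
  g2 <- read_street_graph_geojson(f)
  expect_equal(as.data.frame(g2$nodes[order(g2$nodes$id), ]),
               as.data.frame(g$nodes[order(g$nodes$id), ]),
               ignore_attr = TRUE)
  ek <- function(x) sort(paste(pmin(x$from, x$to), pmax(x$from, x$to)))
  expect_equal(ek(g2$edges), ek(g$edges))
  expect_equal(sum(g2$edges$length_km), sum(g$edges$length_km))
  rf <- tempfile(fileext = ".geojson")
  write_route_geojson(g, detour_route, "detour", rf)
  rt <- read_route_geojson(rf)
  expect_equal(rt$route_type, "detour")
  expect_equal(rt$path, detour_route)
})

test_that("graph validation rejects broken networks", {
  nodes <- tibble::tibble(id = c("a", "b", "c"), x = 1:3, y = 0)
  expect_error(street_graph(nodes, tibble::tibble(from = "a", to = "b",
                                                  length_km = 1)),
               "connected")
  expect_error(street_graph(nodes, tibble::tibble(from = c("a", "b"),
                                                  to = c("b", "c"),
                                                  length_km = c(1, -1))),
               "> 0")
})
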