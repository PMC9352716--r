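# Shared fixtures built in code.

# Toy street network for wrong-turn scenarios:
#
#   X1 - A - B - C - D        A..D: the original route (A, B, C are
#        |   |   |            intersections; D is the destination)
#   X2 - E - F - G            E..G: a viable detour corridor
#            |
#            H                dead ends hanging off the corridors
#
# Every labelled node gets explicit intersection flags so scenarios are
# unambiguous.
toy_graph <- function() {
  nodes <- tibble::tibble(
    id = c("A", "B", "C", "D", "E", "F", "G", "H", "X1", "X2"),
    x  = c(1, 2, 3, 4, 1, 2, 3, 2, 0, 0),
    y  = c(1, 1, 1, 1, 0, 0, 0, -1, 1, 0),
    intersection = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
                     FALSE, FALSE))
  edges <- tibble::tibble(
    from = c("A", "B", "C", "A", "B", "C", "E", "F", "F", "X1", "X2"),
    to   = c("B", "C", "D", "E", "F", "G", "F", "G", "H", "A", "E"),
    length_km = 0.25)
  street_graph(nodes, edges)
}

# Single-decision-point route A-B-C where the only deviation at B leads to
# another intersection (W) with further wrong edges: forces the
# two-consecutive-wrong-turn reset under p_wrong_turn = 1. The corridor
# C-V-W-Z-A provides a non-overlapping detour so route planning succeeds.
double_error_graph <- function() {
  nodes <- tibble::tibble(
    id = c("A", "B", "C", "W", "Z", "V"),
    x  = c(0, 1, 2, 1, 0, 2),
    y  = c(0, 0, 0, 1, 1, 1),
    intersection = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  edges <- tibble::tibble(
    from = c("A", "B", "B", "W", "W", "V", "Z"),
    to   = c("B", "C", "W", "Z", "V", "C", "A"),
    length_km = 0.5)
  street_graph(nodes, edges)
}

# Brute-force oracle for the two-sided Wilcoxon rank-sum test: enumerates
# every assignment of the pooled values to the first sample and derives the
# exact distribution of the Mann-Whitney statistic U.
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(W = u_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}
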