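test_that("differential_tfs applies the universe restriction", {
  tr <- build_transition(
    list(state = c(A = 0L, B = 1L, C = 1L), prob = c(A = .1, B = .99, C = .99)),
    list(state = c(A = 1L, B = 1L, C = 0L), prob = c(A = .99, B = .99, C = .1)))
  expect_setequal(differential_tfs(tr, c("A", "B", "C")), c("A", "C"))
  expect_setequal(differential_tfs(tr, c("B", "C")), "C")
  same <- build_transition(
    list(state = c(A = 1L), prob = c(A = 1)),
    list(state = c(A = 1L), prob = c(A = 1)))
  expect_length(differential_tfs(same, "A"), 0L)
})

test_that("majority_update implements the threshold rule with tie-keep", {
  grn <- transition_grn(
    c("r1", "r2", "r3", "t", "u"),
    data.frame(source = c("r1", "r2", "r3"), target = "t",
               sign = c(1L, 1L, -1L)),
    s_init = c(r1 = 1L, r2 = 1L, r3 = 1L, t = 0L, u = 0L),
    s_final = c(r1 = 0L, r2 = 0L, r3 = 0L, t = 1L, u = 1L))
  st <- c(r1 = 1L, r2 = 1L, r3 = 1L, t = 0L, u = 0L)
  out <- majority_update(st, grn)
  expect_equal(unname(out["t"]), 1L)          # a - i = 1 > 0
  expect_equal(unname(out["u"]), 0L)          # no regulators: keep
  # tie keeps the current state
  grn2 <- transition_grn(
    c("r1", "r2", "t"),
    data.frame(source = c("r1", "r2"), target = "t", sign = c(1L, -1L)),
    s_init = c(r1 = 1L, r2 = 1L, t = 1L),
    s_final = c(r1 = 0L, r2 = 0L, t = 0L))
  expect_equal(unname(majority_update(c(r1 = 1L, r2 = 1L, t = 1L), grn2)["t"]),
               1L)
  expect_equal(unname(majority_update(c(r1 = 1L, r2 = 1L, t = 0L), grn2)["t"]),
               0L)
  # clamping wins
  expect_equal(unname(majority_update(st, grn, clamped = "t")["t"]), 0L)
  expect_error(majority_update(st[-4], grn), "missing")
})

test_that("is_point_attractor is the one-step fixed-point check", {
  edgeless <- transition_grn(c("A", "B"), NULL,
                             c(A = 1L, B = 0L), c(A = 0L, B = 1L))
  expect_true(is_point_attractor(c(A = 1L, B = 0L), edgeless))
  expect_true(is_point_attractor(c(A = 0L, B = 1L), edgeless))
  ab <- transition_grn(c("A", "B"),
                       data.frame(source = "A", target = "B", sign = 1L),
                       c(A = 1L, B = 0L), c(A = 0L, B = 1L))
  expect_false(is_point_attractor(c(A = 1L, B = 0L), ab))   # B would flip on
  cyc <- transition_grn(c("A", "B"),
                        data.frame(source = c("A", "B"), target = c("B", "A"),
                                   sign = 1L),
                        c(A = 1L, B = 1L), c(A = 0L, B = 0L))
  expect_true(is_point_attractor(c(A = 1L, B = 1L), cyc))
})

test_that("prune_to_attractors: module examples", {
  # contradictory edge removed
  g1 <- prune_to_attractors(
    data.frame(source = "A", target = "B", sign = 1L),
    s_init = c(A = 1L, B = 0L), s_final = c(A = 0L, B = 1L))
  expect_equal(nrow(g1$edges), 0L)
  expect_equal(g1$removed$reason, "attractor_conflict")
  # consistent edge kept
  g2 <- prune_to_attractors(
    data.frame(source = "A", target = "B", sign = 1L),
    s_init = c(A = 1L, B = 1L), s_final = c(A = 0L, B = 0L))
  expect_equal(nrow(g2$edges), 1L)
  # empty prior unchanged
  g3 <- prune_to_attractors(NULL, c(A = 1L), c(A = 0L))
  expect_equal(nrow(g3$edges), 0L)
})

test_that("pruning contract on random instances", {
  set.seed(11)
  for (i in 1:40) {
    pr <- random_grn_prior(sample(3:7, 1), edge_prob = 0.4, p_zero_sign = 0.15)
    s_init <- random_state(pr$tfs)
    s_final <- 1L - s_init
    grn <- prune_to_attractors(pr$edges, s_init, s_final)
    expect_true(is_point_attractor(s_init, grn))
    expect_true(is_point_attractor(s_final, grn))
    # never adds edges
    ek <- function(e) paste(e$source, e$target, e$sign)
    expect_true(all(ek(grn$edges) %in% ek(pr$edges)))
    # maximality: restoring any removed edge breaks an attractor
    if (!is.null(grn$removed) && nrow(pr$edges) <= 15) {
      for (j in seq_len(nrow(grn$removed))) {
        aug <- grn
        aug$edges <- rbind(grn$edges,
                           grn$removed[j, c("source", "target", "sign")])
        expect_true(!is_point_attractor(s_init, aug) ||
                      !is_point_attractor(s_final, aug))
      }
    }
  }
})

test_that("grn_passes_filter counts connected TFs with inclusive boundary", {
  mk <- function(n_connected, n_total) {
    tfs <- sprintf("t%02d", seq_len(n_total))
    e <- if (n_connected >= 2)
      data.frame(source = tfs[seq_len(n_connected - 1L)],
                 target = tfs[2:n_connected], sign = 1L)
    else NULL
    s <- setNames(rep(0L, n_total), tfs)
    transition_grn(tfs, e, s, 1L - s)
  }
  expect_false(grn_passes_filter(mk(9, 12)))
  expect_true(grn_passes_filter(mk(10, 12)))
  expect_false(grn_passes_filter(mk(0, 12)))
})
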