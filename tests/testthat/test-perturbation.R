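make_toy_system <- function() {
  # GRN: A -> B (+); interface TF I -> A (+); I is A's only regulator
  grn <- transition_grn(
    c("A", "B"),
    data.frame(source = "A", target = "B", sign = 1L),
    s_init = c(A = 0L, B = 0L), s_final = c(A = 1L, B = 1L))
  add_external_inputs(grn, data.frame(source = "I", target = "A", sign = 1L))
}

test_that("identify_interface_tfs needs regulation, expression and an expressed path", {
  sig <- signed_network(data.frame(
    source = c("S", "m", "S2", "m2"),
    target = c("m", "t1", "m2", "t2"),
    sign = 1L, mechanism = "Binding"), "signalling")
  reg <- signed_network(data.frame(
    source = c("t1", "t2", "t3"), target = c("A", "A", "A"), sign = 1L,
    mechanism = "Transcriptional regulation"), "regulatory")
  grn <- transition_grn("A", NULL, c(A = 0L), c(A = 1L))
  tr_state <- function(states) {
    probs <- setNames(ifelse(states == 1L, 0.99, 0.1), names(states))
    list(state = states, prob = probs)
  }
  # all expressed: t1 and t2 qualify (t3 not in signalling network)
  st <- c(S = 1L, m = 1L, t1 = 1L, S2 = 1L, m2 = 1L, t2 = 1L, A = 0L)
  tr <- build_transition(tr_state(st), tr_state(c(st[-7], A = 1L)))
  expect_setequal(identify_interface_tfs(sig, reg, grn, tr), c("t1", "t2"))
  # t1 not expressed initially -> excluded
  st2 <- st; st2["t1"] <- 0L
  tr2 <- build_transition(tr_state(st2), tr_state(c(st2[-7], A = 1L)))
  expect_equal(identify_interface_tfs(sig, reg, grn, tr2), "t2")
  # intermediate m not expressed -> path not expressed -> t1 excluded
  st3 <- st; st3["m"] <- 0L
  tr3 <- build_transition(tr_state(st3), tr_state(c(st3[-7], A = 1L)))
  expect_equal(identify_interface_tfs(sig, reg, grn, tr3), "t2")
})

test_that("simulate_clamped reaches the hand-computed fixed point", {
  grn <- make_toy_system()
  res <- simulate_clamped(grn, c(A = 0L, B = 0L), c(I = 1L))
  expect_true(res$converged)
  expect_setequal(res$flipped, c("A", "B"))
  expect_equal(res$flipping_score, 2L)
  # clamping to the current value of an edgeless GRN: no flips
  lone <- transition_grn("A", NULL, c(A = 1L), c(A = 0L))
  lone <- add_external_inputs(lone, data.frame(source = "I", target = "A",
                                               sign = -1L))
  res0 <- simulate_clamped(lone, c(A = 1L), c(I = 0L))
  expect_equal(res0$flipping_score, 0L)
  expect_error(simulate_clamped(grn, c(A = 0L, B = 0L), c(I = 1L, I = 0L)),
               "more than one state")
})

test_that("simulate_clamped detects oscillation", {
  # weighted negative feedback realizing a' = !b, b' = a under held inputs:
  # A =(-2)= B -> A via parallel edges, constitutive pushes from I and J
  grn <- transition_grn(
    c("A", "B"),
    data.frame(source = c("B", "B", "A", "A"), target = c("A", "A", "B", "B"),
               sign = c(-1L, -1L, 1L, 1L)),
    s_init = c(A = 0L, B = 0L), s_final = c(A = 1L, B = 1L))
  grn <- add_external_inputs(grn, data.frame(source = c("I", "J"),
                                             target = c("A", "B"),
                                             sign = c(1L, -1L)))
  # (0,0) -> (1,0) -> (1,1) -> (0,1) -> (0,0): a 4-cycle, never a fixed point
  res <- simulate_clamped(grn, c(A = 0L, B = 0L), c(I = 1L),
                          external_inputs = c(J = 1L))
  expect_false(res$converged)
  expect_equal(res$flipping_score, -1L)
})

test_that("clamped simulation equals exhaustive trajectory on random GRNs", {
  set.seed(5)
  for (i in 1:25) {
    pr <- random_grn_prior(sample(3:8, 1), edge_prob = 0.35)
    s0 <- random_state(pr$tfs)
    grn <- transition_grn(pr$tfs, pr$edges, s0, 1L - s0)
    ext <- data.frame(source = "EXT", target = sample(pr$tfs, 2),
                      sign = sample(c(-1L, 1L), 2, TRUE))
    grn <- add_external_inputs(grn, ext)
    for (j in 1:4) {
      combo <- setNames(sample(0:1, 1), sample(c(pr$tfs, "EXT"), 1))
      held <- c(EXT = 1L)
      res <- simulate_clamped(grn, s0, combo, external_inputs = held)
      full0 <- c(s0, held)
      full0[names(combo)] <- combo
      orc <- oracle_trajectory(full0, rbind(grn$edges, grn$input_edges),
                               pr$tfs,
                               clamped = union(names(combo), "EXT"))
      expect_equal(res$converged, orc$converged)
      if (orc$converged)
        expect_setequal(res$flipped,
                        pr$tfs[orc$fixed[pr$tfs] != s0[pr$tfs]])
    }
  }
})

test_that("enumerate_combinations matches the brute-force generator", {
  tr <- build_transition(
    list(state = c(P = 0L, Q = 1L, R = 1L), prob = c(P = .1, Q = .99, R = .99)),
    list(state = c(P = 1L, Q = 1L, R = 1L), prob = c(P = .99, Q = .99, R = .99)))
  # P is differential (0 -> 1): only state 1 enumerated
  combos <- enumerate_combinations(c("P", "Q"), tr, max_size = 2)
  keys <- sort(vapply(combos, combo_key, character(1)))
  expect_equal(keys, oracle_combinations(
    c("P", "Q"), list(P = 1L, Q = 0:1), 2))
  # counting example: 2 non-differential TFs, sizes 1 and 2 -> 4 + 4
  c1 <- enumerate_combinations(c("Q", "R"), tr, max_size = 1)
  expect_length(c1, 4L)
  c2 <- enumerate_combinations(c("Q", "R"), tr, max_size = 2)
  expect_length(c2, 8L)
  # brute-force sweep over random TF sets
  set.seed(3)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    tfs <- sprintf("T%d", seq_len(n))
    ms <- sample(1:4, 1)
    combos <- enumerate_combinations(tfs, NULL, max_size = ms)
    expect_equal(sort(vapply(combos, combo_key, character(1))),
                 oracle_combinations(tfs,
                                     setNames(rep(list(0:1), n), tfs), ms))
  }
})

test_that("select_bpcs keeps top-3 distinct scores with ties and flags", {
  mk_res <- function(tf, state, score, flipped) {
    structure(list(combination = setNames(as.integer(state), tf),
                   flipped = flipped, flipping_score = length(flipped),
                   converged = TRUE), class = "perturbation_result")
  }
  res <- list(
    mk_res("A", 1, 5, sprintf("g%d", 1:5)),
    mk_res("B", 1, 5, sprintf("g%d", 2:6)),
    mk_res("C", 0, 4, sprintf("g%d", 1:4)),
    mk_res("D", 1, 3, sprintf("g%d", 1:3)),
    mk_res("E", 0, 2, sprintf("g%d", 1:2)))
  sel <- select_bpcs(res, n_grn_tfs = 10)
  got <- vapply(sel$combinations, function(r) names(r$combination), character(1))
  expect_setequal(got, c("A", "B", "C", "D"))    # scores 5,5,4,3 kept; 2 dropped
  expect_equal(sel$best_score, 5L)
  expect_false(sel$flag_low_flip)                 # 5 >= 0.4 * 10
  sel2 <- select_bpcs(res, n_grn_tfs = 20)
  expect_true(sel2$flag_low_flip)                 # 5 < 8
  sel3 <- select_bpcs(res, n_grn_tfs = 12)
  expect_false(sel3$flag_low_flip)                # 5 >= 4.8
  # all scores equal -> all kept
  res_eq <- list(mk_res("A", 1, 3, c("g1", "g2")),
                 mk_res("B", 0, 3, c("g2", "g3")))
  expect_length(select_bpcs(res_eq, 5)$combinations, 2L)
  expect_error(select_bpcs(list(), 5), "no converged")
})

test_that("synergy_filter removes union-equal combos, keeps singletons", {
  mk <- function(tfs, states, flipped) {
    structure(list(combination = setNames(as.integer(states), tfs),
                   flipped = flipped, flipping_score = length(flipped),
                   converged = TRUE), class = "perturbation_result")
  }
  singles <- list("A|1" = "x", "B|1" = "y")
  combo_union <- mk(c("A", "B"), c(1, 1), c("x", "y"))
  combo_syn <- mk(c("A", "B"), c(1, 1), c("x", "y", "z"))
  single <- mk("A", 1, "x")
  out <- synergy_filter(list(combo_union, combo_syn, single), singles)
  expect_length(out, 2L)
  expect_false(any(vapply(out, function(r)
    length(r$combination) == 2L && setequal(r$flipped, c("x", "y")),
    logical(1))))
  expect_error(synergy_filter(list(mk(c("A", "C"), c(1, 1), "x")), singles),
               "missing singleton")
})

test_that("compute_q normalizes BPC pair frequencies", {
  mk <- function(tfs, states) {
    structure(list(combination = setNames(as.integer(states), tfs),
                   flipped = character(), flipping_score = 0L,
                   converged = TRUE), class = "perturbation_result")
  }
  q <- compute_q(list(mk("A", 1), mk(c("A", "B"), c(1, 0))))
  expect_equal(q[["A|1"]], 2 / 3)
  expect_equal(q[["B|0"]], 1 / 3)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_equal(compute_q(list(mk("A", 1)))[["A|1"]], 1)
  expect_false("B|1" %in% names(q))
  expect_error(compute_q(list()), "empty")
})
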