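test_that("scoring_graph drops sign-0 edges, p=0 nodes, applies boosts", {
  net <- signed_network(data.frame(
    source = c("a", "a", "b", "z"),
    target = c("b", "c", "c", "b"),
    sign = c(1L, 0L, -1L, 1L),
    mechanism = "Binding"), "signalling")
  g <- scoring_graph(net, c(a = .9, b = .8, c = .7, z = 0))
  expect_false("z" %in% g$nodes)                 # p = 0 excluded
  expect_equal(nrow(g$edges), 2L)                # sign-0 and z edges dropped
  # correlation boost: matching sign and |r| > threshold
  corr <- data.frame(gene_a = "a", gene_b = "b", r = 0.9)
  gb <- scoring_graph(net, c(a = .9, b = .4, c = .7, z = .5),
                      correlations = corr)
  eb <- gb$edges[gb$nodes[gb$edges$from] == "a" &
                   gb$nodes[gb$edges$to] == "b", ]
  expect_equal(eb$contrib_corr, 0.9)             # max(p, |r|)
  expect_equal(eb$contrib_base, 0.4)
  # sign mismatch: no boost
  gc <- scoring_graph(net, c(a = .9, b = .4, c = .7, z = .5),
                      correlations = data.frame(gene_a = "a", gene_b = "b",
                                                r = -0.9))
  ec <- gc$edges[gc$nodes[gc$edges$from] == "a" &
                   gc$nodes[gc$edges$to] == "b", ]
  expect_equal(ec$contrib_corr, 0.4)
  expect_error(scoring_graph(net, c(a = .9, b = .4, c = .7, z = .5),
                             correlations = data.frame(gene_a = "a",
                                                       gene_b = "b", r = 1.4)),
               "\\[-1, 1\\]")
  # unmeasured nodes take the default probability
  gd <- scoring_graph(net, c(a = .9), default_prob = 0.5)
  expect_equal(unname(gd$p["b"]), 0.5)
})

test_that("mpp on the two-route fixture matches hand calculation", {
  fx <- tiny_two_route_graph()
  # correlation variant picks the two-hop 0.95^2 = 0.9025 route
  m1 <- mpp(fx$graph, "x", "y", "correlation")
  expect_equal(m1$path, c("x", "b", "c", "y"))
  expect_equal(m1$probability, 0.95^2, tolerance = 1e-12)
  expect_equal(m1$sign, 1L)                      # two inhibitions cancel
  # length variant picks the short route: 0.8 e^-2 > 0.9025 e^-3
  m2 <- mpp(fx$graph, "x", "y", "length")
  expect_equal(m2$path, c("x", "a", "y"))
  expect_equal(m2$probability, 0.8 * exp(-2), tolerance = 1e-12)
  expect_equal(m2$sign, 1L)
  # direct edge: empty intermediate product
  net <- signed_network(data.frame(source = "x", target = "y", sign = -1L,
                                   mechanism = "Binding"), "signalling")
  g <- scoring_graph(net, c(x = .9, y = .9))
  expect_equal(mpp(g, "x", "y", "correlation")$probability, 1)
  expect_equal(mpp(g, "x", "y", "length")$probability, exp(-1))
  expect_equal(mpp(g, "x", "y", "length")$sign, -1L)
  expect_null(mpp(g, "y", "x", "correlation"))   # unreachable
  expect_error(mpp(g, "x", "x"), "must differ")
})

test_that("mpp equals brute-force enumeration on random graphs (both variants)", {
  set.seed(2024)
  n_checked <- 0L
  for (i in 1:40) {
    net <- random_signed_net(sample(5:9, 1), edge_prob = 0.3,
                             p_parallel_opposite = 0.1)
    probs <- setNames(runif(length(net$nodes), 0.05, 1), net$nodes)
    corr <- NULL
    if (i %% 3 == 0 && nrow(net$edges) > 2) {
      pick <- sample(nrow(net$edges), 2)
      corr <- data.frame(gene_a = net$edges$source[pick],
                         gene_b = net$edges$target[pick],
                         r = net$edges$sign[pick] * runif(2, 0.75, 0.95))
    }
    g <- scoring_graph(net, probs, correlations = corr)
    ends <- sample(net$nodes, 2)
    for (variant in c("correlation", "length")) {
      got <- mpp(g, ends[1], ends[2], variant)
      want <- oracle_mpp(net, probs, ends[1], ends[2], variant,
                         correlations = corr)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$probability, want$probability, tolerance = 1e-12)
        expect_equal(got$sign, want$sign)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 20L)       # the sweep must actually exercise paths
})

test_that("monotonicity: raising an intermediate probability never lowers M", {
  fx <- tiny_two_route_graph()
  base <- mpp(fx$graph, "x", "y", "correlation")$probability
  for (node in c("a", "b", "c")) {
    p2 <- fx$probs
    p2[node] <- min(1, p2[node] + 0.04)
    g2 <- scoring_graph(fx$net, p2)
    expect_gte(mpp(g2, "x", "y", "correlation")$probability, base - 1e-12)
  }
})

test_that("length-variant score is the plain product times e^-n", {
  fx <- tiny_two_route_graph()
  m <- mpp(fx$graph, "x", "y", "length")
  n <- length(m$path) - 1L
  plain <- prod(fx$probs[setdiff(m$path, c("x", "y"))])
  expect_equal(m$probability, plain * exp(-n), tolerance = 1e-12)
})

test_that("path_sign multiplies edge signs", {
  e <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "d"),
                  sign = c(1L, -1L, -1L), mechanism = "Binding")
  g <- scoring_graph(signed_network(e, "signalling"),
                     setNames(rep(.9, 4), c("a", "b", "c", "d")))
  expect_equal(path_sign(c("a", "b", "c", "d"), g), 1L)
  expect_equal(path_sign(c("b", "c"), g), -1L)
  e$sign <- c(-1L, -1L, -1L)
  g2 <- scoring_graph(signed_network(e, "signalling"),
                      setNames(rep(.9, 4), c("a", "b", "c", "d")))
  expect_equal(path_sign(c("a", "b", "c", "d"), g2), -1L)
})

test_that("opposite-sign parallel tie is flagged and resolved to +1", {
  e <- data.frame(source = c("x", "x", "a"), target = c("a", "a", "y"),
                  sign = c(1L, -1L, 1L), mechanism = c("Binding", "Phos", "B"))
  g <- scoring_graph(signed_network(e, "signalling"),
                     c(x = .9, a = .8, y = .9))
  m <- mpp(g, "x", "y", "correlation")
  expect_equal(m$sign, 1L)
  expect_true(m$sign_ambiguous)
})

test_that("molecule_profiles: normalization, sign flip, degenerate cases", {
  # x reaches y (sign +, M = 0.8) and z (sign -, M = 0.2)
  e <- data.frame(source = c("x", "a", "x", "b"),
                  target = c("a", "y", "b", "z"),
                  sign = c(1L, 1L, 1L, -1L), mechanism = "Binding")
  g <- scoring_graph(signed_network(e, "signalling"),
                     c(x = .9, a = .8, b = .2, y = .99, z = .99))
  pr <- molecule_profiles(g, "x", c("y", "z"), "correlation")
  expect_equal(pr$activation[["y|1"]], 0.8, tolerance = 1e-12)
  expect_equal(pr$activation[["z|0"]], 0.2, tolerance = 1e-12)
  expect_equal(pr$inhibition[["y|0"]], 0.8, tolerance = 1e-12)
  expect_equal(pr$inhibition[["z|1"]], 0.2, tolerance = 1e-12)
  expect_equal(sum(pr$activation), 1, tolerance = 1e-12)
  # single reachable TF: degenerate P = 1
  pr_b <- molecule_profiles(g, "b", c("y", "z"), "correlation")
  expect_equal(unname(pr_b$activation), 1)
  expect_equal(names(pr_b$activation), "z|0")
  # unreachable molecule: empty profiles
  pr_y <- molecule_profiles(g, "y", c("y", "z"), "correlation")
  expect_length(pr_y$activation, 0L)
  # activation/inhibition share probabilities with complementary states
  expect_equal(unname(sort(pr$activation)), unname(sort(pr$inhibition)))
})
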