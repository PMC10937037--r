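test_that("a decoupled node relaxes to its input", {
  net <- tln_network(matrix(0, 1, 1), b = 1)
  tr <- simulate_tln(net, x0 = 0, T = 20)
  expect_lt(abs(tr$x[nrow(tr$x), 1] - 1), 1e-6)
})

test_that("weak uniform III cycle converges to the full-support fixed point", {
  c <- cycle_tln(rep("I", 3), rep(0.5, 3), rep(1, 3))
  set.seed(1)
  for (rep in 1:3) {
    tr <- simulate_tln(c, T = 60)
    expect_equal(classify_trajectory(tr), "converged-fixed-point")
    # x (1 + w) = b on the full support
    expect_equal(unname(tr$x[nrow(tr$x), ]), rep(2 / 3, 3), tolerance = 1e-6)
  }
})

test_that("strong uniform III cycle sustains an oscillation", {
  c <- cycle_tln(rep("I", 3), rep(2.5, 3), rep(1, 3))
  set.seed(2)
  tr <- simulate_tln(c, T = 200)
  expect_equal(classify_trajectory(tr), "sustained-oscillation")
})

test_that("trajectories stay nonnegative", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    nI <- sample(n, 1)
    if (n == 2 && nI == 1) nI <- 2
    c <- generate_random_cycle_tln(n, nI)
    tr <- simulate_tln(c, T = 50)
    expect_true(all(tr$x >= 0))
  }
})

test_that("default initial states respect the admissible box", {
  c <- cycle_tln(c("I", "E", "E"), c(2, 1.5, 0.8), c(0, 2, 0))
  set.seed(4)
  for (rep in 1:20) {
    x0 <- random_initial_state(c)
    # segment starts at inhibited node 2 with b = 2; bounds 2, 2*w2, 2*w2*w3
    expect_true(all(x0 >= 0))
    expect_lte(x0[2], 2)
    expect_lte(x0[3], 2 * 1.5)
    expect_lte(x0[1], 2 * 1.5 * 0.8)
  }
})

test_that("acyclic fixed points propagate forward exactly", {
  # excitatory chain: b = (1, 0), unit weight
  g1 <- signed_digraph(c("E1", "E2"), c("E", "E"),
                       data.frame(source = "E1", target = "E2"))
  expect_equal(dag_fixed_point(tln_from_graph(g1, b = c(1, 0)), g1)$x, c(1, 1))
  # inhibitory chain: the threshold clips the downstream node to 0
  g2 <- signed_digraph(c("I1", "E2"), c("I", "E"),
                       data.frame(source = "I1", target = "E2"))
  expect_equal(dag_fixed_point(tln_from_graph(g2, b = c(1, 0)), g2)$x, c(1, 0))
  expect_error(dag_fixed_point(tln_from_graph(graph_fixture("EI")),
                               graph_fixture("EI")), "not acyclic")
})

test_that("random DAG dynamics converge to the propagated fixed point", {
  set.seed(5)
  dag <- random_dag_tln(6)
  fp <- dag_fixed_point(dag$net, dag$g)
  for (rep in 1:20) {
    x0 <- stats::runif(6, 0, 2)
    tr <- simulate_tln(dag$net, x0 = x0, T = 60)
    expect_lt(max(abs(tr$x[nrow(tr$x), ] - fp$x)), 1e-6)
  }
})

test_that("support enumeration finds the winner-take-all pair", {
  fp <- enumerate_fixed_points(tln_network(rbind(c(0, -2), c(-2, 0)), c(1, 1)))
  stable <- Filter(function(f) f$stability == "linearly-stable", fp)
  expect_length(stable, 2L)
  sup <- lapply(stable, `[[`, "support")
  expect_setequal(sup, list(1L, 2L))
  expect_equal(sort(vapply(stable, function(f) max(f$x), 0)), c(1, 1))
})

test_that("strong even-cycle fixed points have strictly complementary supports", {
  c <- cycle_tln(c("E", "I", "I"), rep(2, 3))
  fp <- enumerate_fixed_points(c)
  stable <- Filter(function(f) f$stability == "linearly-stable", fp)
  expect_length(stable, 2L)
  s1 <- stable[[1]]$support; s2 <- stable[[2]]$support
  expect_length(intersect(s1, s2), 0L)
  expect_setequal(union(s1, s2), 1:3)
})

test_that("every enumerated fixed point satisfies x = [Wx + b]+", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    nI <- sample(n, 1)
    if (n == 2 && nI == 1) nI <- 2
    c <- generate_random_cycle_tln(n, nI)
    net <- as_tln(c)
    for (f in enumerate_fixed_points(net)) {
      resid <- f$x - pmax(net$W %*% f$x + net$b, 0)
      expect_lt(max(abs(resid)), 1e-8)
      expect_setequal(which(f$x > 1e-9), f$support)
    }
  }
})
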