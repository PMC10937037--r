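test_that("construction enforces the node-sign and edge invariants", {
  expect_error(signed_digraph(c("a", "a"), c("E", "I"),
                              data.frame(source = "a", target = "a")),
               "duplicate node")
  expect_error(signed_digraph(c("a", "b"), c("E", "X"),
                              data.frame(source = "a", target = "b")),
               "sign")
  expect_error(signed_digraph(c("a", "b"), c("E", "I"),
                              data.frame(source = c("a", "a"),
                                         target = c("b", "b"))),
               "duplicate directed edges")
  expect_error(signed_digraph(c("a", "b"), c("E", "I"),
                              data.frame(source = "a", target = "c")),
               "unknown node")
  g <- signed_digraph(c("a", "b"), c("E", "I"),
                      data.frame(source = c("a", "b"), target = c("b", "a")))
  expect_equal(g$edges$sign, c("excitatory", "inhibitory"))
})

test_that("simple-cycle enumeration matches a brute-force oracle on random graphs", {
  set.seed(42)
  for (rep in 1:50) {
    g <- random_signed_graph(sample(3:6, 1))
    recs <- enumerate_simple_cycles(g)
    expect_equal(cycle_strings(recs), oracle_cycles(g))
  }
})

test_that("two-node and ring graphs yield exactly one cycle", {
  ei <- graph_fixture("EI")
  expect_length(enumerate_simple_cycles(ei), 1L)
  iii <- graph_fixture("III")
  recs <- enumerate_simple_cycles(iii)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$length, 3L)
  expect_equal(recs[[1]]$n_inhibitory, 3L)
})

test_that("cycle parity is invariant under rotation of the node sequence", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_signed_graph(6)
    for (r in enumerate_simple_cycles(g)) {
      k <- sample(r$length, 1)
      rotated <- c(r$nodes[k:r$length], r$nodes[seq_len(k - 1)])
      n_inh <- sum(g$sign[rotated] == "I")
      expect_equal(n_inh %% 2L, r$n_inhibitory %% 2L)
    }
  }
})

test_that("the odd inhibitory cycle rule classifies the canonical motifs", {
  cls <- function(fx) classify_cycle(enumerate_simple_cycles(graph_fixture(fx))[[1]])
  expect_equal(cls("EI"), "oscillation-capable")     # one inhibitory edge
  expect_equal(cls("EII"), "not-capable")            # two inhibitory edges
  expect_equal(cls("III"), "oscillation-capable")    # three inhibitory edges
  expect_equal(cls("EEI"), "oscillation-capable")
})

test_that("network potential needs a negative loop", {
  # feed-forward graph: no cycles at all
  ff <- signed_digraph(c("a", "b", "c"), c("E", "I", "E"),
                       data.frame(source = c("a", "a", "b"),
                                  target = c("b", "c", "c")))
  rep_ff <- network_oscillation_potential(ff)
  expect_false(rep_ff$overall)
  expect_equal(nrow(rep_ff$cycles), 0L)
  # a network whose only cycle is an EII loop cannot oscillate
  expect_false(network_oscillation_potential(graph_fixture("EII"))$overall)
  # adding any odd-inhibitory loop flips the verdict
  expect_true(network_oscillation_potential(graph_fixture("EEI"))$overall)
  # an inhibitory self-loop is a negative loop of length 1
  selfg <- signed_digraph("a", "I", data.frame(source = "a", target = "a"))
  repo <- network_oscillation_potential(selfg)
  expect_true(repo$overall)
  expect_true(repo$cycles$self_loop[1])
})

test_that("subnetwork enumeration count equals the binomial sum", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(2:10, 1)
    g <- random_signed_graph(n, p_edge = 0.2)
    kmin <- sample(seq_len(n), 1)
    kmax <- if (kmin == n) n else sample(kmin:n, 1)
    subs <- enumerate_subnetworks(g, kmin, kmax)
    expect_length(subs, sum(choose(n, kmin:kmax)))
    expect_false(anyDuplicated(vapply(subs, paste, "", collapse = ",")) > 0)
  }
  expect_error(enumerate_subnetworks(graph_fixture("III"), 2, 5), "kmax")
})

test_that("loop coverage agrees with inclusion-exclusion", {
  g <- graph_fixture("CBG-core")
  loops <- cbg_loops()
  cov <- loop_coverage(g, loops, 2, 7)
  expect_equal(cov$covered, oracle_coverage(8, loops, 2, 7))
  expect_equal(cov$total, sum(choose(8, 2:7)))
  # random graphs and random loop sets
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    gg <- random_signed_graph(n, p_edge = 0.3)
    nl <- sample(1:4, 1)
    rl <- lapply(seq_len(nl), function(i)
      sample(gg$nodes, sample(2:min(4, n), 1)))
    kmin <- sample(1:2, 1); kmax <- sample((n - 1):n, 1)
    expect_equal(loop_coverage(gg, rl, kmin, kmax)$covered,
                 oracle_coverage(n, rl, kmin, kmax))
  }
  expect_error(loop_coverage(g, list(c("Proto", "nope")), 2, 7),
               "not in graph")
})

test_that("small-graph coverage example: one 2-node loop over a 3-node graph", {
  g <- signed_digraph(c("a", "b", "c"), c("E", "I", "E"),
                      data.frame(source = c("a", "b"), target = c("b", "a")))
  cov <- loop_coverage(g, list(c("a", "b")), 2, 3)
  # subsets {a,b}, {a,c}, {b,c}, {a,b,c}: exactly {a,b} and {a,b,c} qualify
  expect_equal(cov$total, 4L)
  expect_equal(cov$covered, 2L)
})

test_that("topological order errors on cyclic graphs, naming a cycle", {
  expect_error(topological_order(graph_fixture("EI")), "not acyclic")
  ff <- signed_digraph(c("a", "b"), c("E", "E"),
                       data.frame(source = "a", target = "b"))
  expect_equal(topological_order(ff), c(1L, 2L))
})
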