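test_that("uniform cycles land in the regimes the weight alone dictates", {
  # all-inhibitory triangle, uniform b: behavior depends on w only
  expect_equal(classify_regime(cycle_tln(rep("I", 3), rep(0.5, 3)))$label,
               "WEAK_GLOBAL_STABLE")
  expect_equal(classify_regime(cycle_tln(rep("I", 3), rep(1.5, 3)))$label,
               "ODD_STABLE")                      # 1 < 1.5 < 1/cos(pi/3) = 2
  expect_equal(classify_regime(cycle_tln(rep("I", 3), rep(2.5, 3)))$label,
               "ODD_UNSTABLE_OSCILLATORY")
  expect_equal(classify_regime(cycle_tln(c("E", "I", "I"), rep(1.5, 3)))$label,
               "EVEN_BISTABLE")
  expect_equal(classify_regime(cycle_tln(c("E", "I", "I"), rep(0.5, 3)))$label,
               "WEAK_GLOBAL_STABLE")
})

test_that("boundary and mixed cases are reported as indeterminate, not guessed", {
  # uniform w = 1: every segment product equals its input ratio
  expect_equal(classify_regime(cycle_tln(rep("I", 3), rep(1, 3)))$label,
               "INDETERMINATE_GAP")
  # geometric mean exactly at 1/cos(pi/3) = 2
  expect_equal(classify_regime(cycle_tln(rep("I", 3), rep(2, 3)))$label,
               "INDETERMINATE_GAP")
  # segments disagreeing (one below, one above its ratio)
  c <- cycle_tln(c("I", "I", "E"), c(0.2, 3, 3), c(0, 1, 1))
  expect_equal(classify_regime(c)$label, "INDETERMINATE_GAP")
})

test_that("the EI pair and purely excitatory rings sit outside the classification", {
  expect_equal(classify_regime(cycle_tln(c("E", "I"), c(1, 1), c(1, 0)))$label,
               "OUT_OF_SCOPE")
})

test_that("parity consistency: regime labels never contradict the odd rule", {
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    nI <- sample(n, 1)
    if (n == 2 && nI == 1) nI <- 2
    rg <- classify_regime(generate_random_cycle_tln(n, nI))
    if (rg$label == "EVEN_BISTABLE") expect_equal(nI %% 2, 0)
    if (rg$label %in% c("ODD_STABLE", "ODD_UNSTABLE_OSCILLATORY"))
      expect_equal(nI %% 2, 1)
  }
})

test_that("closed-form cycle spectrum matches the printed EI case and marginality", {
  expect_equal(cycle_eigenvalues(cycle_tln(c("E", "I"), c(1, 1), c(1, 0))),
               c(-1 + 1i, -1 - 1i))
  # odd triangle at w = 2: leading eigenvalue exactly marginal
  ev <- cycle_eigenvalues(cycle_tln(rep("I", 3), rep(2, 3)))
  expect_equal(max(Re(ev)), 0, tolerance = 1e-12)
})

test_that("quench predictions follow the weight-product inequality", {
  c <- cycle_tln(c("I", "E", "E"), rep(1, 3), c(0, 1, 0))
  q <- quench_condition(c, 3, 2)     # 2 * w3 * w1 = 2 > b = 1
  expect_equal(q$prediction, "oscillation-destroyed")
  expect_equal(quench_condition(c, 3, 0)$prediction, "unchanged")
  expect_equal(quench_condition(c, 3, 0.5)$prediction, "not-destroyed")
  q2 <- quench_condition(c, 3, -0.5)
  expect_equal(q2$prediction, "modified-threshold")
  expect_true(is.logical(q2$weak_condition_satisfied))
  expect_error(quench_condition(c, 2, 1), "inhibited")
})
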