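test_that("the CBG core graph holds exactly the six loops' edges plus the Proto self-loop", {
  g <- graph_fixture("CBG-core")
  expect_length(g$nodes, 8L)
  expect_equal(nrow(g$edges), 15L)
  expect_true(any(g$edges$source == "Proto" & g$edges$target == "Proto"))
  cyc <- network_oscillation_potential(g)$cycles
  for (loop in cbg_loops()) {
    hit <- vapply(strsplit(cyc$cycle, "->", fixed = TRUE), function(nodes)
      length(nodes) == length(loop) && setequal(nodes, loop), NA)
    expect_true(any(hit & cyc$parity == "negative"))
  }
  ext <- graph_fixture("CBG-extended")
  expect_gt(nrow(ext$edges), nrow(g$edges))
})

test_that("graph fixtures round-trip through JSON and CSV", {
  g <- graph_fixture("CBG-core")
  jf <- tempfile(fileext = ".json")
  write_graph_json(g, jf)
  g2 <- read_graph_json(jf)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$sign, g$sign)
  expect_equal(g2$edges$source, g$edges$source)
  expect_equal(g2$edges$target, g$edges$target)
  ef <- tempfile(fileext = ".csv"); nf <- tempfile(fileext = ".csv")
  utils::write.csv(g$edges[, c("source", "target", "weight")], ef,
                   row.names = FALSE)
  utils::write.csv(data.frame(node = g$nodes, sign = unname(g$sign)), nf,
                   row.names = FALSE)
  g3 <- read_graph_csv(ef, nf)
  expect_equal(g3$edges$target, g$edges$target)
  dot <- graph_to_dot(g)
  expect_match(dot, "digraph")
  expect_match(dot, "Proto")
})

test_that("TLN specs round-trip through JSON", {
  c <- generate_random_cycle_tln(4, 2, seed = 3)
  net <- as_tln(c)
  f <- tempfile(fileext = ".json")
  write_tln_json(net, f)
  net2 <- read_tln_json(f)
  expect_equal(net2$W, net$W)
  expect_equal(net2$b, net$b)
})

test_that("the random-cycle generator is seed-deterministic and validated", {
  a <- generate_random_cycle_tln(3, 3, seed = 1)
  b <- generate_random_cycle_tln(3, 3, seed = 1)
  expect_identical(a, b)
  expect_error(generate_random_cycle_tln(2, 1), "at least 3")
  for (s in 1:10) {
    n <- 2 + (s %% 5)
    nI <- max(2, s %% (n + 1))
    c <- generate_random_cycle_tln(n, min(nI, n), seed = s)
    expect_s3_class(c, "cycle_tln")
    expect_true(all(c$b[c$A] > 0))
    expect_true(all(c$b[setdiff(seq_len(c$n), c$A)] == 0))
  }
})

test_that("wilson-cowan fixtures load with the documented shapes", {
  iii <- wc_fixture("III")
  expect_equal(dim(iii$W), c(3L, 3L))
  expect_equal(sum(iii$W != 0), 3L)
  expect_true(all(iii$W[iii$W != 0] == -15))
  bg <- wc_fixture("BG4")
  expect_equal(bg$W["Proto", "Proto"], -8)
  expect_equal(bg$W["STN", "STN"], 5)
  expect_equal(wc_fixture("BG4", stn_self = FALSE)$W["STN", "STN"], 0)
  expect_equal(unname(wc_fixture("BG4", proto_input = 4)$I_ext["Proto"]), 4)
})

test_that("the command-line interface reproduces the counts report", {
  cli <- system.file("cli", "oscicycle", package = "oscicycle")
  expect_true(nzchar(cli))
  out <- tempfile(fileext = ".json")
  res <- system2("Rscript", c(cli, "counts", "reproduce", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  counts <- jsonlite::read_json(out)
  expect_equal(counts$total, 246L)
  expect_equal(counts$covered, 96L)
})
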