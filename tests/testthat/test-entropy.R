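test_that("edge weights follow the closed forms", {
  expect_equal(edge_weight(weight_scheme("ga"), 3, 3), 1)
  expect_equal(edge_weight(weight_scheme("abc"), 2, 2), sqrt(1 / 2))
  expect_equal(edge_weight(weight_scheme("randic", -1), 2, 3), 1 / 6)
  expect_equal(edge_weight(weight_scheme("abc4"), 4, 4), sqrt(6) / 4)
  expect_equal(edge_weight(weight_scheme("ga5"), 5, 8),
               2 * sqrt(40) / 13)

  expect_error(weight_scheme("randic"), "alpha")
  expect_error(weight_scheme("abc", alpha = 1), "only meaningful")
  expect_error(edge_weight(weight_scheme("abc"), 1, 1), "a \\+ b > 2")
  expect_error(edge_weight(weight_scheme("ga"), 0, 2), ">= 1")
})

test_that("index values accumulate count times weight", {
  c12 <- partition_edges(cycle_g(12), "degree")
  expect_equal(index_value(c12, weight_scheme("randic", 1)), 48)

  t6 <- printed_partition(family_spec("ZCS", 4, 4, 4), "degree")
  expect_equal(index_value(t6, weight_scheme("randic", 1)), 2445)

  conv <- edge_partition(data.frame(a = 4L, b = 4L, count = 9L), "degree_sum")
  expect_equal(index_value(conv, weight_scheme("abc4")), 9 * sqrt(6) / 4)

  expect_error(index_value(c12, weight_scheme("abc4")), "degree_sum")
  empty <- edge_partition(data.frame(a = integer(), b = integer(),
                                     count = integer()), "degree")
  expect_error(index_value(empty, weight_scheme("ga")), "empty")
})

test_that("entropy reproduces the worked examples", {
  c12 <- partition_edges(cycle_g(12), "degree")
  for (sch in list(weight_scheme("randic", 1), weight_scheme("randic", -0.5),
                   weight_scheme("abc"), weight_scheme("ga"))) {
    expect_equal(partition_entropy(c12, sch)$entropy_value, log(12),
                 tolerance = 1e-12)
  }

  t6 <- printed_partition(family_spec("ZCS", 4, 4, 4), "degree")
  expect_equal(partition_entropy(t6, weight_scheme("randic", 1))$entropy_value,
               5.7200, tolerance = 5e-4)

  conv <- edge_partition(data.frame(a = 4L, b = 4L, count = 9L), "degree_sum")
  r <- partition_entropy(conv, weight_scheme("abc4"))
  expect_equal(r$entropy_value, log(9), tolerance = 1e-12)
  expect_equal(r$edge_total, 9)
  expect_equal(sum(r$per_class$prob_mass), 1, tolerance = 1e-12)
})

test_that("entropy from a graph matches the published H-family values", {
  ls <- generate_family(family_spec("H", 2, 2), op = "LS")
  expect_equal(entropy_from_graph(ls, weight_scheme("abc"))$entropy_value,
               3.8497, tolerance = 5e-4)
  expect_equal(entropy_from_graph(ls, weight_scheme("ga"))$entropy_value,
               3.8501, tolerance = 5e-4)
  c12 <- generate_family(family_spec("H", 1, 1), op = "LS")
  expect_equal(entropy_from_graph(c12, weight_scheme("ga"))$entropy_value,
               log(12), tolerance = 1e-12)
  expect_error(entropy_from_graph(molecular_graph(matrix(character(), ncol = 2),
                                                  vertices = "a"),
                                  weight_scheme("ga")),
               "no edges")
})

test_that("single-class partitions collapse to log |E| for every scheme", {
  schemes <- list(weight_scheme("randic", 1), weight_scheme("randic", -1),
                  weight_scheme("randic", 0.5), weight_scheme("abc"),
                  weight_scheme("ga"))
  one_class <- partition_edges(cycle_g(17), "degree")
  for (sch in schemes) {
    expect_equal(partition_entropy(one_class, sch)$entropy_value, log(17),
                 tolerance = 1e-12)
  }
  ds <- partition_edges(cycle_g(17), "degree_sum")
  for (sch in list(weight_scheme("abc4"), weight_scheme("ga5"))) {
    expect_equal(partition_entropy(ds, sch)$entropy_value, log(17),
                 tolerance = 1e-12)
  }
})

test_that("entropy is bounded by log |E| with equality iff weights tie", {
  specs <- list(family_spec("T", 4), family_spec("H", 3, 2),
                family_spec("ZCS", 4, 5, 4))
  schemes <- list(weight_scheme("randic", 1), weight_scheme("randic", -0.5),
                  weight_scheme("abc"), weight_scheme("ga"),
                  weight_scheme("abc4"), weight_scheme("ga5"))
  for (spec in specs) {
    g <- generate_family(spec, op = "LS")
    for (sch in schemes) {
      r <- entropy_from_graph(g, sch)
      expect_lte(r$entropy_value, log(r$edge_total) + 1e-9)
      expect_gte(r$entropy_value, 0)
    }
  }
})

test_that("Randic alpha = 0 gives exactly log |E|", {
  g <- generate_family(family_spec("T", 3), op = "LS")
  r <- entropy_from_graph(g, weight_scheme("randic", 0))
  expect_equal(r$index_value, r$edge_total)
  expect_equal(r$entropy_value, log(r$edge_total), tolerance = 1e-12)
})

test_that("entropy is invariant under global weight scaling", {
  p <- printed_partition(family_spec("ZCS", 5, 5, 5), "degree")
  alpha <- 0.5
  base <- partition_entropy(p, weight_scheme("randic", alpha))$entropy_value
  for (c_scale in c(0.01, 3, 1e4)) {
    w <- c_scale * (p$classes$a * p$classes$b)^alpha
    idx <- sum(p$classes$count * w)
    scaled <- log(idx) - sum(p$classes$count * w * log(w)) / idx
    expect_equal(scaled, base, tolerance = 1e-10)
  }
})

test_that("classed evaluation equals the per-edge evaluation", {
  specs <- list(family_spec("T", 3), family_spec("H", 2, 4),
                family_spec("ZCS", 4, 4, 4))
  schemes <- list(weight_scheme("randic", -0.5), weight_scheme("abc"),
                  weight_scheme("ga"), weight_scheme("abc4"),
                  weight_scheme("ga5"))
  for (spec in specs) {
    g <- generate_family(spec, op = "LS")
    for (sch in schemes) {
      expect_equal(entropy_from_graph(g, sch)$entropy_value,
                   per_edge_entropy(g, sch), tolerance = 1e-12)
    }
  }
})
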