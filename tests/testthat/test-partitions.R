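test_that("direct edge partitions match hand-counted examples", {
  expect_equal(class_counts(partition_edges(cycle_g(12), "degree")),
               c("2,2" = 12L))

  ls_t2 <- generate_family(family_spec("T", 2), op = "LS")
  expect_equal(class_counts(partition_edges(ls_t2, "degree")),
               c("2,2" = 15L, "2,3" = 6L, "3,3" = 15L))

  ls_h22 <- generate_family(family_spec("H", 2, 2), op = "LS")
  expect_equal(class_counts(partition_edges(ls_h22, "degree")),
               c("2,2" = 16L, "2,3" = 8L, "3,3" = 23L))

  p <- partition_edges(ls_h22, "degree_sum")
  expect_identical(p$basis, "degree_sum")
  expect_equal(p$total, igraph::ecount(ls_h22))
})

test_that("partition totals equal the edge count on seeded fixtures", {
  for (g in fixture_graphs(seed = 11, n = 12)) {
    for (basis in c("degree", "degree_sum")) {
      if (basis == "degree_sum" && igraph::ecount(g) == 0) next
      expect_equal(partition_edges(g, basis)$total, igraph::ecount(g))
    }
  }
})

test_that("printed partitions evaluate the published formulas verbatim", {
  expect_equal(
    class_counts(printed_partition(family_spec("T", 5), "degree")),
    c("2,2" = 16L, "2,3" = 24L, "3,3" = 114L)
  )
  expect_equal(
    class_counts(printed_partition(family_spec("ZCS", 4, 4, 4), "degree")),
    c("2,2" = 42L, "2,3" = 60L, "3,3" = 213L)
  )
  expect_equal(
    class_counts(printed_partition(family_spec("H", 1, 3), "degree_sum")),
    c("4,4" = 10L, "4,5" = 4L, "5,5" = 2L, "5,8" = 8L, "8,8" = 4L,
      "8,9" = 4L, "9,9" = 2L)
  )
  # the degree-sum table for T carries the y -> x substitution note
  p <- printed_partition(family_spec("T", 3), "degree_sum")
  expect_match(p$notes, "substituted")
})

test_that("printed partitions enforce the stated validity regimes", {
  expect_error(printed_partition(family_spec("T", 1), "degree_sum"),
               "x != 1")
  expect_error(printed_partition(family_spec("ZCS", 4, 4, 5), "degree_sum"),
               "x = y = z")
  expect_error(printed_partition(family_spec("H", 1, 1), "degree_sum"),
               "H\\(1, 1\\)")
  # H(2,1) drives the published (5,5) formula negative: error, not clamping
  expect_error(printed_partition(family_spec("H", 2, 1), "degree_sum"),
               "negative")
})

test_that("printed class sums match the printed |E(L(S))| where consistent", {
  for (x in 1:10) {
    for (y in c(1, 3, 10)) {
      spec <- family_spec("H", x, y)
      expect_equal(printed_partition(spec, "degree")$total,  # Table 3
                   9 * x * y + 4 * x + 4 * y - 5)
    }
  }
  for (spec in zcs_grid()) {
    s <- spec$x + spec$y + spec$z
    expect_equal(printed_partition(spec, "degree")$total, 39 * s - 153)
    if (spec$x == spec$y && spec$y == spec$z) {
      expect_equal(printed_partition(spec, "degree_sum")$total, 39 * s - 153)
    }
  }
})

test_that("printed class sums expose the published inconsistencies", {
  # endpoint-degree table for T is short by x + 3 edges
  for (x in 2:8) {
    expect_equal(printed_partition(family_spec("T", x), "degree")$total,
                 3 / 2 * (3 * x^2 + 7 * x - 2) - (x + 3))
  }
  # degree-sum table for H (x > 1) is short by 2(x + y) - 4 edges
  for (xy in list(c(2, 2), c(3, 5), c(10, 10))) {
    spec <- family_spec("H", xy[1], xy[2])
    expect_equal(printed_partition(spec, "degree_sum")$total,
                 9 * prod(xy) + 4 * sum(xy) - 5 - (2 * sum(xy) - 4))
  }
  # degree-sum table for H at x = 1 sums to 11y + 1, not 13y - 1
  expect_equal(printed_partition(family_spec("H", 1, 3), "degree_sum")$total,
               34)
})

test_that("benzenoid lift predicts the L(S) partition", {
  t2 <- triangular_benzenoid(2)
  lifted <- benzenoid_lift(partition_edges(t2, "degree"),
                           degree2_count = 9, degree3_count = 4)
  expect_equal(class_counts(lifted),
               c("2,2" = 15L, "2,3" = 6L, "3,3" = 15L))

  benzene <- hexagonal_parallelogram(1, 1)
  expect_equal(
    class_counts(benzenoid_lift(partition_edges(benzene, "degree"), 6, 0)),
    c("2,2" = 12L)
  )

  zp <- edge_partition(
    data.frame(a = c(2L, 2L, 3L), b = c(2L, 3L, 3L), count = c(6L, 60L, 51L)),
    basis = "degree"
  )
  expect_equal(class_counts(benzenoid_lift(zp, 36, 54)),
               c("2,2" = 42L, "2,3" = 60L, "3,3" = 213L))

  bad <- edge_partition(data.frame(a = 1L, b = 2L, count = 3L), "degree")
  expect_error(benzenoid_lift(bad, 1, 1), "degrees in \\{2, 3\\}")
})

test_that("lift identity holds across the family grids", {
  specs <- c(lapply(1:6, function(k) family_spec("T", k)),
             lapply(1:5, function(k) family_spec("H", k, 6 - k)),
             list(family_spec("ZCS", 4, 4, 4), family_spec("ZCS", 5, 6, 7)))
  for (spec in specs) {
    g <- generate_family(spec)
    d <- igraph::degree(g)
    lifted <- benzenoid_lift(partition_edges(g, "degree"),
                             sum(d == 2), sum(d == 3))
    direct <- partition_edges(line_of_subdivision(g), "degree")
    expect_true(compare_partitions(lifted, direct)$agree)
  }
})

test_that("partition comparison reports per-class deltas", {
  t2 <- family_spec("T", 2)
  printed <- printed_partition(t2, "degree")
  direct <- partition_edges(generate_family(t2, op = "LS"), "degree")
  cmp <- compare_partitions(printed, direct)
  expect_false(cmp$agree)
  expect_equal(cmp$total_a, 31)
  expect_equal(cmp$total_b, 36)
  d22 <- cmp$classes$delta[cmp$classes$a == 2 & cmp$classes$b == 2]
  expect_equal(d22, 5)  # printed 2(x+3) = 10 vs direct 3(x+3) = 15

  same <- compare_partitions(direct, direct)
  expect_true(same$agree)
  expect_true(all(same$classes$delta == 0))

  expect_error(
    compare_partitions(printed, partition_edges(generate_family(t2, op = "LS"),
                                                "degree_sum")),
    "different bases"
  )
})

test_that("edge_partition rejects invalid class tables", {
  expect_error(edge_partition(data.frame(a = 3L, b = 2L, count = 1L),
                              "degree"), "canonical")
  expect_error(edge_partition(data.frame(a = 2L, b = 2L, count = -1L),
                              "degree"), "negative")
  expect_error(edge_partition(data.frame(a = c(2L, 2L), b = c(2L, 2L),
                                         count = c(1L, 2L)), "degree"),
               "duplicated")
})
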