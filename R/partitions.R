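# Edge partitions by endpoint label, in two strictly separated modes:
# "direct" (counted on a constructed graph) and "printed" (the published
# closed-form class counts, evaluated as polynomials in the family
# parameters without consulting any graph).

#' Edge partition object
#'
#' A multiset of unordered label-pair classes with nonnegative counts.
#' The basis records what the labels are: endpoint degrees (`"degree"`)
#' or neighbour degree sums (`"degree_sum"`).
#'
#' @param classes data frame with integer columns `a`, `b` (canonical,
#'   `a <= b`) and `count`.
#' @param basis `"degree"` or `"degree_sum"`.
#' @param mode `"direct"` or `"printed"`.
#' @param notes optional character vector of caveats attached to the
#'   partition (e.g. a symbol substitution applied to a published row).
#' @return an object of class `edge_partition` with fields `classes`,
#'   `basis`, `total`, `mode`, `notes`.
#' @export
edge_partition <- function(classes, basis = c("degree", "degree_sum"),
                           mode = c("direct", "printed"), notes = character()) {
  basis <- match.arg(basis)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(classes), all(c("a", "b", "count") %in% names(classes)))
  classes <- classes[, c("a", "b", "count")]
  if (any(classes$a > classes$b)) {
    stop("class keys must be canonical: a <= b", call. = FALSE)
  }
  if (any(classes$count != round(classes$count))) {
    stop("class counts must be integers", call. = FALSE)
  }
  if (any(classes$count < 0)) {
    stop("negative class count: published formula evaluated outside its ",
         "validity regime", call. = FALSE)
  }
  if (anyDuplicated(paste(classes$a, classes$b))) {
    stop("duplicated class keys", call. = FALSE)
  }
  classes <- classes[order(classes$a, classes$b), , drop = FALSE]
  rownames(classes) <- NULL
  structure(
    list(classes = classes, basis = basis, total = sum(classes$count),
         mode = mode, notes = notes),
    class = "edge_partition"
  )
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("Edge partition (%s basis, %s mode), %d edges in %d classes\n",
              x$basis, x$mode, x$total, nrow(x$classes)))
  for (i in seq_len(nrow(x$classes))) {
    cat(sprintf("  (%d, %d): %d\n", x$classes$a[i], x$classes$b[i],
                x$classes$count[i]))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Partition the edges of a graph by endpoint labels
#'
#' Every edge is assigned to the class keyed by the sorted pair of its
#' endpoint labels: vertex degrees, or neighbour degree sums (computed on
#' the graph itself).
#'
#' @param g a molecular graph.
#' @param basis `"degree"` or `"degree_sum"`.
#' @return an [edge_partition()] in `"direct"` mode whose total equals
#'   `igraph::ecount(g)`.
#' @examples
#' c12 <- molecular_graph(cbind(1:12, c(2:12, 1)))
#' partition_edges(c12, "degree")  # single class (2, 2) with count 12
#' @export
partition_edges <- function(g, basis = c("degree", "degree_sum")) {
  basis <- match.arg(basis)
  g <- as_molecular_graph(g)
  lab <- if (basis == "degree") igraph::degree(g) else neighbor_degree_sum(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(e) == 0L) {
    return(edge_partition(
      data.frame(a = integer(), b = integer(), count = integer()),
      basis = basis
    ))
  }
  a <- pmin(lab[e[, 1L]], lab[e[, 2L]])
  b <- pmax(lab[e[, 1L]], lab[e[, 2L]])
  tab <- stats::aggregate(
    list(count = rep(1L, length(a))),
    by = list(a = as.integer(a), b = as.integer(b)),
    FUN = sum
  )
  edge_partition(tab, basis = basis)
}

# ---------------------------------------------------------------------------
# Published partition tables, verbatim.  Each entry returns the class
# counts as polynomials in the parameters; regime constraints are the ones
# stated alongside the tables.

.printed_T_degree <- function(x) {
  data.frame(
    a = c(2L, 2L, 3L), b = c(2L, 3L, 3L),
    count = c(2 * (x + 3), 6 * (x - 1), 1.5 * (3 * x^2 + x - 4))
  )
}

.printed_T_degsum <- function(x) {
  # the published (5,8) row reads 6(y - 1) in a single-parameter family;
  # x is substituted for y and the substitution is recorded as a note
  data.frame(
    a = c(4L, 4L, 5L, 5L, 8L, 8L, 9L),
    b = c(4L, 5L, 5L, 8L, 8L, 9L, 9L),
    count = c(9, 6, 3 * (x - 2), 6 * (x - 1), 3 * (x - 1), 6 * (x - 1),
              1.5 * (3 * x^2 - 5 * x + 2))
  )
}

.printed_H_degree <- function(x, y) {
  data.frame(
    a = c(2L, 2L, 3L), b = c(2L, 3L, 3L),
    count = c(2 * (x + y + 4), 4 * (x + y - 2), 9 * x * y - 2 * x - 2 * y - 5)
  )
}

.printed_H_degsum <- function(x, y) {
  data.frame(
    a = c(4L, 4L, 5L, 5L, 8L, 8L, 9L),
    b = c(4L, 5L, 5L, 8L, 8L, 9L, 9L),
    count = c(8, 8, 2 * (x + y - 4), 4 * (x + y - 2), 2 * (x + y - 2),
              2 * (x + y - 2), 9 * x * y - 8 * x - 8 * y + 7)
  )
}

.printed_H1_degsum <- function(y) {
  data.frame(
    a = c(4L, 4L, 5L, 5L, 8L, 8L, 9L),
    b = c(4L, 5L, 5L, 8L, 8L, 9L, 9L),
    count = c(10, 4, 2 * (y - 2), 4 * (y - 1), 2 * (y - 1), 2 * (y - 1),
              y - 1)
  )
}

.printed_ZCS_degree <- function(s) {
  data.frame(
    a = c(2L, 2L, 3L), b = c(2L, 3L, 3L),
    count = c(6 * (s - 5), 12 * (s - 7), 21 * s - 39)
  )
}

.printed_ZCS_degsum <- function(s) {
  data.frame(
    a = c(4L, 4L, 5L, 5L, 8L, 8L, 9L),
    b = c(4L, 5L, 5L, 8L, 8L, 9L, 9L),
    count = c(6, 12, 6 * (s - 8), 12 * (s - 7), 6 * (s - 9), 12 * (s - 5),
              3 * (s + 25))
  )
}

#' Published edge-partition class counts
#'
#' Evaluates the published closed-form partition tables of
#' `L(S(.))` for a family instance, without constructing any graph.
#' Regime constraints stated alongside the tables are enforced: the
#' degree-sum table for the triangular benzenoid requires `x != 1`, the
#' hexagonal parallelogram has separate degree-sum tables for `x > 1` and
#' `x = 1`, and the ZCS degree-sum table is stated only for
#' `x = y = z >= 4`.  A formula that evaluates to a negative count raises
#' an error rather than being clamped.
#'
#' @param spec a [family_spec()].
#' @param basis `"degree"` or `"degree_sum"`.
#' @return an [edge_partition()] in `"printed"` mode.
#' @examples
#' printed_partition(family_spec("ZCS", 4, 4, 4), "degree")
#' @export
printed_partition <- function(spec, basis = c("degree", "degree_sum")) {
  stopifnot(inherits(spec, "family_spec"))
  basis <- match.arg(basis)
  notes <- character()
  if (spec$family == "T") {
    if (basis == "degree") {
      cls <- .printed_T_degree(spec$x)
    } else {
      if (spec$x == 1L) {
        stop("the published degree-sum partition for the triangular ",
             "benzenoid is stated only for x != 1; at x = 1 the single ",
             "class {(4,4): 9} convention applies (see special_case_T_x1)",
             call. = FALSE)
      }
      cls <- .printed_T_degsum(spec$x)
      notes <- paste("published (5,8) row reads 6(y - 1);",
                     "x substituted for y")
    }
  } else if (spec$family == "H") {
    if (basis == "degree") {
      cls <- .printed_H_degree(spec$x, spec$y)
    } else if (spec$x > 1L) {
      cls <- .printed_H_degsum(spec$x, spec$y)
    } else {
      if (spec$y == 1L) {
        stop("no published degree-sum partition exists for H(1, 1)",
             call. = FALSE)
      }
      cls <- .printed_H1_degsum(spec$y)
    }
  } else {
    s <- spec$x + spec$y + spec$z
    if (basis == "degree") {
      cls <- .printed_ZCS_degree(s)
    } else {
      if (!(spec$x == spec$y && spec$y == spec$z && spec$x >= 4L)) {
        stop("the published degree-sum partition for ZCS is stated only ",
             "for x = y = z >= 4", call. = FALSE)
      }
      cls <- .printed_ZCS_degsum(s)
    }
  }
  cls <- cls[cls$count != 0, , drop = FALSE]
  edge_partition(cls, basis = basis, mode = "printed", notes = notes)
}

#' Predict the L(S(G)) partition from a benzenoid's own degree data
#'
#' For a benzenoid G (all degrees 2 or 3) with endpoint-degree classes
#' `m22, m23, m33` and `n2` / `n3` vertices of degree 2 / 3, the
#' endpoint-degree partition of `L(S(G))` is
#' `(2,2): m22 + n2`, `(2,3): m23`, `(3,3): m33 + 3 n3`.  Each edge of G
#' becomes a degree-`d(u)`/`d(v)` pair of adjacent line-graph vertices
#' joined through its subdivision point, and each degree-3 vertex of G
#' contributes a triangle of degree-3 line-graph vertices.
#'
#' @param partition_of_g endpoint-degree [edge_partition()] of the
#'   benzenoid itself (classes among (2,2), (2,3), (3,3)).
#' @param degree2_count,degree3_count numbers of degree-2 and degree-3
#'   vertices of the benzenoid.
#' @return the predicted endpoint-degree [edge_partition()] of `L(S(G))`.
#' @export
benzenoid_lift <- function(partition_of_g, degree2_count, degree3_count) {
  stopifnot(inherits(partition_of_g, "edge_partition"))
  if (partition_of_g$basis != "degree") {
    stop("`partition_of_g` must use the endpoint-degree basis", call. = FALSE)
  }
  cls <- partition_of_g$classes
  if (!all(cls$a %in% 2:3 & cls$b %in% 2:3)) {
    stop("benzenoid lift requires all degrees in {2, 3}", call. = FALSE)
  }
  if (degree2_count < 0 || degree3_count < 0) {
    stop("vertex counts must be nonnegative", call. = FALSE)
  }
  pick <- function(a, b) {
    i <- cls$a == a & cls$b == b
    if (any(i)) cls$count[i] else 0L
  }
  out <- data.frame(
    a = c(2L, 2L, 3L), b = c(2L, 3L, 3L),
    count = c(pick(2, 2) + degree2_count,
              pick(2, 3),
              pick(3, 3) + 3 * degree3_count)
  )
  out <- out[out$count != 0, , drop = FALSE]
  edge_partition(out, basis = "degree", mode = partition_of_g$mode)
}

#' Compare two edge partitions class by class
#'
#' @param a,b [edge_partition()] objects on the same basis.
#' @return an object of class `partition_comparison`: a per-class table of
#'   counts and deltas (`b` minus `a`), the totals, and an agreement flag.
#' @examples
#' t2 <- family_spec("T", 2)
#' cmp <- compare_partitions(
#'   printed_partition(t2, "degree"),
#'   partition_edges(generate_family(t2, op = "LS"), "degree")
#' )
#' cmp$agree
#' @export
compare_partitions <- function(a, b) {
  stopifnot(inherits(a, "edge_partition"), inherits(b, "edge_partition"))
  if (a$basis != b$basis) {
    stop("cannot compare partitions on different bases", call. = FALSE)
  }
  m <- merge(a$classes, b$classes, by = c("a", "b"), all = TRUE,
             suffixes = c("_a", "_b"))
  m$count_a[is.na(m$count_a)] <- 0L
  m$count_b[is.na(m$count_b)] <- 0L
  m$delta <- m$count_b - m$count_a
  m <- m[order(m$a, m$b), , drop = FALSE]
  rownames(m) <- NULL
  structure(
    list(basis = a$basis, classes = m,
         total_a = a$total, total_b = b$total,
         total_delta = b$total - a$total,
         agree = all(m$delta == 0L)),
    class = "partition_comparison"
  )
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("Partition comparison (%s basis): %s\n", x$basis,
              if (x$agree) "agree" else "DISAGREE"))
  print(x$classes, row.names = FALSE)
  cat(sprintf("  totals: %d vs %d (delta %+d)\n",
              x$total_a, x$total_b, x$total_delta))
  invisible(x)
}
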