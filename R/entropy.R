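# Edge-weight schemes, degree-based indices, and the graph entropy they
# induce.  For a weight w(e) > 0 on every edge, the index is
# I = sum_e w(e) and the entropy is the Shannon entropy (natural log) of
# the distribution p(e) = w(e) / I:
#
#   ENT = log(I) - (1/I) * sum_e w(e) log w(e).
#
# Weights depend on an edge only through the sorted pair of endpoint
# labels, so the sum collapses onto partition classes:
# ENT = log(I) - (1/I) * sum_i N_i w_i log w_i.

#' Weight scheme
#'
#' A named edge-weight function over a label pair (a, b), a <= b:
#' \describe{
#'   \item{randic}{\eqn{(ab)^\alpha}; endpoint degrees, exponent `alpha`.}
#'   \item{abc}{\eqn{\sqrt{(a+b-2)/(ab)}}; endpoint degrees.}
#'   \item{ga}{\eqn{2\sqrt{ab}/(a+b)}; endpoint degrees.}
#'   \item{abc4}{the ABC form applied to neighbour degree sums.}
#'   \item{ga5}{the GA form applied to neighbour degree sums.}
#' }
#'
#' @param name scheme name.
#' @param alpha Randic exponent; required iff `name = "randic"`.  The
#'   published tables use 1, -1, 1/2, -1/2, but any finite real is
#'   accepted.
#' @return an object of class `weight_scheme`.
#' @export
weight_scheme <- function(name = c("randic", "abc", "ga", "abc4", "ga5"),
                          alpha = NULL) {
  name <- match.arg(name)
  if (name == "randic") {
    if (is.null(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
      stop("the randic scheme requires a single finite `alpha`",
           call. = FALSE)
    }
  } else if (!is.null(alpha)) {
    stop("`alpha` is only meaningful for the randic scheme", call. = FALSE)
  }
  structure(list(name = name, alpha = alpha), class = "weight_scheme")
}

#' @export
format.weight_scheme <- function(x, ...) {
  if (x$name == "randic") sprintf("randic(alpha = %g)", x$alpha) else x$name
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Label basis a scheme applies to
#'
#' @param scheme a [weight_scheme()].
#' @return `"degree"` for randic/abc/ga, `"degree_sum"` for abc4/ga5.
#' @export
scheme_basis <- function(scheme) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (scheme$name %in% c("abc4", "ga5")) "degree_sum" else "degree"
}

#' Edge weight of a label pair
#'
#' @param scheme a [weight_scheme()].
#' @param a,b label pair (vectorised); labels must be >= 1, and for the
#'   ABC-type schemes a + b > 2.
#' @return positive numeric vector of weights.
#' @examples
#' edge_weight(weight_scheme("ga"), 3, 3)         # 1
#' edge_weight(weight_scheme("abc"), 2, 2)        # sqrt(1/2)
#' edge_weight(weight_scheme("randic", -1), 2, 3) # 1/6
#' @export
edge_weight <- function(scheme, a, b) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (any(a < 1) || any(b < 1)) {
    stop("labels must be >= 1", call. = FALSE)
  }
  w <- switch(scheme$name,
    randic = (a * b)^scheme$alpha,
    abc = ,
    abc4 = {
      if (any(a + b <= 2)) {
        stop("ABC-type weights require a + b > 2", call. = FALSE)
      }
      sqrt((a + b - 2) / (a * b))
    },
    ga = ,
    ga5 = 2 * sqrt(a * b) / (a + b)
  )
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("edge weights must be finite and positive", call. = FALSE)
  }
  w
}

.check_scheme_partition <- function(p, scheme) {
  stopifnot(inherits(p, "edge_partition"), inherits(scheme, "weight_scheme"))
  if (p$basis != scheme_basis(scheme)) {
    stop(sprintf("scheme %s needs a %s-basis partition, got %s",
                 format(scheme), scheme_basis(scheme), p$basis),
         call. = FALSE)
  }
  if (p$total <= 0) {
    stop("empty partition: no edges to weight", call. = FALSE)
  }
}

#' Degree-based index of an edge partition
#'
#' The index associated with a weight scheme is the sum of edge weights,
#' \eqn{I = \sum_i N_i w_i} over the partition classes.
#'
#' @param p an [edge_partition()] whose basis matches the scheme.
#' @param scheme a [weight_scheme()].
#' @return the index value, a positive number.
#' @examples
#' c12 <- partition_edges(molecular_graph(cbind(1:12, c(2:12, 1))), "degree")
#' index_value(c12, weight_scheme("randic", 1))  # 12 * 4 = 48
#' @export
index_value <- function(p, scheme) {
  .check_scheme_partition(p, scheme)
  cls <- p$classes[p$classes$count > 0, , drop = FALSE]
  sum(cls$count * edge_weight(scheme, cls$a, cls$b))
}

#' Graph entropy of an edge partition
#'
#' Evaluates the entropy functional
#' \eqn{ENT = \log I - (1/I) \sum_i N_i w_i \log w_i} (natural logarithm)
#' over the classes with positive count; this is the Shannon entropy, in
#' nats, of the distribution assigning each edge the probability mass
#' \eqn{w_i / I}.
#'
#' @inheritParams index_value
#' @return an object of class `entropy_result` with fields `index_value`,
#'   `entropy_value`, `edge_total`, `scheme` and a `per_class` table of
#'   counts, weights and probability masses.
#' @examples
#' p <- printed_partition(family_spec("ZCS", 4, 4, 4), "degree")
#' partition_entropy(p, weight_scheme("randic", 1))  # 5.7200 nats
#' @export
partition_entropy <- function(p, scheme) {
  .check_scheme_partition(p, scheme)
  cls <- p$classes[p$classes$count > 0, , drop = FALSE]
  w <- edge_weight(scheme, cls$a, cls$b)
  idx <- sum(cls$count * w)
  ent <- log(idx) - sum(cls$count * w * log(w)) / idx
  per_class <- data.frame(
    a = cls$a, b = cls$b, count = cls$count, weight = w,
    prob_mass = cls$count * w / idx
  )
  rownames(per_class) <- NULL
  total <- sum(cls$count)
  stopifnot(abs(sum(per_class$prob_mass) - 1) <= 1e-9,
            ent >= -1e-9, ent <= log(total) + 1e-9)
  structure(
    list(index_value = idx, entropy_value = ent, edge_total = total,
         scheme = scheme, basis = p$basis, mode = p$mode,
         per_class = per_class),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s: index = %.*f, entropy = %.*f nats (%d edges, %s mode)\n",
              format(x$scheme), digits, x$index_value, digits,
              x$entropy_value, x$edge_total, x$mode))
  invisible(x)
}

#' Graph entropy computed from a graph
#'
#' Partitions the edges of `g` on the basis the scheme requires and
#' evaluates the entropy functional; equivalent to, but much cheaper
#' than, the per-edge evaluation over all of `E(g)`.
#'
#' @param g a molecular graph with at least one edge.
#' @param scheme a [weight_scheme()].
#' @return an `entropy_result`.
#' @examples
#' benzene <- hexagonal_parallelogram(1, 1)
#' r <- entropy_from_graph(line_of_subdivision(benzene),
#'                         weight_scheme("ga"))
#' r$entropy_value  # log(12): all twelve edges carry equal weight
#' @export
entropy_from_graph <- function(g, scheme) {
  g <- as_molecular_graph(g)
  if (igraph::ecount(g) == 0L) {
    stop("graph has no edges", call. = FALSE)
  }
  partition_entropy(partition_edges(g, scheme_basis(scheme)), scheme)
}
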