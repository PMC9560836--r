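# Independent oracles and small builders used across the suite.

cycle_g <- function(n) molecular_graph(cbind(seq_len(n), c(seq_len(n)[-1], 1)))

path_g <- function(n) molecular_graph(cbind(seq_len(n - 1), 2:n))

# O(m^2) all-pairs shared-endpoint line graph, independent of
# igraph::make_line_graph
brute_force_line_graph <- function(g) {
  e <- igraph::as_edgelist(g, names = TRUE)
  m <- nrow(e)
  lab <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "~")
  pairs <- NULL
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (length(intersect(e[i, ], e[j, ])) == 1L) {
          pairs <- rbind(pairs, c(lab[i], lab[j]))
        }
      }
    }
  }
  molecular_graph(if (is.null(pairs)) matrix(character(), ncol = 2) else pairs,
                  vertices = lab)
}

canonical_edges <- function(g) {
  e <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(e) == 0L) return(character())
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# per-edge evaluation of the entropy functional, without any classing
per_edge_entropy <- function(g, scheme) {
  lab <- if (scheme_basis(scheme) == "degree") {
    igraph::degree(g)
  } else {
    neighbor_degree_sum(g)
  }
  e <- igraph::as_edgelist(g, names = FALSE)
  w <- edge_weight(scheme, pmin(lab[e[, 1]], lab[e[, 2]]),
                   pmax(lab[e[, 1]], lab[e[, 2]]))
  idx <- sum(w)
  log(idx) - sum(w * log(w)) / idx
}

# class counts of a partition as a named vector "a,b" -> count
class_counts <- function(p) {
  stats::setNames(p$classes$count, paste(p$classes$a, p$classes$b, sep = ","))
}

# a representative ZCS parameter grid covering every s = x+y+z in 12..30,
# symmetric where possible plus asymmetric triples
zcs_grid <- function() {
  specs <- lapply(seq(4, 10), function(k) family_spec("ZCS", k, k, k))
  asym <- lapply(12:30, function(s) family_spec("ZCS", 4, 4, s - 8))
  c(specs, asym, list(family_spec("ZCS", 5, 7, 10), family_spec("ZCS", 4, 9, 6)))
}
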