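# Hexagonal-lattice generators for the three benzenoid families.
#
# Cells (hexagons) live on axial coordinates (q, r).  Corner vertices are
# identified by exact integer lattice coordinates so that fused hexagons
# share vertices and edges bit-reproducibly: the cartesian corner position
# of cell (q, r) is (0.5, sqrt(3)/2)-units times (3q + dx, 2r + q + dy)
# with the six integer offsets below.  Adjacent cells (axial difference in
# {(1,0),(0,1),(1,-1)} up to sign) then share exactly two corners, i.e. an
# edge, with no floating-point merging involved.

.hex_offsets <- matrix(
  c(2, 0, 1, 1, -1, 1, -2, 0, -1, -1, 1, -1),
  ncol = 2L, byrow = TRUE
)

# cells: data.frame with integer columns q, r -> molecular graph of the
# benzenoid obtained by fusing the unit hexagons of those cells
.benzenoid_from_cells <- function(cells) {
  stopifnot(nrow(cells) >= 1L)
  if (anyDuplicated(paste(cells$q, cells$r))) {
    stop("internal error: duplicated hexagon cells", call. = FALSE)
  }
  edges <- vector("list", nrow(cells))
  nxt <- c(2:6, 1L)
  for (i in seq_len(nrow(cells))) {
    vx <- 3L * cells$q[i] + .hex_offsets[, 1L]
    vy <- 2L * cells$r[i] + cells$q[i] + .hex_offsets[, 2L]
    nm <- sprintf("v%d_%d", vx, vy)
    edges[[i]] <- cbind(nm, nm[nxt])
  }
  ee <- do.call(rbind, edges)
  lo <- pmin(ee[, 1L], ee[, 2L])
  hi <- pmax(ee[, 1L], ee[, 2L])
  keep <- !duplicated(paste0(lo, "\r", hi))
  molecular_graph(cbind(lo[keep], hi[keep]))
}

.check_count <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer", what), call. = FALSE)
  }
  as.integer(x)
}

#' Triangular benzenoid T_x
#'
#' Rows of 1, 2, ..., x fused hexagons forming a triangle; `x` counts the
#' hexagons in the bottom row, for x(x+1)/2 hexagons in total.  The
#' resulting benzenoid has `x^2 + 4x + 1` vertices and `3x(x+3)/2` edges,
#' all degrees in \{2, 3\}.
#'
#' @param x number of hexagons in the bottom row (positive integer).
#' @return a molecular graph.
#' @examples
#' igraph::vcount(triangular_benzenoid(2))  # 13
#' @export
triangular_benzenoid <- function(x) {
  x <- .check_count(x, "x")
  cells <- expand.grid(q = 0:(x - 1L), r = 0:(x - 1L))
  .benzenoid_from_cells(cells[cells$q + cells$r <= x - 1L, , drop = FALSE])
}

#' Hexagonal parallelogram H(x, y)
#'
#' An x-by-y rhombus of fused hexagons (x hexagons per row, y per column).
#' The benzenoid has `2(x + y + xy)` vertices and `3xy + 2x + 2y - 1`
#' edges; H(1, 1) is benzene.
#'
#' @param x,y numbers of hexagons per row and per column (positive
#'   integers).
#' @return a molecular graph.
#' @export
hexagonal_parallelogram <- function(x, y) {
  x <- .check_count(x, "x")
  y <- .check_count(y, "y")
  .benzenoid_from_cells(expand.grid(q = 0:(x - 1L), r = 0:(y - 1L)))
}

# Cell layout for the zigzag-edge coronoid fused with starphene.
#
# The coronoid is the ring of cells along the boundary of the hexagonal
# region {0 <= r, 0 <= q + r <= x + y - 2, 1 - z <= q <= x - 1,
# r <= y + z - 2}, whose six sides contain x, y, z, x, y, z cells.  The
# starphene is a central cell at (0, y - 1) with three straight acene arms
# of x - 2, y - 2 and z - 2 cells, each docking into one of the three
# alternate ring corners so that the arm tip shares three consecutive
# edges with the ring (the pericondensed junction).  This realisation is
# validated against the structural contract (order, size, degree counts,
# endpoint-degree edge classes) after construction.
.zcs_cells <- function(x, y, z) {
  ring <- rbind(
    cbind(0:(x - 1L), 0L),                                  # bottom
    cbind(x - 1L, 1:(y - 1L)),                              # lower right
    cbind(x - 1L - (1:(z - 1L)), y - 1L + (1:(z - 1L))),    # upper right
    cbind(x - z - (1:(x - 1L)), y + z - 2L),                # top
    cbind(1L - z, y + z - 2L - (1:(y - 1L))),               # upper left
    cbind(1L - z + (1:(z - 2L)), z - 1L - (1:(z - 2L)))     # lower left
  )
  star <- rbind(
    c(0L, y - 1L),                                          # hub
    cbind(0L, 1:(y - 2L)),                                  # arm to (0, 0)
    cbind(1:(x - 2L), y - 1L),                              # arm to lower right
    cbind(-(1:(z - 2L)), y - 1L + (1:(z - 2L)))             # arm to upper left
  )
  data.frame(q = c(ring[, 1L], star[, 1L]), r = c(ring[, 2L], star[, 2L]))
}

#' Zigzag-edge coronoid fused with starphene ZCS(x, y, z)
#'
#' A macrocyclic benzenoid: a coronoid ring whose six sides carry
#' x, y, z, x, y, z hexagons, fused with a three-armed starphene filling
#' its cavity.  With `s = x + y + z` the graph has `12s - 54` vertices and
#' `15s - 63` edges, `6s - 36` vertices of degree 2 and `6s - 18` of
#' degree 3, and endpoint-degree edge classes
#' `(2,2): 6`, `(2,3): 12s - 84`, `(3,3): 3s + 15`.  The construction is
#' checked against all of these counts before the graph is returned.
#'
#' @param x,y,z side lengths of the coronoid ring (integers, all at least
#'   4, the regime in which the published partition tables are stated).
#' @return a molecular graph.
#' @examples
#' igraph::ecount(zcs(4, 4, 4))  # 117
#' @export
zcs <- function(x, y, z) {
  x <- .check_count(x, "x")
  y <- .check_count(y, "y")
  z <- .check_count(z, "z")
  if (x < 4L || y < 4L || z < 4L) {
    stop("ZCS(x, y, z) is only constructed for x, y, z >= 4, ",
         "the validated parameter regime", call. = FALSE)
  }
  g <- .benzenoid_from_cells(.zcs_cells(x, y, z))
  s <- x + y + z
  deg <- igraph::degree(g)
  p <- partition_edges(g, basis = "degree")
  cls <- stats::setNames(p$classes$count,
                         paste(p$classes$a, p$classes$b, sep = ","))
  ok <- igraph::vcount(g) == 12L * s - 54L &&
    igraph::ecount(g) == 15L * s - 63L &&
    sum(deg == 2L) == 6L * s - 36L &&
    sum(deg == 3L) == 6L * s - 18L &&
    identical(sort(names(cls)), c("2,2", "2,3", "3,3")) &&
    cls[["2,2"]] == 6L && cls[["2,3"]] == 12L * s - 84L &&
    cls[["3,3"]] == 3L * s + 15L
  if (!ok) {
    stop("internal error: ZCS construction violates its structural contract",
         call. = FALSE)
  }
  g
}

#' Family specification
#'
#' A tagged set of parameters identifying one instance of a benzenoid
#' family: `"T"` (triangular benzenoid, parameter `x`), `"H"` (hexagonal
#' parallelogram, `x`, `y`) or `"ZCS"` (zigzag-edge coronoid fused with
#' starphene, `x`, `y`, `z`).
#'
#' @param family one of `"T"`, `"H"`, `"ZCS"`.
#' @param x,y,z positive integer parameters; `y` is required for `"H"` and
#'   `"ZCS"`, `z` for `"ZCS"`.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(family = c("T", "H", "ZCS"), x, y = NULL, z = NULL) {
  family <- match.arg(family)
  x <- .check_count(x, "x")
  spec <- list(family = family, x = x)
  if (family %in% c("H", "ZCS")) {
    if (is.null(y)) stop("family ", family, " requires `y`", call. = FALSE)
    spec$y <- .check_count(y, "y")
  } else if (!is.null(y)) {
    stop("family T takes only `x`", call. = FALSE)
  }
  if (family == "ZCS") {
    if (is.null(z)) stop("family ZCS requires `z`", call. = FALSE)
    spec$z <- .check_count(z, "z")
  } else if (!is.null(z)) {
    stop("`z` is only used by family ZCS", call. = FALSE)
  }
  structure(spec, class = "family_spec")
}

#' @export
format.family_spec <- function(x, ...) {
  sprintf("%s(%s)", x$family,
          paste(unlist(x[c("x", "y", "z")]), collapse = ", "))
}

#' @export
print.family_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build the graph of a family instance
#'
#' @param spec a [family_spec()].
#' @param op structural operator to apply: `"none"` for the benzenoid
#'   itself, `"S"` for its subdivision, `"LS"` for the line graph of the
#'   subdivision.
#' @return a molecular graph.
#' @examples
#' g <- generate_family(family_spec("T", 2), op = "LS")
#' igraph::vcount(g)  # 30
#' @export
generate_family <- function(spec, op = c("none", "S", "LS")) {
  stopifnot(inherits(spec, "family_spec"))
  op <- match.arg(op)
  g <- switch(spec$family,
    T   = triangular_benzenoid(spec$x),
    H   = hexagonal_parallelogram(spec$x, spec$y),
    ZCS = zcs(spec$x, spec$y, spec$z)
  )
  switch(op, none = g, S = subdivision(g), LS = line_of_subdivision(g))
}
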