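#' @include AllClasses.R
NULL

# Icosahedron with unit circumradius (up to scaling).
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  coords <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  triangles <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(coords = coords, triangles = triangles)
}

# One 4-to-1 subdivision pass; midpoints shared through a keyed cache.
.subdivideOnce <- function(coords, triangles) {
  nv <- nrow(coords)
  midKey <- new.env(parent = emptyenv())
  newCoords <- list()
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    idx <- midKey[[key]]
    if (is.null(idx)) {
      newCoords[[length(newCoords) + 1L]] <<- (coords[a, ] + coords[b, ]) / 2
      idx <- nv + length(newCoords)
      midKey[[key]] <- idx
    }
    idx
  }
  out <- matrix(0L, nrow = 4L * nrow(triangles), ncol = 3L)
  for (f in seq_len(nrow(triangles))) {
    v <- triangles[f, ]
    ab <- midpoint(v[1], v[2]); bc <- midpoint(v[2], v[3])
    ca <- midpoint(v[3], v[1])
    out[4L * f - 3L, ] <- c(v[1], ab, ca)
    out[4L * f - 2L, ] <- c(v[2], bc, ab)
    out[4L * f - 1L, ] <- c(v[3], ca, bc)
    out[4L * f, ]      <- c(ab, bc, ca)
  }
  list(coords = rbind(coords, do.call(rbind, newCoords)), triangles = out)
}

#' Generate a two-hemisphere icosphere cortical surface
#'
#' Builds one icosphere per hemisphere by recursive 4-to-1 subdivision of an
#' icosahedron projected onto a sphere of the requested radius. Each
#' hemisphere has \eqn{V = 10 \cdot 4^{s} + 2} vertices; the right
#' hemisphere is the mirror image of the left (x negated, winding flipped so
#' both stay outward-oriented). The spheres stand in for a downsampled
#' standard cortical grid at desk scale.
#'
#' @param subdivisions non-negative integer number of subdivision passes
#'   (at most 6, guarding against memory blow-up).
#' @param radius_mm sphere radius in mm; the default of 100 mm gives each
#'   hemisphere an area close to a human cortical hemisphere.
#' @return a [CorticalSurface].
#' @examples
#' surf <- makeMesh(2)
#' nVertices(surf)  # 2 * 162
#' @export
makeMesh <- function(subdivisions = 2L, radius_mm = 100) {
  if (subdivisions < 0 || subdivisions > 6)
    stop("subdivisions must be in 0..6", call. = FALSE)
  if (radius_mm <= 0) stop("radius_mm must be positive", call. = FALSE)
  m <- .icosahedron()
  s <- 0L
  while (s < subdivisions) {
    m <- .subdivideOnce(m$coords, m$triangles)
    s <- s + 1L
  }
  r <- sqrt(rowSums(m$coords^2))
  coords <- m$coords * (radius_mm / r)
  tri <- matrix(as.integer(m$triangles), ncol = 3L)
  left <- new("CorticalMesh", hemisphere = "left", coords = coords,
              triangles = tri)
  rightCoords <- coords
  rightCoords[, 1] <- -rightCoords[, 1]
  right <- new("CorticalMesh", hemisphere = "right", coords = rightCoords,
               triangles = tri[, c(1L, 3L, 2L), drop = FALSE])
  new("CorticalSurface", left = left, right = right)
}

#' Edge list of a mesh
#'
#' @param mesh a [CorticalMesh].
#' @return integer matrix (E x 2) of unique vertex index pairs, first index
#'   smaller.
#' @export
meshEdges <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Vertex adjacency list of a mesh
#'
#' @param mesh a [CorticalMesh].
#' @return list of sorted integer neighbour vectors, one per vertex.
#' @export
meshAdjacency <- function(mesh) {
  e <- meshEdges(mesh)
  v <- nVertices(mesh)
  adj <- split(c(e[, 2], e[, 1]),
               factor(c(e[, 1], e[, 2]), levels = seq_len(v)))
  lapply(adj, function(x) sort(unique(as.integer(x))))
}

#' Whole-surface adjacency list
#'
#' Block adjacency over both hemispheres, right-hemisphere vertex ids offset
#' by the left vertex count. Hemispheres are not connected to each other.
#'
#' @param surface a [CorticalSurface].
#' @return list of integer neighbour vectors over all vertices.
#' @export
surfaceAdjacency <- function(surface) {
  vl <- nVertices(surface@left)
  c(meshAdjacency(surface@left),
    lapply(meshAdjacency(surface@right), function(x) x + vl))
}

#' @rdname meshAreas
#' @export
triangleAreas <- function(mesh) {
  co <- mesh@coords
  tr <- mesh@triangles
  a <- co[tr[, 2], , drop = FALSE] - co[tr[, 1], , drop = FALSE]
  b <- co[tr[, 3], , drop = FALSE] - co[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Mesh and vertex areas
#'
#' `triangleAreas` gives the area of each triangle; `vertexAreas` assigns a
#' third of each adjacent triangle's area to its vertices (so vertex areas
#' sum to the surface area); `surfaceVertexAreas` concatenates both
#' hemispheres.
#'
#' @param mesh a [CorticalMesh].
#' @param surface a [CorticalSurface].
#' @return numeric vector of areas in mm^2.
#' @name meshAreas
#' @export
vertexAreas <- function(mesh) {
  ta <- triangleAreas(mesh)
  va <- numeric(nVertices(mesh))
  tr <- mesh@triangles
  for (j in 1:3) {
    acc <- rowsum(ta, tr[, j])
    idx <- as.integer(rownames(acc))
    va[idx] <- va[idx] + acc[, 1] / 3
  }
  va
}

#' @rdname meshAreas
#' @export
surfaceVertexAreas <- function(surface)
  c(vertexAreas(surface@left), vertexAreas(surface@right))

#' Euler characteristic V - E + F
#'
#' Equals 2 for every closed orientable genus-0 mesh, e.g. each generated
#' hemisphere.
#' @param mesh a [CorticalMesh].
#' @return integer scalar.
#' @export
eulerCharacteristic <- function(mesh)
  nVertices(mesh) - nrow(meshEdges(mesh)) + nrow(mesh@triangles)

# Edge lengths matching meshEdges() row order.
.edgeLengths <- function(mesh) {
  e <- meshEdges(mesh)
  d <- mesh@coords[e[, 1], , drop = FALSE] - mesh@coords[e[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}
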