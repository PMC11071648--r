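#' @include mesh.R
NULL

.yeo7 <- c("Visual", "SomMot", "DorsAttn", "VentAttn", "Limbic",
           "Control", "Default")

# Multi-source breadth-first label growth over an adjacency list.
.growPatches <- function(adj, seeds) {
  lab <- integer(length(adj))
  lab[seeds] <- seq_along(seeds)
  frontier <- seeds
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (lab[u] == 0L) {
          lab[u] <- lab[v]
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  lab
}

#' Grow a contiguous network parcellation
#'
#' Partitions each hemisphere into `k` spatially contiguous patches by
#' breadth-first expansion from `k` random seed vertices. Labels are
#' mirrored across hemispheres (the right hemisphere reuses the left's
#' patch assignment, which is exact because the two meshes share topology).
#' With the default `k = 7` the patches are named after the seven canonical
#' intrinsic networks (Visual, SomMot, DorsAttn, VentAttn, Limbic, Control,
#' Default).
#'
#' @param surface a [CorticalSurface].
#' @param k number of networks per hemisphere (at most the per-hemisphere
#'   vertex count).
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return a [Parcellation] over all vertices (left hemisphere first).
#' @examples
#' parc <- makeParcellation(makeMesh(1), k = 7, seed = 1)
#' table(parcelLabels(parc))
#' @export
makeParcellation <- function(surface, k = 7L, seed = 1L) {
  vl <- nVertices(surface@left)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  if (k > vl)
    stop("k exceeds the per-hemisphere vertex count (", vl, ")",
         call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(vl, k)
  lab <- .growPatches(meshAdjacency(surface@left), seeds)
  nm <- if (k == 7L) .yeo7 else paste0("Network", seq_len(k))
  new("Parcellation", labels = c(lab, lab), networkNames = nm)
}
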