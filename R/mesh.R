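#' Triangulated surface mesh
#'
#' Constructor and validator for a triangle surface mesh. Vertices are in
#' metres. When `closed = TRUE` the mesh is required to be watertight
#' (every edge shared by exactly two triangles) and free of zero-area
#' triangles.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (m).
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @param name label for the mesh.
#' @param closed logical; enforce watertightness.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, name = "surface", closed = FALSE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle index out of range")
  areas <- triangle_areas(vertices, triangles)
  if (any(areas <= 0))
    stop("degenerate (zero-area) triangle in surface mesh '", name, "'")
  m <- structure(list(vertices = vertices, triangles = triangles,
                      name = name, closed = closed),
                 class = "surface_mesh")
  if (closed && !is_watertight(m))
    stop("surface mesh '", name, "' flagged closed but is not watertight")
  m
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total area of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return total area (m^2).
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$triangles))

#' Watertightness check: every edge shared by exactly two triangles
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Mean triangle edge length of an isoparametric surface mesh
#'
#' Assumes the average triangle is equilateral: an equilateral triangle of
#' edge L has area (sqrt(3)/4) L^2, so equating this to the mean triangle
#' area A/n gives L = sqrt(4 A / (sqrt(3) n)). Volume meshing constrains the
#' maximum tetrahedral edge to twice this value so element aspect ratios
#' stay acceptable.
#'
#' @param A total surface area (m^2), > 0.
#' @param n number of triangles, >= 1.
#' @return mean edge length (m).
#' @examples
#' mean_edge_length(sqrt(3) / 4, 1) # unit equilateral triangle -> 1
#' @export
mean_edge_length <- function(A, n) {
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A <= 0)
    stop("invalid argument: A must be a positive number")
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1)
    stop("invalid argument: n must be >= 1")
  sqrt(4 * A / (sqrt(3) * n))
}

#' Tetrahedral volume mesh
#'
#' @param nodes n x 3 matrix of node coordinates (m).
#' @param tets m x 4 integer matrix of node indices.
#' @param entity integer vector (length m) labelling each tet's entity
#'   (bone, cartilage, knee composite, bookend...).
#' @param entity_names optional named translation of entity codes.
#' @return object of class `volume_mesh`.
#' @export
volume_mesh <- function(nodes, tets, entity, entity_names = NULL) {
  nodes <- as.matrix(nodes)
  tets <- matrix(as.integer(as.matrix(tets)), ncol = 4)
  entity <- as.integer(entity)
  stopifnot(ncol(nodes) == 3, length(entity) == nrow(tets))
  v <- tet_volumes(nodes, tets)
  if (any(v <= 0))
    stop("volume mesh contains non-positive tet volumes (elements ",
         paste(utils::head(which(v <= 0), 5), collapse = ", "), ")")
  if (!all(seq_len(nrow(nodes)) %in% unique(as.vector(tets))))
    stop("volume mesh has unreferenced nodes")
  structure(list(nodes = nodes, tets = tets, entity = entity,
                 entity_names = entity_names, volumes = v),
            class = "volume_mesh")
}

#' Signed tetrahedron volumes
#' @param nodes node coordinates.
#' @param tets element connectivity.
#' @return numeric vector of volumes.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

# Kuhn subdivision of the unit cube into 6 tets. Every cell uses the same
# rule, so face diagonals match between neighbouring cells and the global
# mesh is conforming (interface nodes shared exactly).
.kuhn_perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Voxel-lattice tetrahedral mesher for labelled implicit solids
#'
#' Meshes a set of solids given as label functions on a shared cubic
#' lattice: each lattice cell whose centre lies inside a solid is split into
#' six tetrahedra (Kuhn subdivision). Because all entities are meshed on the
#' one lattice, interfaces between adjacent entities share nodes exactly,
#' which is how bonded contact is realized downstream.
#'
#' @param label_fun function taking an n x 3 matrix of cell-centre
#'   coordinates and returning an integer label per point (0 = outside all
#'   solids).
#' @param lower,upper bounding box corners (length 3, m).
#' @param h lattice spacing (m).
#' @param entity_names optional named character translation of labels.
#' @return a `volume_mesh`.
#' @export
lattice_tet_mesh <- function(label_fun, lower, upper, h, entity_names = NULL) {
  nx <- max(1L, as.integer(ceiling((upper[1] - lower[1]) / h)))
  ny <- max(1L, as.integer(ceiling((upper[2] - lower[2]) / h)))
  nz <- max(1L, as.integer(ceiling((upper[3] - lower[3]) / h)))
  cx <- lower[1] + (seq_len(nx) - 0.5) * h
  cy <- lower[2] + (seq_len(ny) - 0.5) * h
  cz <- lower[3] + (seq_len(nz) - 0.5) * h
  centres <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  lab <- as.integer(label_fun(centres))
  keep <- which(lab > 0L)
  if (length(keep) == 0) stop("generation error: no lattice cell fell inside any solid")
  # cell integer coordinates (0-based)
  ijk <- cbind((keep - 1L) %% nx,
               ((keep - 1L) %/% nx) %% ny,
               (keep - 1L) %/% (nx * ny))
  # 8 cube corners per cell as global lattice-point keys
  corner_off <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))
  npx <- nx + 1L; npy <- ny + 1L
  corner_key <- function(ci, off) {
    (ci[, 1] + off[1]) + npx * ((ci[, 2] + off[2]) + npy * (ci[, 3] + off[3]))
  }
  keys8 <- sapply(seq_len(8), function(k) corner_key(ijk, corner_off[k, ]))
  if (is.null(dim(keys8))) keys8 <- matrix(keys8, nrow = 1)
  ukeys <- sort(unique(as.vector(keys8)))
  idx8 <- matrix(match(keys8, ukeys), nrow = nrow(ijk))
  # node coordinates from keys
  kx <- ukeys %% npx
  ky <- (ukeys %/% npx) %% npy
  kz <- ukeys %/% (npx * npy)
  nodes <- cbind(lower[1] + kx * h, lower[2] + ky * h, lower[3] + kz * h)
  # corner order in corner_off: (dx,dy,dz) with dx fastest
  corner_index <- function(dx, dy, dz) 1L + dx + 2L * dy + 4L * dz
  tets <- vector("list", 6)
  for (p in seq_along(.kuhn_perms)) {
    perm <- .kuhn_perms[[p]]
    steps <- diag(3)[perm, , drop = FALSE]
    v0 <- c(0, 0, 0)
    v1 <- v0 + steps[1, ]; v2 <- v1 + steps[2, ]; v3 <- c(1, 1, 1)
    ci <- c(corner_index(v0[1], v0[2], v0[3]), corner_index(v1[1], v1[2], v1[3]),
            corner_index(v2[1], v2[2], v2[3]), corner_index(v3[1], v3[2], v3[3]))
    tets[[p]] <- idx8[, ci, drop = FALSE]
  }
  tets <- do.call(rbind, tets)
  entity <- rep(lab[keep], 6)
  # fix orientation: swap last two nodes where signed volume is negative
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  volume_mesh(nodes, tets, entity, entity_names = entity_names)
}

#' Boundary triangles of (an entity of) a volume mesh
#'
#' Extracts the faces that belong to exactly one tetrahedron of the selected
#' entity set, oriented outward.
#'
#' @param vm a `volume_mesh`.
#' @param entities entity labels to include (default: all).
#' @param name label for the resulting surface mesh.
#' @return a `surface_mesh` (closed).
#' @export
boundary_surface <- function(vm, entities = NULL, name = "boundary") {
  sel <- if (is.null(entities)) seq_len(nrow(vm$tets)) else which(vm$entity %in% entities)
  if (length(sel) == 0) stop("no tets in selected entities")
  tt <- vm$tets[sel, , drop = FALSE]
  # faces opposite each vertex, ordered so outward normal is consistent
  f <- rbind(tt[, c(2, 3, 4)], tt[, c(1, 4, 3)], tt[, c(1, 2, 4)], tt[, c(1, 3, 2)])
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  bnd <- f[key %in% names(tab)[tab == 1L], , drop = FALSE]
  used <- sort(unique(as.vector(bnd)))
  remap <- integer(nrow(vm$nodes)); remap[used] <- seq_along(used)
  tri <- matrix(remap[bnd], ncol = 3)
  surface_mesh(vm$nodes[used, , drop = FALSE], tri, name = name, closed = TRUE)
}

#' Surface (boundary) node indices of an entity
#' @param vm a `volume_mesh`.
#' @param entities entity labels.
#' @return integer vector of node indices into `vm$nodes`.
#' @export
entity_surface_nodes <- function(vm, entities = NULL) {
  sel <- if (is.null(entities)) seq_len(nrow(vm$tets)) else which(vm$entity %in% entities)
  tt <- vm$tets[sel, , drop = FALSE]
  f <- rbind(tt[, c(2, 3, 4)], tt[, c(1, 4, 3)], tt[, c(1, 2, 4)], tt[, c(1, 3, 2)])
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  bnd <- f[key %in% names(tab)[tab == 1L], , drop = FALSE]
  sort(unique(as.vector(bnd)))
}

#' Node indices of an entity
#' @param vm a `volume_mesh`.
#' @param entities entity labels.
#' @return integer vector of node indices.
#' @export
entity_nodes <- function(vm, entities) {
  sort(unique(as.vector(vm$tets[vm$entity %in% entities, , drop = FALSE])))
}

#' Audit a volume mesh: positive volumes, node use, bonded interfaces
#'
#' Iterates all tets and all pairs of entities, checking that every tet has
#' positive volume, every node is referenced, and that adjacent entities
#' share interface nodes exactly (node-matched bonding).
#'
#' @param vm a `volume_mesh`.
#' @return list with fields `ok`, `min_volume`, `n_unreferenced`,
#'   `interfaces` (data.frame of entity pairs and shared-node counts).
#' @export
mesh_audit <- function(vm) {
  v <- tet_volumes(vm$nodes, vm$tets)
  unref <- sum(!(seq_len(nrow(vm$nodes)) %in% unique(as.vector(vm$tets))))
  ents <- sort(unique(vm$entity))
  pairs <- if (length(ents) > 1) utils::combn(ents, 2) else matrix(numeric(0), 2, 0)
  inter <- data.frame(a = integer(0), b = integer(0), shared_nodes = integer(0))
  nodes_by_ent <- lapply(ents, function(e) entity_nodes(vm, e))
  names(nodes_by_ent) <- as.character(ents)
  if (ncol(pairs) > 0) {
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      s <- length(intersect(nodes_by_ent[[as.character(a)]],
                            nodes_by_ent[[as.character(b)]]))
      inter <- rbind(inter, data.frame(a = a, b = b, shared_nodes = s))
    }
  }
  list(ok = all(v > 0) && unref == 0, min_volume = min(v),
       n_unreferenced = unref, interfaces = inter)
}

#' Maximum edge length over all tets
#' @param vm a `volume_mesh`.
#' @return maximum edge length (m).
#' @export
max_tet_edge <- function(vm) {
  tt <- vm$tets
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  mx <- 0
  for (p in pairs) {
    d <- vm$nodes[tt[, p[1]], , drop = FALSE] - vm$nodes[tt[, p[2]], , drop = FALSE]
    mx <- max(mx, sqrt(max(rowSums(d^2))))
  }
  mx
}

#' Nearest mesh node to a point
#' @param vm a `volume_mesh`.
#' @param p length-3 point.
#' @param candidates optional node subset.
#' @return node index.
#' @export
nearest_node <- function(vm, p, candidates = NULL) {
  idx <- if (is.null(candidates)) seq_len(nrow(vm$nodes)) else candidates
  d <- (vm$nodes[idx, 1] - p[1])^2 + (vm$nodes[idx, 2] - p[2])^2 +
       (vm$nodes[idx, 3] - p[3])^2
  idx[which.min(d)]
}
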