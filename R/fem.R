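#' Assemble the global stiffness operator for a tetrahedral mesh
#'
#' Constant-strain (4-node) tetrahedral elements with isotropic linear
#' elasticity per entity. Also builds the element stress operator (the
#' sparse map from nodal displacements to the six Voigt stress components of
#' every element) and lumped nodal masses, both reused across solves.
#'
#' Voigt order is (xx, yy, zz, xy, yz, zx) with engineering shear strains.
#'
#' @param vm a `volume_mesh`.
#' @param materials list of `material` objects, indexed by
#'   `material_of[entity]`.
#' @param material_of character vector mapping entity code to material name.
#' @return list with `K` (dgCMatrix, 3n x 3n), `S` (stress operator,
#'   6m x 3n), `nodal_mass`, `element_mass`, `centroids` (m x 3).
#' @export
assemble_stiffness <- function(vm, materials, material_of) {
  nodes <- vm$nodes; tets <- vm$tets
  n <- nrow(nodes); m <- nrow(tets)
  V <- vm$volumes
  if (any(V <= 0))
    stop("assembly error: inverted tet element(s) ",
         paste(utils::head(which(V <= 0), 5), collapse = ", "))
  x <- array(0, c(m, 4, 3))
  for (k in 1:4) x[, k, ] <- nodes[tets[, k], , drop = FALSE]
  # shape-function gradients: rows of inv(J) for nodes 2..4, node 1 = -sum
  e1 <- x[, 2, ] - x[, 1, ]; e2 <- x[, 3, ] - x[, 1, ]; e3 <- x[, 4, ] - x[, 1, ]
  # inverse of J = [e1; e2; e3] (rows), det = 6V
  det <- 6 * V
  inv <- array(0, c(m, 3, 3))
  inv[, 1, 1] <- (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) / det
  inv[, 1, 2] <- (e1[, 3] * e3[, 2] - e1[, 2] * e3[, 3]) / det
  inv[, 1, 3] <- (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]) / det
  inv[, 2, 1] <- (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) / det
  inv[, 2, 2] <- (e1[, 1] * e3[, 3] - e1[, 3] * e3[, 1]) / det
  inv[, 2, 3] <- (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]) / det
  inv[, 3, 1] <- (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]) / det
  inv[, 3, 2] <- (e1[, 2] * e3[, 1] - e1[, 1] * e3[, 2]) / det
  inv[, 3, 3] <- (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / det
  # grad of barycentric coordinate for node k (m x 3): node k+1 -> column k of inv
  grad <- array(0, c(m, 4, 3))
  for (k in 2:4) grad[, k, ] <- inv[, , k - 1]
  grad[, 1, ] <- -(grad[, 2, ] + grad[, 3, ] + grad[, 4, ])

  # material constants per element
  ent <- vm$entity
  lam <- mu <- rho <- numeric(m)
  for (e in sort(unique(ent))) {
    mt <- materials[[material_of[e]]]
    E <- mt$youngs_modulus; nu <- mt$poissons_ratio
    sel <- ent == e
    lam[sel] <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu[sel] <- E / (2 * (1 + nu))
    rho[sel] <- mt$density
  }

  # B matrix entries per element: for node k, dof d, the 6 Voigt rows.
  # B[row, 3(k-1)+d]: xx row gets g_x for d=x etc.; shear rows engineering.
  # Build element stiffness via Ke = V * B' D B using vectorized products.
  Brow <- function(k, d) {
    # returns m x 6 matrix: column of B for node k, dof d
    g <- grad[, k, ]
    out <- matrix(0, m, 6)
    if (d == 1) { out[, 1] <- g[, 1]; out[, 4] <- g[, 2]; out[, 6] <- g[, 3] }
    if (d == 2) { out[, 2] <- g[, 2]; out[, 4] <- g[, 1]; out[, 5] <- g[, 3] }
    if (d == 3) { out[, 3] <- g[, 3]; out[, 5] <- g[, 2]; out[, 6] <- g[, 1] }
    out
  }
  Bcols <- vector("list", 12)
  for (k in 1:4) for (d in 1:3) Bcols[[3 * (k - 1) + d]] <- Brow(k, d)
  # D * B columns (isotropic): D = lam*1x1' on normal block + 2mu*diag(normal)
  # + mu*diag(shear)
  DB <- lapply(Bcols, function(Bc) {
    tr <- Bc[, 1] + Bc[, 2] + Bc[, 3]
    cbind(lam * tr + 2 * mu * Bc[, 1],
          lam * tr + 2 * mu * Bc[, 2],
          lam * tr + 2 * mu * Bc[, 3],
          mu * Bc[, 4], mu * Bc[, 5], mu * Bc[, 6])
  })
  # triplets for K
  gdof <- matrix(0L, m, 12)
  for (k in 1:4) for (d in 1:3)
    gdof[, 3 * (k - 1) + d] <- 3L * (tets[, k] - 1L) + d
  ii <- jj <- vv <- vector("list", 144)
  idx <- 1
  for (a in 1:12) {
    Ba <- Bcols[[a]]
    for (b in 1:12) {
      kab <- V * rowSums(Ba * DB[[b]])
      ii[[idx]] <- gdof[, a]; jj[[idx]] <- gdof[, b]; vv[[idx]] <- kab
      idx <- idx + 1
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(3 * n, 3 * n))
  K <- (K + Matrix::t(K)) / 2  # symmetrize roundoff
  # stress operator: rows 6 per element, sigma = DB * u_e
  si <- sj <- sv <- vector("list", 12)
  for (a in 1:12) {
    DBa <- DB[[a]]
    rows <- rep((seq_len(m) - 1L) * 6L, 6) + rep(1:6, each = m)
    si[[a]] <- rows
    sj[[a]] <- rep(gdof[, a], 6)
    sv[[a]] <- as.vector(DBa)
  }
  S <- Matrix::sparseMatrix(i = unlist(si), j = unlist(sj), x = unlist(sv),
                            dims = c(6 * m, 3 * n))
  emass <- rho * V
  nodal_mass <- numeric(n)
  for (k in 1:4) {
    am <- tapply(emass / 4, tets[, k], sum)
    nodal_mass[as.integer(names(am))] <- nodal_mass[as.integer(names(am))] + am
  }
  centroids <- (x[, 1, ] + x[, 2, ] + x[, 3, ] + x[, 4, ]) / 4
  list(K = K, S = S, nodal_mass = nodal_mass, element_mass = emass,
       centroids = centroids)
}

#' Spread a point force evenly over nearby surface nodes
#'
#' Divides a force equally over the `spread_count` surface nodes nearest the
#' focal node; the vector sum equals the input force exactly.
#'
#' @param vm a `volume_mesh`.
#' @param force length-3 force (N).
#' @param focal_node node index at the centre of the spread.
#' @param surface_nodes candidate surface node indices.
#' @param spread_count number of nodes to spread over (default 20).
#' @return data.frame with `node` and force components `fx`, `fy`, `fz`.
#' @export
distribute_point_force <- function(vm, force, focal_node, surface_nodes,
                                   spread_count = 20) {
  if (length(surface_nodes) < spread_count) {
    warning("fewer surface nodes (", length(surface_nodes),
            ") than spread_count (", spread_count, "); using all")
    spread_count <- length(surface_nodes)
  }
  p <- vm$nodes[focal_node, ]
  d2 <- (vm$nodes[surface_nodes, 1] - p[1])^2 +
        (vm$nodes[surface_nodes, 2] - p[2])^2 +
        (vm$nodes[surface_nodes, 3] - p[3])^2
  sel <- surface_nodes[order(d2)[seq_len(spread_count)]]
  data.frame(node = sel,
             fx = force[1] / spread_count,
             fy = force[2] / spread_count,
             fz = force[3] / spread_count)
}

#' Statically equivalent nodal loads for a force at a remote point
#'
#' Distributes a force over a scoped node set such that the resultant equals
#' the force and the resultant moment about the remote point is zero, using
#' the minimum-norm (least-squares) distribution. This reproduces the
#' contract of a remote-force attachment -- the net force vector passes
#' through the remote point -- without multipoint constraint equations.
#'
#' @param vm a `volume_mesh`.
#' @param remote_point length-3 point (local frame).
#' @param force length-3 force (N).
#' @param scoped_nodes node indices receiving the load.
#' @return data.frame with `node`, `fx`, `fy`, `fz`.
#' @export
apply_remote_force <- function(vm, remote_point, force, scoped_nodes) {
  if (length(scoped_nodes) == 0) stop("invalid argument: empty node scope")
  equivalent_nodal_loads(vm$nodes[scoped_nodes, , drop = FALSE], remote_point,
                         force, c(0, 0, 0), scoped_nodes)
}

#' Statically equivalent nodal loads for a pure couple on a node set
#'
#' Minimum-norm nodal force set with zero resultant and a prescribed
#' resultant moment; used to apply a joint moment directly to the contact
#' surface of a bone.
#'
#' @param vm a `volume_mesh`.
#' @param moment length-3 couple (Nm).
#' @param scoped_nodes node indices.
#' @param about reference point for the moment (default node centroid).
#' @return data.frame with `node`, `fx`, `fy`, `fz`.
#' @export
apply_surface_moment <- function(vm, moment, scoped_nodes, about = NULL) {
  pts <- vm$nodes[scoped_nodes, , drop = FALSE]
  if (is.null(about)) about <- colMeans(pts)
  equivalent_nodal_loads(pts, about, c(0, 0, 0), moment, scoped_nodes)
}

# minimum-norm nodal loads with prescribed resultant force and moment about
# a reference point: f = A' (A A')^-1 [F; M], A the 6 x 3k equilibrium map
equivalent_nodal_loads <- function(pts, about, force, moment, node_ids) {
  k <- nrow(pts)
  r <- sweep(pts, 2, about)
  A <- matrix(0, 6, 3 * k)
  A[1, seq(1, 3 * k, 3)] <- 1
  A[2, seq(2, 3 * k, 3)] <- 1
  A[3, seq(3, 3 * k, 3)] <- 1
  # moment rows: (r x f) = [0 -rz ry; rz 0 -rx; -ry rx 0] f
  A[4, seq(2, 3 * k, 3)] <- -r[, 3]; A[4, seq(3, 3 * k, 3)] <- r[, 2]
  A[5, seq(1, 3 * k, 3)] <- r[, 3];  A[5, seq(3, 3 * k, 3)] <- -r[, 1]
  A[6, seq(1, 3 * k, 3)] <- -r[, 2]; A[6, seq(2, 3 * k, 3)] <- r[, 1]
  G <- A %*% t(A)
  rhs <- c(force, moment)
  lam <- tryCatch(solve(G, rhs), error = function(e)
    as.numeric(pinv_svd(G) %*% rhs))
  f <- as.numeric(t(A) %*% lam)
  data.frame(node = node_ids, fx = f[seq(1, 3 * k, 3)],
             fy = f[seq(2, 3 * k, 3)], fz = f[seq(3, 3 * k, 3)])
}

#' Inertia-relief correction loads
#'
#' Computes mass-proportional body loads (a uniform acceleration plus an
#' angular term about the model centre of mass) that cancel the net force
#' and net moment of an applied load set, so an (effectively) unconstrained
#' static model carries no rigid-body resultant.
#'
#' @param vm a `volume_mesh`.
#' @param nodal_mass lumped nodal masses (kg).
#' @param loads data.frame with `node`, `fx`, `fy`, `fz`.
#' @return data.frame of correction loads in the same format.
#' @export
inertia_relief <- function(vm, nodal_mass, loads) {
  M <- sum(nodal_mass)
  if (M <= 0) stop("invalid model: zero total mass")
  com <- colSums(vm$nodes * nodal_mass) / M
  Fnet <- c(sum(loads$fx), sum(loads$fy), sum(loads$fz))
  r <- sweep(vm$nodes[loads$node, , drop = FALSE], 2, com)
  Mnet <- c(sum(r[, 2] * loads$fz - r[, 3] * loads$fy),
            sum(r[, 3] * loads$fx - r[, 1] * loads$fz),
            sum(r[, 1] * loads$fy - r[, 2] * loads$fx))
  rc <- sweep(vm$nodes, 2, com)
  # inertia tensor about COM (point masses)
  xx <- sum(nodal_mass * (rc[, 2]^2 + rc[, 3]^2))
  yy <- sum(nodal_mass * (rc[, 1]^2 + rc[, 3]^2))
  zz <- sum(nodal_mass * (rc[, 1]^2 + rc[, 2]^2))
  xy <- -sum(nodal_mass * rc[, 1] * rc[, 2])
  xz <- -sum(nodal_mass * rc[, 1] * rc[, 3])
  yz <- -sum(nodal_mass * rc[, 2] * rc[, 3])
  I <- matrix(c(xx, xy, xz, xy, yy, yz, xz, yz, zz), 3, 3)
  a <- -Fnet / M
  alpha <- tryCatch(solve(I, -Mnet), error = function(e)
    as.numeric(pinv_svd(I) %*% (-Mnet)))
  f <- nodal_mass * (matrix(a, nrow(vm$nodes), 3, byrow = TRUE) +
                     cbind(alpha[2] * rc[, 3] - alpha[3] * rc[, 2],
                           alpha[3] * rc[, 1] - alpha[1] * rc[, 3],
                           alpha[1] * rc[, 2] - alpha[2] * rc[, 1]))
  data.frame(node = seq_len(nrow(vm$nodes)), fx = f[, 1], fy = f[, 2],
             fz = f[, 3])
}

# net force and moment (about `about`) of a nodal load set
load_resultant <- function(vm, loads, about = c(0, 0, 0)) {
  Fnet <- c(sum(loads$fx), sum(loads$fy), sum(loads$fz))
  r <- sweep(vm$nodes[loads$node, , drop = FALSE], 2, about)
  Mnet <- c(sum(r[, 2] * loads$fz - r[, 3] * loads$fy),
            sum(r[, 3] * loads$fx - r[, 1] * loads$fz),
            sum(r[, 1] * loads$fy - r[, 2] * loads$fx))
  list(force = Fnet, moment = Mnet)
}

#' Build a reusable FE context (stiffness factorization) for an assembly
#'
#' Restrains all translations of the given node set, eliminates those DOFs
#' and Cholesky-factorizes the reduced stiffness once; subsequent solves for
#' different load vectors reuse the factorization.
#'
#' @param vm a `volume_mesh`.
#' @param materials list of materials.
#' @param material_of entity -> material name map.
#' @param restrained_nodes node indices fixed in all three translations.
#' @return list (class `fe_context`) with factorization and operators.
#' @export
fe_context <- function(vm, materials, material_of, restrained_nodes) {
  asm <- assemble_stiffness(vm, materials, material_of)
  n <- nrow(vm$nodes)
  fixed_dofs <- as.vector(rbind(3 * (restrained_nodes - 1) + 1,
                                3 * (restrained_nodes - 1) + 2,
                                3 * (restrained_nodes - 1) + 3))
  free_dofs <- setdiff(seq_len(3 * n), fixed_dofs)
  if (length(fixed_dofs) == 0)
    stop("rank-deficiency: no restrained nodes; rigid-body modes unconstrained")
  Kff <- asm$K[free_dofs, free_dofs]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, perm = TRUE)
  structure(list(mesh = vm, assembly = asm, fixed_dofs = fixed_dofs,
                 free_dofs = free_dofs, factor = fac,
                 restrained_nodes = restrained_nodes),
            class = "fe_context")
}

#' Solve a linear static load case on a prepared FE context
#'
#' Applies the nodal loads (with optional inertia-relief balancing), solves
#' for displacements, and recovers element (constant) stresses and nodal
#' stresses by volume-weighted averaging of adjacent elements.
#'
#' @param ctx an `fe_context`.
#' @param loads data.frame with `node`, `fx`, `fy`, `fz`.
#' @param use_inertia_relief add balancing body loads before solving.
#' @return object of class `stress_field`: `displacements` (n x 3),
#'   `element_stress` (m x 6 Voigt), `nodal_stress` (n x 6),
#'   `reactions` (restrained-node resultant), `loads` (as applied).
#' @export
solve_linear_static <- function(ctx, loads, use_inertia_relief = TRUE) {
  vm <- ctx$mesh
  n <- nrow(vm$nodes)
  if (any(loads$node < 1 | loads$node > n))
    stop("load references a node outside the mesh")
  if (use_inertia_relief) {
    corr <- inertia_relief(vm, ctx$assembly$nodal_mass, loads)
    loads <- rbind(loads, corr)
  }
  f <- rowsum_dense(loads, n)  # accumulate (nodes may repeat)
  uf <- as.numeric(Matrix::solve(ctx$factor, f[ctx$free_dofs]))
  u <- numeric(3 * n)
  u[ctx$free_dofs] <- uf
  sig_e <- matrix(as.numeric(ctx$assembly$S %*% u), ncol = 6, byrow = TRUE)
  # nodal recovery: volume-weighted average over adjacent elements
  vol <- vm$volumes
  nodal <- matrix(0, n, 6)
  wsum <- numeric(n)
  for (k in 1:4) {
    idx <- vm$tets[, k]
    for (cc in 1:6) {
      acc <- tapply(sig_e[, cc] * vol, idx, sum)
      nodal[as.integer(names(acc)), cc] <- nodal[as.integer(names(acc)), cc] + acc
    }
    ws <- tapply(vol, idx, sum)
    wsum[as.integer(names(ws))] <- wsum[as.integer(names(ws))] + ws
  }
  nodal <- nodal / wsum
  # reactions at restrained DOFs
  Kcf <- ctx$assembly$K[ctx$fixed_dofs, , drop = FALSE]
  reac <- as.numeric(Kcf %*% u) - f[ctx$fixed_dofs]
  structure(list(displacements = matrix(u, ncol = 3, byrow = TRUE),
                 element_stress = sig_e, nodal_stress = nodal,
                 reaction_dofs = ctx$fixed_dofs, reactions = reac,
                 applied = loads), class = "stress_field")
}

# accumulate a loads data.frame into a dense 3n force vector
rowsum_dense <- function(loads, n) {
  f <- numeric(3 * n)
  for (d in 1:3) {
    comp <- c("fx", "fy", "fz")[d]
    acc <- rowsum(loads[[comp]], loads$node)
    ids <- as.integer(rownames(acc))
    f[3 * (ids - 1) + d] <- acc[, 1]
  }
  f
}
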