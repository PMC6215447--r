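# Free degrees of freedom, in hierarchy order. Each has a joint, a rotation
# axis in the global frame at a given posture, and a sign linking the
# posture parameter to a right-handed rotation about that axis.
.free_dofs <- c("hip_extension", "hip_abduction", "hip_lar",
                "knee_flexion", "ankle_flexion", "mtp_angle")

dof_axis <- function(model, posed, dof) {
  p <- posed$posture
  tr <- posed$transforms
  jc <- joint_centres(posed, model)
  switch(dof,
    hip_extension = list(centre = jc["hip", ], axis = c(0, 1, 0), sign = -1,
                         distal = c("thigh", "shank", "tmt", "pes")),
    hip_abduction = list(centre = jc["hip", ],
                         axis = as.numeric(rot_y(-(90 + p$hip_extension)) %*% c(1, 0, 0)),
                         sign = -1, distal = c("thigh", "shank", "tmt", "pes")),
    hip_lar = list(centre = jc["hip", ],
                   axis = as.numeric(rot_y(-(90 + p$hip_extension)) %*%
                                     rot_x(-p$hip_abduction) %*% c(0, 0, 1)),
                   sign = -1, distal = c("thigh", "shank", "tmt", "pes")),
    knee_flexion = list(centre = jc["knee", ],
                        axis = as.numeric(tr$thigh$R %*% c(0, 1, 0)),
                        sign = 1, distal = c("shank", "tmt", "pes")),
    ankle_flexion = list(centre = jc["ankle", ],
                         axis = as.numeric(tr$shank$R %*% c(0, 1, 0)),
                         sign = -1, distal = c("tmt", "pes")),
    mtp_angle = list(centre = jc["mtp", ],
                     axis = as.numeric(tr$tmt$R %*% c(0, 1, 0)),
                     sign = -1, distal = c("pes")),
    stop("unknown degree of freedom: ", dof))
}

#' Posed actuator path
#'
#' Transforms an actuator's segment-local path points into the global frame
#' at a posture.
#'
#' @param actuator an actuator entry from a `limb_model`.
#' @param posed a `posed_limb`.
#' @return k x 3 matrix of global points; attribute `segments` gives hosts.
#' @export
actuator_path_points <- function(actuator, posed) {
  pts <- t(vapply(actuator$path, function(pt)
    apply_transform(posed$transforms[[pt$segment]], pt$p), numeric(3)))
  attr(pts, "segments") <- vapply(actuator$path, function(pt) pt$segment,
                                  character(1))
  pts
}

path_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

#' Tendon-excursion moment arm
#'
#' The moment arm of an actuator about a degree of freedom, computed as
#' r = -dL/dtheta by central finite difference of the posed path length over
#' the DOF angle (in radians). For a straight path tangent to a circle about
#' a hinge axis this equals the geometric lever arm; the excursion
#' definition generalizes it to via-point polylines.
#'
#' @param actuator an actuator entry from a `limb_model`.
#' @param model a `limb_model`.
#' @param post a `posture`.
#' @param dof one of the six free DOF names.
#' @param delta_deg half-width of the central difference (degrees).
#' @return signed moment arm (m).
#' @export
moment_arm <- function(actuator, model, post, dof, delta_deg = 0.25) {
  post <- as_posture(post)
  perturb <- function(d) {
    v <- unclass(post)[.free_dofs]
    v[[dof]] <- v[[dof]] + d
    do.call(posture, c(v, list(ranges = list())))
  }
  Lp <- path_length(actuator_path_points(
    actuator, pose_limb(model, perturb(delta_deg), check = FALSE)))
  Lm <- path_length(actuator_path_points(
    actuator, pose_limb(model, perturb(-delta_deg), check = FALSE)))
  -(Lp - Lm) / (2 * delta_deg * pi / 180)
}

#' Moment-arm matrix for all actuators and free DOFs
#' @param model a `limb_model`.
#' @param post a `posture`.
#' @param actuators subset of actuator names (default all).
#' @return 6 x n matrix, rows named by DOF, columns by actuator.
#' @export
moment_arm_matrix <- function(model, post, actuators = names(model$actuators)) {
  post <- as_posture(post)
  delta <- 0.25
  vals0 <- unclass(post)[.free_dofs]
  # pose cache: 12 perturbed poses
  lengths <- matrix(0, 2, length(actuators))
  R <- matrix(0, length(.free_dofs), length(actuators),
              dimnames = list(.free_dofs, actuators))
  for (i in seq_along(.free_dofs)) {
    for (sgn in c(1, -1)) {
      v <- vals0
      v[[.free_dofs[i]]] <- v[[.free_dofs[i]]] + sgn * delta
      posed <- pose_limb(model, do.call(posture, c(v, list(ranges = list()))),
                         check = FALSE)
      L <- vapply(actuators, function(nm)
        path_length(actuator_path_points(model$actuators[[nm]], posed)),
        numeric(1))
      if (sgn == 1) lengths[1, ] <- L else lengths[2, ] <- L
    }
    R[i, ] <- -(lengths[1, ] - lengths[2, ]) / (2 * delta * pi / 180)
  }
  R
}

#' Unit force directions along a posed actuator path
#'
#' Unit tangents of the polyline at the origin-side and insertion-side end
#' points (pointing away from the attachment, i.e. the direction the
#' attachment is pulled under tension), plus the net pull direction at each
#' via point.
#'
#' @param actuator an actuator entry.
#' @param posed a `posed_limb`.
#' @return list with `points`, `segments`, and `directions` (k x 3; row i is
#'   the direction of the force that tension applies at point i, unnormalized
#'   for via points where it is the vector sum of the two adjacent unit
#'   tangents; rows 1 and k are unit vectors).
#' @export
actuator_force_directions <- function(actuator, posed) {
  pts <- actuator_path_points(actuator, posed)
  k <- nrow(pts)
  if (k < 2) stop("degenerate path: fewer than 2 points")
  seglen <- sqrt(rowSums(diff(pts)^2))
  if (any(seglen == 0)) stop("degenerate path: zero-length segment")
  u <- diff(pts) / seglen   # unit vectors point i -> i+1
  dirs <- matrix(0, k, 3)
  dirs[1, ] <- u[1, ]                 # pulled toward the next point
  dirs[k, ] <- -u[k - 1, ]            # pulled back toward the previous point
  if (k > 2) for (i in 2:(k - 1)) dirs[i, ] <- u[i, ] - u[i - 1, ]
  list(points = pts, segments = attr(pts, "segments"), directions = dirs)
}

#' Construct the external loads for a posed limb
#'
#' A vertical ground reaction force of magnitude 1 BW applied at the pes
#' centroid (COP), together with the pes couple that restores global static
#' equilibrium: its mediolateral (x) component has magnitude
#' BW * |COP_y - COM_y| and its y component absorbs the small residual
#' anteroposterior COP-COM offset. Segment weights act at the posed segment
#' centres of mass.
#'
#' @param posed a `posed_limb`.
#' @param model a `limb_model`.
#' @return object of class `external_loads`: `grf`, `cop`, `m_x`, `m_y`,
#'   `couple` (vector applied to the pes), and per-segment weights.
#' @export
build_external_loads <- function(posed, model) {
  if (is.null(posed$com) || is.null(posed$cop))
    stop("invalid input: posed limb lacks COM/COP")
  bw <- model$bw
  grf <- c(0, 0, bw)
  m <- model$body_mass; g <- model$gravity
  m_x <- m * g * (posed$cop[2] - posed$com[2])
  m_y <- m * g * (posed$com[1] - posed$cop[1])
  # couple applied to the pes restoring equilibrium: cancel the moment of
  # gravity about the COP (the GRF contributes none there)
  couple <- c(-m_x, -m_y, 0)
  weights <- lapply(model$segments, function(s)
    list(force = c(0, 0, -s$mass * g), segment = s$name))
  structure(list(grf = grf, cop = posed$cop, m_x = m_x, m_y = m_y,
                 couple = couple, weights = weights),
            class = "external_loads")
}

# generalized external moment about each free DOF (virtual-work consistent)
external_generalized_moments <- function(model, posed, loads) {
  seg_keys <- c(pelvis = "pelvis", thigh = "thigh", shank = "shank",
                tmt = "tmt", pes = "pes")
  seg_com <- lapply(names(seg_keys), function(k)
    apply_transform(posed$transforms[[k]], model$segments[[k]]$com_local))
  names(seg_com) <- names(seg_keys)
  g <- model$gravity
  Q <- numeric(length(.free_dofs)); names(Q) <- .free_dofs
  for (i in seq_along(.free_dofs)) {
    d <- dof_axis(model, posed, .free_dofs[i])
    mom <- c(0, 0, 0)
    for (k in d$distal) {
      Fg <- c(0, 0, -model$segments[[k]]$mass * g)
      mom <- mom + cross3(seg_com[[k]] - d$centre, Fg)
    }
    if ("pes" %in% d$distal) {
      mom <- mom + cross3(posed$cop - d$centre, loads$grf) + loads$couple
    }
    Q[i] <- d$sign * sum(d$axis * mom)
  }
  Q
}

#' Static optimization of actuator activations
#'
#' Resolves actuator redundancy at a posed, externally loaded limb by
#' minimizing the sum of squared activations subject to moment balance at
#' each of the six free DOFs (hip x3, knee, ankle, MTP), activation bounds
#' 0 <= a <= 1, and a reserve actuator on the MTP row only, bounded at
#' +/- 1000 Nm and carrying a small penalty weight so it is recruited only
#' when the crossing muscles cannot balance the joint.
#'
#' @param model a `limb_model`.
#' @param posed a `posed_limb`.
#' @param loads an `external_loads` (default built from the posed limb).
#' @param reserve_weight objective weight on the squared reserve moment.
#' @return object of class `activation_solution`: activations, forces (N),
#'   `mtp_reserve` (Nm), objective, residuals per DOF.
#' @export
solve_static_optimization <- function(model, posed, loads = NULL,
                                      reserve_weight = 1e-6) {
  if (is.null(loads)) loads <- build_external_loads(posed, model)
  act_names <- names(model$actuators)[vapply(model$actuators,
                                             function(a) a$active, logical(1))]
  R <- moment_arm_matrix(model, posed$posture, act_names)
  fmax <- vapply(act_names, function(nm) model$actuators[[nm]]$f_max, numeric(1))
  Q <- external_generalized_moments(model, posed, loads)
  n <- length(act_names)
  A <- cbind(sweep(R, 2, fmax, `*`),
             reserve = as.numeric(.free_dofs == "mtp_angle"))
  b <- -Q
  w <- c(rep(1, n), reserve_weight)
  lb <- c(rep(0, n), -1000)
  ub <- c(rep(1, n), 1000)
  sol <- solve_box_eq_qp(w, A, b, lb, ub)
  resid <- as.numeric(A %*% sol$x) - b
  if (max(abs(resid)) > 1e-6 * max(1, max(abs(b)))) {
    bad <- .free_dofs[abs(resid) > 1e-6 * max(1, max(abs(b)))]
    stop("static optimization infeasible: moment balance violated at DOF(s) ",
         paste(bad, collapse = ", "),
         " (residuals ", paste(signif(resid[match(bad, .free_dofs)], 3),
                               collapse = ", "), " Nm)")
  }
  a <- sol$x[seq_len(n)]; names(a) <- act_names
  structure(list(activations = a, forces = a * fmax,
                 mtp_reserve = sol$x[n + 1],
                 objective = sum(a^2),
                 moment_arms = R, external_moments = Q,
                 residuals = resid), class = "activation_solution")
}

#' @export
print.activation_solution <- function(x, ...) {
  cat("Static optimization solution\n")
  cat(sprintf("  objective sum(a^2) = %.4f, MTP reserve = %.4f Nm\n",
              x$objective, x$mtp_reserve))
  top <- sort(x$activations, decreasing = TRUE)
  top <- top[top > 0.01]
  if (length(top)) {
    cat("  activations > 0.01:\n")
    for (nm in names(top)) cat(sprintf("    %-5s %.3f\n", nm, top[[nm]]))
  }
  invisible(x)
}

# point forces each actuator applies to each segment at a tension T
actuator_segment_forces <- function(model, posed, solution) {
  out <- list(pelvis = list(), thigh = list(), shank = list(),
              tmt = list(), pes = list())
  for (nm in names(solution$activations)) {
    Tn <- solution$forces[[nm]]
    if (Tn <= 0) next
    fd <- actuator_force_directions(model$actuators[[nm]], posed)
    for (i in seq_len(nrow(fd$points))) {
      seg <- fd$segments[i]
      f <- Tn * fd$directions[i, ]
      if (sum(abs(f)) == 0) next
      out[[seg]] <- c(out[[seg]], list(list(point = fd$points[i, ], force = f,
                                            actuator = nm)))
    }
  }
  out
}

#' Joint reaction forces and moments
#'
#' Quasi-static Newton-Euler balance of each segment, distal to proximal,
#' under gravity, actuator point forces (from the posed lines of action) and
#' the external pes loads. Reactions are the force and moment exerted on the
#' distal segment by its proximal neighbour, expressed in the global frame
#' about the joint centre.
#'
#' @param model a `limb_model`.
#' @param posed a `posed_limb`.
#' @param solution an `activation_solution`.
#' @param loads an `external_loads`.
#' @param tol equilibrium residual tolerance (N, Nm) for the consistency
#'   check on each segment.
#' @return object of class `joint_loads`: per joint, `force` (N) and
#'   `moment` (Nm) on the distal segment, plus per-segment residuals.
#' @export
joint_reactions <- function(model, posed, solution, loads, tol = 1e-4) {
  g <- model$gravity
  muscle <- actuator_segment_forces(model, posed, solution)
  jc <- joint_centres(posed, model)
  chain <- c("pes", "tmt", "shank", "thigh")
  joint_of <- c(pes = "mtp", tmt = "ankle", shank = "knee", thigh = "hip")
  react <- list()
  child_force <- c(0, 0, 0); child_moment <- c(0, 0, 0)
  child_point <- c(0, 0, 0)
  for (seg in chain) {
    jname <- joint_of[[seg]]
    centre <- jc[c(mtp = "mtp", ankle = "ankle", knee = "knee",
                   hip = "hip")[[jname]], ]
    Fsum <- c(0, 0, 0); Msum <- c(0, 0, 0)
    com <- apply_transform(posed$transforms[[seg]],
                           model$segments[[seg]]$com_local)
    W <- c(0, 0, -model$segments[[seg]]$mass * g)
    Fsum <- Fsum + W; Msum <- Msum + cross3(com - centre, W)
    for (mf in muscle[[seg]]) {
      Fsum <- Fsum + mf$force
      Msum <- Msum + cross3(mf$point - centre, mf$force)
    }
    if (seg == "pes") {
      Fsum <- Fsum + loads$grf
      Msum <- Msum + cross3(loads$cop - centre, loads$grf) + loads$couple
    } else {
      # reaction from the child segment: equal and opposite
      Fsum <- Fsum - child_force
      Msum <- Msum - child_moment - cross3(child_point - centre, child_force)
    }
    Freact <- -Fsum
    Mreact <- -Msum
    react[[jname]] <- list(force = Freact, moment = Mreact, centre = centre)
    child_force <- Freact; child_moment <- Mreact; child_point <- centre
  }
  # consistency: hip is a ball-and-socket and resists no moment
  if (norm3(react$hip$moment) > max(tol, 1e-6 * model$bw * 0.1)) {
    warning("hip reaction moment is non-zero (", signif(norm3(react$hip$moment), 3),
            " Nm); moment balance may be inconsistent")
  }
  structure(list(joints = react), class = "joint_loads")
}

#' @export
print.joint_loads <- function(x, ...) {
  cat("Joint reactions (global frame, on distal segment)\n")
  for (nm in names(x$joints)) {
    j <- x$joints[[nm]]
    cat(sprintf("  %-5s F = (%8.3f, %8.3f, %8.3f) N  M = (%8.4f, %8.4f, %8.4f) Nm\n",
                nm, j$force[1], j$force[2], j$force[3],
                j$moment[1], j$moment[2], j$moment[3]))
  }
  invisible(x)
}
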