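#' Fabric generation settings
#'
#' @param noise_sd angular noise standard deviation (degrees, >= 0).
#' @param seed integer seed for the noise stream.
#' @return list of class `fabric_gen_spec`.
#' @export
fabric_gen_spec <- function(noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fabric_gen_spec")
}

# rotate each axial vector about a random perpendicular axis by a
# folded-normal angle of scale sd_deg (axial-data noise model)
perturb_axes <- function(V, sd_deg, seed) {
  if (sd_deg <= 0) return(V)
  n <- nrow(V)
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed",
    envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  ang <- abs(stats::rnorm(n, 0, sd_deg))
  phi <- stats::runif(n, 0, 2 * pi)
  out <- V
  for (i in seq_len(n)) {
    v <- V[i, ]
    # orthonormal pair perpendicular to v
    a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit3(cross3(v, a))
    e2 <- cross3(v, e1)
    axis <- cos(phi[i]) * e1 + sin(phi[i]) * e2
    out[i, ] <- axial_canonical(as.numeric(rot_axis(axis, ang[i]) %*% v))
  }
  out
}

#' Forward-generate a fabric field from a known posture
#'
#' Runs the forward pipeline (statics, femur finite-element solve,
#' eigenanalysis) at a posture and takes the principal-stress directions as
#' the fabric: sigma3 (compressive) where compression dominates, sigma1
#' where tension dominates (|sigma1| > |sigma3|), mirroring the forward
#' direction of the trajectorial theory. Each axis is then perturbed by
#' seeded axial noise. Points are element centroids of the femur in its
#' local frame.
#'
#' Within the scored comparison regions the sampled component is the
#' region's own (sigma3 for the compressive femoral head and condyle), so a
#' zero-noise field scores exactly zero at the generating posture; outside
#' the regions the locally dominant component is used (sigma1 where tension
#' dominates, as on the anterior cnemial crest).
#'
#' @param model a `limb_model`.
#' @param post the generating `posture`.
#' @param spec a `fabric_gen_spec`.
#' @param regions scored regions (default [default_regions()]).
#' @return a `fabric_field` with provenance "synthetic-forward".
#' @export
fabric_from_posture <- function(model, post, spec = fabric_gen_spec(),
                                regions = default_regions(model)) {
  post <- as_posture(post)
  posed <- pose_limb(model, post)
  loads <- build_external_loads(posed, model)
  sol <- solve_static_optimization(model, posed, loads)
  jl <- joint_reactions(model, posed, sol, loads)
  sf <- solve_bone_fe(model, posed, sol, jl, "femur")
  pf <- bone_principal_field(model, "femur", sf)
  tension <- abs(pf$values[, 1]) > abs(pf$values[, 3])
  u1 <- pf$v3
  u1[tension, ] <- pf$v1[tension, , drop = FALSE]
  for (r in regions) {
    inside <- in_region(pf$points, r)
    comp <- switch(r$which, sigma1 = pf$v1, sigma3 = pf$v3, pf$v3)
    u1[inside, ] <- comp[inside, , drop = FALSE]
  }
  u1 <- perturb_axes(u1, spec$noise_sd, spec$seed)
  fabric_field(pf$points, u1, provenance = "synthetic-forward",
               valid = !pf$degenerate)
}

#' Analytic archetype fabric field
#'
#' Builds a fabric field from per-region axial directions, smoothly blended
#' between regions through the orientation tensor: at each sample point the
#' region axes are combined with Gaussian distance weights and the dominant
#' eigenvector taken, which interpolates monotonically in angle along a
#' path between two regions.
#'
#' @param points n x 3 sample locations (bone-local frame).
#' @param region_axes list of entries `list(centre=, axis=, scale=)`;
#'   `scale` is the Gaussian blend length (m, default 1.5x region spacing).
#' @return a `fabric_field` with provenance "archetype".
#' @export
archetype_fabric <- function(points, region_axes) {
  if (length(region_axes) == 0) stop("no region axes given")
  points <- as.matrix(points)
  n <- nrow(points)
  u1 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    M <- matrix(0, 3, 3)
    for (r in region_axes) {
      sc <- if (is.null(r$scale)) 0.01 else r$scale
      d2 <- sum((points[i, ] - r$centre)^2)
      w <- exp(-d2 / (2 * sc^2))
      a <- unit3(r$axis)
      M <- M + w * (a %o% a)
    }
    e <- eigen(M, symmetric = TRUE)
    u1[i, ] <- axial_canonical(e$vectors[, 1])
  }
  fabric_field(points, u1, provenance = "archetype")
}

#' Default archetype axes for the synthetic femur
#'
#' Femoral-head u1 inclined proximomedially; condylar u1 parallel to the
#' sagittal plane and steeply inclined. Values are in the femur-local frame
#' and are intended as a plausible stand-in for avian fabric patterns; they
#' are synthetic, not measured.
#'
#' @param model a `limb_model`.
#' @return list of region-axis entries for [archetype_fabric()].
#' @export
default_archetype_axes <- function(model) {
  hf <- model$articular$head_fit
  cf <- model$articular$med_condyle_fit
  list(
    head = list(centre = hf$centre + c(0, 0, hf$radius / 2),
                axis = unit3(c(0, 0.35, 0.9)), scale = 0.008),
    medial_condyle = list(centre = cf$centre,
                          axis = unit3(c(0.35, 0, 0.94)), scale = 0.008))
}
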