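voigt_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}

# deterministic axial sign convention: first component of magnitude above
# tolerance is made positive
axial_canonical <- function(v) {
  k <- which(abs(v) > 1e-12)
  if (length(k) == 0) return(v)
  if (v[k[1]] < 0) -v else v
}

#' Principal stresses of a symmetric 3x3 stress tensor
#'
#' Eigen-decomposition with eigenvalues sorted descending
#' (sigma1 >= sigma2 >= sigma3) and orthonormal axial eigenvectors under a
#' deterministic sign convention (first nonzero component positive).
#' Near-repeated eigenvalues are flagged degenerate, since the associated
#' directions are not meaningful.
#'
#' @param tensor 3x3 symmetric matrix (Pa), or length-6 Voigt vector
#'   (xx, yy, zz, xy, yz, zx).
#' @param sym_tol relative symmetry tolerance.
#' @return list with `values` (length 3), `vectors` (3x3, columns), and
#'   `degenerate` flag.
#' @export
principal_stresses <- function(tensor, sym_tol = 1e-8) {
  if (length(tensor) == 6) tensor <- voigt_to_tensor(tensor)
  nrm <- max(abs(tensor), 1e-300)
  if (max(abs(tensor - t(tensor))) > sym_tol * nrm * 10)
    stop("invalid tensor: not symmetric within tolerance")
  tensor <- (tensor + t(tensor)) / 2
  e <- eigen(tensor, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in 1:3) vecs[, k] <- axial_canonical(vecs[, k])
  degen <- (vals[1] - vals[2]) < 1e-6 * nrm || (vals[2] - vals[3]) < 1e-6 * nrm
  list(values = vals, vectors = vecs, degenerate = degen)
}

#' Principal field from a matrix of stress tensors
#'
#' Runs the per-point eigenanalysis over a field of Voigt stress rows.
#'
#' @param points n x 3 sample locations.
#' @param stress n x 6 Voigt stress rows.
#' @return object of class `principal_field`: `points`, `values` (n x 3),
#'   `v1`, `v2`, `v3` (n x 3 axial unit eigenvectors), `degenerate` flags.
#' @export
principal_field <- function(points, stress) {
  n <- nrow(stress)
  vals <- matrix(0, n, 3)
  v1 <- v2 <- v3 <- matrix(0, n, 3)
  degen <- logical(n)
  for (i in seq_len(n)) {
    ps <- principal_stresses(stress[i, ])
    vals[i, ] <- ps$values
    v1[i, ] <- ps$vectors[, 1]; v2[i, ] <- ps$vectors[, 2]
    v3[i, ] <- ps$vectors[, 3]
    degen[i] <- ps$degenerate
  }
  structure(list(points = points, values = vals, v1 = v1, v2 = v2, v3 = v3,
                 degenerate = degen), class = "principal_field")
}

#' Fabric field constructor
#'
#' Point-sampled unit axial vectors describing the primary direction of
#' trabecular alignment (u1). Axial semantics: v and -v are the same datum.
#'
#' @param points n x 3 sample locations (m).
#' @param u1 n x 3 unit axial vectors.
#' @param provenance one of "synthetic-forward", "archetype", "imported".
#' @param valid logical vector marking usable samples (forward-generated
#'   fields mark samples with degenerate source tensors invalid).
#' @return object of class `fabric_field`.
#' @export
fabric_field <- function(points, u1, provenance = "imported", valid = NULL) {
  points <- as.matrix(points); u1 <- as.matrix(u1)
  stopifnot(nrow(points) == nrow(u1), ncol(u1) == 3)
  if (is.null(valid)) valid <- rep(TRUE, nrow(u1))
  nrm <- sqrt(rowSums(u1^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("fabric vectors not unit length; normalizing")
    u1 <- u1 / nrm
  }
  structure(list(points = points, u1 = u1, provenance = provenance,
                 valid = valid),
            class = "fabric_field")
}

#' Spherical comparison region
#'
#' The two standard regions are the femoral head (radius one-half of the
#' sphere fitted to the head, centred just under the bone surface beneath
#' where the hip force arrives) and the medial femoral condyle (radius
#' one-third of the condyle sphere, at the anatomical centre of the
#' condyle).
#'
#' @param centre length-3 centre (m).
#' @param radius sphere radius (m), > 0.
#' @param name label.
#' @param which which directional quantity to compare in this region
#'   ("sigma3" or "sigma1" for stress, always u1 for fabric).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(centre, radius, name = "region", which = "sigma3") {
  if (!(radius > 0)) stop("region radius must be > 0")
  structure(list(centre = as.numeric(centre), radius = radius, name = name,
                 which = which), class = "region_spec")
}

in_region <- function(points, region) {
  (points[, 1] - region$centre[1])^2 + (points[, 2] - region$centre[2])^2 +
    (points[, 3] - region$centre[3])^2 <= region$radius^2
}

orientation_tensor_mean <- function(V) {
  M <- crossprod(V) / nrow(V)
  e <- eigen(M, symmetric = TRUE)
  if (e$values[1] - e$values[2] < 1e-10)
    warning("orientation tensor nearly isotropic; mean direction ill-defined")
  axial_canonical(e$vectors[, 1])
}

#' Mean axial direction of a field within a spherical region
#'
#' The dominant eigenvector of the orientation tensor (1/N) sum(v v') over
#' the in-region samples: the proper sign-free mean for axial data.
#' Degenerate (repeated-eigenvalue) stress samples are excluded.
#'
#' @param field a `principal_field` or `fabric_field`.
#' @param region a `region_spec`.
#' @param which "u1" (fabric), "sigma1" or "sigma3" (principal field);
#'   default picks `region$which` for principal fields, u1 for fabric.
#' @param min_samples minimum in-region sample count.
#' @return unit axial vector (length 3), attribute `n` = samples used.
#' @export
regional_mean_direction <- function(field, region, which = NULL,
                                    min_samples = 5) {
  inside <- in_region(field$points, region)
  if (inherits(field, "fabric_field")) {
    V <- field$u1[inside & field$valid, , drop = FALSE]
  } else {
    if (is.null(which)) which <- region$which
    keep <- inside & !field$degenerate
    V <- switch(which, sigma1 = field$v1, sigma3 = field$v3,
                sigma2 = field$v2,
                stop("unknown component: ", which))[keep, , drop = FALSE]
  }
  if (nrow(V) == 0) stop("empty region: no samples inside '", region$name, "'")
  if (nrow(V) < min_samples)
    stop("region '", region$name, "' has only ", nrow(V),
         " samples (need >= ", min_samples, ")")
  v <- orientation_tensor_mean(V)
  attr(v, "n") <- nrow(V)
  v
}

#' Angular deviation between two axial unit vectors
#'
#' arccos(|a . b|) in degrees, in [0, 90]; sign-free, as appropriate for
#' axial data (a and -a are the same direction).
#'
#' @param a,b unit 3-vectors.
#' @return angle in degrees.
#' @export
angular_deviation <- function(a, b) {
  na <- norm3(a); nb <- norm3(b)
  if (abs(na - 1) > 1e-6 || abs(nb - 1) > 1e-6) {
    warning("non-unit input to angular_deviation; normalizing")
  }
  d <- abs(sum((a / na) * (b / nb)))
  acos(min(1, d)) * 180 / pi
}

#' Alignment score between principal stresses and fabric over regions
#'
#' For each region, the angular deviation between the regional mean
#' principal-stress direction (sigma3 by default; sigma1 in
#' tension-dominated regions) and the regional mean fabric direction u1.
#' The scalar is the weighted mean of the per-region deviations; by default
#' the femoral-head region outweighs the medial-condyle region, mirroring
#' the priority given to the hip when ranking candidate postures.
#'
#' @param principal a `principal_field`.
#' @param fabric a `fabric_field` over the same bone frame.
#' @param regions list of `region_spec`.
#' @param weights numeric weights, recycled along regions (default:
#'   descending 2, 1, 1, ...: first region dominates).
#' @return object of class `alignment_score`: `regions` data.frame with
#'   per-region deviations (deg), `score` (weighted mean, deg), `errors`.
#' @export
alignment_score <- function(principal, fabric, regions,
                            weights = NULL) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  nr <- length(regions)
  if (is.null(weights)) weights <- if (nr >= 1) c(2, rep(1, nr - 1)) else numeric(0)
  weights <- rep_len(weights, nr)
  dev <- rep(NA_real_, nr)
  nms <- vapply(regions, function(r) r$name, character(1))
  errs <- character(0)
  used_n <- integer(nr)
  for (i in seq_len(nr)) {
    res <- tryCatch({
      vs <- regional_mean_direction(principal, regions[[i]])
      vf <- regional_mean_direction(fabric, regions[[i]])
      used_n[i] <- attr(vs, "n")
      angular_deviation(vs, vf)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errs <- c(errs, paste0(nms[i], ": ", res))
      warning("region '", nms[i], "' skipped: ", res)
    } else dev[i] <- res
  }
  ok <- !is.na(dev)
  score <- if (any(ok)) sum(weights[ok] * dev[ok]) / sum(weights[ok]) else NA_real_
  structure(list(regions = data.frame(name = nms, deviation_deg = dev,
                                      weight = weights, n_samples = used_n,
                                      stringsAsFactors = FALSE),
                 score = score, errors = errs), class = "alignment_score")
}

#' @export
print.alignment_score <- function(x, ...) {
  cat("Fabric / principal-stress alignment\n")
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  %-16s %6.2f deg (w = %.1f, n = %d)\n", x$regions$name[i],
                x$regions$deviation_deg[i], x$regions$weight[i],
                x$regions$n_samples[i]))
  cat(sprintf("  weighted score: %.3f deg\n", x$score))
  if (length(x$errors)) cat("  errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Downsample a vector field to a regular grid
#'
#' Averages axial vectors (orientation-tensor mean) over the samples in
#' each cubic grid cell; cells without samples are dropped. Intended for
#' visualization and export of stress trajectories.
#'
#' @param points n x 3 sample locations.
#' @param vectors n x 3 axial vectors.
#' @param spacing grid spacing (m), > 0.
#' @return list with `points` (cell centres) and `vectors` (axial means).
#' @export
downsample_field <- function(points, vectors, spacing) {
  if (!(spacing > 0)) stop("spacing must be > 0")
  lo <- apply(points, 2, min)
  idx <- floor(sweep(points, 2, lo) / spacing)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  groups <- split(seq_len(nrow(points)), key)
  if (length(groups) == 0) {
    warning("empty output: spacing larger than field extent")
    return(list(points = matrix(0, 0, 3), vectors = matrix(0, 0, 3)))
  }
  ctr <- t(vapply(groups, function(g) colMeans(points[g, , drop = FALSE]),
                  numeric(3)))
  vec <- t(vapply(groups, function(g)
    orientation_tensor_mean(vectors[g, , drop = FALSE]), numeric(3)))
  list(points = ctr, vectors = vec)
}

#' Mid-shaft loading summary
#'
#' Characterizes the loading regime at a diaphyseal cross-section from the
#' principal-stress field: torsion obliquity (angle between the most
#' axis-parallel principal direction and the bone long axis; 0 for pure
#' axial load, 45 degrees for pure torsion), the sense of torsion (sign of
#' the helical wrap of sigma1 about the axis; positive = proximal end
#' rotated counterclockwise relative to the distal end, viewed proximally),
#' and the orientation of the neutral surface of bending measured from the
#' mediolateral axis (from a linear fit of axial stress over the section).
#'
#' @param field a `principal_field` in the bone-local frame (long axis z).
#' @param centre_z z-coordinate of the section centre (m).
#' @param half_thickness slab half-thickness (m).
#' @param axis long-axis unit vector (default +z).
#' @return list: `obliquity_deg`, `torsion_sense` (+1/-1/0),
#'   `neutral_angle_deg` (from the mediolateral y-axis, [0, 90]), `n`.
#' @export
midshaft_loading_summary <- function(field, centre_z, half_thickness = 0.004,
                                     axis = c(0, 0, 1)) {
  z <- field$points[, 3]
  sel <- which(abs(z - centre_z) <= half_thickness & !field$degenerate)
  if (length(sel) == 0) stop("empty mid-shaft slab")
  axis <- unit3(axis)
  ang_to_axis <- function(V) acos(pmin(1, abs(V %*% axis))) * 180 / pi
  a1 <- ang_to_axis(field$v1[sel, , drop = FALSE])
  a3 <- ang_to_axis(field$v3[sel, , drop = FALSE])
  # per sample, the more axis-parallel of the sigma1/sigma3 directions
  obliquity <- mean(pmin(a1, a3))
  # torsion sense from the helicity of sigma1 (axial-safe: product of the
  # axial and circumferential components is sign-invariant under v -> -v)
  ctr <- colMeans(field$points[sel, , drop = FALSE])
  rad <- sweep(field$points[sel, 1:2, drop = FALSE], 2, ctr[1:2])
  rr <- sqrt(rowSums(rad^2))
  keep <- rr > 1e-9
  helic <- 0
  if (any(keep)) {
    e_theta <- cbind(-rad[keep, 2], rad[keep, 1]) / rr[keep]
    v1 <- field$v1[sel, , drop = FALSE][keep, , drop = FALSE]
    vth <- rowSums(v1[, 1:2, drop = FALSE] * e_theta)
    vz <- v1[, 3]
    helic <- mean(vth * vz)
  }
  sense <- if (abs(helic) < 1e-8) 0 else sign(helic)
  # neutral surface: linear fit of axial stress over the section
  # requires nodal/element stresses: reconstruct sigma_zz from values/dirs
  # sigma_zz = sum_k values_k * (v_k . z)^2
  szz <- field$values[sel, 1] * (field$v1[sel, , drop = FALSE] %*% axis)^2 +
         field$values[sel, 2] * (field$v2[sel, , drop = FALSE] %*% axis)^2 +
         field$values[sel, 3] * (field$v3[sel, , drop = FALSE] %*% axis)^2
  xy <- field$points[sel, 1:2, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, xy[, 1] - ctr[1], xy[, 2] - ctr[2]),
                       as.numeric(szz))
  bx <- fit$coefficients[2]; by <- fit$coefficients[3]
  neutral_angle <- if (abs(bx) < 1e-12 && abs(by) < 1e-12) NA_real_ else {
    # neutral line direction is perpendicular to the stress gradient (bx, by)
    d <- c(-by, bx)
    acos(min(1, abs(d[2]) / sqrt(sum(d^2)))) * 180 / pi
  }
  list(obliquity_deg = obliquity, torsion_sense = sense,
       neutral_angle_deg = neutral_angle, n = length(sel))
}
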