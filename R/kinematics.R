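#' Posture of the six free joint angles
#'
#' Angles are in degrees. `hip_extension` is the elevation of the femur
#' relative to the horizontal (negative = distal end below the horizontal);
#' `hip_abduction` and `hip_lar` follow the convention that positive values
#' indicate abduction and external rotation of the right limb. Knee and
#' ankle angles are flexion from the neutral (fully columnar) orientation;
#' `mtp_angle` is extension of the pes from neutral. Hip rotation is
#' composed flexion-extension, then adduction-abduction, then long-axis
#' rotation.
#'
#' @param hip_extension,hip_abduction,hip_lar hip angles (deg).
#' @param knee_flexion,ankle_flexion,mtp_angle distal joint angles (deg).
#' @param ranges named list of c(lo, hi) physiological ranges (deg).
#' @return object of class `posture`.
#' @export
posture <- function(hip_extension = -30, hip_abduction = 5, hip_lar = 20,
                    knee_flexion = 93, ankle_flexion = 46, mtp_angle = 16,
                    ranges = default_posture_ranges()) {
  p <- c(hip_extension = hip_extension, hip_abduction = hip_abduction,
         hip_lar = hip_lar, knee_flexion = knee_flexion,
         ankle_flexion = ankle_flexion, mtp_angle = mtp_angle)
  for (nm in names(p)) {
    r <- ranges[[nm]]
    if (!is.null(r) && (p[[nm]] < r[1] || p[[nm]] > r[2]))
      stop("posture angle ", nm, " = ", p[[nm]],
           " outside declared range [", r[1], ", ", r[2], "]")
  }
  structure(as.list(p), ranges = ranges, class = "posture")
}

#' Default physiological joint ranges (degrees)
#' @return named list of c(lo, hi).
#' @export
default_posture_ranges <- function() {
  list(hip_extension = c(-80, 10), hip_abduction = c(-25, 35),
       hip_lar = c(-30, 60), knee_flexion = c(20, 150),
       ankle_flexion = c(-20, 120), mtp_angle = c(-40, 80))
}

#' @export
print.posture <- function(x, ...) {
  cat(sprintf(paste0("posture (deg): hip ext %.1f, abd %.1f, lar %.1f | ",
                     "knee %.1f, ankle %.1f, mtp %.1f\n"),
              x$hip_extension, x$hip_abduction, x$hip_lar,
              x$knee_flexion, x$ankle_flexion, x$mtp_angle))
  invisible(x)
}

as_posture <- function(x) {
  if (inherits(x, "posture")) return(x)
  do.call(posture, as.list(x))
}

#' Hip rotation matrix for a posture
#'
#' Composition order: flexion-extension (about the global mediolateral
#' axis), then adduction-abduction, then long-axis rotation, applied
#' intrinsically. The femur's neutral long axis points proximally (+z), so
#' the flexion-extension angle from neutral is -(90 + hip_extension).
#'
#' @param p a `posture`.
#' @return 3x3 rotation matrix.
#' @export
hip_rotation <- function(p) {
  rot_y(-(90 + p$hip_extension)) %*% rot_x(-p$hip_abduction) %*%
    rot_z(-p$hip_lar)
}

#' Pose the limb
#'
#' Composes segment rigid transforms down the chain hip -> knee -> ankle ->
#' MTP in the global frame (+x anterior, +y medial, +z dorsal; right limb;
#' pelvis fixed at identity with the hip joint centre at the origin).
#'
#' @param model a `limb_model`.
#' @param post a `posture`.
#' @param check validate angle ranges (default TRUE).
#' @return object of class `posed_limb`: per-segment transforms, whole-body
#'   COM, pes centroid (COP), hip height.
#' @export
pose_limb <- function(model, post, check = TRUE) {
  post <- as_posture(post)
  j <- model$joints
  t_pelvis <- rigid_transform()
  t_thigh <- compose_transform(
    t_pelvis, rigid_transform(hip_rotation(post), j$hip$centre_parent))
  t_shank <- compose_transform(
    t_thigh, rigid_transform(rot_y(post$knee_flexion), j$knee$centre_parent))
  t_tmt <- compose_transform(
    t_shank, rigid_transform(rot_y(-post$ankle_flexion), j$ankle$centre_parent))
  t_pes <- compose_transform(
    t_tmt, rigid_transform(rot_y(-post$mtp_angle), j$mtp$centre_parent))
  tr <- list(pelvis = t_pelvis, thigh = t_thigh, shank = t_shank,
             tmt = t_tmt, pes = t_pes)

  q <- model$params
  pes_centroid_local <- c(q$pes_length / 2, 0, -0.004 - q$pes_thickness / 2)
  pes_base_local <- c(q$pes_length / 2, 0, -0.004 - q$pes_thickness)
  cop <- apply_transform(t_pes, pes_centroid_local)
  base <- apply_transform(t_pes, pes_base_local)
  hip <- apply_transform(t_pelvis, j$hip$centre_parent)

  posed <- structure(list(model_ref = NULL, posture = post, transforms = tr,
                          cop = cop, hip = hip,
                          hip_height = hip[3] - base[3]),
                     class = "posed_limb")
  posed$com <- whole_body_com(posed, model)
  posed
}

#' Joint centres of a posed limb in the global frame
#' @param posed a `posed_limb`.
#' @param model a `limb_model`.
#' @return 4 x 3 matrix (hip, knee, ankle, mtp).
#' @export
joint_centres <- function(posed, model) {
  j <- model$joints
  rbind(hip = apply_transform(posed$transforms$pelvis, j$hip$centre_parent),
        knee = apply_transform(posed$transforms$thigh, j$knee$centre_parent),
        ankle = apply_transform(posed$transforms$shank, j$ankle$centre_parent),
        mtp = apply_transform(posed$transforms$tmt, j$mtp$centre_parent))
}

#' Whole-body centre of mass in the global frame
#'
#' Mass-weighted mean of the posed segment centres of mass.
#'
#' @param posed a `posed_limb`.
#' @param model a `limb_model`.
#' @return length-3 point (m).
#' @export
whole_body_com <- function(posed, model) {
  segs <- model$segments
  total <- sum(vapply(segs, function(s) s$mass, numeric(1)))
  if (total <= 0) stop("invalid model: zero total mass")
  acc <- c(0, 0, 0)
  seg_keys <- c(pelvis = "pelvis", thigh = "thigh", shank = "shank",
                tmt = "tmt", pes = "pes")
  for (k in names(seg_keys)) {
    s <- segs[[k]]
    acc <- acc + s$mass * apply_transform(posed$transforms[[k]], s$com_local)
  }
  acc / total
}

#' Evaluate the three posture admissibility criteria
#'
#' 1. No bone-bone interpenetration between posed bones (articulating
#'    neighbours, which are bridged by joint soft tissue, are whitelisted).
#' 2. The pes centroid (taken as the COP of the GRF) lies underneath the
#'    whole-body COM in the sagittal (x) direction, within `cop_tol`; the
#'    mediolateral offset is carried by the pes moment instead.
#' 3. Mediolateral step width (twice the distance from the pes centroid to
#'    the body midline) is less than 15 percent of hip height.
#'
#' @param posed a `posed_limb`.
#' @param model a `limb_model`.
#' @param cop_tol tolerance on |COP_x - COM_x| (m), default 1 mm.
#' @param step_width_max maximum step-width-to-hip-height ratio.
#' @return list of per-criterion pass flags and margins, plus `all_pass`.
#' @export
check_posture_constraints <- function(posed, model, cop_tol = 0.001,
                                      step_width_max = 0.15) {
  # 1: interpenetration among non-adjacent bone pairs (vertex-in-implicit)
  adjacency <- list(c("pelvis", "thigh"), c("thigh", "shank"),
                    c("shank", "tmt"), c("tmt", "pes"))
  segs <- c("pelvis", "thigh", "shank", "tmt", "pes")
  pen <- FALSE; pen_pairs <- character(0)
  for (i in seq_along(segs)) for (k in seq_along(segs)) {
    if (i >= k) next
    pair <- c(segs[i], segs[k])
    if (any(vapply(adjacency, function(a) setequal(a, pair), logical(1)))) next
    va <- apply_transform(posed$transforms[[segs[i]]],
                          model$meshes[[segs[i]]]$vertices)
    # map into the other bone's local frame and test its implicit solid
    tb <- posed$transforms[[segs[k]]]
    va_local <- t(t(tb$R) %*% (t(va) - tb$t))
    hit <- any(model$inside[[segs[k]]](va_local))
    if (!hit) {
      vb <- apply_transform(tb, model$meshes[[segs[k]]]$vertices)
      ta <- posed$transforms[[segs[i]]]
      vb_local <- t(t(ta$R) %*% (t(vb) - ta$t))
      hit <- any(model$inside[[segs[i]]](vb_local))
    }
    if (hit) { pen <- TRUE; pen_pairs <- c(pen_pairs, paste(pair, collapse = "-")) }
  }
  # ground contact: no bone other than the pes below the pes base plane
  base_z <- posed$hip[3] - posed$hip_height

  # 2: COP under COM in x
  dx <- posed$cop[1] - posed$com[1]
  # 3: step width
  midline_y <- model$params$hip_to_midline
  step_width <- 2 * abs(posed$cop[2] - midline_y)
  ratio <- step_width / posed$hip_height

  res <- list(
    interpenetration = list(pass = !pen, pairs = pen_pairs),
    cop_under_com = list(pass = abs(dx) <= cop_tol, margin = abs(dx) - cop_tol,
                         offset_x = dx),
    step_width = list(pass = ratio < step_width_max,
                      ratio = ratio, limit = step_width_max,
                      step_width = step_width))
  res$all_pass <- res$interpenetration$pass && res$cop_under_com$pass &&
    res$step_width$pass
  res
}

#' Degree of crouch of a posed limb
#'
#' A scalar summary of limb flexion. The default metric is
#' 1 - hip_height / total_limb_length, where total limb length is the sum of
#' the functional segment lengths (femur, tibiotarsus, tarsometatarsus);
#' a fully extended vertical limb scores 0. The metric is pluggable via
#' `metric`.
#'
#' @param posed a `posed_limb`.
#' @param model a `limb_model`.
#' @param metric either "height_ratio" (default) or a function
#'   `(posed, model) -> numeric`.
#' @return list with `value` and `metric` (name recorded for audit).
#' @export
degree_of_crouch <- function(posed, model, metric = "height_ratio") {
  if (is.function(metric)) {
    return(list(value = metric(posed, model), metric = "custom"))
  }
  q <- model$params
  # functional limb length: the hip-to-ground distance of the fully
  # extended column (bone lengths plus the pes pad depth)
  L <- q$femur_length + q$tibio_length + q$tmt_length + 0.004 + q$pes_thickness
  if (L <= 0) stop("invalid model: zero limb length")
  list(value = 1 - posed$hip_height / L, metric = "height_ratio")
}

#' Set the MTP angle so the pes lies flat on the ground
#'
#' Solves for the metatarsophalangeal angle that makes the pes long axis
#' horizontal (parallel to the x-y plane) and anterior.
#'
#' @param model a `limb_model`.
#' @param post a `posture` (its `mtp_angle` is ignored).
#' @return the input posture with `mtp_angle` replaced.
#' @export
flat_foot_mtp <- function(model, post) {
  post <- as_posture(post)
  probe <- posture(post$hip_extension, post$hip_abduction, post$hip_lar,
                   post$knee_flexion, post$ankle_flexion, 0,
                   ranges = list())
  posed <- pose_limb(model, probe, check = FALSE)
  R_tmt <- posed$transforms$tmt$R
  # pes local +x axis under mtp rotation about -y: global dir = R_tmt Ry(-m) x
  # choose m so that the global z-component vanishes with x-component > 0
  v <- R_tmt %*% c(1, 0, 0)   # m = 0 image of local +x
  w <- R_tmt %*% c(0, 0, 1)   # m = 0 image of local +z
  # z-comp of Ry(-m) x = cos(m) v_z + sin(m) w_z... direction: Ry(-m)x =
  # (cos m, 0, sin m) in tmt frame -> global cos(m) v + sin(m) w
  m <- atan2(-v[3], w[3]) * 180 / pi
  # ensure anterior orientation
  xg <- cos(m * pi / 180) * v[1] + sin(m * pi / 180) * w[1]
  if (xg < 0) m <- m + 180
  m <- ((m + 180) %% 360) - 180
  posture(post$hip_extension, post$hip_abduction, post$hip_lar,
          post$knee_flexion, post$ankle_flexion, m, ranges = list())
}
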