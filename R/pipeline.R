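# Muscle point loads on a bone, with host-local coordinates and (for
# snapped attachment points) the mesh node, used to build FE load cases on
# the exact nodes the musculoskeletal model attaches to.
muscle_loads_on_bone <- function(model, posed, solution, segment) {
  out <- list()
  Rl <- posed$transforms[[segment]]$R
  for (nm in names(solution$activations)) {
    Tn <- solution$forces[[nm]]
    if (Tn <= 0) next
    act <- model$actuators[[nm]]
    fd <- actuator_force_directions(act, posed)
    for (i in seq_len(nrow(fd$points))) {
      if (fd$segments[i] != segment) next
      fg <- Tn * fd$directions[i, ]
      if (sum(abs(fg)) == 0) next
      out[[length(out) + 1]] <- list(
        local_point = act$path[[i]]$p,
        node = act$path[[i]]$node,
        force_local = as.numeric(t(Rl) %*% fg),
        actuator = nm)
    }
  }
  out
}

# lazily built, cached FE context for one of the two assemblies
get_fe_context <- function(model, which = c("femur", "shank")) {
  which <- match.arg(which)
  if (is.null(model$cache)) stop("model has no cache environment")
  key <- paste0(which, "_ctx")
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  fe <- model$fe[[which]]
  vm <- fe$mesh
  # restrain the bookend's outer nodes (all nodes not shared with the
  # adjacent soft-tissue entity)
  book <- entity_nodes(vm, fe$restrain_entity)
  soft <- entity_nodes(vm, if (which == "femur") 2L else 4L)
  restrained <- setdiff(book, soft)
  ctx <- fe_context(vm, model$materials, fe$material_of, restrained)
  model$cache[[key]] <- ctx
  ctx
}

#' Build and solve one finite-element simulation for a posed, solved limb
#'
#' Assembles the load case for the focal bone (femur, or tibiotarsus +
#' fibula) in its local frame: muscle and ligament forces spread over about
#' 20 surface nodes centred on the attachment node, the knee joint force as
#' a statically equivalent remote force at the knee joint centre scoped to
#' the neighbouring bookend, the knee joint moment applied directly to the
#' bone surface in contact with the knee soft tissues, and the segment
#' weight via a remote attachment at the segment centre of mass. The
#' opposite bookend is restrained in all translations. The ankle joint
#' moment is, deliberately, not applied in the tibiotarsus simulation
#' (config flag `apply_ankle_moment` enables it for exploration).
#'
#' @param model a `limb_model`.
#' @param posed a `posed_limb`.
#' @param solution an `activation_solution`.
#' @param jl a `joint_loads`.
#' @param which "femur" or "shank".
#' @param spread_count nodes per spread muscle force.
#' @param apply_ankle_moment apply the ankle moment in the shank simulation.
#' @return a `stress_field` (in the bone-local frame), with attribute
#'   `context` the `fe_context` used.
#' @export
solve_bone_fe <- function(model, posed, solution, jl,
                          which = c("femur", "shank"), spread_count = 20,
                          apply_ankle_moment = FALSE) {
  which <- match.arg(which)
  fe <- model$fe[[which]]
  vm <- fe$mesh
  ctx <- get_fe_context(model, which)
  seg <- if (which == "femur") "thigh" else "shank"
  Rl <- posed$transforms[[seg]]$R
  to_local <- function(v) as.numeric(t(Rl) %*% v)
  bone_surf <- entity_surface_nodes(vm, 1L)
  loads <- list()
  # muscle forces at attachment nodes
  for (ml in muscle_loads_on_bone(model, posed, solution, seg)) {
    focal <- if (!is.null(ml$node)) ml$node else
      nearest_node(vm, ml$local_point, bone_surf)
    loads[[length(loads) + 1]] <-
      distribute_point_force(vm, ml$force_local, focal, bone_surf,
                             spread_count)
  }
  # knee joint force via the neighbouring bookend (remote at knee centre)
  knee_local <- model$joints$knee$centre_parent
  if (which == "shank") knee_local <- model$joints$knee$centre_child
  kf_global <- if (which == "femur") -jl$joints$knee$force else
    jl$joints$knee$force
  remote_nodes <- entity_nodes(vm, fe$remote_entity)
  loads[[length(loads) + 1]] <-
    apply_remote_force(vm, knee_local, to_local(kf_global), remote_nodes)
  # knee joint moment directly on the bone's knee contact surface
  km_global <- if (which == "femur") -jl$joints$knee$moment else
    jl$joints$knee$moment
  contact <- intersect(entity_nodes(vm, 1L),
                       entity_nodes(vm, fe$knee_contact_entities))
  loads[[length(loads) + 1]] <-
    apply_surface_moment(vm, to_local(km_global), contact)
  if (which == "shank" && apply_ankle_moment) {
    am_global <- -jl$joints$ankle$moment
    acontact <- intersect(entity_nodes(vm, 1L), entity_nodes(vm, 4L))
    loads[[length(loads) + 1]] <-
      apply_surface_moment(vm, to_local(am_global), acontact)
  }
  # segment weight via a remote point at the segment COM, scoped to the bone
  wseg <- c(0, 0, -model$segments[[seg]]$mass * model$gravity)
  loads[[length(loads) + 1]] <-
    apply_remote_force(vm, model$segments[[seg]]$com_local, to_local(wseg),
                       entity_nodes(vm, 1L))
  loads <- do.call(rbind, loads)
  sf <- solve_linear_static(ctx, loads, use_inertia_relief = FALSE)
  attr(sf, "context") <- ctx
  sf
}

#' Default comparison regions on the femur
#'
#' Femoral head: sphere of half the fitted head radius, centred one region
#' radius beneath the contact centroid where the hip force arrives.
#' Medial condyle: sphere of one-third the fitted condyle radius at the
#' anatomical condyle centre.
#'
#' @param model a `limb_model`.
#' @return list of `region_spec` (femoral head first: it carries the higher
#'   comparison weight).
#' @export
default_regions <- function(model) {
  hf <- model$articular$head_fit
  rh <- hf$radius
  head_centre <- hf$centre + c(0, 0, rh - rh / 2)
  cf <- model$articular$med_condyle_fit
  list(region_spec(head_centre, rh / 2, name = "femoral_head",
                   which = "sigma3"),
       region_spec(cf$centre, cf$radius / 3, name = "medial_condyle",
                   which = "sigma3"))
}

# principal field over element centroids of the focal bone entity
bone_principal_field <- function(model, which, sf, restrict_points = NULL) {
  vm <- model$fe[[which]]$mesh
  ctx <- get_fe_context(model, which)
  sel <- which(vm$entity == 1L)
  cen <- ctx$assembly$centroids[sel, , drop = FALSE]
  if (!is.null(restrict_points)) {
    keep <- restrict_points(cen)
    sel <- sel[keep]; cen <- cen[keep, , drop = FALSE]
  }
  principal_field(cen, sf$element_stress[sel, , drop = FALSE])
}

#' Evaluate one posture against a fabric field
#'
#' Runs the full quasi-static pipeline at a posture: external loads,
#' static optimization, joint reactions, the femur and tibiotarsus + fibula
#' finite-element solves, eigenanalysis, and the regional alignment score
#' of sigma3 against the fabric u1.
#'
#' @param model a `limb_model`.
#' @param post a `posture`.
#' @param fabric a `fabric_field` in the femur-local frame.
#' @param regions list of `region_spec` (default [default_regions()]).
#' @param run_shank also run the tibiotarsus + fibula simulation (default
#'   TRUE; the default regions score the femur only, so searches may skip
#'   it for speed).
#' @param keep_fields keep the full stress/principal fields in the report.
#' @return list report: `posture`, `score` (an `alignment_score`),
#'   `activations`, `joint_loads`, `constraints`, optional fields.
#' @export
evaluate_posture <- function(model, post, fabric,
                             regions = default_regions(model),
                             run_shank = TRUE, keep_fields = FALSE) {
  post <- as_posture(post)
  posed <- pose_limb(model, post)
  constraints <- check_posture_constraints(posed, model)
  loads <- build_external_loads(posed, model)
  sol <- solve_static_optimization(model, posed, loads)
  jl <- joint_reactions(model, posed, sol, loads)
  sf_fem <- tryCatch(solve_bone_fe(model, posed, sol, jl, "femur"),
                     error = function(e)
                       stop("femur FE stage failed: ", conditionMessage(e)))
  # restrict eigenanalysis to the scored regions for speed
  restrict <- function(p) {
    keep <- rep(FALSE, nrow(p))
    for (r in regions) keep <- keep | in_region(p, r)
    keep
  }
  pf <- bone_principal_field(model, "femur", sf_fem, restrict)
  score <- alignment_score(pf, fabric, regions)
  sf_shk <- NULL
  if (run_shank) {
    sf_shk <- tryCatch(solve_bone_fe(model, posed, sol, jl, "shank"),
                       error = function(e)
                         stop("tibiotarsus FE stage failed: ",
                              conditionMessage(e)))
  }
  rep <- list(posture = post, score = score, activations = sol,
              joint_loads = jl, external_loads = loads,
              constraints = constraints,
              crouch = degree_of_crouch(posed, model))
  if (keep_fields) {
    rep$femur_stress <- sf_fem
    rep$femur_principal <- bone_principal_field(model, "femur", sf_fem)
    if (run_shank) {
      rep$shank_stress <- sf_shk
      rep$shank_principal <- bone_principal_field(model, "shank", sf_shk)
    }
  }
  rep
}
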