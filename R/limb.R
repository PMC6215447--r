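#' Material definition
#'
#' Solid, isotropic, linearly elastic material. Young's modulus is stored in
#' Pa (SI); the conventional literature values are quoted in MPa, so use
#' [default_materials()] for the standard set.
#'
#' @param density kg/m^3, > 0.
#' @param youngs_modulus Pa, > 0.
#' @param poissons_ratio dimensionless, in [0, 0.5).
#' @return object of class `material`.
#' @export
material <- function(density, youngs_modulus, poissons_ratio) {
  if (!(density > 0)) stop("material density must be > 0")
  if (!(youngs_modulus > 0)) stop("Young's modulus must be > 0")
  if (!(poissons_ratio >= 0 && poissons_ratio < 0.5))
    stop("Poisson's ratio must be in [0, 0.5)")
  structure(list(density = density, youngs_modulus = youngs_modulus,
                 poissons_ratio = poissons_ratio), class = "material")
}

#' Default material set
#'
#' Cortical bone 17,000 MPa / 0.3 / 2,060 kg/m^3; articular cartilage
#' 50 MPa / 0.45 / 1,100; a knee soft-tissue composite (cartilage plus
#' menisci treated as one homogeneous entity) 100 MPa / 0.3 / 1,100. MPa
#' values are converted to Pa on construction.
#'
#' @return named list of `material` objects: bone, cartilage, knee_composite.
#' @export
default_materials <- function() {
  list(bone = material(2060, 17000e6, 0.30),
       cartilage = material(1100, 50e6, 0.45),
       knee_composite = material(1100, 100e6, 0.30))
}

# Activity flags at around mid-stance (X = active, O = inactive), assembled
# from avian electromyography-based reasoning; ligaments are always carried.
.default_activity <- c(
  IC = FALSE, ILPR = FALSE, ILPO = TRUE, AMB = TRUE, FMTE = TRUE,
  FMTM = TRUE, FMTI = TRUE, ILFB = TRUE, FCLP = TRUE, FCLA = TRUE,
  FCM = TRUE, IFE = FALSE, IFI = FALSE, ITCR = FALSE, ITM = TRUE,
  ITC = TRUE, ISF = TRUE, CFC = TRUE, CFP = TRUE, OM = FALSE,
  PIFL = TRUE, PIFM = TRUE, GL = TRUE, GI = TRUE, GM = TRUE,
  FDL = TRUE, ODF = TRUE, FHL = TRUE, EDL = FALSE, ODE = FALSE,
  TCF = FALSE, TCT = FALSE, FL = TRUE, FB = TRUE,
  KMCL = TRUE, KLCL = TRUE, AMCL = TRUE, ALCL = TRUE)

# Muscle-specific maximum forces (N) for the sensitivity mode, computed from
# junglefowl architecture scaled by mass at a constant isometric stress of
# 3e5 N/m^2. Ligaments keep the uniform default.
.muscle_specific_fmax <- c(
  ILPO = 30.111, AMB = 1.112, FMTE = 19.636, FMTM = 21.007, FMTI = 92.110,
  ILFB = 24.777, FCLP = 20.760, FCLA = 18.656, FCM = 8.713, ITM = 3.003,
  ITC = 77.382, ISF = 25.635, CFC = 1.625, CFP = 6.300, PIFL = 7.981,
  PIFM = 17.940, GL = 59.539, GI = 10.863, GM = 71.969, FDL = 31.022,
  ODF = 58.122, FHL = 22.672, FL = 51.621, FB = 8.737)

#' Default synthetic-limb parameters
#'
#' Dimensions (m) and masses (kg) of an idealized adult-chicken-sized
#' bipedal hindlimb. Segment masses sum to `body_mass`; the pelvis segment
#' (body minus the modelled limb) receives the remainder. `mesh_h` is the
#' lattice spacing used for the finite-element assemblies.
#'
#' @param body_mass total body mass (kg).
#' @param limb_masses named vector: thigh, shank, tarsometatarsus, pes (kg).
#' @param mesh_h lattice spacing (m) for FE volume meshes.
#' @return named list of parameters.
#' @export
default_limb_params <- function(body_mass = 1.56,
                                limb_masses = c(thigh = 0.080, shank = 0.050,
                                                tarsometatarsus = 0.020,
                                                pes = 0.009),
                                mesh_h = 0.002) {
  list(
    body_mass = body_mass,
    limb_masses = limb_masses,
    gravity = 9.81,
    mesh_h = mesh_h,
    # femur
    femur_length = 0.075, head_radius = 0.006, neck_offset = 0.007,
    femur_shaft_radius = 0.0045, condyle_radius = 0.0055,
    condyle_spacing = 0.012,
    # tibiotarsus + fibula
    tibio_length = 0.112, tibio_shaft_radius = 0.004,
    crest_length = 0.026, crest_reach = 0.014,
    fibula_radius = 0.002, fibula_offset = 0.0065,
    # tarsometatarsus
    tmt_length = 0.088, tmt_shaft_radius = 0.0035,
    # pes prism ("length of digit III")
    pes_length = 0.045, pes_width = 0.018, pes_thickness = 0.004,
    # pelvis
    pelvis_com_anterior = 0.068, hip_to_midline = 0.012,
    # soft-tissue / bookend thicknesses
    cartilage_thickness = 0.003, bookend_thickness = 0.004,
    joint_gap_knee = 0.0075, joint_gap_ankle = 0.0055)
}

# ---- implicit solids (bone-local frames) ------------------------------------

.in_sphere <- function(p, c, r) {
  (p[, 1] - c[1])^2 + (p[, 2] - c[2])^2 + (p[, 3] - c[3])^2 <= r^2
}

.in_box <- function(p, lo, hi) {
  p[, 1] >= lo[1] & p[, 1] <= hi[1] &
  p[, 2] >= lo[2] & p[, 2] <= hi[2] &
  p[, 3] >= lo[3] & p[, 3] <= hi[3]
}

.in_zcolumn <- function(p, cx, cy, r, z0, z1) {
  (p[, 1] - cx)^2 + (p[, 2] - cy)^2 <= r^2 & p[, 3] >= z0 & p[, 3] <= z1
}

.in_capsule <- function(p, a, b, r) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
        (p[, 3] - a[3]) * ab[3]) / L2
  t <- pmin(1, pmax(0, t))
  dx <- p[, 1] - (a[1] + t * ab[1])
  dy <- p[, 2] - (a[2] + t * ab[2])
  dz <- p[, 3] - (a[3] + t * ab[3])
  dx^2 + dy^2 + dz^2 <= r^2
}

# femur in its local frame: head sphere centred at the origin (= hip joint
# centre), laterally offset shaft, condylar block distally.
femur_inside <- function(p, q) {
  Lf <- q$femur_length; dn <- q$neck_offset
  .in_sphere(p, c(0, 0, 0), q$head_radius) |
    .in_capsule(p, c(0, 0, -0.001), c(0, -dn, -0.012), 0.004) |
    .in_zcolumn(p, 0, -dn, q$femur_shaft_radius, -(Lf - 0.005), -0.004) |
    .in_box(p, c(-q$condyle_radius, -dn - q$condyle_spacing / 2 - q$condyle_radius,
                 -(Lf + q$condyle_radius)),
            c(q$condyle_radius, -dn + q$condyle_spacing / 2 + q$condyle_radius,
              -(Lf - 0.006)))
}

# tibiotarsus + fibula in the shank local frame (origin = knee joint centre)
shank_inside <- function(p, q) {
  Lt <- q$tibio_length; g <- q$joint_gap_knee
  .in_zcolumn(p, 0, 0, q$tibio_shaft_radius, -(Lt - 0.004), -g) |
    # cnemial crest block, anterior and proximal
    .in_box(p, c(0.003, -0.004, -(g + q$crest_length)),
            c(q$crest_reach, 0.004, -0.004)) |
    # fibula: lateral rod, enlarged head, fused distally via a bridge
    .in_zcolumn(p, -0.001, -q$fibula_offset, q$fibula_radius, -0.065, -g) |
    .in_zcolumn(p, -0.001, -q$fibula_offset, 0.003, -0.014, -g) |
    .in_box(p, c(-0.003, -q$fibula_offset - 0.001, -0.065),
            c(0.003, 0.002, -0.055)) |
    # distal condyles
    .in_box(p, c(-0.005, -0.007, -(Lt + 0.004)), c(0.005, 0.007, -(Lt - 0.004)))
}

tmt_inside <- function(p, q) {
  Lm <- q$tmt_length; g <- q$joint_gap_ankle
  .in_zcolumn(p, 0, 0, q$tmt_shaft_radius, -(Lm - 0.0025), -g) |
    .in_box(p, c(-0.005, -0.005, -0.010), c(0.005, 0.005, -g)) |
    .in_box(p, c(-0.004, -q$pes_width / 2, -(Lm + 0.004)),
            c(0.004, q$pes_width / 2, -(Lm - 0.004)))
}

pes_inside <- function(p, q) {
  .in_box(p, c(0, -q$pes_width / 2, -0.004 - q$pes_thickness),
          c(q$pes_length, q$pes_width / 2, -0.004))
}

pelvis_inside <- function(p, q) {
  .in_box(p, c(-0.050, -0.002, 0.008), c(0.035, 0.030, 0.028))
}

# ---- FE assembly labellers --------------------------------------------------

# femur simulation assembly, femur local frame.
# entities: 1 femur, 2 hip cartilage, 3 acetabulum bookend,
#           4 knee composite, 5 crus bookend
femur_assembly_label <- function(p, q) {
  lab <- integer(nrow(p))
  tc <- q$cartilage_thickness; tb <- q$bookend_thickness
  rh <- q$head_radius
  bone <- femur_inside(p, q)
  lab[bone] <- 1L
  d2 <- p[, 1]^2 + p[, 2]^2 + p[, 3]^2
  cart <- !bone & d2 <= (rh + tc)^2 & p[, 3] > 0
  lab[cart] <- 2L
  book <- lab == 0L & d2 > (rh + tc)^2 & d2 <= (rh + tc + tb)^2 & p[, 3] > 0
  lab[book] <- 3L
  Lf <- q$femur_length; dn <- q$neck_offset
  ylo <- -dn - q$condyle_spacing / 2 - q$condyle_radius
  yhi <- -dn + q$condyle_spacing / 2 + q$condyle_radius
  knee <- lab == 0L & .in_box(p, c(-q$condyle_radius, ylo,
                                   -(Lf + q$condyle_radius + q$joint_gap_knee)),
                              c(q$condyle_radius, yhi, -(Lf - 0.002)))
  lab[knee] <- 4L
  crus <- lab == 0L & .in_box(p, c(-q$condyle_radius, ylo,
                                   -(Lf + q$condyle_radius + q$joint_gap_knee + tb)),
                              c(q$condyle_radius, yhi,
                                -(Lf + q$condyle_radius + q$joint_gap_knee)))
  lab[crus] <- 5L
  lab
}

# tibiotarsus + fibula simulation assembly, shank local frame.
# entities: 1 tibiotarsus+fibula, 2 knee composite, 3 distal-femur bookend,
#           4 ankle cartilage, 5 tarsometatarsus bookend
shank_assembly_label <- function(p, q) {
  lab <- integer(nrow(p))
  tb <- q$bookend_thickness; Lt <- q$tibio_length; g <- q$joint_gap_knee
  bone <- shank_inside(p, q)
  lab[bone] <- 1L
  knee <- !bone & .in_box(p, c(-0.008, -q$fibula_offset - 0.003, -g),
                          c(0.007, 0.007, -0.0015))
  lab[knee] <- 2L
  fem <- lab == 0L & .in_box(p, c(-0.008, -q$fibula_offset - 0.003, -0.0015),
                             c(0.007, 0.007, -0.0015 + tb))
  lab[fem] <- 3L
  cart <- lab == 0L & .in_box(p, c(-0.005, -0.007, -(Lt + 0.004 + q$joint_gap_ankle)),
                              c(0.005, 0.007, -(Lt + 0.004)))
  lab[cart] <- 4L
  tmtb <- lab == 0L & .in_box(p, c(-0.005, -0.007,
                                   -(Lt + 0.004 + q$joint_gap_ankle + tb)),
                              c(0.005, 0.007, -(Lt + 0.004 + q$joint_gap_ankle)))
  lab[tmtb] <- 5L
  lab
}

# ---- actuator table ---------------------------------------------------------

# Path points are segment-local (m). Reduced-fidelity topology: origin,
# insertion and the minimum via points needed for a physiological line of
# action across the modelled range of motion.
.pt <- function(seg, x, y, z) list(segment = seg, p = c(x, y, z))

default_actuator_paths <- function(q) {
  Lf <- q$femur_length; Lt <- q$tibio_length; Lm <- q$tmt_length
  list(
    IC   = list(.pt("pelvis", 0.030, -0.004, 0.012),
                .pt("thigh", 0.011, -0.007, -(Lf - 0.001)),
                .pt("shank", 0.0135, -0.002, -0.0055),
                .pt("shank", 0.012, -0.002, -0.014)),
    ILPR = list(.pt("pelvis", 0.020, -0.008, 0.014),
                .pt("thigh", 0.011, -0.008, -(Lf - 0.001)),
                .pt("shank", 0.0135, -0.003, -0.0055),
                .pt("shank", 0.012, -0.003, -0.014)),
    ILPO = list(.pt("pelvis", -0.015, -0.009, 0.012),
                .pt("thigh", 0.011, -0.009, -(Lf - 0.001)),
                .pt("shank", 0.0135, -0.003, -0.0055),
                .pt("shank", 0.012, -0.003, -0.014)),
    AMB  = list(.pt("pelvis", 0.012, -0.002, -0.012),
                .pt("thigh", 0.010, -0.006, -(Lf - 0.001)),
                .pt("shank", 0.012, -0.007, -0.0055),
                .pt("shank", 0.005, -0.0085, -0.012)),
    FMTE = list(.pt("thigh", 0.002, -0.0115, -0.040),
                .pt("thigh", 0.011, -0.008, -(Lf - 0.001)),
                .pt("shank", 0.0135, -0.002, -0.0055),
                .pt("shank", 0.012, -0.002, -0.014)),
    FMTM = list(.pt("thigh", 0.0045, -0.007, -0.035),
                .pt("thigh", 0.011, -0.007, -(Lf - 0.001)),
                .pt("shank", 0.0135, -0.002, -0.0055),
                .pt("shank", 0.012, -0.002, -0.014)),
    FMTI = list(.pt("thigh", 0.002, -0.0025, -0.040),
                .pt("thigh", 0.011, -0.006, -(Lf - 0.001)),
                .pt("shank", 0.0135, -0.001, -0.0055),
                .pt("shank", 0.012, -0.001, -0.014)),
    ILFB = list(.pt("pelvis", -0.020, -0.009, 0.010),
                .pt("thigh", -0.006, -0.009, -0.050),
                .pt("shank", -0.002, -0.0075, -0.015)),
    FCLP = list(.pt("pelvis", -0.035, -0.005, 0.004),
                .pt("thigh", -0.007, -0.007, -(Lf - 0.010)),
                .pt("shank", 0.000, 0.003, -0.012)),
    FCLA = list(.pt("pelvis", -0.035, -0.005, 0.004),
                .pt("thigh", -0.007, -0.007, -(Lf - 0.015)),
                .pt("thigh", -0.005, -0.007, -(Lf - 0.007))),
    FCM  = list(.pt("pelvis", -0.025, -0.003, -0.010),
                .pt("thigh", -0.007, -0.005, -(Lf - 0.010)),
                .pt("shank", 0.000, 0.003, -0.014)),
    IFE  = list(.pt("pelvis", 0.005, -0.010, 0.012),
                .pt("thigh", 0.002, -0.0115, -0.008)),
    IFI  = list(.pt("pelvis", 0.015, -0.002, 0.006),
                .pt("thigh", 0.000, -0.003, -0.010)),
    ITCR = list(.pt("pelvis", 0.022, -0.006, 0.008),
                .pt("thigh", 0.004, -0.010, -0.006)),
    ITM  = list(.pt("pelvis", 0.017, -0.006, 0.009),
                .pt("thigh", 0.004, -0.010, -0.008)),
    ITC  = list(.pt("pelvis", 0.025, -0.009, 0.010),
                .pt("thigh", 0.004, -0.011, -0.005)),
    ISF  = list(.pt("pelvis", -0.012, -0.008, -0.004),
                .pt("thigh", -0.003, -0.011, -0.008)),
    CFC  = list(.pt("pelvis", -0.045, -0.003, -0.002),
                .pt("thigh", -0.004, -0.008, -0.018)),
    CFP  = list(.pt("pelvis", -0.030, -0.008, 0.004),
                .pt("thigh", -0.004, -0.0095, -0.018)),
    OM   = list(.pt("pelvis", -0.015, -0.002, -0.015),
                .pt("pelvis", -0.002, -0.010, -0.002),
                .pt("thigh", -0.003, -0.010, -0.006)),
    PIFL = list(.pt("pelvis", -0.010, -0.004, -0.018),
                .pt("thigh", -0.004, -0.009, -0.040)),
    PIFM = list(.pt("pelvis", -0.008, -0.002, -0.020),
                .pt("thigh", -0.004, -0.006, -0.042)),
    GL   = list(.pt("thigh", -0.004, -0.010, -(Lf - 0.007)),
                .pt("shank", -0.006, -0.004, -0.020),
                .pt("shank", -0.010, -0.001, -(Lt - 0.002)),
                .pt("tmt", -0.0095, 0.000, -0.007),
                .pt("tmt", -0.006, 0.000, -0.018)),
    GI   = list(.pt("thigh", -0.004, -0.004, -(Lf - 0.005)),
                .pt("shank", -0.006, -0.001, -0.020),
                .pt("shank", -0.010, 0.000, -(Lt - 0.002)),
                .pt("tmt", -0.0095, 0.000, -0.007),
                .pt("tmt", -0.006, 0.000, -0.018)),
    GM   = list(.pt("shank", 0.004, 0.003, -0.010),
                .pt("shank", -0.010, 0.001, -(Lt - 0.002)),
                .pt("tmt", -0.0095, 0.000, -0.007),
                .pt("tmt", -0.006, 0.000, -0.018)),
    FDL  = list(.pt("shank", -0.004, 0.000, -0.030),
                .pt("shank", -0.010, 0.000, -(Lt - 0.002)),
                .pt("tmt", -0.0095, 0.000, -0.007),
                .pt("tmt", -0.005, 0.000, -(Lm - 0.0025)),
                .pt("pes", 0.002, 0.000, -0.008),
                .pt("pes", 0.012, 0.000, -0.0075)),
    ODF  = list(.pt("thigh", -0.004, -0.009, -(Lf - 0.005)),
                .pt("shank", -0.006, -0.002, -0.030),
                .pt("shank", -0.010, 0.000, -(Lt - 0.002)),
                .pt("tmt", -0.0095, 0.000, -0.007),
                .pt("tmt", -0.005, 0.000, -(Lm - 0.0025)),
                .pt("pes", 0.002, 0.000, -0.008),
                .pt("pes", 0.013, 0.000, -0.0075)),
    FHL  = list(.pt("thigh", -0.004, -0.006, -(Lf - 0.004)),
                .pt("shank", -0.005, -0.001, -0.040),
                .pt("shank", -0.010, 0.000, -(Lt - 0.002)),
                .pt("tmt", -0.0095, 0.000, -0.007),
                .pt("tmt", -0.005, 0.000, -(Lm - 0.0025)),
                .pt("pes", 0.002, -0.002, -0.008),
                .pt("pes", 0.010, -0.002, -0.0075)),
    EDL  = list(.pt("shank", 0.006, 0.000, -0.020),
                .pt("shank", 0.005, 0.000, -(Lt - 0.002)),
                .pt("tmt", 0.004, 0.000, -(Lm - 0.002)),
                .pt("pes", 0.010, 0.000, -0.004)),
    ODE  = list(.pt("tmt", 0.0035, 0.000, -0.020),
                .pt("tmt", 0.004, 0.000, -(Lm - 0.002)),
                .pt("pes", 0.010, 0.000, -0.004)),
    TCF  = list(.pt("thigh", 0.003, -0.010, -(Lf - 0.002)),
                .pt("shank", 0.006, 0.000, -0.015),
                .pt("shank", 0.005, 0.000, -(Lt - 0.002)),
                .pt("tmt", 0.0035, 0.000, -0.008)),
    TCT  = list(.pt("shank", 0.012, -0.001, -0.010),
                .pt("shank", 0.005, 0.000, -(Lt - 0.002)),
                .pt("tmt", 0.0035, 0.000, -0.008)),
    FL   = list(.pt("shank", 0.010, -0.004, -0.009),
                .pt("shank", -0.010, -0.004, -(Lt - 0.002)),
                .pt("tmt", -0.0095, -0.002, -0.007),
                .pt("tmt", -0.005, -0.001, -(Lm - 0.0025)),
                .pt("pes", 0.002, -0.001, -0.008),
                .pt("pes", 0.012, 0.000, -0.0075)),
    FB   = list(.pt("shank", 0.003, -0.005, -0.030),
                .pt("shank", -0.002, -0.005, -(Lt - 0.002)),
                .pt("tmt", 0.000, -0.0045, -0.007)),
    KMCL = list(.pt("thigh", 0.000, 0.0040, -(Lf - 0.002)),
                .pt("shank", 0.000, 0.0040, -0.010)),
    KLCL = list(.pt("thigh", 0.000, -0.0180, -(Lf - 0.002)),
                .pt("shank", 0.002, -0.0085, -0.009)),
    AMCL = list(.pt("shank", 0.000, 0.0060, -(Lt - 0.001)),
                .pt("tmt", 0.000, 0.0045, -0.007)),
    ALCL = list(.pt("shank", 0.000, -0.0060, -(Lt - 0.001)),
                .pt("tmt", 0.001, -0.0045, -0.007)))
}

.lig_names <- c("KMCL", "KLCL", "AMCL", "ALCL")

#' Generate the synthetic bipedal hindlimb model
#'
#' Builds an idealized bird-like right hindlimb: femur (shaft, medially
#' offset spherical head, condylar block), tibiotarsus with cnemial crest
#' and a slender fibula fused distally, tarsometatarsus, pes modelled as a
#' rectangular prism (length standing in for digit III), and a pelvis stub
#' carrying the acetabulum. Joint soft-tissue volumes and bookend structures
#' are meshed conformally with each focal bone on a shared lattice so that
#' bonded interfaces share nodes exactly. Also attaches the 38-actuator
#' musculotendon set, activity flags, segment mass properties and the
#' finite-element assemblies for the femur and tibiotarsus + fibula
#' simulations.
#'
#' Actuator end points hosted on the femur or tibiotarsus are snapped to the
#' nearest bone surface node so the musculoskeletal and finite-element
#' simulations use the exact same attachment nodes.
#'
#' @param params parameter list from [default_limb_params()].
#' @param seed integer seed recorded in the model (generation itself is
#'   deterministic).
#' @return object of class `limb_model`.
#' @export
generate_synthetic_limb <- function(params = default_limb_params(), seed = 1L) {
  q <- params
  masses <- q$limb_masses
  if (any(masses < 0)) stop("segment masses must be non-negative")
  pelvis_mass <- q$body_mass - sum(masses)
  if (pelvis_mass <= 0)
    stop("limb masses exceed body mass")
  gravity <- q$gravity
  bw <- q$body_mass * gravity

  segments <- list(
    pelvis = list(name = "pelvis", mass = pelvis_mass,
                  com_local = c(q$pelvis_com_anterior, q$hip_to_midline, 0)),
    thigh = list(name = "thigh", mass = masses[["thigh"]],
                 com_local = c(0.004, -0.006, -0.032)),
    shank = list(name = "shank", mass = masses[["shank"]],
                 com_local = c(0, 0, -0.045)),
    tmt = list(name = "tarsometatarsus", mass = masses[["tarsometatarsus"]],
               com_local = c(0, 0, -0.040)),
    pes = list(name = "pes", mass = masses[["pes"]],
               com_local = c(q$pes_length / 2, 0, -0.004 - q$pes_thickness / 2)))

  joints <- list(
    hip = list(name = "hip", type = "ball_and_socket", parent = "pelvis",
               child = "thigh", centre_parent = c(0, 0, 0),
               centre_child = c(0, 0, 0)),
    knee = list(name = "knee", type = "hinge", parent = "thigh",
                child = "shank", axis = c(0, 1, 0),
                centre_parent = c(0, -q$neck_offset, -q$femur_length),
                centre_child = c(0, 0, 0)),
    ankle = list(name = "ankle", type = "hinge", parent = "shank",
                 child = "tmt", axis = c(0, 1, 0),
                 centre_parent = c(0, 0, -q$tibio_length),
                 centre_child = c(0, 0, 0)),
    mtp = list(name = "mtp", type = "hinge", parent = "tmt",
               child = "pes", axis = c(0, 1, 0),
               centre_parent = c(0, 0, -q$tmt_length),
               centre_child = c(0, 0, 0)))

  # FE assemblies (bone-local frames); bounding boxes with small margins
  h <- q$mesh_h
  rh <- q$head_radius; tcb <- q$cartilage_thickness + q$bookend_thickness
  fem_lower <- c(-(rh + tcb + h), -q$neck_offset - q$condyle_spacing / 2 -
                   q$condyle_radius - h, -(q$femur_length + q$condyle_radius +
                   q$joint_gap_knee + q$bookend_thickness + h))
  fem_upper <- c(rh + tcb + h, rh + tcb + h, rh + tcb + h)
  fem_names <- c("1" = "femur", "2" = "hip_cartilage", "3" = "acetabulum_bookend",
                 "4" = "knee_composite", "5" = "crus_bookend")
  fem_mesh <- lattice_tet_mesh(function(p) femur_assembly_label(p, q),
                               fem_lower, fem_upper, h, entity_names = fem_names)

  shk_lower <- c(-0.009, -q$fibula_offset - 0.004,
                 -(q$tibio_length + 0.004 + q$joint_gap_ankle +
                   q$bookend_thickness + h))
  shk_upper <- c(q$crest_reach + h, 0.008, -0.0015 + q$bookend_thickness + h)
  shk_names <- c("1" = "tibiotarsus_fibula", "2" = "knee_composite",
                 "3" = "femur_bookend", "4" = "ankle_cartilage",
                 "5" = "tmt_bookend")
  shk_mesh <- lattice_tet_mesh(function(p) shank_assembly_label(p, q),
                               shk_lower, shk_upper, h, entity_names = shk_names)

  # analytic articular point samples (deterministic) for sphere fitting
  head_points <- fibonacci_sphere(200, centre = c(0, 0, 0), radius = rh)
  med_condyle_centre <- c(0, -q$neck_offset + q$condyle_spacing / 2,
                          -q$femur_length)
  med_condyle_points <- fibonacci_sphere(200, centre = med_condyle_centre,
                                         radius = q$condyle_radius)

  # per-bone surface meshes (coarser lattice, for posing / IO / collision)
  hb <- max(h, 0.003)
  bone_meshes <- list(
    pelvis = boundary_surface(lattice_tet_mesh(function(p)
      as.integer(pelvis_inside(p, q)), c(-0.052, -0.004, 0.006),
      c(0.037, 0.032, 0.030), hb), name = "pelvis"),
    thigh = boundary_surface(fem_mesh, entities = 1L, name = "femur"),
    shank = boundary_surface(shk_mesh, entities = 1L, name = "tibiotarsus_fibula"),
    tmt = boundary_surface(lattice_tet_mesh(function(p)
      as.integer(tmt_inside(p, q)), c(-0.007, -q$pes_width / 2 - hb, -(q$tmt_length + 0.006)),
      c(0.007, q$pes_width / 2 + hb, -0.004), hb), name = "tarsometatarsus"),
    pes = boundary_surface(lattice_tet_mesh(function(p)
      as.integer(pes_inside(p, q)), c(-hb, -q$pes_width / 2 - hb, -0.009 - hb),
      c(q$pes_length + hb, q$pes_width / 2 + hb, -0.003), hb), name = "pes"))

  inside_funs <- list(
    pelvis = function(p) pelvis_inside(p, q),
    thigh = function(p) femur_inside(p, q),
    shank = function(p) shank_inside(p, q),
    tmt = function(p) tmt_inside(p, q),
    pes = function(p) pes_inside(p, q))

  # actuators, with femur/shank-hosted points snapped to bone surface nodes
  paths <- default_actuator_paths(q)
  fem_surf <- entity_surface_nodes(fem_mesh, 1L)
  shk_surf <- entity_surface_nodes(shk_mesh, 1L)
  snap <- function(pt) {
    if (pt$segment == "thigh") {
      ni <- nearest_node(fem_mesh, pt$p, fem_surf)
      pt$p <- fem_mesh$nodes[ni, ]; pt$node <- ni
    } else if (pt$segment == "shank") {
      ni <- nearest_node(shk_mesh, pt$p, shk_surf)
      pt$p <- shk_mesh$nodes[ni, ]; pt$node <- ni
    }
    pt
  }
  paths <- lapply(paths, function(path) {
    path[[1]] <- snap(path[[1]])
    path[[length(path)]] <- snap(path[[length(path)]])
    path
  })

  actuators <- lapply(names(paths), function(nm) {
    list(name = nm,
         kind = if (nm %in% .lig_names) "ligament" else "muscle",
         path = paths[[nm]],
         active = .default_activity[[nm]],
         f_max = 2 * bw)
  })
  names(actuators) <- names(paths)

  model <- structure(list(
    params = q, seed = as.integer(seed),
    body_mass = q$body_mass, gravity = gravity, bw = bw,
    segments = segments, joints = joints, actuators = actuators,
    materials = default_materials(),
    meshes = bone_meshes, inside = inside_funs,
    fe = list(femur = list(mesh = fem_mesh,
                           material_of = c("bone", "cartilage", "bone",
                                           "knee_composite", "bone"),
                           restrain_entity = 3L, remote_entity = 5L,
                           knee_contact_entities = 4L),
              shank = list(mesh = shk_mesh,
                           material_of = c("bone", "knee_composite", "bone",
                                           "cartilage", "bone"),
                           restrain_entity = 5L, remote_entity = 3L,
                           knee_contact_entities = 2L)),
    articular = list(head_points = head_points,
                     head_fit = fit_sphere(head_points),
                     med_condyle_centre = med_condyle_centre,
                     med_condyle_points = med_condyle_points,
                     med_condyle_fit = fit_sphere(med_condyle_points))),
    class = "limb_model")
  # per-session cache for FE factorizations; not part of the model data
  # (strip it before comparing two models for identity)
  model$cache <- new.env(parent = emptyenv())
  model
}

#' Drop the session cache from a model (for serialization / comparison)
#' @param model a `limb_model`.
#' @return the model without its cache environment.
#' @export
strip_cache <- function(model) {
  model$cache <- NULL
  model
}

#' @export
print.limb_model <- function(x, ...) {
  cat("Synthetic bipedal hindlimb model\n")
  cat(sprintf("  body mass %.3f kg (BW %.3f N), pelvis segment %.3f kg\n",
              x$body_mass, x$bw, x$segments$pelvis$mass))
  cat(sprintf("  %d actuators (%d active), femur FE mesh: %d tets / %d nodes\n",
              length(x$actuators),
              sum(vapply(x$actuators, function(a) a$active, logical(1))),
              nrow(x$fe$femur$mesh$tets), nrow(x$fe$femur$mesh$nodes)))
  cat(sprintf("  tibiotarsus FE mesh: %d tets / %d nodes\n",
              nrow(x$fe$shank$mesh$tets), nrow(x$fe$shank$mesh$nodes)))
  invisible(x)
}

#' Per-muscle maximum-force sensitivity mode
#'
#' Returns a copy of the model with muscle-specific maximum forces (derived
#' from muscle architecture at a constant isometric stress of 3e5 N/m^2)
#' assigned to the active muscles; ligament maxima are left at the uniform
#' default. Everything else, including the solver path, is unchanged.
#'
#' @param model a `limb_model`.
#' @return modified `limb_model`.
#' @export
apply_muscle_specific_fmax <- function(model) {
  for (nm in names(.muscle_specific_fmax)) {
    if (nm %in% names(model$actuators))
      model$actuators[[nm]]$f_max <- .muscle_specific_fmax[[nm]]
  }
  model
}

#' Scale the maximum force of every actuator
#' @param model a `limb_model`.
#' @param factor multiplicative factor.
#' @return modified `limb_model`.
#' @export
scale_fmax <- function(model, factor) {
  for (nm in names(model$actuators))
    model$actuators[[nm]]$f_max <- model$actuators[[nm]]$f_max * factor
  model
}
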