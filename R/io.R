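# Global frame stamped into every output: +x anterior, +y medial, +z dorsal
# (right limb). Guards against silent frame mismatches between files.
.frame_stamp <- "+x anterior, +y medial, +z dorsal; right limb; SI units (m)"

#' Write a surface mesh as ASCII STL
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nn <- sqrt(rowSums(nrm^2)); nrm <- nrm / pmax(nn, 1e-300)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s (%s)", mesh$name, .frame_stamp), con)
  for (i in seq_len(nrow(tr))) {
    writeLines(c(sprintf("  facet normal %.9e %.9e %.9e",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9e %.9e %.9e",
                         c(a[i, 1], b[i, 1], c_[i, 1]),
                         c(a[i, 2], b[i, 2], c_[i, 2]),
                         c(a[i, 3], b[i, 3], c_[i, 3])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
  invisible(path)
}

#' Read an ASCII STL surface mesh
#' @param path STL file.
#' @param name mesh label (default from the solid line).
#' @return a `surface_mesh` with merged vertices.
#' @export
read_stl <- function(path, name = NULL) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(s)
    as.numeric(s[2:4])))
  if (nrow(xyz) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- apply(xyz, 1, function(r) paste(sprintf("%.12e", r), collapse = "_"))
  uk <- !duplicated(key)
  verts <- xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  if (is.null(name)) {
    sl <- grep("^solid", lines, value = TRUE)
    name <- if (length(sl)) sub("^solid\\s*", "", sl[1]) else "stl"
  }
  surface_mesh(verts, tris, name = name)
}

#' Write a surface mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment", mesh$name, "-", .frame_stamp),
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, digits = 12, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#' @param path PLY file.
#' @param name mesh label.
#' @return a `surface_mesh`.
#' @export
read_ply <- function(path, name = "ply") {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[endh + seq_len(nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(s)
    as.numeric(s[1:3])))
  fl <- lines[endh + nv + seq_len(nf)]
  tris <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(s)
    as.integer(s[2:4]) + 1L))
  surface_mesh(verts, tris, name = name)
}

#' Write a volume mesh (with optional nodal fields) as legacy VTK
#'
#' Unstructured grid of tetrahedra. Nodal fields are written as POINT_DATA:
#' matrices with 3 columns as VECTORS, 6 columns as symmetric TENSORS
#' (expanded to 9 components), 1 column as SCALARS.
#'
#' @param vm a `volume_mesh` (or a list with `nodes` only, written as a
#'   point cloud of VERTICES).
#' @param path output .vtk file.
#' @param point_data named list of per-node fields.
#' @export
write_vtk <- function(vm, path, point_data = list()) {
  con <- file(path, "w"); on.exit(close(con))
  nodes <- vm$nodes
  writeLines(c("# vtk DataFile Version 3.0",
               paste("fabpose output;", .frame_stamp),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(nodes), "double")), con)
  utils::write.table(format(nodes, digits = 9), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(vm$tets)) {
    m <- nrow(vm$tets)
    writeLines(paste("CELLS", m, 5 * m), con)
    utils::write.table(cbind(4L, vm$tets - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    writeLines(paste("CELL_TYPES", m), con)
    writeLines(as.character(rep(10L, m)), con)
  } else {
    n <- nrow(nodes)
    writeLines(paste("CELLS", n, 2 * n), con)
    utils::write.table(cbind(1L, seq_len(n) - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    writeLines(paste("CELL_TYPES", n), con)
    writeLines(as.character(rep(1L, n)), con)
  }
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", nrow(nodes)), con)
    for (nm in names(point_data)) {
      fd <- as.matrix(point_data[[nm]])
      if (ncol(fd) == 3) {
        writeLines(paste("VECTORS", nm, "double"), con)
        utils::write.table(format(fd, digits = 9), con, row.names = FALSE,
                           col.names = FALSE, quote = FALSE)
      } else if (ncol(fd) == 6) {
        writeLines(paste("TENSORS", nm, "double"), con)
        full <- fd[, c(1, 4, 6, 4, 2, 5, 6, 5, 3), drop = FALSE]
        for (i in seq_len(nrow(full)))
          writeLines(paste(format(full[i, ], digits = 9), collapse = " "), con)
      } else {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(fd[, 1], digits = 9), con)
      }
    }
  }
  invisible(path)
}

#' Write / read a fabric field as CSV (x, y, z, u1x, u1y, u1z)
#' @param fabric a `fabric_field`.
#' @param path CSV file.
#' @export
write_fabric_csv <- function(fabric, path) {
  df <- data.frame(x = fabric$points[, 1], y = fabric$points[, 2],
                   z = fabric$points[, 3], u1x = fabric$u1[, 1],
                   u1y = fabric$u1[, 2], u1z = fabric$u1[, 3],
                   valid = as.integer(fabric$valid))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# frame:", .frame_stamp),
               paste("# provenance:", fabric$provenance)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fabric_csv
#' @return a `fabric_field`.
#' @export
read_fabric_csv <- function(path) {
  lines <- readLines(path)
  prov <- sub("^# provenance:\\s*", "",
              grep("^# provenance:", lines, value = TRUE))
  if (length(prov) == 0) prov <- "imported"
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  valid <- if ("valid" %in% names(df)) df$valid > 0 else NULL
  fabric_field(as.matrix(df[, c("x", "y", "z")]),
               as.matrix(df[, c("u1x", "u1y", "u1z")]),
               provenance = prov, valid = valid)
}

#' Write / read a posture as YAML or JSON (by file extension)
#' @param post a `posture`.
#' @param path output path ending in .yaml/.yml or .json.
#' @export
write_posture <- function(post, path) {
  post <- as_posture(post)
  x <- list(frame = .frame_stamp,
            units = "degrees",
            sign_conventions = paste("positive hip_abduction = abduction;",
                                     "positive hip_lar = external rotation"),
            angles = unclass(post)[.free_dofs])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_posture
#' @return a `posture`.
#' @export
read_posture <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  do.call(posture, c(x$angles, list(ranges = list())))
}

#' Write an activation solution as CSV (actuator, activation, force)
#' @param solution an `activation_solution`.
#' @param path CSV file.
#' @export
write_activations_csv <- function(solution, path) {
  df <- data.frame(actuator = names(solution$activations),
                   activation = as.numeric(solution$activations),
                   force_N = as.numeric(solution$forces))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write joint reactions as JSON
#' @param jl a `joint_loads`.
#' @param path JSON file.
#' @export
write_joint_loads_json <- function(jl, path) {
  x <- list(frame = .frame_stamp,
            joints = lapply(jl$joints, function(j)
              list(force_N = j$force, moment_Nm = j$moment,
                   centre_m = j$centre)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the actuator table as CSV (one row per path point)
#'
#' Columns mirror an anatomy table: actuator, kind, active flag, maximum
#' force, point index, host segment and local coordinates.
#'
#' @param model a `limb_model`.
#' @param path CSV file.
#' @export
write_actuator_csv <- function(model, path) {
  rows <- list()
  for (nm in names(model$actuators)) {
    a <- model$actuators[[nm]]
    for (i in seq_along(a$path)) {
      pt <- a$path[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        actuator = nm, kind = a$kind, active = a$active, f_max = a$f_max,
        point = i, segment = pt$segment, x = pt$p[1], y = pt$p[2],
        z = pt$p[3], stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an actuator table written by [write_actuator_csv()]
#' @param path CSV file.
#' @return named list of actuator entries.
#' @export
read_actuator_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (nm in unique(df$actuator)) {
    sub <- df[df$actuator == nm, , drop = FALSE]
    sub <- sub[order(sub$point), , drop = FALSE]
    out[[nm]] <- list(
      name = nm, kind = sub$kind[1], active = as.logical(sub$active[1]),
      f_max = sub$f_max[1],
      path = lapply(seq_len(nrow(sub)), function(i)
        list(segment = sub$segment[i],
             p = c(sub$x[i], sub$y[i], sub$z[i]))))
  }
  out
}

#' Axial vectors to stereoplot coordinates
#'
#' Azimuth (degrees from +x, counterclockwise about +z) and inclination
#' (degrees below the horizontal plane) of each axial vector, using the
#' lower-hemisphere convention (vectors are flipped to point downward).
#'
#' @param V n x 3 axial unit vectors.
#' @return data.frame with `azimuth_deg`, `inclination_deg`.
#' @export
axial_to_stereo <- function(V) {
  V <- as.matrix(V)
  flip <- V[, 3] > 0
  V[flip, ] <- -V[flip, , drop = FALSE]
  az <- atan2(V[, 2], V[, 1]) * 180 / pi
  inc <- asin(pmin(1, -V[, 3])) * 180 / pi
  data.frame(azimuth_deg = az, inclination_deg = inc)
}
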