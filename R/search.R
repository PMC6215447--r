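#' Search configuration
#'
#' @param start a `posture`: the initial (avian mid-stance) posture.
#' @param steps step-size schedule (degrees) for the coordinate descent.
#' @param min_improve minimum score improvement (degrees) that counts as
#'   progress; smaller changes are treated as "similar correspondence".
#' @param max_evals cap on pipeline evaluations.
#' @param dims joints varied directly by the search, in hierarchy order;
#'   ankle and MTP angles are always re-derived by the admissibility repair
#'   (flat foot, COP under COM), and hip abduction/long-axis rotation by the
#'   step-width repair.
#' @param step_ratio_target step-width-to-hip-height ratio the repair aims
#'   for (must be below the 0.15 admissibility limit).
#' @param cop_tol tolerance on |COP_x - COM_x| (m).
#' @param run_shank run the tibiotarsus simulation in each evaluation.
#' @param seed integer seed recorded in the audit trail.
#' @return list of class `search_config`.
#' @export
search_config <- function(start = posture(), steps = c(10, 5, 2.5),
                          min_improve = 0.5, max_evals = 80,
                          dims = c("hip_extension", "knee_flexion"),
                          step_ratio_target = 0.10, cop_tol = 0.001,
                          run_shank = FALSE, seed = 1L) {
  structure(list(start = start, steps = steps, min_improve = min_improve,
                 max_evals = max_evals, dims = dims,
                 step_ratio_target = step_ratio_target, cop_tol = cop_tol,
                 run_shank = run_shank, seed = as.integer(seed)),
            class = "search_config")
}

#' Repair a posture to admissibility
#'
#' Adjusts the distal and frontal-plane joints so the posture satisfies the
#' three admissibility criteria: the MTP angle is set so the pes lies flat
#' on the ground; hip abduction is adjusted (secant iteration) until the
#' step width reaches the target fraction of hip height; the ankle angle is
#' adjusted until the COP lies under the whole-body COM in x. Hip extension
#' and knee flexion are never modified.
#'
#' @param model a `limb_model`.
#' @param post a `posture`.
#' @param config a `search_config` (for targets/tolerances).
#' @return an admissible `posture`.
#' @export
repair_posture <- function(model, post, config = search_config()) {
  post <- as_posture(post)
  ranges <- default_posture_ranges()
  clamp <- function(v, nm) min(max(v, ranges[[nm]][1]), ranges[[nm]][2])
  mid_y <- model$params$hip_to_midline
  set <- function(p, nm, v) {
    vals <- unclass(p)[.free_dofs]; vals[[nm]] <- v
    do.call(posture, c(vals, list(ranges = list())))
  }
  secant <- function(p, nm, fun, target, tol, d0 = 4) {
    x0 <- unclass(p)[[nm]]; f0 <- fun(set(p, nm, x0)) - target
    if (abs(f0) < tol) return(p)
    x1 <- clamp(x0 + d0, nm); f1 <- fun(set(p, nm, x1)) - target
    for (k in 1:25) {
      if (f1 == f0) break
      x2 <- clamp(x1 - f1 * (x1 - x0) / (f1 - f0), nm)
      x0 <- x1; f0 <- f1
      x1 <- x2; f1 <- fun(set(p, nm, x1)) - target
      if (abs(f1) < tol) break
    }
    set(p, nm, x1)
  }
  for (outer in 1:6) {
    post <- flat_foot_mtp(model, post)
    posed <- pose_limb(model, post, check = FALSE)
    hh <- posed$hip_height
    # step width toward target ratio (right foot lateral of the midline)
    target_y <- mid_y - config$step_ratio_target * hh / 2
    fy <- function(p) {
      p <- flat_foot_mtp(model, p)
      pose_limb(model, p, check = FALSE)$cop[2]
    }
    post <- secant(post, "hip_abduction", fy, target_y, 2e-4)
    post <- flat_foot_mtp(model, post)
    # COP under COM in x via the ankle: closed-form initialization picking
    # the least-reclined tarsometatarsus branch, then secant polish
    posed <- pose_limb(model, post, check = FALSE)
    jc <- joint_centres(posed, model)
    Lm <- model$params$tmt_length
    dx <- (posed$com[1] - model$params$pes_length / 2) - jc["ankle", 1]
    dx <- min(max(dx, -0.9 * Lm), 0.9 * Lm)
    d_glob <- c(sin(asin(dx / Lm)), 0, -cos(asin(dx / Lm)))
    d_loc <- as.numeric(t(posed$transforms$shank$R) %*% d_glob)
    a_init <- atan2(d_loc[1], -d_loc[3]) * 180 / pi
    post <- set(post, "ankle_flexion", clamp(a_init, "ankle_flexion"))
    fx <- function(p) {
      p <- flat_foot_mtp(model, p)
      q <- pose_limb(model, p, check = FALSE)
      q$cop[1] - q$com[1]
    }
    post <- secant(post, "ankle_flexion", fx, 0, config$cop_tol / 4, d0 = 2)
    post <- flat_foot_mtp(model, post)
    posed <- pose_limb(model, post, check = FALSE)
    cc <- check_posture_constraints(posed, model, cop_tol = config$cop_tol)
    if (cc$all_pass) return(post)
  }
  stop("search stall: no admissible posture found near (",
       paste(signif(unlist(unclass(post)[.free_dofs]), 4), collapse = ", "),
       "); violated: ",
       paste(names(Filter(function(x) is.list(x) && !x$pass,
                          cc[c("interpenetration", "cop_under_com",
                               "step_width")])), collapse = ", "))
}

#' Propose the next candidate posture
#'
#' Perturbs the highest-priority joint not yet explored at the current step
#' size (hip extension before knee), then repairs admissibility. Used
#' internally by [run_search()]; exposed for audit and testing.
#'
#' @param model a `limb_model`.
#' @param state search state (list with `best`, `step`, `dim_index`,
#'   `direction`, `config`).
#' @return list with the proposed admissible `posture` and the updated
#'   state cursor.
#' @export
propose_posture <- function(model, state) {
  cfg <- state$config
  dim <- cfg$dims[state$dim_index]
  vals <- unclass(state$best$posture)[.free_dofs]
  vals[[dim]] <- vals[[dim]] + state$direction * state$step
  cand <- do.call(posture, c(vals, list(ranges = list())))
  cand <- repair_posture(model, cand, cfg)
  list(posture = cand, dim = dim, direction = state$direction)
}

#' Run the posture search
#'
#' Deterministic coordinate descent over the joint hierarchy with a
#' shrinking step schedule, formalizing the manual iterate-and-compare
#' protocol: propose a perturbed posture (hip extension first, then knee),
#' repair it to admissibility, evaluate the full pipeline, and accept
#' strict improvements of the weighted alignment score. A step level
#' terminates when a full sweep yields no improvement of at least
#' `min_improve` degrees; the search ends after the final (smallest) step
#' level, or at the evaluation cap.
#'
#' @param model a `limb_model`.
#' @param fabric a `fabric_field` (femur-local frame).
#' @param config a `search_config`.
#' @param regions scored regions (default [default_regions()]).
#' @param verbose print progress lines.
#' @return list with `posture` (solution), `score`, `history` (data.frame
#'   audit trail), `evaluations`, `capped`.
#' @export
run_search <- function(model, fabric, config = search_config(),
                       regions = default_regions(model), verbose = FALSE) {
  eval_one <- function(post) {
    evaluate_posture(model, post, fabric, regions = regions,
                     run_shank = config$run_shank)
  }
  hist <- list()
  push <- function(post, score, accepted, note) {
    vals <- unclass(post)[.free_dofs]
    hist[[length(hist) + 1]] <<- data.frame(
      eval = length(hist) + 1L, as.data.frame(vals),
      score = score, accepted = accepted, note = note,
      stringsAsFactors = FALSE)
  }
  start <- repair_posture(model, config$start, config)
  rep0 <- eval_one(start)
  best <- list(posture = start, report = rep0, score = rep0$score$score)
  push(start, best$score, TRUE, "start")
  n_eval <- 1L
  capped <- FALSE
  for (step in config$steps) {
    repeat {
      improved <- FALSE
      for (di in seq_along(config$dims)) {
        for (dir in c(1, -1)) {
          if (n_eval >= config$max_evals) { capped <- TRUE; break }
          state <- list(best = best, step = step, dim_index = di,
                        direction = dir, config = config)
          cand <- tryCatch(propose_posture(model, state),
                           error = function(e) NULL)
          if (is.null(cand)) next
          rep <- tryCatch(eval_one(cand$posture), error = function(e) NULL)
          n_eval <- n_eval + 1L
          if (is.null(rep)) {
            push(cand$posture, NA_real_, FALSE, paste0(cand$dim, " failed"))
            next
          }
          acc <- rep$score$score < best$score - config$min_improve
          push(cand$posture, rep$score$score, acc,
               paste0(cand$dim, ifelse(dir > 0, "+", "-"), step))
          if (verbose)
            cat(sprintf("eval %d %s%s%g score %.2f (best %.2f)%s\n", n_eval,
                        cand$dim, ifelse(dir > 0, "+", "-"), step,
                        rep$score$score, best$score, if (acc) " *" else ""))
          if (acc) {
            best <- list(posture = cand$posture, report = rep,
                         score = rep$score$score)
            improved <- TRUE
          }
        }
        if (capped) break
      }
      if (!improved || capped) break
    }
    if (capped) break
  }
  if (capped) warning("evaluation cap reached; returning best so far")
  list(posture = best$posture, score = best$score, report = best$report,
       history = do.call(rbind, hist), evaluations = n_eval, capped = capped)
}

#' Fit the characteristic posture to a fabric field
#'
#' The top-level estimator: searches for the limb posture whose
#' continuum-level principal-stress trajectories best align with the given
#' cancellous-bone fabric field, and returns a fitted-model object.
#'
#' @param model a `limb_model`.
#' @param fabric a `fabric_field`.
#' @param config a `search_config`.
#' @param ... passed to [run_search()].
#' @return object of class `posture_fit`.
#' @export
fit_posture <- function(model, fabric, config = search_config(), ...) {
  res <- run_search(model, fabric, config, ...)
  posed <- pose_limb(model, res$posture)
  structure(list(posture = res$posture, score = res$score,
                 report = res$report, history = res$history,
                 evaluations = res$evaluations, capped = res$capped,
                 config = config, model = model,
                 crouch = degree_of_crouch(posed, model)),
            class = "posture_fit")
}

#' @export
print.posture_fit <- function(x, ...) {
  cat("Characteristic posture fit\n")
  print(x$posture)
  cat(sprintf("  weighted alignment score: %.2f deg over %d evaluations\n",
              x$score, x$evaluations))
  invisible(x)
}

#' @export
coef.posture_fit <- function(object, ...) {
  unlist(unclass(object$posture)[.free_dofs])
}

#' @export
summary.posture_fit <- function(object, ...) {
  cat("Characteristic posture fit\n")
  print(object$posture)
  cat(sprintf("  weighted alignment score: %.2f deg\n", object$score))
  print(object$report$score)
  cat(sprintf("  degree of crouch: %.3f (%s metric)\n",
              object$crouch$value, object$crouch$metric))
  cat(sprintf("  evaluations: %d; accepted improvements: %d\n",
              object$evaluations, sum(object$history$accepted, na.rm = TRUE)))
  invisible(object)
}

#' @export
plot.posture_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::plot(h$eval, h$score, type = "p", pch = 16,
                 col = ifelse(h$accepted, "firebrick", "grey60"),
                 xlab = "evaluation", ylab = "alignment score (deg)",
                 main = "search trajectory")
  acc <- h[which(h$accepted), ]
  graphics::lines(acc$eval, acc$score, col = "firebrick")
  posed <- pose_limb(x$model, x$posture)
  jc <- joint_centres(posed, x$model)
  pts <- rbind(jc, apply_transform(posed$transforms$pes,
                                   c(x$model$params$pes_length, 0, -0.006)))
  graphics::plot(pts[, 1], pts[, 3], type = "o", pch = 16, asp = 1,
                 xlab = "x (anterior, m)", ylab = "z (dorsal, m)",
                 main = "solution posture (sagittal)")
  invisible(x)
}
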