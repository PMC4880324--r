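#' Interaction record
#'
#' One step of a correction session: a contour drag on a slice plane, or a
#' change of the active control-grid mode. Traces of these records are fully
#' self-describing — replaying them against the same initial segmentation
#' reproduces the same final mesh.
#'
#' @param kind "drag", "set_local_grid" or "set_global_grid".
#' @param plane a [slice_plane()] (drag records).
#' @param start2d,end2d length-2 in-plane mm coordinates (drag records).
#' @param grid_center,grid_size length-3 mm (set_local_grid records).
#' @param timestamp numeric wall-clock seconds (informational only).
#' @return an `interaction_record`.
#' @export
interaction_record <- function(kind, plane = NULL, start2d = NULL,
                               end2d = NULL, grid_center = NULL,
                               grid_size = NULL,
                               timestamp = as.numeric(Sys.time())) {
  kind <- match.arg(kind, c("drag", "set_local_grid", "set_global_grid"))
  if (kind == "drag" && (is.null(plane) || is.null(start2d) || is.null(end2d)))
    stop("drag records need plane, start2d and end2d")
  if (kind == "set_local_grid" && (is.null(grid_center) || is.null(grid_size)))
    stop("set_local_grid records need grid_center and grid_size")
  structure(list(kind = kind, plane = plane,
                 start2d = if (is.null(start2d)) NULL else as.numeric(start2d),
                 end2d = if (is.null(end2d)) NULL else as.numeric(end2d),
                 grid_center = if (is.null(grid_center)) NULL else as.numeric(grid_center),
                 grid_size = if (is.null(grid_size)) NULL else as.numeric(grid_size),
                 timestamp = timestamp),
            class = "interaction_record")
}

# The single engine step shared by the scripted user and trace replay, so a
# replayed trace goes through bit-identical arithmetic. State holds the
# current mesh and the active grid mode.
apply_interaction <- function(state, record, geometry, config) {
  if (record$kind == "set_global_grid") {
    state$grid_mode <- "global"
    state$local_center <- NULL; state$local_size <- NULL
    return(state)
  }
  if (record$kind == "set_local_grid") {
    state$grid_mode <- "local"
    state$local_center <- record$grid_center
    state$local_size <- record$grid_size
    return(state)
  }
  lifted <- lift_drag(record$plane, geometry, record$start2d, record$end2d)
  contour <- extract_contour(state$mesh, record$plane, geometry)
  if (length(contour$polylines) == 0L)
    stop("drag plane does not intersect the mesh")
  vid <- pick_vertex(state$mesh, contour, lifted$start)
  grid <- if (state$grid_mode == "local") {
    fit_local_grid(state$local_center, state$local_size, config$degrees)
  } else {
    fit_global_grid(state$mesh, config$degrees, config$padding)
  }
  state$mesh <- apply_drag(state$mesh, grid, vid, lifted$displacement)
  state
}

#' Scripted-user correction simulation
#'
#' Deterministic stand-in for a human operator following a slice-wise
#' correction protocol: scan a fixed, axis-interleaved set of slice planes;
#' on each plane compare the current segmentation contour with the
#' ground-truth contour; pick the contour point with the largest in-plane
#' error; drag it to its nearest ground-truth contour point (one drag per
#' interaction); repeat until the Dice target is reached, the interaction
#' cap is hit, or the largest remaining contour error falls below
#' `min_drag_mm`. Every interaction is recorded together with the post-step
#' Dice; a drag that decreases Dice is kept but flagged.
#'
#' @param initial_mesh the imperfect segmentation [triangle_mesh()].
#' @param gt_mask ground-truth `seg_mask` (drives the Dice stop criterion).
#' @param gt_mesh ground-truth [triangle_mesh()] (drives contour targets).
#' @param geometry the [image_geometry()] of the case.
#' @param policy "global" (one fixed grid around the shape) or "local"
#'   (a grid re-fitted around each drag point, sized by the error).
#' @param dice_target stop when Dice reaches this (default 0.95).
#' @param max_interactions interaction cap (default 150).
#' @param stride scan every `stride`-th slice per axis (default 8).
#' @param min_drag_mm ignore residual contour errors below this (default 0.1).
#' @param config a [correction_config()].
#' @param case_id label stored in the trace metadata.
#' @return a `correction_trace`: list with `records`, `steps` (data.frame of
#'   per-interaction Dice), `initial_dice`, `final_dice`, `final_mesh`,
#'   `n_interactions`, `elapsed_s`, `config`, `policy`, `case_id`.
#' @export
scripted_user <- function(initial_mesh, gt_mask, gt_mesh, geometry,
                          policy = c("global", "local"),
                          dice_target = 0.95, max_interactions = 150L,
                          stride = 8L, min_drag_mm = 0.1,
                          config = correction_config(),
                          case_id = "case") {
  policy <- match.arg(policy)
  t0 <- proc.time()[["elapsed"]]
  planes <- scan_planes(geometry, stride)
  gt_contours <- lapply(planes, function(pl)
    extract_contour(gt_mesh, pl, geometry))
  state <- list(mesh = initial_mesh, grid_mode = "global",
                local_center = NULL, local_size = NULL)
  dice0 <- dice_coefficient(rasterize_mesh(initial_mesh, geometry), gt_mask)
  dice <- dice0
  records <- list()
  steps <- list()
  n_drag <- 0L
  while (dice < dice_target && n_drag < max_interactions) {
    worst <- find_worst_error(state$mesh, gt_contours, planes, geometry)
    if (is.null(worst) || worst$err < min_drag_mm) break
    new_records <- list()
    if (policy == "local") {
      size <- pmax(config$local_size_factor * worst$err,
                   config$local_floor_voxels * geometry$spacing)
      new_records[[1]] <- interaction_record(
        "set_local_grid", grid_center = worst$start_world, grid_size = size)
    }
    new_records[[length(new_records) + 1L]] <- interaction_record(
      "drag", plane = worst$plane, start2d = worst$start2d,
      end2d = worst$end2d)
    for (rec in new_records)
      state <- apply_interaction(state, rec, geometry, config)
    records <- c(records, new_records)
    n_drag <- n_drag + 1L
    prev <- dice
    dice <- dice_coefficient(rasterize_mesh(state$mesh, geometry), gt_mask)
    steps[[n_drag]] <- data.frame(
      interaction = n_drag,
      axis = if (worst$plane$kind == "canonical") worst$plane$axis else "arbitrary",
      index = if (worst$plane$kind == "canonical") worst$plane$index else NA_integer_,
      error_mm = worst$err, dice = dice, decreased_dice = dice < prev)
  }
  structure(list(
    records = records,
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(interaction = integer(), axis = character(),
                 index = integer(), error_mm = numeric(), dice = numeric(),
                 decreased_dice = logical()),
    initial_dice = dice0, final_dice = dice, final_mesh = state$mesh,
    n_interactions = n_drag,
    elapsed_s = proc.time()[["elapsed"]] - t0,
    config = config, policy = policy, case_id = case_id),
    class = "correction_trace")
}

#' @export
print.correction_trace <- function(x, ...) {
  cat(sprintf("correction_trace '%s': %d interaction(s), Dice %.4f -> %.4f (%.1f s, %s grid policy)\n",
              x$case_id, x$n_interactions, x$initial_dice, x$final_dice,
              x$elapsed_s, x$policy))
  invisible(x)
}

# Fixed, deterministic slice-scan order: every `stride`-th slice of each
# axis, round-robin over axial / coronal / sagittal.
scan_planes <- function(geometry, stride) {
  per_axis <- lapply(c("axial", "coronal", "sagittal"), function(ax) {
    nax <- geometry$shape[canonical_axis_index(ax)]
    idx <- seq(max(stride %/% 2, 1L), nax - 1L, by = stride)
    lapply(idx, function(i) slice_plane(axis = ax, index = i))
  })
  nmax <- max(lengths(per_axis))
  out <- list()
  for (i in seq_len(nmax))
    for (a in 1:3)
      if (i <= length(per_axis[[a]]))
        out[[length(out) + 1L]] <- per_axis[[a]][[i]]
  out
}

# Largest in-plane contour-to-contour error over the scanned planes; returns
# the drag endpoints in both 2D and world coordinates.
find_worst_error <- function(mesh, gt_contours, planes, geometry) {
  worst <- NULL
  for (pi in seq_along(planes)) {
    gtc <- gt_contours[[pi]]
    if (length(gtc$polylines) == 0L) next
    cur <- extract_contour(mesh, planes[[pi]], geometry)
    if (length(cur$polylines) == 0L) next
    cp <- contour_points(cur)
    gp <- contour_points(gtc)
    d2 <- outer(rowSums(cp$plane2d^2), rowSums(gp$plane2d^2), `+`) -
      2 * cp$plane2d %*% t(gp$plane2d)
    nearest <- apply(d2, 1, which.min)
    derr <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), nearest)], 0))
    imax <- which.max(derr)
    if (is.null(worst) || derr[imax] > worst$err) {
      worst <- list(err = derr[imax], plane = planes[[pi]],
                    start2d = cp$plane2d[imax, ],
                    end2d = gp$plane2d[nearest[imax], ],
                    start_world = cp$world[imax, ])
    }
  }
  worst
}

#' Replay an interaction trace
#'
#' Applies recorded interactions in order through the same engine step used
#' when they were captured; with the same initial mesh and geometry the
#' result is bit-for-bit the mesh of the original session. If a ground-truth
#' mask is supplied, per-step Dice is recomputed.
#'
#' @param initial_mesh the starting [triangle_mesh()].
#' @param geometry the [image_geometry()].
#' @param records list of [interaction_record()]s (or a `correction_trace`).
#' @param config a [correction_config()]; defaults to the trace's own config
#'   when `records` is a `correction_trace`.
#' @param gt_mask optional ground-truth `seg_mask` for per-step Dice.
#' @return list with `final_mesh` and `trace` (a `correction_trace`).
#' @export
replay_trace <- function(initial_mesh, geometry, records,
                         config = NULL, gt_mask = NULL) {
  if (inherits(records, "correction_trace")) {
    if (is.null(config)) config <- records$config
    records <- records$records
  }
  if (is.null(config)) config <- correction_config()
  state <- list(mesh = initial_mesh, grid_mode = "global",
                local_center = NULL, local_size = NULL)
  dice0 <- if (is.null(gt_mask)) NA_real_ else
    dice_coefficient(rasterize_mesh(initial_mesh, geometry), gt_mask)
  dice <- dice0
  steps <- list()
  n_drag <- 0L
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    state <- tryCatch(
      apply_interaction(state, rec, geometry, config),
      error = function(e) stop(sprintf("record %d: %s", ri, conditionMessage(e)),
                               call. = FALSE))
    if (rec$kind == "drag") {
      n_drag <- n_drag + 1L
      prev <- dice
      if (!is.null(gt_mask))
        dice <- dice_coefficient(rasterize_mesh(state$mesh, geometry), gt_mask)
      steps[[n_drag]] <- data.frame(
        interaction = n_drag,
        axis = if (rec$plane$kind == "canonical") rec$plane$axis else "arbitrary",
        index = if (rec$plane$kind == "canonical") rec$plane$index else NA_integer_,
        error_mm = NA_real_, dice = dice,
        decreased_dice = !is.null(gt_mask) && !is.na(prev) && dice < prev)
    }
  }
  trace <- structure(list(
    records = records,
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(interaction = integer(), axis = character(),
                 index = integer(), error_mm = numeric(), dice = numeric(),
                 decreased_dice = logical()),
    initial_dice = dice0, final_dice = dice, final_mesh = state$mesh,
    n_interactions = n_drag, elapsed_s = NA_real_,
    config = config, policy = "replay", case_id = "replay"),
    class = "correction_trace")
  list(final_mesh = state$mesh, trace = trace)
}

#' Write an interaction trace to JSON
#'
#' Self-describing: the file embeds the correction configuration, so replay
#' needs only the trace and the initial segmentation.
#'
#' @param trace a `correction_trace` (or plain list of records).
#' @param path output `.json` path.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "correction_trace")) {
    records <- trace$records; config <- trace$config
    meta <- list(case_id = trace$case_id, policy = trace$policy,
                 initial_dice = trace$initial_dice,
                 final_dice = trace$final_dice,
                 n_interactions = trace$n_interactions,
                 elapsed_s = trace$elapsed_s)
  } else {
    records <- trace; config <- correction_config(); meta <- NULL
  }
  recs <- lapply(records, function(r) {
    out <- list(kind = r$kind, timestamp = r$timestamp)
    if (!is.null(r$plane)) {
      out$plane <- if (r$plane$kind == "canonical")
        list(axis = r$plane$axis, index = r$plane$index)
      else list(point = r$plane$point, normal = r$plane$normal)
    }
    for (f in c("start2d", "end2d", "grid_center", "grid_size"))
      if (!is.null(r[[f]])) out[[f]] <- r[[f]]
    out
  })
  jsonlite::write_json(list(format = "dmffd-trace-1",
                            config = unclass(config), metadata = meta,
                            records = recs),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read an interaction trace from JSON
#' @param path file written by [write_trace()].
#' @return list with `records` and `config`.
#' @export
read_trace <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(x$format, "dmffd-trace-1"))
    stop("not a dmffd trace file")
  cfg <- correction_config(unlist(x$config$degrees), x$config$padding,
                           x$config$local_size_factor,
                           x$config$local_floor_voxels)
  records <- lapply(x$records, function(r) {
    plane <- NULL
    if (!is.null(r$plane)) {
      plane <- if (!is.null(r$plane$axis))
        slice_plane(axis = r$plane$axis, index = r$plane$index)
      else slice_plane(point = unlist(r$plane$point),
                       normal = unlist(r$plane$normal))
    }
    interaction_record(r$kind, plane = plane,
                       start2d = unlist(r$start2d), end2d = unlist(r$end2d),
                       grid_center = unlist(r$grid_center),
                       grid_size = unlist(r$grid_size),
                       timestamp = if (is.null(r$timestamp)) NA_real_ else r$timestamp)
  })
  list(records = records, config = cfg)
}

#' Export a contour as JSON
#'
#' Plane specification plus polylines in both world and in-plane
#' coordinates.
#'
#' @param contour a `mesh_contour`.
#' @param path output `.json` path.
#' @export
write_contour_json <- function(contour, path) {
  pl <- contour$plane
  plane <- if (pl$kind == "canonical")
    list(axis = pl$axis, index = pl$index)
  else list(point = pl$point, normal = pl$normal)
  polys <- lapply(contour$polylines, function(p)
    list(closed = p$closed,
         world = as.data.frame(p$world),
         plane2d = as.data.frame(p$plane2d)))
  jsonlite::write_json(list(plane = plane, polylines = polys), path,
                       digits = I(17), auto_unbox = TRUE)
  invisible(path)
}
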