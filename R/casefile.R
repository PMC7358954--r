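#' Surgical case file
#'
#' A case bundles everything a navigation session needs: landmark pairs in
#' frame and anatomical space, named targets, per-side dial readings,
#' fixed trajectories, the frame model, and free-text provenance notes.
#' Cases serialize losslessly to JSON ([write_case()] / [read_case()]) and
#' landmark/point tables import from CSV ([read_landmarks_csv()]).
#'
#' @param landmarks Named list of [point3] objects (landmarks and targets
#'   in any space; names like `"ac_frame"`, `"ac_anatomical"` pair up by
#'   prefix).
#' @param dials Named list per side, each `list(ring =, arc =, gamma =)`.
#' @param trajectories Named list of [trajectory] objects.
#' @param frame_model Frame model name (see [list_frame_models()]).
#' @param notes Character provenance notes.
#' @return An object of class `case_file`.
#' @export
case_file <- function(landmarks = list(), dials = list(),
                      trajectories = list(), frame_model = "CRW",
                      notes = character()) {
  stopifnot(is.list(landmarks), is.list(dials), is.list(trajectories))
  if (length(landmarks) && is.null(names(landmarks))) {
    stop("landmarks must be named", call. = FALSE)
  }
  for (nm in names(landmarks)) {
    p <- landmarks[[nm]]
    if (!is_point3(p)) {
      stop(sprintf("landmarks$%s: not a point3", nm), call. = FALSE)
    }
  }
  frame_model(frame_model)                # validates the name
  structure(list(landmarks = landmarks, dials = dials,
                 trajectories = trajectories, frame_model = frame_model,
                 notes = notes, schema_version = 1L),
            class = "case_file")
}

#' @export
print.case_file <- function(x, ...) {
  cat(sprintf("<case_file> frame %s: %d landmarks, %d dial sets, %d trajectories\n",
              x$frame_model, length(x$landmarks), length(x$dials),
              length(x$trajectories)))
  invisible(x)
}

#' Write a case file to JSON
#'
#' Full double precision is kept (digits = NA); a written case reads back
#' exactly.
#'
#' @param case A [case_file].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "case_file"))
  obj <- list(
    schema_version = case$schema_version,
    frame_model = case$frame_model,
    notes = case$notes,
    landmarks = lapply(case$landmarks, function(p)
      list(space = p$space, ap = p$coords[["ap"]], lat = p$coords[["lat"]],
           vert = p$coords[["vert"]])),
    dials = case$dials,
    trajectories = lapply(case$trajectories, function(tr)
      list(space = tr$space,
           entry = as.list(stats::setNames(tr$entry, c("ap", "lat", "vert"))),
           target = as.list(stats::setNames(tr$target, c("ap", "lat", "vert")))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a case file from JSON
#'
#' Validates the schema and reports the offending field path on failure.
#'
#' @param path Path to a JSON case written by [write_case()].
#' @return A [case_file].
#' @export
read_case <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  get_num <- function(x, field) {
    v <- x[[field]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
      stop(sprintf("case file field '%s' is missing or non-numeric", field),
           call. = FALSE)
    }
    v
  }
  parse_point <- function(x, where) {
    sp <- x[["space"]]
    if (is.null(sp) || !sp %in% SPACES) {
      stop(sprintf("%s: invalid or missing space tag '%s'", where,
                   if (is.null(sp)) "" else sp), call. = FALSE)
    }
    point3(get_num(x, "ap"), get_num(x, "lat"), get_num(x, "vert"), sp)
  }
  landmarks <- obj$landmarks %||% list()
  landmarks <- stats::setNames(
    lapply(names(landmarks), function(nm)
      parse_point(landmarks[[nm]], paste0("landmarks.", nm))),
    names(landmarks))
  trajectories <- obj$trajectories %||% list()
  trajectories <- stats::setNames(
    lapply(names(trajectories), function(nm) {
      tr <- trajectories[[nm]]
      sp <- tr[["space"]] %||% "anatomical"
      trajectory(
        parse_point(c(tr$entry, space = sp),
                    paste0("trajectories.", nm, ".entry")),
        parse_point(c(tr$target, space = sp),
                    paste0("trajectories.", nm, ".target")))
    }),
    names(trajectories))
  case_file(landmarks = landmarks,
            dials = lapply(obj$dials %||% list(), function(d)
              lapply(d, as.numeric)),
            trajectories = trajectories,
            frame_model = obj$frame_model %||% "CRW",
            notes = as.character(obj$notes %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read landmarks from a CSV table
#'
#' Expects the header `name,space,ap,lat,vert`.
#'
#' @param path CSV path.
#' @return Named list of [point3] objects.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "space", "ap", "lat", "vert")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("landmark CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(
    lapply(seq_len(nrow(df)), function(i)
      point3(df$ap[i], df$lat[i], df$vert[i], df$space[i])),
    df$name)
}

#' The bundled deep-brain-stimulation worked case
#'
#' A complete bilateral subthalamic-nucleus plan exported from a planning
#' station: AC, PC and mid-falx localized in CRW frame space and in
#' mid-commissural space, both planned targets, and the per-side ring/arc
#' dials. This is the case every worked example in the documentation (and
#' the acceptance suite) runs on.
#'
#' @return A [case_file].
#' @export
example_dbs_case <- function() {
  case_file(
    landmarks = list(
      ac_frame = point3(14.2, 2.9, 2.4, "frame"),
      pc_frame = point3(-10.1, 2.1, 5.0, "frame"),
      falx_frame = point3(9.3, 5.9, 54.2, "frame"),
      right_target_frame = point3(-1.8, 13.6, 0.3, "frame"),
      left_target_frame = point3(-0.8, -9.3, 1.7, "frame"),
      ac_anatomical = point3(12.23, 0, 0, "anatomical"),
      pc_anatomical = point3(-12.23, 0, 0, "anatomical"),
      falx_anatomical = point3(1.98, 0, 51.09, "anatomical"),
      right_target_anatomical = point3(-3, 11.5, -3, "anatomical"),
      left_target_anatomical = point3(-3, -11.5, -3, "anatomical")
    ),
    dials = list(right = list(ring = 51.8, arc = 20.5, gamma = 0),
                 left = list(ring = 51.6, arc = 10.1, gamma = 0)),
    frame_model = "CRW",
    notes = "Bilateral STN DBS plan; planning-station export, CRW frame.")
}

#' Generate a synthetic case with known ground truth
#'
#' Draws a random rigid frame pose (rotation within `max_tilt_deg` of
#' aligned, mid-commissural origin uniform in a frame-typical range),
#' pushes canonical anatomical landmarks through it, and perturbs the
#' frame-space landmarks with isotropic Gaussian noise of standard
#' deviation `noise_sd` — emulating the millimetre-scale localization
#' uncertainty of commissure picking on imaging. At `noise_sd = 0` the
#' three-point registration recovers the ground truth exactly.
#'
#' @param seed Integer seed; same seed, same case, bit for bit.
#' @param noise_sd Landmark noise standard deviation, mm (default 0).
#' @param acpc_mm AC-PC distance of the synthetic anatomy, mm. Default 25
#'   (population average is close to 25 mm with about 1.4 mm SD).
#' @param max_tilt_deg Maximum frame tilt from anatomical alignment.
#' @return A list with `case` (a [case_file]) and `truth` (the
#'   `rigid_transform` that generated it).
#' @export
generate_synthetic_case <- function(seed, noise_sd = 0, acpc_mm = 25,
                                    max_tilt_deg = 15) {
  stopifnot(noise_sd >= 0, acpc_mm > 0)
  set.seed(as.integer(seed))
  ## random small rotation: axis uniform on the sphere, angle uniform
  ax <- stats::rnorm(3); ax <- ax / euclidean_norm(ax)
  ang <- stats::runif(1, 0, max_tilt_deg) * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)  # anatomy -> frame
  origin <- stats::runif(3, -5, 5)        # mid-commissural point, frame space

  anat <- list(ac = c(acpc_mm / 2, 0, 0),
               pc = c(-acpc_mm / 2, 0, 0),
               falx = c(2, 0, 50),
               right_target = c(-3, 11.5, -3),
               left_target = c(-3, -11.5, -3))
  frame_pts <- lapply(anat, function(v) {
    w <- drop(R %*% v) + origin
    if (noise_sd > 0) w <- w + stats::rnorm(3, sd = noise_sd)
    w
  })

  lms <- c(
    stats::setNames(lapply(frame_pts, function(v)
      point3(v[1], v[2], v[3], "frame")),
      paste0(names(anat), "_frame")),
    stats::setNames(lapply(anat, function(v)
      point3(v[1], v[2], v[3], "anatomical")),
      paste0(names(anat), "_anatomical")))

  truth <- structure(
    list(rotation = t(R),                 # stored as frame -> anatomy
         origin = origin, falx_below = FALSE,
         frame_space = "frame", anatomy_space = "anatomical"),
    class = "rigid_transform")

  list(case = case_file(landmarks = lms, frame_model = "CRW",
                        notes = sprintf("synthetic case, seed %d, noise sd %.3g mm",
                                        as.integer(seed), noise_sd)),
       truth = truth)
}
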