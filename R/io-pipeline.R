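#' Write a voxel stack as multi-page TIFF with a metadata sidecar
#'
#' Intensities are stored as 8- or 16-bit grayscale pages (slice order =
#' z); voxel size and bit depth go to a JSON sidecar `<path>.json` so the
#' round trip is lossless.
#'
#' @param stack a [voxel_stack()]; intensities must be integers within the
#'   chosen bit depth.
#' @param path output TIFF path.
#' @param bits 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "voxel_stack"), bits %in% c(8L, 16L))
  arr <- stack$intensities
  maxval <- 2^bits - 1
  if (any(arr != round(arr)) || max(arr) > maxval)
    stop("intensities must be integers in [0, ", maxval, "] for ", bits,
         "-bit storage", call. = FALSE)
  pages <- lapply(seq_len(dim(arr)[1L]), function(s) arr[s, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(list(voxel_size = stack$voxel_size, bits = bits),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF voxel stack
#'
#' @param path TIFF path; the sidecar `<path>.json` written by
#'   [write_stack()] supplies the voxel size unless `voxel_size` is given.
#' @param voxel_size optional `(dz, dy, dx)` in um, overriding the sidecar.
#' @return A [voxel_stack()] with integer intensities.
#' @export
read_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  bits <- NULL
  if (is.null(voxel_size)) {
    if (!file.exists(sidecar))
      stop("missing sidecar ", sidecar, ": supply voxel_size explicitly",
           call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    voxel_size <- meta$voxel_size
    bits <- meta$bits
  } else if (file.exists(sidecar)) {
    bits <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$bits
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e)
                      stop("malformed TIFF '", path, "': ", conditionMessage(e),
                           call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(bits)) bits <- 16L
  maxval <- 2^bits - 1
  arr <- array(0, dim = c(length(pages), dim(pages[[1L]])[1:2]))
  for (s in seq_along(pages)) {
    pg <- pages[[s]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # first channel of RGB pages
    if (!identical(dim(pg), dim(pages[[1L]])[1:2]))
      stop("malformed TIFF: page ", s, " has inconsistent dimensions",
           call. = FALSE)
    arr[s, , ] <- round(pg * maxval)
  }
  voxel_stack(arr, voxel_size)
}

#' Write / read a trajectory as CSV
#'
#' Column headers carry explicit units:
#' `t_s,x_um,v_um_per_s,n_b,F_A_pN,F_pillar_pN,P_W`.
#'
#' @param traj a `trajectory` from [simulate_contraction()].
#' @param path CSV path.
#' @return `path` (write) / a `trajectory` data frame (read), with plain
#'   column names `t, x, v, n_b, F_A, F_pillar, P`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  out <- data.frame(t_s = traj$t, x_um = traj$x, v_um_per_s = traj$v,
                    n_b = traj$n_b, F_A_pN = traj$F_A,
                    F_pillar_pN = traj$F_pillar, P_W = traj$P)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "x_um")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have at least columns t_s,x_um", call. = FALSE)
  out <- data.frame(t = df$t_s, x = df$x_um)
  map <- c(v = "v_um_per_s", n_b = "n_b", F_A = "F_A_pN",
           F_pillar = "F_pillar_pN", P = "P_W")
  for (nm in names(map)) if (map[[nm]] %in% names(df)) out[[nm]] <- df[[map[[nm]]]]
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Write / read deflection profiles as CSV
#'
#' Single-profile files use header `z_um,w_um[,sigma_um]`; multi-pillar
#' files prepend `pillar_id`.
#'
#' @param profiles a [deflection_profile()] or a list of them.
#' @param path CSV path.
#' @return `path` (write) / a list of `deflection_profile`s (read).
#' @export
write_profiles <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    out <- data.frame(pillar_id = i, z_um = p$z, w_um = p$w)
    if (!is.null(p$sigma)) out$sigma_um <- p$sigma
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("z_um", "w_um") %in% names(df)))
    stop("profile CSV must have columns z_um,w_um", call. = FALSE)
  ids <- if ("pillar_id" %in% names(df)) unique(df$pillar_id) else 1L
  lapply(ids, function(id) {
    sub <- if ("pillar_id" %in% names(df)) df[df$pillar_id == id, ] else df
    deflection_profile(sub$z_um, sub$w_um,
                       sigma = if ("sigma_um" %in% names(df)) sub$sigma_um)
  })
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' Accepted top-level blocks: `model`, `geometry`, `render`, `extraction`,
#' `fitting`, `quantification`, plus `seed`, `out_dir` and `log_level`.
#' Unknown keys are rejected so typos fail loudly before any stage runs.
#'
#' @param path YAML or JSON file.
#' @return A named list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)  # YAML is a superset of JSON
  allowed <- c("model", "geometry", "render", "extraction", "fitting",
               "quantification", "seed", "out_dir", "log_level")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the pillar-ring pipeline end to end
#'
#' Renders a synthetic pillar ring (or ingests stacks from `config$render$
#' before`/`after` paths), segments both states, extracts centrelines,
#' assembles deflection profiles and fits one active force per pillar;
#' optionally calibrates the contractility model to a supplied trajectory.
#' All intermediate artefacts are written under `out_dir` and listed in the
#' returned report, which is also serialised as `report.json`. Given an
#' identical configuration the run is deterministic.
#'
#' @param config a `pipeline_config` (from [read_config()]) or an
#'   equivalent named list.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return The report: list with per-stage parameters, seeds, file paths
#'   and the per-pillar fitted forces.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  gcfg <- config$geometry
  geom <- do.call(pillar_geometry, if (is.null(gcfg)) {
    list(L = 15, d = 2, E = 57)
  } else gcfg)

  stage <- "render"
  report <- list(seed = seed, stages = list())
  res <- tryCatch({
    rcfg <- if (is.null(config$render)) list() else config$render
    if (!is.null(rcfg$before) && !is.null(rcfg$after)) {
      before <- read_stack(rcfg$before)
      after <- read_stack(rcfg$after)
      truth <- NULL
      ring_centre <- unlist(rcfg$ring_centre)
      if (is.null(ring_centre))
        stop("ingested stacks require render$ring_centre", call. = FALSE)
    } else {
      rcfg$geom <- geom
      rcfg$before <- NULL; rcfg$after <- NULL; rcfg$ring_centre <- NULL
      if (is.null(rcfg$seed)) rcfg$seed <- seed
      spec <- do.call(render_spec, rcfg)
      rend <- render_pillar_ring(spec)
      before <- rend$before; after <- rend$after; truth <- rend$truth
      ring_centre <- truth$ring_centre
      write_stack(before, file.path(out_dir, "before.tif"))
      write_stack(after, file.path(out_dir, "after.tif"))
    }
    report$stages$render <- list(seed = seed,
                                 files = c(file.path(out_dir, "before.tif"),
                                           file.path(out_dir, "after.tif")))

    stage <- "extract"
    ecfg <- if (is.null(config$extraction)) list() else config$extraction
    exp_n <- ecfg$n_pillars
    if (!is.null(exp_n) && !is.null(truth) && exp_n != length(truth$forces))
      stop("config mismatch: extraction expects ", exp_n,
           " pillars but render produced ", length(truth$forces),
           call. = FALSE)
    seg_args <- ecfg[intersect(names(ecfg),
                               c("threshold_method", "threshold_value",
                                 "min_area_voxels", "watershed_tolerance"))]
    seg_b <- do.call(segment_stack, c(list(before), seg_args))
    seg_a <- do.call(segment_stack, c(list(after), seg_args))
    cl_b <- extract_centerlines(seg_b, before)
    cl_a <- extract_centerlines(seg_a, after)
    profiles <- profiles_from_centerlines(cl_b, cl_a, ring_centre)
    write_profiles(profiles, file.path(out_dir, "profiles.csv"))
    report$stages$extract <- list(n_pillars = length(profiles),
                                  files = file.path(out_dir, "profiles.csv"))

    stage <- "beamfit"
    fits <- lapply(profiles, fit_force, geom = geom)
    forces <- vapply(fits, `[[`, numeric(1), "F_hat")
    report$stages$beamfit <- list(
      k_p = pillar_stiffness(geom),
      forces_pN = forces,
      residual_rms_um = vapply(fits, `[[`, numeric(1), "residual_rms"))
    if (!is.null(truth)) report$stages$beamfit$true_forces_pN <- truth$forces

    if (!is.null(config$fitting) && !is.null(config$fitting$observed)) {
      stage <- "modelfit"
      obs <- read_trajectory(config$fitting$observed)
      fs_args <- config$fitting[intersect(names(config$fitting),
                                          c("free", "n_starts"))]
      fs_args$seed <- seed
      mspec <- do.call(fit_spec, fs_args)
      mfit <- fit_model_to_trajectory(obs, mspec, k_p = pillar_stiffness(geom))
      report$stages$modelfit <- list(estimates = as.list(mfit$estimates),
                                     loss = mfit$loss,
                                     convergence = mfit$convergence)
    }
    report
  }, error = function(e) {
    jsonlite::write_json(list(failed_stage = stage,
                              error = conditionMessage(e),
                              stages = report$stages),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res
}
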