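#' 3D fluorescence voxel stack
#'
#' @param intensities non-negative 3D array indexed `(z, y, x)` (slice,
#'   row, column).
#' @param voxel_size `(dz, dy, dx)` in um. The centre of voxel index
#'   `(1, 1, 1)` sits at physical position `(0, 0, 0)`.
#' @return A `voxel_stack`.
#' @export
voxel_stack <- function(intensities, voxel_size) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(intensities) < 1L)) stop("all dims must be >= 1", call. = FALSE)
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (dz, dy, dx)",
         call. = FALSE)
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("voxel_stack: %d slices x %d x %d voxels, voxel %.3g x %.3g x %.3g um\n",
              d[1L], d[2L], d[3L],
              x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L]))
  invisible(x)
}

# Greedy nearest match of new centroids to existing tracks; ties by smaller
# label id (rows are ordered by label).
.link_to_tracks <- function(track_pos, new_pos) {
  n_new <- nrow(new_pos)
  assign <- rep(NA_integer_, n_new)
  if (nrow(track_pos) > 0L && n_new > 0L) {
    d <- outer(seq_len(nrow(track_pos)), seq_len(n_new),
               Vectorize(function(i, j)
                 sqrt(sum((track_pos[i, ] - new_pos[j, ])^2))))
    used_t <- logical(nrow(track_pos)); used_n <- logical(n_new)
    for (k in seq_len(min(nrow(track_pos), n_new))) {
      d_mask <- d
      d_mask[used_t, ] <- Inf; d_mask[, used_n] <- Inf
      ij <- which(d_mask == min(d_mask), arr.ind = TRUE)[1L, ]
      assign[ij[2L]] <- ij[1L]
      used_t[ij[1L]] <- TRUE; used_n[ij[2L]] <- TRUE
    }
  }
  assign
}

#' Segment a pillar-ring z-stack
#'
#' Slice-wise segmentation mirroring the standard pillar-tracking protocol:
#' each slice is binarized (Otsu threshold by default), adjacent pillars
#' are separated by a watershed transform of the Euclidean distance map,
#' small components are discarded, and components are linked across slices
#' into consistent pillar labels by nearest-centroid matching.
#'
#' @param stack a [voxel_stack()].
#' @param threshold_method `"otsu"` (per-slice, default), `"fixed"` or
#'   `"percentile"`.
#' @param threshold_value intensity for `"fixed"`, probability in (0,1) for
#'   `"percentile"`.
#' @param min_area_voxels discard in-slice components smaller than this
#'   (default 20).
#' @param watershed_tolerance minimum object-height separation in the
#'   distance map (pixels) for the watershed split (default 1).
#' @return list of class `segmented_stack`: `labels` (integer array, same
#'   dim as the stack; 0 = background, k = pillar k), `n_objects`, and
#'   `centroids` (per slice, binary centroids used for linking).
#' @export
segment_stack <- function(stack, threshold_method = c("otsu", "fixed", "percentile"),
                          threshold_value = NULL, min_area_voxels = 20,
                          watershed_tolerance = 1) {
  stopifnot(inherits(stack, "voxel_stack"))
  threshold_method <- match.arg(threshold_method)
  arr <- stack$intensities
  nz <- dim(arr)[1L]
  vmax <- max(arr)
  if (vmax <= 0) stop("no objects found: stack is all zero", call. = FALSE)

  labels <- array(0L, dim = dim(arr))
  track_pos <- matrix(numeric(0), ncol = 2L)  # (y, x) voxel centroids
  n_tracks <- 0L
  centroids <- vector("list", nz)

  for (s in seq_len(nz)) {
    sl <- arr[s, , ]
    th <- switch(threshold_method,
      otsu = {
        img <- EBImage::Image(t(sl) / vmax)  # EBImage is (x, y)
        EBImage::otsu(img, range = c(0, 1)) * vmax
      },
      fixed = {
        if (is.null(threshold_value)) stop("threshold_value required", call. = FALSE)
        threshold_value
      },
      percentile = {
        if (is.null(threshold_value)) stop("threshold_value required", call. = FALSE)
        stats::quantile(sl, probs = threshold_value, names = FALSE)
      })
    bin <- EBImage::Image(t(sl > th) * 1)  # (x, y) orientation
    if (sum(bin) == 0) { centroids[[s]] <- NULL; next }
    dmap <- EBImage::distmap(bin)
    ws <- EBImage::watershed(dmap, tolerance = watershed_tolerance, ext = 1)
    lab <- t(EBImage::imageData(ws))  # back to (y, x)
    sizes <- table(lab[lab > 0])
    keep_ids <- as.integer(names(sizes)[sizes >= min_area_voxels])
    if (length(keep_ids) == 0L) { centroids[[s]] <- NULL; next }

    cen <- t(vapply(keep_ids, function(id) {
      idx <- which(lab == id, arr.ind = TRUE)
      c(mean(idx[, 1L]), mean(idx[, 2L]))  # (row = y, col = x)
    }, numeric(2)))

    assign <- .link_to_tracks(track_pos, cen)
    slice_lab <- array(0L, dim = dim(lab))
    for (j in seq_along(keep_ids)) {
      tid <- assign[j]
      if (is.na(tid)) {
        n_tracks <- n_tracks + 1L
        tid <- n_tracks
        track_pos <- rbind(track_pos, cen[j, , drop = FALSE])
      } else {
        track_pos[tid, ] <- cen[j, ]
      }
      slice_lab[lab == keep_ids[j]] <- tid
    }
    labels[s, , ] <- slice_lab
    centroids[[s]] <- cen
  }
  if (n_tracks == 0L)
    stop("no objects found in any slice after thresholding", call. = FALSE)
  structure(list(labels = labels, n_objects = n_tracks,
                 voxel_size = stack$voxel_size, centroids = centroids),
            class = "segmented_stack")
}

#' Extract per-pillar centrelines from a segmented stack
#'
#' For every slice and pillar label, computes the intensity-weighted
#' centroid ("centre of mass") of the labelled cross-section in physical
#' micrometre coordinates. Slices where a pillar is absent are simply
#' missing from its centreline.
#'
#' @param seg a [segment_stack()] result.
#' @param stack the [voxel_stack()] the segmentation came from (supplies
#'   the intensity weights).
#' @return list of `centerline` data frames (`pillar_id`, `z`, `cx`, `cy`
#'   in um), one per pillar, ordered by pillar id.
#' @export
extract_centerlines <- function(seg, stack) {
  stopifnot(inherits(seg, "segmented_stack"), inherits(stack, "voxel_stack"))
  arr <- stack$intensities
  stopifnot(identical(dim(arr), dim(seg$labels)))
  dz <- stack$voxel_size[1L]; dyv <- stack$voxel_size[2L]; dxv <- stack$voxel_size[3L]
  nz <- dim(arr)[1L]

  out <- lapply(seq_len(seg$n_objects), function(id) {
    rows <- lapply(seq_len(nz), function(s) {
      mask <- seg$labels[s, , ] == id
      if (!any(mask)) return(NULL)
      wts <- arr[s, , ][mask]
      idx <- which(mask, arr.ind = TRUE)
      if (sum(wts) <= 0) wts <- rep(1, length(wts))
      cy <- sum(idx[, 1L] * wts) / sum(wts)
      cx <- sum(idx[, 2L] * wts) / sum(wts)
      data.frame(pillar_id = id, z = (s - 1L) * dz,
                 cx = (cx - 1) * dxv, cy = (cy - 1) * dyv)
    })
    cl <- do.call(rbind, rows)
    class(cl) <- c("centerline", "data.frame")
    cl
  })
  out
}

#' Deflection profiles from before/after centrelines
#'
#' Matches pillars across the two states by nearest base centroid, then,
#' slice by slice, projects the centroid displacement onto the unit vector
#' pointing from the pillar base toward the ring centre. Positive
#' deflection means motion toward the centre.
#'
#' @param before,after lists of centrelines from [extract_centerlines()].
#' @param ring_centre `(cx, cy)` of the ring centre (um).
#' @return list of [deflection_profile()]s, ordered as `before`.
#' @export
profiles_from_centerlines <- function(before, after, ring_centre) {
  if (length(before) != length(after))
    stop("unmatched pillar counts: ", length(before), " before vs ",
         length(after), " after", call. = FALSE)
  stopifnot(length(ring_centre) == 2L)

  base_of <- function(cl) unlist(cl[1L, c("cx", "cy")])
  bases_b <- t(vapply(before, base_of, numeric(2)))
  bases_a <- t(vapply(after, base_of, numeric(2)))
  assign <- .link_to_tracks(bases_b, bases_a)  # after j -> before i
  if (any(is.na(assign)))
    stop("pillar matching failed: orphan after-pillars ",
         paste(which(is.na(assign)), collapse = ", "), call. = FALSE)

  lapply(seq_along(before), function(i) {
    j <- which(assign == i)
    b <- before[[i]]; a <- after[[j]]
    zs <- intersect(b$z, a$z)
    b <- b[match(zs, b$z), ]; a <- a[match(zs, a$z), ]
    ux <- ring_centre[1L] - b$cx[1L]
    uy <- ring_centre[2L] - b$cy[1L]
    nrm <- sqrt(ux^2 + uy^2)
    if (nrm == 0) stop("pillar base coincides with ring centre", call. = FALSE)
    ux <- ux / nrm; uy <- uy / nrm
    w <- (a$cx - b$cx) * ux + (a$cy - b$cy) * uy
    deflection_profile(zs, w)
  })
}
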