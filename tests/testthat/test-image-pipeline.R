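# Small rendered fixtures: coarse lateral voxels keep these tests fast
# while leaving several voxels across each 2-um pillar.

small_spec <- function(...) {
  render_spec(n_pillars = 4, ring_diameter = 16,
              geom = pillar_geometry(L = 10, d = 2, E = 57),
              voxel_size = c(1, 0.2, 0.2), margin = 2.5, ...)
}

test_that("voxel stack validation", {
  expect_error(voxel_stack(matrix(0, 2, 2), c(1, 1, 1)), "3D array")
  expect_error(voxel_stack(array(-1, c(2, 2, 2)), c(1, 1, 1)),
               "non-negative")
  expect_error(voxel_stack(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
})

test_that("a single straight cylinder yields one label per slice and a centred centerline", {
  arr <- array(0, dim = c(8, 51, 51))
  ys <- (0:50) * 0.2; xs <- ys
  dd <- outer((ys - 5)^2, (xs - 5)^2, "+")
  for (s in 1:8) arr[s, , ] <- (dd <= 1) * 200
  st <- voxel_stack(arr, c(1, 0.2, 0.2))
  seg <- segment_stack(st)
  expect_equal(seg$n_objects, 1)
  expect_true(all(apply(seg$labels, 1, function(sl) length(setdiff(unique(c(sl)), 0L))) == 1))
  cl <- extract_centerlines(seg, st)
  expect_length(cl, 1)
  expect_true(all(abs(cl[[1]]$cx - 5) < 0.25 * 0.2))
  expect_true(all(abs(cl[[1]]$cy - 5) < 0.25 * 0.2))
  expect_equal(cl[[1]]$z, 0:7)
})

test_that("an all-zero stack raises a no-object error", {
  st <- voxel_stack(array(0, c(3, 20, 20)), c(1, 0.2, 0.2))
  expect_error(segment_stack(st), "no objects")
})

test_that("watershed separates two touching blurred cylinders", {
  # two cylinders 2.4 um apart: their blurred footprints merge above the
  # threshold without the distance-transform watershed split
  arr <- array(0, dim = c(5, 61, 61))
  ys <- (0:60) * 0.1; xs <- ys
  for (s in 1:5) {
    d1 <- outer((ys - 3)^2, (xs - 1.8)^2, "+")
    d2 <- outer((ys - 3)^2, (xs - 4.2)^2, "+")
    sl <- pmax((d1 <= 1) * 1, (d2 <= 1) * 1)
    sl <- pmax(as.matrix(EBImage::gblur(sl, sigma = 3)), 0)
    arr[s, , ] <- sl * 200
  }
  st <- voxel_stack(arr, c(1, 0.1, 0.1))
  seg <- segment_stack(st, watershed_tolerance = 0.5)
  expect_equal(seg$n_objects, 2)
  counts <- apply(seg$labels, 1, function(sl) length(setdiff(unique(c(sl)), 0L)))
  expect_true(all(counts == 2))
})

test_that("rendered bent pillars give centerlines close to the beam truth", {
  r <- render_pillar_ring(small_spec(forces = 60, seed = 5))
  seg <- segment_stack(r$after)
  expect_equal(seg$n_objects, 4)
  cl <- extract_centerlines(seg, r$after)
  # match each recovered centerline to its ground-truth pillar by base
  rmse <- vapply(cl, function(b) {
    bases <- vapply(r$truth$centerlines_after,
                    function(d) (d$cx[1] - b$cx[1])^2 + (d$cy[1] - b$cy[1])^2,
                    numeric(1))
    tt <- r$truth$centerlines_after[[which.min(bases)]]
    m <- match(b$z, tt$z)
    sqrt(mean((b$cx - tt$cx[m])^2 + (b$cy - tt$cy[m])^2))
  }, numeric(1))
  expect_true(all(rmse < 0.5 * 0.2))
})

test_that("centroids are equivariant under y/x transposition", {
  r <- render_pillar_ring(small_spec(forces = 40, seed = 8))
  st <- r$after
  cl <- extract_centerlines(segment_stack(st), st)
  arr_t <- aperm(st$intensities, c(1, 3, 2))
  st_t <- voxel_stack(arr_t, st$voxel_size[c(1, 3, 2)])
  cl_t <- extract_centerlines(segment_stack(st_t), st_t)
  expect_length(cl_t, length(cl))
  # discovery order may differ; match pillars by their (swapped) bases
  for (i in seq_along(cl)) {
    d <- vapply(cl_t, function(b)
      (b$cx[1] - cl[[i]]$cy[1])^2 + (b$cy[1] - cl[[i]]$cx[1])^2, numeric(1))
    j <- which.min(d)
    expect_equal(cl_t[[j]]$cx, cl[[i]]$cy, tolerance = 1e-10)
    expect_equal(cl_t[[j]]$cy, cl[[i]]$cx, tolerance = 1e-10)
  }
})

test_that("profile projection isolates the radial displacement component", {
  z <- 0:5
  centre <- c(10, 10)
  before <- list(structure(data.frame(pillar_id = 1, z = z, cx = 4, cy = 10),
                           class = c("centerline", "data.frame")))
  shift <- function(dx, dy) list(structure(
    data.frame(pillar_id = 1, z = z, cx = 4 + dx, cy = 10 + dy),
    class = c("centerline", "data.frame")))
  # identical states -> zero deflection
  expect_true(all(profiles_from_centerlines(before, before, centre)[[1]]$w == 0))
  # 1 um directly toward the centre -> w = 1 at every slice
  expect_equal(profiles_from_centerlines(before, shift(1, 0), centre)[[1]]$w,
               rep(1, 6))
  # 1 um perpendicular -> w = 0
  expect_equal(profiles_from_centerlines(before, shift(0, 1), centre)[[1]]$w,
               rep(0, 6), tolerance = 1e-12)
  expect_error(profiles_from_centerlines(before, list(), centre),
               "unmatched pillar counts")
})

test_that("centroid error grows with noise amplitude", {
  errs <- vapply(c(5, 40, 160), function(read_sigma) {
    r <- render_pillar_ring(small_spec(forces = 0, noise_model = "gaussian",
                                       read_sigma = read_sigma, seed = 31))
    cl <- extract_centerlines(segment_stack(r$after), r$after)
    mean(vapply(cl, function(b) {
      bases <- vapply(r$truth$centerlines_after,
                      function(d) (d$cx[1] - b$cx[1])^2 + (d$cy[1] - b$cy[1])^2,
                      numeric(1))
      tt <- r$truth$centerlines_after[[which.min(bases)]]
      m <- match(b$z, tt$z)
      sqrt(mean((b$cx - tt$cx[m])^2 + (b$cy - tt$cy[m])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})
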