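test_that("NIfTI volumes round-trip with geometry intact", {
  arr <- array(rnorm(6 * 5 * 4), dim = c(6, 5, 4))
  vol <- brain_volume(arr, voxel_size = c(2, 2, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$values, arr, tolerance = 1e-6)
  expect_equal(back$voxel_size, c(2, 2, 2))
})

test_that("malformed and non-3D files are rejected with clear errors", {
  bad <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti file", bad)
  expect_error(suppressWarnings(read_volume(bad)), "format error")
  arr4 <- array(0, dim = c(3, 3, 3, 2))
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), p4)
  expect_error(read_volume(p4), "4D")
  expect_error(brain_volume(array(0, dim = c(2, 2))), "3D")
})

test_that("gaussian smoothing honors identity, conservation, kernel shape", {
  arr <- array(rnorm(10^3), dim = c(10, 10, 10))
  vol <- brain_volume(arr, voxel_size = c(2, 2, 2))
  expect_equal(smooth_volume(vol, 0)$values, arr)

  const <- brain_volume(array(5, dim = c(8, 8, 8)), voxel_size = c(2, 2, 2))
  sm <- smooth_volume(const, 8)
  expect_equal(sm$values, const$values, tolerance = 1e-12)

  # unit impulse, fwhm 8 mm on 2 mm voxels: neighbour/center ratio is the
  # gaussian kernel ratio exp(-d^2 / (2 sigma^2)), sigma = 8/2.3548.. mm
  imp <- array(0, dim = c(25, 25, 25))
  imp[13, 13, 13] <- 1
  sm <- smooth_volume(brain_volume(imp, voxel_size = c(2, 2, 2)), 8)
  sigma <- 8 / (2 * sqrt(2 * log(2)))
  expect_equal(sm$values[14, 13, 13] / sm$values[13, 13, 13],
               exp(-2^2 / (2 * sigma^2)), tolerance = 1e-10)
  expect_error(smooth_volume(vol, -1), "nonnegative")
})

test_that("voxel extraction excludes background zeros and counts match", {
  cfg <- small_config(seed = 4)
  atlas <- generate_atlas(cfg)
  vals <- array(rnorm(prod(cfg$grid_shape)), dim = cfg$grid_shape)
  # zero out some cortex voxels explicitly
  ids <- atlas$regions$region_id[atlas$regions$compartment == "cortex"]
  cortex_vox <- which(array(atlas$labels %in% ids, dim = cfg$grid_shape))
  zeroed <- cortex_vox[seq(1, length(cortex_vox), by = 7)]
  vals[zeroed] <- 0
  vol <- brain_volume(vals, voxel_size = atlas$voxel_size)
  prof <- extract_voxel_profile(vol, atlas, "cortex")
  # brute-force oracle count
  expect_equal(nrow(prof), sum(atlas$labels %in% ids & vals != 0))
  expect_false(any(prof$value == 0))

  vals[cortex_vox] <- 0
  expect_error(extract_voxel_profile(brain_volume(vals, atlas$voxel_size),
                                     atlas, "cortex"), "empty profile")
})

test_that("region extraction means nonzero voxels only", {
  cfg <- small_config(seed = 5)
  atlas <- generate_atlas(cfg)
  vals <- array(0, dim = cfg$grid_shape)
  ids <- atlas$regions$region_id
  # paint region 1 constant 4 but zero half its voxels
  r1 <- which(atlas$labels == ids[1])
  vals[r1] <- 4
  vals[r1[seq_len(length(r1) %/% 2)]] <- 0
  for (id in ids[-1]) vals[atlas$labels == id] <- rnorm(sum(atlas$labels == id))
  vol <- brain_volume(vals, voxel_size = atlas$voxel_size)
  prof <- suppressWarnings(extract_region_profile(vol, atlas, "cortex"))
  expect_equal(prof$value[prof$unit_id == as.character(ids[1])], 4)

  # independent scan oracle over all surviving cortex regions
  for (id in prof$unit_id) {
    v <- vals[atlas$labels == as.integer(id)]
    expect_equal(prof$value[prof$unit_id == id], mean(v[v != 0]))
  }
  # smoothing with fwhm 0 leaves region profiles unchanged
  prof0 <- suppressWarnings(
    extract_region_profile(smooth_volume(vol, 0), atlas, "cortex"))
  expect_identical(prof0$value, prof$value)
})

test_that("painted volumes recover region means and geometry mismatch errors", {
  cfg <- small_config(seed = 6)
  atlas <- generate_atlas(cfg)
  vals <- setNames(rnorm(nrow(atlas$regions)) + 5,
                   as.character(atlas$regions$region_id))
  vol <- paint_volume(atlas, vals, jitter_sd = 0.1, seed = 2)
  prof <- extract_region_profile(vol, atlas, "subcortex")
  expect_equal(prof$value,
               unname(vals[prof$unit_id]), tolerance = 1e-10)
  bad <- brain_volume(array(1, dim = c(5, 5, 5)))
  expect_error(extract_region_profile(bad, atlas, "cortex"),
               "geometry mismatch")
})
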