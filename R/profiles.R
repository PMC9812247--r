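#' Construct a spatial profile
#'
#' One value per spatial unit (voxel or region) of a single map, with unit
#' coordinates in mm. The profile is the package's per-compartment analysis
#' vector: background units are excluded before construction.
#'
#' @param unit_ids unique unit identifiers (voxel linear index or region id).
#' @param values numeric values, one per unit.
#' @param coordinates numeric matrix (n x 3) of mm coordinates.
#' @param compartment per-unit compartment label or a scalar.
#' @param granularity `"voxel"` or `"region"`.
#' @return data frame of class `spatial_profile` with columns `unit_id`,
#'   `compartment`, `x`, `y`, `z`, `value`.
#' @export
spatial_profile <- function(unit_ids, values, coordinates,
                            compartment = "cortex",
                            granularity = c("region", "voxel")) {
  granularity <- match.arg(granularity)
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids)) stop_imtx("unit ids must be unique")
  if (length(values) != length(unit_ids))
    stop_imtx("values and unit_ids lengths differ")
  coordinates <- as.matrix(coordinates)
  structure(data.frame(unit_id = unit_ids,
                       compartment = rep_len(compartment, length(unit_ids)),
                       x = coordinates[, 1], y = coordinates[, 2],
                       z = coordinates[, 3],
                       value = as.numeric(values),
                       stringsAsFactors = FALSE),
            granularity = granularity,
            class = c("spatial_profile", "data.frame"))
}

#' Subset a spatial profile to one compartment
#'
#' @param profile a [spatial_profile()].
#' @param compartment `"cortex"` or `"subcortex"`.
#' @return a [spatial_profile()] restricted to the compartment.
#' @export
subset_compartment <- function(profile, compartment) {
  stopifnot(inherits(profile, "spatial_profile"))
  out <- profile[profile$compartment == compartment, , drop = FALSE]
  if (nrow(out) == 0)
    stop_imtx("no units in compartment '%s'", compartment)
  attr(out, "granularity") <- attr(profile, "granularity")
  class(out) <- c("spatial_profile", "data.frame")
  rownames(out) <- NULL
  out
}

#' Pairwise Euclidean distances between profile units (mm)
#'
#' @param profile a [spatial_profile()].
#' @return symmetric distance matrix.
#' @export
profile_distances <- function(profile) {
  stopifnot(inherits(profile, "spatial_profile"))
  as.matrix(dist(as.matrix(profile[, c("x", "y", "z")])))
}

# map a volume onto the atlas grid; only identity or integer-scale
# compatible shapes are accepted (silent resampling hides alignment bugs)
align_to_atlas <- function(vol, atlas) {
  dv <- dim(vol$values)
  da <- dim(atlas$labels)
  if (all(dv == da)) return(vol$values)
  ratio <- dv / da
  if (all(ratio == round(ratio)) && all(ratio >= 1)) {
    r <- as.integer(ratio)
    idx <- lapply(1:3, function(a) ((seq_len(da[a]) - 1L) * r[a]) + (r[a] + 1L) %/% 2L)
    return(vol$values[idx[[1]], idx[[2]], idx[[3]]])
  }
  stop_imtx("geometry mismatch: volume %s vs atlas %s",
            paste(dv, collapse = "x"), paste(da, collapse = "x"))
}

#' Extract a voxel-wise profile for one compartment
#'
#' One entry per voxel whose atlas label belongs to the compartment and whose
#' value is nonzero (zero is the background sentinel and is excluded).
#' Ordering is the deterministic lexicographic voxel index, so profiles are
#' stable across runs.
#'
#' @param vol a [brain_volume()].
#' @param atlas a `brain_atlas`.
#' @param compartment `"cortex"` or `"subcortex"`.
#' @return a [spatial_profile()] with voxel granularity.
#' @export
extract_voxel_profile <- function(vol, atlas, compartment) {
  stopifnot(inherits(vol, "brain_volume"), inherits(atlas, "brain_atlas"))
  vals3d <- align_to_atlas(vol, atlas)
  ids <- atlas$regions$region_id[atlas$regions$compartment == compartment]
  if (length(ids) == 0) stop_imtx("no regions in compartment '%s'", compartment)
  sel <- which(atlas$labels %in% ids & vals3d != 0)
  if (length(sel) == 0)
    stop_imtx("empty profile: all '%s' voxels are zero-valued", compartment)
  g <- dim(atlas$labels)
  mm <- (arrayInd(sel, g) - 0.5) * rep(atlas$voxel_size, each = length(sel))
  spatial_profile(unit_ids = sel, values = vals3d[sel], coordinates = mm,
                  compartment = compartment, granularity = "voxel")
}

#' Extract a region-wise profile for one compartment
#'
#' One entry per region; the value is the arithmetic mean over the region's
#' voxels after excluding zero-valued (background) voxels. Regions whose
#' voxels are all zero are dropped with a warning. Coordinates are the
#' region centroids from the atlas table.
#'
#' @inheritParams extract_voxel_profile
#' @return a [spatial_profile()] with region granularity.
#' @export
extract_region_profile <- function(vol, atlas, compartment) {
  stopifnot(inherits(vol, "brain_volume"), inherits(atlas, "brain_atlas"))
  vals3d <- align_to_atlas(vol, atlas)
  reg <- atlas$regions[atlas$regions$compartment == compartment, ,
                       drop = FALSE]
  if (nrow(reg) == 0) stop_imtx("no regions in compartment '%s'", compartment)
  means <- vapply(reg$region_id, function(id) {
    v <- vals3d[atlas$labels == id]
    v <- v[v != 0]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  dropped <- is.na(means)
  if (all(dropped))
    stop_imtx("empty profile: every '%s' region is all-background", compartment)
  if (any(dropped))
    warning(sprintf("dropped %d region(s) with no surviving voxels",
                    sum(dropped)), call. = FALSE)
  reg <- reg[!dropped, , drop = FALSE]
  spatial_profile(unit_ids = reg$region_id, values = means[!dropped],
                  coordinates = as.matrix(reg[, c("x", "y", "z")]),
                  compartment = compartment, granularity = "region")
}

#' Write a spatial profile as TSV
#'
#' Columns: unit_id, compartment, x, y, z, value.
#'
#' @param profile a [spatial_profile()].
#' @param path output path.
#' @param header optional comment line (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
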