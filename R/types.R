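# S3 containers carried through the pipeline.
#
# All volumes share the convention: world = affine %*% c(i, j, k, 1) with
# 0-based voxel indices and millimetre RAS world coordinates (+x right,
# +y anterior, +z superior).

#' Labeled head volume
#'
#' Voxel grid of tissue labels (0 = air, 1 = skin, 2 = fat, 3 = skull,
#' 4 = CSF, 5 = gray matter, 6 = white matter, 7 = electrode gel) with a
#' voxel-to-world affine in mm.
#'
#' @param labels 3D integer array.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(labels, affine) {
  stopifnot(length(dim(labels)) == 3L, all(dim(affine) == c(4, 4)))
  storage.mode(labels) <- "integer"
  if (abs(det(affine)) < 1e-12) stop_repe("affine is singular", "repe_parameter_error")
  structure(list(labels = labels, affine = affine,
                 voxel_size = abs(diag(affine)[1:3])),
            class = "labeled_volume")
}

#' Intensity volume
#'
#' @param values 3D numeric array (arbitrary units).
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return An `intensity_volume` object.
#' @export
intensity_volume <- function(values, affine) {
  stopifnot(length(dim(values)) == 3L)
  if (!all(is.finite(values))) stop_repe("non-finite intensities", "repe_input_error")
  structure(list(values = values, affine = affine,
                 voxel_size = abs(diag(affine)[1:3])),
            class = "intensity_volume")
}

#' Ordered sulcus trace
#'
#' An ordered 3D polyline (mm) with a tag recording which space it lives in:
#' `template` (MNI-like), `individual`, `scalp` (projected onto the scalp
#' surface) or `plane` (flattened; third coordinate is 0).
#'
#' @param points n x 3 matrix of points (mm).
#' @param space one of `"template"`, `"individual"`, `"scalp"`, `"plane"`.
#' @return A `sulcus_trace` object.
#' @export
sulcus_trace <- function(points, space = c("template", "individual", "scalp", "plane")) {
  space <- match.arg(space)
  points <- as_points(points)
  if (nrow(points) < 2L) stop_repe("trace needs >= 2 points", "repe_input_error")
  seg <- rownorms(diff(points))
  if (any(seg == 0)) stop_repe("consecutive duplicate points in trace", "repe_input_error")
  if (space == "plane" && any(points[, 3] != 0))
    stop_repe("plane trace must have zero third coordinate", "repe_input_error")
  structure(list(points = points, space = space), class = "sulcus_trace")
}

#' @export
print.sulcus_trace <- function(x, ...) {
  cat(sprintf("<sulcus_trace> %d points in %s space, length %.1f mm\n",
              nrow(x$points), x$space, trace_length(x)))
  invisible(x)
}

#' Total polyline length of a trace (mm)
#' @param trace a `sulcus_trace`.
#' @export
trace_length <- function(trace) sum(rownorms(diff(trace$points)))

#' Fiducial landmark set (nasion, inion)
#' @param nasion,inion 3-vectors (mm), on the scalp surface.
#' @export
fiducial_set <- function(nasion, inion) {
  structure(list(nasion = as.numeric(nasion), inion = as.numeric(inion)),
            class = "fiducial_set")
}

#' Binary mask on a volume grid
#' @param mask 3D logical array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param role `"iBrain"` or `"iScalp"` (or other free tag).
#' @export
binary_mask <- function(mask, affine, role = "mask") {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop_repe("empty mask", "repe_segmentation_error")
  structure(list(mask = mask, affine = affine, role = role), class = "binary_mask")
}

#' Affine transform between world spaces (mm -> mm)
#' @param matrix 4x4 invertible matrix; by convention maps individual -> template.
#' @export
affine_transform <- function(matrix) {
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix)) < 1e-12 || !all(is.finite(matrix)))
    stop_repe("transform matrix is singular", "repe_transform_error")
  structure(list(matrix = matrix), class = "affine_transform")
}

tissue_names <- c("air", "skin", "fat", "skull", "csf", "gray", "white", "gel")
tissue_label <- function(name) match(name, tissue_names) - 1L
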