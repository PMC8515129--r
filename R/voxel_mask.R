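#' Labeled voxel mask
#'
#' Container for a 3D labeled segmentation volume with physical voxel
#' spacing.  Labels follow the convention 0 = background, 1 = tumor,
#' 2 = left internal carotid artery, 3 = right internal carotid artery
#' (configurable through `label_map`).
#'
#' @param labels 3D integer array of voxel labels.
#' @param spacing numeric length-3, mm per voxel along each array axis;
#'   all components must be positive.
#' @param axial_axis index (1, 2 or 3) of the array axis perpendicular to
#'   horizontal (axial) slices.  Voxel coordinates increase with index, so
#'   higher slice indices are more cranial.
#' @param origin numeric length-3, mm world coordinate of the center of
#'   voxel (1,1,1).
#' @param label_map named integer vector mapping role names
#'   (`tumor`, `left_carotid`, `right_carotid`) to label values.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(labels, spacing = c(1, 1, 1), axial_axis = 3,
                       origin = c(0, 0, 0),
                       label_map = c(tumor = 1L, left_carotid = 2L,
                                     right_carotid = 3L)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers (mm)")
  if (!axial_axis %in% 1:3)
    stop("axial_axis must be 1, 2 or 3")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  allowed <- c(0L, as.integer(label_map))
  if (!all(unique(as.vector(labels)) %in% allowed))
    stop("labels contain values outside the declared label set (",
         paste(allowed, collapse = ", "), ")")
  structure(list(labels = labels, spacing = spacing,
                 axial_axis = as.integer(axial_axis), origin = origin,
                 label_map = label_map),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat("voxel_mask: ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, axial axis ", x$axial_axis, "\n", sep = "")
  counts <- table(factor(x$labels[x$labels != 0L],
                         levels = as.integer(x$label_map)))
  names(counts) <- names(x$label_map)
  for (nm in names(counts))
    cat("  ", nm, ": ", counts[[nm]], " voxels\n", sep = "")
  invisible(x)
}

label_value <- function(mask, role) {
  if (is.character(role)) {
    if (!role %in% names(mask$label_map))
      stop("unknown label role: ", role)
    as.integer(mask$label_map[[role]])
  } else as.integer(role)
}

#' Labeled-region volume by voxel counting
#'
#' Volume of all voxels carrying a given label: voxel count times the
#' product of the spacing components.  An empty label yields 0.
#'
#' @param mask a [voxel_mask].
#' @param label label value or role name (`"tumor"`, `"left_carotid"`,
#'   `"right_carotid"`).
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask, label = "tumor") {
  stopifnot(inherits(mask, "voxel_mask"))
  lab <- label_value(mask, label)
  sum(mask$labels == lab) * prod(mask$spacing)
}

# mm coordinates of slice centers along the axial axis
axial_coordinates <- function(mask) {
  ax <- mask$axial_axis
  n <- dim(mask$labels)[ax]
  mask$origin[ax] + (seq_len(n) - 1) * mask$spacing[ax]
}

# 2D label matrix for axial slice k (1-based index along axial_axis)
axial_slice <- function(mask, k) {
  switch(mask$axial_axis,
         mask$labels[k, , ],
         mask$labels[, k, ],
         mask$labels[, , k])
}

# in-plane mm coordinates (n x 2 matrix) of voxels with `label` on slice k
slice_coords <- function(mask, k, label) {
  lab <- label_value(mask, label)
  sl <- axial_slice(mask, k)
  idx <- which(sl == lab, arr.ind = TRUE)
  inplane <- setdiff(1:3, mask$axial_axis)
  cbind(mask$origin[inplane[1]] + (idx[, 1] - 1) * mask$spacing[inplane[1]],
        mask$origin[inplane[2]] + (idx[, 2] - 1) * mask$spacing[inplane[2]])
}

# number of `label` voxels per axial slice
slice_counts <- function(mask, label = "tumor") {
  lab <- label_value(mask, label)
  ax <- mask$axial_axis
  apply(mask$labels == lab, ax, sum)
}

#' Read a labeled NIfTI mask
#'
#' Loads a `.nii`/`.nii.gz` label volume.  Voxel spacing is taken from the
#' header `pixdim`; the axial axis defaults to the third array axis (the
#' usual slice axis of axial acquisitions) and can be overridden — the
#' volume is never silently resampled or reoriented.
#'
#' @param path file path to the NIfTI volume.
#' @param axial_axis index of the slice axis (default 3).
#' @param label_map named integer vector, see [voxel_mask()].
#' @return A [voxel_mask].
#' @export
read_mask_nifti <- function(path, axial_axis = 3,
                            label_map = c(tumor = 1L, left_carotid = 2L,
                                          right_carotid = 3L)) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  voxel_mask(round(as.array(img)), spacing = spacing,
             axial_axis = axial_axis, origin = c(0, 0, 0),
             label_map = label_map)
}

#' Write a voxel mask to NIfTI
#'
#' @param mask a [voxel_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
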