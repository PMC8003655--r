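#' 4-channel MR volume container
#'
#' A `volume4ch` holds a 4-channel 3D intensity array with voxel-spacing
#' metadata.  Channel order is fixed as T1, T2, FLAIR, GdT1 and arrays are
#' stored channel-last, i.e. `dim(data) == c(X, Y, Z, 4)`.
#'
#' @param data numeric 4D array, 4 channels in the last dimension.
#' @param spacing numeric length-3, mm per voxel along x, y, z.
#' @param id character identifier.
#' @return An object of class `volume4ch`.
#' @export
volume4ch <- function(data, spacing = c(1, 1, 1), id = "case") {
  d <- dim(data)
  if (length(d) != 4L || d[4] != 4L)
    stop("volume4ch needs a 4D array with exactly 4 channels; got dim [",
         paste(d, collapse = ", "), "]")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(data = data, spacing = as.numeric(spacing), id = id),
            class = "volume4ch")
}

#' @export
print.volume4ch <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4ch '%s'> %d x %d x %d x 4, spacing %s mm\n",
              x$id, d[1], d[2], d[3], paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' @param data 3D array of 0/1 values (logical is coerced).
#' @param spacing numeric length-3, mm per voxel.
#' @param id character identifier.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(data, spacing = c(1, 1, 1), id = "case") {
  if (length(dim(data)) != 3L)
    stop("voi_mask needs a 3D array")
  storage.mode(data) <- "double"
  if (!all(data %in% c(0, 1)))
    stop("voi_mask values must be 0 or 1")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(data = data, spacing = as.numeric(spacing), id = id),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voi_mask '%s'> %d x %d x %d, %d voxels on\n",
              x$id, d[1], d[2], d[3], sum(x$data != 0)))
  invisible(x)
}

#' Merge sub-region labels into the whole-tumor VOI
#'
#' Collapses a multi-label mask (BraTS codes: 1 necrotic core, 2 edema,
#' 4 enhancing tumor) into one binary whole-tumor mask: a voxel is in the
#' VOI exactly when its label is nonzero.
#'
#' @param labels 3D array of nonnegative integer label codes (0 background).
#' @param spacing,id passed through to [voi_mask()].
#' @return A [voi_mask()].
#' @export
merge_voi <- function(labels, spacing = c(1, 1, 1), id = "case") {
  if (inherits(labels, "voi_mask")) return(labels)
  if (any(labels < 0)) stop("label codes must be nonnegative integers")
  voi_mask((labels != 0) * 1, spacing = spacing, id = id)
}

# in-brain support: voxels nonzero in any channel
.support_mask <- function(vol) {
  d <- dim(vol$data)
  m <- array(FALSE, d[1:3])
  for (c in 1:4) m <- m | (vol$data[, , , c] != 0)
  m
}

#' Z-score normalize a 4-channel volume over its in-brain support
#'
#' Per channel, subtracts the mean and divides by the population standard
#' deviation computed over the support region (default: voxels that are
#' nonzero in any channel, i.e. in-brain for skull-stripped data).  Voxels
#' outside the support are set to 0.  Background zeros are excluded from the
#' statistics because they would otherwise dominate them.
#'
#' @param vol a [volume4ch()].
#' @param region optional logical/0-1 3D array giving the support explicitly.
#' @return A normalized [volume4ch()].
#' @export
zscore_normalize <- function(vol, region = NULL) {
  stopifnot(inherits(vol, "volume4ch"))
  supp <- if (is.null(region)) .support_mask(vol) else {
    if (!identical(dim(region), dim(vol$data)[1:3]))
      stop("region shape does not match volume")
    region != 0
  }
  n <- sum(supp)
  if (n < 2L) stop("support region must contain at least 2 voxels")
  out <- vol$data
  chn <- c("T1", "T2", "FLAIR", "GdT1")
  for (c in 1:4) {
    v <- vol$data[, , , c][supp]
    mu <- mean(v)
    sdp <- sqrt(sum((v - mu)^2) / n)  # population SD, fixed for determinism
    if (sdp == 0)
      stop("channel ", chn[c], " has zero variance over the support region")
    z <- array(0, dim(vol$data)[1:3])
    z[supp] <- (vol$data[, , , c][supp] - mu) / sdp
    out[, , , c] <- z
  }
  volume4ch(out, spacing = vol$spacing, id = vol$id)
}

# Tight half-open bounding box [lo, hi) of TRUE voxels, 0-based
.bounding_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  lo <- apply(idx, 2, min) - 1L
  hi <- apply(idx, 2, max)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# Trilinear resample of one 3D array from a half-open box to target shape
.resample3 <- function(arr, box, target, nearest = FALSE) {
  src <- arr[(box$lo[1] + 1):box$hi[1],
             (box$lo[2] + 1):box$hi[2],
             (box$lo[3] + 1):box$hi[3], drop = FALSE]
  sdim <- dim(src)
  coord <- lapply(1:3, function(a) {
    (seq_len(target[a]) - 0.5) * sdim[a] / target[a] - 0.5
  })
  if (nearest) {
    idx <- lapply(1:3, function(a) pmin(pmax(round(coord[[a]]) + 1, 1), sdim[a]))
    return(src[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(coord[[a]]), 0), sdim[a] - 1))
  fr <- lapply(1:3, function(a) {
    f <- coord[[a]] - lo[[a]]
    pmin(pmax(f, 0), 1)
  })
  i0 <- lapply(1:3, function(a) as.integer(lo[[a]]) + 1L)
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, sdim[a]))
  out <- array(0, target)
  g <- function(ix, iy, iz) src[ix, iy, iz, drop = FALSE]
  fx <- array(fr[[1]], target); fy <- array(rep(fr[[2]], each = target[1]), target)
  fz <- array(rep(fr[[3]], each = target[1] * target[2]), target)
  out <- g(i0[[1]], i0[[2]], i0[[3]]) * (1 - fx) * (1 - fy) * (1 - fz) +
         g(i1[[1]], i0[[2]], i0[[3]]) * fx       * (1 - fy) * (1 - fz) +
         g(i0[[1]], i1[[2]], i0[[3]]) * (1 - fx) * fy       * (1 - fz) +
         g(i1[[1]], i1[[2]], i0[[3]]) * fx       * fy       * (1 - fz) +
         g(i0[[1]], i0[[2]], i1[[3]]) * (1 - fx) * (1 - fy) * fz +
         g(i1[[1]], i0[[2]], i1[[3]]) * fx       * (1 - fy) * fz +
         g(i0[[1]], i1[[2]], i1[[3]]) * (1 - fx) * fy       * fz +
         g(i1[[1]], i1[[2]], i1[[3]]) * fx       * fy       * fz
  out
}

#' Crop to the brain bounding box and resample to the model input shape
#'
#' Images are cropped to the tight bounding box of their in-brain support
#' (or to `box` if given) and resampled to `target_shape` with trilinear
#' interpolation.  Masks must be given the box computed from their paired
#' image and are resampled nearest-neighbor so they stay binary.  Spacing
#' metadata is rescaled by (box extent / target extent).
#'
#' @param x a [volume4ch()] or [voi_mask()].
#' @param target_shape integer length-3.
#' @param mode `"image"` or `"mask"`.
#' @param box optional list(lo, hi) 0-based half-open bounding box; required
#'   for masks.
#' @return The resampled object, with the box used attached as
#'   `attr(, "box")`.
#' @export
crop_resize <- function(x, target_shape, mode = c("image", "mask"),
                        box = NULL) {
  mode <- match.arg(mode)
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape >= 1L))
  if (mode == "image") {
    stopifnot(inherits(x, "volume4ch"))
    if (is.null(box)) {
      box <- .bounding_box(.support_mask(x))
      if (is.null(box))
        stop("volume has empty support and no explicit box was supplied")
    }
    ext <- box$hi - box$lo
    out <- array(0, c(target_shape, 4L))
    for (c in 1:4) out[, , , c] <- .resample3(x$data[, , , c], box, target_shape)
    res <- volume4ch(out, spacing = x$spacing * ext / target_shape, id = x$id)
  } else {
    stopifnot(inherits(x, "voi_mask"))
    if (is.null(box))
      stop("mask resampling requires the bounding box of the paired image")
    ext <- box$hi - box$lo
    out <- .resample3(x$data, box, target_shape, nearest = TRUE)
    res <- voi_mask(out, spacing = x$spacing * ext / target_shape, id = x$id)
  }
  attr(res, "box") <- box
  res
}

#' Read a case (4-channel image + label volume) from NIfTI files
#'
#' @param image_path path to a 4D NIfTI image (channels in the 4th
#'   dimension, order T1, T2, FLAIR, GdT1).
#' @param label_path path to a 3D integer NIfTI label image.
#' @return list with `volume` ([volume4ch()]) and `labels` (3D array).
#' @export
read_case <- function(image_path, label_path) {
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(label_path)
  di <- dim(img)
  if (length(di) != 4L || di[4] != 4L)
    stop("image must be 4D with exactly 4 channels; got ",
         length(di), "D with dim [", paste(di, collapse = ", "), "]")
  if (!identical(dim(lab)[1:3], di[1:3]))
    stop("label shape [", paste(dim(lab), collapse = ", "),
         "] does not match image shape [", paste(di[1:3], collapse = ", "), "]")
  spacing <- RNifti::pixdim(img)[1:3]
  id <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  list(volume = volume4ch(array(as.numeric(img), di), spacing = spacing, id = id),
       labels = array(as.numeric(lab), dim(lab)[1:3]))
}

#' Write a case to NIfTI files
#'
#' @param volume a [volume4ch()].
#' @param labels 3D label array (integer codes).
#' @param image_path,label_path output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_case <- function(volume, labels, image_path, label_path) {
  stopifnot(inherits(volume, "volume4ch"))
  if (!identical(dim(labels), dim(volume$data)[1:3]))
    stop("label shape does not match volume shape")
  sp <- volume$spacing
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(sp, 1)
  RNifti::writeNifti(img, image_path, datatype = "double")
  lab <- RNifti::asNifti(array(as.integer(labels), dim(labels)))
  RNifti::pixdim(lab) <- sp
  RNifti::writeNifti(lab, label_path, datatype = "int")
  invisible(c(image_path, label_path))
}

#' Preprocess a case to model-ready tensors
#'
#' Applies the standard chain: merge sub-region labels to the whole-tumor
#' VOI, crop image and mask to the image's brain bounding box, resample to
#' `target_shape`, then Z-score normalize the image (normalization last, so
#' the model always sees zero-mean unit-variance input regardless of
#' interpolation).
#'
#' @param volume a [volume4ch()].
#' @param labels 3D multi-label array (or a [voi_mask()]).
#' @param target_shape integer length-3 model input shape.
#' @return list with `x` (normalized 4D array), `y` (binary 3D array),
#'   `spacing` (resampled spacing), `id`.
#' @export
preprocess_case <- function(volume, labels, target_shape) {
  voi <- merge_voi(labels, spacing = volume$spacing, id = volume$id)
  img <- crop_resize(volume, target_shape, mode = "image")
  msk <- crop_resize(voi, target_shape, mode = "mask", box = attr(img, "box"))
  img <- zscore_normalize(img)
  list(x = img$data, y = msk$data, spacing = img$spacing, id = volume$id)
}
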