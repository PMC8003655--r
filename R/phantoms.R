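#' Facility acquisition specification
#'
#' Bundles the parameters of one simulated facility's acquisition
#' characteristics (its "domain"): per-channel intensity scale and offset,
#' a gamma (pointwise power on unit-normalized intensities), a smooth
#' multiplicative bias field amplitude, additive Gaussian noise, and a
#' slice-thickness factor that emulates thick axial slices by z block
#' averaging.  Two specs with identical fields produce identical transforms
#' under identical seeds.
#'
#' @param facility_id short string naming the facility.
#' @param intensity_scale positive scalar or length-4 vector (per channel).
#' @param intensity_offset scalar or length-4 vector.
#' @param gamma positive scalar; power applied to unit-normalized
#'   intensities (1 = identity).
#' @param bias_field_amplitude nonnegative; peak relative deviation of the
#'   multiplicative low-order polynomial field.
#' @param noise_sigma nonnegative; additive Gaussian SD in normalized
#'   intensity units, applied inside the brain only (background stays 0 as
#'   for skull-stripped data).
#' @param slice_thickness_factor integer >= 1; z-axis block-average factor.
#'   Clinical slice thickness in multi-facility glioma data ranges roughly
#'   3.3 to 9 mm against ~1 mm in-plane, i.e. factors of about 3 to 9.
#' @param rng_seed_offset integer mixed into per-case seeds.
#' @return An object of class `facility_spec`.
#' @export
facility_spec <- function(facility_id,
                          intensity_scale = 1,
                          intensity_offset = 0,
                          gamma = 1,
                          bias_field_amplitude = 0,
                          noise_sigma = 0,
                          slice_thickness_factor = 1L,
                          rng_seed_offset = 0L) {
  intensity_scale <- rep_len(as.numeric(intensity_scale), 4L)
  intensity_offset <- rep_len(as.numeric(intensity_offset), 4L)
  if (any(intensity_scale <= 0)) stop("intensity_scale must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (bias_field_amplitude < 0) stop("bias_field_amplitude must be nonnegative")
  slice_thickness_factor <- as.integer(slice_thickness_factor)
  if (slice_thickness_factor < 1L) stop("slice_thickness_factor must be >= 1")
  structure(list(facility_id = facility_id,
                 intensity_scale = intensity_scale,
                 intensity_offset = intensity_offset,
                 gamma = gamma,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_sigma = noise_sigma,
                 slice_thickness_factor = slice_thickness_factor,
                 rng_seed_offset = as.integer(rng_seed_offset)),
            class = "facility_spec")
}

#' Read facility specs from a YAML file
#'
#' The file maps facility_id to parameter fields of [facility_spec()].
#'
#' @param path YAML file path.
#' @return Named list of `facility_spec` objects.
#' @export
read_facility_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    do.call(facility_spec, c(list(facility_id = id), raw[[id]]))
  })
  names(out) <- names(raw)
  out
}

# Mean tissue intensities per compartment (rows) and channel (columns
# T1, T2, FLAIR, GdT1), on a nominal [0, 1] scale.  Ordering encodes the
# standard glioma appearance: tumor+edema hyperintense on T2/FLAIR,
# enhancing rim bright on GdT1, necrotic core dark on T1.  Contrasts are
# deliberately moderate (infiltrative margins are diffuse in real images)
# and a CSF compartment provides ventricle-like distractors that are
# T2-bright but FLAIR-suppressed, so segmentation requires multi-channel
# context rather than a single-channel threshold.  The WMH row mimics
# white-matter-hyperintensity-like lesions: almost the edema signature,
# separated only by a narrow intensity margin, so accurate segmentation
# depends on calibrated intensities - the calibration a facility shift
# corrupts.
.tissue_means <- function() {
  rbind(tissue = c(0.60, 0.50, 0.52, 0.55),
        edema  = c(0.52, 0.64, 0.66, 0.52),
        rim    = c(0.50, 0.60, 0.62, 0.72),
        core   = c(0.42, 0.66, 0.60, 0.42),
        csf    = c(0.35, 0.85, 0.30, 0.35),
        wmh    = c(0.53, 0.62, 0.63, 0.53))
}

# Smooth 3D Gaussian random field via separable smoothing of white noise,
# normalized to zero mean / unit max-abs.
.smooth_field <- function(shape, sigma = 2.5) {
  f <- array(rnorm(prod(shape)), shape)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  sm1 <- function(a, axis) {
    ap <- aperm(a, c(axis, setdiff(1:3, axis)))
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    n <- d[1]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    aperm(array(out, d), order(c(axis, setdiff(1:3, axis))))
  }
  f <- sm1(sm1(sm1(f, 1), 2), 3)
  f <- f - mean(f)
  f / max(abs(f))
}

.ellipsoid_mask <- function(shape, center, radii) {
  if (any(radii <= 0)) return(array(FALSE, shape))
  x <- ((seq_len(shape[1]) - center[1]) / radii[1])^2
  y <- ((seq_len(shape[2]) - center[2]) / radii[2])^2
  z <- ((seq_len(shape[3]) - center[3]) / radii[3])^2
  r2 <- outer(outer(x, y, `+`), z, `+`)
  r2 <= 1
}

#' Generate a base multi-channel brain phantom with a labeled tumor
#'
#' Builds a skull-free brain modeled as an axis-aligned ellipsoid with
#' smooth low-frequency internal texture, and embeds a three-compartment
#' tumor (necrotic core innermost, enhancing rim, outer edema shell) as
#' concentric ellipsoids.  Labels use BraTS codes: 1 necrotic core,
#' 2 edema, 4 enhancing tumor.  Voxels outside the brain are exactly zero.
#'
#' @param shape integer length-3, each >= 8.
#' @param tumor_params list with `center` (voxel coords), `radii` (length-3
#'   outer radii of the enhancing tumor; all 0 for no tumor), `rim_width`
#'   (voxels), `edema_width` (voxels, default 2).
#' @param seed integer; output is a pure function of (shape, tumor_params,
#'   seed).
#' @param spacing voxel spacing in mm (default 1x1x1).
#' @param texture_sd relative amplitude of the intra-brain texture field.
#' @param metadata_label arbitrary stratum label attached to the case.
#' @param id case identifier.
#' @return A `phantom_case`: list with `volume` ([volume4ch()]), `labels`
#'   (3D array), `facility_id` (`"base"` until a facility transform is
#'   applied), `metadata_label`, `tumor_volume_ml`, `id`.
#' @export
make_base_phantom <- function(shape, tumor_params, seed,
                              spacing = c(1, 1, 1), texture_sd = 0.15,
                              metadata_label = "unspecified", id = "phantom") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (any(shape < 8L)) stop("each dimension of shape must be >= 8")
  tp <- modifyList(list(edema_width = 2, rim_width = 2), tumor_params)
  center <- tp$center; radii <- rep_len(as.numeric(tp$radii), 3L)
  brain_center <- (shape + 1) / 2
  brain_radii <- 0.44 * shape

  has_tumor <- any(radii > 0)
  if (has_tumor) {
    outer_r <- radii + tp$edema_width
    for (a in 1:3) {
      if (abs(center[a] - brain_center[a]) + outer_r[a] > brain_radii[a])
        stop(sprintf(
          "tumor radius %.1f (+ edema %.1f) along axis %d does not fit inside the brain ellipsoid",
          radii[a], tp$edema_width, a))
    }
  }

  with_seed(seed, {
    brain <- .ellipsoid_mask(shape, brain_center, brain_radii)
    tex <- .smooth_field(shape)
    # ventricle-like CSF distractors: paired para-midline ellipsoids,
    # jittered per case
    csf <- array(FALSE, shape)
    for (side in c(-1, 1)) {
      vc <- brain_center + c(side * 0.22 * shape[1], 0, 0) + runif(3, -1.5, 1.5)
      vr <- c(0.08, 0.2, 0.12) * shape * runif(3, 0.8, 1.2)
      csf <- csf | .ellipsoid_mask(shape, vc, vr)
    }
    csf <- csf & brain
    # small non-tumor lesions with near-edema signature, away from the tumor
    wmh <- array(FALSE, shape)
    for (b in seq_len(4)) {
      for (try in 1:20) {
        bc <- brain_center + runif(3, -1, 1) * 0.55 * brain_radii
        br <- runif(1, 1.5, 3) * runif(3, 0.8, 1.2)
        sep_ok <- !has_tumor ||
          sqrt(sum(((bc - center) / (radii + tp$edema_width + 2))^2)) > 1
        if (sep_ok && sqrt(sum(((bc - brain_center) / brain_radii)^2)) < 0.85) {
          wmh <- wmh | .ellipsoid_mask(shape, bc, br)
          break
        }
      }
    }
    wmh <- wmh & brain & !csf
    labels <- array(0, shape)
    if (has_tumor) {
      core_r <- pmax(radii - tp$rim_width, 0)
      whole <- .ellipsoid_mask(shape, center, radii) & brain
      core <- .ellipsoid_mask(shape, center, core_r) & brain
      edema <- .ellipsoid_mask(shape, center, radii + tp$edema_width) & brain
      labels[edema] <- 2          # edema shell
      labels[whole] <- 4          # enhancing tumor
      labels[core] <- 1           # necrotic core
    }
    # normalized ellipsoidal radius of every voxel w.r.t. the tumor: the
    # edema contrast fades linearly from the enhancing-tumor boundary
    # (rho = 1) to zero one edema-width beyond the labeled edema edge, so
    # the label boundary sits at the 50% point of an infiltration ramp
    # rather than on an intensity step
    rho <- NULL
    if (has_tumor) {
      rx <- ((seq_len(shape[1]) - center[1]) / radii[1])^2
      ry <- ((seq_len(shape[2]) - center[2]) / radii[2])^2
      rz <- ((seq_len(shape[3]) - center[3]) / radii[3])^2
      rho <- sqrt(outer(outer(rx, ry, `+`), rz, `+`))
    }
    contrast <- if (is.null(tp$contrast)) 1 else tp$contrast
    mu <- .tissue_means()
    vol <- array(0, c(shape, 4L))
    for (c in 1:4) {
      ch <- array(0, shape)
      ch[brain] <- mu["tissue", c]
      ch[csf & labels == 0] <- mu["csf", c]
      ch[wmh & labels == 0] <- mu["wmh", c]
      if (has_tumor) {
        rho_out <- 1 + 2 * tp$edema_width / mean(radii)
        fade <- brain & rho >= 1 & rho < rho_out & !(csf & labels == 0) &
          !(wmh & labels == 0)
        w <- (rho_out - rho[fade]) / (rho_out - 1)
        ch[fade] <- mu["tissue", c] +
          contrast * w * (mu["edema", c] - mu["tissue", c])
        ch[labels == 4] <- mu["tissue", c] +
          contrast * (mu["rim", c] - mu["tissue", c])
        ch[labels == 1] <- mu["tissue", c] +
          contrast * (mu["core", c] - mu["tissue", c])
      }
      ch[brain] <- pmax(ch[brain] * (1 + texture_sd * tex[brain]), 1e-3)
      vol[, , , c] <- ch
    }
    structure(list(volume = volume4ch(vol, spacing = spacing, id = id),
                   labels = labels,
                   facility_id = "base",
                   metadata_label = metadata_label,
                   tumor_volume_ml = sum(labels != 0) * prod(spacing) / 1000,
                   id = id),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case '%s'> facility %s, tumor %.2f mL, label '%s'\n",
              x$id, x$facility_id, x$tumor_volume_ml, x$metadata_label))
  invisible(x)
}

# degree-2 polynomial bias field, normalized to peak |deviation| = amplitude
.bias_field <- function(shape, amplitude) {
  u <- seq(-1, 1, length.out = shape[1])
  v <- seq(-1, 1, length.out = shape[2])
  w <- seq(-1, 1, length.out = shape[3])
  cf <- runif(9, -1, 1)
  U <- array(u, shape)
  V <- array(rep(v, each = shape[1]), shape)
  W <- array(rep(w, each = shape[1] * shape[2]), shape)
  P <- cf[1] * U + cf[2] * V + cf[3] * W +
       cf[4] * U * V + cf[5] * U * W + cf[6] * V * W +
       cf[7] * U^2 + cf[8] * V^2 + cf[9] * W^2
  1 + amplitude * P / max(abs(P))
}

# z block average then piecewise-constant replication (thick-slice surrogate)
.thick_slices <- function(ch, factor) {
  if (factor == 1L) return(ch)
  nz <- dim(ch)[3]
  grp <- ((seq_len(nz) - 1L) %/% factor) + 1L
  out <- ch
  for (g in unique(grp)) {
    sl <- which(grp == g)
    m <- apply(ch[, , sl, drop = FALSE], c(1, 2), mean)
    for (s in sl) out[, , s] <- m
  }
  out
}

#' Apply one facility's acquisition transform to a phantom case
#'
#' Intensities are transformed per channel in a fixed, documented order:
#' scale/offset, then gamma on unit-normalized intensities, then the
#' multiplicative bias field, then slice-thickness degradation, then
#' additive in-brain Gaussian noise.  The order is part of the contract
#' (changing it changes outputs).  Labels are never modified.
#'
#' @param case a `phantom_case`.
#' @param spec a [facility_spec()].
#' @param seed integer; with `spec$rng_seed_offset` it fully determines the
#'   random components (bias field orientation, noise draw).
#' @return The transformed `phantom_case`, with `facility_id` set from the
#'   spec.
#' @export
apply_facility_transform <- function(case, spec, seed) {
  stopifnot(inherits(case, "phantom_case"), inherits(spec, "facility_spec"))
  vol <- case$volume$data
  shape <- dim(vol)[1:3]
  brain <- .support_mask(case$volume)
  with_seed(derive_seed(seed, spec$rng_seed_offset, "facility"), {
    bias <- if (spec$bias_field_amplitude > 0)
      .bias_field(shape, spec$bias_field_amplitude) else NULL
    for (c in 1:4) {
      ch <- vol[, , , c]
      ch[brain] <- ch[brain] * spec$intensity_scale[c] + spec$intensity_offset[c]
      if (spec$gamma != 1) {
        if (any(ch[brain] <= 0))
          stop("gamma transform requires strictly positive in-brain intensities")
        mx <- max(ch[brain])
        ch[brain] <- (ch[brain] / mx)^spec$gamma
      }
      if (!is.null(bias)) ch[brain] <- ch[brain] * bias[brain]
      ch <- .thick_slices(ch, spec$slice_thickness_factor)
      ch[!brain] <- 0  # block averaging can bleed over the brain edge
      if (spec$noise_sigma > 0)
        ch[brain] <- ch[brain] + rnorm(sum(brain), 0, spec$noise_sigma)
      vol[, , , c] <- ch
    }
  })
  out <- case
  out$volume <- volume4ch(vol, spacing = case$volume$spacing, id = case$id)
  out$facility_id <- spec$facility_id
  out
}

#' Default tumor sampler parameters
#'
#' Governs the per-case tumor draw in [generate_facility_dataset()]:
#' per-axis radii uniform in `radius_range`, center jittered uniformly up
#' to `center_jitter` voxels per axis (clamped so the tumor plus edema
#' stays inside the brain), fixed rim and edema widths.
#'
#' @param radius_range length-2 numeric, voxels.
#' @param rim_width,edema_width voxels.
#' @param center_jitter voxels.
#' @param contrast_range length-2; per-case multiplier on all tumor
#'   compartment contrasts (lesion conspicuity varies across patients).
#' @param metadata_labels character pool the per-case stratum label is
#'   drawn from (arbitrary strata so group-by machinery is exercised).
#' @return list of sampler settings.
#' @export
tumor_sampler <- function(radius_range = c(2.5, 5.5), rim_width = 2,
                          edema_width = 2, center_jitter = 4,
                          contrast_range = c(0.65, 1.2),
                          metadata_labels = c("astrocytoma",
                                              "oligodendroglioma",
                                              "glioblastoma")) {
  stopifnot(length(radius_range) == 2L, radius_range[1] <= radius_range[2])
  list(radius_range = radius_range, rim_width = rim_width,
       edema_width = edema_width, center_jitter = center_jitter,
       contrast_range = contrast_range, metadata_labels = metadata_labels)
}

#' Generate a dataset of phantom cases for one facility
#'
#' Each case gets an independent tumor draw and the facility transform;
#' per-case seeds are derived deterministically from `(seed, case index,
#' spec$rng_seed_offset)` so datasets are reproducible case by case.
#'
#' @param spec a [facility_spec()].
#' @param n_cases integer >= 1.
#' @param shape integer length-3 volume shape.
#' @param sampler a [tumor_sampler()] bundle.
#' @param seed integer master seed.
#' @param spacing voxel spacing (mm).
#' @return list of `phantom_case` objects.
#' @export
generate_facility_dataset <- function(spec, n_cases, shape,
                                      sampler = tumor_sampler(), seed = 1,
                                      spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "facility_spec"), n_cases >= 1)
  shape <- as.integer(shape)
  brain_center <- (shape + 1) / 2
  brain_radii <- 0.44 * shape
  lapply(seq_len(n_cases), function(i) {
    si <- derive_seed(seed, i, spec$rng_seed_offset)
    draw <- with_seed(derive_seed(si, "tumor"), {
      radii <- runif(3, sampler$radius_range[1], sampler$radius_range[2])
      outer_r <- radii + sampler$edema_width
      jmax <- pmax(pmin(sampler$center_jitter, brain_radii - outer_r - 1), 0)
      center <- brain_center + runif(3, -1, 1) * jmax
      contrast <- runif(1, sampler$contrast_range[1], sampler$contrast_range[2])
      label <- sample(sampler$metadata_labels, 1)
      list(radii = radii, center = center, contrast = contrast, label = label)
    })
    id <- sprintf("%s_%03d", spec$facility_id, i)
    base <- make_base_phantom(
      shape,
      list(center = draw$center, radii = draw$radii,
           rim_width = sampler$rim_width, edema_width = sampler$edema_width,
           contrast = draw$contrast),
      seed = derive_seed(si, "phantom"), spacing = spacing,
      metadata_label = draw$label, id = id)
    apply_facility_transform(base, spec, seed = derive_seed(si, "transform"))
  })
}
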