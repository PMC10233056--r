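# Synthetic multi-phase liver phantom generator.
#
# Each patient is three co-registered contrast phases (arterial,
# portal-venous, delayed) of a simplified abdomen: air background, a body
# ellipsoid with a bright subcutaneous-fat ring (the brightest tissue, as
# in T1-weighted imaging - it carries the intensity tail the
# 99th-percentile normalization absorbs), mid-intensity soft tissue, and a
# liver ellipsoid containing spherical lesions plus sparse bright vessel
# voxels. Lesion contrast dynamics encode the three major LI-RADS
# features: arterial-phase hyperenhancement (APHE, B1), washout (B2) and
# an enhancing capsule rim (B3). Lesions without washout are rendered with
# persistent enhancement (mildly hyperintense in the later phases) so that
# the "depressed iff washout" contrast contract holds while every lesion
# remains visible in the delayed phase.

#' Specification of a synthetic multi-phase phantom dataset
#'
#' Defaults mirror the composition of the clinical cohort the pipeline is
#' designed for: lesion diameters 4-164 mm with roughly 45% under 20 mm
#' (sampled from a truncated log-normal with median ~22 mm), up to 3 lesions
#' per patient (some patients lesion-free), and feature prevalences typical
#' of an LR-3/4/5 population.
#'
#' @param n_patients Number of patients to generate.
#' @param lesions_per_patient Integer range `c(min, max)` of lesions per
#'   patient (sampled uniformly).
#' @param diameter_mm Range `c(low, high)` of lesion diameters in mm.
#' @param small_lesion_fraction Target proportion of lesions under 20 mm.
#' @param feature_prevalence Named probabilities `c(p_aphe, p_washout,
#'   p_capsule)`, each in \[0, 1\].
#' @param contrast Named list of signal offsets (scanner units) applied to
#'   lesion voxels per (phase, feature): `aphe` (arterial, B1 = 1),
#'   `arterial_hypo` (arterial, B1 = 0), `washout` (PV/delayed, B2 = 1),
#'   `persistent` (PV/delayed, B2 = 0), `capsule` (PV/delayed rim, B3 = 1).
#' @param noise_sigma Additive Gaussian noise scale.
#' @param volume_shape Integer `c(slices, rows, cols)`; rows must equal cols.
#' @param spacing_mm Voxel spacing `c(z, y, x)` in mm.
#' @param liver_intensity,outside_intensity Signal of liver parenchyma and
#'   of the air outside the body. The air value sits below the
#'   normalization floor of 80 so it maps to 0, as scanner background does.
#' @param soft_tissue_intensity Signal of non-liver abdominal tissue.
#' @param fat_intensity Signal of the subcutaneous-fat ring at the body
#'   surface - the brightest structure in the volume, so the
#'   99th-percentile normalization threshold lands in it rather than on
#'   lesions.
#' @param vessel_fraction Fraction of the whole volume rendered as sparse
#'   bright vessel voxels inside the liver (present in every phase,
#'   excluded from the lesion mask).
#' @param vessel_intensity Signal of the vessel voxels.
#' @param seed Integer dataset seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 111L,
                         lesions_per_patient = c(0L, 3L),
                         diameter_mm = c(4, 164),
                         small_lesion_fraction = 0.448,
                         feature_prevalence = c(p_aphe = 0.7,
                                                p_washout = 0.6,
                                                p_capsule = 0.4),
                         contrast = list(aphe = 120, arterial_hypo = -60,
                                         washout = -100, persistent = 60,
                                         capsule = 140),
                         noise_sigma = 10,
                         volume_shape = c(48L, 160L, 160L),
                         spacing_mm = c(5, 2.5, 2.5),
                         liver_intensity = 400,
                         outside_intensity = 40,
                         soft_tissue_intensity = 250,
                         fat_intensity = 600,
                         vessel_fraction = 0.003,
                         vessel_intensity = 650,
                         seed = 1L) {
  stopifnot(n_patients >= 1,
            length(lesions_per_patient) == 2,
            lesions_per_patient[1] <= lesions_per_patient[2],
            lesions_per_patient[1] >= 0,
            length(diameter_mm) == 2, diameter_mm[1] > 0,
            diameter_mm[1] <= diameter_mm[2],
            small_lesion_fraction >= 0, small_lesion_fraction <= 1,
            length(feature_prevalence) == 3,
            all(feature_prevalence >= 0), all(feature_prevalence <= 1),
            length(volume_shape) == 3, all(volume_shape >= 1),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            vessel_fraction >= 0, vessel_fraction < 1)
  if (volume_shape[2] != volume_shape[3])
    stop("volume_shape rows must equal cols (square slices)")
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 diameter_mm = as.numeric(diameter_mm),
                 small_lesion_fraction = small_lesion_fraction,
                 feature_prevalence = feature_prevalence,
                 contrast = contrast,
                 noise_sigma = noise_sigma,
                 volume_shape = as.integer(volume_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 liver_intensity = liver_intensity,
                 outside_intensity = outside_intensity,
                 soft_tissue_intensity = soft_tissue_intensity,
                 fat_intensity = fat_intensity,
                 vessel_fraction = vessel_fraction,
                 vessel_intensity = vessel_intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Easy phantom preset for desk-scale end-to-end runs
#'
#' High contrast, low noise, 1-2 clearly visible lesions per patient on
#' 64 x 64 slices: the regime in which the scaled-down networks are expected
#' to segment and characterize well.
#'
#' @param n_patients Number of patients.
#' @param seed Dataset seed.
#' @param ... Overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_easy <- function(n_patients = 40L, seed = 1L, ...) {
  args <- list(n_patients = n_patients,
               lesions_per_patient = c(1L, 2L),
               diameter_mm = c(10, 40),
               small_lesion_fraction = 0.35,
               noise_sigma = 5,
               volume_shape = c(16L, 64L, 64L),
               spacing_mm = c(5, 2.5, 2.5),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantom_spec, args)
}

# Derive a reproducible sub-seed; kept below 2^31 - 1.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed %% 1000003L) * 2011 +
                as.double(index) * 7919 + as.double(salt) * 104729) %%
               2147483629)
}

.sample_diameter <- function(spec) {
  lo <- spec$diameter_mm[1]; hi <- spec$diameter_mm[2]
  want_small <- stats::runif(1) < spec$small_lesion_fraction && lo < 20
  bounds <- if (want_small) c(lo, min(20, hi)) else c(max(min(20, hi), lo), hi)
  if (bounds[1] >= bounds[2]) return(stats::runif(1, lo, hi))
  # truncated log-normal (median ~22 mm) matching the cohort's size profile
  for (i in 1:200) {
    d <- stats::rlnorm(1, meanlog = log(22), sdlog = 0.75)
    if (d >= bounds[1] && d <= bounds[2]) return(d)
  }
  stats::runif(1, bounds[1], bounds[2])
}

#' Generate one synthetic multi-phase study
#'
#' Produces three co-registered phase volumes, a binary ground-truth lesion
#' mask, and the per-lesion ground truth (features, diameter, LI-RADS label
#' from the rule engine). Bit-deterministic given `(spec, patient_seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param patient_seed Integer seed for this patient.
#' @param patient_id Identifier recorded in the study.
#' @return A list with elements `phases` (named list of `rows x cols x
#'   slices` arrays for `arterial`, `portal_venous`, `delayed`), `mask`
#'   (same grid, 0/1), `spacing_mm` (z, y, x), `patient_id`, and `lesions`
#'   (data frame: lesion_id, center_z/y/x, diameter_mm, B1, B2, B3, label,
#'   resolved).
#' @export
generate_study <- function(spec, patient_seed, patient_id = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(patient_seed)
  nz <- spec$volume_shape[1]; ny <- spec$volume_shape[2]
  nx <- spec$volume_shape[3]
  sp <- spec$spacing_mm  # (z, y, x)
  ctr <- c((ny + 1) / 2, (nx + 1) / 2, (nz + 1) / 2)     # (y, x, z) voxels
  semi <- c(0.34 * ny, 0.34 * nx, 0.44 * nz)             # liver
  body_semi <- c(0.48 * ny, 0.48 * nx, 0.49 * nz)

  yy <- rep(seq_len(ny), times = nx * nz)
  xx <- rep(rep(seq_len(nx), each = ny), times = nz)
  zz <- rep(seq_len(nz), each = ny * nx)
  rb <- sqrt(((yy - ctr[1]) / body_semi[1])^2 +
             ((xx - ctr[2]) / body_semi[2])^2 +
             ((zz - ctr[3]) / body_semi[3])^2)
  inside <- ((yy - ctr[1]) / semi[1])^2 + ((xx - ctr[2]) / semi[2])^2 +
    ((zz - ctr[3]) / semi[3])^2 <= 1
  base <- array(spec$outside_intensity, c(ny, nx, nz))   # air
  base[rb <= 1] <- spec$fat_intensity                    # fat ring ...
  base[rb <= 0.90] <- spec$soft_tissue_intensity         # ... over tissue
  base[inside] <- spec$liver_intensity

  arterial <- base; pv <- base; delayed <- base
  mask <- array(0L, c(ny, nx, nz))

  n_les <- if (spec$lesions_per_patient[1] == spec$lesions_per_patient[2])
    spec$lesions_per_patient[1] else
      sample(spec$lesions_per_patient[1]:spec$lesions_per_patient[2], 1)

  shell_mm <- 1.5 * mean(sp[2:3])   # capsule rim thickness: 1-2 voxels
  placed <- list()
  rows <- list()
  # sample every lesion's size and features first, then place largest-first
  # (greedy packing keeps crowded patients feasible); ids follow placement
  # order
  props <- list()
  if (n_les > 0) for (li in seq_len(n_les)) {
    set.seed(derive_seed(patient_seed, li, salt = 17L))
    d <- .sample_diameter(spec)
    max_d <- 2 * min((semi - 1) * c(sp[2], sp[3], sp[1])) * 0.8
    props[[li]] <- list(d = min(d, max_d),
                        B1 = stats::runif(1) < spec$feature_prevalence[[1]],
                        B2 = stats::runif(1) < spec$feature_prevalence[[2]],
                        B3 = stats::runif(1) < spec$feature_prevalence[[3]])
  }
  if (n_les > 0) props <- props[order(-vapply(props, `[[`, 0, "d"))]
  if (n_les > 0) for (li in seq_len(n_les)) {
    set.seed(derive_seed(patient_seed, li, salt = 19L))
    d <- props[[li]]$d
    ok <- FALSE
    for (try in 1:300) {
      # two bounded shrink steps if the patient is too crowded
      if (try == 101 || try == 201) d <- 0.85 * d
      r <- d / 2
      rv <- c(r / sp[2], r / sp[3], r / sp[1]) +
        shell_mm / c(sp[2], sp[3], sp[1])
      margin <- semi - rv - 0.5
      if (any(margin <= 0)) next
      cand <- c(ctr[1] + stats::runif(1, -1, 1) * margin[1],
                ctr[2] + stats::runif(1, -1, 1) * margin[2],
                ctr[3] + stats::runif(1, -1, 1) * margin[3])
      cand <- round(cand)
      if (((cand[1] - ctr[1]) / margin[1])^2 +
          ((cand[2] - ctr[2]) / margin[2])^2 +
          ((cand[3] - ctr[3]) / margin[3])^2 > 1) next
      clash <- FALSE
      for (p in placed) {
        dd <- sqrt(((cand[1] - p$c[1]) * sp[2])^2 +
                   ((cand[2] - p$c[2]) * sp[3])^2 +
                   ((cand[3] - p$c[3]) * sp[1])^2)
        if (dd < r + p$r + 2 * shell_mm + 2) { clash <- TRUE; break }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("patient %s: could not place lesion %d after retries",
                   patient_id, li))
    r <- d / 2
    B1 <- props[[li]]$B1; B2 <- props[[li]]$B2; B3 <- props[[li]]$B3

    dist_mm <- sqrt(((yy - cand[1]) * sp[2])^2 + ((xx - cand[2]) * sp[3])^2 +
                    ((zz - cand[3]) * sp[1])^2)
    core <- dist_mm <= r
    shell <- dist_mm > r & dist_mm <= r + shell_mm
    cz <- spec$contrast
    arterial[core] <- spec$liver_intensity +
      if (B1) cz$aphe else cz$arterial_hypo
    late_off <- if (B2) cz$washout else cz$persistent
    pv[core] <- spec$liver_intensity + late_off
    delayed[core] <- spec$liver_intensity + late_off
    if (B3) {
      pv[shell] <- spec$liver_intensity + cz$capsule
      delayed[shell] <- spec$liver_intensity + cz$capsule
    }
    mask[core] <- 1L
    placed[[length(placed) + 1]] <- list(c = cand, r = r)
    cat_res <- infer_lirads(B1, B2, B3, d, policy = "prefer_washout_rule")
    rows[[li]] <- data.frame(lesion_id = li,
                             center_z = cand[3], center_y = cand[1],
                             center_x = cand[2],
                             diameter_mm = d, B1 = B1, B2 = B2, B3 = B3,
                             label = cat_res$value,
                             resolved = cat_res$resolved,
                             stringsAsFactors = FALSE)
  }

  # vessel-like bright speckle in every phase (never inside lesion voxels or
  # capsule rims): carries the volume's upper intensity tail, as vasculature
  # does in real contrast-enhanced MR
  if (spec$vessel_fraction > 0) {
    set.seed(derive_seed(patient_seed, 0L, salt = 43L))
    liver_free <- which(inside & mask == 0 & pv == spec$liver_intensity &
                          arterial == spec$liver_intensity)
    n_ves <- round(spec$vessel_fraction * length(base))
    if (n_ves > 0 && length(liver_free) > n_ves) {
      ves <- sample(liver_free, n_ves)
      arterial[ves] <- spec$vessel_intensity
      pv[ves] <- spec$vessel_intensity
      delayed[ves] <- spec$vessel_intensity
    }
  }

  if (spec$noise_sigma > 0) {
    set.seed(derive_seed(patient_seed, 0L, salt = 29L))
    n <- length(base)
    arterial <- arterial + stats::rnorm(n, sd = spec$noise_sigma)
    pv <- pv + stats::rnorm(n, sd = spec$noise_sigma)
    delayed <- delayed + stats::rnorm(n, sd = spec$noise_sigma)
  }

  lesions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lesion_id = integer(0), center_z = integer(0),
               center_y = integer(0), center_x = integer(0),
               diameter_mm = numeric(0), B1 = logical(0), B2 = logical(0),
               B3 = logical(0), label = character(0),
               resolved = character(0), stringsAsFactors = FALSE)
  list(phases = list(arterial = arterial, portal_venous = pv,
                     delayed = delayed),
       mask = mask, spacing_mm = sp, patient_id = patient_id,
       lesions = lesions)
}

#' Generate and write a phantom dataset to disk
#'
#' Writes one NIfTI volume per phase per patient plus a NIfTI mask, a CSV
#' manifest with one row per lesion, and a JSON copy of the spec.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (columns `patient_id,
#'   lesion_id, diameter_mm, B1, B2, B3, label`).
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  detail <- list()
  for (i in seq_len(spec$n_patients)) {
    ps <- derive_seed(spec$seed, i)
    st <- generate_study(spec, ps, patient_id = i)
    write_study(st, out_dir)
    if (nrow(st$lesions))
      detail[[length(detail) + 1]] <- cbind(patient_id = i, st$lesions)
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(patient_id = integer(0), lesion_id = integer(0),
               center_z = integer(0), center_y = integer(0),
               center_x = integer(0), diameter_mm = numeric(0),
               B1 = logical(0), B2 = logical(0), B3 = logical(0),
               label = character(0), resolved = character(0))
  manifest <- detail[, c("patient_id", "lesion_id", "diameter_mm",
                         "B1", "B2", "B3", "label")]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(detail, file.path(out_dir, "lesions_detail.csv"),
                   row.names = FALSE)
  sp <- unclass(spec)
  jsonlite::write_json(sp, file.path(out_dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname generate_dataset
#' @param study A study list as returned by [generate_study()].
#' @param dir Directory to write into.
#' @export
write_study <- function(study, dir) {
  pid <- study$patient_id
  sp <- study$spacing_mm
  pd <- c(sp[2], sp[3], sp[1])  # array dims are (y, x, z)
  for (ph in names(study$phases)) {
    img <- RNifti::asNifti(study$phases[[ph]])
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, file.path(dir, sprintf("patient%03d_%s.nii.gz",
                                                   pid, ph)))
  }
  msk <- RNifti::asNifti(study$mask + 0)
  RNifti::pixdim(msk) <- pd
  RNifti::writeNifti(msk, file.path(dir, sprintf("patient%03d_mask.nii.gz",
                                                 pid)))
  invisible(NULL)
}

#' Read a phantom study back from disk
#'
#' @param dir Dataset directory.
#' @param patient_id Patient number.
#' @return A study list (as from [generate_study()] but without the lesion
#'   table; read it from `manifest.csv`).
#' @export
read_study <- function(dir, patient_id) {
  rd <- function(suffix) {
    f <- file.path(dir, sprintf("patient%03d_%s.nii.gz", patient_id, suffix))
    if (!file.exists(f)) stop("missing file: ", f)
    img <- RNifti::readNifti(f)
    a <- array(as.numeric(img), dim(img))
    attr(a, "pixdim") <- RNifti::pixdim(img)
    a
  }
  arterial <- rd("arterial")
  pd <- attr(arterial, "pixdim")
  list(phases = list(arterial = arterial,
                     portal_venous = rd("portal_venous"),
                     delayed = rd("delayed")),
       mask = rd("mask"),
       spacing_mm = c(pd[3], pd[1], pd[2]),
       patient_id = patient_id)
}
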