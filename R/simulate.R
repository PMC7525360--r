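#' Phantom specification for the synthetic multi-echo generator
#'
#' Declares a digital phantom mixing three water pools per voxel: myelin
#' water (fraction = the voxel's true MWF), CSF (per `csf_fraction`), and
#' intra/extracellular water (the remainder). True MWF is drawn per voxel
#' from a region-wise normal distribution truncated to (0.01, 0.5). Each
#' voxel's echo train is synthesized by the EPG forward model at the
#' voxel's refocusing flip, and i.i.d. Gaussian noise is added with
#' `SD = mean first-echo tissue signal / snr`.
#'
#' @param shape 3D voxel dimensions, e.g. `c(20, 20, 4)`.
#' @param regions list of regions; each a list with `label`, `geometry`
#'   (see [geom_box()]/[geom_sphere()]), `mwf_mean`, `mwf_sd`. Later
#'   regions win where regions overlap.
#' @param lesions optional list of lesion blobs, each a list with
#'   `geometry`, `mwf_mean`, `mwf_sd` (defaults 0.04/0.01: demyelinated
#'   tissue). Applied after regions.
#' @param pool_t2s T2 of the myelin / intra-extracellular / CSF pools (s).
#' @param pool_t1s matching T1 values (s).
#' @param csf_fraction scalar CSF partial-volume fraction (or 3D array).
#' @param flip_field refocusing flip in degrees: scalar or 3D array.
#' @param snr first-echo tissue signal over noise SD; `Inf` for noiseless.
#' @param noise_model `"gaussian"` (default, matching the fitter's
#'   assumption) or `"rician"` (magnitude of complex Gaussian noise, for
#'   robustness experiments).
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(20L, 20L, 4L),
                         regions = list(list(label = "wm",
                                             geometry = geom_box(c(1, 1, 1), shape),
                                             mwf_mean = 0.12, mwf_sd = 0.02)),
                         lesions = list(),
                         pool_t2s = c(myelin = 0.020, ie = 0.080, csf = 2.0),
                         pool_t1s = c(myelin = 0.5, ie = 1.0, csf = 4.0),
                         csf_fraction = 0,
                         flip_field = 165,
                         snr = Inf,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(shape) == 3L, length(pool_t2s) == 3L, length(pool_t1s) == 3L)
  if (!is.finite(snr) && !is.infinite(snr) || (is.finite(snr) && snr <= 0))
    stop("snr must be > 0 (Inf for noiseless)", call. = FALSE)
  for (r in regions) {
    if (!all(c("label", "geometry", "mwf_mean", "mwf_sd") %in% names(r)))
      stop("each region needs label, geometry, mwf_mean, mwf_sd", call. = FALSE)
    if (r$mwf_mean <= 0 || r$mwf_mean >= 1 || r$mwf_sd < 0)
      stop("region mwf_mean must lie in (0,1) and mwf_sd >= 0", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), regions = regions,
                 lesions = lesions, pool_t2s = pool_t2s, pool_t1s = pool_t1s,
                 csf_fraction = csf_fraction, flip_field = flip_field,
                 snr = snr, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Geometry primitives for phantom regions
#'
#' `geom_box()` is an axis-aligned box given by inclusive voxel index
#' corners; `geom_sphere()` a ball of given radius (in voxels) around a
#' center.
#'
#' @param from,to inclusive integer voxel corners `c(i, j, k)`.
#' @return a geometry descriptor consumed by [generate_phantom()].
#' @export
geom_box <- function(from, to) {
  list(type = "box", from = as.integer(from), to = as.integer(to))
}

#' @rdname geom_box
#' @param center sphere center `c(i, j, k)` (voxel coordinates).
#' @param radius radius in voxels.
#' @export
geom_sphere <- function(center, radius) {
  list(type = "sphere", center = as.numeric(center), radius = as.numeric(radius))
}

region_mask <- function(geom, shape) {
  idx <- arrayInd(seq_len(prod(shape)), shape)
  inside <- switch(
    geom$type,
    box = idx[, 1] >= geom$from[1] & idx[, 1] <= geom$to[1] &
          idx[, 2] >= geom$from[2] & idx[, 2] <= geom$to[2] &
          idx[, 3] >= geom$from[3] & idx[, 3] <= geom$to[3],
    sphere = sqrt((idx[, 1] - geom$center[1])^2 +
                  (idx[, 2] - geom$center[2])^2 +
                  (idx[, 3] - geom$center[3])^2) <= geom$radius,
    stop("unknown geometry type: ", geom$type, call. = FALSE)
  )
  array(as.integer(inside), shape)
}

# region-wise truncated normal draw (rejection sampling)
rtruncnorm01 <- function(n, mean, sd, lo = 0.01, hi = 0.5) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(n); need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic multi-echo phantom
#'
#' Realizes a [phantom_spec()] into a 4D multi-echo volume plus masks and
#' ground-truth maps. Deterministic given the spec's seed (identical seed,
#' identical bits).
#'
#' @param spec a [phantom_spec()].
#' @param seq a [grase_sequence()].
#' @return list with `volume4d` (x,y,z,echo), `masks` (list: `wm` = union
#'   of regions, one mask per region label, `lesions`), `truth` (list:
#'   `mwf`, `flip` 3D arrays), `noise_sd`, and the spec.
#' @export
generate_phantom <- function(spec, seq = grase_sequence()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(seq, "grase_sequence"))
  shape <- spec$shape
  nvox <- prod(shape)

  with_rng_seed(spec$seed, {
    region_masks <- lapply(spec$regions, function(r) region_mask(r$geometry, shape))
    names(region_masks) <- vapply(spec$regions, `[[`, character(1), "label")

    assigned <- array(0L, shape)        # region index per voxel; later wins
    for (i in seq_along(region_masks)) {
      ov <- region_masks[[i]] > 0 & assigned > 0
      if (any(ov))
        message(sprintf("generate_phantom: region '%s' overwrites %d voxels",
                        names(region_masks)[i], sum(ov)))
      assigned[region_masks[[i]] > 0] <- i
    }

    truth_mwf <- array(NaN, shape)
    for (i in seq_along(spec$regions)) {
      vox <- which(assigned == i)
      truth_mwf[vox] <- rtruncnorm01(length(vox), spec$regions[[i]]$mwf_mean,
                                     spec$regions[[i]]$mwf_sd)
    }

    lesion_mask <- array(0L, shape)
    for (le in spec$lesions) {
      lm <- region_mask(le$geometry, shape)
      vox <- which(lm > 0 & assigned > 0)   # lesions live inside tissue
      lesion_mask[vox] <- 1L
      mwf_mean <- if (!is.null(le$mwf_mean)) le$mwf_mean else 0.04
      mwf_sd <- if (!is.null(le$mwf_sd)) le$mwf_sd else 0.01
      truth_mwf[vox] <- rtruncnorm01(length(vox), mwf_mean, mwf_sd)
    }

    flip <- spec$flip_field
    flip_map <- if (length(flip) == 1L) array(as.numeric(flip), shape)
                else array(as.numeric(flip), shape)
    csf <- spec$csf_fraction
    csf_map <- if (length(csf) == 1L) array(as.numeric(csf), shape)
               else array(as.numeric(csf), shape)

    tissue <- which(assigned > 0L)
    vol <- array(0, c(shape, seq$n_echoes))
    vol_mat <- matrix(0, nvox, seq$n_echoes)

    # synthesize per unique flip (quantized to 0.05 deg): three pool curves
    # per flip, then a linear mix per voxel
    fq <- round(flip_map[tissue] / 0.05) * 0.05
    for (fu in unique(fq)) {
      vox <- tissue[fq == fu]
      curves <- epg_decay_matrix(spec$pool_t2s, spec$pool_t1s, fu, seq)
      mw <- truth_mwf[vox]; cf <- csf_map[vox]
      ie <- pmax(1 - mw - cf, 0)
      frac <- rbind(mw, ie, cf)            # pools x voxels
      vol_mat[vox, ] <- t(curves %*% frac)
    }

    noise_sd <- 0
    if (is.finite(spec$snr)) {
      noise_sd <- mean(vol_mat[tissue, 1L]) / spec$snr
      nm <- if (is.null(spec$noise_model)) "gaussian" else spec$noise_model
      if (nm == "rician") {
        # magnitude of the complex signal with Gaussian noise per channel
        vol_mat <- sqrt((vol_mat + stats::rnorm(length(vol_mat), 0, noise_sd))^2 +
                        stats::rnorm(length(vol_mat), 0, noise_sd)^2)
      } else {
        vol_mat <- vol_mat + stats::rnorm(length(vol_mat), 0, noise_sd)
      }
    }
    vol[] <- vol_mat

    wm <- array(as.integer(assigned > 0L), shape)
    truth_flip <- array(NaN, shape); truth_flip[tissue] <- flip_map[tissue]

    list(volume4d = vol,
         masks = c(list(wm = wm), region_masks, list(lesions = lesion_mask)),
         truth = list(mwf = truth_mwf, flip = truth_flip),
         noise_sd = noise_sd, spec = spec, seq = seq)
  })
}

#' Cohort specification for the synthetic cohort generator
#'
#' Declares a two-group cohort (patients and controls) with per-ROI MHI
#' values and cognitive scores. Patient scores are linearly coupled to the
#' MHI of a reference ROI: `score = intercept + b * MHI + N(0, sigma_eps)`.
#' When `target_r` is given, the noise SD is solved from
#' `sigma_eps = |b| * sigma_MHI * sqrt(1 / r^2 - 1)`, which makes the
#' population correlation between score and reference-ROI MHI equal to
#' `target_r`. Control scores are drawn independently of MHI. The other
#' ROIs' MHI values correlate with the reference ROI at `roi_cor`.
#'
#' Defaults emulate a 73-patient / 22-control cross-sectional myelin
#' imaging cohort: mean (SD) age 50.2 (10.7) vs 46.4 (13.5) years, 66% vs
#' 64% female, education 14.7 (2.2) vs 15.8 (2.2) years, relapsing /
#' primary-progressive / secondary-progressive phenotypes at 38/12/23, and
#' per-test missingness reflecting completion of 66, 65 and 63 of 73
#' patients for the recall/retrieval/visuospatial tests.
#'
#' @param n_patients,n_controls group sizes (>= 2).
#' @param rois ROI labels; the first is the reference ROI for coupling.
#' @param tests named list: per test, a list with `control_mean`,
#'   `control_sd`, `patient_mean`, `b` (slope, score units per MHI unit)
#'   and `missingness` (probability a subject lacks the score).
#' @param mhi_mean_patient,mhi_sd_patient patient MHI distribution per ROI.
#' @param mhi_mean_control,mhi_sd_control control MHI distribution per ROI.
#' @param target_r population correlation between patient scores and
#'   reference-ROI MHI (`NULL` to use `sigma_eps` directly).
#' @param sigma_eps residual score SD, used when `target_r` is `NULL`.
#' @param roi_cor correlation of non-reference ROI MHI with the reference.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 73L, n_controls = 22L,
                        rois = c("slf", "cc", "cingulum"),
                        tests = list(
                          sdmt  = list(control_mean = 62, control_sd = 10,
                                       patient_mean = 56, b = -60, missingness = 0),
                          srt   = list(control_mean = 62, control_sd = 9,
                                       patient_mean = 55, b = -55, missingness = 0.10),
                          cowat = list(control_mean = 69, control_sd = 11,
                                       patient_mean = 60, b = -60, missingness = 0.11),
                          bvmtr = list(control_mean = 56, control_sd = 9,
                                       patient_mean = 49, b = -50, missingness = 0.14)),
                        mhi_mean_patient = 0.35, mhi_sd_patient = 0.10,
                        mhi_mean_control = 0.25, mhi_sd_control = 0.05,
                        target_r = -0.49, sigma_eps = NULL,
                        roi_cor = 0.8, seed = 1L) {
  if (n_patients < 2L || n_controls < 2L)
    stop("both groups need >= 2 subjects", call. = FALSE)
  if (!is.null(target_r)) {
    if (target_r == 0)
      stop("target_r = 0 cannot be combined with a nonzero slope; set target_r = NULL and b = 0 instead",
           call. = FALSE)
    if (abs(target_r) >= 1) stop("|target_r| must be < 1", call. = FALSE)
  }
  miss <- vapply(tests, function(t) t$missingness, numeric(1))
  if (any(miss < 0 | miss >= 1)) stop("missingness must lie in [0, 1)", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 rois = rois, tests = tests,
                 mhi_mean_patient = mhi_mean_patient,
                 mhi_sd_patient = mhi_sd_patient,
                 mhi_mean_control = mhi_mean_control,
                 mhi_sd_control = mhi_sd_control,
                 target_r = target_r, sigma_eps = sigma_eps,
                 roi_cor = roi_cor, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `subject_id`, `group`, `phenotype`,
#'   `age`, `sex`, `education`, `mhi_<roi>` per ROI, and one score column
#'   per test (NA where missing). Deterministic given the spec's seed.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_rng_seed(spec$seed, {
    np <- spec$n_patients; nc <- spec$n_controls
    n <- np + nc
    group <- c(rep("MS", np), rep("control", nc))
    phenotype <- c(sample(rep(c("RRMS", "PPMS", "SPMS"),
                              times = pmax(round(np * c(38, 12, 23) / 73), 1))[seq_len(np)]),
                   rep(NA_character_, nc))
    age <- c(pmin(pmax(stats::rnorm(np, 50.2, 10.7), 26), 65),
             pmin(pmax(stats::rnorm(nc, 46.4, 13.5), 27), 65))
    sex <- c(ifelse(stats::runif(np) < 0.66, "F", "M"),
             ifelse(stats::runif(nc) < 0.64, "F", "M"))
    education <- c(pmin(pmax(stats::rnorm(np, 14.7, 2.2), 12), 22),
                   pmin(pmax(stats::rnorm(nc, 15.8, 2.2), 12), 22))

    # latent per-subject myelin damage; reference ROI loads on it fully
    z <- stats::rnorm(n)
    mhi <- matrix(NA_real_, n, length(spec$rois),
                  dimnames = list(NULL, paste0("mhi_", spec$rois)))
    for (j in seq_along(spec$rois)) {
      load <- if (j == 1L) 1 else spec$roi_cor
      zj <- load * z + sqrt(1 - load^2) * stats::rnorm(n)
      mhi[, j] <- c(spec$mhi_mean_patient + spec$mhi_sd_patient * zj[seq_len(np)],
                    spec$mhi_mean_control + spec$mhi_sd_control * zj[np + seq_len(nc)])
      mhi[, j] <- pmax(mhi[, j], 0.01)
    }
    ref <- mhi[seq_len(np), 1L]

    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      group = group, phenotype = phenotype, age = age,
                      sex = sex, education = education,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(mhi))

    for (nm in names(spec$tests)) {
      tt <- spec$tests[[nm]]
      b <- tt$b
      sig <- spec$sigma_eps
      if (!is.null(spec$target_r) && b != 0) {
        sig <- abs(b) * spec$mhi_sd_patient * sqrt(1 / spec$target_r^2 - 1)
      } else if (is.null(sig)) {
        sig <- tt$control_sd
      }
      intercept <- tt$patient_mean - b * spec$mhi_mean_patient
      score_p <- intercept + b * ref + stats::rnorm(np, 0, sig)
      score_c <- stats::rnorm(nc, tt$control_mean, tt$control_sd)
      sc <- c(score_p, score_c)
      if (tt$missingness > 0)
        sc[stats::runif(n) < tt$missingness] <- NA_real_
      out[[nm]] <- sc
    }
    out
  })
}

#' Miniature end-to-end fixture
#'
#' A deterministic 16 x 16 x 4 phantom with three tract-named ROIs
#' ("cingulum", "slf", "cc"), one lesion blob overlapping the slf box, and
#' a 20-subject cohort table. Small enough for integration tests and
#' documentation examples; regenerates bit-identically from its fixed seed.
#'
#' @param seed integer seed (fixed default; change only for experiments).
#' @return list with `phantom` (see [generate_phantom()]), `cohort`
#'   (see [generate_cohort()]), `seq` and the two specs.
#' @export
make_toy_fixture <- function(seed = 20170823L) {
  seq <- grase_sequence()
  pspec <- phantom_spec(
    shape = c(16L, 16L, 4L),
    regions = list(
      list(label = "cingulum", geometry = geom_box(c(2, 2, 1), c(15, 6, 4)),
           mwf_mean = 0.13, mwf_sd = 0.02),
      list(label = "slf", geometry = geom_box(c(2, 7, 1), c(15, 11, 4)),
           mwf_mean = 0.10, mwf_sd = 0.02),
      list(label = "cc", geometry = geom_box(c(2, 12, 1), c(15, 15, 4)),
           mwf_mean = 0.16, mwf_sd = 0.02)
    ),
    lesions = list(list(geometry = geom_sphere(c(8, 9, 2), 1.6),
                        mwf_mean = 0.04, mwf_sd = 0.005)),
    flip_field = 165, snr = 300, seed = seed
  )
  cspec <- cohort_spec(n_patients = 14L, n_controls = 6L,
                       rois = c("slf", "cc", "cingulum"), seed = seed + 1L)
  list(phantom = generate_phantom(pspec, seq),
       cohort = generate_cohort(cspec),
       seq = seq, phantom_spec = pspec, cohort_spec = cspec)
}
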