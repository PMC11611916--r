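#' Generate a complete synthetic aging study on disk
#'
#' Writes a full study tree emulating a multi-sample accelerated-aging
#' experiment: for each storage temperature and acquisition cycle one
#' nitrogen reference waveform, and for each (temperature, replicate,
#' timepoint) one tablet transmission waveform whose absorption follows the
#' sequential amorphous -> beta -> alpha kinetics. Tablet thickness is drawn
#' once per tablet, uniformly from `thickness_range_mm`, and stored in the
#' scan metadata; the sample's refractive index is the fraction-weighted mix
#' of the per-form constants. Three pure-form calibration scans (amorphous,
#' beta, alpha; sample ids `calib_*`) are written alongside the study so the
#' reference-model fitting stage has pure spectra to work from, mirroring
#' the practice of measuring pure-form tablets before an aging run.
#'
#' A `manifest.tsv` indexes every file together with the ground-truth phase
#' fractions, which downstream tests use as the oracle.
#'
#' The default protocol (144 h at 3.5-min cadence, 3 temperatures x 5
#' replicates) produces a large tree; scale `duration_h`/`cadence_min` down
#' for examples and tests.
#'
#' @param kinetics A [kinetics_params()].
#' @param ref_alpha,ref_beta Pure-form [reference_model()]s driving the
#'   crystalline signatures.
#' @param pulse A [pulse_params()].
#' @param out_dir Output directory; must be empty unless `overwrite = TRUE`.
#' @param seed Integer seed; identical `(configuration, seed)` yields a
#'   byte-identical study tree.
#' @param overwrite Allow writing into a non-empty directory.
#' @param background_amorphous,background_crystalline Quadratic background
#'   levels passed to [compose_absorption()].
#' @param n_amorphous,n_beta,n_alpha Per-form refractive indices (constant
#'   in frequency; dispersion is not modeled).
#' @param thickness_range_mm Uniform range tablet thicknesses are drawn from.
#' @return The manifest as a tibble, invisibly.
#' @export
generate_study <- function(kinetics = kinetics_params(),
                           ref_alpha = nif_reference_alpha(),
                           ref_beta = nif_reference_beta(),
                           pulse = pulse_params(),
                           out_dir, seed = 1L, overwrite = FALSE,
                           background_amorphous = c(0.5, 2, 3),
                           background_crystalline = 0.5 * background_amorphous,
                           n_amorphous = 1.6, n_beta = 1.7, n_alpha = 1.8,
                           thickness_range_mm = c(1.1, 1.6)) {
  stopifnot(inherits(kinetics, "kinetics_params"), inherits(pulse, "pulse_params"))
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = TRUE, no.. = TRUE)) > 0) {
    if (!overwrite) {
      abort(sprintf("output directory %s is not empty; pass overwrite = TRUE to reuse it.", out_dir))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  times_h <- seq(0, kinetics$duration_h, by = kinetics$cadence_min / 60)
  temps <- sort(kinetics$temperatures_C)
  noise_sd <- pulse$noise_std_au / sqrt(pulse$n_averages)
  t_axis <- pulse_time_axis(pulse)
  base_field <- pulse_field(pulse, t_axis)
  m <- length(t_axis)

  add_noise <- function(field) {
    if (noise_sd > 0) field + rnorm(m, sd = noise_sd) else field
  }
  # one absorption model per (temperature, timepoint) is recomputed per
  # sample only through cheap vector arithmetic; the FFT dominates anyway
  synth_sample <- function(fracs, d_mm) {
    n_mix <- fracs$x_amorphous * n_amorphous + fracs$x_beta * n_beta +
      fracs$x_alpha * n_alpha
    a_tab <- function(f) {
      cryst <- fracs$x_beta + fracs$x_alpha
      bg <- (1 - cryst) * background_amorphous + cryst * background_crystalline
      fracs$x_alpha * peak_sum(ref_alpha, f) + fracs$x_beta * peak_sum(ref_beta, f) +
        quad_eval(bg, f)
    }
    apply_slab(base_field, pulse$dt_ps, function(f) rep(n_mix, length(f)), a_tab, d_mm)
  }

  rows <- list()
  set.seed(seed)

  # calibration scans: one reference plus pure amorphous/beta/alpha tablets
  calib_dir <- file.path(out_dir, "calib")
  dir.create(calib_dir, showWarnings = FALSE)
  calib_ref <- waveform(t_axis, add_noise(base_field),
                        scan_meta(sample_id = "calib_ref", role = "reference",
                                  time_h = 0, n_averages = pulse$n_averages))
  write_waveform(calib_ref, file.path(calib_dir, "reference.txt"))
  rows[[length(rows) + 1]] <- tibble(
    file = "calib/reference.txt", role = "reference", sample_id = "calib_ref",
    temperature_C = NA_real_, replicate = NA_integer_, time_h = 0,
    thickness_mm = NA_real_, x_amorphous = NA_real_, x_beta = NA_real_,
    x_alpha = NA_real_, seed = seed)
  calib_forms <- list(
    calib_amorphous = list(x_amorphous = 1, x_beta = 0, x_alpha = 0),
    calib_beta = list(x_amorphous = 0, x_beta = 1, x_alpha = 0),
    calib_alpha = list(x_amorphous = 0, x_beta = 0, x_alpha = 1))
  for (nm in names(calib_forms)) {
    d_mm <- runif(1, thickness_range_mm[1], thickness_range_mm[2])
    wf <- waveform(t_axis, add_noise(synth_sample(calib_forms[[nm]], d_mm)),
                   scan_meta(sample_id = nm, thickness_mm = d_mm, time_h = 0,
                             n_averages = pulse$n_averages))
    rel <- file.path("calib", paste0(nm, ".txt"))
    write_waveform(wf, file.path(out_dir, rel))
    fr <- calib_forms[[nm]]
    rows[[length(rows) + 1]] <- tibble(
      file = rel, role = "sample", sample_id = nm, temperature_C = NA_real_,
      replicate = NA_integer_, time_h = 0, thickness_mm = d_mm,
      x_amorphous = fr$x_amorphous, x_beta = fr$x_beta, x_alpha = fr$x_alpha,
      seed = seed)
  }

  for (temp in temps) {
    fr_traj <- simulate_kinetics(kinetics, temp, times_h)
    tdir <- sprintf("T%04.1fC", temp)
    dir.create(file.path(out_dir, tdir), showWarnings = FALSE)
    thick <- runif(kinetics$n_replicates, thickness_range_mm[1], thickness_range_mm[2])
    for (rep_i in seq_len(kinetics$n_replicates)) {
      dir.create(file.path(out_dir, tdir, sprintf("rep%02d", rep_i)), showWarnings = FALSE)
    }
    for (ti in seq_along(times_h)) {
      t_h <- times_h[ti]
      # one nitrogen reference per acquisition cycle, shared by all samples
      ref_rel <- file.path(tdir, sprintf("ref_%05d.txt", ti - 1L))
      ref_wf <- waveform(t_axis, add_noise(base_field),
                         scan_meta(sample_id = sprintf("ref_%s", tdir),
                                   role = "reference", temperature_C = temp,
                                   time_h = t_h, n_averages = pulse$n_averages))
      write_waveform(ref_wf, file.path(out_dir, ref_rel))
      rows[[length(rows) + 1]] <- tibble(
        file = ref_rel, role = "reference", sample_id = sprintf("ref_%s", tdir),
        temperature_C = temp, replicate = NA_integer_, time_h = t_h,
        thickness_mm = NA_real_, x_amorphous = NA_real_, x_beta = NA_real_,
        x_alpha = NA_real_, seed = seed)
      fr <- fr_traj[ti, ]
      for (rep_i in seq_len(kinetics$n_replicates)) {
        sid <- sprintf("%s_rep%02d", tdir, rep_i)
        rel <- file.path(tdir, sprintf("rep%02d", rep_i), sprintf("scan_%05d.txt", ti - 1L))
        wf <- waveform(
          t_axis, add_noise(synth_sample(fr, thick[rep_i])),
          scan_meta(sample_id = sid, thickness_mm = thick[rep_i],
                    temperature_C = temp, time_h = t_h,
                    n_averages = pulse$n_averages))
        write_waveform(wf, file.path(out_dir, rel))
        rows[[length(rows) + 1]] <- tibble(
          file = rel, role = "sample", sample_id = sid, temperature_C = temp,
          replicate = rep_i, time_h = t_h, thickness_mm = thick[rep_i],
          x_amorphous = fr$x_amorphous, x_beta = fr$x_beta,
          x_alpha = fr$x_alpha, seed = seed)
      }
    }
  }

  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
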