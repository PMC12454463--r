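#' Pipeline configuration
#'
#' One configuration object with per-stage blocks drives the whole analysis;
#' every default is echoed into the run log so each processing choice is
#' auditable. Input is either a [phantom_spec()] to simulate or a directory
#' containing a `manifest.csv` written by [simulate_repeatability_study()].
#'
#' @param input a [phantom_spec()] or a manifest directory path.
#' @param preprocess list: `enabled`, `window` (MP-PCA), `neighborhood`,
#'   `n_shifts` (Gibbs).
#' @param dti list: `shells` for the perfusion-suppressed tensor fit,
#'   `n_passes`.
#' @param msdki list: `shells` (three required), `n_passes`.
#' @param adc list: `b_low`, `b_high`, `direction_index`.
#' @param qc a [plausibility_rules()].
#' @param readers list: `simulate_second` — derive a second, conservative
#'   reader ROI by one-voxel in-plane erosion, so inter-reader ICC can be
#'   computed on phantom data; supply your own label maps for real data.
#' @param output_dir optional directory for CSV/JSON outputs and maps.
#' @param write_maps write per-acquisition scalar maps as NIfTI.
#' @param overwrite allow writing into a non-empty output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = phantom_spec(),
                            preprocess = list(enabled = TRUE,
                                              window = c(5L, 5L, 3L),
                                              neighborhood = 3L,
                                              n_shifts = 20L),
                            dti = list(shells = c(200, 1000), n_passes = 2L),
                            msdki = list(shells = c(200, 1000, 1700),
                                         n_passes = 2L),
                            adc = list(b_low = 200, b_high = 1000,
                                       direction_index = 1L),
                            qc = plausibility_rules(),
                            readers = list(simulate_second = TRUE),
                            output_dir = NULL, write_maps = FALSE,
                            overwrite = FALSE) {
  if (length(msdki$shells) < 3L) {
    stop("validation error: mean-signal DKI requires 3 shells")
  }
  structure(list(input = input, preprocess = preprocess, dti = dti,
                 msdki = msdki, adc = adc, qc = qc, readers = readers,
                 output_dir = output_dir, write_maps = write_maps,
                 overwrite = overwrite),
            class = "pipeline_config")
}

#' Fit all scalar maps for one acquisition
#'
#' The per-acquisition core of the pipeline: optional preprocessing
#' (MP-PCA denoising then Gibbs unringing), weighted-least-squares tensor
#' fit on the perfusion-suppressed shells, mean-signal DKI on the
#' directional averages of the three kurtosis shells, and the two-point
#' first-direction ADC.
#'
#' @param dataset a [dwi_dataset()].
#' @param config a [pipeline_config()].
#' @return list: `maps` (a [scalar_maps()] with md, ad, rd, fa, mk, adc,
#'   s0_msdki), `tensor` (the `tensor_field`), `noise` (noise_map or NULL).
#' @export
fit_acquisition <- function(dataset, config = pipeline_config()) {
  noise <- NULL
  if (isTRUE(config$preprocess$enabled)) {
    den <- mppca_denoise(dataset, window = config$preprocess$window)
    noise <- den$noise
    dataset <- gibbs_unring(den$dataset,
                            neighborhood = config$preprocess$neighborhood,
                            n_shifts = config$preprocess$n_shifts)
  }
  dti_ds <- select_shells(dataset, config$dti$shells)
  tf <- fit_dti_wls(dti_ds, n_passes = config$dti$n_passes)
  dti_maps <- compute_dti_maps(tf)
  dki_ds <- select_shells(dataset, config$msdki$shells)
  avg <- directional_average(dki_ds)
  kur <- fit_msdki(avg, n_passes = config$msdki$n_passes)
  adc <- compute_adc(dataset, b_low = config$adc$b_low,
                     b_high = config$adc$b_high,
                     direction_index = config$adc$direction_index)
  maps <- scalar_maps(md = dti_maps$md, ad = dti_maps$ad, rd = dti_maps$rd,
                      fa = dti_maps$fa, mk = kur$mk, adc = adc,
                      s0_msdki = kur$s0_msdki)
  list(maps = maps, tensor = tf, noise = noise)
}

# one-voxel in-plane erosion of a label (4-neighbourhood), used to derive a
# conservative second-reader ROI variant on phantom data
#' @keywords internal
erode_roi <- function(roi, label = 1L) {
  lab <- roi$labels
  out <- lab
  d <- dim(lab)
  for (z in seq_len(d[3])) {
    sl <- lab[, , z] == label
    if (!any(sl)) next
    shr <- sl
    shr[-1, ] <- shr[-1, ] & sl[-d[1], ]
    shr[-d[1], ] <- shr[-d[1], ] & sl[-1, ]
    shr[, -1] <- shr[, -1] & sl[, -d[2]]
    shr[, -d[2]] <- shr[, -d[2]] & sl[, -1]
    slo <- out[, , z]
    slo[sl & !shr] <- 0L
    out[, , z] <- slo
  }
  roi_label_map(out)
}

#' Run the full study workflow
#'
#' Per subject and repeat: preprocessing, tensor fit (b = 200/1000),
#' mean-signal DKI (b = 200/1000/1700), ADC, plausibility masking and ROI
#' statistics; then cohort summaries (repeats averaged per subject),
#' Bland-Altman repeatability with the RMS coefficient of repeatability per
#' metric, and inter-reader ICC across ROI variants. Deterministic given the
#' spec seed.
#'
#' @param config a [pipeline_config()].
#' @return list of data.frames: `roi_stats` (long form), `cohort`,
#'   `repeatability`, `agreement`, plus `log` (the resolved parameters).
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  acqs <- load_acquisitions(config)
  metrics <- c("md", "ad", "rd", "fa", "mk", "adc")
  rows <- list()
  for (acq in acqs) {
    fit <- fit_acquisition(acq$dataset, config)
    masks <- plausibility_mask(fit$maps, config$qc)
    rois <- list(reader1 = acq$roi)
    if (isTRUE(config$readers$simulate_second)) {
      rois$reader2 <- erode_roi(acq$roi)
    }
    for (rd_name in names(rois)) {
      for (m in metrics) {
        st <- roi_statistics(fit$maps[[m]], rois[[rd_name]], label = 1L,
                             mask = masks[[m]], map_name = m)
        st$subject <- acq$subject
        st$repeat_idx <- acq$repeat_idx
        st$protocol <- acq$protocol
        st$reader <- rd_name
        rows[[length(rows) + 1L]] <- st
      }
    }
    if (config$write_maps && !is.null(config$output_dir)) {
      for (m in metrics) {
        write_scalar_map(fit$maps[[m]], acq$dataset$voxel_size,
                         file.path(config$output_dir,
                                   sprintf("sub-%02d_rep-%d_%s.nii.gz",
                                           acq$subject, acq$repeat_idx, m)))
      }
    }
  }
  roi_stats <- do.call(rbind, rows)

  first_reader <- roi_stats[roi_stats$reader == "reader1", ]
  cohort_in <- data.frame(subject = first_reader$subject,
                          metric = first_reader$map_name,
                          value = first_reader$median,
                          protocol = first_reader$protocol)
  cohort <- summarize_cohort(cohort_in)

  rep_rows <- list()
  for (m in metrics) {
    d <- first_reader[first_reader$map_name == m, ]
    w <- stats::reshape(d[, c("subject", "repeat_idx", "median")],
                        direction = "wide", idvar = "subject",
                        timevar = "repeat_idx")
    if (ncol(w) >= 3 && sum(stats::complete.cases(w)) >= 2) {
      cc <- w[stats::complete.cases(w), ]
      ba <- bland_altman(cc[[2]], cc[[3]])
      rep_rows[[m]] <- data.frame(metric = m, n = ba$n,
                                  mean_diff = ba$mean_diff,
                                  loa_low = ba$loa_low, loa_high = ba$loa_high,
                                  r = ba$r,
                                  proportional_bias_slope = ba$proportional_bias_slope)
    }
  }
  repeatability <- do.call(rbind, rep_rows)
  rownames(repeatability) <- NULL

  agreement <- NULL
  if (length(unique(roi_stats$reader)) >= 2) {
    agr_rows <- list()
    for (m in metrics) {
      d <- roi_stats[roi_stats$map_name == m, ]
      per <- stats::aggregate(median ~ subject + reader, data = d, FUN = mean)
      w <- stats::reshape(per, direction = "wide", idvar = "subject",
                          timevar = "reader")
      cc <- w[stats::complete.cases(w), -1, drop = FALSE]
      if (nrow(cc) >= 3) {
        res <- icc_absolute_agreement(cc)
        agr_rows[[m]] <- data.frame(metric = m, icc = res$icc,
                                    icc_band = res$icc_band)
      }
    }
    agreement <- do.call(rbind, agr_rows)
    rownames(agreement) <- NULL
  }

  log <- pipeline_log(config)
  out <- list(roi_stats = roi_stats, cohort = cohort,
              repeatability = repeatability, agreement = agreement,
              log = log)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config)
  out
}

#' @keywords internal
load_acquisitions <- function(config) {
  input <- config$input
  acqs <- list()
  if (inherits(input, "phantom_spec")) {
    for (s in seq_len(input$n_subjects)) {
      for (r in seq_len(input$n_repeats)) {
        sim <- simulate_dataset(input, subject = s, repeat_idx = r)
        acqs[[length(acqs) + 1L]] <- list(dataset = sim$dataset,
                                          roi = sim$roi, truth = sim$truth,
                                          subject = s, repeat_idx = r,
                                          protocol = input$protocol)
      }
    }
  } else if (is.character(input) && dir.exists(input)) {
    man <- utils::read.csv(file.path(input, "manifest.csv"))
    for (i in seq_len(nrow(man))) {
      ds <- read_dwi(file.path(input, man$dwi[i]),
                     file.path(input, man$bval[i]),
                     file.path(input, man$bvec[i]))
      roi <- roi_label_map(read_scalar_map(file.path(input, man$roi[i])))
      acqs[[length(acqs) + 1L]] <- list(dataset = ds, roi = roi, truth = NULL,
                                        subject = man$subject[i],
                                        repeat_idx = man$repeat_idx[i],
                                        protocol = man$protocol[i])
    }
  } else {
    stop("fail fast at stage 'input': need a phantom_spec or a manifest directory")
  }
  acqs
}

#' @keywords internal
pipeline_log <- function(config) {
  input_desc <- if (inherits(config$input, "phantom_spec")) {
    unclass(config$input)[c("grid", "protocol", "snr", "seed",
                            "n_subjects", "n_repeats")]
  } else list(dir = config$input)
  list(input = input_desc,
       preprocess = config$preprocess,
       dti = config$dti, msdki = config$msdki, adc = config$adc,
       qc = unclass(config$qc), readers = config$readers)
}

#' @keywords internal
write_pipeline_outputs <- function(out, config) {
  od <- config$output_dir
  if (dir.exists(od) && length(list.files(od, pattern = "\\.csv$")) > 0 &&
      !config$overwrite) {
    stop(sprintf("refusing to write into non-empty %s (set overwrite = TRUE)", od))
  }
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(add_units(out$roi_stats), file.path(od, "roi_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(add_units(out$cohort), file.path(od, "cohort.csv"),
                   row.names = FALSE)
  if (!is.null(out$repeatability)) {
    utils::write.csv(add_units(out$repeatability),
                     file.path(od, "repeatability.csv"), row.names = FALSE)
  }
  if (!is.null(out$agreement)) {
    utils::write.csv(out$agreement, file.path(od, "agreement.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(out$log, file.path(od, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(od)
}

# attach an explicit units column (diffusivities reported as x1e-3 mm^2/s)
#' @keywords internal
add_units <- function(df) {
  mcol <- intersect(c("metric", "map_name"), names(df))[1]
  if (is.na(mcol)) return(df)
  df$units <- ifelse(df[[mcol]] %in% c("md", "ad", "rd", "adc"),
                     "mm^2/s (report x1e-3)", "dimensionless")
  df
}
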