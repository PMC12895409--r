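# Run configuration, record persistence and the end-to-end pipeline:
# sample -> (FP: excite + propagate per pulse | AXE/SXE: propagate once,
# repropagate per pulse) -> balance -> observables, with a manifest capturing
# seeds, trajectory counts and file hashes so a rerun is verifiably identical.

#' Read a run configuration
#'
#' YAML with sections `model` (see [read_model_config()]; inline, or
#' `preset: glycine_like`), `wigner` (`n_geometries`, `seed`, optionally
#' `frequencies` when the model does not imply them), `pulse` (one) or
#' `pulses` (a list), `propagation` (`dt_fs = 0.3`, `n_substeps = 51`,
#' `t_final_fs = 14.1`, `energy_tolerance_eV = 0.5`), `decoherence`
#' (`scheme`, `omega_pfm`, `eta`, `edc_C`) and `ensemble` (`scheme` in
#' fp/axe/sxe, optional `windows` boundaries in eV, `base_seed`).
#'
#' @param path YAML file.
#' @return a `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$propagation <- utils::modifyList(
    list(dt_fs = 0.3, n_substeps = 51L, t_final_fs = 14.1,
         energy_tolerance_eV = 0.5), as.list(cfg$propagation))
  cfg$decoherence <- utils::modifyList(
    list(scheme = "PFM", omega_pfm = 4.825e-3, eta = 1e-4, edc_C = 0.1),
    as.list(cfg$decoherence))
  cfg$wigner <- utils::modifyList(list(n_geometries = 100L, seed = 1L),
                                  as.list(cfg$wigner))
  cfg$ensemble <- utils::modifyList(
    list(scheme = "fp", windows = numeric(0), base_seed = 1L),
    as.list(cfg$ensemble))
  if (is.null(cfg$pulses)) cfg$pulses <- list(cfg$pulse)
  if (is.null(cfg$pulses[[1]])) stop("config must define a pulse")
  structure(cfg, class = "run_config")
}

config_model <- function(cfg) {
  if (!is.null(cfg$model$preset) && cfg$model$preset == "glycine_like")
    return(glycine_like_model())
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg$model, f)
  m <- read_model_config(f)
  freqs <- if (!is.null(cfg$wigner$frequencies)) as.numeric(cfg$wigner$frequencies)
           else if (!is.null(m$params$frequencies)) m$params$frequencies
           else stop("wigner frequencies needed: model does not imply them")
  list(model = m, reference = harmonic_reference(freqs))
}

config_pulse <- function(p) {
  gaussian_pulse(omega_L_eV = p$omega_L_eV, delta_omega_eV = p$delta_omega_eV,
                 polarization = if (is.null(p$polarization)) c(0, 0, 1)
                                else as.numeric(p$polarization),
                 amplitude = if (is.null(p$amplitude)) 1 else p$amplitude)
}

#' Persist and reload trajectory records
#'
#' Each record is written as an uncompressed RDS file (bit-exact round trip)
#' next to a JSON sidecar with its validity, seed, model hash and schema
#' version; a `manifest.json` carries the set-level metadata and per-file md5
#' hashes.
#'
#' @param records list of `trajectory_record`.
#' @param dir target directory (created if needed).
#' @return `write_records` returns `dir`; `read_records` the list of records.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(records))
  for (i in seq_along(records)) {
    f <- file.path(dir, sprintf("traj_%05d.rds", i))
    saveRDS(records[[i]], f, compress = FALSE)
    jsonlite::write_json(
      list(index = i, valid = records[[i]]$valid,
           invalid_reason = records[[i]]$invalid_reason,
           seed = records[[i]]$seed, model_id = records[[i]]$model_id,
           schema_version = records[[i]]$schema_version,
           n_done = records[[i]]$n_done,
           n_hops = sum(records[[i]]$hops$accepted)),
      file.path(dir, sprintf("traj_%05d.json", i)), auto_unbox = TRUE)
    files[i] <- f
  }
  jsonlite::write_json(
    list(schema_version = RECORD_SCHEMA_VERSION, n_records = length(records),
         model_id = records[[1]]$model_id,
         md5 = as.list(setNames(unname(tools::md5sum(files)), basename(files)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_records
#' @export
read_records <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  if (manifest$schema_version != RECORD_SCHEMA_VERSION)
    stop("record store schema version ", manifest$schema_version,
         " does not match this package's version ", RECORD_SCHEMA_VERSION)
  files <- file.path(dir, sprintf("traj_%05d.rds", seq_len(manifest$n_records)))
  lapply(files, function(f) {
    tryCatch(readRDS(f),
             error = function(e) stop("corrupt or truncated record file ", f,
                                      ": ", conditionMessage(e), call. = FALSE))
  })
}

write_series_csv <- function(series, path) {
  df <- data.frame(t_fs = series$t_fs, series$populations,
                   check.names = FALSE)
  ch <- as.data.frame(series$coherences)
  names(ch) <- paste0("coh_", colnames(series$coherences))
  dp <- as.data.frame(series$dipole)
  names(dp) <- paste0("dip_", c("x", "y", "z"))
  utils::write.csv(cbind(df, ch, dp), path, row.names = FALSE)
  path
}

#' Run the full simulation pipeline from a configuration
#'
#' Samples the Wigner distribution, builds the requested ensemble, propagates
#' its trajectories (once, for AXE/SXE, regardless of how many pulses are
#' given; once per pulse for FP, whose trajectories depend on the pulse),
#' discards and balances energy-non-conserving trajectories, computes the
#' standard observables for every pulse, and writes all artifacts plus a
#' manifest with seeds, counts and hashes to `out_dir`.
#'
#' @param cfg a `run_config` (or path to one).
#' @param out_dir artifact directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "model"
  manifest <- list(propagation_passes = 0L, repropagation_passes = 0L)
  result <- tryCatch({
    mm <- config_model(cfg)
    model <- mm$model
    pcfg <- do.call(propagator_config, cfg$propagation)
    dcfg <- do.call(decoherence_config, cfg$decoherence)
    pulses <- lapply(cfg$pulses, config_pulse)

    stage <- "sample"
    samples <- sample_wigner(mm$reference, cfg$wigner$n_geometries,
                             cfg$wigner$seed)
    write_samples(samples, file.path(out_dir, "samples.tsv"))

    scheme <- toupper(cfg$ensemble$scheme)
    base_seed <- cfg$ensemble$base_seed
    counts <- list()
    if (scheme == "FP") {
      for (ip in seq_along(pulses)) {
        stage <- sprintf("excite+propagate (pulse %d)", ip)
        spec <- build_fp(samples, model, pulses[[ip]], seed = base_seed)
        recs <- propagate_ensemble(spec, model, pcfg, dcfg, base_seed)
        manifest$propagation_passes <- manifest$propagation_passes + 1L
        valid <- vapply(recs, function(r) r$valid, TRUE)
        bspec <- balance_ensemble(spec, valid, seed = base_seed)
        brecs <- recs[bspec$kept]
        counts[[ip]] <- list(pulse = ip, initially_run = length(recs),
                             valid = sum(valid), balanced = length(brecs))
        rdir <- file.path(out_dir, sprintf("records_pulse%d", ip))
        write_records(recs, rdir)
        stage <- sprintf("observe (pulse %d)", ip)
        ser <- standard_series(brecs, bspec$members$weight)
        write_series_csv(ser, file.path(out_dir,
                                        sprintf("observables_fp_pulse%d.csv", ip)))
      }
    } else {
      stage <- "ensemble build"
      spec <- if (scheme == "AXE") build_axe(samples, model$n_states)
              else build_sxe(samples, model,
                             windows = as.numeric(cfg$ensemble$windows),
                             seed = base_seed)
      stage <- "propagate"
      recs <- propagate_ensemble(spec, model, pcfg, dcfg, base_seed)
      manifest$propagation_passes <- 1L
      valid <- vapply(recs, function(r) r$valid, TRUE)
      bspec <- balance_ensemble(spec, valid, seed = base_seed)
      brecs <- recs[bspec$kept]
      write_records(recs, file.path(out_dir, "records"))
      for (ip in seq_along(pulses)) {
        stage <- sprintf("repropagate (pulse %d)", ip)
        rp <- repropagate_ensemble(bspec, brecs, pulses[[ip]], model, dcfg)
        manifest$repropagation_passes <- manifest$repropagation_passes + 1L
        counts[[ip]] <- list(pulse = ip, initially_run = length(recs),
                             valid = sum(valid), balanced = length(brecs))
        stage <- sprintf("observe (pulse %d)", ip)
        ser <- standard_series(rp$runs, rp$spec$members$weight, records = brecs)
        write_series_csv(ser, file.path(
          out_dir, sprintf("observables_rp_%s_pulse%d.csv", tolower(scheme), ip)))
      }
    }
    manifest$scheme <- scheme
    manifest$counts <- counts
    manifest$seeds <- list(wigner = cfg$wigner$seed, base = base_seed)
    manifest$model_id <- model$id
    arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    arts <- arts[!grepl("manifest\\.json$", arts)]
    manifest$hashes <- as.list(setNames(unname(tools::md5sum(arts)),
                                        sub(paste0(out_dir, "/?"), "", arts)))
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(result, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(result)
}
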