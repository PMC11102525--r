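#' Read and write image volumes
#'
#' NIfTI (\code{.nii} / \code{.nii.gz}) volumes round-trip losslessly
#' with voxel spacing in the header.  Multi-page TIFF (\code{.tif} /
#' \code{.tiff}) stores 32-bit samples normalised to [0, 1]; the affine
#' range and the voxel spacing are kept in a JSON sidecar
#' (\code{<path>.json}) and restored on read, so values round-trip to
#' 32-bit float precision.
#'
#' @param path file path; the extension selects the format.
#' @param volume numeric matrix or 3D array.
#' @param spacing_mm voxel spacing in mm (scalar or per-axis).
#' @return \code{read_volume}: list with \code{data} (array) and
#'   \code{spacing_mm}.  \code{write_volume}: \code{path}, invisibly.
#' @export
write_volume <- function(volume, path, spacing_mm = 0.075) {
  ext <- volume_format(path)
  spacing <- rep_len(spacing_mm, max(length(dim(volume)), 2))
  if (ext == "nifti") {
    img <- RNifti::asNifti(volume)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else {
    rng <- range(volume)
    den <- if (diff(rng) > 0) diff(rng) else 1
    pages <- if (length(dim(volume)) == 3)
      lapply(seq_len(dim(volume)[3]),
             function(k) (volume[, , k] - rng[1]) / den)
    else list((volume - rng[1]) / den)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
    jsonlite::write_json(list(min = rng[1], max = rng[2],
                              spacing_mm = spacing),
                         paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e)
      stop("cannot read NIfTI '", path, "': ", conditionMessage(e),
           call. = FALSE))
    d <- dim(img)
    list(data = array(as.numeric(img), dim = d),
         spacing_mm = RNifti::pixdim(img))
  } else {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e)
                        stop("cannot read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    arr <- if (length(pages) > 1)
      array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    else pages[[1]]
    sidecar <- paste0(path, ".json")
    spacing <- NA_real_
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      arr <- arr * (meta$max - meta$min) + meta$min
      spacing <- meta$spacing_mm
    }
    list(data = arr, spacing_mm = spacing)
  }
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.tiff?$", low)) return("tiff")
  stop("unknown volume format (expect .nii, .nii.gz, .tif or .tiff): ",
       path, call. = FALSE)
}

#' Read and validate a pipeline run configuration
#'
#' A run configuration is a YAML file (or list) with blocks:
#' \code{plan} (scan-plan fields), \code{filter} (\code{we}),
#' \code{phantom} (\code{kind}, \code{shape}, geometry \code{params}),
#' \code{noise} (\code{sigma}), \code{unmix} (\code{n_rates},
#' \code{b_max}, \code{sentinel}), plus a top-level integer \code{seed}
#' and \code{out_dir}.  Unknown keys are rejected.
#'
#' @param config path to a YAML file, or an equivalent list.
#' @return validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("plan", "filter", "phantom", "noise", "unmix", "seed",
             "out_dir", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- list(
    plan = list(n_angles = 32, n_cycles = 8, translation_range_mm = 9.6,
                translation_step_mm = 0.6, order_mode = "jumping"),
    filter = list(we = default_we()),
    phantom = list(kind = "tube", shape = c(64, 64), params = list()),
    noise = list(sigma = 0),
    unmix = list(n_rates = 12, b_max = 0.09, sentinel = 1e-4),
    seed = 1L, out_dir = "pattern_out", log_level = "info")
  for (blk in c("plan", "filter", "phantom", "noise", "unmix")) {
    cfgblk <- config[[blk]]
    if (!is.null(cfgblk)) {
      bad <- setdiff(names(cfgblk), names(defaults[[blk]]))
      if (length(bad))
        stop("unknown config keys in '", blk, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[[blk]] <- utils::modifyList(defaults[[blk]],
                                         cfgblk %||% list())
  }
  for (k in c("seed", "out_dir", "log_level"))
    if (!is.null(config[[k]])) defaults[[k]] <- config[[k]]
  defaults
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate-fuse-unmix pipeline
#'
#' Executes the full synthetic pipeline: build the scan plan, generate
#' the phantom, simulate the tomogram stream, fuse it with a sliding
#' window, unmix voxelwise, and write the parameter maps plus a manifest.
#' Every output is a new file; inputs are never mutated.  Outputs are
#' deterministic given the config seed (per-stage seeds derive from it).
#'
#' @param config a config list or YAML path, see [read_run_config()].
#' @return invisibly, a list with the \code{manifest} (data.frame of
#'   \code{stage}, \code{file}, \code{md5}), the output directory, and
#'   the in-memory \code{unmix} result.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_info <- function(...) if (cfg$log_level != "quiet")
    message("[patternrecon] ", ...)
  files <- list()
  add <- function(stage, path) files[[length(files) + 1]] <<-
    data.frame(stage = stage, file = basename(path),
               md5 = unname(tools::md5sum(path)))

  log_info("plan: ", cfg$plan$n_angles, " angles x ", cfg$plan$n_cycles,
           " cycles, ", cfg$plan$order_mode, " order")
  plan <- scan_plan(cfg$plan$n_angles, cfg$plan$n_cycles,
                    cfg$plan$translation_range_mm,
                    cfg$plan$translation_step_mm, cfg$plan$order_mode)
  write_scan_plan(plan, file.path(out, "plan.yaml"))
  add("plan", file.path(out, "plan.yaml"))

  log_info("simulate: '", cfg$phantom$kind, "' phantom ",
           paste(cfg$phantom$shape, collapse = "x"))
  phantom <- make_phantom(cfg$phantom$kind,
                          shape = unlist(cfg$phantom$shape),
                          params = cfg$phantom$params,
                          seed = cfg$seed)
  for (m in c("a", "b", "c")) {
    p <- file.path(out, paste0("phantom_", m, ".nii.gz"))
    write_volume(phantom[[m]], p, phantom$spacing_mm)
    add("simulate", p)
  }
  stream <- simulate_acquisition(phantom, plan, cfg$filter$we,
                                 noise_sigma = cfg$noise$sigma,
                                 seed = cfg$seed * 1000L)

  log_info("fuse: sliding window over ", length(stream), " tomograms")
  fused <- sliding_fuse(stream, plan, cfg$filter$we)
  p <- file.path(out, "fused_series.nii.gz")
  write_volume(as_series_array(fused), p, phantom$spacing_mm)
  add("fuse", p)
  fused_manifest <- data.frame(volume = seq_along(fused$images) - 1L,
                               timestamp = fused$timestamps)
  pm <- file.path(out, "fused_manifest.csv")
  utils::write.csv(fused_manifest, pm, row.names = FALSE)
  add("fuse", pm)

  log_info("unmix: ", cfg$unmix$n_rates, " candidate rates")
  grid <- build_rate_grid(cfg$unmix$b_max, cfg$unmix$n_rates,
                          cfg$unmix$sentinel)
  um <- unmix_volume(fused, grid = grid)
  for (m in c("a", "b", "c", "confidence")) {
    p <- file.path(out, paste0("unmixed_", m, ".nii.gz"))
    write_volume(um[[m]], p, phantom$spacing_mm)
    add("unmix", p)
  }

  sidecar <- list(rates = grid$rates, we = cfg$filter$we,
                  noise_sigma = cfg$noise$sigma, seed = cfg$seed)
  jsonlite::write_json(sidecar, file.path(out, "unmix_params.json"),
                       auto_unbox = TRUE, digits = NA)
  add("unmix", file.path(out, "unmix_params.json"))

  manifest <- do.call(rbind, files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", digits = NA)
  log_info("done: ", nrow(manifest), " artifacts in ", out)
  invisible(list(manifest = manifest, out_dir = out, unmix = um,
                 plan = plan))
}
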