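# Image convention used throughout: row-major matrices, origin top-left,
# 1-based indices in R; the fringe axis is the image column axis.

#' Write an acquisition to TIFF files plus a YAML manifest
#'
#' Persists simulator (or imported) stacks as 16-bit grayscale TIFFs,
#' one file per image, and writes a manifest recording for every file
#' its role (sample or reference), spatial frequency, phase index and
#' wavelength, together with the run-level intensity scale, whiteboard
#' reflectance and refractive index. Masked (`NA`) pixels are stored as
#' zero; the demodulation masking floor recovers them downstream.
#'
#' @param stacks List from [simulate_stack()] (`sample`, `reference`,
#'   `fx_list`).
#' @param dir Output directory (created if missing).
#' @param wavelength Wavelength tag, nm. Default 527.
#' @param scale Intensity scale mapping stored 16-bit counts to the
#'   stack's linear units. Default the stack maximum.
#' @param rd_ref Whiteboard reflectance recorded in the manifest.
#' @param n Refractive index recorded in the manifest.
#' @return Path to the written `manifest.yaml`, invisibly.
#' @export
write_acquisition <- function(stacks, dir, wavelength = 527,
                              scale = NULL, rd_ref = 0.99, n = 1.35) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_imgs <- unlist(lapply(c(stacks$sample, stacks$reference), function(x) {
    if (is.list(x)) x else list(x)
  }), recursive = FALSE)
  if (is.null(scale)) scale <- max(vapply(all_imgs, max, numeric(1L),
                                          na.rm = TRUE))
  records <- list()
  put <- function(img, role, fx, phase) {
    fn <- sprintf("%s_fx%0.4f_p%d.tif", role, fx, phase)
    img[is.na(img)] <- 0
    tiff::writeTIFF(pmin(pmax(img / scale, 0), 1),
                    file.path(dir, fn), bits.per.sample = 16L)
    records[[length(records) + 1L]] <<- list(
      file = fn, role = role, wavelength = wavelength,
      fx = fx, phase = as.integer(phase))
  }
  for (i in seq_along(stacks$fx_list)) {
    fx <- stacks$fx_list[i]
    for (role in c("sample", "reference")) {
      entry <- stacks[[role]][[i]]
      if (fx == 0) put(entry, role, fx, 0L)
      else for (k in 1:3) put(entry[[k]], role, fx, k - 1L)
    }
  }
  manifest <- list(rd_ref = rd_ref, n = n, scale = scale,
                   wavelength = wavelength, records = records)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load and validate an acquisition manifest
#'
#' Parses a YAML manifest and checks its structural invariants: every
#' (role, frequency) pair must carry exactly the phase set {0, 1, 2}
#' except the planar channel (fx = 0), which has a single record; no
#' duplicates; every referenced file must exist. All violations are
#' collected and reported together.
#'
#' @param path Path to `manifest.yaml`.
#' @return The validated manifest with an added `dir` field.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  problems <- character(0)
  if (length(m$records) == 0L) {
    stop("empty manifest: no records", call. = FALSE)
  }
  rec <- do.call(rbind, lapply(m$records, function(r) {
    data.frame(file = r$file, role = r$role, fx = as.numeric(r$fx),
               phase = as.integer(r$phase))
  }))
  dup <- duplicated(rec[c("role", "fx", "phase")])
  if (any(dup)) {
    problems <- c(problems, sprintf("duplicate record: %s fx=%g phase=%d",
                                    rec$role[dup], rec$fx[dup],
                                    rec$phase[dup]))
  }
  for (role in unique(rec$role)) {
    for (fx in unique(rec$fx[rec$role == role])) {
      ph <- sort(rec$phase[rec$role == role & rec$fx == fx])
      want <- if (fx == 0) 0L else 0:2
      if (!identical(ph, as.integer(want))) {
        problems <- c(problems, sprintf(
          "%s fx=%g: phases {%s}, expected {%s}", role, fx,
          paste(ph, collapse = ","), paste(want, collapse = ",")))
      }
    }
  }
  missing <- !file.exists(file.path(dir, rec$file))
  if (any(missing)) {
    problems <- c(problems, paste("missing file:", rec$file[missing]))
  }
  if (length(problems)) {
    stop("invalid manifest:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  m$dir <- dir
  m
}

#' Read the image stacks referenced by a manifest
#'
#' @param manifest Validated manifest from [load_manifest()].
#' @return List with `sample`, `reference`, `fx_list` in the layout
#'   produced by [simulate_stack()], intensities restored to the
#'   manifest's linear scale.
#' @export
read_acquisition <- function(manifest) {
  rec <- do.call(rbind, lapply(manifest$records, function(r) {
    data.frame(file = r$file, role = r$role, fx = as.numeric(r$fx),
               phase = as.integer(r$phase))
  }))
  fx_list <- sort(unique(rec$fx))
  get_img <- function(role, fx, phase) {
    fn <- rec$file[rec$role == role & rec$fx == fx & rec$phase == phase]
    img <- tiff::readTIFF(file.path(manifest$dir, fn))
    img * manifest$scale
  }
  fetch <- function(role) {
    lapply(fx_list, function(fx) {
      if (fx == 0) get_img(role, fx, 0L)
      else lapply(0:2, function(p) get_img(role, fx, p))
    })
  }
  list(sample = fetch("sample"), reference = fetch("reference"),
       fx_list = fx_list)
}

#' Write a coefficient map as 32-bit float TIFF with a JSON sidecar
#'
#' The map is stored normalised to [0, 1]; the sidecar records the
#' scale (mm^-1 per stored unit) and any fit diagnostics so the map can
#' be restored exactly. Masked pixels are stored as zero and listed in
#' the sidecar mask count.
#'
#' @param map Numeric matrix, mm^-1.
#' @param path Output TIFF path; the sidecar gets extension `.json`.
#' @param diagnostics Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path, diagnostics = list()) {
  scale <- max(map, na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  img <- map / scale
  img[is.na(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  sidecar <- c(list(scale = scale, n_masked = sum(is.na(map)),
                    rows = nrow(map), cols = ncol(map)), diagnostics)
  jsonlite::write_json(sidecar, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a coefficient map written by [write_map_tiff()]
#'
#' @param path TIFF path.
#' @return Matrix in mm^-1 (masked pixels restored to `NA` when the
#'   sidecar records a mask).
#' @export
read_map_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  sidecar <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                                 simplifyVector = TRUE)
  map <- img * sidecar$scale
  if (!is.null(sidecar$n_masked) && sidecar$n_masked > 0) {
    map[img == 0] <- NA_real_
  }
  map
}

#' Run the demodulation-inversion pipeline on an acquisition
#'
#' Executes the stages in order: load and validate the manifest, read
#' the stacks, demodulate and calibrate every channel against the
#' whiteboard, invert the multi-frequency reflectance per pixel, apply
#' optional linear correction factors, and write the coefficient maps
#' (32-bit float TIFF + JSON diagnostics). Deterministic: identical
#' inputs produce identical numeric outputs.
#'
#' @param manifest_path Path to the acquisition `manifest.yaml`.
#' @param out_dir Output directory for maps and diagnostics.
#' @param bin Superpixel binning for the inversion. Default 1
#'   (per-pixel).
#' @param k_mua,k_musp Linear correction ratios applied to the maps.
#'   Default 1 (no correction).
#' @return List with `mua`, `musp` (corrected maps), `residual`,
#'   `fx_list`, and `out_dir`.
#' @export
run_pipeline <- function(manifest_path, out_dir, bin = 1L,
                         k_mua = 1, k_musp = 1) {
  manifest <- load_manifest(manifest_path)
  stacks <- read_acquisition(manifest)
  if (length(stacks$fx_list) < 2L) {
    stop("pipeline requires at least two spatial frequencies", call. = FALSE)
  }
  message(sprintf("demodulating %d frequencies", length(stacks$fx_list)))
  demod <- demodulate_acquisition(stacks$sample, stacks$reference,
                                  stacks$fx_list, rd_ref = manifest$rd_ref)
  message(sprintf("inverting (bin = %d)", bin))
  medium <- medium_constants(n = if (is.null(manifest$n)) 1.35 else manifest$n)
  maps <- invert_map(demod$rd, stacks$fx_list, medium = medium, bin = bin)
  maps$mua <- apply_correction(maps$mua, k_mua)
  maps$musp <- apply_correction(maps$musp, k_musp)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  diag <- list(fx_list = stacks$fx_list, bin = bin,
               k_mua = k_mua, k_musp = k_musp,
               median_residual = stats::median(maps$residual, na.rm = TRUE),
               frac_converged = mean(maps$converged, na.rm = TRUE))
  write_map_tiff(maps$mua, file.path(out_dir, "mua.tif"), diag)
  write_map_tiff(maps$musp, file.path(out_dir, "musp.tif"), diag)
  c(maps[c("mua", "musp", "residual")],
    list(fx_list = stacks$fx_list, out_dir = out_dir))
}
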