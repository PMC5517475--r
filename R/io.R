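# reinterpret doubles as 32-bit float bit patterns (signed int32) and back
float32_bits <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "integer", n = length(x), size = 4L, endian = "little")
}
float32_from_bits <- function(i) {
  readBin(writeBin(as.integer(i), raw(), size = 4L, endian = "little"),
          "numeric", n = length(i), size = 4L, endian = "little")
}

#' Write an image stack to TIFF
#'
#' Three dtype contracts are supported, chosen by `kind`:
#' `"strength32f"` (real values, stored bit-exactly at 32-bit float
#' precision in a 32-bit-per-sample TIFF), `"codes16u"` (integer codes
#' 0..65535) and `"mask8u"` (logical masks).  Matrices become single-page,
#' arrays `[row, col, frame]` multi-page TIFFs.  Every kind round-trips
#' losslessly through [read_stack()] (strengths to float32 precision).
#'
#' @param path Output file.
#' @param data Matrix or 3-D array.
#' @param kind Dtype contract.
#' @return `path`, invisibly.
#' @export
write_stack <- function(path, data,
                        kind = c("strength32f", "codes16u", "mask8u")) {
  kind <- match.arg(kind)
  if (!(is.matrix(data) || (is.array(data) && length(dim(data)) == 3))) {
    stop("`data` must be a matrix or a [row, col, frame] array", call. = FALSE)
  }
  pages <- if (is.matrix(data)) list(data) else {
    lapply(seq_len(dim(data)[3]), function(f) data[, , f])
  }
  if (kind == "strength32f") {
    if (!is.numeric(data)) stop("strength32f needs numeric data", call. = FALSE)
    tiff::writeTIFF(lapply(pages, function(p) {
      bits <- float32_bits(p)
      u <- ifelse(bits < 0, bits + 2^32, bits)   # unsigned bit pattern
      matrix(u / (2^32 - 1), nrow(p), ncol(p))
    }), path, bits.per.sample = 32L)
  } else if (kind == "codes16u") {
    if (any(data != round(data)) || any(data < 0) || any(data > 65535)) {
      stop("codes16u needs integer values in [0, 65535]", call. = FALSE)
    }
    tiff::writeTIFF(lapply(pages, function(p) p / 65535),
                    path, bits.per.sample = 16L)
  } else {
    if (!all(data %in% c(0, 1, TRUE, FALSE))) {
      stop("mask8u needs logical (0/1) values", call. = FALSE)
    }
    tiff::writeTIFF(lapply(pages, function(p) {
      storage.mode(p) <- "double"; p
    }), path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF file.
#' @param kind Dtype contract the file was written with.
#' @return Matrix (single page) or `[row, col, frame]` array.
#' @export
read_stack <- function(path, kind = c("strength32f", "codes16u", "mask8u")) {
  kind <- match.arg(kind)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (kind == "strength32f"))
  pages <- lapply(pages, function(p) {
    switch(kind,
           strength32f = matrix(float32_from_bits(p), nrow(p), ncol(p)),
           codes16u = round(p * 65535),
           mask8u = p > 0.5)
  })
  if (length(pages) == 1) {
    pages[[1]]
  } else {
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
}

#' Write a run manifest
#'
#' Records everything needed to regenerate a run: the configuration and noise
#' snapshot, seeds, package version, and every output file with its MD5
#' checksum.
#'
#' @param path Manifest JSON file.
#' @param cfg An [acquisition_config()].
#' @param noise A [noise_model()].
#' @param seeds Named list or vector of seeds used.
#' @param files Character vector of output files to checksum.
#' @param extra Optional named list of extra fields (e.g. clip counts).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, cfg, noise = NULL, seeds = NULL,
                               files = character(), extra = NULL) {
  files <- files[file.exists(files)]
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "aiscope",
    version = as.character(utils::packageVersion("aiscope")),
    acquisition = unclass(cfg),
    noise = if (!is.null(noise)) unclass(noise),
    seeds = seeds,
    files = lapply(files, function(f) {
      list(path = f, bytes = file.size(f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  if (!is.null(extra)) manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest JSON file.
#' @return The manifest as a list.
#' @export
read_run_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write a scene to disk
#'
#' Strength as 32-bit float TIFF, ground truth as CSV, parameters as a JSON
#' sidecar.
#'
#' @param scene A `scene_map` or `functional_scene`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(stem, "_strength.tif"))
  csv <- file.path(dir, paste0(stem, "_truth.csv"))
  side <- file.path(dir, paste0(stem, "_params.json"))
  if (inherits(scene, "scene_map")) {
    write_stack(tif, scene$strength, "strength32f")
    params <- scene[c("seed", "range_ratio", "strength_min", "shape", "counts")]
  } else {
    write_stack(tif, scene$frames, "strength32f")
    params <- scene[c("seed", "dt", "n_frames", "stim_onset",
                      "kernel_params", "shape")]
  }
  utils::write.csv(ground_truth_summary(scene), csv, row.names = FALSE)
  jsonlite::write_json(params, side, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, csv, side))
}

#' Write an encoded frame with its reconstruction sidecar
#'
#' The re-digitized log map goes to a 16-bit TIFF; `G_M`, `C`, `G_L` and
#' `alpha` — required for post-hoc linearization — go to a JSON sidecar.
#'
#' @param enc An `encoded_frame`.
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return Files written, invisibly.
#' @export
write_encoded_frame <- function(enc, dir, stem = "encoded") {
  stopifnot(inherits(enc, "encoded_frame"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(stem, "_Ldd.tif"))
  side <- file.path(dir, paste0(stem, "_sidecar.json"))
  write_stack(tif, enc$L_dd, "codes16u")
  jsonlite::write_json(enc[c("G_M_used", "G_L", "C", "alpha")], side,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(tif, side))
}

#' Reconstruct from files written by [write_encoded_frame()]
#'
#' @param ldd_path 16-bit TIFF of re-digitized log codes.
#' @param sidecar_path JSON sidecar with `G_L` and `G_M_used`.
#' @return A `recon_image`.
#' @export
reconstruct_from_files <- function(ldd_path, sidecar_path) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  L_dd <- read_stack(ldd_path, "codes16u")
  reconstruct_linear(L_dd, side$G_L, side$G_M_used)
}

#' Reconstruct from user-supplied paired signal/power stacks
#'
#' Reconstruction-only entry point for externally acquired data: paired
#' 16-bit TIFF stacks of signal and power codes are log-encoded and
#' linearized under the supplied configuration.
#'
#' @param signal_path,power_path 16-bit TIFF code stacks (same shape).
#' @param cfg An [acquisition_config()] describing the acquisition.
#' @return A `recon_image` (3-D `X` / `log2X` for multi-page stacks).
#' @export
reconstruct_stacks <- function(signal_path, power_path, cfg) {
  S <- read_stack(signal_path, "codes16u")
  P <- read_stack(power_path, "codes16u")
  if (!all(dim(S) == dim(P))) {
    stop("signal and power stacks must have the same shape", call. = FALSE)
  }
  luts <- encoder_luts(cfg)
  L <- log_encode(pmax(S, 1), pmax(P, 1), cfg, luts = luts)
  rd <- redigitize(L, cfg)
  out <- reconstruct_linear(rd$L_dd, cfg$G_L, rd$G_M_used)
  if (length(dim(S)) == 3) {
    out$X <- array(out$X, dim(S))
    out$log2X <- array(out$log2X, dim(S))
  }
  out
}
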