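#' Read a multi-echo acquisition from per-echo NIfTI files
#'
#' All echoes must share grid, frame count and voxel size; a mismatch
#' raises an error naming the offending file.
#'
#' @param paths one NIfTI path per echo, ordered by echo time
#' @param teMs echo times (ms), one per path
#' @param trS repetition time (s)
#' @param labelParity label/control frame parity convention
#' @return a [MultiEchoSeries-class]
#' @export
readMultiEcho <- function(paths, teMs, trS, labelParity = "even-control") {
  stopifnot(length(paths) == length(teMs))
  vols <- lapply(paths, RNifti::readNifti)
  d1 <- dim(vols[[1L]])
  if (length(d1) != 4L) .stopf("'%s' is not a 4-D series", paths[1L])
  vs <- RNifti::pixdim(vols[[1L]])[1:3]
  for (i in seq_along(vols)[-1L]) {
    if (!identical(dim(vols[[i]]), d1))
      .stopf("grid mismatch: '%s' has dimensions %s, expected %s", paths[i],
             paste(dim(vols[[i]]), collapse = "x"), paste(d1, collapse = "x"))
  }
  data <- array(0, c(d1, length(vols)))
  for (i in seq_along(vols)) data[, , , , i] <- as.array(vols[[i]])
  new("MultiEchoSeries", data = data, teMs = teMs, trS = trS,
      labelParity = labelParity, voxelSizeMm = as.numeric(vs))
}

#' Read a mask volume matched to a series grid
#'
#' @param path NIfTI path
#' @param dims3 expected 3-D grid
#' @return logical array
#' @export
readMask <- function(path, dims3 = NULL) {
  v <- as.array(RNifti::readNifti(path))
  if (!is.null(dims3) && !identical(dim(v)[1:3], as.integer(dims3)))
    .stopf("mask '%s' grid %s does not match the series grid %s", path,
           paste(dim(v), collapse = "x"), paste(dims3, collapse = "x"))
  array(v > 0.5, dim(v)[1:3])
}

#' Write an array or series as NIfTI
#'
#' Writes a 3-D map or a 4-D series with the voxel size recorded in the
#' header (diagonal affine). Data round-trip at float precision.
#'
#' @param x array, [VoxelSeries-class] or [MultiEchoSeries-class] (one
#'   file per echo is written for the latter, with `_e<n>` suffixes)
#' @param path output path (`.nii` or `.nii.gz`)
#' @param voxelSizeMm voxel size for bare arrays
#' @param trS frame spacing for 4-D data (s)
#' @return the path(s) written, invisibly
#' @export
writeVolume <- function(x, path, voxelSizeMm = c(1, 1, 1), trS = 1) {
  if (is(x, "MultiEchoSeries")) {
    paths <- vapply(seq_len(nEchoes(x)), function(e) {
      pe <- sub("(\\.nii(\\.gz)?)$", sprintf("_e%d\\1", e), path)
      writeVolume(.echo_array(x, e), pe,
                  voxelSizeMm = x@voxelSizeMm, trS = x@trS)
      pe
    }, character(1))
    return(invisible(paths))
  }
  if (is(x, "VoxelSeries")) {
    voxelSizeMm <- x@voxelSizeMm
    trS <- x@trS
    x <- x@data
  }
  if (is.logical(x)) x <- x * 1
  img <- RNifti::asNifti(x)
  nd <- length(dim(x))
  pd <- c(voxelSizeMm, if (nd >= 4L) trS)
  RNifti::pixdim(img) <- c(pd, rep(1, nd - length(pd)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML file with (all optional, defaults in parentheses): a `paradigm`
#' block with the [buildParadigm()] fields; `te_ms` (9.1/25/39.6/54.3);
#' `echo_paths` and `mask_paths` (gm/wm) for real data, or a `phantom`
#' block (fields of [phantomTruth()]) to simulate; `fwhm_mm` (4.5);
#' `trend_order` (3); `p_threshold` (0.001); `prewhiten` (false);
#' `alpha` (0.2) / `beta` (1); `baseline_mode_bold` ("mean") /
#' `baseline_mode_pw` ("intercept"); `cutoff_hz` (0.09); `filter_order`
#' (4); `label_parity` ("even-control"); `shifts_s`; `seed` (1);
#' `out_dir`; `sessions` (1 or 2) with `cvr_jitter` / `cbf_jitter` for
#' the second phantom session.
#'
#' @param path YAML file path
#' @return a named list of configuration values with defaults filled in
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  fillRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a partially specified configuration list
#' @export
fillRunConfig <- function(cfg = list()) {
  def <- list(
    te_ms = c(9.1, 25, 39.6, 54.3), fwhm_mm = 4.5, trend_order = 3L,
    p_threshold = 0.001, prewhiten = FALSE, alpha = 0.2, beta = 1,
    baseline_mode_bold = "mean", baseline_mode_pw = "intercept",
    cutoff_hz = 0.09, filter_order = 4L, label_parity = "even-control",
    seed = 1L, sessions = 1L, cvr_jitter = 0, cbf_jitter = 0,
    out_dir = NULL, echo_paths = NULL, gm_mask = NULL, wm_mask = NULL,
    phantom = list(), paradigm = list(), shifts_s = NULL, bold_echo = 2L
  )
  for (nm in names(def)) if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  cfg
}

#' Write phantom data, masks and ground truth to a directory
#'
#' One 4-D NIfTI per echo, GM/WM mask NIfTIs, per-map truth NIfTIs and a
#' YAML sidecar with the scalar truth parameters. Deterministic given the
#' truth seed.
#'
#' @param truth a [PhantomTruth-class]
#' @param series the generated [MultiEchoSeries-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writePhantom <- function(truth, series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(series, file.path(dir, "echo.nii.gz"))
  vs <- truth@voxelSizeMm
  writeVolume(truth@gmMask, file.path(dir, "gm_mask.nii.gz"), vs)
  writeVolume(truth@wmMask, file.path(dir, "wm_mask.nii.gz"), vs)
  for (nm in c("s0Map", "t2starMs", "lagS", "cvr", "cbfRatio", "perfusionAmp"))
    writeVolume(slot(truth, nm), file.path(dir, paste0("truth_", nm, ".nii.gz")), vs)
  yaml::write_yaml(list(referenceTeMs = truth@referenceTeMs,
                        noiseSd = truth@noiseSd, arCoef = truth@arCoef,
                        voxelSizeMm = as.numeric(vs), seed = truth@seed),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
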