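#' Image stack: a volume plus its acquisition metadata
#'
#' Couples a 3-D (or 4-D, echoes last) signal array with the [seq_params]
#' it was acquired with and the scanner intensity scale factor that must be
#' divided out before quantitative fitting.
#'
#' @param data Numeric array, 3-D or 4-D.
#' @param seq A [seq_params].
#' @param scale Scanner intensity scale factor (default 1).
#' @param affine Optional 4x4 voxel-to-world matrix (NIfTI convention).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, seq, scale = 1, affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L),
            inherits(seq, "seq_params"), is.numeric(scale), scale > 0)
  structure(list(data = data, seq = seq, scale = scale, affine = affine),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s, dims %s, scale %g\n", x$seq$kind,
              paste(dim(x$data), collapse = "x"), x$scale))
  invisible(x)
}

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write an image stack as NIfTI-1 plus sidecar JSON
#'
#' The volume is written as float32 NIfTI-1; the acquisition parameters
#' (seconds/degrees) and the intensity scale factor go to a JSON sidecar
#' next to it (same basename, `.json`).
#'
#' @param stack An [image_stack].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  img <- RNifti::asNifti(stack$data, datatype = "float")
  RNifti::writeNifti(img, path)
  side <- list(
    kind = stack$seq$kind, tr = stack$seq$tr, te = stack$seq$te,
    ti = stack$seq$ti, flip = stack$seq$flip,
    echo_spacing = stack$seq$echo_spacing,
    train_length = stack$seq$train_length,
    readout_index = stack$seq$readout_index,
    scale = stack$scale)
  jsonlite::write_json(side[!vapply(side, is.null, TRUE)],
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a NIfTI-1 volume with its sidecar into an image stack
#'
#' Honours NIfTI on-disk slope/intercept scaling (applied by RNifti on
#' read). The sidecar JSON must provide the sequence kind and timing fields
#' (seconds) plus the scanner intensity `scale` factor.
#'
#' @param path Path to a `.nii`/`.nii.gz` file with a `.json` sidecar.
#' @return An [image_stack].
#' @export
read_volume <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar JSON '", sp, "'; expected fields: kind, tr, te, ",
         "ti, flip, echo_spacing, train_length, scale", call. = FALSE)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  sq <- seq_params(kind = side$kind, tr = side$tr, te = side$te,
                   ti = side$ti, flip = side$flip,
                   echo_spacing = side$echo_spacing,
                   train_length = side$train_length,
                   readout_index = side$readout_index)
  arr <- array(as.numeric(img), dim = dim(img))
  image_stack(arr, sq, scale = side$scale %||% 1,
              affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a parameter map as float32 NIfTI-1
#'
#' Units are 1/s for R1/R2* maps and dimensionless for the flip-angle-scale
#' map; unfit voxels carry the `NA` sentinel (stored as NaN).
#'
#' @param map Numeric array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  img <- RNifti::asNifti(map, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parameter map written by [write_map]
#' @param path NIfTI path.
#' @return Numeric array (NaN mapped to `NA`).
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  arr[is.nan(arr)] <- NA_real_
  arr
}

#' Check that two volumes share a grid (and affine, when both carry one)
#' @param a,b Arrays or [image_stack]s.
#' @return `TRUE`, invisibly; error on mismatch.
#' @export
check_congruent <- function(a, b) {
  da <- if (inherits(a, "image_stack")) dim(a$data)[1:3] else dim(a)[1:3]
  db <- if (inherits(b, "image_stack")) dim(b$data)[1:3] else dim(b)[1:3]
  if (!all(da == db))
    stop("volumes are not congruent: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), call. = FALSE)
  aa <- if (inherits(a, "image_stack")) a$affine else attr(a, "affine")
  ab <- if (inherits(b, "image_stack")) b$affine else attr(b, "affine")
  if (!is.null(aa) && !is.null(ab) &&
      max(abs(unclass(aa) - unclass(ab))) > 1e-4)
    stop("volumes are not congruent: affines differ (no resampling is ",
         "performed; co-register upstream)", call. = FALSE)
  invisible(TRUE)
}

#' Write a provenance record for a pipeline run
#'
#' Emits a JSON log with the package version, seed, configuration hash and
#' parameters — sufficient to reproduce deterministic stages bit-exactly.
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters.
#' @param seed Integer seed used (or `NA`).
#' @return The record, invisibly.
#' @export
write_provenance <- function(path, params, seed = NA_integer_) {
  rec <- list(
    package = "qrelax",
    version = as.character(utils::packageVersion("qrelax")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(params), collapse = ""))),
    params = params)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(rec)
}
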