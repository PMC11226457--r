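#' Read a SAIM acquisition: multi-page TIFF stack + YAML optics sidecar
#'
#' The stack stores one page per sweep angle, ascending. The sidecar gives
#' `angles_deg`, `wavelength_nm`, `oxide_thickness_nm` and optional index
#' overrides (`n_medium`, `n_oxide`, `n_silicon_re`, `n_silicon_im`).
#'
#' @param stack_path Path to the multi-page TIFF.
#' @param optics_path Path to the YAML sidecar.
#' @param mask_path Optional single-page TIFF mask (nonzero = in ROI).
#' @return List: `image_stack` (angles x rows x cols), `sweep`, `stack`,
#'   `mask` (or NULL).
#' @export
read_saim_stack <- function(stack_path, optics_path, mask_path = NULL) {
  pages <- tiff::readTIFF(stack_path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  opt <- yaml::read_yaml(optics_path)
  sweep <- angle_sweep(as.numeric(opt$angles_deg))
  if (length(pages) != length(sweep)) {
    stop("stack has ", length(pages), " pages but sidecar lists ",
         length(sweep), " angles", call. = FALSE)
  }
  stk <- layer_stack(
    wavelength_nm = opt$wavelength_nm %||% 488,
    oxide_thickness_nm = opt$oxide_thickness_nm %||% 500,
    n_medium = opt$n_medium %||% 1.33,
    n_oxide = opt$n_oxide %||% 1.463,
    n_silicon = complex(real = opt$n_silicon_re %||% 4.37,
                        imaginary = opt$n_silicon_im %||% -0.08))
  arr <- array(NA_real_, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- tiff::readTIFF(mask_path) != 0
    if (length(dim(mask)) > 2) mask <- mask[, , 1]
  }
  list(image_stack = arr, sweep = sweep, stack = stk, mask = mask)
}

#' Write and read height maps as 32-bit float TIFF
#'
#' Float TIFF samples are constrained to `[0, 1]` by the writer, so heights
#' are stored affinely encoded as `(nm + 100) / 1000` (covering -100 to
#' 900 nm); unfitted (`NA`) pixels are stored as 0, below the encodable
#' range. [read_height_map()] inverts the encoding exactly.
#'
#' @param height_map Numeric matrix in nm.
#' @param path Output path.
#' @return `write_height_map()`: `path`, invisibly. `read_height_map()`:
#'   the height matrix in nm with `NA` for unfitted pixels.
#' @export
write_height_map <- function(height_map, path) {
  hm <- (height_map + 100) / 1000
  hm[!is.finite(height_map)] <- 0
  if (any(hm < 0 | hm > 1, na.rm = TRUE)) {
    stop("heights outside the encodable -100..900 nm range", call. = FALSE)
  }
  tiff::writeTIFF(hm, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  hm <- tiff::readTIFF(path)
  if (length(dim(hm)) > 2) hm <- hm[, , 1]
  out <- hm * 1000 - 100
  out[hm == 0] <- NA_real_
  out
}

#' Read a magnetic-tweezer trace CSV
#'
#' Expected columns: `time_s`, `force_pN`, `height_nm`.
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_tweezer_trace <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path))
  validate_trace(tr)
  tr
}

#' Read a FRAP trace CSV
#'
#' Expected columns: `time_s`, `i_frap`, `i_ref`, `i_back`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_frap_trace <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("time_s", "i_frap", "i_ref", "i_back") %in% names(tr)))
  tr
}

#' Read an ablation edge-track CSV
#'
#' Expected columns: `time_s`, `e1x_um`, `e1y_um`, `e2x_um`, `e2y_um`,
#' optional `ablation_time_s`.
#' @param path CSV path.
#' @return Tibble with an `ablation_time_s` attribute.
#' @export
read_edge_track <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("time_s", "e1x_um", "e1y_um", "e2x_um", "e2y_um") %in% names(tr)))
  attr(tr, "ablation_time_s") <- ablation_time(tr)
  tr
}

#' Read long-format velocity fields CSV
#'
#' Expected columns: `frame`, `x_um`, `y_um`, `u_um_h`, `v_um_h`,
#' optional `valid`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_velocity_fields <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("u_um_h", "v_um_h") %in% names(tr)))
  tr
}
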