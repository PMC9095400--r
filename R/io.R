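# Image and configuration I/O. Canonical image form throughout the package:
# numeric matrix of intensities in [0, 2^8 - 1]; files are 8-bit grayscale
# PNG or TIFF. Multi-channel inputs are converted to luminance with a
# warning; 16-bit TIFF is rescaled to 8 bits with a warning.

#' Read a grayscale image
#'
#' @param path PNG or TIFF file.
#' @return numeric matrix of 8-bit intensities (0..255).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
                         png = png::readPNG(path),
                         tif = ,
                         tiff = tiff::readTIFF(path),
                         stop("unsupported image format '", ext,
                              "' (PNG or TIFF expected)", call. = FALSE)),
                  error = function(e) stop("cannot read '", path, "' as ", ext,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      warning("multi-channel image converted to luminance", call. = FALSE)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  round(img * 255)
}

#' Write a grayscale image (8-bit)
#'
#' `write_gray_image()` then [read_gray_image()] is bit-exact for quantized
#' 8-bit content.
#'
#' @param image numeric matrix in [0, 255].
#' @param path output path; format chosen by extension (.png, .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  if (!is.matrix(image)) stop("'image' must be a numeric matrix", call. = FALSE)
  x <- quantize(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(x, path),
         tif = ,
         tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
         stop("unsupported image format '", ext, "' (PNG or TIFF expected)",
              call. = FALSE))
  invisible(path)
}

# Allowed configuration blocks and fields, with defaults.
run_config_schema <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    log_level = "info",
    phantom = list(height = 64L, width = 64L),
    noise = list(model = "multiplicative_speckle", sigma = 1.0),
    architecture = list(kind = "improved_unet", depth = 2L, base_channels = 8L),
    training = list(epochs = 30L, batch_size = 8L, learning_rate = 1e-3,
                    patch_size = 64L),
    benchmark = list(n_images = 50L, sigmas = c(0.5, 1, 1.5, 2, 2.5)),
    clinical_fixture = NULL
  )
}

#' Load and validate a run configuration
#'
#' YAML or JSON (by extension). Unknown keys are rejected by name; known
#' blocks are filled with defaults. Basic value checks (non-negative sigma,
#' positive sizes) are applied.
#'
#' @param path configuration file.
#' @return validated, fully defaulted config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format '", ext, "'", call. = FALSE))
  if (is.null(raw)) raw <- list()
  schema <- run_config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in intersect(names(raw), names(schema))) {
    if (is.list(schema[[blk]]) && is.list(raw[[blk]])) {
      bad <- setdiff(names(raw[[blk]]), names(schema[[blk]]))
      if (length(bad) > 0)
        stop("unknown config keys in '", blk, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  cfg <- modifyList(schema, raw, keep.null = TRUE)
  if (cfg$noise$sigma < 0)
    stop("invalid config: noise.sigma must be >= 0", call. = FALSE)
  if (cfg$phantom$height < 1 || cfg$phantom$width < 1)
    stop("invalid config: phantom size must be positive", call. = FALSE)
  if (cfg$training$learning_rate < 0)
    stop("invalid config: training.learning_rate must be >= 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Save model parameters as a portable checkpoint
#'
#' A single JSON file: the architecture description in the header, the
#' parameter arrays (with dimensions) in the body. Text-based and
#' platform-independent.
#'
#' @param model a `denoiser_model` or `trained_denoiser`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "trained_denoiser")) model <- model$model
  payload <- list(
    architecture = unclass(model$arch),
    trained = model$trained,
    params = lapply(model$params, function(p)
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = as.numeric(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return a `denoiser_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(architecture_spec, payload$architecture[
    c("kind", "depth", "base_channels", "downsample", "use_residual_blocks",
      "use_rdub", "use_recon", "residual", "prelu_shared", "init_seed")])
  params <- lapply(payload$params, function(p) {
    d <- unlist(p$dim)
    v <- as.numeric(unlist(p$data))
    if (length(d) > 1L) array(v, dim = d) else v
  })
  structure(list(arch = spec, params = params,
                 trained = isTRUE(payload$trained)),
            class = c(spec$kind, "denoiser_model"))
}
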