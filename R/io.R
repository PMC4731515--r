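# File interchange: multi-page TIFF movies with a JSON calibration
# sidecar, CSV tables, YAML/JSON configs.

#' Write an image stack as a multi-page TIFF
#'
#' Pixel values are scaled to [0, 1] for storage (32-bit float); the
#' scale factor and the physical calibration (pixel size, frame interval,
#' origin) are written to a JSON sidecar `<file>.json` so that
#' [read_movie_tiff()] restores the stack exactly.
#'
#' @param stack An `image_stack`.
#' @param file Output TIFF path.
#' @return `file`, invisibly.
#' @export
write_movie_tiff <- function(stack, file) {
  n <- dim(stack)[3]
  mx <- max(stack, 1e-12)
  mn <- min(stack, 0)
  pages <- purrr::map(seq_len(n), function(k) {
    (stack[, , k] - mn) / (mx - mn)
  })
  tiff::writeTIFF(pages, file, bits.per.sample = 32, compression = "none",
                  reduce = FALSE)
  meta <- list(schema = "endodance-movie/1",
               pixel_size_um = attr(stack, "pixel_size"),
               frame_interval_s = attr(stack, "frame_interval"),
               origin_um = attr(stack, "origin") %||% c(0, 0),
               value_offset = mn, value_scale = mx - mn)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a multi-page TIFF movie written by [write_movie_tiff()]
#'
#' @param file TIFF path (the `<file>.json` sidecar must sit next to it;
#'   without it the stack is returned unscaled with unit calibration).
#' @return An `image_stack`.
#' @export
read_movie_tiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  side <- paste0(file, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    arr <- arr * meta$value_scale + meta$value_offset
    structure(arr, class = c("image_stack", "array"),
              pixel_size = meta$pixel_size_um,
              frame_interval = meta$frame_interval_s,
              origin = meta$origin_um)
  } else {
    structure(arr, class = c("image_stack", "array"),
              pixel_size = 1, frame_interval = 1, origin = c(0, 0))
  }
}

#' Write ground truth tables as CSV
#'
#' @param truth An `endosome_truth`.
#' @param dir Output directory (created if needed); writes
#'   `particles.csv` and `events.csv`.
#' @return `dir`, invisibly.
#' @export
write_truth_csv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$particles, file.path(dir, "particles.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read / write a pipeline configuration
#'
#' Configurations are plain named lists with a `schema` field
#' (`"endodance-config/1"`); YAML or JSON by file extension.
#'
#' @param config Named list.
#' @param file Path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config()`: the list; `write_config()`: `file`,
#'   invisibly.
#' @export
write_config <- function(config, file) {
  config$schema <- config$schema %||% "endodance-config/1"
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(config, file)
  }
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  if (!identical(cfg$schema, "endodance-config/1")) {
    rlang::warn("config has no/unknown schema tag; attempting to use it anyway")
  }
  cfg
}
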