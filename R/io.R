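#' Read a recorded intensity image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF and maps it to `[0, 1]`
#' (a 16-bit image with maximum value 65535 maps to 1.0).  Colour images
#' are rejected: convert to grayscale first.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric intensity matrix in `[0, 1]`.
#' @export
read_intensity <- function(path) {
  img <- read_gray(path)
  img
}

read_gray <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext,
         "' (use grayscale PNG or TIFF)", call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1L]  # gray + alpha
    else stop("colour image: convert to grayscale first", call. = FALSE)
  }
  img
}

#' Write an intensity image
#'
#' Writes a `[0, 1]` intensity matrix as 16-bit grayscale TIFF or PNG.
#'
#' @param path Destination (`.tif`/`.tiff` or `.png`).
#' @param intensity Numeric matrix in `[0, 1]`.
#' @export
write_intensity <- function(path, intensity) {
  if (min(intensity) < 0 || max(intensity) > 1)
    stop("intensity must lie in [0, 1]", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(intensity, path),
    tif = , tiff = tiff::writeTIFF(intensity, path, bits.per.sample = 16L),
    stop("unsupported image format '.", ext, "'", call. = FALSE))
  invisible(path)
}

#' Persist a phase map as float TIFF with a key-value sidecar
#'
#' TIFF storage covers `[0, 1]`, so the phase values are affinely mapped
#' into that range and written at 32 bits per sample; the offset and scale
#' (plus pixel pitch, wavelength and wrap flag) go into a YAML sidecar
#' `<path>.yml` from which [read_phase()] restores the map.  Values
#' round-trip at 32-bit quantization precision (relative error below
#' 1e-9 of the map's range).
#'
#' @param path Destination `.tif` path.
#' @param phase A `qpi_phase` or phase matrix (radians).
#' @export
write_phase <- function(path, phase) {
  pm <- if (inherits(phase, "qpi_phase")) phase else phase_map(phase)
  lo <- min(pm$values)
  span <- max(pm$values) - lo
  scaled <- if (span > 0) (pm$values - lo) / span else pm$values * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  meta <- list(kind = "phase_map", offset = lo, scale = span,
               pixel = pm$pixel, wavelength = pm$wavelength,
               n = pm$n, wrapped = pm$wrapped)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_phase
#' @return `read_phase()` returns the restored `qpi_phase`.
#' @export
read_phase <- function(path) {
  scaled <- tiff::readTIFF(path)
  meta <- yaml::read_yaml(sidecar_path(path))
  values <- scaled * meta$scale + meta$offset
  phase_map(values,
            pixel = meta$pixel %||% NA_real_,
            wavelength = meta$wavelength %||% NA_real_,
            n = meta$n %||% NA_real_,
            wrapped = isTRUE(meta$wrapped) && max(values) < 2 * pi &&
              min(values) >= 0)
}

#' Persist a complex field as a two-page float TIFF
#'
#' Page 1 holds the amplitude and page 2 the phase, each affinely mapped
#' into `[0, 1]` with offsets and scales recorded in the YAML sidecar.
#'
#' @param path Destination `.tif` path.
#' @param field A `qpi_field`.
#' @export
write_field <- function(path, field) {
  stopifnot(inherits(field, "qpi_field"))
  amp <- Mod(field$values)
  ph <- Arg(field$values)
  sc <- function(m) {
    lo <- min(m); span <- max(m) - lo
    list(values = if (span > 0) (m - lo) / span else m * 0,
         offset = lo, scale = span)
  }
  a <- sc(amp); p <- sc(ph)
  tiff::writeTIFF(list(a$values, p$values), path, bits.per.sample = 32L)
  g <- field$grid
  yaml::write_yaml(list(kind = "complex_field", plane = field$plane,
                        amp_offset = a$offset, amp_scale = a$scale,
                        phase_offset = p$offset, phase_scale = p$scale,
                        n1 = g$n1, n2 = g$n2, pixel = g$pixel,
                        wavelength = g$wavelength),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_field
#' @return `read_field()` returns the restored `qpi_field`.
#' @export
read_field <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(sidecar_path(path))
  amp <- pages[[1]] * meta$amp_scale + meta$amp_offset
  ph <- pages[[2]] * meta$phase_scale + meta$phase_offset
  grid <- make_grid(meta$n1, meta$n2, meta$pixel, meta$wavelength)
  complex_field(amp * exp(1i * ph), grid, plane = meta$plane)
}

sidecar_path <- function(path) paste0(path, ".yml")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write experiment configuration files
#'
#' The configuration is a flat YAML key-value document holding the
#' geometry (`d1`, `d2`, `wavelength`, `pixel`, `n1`, `n2`), the phantom
#' selection and parameters, and the retrieval settings; all lengths are
#' strings with explicit unit suffixes (`"20cm"`, `"530nm"`, `"4.65um"`)
#' or plain numbers in metres.  [read_config()] resolves every length to
#' metres.
#'
#' @param path Path to the YAML config.
#' @return `read_config()` returns the resolved named list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rapply(raw, function(x) {
    if (is.character(x) && length(x) == 1L &&
        grepl("^-?[0-9.eE+-]+ ?(m|cm|mm|um|nm)$", x)) parse_length(x) else x
  }, how = "replace")
}

#' @rdname read_config
#' @param config Named list to serialize.
#' @export
write_config <- function(path, config) {
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' Parse a length with an explicit unit suffix
#'
#' Accepts `m`, `cm`, `mm`, `um`, `nm` suffixes (`"20cm"` -> `0.2`);
#' plain numbers pass through unchanged and are taken as metres.
#'
#' @param x A character scalar like `"4.65um"`, or a number (metres).
#' @return Length in metres.
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^(-?[0-9.eE+-]+) ?(m|cm|mm|um|nm)$", x))[[1]]
  if (length(m) != 3L)
    stop("cannot parse length '", x,
         "' (use e.g. '20cm', '4.65um', '530nm')", call. = FALSE)
  as.numeric(m[2]) * c(m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6, nm = 1e-9)[[m[3]]]
}
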