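#' Construct a canopy thermal image
#'
#' Wraps a 2-D grid of temperatures (degrees Celsius) together with the
#' ambient air temperature recorded alongside the image and a plant
#' identifier.
#'
#' @param pixels numeric matrix of per-pixel temperatures in degC.
#' @param ambient_temp ambient (air) temperature in degC.
#' @param plant_id identifier of the imaged plant/pot.
#' @return An object of class `"thermal_image"`.
#' @export
thermal_image <- function(pixels, ambient_temp, plant_id = "plant") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("all pixels must be finite temperatures", call. = FALSE)
  .check_scalar(ambient_temp, "ambient_temp")
  structure(list(pixels = pixels, ambient_temp = ambient_temp,
                 plant_id = as.character(plant_id)),
            class = "thermal_image")
}

#' @export
print.thermal_image <- function(x, ...) {
  cat("Thermal image '", x$plant_id, "': ", nrow(x$pixels), " x ",
      ncol(x$pixels), " pixels, range ",
      sprintf("%.2f-%.2f", min(x$pixels), max(x$pixels)),
      " degC, ambient ", sprintf("%.2f", x$ambient_temp), " degC\n", sep = "")
  invisible(x)
}

#' Read a thermal matrix with its metadata sidecar
#'
#' The payload is either a delimited numeric grid (`format: "csv"`) or a
#' raw little-endian float32 grid (`format: "float32"`).  The JSON sidecar
#' must provide `plant_id`, `ambient_temp`, `n_rows`, `n_cols` and
#' `format`; the payload shape is checked against it.
#'
#' @param path path to the matrix payload.
#' @param metadata_path path to the JSON sidecar.
#' @return A [thermal_image()].
#' @export
read_thermal_matrix <- function(path, metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  need <- c("plant_id", "ambient_temp", "n_rows", "n_cols", "format")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("thermal metadata missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nr <- as.integer(meta$n_rows); nc <- as.integer(meta$n_cols)
  if (identical(meta$format, "float32")) {
    n <- file.size(path) / 4L
    if (n != nr * nc)
      stop("shape mismatch: metadata declares ", nr, "x", nc,
           " but payload holds ", n, " float32 values", call. = FALSE)
    vals <- readBin(path, what = "numeric", n = nr * nc, size = 4L,
                    endian = "little")
    px <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  } else if (identical(meta$format, "csv")) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != nr)
      stop("shape mismatch: metadata declares ", nr, " rows but payload has ",
           length(lines), call. = FALSE)
    px <- matrix(NA_real_, nrow = nr, ncol = nc)
    for (i in seq_len(nr)) {
      cells <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1L]])
      if (length(cells) != nc)
        stop("shape mismatch: row ", i, " has ", length(cells),
             " cells, expected ", nc, call. = FALSE)
      v <- suppressWarnings(as.numeric(cells))
      if (anyNA(v)) {
        j <- which(is.na(v))[1L]
        stop("non-numeric cell at row ", i, ", column ", j, ": '",
             cells[j], "'", call. = FALSE)
      }
      px[i, ] <- v
    }
  } else {
    stop("unknown thermal payload format '", meta$format, "'", call. = FALSE)
  }
  thermal_image(px, ambient_temp = as.numeric(meta$ambient_temp),
                plant_id = as.character(meta$plant_id))
}

#' Write a thermal image and its metadata sidecar
#'
#' @param img a [thermal_image()].
#' @param path payload output path.
#' @param metadata_path sidecar output path.
#' @param format `"csv"` (delimited text) or `"float32"` (raw little-endian).
#' @return `path`, invisibly.
#' @export
write_thermal_matrix <- function(img, path, metadata_path,
                                 format = c("csv", "float32")) {
  stopifnot(inherits(img, "thermal_image"))
  format <- match.arg(format)
  meta <- list(plant_id = img$plant_id, ambient_temp = img$ambient_temp,
               n_rows = nrow(img$pixels), n_cols = ncol(img$pixels),
               format = format)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  if (format == "float32") {
    writeBin(as.numeric(t(img$pixels)), path, size = 4L, endian = "little")
  } else {
    lines <- apply(img$pixels, 1L, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = ","))
    writeLines(lines, path)
  }
  invisible(path)
}
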