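# File I/O: delimited grid export/import, PNG rendering, result export with
# provenance.

#' Write / read a grid as delimited text
#'
#' One CSV row per grid row, preceded by comment lines (`#`) recording the
#' name and units; round-trips exactly at full double precision.
#'
#' @param grid Numeric matrix.
#' @param path File path.
#' @param name Identifier written to the header.
#' @param units Units note written to the header.
#' @return `write_grid` returns `path` invisibly; `read_grid` the matrix
#'   with attributes `name` and `units`.
#' @export
write_grid <- function(grid, path, name = "grid", units = "unitless") {
  stopifnot(is.matrix(grid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# name: %s", name), con)
  writeLines(sprintf("# units: %s", units), con)
  utils::write.table(format(grid, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- sub("^# *", "", lines[hdr])
  m <- as.matrix(utils::read.csv(text = lines[!hdr], header = FALSE))
  dimnames(m) <- NULL
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1])) else NA
  }
  attr(m, "name") <- get_field("name")
  attr(m, "units") <- get_field("units")
  m
}

#' Export a grid as a PNG image
#'
#' Linear gray mapping from `zlim[1]` (black) to `zlim[2]` (white), one
#' image pixel per grid cell times `scale`.
#'
#' @param grid Numeric matrix.
#' @param path Output PNG path.
#' @param zlim Values mapped to black/white; defaults to the grid range.
#' @param scale Pixels per cell.
#' @return `path`, invisibly.
#' @export
write_grid_png <- function(grid, path, zlim = range(grid), scale = 16L) {
  stopifnot(is.matrix(grid))
  if (diff(zlim) == 0) zlim <- zlim + c(-0.5, 0.5)
  g <- (grid - zlim[1]) / diff(zlim)
  g <- pmin(pmax(g, 0), 1)
  grDevices::png(path, width = ncol(grid) * scale, height = nrow(grid) * scale)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(g[nrow(g):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1), zlim = c(0, 1),
                  useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Export a decomposition with provenance
#'
#' Writes paired CSV grids (illuminance, reflectance) and a JSON sidecar
#' holding energy, iteration count, convergence flag and the parameter
#' hash, plus optional PNG renderings.
#'
#' @param fit A `mir_fit`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the stimulus name.
#' @param png Also write PNG renderings?
#' @return The sidecar path, invisibly.
#' @export
export_fit <- function(fit, dir, stem = NULL, png = FALSE) {
  stopifnot(inherits(fit, "mir_fit"))
  if (is.null(stem)) {
    stem <- if (!is.null(fit$stimulus)) fit$stimulus$name else "decomposition"
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(fit$illuminance, file.path(dir, paste0(stem, "_illuminance.csv")),
             name = paste0(stem, " illuminance"), units = "model lux")
  write_grid(fit$reflectance, file.path(dir, paste0(stem, "_reflectance.csv")),
             name = paste0(stem, " reflectance"), units = "fraction")
  if (png) {
    write_grid_png(fit$luminance, file.path(dir, paste0(stem, "_luminance.png")))
    write_grid_png(log10(fit$illuminance),
                   file.path(dir, paste0(stem, "_illuminance.png")))
    write_grid_png(fit$reflectance, file.path(dir, paste0(stem, "_reflectance.png")),
                   zlim = c(0, 1))
  }
  sidecar <- file.path(dir, paste0(stem, "_result.json"))
  jsonlite::write_json(
    list(stimulus = stem, energy = fit$energy, iterations = fit$iterations,
         converged = fit$converged, method = fit$method,
         params_hash = params_hash(fit$params)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
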