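## TIFF stack and axon-trace I/O

#' Write a rendered stack as a multi-page 32-bit float TIFF
#'
#' Voxel intensities are scaled into [0, 1] for storage; the scale factor,
#' pixel size, z-step and z origin are stored in a JSON sidecar
#' (`<path>.json`) so [read_stack_tiff()] can restore intensities and
#' geometry. The write-read cycle is exact at 32-bit float precision and
#' idempotent thereafter.
#'
#' @param stack a `rendered_stack`
#' @param path output file (`.tif`); metadata goes to `<path>.json`
#' @return `path`, invisibly
#' @export
write_stack_tiff <- function(stack, path) {
  vox <- stack$vox
  ## power-of-two scale keeps the unscaling exact in binary floating point
  sc <- 2^ceiling(log2(max(vox, 1e-12)))
  meta <- list(intensity_scale = sc,
               pixel_size_um = stack$spec$pixel_size,
               z_step_um = stack$spec$z_step,
               z0_um = stack$z_values_um[1],
               segment_id = stack$segment_id, day = stack$day)
  ## pre-quantise onto the codec's 32-bit grid (it truncates on write and
  ## rescales by 2^32 on read); the half-quantum bias makes the write-read
  ## cycle exact and idempotent
  D <- 2^32
  pages <- lapply(seq_len(dim(vox)[3]), function(z) {
    k <- pmin(round(pmax(vox[, , z], 0) / sc * D), D - 1)
    (k + 0.5) / (D - 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF file
#' @param spec optional [imaging_spec()] to attach; geometry fields are
#'   overridden by the file's metadata
#' @return a `rendered_stack` (without a trace; attach one from SWC/CSV)
#' @export
read_stack_tiff <- function(path, spec = imaging_spec()) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else
    list(intensity_scale = 1)
  spec$pixel_size <- meta$pixel_size_um %||% spec$pixel_size
  spec$z_step <- meta$z_step_um %||% spec$z_step
  nz <- length(pages)
  vox <- array(0, c(dim(pages[[1]])[1:2], nz))
  for (k in seq_len(nz)) vox[, , k] <- pages[[k]][, , drop = TRUE] *
      meta$intensity_scale
  z0 <- meta$z0_um %||% 0
  structure(list(vox = vox, spec = spec, trace = NULL,
                 z_values_um = z0 + (seq_len(nz) - 1) * spec$z_step,
                 segment_id = meta$segment_id %||% NA,
                 day = meta$day %||% NA, seed = NA),
            class = "rendered_stack")
}

#' Write an axon trace as SWC
#'
#' Standard seven-column SWC with structure type 2 (axon), radius 0.3 um,
#' each point parented to the previous one.
#'
#' @param trace data frame with `x_um`, `y_um`, `z_um`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trace_swc <- function(trace, path) {
  n <- nrow(trace)
  lines <- c("# SWC axon backbone trace (um)",
             sprintf("%d 2 %.4f %.4f %.4f 0.3 %d",
                     seq_len(n), trace$x_um, trace$y_um, trace$z_um,
                     c(-1L, seq_len(n - 1))))
  writeLines(lines, path)
  invisible(path)
}

#' Read an axon trace from SWC or ordered CSV
#'
#' SWC files are recognised by extension `.swc` (seven whitespace-separated
#' columns, comments with `#`); anything else is read as a CSV with columns
#' `x_um`, `y_um`, `z_um`.
#'
#' @param path input file
#' @return data frame with `arc_um`, `x_um`, `y_um`, `z_um`
#' @export
read_trace <- function(path) {
  if (grepl("\\.swc$", path, ignore.case = TRUE)) {
    tab <- utils::read.table(path, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
    tr <- data.frame(x_um = tab$x, y_um = tab$y, z_um = tab$z)
  } else {
    tab <- utils::read.csv(path)
    tr <- data.frame(x_um = tab$x_um, y_um = tab$y_um, z_um = tab$z_um)
  }
  tr$arc_um <- c(0, cumsum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 +
                                  diff(tr$z_um)^2)))
  tr[, c("arc_um", "x_um", "y_um", "z_um")]
}
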