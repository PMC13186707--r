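#' Write an image stack as a multi-page TIFF
#'
#' One 16-bit page per z plane. Photon counts are integers well below the
#' 16-bit ceiling, so the round trip through [read_image_stack()] is
#' voxel-exact.
#'
#' @param stack an [image_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  .check(inherits(stack, "image_stack"), "stack must be an image_stack")
  counts <- stack$counts
  .check(max(counts) <= 65535, "photon counts exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(counts)[1]), function(z) counts[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_stack()]
#'
#' @param path `.tif` path.
#' @param pixel_size_um,z_step_um,channel,frame,day metadata to attach
#'   (normally supplied from the manifest).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_um = 0.045, z_step_um = 0.3,
                             channel = "GFP", frame = 0L, day = "day1") {
  .check(file.exists(path), sprintf("TIFF not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  counts <- array(0L, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) counts[z, , ] <- pages[[z]]
  image_stack(counts, pixel_size_um, z_step_um, channel, frame, day)
}

#' Write the acquisition manifest for a set of stacks
#'
#' @param stacks list of [image_stack()] objects.
#' @param files character vector of TIFF paths, parallel to `stacks` (stored
#'   as given; keep them relative to the manifest's directory for portable
#'   runs).
#' @param path output manifest CSV path.
#' @param frame_interval_min frame interval metadata, minutes.
#' @return `path`, invisibly.
#' @export
write_image_manifest <- function(stacks, files, path,
                                 frame_interval_min = 10) {
  .check(length(stacks) == length(files), "one file per stack required")
  rows <- do.call(rbind, lapply(seq_along(stacks), function(i) {
    s <- stacks[[i]]
    data.frame(file = files[i], channel = s$channel, frame = s$frame,
               z_planes = dim(s$counts)[1], pixel_size_um = s$pixel_size_um,
               z_step_um = s$z_step_um,
               frame_interval_min = frame_interval_min, day = s$day,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate an acquisition manifest
#'
#' Checks that every referenced TIFF exists, that all stacks of one channel
#' share a shape, and that the (channel, frame) grid carries consistent
#' metadata; loads the stacks.
#'
#' @param path manifest CSV path (TIFF paths are resolved relative to it).
#' @return list with `manifest` (the validated data.frame) and `stacks`
#'   (list of [image_stack()], in manifest row order).
#' @export
read_image_manifest <- function(path) {
  .check(file.exists(path), sprintf("manifest not found: %s", path))
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "channel", "frame", "z_planes", "pixel_size_um",
            "z_step_um", "frame_interval_min", "day")
  .check(all(need %in% names(man)),
         paste("manifest missing columns:",
               paste(setdiff(need, names(man)), collapse = ", ")))
  base <- dirname(path)
  stacks <- vector("list", nrow(man))
  shapes <- list()
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$file[i])
    if (!file.exists(f))
      stop(sprintf("manifest row %d: file not found: %s", i, man$file[i]),
           call. = FALSE)
    s <- read_image_stack(f, man$pixel_size_um[i], man$z_step_um[i],
                          man$channel[i], man$frame[i], man$day[i])
    if (dim(s$counts)[1] != man$z_planes[i])
      stop(sprintf("manifest row %d: expected %d z-planes, found %d", i,
                   man$z_planes[i], dim(s$counts)[1]), call. = FALSE)
    ch <- man$channel[i]
    shp <- dim(s$counts)[-1]
    if (!is.null(shapes[[ch]]) && !all(shapes[[ch]] == shp))
      stop(sprintf("manifest row %d: channel %s shape mismatch", i, ch),
           call. = FALSE)
    shapes[[ch]] <- shp
    stacks[[i]] <- s
  }
  list(manifest = man, stacks = stacks)
}

# CSV with reproducibility header comments; read back with
# read_pipeline_table (comment.char = "#")
.write_table_commented <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", c(paste("apopore", packageVersion("apopore")),
                               meta)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table
#'
#' Skips the `#` reproducibility header lines written by [run_pipeline()].
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_pipeline_table <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
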