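# File I/O: minimal baseline TIFF (uncompressed, grayscale, 32-bit float),
# track tables, calibration and configuration serialization.
#
# No TIFF package ships with the supported environment, so a small
# single-strip baseline-TIFF codec is included. It covers exactly what the
# package writes: uncompressed little-endian grayscale pages, 32-bit
# floating-point samples.

#' Write matrices as a multi-page TIFF
#'
#' Uncompressed grayscale baseline TIFF, one page per matrix, 32-bit float
#' samples, little-endian.
#'
#' @param images a matrix or list of equally shaped matrices.
#' @param path output file.
#' @export
write_tiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("II", con, eos = NULL)
  w16(42)
  # layout: header(8) | page data... | IFDs...
  sizes <- vapply(images, length, integer(1)) * 4L
  data_off <- 8L + cumsum(c(0L, sizes[-length(sizes)]))
  ifd_base <- 8L + sum(sizes)
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  w32(ifd_base)  # offset of first IFD
  seek(con, 8)
  for (img in images) {
    writeBin(as.numeric(as.vector(t(img))), con, size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3 && count == 1) { w16(value); w16(0) } else w32(value)
  }
  for (i in seq_along(images)) {
    img <- images[[i]]
    seek(con, ifd_base + (i - 1L) * ifd_size)
    w16(n_entries)
    entry(256, 3, 1, ncol(img))          # ImageWidth
    entry(257, 3, 1, nrow(img))          # ImageLength
    entry(258, 3, 1, 32)                 # BitsPerSample
    entry(259, 3, 1, 1)                  # Compression: none
    entry(262, 3, 1, 1)                  # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[i])        # StripOffsets
    entry(278, 3, 1, nrow(img))          # RowsPerStrip
    entry(279, 4, 1, sizes[i])           # StripByteCounts
    entry(339, 3, 1, 3)                  # SampleFormat: IEEE float
    w32(if (i < length(images)) ifd_base + i * ifd_size else 0L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports the subset of baseline TIFF the package emits: little-endian,
#' uncompressed, single strip per page, 8/16/32-bit unsigned or 32-bit float
#' samples.
#'
#' @param path input file.
#' @return List of numeric matrices.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(raw[1:2]), "II"))
    stop("unsupported TIFF: only little-endian files are handled")
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2)
      val <- if (type == 3) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- val
    }
    width <- tags[["256"]]; height <- tags[["257"]]
    bits <- tags[["258"]] %||% 8
    if ((tags[["259"]] %||% 1) != 1) stop("unsupported TIFF: compressed data")
    off <- tags[["273"]]
    fmt <- tags[["339"]] %||% 1
    npx <- width * height
    bytes <- raw[off + seq_len(npx * bits / 8)]
    v <- if (fmt == 3) {
      readBin(bytes, "numeric", n = npx, size = 4, endian = "little")
    } else {
      readBin(bytes, "integer", n = npx, size = bits / 8, signed = bits < 32,
              endian = "little")
    }
    pages[[length(pages) + 1]] <- matrix(v, nrow = height, ncol = width,
                                         byrow = TRUE)
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  pages
}

#' Write a multifocal recording as TIFF
#'
#' Either a multi-page stack (pages ordered plane 1..k per timepoint) or a
#' single-page 2 x 2 quadrant tile per timepoint (plane 1 top-left, 2
#' top-right, 3 bottom-left, 4 bottom-right), matching the image-splitter
#' geometry.
#'
#' @param frames list of [multifocal_frame()]s.
#' @param path output file.
#' @param layout "stack" or "tiled" (tiled requires exactly 4 planes).
#' @export
write_multifocal_tiff <- function(frames, path, layout = c("stack", "tiled")) {
  layout <- match.arg(layout)
  if (layout == "stack") {
    pages <- unlist(lapply(frames, function(fr) fr$planes), recursive = FALSE)
  } else {
    pages <- lapply(frames, function(fr) {
      if (length(fr$planes) != 4) stop("tiled layout needs exactly 4 planes")
      rbind(cbind(fr$planes[[1]], fr$planes[[2]]),
            cbind(fr$planes[[3]], fr$planes[[4]]))
    })
  }
  write_tiff(pages, path)
}

#' Read a multifocal TIFF back into frames
#'
#' @param path input file.
#' @param plane_offsets focal offsets (um) to attach.
#' @param layout "stack" (consecutive pages per timepoint) or "tiled"
#'   (single 2 x 2 page per timepoint).
#' @param pixel_pitch um per px.
#' @param frame_rate frames per second (sets timestamps).
#' @return List of [multifocal_frame()]s.
#' @export
read_multifocal_tiff <- function(path, plane_offsets,
                                 layout = c("stack", "tiled"),
                                 pixel_pitch = 11 / 32, frame_rate = 500) {
  layout <- match.arg(layout)
  pages <- read_tiff(path)
  k <- length(plane_offsets)
  if (layout == "stack") {
    n_t <- length(pages) / k
    if (n_t != floor(n_t)) stop("page count is not a multiple of the plane count")
    lapply(seq_len(n_t), function(ti) {
      multifocal_frame(pages[(ti - 1) * k + seq_len(k)], plane_offsets,
                       timestamp = (ti - 1) / frame_rate,
                       pixel_pitch = pixel_pitch)
    })
  } else {
    lapply(seq_along(pages), function(ti) {
      p <- pages[[ti]]
      hy <- nrow(p) / 2; hx <- ncol(p) / 2
      planes <- list(p[1:hy, 1:hx], p[1:hy, hx + 1:hx],
                     p[hy + 1:hy, 1:hx], p[hy + 1:hy, hx + 1:hx])
      multifocal_frame(planes, plane_offsets,
                       timestamp = (ti - 1) / frame_rate,
                       pixel_pitch = pixel_pitch)
    })
  }
}

#' Write / read bead tracks as CSV
#'
#' Columns: track_id, frame, t_s, x_um, y_um, z_um, sigma_z_um,
#' n_planes_used, excluded_reason.
#'
#' @param tracks data frame (e.g. from [link_tracks()], possibly augmented).
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  d <- as.data.frame(tracks)
  out <- data.frame(
    track_id = d$track,
    frame = d$frame,
    t_s = d$t %||% d$frame,
    x_um = d$x, y_um = d$y, z_um = d$z,
    sigma_z_um = if ("sigma_z" %in% names(d)) d$sigma_z else NA_real_,
    n_planes_used = if ("n_planes" %in% names(d)) d$n_planes else NA_integer_,
    excluded_reason = if ("reason" %in% names(d)) d$reason else "")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(track = d$track_id, frame = d$frame, t = d$t_s,
             x = d$x_um, y = d$y_um, z = d$z_um,
             sigma_z = d$sigma_z_um, n_planes = d$n_planes_used,
             reason = d$excluded_reason)
}

#' Serialize a radius calibration to JSON
#'
#' @param calibration a [build_radius_calibration()] result.
#' @param path file path.
#' @export
write_radius_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "radius_calibration"))
  obj <- lapply(calibration, function(x) {
    if (is.matrix(x)) {
      x[!is.finite(x)] <- NA
      unclass(as.data.frame(x))
    } else x
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_radius_calibration
#' @export
read_radius_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(x) {
    m <- as.matrix(as.data.frame(x))
    m[is.na(m)] <- Inf
    dimnames(m) <- NULL
    m
  }
  structure(list(z = obj$z, r = to_mat(obj$r), sigma_r = to_mat(obj$sigma_r),
                 sigma_z = to_mat(obj$sigma_z), offsets = obj$offsets),
            class = "radius_calibration")
}

#' Read / write configuration as YAML
#'
#' @param path file path.
#' @param config named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Serialize a registration model to JSON
#'
#' @param model a [registration_model()].
#' @param path file path.
#' @export
write_registration_json <- function(model, path) {
  stopifnot(inherits(model, "registration_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_registration_json
#' @export
read_registration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  registration_model(lapply(obj$transforms, function(tr) {
    list(scale = tr$scale, theta = tr$theta, tx = tr$tx, ty = tr$ty)
  }), residual_px = unlist(obj$residual_px))
}
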