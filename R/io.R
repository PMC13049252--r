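#' Write a k-space series to the package's container format
#'
#' Single-file binary container: a JSON header (dataset names, shapes,
#' dtypes, geometry attributes) followed by little-endian float64 payloads.
#' Logical dataset layout: \code{/kspace/data} (frames x coils x samples,
#' complex stored as interleaved re/im), \code{/kspace/frame_signs},
#' \code{/kspace/ti_values_ms}, \code{/traj/coords} (frames x samples x 2,
#' cycles/FOV), \code{/traj/dcf}, with attributes \code{fov_mm},
#' \code{res_mm}, \code{readout_ms}.
#'
#' @param kspace a \code{kspace_series}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "kspace_series"))
  traj <- kspace$traj
  nf <- dim(kspace$data)[1]
  ga <- kspace$angles_deg
  coords <- array(0, dim = c(nf, length(traj$kx), 2))
  for (f in seq_len(nf)) {
    th <- ga[f] * pi / 180
    coords[f, , 1] <- cos(th) * traj$kx - sin(th) * traj$ky
    coords[f, , 2] <- sin(th) * traj$kx + cos(th) * traj$ky
  }
  sch <- kspace$schedule
  datasets <- list(
    "/kspace/data" = list(x = kspace$data, complex = TRUE),
    "/kspace/frame_signs" = list(x = kspace$frame_signs, complex = FALSE),
    "/kspace/ti_values_ms" = list(x = sch$ti_values_ms, complex = FALSE),
    "/traj/coords" = list(x = coords, complex = FALSE),
    "/traj/dcf" = list(x = traj$dcf, complex = FALSE),
    "/traj/t_ms" = list(x = traj$t_ms, complex = FALSE),
    "/traj/r" = list(x = traj$r, complex = FALSE)
  )
  header <- list(
    format = "spiralT1-kspace-v1",
    attrs = list(fov_mm = traj$fov_mm, res_mm = traj$res_mm,
                 readout_ms = traj$readout_ms,
                 first_ti_ms = sch$first_ti_ms, delta_ti_ms = sch$delta_ti_ms,
                 n_acquired = sch$n_acquired, n_appended = sch$n_appended,
                 n_prepended = sch$n_prepended),
    frame_roles = kspace$frame_roles,
    angles_deg = ga,
    datasets = lapply(datasets, function(d)
      list(dim = if (is.null(dim(d$x))) length(d$x) else dim(d$x),
           complex = d$complex))
  )
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(hjson))
  writeBin(length(hraw), con, size = 8, endian = "little")
  writeBin(hraw, con)
  for (d in datasets) {
    v <- as.vector(d$x)
    if (d$complex) {
      buf <- numeric(2 * length(v))
      buf[c(TRUE, FALSE)] <- Re(v)
      buf[c(FALSE, TRUE)] <- Im(v)
      writeBin(buf, con, size = 8, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

#' Read a k-space series from the package's container format
#'
#' @param path file written by \code{\link{write_kspace}}.
#' @return a \code{kspace_series} (with a reconstructed trajectory object).
#' @export
read_kspace <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  if (!identical(header$format, "spiralT1-kspace-v1"))
    stop("not a spiralT1 k-space container")
  read_ds <- function(meta) {
    nelem <- prod(meta$dim)
    if (isTRUE(meta$complex)) {
      buf <- readBin(con, "numeric", 2 * nelem, size = 8, endian = "little")
      v <- complex(real = buf[c(TRUE, FALSE)], imaginary = buf[c(FALSE, TRUE)])
    } else {
      v <- readBin(con, "numeric", nelem, size = 8, endian = "little")
    }
    if (length(meta$dim) > 1) dim(v) <- meta$dim
    v
  }
  ds <- lapply(header$datasets, read_ds)
  at <- header$attrs
  sch <- ti_schedule(at$first_ti_ms, at$delta_ti_ms, at$n_acquired,
                     at$n_appended, at$n_prepended)
  traj <- structure(list(
    kx = ds[["/traj/coords"]][1, , 1], ky = ds[["/traj/coords"]][1, , 2],
    r = ds[["/traj/r"]], t_ms = ds[["/traj/t_ms"]], dcf = ds[["/traj/dcf"]],
    fov_mm = at$fov_mm, res_mm = at$res_mm,
    matrix = round(at$fov_mm / at$res_mm), readout_ms = at$readout_ms,
    profile = NULL), class = "spiral_trajectory")
  structure(list(data = ds[["/kspace/data"]],
                 frame_signs = ds[["/kspace/frame_signs"]],
                 schedule = sch, traj = traj,
                 angles_deg = header$angles_deg,
                 frame_roles = header$frame_roles),
            class = "kspace_series")
}

#' Write an image series as 4D NIfTI
#'
#' Frames become the 4th dimension. Complex series are written as two files,
#' magnitude and signed-real (after global phase alignment); real series as
#' one.
#'
#' @param series an \code{\link{image_series}}.
#' @param path output path (\code{.nii} / \code{.nii.gz}); for complex input
#'   the suffixes \code{_mag} and \code{_real} are inserted.
#' @return invisibly, character vector of files written.
#' @export
write_series_nifti <- function(series, path) {
  dat <- series$data
  nf <- dim(dat)[1]; n1 <- dim(dat)[2]; n2 <- dim(dat)[3]
  res <- if (is.na(series$res_mm)) 1 else series$res_mm
  tovol <- function(a) {
    vol <- array(0, dim = c(n1, n2, 1, nf))
    for (f in seq_len(nf)) vol[, , 1, f] <- a[f, , ]
    vol <- RNifti::asNifti(vol)
    RNifti::pixdim(vol) <- c(res, res, 1, 1)
    vol
  }
  if (is.complex(dat)) {
    sr <- signed_real_series(series)
    base <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- sub(paste0("^", gsub("([.$^\\\\])", "\\\\\\1", base)), "", path)
    if (identical(ext, path)) ext <- ".nii"
    f1 <- paste0(base, "_mag", ext); f2 <- paste0(base, "_real", ext)
    RNifti::writeNifti(tovol(abs(dat)), f1)
    RNifti::writeNifti(tovol(sr$data), f2)
    invisible(c(f1, f2))
  } else {
    RNifti::writeNifti(tovol(dat), path)
    invisible(path)
  }
}

#' Read a 4D NIfTI file into an image series
#'
#' @param path NIfTI file with frames in the 4th (or 3rd) dimension.
#' @return an \code{\link{image_series}}.
#' @export
read_series_nifti <- function(path) {
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) == 4) {
    nf <- d[4]
    dat <- array(0, dim = c(nf, d[1], d[2]))
    for (f in seq_len(nf)) dat[f, , ] <- vol[, , 1, f]
  } else if (length(d) == 3) {
    nf <- d[3]
    dat <- array(0, dim = c(nf, d[1], d[2]))
    for (f in seq_len(nf)) dat[f, , ] <- vol[, , f]
  } else stop("expected a 3D or 4D NIfTI volume")
  px <- attr(vol, "pixdim")
  image_series(dat, res_mm = if (!is.null(px)) px[1] else NA)
}

#' Write per-vessel T1 fit results to CSV
#'
#' @param fits named list of \code{\link{fit_ir_t1}} results (names become
#'   vessel ids).
#' @param path output CSV path.
#' @return invisibly, the data frame written.
#' @export
write_fit_csv <- function(fits, path) {
  df <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(vessel = if (!is.null(names(fits))) names(fits)[i] else i,
               t1_ms = f$t1_ms, m0 = f$m0, minit = f$minit,
               r_squared = f$r_squared,
               ci95_width_ms = 2 * f$ci95_halfwidth_ms,
               excluded = f$excluded)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
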