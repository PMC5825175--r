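#' Build a hexagonal stimulating-electrode array
#'
#' Constructs the geometry of a planar multi-electrode array with electrodes
#' on a hexagonal lattice, mirroring the 20-electrode platinum array used for
#' epiretinal white-noise stimulation: 1 mm centre-to-centre pitch, 400 um
#' electrode diameter, total footprint approximately 3.5 x 3.5 mm.
#'
#' For electrode counts that fill concentric hexagonal rings exactly
#' (1, 7, 19, 37, ...) the array is laid out as a compact hexagon around the
#' centre; otherwise rows of an offset (hexagonal) lattice are filled to give
#' a near-square footprint.  The array is centred on its centroid and then
#' translated so that centroid sits at `recording_loc`: unless stated
#' otherwise the recording site is taken to be the middle of the array.
#'
#' @param n_electrodes Number of electrodes (>= 1).
#' @param pitch_mm Centre-to-centre spacing between nearest neighbours, mm.
#' @param diameter_um Electrode diameter, micrometres (metadata only).
#' @param recording_loc Length-2 numeric, (x, y) of the recording site in mm.
#'
#' @return A tibble of class `electrode_array` with columns `electrode`
#'   (label `e01`, `e02`, ...), `x_mm`, `y_mm`, and attributes `pitch_mm`,
#'   `diameter_um`, `recording_loc`.
#' @examples
#' arr <- make_electrode_array(20)
#' diff(range(arr$x_mm))  # ~3.5 mm
#' @export
make_electrode_array <- function(n_electrodes = 20, pitch_mm = 1,
                                 diameter_um = 400,
                                 recording_loc = c(0, 0)) {
  n <- check_count(n_electrodes, "n_electrodes")
  pitch <- check_positive(pitch_mm, "pitch_mm")
  stopifnot(length(recording_loc) == 2, is.numeric(recording_loc))

  if (n == 1) {
    pos <- matrix(0, 1, 2)
  } else if (is_centered_hexagonal(n)) {
    pos <- hex_rings(n) * pitch
  } else {
    pos <- hex_rows(n) * pitch
  }
  # centre on centroid, then translate to the recording location
  pos <- sweep(pos, 2, colMeans(pos))
  pos <- sweep(pos, 2, as.numeric(recording_loc), `+`)

  out <- tibble::tibble(
    electrode = sprintf("e%02d", seq_len(n)),
    x_mm = pos[, 1],
    y_mm = pos[, 2]
  )
  attr(out, "pitch_mm") <- pitch
  attr(out, "diameter_um") <- check_positive(diameter_um, "diameter_um")
  attr(out, "recording_loc") <- as.numeric(recording_loc)
  class(out) <- c("electrode_array", class(out))
  out
}

is_centered_hexagonal <- function(n) {
  k <- (-3 + sqrt(9 + 12 * (n - 1))) / 6
  n > 1 && abs(k - round(k)) < 1e-9
}

# Concentric rings of a unit hex lattice: centre + rings of 6k points.
hex_rings <- function(n) {
  pts <- matrix(0, 1, 2)
  ring <- 1
  while (nrow(pts) < n) {
    # walk the hexagon ring at radius `ring`
    corners <- t(vapply(0:5, function(i) {
      a <- pi / 3 * i
      ring * c(cos(a), sin(a))
    }, numeric(2)))
    ringpts <- do.call(rbind, lapply(1:6, function(i) {
      from <- corners[i, ]
      to <- corners[if (i == 6) 1 else i + 1, ]
      t(vapply(0:(ring - 1), function(s) from + (to - from) * s / ring,
               numeric(2)))
    }))
    pts <- rbind(pts, ringpts)
    ring <- ring + 1
  }
  pts[seq_len(n), , drop = FALSE]
}

# Row-filled offset lattice, near-square footprint (rows sqrt(3)/2 apart,
# alternate rows shifted by half a pitch).
hex_rows <- function(n) {
  n_cols <- max(2L, round(sqrt(n * sqrt(3) / 2)))
  n_rows <- ceiling(n / n_cols)
  pos <- matrix(NA_real_, n_rows * n_cols, 2)
  k <- 1
  for (r in seq_len(n_rows) - 1) {
    for (c in seq_len(n_cols) - 1) {
      pos[k, ] <- c(c + (r %% 2) / 2, r * sqrt(3) / 2)
      k <- k + 1
    }
  }
  pos[seq_len(n), , drop = FALSE]
}

#' Pairwise distances from electrodes to the recording site
#' @param array An `electrode_array`.
#' @return Numeric vector of distances in mm, one per electrode.
#' @export
electrode_distances <- function(array) {
  rec <- attr(array, "recording_loc")
  sqrt((array$x_mm - rec[1])^2 + (array$y_mm - rec[2])^2)
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf(
    "<electrode_array> %d electrodes, pitch %.3g mm, diameter %.3g um\n",
    nrow(x), attr(x, "pitch_mm"), attr(x, "diameter_um")
  ))
  NextMethod()
}
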