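#' Canonical 10-20 channel order and naming
#'
#' The pipeline works on the classic 19-electrode 10-20 montage. Both the
#' older temporal/posterior names (T3, T4, T5, T6) and the modern ones
#' (T7, T8, P7, P8) are accepted; internally everything is normalized to
#' the older set, in a fixed canonical order.
#'
#' @return Character vector of the 19 canonical labels, in canonical order.
#' @export
eegic_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

.chan_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize 10-20 channel labels
#'
#' Case-insensitive; maps modern aliases (T7/T8/P7/P8) onto the canonical
#' older names.
#'
#' @param labels character vector of electrode names.
#' @return Canonical labels, same length and order as the input.
#' @export
normalize_labels <- function(labels) {
  canon <- eegic_channels()
  lut <- c(stats::setNames(canon, toupper(canon)),
           stats::setNames(unname(.chan_aliases), toupper(names(.chan_aliases))))
  key <- toupper(trimws(labels))
  hit <- lut[key]
  if (anyNA(hit)) {
    stop("montage error: unknown channel label(s): ",
         paste(labels[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  unname(hit)
}

# Idealized spherical head: x points to the subject's right, y to the
# nasion, z to the vertex. Electrodes are placed by inclination from the
# vertex and azimuth from the nasion (positive to the right); F3/F4/P3/P4
# are the 10-20 construction's arc midpoints, obtained by spherical
# interpolation so that unit norm and mirror symmetry are exact.
.montage_3d <- function() {
  sph <- function(inc_deg, azi_deg) {
    inc <- inc_deg * pi / 180; azi <- azi_deg * pi / 180
    c(sin(inc) * sin(azi), sin(inc) * cos(azi), cos(inc))
  }
  slerp_mid <- function(a, b) {
    m <- a + b
    m / sqrt(sum(m^2))
  }
  p <- list(
    Fp1 = sph(90, -18), Fp2 = sph(90, 18),
    F7 = sph(90, -54), F8 = sph(90, 54),
    T3 = sph(90, -90), T4 = sph(90, 90),
    T5 = sph(90, -126), T6 = sph(90, 126),
    O1 = sph(90, -162), O2 = sph(90, 162),
    Fz = sph(45, 0), Cz = sph(0, 0), Pz = sph(45, 180),
    C3 = sph(45, -90), C4 = sph(45, 90)
  )
  p$F3 <- slerp_mid(p$Fz, p$F7)
  p$F4 <- slerp_mid(p$Fz, p$F8)
  p$P3 <- slerp_mid(p$Pz, p$T5)
  p$P4 <- slerp_mid(p$Pz, p$T6)
  do.call(rbind, p[eegic_channels()])
}

#' Standard 10-20 montage positions
#'
#' Returns head-centered unit-sphere electrode coordinates together with
#' their 2D projection used for topographic mapping. The projection is
#' azimuthal equidistant (radius proportional to inclination from the
#' vertex), scaled so the outermost 10-20 ring sits at 95% of the unit
#' head disc; the nasion points "up" (+y), so the top of a map is the
#' front of the head.
#'
#' @param channel_labels electrode names (aliases T7/T8/P7/P8 accepted).
#' @param outer_frac fraction of the head-disc radius at which the
#'   90-degree-inclination ring is drawn.
#' @return Object of class `montage_positions`: list with `labels`,
#'   `pos3d` (n x 3, unit rows) and `pos2d` (n x 2).
#' @export
standard_1020_montage <- function(channel_labels = eegic_channels(),
                                  outer_frac = 0.95) {
  labels <- normalize_labels(channel_labels)
  if (anyDuplicated(labels)) {
    stop("montage error: duplicated channel label after alias resolution",
         call. = FALSE)
  }
  all3d <- .montage_3d()
  pos3d <- all3d[labels, , drop = FALSE]
  inc <- acos(pmin(1, pmax(-1, pos3d[, 3])))
  azi <- atan2(pos3d[, 1], pos3d[, 2])
  r2 <- (inc / (pi / 2)) * outer_frac
  pos2d <- cbind(x = r2 * sin(azi), y = r2 * cos(azi))
  structure(list(labels = labels, pos3d = pos3d, pos2d = pos2d),
            class = "montage_positions")
}

#' @export
print.montage_positions <- function(x, ...) {
  cat("<montage_positions> ", length(x$labels), " electrodes: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}
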