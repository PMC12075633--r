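#' Threshold spot detection in the donor channel
#'
#' Spots are local maxima of the time-averaged donor-channel image over the
#' green-segment frames that exceed `threshold` counts. Maxima closer than
#' `min_separation` pixels keep only the brighter one; the result is ordered
#' deterministically by (row, column). Frames with saturated pixels are
#' flagged, not dropped.
#'
#' @param movie a `fret_movie`.
#' @param threshold intensity threshold (counts above which a local maximum
#'   counts as a spot).
#' @param min_separation suppression radius (pixels).
#' @param saturation pixel value treated as saturated.
#' @return data frame of detections: `row`, `col` (0-based pixel
#'   coordinates), `peak` (averaged-image value); attribute
#'   `saturated_frames` lists flagged frames.
#' @export
detect_spots <- function(movie, threshold, min_separation = 5,
                         saturation = 65535) {
  lay <- movie$layout
  green_f <- (lay[1] + 1L):(lay[1] + lay[2])
  donor <- movie$stack[, seq_len(movie$ncol_ch), , drop = FALSE]
  sat <- which(apply(movie$stack, 3, function(fr) any(fr >= saturation)))
  avg <- apply(donor[, , green_f, drop = FALSE], c(1, 2), mean)
  nr <- nrow(avg); nc <- ncol(avg)
  # 8-neighbourhood local maxima (strictly greater than every neighbour,
  # ties broken towards the smaller index by >= on forward neighbours)
  is_max <- matrix(TRUE, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    nb <- matrix(-Inf, nr, nc)
    r_src <- max(1, 1 + dr):min(nr, nr + dr)
    c_src <- max(1, 1 + dc):min(nc, nc + dc)
    nb[r_src - dr, c_src - dc] <- avg[r_src, c_src]
    cmp <- if (dr > 0 || (dr == 0 && dc > 0)) avg >= nb else avg > nb
    is_max <- is_max & cmp
  }
  idx <- which(is_max & avg > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- data.frame(row = numeric(0), col = numeric(0), peak = numeric(0))
    attr(out, "saturated_frames") <- sat
    return(out)
  }
  det <- data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1,
                    peak = avg[idx])
  # suppression: brighter spot wins within min_separation
  det <- det[order(-det$peak), ]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prior <- det[which(keep[seq_len(i - 1)]), , drop = FALSE]
    d <- sqrt((prior$row - det$row[i])^2 + (prior$col - det$col[i])^2)
    keep[i] <- all(d >= min_separation)
  }
  det <- det[keep, , drop = FALSE]
  det <- det[order(det$row, det$col), , drop = FALSE]
  rownames(det) <- NULL
  attr(det, "saturated_frames") <- sat
  det
}

#' Aperture-photometry trace extraction
#'
#' Per-frame circular-aperture sums in both channels around the detected
#' center (the acceptor channel uses the same coordinates shifted by the
#' dual-view channel offset); the background series are per-frame annulus
#' means scaled to the aperture area. `I_AA` is taken from the acceptor
#' channel during red segments. Spot centers are not refit per frame.
#'
#' @param movie a `fret_movie`.
#' @param row,col spot center (0-based pixels in the donor channel).
#' @param aperture aperture radius (pixels).
#' @param annulus inner and outer background-annulus radii (pixels); the
#'   inner radius must exceed the aperture.
#' @param offset integer `(row, col)` offset mapping donor to acceptor
#'   coordinates within the acceptor half (channels assumed pre-aligned).
#' @param trace_id,condition metadata.
#' @return a `fret_trace`.
#' @export
extract_trace <- function(movie, row, col, aperture = 3, annulus = c(5, 8),
                          offset = c(0, 0), trace_id = "spot",
                          condition = "extracted") {
  if (annulus[1] <= aperture) stop("annulus inner radius must exceed aperture")
  nr <- dim(movie$stack)[1]; nc_ch <- movie$ncol_ch
  nf <- dim(movie$stack)[3]
  r0 <- row + 1; c0 <- col + 1  # 1-based center
  rmax <- ceiling(annulus[2])
  if (r0 - rmax < 1 || r0 + rmax > nr || c0 - rmax < 1 || c0 + rmax > nc_ch)
    stop("spot overlaps the frame edge")
  rr <- (r0 - rmax):(r0 + rmax)
  cc <- (c0 - rmax):(c0 + rmax)
  dmat <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
  ap <- dmat <= aperture
  an <- dmat > annulus[1] & dmat <= annulus[2]
  n_ap <- sum(ap)
  sum_region <- function(ch_off, mask, fun) {
    vapply(seq_len(nf), function(f) {
      fun(movie$stack[rr, cc + ch_off, f][mask])
    }, numeric(1))
  }
  don_ap <- sum_region(0L, ap, sum)
  acc_ap <- sum_region(nc_ch + offset[2], ap, sum)
  bg_D <- sum_region(0L, an, mean) * n_ap
  bg_A <- sum_region(nc_ch + offset[2], an, mean) * n_ap
  lay <- movie$layout
  segment <- rep(c("red_head", "green", "red_tail"), times = lay)
  green <- segment == "green"
  I_D <- ifelse(green, don_ap, NA_real_)
  I_A <- ifelse(green, acc_ap, NA_real_)
  I_AA <- ifelse(green, NA_real_, acc_ap)
  out <- data.frame(time_s = (seq_len(nf) - 1) * movie$frame_time,
                    I_D = I_D, I_A = I_A, I_AA = I_AA, segment = segment,
                    bg_D = bg_D, bg_A = bg_A, stringsAsFactors = FALSE)
  attr(out, "trace_id") <- trace_id
  attr(out, "condition") <- condition
  attr(out, "frame_time") <- movie$frame_time
  class(out) <- c("fret_trace", "data.frame")
  out
}

#' Fraction of a Gaussian PSF inside a circular aperture
#'
#' Analytic mass of an isotropic 2-D Gaussian within radius `r`:
#' `1 - exp(-r^2 / (2 sigma^2))`. Used to compare aperture sums with the
#' generating trace on synthetic movies.
#'
#' @param r aperture radius (pixels).
#' @param sigma PSF standard deviation (pixels).
#' @return contained fraction in `[0, 1]`.
#' @export
psf_aperture_fraction <- function(r, sigma) 1 - exp(-r^2 / (2 * sigma^2))
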