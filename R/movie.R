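#' Simulate a dual-view TIRF image stack from traces
#'
#' Renders a two-channel movie mimicking a dual-view splitter: donor channel
#' in the left half, acceptor channel in the right half of every frame. Each
#' spot is a 2-D Gaussian point-spread function whose integrated mass per
#' frame equals the trace's background-subtracted channel counts (donor and
#' FRET acceptor on green frames, acceptor-excitation signal on red frames);
#' a uniform background and Gaussian pixel noise are added on top. Traces
#' should be rendered without their own background/noise (pass a noiseless
#' scenario to [render_trace()]) so the movie owns the noise model.
#'
#' @param traces list of `fret_trace` sharing one ALEX layout.
#' @param positions optional data frame `row`, `col` (continuous pixel
#'   coordinates within the left channel, 0-based); auto-placed on a grid
#'   when `NULL`.
#' @param nrow_px,ncol_px image size per channel (pixels).
#' @param psf_sigma Gaussian PSF standard deviation (pixels).
#' @param bg uniform background level (counts/pixel/frame).
#' @param noise_sd Gaussian pixel noise SD (counts).
#' @param min_separation minimal pairwise spot distance (pixels); closer
#'   placements are an error since downstream extraction could not resolve
#'   them.
#' @param margin minimal distance of spot centers from the channel edge.
#' @param seed integer seed.
#' @return object of class `fret_movie`: list with `stack` (array
#'   `nrow_px x 2*ncol_px x n_frames`), `spots` (true centers), `layout`,
#'   `frame_time`, `ncol_ch`.
#' @export
simulate_movie <- function(traces, positions = NULL, nrow_px = 64L,
                           ncol_px = 64L, psf_sigma = 1.2, bg = 20,
                           noise_sd = 2, min_separation = 8, margin = 10,
                           seed = 1) {
  set.seed(seed)
  n_spots <- length(traces)
  if (is.null(positions)) {
    usable <- function(k) seq(margin, k - 1 - margin,
                              by = max(min_separation, 1))
    gr <- expand.grid(row = usable(nrow_px), col = usable(ncol_px))
    if (nrow(gr) < n_spots) stop("field too small for the requested spots")
    positions <- gr[seq_len(n_spots), , drop = FALSE]
  }
  stopifnot(nrow(positions) == n_spots)
  if (any(positions$row < margin | positions$row > nrow_px - 1 - margin |
          positions$col < margin | positions$col > ncol_px - 1 - margin))
    stop("spot centers must lie at least `margin` pixels inside the field")
  if (n_spots > 1) {
    dmat <- as.matrix(stats::dist(positions[, c("row", "col")]))
    diag(dmat) <- Inf
    if (min(dmat) < min_separation)
      stop("spots closer than min_separation cannot be resolved")
  }
  seg <- traces[[1]]$segment
  nf <- length(seg)
  green <- seg == "green"
  # per-spot, per-frame source counts in each channel
  donor_counts <- matrix(0, n_spots, nf)
  acc_counts <- matrix(0, n_spots, nf)
  for (i in seq_len(n_spots)) {
    tr <- traces[[i]]
    donor_counts[i, green] <- pmax(tr$I_D[green] - tr$bg_D[green], 0)
    acc_counts[i, green] <- pmax(tr$I_A[green] - tr$bg_A[green], 0)
    acc_counts[i, !green] <- pmax(tr$I_AA[!green] - tr$bg_A[!green], 0)
  }
  # pixel-integrated Gaussian masses per spot (exact over pixel edges)
  masses <- lapply(seq_len(n_spots), function(i) {
    r0 <- positions$row[i]; c0 <- positions$col[i]
    rr <- floor(r0 - 5 * psf_sigma):ceiling(r0 + 5 * psf_sigma)
    cc <- floor(c0 - 5 * psf_sigma):ceiling(c0 + 5 * psf_sigma)
    rr <- rr[rr >= 0 & rr < nrow_px]; cc <- cc[cc >= 0 & cc < ncol_px]
    mr <- stats::pnorm(rr + 0.5, r0, psf_sigma) -
      stats::pnorm(rr - 0.5, r0, psf_sigma)
    mc <- stats::pnorm(cc + 0.5, c0, psf_sigma) -
      stats::pnorm(cc - 0.5, c0, psf_sigma)
    list(rows = rr + 1L, cols = cc + 1L, m = outer(mr, mc))
  })
  stack <- array(bg, dim = c(nrow_px, 2L * ncol_px, nf))
  for (f in seq_len(nf)) {
    for (i in seq_len(n_spots)) {
      ms <- masses[[i]]
      if (donor_counts[i, f] > 0)
        stack[ms$rows, ms$cols, f] <- stack[ms$rows, ms$cols, f] +
          donor_counts[i, f] * ms$m
      if (acc_counts[i, f] > 0)
        stack[ms$rows, ms$cols + ncol_px, f] <-
          stack[ms$rows, ms$cols + ncol_px, f] + acc_counts[i, f] * ms$m
    }
  }
  if (noise_sd > 0)
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd),
                           dim = dim(stack))
  layout <- c(sum(seg == "red_head"), sum(green), sum(seg == "red_tail"))
  structure(list(stack = stack,
                 spots = data.frame(id = seq_len(n_spots),
                                    row = positions$row, col = positions$col),
                 layout = layout,
                 frame_time = attr(traces[[1]], "frame_time") %||% 0.2,
                 ncol_ch = ncol_px),
            class = "fret_movie")
}

#' Write / read a dual-view stack as multi-page TIFF
#'
#' Frames are stored as 16-bit pages scaled by `scale` counts per unit;
#' channels remain side by side within each page. Layout and frame time are
#' not stored in the TIFF and must be supplied when reading.
#'
#' @param movie a `fret_movie`.
#' @param path file path.
#' @param scale counts corresponding to full scale.
#' @export
write_movie_tiff <- function(movie, path, scale = 65535) {
  pages <- lapply(seq_len(dim(movie$stack)[3]), function(f)
    pmin(pmax(movie$stack[, , f] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param layout ALEX layout in frames `(red_head, green, red_tail)`.
#' @param frame_time frame duration (s).
#' @export
read_movie_tiff <- function(path, layout, frame_time = 0.2, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nf <- length(pages)
  if (nf != sum(layout)) stop("layout does not match the page count")
  d <- dim(pages[[1]])
  stack <- array(0, dim = c(d[1], d[2], nf))
  for (f in seq_len(nf)) stack[, , f] <- pages[[f]] * scale
  structure(list(stack = stack, spots = NULL, layout = layout,
                 frame_time = frame_time, ncol_ch = d[2] %/% 2L),
            class = "fret_movie")
}
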