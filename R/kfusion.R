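#' Slab transfer function of a single translational scan
#'
#' A translational scan at rotation angle \eqn{\theta} is band-limited
#' along its elevational axis: in 2D k-space it occupies a slab of
#' half-width \code{We} through the origin,
#' \deqn{S(\theta) = \mathrm{step}(k_x\cos\theta - k_y\sin\theta + W_e)
#'   - \mathrm{step}(k_x\cos\theta - k_y\sin\theta - W_e),}
#' i.e. 1 where \eqn{|k_x\cos\theta - k_y\sin\theta| \le W_e} (closed
#' boundary, step(0) = 1) and 0 elsewhere.  \code{k_x} runs along image
#' columns and \code{k_y} along rows (y upward), in cycles per voxel.
#'
#' @param angle_deg slab angle in degrees.
#' @param We elevational cutoff frequency in cycles/voxel, in (0, 0.5].
#' @param grid integer length-2 grid shape (rows, cols).
#' @param centered if \code{TRUE} (default) the zero frequency sits at the
#'   grid centre (row \code{floor(nr/2)+1}); if \code{FALSE} the mask is
#'   laid out in natural FFT order, ready to multiply \code{stats::fft}
#'   output.
#' @return binary matrix of shape \code{grid}.
#' @export
slab_indicator <- function(angle_deg, We = default_we(), grid = c(256, 256),
                           centered = TRUE) {
  check_we(We)
  stopifnot(length(grid) == 2, all(grid >= 1))
  fr <- if (centered) centered_freq(grid[1]) else fft_freq(grid[1])
  fc <- if (centered) centered_freq(grid[2]) else fft_freq(grid[2])
  th <- angle_deg * pi / 180
  # u[r, c] = kx*cos - ky*sin with kx = fc[c], ky = -fr[r] (y upward)
  u <- outer(fr * sin(th), fc * cos(th), "+")
  m <- (abs(u) <= We) * 1
  # Hermitian symmetry: on even grids the Nyquist bin carries both +0.5
  # and -0.5; include it when either sign is inside the slab, so that
  # masked spectra of real images stay conjugate-symmetric (odd axes are
  # already exactly symmetric, where this is a no-op)
  mr <- freq_mirror(grid[1], centered)
  mc <- freq_mirror(grid[2], centered)
  pmax(m, m[mr, mc])
}

# index permutation realising k -> -k (mod n) for either FFT layout
freq_mirror <- function(n, centered) {
  if (n == 1) return(1L)
  if (n %% 2 == 0 || !centered) c(1L, n:2) else n:1
}

#' Default elevational cutoff
#'
#' 0.11 times the Nyquist frequency (0.5 cycles/voxel), reflecting a
#' roughly 9:1 anisotropy between in-plane and elevational resolution of
#' a single translational scan.
#' @return cutoff in cycles/voxel.
#' @export
default_we <- function() 0.055

#' Density-normalised k-space weights
#'
#' Overlapping slabs oversample the centre of k-space.  The fusion weight
#' for angle \eqn{\theta} divides its slab by the total sampling density,
#' \deqn{H(\theta) = S(\theta) / \sum_{\theta'} S(\theta'),}
#' set to 0 where no slab samples (so frequencies outside the union
#' support carry no noise).  The weights sum to 1 on the union support.
#'
#' @param angles vector of slab angles in degrees (distinct).
#' @inheritParams slab_indicator
#' @return list of weight matrices, one per angle, named by angle.
#' @export
density_filter <- function(angles, We = default_we(), grid = c(256, 256),
                           centered = TRUE) {
  if (!length(angles)) stop("'angles' must be non-empty", call. = FALSE)
  S <- lapply(angles, slab_indicator, We = We, grid = grid,
              centered = centered)
  total <- Reduce(`+`, S)
  inv <- ifelse(total > 0, 1 / total, 0)
  H <- lapply(S, function(s) s * inv)
  names(H) <- as.character(angles)
  H
}

#' Simulated single-angle acquisition
#'
#' Idealised stand-in for one reconstructed translational scan: the true
#' image is band-limited to the slab at \code{angle_deg} (multiplication
#' by \eqn{S(\theta)} in k-space) and Gaussian image noise is added.
#' Applying the operator twice at the same angle is idempotent.
#'
#' @param truth_image numeric matrix, the scene at acquisition time.
#' @param angle_deg rotation angle in degrees.
#' @inheritParams slab_indicator
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed seed used when \code{noise_sigma > 0}.
#' @param tomogram_index global 0-based acquisition index (metadata).
#' @return object of class \code{tomogram}: list with \code{image},
#'   \code{angle_deg}, \code{tomogram_index}, \code{noise_sigma}.
#' @export
acquire_tomogram <- function(truth_image, angle_deg, We = default_we(),
                             noise_sigma = 0, seed = 1L,
                             tomogram_index = 0L) {
  if (!all(is.finite(truth_image)))
    stop("'truth_image' must be finite", call. = FALSE)
  mask <- slab_indicator(angle_deg, We, dim(truth_image), centered = FALSE)
  img <- Re(stats::fft(stats::fft(truth_image) * mask, inverse = TRUE)) /
    length(truth_image)
  img <- add_noise(img, noise_sigma, seed)
  structure(list(image = img, angle_deg = angle_deg,
                 tomogram_index = as.integer(tomogram_index),
                 noise_sigma = noise_sigma),
            class = "tomogram")
}

#' Multi-angle k-space fusion
#'
#' Fuses one tomogram per angle into a near-isotropic image: each
#' tomogram is transformed to k-space, weighted by its density-normalised
#' filter \eqn{H(\theta)} and summed, and the uniformly filled spectrum is
#' transformed back, \deqn{\mathrm{fused} = \mathcal{F}^{-1}\!\Big(
#'   \sum_\theta H(\theta)\,\mathcal{F}(\mathrm{tomogram}_\theta)\Big).}
#' Amplitudes are attenuated by the sampling density while phase is
#' preserved; frequencies outside the union slab support are zero.
#'
#' @param tomograms list of [acquire_tomogram()] objects sharing one grid,
#'   with pairwise distinct angles.
#' @inheritParams slab_indicator
#' @return fused real-valued matrix.
#' @export
fuse <- function(tomograms, We = default_we()) {
  stopifnot(length(tomograms) >= 1,
            all(vapply(tomograms, inherits, logical(1), "tomogram")))
  angles <- vapply(tomograms, `[[`, numeric(1), "angle_deg")
  if (anyDuplicated(angles))
    stop("duplicate angles in fusion window", call. = FALSE)
  grid <- dim(tomograms[[1]]$image)
  H <- density_filter(angles, We, grid, centered = FALSE)
  acc <- matrix(0 + 0i, grid[1], grid[2])
  for (i in seq_along(tomograms)) {
    if (!identical(dim(tomograms[[i]]$image), grid))
      stop("tomograms do not share a grid", call. = FALSE)
    acc <- acc + H[[i]] * stats::fft(tomograms[[i]]$image)
  }
  Re(stats::fft(acc, inverse = TRUE)) / prod(grid)
}

#' Simulate a full tomogram stream from a phantom
#'
#' Runs the forward model over an entire acquisition: tomogram \code{m}
#' (0-based) images the phantom at time \code{t = m} (per-voxel decay
#' \code{a*exp(-b*m) + c}) through the slab operator at the plan's
#' \code{m}-th angle, with optional noise.
#'
#' @param phantom a [make_phantom()] object.
#' @param plan a [scan_plan()].
#' @inheritParams acquire_tomogram
#' @return list of \code{n_angles * n_cycles} tomograms.
#' @export
simulate_acquisition <- function(phantom, plan, We = default_we(),
                                 noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(plan, "scan_plan"))
  sched <- acquisition_timestamps(plan)
  lapply(seq_len(nrow(sched)), function(i) {
    acquire_tomogram(phantom_image(phantom, sched$time[i]),
                     sched$angle_deg[i], We,
                     noise_sigma = noise_sigma,
                     seed = seed + sched$tomogram_index[i],
                     tomogram_index = sched$tomogram_index[i])
  })
}

#' Sliding-window fusion into a volume time series
#'
#' Repeats the multi-angle fusion for every window of \code{n_angles}
#' adjacent tomograms in the stream, producing
#' \code{fused_volume_count(n_angles, n_cycles)} images.  Window \code{j}
#' (0-based) fuses tomograms \code{j .. j+n_angles-1} and carries
#' timestamp \code{t = j} (the window start, matching the cycle-integral
#' amplitude model).  Spectra are accumulated incrementally: stepping the
#' window forward swaps one tomogram for the next one at the same angle.
#'
#' @param stream list of tomograms from [simulate_acquisition()] (length
#'   \code{n_angles * n_cycles}, consecutive indices).
#' @param plan a [scan_plan()].
#' @inheritParams slab_indicator
#' @return object of class \code{fused_series}: list with \code{images}
#'   (list of matrices), \code{timestamps}, \code{window_starts} and the
#'   \code{plan}.
#' @export
sliding_fuse <- function(stream, plan, We = default_we()) {
  stopifnot(inherits(plan, "scan_plan"))
  n <- plan$n_angles
  total <- n * plan$n_cycles
  if (length(stream) != total)
    stop("stream length must be n_angles * n_cycles = ", total,
         call. = FALSE)
  grid <- dim(stream[[1]]$image)
  H <- density_filter(plan$angle_sequence_deg, We, grid, centered = FALSE)
  n_vol <- fused_volume_count(plan$n_angles, plan$n_cycles)
  # spectra of all tomograms, computed once
  Fs <- lapply(stream, function(tm) {
    if (!identical(dim(tm$image), grid))
      stop("tomograms do not share a grid", call. = FALSE)
    stats::fft(tm$image)
  })
  images <- vector("list", n_vol)
  acc <- matrix(0 + 0i, grid[1], grid[2])
  for (m in seq_len(n)) acc <- acc + H[[m]] * Fs[[m]]
  images[[1]] <- Re(stats::fft(acc, inverse = TRUE)) / prod(grid)
  if (n_vol > 1) {
    for (j in seq_len(n_vol - 1)) {           # window start j (0-based)
      slot <- (j - 1) %% n + 1                # angle slot being swapped
      acc <- acc + H[[slot]] * (Fs[[j + n]] - Fs[[j]])
      images[[j + 1]] <- Re(stats::fft(acc, inverse = TRUE)) / prod(grid)
    }
  }
  structure(list(images = images,
                 timestamps = as.numeric(0:(n_vol - 1)),
                 window_starts = 0:(n_vol - 1),
                 plan = plan, We = We),
            class = "fused_series")
}

#' @export
print.fused_series <- function(x, ...) {
  g <- dim(x$images[[1]])
  cat("Fused volume series:", length(x$images), "volumes of",
      g[1], "x", g[2], "| We =", x$We, "cycles/voxel\n")
  invisible(x)
}

#' Stack a fused series into an array
#'
#' @param x a \code{fused_series}.
#' @return array (rows, cols, time).
#' @export
as_series_array <- function(x) {
  stopifnot(inherits(x, "fused_series"))
  array(unlist(x$images), dim = c(dim(x$images[[1]]), length(x$images)))
}

# ---- internal ---------------------------------------------------------

check_we <- function(We) {
  if (!is.numeric(We) || length(We) != 1 || We <= 0 || We > 0.5)
    stop("'We' must be in (0, 0.5] cycles/voxel", call. = FALSE)
  invisible(We)
}

# centred frequencies (zero at floor(n/2)+1), cycles/voxel
centered_freq <- function(n) {
  ((seq_len(n) - 1) - floor(n / 2)) / n
}
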