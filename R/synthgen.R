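#' Photobleaching physics parameters
#'
#' Parameters of the per-voxel photoacoustic photobleaching forward model.
#' The instantaneous amplitude is proportional to
#' \eqn{\Gamma \eta_{th} C_0 I \exp(-k I^\beta t)}: the Grueneisen
#' coefficient and thermalisation efficiency enter only as the lumped
#' prefactor \code{gamma_eta}, \code{C0} is the molecular concentration,
#' \code{I} the excitation intensity, and the bleaching rate is
#' \eqn{k I^\beta} with intensity power dependence \eqn{\beta \ge 0}.
#' All quantities are in arbitrary (proportional) units; time is measured
#' in translational scans.
#'
#' @param gamma_eta lumped Grueneisen x thermalisation constant (default 1).
#' @param k_rate bleaching rate constant at unit intensity, per
#'   translational scan.
#' @param beta intensity power dependence, >= 0.
#' @param C0 molecular concentration.
#' @param I excitation intensity.
#' @return object of class \code{phys_params}.
#' @export
phys_params <- function(gamma_eta = 1, k_rate = 0.01, beta = 1,
                        C0 = 1, I = 1) {
  vals <- c(gamma_eta = gamma_eta, k_rate = k_rate, beta = beta,
            C0 = C0, I = I)
  if (any(!is.finite(vals)) || any(vals[c("k_rate", "beta", "C0", "I")] < 0))
    stop("k_rate, beta, C0 and I must be finite and non-negative",
         call. = FALSE)
  structure(as.list(vals), class = "phys_params")
}

#' Instantaneous photoacoustic amplitude under photobleaching
#'
#' Evaluates \eqn{P(t) = \Gamma\eta_{th} C_0 I \exp(-k I^\beta t)} with
#' the proportionality constant fixed at 1.
#'
#' @param phys a [phys_params()].
#' @param t time(s) in translational scans, >= 0.
#' @return amplitude(s), same length as \code{t}.
#' @export
pa_amplitude <- function(phys, t) {
  stopifnot(inherits(phys, "phys_params"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  with(phys, gamma_eta * C0 * I * exp(-k_rate * I^beta * t))
}

#' Cycle-integrated photoacoustic amplitude
#'
#' The amplitude recovered by multi-angle fusion integrates the
#' instantaneous amplitude over one scan cycle of duration \code{T}:
#' \deqn{A(t) = \frac{\Gamma\eta_{th} C_0 I}{k I^\beta}
#'   (1 - e^{-k I^\beta T}) e^{-k I^\beta t},}
#' with the \eqn{k I^\beta \to 0} limit
#' \eqn{\Gamma\eta_{th} C_0 I\, T\, } (integral of a constant).
#'
#' @inheritParams pa_amplitude
#' @param T scan-cycle duration in translational scans, > 0.
#' @return amplitude(s).
#' @export
cycle_amplitude <- function(phys, t, T) {
  stopifnot(inherits(phys, "phys_params"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (T <= 0) stop("'T' must be positive", call. = FALSE)
  rate <- phys$k_rate * phys$I^phys$beta
  pre <- phys$gamma_eta * phys$C0 * phys$I
  if (rate < 1e-12) return(rep(pre * T, length(t)))
  pre / rate * (1 - exp(-rate * T)) * exp(-rate * t)
}

#' Per-voxel bleaching curve
#'
#' The three-parameter decay \eqn{A(t) = a e^{-bt} + c}: bleachable
#' amplitude \code{a} (the fluorescent-tag component), bleaching rate
#' \code{b} per translational scan, unbleachable background \code{c}.
#'
#' @param a,b,c decay parameters (scalars).
#' @param times non-empty vector of non-negative times.
#' @return numeric vector \code{a*exp(-b*times) + c}.
#' @export
bleach_curve <- function(a, b, c, times) {
  if (!length(times) || any(times < 0))
    stop("'times' must be non-empty and non-negative", call. = FALSE)
  a * exp(-b * times) + c
}

#' Digital phantoms for the forward simulation
#'
#' Builds per-voxel maps of the decay parameters (a, b, c) realising a
#' requested geometry on a 2D grid:
#' \describe{
#'   \item{point}{a single bleachable pixel at the grid centre.}
#'   \item{line}{a 1-pixel-wide bleachable line through the centre at
#'     \code{params$orientation_deg} (0 = along the x/column axis).}
#'   \item{bead_field}{\code{params$n} single-pixel bleachable beads at
#'     uniform random positions.}
#'   \item{tube}{a filled bleachable disk of radius
#'     \code{params$radius_px} at the centre (cross-section of a
#'     protein-filled tube).}
#'   \item{blob_brain}{smooth random unbleachable background (tissue)
#'     with \code{params$n_blobs} Gaussian bleachable blobs (labelled
#'     structures).}
#' }
#' Foreground voxels get \code{a = params$a} (default 1) and
#' \code{b = params$b} (default 0.03); background \code{c} defaults to 0
#' except for \code{blob_brain}.
#'
#' @param kind phantom geometry, see Details.
#' @param shape integer length-2 grid shape (rows, cols).
#' @param params list of geometry parameters (see above).
#' @param seed integer seed for the random kinds.
#' @param spacing_mm isotropic voxel spacing in mm (default 0.075).
#' @return object of class \code{phantom}: list with matrices \code{a},
#'   \code{b}, \code{c}, the \code{shape}, \code{spacing_mm} and
#'   optionally a \code{fluence} map.
#' @export
make_phantom <- function(kind = c("point", "line", "bead_field", "tube",
                                  "blob_brain"),
                         shape = c(256, 256), params = list(), seed = 1L,
                         spacing_mm = 0.075) {
  kind <- match.arg(kind)
  stopifnot(length(shape) == 2, all(shape >= 1))
  p <- utils::modifyList(list(a = 1, b = 0.03, c = 0,
                              orientation_deg = 0, n = 10,
                              radius_px = 4, n_blobs = 3), params)
  nr <- shape[1]; nc <- shape[2]
  a <- matrix(0, nr, nc); cc <- matrix(p$c, nr, nc)
  ctr <- c(floor(nr / 2) + 1L, floor(nc / 2) + 1L)
  set.seed(as.integer(seed))
  if (kind == "point") {
    a[ctr[1], ctr[2]] <- p$a
  } else if (kind == "line") {
    a <- line_mask(nr, nc, p$orientation_deg) * p$a
  } else if (kind == "bead_field") {
    if (p$n > 0) {
      pos <- cbind(sample.int(nr, p$n, replace = TRUE),
                   sample.int(nc, p$n, replace = TRUE))
      a[unique(pos, MARGIN = 1)] <- p$a
    }
  } else if (kind == "tube") {
    d2 <- outer((seq_len(nr) - ctr[1])^2, (seq_len(nc) - ctr[2])^2, "+")
    a[d2 <= p$radius_px^2] <- p$a
  } else if (kind == "blob_brain") {
    # smooth tissue background: low-frequency random field, positive
    bg <- matrix(stats::rnorm(nr * nc), nr, nc)
    bg <- Re(stats::fft(stats::fft(bg) * gauss_lowpass(nr, nc, 0.03),
                        inverse = TRUE)) / (nr * nc)
    cc <- (bg - min(bg)) / (max(bg) - min(bg) + 1e-12) * 0.5 + 0.25
    x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    y <- matrix(rep(seq_len(nr), nc), nr, nc)
    for (i in seq_len(p$n_blobs)) {
      cx <- stats::runif(1, nc * 0.25, nc * 0.75)
      cy <- stats::runif(1, nr * 0.25, nr * 0.75)
      s <- stats::runif(1, 2, max(2, min(nr, nc) / 16))
      a <- a + p$a * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
    }
  }
  b <- matrix(0, nr, nc)
  b[a > 0] <- p$b
  structure(list(a = a, b = b, c = cc, shape = as.integer(shape),
                 spacing_mm = spacing_mm, kind = kind, fluence = NULL),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Phantom '", x$kind, "': ", x$shape[1], " x ", x$shape[2],
      " @ ", x$spacing_mm * 1000, " um\n", sep = "")
  cat("  bleachable voxels:", sum(x$a > 0),
      "| max a:", signif(max(x$a), 3),
      "| rate b:", signif(max(x$b), 3), "\n")
  invisible(x)
}

#' Evaluate a phantom's true image at a given time
#'
#' @param phantom a [make_phantom()] object.
#' @param t time in translational scans.
#' @return matrix \code{a*exp(-b*t) + c}.
#' @export
phantom_image <- function(phantom, t) {
  stopifnot(inherits(phantom, "phantom"))
  phantom$a * exp(-phantom$b * t) + phantom$c
}

#' Additive Gaussian image noise
#'
#' @param image numeric matrix/array.
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return image plus i.i.d. N(0, sigma^2) noise.
#' @export
add_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (sigma == 0) return(image)
  set.seed(as.integer(seed))
  image + array(stats::rnorm(length(image), 0, sigma), dim = dim(image))
}

#' Depth-dependent excitation fluence map
#'
#' Simple Beer-Lambert stand-in for light transport in scattering tissue:
#' intensity decays exponentially with depth from the top boundary
#' (row 1), \eqn{I(d) = I_0 e^{-\mu_{eff} d}}.
#'
#' @param shape grid shape (rows, cols); depth increases along rows.
#' @param surface_intensity intensity at depth 0.
#' @param mu_eff effective attenuation coefficient per mm, >= 0.
#' @param spacing_mm voxel spacing in mm.
#' @return positive matrix of shape \code{shape}.
#' @export
fluence_map <- function(shape, surface_intensity = 1, mu_eff = 0.5,
                        spacing_mm = 0.075) {
  if (mu_eff < 0) stop("'mu_eff' must be non-negative", call. = FALSE)
  depth <- (seq_len(shape[1]) - 1) * spacing_mm
  matrix(rep(surface_intensity * exp(-mu_eff * depth), shape[2]),
         shape[1], shape[2])
}

#' Compensate an image for excitation fluence
#'
#' Divides voxelwise by the fluence, floored at
#' \code{floor_fraction * max(fluence)} so that deep, dark voxels are not
#' amplified without bound.
#'
#' @param image numeric matrix.
#' @param fluence positive matrix of the same shape.
#' @param floor_fraction lower floor as a fraction of the fluence maximum,
#'   in (0, 1].
#' @return compensated image.
#' @export
fluence_compensate <- function(image, fluence, floor_fraction = 0.05) {
  if (!identical(dim(image), dim(fluence)))
    stop("image and fluence shapes differ", call. = FALSE)
  if (floor_fraction <= 0 || floor_fraction > 1)
    stop("'floor_fraction' must be in (0, 1]", call. = FALSE)
  image / pmax(fluence, floor_fraction * max(fluence))
}

# ---- internal ---------------------------------------------------------

# 1-px-wide line through the grid centre at `deg` degrees from the
# column (x) axis, measured in raster coordinates (row index as +y) so
# that a line at orientation `deg` is invariant under the slab filter at
# angle `deg`; nearest-pixel raster
line_mask <- function(nr, nc, deg) {
  m <- matrix(0, nr, nc)
  ctr <- c(floor(nr / 2) + 1L, floor(nc / 2) + 1L)
  th <- deg * pi / 180
  n <- max(nr, nc) * 2L
  s <- seq(-n, n)
  r <- round(ctr[1] + s * sin(th))
  cl <- round(ctr[2] + s * cos(th))
  ok <- r >= 1 & r <= nr & cl >= 1 & cl <= nc
  m[cbind(r[ok], cl[ok])] <- 1
  m
}

# centred Gaussian low-pass in unshifted FFT layout (cycles/voxel cutoff)
gauss_lowpass <- function(nr, nc, cutoff) {
  fr <- fft_freq(nr); fc <- fft_freq(nc)
  f2 <- outer(fr^2, fc^2, "+")
  exp(-f2 / (2 * cutoff^2))
}

# frequencies in cycles/voxel in natural (unshifted) FFT order
fft_freq <- function(n) {
  i <- 0:(n - 1)
  ifelse(i <= (n - 1) %/% 2, i, i - n) / n
}
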