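#' Equivalent excitation intensity
#'
#' From a fitted cycle-integrated decay \eqn{A(t) = a e^{-bt}} the local
#' excitation intensity is recovered up to the constant
#' \eqn{\Gamma\eta_{th} C_0}:
#' \deqn{I_{eq} = \frac{ab}{1 - e^{-bT}},}
#' with the \eqn{b \to 0} limit \eqn{a/T}.  \eqn{I_{eq} \propto I} when
#' the concentration is constant across samples (e.g. along one
#' protein-filled tube).
#'
#' @param a fitted amplitude(s), >= 0.
#' @param b fitted bleaching rate(s) per translational scan, >= 0.
#' @param T scan-cycle duration in translational scans, > 0.
#' @return equivalent intensity (arbitrary units), vectorised over
#'   \code{a}, \code{b}.
#' @export
equivalent_intensity <- function(a, b, T) {
  if (T <= 0) stop("'T' must be positive", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("'a' and 'b' must be non-negative", call. = FALSE)
  ifelse(b < 1e-12, a / T, a * b / (1 - exp(-b * T)))
}

#' Calibrate the intensity power dependence of photobleaching
#'
#' The bleaching rate depends on the local excitation intensity as
#' \eqn{b = k I^\beta}.  Taking logs and substituting the equivalent
#' intensity gives the linear model
#' \deqn{\ln b = [\ln k - \beta\ln(\Gamma\eta_{th}C_0)] +
#'   \beta \ln I_{eq},}
#' whose slope is \eqn{\beta}.  The fit is the closed-form
#' normal-equation least squares
#' \eqn{\hat\theta = (XX^T)^{-1} X \ln \mathbf{b}} with
#' \eqn{X = [\mathbf{1}; \ln \mathbf{I}_{eq}]} (2 x n).  Samples with
#' non-positive \code{a} or \code{b} (including sentinel-rate,
#' unbleachable fits) are excluded with a warning.
#'
#' @param samples data.frame with columns \code{a} and \code{b} (fitted
#'   amplitude and rate per calibration position); other columns are
#'   carried as metadata.
#' @param T scan-cycle duration in translational scans.
#' @param sentinel rates at or below this are treated as unbleachable and
#'   excluded.
#' @return object of class \code{beta_calibration}: list with
#'   \code{beta}, \code{intercept} (\eqn{\ln k - \beta\ln(\Gamma\eta_{th}
#'   C_0)}), \code{rss}, \code{n_samples}, and the design data
#'   (\code{log_I_eq}, \code{log_b}).
#' @examples
#' ph <- lapply(c(1, 2, 4), function(I) phys_params(k_rate = 0.01, I = I))
#' samples <- data.frame(
#'   a = vapply(ph, cycle_amplitude, numeric(1), t = 0, T = 32),
#'   b = vapply(ph, function(p) p$k_rate * p$I^p$beta, numeric(1)))
#' calibrate_beta(samples, T = 32)
#' @export
calibrate_beta <- function(samples, T, sentinel = 1e-4) {
  if (T <= 0) stop("'T' must be positive", call. = FALSE)
  stopifnot(is.data.frame(samples), all(c("a", "b") %in% names(samples)))
  ok <- is.finite(samples$a) & is.finite(samples$b) &
    samples$a > 0 & samples$b > sentinel
  if (any(!ok))
    warning(sum(!ok), " sample(s) with non-positive or sentinel-rate ",
            "fits excluded from calibration", call. = FALSE)
  s <- samples[ok, , drop = FALSE]
  if (nrow(s) < 2)
    stop("need at least 2 usable calibration samples", call. = FALSE)
  I_eq <- equivalent_intensity(s$a, s$b, T)
  x <- log(I_eq)
  y <- log(s$b)
  if (max(x) - min(x) < 1e-12)
    stop("singular design: all equivalent intensities equal",
         call. = FALSE)
  X <- rbind(rep(1, length(x)), x)              # 2 x n design
  theta <- solve(X %*% t(X), X %*% y)
  fittedv <- drop(t(X) %*% theta)
  structure(list(beta = theta[2], intercept = theta[1],
                 rss = sum((y - fittedv)^2), n_samples = length(x),
                 log_I_eq = x, log_b = y, T = T),
            class = "beta_calibration")
}

#' @export
print.beta_calibration <- function(x, digits = 5, ...) {
  cat("Photobleaching nonlinearity calibration (b = k * I^beta)\n")
  cat("  beta      =", signif(x$beta, digits), "\n")
  cat("  intercept =", signif(x$intercept, digits),
      "(ln k - beta * ln(Gamma*eta_th*C0))\n")
  cat("  n =", x$n_samples, "| RSS =", signif(x$rss, digits), "\n")
  invisible(x)
}

#' @export
coef.beta_calibration <- function(object, ...) {
  c(intercept = object$intercept, beta = object$beta)
}

#' Equivalent molecular concentration
#'
#' With a calibrated intensity power dependence \eqn{\beta}, the
#' concentration of the bleachable chromophore is recovered from a voxel
#' fit up to a protein-wide constant:
#' \deqn{C_{eq} = \frac{a\, b^{(\beta-1)/\beta}}{1 - e^{-bT}}
#'   \propto C_0.}
#'
#' @param a fitted tag amplitude(s), >= 0.
#' @param b fitted bleaching rate(s), > 0.
#' @param T scan-cycle duration in translational scans, > 0.
#' @param beta calibrated intensity power dependence, > 0.
#' @return equivalent concentration (arbitrary units), vectorised.
#' @export
equivalent_concentration <- function(a, b, T, beta) {
  if (T <= 0) stop("'T' must be positive", call. = FALSE)
  if (beta <= 0) stop("'beta' must be positive", call. = FALSE)
  if (any(b <= 0)) stop("'b' must be positive", call. = FALSE)
  if (any(a < 0)) stop("'a' must be non-negative", call. = FALSE)
  a * b^((beta - 1) / beta) / (1 - exp(-b * T))
}

#' Read / write calibration samples as CSV
#'
#' @param path CSV file with columns \code{label}, \code{a}, \code{b}.
#' @return data.frame of samples.
#' @export
read_calibration_csv <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("a", "b") %in% names(s)))
    stop("calibration CSV needs columns 'a' and 'b'", call. = FALSE)
  s
}

#' @param samples data.frame with at least columns \code{a}, \code{b}.
#' @rdname read_calibration_csv
#' @export
write_calibration_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
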