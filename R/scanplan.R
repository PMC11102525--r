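#' Bit-reversal ("jumping") rotation sequence
#'
#' Generates the order in which rotation angles are visited within one scan
#' cycle.  The \code{n_angles} equally spaced angles (spacing
#' \code{180/n_angles} degrees, wrapped to the half-open interval
#' \eqn{(-90, 90]}) are permuted by bit-reversing their index, so that
#' consecutive translational scans jump between widely separated k-space
#' orientations.  Under photobleaching this spreads the amplitude decay
#' evenly over orientations instead of concentrating it on one side of
#' k-space.
#'
#' For 32 angles the sequence starts 0, 90, 45, -45, 22.5, -67.5, 67.5,
#' -22.5, ...
#'
#' @param n_angles number of rotation angles per scan cycle; must be a
#'   power of two, at least 2.
#' @return numeric vector of \code{n_angles} angles in degrees, a
#'   permutation of the equally spaced set wrapped to \eqn{(-90, 90]}.
#' @seealso [sequential_sequence()] for the ascending control ordering.
#' @examples
#' jump_sequence(8)
#' @export
jump_sequence <- function(n_angles) {
  check_power_of_two(n_angles)
  bits <- as.integer(round(log2(n_angles)))
  idx <- vapply(0:(n_angles - 1L), bit_reverse, integer(1), bits = bits)
  wrap_angle(idx * (180 / n_angles))
}

#' Sequential rotation sequence
#'
#' The ascending control ordering: \code{n_angles} equally spaced angles
#' from -90 degrees upward with spacing \code{180/n_angles}.  Covers the
#' same set of slab orientations as [jump_sequence()] (an angle and
#' angle + 180 select the same slab), but visits them in monotone order, so
#' photobleaching decay accumulates across one side of k-space.
#'
#' @inheritParams jump_sequence
#' @return numeric vector of \code{n_angles} ascending angles in degrees,
#'   running from -90 to \code{90 - 180/n_angles}.
#' @export
sequential_sequence <- function(n_angles) {
  if (!is_count(n_angles) || n_angles < 2)
    stop("'n_angles' must be an integer >= 2", call. = FALSE)
  -90 + (0:(n_angles - 1)) * (180 / n_angles)
}

#' Number of fused volumes in a sliding-window acquisition
#'
#' Fusing every window of \code{n_angles} adjacent tomograms over
#' \code{n_angles * n_cycles} tomograms yields
#' \code{n_angles * (n_cycles - 1) + 1} volumes; the standard 32-angle,
#' 8-cycle acquisition gives 225.
#'
#' @inheritParams jump_sequence
#' @param n_cycles number of scan cycles (positive integer).
#' @return integer count of fused volumes.
#' @export
fused_volume_count <- function(n_angles, n_cycles) {
  if (!is_count(n_angles) || n_angles < 1)
    stop("'n_angles' must be a positive integer", call. = FALSE)
  if (!is_count(n_cycles) || n_cycles < 1)
    stop("'n_cycles' must be a positive integer", call. = FALSE)
  as.integer(n_angles * (n_cycles - 1) + 1)
}

#' Scan plan constructor
#'
#' Bundles the acquisition geometry: rotation angles per cycle, cycle
#' count, translation range and step, and the ordered angle sequence.
#' One translational scan (one tomogram) is the time unit throughout the
#' package; a scan cycle therefore has duration \code{T = n_angles}.
#'
#' @param n_angles rotation angles per scan cycle (power of two for
#'   \code{order_mode = "jumping"}); default 32.
#' @param n_cycles scan cycles; default 8.
#' @param translation_range_mm half-range of the translation stage in mm
#'   (the stage covers \code{[-range, +range]}); default 9.6.
#' @param translation_step_mm translation step length in mm; default 0.6.
#' @param order_mode \code{"jumping"} (bit-reversal) or
#'   \code{"sequential"}.
#' @return an object of class \code{scan_plan}: a list with fields
#'   \code{n_angles}, \code{n_cycles}, \code{translation_range_mm},
#'   \code{translation_step_mm}, \code{angle_sequence_deg},
#'   \code{order_mode} and \code{cycle_duration_T}.
#' @examples
#' plan <- scan_plan(32, 8)
#' fused_volume_count(plan$n_angles, plan$n_cycles)
#' @export
scan_plan <- function(n_angles = 32, n_cycles = 8,
                      translation_range_mm = 9.6,
                      translation_step_mm = 0.6,
                      order_mode = c("jumping", "sequential")) {
  order_mode <- match.arg(order_mode)
  if (!is_count(n_cycles) || n_cycles < 1)
    stop("'n_cycles' must be a positive integer", call. = FALSE)
  if (!is.numeric(translation_range_mm) || translation_range_mm <= 0 ||
      !is.numeric(translation_step_mm) || translation_step_mm <= 0)
    stop("translation range and step must be strictly positive", call. = FALSE)
  steps <- 2 * translation_range_mm / translation_step_mm
  if (abs(steps - round(steps)) > 1e-9 * steps)
    stop("translation step must divide 2*range evenly", call. = FALSE)
  seq_deg <- switch(order_mode,
    jumping = jump_sequence(n_angles),
    sequential = sequential_sequence(n_angles))
  structure(list(
    n_angles = as.integer(n_angles),
    n_cycles = as.integer(n_cycles),
    translation_range_mm = translation_range_mm,
    translation_step_mm = translation_step_mm,
    angle_sequence_deg = seq_deg,
    order_mode = order_mode,
    cycle_duration_T = as.integer(n_angles)
  ), class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat("Scan plan:", x$n_angles, "angles x", x$n_cycles, "cycles (",
      x$order_mode, "order )\n")
  cat("  translation: +/-", x$translation_range_mm, "mm in",
      x$translation_step_mm, "mm steps\n")
  st <- translation_steps(x)
  cat("  steps: ", st["steps_per_tomogram"], " per tomogram, ",
      st["steps_per_cycle"], " per cycle\n", sep = "")
  cat("  tomograms:", x$n_angles * x$n_cycles,
      "| fused volumes:", fused_volume_count(x$n_angles, x$n_cycles), "\n")
  cat("  first angles (deg):",
      paste(utils::head(x$angle_sequence_deg, 8), collapse = ", "),
      if (x$n_angles > 8) "...", "\n")
  invisible(x)
}

#' Translation step counts
#'
#' @param plan a [scan_plan()].
#' @return named integer vector with \code{steps_per_tomogram} (steps in
#'   one translational scan, \code{2*range/step}) and
#'   \code{steps_per_cycle} (that times \code{n_angles}); the default
#'   plan gives 32 and 1024.
#' @export
translation_steps <- function(plan) {
  stopifnot(inherits(plan, "scan_plan"))
  per_tomo <- as.integer(round(2 * plan$translation_range_mm /
                                 plan$translation_step_mm))
  c(steps_per_tomogram = per_tomo,
    steps_per_cycle = per_tomo * plan$n_angles)
}

#' Acquisition schedule
#'
#' Assigns every tomogram its global index, cycle, rotation angle and
#' timestamp.  Tomogram \code{m} (0-based over the whole acquisition) is
#' acquired at time \code{t = m} in units of translational scans, at angle
#' \code{angle_sequence_deg[m %% n_angles + 1]}.
#'
#' @param plan a [scan_plan()].
#' @return data.frame with columns \code{tomogram_index},
#'   \code{cycle_index} (both 0-based), \code{angle_deg} and \code{time}.
#' @export
acquisition_timestamps <- function(plan) {
  stopifnot(inherits(plan, "scan_plan"))
  m <- 0:(plan$n_angles * plan$n_cycles - 1L)
  data.frame(
    tomogram_index = m,
    cycle_index = m %/% plan$n_angles,
    angle_deg = plan$angle_sequence_deg[m %% plan$n_angles + 1L],
    time = as.numeric(m)
  )
}

#' Write / read a scan plan as YAML
#'
#' The angle sequence is regenerated from \code{order_mode} on read, so
#' the file stores geometry only.
#'
#' @param plan a [scan_plan()].
#' @param path file path.
#' @return \code{write_scan_plan} returns \code{path} invisibly;
#'   \code{read_scan_plan} returns a [scan_plan()].
#' @export
write_scan_plan <- function(plan, path) {
  stopifnot(inherits(plan, "scan_plan"))
  yaml::write_yaml(list(
    n_angles = plan$n_angles, n_cycles = plan$n_cycles,
    translation_range_mm = plan$translation_range_mm,
    translation_step_mm = plan$translation_step_mm,
    order_mode = plan$order_mode), path)
  invisible(path)
}

#' @rdname write_scan_plan
#' @export
read_scan_plan <- function(path) {
  f <- yaml::read_yaml(path)
  allowed <- c("n_angles", "n_cycles", "translation_range_mm",
               "translation_step_mm", "order_mode")
  unknown <- setdiff(names(f), allowed)
  if (length(unknown))
    stop("unknown scan plan keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  scan_plan(f$n_angles, f$n_cycles, f$translation_range_mm,
            f$translation_step_mm, f$order_mode)
}

# ---- internal helpers -------------------------------------------------

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && abs(x - round(x)) < 1e-9
}

check_power_of_two <- function(n) {
  if (!is_count(n) || n < 2)
    stop("'n_angles' must be an integer >= 2", call. = FALSE)
  n <- as.integer(round(n))
  if (bitwAnd(n, n - 1L) != 0L)
    stop("'n_angles' must be a power of two", call. = FALSE)
  invisible(n)
}

bit_reverse <- function(i, bits) {
  r <- 0L
  for (b in seq_len(bits)) {
    r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(i, 1L))
    i <- bitwShiftR(i, 1L)
  }
  r
}

# wrap degrees to (-90, 90]
wrap_angle <- function(deg) {
  w <- ((deg + 90) %% 180) - 90
  w[w <= -90 + 1e-12] <- w[w <= -90 + 1e-12] + 180
  w
}
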