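#' Channel specification for a gait waveform
#'
#' A channel is one biomechanical time series over the stance phase, either a
#' joint angle (degrees) or a mass-normalized external joint moment (N m/kg).
#' Its healthy template curve is a superposition of smooth Gaussian bumps on
#' the normalized stance grid \[0, 1\].
#'
#' @param name Channel name (unique within a channel set).
#' @param kind Either `"angle"` or `"moment"`.
#' @param bumps List of bumps, each a list with elements `center` (in
#'   \[0, 1\]), `width` (> 0, in stance-fraction units) and `amplitude`
#'   (degrees or N m/kg).
#' @return An object of class `channel_spec`.
#' @seealso [default_channel_specs()], [generate_templates()]
#' @export
channel_spec <- function(name, kind = c("angle", "moment"), bumps = list()) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (b in bumps) {
    if (!all(c("center", "width", "amplitude") %in% names(b))) {
      stop("each bump needs 'center', 'width' and 'amplitude'", call. = FALSE)
    }
    if (!is.finite(b$width) || b$width <= 0) {
      stop("bump width must be strictly positive in channel '", name, "'",
           call. = FALSE)
    }
  }
  structure(list(name = name, kind = kind, bumps = bumps),
            class = "channel_spec")
}

#' The 18 stance-phase channels of the standard lower-body gait set
#'
#' Eleven joint-angle waveforms (pelvic tilt, obliquity and rotation; hip
#' flexion, adduction and rotation; knee flexion, adduction and rotation;
#' ankle plantarflexion; foot progression) and seven joint-moment waveforms
#' (hip, knee flexion/adduction/rotation; ankle plantarflexion). Template
#' bump parameters are chosen to give physiologically plausible smooth shapes
#' and magnitudes; they are synthetic, not measured curves.
#'
#' @return A list of 18 [channel_spec()] objects.
#' @export
default_channel_specs <- function() {
  b <- function(center, width, amplitude) {
    list(center = center, width = width, amplitude = amplitude)
  }
  list(
    channel_spec("pelvic_tilt", "angle",
                 list(b(0.5, 0.6, 10), b(0.8, 0.15, 2))),
    channel_spec("pelvic_obliquity", "angle",
                 list(b(0.15, 0.12, 4), b(0.7, 0.2, -3))),
    channel_spec("pelvic_rotation", "angle",
                 list(b(0.1, 0.2, 5), b(0.9, 0.2, -5))),
    channel_spec("hip_flexion_angle", "angle",
                 list(b(0.05, 0.18, 30), b(0.85, 0.15, -12))),
    channel_spec("hip_adduction_angle", "angle",
                 list(b(0.3, 0.25, 8), b(0.9, 0.1, -4))),
    channel_spec("hip_rotation_angle", "angle",
                 list(b(0.4, 0.3, 6))),
    channel_spec("knee_flexion_angle", "angle",
                 list(b(0.15, 0.12, 18), b(0.95, 0.12, 30))),
    channel_spec("knee_adduction_angle", "angle",
                 list(b(0.2, 0.2, 4), b(0.8, 0.2, 3))),
    channel_spec("knee_rotation_angle", "angle",
                 list(b(0.1, 0.15, -5), b(0.6, 0.3, 4))),
    channel_spec("ankle_plantarflexion_angle", "angle",
                 list(b(0.07, 0.06, -6), b(0.45, 0.25, 10), b(0.97, 0.06, -15))),
    channel_spec("foot_progression_angle", "angle",
                 list(b(0.5, 0.5, -8))),
    channel_spec("hip_flexion_moment", "moment",
                 list(b(0.1, 0.1, 0.9), b(0.75, 0.18, -0.8))),
    channel_spec("hip_adduction_moment", "moment",
                 list(b(0.2, 0.12, 0.9), b(0.75, 0.15, 0.7))),
    channel_spec("hip_rotation_moment", "moment",
                 list(b(0.3, 0.25, 0.15), b(0.8, 0.12, -0.1))),
    channel_spec("knee_flexion_moment", "moment",
                 list(b(0.18, 0.1, 0.5), b(0.7, 0.2, -0.3))),
    channel_spec("knee_adduction_moment", "moment",
                 list(b(0.2, 0.1, 0.45), b(0.8, 0.12, 0.35))),
    channel_spec("knee_rotation_moment", "moment",
                 list(b(0.25, 0.2, 0.12))),
    channel_spec("ankle_plantarflexion_moment", "moment",
                 list(b(0.75, 0.22, 1.5)))
  )
}

channel_names <- function(channel_specs) {
  vapply(channel_specs, function(s) s$name, character(1))
}

validate_channel_specs <- function(channel_specs) {
  nm <- channel_names(channel_specs)
  if (anyDuplicated(nm)) {
    stop("channel names must be unique; duplicated: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  invisible(channel_specs)
}

# Gaussian bump evaluated on the normalized stance grid.
eval_bumps <- function(bumps, grid) {
  y <- numeric(length(grid))
  for (b in bumps) {
    if (!is.finite(b$width) || b$width <= 0) {
      stop("bump width must be strictly positive", call. = FALSE)
    }
    y <- y + b$amplitude * exp(-0.5 * ((grid - b$center) / b$width)^2)
  }
  y
}

#' Evaluate healthy template curves for a channel set
#'
#' Each channel's template is the superposition of its Gaussian bumps,
#' evaluated on a uniform grid over the normalized stance phase \[0, 1\].
#' The result is fully determined by the channel specifications.
#'
#' @param channel_specs List of [channel_spec()] objects.
#' @param n_timepoints Number of grid points (default 101).
#' @return Numeric matrix `[channel x timepoint]` with channel names as row
#'   names.
#' @examples
#' tpl <- generate_templates(default_channel_specs())
#' dim(tpl) # 18 x 101
#' @export
generate_templates <- function(channel_specs, n_timepoints = 101L) {
  validate_channel_specs(channel_specs)
  grid <- seq(0, 1, length.out = n_timepoints)
  out <- t(vapply(channel_specs, function(s) eval_bumps(s$bumps, grid),
                  numeric(n_timepoints)))
  rownames(out) <- channel_names(channel_specs)
  colnames(out) <- sprintf("t%03d", seq_len(n_timepoints) - 1L)
  out
}
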