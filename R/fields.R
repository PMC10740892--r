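# Quasistatic volume conductor. The finite-element solve over real anatomy is
# replaced by analytic point-source potentials in an unbounded homogeneous
# (optionally anisotropic) medium; every downstream computation (drive,
# reciprocity, eCAP synthesis) is preserved and exactly testable. Any function
# accepting a `medium` will take a custom potential kernel through it, so a
# numerical backend can be slotted in later.

#' Define a volume-conduction medium
#'
#' Isotropic by default. Supplying distinct longitudinal/transverse
#' conductivities with a nerve-axis direction selects the closed-form
#' anisotropic point-source potential, which reduces continuously to the
#' isotropic form as `sigma_long -> sigma_trans`.
#'
#' @param sigma_iso isotropic conductivity, S/m (default 0.3, soft tissue;
#'   use 1.4 for 0.9% saline bench mode).
#' @param sigma_long,sigma_trans longitudinal/transverse conductivity along
#'   `axis`, S/m (both or neither).
#' @param axis nerve-axis direction for the anisotropic form (unit 3-vector).
#' @return object of class `vest_medium`.
#' @examples
#' medium()                     # tissue
#' medium(sigma_iso = 1.4)      # saline bench
#' @export
medium <- function(sigma_iso = 0.3, sigma_long = NULL, sigma_trans = NULL,
                   axis = c(1, 0, 0)) {
  aniso <- !is.null(sigma_long) || !is.null(sigma_trans)
  if (aniso) {
    if (is.null(sigma_long) || is.null(sigma_trans)) {
      stop_invalid("supply both `sigma_long` and `sigma_trans` or neither")
    }
    check_number(sigma_long, "sigma_long", lower = 0, strict_lower = TRUE)
    check_number(sigma_trans, "sigma_trans", lower = 0, strict_lower = TRUE)
    axis <- unit_vec(axis)
  } else {
    check_number(sigma_iso, "sigma_iso", lower = 0, strict_lower = TRUE)
  }
  structure(list(sigma_iso = sigma_iso, sigma_long = sigma_long,
                 sigma_trans = sigma_trans, axis = axis, anisotropic = aniso),
            class = "vest_medium")
}

#' Extracellular potential of a point current source
#'
#' Isotropic: `V = I / (4 pi sigma r)`. Anisotropic (conductivity tensor with
#' `sigma_long` along the nerve axis, `sigma_trans` across it): closed form by
#' coordinate scaling,
#' `V = I / (4 pi sigma_trans sqrt(sigma_long) sqrt(x_par^2/sigma_long + r_perp^2/sigma_trans))`.
#' With current in uA, distances in mm and conductivity in S/m the result is
#' in mV.
#'
#' @param r_mm displacement(s) from the source: length-3 vector or n x 3
#'   matrix. A scalar is taken as a radial distance (isotropic only).
#' @param I_uA source current, microamperes.
#' @param medium a [medium()].
#' @return potential(s) in mV.
#' @export
point_potential <- function(r_mm, I_uA, medium = vestibsim::medium()) {
  stopifnot(inherits(medium, "vest_medium"))
  if (is.matrix(r_mm)) {
    disp <- r_mm
  } else if (length(r_mm) == 3L) {
    disp <- matrix(r_mm, nrow = 1)
  } else if (length(r_mm) == 1L) {
    if (medium$anisotropic) {
      stop_invalid("anisotropic potential needs a 3-vector displacement")
    }
    disp <- matrix(c(r_mm, 0, 0), nrow = 1)
  } else {
    stop_invalid("`r_mm` must be a scalar distance, 3-vector, or n x 3 matrix")
  }
  r <- sqrt(rowSums(disp^2))
  if (any(r == 0)) {
    stop_invalid("potential is singular at the source location",
                 class = "vestibsim_singularity")
  }
  if (!medium$anisotropic) {
    return(I_uA / (4 * pi * medium$sigma_iso * r))
  }
  sl <- medium$sigma_long
  st <- medium$sigma_trans
  x_par <- as.numeric(disp %*% medium$axis)
  r_perp2 <- pmax(r^2 - x_par^2, 0)
  I_uA / (4 * pi * st * sqrt(sl) * sqrt(x_par^2 / sl + r_perp2 / st))
}

# potential coefficients (mV per uA) at points `pts` (n x 3) from a source at
# `src`; the shared kernel behind drive, lead fields and current spread
potential_coeff <- function(pts, src, medium) {
  disp <- sweep(pts, 2, src)
  point_potential(disp, 1, medium)
}

#' Extracellular drive matrix for one fiber
#'
#' Quasistatic separable product: the spatial profile of potential per unit
#' current at each node of Ranvier times the stimulus current time-series.
#'
#' @param fiber one row of an anatomy `fibers` tibble (or a list with a
#'   `nodes` matrix).
#' @param stim_electrode_mm stimulating electrode position, length-3 (mm).
#' @param waveform a rendered `vest_waveform`.
#' @param medium a [medium()].
#' @return matrix of extracellular potentials, nodes x time, mV; sample times
#'   are attached as attribute `"t_us"`.
#' @export
drive_matrix <- function(fiber, stim_electrode_mm, waveform,
                         medium = vestibsim::medium()) {
  nodes <- fiber_nodes(fiber)
  if (nrow(nodes) < 2) stop_invalid("fiber must have at least 2 nodes")
  stopifnot(inherits(waveform, "vest_waveform"))
  coeff <- potential_coeff(nodes, stim_electrode_mm, medium)
  phi <- outer(coeff, waveform$i_uA)
  attr(phi, "t_us") <- waveform$t_us
  phi
}

fiber_nodes <- function(fiber) {
  if (is.matrix(fiber)) return(fiber)
  if (is.data.frame(fiber)) {
    stopifnot(nrow(fiber) == 1)
    return(fiber$nodes[[1]])
  }
  if (is.list(fiber) && !is.null(fiber$nodes)) {
    n <- fiber$nodes
    return(if (is.list(n)) n[[1]] else n)
  }
  stop_invalid("cannot extract node coordinates from `fiber`")
}

#' Reciprocal lead field of a recording electrode
#'
#' By reciprocity, the weight mapping a compartment's transmembrane current to
#' the voltage on a recording electrode equals the potential a unit current
#' injected at that electrode would impress at the compartment. In the
#' homogeneous analytic medium this is the same point-source kernel as the
#' forward problem, which makes the reciprocity property exactly testable.
#'
#' @param rec_electrode_mm recording electrode position, length-3 (mm).
#' @param compartments_mm n x 3 matrix of compartment positions.
#' @param medium a [medium()].
#' @return tibble of class `vest_leadfield` with one row per compartment and
#'   a `weight_mV_per_uA` column.
#' @export
lead_field <- function(rec_electrode_mm, compartments_mm,
                       medium = vestibsim::medium()) {
  if (!is.matrix(compartments_mm) || nrow(compartments_mm) < 1) {
    stop_invalid("`compartments_mm` must be a non-empty n x 3 matrix")
  }
  w <- potential_coeff(compartments_mm, rec_electrode_mm, medium)
  tibble::new_tibble(
    list(compartment = seq_len(nrow(compartments_mm)),
         weight_mV_per_uA = w),
    class = "vest_leadfield"
  )
}

#' Bench-test current spread emulation
#'
#' Open-circuit potentials at sense electrodes while one electrode stimulates
#' in a conductive bath, plus a normalized spread index: each sense potential
#' divided by the potential at a fixed 0.1 mm reference distance from the
#' stimulating site. Monotonically decreasing with distance in the
#' homogeneous medium.
#'
#' @param stim_mm stimulating electrode position, length-3 (mm).
#' @param sense_mm n x 3 matrix of sense-electrode positions.
#' @param medium a [medium()] (default 0.9% saline, 1.4 S/m).
#' @param I_uA stimulation current, microamperes.
#' @param ref_mm reference distance for the spread index (default 0.1 mm).
#' @return tibble with `distance_mm`, `potential_mV`, `spread_index`.
#' @export
current_spread <- function(stim_mm, sense_mm, medium = vestibsim::medium(1.4),
                           I_uA = 240, ref_mm = 0.1) {
  if (!is.matrix(sense_mm) || nrow(sense_mm) < 1) {
    stop_invalid("need at least one sense electrode")
  }
  v <- potential_coeff(sense_mm, stim_mm, medium) * I_uA
  v_ref <- point_potential(ref_mm, I_uA, medium)
  tibble::tibble(
    distance_mm = sqrt(rowSums(sweep(sense_mm, 2, stim_mm)^2)),
    potential_mV = v,
    spread_index = if (I_uA == 0) rep(0, length(v)) else v / v_ref
  )
}
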