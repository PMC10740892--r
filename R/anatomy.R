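# Procedural synthetic labyrinth: three semicircular-canal (SCC) ampullary
# nerves with model afferent fibers, a stimulating/recording electrode array,
# and canal rotation axes. Coordinates in mm, right-handed frame.

# geometric layout constants (mm)
CRISTA_RADIUS_MM <- 0.30     # disc on which afferent start points are sampled
CRISTA_DIST_MM <- 3.5        # crista center distance from the labyrinth origin
CONVERGE_DIST_MM <- 1.2      # per-branch nerve convergence waypoint
TRUNK_LEN_MM <- 3.2          # common trunk run toward the brainstem
STIM_OFFSET_MM <- 0.2        # stimulating electrode to crista center

# default crista placement directions (positions, not canal axes)
BRANCH_DIRS <- list(
  LH = c(1, 0, 0),
  LA = c(0, 1, 0),
  LP = c(0, 0, 1)
)

# default canal rotation axes in the {horizontal, LARP, RALP} frame:
# LH axis vertical, LA/LP at +/-45 degrees in the horizontal plane
DEFAULT_AXES <- list(
  LH = c(0, 0, 1),
  LA = c(1, 1, 0) / sqrt(2),
  LP = c(1, -1, 0) / sqrt(2)
)

# unit vector orthogonal to d (deterministic choice)
orth_unit <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(pracma_cross(d, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# points at arc lengths s (mm) along a polyline given by vertex matrix (k x 3)
polyline_points <- function(verts, s) {
  seg <- diff(verts)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  if (any(s > cum[length(cum)] + 1e-12)) {
    stop_invalid("arc length beyond polyline end")
  }
  out <- matrix(0, nrow = length(s), ncol = 3)
  for (i in seq_along(s)) {
    j <- max(which(cum <= s[i] + 1e-12))
    j <- min(j, nrow(seg))
    frac <- (s[i] - cum[j]) / seg_len[j]
    out[i, ] <- verts[j, ] + frac * seg[j, ]
  }
  out
}

# allocate n fibers over zones by proportions, remainders by largest fraction
allocate_zones <- function(n, props = c(peripheral = 0.4, intermediate = 0.3,
                                        central = 0.3)) {
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_idx <- order(raw - counts, decreasing = TRUE)
    counts[order_idx[seq_len(rem)]] <- counts[order_idx[seq_len(rem)]] + 1
  }
  counts
}

# truncated-normal fiber diameters (um)
draw_diameters <- function(n, mean = 3, sd = 0.5, lower = 2, upper = 4) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, d[d >= lower & d <= upper])
  }
  out[seq_len(n)]
}

build_branch_fibers <- function(branch, n, internode_ratio, diam_mean,
                                diam_sd, diam_bounds) {
  d <- unit_vec(BRANCH_DIRS[[branch]])
  center <- CRISTA_DIST_MM * d
  e1 <- orth_unit(d)
  e2 <- pracma_cross(d, e1)
  trunk_dir <- -unit_vec(c(1, 1, 1))

  counts <- allocate_zones(n)
  zones <- rep(names(counts), counts)
  # radial bands: central innermost, peripheral outermost
  band <- c(peripheral = 1.0, intermediate = 2 / 3, central = 1 / 3)
  r_hi <- band[zones]
  r_lo <- r_hi - 1 / 3
  # area-uniform radius within each band, uniform angle
  u <- stats::runif(n)
  radius <- CRISTA_RADIUS_MM * sqrt(r_lo^2 + u * (r_hi^2 - r_lo^2))
  theta <- stats::runif(n, 0, 2 * pi)
  diam <- draw_diameters(n, diam_mean, diam_sd, diam_bounds[1], diam_bounds[2])

  fibers <- vector("list", n)
  for (i in seq_len(n)) {
    p0 <- center + radius[i] * (cos(theta[i]) * e1 + sin(theta[i]) * e2)
    # straight run from the crista surface to the common trunk endpoint:
    # trajectories converge while consecutive-node distances stay exactly at
    # the internodal spacing
    q2 <- CONVERGE_DIST_MM * d + TRUNK_LEN_MM * trunk_dir
    verts <- rbind(p0, q2)
    spacing <- internode_ratio * diam[i] / 1000  # um -> mm
    total_len <- sum(sqrt(rowSums(diff(verts)^2)))
    n_nodes <- max(11L, as.integer(floor(total_len / spacing)) + 1L)
    if ((n_nodes - 1) * spacing > total_len) {
      stop_invalid(sprintf(
        "fiber path too short for 11 nodes at spacing %.3f mm", spacing))
    }
    fibers[[i]] <- polyline_points(verts, spacing * (seq_len(n_nodes) - 1))
  }
  tibble::tibble(
    branch = branch, fiber = seq_len(n), zone = zones,
    diameter_um = diam, spacing_mm = internode_ratio * diam / 1000,
    n_nodes = purrr::map_int(fibers, nrow), nodes = fibers
  )
}

#' Build the default synthetic labyrinth
#'
#' Generates a parametric stand-in for a segmented primate labyrinth: three
#' SCC ampullary-nerve branches (LH, LA, LP) with `n_per_crista` model
#' afferents each, distributed over peripheral/intermediate/central crista
#' zones (default 40/30/30 split), fiber trajectories converging from the
#' crista surface to a common nerve trunk, nodes of Ranvier spaced at
#' `internode_ratio` times the fiber diameter, one stimulating electrode
#' 0.2 mm from each crista center, a distant return electrode, and a
#' recording/reference electrode pair per branch. Fully reproducible given
#' `seed`.
#'
#' @param n_per_crista model fibers per crista (default 100; minimum 3, one
#'   per zone).
#' @param seed integer seed controlling start positions and fiber diameters.
#' @param internode_ratio node-of-Ranvier spacing as a multiple of fiber
#'   diameter (default 100).
#' @param diam_mean_um,diam_sd_um,diam_bounds_um truncated-normal fiber
#'   diameter distribution, micrometers.
#' @param axes optional named list of canal rotation axes (unit 3-vectors for
#'   LH, LA, LP); normalized before use.
#' @return an object of class `vest_anatomy`: list with tibbles `fibers`
#'   (one row per fiber, node coordinates as a list-column of matrices) and
#'   `electrodes`, the canal `axes`, and the generating `params`.
#' @examples
#' anat <- build_default_labyrinth(n_per_crista = 5, seed = 1)
#' dplyr::count(anat$fibers, branch)
#' @export
build_default_labyrinth <- function(n_per_crista = 100, seed = 1,
                                    internode_ratio = 100,
                                    diam_mean_um = 3, diam_sd_um = 0.5,
                                    diam_bounds_um = c(2, 4),
                                    axes = NULL) {
  check_number(n_per_crista, "n_per_crista", lower = 3)
  check_number(internode_ratio, "internode_ratio", lower = 1)
  n_per_crista <- as.integer(n_per_crista)

  fibers <- with_local_seed(seed, {
    dplyr::bind_rows(lapply(names(BRANCH_DIRS), function(b) {
      build_branch_fibers(b, n_per_crista, internode_ratio,
                          diam_mean_um, diam_sd_um, diam_bounds_um)
    }))
  })

  electrodes <- dplyr::bind_rows(lapply(names(BRANCH_DIRS), function(b) {
    d <- unit_vec(BRANCH_DIRS[[b]])
    center <- CRISTA_DIST_MM * d
    lat <- orth_unit(d)
    stim <- center + STIM_OFFSET_MM * d
    rec <- stim + 0.35 * lat
    ref <- stim + 0.70 * lat
    tibble::tibble(
      label = paste0(b, c("_stim", "_rec", "_ref")),
      role = c("STIM", "RECORD", "REFERENCE"),
      branch = b,
      x = c(stim[1], rec[1], ref[1]),
      y = c(stim[2], rec[2], ref[2]),
      z = c(stim[3], rec[3], ref[3])
    )
  }))
  electrodes <- dplyr::bind_rows(
    electrodes,
    tibble::tibble(label = "return", role = "RETURN", branch = NA_character_,
                   x = 12, y = 12, z = 12)
  )

  axes <- if (is.null(axes)) DEFAULT_AXES else lapply(axes, unit_vec)
  stopifnot(all(c("LH", "LA", "LP") %in% names(axes)))
  validate_axes(axes)

  structure(
    list(fibers = fibers, electrodes = electrodes, axes = axes,
         params = list(n_per_crista = n_per_crista, seed = seed,
                       internode_ratio = internode_ratio,
                       diam_mean_um = diam_mean_um, diam_sd_um = diam_sd_um,
                       diam_bounds_um = diam_bounds_um,
                       frame = c("horizontal", "LARP", "RALP"))),
    class = "vest_anatomy"
  )
}

validate_axes <- function(axes) {
  scc <- axes[intersect(names(axes), c("LH", "LA", "LP"))]
  for (a in scc) {
    if (abs(vec_norm(a) - 1) > 1e-9) stop_invalid("canal axes must be unit-norm")
  }
  pairs <- utils::combn(length(scc), 2)
  for (k in seq_len(ncol(pairs))) {
    ang <- acos(min(1, abs(sum(scc[[pairs[1, k]]] * scc[[pairs[2, k]]])))) * 180 / pi
    if (ang < 30) stop_invalid("SCC axes must be pairwise non-parallel (> 30 deg)")
  }
  invisible(axes)
}

#' @export
print.vest_anatomy <- function(x, ...) {
  cat(sprintf("<vest_anatomy> %d fibers in %d branches, %d electrodes (seed %s)\n",
              nrow(x$fibers), length(unique(x$fibers$branch)),
              nrow(x$electrodes), format(x$params$seed)))
  invisible(x)
}

#' Canal rotation axes of an anatomy
#'
#' @param anatomy a `vest_anatomy`.
#' @return named list mapping branch to its unit rotation axis in the
#'   {horizontal, LARP, RALP} frame.
#' @export
canal_axes <- function(anatomy) {
  stopifnot(inherits(anatomy, "vest_anatomy"))
  lapply(anatomy$axes, unit_vec)
}

#' Add a facial-nerve branch for upper-limit detection
#'
#' Places a non-SCC fiber bundle `offset_mm` away from the horizontal-canal
#' crista, farther from every stimulating electrode than the target fibers.
#' Facial-nerve activation sets the upper limit of usable stimulation current.
#'
#' @param anatomy a `vest_anatomy`.
#' @param offset_mm distance from the LH crista center (> 0; default 1.5).
#' @param n_fibers fiber count (default 50; 0 adds an empty branch).
#' @param seed RNG seed for start positions and diameters.
#' @return the anatomy with a `FACIAL` branch appended.
#' @export
add_facial_branch <- function(anatomy, offset_mm = 1.5, n_fibers = 50,
                              seed = anatomy$params$seed + 1000L) {
  stopifnot(inherits(anatomy, "vest_anatomy"))
  check_number(offset_mm, "offset_mm", lower = 0, strict_lower = TRUE)
  check_number(n_fibers, "n_fibers", lower = 0)
  n_fibers <- as.integer(n_fibers)
  if (n_fibers == 0) return(anatomy)

  d <- unit_vec(BRANCH_DIRS$LH)
  lat <- -orth_unit(d)  # opposite side from the recording electrodes
  base <- CRISTA_DIST_MM * d + offset_mm * lat
  fibers <- with_local_seed(seed, {
    e2 <- pracma_cross(d, lat)
    radius <- 0.15 * sqrt(stats::runif(n_fibers))
    theta <- stats::runif(n_fibers, 0, 2 * pi)
    diam <- draw_diameters(n_fibers, anatomy$params$diam_mean_um,
                           anatomy$params$diam_sd_um,
                           anatomy$params$diam_bounds_um[1],
                           anatomy$params$diam_bounds_um[2])
    purrr::map(seq_len(n_fibers), function(i) {
      p0 <- base + radius[i] * (cos(theta[i]) * lat + sin(theta[i]) * e2)
      verts <- rbind(p0, p0 + 5.0 * unit_vec(lat - unit_vec(c(1, 1, 1))))
      spacing <- anatomy$params$internode_ratio * diam[i] / 1000
      n_nodes <- max(11L, as.integer(floor(5.0 / spacing)) + 1L)
      list(nodes = polyline_points(verts, spacing * (seq_len(n_nodes) - 1)),
           diam = diam[i], spacing = spacing)
    })
  })

  new_rows <- tibble::tibble(
    branch = "FACIAL", fiber = seq_len(n_fibers), zone = "central",
    diameter_um = purrr::map_dbl(fibers, "diam"),
    spacing_mm = purrr::map_dbl(fibers, "spacing"),
    n_nodes = purrr::map_int(fibers, ~ nrow(.x$nodes)),
    nodes = purrr::map(fibers, "nodes")
  )

  # geometry check: facial fibers must not overlap SCC fibers
  scc_nodes <- do.call(rbind, anatomy$fibers$nodes)
  fac_nodes <- do.call(rbind, new_rows$nodes)
  min_d <- min_pairwise_distance(fac_nodes, scc_nodes)
  if (min_d < 0.05) {
    stop_invalid(sprintf(
      "facial branch overlaps SCC fibers (min distance %.3f mm < 0.05 mm)",
      min_d), class = "vestibsim_geometry")
  }

  anatomy$fibers <- dplyr::bind_rows(anatomy$fibers, new_rows)
  anatomy
}

min_pairwise_distance <- function(a, b) {
  # chunked to bound memory for large node sets
  best <- Inf
  idx <- split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / 2000))
  for (ii in idx) {
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[ii, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Serialize / restore an anatomy as JSON
#'
#' Full-precision coordinates: a write/read round-trip reproduces the anatomy
#' exactly. The schema is versioned via a top-level `format` field.
#'
#' @param anatomy a `vest_anatomy`.
#' @param path file path.
#' @export
write_anatomy_json <- function(anatomy, path) {
  stopifnot(inherits(anatomy, "vest_anatomy"))
  payload <- list(
    format = "vestibsim-anatomy-1",
    fibers = lapply(seq_len(nrow(anatomy$fibers)), function(i) {
      r <- anatomy$fibers[i, ]
      list(branch = r$branch, fiber = r$fiber, zone = r$zone,
           diameter_um = r$diameter_um, spacing_mm = r$spacing_mm,
           nodes = apply(r$nodes[[1]], 1, identity, simplify = FALSE))
    }),
    electrodes = as.list(anatomy$electrodes),
    axes = anatomy$axes,
    params = anatomy$params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_anatomy_json
#' @export
read_anatomy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(x$format) || !identical(x$format, "vestibsim-anatomy-1")) {
    stop_invalid("not a vestibsim anatomy JSON (or incompatible version)",
                 class = "vestibsim_incompatible")
  }
  fib <- x$fibers
  nodes <- purrr::map(fib$nodes, function(m) {
    m <- if (is.list(m)) do.call(rbind, m) else as.matrix(m)
    dimnames(m) <- NULL
    m
  })
  fibers <- tibble::tibble(
    branch = fib$branch, fiber = as.integer(fib$fiber), zone = fib$zone,
    diameter_um = fib$diameter_um, spacing_mm = fib$spacing_mm,
    n_nodes = purrr::map_int(nodes, nrow), nodes = nodes
  )
  params <- x$params
  params$diam_bounds_um <- unlist(params$diam_bounds_um)
  params$frame <- unlist(params$frame)
  structure(
    list(fibers = fibers,
         electrodes = tibble::as_tibble(x$electrodes),
         axes = lapply(x$axes, as.numeric),
         params = params),
    class = "vest_anatomy"
  )
}

# electrode lookup helpers
electrode_pos <- function(anatomy, label) {
  row <- anatomy$electrodes[anatomy$electrodes$label == label, ]
  if (nrow(row) != 1) stop_invalid(paste("unknown electrode:", label))
  c(row$x, row$y, row$z)
}

stim_electrode_for <- function(anatomy, branch) {
  paste0(branch, "_stim")
}
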