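# Rigid water geometry (3-site): O-H bond length and H-O-H angle.
.WATER_OH <- 0.09572      # nm
.WATER_HOH <- 104.52      # degrees

# Toy solute template: a central carbon scaffold carrying two hydroxyl-like
# oxygen sites (O9, O9p, each with a hydrogen) and four methoxy-like
# acceptor oxygens (O3, O4, O4p, O5p) on octahedral axes 0.25 nm from the
# centre. Hydroxyl hydrogens are tilted 120 degrees off the binding axis so
# a first-shell water never strays within the 0.30 nm cutoff of them.
.solute_template <- function() {
  r_site <- 0.25; r_oh <- 0.10
  axes <- rbind(O9 = c(1, 0, 0), O9p = c(-1, 0, 0), O3 = c(0, 1, 0),
                O4 = c(0, -1, 0), O4p = c(0, 0, 1), O5p = c(0, 0, -1))
  coords <- rbind(C = c(0, 0, 0))
  tilt <- function(axis) {
    # unit vector at 120 deg from `axis`, in a fixed perpendicular plane
    perp <- if (abs(axis[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    perp <- perp - sum(perp * axis) * axis
    perp <- perp / sqrt(sum(perp^2))
    cos(120 * pi / 180) * axis + sin(120 * pi / 180) * perp
  }
  coords <- rbind(coords,
                  O9 = axes["O9", ] * r_site,
                  H9 = axes["O9", ] * r_site + tilt(axes["O9", ]) * r_oh,
                  O9p = axes["O9p", ] * r_site,
                  H9p = axes["O9p", ] * r_site + tilt(axes["O9p", ]) * r_oh,
                  O3 = axes["O3", ] * r_site, O4 = axes["O4", ] * r_site,
                  O4p = axes["O4p", ] * r_site, O5p = axes["O5p", ] * r_site)
  list(
    template = list(
      name = "LIG",
      elements = c("C", "O", "H", "O", "H", "O", "O", "O", "O"),
      bonds = cbind(c(1L, 2L, 1L, 4L, 1L, 1L, 1L, 1L),
                    c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)),
      sites = data.frame(
        label = c("O9", "H9", "O9p", "H9p", "O3", "O4", "O4p", "O5p"),
        local = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
        roles = c("donor,acceptor", "hydrogen", "donor,acceptor",
                  "hydrogen", "acceptor", "acceptor", "acceptor",
                  "acceptor"),
        stringsAsFactors = FALSE)),
    coords = coords,
    binding_sites = c("O9", "O9p", "O3", "O4", "O4p", "O5p"),
    site_axes = axes,
    site_local = c(O9 = 2L, O9p = 4L, O3 = 6L, O4 = 7L, O4p = 8L,
                   O5p = 9L))
}

.water_template <- function() {
  list(name = "WAT", elements = c("O", "H", "H"),
       bonds = cbind(c(1L, 1L), c(2L, 3L)),
       sites = data.frame(label = c("O", "H1", "H2"), local = 1:3,
                          roles = c("donor,acceptor", "hydrogen",
                                    "hydrogen"),
                          stringsAsFactors = FALSE))
}

#' Parameters of the synthetic trajectory generator
#'
#' Defines a toy solvated system with known ground truth: a rigid six-site
#' solute at the centre of a cubic periodic box, surrounded by rigid 3-site
#' waters. Each solute oxygen site carries one binding slot whose occupancy
#' evolves as a two-state Markov chain: a bound water unbinds with per-frame
#' probability `p_unbind` (so the true mean bound time is `1/p_unbind`
#' frames), an empty slot binds a free water with probability `r_rebind`,
#' and a water that stays bound swaps which hydrogen points at the site with
#' probability `q_swap`. Bound waters sit in the first shell (near hydrogen
#' at `shell_radius` from the site oxygen, far hydrogen geometrically fixed
#' near 0.31 nm); free waters are uniform in the box outside an exclusion
#' zone, so they never cross the 0.30 nm criterion.
#'
#' @param n_waters number of water molecules.
#' @param box_edge cubic box edge, nm.
#' @param n_frames number of frames.
#' @param frame_interval time between frames, ps.
#' @param shell_radius mean site-oxygen to near-hydrogen distance, nm.
#' @param radial_jitter_sd Gaussian jitter of `shell_radius`, nm (truncated
#'   at two standard deviations so bound geometry never crosses the
#'   criterion boundary).
#' @param angular_jitter_deg half-angle of the cone around the binding axis
#'   within which the bound-water direction is drawn.
#' @param p_unbind per-frame unbind probability.
#' @param q_swap per-frame hydrogen-swap probability for a water that stays
#'   bound; `NULL` selects the balanced rate `p_unbind / (1 - p_unbind)`,
#'   under which a bound stay comprises two hydrogen episodes on average so
#'   the hydrogen-mode doubling convention is exact in expectation.
#' @param r_rebind per-frame rebind probability of an empty slot.
#' @param both_hydrogens place bound waters oxygen-first so both hydrogens
#'   fall inside the 0.30 nm cutoff (raw degree 2 per bound water).
#' @param seed integer random seed; identical seeds give byte-identical
#'   trajectories.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_waters = 200L, box_edge = 3.0,
                             n_frames = 500L, frame_interval = 0.5,
                             shell_radius = 0.18,
                             radial_jitter_sd = 0.005,
                             angular_jitter_deg = 10,
                             p_unbind = 0.2, q_swap = NULL,
                             r_rebind = 0.9, both_hydrogens = FALSE,
                             seed = 1L) {
  if (is.null(q_swap)) {
    # balanced rate: a bound stay splits into two hydrogen episodes on
    # average (degenerate when every stay lasts a single frame)
    q_swap <- if (p_unbind >= 1) 0 else
      min(1, p_unbind / (1 - p_unbind))
  }
  for (p in c(p_unbind = p_unbind, q_swap = q_swap, r_rebind = r_rebind))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (n_waters < 7L)
    stop("need at least 7 waters (one per binding slot plus one free)")
  if (box_edge < 1.5)
    stop("box_edge too small to hold the solute plus an exclusion zone")
  if (n_waters * 0.004 > box_edge^3)
    stop("box too small to place ", n_waters, " waters without overlap")
  if (shell_radius + 2 * radial_jitter_sd >= 0.30 - 0.05)
    stop("shell_radius + jitter too close to the 0.30 nm criterion")
  structure(list(n_waters = as.integer(n_waters), box_edge = box_edge,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 shell_radius = shell_radius,
                 radial_jitter_sd = radial_jitter_sd,
                 angular_jitter_deg = angular_jitter_deg,
                 p_unbind = p_unbind, q_swap = q_swap,
                 r_rebind = r_rebind,
                 both_hydrogens = isTRUE(both_hydrogens),
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

# random unit vector
.rand_unit <- function() {
  repeat {
    u <- stats::rnorm(3L)
    n2 <- sum(u^2)
    if (n2 > 1e-12) return(u / sqrt(n2))
  }
}

# random unit vector within a cone of half-angle `deg` around `axis`
.rand_cone <- function(axis, deg) {
  if (deg <= 0) return(axis)
  ct <- stats::runif(1L, cos(deg * pi / 180), 1)
  st <- sqrt(max(0, 1 - ct^2))
  phi <- stats::runif(1L, 0, 2 * pi)
  perp <- if (abs(axis[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- perp - sum(perp * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2L] * e1[3L] - axis[3L] * e1[2L],
          axis[3L] * e1[1L] - axis[1L] * e1[3L],
          axis[1L] * e1[2L] - axis[2L] * e1[1L])
  ct * axis + st * (cos(phi) * e1 + sin(phi) * e2)
}

# place a rigid water bound to a site: returns 3x3 coords (O, H1, H2)
# ordered by local index, with the "active" hydrogen nearest the site
.place_bound_water <- function(site_pos, axis, active_h, params) {
  u <- .rand_cone(axis, params$angular_jitter_deg)
  hoh <- .WATER_HOH * pi / 180
  perp <- .rand_unit()
  perp <- perp - sum(perp * u) * u
  perp <- perp / sqrt(sum(perp^2))
  if (params$both_hydrogens) {
    b <- params$shell_radius + 0.04
    ow <- site_pos + u * b
    half <- hoh / 2
    to_site <- -u
    h_a <- ow + .WATER_OH * (cos(half) * to_site + sin(half) * perp)
    h_b <- ow + .WATER_OH * (cos(half) * to_site - sin(half) * perp)
  } else {
    s <- params$shell_radius
    if (params$radial_jitter_sd > 0) {
      repeat {
        s <- stats::rnorm(1L, params$shell_radius, params$radial_jitter_sd)
        if (abs(s - params$shell_radius) <= 2 * params$radial_jitter_sd)
          break
      }
    }
    h_a <- site_pos + u * s
    ow <- site_pos + u * (s + .WATER_OH)
    # far hydrogen: HOH angle away from the near one, random azimuth
    dir <- cos(hoh) * (-u) + sin(hoh) * perp
    h_b <- ow + .WATER_OH * dir
  }
  if (active_h == 1L) rbind(ow, h_a, h_b) else rbind(ow, h_b, h_a)
}

# place a free water uniformly in the box, outside `excl` nm of all site
# oxygens (minimum-image); error after `retries` failures
.place_free_water <- function(site_pos_mat, box, excl, retries = 200L) {
  for (k in seq_len(retries)) {
    ow <- stats::runif(3L, 0, box)
    a <- matrix(ow, nrow = nrow(site_pos_mat), ncol = 3L, byrow = TRUE)
    d <- minimum_image_distance(a, site_pos_mat, box)$distance
    if (all(d > excl)) {
      u1 <- .rand_unit()
      perp <- .rand_unit()
      perp <- perp - sum(perp * u1) * u1
      perp <- perp / sqrt(sum(perp^2))
      hoh <- .WATER_HOH * pi / 180
      h1 <- ow + .WATER_OH * u1
      h2 <- ow + .WATER_OH * (cos(hoh) * u1 + sin(hoh) * perp)
      return(rbind(ow, h1, h2))
    }
  }
  stop("generation error: could not place a free water after ",
       retries, " retries (box too crowded)")
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Simulates the Markovian site-occupancy model described in
#' [synthetic_params()] and renders it as coordinate frames (and optionally
#' as the same .xyz/.gro/topology files the readers consume). The exact
#' bound/unbound state sequence is returned, together with the analytic
#' expectations it was generated from, so analysis results can be checked
#' against construction-time truth.
#'
#' @param params a [synthetic_params()] object.
#' @param dir optional output directory; when given, writes
#'   `<basename>.topology`, `<basename>.xyz`, `<basename>.gro` (first
#'   frame), `<basename>_truth.csv` and `<basename>_expectations.json`.
#' @param basename file name stem used under `dir`.
#' @return A list of class `synthetic_trajectory`: `frames` (list of
#'   [md_frame()]), `topology`, `truth` (data.frame `frame`, `site`,
#'   `water` id or `NA`, `active_h`), `expectations` (list:
#'   `mean_bound_frames = 1/p`, `mean_lifetime_ps`, `occupancy =
#'   r/(p + r)`, `mean_h_episode_frames`), `params`, `files`.
#' @export
generate_trajectory <- function(params, dir = NULL,
                                basename = "synthetic") {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  sol <- .solute_template()
  topology <- system_topology(
    templates = list(LIG = sol$template, WAT = .water_template()),
    layout = data.frame(template = c("LIG", "WAT"),
                        count = c(1L, params$n_waters),
                        stringsAsFactors = FALSE),
    solvent = "WAT", box_edge = params$box_edge)
  box <- params$box_edge
  centre <- rep(box / 2, 3L)
  sol_coords <- sweep(sol$coords, 2L, centre, `+`)
  sites <- sol$binding_sites
  ns <- length(sites)
  site_pos <- sol_coords[sites, , drop = FALSE]
  site_axes <- sol$site_axes[sites, , drop = FALSE]
  excl <- 0.45                       # free-water exclusion radius, nm

  p <- params$p_unbind; q <- params$q_swap; r <- params$r_rebind
  occ_stat <- if (p + r > 0) r / (p + r) else 1
  state <- data.frame(site = sites, water = NA_integer_,
                      active_h = NA_integer_, stringsAsFactors = FALSE)
  free <- seq_len(params$n_waters)
  for (k in seq_len(ns)) {
    if (stats::runif(1L) < occ_stat) {
      w <- free[sample.int(length(free), 1L)]
      free <- setdiff(free, w)
      state$water[k] <- w
      state$active_h[k] <- sample(1:2, 1L)
    }
  }

  n_atoms <- nrow(topology$atoms)
  wat_offset <- nrow(sol_coords)     # atoms before the first water
  frames <- vector("list", params$n_frames)
  truth <- vector("list", params$n_frames)
  elements <- topology$atoms$element

  for (t in seq_len(params$n_frames)) {
    if (t > 1L) {
      for (k in seq_len(ns)) {
        if (!is.na(state$water[k])) {
          if (stats::runif(1L) < p) {
            free <- c(free, state$water[k])
            state$water[k] <- NA_integer_
            state$active_h[k] <- NA_integer_
          } else if (stats::runif(1L) < q) {
            state$active_h[k] <- 3L - state$active_h[k]
          }
        } else if (length(free) && stats::runif(1L) < r) {
          w <- free[sample.int(length(free), 1L)]
          free <- setdiff(free, w)
          state$water[k] <- w
          state$active_h[k] <- sample(1:2, 1L)
        }
      }
    }
    coords <- matrix(NA_real_, n_atoms, 3L)
    coords[seq_len(wat_offset), ] <- sol_coords
    placed <- rep(FALSE, params$n_waters)
    for (k in seq_len(ns)) {
      w <- state$water[k]
      if (!is.na(w)) {
        wc <- .place_bound_water(site_pos[k, ], site_axes[k, ],
                                 state$active_h[k], params)
        rows <- wat_offset + (w - 1L) * 3L + 1:3
        coords[rows, ] <- wc
        placed[w] <- TRUE
      }
    }
    for (w in which(!placed)) {
      rows <- wat_offset + (w - 1L) * 3L + 1:3
      coords[rows, ] <- .place_free_water(site_pos, box, excl)
    }
    frames[[t]] <- md_frame(elements, coords, box_edge = box,
                            index = t - 1L,
                            time = (t - 1L) * params$frame_interval)
    truth[[t]] <- data.frame(frame = t - 1L, site = state$site,
                             water = state$water,
                             active_h = state$active_h,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  expectations <- list(
    mean_bound_frames = if (p > 0) 1 / p else Inf,
    mean_lifetime_ps = if (p > 0) params$frame_interval / p else Inf,
    occupancy = occ_stat,
    mean_h_episode_frames = if (p + q - p * q > 0) 1 / (p + q - p * q)
                            else Inf)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      topology = file.path(dir, paste0(basename, ".topology")),
      xyz = file.path(dir, paste0(basename, ".xyz")),
      gro = file.path(dir, paste0(basename, ".gro")),
      truth = file.path(dir, paste0(basename, "_truth.csv")),
      expectations = file.path(dir,
                               paste0(basename, "_expectations.json")))
    write_topology(topology, files$topology)
    write_xyz_trajectory(frames, files$xyz)
    write_gro_structure(frames[[1L]], files$gro, topology = topology)
    utils::write.csv(truth, files$truth, row.names = FALSE)
    jsonlite::write_json(expectations, files$expectations,
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(frames = frames, topology = topology, truth = truth,
                 expectations = expectations, params = params,
                 files = files),
            class = "synthetic_trajectory")
}

#' @export
print.synthetic_trajectory <- function(x, ...) {
  cat(sprintf(
    "synthetic_trajectory: %d frames, %d waters, box %.3g nm, seed %d\n",
    x$params$n_frames, x$params$n_waters, x$params$box_edge,
    x$params$seed))
  cat(sprintf(
    "  p_unbind %.3g, q_swap %.3g, r_rebind %.3g -> E[bound] %.3g frames\n",
    x$params$p_unbind, x$params$q_swap, x$params$r_rebind,
    x$expectations$mean_bound_frames))
  invisible(x)
}
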