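#' Define a geometric hydrogen-bond criterion
#'
#' Two families of criteria are supported. The graph-formalism default
#' measures the nonbonded distance between an oxygen site and a (covalently
#' bound) hydrogen, `r(O...H) < 0.30 nm`, with the bond angle left
#' unspecified so every orientation counts. The comparison criterion used by
#' donor-acceptor analyses measures the donor-oxygen to acceptor-oxygen
#' distance, `r(DA) <= 0.35 nm`, together with an `H-D-A` angle of at most
#' 30 degrees.
#'
#' @param name short name recorded in outputs.
#' @param measured_pair `"OH"` (oxygen site vs hydrogen) or `"DA"`
#'   (donor oxygen vs acceptor oxygen).
#' @param distance_cutoff distance cutoff in nm.
#' @param strict logical: `TRUE` compares with `<`, `FALSE` with `<=`.
#' @param angle_cutoff angle cutoff in degrees, or `NULL` for no angle test.
#' @param angle_convention `"HDA"`: the angle at the donor between D->H and
#'   D->A must be `<= angle_cutoff`; `"DHA"`: the deviation from linearity of
#'   the D-H...A angle at the hydrogen (180 minus the angle) must be
#'   `<= angle_cutoff`.
#' @return An object of class `hb_rule`.
#' @export
hb_rule <- function(name = "oh_distance",
                    measured_pair = c("OH", "DA"),
                    distance_cutoff = 0.30,
                    strict = TRUE,
                    angle_cutoff = NULL,
                    angle_convention = c("HDA", "DHA")) {
  measured_pair <- match.arg(measured_pair)
  angle_convention <- match.arg(angle_convention)
  if (!is.numeric(distance_cutoff) || distance_cutoff <= 0)
    stop("distance_cutoff must be positive")
  if (!is.null(angle_cutoff) &&
      (!is.numeric(angle_cutoff) || angle_cutoff <= 0 || angle_cutoff > 180))
    stop("angle_cutoff must lie in (0, 180] degrees (or be NULL)")
  structure(list(name = name, measured_pair = measured_pair,
                 distance_cutoff = distance_cutoff, strict = isTRUE(strict),
                 angle_cutoff = angle_cutoff,
                 angle_convention = angle_convention),
            class = "hb_rule")
}

#' @export
print.hb_rule <- function(x, ...) {
  cat(sprintf("hb_rule '%s': r(%s) %s %.4g nm, angle %s\n", x$name,
              if (x$measured_pair == "OH") "O...H" else "DA",
              if (x$strict) "<" else "<=", x$distance_cutoff,
              if (is.null(x$angle_cutoff)) "unspecified"
              else sprintf("%s <= %g deg", x$angle_convention,
                           x$angle_cutoff)))
  invisible(x)
}

#' Minimum-image distance in a cubic periodic box
#'
#' Returns the distance between `a` and the nearest periodic image of `b`,
#' together with the integer image shift applied to `b` (in box lengths), so
#' that `b + shift * box_edge` is the image actually measured.
#'
#' @param a,b numeric length-3 positions (nm), or n-by-3 matrices for a
#'   vectorised call (rows paired).
#' @param box_edge cubic box edge length in nm.
#' @return For vector input, a list with `distance` (scalar, nm) and `shift`
#'   (integer triple). For matrix input, `distance` is a vector and `shift`
#'   an n-by-3 matrix.
#' @export
minimum_image_distance <- function(a, b, box_edge) {
  if (!is.numeric(box_edge) || box_edge <= 0)
    stop("box_edge must be positive")
  vec_in <- is.null(dim(a))
  a <- unname(rbind(a)); b <- unname(rbind(b))
  disp <- b - a
  shift <- -round(disp / box_edge)
  dm <- disp + shift * box_edge
  d <- unname(sqrt(rowSums(dm * dm)))
  if (vec_in) list(distance = d[1L], shift = as.integer(shift[1L, ]))
  else list(distance = d, shift = shift)
}

# Minimum-image displacement vectors a -> b (rows paired), no shift returned.
.min_image_disp <- function(a, b, box_edge) {
  disp <- b - a
  disp - round(disp / box_edge) * box_edge
}

## ------------------------------------------------------------------------
## Candidate pair table (precomputable per topology + rule)

# Which vertex pairs can form an edge under the rule: returns integer vectors
# i, j into the vertex table. Intramolecular pairs are excluded; solvent-
# solvent pairs only when include_water_water.
.candidate_pairs <- function(topology, rule,
                             include_water_water = FALSE) {
  v <- topology$vertices
  if (rule$measured_pair == "OH") {
    ia <- which(v$element == "O")
    ib <- which(v$hydrogen)
  } else {
    ia <- which(v$donor)
    ib <- which(v$acceptor)
  }
  if (!length(ia) || !length(ib))
    return(list(i = integer(), j = integer()))
  g <- expand.grid(i = ia, j = ib, KEEP.OUT.ATTRS = FALSE)
  keep <- v$molecule[g$i] != v$molecule[g$j]
  if (!include_water_water)
    keep <- keep & !(v$solvent[g$i] & v$solvent[g$j])
  if (rule$measured_pair == "DA") {
    # donor and acceptor roles overlap (water O is both); drop duplicate
    # unordered pairs so each O-O pair is tested once
    key_lo <- pmin(g$i, g$j); key_hi <- pmax(g$i, g$j)
    keep <- keep & !duplicated(key_lo + (key_hi - 1) * (nrow(v) + 1))
  }
  list(i = g$i[keep], j = g$j[keep])
}

# For every hydrogen vertex, the serial of its covalently bonded heavy atom
# (its donor); for every donor oxygen vertex, serials of its hydrogens.
.parent_maps <- function(topology) {
  at <- topology$atoms
  bonds <- topology$bond_serials
  nb <- list()
  if (nrow(bonds)) {
    nb <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
  }
  neigh <- function(serial) {
    x <- nb[[as.character(serial)]]
    if (is.null(x)) integer() else x
  }
  v <- topology$vertices
  h_parent <- rep(NA_integer_, nrow(v))
  o_hydrogens <- vector("list", nrow(v))
  for (k in seq_len(nrow(v))) {
    nbr <- neigh(v$serial[k])
    if (v$element[k] == "H") {
      heavy <- nbr[at$element[nbr] != "H"]
      if (length(heavy)) h_parent[k] <- heavy[1L]
    } else if (v$element[k] == "O") {
      o_hydrogens[[k]] <- nbr[at$element[nbr] == "H"]
    }
  }
  list(h_parent = h_parent, o_hydrogens = o_hydrogens)
}

.angle_deg <- function(v1, v2) {
  # angle between paired row vectors, degrees
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

#' Build the per-frame intermolecular interaction graph
#'
#' Applies a geometric hydrogen-bond criterion to one frame and returns the
#' resulting graph. Vertices are atom-level interaction sites (every
#' site-labelled atom of every molecule instance), so a water whose two
#' hydrogens both fall within the cutoff of a site contributes two edges to
#' that site. Intramolecular pairs are never edges. Distances honour
#' periodic boundaries via the minimum-image convention, so edges may cross
#' the box boundary; the image shift used is stored on each edge.
#'
#' @param frame an [md_frame()]; its `box_edge` (or the topology's) must be
#'   known.
#' @param topology a `system_topology` consistent with the frame.
#' @param rule an [hb_rule()]; default: `r(O...H) < 0.30` nm, no angle test.
#' @param include_water_water also compute solvent-solvent edges (needed for
#'   geodesics through the solvent network; off by default for speed).
#' @param pairs optional precomputed candidate pair table (see
#'   [build_frame_graphs()]); computed from the topology when `NULL`.
#' @return An object of class `frame_graph`: `frame_index`, `time`,
#'   `vertices` (the topology's vertex table), `edges` (data.frame with
#'   vertex indices `v1 < v2`, `distance` in nm, the image shift columns
#'   `sx`, `sy`, `sz`, and `h_serial`, the hydrogen mediating a
#'   donor-acceptor edge, `NA` for `"OH"`-rule edges).
#' @export
build_frame_graph <- function(frame, topology, rule = hb_rule(),
                              include_water_water = FALSE, pairs = NULL) {
  check_frame_topology(frame, topology)
  box <- frame$box_edge
  if (is.na(box)) box <- topology$box_edge
  if (is.na(box))
    stop("no box_edge known (set it on the frame or in the topology)")
  v <- topology$vertices
  if (is.null(pairs))
    pairs <- .candidate_pairs(topology, rule, include_water_water)
  i <- pairs$i; j <- pairs$j
  edges <- data.frame(v1 = integer(), v2 = integer(), distance = numeric(),
                      sx = integer(), sy = integer(), sz = integer(),
                      h_serial = integer())
  if (length(i)) {
    pa <- frame$coords[v$serial[i], , drop = FALSE]
    pb <- frame$coords[v$serial[j], , drop = FALSE]
    mi <- minimum_image_distance(pa, pb, box)
    keep <- if (rule$strict) mi$distance < rule$distance_cutoff
            else mi$distance <= rule$distance_cutoff
    i <- i[keep]; j <- j[keep]
    d <- mi$distance[keep]
    sh <- mi$shift[keep, , drop = FALSE]
    h_serial <- rep(NA_integer_, length(i))
    if (!is.null(rule$angle_cutoff) && length(i)) {
      pm <- .parent_maps(topology)
      if (rule$measured_pair == "OH") {
        # donor = heavy atom bonded to the hydrogen endpoint (j)
        dser <- pm$h_parent[j]
        ok <- !is.na(dser)
        ang <- rep(NA_real_, length(i))
        if (any(ok)) {
          D <- frame$coords[dser[ok], , drop = FALSE]
          H <- frame$coords[v$serial[j[ok]], , drop = FALSE]
          A <- frame$coords[v$serial[i[ok]], , drop = FALSE]
          if (rule$angle_convention == "HDA")
            ang[ok] <- .angle_deg(.min_image_disp(D, H, box),
                                  .min_image_disp(D, A, box))
          else
            ang[ok] <- 180 - .angle_deg(.min_image_disp(H, D, box),
                                        .min_image_disp(H, A, box))
        }
        keep2 <- ok & ang <= rule$angle_cutoff
        i <- i[keep2]; j <- j[keep2]; d <- d[keep2]
        sh <- sh[keep2, , drop = FALSE]
        h_serial <- h_serial[keep2]
      } else {
        # expand each O-O pair over every admissible donor direction and
        # each such donor's hydrogens; an edge per (donor hydrogen,
        # acceptor) pair that passes the test. Both endpoints can act as
        # donor (water O towards a hydroxyl O and vice versa).
        dir1 <- v$donor[i] & v$acceptor[j]   # i donates to j
        dir2 <- v$donor[j] & v$acceptor[i]   # j donates to i
        don0 <- c(i[dir1], j[dir2])
        acc0 <- c(j[dir1], i[dir2])
        pair0 <- c(seq_along(i)[dir1], seq_along(i)[dir2])
        hs <- pm$o_hydrogens[don0]
        nh <- lengths(hs)
        rep_idx <- pair0[rep.int(seq_along(don0), nh)]
        don_rep <- rep.int(don0, nh)
        acc_rep <- rep.int(acc0, nh)
        hser <- unlist(hs, use.names = FALSE)
        if (length(rep_idx)) {
          D <- frame$coords[v$serial[don_rep], , drop = FALSE]
          A <- frame$coords[v$serial[acc_rep], , drop = FALSE]
          H <- frame$coords[hser, , drop = FALSE]
          ang <- if (rule$angle_convention == "HDA")
            .angle_deg(.min_image_disp(D, H, box), .min_image_disp(D, A, box))
          else
            180 - .angle_deg(.min_image_disp(H, D, box),
                             .min_image_disp(H, A, box))
          keep2 <- ang <= rule$angle_cutoff
          i <- i[rep_idx][keep2]; j <- j[rep_idx][keep2]
          d <- d[rep_idx][keep2]
          sh <- sh[rep_idx, , drop = FALSE][keep2, , drop = FALSE]
          h_serial <- hser[keep2]
        } else {
          i <- j <- integer(); d <- numeric()
          sh <- matrix(0, 0L, 3L); h_serial <- integer()
        }
      }
    }
    if (length(i)) {
      # normalise v1 < v2; flip the image shift when endpoints swap
      swap <- i > j
      v1 <- ifelse(swap, j, i); v2 <- ifelse(swap, i, j)
      sh[swap, ] <- -sh[swap, , drop = FALSE]
      ord <- order(v1, v2, h_serial, method = "radix")
      edges <- data.frame(v1 = v1, v2 = v2, distance = d,
                          sx = as.integer(sh[, 1L]),
                          sy = as.integer(sh[, 2L]),
                          sz = as.integer(sh[, 3L]),
                          h_serial = as.integer(h_serial))[ord, ]
      rownames(edges) <- NULL
    }
  }
  structure(list(frame_index = frame$index, time = frame$time,
                 vertices = v, edges = edges, rule = rule,
                 box_edge = box),
            class = "frame_graph")
}

#' @export
print.frame_graph <- function(x, ...) {
  cat(sprintf("frame_graph: frame %d, %d vertices, %d edges (rule '%s')\n",
              x$frame_index, nrow(x$vertices), nrow(x$edges), x$rule$name))
  invisible(x)
}

#' Build graphs for a whole trajectory
#'
#' Convenience wrapper that precomputes the candidate pair table once and
#' applies [build_frame_graph()] to every frame.
#'
#' @inheritParams build_frame_graph
#' @param frames list of [md_frame()] objects.
#' @return List of `frame_graph` objects, in frame order.
#' @export
build_frame_graphs <- function(frames, topology, rule = hb_rule(),
                               include_water_water = FALSE) {
  pairs <- .candidate_pairs(topology, rule, include_water_water)
  lapply(frames, build_frame_graph, topology = topology, rule = rule,
         include_water_water = include_water_water, pairs = pairs)
}

#' Build the donor-acceptor comparison graph
#'
#' Applies the donor-acceptor criterion `r(DA) <= 0.35` nm with an `H-D-A`
#' angle of at most 30 degrees, the geometric definition used by the
#' standard GROMACS hydrogen-bond analysis. Edges connect donor-oxygen and
#' acceptor-oxygen vertices, one edge per qualifying (donor hydrogen,
#' acceptor) pair, with the mediating hydrogen's serial recorded.
#'
#' @inheritParams build_frame_graph
#' @param rule the donor-acceptor criterion; override to change cutoffs.
#' @return A `frame_graph`.
#' @export
build_gmx_graph <- function(frame, topology,
                            rule = hb_rule("gmx_hbond", "DA", 0.35,
                                           strict = FALSE, angle_cutoff = 30,
                                           angle_convention = "HDA"),
                            include_water_water = FALSE, pairs = NULL) {
  build_frame_graph(frame, topology, rule = rule,
                    include_water_water = include_water_water, pairs = pairs)
}
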