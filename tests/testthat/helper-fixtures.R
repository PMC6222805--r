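# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written from first principles (explicit loops,
# 27-image enumeration, igraph BFS) so they do not share code paths with
# the implementation they check.

water_template_fixture <- function() {
  list(name = "WAT", elements = c("O", "H", "H"),
       bonds = cbind(c(1L, 1L), c(2L, 3L)),
       sites = data.frame(label = c("O", "H1", "H2"), local = 1:3,
                          roles = c("donor,acceptor", "hydrogen",
                                    "hydrogen"),
                          stringsAsFactors = FALSE))
}

# minimal solute: one hydroxyl-like oxygen site (with hydrogen) plus an
# extra acceptor oxygen, enough to exercise multi-site bookkeeping
diol_topology <- function(n_waters, box_edge = 2.0) {
  sol <- list(name = "SOL", elements = c("O", "H", "O"),
              bonds = cbind(c(1L, 1L), c(2L, 3L)),
              sites = data.frame(
                label = c("OA", "HA", "OB"), local = 1:3,
                roles = c("donor,acceptor", "hydrogen", "acceptor"),
                stringsAsFactors = FALSE))
  system_topology(list(SOL = sol, WAT = water_template_fixture()),
                  layout = data.frame(template = c("SOL", "WAT"),
                                      count = c(1L, n_waters),
                                      stringsAsFactors = FALSE),
                  solvent = "WAT", box_edge = box_edge)
}

# frame with explicit coordinates for the diol topology: `solute` is a
# 3 x 3 matrix (OA, HA, OB), `waters` an (n*3) x 3 matrix (O,H1,H2 per water)
diol_frame <- function(solute, waters, box_edge = 2.0, index = 0L,
                       time = 0) {
  n_w <- nrow(waters) / 3L
  md_frame(c("O", "H", "O", rep(c("O", "H", "H"), n_w)),
           rbind(solute, waters), box_edge = box_edge, index = index,
           time = time)
}

# brute-force minimum image over all 27 neighbour images
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- sqrt(sum((b + c(ix, iy, iz) * box - a)^2))
    if (d < best) best <- d
  }
  best
}

# brute-force edge scan under an hb_rule (distance test only, O...H pairs):
# returns sorted "serial1-serial2" strings with serial1 the oxygen
brute_oh_edges <- function(frame, topology, cutoff = 0.30, strict = TRUE,
                           include_water_water = FALSE) {
  v <- topology$vertices
  out <- character()
  for (i in seq_len(nrow(v))) for (j in seq_len(nrow(v))) {
    if (v$element[i] != "O" || !v$hydrogen[j]) next
    if (v$molecule[i] == v$molecule[j]) next
    if (!include_water_water && v$solvent[i] && v$solvent[j]) next
    d <- brute_min_image(frame$coords[v$serial[i], ],
                         frame$coords[v$serial[j], ], frame$box_edge)
    hit <- if (strict) d < cutoff else d <= cutoff
    if (hit) out <- c(out, paste0(v$serial[i], "-", v$serial[j]))
  }
  sort(out)
}

# brute-force donor-acceptor scan with the H-D-A angle test; returns sorted
# "donorSerial-acceptorSerial-hydrogenSerial" strings
brute_da_edges <- function(frame, topology, cutoff = 0.35,
                           angle_cutoff = 30,
                           include_water_water = FALSE) {
  v <- topology$vertices
  at <- topology$atoms
  bonds <- topology$bond_serials
  box <- frame$box_edge
  mi_vec <- function(a, b) {
    d <- b - a
    d - round(d / box) * box
  }
  out <- character()
  for (i in seq_len(nrow(v))) for (j in seq_len(nrow(v))) {
    if (!v$donor[i] || !v$acceptor[j]) next
    if (v$molecule[i] == v$molecule[j]) next
    if (!include_water_water && v$solvent[i] && v$solvent[j]) next
    dda <- brute_min_image(frame$coords[v$serial[i], ],
                           frame$coords[v$serial[j], ], box)
    if (dda > cutoff) next
    hs <- c(bonds[bonds[, 1L] == v$serial[i], 2L],
            bonds[bonds[, 2L] == v$serial[i], 1L])
    hs <- hs[at$element[hs] == "H"]
    for (h in hs) {
      vdh <- mi_vec(frame$coords[v$serial[i], ], frame$coords[h, ])
      vda <- mi_vec(frame$coords[v$serial[i], ],
                    frame$coords[v$serial[j], ])
      ang <- acos(min(1, max(-1, sum(vdh * vda) /
                               sqrt(sum(vdh^2) * sum(vda^2))))) * 180 / pi
      if (ang <= angle_cutoff)
        out <- c(out, paste0(v$serial[i], "-", v$serial[j], "-", h))
    }
  }
  sort(out)
}

# edge key sets of a frame_graph for comparison with the oracles
graph_oh_keys <- function(g) {
  v <- g$vertices
  e <- g$edges
  if (!nrow(e)) return(character())
  o_first <- ifelse(v$element[e$v1] == "O", e$v1, e$v2)
  h_second <- ifelse(v$element[e$v1] == "O", e$v2, e$v1)
  sort(paste0(v$serial[o_first], "-", v$serial[h_second]))
}

graph_da_keys <- function(g, topology) {
  v <- g$vertices
  e <- g$edges
  if (!nrow(e)) return(character())
  # the true donor endpoint is the one in the same molecule as the
  # mediating hydrogen (both endpoints can carry the donor role)
  h_mol <- topology$atoms$molecule[e$h_serial]
  don <- ifelse(v$molecule[e$v1] == h_mol, e$v1, e$v2)
  acc <- ifelse(v$molecule[e$v1] == h_mol, e$v2, e$v1)
  sort(paste0(v$serial[don], "-", v$serial[acc], "-", e$h_serial))
}

# a bare-bones frame_graph for pure graph-algorithm tests
fake_graph <- function(n, edge_mat) {
  vertices <- data.frame(
    vertex = seq_len(n), key = sprintf("v%02d", seq_len(n)),
    serial = seq_len(n), molecule = seq_len(n), template = "X",
    instance = seq_len(n), site = sprintf("s%d", seq_len(n)),
    element = "O", donor = FALSE, acceptor = TRUE, hydrogen = FALSE,
    solvent = FALSE, molkey = sprintf("X%d", seq_len(n)),
    stringsAsFactors = FALSE)
  edges <- if (is.null(edge_mat) || nrow(edge_mat) == 0L)
    data.frame(v1 = integer(), v2 = integer(), distance = numeric(),
               sx = integer(), sy = integer(), sz = integer(),
               h_serial = integer())
  else data.frame(v1 = pmin(edge_mat[, 1L], edge_mat[, 2L]),
                  v2 = pmax(edge_mat[, 1L], edge_mat[, 2L]),
                  distance = 0.2, sx = 0L, sy = 0L, sz = 0L,
                  h_serial = NA_integer_)
  structure(list(frame_index = 0L, time = 0, vertices = vertices,
                 edges = edges,
                 rule = hb_rule(), box_edge = 2),
            class = "frame_graph")
}

random_graph <- function(n, p_edge = 0.1) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  fake_graph(n, pairs[keep, , drop = FALSE])
}

# igraph BFS oracle for geodesic distances
igraph_distances <- function(g) {
  n <- nrow(g$vertices)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, rbind(g$edges$v1, g$edges$v2))
  igraph::distances(ig, algorithm = "unweighted")
}

# synthetic boolean partner series toggled by a two-state Markov chain
markov_series <- function(n, a, b, init = NULL) {
  s <- logical(n)
  pi1 <- b / (a + b)
  s[1L] <- if (is.null(init)) stats::runif(1L) < pi1 else init
  for (t in 2:n)
    s[t] <- if (s[t - 1L]) stats::runif(1L) >= a else stats::runif(1L) < b
  s
}
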