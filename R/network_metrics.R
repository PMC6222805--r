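# Resolve a user-supplied site identifier to a vertex index.
# Accepts a bare site label (must be unique among non-solvent vertices
# unless allow_solvent) or a fully qualified vertex key "WAT37:H1".
.resolve_vertex <- function(vertices, site, allow_solvent = FALSE) {
  hit <- which(vertices$key == site)
  if (length(hit) == 1L) return(hit)
  pool <- if (allow_solvent) vertices else
    vertices[!vertices$solvent, , drop = FALSE]
  hit <- pool$vertex[pool$site == site]
  if (length(hit) == 0L)
    stop("unknown site label or vertex key: '", site, "'")
  if (length(hit) > 1L)
    stop("site label '", site, "' is ambiguous (", length(hit),
         " vertices); use a qualified key such as '",
         pool$key[pool$site == site][1L], "'")
  hit
}

.graph_degrees <- function(graph) {
  e <- graph$edges
  tabulate(c(as.integer(e$v1), as.integer(e$v2)),
           nbins = nrow(graph$vertices))
}

#' Per-site degree census over a trajectory
#'
#' For each requested interaction site, counts the number of frames `N(i)` in
#' which the site has raw hydrogen-bond degree `i` (number of incident graph
#' edges; both hydrogens of one water count separately under the `"OH"`
#' rule). The census satisfies `sum_i N(i) = number of frames` for every
#' site.
#'
#' @param graphs list of `frame_graph` objects sharing one vertex universe.
#' @param sites character vector of site labels or qualified vertex keys;
#'   default: every site of the non-solvent molecules.
#' @return An object of class `degree_census`: per-site integer count
#'   vectors (index `i + 1` holds `N(i)`), plus `n_frames`. Use
#'   [as.data.frame()] for a tidy (site, degree, count) table.
#' @export
degree_census <- function(graphs, sites = NULL) {
  if (!length(graphs)) {
    out <- structure(list(counts = stats::setNames(list(), character()),
                          n_frames = 0L, vertex_ids = integer()),
                     class = "degree_census")
    return(out)
  }
  v <- graphs[[1L]]$vertices
  if (is.null(sites)) {
    solv <- v[!v$solvent, , drop = FALSE]
    sites <- solv$site
    if (anyDuplicated(sites)) sites <- solv$key
  }
  ids <- vapply(sites, .resolve_vertex, 0L, vertices = v,
                allow_solvent = TRUE)
  deg <- vapply(graphs, function(g) .graph_degrees(g)[ids],
                numeric(length(ids)))
  deg <- matrix(deg, nrow = length(ids))   # sites x frames
  counts <- lapply(seq_along(ids), function(k)
    tabulate(deg[k, ] + 1L, nbins = max(deg[k, ]) + 1L))
  names(counts) <- sites
  structure(list(counts = counts, n_frames = length(graphs),
                 vertex_ids = ids),
            class = "degree_census")
}

#' @export
as.data.frame.degree_census <- function(x, ...) {
  if (!length(x$counts))
    return(data.frame(site = character(), degree = integer(),
                      count = integer()))
  do.call(rbind, lapply(names(x$counts), function(s) {
    cnt <- x$counts[[s]]
    data.frame(site = s, degree = seq_along(cnt) - 1L, count = cnt,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.degree_census <- function(x, ...) {
  cat("degree_census over", x$n_frames, "frames,",
      length(x$counts), "sites\n")
  if (length(x$counts)) print(utils::head(as.data.frame(x), 20L))
  invisible(x)
}

#' Weighted mean hydrogen-bond degree per site
#'
#' Computes `sum_i i * N(i) / sum_i N(i)` for every site of a census. With
#' `halve = TRUE` the result is divided by two, converting the raw
#' hydrogen-counting degree (where a water with both hydrogens inside the
#' cutoff counts twice) into a water-molecule-level degree comparable to
#' donor-acceptor hydrogen-bond counts.
#'
#' @param census a [degree_census()].
#' @param halve divide the mean by two (water-molecule convention).
#' @return Named numeric vector of per-site mean degrees.
#' @export
weighted_mean_degree <- function(census, halve = FALSE) {
  if (!length(census$counts) || census$n_frames == 0L)
    stop("undefined value: census covers zero frames")
  out <- vapply(census$counts, function(cnt) {
    i <- seq_along(cnt) - 1
    sum(i * cnt) / sum(cnt)
  }, 0)
  if (halve) out <- out / 2
  out
}

#' All-pairs geodesic distance matrix of one frame graph
#'
#' Converts the graph's adjacency matrix into a geodesic-distance matrix via
#' the Floyd-Warshall algorithm: entry `(u, v)` is the number of edges in
#' the shortest path connecting the two vertices. Unreachable pairs hold
#' `Inf`. A next-hop matrix is kept so one canonical shortest path per pair
#' can be reconstructed (ties resolved toward the lowest-index intermediate
#' vertex considered first; arbitrary among equals).
#'
#' @param graph a `frame_graph`.
#' @return An object of class `geodesic_matrix`: `keys` (vertex keys), `gd`
#'   (N-by-N numeric matrix, `Inf` = unreachable), `next_hop` (integer
#'   matrix, `NA` = no path), `frame_index`.
#' @export
geodesic_matrix <- function(graph) {
  v <- graph$vertices
  n <- nrow(v)
  gd <- matrix(Inf, n, n)
  nxt <- matrix(NA_integer_, n, n)
  diag(gd) <- 0
  e <- graph$edges
  if (nrow(e)) {
    i <- as.integer(e$v1); j <- as.integer(e$v2)
    gd[cbind(i, j)] <- 1; gd[cbind(j, i)] <- 1
    nxt[cbind(i, j)] <- j; nxt[cbind(j, i)] <- i
  }
  for (k in seq_len(n)) {
    dk <- gd[, k]
    if (all(!is.finite(dk))) next
    cand <- outer(dk, gd[k, ], `+`)
    upd <- which(cand < gd)
    if (length(upd)) {
      gd[upd] <- cand[upd]
      rows <- ((upd - 1L) %% n) + 1L
      nxt[upd] <- nxt[cbind(rows, k)]
    }
  }
  dimnames(gd) <- list(v$key, v$key)
  structure(list(keys = v$key, gd = gd, next_hop = nxt,
                 frame_index = graph$frame_index),
            class = "geodesic_matrix")
}

#' @export
print.geodesic_matrix <- function(x, ...) {
  fin <- is.finite(x$gd) & upper.tri(x$gd)
  cat(sprintf(
    "geodesic_matrix: frame %d, %d vertices, %d connected pairs%s\n",
    x$frame_index, length(x$keys), sum(fin),
    if (any(fin)) sprintf(", max gd %d", max(x$gd[fin])) else ""))
  invisible(x)
}

#' Enumerate geodesic paths from a geodesic matrix
#'
#' Lists, for every unordered vertex pair with a finite nonzero geodesic
#' distance, the distance and one canonical shortest path (vertex keys
#' joined by `->`).
#'
#' @param gm a [geodesic_matrix()].
#' @return data.frame with columns `from`, `to`, `distance`, `path`.
#' @export
geodesic_paths <- function(gm) {
  n <- length(gm$keys)
  idx <- which(is.finite(gm$gd) & upper.tri(gm$gd))
  if (!length(idx))
    return(data.frame(from = character(), to = character(),
                      distance = integer(), path = character(),
                      stringsAsFactors = FALSE))
  ii <- ((idx - 1L) %% n) + 1L
  jj <- ((idx - 1L) %/% n) + 1L
  path_str <- character(length(idx))
  for (k in seq_along(idx)) {
    u <- ii[k]; vtx <- jj[k]
    p <- u
    while (u != vtx) {
      u <- gm$next_hop[u, vtx]
      p <- c(p, u)
    }
    path_str[k] <- paste(gm$keys[p], collapse = "->")
  }
  data.frame(from = gm$keys[ii], to = gm$keys[jj],
             distance = as.integer(gm$gd[idx]), path = path_str,
             stringsAsFactors = FALSE)
}

# Single-source BFS distances over a frame graph's edge list.
.bfs_distances <- function(graph, src) {
  n <- nrow(graph$vertices)
  e <- graph$edges
  adj <- vector("list", n)
  if (nrow(e)) {
    i <- as.integer(e$v1); j <- as.integer(e$v2)
    adj <- split(c(j, i), factor(c(i, j), levels = seq_len(n)))
  }
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Geodesic distance between two sites along a trajectory
#'
#' Tracks the geodesic distance `gd(u, v)` frame by frame and reports the
#' maximal runs over which it stays constant and finite, with durations in
#' frames and ps. Frames where the pair is disconnected break runs and are
#' reported separately via the per-frame series.
#'
#' @param graphs list of `frame_graph` objects.
#' @param u,v site labels or qualified vertex keys.
#' @param frame_interval time between frames, ps.
#' @return A list of class `geodesic_persistence`: `series` (per-frame
#'   data.frame `frame`, `gd`) and `runs` (data.frame `gd`, `start_frame`,
#'   `length_frames`, `duration_ps`).
#' @export
geodesic_persistence <- function(graphs, u, v, frame_interval = 0.5) {
  if (!length(graphs)) stop("no frames supplied")
  vt <- graphs[[1L]]$vertices
  iu <- .resolve_vertex(vt, u, allow_solvent = TRUE)
  iv <- .resolve_vertex(vt, v, allow_solvent = TRUE)
  gd <- vapply(graphs, function(g) .bfs_distances(g, iu)[iv], 0)
  frames <- vapply(graphs, `[[`, 0L, "frame_index")
  r <- rle(gd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fin <- is.finite(r$values)
  runs <- data.frame(gd = r$values[fin],
                     start_frame = frames[starts[fin]],
                     length_frames = r$lengths[fin],
                     duration_ps = r$lengths[fin] * frame_interval)
  structure(list(series = data.frame(frame = frames, gd = gd),
                 runs = runs, u = vt$key[iu], v = vt$key[iv],
                 frame_interval = frame_interval),
            class = "geodesic_persistence")
}

#' @export
print.geodesic_persistence <- function(x, ...) {
  cat(sprintf("geodesic_persistence %s ~ %s: %d frames, %d constant runs\n",
              x$u, x$v, nrow(x$series), nrow(x$runs)))
  if (nrow(x$runs))
    cat(sprintf("  mean run %.3f ps, mean finite gd %.3f\n",
                mean(x$runs$duration_ps),
                mean(x$series$gd[is.finite(x$series$gd)])))
  invisible(x)
}
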