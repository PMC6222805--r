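#' Site-resolved solute-water distance distribution
#'
#' Histograms the minimum-image distances from a solute interaction-site
#' oxygen to every water hydrogen, collecting everything below a generous
#' collection cutoff. The covalent O-H bond of the water itself is not part
#' of any measured pair (distances are intermolecular), so the first
#' hydration-shell peak sits near the bare O...H hydrogen-bond length
#' (about 0.18 nm), not the donor-acceptor distance. Note that truncating
#' at the collection cutoff clips the second-shell peak, which can make it
#' look artificially sharp; the cutoff used is recorded on the histogram.
#'
#' @param frames list of [md_frame()] objects.
#' @param topology a `system_topology`.
#' @param site a solute site label (oxygen), a qualified vertex key, or
#'   `"ALL"` to pool every non-solvent oxygen site.
#' @param collection_cutoff largest distance collected, nm.
#' @param bin_width uniform bin width, nm.
#' @return An object of class `distance_histogram`: `site`, `breaks`,
#'   `mids`, `counts`, `n_frames`, `collection_cutoff`, `bin_width`. Use
#'   [as.data.frame()] for a tidy table (with a `probability` column).
#' @export
distance_distribution <- function(frames, topology, site = "ALL",
                                  collection_cutoff = 0.35,
                                  bin_width = 0.005) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (bin_width > collection_cutoff)
    stop("bin_width exceeds collection_cutoff")
  v <- topology$vertices
  if (identical(site, "ALL")) {
    ids <- v$vertex[!v$solvent & v$element == "O"]
    if (!length(ids)) stop("topology has no solute oxygen sites")
  } else {
    ids <- .resolve_vertex(v, site)
    if (v$element[ids] != "O")
      stop("site '", site, "' is not an oxygen site")
  }
  hyd <- v$serial[v$solvent & v$hydrogen]
  site_serials <- v$serial[ids]
  nb <- ceiling(collection_cutoff / bin_width - 1e-9)
  breaks <- seq(0, nb * bin_width, by = bin_width)
  counts <- integer(nb)
  box_known <- FALSE
  for (fr in frames) {
    box <- fr$box_edge
    if (is.na(box)) box <- topology$box_edge
    if (is.na(box)) stop("no box_edge known for frame ", fr$index)
    box_known <- TRUE
    if (!length(hyd)) next
    for (s in site_serials) {
      a <- matrix(fr$coords[s, ], nrow = length(hyd), ncol = 3L,
                  byrow = TRUE)
      d <- minimum_image_distance(a, fr$coords[hyd, , drop = FALSE],
                                  box)$distance
      d <- d[d < collection_cutoff]
      if (length(d))
        counts <- counts + tabulate(pmin(nb, floor(d / bin_width) + 1L),
                                    nbins = nb)
    }
  }
  structure(list(site = if (identical(site, "ALL")) "ALL"
                        else v$key[ids],
                 breaks = breaks, mids = breaks[-1L] - bin_width / 2,
                 counts = counts, n_frames = length(frames),
                 collection_cutoff = collection_cutoff,
                 bin_width = bin_width),
            class = "distance_histogram")
}

#' @export
as.data.frame.distance_histogram <- function(x, ...) {
  tot <- sum(x$counts)
  data.frame(site = x$site, r_nm = x$mids, count = x$counts,
             probability = if (tot > 0) x$counts / tot else 0,
             stringsAsFactors = FALSE)
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf(
    "distance_histogram: site %s, %d distances over %d frames (< %.3g nm, bin %.3g nm)\n",
    x$site, sum(x$counts), x$n_frames, x$collection_cutoff, x$bin_width))
  invisible(x)
}

# Local maxima of a numeric vector, plateau-aware: returns the (central)
# index of every run strictly higher than both neighbouring runs.
.local_maxima <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  if (k == 0L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  is_max <- r$values > left & r$values > right
  mid <- (starts + ends) %/% 2L
  mid[is_max]
}

#' Suggest a hydrogen-bond distance cutoff from a distance distribution
#'
#' Locates the interior minimum separating the first two hydration-shell
#' peaks of a site-water distance histogram and returns its bin centre —
#' the distance cutoff that keeps first-shell waters while excluding the
#' second shell. Peak and valley detection runs on a lightly smoothed copy
#' of the counts (centred moving average) so single-bin noise does not
#' masquerade as a shell; ties in the valley resolve to the middle bin of
#' the flat region.
#'
#' @param hist a [distance_distribution()] result.
#' @param smooth_window odd window length (bins) of the moving average used
#'   for peak detection; 1 disables smoothing.
#' @param min_peak_frac peaks lower than this fraction of the highest peak
#'   are ignored as noise.
#' @return Suggested cutoff in nm, with attributes `peaks_nm` (the two peak
#'   positions used) and `valley_count` (smoothed count at the minimum).
#' @export
suggest_cutoff <- function(hist, smooth_window = 5L, min_peak_frac = 0.05) {
  y <- as.numeric(hist$counts)
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
    pad <- smooth_window %/% 2L
    yp <- c(rep(y[1L], pad), y, rep(y[length(y)], pad))
    ys <- as.numeric(stats::filter(yp, rep(1 / smooth_window,
                                           smooth_window), sides = 2L))
    ys <- ys[(pad + 1L):(pad + length(y))]
  } else ys <- y
  peaks <- .local_maxima(ys)
  peaks <- peaks[ys[peaks] >= min_peak_frac * max(ys)]
  if (length(peaks) < 2L)
    stop("no interior minimum: distance distribution is unimodal ",
         "(need two hydration-shell peaks to place a cutoff)")
  p1 <- peaks[1L]; p2 <- peaks[2L]
  if (p2 - p1 < 2L)
    stop("no interior minimum: the first two peaks are adjacent bins")
  between <- (p1 + 1L):(p2 - 1L)
  vall <- between[ys[between] == min(ys[between])]
  idx <- vall[(length(vall) + 1L) %/% 2L]
  structure(hist$mids[idx],
            peaks_nm = hist$mids[c(p1, p2)],
            valley_count = ys[idx])
}
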