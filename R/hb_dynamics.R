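# Per-frame partner keys of a site vertex under a counting convention.
# hydrogen mode: partners are individual atom vertices (water hydrogen
# labels distinguish which hydrogen points at the site); molecule mode:
# partners are molecule identities, so hydrogen swaps do not end a contact.
.frame_partners <- function(graph, vid, partner_mode) {
  e <- graph$edges
  if (!nrow(e)) return(character())
  p <- c(e$v2[e$v1 == vid], e$v1[e$v2 == vid])
  if (!length(p)) return(character())
  v <- graph$vertices
  if (partner_mode == "hydrogen") unique(v$key[p]) else unique(v$molkey[p])
}

#' Trace continuous persistence of site-partner contacts
#'
#' Follows every contact of one site along the trajectory and extracts the
#' maximal uninterrupted runs (persistence events). By default a single
#' absent frame terminates a run (zero gap tolerance); `gap_tolerance = g`
#' lets a contact survive interruptions of up to `g` frames. Events touching
#' the first or last frame are flagged as censored: their true length is
#' unknown because the trajectory ends.
#'
#' @param graphs list of `frame_graph` objects in frame order.
#' @param site site label or qualified vertex key to trace.
#' @param partner_mode `"hydrogen"`: partners are individual hydrogen-atom
#'   vertices (a bound water that swaps which hydrogen points at the site
#'   ends one event and starts another); `"molecule"`: partners are water
#'   molecule identities (hydrogen swaps do not interrupt).
#' @param gap_tolerance maximum number of consecutive absent frames bridged
#'   within one event (default 0, i.e. strictly uninterrupted).
#' @return A data.frame of class `persistence_events` with columns `site`,
#'   `partner`, `start` (0-based frame), `length` (frames, spanning any
#'   bridged gaps), `left_censored`, `right_censored`; attributes
#'   `partner_mode` and `n_frames`.
#' @export
trace_persistence <- function(graphs, site,
                              partner_mode = c("hydrogen", "molecule"),
                              gap_tolerance = 0L) {
  partner_mode <- match.arg(partner_mode)
  if (!length(graphs)) stop("at least one frame is required")
  v <- graphs[[1L]]$vertices
  vid <- .resolve_vertex(v, site, allow_solvent = TRUE)
  site_key <- v$key[vid]
  n <- length(graphs)
  per_frame <- lapply(graphs, .frame_partners, vid = vid,
                      partner_mode = partner_mode)
  partner_all <- unlist(per_frame, use.names = FALSE)
  frame_all <- rep.int(seq_len(n) - 1L, lengths(per_frame))
  if (!length(partner_all)) {
    ev <- data.frame(site = character(), partner = character(),
                     start = integer(), length = integer(),
                     left_censored = logical(), right_censored = logical(),
                     stringsAsFactors = FALSE)
  } else {
    by_partner <- split(frame_all, partner_all)
    ev <- do.call(rbind, lapply(names(by_partner), function(p) {
      f <- by_partner[[p]]       # sorted: frames visited in order
      new_run <- c(TRUE, diff(f) > gap_tolerance + 1L)
      run_id <- cumsum(new_run)
      start <- f[new_run]
      end <- f[c(new_run[-1L], TRUE)]
      data.frame(site = site_key, partner = p, start = start,
                 length = end - start + 1L,
                 left_censored = start == 0L,
                 right_censored = end == n - 1L,
                 stringsAsFactors = FALSE)
    }))
    ev <- ev[order(ev$start, ev$partner), ]
    rownames(ev) <- NULL
  }
  attr(ev, "partner_mode") <- partner_mode
  attr(ev, "n_frames") <- n
  class(ev) <- c("persistence_events", class(ev))
  ev
}

#' Residence time (lifetime) from persistence events
#'
#' Estimates the mean lifetime of the site-partner contact as the average of
#' all event durations weighted by the relative occurrence probability
#' `P(t_i)` of each duration: `mean = sum_i t_i P(t_i) * correction`, which
#' equals the plain event average times the correction factor. In hydrogen
#' mode the conventional correction is 2: a bound water alternates which of
#' its two hydrogens points at the site, so each hydrogen-labelled event
#' covers on average half of the molecule's stay. In molecule mode no
#' correction is needed.
#'
#' @param events a [trace_persistence()] result (or compatible data.frame
#'   with a `length` column in frames).
#' @param frame_interval time between frames, ps.
#' @param correction `"auto"` (2 in hydrogen mode, 1 in molecule mode) or an
#'   explicit numeric factor.
#' @param include_censored include events truncated by the trajectory ends
#'   (default TRUE, plain run averaging; set FALSE to drop them).
#' @return A data.frame of class `residence_time_summary`, one row per site:
#'   `site`, `mean_lifetime_ps`, `n_events`, `correction`; attribute
#'   `histograms` holds per-site duration histograms (`duration_frames`,
#'   `count`, `probability`).
#' @export
residence_time <- function(events, frame_interval = 0.5,
                           correction = "auto", include_censored = TRUE) {
  mode <- attr(events, "partner_mode")
  if (identical(correction, "auto")) {
    if (is.null(mode))
      stop("correction = 'auto' requires events from trace_persistence()")
    correction <- if (mode == "hydrogen") 2 else 1
  }
  if (!is.numeric(correction) || correction <= 0)
    stop("correction must be a positive number (or 'auto')")
  if (!include_censored)
    events <- events[!(events$left_censored | events$right_censored), ,
                     drop = FALSE]
  if (!nrow(events))
    stop("undefined value: no persistence events",
         if (!include_censored) " after censoring filter" else "")
  sites <- unique(events$site)
  hists <- list()
  rows <- lapply(sites, function(s) {
    len <- events$length[events$site == s]
    tab <- table(len)
    hist <- data.frame(duration_frames = as.integer(names(tab)),
                       count = as.integer(tab),
                       probability = as.numeric(tab) / length(len))
    hists[[s]] <<- hist
    data.frame(site = s,
               mean_lifetime_ps =
                 mean(len) * frame_interval * correction,
               n_events = length(len), correction = correction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("residence_time_summary", class(out))
  out
}

#' Per-pair bond state matrix
#'
#' Collects, for one site, the frame-by-frame bonded/unbonded state of every
#' partner that is ever in contact — the input for [hb_correlation()].
#'
#' @inheritParams trace_persistence
#' @return Logical matrix, `n_frames` rows by one column per partner
#'   (partner keys as column names).
#' @export
pair_state_matrix <- function(graphs, site,
                              partner_mode = c("hydrogen", "molecule")) {
  partner_mode <- match.arg(partner_mode)
  if (!length(graphs)) stop("at least one frame is required")
  v <- graphs[[1L]]$vertices
  vid <- .resolve_vertex(v, site, allow_solvent = TRUE)
  n <- length(graphs)
  per_frame <- lapply(graphs, .frame_partners, vid = vid,
                      partner_mode = partner_mode)
  partners <- sort(unique(unlist(per_frame, use.names = FALSE)))
  S <- matrix(FALSE, n, length(partners),
              dimnames = list(NULL, partners))
  for (t in seq_len(n)) {
    p <- per_frame[[t]]
    if (length(p)) S[t, p] <- TRUE
  }
  S
}

#' Construct a correlation series
#'
#' Container for a (possibly externally computed) hydrogen-bond correlation
#' function sampled on an ascending lag grid.
#'
#' @param lag_ps ascending lag times, ps; the first lag should be 0.
#' @param value correlation values in `[0, 1]`.
#' @param n_samples number of (pair, origin) samples per lag (optional).
#' @return An object of class `correlation_series`.
#' @export
correlation_series <- function(lag_ps, value, n_samples = NA_real_) {
  if (length(lag_ps) != length(value))
    stop("lag_ps and value must have equal length")
  if (is.unsorted(lag_ps, strictly = TRUE))
    stop("lag_ps must be strictly ascending")
  if (any(value < -1e-9 | value > 1 + 1e-9))
    stop("correlation values must lie in [0, 1]")
  structure(data.frame(lag_ps = lag_ps, value = pmin(pmax(value, 0), 1),
                       n_samples = n_samples),
            class = c("correlation_series", "data.frame"))
}

#' Intermittent hydrogen-bond correlation function
#'
#' Computes `C_HB(t) = <s(t0) s(t0 + t)> / <s(t0)^2>`, where `s` is the
#' bonded indicator of a specific pair, averaged over every pair and every
#' time origin. A pair bonded at `t0` and again at `t0 + t` contributes even
#' if the bond was absent in between (intermittent definition), so the decay
#' of `C_HB` reflects how long a pair stays associated, rebinding included.
#' `C_HB(0) = 1` by construction.
#'
#' @param pair_states logical matrix (frames by pairs) as from
#'   [pair_state_matrix()], or a single logical vector.
#' @param frame_interval time between frames, ps.
#' @param max_lag largest lag in ps; default half the trajectory length.
#' @return A [correlation_series()] with the integrated lifetime available
#'   via [integrate_lifetime()].
#' @export
hb_correlation <- function(pair_states, frame_interval = 0.5,
                           max_lag = NULL) {
  S <- if (is.null(dim(pair_states))) matrix(pair_states, ncol = 1L)
       else as.matrix(pair_states)
  storage.mode(S) <- "double"
  n <- nrow(S)
  if (n < 1L) stop("pair_states has no frames")
  if (!any(S > 0))
    stop("undefined value: no pair is ever bonded")
  lmax <- if (is.null(max_lag)) n %/% 2L
          else min(n - 1L, floor(max_lag / frame_interval))
  lmax <- max(0L, min(n - 1L, lmax))
  # FFT autocorrelation: raw[l+1] = sum over pairs, t of s(t) s(t+l)
  m <- stats::nextn(2L * n, 2L)
  Fm <- stats::mvfft(rbind(S, matrix(0, m - n, ncol(S))))
  pw <- rowSums(Mod(Fm)^2)
  raw <- round(Re(stats::fft(pw, inverse = TRUE)) / m)
  raw <- raw[seq_len(lmax + 1L)]
  lags <- 0:lmax
  # normalise by <s^2> over all origins; per-lag origin count n - l
  value <- (raw / (n - lags)) / (raw[1L] / n)
  correlation_series(lag_ps = lags * frame_interval, value = value,
                     n_samples = ncol(S) * (n - lags))
}

#' Integrated hydrogen-bond lifetime
#'
#' Integrates a correlation function over its available lags by the
#' trapezoidal rule. For an exponential decay `exp(-t / tau)` sampled
#' densely to several `tau`, the integral recovers `tau`.
#'
#' @param series a [correlation_series()].
#' @return Lifetime in ps, with attribute `truncation_lag_ps` (the largest
#'   lag available; the integral is truncated there).
#' @export
integrate_lifetime <- function(series) {
  if (!nrow(series)) stop("empty correlation series")
  x <- series$lag_ps; y <- series$value
  lt <- if (length(x) < 2L) 0
        else sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
  structure(lt, truncation_lag_ps = x[length(x)])
}
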