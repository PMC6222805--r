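#' Run the full analysis pipeline
#'
#' Ties the stages together: read (or synthesise) a trajectory, convert
#' every frame to an interaction graph, then run the requested analyses and
#' write deterministic CSV outputs plus a JSON manifest listing every output
#' file with its row count and MD5 checksum. Re-running with the same
#' configuration and seed reproduces the manifest byte for byte.
#'
#' Configuration keys (a named list, or a path to a YAML/JSON file):
#' \describe{
#'   \item{topology, trajectory, gro}{input paths; `gro` is optional and
#'     supplies the box edge when the topology has none.}
#'   \item{synthetic}{instead of input paths: a list of
#'     [synthetic_params()] arguments; the system is generated in memory.}
#'   \item{frame_interval}{ps between frames (default 0.5).}
#'   \item{cutoff, measured_pair, strict, angle, angle_convention}{the
#'     interaction criterion (defaults 0.30 nm, `"OH"`, strict `<`, no
#'     angle test).}
#'   \item{stages}{subset of `degree`, `lifetimes`, `hbcorr`, `distances`,
#'     `geodesics`, `graphs` (default: first three plus `distances`).}
#'   \item{sites}{site labels to analyse (default: all solute sites for the
#'     census; oxygen sites for lifetimes/distances).}
#'   \item{max_lag_ps, collection_cutoff, bin_width}{stage parameters.}
#'   \item{graph_frames}{frame indices (0-based) for which `.graph` /
#'     `.geopath` files are written (default 0).}
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{integer seed for any randomness (default 1).}
#' }
#'
#' @param config named list or path to a YAML/JSON configuration file.
#' @return The manifest (list), invisibly; `manifest$status` is 0 on
#'   success, 1 if any stage failed (failures recorded in
#'   `manifest$errors`).
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  # validate inputs before any computation
  if (is.null(cfg$synthetic)) {
    for (key in c("topology", "trajectory")) {
      if (is.null(cfg[[key]]))
        stop("config must name '", key, "' (or a 'synthetic' block)")
      if (!file.exists(cfg[[key]]))
        stop("validation failure: ", key, " file not found: ", cfg[[key]])
    }
    if (!is.null(cfg$gro) && !file.exists(cfg$gro))
      stop("validation failure: gro file not found: ", cfg$gro)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  frame_interval <- if (is.null(cfg$frame_interval)) 0.5
                    else cfg$frame_interval
  stages <- if (is.null(cfg$stages))
    c("degree", "lifetimes", "distances") else unlist(cfg$stages)
  rule <- hb_rule(
    name = if (is.null(cfg$rule_name)) "oh_distance" else cfg$rule_name,
    measured_pair = if (is.null(cfg$measured_pair)) "OH"
                    else cfg$measured_pair,
    distance_cutoff = if (is.null(cfg$cutoff)) 0.30 else cfg$cutoff,
    strict = if (is.null(cfg$strict)) TRUE else isTRUE(cfg$strict),
    angle_cutoff = cfg$angle,
    angle_convention = if (is.null(cfg$angle_convention)) "HDA"
                       else cfg$angle_convention)

  manifest <- list(package = "solvgraph",
                   version = as.character(utils::packageVersion("solvgraph")),
                   seed = seed, rule = unclass(rule),
                   frame_interval = frame_interval,
                   stages = as.character(stages),
                   outputs = list(), errors = list(), status = 0L)
  outputs <- list()
  record <- function(path, rows) {
    outputs[[length(outputs) + 1L]] <<- list(
      file = basename(path), rows = as.integer(rows),
      md5 = unname(tools::md5sum(path)))
  }
  fail <- function(stage, err) {
    manifest$errors[[length(manifest$errors) + 1L]] <<-
      list(stage = stage, message = conditionMessage(err))
    manifest$status <<- 1L
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    sp_args <- cfg$synthetic
    if (is.null(sp_args$seed)) sp_args$seed <- seed
    if (is.null(sp_args$frame_interval))
      sp_args$frame_interval <- frame_interval
    syn <- do.call(synthetic_params, sp_args)
    traj <- generate_trajectory(syn)
    frames <- traj$frames
    topology <- traj$topology
    frame_interval <- syn$frame_interval
    truth_path <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(traj$truth, truth_path, row.names = FALSE)
    record(truth_path, nrow(traj$truth))
  } else {
    topology <- parse_topology(cfg$topology)
    box <- topology$box_edge
    if (!is.null(cfg$gro)) {
      gro <- read_gro_structure(cfg$gro)
      box <- gro$box_edge
    }
    frames <- read_xyz_trajectory(cfg$trajectory,
                                  frame_interval = frame_interval,
                                  box_edge = box)
    if (!length(frames)) stop("trajectory contains no frames")
    check_frame_topology(frames[[1L]], topology)
  }

  graphs <- build_frame_graphs(frames, topology, rule = rule)

  v <- topology$vertices
  solute_o <- v$site[!v$solvent & v$element == "O"]
  census_sites <- if (is.null(cfg$sites)) v$site[!v$solvent]
                  else unlist(cfg$sites)
  o_sites <- if (is.null(cfg$sites)) solute_o
             else intersect(unlist(cfg$sites), solute_o)

  # --- stages ---------------------------------------------------------
  if ("degree" %in% stages) tryCatch({
    census <- degree_census(graphs, census_sites)
    cdf <- as.data.frame(census)
    path <- file.path(out_dir, "degree_census.csv")
    utils::write.csv(cdf, path, row.names = FALSE)
    record(path, nrow(cdf))
    md <- data.frame(site = names(weighted_mean_degree(census)),
                     mean_degree = unname(weighted_mean_degree(census)),
                     mean_degree_halved =
                       unname(weighted_mean_degree(census, halve = TRUE)))
    path <- file.path(out_dir, "mean_degree.csv")
    utils::write.csv(md, path, row.names = FALSE)
    record(path, nrow(md))
  }, error = function(e) fail("degree", e))

  if ("lifetimes" %in% stages) tryCatch({
    for (mode in c("hydrogen", "molecule")) {
      ev_all <- list(); summ <- list()
      for (s in o_sites) {
        ev <- trace_persistence(graphs, s, partner_mode = mode)
        if (nrow(ev)) {
          ev_all[[s]] <- ev
          summ[[s]] <- residence_time(ev, frame_interval = frame_interval,
                                      correction = "auto")
        }
      }
      ev_df <- if (length(ev_all)) do.call(rbind, ev_all) else
        data.frame(site = character(), partner = character(),
                   start = integer(), length = integer(),
                   left_censored = logical(), right_censored = logical())
      rownames(ev_df) <- NULL
      path <- file.path(out_dir, sprintf("events_%s.csv", mode))
      utils::write.csv(as.data.frame(ev_df), path, row.names = FALSE)
      record(path, nrow(ev_df))
      sm <- if (length(summ)) do.call(rbind, lapply(summ, as.data.frame))
            else data.frame(site = character(),
                            mean_lifetime_ps = numeric(),
                            n_events = integer(), correction = numeric())
      rownames(sm) <- NULL
      path <- file.path(out_dir, sprintf("lifetimes_%s.csv", mode))
      utils::write.csv(sm, path, row.names = FALSE)
      record(path, nrow(sm))
    }
  }, error = function(e) fail("lifetimes", e))

  if ("hbcorr" %in% stages) tryCatch({
    rows <- list()
    for (s in o_sites) {
      st <- pair_state_matrix(graphs, s, partner_mode = "hydrogen")
      if (!ncol(st) || !any(st)) next
      cs <- hb_correlation(st, frame_interval = frame_interval,
                           max_lag = cfg$max_lag_ps)
      lt <- integrate_lifetime(cs)
      rows[[s]] <- data.frame(site = s, lag_ps = cs$lag_ps,
                              value = cs$value, n_samples = cs$n_samples,
                              integrated_lifetime_ps = as.numeric(lt))
    }
    hc <- if (length(rows)) do.call(rbind, rows) else
      data.frame(site = character(), lag_ps = numeric(),
                 value = numeric(), n_samples = numeric(),
                 integrated_lifetime_ps = numeric())
    rownames(hc) <- NULL
    path <- file.path(out_dir, "hb_correlation.csv")
    utils::write.csv(hc, path, row.names = FALSE)
    record(path, nrow(hc))
  }, error = function(e) fail("hbcorr", e))

  if ("distances" %in% stages) tryCatch({
    cc <- if (is.null(cfg$collection_cutoff)) 0.35
          else cfg$collection_cutoff
    bw <- if (is.null(cfg$bin_width)) 0.005 else cfg$bin_width
    rows <- lapply(c("ALL", o_sites), function(s)
      as.data.frame(distance_distribution(frames, topology, site = s,
                                          collection_cutoff = cc,
                                          bin_width = bw)))
    dh <- do.call(rbind, rows)
    rownames(dh) <- NULL
    path <- file.path(out_dir, "distance_histograms.csv")
    utils::write.csv(dh, path, row.names = FALSE)
    record(path, nrow(dh))
  }, error = function(e) fail("distances", e))

  if (any(c("geodesics", "graphs") %in% stages)) tryCatch({
    gframes <- if (is.null(cfg$graph_frames)) 0L
               else as.integer(unlist(cfg$graph_frames))
    idx <- vapply(frames, `[[`, 0L, "index")
    for (gf in gframes) {
      k <- match(gf, idx)
      if (is.na(k)) stop("graph_frames index ", gf, " not in trajectory")
      gg <- build_frame_graph(frames[[k]], topology, rule = rule,
                              include_water_water = TRUE)
      if ("graphs" %in% stages) {
        path <- file.path(out_dir, sprintf("frame%06d.graph", gf))
        write_graph_file(gg, path)
        record(path, nrow(gg$edges))
      }
      if ("geodesics" %in% stages) {
        gm <- geodesic_matrix(gg)
        path <- file.path(out_dir, sprintf("frame%06d.geopath", gf))
        write_geopath(gm, path)
        record(path, sum(is.finite(gm$gd) & upper.tri(gm$gd)))
      }
    }
  }, error = function(e) fail("geodesics", e))

  manifest$outputs <- outputs
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("validation failure: config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    cfg <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) {
    cfg <- config
  } else stop("config must be a named list or a file path")
  cfg
}
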