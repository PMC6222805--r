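#' Construct a trajectory frame
#'
#' A frame holds the Cartesian coordinates of every atom at one snapshot,
#' together with the cubic box edge and a time stamp.
#'
#' @param elements character vector of chemical symbols, one per atom.
#' @param coords numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box_edge cubic box edge length in nm (`NA` if unknown; xyz files
#'   carry no box, so the edge usually comes from a gro file or the topology).
#' @param index 0-based frame number within the trajectory.
#' @param time time stamp in ps; by convention `index * frame_interval`.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(elements, coords, box_edge = NA_real_, index = 0L,
                     time = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have three columns (x, y, z in nm)")
  if (length(elements) != nrow(coords))
    stop("length(elements) must equal nrow(coords)")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  if (!is.na(box_edge) && box_edge <= 0)
    stop("box_edge must be positive")
  if (!all(grepl("^[A-Za-z][A-Za-z]?$", elements)))
    stop("elements must be one- or two-letter chemical symbols")
  structure(list(elements = as.character(elements), coords = coords,
                 box_edge = as.numeric(box_edge), index = as.integer(index),
                 time = as.numeric(time)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d atoms, frame %d, t = %.3f ps, box = %s nm\n",
              nrow(x$coords), x$index, x$time,
              if (is.na(x$box_edge)) "?" else format(x$box_edge)))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Reads the plain-text xyz format: per frame, an atom-count line, a comment
#' line, then one `element x y z` line per atom (coordinates in nm). The xyz
#' format carries no box information, so `box_edge` may be supplied here or
#' later from a gro file or topology. Time stamps are assigned as
#' `index * frame_interval`.
#'
#' @param path path to the xyz file.
#' @param frame_interval time between consecutive frames in ps.
#' @param box_edge optional cubic box edge (nm) stored on every frame.
#' @return A list of [md_frame()] objects (empty list for an empty file).
#' @export
read_xyz_trajectory <- function(path, frame_interval = 0.5,
                                box_edge = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # drop trailing blank lines only; blanks inside a frame are malformed
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  frames <- list()
  pos <- 1L
  n_expected <- NA_integer_
  fi <- 0L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 0L)
      stop(sprintf("malformed atom-count line %d: '%s'", pos, lines[pos]))
    if (is.na(n_expected)) n_expected <- n
    else if (n != n_expected)
      stop(sprintf(
        "atom count changed from %d to %d at frame %d (line %d)",
        n_expected, n, fi, pos))
    if (pos + 1L + n > length(lines))
      stop(sprintf("truncated frame %d starting at line %d", fi, pos))
    atom_lines <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad))
      stop(sprintf("malformed atom line %d in frame %d", pos + 1L + bad[1L], fi))
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(toks, function(t) t[2:4])))), ncol = 3L, byrow = TRUE)
    if (anyNA(xyz))
      stop(sprintf("non-numeric coordinate in frame %d", fi))
    frames[[fi + 1L]] <- md_frame(el, xyz, box_edge = box_edge, index = fi,
                                  time = fi * frame_interval)
    pos <- pos + 2L + n
    fi <- fi + 1L
  }
  frames
}

#' Write a multi-frame XYZ trajectory
#'
#' @param frames a list of [md_frame()] objects (or a single frame).
#' @param path output path.
#' @param digits number of decimal places for coordinates.
#' @export
write_xyz_trajectory <- function(frames, path, digits = 6L) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  fmt <- sprintf("%%-2s %%12.%df %%12.%df %%12.%df", digits, digits, digits)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("frame %d time %.4f ps", fr$index, fr$time), con)
    writeLines(sprintf(fmt, fr$elements,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a gro structure file
#'
#' Parses the fixed-column gro dialect (positions in nm). Velocities, if
#' present, are ignored. The box line must describe a cubic box: the first
#' three components equal within `cubic_tol` and any remaining (off-diagonal)
#' components zero.
#'
#' @param path path to the gro file.
#' @param cubic_tol tolerance (nm) for accepting the box as cubic.
#' @return A single [md_frame()] with `box_edge` taken from the box line.
#' @export
read_gro_structure <- function(path, cubic_tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("gro file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 0L)
    stop("malformed atom-count line in gro file: '", lines[2L], "'")
  if (length(lines) < 2L + n + 1L)
    stop("gro file truncated: expected ", n, " atom lines plus a box line")
  atom_lines <- lines[3:(2L + n)]
  name <- trimws(substr(atom_lines, 11L, 15L))
  x <- as.numeric(substr(atom_lines, 21L, 28L))
  y <- as.numeric(substr(atom_lines, 29L, 36L))
  z <- as.numeric(substr(atom_lines, 37L, 44L))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("non-numeric coordinate field in gro file")
  # element = leading alphabetic part of the atom name, capitalised
  el <- sub("^([A-Za-z]).*$", "\\1", name)
  el <- toupper(el)
  box <- suppressWarnings(as.numeric(
    strsplit(trimws(lines[2L + n + 1L]), "[[:space:]]+")[[1L]]))
  if (length(box) < 3L || anyNA(box[1:3]))
    stop("malformed box line in gro file")
  if (max(box[1:3]) - min(box[1:3]) > cubic_tol ||
      (length(box) > 3L && any(abs(box[-(1:3)]) > cubic_tol)))
    stop("unsupported geometry: box is not cubic within tolerance (",
         paste(format(box), collapse = " "), ")")
  md_frame(el, cbind(x, y, z), box_edge = box[1L], index = 0L, time = 0)
}

#' Write a gro structure file
#'
#' Residue numbering and names are taken from `topology` when given (one
#' residue per molecule instance, residue name = template name, atom name =
#' site label where defined, otherwise element plus local index); without a
#' topology every atom goes into a single residue `MOL`.
#'
#' @param frame an [md_frame()] with a known `box_edge`.
#' @param path output path.
#' @param topology optional [parse_topology()] result used for naming.
#' @export
write_gro_structure <- function(frame, path, topology = NULL) {
  n <- nrow(frame$coords)
  if (is.na(frame$box_edge))
    stop("frame has no box_edge; gro requires a box line")
  if (is.null(topology)) {
    resid <- rep(1L, n); resname <- rep("MOL", n)
    aname <- paste0(frame$elements, seq_len(n))
  } else {
    at <- topology$atoms
    if (nrow(at) != n)
      stop("topology describes ", nrow(at), " atoms but frame has ", n)
    resid <- at$molecule
    resname <- at$template
    aname <- ifelse(is.na(at$site),
                    paste0(at$element, at$local), at$site)
  }
  lines <- c(
    "solvgraph structure",
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid %% 100000L, substr(resname, 1L, 5L),
            substr(aname, 1L, 5L), seq_len(n) %% 100000L,
            frame$coords[, 1], frame$coords[, 2], frame$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f",
            frame$box_edge, frame$box_edge, frame$box_edge))
  writeLines(lines, path)
  invisible(path)
}

## ------------------------------------------------------------------------
## System topology

#' Parse a system topology definition
#'
#' The topology file partitions every frame's atoms into molecule instances
#' and names the interaction sites. Grammar (one directive per line, `#`
#' comments allowed):
#'
#' ```
#' template WAT solvent        # 'solvent' tags the solvent template
#'   atoms O H H               # element sequence, local indices 1..n
#'   bond 1 2                  # internal bonds, 1-based local indices
#'   bond 1 3
#'   site O  1 donor acceptor  # label, local index, optional roles
#'   site H1 2 hydrogen
#'   site H2 3 hydrogen
#' end
#' layout LIG 1                # instance counts, in frame order
#' layout WAT 200
#' box 3.0                     # optional cubic box edge, nm
#' ```
#'
#' Roles (`donor`, `acceptor`, `hydrogen`) may be omitted, in which case they
#' are inferred: an oxygen site is an acceptor, and additionally a donor when
#' the template bonds it to a hydrogen; a hydrogen site bonded to an oxygen
#' gets the `hydrogen` role.
#'
#' @param path path to the topology file.
#' @return An object of class `system_topology` with elements `templates`,
#'   `layout`, `solvent`, `box_edge`, `atoms` (per-atom table over one frame)
#'   and `vertices` (the interaction-site vertex table used by graphs).
#' @export
parse_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  templates <- list()
  layout <- list()
  box_edge <- NA_real_
  solvent <- character()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    kw <- tok[1L]
    if (kw == "template") {
      if (!is.null(cur)) stop("nested 'template' before 'end' (", tok[2L], ")")
      if (length(tok) < 2L) stop("'template' needs a name")
      cur <- list(name = tok[2L], elements = character(),
                  bonds = matrix(integer(), ncol = 2L),
                  sites = data.frame(label = character(), local = integer(),
                                     roles = character(),
                                     stringsAsFactors = FALSE))
      if (length(tok) >= 3L && tok[3L] == "solvent")
        solvent <- c(solvent, tok[2L])
    } else if (kw == "atoms") {
      if (is.null(cur)) stop("'atoms' outside a template block")
      cur$elements <- c(cur$elements, tok[-1L])
    } else if (kw == "bond") {
      if (is.null(cur)) stop("'bond' outside a template block")
      ij <- suppressWarnings(as.integer(tok[2:3]))
      if (length(tok) != 3L || anyNA(ij))
        stop("malformed bond line in template ", cur$name, ": '", ln, "'")
      cur$bonds <- rbind(cur$bonds, ij)
    } else if (kw == "site") {
      if (is.null(cur)) stop("'site' outside a template block")
      idx <- suppressWarnings(as.integer(tok[3L]))
      if (length(tok) < 3L || is.na(idx))
        stop("malformed site line in template ", cur$name, ": '", ln, "'")
      roles <- tok[-(1:3)]
      bad <- setdiff(roles, c("donor", "acceptor", "hydrogen"))
      if (length(bad))
        stop("unknown site role '", bad[1L], "' in template ", cur$name)
      cur$sites <- rbind(cur$sites,
                         data.frame(label = tok[2L], local = idx,
                                    roles = paste(roles, collapse = ","),
                                    stringsAsFactors = FALSE))
    } else if (kw == "end") {
      if (is.null(cur)) stop("'end' without an open template block")
      templates[[cur$name]] <- .validate_template(cur)
      cur <- NULL
    } else if (kw == "layout") {
      cnt <- suppressWarnings(as.integer(tok[3L]))
      if (length(tok) != 3L || is.na(cnt) || cnt < 0L)
        stop("malformed layout line: '", ln, "'")
      layout[[length(layout) + 1L]] <- list(template = tok[2L], count = cnt)
    } else if (kw == "solvent") {
      solvent <- c(solvent, tok[-1L])
    } else if (kw == "box") {
      box_edge <- suppressWarnings(as.numeric(tok[2L]))
      if (is.na(box_edge) || box_edge <= 0)
        stop("malformed box line: '", ln, "'")
    } else {
      stop("unknown topology directive: '", kw, "'")
    }
  }
  if (!is.null(cur)) stop("template ", cur$name, " not closed with 'end'")
  if (!length(layout)) stop("topology defines no layout")
  layout <- data.frame(
    template = vapply(layout, `[[`, "", "template"),
    count = vapply(layout, `[[`, 0L, "count"),
    stringsAsFactors = FALSE)
  missing_t <- setdiff(layout$template, names(templates))
  if (length(missing_t))
    stop("layout references unknown template '", missing_t[1L], "'")
  missing_s <- setdiff(solvent, names(templates))
  if (length(missing_s))
    stop("solvent tag references unknown template '", missing_s[1L], "'")
  system_topology(templates, layout, solvent = unique(solvent),
                  box_edge = box_edge)
}

.validate_template <- function(tpl) {
  n <- length(tpl$elements)
  if (n == 0L) stop("template ", tpl$name, " has no atoms")
  if (nrow(tpl$bonds) &&
      (any(tpl$bonds < 1L) || any(tpl$bonds > n)))
    stop("bond references unknown atom in template ", tpl$name)
  if (nrow(tpl$sites)) {
    if (any(tpl$sites$local < 1L) || any(tpl$sites$local > n))
      stop("site references unknown atom in template ", tpl$name)
    if (anyDuplicated(tpl$sites$label))
      stop("duplicate site label in template ", tpl$name)
  }
  rownames(tpl$bonds) <- NULL
  tpl
}

#' Build a system topology in code
#'
#' Programmatic counterpart of [parse_topology()]; used by the synthetic
#' generator and available for users who prefer constructing topologies in R.
#'
#' @param templates named list of templates (`name`, `elements`, `bonds`
#'   2-column matrix of 1-based local indices, `sites` data.frame with
#'   `label`, `local` and comma-separated `roles` columns, possibly empty).
#' @param layout data.frame with `template` and `count` columns, in the order
#'   template instances appear in each frame.
#' @param solvent character vector of template names regarded as solvent.
#' @param box_edge optional cubic box edge in nm.
#' @return A `system_topology` object.
#' @export
system_topology <- function(templates, layout, solvent = character(),
                            box_edge = NA_real_) {
  templates <- lapply(templates, .validate_template)
  top <- list(templates = templates, layout = layout,
              solvent = solvent, box_edge = box_edge)
  top$atoms <- .topology_atom_table(top)
  top$vertices <- .topology_vertex_table(top)
  top$bond_serials <- .topology_bond_serials(top)
  class(top) <- "system_topology"
  top
}

#' @export
print.system_topology <- function(x, ...) {
  cat("system_topology:", nrow(x$atoms), "atoms/frame,",
      sum(x$layout$count), "molecules,", nrow(x$vertices),
      "interaction-site vertices\n")
  for (i in seq_len(nrow(x$layout)))
    cat(sprintf("  %s x %d (%d atoms each)%s\n", x$layout$template[i],
                x$layout$count[i],
                length(x$templates[[x$layout$template[i]]]$elements),
                if (x$layout$template[i] %in% x$solvent) " [solvent]" else ""))
  invisible(x)
}

# Flatten the layout: one row per atom of one frame, with molecule identity.
.topology_atom_table <- function(top) {
  rows <- list()
  mol <- 0L
  serial0 <- 0L
  for (i in seq_len(nrow(top$layout))) {
    tname <- top$layout$template[i]
    tpl <- top$templates[[tname]]
    na <- length(tpl$elements)
    site_by_local <- rep(NA_character_, na)
    roles_by_local <- rep("", na)
    if (nrow(tpl$sites)) {
      site_by_local[tpl$sites$local] <- tpl$sites$label
      roles_by_local[tpl$sites$local] <- tpl$sites$roles
    }
    for (k in seq_len(top$layout$count[i])) {
      mol <- mol + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial0 + seq_len(na), molecule = mol, template = tname,
        instance = k, local = seq_len(na), element = tpl$elements,
        site = site_by_local, roles = roles_by_local,
        stringsAsFactors = FALSE)
      serial0 <- serial0 + na
    }
  }
  at <- do.call(rbind, rows)
  rownames(at) <- NULL
  at
}

# Interaction-site vertices: atoms carrying a site label, with resolved roles.
.topology_vertex_table <- function(top) {
  at <- top$atoms
  v <- at[!is.na(at$site), , drop = FALSE]
  if (!nrow(v)) {
    v$key <- character(0); v$vertex <- integer(0)
    v$donor <- v$acceptor <- v$hydrogen <- v$solvent <- logical(0)
    return(v)
  }
  # infer roles where none were declared
  role_list <- strsplit(v$roles, ",", fixed = TRUE)
  donor <- acceptor <- hydrogen <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- role_list[[i]]
    if (length(r) && nzchar(r[1L])) {
      donor[i] <- "donor" %in% r
      acceptor[i] <- "acceptor" %in% r
      hydrogen[i] <- "hydrogen" %in% r
    } else {
      tpl <- top$templates[[v$template[i]]]
      el <- v$element[i]
      bnd <- tpl$bonds
      partners <- c(bnd[bnd[, 1L] == v$local[i], 2L],
                    bnd[bnd[, 2L] == v$local[i], 1L])
      pel <- tpl$elements[partners]
      if (el == "O") {
        acceptor[i] <- TRUE
        donor[i] <- any(pel == "H")
      } else if (el == "H") {
        hydrogen[i] <- any(pel %in% c("O", "N"))
      }
    }
  }
  v$donor <- donor; v$acceptor <- acceptor; v$hydrogen <- hydrogen
  v$solvent <- v$template %in% top$solvent
  v$key <- paste0(v$template, v$molecule, ":", v$site)
  v$molkey <- paste0(v$template, v$molecule)
  v$vertex <- seq_len(nrow(v))
  v$roles <- NULL
  rownames(v) <- NULL
  v
}

# Global (serial-indexed) bond list over one frame.
.topology_bond_serials <- function(top) {
  at <- top$atoms
  out <- list()
  offset <- 0L
  for (i in seq_len(nrow(top$layout))) {
    tpl <- top$templates[[top$layout$template[i]]]
    na <- length(tpl$elements)
    for (k in seq_len(top$layout$count[i])) {
      if (nrow(tpl$bonds))
        out[[length(out) + 1L]] <- tpl$bonds + offset
      offset <- offset + na
    }
  }
  if (!length(out)) matrix(integer(), ncol = 2L) else do.call(rbind, out)
}

#' Write a topology definition file
#'
#' Inverse of [parse_topology()]: emits the documented plain-text grammar.
#'
#' @param topology a `system_topology`.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  out <- character()
  for (tpl in topology$templates) {
    hdr <- paste("template", tpl$name,
                 if (tpl$name %in% topology$solvent) "solvent" else "")
    out <- c(out, trimws(hdr),
             paste("  atoms", paste(tpl$elements, collapse = " ")))
    for (b in seq_len(nrow(tpl$bonds)))
      out <- c(out, sprintf("  bond %d %d", tpl$bonds[b, 1L], tpl$bonds[b, 2L]))
    for (s in seq_len(nrow(tpl$sites))) {
      roles <- gsub(",", " ", tpl$sites$roles[s])
      out <- c(out, trimws(sprintf("  site %s %d %s", tpl$sites$label[s],
                                   tpl$sites$local[s], roles)))
    }
    out <- c(out, "end")
  }
  for (i in seq_len(nrow(topology$layout)))
    out <- c(out, sprintf("layout %s %d", topology$layout$template[i],
                          topology$layout$count[i]))
  if (!is.na(topology$box_edge))
    out <- c(out, sprintf("box %.6g", topology$box_edge))
  writeLines(out, path)
  invisible(path)
}

# Frame/topology consistency: counts and element sequence must agree.
check_frame_topology <- function(frame, topology) {
  at <- topology$atoms
  if (nrow(frame$coords) != nrow(at))
    stop("layout mismatch: topology describes ", nrow(at),
         " atoms but frame ", frame$index, " has ", nrow(frame$coords))
  mism <- which(toupper(frame$elements) != toupper(at$element))
  if (length(mism))
    stop("layout mismatch: element '", frame$elements[mism[1L]],
         "' at serial ", mism[1L], " of frame ", frame$index,
         " but topology expects '", at$element[mism[1L]], "'")
  invisible(TRUE)
}

## ------------------------------------------------------------------------
## Graph-formalism output files

#' Write a frame graph as an edge-list (.graph) file
#'
#' One line per undirected edge; each endpoint is written as molecule key,
#' site label and 1-based atom serial. Edges are ordered by ascending vertex
#' index pairs, so output is byte-identical across runs on the same graph.
#'
#' @param graph a `frame_graph` from [build_frame_graph()].
#' @param path output path.
#' @export
write_graph_file <- function(graph, path) {
  v <- graph$vertices
  e <- graph$edges
  hdr <- c("# solvgraph .graph edge list",
           sprintf("# frame %d", graph$frame_index),
           sprintf("# rule %s cutoff %.4g nm", graph$rule$name,
                   graph$rule$distance_cutoff),
           "# mol1 site1 serial1 mol2 site2 serial2 distance_nm")
  if (nrow(e)) {
    i <- e$v1; j <- e$v2
    body <- sprintf("%s %s %d %s %s %d %.6f",
                    v$molkey[i], v$site[i], v$serial[i],
                    v$molkey[j], v$site[j], v$serial[j], e$distance)
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a geodesics (.geopath) file
#'
#' One record per vertex pair with finite geodesic distance: the pair, the
#' distance (edge count) and one canonical shortest path's vertex sequence.
#'
#' @param gm a `geodesic_matrix` from [geodesic_matrix()].
#' @param path output path.
#' @export
write_geopath <- function(gm, path) {
  hdr <- c("# solvgraph .geopath geodesic listing",
           sprintf("# frame %d", gm$frame_index),
           "# from to gd path")
  p <- geodesic_paths(gm)
  body <- if (nrow(p))
    sprintf("%s %s %d %s", p$from, p$to, p$distance, p$path)
  else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
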