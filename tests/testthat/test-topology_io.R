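test_that("xyz trajectories read with assigned time stamps", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "c1",
               "O 0.0 0.0 0.0", "H 0.1 0.0 0.0", "H 0.0 0.1 0.0",
               "3", "c2",
               "O 0.5 0.5 0.5", "H 0.6 0.5 0.5", "H 0.5 0.6 0.5"),
             path)
  fr <- read_xyz_trajectory(path, frame_interval = 0.5)
  expect_length(fr, 2L)
  expect_equal(vapply(fr, `[[`, 0, "time"), c(0.0, 0.5))
  expect_equal(vapply(fr, `[[`, 0L, "index"), c(0L, 1L))
  expect_equal(fr[[2]]$coords[1, ], c(0.5, 0.5, 0.5))
  expect_equal(fr[[1]]$elements, c("O", "H", "H"))
})

test_that("empty xyz file yields an empty trajectory", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(), path)
  expect_length(read_xyz_trajectory(path), 0L)
})

test_that("xyz write/read round-trips coordinates at printed precision", {
  set.seed(11)
  frames <- lapply(0:9, function(i)
    md_frame(rep(c("O", "H", "C", "N", "S"), 10),
             matrix(round(runif(150, 0, 5), 6), ncol = 3),
             box_edge = 5, index = i, time = i * 0.5))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(frames, path)
  back <- read_xyz_trajectory(path, frame_interval = 0.5, box_edge = 5)
  expect_length(back, 10L)
  for (i in 1:10) {
    expect_equal(back[[i]]$coords, frames[[i]]$coords,
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$elements, frames[[i]]$elements)
  }
})

test_that("malformed xyz input produces named errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("oops", "c", "O 0 0 0"), path)
  expect_error(read_xyz_trajectory(path), "count line 1")
  writeLines(c("1", "c", "O 0 0 0", "2", "c",
               "O 0 0 0", "H 0.1 0 0"), path)
  expect_error(read_xyz_trajectory(path), "changed from 1 to 2 at frame 1")
})

test_that("gro reader extracts cubic boxes and coordinates", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("one water", "    3",
               "    1WAT      O    1   1.000   1.100   1.200",
               "    1WAT     H1    2   1.096   1.100   1.200",
               "    1WAT     H2    3   0.976   1.193   1.200",
               "   2.00000   2.00000   2.00000"), path)
  fr <- read_gro_structure(path)
  expect_equal(fr$box_edge, 2.0)
  expect_equal(fr$coords[1, ], c(1.0, 1.1, 1.2), ignore_attr = TRUE)
  expect_equal(fr$elements, c("O", "H", "H"))
})

test_that("gro reader accepts a 5.2 nm cubic box and rejects non-cubic", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               "    1MOL      O    1   1.000   1.000   1.000",
               "   5.20000   5.20000   5.20000"), path)
  expect_equal(read_gro_structure(path)$box_edge, 5.2)
  writeLines(c("t", "    1",
               "    1MOL      O    1   1.000   1.000   1.000",
               "   5.20000   5.60000   5.20000"), path)
  expect_error(read_gro_structure(path), "not cubic")
})

test_that("gro write/read round-trips generator output", {
  tr <- generate_trajectory(synthetic_params(n_waters = 10, n_frames = 1,
                                             seed = 3))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro_structure(tr$frames[[1]], path, topology = tr$topology)
  back <- read_gro_structure(path)
  expect_equal(back$box_edge, tr$params$box_edge)
  # gro prints three decimals: round-trip exact to the printed precision
  expect_true(all(abs(back$coords - tr$frames[[1]]$coords) <= 5e-4))
  expect_equal(back$coords, round(tr$frames[[1]]$coords, 3),
               ignore_attr = TRUE)
})

test_that("topology parsing handles water and multi-site solutes", {
  path <- withr::local_tempfile(fileext = ".topology")
  writeLines(c("# water box",
               "template WAT solvent",
               "  atoms O H H",
               "  bond 1 2", "  bond 1 3",
               "  site O 1", "  site H1 2", "  site H2 3",
               "end",
               "layout WAT 5", "box 2.0"), path)
  top <- parse_topology(path)
  expect_equal(nrow(top$templates$WAT$bonds), 2L)
  expect_equal(top$templates$WAT$sites$label, c("O", "H1", "H2"))
  expect_equal(top$box_edge, 2.0)
  expect_equal(nrow(top$atoms), 15L)
  # inferred roles: water O donates and accepts, hydrogens are hydrogens
  v <- top$vertices
  expect_true(v$donor[v$site == "O"][1] && v$acceptor[v$site == "O"][1])
  expect_true(all(v$hydrogen[v$site %in% c("H1", "H2")]))
})

test_that("a six-oxygen solute template parses with all named sites", {
  tr <- generate_trajectory(synthetic_params(n_waters = 8, n_frames = 1,
                                             seed = 5))
  path <- withr::local_tempfile(fileext = ".topology")
  write_topology(tr$topology, path)
  top <- parse_topology(path)
  o_sites <- top$templates$LIG$sites$label[
    top$templates$LIG$elements[top$templates$LIG$sites$local] == "O"]
  expect_setequal(o_sites, c("O9", "O9p", "O3", "O4", "O4p", "O5p"))
  expect_equal(top$layout, tr$topology$layout)
  expect_equal(top$templates$LIG$bonds, tr$topology$templates$LIG$bonds,
               ignore_attr = TRUE)
})

test_that("topology validation names the offending template", {
  path <- withr::local_tempfile(fileext = ".topology")
  writeLines(c("template BAD", "  atoms O H", "  bond 1 5", "end",
               "layout BAD 1"), path)
  expect_error(parse_topology(path), "BAD")
  writeLines(c("template OK", "  atoms O", "end", "layout NOPE 1"), path)
  expect_error(parse_topology(path), "NOPE")
})

test_that("every atom of a frame belongs to exactly one molecule", {
  top <- diol_topology(4)
  at <- top$atoms
  expect_equal(at$serial, seq_len(nrow(at)))         # partition, no gaps
  expect_equal(nrow(at), 3 + 4 * 3)
  expect_equal(max(at$molecule), 5L)
  expect_true(all(table(at$molecule) == c(3, 3, 3, 3, 3)))
})

test_that("graph files list one line per edge, deterministically", {
  top <- diol_topology(2)
  solute <- rbind(c(1, 1, 1), c(1.06, 1.08, 1), c(1.2, 1, 1))
  # water 1 H1 close to OA; water 2 far away
  waters <- rbind(c(1, 1.28, 1), c(1, 1.18, 1), c(1.09, 1.31, 1),
                  c(0.3, 0.3, 0.3), c(0.39, 0.3, 0.3), c(0.27, 0.39, 0.3))
  g <- build_frame_graph(diol_frame(solute, waters), top)
  path1 <- withr::local_tempfile(fileext = ".graph")
  path2 <- withr::local_tempfile(fileext = ".graph")
  write_graph_file(g, path1)
  lines <- readLines(path1)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(g$edges))
  expect_gte(nrow(g$edges), 1L)
  write_graph_file(g, path2)
  expect_identical(readLines(path1), readLines(path2))
  # empty graph: header only
  g0 <- build_frame_graph(diol_frame(solute, waters * 0 + 0.3), top)
  write_graph_file(g0, path1)
  expect_true(all(startsWith(readLines(path1), "#")))
})

test_that("a ten-edge graph writes ten edge lines", {
  g <- fake_graph(12, cbind(1:10, 2:11))
  path <- withr::local_tempfile(fileext = ".graph")
  write_graph_file(g, path)
  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, "#")), 10L)
})

test_that("geopath files list every finite pair with a path", {
  # single edge: one record, distance 1
  gm <- geodesic_matrix(fake_graph(2, cbind(1, 2)))
  path <- withr::local_tempfile(fileext = ".geopath")
  write_geopath(gm, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_length(body, 1L)
  expect_match(body, " 1 ")
  # 3-vertex path graph: all three connected pairs
  gm3 <- geodesic_matrix(fake_graph(3, rbind(c(1, 2), c(2, 3))))
  write_geopath(gm3, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_length(body, 3L)
  expect_match(body[2], "v01->v02->v03")
  # empty graph: header only
  write_geopath(geodesic_matrix(fake_graph(3, NULL)), path)
  expect_true(all(startsWith(readLines(path), "#")))
})
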