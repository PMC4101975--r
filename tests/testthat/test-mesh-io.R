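canonical_vertices <- function(mesh) {
  v <- round(mesh$vertices, 6)
  v[order(v[, 1L], v[, 2L], v[, 3L]), , drop = FALSE]
}

test_that("a single-triangle ASCII STL reads as 3 vertices and 1 face", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid tri",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid tri"), path)
  mesh <- read_mesh(path)
  expect_equal(nrow(mesh$vertices), 3L)
  expect_equal(nrow(mesh$faces), 1L)
  expect_equal(sort(mesh$vertices[, 1L]), c(0, 0, 1))
})

test_that("binary and ASCII STL of the same phantom agree after canonical ordering", {
  ph <- generate_phantom(coarse_phantom_spec())
  pa <- withr::local_tempfile(fileext = ".stl")
  pb <- withr::local_tempfile(fileext = ".stl")
  write_mesh(ph$mesh, pa, binary = FALSE)
  write_mesh(ph$mesh, pb, binary = TRUE)
  ma <- read_mesh(pa)
  mb <- read_mesh(pb)
  expect_equal(nrow(ma$vertices), nrow(ph$mesh$vertices))
  expect_equal(nrow(mb$faces), nrow(ph$mesh$faces))
  # binary STL stores float32: agreement to 1e-6 mm after sorting
  expect_equal(canonical_vertices(ma), canonical_vertices(mb), tolerance = 1e-6)
  # ASCII round trip is exact
  expect_equal(canonical_vertices(ma), canonical_vertices(ph$mesh))
})

test_that("PLY and OBJ round trips preserve geometry and topology", {
  ph <- generate_phantom(coarse_phantom_spec())
  for (ext in c("ply", "obj")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(ph$mesh, p)
    m <- read_mesh(p)
    expect_equal(m$vertices, ph$mesh$vertices, tolerance = 1e-12)
    expect_equal(m$faces, ph$mesh$faces)
  }
})

test_that("truncated mesh files produce descriptive parse errors", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid tri",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0"), p)
  expect_error(read_mesh(p), "truncated")

  # binary STL that declares more triangles than it contains
  pb <- withr::local_tempfile(fileext = ".stl")
  con <- file(pb, "wb")
  writeBin(raw(80L), con)
  writeBin(5L, con, size = 4L, endian = "little")
  writeBin(raw(50L), con)  # only one triangle's worth of bytes
  close(con)
  expect_error(read_mesh(pb), "truncated")

  px <- withr::local_tempfile(fileext = ".xyz")
  writeLines("not a mesh", px)
  expect_error(read_mesh(px), "format")
  expect_error(read_mesh("does-not-exist.stl"), "not found")
})

test_that("degenerate faces are flagged but kept", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L))  # second face is collinear
  expect_warning(mesh <- surface_mesh(v, f), "degenerate")
  expect_equal(mesh$degenerate_faces, 2L)
  expect_equal(nrow(mesh$faces), 2L)
  expect_error(surface_mesh(v, rbind(c(1L, 2L, 9L))), "out of range")
})

test_that("landmark JSON round trip is exact and errors are descriptive", {
  lm <- landmark_set(R = c(5.123456789, 0, 0), C = c(0, 0, 0),
                     A = c(0.1, -0.2, 4.4), I = c(4, 0, 0), side = "right")
  p <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, p)
  lm2 <- read_landmarks(p)
  for (k in c("R", "C", "A", "I")) expect_equal(lm2[[k]], lm[[k]], tolerance = 1e-12)
  expect_equal(lm2$side, "right")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"R":[5,0,0],"C":[0,0,0],"A":[0,0,4]}', bad)
  expect_error(read_landmarks(bad), "'I'")
  writeLines('{"R":[0,0,0],"C":[0,0,0],"A":[0,0,4],"I":[1,0,0]}', bad)
  expect_error(read_landmarks(bad), "R and C")
})

test_that("plan JSON round trip reproduces all floats to 1e-9", {
  ph <- generate_phantom(coarse_phantom_spec())
  res <- plan_cochleostomy(ph$mesh, ph$landmarks,
                           plan_config(theta_step = 5, theta_max = 20))
  p <- withr::local_tempfile(fileext = ".json")
  write_plan(res$plan, res$frame, p)
  back <- read_plan(p)
  expect_length(back$plan, length(res$plan))
  for (i in seq_along(res$plan)) {
    for (f in c("theta_c", "anchor", "insertion_dir", "target", "exit_distance")) {
      expect_equal(back$plan[[i]][[f]], res$plan[[i]][[f]], tolerance = 1e-9)
    }
    expect_equal(back$plan[[i]]$face_index, res$plan[[i]]$face_index)
  }
  expect_equal(back$frame$rotation, res$frame$rotation, tolerance = 1e-12)
  expect_error(write_plan(list(), res$frame, p), "empty plan")
})
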