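test_that("a minimal ASCII PLY triangle reads back as one face", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_equal(m$faces[1, ], c(1L, 2L, 3L), ignore_attr = TRUE)
})

test_that("VTP roundtrip preserves vertices, faces and fields bit-exactly", {
  m <- cylinder_mesh(5, 7)
  set.seed(1)
  m$fields$scalar <- rnorm(nrow(m$vertices))
  m$fields$vec <- matrix(rnorm(3 * nrow(m$vertices)), ncol = 3)
  path <- withr::local_tempfile(fileext = ".vtp")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_identical(m2$vertices, m$vertices)
  expect_identical(m2$faces, m$faces)
  expect_identical(m2$fields$scalar, m$fields$scalar)
  expect_identical(m2$fields$vec, m$fields$vec)
  expect_identical(m2$ostium_ring, m$ostium_ring)
  expect_identical(m2$landmark, m$landmark)
})

test_that("legacy VTK and OBJ roundtrips preserve geometry", {
  m <- icosphere(1)
  m$fields$f1 <- seq_len(nrow(m$vertices)) * 0.5
  for (ext in c(".vtk", ".obj")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_identical(m2$vertices, m$vertices)
    expect_identical(m2$faces, m$faces)
    if (ext == ".vtk") expect_identical(m2$fields$f1, m$fields$f1)
  }
})

test_that("STL welding recovers shared cube topology from 12 facets", {
  # axis-aligned unit cube, 12 triangles with duplicated corner coordinates
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "w")
  writeLines("solid cube", con)
  for (q in quads) {
    for (tri in list(q[c(1, 2, 3)], q[c(1, 3, 4)])) {
      writeLines("facet normal 0 0 0", con)
      writeLines("outer loop", con)
      for (i in tri)
        writeLines(sprintf("vertex %g %g %g", corners[i, 1], corners[i, 2],
                           corners[i, 3]), con)
      writeLines(c("endloop", "endfacet"), con)
    }
  }
  writeLines("endsolid cube", con)
  close(con)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
})

test_that("binary STL and PLY inputs parse", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  # binary STL
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(raw(80), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0), con, size = 4,
           endian = "little")
  writeBin(raw(2), con)
  close(con)
  m2 <- read_mesh(path)
  expect_equal(nrow(m2$vertices), 3)
  # binary little-endian PLY
  path2 <- withr::local_tempfile(fileext = ".ply")
  con <- file(path2, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 3", "property float x", "property float y",
               "property float z", "element face 1",
               "property list uchar int vertex_indices", "end_header"), con)
  writeBin(as.numeric(t(m$vertices)), con, size = 4, endian = "little")
  writeBin(as.raw(3), con)
  writeBin(c(0L, 1L, 2L), con, size = 4, endian = "little")
  close(con)
  m3 <- read_mesh(path2)
  expect_equal(m3$vertices, m$vertices, ignore_attr = TRUE, tolerance = 1e-7)
  expect_equal(m3$faces, m$faces, ignore_attr = TRUE)
})

test_that("polygonal faces are rejected with the face kind named", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), path)
  expect_error(read_mesh(path), "quad")
  expect_error(read_mesh(withr::local_tempfile(fileext = ".ply")),
               "not found")
})
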