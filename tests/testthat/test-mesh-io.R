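test_that("PLY round-trip preserves a generated cone exactly", {
  m <- make_cone(4, 1, 100, base_center = c(1, 2, 3), axis = c(0.3, 0.4, 0.866),
                 name = "c1", label = 3L)
  expect_equal(nrow(m$faces), 200L)
  p <- file.path(tempdir(), "c1.ply")
  write_mesh(m, p)
  back <- read_mesh(p, name = "c1", label = 3L)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(back$faces, m$faces)
  expect_equal(back$name, "c1")
})

test_that("the same geometry agrees across PLY, binary STL and OBJ", {
  m <- make_cone(4, 1, 48, base_center = c(1, 2, 3), axis = c(0.3, 0.4, 0.866))
  td <- withr::local_tempdir()
  for (ext in c("ply", "stl", "obj")) write_mesh(m, file.path(td, paste0("m.", ext)))
  ply <- read_mesh(file.path(td, "m.ply"))
  stl <- read_mesh(file.path(td, "m.stl"))
  obj <- read_mesh(file.path(td, "m.obj"))
  expect_equal(obj$vertices, m$vertices, tolerance = 1e-9)
  # STL renumbers and merges vertices: compare as point sets
  expect_lt(max_nn_dist(stl$vertices, ply$vertices), 1e-6)
  expect_equal(surface_area(stl), surface_area(ply), tolerance = 1e-6)
})

test_that("degenerate and unreadable mesh files are rejected with clear errors", {
  p <- file.path(tempdir(), "bad.ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), p)
  expect_error(read_mesh(p), "degenerate")
  junk <- file.path(tempdir(), "junk.ply")
  writeLines("not a mesh at all", junk)
  expect_error(read_mesh(junk), "junk.ply")
  expect_error(read_mesh(file.path(tempdir(), "absent.ply")), "not found")
})

test_that("binary PLY (both endiannesses of header metadata) reads as ASCII does", {
  # hand-built binary little-endian PLY: float vertices, uchar/int face lists
  m <- make_cone(2, 0.5, 16)
  p <- file.path(tempdir(), "bin.ply")
  con <- file(p, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in seq_len(nrow(m$vertices)))
    writeBin(as.numeric(m$vertices[i, ]), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4L, endian = "little")
  }
  close(con)
  back <- read_mesh(p)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(back$faces, m$faces)
})

test_that("labelmap extraction produces one mesh per label in mm coordinates", {
  vol <- array(0L, c(10, 10, 10))
  vol[2:3, 2:3, 2:3] <- 1L
  vol[6, 6, 6] <- 2L
  vol[8:9, 2:4, 5] <- 3L
  td <- withr::local_tempdir()
  nii <- file.path(td, "lab.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), nii)
  meshes <- read_labelmap(nii)
  expect_length(meshes, 3L)
  expect_equal(vapply(meshes, function(m) m$label, integer(1)),
               c(tooth_1 = 1L, tooth_2 = 2L, tooth_3 = 3L))
  # single voxel at unit spacing is a cube of area 6 (exact for the
  # unsmoothed voxel-boundary surface; the spec tolerance is 10%)
  expect_equal(surface_area(meshes[[2]]), 6, tolerance = 0.1)
  # all-zero volume: no teeth
  zero <- file.path(td, "zero.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0L, c(4, 4, 4))), zero)
  expect_length(read_labelmap(zero), 0L)
  # non-integer volume rejected
  bad <- file.path(td, "frac.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0.5, c(4, 4, 4))), bad)
  expect_error(read_labelmap(bad), "integer")
})

test_that("labelmap output is invariant to relabeling and matches NRRD/NIfTI", {
  vol <- array(0L, c(8, 8, 8))
  vol[2:3, 2:3, 2:3] <- 1L
  vol[6:7, 5:6, 3:5] <- 2L
  td <- withr::local_tempdir()
  nii <- file.path(td, "a.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), nii)
  a <- read_labelmap(nii)
  # permute labels 1<->2: same surfaces, swapped order
  vol2 <- vol
  vol2[vol == 1L] <- 2L; vol2[vol == 2L] <- 1L
  nii2 <- file.path(td, "b.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol2), nii2)
  b <- read_labelmap(nii2)
  expect_equal(surface_area(a[["tooth_1"]]), surface_area(b[["tooth_2"]]))
  expect_equal(surface_area(a[["tooth_2"]]), surface_area(b[["tooth_1"]]))
  # same volume through the NRRD path (fixture written independently)
  nrrd <- file.path(td, "a.nrrd")
  write_nrrd_fixture(vol, nrrd)
  n <- read_labelmap(nrrd)
  expect_length(n, 2L)
  expect_equal(vapply(n, surface_area, numeric(1)),
               vapply(a, surface_area, numeric(1)))
  # spacing override rescales the physical size
  half <- read_labelmap(nrrd, spacing_override = c(0.5, 0.5, 0.5))
  expect_equal(surface_area(half[[1]]), surface_area(n[[1]]) / 4)
})

test_that("FCSV and JSON landmarks parse into one internal convention", {
  td <- withr::local_tempdir()
  js <- file.path(td, "lm.json")
  writeLines('{"jaw_joint": [0,0,0], "jaw_tip": [10,0,0]}', js)
  lm <- read_landmarks(js)
  expect_s3_class(lm, "landmark_set")
  expect_equal(lm$jaw_tip, c(10, 0, 0))
  # LPS FCSV: first two axes flip on read
  fc <- file.path(td, "lm.fcsv")
  writeLines(c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = LPS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
               "n0,1,2,3,0,0,0,1,1,1,0,jaw_joint,,",
               "n1,-10,0,0,0,0,0,1,1,1,0,jaw_tip,,"), fc)
  lf <- read_landmarks(fc)
  expect_equal(lf$jaw_joint, c(-1, -2, 3))
  expect_equal(lf$jaw_tip, c(10, 0, 0))
  # RAS FCSV taken as-is
  fr <- file.path(td, "ras.fcsv")
  writeLines(c("# CoordinateSystem = RAS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
               "n0,1,2,3,0,0,0,1,1,1,0,jaw_joint,,",
               "n1,9,9,9,0,0,0,1,1,1,0,jaw_tip,,"), fr)
  expect_equal(read_landmarks(fr)$jaw_joint, c(1, 2, 3))
  # missing required landmark
  f2 <- file.path(td, "only_tip.json")
  writeLines('{"jaw_tip": [10,0,0]}', f2)
  expect_error(read_landmarks(f2), "jaw_joint")
})

test_that("landmark parsing is idempotent: read-write-read is identity", {
  lm <- landmark_set(list(jaw_joint = c(0.1, -2.5, 3), jaw_tip = c(19.7, 0.3, -1),
                          insertion_1 = c(2, 0.5, 1.5), origin_1 = c(2, 3.5, 6)))
  td <- withr::local_tempdir()
  for (ext in c("fcsv", "json")) {
    p <- file.path(td, paste0("lm.", ext))
    write_landmarks(lm, p)
    back <- read_landmarks(p)
    expect_equal(unclass(back), unclass(lm), tolerance = 1e-12)
    write_landmarks(back, p)
    expect_equal(unclass(read_landmarks(p)), unclass(back))
  }
  expect_error(landmark_set(list(jaw_joint = c(0, 0, 0), jaw_tip = c(1, 0, 0),
                                 origin_2 = c(1, 1, 1))), "insertion_2")
})

test_that("trait tables round-trip through CSV at full numeric precision", {
  jaw <- make_jaw(jaw_spec(n_teeth = 5, segments = 16))
  traits <- compute_dentition(jaw$meshes, jaw$landmarks)
  traits$tooth[3] <- "molar, lower left"  # comma must be quoted per CSV
  p <- file.path(tempdir(), "traits.csv")
  write_traits_table(traits, p)
  back <- read_traits_table(p)
  expect_equal(nrow(back), 5L)
  expect_equal(back$tooth[3], "molar, lower left")
  num <- vapply(traits, is.numeric, logical(1))
  for (cn in names(traits)[num])
    expect_equal(back[[cn]], traits[[cn]], tolerance = 1e-9, label = cn)
  expect_error(write_traits_table(traits[0, ], p), "non-empty")
})
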