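test_that("mesh constructor validates faces and closedness is detected", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  F_ <- rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  tet <- triangle_mesh(V, F_)
  expect_true(mesh_is_closed(tet))
  expect_false(mesh_is_closed(triangle_mesh(V, F_[1:3, ])))
  expect_error(triangle_mesh(V, rbind(c(1, 2, 9))), "out of range")
})

test_that("welding merges shared boundaries into a watertight mesh", {
  s <- sphere_mesh(4, 32, 24)
  # split vertices apart (no shared indices), then weld back
  f <- s$faces
  V <- s$vertices[as.vector(t(f)), ]
  soup <- triangle_mesh(V, matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE))
  expect_false(mesh_is_closed(soup))
  expect_true(mesh_is_closed(toothrecon:::weld_mesh(soup)))
})

test_that("slicing counts contours of disjoint tubes", {
  cyl <- cylinder_mesh(3, 10)
  two <- merge_meshes(cyl, transform_mesh(cyl, translation = c(10, 0, 0)))
  s1 <- toothrecon:::mesh_slice(cyl, 5.0001, contours = TRUE)
  s2 <- toothrecon:::mesh_slice(two, 5.0001, contours = TRUE)
  expect_equal(s1$n_contours, 1L)
  expect_equal(s2$n_contours, 2L)
  expect_equal(toothrecon:::slice_widths(cyl, 5.0001), 6, tolerance = 0.05)
  expect_true(is.na(toothrecon:::slice_widths(cyl, 50)))
})

test_that("rigid transforms and scaling act on vertices as expected", {
  s <- sphere_mesh(2, 16, 12)
  tr <- random_rigid()
  m2 <- transform_mesh(s, tr$rotation, tr$translation)
  expect_equal(m2$vertices, apply_transform(tr, s$vertices),
               ignore_attr = TRUE)
  m3 <- scale_mesh(s, 2)
  expect_equal(mesh_area(m3), 4 * mesh_area(s), tolerance = 1e-9)
})

test_that("STL and PLY round-trip a watertight mesh", {
  m <- sphere_mesh(5, 24, 16)
  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, stl)
  m2 <- read_stl(stl)
  expect_true(mesh_is_closed(m2))
  expect_equal(nrow(m2$faces), nrow(m$faces))
  expect_equal(sort(round(as.vector(m2$vertices), 4)),
               sort(round(as.vector(m$vertices), 4)), tolerance = 1e-3)
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, ply, scalar = rowSums(m$vertices))
  m3 <- read_ply(ply)
  expect_equal(nrow(m3$vertices), nrow(m$vertices))
  expect_equal(m3$faces, m$faces, ignore_attr = TRUE)
})

test_that("NRRD volumes round-trip in raw and ascii encodings", {
  vol <- scalar_volume(array(stats::rnorm(4 * 5 * 6), dim = c(4, 5, 6)),
                       spacing = c(0.4, 0.4, 0.5), origin = c(-1, 0, 2))
  for (enc in c("raw", "ascii")) {
    p <- withr::local_tempfile(fileext = ".nrrd")
    write_nrrd(vol, p, encoding = enc)
    v2 <- read_nrrd(p)
    expect_equal(v2$values, vol$values, tolerance = 1e-9)
    expect_equal(v2$spacing, vol$spacing)
    expect_equal(v2$origin, vol$origin)
  }
})
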