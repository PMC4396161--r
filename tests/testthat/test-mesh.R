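test_that("ellipse mesh covers the domain with well-shaped triangles", {
  m <- ellipse_mesh(2, 1, 0.2)
  expect_s3_class(m, "triangle_mesh")
  expect_lt(abs(mesh_area(m) - 2 * pi) / (2 * pi), 0.05)
  expect_lte(mesh_size(m), 1.5 * 0.2)
  expect_gt(mesh_min_angle(m), 15)
  # boundary nodes lie exactly on the ellipse
  bn <- m$nodes[m$boundary_nodes, ]
  expect_lt(max(abs((bn[, 1] / 2)^2 + bn[, 2]^2 - 1)), 1e-12)
})

test_that("disc special case puts boundary nodes on the unit circle", {
  m <- ellipse_mesh(1, 1, 0.25)
  r <- sqrt(rowSums(m$nodes[m$boundary_nodes, ]^2))
  expect_lt(max(abs(r - 1)), 1e-12)
})

test_that("halving the target mesh size multiplies elements by 3 to 5", {
  m1 <- ellipse_mesh(2, 1, 0.3)
  m2 <- ellipse_mesh(2, 1, 0.15)
  ratio <- nrow(m2$triangles) / nrow(m1$triangles)
  expect_gte(ratio, 3)
  expect_lte(ratio, 5)
})

test_that("area error decreases monotonically under refinement", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    abs(mesh_area(ellipse_mesh(2, 1, h)) - 2 * pi)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("mesh_size is the maximal element diameter", {
  expect_equal(mesh_size(unit_right_mesh()), sqrt(2))
  m <- ellipse_mesh(2, 1, 0.4)
  diams <- apply(m$triangles, 1, function(tri) max(dist(m$nodes[tri, ])))
  expect_gte(mesh_size(m), max(diams) - 1e-14)
})

test_that("midpoint refinement halves the mesh size exactly", {
  m <- ellipse_mesh(2, 1, 0.4)
  r <- refine_mesh(m)
  expect_equal(mesh_size(r), mesh_size(m) / 2, tolerance = 1e-12)
  expect_equal(nrow(r$triangles), 4 * nrow(m$triangles))
  expect_equal(mesh_area(r), mesh_area(m), tolerance = 1e-12)
})

test_that("mesh construction rejects invalid input", {
  expect_error(ellipse_mesh(1, 2, 0.2), "a >= b")
  expect_error(ellipse_mesh(2, 1, 1.5), "h < b")
  expect_error(triangle_mesh(rbind(c(0, 0), c(1, 0), c(2, 0)),
                             rbind(c(1L, 2L, 3L))), "degenerate")
  expect_error(triangle_mesh(rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5)),
                             rbind(c(1L, 2L, 3L))), "orphan")
})

test_that("MSH v2.2 write/read round trip is exact", {
  m <- ellipse_mesh(2, 1, 0.5)
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(m, f)
  m2 <- read_msh(f)
  expect_identical(m2$nodes, m$nodes)
  expect_identical(m2$triangles, m$triangles)
  expect_identical(m2$boundary_nodes, m$boundary_nodes)
})

test_that("MSH reader names the offending section on malformed files", {
  m <- unit_right_mesh()
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(m, f)
  ln <- readLines(f)
  writeLines(ln[!grepl("Elements", ln)], f)
  expect_error(read_msh(f), "\\$Elements")
  writeLines(sub("^2\\.2", "4.1", ln), f)
  expect_error(read_msh(f), "\\$MeshFormat|version")
})

test_that("written MSH has the documented v2.2 structure", {
  # independent line-level check of the format contract
  m <- unit_right_mesh()
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(m, f)
  ln <- readLines(f)
  expect_equal(ln[1:3], c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"))
  i <- match("$Nodes", ln)
  expect_equal(as.integer(ln[i + 1]), 3L)
  node1 <- as.numeric(strsplit(ln[i + 2], " ")[[1]])
  expect_equal(node1, c(1, 0, 0, 0))
  j <- match("$Elements", ln)
  expect_equal(as.integer(ln[j + 1]), 3L + 1L)  # 3 boundary edges + 1 triangle
  last <- strsplit(ln[j + 1 + 4], " ")[[1]]
  expect_equal(as.integer(last[2]), 2L)          # element type: triangle
})
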