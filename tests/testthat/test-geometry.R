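# Synthetic denture geometry: patch structure, symmetry, areas.

test_that("default geometry carries the full functional patch set", {
  m <- fast_mesh()
  pn <- patch_names(m)
  occl <- grep("^occlusal_", pn, value = TRUE)
  intag <- grep("^intaglio_seg_", pn, value = TRUE)
  expect_length(occl, 8)   # 4 blocks x 2 sides
  expect_length(intag, 8)  # 4 mucosa segments per side
  expect_setequal(grep("^retention_", pn, value = TRUE),
                  c("retention_left", "retention_right"))
  expect_true("border_seal" %in% pn)
  expect_true("cutout" %in% pn)
  # every patch has positive area; tooth elements are present
  for (p in pn) expect_gt(patch_area(m, p), 0)
  expect_true(all(c("base", "tooth") %in% m$elem_label))
  expect_silent(validate_mesh(m))
})

test_that("degenerate ridge height still meshes validly", {
  m <- generate_denture(fast_params(ridge_height = 0, flange_height = 3))
  expect_silent(validate_mesh(m))
  # flat intaglio: all bottom-patch nodes at a single height
  bot <- unique(as.vector(m$facets[grepl("^intaglio",
                                          m$facet_patch), 1:3]))
  expect_lt(diff(range(m$nodes[bot, 3])), 1e-9)
})

test_that("mesh is mirror-symmetric about the midsagittal plane", {
  m <- fast_mesh()
  refl <- m$nodes
  refl[, 1] <- -refl[, 1]
  # nearest-neighbour distance after reflection, well under mesh_size/10
  d2 <- vapply(seq_len(nrow(refl)), function(i)
    min(colSums((t(m$nodes) - refl[i, ])^2)), 0)
  expect_lt(sqrt(max(d2)), m$mesh_size / 10)
  expect_equal(sqrt(max(d2)), 0)  # exact by construction
})

test_that("generation is deterministic", {
  a <- generate_denture(fast_params(), seed = 7L)
  b <- generate_denture(fast_params(), seed = 7L)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$elems, b$elems)
  expect_identical(a$facet_patch, b$facet_patch)
})

test_that("block displacement moves the occlusal centroid as requested", {
  d <- 2
  m0 <- fast_mesh()
  m1 <- generate_denture(fast_params(),
                         arrangement_spec(disp_vo = c(III = d)))
  centroid <- function(m, p) {
    ids <- unique(as.vector(m$facets[m$facet_patch == p, ]))
    colMeans(m$nodes[ids, , drop = FALSE])
  }
  for (sd in c("left", "right")) {
    mv <- centroid(m1, paste0("occlusal_III_", sd)) -
      centroid(m0, paste0("occlusal_III_", sd))
    # outward normals vary along the block; the centroid shift magnitude
    # matches the requested displacement to within that chord defect
    expect_equal(sqrt(sum(mv^2)), d, tolerance = 0.02)
    expect_equal(mv[3], 0, tolerance = 1e-12)  # in-plane displacement
  }
  # untouched blocks identical
  expect_equal(centroid(m1, "occlusal_I_right"),
               centroid(m0, "occlusal_I_right"))
  # inclined variant still yields a valid mesh
  m2 <- generate_denture(fast_params(),
                         arrangement_spec(incl_deg = c(I = 15, II = 15)))
  expect_silent(validate_mesh(m2))
})

test_that("degenerate parameters raise errors naming the parameter", {
  expect_error(arch_parameters(base_thickness = -1), "base_thickness")
  expect_error(arch_parameters(flange_height = 1, base_thickness = 3),
               "flange_height")
  expect_error(arch_parameters(cutout_depth = 9), "cutout_depth")
  expect_error(generate_denture(
    fast_params(block_footprints = c(I = 300, II = 200, III = 300, IV = 400))),
    "block_footprints")
  expect_error(arrangement_spec(disp_vo = c(I = 99)), "limit")
  expect_error(arrangement_spec(disp_vo = c(V = 1)), "I..IV")
})

test_that("patch areas follow closed forms", {
  # flat rectangular patch: w x h exactly
  b <- mesh_box(c(3, 2, 1), n = c(3, 2, 1))
  expect_equal(patch_area(b, "zmax"), 3 * 2, tolerance = 1e-12)
  expect_error(patch_area(b, "nope"), "unknown patch")
  # patches partition the boundary
  tot <- sum(vapply(patch_names(b), function(p) patch_area(b, p), 0))
  expect_equal(tot, 2 * (3 * 2 + 3 * 1 + 2 * 1), tolerance = 1e-12)
  m <- fast_mesh()
  g <- rcdlife:::facet_geometry(m$nodes, m$facets)
  expect_equal(sum(vapply(patch_names(m), function(p) patch_area(m, p), 0)),
               sum(g$area), tolerance = 1e-9)
  # triangulated hemisphere: area -> 2 pi r^2 at fine triangulation
  h <- hemisphere_surface(r = 2)
  expect_equal(patch_area(h, "hemisphere"), 2 * pi * 4, tolerance = 0.01)
})

test_that("quadratic conversion preserves geometry and labels", {
  m4 <- fast_mesh()
  m10 <- as_tet10(m4)
  expect_identical(m10$order, 2L)
  expect_identical(ncol(m10$elems), 10L)
  expect_identical(ncol(m10$facets), 6L)
  expect_identical(m10$facet_patch, m4$facet_patch)
  expect_identical(m10$elems[, 1:4], m4$elems)
  expect_silent(validate_mesh(m10))
  # midedge nodes sit at edge midpoints
  e <- m10$elems[1, ]
  expect_equal(m10$nodes[e[5], ],
               (m10$nodes[e[1], ] + m10$nodes[e[2], ]) / 2)
  expect_equal(m10$nodes[e[10], ],
               (m10$nodes[e[3], ] + m10$nodes[e[4], ]) / 2)
})
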