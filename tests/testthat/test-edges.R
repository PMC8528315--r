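# energy/size fields of a noise-free straight tube, plus hand-placed seed
# vertices at the two ends of the axis
tube_fields_and_vertices <- function(radius = 3, dims = c(28, 28, 72)) {
  img <- tube_image(dims, radius)
  bank <- scale_bank(2, 6, 3, f_G = 0.5, f_S = 1)
  fl <- energy_fields(img, bank)
  zc <- (dims[1] + 1) / 2
  mk <- function(x) {
    z <- floor(zc); y <- floor(zc)
    data.frame(z = z, y = y, x = x, z_um = z - 1, y_um = y - 1, x_um = x - 1,
               radius_um = fl$size$values[z, y, x],
               energy = fl$energy$values[z, y, x])
  }
  verts <- rbind(mk(6), mk(dims[3] - 5))
  verts <- cbind(id = 1:2, verts)
  list(fields = fl, vertices = verts, image = img)
}

test_that("a lone vertex finds no edges", {
  tf <- tube_fields_and_vertices()
  expect_identical(extract_edges(tf$vertices[1, ], tf$fields), list())
})

test_that("two vertices on a tube connect by one in-lumen trace", {
  tf <- tube_fields_and_vertices()
  edges <- extract_edges(tf$vertices, tf$fields)
  ## both ends discover each other; mutual dedup keeps one trace
  expect_true(length(edges) >= 1)
  kept <- deduplicate_mutual(edges)
  expect_length(kept, 1L)
  e <- kept[[1]]
  expect_setequal(c(e$vertex_a, e$vertex_b), 1:2)
  ## trace endpoints coincide with the two vertex centres
  ends <- rbind(e$trace[1, ], e$trace[nrow(e$trace), ])
  want <- as.matrix(tf$vertices[c(e$vertex_b, e$vertex_a),
                                c("z", "y", "x")])
  expect_equal(unname(ends), unname(want))
  ## every trace point lies in the tube's negative-energy core
  en <- apply(e$trace, 1L, function(ix)
    tf$fields$energy$values[ix[1], ix[2], ix[3]])
  expect_true(all(en < 0))
  expect_equal(e$max_energy, max(en))
  ## and inside the (slightly dilated) tube lumen
  ctr <- (dim(tf$image$values)[1] + 1) / 2
  rad <- sqrt((e$trace[, 1] - ctr)^2 + (e$trace[, 2] - ctr)^2)
  expect_true(all(rad <= 3 + 1.5))
  ## consecutive points are 26-neighbours
  stp <- abs(diff(e$trace))
  expect_true(all(stp <= 1) && all(rowSums(stp) >= 1))
})

test_that("edge count per origin respects the limit at a junction", {
  ## 6-armed star: arms along +-z, +-y, +-x from the centre
  n <- 49; ctr <- 25
  arr <- array(0, c(n, n, n))
  ax <- (1:n) - ctr
  cross <- outer(ax^2, ax^2, "+") <= 2 # 3-voxel-wide arm cross-section
  for (i in 1:n) {
    arr[i, , ][cross] <- 1 # arm along z
    arr[, i, ][cross] <- 1 # arm along y
    arr[, , i][cross] <- 1 # arm along x
  }
  img <- voxel_grid(arr)
  bank <- scale_bank(1, 3, 3, f_G = 0.5, f_S = 1)
  fl <- energy_fields(img, bank)
  at <- function(z, y, x) data.frame(z = z, y = y, x = x, z_um = z - 1,
                                     y_um = y - 1, x_um = x - 1,
                                     radius_um = max(fl$size$values[z, y, x],
                                                     1),
                                     energy = fl$energy$values[z, y, x])
  verts <- rbind(at(ctr, ctr, ctr),
                 at(4, ctr, ctr), at(n - 3, ctr, ctr),
                 at(ctr, 4, ctr), at(ctr, n - 3, ctr),
                 at(ctr, ctr, 4), at(ctr, ctr, n - 3))
  verts <- cbind(id = 1:7, verts)
  edges <- extract_edges(verts, fl,
                         extraction_limits(max_edges_per_vertex = 4,
                                           max_trace_factor = 100))
  from_centre <- sum(vapply(edges, function(e) e$vertex_a == 1, logical(1)))
  expect_lte(from_centre, 4L)
  expect_gt(length(edges), 0L)
})

test_that("per-origin edges arrive in non-decreasing max-energy order and
           traces respect the length cap", {
  tf <- tube_fields_and_vertices()
  lim <- extraction_limits(max_trace_factor = 30)
  edges <- extract_edges(tf$vertices, tf$fields, lim)
  for (a in unique(vapply(edges, `[[`, numeric(1), "vertex_a"))) {
    me <- vapply(Filter(function(e) e$vertex_a == a, edges),
                 `[[`, numeric(1), "max_energy")
    expect_true(!is.unsorted(me))
  }
  for (e in edges) {
    steps <- sqrt(rowSums(diff(e$trace)^2))
    cap <- lim$max_trace_factor *
      tf$vertices$radius_um[tf$vertices$id == e$vertex_a]
    expect_lte(sum(steps), cap + sqrt(3))
  }
})

test_that("mutual discoveries keep only the more probable trace", {
  e1 <- toy_edge(1, 2, -5); e2 <- toy_edge(2, 1, -3)
  kept <- deduplicate_mutual(list(e1, e2))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$max_energy, -5)

  disjoint <- list(toy_edge(1, 2, -5), toy_edge(3, 4, -3))
  expect_identical(deduplicate_mutual(disjoint), disjoint)

  three <- list(toy_edge(1, 2, -5), toy_edge(2, 1, -3),
                toy_edge(3, 4, -2), toy_edge(4, 3, -6),
                toy_edge(5, 6, -1), toy_edge(6, 5, -9))
  kept <- deduplicate_mutual(three)
  expect_length(kept, 3L)
  expect_setequal(vapply(kept, `[[`, numeric(1), "max_energy"),
                  c(-5, -6, -9))
})

test_that("small-cycle removal deletes the least probable edge and leaves
           no triangle", {
  tri <- list(toy_edge(1, 2, -5), toy_edge(2, 3, -4), toy_edge(3, 1, -2))
  out <- remove_small_cycles(NULL, tri)
  expect_length(out, 2L)
  expect_false(any(vapply(out, `[[`, numeric(1), "max_energy") == -2))

  path <- list(toy_edge(1, 2, -5), toy_edge(2, 3, -4), toy_edge(3, 4, -2))
  expect_identical(remove_small_cycles(NULL, path), path)

  two_tri <- c(tri, list(toy_edge(10, 11, -5), toy_edge(11, 12, -4),
                         toy_edge(12, 10, -1)))
  out <- remove_small_cycles(NULL, two_tri)
  expect_length(out, 4L)
  expect_identical(count_triangles(out), 0L)
})

test_that("random graphs are triangle-free after cleanup (brute-force
           check)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 9
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    take <- pairs[runif(nrow(pairs)) < 0.35, , drop = FALSE]
    edges <- lapply(seq_len(nrow(take)), function(i)
      toy_edge(take[i, 1], take[i, 2], -runif(1, 1, 10)))
    out <- remove_small_cycles(NULL, edges)
    expect_identical(count_triangles(out), 0L)
    ## only edges are removed, never added
    expect_lte(length(out), length(edges))
  }
})
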