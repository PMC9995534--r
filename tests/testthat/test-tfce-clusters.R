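test_that("TFCE of an isolated voxel reproduces the h^3/3 closed form", {
  m <- array(0, c(7, 7, 7))
  h <- 4
  m[4, 4, 4] <- h
  # integral of 1 * u^2 du from 0 to h; exact mode hits it to precision
  expect_equal(tfce_enhance(m, H = 2, E = 0.5)[4, 4, 4], h^3 / 3)
  # the discrete sum converges to the same value as dh shrinks
  err <- vapply(c(50, 500, 2000),
                function(k) abs(tfce_enhance(m, dh = h / k)[4, 4, 4] - h^3 / 3),
                numeric(1))
  expect_lt(err[3] / (h^3 / 3), 0.005)
  expect_true(all(diff(err) < 0))
  expect_equal(tfce_enhance(array(0, c(5, 5, 5))), array(0, c(5, 5, 5)))
})

test_that("TFCE matches the fine-step brute-force oracle on random maps", {
  set.seed(42)
  d <- c(12, 12, 12)
  edges <- lattice_edges(d, 26)
  for (i in 1:5) {
    stat <- array(rnorm(prod(d)), d)
    vmax <- max(abs(stat))
    dh <- vmax / 30
    fast <- tfce_enhance(stat, H = 2, E = 0.5)
    ref <- oracle_tfce_pos(pmax(stat, 0) * 1, H = 2, E = 0.5, dh = dh / 10,
                           edges = edges) -
      oracle_tfce_pos(pmax(-stat, 0) * 1, H = 2, E = 0.5, dh = dh / 10,
                      edges = edges)
    expect_lt(max(abs(fast - ref)) / max(abs(ref)), 0.01)
    # discrete mode approaches the exact integral from its own direction
    disc <- tfce_enhance(stat, H = 2, E = 0.5, dh = vmax / 400)
    expect_lt(max(abs(disc - fast)) / max(abs(fast)), 0.01)
  }
})

test_that("TFCE respects masks, connectivity and scaling monotonicity", {
  set.seed(7)
  d <- c(8, 8, 8)
  stat <- array(rnorm(prod(d)), d)
  mask <- array(TRUE, d); mask[1:2, , ] <- FALSE
  enh <- tfce_enhance(stat, mask)
  expect_true(all(enh[!mask] == 0))
  # multiplying the map by c > 1 never decreases any enhanced value
  e1 <- tfce_enhance(stat, dh = 0.02)
  e2 <- tfce_enhance(2.5 * stat, dh = 0.02)
  expect_true(all(abs(e2) >= abs(e1) - 1e-12))
  expect_true(all(sign(e2) == sign(e1) | e1 == 0))
  # two voxels joined under 26- but not 6-connectivity
  m <- array(0, c(4, 4, 4)); m[2, 2, 2] <- 1; m[3, 3, 3] <- 1
  lab26 <- label_components(m > 0, 26)
  lab6 <- label_components(m > 0, 6)
  expect_equal(max(lab26), 1L)
  expect_equal(max(lab6), 2L)
  expect_error(tfce_enhance(stat, dh = -1), "dh must be positive")
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(11)
  for (conn in c(6L, 18L, 26L)) {
    for (i in 1:10) {
      d <- c(sample(5:10, 1), sample(5:10, 1), sample(5:10, 1))
      act <- array(runif(prod(d)) < 0.35, d)
      got <- label_components(act, conn)
      ref <- oracle_label_components(act, conn)
      # same partition: cluster size multisets match and labels are a bijection
      expect_equal(sort(tabulate(got[act])), sort(tabulate(ref[act])))
      expect_equal(length(unique(got[act])), length(unique(ref[act])))
      pairing <- table(got[act], ref[act])
      expect_true(all(rowSums(pairing > 0) == 1))
    }
  }
})

test_that("clusters are extracted with extent, peak and world coordinates", {
  mask <- array(TRUE, c(10, 10, 10))
  p <- array(1, c(10, 10, 10))
  p[2:8, 2, 2] <- 0.01          # 7-voxel blob
  p[5:7, 8, 8] <- c(0.02, 0.01, 0.03)  # 3-voxel blob
  ct <- extract_clusters(p, mask, alpha = 0.05)
  expect_equal(nrow(ct), 2)
  expect_equal(ct$k_e, c(7, 3))
  expect_equal(ct$p_fwe, c(0.01, 0.01))
  expect_equal(ct$i[2], 6)  # peak at the minimum-p voxel
  # empty result is an empty table, not an error
  ct0 <- extract_clusters(array(1, c(5, 5, 5)), array(TRUE, c(5, 5, 5)))
  expect_equal(nrow(ct0), 0)
  # affine maps peak indices to world coordinates (0-based voxel convention)
  aff <- rbind(c(2, 0, 0, -10), c(0, 2, 0, -20), c(0, 0, 2, -30), c(0, 0, 0, 1))
  st <- cohort_stack(matrix(0, 2, 1000), mask, affine = aff)
  ct2 <- extract_clusters(p, st, alpha = 0.05)
  expect_equal(ct2$x[1], 2 * (ct2$i[1] - 1) - 10)
})

test_that("cluster extents match the flood-fill oracle on random maps", {
  set.seed(19)
  for (i in 1:10) {
    d <- c(9, 9, 9)
    p <- array(runif(prod(d)), d)
    mask <- array(TRUE, d)
    ct <- extract_clusters(p, mask, alpha = 0.2)
    ref <- oracle_label_components(p < 0.2, 26)
    expect_equal(sort(ct$k_e), sort(tabulate(ref[ref > 0])))
  }
})

test_that("atlas overlap percentages follow the 5 percent reporting rule", {
  mask <- array(TRUE, c(10, 10, 10))
  p <- array(1, c(10, 10, 10))
  p[1:10, 1, 1] <- 0.01
  p[1:10, 5, 5] <- 0.01
  ct <- extract_clusters(p, mask, alpha = 0.05)
  atlas <- array(0L, c(10, 10, 10))
  lookup <- data.frame(id = 1:3, name = c("alpha", "beta", "gamma"))
  # cluster 1 wholly inside label 1
  atlas[, 1, 1] <- 1L
  # cluster 2 split 5/5 across labels 2 and 3
  atlas[1:5, 5, 5] <- 2L
  atlas[6:10, 5, 5] <- 3L
  lc <- label_clusters(ct, atlas, lookup)
  ov <- lc$labels
  whole <- ov[[which(vapply(ov, function(x) any(x$id == 1), logical(1)))]]
  expect_equal(whole$overlap_pct, 100)
  split <- ov[[which(vapply(ov, function(x) any(x$id == 2), logical(1)))]]
  expect_equal(sort(split$overlap_pct), c(50, 50))
  # a 4 percent overlap is suppressed at the default 5 percent threshold
  p2 <- array(1, c(10, 10, 10))
  p2[1:25] <- 0.01  # 25-voxel cluster in the first column-block
  ct2 <- extract_clusters(p2, mask, alpha = 0.05)
  expect_equal(ct2$k_e, 25)
  atlas2 <- array(0L, c(10, 10, 10))
  atlas2[1] <- 1L                 # 1/25 = 4 percent
  atlas2[2:25] <- 2L              # 96 percent
  lc2 <- label_clusters(ct2, atlas2, lookup)
  expect_false(any(lc2$labels[[1]]$id == 1))
  expect_true(any(lc2$labels[[1]]$id == 2))
  # the suppressed label reappears when the threshold allows it
  lc3 <- label_clusters(ct2, atlas2, lookup, min_overlap = 3)
  expect_true(any(lc3$labels[[1]]$id == 1))
  expect_error(label_clusters(ct2, array(0L, c(5, 5, 5)), lookup),
               "grid")
})
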