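# Discrete system assembly and the splitting step: conservation, interface
# handling, fixed points, gauge invariance and dense-oracle equivalence.

test_that("passive-box operator has zero row sums except the pinned row", {
  f <- make_box_field(5)
  m <- tissue_model(f)
  sys <- assemble(m, ground = linear_index(f, 2L, 2L, 2L))
  K <- as.matrix(sys$K)
  rs <- rowSums(K)
  gn <- sys$gn
  expect_equal(rs[gn], 1)
  # rows not adjacent to the pinned node conserve current exactly
  # (pinning zeroes the ground column, which leaves the ground's grid
  # neighbours with the absorbed conductance in their row sum)
  gnbr_vox <- linear_index(f, c(3L, 2L, 2L), c(2L, 3L, 2L), c(2L, 2L, 3L))
  gnbr <- sys$nodes_of[gnbr_vox]
  untouched <- setdiff(seq_len(nrow(K)), c(gn, gnbr))
  expect_lt(max(abs(rs[untouched])), 1e-12 * max(abs(K)))
  # the sparse operator is symmetric
  expect_lt(max(abs(K - t(K))), 1e-14)
})

test_that("face coupling equals the harmonic mean of the two conductivities", {
  f <- make_box_field(2, dx = 0.01)
  m <- tissue_model(f)
  v1 <- linear_index(f, 2L, 2L, 2L)
  v2 <- linear_index(f, 3L, 2L, 2L)
  m$sigma_o[v1] <- 0.2
  m$sigma_o[v2] <- 0.05
  sys <- assemble(m, ground = linear_index(f, 2L, 3L, 3L))
  K <- as.matrix(sys$K)
  a <- sys$nodes_of[v1]
  b <- sys$nodes_of[v2]
  g_expect <- 2 * 0.2 * 0.05 / (0.2 + 0.05) / 0.01^2
  expect_equal(-K[a, b], g_expect, tolerance = 1e-12)
})

test_that("the intracellular operator never couples across the heart boundary", {
  f <- make_heart_block_field(4)
  m <- tissue_model(f)
  sys <- assemble(m)
  LiA <- as.matrix(sys$L_iA)
  # rows of passive nodes carry no intracellular coupling at all
  expect_equal(max(abs(LiA[!sys$hsel, , drop = FALSE])), 0)
  # each intracellular column conserves current (zero column sum)
  expect_lt(max(abs(colSums(LiA))), 1e-10)
})

test_that("the global rest state is stationary and the ground stays pinned", {
  f <- make_heart_block_field(4)
  m <- tissue_model(f)
  sys <- assemble(m)
  st <- initial_field_state(sys)
  for (i in 1:200) st <- step(sys, st, 5e-5)   # 10 ms
  expect_lt(max(abs(st$vm + 0.085)), 1e-9)     # drift well under 10 uV/s
  expect_lt(max(abs(st$phi)), 1e-9)
  expect_identical(st$phi[sys$gn], 0)
})

test_that("the elliptic solve is gauge-fixed by the ground pin", {
  f <- make_heart_block_field(4)
  m <- tissue_model(f)
  sys <- assemble(m)
  st <- initial_field_state(sys)
  st$vm[20] <- -0.010                          # an excited voxel
  s1 <- step(sys, st, 5e-5)
  st2 <- st
  st2$phi <- st2$phi + 0.25                    # constant offset in Ve/V
  s2 <- step(sys, st2, 5e-5)
  expect_lt(max(abs(s1$phi - s2$phi)), 1e-9)
  expect_identical(s1$phi[sys$gn], 0)
  # residual of the elliptic system is at solver tolerance
  b <- as.numeric(sys$L_iA %*% s1$vm)
  b[sys$gn] <- 0
  expect_lt(max(abs(as.numeric(sys$K %*% s1$phi) - b)),
            1e-9 * max(abs(b)))
})

test_that("one splitting step matches the dense brute-force oracle", {
  f <- make_heart_block_field(4, dx = 0.004)
  m <- tissue_model(f)
  sys <- assemble(m)
  st <- initial_field_state(sys)
  exc <- which(sys$region == "Ventricles")[c(10, 25)]
  st$vm[exc] <- 0.010
  dt <- 5e-5
  ops <- dense_operators(m)
  plist <- lapply(sys$region, region_defaults)
  nsub <- vapply(plist, function(p) bidecg:::.cell_substeps(p, dt),
                 integer(1))
  vm <- st$vm; u <- st$u; phi <- st$phi
  s <- st
  for (i in 1:3) {
    s <- step(sys, s, dt)
    dres <- dense_step(m, ops, vm, u, phi, dt, sys$ground_voxel, plist, nsub)
    vm <- dres$vm; u <- dres$u; phi <- dres$phi
  }
  expect_equal(s$vm, vm, tolerance = 1e-8)
  expect_equal(s$u, u, tolerance = 1e-8)
  expect_equal(s$phi, phi, tolerance = 1e-8)
})

test_that("an excited voxel spreads to face neighbours first", {
  f <- make_heart_block_field(5, dx = 0.004)
  m <- tissue_model(f)
  sys <- assemble(m)
  st <- initial_field_state(sys)
  centre <- linear_index(f, 5L, 5L, 5L)
  hidx <- match(centre, sys$hvox)
  st$vm[hidx] <- 0.010
  s1 <- step(sys, st, 5e-5)
  d <- dim(f$lab)
  face_vox <- centre + c(1, -1, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  corner_vox <- centre + (1 + d[1] + d[1] * d[2]) * c(1, -1)
  fi <- match(face_vox, sys$hvox)
  ci <- match(corner_vox, sys$hvox)
  dv <- s1$vm - st$vm
  expect_true(all(dv[fi] > 0))
  # corner-diagonal neighbours see only a higher-order remnant of the
  # implicit solve, well below the face-neighbour change
  expect_lt(max(abs(dv[ci])), 0.02 * min(dv[fi]))
})

test_that("a globally infarcted heart never activates", {
  cfg <- make_fixture("tiny-3d")
  cfg$solver$duration <- 0.4
  cfg$regions <- list(SAN = list(sigma_i = 0, k = 0),
                      Atria = list(sigma_i = 0, k = 0),
                      AVN = list(sigma_i = 0, k = 0),
                      His = list(sigma_i = 0, k = 0),
                      BNL = list(sigma_i = 0, k = 0),
                      Purkinje = list(sigma_i = 0, k = 0),
                      Ventricles = list(sigma_i = 0, k = 0))
  res <- run_simulation(cfg)
  expect_true(all(is.na(res$activation)))
})
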