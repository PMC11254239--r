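# Brute-force oracles: direct voxel-pair / zone enumeration written
# independently of the array-shift implementation.

brute_glcm <- function(disc, offset, n_levels) {
  d <- dim(disc)
  P <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- disc[x, y, z]
    if (a == 0) next
    xx <- x + offset[1]; yy <- y + offset[2]; zz <- z + offset[3]
    if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
    b <- disc[xx, yy, zz]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

test_that("GLCM counts equal a hand-enumerated co-occurrence oracle", {
  # classic 4x4 two-level style toy image (one slice)
  img <- matrix(c(1, 2, 5, 2,
                  3, 5, 1, 3,
                  5, 3, 5, 3,
                  3, 2, 1, 1), 4, 4, byrow = TRUE)
  disc <- array(0L, c(4, 4, 1))
  disc[, , 1] <- img
  mats <- texture_matrices(disc, 5)
  for (k in seq_len(nrow(DIRECTIONS_13))) {
    expect_equal(mats$glcm[[k]],
                 brute_glcm(disc, DIRECTIONS_13[k, ], 5),
                 label = paste("direction", k))
  }
  # and on a random 3-D region
  disc3 <- random_disc_region(c(6, 6, 4), n_levels = 5, seed = 2)
  mats3 <- texture_matrices(disc3, 5)
  for (k in c(1, 4, 10, 13)) {
    expect_equal(mats3$glcm[[k]], brute_glcm(disc3, DIRECTIONS_13[k, ], 5))
  }
})

test_that("constant region has degenerate GLCM and single maximal runs", {
  disc <- array(2L, c(4, 4, 4))
  mats <- texture_matrices(disc, 4)
  for (P in mats$glcm) {
    expect_equal(sum(P > 0), 1)
    expect_equal(which(P > 0), 2 + (2 - 1) * 4)  # only (2,2) occupied
  }
  f <- texture_features(mats)
  expect_equal(f[["glcm_Contrast"]], 0)
  # along each axis direction every line is one maximal run
  ax <- mats$glrlm[[1]]   # direction (1,0,0): 16 runs of length 4
  expect_equal(sum(ax), 16)
  expect_equal(ax[2, 4], 16)
  # one zone covering everything
  expect_equal(sum(mats$glszm), 1)
  expect_equal(mats$glszm[2, 64], 1)
})

test_that("checkerboard has no same-level co-occurrence along axes", {
  d <- c(6, 6, 6)
  g <- expand.grid(x = 1:6, y = 1:6, z = 1:6)
  disc <- array(ifelse((g$x + g$y + g$z) %% 2 == 0, 1L, 2L), d)
  mats <- texture_matrices(disc, 2)
  for (k in 1:3) {   # axis directions
    P <- mats$glcm[[k]]
    expect_equal(P[1, 1], 0)
    expect_equal(P[2, 2], 0)
  }
})

test_that("GLSZM zones match a hand-built two-zone configuration", {
  disc <- array(0L, c(5, 5, 1))
  disc[1:2, 1:2, 1] <- 1L          # 4-voxel zone of level 1
  disc[4:5, 4:5, 1] <- 1L          # separate 4-voxel zone of level 1
  disc[4, 1, 1] <- 3L              # singleton zone of level 3
  mats <- texture_matrices(disc, 3)
  expect_equal(mats$glszm[1, 4], 2)
  expect_equal(mats$glszm[3, 1], 1)
  expect_equal(sum(mats$glszm), 3)
})

test_that("GLDM dependence counts match direct neighbourhood enumeration", {
  disc <- random_disc_region(c(5, 5, 4), n_levels = 3, seed = 7)
  mats <- texture_matrices(disc, 3)
  d <- dim(disc)
  ref <- matrix(0, 3, 27)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- disc[x, y, z]
    if (a == 0) next
    dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      if (disc[xx, yy, zz] == a) dep <- dep + 1
    }
    ref[a, dep + 1] <- ref[a, dep + 1] + 1
  }
  expect_equal(unname(mats$gldm), ref[, seq_len(ncol(mats$gldm)), drop = FALSE])
})

test_that("NGTDM terms match direct enumeration on a tiny region", {
  disc <- array(c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L), c(2, 2, 2))
  mats <- texture_matrices(disc, 2)
  # every voxel has 7 valid neighbours; enumerate s_i directly
  d <- dim(disc)
  s_ref <- c(0, 0); n_ref <- c(0, 0)
  for (x in 1:2) for (y in 1:2) for (z in 1:2) {
    a <- disc[x, y, z]
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > 2 || yy < 1 || yy > 2 || zz < 1 || zz > 2) next
      nb <- c(nb, disc[xx, yy, zz])
    }
    s_ref[a] <- s_ref[a] + abs(a - mean(nb))
    n_ref[a] <- n_ref[a] + 1
  }
  expect_equal(mats$ngtdm$s, s_ref)
  expect_equal(mats$ngtdm$n, n_ref)
})

test_that("the texture block has exactly the documented 74 features", {
  disc <- random_disc_region(c(8, 8, 6), n_levels = 8, seed = 3)
  f <- texture_features(texture_matrices(disc, 8))
  expect_named_length(f, 74)
  expect_true(all(is.finite(f)))
  counts <- table(sub("_.*", "", names(f)))
  expect_equal(unname(counts[c("glcm", "glrlm", "glszm", "gldm", "ngtdm")]),
               c(23, 16, 16, 14, 5), ignore_attr = TRUE)
  key <- c("gldm_DependenceNonUniformity", "glcm_InverseVariance",
           "glszm_SizeZoneNonUniformityNormalized",
           "glszm_SmallAreaHighGrayLevelEmphasis")
  expect_true(all(key %in% names(f)))
  expect_false("glcm_SumAverage" %in% names(f))
})

test_that("selected texture features match their defining formulas", {
  disc <- random_disc_region(c(7, 7, 5), n_levels = 6, seed = 9)
  mats <- texture_matrices(disc, 6)
  f <- texture_features(mats)
  # GLCM contrast recomputed from the summed definition, averaged over dirs
  contr <- mean(vapply(mats$glcm, function(P) {
    occ <- which(rowSums(P) + colSums(P) > 0)
    p <- P[occ, occ] / sum(P)
    sum(outer(occ, occ, "-")^2 * p)
  }, numeric(1)))
  expect_equal(f[["glcm_Contrast"]], contr, tolerance = 1e-12)
  # GLSZM SmallAreaHighGrayLevelEmphasis from its definition
  P <- mats$glszm
  occ <- which(rowSums(P) > 0)
  p <- P[occ, , drop = FALSE] / sum(P)
  szv <- matrix(seq_len(ncol(P)), length(occ), ncol(P), byrow = TRUE)
  lvv <- matrix(occ, length(occ), ncol(P))
  expect_equal(f[["glszm_SmallAreaHighGrayLevelEmphasis"]],
               sum(p * lvv^2 / szv^2), tolerance = 1e-12)
  # NGTDM coarseness from its definition
  ng <- mats$ngtdm
  expect_equal(f[["ngtdm_Coarseness"]], 1 / sum(ng$p * ng$s), tolerance = 1e-12)
})
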