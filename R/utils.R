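# Internal numerical helpers shared across modules.

# Derive a reproducible child seed from a master seed. All stochastic stages
# take their own seed derived this way, so a single master seed determines the
# whole analysis. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  key <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + key * 16807) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian smoothing of a 3-D array (zero padding). sigma in voxels,
# recycled per axis; sigma = 0 disables the corresponding pass.
gaussian_smooth3d <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3)
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    mm <- matrix(m, dm[1], dm[2] * dm[3])
    mp <- rbind(matrix(0, r, ncol(mm)), mm, matrix(0, r, ncol(mm)))
    out <- matrix(0, dm[1], ncol(mm))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + dm[1] - 1), , drop = FALSE]
    a <- aperm(array(out, dm), order(perm))
  }
  a
}

# Shift a 3-D array by an integer offset, padding with `fill`.
shift3d <- function(a, offset, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- offset[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      src[[ax]] <- 1:(d[ax] - o); dst[[ax]] <- (1 + o):d[ax]
    } else {
      src[[ax]] <- (1 - o):d[ax]; dst[[ax]] <- 1:(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique 3-D direction offsets (half of the 26-neighbourhood).
DIRECTIONS_13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

# All 26 neighbour offsets.
OFFSETS_26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
OFFSETS_26 <- OFFSETS_26[rowSums(abs(OFFSETS_26)) > 0, , drop = FALSE]

# Crop an array to the bounding box of `mask` with a 0-voxel margin.
crop_to_mask <- function(a, mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  a[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3], drop = FALSE]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, about 0 for independent ones. Used to compare
#' recovered subregion maps with planted ground-truth habitats.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
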