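# Internal helpers shared across modules.

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized", call. = FALSE)
  v / n
}

# World coordinates (mm) of voxel centers along one axis.
# Convention: 0-based corner origin, coordinate = index * voxel_size.
axis_coords <- function(n, voxel_size) (seq_len(n) - 1) * voxel_size

# Coordinates normalized to [-1, 1] per axis (polynomial conditioning).
# Shared between the phantom's offset injection and the background fit.
axis_coords_norm <- function(n) {
  if (n == 1) return(0)
  2 * (seq_len(n) - 1) / (n - 1) - 1
}

# Exponent table for monomials x^a y^b z^c with a+b+c <= order.
# Fixed ordering: total degree, then lexicographic in (a, b, c).
poly_exponents <- function(order = 3) {
  stopifnot(order >= 0)
  ex <- expand.grid(c = 0:order, b = 0:order, a = 0:order)
  ex <- ex[ex$a + ex$b + ex$c <= order, c("a", "b", "c")]
  ex <- ex[order(ex$a + ex$b + ex$c, ex$a, ex$b, ex$c), ]
  rownames(ex) <- NULL
  as.matrix(ex)
}

# Design matrix of monomials evaluated at points (n x 3, normalized coords).
poly_basis <- function(pts, order = 3) {
  ex <- poly_exponents(order)
  out <- matrix(1, nrow(pts), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    out[, j] <- pts[, 1]^ex[j, 1] * pts[, 2]^ex[j, 2] * pts[, 3]^ex[j, 3]
  }
  colnames(out) <- apply(ex, 1, function(e) paste0("x", e[1], "y", e[2], "z", e[3]))
  out
}

# Normalized-coordinate grid of a field as an (nvox x 3) matrix.
grid_coords_norm <- function(dims) {
  cbind(
    rep(axis_coords_norm(dims[1]), times = dims[2] * dims[3]),
    rep(rep(axis_coords_norm(dims[2]), each = dims[1]), times = dims[3]),
    rep(axis_coords_norm(dims[3]), each = dims[1] * dims[2])
  )
}

# Trilinear interpolation of a 3-D array at mm positions.
# pts: n x 3 matrix in mm, corner-origin convention. Values outside the
# grid return NA (callers decide whether that is an error).
interp_trilinear <- function(arr, pts, voxel_size) {
  d <- dim(arr)
  g <- pts / voxel_size  # 0-based continuous index
  ok <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
    g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
    g[, 3] >= 0 & g[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  g <- g[ok, , drop = FALSE]
  i0 <- pmin(floor(g[, 1]), d[1] - 2)
  j0 <- pmin(floor(g[, 2]), d[2] - 2)
  k0 <- pmin(floor(g[, 3]), d[3] - 2)
  fx <- g[, 1] - i0; fy <- g[, 2] - j0; fz <- g[, 3] - k0
  lin <- function(i, j, k) i + 1L + d[1] * (j + d[2] * k)
  v000 <- arr[lin(i0, j0, k0)];     v100 <- arr[lin(i0 + 1, j0, k0)]
  v010 <- arr[lin(i0, j0 + 1, k0)]; v110 <- arr[lin(i0 + 1, j0 + 1, k0)]
  v001 <- arr[lin(i0, j0, k0 + 1)]; v101 <- arr[lin(i0 + 1, j0, k0 + 1)]
  v011 <- arr[lin(i0, j0 + 1, k0 + 1)]; v111 <- arr[lin(i0 + 1, j0 + 1, k0 + 1)]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz) + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz + v111 * fx * fy * fz
  out
}

# Lower median: for even counts the lower of the two central order statistics.
# Deterministic, used for the median RR interval.
lower_median <- function(x) {
  s <- sort(x)
  s[floor((length(s) + 1) / 2)]
}
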