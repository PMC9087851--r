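# Index bookkeeping for symmetric rank-2 (diffusion) and rank-4 (kurtosis)
# tensors stored as their unique components.
#
# D: 6 components, order (xx, yy, zz, xy, xz, yz), multiplicities (1,1,1,2,2,2).
# W: 15 components, the multisets of size 4 over {x,y,z} in lexicographic
#    order; multiplicity of a component is the multinomial count 4!/prod(k!).

d6_index <- function() {
  cbind(i = c(1, 2, 3, 1, 1, 2), j = c(1, 2, 3, 2, 3, 3))
}

d6_mult <- function() c(1, 1, 1, 2, 2, 2)

w15_index <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    # all sorted 4-tuples (multisets) over {1,2,3}
    idx <- expand.grid(l = 1:3, k = 1:3, j = 1:3, i = 1:3)
    idx <- as.matrix(idx[, 4:1])
    sorted <- t(apply(idx, 1, sort))
    uniq <- unique(sorted)
    cache <<- uniq[order(uniq[, 1], uniq[, 2], uniq[, 3], uniq[, 4]), , drop = FALSE]
    cache
  }
})

w15_mult <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- apply(w15_index(), 1, function(r) {
      counts <- tabulate(r, 3)
      factorial(4) / prod(factorial(counts))
    })
    cache
  }
})

# Design-row weights: for unit direction n, D_app = sum(mult * prod(n[idx]) * D6)
d6_dirprod <- function(n) {
  idx <- d6_index()
  n[idx[, 1]] * n[idx[, 2]]
}

w15_dirprod <- function(n) {
  idx <- w15_index()
  n[idx[, 1]] * n[idx[, 2]] * n[idx[, 3]] * n[idx[, 4]]
}

# ndir x 6 / ndir x 15 direction-product matrices (with multiplicities)
dirprod2_matrix <- function(dirs) {
  dirs <- matrix(dirs, ncol = 3)
  idx <- d6_index()
  m <- d6_mult()
  out <- matrix(0, nrow(dirs), 6)
  for (r in seq_len(6)) out[, r] <- m[r] * dirs[, idx[r, 1]] * dirs[, idx[r, 2]]
  out
}

dirprod4_matrix <- function(dirs) {
  dirs <- matrix(dirs, ncol = 3)
  idx <- w15_index()
  m <- w15_mult()
  out <- matrix(0, nrow(dirs), 15)
  for (r in seq_len(15))
    out[, r] <- m[r] * dirs[, idx[r, 1]] * dirs[, idx[r, 2]] *
      dirs[, idx[r, 3]] * dirs[, idx[r, 4]]
  out
}

# Apparent diffusivity along each row of directions for D stored as
# (nvox x 6); returns nvox x ndir.
apparent_diffusivity <- function(d6, dirs) {
  d6 %*% t(dirprod2_matrix(dirs))
}

apparent_w <- function(w15, dirs) {
  w15 %*% t(dirprod4_matrix(dirs))
}

# 6-vector <-> symmetric 3x3
d6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

mat_to_d6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

# Map the 81 entries of the full rank-4 tensor to their unique-component row,
# and the rows that read the unique components back out.
w81_maps <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    idx <- w15_index()
    key15 <- apply(idx, 1, paste, collapse = "")
    grid <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3, l = 1:3))
    key81 <- apply(grid, 1, function(r) paste(sort(r), collapse = ""))
    to15 <- match(key81, key15)
    # position of each full entry in the 9x9 unfolding W[(i,j),(k,l)]
    rows <- grid[, 1] + 3 * (grid[, 2] - 1)
    cols <- grid[, 3] + 3 * (grid[, 4] - 1)
    pos99 <- rows + 9 * (cols - 1)
    # one representative full-entry position per unique component
    rep81 <- match(seq_len(15), to15)
    cache <<- list(to15 = to15, pos99 = pos99, rep81 = rep81)
    cache
  }
})

# Rotate a rank-4 fully symmetric tensor given as 15 unique components:
# W'_ijkl = R_ia R_jb R_kc R_ld W_abcd, via the 9x9 unfolding
# W' = (R (x) R) W (R (x) R)^T.
rotate_w15 <- function(w15, rot) {
  mp <- w81_maps()
  w99 <- numeric(81)
  w99[mp$pos99] <- w15[mp$to15]
  k <- kronecker(rot, rot)
  w99r <- k %*% matrix(w99, 9, 9) %*% t(k)
  as.numeric(w99r)[mp$pos99[mp$rep81]]
}

# Axially symmetric eigenvalues (l1, l2, l2) matching a target FA and MD.
# FA formula inverted numerically over l1 in [MD, 3 MD).
eigs_from_fa_md <- function(fa, md) {
  if (fa < 0 || fa >= 1) stopf("FA target %.3f outside [0, 1)", fa)
  if (fa == 0) return(c(md, md, md))
  fa_of <- function(l1) {
    l2 <- (3 * md - l1) / 2
    lam <- c(l1, l2, l2)
    lb <- mean(lam)
    sqrt(3 / 2) * sqrt(sum((lam - lb)^2) / sum(lam^2))
  }
  l1 <- stats::uniroot(function(l) fa_of(l) - fa, c(md * (1 + 1e-9), 3 * md * (1 - 1e-9)),
                       tol = 1e-14)$root
  l2 <- (3 * md - l1) / 2
  c(l1, l2, l2)
}

# Axially symmetric kurtosis tensor (axis e1 of the given frame) hitting the
# target AK (along the axis), RK (perpendicular) and MK (direction average).
# Returned in the laboratory frame as 15 unique components.
w15_from_kurtosis <- function(mk, ak, rk, eigs, frame, dirs = kurtosis_dirs()) {
  md <- mean(eigs)
  w <- numeric(15)
  idx <- w15_index()
  key <- apply(idx, 1, paste, collapse = "")
  set <- function(k, v) w[match(k, key)] <<- v
  w1111 <- ak * eigs[1]^2 / md^2
  w2222 <- rk * eigs[2]^2 / md^2
  set("1111", w1111)
  set("2222", w2222); set("3333", w2222)
  set("2233", w2222 / 3)
  # choose the mixed component to hit the MK target (MK is linear in it)
  d6 <- mat_to_d6(frame %*% diag(eigs) %*% t(frame))
  mk_of <- function(t) {
    w2 <- w
    w2[match(c("1122", "1133"), key)] <- t
    wl <- rotate_w15(w2, frame)
    dapp <- as.numeric(apparent_diffusivity(matrix(d6, 1), dirs))
    wapp <- as.numeric(apparent_w(matrix(wl, 1), dirs))
    mean(md^2 / dapp^2 * wapp)
  }
  m0 <- mk_of(0); m1 <- mk_of(1)
  tmix <- if (abs(m1 - m0) < 1e-12) 0 else (mk - m0) / (m1 - m0)
  w[match(c("1122", "1133"), key)] <- tmix
  rotate_w15(w, frame)
}

# deterministic direction set for kurtosis averages
kurtosis_dirs <- function(n = 64) fibonacci_sphere(n)

# Orthonormal frame with first column along v.
frame_from_axis <- function(v) {
  v <- v / vnorm(v)
  helper <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- helper - sum(helper * v) * v
  u2 <- u2 / vnorm(u2)
  u3 <- c(v[2] * u2[3] - v[3] * u2[2],
          v[3] * u2[1] - v[1] * u2[3],
          v[1] * u2[2] - v[2] * u2[1])
  cbind(v, u2, u3, deparse.level = 0)
}
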