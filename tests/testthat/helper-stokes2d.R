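# Independent 2-D Stokes oracle: creeping flow normal to a periodic row of
# circular cylinders, solved as a sparse saddle-point system on a MAC grid
# (Matrix::solve), entirely separate from the package's 3-D kernel. The drag
# per cylinder per unit length follows from the momentum balance F = dP * L.
stokes2d_row_drag <- function(a, L, mu = 1e-3, h = a / 12,
                              H = 4 * max(a, L / 2), U = 1) {
  nx <- max(8L, as.integer(round(L / h)))
  h <- L / nx  # exact periodic fit
  ny <- as.integer(round(2 * H / h))
  Ly <- ny * h
  alpha_pen <- 1e6 * mu / h^2
  yc <- (seq_len(ny) - 0.5) * h
  xc <- (seq_len(nx) - 0.5) * h
  cy <- Ly / 2; cx <- L / 2

  # solid volume fraction by 3x3 subsampling
  sub <- c(-1, 0, 1) / 3 * h
  frac <- matrix(0, nx, ny)
  for (dx in sub) for (dy in sub) {
    px <- outer(xc + dx, rep(1, ny))
    py <- outer(rep(1, nx), yc + dy)
    frac <- frac + ((px - cx)^2 + (py - cy)^2 <= a^2)
  }
  frac <- frac / 9

  wrap <- function(i) ((i - 1L) %% nx) + 1L
  iu <- function(i, j) (j - 1L) * nx + wrap(i)
  nu <- nx * ny
  iv <- function(i, j) nu + (j - 1L) * nx + wrap(i)
  nv <- nx * (ny + 1L)
  ip <- function(i, j) nu + nv + (j - 1L) * nx + wrap(i)
  n <- nu + nv + nx * ny

  cap <- 12L * n
  ti <- integer(cap); tj <- integer(cap); tx <- numeric(cap)
  cnt <- 0L
  rhs <- numeric(n)
  add <- function(r, c, v) {
    cnt <<- cnt + 1L
    ti[cnt] <<- r; tj[cnt] <<- c; tx[cnt] <<- v
  }
  c1 <- mu / h^2

  for (j in seq_len(ny)) for (i in seq_len(nx)) {   # u momentum
    r <- iu(i, j)
    af <- alpha_pen * (frac[wrap(i - 1L), j] + frac[i, j]) / 2
    diag <- af + 2 * c1
    add(r, iu(i - 1L, j), -c1); add(r, iu(i + 1L, j), -c1)
    if (j > 1L) { add(r, iu(i, j - 1L), -c1); diag <- diag + c1 }
    else diag <- diag + 3 * c1
    if (j < ny) { add(r, iu(i, j + 1L), -c1); diag <- diag + c1 }
    else diag <- diag + 3 * c1
    add(r, r, diag)
    add(r, ip(i, j), 1 / h); add(r, ip(i - 1L, j), -1 / h)
  }
  for (j in seq_len(ny + 1L)) for (i in seq_len(nx)) {  # v momentum
    r <- iv(i, j)
    if (j == 1L || j == ny + 1L) { add(r, r, 1); rhs[r] <- U; next }
    af <- alpha_pen * (frac[i, j - 1L] + frac[i, j]) / 2
    add(r, iv(i - 1L, j), -c1); add(r, iv(i + 1L, j), -c1)
    add(r, iv(i, j - 1L), -c1); add(r, iv(i, j + 1L), -c1)
    add(r, r, 4 * c1 + af)
    add(r, ip(i, j), 1 / h); add(r, ip(i, j - 1L), -1 / h)
  }
  for (j in seq_len(ny)) for (i in seq_len(nx)) {   # continuity, p pinned
    r <- ip(i, j)
    if (i == 1L && j == 1L) { add(r, r, 1); next }
    add(r, iu(i + 1L, j), 1 / h); add(r, iu(i, j), -1 / h)
    add(r, iv(i, j + 1L), 1 / h); add(r, iv(i, j), -1 / h)
  }

  A <- Matrix::sparseMatrix(i = ti[1:cnt], j = tj[1:cnt], x = tx[1:cnt],
                            dims = c(n, n))
  sol <- as.numeric(Matrix::solve(A, rhs))
  p <- matrix(sol[(nu + nv + 1):n], nx, ny)
  dP <- mean(p[, 2]) - mean(p[, ny - 1L])
  list(dP = dP, F = dP * L, F_over_muU = dP * L / (mu * U), h = h)
}
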