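# Brute-force dense reference for one operator-splitting step, built by
# explicit voxel loops and dense base-R linear algebra, independent of the
# package's sparse assembly path.

dense_operators <- function(model) {
  field <- model$field
  lab <- field$lab
  d <- dim(lab)
  dx <- field$dx
  cond <- which(lab > 0L)
  n <- length(cond)
  id <- array(0L, d)
  id[cond] <- seq_len(n)
  sig_ep <- model$sigma_e + model$sigma_o
  harm1 <- function(a, b) if (a + b > 0) 2 * a * b / (a + b) else 0
  Li <- matrix(0, n, n)
  Le <- matrix(0, n, n)
  for (p in cond) {
    k <- (p - 1) %/% (d[1] * d[2])
    j <- (p - 1 - k * d[1] * d[2]) %/% d[1]
    i <- p - 1 - k * d[1] * d[2] - j * d[1]
    ijk <- c(i, j, k) + 1L
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[ax] <- nb[ax] + s
      if (nb[ax] < 1L || nb[ax] > d[ax]) next
      q <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
      if (lab[q] == 0L) next
      gi <- harm1(model$sigma_i_op[p], model$sigma_i_op[q]) / dx^2
      if (xor(model$frozen[p], model$frozen[q])) {
        wlab <- unname(label_table()[c("atria", "ventricles")])
        if (lab[p] %in% wlab && lab[q] %in% wlab)
          gi <- gi * model$border_coupling
        else gi <- 0
      }
      ge <- harm1(sig_ep[p], sig_ep[q]) / dx^2
      a <- id[p]; b <- id[q]
      Li[a, b] <- Li[a, b] + gi
      Li[a, a] <- Li[a, a] - gi
      Le[a, b] <- Le[a, b] + ge
      Le[a, a] <- Le[a, a] - ge
    }
  }
  list(Li = Li, Le = Le, id = id, cond = cond, n = n,
       heart = lab[cond] %in% label_table()[5:11])
}

# subcycled RK4 reaction in plain R through the exported kinetics functions
dense_reaction <- function(vm, u, dt, plist, nsub) {
  for (i in seq_along(vm)) {
    p <- plist[[i]]
    if (p$k == 0) next
    h <- dt / nsub[i]
    v <- vm[i]; uu <- u[i]
    for (s in seq_len(nsub[i])) {
      k1v <- -iion(v * 1000, uu, p); k1u <- du_dt(v * 1000, uu, p)
      v2 <- v + h / 2 * k1v; u2 <- uu + h / 2 * k1u
      k2v <- -iion(v2 * 1000, u2, p); k2u <- du_dt(v2 * 1000, u2, p)
      v3 <- v + h / 2 * k2v; u3 <- uu + h / 2 * k2u
      k3v <- -iion(v3 * 1000, u3, p); k3u <- du_dt(v3 * 1000, u3, p)
      v4 <- v + h * k3v; u4 <- uu + h * k3u
      k4v <- -iion(v4 * 1000, u4, p); k4u <- du_dt(v4 * 1000, u4, p)
      v <- v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      uu <- uu + h / 6 * (k1u + 2 * k2u + 2 * k3u + k4u)
    }
    vm[i] <- v; u[i] <- uu
  }
  list(vm = vm, u = u)
}

# one full splitting step with dense algebra; mirrors the documented update
dense_step <- function(model, ops, vm, u, phi, dt, gvox, plist, nsub) {
  hsel <- ops$heart
  r <- dense_reaction(vm, u, dt, plist, nsub)
  Lhh <- ops$Li[hsel, hsel, drop = FALSE]
  M <- diag(length(vm)) / dt - Lhh
  vmn <- solve(M, r$vm / dt + Lhh %*% phi[hsel])
  K <- -(ops$Le + ops$Li)
  gn <- ops$id[gvox]
  K[gn, ] <- 0; K[, gn] <- 0; K[gn, gn] <- 1
  vfull <- numeric(ops$n)
  vfull[hsel] <- vmn
  b <- ops$Li %*% vfull
  b[gn] <- 0
  phin <- solve(K, b)
  list(vm = as.numeric(vmn), u = r$u, phi = as.numeric(phin))
}
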