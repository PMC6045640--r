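# Independent oracles and fixture builders shared by the test files. Each
# oracle is a deliberately naive implementation (brute force, enumeration or
# textbook series) kept separate from the code paths it checks.

# per-ray maximum by explicit looping
oracle_mip <- function(arr, axis) {
  keep <- setdiff(1:3, axis)
  dm <- dim(arr)
  plane <- matrix(-Inf, dm[keep[1]], dm[keep[2]])
  for (a in seq_len(dm[keep[1]])) for (b in seq_len(dm[keep[2]])) {
    ray <- switch(axis, arr[, a, b], arr[a, , b], arr[a, b, ])
    plane[a, b] <- max(ray)
  }
  plane
}

# widest-path (maximin) value between two pixels of a matrix, 8-connectivity:
# maximize over paths the minimum node value (naive O(V^2) Dijkstra variant)
oracle_widest_path <- function(plane, a, b) {
  dm <- dim(plane)
  n <- length(plane)
  best <- rep(-Inf, n)
  done <- rep(FALSE, n)
  id <- function(p) p[1] + (p[2] - 1L) * dm[1]
  best[id(a)] <- plane[a[1], a[2]]
  repeat {
    u <- which.max(ifelse(done, -Inf, best))
    if (done[u] || best[u] == -Inf) break
    done[u] <- TRUE
    if (u == id(b)) return(best[u])
    i <- ((u - 1L) %% dm[1]) + 1L
    j <- ((u - 1L) %/% dm[1]) + 1L
    for (da in -1:1) for (db in -1:1) {
      if (da == 0 && db == 0) next
      ii <- i + da; jj <- j + db
      if (ii < 1 || jj < 1 || ii > dm[1] || jj > dm[2]) next
      v <- id(c(ii, jj))
      cand <- min(best[u], plane[ii, jj])
      if (cand > best[v]) best[v] <- cand
    }
  }
  best[id(b)]
}

# exhaustive O(n^2) Hausdorff over surface point matrices
oracle_hausdorff <- function(A, B) {
  dAB <- max(apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2)))))
  dBA <- max(apply(B, 1, function(p) min(sqrt(colSums((t(A) - p)^2)))))
  max(dAB, dBA)
}

# two-tailed Student-t tail probability via the textbook incomplete-beta
# continued fraction (independent of stats::pt)
oracle_pt2 <- function(t, df) {
  betacf <- function(a, b, x) {
    qab <- a + b; qap <- a + 1; qam <- a - 1
    c <- 1; d <- 1 - qab * x / qap
    if (abs(d) < 1e-30) d <- 1e-30
    d <- 1 / d; h <- d
    for (m in 1:200) {
      m2 <- 2 * m
      aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
      d <- 1 + aa * d; if (abs(d) < 1e-30) d <- 1e-30
      c <- 1 + aa / c; if (abs(c) < 1e-30) c <- 1e-30
      d <- 1 / d; h <- h * d * c
      aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
      d <- 1 + aa * d; if (abs(d) < 1e-30) d <- 1e-30
      c <- 1 + aa / c; if (abs(c) < 1e-30) c <- 1e-30
      d <- 1 / d
      del <- d * c
      h <- h * del
      if (abs(del - 1) < 1e-12) break
    }
    h
  }
  betai <- function(a, b, x) {
    if (x <= 0) return(0)
    if (x >= 1) return(1)
    bt <- exp(lgamma(a + b) - lgamma(a) - lgamma(b) +
                a * log(x) + b * log(1 - x))
    if (x < (a + 1) / (a + b + 2)) bt * betacf(a, b, x) / a
    else 1 - bt * betacf(b, a, 1 - x) / b
  }
  betai(df / 2, 0.5, df / (df + t^2))
}

# enumeration count of voxel centres within a physical radius
oracle_ball_count <- function(radius_mm, spacing) {
  nr <- floor(radius_mm / spacing)
  g <- expand.grid(-nr[1]:nr[1], -nr[2]:nr[2], -nr[3]:nr[3])
  sum((g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
        (g[, 3] * spacing[3])^2 <= radius_mm^2 + 1e-9)
}

# two additive 2-D Gaussian bumps; returns the plane and the two centres
make_twin_blobs <- function(n = 40, h1 = 10, h2 = 8, sep = 20,
                            sigma = 4, angle = 0) {
  c1 <- c(n / 2 - sep / 2 * cos(angle), n / 2 - sep / 2 * sin(angle))
  c2 <- c(n / 2 + sep / 2 * cos(angle), n / 2 + sep / 2 * sin(angle))
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  d1 <- (ij$i - c1[1])^2 + (ij$j - c1[2])^2
  d2 <- (ij$i - c2[1])^2 + (ij$j - c2[2])^2
  plane <- matrix(h1 * exp(-d1 / (2 * sigma^2)) +
                    h2 * exp(-d2 / (2 * sigma^2)), n, n)
  list(plane = plane,
       p1 = round(c1), p2 = round(c2))
}

# wrap a matrix as a minimal mip_image (unit plane spacing)
as_mip <- function(plane, spacing2 = c(1, 1)) {
  structure(list(plane = plane, depth = array(1L, dim = dim(plane)),
                 axis = 3L, spacing2 = spacing2, spacing_axis = 1),
            class = "mip_image")
}

# a small blurred uniform sphere scene for shrink tests
make_sphere_scene <- function(n = 40, radius_vox = 9, suv = 10, bg = 0,
                              blur = 1) {
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  rho <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  truth <- rho <= radius_vox
  f <- array(bg, dim = c(n, n, n))
  f[truth] <- suv
  if (blur > 0) f <- mtvseg:::gauss_smooth(f, blur)
  vol <- suv_volume(f, c(2, 2, 2))
  list(vol = vol, truth = mask3d(truth, c(2, 2, 2)),
       seed = seed_voxel(rep(round(ctr), 3), vol))
}

expect_mask_equal <- function(a, b) {
  expect_identical(mtvseg:::mask_fg(a), mtvseg:::mask_fg(b))
}
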