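# Independent oracles used across the suite. These deliberately use
# different machinery from the implementation they check.

# Dense multivariate-normal log-density for the increment model, built
# directly from the mean vector and covariance matrix via determinant and
# solve() (no Cholesky shortcut shared with the implementation).
mvn_increment_oracle <- function(years, values, mu, sigma2, tau2) {
  d <- diff(values)
  delta <- diff(years)
  m <- length(d)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) S[i, j] <- sigma2 * delta[i] + 2 * tau2
      if (abs(i - j) == 1) S[i, j] <- -tau2
    }
  }
  r <- d - mu * delta
  as.numeric(-0.5 * (m * log(2 * pi) + determinant(S)$modulus +
                       t(r) %*% solve(S) %*% r))
}

# Brute-force dip oracle: for each admissible mode position, the minimal
# band half-width admitting a unimodal piecewise-linear CDF is found as an
# exact linear program; the dip is the minimum over modes. Batched through
# the scipy/HiGHS solver (dip_oracle.py) for numerical robustness on
# degenerate vertices. Used on n <= 12 only.
dip_oracle_batch <- function(samples) {
  stopifnot(is.list(samples))
  infile <- tempfile(fileext = ".json")
  jsonlite::write_json(samples, infile, digits = NA)
  out <- system2("python",
                 c(testthat::test_path("dip_oracle.py")),
                 stdin = infile, stdout = TRUE)
  unlist(jsonlite::fromJSON(paste(out, collapse = "")))
}

# Single-sample LP oracle in R (boot::simplex). Retained as a secondary
# cross-check; simplex can sit on a degenerate vertex, so comparisons use
# the scipy batch oracle as primary.
dip_oracle <- function(x) {
  sx <- sort(x)
  n <- length(sx)
  w <- unique(sx)
  K <- length(w)
  cum <- cumsum(tabulate(match(sx, w), K))
  lo_b <- cum / n          # value must be >= lo_b - rho
  hi_b <- c(0, cum[-K]) / n  # value must be <= hi_b + rho

  # Build one LP: variables (rho, g_1..g_np, h_1..h_ns) for a split with
  # np prefix knots (convex, indices pi) and ns suffix knots (concave,
  # indices si). relax_last_l: waive prefix's final lower bound;
  # relax_first_u: waive suffix's first upper bound (atom at the mode).
  solve_split <- function(pi, si, relax_last_l = FALSE,
                          relax_first_u = FALSE, couple = TRUE) {
    np <- length(pi); ns <- length(si)
    nv <- 1 + np + ns
    A1 <- NULL; b1 <- NULL  # A1 x <= b1
    A2 <- NULL; b2 <- NULL  # A2 x >= b2
    row <- function(...) { r <- rep(0, nv); v <- list(...)
      for (k in seq(1, length(v), 2)) r[v[[k]]] <- v[[k + 1]]; r }
    gi <- function(j) 1 + j        # prefix var index
    hi_ <- function(j) 1 + np + j  # suffix var index
    for (j in seq_len(np)) {
      i <- pi[j]
      # g_j <= hi_b[i] + rho
      A1 <- rbind(A1, row(gi(j), 1, 1, -1)); b1 <- c(b1, hi_b[i])
      skip_l <- relax_last_l && j == np
      if (!skip_l) {
        A2 <- rbind(A2, row(gi(j), 1, 1, 1)); b2 <- c(b2, lo_b[i])
      }
    }
    for (j in seq_len(ns)) {
      i <- si[j]
      skip_u <- relax_first_u && j == 1
      if (!skip_u) {
        A1 <- rbind(A1, row(hi_(j), 1, 1, -1)); b1 <- c(b1, hi_b[i])
      }
      A1 <- rbind(A1, row(hi_(j), 1)); b1 <- c(b1, 1)  # h <= 1
      A2 <- rbind(A2, row(hi_(j), 1, 1, 1)); b2 <- c(b2, lo_b[i])
    }
    # monotone + convex prefix: slopes nondecreasing, first slope >= 0
    if (np >= 2) {
      A2 <- rbind(A2, row(gi(2), 1, gi(1), -1)); b2 <- c(b2, 0)
      if (np >= 3) {
        for (j in 1:(np - 2)) {
          d1 <- w[pi[j + 1]] - w[pi[j]]
          d2 <- w[pi[j + 2]] - w[pi[j + 1]]
          # (g_{j+2}-g_{j+1})/d2 - (g_{j+1}-g_j)/d1 >= 0
          A2 <- rbind(A2, row(gi(j + 2), 1 / d2,
                              gi(j + 1), -1 / d2 - 1 / d1,
                              gi(j), 1 / d1))
          b2 <- c(b2, 0)
        }
      }
    }
    # monotone + concave suffix: slopes nonincreasing, last slope >= 0
    if (ns >= 2) {
      A2 <- rbind(A2, row(hi_(ns), 1, hi_(ns - 1), -1)); b2 <- c(b2, 0)
      if (ns >= 3) {
        for (j in 1:(ns - 2)) {
          d1 <- w[si[j + 1]] - w[si[j]]
          d2 <- w[si[j + 2]] - w[si[j + 1]]
          # slope j+1..j+2 <= slope j..j+1
          A1 <- rbind(A1, row(hi_(j + 2), 1 / d2,
                              hi_(j + 1), -1 / d2 - 1 / d1,
                              hi_(j), 1 / d1))
          b1 <- c(b1, 0)
        }
      }
    }
    if (couple && np >= 1 && ns >= 1) {
      A1 <- rbind(A1, row(gi(np), 1, hi_(1), -1)); b1 <- c(b1, 0)
    }
    obj <- row(1, 1)
    fit <- tryCatch(
      boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    maxi = FALSE, eps = 1e-12),
      error = function(e) NULL)
    if (is.null(fit) || fit$solved != 1) return(Inf)
    fit$value
  }

  best <- Inf
  # mode in the gap after knot k (k = 0: all concave; k = K: all convex)
  for (k in 0:K) {
    pi <- if (k >= 1) 1:k else integer(0)
    si <- if (k < K) (k + 1):K else integer(0)
    best <- min(best, solve_split(pi, si))
  }
  # mode with an atom at knot m: knot m appears on both sides, inner
  # bounds waived
  for (m in 1:K) {
    best <- min(best, solve_split(1:m, m:K, relax_last_l = TRUE,
                                  relax_first_u = TRUE))
  }
  best
}

# Spherical-excess area of a polygon on a sphere of radius R_km, via
# l'Huilier's formula on a fan triangulation (independent of geosphere).
spherical_polygon_area_km2 <- function(lat, lon, R_km = 6371) {
  to_xyz <- function(lat, lon) {
    la <- lat * pi / 180; lo <- lon * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  ang <- function(a, b) {
    2 * asin(pmin(1, sqrt(sum((a - b)^2)) / 2))
  }
  tri_area <- function(a, b, c) {
    A <- ang(b, c); B <- ang(a, c); C <- ang(a, b)
    s <- (A + B + C) / 2
    t <- sqrt(max(0, tan(s / 2) * tan((s - A) / 2) * tan((s - B) / 2) *
                    tan((s - C) / 2)))
    4 * atan(t)
  }
  pts <- lapply(seq_along(lat), function(i) to_xyz(lat[i], lon[i]))
  total <- 0
  for (i in 2:(length(pts) - 1)) {
    total <- total + tri_area(pts[[1]], pts[[i]], pts[[i + 1]])
  }
  total * R_km^2
}

# Shared-path phylogenetic correlation by explicit root-to-tip traversal
# (independent of ape::vcv).
phylo_corr_bruteforce <- function(tree) {
  m <- length(tree$tip.label)
  root <- m + 1L
  # path of edges from root to each node
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_nodes <- function(tip) {
    nodes <- integer(0)
    nd <- tip
    while (nd != root) {
      nodes <- c(nodes, nd)
      nd <- parent[nd]
    }
    nodes
  }
  paths <- lapply(seq_len(m), path_nodes)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(elen[shared])
    }
  }
  C <- V / max(diag(V))
  diag(C) <- 1
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

# Enumerate all multisets of a given size from a value grid (for the
# exhaustive dip comparison).
multisets_from_grid <- function(grid, size) {
  combs <- utils::combn(length(grid) + size - 1, size)
  apply(combs, 2, function(cc) grid[cc - seq_len(size) + 1])
}
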