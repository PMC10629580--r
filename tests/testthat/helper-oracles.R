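# Independent oracle implementations used across tests. These deliberately
# avoid the code paths they check.

# Closed-form constant-rate reconstructed-process log-likelihood with
# sampling fraction f (p0/p1 parameterization), conditioned on crown
# survival unless stated otherwise. No quadrature anywhere.
nee_loglik <- function(bt, lam, mu, f, conditioning = "crown_survival") {
  r <- lam - mu
  D <- function(t) f * lam + (lam * (1 - f) - mu) * exp(-r * t)
  p0 <- function(t) 1 - f * r / D(t)
  p1 <- function(t) f * r^2 * exp(-r * t) / D(t)^2
  t1 <- bt[1]
  ll <- length(bt) * log(lam) + 2 * log(p1(t1)) + sum(log(p1(bt[-1])))
  if (conditioning == "crown_survival") ll <- ll - 2 * log(1 - p0(t1))
  ll
}

# Brute-force root-to-tip traversal: internal node ages as (max tip depth
# minus node depth), recursing over the edge table directly.
bt_oracle <- function(phy) {
  n <- length(phy$tip.label)
  depth <- numeric(n + phy$Nnode)
  done <- rep(FALSE, n + phy$Nnode)
  done[n + 1] <- TRUE
  # walk down from the root repeatedly until all depths are set
  while (!all(done[phy$edge[, 2]])) {
    for (i in seq_len(nrow(phy$edge))) {
      p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
      if (done[p] && !done[ch]) {
        depth[ch] <- depth[p] + phy$edge.length[i]
        done[ch] <- TRUE
      }
    }
  }
  h <- max(depth[1:n])
  sort(h - depth[(n + 2):(n + phy$Nnode)], decreasing = TRUE)  # non-root
}

# Brute-force LTT: count edges whose age interval straddles each query age.
ltt_oracle <- function(phy, grid) {
  n <- length(phy$tip.label)
  depth <- numeric(n + phy$Nnode)
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(ord$edge)))
    depth[ord$edge[i, 2]] <- depth[ord$edge[i, 1]] + ord$edge.length[i]
  h <- max(depth[1:n])
  age_top <- h - depth[phy$edge[, 1]]    # older end of each edge
  age_bot <- h - depth[phy$edge[, 2]]    # younger end
  eps <- 1e-9 * max(h, 1)
  vapply(grid, function(a) {
    if (a >= h - eps) return(2L)
    sum(age_top > a + eps & age_bot <= a + eps)
  }, integer(1))
}

# Definitional DCCA sums, coded independently (explicit lm detrending).
dcca_oracle <- function(x, y, box) {
  X <- cumsum(x - mean(x)); Y <- cumsum(y - mean(y))
  n <- length(x)
  fx <- fy <- fxy <- c()
  for (b in 1:(n - box + 1)) {
    ix <- b:(b + box - 1)
    t <- seq_along(ix)
    rx <- stats::resid(stats::lm(X[ix] ~ t))
    ry <- stats::resid(stats::lm(Y[ix] ~ t))
    fx <- c(fx, mean(rx^2)); fy <- c(fy, mean(ry^2)); fxy <- c(fxy, mean(rx * ry))
  }
  mean(fxy) / sqrt(mean(fx) * mean(fy))
}

# Hand path-walk equal-splits oracle.
es_oracle <- function(phy) {
  n <- length(phy$tip.label)
  out <- numeric(n)
  for (tip in 1:n) {
    node <- tip; j <- 0; acc <- 0
    repeat {
      row <- which(phy$edge[, 2] == node)
      if (length(row) == 0) break
      acc <- acc + phy$edge.length[row] / 2^j
      j <- j + 1
      node <- phy$edge[row, 1]
    }
    out[tip] <- acc
  }
  stats::setNames(out, phy$tip.label)
}

# Iterated running-median-of-3 with endpoint copy (convergent plain 3R
# smoother; agrees with the compound smoother on series without 2-flats).
runmed3_oracle <- function(v) {
  repeat {
    w <- v
    for (i in 2:(length(v) - 1)) w[i] <- stats::median(v[(i - 1):(i + 1)])
    if (all(w == v)) return(w)
    v <- w
  }
}

# A random ultrametric test tree of n tips scaled to a given crown age.
rand_tree <- function(n, crown = 20, f = 1) {
  phy <- ape::rcoal(n)
  phy$edge.length <- phy$edge.length /
    max(ape::node.depth.edgelength(phy)) * crown
  time_tree(phy, sampling_fraction = f)
}
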