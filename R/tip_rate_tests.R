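#' Equal-splits statistic and DR tip-rate proxy
#'
#' For each tip, `ES` is the weighted sum of branch lengths along the
#' tip-to-root path, the weight halving at each step toward the root
#' (tip edge weight 1, its parent edge 1/2, ...). A root (stem) edge, when
#' present, is included as the last path segment. `DR = 1/ES` is the
#' standard inverse-equal-splits tip speciation-rate proxy.
#'
#' @param tree a [time_tree()] (any rooted binary `phylo` works).
#' @return data frame with columns `species`, `ES`, `DR` (rows in tip
#'   order).
#' @export
es_statistic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  root <- n + 1L
  es <- numeric(n)
  stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  for (tip in seq_len(n)) {
    node <- tip; w <- 1; acc <- 0
    while (node != root) {
      acc <- acc + w * plen[node]
      node <- parent[node]
      w <- w / 2
    }
    es[tip] <- acc + w * stem
  }
  data.frame(species = tree$tip.label, ES = es, DR = 1 / es)
}

# Simulate Brownian-motion tip values on a tree: independent normal
# increments on each edge, accumulated root to tips. Returns tips x nsim.
sim_bm_tips <- function(tree, sigma2 = 1, root_state = 0, nsim = 1L) {
  n <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(0, n + tree$Nnode, nsim)
  states[n + 1L, ] <- root_state
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    states[ch, ] <- states[p, ] +
      stats::rnorm(nsim, 0, sqrt(sigma2 * ord$edge.length[i]))
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# ML estimate of the BM rate and root state for a continuous trait
# (closed form via GLS with the shared-path-length covariance).
bm_ml <- function(tree, x) {
  C <- ape::vcv.phylo(tree)
  x <- x[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, length(x))
  mu <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  s2 <- as.numeric(t(x - mu) %*% Ci %*% (x - mu)) / length(x)
  list(sigma2 = s2, root = mu)
}

#' Es-Sim test: tip-rate association with a continuous trait
#'
#' The observed statistic is the Pearson correlation between the trait and
#' `log(DR)`. The null distribution is the same statistic computed on
#' `n_sim` Brownian-motion simulations of the trait along the tree, with
#' the BM rate estimated from the observed trait by maximum likelihood.
#' Two-tailed p-value with the small-sample `(1+k)/(1+n)` estimator.
#'
#' @param tree a [time_tree()].
#' @param trait named numeric vector (names = tip labels) or vector in tip
#'   order; must vary.
#' @param n_sim number of BM simulations (>= 100).
#' @param seed optional RNG seed for reproducibility.
#' @return list of class `tip_test`: `statistic`, `p_value`, `n_sim`.
#' @export
essim_test <- function(tree, trait, n_sim = 1000L, seed = NULL) {
  n <- length(tree$tip.label)
  trait <- align_trait(trait, tree)
  if (stats::sd(trait) == 0) stop("trait is constant")
  if (n_sim < 100L) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  logdr <- log(es_statistic(tree)$DR)
  obs <- stats::cor(trait, logdr)
  ml <- bm_ml(tree, stats::setNames(trait, tree$tip.label))
  sims <- sim_bm_tips(tree, sigma2 = ml$sigma2, root_state = ml$root,
                      nsim = n_sim)
  null_stats <- as.numeric(stats::cor(sims, logdr))
  p <- (1 + sum(abs(null_stats) >= abs(obs))) / (1 + n_sim)
  structure(list(statistic = c(pearson_r = obs), p_value = p,
                 n_sim = n_sim, tail = "two-tailed vs BM null"),
            class = "tip_test")
}

#' @export
print.tip_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%s)\n", names(x$statistic)[1],
              x$statistic[1], x$p_value,
              if (!is.null(x$n_sim)) paste(x$n_sim, "simulations")
              else paste(x$n_perm, "permutations")))
  invisible(x)
}

align_trait <- function(trait, tree) {
  if (!is.null(names(trait))) {
    miss <- setdiff(tree$tip.label, names(trait))
    if (length(miss)) stop("trait missing for tips: ", paste(miss, collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    stop("unnamed trait must have one value per tip")
  }
  unname(trait)
}

#' STRAPP-style structured rate permutation test
#'
#' Tests whether tip speciation rates are associated with a trait while
#' respecting the block structure of rate regimes: each regime keeps its
#' tip set, and the regimes' rate values are shuffled among regimes. Rates
#' enter at regime resolution (every tip carries its regime's mean tip
#' rate, including in the observed statistic), which makes the statistic
#' exactly permutation-invariant when there is a single regime. This is a
#' structure-preserving simplification of posterior-shift-configuration
#' STRAPP that requires no Bayesian rate machinery.
#'
#' @param tips data frame with columns `tip_rate` (> 0) and `regime`
#'   (integer/factor partition labels).
#' @param trait per-tip trait: numeric for `"spearman"`, two-level for
#'   `"mann_whitney"`, categorical for `"kruskal_wallis"`.
#' @param stat test statistic to use.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return list of class `tip_test`: `statistic`, `p_value`, `n_perm`.
#' @export
strapp_test <- function(tips, trait,
                        stat = c("spearman", "mann_whitney", "kruskal_wallis"),
                        n_perm = 1000L, seed = NULL) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(tips), all(c("tip_rate", "regime") %in% names(tips)))
  if (any(tips$tip_rate <= 0)) stop("tip rates must be > 0")
  if (length(trait) != nrow(tips)) stop("trait must have one value per tip")
  if (!is.null(seed)) set.seed(seed)
  regime <- as.integer(factor(tips$regime))
  k <- max(regime)
  rmeans <- as.numeric(tapply(tips$tip_rate, regime, mean))
  stat_fun <- switch(stat,
    spearman = function(r) stats::cor(r, as.numeric(trait), method = "spearman"),
    mann_whitney = {
      g <- factor(trait)
      if (nlevels(g) != 2L) stop("mann_whitney requires a two-level trait")
      i1 <- g == levels(g)[1L]
      n1 <- sum(i1); n2 <- sum(!i1)
      function(r) sum(rank(r)[i1]) - n1 * (n1 + 1) / 2 - n1 * n2 / 2
    },
    kruskal_wallis = {
      g <- factor(trait)
      if (nlevels(g) < 2L) stop("kruskal_wallis requires >= 2 trait levels")
      function(r) unname(stats::kruskal.test(r, g)$statistic)
    })
  rates_for <- function(perm) rmeans[perm][regime]
  if (k < 2L) {
    # regime-resolution rates are constant: statistic degenerate
    obs <- suppressWarnings(stat_fun(rates_for(seq_len(k))))
    warning("single rate regime: statistic is permutation-invariant, p = 1")
    return(structure(list(statistic = stats::setNames(obs, stat), p_value = 1,
                          n_perm = n_perm, tail = "invariant"),
                     class = "tip_test"))
  }
  obs <- stat_fun(rates_for(seq_len(k)))
  two_tailed <- stat != "kruskal_wallis"
  perm_stats <- vapply(seq_len(n_perm),
                       function(i) stat_fun(rates_for(sample.int(k))),
                       numeric(1))
  exceed <- if (two_tailed) sum(abs(perm_stats) >= abs(obs))
            else sum(perm_stats >= obs)
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(statistic = stats::setNames(obs, stat), p_value = p,
                 n_perm = n_perm,
                 tail = if (two_tailed) "two-tailed" else "upper"),
            class = "tip_test")
}

# Fritz-Purvis d: estimate nodal values by post-order daughter averaging,
# then sum the absolute sister differences over internal nodes. Returns a
# closure with the traversal precomputed, since calibration loops evaluate
# d on many permuted/simulated states of the same tree.
d_sum_maker <- function(tree) {
  n <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  parents <- ord$edge[, 1L]
  # bottom-up node order: a node's last appearance as a parent comes after
  # every edge in its subtree
  nodes <- rev(unique(rev(parents)))
  kids <- split(ord$edge[, 2L], parents)
  if (any(lengths(kids) != 2L)) stop("tree must be binary")
  ch1 <- vapply(as.character(nodes), function(k) kids[[k]][1L], integer(1))
  ch2 <- vapply(as.character(nodes), function(k) kids[[k]][2L], integer(1))
  function(states) {
    val <- numeric(n + tree$Nnode)
    val[seq_len(n)] <- states
    dsum <- 0
    for (i in seq_along(nodes)) {
      a <- val[ch1[i]]; b <- val[ch2[i]]
      val[nodes[i]] <- (a + b) / 2
      dsum <- dsum + abs(a - b)
    }
    dsum
  }
}

#' D statistic of phylogenetic signal in a binary trait
#'
#' Fritz-Purvis D: the observed sum of sister-clade differences `d_obs` is
#' scaled between its expectation under random shuffling of tip states
#' (`D = 1`) and under threshold-discretised Brownian motion at the
#' observed prevalence (`D = 0`); `D < 0` indicates stronger clumping than
#' Brownian evolution.
#'
#' @param tree a [time_tree()].
#' @param trait binary (0/1, logical, or two-level) per-tip trait, named or
#'   in tip order; both states must be present.
#' @param n_perm random shuffles for the `D = 1` reference (>= 100).
#' @param n_sim Brownian threshold simulations for the `D = 0` reference
#'   (>= 100).
#' @param seed optional RNG seed.
#' @return list of class `d_result`: `D`, `d_obs`, `mean_d_random`,
#'   `mean_d_bm`, `prevalence`.
#' @export
d_statistic <- function(tree, trait, n_perm = 1000L, n_sim = 1000L,
                        seed = NULL) {
  states <- align_trait(trait, tree)
  states <- as.numeric(as.integer(factor(states)) - 1L)
  if (length(unique(states)) < 2L) stop("trait is monomorphic")
  if (n_perm < 100L || n_sim < 100L) stop("n_perm and n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  n1 <- sum(states == 1)
  d_fun <- d_sum_maker(tree)
  d_obs <- d_fun(states)
  d_rand <- vapply(seq_len(n_perm),
                   function(i) d_fun(sample(states)), numeric(1))
  sims <- sim_bm_tips(tree, sigma2 = 1, nsim = n_sim)
  d_bm <- vapply(seq_len(n_sim), function(j) {
    x <- sims[, j]
    # top-n1 tips by the latent value get state 1: exact observed prevalence
    s <- numeric(n); s[order(x, decreasing = TRUE)[seq_len(n1)]] <- 1
    d_fun(s)
  }, numeric(1))
  D <- (d_obs - mean(d_bm)) / (mean(d_rand) - mean(d_bm))
  structure(list(D = D, d_obs = d_obs, mean_d_random = mean(d_rand),
                 mean_d_bm = mean(d_bm), prevalence = n1 / n,
                 n_perm = n_perm, n_sim = n_sim),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D = %.3f (d_obs %.3f; random ref %.3f; BM ref %.3f; prevalence %.2f)\n",
              x$D, x$d_obs, x$mean_d_random, x$mean_d_bm, x$prevalence))
  invisible(x)
}

#' Classify species as tropical from occurrence records
#'
#' Strict-majority rule: a species is tropical if more than half of its
#' occurrence localities qualify - by latitude (within +/-23.5 degrees of
#' the equator, boundary counted as inside) or by temperature (locality
#' mean temperature above 18 C). Exactly half qualifying is nontropical.
#'
#' @param occurrences data frame with columns `species`, `lon`, `lat`, and
#'   `mean_temp_c` when `mode = "temperature"`.
#' @param mode `"latitude"` or `"temperature"`.
#' @param lat_band half-width of the tropical latitude band (degrees).
#' @param temp_threshold temperature cutoff in degrees C.
#' @return named logical vector (TRUE = tropical), one entry per species
#'   with at least one occurrence.
#' @export
classify_tropical <- function(occurrences, mode = c("latitude", "temperature"),
                              lat_band = 23.5, temp_threshold = 18) {
  mode <- match.arg(mode)
  stopifnot(all(c("species", "lat") %in% names(occurrences)))
  if (mode == "temperature" && !"mean_temp_c" %in% names(occurrences))
    stop("temperature mode requires a `mean_temp_c` column")
  qual <- if (mode == "latitude") abs(occurrences$lat) <= lat_band
          else occurrences$mean_temp_c > temp_threshold
  frac <- tapply(qual, occurrences$species, mean)
  out <- frac > 0.5
  stats::setNames(as.logical(out), names(frac))
}
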