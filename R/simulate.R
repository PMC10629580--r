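#' Simulate a paleoclimate proxy scenario
#'
#' Generates a proxy curve emulating a protracted monotone climate trend
#' (e.g. Cenozoic cooling) with superimposed periodic oscillation and
#' observational noise: a linear trend from `start` at the oldest age to
#' `end` at the present, plus `amplitude * sin(2*pi*age/period)` and
#' i.i.d. Gaussian noise. Deterministic given `seed`; with zero amplitude
#' and noise it is exactly the linear trend.
#'
#' @param span curve span in My (> 0); ages run 0..span.
#' @param start proxy value at the oldest age (`span` Mya).
#' @param end proxy value at the present (age 0).
#' @param amplitude oscillation amplitude (proxy units).
#' @param period oscillation period (My).
#' @param noise_sd sd of additive Gaussian noise (>= 0).
#' @param step grid step (My, > 0).
#' @param seed RNG seed.
#' @param unit unit tag for the resulting series.
#' @return a [paleo_series()].
#' @export
simulate_climate <- function(span = 65, start = 4, end = 0.5, amplitude = 1.5,
                             period = 18, noise_sd = 0.15, step = 0.5,
                             seed = 1L, unit = "proxy") {
  stopifnot(span > 0, step > 0, noise_sd >= 0)
  set.seed(seed)
  age <- seq(0, span, by = step)
  v <- end + (start - end) * age / span
  if (amplitude != 0) v <- v + amplitude * sin(2 * pi * age / period)
  if (noise_sd > 0) v <- v + stats::rnorm(length(age), 0, noise_sd)
  paleo_series(age, v, unit = unit)
}

#' Simulate a reconstructed birth-death tree with incomplete sampling
#'
#' Forward birth-death simulation from two crown lineages under
#' time-varying speciation/extinction [rate_spec()]s, using thinning
#' (piecewise constant upper bound on the total rate per 1-My window,
#' rejection by the true rates). Extinct lineages are pruned, extant tips
#' are subsampled binomially with probability `f`, and the whole replicate
#' is rejected and redrawn until the sampled tip count falls within
#' `[min_tips, max_tips]` (and, if `condition_on_crown`, until both crown
#' lineages retain a sampled descendant, matching the crown-survival
#' conditioning of the likelihood).
#'
#' @param speciation speciation [rate_spec()].
#' @param extinction extinction [rate_spec()] or `NULL`.
#' @param crown_ag crown age in My.
#' @param f sampling fraction in (0, 1].
#' @param min_tips,max_tips accepted range of sampled tip counts.
#' @param condition_on_crown require both crown lineages sampled (default
#'   TRUE; turn off for unconditional branching-process checks).
#' @param seed RNG seed.
#' @param max_lineages abort a replicate whose standing lineage count
#'   exceeds this (default 1e5).
#' @param max_rejects error after this many rejected replicates.
#' @param rate_grid_step age step (My) for the reported true rate curve.
#' @return list with `tree` (a [time_tree()], or `NULL` if the accepted
#'   replicate had < 2 sampled tips - only possible when `min_tips < 2`),
#'   `n_tips` (sampled tip count), `true_lambda` (data frame `age`,
#'   `lambda` of the generating speciation curve), `n_rejected`.
#' @export
simulate_bd_tree <- function(speciation, extinction = NULL, crown_ag = 60,
                             f = 1, min_tips = 2L, max_tips = 100000L,
                             condition_on_crown = TRUE, seed = 1L,
                             max_lineages = 1e5, max_rejects = 1000L,
                             rate_grid_step = 0.5) {
  stopifnot(inherits(speciation, "rate_spec"), crown_ag > 0, f > 0, f <= 1)
  set.seed(seed)
  lam_f <- function(age) rate_at(speciation, age)
  mu_f <- if (is.null(extinction)) function(age) rep(0, length(age))
          else function(age) rate_at(extinction, age)
  # per-1-My-window upper bounds on lambda + mu (1.1 x max on a fine subgrid)
  w_edges <- seq(0, crown_ag, by = 1)
  if (w_edges[length(w_edges)] < crown_ag) w_edges <- c(w_edges, crown_ag)
  bounds <- vapply(seq_len(length(w_edges) - 1L), function(i) {
    sub <- seq(w_edges[i], w_edges[i + 1L], length.out = 21L)
    1.1 * max(lam_f(crown_ag - sub) + mu_f(crown_ag - sub))
  }, numeric(1))

  n_rejected <- 0L
  repeat {
    rep_out <- sim_bd_once(lam_f, mu_f, crown_ag, f, w_edges, bounds,
                           max_lineages)
    ok <- !is.null(rep_out) &&
      rep_out$n_sampled >= min_tips && rep_out$n_sampled <= max_tips &&
      (!condition_on_crown || isTRUE(rep_out$crown_ok))
    if (ok) break
    n_rejected <- n_rejected + 1L
    if (n_rejected > max_rejects)
      stop("more than ", max_rejects, " rejected replicates; ",
           "check rates / tip-count window")
  }
  ages <- seq(0, crown_ag, by = rate_grid_step)
  list(tree = if (!is.null(rep_out$phy))
         time_tree(rep_out$phy, sampling_fraction = f) else NULL,
       n_tips = rep_out$n_sampled,
       true_lambda = data.frame(age = ages, lambda = lam_f(ages)),
       n_rejected = n_rejected)
}

# One forward pass. Time tau runs 0 (crown) -> crown_ag (present);
# age = crown_ag - tau. Returns NULL if the lineage cap was hit.
sim_bd_once <- function(lam_f, mu_f, crown_ag, f, w_edges, bounds,
                        max_lineages) {
  parent <- c(NA_integer_, NA_integer_)   # two crown lineages
  birth <- c(0, 0)
  death <- c(NA_real_, NA_real_)
  events <- list(integer(0), integer(0))  # child lineage ids, in time order
  etimes <- list(numeric(0), numeric(0))
  alive <- c(1L, 2L)
  tau <- 0
  w <- 1L
  n_win <- length(bounds)
  repeat {
    if (length(alive) == 0L) break
    if (length(alive) > max_lineages) return(NULL)
    B <- bounds[w]
    dt <- stats::rexp(1L, rate = length(alive) * B)
    if (tau + dt > w_edges[w + 1L]) {
      tau <- w_edges[w + 1L]
      if (w == n_win) break
      w <- w + 1L
      next
    }
    tau <- tau + dt
    lin <- alive[sample.int(length(alive), 1L)]
    age <- crown_ag - tau
    u <- stats::runif(1L)
    la <- lam_f(age); mu <- mu_f(age)
    if (u < la / B) {
      id <- length(parent) + 1L
      parent[id] <- lin; birth[id] <- tau; death[id] <- NA_real_
      events[[id]] <- integer(0); etimes[[id]] <- numeric(0)
      events[[lin]] <- c(events[[lin]], id)
      etimes[[lin]] <- c(etimes[[lin]], tau)
      alive <- c(alive, id)
    } else if (u < (la + mu) / B) {
      death[lin] <- tau
      alive <- setdiff(alive, lin)
    }
  }
  extant <- which(is.na(death))
  sampled <- extant[stats::runif(length(extant)) < f]
  n_sampled <- length(sampled)
  if (n_sampled < 2L)
    return(list(phy = NULL, n_sampled = n_sampled, crown_ok = FALSE))
  # crown side of each lineage: follow parents back to lineage 1 or 2
  side <- function(id) { while (!is.na(parent[id])) id <- parent[id]; id }
  crown_ok <- length(unique(vapply(sampled, side, integer(1)))) == 2L

  newick <- function(lin, from) {
    ev <- etimes[[lin]]; ch <- events[[lin]]
    nxt <- which(ev > from + 1e-12)
    if (length(nxt) == 0L) {
      end <- if (is.na(death[lin])) crown_ag else death[lin]
      sprintf("t%d:%.10g", lin, end - from)
    } else {
      i <- nxt[1L]
      sprintf("(%s,%s):%.10g", newick(lin, ev[i]), newick(ch[i], ev[i]),
              ev[i] - from)
    }
  }
  txt <- sprintf("(%s,%s);", newick(1L, 0), newick(2L, 0))
  phy <- ape::read.tree(text = txt)
  keep <- paste0("t", sampled)
  phy <- ape::drop.tip(phy, setdiff(phy$tip.label, keep))
  if (is.null(phy) || length(phy$tip.label) < 2L)
    return(list(phy = NULL, n_sampled = n_sampled, crown_ok = FALSE))
  list(phy = phy, n_sampled = n_sampled, crown_ok = crown_ok)
}

#' Simulate a posterior rate-through-time ensemble around a true curve
#'
#' Each posterior sample is the true curve multiplied entrywise by
#' i.i.d. lognormal noise with mean 1 (`meanlog = -noise_sd^2/2`). With
#' zero noise every row equals the truth; rates stay positive.
#'
#' @param ages age grid.
#' @param true_curve true speciation rates on `ages` (> 0).
#' @param n_samples number of posterior rows.
#' @param noise_sd sdlog of the multiplicative noise (>= 0).
#' @param seed RNG seed.
#' @return an [rtt_ensemble()].
#' @export
simulate_rtt_ensemble <- function(ages, true_curve, n_samples = 100L,
                                  noise_sd = 0.1, seed = 1L) {
  stopifnot(length(ages) == length(true_curve), noise_sd >= 0, n_samples >= 1)
  set.seed(seed)
  m <- length(ages)
  noise <- if (noise_sd == 0) matrix(1, n_samples, m)
           else matrix(stats::rlnorm(n_samples * m, -noise_sd^2 / 2, noise_sd),
                       n_samples, m)
  rtt_ensemble(ages, sweep(noise, 2L, true_curve, `*`))
}

#' Simulate per-tip traits on a tree
#'
#' \describe{
#'   \item{bm}{Brownian motion with rate `sigma2` from root state 0.}
#'   \item{threshold_binary}{BM thresholded so that exactly
#'     `round(n * prevalence)` tips (the largest latent values) are in
#'     state 1.}
#'   \item{regime_rates}{paints `k` rate regimes on clades: `k - 1` random
#'     internal nodes define regimes (most recent enclosing painted node
#'     wins), the root background is regime `k`; each regime gets a
#'     distinct rate.}
#' }
#'
#' @param tree a [time_tree()].
#' @param kind `"bm"`, `"threshold_binary"` or `"regime_rates"`.
#' @param sigma2 BM rate (bm / threshold_binary).
#' @param prevalence target fraction of state-1 tips, strictly in (0, 1).
#' @param k number of regimes (regime_rates).
#' @param regime_rates optional numeric vector of `k` regime rates; by
#'   default lognormal draws around `base_rate`.
#' @param base_rate median regime rate for the default draws.
#' @param rate_sdlog spread (sdlog) of the default regime-rate draws.
#' @param seed RNG seed.
#' @return for `bm` a named numeric vector; for `threshold_binary` a named
#'   0/1 vector; for `regime_rates` a list with `tip_rate` (named),
#'   `regime` (named integer labels), `rates` (per-regime).
#' @export
simulate_traits <- function(tree, kind = c("bm", "threshold_binary",
                                           "regime_rates"),
                            sigma2 = 1, prevalence = 0.5, k = 3L,
                            regime_rates = NULL, base_rate = 0.1,
                            rate_sdlog = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  n <- length(tree$tip.label)
  if (kind == "bm") {
    x <- sim_bm_tips(tree, sigma2 = sigma2, nsim = 1L)[, 1L]
    return(x)
  }
  if (kind == "threshold_binary") {
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must be strictly between 0 and 1")
    x <- sim_bm_tips(tree, sigma2 = sigma2, nsim = 1L)[, 1L]
    n1 <- max(1L, min(n - 1L, round(n * prevalence)))
    s <- stats::setNames(numeric(n), names(x))
    s[order(x, decreasing = TRUE)[seq_len(n1)]] <- 1
    return(s)
  }
  # regime_rates
  if (k < 1L) stop("k must be >= 1")
  regime <- stats::setNames(rep(k, n), tree$tip.label)
  if (k > 1L) {
    internal <- setdiff(seq_len(n + tree$Nnode), c(seq_len(n), n + 1L))
    picks <- sample(internal, min(k - 1L, length(internal)))
    # paint in random order; later (nested) picks overwrite: most recent wins
    depth <- node_depths(tree)
    picks <- picks[order(depth[picks])]
    for (j in seq_along(picks)) {
      tips_j <- ape::extract.clade(tree, picks[j])$tip.label
      regime[tips_j] <- j
    }
    regime <- stats::setNames(as.integer(factor(regime)), names(regime))
  }
  kk <- length(unique(regime))
  rates <- if (!is.null(regime_rates)) {
    if (length(regime_rates) < kk) stop("need at least ", kk, " regime rates")
    regime_rates[seq_len(kk)]
  } else base_rate * stats::rlnorm(kk, 0, rate_sdlog)
  list(tip_rate = stats::setNames(rates[regime], names(regime)),
       regime = regime, rates = rates)
}

#' Simulate clustered occurrence records
#'
#' Gaussian scatter of `n_per_species` records around each species'
#' bioregion center, with coordinates clipped to valid lon/lat ranges.
#'
#' @param species character vector of species ids.
#' @param region_centers data frame `bioregion`, `lon`, `lat`.
#' @param assignment optional named character vector species -> bioregion;
#'   by default regions are assigned uniformly at random.
#' @param spread_deg sd of the scatter in degrees.
#' @param n_per_species records per species (>= 1).
#' @param seed RNG seed.
#' @return data frame `species`, `lon`, `lat`, `bioregion` with exactly
#'   `length(species) * n_per_species` rows.
#' @export
simulate_occurrences <- function(species, region_centers, assignment = NULL,
                                 spread_deg = 2, n_per_species = 10L,
                                 seed = 1L) {
  stopifnot(n_per_species >= 1L,
            all(c("bioregion", "lon", "lat") %in% names(region_centers)))
  set.seed(seed)
  if (is.null(assignment)) {
    assignment <- stats::setNames(
      sample(region_centers$bioregion, length(species), replace = TRUE),
      species)
  }
  idx <- match(assignment[species], region_centers$bioregion)
  if (any(is.na(idx))) stop("assignment names a region without a center")
  sp <- rep(species, each = n_per_species)
  cx <- rep(region_centers$lon[idx], each = n_per_species)
  cy <- rep(region_centers$lat[idx], each = n_per_species)
  m <- length(sp)
  data.frame(species = sp,
             lon = pmin(180, pmax(-180, cx + stats::rnorm(m, 0, spread_deg))),
             lat = pmin(90, pmax(-90, cy + stats::rnorm(m, 0, spread_deg))),
             bioregion = rep(assignment[species], each = n_per_species),
             row.names = NULL)
}

#' Default seven-region centers for synthetic scenarios
#'
#' Rough continental centroids for the seven orchid bioregions, used only
#' by the synthetic occurrence generator.
#' @return data frame `bioregion`, `lon`, `lat`.
#' @export
default_region_centers <- function() {
  data.frame(
    bioregion = c("Africa", "Australia", "Eurasia", "North America",
                  "Neotropics", "Pacific", "Southeast Asia"),
    lon = c(22, 134, 60, -100, -60, -160, 105),
    lat = c(0, -25, 50, 45, -10, -15, 10))
}
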