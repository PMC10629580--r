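#' Keep only bioregion-endemic species
#'
#' @param assignment data frame with columns `species`, `bioregion`
#'   (repeated rows for species present in several regions).
#' @return data frame `species`, `bioregion` restricted to species present
#'   in exactly one region; warns if nothing is endemic.
#' @export
filter_endemics <- function(assignment) {
  stopifnot(all(c("species", "bioregion") %in% names(assignment)))
  a <- unique(assignment[, c("species", "bioregion")])
  n_reg <- table(a$species)
  keep <- names(n_reg)[n_reg == 1L]
  out <- a[a$species %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no species is endemic to a single bioregion")
  out
}

#' Gridded species richness and mean tip speciation rate
#'
#' Bins occurrence records into equal-angle lon/lat cells sized to a target
#' area at the equator, and reports per-cell species richness (distinct
#' species) and the unweighted mean tip rate of those species.
#'
#' @param occurrences data frame `species`, `lon`, `lat` (degrees; lon in
#'   \[-180, 180\], lat in \[-90, 90\]).
#' @param tip_rates named numeric vector of tip rates (> 0); occurrences of
#'   species without a rate are excluded (a message reports the count).
#' @param cell_area_km2 target cell area at the equator (default 200).
#' @return data frame `cell_id`, `lon`, `lat` (cell centers), `richness`,
#'   `mean_rate`.
#' @export
grid_summary <- function(occurrences, tip_rates, cell_area_km2 = 200) {
  stopifnot(all(c("species", "lon", "lat") %in% names(occurrences)))
  if (any(occurrences$lon < -180 | occurrences$lon > 180 |
          occurrences$lat < -90 | occurrences$lat > 90))
    stop("occurrence coordinates out of range")
  known <- occurrences$species %in% names(tip_rates)
  if (any(!known)) {
    message(sum(!known), " occurrence(s) excluded: species without a tip rate")
    occurrences <- occurrences[known, , drop = FALSE]
  }
  if (nrow(occurrences) == 0L) stop("no occurrences with tip rates")
  step <- sqrt(cell_area_km2) / 111.195   # degrees per cell side at equator
  ix <- floor(occurrences$lon / step)
  iy <- floor(occurrences$lat / step)
  key <- paste(ix, iy, sep = ":")
  cells <- split(occurrences$species, key)
  uniq_idx <- !duplicated(key)
  centers <- data.frame(key = key[uniq_idx],
                        lon = (ix[uniq_idx] + 0.5) * step,
                        lat = (iy[uniq_idx] + 0.5) * step)
  centers <- centers[order(centers$key), ]
  sp_sets <- lapply(cells, unique)
  data.frame(cell_id = names(cells),
             lon = centers$lon[match(names(cells), centers$key)],
             lat = centers$lat[match(names(cells), centers$key)],
             richness = lengths(sp_sets),
             mean_rate = vapply(sp_sets, function(s) mean(tip_rates[s]),
                                numeric(1)),
             row.names = NULL)
}

#' Pairwise correlation of per-region rate-through-time curves
#'
#' Pearson correlations between the mean speciation-rate curves of each
#' bioregion on a shared age grid.
#'
#' @param region_curves named list of numeric rate vectors, all on the same
#'   grid (equal lengths).
#' @return symmetric correlation matrix with unit diagonal; rows for
#'   regions with a constant (zero-variance) curve are `NA` with a warning.
#' @export
region_rtt_correlations <- function(region_curves) {
  if (length(region_curves) < 2L) stop("need at least 2 regions")
  lens <- lengths(region_curves)
  if (length(unique(lens)) != 1L) stop("curves must share one age grid")
  m <- do.call(cbind, region_curves)
  flat <- apply(m, 2L, stats::sd) == 0
  if (any(flat))
    warning("constant curve(s): ", paste(names(region_curves)[flat],
                                         collapse = ", "),
            " - correlations undefined (NA)")
  cc <- suppressWarnings(stats::cor(m))
  diag(cc) <- 1
  cc
}
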