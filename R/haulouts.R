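#' Generate haul-out sites, true counts, and a partial-coverage count survey
#'
#' Picks `n_sites` coastal land cells as haul-outs and allocates
#' `total_population` seals among them multinomially with Dirichlet-random
#' site weights (so site sizes vary, and small sites can draw a zero). The
#' survey emulates August moult counts: a random fraction
#' `survey_coverage` of all coastal cells is surveyed; a surveyed cell
#' records the number of seals hauled out there (zero if none) and a survey
#' year in 2008--2015, while unsurveyed cells carry `NA` -- a surveyed zero
#' is never conflated with "no survey effort".
#'
#' @param grid a [GridSpec-class].
#' @param n_sites number of haul-out sites (>= 1).
#' @param total_population total number of seals (>= `n_sites`).
#' @param survey_coverage fraction of coastal cells surveyed, in (0, 1].
#' @param seed integer seed.
#' @return a list with `haulouts` (data.frame `cell`, `true_count`) and
#'   `survey` (data.frame `cell`, `row`, `col`, `count`, `survey_year`;
#'   `count` and `survey_year` are `NA` for unsurveyed coastal cells).
#' @export
genHauloutsAndCounts <- function(grid, n_sites, total_population,
                                 survey_coverage = 0.8, seed = 1) {
  stopifnot(n_sites >= 1, total_population >= n_sites,
            survey_coverage > 0, survey_coverage <= 1)
  coast <- coastalLandCells(grid)
  if (length(coast) < n_sites)
    stop(sprintf("only %d coastal cells available for %d haul-out sites",
                 length(coast), n_sites))
  set.seed(seed)
  sites <- sort(sample(coast, n_sites))
  w <- stats::rgamma(n_sites, shape = 1.5)   # Dirichlet(1.5) weights
  counts <- as.numeric(stats::rmultinom(1, total_population, prob = w / sum(w)))

  n_surv <- max(1L, round(survey_coverage * length(coast)))
  surveyed <- if (survey_coverage >= 1) coast else sort(sample(coast, n_surv))
  site_count <- stats::setNames(counts, sites)
  cnt <- rep(NA_real_, length(coast))
  yr <- rep(NA_integer_, length(coast))
  is_surv <- coast %in% surveyed
  cnt[is_surv] <- 0
  hit <- is_surv & coast %in% sites
  cnt[hit] <- site_count[as.character(coast[hit])]
  yr[is_surv] <- sample(2008:2015, sum(is_surv), replace = TRUE)
  rc <- cellRowCol(grid, coast)
  survey <- data.frame(cell = coast, row = rc[, "row"], col = rc[, "col"],
                       count = cnt, survey_year = yr)
  list(haulouts = data.frame(cell = sites, true_count = counts),
       survey = survey)
}
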