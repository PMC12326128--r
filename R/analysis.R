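#' Empirical cumulative distribution of reaction times
#'
#' Proportion of RTs at or below each grid point. Anticipatory and
#' no-response trials are expected to be excluded upstream.
#'
#' @param rts numeric vector of valid RTs (>= 1 value, no NAs).
#' @param grid evaluation grid, ms (non-decreasing).
#' @return List of class `av_cdf`: `grid_ms`, `p` (non-decreasing, in
#'   `[0, 1]`), `n`.
#' @export
empirical_cdf <- function(rts, grid) {
  if (length(rts) < 1L || anyNA(rts)) {
    stop("empirical_cdf needs at least one valid RT and no NAs")
  }
  p <- vapply(grid, function(t) mean(rts <= t), numeric(1))
  structure(list(grid_ms = grid, p = p, n = length(rts)), class = "av_cdf")
}

#' Independent-race (Raab) model CDF
#'
#' Statistical-facilitation prediction for the bimodal condition under
#' channel independence: `P(t) = P_A(t) + P_V(t) - P_A(t) * P_V(t)`.
#'
#' @param cdf_a,cdf_v `av_cdf` objects on the same grid.
#' @return An `av_cdf` on the shared grid.
#' @export
raab_race_cdf <- function(cdf_a, cdf_v) {
  if (!isTRUE(all.equal(cdf_a$grid_ms, cdf_v$grid_ms))) {
    stop("raab_race_cdf: the two CDFs must share the same grid")
  }
  p <- cdf_a$p + cdf_v$p - cdf_a$p * cdf_v$p
  structure(list(grid_ms = cdf_a$grid_ms, p = p,
                 n = min(cdf_a$n, cdf_v$n)), class = "av_cdf")
}

# trapezoidal integral of max(0, upper - lower) over the shared grid
.area_between <- function(grid, upper, lower) {
  d <- pmax(0, upper - lower)
  sum(diff(grid) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Redundancy benefit area over the faster unisensory condition
#'
#' Area (probability x ms, trapezoidal) between an upper CDF (bimodal
#' condition, or the race model) and the pointwise-faster envelope of the two
#' unisensory CDFs, clamped at zero where the upper curve falls below the
#' envelope.
#'
#' @param cdf_upper `av_cdf` of the bimodal condition or race model.
#' @param cdf_a,cdf_v unisensory `av_cdf`s on the same grid.
#' @return Non-negative area.
#' @export
benefit_area <- function(cdf_upper, cdf_a, cdf_v) {
  if (!isTRUE(all.equal(cdf_upper$grid_ms, cdf_a$grid_ms)) ||
      !isTRUE(all.equal(cdf_upper$grid_ms, cdf_v$grid_ms))) {
    stop("benefit_area: all CDFs must share the same grid")
  }
  env <- pmax(cdf_a$p, cdf_v$p)
  .area_between(cdf_upper$grid_ms, cdf_upper$p, env)
}

#' Multisensory gain beyond the race model
#'
#' Area between the bimodal CDF and the independent-race prediction,
#' clamped at zero; strictly positive gain indicates a race-model violation
#' (integration beyond statistical facilitation).
#'
#' @param cdf_av bimodal `av_cdf`.
#' @param race_cdf race-model `av_cdf` on the same grid.
#' @return Non-negative area (probability x ms).
#' @export
multisensory_gain <- function(cdf_av, race_cdf) {
  if (!isTRUE(all.equal(cdf_av$grid_ms, race_cdf$grid_ms))) {
    stop("multisensory_gain: CDFs must share the same grid")
  }
  .area_between(cdf_av$grid_ms, cdf_av$p, race_cdf$p)
}

#' Pooled-percentile RT grid
#'
#' Standard grid for RT CDF comparisons: percentiles of the pooled sample
#' (5th to 100th in 5\% steps by default).
#'
#' @param ... RT vectors to pool.
#' @param probs percentile levels.
#' @return Numeric grid, ms.
#' @export
rt_quantile_grid <- function(..., probs = seq(0.05, 1, by = 0.05)) {
  pooled <- unlist(list(...), use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  unname(stats::quantile(pooled, probs = probs, type = 7))
}

#' Modality switch cost from trial records
#'
#' `mean(Sw RT) - mean(Rp RT)` within each unisensory modality, averaged over
#' the two modalities. Accepts the records of [run_rt_task()] (valid,
#' non-anticipatory responses are selected automatically) or any data frame
#' with `label` and `rt_ms`.
#'
#' @param records data frame with `label` (`RpA`, `SwA`, `RpV`, `SwV`, ...)
#'   and `rt_ms`; or an `av_rt_task`.
#' @return List: `cost_ms` (modality average), `cost_a_ms`, `cost_v_ms`.
#' @export
switch_cost <- function(records) {
  if (inherits(records, "av_rt_task")) records <- records$records
  if ("responded" %in% names(records)) {
    records <- records[records$responded, ]
  }
  if ("anticipatory" %in% names(records)) {
    records <- records[!records$anticipatory, ]
  }
  m <- function(lab) {
    x <- records$rt_ms[records$label == lab]
    if (length(x) == 0L) return(NA_real_)
    mean(x, na.rm = TRUE)
  }
  cost_a <- m("SwA") - m("RpA")
  cost_v <- m("SwV") - m("RpV")
  list(cost_ms = mean(c(cost_a, cost_v)), cost_a_ms = cost_a,
       cost_v_ms = cost_v)
}

#' Race-model analysis of a set of RT records
#'
#' Builds the A, V and AV empirical CDFs on a pooled-percentile grid,
#' the Raab race prediction, and the benefit/gain areas.
#'
#' @param records data frame with `modality` (`A`, `V`, `AV`), `rt_ms`,
#'   and optionally `responded` / `anticipatory` (used to filter); or an
#'   `av_rt_task`.
#' @param grid optional explicit grid, ms.
#' @return List of class `av_race`: the four `av_cdf`s (`cdf_a`, `cdf_v`,
#'   `cdf_av`, `cdf_race`), `gain` (AV vs race), `benefit_av` and
#'   `benefit_race` (vs the faster-unisensory envelope), the `grid_ms`,
#'   and the excluded-trial counts.
#' @export
race_analysis <- function(records, grid = NULL) {
  if (inherits(records, "av_rt_task")) records <- records$records
  n_total <- nrow(records)
  if ("responded" %in% names(records)) {
    records <- records[records$responded, ]
  }
  records <- records[!is.na(records$rt_ms), ]
  n_noresp <- n_total - nrow(records)
  if ("anticipatory" %in% names(records)) {
    n_antic <- sum(records$anticipatory)
    records <- records[!records$anticipatory, ]
  } else n_antic <- 0L
  rt_a <- records$rt_ms[records$modality == "A"]
  rt_v <- records$rt_ms[records$modality == "V"]
  rt_av <- records$rt_ms[records$modality == "AV"]
  if (length(rt_a) == 0L || length(rt_v) == 0L || length(rt_av) == 0L) {
    stop("race_analysis needs RTs in all three conditions (A, V, AV)")
  }
  if (is.null(grid)) grid <- rt_quantile_grid(rt_a, rt_v, rt_av)
  cdf_a <- empirical_cdf(rt_a, grid)
  cdf_v <- empirical_cdf(rt_v, grid)
  cdf_av <- empirical_cdf(rt_av, grid)
  cdf_race <- raab_race_cdf(cdf_a, cdf_v)
  structure(list(
    cdf_a = cdf_a, cdf_v = cdf_v, cdf_av = cdf_av, cdf_race = cdf_race,
    gain = multisensory_gain(cdf_av, cdf_race),
    benefit_av = benefit_area(cdf_av, cdf_a, cdf_v),
    benefit_race = benefit_area(cdf_race, cdf_a, cdf_v),
    grid_ms = grid, n_excluded_no_response = n_noresp,
    n_excluded_anticipatory = n_antic
  ), class = "av_race")
}
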