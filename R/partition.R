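#' Partition OS and PFS curves into three-state occupancy
#'
#' The partitioned survival model derives state membership directly from
#' the two survival curves at every time point: the progression-free
#' proportion is PFS(t), the post-progression proportion is
#' OS(t) - PFS(t), and the dead proportion is 1 - OS(t). PFS(t) must
#' never exceed OS(t); digitized curves commonly cross by a pixel's
#' worth of error, so an excess of at most `clamp_tol` is clamped down
#' to OS with a warning, while a larger excess is an error naming the
#' first offending time.
#'
#' @param os overall-survival `survival_curve`.
#' @param pfs progression-free-survival `survival_curve`.
#' @param grid evaluation time grid in years; defaults to a uniform
#'   weekly grid over `[0, horizon]`.
#' @param horizon model horizon in years (used only to build the default
#'   grid).
#' @param clamp_tol maximum tolerated PFS excess over OS treated as
#'   digitization noise (default 0.005).
#' @return a `state_occupancy` object: a data frame with columns
#'   `time`, `pf`, `pp`, `dead` summing to 1 at every grid point, with
#'   the source curves attached as attributes.
#' @export
#' @examples
#' occ <- partition(exp_curve(rate = 0.1), exp_curve(rate = 0.3), horizon = 5)
#' head(occ)
partition <- function(os, pfs, grid = NULL, horizon = 5, clamp_tol = 0.005) {
  stopifnot(inherits(os, "survival_curve"), inherits(pfs, "survival_curve"))
  if (is.null(grid)) grid <- weekly_grid(horizon)
  s_os <- evaluate(os, grid)
  s_pfs <- evaluate(pfs, grid)
  excess <- s_pfs - s_os
  if (any(excess > clamp_tol)) {
    t_bad <- grid[which(excess > clamp_tol)[1]]
    stop(sprintf(
      "PFS exceeds OS by more than %g (first at t = %.4f years): curves cross",
      clamp_tol, t_bad), call. = FALSE)
  }
  if (any(excess > 0)) {
    warning(sprintf(
      "PFS marginally exceeds OS at %d grid point(s) (max excess %.2g); clamped to OS",
      sum(excess > 0), max(excess)), call. = FALSE)
    # remember the clamp so downstream exact integrals see PFS <= OS too
    s_pfs <- pmin(s_pfs, s_os)
    pfs <- survival_curve("step", times = grid, probs = cummin(s_pfs),
                          label = pfs$label)
  }
  out <- data.frame(time = grid, pf = s_pfs, pp = s_os - s_pfs,
                    dead = 1 - s_os)
  structure(out, class = c("state_occupancy", "data.frame"),
            os = os, pfs = pfs)
}

#' Uniform weekly evaluation grid
#'
#' @param horizon horizon in years.
#' @param step grid step in years (default one week, 7/365.25).
#' @return numeric grid covering `[0, horizon]`, horizon included.
#' @export
weekly_grid <- function(horizon, step = weeks(1)) {
  stopifnot(horizon > 0, step > 0)
  g <- seq(0, horizon, by = step)
  if (g[length(g)] < horizon) g <- c(g, horizon)
  g
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat(sprintf("<state_occupancy: %d grid points over [0, %.3g] years>\n",
              nrow(x), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# Source curves attached by partition(); NULL when absent.
occ_pfs_curve <- function(occ) attr(occ, "pfs", exact = TRUE)
occ_os_curve <- function(occ) attr(occ, "os", exact = TRUE)
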