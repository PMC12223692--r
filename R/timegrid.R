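#' Construct a time grid
#'
#' @param edges strictly increasing right bin edges; the last edge is the
#'   horizon `E_max`.
#' @param start left edge of the first bin (default 0).
#' @return a validated [TimeGrid].
#' @export
timeGrid <- function(edges, start = 0) {
  new("TimeGrid", edges = as.numeric(edges), start = as.numeric(start))
}

#' Yearly time grid over a horizon
#'
#' Convenience constructor for yearly bins `(start, start+1], ...` up to
#' `horizon`.
#'
#' @param horizon the horizon `E_max` in years.
#' @param start left edge of the first bin (default 0).
#' @return a [TimeGrid].
#' @export
yearlyGrid <- function(horizon, start = 0)
  timeGrid(seq(floor(start) + 1, horizon), start = start)

#' @rdname TimeGrid-utils
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Time-grid utilities
#'
#' `nBins()` gives the number of within-horizon bins (the beyond-horizon
#' category is extra); `horizon()` the last edge; `binIndex()` maps times to
#' bin indices, with times above the horizon mapped to `nBins + 1` (the
#' beyond-horizon category) and times at or below `start` an error.
#'
#' @param x,grid a [TimeGrid].
#' @param t numeric vector of times.
#' @name TimeGrid-utils
#' @export
setMethod("nBins", "TimeGrid", function(x) length(x@edges))

#' @rdname TimeGrid-utils
#' @export
setGeneric("horizon", function(x) standardGeneric("horizon"))

#' @rdname TimeGrid-utils
#' @export
setMethod("horizon", "TimeGrid", function(x) x@edges[length(x@edges)])

#' @rdname TimeGrid-utils
#' @export
binIndex <- function(grid, t) {
  .stopIfNot(all(t > grid@start),
             "times at or below the grid start cannot be binned")
  # bin i is (edge_{i-1}, edge_i]; beyond-horizon times get nBins + 1
  idx <- findInterval(t, c(grid@start, grid@edges), left.open = TRUE,
                      rightmost.closed = FALSE)
  pmin(idx, length(grid@edges) + 1L)
}

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf("TimeGrid: %d bins on (%g, %g] plus beyond-horizon\n",
              length(object@edges), object@start, horizon(object)))
  invisible(object)
})

#' Construct a per-patient discrete distribution over time bins
#'
#' @param probs numeric matrix (or vector for one patient) with
#'   `nBins(grid) + 1` columns: one per bin plus the beyond-horizon mass.
#' @param grid the [TimeGrid].
#' @return a validated [DiscreteDistribution].
#' @export
discreteDistribution <- function(probs, grid) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  new("DiscreteDistribution", probs = probs, grid = grid)
}

setMethod("show", "DiscreteDistribution", function(object) {
  cat(sprintf("DiscreteDistribution: %d patients x %d bins (+beyond)\n",
              nrow(object@probs), nBins(object@grid)))
  invisible(object)
})

#' Cumulative event probability by time t
#'
#' Sums the mass of all bins completed at or before `t` (step-function
#' interpolation at bin right edges, matching the resolution of the discrete
#' likelihood). Non-decreasing in `t`; at the horizon it equals one minus
#' the beyond-horizon mass.
#'
#' @param dist a [DiscreteDistribution].
#' @param t a single evaluation time in `(0, E_max]`.
#' @return numeric vector of per-patient event probabilities.
#' @export
eventProbabilityBy <- function(dist, t) {
  grid <- dist@grid
  .stopIfNot(length(t) == 1L && t > 0 && t <= horizon(grid) + 1e-9,
             "t must lie in (0, E_max]")
  k <- sum(grid@edges <= t + 1e-9)
  if (k == 0L) return(rep(0, nrow(dist@probs)))
  rowSums(dist@probs[, seq_len(k), drop = FALSE])
}

#' Survival probabilities implied by a discrete distribution
#'
#' @param dist a [DiscreteDistribution].
#' @param t evaluation time in `(0, E_max]`.
#' @return per-patient `P(T > t)` under the step-function convention.
#' @export
survivalProbabilityAt <- function(dist, t) 1 - eventProbabilityBy(dist, t)
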