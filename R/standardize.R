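#' Fit a lane-standardization warp from internal migration standards
#'
#' Each gel lane carries internal migration standards of known identity. The
#' warp maps the lane's observed standard positions onto the shared reference
#' positions by a monotone piecewise-linear function with a knot per
#' standard: linear interpolation between knots, linear extrapolation from
#' the terminal segments, exactness at the knots. With the usual three
#' standards this gives two interior segments; the minimal monotone choice
#' given only the standards' positions.
#'
#' @param observed data.frame (`standard_id`, `observed_distance`) or named
#'   numeric vector of the lane's observed standard positions.
#' @param reference data.frame (`standard_id`, `reference_distance`) or
#'   named numeric vector of the shared reference positions.
#' @return A [WarpFunction-class].
#' @section Errors: fewer than 2 shared standard ids, co-migrating standards
#'   (duplicate observed distances), or observed order inconsistent with
#'   reference order (a gel inversion) all abort.
#' @examples
#' w <- fitWarp(c(S1 = 10, S2 = 20, S3 = 30), c(S1 = 10, S2 = 25, S3 = 30))
#' applyWarp(w, 15)  # 17.5, linear on the first segment
#' @export
fitWarp <- function(observed, reference) {
  toVec <- function(x, col) {
    if (is.data.frame(x)) structure(x[[col]], names = x$standard_id)
    else x
  }
  obs <- toVec(observed, "observed_distance")
  ref <- toVec(reference, "reference_distance")
  shared <- intersect(names(obs), names(ref))
  if (length(shared) < 2)
    stop("standardization error: fewer than 2 shared internal standards")
  obs <- obs[shared]
  ref <- ref[shared]
  if (anyDuplicated(obs))
    stop("standardization error: co-migrating standards (duplicate observed distance)")
  o <- order(obs)
  obs <- obs[o]
  ref <- ref[o]
  if (any(diff(ref) <= 0))
    stop("gel-inversion error: observed standard order does not match reference order")
  new("WarpFunction", knots = cbind(observed = unname(obs),
                                    reference = unname(ref)))
}

#' Apply a standardization warp to raw migration distances
#'
#' Piecewise-linear within the knot range, linear terminal-segment
#' extrapolation outside it; strictly monotone, exact at the knots. Total on
#' non-negative inputs.
#'
#' @param warp a [WarpFunction-class].
#' @param distance_raw numeric vector of raw distances (>= 0).
#' @return numeric vector of standardized distances.
#' @export
applyWarp <- function(warp, distance_raw) {
  stopifnot(is(warp, "WarpFunction"))
  if (any(distance_raw < 0, na.rm = TRUE))
    stop("distance_raw must be non-negative")
  k <- warp@knots
  x <- k[, 1]
  y <- k[, 2]
  n <- nrow(k)
  # segment index: terminal segments extended for extrapolation
  i <- findInterval(distance_raw, x, all.inside = TRUE)
  slope <- (y[i + 1] - y[i]) / (x[i + 1] - x[i])
  y[i] + slope * (distance_raw - x[i])
}

#' Standardize a fingerprint's band distances
#'
#' Fits the lane warp from its observed internal standards against the
#' shared reference positions and adds a `distance_std` column to the bands.
#' Band order is preserved (the warp is monotone); standards map exactly to
#' their reference positions.
#'
#' @param fp a non-failed [Fingerprint-class] with standards observed.
#' @param standardsReference named numeric vector or data.frame
#'   (`standard_id`, `reference_distance`) of shared reference positions.
#' @return The fingerprint with `bands(fp)$distance_std` filled in.
#' @export
standardizeFingerprint <- function(fp, standardsReference) {
  stopifnot(is(fp, "Fingerprint"))
  if (amplificationFailed(fp))
    stop("cannot standardize failed lane ", laneId(fp), " (sample ",
         sampleId(fp), ")")
  warp <- tryCatch(fitWarp(standardsObserved(fp), standardsReference),
                   error = function(e)
                     stop("lane ", laneId(fp), " (gel ", gelId(fp), "): ",
                          conditionMessage(e), call. = FALSE))
  b <- fp@bands
  b$distance_std <- if (nrow(b)) applyWarp(warp, b$distance_raw) else numeric()
  fp@bands <- b
  fp
}
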