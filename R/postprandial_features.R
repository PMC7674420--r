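#' Normalized series volatility (fluc1)
#'
#' Sums the absolute consecutive differences of a (min-max normalized)
#' series and divides by its length:
#' \deqn{fluc1 = \sum_{i=2}^{len(x)} |x_i - x_{i-1}| / len(x).}
#' Note the divisor is the number of points, not the number of differences.
#'
#' @param x numeric vector (normalized series values), no missing values.
#' @return non-negative scalar; 0 iff the series is constant.
#' @examples
#' fluc1(c(0, 1, 0, 1, 0))  # 0.8
#' @export
fluc1 <- function(x) {
  if (length(x) < 2) stopf("fluc1 needs a series of length >= 2")
  if (anyNA(x)) stopf("fluc1 requires a complete series; apply fill_or_flag first")
  sum(abs(diff(x))) / length(x)
}

#' Min-max normalize a series against marker-wide bounds
#'
#' @param x numeric vector.
#' @param bounds length-2 `(min, max)` bounds, typically cohort-wide for the
#'   marker; defaults to the series' own range.
#' @return vector rescaled to \[0, 1\] under the bounds.
#' @export
minmax_normalize <- function(x, bounds = range(x, na.rm = TRUE)) {
  if (bounds[2] <= bounds[1]) stopf("degenerate bounds: min must be < max")
  (x - bounds[1]) / (bounds[2] - bounds[1])
}

#' Handle missing points in a measured series
#'
#' Exactly one missing value is replaced by interpolating the remaining
#' points (cubic spline when at least four support points exist, otherwise
#' linear); two or more missing values mark the series degenerate, in which
#' case the image representations (fluc2/fluc3) are set to 0 downstream.
#'
#' @param times time points in minutes, strictly increasing.
#' @param values marker values, `NA` allowed.
#' @return list with `times`, `values` (dense when repaired) and logical
#'   `degenerate`.
#' @export
fill_or_flag <- function(times, values) {
  stopifnot(length(times) == length(values))
  n_miss <- sum(is.na(values))
  if (n_miss == 0)
    return(list(times = times, values = values, degenerate = FALSE))
  if (n_miss >= 2 || n_miss == length(values))
    return(list(times = times, values = values, degenerate = TRUE))
  ok <- !is.na(values)
  filled <- if (sum(ok) >= 4) {
    spline(times[ok], values[ok], xout = times[!ok], method = "fmm")$y
  } else {
    approx(times[ok], values[ok], xout = times[!ok], rule = 2)$y
  }
  values[!ok] <- filled
  list(times = times, values = values, degenerate = FALSE)
}

#' Densify a series with cubic-spline interpolation
#'
#' Evaluates a cubic interpolating spline at `n_points` equally spaced times
#' spanning the observed range; the dense curve passes through the observed
#' points. With fewer than four support points, falls back to linear
#' interpolation (with a message).
#'
#' @param times,values complete observed series.
#' @param n_points number of interpolated points (default 100).
#' @return list with dense `times` and `values`.
#' @export
interpolate_dense <- function(times, values, n_points = 100) {
  if (anyNA(values)) stopf("interpolate_dense requires a complete series")
  grid <- seq(min(times), max(times), length.out = n_points)
  if (length(times) < 4) {
    message("fewer than 4 support points: falling back to linear interpolation")
    return(list(times = grid, values = approx(times, values, xout = grid)$y))
  }
  list(times = grid, values = spline(times, values, xout = grid, method = "fmm")$y)
}

#' Rasterize a dense series into a binary grid image vector
#'
#' The time axis is split into `g` equal bins over the series' own time span
#' and the value axis into `g` equal bins over marker-wide `y_bounds` (the
#' same axis scale for every individual). A cell is 1 iff at least one dense
#' point falls in it. The vector is assembled column by column, each column
#' read from the lower value boundary to the upper. Interior bin edges are
#' half-open (a point on an edge belongs to the upper bin); the last bin is
#' closed. Values outside `y_bounds` are clamped into the boundary cell.
#'
#' @param times,values dense series (e.g. from [interpolate_dense()]).
#' @param g grid size (10 or 50 in the standard configurations).
#' @param y_bounds length-2 `(min, max)` cohort-wide marker bounds.
#' @return object of class `raster_image`: list with binary `vec` (length
#'   g^2, column-major bottom-to-top), `g`, `y_bounds`.
#' @export
rasterize <- function(times, values, g, y_bounds) {
  if (y_bounds[2] <= y_bounds[1]) stopf("y_bounds must satisfy min < max")
  if (anyNA(values)) stopf("rasterize requires a complete series")
  t0 <- min(times); t1 <- max(times)
  if (t1 <= t0) stopf("series time span is degenerate")
  col <- pmin(g, floor((times - t0) / (t1 - t0) * g) + 1)
  yc <- pmin(pmax(values, y_bounds[1]), y_bounds[2])  # clamp out-of-bound values
  row <- pmin(g, floor((yc - y_bounds[1]) / (y_bounds[2] - y_bounds[1]) * g) + 1)
  vec <- integer(g * g)
  vec[(col - 1L) * g + row] <- 1L
  structure(list(vec = vec, g = g, y_bounds = y_bounds), class = "raster_image")
}

#' Occupied-cell count of a raster image (fluc2)
#'
#' @param image a `raster_image` from [rasterize()].
#' @return integer: the sum of the binary image vector.
#' @export
fluc2 <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  sum(image$vec)
}

#' Run-filtered occupied-cell count (fluc3)
#'
#' Counts only 1-cells lying in runs of two or more consecutive 1s in the
#' image vector. By default runs are scanned within each column (a run never
#' spans the boundary between the top of one column and the bottom of the
#' next); set `cross_columns = TRUE` to scan the concatenated vector as one
#' sequence.
#'
#' @param image a `raster_image`.
#' @param cross_columns allow runs to span column boundaries (default FALSE).
#' @return integer, always `<=` [fluc2()] of the same image.
#' @export
fluc3 <- function(image, cross_columns = FALSE) {
  stopifnot(inherits(image, "raster_image"))
  count_runs <- function(v) {
    r <- rle(v)
    sum(r$lengths[r$values == 1L & r$lengths >= 2])
  }
  if (cross_columns) return(count_runs(image$vec))
  g <- image$g
  cols <- matrix(image$vec, nrow = g)
  sum(apply(cols, 2, count_runs))
}

#' Trapezoidal area under a postprandial curve
#'
#' @param times,values complete series, at least 2 points.
#' @return area in marker units x minutes over the observed time range.
#' @export
auc_trapezoid <- function(times, values) {
  if (length(times) < 2) stopf("AUC needs at least 2 points")
  if (anyNA(values)) stopf("AUC requires a complete series")
  sum(diff(times) * (head(values, -1) + values[-1]) / 2)
}

#' Full volatility featurization of one series
#'
#' Applies the missing-value policy, computes fluc1 on the min-max normalized
#' measured series, then densifies and rasterizes the raw series at grid size
#' `g` for fluc2/fluc3 plus the trapezoidal AUC. For a degenerate series
#' (>= 2 missing points) the image representations are 0 and fluc1/AUC are NA.
#'
#' @param times,values measured series (NA allowed).
#' @param g grid size.
#' @param y_bounds cohort-wide marker bounds.
#' @param n_points dense interpolation size.
#' @param cross_columns run semantics for [fluc3()].
#' @return list: `fluc1`, `fluc2`, `fluc3`, `auc`, `degenerate`.
#' @export
fluc_features <- function(times, values, g, y_bounds, n_points = 100,
                          cross_columns = FALSE) {
  fl <- fill_or_flag(times, values)
  if (fl$degenerate)
    return(list(fluc1 = NA_real_, fluc2 = 0L, fluc3 = 0L, auc = NA_real_,
                degenerate = TRUE))
  f1 <- fluc1(minmax_normalize(fl$values, y_bounds))
  dense <- interpolate_dense(fl$times, fl$values, n_points)
  img <- rasterize(dense$times, dense$values, g, y_bounds)
  list(fluc1 = f1, fluc2 = fluc2(img), fluc3 = fluc3(img, cross_columns),
       auc = auc_trapezoid(fl$times, fl$values), degenerate = FALSE)
}

#' Build the postprandial feature block from long-format series data
#'
#' Computes, per sample and marker, the AUC and the three volatility
#' features at each requested grid size, using cohort-wide per-marker value
#' bounds for normalization and rasterization. Duplicate fasting (t = 0)
#' measurements are averaged before featurization. Column naming follows the
#' `"<marker>_PostPranFluc<K>_<G>"` convention (plus `"<marker>_AUC"`).
#'
#' @param pp long-format data.frame: `sample_id`, `marker`, `time_min`,
#'   `value` (as produced by [simulate_postprandial()] or read from TSV).
#' @param grid_sizes integer vector of raster grid sizes (default c(10, 50)).
#' @param cross_columns run semantics for [fluc3()].
#' @return a [feature_block()] labelled `"PostPran"`.
#' @export
postprandial_feature_block <- function(pp, grid_sizes = c(10, 50),
                                       cross_columns = FALSE) {
  markers <- sort(unique(pp$marker))
  ids <- unique(pp$sample_id)
  bounds <- lapply(markers, function(m)
    range(pp$value[pp$marker == m], na.rm = TRUE))
  names(bounds) <- markers

  cols <- list()
  for (m in markers) {
    sub <- pp[pp$marker == m, , drop = FALSE]
    per_sample <- lapply(ids, function(id) {
      s <- sub[sub$sample_id == id, , drop = FALSE]
      s <- s[order(s$time_min), , drop = FALSE]
      # average duplicate fasting measurements
      if (anyDuplicated(s$time_min)) {
        agg <- tapply(s$value, s$time_min, function(v)
          if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
        s <- data.frame(time_min = as.numeric(names(agg)), value = as.numeric(agg))
      }
      res <- list(fluc1 = NA_real_, auc = NA_real_)
      for (g in grid_sizes) {
        res[[paste0("fluc2_", g)]] <- NA_real_
        res[[paste0("fluc3_", g)]] <- NA_real_
      }
      if (nrow(s) >= 2) {
        for (g in grid_sizes) {
          ft <- fluc_features(s$time_min, s$value, g, bounds[[m]],
                              cross_columns = cross_columns)
          res$fluc1 <- ft$fluc1
          res$auc <- ft$auc
          res[[paste0("fluc2_", g)]] <- ft$fluc2
          res[[paste0("fluc3_", g)]] <- ft$fluc3
        }
      }
      unlist(res)
    })
    mat <- do.call(rbind, per_sample)
    nm <- c(paste0(m, "_PostPranFluc1"), paste0(m, "_AUC"))
    for (g in grid_sizes) nm <- c(nm, paste0(m, "_PostPranFluc2_", g),
                                  paste0(m, "_PostPranFluc3_", g))
    # unlist order: fluc1, auc, then per-g fluc2/fluc3
    colnames(mat) <- nm
    cols[[m]] <- mat
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- ids
  # degenerate series leave NA fluc1/AUC; impute column medians so the block
  # stays model-ready, as degenerate image features are already coded 0
  for (j in seq_len(ncol(vals))) {
    nas <- is.na(vals[, j])
    if (any(nas)) vals[nas, j] <- stats::median(vals[, j], na.rm = TRUE)
  }
  feature_block(vals, "PostPran")
}

#' Read / write long-format postprandial series TSV
#' @param path file path.
#' @export
read_postprandial_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_postprandial_tsv
#' @param pp long-format postprandial data.frame.
#' @export
write_postprandial_tsv <- function(pp, path) {
  write.table(pp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
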