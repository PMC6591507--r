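#' Curve containers
#'
#' Time-resolved curves (TPSFs, IRFs, measurements) are plain tibbles with
#' columns `time_ps` (bin centres on a uniform grid) and `intensity`
#' (non-negative).  `as_curve()` validates an existing data frame;
#' `new_curve()` builds one from vectors.  All curve-consuming functions in
#' the package accept any data frame with these two columns.
#'
#' @param time_ps Bin-centre times, ps, uniformly spaced.
#' @param intensity Non-negative intensities, same length.
#' @return A tibble of class `tpsf_curve`.
#' @export
new_curve <- function(time_ps, intensity) {
  stopifnot(length(time_ps) == length(intensity), length(time_ps) >= 2)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    abort("`intensity` must be finite and non-negative")
  out <- tibble::tibble(time_ps = as.numeric(time_ps),
                        intensity = as.numeric(intensity))
  class(out) <- c("tpsf_curve", class(out))
  out
}

#' @rdname new_curve
#' @param x A data frame with columns `time_ps` and `intensity`.
#' @export
as_curve <- function(x) {
  if (!is.data.frame(x) || !all(c("time_ps", "intensity") %in% names(x)))
    abort("a curve needs columns `time_ps` and `intensity`")
  cv <- new_curve(x$time_ps, x$intensity)
  check_uniform_grid(cv$time_ps)
  cv
}

check_uniform_grid <- function(t, tol = 1e-6) {
  d <- diff(t)
  if (any(d <= 0) || (max(d) - min(d)) > tol * stats::median(d))
    abort("`time_ps` must be a strictly increasing uniform grid")
  invisible(stats::median(d))
}

#' Bin width of a curve, ps
#' @param curve A curve data frame.
#' @export
bin_width_of <- function(curve) {
  check_uniform_grid(curve$time_ps)
}

#' Normalize a curve to unit peak
#'
#' Divides all bins by the maximum value so the peak equals 1 exactly; the
#' shape is preserved.  Idempotent and invariant under positive scaling of
#' the input.  An all-zero curve is rejected.
#'
#' @param curve A curve data frame (or a bare numeric vector of bin values).
#' @return The input with `intensity` scaled to unit peak.
#' @export
peak_normalize <- function(curve) {
  if (is.numeric(curve) && is.null(dim(curve))) {
    m <- max(curve)
    if (!is.finite(m) || m <= 0) abort("cannot normalize an all-zero curve")
    return(curve / m)
  }
  m <- max(curve$intensity)
  if (!is.finite(m) || m <= 0) abort("cannot normalize an all-zero curve")
  dplyr::mutate(curve, intensity = .data$intensity / m)
}

is_peak_normalized <- function(curve, tol = 1e-9) {
  abs(max(curve$intensity) - 1) <= tol
}

#' Full width at half maximum of a curve
#'
#' Linear interpolation between the bins bracketing the half-peak crossings
#' on either side of the maximum.
#'
#' @param curve A curve data frame with a single dominant peak.
#' @return FWHM in ps.
#' @export
measure_fwhm <- function(curve) {
  y <- curve$intensity / max(curve$intensity)
  t <- curve$time_ps
  ipk <- which.max(y)
  cross <- function(idx_range, decreasing) {
    ys <- y[idx_range]
    below <- which(ys < 0.5)
    if (length(below) == 0) abort("curve never falls below half maximum")
    if (decreasing) {
      i2 <- idx_range[below[1]]; i1 <- i2 - 1
    } else {
      i1 <- idx_range[below[length(below)]]; i2 <- i1 + 1
    }
    t[i1] + (0.5 - y[i1]) * (t[i2] - t[i1]) / (y[i2] - y[i1])
  }
  left <- cross(seq_len(ipk), decreasing = FALSE)
  right <- cross(ipk:length(y), decreasing = TRUE)
  right - left
}

#' Read and write curve files
#'
#' Curves are stored as two-column whitespace-delimited text
#' (`time_ps intensity`) with `#`-prefixed metadata header lines
#' (`key: value`).  `read_curve()` validates uniform time spacing and
#' returns the metadata as an attribute.
#'
#' @param path File path.
#' @param curve A curve data frame.
#' @param meta Named list written into the header.
#' @return `read_curve()`: a `tpsf_curve` tibble with attribute `meta`.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort(sprintf("curve file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#|^\\s*$", lines)]
  if (length(body) < 2) abort(sprintf("no data rows in %s", path))
  mat <- suppressWarnings(  # non-numeric tokens surface as the error below
    do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric)))
  if (ncol(mat) < 2 || any(!is.finite(mat[, 1:2])))
    abort(sprintf("malformed curve data in %s", path))
  cv <- new_curve(mat[, 1], pmax(mat[, 2], 0))
  check_uniform_grid(cv$time_ps)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    if (grepl(":", kv, fixed = TRUE)) {
      k <- trimws(sub(":.*$", "", kv))
      v <- trimws(sub("^[^:]*:", "", kv))
      meta[[k]] <- v
    }
  }
  attr(cv, "meta") <- meta
  cv
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path, meta = list()) {
  curve <- as_curve(curve)
  meta <- modifyList(list(bin_width_ps = format(bin_width_of(curve)),
                          units = "ps, arbitrary"), meta)
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, format, character(1)))
  rows <- sprintf("%.10g %.12g", curve$time_ps, curve$intensity)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

bin_centers <- function(n_bins, bin_width) (seq_len(n_bins) - 0.5) * bin_width
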