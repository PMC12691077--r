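#' Extract ROI temperature statistics from a radiometric map
#'
#' A pixel belongs to the box when its centre falls in the half-open
#' rectangle `[x1, x2) x [y1, y2)`; pixel `(row r, column c)` has centre
#' `(c - 0.5, r - 0.5)`.  Reports the maximum, minimum and mean
#' temperature over the member pixels.  The maximum is the conventional
#' body-surface temperature characteristic: the ROI skin is warmer than
#' everything else inside the detection box, so the within-box maximum is
#' robust to background pixels.
#'
#' @param temps H x W numeric matrix of temperatures in degrees Celsius.
#' @param box Detection box `(x1, y1, x2, y2)` in pixel coordinates
#'   (x along columns, y along rows, origin top-left).
#' @return A list of class `roi_temperatures` with `t_max`, `t_min`,
#'   `t_avg` and `n_pixels`.
#' @export
extract_roi_temperatures <- function(temps, box) {
  check_bbox(box)
  h <- nrow(temps); w <- ncol(temps)
  cols <- which(seq_len(w) - 0.5 >= box[[1]] & seq_len(w) - 0.5 < box[[3]])
  rows <- which(seq_len(h) - 0.5 >= box[[2]] & seq_len(h) - 0.5 < box[[4]])
  if (length(rows) == 0L || length(cols) == 0L)
    stop("box does not cover any pixel centre", call. = FALSE)
  vals <- temps[rows, cols]
  structure(list(t_max = max(vals), t_min = min(vals), t_avg = mean(vals),
                 n_pixels = length(vals)),
            class = "roi_temperatures")
}

#' Temperature extraction error statistics
#'
#' Per-animal absolute errors between extracted and reference
#' temperatures, summarized by their maximum, minimum and mean.  The
#' signed mean is reported as a secondary field because inaccurate
#' detections typically bias the extraction toward slight
#' underestimation.
#'
#' @param extracted,reference Equal-length numeric vectors in degrees
#'   Celsius.
#' @return A list of class `temp_error_stats` with `max_error`,
#'   `min_error`, `mean_error` (absolute) and `signed_mean_error`.
#' @export
temperature_errors <- function(extracted, reference) {
  if (length(extracted) != length(reference))
    stop("`extracted` and `reference` must have equal length", call. = FALSE)
  if (length(extracted) < 1L) stop("need at least one pair", call. = FALSE)
  err <- extracted - reference
  structure(list(max_error = max(abs(err)), min_error = min(abs(err)),
                 mean_error = mean(abs(err)), signed_mean_error = mean(err)),
            class = "temp_error_stats")
}

#' Spearman correlation matrix of temperature sites
#'
#' Pairwise Spearman rank correlation (average ranks on ties) between the
#' numeric site columns of a temperature table.  Constant columns have no
#' defined rank correlation; the affected pairs are returned as `NA` with
#' a warning.
#'
#' @param table Data frame whose numeric columns are measurement sites
#'   (e.g. RT, LU, AA); non-numeric columns such as cow identifiers are
#'   ignored.  At least 3 complete rows are required.
#' @return Symmetric site x site correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (ncol(num) < 2L) stop("need at least two numeric site columns", call. = FALSE)
  if (nrow(num) < 3L) stop("need at least three rows", call. = FALSE)
  if (anyNA(num)) stop("missing values in analysed columns", call. = FALSE)
  # constant columns are flagged below; silence cor()'s own zero-sd warning
  m <- suppressWarnings(stats::cor(as.matrix(num), method = "spearman"))
  const <- vapply(num, function(x) length(unique(x)) == 1L, logical(1))
  if (any(const)) {
    warning("constant column(s): ", paste(names(num)[const], collapse = ", "),
            "; their correlations are undefined", call. = FALSE)
    m[const, ] <- NA_real_
    m[, const] <- NA_real_
  }
  diag(m) <- 1
  m
}

#' Rank candidate ROIs by correlation with a target site
#'
#' Returns the `k` non-target sites whose Spearman correlation with the
#' target is largest, ties broken alphabetically.
#'
#' @param matrix Correlation matrix from [spearman_matrix()].
#' @param target Target site name (default `"RT"`, the rectal reference).
#' @param k Number of sites to return (default 2).
#' @return Character vector of the `k` best sites, best first.
#' @export
select_rois <- function(matrix, target = "RT", k = 2L) {
  if (!target %in% rownames(matrix))
    stop(sprintf("target site '%s' not in the matrix", target), call. = FALSE)
  rho <- matrix[target, setdiff(colnames(matrix), target)]
  if (k > length(rho))
    stop("`k` exceeds the number of candidate sites", call. = FALSE)
  ord <- order(-rho, names(rho))
  names(rho)[ord][seq_len(k)]
}
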