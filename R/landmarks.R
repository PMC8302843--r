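#' A 38-point facial landmark set
#'
#' Planar landmark coordinates (pixel units) extracted from a face
#' photograph, with the nasal-tip point designated as the base point. The
#' distances from the other 37 points to the base point summarise face
#' geometry; comparing them before and after a wearable is attached
#' quantifies how much the device restricts facial motion.
#'
#' @param points Numeric 38 x 2 matrix (columns x, y).
#' @param base_index Row index of the nasal-tip base point (default 1).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, base_index = 1L) {
  points <- as.matrix(points)
  if (!all(dim(points) == c(38L, 2L))) {
    stop_feree("landmark set must be a 38 x 2 coordinate matrix",
               "feree_landmark_error")
  }
  base_index <- as.integer(base_index)
  if (base_index < 1L || base_index > 38L) {
    stop_feree("base_index must be in 1..38", "feree_landmark_error")
  }
  d <- sqrt(rowSums(sweep(points, 2, points[base_index, ])^2))
  if (any(d[-base_index] == 0)) {
    stop_feree("a landmark coincides with the base point",
               "feree_degenerate_geometry_error")
  }
  structure(list(points = points, base_index = base_index),
            class = "landmark_set")
}

#' Distances from each landmark to the nasal-tip base point
#'
#' @param s A [landmark_set()].
#' @return Numeric vector of length 37: Euclidean distances of the non-base
#'   points to the base point, in input order with the base point omitted.
#' @export
landmark_distances <- function(s) {
  stopifnot(inherits(s, "landmark_set"))
  d <- sqrt(rowSums(sweep(s$points, 2, s$points[s$base_index, ])^2))
  d[-s$base_index]
}

#' Mean relative error of landmark distances
#'
#' For matched landmark sets photographed before and after a device is
#' attached, `mre()` is the mean over the 37 non-base points of
#' `|l_after - l_before| / l_before`, where `l` is the distance to the
#' nasal-tip base point. The natural (before-attachment) face is the
#' reference, which makes the metric scale-free: a uniform scaling of the
#' face about the base point by factor `s` yields exactly `|s - 1|`, and
#' any rigid motion of either set leaves it unchanged. Smaller MRE means
#' the device restricts spontaneous expression less.
#'
#' @param before,after [landmark_set()] objects with identical point
#'   correspondence and base index.
#' @return Nonnegative scalar; 0 iff all distances are unchanged.
#' @export
mre <- function(before, after) {
  stopifnot(inherits(before, "landmark_set"), inherits(after, "landmark_set"))
  if (before$base_index != after$base_index) {
    stop_feree("base points must correspond", "feree_landmark_error")
  }
  lb <- landmark_distances(before)
  la <- landmark_distances(after)
  mean(abs(la - lb) / lb)
}

#' MRE over repeated photographs
#'
#' Photo sessions usually take several independent pictures per condition.
#' Two aggregations are available: `"photos"` (default) computes one MRE
#' per before/after photo pair and averages the pair MREs; `"points"`
#' first averages each landmark's distance across photos and computes a
#' single MRE on the averaged geometry.
#'
#' @param before_list,after_list Equal-length lists of [landmark_set()].
#' @param average `"photos"` or `"points"`.
#' @return Nonnegative scalar.
#' @export
mre_repeated <- function(before_list, after_list,
                         average = c("photos", "points")) {
  average <- match.arg(average)
  if (length(before_list) != length(after_list) || !length(before_list)) {
    stop_feree("before/after photo lists must be non-empty and equal length",
               "feree_landmark_error")
  }
  if (average == "photos") {
    return(mean(mapply(mre, before_list, after_list)))
  }
  lb <- rowMeans(sapply(before_list, landmark_distances))
  la <- rowMeans(sapply(after_list, landmark_distances))
  mean(abs(la - lb) / lb)
}

#' Read and write landmark coordinate tables
#'
#' CSV dialect: an optional `#base=<point_id>` header line flags the
#' nasal-tip base point, then columns `point_id,x,y` with 38 rows.
#'
#' @param path CSV file path.
#' @param s A [landmark_set()].
#' @return `read_landmarks()` returns a `landmark_set`;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  base_id <- 1L
  hdr <- grep("^#base=", lines, value = TRUE)
  if (length(hdr)) base_id <- as.integer(sub("^#base=", "", hdr[[1]]))
  dat <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  if (!all(c("point_id", "x", "y") %in% names(dat))) {
    stop_feree("landmark CSV needs point_id,x,y columns",
               "feree_format_error")
  }
  dat <- dat[order(dat$point_id), ]
  landmark_set(cbind(dat$x, dat$y), base_index = match(base_id, dat$point_id))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(s, path) {
  stopifnot(inherits(s, "landmark_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#base=%d", s$base_index), con)
  utils::write.csv(
    data.frame(point_id = seq_len(38L), x = s$points[, 1], y = s$points[, 2]),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
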