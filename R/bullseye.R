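# AHA 17-segment mapping: per-view wall/level segment assignment and fusion
# of the three long-axis views into the bullseye.

#' Standard AHA 17-segment names
#'
#' @return character vector of length 17, indexed by segment id.
#' @export
aha_segment_names <- function() {
  c("Basal anterior", "Basal anteroseptal", "Basal inferoseptal",
    "Basal inferior", "Basal inferolateral", "Basal anterolateral",
    "Mid-anterior", "Mid-anteroseptal", "Mid-inferoseptal",
    "Mid-inferior", "Mid-inferolateral", "Mid-anterolateral",
    "Apical anterior", "Apical septal", "Apical inferior",
    "Apical lateral", "Apex")
}

#' Default view-to-segment map
#'
#' Binds each wall (the two annulus-to-apex halves of a view's polyline) to
#' its basal, mid-cavity and apical segment ids, following common vendor
#' triplane conventions: the 4CH view samples the inferoseptal (3, 9, 14) and
#' anterolateral (6, 12, 16) walls; the 2CH view the inferior (4, 10, 15) and
#' anterior (1, 7, 13) walls; the 3CH view the anteroseptal wall (2, 8,
#' contributing apically to 13) and the inferolateral wall (5, 11,
#' contributing apically to 16).  The apical cap (segment 17) receives the
#' points nearest the apex from every view.  `wall1` is the wall entered from
#' the contour's first annulus point.
#'
#' @param cap_fraction fraction of each wall's arc, adjacent to the apex,
#'   assigned to the apical-cap segment 17 (default 0.10).
#' @return object of class `"segment_map"`.
#' @export
default_segment_map <- function(cap_fraction = 0.10) {
  m <- list(
    `4CH` = list(wall1 = c(3L, 9L, 14L),  wall1_name = "inferoseptal",
                 wall2 = c(6L, 12L, 16L), wall2_name = "anterolateral"),
    `2CH` = list(wall1 = c(4L, 10L, 15L), wall1_name = "inferior",
                 wall2 = c(1L, 7L, 13L),  wall2_name = "anterior"),
    `3CH` = list(wall1 = c(2L, 8L, 13L),  wall1_name = "anteroseptal",
                 wall2 = c(5L, 11L, 16L), wall2_name = "inferolateral"))
  structure(list(views = m, cap_segment = 17L, cap_fraction = cap_fraction),
            class = "segment_map")
}

validate_segment_map <- function(map) {
  if (!inherits(map, "segment_map")) stop("`map` must be a segment_map")
  if (map$cap_fraction <= 0 || map$cap_fraction >= 1 / 3)
    stop("cap_fraction must be in (0, 1/3)")
  segs <- unlist(lapply(map$views, function(v) c(v$wall1, v$wall2)))
  covered <- sort(unique(c(segs, map$cap_segment)))
  if (!identical(covered, 1:17))
    stop("segment map must cover segments 1..17 exactly; got ",
         paste(covered, collapse = ","))
  invisible(map)
}

#' Assign contour points of one view to AHA segments
#'
#' Each wall's arc, measured from its annulus to the apex, is split at
#' fractions given by `boundaries` into basal, mid-cavity and apical bands;
#' points within `cap_fraction` of the apex on either wall form the apical
#' cap (segment 17).  The apex point is the contour point farthest from the
#' annular midpoint.
#'
#' @param points_ed n x 2 matrix of ED points (the resampled or paired points
#'   of one view, in contour order).
#' @param axis the view's [fit_axis()] result.
#' @param view `"2CH"`, `"3CH"` or `"4CH"`.
#' @param map a [default_segment_map()] (or override).
#' @param boundaries wall-arc fractions separating basal/mid and mid/apical
#'   bands (default `c(1/3, 2/3)`).
#' @return data.frame with `wall` (1 or 2), `wall_frac` (0 at annulus, 1 at
#'   apex) and `segment` per point.
#' @export
assign_segments <- function(points_ed, axis, view, map = default_segment_map(),
                            boundaries = c(1 / 3, 2 / 3)) {
  validate_segment_map(map)
  view <- match.arg(view, IND_VIEWS)
  p <- contour_points(points_ed)
  n <- nrow(p)
  s <- arc_positions(p)
  d2 <- (p[, 1L] - axis$base_mid[1L])^2 + (p[, 2L] - axis$base_mid[2L])^2
  ai <- which.max(round(d2, 6))  # pose-invariant tie-break, as in fit_axis
  if (ai == 1L || ai == n) stop("degenerate segmentation: apex at an annulus")
  wall <- ifelse(seq_len(n) <= ai, 1L, 2L)
  frac <- numeric(n)
  frac[wall == 1L] <- s[wall == 1L] / s[ai]
  frac[wall == 2L] <- (s[n] - s[wall == 2L]) / (s[n] - s[ai])
  vm <- map$views[[view]]
  seg <- integer(n)
  cap <- frac >= 1 - map$cap_fraction
  seg[cap] <- map$cap_segment
  lev <- findInterval(frac, c(boundaries, 1 - map$cap_fraction)) + 1L
  for (w in 1:2) {
    idx <- !cap & wall == w
    seg[idx] <- (if (w == 1L) vm$wall1 else vm$wall2)[pmin(lev[idx], 3L)]
    if (!any(idx))
      stop("degenerate segmentation: wall ", w, " empty after cap removal")
  }
  data.frame(wall = wall, wall_frac = frac, segment = seg)
}

#' Per-segment mean inward displacement for one view
#'
#' Unweighted arithmetic mean of point-wise InD (%) over the points assigned
#' to each segment present in the view.
#'
#' @param ind_pct numeric vector of point-wise InD (%).
#' @param segment integer vector of segment ids (same length).
#' @return data.frame with `segment`, `mean_pct`, `n`.
#' @export
segment_means <- function(ind_pct, segment) {
  stopifnot(length(ind_pct) == length(segment))
  if (!all(is.finite(ind_pct))) stop("non-finite InD values")
  segs <- sort(unique(segment))
  data.frame(
    segment = segs,
    mean_pct = vapply(segs, function(sg) mean(ind_pct[segment == sg]),
                      numeric(1)),
    n = vapply(segs, function(sg) sum(segment == sg), integer(1)))
}

#' Fuse per-view segment means into the 17-segment bullseye
#'
#' Segments contributed by a single view are copied; segments shared between
#' views (13, 16 and the apical cap 17 under the default map) are combined as
#' the unweighted mean of the contributing views' means (or point-count
#' weighted with `weighting = "points"`).
#'
#' @param view_tables named list of [segment_means()] data frames, one per view.
#' @param weighting `"unweighted"` (default) or `"points"`.
#' @param partial if `TRUE`, segments covered by no view become `NA` with a
#'   warning instead of an error.
#' @return a `"bullseye17"` object; see [bullseye17()].
#' @export
merge_views <- function(view_tables, weighting = c("unweighted", "points"),
                        partial = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(is.list(view_tables), length(view_tables) >= 1L)
  seg_pct <- rep(NA_real_, 17L)
  n_points <- integer(17L)
  n_views <- integer(17L)
  for (k in 1:17) {
    vals <- numeric(0); wts <- numeric(0)
    for (tb in view_tables) {
      row <- tb[tb$segment == k, , drop = FALSE]
      if (nrow(row) == 1L) {
        vals <- c(vals, row$mean_pct)
        wts <- c(wts, row$n)
        n_points[k] <- n_points[k] + row$n
      }
    }
    n_views[k] <- length(vals)
    if (length(vals))
      seg_pct[k] <- if (weighting == "points")
        stats::weighted.mean(vals, wts) else mean(vals)
  }
  if (anyNA(seg_pct)) {
    missing <- which(is.na(seg_pct))
    msg <- paste("segments covered by no view:",
                 paste(missing, collapse = ", "))
    if (partial) warning(msg) else stop(msg)
  }
  bullseye17(seg_pct, n_points = n_points, n_views = n_views)
}

#' 17-segment bullseye container
#'
#' @param seg_pct numeric vector of 17 segmental InD values (%); `NA` marks a
#'   segment not covered by the available views.
#' @param n_points,n_views optional per-segment point and view counts.
#' @return object of class `"bullseye17"` with full-precision regional means
#'   (`base` = segments 1-6, `mid` = 7-12, `apex` = 13-17, `overall` = 1-17,
#'   computed over non-missing segments).
#' @export
bullseye17 <- function(seg_pct, n_points = NULL, n_views = NULL) {
  if (length(seg_pct) != 17L) stop("need 17 segmental values")
  seg_pct <- as.numeric(seg_pct)
  names(seg_pct) <- as.character(1:17)
  structure(list(
    seg_pct = seg_pct,
    n_points = n_points, n_views = n_views,
    base = mean(seg_pct[1:6], na.rm = TRUE),
    mid = mean(seg_pct[7:12], na.rm = TRUE),
    apex = mean(seg_pct[13:17], na.rm = TRUE),
    overall = mean(seg_pct, na.rm = TRUE),
    missing = which(is.na(seg_pct))), class = "bullseye17")
}

#' @export
print.bullseye17 <- function(x, digits = 1, ...) {
  cat("AHA 17-segment inward displacement (%)\n")
  df <- data.frame(segment = 1:17, name = aha_segment_names(),
                   ind_pct = round(x$seg_pct, digits))
  if (!is.null(x$n_points)) df$n_points <- x$n_points
  print(df, row.names = FALSE)
  cat(sprintf("base %.1f  mid %.1f  apex %.1f  overall %.1f\n",
              x$base, x$mid, x$apex, x$overall))
  invisible(x)
}

#' Regional averages of the 17-segment bullseye
#'
#' Arithmetic means over the basal (segments 1-6), mid-cavity (7-12) and
#' apical (13-17) regions and over all 17 segments, reported at one decimal
#' by default.
#'
#' @param seg_pct numeric vector of 17 finite segmental values, or a
#'   `"bullseye17"` object.
#' @param digits rounding of the reported means (`NULL` for full precision).
#' @return named numeric vector `c(base, mid, apex, overall)`.
#' @examples
#' region_averages(c(rep(10, 6), rep(0, 11)))  # base 10, overall 3.5
#' @export
region_averages <- function(seg_pct, digits = 1) {
  if (inherits(seg_pct, "bullseye17")) seg_pct <- seg_pct$seg_pct
  if (length(seg_pct) != 17L || !all(is.finite(seg_pct)))
    stop("need 17 finite segmental values")
  out <- c(base = mean(seg_pct[1:6]), mid = mean(seg_pct[7:12]),
           apex = mean(seg_pct[13:17]), overall = mean(seg_pct))
  if (!is.null(digits)) out <- round(out, digits)
  out
}
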