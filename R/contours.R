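#' @keywords internal
"_PACKAGE"

IND_VIEWS <- c("2CH", "3CH", "4CH")
IND_PHASES <- c("ED", "ES")

#' Long-axis endocardial contour
#'
#' Constructs a validated endocardial contour for one long-axis view and one
#' cardiac phase.  Points are an ordered open polyline in millimetres: the
#' first point is one mitral-annulus insertion, the last point is the other,
#' and the polyline traverses the apex in between.  By package convention the
#' y coordinate increases toward the apex.
#'
#' @param points numeric n x 2 matrix (or coercible) of (x, y) coordinates in
#'   mm, n >= 20.
#' @param view one of `"2CH"`, `"3CH"`, `"4CH"`.
#' @param phase one of `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @return an object of class `"lax_contour"`: a list with elements `view`,
#'   `phase` and `points`.
#' @examples
#' th <- seq(0, pi, length.out = 51)
#' ed <- lax_contour(cbind(-22 * cos(th), 90 * sin(th)), "4CH", "ED")
#' @export
lax_contour <- function(points, view, phase) {
  view <- match.arg(view, IND_VIEWS)
  phase <- match.arg(phase, IND_PHASES)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop("contour points must be an n x 2 matrix of (x, y) in mm")
  if (nrow(points) < 20L)
    stop("contour must have at least 20 points, got ", nrow(points))
  if (!all(is.finite(points)))
    stop("contour contains non-finite coordinates")
  if (identical(points[1L, ], points[nrow(points), ]))
    stop("contour polyline must be open (first point must differ from last)")
  if (polyline_length(points) <= 0)
    stop("contour has zero arc length")
  structure(list(view = view, phase = phase, points = unname(points)),
            class = "lax_contour")
}

#' @export
print.lax_contour <- function(x, ...) {
  cat(sprintf("<lax_contour> %s %s, %d points, arc length %.1f mm\n",
              x$view, x$phase, nrow(x$points), polyline_length(x$points)))
  invisible(x)
}

contour_points <- function(x) {
  if (inherits(x, "lax_contour")) x$points else as.matrix(x)
}

#' Per-subject contour set
#'
#' Bundles the long-axis contours of one subject, with optional pairing
#' information and anthropometrics.  When `paired = TRUE` the ED and ES
#' contours of each view must have equal point counts and matching indices
#' declare the ED-to-ES point correspondence (externally tracked points);
#' otherwise correspondence is established by arc-length resampling during
#' analysis.
#'
#' @param contours list of [lax_contour] objects (at most one per view/phase).
#' @param subject_id character identifier.
#' @param paired logical; are ED/ES point indices matched?
#' @param height_cm,weight_kg optional anthropometrics for BSA indexing.
#' @return object of class `"contour_set"`.
#' @export
contour_set <- function(contours, subject_id = "subject", paired = FALSE,
                        height_cm = NULL, weight_kg = NULL) {
  stopifnot(is.list(contours), length(contours) >= 1L)
  ok <- vapply(contours, inherits, logical(1), "lax_contour")
  if (!all(ok)) stop("all elements of `contours` must be lax_contour objects")
  keys <- vapply(contours, function(ct) paste(ct$view, ct$phase), character(1))
  if (anyDuplicated(keys))
    stop("duplicate view/phase contour: ", keys[duplicated(keys)][1L])
  names(contours) <- keys
  if (isTRUE(paired)) {
    for (v in unique(vapply(contours, `[[`, character(1), "view"))) {
      ed <- contours[[paste(v, "ED")]]
      es <- contours[[paste(v, "ES")]]
      if (!is.null(ed) && !is.null(es) &&
          nrow(ed$points) != nrow(es$points))
        stop("paired contour set: ED/ES point counts differ in view ", v)
    }
  }
  structure(list(subject_id = as.character(subject_id), contours = contours,
                 paired = isTRUE(paired),
                 height_cm = height_cm, weight_kg = weight_kg),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> subject %s, %d contours (%s)%s\n",
              x$subject_id, length(x$contours),
              paste(names(x$contours), collapse = ", "),
              if (x$paired) ", paired" else ""))
  invisible(x)
}

get_contour <- function(set, view, phase) {
  set$contours[[paste(view, phase)]]
}

set_views <- function(set) {
  unique(vapply(set$contours, `[[`, character(1), "view"))
}

polyline_length <- function(points) {
  d <- diff(as.matrix(points))
  sum(sqrt(rowSums(d^2)))
}

arc_positions <- function(points) {
  d <- diff(as.matrix(points))
  c(0, cumsum(sqrt(rowSums(d^2))))
}
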