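# Contour readers/writers and result reports.  Coordinates are physical
# millimetres in the view plane; y increases toward the apex.

#' Read a contour set from JSON or CSV
#'
#' JSON schema:
#' `{subject_id, paired, height_cm, weight_kg,
#'   views: [{view: "2CH"|"3CH"|"4CH", phase: "ED"|"ES",
#'            points_mm: [[x, y], ...]}, ...]}`.
#' CSV is the equivalent long format with columns
#' `subject_id, view, phase, point_index, x_mm, y_mm` (pairing may be
#' declared by a constant `paired` column).  The round trip through
#' [write_contours()] is lossless.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return a [contour_set()].
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed JSON in ", path, ": ", conditionMessage(e)))
    if (is.null(j$views)) stop("contour JSON lacks a 'views' field: ", path)
    views <- j$views
    if (is.data.frame(views))
      views <- lapply(seq_len(nrow(views)), function(i)
        list(view = views$view[i], phase = views$phase[i],
             points_mm = views$points_mm[[i]]))
    contours <- lapply(views, function(vw) {
      if (is.null(vw$view) || is.null(vw$phase) || is.null(vw$points_mm))
        stop("contour JSON view entry needs fields view, phase, points_mm")
      lax_contour(vw$points_mm, vw$view, vw$phase)
    })
    contour_set(contours,
                subject_id = if (is.null(j$subject_id)) "subject" else j$subject_id,
                paired = isTRUE(j$paired),
                height_cm = j$height_cm, weight_kg = j$weight_kg)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject_id", "view", "phase", "point_index", "x_mm", "y_mm")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("contour CSV ", path, " lacks column(s): ",
           paste(miss, collapse = ", "))
    sid <- unique(df$subject_id)
    if (length(sid) != 1L)
      stop("contour CSV must hold one subject; found: ",
           paste(sid, collapse = ", "))
    contours <- lapply(split(df, paste(df$view, df$phase)), function(g) {
      g <- g[order(g$point_index), ]
      lax_contour(cbind(g$x_mm, g$y_mm), g$view[1L], g$phase[1L])
    })
    contour_set(unname(contours), subject_id = sid,
                paired = "paired" %in% names(df) && isTRUE(all(df$paired)))
  } else stop("unsupported contour format (need .json or .csv): ", path)
}

#' Write a contour set to JSON
#'
#' @param set a [contour_set()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_contours <- function(set, path) {
  stopifnot(inherits(set, "contour_set"))
  out <- list(subject_id = set$subject_id, paired = set$paired,
              views = lapply(unname(set$contours), function(ct)
                list(view = ct$view, phase = ct$phase,
                     points_mm = ct$points)))
  if (!is.null(set$height_cm)) out$height_cm <- set$height_cm
  if (!is.null(set$weight_kg)) out$weight_kg <- set$weight_kg
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write analysis reports
#'
#' Writes `<prefix>_bullseye.csv` (segment_id, segment_name, ind_pct,
#' n_points) and `<prefix>_report.json` holding the segmental values,
#' regional and overall means, volumetric metrics and the effective
#' configuration (for provenance).
#'
#' @param result an [inward_displacement()] result.
#' @param prefix output path prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
write_report <- function(result, prefix) {
  stopifnot(inherits(result, "ind"))
  b <- result$bullseye
  csv_path <- paste0(prefix, "_bullseye.csv")
  utils::write.csv(
    data.frame(segment_id = 1:17, segment_name = aha_segment_names(),
               ind_pct = unname(b$seg_pct),
               n_points = if (is.null(b$n_points)) NA_integer_ else b$n_points),
    csv_path, row.names = FALSE)
  json_path <- paste0(prefix, "_report.json")
  jsonlite::write_json(
    list(subject_id = result$subject_id,
         segments = stats::setNames(as.list(unname(b$seg_pct)),
                                    aha_segment_names()),
         regions = list(base = b$base, mid = b$mid, apex = b$apex,
                        overall = b$overall),
         metrics = result$metrics,
         views = result$views,
         config = config_echo(result$config)),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv_path, json_path))
}

#' Read a bullseye CSV written by [write_report()]
#'
#' @param path path to a `*_bullseye.csv` file.
#' @return a [bullseye17()] object.
#' @export
read_bullseye <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "ind_pct")
  if (!all(need %in% names(df)))
    stop("bullseye CSV needs columns ", paste(need, collapse = ", "))
  df <- df[order(df$segment_id), ]
  if (!identical(as.integer(df$segment_id), 1:17))
    stop("bullseye CSV must hold segments 1..17")
  bullseye17(df$ind_pct,
             n_points = if ("n_points" %in% names(df)) df$n_points else NULL)
}
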