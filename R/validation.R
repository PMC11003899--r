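# Scoring detections against a reference (planted ground truth or a
# manual observer count): one-to-one matching, false-positive and
# false-negative rates relative to the reference count.

#' Match detections to reference glomeruli
#'
#' Greedy one-to-one matching in physical coordinates: a detection is
#' eligible for a reference glomerulus when its centroid falls inside
#' the reference ellipse footprint (\code{criterion = "footprint"}) or
#' within \code{radius_um} of a reference point
#' (\code{criterion = "radius"}). Eligible pairs are accepted in order
#' of increasing centroid distance, each side at most once. Unmatched
#' detections are false positives, unmatched references false
#' negatives.
#'
#' @param detected \code{detected_objects} data.frame with
#'   centroid_x_um / centroid_y_um.
#' @param reference ground-truth glomerulus table (columns cx_um,
#'   cy_um and, for the footprint criterion, axis_a_um, axis_b_um and
#'   optionally theta) or a point list (cx_um, cy_um).
#' @param criterion \code{"footprint"} or \code{"radius"}.
#' @param radius_um match radius for point references; the default is
#'   the radius of the smallest keepable glomerulus,
#'   \code{sqrt(10000/pi)} (about 56 um).
#' @return an object of class \code{match_result}: counts
#'   (n_reference, n_algorithm, n_matched, n_false_positive,
#'   n_false_negative) and the matched pair table.
#' @export
match_objects <- function(detected, reference,
                          criterion = c("footprint", "radius"),
                          radius_um = sqrt(10000 / pi)) {
  criterion <- match.arg(criterion)
  if (criterion == "footprint" &&
      !all(c("axis_a_um", "axis_b_um") %in% names(reference)))
    criterion <- "radius"
  nd <- nrow(detected); nr <- nrow(reference)
  pairs <- NULL
  if (nd > 0 && nr > 0) {
    dx <- outer(detected$centroid_x_um, reference$cx_um, "-")
    dy <- outer(detected$centroid_y_um, reference$cy_um, "-")
    dist <- sqrt(dx^2 + dy^2)
    if (criterion == "footprint") {
      th <- if ("theta" %in% names(reference)) reference$theta else rep(0, nr)
      xr <- sweep(dx, 2, cos(th), "*") + sweep(dy, 2, sin(th), "*")
      yr <- sweep(-dx, 2, sin(th), "*") + sweep(dy, 2, cos(th), "*")
      elig <- sweep(xr^2, 2, reference$axis_a_um^2, "/") +
        sweep(yr^2, 2, reference$axis_b_um^2, "/") <= 1
    } else {
      elig <- dist <= radius_um
    }
    idx <- which(elig, arr.ind = TRUE)
    if (nrow(idx)) {
      ord <- order(dist[idx])
      idx <- idx[ord, , drop = FALSE]
      used_d <- logical(nd); used_r <- logical(nr)
      keep <- logical(nrow(idx))
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1]; j <- idx[k, 2]
        if (!used_d[i] && !used_r[j]) {
          used_d[i] <- used_r[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      m <- idx[keep, , drop = FALSE]
      pairs <- data.frame(
        detected_id = detected$object_id[m[, 1]],
        reference_id = reference$id[m[, 2]] %||% m[, 2],
        distance_um = dist[m]
      )
    }
  }
  n_matched <- if (is.null(pairs)) 0L else nrow(pairs)
  structure(list(
    n_reference = nr, n_algorithm = nd, n_matched = n_matched,
    n_false_positive = nd - n_matched, n_false_negative = nr - n_matched,
    pairs = pairs %||% data.frame(detected_id = integer(0),
                                  reference_id = integer(0),
                                  distance_um = numeric(0))
  ), class = "match_result")
}

#' False-positive and false-negative rates
#'
#' Both rates are expressed as percentages of the reference count
#' (the convention used when an algorithm is audited against a manual
#' observer). The precision/recall convention is reported alongside.
#'
#' @param match a \code{match_result}.
#' @param digits rounding for the reported percentages (default 2).
#' @return list: fp_percent, fn_percent (of n_reference), plus
#'   precision and recall.
#' @export
error_rates <- function(match, digits = 2) {
  stopifnot(inherits(match, "match_result"))
  if (match$n_reference == 0L) stopf("reference count is 0: rates undefined")
  list(
    fp_percent = round(100 * match$n_false_positive / match$n_reference, digits),
    fn_percent = round(100 * match$n_false_negative / match$n_reference, digits),
    precision = if (match$n_algorithm > 0) match$n_matched / match$n_algorithm else NA_real_,
    recall = match$n_matched / match$n_reference
  )
}

#' Validation report over slides
#'
#' @param matches named list of \code{match_result}s (names = slide
#'   ids).
#' @return data.frame: slide_id, n_reference, n_algorithm, n_fp, n_fn,
#'   fp_percent, fn_percent.
#' @export
validation_report <- function(matches) {
  rows <- lapply(names(matches), function(id) {
    m <- matches[[id]]
    r <- error_rates(m)
    data.frame(slide_id = id, n_reference = m$n_reference,
               n_algorithm = m$n_algorithm, n_fp = m$n_false_positive,
               n_fn = m$n_false_negative, fp_percent = r$fp_percent,
               fn_percent = r$fn_percent)
  })
  do.call(rbind, rows)
}
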