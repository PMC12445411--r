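#  AHA 16-segment parcellation of short-axis slices, with the standard
#  coronary-territory grouping. Segment IDs: basal 1-6, mid 7-12, apical
#  13-16 (the apical-cap segment 17 is not part of the 16-segment model).

slice_offsets <- c(basal = 0L, mid = 6L, apical = 12L)
slice_n_segments <- c(basal = 6L, mid = 6L, apical = 4L)

#' Segment IDs belonging to a slice
#'
#' @param slice `"basal"`, `"mid"` or `"apical"`.
#' @return integer vector of AHA segment IDs (1-6, 7-12 or 13-16).
#' @export
slice_segments <- function(slice) {
  if (length(slice) != 1 || !slice %in% names(slice_offsets)) {
    stop_tp("unknown slice label %s (expected basal, mid or apical)",
            deparse(substitute(slice)))
  }
  seq_len(slice_n_segments[[slice]]) + slice_offsets[[slice]]
}

#' Coronary territory of each AHA segment
#'
#' The fixed 16-segment territory map: LAD {1,2,7,8,13,14},
#' RCA {3,4,9,10,15}, LCX {5,6,11,12,16}.
#'
#' @return named character vector of length 16 mapping segment ID to
#'   `"LAD"`, `"RCA"` or `"LCX"`.
#' @export
territory_of_segments <- function() {
  map <- rep(NA_character_, 16)
  map[c(1, 2, 7, 8, 13, 14)] <- "LAD"
  map[c(3, 4, 9, 10, 15)] <- "RCA"
  map[c(5, 6, 11, 12, 16)] <- "LCX"
  stats::setNames(map, as.character(1:16))
}

#' @rdname territory_of_segments
#' @param segment integer segment ID(s) in 1..16.
#' @export
territory_of <- function(segment) {
  if (any(!segment %in% 1:16)) {
    stop_tp("segment ID out of range: the 16-segment model has IDs 1..16 (no apical cap)")
  }
  unname(territory_of_segments()[as.character(segment)])
}

#' Parcellate a slice into AHA segments
#'
#' Labels every myocardial pixel by the angular sector that contains its
#' direction from the blood-pool centre: six 60-degree sectors on basal and
#' mid slices, four 90-degree sectors on the apical slice. Sector boundaries
#' are anchored at the anterior RV-insertion angle; numbering proceeds
#' counter-clockwise from that anchor in the (x, y) frame, the AHA
#' convention in standard display orientation.
#'
#' @param masks a [assign_layers()] result.
#' @param contours the [contour_set()] used to build the masks; must carry an
#'   `rv_insertion` landmark.
#' @param slice `"basal"`, `"mid"` or `"apical"`.
#' @return an object of class `segment_model`: integer `labels` matrix
#'   (0 = background), the slice label, the territory map and the reference
#'   angle (degrees).
#' @export
build_segments <- function(masks, contours, slice) {
  stopifnot(inherits(masks, "layer_masks"), inherits(contours, "contour_set"))
  if (length(slice) != 1 || !slice %in% names(slice_offsets)) {
    stop_tp("unknown slice label (expected basal, mid or apical)")
  }
  if (is.null(contours$rv_insertion)) {
    stop_tp("contours carry no rv_insertion landmark; it is required to anchor segments")
  }
  center <- blood_pool_center(contours)
  ref <- atan2(contours$rv_insertion[2] - center[2],
               contours$rv_insertion[1] - center[1])
  n_seg <- slice_n_segments[[slice]]
  span <- 2 * pi / n_seg
  x <- (col(masks$myocardium) - 0.5) * masks$spacing[2]
  y <- (row(masks$myocardium) - 0.5) * masks$spacing[1]
  rel <- (atan2(y - center[2], x - center[1]) - ref) %% (2 * pi)
  sector <- pmin(floor(rel / span) + 1, n_seg)
  labels <- matrix(0L, nrow(masks$myocardium), ncol(masks$myocardium))
  labels[masks$myocardium] <- as.integer(sector[masks$myocardium] + slice_offsets[[slice]])
  structure(list(labels = labels, slice = slice,
                 territory_of = territory_of_segments(),
                 reference_angle_deg = ref * 180 / pi),
            class = "segment_model")
}

#' @export
print.segment_model <- function(x, ...) {
  ids <- sort(unique(x$labels[x$labels > 0]))
  cat(sprintf("<segment_model> %s slice, segments %s, anchor %.1f deg\n",
              x$slice, paste(range(ids), collapse = "-"), x$reference_angle_deg))
  invisible(x)
}

#' Pixel mask of one or more segments
#'
#' @param segments a [build_segments()] result.
#' @param ids segment IDs to select.
#' @return logical matrix.
#' @export
segment_mask <- function(segments, ids) {
  stopifnot(inherits(segments, "segment_model"))
  matrix(segments$labels %in% ids, nrow(segments$labels), ncol(segments$labels))
}
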