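#' @title Lesion disconnectome construction
#' @description
#' Builds the individualized structural-disconnection (damage) matrix from
#' three co-registered inputs: a labeled parcellation volume (parcel labels
#' 1..N, 0 = background), a binary lesion mask on the same grid, and a set of
#' normative streamlines given as 3-D polylines in world (mm) coordinates.
#' The normative connectome counts streamlines per parcel pair; a streamline
#' is disrupted when any point of its (densely resampled) course falls inside
#' a lesion voxel; the damage matrix is the elementwise fraction
#' disrupted / normative, in [0, 1].
#' @name disconnectome
NULL

# Normalize a volume argument: RNifti image, or plain array (identity affine),
# or list(data=, affine=). Returns list(arr, affine, iaffine, voxdim).
.vol_info <- function(vol) {
  if (inherits(vol, "niftiImage")) {
    affine <- structure(RNifti::xform(vol), class = NULL)
    arr <- as.array(vol)
  } else if (is.list(vol) && !is.null(vol$data)) {
    arr <- vol$data
    affine <- if (is.null(vol$affine)) diag(4) else vol$affine
  } else {
    arr <- vol
    affine <- attr(vol, "affine")
    if (is.null(affine)) affine <- diag(4)
  }
  affine <- unclass(as.matrix(affine))
  list(arr = arr, affine = affine, iaffine = solve(affine),
       voxdim = sqrt(colSums(affine[1:3, 1:3]^2)))
}

# points: k x 3 world coords -> k x 3 zero-based voxel coordinates (continuous)
.world_to_voxel <- function(points, iaffine) {
  p <- cbind(points, 1) %*% t(iaffine)
  p[, 1:3, drop = FALSE]
}

.voxel_label <- function(vox, arr) {
  # vox: k x 3 continuous zero-based voxel coords; nearest-voxel lookup,
  # out-of-bounds -> NA
  idx <- round(vox) + 1
  dims <- dim(arr)
  ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
        idx[, 2] >= 1 & idx[, 2] <= dims[2] &
        idx[, 3] >= 1 & idx[, 3] <= dims[3]
  out <- rep(NA_real_, nrow(idx))
  if (any(ok)) out[ok] <- arr[idx[ok, , drop = FALSE]]
  out
}

#' Parcel labels at the two endpoints of a streamline
#'
#' Maps both endpoints through the inverse affine, rounds to the nearest
#' voxel and reads the parcel label. Returns the unordered pair of labels
#' when both fall inside distinct parcels (> 0); `NULL` when either endpoint
#' lies in background, outside the volume, or both lie in the same parcel
#' (same-parcel streamlines do not contribute to a zero-diagonal connectome).
#'
#' @param streamline numeric matrix (k x 3) of world coordinates, k >= 2.
#' @param atlas labeled parcellation volume (RNifti image, array with an
#'   `affine` attribute, or `list(data=, affine=)`).
#' @return Sorted integer pair `c(i, j)` with `i < j`, or `NULL`.
#' @export
endpointParcels <- function(streamline, atlas) {
  streamline <- as.matrix(streamline)
  if (nrow(streamline) < 2L) stop("streamline must have >= 2 points")
  v <- .vol_info(atlas)
  ends <- streamline[c(1L, nrow(streamline)), , drop = FALSE]
  labs <- .voxel_label(.world_to_voxel(ends, v$iaffine), v$arr)
  if (anyNA(labs) || any(labs <= 0) || labs[1] == labs[2]) return(NULL)
  sort(as.integer(labs))
}

#' Normative streamline-count connectome
#'
#' Counts, for every unordered parcel pair, the streamlines whose endpoints
#' fall in that pair (per [endpointParcels()]). Symmetric with zero diagonal.
#'
#' @param streamlines list of k x 3 polyline matrices (world mm).
#' @param atlas labeled parcellation volume (see [endpointParcels()]).
#' @param nParcels number of parcels N; defaults to the maximum atlas label.
#' @return N x N integer matrix of streamline counts.
#' @export
normativeConnectome <- function(streamlines, atlas, nParcels = NULL) {
  v <- .vol_info(atlas)
  if (is.null(nParcels)) nParcels <- as.integer(max(v$arr))
  counts <- matrix(0L, nParcels, nParcels)
  for (s in streamlines) {
    pr <- endpointParcels(s, atlas)
    if (!is.null(pr)) {
      counts[pr[1], pr[2]] <- counts[pr[1], pr[2]] + 1L
      counts[pr[2], pr[1]] <- counts[pr[2], pr[1]] + 1L
    }
  }
  counts
}

# Arc-length resampling of a polyline to spacing <= h (keeps all vertices).
.resample_polyline <- function(points, h) {
  k <- nrow(points)
  if (k < 2L) return(points)
  out <- vector("list", k - 1L)
  for (i in seq_len(k - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / h))
    tt <- seq(0, 1, length.out = nseg + 1L)
    out[[i]] <- cbind(a[1] + tt * (b[1] - a[1]),
                      a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Does a streamline pass through the lesion?
#'
#' The polyline is resampled at no more than half a voxel edge of arc-length
#' spacing (so a segment cannot jump over a lesion voxel), each sample is
#' voxelized by nearest-voxel rounding, and the function returns `TRUE` iff
#' any sample lands in a nonzero lesion voxel. Intersection anywhere along
#' the course counts as disruption, not only at the termination points.
#'
#' @param streamline numeric matrix (k x 3) of world coordinates.
#' @param lesionMask binary lesion volume (same conventions as the atlas).
#' @return logical scalar.
#' @export
streamlineHitsLesion <- function(streamline, lesionMask) {
  v <- .vol_info(lesionMask)
  if (!any(v$arr != 0)) return(FALSE)
  h <- 0.5 * min(v$voxdim)
  pts <- .resample_polyline(as.matrix(streamline), h)
  labs <- .voxel_label(.world_to_voxel(pts, v$iaffine), v$arr)
  any(!is.na(labs) & labs != 0)
}

#' Disrupted streamline-count connectome
#'
#' Like [normativeConnectome()], restricted to streamlines intersecting the
#' lesion (per [streamlineHitsLesion()]). Elementwise `disrupted <= normative`.
#'
#' @inheritParams normativeConnectome
#' @param lesionMask binary lesion volume on the atlas grid.
#' @return N x N integer matrix.
#' @export
disruptedConnectome <- function(streamlines, atlas, lesionMask,
                                nParcels = NULL) {
  hit <- vapply(streamlines, streamlineHitsLesion, logical(1),
                lesionMask = lesionMask)
  normativeConnectome(streamlines[hit], atlas, nParcels = nParcels %||%
                        as.integer(max(.vol_info(atlas)$arr)))
}

#' Structural-disconnection (damage) matrix from a tractogram fixture
#'
#' `SD[i, j]` is the fraction of normative streamlines between parcels i and
#' j that the lesion transects: `disrupted / normative` where
#' `normative > 0`, else 0. Stored as a fraction in [0, 1] (not a
#' percentage), symmetric with zero diagonal.
#'
#' @param tractogram a fixture as produced by [makeTractogramFixture()], or
#'   any list with elements `streamlines`, `atlas`, `lesionMask` (and
#'   optionally `nParcels`).
#' @return list with `damage` (N x N in [0, 1]), `normative` and `disrupted`
#'   count matrices.
#' @export
lesionDamageMatrix <- function(tractogram) {
  atlas <- tractogram$atlas
  n <- tractogram$nParcels %||% as.integer(max(.vol_info(atlas)$arr))
  normative <- normativeConnectome(tractogram$streamlines, atlas, n)
  disrupted <- disruptedConnectome(tractogram$streamlines, atlas,
                                   tractogram$lesionMask, n)
  sd_mat <- matrix(0, n, n)
  pos <- normative > 0L
  sd_mat[pos] <- disrupted[pos] / normative[pos]
  list(damage = sd_mat, normative = normative, disrupted = disrupted)
}

#' Read streamlines from a TSV polyline table
#'
#' Expects columns `streamline_id`, `x`, `y`, `z`; rows of one streamline are
#' consecutive and ordered. (Readers for binary TRK/TCK tractography formats
#' are intentionally not provided; convert to this text format upstream.)
#'
#' @param file path to the TSV file.
#' @return list of k x 3 matrices, one per streamline id (in order of first
#'   appearance).
#' @export
readStreamlinesTSV <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE)
  need <- c("streamline_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("streamline TSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$streamline_id)
  lapply(ids, function(i) {
    as.matrix(df[df$streamline_id == i, c("x", "y", "z")])
  })
}

#' Write streamlines to the TSV polyline format
#'
#' @param streamlines list of k x 3 matrices.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeStreamlinesTSV <- function(streamlines, file) {
  rows <- lapply(seq_along(streamlines), function(i) {
    m <- streamlines[[i]]
    data.frame(streamline_id = i - 1L, x = m[, 1], y = m[, 2], z = m[, 3])
  })
  write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
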