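#' Segmentation volume
#'
#' @param labels 3D nonnegative integer array.
#' @param affine 4x4 voxel-to-world map.
#' @param dictionary optional data.frame (columns `label`, `name`) mapping
#'   label IDs to region names.
#' @export
segmentation_volume <- function(labels, affine = diag(4), dictionary = NULL) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3, all(labels >= 0))
  structure(list(labels = labels, affine = affine, dictionary = dictionary),
            class = "segmentation_volume")
}

seg_labels <- function(x) {
  if (inherits(x, "segmentation_volume")) x$labels
  else if (inherits(x, "label_volume")) x$labels
  else as.array(x)
}

#' Dice overlap of one label between two segmentations
#'
#' `2 |A n B| / (|A| + |B|)` over the voxel sets carrying `label`. By
#' convention the score is 1 when the label is absent from both volumes and
#' 0 when it is absent from exactly one. Both volumes must share a grid
#' (resample first with [resample_labels_nn()] if needed; resampling
#' affects scores, so it is never done implicitly).
#'
#' @param a,b segmentations ([segmentation_volume()], [label_volume()] or
#'   plain integer arrays) on the same grid.
#' @param label the label ID to score.
#' @return Dice coefficient in [0, 1].
#' @export
dice_score <- function(a, b, label) {
  la <- seg_labels(a); lb <- seg_labels(b)
  if (!all(dim(la) == dim(lb)))
    stop("segmentations are not on the same grid")
  ma <- la == label; mb <- lb == label
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(1)
  2 * sum(ma & mb) / (na + nb)
}

#' Region-wise Dice table
#'
#' @inheritParams dice_score
#' @param labels integer vector of label IDs to score (default: the union
#'   of non-background labels in either volume, sorted).
#' @return data.frame with columns `label`, `name` (if a dictionary is
#'   available), `dice`, and `empty_empty` flagging the both-absent
#'   convention rows.
#' @export
region_dice_table <- function(a, b, labels = NULL) {
  la <- seg_labels(a); lb <- seg_labels(b)
  if (!all(dim(la) == dim(lb)))
    stop("segmentations are not on the same grid")
  present <- sort(setdiff(union(unique(as.vector(la)), unique(as.vector(lb))), 0))
  if (is.null(labels)) labels <- present
  unknown <- setdiff(labels, union(present, 0))
  dict <- if (inherits(a, "segmentation_volume")) a$dictionary else NULL
  out <- data.frame(label = as.integer(labels), dice = NA_real_,
                    empty_empty = FALSE)
  for (i in seq_along(labels)) {
    out$dice[i] <- dice_score(la, lb, labels[i])
    out$empty_empty[i] <- !any(la == labels[i]) && !any(lb == labels[i])
  }
  if (length(unknown) && all(out$empty_empty[match(unknown, out$label)]))
    slab_log("warn", sprintf("labels absent from both volumes: %s",
                             paste(unknown, collapse = ", ")))
  if (!is.null(dict))
    out$name <- dict$name[match(out$label, dict$label)]
  out[order(out$label), c(intersect(c("label", "name"), names(out)),
                          "dice", "empty_empty")]
}

#' Nearest-neighbor label resampling onto a target grid
#'
#' Maps each target voxel through the target affine to world space and back
#' through the source affine; labels are categorical so interpolation is
#' nearest-neighbor. Callers opt in explicitly: resampling changes Dice.
#'
#' @param seg a [segmentation_volume()].
#' @param target_dim integer target grid dimensions.
#' @param target_affine 4x4 voxel-to-world map of the target grid.
#' @export
resample_labels_nn <- function(seg, target_dim, target_affine) {
  stopifnot(inherits(seg, "segmentation_volume"), length(target_dim) == 3)
  d <- as.integer(target_dim)
  n <- prod(d)
  i <- rep_len(seq_len(d[1]), n)
  j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  k <- rep(seq_len(d[3]), each = d[1] * d[2])
  M <- solve(seg$affine) %*% target_affine
  si <- round(M[1, 1] * i + M[1, 2] * j + M[1, 3] * k + M[1, 4])
  sj <- round(M[2, 1] * i + M[2, 2] * j + M[2, 3] * k + M[2, 4])
  sk <- round(M[3, 1] * i + M[3, 2] * j + M[3, 3] * k + M[3, 4])
  ds <- dim(seg$labels)
  ok <- si >= 1 & si <= ds[1] & sj >= 1 & sj <= ds[2] & sk >= 1 & sk <= ds[3]
  out <- integer(n)
  out[ok] <- seg$labels[(sk[ok] - 1) * ds[1] * ds[2] + (sj[ok] - 1) * ds[1] + si[ok]]
  segmentation_volume(array(out, dim = d), target_affine, seg$dictionary)
}

#' Triangle surface mesh
#'
#' @param vertices N x 3 matrix of world coordinates (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param labels optional per-vertex parcel labels (length N).
#' @export
surface_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(vertices) >= 3,
            all(faces >= 1), all(faces <= nrow(vertices)))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(vertices))
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$labels)) "" else
                sprintf(", %d parcels", length(unique(x$labels)))))
  invisible(x)
}

# squared distances from point p (length 3) to a set of triangles given by
# vertex matrices A, B, C (k x 3): min over the interior projection (when
# the projection's barycentric coordinates are nonnegative) and the three
# boundary segments.
point_tri_dist2 <- function(p, A, B, C) {
  seg_d2 <- function(P, Q) {
    D <- Q - P
    W <- matrix(p, nrow(P), 3, byrow = TRUE) - P
    len2 <- rowSums(D * D)
    t <- ifelse(len2 > 0, pmin(pmax(rowSums(W * D) / len2, 0), 1), 0)
    E <- W - D * t
    rowSums(E * E)
  }
  d2 <- pmin(seg_d2(A, B), seg_d2(A, C), seg_d2(B, C))
  E0 <- B - A
  E1 <- C - A
  Nrm <- cbind(E0[, 2] * E1[, 3] - E0[, 3] * E1[, 2],
               E0[, 3] * E1[, 1] - E0[, 1] * E1[, 3],
               E0[, 1] * E1[, 2] - E0[, 2] * E1[, 1])
  n2 <- rowSums(Nrm * Nrm)
  W <- matrix(p, nrow(A), 3, byrow = TRUE) - A
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  d <- rowSums(E0 * W); e <- rowSums(E1 * W)
  det <- a * c - b * b
  s <- (c * d - b * e)
  t <- (a * e - b * d)
  inside <- det > 0 & s >= 0 & t >= 0 & (s + t) <= det
  if (any(inside)) {
    h <- rowSums(Nrm * W)^2 / pmax(n2, .Machine$double.xmin)
    d2[inside] <- pmin(d2[inside], h[inside])
  }
  d2
}

#' Closest-point distances from one mesh to another
#'
#' For every vertex of `src`, the Euclidean distance to the nearest point
#' on `ref`'s triangle set (point-to-triangle, not vertex-to-vertex). The
#' measure is asymmetric; evaluate both directions explicitly if a
#' symmetric summary is wanted.
#'
#' @param src,ref [surface_mesh()]es.
#' @return numeric vector of nonnegative distances (mm), one per `src`
#'   vertex.
#' @export
closest_point_distances <- function(src, ref) {
  stopifnot(inherits(src, "surface_mesh"), inherits(ref, "surface_mesh"))
  if (nrow(src$vertices) == 0 || nrow(ref$faces) == 0)
    stop("empty mesh")
  V <- ref$vertices
  A <- V[ref$faces[, 1], , drop = FALSE]
  B <- V[ref$faces[, 2], , drop = FALSE]
  C <- V[ref$faces[, 3], , drop = FALSE]
  ctr <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - ctr)^2), rowSums((B - ctr)^2),
                   rowSums((C - ctr)^2)))
  P <- src$vertices
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    dv2 <- (V[, 1] - p[1])^2 + (V[, 2] - p[2])^2 + (V[, 3] - p[3])^2
    ub <- sqrt(min(dv2))
    dc <- sqrt((ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2 + (ctr[, 3] - p[3])^2)
    cand <- which(dc - rad <= ub + 1e-12)
    d2 <- point_tri_dist2(p, A[cand, , drop = FALSE], B[cand, , drop = FALSE],
                          C[cand, , drop = FALSE])
    out[i] <- sqrt(min(d2))
  }
  out
}

#' Per-parcel mean distances and their grand mean
#'
#' Unweighted mean within each parcel; the grand value is the mean of the
#' parcel means (not vertex-weighted), so every labeled area contributes
#' equally regardless of its vertex count. Requested parcels with no
#' vertices are excluded and logged.
#'
#' @param distances per-vertex distances (e.g. from
#'   [closest_point_distances()]).
#' @param parcel_labels per-vertex parcel labels (same length).
#' @param parcels optional parcel set to report (default: all present).
#' @return list with `parcel` (data.frame parcel/mean/n_vertices) and
#'   `grand_mean`.
#' @export
mean_parcel_distance <- function(distances, parcel_labels, parcels = NULL) {
  stopifnot(length(distances) == length(parcel_labels))
  if (is.null(parcels)) parcels <- sort(unique(parcel_labels))
  empty <- setdiff(parcels, unique(parcel_labels))
  if (length(empty)) {
    slab_log("warn", sprintf("empty parcels excluded: %s",
                             paste(empty, collapse = ", ")))
    parcels <- setdiff(parcels, empty)
  }
  means <- vapply(parcels, function(pp) mean(distances[parcel_labels == pp]),
                  numeric(1))
  ns <- vapply(parcels, function(pp) sum(parcel_labels == pp), numeric(1))
  list(parcel = data.frame(parcel = parcels, mean = means, n_vertices = ns),
       grand_mean = mean(means))
}

#' Cortical thickness from white and pial surfaces
#'
#' Per white-matter-vertex closest-point distance to the pial surface
#' (one-directional).
#'
#' @param white,pial [surface_mesh()]es of the same hemisphere.
#' @return per-vertex thickness (mm), one value per `white` vertex.
#' @export
cortical_thickness <- function(white, pial) {
  closest_point_distances(white, pial)
}

#' Per-parcel absolute thickness error
#'
#' Compares two per-vertex thickness maps parcel-wise: the error of a
#' parcel is the absolute difference of its mean thicknesses, and the grand
#' value is the mean over parcels. Parcel-mean comparison is used (rather
#' than vertexwise differences) so meshes of different topology can be
#' compared through a shared parcellation.
#'
#' @param thickness_a,thickness_b per-vertex thickness maps.
#' @param labels_a per-vertex parcel labels for map a.
#' @param labels_b labels for map b (defaults to `labels_a`, i.e. shared
#'   topology).
#' @return list with `parcel` (data.frame parcel/mean_a/mean_b/abs_error)
#'   and `grand_mean`.
#' @export
thickness_error <- function(thickness_a, thickness_b, labels_a,
                            labels_b = labels_a) {
  pa <- sort(unique(labels_a)); pb <- sort(unique(labels_b))
  if (!identical(pa, pb)) stop("parcel sets disagree")
  ma <- vapply(pa, function(pp) mean(thickness_a[labels_a == pp]), numeric(1))
  mb <- vapply(pa, function(pp) mean(thickness_b[labels_b == pp]), numeric(1))
  err <- abs(ma - mb)
  list(parcel = data.frame(parcel = pa, mean_a = ma, mean_b = mb,
                           abs_error = err),
       grand_mean = mean(err))
}
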