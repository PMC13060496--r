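#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving data, affine (sform) and integer
#' datatypes across a round trip. Multi-channel (RGB) volumes are stored as
#' a 4th dimension of size 3. By package convention the AP axis is voxel
#' axis 3; `ap_axis` permutes the volume so that convention holds after
#' reading.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param ap_axis index of the anterior-posterior axis in the file (the
#'   volume is permuted so it becomes axis 3).
#' @return `read_volume`: list with `data` (array) and `affine` (4x4).
#' @export
read_volume <- function(path, ap_axis = 3L) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    format_error(sprintf("not a readable NIfTI file: %s (%s)",
                                         path, conditionMessage(e))))
  data <- as.array(img)
  # strip the niftiImage attributes down to a plain array
  data <- array(as.vector(data), dim = dim(data))
  affine <- structure(as.vector(RNifti::xform(img)), dim = c(4, 4))
  if (ap_axis != 3L) {
    stopifnot(ap_axis %in% 1:3)
    perm <- c(setdiff(1:3, ap_axis), ap_axis)
    if (length(dim(data)) == 4) perm <- c(perm, 4L)
    data <- aperm(data, perm)
    affine[, 1:3] <- affine[, perm[1:3]]
  }
  list(data = data, affine = affine)
}

#' @rdname read_volume
#' @param data numeric or integer array (3D, or 4D with channels last).
#' @param affine 4x4 voxel-to-world matrix written as the s/qform.
#' @param datatype NIfTI datatype; integer input defaults to `"int32"`,
#'   numeric to `"double"`.
#' @export
write_volume <- function(data, path, affine = diag(4), datatype = NULL) {
  if (is.null(datatype))
    datatype <- if (is.integer(data) || inherits(data, "label_volume"))
      "int32" else "double"
  if (inherits(data, "label_volume")) {
    affine <- data$affine
    data <- data$labels
  }
  storage.mode(data) <- if (datatype == "int32") "integer" else "double"
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write triangle meshes (ASCII OFF format)
#'
#' Plain-text OFF: a header line `OFF`, a count line
#' `n_vertices n_faces 0`, then vertex coordinate lines and face lines
#' (`3 i j k`, zero-based indices). Per-vertex parcel labels, when present,
#' travel in a sidecar file `<path>.labels` (one integer per line).
#'
#' @param path mesh file path.
#' @return `read_mesh`: a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2 || trimws(lines[1]) != "OFF")
    format_error(sprintf("not an OFF mesh file: %s", path))
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf)
    format_error("truncated OFF file")
  vt <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"))),
               ncol = 3, byrow = TRUE)
  fc <- matrix(as.integer(unlist(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]),
                                          "\\s+"))), ncol = 4, byrow = TRUE)
  if (any(fc[, 1] != 3L)) format_error("only triangle faces are supported")
  faces <- fc[, 2:4, drop = FALSE] + 1L
  if (any(faces < 1) || any(faces > nv))
    format_error("face index out of range")
  labels <- NULL
  lab_path <- paste0(path, ".labels")
  if (file.exists(lab_path)) {
    labels <- as.integer(readLines(lab_path))
    if (length(labels) != nv)
      format_error("label sidecar length does not match vertex count")
  }
  surface_mesh(vt, faces, labels)
}

#' @rdname read_mesh
#' @param mesh a [surface_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  if (!is.null(mesh$labels))
    writeLines(as.character(mesh$labels), paste0(path, ".labels"))
  invisible(path)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with vertices projected onto the sphere of the
#' requested radius; the standard well-conditioned sphere tessellation used
#' as an analytic fixture for the surface metrics.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = plain
#'   icosahedron with 12 vertices; each level roughly quadruples faces).
#' @param center sphere center (length-3).
#' @return a [surface_mesh()].
#' @export
make_sphere_mesh <- function(radius, subdivisions = 3L, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vts <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vts[[length(vts) + 1L]] <<- m
      edge_mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vts)
    f <- nf
  }
  vt <- v * radius
  vt <- sweep(vt, 2, center, "+")
  surface_mesh(vt, f)
}
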