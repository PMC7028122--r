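#' Landmark representation of a face
#'
#' A face is represented by 127 planar feature points (head shape, hairline
#' and internal feature locations) in an arbitrary but consistent coordinate
#' system. All dissimilarity arithmetic operates on these point sets; no
#' image data is involved.
#'
#' @param points numeric matrix with 127 rows and 2 columns (x, y), or an
#'   object coercible to one. All coordinates must be finite.
#' @param id character identifier for the face.
#' @return an object of class \code{landmark_face} with elements
#'   \code{points} (127 x 2 matrix) and \code{id}.
#' @examples
#' f <- landmark_face(matrix(rnorm(254), ncol = 2), id = "demo")
#' face_dissimilarity(f, f)  # 0
#' @export
landmark_face <- function(points, id = "face") {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("'points' must be a numeric matrix with two columns (x, y)",
         call. = FALSE)
  if (nrow(points) != 127L)
    stop(sprintf("a landmark face has exactly 127 points; got %d",
                 nrow(points)), call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates must all be finite", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, id = as.character(id)),
            class = "landmark_face")
}

#' @export
print.landmark_face <- function(x, ...) {
  cat(sprintf("<landmark_face '%s': 127 points, bbox x [%.3g, %.3g], y [%.3g, %.3g]>\n",
              x$id, min(x$points[, 1]), max(x$points[, 1]),
              min(x$points[, 2]), max(x$points[, 2])))
  invisible(x)
}

check_landmark_pair <- function(a, b) {
  if (!inherits(a, "landmark_face") || !inherits(b, "landmark_face"))
    stop("both arguments must be 'landmark_face' objects", call. = FALSE)
  if (nrow(a$points) != nrow(b$points))
    stop("landmark point counts differ between faces", call. = FALSE)
  invisible(NULL)
}

#' Landmark-space dissimilarity between two faces
#'
#' The dissimilarity axis of the face-discrimination test: the Euclidean
#' distance between two faces' stacked landmark vectors, i.e. the square
#' root of the summed squared coordinate differences over all 127 points.
#' Units are denoted \emph{d}; larger values are easier discriminations.
#'
#' @param standard,target \code{landmark_face} objects with corresponding
#'   point order.
#' @return a non-negative scalar, symmetric in its arguments.
#' @export
face_dissimilarity <- function(standard, target) {
  check_landmark_pair(standard, target)
  sqrt(sum((standard$points - target$points)^2))
}

#' Morph a face away from a reference
#'
#' Moves every landmark \code{pct}/100 of the way along the (face - reference)
#' direction beyond the face itself (linear extrapolation), producing a
#' progressively more dissimilar version of \code{face} relative to
#' \code{reference}. \code{pct = 0} returns the face unchanged; the
#' dissimilarity from the reference grows linearly in \code{pct}.
#'
#' @param face,reference \code{landmark_face} objects with matching point
#'   order.
#' @param pct percentage of extrapolation (scalar; may be negative, which
#'   interpolates back towards the reference).
#' @return a new \code{landmark_face}.
#' @export
morph_face <- function(face, reference, pct) {
  check_landmark_pair(face, reference)
  assert_scalar_number(pct, "pct")
  pts <- face$points + (pct / 100) * (face$points - reference$points)
  landmark_face(pts, id = sprintf("%s+%g%%", face$id, pct))
}

#' Read / write landmark files
#'
#' Plain-text format: 127 lines, each "x y" (whitespace separated). The
#' reader validates the point count.
#'
#' @param path file path.
#' @param id face identifier for the returned object (defaults to the file
#'   base name).
#' @return \code{read_landmarks} returns a \code{landmark_face};
#'   \code{write_landmarks} invisibly returns \code{path}.
#' @export
read_landmarks <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such landmark file: ", path, call. = FALSE)
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y")))
  landmark_face(m, id = id)
}

#' @rdname read_landmarks
#' @param face a \code{landmark_face} to write.
#' @export
write_landmarks <- function(face, path) {
  if (!inherits(face, "landmark_face"))
    stop("'face' must be a landmark_face", call. = FALSE)
  utils::write.table(face$points, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
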