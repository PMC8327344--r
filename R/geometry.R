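#' Minimum-image distance under an orthorhombic periodic box
#'
#' Euclidean distance between two points after applying the minimum-image
#' convention independently along each axis of an orthorhombic box.
#'
#' @param a,b numeric 3-vectors, Angstrom.
#' @param box numeric 3-vector of orthorhombic box edge lengths (Angstrom).
#' @return distance in Angstrom (non-negative scalar).
#' @examples
#' min_image_distance(c(0.5, 0, 0), c(99.5, 0, 0), c(100, 100, 100))  # 1
#' @export
min_image_distance <- function(a, b, box) {
  check_box(box)
  d <- min_image_disp(rbind(as.numeric(a)), rbind(as.numeric(b)), box)
  sqrt(sum(d^2))
}

## Row-wise minimum-image displacement a - b (matrices n x 3), vectorized.
min_image_disp <- function(a, b, box) {
  d <- a - b
  for (k in 1:3) {
    L <- box[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
  }
  d
}

## All-pairs minimum-image distance matrix between coordinate sets
## x (n x 3) and y (m x 3).  Dense by design: the systems this package
## targets are small enough that the O(nm) matrix is cheaper than
## maintaining cell lists, and it is exactly the all-pairs contract the
## contact analysis promises.
min_image_dist_matrix <- function(x, y, box) {
  n <- nrow(x); m <- nrow(y)
  acc <- matrix(0, n, m)
  for (k in 1:3) {
    L <- box[k]
    d <- outer(x[, k], y[, k], "-")
    d <- d - L * round(d / L)
    acc <- acc + d * d
  }
  sqrt(acc)
}

## Wrap coordinates into [origin, origin + box) along each axis.
wrap_coords <- function(xyz, box, origin = c(0, 0, 0)) {
  for (k in 1:3) {
    L <- box[k]
    xyz[, k] <- origin[k] + ((xyz[, k] - origin[k]) %% L)
    ## guard: x %% L can return L itself when x is a tiny negative number
    xyz[xyz[, k] >= origin[k] + L, k] <- origin[k]
  }
  xyz
}

check_box <- function(box) {
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths (Angstrom); ",
         "triclinic boxes are not supported", call. = FALSE)
  invisible(box)
}
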