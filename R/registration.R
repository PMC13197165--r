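#' Rigid 3D transforms between dual-view acquisitions
#'
#' Opposing views of the same sample are related, to a good approximation, by
#' a rigid transform: a 180 degree flip about the X axis plus a small residual
#' rotation and translation. Transforms are stored as a proper rotation
#' matrix, a translation and a rotation centre, all in physical um
#' coordinates ordered (z, y, x). A point `x` maps to
#' `R (x - centre) + centre + translation`.
#'
#' @param rotation 3x3 proper rotation matrix, or length-3 Euler angles in
#'   degrees applied in Z, then Y, then X order (intrinsic axes of the
#'   physical z/y/x frame).
#' @param translation length-3 translation in um (z, y, x).
#' @param centre length-3 rotation centre in um.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            centre = c(0, 0, 0)) {
  R <- if (is.matrix(rotation)) rotation else euler_zyx(rotation)
  if (!all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation must be a proper orthonormal 3x3 matrix")
  structure(list(R = R, t = as.numeric(translation),
                 centre = as.numeric(centre)),
            class = "rigid_transform")
}

# rotation matrix from Euler angles (degrees) about the z, y, x axes of the
# (z, y, x)-ordered physical frame; "rotation about X" mixes z and y etc.
euler_zyx <- function(angles_deg) {
  a <- angles_deg * pi / 180
  # axis k leaves coordinate k fixed; coordinates ordered (z, y, x)
  rot_about <- function(axis, th) {
    R <- diag(3)
    ij <- setdiff(1:3, axis)
    R[ij[1], ij[1]] <- cos(th); R[ij[2], ij[2]] <- cos(th)
    R[ij[1], ij[2]] <- -sin(th); R[ij[2], ij[1]] <- sin(th)
    R
  }
  # angles given as (about Z, about Y, about X) = axes (1, 2, 3) of the frame
  rot_about(3, a[3]) %*% rot_about(2, a[2]) %*% rot_about(1, a[1])
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation (3x3):\n")
  print(round(x$R, 6))
  cat(sprintf("  translation: %s um\n  centre: %s um\n",
              paste(round(x$t, 3), collapse = ", "),
              paste(round(x$centre, 3), collapse = ", ")))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' 180 degree flip about the X axis (the slide-flip preset)
#'
#' Re-imaging a mounted sample from the opposite side corresponds to flipping
#' the slide about X: z and y are negated about the stack centre.
#'
#' @param image image whose physical centre is used as rotation centre, or
#'   `NULL` with an explicit `centre`.
#' @param centre rotation centre in um, used when `image` is `NULL`.
#' @return `rigid_transform`.
#' @export
rigid_flip_x <- function(image = NULL, centre = NULL) {
  if (!is.null(image))
    centre <- (dim(image) - 1) * vox_spacing(image) / 2
  if (is.null(centre)) stop("need an image or an explicit centre")
  rigid_transform(euler_zyx(c(0, 0, 180)), centre = centre)
}

as_affine <- function(T) {
  A <- diag(4)
  A[1:3, 1:3] <- T$R
  A[1:3, 4] <- T$t + T$centre - T$R %*% T$centre
  A
}

from_affine <- function(A) {
  rigid_transform(A[1:3, 1:3], translation = A[1:3, 4], centre = c(0, 0, 0))
}

#' @describeIn rigid_transform compose two transforms (`first` applied first).
#' @param second,first transforms to compose.
#' @export
compose_rigid <- function(second, first) {
  from_affine(as_affine(second) %*% as_affine(first))
}

#' @describeIn rigid_transform inverse transform.
#' @param T a `rigid_transform`.
#' @export
invert_rigid <- function(T) {
  from_affine(solve(as_affine(T)))
}

#' @describeIn rigid_transform apply a transform to an `n x 3` matrix of
#'   physical points (um).
#' @param points n x 3 matrix.
#' @export
transform_points <- function(T, points) {
  A <- as_affine(T)
  p <- as.matrix(points)
  t(A[1:3, 1:3] %*% t(p) + A[1:3, 4])
}

#' Pair opposing-view acquisitions by stage position
#'
#' Samples imaged from both sides of a slide are matched by minimising the
#' total distance between their recorded XY stage positions with a linear
#' assignment (positions of the second side must already be expressed in the
#' flipped frame). When the lists differ in length the surplus entries are
#' left unmatched and reported.
#'
#' @param positions_a,positions_b matrices (n x 2) of XY positions in um.
#' @param ambiguity_tol warn if swapping any two matches changes the total
#'   cost by less than this (grossly ambiguous pairing).
#' @return data.frame with columns `a`, `b`, `distance`; unmatched indices in
#'   attribute `unmatched` (list with `a`, `b`).
#' @export
pair_views <- function(positions_a, positions_b, ambiguity_tol = 1e-6) {
  pa <- as.matrix(positions_a); pb <- as.matrix(positions_b)
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("empty position list")
  cost <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                function(i, j) sqrt((pa[i, 1] - pb[j, 1])^2 +
                                      (pa[i, 2] - pb[j, 2])^2))
  swap <- nrow(pa) > nrow(pb)
  cm <- if (swap) t(cost) else cost
  assign <- solve_assignment(cm)
  rows <- seq_len(nrow(cm))
  if (swap) {
    res <- data.frame(a = assign, b = rows)
  } else {
    res <- data.frame(a = rows, b = assign)
  }
  res$distance <- cost[cbind(res$a, res$b)]
  res <- res[order(res$a), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unmatched") <- list(
    a = setdiff(seq_len(nrow(pa)), res$a),
    b = setdiff(seq_len(nrow(pb)), res$b))
  # cheap ambiguity check: any pairwise swap almost as good?
  n <- nrow(res)
  if (n >= 2) {
    best <- sum(res$distance)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      alt <- best - res$distance[i] - res$distance[j] +
        cost[res$a[i], res$b[j]] + cost[res$a[j], res$b[i]]
      if (alt - best < ambiguity_tol) {
        warning(sprintf(
          "ambiguous pairing: swapping matches %d and %d costs %.6g vs %.6g",
          i, j, alt, best))
      }
    }
  }
  res
}

# Jonker-Volgenant style shortest-augmenting-path linear assignment,
# minimizing total cost; cost is n x m with n <= m. Returns the assigned
# column for each row.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1L)        # v[j + 1], j = 0..m (0 = sentinel column)
  p <- integer(m + 1L)        # p[j + 1] = row matched to column j
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) if (!used[j + 1L]) {
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}

#' Least-squares rigid fit from matched landmarks
#'
#' Singular value decomposition of the cross-covariance of matched point sets
#' yields the optimal rotation (reflections are corrected by flipping the
#' smallest singular direction) and translation.
#'
#' @param src,dst matched n x 3 point matrices (um), n >= 3, not collinear.
#' @return `rigid_transform` mapping `src` onto `dst`; attribute `rms` holds
#'   the root-mean-square residual in um.
#' @export
fit_rigid_landmarks <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) stop("point counts differ")
  if (nrow(src) < 3) stop("need at least 3 landmark pairs")
  cs <- colMeans(src); cd <- colMeans(dst)
  X <- sweep(src, 2, cs); Y <- sweep(dst, 2, cd)
  if (svd(X)$d[2] < 1e-9 * max(svd(X)$d[1], 1))
    stop("landmarks are collinear: rotation underdetermined")
  H <- crossprod(X, Y)
  s <- svd(H)
  S <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% S %*% t(s$u)
  tr <- cd - as.numeric(R %*% cs)
  T <- rigid_transform(R, translation = tr)
  res <- transform_points(T, src) - dst
  attr(T, "rms") <- sqrt(mean(rowSums(res^2)))
  T
}

#' Resample an image under a rigid transform
#'
#' The transform maps source coordinates to target coordinates; the image is
#' resampled on the output grid by inverse mapping, trilinearly for
#' intensities and nearest-neighbour for labels. Voxels that map outside the
#' source volume are filled with 0 and flagged invalid.
#'
#' @param image `voxel_image` or `label_image`.
#' @param T `rigid_transform` (source -> target, physical um).
#' @param output_grid list with `dim` and `spacing` of the target grid;
#'   defaults to the input grid.
#' @return resampled image of the same type; attribute `valid` is a logical
#'   array marking voxels sampled from inside the source.
#' @export
apply_rigid <- function(image, T, output_grid = NULL) {
  sp <- vox_spacing(image)
  if (is.null(output_grid)) output_grid <- list(dim = dim(image), spacing = sp)
  od <- output_grid$dim; osp <- output_grid$spacing
  is_lab <- inherits(image, "label_image")
  tgt <- as.matrix(expand.grid(z = axis_coords(od[1], osp[1]),
                               y = axis_coords(od[2], osp[2]),
                               x = axis_coords(od[3], osp[3])))
  srcpos <- transform_points(invert_rigid(T), tgt)
  idx <- um_to_index(srcpos, sp)
  vals <- interp3(unclass_arr(image), idx,
                  method = if (is_lab) "nearest" else "linear", fill = 0)
  valid <- array(attr(vals, "valid"), od)
  out <- array(as.numeric(vals), od)
  out <- if (is_lab) {
    storage.mode(out) <- "integer"
    labels3d(out, spacing = osp)
  } else vox(out, spacing = osp, channel = attr(image, "channel"))
  attr(out, "valid") <- valid
  out
}

#' Refine a rigid transform by grid search over small rotations
#'
#' Starting from an initial fit (e.g. from landmarks), searches residual Euler
#' angles on a coarse grid, re-centring translation on the masked centroids,
#' and keeps the candidate maximising the normalized cross-correlation between
#' the transformed floating image and the reference. Intended for the small
#' residual flip rotations (order 10 degrees) left after the slide-flip
#' preset.
#'
#' @param reference,floating `voxel_image`s (typically the ubiquitous nuclei
#'   channel, downsampled).
#' @param init initial `rigid_transform` (floating -> reference).
#' @param range_deg half-range of the search per axis, degrees.
#' @param step_deg grid step, degrees.
#' @return best `rigid_transform`; attribute `ncc` holds its score.
#' @export
refine_rigid <- function(reference, floating, init, range_deg = 15,
                         step_deg = 2.5) {
  angs <- seq(-range_deg, range_deg, by = step_deg)
  ref <- unclass_arr(reference)
  best <- NULL; best_ncc <- -Inf
  centre <- (dim(floating) - 1) * vox_spacing(floating) / 2
  for (az in angs) for (ay in angs) for (ax in angs) {
    dT <- rigid_transform(euler_zyx(c(az, ay, ax)), centre = centre)
    cand <- compose_rigid(init, dT)
    moved <- apply_rigid(floating, cand,
                         output_grid = list(dim = dim(reference),
                                            spacing = vox_spacing(reference)))
    ok <- attr(moved, "valid")
    if (sum(ok) < 10) next
    a <- ref[ok]; b <- unclass_arr(moved)[ok]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    ncc <- stats::cor(a, b)
    if (ncc > best_ncc) { best_ncc <- ncc; best <- cand }
  }
  if (is.null(best)) stop("no valid overlap in search range")
  attr(best, "ncc") <- best_ncc
  best
}

#' Serialize / read rigid transforms as JSON
#'
#' @param T `rigid_transform`.
#' @param path file path.
#' @return `write_rigid_json` returns `path` invisibly; `read_rigid_json`
#'   returns the `rigid_transform`.
#' @export
write_rigid_json <- function(T, path) {
  jsonlite::write_json(list(rotation = T$R, translation = T$t,
                            centre = T$centre,
                            convention = "zyx-um; x -> R(x-c)+c+t"),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rigid_json
#' @export
read_rigid_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- j$rotation
  if (!is.matrix(rot)) rot <- matrix(unlist(rot), 3, 3, byrow = TRUE)
  rigid_transform(rot, translation = j$translation, centre = j$centre)
}
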