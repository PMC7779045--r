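# Trajectory summary statistics: least-squares (Kabsch) superposition RMSD,
# per-atom RMSF about the iteratively refined average structure, and
# essential-dynamics PCA of the positional covariance.

#' Construct a trajectory
#'
#' @param coordinates numeric array of dimension frames x atoms x 3
#'   (Angstrom), or a frames x (3*atoms) matrix laid out x1,y1,z1,x2,...
#' @param frame_times optional per-frame times (ns).
#' @param atom_labels optional per-atom labels.
#' @return an object of class \code{trajectory}.
#' @export
trajectory <- function(coordinates, frame_times = NULL, atom_labels = NULL) {
  if (is.matrix(coordinates)) {
    if (ncol(coordinates) %% 3L != 0L)
      stop("flat coordinate matrix must have 3*atoms columns", call. = FALSE)
    natom <- ncol(coordinates) / 3L
    coordinates <- aperm(array(t(coordinates),
                               c(3L, natom, nrow(coordinates))), c(3L, 2L, 1L))
  }
  if (length(dim(coordinates)) != 3L || dim(coordinates)[3L] != 3L)
    stop("coordinates must be a frames x atoms x 3 array", call. = FALSE)
  if (any(!is.finite(coordinates)))
    stop("coordinates must be finite", call. = FALSE)
  structure(list(coords = coordinates, frame_times = frame_times,
                 atom_labels = atom_labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("trajectory:", d[1L], "frames x", d[2L], "atoms\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1L]
n_atoms <- function(traj) dim(traj$coords)[2L]
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Read a plain-text trajectory
#'
#' @param path whitespace- or tab-delimited file with columns frame, atom, x,
#'   y, z (header optional); frames and atoms may be arbitrary sorted labels.
#' @return a \code{trajectory}.
#' @export
read_trajectory <- function(path) {
  d <- utils::read.table(path, header = looks_like_header(path))
  if (ncol(d) < 5L)
    stop("trajectory table needs columns frame, atom, x, y, z", call. = FALSE)
  names(d)[1:5] <- c("frame", "atom", "x", "y", "z")
  frames <- sort(unique(d$frame)); atoms <- sort(unique(d$atom))
  arr <- array(NA_real_, c(length(frames), length(atoms), 3L))
  fi <- match(d$frame, frames); ai <- match(d$atom, atoms)
  arr[cbind(fi, ai, 1L)] <- d$x
  arr[cbind(fi, ai, 2L)] <- d$y
  arr[cbind(fi, ai, 3L)] <- d$z
  if (any(is.na(arr)))
    stop("trajectory is ragged: not every frame lists every atom",
         call. = FALSE)
  trajectory(arr, atom_labels = as.character(atoms))
}

looks_like_header <- function(path) {
  first <- readLines(path, n = 1L)
  is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                             "[ \t,]+")[[1L]][1L])))
}

#' Write a trajectory as plain text
#' @param traj a \code{trajectory}.
#' @param path output path (TSV with header frame, atom, x, y, z).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- dim(traj$coords)
  tab <- data.frame(frame = rep(seq_len(d[1L]), each = d[2L]),
                    atom = rep(seq_len(d[2L]), d[1L]),
                    x = as.vector(t(traj$coords[, , 1L])),
                    y = as.vector(t(traj$coords[, , 2L])),
                    z = as.vector(t(traj$coords[, , 3L])))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' \code{mobile} onto \code{reference}.
#'
#' @param reference,mobile atoms x 3 coordinate matrices (equal atom counts,
#'   at least 3 non-collinear atoms).
#' @return list with \code{rotation} (3 x 3, determinant +1),
#'   \code{translation} (length 3), \code{rmsd} (Angstrom) and \code{fitted}
#'   (the transformed mobile coordinates,
#'   \code{mobile \%*\% rotation + translation}).
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!identical(dim(reference), dim(mobile)))
    stop("coordinate sets differ in shape", call. = FALSE)
  if (nrow(reference) < 3L)
    stop("need at least 3 atoms to superpose", call. = FALSE)
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2L, cr); B <- sweep(mobile, 2L, cm)
  if (min(svd(A)$d) < 1e-10 * max(svd(A)$d, 1))
    stop("degenerate (collinear) reference configuration", call. = FALSE)
  H <- crossprod(B, A)                 # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)            # mobile %*% R aligns onto reference
  fitted <- B %*% R
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  fitted <- sweep(fitted, 2L, cr, "+")
  list(rotation = R, translation = cr - as.vector(cm %*% R), rmsd = rmsd,
       fitted = fitted)
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame is optimally superposed onto the reference frame before the
#' deviation is measured.
#'
#' @param traj a \code{trajectory}.
#' @param reference_frame index of the reference frame (default 1).
#' @param atoms optional atom index subset to fit and measure on.
#' @return numeric vector of per-frame RMSDs (Angstrom); zero at the
#'   reference index.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, atoms = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (reference_frame < 1L || reference_frame > n_frames(traj))
    stop("reference_frame out of range", call. = FALSE)
  sel <- if (is.null(atoms)) seq_len(n_atoms(traj)) else atoms
  ref <- frame_coords(traj, reference_frame)[sel, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(i)
    kabsch_superpose(ref, frame_coords(traj, i)[sel, , drop = FALSE])$rmsd, 0)
}

# superpose every frame onto a target structure; returns the array
superpose_all <- function(arr, target) {
  for (i in seq_len(dim(arr)[1L])) {
    m <- arr[i, , ]
    dim(m) <- dim(arr)[2:3]
    arr[i, , ] <- kabsch_superpose(target, m)$fitted
  }
  arr
}

# superposition onto the iteratively refined average structure: refit and
# re-average until the mean stops moving, so the result is invariant (to
# tight numerical tolerance) under arbitrary per-frame rigid motions
align_to_mean <- function(traj, atoms = NULL, max_iterations = 30L,
                          tol = 1e-12) {
  arr <- traj$coords
  if (!is.null(atoms)) arr <- arr[, atoms, , drop = FALSE]
  target <- apply(arr, c(2L, 3L), mean)
  for (k in seq_len(max_iterations)) {
    arr <- superpose_all(arr, target)
    new_target <- apply(arr, c(2L, 3L), mean)
    delta <- max(abs(new_target - target))
    target <- new_target
    if (k >= 2L && delta < tol) break
  }
  list(coords = arr, mean = target)
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed onto the average structure, the average is
#' recomputed and the fit repeated until the average converges; each atom's
#' RMS deviation from its mean position is then reported.
#'
#' @param traj a \code{trajectory} with at least two frames.
#' @param atoms optional atom index subset.
#' @return numeric vector, one value per (selected) atom (Angstrom).
#' @export
rmsf <- function(traj, atoms = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("need at least two frames", call. = FALSE)
  al <- align_to_mean(traj, atoms)
  dev <- sweep(al$coords, c(2L, 3L), al$mean)
  sqrt(apply(dev^2, 2L, function(a) mean(rowSums(matrix(a, ncol = 3L)))))
}

#' Essential dynamics (PCA of positional covariance)
#'
#' Frames are superposed onto the refined average structure as in
#' \code{rmsf}; the 3N-dimensional positional covariance is then
#' eigendecomposed. Eigenvalues are non-negative, in decreasing order, and
#' sum to the total positional variance.
#'
#' @param traj a \code{trajectory} with at least two frames.
#' @param n_components number of components to return (default: all with
#'   nonzero rank, capped at 3 * atoms).
#' @param atoms optional atom index subset.
#' @return list with \code{eigenvalues} (Angstrom^2), \code{eigenvectors}
#'   (3N x k, orthonormal columns), \code{projections} (frames x k) and
#'   \code{mean} (the average structure).
#' @export
essential_dynamics <- function(traj, n_components = NULL, atoms = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("need at least two frames", call. = FALSE)
  al <- align_to_mean(traj, atoms)
  nf <- dim(al$coords)[1L]; na <- dim(al$coords)[2L]
  X <- matrix(al$coords, nrow = nf)          # frames x (atoms*3), atom-major
  X <- sweep(X, 2L, colMeans(X))
  if (is.null(n_components)) n_components <- min(nf - 1L, 3L * na)
  if (n_components < 1L || n_components > 3L * na)
    stop("n_components must lie in 1..3*atoms", call. = FALSE)
  s <- svd(X, nu = 0, nv = min(3L * na, nf))
  eig <- s$d^2 / (nf - 1L)
  k <- n_components
  vecs <- s$v[, seq_len(min(k, ncol(s$v))), drop = FALSE]
  if (ncol(vecs) < k) {                      # pad with zero-variance directions
    eig <- c(eig, rep(0, k))
    pad <- matrix(0, nrow(vecs), k - ncol(vecs))
    vecs <- cbind(vecs, pad)
  }
  list(eigenvalues = eig[seq_len(k)], eigenvectors = vecs,
       projections = X %*% vecs, mean = al$mean)
}
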