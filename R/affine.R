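#' 12-parameter affine transform parameters
#'
#' Parameter vector for the world-to-world affine used in spatial
#' normalization: translations (mm), rotations (radians), zooms, shears,
#' composed in the fixed order translate o rotate o shear o zoom (zoom acts
#' first on coordinates).  All-default parameters give the identity matrix.
#'
#' @param tx,ty,tz translations, mm.
#' @param rx,ry,rz rotations about the x/y/z axes, radians.
#' @param zx,zy,zz zooms (must be > 0).
#' @param sxy,sxz,syz shears.
#' @return A named numeric vector of class `affine_params`.
#' @export
affine_params <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                          zx = 1, zy = 1, zz = 1, sxy = 0, sxz = 0, syz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz,
         zx = zx, zy = zy, zz = zz, sxy = sxy, sxz = sxz, syz = syz)
  if (any(p[7:9] <= 0)) stop("zooms must be > 0")
  structure(p, class = "affine_params")
}

as_affine_params <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 12L)
  affine_params(p[1], p[2], p[3], p[4], p[5], p[6], p[7], p[8], p[9],
                p[10], p[11], p[12])
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf(paste0("<affine_params> t = (%.2f, %.2f, %.2f) mm, ",
                     "r = (%.4f, %.4f, %.4f) rad,\n  z = (%.4f, %.4f, %.4f), ",
                     "shear = (%.4f, %.4f, %.4f)\n"),
              x[1], x[2], x[3], x[4], x[5], x[6], x[7], x[8], x[9],
              x[10], x[11], x[12]))
  invisible(x)
}

#' Build the 4x4 matrix of an `affine_params` vector
#'
#' @param p an [affine_params()] vector (or any numeric length 12 in the
#'   same order).
#' @return 4x4 world-to-world matrix.
#' @export
affine_matrix <- function(p) {
  p <- as.numeric(p)
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  M3 <- Rx %*% Ry %*% Rz %*% Sh %*% diag(p[7:9])
  M <- diag(4)
  M[1:3, 1:3] <- M3
  M[1:3, 4] <- p[1:3]
  M
}

# Derivative of affine_matrix with respect to each parameter (central
# differences on the 4x4 entries; exact to ~1e-9 and cheap).
affine_matrix_grad <- function(p) {
  h <- 1e-6
  lapply(seq_len(12L), function(k) {
    pp <- as.numeric(p); pm <- as.numeric(p)
    pp[k] <- pp[k] + h; pm[k] <- pm[k] - h
    (affine_matrix(pp) - affine_matrix(pm)) / (2 * h)
  })
}

# Small rigid-only constructor used by coregistration (zooms 1, shears 0).
rigid_params <- function(t = c(0, 0, 0), r = c(0, 0, 0)) {
  affine_params(t[1], t[2], t[3], r[1], r[2], r[3])
}
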