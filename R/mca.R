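#' Maximum covariance analysis of two anomaly fields
#'
#' MCA finds pairs of spatial patterns, one per field, whose projected
#' time series (expansion coefficients) have maximal covariance: the
#' singular value decomposition of the cross-covariance matrix
#' `C = X'Y / (n - 1)` between two time x space fields. Mode k explains a
#' squared covariance fraction `SCF_k = sigma_k^2 / sum(sigma^2)`.
#'
#' Missing cells are handled before the decomposition: columns with less
#' than `max_fill_fraction` missing are filled with 0 (the climatological
#' anomaly, covariance-conservative) with a warning; columns with more
#' missing are dropped.
#'
#' The SVD sign ambiguity is fixed per mode: the element of largest
#' magnitude in the left pattern is made positive, and the right pattern
#' and both expansion coefficients flip with it.
#'
#' @param X,Y numeric matrices (n x p, n x q) of deseasonalized anomalies
#'   sharing the time index, or [anomaly_field()] objects.
#' @param K number of modes to retain (`K <= min(p, q)`).
#' @param center column-center the fields first (default `TRUE`; anomaly
#'   fields are already near-centered, centering is idempotent).
#' @param max_fill_fraction zero-fill threshold for missing cells.
#' @return list of class `mca_result`: `singular_values` (all
#'   `min(p, q)`, non-increasing), `scf` (sums to 1 over all modes),
#'   `left_patterns`, `right_patterns` (orthonormal columns, K modes),
#'   `left_ec`, `right_ec` (n x K expansion coefficients),
#'   `ec_correlation`, covariance maps `homo_left`, `hetero_left`,
#'   `homo_right`, `hetero_right` (K x station matrices), and the ids
#'   retained after missing-data handling.
#' @export
compute_mca <- function(X, Y, K = 6, center = TRUE,
                        max_fill_fraction = 0.1) {
  xl <- prepare_field(X, max_fill_fraction, "left")
  yl <- prepare_field(Y, max_fill_fraction, "right")
  X <- xl$m; Y <- yl$m
  n <- nrow(X)
  if (nrow(Y) != n) stop("fields must share the time dimension")
  if (n < 3) stop("need n >= 3 time steps")
  K <- as.integer(K)
  kmax <- min(ncol(X), ncol(Y))
  if (K > kmax)
    stop("K = ", K, " exceeds min(p, q) = ", kmax)
  if (center) {
    X <- scale(X, center = TRUE, scale = FALSE)
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  C <- crossprod(X, Y) / (n - 1)
  sv <- svd(C)
  sigma <- sv$d
  scf <- sigma^2 / sum(sigma^2)
  U <- sv$u[, seq_len(K), drop = FALSE]
  V <- sv$v[, seq_len(K), drop = FALSE]
  # sign convention: dominant element of each left pattern positive
  for (k in seq_len(K)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  A <- X %*% U  # left expansion coefficients
  B <- Y %*% V
  cov_map <- function(ec, field) {
    # K x stations: cov(ec_k, field_j) with the same 1/(n-1) normalization
    crossprod(scale(ec, center = TRUE, scale = FALSE), field) / (n - 1)
  }
  homo_left <- cov_map(A, X); hetero_left <- cov_map(A, Y)
  homo_right <- cov_map(B, Y); hetero_right <- cov_map(B, X)
  rownames(homo_left) <- rownames(hetero_left) <- rownames(homo_right) <-
    rownames(hetero_right) <- sprintf("mode%d", seq_len(K))
  colnames(homo_left) <- colnames(hetero_right) <- xl$ids
  colnames(homo_right) <- colnames(hetero_left) <- yl$ids
  ec_cor <- vapply(seq_len(K),
                   function(k) stats::cor(A[, k], B[, k]), numeric(1))
  structure(list(singular_values = sigma, scf = scf, K = K,
                 left_patterns = U, right_patterns = V,
                 left_ec = A, right_ec = B, ec_correlation = ec_cor,
                 homo_left = homo_left, hetero_left = hetero_left,
                 homo_right = homo_right, hetero_right = hetero_right,
                 left_ids = xl$ids, right_ids = yl$ids),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat("MCA:", length(x$left_ids), "x", length(x$right_ids), "series,",
      x$K, "modes retained\n")
  cat("  SCF:", paste(sprintf("%.1f%%", 100 * x$scf[seq_len(x$K)]),
                      collapse = " "), "\n")
  if (!is.null(x$upci))
    cat("  significant:",
        paste(ifelse(x$significant[seq_len(x$K)], "yes", "no"),
              collapse = " "), "\n")
  invisible(x)
}

prepare_field <- function(f, max_fill_fraction, side) {
  if (inherits(f, "anomaly_field")) {
    m <- f$anomalies; ids <- f$ids
  } else {
    m <- as.matrix(f)
    ids <- colnames(m)
    if (is.null(ids)) ids <- sprintf("%s%02d", toupper(substr(side, 1, 1)),
                                     seq_len(ncol(m)))
  }
  frac <- colMeans(is.na(m))
  drop <- frac > max_fill_fraction
  if (any(drop)) {
    warning(sum(drop), " ", side, " column(s) with > ",
            round(100 * max_fill_fraction), "% missing dropped before MCA")
    m <- m[, !drop, drop = FALSE]
    ids <- ids[!drop]
    frac <- frac[!drop]
  }
  if (!ncol(m)) stop("no ", side, " columns left after missing-data handling")
  if (any(frac > 0)) {
    warning("zero-filling ", sum(colSums(is.na(m))), " missing ", side,
            " anomaly cell(s)")
    m[is.na(m)] <- 0
  }
  list(m = m, ids = ids)
}

#' Monte Carlo permutation significance of MCA modes
#'
#' The time rows of one field are randomly permuted `B` times (the other
#' held fixed), the SCF spectrum is recomputed for each permutation, and
#' mode k is deemed significant when its observed SCF exceeds the 95th
#' percentile of its permutation distribution (the upper permutation
#' confidence interval, UPCI). Permuting whole rows preserves each field's
#' spatial covariance and destroys only the temporal pairing.
#'
#' @param X,Y fields as in [compute_mca()].
#' @param K modes to test.
#' @param B number of permutations (>= 19 for a meaningful 95% quantile).
#' @param seed integer RNG seed.
#' @param permute which field's rows to shuffle ("right" or "left").
#' @param center as in [compute_mca()].
#' @return the [compute_mca()] result augmented with `upci`,
#'   `significant` and `B`.
#' @export
permutation_significance <- function(X, Y, K = 6, B = 499, seed = 1L,
                                     permute = c("right", "left"),
                                     center = TRUE) {
  permute <- match.arg(permute)
  if (B < 19) stop("B must be >= 19 for a 95% permutation quantile")
  res <- compute_mca(X, Y, K, center = center)
  Xm <- suppressWarnings(prepare_field(X, 0.1, "left"))$m
  Ym <- suppressWarnings(prepare_field(Y, 0.1, "right"))$m
  if (center) {
    Xm <- scale(Xm, center = TRUE, scale = FALSE)
    Ym <- scale(Ym, center = TRUE, scale = FALSE)
  }
  n <- nrow(Xm)
  kmax <- min(ncol(Xm), ncol(Ym))
  set.seed(seed)
  null_scf <- matrix(NA_real_, B, kmax)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    Cb <- if (permute == "right") crossprod(Xm, Ym[perm, , drop = FALSE])
          else crossprod(Xm[perm, , drop = FALSE], Ym)
    d2 <- svd(Cb / (n - 1), nu = 0, nv = 0)$d^2
    null_scf[b, ] <- d2 / sum(d2)
  }
  upci <- apply(null_scf, 2, stats::quantile, probs = 0.95, names = FALSE)
  res$upci <- upci[seq_len(K)]
  res$significant <- res$scf[seq_len(K)] > res$upci
  res$B <- B
  res
}

#' Standardize an expansion coefficient series to unit SD
#'
#' @param ec numeric series with positive SD.
#' @return the series divided by its standard deviation.
#' @export
standardize_ec <- function(ec) {
  s <- stats::sd(ec, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero-SD series cannot be standardized")
  ec / s
}
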