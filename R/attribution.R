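#' Select a hotspot region from a covariance map
#'
#' Keeps the ids whose map value has the dominant sign (the sign of the
#' largest-magnitude element) and magnitude at least `tau` times the
#' maximum magnitude. The selection is invariant to positive rescaling of
#' the map. An explicit id list bypasses thresholding.
#'
#' @param map named numeric vector (one mode's covariance map).
#' @param tau threshold fraction in (0, 1].
#' @param ids optional explicit id list (explicit-list provenance).
#' @return list of class `region_mask`: `ids`, `provenance`.
#' @export
select_hotspot <- function(map, tau = 0.5, ids = NULL) {
  if (!is.null(ids)) {
    if (!length(ids)) stop("explicit id list is empty")
    return(structure(list(ids = as.character(ids),
                          provenance = "explicit-list"),
                     class = "region_mask"))
  }
  if (!length(map)) stop("empty covariance map")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (is.null(names(map))) names(map) <- sprintf("V%02d", seq_along(map))
  peak <- which.max(abs(map))
  if (abs(map[peak]) == 0)
    stop("map is identically zero; no hotspot can be selected")
  dom_sign <- sign(map[peak])
  sel <- names(map)[sign(map) == dom_sign &
                      abs(map) >= tau * abs(map[peak])]
  if (!length(sel)) stop("empty hotspot selection; use a smaller tau")
  structure(list(ids = sel, provenance = "threshold-on-map"),
            class = "region_mask")
}

#' Regional mean anomaly series over a hotspot mask
#'
#' @param field an [anomaly_field()] or a time x ids matrix.
#' @param mask a [select_hotspot()] mask or character id vector.
#' @return numeric series: missing-aware mean across the selected columns.
#' @export
regional_mean_series <- function(field, mask) {
  m <- if (inherits(field, "anomaly_field")) field$anomalies else
    as.matrix(field)
  ids <- if (inherits(mask, "region_mask")) mask$ids else as.character(mask)
  if (!length(ids)) stop("empty mask")
  cols <- match(ids, colnames(m))
  if (anyNA(cols))
    stop("mask ids not in field: ",
         paste(utils::head(ids[is.na(cols)], 3), collapse = ", "))
  out <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Principal components of a regional anomaly field
#'
#' Columns are centered; the eigenvectors of the sample covariance matrix
#' define the components. PC series are the projections, explained
#' fractions are `lambda_i / sum(lambda)`. Missing cells follow the MCA
#' filling rule (zero-fill sparse gaps, drop gap-heavy columns). The sign
#' of each component is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param field an [anomaly_field()] or matrix.
#' @param mask optional hotspot mask restricting the columns.
#' @param n_components number of components to return.
#' @return list: `scores` (n x k), `loadings` (ids x k),
#'   `explained` (fractions), `ids`.
#' @export
field_pca <- function(field, mask = NULL, n_components = 2) {
  m <- if (inherits(field, "anomaly_field")) field$anomalies else
    as.matrix(field)
  if (!is.null(mask)) {
    ids <- if (inherits(mask, "region_mask")) mask$ids else as.character(mask)
    cols <- match(ids, colnames(m))
    if (anyNA(cols)) stop("mask ids not in field")
    m <- m[, cols, drop = FALSE]
  }
  pf <- prepare_field(m, 0.1, "pca")
  m <- scale(pf$m, center = TRUE, scale = FALSE)
  if (ncol(m) < n_components)
    stop("fewer columns (", ncol(m), ") than requested components")
  sv <- svd(m)
  lambda <- sv$d^2 / (nrow(m) - 1)
  tol <- max(lambda) * 1e-12
  if (sum(lambda > tol) < n_components)
    stop("field rank below n_components")
  k <- seq_len(n_components)
  W <- sv$v[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  scores <- m %*% W
  colnames(scores) <- colnames(W) <- sprintf("PC%d", k)
  rownames(W) <- pf$ids
  list(scores = scores, loadings = W,
       explained = lambda[k] / sum(lambda), ids = pf$ids)
}

# OLS R^2 via SVD pseudoinverse: handles singular designs deterministically
r2_pinv <- function(y, X) {
  if (is.null(X) || NCOL(X) == 0) return(0)
  Xc <- cbind(1, as.matrix(X))
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  res <- y - Xc %*% beta
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)
  1 - sum(res^2) / ss_tot
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing
#' regressor j on the others. Values above 10 flag collinearity.
#'
#' @param regressors numeric matrix or data.frame (>= 2 columns).
#' @return named numeric vector of VIFs (Inf when `R^2_j = 1`), with
#'   attribute `collinear` (`TRUE` when any VIF exceeds 10).
#' @export
compute_vif <- function(regressors) {
  X <- as.matrix(regressors)
  if (ncol(X) < 2) stop("need >= 2 regressors for VIF")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- r2_pinv(X[, j], X[, -j, drop = FALSE])
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  attr(vif, "collinear") <- any(vif > 10)
  vif
}

#' LMG relative-importance decomposition
#'
#' The LMG share of regressor j is its average R^2 gain over all p!
#' orderings of entry into the model — equivalently a weighted average of
#' `R^2(S + j) - R^2(S)` over subsets S, with weights
#' `|S|! (p - 1 - |S|)! / p!`. Computed exactly by subset enumeration with
#' R^2 caching for `p <= max_exact`; beyond that a fixed number of random
#' orderings is averaged. Unnormalized LMG values sum to the full-model
#' R^2.
#'
#' @param y response vector.
#' @param regressors numeric matrix or data.frame of regressors.
#' @param normalized if `TRUE`, rescale the shares to sum to 1.
#' @param max_exact largest p for exact enumeration.
#' @param n_orderings sampled orderings used when `p > max_exact`.
#' @param seed seed for the sampled-orderings path.
#' @return named numeric vector of LMG shares.
#' @export
compute_lmg <- function(y, regressors, normalized = FALSE,
                        max_exact = 10, n_orderings = 2000, seed = 1L) {
  X <- as.matrix(regressors)
  p <- ncol(X)
  if (p < 1) stop("need at least one regressor")
  if (p <= max_exact) {
    r2 <- numeric(2^p)  # subset bitmask -> R^2, mask 0 = intercept only
    for (mask in seq_len(2^p - 1)) {
      cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0)
      r2[mask + 1] <- r2_pinv(y, X[, cols, drop = FALSE])
    }
    wts <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
                 lfactorial(p))
    lmg <- numeric(p)
    for (j in seq_len(p)) {
      bit_j <- bitwShiftL(1L, j - 1)
      for (mask in 0:(2^p - 1)) {
        if (bitwAnd(mask, bit_j) != 0) next
        s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0)
        lmg[j] <- lmg[j] + wts[s + 1] * (r2[bitwOr(mask, bit_j) + 1] -
                                           r2[mask + 1])
      }
    }
  } else {
    set.seed(seed)
    gains <- matrix(0, n_orderings, p)
    for (b in seq_len(n_orderings)) {
      ord <- sample.int(p)
      prev <- 0
      for (i in seq_len(p)) {
        cur <- r2_pinv(y, X[, ord[seq_len(i)], drop = FALSE])
        gains[b, ord[i]] <- cur - prev
        prev <- cur
      }
    }
    lmg <- colMeans(gains)
  }
  names(lmg) <- colnames(X)
  if (normalized) lmg <- lmg / sum(lmg)
  lmg
}

#' Semi-partial R-squared gains (last-in and first-in)
#'
#' `l_spr_j` is the R^2 drop when regressor j is removed from the full
#' model (its gain when entered last); `f_spr_j` is the R^2 of the model
#' containing only j (its gain when entered first).
#'
#' @param y response vector.
#' @param regressors numeric matrix or data.frame.
#' @return data.frame: regressor, l_spr, f_spr.
#' @export
compute_spr <- function(y, regressors) {
  X <- as.matrix(regressors)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  r2_full <- r2_pinv(y, X)
  l_spr <- vapply(seq_len(ncol(X)), function(j)
    r2_full - r2_pinv(y, X[, -j, drop = FALSE]), numeric(1))
  f_spr <- vapply(seq_len(ncol(X)), function(j)
    r2_pinv(y, X[, j, drop = FALSE]), numeric(1))
  data.frame(regressor = colnames(X), l_spr = pmax(l_spr, 0), f_spr = f_spr,
             stringsAsFactors = FALSE)
}

#' Standardized multiple linear regression with importance measures
#'
#' Fits OLS of a regional pollutant series on standardized regressors
#' (each centered and divided by its SD), then attaches VIFs, the LMG
#' decomposition and semi-partial R^2 gains.
#'
#' @param y response series (e.g. a regional PM2.5 anomaly mean).
#' @param regressors named numeric matrix or data.frame (e.g. PC series
#'   of precursor fields).
#' @param explained_variance optional named fractions (the share of its
#'   parent PCA's variance each regressor explains), carried into the
#'   result table.
#' @return list of class `attribution_result`: `table` (per-regressor
#'   coefficient, p_value, vif, lmg, l_spr, f_spr, explained_variance),
#'   `r_squared`, `n`, `significant` (p < 0.05 flags).
#' @export
fit_attribution <- function(y, regressors, explained_variance = NULL) {
  X <- as.matrix(regressors)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  ok <- stats::complete.cases(cbind(y, X))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n < p + 2) stop("need n >= p + 2 observations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant regressor: ", colnames(X)[which(sds == 0)[1]])
  Xs <- scale(X)
  cc <- stats::cor(Xs)
  diag(cc) <- 0
  if (any(abs(cc) > 1 - 1e-12)) {
    pair <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("perfectly collinear regressors: ", colnames(X)[pair[1]], " and ",
         colnames(X)[pair[2]])
  }
  df <- data.frame(y = y, Xs)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  coefs <- sm$coefficients[-1, , drop = FALSE]
  vif <- compute_vif(Xs)
  lmg <- compute_lmg(y, Xs)
  spr <- compute_spr(y, Xs)
  tab <- data.frame(regressor = colnames(X),
                    coefficient = unname(coefs[, 1]),
                    p_value = unname(coefs[, 4]),
                    vif = unname(vif), lmg = unname(lmg),
                    l_spr = spr$l_spr, f_spr = spr$f_spr,
                    stringsAsFactors = FALSE)
  if (!is.null(explained_variance))
    tab$explained_variance <-
      unname(explained_variance[match(tab$regressor,
                                      names(explained_variance))])
  structure(list(table = tab, r_squared = unname(sm$r.squared), n = n,
                 significant = stats::setNames(tab$p_value < 0.05,
                                               tab$regressor)),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("Attribution model: R^2 = %.3f, n = %d\n", x$r_squared, x$n))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}
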