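#' Robust or classical location and scatter of multivariate data
#'
#' Fits the centre and covariance of `X` either classically (sample mean and
#' covariance) or robustly with the minimum covariance determinant (MCD):
#' find the h-row subset whose covariance has minimal determinant, so that
#' outlying rows — here, gene knockouts that genuinely shift the mutational
#' spectrum — cannot drag the centre or inflate the scatter.
#'
#' The MCD search is FastMCD: many random (p+1)-point starts, each improved
#' by concentration steps (recompute distances, keep the h closest rows), the
#' best candidates iterated to convergence. The raw subset covariance is
#' rescaled by the chi-square consistency factor
#' `median(d^2) / qchisq(0.5, p)`, then a single reweighting step recomputes
#' mean and covariance from the rows with `d^2 <= qchisq(0.975, p)`, with the
#' trimmed-normal consistency factor applied so the scatter is unbiased for
#' Gaussian data.
#'
#' @param X numeric matrix, n rows (observations) by p columns.
#' @param method `"mcd"` (default) or `"classical"`.
#' @param support_fraction fraction h/n of rows in the MCD subset, in
#'   (0.5, 1]; default `floor((n + p + 1)/2) / n`, the highest-breakdown
#'   choice.
#' @param seed integer seed for the random subset starts (required for
#'   `"mcd"`); identical seeds give identical fits.
#' @param n_starts number of random initial subsets; default 500.
#' @return object of class `robust_fit`: list with `location` (length p),
#'   `scatter` (p x p), `support` (logical, rows in the raw best subset),
#'   `weights` (logical, rows kept by the reweighting step), `method`,
#'   `support_fraction`, `seed`.
#' @export
#' @examples
#' X <- matrix(rnorm(600), 100, 6)
#' fit <- fit_center_scatter(X, method = "mcd", seed = 7)
#' round(fit$location, 2)
fit_center_scatter <- function(X, method = c("mcd", "classical"),
                               support_fraction = NULL, seed = NULL,
                               n_starts = 500L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite")
  n <- nrow(X)
  p <- ncol(X)
  if (n <= 2 * p) stop("need n > 2p observations for a stable fit")

  if (method == "classical") {
    loc <- colMeans(X)
    S <- stats::cov(X)
    check_pd(S)
    return(structure(list(location = loc, scatter = S,
                          support = rep(TRUE, n), weights = rep(TRUE, n),
                          method = "classical", support_fraction = 1,
                          seed = seed),
                     class = "robust_fit"))
  }

  if (is.null(seed)) stop("method 'mcd' requires an explicit seed")
  if (is.null(support_fraction)) {
    support_fraction <- floor((n + p + 1) / 2) / n
  }
  if (support_fraction <= 0.5 || support_fraction > 1) {
    stop("support_fraction must be in (0.5, 1]")
  }
  h <- floor(n * support_fraction)

  cstep <- function(idx) {
    loc <- colMeans(X[idx, , drop = FALSE])
    S <- stats::cov(X[idx, , drop = FALSE])
    if (!is.finite(det(S)) || det(S) < .Machine$double.eps^2) {
      return(NULL)
    }
    d2 <- stats::mahalanobis(X, loc, S)
    order(d2)[seq_len(h)]
  }

  best <- with_seed(seed, {
    cands <- vector("list", n_starts)
    dets <- rep(Inf, n_starts)
    for (s in seq_len(n_starts)) {
      idx <- sample.int(n, p + 1)
      # grow a singular start until its covariance is invertible
      while (det(stats::cov(X[idx, , drop = FALSE])) <
             .Machine$double.eps^2 && length(idx) < n) {
        idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
      }
      for (k in 1:2) {
        nxt <- cstep(idx)
        if (is.null(nxt)) break
        idx <- nxt
      }
      if (length(idx) == h) {
        cands[[s]] <- idx
        dets[s] <- det(stats::cov(X[idx, , drop = FALSE]))
      }
    }
    keep <- order(dets)[seq_len(min(10L, sum(is.finite(dets))))]
    best_idx <- NULL
    best_det <- Inf
    for (s in keep) {
      idx <- cands[[s]]
      if (is.null(idx)) next
      repeat {
        nxt <- cstep(idx)
        if (is.null(nxt) || identical(sort(nxt), sort(idx))) break
        idx <- nxt
      }
      dd <- det(stats::cov(X[idx, , drop = FALSE]))
      if (dd < best_det) {
        best_det <- dd
        best_idx <- idx
      }
    }
    best_idx
  })
  if (is.null(best)) {
    stop("MCD scatter is singular: data concentrate on a lower-dimensional ",
         "subspace (e.g. duplicated rows)")
  }

  raw_loc <- colMeans(X[best, , drop = FALSE])
  raw_S <- stats::cov(X[best, , drop = FALSE])
  check_pd(raw_S)
  d2 <- stats::mahalanobis(X, raw_loc, raw_S)
  raw_S <- raw_S * stats::median(d2) / stats::qchisq(0.5, p)

  # one reweighting step at the 97.5% chi-square cutoff
  d2 <- stats::mahalanobis(X, raw_loc, raw_S)
  w <- d2 <= stats::qchisq(0.975, p)
  loc <- colMeans(X[w, , drop = FALSE])
  S <- stats::cov(X[w, , drop = FALSE])
  # trimmed-normal consistency: E[cov of retained 97.5%] understates the truth
  S <- S * 0.975 / stats::pchisq(stats::qchisq(0.975, p), p + 2)
  check_pd(S)

  support <- rep(FALSE, n)
  support[best] <- TRUE
  structure(list(location = loc, scatter = S, support = support, weights = w,
                 method = "mcd", support_fraction = support_fraction,
                 seed = seed),
            class = "robust_fit")
}

check_pd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(abs(ev)) * nrow(S)) {
    stop("scatter matrix is singular or not positive definite")
  }
  invisible(S)
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> method=%s  p=%d  support_fraction=%.3f\n",
              x$method, length(x$location), x$support_fraction))
  cat("location:", paste(sprintf("%.3f", x$location), collapse = " "), "\n")
  invisible(x)
}

#' Mahalanobis distance to a fitted centre
#'
#' `d = sqrt((x - location)' scatter^-1 (x - location))`: the covariance-
#' scaled distance of a point to the distribution centre. With an identity
#' scatter this is the Euclidean distance.
#'
#' @param x numeric vector of length p, or n x p matrix of rows.
#' @param fit a `robust_fit` (see [fit_center_scatter()]), or any list with
#'   `location` and `scatter`.
#' @return non-negative distance(s).
#' @export
#' @examples
#' fit <- list(location = c(0, 0), scatter = diag(c(4, 1)))
#' mahalanobis_distance(c(2, 0), fit)  # 1
mahalanobis_distance <- function(x, fit) {
  p <- length(fit$location)
  if (is.matrix(x)) {
    if (ncol(x) != p) stop("dimension mismatch: x has ", ncol(x),
                           " columns, fit is ", p, "-dimensional")
    return(sqrt(stats::mahalanobis(x, fit$location, fit$scatter)))
  }
  if (length(x) != p) stop("dimension mismatch: x has length ", length(x),
                           ", fit is ", p, "-dimensional")
  sqrt(stats::mahalanobis(matrix(x, 1), fit$location, fit$scatter))
}
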