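#' Maximal canonical correlation between two multichannel signals
#'
#' Finds the largest correlation achievable between linear combinations of
#' the rows of `X` and the rows of `Y`. Covariances are ridge-stabilised
#' (epsilon = 1e-8 * trace / dim added to each diagonal) so short, nearly
#' rank-deficient windows never crash.
#'
#' @param X Numeric matrix, channels x samples.
#' @param Y Numeric matrix, reference rows x samples (same sample count).
#' @return The first canonical correlation, in [0, 1].
#' @export
cca_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("X and Y must have the same number of samples (columns)",
         call. = FALSE)
  }
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  n <- ncol(Xc)
  Cxx <- tcrossprod(Xc) / n
  Cyy <- tcrossprod(Yc) / n
  Cxy <- tcrossprod(Xc, Yc) / n
  Cxx <- ridge(Cxx)
  Cyy <- ridge(Cyy)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  ev <- eigen(M, only.values = TRUE)$values
  rho2 <- max(0, Re(ev[1]))
  min(1, sqrt(rho2))
}

ridge <- function(C, eps = 1e-8) {
  d <- nrow(C)
  tr <- sum(diag(C))
  C + diag(max(eps * tr / d, .Machine$double.xmin * 1e10), d)
}

#' Classify one epoch by standard CCA
#'
#' Scores every codebook target by the canonical correlation between the
#' epoch and that target's sinusoidal references; the highest-scoring target
#' wins (ties broken toward the lowest index).
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param refs A [build_references()] set built for the same sample count.
#' @return The predicted target index.
#' @export
cca_classify <- function(epoch, refs) {
  scores <- cca_scores(epoch, refs)
  which.max(scores)
}

# per-target CCA correlations for one epoch; the epoch-side covariance is
# factorised once and the cached reference factors are reused per target
cca_scores <- function(epoch, refs) {
  stopifnot(inherits(refs, "reference_set"))
  epoch <- as.matrix(epoch)
  if (ncol(epoch) != refs$n_samples) {
    stop("epoch has ", ncol(epoch), " samples but the references were built",
         " for ", refs$n_samples, call. = FALSE)
  }
  if (all(epoch == 0)) {
    stop("degenerate epoch: all samples are zero", call. = FALSE)
  }
  n <- ncol(epoch)
  Xc <- epoch - rowMeans(epoch)
  Kxx <- chol2inv(chol(ridge(tcrossprod(Xc) / n)))
  vapply(refs$prep, function(p) {
    Cxy <- tcrossprod(Xc, p$Yc) / n
    M <- Kxx %*% Cxy %*% p$Myy %*% t(Cxy)
    rho2 <- max(0, Re(eigen(M, only.values = TRUE)$values[1]))
    min(1, sqrt(rho2))
  }, numeric(1))
}

#' Classify one epoch by filter-bank CCA
#'
#' Runs CCA per sub-band and combines the squared correlations with the
#' filter-bank weights: feature(target) = sum_n w(n) rho_n(target)^2. The
#' target with the largest feature wins.
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param refs A [build_references()] set for the same sample count.
#' @param spec A [filterbank_spec()]. Default: the standard 5-band bank.
#' @param sfreq Sampling rate of the epoch, Hz (needed to design the
#'   filters). Defaults to the reference set's rate.
#' @return The predicted target index.
#' @export
fbcca_classify <- function(epoch, refs, spec = filterbank_spec(),
                           sfreq = refs$sfreq) {
  filts <- band_filters(spec, sfreq)
  fbcca_classify_prepared(epoch, refs, spec, filts)
}

fbcca_classify_prepared <- function(epoch, refs, spec, filts) {
  epoch <- as.matrix(epoch)
  if (all(epoch == 0)) {
    stop("degenerate epoch: all samples are zero", call. = FALSE)
  }
  feat <- numeric(n_targets(refs$codebook))
  for (m in seq_along(filts)) {
    Xm <- filter_matrix(epoch, filts[[m]])
    rho <- cca_scores(Xm, refs)
    feat <- feat + spec$weights[m] * rho^2
  }
  which.max(feat)
}
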