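#' Fit an ensemble task-related component analysis (eTRCA) model
#'
#' For every codebook target and every filter-bank sub-band, finds the
#' spatial filter maximising the reproducibility of the response across
#' training trials: the leading eigenvector of Q^-1 S, where S is the sum of
#' cross-trial covariances (trials centred per trial) and Q the summed
#' within-trial covariance. The ensemble concatenates all targets' filters;
#' templates are the per-target mean trials. Sub-band scores are later
#' combined with the same weight curve as FBCCA.
#'
#' @param train An [ssvep_epochs()] object with at least 2 trials per
#'   target, already cut to the classification window.
#' @param spec A [filterbank_spec()]. Default: the standard 5-band bank.
#' @return A list of class `trained_model` with `kind = "etrca"`.
#' @export
etrca_fit <- function(train, spec = filterbank_spec()) {
  stopifnot(inherits(train, "ssvep_epochs"))
  cb <- train$codebook
  counts <- tabulate(train$labels, n_targets(cb))
  if (any(counts < 2L)) {
    stop("target ", which(counts < 2L)[1],
         " has fewer than 2 training trials", call. = FALSE)
  }
  filts <- band_filters(spec, train$sfreq)
  banded <- apply_filter_bank(train, spec)
  bands <- lapply(banded, function(bep) etrca_fit_band(bep, cb))
  structure(list(kind = "etrca", bands = bands, filters = filts,
                 filterbank = spec, codebook = cb,
                 n_samples = n_samples(train), sfreq = train$sfreq),
            class = "trained_model")
}

# fit one sub-band from already band-filtered training epochs
etrca_fit_band <- function(bep, cb) {
  W <- matrix(0, n_channels(bep), n_targets(cb))
  templates <- vector("list", n_targets(cb))
  for (tg in seq_len(n_targets(cb))) {
    idx <- which(bep$labels == tg)
    Xs <- lapply(idx, function(i) {
      X <- trial_matrix(bep, i)
      X - rowMeans(X)
    })
    Ssum <- Reduce(`+`, Xs)
    Q <- Reduce(`+`, lapply(Xs, tcrossprod))
    S <- tcrossprod(Ssum) - Q              # sum over i != j of Xi Xj'
    ev <- eigen(solve(ridge(Q), S))
    W[, tg] <- Re(ev$vectors[, 1])
    templates[[tg]] <- Reduce(`+`, Xs) / length(Xs)
  }
  # ensemble-filtered templates, cached for classification
  ftempl <- lapply(templates, function(Tm) as.numeric(crossprod(W, Tm)))
  list(W = W, templates = templates, ftempl = ftempl)
}

# fit from a list of pre-filtered epoch objects (one per band)
etrca_fit_prefiltered <- function(banded, spec, filts = NULL) {
  cb <- banded[[1]]$codebook
  counts <- tabulate(banded[[1]]$labels, n_targets(cb))
  if (any(counts < 2L)) {
    stop("target ", which(counts < 2L)[1],
         " has fewer than 2 training trials", call. = FALSE)
  }
  bands <- lapply(banded, function(bep) etrca_fit_band(bep, cb))
  structure(list(kind = "etrca", bands = bands, filters = filts,
                 filterbank = spec, codebook = cb,
                 n_samples = n_samples(banded[[1]]),
                 sfreq = banded[[1]]$sfreq),
            class = "trained_model")
}

# classify from a list of already band-filtered channels x samples matrices
etrca_classify_banded <- function(band_mats, model) {
  w <- model$filterbank$weights
  feat <- numeric(n_targets(model$codebook))
  for (m in seq_along(model$bands)) {
    band <- model$bands[[m]]
    X <- band_mats[[m]]
    X <- X - rowMeans(X)
    fx <- as.numeric(crossprod(band$W, X))
    for (tg in seq_along(band$templates)) {
      feat[tg] <- feat[tg] + w[m] * stats::cor(fx, band$ftempl[[tg]])
    }
  }
  which.max(feat)
}

#' Classify one epoch with a fitted eTRCA model
#'
#' Per sub-band, correlates the ensemble-filtered epoch with each target's
#' ensemble-filtered template and combines the correlations across bands
#' with the filter-bank weights. The best-scoring target wins.
#'
#' @param epoch Numeric matrix, channels x samples (same window as
#'   training).
#' @param model A [etrca_fit()] model.
#' @return The predicted target index.
#' @export
etrca_classify <- function(epoch, model) {
  stopifnot(inherits(model, "trained_model"), model$kind == "etrca")
  epoch <- as.matrix(epoch)
  if (ncol(epoch) != model$n_samples) {
    stop("epoch has ", ncol(epoch), " samples but the model was trained on ",
         model$n_samples, call. = FALSE)
  }
  if (all(epoch == 0)) {
    stop("degenerate epoch: all samples are zero", call. = FALSE)
  }
  band_mats <- lapply(model$filters, function(filt) {
    filter_matrix(epoch, filt)
  })
  etrca_classify_banded(band_mats, model)
}
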