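#' Fit a task discriminant component analysis (TDCA) model
#'
#' Each training trial is delay-augmented (the original plus delayed copies
#' in 0.1 s steps spanning `Np` seconds, stacked along the channel axis) and
#' concatenated with its projection onto its own class's sinusoidal
#' reference row space (projector Y'(YY')^-1 Y). A multi-class discriminant
#' is then solved on the augmented spatial dimension: the top
#' `n_components` eigenvectors of Sw^-1 Sb, where Sb / Sw are the between- /
#' within-class scatter of the augmented-projected trial matrices. One model
#' is fitted per filter-bank sub-band.
#'
#' Training trials must be `Np` seconds longer than the classification
#' window: the classification window length is inferred as the training
#' extent minus the delay span.
#'
#' @param train An [ssvep_epochs()] object cut to classification window +
#'   `Np` seconds.
#' @param Np Delay span in seconds (multiples of 0.1 s). Default 1.
#' @param n_components Number of discriminant components kept. Default 9,
#'   the setting at which adding more stops helping.
#' @param spec A [filterbank_spec()].
#' @param Nh Harmonics for the projection references. Default 5.
#' @return A list of class `trained_model` with `kind = "tdca"`.
#' @export
tdca_fit <- function(train, Np = 1, n_components = 9,
                     spec = filterbank_spec(), Nh = 5) {
  stopifnot(inherits(train, "ssvep_epochs"))
  banded <- apply_filter_bank(train, spec)
  tdca_fit_prefiltered(banded, Np, n_components, spec, Nh,
                       filts = band_filters(spec, train$sfreq))
}

tdca_fit_prefiltered <- function(banded, Np = 1, n_components = 9,
                                 spec = filterbank_spec(), Nh = 5,
                                 filts = NULL) {
  train <- banded[[1]]
  cb <- train$codebook
  counts <- tabulate(train$labels, n_targets(cb))
  if (any(counts < 2L)) {
    stop("target ", which(counts < 2L)[1],
         " has fewer than 2 training trials", call. = FALSE)
  }
  fs <- train$sfreq
  q <- round(0.1 * fs)                       # delay step in samples
  l <- round(Np / 0.1)                       # number of delayed copies
  L <- n_samples(train) - l * q              # classification window samples
  if (L < 2L) {
    max_np <- (n_samples(train) - 2L) %/% q * 0.1
    stop(sprintf("Np = %.2g s is too large for the training window; the maximum supported Np is %.2g s",
                 Np, max_np), call. = FALSE)
  }
  A <- (l + 1L) * n_channels(train)          # augmented channel count
  if (n_components > A) {
    stop("n_components (", n_components, ") exceeds the augmented channel ",
         "rank (", A, ")", call. = FALSE)
  }
  refs <- build_references(cb, Nh, fs, L)
  # orthonormal bases of the reference row spaces; the projector onto the
  # row space is t(Qy) %*% Qy, applied in factored form for speed
  projectors <- lapply(refs$refs, function(Y) {
    t(qr.Q(qr(t(Y))))
  })
  bands <- lapply(banded, function(bep) {
    # augmented-projected trials per class
    Zs <- vector("list", n_targets(cb))
    for (tg in seq_len(n_targets(cb))) {
      idx <- which(bep$labels == tg)
      Qy <- projectors[[tg]]
      Zs[[tg]] <- lapply(idx, function(i) {
        X <- trial_matrix(bep, i)
        Xa <- augment_trial(X, L, q, l, pad = FALSE)
        cbind(Xa, (Xa %*% t(Qy)) %*% Qy)
      })
    }
    means <- lapply(Zs, function(zz) Reduce(`+`, zz) / length(zz))
    gmean <- Reduce(`+`, means) / length(means)
    Sb <- matrix(0, A, A); Sw <- matrix(0, A, A)
    for (tg in seq_len(n_targets(cb))) {
      d <- means[[tg]] - gmean
      Sb <- Sb + tcrossprod(d)
      for (Z in Zs[[tg]]) {
        e <- Z - means[[tg]]
        Sw <- Sw + tcrossprod(e)
      }
    }
    # ridge scaled by the total scatter: keeps the discriminant well posed
    # even when the within-class scatter vanishes (e.g. noiseless data)
    reg <- max(1e-8 * (sum(diag(Sw)) + sum(diag(Sb))) / A,
               .Machine$double.xmin * 1e10)
    ev <- eigen(solve(Sw + diag(reg, A), Sb))
    vals <- Re(ev$values)
    # the between-class scatter has rank <= C - 1: directions beyond the
    # effective rank carry no class information and are dropped
    r_eff <- max(1L, sum(vals > 1e-8 * vals[1]))
    W <- Re(ev$vectors[, seq_len(min(n_components, r_eff)),
                       drop = FALSE])
    templates <- lapply(means, function(m) crossprod(W, m))
    list(W = W, templates = templates)
  })
  structure(list(kind = "tdca", bands = bands, filters = filts,
                 filterbank = spec, codebook = cb, projectors = projectors,
                 n_samples = L, q = q, l = l, Np = Np,
                 n_components = n_components, sfreq = fs),
            class = "trained_model")
}

# Stack delayed copies of X along the channel axis. For training trials
# (pad = FALSE) X has L + l*q samples and copy j takes samples
# [j*q + 1, j*q + L]; for test trials (pad = TRUE) X has L samples and the
# tail of each delayed copy is zero-filled.
augment_trial <- function(X, L, q, l, pad) {
  blocks <- vector("list", l + 1L)
  for (j in 0:l) {
    if (!pad) {
      blocks[[j + 1L]] <- X[, (j * q + 1L):(j * q + L), drop = FALSE]
    } else {
      if (j * q >= ncol(X)) {
        blocks[[j + 1L]] <- matrix(0, nrow(X), L)
      } else {
        seg <- X[, (j * q + 1L):ncol(X), drop = FALSE]
        blocks[[j + 1L]] <- cbind(seg, matrix(0, nrow(X), L - ncol(seg)))
      }
    }
  }
  do.call(rbind, blocks)
}

#' Classify one epoch with a fitted TDCA model
#'
#' The epoch is delay-augmented with zero padding, projected per candidate
#' class onto that class's reference subspace, reduced by the discriminant
#' components, and correlated with the class template; sub-band scores are
#' combined with the filter-bank weights.
#'
#' @param epoch Numeric matrix, channels x samples (the classification
#'   window the model was fitted for).
#' @param model A [tdca_fit()] model.
#' @return The predicted target index.
#' @export
tdca_classify <- function(epoch, model) {
  stopifnot(inherits(model, "trained_model"), model$kind == "tdca")
  epoch <- as.matrix(epoch)
  if (ncol(epoch) != model$n_samples) {
    stop("epoch has ", ncol(epoch), " samples but the model expects ",
         model$n_samples, call. = FALSE)
  }
  if (all(epoch == 0)) {
    stop("degenerate epoch: all samples are zero", call. = FALSE)
  }
  band_mats <- lapply(model$filters, function(filt) {
    filter_matrix(epoch, filt)
  })
  tdca_classify_banded(band_mats, model)
}

# classify from already band-filtered channels x samples matrices
tdca_classify_banded <- function(band_mats, model) {
  w <- model$filterbank$weights
  feat <- numeric(n_targets(model$codebook))
  for (m in seq_along(model$bands)) {
    band <- model$bands[[m]]
    Xa <- augment_trial(band_mats[[m]], model$n_samples, model$q, model$l,
                        pad = TRUE)
    WXa <- crossprod(band$W, Xa)         # components x samples
    for (tg in seq_along(band$templates)) {
      Qy <- model$projectors[[tg]]
      fz <- as.numeric(cbind(WXa, (WXa %*% t(Qy)) %*% Qy))
      feat[tg] <- feat[tg] + w[m] * stats::cor(fz,
                                               as.numeric(band$templates[[tg]]))
    }
  }
  which.max(feat)
}
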