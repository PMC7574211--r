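#' Extract a 5x5 intensity window around a position
#'
#' Windows are centred on the rounded pixel position; positions closer than
#' 2 px to the border are padded by edge replication.
#'
#' @param image Numeric matrix of normalized intensities.
#' @param x,y 0-based continuous position (`x` = column, `y` = row).
#' @return A 5x5 numeric matrix.
#' @export
extract_window <- function(image, x, y) {
  r0 <- floor(y + 0.5) + 1L; c0 <- floor(x + 0.5) + 1L
  rows <- pmin(pmax(r0 + (-2:2), 1L), nrow(image))
  cols <- pmin(pmax(c0 + (-2:2), 1L), ncol(image))
  image[rows, cols, drop = FALSE]
}

window_features <- function(w) {
  v <- as.vector(w)
  c(v, center = w[3, 3], max = max(v), mean = mean(v), sd = stats::sd(v))
}

#' Train the default signal probability model
#'
#' Fits a ridge-regularized logistic model on the 25 window pixels plus
#' summary features (centre, max, mean, sd), replacing the per-candidate
#' signal/noise classifier with a lightweight, swappable predictor; any
#' object implementing [predict_signal_prob()]'s contract (a probability in
#' \[0, 1\] for every 5x5 window) can stand in. Class balance is enforced by
#' downsampling the majority class (seeded).
#'
#' @param examples Tibble with a `window` list-column of 5x5 matrices and a
#'   `label` column (`"signal"` / `"noise"`); both classes must be present.
#' @param seed Integer seed for the class-balancing downsample and the
#'   cross-validation folds.
#' @param lambda Ridge penalty.
#' @param n_folds Folds for the reported cross-validated AUC.
#' @return An `iss_signal_model` with fitted coefficients, feature scaling,
#'   the cross-validated training AUC (an unbiased discrimination estimate:
#'   near 0.5 when the labels carry no signal) and metadata.
#' @export
train_signal_model <- function(examples, seed = 1L, lambda = 1e-3,
                               n_folds = 5) {
  stopifnot(all(c("window", "label") %in% names(examples)))
  lab <- examples$label
  if (length(unique(lab)) < 2) stop("training data must contain both classes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx_s <- which(lab == "signal"); idx_n <- which(lab == "noise")
  m <- min(length(idx_s), length(idx_n))
  keep <- sort(c(sample(idx_s, m), sample(idx_n, m)))
  X <- t(vapply(examples$window[keep], window_features, numeric(29)))
  y <- as.integer(lab[keep] == "signal")
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  beta <- ridge_logistic(Xs, y, lambda)
  # held-out AUC by k-fold cross-validation (in-sample AUC is optimistic
  # with 29 features)
  fold <- sample(rep_len(seq_len(n_folds), length(y)))
  cv_p <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    b <- ridge_logistic(Xs[tr, , drop = FALSE], y[tr], lambda)
    cv_p[!tr] <- plogis(drop(cbind(1, Xs[!tr, , drop = FALSE]) %*% b))
  }
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = cv_p, levels = c(0, 1),
    direction = "<", quiet = TRUE)))
  structure(list(
    beta = beta, center = mu, scale = sdv, lambda = lambda,
    training_auc = auc, n_examples = 2L * m, seed = seed, version = "1"
  ), class = "iss_signal_model")
}

# L2-penalized logistic regression by damped IRLS (intercept unpenalized)
ridge_logistic <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    A <- crossprod(Xi * w, Xi) + pen
    b_new <- drop(solve(A, crossprod(Xi * w, z)))
    if (max(abs(b_new - beta)) < tol) { beta <- b_new; break }
    beta <- b_new
  }
  beta
}

#' @export
print.iss_signal_model <- function(x, ...) {
  cat(sprintf("<iss_signal_model> ridge logistic, %d training examples, AUC %.3f\n",
              x$n_examples, x$training_auc))
  invisible(x)
}

#' Predict signal probabilities for candidates
#'
#' Fills the `p` column of a candidate tibble: for each candidate a 5x5
#' window is read from the normalized image of its cycle and channel and fed
#' to the model. Probabilities are clamped to \[1e-6, 1\] so that downstream
#' `-log(p)` node weights stay finite. If candidates carry a `merged_from`
#' list-column, the suppressed candidates are scored too (they act as
#' competitors in per-base quality scoring).
#'
#' @param model An `iss_signal_model` (or any object with a
#'   `predict_window_prob` method).
#' @param candidates Candidate tibble (`cycle`, `channel`, `x`, `y`).
#' @param stack The normalized `iss_stack` the candidates came from.
#' @return `candidates` with `p` filled, row order preserved.
#' @export
predict_signal_prob <- function(model, candidates, stack) {
  score <- function(df) {
    if (nrow(df) == 0) return(numeric(0))
    if (inherits(model, "iss_signal_model")) {
      # batch path: one feature matrix, one linear predictor
      X <- t(vapply(seq_len(nrow(df)), function(i) {
        window_features(extract_window(
          stack_image(stack, df$cycle[i], df$channel[i]), df$x[i], df$y[i]))
      }, numeric(29)))
      Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
      p <- plogis(drop(cbind(1, Xs) %*% model$beta))
      return(pmin(pmax(p, 1e-6), 1))
    }
    vapply(seq_len(nrow(df)), function(i) {
      w <- extract_window(stack_image(stack, df$cycle[i], df$channel[i]),
                          df$x[i], df$y[i])
      predict_window_prob(model, w)
    }, numeric(1))
  }
  candidates$p <- score(candidates)
  if ("merged_from" %in% names(candidates)) {
    candidates$merged_from <- purrr::map(candidates$merged_from, function(mf) {
      if (!is.null(mf) && nrow(mf)) mf$p <- score(mf)
      mf
    })
  }
  candidates
}

#' Probability that one 5x5 window is true signal
#' @param model A fitted model.
#' @param window A 5x5 numeric matrix.
#' @return A probability in \[1e-6, 1\].
#' @export
predict_window_prob <- function(model, window) UseMethod("predict_window_prob")

#' @export
predict_window_prob.iss_signal_model <- function(model, window) {
  if (is.null(model$beta)) stop("model is not fitted")
  f <- (window_features(window) - model$center) / model$scale
  p <- plogis(drop(c(1, f) %*% model$beta))
  min(max(p, 1e-6), 1)
}

#' Assemble training windows from a simulation with known ground truth
#'
#' Mirrors how annotation works on real data: candidates are first nominated
#' by the detection step on every cycle and channel, then labelled. A
#' candidate is a signal example if it sits within `signal_radius` px of a
#' rolony whose barcode letter for that cycle matches the candidate's
#' channel, or of an injected spurious spot in the same image — both are
#' genuine fluorescent spots, and distinguishing rolonies from spurious
#' signal is the job of the decoding graph and codebook, not of the spot
#' classifier. A candidate is a noise example if it is at least
#' `exclusion_radius` px from every rolony and same-image spurious spot;
#' ambiguous candidates in between (and bleed-through twins) are discarded.
#' This exposes the classifier to the borderline noise peaks it must reject,
#' not just flat background.
#'
#' @param sim Result of [simulate_iss()].
#' @param stack_norm The normalized stack of `sim$stack`.
#' @param h,tophat_radius Detection parameters used for nomination. The
#'   default `h` is more generous (lower) than the decoding default so that
#'   enough borderline noise peaks are nominated into the noise class.
#' @param signal_radius Maximum distance of a signal candidate from its
#'   rolony.
#' @param exclusion_radius Minimum distance of noise candidates from any
#'   rolony.
#' @param seed Integer seed (subsampling when one class is very large).
#' @param max_per_class Cap per class (subsampled, seeded).
#' @return A tibble with `window` (list of 5x5 matrices) and `label`.
#' @export
training_windows <- function(sim, stack_norm, h = 0.08, tophat_radius = 2,
                             signal_radius = 1.5, exclusion_radius = 5,
                             seed = 1L, max_per_class = 500) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  truth <- sim$truth
  nc <- n_cycles(stack_norm)
  win <- list(); lab <- character(0)
  fs <- sim$false_spots
  if (is.null(fs)) {
    fs <- tibble::tibble(cycle = integer(), channel = character(),
                         x = numeric(), y = numeric())
  }
  for (cyc in seq_len(nc)) {
    letter <- substr(truth$barcode, cyc, cyc)
    for (ch in iss_bases()) {
      cand <- detect_candidates(stack_image(stack_norm, cyc, ch),
                                h = h, tophat_radius = tophat_radius,
                                cycle = cyc, channel = ch)
      if (nrow(cand) == 0) next
      fsc <- fs[fs$cycle == cyc & fs$channel == ch, ]
      for (i in seq_len(nrow(cand))) {
        d2 <- (truth$x - cand$x[i])^2 + (truth$y - cand$y[i])^2
        d2f <- if (nrow(fsc)) (fsc$x - cand$x[i])^2 + (fsc$y - cand$y[i])^2
               else Inf
        near_rolony <- nrow(truth) > 0 && min(d2) <= signal_radius^2 &&
          letter[which.min(d2)] == ch
        if (near_rolony || min(d2f) <= signal_radius^2) {
          cls <- "signal"
        } else if ((nrow(truth) == 0 || min(d2) >= exclusion_radius^2) &&
                   min(d2f) >= exclusion_radius^2) {
          cls <- "noise"
        } else next
        win[[length(win) + 1L]] <-
          extract_window(stack_image(stack_norm, cyc, ch), cand$x[i], cand$y[i])
        lab <- c(lab, cls)
      }
    }
  }
  out <- tibble::tibble(window = win, label = lab)
  keep <- unlist(purrr::map(split(seq_len(nrow(out)), out$label), function(ix) {
    if (length(ix) > max_per_class) sort(sample(ix, max_per_class)) else ix
  }), use.names = FALSE)
  out[sort(keep), ]
}

#' Serialize a signal model to a YAML file
#' @param model An `iss_signal_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal_model <- function(model, path) {
  yaml::write_yaml(list(
    version = model$version, lambda = model$lambda,
    training_auc = model$training_auc, n_examples = model$n_examples,
    seed = model$seed, beta = as.numeric(model$beta),
    center = as.numeric(model$center), scale = as.numeric(model$scale)
  ), path)
  invisible(path)
}

#' Read a signal model written by [write_signal_model()]
#' @param path YAML path.
#' @return An `iss_signal_model`.
#' @export
read_signal_model <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(
    beta = as.numeric(y$beta), center = as.numeric(y$center),
    scale = as.numeric(y$scale), lambda = y$lambda,
    training_auc = y$training_auc, n_examples = y$n_examples,
    seed = y$seed, version = y$version
  ), class = "iss_signal_model")
}
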