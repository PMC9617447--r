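# One-class SVM on a precomputed graph-kernel Gram matrix, with the two
# heuristics for choosing nu: QMS2 (discard training instances below the
# first kneedle knee of the sorted KNN-similarity profile, then nu = 0.01)
# and the MAD rule (nu = fraction of instances deviating from the median
# KNN similarity by more than 3 x MAD).
#
# The dual solved here is  min_a 1/2 a'Ka  s.t.  0 <= a_i <= 1/(nu n),
# sum a_i = 1, by SMO over maximal-violating pairs. At the optimum the
# nu-property holds: the training-outlier fraction is at most nu and the
# support-vector fraction at least nu.

#' Average similarity to the K nearest neighbours
#'
#' K is 3% of the training size (at least 1); the instance itself is
#' excluded from its neighbour set.
#'
#' @param gram square kernel matrix over the training set (N >= 2).
#' @return list of class `similarity_profile`: `s` (per-instance mean
#'   similarity to the K most similar other instances), `K`, `N`.
#' @export
knn_profile <- function(gram) {
  N <- nrow(gram)
  if (is.null(N) || N < 2 || N != ncol(gram)) {
    stop("knn_profile needs a square Gram matrix with N >= 2")
  }
  K <- max(1L, as.integer(round(0.03 * N)))
  s <- vapply(seq_len(N), function(i) {
    row <- gram[i, -i]
    mean(sort(row, decreasing = TRUE)[seq_len(K)])
  }, numeric(1))
  structure(list(s = s, K = K, N = N), class = "similarity_profile")
}

#' Kneedle knee of an ascending curve
#'
#' Detects the first knee of the concave-increasing rank-vs-value curve:
#' both axes are min-max normalised, the difference curve d = y - x is
#' formed, and the first local maximum of d whose threshold
#' `d_max - sensitivity / (n - 1)` is undercut before the next local maximum
#' (or the end of the curve) is returned.
#'
#' @param values numeric vector sorted in ascending order.
#' @param sensitivity kneedle sensitivity S (default 1).
#' @return integer rank of the knee, or `NA_integer_` when no knee exists
#'   (constant, too-short, or curvature-free input).
#' @export
kneedle_knee <- function(values, sensitivity = 1) {
  n <- length(values)
  if (n < 3) return(NA_integer_)
  if (is.unsorted(values)) stop("values must be sorted ascending")
  rng <- max(values) - min(values)
  if (rng == 0) return(NA_integer_)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / rng
  d <- y - x
  # local maxima of the difference curve
  lmx <- which(diff(sign(diff(d))) < 0) + 1L
  if (!length(lmx)) return(NA_integer_)
  thr <- d[lmx] - sensitivity * mean(diff(x))
  for (k in seq_along(lmx)) {
    i <- lmx[k]
    stop_at <- if (k < length(lmx)) lmx[k + 1L] - 1L else n
    if (stop_at > i && any(d[(i + 1L):stop_at] < thr[k])) return(i)
  }
  NA_integer_
}

#' QMS2 training selection
#'
#' Sorts the KNN-similarity profile ascending, finds the first kneedle knee,
#' and discards the instances ranked strictly below it (the low-similarity
#' outliers); nu is fixed at 0.01. Without a knee all instances are
#' retained.
#'
#' @param profile a [knn_profile()].
#' @param sensitivity kneedle sensitivity.
#' @return list of class `training_selection`: `retained_indices`, `nu`,
#'   `method`, `knee_rank`.
#' @export
qms2_select <- function(profile, sensitivity = 1) {
  ord <- order(profile$s)
  knee <- kneedle_knee(profile$s[ord], sensitivity)
  retained <- if (is.na(knee) || knee <= 1) {
    seq_len(profile$N)
  } else {
    sort(ord[knee:profile$N])
  }
  structure(list(retained_indices = retained, nu = 0.01, method = "qms2",
                 knee_rank = knee), class = "training_selection")
}

#' MAD-based nu selection
#'
#' nu is the fraction of instances whose KNN similarity deviates from the
#' median by strictly more than 3 x MAD (raw MAD, no consistency scaling),
#' clamped to at least 1/N; all instances are retained.
#'
#' @param profile a [knn_profile()].
#' @return a `training_selection` with `method = "mad"`.
#' @export
mad_nu <- function(profile) {
  s <- profile$s
  med <- stats::median(s)
  mad_raw <- stats::median(abs(s - med))
  frac <- mean(abs(s - med) > 3 * mad_raw)
  nu <- min(1, max(1 / profile$N, frac))
  structure(list(retained_indices = seq_len(profile$N), nu = nu,
                 method = "mad", knee_rank = NA_integer_),
            class = "training_selection")
}

#' Train a nu-one-class SVM on a precomputed kernel
#'
#' Solves the one-class dual by SMO. The offset rho is taken as the mean of
#' `(K alpha)_i` over margin support vectors (0 < alpha_i < 1/(nu n)); the
#' decision function is `f(q) = sum_i alpha_i k(x_i, q) - rho`, negative for
#' outliers.
#'
#' @param K square PSD kernel matrix over the (retained) training set.
#' @param nu nu parameter in (0, 1].
#' @param tol SMO stopping tolerance on the maximal KKT violation.
#' @param max_iter iteration cap.
#' @return list of class `ocsvm_fit`: `alpha`, `rho`, `nu`,
#'   `decision_train` (training decision values).
#' @export
train_ocsvm <- function(K, nu, tol = 1e-8, max_iter = NULL) {
  n <- nrow(K)
  if (is.null(n) || n != ncol(K)) stop("K must be square")
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0 || nu > 1) {
    stop("nu must lie in (0, 1]")
  }
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(1, max(abs(K)))) {
    stop("kernel matrix is not positive semidefinite; add diagonal jitter")
  }
  C <- 1 / (nu * n)
  m <- floor(nu * n)
  alpha <- numeric(n)
  if (m > 0) alpha[seq_len(m)] <- C
  if (m < n) alpha[m + 1L] <- 1 - m * C
  g <- as.numeric(K %*% alpha)  # gradient of 1/2 a'Ka
  if (is.null(max_iter)) max_iter <- max(10000L, 200L * n)
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    up <- alpha < C - eps      # can increase
    dn <- alpha > eps          # can decrease
    i <- which(up)[which.min(g[up])]
    j <- which(dn)[which.max(g[dn])]
    viol <- g[j] - g[i]
    if (!length(i) || !length(j) || viol < tol) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_step <- if (eta > eps) viol / eta else Inf
    t_step <- min(t_step, C - alpha[i], alpha[j])
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + t_step
    alpha[j] <- alpha[j] - t_step
    g <- g + t_step * (K[, i] - K[, j])
  }
  margin <- alpha > eps & alpha < C - eps
  # at the exact optimum all margin-SV gradients coincide; taking the
  # minimum (rather than the mean) keeps boundary points on the inlier
  # side of f = 0 despite solver-tolerance noise
  rho <- if (any(margin)) {
    min(g[margin])
  } else {
    # degenerate: all alphas at bounds; rho sits between the two groups
    lo <- if (any(alpha >= C - eps)) max(g[alpha >= C - eps]) else -Inf
    hi <- if (any(alpha <= eps)) min(g[alpha <= eps]) else Inf
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(lo)) lo else mean(g)
  }
  structure(list(alpha = alpha, rho = rho, nu = nu,
                 decision_train = g - rho),
            class = "ocsvm_fit")
}

#' Train a binding-mode model from IPA triplet frames
#'
#' End-to-end training: optional Polar filtering, graph construction,
#' fingerprinting, Gram matrix, KNN-similarity profile, heuristic selection
#' of nu (and of the retained training set for QMS2), and the one-class SVM
#' fit. `method = "nn"` uses the non-normalized kernel with QMS2 selection;
#' the other methods use the normalized (cosine) kernel.
#'
#' @param triplet_sets list of [ipa_triplets()] tables, one per training
#'   frame.
#' @param interaction_set `"hyd"`, `"newhyd"` (both: frames used as given)
#'   or `"polar"` (hydrophobic triplets removed).
#' @param method `"qms2"`, `"mad"`, or `"nn"`.
#' @param sensitivity kneedle sensitivity for QMS2.
#' @return object of class `binding_mode_model` holding the support
#'   coefficients, offset, nu, kernel mode, vocabulary, retained training
#'   fingerprints and selection metadata.
#' @export
train_binding_mode_model <- function(triplet_sets,
                                     interaction_set = c("hyd", "newhyd",
                                                         "polar"),
                                     method = c("qms2", "mad", "nn"),
                                     sensitivity = 1) {
  interaction_set <- match.arg(interaction_set)
  method <- match.arg(method)
  if (interaction_set == "polar") {
    triplet_sets <- lapply(triplet_sets, filter_polar)
  }
  keep <- vapply(triplet_sets, nrow, integer(1)) > 0
  if (!all(keep)) {
    warning(sum(!keep), " empty training frame(s) dropped")
    triplet_sets <- triplet_sets[keep]
  }
  if (length(triplet_sets) < 2) stop("need at least 2 non-empty frames")
  kernel_mode <- if (method == "nn") "nn" else "normalized"
  fps <- lapply(triplet_sets, function(tr) sp_fingerprint(build_graph(tr)))
  gram <- sp_gram(fps, kernel_mode)
  profile <- knn_profile(gram)
  sel <- if (method == "mad") mad_nu(profile)
         else qms2_select(profile, sensitivity)
  idx <- sel$retained_indices
  fit <- train_ocsvm(gram[idx, idx, drop = FALSE], sel$nu)
  structure(list(
    alpha = fit$alpha, rho = fit$rho, nu = sel$nu,
    kernel_mode = kernel_mode, interaction_set = interaction_set,
    method = method, vocabulary = fit_vocabulary(fps[idx]),
    training_fps = fps[idx], selection = sel, profile = profile
  ), class = "binding_mode_model")
}

#' @export
print.binding_mode_model <- function(x, ...) {
  cat(sprintf(paste0("<binding_mode_model> %s/%s kernel=%s: %d training",
                     " graphs, nu=%.4g, %d SVs\n"),
              x$interaction_set, x$method, x$kernel_mode,
              length(x$training_fps), x$nu, sum(x$alpha > 1e-12)))
  invisible(x)
}

#' Score a graph against a trained model
#'
#' @param model a `binding_mode_model`.
#' @param graph an `interaction_graph`, or a precomputed fingerprint.
#' @return signed decision value; negative scores indicate an outlier.
#' @export
score_graph <- function(model, graph) {
  fp <- if (inherits(graph, "path_fingerprint")) graph
        else sp_fingerprint(graph)
  if (!length(fp)) {
    warning("empty fingerprint scored as outlier")
    return(-abs(model$rho))
  }
  k <- sp_cross(model$training_fps, fp, model$kernel_mode)[, 1]
  sum(model$alpha * k) - model$rho
}

#' Score an IPA triplet frame (pose) against a trained model
#'
#' Applies the model's interaction set (Polar filtering when required)
#' before graph construction; an empty pose is an outlier.
#'
#' @param model a `binding_mode_model`.
#' @param triplets an [ipa_triplets()] table.
#' @return signed decision value.
#' @export
score_pose <- function(model, triplets) {
  if (model$interaction_set == "polar") triplets <- filter_polar(triplets)
  if (is.null(triplets) || nrow(triplets) == 0) {
    warning("pose with no interactions scored as outlier")
    return(-abs(model$rho))
  }
  score_graph(model, build_graph(triplets))
}

#' @rdname score_graph
#' @param object a `binding_mode_model`.
#' @param newdata an `interaction_graph`, fingerprint, or list of them.
#' @param ... unused.
#' @return factor of `"inlier"`/`"outlier"` (score >= 0 is an inlier).
#' @export
predict.binding_mode_model <- function(object, newdata, ...) {
  if (!is.list(newdata) || inherits(newdata, "interaction_graph")) {
    newdata <- list(newdata)
  }
  sc <- vapply(newdata, function(g) score_graph(object, g), numeric(1))
  factor(ifelse(sc >= 0, "inlier", "outlier"),
         levels = c("inlier", "outlier"))
}

#' Serialise / restore a trained model as a JSON bundle
#'
#' @param model a `binding_mode_model`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  obj <- list(
    alpha = model$alpha, rho = model$rho, nu = model$nu,
    kernel_mode = model$kernel_mode, interaction_set = model$interaction_set,
    method = model$method, vocabulary = as.character(model$vocabulary),
    training_fps = lapply(model$training_fps, function(fp) {
      list(features = names(fp), counts = as.integer(fp))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fps <- lapply(obj$training_fps, function(e) {
    fp <- stats::setNames(as.integer(unlist(e$counts)),
                          as.character(unlist(e$features)))
    class(fp) <- "path_fingerprint"
    fp
  })
  vocab <- as.character(unlist(obj$vocabulary))
  class(vocab) <- c("sp_vocabulary", class(vocab))
  structure(list(
    alpha = as.numeric(unlist(obj$alpha)), rho = obj$rho, nu = obj$nu,
    kernel_mode = obj$kernel_mode, interaction_set = obj$interaction_set,
    method = obj$method, vocabulary = vocab, training_fps = fps,
    selection = NULL, profile = NULL
  ), class = "binding_mode_model")
}
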