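#' @title Extreme learning machine with analytic output weights
#'
#' @description
#' A single-hidden-layer feed-forward classifier in which the hidden-layer
#' parameters are drawn at random and only the output weights are learned,
#' in closed form, as the minimum-norm least-squares solution
#' `W = Y %*% pinv(Yh)`, where `Yh` is the hidden-layer response to the
#' training samples, `Y` the one-of-C encoded class targets, and `pinv` the
#' Moore-Penrose pseudoinverse.  Prediction takes the argmax over the C
#' output rows.  Because no iterative optimisation is involved, training is
#' fast enough to sit inside a wrapper feature-selection loop that fits
#' thousands of models.
#'
#' @name elm
NULL

# ---- label encoding ---------------------------------------------------------

#' One-of-C label encoding with symmetric targets
#'
#' Each class is represented by an output row; the true class gets
#' `target_hi` and all others `target_lo`.  Symmetric +1/-1 targets keep the
#' least-squares problem centred.
#'
#' @param labels Vector of class labels (character or factor).
#' @param target_hi Target value for the true class (default +1).
#' @param target_lo Target value for the other classes (default -1).
#' @return A `label_encoding` object: `classes` (sorted unique labels),
#'   `target_hi`, `target_lo`.
#' @export
label_encoding <- function(labels, target_hi = 1, target_lo = -1) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L)
    stop("label encoding needs >= 2 distinct classes, got ", length(classes))
  if (!(target_hi > target_lo))
    stop("target_hi must be > target_lo")
  structure(list(classes = classes, target_hi = target_hi,
                 target_lo = target_lo),
            class = "label_encoding")
}

#' Encode labels as a classes-by-samples target matrix
#'
#' @param encoding A `label_encoding`.
#' @param labels Labels to encode; must all be known to the encoding.
#' @return Numeric matrix, `n_classes` rows by `length(labels)` columns.
#' @export
encode_labels <- function(encoding, labels) {
  labels <- as.character(labels)
  idx <- match(labels, encoding$classes)
  if (anyNA(idx))
    stop("unknown class label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  Y <- matrix(encoding$target_lo, nrow = length(encoding$classes),
              ncol = length(labels),
              dimnames = list(encoding$classes, NULL))
  Y[cbind(idx, seq_along(labels))] <- encoding$target_hi
  Y
}

#' Decode a score matrix back to labels by row-wise argmax
#'
#' Ties resolve to the lowest class index (first maximum), which makes
#' prediction deterministic.
#'
#' @param encoding A `label_encoding`.
#' @param scores Matrix of outputs, `n_classes` rows by `n_samples` columns.
#' @return Character vector of predicted labels.
#' @export
decode_scores <- function(encoding, scores) {
  if (nrow(scores) != length(encoding$classes))
    stop("score matrix has ", nrow(scores), " rows but encoding has ",
         length(encoding$classes), " classes")
  encoding$classes[apply(scores, 2L, which.max)]
}

# ---- feature scaling --------------------------------------------------------

# z-score statistics learned on the training split; zero-variance features
# get scale 1 so they pass through centred without a divide-by-zero.
fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

# ---- hidden layer -----------------------------------------------------------

#' Draw random hidden-layer parameters
#'
#' For the sigmoid activation, input weights and biases are uniform on
#' \[-1, 1\].  For the Gaussian RBF activation, centers are sampled (with
#' replacement if needed) from the training rows and every width is set to
#' the median pairwise distance between training samples.
#'
#' @param n_hidden Number of hidden neurons (>= 1).
#' @param n_features Number of input features.
#' @param activation `"sigmoid"` or `"rbf"`.
#' @param X_train Training matrix (samples x features); required for rbf.
#' @param seed Integer seed.
#' @return A `hidden_layer_params` object with `input_weights`
#'   (`n_hidden` x `n_features`), `bias` (length `n_hidden`), `activation`.
#' @export
random_hidden_params <- function(n_hidden, n_features,
                                 activation = c("sigmoid", "rbf"),
                                 X_train = NULL, seed = 1L) {
  activation <- match.arg(activation)
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) stop("n_hidden must be >= 1")
  if (activation == "sigmoid") {
    out <- with_seed(seed, {
      V <- matrix(stats::runif(n_hidden * n_features, -1, 1),
                  nrow = n_hidden)
      b <- stats::runif(n_hidden, -1, 1)
      list(V = V, b = b)
    })
  } else {
    if (is.null(X_train))
      stop("rbf activation needs X_train to draw centers and widths")
    D <- stats::dist(X_train)
    sigma <- stats::median(D)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    out <- with_seed(seed, {
      take <- sample.int(nrow(X_train), n_hidden,
                         replace = n_hidden > nrow(X_train))
      list(V = X_train[take, , drop = FALSE], b = rep(sigma, n_hidden))
    })
  }
  structure(list(n_hidden = n_hidden, input_weights = out$V, bias = out$b,
                 activation = activation),
            class = "hidden_layer_params")
}

#' Hidden-layer response matrix
#'
#' Sigmoid neurons compute `1 / (1 + exp(-(v_j . x_i + b_j)))`; RBF neurons
#' compute `exp(-||x_i - mu_j||^2 / (2 sigma_j^2))` with center `mu_j` (row
#' j of the input weights) and width `sigma_j` (bias entry j).
#'
#' @param X Feature matrix, samples in rows.
#' @param hidden A `hidden_layer_params` object.
#' @return Matrix of responses, `n_hidden` rows by `n_samples` columns.
#' @export
hidden_response <- function(X, hidden) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X)))
    stop("feature matrix contains non-finite values")
  if (ncol(X) != ncol(hidden$input_weights))
    stop("feature count mismatch: X has ", ncol(X), " features, hidden ",
         "layer expects ", ncol(hidden$input_weights))
  if (hidden$activation == "sigmoid") {
    A <- hidden$input_weights %*% t(X) + hidden$bias
    1 / (1 + exp(-A))
  } else {
    # squared distances via the expansion ||x||^2 - 2 x.mu + ||mu||^2
    mu <- hidden$input_weights
    d2 <- outer(rowSums(mu^2), rowSums(X^2), "+") - 2 * mu %*% t(X)
    d2[d2 < 0] <- 0 # numerical guard
    exp(-d2 / (2 * hidden$bias^2))
  }
}

# ---- pseudoinverse ----------------------------------------------------------

# SVD-based Moore-Penrose pseudoinverse.  Singular values below
# rtol * max(sv) are treated as zero; robust to the rank deficiency that
# arises routinely when n_hidden exceeds the training-set size.
pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# ---- training / prediction --------------------------------------------------

#' Train an extreme learning machine
#'
#' Features are z-scored with training-split statistics, a random hidden
#' layer is drawn, and the output weights are the least-squares solution
#' `W = Y_encoded %*% pinv(Yh)`.
#'
#' @param X Training matrix, samples in rows, features in columns.
#' @param y Training class labels (length `nrow(X)`); >= 2 classes required.
#' @param n_hidden Hidden neurons; default `min(nrow(X), 100)`.
#' @param activation `"sigmoid"` (default) or `"rbf"`.
#' @param seed Integer seed controlling the hidden-layer draw.
#' @param hidden Optionally, a pre-built `hidden_layer_params` object
#'   (then `n_hidden`, `activation` and `seed` are ignored).
#' @return An `elm_model`: `hidden`, `output_weights` (classes x hidden),
#'   `encoding`, `scaler`, `n_features`.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- rep(c("a", "b"), each = 10)
#' X[y == "b", ] <- X[y == "b", ] + 3
#' m <- train_elm(X, y, n_hidden = 10, seed = 1)
#' mean(predict_elm(m, X) == y)
#' @export
train_elm <- function(X, y, n_hidden = NULL,
                      activation = c("sigmoid", "rbf"), seed = 1L,
                      hidden = NULL) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y))
    stop("X has ", nrow(X), " rows but y has ", length(y), " labels")
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; the argmax decision rule ",
         "is undefined")
  if (anyNA(X) || any(!is.finite(X)))
    stop("training matrix contains non-finite values")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  if (is.null(hidden)) {
    if (is.null(n_hidden)) n_hidden <- min(nrow(X), 100L)
    hidden <- random_hidden_params(n_hidden, ncol(X), activation,
                                   X_train = Xs, seed = seed)
  }
  encoding <- label_encoding(y)
  Yh <- hidden_response(Xs, hidden)     # n_hidden x n_train
  Y <- encode_labels(encoding, y)       # n_classes x n_train
  W <- Y %*% pinv(Yh)
  structure(list(hidden = hidden, output_weights = W, encoding = encoding,
                 scaler = scaler, n_features = ncol(X)),
            class = "elm_model")
}

#' Raw class scores of an ELM
#'
#' @param model An `elm_model`.
#' @param X Feature matrix, samples in rows.
#' @return Score matrix, classes x samples.
#' @export
elm_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature count mismatch: X has ", ncol(X), " features, model was ",
         "trained on ", model$n_features)
  model$output_weights %*% hidden_response(apply_scaler(model$scaler, X),
                                           model$hidden)
}

#' Predict class labels with a trained ELM
#'
#' Returns, per sample, the class whose output is maximal; ties resolve to
#' the lowest class index.
#'
#' @inheritParams elm_scores
#' @return Character vector of predicted labels.
#' @export
predict_elm <- function(model, X) {
  decode_scores(model$encoding, elm_scores(model, X))
}

#' @export
predict.elm_model <- function(object, newdata, ...) {
  predict_elm(object, newdata)
}

#' @export
print.elm_model <- function(x, ...) {
  cat("<elm_model> ", x$hidden$n_hidden, " ", x$hidden$activation,
      " hidden neurons, ", length(x$encoding$classes), " classes, ",
      x$n_features, " features\n", sep = "")
  invisible(x)
}

# ---- tuning -----------------------------------------------------------------

#' Select hidden-layer size and random weights by validation error
#'
#' Random-restart search over a grid of hidden-neuron counts: every
#' (count, restart) pair trains a fresh model and is scored on the
#' validation set.  The primary criterion is the misclassification count;
#' ties break on the squared error between encoded targets and raw outputs,
#' then on the earlier candidate (deterministic given `seed`).
#'
#' @param X_train,y_train Training samples and labels.
#' @param X_val,y_val Validation samples and labels (nonempty).
#' @param candidate_hidden_counts Integer vector of hidden-layer sizes.
#' @param n_restarts Random restarts per candidate size (>= 1).
#' @param activation `"sigmoid"` or `"rbf"`.
#' @param seed Integer master seed.
#' @return The winning `elm_model`, with attributes `val_errors` (matrix of
#'   misclassification counts, candidates x restarts) and `selected`
#'   (list with `n_hidden`, `restart`).
#' @export
tune_elm <- function(X_train, y_train, X_val, y_val,
                     candidate_hidden_counts, n_restarts = 1L,
                     activation = c("sigmoid", "rbf"), seed = 1L) {
  activation <- match.arg(activation)
  if (length(candidate_hidden_counts) < 1L)
    stop("candidate_hidden_counts must be nonempty")
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  X_val <- as.matrix(X_val)
  if (nrow(X_val) < 1L) stop("validation set is empty")
  y_val <- as.character(y_val)

  best <- NULL
  errs <- matrix(NA_real_, length(candidate_hidden_counts), n_restarts)
  for (ci in seq_along(candidate_hidden_counts)) {
    for (ri in seq_len(n_restarts)) {
      m <- train_elm(X_train, y_train,
                     n_hidden = candidate_hidden_counts[ci],
                     activation = activation,
                     seed = derive_seed(seed, ci, ri))
      pred <- predict_elm(m, X_val)
      miscls <- sum(pred != y_val)
      T_val <- elm_scores(m, X_val)
      Y_val <- encode_labels(m$encoding, y_val)
      sq <- sum((Y_val - T_val)^2)
      errs[ci, ri] <- miscls
      if (is.null(best) || miscls < best$miscls ||
          (miscls == best$miscls && sq < best$sq)) {
        best <- list(model = m, miscls = miscls, sq = sq,
                     n_hidden = candidate_hidden_counts[ci], restart = ri)
      }
    }
  }
  out <- best$model
  attr(out, "val_errors") <- errs
  attr(out, "selected") <- list(n_hidden = best$n_hidden,
                                restart = best$restart,
                                miscls = best$miscls, sq_error = best$sq)
  out
}

# ---- serialization ----------------------------------------------------------

#' Save / load an ELM model as JSON
#'
#' The stored parameters (hidden weights, biases, output weights, encoding,
#' scaler) fully determine predictions on new samples.
#'
#' @param model An `elm_model`.
#' @param path File path.
#' @return `write_elm` returns `path` invisibly; `read_elm` the model.
#' @export
write_elm <- function(model, path) {
  obj <- list(
    activation = model$hidden$activation,
    n_hidden = model$hidden$n_hidden,
    input_weights = model$hidden$input_weights,
    bias = model$hidden$bias,
    output_weights = model$output_weights,
    classes = model$encoding$classes,
    target_hi = model$encoding$target_hi,
    target_lo = model$encoding$target_lo,
    scaler_center = model$scaler$center,
    scaler_scale = model$scaler$scale,
    n_features = model$n_features
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  hidden <- structure(list(n_hidden = as.integer(o$n_hidden),
                           input_weights = as.matrix(o$input_weights),
                           bias = as.numeric(o$bias),
                           activation = o$activation),
                      class = "hidden_layer_params")
  enc <- structure(list(classes = as.character(o$classes),
                        target_hi = o$target_hi, target_lo = o$target_lo),
                   class = "label_encoding")
  W <- as.matrix(o$output_weights)
  rownames(W) <- enc$classes
  structure(list(hidden = hidden, output_weights = W, encoding = enc,
                 scaler = list(center = as.numeric(o$scaler_center),
                               scale = as.numeric(o$scaler_scale)),
                 n_features = as.integer(o$n_features)),
            class = "elm_model")
}
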