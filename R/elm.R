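## Extreme learning machine: single-hidden-layer network with randomly drawn
## hidden-node parameters and output weights solved in closed form from
## H beta = T (minimum-norm least squares).

elm_node_types <- c("sigmoid", "rbf", "wavelet")

## hidden-layer output matrix for an N x n feature matrix
elm_hidden_matrix <- function(X, a, b, node_type) {
  switch(node_type,
    sigmoid = {
      Z <- X %*% t(a) + matrix(b, nrow(X), length(b), byrow = TRUE)
      1 / (1 + exp(-Z))
    },
    rbf = {
      D2 <- outer(rowSums(X^2), rowSums(a^2), "+") - 2 * X %*% t(a)
      exp(-sweep(pmax(D2, 0), 2, b, "*"))
    },
    wavelet = {
      D2 <- pmax(outer(rowSums(X^2), rowSums(a^2), "+") - 2 * X %*% t(a), 0)
      Z <- sweep(sqrt(D2), 2, b, "/")
      (1 - Z^2) * exp(-Z^2 / 2)
    },
    stopf("unknown node_type '%s'", node_type))
}

## minimum-norm least-squares solution of H beta = T via SVD pseudo-inverse
pinv_solve <- function(H, T, ridge = 0) {
  if (ridge > 0)
    return(solve(crossprod(H) + ridge * diag(ncol(H)), crossprod(H, T)))
  sv <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(H), ncol(T)))
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% T) / sv$d[pos])
}

#' Fit an extreme learning machine classifier
#'
#' Hidden-node input weights `a` are drawn uniformly on `[-1, 1]` and biases
#' or widths `b` uniformly on `(0, 1]` from a private generator seeded by
#' `seed`; output weights solve `H beta = T` (one-hot targets in `{0, 1}`)
#' by the minimum-norm pseudo-inverse, so a rank-deficient hidden matrix is
#' handled without failure. With `L >= N` distinct samples the network
#' interpolates the training set with zero error.
#'
#' @param x numeric feature matrix (N x n) or vector (one sample).
#' @param y class labels (factor or character/numeric), length N.
#' @param L number of hidden nodes (>= 1).
#' @param node_type `"sigmoid"` (logistic additive node), `"rbf"`
#'   (Gaussian radial node) or `"wavelet"` (Mexican-hat radial node).
#' @param seed integer seed for the hidden-node draw (mandatory).
#' @param ridge optional ridge penalty on the output weights; default 0
#'   (pure pseudo-inverse).
#' @return An object of class `elm`.
#' @export
elm <- function(x, y, L, node_type = c("sigmoid", "rbf", "wavelet"), seed,
                ridge = 0) {
  node_type <- match.arg(node_type)
  if (missing(seed)) stopf("`seed` is mandatory for a reproducible ELM")
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  x <- check_matrix(x, "x")
  L <- check_count(L, "L")
  if (length(y) != nrow(x)) stopf("`y` must have one label per row of `x`")
  y <- factor(y)
  classes <- levels(y)
  N <- nrow(x); n <- ncol(x); m <- length(classes)
  T <- matrix(0, N, m)
  T[cbind(seq_len(N), as.integer(y))] <- 1
  draws <- with_seed(seed, list(
    a = matrix(runif(L * n, -1, 1), L, n),
    b = pmax(runif(L), 1e-8)))
  H <- elm_hidden_matrix(x, draws$a, draws$b, node_type)
  beta_out <- pinv_solve(H, T, ridge)
  structure(list(a = draws$a, b = draws$b, beta_out = beta_out,
                 node_type = node_type, L = L, n_features = n,
                 classes = classes, seed = as.integer(seed), ridge = ridge),
            class = "elm")
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("ELM classifier: %d %s hidden nodes, %d features, %d classes (seed %d)\n",
              x$L, x$node_type, x$n_features, length(x$classes), x$seed))
  invisible(x)
}

#' @export
coef.elm <- function(object, ...) object$beta_out

#' Predict classes or scores from an ELM
#'
#' @param object an [elm()] fit.
#' @param newdata numeric matrix (N x n) or single feature vector.
#' @param type `"class"` for labels (argmax of the output vector, ties to the
#'   lowest class index) or `"score"` for the raw N x m output matrix.
#' @param ... unused.
#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.vector(newdata) && is.numeric(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- check_matrix(newdata, "newdata")
  if (ncol(newdata) != object$n_features)
    stopf("`newdata` has %d features; model expects %d", ncol(newdata),
          object$n_features)
  H <- elm_hidden_matrix(newdata, object$a, object$b, object$node_type)
  S <- H %*% object$beta_out
  colnames(S) <- object$classes
  if (type == "score") return(S)
  factor(object$classes[apply(S, 1, which.max)], levels = object$classes)
}

#' Hidden-node outputs for a single feature vector
#'
#' Evaluates the L hidden nodes at `x`: logistic `g(a_i . x + b_i)` for
#' sigmoid nodes, `exp(-b_i ||x - a_i||^2)` for RBF nodes, and the
#' Mexican-hat `(1 - z^2) exp(-z^2 / 2)` with `z = ||x - a_i|| / b_i` for
#' wavelet nodes.
#'
#' @param model an [elm()] fit.
#' @param x numeric feature vector of length `n_features`.
#' @return Numeric L-vector.
#' @export
hidden_output <- function(model, x) {
  if (!inherits(model, "elm")) stopf("`model` must be an elm")
  if (!is.numeric(x) || length(x) != model$n_features)
    stopf("`x` must be a numeric vector of length %d", model$n_features)
  as.numeric(elm_hidden_matrix(matrix(x, nrow = 1), model$a, model$b,
                               model$node_type))
}

#' Serialise an ELM to a text archive
#'
#' Metadata record (node type, L, feature count, classes, seed) plus flat
#' arrays `a`, `b`, `beta_out`; numeric values round-trip bit-exactly.
#'
#' @param model an [elm()] fit.
#' @param path file path.
#' @export
write_elm <- function(model, path) {
  write_archive(path, "elm",
                meta = list(node_type = model$node_type, L = model$L,
                            n_features = model$n_features,
                            classes = paste(model$classes, collapse = ","),
                            seed = model$seed, ridge = model$ridge),
                arrays = list(a = model$a, b = model$b,
                              beta_out = model$beta_out))
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  ar <- read_archive(path, "elm")
  m <- ar$meta
  structure(list(a = ar$arrays$a, b = as.numeric(ar$arrays$b),
                 beta_out = ar$arrays$beta_out,
                 node_type = m$node_type,
                 L = as.integer(meta_num(m, "L")),
                 n_features = as.integer(meta_num(m, "n_features")),
                 classes = strsplit(m$classes, ",", fixed = TRUE)[[1]],
                 seed = as.integer(meta_num(m, "seed")),
                 ridge = meta_num(m, "ridge")),
            class = "elm")
}
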