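#' Kernel specification for the final-stage SVM
#'
#' Two kernel families are supported: the polynomial kernel
#' `(scale * <x, z> + offset)^degree` (defaults: degree 3, scale 1, offset
#' 0) and a classically simulated second-order-expansion quantum feature
#' map, where each feature vector (rescaled to `[0, pi]`) is encoded as the
#' statevector of `[H^n . diag-phase]^repetitions |0...0>` with first-order
#' Pauli-Z angles `theta_i = x_i` and pairwise ZZ angles
#' `theta_ij = (pi - x_i)(pi - x_j)`, and the kernel is the squared state
#' overlap `|<phi(x), phi(z)>|^2`.
#'
#' @param family `"polynomial"` (default, matching the hyperparameter-table
#'   reading) or `"quantum_second_order"`.
#' @param degree Polynomial degree (>= 1). Default 3.
#' @param scale Polynomial scale. Default 1.
#' @param offset Polynomial offset. Default 0.
#' @param n_qubits Qubit count = feature dimension for the quantum family
#'   (1..12, statevector bound). Default 4.
#' @param repetitions Feature-map depth. Default 2.
#' @param entanglement Two-column integer matrix of qubit pairs; `NULL`
#'   (default) means all pairs `i < j`.
#' @param angle_scale Multiplier mapping features to rotation angles,
#'   `theta_i = angle_scale * x_i` (the kernel's bandwidth control). With
#'   features rescaled to `[0, pi]`, the default 0.1 keeps within-class
#'   phase spreads well below a radian so the fidelity kernel stays wide;
#'   `angle_scale = 1` gives the raw textbook map.
#'
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("polynomial", "quantum_second_order"),
                        degree = 3, scale = 1.0, offset = 0.0,
                        n_qubits = 4, repetitions = 2, entanglement = NULL,
                        angle_scale = 0.1) {
  family <- match.arg(family)
  ll_assert(angle_scale > 0, "`angle_scale` must be > 0")
  ll_assert(degree >= 1, "`degree` must be >= 1")
  ll_assert(n_qubits >= 1, "`n_qubits` must be >= 1")
  if (!is.null(entanglement)) {
    entanglement <- as.matrix(entanglement)
    ll_assert(ncol(entanglement) == 2 &&
                all(entanglement >= 1 & entanglement <= n_qubits),
              "entanglement pairs must index qubits 1..n_qubits")
  }
  structure(
    list(family = family, degree = degree, scale = scale, offset = offset,
         n_qubits = as.integer(n_qubits), repetitions = as.integer(repetitions),
         entanglement = entanglement, angle_scale = angle_scale),
    class = "kernel_spec"
  )
}

default_entanglement <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(n, 2))
}

#' Polynomial kernel
#'
#' `K(x, z) = (scale * <x, z> + offset)^degree`.
#'
#' @param x,z Feature vectors of equal length.
#' @param spec A [kernel_spec()].
#' @return Scalar kernel value.
#' @export
poly_kernel <- function(x, z, spec = kernel_spec()) {
  ll_assert(length(x) == length(z), "feature dimensions differ",
            "lesionlab_shape_mismatch")
  (spec$scale * sum(x * z) + spec$offset)^spec$degree
}

# Fast Walsh-Hadamard transform with 1/sqrt(2) normalization per stage,
# i.e. application of H^{\otimes n} to a length-2^n amplitude vector.
fwht_unitary <- function(psi) {
  len <- length(psi)
  h <- 1L
  while (h < len) {
    for (start in seq(1L, len, by = 2L * h)) {
      a <- psi[start:(start + h - 1L)]
      b <- psi[(start + h):(start + 2L * h - 1L)]
      psi[start:(start + h - 1L)] <- a + b
      psi[(start + h):(start + 2L * h - 1L)] <- a - b
    }
    h <- 2L * h
  }
  psi / sqrt(len)
}

# Pauli-Z eigenvalue table: 2^n x n matrix of +1/-1, qubit 1 fastest.
z_eigen_table <- function(n) {
  b <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  1 - 2 * b
}

# Diagonal phase vector of the second-order-expansion layer for features x.
soe_phase <- function(x, spec) {
  x <- spec$angle_scale * x
  n <- length(x)
  Z <- z_eigen_table(n)
  phase <- Z %*% x
  ent <- spec$entanglement
  if (is.null(ent)) ent <- default_entanglement(n)
  if (nrow(ent)) {
    th2 <- (pi - x[ent[, 1L]]) * (pi - x[ent[, 2L]])
    phase <- phase + (Z[, ent[, 1L], drop = FALSE] *
                        Z[, ent[, 2L], drop = FALSE]) %*% th2
  }
  exp(1i * as.vector(phase))
}

#' Second-order-expansion statevector
#'
#' Amplitudes of `[diag-phase . H^n]^repetitions |0...0>` for the feature
#' vector `x`: each repetition applies a Hadamard on every qubit followed by
#' the diagonal phase layer with single-qubit angles `x_i` and pairwise ZZ
#' angles `(pi - x_i)(pi - x_j)` over the entanglement pairs.
#'
#' @param x Feature vector; `length(x)` must equal `spec$n_qubits` (<= 12).
#' @param spec A [kernel_spec()].
#' @return Complex amplitude vector of length `2^n_qubits` with unit norm.
#' @export
soe_statevector <- function(x, spec = kernel_spec(n_qubits = length(x))) {
  n <- length(x)
  ll_assert(n == spec$n_qubits, "feature dimension must equal n_qubits",
            "lesionlab_shape_mismatch")
  ll_assert(n <= 12, "statevector simulation bounded at 12 qubits",
            "lesionlab_too_many_qubits")
  phase <- soe_phase(x, spec)
  psi <- complex(real = c(1, numeric(2^n - 1)))
  for (r in seq_len(max(1L, spec$repetitions))) {
    psi <- phase * fwht_unitary(psi)
  }
  psi
}

#' Quantum fidelity kernel
#'
#' `K(x, z) = |<phi(x), phi(z)>|^2` with `phi` the second-order-expansion
#' statevector. `K(x, x) = 1` and `K` is symmetric.
#'
#' @param x,z Feature vectors of length `spec$n_qubits`.
#' @param spec A [kernel_spec()].
#' @return Scalar kernel value in \[0, 1\].
#' @export
quantum_kernel <- function(x, z, spec = kernel_spec(n_qubits = length(x))) {
  phi_x <- soe_statevector(x, spec)
  phi_z <- soe_statevector(z, spec)
  Mod(sum(Conj(phi_x) * phi_z))^2
}

# Statevector matrix (n_samples x 2^n) for the quantum family.
soe_statevectors <- function(X, spec) {
  t(apply(X, 1L, soe_statevector, spec = spec))
}

#' Kernel Gram matrix
#'
#' @param X Feature matrix (samples in rows).
#' @param spec A [kernel_spec()].
#' @return Symmetric Gram matrix; unit diagonal for the quantum family.
#' @export
gram_matrix <- function(X, spec = kernel_spec()) {
  X <- as.matrix(X)
  ll_assert(all(is.finite(X)), "non-finite features",
            "lesionlab_invalid_argument")
  G <- if (spec$family == "polynomial") {
    (spec$scale * tcrossprod(X) + spec$offset)^spec$degree
  } else {
    S <- soe_statevectors(X, spec)
    Mod(tcrossprod(S, Conj(S)))^2
  }
  (G + t(G)) / 2
}

cross_kernel <- function(X_new, X_ref, spec) {
  if (spec$family == "polynomial") {
    (spec$scale * tcrossprod(as.matrix(X_new), as.matrix(X_ref)) +
       spec$offset)^spec$degree
  } else {
    Sn <- soe_statevectors(as.matrix(X_new), spec)
    Sr <- soe_statevectors(as.matrix(X_ref), spec)
    Mod(tcrossprod(Sn, Conj(Sr)))^2
  }
}

#' Reduce latent codes to kernel-ready features
#'
#' Mean-centered linear projection onto the `n_components` leading-variance
#' directions (principal components) followed by an affine rescale of each
#' coordinate to `[0, pi]`. The projection is fitted on training data only;
#' apply it to new data with [project_features()] (coordinates are clamped
#' to `[0, pi]`).
#'
#' @param Z Latent feature matrix (samples in rows, >= 2 rows).
#' @param n_components Number of components to keep (<= latent dimension).
#' @return List with `features` (n x n_components matrix in `[0, pi]`) and
#'   `projection` (an object of class `latent_projection`).
#' @export
reduce_features <- function(Z, n_components) {
  Z <- as.matrix(Z)
  ll_assert(nrow(Z) >= 2, "need at least 2 samples to fit the projection",
            "lesionlab_empty_input")
  ll_assert(ncol(Z) >= n_components,
            "latent dimension must be >= n_components")
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  lo <- apply(scores, 2L, min)
  hi <- apply(scores, 2L, max)
  span <- pmax(hi - lo, 1e-12)
  proj <- structure(
    list(rotation = rot, center = pc$center, lo = lo, span = span,
         n_components = as.integer(n_components)),
    class = "latent_projection"
  )
  list(features = project_features(proj, Z), projection = proj)
}

#' Apply a fitted latent projection
#'
#' @param projection A `latent_projection` from [reduce_features()].
#' @param Z New latent matrix (samples in rows).
#' @return Feature matrix with coordinates clamped to `[0, pi]`.
#' @export
project_features <- function(projection, Z) {
  Z <- as.matrix(Z)
  scores <- sweep(Z, 2L, projection$center) %*% projection$rotation
  scaled <- sweep(sweep(scores, 2L, projection$lo), 2L, projection$span, "/")
  clamp(scaled, 0, 1) * pi
}

#' Fit a soft-margin kernel SVM (one-vs-rest)
#'
#' Solves, for each class, the dual of
#' `argmin_w 1/2 ||w||^2 + C sum_i xi_i` over the precomputed Gram matrix
#' (interior-point QP via `kernlab::ipop`), and stores support vectors, dual
#' coefficients `alpha`, labels and bias `d` per binary machine. The duals
#' satisfy the KKT box constraint `0 <= alpha_i <= C` and
#' `sum_i alpha_i y_i = 0` within solver tolerance.
#'
#' @param X Feature matrix (samples in rows).
#' @param y Integer class labels `0..K-1` (>= 2 classes present).
#' @param spec A [kernel_spec()].
#' @param C Slack penalty bound (> 0). Default 1.
#' @param projection Optional `latent_projection` stored with the model so
#'   that [predict()] can map raw latents.
#' @return An object of class `qsvm_model`.
#' @export
fit_qsvm <- function(X, y, spec = kernel_spec(), C = 1.0, projection = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  classes <- sort(unique(y))
  ll_assert(length(classes) >= 2, "need at least 2 classes",
            "lesionlab_single_class")
  ll_assert(C > 0, "`C` must be > 0")
  n <- nrow(X)
  G <- gram_matrix(X, spec)
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6) {
    ll_stop(paste0("Gram matrix is not PSD (min eigenvalue ", ev_min,
                   "); consider adding jitter"), "lesionlab_not_psd")
  }
  # diagonal jitter proportional to the kernel scale; escalate on the rare
  # near-singular interior-point systems
  jitter0 <- 1e-8 * max(1, mean(diag(G)))
  machines <- lapply(classes, function(cls) {
    yb <- ifelse(y == cls, 1, -1)
    sol <- NULL
    jitter <- jitter0
    for (attempt in 1:4) {
      H <- (yb %o% yb) * G + diag(jitter, n)
      sol <- tryCatch(
        kernlab::ipop(c = rep(-1, n), H = H, A = matrix(yb, 1L, n), b = 0,
                      l = rep(0, n), u = rep(C, n), r = 0,
                      sigf = 8, maxiter = 100),
        error = function(e) NULL
      )
      if (!is.null(sol)) break
      jitter <- jitter * 100
    }
    if (is.null(sol)) {
      ll_stop("dual QP solve failed even with diagonal jitter",
              "lesionlab_qp_failure")
    }
    alpha <- clamp(kernlab::primal(sol), 0, C)
    alpha[alpha < 1e-8 * C] <- 0
    f0 <- as.vector(G %*% (alpha * yb))
    free <- alpha > 1e-6 * C & alpha < C * (1 - 1e-6)
    d <- if (any(free)) {
      mean(yb[free] - f0[free])
    } else if (any(alpha > 0)) {
      mean(yb[alpha > 0] - f0[alpha > 0])
    } else 0
    list(class = cls, alpha = alpha, yb = yb, d = d)
  })
  structure(
    list(machines = machines, classes = classes, spec = spec, C = C,
         X = X, projection = projection),
    class = "qsvm_model"
  )
}

#' @export
print.qsvm_model <- function(x, ...) {
  cat(sprintf("<qsvm_model> %d classes (one-vs-rest), %s kernel, C = %g\n",
              length(x$classes), x$spec$family, x$C))
  for (m in x$machines) {
    cat(sprintf("  class %d: %d support vectors, bias %.4f\n",
                m$class, sum(m$alpha > 0), m$d))
  }
  invisible(x)
}

#' Predict classes with a fitted kernel SVM
#'
#' Decision values are `f(x) = sum_i alpha_i y_i K(s_i, x) + d` per binary
#' machine; the multi-class label is the argmax over one-vs-rest scores with
#' ties broken toward the lowest class index.
#'
#' @param object A `qsvm_model`.
#' @param X Feature matrix; when the model stores a projection and `project =
#'   TRUE`, raw latent rows are mapped through it first.
#' @param type `"class"` (default) for labels, `"score"` for the decision
#'   matrix.
#' @param project Whether to apply the stored projection. Default `TRUE`
#'   when one is present and the column count matches its input space.
#' @param ... Unused.
#' @return Integer labels (with the score matrix as attribute `"scores"`),
#'   or the score matrix itself for `type = "score"`.
#' @export
predict.qsvm_model <- function(object, X, type = c("class", "score"),
                               project = NULL, ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (is.null(project)) {
    project <- !is.null(object$projection) &&
      ncol(X) == nrow(object$projection$rotation) &&
      ncol(X) != ncol(object$X)
  }
  if (project) X <- project_features(object$projection, X)
  ll_assert(ncol(X) == ncol(object$X), "feature dimension mismatch",
            "lesionlab_shape_mismatch")
  Kx <- cross_kernel(X, object$X, object$spec)
  scores <- vapply(object$machines, function(m) {
    as.vector(Kx %*% (m$alpha * m$yb)) + m$d
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  colnames(scores) <- as.character(object$classes)
  if (type == "score") return(scores)
  labels <- object$classes[max.col(scores, ties.method = "first")]
  attr(labels, "scores") <- scores
  labels
}
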