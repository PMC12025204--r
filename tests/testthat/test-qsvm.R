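test_that("polynomial kernel evaluates its closed form", {
  spec <- kernel_spec()
  e1 <- c(1, 0, 0)
  expect_equal(poly_kernel(e1, e1, spec), 1)
  expect_equal(poly_kernel(c(1, 0), c(0, 1), spec), 0)
  set.seed(2)
  x <- rnorm(5); z <- rnorm(5)
  expect_lt(abs(poly_kernel(x, z, spec) - (sum(x * z))^3), 1e-12)
  expect_lt(abs(poly_kernel(x, z, kernel_spec(degree = 2, scale = 0.5,
                                              offset = 1.5)) -
                  (0.5 * sum(x * z) + 1.5)^2), 1e-12)
  expect_error(poly_kernel(x, z[1:3], spec),
               class = "lesionlab_shape_mismatch")
})

test_that("statevectors are unit norm with uniform zero-angle probabilities", {
  for (n in 2:4) {
    spec <- kernel_spec("quantum_second_order", n_qubits = n,
                        repetitions = 1, angle_scale = 1)
    psi <- soe_statevector(rep(0, n), spec)
    expect_equal(sum(Mod(psi)^2), 1, tolerance = 1e-10)
    expect_equal(Mod(psi)^2, rep(2^-n, 2^n), tolerance = 1e-10)
    set.seed(n)
    psi2 <- soe_statevector(runif(n, 0, pi),
                            kernel_spec("quantum_second_order", n_qubits = n,
                                        angle_scale = 1))
    expect_equal(sum(Mod(psi2)^2), 1, tolerance = 1e-10)
  }
  expect_error(
    soe_statevector(rep(0, 13),
                    kernel_spec("quantum_second_order", n_qubits = 13,
                                angle_scale = 1)),
    class = "lesionlab_too_many_qubits")
})

test_that("statevectors match the dense-unitary oracle", {
  spec2 <- kernel_spec("quantum_second_order", n_qubits = 2,
                       repetitions = 2, angle_scale = 1)
  x <- c(0.3, 1.1)
  expect_lt(max(Mod(soe_statevector(x, spec2) -
                      oracle_soe_statevector(x, repetitions = 2))), 1e-10)
  set.seed(7)
  for (n in 2:4) {
    spec <- kernel_spec("quantum_second_order", n_qubits = n,
                        repetitions = 2, angle_scale = 1)
    for (t in 1:5) {
      v <- runif(n, 0, pi)
      expect_lt(max(Mod(soe_statevector(v, spec) -
                          oracle_soe_statevector(v, repetitions = 2))), 1e-10)
    }
  }
})

test_that("the quantum kernel is a normalized symmetric fidelity", {
  set.seed(3)
  spec <- kernel_spec("quantum_second_order", n_qubits = 3, angle_scale = 1)
  for (t in 1:5) {
    x <- runif(3, 0, pi); z <- runif(3, 0, pi)
    expect_equal(quantum_kernel(x, x, spec), 1, tolerance = 1e-10)
    kxz <- quantum_kernel(x, z, spec)
    expect_equal(kxz, quantum_kernel(z, x, spec), tolerance = 1e-12)
    oracle <- Mod(sum(Conj(oracle_soe_statevector(x)) *
                        oracle_soe_statevector(z)))^2
    expect_lt(abs(kxz - oracle), 1e-10)
  }
})

test_that("Gram matrices are symmetric PSD with entrywise agreement", {
  set.seed(4)
  spec <- kernel_spec("quantum_second_order", n_qubits = 3, angle_scale = 1)
  expect_equal(gram_matrix(matrix(runif(3, 0, pi), 1), spec),
               matrix(1, 1, 1), tolerance = 1e-10)
  X <- matrix(runif(30, 0, pi), 10, 3)
  for (fam in list(spec, kernel_spec())) {
    G <- gram_matrix(X, fam)
    expect_equal(G, t(G))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    for (t in 1:5) {
      i <- sample(10, 1); j <- sample(10, 1)
      kij <- if (fam$family == "polynomial") {
        poly_kernel(X[i, ], X[j, ], fam)
      } else quantum_kernel(X[i, ], X[j, ], fam)
      expect_lt(abs(G[i, j] - kij), 1e-10)
    }
  }
  expect_error(gram_matrix(matrix(c(1, NA), 1), kernel_spec()))
})

test_that("feature reduction projects, rescales and orders variance", {
  set.seed(5)
  Z <- matrix(rnorm(200 * 10), 200, 10) %*% diag(c(5, 3, rep(0.5, 8)))
  red <- reduce_features(Z, 4)
  expect_equal(dim(red$features), c(200L, 4L))
  expect_true(all(red$features >= 0 & red$features <= pi))
  # kept directions are the leading-variance ones (eigen-decomposition oracle)
  scores <- sweep(Z, 2, red$projection$center) %*% red$projection$rotation
  ev <- eigen(cov(Z), symmetric = TRUE)$values[1:4]
  expect_equal(as.vector(apply(scores, 2, var)), ev, tolerance = 1e-8)
  expect_true(all(diff(apply(scores, 2, var)) <= 1e-8))
  # projection reuse: held-out data passes through the stored transform
  Znew <- matrix(rnorm(50 * 10), 50, 10)
  Fnew <- project_features(red$projection, Znew)
  expect_true(all(Fnew >= 0 & Fnew <= pi))
  expect_error(reduce_features(Z[1, , drop = FALSE], 2),
               class = "lesionlab_empty_input")
})

test_that("separable problems are solved exactly with valid KKT duals", {
  # 1-D separable pair, linear kernel
  lin <- kernel_spec(degree = 1)
  fit <- fit_qsvm(matrix(c(-1, 1), 2, 1), c(0, 1), lin, C = 1)
  expect_equal(as.integer(predict(fit, matrix(c(-1, 1), 2, 1))), c(0L, 1L))
  # XOR with the degree-3 polynomial kernel (offset 1 for a usable basis)
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  fx <- fit_qsvm(X, y, kernel_spec(degree = 3, offset = 1), C = 10)
  expect_equal(as.integer(predict(fx, X)), y)
  for (m in fx$machines) {
    expect_true(all(m$alpha >= -1e-8 & m$alpha <= 10 + 1e-8))
    expect_lt(abs(sum(m$alpha * m$yb)), 1e-4)
  }
  expect_error(fit_qsvm(X, rep(1, 4), kernel_spec()),
               class = "lesionlab_single_class")
})

test_that("XOR solution agrees with an independent SVM implementation", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  fit <- fit_qsvm(X, y, kernel_spec(degree = 3, offset = 1), C = 10)
  ref <- e1071::svm(X, factor(y), kernel = "polynomial", degree = 3,
                    gamma = 1, coef0 = 1, cost = 10, scale = FALSE)
  expect_equal(as.integer(predict(fit, X)),
               as.integer(as.character(predict(ref, X))))
})

test_that("both kernel families separate Gaussian blobs", {
  set.seed(11)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 4, mean = 0, sd = 0.5), ncol = 4),
             matrix(rnorm(n / 2 * 4, mean = 3, sd = 0.5), ncol = 4))
  y <- rep(c(0, 1), each = n / 2)
  ho <- rbind(matrix(rnorm(20 * 4, 0, 0.5), ncol = 4),
              matrix(rnorm(20 * 4, 3, 0.5), ncol = 4))
  yho <- rep(c(0, 1), each = 20)
  for (fam in c("polynomial", "quantum_second_order")) {
    # rescale to [0, pi] via the projection used in the pipeline
    red <- reduce_features(X, 4)
    spec <- kernel_spec(fam, degree = 3, offset = 1, n_qubits = 4)
    fit <- fit_qsvm(red$features, y, spec, C = 1,
                    projection = red$projection)
    expect_equal(mean(as.integer(predict(fit, red$features)) == y), 1)
    pred_ho <- predict(fit, project_features(red$projection, ho),
                       project = FALSE)
    expect_gte(mean(as.integer(pred_ho) == yho), 0.95)
  }
})

test_that("prediction equals the brute-force decision function", {
  set.seed(13)
  X <- matrix(runif(30, 0, pi), 10, 3)
  y <- sample(0:2, 10, replace = TRUE)
  while (length(unique(y)) < 3) y <- sample(0:2, 10, replace = TRUE)
  spec <- kernel_spec(degree = 2, offset = 0.5)
  fit <- fit_qsvm(X, y, spec, C = 2)
  Xn <- matrix(runif(15, 0, pi), 5, 3)
  scores <- predict(fit, Xn, type = "score")
  for (mi in seq_along(fit$machines)) {
    m <- fit$machines[[mi]]
    for (r in 1:5) {
      f <- sum(vapply(seq_len(nrow(X)), function(i) {
        m$alpha[i] * m$yb[i] * poly_kernel(X[i, ], Xn[r, ], spec)
      }, numeric(1))) + m$d
      expect_lt(abs(scores[r, mi] - f), 1e-8)
    }
  }
  labs <- predict(fit, Xn)
  expect_equal(as.integer(labs),
               fit$classes[max.col(scores, ties.method = "first")])
  # determinism
  expect_identical(tidy(fit), tidy(fit_qsvm(X, y, spec, C = 2)))
})
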