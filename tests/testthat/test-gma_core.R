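test_that("parser handles minimal models and counts terms correctly", {
  m <- parse_gma_model("x' = a - b*x")
  expect_length(m$equations, 1)
  eq <- m$equations$x
  expect_length(eq$production, 1)
  expect_length(eq$consumption, 1)
  expect_equal(eq$production[[1]]$coefs, c(a = 1))
  expect_length(eq$production[[1]]$exps, 0)
  expect_equal(eq$consumption[[1]]$exps, c(x = 1))

  m2 <- parse_gma_model("y' = a*x + c*y - d*y")
  expect_length(m2$equations$y$production, 2)
  expect_length(m2$equations$y$consumption, 1)
})

test_that("parser rejects malformed input with informative errors", {
  expect_error(parse_gma_model(c("x' = a - b*x", "x' = c - d*x")), "duplicate")
  expect_error(parse_gma_model("x' = a % b"), "unknown operator|not an equation")
  expect_error(parse_gma_model("x' = a - "), "empty|malformed|not an equation")
  expect_error(parse_gma_model("x' = a"), "production and one consumption")
  expect_error(parse_gma_model("x' = - b*x"), "production and one consumption")
})

test_that("built-in Design 3 exposes the reconstructed parameter registry", {
  d3 <- get_design("3")
  expect_equal(nrow(d3$model$parameters), 21)
  expect_setequal(
    d3$model$parameters$name,
    c("v_x", "v_y", "v_z", "v_s", "beta_x", "beta_y", "beta_z", "beta_s",
      "alpha_xy", "alpha_yy", "alpha_xz", "alpha_yz", "alpha_zz",
      "gamma_yx", "gamma_zx", "gamma_yy", "gamma_zy", "gamma_zz",
      "delta", "epsilon", "K_A"))
})

test_that("parser/writer round-trip is the identity on the text format", {
  for (id in c("1A", "2", "3", "4", "6")) {
    path <- system.file("extdata", "designs", paste0("design", id, ".gma"),
                        package = "oscidesign")
    txt <- paste0(paste(grep("^#", readLines(path), value = TRUE, invert = TRUE),
                        collapse = "\n"), "\n")
    m <- read_gma_model(path)
    expect_identical(write_gma_model(m), txt, label = paste("design", id))
  }
  # idempotence on arbitrary parsed models
  for (seed in 1:5) {
    m <- random_gma_model(4, 3, seed)
    w1 <- write_gma_model(m)
    expect_identical(write_gma_model(parse_gma_model(w1)), w1)
  }
})

test_that("evaluate_rates matches closed forms and a symbolic oracle", {
  m <- toy_1eq()
  expect_equal(unname(evaluate_rates(m, c(a = 2, b = 4), c(x = 0.5))), 0)

  # single term contribution: b*x*y with b=3, x=2, y=5 consumes 30
  m2 <- parse_gma_model(c("x' = a - b*x*y", "y' = a - d*y"))
  r <- evaluate_rates(m2, c(a = 0, b = 3, d = 1e-9) + c(1e-12, 0, 0),
                      c(x = 2, y = 5))
  expect_equal(unname(r[1]), 1e-12 - 30, tolerance = 1e-12)

  txt <- "x' = a*x^0.5 + b*y - c*x*y\ny' = d*x - e*y^2 - f*y"
  m3 <- parse_gma_model(txt)
  for (seed in 1:100) {
    p <- random_params(m3, seed)
    x <- random_state(m3, seed)
    got <- evaluate_rates(m3, p, x)
    want <- symbolic_rates(txt, p, x)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("rates are homogeneous of degree one in the coefficients", {
  for (seed in 1:10) {
    m <- random_gma_model(3, 3, seed)
    p <- random_params(m, seed)
    x <- random_state(m, seed)
    lam <- 3.7
    expect_equal(evaluate_rates(m, p * lam, x),
                 lam * evaluate_rates(m, p, x), tolerance = 1e-12)
  }
})

test_that("analytic Jacobian is exact", {
  m <- toy_1eq()
  expect_equal(unname(analytic_jacobian(m, c(a = 2, b = 4), c(x = 0.5))),
               matrix(-4), tolerance = 1e-14)

  # Lotka-Volterra at its fixed point has trace zero
  lv <- lv_model()
  p <- c(a = 1.3, b = 0.7, c = 2.1, d = 0.9)
  J <- analytic_jacobian(lv, p, c(x = p[["d"]] / p[["c"]], y = p[["a"]] / p[["b"]]))
  expect_equal(sum(diag(J)), 0, tolerance = 1e-12)

  m4 <- random_gma_model(4, 3, seed = 42)
  for (seed in 1:50) {
    p <- random_params(m4, seed)
    x <- random_state(m4, seed)
    expect_equal(analytic_jacobian(m4, p, x), fd_jacobian(m4, p, x),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("analytic Jacobian matches finite differences on random models", {
  for (seed in 1:12) {
    m <- random_gma_model(sample(2:5, 1), 4, seed)
    p <- random_params(m, seed)
    x <- random_state(m, seed)
    expect_equal(analytic_jacobian(m, p, x), fd_jacobian(m, p, x),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("substitute_auxiliaries flattens pure power-law auxiliaries", {
  m <- parse_gma_model(c("x' = v - delta*c_x", "s' = w - b*s", "c_x = K_A*x*s"))
  f <- substitute_auxiliaries(m)
  expect_length(f$auxiliary, 0)
  t <- f$equations$x$consumption[[1]]
  expect_equal(t$coefs[order(names(t$coefs))], c(K_A = 1, delta = 1))
  expect_equal(t$exps[order(names(t$exps))], c(s = 1, x = 1))

  m2 <- toy_2eq()
  expect_identical(substitute_auxiliaries(m2), m2)

  expect_error(substitute_auxiliaries(parse_gma_model(c(
    "x' = a - b*x", "u = k*w", "w = q*u"))), "cyclic")
})

test_that("flattened Design 3 reproduces unflattened rates", {
  d3 <- get_design("3")$model
  f <- substitute_auxiliaries(d3)
  for (seed in 1:100) {
    p <- random_params(d3, seed)
    x <- random_state(d3, seed)
    expect_equal(evaluate_rates(f, p, x), evaluate_rates(d3, p, x),
                 tolerance = 1e-12)
  }
})

test_that("denominator auxiliaries are retained and evaluated exactly", {
  m <- parse_gma_model(c("x' = v*K*D^-1 - b*x", "D = K + x"))
  f <- substitute_auxiliaries(m)
  expect_equal(f$auxiliary, "D")
  p <- c(v = 2, K = 3, b = 0.5)
  r <- evaluate_rates(m, p, c(x = 1))
  expect_equal(unname(r), 2 * 3 / (3 + 1) - 0.5)
})

test_that("domain errors are raised for bad states and parameters", {
  m <- toy_1eq()
  expect_error(evaluate_rates(m, c(a = 1, b = 1), c(x = -1)), "positive")
  expect_error(evaluate_rates(m, c(a = 1), c(x = 1)), "missing parameter")
})
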