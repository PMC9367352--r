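test_that("Jacobian is diagonal (r, -mu_E, -mu_C) at the origin", {
  p <- model_parameters()
  J <- model_jacobian(c(0, 0, 0), p)
  expect_equal(J, diag(c(p$r, -p$mu_E, -p$mu_C)) |>
                 `dimnames<-`(dimnames(J)))
})

test_that("analytic Jacobian agrees with central finite differences", {
  p <- model_parameters(mu_AC = 0.0161, mu_C = 0.221)
  state <- c(A = 3.7e5, E = 1800, C = 8e14)
  J <- model_jacobian(state, p)
  h <- pmax(abs(state) * 1e-6, 1e-6)
  for (j in 1:3) {
    up <- state; up[j] <- up[j] + h[j]
    dn <- state; dn[j] <- dn[j] - h[j]
    fd <- (evaluate_rhs(up, p) - evaluate_rhs(dn, p)) / (2 * h[j])
    expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-6)
  }
})

test_that("drug-free system has unstable extinction and stable capacity states", {
  p <- model_parameters()
  eq <- find_equilibria(p)
  labels <- vapply(eq, function(e) e$label, character(1))
  eqm0 <- eq[[which(labels == "Eqm0")]]
  eqm1 <- eq[[which(labels == "Eqm1")]]
  expect_equal(unname(eqm0$point), c(0, 0, 0))
  expect_identical(eqm0$classification, "unstable")
  # the unstable direction is the tumor axis with eigenvalue +r
  expect_true(any(abs(eqm0$eigenvalues - p$r) < 1e-12))
  expect_equal(unname(eqm1$point), c(p$K, 0, 0))
  expect_identical(eqm1$classification, "stable")
  # triangular Jacobian at (K, 0, 0): eigenvalues are the diagonal
  diag_expect <- c(-p$r,
                   -p$mu_E + p$p * p$K / (p$c + p$K) - p$mu_EA * p$K,
                   -p$mu_C - p$mu_CA * p$K / (p$a + p$K))
  expect_equal(sort(Re(eqm1$eigenvalues)), sort(diag_expect))
  expect_true(all(Re(eqm1$eigenvalues) < 0))
  # every reported equilibrium is a genuine root of the smooth flow
  for (e in eq) expect_lt(e$residual, 1e-8)
  # under default magnitudes no interior (immune-controlled) equilibrium exists
  expect_false("other" %in% labels)
})

test_that("trajectories confirm the eigenvalue classification", {
  p <- model_parameters()
  # small perturbation off the stable capacity state returns toward it
  tr <- simulate_model(p, initial = system_state(A = 0.99 * p$K, E = 10),
                       t_end = 400)
  a_err <- abs(tr$A_cells - p$K)
  expect_lt(a_err[length(a_err)], a_err[1])
  # perturbation off the unstable extinction state departs along the tumor axis
  tr0 <- simulate_model(p, initial = system_state(A = 10, E = 0), t_end = 400)
  expect_gt(tr0$A_cells[nrow(tr0)], 10 * exp(0.01 * 400) * 0.9)
})

test_that("frozen-drug analysis yields the suppressed-tumor equilibrium branch", {
  p <- model_parameters(mu_AC = 0.0161, mu_CA = 0.161, mu_C = 0.221)
  # constant drug level well below kill saturation shifts the tumor equilibrium
  C_level <- 1e3  # comparable to a, so the kill term is partial
  eq <- find_equilibria(p, C_const = C_level)
  labels <- vapply(eq, function(e) e$label, character(1))
  expect_true("Eqm2" %in% labels)
  eqm2 <- eq[[which(labels == "Eqm2")[1]]]
  kill <- p$mu_AC * C_level / (p$a + C_level)
  expect_equal(unname(eqm2$point[["A"]]), p$K * (1 - kill / p$r))
  expect_lt(eqm2$point[["A"]], p$K)
  # drug high enough to make the kill rate exceed r removes the Eqm2 branch
  eq_hi <- find_equilibria(p, C_const = 1e15)
  expect_false("Eqm2" %in% vapply(eq_hi, function(e) e$label, character(1)))
})

test_that("equilibrium reports serialize to JSON", {
  eq <- find_equilibria(model_parameters())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_equilibria(eq, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$label, c("Eqm0", "Eqm1"))
  expect_equal(back$classification, c("unstable", "stable"))
})
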