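test_that("isotropic Voigt stiffness has the textbook entries", {
  mu <- 1.7; nu <- 0.3
  C <- isotropic_stiffness(elastic_material(mu, nu))
  C <- unclass(C)
  lambda <- 2 * mu * nu / (1 - 2 * nu)
  expect_equal(C[1, 1], lambda + 2 * mu)
  expect_equal(C[1, 2], lambda)
  expect_equal(C[4, 4], mu)
  expect_equal(C, t(C))
  ## engineering-shear convention: shear blocks carry mu, not 2 mu
  eps <- c(0, 0, 0, 2 * 0.1, 0, 0)  # engineering gamma_yz = 0.2
  expect_equal((C %*% eps)[4], 2 * mu * 0.1)
})

test_that("material validation rejects the incompressible limit", {
  expect_error(elastic_material(1, 0.5))
  expect_error(elastic_material(-1, 0.3))
  expect_silent(elastic_material(1, 0.49))
})

test_that("Voigt and full-tensor representations agree on contraction", {
  mat <- elastic_material(2, 0.25)
  Cv <- unclass(isotropic_stiffness(mat))
  Ct <- isotropic_stiffness_tensor(mat)
  set.seed(7)
  e <- matrix(rnorm(9), 3); e <- (e + t(e)) / 2
  ## sigma_ij = C_ijkl e_kl
  sig_t <- apply(Ct, c(1, 2), function(Ckl) sum(Ckl * e))
  ev <- c(e[1, 1], e[2, 2], e[3, 3], 2 * e[2, 3], 2 * e[1, 3], 2 * e[1, 2])
  sv <- as.vector(Cv %*% ev)
  sig_v <- matrix(c(sv[1], sv[6], sv[5],
                    sv[6], sv[2], sv[4],
                    sv[5], sv[4], sv[3]), 3, 3)
  expect_equal(sig_t, sig_v, tolerance = 1e-12)
})

test_that("Mandel round trips are exact", {
  set.seed(11)
  s <- matrix(rnorm(9), 3); s <- (s + t(s)) / 2
  expect_equal(mandel_to_sym(sym_to_mandel(s)), s, tolerance = 1e-14)
  C <- isotropic_stiffness_tensor(elastic_material(1, 0.2))
  Cm <- tensor4_to_mandel(C)
  expect_equal(Cm, t(Cm), tolerance = 1e-12)
  ## isotropic contraction via Mandel equals direct contraction
  sig <- apply(C, c(1, 2), function(Ckl) sum(Ckl * s))
  expect_equal(mandel_to_sym(as.vector(Cm %*% sym_to_mandel(s))), sig,
               tolerance = 1e-12)
})

test_that("rotation leaves the isotropic tensor invariant", {
  C <- isotropic_stiffness_tensor(elastic_material(1, 0.3))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  expect_equal(rotate_tensor4(C, R), C, tolerance = 1e-12)
})

test_that("orthotropic tensor has its axes as principal directions", {
  th <- 0.4
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  dC <- orthotropic_tensor(R, normal_block = diag(c(3, 2, 1)),
                           shear_diag = c(0.5, 0.4, 0.3))
  ## minor and major symmetries
  expect_equal(dC, aperm(dC, c(2, 1, 3, 4)), tolerance = 1e-12)
  expect_equal(dC, aperm(dC, c(3, 4, 1, 2)), tolerance = 1e-12)
  ## the identity contraction dC : I is diagonal in the axis frame
  m <- apply(dC, c(1, 2), function(Ckl) sum(Ckl * diag(3)))
  d <- t(R) %*% m %*% R
  expect_equal(d, diag(diag(d)), tolerance = 1e-12)
})

test_that("equivalent-strain axes follow the stiffness-change axes", {
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  dC <- orthotropic_tensor(R, normal_block = 0.01 * diag(c(5, 2, 1)),
                           shear_diag = 0.01 * c(1, 1, 1))
  out <- equivalent_specified_strain(elastic_material(1, 0.3), dC)
  expect_equal(out$kappa, t(out$kappa), tolerance = 1e-12)
  for (k in 1:3) {
    align <- max(abs(crossprod(R, out$axes[, k])))
    expect_gt(align, 1 - 1e-10)
  }
})

test_that("large stiffness changes trigger the perturbation warning", {
  dC <- orthotropic_tensor(diag(3), normal_block = diag(c(5, 2, 1)),
                           shear_diag = c(1, 1, 1))
  expect_warning(equivalent_specified_strain(elastic_material(1, 0.3), dC),
                 "not small")
})
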