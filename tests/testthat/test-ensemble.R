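test_that("superposition is exact for rigid transformations", {
  tc <- gen_toy_complex(seed = 2)
  m1 <- get_model(tc$ensemble, 1)
  expect_equal(superpose(m1, m1, "backbone")$rmsd, 0, tolerance = 1e-10)
  # pure translation
  m2 <- m1; m2$xyz <- sweep(m1$xyz, 2, c(5, 0, 0), "+")
  expect_equal(superpose(m1, m2, "backbone")$rmsd, 0, tolerance = 1e-10)
  # rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m3 <- m1; m3$xyz <- m1$xyz %*% R + matrix(c(1, -2, 3), nrow(m1$xyz), 3,
                                            byrow = TRUE)
  fit <- superpose(m1, m3, "heavy")
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(max(abs(sweep(m3$xyz %*% fit$rotation, 2, fit$translation,
                             "+") - m1$xyz)), 0, tolerance = 1e-8)
})

test_that("4-point superposition matches a brute-force rotation grid", {
  A <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2, 0), c(0.5, 0.5, 1.2))
  set.seed(42)
  B <- A + matrix(rnorm(12, 0, 0.3), 4, 3)
  ma <- list(atoms = data.frame(chain = "A", resno = 1:4, resid = "ALA",
                                elety = "CA", elesy = "C"), xyz = A)
  mb <- ma; mb$xyz <- B
  fit <- superpose(ma, mb, "*:*:CA")
  # Euler-angle grid search plus local refinement (independent oracle)
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  euler_rmsd <- function(p) {
    a <- p[1]; b <- p[2]; g <- p[3]
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    sqrt(mean(rowSums((B0 %*% (Rz1 %*% Ry %*% Rz2) - A0)^2)))
  }
  ang <- seq(0, 2 * pi, by = pi / 12)
  bng <- seq(0, pi, by = pi / 12)
  grid <- as.matrix(expand.grid(ang, bng, ang))
  vals <- apply(grid, 1, euler_rmsd)
  start <- grid[which.min(vals), ]
  best <- stats::optim(start, euler_rmsd,
                       control = list(reltol = 1e-12, maxit = 2000))$value
  expect_equal(fit$rmsd, best, tolerance = 1e-3)
  expect_lte(fit$rmsd, best + 1e-9)
  expect_error(superpose(ma, mb, "A:9:CA"), "no atoms")
})

test_that("pairwise ensemble RMSD has the expected invariances", {
  tc <- gen_toy_complex(n_models = 3, model_rms = 0, seed = 1)
  pr <- pairwise_rmsd(tc$ensemble, "backbone")
  expect_equal(pr$mean, 0, tolerance = 1e-10)
  expect_equal(pr$sd, 0, tolerance = 1e-10)

  tc2 <- gen_toy_complex(n_models = 4, model_rms = 0.8, seed = 6)
  # permuting model order leaves the mean unchanged
  perm <- tc2$ensemble
  perm$coords <- perm$coords[, , c(3, 1, 4, 2)]
  expect_equal(pairwise_rmsd(perm, "backbone")$mean,
               pairwise_rmsd(tc2$ensemble, "backbone")$mean,
               tolerance = 1e-10)
  # rigid motion of one model does not change RMSDs
  rot <- tc2$ensemble
  th <- 0.5
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot$coords[, , 2] <- rot$coords[, , 2] %*% R + 7
  expect_equal(pairwise_rmsd(rot, "backbone")$mean,
               pairwise_rmsd(tc2$ensemble, "backbone")$mean,
               tolerance = 1e-8)
  expect_error(pairwise_rmsd(gen_toy_complex(seed = 1)$ensemble), "2 models")
})

test_that("ensemble distances reduce correctly and symmetrically", {
  atoms <- data.frame(chain = c("A", "B", rep("L", 2)), resno = 1,
                      resid = c("ALA", "ALA", "TPP", "TPP"),
                      elety = c("CA", "CA", "F1", "F2"),
                      elesy = c("C", "C", "F", "F"))
  x1 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(0, 9, 0))
  x2 <- x1; x2[2, ] <- c(0, 0, 3)
  ens <- structure_ensemble(atoms, array(c(x1, x2), c(4, 3, 2)))
  d <- ensemble_distance(ens, "A:1:CA", "B:1:CA", "pair")
  expect_equal(d$mean, 3); expect_equal(d$sd, 0)
  # symmetry in the two selections
  expect_equal(ensemble_distance(ens, "B:1:CA", "A:1:CA", "pair")$mean, 3)
  # minimum over a set equals the brute-force minimum
  dm <- ensemble_distance(ens, "A:1:CA", "L:1:F1,F2", "min_over_b")
  expect_equal(dm$values, c(4, 4))
  expect_error(ensemble_distance(ens, "L:1:F1,F2", "A:1:CA", "pair"),
               "single atom")
})

test_that("pocket water counting applies both criteria and is monotone", {
  none <- gen_toy_complex(seed = 4)
  m0 <- get_model(none$ensemble, 1)
  expect_identical(count_pocket_waters(m0, "L:1:*", 15,
                                       none$truth$z_bound_atoms), 0L)

  tc <- gen_toy_complex(n_waters_inside = 12, n_waters_outside = 20, seed = 8)
  m <- get_model(tc$ensemble, 1)
  zb <- tc$truth$z_bound_atoms
  expect_identical(count_pocket_waters(m, "L:1:*", 15, zb), 12L)
  # monotone non-decreasing in the cutoff
  counts <- vapply(c(5, 10, 15, 30, 60), function(ct)
    count_pocket_waters(m, "L:1:*", ct, zb), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(count_pocket_waters(m, "L:1:*", 15, c("A:99:CA", zb[2])),
               "no atoms")
})
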