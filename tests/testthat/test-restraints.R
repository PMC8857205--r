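test_that("effective distance is the minimum or the assigned pair", {
  # single proton at origin, four fluorines at 5, 6, 7, 8 A along x
  atoms <- data.frame(chain = c("A", rep("L", 4)),
                      resno = c(1, rep(1, 4)), resid = c("ALA", rep("TPP", 4)),
                      elety = c("H", paste0("F", 1:4)),
                      elesy = c("H", rep("F", 4)))
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(6, 0, 0), c(7, 0, 0), c(8, 0, 0))
  ens <- structure_ensemble(atoms, array(xyz, c(5, 3, 1)))
  m <- get_model(ens, 1)
  fl <- paste0("L:1:F", 1:4)
  r <- ambiguous_restraint("A:1:H", fl, "measured", lower = 4, upper = 6)
  expect_equal(effective_distance(m, r), 5)
  r2 <- ambiguous_restraint("A:1:H", fl, "measured", lower = 4, upper = 6,
                            assigned_fluorine = "L:1:F3")
  expect_equal(effective_distance(m, r2), 7)
  bad <- ambiguous_restraint("A:9:H", fl, "measured", lower = 4, upper = 6)
  expect_error(effective_distance(m, bad), "not found")

  # violations: satisfied, upper excess, lower-bound shortfall per fluorine
  expect_equal(violation(m, r), 0)
  expect_equal(violation(m, r2), 1)  # 7 vs upper 6
  lb <- ambiguous_restraint("A:1:H", fl, "lower_bound", lower = 10, upper = 40)
  expect_equal(violation(m, lb), (10 - 5) + (10 - 6) + (10 - 7) + (10 - 8))
  lb1 <- ambiguous_restraint("A:1:H", fl, "lower_bound", lower = 10,
                             upper = 40, assigned_fluorine = "L:1:F4")
  expect_equal(violation(m, lb1), 2)
})

test_that("toy-complex effective distance matches coordinate arithmetic", {
  tc <- gen_toy_complex(seed = 3)
  m <- get_model(tc$ensemble, 1)
  fl <- tc$truth$fluorine_sites
  r <- ambiguous_restraint("A:8:H", fl, "measured", lower = 3, upper = 12)
  hand <- tc$truth$hf_distances
  expect_equal(effective_distance(m, r),
               hand$min_hf[hand$chain == "A" & hand$resno == 8],
               tolerance = 1e-9)
})

test_that("structure scoring ranks by violation sum and count", {
  atoms <- data.frame(chain = c("A", rep("L", 4)), resno = 1,
                      resid = c("ALA", rep("TPP", 4)),
                      elety = c("H", paste0("F", 1:4)),
                      elesy = c("H", rep("F", 4)))
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(6, 0, 0), c(7, 0, 0), c(8, 0, 0))
  shifted <- base; shifted[1, 1] <- -1        # proton 1 A further: d_eff = 6
  ens <- structure_ensemble(atoms, array(c(base, shifted), c(5, 3, 2)))
  fl <- paste0("L:1:F", 1:4)
  r <- ambiguous_restraint("A:1:H", fl, "measured", lower = 3, upper = 5)
  sc <- score_structures(ens, list(r))
  expect_equal(sc$reports$sum_violation, c(0, 1))
  expect_equal(sc$reports$n_violations, c(0, 1))
  expect_equal(sc$ranking_sum[1], 1)
  expect_equal(sc$ranking_count[1], 1)
  expect_equal(sc$reports$sum_violation, rowSums(sc$per_restraint))
  expect_equal(sc$reports$n_violations, rowSums(sc$per_restraint > 0))

  # model-order permutation flips the ranking consistently
  ens_rev <- structure_ensemble(atoms, array(c(shifted, base), c(5, 3, 2)))
  sc_rev <- score_structures(ens_rev, list(r))
  expect_equal(sc_rev$ranking_sum[1], 2)
  # all satisfied: ranking stays in input order
  r_ok <- ambiguous_restraint("A:1:H", fl, "measured", lower = 3, upper = 10)
  sc_ok <- score_structures(ens, list(r_ok))
  expect_equal(sc_ok$ranking_sum, 1:2)
  expect_true(all(sc_ok$reports$sum_violation == 0))
  expect_error(score_structures(ens, list()), "no restraints")
})

test_that("restraint building follows the 4 x weak + measured counting rule", {
  fl <- paste0("L:1:F", 1:4)
  mk_fit <- function(id, weak) {
    structure(list(site_id = id,
                   best_distance = if (weak) NA_real_ else 5,
                   lower = if (weak) 10 else 4, upper = if (weak) 40 else 6,
                   is_lower_bound_only = weak, overlapped = FALSE),
              class = "distance_fit")
  }
  fits <- c(lapply(sprintf("w%02d", 1:92), mk_fit, weak = TRUE),
            lapply(sprintf("m%02d", 1:24), mk_fit, weak = FALSE))
  sites <- setNames(as.list(sprintf("A:%d:H", seq_along(fits))),
                    vapply(fits, `[[`, character(1), "site_id"))
  rs <- build_restraints(fits, sites, fl)
  expect_identical(length(rs), 92L * 4L + 24L)
  kinds <- vapply(rs, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "lower_bound"), 368L)
  expect_identical(sum(kinds == "measured"), 24L)
  # every lower-bound restraint is a single-fluorine >= 10 A constraint
  lbs <- rs[kinds == "lower_bound"]
  expect_true(all(vapply(lbs, function(r) !is.null(r$assigned_fluorine),
                         logical(1))))
  expect_true(all(vapply(lbs, `[[`, numeric(1), "lower") == 10))

  expect_identical(build_restraints(list(), list(), fl), list())
  small <- build_restraints(fits[c(1, 2, 93)], sites, fl)
  expect_identical(length(small), 9L)  # 2 weak + 1 measured
  expect_error(build_restraints(fits[1], list(), fl), "no proton site")
})

test_that("disambiguation picks the nearest fluorine and respects ties", {
  atoms <- data.frame(chain = c("A", rep("L", 4)), resno = 1,
                      resid = c("ALA", rep("TPP", 4)),
                      elety = c("H", paste0("F", 1:4)),
                      elesy = c("H", rep("F", 4)))
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(6, 0, 0), c(7, 0, 0), c(8, 0, 0))
  ens <- structure_ensemble(atoms, array(xyz, c(5, 3, 1)))
  m <- get_model(ens, 1)
  fl <- paste0("L:1:F", 1:4)
  r <- ambiguous_restraint("A:1:H", fl, "measured", lower = 4, upper = 6)
  out <- disambiguate(list(r), m)
  expect_identical(out[[1]]$assigned_fluorine, "L:1:F1")

  # exact tie stays ambiguous
  tie_xyz <- xyz; tie_xyz[3, ] <- c(-5, 0, 0)
  tie_ens <- structure_ensemble(atoms, array(tie_xyz, c(5, 3, 1)))
  expect_warning(out2 <- disambiguate(list(r), get_model(tie_ens, 1)), "tie")
  expect_null(out2[[1]]$assigned_fluorine)

  # on the toy complex, assignments equal an exhaustive nearest search,
  # and assignment never increases the reference model's violation
  tc <- gen_toy_complex(seed = 5)
  mt <- get_model(tc$ensemble, 1)
  flt <- tc$truth$fluorine_sites
  rs <- lapply(c(5, 8, 11), function(i)
    ambiguous_restraint(sprintf("A:%d:H", i), flt, "measured",
                        lower = 3, upper = 8))
  before <- vapply(rs, function(r) violation(mt, r), numeric(1))
  da <- disambiguate(rs, mt)
  after <- vapply(da, function(r) violation(mt, r), numeric(1))
  expect_true(all(after <= before + 1e-12))
  for (j in seq_along(rs)) {
    h <- mt$xyz[atom_select(mt, rs[[j]]$proton_site), ]
    d <- vapply(flt, function(s)
      sqrt(sum((h - mt$xyz[atom_select(mt, s), ])^2)), numeric(1))
    expect_identical(da[[j]]$assigned_fluorine, unname(flt[which.min(d)]))
  }
})
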