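test_that("scaffold satisfies its geometric construction constraints", {
  s <- default_scaffold(seed = 1)
  ca <- s$xyz[ca_indices(s), ]
  expect_equal(nrow(ca), 128)
  consec <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(consec >= 3.7 & consec <= 3.9))
  d <- as.matrix(dist(ca)); diag(d) <- Inf
  for (i in 1:(nrow(ca) - 1)) d[i, i + 1] <- d[i + 1, i] <- Inf
  expect_gte(min(d), 3.5)
  # deterministic per seed
  expect_identical(s$xyz, default_scaffold(seed = 1)$xyz)
  expect_false(identical(s$xyz, default_scaffold(seed = 2)$xyz))
  # compact enough to hold a real contact set under default parameters
  expect_gte(find_native_contacts(s)$N, 50)
})

test_that("pseudo-side-chain scaffolds keep one CA per residue", {
  s <- build_scaffold(scaffold_spec(n_residues = 30, atoms_per_residue = 3,
                                    seed = 5))
  expect_equal(nrow(s$atoms), 90)
  expect_equal(sum(s$atoms$atom_name == "CA"), 30)
  expect_equal(s$n_residues, 30)
})

test_that("zero-amplitude ensembles reproduce the reference exactly", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  ens <- generate_ensemble(quick_spec(s, ann, list(CDR1 = 0), n_frames = 10))
  expect_true(all(vapply(ens[[1]]$frames, function(f)
    identical(f, unname(s$xyz)) || max(abs(f - s$xyz)) == 0, logical(1))))
  cs <- find_native_contacts(s)
  expect_true(all(q_series(ens[[1]], cs) > 0.999))
  expect_equal(max(cdr_rmsd_series(ens[[1]], s, ann, "CDR1")$values), 0,
               tolerance = 1e-12)
})

test_that("pure rigid noise leaves fitted RMSD ~0 and Q untouched", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  cs <- find_native_contacts(s)
  ens <- generate_ensemble(quick_spec(
    s, ann, list(CDR1 = 0), n_frames = 25,
    rigid = list(rotation_deg = 20, translation_A = 5)))[[1]]
  expect_lt(max(global_rmsd_series(ens, s)$values), 1e-6)
  q0 <- q_value(s$xyz, cs)
  expect_true(all(abs(q_series(ens, cs) - q0) < 1e-12))
})

test_that("injected region amplitude is recovered by the fitted RMSD", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  sigma <- 1.0
  ens <- generate_ensemble(quick_spec(s, ann, list(CDR1 = sigma),
                                      n_frames = 500, seed = 3))[[1]]
  m <- mean(cdr_rmsd_series(ens, s, ann, "CDR1")$values)
  expected <- sqrt(3) * sigma  # per-atom isotropic displacement
  expect_gt(m, 0.8 * expected)
  expect_lt(m, 1.2 * expected)
})

test_that("ensembles are bit-reproducible and written identically", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  sp <- quick_spec(s, ann, list(CDR1 = 1.2, CDR3 = 1.8), n_frames = 8,
                   n_runs = 2, seed = 11,
                   rigid = list(rotation_deg = 3, translation_A = 0.5))
  e1 <- generate_ensemble(sp); e2 <- generate_ensemble(sp)
  expect_identical(e1[[2]]$frames, e2[[2]]$frames)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e1[[1]], p1); write_multimodel_pdb(e2[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("mean region RMSD is monotone in that region's amplitude", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  means <- vapply(c(0, 0.5, 1.0, 2.0), function(sg) {
    e <- generate_ensemble(quick_spec(s, ann, list(CDR3 = sg),
                                      n_frames = 120, seed = 6))[[1]]
    mean(cdr_rmsd_series(e, s, ann, "CDR3")$values)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("changing one region's amplitude leaves other regions' draws
           untouched (stream independence)", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  e_a <- generate_ensemble(quick_spec(s, ann,
                                      list(CDR1 = 1.0, CDR2 = 0.3),
                                      n_frames = 6, seed = 4))[[1]]
  e_b <- generate_ensemble(quick_spec(s, ann,
                                      list(CDR1 = 1.0, CDR2 = 2.0),
                                      n_frames = 6, seed = 4))[[1]]
  cdr1 <- region_atom_indices(s, ann, "CDR1", "all")
  cdr2 <- region_atom_indices(s, ann, "CDR2", "all")
  for (k in seq_along(e_a$frames)) {
    expect_identical(e_a$frames[[k]][cdr1, ], e_b$frames[[k]][cdr1, ])
    expect_false(identical(e_a$frames[[k]][cdr2, ], e_b$frames[[k]][cdr2, ]))
  }
})

test_that("a two-state alternative loop produces a bimodal RMSD density", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  e <- generate_ensemble(quick_spec(
    s, ann, list(CDR1 = 0.3), n_frames = 600, seed = 12,
    altstate = list(region = "CDR1", magnitude = 3, weight = 0.4)))[[1]]
  r <- cdr_rmsd_series(e, s, ann, "CDR1")$values
  prof <- kde_profile(r)
  peaks <- which(diff(sign(diff(prof$density))) == -2) + 1
  big <- peaks[prof$density[peaks] > 0.2]
  expect_gte(length(big), 2)
  # occupancy of the displaced state near its mixture weight
  expect_gt(mean(r > 1.5), 0.3); expect_lt(mean(r > 1.5), 0.5)
})

test_that("the contrast preset pairs a flexible and a restrained system", {
  pr <- preset("vhh_contrast", base_seed = 1)
  expect_identical(pr$broad$reference$xyz, pr$narrow$reference$xyz)
  expect_equal(pr$broad$region_amplitudes[["CDR1"]], 1.5)
  expect_equal(pr$narrow$region_amplitudes[["CDR1"]], 0.5)
  same <- setdiff(names(pr$broad$region_amplitudes), "CDR1")
  expect_identical(pr$broad$region_amplitudes[same],
                   pr$narrow$region_amplitudes[same])
  # both keep CDR3 > CDR1 > CDR2 amplitudes
  for (spx in list(pr$broad, pr$narrow)) {
    a <- spx$region_amplitudes
    expect_true(a[["CDR3"]] > a[["CDR1"]] &&
                  a[["CDR1"]] > a[["CDR2"]])
  }
  # the flexible system explores an alternative CDR1 conformation
  expect_false(is.null(pr$broad$altstate))
  expect_identical(pr$broad$altstate$region, "CDR1")
  expect_null(pr$narrow$altstate)
  expect_error(preset("nope"), "unknown preset")
})

test_that("unknown region labels are rejected at spec time", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  expect_error(quick_spec(s, ann, list(CDRX = 1)), "unknown region")
  expect_error(quick_spec(s, ann, list(CDR1 = -1)), ">= 0")
  expect_error(quick_spec(s, ann, list(CDR1 = 1),
                          altstate = list(region = "CDR1", magnitude = 1,
                                          weight = 2)), "weight")
})
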