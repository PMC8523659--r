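test_that("kabsch fit recovers exact rigid motions", {
  set.seed(1)
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  tr <- kabsch_fit(ref, ref)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(tr$translation)), 1e-10)
  # 90 degrees about z plus a shift is inverted exactly
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mobile <- apply_rigid(ref, Rz, c(1, 2, 3))
  tr <- kabsch_fit(mobile, ref)
  expect_lt(rmsd(apply_transform(tr, mobile), ref), 1e-8)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-8)
})

test_that("fitted RMSD never exceeds unfitted RMSD and ties brute force", {
  set.seed(42)
  for (rep in 1:5) {
    ref <- matrix(rnorm(30, sd = 3), 10, 3)
    mobile <- apply_rigid(ref, random_rotation(), rnorm(3)) +
      matrix(rnorm(30, sd = 0.1), 10, 3)
    tr <- kabsch_fit(mobile, ref)
    fitted <- rmsd(apply_transform(tr, mobile), ref)
    expect_lte(fitted, rmsd(mobile, ref) + 1e-12)
    # a quick random-rotation search (the exhaustive one runs in the
    # acceptance suite): centered candidates never beat the fit
    P <- sweep(mobile, 2, colMeans(mobile))
    Q <- sweep(ref, 2, colMeans(ref))
    best <- min(replicate(2000, {
      R <- random_rotation()
      sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
    }))
    expect_lte(fitted, best + 1e-12)
    # independent route: bio3d's least-squares fit agrees
    v <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                        mobile = as.vector(t(mobile)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
    expect_equal(fitted, rmsd(matrix(v, ncol = 3, byrow = TRUE), ref),
                 tolerance = 1e-8)
  }
})

test_that("rmsd matches the naive double-loop formula", {
  expect_equal(rmsd(diag(3), diag(3)), 0)
  a <- matrix(rnorm(12), 4, 3)
  expect_equal(rmsd(a, sweep(a, 2, c(-1, 0, 0))), 1.0, tolerance = 1e-12)
  b <- matrix(rnorm(12), 4, 3)
  acc <- 0
  for (i in 1:4) acc <- acc + sum((a[i, ] - b[i, ])^2)
  expect_equal(rmsd(a, b), sqrt(acc / 4), tolerance = 1e-12)
  expect_error(rmsd(a, b[1:3, ]), "shape")
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 1), "degenerate")
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})

test_that("framework-fit CDR RMSD is zero for identical frames and
           invariant under rigid motions", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  ens0 <- new_ensemble(s, replicate(5, s$xyz, simplify = FALSE))
  for (rg in c("CDR1", "CDR2", "CDR3"))
    expect_equal(max(cdr_rmsd_series(ens0, s, ann, rg)$values), 0,
                 tolerance = 1e-9)
  set.seed(3)
  moved <- lapply(1:20, function(k)
    apply_rigid(s$xyz, random_rotation(), rnorm(3, sd = 10)))
  ensr <- new_ensemble(s, moved)
  for (rg in c("CDR1", "CDR3", "global")) {
    ser <- if (rg == "global") global_rmsd_series(ensr, s)
           else cdr_rmsd_series(ensr, s, ann, rg)
    expect_lt(max(ser$values), 1e-6)
  }
})

test_that("higher injected CDR1 amplitude raises mean CDR1 RMSD", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  amps_hi <- list(CDR1 = 1.5); amps_lo <- list(CDR1 = 0.5)
  e_hi <- generate_ensemble(quick_spec(s, ann, amps_hi, n_frames = 200))[[1]]
  e_lo <- generate_ensemble(quick_spec(s, ann, amps_lo, n_frames = 200))[[1]]
  m_hi <- mean(cdr_rmsd_series(e_hi, s, ann, "CDR1")$values)
  m_lo <- mean(cdr_rmsd_series(e_lo, s, ann, "CDR1")$values)
  expect_gt(m_hi, m_lo)
})

test_that("global RMSD of an inflated frame matches an independent fit", {
  s <- default_scaffold()
  ctr <- colMeans(s$xyz)
  inflated <- sweep(sweep(s$xyz, 2, ctr) * 1.1, 2, -ctr)
  ens <- new_ensemble(s, list(inflated))
  mine <- global_rmsd_series(ens, s)$values
  expect_gt(mine, 0)
  # independent route: bio3d rigid fit, then plain deviation
  nc <- 3 * nrow(inflated)
  v <- bio3d::fit.xyz(fixed = as.vector(t(s$xyz)),
                      mobile = as.vector(t(inflated)),
                      fixed.inds = 1:nc, mobile.inds = 1:nc)
  other <- rmsd(matrix(v, ncol = 3, byrow = TRUE), s$xyz)
  expect_equal(mine, other, tolerance = 1e-9)
})
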