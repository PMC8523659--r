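test_that("contact enumeration honors cutoff and sequence separation", {
  # two residues 10 A apart, separation 5: nothing qualifies
  far <- make_ca_structure(rbind(c(0, 0, 0), c(10, 0, 0)), resno = c(1, 6))
  expect_error(find_native_contacts(far), "no native contacts")
  # straight chain: all |i-j| > 3 pairs are >= 15.2 A apart
  expect_error(find_native_contacts(make_chain(6)), "no native contacts")
  # compact scaffold: plenty of contacts
  cs <- find_native_contacts(default_scaffold())
  expect_gt(cs$N, 0)
  expect_true(all(cs$pairs$i < cs$pairs$j))
  expect_true(all(cs$pairs$r0 <= 4.5))
  expect_true(all(abs(cs$pairs$res_i - cs$pairs$res_j) > 3))
})

test_that("contact list matches a brute-force double loop", {
  for (seed in 1:3) {
    s <- random_packed_structure(30, radius = 7, seed = seed)
    naive <- brute_force_contacts(s)
    if (is.null(naive)) {
      expect_error(find_native_contacts(s), "no native contacts")
      next
    }
    cs <- find_native_contacts(s)
    expect_equal(cs$N, nrow(naive))
    expect_equal(cbind(cs$pairs$i, cs$pairs$j),
                 unname(naive[, 1:2, drop = FALSE]), tolerance = 1e-12)
    expect_equal(cs$pairs$r0, naive[, 3], tolerance = 1e-12)
  }
})

test_that("q_value reproduces the smoothed-contact formula exactly", {
  params <- q_params()
  # single contact at r = lambda * r0: logistic midpoint, Q = 0.5
  s <- make_ca_structure(rbind(c(0, 0, 0), c(4, 0, 0)), resno = c(1, 10))
  cs <- find_native_contacts(s, params)
  expect_equal(cs$N, 1)
  frame <- rbind(c(0, 0, 0), c(4 * 1.8, 0, 0))
  expect_equal(q_value(frame, cs, params), 0.5, tolerance = 1e-12)
  # native frame: every formed contact contributes essentially 1
  expect_gt(q_value(s$xyz, cs, params), 0.999)
  # three-contact toy against the independent scalar oracle
  toy_pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  r0 <- c(4, 4, 4)
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 7.2, 0))
  fake <- structure(list(pairs = data.frame(i = toy_pairs[, 1],
                                            j = toy_pairs[, 2],
                                            res_i = c(1, 1, 5),
                                            res_j = c(5, 9, 9), r0 = r0),
                         N = 3, params = params), class = "contact_set")
  expect_equal(q_value(coords, fake, params),
               scalar_q_oracle(coords, toy_pairs, r0, 5, 1.8),
               tolerance = 1e-12)
})

test_that("Q is rigid-invariant, bounded and monotone under expansion", {
  s <- default_scaffold()
  cs <- find_native_contacts(s)
  set.seed(5)
  for (k in 1:5) {
    moved <- apply_rigid(s$xyz, random_rotation(), rnorm(3, sd = 20))
    expect_equal(q_value(moved, cs), q_value(s$xyz, cs), tolerance = 1e-12)
  }
  ctr <- colMeans(s$xyz)
  qs <- vapply(c(1.0, 1.2, 1.5, 2.0, 3.0), function(sc)
    q_value(sweep(sweep(s$xyz, 2, ctr) * sc, 2, -ctr), cs), numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_true(all(qs > 0 & qs < 1))
})

test_that("q_series is the frame-wise Q in frame order", {
  s <- default_scaffold()
  ann <- scaffold_annotation(s)
  cs <- find_native_contacts(s)
  ens <- new_ensemble(s, replicate(4, s$xyz, simplify = FALSE))
  expect_true(all(q_series(ens, cs) > 0.999))
  # expansion ladder: strictly decreasing Q
  ctr <- colMeans(s$xyz)
  ens2 <- new_ensemble(s, lapply(c(1.0, 1.5, 2.0), function(sc)
    sweep(sweep(s$xyz, 2, ctr) * sc, 2, -ctr)))
  expect_true(all(diff(q_series(ens2, cs)) < 0))
  # synthetic ensemble equals the scalar oracle frame by frame
  e <- generate_ensemble(quick_spec(s, ann, list(CDR1 = 1.0, CDR3 = 1.5),
                                    n_frames = 20, seed = 9))[[1]]
  got <- q_series(e, cs)
  want <- vapply(e$frames, scalar_q_oracle, numeric(1),
                 pairs = cbind(cs$pairs$i, cs$pairs$j), r0 = cs$pairs$r0,
                 beta = 5, lambda = 1.8)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("q_params validates its bounds", {
  expect_error(q_params(beta = -1), "beta")
  expect_error(q_params(lambda = 0.5), "lambda")
  expect_error(q_params(contact_cutoff = 0), "contact_cutoff")
  expect_error(q_params(min_seq_separation = -1), "min_seq_separation")
  # out-of-range contact indices are a topology error
  s <- default_scaffold()
  cs <- find_native_contacts(s)
  expect_error(q_value(s$xyz[1:10, ], cs), "topology")
})
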