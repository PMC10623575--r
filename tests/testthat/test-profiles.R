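test_that("build_profile averages snapshot totals per residue", {
  one <- data.frame(snapshot = 1L, residue_label = c("A", "B"),
                    total = c(-1.5, 0.3))
  p1 <- build_profile(one)
  expect_equal(p1$energies, c(A = -1.5, B = 0.3))
  expect_equal(p1$n_snapshots, 1L)

  two <- rbind(one, data.frame(snapshot = 2L, residue_label = c("A", "B"),
                               total = c(1.5, -0.3)))
  expect_equal(build_profile(two)$energies, c(A = 0, B = 0))

  # 50-snapshot toy run vs a Welford streaming-mean oracle
  set.seed(5)
  rows <- do.call(rbind, lapply(1:50, function(m)
    data.frame(snapshot = m, residue_label = paste0("R", 1:6),
               total = rnorm(6, -1, 2))))
  p <- build_profile(rows)
  expect_equal(p$energies, oracle_streaming_means(rows), tolerance = 1e-9)
  expect_equal(p$n_snapshots, 50L)

  bad <- rbind(one, data.frame(snapshot = 2L, residue_label = c("A", "C"),
                               total = c(0, 0)))
  expect_error(build_profile(bad), "symmetric difference: .*[BC]")
})

test_that("key residues are those at or below -0.1 kcal/mol", {
  p <- interaction_profile(c(F183 = -2.16, X1 = -0.05))
  expect_equal(select_key_residues(p), "F183")
  expect_equal(select_key_residues(interaction_profile(c(A = -0.1))), "A")
  expect_equal(select_key_residues(interaction_profile(c(A = 0.5, B = -0.05))),
               character(0))
  expect_error(select_key_residues(
    structure(list(energies = numeric(0)), class = "interaction_profile")),
    "empty")
})

test_that("build_signature combines key residues across references", {
  ref1 <- interaction_profile(c(A = -1, B = -0.2), "r1", "CB2_inactive")
  ref2 <- interaction_profile(c(A = -3, B = -0.2), "r2", "CB2_inactive")
  sig <- build_signature(list(ref1, ref2), residue_rule = "union")
  expect_equal(unname(sig$mean_energy), c(-2, -0.2))
  expect_equal(unname(sig$sd_energy), c(sqrt(2), 0), tolerance = 1e-6)
  expect_equal(sig$reference_ids, c("r1", "r2"))

  # single reference: its key sub-profile, sd = 0; idempotent under repeats
  solo <- interaction_profile(c(A = -1, B = -0.05, C = -0.6), "s",
                              "CB2_active")
  s1 <- build_signature(list(solo))
  expect_equal(s1$residues, c("A", "C"))
  expect_equal(unname(s1$mean_energy), c(-1, -0.6))
  expect_equal(unname(s1$sd_energy), c(0, 0))
  s3 <- build_signature(list(solo, solo, solo))
  expect_equal(s3$mean_energy, s1$mean_energy)
  expect_equal(unname(s3$sd_energy), c(0, 0))

  # a residue missing from one reference counts as 0 kcal/mol
  refa <- interaction_profile(c(A = -1, B = -2), "a", "CB2_active")
  refb <- interaction_profile(c(A = -1), "b", "CB2_active")
  su <- build_signature(list(refa, refb), residue_rule = "union")
  expect_equal(su$mean_energy[["B"]], -1)
  si <- build_signature(list(refa, refb), residue_rule = "intersection")
  expect_equal(si$residues, "A")

  # sd_cap drops high-deviation residues
  sc <- build_signature(list(ref1, ref2), sd_cap = 1)
  expect_equal(sc$residues, "B")

  expect_error(build_signature(list(
    interaction_profile(c(A = 1), "x", "CB2_active"))), "empty")
  expect_error(build_signature(list(ref1,
    interaction_profile(c(A = -1), "x", "CB1_active"))), "mix")
})

test_that("packaged reference sets carry the CB2-inactive ids verbatim", {
  refs <- paper_fixture("reference_sets")
  cb2i <- refs$compound_id[refs$receptor_state == "CB2_inactive"]
  expect_equal(cb2i, c("AM-10257", "AM-630", "THC"))
  expect_setequal(unique(refs$receptor_state),
                  c("CB1_active", "CB1_inactive", "CB2_active",
                    "CB2_inactive"))
})

test_that("similarity: exact cases, shift invariance, oracle equality", {
  sig <- build_signature(list(interaction_profile(
    c(A = -1.2, B = -0.5, C = -2.4, D = -0.3), "ref", "CB2_active")))
  same <- interaction_profile(c(A = -1.2, B = -0.5, C = -2.4, D = -0.3))
  s0 <- similarity(same, sig)
  expect_equal(s0$r, 1)
  expect_equal(s0$r2, 1)
  expect_equal(c(s0$rmse, s0$aue, s0$ase), c(0, 0, 0))

  shifted <- interaction_profile(
    c(A = -1.2, B = -0.5, C = -2.4, D = -0.3) + 0.7)
  s1 <- similarity(shifted, sig)
  expect_equal(s1$r, 1, tolerance = 1e-12)
  expect_equal(s1$ase, 0.7, tolerance = 1e-12)
  expect_equal(s1$aue, 0.7, tolerance = 1e-12)
  expect_equal(s1$rmse, 0.7, tolerance = 1e-12)

  # residues absent from the query contribute 0
  partial <- interaction_profile(c(A = -1.2))
  sp <- similarity(partial, sig)
  om <- oracle_metrics(c(-1.2, 0, 0, 0), unname(sig$mean_energy))
  expect_equal(sp$r, om$r, tolerance = 1e-12)
  expect_equal(sp$rmse, om$rmse, tolerance = 1e-12)

  # seeded random pairs match brute-force formulas to 1e-12
  set.seed(17)
  for (k in 1:25) {
    labs <- paste0("R", 1:10)
    q <- rnorm(10, -1, 1.5)
    m <- rnorm(10, -1, 1.5)
    sigk <- structure(list(receptor_state = "other", residues = labs,
                           mean_energy = stats::setNames(m, labs),
                           sd_energy = stats::setNames(rep(0, 10), labs),
                           reference_ids = "x"),
                      class = "signature_profile")
    got <- similarity(interaction_profile(stats::setNames(q, labs)), sigk)
    want <- oracle_metrics(q, m)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    expect_equal(got$aue, want$aue, tolerance = 1e-12)
    expect_equal(got$ase, want$ase, tolerance = 1e-12)
    expect_true(got$rmse >= got$aue && got$aue >= abs(got$ase))
    expect_equal(got$r2, got$r^2, tolerance = 1e-12)
  }
})

test_that("similarity is invariant under residue reordering", {
  labs <- paste0("R", 1:5)
  set.seed(23)
  q <- stats::setNames(rnorm(5), labs)
  m <- stats::setNames(rnorm(5), labs)
  sig <- structure(list(receptor_state = "other", residues = labs,
                        mean_energy = m,
                        sd_energy = stats::setNames(rep(0, 5), labs),
                        reference_ids = "x"),
                   class = "signature_profile")
  perm <- c(4, 1, 5, 3, 2)
  sig_p <- sig
  sig_p$residues <- labs[perm]
  sig_p$mean_energy <- m[perm]
  a <- similarity(interaction_profile(q), sig)
  b <- similarity(interaction_profile(q[perm]), sig_p)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$rmse, b$rmse, tolerance = 1e-12)
})

test_that("zero-variance vectors yield a flagged, undefined correlation", {
  sig <- build_signature(list(interaction_profile(
    c(A = -1, B = -2, C = -3), "ref", "CB2_active")))
  flat <- interaction_profile(c(A = -1, B = -1, C = -1))
  s <- similarity(flat, sig)
  expect_false(s$r_defined)
  expect_true(is.na(s$r))
  expect_true(is.finite(s$rmse))
})

test_that("signature file round-trip preserves the signature", {
  d <- withr::local_tempdir()
  sig <- build_signature(list(
    interaction_profile(c(A = -1, B = -0.2, C = -0.8), "r1", "CB2_active"),
    interaction_profile(c(A = -3, C = -0.4), "r2", "CB2_active")))
  path <- file.path(d, "sig.tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$mean_energy, sig$mean_energy)
  expect_equal(back$sd_energy, sig$sd_energy)
  expect_equal(back$reference_ids, sig$reference_ids)
  expect_equal(back$receptor_state, "CB2_active")
})
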