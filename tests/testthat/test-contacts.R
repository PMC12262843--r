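test_that("distance_map computes Euclidean distances (3-4-5 fixture)", {
  m <- model_from_coords(rbind(c(0, 0, 0), c(3, 4, 0)), resno = 1:2)
  dm <- distance_map(m, c(1, 2), c(2, 3), metric = "CA")
  expect_equal(as.numeric(dm$d), 5)

  self <- distance_map(m, c(1, 3), c(1, 3), metric = "CA")
  expect_equal(unname(diag(self$d)), c(0, 0))
  expect_equal(self$d, t(self$d))
  expect_error(distance_map(m, c(50, 60), c(1, 3)), "no residues")
})

test_that("residue_COM distances match a mass-weighted nested-loop oracle", {
  set.seed(3)
  atoms <- data.frame(chain = "A",
                      resno = rep(1:10, each = 3),
                      resname = "ALA",
                      atom = rep(c("N", "CA", "O"), 10),
                      x = rnorm(30, sd = 5), y = rnorm(30, sd = 5),
                      z = rnorm(30, sd = 5))
  m <- structure_model(atoms)
  dm <- distance_map(m, c(1, 6), c(6, 11), metric = "residue_COM")
  masses <- tmrscape:::guess_mass(atoms$atom)
  comA <- t(sapply(1:5, function(r) loop_com_oracle(atoms, r, masses)))
  comB <- t(sapply(6:10, function(r) loop_com_oracle(atoms, r, masses)))
  expect_equal(unname(dm$d), loop_distance_oracle(comA, comB),
               tolerance = 1e-10)
})

test_that("CA and residue_COM agree exactly on single-atom residues", {
  xyz <- matrix(rnorm(18, sd = 4), 6, 3)
  m <- model_from_coords(xyz, resno = 1:6)
  d1 <- distance_map(m, c(1, 4), c(4, 7), metric = "CA")
  d2 <- distance_map(m, c(1, 4), c(4, 7), metric = "residue_COM")
  expect_equal(d1$d, d2$d)
})

test_that("contact_map thresholds inclusively and is monotone in cutoff", {
  m <- model_from_coords(rbind(c(0, 0, 0), c(12, 0, 0), c(30, 0, 0)),
                         resno = 1:3)
  dm <- distance_map(m, c(1, 2), c(2, 4), metric = "CA")
  cm <- contact_map(dm, 12)
  expect_identical(as.logical(cm$m), c(TRUE, FALSE))  # exactly 12.0 counts
  far <- contact_map(distance_map(m, c(1, 2), c(3, 4)), 12)
  expect_false(any(far$m))
  expect_error(contact_map(dm, -1), "cutoff")
})

test_that("contact monotonicity holds on random maps", {
  set.seed(9)
  for (rep in 1:20) {
    m <- model_from_coords(matrix(rnorm(60, sd = 8), 20, 3), resno = 1:20)
    dm <- distance_map(m, c(1, 11), c(11, 21))
    c8 <- contact_map(dm, 8)$m
    c12 <- contact_map(dm, 12)$m
    expect_true(all(c12[c8]))   # contacts at 8 are a subset of contacts at 12
  }
})

test_that("classify_interface types the planted architectures", {
  sm <- make_subdomain_map()
  built <- function(arch, seed = 1)
    build_bundle(synthetic_spec(architecture = arch, seed = seed))$model
  expect_equal(classify_interface(built("TM2-TM3"), sm)$label, "TM2-TM3")
  expect_equal(classify_interface(built("TM1-TM4"), sm)$label, "TM1-TM4")
  sep <- classify_interface(built("separated"), sm)
  expect_equal(sep$label, "none")
  expect_true(all(sep$min_distance > 12))
  mixed <- classify_interface(built("mixed_B"), sm)
  expect_equal(mixed$label, "other")
  expect_true(all(mixed$fractions[c("TM2-TM3", "TM2-TM4")] >= 0.05))
  ic <- classify_interface(built("TM2-TM3"), sm)
  expect_true(all(ic$fractions >= 0 & ic$fractions <= 1))
})

test_that("chain_contact_decomposition separates intra and inter patterns", {
  sm <- make_subdomain_map()
  b <- build_bundle(synthetic_spec(architecture = "TM2-TM3", sigma = 0))
  a1 <- b$model$atoms

  # far-apart duplicate -> empty inter map
  a2 <- a1; a2$chain <- "B"; a2$x <- a2$x + 500
  dimer_far <- structure_model(rbind(a1, a2), model_id = "far")
  dec <- chain_contact_decomposition(dimer_far, sm)
  expect_false(any(dec$inter$m))
  expect_true(any(dec$intra$A$m))

  # perfect overlay -> inter pattern equals intra pattern on HP1 x HP2
  a3 <- a1; a3$chain <- "B"
  dimer_overlay <- structure_model(rbind(a1, a3), model_id = "overlay")
  dec2 <- chain_contact_decomposition(dimer_overlay, sm)
  hp1 <- interval_residues(sm$HP1); hp2 <- interval_residues(sm$HP2)
  inter_block <- dec2$inter$m[as.character(hp1), as.character(hp2)]
  expect_equal(unname(inter_block), unname(dec2$intra$A$m))

  # planted inter-chain TM1(A)-TM4(B) interaction
  a4 <- a1; a4$chain <- "B"
  tm1x <- mean(a1$x[a1$resno %in% interval_residues(sm$intervals$TM1)])
  tm4x <- mean(a4$x[a4$resno %in% interval_residues(sm$intervals$TM4)])
  a4$x <- a4$x + (tm1x - tm4x) - 8  # park B's TM4 next to A's TM1
  a4$y <- a4$y + 0
  dimer <- structure_model(rbind(a1, a4), model_id = "dimer")
  dec3 <- chain_contact_decomposition(dimer, sm)
  inter_pairs <- dec3$summary$pair[dec3$summary$category == "inter"]
  expect_true("TM1(A)-TM4(B)" %in% inter_pairs)
  expect_true(all(c("intra_A", "intra_B") %in% dec3$summary$category))
  expect_true(all(dec3$summary$pair[dec3$summary$category == "intra_A"] ==
                    "TM2-TM3"))

  expect_error(chain_contact_decomposition(b$model, sm), "2 chains")
})

test_that("mean_contact_map averages per-frame boolean maps", {
  sm <- make_subdomain_map()
  sim <- simulate_trajectory(synthetic_spec(architecture = "TM2-TM3",
                                            n_frames = 100, seed = 4))
  tm2 <- sm$intervals$TM2; tm3 <- sm$intervals$TM3
  mcm <- mean_contact_map(sim$traj, 1:100, tm2, tm3, metric = "CA")
  acc <- 0
  for (i in 1:100) {
    fs <- frame_structure(sim$traj, i)
    acc <- acc + contact_map(distance_map(fs, tm2, tm3, metric = "CA"), 12)$m
  }
  expect_equal(mcm, acc / 100)
  expect_true(all(mcm >= 0 & mcm <= 1))

  one <- mean_contact_map(sim$traj, 5L, tm2, tm3, metric = "CA")
  fs <- frame_structure(sim$traj, 5L)
  expect_equal(one, contact_map(distance_map(fs, tm2, tm3, metric = "CA"),
                                12)$m + 0)
  expect_error(mean_contact_map(sim$traj, integer(0), tm2, tm3), "empty")
})

test_that("map writer emits TSV plus JSON sidecar", {
  m <- model_from_coords(matrix(rnorm(12), 4, 3), resno = 1:4)
  dm <- distance_map(m, c(1, 3), c(3, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_map(contact_map(dm, 10), path, meta = list(note = "test"))
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), 2L)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$cutoff, 10)
  expect_equal(meta$note, "test")
})
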