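toy_pair <- function(L, sigma, seed) {
  set.seed(seed)
  base <- cmtools:::helix_trace(L)
  noisy <- base + matrix(rnorm(3 * L, sd = sigma), ncol = 3)
  list(model = coord_set(random_rigid(noisy), 1:L),
       ref = coord_set(base, 1:L))
}

test_that("pair_by_label intersects labels in the first set's order", {
  a <- coord_set(matrix(1:15, ncol = 3), letters[1:5])
  b <- coord_set(matrix(15:1, ncol = 3), letters[3:7])
  p <- pair_by_label(a, b)
  expect_equal(p$a$labels, c("c", "d", "e"))
  expect_equal(p$b$labels, p$a$labels)
  expect_error(pair_by_label(a, coord_set(matrix(1:9, ncol = 3), letters[10:12])),
               "insufficient overlap")
})

test_that("kabsch_superpose recovers rigid transformations exactly", {
  set.seed(21)
  P <- matrix(rnorm(30, sd = 5), ncol = 3)
  a <- coord_set(P, 1:10)
  sp <- kabsch_superpose(a, a)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  b <- coord_set(random_rigid(P), 1:10)
  sp2 <- kabsch_superpose(b, a)
  expect_lt(sp2$rmsd, 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-6)
  # collinear points are rejected
  line <- coord_set(cbind(1:5, 0, 0), 1:5)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("kabsch agrees with the quaternion closed form on random sets", {
  set.seed(22)
  for (i in 1:25) {
    P <- matrix(rnorm(30, sd = 5), ncol = 3)
    Q <- matrix(rnorm(30, sd = 5), ncol = 3)
    expect_equal(kabsch_superpose(coord_set(P, 1:10),
                                  coord_set(Q, 1:10))$rmsd,
                 quaternion_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("superposed RMSD never exceeds the unsuperposed RMSD", {
  set.seed(23)
  for (i in 1:10) {
    P <- matrix(rnorm(45, sd = 4), ncol = 3)
    Q <- matrix(rnorm(45, sd = 4), ncol = 3)
    raw <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(kabsch_superpose(coord_set(P, 1:15), coord_set(Q, 1:15))$rmsd,
               raw + 1e-12)
  }
})

test_that("self-comparison gives perfect scores; scores are rigid-invariant", {
  tp <- toy_pair(30, 1.2, seed = 31)
  self <- tp$ref
  expect_equal(kabsch_superpose(self, self)$rmsd, 0, tolerance = 1e-10)
  expect_equal(tm_score(self, self), 1)
  expect_equal(gdt_ha(self, self), 100)
  expect_equal(lddt(self, self), 1)
  # lddt is invariant under an independent rigid transform of either input
  set.seed(32)
  moved <- coord_set(random_rigid(tp$model$xyz), tp$model$labels)
  expect_equal(lddt(moved, tp$ref), lddt(tp$model, tp$ref), tolerance = 1e-9)
  # tm/gdt invariant under joint transformation of both inputs
  set.seed(33)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  jm <- coord_set(random_rigid(tp$model$xyz), tp$model$labels)
  jr <- coord_set(random_rigid(tp$ref$xyz), tp$ref$labels)
  expect_equal(tm_score(jm, tp$ref), tm_score(tp$model, tp$ref),
               tolerance = 0.005)
})

test_that("tm_score and gdt_ha match the exhaustive refined-seed oracle", {
  set.seed(34)
  for (i in 1:5) {
    tp <- toy_pair(sample(25:35, 1), sample(c(0.5, 1, 2), 1), seed = 340 + i)
    mob <- tp$model$xyz[match(tp$ref$labels, tp$model$labels), , drop = FALSE]
    o <- oracle_window_scores(mob, tp$ref$xyz)
    expect_equal(tm_score(tp$model, tp$ref), o$tm, tolerance = 0.01)
    expect_equal(gdt_ha(tp$model, tp$ref), o$gdt_ha, tolerance = 1)
  }
})

test_that("lddt equals the direct O(n^2) recomputation", {
  for (i in 1:5) {
    tp <- toy_pair(10, 1.5, seed = 350 + i)
    mob <- tp$model$xyz[match(tp$ref$labels, tp$model$labels), , drop = FALSE]
    expect_equal(lddt(tp$model, tp$ref), oracle_lddt_ca(mob, tp$ref$xyz),
                 tolerance = 1e-12)
  }
  # StructureModel route on a fixture pair
  spec <- fixture_spec(seed = 9, length = 25, coord_noise_sigma = 1)
  pair <- generate_pair(spec)
  a <- parse_pdb(pair$template_pdb); b <- parse_pdb(pair$target_pdb)
  v <- lddt(a, b)
  expect_true(v > 0 && v < 1)
})

test_that("rmsd_diff subtracts template accuracy with sign", {
  expect_equal(rmsd_diff(2.5, 1.0), 1.5)
  expect_equal(rmsd_diff(1.3, 1.3), 0)
  expect_equal(rmsd_diff(1.0, 2.0), -1.0)
  expect_error(rmsd_diff(-1, 0))
})

test_that("longest_common_segment trims to the longest shared contiguous run", {
  xyz <- function(n, off = 0) cbind(seq_len(n) + off, 1, 1)
  full <- coord_set(xyz(100), 1:100)
  inner <- coord_set(xyz(86), 5:90)
  tr <- longest_common_segment(list(full, inner))
  expect_equal(tr[[1]]$labels, as.character(5:90))
  expect_equal(tr[[2]]$labels, tr[[1]]$labels)
  # identical models unchanged
  same <- longest_common_segment(list(full, full))
  expect_equal(same[[1]]$labels, full$labels)
  # two candidate runs: the longer one wins
  a <- coord_set(xyz(21), c(1:10, 50, 20:29))
  b <- coord_set(xyz(20), c(1:10, 20:29))
  tr2 <- longest_common_segment(list(a, b))
  expect_equal(tr2[[1]]$labels, as.character(c(1:10)))
  expect_error(longest_common_segment(list(full, coord_set(xyz(3), 200:202))),
               "no labels common")
})

test_that("scores degrade monotonically with coordinate noise (spot check)", {
  set.seed(36)
  L <- 35
  base <- cmtools:::helix_trace(L)
  ref <- coord_set(base, 1:L)
  res <- sapply(c(0.5, 2), function(s) {
    m <- coord_set(base + matrix(rnorm(3 * L, sd = s), ncol = 3), 1:L)
    c(rmsd = kabsch_superpose(m, ref)$rmsd, tm = tm_score(m, ref))
  })
  expect_lt(res["rmsd", 1], res["rmsd", 2])
  expect_gt(res["tm", 1], res["tm", 2])
})
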