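test_that("spherePoints gives unit vectors centred on the origin", {
  expect_equal(nrow(spherePoints(1)), 1L)
  p <- spherePoints(960)
  norms <- sqrt(rowSums(p^2))
  expect_true(all(abs(norms - 1) < 1e-12))
  expect_lt(sqrt(sum(colMeans(p)^2)), 0.05)
  expect_error(spherePoints(0), class = "mcwoundRangeError")
})

test_that("single-atom SASA matches the closed form 4*pi*(r+probe)^2", {
  a <- makeAtoms(c(0, 0, 0))
  s <- computeSasa(a, nPoints = 960)
  exact <- 4 * pi * 3.1^2
  expect_lt(abs(s$total_area - exact) / exact, 0.01)
  expect_equal(s$total_area, sum(s$per_atom_area))
})

test_that("disjoint atoms are additive; overlapping match the cap formula", {
  far <- makeAtoms(c(0, 0, 0), c(100, 0, 0))
  exact1 <- 4 * pi * 3.1^2
  expect_lt(abs(computeSasa(far)$total_area - 2 * exact1) / (2 * exact1),
            0.01)
  near <- makeAtoms(c(0, 0, 0), c(3.1, 0, 0))
  exact2 <- twoSphereExact(3.1, 3.1)
  expect_lt(abs(computeSasa(near)$total_area - exact2) / exact2, 0.01)
})

test_that("per-atom areas are bounded by the expanded-sphere surface", {
  fx <- generateComplexFixture(nEnzymeAtoms = 16, nSubstrateAtoms = 16,
                               separation = 3.3, seed = 3)
  s <- computeSasa(atoms(fx$model))
  rad <- defaultRadii()
  rmax <- radiusFor(rad, atoms(fx$model)$element[
    !(atoms(fx$model)$element %in% c("H", "D"))]) + 1.4
  expect_true(all(s$per_atom_area >= 0))
  expect_true(all(s$per_atom_area <= 4 * pi * rmax^2 + 1e-9))
})

test_that("BSA matches the two-sphere cap oracle and clamps at zero", {
  m <- twoAtomModel(3.1)
  exact <- (2 * 4 * pi * 3.1^2 - twoSphereExact(3.1, 3.1)) / 2  # 30.19
  bsa <- buriedInterfaceArea(m)
  expect_lt(abs(bsa - exact) / exact, 0.02)
  expect_identical(buriedInterfaceArea(twoAtomModel(100)), 0)
  # role labels do not matter: the formula is symmetric
  sw <- StructureModel(atoms(m), "B", "A", "swapped")
  expect_equal(buriedInterfaceArea(sw), bsa)
  # unhalved variant doubles the area
  expect_equal(buriedInterfaceArea(m, halve = FALSE), 2 * bsa,
               tolerance = 1e-9)
})

test_that("BSA is zero when no expanded spheres can touch", {
  # threshold distance: r_i + r_j + 2 * probe = 6.2 for two carbons
  expect_identical(buriedInterfaceArea(twoAtomModel(6.5)), 0)
  expect_gt(buriedInterfaceArea(twoAtomModel(5.5)), 0)
})

test_that("BSA is invariant under rigid motion of the whole complex", {
  fx <- generateComplexFixture(nEnzymeAtoms = 9, nSubstrateAtoms = 9,
                               separation = 3.3, seed = 11)
  bsa0 <- buriedInterfaceArea(fx$model)
  a <- atoms(fx$model)
  # translation: exact up to floating-point noise
  at <- a; at$x <- at$x + 13.7; at$y <- at$y - 5.1; at$z <- at$z + 2.2
  expect_equal(buriedInterfaceArea(StructureModel(at, "A", "B")), bsa0,
               tolerance = 1e-9)
  # rotation: the quadrature frame is fixed, so only approximate
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  ar <- a; ar$x <- xyz[, 1]; ar$y <- xyz[, 2]; ar$z <- xyz[, 3]
  bsar <- buriedInterfaceArea(StructureModel(ar, "A", "B"))
  expect_lt(abs(bsar - bsa0) / bsa0, 0.02)
})

test_that("clash threshold arithmetic follows the 0.4 A overlap rule", {
  # two carbons: overlap = 3.4 - d
  expect_identical(countClashes(twoAtomModel(3.5))$clash_count, 0L)
  rep29 <- countClashes(twoAtomModel(2.9))
  expect_identical(rep29$clash_count, 1L)
  expect_equal(rep29$pairs$overlap, 0.5)
  expect_identical(countClashes(twoAtomModel(2.99))$clash_count, 1L)
  expect_identical(countClashes(twoAtomModel(3.01))$clash_count, 0L)
  expect_equal(rep29$per_1000_atoms, 1000 * 1 / 2)
})

test_that("grid clash count equals the brute-force oracle exactly", {
  for (seed in 1:20) {
    m <- randomCloudModel(seed = seed)
    expect_identical(countClashes(m)$clash_count, oracleClashCount(m))
  }
})

test_that("clash report lists only inter-chain pairs above threshold", {
  m <- randomCloudModel(seed = 5)
  rep <- countClashes(m)
  expect_identical(rep$clash_count, nrow(rep$pairs))
  expect_true(all(rep$pairs$overlap >= rep$overlap_threshold))
  enzSerials <- chainAtoms(m, "enzyme")$serial
  subSerials <- chainAtoms(m, "substrate")$serial
  expect_true(all(rep$pairs$serial_enzyme %in% enzSerials))
  expect_true(all(rep$pairs$serial_substrate %in% subSerials))
})

test_that("catalytic geometry takes the minimum over substrate atoms", {
  a <- rbind(makeAtoms(c(0, 0, 0), atom = "SG", element = "S",
                       resname = "CYS"),
             transform(makeAtoms(c(5, 0, 0), c(0, 4.4, 0)),
                       chain = "B", serial = 2:3, resseq = 1:2))
  m <- StructureModel(a, "A", "B")
  g <- catalyticGeometry(m, catalyticSite("A", 1, "SG"))
  expect_equal(g$min_distance, 4.4)
  expect_identical(g$nearest_atom, 3L)
})

test_that("cleavage-site candidates are Arg/Lys main-chain O, ranked by distance", {
  sg <- makeAtoms(c(0, 0, 0), atom = "SG", element = "S", resname = "CYS")
  sub <- data.frame(serial = 2:7,
                    atom = c("CA", "O", "CA", "O", "CA", "O"),
                    element = c("C", "O", "C", "O", "C", "O"),
                    resname = rep(c("LYS", "ARG", "GLY"), each = 2),
                    resseq = rep(1:3, each = 2),
                    chain = "B",
                    x = c(3.5, 3.0, 6.5, 6.0, 2.0, 1.8),
                    y = 0, z = 0, occ = 1, b = 0)
  m <- StructureModel(rbind(sg, sub), "A", "B")
  g <- catalyticGeometry(m, catalyticSite("A", 1, "SG"))
  expect_identical(g$site_candidates$resname, c("LYS", "ARG"))
  expect_equal(g$site_candidates$distance, c(3.0, 6.0))
  # GLY O is closer than both but is not a candidate
  expect_equal(g$min_distance, 1.8)
})

test_that("a substrate without Arg/Lys yields an empty candidate list", {
  fx <- generateComplexFixture(nSubstrateAtoms = 9, separation = 3.3,
                               placeArgLys = FALSE)
  g <- catalyticGeometry(fx$model, fx$site)
  expect_identical(nrow(g$site_candidates), 0L)
  expect_true(is.finite(g$min_distance))
})

test_that("distance ties among candidates break by residue number", {
  sg <- makeAtoms(c(0, 0, 0), atom = "SG", element = "S", resname = "CYS")
  sub <- data.frame(serial = 2:3, atom = "O", element = "O",
                    resname = c("ARG", "LYS"), resseq = c(9L, 2L),
                    chain = "B", x = c(0, 0), y = c(4, -4), z = 0,
                    occ = 1, b = 0)
  m <- StructureModel(rbind(sg, sub), "A", "B")
  g <- catalyticGeometry(m, catalyticSite("A", 1, "SG"))
  expect_identical(g$site_candidates$resseq, c(2L, 9L))
})
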