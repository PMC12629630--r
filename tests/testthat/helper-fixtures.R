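# Build a minimal atom table row-by-row.
makeAtoms <- function(..., chain = "A", atom = "CA", element = "C",
                      resname = "ALA") {
  xyz <- do.call(rbind, list(...))
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             atom = rep_len(atom, n),
             element = rep_len(element, n),
             resname = rep_len(resname, n),
             resseq = seq_len(n),
             chain = rep_len(chain, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = 1, b = 0, stringsAsFactors = FALSE)
}

# Two single-atom chains separated by d along a unit direction.
twoAtomModel <- function(d, u = c(1, 0, 0), element = "C") {
  a <- makeAtoms(c(0, 0, 0), d * u, element = element)
  a$chain <- c("A", "B")
  StructureModel(a, "A", "B", label = "two-atom")
}

# Random two-chain atom cloud for clash-oracle comparisons.
randomCloudModel <- function(nA = 50, nB = 50, boxA = 12, seed = 1) {
  set.seed(seed)
  elements <- c("C", "N", "O", "S")
  mk <- function(n, chain, offset) {
    data.frame(serial = seq_len(n),
               atom = "CA",
               element = sample(elements, n, replace = TRUE),
               resname = "ALA",
               resseq = seq_len(n),
               chain = chain,
               x = stats::runif(n, 0, boxA) + offset,
               y = stats::runif(n, 0, boxA),
               z = stats::runif(n, 0, boxA),
               occ = 1, b = 0, stringsAsFactors = FALSE)
  }
  a <- rbind(mk(nA, "A", 0), mk(nB, "B", stats::runif(1, 0, 6)))
  a$serial <- seq_len(nrow(a))
  StructureModel(a, "A", "B", label = "cloud")
}

# Analytic SASA of two equal spheres of expanded radius R at distance d
# (d < 2R): each loses a spherical cap of height h = R - d/2.
twoSphereExact <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}
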