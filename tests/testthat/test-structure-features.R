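fakeAtoms <- function(xyz, elety = "CA", resno = NULL, chain = "A",
                      aa = "A") {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(chain = chain, resno = resno,
             resid = unname(abundmat:::ONE_TO_THREE[rep(aa, length.out = n)]),
             aa = rep(aa, length.out = n),
             elety = rep(elety, length.out = n), elem = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
             stringsAsFactors = FALSE)
}

test_that("numerical SASA matches closed-form sphere areas", {
  R <- vdwRadii()[["C"]] + 1.4
  # isolated atom: full sphere
  a1 <- fakeAtoms(matrix(0, 1, 3))
  expect_equal(atomSasa(a1, nPoints = 500), 4 * pi * R^2, tolerance = 1e-6)
  # two equal spheres at distance d: each loses a cap of height R - d/2
  d <- 2.0
  a2 <- fakeAtoms(rbind(c(0, 0, 0), c(d, 0, 0)))
  analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  got <- atomSasa(a2, nPoints = 2000)
  expect_equal(got, rep(analytic, 2), tolerance = 0.01)
  # atom enclosed in a shell of dummies: zero accessible area
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  shell <- sweep(dirs / sqrt(rowSums(dirs^2)), 1, 2.5, `*`)
  a3 <- fakeAtoms(rbind(c(0, 0, 0), shell))
  expect_equal(atomSasa(a3, nPoints = 500)[1], 0)
})

test_that("rASA is numerically converged at the default resolution", {
  bm <- benchmarkFixture()
  atoms <- readStructure(bm$structures[["SYN1"]]$monomer)
  lo <- computeRasa(atoms, maxAsa = syntheticMaxAsa(), nPoints = 192)
  hi <- computeRasa(atoms, maxAsa = syntheticMaxAsa(), nPoints = 384)
  expect_true(all(abs(lo$rasa - hi$rasa) < 0.02))
})

test_that("rASA normalisation and residue aggregation behave", {
  # one residue, two atoms, far from anything: rasa = raw / max
  a <- fakeAtoms(rbind(c(0, 0, 0), c(2.4, 0, 0)), elety = c("CA", "CB"),
                 resno = c(1, 1))
  ra <- computeRasa(a, maxAsa = syntheticMaxAsa(), nPoints = 960)
  expect_equal(ra$rasa, 1, tolerance = 0.01)
  expect_error(computeRasa(a, chain = "Z"), "absent")
  expect_error(computeRasa(a, maxAsa = c(G = 100)), "lacks residue type")
})

test_that("monomer vs dimer context reduces interface rASA (synthetic dimer)", {
  bm <- benchmarkFixture()
  st <- bm$structures[["SYN6"]]
  fm <- bm$featuresMonomer[bm$featuresMonomer$protein == "SYN6", ]
  fd <- bm$featuresAnalysis[bm$featuresAnalysis$protein == "SYN6", ]
  iface <- st$truth$position[st$truth$interface]
  dm <- fd$rasa[match(iface, fd$position)]
  mo <- fm$rasa[match(iface, fm$position)]
  expect_true(all(dm <= mo + 1e-9))
  expect_gt(mean(mo > 0.1), 0.9)        # exposed in the monomer
  expect_gt(mean(dm <= 0.1), 0.8)       # buried in the dimer (edges less so)
  found <- findInterface(fm, fd)
  expect_gt(sum(found$is_interface), 10)
  expect_true(all(found$position[found$is_interface] %in% iface))
})

test_that("interface rule enforces exposure change and minimum rASA drop", {
  mk <- function(rasa) data.frame(protein = "p", chain = "A", position = 1,
                                  wt = "L", rasa = rasa, wcn = 5,
                                  ss3 = "loop", ss8 = " ", phi = NA,
                                  psi = NA, crystal_resolved = TRUE)
  expect_true(findInterface(mk(0.30), mk(0.05))$is_interface)
  expect_false(findInterface(mk(0.105), mk(0.098))$is_interface)  # drop 0.007
  expect_false(findInterface(mk(0.05), mk(0.02))$is_interface)    # not exposed
  expect_error(findInterface(mk(0.3), transform(mk(0.1), position = 2)),
               "different positions")
})

test_that("WCN kernel closed forms agree and WCN is rigid-motion invariant", {
  expect_equal(wcnKernel(7), 0.5)       # removable singularity limit
  expect_equal(wcnKernel(0), 1)
  r <- seq(0.1, 30, 0.1); r <- r[abs(r - 7) > 1e-9]
  expect_true(all(abs(wcnKernel(r) - wcnKernel(r, form = "rational")) < 1e-12))
  expect_true(all(diff(wcnKernel(seq(0.1, 30, 0.1))) < 0))

  # two residues whose side chains sit 7 A apart: WCN = 1/2 each
  a <- rbind(fakeAtoms(matrix(c(0, 0, 0), 1), elety = "CB", resno = 1),
             fakeAtoms(matrix(c(7, 0, 0), 1), elety = "CB", resno = 2))
  w <- computeWcn(a)
  expect_equal(w$wcn, c(0.5, 0.5))
  expect_error(computeWcn(fakeAtoms(matrix(0, 1, 3))), "two residues")

  # rigid rotation + translation leaves WCN unchanged
  bm <- benchmarkFixture()
  atoms <- readStructure(bm$structures[["SYN1"]]$monomer)
  w1 <- computeWcn(atoms)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% Rz
  atoms2 <- atoms
  atoms2$x <- xyz[, 1] + 11.3; atoms2$y <- xyz[, 2] - 4.2
  atoms2$z <- xyz[, 3] + 0.9
  w2 <- computeWcn(atoms2)
  expect_equal(w2$wcn, w1$wcn, tolerance = 1e-9)
})

test_that("glycine contact distances use all atoms, others side chains only", {
  # residue 1 (ALA): CA at 0, CB at x = 1; residue 2 (GLY): CA at x = 8.
  # side-chain rule: d(1->2) from CB of 1 to CA of 2 = 7 (GLY -> all atoms)
  a <- rbind(fakeAtoms(rbind(c(0, 0, 0), c(1, 0, 0)),
                       elety = c("CA", "CB"), resno = c(1, 1), aa = "A"),
             fakeAtoms(matrix(c(8, 0, 0), 1), elety = "CA", resno = 2,
                       aa = "G"))
  w <- computeWcn(a)
  expect_equal(w$wcn, rep(wcnKernel(7), 2))
})

test_that("backbone dihedrals recover generating angles and match bio3d", {
  phi <- c(-57, -57, -57, 60, -120, -70)
  psi <- c(-47, -47, -47, 40, 120, 150)
  bb <- buildBackbone(phi, psi)
  d <- computeDihedrals(bb)
  expect_true(all(abs(d$phi[-1] - phi[-1]) < 1))
  expect_true(all(abs(d$psi[-length(psi)] - psi[-length(psi)]) < 1))
  expect_true(is.na(d$phi[1]))          # chain start
  expect_true(is.na(d$psi[length(psi)]))

  tf <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tf,
                   xyz = as.vector(t(as.matrix(bb[, c("x", "y", "z")]))),
                   resno = bb$resno, resid = bb$resid, elety = bb$elety,
                   chain = bb$chain, o = rep(1, nrow(bb)),
                   b = rep(0, nrow(bb)))
  tp <- bio3d::torsion.pdb(bio3d::read.pdb(tf))
  expect_equal(d$phi[-1], unname(tp$phi[-1]), tolerance = 0.1)

  # missing C atom: dihedrals NA with a warning, not an error
  bb2 <- bb[!(bb$resno == 3 & bb$elety == "C"), ]
  expect_warning(d2 <- computeDihedrals(bb2), "backbone")
  expect_true(is.na(d2$phi[3]) && is.na(d2$psi[3]))
})

test_that("DSSP files parse and map onto three secondary structure classes", {
  tf <- writeDsspFixture(tempfile(), resno = 10:17, chain = "A",
                         aa = c("A", "L", "K", "G", "V", "F", "S", "T"),
                         ss = c("H", "G", "I", "E", "B", "T", "S", " "))
  ss <- assignSs3(tf, chain = "A")
  expect_equal(ss$ss3, c("helix", "helix", "helix", "strand", "strand",
                         "loop", "loop", "loop"))
  ssA <- assignSs3(tf, chain = "A", alphaOnly = TRUE)
  expect_equal(ssA$ss3[1:3], c("helix", "loop", "loop"))
  expect_error(assignSs3(tf, chain = "A", positions = c(10, 99)), "absent")
  expect_error(ss3FromSs8("Q"), "unknown")
  expect_error(readDssp(tempfile_with <- {
    f <- tempfile(); writeLines("not dssp", f); f
  }), "not a DSSP file")
})
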