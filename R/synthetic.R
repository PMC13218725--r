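# Synthetic-data generator: compact pseudo-structures, ground-truth labels
# and VAMP-seq-like score tables, so the whole pipeline can be exercised
# against a known answer without any external downloads.

#' Generating mean matrices for the synthetic benchmark
#'
#' Buried means decrease with a physicochemical substitution distance
#' (hydropathy + side-chain volume, echoing the empirical pattern that
#' buried environments punish non-conservative substitutions), ranging from
#' ~0.95 (conservative) down to ~0.05. Exposed means sit near wild-type
#' (~0.95) with a mild distance dependence. Substitutions to proline score
#' poorly in both environments (0.5 exposed, at most 0.45 buried).
#' Diagonals are structurally missing.
#'
#' @return List with 20x20 `buried` and `exposed` matrices.
#' @export
defaultTrueMatrices <- function() {
  dKd <- abs(outer(kdHydropathy[AA20], kdHydropathy[AA20], `-`))
  dKd <- dKd / max(dKd)
  dV <- abs(outer(aaVolume[AA20], aaVolume[AA20], `-`))
  dV <- dV / max(dV)
  dist <- 0.6 * dKd + 0.4 * dV
  buried <- 0.95 - 0.9 * dist
  exposed <- 0.98 - 0.13 * dist
  exposed[, "P"] <- 0.5
  buried[, "P"] <- pmin(buried[, "P"], 0.45)  # proline is harsh everywhere
  dimnames(buried) <- dimnames(exposed) <- list(AA20, AA20)
  diag(buried) <- diag(exposed) <- NA_real_
  list(buried = buried, exposed = exposed)
}

# Mean profile planted at left-handed-helix-like loop sites: substitution to
# glycine is well tolerated, to beta-branched/bulky P/I/V/W poorly.
lefthandedProfile <- function() {
  p <- stats::setNames(rep(0.55, 20L), AA20)
  p["G"] <- 0.9
  p[c("P", "I", "V", "W")] <- 0.1
  p
}

#' Configuration for the synthetic benchmark generator
#'
#' Defaults define the package's reference benchmark ("benchmark6"): six
#' proteins of 150 residues, per-variant Gaussian noise sd 0.05, 90%
#' mutational completeness, the last two proteins homodimers with a planted
#' full-face interface patch, plus 2 degron-like and 6 left-handed-loop
#' sites per protein.
#'
#' @param nProteins,nResidues Number of proteins and residues per protein.
#' @param noiseSd Per-variant Gaussian noise standard deviation (score
#'   units); also reported as each score's sd.
#' @param completeness Fraction of possible variants retained, in (0, 1].
#' @param nDimers Number of proteins (taken from the end of the list) that
#'   form homodimers with an interface patch.
#' @param interfaceSize Residues in each planted interface patch (the
#'   most central sites of the dimer contact face; the default covers the
#'   whole face of the reference lattice, since every contact-face residue
#'   is occluded by the partner chain).
#' @param nDegron Solvent-exposed degron-like sites per protein whose
#'   profiles follow the buried matrix despite their exposure.
#' @param nLefthanded Loop sites per protein with left-handed-helix-like
#'   dihedrals and the planted intolerance profile.
#' @param trueMatrices Generating means (see [defaultTrueMatrices()]).
#' @param addControls Also inject synonymous and nonsense rows (for filter
#'   tests).
#' @param seed Integer seed (mandatory).
#' @return List of class `"abundmatGeneratorConfig"`.
#' @export
generatorConfig <- function(nProteins = 6L, nResidues = 150L, noiseSd = 0.05,
                            completeness = 0.9, nDimers = 2L,
                            interfaceSize = 25L, nDegron = 2L,
                            nLefthanded = 6L,
                            trueMatrices = defaultTrueMatrices(),
                            addControls = FALSE, seed) {
  if (missing(seed)) stop("generatorConfig requires an explicit seed")
  stopifnot(completeness > 0, completeness <= 1, nProteins >= 1,
            nResidues >= 27, nDimers <= nProteins,
            all(is.na(diag(trueMatrices$buried))),
            all(is.na(diag(trueMatrices$exposed))))
  structure(list(nProteins = as.integer(nProteins),
                 nResidues = as.integer(nResidues), noiseSd = noiseSd,
                 completeness = completeness, nDimers = as.integer(nDimers),
                 interfaceSize = as.integer(interfaceSize),
                 nDegron = as.integer(nDegron),
                 nLefthanded = as.integer(nLefthanded),
                 trueMatrices = trueMatrices, addControls = addControls,
                 seed = as.integer(seed)),
            class = "abundmatGeneratorConfig")
}

# Boustrophedon (snake) path through an nx x ny x nz lattice: consecutive
# sites are always one unit step apart, giving a self-avoiding compact chain
# with uniform backbone spacing once scaled.
latticePath <- function(n) {
  # prefer a box that the chain fills exactly (near-cubic divisor triple);
  # fall back to a covering box with a truncated last layer
  dims <- NULL
  divs <- which(n %% seq_len(n) == 0L)
  nzc <- divs[which.min(abs(divs - n^(1 / 3)))]
  m <- n %/% nzc
  divs2 <- which(m %% seq_len(m) == 0L)
  nyc <- divs2[which.min(abs(divs2 - sqrt(m)))]
  nxc <- m %/% nyc
  if (max(nxc, nyc, nzc) <= 2L * min(nxc, nyc, nzc) && min(nxc, nyc, nzc) >= 3L)
    dims <- sort(c(nxc, nyc, nzc), decreasing = TRUE)
  if (is.null(dims)) {
    nx <- ceiling(n^(1 / 3)) + 1L
    ny <- nz <- ceiling(sqrt(n / nx))
    while (nx * ny * nz < n) nz <- nz + 1L
    dims <- c(nx, ny, nz)
  }
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  out <- matrix(0L, nx * ny * nz, 3L)
  k <- 1L
  for (z in 0:(nz - 1L)) {
    ys <- 0:(ny - 1L); if (z %% 2L) ys <- rev(ys)
    for (yi in seq_along(ys)) {
      xs <- 0:(nx - 1L)
      if ((z * ny + (yi - 1L)) %% 2L) xs <- rev(xs)
      for (x in xs) {
        out[k, ] <- c(x, ys[yi], z)
        k <- k + 1L
      }
    }
  }
  out[seq_len(n), , drop = FALSE]
}

# A site is core (ground-truth buried) iff all 26 lattice neighbours are
# occupied.
coreSites <- function(sites) {
  key <- paste(sites[, 1L], sites[, 2L], sites[, 3L])
  occupied <- new.env(hash = TRUE)
  for (k in key) assign(k, TRUE, envir = occupied)
  vapply(seq_len(nrow(sites)), function(i) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0L && dy == 0L && dz == 0L) next
      if (!exists(paste(sites[i, 1L] + dx, sites[i, 2L] + dy, sites[i, 3L] + dz),
                  envir = occupied)) return(FALSE)
    }
    TRUE
  }, TRUE)
}

SPACING <- 3.8          # backbone (consecutive-residue) spacing, Angstrom
CB_LENGTH <- 2.4        # pseudo side-chain offset from CA, Angstrom
DIMER_GAP <- 4.4        # CA-CA distance across the dimer contact, Angstrom

#' Maximum accessible area of the pseudo-atom residue model
#'
#' The synthetic structures represent every residue by one CA atom plus one
#' pseudo side-chain atom (a deliberately uniform model), so relative
#' accessibility must be normalised by the maximum area of that model, not
#' by the all-atom theoretical scale: the closed-form area of the union of
#' the two probe-extended spheres. Pass this table as `maxAsa` whenever
#' computing rASA on generator output.
#'
#' @param probe Probe radius (Angstrom), matching the SASA computation.
#' @return Named numeric vector over [AA20] (Angstrom^2).
#' @export
syntheticMaxAsa <- function(probe = 1.4) {
  R <- vdwRadii()[["C"]] + probe
  capH <- R - CB_LENGTH / 2
  pair <- 2 * (4 * pi * R^2 - 2 * pi * R * capH)
  stats::setNames(rep(pair, 20L), AA20)
}

# Build one synthetic protein: coordinates, ground-truth labels, sequence.
buildSyntheticProtein <- function(cfg, index, dimer) {
  n <- cfg$nResidues
  sites <- latticePath(n)
  core <- coreSites(sites)
  xmax <- max(sites[, 1L])
  seedP <- cfg$seed + 7919L * index
  withSeed(seedP, {
    wt <- sample(AA20, n, replace = TRUE)
    jitter <- matrix(stats::runif(3L * n, -0.12, 0.12), n, 3L)

    surface <- !core
    # planted special sites, all on the surface, mutually exclusive
    interface <- rep(FALSE, n)
    if (dimer) {
      face <- which(surface & sites[, 1L] == xmax)
      ctr <- colMeans(sites[face, , drop = FALSE])
      ord <- face[order((sites[face, 2L] - ctr[2L])^2 +
                          (sites[face, 3L] - ctr[3L])^2, face)]
      interface[utils::head(ord, cfg$interfaceSize)] <- TRUE
    }
    degron <- rep(FALSE, n)
    face0 <- which(surface & !interface & sites[, 1L] == 0L)
    ctr0 <- colMeans(sites[face0, , drop = FALSE])
    ord0 <- face0[order((sites[face0, 2L] - ctr0[2L])^2 +
                          (sites[face0, 3L] - ctr0[3L])^2, face0)]
    degron[utils::head(ord0, cfg$nDegron)] <- TRUE
    lefthanded <- rep(FALSE, n)
    faceY <- which(surface & !interface & !degron & sites[, 2L] == 0L)
    lefthanded[utils::head(faceY, cfg$nLefthanded)] <- TRUE
    wt[lefthanded] <- sample(c("G", "N", "D", "H"), sum(lefthanded),
                             replace = TRUE)

    # ground-truth secondary structure / dihedrals (the pseudo-structure has
    # no N/C backbone, so these are generated labels, not measurements)
    frac <- seq_len(n) / n
    ss8 <- ifelse(frac <= 0.4, "H", ifelse(frac <= 0.65, "E", " "))
    phi <- ifelse(ss8 == "H", -57, ifelse(ss8 == "E", -120, -70))
    psi <- ifelse(ss8 == "H", -47, ifelse(ss8 == "E", 120, 150))
    ss8[lefthanded] <- " "
    phi[lefthanded] <- 65
    psi[lefthanded] <- 30
    crystal <- rep(TRUE, n)
    notSpecial <- which(!interface & !degron & !lefthanded)
    crystal[utils::tail(notSpecial, 3L)] <- FALSE

    ca <- sites * SPACING + jitter
    centre <- colMeans(ca)
    dir <- ca - matrix(centre, n, 3L, byrow = TRUE)
    nrm <- sqrt(rowSums(dir^2))
    nrm[nrm < 1e-9] <- 1
    cb <- ca + CB_LENGTH * dir / nrm

    list(index = index, dimer = dimer, wt = wt, ca = ca, cb = cb,
         truth = data.frame(position = seq_len(n), wt = wt, buried = core,
                            interface = interface, degron = degron,
                            lefthanded = lefthanded, ss8 = ss8,
                            ss3 = ss3FromSs8(ss8), phi = phi, psi = psi,
                            crystal_resolved = crystal,
                            stringsAsFactors = FALSE),
         xface = xmax * SPACING)
  })
}

writeSyntheticPdb <- function(prot, file, withPartner = FALSE) {
  buildChain <- function(ca, cb, wt, chain) {
    hasCb <- rep(TRUE, length(wt))
    natom <- sum(hasCb) + length(wt)
    xyz <- matrix(NA_real_, natom, 3L)
    resno <- integer(natom); elety <- character(natom)
    k <- 1L
    for (i in seq_along(wt)) {
      xyz[k, ] <- ca[i, ]; resno[k] <- i; elety[k] <- "CA"; k <- k + 1L
      if (hasCb[i]) {
        xyz[k, ] <- cb[i, ]; resno[k] <- i; elety[k] <- "CB"; k <- k + 1L
      }
    }
    list(xyz = xyz, resno = resno, elety = elety,
         resid = unname(ONE_TO_THREE[wt])[resno],
         chain = rep(chain, natom))
  }
  a <- buildChain(prot$ca, prot$cb, prot$wt, "A")
  parts <- list(a)
  if (withPartner) {
    mirror <- function(m) {
      m[, 1L] <- 2 * prot$xface + DIMER_GAP - m[, 1L]
      m
    }
    parts <- c(parts, list(buildChain(mirror(prot$ca), mirror(prot$cb),
                                      prot$wt, "B")))
  }
  xyz <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  natom <- nrow(xyz)
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(xyz)),
                   resno = unlist(lapply(parts, `[[`, "resno")),
                   resid = unlist(lapply(parts, `[[`, "resid")),
                   elety = unlist(lapply(parts, `[[`, "elety")),
                   chain = unlist(lapply(parts, `[[`, "chain")),
                   o = rep(1, natom), b = rep(0, natom))
  invisible(file)
}

#' Generate synthetic structures with ground-truth burial labels
#'
#' Writes valid PDB files of a compact pseudo-structure (CA plus one
#' pseudo-side-chain atom per non-glycine residue, consecutive residues 3.8
#' Angstrom apart on a self-avoiding lattice path with small positional
#' jitter). Core residues are geometrically enclosed; for dimer proteins a
#' designated surface patch forms the homodimer contact in a two-chain file.
#' Identical config (including seed) gives byte-identical files.
#'
#' @param cfg A [generatorConfig()].
#' @param dir Output directory (created if needed).
#' @return List, one element per protein, each with `protein`, `monomer` and
#'   (for dimers) `dimer` PDB paths, and the ground-truth `truth` table
#'   (`position`, `wt`, `buried`, `interface`, `degron`, `lefthanded`,
#'   `ss8`, `ss3`, `phi`, `psi`, `crystal_resolved`).
#' @export
makeStructures <- function(cfg, dir) {
  stopifnot(inherits(cfg, "abundmatGeneratorConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vector("list", cfg$nProteins)
  for (i in seq_len(cfg$nProteins)) {
    id <- sprintf("SYN%d", i)
    dimer <- i > cfg$nProteins - cfg$nDimers
    prot <- buildSyntheticProtein(cfg, i, dimer)
    mono <- file.path(dir, sprintf("%s_monomer.pdb", id))
    writeSyntheticPdb(prot, mono, withPartner = FALSE)
    dim_ <- NULL
    if (dimer) {
      dim_ <- file.path(dir, sprintf("%s_dimer.pdb", id))
      writeSyntheticPdb(prot, dim_, withPartner = TRUE)
    }
    out[[i]] <- list(protein = id, monomer = mono, dimer = dim_,
                     isDimer = dimer, truth = prot$truth)
  }
  names(out) <- vapply(out, `[[`, "", "protein")
  out
}

#' Generate a synthetic score table for one protein
#'
#' For each residue, all 19 substitutions are drawn from
#' `Normal(true mean, noiseSd)` where the true mean comes from the buried or
#' exposed generating matrix according to the residue's ground-truth label.
#' Special sites override the label: interface and degron-like sites draw
#' from the buried matrix regardless of their monomer exposure, and
#' left-handed-loop sites use the planted intolerance profile. A random
#' `1 - completeness` fraction of variants is dropped; reported sd equals
#' `noiseSd`.
#'
#' @param cfg A [generatorConfig()].
#' @param truth Ground-truth table from [makeStructures()].
#' @param proteinId Protein id for the dataset.
#' @param seed Integer seed for this table.
#' @return An [AbundanceDataset-class] (already missense-only unless
#'   `cfg$addControls`).
#' @export
makeScores <- function(cfg, truth, proteinId, seed) {
  M <- cfg$trueMatrices
  lh <- lefthandedProfile()
  withSeed(seed, {
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      wt <- truth$wt[i]
      vars <- setdiff(AA20, wt)
      mu <- if (truth$lefthanded[i]) lh[vars]
            else if (truth$buried[i] || truth$interface[i] || truth$degron[i])
              M$buried[wt, vars]
            else M$exposed[wt, vars]
      sc <- mu + stats::rnorm(length(vars), 0, cfg$noiseSd)
      keep <- stats::runif(length(vars)) < cfg$completeness
      rows[[i]] <- data.frame(chain = "A", position = truth$position[i],
                              wt = wt, var = vars, score = unname(sc),
                              sd = cfg$noiseSd,
                              stringsAsFactors = FALSE)[keep, , drop = FALSE]
    }
    rec <- do.call(rbind, rows)
    if (cfg$addControls) {
      pos <- utils::head(truth$position, 10L)
      wtc <- truth$wt[match(pos, truth$position)]
      ctrl <- data.frame(chain = "A", position = rep(pos, 2L),
                         wt = rep(wtc, 2L),
                         var = c(wtc, rep("*", length(pos))),
                         score = c(stats::rnorm(length(pos), 1, cfg$noiseSd),
                                   stats::rnorm(length(pos), 0, cfg$noiseSd)),
                         sd = cfg$noiseSd, stringsAsFactors = FALSE)
      rec <- rbind(rec, ctrl)
    }
    rownames(rec) <- NULL
    new("AbundanceDataset", proteinId = proteinId, records = rec,
        nResidues = nrow(truth), metadata = list(synthetic = TRUE))
  })
}

#' Generate the full synthetic benchmark
#'
#' Runs the generator end to end: structures are written to `dir`, read back
#' and passed through the package's own descriptor stack ([computeRasa()],
#' [computeWcn()]), generated secondary structure and dihedral labels are
#' attached, score tables are drawn and pooled. Dimer proteins get two
#' feature tables: monomer-context and dimer-context (`featuresAnalysis`
#' uses the dimer context, mirroring how obligate dimers are analysed).
#'
#' @param seed Integer seed driving every stochastic step.
#' @param dir Directory for structure files (default: fresh temp directory).
#' @param cfg Optional [generatorConfig()]; defaults to the reference
#'   benchmark with this `seed`.
#' @return List with `cfg`, `dir`, `structures` (from [makeStructures()]),
#'   `datasets`, `pool` ([VariantPool-class]), `featuresMonomer`,
#'   `featuresAnalysis` (both spanning all proteins), `interfaces` (one
#'   [findInterface()] table per dimer protein), and `truth` (per protein).
#' @export
syntheticBenchmark <- function(seed, dir = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- generatorConfig(seed = seed)
  if (is.null(dir)) dir <- tempfile("benchmark")
  structures <- makeStructures(cfg, dir)
  datasets <- list()
  featM <- featA <- list()
  interfaces <- list()
  for (i in seq_along(structures)) {
    st <- structures[[i]]
    truth <- st$truth
    ssTab <- truth[, c("position", "ss8", "ss3")]
    monoAtoms <- readStructure(st$monomer)
    fm <- computeFeatures(monoAtoms, protein = st$protein, chain = "A",
                          ss = ssTab, maxAsa = syntheticMaxAsa(),
                          crystalResolved = truth$position[truth$crystal_resolved])
    fm$phi <- truth$phi[match(fm$position, truth$position)]
    fm$psi <- truth$psi[match(fm$position, truth$position)]
    featM[[i]] <- fm
    if (st$isDimer) {
      dimAtoms <- readStructure(st$dimer)
      fd <- computeFeatures(dimAtoms, protein = st$protein, chain = "A",
                            ss = ssTab, maxAsa = syntheticMaxAsa(),
                            crystalResolved = truth$position[truth$crystal_resolved])
      fd$phi <- truth$phi[match(fd$position, truth$position)]
      fd$psi <- truth$psi[match(fd$position, truth$position)]
      featA[[i]] <- fd
      interfaces[[st$protein]] <- findInterface(fm, fd)
    } else {
      featA[[i]] <- fm
    }
    datasets[[i]] <- makeScores(cfg, truth, st$protein,
                                seed = cfg$seed + 104729L * i)
  }
  pool <- combineDatasets(lapply(datasets, filterSubstitutions))
  list(cfg = cfg, dir = dir, structures = structures, datasets = datasets,
       pool = pool,
       featuresMonomer = do.call(rbind, featM),
       featuresAnalysis = do.call(rbind, featA),
       interfaces = interfaces,
       truth = lapply(structures, `[[`, "truth"))
}
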