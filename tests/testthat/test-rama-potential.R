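test_that("dihedral handles cis, trans and rigid motions", {
  p1 <- c(0, 0, 0); p2 <- c(1, 0, 0); p3 <- c(1, 1, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(0, 1, 0)), 0)
  tr <- dihedral_angle(p1, p2, p3, c(2, 1, 0))
  expect_equal(angdiff(tr, 180), 0, tolerance = 1e-9)
  expect_true(tr >= -180 && tr < 180)

  # rigid rotation + translation invariance
  set.seed(3)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  shift <- c(3, -2, 5)
  for (i in 1:20) {
    q <- matrix(stats::rnorm(12), 4, 3)
    a1 <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    qr <- t(R %*% t(q)) + matrix(shift, 4, 3, byrow = TRUE)
    a2 <- dihedral_angle(qr[1, ], qr[2, ], qr[3, ], qr[4, ])
    expect_equal(angdiff(a1, a2), 0, tolerance = 1e-9)
  }
})

test_that("dihedral sign flips under mirror reflection, magnitude invariant", {
  set.seed(5)
  for (i in 1:20) {
    q <- matrix(stats::rnorm(12), 4, 3)
    qm <- q; qm[, 3] <- -qm[, 3]
    a <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    b <- dihedral_angle(qm[1, ], qm[2, ], qm[3, ], qm[4, ])
    expect_equal(angdiff(a, -b), 0, tolerance = 1e-9)
  }
})

test_that("dihedral agrees with the plane-normal oracle on random quadruples", {
  set.seed(17)
  for (i in 1:1000) {
    q <- matrix(stats::rnorm(12), 4, 3)
    expect_equal(angdiff(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                         oracle_dihedral(q[1, ], q[2, ], q[3, ], q[4, ])),
                 0, tolerance = 1e-9)
  }
})

test_that("degenerate geometry raises a domain error", {
  p <- c(0, 0, 0)
  expect_error(dihedral_angle(p, p, c(1, 0, 0), c(1, 1, 0)), "degenerate")
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("extraction masks terminal angles and matches bio3d torsions", {
  phi <- c(0, -60, -120, 45, -75)
  psi <- c(-45, 130, 60, 150, 0)
  ch <- build_backbone(phi, psi)
  ts <- extract_torsions(ch)
  expect_false(ts$phi_mask[1])
  expect_false(ts$psi_mask[5])
  expect_true(all(ts$phi_mask[-1]))
  expect_true(all(ts$psi_mask[-5]))
  # independent cross-check through the PDB route and bio3d's torsions
  path <- tempfile(fileext = ".pdb")
  write_pdb_backbone(ch, path)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(path, verbose = FALSE))
  # PDB coordinates carry three decimals, so allow that rounding
  expect_lt(max(angdiff(ts$phi[-1], tor$phi[-1])), 0.1)
  expect_lt(max(angdiff(ts$psi[-5], tor$psi[-5])), 0.1)
})

test_that("chain breaks and incomplete residues mask the spanning angles", {
  phi <- c(0, -60, -120, 45)
  psi <- c(-45, 130, 60, 0)
  ch <- build_backbone(phi, psi)
  # open a gap between residues 2 and 3
  for (nm in c("N", "CA", "C")) {
    ch$coords[[3]][nm, ] <- ch$coords[[3]][nm, ] + c(5, 0, 0)
    ch$coords[[4]][nm, ] <- ch$coords[[4]][nm, ] + c(5, 0, 0)
  }
  ts <- extract_torsions(ch)
  expect_false(ts$phi_mask[3])
  expect_false(ts$psi_mask[2])
  expect_true(ts$phi_mask[4])

  ch2 <- build_backbone(phi, psi)
  ch2$residues$complete[2] <- FALSE
  ts2 <- extract_torsions(ch2)
  expect_false(ts2$phi_mask[2])
  expect_false(ts2$phi_mask[3])
  expect_false(ts2$psi_mask[1])
  expect_false(ts2$psi_mask[2])
  ch3 <- build_backbone(c(0, 0), c(0, 0))
  ch3$residues$complete <- c(TRUE, FALSE)
  expect_error(extract_torsions(ch3), "at least 2")
})

test_that("basin binning follows the half-open 5-degree convention", {
  rec <- data.frame(left = "A", center = "N", right = "C",
                    phi = -60, psi = -45)
  pot <- build_basin_potential(rec, pseudocount = 0, min_triplet_count = 1)
  m <- pot$triplet_maps[["ANC"]]
  # 0-based floor((angle+180)/5) = (24, 27) -> R indices (25, 28)
  expect_equal(m[25, 28], 1)
  expect_equal(sum(m), 1)
  # +180 wraps to -180 (bin 1), -180 also bin 1, 179.999 in bin 72
  expect_equal(esiden:::rama_bin(c(180, -180, 179.99, -0.01, 0)),
               c(1L, 1L, 72L, 36L, 37L))
})

test_that("all retained maps are probability distributions", {
  set.seed(23)
  rec <- data.frame(
    left = sample(c("A", "R"), 200, TRUE),
    center = sample(c("N", "G"), 200, TRUE),
    right = sample(c("C", "D"), 200, TRUE),
    phi = stats::runif(200, -180, 180),
    psi = stats::runif(200, -180, 180))
  pot <- build_basin_potential(rec, pseudocount = 1 / 5184,
                               min_triplet_count = 5)
  for (m in c(pot$center_maps, pot$triplet_maps)) {
    expect_equal(sum(m), 1, tolerance = 1e-9)
    expect_true(all(m >= 0))
  }
})

test_that("center maps are the count-weighted mixture of their triplet maps", {
  set.seed(29)
  rec <- data.frame(
    left = sample(c("A", "R"), 400, TRUE),
    center = "N",
    right = sample(c("C", "D"), 400, TRUE),
    phi = stats::runif(400, -180, 180),
    psi = stats::runif(400, -180, 180))
  pot <- build_basin_potential(rec, pseudocount = 0, min_triplet_count = 1)
  mix <- Reduce(`+`, lapply(names(pot$triplet_maps), function(k) {
    pot$triplet_maps[[k]] * pot$triplet_counts[[k]]
  })) / sum(pot$triplet_counts)
  expect_equal(pot$center_maps[["N"]], mix, tolerance = 1e-12)
})

test_that("sparse triplets fall back to the center map", {
  rec <- data.frame(left = c("A", "A", "A"), center = "N",
                    right = c("C", "C", "D"),
                    phi = c(-60, -61, 100), psi = c(-45, -44, 10))
  pot0 <- build_basin_potential(rec, pseudocount = 0, min_triplet_count = 2)
  expect_true("ANC" %in% names(pot0$triplet_maps))
  expect_false("AND" %in% names(pot0$triplet_maps))  # count 1 < 2: dropped
  # smoothed potential carries backoff maps for all 20 residues
  pot <- build_basin_potential(rec, min_triplet_count = 2)
  expect_setequal(setdiff(names(pot$center_maps), "N"),
                  setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                          "N"))
  red <- reduce_basins(pot, method = "pca", seed = 1)
  seq <- esiden:::new_sequence("q", "ANDN")
  feats <- rbp_features(seq, red)
  # position 2 keys (A,N,D): unseen triplet -> center backoff of N
  expect_equal(feats[2, ], as.vector(t(red$embeddings[["N"]])))
  # missing backoff map errors
  red2 <- red; red2$embeddings[["A"]] <- NULL
  expect_error(rbp_features(seq, red2), "no basin embedding")
  expect_error(build_basin_potential(rec[0, ]), "no torsion")
})

test_that("reductions have shape 72 x 2 and are seed-deterministic", {
  set.seed(31)
  rec <- data.frame(left = "A", center = c("N", "G"), right = "C",
                    phi = stats::runif(100, -180, 180),
                    psi = stats::runif(100, -180, 180))
  pot <- build_basin_potential(rec, min_triplet_count = 10)
  for (method in c("pca", "tsne")) {
    r1 <- reduce_basins(pot, method = method, seed = 13)
    r2 <- reduce_basins(pot, method = method, seed = 13)
    expect_identical(r1$embeddings, r2$embeddings)
    for (e in r1$embeddings) expect_equal(dim(e), c(72L, 2L))
  }
})

test_that("identical map rows embed to coincident points under pca", {
  m <- matrix(1 / (72 * 72), 72, 72)
  m[10, ] <- m[20, ] <- seq_len(72) / sum(seq_len(72)) / 72
  pot <- structure(list(center_maps = list(A = m / sum(m)),
                        triplet_maps = list(), center_counts = c(A = 1),
                        triplet_counts = numeric(0), bin_width = 5,
                        pseudocount = 0, min_triplet_count = 1, ss_mode = "A"),
                   class = "basin_potential")
  red <- reduce_basins(pot, method = "pca", seed = 1)
  expect_equal(red$embeddings[["A"]][10, ], red$embeddings[["A"]][20, ],
               tolerance = 1e-9)
})

test_that("the RBP feature keys residues by their sequence triplet", {
  set.seed(37)
  torsos <- lapply(1:8, function(i) {
    phi <- stats::runif(20, -180, 180); psi <- stats::runif(20, -180, 180)
    list(chain = build_backbone(phi, psi,
                                aa = sample(c("A", "R", "N", "C", "F", "G", "D"),
                                            20, TRUE)),
         torsions = new_torsion_series(phi, psi))
  })
  rec <- collect_torsion_records(lapply(torsos, `[[`, "chain"),
                                 lapply(torsos, `[[`, "torsions"))
  pot <- build_basin_potential(rec, min_triplet_count = 1)
  red <- reduce_basins(pot, method = "pca", seed = 2)
  seq <- esiden:::new_sequence("q", "ARNCFGD")
  feats <- rbp_features(seq, red)
  expect_equal(dim(feats), c(7L, 144L))
  # residue N (position 3) keys (R, N, C) when that triplet map exists
  key <- if ("RNC" %in% names(red$embeddings)) "RNC" else "N"
  expect_equal(feats[3, ], as.vector(t(red$embeddings[[key]])))
  # terminal residues use the center backoff
  expect_equal(feats[1, ], as.vector(t(red$embeddings[["A"]])))
  expect_equal(feats[7, ], as.vector(t(red$embeddings[["D"]])))
})

test_that("basin potentials serialize through JSON losslessly", {
  rec <- data.frame(left = c("A", "A"), center = "N", right = "C",
                    phi = c(-60, -65), psi = c(-45, -40))
  pot <- build_basin_potential(rec, min_triplet_count = 1)
  red <- reduce_basins(pot, method = "pca", seed = 13)
  path <- tempfile(fileext = ".json")
  write_basin_potential(pot, path, reduced = red)
  back <- read_basin_potential(path)
  expect_equal(back$potential$center_maps[["N"]], pot$center_maps[["N"]])
  expect_equal(back$potential$triplet_maps[["ANC"]], pot$triplet_maps[["ANC"]])
  expect_equal(back$reduced$embeddings[["ANC"]], red$embeddings[["ANC"]])
  expect_equal(back$reduced$seed, 13L)
})

test_that("build-then-extract reproduces prescribed torsions", {
  set.seed(41)
  for (rep in 1:5) {
    L <- sample(5:30, 1)
    phi <- stats::runif(L, -179, 179)
    psi <- stats::runif(L, -179, 179)
    ts <- extract_torsions(build_backbone(phi, psi))
    expect_lt(max(angdiff(ts$phi[ts$phi_mask], phi[ts$phi_mask])), 1e-3)
    expect_lt(max(angdiff(ts$psi[ts$psi_mask], psi[ts$psi_mask])), 1e-3)
  }
})
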