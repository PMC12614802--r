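test_that("vdW radii come from the element table with a warned default", {
  lines <- c(
    pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "OX", "ALA", "A", 2, 4, 0, 0, element = "O"),
    pdb_atom_line(3, "PX", "ALA", "A", 3, 8, 0, 0, element = "P"),
    "END")
  s <- assign_vdw_radii(parse_pdb_text(lines)[[1]])
  expect_equal(s$atoms$vdw_radius, c(1.70, 1.52, 1.80))
  # unknown element falls back with a warning
  cfg <- default_config()
  cfg$vdw_radii <- cfg$vdw_radii[c("C", "O")]
  expect_warning(s2 <- assign_vdw_radii(s, cfg), "default")
  expect_equal(s2$atoms$vdw_radius[3], cfg$vdw_default)
})

test_that("neighbor pairs are complete and annotated with bond path", {
  # 3 collinear atoms at 0, 2, 4 A, cutoff 3 -> pairs (1,2), (2,3) only
  lines <- c(
    pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 2, 2, 0, 0),
    pdb_atom_line(3, "CB", "ALA", "A", 3, 4, 0, 0),
    "END")
  s <- parse_pdb_text(lines)[[1]]
  p <- neighbor_pairs(s, 3)
  expect_equal(nrow(p), 2)
  expect_equal(p[, c("i", "j")], data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  expect_equal(neighbor_pairs(s, 1.5), p[0, ])   # below min distance: empty
  # random cloud: identical pair set to an O(n^2) brute-force loop
  cl <- make_atom_cloud(50, box = 16, seed = 11)
  xyz <- as.matrix(cl$atoms[, c("x", "y", "z")])
  for (cutoff in c(3, 5, 8)) {
    got <- neighbor_pairs(cl, cutoff)
    want <- NULL
    for (i in 1:49) for (j in (i + 1):50) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        want <- rbind(want, c(i, j))
      }
    }
    expect_equal(as.matrix(got[order(got$i, got$j), c("i", "j")]),
                 want, ignore_attr = TRUE)
  }
  # a bonded chain gets exact path classes up to the 1-5 horizon
  h <- .ensure_helix(6)
  ph <- neighbor_pairs(h, 12)
  at <- h$atoms
  n1 <- which(at$name == "N" & at$res_index == 1)
  pick <- function(a, b) {
    r <- ph[(ph$i == a & ph$j == b) | (ph$i == b & ph$j == a), ]
    r$bonded_path
  }
  ca1 <- which(at$name == "CA" & at$res_index == 1)
  c1 <- which(at$name == "C" & at$res_index == 1)
  n2 <- which(at$name == "N" & at$res_index == 2)
  ca2 <- which(at$name == "CA" & at$res_index == 2)
  c2 <- which(at$name == "C" & at$res_index == 2)
  expect_equal(pick(n1, ca1), 1)
  expect_equal(pick(n1, c1), 2)
  expect_equal(pick(n1, n2), 3)
  expect_equal(pick(n1, ca2), 4)
  expect_equal(pick(n1, c2), 5)
})

test_that("geometric centers average the atom and its covalent neighbours", {
  lines <- c(
    pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 2, 1.5, 0, 0),
    "END")
  s <- parse_pdb_text(lines)[[1]]
  expect_equal(geometric_center(s, 1), c(0.75, 0, 0), ignore_attr = TRUE)
  # symmetric neighbours cancel
  lines3 <- c(
    pdb_atom_line(1, "CB", "ALA", "A", 1, -1.4, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 2, 0, 0, 0),
    pdb_atom_line(3, "CB", "ALA", "A", 3, 1.4, 0, 0),
    "END")
  s3 <- parse_pdb_text(lines3)[[1]]
  expect_equal(geometric_center(s3, 2), c(0, 0, 0), ignore_attr = TRUE)
  # isolated atom has no center
  iso <- parse_pdb_text(c(pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
                          "END"))[[1]]
  expect_error(geometric_center(iso, 1), "no covalent neighbour")
  # carbonyl O center in the helix: mean of O and its C neighbour
  h <- .ensure_helix(6)
  o1 <- which(h$atoms$name == "O" & h$atoms$res_index == 1)
  c1 <- which(h$atoms$name == "C" & h$atoms$res_index == 1)
  hand <- colMeans(as.matrix(h$atoms[c(o1, c1), c("x", "y", "z")]))
  expect_equal(geometric_center(h, o1), hand, tolerance = 1e-12)
})

test_that("donor angle is 180 for linear and 90 for perpendicular acceptors", {
  lines <- c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.45, 0, 0),
    pdb_atom_line(3, "O",  "GLY", "A", 5, -3, 0, 0),
    pdb_atom_line(4, "O",  "GLY", "A", 9, 0, 3, 0),
    "END")
  s <- parse_pdb_text(lines)[[1]]
  expect_equal(hbond_angle(s, 1, 3), 180)
  expect_equal(hbond_angle(s, 1, 4), 90)
})

test_that("helix backbone donors point at their i-4 acceptors", {
  h <- make_ideal_helix(10)
  s <- .ensure_helix_obj(h)
  for (k in seq_len(nrow(h$hbond_pairs))) {
    a <- hbond_angle(s, h$hbond_pairs$donor[k], h$hbond_pairs$acceptor[k])
    expect_gte(a, 140)
    expect_lte(a, 180)
  }
})

test_that("hydrogen-bond scoring saturates at ideal geometry, zero at bounds", {
  # donor N (with CA neighbour) and backbone O acceptor, collinear
  mk <- function(d) c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.45, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 9, -d - 1.43, -1.23, 0),
    pdb_atom_line(4, "C",  "GLY", "A", 9, -d - 1.23, 0, 0),
    pdb_atom_line(5, "O",  "GLY", "A", 9, -d, 0, 0),
    "END")
  s <- parse_pdb_text(mk(2.6))[[1]]
  hb <- detect_hbonds(s)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$alpha, 180, tolerance = 1e-3)
  expect_equal(hb$score, 1, tolerance = 1e-6)
  # boundary distance scores zero
  s35 <- parse_pdb_text(mk(3.5))[[1]]
  hb35 <- detect_hbonds(s35)
  expect_equal(nrow(hb35), 1)
  expect_equal(hb35$score, 0, tolerance = 1e-9)
  # beyond the ceiling: nothing
  expect_equal(nrow(detect_hbonds(parse_pdb_text(mk(3.6))[[1]])), 0)
})

test_that("ideal helices recover the i -> i+4 hydrogen-bond ladder", {
  for (n in c(5, 10, 20)) {
    h <- make_ideal_helix(n)
    hb <- detect_hbonds(h$structure)
    expect_gte(nrow(hb), h$expected_hbonds)
    found <- paste(hb$donor, hb$acceptor)
    want <- paste(h$hbond_pairs$donor, h$hbond_pairs$acceptor)
    expect_true(all(want %in% found))
    # score monotone structure: all scores in (0, 1]
    expect_true(all(hb$score > 0 & hb$score <= 1))
  }
})

test_that("hydrogen-bond detection ignores explicit hydrogens", {
  h <- make_ideal_helix(8)
  s <- .ensure_helix_obj(h)
  hb0 <- detect_hbonds(s)
  # add an amide hydrogen on every backbone N, 1.0 A opposite the center
  lines <- write_pdb(s)
  extra <- character(0)
  for (i in which(s$atoms$name == "N")) {
    ctr <- geometric_center(s, i)
    pos <- as.numeric(s$atoms[i, c("x", "y", "z")])
    dir <- pos - ctr
    hpos <- pos + dir / sqrt(sum(dir^2))
    extra <- c(extra, pdb_atom_line(900 + i, "H", "ALA", "A",
                                    s$atoms$res_index[i],
                                    hpos[1], hpos[2], hpos[3],
                                    element = "H"))
  }
  sh <- parse_pdb_text(c(setdiff(lines, "END"), extra, "END"))[[1]]
  expect_equal(sum(sh$atoms$element == "H"), 8)
  hb1 <- detect_hbonds(sh)
  expect_equal(nrow(hb1), nrow(hb0))
  expect_equal(sort(hb1$score), sort(hb0$score), tolerance = 1e-9)
})

test_that("distances, angles and hydrogen bonds are rigid-motion invariant", {
  h <- make_ideal_helix(10)$structure
  ht <- rigid_transform(h)
  p0 <- neighbor_pairs(h, 6.8)
  p1 <- neighbor_pairs(ht, 6.8)
  expect_equal(p0[, c("i", "j", "bonded_path")], p1[, c("i", "j", "bonded_path")])
  expect_equal(p0$d, p1$d, tolerance = 1e-6)
  hb0 <- detect_hbonds(h)
  hb1 <- detect_hbonds(ht)
  expect_equal(hb0[, c("donor", "acceptor")], hb1[, c("donor", "acceptor")])
  expect_equal(hb0$score, hb1$score, tolerance = 1e-6)
})
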