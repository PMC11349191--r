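# Donor/acceptor roles, hydrogen placement, geometric hydrogen-bond
# detection and the per-water valence cap.

test_that("roles follow residue chemistry", {
  s <- mini_structure(
    list("N", "N", "ALA", 1, "A", 0, 0, 0),
    list("O", "O", "ALA", 1, "A", 2, 0, 0),
    list("OG", "O", "SER", 2, "A", 4, 0, 0),
    list("OD1", "O", "ASP", 3, "A", 6, 0, 0),
    list("NZ", "N", "LYS", 4, "A", 8, 0, 0),
    list("SD", "S", "MET", 5, "A", 10, 0, 0),
    list("CA", "C", "ALA", 1, "A", 1, 0, 0),
    list("O", "O", "HOH", 101, "W", 12, 0, 0))
  r <- assign_roles(s)
  expect_equal(r, c("donor", "acceptor", "both", "acceptor", "donor",
                    "acceptor", "none", "both"))
})

test_that("unknown residues get conservative 'both' with a warning", {
  s <- mini_structure(list("O1", "O", "XYZ", 1, "A", 0, 0, 0))
  expect_warning(r <- assign_roles(s), "XYZ")
  expect_equal(r, "both")
})

test_that("proline backbone N is not a donor", {
  s <- mini_structure(list("N", "N", "PRO", 1, "A", 0, 0, 0))
  expect_equal(assign_roles(s), "none")
})

test_that("bare waters get two hydrogens at canonical internal geometry", {
  s <- mini_structure(list("O", "O", "HOH", 101, "W", 1, 2, 3))
  s2 <- place_missing_hydrogens(s)
  expect_equal(nrow(s2$atoms), 3)
  xyz <- frame_coords(s2, 1)
  o <- which(s2$atoms$element == "O")
  hs <- which(s2$atoms$is_hydrogen)
  d <- sqrt(rowSums(sweep(xyz[hs, ], 2, xyz[o, ])^2))
  expect_equal(d, c(0.96, 0.96), tolerance = 1e-9)
  ang <- aquabridge:::angle_deg(xyz[hs[1], ], xyz[o, ], xyz[hs[2], ])
  expect_equal(ang, 104.5, tolerance = 0.1)
})

test_that("hydrogen placement is idempotent and targets the nearest acceptor", {
  s <- do.call(mini_structure, water_at(c(0, 0, 0), 101))
  expect_equal(nrow(place_missing_hydrogens(s)$atoms), 3)

  # bare water with one acceptor at 2.8 A: a hydrogen points at it
  s2 <- mini_structure(
    list("O", "O", "HOH", 101, "W", 0, 0, 0),
    list("O", "O", "ALA", 1, "A", 2.8 / sqrt(2), 2.8 / sqrt(2), 0))
  s3 <- place_missing_hydrogens(s2)
  xyz <- frame_coords(s3, 1)
  wo <- which(s3$atoms$is_water & s3$atoms$element == "O")
  acc <- which(!s3$atoms$is_water)
  hs <- which(s3$atoms$is_hydrogen)
  to_acc <- aquabridge:::unit_vec(xyz[acc, ] - xyz[wo, ])
  devs <- vapply(hs, function(h) {
    hv <- aquabridge:::unit_vec(xyz[h, ] - xyz[wo, ])
    acos(min(1, sum(hv * to_acc))) * 180 / pi
  }, numeric(1))
  expect_lt(min(devs), 15)
})

linear_pair <- function(acceptor_x) mini_structure(
  list("OG", "O", "SER", 1, "A", 0, 0, 0),
  list("HG", "H", "SER", 1, "A", 1.0, 0, 0),
  list("O", "O", "HOH", 101, "W", acceptor_x, 0, 0))

test_that("detect_hbond accepts ideal linear geometry and rejects violations", {
  cr <- wb_criteria(distDA = 3.5, anglePDWA = c(100, 180))
  s <- linear_pair(2.8)
  hb <- detect_hbond(s, 1, 3, 1, cr)
  expect_equal(hb$distance, 2.8)
  expect_equal(hb$angle, 180)
  expect_equal(hb$kind, "protein-water")

  expect_null(detect_hbond(linear_pair(4.0), 1, 3, 1, cr))  # 4.0 > 3.5

  bent <- mini_structure(
    list("OG", "O", "SER", 1, "A", 0, 0, 0),
    list("HG", "H", "SER", 1, "A", 0, 1, 0),
    list("O", "O", "HOH", 101, "W", 2.8, 0, 0))
  # angle at H between H->OG and H->O(wat): about 70.3 degrees
  expect_null(detect_hbond(bent, 1, 3, 1, cr))
  hb2 <- detect_hbond(bent, 1, 3, 1, wb_criteria(anglePDWA = c(60, 180)))
  expect_equal(hb2$angle, 70.3, tolerance = 0.1)
})

test_that("same-residue pairs are never bonds", {
  s <- mini_structure(
    list("N", "N", "SER", 1, "A", 0, 0, 0),
    list("H", "H", "SER", 1, "A", 1, 0, 0),
    list("OG", "O", "SER", 1, "A", 2.8, 0, 0))
  expect_null(detect_hbond(s, 1, 3, 1, wb_criteria()))
})

test_that("angle-free mode accepts a superset of with-hydrogens mode", {
  set.seed(19)
  cr_h <- wb_criteria(angle_mode = "with-hydrogens")
  cr_f <- wb_criteria(angle_mode = "angle-free")
  n_h <- 0; n_f <- 0
  for (i in 1:1000) {
    acc <- runif(3, -4, 4)
    hdir <- aquabridge:::unit_vec(runif(3, -1, 1))
    s <- mini_structure(
      list("N", "N", "GLN", 1, "A", 0, 0, 0),
      list("H", "H", "GLN", 1, "A", hdir[1], hdir[2], hdir[3]),
      list("O", "O", "HOH", 101, "W", acc[1], acc[2], acc[3]))
    a_h <- !is.null(detect_hbond(s, 1, 3, 1, cr_h))
    a_f <- !is.null(detect_hbond(s, 1, 3, 1, cr_f))
    if (a_h) expect_true(a_f)
    n_h <- n_h + a_h; n_f <- n_f + a_f
  }
  expect_gt(n_f, n_h)   # strict superset over the random ensemble
})

test_that("rotatable donors without hydrogens fall back to distance-only", {
  s <- mini_structure(
    list("OG", "O", "SER", 1, "A", 0, 0, 0),
    list("O", "O", "HOH", 101, "W", 2.8, 0, 0))
  hb <- detect_hbond(s, 1, 2, 1, wb_criteria(angle_mode = "with-hydrogens"))
  expect_false(is.null(hb))
  expect_true(is.na(hb$angle))
})

test_that("a water donates to at most two acceptors (nearest kept)", {
  # one water surrounded by 5 acceptors at staggered distances
  accs <- lapply(1:5, function(i) {
    ang <- 2 * pi * i / 5
    d <- 2.7 + 0.1 * i
    list("OD1", "O", "ASP", i, "A", d * cos(ang), d * sin(ang), 0)
  })
  s <- do.call(mini_structure, c(accs, list(
    list("O", "O", "HOH", 101, "W", 0, 0, 0))))
  g <- hbond_graph(s, 1, wb_criteria(angle_mode = "angle-free"))
  wo <- select_atoms(s, "water-oxygen")
  donated <- sum(g$edges$donor == wo)
  expect_equal(donated, 2)
  # kept bonds are the two shortest
  expect_equal(sort(g$edges$distance[g$edges$donor == wo]),
               c(2.8, 2.9), tolerance = 1e-9)
})

test_that("valence cap holds on random dense water boxes", {
  cr <- wb_criteria(angle_mode = "angle-free")
  for (seed in 1:20) {
    set.seed(seed)
    n <- 25
    pos <- matrix(runif(3 * n, 0, 8), ncol = 3)
    s <- do.call(mini_structure, lapply(seq_len(n), function(i)
      list("O", "O", "HOH", 100 + i, "W", pos[i, 1], pos[i, 2], pos[i, 3])))
    g <- hbond_graph(s, 1, cr)
    if (!nrow(g$edges)) next
    expect_lte(max(table(g$edges$donor)), 2)
    expect_lte(max(table(g$edges$acceptor)), 2)
  }
})

test_that("cell-list neighbor search matches the all-pairs oracle", {
  for (seed in c(1, 7, 23)) {
    set.seed(seed)
    n <- 50 + 50 * (seed == 23)
    xyz <- matrix(runif(3 * n, 0, 12), ncol = 3)
    got <- aquabridge:::neighbor_pairs(xyz, 3.5)
    ref <- brute_pairs(xyz, 3.5)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(as.matrix(got[, c("i", "j")]), ref,
                 ignore_attr = TRUE)
  }
})

test_that("enlarging distDA or angle ranges never removes accepted bonds", {
  set.seed(31)
  pos <- matrix(runif(3 * 12, 0, 7), ncol = 3)
  s <- do.call(mini_structure, c(
    lapply(1:4, function(i)
      list("OG", "O", "SER", i, "A", pos[i, 1], pos[i, 2], pos[i, 3])),
    unlist(lapply(5:12, function(i) water_at(pos[i, ], 100 + i)),
           recursive = FALSE)))
  base <- hbond_graph(s, 1, wb_criteria(distDA = 3.0, angleWW = c(150, 180)))
  wide <- hbond_graph(s, 1, wb_criteria(distDA = 3.5, angleWW = c(120, 180),
                                        max_donated_per_water = 99,
                                        max_accepted_per_water = 99))
  key <- function(g) paste(g$edges$donor, g$edges$acceptor)
  # pre-pruning monotonicity: compare the loose graph against base edges
  expect_true(all(key(base) %in% key(wide)))
})
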