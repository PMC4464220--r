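hexagon_residue <- function(center = c(0, 0, 0), R = diag(3), noise_z = NULL) {
  ang <- c(-60, 0, 60, 120, 180, 240) * pi / 180
  local <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  if (!is.null(noise_z)) local[, 3] <- local[, 3] + noise_z
  world <- sweep(local %*% t(R), 2, center, `+`)
  data.frame(name = c("N1", "C2", "N3", "C4", "C5", "C6"),
             x = world[, 1], y = world[, 2], z = world[, 3])
}

test_that("build_frame recovers the frame of a constructed hexagon", {
  fr <- build_frame(hexagon_residue())
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fr$axes["x", ], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(sum(fr$axes["z", ] * c(0, 0, 1))), 1, tolerance = 1e-12)
  # orthonormal, right-handed
  expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
})

test_that("build_frame is equivariant under rigid motion", {
  f0 <- build_frame(hexagon_residue())
  for (s in 1:4) {
    R <- random_rotation(100 + s)
    t <- c(3, -2, 7) + s
    fr <- build_frame(hexagon_residue(center = R %*% c(0, 0, 0) + t, R = R))
    expect_equal(fr$origin, as.vector(t), tolerance = 1e-9)
    expect_equal(fr$axes, f0$axes %*% t(R), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("plane normal is robust to out-of-plane noise (within 5 deg)", {
  set.seed(42)
  for (rep in 1:10) {
    noise <- runif(6, -0.05, 0.05)
    fr <- build_frame(hexagon_residue(noise_z = noise))
    angle <- acos(min(1, abs(sum(fr$axes["z", ] * c(0, 0, 1))))) * 180 / pi
    expect_lt(angle, 5)
  }
})

test_that("build_frame reports missing atoms and degenerate rings", {
  r <- hexagon_residue()
  expect_error(build_frame(r[-2, ], resid = 17), "residue 17.*C2")
  collinear <- data.frame(name = c("N1", "C2", "N3", "C4", "C5", "C6"),
                          x = 1:6, y = 0, z = 0)
  expect_error(build_frame(collinear), "degenerate")
})

test_that("relative_position expresses centre k in frame j", {
  fj <- make_frame(c(0, 0, 0), diag(3))
  fk <- make_frame(c(3, 0, 0), diag(3))
  expect_equal(relative_position(fj, fk), c(3, 0, 0))
  expect_equal(relative_position(fj, fj), c(0, 0, 0))
  # |r_jk| == |r_kj| for arbitrary frames
  for (s in 1:5) {
    fa <- make_frame(rnorm(3), random_rotation(s))
    fb <- make_frame(rnorm(3), random_rotation(s + 50))
    expect_equal(sqrt(sum(relative_position(fa, fb)^2)),
                 sqrt(sum(relative_position(fb, fa)^2)), tolerance = 1e-9)
  }
})

test_that("ellipsoidal_distance matches the anisotropic form", {
  expect_equal(ellipsoidal_distance(c(0, 0, 0)), 0)
  expect_equal(ellipsoidal_distance(c(5, 0, 0)), 1)
  expect_equal(ellipsoidal_distance(c(0, 0, 3)), 1)
  expect_equal(ellipsoidal_distance(c(5, 0, 3)), 2)
  expect_equal(ellipsoidal_distance(c(1, 2, 3), c(1, 2, 3)), 3)
})

test_that("wc_score matches the closed-form trivariate normal product", {
  mu <- c(5.5, 0, 0)
  m <- wc_model(mu, diag(3))
  # r_jk = r_kj = mu + (1,0,0): density (2 pi)^(-3/2) e^(-1/2), squared
  expect_equal(wc_score(mu + c(1, 0, 0), mu + c(1, 0, 0), m),
               (2 * pi)^-3 * exp(-1), tolerance = 1e-12)
  # global maximum at the mean, symmetric under swap
  expect_equal(wc_score(mu, mu, m), (2 * pi)^-3)
  expect_gt(wc_score(mu, mu, m), wc_score(mu + 0.5, mu, m))
  expect_identical(wc_score(mu + c(1, 0, 0), mu + c(0, 1, 0), m),
                   wc_score(mu + c(0, 1, 0), mu + c(1, 0, 0), m))
  # monotone decay along a ray with isotropic sigma
  d <- vapply(seq(0, 4, 0.5), function(s) wc_score(mu + s, mu + s, m), 0)
  expect_true(all(diff(d) < 0))
  # anisotropic covariance is used as a full trivariate model
  sig <- matrix(c(1, 0.5, 0, 0.5, 1, 0, 0, 0, 1), 3)
  ma <- wc_model(mu, sig)
  q <- c(1, -1, 0)
  expect_equal(wc_score(mu + q, mu, ma),
               exp(-0.5 * drop(q %*% solve(sig, q))) /
                 ((2 * pi)^3 * det(sig)), tolerance = 1e-12)
  expect_error(wc_model(mu, matrix(0, 3, 3)), "positive definite|not")
})

test_that("classify_pair follows the stated precedence (hand-derived cases)", {
  # coaxial stack: r_jk = r_kj = (0, 0, 3.4)
  fj <- make_frame(c(0, 0, 0), diag(3))
  fk <- make_frame(c(0, 0, 3.4),
                   matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, byrow = TRUE))
  expect_equal(relative_position(fj, fk), c(0, 0, 3.4))
  expect_equal(relative_position(fk, fj), c(0, 0, 3.4))
  expect_identical(classify_pair(fj, fk, "A", "A")$category, "STACKING")

  # in-plane G-A pair: r_jk = (4, 0, 0.5), r_kj = (4, 0, -0.5)
  fk2 <- make_frame(c(4, 0, 0.5), rot_z(180))
  expect_equal(relative_position(make_frame(c(0, 0, 0), diag(3)), fk2),
               c(4, 0, 0.5))
  expect_equal(relative_position(fk2, make_frame(c(0, 0, 0), diag(3))),
               c(4, 0, -0.5))
  expect_identical(classify_pair(fj, fk2, "G", "A")$category, "NONCANONICAL")

  # G-C at the model mean -> WC (score maximal)
  wm <- default_wc_model()
  fk3 <- make_frame(wm$mu, rot_z(180))
  expect_identical(classify_pair(fj, fk3, "G", "C")$category, "WC")
  # same geometry, non-WC-able sequence -> falls through to NONCANONICAL
  expect_identical(classify_pair(fj, fk3, "G", "G")$category, "NONCANONICAL")

  # literal stacking-z flag makes a coaxial stack undetectable
  lit <- annotation_criteria(literal_stack_z = TRUE)
  expect_identical(classify_pair(fj, fk, "A", "A", lit)$category, "NONE")
})

test_that("classification is symmetric and rigid-motion invariant", {
  kinds <- c("wc_pair", "noncanonical_pair", "stack", "none")
  for (s in seq_along(kinds)) {
    g <- build_geometry(geometry_recipe(kinds[s], jitter = 0.1), seed = s)
    mf <- model_frames(g)
    c0 <- classify_pair(mf$frames[[1]], mf$frames[[2]], mf$bases[1],
                        mf$bases[2])$category
    swapped <- classify_pair(mf$frames[[2]], mf$frames[[1]], mf$bases[2],
                             mf$bases[1])$category
    expect_identical(swapped, c0)
    moved <- transform_model(g, random_rotation(300 + s), c(-5, 9, 2))
    expect_identical(classify_model(moved), c0)
  }
})

test_that("pair and stack z-windows are mutually exclusive", {
  # any |z| is either < 2 (pair-like) or >= 2 (stack-like), never both
  crit <- annotation_criteria()
  expect_identical(crit$z_pair_max, crit$z_stack_min)
  fj <- make_frame(c(0, 0, 0), diag(3))
  for (z in c(0.5, 1.9, 2.0, 2.1, 3.4)) {
    fk <- make_frame(c(1, 0, z),
                     matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, byrow = TRUE))
    cat_ <- classify_pair(fj, fk, "A", "A", crit)$category
    expect_identical(cat_, if (z < 2) "NONCANONICAL" else "STACKING")
  }
})

test_that("calibrate_wc_model estimates mean and covariance", {
  # identical examples -> mu = r0, sigma = eps I
  r0 <- c(5.5, 0.2, -0.1)
  m <- calibrate_wc_model(matrix(rep(r0, 10), ncol = 3, byrow = TRUE))
  expect_equal(m$mu, r0)
  expect_equal(m$sigma, diag(1e-6, 3))
  expect_error(calibrate_wc_model(matrix(rep(r0, 3), ncol = 3, byrow = TRUE)),
               "at least 4")

  # Monte-Carlo recovery from a known trivariate normal
  mu0 <- c(5.4, 0.1, 0)
  sd0 <- c(0.15, 0.3, 0.2)
  set.seed(99)
  draws <- sweep(sweep(matrix(rnorm(30000), ncol = 3), 2, sd0, `*`), 2, mu0, `+`)
  cal <- calibrate_wc_model(draws)
  se <- sd0 / sqrt(nrow(draws))
  expect_true(all(abs(cal$mu - mu0) < 3 * se))
  expect_equal(sqrt(diag(cal$sigma)), sd0, tolerance = 0.05)

  # held-out draws from the same distribution score above threshold
  held <- sweep(sweep(matrix(rnorm(3000), ncol = 3), 2, sd0, `*`), 2, mu0, `+`)
  sc <- vapply(seq_len(nrow(held)), function(i) {
    wc_score(held[i, ], held[i, ], cal)
  }, 0)
  expect_gte(mean(sc > cal$threshold), 0.99)
})

test_that("annotate_frame partitions inter/intra contacts with ground truth", {
  kc <- build_geometry(geometry_recipe("kissing_complex"), seed = 1)
  tr <- attr(kc, "truth")
  res <- annotate_frame(kc, tr$loopA, tr$loopB)
  expect_identical(res$counts$wc_inter, tr$wc_inter)
  expect_identical(res$counts$stack_intra, tr$stack_intra)
  wc <- res$pairs[res$pairs$category == "WC" & res$pairs$inter, ]
  expect_setequal(paste(wc$res_j, wc$res_k), c("25 49", "26 48"))

  # separated loops: no inter-loop contacts of any kind
  far <- build_geometry(geometry_recipe("undocking_series",
                                        separations = 50), seed = 1)[[1]]
  cf <- annotate_frame(far, tr$loopA, tr$loopB)$counts
  expect_identical(cf$wc_inter + cf$noncanonical_inter + cf$stack_inter, 0L)
  expect_identical(cf$stack_intra, tr$stack_intra)

  # A-form 7-mer as a single loop: 6 sequential intra stacks
  strand <- build_geometry(geometry_recipe("aform_strand", n = 7), seed = 1)
  cs <- annotate_frame(strand, loop_definition("S", 1, 7),
                       loop_definition("X", 90, 91))$counts
  expect_identical(cs$stack_intra, 6L)
  expect_identical(cs$stack_inter + cs$wc_inter + cs$noncanonical_inter, 0L)
})

test_that("every WC pair also satisfies the pairing geometric envelope", {
  kc <- build_geometry(geometry_recipe("kissing_complex", jitter = 0.1),
                       seed = 2)
  tr <- attr(kc, "truth")
  p <- annotate_frame(kc, tr$loopA, tr$loopB)$pairs
  wc <- p[p$category == "WC", ]
  expect_gt(nrow(wc), 0)
  for (i in seq_len(nrow(wc))) {
    expect_lt(ellipsoidal_distance(unlist(wc[i, c("x_jk", "y_jk", "z_jk")])), 2.5)
    expect_lt(abs(wc$z_jk[i]), 2)
    expect_lt(abs(wc$z_kj[i]), 2)
  }
})

test_that("annotate_trajectory averages per frame and per group", {
  kc <- build_geometry(geometry_recipe("kissing_complex"), seed = 1)
  tr <- attr(kc, "truth")
  res <- annotate_trajectory(list(kc, kc, kc), tr$loopA, tr$loopB)
  expect_identical(nrow(res$per_frame), 3L)
  expect_equal(res$averages$wc_inter, 2)

  # mean over frames with wc_inter = 2, 2, 0, 0 -> 1.0
  far <- build_geometry(geometry_recipe("undocking_series",
                                        separations = 50), seed = 1)[[1]]
  res4 <- annotate_trajectory(list(kc, kc, far, far), tr$loopA, tr$loopB)
  expect_equal(res4$averages$wc_inter, 1.0)
  resg <- annotate_trajectory(list(kc, kc, far, far), tr$loopA, tr$loopB,
                              groups = c("a", "a", "b", "b"))
  expect_equal(resg$averages$wc_inter[resg$averages$group == "a"], 2)
  expect_equal(resg$averages$wc_inter[resg$averages$group == "b"], 0)
})

test_that("inter-loop WC contacts decay along an undocking series", {
  seps <- c(12.5, 16, 20, 26, 34)
  models <- build_geometry(geometry_recipe("undocking_series",
                                           separations = seps), seed = 1)
  tr <- attr(models, "truth")
  wc <- vapply(models, function(m) {
    annotate_frame(m, tr$loopA, tr$loopB)$counts$wc_inter
  }, 0L)
  expect_true(all(diff(wc) <= 0))
  expect_identical(wc[length(wc)], 0L)
})
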