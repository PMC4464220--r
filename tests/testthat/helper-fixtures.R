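# Shared fixtures and small oracles, all built in code at test time.

# frames + base letters of every nucleotide residue of a model
model_frames <- function(model) {
  resids <- unique(model$atoms$resid[model$atoms$nucleotide])
  frames <- lapply(resids, function(r) {
    build_frame(model$atoms[model$atoms$resid == r, ], r)
  })
  bases <- vapply(resids, function(r) {
    model$atoms$resname[model$atoms$resid == r][1]
  }, "")
  list(resids = resids, frames = frames, bases = bases)
}

# classify a 2-residue model built by a pair recipe
classify_model <- function(model, criteria = annotation_criteria()) {
  mf <- model_frames(model)
  classify_pair(mf$frames[[1]], mf$frames[[2]], mf$bases[1], mf$bases[2],
                criteria)$category
}

# a uniformly random proper rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply x -> R x + t to all atoms of a model
transform_model <- function(model, R, t) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]
  a$y <- xyz[, 2] + t[2]
  a$z <- xyz[, 3] + t[3]
  structure_model(a, model$model_id)
}

# a BaseFrame from explicit origin/axes (rows x, y, z)
make_frame <- function(origin, axes) {
  structure(list(origin = origin, axes = axes), class = "BaseFrame")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# hand-written two-residue PDB content (valid fixed-width records)
pdb_fixture_lines <- function() {
  atom <- function(serial, name, resname, resid, x, y, z) {
    nm <- if (nchar(name) < 4) paste0(" ", name) else name
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, nm, resname, resid, x, y, z, substr(name, 1, 1))
  }
  res <- function(resid, resname, x0) {
    ang <- c(-60, 0, 60, 120, 180, 240) * pi / 180
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    c(vapply(1:6, function(i) {
      atom((resid - 1) * 7 + i, nm[i], resname, resid,
           x0 + 1.4 * cos(ang[i]), 1.4 * sin(ang[i]), 0)
    }, ""),
    atom((resid - 1) * 7 + 7, "C4'", resname, resid, x0 - 4, 0.5, 0.3))
  }
  list(model1 = c(res(1, "G", 0), res(2, "C", 8)),
       model2 = c(res(1, "G", 0.5), res(2, "C", 8.5)))
}

# a small umbrella campaign on the default double-well PMF
small_campaign <- function(n = 1000, seed = 1, direction = "forward",
                           shift = 0, pmf = analytic_pmf("double_well"),
                           n_windows = 44, keep_last = 4000) {
  ws <- make_windows(12.5, 34, n_windows, 20, direction = direction)
  ser <- sample_campaign(pmf, ws,
                         sampler_settings(seed = seed, n_per_window = n),
                         hysteresis_shift = shift)
  lapply(ser, discard_equilibration, keep_last = keep_last)
}

# analytic ground-truth undocking delta G of a pmf (fine-grid evaluation)
true_delta_g <- function(pmf, L_ref = 34) {
  grid <- seq(pmf$domain[1], pmf$domain[2], by = 0.001)
  eval_pmf(pmf, L_ref) - min(eval_pmf(pmf, grid))
}

# the labelled jitter-free oracle suite: >= 100 recipes spanning the four
# categories, every case >= 0.3 Angstrom from each decision surface
oracle_suite <- function() {
  cases <- list()
  add <- function(recipe) cases[[length(cases) + 1]] <<- recipe
  # WC: nominal geometry, sequence variants, small separation sweep
  # (Gaussian-score boundary lies beyond ~ +/-0.4 A from the 5.5 A nominal)
  for (sep in c(5.4, 5.45, 5.5, 5.55, 5.6)) {
    for (sq in list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"))) {
      add(geometry_recipe("wc_pair", sequence = sq, separation = sep))
    }
  }
  # stacking: in-plane offsets rho^2 <= 2, rise 2.5-4.0 A
  for (x in c(-1, 0, 1)) for (y in c(-1, 0, 1)) {
    for (z in c(2.5, 3.0, 3.4, 4.0)) {
      if (z == 2.5 && x == 0 && y == 0) next  # keep the count at >= 100 anyway
      add(geometry_recipe("stack", offset = c(x, y, z), twist_deg = 30))
    }
  }
  # non-canonical: in-plane pairs, |z| <= 1.2, non-WC sequence
  for (x in c(3.5, 4, 4.5)) for (y in c(-0.8, 0, 0.8)) {
    for (z in c(-1.2, -0.5, 0, 0.5, 1.2)) {
      add(geometry_recipe("noncanonical_pair", offset = c(x, y, z),
                          twist_deg = 40))
    }
  }
  # none: far in-plane, far along the normal, and rho^2 >> 5 at stack rise
  for (x in c(9, 10, 12)) add(geometry_recipe("none", offset = c(x, 0, 0)))
  for (z in c(6, 7, 8)) add(geometry_recipe("none", offset = c(0, 0, z)))
  for (x in c(7, 8)) add(geometry_recipe("none", offset = c(x, 0, 3.4)))
  cases
}
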