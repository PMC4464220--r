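## synthetic_data: analytic PMFs, equilibrium biased samplers (grid inverse
## CDF, optional AR(1) Gaussian copula), planted-hysteresis campaigns, and
## idealized labelled base geometries.

#' Construct an analytic ground-truth PMF
#'
#' A 1-D free-energy function G(L) with known shape, used by the synthetic
#' sampler and for parameter-recovery tests. Forms:
#' \describe{
#'   \item{harmonic}{G = kappa/2 (L - min_at)^2; params `min_at` (default
#'     12.5), `kappa` (default 0.5 (kcal/mol)/A^2).}
#'   \item{double_well}{two Gaussian wells plus a Gaussian barrier; params
#'     `wells` (centres, default c(15, 34)), `depths` (default c(9, 1),
#'     i.e. a well-depth difference of 8 kcal/mol), `widths` (default
#'     c(1.2, 1.2)), `barrier_height` (2), `barrier_at` (24),
#'     `barrier_width` (2).}
#'   \item{well_barrier}{one well and one barrier; params `well_at` (15),
#'     `depth` (6), `well_width` (1.5), `barrier_at` (20),
#'     `barrier_height` (3), `barrier_width` (1.5).}
#'   \item{tabulated}{natural-spline interpolation through nodes `L`, `G`
#'     (exact at the nodes).}
#' }
#'
#' @param form one of `"harmonic"`, `"double_well"`, `"well_barrier"`,
#'   `"tabulated"`.
#' @param domain evaluable interval (L_lo, L_hi), Angstrom.
#' @param ... form parameters, see above.
#' @return object of class `AnalyticPmf` with fields `form`, `domain`,
#'   `params`, `fn`.
#' @export
analytic_pmf <- function(form = c("harmonic", "double_well", "well_barrier",
                                  "tabulated"),
                         domain = c(12, 35), ...) {
  form <- match.arg(form)
  p <- list(...)
  gauss <- function(L, at, width) exp(-(L - at)^2 / (2 * width^2))
  fn <- switch(form,
    harmonic = {
      p <- utils::modifyList(list(min_at = 12.5, kappa = 0.5), p)
      function(L) 0.5 * p$kappa * (L - p$min_at)^2
    },
    double_well = {
      p <- utils::modifyList(list(wells = c(15, 34), depths = c(9, 1),
                                  widths = c(1.2, 1.2), barrier_height = 2,
                                  barrier_at = 24, barrier_width = 2), p)
      function(L) {
        -p$depths[1] * gauss(L, p$wells[1], p$widths[1]) -
          p$depths[2] * gauss(L, p$wells[2], p$widths[2]) +
          p$barrier_height * gauss(L, p$barrier_at, p$barrier_width)
      }
    },
    well_barrier = {
      p <- utils::modifyList(list(well_at = 15, depth = 6, well_width = 1.5,
                                  barrier_at = 20, barrier_height = 3,
                                  barrier_width = 1.5), p)
      function(L) {
        -p$depth * gauss(L, p$well_at, p$well_width) +
          p$barrier_height * gauss(L, p$barrier_at, p$barrier_width)
      }
    },
    tabulated = {
      if (is.null(p$L) || is.null(p$G)) stop("tabulated form needs L and G nodes")
      stats::splinefun(p$L, p$G, method = "natural")
    })
  structure(list(form = form, domain = domain, params = p, fn = fn),
            class = "AnalyticPmf")
}

#' Evaluate an analytic PMF
#'
#' @param pmf an [analytic_pmf()].
#' @param L value(s) within the PMF domain, Angstrom.
#' @return G(L), kcal/mol.
#' @export
eval_pmf <- function(pmf, L) {
  if (any(L < pmf$domain[1] - 1e-9 | L > pmf$domain[2] + 1e-9)) {
    stop(sprintf("L outside PMF domain [%.2f, %.2f]",
                 pmf$domain[1], pmf$domain[2]))
  }
  pmf$fn(L)
}

#' Raise the docked well of a PMF (planted hysteresis)
#'
#' Adds `shift` to G for L below `L_star` via a narrow logistic step; used
#' to emulate a backward protocol in which the native contacts of the
#' docked state are not reformed, so the docked basin appears shallower.
#'
#' @param pmf an [analytic_pmf()].
#' @param shift amount to raise the docked basin, kcal/mol.
#' @param L_star switch-over distance, Angstrom (between the basins).
#' @param width logistic step width, Angstrom.
#' @return a modified `AnalyticPmf`.
#' @export
raise_docked_well <- function(pmf, shift, L_star = 24, width = 0.25) {
  base_fn <- pmf$fn
  out <- pmf
  out$fn <- function(L) base_fn(L) + shift * stats::plogis((L_star - L) / width)
  out$params$hysteresis_shift <- shift
  out$params$hysteresis_L_star <- L_star
  out
}

#' Sampler settings
#'
#' @param seed base RNG seed; each window derives its own sub-seed so a
#'   campaign is reproducible regardless of evaluation order.
#' @param n_per_window samples per window (default 5000, emulating a 5 ns
#'   window sampled every picosecond).
#' @param temperature Kelvin.
#' @param ar1_phi lag-1 autocorrelation of the Gaussian copula chain in
#'   [0, 1); 0 gives independent equilibrium samples.
#' @param grid_resolution inverse-CDF grid spacing, Angstrom.
#' @param total_time_ps nominal duration represented by the series.
#' @return object of class `SamplerSettings`.
#' @export
sampler_settings <- function(seed = 1, n_per_window = 5000, temperature = 298,
                             ar1_phi = 0, grid_resolution = 0.01,
                             total_time_ps = 5000) {
  stopifnot(n_per_window >= 1, ar1_phi >= 0, ar1_phi < 1,
            grid_resolution > 0, temperature > 0)
  structure(list(seed = as.integer(seed), n_per_window = as.integer(n_per_window),
                 temperature = temperature, ar1_phi = ar1_phi,
                 grid_resolution = grid_resolution,
                 total_time_ps = total_time_ps), class = "SamplerSettings")
}

#' Draw equilibrium samples of one umbrella window
#'
#' Samples L from p(L) proportional to exp(-beta (G(L) + U(L))) by grid
#' inverse-CDF (piecewise-linear inverse of the cumulative distribution on
#' a `grid_resolution` grid). With `ar1_phi > 0` the draws come from a
#' Gaussian-copula AR(1) chain whose stationary marginal is exactly p(L),
#' so autocorrelation is added without changing the distribution.
#'
#' @param pmf an [analytic_pmf()].
#' @param window an [umbrella_window()].
#' @param settings a [sampler_settings()].
#' @param seed_offset extra offset folded into the per-window seed (used to
#'   decorrelate forward/backward campaigns).
#' @return a [cv_series()].
#' @export
sample_window <- function(pmf, window, settings = sampler_settings(),
                          seed_offset = 0) {
  if (window$center < pmf$domain[1] || window$center > pmf$domain[2]) {
    stop("window centre outside PMF domain")
  }
  kT <- .kB * settings$temperature
  h <- settings$grid_resolution
  grid <- seq(pmf$domain[1], pmf$domain[2], by = h)
  logw <- -(eval_pmf(pmf, grid) + bias_energy(grid, window)) / kT
  logw <- logw - max(logw)
  w <- exp(logw)
  if (!any(w > 0)) stop("biased density underflows everywhere; check units")
  cum <- c(0, cumsum(w))
  cum <- cum / cum[length(cum)]
  edges <- c(grid[1] - h / 2, grid + h / 2)

  n <- settings$n_per_window
  seed <- (settings$seed + 100003 * window$index + seed_offset) %% 2147483647
  u <- .with_seed(seed, function() {
    if (settings$ar1_phi == 0) return(stats::runif(n))
    phi <- settings$ar1_phi
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    eps <- stats::rnorm(n - 1) * sqrt(1 - phi^2)
    for (t in 2:n) z[t] <- phi * z[t - 1] + eps[t - 1]
    stats::pnorm(z)
  })
  x <- stats::approx(cum, edges, xout = u, ties = "ordered", rule = 2)$y
  dt <- settings$total_time_ps / n
  cv_series(window, dt * seq_len(n), x)
}

#' Sample a whole umbrella campaign
#'
#' One [cv_series()] per window, in iteration order. For a backward window
#' set with `hysteresis_shift > 0`, samples are drawn from the PMF with its
#' docked basin raised by `hysteresis_shift` (see [raise_docked_well()]),
#' planting a known forward/backward asymmetry; the forward direction uses
#' the PMF unchanged. Backward campaigns also use an independent seed
#' stream.
#'
#' @param pmf an [analytic_pmf()].
#' @param windows a [make_windows()] result.
#' @param settings a [sampler_settings()].
#' @param hysteresis_shift kcal/mol (default 0: converged sampling).
#' @param shift_below L_star passed to [raise_docked_well()].
#' @return list of [cv_series()].
#' @export
sample_campaign <- function(pmf, windows, settings = sampler_settings(),
                            hysteresis_shift = 0, shift_below = 24) {
  backward <- identical(windows$direction, "backward")
  eff <- if (backward && hysteresis_shift > 0) {
    raise_docked_well(pmf, hysteresis_shift, shift_below)
  } else pmf
  offset <- if (backward) 555007 else 0
  lapply(seq_len(nrow(windows$windows)), function(i) {
    sample_window(eff, .window_i(windows, i), settings, seed_offset = offset)
  })
}

## ---------------------------------------------------------------------------
## labelled base geometries

#' A recipe for a labelled synthetic base geometry
#'
#' Kinds and their ground-truth labels:
#' \describe{
#'   \item{wc_pair}{two coplanar rings, x axes antialigned, centres
#'     `separation` (default 5.5 A) apart -> `WC` (sequence default G, C).}
#'   \item{noncanonical_pair}{in-plane pair at `offset` (default
#'     c(4, 0.8, 0.5)) with `twist_deg` about z -> `NONCANONICAL`
#'     (sequence default G, A).}
#'   \item{stack}{parallel rings at `offset` (default c(0.7, 0.7, 3.4)) ->
#'     `STACKING`.}
#'   \item{none}{rings at `offset` (default c(12, 0, 0)) -> `NONE`.}
#'   \item{aform_strand}{`n` consecutively stacked rings (rise 3.4 A);
#'     ground truth: n - 1 intra stacks.}
#'   \item{kissing_complex}{two 7-residue loops numbered 20-26 (L2) and
#'     48-54 (L3) with exactly two planted inter-loop WC pairs G25-C49 and
#'     G26-C48 and six intra-loop stacks per loop. A synthetic stand-in for
#'     a kissing-loop crystal structure.}
#'   \item{undocking_series}{kissing complex rigidly separated to each of
#'     `separations` (backbone-CoM distances, Angstrom); one model per
#'     separation.}
#' }
#'
#' @param kind recipe kind, see above.
#' @param sequence base letters where applicable.
#' @param jitter Gaussian atomic-coordinate noise sd, Angstrom.
#' @param ... placement parameters (see kinds above).
#' @return object of class `GeometryRecipe` carrying its ground-truth
#'   `label` (pair kinds).
#' @export
geometry_recipe <- function(kind = c("wc_pair", "noncanonical_pair", "stack",
                                     "none", "aform_strand", "kissing_complex",
                                     "undocking_series"),
                            sequence = NULL, jitter = 0, ...) {
  kind <- match.arg(kind)
  stopifnot(jitter >= 0)
  if (kind %in% c("wc_pair", "noncanonical_pair", "stack", "none") &&
      jitter > 0.25) {
    stop("jitter > 0.25 Angstrom can violate the planted label; use less")
  }
  defaults <- switch(kind,
    wc_pair = list(separation = 5.5, sequence = c("G", "C")),
    noncanonical_pair = list(offset = c(4, 0.8, 0.5), twist_deg = 55,
                             sequence = c("G", "A")),
    stack = list(offset = c(0.7, 0.7, 3.4), twist_deg = 36,
                 sequence = c("A", "A")),
    none = list(offset = c(12, 0, 0), twist_deg = 0, sequence = c("A", "U")),
    aform_strand = list(n = 7, rise = 3.4, twist_deg = 32.7,
                        sequence = NULL),
    kissing_complex = list(separation = 5.5, rise = 3.4, splay = 1.5),
    undocking_series = list(separations = c(12.5, 20, 34), separation = 5.5,
                            rise = 3.4, splay = 1.5))
  p <- utils::modifyList(defaults, list(...))
  if (!is.null(sequence)) p$sequence <- sequence
  label <- switch(kind, wc_pair = "WC", noncanonical_pair = "NONCANONICAL",
                  stack = "STACKING", none = "NONE", NA_character_)
  structure(list(kind = kind, params = p, jitter = jitter, label = label),
            class = "GeometryRecipe")
}

.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

## atoms of one idealized residue: hexagonal ring (radius 1.4 A, C2 on the
## local +x axis, N1->C2->N3 winding giving +z normal) plus minimal backbone.
.place_base <- function(resname, resid, origin, axes, chain = "A") {
  ang <- c(-60, 0, 60, 120, 180, 240) * pi / 180   # N1 C2 N3 C4 C5 C6
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  bb <- rbind(c(-4.8, 1.2, 0.4), c(-3.9, -0.6, 0.8), c(-4.4, -1.8, -0.3))
  local <- rbind(ring, bb)
  world <- sweep(local %*% axes, 2, origin, `+`)
  data.frame(name = c(.ring_atoms, "P", "C4'", "O3'"),
             resname = resname, resid = as.integer(resid), chain = chain,
             x = world[, 1], y = world[, 2], z = world[, 3],
             stringsAsFactors = FALSE)
}

.kissing_atoms <- function(p) {
  seq_l2 <- c("C", "A", "U", "U", "A", "G", "G")  # residues 20..26
  seq_l3 <- c("C", "C", "U", "A", "A", "U", "G")  # residues 48..54
  flip <- .rot_z(180)
  rows <- list()
  for (r in 20:26) {  # 25 at origin, stacked upward to 26, splayed below 25
    origin <- c(-p$splay * max(0, 25 - r), 0, p$rise * (r - 25))
    rows[[length(rows) + 1]] <-
      .place_base(seq_l2[r - 19], r, origin, diag(3))
  }
  for (s in 48:54) {  # 49 pairs 25; 48 pairs 26; splayed beyond 49
    origin <- c(p$separation + p$splay * max(0, s - 49), 0, p$rise * (49 - s))
    rows[[length(rows) + 1]] <-
      .place_base(seq_l3[s - 47], s, origin, flip)
  }
  do.call(rbind, rows)
}

#' Build a labelled synthetic geometry
#'
#' Deterministic given `(recipe, seed)`; the seed drives only the jitter.
#' All models are plain [structure_model()]s, so the annotation and
#' loop-distance machinery applies unchanged. Ground truth is attached as
#' attribute `"truth"`.
#'
#' @param recipe a [geometry_recipe()].
#' @param seed RNG seed for the jitter.
#' @return a `StructureModel`, or a list of them for `undocking_series`.
#' @export
build_geometry <- function(recipe, seed = 1) {
  p <- recipe$params
  jit <- function(df) {
    if (recipe$jitter == 0) return(df)
    .with_seed(seed, function() {
      df$x <- df$x + stats::rnorm(nrow(df), 0, recipe$jitter)
      df$y <- df$y + stats::rnorm(nrow(df), 0, recipe$jitter)
      df$z <- df$z + stats::rnorm(nrow(df), 0, recipe$jitter)
      df
    })
  }
  if (recipe$kind %in% c("wc_pair", "noncanonical_pair", "stack", "none")) {
    axes_k <- switch(recipe$kind,
                     wc_pair = .rot_z(180),
                     .rot_z(p$twist_deg))
    origin_k <- if (recipe$kind == "wc_pair") c(p$separation, 0, 0) else p$offset
    atoms <- rbind(.place_base(p$sequence[1], 1, c(0, 0, 0), diag(3)),
                   .place_base(p$sequence[2], 3, origin_k, axes_k))
    m <- structure_model(jit(atoms))
    attr(m, "truth") <- list(label = recipe$label,
                             residues = c(1L, 3L))
    return(m)
  }
  if (recipe$kind == "aform_strand") {
    n <- p$n
    seqs <- if (is.null(p$sequence)) rep(c("A", "U", "G", "C"), length.out = n)
            else p$sequence
    rows <- lapply(seq_len(n), function(i) {
      .place_base(seqs[i], i, c(0, 0, p$rise * (i - 1)),
                  .rot_z(p$twist_deg * (i - 1)))
    })
    m <- structure_model(jit(do.call(rbind, rows)))
    attr(m, "truth") <- list(stack_intra = n - 1L)
    return(m)
  }
  if (recipe$kind == "kissing_complex") {
    m <- structure_model(jit(.kissing_atoms(p)))
    attr(m, "truth") <- list(
      wc_inter = 2L,
      wc_pairs = list(c(25L, 49L), c(26L, 48L)),
      stack_intra = 12L,
      loopA = loop_definition("L2", 20, 26),
      loopB = loop_definition("L3", 48, 54))
    return(m)
  }
  ## undocking_series
  base <- structure_model(jit(.kissing_atoms(p)))
  la <- loop_definition("L2", 20, 26)
  lb <- loop_definition("L3", 48, 54)
  ca <- backbone_com(base, la)
  cb <- backbone_com(base, lb)
  u <- .unit(cb - ca)
  d0 <- sqrt(sum((cb - ca)^2))
  models <- lapply(seq_along(p$separations), function(i) {
    shift <- (p$separations[i] - d0) * u
    a <- base$atoms
    sel <- a$resid >= lb$from & a$resid <= lb$to
    a$x[sel] <- a$x[sel] + shift[1]
    a$y[sel] <- a$y[sel] + shift[2]
    a$z[sel] <- a$z[sel] + shift[3]
    structure_model(a, model_id = i)
  })
  attr(models, "truth") <- list(separations = p$separations,
                                loopA = la, loopB = lb)
  models
}
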