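## pmf_wham: WHAM reconstruction of G(L), four-block error estimation,
## profile alignment, delta-G extraction and hysteresis diagnostics.

#' WHAM settings
#'
#' @param bin_width histogram bin width, Angstrom (default 0.1).
#' @param L_range histogram range (min, max), Angstrom (default c(12, 34.5),
#'   bracketing the 12.5-34 window grid).
#' @param tolerance convergence tolerance on the per-window free-energy
#'   constants f_i, kcal/mol.
#' @param max_iterations iteration cap.
#' @param temperature Kelvin (default 298).
#' @return object of class `WhamSettings`.
#' @export
wham_settings <- function(bin_width = 0.1, L_range = c(12, 34.5),
                          tolerance = 1e-7, max_iterations = 100000,
                          temperature = 298) {
  stopifnot(bin_width > 0, tolerance > 0, temperature > 0,
            length(L_range) == 2, L_range[2] > L_range[1])
  structure(list(bin_width = bin_width, L_range = L_range,
                 tolerance = tolerance, max_iterations = max_iterations,
                 temperature = temperature), class = "WhamSettings")
}

.bin_edges <- function(settings) {
  nb <- ceiling((settings$L_range[2] - settings$L_range[1]) / settings$bin_width)
  settings$L_range[1] + settings$bin_width * (0:nb)
}

.pmf_profile <- function(grid, G, counts, settings, errors = NULL,
                         alignment_ref = NA_real_, f = NULL, p = NULL) {
  structure(list(grid = grid, G = G, errors = errors, counts = counts,
                 alignment_ref = alignment_ref, f = f, p = p,
                 temperature = settings$temperature,
                 bin_width = settings$bin_width), class = "PmfProfile")
}

#' @export
print.PmfProfile <- function(x, ...) {
  fin <- is.finite(x$G)
  cat(sprintf("<PmfProfile: %d bins (%.2f-%.2f A), %d populated, G range %.2f-%.2f kcal/mol>\n",
              length(x$grid), min(x$grid), max(x$grid), sum(fin),
              min(x$G[fin]), max(x$G[fin])))
  invisible(x)
}

## bin index containing L (grid/edges of a profile or settings)
.bin_of <- function(edges, L) {
  i <- findInterval(L, edges, rightmost.closed = TRUE)
  if (i < 1 || i > length(edges) - 1) {
    stop(sprintf("L = %.3f outside histogram range [%.3f, %.3f]",
                 L, edges[1], edges[length(edges)]))
  }
  i
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Self-consistent iteration of
#' p(b) = sum_i n_i(b) / sum_i N_i exp((f_i - U_i(b)) / kT),
#' f_i = -kT log sum_b p(b) exp(-U_i(b) / kT),
#' starting from f_i = 0, until max |delta f_i| < `tolerance`. The unbiased
#' probability is normalized, G(b) = -kT log p(b) is shifted so its minimum
#' is 0; unpopulated bins carry G = +Inf.
#'
#' @param series list of [cv_series()] (one per window).
#' @param settings a [wham_settings()].
#' @param convention bias convention, see [bias_energy()].
#' @return a `PmfProfile`: `grid` (bin centres), `G`, `counts`, `f`
#'   (per-window free-energy constants in input order).
#' @export
wham_solve <- function(series, settings = wham_settings(),
                       convention = "half_k") {
  stopifnot(length(series) >= 1)
  kT <- .kB * settings$temperature
  edges <- .bin_edges(settings)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)
  nw <- length(series)

  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    v <- series[[i]]$values
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= nb]
    if (!length(idx)) {
      stop("window ", series[[i]]$window$index,
           " has no samples inside the histogram range")
    }
    counts[i, ] <- tabulate(idx, nb)
  }
  N <- rowSums(counts)

  ## adjacent-window histogram overlap check (ordered by centre)
  ord <- order(vapply(series, function(s) s$window$center, 0))
  if (nw > 1) {
    for (k in seq_len(nw - 1)) {
      s1 <- range(which(counts[ord[k], ] > 0))
      s2 <- range(which(counts[ord[k + 1], ] > 0))
      if (s1[2] < s2[1] - 1 || s2[2] < s1[1] - 1) {
        stop(sprintf(
          "histogram gap between windows centred at %.3f and %.3f Angstrom",
          series[[ord[k]]]$window$center, series[[ord[k + 1]]]$window$center))
      }
    }
  }

  U <- t(vapply(series, function(s) bias_energy(centers, s$window, convention),
                numeric(nb)))
  expB <- exp(-U / kT)          # nw x nb
  num <- colSums(counts)

  f <- numeric(nw)
  delta <- Inf
  for (it in seq_len(settings$max_iterations)) {
    denom <- as.vector(crossprod(expB, N * exp(f / kT)))
    p <- num / denom
    fnew <- -kT * log(as.vector(expB %*% p))
    fnew <- fnew - fnew[1]      # gauge: f_1 = 0
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < settings$tolerance) break
  }
  if (delta >= settings$tolerance) {
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                 settings$max_iterations, delta))
  }
  p <- p / sum(p)
  G <- -kT * log(p)             # empty bins: p = 0 -> +Inf
  G <- G - min(G[is.finite(G)])
  .pmf_profile(centers, G, num, settings, f = f, p = p)
}

#' Align a profile (pin G = 0 at the bin containing L_ref)
#'
#' @param profile a `PmfProfile`.
#' @param L_ref alignment reference, Angstrom.
#' @return the shifted profile with `alignment_ref = L_ref`.
#' @export
align_profile <- function(profile, L_ref) {
  edges <- c(profile$grid - profile$bin_width / 2,
             profile$grid[length(profile$grid)] + profile$bin_width / 2)
  i <- .bin_of(edges, L_ref)
  if (!is.finite(profile$G[i])) {
    stop(sprintf("alignment bin at L = %.3f Angstrom is unpopulated", L_ref))
  }
  profile$G <- profile$G - profile$G[i]
  profile$alignment_ref <- L_ref
  profile
}

#' Align two profiles at a common reference
#'
#' Additive constants are chosen so both profiles are 0 in the bin
#' containing `L_ref`; shapes are unchanged.
#'
#' @param profile_a,profile_b `PmfProfile`s on compatible grids.
#' @param L_ref reference L, Angstrom.
#' @return list of the two aligned profiles.
#' @export
align_profiles <- function(profile_a, profile_b, L_ref) {
  list(align_profile(profile_a, L_ref), align_profile(profile_b, L_ref))
}

#' Per-block spread of aligned profiles
#'
#' Standard deviation (n-1 normalization) across block profiles divided by
#' sqrt(number of blocks), per bin; the blocking standard error. Bins where
#' any block is unpopulated get `NA`.
#'
#' @param G_matrix numeric matrix, one row per block profile.
#' @return numeric vector of per-bin errors.
#' @export
block_se <- function(G_matrix) {
  G_matrix <- as.matrix(G_matrix)
  nb <- ncol(G_matrix)
  out <- rep(NA_real_, nb)
  ok <- colSums(!is.finite(G_matrix)) == 0
  if (any(ok)) {
    out[ok] <- apply(G_matrix[, ok, drop = FALSE], 2, stats::sd) /
      sqrt(nrow(G_matrix))
  }
  out
}

## split a CvSeries into n contiguous equal-duration blocks
.split_blocks <- function(series, n_blocks) {
  t <- series$times
  b_edges <- seq(t[1] - 1e-9, t[length(t)], length.out = n_blocks + 1)
  idx <- findInterval(t, b_edges, rightmost.closed = TRUE)
  lapply(seq_len(n_blocks), function(b) {
    keep <- idx == b
    if (!any(keep)) {
      stop("window ", series$window$index, ", block ", b, " is empty")
    }
    cv_series(series$window, t[keep], series$values[keep])
  })
}

#' Blocking error estimate for a WHAM profile
#'
#' Splits every window's series into `n_blocks` contiguous equal-duration
#' blocks, solves WHAM once per block (block b of every window together),
#' aligns the block profiles at `align_at`, and reports the per-bin standard
#' deviation across blocks divided by sqrt(n_blocks).
#'
#' @param series list of [cv_series()].
#' @param settings a [wham_settings()].
#' @param n_blocks number of blocks (default 4, i.e. 1 ns blocks of a 4 ns
#'   production segment).
#' @param align_at alignment reference for the block profiles, Angstrom.
#' @param convention bias convention.
#' @return list with `errors` (per-bin), `grid`, and `block_profiles`.
#' @export
blocking_errors <- function(series, settings = wham_settings(), n_blocks = 4,
                            align_at, convention = "half_k") {
  blocks <- lapply(series, .split_blocks, n_blocks = n_blocks)
  profs <- lapply(seq_len(n_blocks), function(b) {
    align_profile(wham_solve(lapply(blocks, `[[`, b), settings, convention),
                  align_at)
  })
  Gm <- do.call(rbind, lapply(profs, `[[`, "G"))
  list(errors = block_se(Gm), grid = profs[[1]]$grid, block_profiles = profs)
}

#' Full WHAM profile with blocking errors
#'
#' Convenience wrapper: [wham_solve()] on the full data plus
#' [blocking_errors()], returning one `PmfProfile` with `errors` attached
#' (and aligned at `align_at` if given).
#'
#' @inheritParams blocking_errors
#' @param align_at optional alignment reference; `NA` leaves the profile
#'   pinned at its minimum.
#' @return a `PmfProfile` with `errors`.
#' @export
wham_profile <- function(series, settings = wham_settings(), n_blocks = 4,
                         align_at = NA, convention = "half_k") {
  prof <- wham_solve(series, settings, convention)
  be <- blocking_errors(series, settings, n_blocks,
                        align_at = if (is.na(align_at))
                          prof$grid[which.min(prof$G)] else align_at,
                        convention = convention)
  prof$errors <- be$errors
  if (!is.na(align_at)) prof <- align_profile(prof, align_at)
  prof
}

#' Extract a docking / undocking free energy from a profile
#'
#' Undocking: delta G = G(L_ref) - G(L_min) >= 0; docking: the negative.
#' The minimum is the global minimum over populated bins (ties broken toward
#' smaller L). The error combines the blocking errors of the two bins in
#' quadrature.
#'
#' @param profile a `PmfProfile`.
#' @param L_ref reference (undocked) distance, Angstrom.
#' @param mode `"undocking"` or `"docking"`.
#' @return object of class `DeltaGResult`: `delta_g`, `error`, `L_min`,
#'   `L_ref`, `min_at_edge` (warning flag).
#' @export
extract_delta_g <- function(profile, L_ref,
                            mode = c("undocking", "docking")) {
  mode <- match.arg(mode)
  fin <- which(is.finite(profile$G))
  if (!length(fin)) stop("profile has no populated bins")
  imin <- fin[which.min(profile$G[fin])]   # first minimum = smaller L
  edges <- c(profile$grid - profile$bin_width / 2,
             profile$grid[length(profile$grid)] + profile$bin_width / 2)
  iref <- .bin_of(edges, L_ref)
  if (!is.finite(profile$G[iref])) {
    stop(sprintf("reference bin at L = %.3f Angstrom is unpopulated", L_ref))
  }
  min_at_edge <- imin == fin[1] || imin == fin[length(fin)]
  dg <- profile$G[iref] - profile$G[imin]
  if (mode == "docking") dg <- -dg
  err <- if (is.null(profile$errors)) NA_real_ else
    sqrt(profile$errors[imin]^2 + profile$errors[iref]^2)
  structure(list(delta_g = dg, error = err, L_min = profile$grid[imin],
                 L_ref = profile$grid[iref], min_at_edge = min_at_edge,
                 mode = mode), class = "DeltaGResult")
}

#' Forward/backward hysteresis diagnostics
#'
#' Aligns the two profiles at `L_ref`, extracts both free energies, the
#' maximum absolute gap between the aligned profiles over the bins populated
#' in both, and reports delta-delta-G bounds (min, max of the two
#' estimates): with non-converged sampling the converged answer is expected
#' to lie between the forward and backward results.
#'
#' @param forward,backward `PmfProfile`s.
#' @param L_ref alignment/reference distance, Angstrom.
#' @param mode passed to [extract_delta_g()].
#' @return object of class `HysteresisReport`: `delta_g_forward`,
#'   `delta_g_backward`, `max_profile_gap`, `delta_delta_g_bounds`,
#'   `error_forward`, `error_backward`.
#' @export
hysteresis_report <- function(forward, backward, L_ref,
                              mode = c("undocking", "docking")) {
  mode <- match.arg(mode)
  al <- align_profiles(forward, backward, L_ref)
  dgf <- extract_delta_g(al[[1]], L_ref, mode)
  dgb <- extract_delta_g(al[[2]], L_ref, mode)
  both <- is.finite(al[[1]]$G) & is.finite(al[[2]]$G)
  gap <- max(abs(al[[1]]$G[both] - al[[2]]$G[both]))
  bounds <- sort(c(dgf$delta_g, dgb$delta_g))
  structure(list(delta_g_forward = dgf$delta_g,
                 delta_g_backward = dgb$delta_g,
                 error_forward = dgf$error, error_backward = dgb$error,
                 max_profile_gap = gap,
                 delta_delta_g_bounds = bounds,
                 L_ref = L_ref), class = "HysteresisReport")
}

#' Write / read a PMF profile as CSV
#'
#' Columns: `L`, `G_kcal_mol`, `err_kcal_mol`, `counts`. Unpopulated bins
#' are written with empty G.
#'
#' @param profile a `PmfProfile`.
#' @param path CSV path.
#' @return `path` invisibly, or a `PmfProfile`.
#' @export
write_pmf <- function(profile, path) {
  g <- profile$G
  g[!is.finite(g)] <- NA
  err <- if (is.null(profile$errors)) rep(NA_real_, length(g)) else profile$errors
  utils::write.csv(data.frame(L = profile$grid, G_kcal_mol = g,
                              err_kcal_mol = err, counts = profile$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @param temperature,bin_width metadata not stored in the CSV; defaults
#'   298 K and the grid spacing.
#' @export
read_pmf <- function(path, temperature = 298, bin_width = NULL) {
  d <- utils::read.csv(path)
  g <- d$G_kcal_mol
  g[is.na(g)] <- Inf
  if (is.null(bin_width)) bin_width <- stats::median(diff(d$L))
  structure(list(grid = d$L, G = g,
                 errors = if (all(is.na(d$err_kcal_mol))) NULL else d$err_kcal_mol,
                 counts = d$counts, alignment_ref = NA_real_, f = NULL,
                 temperature = temperature, bin_width = bin_width),
            class = "PmfProfile")
}
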