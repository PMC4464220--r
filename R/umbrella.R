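## umbrella: window grids, harmonic restraints, CV time-series containers
## and their plain-text dialect.

#' A single umbrella window
#'
#' @param index window index (1-based).
#' @param center restraint centre L_i, Angstrom.
#' @param stiffness restraint stiffness k, (kcal/mol)/Angstrom^2. Zero is
#'   allowed (an unbiased "window") so that the no-bias limit of WHAM can
#'   be exercised.
#' @return object of class `UmbrellaWindow`.
#' @export
umbrella_window <- function(index, center, stiffness) {
  stopifnot(is.numeric(center), is.finite(center), center >= 0,
            is.numeric(stiffness), stiffness >= 0)
  structure(list(index = as.integer(index), center = center,
                 stiffness = stiffness), class = "UmbrellaWindow")
}

#' Build a uniformly spaced umbrella-window grid
#'
#' `n` centres uniformly spaced from `L_min` to `L_max` inclusive. The
#' canonical design of the study this package emulates is
#' `make_windows(12.5, 34, 44, 20)`: 44 windows at 0.5 Angstrom spacing.
#'
#' @param L_min,L_max first and last centre, Angstrom.
#' @param n number of windows.
#' @param stiffness production-phase stiffness k, (kcal/mol)/Angstrom^2.
#' @param direction `"forward"` (centres iterated in increasing order during
#'   initialization) or `"backward"` (decreasing).
#' @param init_stiffness stiffness used during sequential initialization
#'   (metadata only; the package runs no dynamics).
#' @return object of class `WindowSet`: list with `windows` (data frame
#'   `index`, `center`, `stiffness` in iteration order), `direction`,
#'   `init_stiffness`.
#' @export
make_windows <- function(L_min, L_max, n, stiffness = 20,
                         direction = c("forward", "backward"),
                         init_stiffness = 40) {
  direction <- match.arg(direction)
  if (n < 1) stop("need at least one window")
  if (L_max < L_min) stop("L_max must be >= L_min")
  if (n == 1 && L_max != L_min) stop("a single window needs L_min == L_max")
  if (n > 1 && L_max == L_min) stop("n > 1 needs L_max > L_min")
  centers <- if (n == 1) L_min else seq(L_min, L_max, length.out = n)
  if (direction == "backward") centers <- rev(centers)
  structure(list(windows = data.frame(index = seq_len(n), center = centers,
                                      stiffness = stiffness),
                 direction = direction, init_stiffness = init_stiffness),
            class = "WindowSet")
}

.window_i <- function(ws, i) {
  umbrella_window(ws$windows$index[i], ws$windows$center[i],
                  ws$windows$stiffness[i])
}

#' Harmonic bias energy
#'
#' U(L) = 1/2 k (L - L_0)^2 by default, matching the restraint convention of
#' the common biasing engines; `convention = "full_k"` gives k (L - L_0)^2
#' for cross-checking tools that use that convention.
#'
#' @param L collective-variable value(s), Angstrom.
#' @param window an [umbrella_window()] (or any list with `center`,
#'   `stiffness`).
#' @param convention `"half_k"` (default) or `"full_k"`.
#' @return bias energy, kcal/mol (vectorized over `L`).
#' @export
bias_energy <- function(L, window, convention = c("half_k", "full_k")) {
  convention <- match.arg(convention)
  pref <- if (convention == "half_k") 0.5 else 1
  pref * window$stiffness * (L - window$center)^2
}

#' A biased collective-variable time series
#'
#' @param window the [umbrella_window()] the samples were collected under.
#' @param times sample times, ps, strictly increasing.
#' @param values collective-variable samples L, Angstrom.
#' @return object of class `CvSeries`.
#' @export
cv_series <- function(window, times, values) {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) == 0) stop("empty series")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("non-finite CV values")
  structure(list(window = window, times = as.numeric(times),
                 values = as.numeric(values)), class = "CvSeries")
}

#' Drop the equilibration part of a series
#'
#' Keeps only samples in the final `keep_last` ps of the series (time
#' strictly greater than t_end - keep_last). The study analyzed the last
#' 4 ns of each 5 ns window.
#'
#' @param series a [cv_series()].
#' @param keep_last duration to keep, ps.
#' @return a trimmed `CvSeries`.
#' @export
discard_equilibration <- function(series, keep_last) {
  t <- series$times
  duration <- t[length(t)] - t[1]
  if (duration < keep_last - 1e-9) {
    stop(sprintf("series spans %.1f ps, shorter than keep_last = %.1f ps",
                 duration, keep_last))
  }
  if (keep_last >= duration - 1e-9) return(series)   # keep everything
  keep <- t > t[length(t)] - keep_last
  cv_series(series$window, t[keep], series$values[keep])
}

#' Write a CV series to plain text
#'
#' Dialect: two '#'-prefixed header lines carrying the window metadata
#' (`# center_angstrom: <float>`, `# stiffness_kcal_mol_A2: <float>`), then
#' two whitespace-separated columns `time_ps value_angstrom`. Full double
#' precision is preserved.
#'
#' @param series a [cv_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center_angstrom: %.17g", series$window$center),
               sprintf("# stiffness_kcal_mol_A2: %.17g", series$window$stiffness),
               sprintf("%.17g %.17g", series$times, series$values)), con)
  invisible(path)
}

#' Read a CV series from plain text
#'
#' @param path path to a file in the [write_cv()] dialect.
#' @param index window index to attach (default parsed from a
#'   `window_<index>.cv` file name, else 1).
#' @return a [cv_series()].
#' @export
read_cv <- function(path, index = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("missing metadata header '", key, "' in ", path)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", m[1]))
  }
  center <- get_meta("center_angstrom")
  stiffness <- get_meta("stiffness_kcal_mol_A2")
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("empty series in ", path)
  fields <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  if (ncol(fields) != 2) stop("expected two columns in ", path)
  if (is.null(index)) {
    m <- regmatches(basename(path), regexpr("[0-9]+", basename(path)))
    index <- if (length(m)) as.integer(m) else 1L
  }
  cv_series(umbrella_window(index, center, stiffness),
            as.numeric(fields[, 1]), as.numeric(fields[, 2]))
}

#' Write / read a whole campaign of CV files
#'
#' One `window_<index>.cv` file per series.
#'
#' @param series_list list of [cv_series()].
#' @param dir directory.
#' @return file paths (write) or list of series (read), invisibly/visibly.
#' @export
write_cv_dir <- function(series_list, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(series_list, function(s) {
    p <- file.path(dir, sprintf("window_%03d.cv", s$window$index))
    write_cv(s, p)
    p
  }, "")
  invisible(paths)
}

#' @rdname write_cv_dir
#' @param paths explicit file paths (read); default all `*.cv` in `dir`.
#' @export
read_cv_dir <- function(dir, paths = NULL) {
  if (is.null(paths)) paths <- sort(list.files(dir, "\\.cv$", full.names = TRUE))
  if (!length(paths)) stop("no .cv files found in ", dir)
  lapply(paths, read_cv)
}

#' Serialize / deserialize a window set as YAML
#'
#' @param ws a [make_windows()] result.
#' @param path YAML path.
#' @return `path` invisibly, or a `WindowSet`.
#' @export
write_window_set <- function(ws, path) {
  yaml::write_yaml(list(direction = ws$direction,
                        init_stiffness = ws$init_stiffness,
                        windows = lapply(seq_len(nrow(ws$windows)), function(i) {
                          as.list(ws$windows[i, ])
                        })), path)
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  y <- yaml::read_yaml(path)
  w <- do.call(rbind, lapply(y$windows, as.data.frame))
  structure(list(windows = w, direction = y$direction,
                 init_stiffness = y$init_stiffness), class = "WindowSet")
}
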