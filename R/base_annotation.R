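## base_annotation: ring-frame geometry and classification of base-base
## relationships (Watson-Crick / non-canonical / stacking / none).

.ring_atoms <- c("N1", "C2", "N3", "C4", "C5", "C6")

#' Build the local coordinate frame of a nucleobase
#'
#' Constructs a right-handed orthonormal frame at the centroid of the
#' six-membered ring (N1, C2, N3, C4, C5, C6 — purines use their pyrimidine
#' ring): z is the unit normal of the least-squares ring plane (sign fixed
#' by the N1->C2->N3 winding so it is deterministic), x the in-plane unit
#' vector toward the C2 atom, y = z x x.
#'
#' @param residue data frame of one residue's atoms (columns `name`, `x`,
#'   `y`, `z`), e.g. a subset of `model$atoms`.
#' @param resid optional residue index, used in error messages.
#' @return object of class `BaseFrame`: list with `origin` (length-3) and
#'   `axes` (3x3 matrix, rows x, y, z).
#' @export
build_frame <- function(residue, resid = NULL) {
  who <- if (is.null(resid)) "" else paste0(" in residue ", resid)
  pos <- match(.ring_atoms, residue$name)
  if (anyNA(pos)) {
    stop("missing ring atom(s)", who, ": ",
         paste(.ring_atoms[is.na(pos)], collapse = ", "))
  }
  X <- as.matrix(residue[pos, c("x", "y", "z")])
  dimnames(X) <- NULL
  if (!all(is.finite(X))) stop("non-finite ring coordinates", who)
  origin <- unname(colMeans(X))
  Xc <- sweep(X, 2, origin)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  if (ev$values[2] < 1e-10) stop("degenerate (collinear) ring", who)
  zhat <- ev$vectors[, 3]
  ## deterministic sign: follow the ring winding N1 -> C2 -> N3
  w <- .cross3(X[2, ] - X[1, ], X[3, ] - X[2, ])
  if (sum(w * zhat) < 0) zhat <- -zhat
  v <- X[2, ] - origin  # toward C2
  v_in <- v - sum(v * zhat) * zhat
  xhat <- .unit(v_in)
  yhat <- .cross3(zhat, xhat)
  structure(list(origin = origin,
                 axes = rbind(x = xhat, y = yhat, z = zhat)),
            class = "BaseFrame")
}

#' Position of ring centre k in the frame of base j
#'
#' @param frame_j,frame_k [build_frame()] results.
#' @return numeric length-3 vector r_jk = (x_jk, y_jk, z_jk), Angstrom.
#' @export
relative_position <- function(frame_j, frame_k) {
  as.vector(frame_j$axes %*% (frame_k$origin - frame_j$origin))
}

#' Ellipsoidal distance
#'
#' D = x^2/a^2 + y^2/b^2 + z^2/c^2 with default semiaxes (5, 5, 3) Angstrom,
#' the anisotropic gate used for both pairing and stacking.
#'
#' @param r length-3 relative position.
#' @param semiaxes ellipsoid semiaxes (a, b, c), Angstrom.
#' @return scalar D (dimensionless).
#' @export
ellipsoidal_distance <- function(r, semiaxes = c(5, 5, 3)) {
  stopifnot(all(semiaxes > 0))
  sum((r / semiaxes)^2)
}

## trivariate normal density (full covariance)
.dmvnorm3 <- function(x, mu, sigma) {
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("singular or non-PD covariance in WC model"))
  z <- backsolve(ch, x - mu, transpose = TRUE)
  exp(-0.5 * sum(z^2)) / ((2 * pi)^1.5 * prod(diag(ch)))
}

#' Construct a Watson-Crick geometry model
#'
#' Trivariate Gaussian model of the relative ring-centre position of WC
#' pairs; the pairing test is the product of the densities at r_jk and
#' r_kj exceeding `threshold`.
#'
#' @param mu length-3 mean, Angstrom.
#' @param sigma 3x3 covariance, Angstrom^2.
#' @param threshold decision threshold on the density product (default 1e-8).
#' @return object of class `WcModel`.
#' @export
wc_model <- function(mu, sigma, threshold = 1e-8) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  stopifnot(length(mu) == 3, all(dim(sigma) == c(3, 3)), threshold > 0)
  if (max(abs(sigma - t(sigma))) > 1e-9) stop("sigma must be symmetric")
  chol(sigma)  # errors if not positive definite
  structure(list(mu = mu, sigma = sigma, threshold = threshold),
            class = "WcModel")
}

#' Watson-Crick geometry score
#'
#' Product of the trivariate normal densities N(r_jk; mu, sigma) and
#' N(r_kj; mu, sigma); symmetric under exchange of j and k.
#'
#' @param r_jk,r_kj relative positions from [relative_position()].
#' @param model a [wc_model()].
#' @return scalar density product.
#' @export
wc_score <- function(r_jk, r_kj, model) {
  .dmvnorm3(r_jk, model$mu, model$sigma) *
    .dmvnorm3(r_kj, model$mu, model$sigma)
}

#' Calibrate a Watson-Crick model from example geometries
#'
#' Sample mean and (ridge-regularized) sample covariance of relative-position
#' vectors observed for known WC pairs.
#'
#' @param examples numeric matrix (n x 3) of relative positions.
#' @param threshold decision threshold (kept at the default 1e-8).
#' @param epsilon ridge added to the covariance diagonal, Angstrom^2.
#' @return a [wc_model()].
#' @export
calibrate_wc_model <- function(examples, threshold = 1e-8, epsilon = 1e-6) {
  examples <- as.matrix(examples)
  if (ncol(examples) != 3) stop("examples must be an n x 3 matrix")
  if (nrow(examples) < 4) stop("need at least 4 example geometries")
  mu <- colMeans(examples)
  sigma <- stats::cov(examples) + diag(epsilon, 3)
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("rank-deficient covariance even after regularization")
  wc_model(mu, sigma, threshold)
}

#' Default Watson-Crick model
#'
#' Calibrated once per session (deterministically, fixed internal seed) with
#' [calibrate_wc_model()] on idealized jittered WC pair geometries from
#' [build_geometry()]. The reference study calibrated on WC pairs of a
#' ribosomal crystal structure; those parameters are not published, so the
#' shipped model is a synthetic stand-in with the same decision structure.
#' Recalibrate from any annotated structure set if absolute scores matter.
#'
#' @return a [wc_model()].
#' @export
default_wc_model <- function() {
  if (!is.null(.pkg_cache$wc_model)) return(.pkg_cache$wc_model)
  ex <- .with_seed(20140601, function() {
    rows <- lapply(seq_len(250), function(i) {
      g <- build_geometry(geometry_recipe("wc_pair", jitter = 0.12), seed = i)
      fr <- .loop_frames(g, unique(g$atoms$resid))
      rbind(relative_position(fr[[1]], fr[[2]]),
            relative_position(fr[[2]], fr[[1]]))
    })
    do.call(rbind, rows)
  })
  .pkg_cache$wc_model <- calibrate_wc_model(ex)
  .pkg_cache$wc_model
}

#' Annotation criteria
#'
#' All thresholds of the three-way base-contact classification. The printed
#' source criteria state |z| < 2 Angstrom for stacking, which no physical
#' stack (|z| ~ 3.4) can satisfy and which collides with the pairing window;
#' the default here requires |z| >= `z_stack_min`, with
#' `literal_stack_z = TRUE` restoring the printed inequality.
#'
#' @param ellipsoid_semiaxes semiaxes (a, b, c), Angstrom.
#' @param D_cutoff ellipsoidal-distance cutoff.
#' @param z_pair_max max |z| for pairing, Angstrom.
#' @param z_stack_min min |z| for stacking, Angstrom.
#' @param rho2_stack_max max in-plane x^2 + y^2 for stacking, Angstrom^2.
#' @param literal_stack_z use |z| < `z_pair_max` for stacking (as printed).
#' @param exclude_adjacent_pairing exclude sequence-adjacent residues
#'   (|delta resid| == 1) from the WC and non-canonical categories.
#' @param wc_model a [wc_model()]; `NULL` means [default_wc_model()].
#' @return object of class `AnnotationCriteria`.
#' @export
annotation_criteria <- function(ellipsoid_semiaxes = c(5, 5, 3),
                                D_cutoff = 2.5,
                                z_pair_max = 2,
                                z_stack_min = 2,
                                rho2_stack_max = 5,
                                literal_stack_z = FALSE,
                                exclude_adjacent_pairing = FALSE,
                                wc_model = NULL) {
  stopifnot(all(ellipsoid_semiaxes > 0), D_cutoff > 0, z_pair_max > 0,
            z_stack_min > 0, rho2_stack_max > 0)
  structure(list(ellipsoid_semiaxes = ellipsoid_semiaxes,
                 D_cutoff = D_cutoff, z_pair_max = z_pair_max,
                 z_stack_min = z_stack_min, rho2_stack_max = rho2_stack_max,
                 literal_stack_z = isTRUE(literal_stack_z),
                 exclude_adjacent_pairing = isTRUE(exclude_adjacent_pairing),
                 wc_model = wc_model),
            class = "AnnotationCriteria")
}

.criteria_wc_model <- function(criteria) {
  if (is.null(criteria$wc_model)) default_wc_model() else criteria$wc_model
}

#' Classify the relationship between two bases
#'
#' Evaluated in strict precedence: Watson-Crick (sequence must be AU or GC
#' and the Gaussian score exceed its threshold), else non-canonical pair,
#' else stacking, else none. Symmetric in the order of the two bases.
#'
#' @param frame_j,frame_k base frames from [build_frame()].
#' @param base_j,base_k base identities, one of "A", "C", "G", "U".
#' @param criteria an [annotation_criteria()].
#' @param adjacent are the residues sequence neighbours? (used only when
#'   `exclude_adjacent_pairing` is set).
#' @return list of class `PairAnnotation` with `category` (one of `"WC"`,
#'   `"NONCANONICAL"`, `"STACKING"`, `"NONE"`), `r_jk`, `r_kj`.
#' @export
classify_pair <- function(frame_j, frame_k, base_j, base_k,
                          criteria = annotation_criteria(),
                          adjacent = FALSE) {
  r_jk <- relative_position(frame_j, frame_k)
  r_kj <- relative_position(frame_k, frame_j)
  a <- criteria$ellipsoid_semiaxes
  D_jk <- ellipsoidal_distance(r_jk, a)
  D_kj <- ellipsoidal_distance(r_kj, a)
  inside <- D_jk < criteria$D_cutoff && D_kj < criteria$D_cutoff
  z_ok_pair <- abs(r_jk[3]) < criteria$z_pair_max &&
    abs(r_kj[3]) < criteria$z_pair_max
  pairing_allowed <- !(criteria$exclude_adjacent_pairing && adjacent)

  category <- "NONE"
  wc_seq <- paste(sort(c(base_j, base_k)), collapse = "") %in% c("AU", "CG")
  if (pairing_allowed && wc_seq) {
    wm <- .criteria_wc_model(criteria)
    if (wc_score(r_jk, r_kj, wm) > wm$threshold) category <- "WC"
  }
  if (category == "NONE" && pairing_allowed && inside && z_ok_pair) {
    category <- "NONCANONICAL"
  }
  if (category == "NONE" && inside) {
    z_ok_stack <- if (criteria$literal_stack_z) {
      z_ok_pair
    } else {
      abs(r_jk[3]) >= criteria$z_stack_min && abs(r_kj[3]) >= criteria$z_stack_min
    }
    rho_ok <- sum(r_jk[1:2]^2) < criteria$rho2_stack_max &&
      sum(r_kj[1:2]^2) < criteria$rho2_stack_max
    if (z_ok_stack && rho_ok) category <- "STACKING"
  }
  structure(list(category = category, r_jk = r_jk, r_kj = r_kj,
                 D_jk = D_jk, D_kj = D_kj),
            class = "PairAnnotation")
}

## frames for a set of residues of one model; errors name the residue
.loop_frames <- function(model, resids) {
  frames <- lapply(resids, function(r) {
    build_frame(.residue_atoms(model, r), resid = r)
  })
  names(frames) <- as.character(resids)
  frames
}

.empty_counts <- function() {
  data.frame(wc_inter = 0L, noncanonical_inter = 0L, stack_inter = 0L,
             stack_intra = 0L, wc_intra = 0L, noncanonical_intra = 0L)
}

#' Annotate all base pairs of a two-loop system in one frame
#'
#' Classifies every unordered residue pair within the union of the two loops
#' and partitions the counts into inter-loop (one residue in each loop) and
#' intra-loop contacts.
#'
#' @param model a `StructureModel`.
#' @param loopA,loopB disjoint [loop_definition()]s.
#' @param criteria an [annotation_criteria()].
#' @return list with `counts` (one-row data frame: `wc_inter`,
#'   `noncanonical_inter`, `stack_inter`, `stack_intra`, `wc_intra`,
#'   `noncanonical_intra`) and `pairs` (data frame of non-`NONE`
#'   annotations with relative-position components).
#' @export
annotate_frame <- function(model, loopA, loopB,
                           criteria = annotation_criteria()) {
  if (!.loops_disjoint(loopA, loopB)) stop("loop definitions overlap")
  a <- model$atoms
  res_a <- intersect(loopA$from:loopA$to, unique(a$resid[a$nucleotide]))
  res_b <- intersect(loopB$from:loopB$to, unique(a$resid[a$nucleotide]))
  resids <- c(res_a, res_b)
  frames <- .loop_frames(model, resids)
  bases <- vapply(resids, function(r) .residue_atoms(model, r)$resname[1], "")
  names(bases) <- as.character(resids)

  counts <- .empty_counts()
  rows <- list()
  n <- length(resids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ri <- resids[i]; rj <- resids[j]
      ann <- classify_pair(frames[[i]], frames[[j]], bases[i], bases[j],
                           criteria, adjacent = abs(ri - rj) == 1L)
      if (ann$category == "NONE") next
      inter <- (ri %in% res_a) != (rj %in% res_a)
      key <- paste0(tolower(ann$category), if (inter) "_inter" else "_intra")
      key <- sub("^wc", "wc", sub("^stacking", "stack", key))
      if (key %in% names(counts)) counts[[key]] <- counts[[key]] + 1L
      rows[[length(rows) + 1]] <- data.frame(
        res_j = ri, res_k = rj, category = ann$category, inter = inter,
        x_jk = ann$r_jk[1], y_jk = ann$r_jk[2], z_jk = ann$r_jk[3],
        x_kj = ann$r_kj[1], y_kj = ann$r_kj[2], z_kj = ann$r_kj[3])
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(res_j = integer(), res_k = integer(), category = character(),
               inter = logical(), x_jk = numeric(), y_jk = numeric(),
               z_jk = numeric(), x_kj = numeric(), y_kj = numeric(),
               z_kj = numeric())
  list(counts = counts, pairs = pairs)
}

#' Annotate a series of frames and average the contact counts
#'
#' @param models list of `StructureModel`s (e.g. from [read_pdb()]).
#' @param loopA,loopB disjoint [loop_definition()]s.
#' @param criteria an [annotation_criteria()].
#' @param groups optional grouping factor (length = number of models), e.g.
#'   umbrella-window labels; averages are then per group.
#' @return list with `per_frame` (data frame, one row per model) and
#'   `averages` (overall or per-group means of the six counts).
#' @export
annotate_trajectory <- function(models, loopA, loopB,
                                criteria = annotation_criteria(),
                                groups = NULL) {
  stopifnot(length(models) >= 1)
  per <- do.call(rbind, lapply(seq_along(models), function(i) {
    cbind(frame = i, annotate_frame(models[[i]], loopA, loopB, criteria)$counts)
  }))
  cols <- setdiff(names(per), "frame")
  if (is.null(groups)) {
    averages <- as.data.frame(t(colMeans(per[cols])))
  } else {
    stopifnot(length(groups) == length(models))
    averages <- stats::aggregate(per[cols], by = list(group = groups), mean)
  }
  list(per_frame = per, averages = averages)
}
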