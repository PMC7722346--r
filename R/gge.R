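# GGE biplot computations. The genotype x environment means matrix is
# environment-centred (column means removed: no transformation, no scaling),
# then decomposed by SVD; the first two axes carry genotype main effect plus
# genotype x environment interaction. Downstream geometry -- which-won-where
# sectors and the average-environment-coordinate (AEC) stability view -- is
# computed from the scores, never from a rendered figure.

#' Fit a GGE model
#'
#' Column-centres the genotype x environment matrix and decomposes it by
#' singular value decomposition. The sign of each axis is fixed by forcing
#' the environment-score vector to a positive sum (both score vectors of an
#' axis are flipped together), which makes all coordinates deterministic.
#'
#' @param means Genotype x environment numeric matrix (no missing cells) or
#'   a `means_table` at `per_environment` level.
#' @param n_axes Number of axes retained (default 2); must not exceed
#'   `min(g - 1, e)`.
#' @return A `gge_model`: ids, `centered` matrix, singular values `d`
#'   (descending), score matrices `xi` (genotype) and `eta` (environment),
#'   `var_explained` per retained axis (`d^2 / sum(d^2)`).
#' @export
fit_gge <- function(means, n_axes = 2) {
  M <- if (is.matrix(means)) means else means_matrix(means)
  if (is.null(rownames(M))) rownames(M) <- paste0("G", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("E", seq_len(ncol(M)))
  g <- nrow(M); e <- ncol(M)
  if (g < 3 || e < 2) stop("need at least 3 genotypes and 2 environments")
  if (anyNA(M)) stop("missing genotype x environment cells; no imputation is done")
  if (n_axes > min(g - 1, e)) stop("n_axes exceeds min(g - 1, e)")
  centered <- sweep(M, 2, colMeans(M))
  sv <- svd(centered)
  for (a in seq_len(ncol(sv$v))) {
    s <- sum(sv$v[, a])
    flip <- if (abs(s) > 1e-12) s < 0 else {
      nz <- which(abs(sv$v[, a]) > 1e-12)[1]
      !is.na(nz) && sv$v[nz, a] < 0
    }
    if (isTRUE(flip)) { sv$u[, a] <- -sv$u[, a]; sv$v[, a] <- -sv$v[, a] }
  }
  tot <- sum(sv$d^2)
  structure(list(genotypes = rownames(M), environments = colnames(M),
                 centered = centered, d = sv$d,
                 xi = sv$u[, seq_len(n_axes), drop = FALSE],
                 eta = sv$v[, seq_len(n_axes), drop = FALSE],
                 n_axes = n_axes,
                 var_explained = if (tot > 0) sv$d[seq_len(n_axes)]^2 / tot
                                 else rep(NA_real_, n_axes)),
            class = "gge_model")
}

svp_f <- c(genotype_focused = 1, environment_focused = 0, symmetric = 0.5)

#' Singular-value-partitioned biplot scores
#'
#' Genotype coordinates `xi * d^f` and environment coordinates
#' `eta * d^(1-f)` with `f` = 1 (genotype-focused, the program setting
#' "SVP = 2" of the source figures), 0 (environment-focused, "SVP = 1"),
#' or 0.5 (symmetric). In every mode the coordinate product reproduces the
#' same rank-`n_axes` approximation.
#'
#' @param model A [fit_gge()] model.
#' @param mode Partitioning mode.
#' @return List with `genotype` and `environment` coordinate matrices and
#'   the `mode`.
#' @export
svp_scores <- function(model, mode = c("symmetric", "genotype_focused",
                                       "environment_focused")) {
  mode <- match.arg(mode)
  f <- svp_f[[mode]]
  k <- model$n_axes
  d <- model$d[seq_len(k)]
  G <- sweep(model$xi, 2, d^f, `*`)
  E <- sweep(model$eta, 2, d^(1 - f), `*`)
  rownames(G) <- model$genotypes
  rownames(E) <- model$environments
  colnames(G) <- colnames(E) <- paste0("PC", seq_len(k))
  list(genotype = G, environment = E, mode = mode)
}

#' Which-won-where geometry
#'
#' Convex hull of the genotype markers in the first two axes, sector
#' boundaries as rays from the origin perpendicular to the hull edges, each
#' environment assigned to the sector containing its marker's angle, and the
#' sector's vertex genotype as its winner. Because environment-centring puts
#' the genotype centroid at the origin, the origin lies inside the hull and
#' the winner equals the genotype maximizing the inner product with the
#' environment marker (invariant to the SVP mode). Environments on a
#' boundary (within 1e-12 radians) go to the counter-clockwise sector.
#'
#' @param model A 2-axis [fit_gge()] model.
#' @return A `biplot_geometry` list: `hull_vertices` (counter-clockwise
#'   genotype ids), `sectors` (vertex + boundary angles), `environments`
#'   (angle, assigned vertex = winner).
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  if (model$n_axes != 2) stop("which_won_where needs a 2-axis model")
  sc <- svp_scores(model, "symmetric")
  P <- sc$genotype
  E <- sc$environment
  if (model$d[1] <= 0 || model$d[2] <= 1e-12 * model$d[1])
    stop("degenerate geometry: genotype markers are collinear through the origin")
  hull <- grDevices::chull(P)           # clockwise order
  hull <- rev(hull)                      # counter-clockwise
  V <- P[hull, , drop = FALSE]
  nv <- nrow(V)
  # boundary ray after vertex k: perpendicular from origin to edge (k, k+1)
  foot_angle <- function(a, b) {
    ab <- b - a
    tpar <- -sum(a * ab) / sum(ab^2)
    foot <- a + tpar * ab
    atan2(foot[2], foot[1])
  }
  rays <- vapply(seq_len(nv), function(k)
    foot_angle(V[k, ], V[if (k == nv) 1 else k + 1, ]), 0)
  env_ang <- atan2(E[, 2], E[, 1])
  norm2pi <- function(x) (x %% (2 * pi))
  tol <- 1e-12
  assign_vertex <- function(theta) {
    # sector of vertex k spans from ray[k-1] to ray[k] (counter-clockwise);
    # a boundary angle belongs to the counter-clockwise (following) sector
    for (k in seq_len(nv)) {
      lo <- rays[if (k == 1) nv else k - 1]
      hi <- rays[k]
      span <- norm2pi(hi - lo)
      off <- norm2pi(theta - lo)
      if (off > tol && (off < span - tol || span == 0)) return(k)
      if (abs(off - span) <= tol) return(if (k == nv) 1 else k + 1)
    }
    # numeric fallback: maximal inner product
    which.max(V %*% c(cos(theta), sin(theta)))
  }
  win_k <- vapply(env_ang, function(a) as.integer(assign_vertex(a)), 0L)
  winners <- rownames(V)[win_k]
  envs <- data.frame(environment = model$environments, angle = env_ang,
                     winner = winners, stringsAsFactors = FALSE)
  sectors <- data.frame(vertex = rownames(V),
                        ray_from = rays[c(nv, seq_len(nv - 1))],
                        ray_to = rays,
                        stringsAsFactors = FALSE)
  structure(list(hull_vertices = rownames(V), sectors = sectors,
                 environments = envs),
            class = "biplot_geometry")
}

#' Average-environment-coordinate stability and ideal-genotype ranking
#'
#' Projects genotype markers (genotype-focused scores) onto the unit vector
#' of the average environment: the projection estimates mean performance,
#' the absolute perpendicular component measures instability (the longer
#' the projection off the axis, the less stable the genotype), and the
#' ideal genotype sits on the positive axis at the maximal mean projection.
#' Genotypes are ranked by Euclidean distance to that ideal point.
#'
#' @param model A 2-axis [fit_gge()] model.
#' @return Data frame: genotype, `mean_projection`, `stability`,
#'   `ideal_distance`, `rank` (ascending distance).
#' @export
aec_stability <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  if (model$n_axes != 2) stop("aec_stability needs a 2-axis model")
  sc <- svp_scores(model, "genotype_focused")
  G <- sc$genotype
  avg_env <- colMeans(sc$environment)
  nrm <- sqrt(sum(avg_env^2))
  if (nrm < 1e-12) stop("zero-length average-environment vector; no mean axis")
  u <- avg_env / nrm
  proj <- as.vector(G %*% u)
  perp <- G - outer(proj, u)
  stab <- sqrt(rowSums(perp^2))
  ideal <- u * max(proj)
  dist <- sqrt(rowSums(sweep(G, 2, ideal)^2))
  out <- data.frame(genotype = model$genotypes, mean_projection = proj,
                    stability = stab, ideal_distance = dist,
                    stringsAsFactors = FALSE)
  out$rank <- rank(out$ideal_distance, ties.method = "first")
  out[order(out$rank), ]
}
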