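#' Moving-window gradient of a raster
#'
#' Each cell becomes `100 * (max - min) / max` over its 3x3 neighbourhood,
#' the window statistic used to turn SST, CHL and bathymetry into frontal /
#' slope proxies (SSTG, CHLG, BATG). Missing and out-of-bounds neighbours are
#' dropped from the window; a window maximum of zero leaves the cell missing
#' (division guard).
#'
#' @param raster An `env_raster`.
#' @return An `env_raster` named `<name>G`, in percent.
#' @export
window_gradient <- function(raster) {
  z <- raster$z
  nr <- nrow(z); nc <- ncol(z)
  mx <- matrix(-Inf, nr, nc)
  mn <- matrix(Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    src_i <- max(1, 1 - di):min(nr, nr - di)
    src_j <- max(1, 1 - dj):min(nc, nc - dj)
    dst_i <- src_i + di; dst_j <- src_j + dj
    nb <- z[src_i, src_j, drop = FALSE]
    cur_mx <- mx[dst_i, dst_j, drop = FALSE]
    cur_mn <- mn[dst_i, dst_j, drop = FALSE]
    ok <- !is.na(nb)
    cur_mx[ok] <- pmax(cur_mx[ok], nb[ok])
    cur_mn[ok] <- pmin(cur_mn[ok], nb[ok])
    mx[dst_i, dst_j] <- cur_mx
    mn[dst_i, dst_j] <- cur_mn
  }
  g <- 100 * (mx - mn) / mx
  g[!is.finite(g) | mx == 0] <- NA
  env_raster(paste0(raster$name, "G"), raster$lon, raster$lat, g, units = "%")
}

#' Distance-to-colony raster
#'
#' Great-circle distance (km) from every cell centre to the colony; the DCOL
#' predictor capturing central-place accessibility.
#'
#' @param grid A list with `lon` and `lat` cell-centre vectors, or any
#'   `env_raster` whose grid should be reused.
#' @param colony `c(lon, lat)`.
#' @return An `env_raster` named "DCOL", in km.
#' @export
distance_to_colony <- function(grid, colony) {
  gg <- expand.grid(lon = grid$lon, lat = grid$lat)
  d <- great_circle_km(cbind(gg$lon, gg$lat), colony)
  z <- matrix(d, nrow = length(grid$lat), ncol = length(grid$lon), byrow = TRUE)
  env_raster("DCOL", grid$lon, grid$lat, z, units = "km")
}

#' Balanced per-bird subsample of ARS locations
#'
#' Draws an equal number of ARS locations per bird -- the minimum per-bird
#' count -- without replacement, so no individual dominates the habitat
#' model. Deterministic given the seed.
#'
#' @param zones_by_bird Named list, one data frame of ARS locations (with
#'   `lon`, `lat`) per bird.
#' @param seed Integer seed.
#' @return Data frame with `bird`, `lon`, `lat`.
#' @export
balanced_subsample <- function(zones_by_bird, seed) {
  if (length(zones_by_bird) == 0) stop("no birds supplied")
  counts <- vapply(zones_by_bird, nrow, integer(1))
  if (any(counts == 0)) stop("every bird needs at least one ARS location")
  n <- min(counts)
  with_seed(seed, {
    out <- lapply(names(zones_by_bird), function(b) {
      z <- zones_by_bird[[b]]
      pick <- if (nrow(z) == n) seq_len(n) else sample(nrow(z), n)
      data.frame(bird = b, lon = z$lon[pick], lat = z$lat[pick],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

## ---- internal feature machinery -------------------------------------------

## cells in lon-fastest order, matching expand.grid(lon, lat)
stack_values <- function(rasters) {
  first <- rasters[[1]]
  for (r in rasters) if (!same_grid(r, first)) stop("rasters are not aligned")
  vals <- vapply(rasters, function(r) as.vector(t(r$z)),
                 numeric(length(first$lon) * length(first$lat)))
  colnames(vals) <- vapply(rasters, function(r) r$name, character(1))
  gg <- expand.grid(lon = first$lon, lat = first$lat)
  list(values = vals, lon = gg$lon, lat = gg$lat,
       grid = list(lon = first$lon, lat = first$lat))
}

cell_index <- function(grid, lon, lat) {
  dlon <- diff(grid$lon[1:2]); dlat <- diff(grid$lat[1:2])
  i <- round((lon - grid$lon[1]) / dlon) + 1
  j <- round((lat - grid$lat[1]) / dlat) + 1
  bad <- i < 1 | i > length(grid$lon) | j < 1 | j > length(grid$lat)
  if (any(bad)) stop("presence point outside the raster extent at row ",
                     which(bad)[1])
  (j - 1) * length(grid$lon) + i
}

## linear + quadratic features on [0,1]-scaled predictors
build_features <- function(scaled) {
  p <- ncol(scaled)
  f <- cbind(scaled, scaled^2)
  colnames(f) <- c(paste0(colnames(scaled), ".l"), paste0(colnames(scaled), ".q"))
  attr(f, "variable") <- rep(colnames(scaled), 2)
  f
}

## ---- model ----------------------------------------------------------------

#' Fit a presence-only maximum-entropy habitat model
#'
#' Fits the Gibbs distribution q(x) proportional to exp(lambda . f(x)) over
#' the background cells (all non-missing cells of the study extent) that
#' maximizes the L1-penalized log-likelihood of the presence cells. Features
#' are linear and quadratic terms of each predictor scaled to \[0, 1\];
#' duplicate presences within a grid cell are collapsed. The logistic output
#' p = exp(H) q / (1 + exp(H) q), with H the entropy of q, maps suitability
#' to (0, 1).
#'
#' @param presences Two-column lon/lat matrix or data frame of presence
#'   points.
#' @param rasters Named list of aligned `env_raster` predictors.
#' @param reg Regularization multiplier scaling the per-feature L1 penalty
#'   `max(sd_presence(f), 0.05) / sqrt(n)`.
#' @param tol Convergence tolerance on the penalized-gain per sweep.
#' @param max_sweeps Sweep cap for the coordinate-descent optimizer.
#' @return A `maxent_model` with weights, entropy, per-variable gain path,
#'   and everything needed to predict on the stack.
#' @export
fit_maxent <- function(presences, rasters, reg = 1.0, tol = 1e-6,
                       max_sweeps = 500) {
  sv <- stack_values(rasters)
  ok_bg <- rowSums(!is.finite(sv$values)) == 0
  if (!any(ok_bg)) stop("no background cell has complete predictors")
  pts <- as.matrix(presences)[, 1:2, drop = FALSE]
  ci <- cell_index(sv$grid, pts[, 1], pts[, 2])
  bad <- !ok_bg[ci]
  if (any(bad))
    stop("non-finite predictor at presence cell ", ci[which(bad)[1]])
  ci <- unique(ci)                              # duplicates removed
  n_pres <- length(ci)
  if (n_pres < 10) stop("need at least 10 distinct presence cells")

  rng <- apply(sv$values[ok_bg, , drop = FALSE], 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  scale01 <- function(v) sweep(sweep(v, 2, rng[1, ]), 2, span, "/")
  f_bg <- build_features(scale01(sv$values[ok_bg, , drop = FALSE]))
  f_pr <- build_features(scale01(sv$values[ci, , drop = FALSE]))
  variable <- attr(f_bg, "variable")

  beta <- reg * pmax(apply(f_pr, 2, sd), 0.05) / sqrt(n_pres)
  fbar <- colMeans(f_pr)

  nf <- ncol(f_bg)
  lambda <- numeric(nf)
  eta <- numeric(nrow(f_bg))
  var_gain <- setNames(numeric(ncol(sv$values)), colnames(sv$values))
  ll <- function(lam, et) {
    m <- max(et)
    sum(fbar * lam) - (m + log(sum(exp(et - m)))) - sum(beta * abs(lam))
  }
  obj <- ll(lambda, eta)
  for (sweep_i in seq_len(max_sweeps)) {
    sweep_gain <- 0
    for (j in seq_len(nf)) {
      m <- max(eta)
      q <- exp(eta - m); q <- q / sum(q)
      eq <- sum(q * f_bg[, j])
      vq <- sum(q * f_bg[, j]^2) - eq^2
      if (vq < 1e-12) next
      g <- fbar[j] - eq
      u <- lambda[j] + g / vq
      new_l <- sign(u) * max(abs(u) - beta[j] / vq, 0)
      delta <- new_l - lambda[j]
      if (abs(delta) < 1e-12) next
      delta <- max(min(delta, 1), -1)           # trust region
      lam_try <- lambda; lam_try[j] <- lambda[j] + delta
      eta_try <- eta + delta * f_bg[, j]
      obj_try <- ll(lam_try, eta_try)
      if (obj_try <= obj) next                  # no penalized gain
      gain <- obj_try - obj
      lambda <- lam_try; eta <- eta_try; obj <- obj_try
      var_gain[variable[j]] <- var_gain[variable[j]] + gain
      sweep_gain <- sweep_gain + gain
    }
    if (sweep_gain < tol) break
  }

  m <- max(eta)
  log_z <- m + log(sum(exp(eta - m)))
  q <- exp(eta - log_z)
  entropy <- -sum(q * log(pmax(q, 1e-300)))
  structure(list(
    lambda = lambda, beta = beta, entropy = entropy, var_gain = var_gain,
    variable = variable, feature_names = colnames(f_bg),
    rng = rng, span = span, grid = sv$grid, ok_bg = ok_bg,
    presence_cells = ci, n_presences = n_pres, reg = reg,
    q_bg = q, log_z = log_z, objective = obj,
    var_names = colnames(sv$values)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("<maxent_model>", x$n_presences, "presence cells,", sum(x$ok_bg),
      "background cells,", sum(x$lambda != 0), "active features; H =",
      round(x$entropy, 3), "\n")
  invisible(x)
}

## raw (Gibbs) and logistic scores for arbitrary predictor rows
maxent_scores <- function(model, values, type = c("logistic", "raw")) {
  type <- match.arg(type)
  scaled <- sweep(sweep(values, 2, model$rng[1, ]), 2, model$span, "/")
  f <- build_features(scaled)
  eta <- as.vector(f %*% model$lambda)
  q <- exp(eta - model$log_z)
  if (type == "raw") return(q)
  eh <- exp(model$entropy)
  eh * q / (1 + eh * q)
}

#' Predict habitat suitability over the stack
#'
#' @param object A `maxent_model`.
#' @param rasters The predictor stack (defaults must match the fitted grid).
#' @param type `"logistic"` (0-1 suitability) or `"raw"` (Gibbs density).
#' @param ... Unused.
#' @return An `env_raster` of predictions (missing where predictors are).
#' @export
predict.maxent_model <- function(object, rasters, type = "logistic", ...) {
  sv <- stack_values(rasters)
  out <- rep(NA_real_, length(sv$lon))
  ok <- rowSums(!is.finite(sv$values)) == 0
  out[ok] <- maxent_scores(object, sv$values[ok, , drop = FALSE], type = type)
  z <- matrix(out, nrow = length(sv$grid$lat), ncol = length(sv$grid$lon),
              byrow = TRUE)
  env_raster(paste0("suitability_", type), sv$grid$lon, sv$grid$lat, z)
}

#' Presence-versus-background AUC
#'
#' Area under the ROC curve for presence scores against background scores
#' (rank / Mann-Whitney form, identical to the trapezoidal rule with ties
#' shared).
#' @param pres,bg Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_presence_background <- function(pres, bg) {
  r <- rank(c(pres, bg))
  np <- length(pres)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(bg))
}

auc_category <- function(auc) {
  if (auc > 0.90) "excellent"
  else if (auc > 0.80) "good"
  else if (auc > 0.70) "acceptable"
  else if (auc > 0.60) "bad"
  else "invalid"
}

#' Replicated evaluation of the habitat model
#'
#' Repeats `replicates` random 70/30 presence splits: fits on the training
#' fraction, scores held-out presences against the background, and records
#' the test AUC. Returns the replicate-mean suitability raster and its
#' coefficient of variation, percent contributions (normalized positive
#' penalized-gain increments per variable along the optimization path),
#' permutation contributions (normalized AUC drop when a variable is
#' permuted across the test presences and background), and jackknife gains
#' (each variable alone / all but that variable, on the full presence set).
#'
#' @param presences Lon/lat presence points.
#' @param rasters Named predictor stack.
#' @param replicates Number of random splits.
#' @param test_fraction Held-out fraction per replicate.
#' @param seed Integer seed; the whole evaluation is a pure function of it.
#' @param reg Regularization multiplier passed to [fit_maxent()].
#' @return A `habitat_evaluation` list; see Details.
#' @export
evaluate_habitat_model <- function(presences, rasters, replicates = 50,
                                   test_fraction = 0.30, seed = 1, reg = 1.0) {
  pts <- as.matrix(presences)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  n_test <- max(1, round(test_fraction * n))
  sv <- stack_values(rasters)
  ok_bg <- rowSums(!is.finite(sv$values)) == 0
  bg_vals <- sv$values[ok_bg, , drop = FALSE]
  p <- ncol(bg_vals)
  var_names <- colnames(bg_vals)

  aucs <- numeric(0)
  pred_sum <- pred_sq <- 0
  pct_list <- list(); perm_list <- list()
  with_seed(seed, {
    for (rep_i in seq_len(replicates)) {
      test_idx <- sample(n, n_test)
      train <- pts[-test_idx, , drop = FALSE]
      test <- pts[test_idx, , drop = FALSE]
      if (nrow(test) < 2) { warning("replicate ", rep_i,
                                    " skipped: < 2 test presences"); next }
      model <- fit_maxent(train, rasters, reg = reg)
      bg_scores <- maxent_scores(model, bg_vals)
      ti <- cell_index(sv$grid, test[, 1], test[, 2])
      test_vals <- sv$values[ti, , drop = FALSE]
      keep <- rowSums(!is.finite(test_vals)) == 0
      test_vals <- test_vals[keep, , drop = FALSE]
      if (nrow(test_vals) < 2) { warning("replicate ", rep_i,
                                         " skipped: < 2 scorable test presences"); next }
      test_scores <- maxent_scores(model, test_vals)
      auc <- auc_presence_background(test_scores, bg_scores)
      aucs <- c(aucs, auc)

      pred <- rep(NA_real_, length(sv$lon)); pred[ok_bg] <- bg_scores
      pred_sum <- pred_sum + pred; pred_sq <- pred_sq + pred^2

      g <- model$var_gain
      pct_list[[length(pct_list) + 1]] <-
        if (sum(g) > 0) 100 * g / sum(g) else rep(100 / p, p)

      drops <- numeric(p)
      comb <- rbind(test_vals, bg_vals)
      n_t <- nrow(test_vals)
      for (v in seq_len(p)) {
        perm <- comb
        perm[, v] <- perm[sample(nrow(perm)), v]
        s <- maxent_scores(model, perm)
        drops[v] <- max(0, auc - auc_presence_background(s[seq_len(n_t)],
                                                         s[-seq_len(n_t)]))
      }
      perm_list[[length(perm_list) + 1]] <-
        if (sum(drops) > 0) 100 * drops / sum(drops) else rep(100 / p, p)
    }
  })
  if (!length(aucs)) stop("no replicate produced an AUC")

  k <- length(aucs)
  mean_pred <- pred_sum / k
  sd_pred <- sqrt(pmax(pred_sq / k - mean_pred^2, 0))
  to_raster <- function(v, nm) {
    env_raster(nm, sv$grid$lon, sv$grid$lat,
               matrix(v, nrow = length(sv$grid$lat), byrow = TRUE))
  }
  norm100 <- function(lst) {
    m <- colMeans(do.call(rbind, lst))
    setNames(100 * m / sum(m), var_names)
  }

  jk <- jackknife_gains(pts, rasters, reg = reg)

  structure(list(
    auc = aucs, mean_auc = mean(aucs), auc_category = auc_category(mean(aucs)),
    mean_prediction = to_raster(mean_pred, "mean_suitability"),
    cv_prediction = to_raster(ifelse(mean_pred > 0, sd_pred / mean_pred, NA),
                              "cv_suitability"),
    pct_contribution = norm100(pct_list),
    permutation_contribution = norm100(perm_list),
    jackknife = jk, replicates_used = k,
    seed = seed, test_fraction = test_fraction),
    class = "habitat_evaluation")
}

#' @export
print.habitat_evaluation <- function(x, ...) {
  cat("<habitat_evaluation>", x$replicates_used, "replicates; mean test AUC",
      round(x$mean_auc, 3), paste0("(", x$auc_category, ")"), "\n")
  top <- names(sort(x$pct_contribution, decreasing = TRUE))[1]
  cat("  top contribution:", top,
      sprintf("(%.1f%%)", max(x$pct_contribution)), "\n")
  invisible(x)
}

## training-gain (penalized log-likelihood above the uniform null, nats per
## presence) with each variable alone and with each variable dropped
jackknife_gains <- function(pts, rasters, reg = 1.0) {
  vn <- vapply(rasters, function(r) r$name, character(1))
  gain_of <- function(rs) {
    m <- fit_maxent(pts, rs, reg = reg)
    null_obj <- -log(sum(m$ok_bg))
    m$objective - null_obj
  }
  full <- gain_of(rasters)
  alone <- vapply(seq_along(rasters), function(i) gain_of(rasters[i]), numeric(1))
  without <- if (length(rasters) > 1)
    vapply(seq_along(rasters), function(i) gain_of(rasters[-i]), numeric(1))
  else rep(NA_real_, length(rasters))
  data.frame(variable = vn, gain_alone = alone, gain_without = without,
             gain_full = full, stringsAsFactors = FALSE)
}
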