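#' Standard ellipse of a bivariate isotope sample
#'
#' The standard ellipse of a (d13C, d15N) sample is the 1-SD Mahalanobis
#' ellipse of the fitted bivariate normal; its area SEA = pi * sqrt(l1 * l2)
#' with l1, l2 the eigenvalues of the sample covariance. SEAc applies the
#' small-sample correction (n - 1) / (n - 2), the convention of the
#' isotope-niche literature.
#'
#' @param samples Data frame or matrix with columns `d13C` and `d15N`.
#' @return A `niche_ellipse`: mean vector, covariance, `n`, `SEA`, `SEAc`
#'   (both per-mil squared).
#' @export
standard_ellipse <- function(samples) {
  m <- iso_matrix(samples)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples")
  S <- cov(m)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("degenerate (collinear) sample covariance")
  sea <- pi * sqrt(prod(ev))
  structure(list(mean = colMeans(m), cov = S, n = n,
                 SEA = sea, SEAc = sea * (n - 1) / (n - 2)),
            class = "niche_ellipse")
}

#' @export
print.niche_ellipse <- function(x, ...) {
  cat(sprintf("<niche_ellipse> n = %d, SEA = %.3f, SEAc = %.3f (permil^2)\n",
              x$n, x$SEA, x$SEAc))
  invisible(x)
}

iso_matrix <- function(samples) {
  if (is.matrix(samples)) {
    m <- samples[, 1:2, drop = FALSE]
  } else {
    if (!all(c("d13C", "d15N") %in% names(samples)))
      stop("samples need columns d13C and d15N")
    m <- cbind(samples$d13C, samples$d15N)
  }
  if (!all(is.finite(m))) stop("non-finite isotope values")
  colnames(m) <- c("d13C", "d15N")
  m
}

#' Bayesian posterior of the standard ellipse area (SEA_B)
#'
#' Draws covariance matrices from the conjugate normal-inverse-Wishart
#' posterior under a weakly informative prior (identity scale matrix,
#' degrees of freedom = dimension + 1 = 3, kappa0 = 1e-3, mu0 = 0) and
#' converts each draw to a standard-ellipse area. Inverse-Wishart draws use
#' the Bartlett decomposition, so the draw sequence is a pure function of
#' the seed.
#'
#' @param samples Data frame/matrix with `d13C`, `d15N` (n >= 4).
#' @param n_draws Number of posterior draws.
#' @param seed Integer seed.
#' @return A `posterior_ellipses`: vector of `areas` (per-mil squared) plus
#'   posterior parameters.
#' @export
sea_bayes <- function(samples, n_draws = 1e4, seed = 1) {
  m <- iso_matrix(samples)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 samples")
  xbar <- colMeans(m)
  Sn <- crossprod(sweep(m, 2, xbar))           # scatter about the mean
  mu0 <- c(0, 0); kappa0 <- 1e-3; nu0 <- 3; Psi0 <- diag(2)
  nu_n <- nu0 + n
  Psi_n <- Psi0 + Sn +
    (kappa0 * n / (kappa0 + n)) * tcrossprod(xbar - mu0)
  Psi_inv_chol <- chol(solve(Psi_n))
  areas <- with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      W <- rwishart_chol(nu_n, Psi_inv_chol)   # Wishart(nu_n, Psi_n^-1)
      Sigma <- chol2inv(chol(W))               # inverse-Wishart(nu_n, Psi_n)
      pi * sqrt(max(det(Sigma), 0))
    }, numeric(1))
  })
  structure(list(areas = areas, n = n, nu_n = nu_n, Psi_n = Psi_n,
                 n_draws = n_draws, seed = seed),
            class = "posterior_ellipses")
}

#' @export
print.posterior_ellipses <- function(x, ...) {
  q <- quantile(x$areas, c(0.025, 0.5, 0.975))
  cat(sprintf("<posterior_ellipses> %d draws; SEA_B median %.3f (95%% CrI %.3f-%.3f)\n",
              x$n_draws, q[2], q[1], q[3]))
  invisible(x)
}

## Wishart(nu, V) draw given chol(V), via Bartlett decomposition
rwishart_chol <- function(nu, V_chol) {
  d <- ncol(V_chol)
  A <- matrix(0, d, d)
  diag(A) <- sqrt(rchisq(d, df = nu - seq_len(d) + 1))
  A[upper.tri(A)] <- rnorm(d * (d - 1) / 2)
  U <- A %*% V_chol
  crossprod(U)
}

#' Posterior probability that niche A is smaller than niche B
#'
#' The proportion of paired posterior draws in which group A's ellipse area
#' is below group B's -- the Bayesian analogue of a one-sided comparison of
#' niche widths.
#'
#' @param post_a,post_b `posterior_ellipses` objects; unequal draw counts are
#'   truncated to the shorter.
#' @return Probability in \[0, 1\].
#' @export
compare_groups <- function(post_a, post_b) {
  a <- post_a$areas; b <- post_b$areas
  if (!length(a) || !length(b)) stop("empty posterior")
  k <- min(length(a), length(b))
  mean(a[seq_len(k)] < b[seq_len(k)])
}

#' Overlap between two standard ellipses
#'
#' Monte-Carlo estimate over the joint bounding box: uniform points are
#' classified against each ellipse (Mahalanobis radius <= 1) and the
#' intersection area is reported as a percentage of each ellipse and of the
#' union (the total niche width of both groups combined).
#'
#' @param e1,e2 `niche_ellipse` objects.
#' @param n_mc Number of Monte-Carlo points.
#' @param seed Integer seed.
#' @return List with `overlap_area`, `pct_of_e1`, `pct_of_e2`, `pct_of_union`.
#' @export
ellipse_overlap <- function(e1, e2, n_mc = 1e5, seed = 1) {
  bb <- ellipse_bbox(e1, e2)
  with_seed(seed, {
    px <- runif(n_mc, bb[1, 1], bb[1, 2])
    py <- runif(n_mc, bb[2, 1], bb[2, 2])
    in1 <- in_ellipse(px, py, e1)
    in2 <- in_ellipse(px, py, e2)
    box_area <- diff(bb[1, ]) * diff(bb[2, ])
    inter <- mean(in1 & in2) * box_area
    union <- mean(in1 | in2) * box_area
    a1 <- mean(in1) * box_area
    a2 <- mean(in2) * box_area
    list(overlap_area = inter,
         pct_of_e1 = if (a1 > 0) 100 * inter / a1 else 0,
         pct_of_e2 = if (a2 > 0) 100 * inter / a2 else 0,
         pct_of_union = if (union > 0) 100 * inter / union else 0)
  })
}

in_ellipse <- function(px, py, e) {
  d <- rbind(px - e$mean[1], py - e$mean[2])
  Q <- solve(e$cov)
  colSums(d * (Q %*% d)) <= 1
}

ellipse_bbox <- function(e1, e2) {
  ext <- function(e) {
    half <- sqrt(diag(e$cov))          # axis-aligned extent of the 1-SD ellipse
    rbind(e$mean[1] + c(-1, 1) * half[1] * 1.05,
          e$mean[2] + c(-1, 1) * half[2] * 1.05)
  }
  b1 <- ext(e1); b2 <- ext(e2)
  rbind(range(b1[1, ], b2[1, ]), range(b1[2, ], b2[2, ]))
}

#' Layman-style niche metrics
#'
#' d15N range (trophic-level breadth), d13C range (basal-resource
#' diversity), and total convex-hull area TA of the isotope biplot
#' (shoelace formula on the hull vertices).
#'
#' @param samples Data frame/matrix with `d13C`, `d15N` (n >= 3).
#' @return List with `d15N_range`, `d13C_range`, `TA`.
#' @export
layman_metrics <- function(samples) {
  m <- iso_matrix(samples)
  if (nrow(m) < 3) stop("need at least 3 samples")
  hull <- grDevices::chull(m)
  ta <- polygon_area(m[hull, , drop = FALSE])
  if (ta == 0) warning("collinear points: hull area is 0")
  list(d15N_range = diff(range(m[, "d15N"])),
       d13C_range = diff(range(m[, "d13C"])),
       TA = ta)
}
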