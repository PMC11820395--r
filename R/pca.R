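#' PCA projection of samples
#'
#' Mean-centers features (no variance scaling by default: the inputs are
#' already log-scale and batch-corrected) and projects samples onto the
#' leading principal components. Components are oriented so each one's
#' largest-magnitude loading is positive, making score plots reproducible.
#'
#' @param m `sebum_matrix` at stage `top_selected`, or a samples x features
#'   numeric matrix.
#' @param n_components components to return.
#' @param scale. also scale features to unit variance (sensitivity option).
#' @return A `pca_result`: `scores` (samples x components),
#'   `var_explained` (fractions, non-increasing), `rotation`, `center`.
#' @export
pca_projection <- function(m, n_components = 2, scale. = FALSE) {
  if (inherits(m, "sebum_matrix")) {
    assert_stage(m, "top_selected")
    x <- t(as.matrix(m$values))
    rownames(x) <- m$sample_ids
  } else {
    x <- as.matrix(m)
  }
  if (nrow(x) < 3) stop("PCA needs at least 3 samples")
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 rotation = rot, center = pc$center),
            class = "pca_result")
}

#' @export
#' @method print pca_result
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Normal-probability concentration ellipses per group
#'
#' For each group of 2-D scores, derives the ellipse containing `level`
#' probability mass of a bivariate normal with the group's mean and
#' covariance: axes are the covariance eigenvectors, semi-axis lengths
#' sqrt(eigenvalue x qchisq(level, 2)).
#'
#' @param scores samples x 2 numeric matrix (e.g. `pca_result$scores`).
#' @param groups group label per sample (>= 3 samples per group).
#' @param level probability level.
#' @return A list per group: `center`, `semi_axes` (major, minor), `angle`
#'   (radians, major axis vs x), `level`, `cov`.
#' @export
group_ellipse <- function(scores, groups, level = 0.95) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  groups <- as.character(groups)
  r2 <- stats::qchisq(level, df = 2)
  out <- lapply(split(seq_len(nrow(scores)), groups), function(idx) {
    if (length(idx) < 3) stop("each group needs at least 3 samples")
    pts <- scores[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    S <- stats::cov(pts)
    eig <- eigen(S, symmetric = TRUE)
    vals <- eig$values
    if (any(vals < .Machine$double.eps * max(abs(vals), 1))) {
      warning("degenerate score covariance: ellipse axis floored at 0")
      vals <- pmax(vals, 0)
    }
    list(center = ctr, semi_axes = sqrt(vals * r2),
         angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
         level = level, cov = S)
  })
  out
}

#' Points on a concentration ellipse boundary
#'
#' Convenience for plotting the ellipses from [group_ellipse()].
#'
#' @param ellipse one element of a [group_ellipse()] result.
#' @param n number of boundary points.
#' @return An n x 2 matrix of (x, y) coordinates.
#' @export
ellipse_points <- function(ellipse, n = 100) {
  theta <- seq(0, 2 * pi, length.out = n)
  unit <- rbind(ellipse$semi_axes[1] * cos(theta),
                ellipse$semi_axes[2] * sin(theta))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  t(rot %*% unit + ellipse$center)
}
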