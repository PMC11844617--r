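# Agreement metrics between fields and point sets.

#' Componentwise relative L2 error (%)
#'
#' `100 * ||test - ref||_2 / ||ref||_2` per column over matched points.
#'
#' @param test,reference Matrices (or vectors) of matched field values.
#' @return Named vector of percent errors, one per component.
#' @export
l2_relative_error <- function(test, reference) {
  test <- as.matrix(test); reference <- as.matrix(reference)
  stopifnot(all(dim(test) == dim(reference)))
  100 * sqrt(colSums((test - reference)^2) / colSums(reference^2))
}

# pairwise Euclidean distances between rows of two point sets
pairwise_dist <- function(P, R) {
  P <- as.matrix(P); R <- as.matrix(R)
  d2 <- outer(rowSums(P^2), rowSums(R^2), "+") - 2 * P %*% t(R)
  sqrt(pmax(d2, 0))
}

#' Mean symmetric distance between two point sets
#'
#' `MSD = 1/2 (mean_p min_r ||p - r|| + mean_r min_p ||p - r||)`: the
#' average nearest-neighbor distance from P to R and from R to P.
#'
#' @param P,R Point sets (rows).
#' @return Scalar distance (length units of the inputs).
#' @export
mean_symmetric_distance <- function(P, R) {
  D <- pairwise_dist(P, R)
  0.5 * (mean(apply(D, 1, min)) + mean(apply(D, 2, min)))
}

#' 95th-percentile Hausdorff distance
#'
#' Directed nearest-neighbor distances are computed in both directions; by
#' default they are pooled and the 95th percentile of the pooled sample is
#' returned (symmetric).  `direction = "max"` instead takes the maximum of
#' the two directed 95th percentiles.  Percentiles use linear
#' interpolation.
#'
#' @param P,R Point sets (rows).
#' @param prob Percentile (default 0.95).
#' @param direction `"pooled"` (default) or `"max"`.
#' @return Scalar distance.
#' @export
hausdorff95 <- function(P, R, prob = 0.95,
                        direction = c("pooled", "max")) {
  direction <- match.arg(direction)
  D <- pairwise_dist(P, R)
  dPR <- apply(D, 1, min)
  dRP <- apply(D, 2, min)
  if (direction == "pooled")
    unname(quantile(c(dPR, dRP), prob, names = FALSE))
  else
    max(quantile(dPR, prob, names = FALSE), quantile(dRP, prob, names = FALSE))
}

#' Tangent modulus from a stress-strain point cloud
#'
#' Fits `sigma(eps) = a eps^2 + b eps + c` by least squares and returns the
#' slope `2 a eps_q + b` at the `q`-th percentile of strain (default the
#' 75th).
#'
#' @param strain,stress Numeric vectors (nodal strain/stress samples).
#' @param prob Strain percentile at which the slope is evaluated.
#' @return Scalar tangent modulus (stress units).
#' @export
tangent_modulus <- function(strain, stress, prob = 0.75) {
  stopifnot(length(strain) == length(stress), length(strain) >= 3)
  fit <- lm(stress ~ strain + I(strain^2))
  e75 <- quantile(strain, prob, names = FALSE)
  cf <- coef(fit)
  unname(2 * cf[3] * e75 + cf[2])
}

#' Mean-squared-error data loss
#'
#' Mean of squared componentwise residuals between predicted and reference
#' displacements (the data loss used by the 2D/3D benchmark trainings).
#'
#' @param predicted,reference Matched matrices.
#' @return Scalar loss.
#' @export
data_loss_mse <- function(predicted, reference) {
  mean((as.matrix(predicted) - as.matrix(reference))^2)
}

#' Mean-symmetric-distance data loss
#'
#' The MSD between predicted and reference deformed point sets, used as the
#' data loss when displacements derive from image intensities rather than
#' material points.  Identical to [mean_symmetric_distance()]; kept as a
#' named loss for the training configuration.
#'
#' @param predicted_points,reference_points Deformed point sets.
#' @return Scalar loss.
#' @export
data_loss_msd <- function(predicted_points, reference_points) {
  mean_symmetric_distance(predicted_points, reference_points)
}

# MSD value + gradient with respect to the predicted points (used by the
# membrane training loop; nearest neighbors treated as locally constant)
msd_with_grad <- function(P, R) {
  D <- pairwise_dist(P, R)
  iPR <- apply(D, 1, which.min)
  dPR <- D[cbind(seq_len(nrow(P)), iPR)]
  iRP <- apply(D, 2, which.min)
  dRP <- D[cbind(iRP, seq_len(nrow(R)))]
  val <- 0.5 * (mean(dPR) + mean(dRP))
  G <- matrix(0, nrow(P), ncol(P))
  nz <- dPR > 0
  G[nz, ] <- 0.5 / nrow(P) *
    (P[nz, , drop = FALSE] - R[iPR[nz], , drop = FALSE]) / dPR[nz]
  nz2 <- which(dRP > 0)
  for (j in nz2) {
    i <- iRP[j]
    G[i, ] <- G[i, ] + 0.5 / nrow(R) * (P[i, ] - R[j, ]) / dRP[j]
  }
  list(value = val, grad = G)
}
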