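#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling (Gower): the squared distance matrix is double-
#' centered, \eqn{B = -\tfrac12 J D^2 J}, and eigendecomposed; coordinates
#' are eigenvectors scaled by the square roots of positive eigenvalues. For
#' Euclidean-embeddable distances the coordinates reproduce the input
#' exactly. Negative eigenvalues (common for Hamming distances, which need
#' not be Euclidean) are reported, excluded from variance proportions, and
#' noted via a message — never silently dropped.
#'
#' @param d a `"hap_dist"` (its p-distance matrix is used), a `dist`, or a
#'   symmetric numeric matrix with zero diagonal.
#' @param n_axes number of coordinate axes to return (default: all axes with
#'   positive eigenvalue).
#' @return object of class `"wolbscan_pcoa"`: `coordinates` (objects x
#'   axes, centered), `eigenvalues` (all, decreasing), `prop_var`
#'   (proportions over positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = NULL) {
  if (inherits(d, "hap_dist")) d <- d$p
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("o", seq_len(n))
  d2 <- d^2
  rm_ <- rowMeans(d2); gm <- mean(d2)
  b <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen(b, symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(abs(ev)) * 1e-10
  if (any(ev < -max(abs(ev), 1e-300) * 1e-10)) {
    message("pcoa: ", sum(ev < 0), " negative eigenvalue(s); distances are not ",
            "Euclidean-embeddable, negative axes excluded from variance proportions")
  }
  k <- n_axes %||% sum(pos)
  k <- min(k, sum(pos))
  coords <- e$vectors[, which(pos)[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[which(pos)[seq_len(k)]]), k, k)
  rownames(coords) <- labels
  colnames(coords) <- if (k > 0) paste0("PCo", seq_len(k)) else character()
  out <- list(coordinates = coords,
              eigenvalues = ev,
              prop_var = if (any(pos)) ev[pos] / sum(ev[pos]) else numeric())
  class(out) <- "wolbscan_pcoa"
  out
}

#' @export
print.wolbscan_pcoa <- function(x, ...) {
  cat(sprintf("pcoa: %d objects, %d positive axes; first axes explain %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * head(x$prop_var, 3)), collapse = ", ")))
  invisible(x)
}

#' Within- and between-strain sequence divergence table
#'
#' Uncorrected percent sequence divergence (p x 100) with standard
#' deviations, within each strain (over unordered haplotype pairs) and
#' between strain pairs (over all cross pairs). By default pairs are
#' weighted per distinct haplotype; `weight = "individual"` weights each
#' haplotype pair by the product (within: unordered combination count) of
#' carrying-individual multiplicities.
#'
#' @param dist a `"hap_dist"` over haplotypes.
#' @param assignment a [assign_strains()] result (or data.frame `haplotype`,
#'   `strain`).
#' @param strains which strains to tabulate (default: major strains if an
#'   assignment object is given, else all).
#' @param weight `"haplotype"` or `"individual"`.
#' @param multiplicities named vector, required for individual weighting.
#' @return list of class `"divergence_table"`: `mean` and `sd` matrices
#'   (percent), lower triangle + diagonal; single-haplotype strains have
#'   `NA` within-strain entries.
#' @export
divergence_table <- function(dist, assignment, strains = NULL,
                             weight = c("haplotype", "individual"),
                             multiplicities = NULL) {
  weight <- match.arg(weight)
  hs <- if (inherits(assignment, "strain_assignment")) assignment$haplotype_strain
        else assignment
  stopifnot(all(c("haplotype", "strain") %in% names(hs)))
  if (is.null(strains)) {
    strains <- if (inherits(assignment, "strain_assignment")) {
      assignment$strains$strain[assignment$strains$major]
    } else sort(unique(hs$strain))
  }
  if (weight == "individual" && is.null(multiplicities)) {
    stop("individual weighting requires multiplicities")
  }
  p <- dist$p * 100
  k <- length(strains)
  mu <- matrix(NA_real_, k, k, dimnames = list(strains, strains))
  sd_ <- mu
  wmean_sd <- function(vals, w) {
    if (length(vals) == 0L || sum(w) == 0) return(c(NA_real_, NA_real_))
    m <- sum(vals * w) / sum(w)
    v <- sum(w * (vals - m)^2) / sum(w)
    c(m, sqrt(v))
  }
  for (i in seq_len(k)) {
    for (jj in seq_len(i)) {
      hi <- hs$haplotype[hs$strain == strains[i]]
      hj <- hs$haplotype[hs$strain == strains[jj]]
      hi <- intersect(hi, dist$labels); hj <- intersect(hj, dist$labels)
      if (i == jj) {
        if (length(hi) < 2L) next
        cmb <- utils::combn(hi, 2)
        vals <- p[cbind(cmb[1, ], cmb[2, ])]
        w <- if (weight == "individual") {
          as.numeric(multiplicities[cmb[1, ]]) * as.numeric(multiplicities[cmb[2, ]])
        } else rep(1, length(vals))
      } else {
        grid <- expand.grid(a = hi, b = hj, stringsAsFactors = FALSE)
        vals <- p[cbind(grid$a, grid$b)]
        w <- if (weight == "individual") {
          as.numeric(multiplicities[grid$a]) * as.numeric(multiplicities[grid$b])
        } else rep(1, length(vals))
      }
      ms <- wmean_sd(vals, w)
      mu[i, jj] <- ms[1]
      sd_[i, jj] <- ms[2]
    }
  }
  out <- list(mean = mu, sd = sd_, weight = weight)
  class(out) <- "divergence_table"
  out
}

#' @export
print.divergence_table <- function(x, digits = 1, ...) {
  cat("percent sequence divergence (p x 100), mean (sd):\n")
  k <- nrow(x$mean)
  for (i in seq_len(k)) {
    row <- vapply(seq_len(i), function(j) {
      if (is.na(x$mean[i, j])) "--"
      else sprintf("%.*f (%.*f)", digits, x$mean[i, j], digits,
                   ifelse(is.na(x$sd[i, j]), 0, x$sd[i, j]))
    }, "")
    cat(rownames(x$mean)[i], "\t", paste(row, collapse = "\t"), "\n")
  }
  invisible(x)
}
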