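#' Pairwise Bray-Curtis dissimilarity
#'
#' For sites j and k with abundances x_ij, d_jk = sum_i |x_ij - x_ik| /
#' sum_i (x_ij + x_ik): 0 for identical composition, 1 for disjoint
#' support.
#'
#' @param x a [community_matrix()] or a sites x species abundance matrix
#'   (>= 2 sites, no all-zero site).
#' @return symmetric dissimilarity matrix in `[0, 1]` with zero diagonal;
#'   site coordinates, when available, are kept in `attr(, "coords")`.
#' @export
bray_curtis <- function(x) {
  coords <- NULL
  if (inherits(x, "community_matrix")) {
    coords <- x$coords
    x <- x$counts
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 sites")
  zero <- rowSums(x) == 0
  if (any(zero))
    stop("all-zero abundance at site(s): ",
         paste(utils::head(rownames(x)[zero] %||% which(zero), 5),
               collapse = ", "))
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  den <- outer(rowSums(x), rowSums(x), `+`)
  d <- num / den
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "coords") <- coords
  d
}

#' Number of unordered site pairs
#'
#' @param n number of sites (>= 2).
#' @return n(n-1)/2.
#' @export
pair_count <- function(n) {
  if (n < 2) stop("need at least 2 sites")
  n * (n - 1) / 2
}

#' Mantel test between two distance matrices
#'
#' The Mantel statistic Mr is the Pearson correlation between the upper
#' triangles of the two matrices; significance comes from a two-sided
#' permutation test that permutes rows and columns of `dy` jointly,
#' respecting the non-independence of dissimilarities. With random
#' permutations the p-value uses the add-one estimator
#' (1 + #{|Mr*| >= |Mr|}) / (n_perm + 1); with `exact = TRUE` all n!
#' relabelings are enumerated (small n only) and the p-value is the exact
#' fraction of relabelings (including the identity) at least as extreme as
#' the observed statistic.
#'
#' @param dx,dy square symmetric matrices over the same sites in the same
#'   order.
#' @param n_perm number of random permutations (ignored when exact).
#' @param seed integer seed for the permutations.
#' @param exact enumerate all permutations (requires n <= 8).
#' @return object of class `mantel_result`: `statistic` (Mr), `p.value`,
#'   `n_perm`, `seed`.
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = NULL, exact = FALSE) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  n <- nrow(dx)
  stopifnot(nrow(dy) == n, ncol(dx) == n, ncol(dy) == n, n >= 3)
  ut <- upper.tri(dx)
  a <- dx[ut]
  if (stats::sd(a) == 0 || stats::sd(dy[ut]) == 0)
    stop("constant upper triangle: Mantel correlation undefined")
  r_obs <- stats::cor(a, dy[ut])
  eps <- 1e-12
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_perms(n)
    r_perm <- vapply(perms, function(p) stats::cor(a, dy[p, p][ut]),
                     numeric(1))
    p <- mean(abs(r_perm) >= abs(r_obs) - eps)
    n_used <- length(perms)
  } else {
    stopifnot(n_perm >= 1)
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(a, dy[p, p][ut])
    }, numeric(1)))
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - eps)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = r_obs, p.value = p, n_perm = n_used,
                 seed = seed, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test: Mr = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p.value, digits = 4),
      if (x$exact) " (exact, " else " (", x$n_perm,
      if (x$exact) " relabelings)\n" else " permutations)\n", sep = "")
  invisible(x)
}

# All permutations of 1..n as a list (n! entries; guard small n upstream).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Sturges' rule for distance-class counts
#'
#' @param n_pairs number of pairwise distances (>= 1).
#' @return ceiling(1 + log2(n_pairs)).
#' @export
sturges_classes <- function(n_pairs) {
  stopifnot(n_pairs >= 1)
  as.integer(ceiling(1 + log2(n_pairs)))
}

#' Mantel correlogram with bootstrap confidence intervals
#'
#' Splits the pairwise geographic distances into equal-width classes (count
#' from [sturges_classes()] by default) and computes, for each class, the
#' Mantel correlation between the dissimilarity matrix and the class
#' membership indicator. The sign convention makes positive Mr mean
#' positive spatial autocorrelation: sites in that distance class are more
#' similar than expected by chance (within-class dissimilarities below
#' background), which is achieved by negating the raw correlation with the
#' 0/1 membership coding. Confidence intervals come from resampling sites
#' with replacement `n_boot` times (pairs formed by duplicated sites, whose
#' geographic distance is zero, are excluded) and taking the 2.5/97.5
#' percentiles of the class Mr values.
#'
#' @param d dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param coords site coordinates in metres (n x 2); taken from
#'   `attr(d, "coords")` when missing.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param n_class number of distance classes (default: Sturges).
#' @return object of class `mantel_correlogram`: data.frame with `class`,
#'   `lower`, `upper` (class distance bounds, m), `midpoint`, `mr`,
#'   `ci_lo`, `ci_hi` and `n_pairs`.
#' @export
mantel_correlogram <- function(d, coords = NULL, n_boot = 500, seed = NULL,
                               n_class = NULL) {
  coords <- coords %||% attr(d, "coords")
  if (is.null(coords)) stop("site coordinates are required")
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 sites for a correlogram")
  stopifnot(nrow(coords) == n, all(is.finite(coords)))
  geo <- as.matrix(stats::dist(coords))
  np <- pair_count(n)
  K <- n_class %||% sturges_classes(np)
  breaks <- seq(0, max(geo), length.out = K + 1)

  ut <- upper.tri(d)
  cls_full <- class_of(geo[ut], breaks)
  mr <- class_mr(d[ut], cls_full, K)
  n_pairs <- tabulate(cls_full, nbins = K)

  boot <- with_seed(seed, {
    if (n_boot > 0) {
      t(vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, replace = TRUE)
        keep <- outer(idx, idx, `!=`)[ut] # drop duplicate-site zero pairs
        db <- d[idx, idx][ut][keep]
        gb <- geo[idx, idx][ut][keep]
        class_mr(db, class_of(gb, breaks), K)
      }, numeric(K)))
    } else matrix(NA_real_, 0, K)
  })
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)

  out <- data.frame(class = seq_len(K),
                    lower = breaks[-(K + 1)], upper = breaks[-1],
                    midpoint = (breaks[-(K + 1)] + breaks[-1]) / 2,
                    mr = mr,
                    ci_lo = if (n_boot > 0) ci[1, ] else NA_real_,
                    ci_hi = if (n_boot > 0) ci[2, ] else NA_real_,
                    n_pairs = n_pairs)
  structure(out, class = c("mantel_correlogram", "data.frame"),
            breaks = breaks, n_boot = n_boot, seed = seed)
}

# Assign distances to classes defined by `breaks` (first class includes its
# lower bound).
class_of <- function(g, breaks) {
  k <- findInterval(g, breaks, rightmost.closed = TRUE, left.open = TRUE)
  k[k == 0] <- 1L
  k
}

# Per-class Mantel correlation of dissimilarities with class membership,
# negated so that positive values mean within-class similarity excess.
class_mr <- function(dv, cls, K) {
  vapply(seq_len(K), function(k) {
    ind <- as.numeric(cls == k)
    if (sum(ind) == 0 || sum(ind) == length(ind) || stats::sd(dv) == 0)
      return(NA_real_)
    -stats::cor(dv, ind)
  }, numeric(1))
}
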